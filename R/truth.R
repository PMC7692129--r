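# Truth-set determination: which variants are evaluative (scored),
# informative (reported back but not scored) or not assessed, and which
# (participant, variant) observations are excluded because the laboratory's
# amplicon panel is incompatible with the insertion cassette used to
# engineer the variant into the cell line.

#' Consensus reporting threshold
#'
#' Smallest integer `k` such that `k / n >= fraction`, i.e. the number of
#' participants that must report a variant for it to reach consensus.
#'
#' @param n_participants Number of enrolled participants.
#' @param fraction Required fraction (default 2/3).
#' @return An integer threshold.
#' @examples
#' consensus_threshold(12) # 8
#' consensus_threshold(16) # 11
#' @export
consensus_threshold <- function(n_participants, fraction = 2 / 3) {
  stopifnot(n_participants >= 1, fraction > 0, fraction <= 1)
  as.integer(ceiling(fraction * n_participants - 1e-9))
}

#' Is a 1-based genomic position inside the regions of interest?
#'
#' Positions are converted to 0-based and checked against half-open
#' `[start, end)` intervals, so a position equal to an interval end is
#' outside. Reports lacking genomic coordinates cannot be checked and
#' return `FALSE` with a warning.
#'
#' @param chrom,pos Chromosome label(s) and 1-based position(s).
#' @param roi Interval tibble (`chrom`, `start`, `end`), 0-based half-open.
#' @return Logical vector.
#' @export
in_roi <- function(chrom, pos, roi) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(pos, n)
  out <- logical(n)
  missing_pos <- is.na(chrom) | is.na(pos)
  if (any(missing_pos)) {
    warning("position missing for ", sum(missing_pos),
            " variant(s); cannot check regions of interest", call. = FALSE)
  }
  if (!nrow(roi)) return(out)
  for (i in which(!missing_pos)) {
    p0 <- pos[i] - 1L
    out[i] <- any(roi$chrom == chrom[i] & roi$start <= p0 & p0 < roi$end)
  }
  out
}

# Canonical per-report keys, cached over unique (gene, p_hgvs, chrom, pos).
report_keys <- function(reports) {
  if (!nrow(reports)) return(character())
  variant_key(reports$gene, reports$p_hgvs, reports$chrom, reports$pos)
}

# Replicates excluded by an explicit invalid status, as a lookup tibble.
invalid_replicates <- function(statuses) {
  if (is.null(statuses) || !nrow(statuses)) return(empty_statuses())
  statuses[!statuses$valid, c("participant", "sample_id", "replicate")]
}

# Drop report rows that fall in explicitly invalidated replicates.
valid_reports <- function(reports, statuses = NULL) {
  inv <- invalid_replicates(statuses)
  if (!nrow(inv) || !nrow(reports)) return(reports)
  key_r <- paste(reports$participant, reports$sample_id, reports$replicate)
  key_i <- paste(inv$participant, inv$sample_id, inv$replicate)
  reports[!key_r %in% key_i, ]
}

#' Count participants reporting a variant
#'
#' A participant counts as reporting when the variant appears in at least
#' one valid replicate of the sample, matched through the canonical variant
#' key ([variant_key()]).
#'
#' @param reports Reports tibble.
#' @param key Canonical variant key.
#' @param sample_id Sample label.
#' @param statuses Optional replicate-status tibble.
#' @return Integer count of distinct reporting participants.
#' @export
count_reporting_participants <- function(reports, key, sample_id,
                                         statuses = NULL) {
  reports <- valid_reports(reports, statuses)
  if (!nrow(reports)) return(0L)
  keys <- report_keys(reports)
  hit <- !is.na(keys) & keys == key & reports$sample_id == sample_id
  length(unique(reports$participant[hit]))
}

validated_under_policy <- function(validation, policy) {
  validation <- as.character(validation)
  if (policy == "ddPCR_only") {
    validation %in% c("ddPCR", "both")
  } else {
    validation %in% c("ddPCR", "WES", "both")
  }
}

#' Classify candidate variants as evaluative, informative or not assessed
#'
#' Candidates are the union of the design's characterized variants and every
#' distinct variant key reported by any participant. A candidate is
#' *evaluative* when it is validated under the benchmark's validation
#' policy, lies inside the regions of interest, and was reported by at
#' least `consensus_threshold()` participants. A candidate inside the ROI
#' that was reported by at least one participant but fails the validation
#' or consensus bar is *informative*. Candidates outside the ROI, lacking a
#' genomic position, or reported by nobody are *not assessed*.
#'
#' @param design An [eqa_design()].
#' @param reports Reports tibble.
#' @param statuses Optional replicate-status tibble.
#' @return A tibble with one row per (sample, variant key) and columns
#'   `classification`, `reporting_count`, `participant_total`, `validated`,
#'   `in_roi`, `ordered`, `expected_af`, `origin`, cassette coordinates.
#' @export
classify_truth <- function(design, reports, statuses = NULL) {
  ov <- design$ordered_variants
  known <- tibble::tibble(
    sample_id = ov$sample_id, key = ov$key, gene = ov$gene,
    p_hgvs = canonical_p_hgvs(ov$p_hgvs),
    chrom = ov$chrom, pos = ov$pos,
    expected_af = ov$expected_af, validation = ov$validation,
    origin = ov$origin, cassette_start = ov$cassette_start,
    cassette_end = ov$cassette_end, ordered = ov$ordered, vus = ov$vus
  )

  vr <- valid_reports(reports, statuses)
  extras <- if (nrow(vr)) {
    keys <- report_keys(vr)
    rep_tab <- tibble::tibble(
      sample_id = vr$sample_id, key = keys, gene = toupper(vr$gene),
      p_hgvs = canonical_p_hgvs(vr$p_hgvs), chrom = vr$chrom, pos = vr$pos
    )
    rep_tab <- rep_tab[!is.na(rep_tab$key), ]
    rep_tab <- dplyr::summarise(
      dplyr::group_by(rep_tab, .data$sample_id, .data$key),
      gene = dplyr::first(.data$gene),
      p_hgvs = dplyr::first(.data$p_hgvs),
      chrom = dplyr::first(stats::na.omit(.data$chrom))[1],
      pos = dplyr::first(stats::na.omit(.data$pos))[1],
      .groups = "drop"
    )
    seen <- paste(known$sample_id, known$key)
    rep_tab <- rep_tab[!paste(rep_tab$sample_id, rep_tab$key) %in% seen, ]
    if (nrow(rep_tab)) {
      rep_tab$expected_af <- NA_real_
      rep_tab$validation <- "none"
      rep_tab$origin <- "endogenous"
      rep_tab$cassette_start <- NA_integer_
      rep_tab$cassette_end <- NA_integer_
      rep_tab$ordered <- FALSE
      rep_tab$vus <- FALSE
    }
    rep_tab
  } else {
    known[0, ]
  }

  cand <- dplyr::bind_rows(known, extras)
  if (!nrow(cand)) {
    cand$classification <- character()
    cand$reporting_count <- integer()
    cand$participant_total <- integer()
    cand$validated <- logical()
    cand$in_roi <- logical()
    return(cand)
  }

  n_part <- length(design$participants)
  threshold <- consensus_threshold(n_part, design$consensus_fraction)
  cand$reporting_count <- vapply(seq_len(nrow(cand)), function(i) {
    count_reporting_participants(vr, cand$key[i], cand$sample_id[i])
  }, integer(1))
  cand$participant_total <- n_part
  cand$validated <- validated_under_policy(cand$validation,
                                           design$validation_policy)
  cand$in_roi <- in_roi(cand$chrom, cand$pos, design$roi)
  cand$classification <- ifelse(
    cand$reporting_count == 0L | !cand$in_roi, "not_assessed",
    ifelse(cand$validated & cand$reporting_count >= threshold,
           "evaluative", "informative")
  )
  dplyr::arrange(cand, .data$sample_id, .data$key)
}

#' Mask observations incompatible with the insertion cassette
#'
#' Variants engineered into cell lines through a ~2 kb insertion cassette
#' cannot be amplified by an amplicon panel whose primers flank the
#' cassette: the amplicon would be ~2 kb longer than designed. An
#' observation (participant, sample, variant) is masked when the
#' participant's panel is amplicon-based and some panel interval contains
#' the variant position *and* strictly spans both cassette boundaries.
#' Masked observations are excluded from success-rate denominators and are
#' never counted as false negatives. Probe-based panels are never masked.
#'
#' @param design An [eqa_design()] whose inserted variants carry cassette
#'   footprints and whose panels carry amplicon intervals.
#' @return A tibble with `participant`, `sample_id`, `key`, `reason`.
#' @export
mask_incompatible <- function(design) {
  out <- tibble::tibble(participant = character(), sample_id = character(),
                        key = character(), reason = character())
  ov <- design$ordered_variants
  ins <- ov[ov$origin == "inserted", ]
  if (!nrow(ins) || !length(design$panels)) return(out)
  missing_panel <- setdiff(design$participants,
                           design$panel_assignments$participant)
  if (length(missing_panel)) {
    warning("no panel definition for participant(s): ",
            paste(missing_panel, collapse = ", "),
            "; no incompatibility masking applied to them", call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(ins))) {
    v <- ins[i, ]
    pos0 <- v$pos - 1L
    for (j in seq_len(nrow(design$panel_assignments))) {
      pa <- design$panel_assignments[j, ]
      panel <- design$panels[[pa$panel_id]]
      if (is.null(panel) || panel$enrichment != "amplicon") next
      iv <- panel$intervals
      spans <- iv$chrom == v$chrom &
        iv$start <= pos0 & pos0 < iv$end &
        iv$start < v$cassette_start & v$cassette_end < iv$end
      if (any(spans)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          participant = pa$participant, sample_id = v$sample_id,
          key = v$key, reason = "cassette_incompatibility"
        )
      }
    }
  }
  if (length(rows)) out <- dplyr::bind_rows(out, rows)
  dplyr::distinct(out)
}
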