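# Readers and writers for benchmark designs, participant submissions and
# interval files. All downstream modules consume the tibbles defined here.
#
# Coordinate conventions: genomic positions in designs and submissions are
# 1-based (VCF convention); all interval tables are 0-based half-open (BED
# convention). Conversion happens only in this module and in `in_roi()`.

SUBMISSION_COLUMNS <- c(
  "record_type", "participant", "sample_id", "replicate", "gene", "chrom",
  "pos", "ref_nt", "obs_nt", "c_hgvs", "transcript", "p_hgvs", "protein_ref",
  "variant_type", "interpretation", "af", "depth", "valid", "reason"
)

# Header synonyms accepted by the permissive submission reader.
.HEADER_SYNONYMS <- list(
  participant = c("participant", "lab", "laboratory", "participant_id", "lab_id"),
  sample_id = c("sample_id", "sample"),
  replicate = c("replicate", "rep", "triplicate"),
  gene = c("gene", "gene_name", "gene_symbol"),
  chrom = c("chrom", "chr", "chromosome"),
  pos = c("pos", "position", "start"),
  ref_nt = c("ref_nt", "ref", "reference", "reference_nucleotide"),
  obs_nt = c("obs_nt", "obs", "alt", "observed", "observed_nucleotide"),
  c_hgvs = c("c_hgvs", "hgvs_c", "dna_hgvs", "cdna"),
  transcript = c("transcript", "nm", "refseq_nm", "transcript_id"),
  p_hgvs = c("p_hgvs", "hgvs_p", "protein_hgvs", "p_hgvs_raw", "protein"),
  protein_ref = c("protein_ref", "np", "refseq_np"),
  variant_type = c("variant_type", "type"),
  interpretation = c("interpretation", "comment", "clinical_interpretation"),
  af = c("af", "vaf", "allelic_frequency", "allele_frequency", "frequency"),
  depth = c("depth", "coverage", "read_coverage", "dp", "reads"),
  record_type = c("record_type", "row_type"),
  valid = c("valid", "replicate_valid"),
  reason = c("reason", "invalid_reason", "qc_reason")
)

normalize_headers <- function(nms) {
  low <- tolower(trimws(nms))
  out <- low
  for (canon in names(.HEADER_SYNONYMS)) {
    out[low %in% .HEADER_SYNONYMS[[canon]]] <- canon
  }
  out
}

#' Read a BED interval file
#'
#' Parses BED3+ lines into a tibble of 0-based half-open intervals sorted by
#' chromosome and start. Track/browser/comment lines are skipped.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(empty_intervals())
  fields <- strsplit(trimws(lines[idx]), "[\t ]+")
  rows <- lapply(seq_along(idx), function(i) {
    f <- fields[[i]]
    line_no <- idx[i]
    if (length(f) < 3L) {
      stop("BED line ", line_no, ": fewer than 3 columns", call. = FALSE)
    }
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end)) {
      stop("BED line ", line_no, ": non-numeric coordinates", call. = FALSE)
    }
    if (start >= end) {
      stop("BED line ", line_no, ": start >= end (", f[2], " >= ", f[3], ")",
           call. = FALSE)
    }
    tibble::tibble(chrom = f[1], start = as.integer(start),
                   end = as.integer(end),
                   name = if (length(f) >= 4L) f[4] else NA_character_)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$chrom, .data$start, .data$end)
}

empty_intervals <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 name = character())
}

intervals_from_list <- function(x, what = "interval") {
  if (is.null(x) || !length(x)) return(empty_intervals())
  rows <- lapply(x, function(iv) {
    tibble::tibble(
      chrom = as.character(iv$chrom),
      start = as.integer(iv$start),
      end = as.integer(iv$end),
      name = if (!is.null(iv$name)) as.character(iv$name) else NA_character_
    )
  })
  out <- dplyr::bind_rows(rows)
  if (any(is.na(out$start) | is.na(out$end))) {
    stop("non-numeric coordinates in ", what, call. = FALSE)
  }
  if (any(out$start >= out$end)) stop(what, ": start >= end", call. = FALSE)
  dplyr::arrange(out, .data$chrom, .data$start, .data$end)
}

parse_fraction <- function(x, default = 2 / 3) {
  if (is.null(x)) return(default)
  if (is.numeric(x)) return(x)
  m <- regmatches(x, regexec("^([0-9.]+)\\s*/\\s*([0-9.]+)$", as.character(x)))[[1]]
  if (length(m)) return(as.numeric(m[2]) / as.numeric(m[3]))
  as.numeric(x)
}

#' Construct a validated benchmark design
#'
#' The design bundles everything fixed before submissions arrive: samples,
#' enrolled participants, the vendor-characterized variant list (ordered and
#' WES-known variants with validation evidence and expected allele
#' frequencies), scoring regions of interest, per-laboratory panel
#' definitions, and the scoring parameters (consensus fraction, |Z|
#' acceptance limit, minimum peer-group size, validation policy).
#'
#' @param benchmark_id Benchmark label, e.g. `"2017/1"`.
#' @param samples Tibble with `sample_id`, `cancer_context`,
#'   `replicate_count`, `targeted_genes` (list-column or character).
#' @param participants Character vector of unique participant identifiers.
#' @param ordered_variants Tibble of characterized variants; see Details.
#' @param roi Tibble of 0-based half-open intervals (`chrom`,`start`,`end`).
#' @param panels Named list of panel definitions: each a list with
#'   `panel_id`, `enrichment` (`"amplicon"` or `"probe"`), `intervals`
#'   (interval tibble).
#' @param panel_assignments Tibble with `participant`, `panel_id`.
#' @param consensus_fraction Fraction of participants required for consensus
#'   (default 2/3).
#' @param z_acceptance Maximum accepted |Z| (default 3.0).
#' @param peer_group_min Minimum reporters for Z allocation in peer-group
#'   mode (default 6).
#' @param validation_policy `"ddPCR_or_WES"` or `"ddPCR_only"` — which
#'   validation evidence makes a variant eligible as evaluative.
#'
#' @details `ordered_variants` columns: `sample_id`, `gene`, `transcript`,
#'   `protein_ref`, `p_hgvs`, `c_hgvs`, `chrom`, `pos` (1-based),
#'   `expected_af` (percent), `validation` (`ddPCR`/`WES`/`both`/`none`),
#'   `origin` (`endogenous`/`inserted`), `cassette_start`/`cassette_end`
#'   (0-based half-open footprint, required iff inserted), optional logical
#'   `ordered` (vendor-ordered vs merely characterized) and `vus`.
#'
#' @return An object of class `eqa_design`.
#' @export
eqa_design <- function(benchmark_id, samples, participants, ordered_variants,
                       roi = empty_intervals(), panels = list(),
                       panel_assignments = NULL,
                       consensus_fraction = 2 / 3, z_acceptance = 3.0,
                       peer_group_min = 6L,
                       validation_policy = c("ddPCR_or_WES", "ddPCR_only")) {
  validation_policy <- match.arg(validation_policy)
  samples <- tibble::as_tibble(samples)
  ordered_variants <- tibble::as_tibble(ordered_variants)
  participants <- as.character(participants)

  if (anyDuplicated(participants)) {
    stop("duplicate participant identifiers", call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in samples", call. = FALSE)
  }
  if (!"replicate_count" %in% names(samples)) samples$replicate_count <- 3L
  if (any(samples$replicate_count < 1L)) {
    stop("replicate_count must be >= 1", call. = FALSE)
  }
  if (!(consensus_fraction > 0 && consensus_fraction <= 1)) {
    stop("consensus_fraction must be in (0, 1]", call. = FALSE)
  }
  if (peer_group_min < 2L) stop("peer_group_min must be >= 2", call. = FALSE)

  ov <- ordered_variants
  for (col in c("transcript", "protein_ref", "c_hgvs")) {
    if (!col %in% names(ov)) ov[[col]] <- NA_character_
  }
  if (!"ordered" %in% names(ov)) ov$ordered <- TRUE
  if (!"vus" %in% names(ov)) ov$vus <- FALSE
  if (!"origin" %in% names(ov)) ov$origin <- "endogenous"
  if (!"cassette_start" %in% names(ov)) ov$cassette_start <- NA_integer_
  if (!"cassette_end" %in% names(ov)) ov$cassette_end <- NA_integer_
  bad_sample <- setdiff(ov$sample_id, samples$sample_id)
  if (length(bad_sample)) {
    stop("ordered variant references unknown sample: ",
         paste(bad_sample, collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(ov$expected_af) & ov$expected_af <= 0)) {
    stop("expected_af must be > 0 for characterized variants", call. = FALSE)
  }
  inserted <- ov$origin == "inserted"
  if (any(inserted & (is.na(ov$cassette_start) | is.na(ov$cassette_end)))) {
    stop("inserted variants must carry a cassette footprint", call. = FALSE)
  }
  if (any(!inserted & !is.na(ov$cassette_start))) {
    stop("cassette footprint only allowed for inserted variants", call. = FALSE)
  }
  ov$key <- variant_key(ov$gene, ov$p_hgvs, ov$chrom, ov$pos)

  if (length(panels)) {
    ids <- vapply(panels, function(p) p$panel_id, character(1))
    if (anyDuplicated(ids)) stop("duplicate panel_id", call. = FALSE)
    names(panels) <- ids
    for (p in panels) {
      if (!nrow(p$intervals)) stop("panel ", p$panel_id, " has no intervals",
                                   call. = FALSE)
      if (!p$enrichment %in% c("amplicon", "probe")) {
        stop("panel enrichment must be 'amplicon' or 'probe'", call. = FALSE)
      }
    }
  }
  if (is.null(panel_assignments)) {
    panel_assignments <- tibble::tibble(participant = character(),
                                        panel_id = character())
  } else {
    panel_assignments <- tibble::as_tibble(panel_assignments)
    unknown <- setdiff(panel_assignments$panel_id, names(panels))
    if (length(unknown)) {
      stop("panel assignment references unknown panel: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }

  structure(
    list(
      benchmark_id = benchmark_id,
      samples = samples,
      participants = participants,
      ordered_variants = ov,
      roi = tibble::as_tibble(roi),
      panels = panels,
      panel_assignments = panel_assignments,
      consensus_fraction = consensus_fraction,
      z_acceptance = z_acceptance,
      peer_group_min = as.integer(peer_group_min),
      validation_policy = validation_policy
    ),
    class = "eqa_design"
  )
}

#' @export
print.eqa_design <- function(x, ...) {
  cat("<eqa_design> benchmark", x$benchmark_id, "\n")
  cat("  participants:", length(x$participants),
      " samples:", nrow(x$samples),
      " characterized variants:", nrow(x$ordered_variants), "\n")
  cat("  consensus fraction:", format(x$consensus_fraction, digits = 4),
      " |Z| acceptance:", x$z_acceptance,
      " peer group min:", x$peer_group_min, "\n")
  invisible(x)
}

#' Read a benchmark design from a YAML file
#'
#' The design file is a YAML document with keys `benchmark_id`, `samples`,
#' `participants`, `ordered_variants`, `roi`, `panels`,
#' `panel_assignments`, and optional `consensus_fraction` (number or
#' `"2/3"`-style string, default 2/3), `z_acceptance` (default 3.0),
#' `peer_group_min` (default 6) and `validation_policy`.
#'
#' @param path Path to the YAML design file.
#' @param roi_bed Optional BED file overriding/replacing the inline `roi`.
#' @return An [eqa_design()] object with defaults applied.
#' @export
read_design <- function(path, roi_bed = NULL) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$benchmark_id)) stop("design: missing benchmark_id", call. = FALSE)
  if (is.null(raw$samples)) stop("design: missing samples", call. = FALSE)
  if (is.null(raw$participants)) stop("design: missing participants", call. = FALSE)

  samples <- dplyr::bind_rows(lapply(raw$samples, function(s) {
    tibble::tibble(
      sample_id = as.character(s$sample_id),
      cancer_context = as.character(s$cancer_context %||% NA_character_),
      replicate_count = as.integer(s$replicate_count %||% 3L),
      targeted_genes = list(as.character(s$targeted_genes %||% character()))
    )
  }))

  ov <- dplyr::bind_rows(lapply(raw$ordered_variants %||% list(), function(v) {
    tibble::tibble(
      sample_id = as.character(v$sample_id),
      gene = as.character(v$gene),
      transcript = as.character(v$transcript %||% NA_character_),
      protein_ref = as.character(v$protein_ref %||% NA_character_),
      p_hgvs = as.character(v$p_hgvs),
      c_hgvs = as.character(v$c_hgvs %||% NA_character_),
      chrom = as.character(v$chrom %||% NA_character_),
      pos = as.integer(v$pos %||% NA_integer_),
      expected_af = as.numeric(v$expected_af %||% NA_real_),
      validation = as.character(v$validation %||% "none"),
      origin = as.character(v$origin %||% "endogenous"),
      cassette_start = as.integer(v$cassette$start %||% NA_integer_),
      cassette_end = as.integer(v$cassette$end %||% NA_integer_),
      ordered = isTRUE(v$ordered %||% TRUE),
      vus = isTRUE(v$vus %||% FALSE)
    )
  }))

  roi <- if (!is.null(roi_bed)) read_bed(roi_bed) else
    intervals_from_list(raw$roi, "roi")

  panels <- lapply(raw$panels %||% list(), function(p) {
    list(panel_id = as.character(p$panel_id),
         enrichment = as.character(p$enrichment %||% "amplicon"),
         intervals = intervals_from_list(p$intervals, "panel interval"))
  })
  pa <- raw$panel_assignments %||% list()
  panel_assignments <- if (length(pa)) {
    tibble::tibble(participant = names(pa),
                   panel_id = vapply(pa, as.character, character(1)))
  } else NULL

  eqa_design(
    benchmark_id = as.character(raw$benchmark_id),
    samples = samples,
    participants = as.character(raw$participants),
    ordered_variants = ov,
    roi = roi,
    panels = panels,
    panel_assignments = panel_assignments,
    consensus_fraction = parse_fraction(raw$consensus_fraction),
    z_acceptance = as.numeric(raw$z_acceptance %||% 3.0),
    peer_group_min = as.integer(raw$peer_group_min %||% 6L),
    validation_policy = as.character(raw$validation_policy %||% "ddPCR_or_WES")
  )
}

empty_reports <- function() {
  tibble::tibble(
    participant = character(), sample_id = character(), replicate = integer(),
    gene = character(), chrom = character(), pos = integer(),
    ref_nt = character(), obs_nt = character(), c_hgvs = character(),
    transcript = character(), p_hgvs = character(), protein_ref = character(),
    variant_type = character(), interpretation = character(),
    af = numeric(), depth = integer()
  )
}

empty_statuses <- function() {
  tibble::tibble(participant = character(), sample_id = character(),
                 replicate = integer(), valid = logical(), reason = character())
}

#' Read participant submissions
#'
#' Submissions are exchanged as a single UTF-8 tab-separated table, one row
#' per reported variant per replicate. Column headers are matched
#' case-insensitively against common synonyms (`lab` for `participant`,
#' `vaf` for `af`, ...). Rows with `record_type = "status"` declare replicate
#' validity instead of a variant (columns `participant`, `sample_id`,
#' `replicate`, `valid`, `reason`); absence of any row for a replicate means
#' "nothing reported" and still counts against repeatability, whereas an
#' explicit invalid status removes the replicate from all denominators.
#'
#' @param path Path to the TSV file.
#' @param design Optional [eqa_design()]; when given, sample and participant
#'   identifiers are checked against it.
#' @return A list with `reports` and `statuses` tibbles.
#' @export
read_submissions <- function(path, design = NULL) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = c("", "NA"))
  if (!nrow(raw)) return(list(reports = empty_reports(), statuses = empty_statuses()))
  names(raw) <- normalize_headers(names(raw))
  required <- c("participant", "sample_id", "replicate")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("submissions: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in SUBMISSION_COLUMNS) if (!col %in% names(raw)) raw[[col]] <- NA_character_
  raw$record_type[is.na(raw$record_type)] <- "variant"
  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1

  is_status <- raw$record_type == "status"
  statuses <- tibble::tibble(
    participant = raw$participant[is_status],
    sample_id = raw$sample_id[is_status],
    replicate = as.integer(raw$replicate[is_status]),
    valid = !tolower(dplyr::coalesce(raw$valid[is_status], "true")) %in%
      c("false", "no", "0"),
    reason = raw$reason[is_status]
  )

  v <- raw[!is_status, ]
  vline <- line_no[!is_status]
  af <- suppressWarnings(as.numeric(v$af))
  bad <- which(!is.na(v$af) & (is.na(af) | af < 0 | af > 100))
  if (length(bad)) {
    stop("submissions line ", vline[bad[1]], ": allelic frequency '",
         v$af[bad[1]], "' outside [0, 100]", call. = FALSE)
  }
  depth <- suppressWarnings(as.integer(v$depth))
  badd <- which(!is.na(v$depth) & (is.na(depth) | depth < 0))
  if (length(badd)) {
    stop("submissions line ", vline[badd[1]], ": invalid read depth '",
         v$depth[badd[1]], "'", call. = FALSE)
  }
  reports <- tibble::tibble(
    participant = v$participant,
    sample_id = v$sample_id,
    replicate = as.integer(v$replicate),
    gene = v$gene,
    chrom = v$chrom,
    pos = suppressWarnings(as.integer(v$pos)),
    ref_nt = v$ref_nt,
    obs_nt = v$obs_nt,
    c_hgvs = v$c_hgvs,
    transcript = v$transcript,
    p_hgvs = v$p_hgvs,
    protein_ref = v$protein_ref,
    variant_type = v$variant_type,
    interpretation = v$interpretation,
    af = af,
    depth = depth
  )

  if (!is.null(design)) {
    bad_s <- setdiff(unique(c(reports$sample_id, statuses$sample_id)),
                     design$samples$sample_id)
    if (length(bad_s)) {
      stop("submissions reference unknown sample_id: ",
           paste(bad_s, collapse = ", "), call. = FALSE)
    }
    bad_p <- setdiff(unique(c(reports$participant, statuses$participant)),
                     design$participants)
    if (length(bad_p)) {
      stop("submissions reference unknown participant: ",
           paste(bad_p, collapse = ", "), call. = FALSE)
    }
  }
  list(reports = reports, statuses = statuses)
}

#' Write submissions to the canonical TSV interchange format
#'
#' Inverse of [read_submissions()]: the written file round-trips.
#'
#' @param reports Reports tibble.
#' @param path Output path.
#' @param statuses Optional replicate-status tibble.
#' @return `path`, invisibly.
#' @export
write_submissions <- function(reports, path, statuses = NULL) {
  rep_out <- reports
  rep_out$record_type <- "variant"
  rep_out$valid <- NA
  rep_out$reason <- NA_character_
  if (!is.null(statuses) && nrow(statuses)) {
    st <- empty_reports()[rep(1L, nrow(statuses)), ]
    st$participant <- statuses$participant
    st$sample_id <- statuses$sample_id
    st$replicate <- statuses$replicate
    st$record_type <- "status"
    st$valid <- statuses$valid
    st$reason <- statuses$reason
    rep_out <- dplyr::bind_rows(rep_out, st)
  }
  rep_out <- rep_out[, SUBMISSION_COLUMNS[SUBMISSION_COLUMNS %in% names(rep_out)]]
  readr::write_tsv(rep_out, path, progress = FALSE)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
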