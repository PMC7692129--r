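# Detection matrix, success rates, repeatability, false-negative cause
# classification, and Z-citation aggregation.

#' Round half-up
#'
#' Display rounding used throughout the reports (so 97.625 prints 97.63),
#' unlike base `round()`'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Build the detection matrix
#'
#' One record per (participant x sample x evaluative variant) with the
#' number of valid replicates (the sample's replicate count minus
#' explicitly invalidated replicates), the number of valid replicates in
#' which the participant reported the variant, the reported allele
#' frequencies, and an assessability flag taken from the incompatibility
#' mask.
#'
#' @param design An [eqa_design()].
#' @param reports Reports tibble.
#' @param truth Output of [classify_truth()].
#' @param statuses Optional replicate-status tibble.
#' @param mask Optional output of [mask_incompatible()].
#' @return A tibble of detection records.
#' @export
detection_matrix <- function(design, reports, truth, statuses = NULL,
                             mask = NULL) {
  ev <- truth[truth$classification == "evaluative", ]
  vr <- valid_reports(reports, statuses)
  keys <- report_keys(vr)
  inv <- invalid_replicates(statuses)
  rep_count <- stats::setNames(design$samples$replicate_count,
                               design$samples$sample_id)
  mask_key <- if (!is.null(mask) && nrow(mask)) {
    paste(mask$participant, mask$sample_id, mask$key)
  } else {
    character()
  }

  grid <- tidyr::expand_grid(participant = design$participants,
                             idx = seq_len(nrow(ev)))
  purrr::map_dfr(seq_len(nrow(grid)), function(r) {
    p <- grid$participant[r]
    t <- ev[grid$idx[r], ]
    n_invalid <- sum(inv$participant == p & inv$sample_id == t$sample_id)
    n_valid <- max(0L, unname(rep_count[t$sample_id]) - n_invalid)
    hit <- !is.na(keys) & keys == t$key & vr$sample_id == t$sample_id &
      vr$participant == p
    reps <- unique(vr$replicate[hit])
    tibble::tibble(
      participant = p, sample_id = t$sample_id, key = t$key,
      gene = t$gene, p_hgvs = t$p_hgvs, expected_af = t$expected_af,
      origin = t$origin,
      replicates_valid = as.integer(n_valid),
      replicates_reported = length(reps),
      reported_afs = list(vr$af[hit]),
      assessable = !(paste(p, t$sample_id, t$key) %in% mask_key)
    )
  })
}

#' Success rates from detection records
#'
#' A variant counts as correctly identified when reported in at least one
#' valid replicate. Only assessable records enter numerators and
#' denominators. Returns per-participant rates, the global rate, and a
#' stratified table of participants by rounded success rate.
#'
#' @param records Detection records from [detection_matrix()].
#' @return A list with `per_participant`, `global` and `strata`.
#' @export
success_rate <- function(records) {
  a <- records[records$assessable, ]
  if (!nrow(a)) stop("no assessable records; success rate undefined",
                     call. = FALSE)
  per <- dplyr::summarise(
    dplyr::group_by(a, .data$participant),
    correct = sum(.data$replicates_reported >= 1L),
    total = dplyr::n(),
    .groups = "drop"
  )
  per$rate_pct <- round_half_up(100 * per$correct / per$total, 2)
  glob <- list(correct = sum(per$correct), total = sum(per$total))
  glob$rate_pct <- round_half_up(100 * glob$correct / glob$total, 2)
  strata <- dplyr::summarise(
    dplyr::group_by(per, .data$rate_pct),
    n_participants = dplyr::n(),
    counts = paste(sort(unique(paste0(.data$correct, "/", .data$total)),
                        decreasing = TRUE), collapse = " or "),
    .groups = "drop"
  )
  strata <- dplyr::arrange(strata, dplyr::desc(.data$rate_pct))
  strata$pct_participants <- round_half_up(
    100 * strata$n_participants / nrow(per), 2)
  list(per_participant = dplyr::arrange(per, .data$participant),
       global = glob, strata = strata)
}

#' Repeatability issues
#'
#' Assessable records where a variant was found in some but not all valid
#' replicates. Replicates invalidated by an explicit status are not part of
#' the denominator, so 2 reported out of 2 valid is not an issue.
#'
#' @param records Detection records.
#' @return The subset of records with `1 <= replicates_reported <
#'   replicates_valid`.
#' @export
repeatability_issues <- function(records) {
  records[records$assessable &
            records$replicates_reported >= 1L &
            records$replicates_reported < records$replicates_valid, ]
}

FN_CAUSES <- c("cassette_incompatibility", "operator_error", "below_lod",
               "near_lod", "vus_policy", "undetermined")

#' Classify the cause of one false negative
#'
#' Decision cascade for an evaluative variant missing from all of a
#' participant's replicates: masked observation -> cassette incompatibility;
#' curated transcription-error flag -> operator error; expected allele
#' frequency below the laboratory's LOD -> below LOD; within
#' `near_factor` times the LOD -> near LOD; curated
#' variant-of-unknown-significance flag -> VUS reporting policy; otherwise
#' undetermined.
#'
#' @param assessable Logical; `FALSE` when the observation was masked.
#' @param expected_af Expected allele frequency (percent) of the variant.
#' @param lod_af The laboratory's reporting LOD (percent), or `NA` when the
#'   policy is unknown (the LOD rules are then skipped with a warning).
#' @param operator_error,vus Curated boolean flags (default `FALSE`).
#' @param near_factor Multiple of the LOD counting as "close to the LOD"
#'   (default 1.5).
#' @return One of `"cassette_incompatibility"`, `"operator_error"`,
#'   `"below_lod"`, `"near_lod"`, `"vus_policy"`, `"undetermined"`.
#' @export
classify_false_negative <- function(assessable, expected_af, lod_af,
                                    operator_error = FALSE, vus = FALSE,
                                    near_factor = 1.5) {
  if (!assessable) return("cassette_incompatibility")
  if (isTRUE(operator_error)) return("operator_error")
  if (is.na(lod_af)) {
    warning("no LOD policy for participant; LOD-based causes skipped",
            call. = FALSE)
  } else if (!is.na(expected_af)) {
    if (expected_af < lod_af) return("below_lod")
    if (expected_af <= near_factor * lod_af) return("near_lod")
  }
  if (isTRUE(vus)) return("vus_policy")
  "undetermined"
}

#' Classify all false negatives in a detection matrix
#'
#' A false negative is any record with zero reported replicates, whether
#' assessable or masked; masked ones are classified as cassette
#' incompatibilities and are excluded from success-rate denominators
#' elsewhere.
#'
#' @param records Detection records.
#' @param policies Optional tibble with `participant`, `lod_af` (percent)
#'   and optionally `lod_depth`.
#' @param curated Optional tibble of curated annotations with
#'   `participant`, `sample_id`, `key` and logical `operator_error`,
#'   `vus` columns (stand-ins for manual read-level review).
#' @param near_factor See [classify_false_negative()].
#' @return The zero-detection records with a `cause` column.
#' @export
false_negatives <- function(records, policies = NULL, curated = NULL,
                            near_factor = 1.5) {
  fn <- records[records$replicates_reported == 0L, ]
  if (!nrow(fn)) {
    fn$cause <- character()
    return(fn)
  }
  lod_of <- if (!is.null(policies)) {
    stats::setNames(policies$lod_af, policies$participant)
  } else {
    stats::setNames(numeric(), character())
  }
  cur_key <- function(p, s, k) paste(p, s, k)
  cur <- if (!is.null(curated) && nrow(curated)) curated else NULL
  fn$cause <- vapply(seq_len(nrow(fn)), function(i) {
    r <- fn[i, ]
    op <- FALSE
    vus <- FALSE
    if (!is.null(cur)) {
      m <- cur_key(cur$participant, cur$sample_id, cur$key) ==
        cur_key(r$participant, r$sample_id, r$key)
      if (any(m)) {
        op <- isTRUE(any(cur$operator_error[m]))
        vus <- isTRUE(any(cur$vus[m]))
      }
    }
    lod <- if (r$participant %in% names(lod_of)) {
      unname(lod_of[r$participant])
    } else {
      NA_real_
    }
    classify_false_negative(r$assessable, r$expected_af, lod,
                            operator_error = op, vus = vus,
                            near_factor = near_factor)
  }, character(1))
  fn
}

#' Tally Z-score citations
#'
#' Sums cited and allocated counts over variants (and, when given a list,
#' over benchmarks).
#'
#' @param stats A [variant_statistics()] tibble (or any tibble with `cited`
#'   and `allocated` counts), or a list of such tibbles.
#' @return A list with `cited`, `allocated`, `proportion` (fraction) and
#'   `pct` (percent, rounded half-up to 2 decimals).
#' @export
z_citation_tally <- function(stats) {
  if (is.data.frame(stats)) stats <- list(stats)
  cited <- sum(vapply(stats, function(s) sum(s$cited), numeric(1)))
  allocated <- sum(vapply(stats, function(s) sum(s$allocated), numeric(1)))
  prop <- if (allocated > 0) cited / allocated else NA_real_
  list(cited = as.integer(cited), allocated = as.integer(allocated),
       proportion = prop, pct = round_half_up(100 * prop, 2))
}

#' Run the full evaluation pipeline for one benchmark
#'
#' Convenience glue: classifies the truth set, computes the
#' incompatibility mask, builds the detection matrix, computes success
#' rates, repeatability issues, per-variant statistics, false-negative
#' causes and the Z-citation tally.
#'
#' @param design An [eqa_design()].
#' @param reports Reports tibble.
#' @param statuses Optional replicate-status tibble.
#' @param policies Optional laboratory policy tibble (see
#'   [false_negatives()]).
#' @param curated Optional curated-annotation tibble.
#' @param mode Z allocation mode, `"global"` or `"peer_group"`.
#' @param alpha Grubbs significance level.
#' @param near_factor Near-LOD factor.
#' @return An object of class `eqa_results`.
#' @export
evaluate_benchmark <- function(design, reports, statuses = NULL,
                               policies = NULL, curated = NULL,
                               mode = c("global", "peer_group"),
                               alpha = 0.05, near_factor = 1.5) {
  mode <- match.arg(mode)
  truth <- classify_truth(design, reports, statuses)
  mask <- mask_incompatible(design)
  records <- detection_matrix(design, reports, truth, statuses, mask)
  stats <- variant_statistics(design, reports, truth, statuses, mode, alpha)
  res <- list(
    benchmark_id = design$benchmark_id,
    design = design,
    truth = truth,
    mask = mask,
    records = records,
    stats = stats,
    success = success_rate(records),
    repeatability = repeatability_issues(records),
    false_negatives = false_negatives(records, policies, curated, near_factor),
    z_tally = z_citation_tally(stats),
    variant_table = variant_table_from_stats(stats, records,
                                             design$benchmark_id),
    informative = informative_table(truth, reports, statuses)
  )
  structure(res, class = "eqa_results")
}

#' @export
print.eqa_results <- function(x, ...) {
  cat("<eqa_results> benchmark", x$benchmark_id, "\n")
  g <- x$success$global
  cat("  success:", g$correct, "/", g$total,
      paste0("(", format(g$rate_pct, nsmall = 2), "%)"), "\n")
  zt <- x$z_tally
  cat("  Z citations:", zt$cited, "/", zt$allocated,
      paste0("(", format(zt$pct, nsmall = 2), "%)"), "\n")
  cat("  false negatives (incl. masked):", nrow(x$false_negatives), "\n")
  invisible(x)
}

# Per-variant display table in the layout of the published global reports.
variant_table_from_stats <- function(stats, records, benchmark_id) {
  if (!nrow(stats)) {
    return(tibble::tibble(benchmark = character(), sample_id = character(),
                          gene = character(), variant = character(),
                          maf = numeric(), sd = numeric(),
                          z_cited = integer(), z_allocated = integer(),
                          success_n = integer(), success_total = integer()))
  }
  succ <- dplyr::summarise(
    dplyr::group_by(records, .data$sample_id, .data$key),
    success_n = sum(.data$assessable & .data$replicates_reported >= 1L),
    success_total = dplyr::n(),
    .groups = "drop"
  )
  out <- dplyr::left_join(
    tibble::tibble(benchmark = benchmark_id, sample_id = stats$sample_id,
                   key = stats$key, gene = stats$gene,
                   variant = stats$p_hgvs, maf = stats$maf, sd = stats$sd,
                   z_cited = as.integer(stats$cited),
                   z_allocated = as.integer(stats$allocated)),
    succ, by = c("sample_id", "key")
  )
  out$key <- NULL
  out
}

# Informative variants with untrimmed median/SD of reporter MRAFs
# (reported back for information only, never scored).
informative_table <- function(truth, reports, statuses = NULL) {
  inf <- truth[truth$classification == "informative", ]
  if (!nrow(inf)) {
    return(tibble::tibble(sample_id = character(), gene = character(),
                          variant = character(), maf = numeric(),
                          sd = numeric(), reporting_count = integer(),
                          participant_total = integer()))
  }
  vr <- valid_reports(reports, statuses)
  keys <- report_keys(vr)
  purrr::map_dfr(seq_len(nrow(inf)), function(i) {
    t <- inf[i, ]
    hit <- !is.na(keys) & keys == t$key & vr$sample_id == t$sample_id
    sub <- vr[hit, ]
    m <- if (nrow(sub)) {
      per_rep <- dplyr::summarise(
        dplyr::group_by(sub, .data$participant, .data$replicate),
        af = stats::median(.data$af), .groups = "drop")
      vapply(split(per_rep$af, per_rep$participant), mraf, numeric(1))
    } else numeric()
    tibble::tibble(
      sample_id = t$sample_id, gene = t$gene,
      variant = if (is.na(t$p_hgvs)) t$key else t$p_hgvs,
      maf = if (length(m)) stats::median(m) else NA_real_,
      sd = if (length(m) >= 2) stats::sd(m) else 0,
      reporting_count = t$reporting_count,
      participant_total = t$participant_total
    )
  })
}
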