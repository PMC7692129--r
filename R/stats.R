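# Per-variant allele-frequency statistics: participant medians over
# replicates (MRAF), the trimmed across-participant median (MAF) and
# standard deviation after iterative Grubbs outlier removal, Z-scores with
# the |Z| acceptance limit, Shapiro-Wilk normality flags, and peer-group
# restricted allocation.

#' Median reported allele frequency over replicates (MRAF)
#'
#' @param replicate_afs Numeric vector of per-replicate allele frequencies
#'   (percent); absent replicates are simply not included.
#' @return The sample median, or `NA_real_` for an empty vector (variant
#'   unreported).
#' @export
mraf <- function(replicate_afs) {
  replicate_afs <- replicate_afs[!is.na(replicate_afs)]
  if (!length(replicate_afs)) return(NA_real_)
  stats::median(replicate_afs)
}

#' Two-sided Grubbs critical value
#'
#' Critical value for the Grubbs statistic `G = max|x - mean(x)| / sd(x)` at
#' two-sided level `alpha`, from the Student-t quantile:
#' `((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n - 2)`.
#'
#' @param n Sample size (>= 3).
#' @param alpha Significance level (default 0.05).
#' @return The critical value.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  stopifnot(n >= 3)
  t2 <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)^2
  ((n - 1) / sqrt(n)) * sqrt(t2 / (n - 2 + t2))
}

#' Trimmed location/scale of participant MRAFs
#'
#' Iterative two-sided Grubbs outlier removal at level `alpha`: while the
#' most extreme value's `G = max|x - mean| / sd` exceeds the critical value
#' and at least 3 values remain, the extreme value is removed and the test
#' repeated. The consensus allele frequency (MAF) is the median of the
#' retained values; the spread (SD) is their sample standard deviation
#' (n - 1 denominator, 0 for a single value). With fewer than 3 values no
#' trimming is performed.
#'
#' @param mrafs Named numeric vector: participant -> MRAF (percent).
#' @param alpha Grubbs significance level (default 0.05).
#' @return A list with `maf`, `sd`, `retained` (names), `removed` (names),
#'   `n_used`.
#' @export
trimmed_stats <- function(mrafs, alpha = 0.05) {
  stopifnot(length(mrafs) >= 1)
  x <- mrafs[!is.na(mrafs)]
  if (is.null(names(x))) names(x) <- as.character(seq_along(x))
  removed <- character()
  while (length(x) >= 3) {
    s <- stats::sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    g <- max(dev) / s
    if (g > grubbs_critical(length(x), alpha)) {
      worst <- names(x)[which.max(dev)][1]
      removed <- c(removed, worst)
      x <- x[names(x) != worst]
    } else {
      break
    }
  }
  list(
    maf = stats::median(x),
    sd = if (length(x) >= 2) stats::sd(x) else 0,
    retained = names(x),
    removed = removed,
    n_used = length(x)
  )
}

#' Z-score for one participant's MRAF
#'
#' `Z = (MRAF - MAF) / SD`. A citation is issued when `|Z|` exceeds the
#' acceptance limit (3.0 by default). When the spread is exactly zero the
#' case is degenerate: a participant equal to the consensus gets `Z = 0`,
#' any other participant cannot be scored and is left unallocated.
#'
#' @param mraf_p The participant's MRAF (percent).
#' @param maf Consensus MAF (percent).
#' @param sd Trimmed standard deviation (percent, >= 0).
#' @param z_acceptance Maximum accepted |Z| (default 3.0).
#' @return A list with `z`, `allocated`, `cited`.
#' @export
z_score <- function(mraf_p, maf, sd, z_acceptance = 3.0) {
  stopifnot(sd >= 0)
  if (sd == 0) {
    if (isTRUE(all.equal(mraf_p, maf))) {
      return(list(z = 0, allocated = TRUE, cited = FALSE))
    }
    return(list(z = NA_real_, allocated = FALSE, cited = FALSE))
  }
  z <- (mraf_p - maf) / sd
  list(z = z, allocated = TRUE, cited = abs(z) > z_acceptance)
}

#' Shapiro-Wilk normality p-value for a MRAF distribution
#'
#' Attached to per-variant statistics for reporting only; it never gates
#' scoring. Degenerate inputs (n < 3 or a constant vector) yield `NA`.
#'
#' @param values Numeric vector of MRAFs.
#' @return A p-value or `NA_real_`.
#' @export
shapiro_flag <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(values) > 5000) return(NA_real_)
  if (stats::sd(values) == 0) return(NA_real_)
  stats::shapiro.test(values)$p.value
}

# Compute Z results for one reporter set given its trimmed stats.
z_for_group <- function(mrafs, trimmed, z_acceptance) {
  purrr::map_dfr(names(mrafs), function(p) {
    zr <- z_score(mrafs[[p]], trimmed$maf, trimmed$sd, z_acceptance)
    tibble::tibble(participant = p, z = zr$z, allocated = zr$allocated,
                   cited = zr$cited)
  })
}

#' Per-variant statistics for all evaluative variants
#'
#' For every evaluative (sample, variant) pair: each reporting
#' participant's MRAF over its valid replicates, the Grubbs-trimmed MAF and
#' SD, the Shapiro-Wilk flag, and per-participant Z results. In `global`
#' mode every reporter is scored against the full reporter distribution
#' (participants removed as outliers still receive a Z against the trimmed
#' consensus). In `peer_group` mode MAF/SD and Z are computed within each
#' gene-panel peer group, and reporters in groups with fewer than
#' `peer_group_min` reporting members are left unallocated. A single
#' reporter cannot form a distribution and is never allocated.
#'
#' @param design An [eqa_design()].
#' @param reports Reports tibble.
#' @param truth Output of [classify_truth()] (only evaluative rows are
#'   used) or a compatible tibble with `sample_id`, `key` and
#'   `classification`.
#' @param statuses Optional replicate-status tibble.
#' @param mode `"global"` or `"peer_group"`.
#' @param alpha Grubbs level (default 0.05).
#' @return A tibble, one row per evaluative variant, with list-columns
#'   `mrafs` (named numeric) and `z` (tibble participant/z/allocated/cited)
#'   plus `maf`, `sd`, `n_used`, `outliers_removed`, `shapiro_p`.
#' @export
variant_statistics <- function(design, reports, truth, statuses = NULL,
                               mode = c("global", "peer_group"),
                               alpha = 0.05) {
  mode <- match.arg(mode)
  ev <- truth[truth$classification == "evaluative", ]
  vr <- valid_reports(reports, statuses)
  keys <- report_keys(vr)
  zacc <- design$z_acceptance
  panel_of <- stats::setNames(design$panel_assignments$panel_id,
                              design$panel_assignments$participant)

  purrr::map_dfr(seq_len(nrow(ev)), function(i) {
    t <- ev[i, ]
    hit <- !is.na(keys) & keys == t$key & vr$sample_id == t$sample_id
    sub <- vr[hit, ]
    mrafs <- if (nrow(sub)) {
      # one AF per replicate (median if a replicate repeats the variant),
      # then the median over replicates
      per_rep <- dplyr::summarise(
        dplyr::group_by(sub, .data$participant, .data$replicate),
        af = stats::median(.data$af), .groups = "drop"
      )
      by_p <- split(per_rep$af, per_rep$participant)
      vapply(by_p, mraf, numeric(1))
    } else {
      stats::setNames(numeric(), character())
    }

    if (mode == "global") {
      if (length(mrafs) >= 2) {
        tr <- trimmed_stats(mrafs, alpha)
        ztab <- z_for_group(mrafs, tr, zacc)
      } else {
        tr <- list(maf = unname(mrafs)[1] %||% NA_real_, sd = NA_real_,
                   removed = character(), n_used = length(mrafs))
        ztab <- tibble::tibble(participant = names(mrafs),
                               z = NA_real_, allocated = FALSE, cited = FALSE)
      }
    } else {
      groups <- split(names(mrafs), unname(panel_of[names(mrafs)]))
      unknown <- names(mrafs)[!names(mrafs) %in% names(panel_of)]
      if (length(unknown)) {
        warning("participant(s) without a panel in peer-group mode: ",
                paste(unknown, collapse = ", "), call. = FALSE)
        groups <- c(groups, list(.unknown = unknown))
      }
      ztab <- purrr::map_dfr(names(groups), function(g) {
        members <- groups[[g]]
        gm <- mrafs[members]
        if (g == ".unknown" || length(gm) < design$peer_group_min) {
          return(tibble::tibble(participant = members, z = NA_real_,
                                allocated = FALSE, cited = FALSE))
        }
        z_for_group(gm, trimmed_stats(gm, alpha), zacc)
      })
      # headline MAF/SD from the largest reporting peer group when any
      # group is big enough, degenerate otherwise
      big <- groups[vapply(groups, length, integer(1)) >= design$peer_group_min]
      tr <- if (length(big)) {
        trimmed_stats(mrafs[big[[which.max(vapply(big, length, integer(1)))]]],
                      alpha)
      } else {
        list(maf = NA_real_, sd = NA_real_, removed = character(), n_used = 0L)
      }
    }

    tibble::tibble(
      sample_id = t$sample_id, key = t$key, gene = t$gene,
      p_hgvs = t$p_hgvs,
      mrafs = list(mrafs),
      maf = tr$maf, sd = tr$sd, n_used = tr$n_used,
      outliers_removed = list(tr$removed),
      shapiro_p = shapiro_flag(mrafs),
      z = list(ztab),
      cited = sum(ztab$cited), allocated = sum(ztab$allocated)
    )
  })
}
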