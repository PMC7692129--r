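# Anonymized global and individual report rendering. Output is
# deterministic: CSV for tables, Markdown for the narrative, JSON for
# machine consumption; no timestamps inside tables.

# 32-bit FNV-1a hash of a string; exact in double arithmetic.
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(enc2utf8(s))) {
    # XOR only touches the low byte; keep arithmetic exact in doubles
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # h * 16777619 mod 2^32, with 16777619 = 2^24 + 403 so every
    # intermediate stays below 2^53 and exact in doubles
    h <- (h * 403 + (h %% 256) * 16777216) %% 2^32
  }
  h
}

to_base36 <- function(x, width = 6L) {
  digits <- c(0:9, LETTERS)
  out <- character(width)
  for (i in seq_len(width)) {
    out[i] <- digits[(x %% 36) + 1]
    x <- x %/% 36
  }
  paste(rev(out), collapse = "")
}

#' Deterministic anonymization codes for participants
#'
#' Keyed-hash codes (6 base-36 characters): injective over the given
#' identifiers (collisions are resolved by re-salting) and stable under an
#' identical seed.
#'
#' @param participants Character vector of participant identifiers.
#' @param seed Integer salt.
#' @return A named character vector: identifier -> opaque code.
#' @export
anonymize_participants <- function(participants, seed = 1L) {
  participants <- as.character(participants)
  stopifnot(!anyDuplicated(participants))
  round <- 0L
  repeat {
    codes <- vapply(participants, function(p) {
      to_base36(fnv1a(paste0("eqa:", seed, ":", round, ":", p)))
    }, character(1))
    if (!anyDuplicated(codes)) break
    round <- round + 1L
  }
  codes
}

fmt2 <- function(x) {
  ifelse(is.na(x), "/", formatC(round_half_up(x, 2), format = "f", digits = 2))
}

# "13.21 (0.60)" / "1/16" / "16/16" cells of the per-variant table.
format_variant_table <- function(vt) {
  tibble::tibble(
    benchmark = vt$benchmark,
    sample = vt$sample_id,
    gene = vt$gene,
    variant = vt$variant,
    median_af_sd = ifelse(is.na(vt$maf), "/",
                          paste0(fmt2(vt$maf), " (", fmt2(vt$sd), ")")),
    z_citations = paste0(vt$z_cited, "/", vt$z_allocated),
    participant_success = paste0(vt$success_n, "/", vt$success_total)
  )
}

#' Render the anonymized global report
#'
#' Writes deterministic CSV tables (evaluative per-variant results,
#' informative variants, stratified success rates, false negatives with
#' causes, repeatability issues), a machine-readable JSON summary and a
#' human-readable Markdown narrative. Participant identifiers are replaced
#' by anonymization codes everywhere.
#'
#' @param results An `eqa_results` object ([evaluate_benchmark()] or
#'   [fixture_results()]).
#' @param out_dir Output directory (created if needed).
#' @param anonymize_seed Salt for [anonymize_participants()].
#' @return Invisibly, the named list of written file paths.
#' @export
render_global <- function(results, out_dir, anonymize_seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  map <- anonymize_participants(
    sort(unique(results$records$participant)), anonymize_seed)
  paths <- list()

  ev <- format_variant_table(results$variant_table)
  paths$evaluative <- file.path(out_dir, "evaluative_variants.csv")
  readr::write_csv(ev, paths$evaluative, progress = FALSE)

  inf <- results$informative
  if (!is.null(inf) && nrow(inf)) {
    inf_out <- tibble::tibble(
      sample = inf$sample_id, gene = inf$gene, variant = inf$variant,
      median_af_sd = ifelse(is.na(inf$maf), "/",
                            paste0(fmt2(inf$maf), " (", fmt2(inf$sd), ")")),
      participant_identification = paste0(inf$reporting_count, "/",
                                          inf$participant_total)
    )
    paths$informative <- file.path(out_dir, "informative_variants.csv")
    readr::write_csv(inf_out, paths$informative, progress = FALSE)
  }

  strat <- results$success$strata
  strat_out <- tibble::tibble(
    success_rate = paste0(fmt2(strat$rate_pct), "% (", strat$counts, ")"),
    participants = paste0(strat$n_participants, " (",
                          fmt2(strat$pct_participants), "%)")
  )
  paths$strata <- file.path(out_dir, "success_rates.csv")
  readr::write_csv(strat_out, paths$strata, progress = FALSE)

  fn <- results$false_negatives
  fn_out <- tibble::tibble(
    participant = unname(map[fn$participant]), sample = fn$sample_id,
    gene = fn$gene, variant = fn$p_hgvs, expected_af = fn$expected_af,
    cause = fn$cause
  )
  fn_out <- dplyr::arrange(fn_out, .data$sample, .data$variant,
                           .data$participant)
  paths$false_negatives <- file.path(out_dir, "false_negatives.csv")
  readr::write_csv(fn_out, paths$false_negatives, progress = FALSE)

  rep_t <- results$repeatability
  rep_out <- tibble::tibble(
    participant = unname(map[rep_t$participant]), sample = rep_t$sample_id,
    gene = rep_t$gene, variant = rep_t$p_hgvs,
    replicates = paste0(rep_t$replicates_reported, "/",
                        rep_t$replicates_valid)
  )
  rep_out <- dplyr::arrange(rep_out, .data$sample, .data$variant,
                            .data$participant)
  paths$repeatability <- file.path(out_dir, "repeatability_issues.csv")
  readr::write_csv(rep_out, paths$repeatability, progress = FALSE)

  g <- results$success$global
  zt <- results$z_tally
  summary <- list(
    benchmark = results$benchmark_id,
    participants = length(map),
    evaluative_variants = nrow(results$variant_table),
    success = list(correct = g$correct, total = g$total,
                   rate_pct = g$rate_pct),
    z_citations = list(cited = zt$cited, allocated = zt$allocated,
                       pct = zt$pct),
    false_negatives = as.list(table(fn$cause)),
    repeatability_issues = nrow(rep_t)
  )
  paths$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  md <- c(
    paste0("# Global report — benchmark ", results$benchmark_id),
    "",
    paste0("Participants: ", length(map), ". Evaluative variants: ",
           nrow(results$variant_table), "."),
    "",
    paste0("Global success rate: **", g$correct, "/", g$total, " (",
           fmt2(g$rate_pct), "%)**. A variant counts as identified when ",
           "reported in at least one valid replicate; observations masked ",
           "for panel/cassette incompatibility are excluded from all ",
           "denominators."),
    "",
    paste0("Z-score citations (|Z| > 3): ", zt$cited, "/", zt$allocated,
           " (", fmt2(zt$pct), "%) of allocated scores. Z-scores inform on ",
           "the reported allele frequency only; they do not affect the ",
           "success rate."),
    "",
    paste0("False negatives investigated (including masked observations): ",
           nrow(fn), "."),
    "",
    "Tables: evaluative_variants.csv, informative_variants.csv,",
    "success_rates.csv, false_negatives.csv, repeatability_issues.csv.",
    ""
  )
  paths$report <- file.path(out_dir, "global_report.md")
  writeLines(md, paths$report)
  invisible(paths)
}

#' Render one participant's individual scorecard
#'
#' Lists the participant's own detections, misses with their classified
#' cause (and the laboratory's own LOD where relevant), own Z-scores with
#' citation flags, and the anonymized per-variant consensus distribution.
#' Contains no other participant's identity. Byte-identical across
#' re-renders with the same inputs and seed.
#'
#' @param results An `eqa_results` object.
#' @param participant Participant identifier.
#' @param out_dir Output directory.
#' @param anonymize_seed Salt for the anonymization map.
#' @param policies Optional policy tibble used to echo the lab's LOD.
#' @return Invisibly, the path of the written scorecard.
#' @export
render_individual <- function(results, participant, out_dir,
                              anonymize_seed = 1L, policies = NULL) {
  all_p <- sort(unique(results$records$participant))
  if (!participant %in% all_p) {
    stop("unknown participant: ", participant, call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  map <- anonymize_participants(all_p, anonymize_seed)
  code <- unname(map[participant])
  rec <- results$records[results$records$participant == participant, ]
  rec <- dplyr::arrange(rec, .data$sample_id, .data$p_hgvs)
  fn <- results$false_negatives
  fn <- fn[fn$participant == participant, ]
  lod <- if (!is.null(policies)) {
    policies$lod_af[match(participant, policies$participant)]
  } else {
    NA_real_
  }

  own_z <- if (is.data.frame(results$stats) && "z" %in% names(results$stats)) {
    purrr::map_dfr(seq_len(nrow(results$stats)), function(i) {
      zt <- results$stats$z[[i]]
      zt <- zt[zt$participant == participant, ]
      if (!nrow(zt)) return(NULL)
      tibble::tibble(sample = results$stats$sample_id[i],
                     variant = results$stats$p_hgvs[i],
                     z = zt$z, allocated = zt$allocated, cited = zt$cited)
    })
  } else {
    NULL
  }

  lines <- c(
    paste0("# Individual report — benchmark ", results$benchmark_id),
    paste0("Participant code: ", code),
    "",
    "## Detections",
    ""
  )
  for (i in seq_len(nrow(rec))) {
    r <- rec[i, ]
    status <- if (!r$assessable) {
      "not assessed (panel/cassette incompatibility)"
    } else if (r$replicates_reported >= 1L) {
      paste0("detected in ", r$replicates_reported, "/", r$replicates_valid,
             " replicates")
    } else {
      cause <- fn$cause[fn$sample_id == r$sample_id & fn$key == r$key]
      extra <- if (length(cause) && cause[1] %in% c("below_lod", "near_lod") &&
                   !is.na(lod)) {
        paste0(" (laboratory LOD ", fmt2(lod), "%)")
      } else {
        ""
      }
      paste0("MISSED — ", if (length(cause)) cause[1] else "undetermined",
             extra)
    }
    lines <- c(lines, paste0("- ", r$sample_id, " ", r$gene, " ", r$p_hgvs,
                             ": ", status))
  }
  lines <- c(lines, "", "## Allele-frequency Z-scores", "")
  if (!is.null(own_z) && nrow(own_z)) {
    for (i in seq_len(nrow(own_z))) {
      z <- own_z[i, ]
      lines <- c(lines, paste0(
        "- ", z$sample, " ", z$variant, ": ",
        if (!z$allocated) "no Z-score allocated"
        else paste0("Z = ", fmt2(z$z),
                    if (z$cited) " — CITED (|Z| > 3)" else "")
      ))
    }
  } else {
    lines <- c(lines, "- Z-scores are summarized at the consensus level for this benchmark.")
  }
  lines <- c(lines, "", "## Consensus distribution (anonymized)", "")
  vt <- format_variant_table(results$variant_table)
  lines <- c(lines, paste0("- ", vt$sample, " ", vt$gene, " ", vt$variant,
                           ": median AF (SD) ", vt$median_af_sd,
                           ", Z citations ", vt$z_citations,
                           ", detected by ", vt$participant_success), "")
  path <- file.path(out_dir, paste0("scorecard_", code, ".md"))
  writeLines(lines, path)
  invisible(path)
}
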