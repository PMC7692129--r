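# Synthetic laboratory cohorts: complete benchmark designs, per-laboratory
# profiles and per-replicate submissions with a planted ground-truth
# ledger, so every pipeline stage can be exercised without external data.
#
# Defaults emulate the study conditions: 16 laboratories, 4 samples, 3
# replicates, expected allele frequencies drawn from 5-50%, reporting LODs
# from 1-10% AF and 100-1000 reads, inter-laboratory AF noise in the
# 0.4-3 percentage-point range, and the six protein-HGVS dialects observed
# across laboratories.

# Gene pool with plausible hotspot context for generated variants.
.SYNTH_GENES <- c("BRAF", "KRAS", "NRAS", "EGFR", "TP53", "JAK2", "KIT",
                  "IDH1", "IDH2", "FLT3", "SF3B1", "BRCA1", "BRCA2")

#' The protein-HGVS rendering dialects used by synthetic laboratories
#'
#' The six renderings of a substitution observed across real laboratories:
#' fully canonical, missing dot, missing parentheses, one-letter codes, and
#' the two single-residue delins spellings.
#'
#' @return Character vector of dialect names.
#' @export
eqa_dialects <- function() {
  c("canonical", "paren_nodot", "nodot", "one_letter",
    "delins_three", "delins_one")
}

#' Render a protein change in a laboratory's dialect
#'
#' Substitutions are rendered in all six dialects; other change kinds fall
#' back to the canonical rendering (one-letter dialects still use
#' one-letter residue codes for substitution-like forms).
#'
#' @param change A `protein_change`.
#' @param dialect One of [eqa_dialects()].
#' @return A protein HGVS string in the requested dialect.
#' @export
render_dialect <- function(change, dialect = "canonical") {
  stopifnot(inherits(change, "protein_change"))
  canon <- canonicalize_protein(change)
  if (!change$kind %in% c("substitution", "nonsense")) return(canon)
  a1 <- aa_three_to_one()
  ref3 <- change$ref_aa[1]
  alt3 <- change$alt[1]
  pos <- change$pos[1]
  switch(
    dialect,
    canonical = canon,
    paren_nodot = paste0("p(", ref3, pos, render_aa(alt3), ")"),
    nodot = paste0("p.", ref3, pos, render_aa(alt3)),
    one_letter = paste0("p.", a1[[ref3]], pos, a1[[alt3]]),
    delins_three = paste0("p.", ref3, pos, "delins", render_aa(alt3)),
    delins_one = paste0("p.", a1[[ref3]], pos, "delins", a1[[alt3]]),
    stop("unknown dialect: ", dialect, call. = FALSE)
  )
}

#' Generate a synthetic benchmark design
#'
#' Builds a deterministic benchmark design: samples, participants,
#' characterized variants (substitutions at hotspot-like positions with
#' expected allele frequencies drawn from `af_range`), regions of interest
#' covering every variant plus decoy intervals, and per-panel amplicon
#' definitions. A fraction of variants is marked as engineered through a
#' 2 kb insertion cassette centered on the variant; default amplicons are
#' much shorter than the cassette, so no observation is masked unless a
#' panel is explicitly widened.
#'
#' @param n_labs,n_samples,variants_per_sample Cohort dimensions.
#' @param af_range Expected allele-frequency range in percent (default
#'   5-50).
#' @param inserted_fraction Fraction of variants carrying a cassette.
#' @param n_panels Number of distinct gene panels assigned round-robin.
#' @param replicate_count Replicates per sample (default 3).
#' @param amplicon_halfwidth Half-width of generated amplicons in bp.
#' @param vus_fraction Fraction of variants flagged as variants of unknown
#'   significance (withheld by labs with a conservative reporting policy).
#' @param seed Integer seed; identical seeds give identical designs.
#' @return An [eqa_design()].
#' @export
generate_design <- function(n_labs = 16, n_samples = 4,
                            variants_per_sample = 4, af_range = c(5, 50),
                            inserted_fraction = 0.25, n_panels = 1,
                            replicate_count = 3L, amplicon_halfwidth = 150L,
                            vus_fraction = 0, seed = 1L) {
  stopifnot(n_labs >= 1, n_samples >= 1, variants_per_sample >= 1,
            length(af_range) == 2, af_range[1] > 0,
            af_range[2] <= 100, af_range[1] <= af_range[2],
            inserted_fraction >= 0, inserted_fraction <= 1, n_panels >= 1)
  withr::with_seed(as.integer(seed), {
    participants <- sprintf("LAB%02d", seq_len(n_labs))
    samples <- tibble::tibble(
      sample_id = sprintf("SYN-%03d", seq_len(n_samples)),
      cancer_context = "synthetic cell-line mix",
      replicate_count = as.integer(replicate_count),
      targeted_genes = list(.SYNTH_GENES)
    )
    n_var <- n_samples * variants_per_sample
    genes <- sample(.SYNTH_GENES, n_var, replace = TRUE)
    chroms <- paste0("chr", sample(1:22, n_var, replace = TRUE))
    pos <- sort(sample(1e6:2e8, n_var))
    aa <- setdiff(names(aa_three_to_one()), "Ter")
    ref_aa <- sample(aa, n_var, replace = TRUE)
    alt_aa <- vapply(ref_aa, function(r) sample(setdiff(aa, r), 1), character(1))
    codon <- sample(50:1500, n_var, replace = TRUE)
    n_ins <- round(inserted_fraction * n_var)
    inserted <- seq_len(n_var) %in% sample(n_var, n_ins)
    n_vus <- round(vus_fraction * n_var)
    vus <- seq_len(n_var) %in% sample(n_var, n_vus)

    ov <- tibble::tibble(
      sample_id = rep(samples$sample_id, each = variants_per_sample),
      gene = genes,
      transcript = NA_character_, protein_ref = NA_character_,
      p_hgvs = paste0("p.(", ref_aa, codon, alt_aa, ")"),
      c_hgvs = NA_character_,
      chrom = chroms, pos = as.integer(pos),
      expected_af = round(stats::runif(n_var, af_range[1], af_range[2]), 1),
      validation = "ddPCR",
      origin = ifelse(inserted, "inserted", "endogenous"),
      cassette_start = ifelse(inserted, as.integer(pos - 1L - 1000L), NA_integer_),
      cassette_end = ifelse(inserted, as.integer(pos - 1L + 1000L), NA_integer_),
      ordered = TRUE,
      vus = vus
    )

    roi <- tibble::tibble(
      chrom = chroms,
      start = as.integer(pos - 1L - 100L),
      end = as.integer(pos + 100L),
      name = paste0(genes, "_roi")
    )
    decoys <- tibble::tibble(
      chrom = paste0("chr", sample(1:22, 3, replace = TRUE)),
      start = as.integer(sample(1e6:2e8, 3)),
      name = paste0("decoy", 1:3)
    )
    decoys$end <- decoys$start + 200L
    roi <- dplyr::arrange(dplyr::bind_rows(roi, decoys[, names(roi)]),
                          .data$chrom, .data$start)

    panel_ids <- sprintf("PNL%02d", seq_len(n_panels))
    panels <- lapply(panel_ids, function(id) {
      list(panel_id = id, enrichment = "amplicon",
           intervals = tibble::tibble(
             chrom = chroms,
             start = as.integer(pos - 1L - amplicon_halfwidth),
             end = as.integer(pos - 1L + amplicon_halfwidth),
             name = paste0(id, "_amp", seq_len(n_var))
           ))
    })
    assignments <- tibble::tibble(
      participant = participants,
      panel_id = panel_ids[((seq_len(n_labs) - 1L) %% n_panels) + 1L]
    )

    eqa_design(
      benchmark_id = paste0("SYN/", seed),
      samples = samples, participants = participants,
      ordered_variants = ov, roi = roi, panels = panels,
      panel_assignments = assignments
    )
  })
}

#' Generate laboratory simulation profiles
#'
#' One profile per participant: reporting LOD (allele frequency and read
#' depth), allele-frequency noise, a systematic AF bias (for planting
#' Z-score outliers), per-replicate miss and dropout probabilities, the
#' HGVS dialect, and whether the lab withholds variants of unknown
#' significance.
#'
#' @param design An [eqa_design()].
#' @param seed Integer seed.
#' @param lod_af_range,lod_depth_range Ranges the LODs are drawn from.
#' @param af_noise_sd_range Range of per-lab AF noise SD (percentage
#'   points).
#' @param miss_prob Per-replicate probability of a spurious miss.
#' @param replicate_dropout_prob Probability a whole replicate fails QC.
#' @param vus_policy_prob Probability a lab withholds VUS calls.
#' @param af_bias Systematic AF shift (percentage points), recycled over
#'   labs.
#' @return A tibble of laboratory profiles.
#' @export
lab_profiles <- function(design, seed = 1L, lod_af_range = c(1, 10),
                         lod_depth_range = c(100, 1000),
                         af_noise_sd_range = c(0.4, 3),
                         miss_prob = 0.02, replicate_dropout_prob = 0.01,
                         vus_policy_prob = 0, af_bias = 0) {
  p <- design$participants
  withr::with_seed(as.integer(seed) + 1L, {
    panel_of <- stats::setNames(design$panel_assignments$panel_id,
                                design$panel_assignments$participant)
    tibble::tibble(
      participant = p,
      lod_af = round(stats::runif(length(p), lod_af_range[1],
                                  lod_af_range[2]), 1),
      lod_depth = as.integer(round(stats::runif(length(p),
                                                lod_depth_range[1],
                                                lod_depth_range[2]))),
      panel_id = unname(panel_of[p]),
      af_noise_sd = round(stats::runif(length(p), af_noise_sd_range[1],
                                       af_noise_sd_range[2]), 2),
      af_bias = rep_len(af_bias, length(p)),
      miss_prob = rep_len(miss_prob, length(p)),
      replicate_dropout_prob = rep_len(replicate_dropout_prob, length(p)),
      dialect = sample(eqa_dialects(), length(p), replace = TRUE),
      vus_policy = stats::runif(length(p)) < vus_policy_prob
    )
  })
}

#' Generate per-replicate participant submissions with a planted ledger
#'
#' For every (laboratory, sample, replicate, variant): the observation is
#' dropped when the lab's amplicon panel spans the variant's insertion
#' cassette, when the lab withholds VUS calls and the variant is flagged,
#' when the noisy allele frequency falls below the lab's LOD, or on a
#' Bernoulli per-replicate miss; whole replicates drop out with the QC
#' failure probability (emitted as invalid replicate statuses). Reported
#' AFs are the true AF plus the lab's bias and Gaussian noise, truncated
#' to \[0, 100\]; protein descriptions are rendered in the lab's dialect.
#'
#' The planted ledger records, per (laboratory, sample, variant), whether
#' the variant was detected in any valid replicate and — for misses — the
#' intended cause, assigned with the same cascade the evaluator uses
#' (cassette incompatibility, then deterministic LOD censoring, then VUS
#' policy, then near-LOD / undetermined for realized random misses). With
#' noise, misses and dropout disabled the pipeline recovers the ledger
#' exactly.
#'
#' @param design An [eqa_design()].
#' @param profiles Output of [lab_profiles()].
#' @param seed Integer seed; identical inputs and seed give byte-identical
#'   output.
#' @param near_factor Near-LOD factor used for ledger cause labels.
#' @return A list with `reports`, `statuses` and `ledger` tibbles.
#' @export
generate_submissions <- function(design, profiles, seed = 1L,
                                 near_factor = 1.5) {
  stopifnot(all(design$participants %in% profiles$participant))
  mask <- mask_incompatible(design)
  mask_key <- if (nrow(mask)) {
    paste(mask$participant, mask$sample_id, mask$key)
  } else {
    character()
  }
  ov <- design$ordered_variants
  rep_count <- stats::setNames(design$samples$replicate_count,
                               design$samples$sample_id)

  withr::with_seed(as.integer(seed) + 2L, {
    reports <- list()
    statuses <- list()
    ledger <- list()
    for (p in design$participants) {
      prof <- profiles[profiles$participant == p, ]
      for (s in design$samples$sample_id) {
        n_rep <- unname(rep_count[s])
        dropped <- stats::runif(n_rep) < prof$replicate_dropout_prob
        if (any(dropped)) {
          statuses[[length(statuses) + 1L]] <- tibble::tibble(
            participant = p, sample_id = s,
            replicate = which(dropped), valid = FALSE,
            reason = "simulated QC failure"
          )
        }
        vs <- ov[ov$sample_id == s, ]
        for (i in seq_len(nrow(vs))) {
          v <- vs[i, ]
          masked <- paste(p, s, v$key) %in% mask_key
          vus_drop <- prof$vus_policy && v$vus
          shifted_af <- v$expected_af + prof$af_bias
          detected_reps <- integer()
          afs <- numeric()
          if (!masked && !vus_drop) {
            for (r in which(!dropped)) {
              af <- shifted_af + stats::rnorm(1, 0, prof$af_noise_sd)
              af <- min(100, max(0, af))
              if (af < prof$lod_af) next
              if (stats::runif(1) < prof$miss_prob) next
              detected_reps <- c(detected_reps, r)
              afs <- c(afs, af)
            }
          }
          if (length(detected_reps)) {
            ch <- parse_protein_hgvs(v$p_hgvs)
            phg <- render_dialect(ch, prof$dialect)
            reports[[length(reports) + 1L]] <- tibble::tibble(
              participant = p, sample_id = s, replicate = detected_reps,
              gene = v$gene, chrom = v$chrom, pos = v$pos,
              ref_nt = NA_character_, obs_nt = NA_character_,
              c_hgvs = NA_character_, transcript = v$transcript,
              p_hgvs = phg, protein_ref = v$protein_ref,
              variant_type = "missense",
              interpretation = NA_character_,
              af = round(afs, 2),
              depth = as.integer(round(stats::runif(length(afs), 500, 2000)))
            )
          }
          cause <- if (length(detected_reps)) {
            NA_character_
          } else if (masked) {
            "cassette_incompatibility"
          } else if (shifted_af < prof$lod_af) {
            "below_lod"
          } else if (shifted_af <= near_factor * prof$lod_af) {
            "near_lod"
          } else if (vus_drop) {
            "vus_policy"
          } else {
            "undetermined"
          }
          ledger[[length(ledger) + 1L]] <- tibble::tibble(
            participant = p, sample_id = s, key = v$key,
            gene = v$gene, p_hgvs = canonical_p_hgvs(v$p_hgvs),
            true_af = v$expected_af,
            detected = length(detected_reps) > 0L,
            replicates_detected = length(detected_reps),
            cause = cause
          )
        }
      }
    }
    list(
      reports = if (length(reports)) dplyr::bind_rows(reports) else empty_reports(),
      statuses = if (length(statuses)) dplyr::bind_rows(statuses) else empty_statuses(),
      ledger = dplyr::bind_rows(ledger)
    )
  })
}
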