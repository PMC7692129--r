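# Independent reference implementations used as oracles. Deliberately
# written from first principles (sorting, explicit formulas) so they share
# no code path with the package.

oracle_median <- function(x) {
  x <- sort(unname(x))
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

oracle_sd <- function(x) {
  n <- length(x)
  if (n < 2) return(0)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / (n - 1))
}

# Textbook two-sided Grubbs critical value, re-derived here.
oracle_grubbs_crit <- function(n, alpha = 0.05) {
  tq <- qt(1 - alpha / (2 * n), df = n - 2)
  (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
}

# One-at-a-time two-sided Grubbs trimming, independent loop structure.
oracle_grubbs_trim <- function(x, alpha = 0.05) {
  removed <- character()
  repeat {
    if (length(x) < 3) break
    s <- oracle_sd(x)
    if (s == 0) break
    m <- sum(x) / length(x)
    devs <- abs(x - m)
    i <- order(devs, decreasing = TRUE)[1]
    if (devs[i] / s <= oracle_grubbs_crit(length(x), alpha)) break
    removed <- c(removed, names(x)[i])
    x <- x[-i]
  }
  list(maf = oracle_median(x), sd = oracle_sd(x),
       retained = names(x), removed = removed)
}

# Brute-force interval membership scan (1-based position vs 0-based
# half-open intervals).
oracle_in_roi <- function(chrom, pos, roi) {
  hit <- FALSE
  for (i in seq_len(nrow(roi))) {
    if (roi$chrom[i] == chrom && pos - 1 >= roi$start[i] &&
        pos - 1 < roi$end[i]) {
      hit <- TRUE
    }
  }
  hit
}

# Random protein_change generator for fuzzing the nomenclature module.
AA20 <- setdiff(names(eqascore::aa_three_to_one()), "Ter")

random_protein_change <- function() {
  kind <- sample(c("substitution", "nonsense", "deletion", "duplication",
                   "insertion", "delins", "frameshift"), 1)
  p1 <- sample(1:2000, 1)
  r1 <- sample(AA20, 1)
  ranged <- kind %in% c("insertion") ||
    (kind %in% c("deletion", "duplication", "delins") && runif(1) < 0.5)
  if (ranged) {
    p2 <- p1 + sample(1:30, 1)
    r2 <- sample(AA20, 1)
  }
  txt <- switch(
    kind,
    substitution = paste0("p.(", r1, p1, sample(setdiff(AA20, r1), 1), ")"),
    nonsense = paste0("p.(", r1, p1, "*)"),
    deletion = if (ranged) paste0("p.(", r1, p1, "_", r2, p2, "del)") else
      paste0("p.(", r1, p1, "del)"),
    duplication = if (ranged) paste0("p.(", r1, p1, "_", r2, p2, "dup)") else
      paste0("p.(", r1, p1, "dup)"),
    insertion = paste0("p.(", r1, p1, "_", r2, p2, "ins",
                       paste(sample(AA20, sample(1:3, 1), replace = TRUE),
                             collapse = ""), ")"),
    delins = {
      alts <- paste(sample(AA20, sample(2:3, 1), replace = TRUE),
                    collapse = "")
      if (ranged) paste0("p.(", r1, p1, "_", r2, p2, "delins", alts, ")") else
        paste0("p.(", r1, p1, "delins", alts, ")")
    },
    frameshift = paste0("p.(", r1, p1, sample(AA20, 1), "fs",
                        if (runif(1) < 0.8) paste0("*", sample(1:60, 1)) else "",
                        ")")
  )
  txt
}

# Render a canonical substitution string in one of the observed dialects.
dialect_render <- function(ref3, pos, alt3, dialect) {
  a1 <- eqascore::aa_three_to_one()
  switch(dialect,
         canonical = paste0("p.(", ref3, pos, alt3, ")"),
         paren_nodot = paste0("p(", ref3, pos, alt3, ")"),
         nodot = paste0("p.", ref3, pos, alt3),
         one_letter = paste0("p.", a1[[ref3]], pos, a1[[alt3]]),
         delins_three = paste0("p.", ref3, pos, "delins", alt3),
         delins_one = paste0("p.", a1[[ref3]], pos, "delins", a1[[alt3]]))
}

# Small hand-built design used across evaluation tests: 4 labs, 1 sample,
# 2 characterized variants (one inserted), tight ROI.
tiny_design <- function(n_labs = 4, validation_policy = "ddPCR_or_WES",
                        consensus_fraction = 2 / 3) {
  labs <- sprintf("T%02d", seq_len(n_labs))
  panels <- list(list(
    panel_id = "PANEL-A", enrichment = "amplicon",
    intervals = tibble::tibble(chrom = "chr7",
                               start = c(1000L, 5000L),
                               end = c(1400L, 5400L),
                               name = c("amp1", "amp2"))
  ))
  eqascore::eqa_design(
    benchmark_id = "TEST/1",
    samples = tibble::tibble(sample_id = "S1", cancer_context = "test",
                             replicate_count = 3L,
                             targeted_genes = list(c("BRAF", "EGFR"))),
    participants = labs,
    ordered_variants = tibble::tibble(
      sample_id = "S1", gene = c("BRAF", "EGFR"),
      p_hgvs = c("p.(Val600Glu)", "p.(Thr790Met)"),
      chrom = "chr7", pos = c(1201L, 5201L),
      expected_af = c(12, 30), validation = c("ddPCR", "WES"),
      origin = c("endogenous", "inserted"),
      cassette_start = c(NA_integer_, 4300L),
      cassette_end = c(NA_integer_, 6300L)
    ),
    roi = tibble::tibble(chrom = "chr7", start = c(1100L, 5100L),
                         end = c(1300L, 5300L), name = c("roi1", "roi2")),
    panels = panels,
    panel_assignments = tibble::tibble(participant = labs,
                                       panel_id = "PANEL-A"),
    consensus_fraction = consensus_fraction,
    validation_policy = validation_policy
  )
}

# Reports where every lab finds every tiny_design variant in all 3
# replicates at the expected AF.
tiny_reports <- function(design, af_by_lab = NULL) {
  ov <- design$ordered_variants
  grid <- tidyr::expand_grid(participant = design$participants,
                             idx = seq_len(nrow(ov)), replicate = 1:3)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    v <- ov[grid$idx[i], ]
    p <- grid$participant[i]
    af <- if (!is.null(af_by_lab)) af_by_lab[[p]][grid$idx[i]] else v$expected_af
    tibble::tibble(participant = p, sample_id = v$sample_id,
                   replicate = grid$replicate[i], gene = v$gene,
                   chrom = v$chrom, pos = v$pos,
                   ref_nt = NA_character_, obs_nt = NA_character_,
                   c_hgvs = NA_character_, transcript = NA_character_,
                   p_hgvs = v$p_hgvs, protein_ref = NA_character_,
                   variant_type = "missense", interpretation = NA_character_,
                   af = af, depth = 1000L)
  })
}
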