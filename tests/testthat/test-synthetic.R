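# Synthetic cohorts: determinism, planted outcomes, censoring behavior.

test_that("identical seeds give identical designs and submissions", {
  d1 <- generate_design(n_labs = 6, n_samples = 2, variants_per_sample = 3,
                        inserted_fraction = 0.3, seed = 5)
  d2 <- generate_design(n_labs = 6, n_samples = 2, variants_per_sample = 3,
                        inserted_fraction = 0.3, seed = 5)
  expect_identical(d1, d2)
  d3 <- generate_design(n_labs = 6, n_samples = 2, variants_per_sample = 3,
                        inserted_fraction = 0.3, seed = 6)
  expect_false(identical(d1$ordered_variants, d3$ordered_variants))

  pr <- lab_profiles(d1, seed = 5, miss_prob = 0.1,
                     replicate_dropout_prob = 0.1)
  s1 <- generate_submissions(d1, pr, seed = 5)
  s2 <- generate_submissions(d1, pr, seed = 5)
  expect_identical(s1, s2)
})

test_that("a quiet cohort scores 100% with no false negatives", {
  d <- generate_design(n_labs = 8, n_samples = 2, variants_per_sample = 3,
                       inserted_fraction = 0, seed = 12)
  pr <- lab_profiles(d, seed = 12, miss_prob = 0, replicate_dropout_prob = 0,
                     af_noise_sd_range = c(0, 0), lod_af_range = c(1, 1))
  sub <- generate_submissions(d, pr, seed = 12)
  res <- evaluate_benchmark(d, sub$reports, sub$statuses, policies = pr)
  expect_equal(res$success$global$rate_pct, 100)
  expect_equal(nrow(res$false_negatives), 0L)
  expect_true(all(sub$ledger$detected))
})

test_that("deterministic LOD censoring plants a recoverable below-LOD miss", {
  d <- generate_design(n_labs = 6, n_samples = 1, variants_per_sample = 3,
                       af_range = c(10, 40), inserted_fraction = 0, seed = 8)
  d$ordered_variants$expected_af[1] <- 3.7
  pr <- lab_profiles(d, seed = 8, miss_prob = 0, replicate_dropout_prob = 0,
                     af_noise_sd_range = c(0, 0), lod_af_range = c(1, 1))
  pr$lod_af[pr$participant == "LAB01"] <- 5
  sub <- generate_submissions(d, pr, seed = 8)
  miss <- sub$ledger[!sub$ledger$detected, ]
  expect_equal(miss$participant, "LAB01")
  expect_equal(miss$cause, "below_lod")
  res <- evaluate_benchmark(d, sub$reports, sub$statuses, policies = pr)
  fn <- res$false_negatives
  expect_equal(nrow(fn), 1L)
  expect_equal(fn$participant, "LAB01")
  expect_equal(fn$cause, "below_lod")
})

test_that("with noise and misses disabled the pipeline recovers the ledger exactly", {
  d <- generate_design(n_labs = 10, n_samples = 2, variants_per_sample = 4,
                       inserted_fraction = 0.25, vus_fraction = 0.25,
                       seed = 31)
  # widen one panel so its labs hit the cassette incompatibility
  wide <- d$panels[["PNL01"]]
  wide$panel_id <- "PNL02"
  ins <- which(d$ordered_variants$origin == "inserted")
  wide$intervals$start[ins] <- d$ordered_variants$cassette_start[ins] - 50L
  wide$intervals$end[ins] <- d$ordered_variants$cassette_end[ins] + 50L
  d$panels[["PNL02"]] <- wide
  d$panel_assignments$panel_id[1:3] <- "PNL02"
  pr <- lab_profiles(d, seed = 31, miss_prob = 0, replicate_dropout_prob = 0,
                     af_noise_sd_range = c(0, 0), lod_af_range = c(5, 8),
                     vus_policy_prob = 0.5)
  sub <- generate_submissions(d, pr, seed = 31)
  curated <- dplyr::mutate(
    tidyr::expand_grid(
      participant = pr$participant[pr$vus_policy],
      idx = which(d$ordered_variants$vus)),
    sample_id = d$ordered_variants$sample_id[idx],
    key = d$ordered_variants$key[idx],
    operator_error = FALSE, vus = TRUE)[, c("participant", "sample_id",
                                            "key", "operator_error", "vus")]
  res <- evaluate_benchmark(d, sub$reports, sub$statuses, policies = pr,
                            curated = curated)
  truth_ev <- res$truth[res$truth$classification == "evaluative", ]
  led <- sub$ledger[paste(sub$ledger$sample_id, sub$ledger$key) %in%
                      paste(truth_ev$sample_id, truth_ev$key), ]
  led_miss <- led[!led$detected, ]
  fn <- res$false_negatives
  expect_gt(nrow(led_miss), 0L)
  expect_equal(nrow(fn), nrow(led_miss))
  m <- match(paste(fn$participant, fn$sample_id, fn$key),
             paste(led_miss$participant, led_miss$sample_id, led_miss$key))
  expect_false(anyNA(m))
  expect_equal(fn$cause, led_miss$cause[m])
  expect_true("cassette_incompatibility" %in% fn$cause)
})

test_that("cassette-spanning amplicons for three labs mask exactly three observations", {
  d <- generate_design(n_labs = 9, n_samples = 1, variants_per_sample = 4,
                       inserted_fraction = 0.25, seed = 14)
  ins <- which(d$ordered_variants$origin == "inserted")
  expect_equal(length(ins), 1L)
  wide <- d$panels[["PNL01"]]
  wide$panel_id <- "PNLW"
  wide$intervals$start[ins] <- d$ordered_variants$cassette_start[ins] - 10L
  wide$intervals$end[ins] <- d$ordered_variants$cassette_end[ins] + 10L
  d$panels[["PNLW"]] <- wide
  d$panel_assignments$panel_id[1:3] <- "PNLW"
  mask <- mask_incompatible(d)
  expect_equal(nrow(mask), 3L)
  pr <- lab_profiles(d, seed = 14, miss_prob = 0, replicate_dropout_prob = 0,
                     af_noise_sd_range = c(0, 0), lod_af_range = c(1, 1))
  sub <- generate_submissions(d, pr, seed = 14)
  res <- evaluate_benchmark(d, sub$reports, sub$statuses, policies = pr)
  n_ev <- sum(res$truth$classification == "evaluative")
  expect_equal(res$success$global$total, 9L * n_ev - 3L)
  expect_equal(res$success$global$correct, res$success$global$total)
})

test_that("removing LOD censoring never decreases any success count", {
  d <- generate_design(n_labs = 8, n_samples = 2, variants_per_sample = 3,
                       af_range = c(2, 20), inserted_fraction = 0, seed = 22)
  pr_hi <- lab_profiles(d, seed = 22, miss_prob = 0,
                        replicate_dropout_prob = 0,
                        af_noise_sd_range = c(0.5, 1),
                        lod_af_range = c(5, 10))
  pr_lo <- pr_hi
  pr_lo$lod_af <- 0
  sub_hi <- generate_submissions(d, pr_hi, seed = 22)
  sub_lo <- generate_submissions(d, pr_lo, seed = 22)
  per_lab <- function(sub) {
    l <- sub$ledger
    vapply(split(l$detected, l$participant), sum, integer(1))
  }
  expect_true(all(per_lab(sub_lo) >= per_lab(sub_hi)))
})

test_that("replicate dropout produces invalid statuses, not misses", {
  d <- generate_design(n_labs = 4, n_samples = 2, variants_per_sample = 2,
                       inserted_fraction = 0, seed = 19)
  pr <- lab_profiles(d, seed = 19, miss_prob = 0,
                     replicate_dropout_prob = 0.5,
                     af_noise_sd_range = c(0, 0), lod_af_range = c(1, 1))
  sub <- generate_submissions(d, pr, seed = 19)
  expect_gt(nrow(sub$statuses), 0L)
  expect_true(all(!sub$statuses$valid))
  res <- evaluate_benchmark(d, sub$reports, sub$statuses, policies = pr)
  # dropped replicates shrink the denominator instead of flagging labs
  expect_equal(nrow(res$repeatability), 0L)
  expect_equal(res$success$global$rate_pct, 100)
})

test_that("every dialect rendering produced by the simulator parses back to its source", {
  ch <- parse_protein_hgvs("p.(Val600Glu)")
  for (dia in eqa_dialects()) {
    rendered <- render_dialect(ch, dia)
    expect_equal(canonical_p_hgvs(rendered), "p.(Val600Glu)", info = dia)
  }
  fs <- parse_protein_hgvs("p.(Asn1784Thrfs*7)")
  expect_equal(canonical_p_hgvs(render_dialect(fs, "one_letter")),
               "p.(Asn1784Thrfs*7)")
})
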