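# Detection matrix, success rates, repeatability and false-negative
# classification.

test_that("detection matrix counts valid and reported replicates", {
  d <- tiny_design(n_labs = 3)
  reports <- tiny_reports(d)
  # T02 misses variant 2 entirely; T03 reports variant 1 in 2/3 replicates
  reports <- reports[!(reports$participant == "T02" & reports$gene == "EGFR"), ]
  reports <- reports[!(reports$participant == "T03" & reports$gene == "BRAF" &
                         reports$replicate == 3L), ]
  statuses <- tibble::tibble(participant = "T01", sample_id = "S1",
                             replicate = 2L, valid = FALSE, reason = "QC")
  truth <- classify_truth(d, reports, statuses)
  rec <- detection_matrix(d, reports, truth, statuses)
  expect_equal(nrow(rec), 3L * 2L)
  t01 <- rec[rec$participant == "T01", ]
  expect_equal(unique(t01$replicates_valid), 2L)
  expect_equal(unique(t01$replicates_reported), 2L)
  expect_equal(rec$replicates_reported[rec$participant == "T02" &
                                         rec$gene == "EGFR"], 0L)
  expect_equal(rec$replicates_reported[rec$participant == "T03" &
                                         rec$gene == "BRAF"], 2L)
  expect_true(all(rec$replicates_reported <= rec$replicates_valid))

  # empty reports: all records at zero
  truth0 <- truth
  rec0 <- detection_matrix(d, reports[0, ], truth0, NULL)
  expect_true(all(rec0$replicates_reported == 0L))
})

test_that("success rates count at-least-one-replicate hits over assessable records", {
  d <- tiny_design(n_labs = 3)
  reports <- tiny_reports(d)
  reports <- reports[!(reports$participant == "T02" & reports$gene == "EGFR"), ]
  truth <- classify_truth(d, reports)
  rec <- detection_matrix(d, reports, truth)
  s <- success_rate(rec)
  expect_equal(s$global$correct, 5L)
  expect_equal(s$global$total, 6L)
  expect_equal(s$global$rate_pct, 83.33)
  per <- s$per_participant
  expect_equal(per$correct[per$participant == "T02"], 1L)
  expect_equal(sum(per$correct), s$global$correct)
  expect_equal(sum(per$total), s$global$total)
  expect_error(success_rate(rec[rec$assessable == FALSE, ]), "no assessable")

  # all reported -> 100%
  s2 <- success_rate(detection_matrix(d, tiny_reports(d),
                                      classify_truth(d, tiny_reports(d))))
  expect_equal(s2$global$rate_pct, 100)
})

test_that("masked observations leave denominators and never become false negatives", {
  d <- tiny_design(n_labs = 6)
  # two labs use a panel whose amplicon spans the cassette
  wide <- d$panels[["PANEL-A"]]
  wide$panel_id <- "PANEL-W"
  wide$intervals$start[2] <- 4200L
  wide$intervals$end[2] <- 6400L
  d$panels[["PANEL-W"]] <- wide
  d$panel_assignments$panel_id[d$panel_assignments$participant %in%
                                 c("T05", "T06")] <- "PANEL-W"
  mask <- mask_incompatible(d)
  expect_equal(sort(mask$participant), c("T05", "T06"))
  # masked labs cannot amplify the inserted variant: drop those reports
  reports <- tiny_reports(d)
  reports <- reports[!(reports$gene == "EGFR" &
                         reports$participant %in% c("T05", "T06")), ]
  res <- evaluate_benchmark(d, reports)
  expect_equal(res$success$global$total, 10L)   # 12 records - 2 masked
  expect_equal(res$success$global$correct, 10L)
  expect_equal(res$success$global$rate_pct, 100)
  fn <- res$false_negatives
  expect_equal(nrow(fn), 2L)  # masked misses listed with their cause flag
  expect_true(all(fn$cause == "cassette_incompatibility"))
  expect_true(all(!fn$assessable))
})

test_that("repeatability issues are partial detections over valid replicates", {
  rec <- tibble::tibble(
    participant = c("A", "B", "C", "D"),
    sample_id = "S1", key = "K", gene = "G", p_hgvs = "p.(X)",
    expected_af = 10, origin = "endogenous",
    replicates_valid = c(3L, 3L, 2L, 3L),
    replicates_reported = c(2L, 3L, 2L, 0L),
    reported_afs = list(1, 1, 1, numeric()),
    assessable = TRUE
  )
  issues <- repeatability_issues(rec)
  expect_equal(issues$participant, "A")  # 2/3 yes; 3/3 no; 2/2 no; 0 is a FN
})

test_that("false-negative causes follow the decision cascade", {
  expect_equal(classify_false_negative(FALSE, 20, 5), "cassette_incompatibility")
  expect_equal(classify_false_negative(TRUE, 20, 5, operator_error = TRUE),
               "operator_error")
  expect_equal(classify_false_negative(TRUE, 3.73, 5.0), "below_lod")
  expect_equal(classify_false_negative(TRUE, 5.12, 5.0), "near_lod")
  expect_equal(classify_false_negative(TRUE, 7.5, 5.0), "near_lod")  # boundary
  expect_equal(classify_false_negative(TRUE, 7.6, 5.0), "undetermined")
  expect_equal(classify_false_negative(TRUE, 47, 5, vus = TRUE), "vus_policy")
  expect_equal(classify_false_negative(TRUE, 20, 5), "undetermined")
  # near-LOD outranks the curated VUS flag in the cascade
  expect_equal(classify_false_negative(TRUE, 5.5, 5, vus = TRUE), "near_lod")
  expect_warning(out <- classify_false_negative(TRUE, 20, NA_real_),
                 "no LOD policy")
  expect_equal(out, "undetermined")
})

test_that("z citation tally sums over variants and benchmarks", {
  s1 <- tibble::tibble(cited = c(1L, 0L), allocated = c(10L, 8L))
  s2 <- tibble::tibble(cited = 2L, allocated = 12L)
  t1 <- z_citation_tally(s1)
  expect_equal(t1$cited, 1L)
  expect_equal(t1$allocated, 18L)
  tall <- z_citation_tally(list(s1, s2))
  expect_equal(tall$cited, 3L)
  expect_equal(tall$allocated, 30L)
  expect_equal(tall$pct, 10)
  expect_true(is.na(z_citation_tally(s1[0, ])$proportion))
})

test_that("removing a participant recomputes every denominator consistently", {
  d <- generate_design(n_labs = 9, n_samples = 2, variants_per_sample = 3,
                       seed = 17)
  pr <- lab_profiles(d, seed = 17, miss_prob = 0.15)
  sub <- generate_submissions(d, pr, seed = 17)
  res_full <- evaluate_benchmark(d, sub$reports, sub$statuses, policies = pr)

  drop <- d$participants[5]
  d2 <- d
  d2$participants <- setdiff(d$participants, drop)
  d2$panel_assignments <- d2$panel_assignments[
    d2$panel_assignments$participant != drop, ]
  reports2 <- sub$reports[sub$reports$participant != drop, ]
  res_sub <- evaluate_benchmark(d2, reports2, sub$statuses,
                                policies = pr[pr$participant != drop, ])

  n_ev <- sum(res_sub$truth$classification == "evaluative")
  expect_equal(res_sub$success$global$total, length(d2$participants) * n_ev)
  expect_equal(sum(res_sub$success$per_participant$total),
               res_sub$success$global$total)
  expect_false(drop %in% res_sub$records$participant)
  # per-participant numerators aggregate exactly to the global numerator
  expect_equal(sum(res_sub$success$per_participant$correct),
               res_sub$success$global$correct)
  expect_equal(sum(res_full$success$per_participant$correct),
               res_full$success$global$correct)
})
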