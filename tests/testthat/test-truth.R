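# Truth-set classification, consensus threshold, ROI membership and
# cassette-incompatibility masking.

test_that("consensus threshold is the smallest k with k/n >= fraction", {
  expect_equal(consensus_threshold(12), 8L)
  expect_equal(consensus_threshold(16), 11L)
  expect_equal(consensus_threshold(15), 10L)
  for (n in 1:40) {
    k <- consensus_threshold(n)
    expect_true(k / n >= 2 / 3 - 1e-12)
    if (k > 1) expect_true((k - 1) / n < 2 / 3)
  }
})

test_that("ROI membership uses half-open 0-based intervals", {
  roi <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L,
                        name = "r")
  expect_true(in_roi("chr1", 101L, roi))   # 1-based 101 -> 0-based 100
  expect_true(in_roi("chr1", 200L, roi))   # 0-based 199, last inside
  expect_false(in_roi("chr1", 201L, roi))  # 0-based 200 == end, outside
  expect_false(in_roi("chr2", 150L, roi))
  expect_warning(out <- in_roi("chr1", NA_integer_, roi), "position missing")
  expect_false(out)
})

test_that("ROI membership agrees with a brute-force scan on random inputs", {
  set.seed(21)
  roi <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                        start = sample(1:5000, 30), name = NA_character_)
  roi$end <- roi$start + sample(1:300, 30, TRUE)
  for (i in 1:200) {
    chrom <- sample(c("chr1", "chr2", "chr3"), 1)
    pos <- sample(1:6000, 1)
    expect_equal(in_roi(chrom, pos, roi), oracle_in_roi(chrom, pos, roi),
                 info = paste(chrom, pos))
  }
})

make_reports_for <- function(design, labs_by_variant) {
  ov <- design$ordered_variants
  purrr::map_dfr(seq_len(nrow(ov)), function(i) {
    labs <- labs_by_variant[[i]]
    if (!length(labs)) return(NULL)
    tidyr::expand_grid(participant = labs, replicate = 1:3) |>
      dplyr::mutate(sample_id = ov$sample_id[i], gene = ov$gene[i],
                    chrom = ov$chrom[i], pos = ov$pos[i],
                    p_hgvs = ov$p_hgvs[i], af = ov$expected_af[i],
                    depth = 1000L)
  })
}

test_that("classification follows validation, ROI and consensus rules", {
  d <- tiny_design(n_labs = 6)
  # variant 1 reported by 5/6 (>= ceil(4) = 4), variant 2 by nobody
  reports <- make_reports_for(d, list(d$participants[1:5], character()))
  truth <- classify_truth(d, reports)
  v1 <- truth[truth$gene == "BRAF", ]
  v2 <- truth[truth$gene == "EGFR", ]
  expect_equal(v1$classification, "evaluative")
  expect_equal(v1$reporting_count, 5L)
  expect_equal(v2$classification, "not_assessed")

  # below consensus: validated in-ROI variant reported by 2/6 -> informative
  truth2 <- classify_truth(d, make_reports_for(d, list(d$participants[1:2],
                                                       character())))
  expect_equal(truth2$classification[truth2$gene == "BRAF"], "informative")

  # unvalidated extra inside ROI reported by most labs -> informative only
  extra <- make_reports_for(d, list(d$participants[1:5], character()))
  extra$gene <- "KRAS"
  extra$p_hgvs <- "p.(Gly12Cys)"
  extra$pos <- 1205L  # inside roi1
  truth3 <- classify_truth(d, dplyr::bind_rows(
    make_reports_for(d, list(d$participants, character())), extra))
  kras <- truth3[truth3$gene == "KRAS", ]
  expect_equal(kras$classification, "informative")
  expect_false(kras$validated)

  # outside ROI -> not assessed regardless of reporting
  off <- extra
  off$pos <- 4000L
  truth4 <- classify_truth(d, dplyr::bind_rows(
    make_reports_for(d, list(d$participants, character())), off))
  expect_equal(truth4$classification[truth4$gene == "KRAS"], "not_assessed")
})

test_that("the ddPCR-only validation policy demotes WES-validated variants", {
  d <- tiny_design(n_labs = 6, validation_policy = "ddPCR_only")
  reports <- make_reports_for(d, list(d$participants, d$participants))
  truth <- classify_truth(d, reports)
  expect_equal(truth$classification[truth$gene == "BRAF"], "evaluative")
  # EGFR variant is WES-validated only -> informative under ddPCR-only
  expect_equal(truth$classification[truth$gene == "EGFR"], "informative")
})

test_that("raising the reporting count never demotes a variant", {
  d <- tiny_design(n_labs = 9)
  ranks <- c(not_assessed = 0L, informative = 1L, evaluative = 2L)
  prev <- -1L
  for (k in 0:9) {
    reports <- make_reports_for(d, list(d$participants[seq_len(k)],
                                        character()))
    truth <- classify_truth(d, reports)
    lvl <- ranks[[truth$classification[truth$gene == "BRAF"]]]
    expect_gte(lvl, prev)
    prev <- lvl
  }
})

test_that("masking requires an amplicon strictly spanning both cassette boundaries", {
  d <- tiny_design()  # amplicon chr7:[5000,5400) vs cassette [4300,6300)
  expect_equal(nrow(mask_incompatible(d)), 0L)

  # widen the amplicon beyond the cassette: every lab masked on the
  # inserted variant
  d2 <- tiny_design()
  d2$panels[["PANEL-A"]]$intervals$start[2] <- 4200L
  d2$panels[["PANEL-A"]]$intervals$end[2] <- 6400L
  m <- mask_incompatible(d2)
  expect_equal(nrow(m), length(d2$participants))
  expect_equal(unique(m$reason), "cassette_incompatibility")
  expect_true(all(grepl("Thr790Met", m$key)))

  # partial overlap (amplicon inside the cassette on one side): assessable
  d3 <- tiny_design()
  d3$panels[["PANEL-A"]]$intervals$start[2] <- 4200L
  d3$panels[["PANEL-A"]]$intervals$end[2] <- 6300L  # end == cassette end
  expect_equal(nrow(mask_incompatible(d3)), 0L)

  # probe-based enrichment is never masked
  d4 <- tiny_design()
  d4$panels[["PANEL-A"]]$intervals$start[2] <- 4200L
  d4$panels[["PANEL-A"]]$intervals$end[2] <- 6400L
  d4$panels[["PANEL-A"]]$enrichment <- "probe"
  expect_equal(nrow(mask_incompatible(d4)), 0L)

  # a participant without a panel triggers a warning and no masking
  d5 <- tiny_design()
  d5$panels[["PANEL-A"]]$intervals$start[2] <- 4200L
  d5$panels[["PANEL-A"]]$intervals$end[2] <- 6400L
  d5$panel_assignments <- d5$panel_assignments[-1, ]
  expect_warning(m5 <- mask_incompatible(d5), "no panel definition")
  expect_equal(nrow(m5), length(d5$participants) - 1L)
})

test_that("counting reporters collapses replicates and respects invalid statuses", {
  d <- tiny_design(n_labs = 4)
  reports <- make_reports_for(d, list(d$participants[1:3], character()))
  key <- d$ordered_variants$key[1]
  expect_equal(count_reporting_participants(reports, key, "S1"), 3L)
  # invalidating all three replicates of one lab removes it
  statuses <- tibble::tibble(participant = "T01", sample_id = "S1",
                             replicate = 1:3, valid = FALSE, reason = "QC")
  expect_equal(count_reporting_participants(reports, key, "S1", statuses), 2L)
  expect_equal(count_reporting_participants(reports[0, ], key, "S1"), 0L)
})
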