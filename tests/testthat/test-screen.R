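test_that("a depletion factor of 1 gives ratio exactly 1 through paired seeds", {
  tr <- make_trna_complement()
  tx <- make_transcriptome(
    4, tr, length_range = c(60, 90),
    planted = tibble::tibble(focal_codon = "CAG", n = 2, count = 5,
                             placement = "dispersed"),
    seed = 6)
  scr <- run_screen(tx$cds, tr, depletion("tRNA-Q-s01", 1.0), seed = 2,
                    config = fast_config(200))
  expect_identical(scr$ratio, rep(1, 4))
  expect_false(any(scr$sensitive))
  sc <- alpha_scan(tx$cds[1, ], tr, depletion("tRNA-Q-s01", 1.0),
                   alphas = c(0.3, 0.05), seed = 2, config = fast_config(200))
  expect_identical(sc$ratio, rep(1, 2))
})

test_that("replacing every focal codon with its synonym makes translation immune", {
  tr <- make_trna_complement()
  far <- far7_like_fixture(tr)
  swapped <- swap_codons(far, "CAG", "CAA")
  sc <- alpha_scan(swapped, tr, depletion("tRNA-Q-s01", 0.25),
                   alphas = c(0.3, 0.1, 0.02), seed = 8, config = fast_config(300))
  expect_identical(sc$ratio, rep(1, 3))
  # the unswapped control is genuinely affected at physiological initiation
  sc0 <- alpha_scan(far, tr, depletion("tRNA-Q-s01", 0.25), alphas = 0.3,
                    seed = 8, config = fast_config(300))
  expect_lt(sc0$ratio, 0.9)
})

test_that("a screen flags exactly the planted queue-prone ORFs", {
  tr <- make_trna_complement()
  tx <- make_transcriptome(
    20, tr,
    planted = tibble::tibble(focal_codon = "CAG", n = 5, count = 12,
                             placement = "clustered_5prime", length = 221),
    seed = 3)
  scr <- run_screen(tx$cds, tr, depletion("tRNA-Q-s01", 0.25), seed = 9,
                    config = fast_config(500))
  expect_equal(scr$sensitive, tx$truth$sensitive_expected)
  # background ORFs carry no focal codon, so their ratios are exactly 1
  expect_identical(scr$ratio[!tx$truth$sensitive_expected], rep(1, 15))
  # screen output is invariant to transcriptome ordering
  perm <- sample(nrow(tx$cds))
  scr2 <- run_screen(tx$cds[perm, ], tr, depletion("tRNA-Q-s01", 0.25),
                     seed = 9, config = fast_config(500))
  expect_equal(scr2$ratio[match(scr$orf_id, scr2$orf_id)], scr$ratio)
  # sensitivity calls are monotone in the threshold
  strict <- run_screen(tx$cds, tr, depletion("tRNA-Q-s01", 0.25), seed = 9,
                       threshold = 0.3, config = fast_config(500))
  expect_true(all(which(strict$sensitive) %in% which(scr$sensitive)))
})

test_that("planted sensitivity calls are reproducible across master seeds", {
  tr <- make_trna_complement()
  tx <- make_transcriptome(
    8, tr,
    planted = tibble::tibble(focal_codon = "CAG", n = 3, count = 12,
                             placement = "clustered_5prime", length = 221),
    seed = 12)
  hits <- sapply(1:5, function(ms) {
    scr <- run_screen(tx$cds, tr, depletion("tRNA-Q-s01", 0.25), seed = ms,
                      config = fast_config(300))
    scr$sensitive
  })
  freq <- rowMeans(hits)
  expect_true(all(freq[tx$truth$sensitive_expected] >= 0.9))
  expect_true(all(freq[!tx$truth$sensitive_expected] <= 0.1))
})

test_that("ORFs shorter than the footprint are skipped with a warning", {
  tr <- make_trna_complement()
  cds <- cds_table(c("ok", "tiny"),
                   list(c("ATG", rep("GAA", 20)), c("ATG", "GAA")))
  expect_warning(
    scr <- run_screen(cds, tr, depletion("tRNA-Q-s01", 0.25), seed = 1,
                      config = fast_config(200)),
    "tiny")
  expect_equal(scr$orf_id, "ok")
  expect_equal(attr(scr, "skipped"), "tiny")
})

test_that("an empty transcriptome yields an empty record table", {
  tr <- make_trna_complement()
  empty <- cds_table(character(), list())[0, ]
  scr <- run_screen(empty, tr, depletion("tRNA-Q-s01", 0.25), seed = 1)
  expect_equal(nrow(scr), 0)
  expect_true(all(c("orf_id", "ratio", "sensitive") %in% names(scr)))
})

test_that("surveying every species flags only each species' planted targets", {
  tr <- make_trna_complement()
  tx <- make_transcriptome(
    10, tr,
    planted = tibble::tibble(focal_codon = c("CAG", "AGG"), n = c(2, 2),
                             count = 12, placement = "clustered_5prime",
                             length = 150),
    seed = 19)
  sv <- multi_trna_screen(tx$cds, tr, factor = 0.25, seed = 5,
                          config = fast_config(300),
                          trna_names = c("tRNA-Q-s01", "tRNA-R-s02"))
  hits <- sv[sv$sensitive, ]
  expect_setequal(hits$orf_id[hits$trna_name == "tRNA-Q-s01"],
                  tx$truth$orf_id[which(tx$truth$focal_codon == "CAG")])
  expect_setequal(hits$orf_id[hits$trna_name == "tRNA-R-s02"],
                  tx$truth$orf_id[which(tx$truth$focal_codon == "AGG")])
  # the two targeted sets are disjoint by construction
  expect_length(intersect(hits$orf_id[hits$trna_name == "tRNA-Q-s01"],
                          hits$orf_id[hits$trna_name == "tRNA-R-s02"]), 0)
  summ <- summarise_survey(sv, tr)
  expect_equal(summ$n_sensitive[summ$trna_name == "tRNA-Q-s01"], 2)
  # factor 1 is a no-op for every species
  sv1 <- multi_trna_screen(tx$cds[1:4, ], tr, factor = 1, seed = 5,
                           config = fast_config(200),
                           trna_names = c("tRNA-Q-s01", "tRNA-D-a03"))
  expect_identical(sv1$ratio, rep(1, 8))
})

test_that("composition-sensitivity correlation recovers planted dependence", {
  # composition-dependent sensitivity: ratio decreases with the focal share
  set.seed(1)
  n <- 60
  comp <- runif(n, 0, 4)
  records <- tibble::tibble(orf_id = sprintf("o%02d", 1:n),
                            ratio = pmax(0.05, 1 - 0.18 * comp + rnorm(n, 0, 0.05)))
  stats <- tibble::tibble(orf_id = records$orf_id, ratio = comp)
  out <- correlate_sensitivity(records, stats, top_n = n)
  expect_lt(out$pearson_r, 0)
  expect_gt(out$r_squared, 0.3)
  # composition independent of sensitivity: correlation consistent with 0
  set.seed(2)
  records$ratio <- runif(n, 0.2, 1)
  out0 <- correlate_sensitivity(records, stats, top_n = n)
  expect_lt(abs(out0$pearson_r), 3 / sqrt(n))
  # undefined cases
  stats$ratio <- 1
  expect_error(correlate_sensitivity(records, stats, top_n = n), "zero variance")
  expect_error(correlate_sensitivity(records[1:2, ], stats[1:2, ], top_n = 5),
               "fewer than 3")
  # non-finite compositions are excluded and counted
  stats$ratio <- comp; stats$ratio[1:4] <- c(Inf, NaN, Inf, NaN)
  set.seed(3)
  records$ratio <- pmax(0.05, 1 - 0.18 * comp + rnorm(n, 0, 0.05))
  out2 <- correlate_sensitivity(records, stats, top_n = n)
  expect_equal(out2$n_excluded, 4)
  expect_equal(out2$n_used, n - 4)
})

test_that("density comparison is symmetric under a no-op depletion", {
  tr <- make_trna_complement()
  far <- far7_like_fixture(tr)
  dc <- density_compare(far, tr, depletion("tRNA-Q-s01", 1.0),
                        window = 1:20, seed = 3, config = fast_config(300))
  expect_true(all(dc$differential$diff == 0))
  expect_identical(dc$summary$mean_diff, c(0, 0))
  expect_error(density_compare(far, tr, depletion("tRNA-Q-s01", 0.25),
                               window = 200:230, seed = 3), "window")
})

test_that("alpha scans are sorted and bounded by 1 within noise", {
  tr <- make_trna_complement()
  far <- far7_like_fixture(tr)
  sc <- alpha_scan(far, tr, depletion("tRNA-Q-s01", 0.25),
                   alphas = c(0.3, 0.01, 0.1), seed = 21,
                   config = fast_config(400))
  expect_identical(sc$alpha, c(0.01, 0.1, 0.3))
  expect_true(all(sc$ratio <= 1 + 3 * sc$ratio_se))
})
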