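test_that("best-sample selection keeps the highest-detection primary sample", {
  em <- tiny_matrix(10, 4, detection = TRUE)
  # patient P1 owns S01 (40% detectable) and S02 (70%); S03 is a metastasis
  em$detection_p[, "S01"] <- c(rep(0.001, 4), rep(0.5, 6))
  em$detection_p[, "S02"] <- c(rep(0.001, 7), rep(0.5, 3))
  ann <- tiny_annotation(colnames(em$values))
  ann$patient_id[2] <- ann$patient_id[1]
  ann$tissue_site[3] <- "other"
  out <- select_best_sample(em, ann)
  expect_setequal(colnames(out$values), c("S02", "S04"))
  # single-sample patients pass through unchanged
  out2 <- select_best_sample(em[, c("S02", "S04")], ann)
  expect_identical(colnames(out2$values), c("S02", "S04"))
  em$detection_p <- NULL
  expect_error(select_best_sample(em, ann), "detection")
})

test_that("detection filter applies strict 30%/10% boundaries, samples first", {
  n <- 100
  v <- matrix(1, n, 4, dimnames = list(sprintf("P%03d", 1:n), paste0("S", 1:4)))
  dp <- matrix(0.5, n, 4, dimnames = dimnames(v))
  dp[1:29, 1] <- 0.001   # 29% detectable: below the 30% bound, removed
  dp[1:30, 2] <- 0.001   # exactly 30%: kept
  dp[1:80, 3] <- 0.001
  dp[1:80, 4] <- 0.001
  em <- expression_matrix(v, detection_p = dp, log2 = TRUE)
  res <- detection_filter(em)
  expect_false("S1" %in% colnames(res$matrix$values))
  expect_true("S2" %in% colnames(res$matrix$values))
  # probes detected in none of the remaining samples are gone
  expect_false(any(rowSums(detectable_mask(res$matrix)) == 0))
  expect_error(detection_filter(em, sample_min = 1.01), "all samples removed")
})

test_that("detection filter counts match hand enumeration on a 10x10 pattern", {
  n <- 10
  v <- matrix(1, n, n, dimnames = list(sprintf("P%02d", 1:n), sprintf("S%02d", 1:n)))
  dp <- matrix(0.5, n, n, dimnames = dimnames(v))
  for (j in 1:n) dp[seq_len(j), j] <- 0.001   # sample j detects probes 1..j
  em <- expression_matrix(v, detection_p = dp, log2 = TRUE)
  res <- detection_filter(em, sample_min = 0.30, probe_min = 0.20)
  # by hand: samples 1-2 fall below 30%; among the 8 left, probe 10 is seen
  # only in sample 10 (1/8 = 12.5% < 20%)
  expect_equal(res$report$steps$n_samples_out, 8)
  expect_equal(res$report$steps$n_probes_out, 9)
  expect_identical(res$report$details$detection_filter$samples_removed,
                   c("S01", "S02"))
  expect_identical(res$report$details$detection_filter$probes_removed, "P10")
})

test_that("longest-run tail probability is exact", {
  expect_equal(run_pvalue(3, 3, 0.5), 0.125)
  for (n in c(2, 5, 8))
    expect_equal(run_pvalue(n, 1, 0.5), 1 - 0.5^n)
  expect_equal(run_pvalue(8, 4, 0.5), run_pvalue_enum(8, 4, 0.5), tolerance = 1e-12)
  expect_equal(run_pvalue(10, 3, 0.8), run_pvalue_enum(10, 3, 0.8), tolerance = 1e-12)
  expect_identical(run_pvalue(5, 2, 0), 1)
  expect_identical(run_pvalue(5, 2, 1), 0)
  expect_error(run_pvalue(5, 0, 0.5), "k must satisfy")
  expect_error(run_pvalue(5, 6, 0.5), "k must satisfy")
})

test_that("batch filter removes slide-clustered dropout, keeps scattered dropout", {
  set.seed(31)
  n_s <- 88; n_p <- 40
  v <- matrix(2^rnorm(n_p * n_s, 8), n_p,
              dimnames = list(sprintf("P%02d", 1:n_p), sprintf("S%02d", 1:n_s)))
  det <- matrix(runif(n_p * n_s) < 0.95, n_p, n_s)   # well-behaved probes
  det[1, ] <- TRUE
  det[1, 33:40] <- FALSE                             # full run on slide 5
  det[2, ] <- runif(n_s) < 0.5                       # scattered 50% dropout
  dp <- matrix(0.5, n_p, n_s, dimnames = dimnames(v))
  dp[det] <- 0.001
  em <- expression_matrix(v, detection_p = dp,
                          slide = sprintf("sl%02d", (seq_len(n_s) - 1) %/% 8 + 1))
  res <- batch_run_filter(em, alpha = 1e-4)
  removed <- res$report$details$batch_run_filter$probes_removed
  expect_true("P01" %in% removed)
  expect_false("P02" %in% removed)
  # oracle: the full-run p-value is Bonferroni-small at a 91% detection rate
  expect_lt(run_pvalue(8, 8, sum(det[1, ]) / n_s) * 11, 1e-4)
  # scattered 50% dropout can never reach alpha with slides of 8
  expect_gt(run_pvalue(8, 8, 0.5) * 11, 1e-4)
  em$slide <- NULL
  expect_error(batch_run_filter(em), "slide")
})

test_that("quantile normalization matches the hand-computed 4x3 case", {
  v <- matrix(c(5, 2, 3, 4,
                4, 1, 4.5, 2,
                3, 6, 8, 7), 4,
              dimnames = list(paste0("P", 1:4), paste0("S", 1:3)))
  em <- expression_matrix(v, log2 = TRUE)
  res <- normalize_expression(em)
  t_exp <- c(2, 11 / 3, 5, 17.5 / 3)  # means of per-sample sorted values
  expect_equal(res$matrix$values[, "S1"], t_exp[c(4, 1, 2, 3)],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(res$matrix$values[, "S2"], t_exp[c(3, 1, 4, 2)],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(res$matrix$values[, "S3"], t_exp[c(1, 2, 4, 3)],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("quantile normalization agrees with the limma oracle on complete data", {
  set.seed(5)
  v <- matrix(rnorm(180, 8), 30, 6,
              dimnames = list(sprintf("P%02d", 1:30), sprintf("S%d", 1:6)))
  em <- expression_matrix(v, log2 = TRUE)
  ours <- normalize_expression(em, outlier_sd = Inf)$matrix$values
  oracle <- limma::normalizeQuantiles(v)
  expect_equal(ours, oracle, tolerance = 1e-9)
})

test_that("normalization guards: constant samples, raw scale, idempotency", {
  set.seed(6)
  v <- matrix(2^rnorm(120, 8), 30, 4,
              dimnames = list(sprintf("P%02d", 1:30), paste0("S", 1:4)))
  v[3, 2] <- 2^16   # a gross outlier on the raw scale
  em <- expression_matrix(v)
  res <- normalize_expression(em)
  expect_true(res$matrix$log2)
  expect_true(res$matrix$imputed[3, 2])
  srt <- apply(res$matrix$values, 2, sort)
  expect_lt(max(abs(srt - srt[, 1])), 1e-12)
  # idempotent on its own output
  again <- normalize_expression(res$matrix)
  expect_equal(again$matrix$values, res$matrix$values, tolerance = 1e-9)
  # constant sample: SD = 0 guard, nothing masked
  v2 <- v; v2[, 4] <- 5
  res2 <- normalize_expression(expression_matrix(v2))
  expect_equal(sum(res2$matrix$imputed[, 4]), 0)
  # non-positive raw intensity errors with the offending cell named
  v3 <- v; v3[2, 1] <- 0
  expect_error(normalize_expression(expression_matrix(v3)), "P02.*S1")
})

test_that("count log transform is exact and monotone", {
  m <- matrix(c(0, 7, 1, 3), 2, dimnames = list(c("G1", "G2"), c("A", "B")))
  lt <- log_transform_counts(m)
  expect_equal(lt["G1", "A"], 0)
  expect_equal(lt["G2", "A"], 3)
  expect_true(attr(lt, "log2"))
  set.seed(2)
  x <- matrix(rpois(30, 10), 5, dimnames = list(paste0("G", 1:5), paste0("S", 1:6)))
  expect_identical(order(x[, 1]), order(log_transform_counts(x)[, 1]))
  expect_error(log_transform_counts(matrix(-1, 1, 1,
                                           dimnames = list("G1", "S1"))),
               "negative")
})

test_that("pipeline QC report telescopes across all four steps", {
  sigs <- synthetic_signatures(sizes = c(basal = 20), n_genes = 300, seed = 2)
  cc <- simulate_cohort(32, 300, sigs, slide_size = 8, n_batch_probes = 2,
                        detect_rate = 0.6, seed = 17)
  pp <- preprocess_pipeline(cc$matrix, cc$annotation)
  st <- pp$report$steps
  expect_identical(st$n_samples_in[-1], st$n_samples_out[-nrow(st)])
  expect_identical(st$n_probes_in[-1], st$n_probes_out[-nrow(st)])
  expect_identical(st$n_samples_out[nrow(st)], ncol(pp$matrix$values))
  expect_identical(st$n_probes_out[nrow(st)], nrow(pp$matrix$values))
})
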