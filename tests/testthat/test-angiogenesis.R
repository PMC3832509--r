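test_that("VEGF rank score averages per-gene expression ranks", {
  genes <- c("VG1", "VG2", "VG3")
  v <- matrix(c(1, 5, 2, 9,    # VG1 ranks 1, 3, 2, 4
                4, 4, 6, 8,    # VG2 ranks 1.5, 1.5, 3, 4 (tie)
                2, 1, 3, 7),   # VG3 ranks 2, 1, 3, 4
              3, byrow = TRUE, dimnames = list(paste0("P", 1:3), paste0("S", 1:4)))
  em <- expression_matrix(v, gene_symbols = genes, log2 = TRUE)
  sc <- vegf_rank_score(em, c(genes, "ABSENT"))
  expect_equal(as.vector(sc), c(mean(c(1, 1.5, 2)), mean(c(3, 1.5, 1)),
                                mean(c(2, 3, 3)), 4), tolerance = 1e-12)
  expect_setequal(attr(sc, "genes_used"), genes)
  # a single gene reduces to that gene's rank vector
  one <- vegf_rank_score(em, "VG3")
  expect_equal(as.vector(one), c(2, 1, 3, 4))
  # the everywhere-maximal sample scores n_samples
  expect_equal(sc[["S4"]], 4)
  expect_error(vegf_rank_score(em, "NOPE"), "no VEGF profile genes")
})

test_that("per-gene group tests report Welch p and Bonferroni multiplier", {
  set.seed(16)
  em <- tiny_matrix(8, 6)
  grp <- rep(c("AA", "EA"), each = 3)
  res <- per_gene_group_test(em, c(em$gene_symbols[1:3], "GONE"), grp)
  expect_match(res$note[res$gene == "GONE"], "absent")
  tested <- res[res$note == "", ]
  expect_equal(tested$bonferroni_p, pmin(1, 3 * tested$p), tolerance = 1e-12)
  # identical groups give p = 1
  em2 <- em
  em2$values[, 4:6] <- em2$values[, 1:3]
  res2 <- per_gene_group_test(em2, em$gene_symbols[1:2], grp)
  expect_equal(res2$p, c(1, 1))
})

test_that("planted shifts in a subset of profile genes are exactly the ones called", {
  # mirrors a profile where 6 of 11 genes respond: at n = 45 per group and a
  # 2 SD shift, exactly the shifted genes should clear Bonferroni-0.05
  genes <- sprintf("VG%02d", 1:11)
  shifted <- genes[1:6]
  hits <- vapply(1:50, function(i) {
    set.seed(400 + i)
    v <- matrix(rnorm(11 * 90, 8, 1), 11,
                dimnames = list(genes, sprintf("S%02d", 1:90)))
    grp <- rep(c("AA", "EA"), each = 45)
    v[1:6, grp == "AA"] <- v[1:6, grp == "AA"] + 2
    em <- expression_matrix(v, gene_symbols = genes, log2 = TRUE)
    res <- per_gene_group_test(em, genes, grp)
    setequal(res$gene[res$bonferroni_p < 0.05], shifted)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("tumor mask recovers planted blobs and applies the 5% exclusion", {
  sim <- simulate_histospot(size_px = 160, tumor_fraction = 0.5,
                            vessel_fraction = 0, seed = 21)
  sp <- tumor_mask(sim$spot)
  expect_false(sp$excluded)
  expect_lt(abs(mean(sp$tumor) - 0.5), 0.05)
  low <- simulate_histospot(size_px = 160, tumor_fraction = 0.03, seed = 22)
  expect_true(tumor_mask(low$spot)$excluded)
  expect_match(tumor_mask(low$spot)$exclusion_reason, "below")
  # blank and noise-only channels are excluded as signal-free
  flat <- histospot(matrix(0.2, 64, 64), matrix(0.1, 64, 64), matrix(0.1, 64, 64))
  expect_match(tumor_mask(flat)$exclusion_reason, "no signal")
  set.seed(23)
  noisy <- histospot(matrix(pmax(0, rnorm(64^2, 0.2, 0.05)), 64),
                     matrix(0.1, 64, 64), matrix(0.1, 64, 64))
  expect_true(tumor_mask(noisy)$excluded)
})

test_that("compartment masks partition the tumor exactly", {
  sim <- simulate_histospot(size_px = 160, tumor_fraction = 0.5,
                            nuclei_frac = 0.2, seed = 24)
  sp <- compartment_masks(tumor_mask(sim$spot))
  expect_identical(sp$nuclear | sp$non_nuclear, sp$tumor)
  expect_false(any(sp$nuclear & sp$non_nuclear))
  expect_lt(abs(sum(sp$nuclear) / sum(sp$tumor) - 0.2), 0.05)
  # blank DAPI: empty nuclear compartment
  sp2 <- tumor_mask(sim$spot)
  sp2$dapi <- matrix(0, nrow(sp2$dapi), ncol(sp2$dapi))
  sp2 <- compartment_masks(sp2)
  expect_equal(sum(sp2$nuclear), 0)
  expect_error(compartment_masks(sim$spot), "tumor mask")
})

test_that("microvessel area recovers planted fractions and nests in the tumor", {
  sim <- simulate_histospot(size_px = 160, vessel_fraction = 0.02, seed = 25)
  r <- quantify_spot(sim$spot)
  expect_lt(abs(r$mva_percent - 100 * sim$truth$vessel_fraction), 0.3)
  expect_true(all(r$vessel <= r$tumor))
  # zero CD31 signal gives exactly zero MVA and low call
  sim0 <- simulate_histospot(size_px = 160, vessel_fraction = 0, seed = 26)
  r0 <- quantify_spot(sim0$spot)
  expect_equal(r0$mva_percent, 0)
  expect_false(r0$high_mva)
  # default dichotomization threshold is 0.6%
  expect_equal(formals(microvessel_area)$threshold_pct, 0.6)
  # excluded spots refuse quantification
  low <- tumor_mask(simulate_histospot(size_px = 160, tumor_fraction = 0.03,
                                       seed = 27)$spot)
  expect_error(microvessel_area(low), "excluded")
})

test_that("MVA quantification is invariant to positive channel scaling", {
  sim <- simulate_histospot(size_px = 128, vessel_fraction = 0.02, seed = 28)
  r1 <- quantify_spot(sim$spot)
  scaled <- sim$spot
  for (ch in c("cytokeratin", "dapi", "cd31")) scaled[[ch]] <- 3.7 * scaled[[ch]]
  r2 <- quantify_spot(scaled)
  expect_equal(r2$mva_percent, r1$mva_percent, tolerance = 1e-12)
  expect_identical(r2$tumor, r1$tumor)
})

test_that("MVA-covariate association reports Fisher and Welch side by side", {
  # perfectly separated 2x2 table: 10 high/pos vs 10 low/neg
  mk <- function(id, mva, excl = FALSE)
    structure(list(spot_id = id, tumor_fraction = 0.5, mva_percent = mva,
                   high_mva = mva > 0.6, excluded = excl,
                   reason = if (excl) "tumor content low" else NULL,
                   tumor = NULL, vessel = NULL), class = "mva_result")
  spots <- c(lapply(1:10, function(i) mk(paste0("hp", i), 2.0)),
             lapply(1:10, function(i) mk(paste0("lp", i), 0.1)),
             list(mk("xx", NA, excl = TRUE)))
  patients <- c(sprintf("PT%02d", 1:20), "PT99")
  ann <- data.frame(patient_id = c(sprintf("PT%02d", 1:20), "PT99"),
                    nodal = c(rep("pos", 10), rep("neg", 10), "pos"),
                    stringsAsFactors = FALSE)
  res <- mva_association(spots, patients, ann, covariate = "nodal")
  expect_setequal(res$tests$test, c("fisher_threshold", "welch_numeric"))
  # exact two-sided Fisher p for the (10,0 / 0,10) table
  p_exact <- 2 / choose(20, 10)
  expect_equal(res$tests$p[res$tests$test == "fisher_threshold"], p_exact,
               tolerance = 1e-10)
  expect_lt(res$tests$p[res$tests$test == "welch_numeric"], 0.001)
  expect_identical(res$dropped_patients, "PT99")
  # per-patient aggregation is the mean over non-excluded spots
  spots2 <- list(mk("a", 1.0), mk("b", 2.0), mk("c", 0.1), mk("d", 0.3),
                 mk("e", 1.4), mk("f", 0.2))
  res2 <- mva_association(spots2, c("P1", "P1", "P2", "P2", "P3", "P4"),
                          data.frame(patient_id = paste0("P", 1:4),
                                     nodal = c("pos", "neg", "pos", "neg")),
                          covariate = "nodal")
  expect_equal(res2$patient_mva$mva_percent[res2$patient_mva$patient_id == "P1"],
               1.5)
  expect_equal(res2$patient_mva$mva_percent[res2$patient_mva$patient_id == "P2"],
               0.2)
})
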