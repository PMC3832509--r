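test_that("activation score is the Pearson correlation with the weight vector", {
  w <- c(2, -1, 0.5, 1.5)
  genes <- paste0("G", 1:4)
  prof <- c(8.2, 6.1, 7.0, 7.9)
  v <- cbind(match = w, hand = prof)
  rownames(v) <- genes
  em <- expression_matrix(v, gene_symbols = genes, log2 = TRUE)
  sig <- gene_signature("s", genes, w)
  sc <- activation_score(em, sig)
  expect_equal(sc[["match"]], 1, tolerance = 1e-12)
  # textbook Pearson formula, spelled out
  r_hand <- sum((w - mean(w)) * (prof - mean(prof))) /
    sqrt(sum((w - mean(w))^2) * sum((prof - mean(prof))^2))
  expect_equal(sc[["hand"]], r_hand, tolerance = 1e-12)
  # a +1/-1 signature against an opposing profile scores -1
  v2 <- matrix(c(2, 8, 2, 8), 4, 1, dimnames = list(genes, "s1"))
  em2 <- expression_matrix(v2, gene_symbols = genes, log2 = TRUE)
  # need >= 3 genes: use 4-gene alternating signature
  sig2 <- gene_signature("dir", genes, c(1, -1, 1, -1))
  expect_equal(activation_score(em2, sig2)[["s1"]], -1, tolerance = 1e-12)
})

test_that("activation score is invariant to affine weight rescaling", {
  set.seed(12)
  em <- tiny_matrix(20, 6)
  genes <- em$gene_symbols[1:10]
  w <- rnorm(10)
  base <- activation_score(em, gene_signature("a", genes, w))
  for (ab in list(c(2, 0), c(0.5, 3), c(10, -7))) {
    resc <- activation_score(em, gene_signature("b", genes, ab[1] * w + ab[2]))
    expect_equal(as.vector(resc), as.vector(base), tolerance = 1e-10)
  }
})

test_that("unscorable signatures and degenerate profiles are flagged, not zeroed", {
  em <- tiny_matrix(6, 3)
  sig <- gene_signature("missing", c("NOPE1", "NOPE2", "G001"), c(1, -1, 0.5))
  sc <- activation_score(em, sig)
  expect_true(attr(sc, "unscorable"))
  expect_true(all(is.na(sc)))
  expect_equal(attr(sc, "n_genes_used"), 1L)
  # zero-variance sample sub-profile gives NA for that sample only
  em2 <- tiny_matrix(6, 3)
  em2$values[, 2] <- 4
  sig2 <- gene_signature("s", em2$gene_symbols[1:4], c(1, -1, 2, 0.5))
  sc2 <- activation_score(em2, sig2)
  expect_true(is.na(sc2[2]))
  expect_false(anyNA(sc2[-2]))
})

test_that("differential activation matches the closed-form Welch test", {
  g1 <- c(0.9, 0.8, 0.85); g2 <- c(0.1, 0.2, 0.15)
  da <- differential_activation(c(g1, g2), rep(c("AA", "EA"), each = 3))
  se2 <- var(g1) / 3 + var(g2) / 3
  t_exp <- (mean(g1) - mean(g2)) / sqrt(se2)
  df_exp <- se2^2 / ((var(g1) / 3)^2 / 2 + (var(g2) / 3)^2 / 2)
  expect_equal(da$t, t_exp, tolerance = 1e-12)
  expect_equal(da$p, 2 * pt(-abs(t_exp), df_exp), tolerance = 1e-12)
  expect_lt(da$p, 0.01)
  # swapping labels flips t, keeps p
  sw <- differential_activation(c(g1, g2), rep(c("EA", "AA"), each = 3))
  expect_equal(sw$t, -da$t, tolerance = 1e-12)
  expect_equal(sw$p, da$p, tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  id <- differential_activation(rep(c(0.3, 0.5), 2), c("A", "A", "B", "B"))
  expect_equal(id$t, 0)
  expect_equal(id$p, 1)
  expect_error(differential_activation(1:3, c("A", "A", "B")), "at least 2")
})

test_that("stratified permutation p matches the exhaustive single-stratum oracle", {
  scores <- c(0.9, 0.7, 0.8, 0.2, 0.3, 0.1)
  groups <- rep(c("AA", "EA"), each = 3)
  # exhaustive: all 20 reassignments of 3 AA labels among 6 samples
  t_obs <- abs(differential_activation(scores, groups)$t)
  combos <- combn(6, 3)
  t_all <- apply(combos, 2, function(idx) {
    g <- rep("EA", 6); g[idx] <- "AA"
    abs(differential_activation(scores, g)$t)
  })
  p_exact <- mean(t_all >= t_obs - 1e-12)
  R <- 4000
  ap <- stage_adjusted_p(scores, groups, rep(1, 6), n_resamples = R, seed = 1)
  expect_lt(abs(ap$p - p_exact), 2 / sqrt(R))
  # p is never below its resolution floor
  expect_gte(ap$p, 1 / (R + 1))
})

test_that("stratified permutation is deterministic and warns on one-group strata", {
  scores <- rnorm(12)
  groups <- rep(c("A", "B"), 6)
  strata <- c(rep(1, 10), 2, 2)
  g2 <- groups; g2[11:12] <- "A"   # stratum 2 holds only group A
  expect_warning(stage_adjusted_p(scores, g2, strata, 99, seed = 2), "one group")
  a <- suppressWarnings(stage_adjusted_p(scores, g2, strata, 99, seed = 2))
  b <- suppressWarnings(stage_adjusted_p(scores, g2, strata, 99, seed = 2))
  expect_identical(a$p, b$p)
  expect_equal(formals(stage_adjusted_p)$n_resamples, 1000)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  set.seed(14)
  for (len in 2:6) {
    p <- round(runif(len), 3)
    expect_equal(fdr_adjust(p), bh_enum(p), tolerance = 1e-12)
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("k-means LAR calling recovers well-separated planted clusters", {
  set.seed(15)
  n <- 50
  ids <- sprintf("S%02d", 1:n)
  high <- 1:6
  ar <- setNames(rnorm(n, 6, 0.3), ids); ar[high] <- rnorm(6, 10, 0.3)
  lar <- setNames(rnorm(n, 0, 0.05), ids); lar[high] <- rnorm(6, 0.6, 0.05)
  cl <- lar_cluster(ar, lar, seed = 4)
  expect_setequal(cl$lar_high_ids, ids[high])
  expect_identical(unname(cl$sizes["LAR-high"]), 6L)
  # duplicated data: identical partition under the same seed
  cl2 <- lar_cluster(ar, lar, seed = 4)
  expect_identical(cl$assignments, cl2$assignments)
  expect_error(lar_cluster(ar[1:3], lar[1:3]), "at least 4")
})

test_that("Spearman rho handles ties like the textbook tie-corrected formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(as.numeric(spearman_pc_signature(x, x * 2 + 1)), 1)
  expect_equal(as.numeric(spearman_pc_signature(x, rev(x))), -1)
  # one tie in y: rho = Pearson correlation of average ranks
  y <- c(10, 20, 20, 30, 40)
  rx <- rank(x); ry <- rank(y)
  rho_hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(as.numeric(spearman_pc_signature(x, y)), rho_hand,
               tolerance = 1e-12)
  expect_warning(out <- spearman_pc_signature(x, rep(1, 5)), "constant")
  expect_true(is.na(out))
  expect_error(spearman_pc_signature(1:2, 2:1), "at least 3")
})
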