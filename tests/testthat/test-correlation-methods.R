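test_that("pearson matrix recovers exact duplicate and mirrored columns", {
  base <- withr::with_seed(1, rpois(20, 50))
  cts <- cbind(A = base, B = base, C = max(base) + 10 - base,
               D = withr::with_seed(2, rpois(20, 50)))
  rownames(cts) <- paste0("S", 1:20)
  tab <- otu_table(cts)
  res <- pearson_matrix(tab, on = "counts")
  expect_equal(res$coef["A", "B"], 1, tolerance = 1e-12)
  expect_equal(res$coef["A", "C"], -1, tolerance = 1e-12)
  expect_lt(res$p_adj["A", "B"], 1e-10)
  expect_equal(res$coef, t(res$coef), tolerance = 1e-12)
  # adjusted p never below raw p, never above 1
  ut <- upper.tri(res$p_raw)
  expect_true(all(res$p_adj[ut] >= res$p_raw[ut] - 1e-15, na.rm = TRUE))
  expect_true(all(res$p_adj[ut] <= 1, na.rm = TRUE))
})

test_that("zero-variance OTUs are excluded from the adjustment", {
  cts <- cbind(A = rep(5L, 10), B = 1:10, C = 10:1)
  rownames(cts) <- paste0("S", 1:10)
  res <- pearson_matrix(otu_table(cts), on = "counts")
  expect_true(all(is.na(res$coef["A", c("B", "C")])))
  expect_false(is.na(res$p_adj["B", "C"]))
  expect_error(pearson_matrix(otu_table(cts[1:2, ])), "3 samples")
})

test_that("BH step-up reproduces the hand-computed adjustment", {
  p <- matrix(NA_real_, 3, 3)
  p[1, 2] <- p[2, 1] <- 0.01
  p[1, 3] <- p[3, 1] <- 0.02
  p[2, 3] <- p[3, 2] <- 0.04
  adj <- cohortnet:::adjust_sym(p)
  expect_equal(adj[1, 2], 0.03, tolerance = 1e-10)
  expect_equal(adj[1, 3], 0.03, tolerance = 1e-10)
  expect_equal(adj[2, 3], 0.04, tolerance = 1e-10)
  expect_equal(adj, t(adj))
})

test_that("CLR transform centers each sample in log space", {
  uni <- otu_table(matrix(rep(7L, 8), 2, 4,
                          dimnames = list(c("S1", "S2"), NULL)))
  expect_true(all(abs(clr_transform(uni)) < 1e-12))
  two <- otu_table(matrix(c(1L, 3L), 1, 2, dimnames = list("S1", NULL)))
  x <- clr_transform(two, pseudocount = 1)
  expect_equal(unname(x[1, ]), c(-log(4) / 2 + log(2) / 2,
                                 log(4) / 2 - log(2) / 2),
               tolerance = 1e-12)
  expect_equal(unname(x[1, ]), c(-0.3465736, 0.3465736), tolerance = 1e-6)
  rnd <- otu_table(matrix(withr::with_seed(3, rpois(40, 9)), 4, 10,
                          dimnames = list(paste0("S", 1:4), NULL)))
  expect_true(all(abs(rowSums(clr_transform(rnd))) < 1e-10))
  expect_error(clr_transform(rnd, pseudocount = 0), "pseudocount")
})

test_that("basis solve is exact on the symmetric 3-component system", {
  t0 <- 0.42
  Tm <- matrix(t0, 3, 3)
  diag(Tm) <- 0
  sol <- sparcc_basis(Tm)
  expect_equal(unname(sol$omega), rep(t0 / 2, 3), tolerance = 1e-10)
  expect_true(all(abs(sol$rho[upper.tri(sol$rho)]) < 1e-10))
  expect_error(sparcc_basis(matrix(0, 2, 2)), "3 components")
})

test_that("sparcc separates a planted pair from independent OTUs", {
  tx <- make_taxonomy(52, 4, seed = 1)
  tr <- make_truth_network(tx, 1, frac_negative = 0, strength = 1,
                           seed = 2, amplitude_range = c(0, 0))
  tab <- simulate_timeseries(tx, tr, 300, depth = 1500, seed = 3)
  sp <- sparcc(tab, seed = 4)
  rho <- sp$result$coef
  pair <- rho[tr$edges$otu_i[1], tr$edges$otu_j[1]]
  expect_gt(pair, 0.5)
  off <- abs(rho[upper.tri(rho)])
  expect_lt(stats::median(off), 0.15)
  expect_equal(rho, t(rho), tolerance = 1e-12)
  expect_error(sparcc(subset_table(tab, otus = 1:3)), "at least 4")
})

test_that("the exclusion loop catches a duplicated OTU pair", {
  base <- withr::with_seed(5, rpois(60, 40))
  cts <- cbind(A = base, B = base,
               C = withr::with_seed(6, rpois(60, 40)),
               D = withr::with_seed(7, rpois(60, 40)),
               E = withr::with_seed(8, rpois(60, 40)))
  rownames(cts) <- paste0("S", 1:60)
  sp <- sparcc(otu_table(cts), seed = 9)
  expect_gte(sp$state$iterations_used, 1)
  ex <- sp$state$excluded_pairs
  expect_true(any(ex[, 1] == 1 & ex[, 2] == 2))
  expect_gt(sp$result$coef["A", "B"], 0.5)
})

test_that("shuffling within OTUs destroys sparcc associations", {
  tx <- make_taxonomy(20, 2, seed = 10)
  tr <- make_truth_network(tx, 10, strength = 1, seed = 11)
  tab <- simulate_timeseries(tx, tr, 300, seed = 12)
  shuf <- tab
  shuf$counts <- withr::with_seed(13,
    apply(tab$counts, 2, sample))
  rownames(shuf$counts) <- rownames(tab$counts)
  sp <- sparcc(shuf, seed = 14)
  expect_lt(stats::median(abs(sp$result$coef[upper.tri(sp$result$coef)])),
            0.05)
})

test_that("bootstrap pseudo-p attains its floor and two-value extremes", {
  base <- withr::with_seed(15, rpois(60, 80))
  cts <- cbind(A = base, B = base,
               withr::with_seed(16,
                 matrix(rpois(60 * 10, 80), 60, 10,
                        dimnames = list(NULL, paste0("X", 1:10)))))
  rownames(cts) <- paste0("S", 1:60)
  tab <- otu_table(cts)
  pv <- sparcc_pvalues(tab, n_boot = 100, seed = 21, max_iter = 50)
  expect_equal(pv$p_raw["A", "B"], 1 / 101, tolerance = 1e-12)
  ut <- upper.tri(pv$p_raw)
  expect_true(all(pv$p_adj[ut] >= pv$p_raw[ut] - 1e-15))
  pv1 <- sparcc_pvalues(tab, n_boot = 1, seed = 22, max_iter = 10)
  expect_true(all(pv1$p_raw[ut] %in% c(0.5, 1)))
})

test_that("dice-sorensen matches set arithmetic", {
  cts <- matrix(0L, 6, 5,
                dimnames = list(paste0("S", 1:6),
                                c("same1", "same2", "dis1", "dis2", "half")))
  cts[1:4, "same1"] <- 1L
  cts[1:4, "same2"] <- 3L
  cts[1:3, "dis1"] <- 1L
  cts[4:6, "dis2"] <- 1L
  cts[c(1, 5), "half"] <- 1L  # |a|=2 overlapping same1 in S1 only
  res <- dice_sorensen(otu_table(cts))
  expect_equal(res$coef["same1", "same2"], 1)
  expect_equal(res$coef["dis1", "dis2"], 0)
  # |a| = 2, |b| = 4, |intersect| = 1 -> 2/6
  expect_equal(res$coef["half", "same1"], 1 / 3)
  two <- matrix(c(1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L), 4, 2,
                dimnames = list(paste0("S", 1:4), c("a", "b")))
  expect_equal(dice_sorensen(otu_table(two))$coef["a", "b"], 0.5)
  co <- res$coef[upper.tri(res$coef)]
  expect_true(all(co >= 0 & co <= 1, na.rm = TRUE))
  # 1 iff identical presence vectors (non-empty)
  pres <- cts > 0
  for (i in 1:4) for (j in (i + 1):5) {
    if (!is.na(res$coef[i, j]) && res$coef[i, j] == 1) {
      expect_equal(pres[, i], pres[, j], ignore_attr = TRUE)
    }
  }
  # an all-absent OTU is undefined against itself
  cts0 <- cbind(cts, none = 0L)
  expect_true(is.na(dice_sorensen(otu_table(cts0))$coef["none", "none"]))
})

test_that("mb builds the requested lambda path and stable graphs", {
  tx <- make_taxonomy(30, 3, seed = 23)
  tr <- make_truth_network(tx, 5, strength = 1, seed = 24)
  tab <- simulate_timeseries(tx, tr, 120, seed = 25)
  mb <- mb_network(tab, seed = 26)
  expect_length(mb$state$lambda_path, 20)
  expect_true(all(diff(mb$state$lambda_path) < 0))
  expect_lte(mb$state$instability_sup[mb$state$selected_index],
             mb$state$beta)
  expect_equal(mb$result$support, t(mb$result$support))
  expect_false(any(diag(mb$result$support)))
  # deterministic under a fixed seed
  mb2 <- mb_network(tab, seed = 26)
  expect_identical(mb$result$support, mb2$result$support)
})

test_that("mb stays near-empty on independent data", {
  tx <- make_taxonomy(50, 4, seed = 27)
  tr <- make_truth_network(tx, 0, seed = 28, amplitude_range = c(0, 0))
  tab <- simulate_timeseries(tx, tr, 300, seed = 29)
  mb <- mb_network(tab, seed = 30)
  dens <- sum(mb$result$support) / (50 * 49)
  expect_lt(dens, 0.02)
})

test_that("mb respects conditional independence on a Markov chain", {
  # the first three OTUs form a latent Markov chain (tridiagonal
  # precision: A-B and B-C partial correlations nonzero, A-C zero);
  # the rest are independent
  hits <- vapply(1:10, function(s) {
    n <- 500
    D <- 40
    counts <- withr::with_seed(1000 + s, {
      rho <- 0.7
      x1 <- stats::rnorm(n)
      x2 <- rho * x1 + sqrt(1 - rho^2) * stats::rnorm(n)
      x3 <- rho * x2 + sqrt(1 - rho^2) * stats::rnorm(n)
      eta <- matrix(stats::rnorm(n * D), n, D)
      eta[, 1] <- 2 * x1
      eta[, 2] <- 2 * x2
      eta[, 3] <- 2 * x3
      p <- exp(eta)
      p <- p / rowSums(p)
      t(apply(p, 1, function(pr) stats::rmultinom(1, 1500, pr)))
    })
    rownames(counts) <- sprintf("S%03d", seq_len(n))
    tab <- otu_table(counts)
    mb <- mb_network(tab, seed = 2000 + s)
    sup <- mb$result$support
    sup[1, 2] && sup[2, 3] && !sup[1, 3]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
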