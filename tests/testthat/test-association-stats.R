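test_that("collinearity pruning removes the right parameters", {
  set.seed(1)
  n <- 120
  env <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  rep0 <- prune_collinear(env)
  expect_equal(nrow(rep0$removed), 0)
  expect_true(all(rep0$vif < 1.5))
  # duplicated parameter: one copy removed for pairwise correlation
  env_dup <- cbind(env, x1copy = env$x1)
  rep1 <- prune_collinear(env_dup)
  expect_equal(nrow(rep1$removed), 1)
  expect_true(grepl("corr", rep1$removed$reason))
  # near-linear combination: removed for VIF
  env_lc <- cbind(env, lc = env$x1 + env$x2 + rnorm(n, sd = 0.01))
  rep2 <- prune_collinear(env_lc)
  expect_gte(nrow(rep2$removed), 1)
  expect_true(any(grepl("vif", rep2$removed$reason)))
  # the retained set satisfies both cutoffs
  ret <- env_lc[, rep2$retained]
  cm <- abs(stats::cor(ret, use = "pairwise.complete.obs"))
  diag(cm) <- 0
  expect_true(all(cm <= 0.7))
  expect_true(all(rep2$vif <= 10))
})

test_that("pruning drops high-missingness parameters first, by missingness", {
  set.seed(2)
  n <- 100
  base <- rnorm(n)
  env <- data.frame(full = base + rnorm(n, sd = 0.05),
                    holey = base + rnorm(n, sd = 0.05),
                    other = rnorm(n))
  env$holey[1:30] <- NA          # most missing of the correlated pair
  env$mostly_na <- rnorm(n)
  env$mostly_na[1:50] <- NA      # 50% missing: stage-1 removal
  rep <- prune_collinear(env)
  expect_equal(rep$removed$parameter[1], "mostly_na")
  expect_equal(rep$removed$reason[1], "missingness")
  expect_true("holey" %in% rep$removed$parameter)
  expect_true("full" %in% rep$retained)
  expect_lte(nrow(rep$removed), ncol(env))
  expect_error(prune_collinear(env[, 1, drop = FALSE]), "2 parameters")
})

test_that("environmental screening flags planted links and respects r_min", {
  tx <- make_taxonomy(10, 2, seed = 3)
  tr <- make_truth_network(tx, 0, seed = 4)
  tab <- simulate_timeseries(tx, tr, 300, seed = 5)
  env <- simulate_env(300, n_params = 6, linked_otus = tx$otu_id[1],
                      link_r = 0.9, missing_frac = 0.05, seed = 6,
                      table = tab)
  clades <- collapse_rank(tab, "otu")
  res <- env_screen(clades, env)
  hit <- res[res$clade == tx$otu_id[1] &
               res$parameter == paste0("env_", tx$otu_id[1]), ]
  expect_true(hit$flag_passed)
  # sub-threshold |r| never passes, regardless of p
  set.seed(7)
  z <- rnorm(4000)
  y <- 0.28 * z + sqrt(1 - 0.28^2) * rnorm(4000)
  m <- matrix(cbind(z, y), ncol = 2,
              dimnames = list(sprintf("S%04d", 1:4000), c("c1", "c2")))
  envz <- data.frame(p1 = y, row.names = rownames(m))
  res2 <- env_screen(m[, 1, drop = FALSE], envz)
  if (abs(res2$r) < 0.3) {
    expect_lt(res2$p_adj, 0.001)  # highly significant ...
    expect_false(res2$flag_passed)  # ... but below the display threshold
  }
})

test_that("null environmental screens almost never flag at alpha 0.001", {
  tx <- make_taxonomy(10, 2, seed = 8)
  tr <- make_truth_network(tx, 0, seed = 9)
  tab <- simulate_timeseries(tx, tr, 200, seed = 10)
  env <- simulate_env(200, n_params = 20, missing_frac = 0, seed = 11,
                      table = tab)
  res <- env_screen(collapse_rank(tab, "otu"), env)
  expect_equal(nrow(res), 200)
  expect_lte(sum(res$flag_passed), 1)
})

test_that("phase screen detects a strongly shifted group", {
  set.seed(12)
  phases <- rep(c("spring", "winter", "autumn"), each = 30)
  x <- rnorm(90)
  x[phases == "winter"] <- x[phases == "winter"] + 5
  m <- matrix(x, ncol = 1, dimnames = list(sprintf("S%02d", 1:90), "clade1"))
  res <- phase_kw(m, phases)
  expect_lt(res$tests$p_raw, 0.001)
  expect_true(all(c("clade1") %in% res$flagged$clade))
  expect_true("winter" %in% res$flagged$phase)
})

test_that("two-group phase screen matches the rank-sum oracle", {
  set.seed(13)
  phases <- rep(c("spring", "winter"), each = 25)
  x <- c(rnorm(25), rnorm(25, mean = 0.8))
  m <- matrix(x, ncol = 1, dimnames = list(sprintf("S%02d", 1:50), "c"))
  res <- phase_kw(m, phases, alpha = 0.05)
  ref <- stats::wilcox.test(x[phases == "spring"], x[phases == "winter"],
                            exact = FALSE, correct = FALSE)
  expect_equal(res$tests$p_raw, ref$p.value, tolerance = 1e-10)
})

test_that("phase screen type-I rate is near nominal under the null", {
  set.seed(14)
  phases <- rep(c("a", "b", "c"), each = 15)
  rejections <- vapply(1:800, function(i) {
    m <- matrix(rnorm(45), ncol = 1,
                dimnames = list(sprintf("S%02d", 1:45), "c"))
    phase_kw(m, phases, alpha = 0.05)$tests$p_raw < 0.05
  }, logical(1))
  rate <- mean(rejections)
  se <- sqrt(0.05 * 0.95 / 800)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("phase screen rejects degenerate groupings", {
  m <- matrix(rnorm(10), ncol = 1,
              dimnames = list(sprintf("S%02d", 1:10), "c"))
  expect_error(phase_kw(m, rep("only", 10)), "at least 2 phase groups")
  expect_warning(phase_kw(m, c(rep("a", 5), rep("b", 4), "tiny")),
                 "tiny")
})

test_that("PD-versus-correlation finds planted distance decay", {
  tx <- make_taxonomy(30, 3, seed = 15)
  target <- tx$otu_id[1]
  others <- tx$otu_id[2:21]
  pdv <- tx$pd[target, others]
  set.seed(16)
  w <- 0.9 - 0.35 * pdv + rnorm(20, sd = 0.05)
  net <- toy_network(data.frame(otu_i = target, otu_j = others,
                                weight = w,
                                sign = ifelse(w >= 0, "+", "-")))
  co <- first_neighbors(net, target)
  res <- pd_vs_correlation(co, net, tx$pd)
  expect_lt(res$r, -0.5)
  expect_lt(res$p, 0.05)
  expect_equal(nrow(res$scatter), 20)
  # a single connected pair is undefined
  net1 <- toy_network(data.frame(otu_i = target, otu_j = others[1],
                                 weight = 0.5))
  res1 <- pd_vs_correlation(first_neighbors(net1, target), net1, tx$pd)
  expect_true(is.na(res1$r))
  expect_match(res1$note, "fewer than 3")
})

test_that("PD-versus-correlation stays null when strengths ignore distance", {
  tx <- make_taxonomy(30, 3, seed = 17)
  target <- tx$otu_id[1]
  others <- tx$otu_id[2:21]
  sig <- vapply(1:20, function(s) {
    w <- withr::with_seed(800 + s, stats::runif(20, 0.3, 0.9))
    net <- toy_network(data.frame(otu_i = target, otu_j = others,
                                  weight = w))
    res <- pd_vs_correlation(first_neighbors(net, target), net, tx$pd)
    res$p <= 0.05
  }, logical(1))
  expect_lte(mean(sig), 0.1)
})

test_that("cross-dataset correlations are exact on self-comparison", {
  tx <- make_taxonomy(25, 3, seed = 18)
  tr <- make_truth_network(tx, 5, seed = 19)
  tab <- simulate_timeseries(tx, tr, 60, seed = 20)
  res <- cross_dataset_corr(tab, tab)
  same <- res[res$comparison %in% c("log_avra_vs_log_avra",
                                    "prevalence_vs_prevalence"), ]
  expect_true(all(abs(same$r - 1) < 1e-12 | is.na(same$r)))
  expect_error(cross_dataset_corr(tab, subset_table(tab, otus = 1:2)),
               "3 shared")
})

test_that("culture prevalence tracks lake composition via occupancy", {
  tx <- make_taxonomy(40, 4, seed = 21)
  tr <- make_truth_network(tx, 0, seed = 22)
  tab <- simulate_timeseries(tx, tr, 100, seed = 23)
  comp <- av_ra(tab)
  mc <- simulate_cultures(tx, tr, comp / sum(comp), n_cultures = 200,
                          seed = 24)
  res <- cross_dataset_corr(tab, mc)
  prev <- res[res$comparison == "prevalence_vs_prevalence", ]
  expect_gt(prev$r, 0.5)
})
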