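test_that("assortativity hits its closed-form extremes", {
  # all edges within labels, two labels present
  labs <- c(A = "P1", B = "P1", C = "P2", D = "P2")
  within <- toy_network(data.frame(otu_i = c("A", "C"), otu_j = c("B", "D")),
                        labels = labs)
  expect_equal(nominal_assortativity(within, "phylum"), 1, tolerance = 1e-12)
  # complete bipartite between two equal groups
  bip <- toy_network(expand.grid(otu_i = c("A", "B"), otu_j = c("C", "D"),
                                 stringsAsFactors = FALSE),
                     labels = labs)
  expect_equal(nominal_assortativity(bip, "phylum"), -1, tolerance = 1e-12)
  # single label: degenerate denominator
  mono <- toy_network(data.frame(otu_i = "A", otu_j = "B"),
                      labels = c(A = "P1", B = "P1"))
  expect_true(is.na(nominal_assortativity(mono, "phylum")))
})

test_that("assortativity matches igraph and is label-rename invariant", {
  set.seed(42)
  edges <- t(utils::combn(12, 2))
  edges <- edges[sample(nrow(edges), 25), ]
  ids <- sprintf("N%02d", 1:12)
  labs <- stats::setNames(sample(c("x", "y", "z"), 12, replace = TRUE), ids)
  net <- toy_network(data.frame(otu_i = ids[edges[, 1]],
                                otu_j = ids[edges[, 2]]), labels = labs)
  ours <- nominal_assortativity(net, "phylum")
  g <- as_igraph(net)
  ref <- igraph::assortativity_nominal(
    g, as.integer(factor(igraph::V(g)$phylum)))
  expect_equal(ours, ref, tolerance = 1e-12)
  renamed <- net
  renamed$nodes$phylum <- paste0("clade_", net$nodes$phylum)
  expect_equal(nominal_assortativity(renamed, "phylum"), ours,
               tolerance = 1e-12)
})

test_that("random-relabeling null matches its exact enumeration oracle", {
  # Newman's coefficient has a small negative bias under random
  # labeling of a fixed graph; the exact null mean comes from
  # enumerating all 2^10 binary labelings
  set.seed(7)
  edges <- t(utils::combn(10, 2))
  edges <- edges[sample(nrow(edges), 20), ]
  ids <- sprintf("N%02d", 1:10)
  net <- toy_network(data.frame(otu_i = ids[edges[, 1]],
                                otu_j = ids[edges[, 2]]))
  r_of <- function(labs) {
    net$nodes$phylum <- labs
    nominal_assortativity(net, "phylum")
  }
  exact <- vapply(0:(2^10 - 1), function(code) {
    r_of(ifelse(bitwAnd(code, 2^(0:9)) > 0, "a", "b"))
  }, numeric(1))
  exact_mean <- mean(exact, na.rm = TRUE)
  expect_lt(exact_mean, 0)  # the finite-size bias is negative
  mc <- replicate(1000, r_of(sample(c("a", "b"), 10, replace = TRUE)))
  mc <- mc[!is.na(mc)]
  se <- stats::sd(mc) / sqrt(length(mc))
  expect_lt(abs(mean(mc) - exact_mean), 3 * se)
})

test_that("planted assortative networks exceed their permuted controls", {
  wins <- vapply(1:10, function(s) {
    tx <- make_taxonomy(40, 4, seed = 500 + s)
    tr <- make_truth_network(tx, 60, assortative_bias = 3, seed = 600 + s)
    labs <- stats::setNames(tx$ranks$phylum, tx$otu_id)
    net <- toy_network(tr$edges[, c("otu_i", "otu_j")], labels = labs)
    r_true <- nominal_assortativity(net, "phylum")
    perm <- net
    perm$nodes$phylum <- withr::with_seed(700 + s,
                                          sample(perm$nodes$phylum))
    r_true > nominal_assortativity(perm, "phylum")
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("modularity matches hand-computed partitions", {
  tri2 <- toy_network(data.frame(
    otu_i = c("a1", "a2", "a3", "b1", "b2", "b3"),
    otu_j = c("a2", "a3", "a1", "b2", "b3", "b1")))
  part <- stats::setNames(rep(1:2, each = 3),
                          c("a1", "a2", "a3", "b1", "b2", "b3"))
  expect_equal(modularity_q(tri2, part), 0.5, tolerance = 1e-12)
  ms <- modularity_stats(tri2)
  expect_equal(ms$Q, 0.5, tolerance = 1e-12)
  # two triangles joined by one bridge, clique partition
  bridged <- toy_network(rbind(tri2$edges[, c("otu_i", "otu_j")],
                               data.frame(otu_i = "a1", otu_j = "b1")))
  expect_equal(modularity_q(bridged, part), 6 / 7 - 1 / 2,
               tolerance = 1e-12)
  # complete graph, single community
  k4 <- toy_network(as.data.frame(t(utils::combn(paste0("n", 1:4), 2)),
                                  col.names = c("otu_i", "otu_j")) |>
                      stats::setNames(c("otu_i", "otu_j")))
  expect_equal(modularity_q(k4, stats::setNames(rep(1, 4),
                                                paste0("n", 1:4))),
               0, tolerance = 1e-12)
})

test_that("greedy partition attains the exhaustive-search optimum (n <= 8)", {
  tri2 <- toy_network(data.frame(
    otu_i = c("a1", "a2", "a3", "b1", "b2", "b3"),
    otu_j = c("a2", "a3", "a1", "b2", "b3", "b1")))
  bridged <- toy_network(rbind(tri2$edges[, c("otu_i", "otu_j")],
                               data.frame(otu_i = "a1", otu_j = "b1")))
  for (net in list(tri2, bridged)) {
    best <- exhaustive_modularity(net)
    got <- modularity_stats(net)$Q
    expect_equal(got, best, tolerance = 1e-10)
    expect_true(got >= -0.5 && got <= 1)
  }
})

test_that("first neighbors follow the strongest-edge annotation rule", {
  star <- toy_network(data.frame(otu_i = "hub",
                                 otu_j = paste0("leaf", 1:4),
                                 weight = c(0.4, -0.5, 0.6, 0.3)))
  co <- first_neighbors(star, "hub")
  expect_setequal(co$neighbors$otu, paste0("leaf", 1:4))
  # two targets share a neighbor via +0.4 and -0.5: keep the -0.5 edge
  net <- toy_network(data.frame(otu_i = c("t1", "t2"),
                                otu_j = c("n", "n"),
                                weight = c(0.4, -0.5),
                                sign = c("+", "-")))
  co2 <- first_neighbors(net, c("t1", "t2"))
  expect_equal(co2$neighbors$otu, "n")
  expect_equal(co2$neighbors$sign, "-")
  expect_equal(co2$neighbors$weight, -0.5)
  # isolated target (node exists, no incident edges)
  iso <- toy_network(data.frame(otu_i = "a", otu_j = "b"),
                     labels = c(a = "P", b = "P", c = "P"))
  expect_equal(nrow(first_neighbors(iso, "c")$neighbors), 0)
  expect_error(first_neighbors(star, "ghost"), "ghost")
})

test_that("first neighbors equal a brute-force edge-list scan", {
  set.seed(11)
  for (rep in 1:5) {
    ids <- sprintf("N%02d", 1:15)
    pairs <- t(utils::combn(15, 2))
    pairs <- pairs[sample(nrow(pairs), 30), ]
    net <- toy_network(data.frame(otu_i = ids[pairs[, 1]],
                                  otu_j = ids[pairs[, 2]],
                                  weight = round(stats::runif(30, -1, 1), 2)))
    target <- sample(ids, 3)
    got <- sort(first_neighbors(net, target)$neighbors$otu)
    want <- sort(setdiff(
      unique(c(net$edges$otu_j[net$edges$otu_i %in% target],
               net$edges$otu_i[net$edges$otu_j %in% target])), target))
    expect_equal(got, want)
  }
})

test_that("cohort overlap reports directional fractions and sign agreement", {
  mk <- function(neigh, signs) {
    structure(list(target = "t",
                   neighbors = data.frame(otu = neigh, sign = signs,
                                          weight = 0.4),
                   subnetwork = NULL, dataset = "TS"),
              class = "cohort")
  }
  a <- mk(paste0("n", 1:4), rep("+", 4))
  b <- mk(paste0("n", c(1, 2, 5:10)), c("+", "-", rep("+", 6)))
  ov <- cohort_overlap(list(A = a, B = b))
  expect_equal(ov$fractions["A", "B"], 0.5)
  expect_equal(ov$fractions["B", "A"], 0.25)
  expect_setequal(ov$sign_agreement$otu, c("n1", "n2"))
  expect_equal(ov$sign_agreement$same_sign[ov$sign_agreement$otu == "n1"],
               TRUE)
  expect_equal(ov$sign_agreement$same_sign[ov$sign_agreement$otu == "n2"],
               FALSE)
  ident <- cohort_overlap(list(A = a, B = a))
  expect_true(all(ident$fractions[!is.na(ident$fractions)] == 1))
  expect_setequal(ident$common_to_all, paste0("n", 1:4))
  disj <- cohort_overlap(list(A = a, B = mk("z1", "+")))
  expect_true(all(disj$fractions[!is.na(disj$fractions)] == 0))
  expect_length(disj$common_to_all, 0)
})
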