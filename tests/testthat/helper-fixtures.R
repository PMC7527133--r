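# Small deterministic fixtures built in code.

# a 4-sample x 4-OTU table with hand-picked counts
tiny_table <- function() {
  cts <- matrix(c(
    10, 0, 5, 0,
    8, 2, 5, 0,
    0, 6, 5, 1,
    0, 8, 5, 0
  ), nrow = 4, byrow = TRUE,
  dimnames = list(paste0("S", 1:4), paste0("OTU_", 1:4)))
  tax <- data.frame(
    domain = "Bacteria",
    phylum = c("P1", "P1", "P2", "P2"),
    class = c("C1", "C1", "C2", "C2"),
    order = c("O1", "O1", "O2", "O2"),
    family = c("F1", "F1", "F2", "F2"),
    genus = c("G1", "G1", "G2", "G3"),
    species = paste0("sp", 1:4),
    row.names = paste0("OTU_", 1:4)
  )
  meta <- data.frame(sample_id = paste0("S", 1:4),
                     date = as.Date("2012-01-01") + (0:3) * 90,
                     phase = c("winter", "spring", "epilimnion", "autumn"),
                     dataset = "TS",
                     row.names = paste0("S", 1:4))
  otu_table(cts, taxonomy = tax, sample_data = meta)
}

# build a consensus_network directly from an edge description
toy_network <- function(edges, labels = NULL, min_methods = 2) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(edges$weight)) edges$weight <- 0.5
  if (is.null(edges$sign)) edges$sign <- ifelse(edges$weight >= 0, "+", "-")
  if (is.null(edges$n_methods)) edges$n_methods <- 2L
  if (is.null(edges$methods)) edges$methods <- "pearson+sparcc"
  if (is.null(edges$sign_conflict)) edges$sign_conflict <- FALSE
  nodes <- data.frame(otu = sort(unique(c(edges$otu_i, edges$otu_j))),
                      stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    extra <- setdiff(names(labels), nodes$otu)
    if (length(extra) > 0) {
      nodes <- rbind(nodes, data.frame(otu = extra))
    }
    nodes$phylum <- unname(labels[nodes$otu])
  }
  rownames(nodes) <- nodes$otu
  structure(list(nodes = nodes, edges = edges, min_methods = min_methods),
            class = "consensus_network")
}

# a bare edge_set for consensus voting tests
toy_edge_set <- function(method, otu_i, otu_j, coef = NULL, sign = NULL,
                         universe = NULL) {
  n <- length(otu_i)
  if (is.null(coef)) coef <- rep(if (method == "mb") NA_real_ else 0.5, n)
  if (is.null(sign)) sign <- ifelse(is.na(coef) | coef >= 0, "+", "-")
  es <- data.frame(otu_i = otu_i, otu_j = otu_j, sign = sign, coef = coef,
                   method = rep(method, n), stringsAsFactors = FALSE)
  attr(es, "otus") <- if (is.null(universe)) unique(c(otu_i, otu_j)) else
    universe
  class(es) <- c("edge_set", "data.frame")
  es
}

# exhaustive maximum-modularity search over all set partitions (n <= 8)
exhaustive_modularity <- function(network) {
  nodes <- network$nodes$otu
  n <- length(nodes)
  stopifnot(n <= 8)
  best <- -Inf
  assign_next <- function(membership, i, n_groups) {
    if (i > n) {
      q <- modularity_q(network, stats::setNames(membership, nodes))
      best <<- max(best, q)
      return(invisible())
    }
    for (g in seq_len(n_groups + 1)) {
      assign_next(c(membership, g), i + 1, max(n_groups, g))
    }
  }
  assign_next(integer(), 1, 0)
  best
}
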