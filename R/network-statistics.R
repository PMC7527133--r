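#' Nominal (categorical) assortativity at a taxonomic rank
#'
#' Newman's nominal assortativity
#' r = (sum_i e_ii - sum_i a_i b_i) / (1 - sum_i a_i b_i) computed from
#' the edge-endpoint label mixing matrix, treating the network as
#' undirected and ignoring edge signs and weights. r = 1 when every
#' edge connects same-label nodes (with >= 2 labels present), negative
#' values mark disassortative mixing (-1 for complete bipartite mixing
#' between two equal groups).
#'
#' @param network A `consensus_network` with >= 1 edge whose nodes carry
#'   the requested rank.
#' @param rank One of [tax_ranks()], or the name of any categorical
#'   node column.
#' @return The assortativity coefficient, or `NA` when only one label is
#'   present (degenerate denominator).
#' @export
nominal_assortativity <- function(network, rank) {
  if (nrow(network$edges) < 1) stop("network has no edges")
  if (!rank %in% names(network$nodes)) {
    stop("nodes carry no '", rank, "' label")
  }
  labels <- stats::setNames(as.character(network$nodes[[rank]]),
                            network$nodes$otu)
  l1 <- labels[network$edges$otu_i]
  l2 <- labels[network$edges$otu_j]
  cats <- sort(unique(c(l1, l2)))
  if (length(cats) < 2) return(NA_real_)
  E <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  for (e in seq_along(l1)) {
    E[l1[e], l2[e]] <- E[l1[e], l2[e]] + 1
    E[l2[e], l1[e]] <- E[l2[e], l1[e]] + 1
  }
  E <- E / sum(E)
  ab <- sum(rowSums(E) * colSums(E))
  (sum(diag(E)) - ab) / (1 - ab)
}

#' Modularity of a given partition
#'
#' Q = sum_c (e_cc - a_c^2) on the unsigned, unweighted graph, where
#' e_cc is the fraction of edges inside community c and a_c the fraction
#' of edge endpoints in c.
#'
#' @param network A `consensus_network` with >= 1 edge.
#' @param membership Named vector (by OTU id) of community labels
#'   covering every node incident to an edge.
#' @return The modularity Q.
#' @export
modularity_q <- function(network, membership) {
  ed <- network$edges
  if (nrow(ed) < 1) stop("network has no edges")
  m1 <- membership[ed$otu_i]
  m2 <- membership[ed$otu_j]
  if (anyNA(m1) || anyNA(m2)) stop("membership missing for some nodes")
  m <- nrow(ed)
  comms <- unique(c(m1, m2))
  q <- 0
  for (cc in comms) {
    e_cc <- sum(m1 == cc & m2 == cc) / m
    a_c <- (sum(m1 == cc) + sum(m2 == cc)) / (2 * m)
    q <- q + e_cc - a_c^2
  }
  q
}

#' Greedy modularity-maximizing partition and its Q
#'
#' Runs greedy agglomerative community detection on the unsigned,
#' unweighted consensus graph and reports the partition with its
#' modularity.
#'
#' @param network A `consensus_network` with >= 1 edge.
#' @return List of class `modularity_stats`: `membership` (named by OTU)
#'   and `Q`.
#' @export
modularity_stats <- function(network) {
  g <- igraph::simplify(as_igraph(network))
  # statistics are topological: drop signed weights before clustering
  if ("weight" %in% igraph::edge_attr_names(g)) {
    g <- igraph::delete_edge_attr(g, "weight")
  }
  cl <- igraph::cluster_fast_greedy(g)
  membership <- stats::setNames(as.integer(igraph::membership(cl)),
                                igraph::V(g)$name)
  structure(list(membership = membership,
                 Q = modularity_q(network, membership)),
            class = "modularity_stats")
}

#' Extract the first-neighbor (primary) cohort of a target taxon set
#'
#' The 1-degree cohort of a target OTU set is every non-target node
#' sharing a consensus edge with any target member, annotated with the
#' sign and weight of its strongest-|weight| connecting edge. The
#' induced subnetwork over target plus cohort is returned alongside.
#'
#' @param network A `consensus_network`.
#' @param target Character vector of OTU ids (all must be nodes).
#' @return A list of class `cohort`: `target`, `neighbors` (data frame
#'   `otu`, `sign`, `weight`), `subnetwork` (a `consensus_network`
#'   induced on target and neighbors), `dataset`.
#' @export
first_neighbors <- function(network, target) {
  missing_ids <- setdiff(target, network$nodes$otu)
  if (length(missing_ids) > 0) {
    stop("target OTUs not in network: ",
         paste(missing_ids, collapse = ", "))
  }
  ed <- network$edges
  touch_i <- ed$otu_i %in% target
  touch_j <- ed$otu_j %in% target
  inc <- ed[xor(touch_i, touch_j) | (touch_i & touch_j), , drop = FALSE]
  # edges with exactly one endpoint outside the target define neighbors
  out_node <- ifelse(inc$otu_i %in% target,
                     ifelse(inc$otu_j %in% target, NA, inc$otu_j),
                     inc$otu_i)
  ext <- inc[!is.na(out_node), , drop = FALSE]
  out_node <- out_node[!is.na(out_node)]
  if (length(out_node) > 0) {
    ord <- order(out_node, -abs(ifelse(is.na(ext$weight), 0, ext$weight)))
    ext <- ext[ord, , drop = FALSE]
    out_node <- out_node[ord]
    first <- !duplicated(out_node)
    neighbors <- data.frame(otu = out_node[first],
                            sign = ext$sign[first],
                            weight = ext$weight[first],
                            stringsAsFactors = FALSE)
  } else {
    neighbors <- data.frame(otu = character(), sign = character(),
                            weight = numeric(), stringsAsFactors = FALSE)
  }
  members <- c(target, neighbors$otu)
  sub_edges <- network$edges[network$edges$otu_i %in% members &
                               network$edges$otu_j %in% members, ,
                             drop = FALSE]
  sub <- structure(list(
    nodes = network$nodes[network$nodes$otu %in% members, , drop = FALSE],
    edges = sub_edges,
    min_methods = network$min_methods
  ), class = "consensus_network")
  dataset <- if ("dataset" %in% names(network$nodes)) {
    network$nodes$dataset[1]
  } else NA_character_
  structure(list(target = target, neighbors = neighbors,
                 subnetwork = sub, dataset = dataset),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d target OTUs, %d first neighbors (%d negative)\n",
              length(x$target), nrow(x$neighbors),
              sum(x$neighbors$sign == "-")))
  invisible(x)
}

#' Overlap and sign agreement between primary cohorts
#'
#' For every ordered cohort pair, the directional shared-neighbor
#' fraction |A intersect B| / |A|; for each shared neighbor, whether the
#' two cohorts agree in edge sign; and the set of neighbors common to
#' all cohorts.
#'
#' @param cohorts Named list of >= 2 `cohort` objects over one network.
#' @return List of class `cohort_overlap`: `fractions` (matrix,
#'   `[a, b]` = share of a's cohort also in b's; `NA` for empty a),
#'   `sign_agreement` (data frame per shared neighbor of each pair),
#'   `common_to_all`.
#' @export
cohort_overlap <- function(cohorts) {
  if (length(cohorts) < 2) stop("need at least 2 cohorts")
  if (is.null(names(cohorts))) {
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  }
  sets <- lapply(cohorts, function(co) co$neighbors$otu)
  k <- length(sets)
  fractions <- matrix(NA_real_, k, k,
                      dimnames = list(names(cohorts), names(cohorts)))
  agree <- NULL
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a == b) next
      if (length(sets[[a]]) > 0) {
        fractions[a, b] <- length(intersect(sets[[a]], sets[[b]])) /
          length(sets[[a]])
      }
      if (a < b) {
        shared <- intersect(sets[[a]], sets[[b]])
        if (length(shared) > 0) {
          sa <- stats::setNames(cohorts[[a]]$neighbors$sign,
                                cohorts[[a]]$neighbors$otu)
          sb <- stats::setNames(cohorts[[b]]$neighbors$sign,
                                cohorts[[b]]$neighbors$otu)
          agree <- rbind(agree, data.frame(
            cohort_a = names(cohorts)[a], cohort_b = names(cohorts)[b],
            otu = shared, sign_a = sa[shared], sign_b = sb[shared],
            same_sign = sa[shared] == sb[shared],
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(agree)) {
    agree <- data.frame(cohort_a = character(), cohort_b = character(),
                        otu = character(), sign_a = character(),
                        sign_b = character(), same_sign = logical(),
                        stringsAsFactors = FALSE)
  }
  rownames(agree) <- NULL
  structure(list(fractions = fractions, sign_agreement = agree,
                 common_to_all = Reduce(intersect, sets)),
            class = "cohort_overlap")
}
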