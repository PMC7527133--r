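edge_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "\r")
}

#' Threshold a method's result into an edge set
#'
#' Coefficient-bearing methods (pearson, sparcc, dice) retain pairs with
#' |coef| above `min_abs_coef` (strictly, by default, per the retention
#' rule "greater than 0.3 absolute"); the neighborhood-selection method
#' retains its entire support adjacency regardless of any coefficient
#' ("detected at all"). Dice edges are always positive.
#'
#' @param result A `correlation_result`.
#' @param min_abs_coef Absolute-coefficient threshold in \[0, 1\]
#'   (default 0.3).
#' @param strict Use strict `>` (default) or inclusive `>=`.
#' @param max_p_adj Optional additional cutoff on adjusted p-values
#'   (applied only to methods that carry them).
#' @return A data frame of class `edge_set` with columns `otu_i`,
#'   `otu_j` (ordered), `sign`, `coef` (`NA` for mb), `method`;
#'   attribute `otus` records the OTU universe.
#' @export
threshold_edges <- function(result, min_abs_coef = 0.3, strict = TRUE,
                            max_p_adj = NULL) {
  stopifnot(min_abs_coef >= 0, min_abs_coef <= 1)
  if (result$method == "mb") {
    sup <- result$support
    ut <- which(upper.tri(sup) & sup, arr.ind = TRUE)
    es <- data.frame(
      otu_i = rownames(sup)[ut[, 1]],
      otu_j = colnames(sup)[ut[, 2]],
      sign = result$sign[ut],
      coef = rep(NA_real_, nrow(ut)),
      method = rep("mb", nrow(ut)),
      stringsAsFactors = FALSE
    )
    universe <- colnames(sup)
  } else {
    cf <- result$coef
    keep <- if (strict) abs(cf) > min_abs_coef else abs(cf) >= min_abs_coef
    keep[is.na(keep)] <- FALSE
    if (!is.null(max_p_adj) && !is.null(result$p_adj)) {
      keep <- keep & !is.na(result$p_adj) & result$p_adj <= max_p_adj
    }
    ut <- which(upper.tri(cf) & keep, arr.ind = TRUE)
    es <- data.frame(
      otu_i = rownames(cf)[ut[, 1]],
      otu_j = colnames(cf)[ut[, 2]],
      sign = if (result$method == "dice") rep("+", nrow(ut)) else
        ifelse(cf[ut] >= 0, "+", "-"),
      coef = cf[ut],
      method = rep(result$method, nrow(ut)),
      stringsAsFactors = FALSE
    )
    universe <- colnames(cf)
  }
  attr(es, "otus") <- universe
  class(es) <- c("edge_set", "data.frame")
  es
}

#' Vote edges across methods into a consensus network
#'
#' An OTU pair becomes a consensus edge iff it appears in at least
#' `min_methods` of the supplied edge sets. The edge weight is the mean
#' of the coefficients from coefficient-bearing supporters (the
#' neighborhood-selection method contributes a vote and a sign, never a
#' coefficient); the sign is the sign of the weight when coefficients
#' exist, else the mb sign. Supporters disagreeing in sign set
#' `sign_conflict`.
#'
#' @param edge_sets List of >= 2 `edge_set` objects from
#'   [threshold_edges()].
#' @param min_methods Minimum number of supporting methods (>= 2).
#' @param table Optional `otu_table` supplying node attributes
#'   (taxonomy, av.ra, prevalence, dataset tag); when given, the node
#'   universe is the table's OTU set.
#' @return A list of class `consensus_network`: `nodes` (data frame with
#'   `otu`, taxonomy ranks, `av_ra`, `prevalence`, `dataset`) and
#'   `edges` (`otu_i`, `otu_j`, `weight`, `sign`, `n_methods`,
#'   `methods`, `sign_conflict`).
#' @export
build_consensus <- function(edge_sets, min_methods = 2, table = NULL) {
  if (length(edge_sets) < 2) stop("consensus needs at least 2 edge sets")
  stopifnot(min_methods >= 2)
  universes <- lapply(edge_sets, attr, "otus")
  shared <- Reduce(intersect, universes)
  if (length(shared) == 0) {
    stop("edge sets cover disjoint OTU universes")
  }
  all_edges <- do.call(rbind, lapply(edge_sets, as.data.frame))
  if (nrow(all_edges) > 0) {
    all_edges$key <- edge_key(all_edges$otu_i, all_edges$otu_j)
    split_e <- split(all_edges, all_edges$key)
    split_e <- split_e[vapply(split_e, function(d)
      length(unique(d$method)), integer(1)) >= min_methods]
    edges <- do.call(rbind, lapply(split_e, function(d) {
      coefs <- d$coef[!is.na(d$coef)]
      w <- if (length(coefs) > 0) mean(coefs) else NA_real_
      sg <- if (!is.na(w)) {
        if (w >= 0) "+" else "-"
      } else {
        d$sign[d$method == "mb"][1]
      }
      data.frame(
        otu_i = d$otu_i[1], otu_j = d$otu_j[1],
        weight = w, sign = sg,
        n_methods = length(unique(d$method)),
        methods = paste(sort(unique(d$method)), collapse = "+"),
        sign_conflict = length(unique(d$sign)) > 1,
        stringsAsFactors = FALSE
      )
    }))
  } else {
    edges <- NULL
  }
  if (is.null(edges)) {
    edges <- data.frame(otu_i = character(), otu_j = character(),
                        weight = numeric(), sign = character(),
                        n_methods = integer(), methods = character(),
                        sign_conflict = logical(),
                        stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$otu_i, edges$otu_j), , drop = FALSE]
  rownames(edges) <- NULL
  if (!is.null(table)) {
    nodes <- data.frame(otu = otu_ids(table), stringsAsFactors = FALSE)
    if (!is.null(table$taxonomy)) {
      nodes <- cbind(nodes, table$taxonomy[nodes$otu, , drop = FALSE])
    }
    nodes$av_ra <- av_ra(table)[nodes$otu]
    nodes$prevalence <- prevalence(table)[nodes$otu]
    if (!is.null(table$sample_data) && "dataset" %in% names(table$sample_data)) {
      nodes$dataset <- table$sample_data$dataset[1]
    }
  } else {
    nodes <- data.frame(otu = sort(unique(c(edges$otu_i, edges$otu_j))),
                        stringsAsFactors = FALSE)
  }
  rownames(nodes) <- nodes$otu
  bad <- setdiff(unique(c(edges$otu_i, edges$otu_j)), nodes$otu)
  if (length(bad) > 0) {
    stop("consensus edges touch OTUs outside the node universe: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(list(nodes = nodes, edges = edges, min_methods = min_methods),
            class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf("consensus_network: %d nodes, %d edges (>= %d methods; %d negative)\n",
              nrow(x$nodes), nrow(x$edges), x$min_methods,
              sum(x$edges$sign == "-")))
  invisible(x)
}

#' Convert a consensus network to an igraph graph
#'
#' @param network A `consensus_network`.
#' @return An undirected `igraph` graph carrying the node and edge
#'   attributes.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    d = network$edges, directed = FALSE,
    vertices = network$nodes
  )
}

#' Score a consensus network against the planted truth
#'
#' Counts unordered OTU pairs: precision = TP / predicted,
#' recall = TP / planted, F1 their harmonic mean, and sign accuracy over
#' the true positives. With both truth and prediction empty, precision
#' and recall are 1 by convention.
#'
#' @param network A `consensus_network`.
#' @param truth A `truth_network`.
#' @return List of class `recovery_metrics`: `precision`, `recall`,
#'   `f1`, `sign_accuracy`, plus the `tp`, `fp`, `fn` counts.
#' @export
evaluate_recovery <- function(network, truth) {
  pred <- network$edges
  pred_keys <- edge_key(pred$otu_i, pred$otu_j)
  true_keys <- edge_key(truth$edges$otu_i, truth$edges$otu_j)
  tp_keys <- intersect(pred_keys, true_keys)
  tp <- length(tp_keys)
  fp <- length(setdiff(pred_keys, true_keys))
  fn <- length(setdiff(true_keys, pred_keys))
  precision <- if (tp + fp > 0) tp / (tp + fp) else
    if (length(true_keys) == 0) 1 else NA_real_
  recall <- if (length(true_keys) > 0) tp / length(true_keys) else 1
  f1 <- if (!is.na(precision) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  sign_acc <- NA_real_
  if (tp > 0) {
    ps <- stats::setNames(pred$sign, pred_keys)
    ts <- stats::setNames(truth$edges$sign, true_keys)
    sign_acc <- mean(ps[tp_keys] == ts[tp_keys])
  }
  structure(list(precision = precision, recall = recall, f1 = f1,
                 sign_accuracy = sign_acc, tp = tp, fp = fp, fn = fn),
            class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf("recovery: precision %.3f | recall %.3f | F1 %.3f | sign acc %s\n",
              x$precision, x$recall, x$f1,
              ifelse(is.na(x$sign_accuracy), "NA",
                     sprintf("%.3f", x$sign_accuracy))))
  invisible(x)
}
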