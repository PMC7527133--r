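#' Write an OTU table as TSV
#'
#' Dialect: rows = OTUs, columns = samples, followed by the 7 taxonomy
#' rank columns when taxonomy is present. Sample metadata goes to a
#' sidecar file `<path>.samples.tsv` when present.
#'
#' @param x An `otu_table`.
#' @param path Output file.
#' @export
write_otu_table_tsv <- function(x, path) {
  out <- as.data.frame(t(x$counts))
  if (!is.null(x$taxonomy)) {
    out <- cbind(out, x$taxonomy[rownames(out), , drop = FALSE])
  }
  out <- cbind(otu_id = rownames(out), out)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(x$sample_data)) {
    utils::write.table(x$sample_data, paste0(path, ".samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read an OTU table written by [write_otu_table_tsv()]
#'
#' @param path TSV file (rows = OTUs, columns = samples, trailing
#'   taxonomy columns recognized by the rank names).
#' @return An `otu_table`.
#' @export
read_otu_table_tsv <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  rownames(raw) <- raw$otu_id
  raw$otu_id <- NULL
  tax_cols <- intersect(tax_ranks(), names(raw))
  taxonomy <- if (length(tax_cols) > 0) raw[, tax_cols, drop = FALSE]
  counts <- t(as.matrix(raw[, setdiff(names(raw), tax_cols),
                            drop = FALSE]))
  sample_meta <- NULL
  sidecar <- paste0(path, ".samples.tsv")
  if (file.exists(sidecar)) {
    sample_meta <- utils::read.table(sidecar, sep = "\t", header = TRUE,
                                     stringsAsFactors = FALSE)
    rownames(sample_meta) <- sample_meta$sample_id
    if ("date" %in% names(sample_meta)) {
      sample_meta$date <- as.Date(sample_meta$date)
    }
  }
  otu_table(counts, taxonomy = taxonomy, sample_data = sample_meta)
}

#' Write a planted truth network as a 4-column edge list TSV
#'
#' @param truth A `truth_network`.
#' @param path Output file (columns otu_i, otu_j, sign, strength).
#' @export
write_truth_network_tsv <- function(truth, path) {
  utils::write.table(truth$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an environmental table as TSV (empty cells for missing)
#'
#' @param env An `env_table`.
#' @param path Output file.
#' @export
write_env_table_tsv <- function(env, path) {
  out <- cbind(sample_id = rownames(env), as.data.frame(env))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write consensus edges as long-format TSV
#'
#' @param network A `consensus_network`.
#' @param path Output file.
#' @export
write_network_tsv <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a consensus network as GraphML
#'
#' Node attributes: taxonomy ranks, av.ra, prevalence, dataset tag;
#' edge attributes: weight, sign, supporting methods.
#'
#' @param network A `consensus_network`.
#' @param path Output file.
#' @export
write_network_graphml <- function(network, path) {
  g <- as_igraph(network)
  # GraphML cannot carry NA weights (mb-only edges); encode as 0
  if ("weight" %in% igraph::edge_attr_names(g)) {
    w <- igraph::E(g)$weight
    w[is.na(w)] <- 0
    igraph::E(g)$weight <- w
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
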