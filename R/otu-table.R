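#' The seven taxonomic ranks carried by every OTU table
#'
#' @return Character vector of rank names, from domain down to a
#'   species-level proxy label.
#' @export
tax_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

#' Construct an OTU count table
#'
#' The universal currency of the pipeline: a non-negative integer count
#' matrix (samples x OTUs) together with a 7-rank taxonomy per OTU and
#' per-sample metadata (date, lake-cycle phase, dataset tag).
#'
#' @param counts Integer matrix, samples in rows, OTUs in columns; both
#'   dimensions must be named.
#' @param taxonomy Data frame with one row per OTU (rownames = OTU ids)
#'   and the columns of [tax_ranks()]. Optional.
#' @param sample_data Data frame with one row per sample (rownames =
#'   sample ids); conventional columns are `date`, `phase` and `dataset`
#'   (`"TS"` for time series, `"MC"` for mixed cultures). Optional.
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(counts, taxonomy = NULL, sample_data = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0) {
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts)) && ncol(counts) > 0) {
    colnames(counts) <- paste0("OTU_", seq_len(ncol(counts)))
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integral")
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    missing_otus <- setdiff(colnames(counts), rownames(taxonomy))
    if (length(missing_otus) > 0) {
      stop("taxonomy missing OTUs: ", paste(utils::head(missing_otus, 5),
                                            collapse = ", "))
    }
    taxonomy <- taxonomy[colnames(counts), , drop = FALSE]
  }
  if (!is.null(sample_data)) {
    sample_data <- as.data.frame(sample_data)
    missing_s <- setdiff(rownames(counts), rownames(sample_data))
    if (length(missing_s) > 0) {
      stop("sample_data missing samples: ",
           paste(utils::head(missing_s, 5), collapse = ", "))
    }
    sample_data <- sample_data[rownames(counts), , drop = FALSE]
  }
  structure(list(counts = counts, taxonomy = taxonomy,
                 sample_data = sample_data),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs (total reads %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  if (!is.null(x$sample_data) && "dataset" %in% names(x$sample_data)) {
    cat("  dataset tag(s):",
        paste(unique(x$sample_data$dataset), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Dimensions and identifiers of an OTU table
#'
#' @param x An `otu_table`.
#' @return Sample/OTU counts or id vectors.
#' @export
n_samples <- function(x) nrow(x$counts)

#' @rdname n_samples
#' @export
n_otus <- function(x) ncol(x$counts)

#' @rdname n_samples
#' @export
otu_ids <- function(x) colnames(x$counts)

#' @rdname n_samples
#' @export
sample_ids <- function(x) rownames(x$counts)

#' Per-sample relative abundances
#'
#' @param x An `otu_table`.
#' @return Matrix of proportions (samples x OTUs); rows of all-zero
#'   samples are returned as zeros.
#' @export
rel_abundance <- function(x) {
  cts <- x$counts
  tot <- rowSums(cts)
  tot[tot == 0] <- 1
  sweep(cts, 1, tot, "/")
}

#' Mean relative abundance (av.ra) per OTU
#'
#' @param x An `otu_table`.
#' @return Named numeric vector, mean per-sample proportion of each OTU.
#' @export
av_ra <- function(x) colMeans(rel_abundance(x))

#' Prevalence per OTU
#'
#' Fraction of samples in which each OTU is detected (count > 0).
#'
#' @param x An `otu_table`.
#' @return Named numeric vector in \[0, 1\].
#' @export
prevalence <- function(x) colMeans(x$counts > 0)

#' Subset an OTU table
#'
#' @param x An `otu_table`.
#' @param otus,samples Logical, integer or character index into OTUs /
#'   samples; `NULL` keeps everything.
#' @return A new `otu_table`.
#' @export
subset_table <- function(x, otus = NULL, samples = NULL) {
  cts <- x$counts
  if (!is.null(samples)) cts <- cts[samples, , drop = FALSE]
  if (!is.null(otus)) cts <- cts[, otus, drop = FALSE]
  tax <- x$taxonomy
  if (!is.null(tax)) tax <- tax[colnames(cts), , drop = FALSE]
  sd <- x$sample_data
  if (!is.null(sd)) sd <- sd[rownames(cts), , drop = FALSE]
  otu_table(cts, tax, sd)
}

#' Rarefy samples to an even sequencing depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads. Samples with fewer than `depth` total reads are dropped (and
#' listed in the `dropped_samples` attribute), mirroring standard
#' single-rarefaction practice.
#'
#' @param x An `otu_table`.
#' @param depth Target reads per sample (>= 1); 1500 for the time-series
#'   preset, 500 for mixed cultures.
#' @param seed Integer seed; rarefaction is deterministic given the seed.
#' @return A rarefied `otu_table` whose every sample sums to `depth`,
#'   with attribute `dropped_samples`.
#' @export
rarefy <- function(x, depth, seed = 1L) {
  stopifnot(depth >= 1)
  tot <- rowSums(x$counts)
  keep <- tot >= depth
  if (!any(keep)) stop("all samples fall below the rarefaction depth")
  dropped <- rownames(x$counts)[!keep]
  sub <- x$counts[keep, , drop = FALSE]
  rar <- withr::with_seed(seed, withCallingHandlers(
    vegan::rrarefy(sub, depth),
    # vegan guesses data are not raw counts when the smallest nonzero
    # count exceeds 1; synthetic tables trip this legitimately
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  out <- subset_table(x, samples = which(keep))
  storage.mode(rar) <- "integer"
  out$counts <- rar
  attr(out, "dropped_samples") <- dropped
  out
}

#' Summarize sparsity and effective diversity of a table
#'
#' Computes the fraction of zero cells and the per-sample inverse
#' Simpson index n_eff = 1 / sum(p_i^2), the two screening statistics
#' used to judge whether a filtered table is suitable for network
#' inference (sparsity <= 50%, mean n_eff >= 10).
#'
#' @param x An `otu_table`.
#' @return A list of class `table_summary` with `sparsity`, the
#'   per-sample `n_eff` vector (NA for zero-read samples), and
#'   `n_eff_min`, `n_eff_mean`, `n_eff_max` over valid samples.
#' @export
summarize_table <- function(x) {
  cts <- x$counts
  if (nrow(cts) < 1) stop("table has no samples")
  tot <- rowSums(cts)
  n_eff <- rep(NA_real_, nrow(cts))
  ok <- tot > 0
  if (any(ok)) {
    n_eff[ok] <- vegan::diversity(cts[ok, , drop = FALSE], index = "invsimpson")
  }
  names(n_eff) <- rownames(cts)
  structure(list(
    sparsity = mean(cts == 0),
    n_eff = n_eff,
    n_eff_min = if (any(ok)) min(n_eff[ok]) else NA_real_,
    n_eff_mean = if (any(ok)) mean(n_eff[ok]) else NA_real_,
    n_eff_max = if (any(ok)) max(n_eff[ok]) else NA_real_,
    n_zero_read_samples = sum(!ok)
  ), class = "table_summary")
}

#' @export
print.table_summary <- function(x, ...) {
  cat(sprintf("sparsity %.3f | n_eff min/mean/max %.2f / %.2f / %.2f\n",
              x$sparsity, x$n_eff_min, x$n_eff_mean, x$n_eff_max))
  invisible(x)
}

#' Apply a detection-frequency / total-abundance filter
#'
#' Keeps an OTU iff it is detected in at least `min_samples` samples and
#' its total relative abundance (per-sample proportions summed over
#' samples) is at least `min_total_ra`. Setting `strict = TRUE` uses
#' strict `>` comparisons instead.
#'
#' @param x An `otu_table`.
#' @param min_samples Minimum number of samples with count > 0.
#' @param min_total_ra Minimum summed relative abundance (at even depth
#'   D, a summed ra of `k/D` corresponds to `k` reads in total).
#' @param strict Use strict inequalities (default inclusive `>=`).
#' @return Filtered `otu_table`.
#' @export
filter_table <- function(x, min_samples = 0, min_total_ra = 0,
                         strict = FALSE) {
  det <- colSums(x$counts > 0)
  tot_ra <- colSums(rel_abundance(x))
  keep <- if (strict) {
    det > min_samples & tot_ra > min_total_ra
  } else {
    det >= min_samples & tot_ra >= min_total_ra
  }
  subset_table(x, otus = which(keep))
}

#' Sweep filter parameters and pick the network-ready table
#'
#' Evaluates every combination of detection-frequency and
#' total-relative-abundance cutoffs, scoring each filtered table by its
#' sparsity and mean inverse-Simpson n_eff. Among grid points achieving
#' sparsity <= `max_sparsity` and mean n_eff >= `min_mean_n_eff`, the
#' one retaining the most OTUs wins (ties broken by lower `min_samples`,
#' then lower `min_total_ra`). If no grid point qualifies, the point
#' with the lowest sparsity is returned and `criteria_met` is `FALSE`.
#'
#' @param x An `otu_table`.
#' @param min_samples_grid Integer vector of detection cutoffs.
#' @param min_total_ra_grid Numeric vector of summed-ra cutoffs.
#' @param max_sparsity,min_mean_n_eff Qualification thresholds
#'   (defaults 0.5 and 10).
#' @param strict Passed to [filter_table()].
#' @return List of class `filter_sweep` with `best` (the chosen
#'   `FilterCriteria`), `table` (the filtered `otu_table`), `grid`
#'   (a data frame of every point's sparsity, mean n_eff and OTUs kept)
#'   and `criteria_met`.
#' @export
filter_sweep <- function(x, min_samples_grid, min_total_ra_grid,
                         max_sparsity = 0.5, min_mean_n_eff = 10,
                         strict = FALSE) {
  if (n_otus(x) == 0 || n_samples(x) == 0) stop("empty table")
  stopifnot(length(min_samples_grid) > 0, length(min_total_ra_grid) > 0)
  grid <- expand.grid(min_samples = sort(min_samples_grid),
                      min_total_ra = sort(min_total_ra_grid))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ft <- filter_table(x, grid$min_samples[i], grid$min_total_ra[i],
                       strict = strict)
    if (n_otus(ft) == 0) {
      return(data.frame(n_otus = 0L, sparsity = NA_real_,
                        n_eff_mean = NA_real_))
    }
    sm <- summarize_table(ft)
    data.frame(n_otus = n_otus(ft), sparsity = sm$sparsity,
               n_eff_mean = sm$n_eff_mean)
  })
  grid <- cbind(grid, do.call(rbind, res))
  grid$qualifies <- !is.na(grid$sparsity) &
    grid$sparsity <= max_sparsity & grid$n_eff_mean >= min_mean_n_eff
  if (any(grid$qualifies)) {
    cand <- grid[grid$qualifies, ]
    cand <- cand[order(-cand$n_otus, cand$min_samples, cand$min_total_ra), ]
    best <- cand[1, ]
    met <- TRUE
  } else {
    cand <- grid[!is.na(grid$sparsity), ]
    if (nrow(cand) == 0) stop("every grid point empties the table")
    cand <- cand[order(cand$sparsity, cand$min_samples, cand$min_total_ra), ]
    best <- cand[1, ]
    met <- FALSE
  }
  structure(list(
    best = list(min_samples = best$min_samples,
                min_total_ra = best$min_total_ra),
    table = filter_table(x, best$min_samples, best$min_total_ra,
                         strict = strict),
    grid = grid,
    criteria_met = met
  ), class = "filter_sweep")
}

#' Remove singleton OTUs
#'
#' Drops OTUs whose total count across all samples is <= 1, the standard
#' pre-network cleanup for the mixed-culture table.
#'
#' @param x An `otu_table`.
#' @return Filtered `otu_table`.
#' @export
drop_singletons <- function(x) {
  subset_table(x, otus = which(colSums(x$counts) > 1))
}

#' Collapse counts to a taxonomic rank
#'
#' Sums counts over OTUs sharing the same label at the requested rank
#' and recomputes proportions; `rank = "otu"` is the identity.
#'
#' @param x An `otu_table` with taxonomy.
#' @param rank One of [tax_ranks()] or `"otu"`.
#' @return A list of class `clade_table`: `counts` and `ra` matrices
#'   (samples x clades) plus the collapsed `rank`.
#' @export
collapse_rank <- function(x, rank) {
  ranks <- c(tax_ranks(), "otu")
  if (!rank %in% ranks) {
    stop("unknown rank '", rank, "'; expected one of: ",
         paste(ranks, collapse = ", "))
  }
  if (rank == "otu") {
    labels <- otu_ids(x)
  } else {
    if (is.null(x$taxonomy)) stop("table has no taxonomy")
    labels <- as.character(x$taxonomy[[rank]])
  }
  groups <- factor(labels, levels = unique(labels))
  cts <- t(rowsum(t(x$counts), groups))
  tot <- rowSums(cts)
  tot[tot == 0] <- 1
  structure(list(counts = cts, ra = sweep(cts, 1, tot, "/"), rank = rank),
            class = "clade_table")
}
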