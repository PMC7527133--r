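#' Generate a nested 7-rank taxonomy with a consistent ultrametric tree
#'
#' Builds a random nested hierarchy (domain > phylum > class > order >
#' family > genus > species-proxy) over `n_otus` OTUs and an ultrametric
#' rooted tree consistent with it: OTUs sharing a label at any rank form
#' a clade. Internal nodes sit at fixed heights per rank so the tree
#' metric is ultrametric with height 1, and the pairwise patristic
#' distance (PD) matrix is emitted alongside.
#'
#' @param n_otus Number of OTUs (>= 1).
#' @param n_phyla Number of phyla (1 <= n_phyla <= n_otus).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A list of class `taxonomy_set`: `otu_id`, `ranks` (data frame,
#'   one row per OTU, columns [tax_ranks()]), `tree` (an `ape::phylo`),
#'   and `pd` (patristic distance matrix).
#' @export
make_taxonomy <- function(n_otus, n_phyla, seed = 1L) {
  if (n_otus < n_phyla || n_phyla < 1) {
    stop("need n_otus >= n_phyla >= 1")
  }
  withr::with_seed(seed, {
    ids <- sprintf("OTU_%03d", seq_len(n_otus))
    ranks <- data.frame(domain = rep("Bacteria", n_otus),
                        row.names = ids, stringsAsFactors = FALSE)
    # recursively partition each group into labelled subgroups
    assign_rank <- function(parent_labels, rank, n_groups_fun) {
      out <- character(n_otus)
      counter <- 0L
      for (g in unique(parent_labels)) {
        members <- which(parent_labels == g)
        m <- length(members)
        k <- n_groups_fun(m)
        grp <- c(seq_len(k), sample.int(k, max(0L, m - k), replace = TRUE))
        grp <- grp[sample.int(m)]
        labs <- sprintf("%s_%02d", toupper(substr(rank, 1, 1)),
                        counter + seq_len(k))
        out[members] <- labs[grp]
        counter <- counter + k
      }
      out
    }
    ranks$phylum <- assign_rank(ranks$domain, "phylum",
                                function(m) min(n_phyla, m))
    split_fun <- function(m) max(1L, min(m, 1L + stats::rbinom(1, m - 1, 0.25)))
    ranks$class <- assign_rank(ranks$phylum, "class", split_fun)
    ranks$order <- assign_rank(ranks$class, "order", split_fun)
    ranks$family <- assign_rank(ranks$order, "family", split_fun)
    ranks$genus <- assign_rank(ranks$family, "genus", split_fun)
    ranks$species <- sprintf("sp_%03d", seq_len(n_otus))

    # height of a node splitting at each rank; the phylum split is the root
    heights <- c(phylum = 1, class = 0.8, order = 0.6, family = 0.4,
                 genus = 0.2)
    rank_cols <- c("phylum", "class", "order", "family", "genus")
    # returns list(str = newick fragment without branch length, top = height)
    build <- function(members, level) {
      if (level > length(rank_cols)) {
        if (length(members) == 1) {
          return(list(str = ids[members], top = 0))
        }
        kids <- vapply(members, function(i) sprintf("%s:%g", ids[i], heights["genus"]),
                       character(1))
        return(list(str = sprintf("(%s)", paste(kids, collapse = ",")),
                    top = heights[["genus"]]))
      }
      groups <- split(members, ranks[[rank_cols[level]]][members])
      if (length(groups) == 1) {
        return(build(groups[[1]], level + 1))
      }
      h <- heights[[rank_cols[level] ]]
      # children live one level down; some collapse further
      kids <- vapply(groups, function(g) {
        child <- build(g, level + 1)
        sprintf("%s:%g", child$str, h - child$top)
      }, character(1))
      list(str = sprintf("(%s)", paste(kids, collapse = ",")), top = h)
    }
    if (n_otus == 1) {
      nwk <- sprintf("(%s:1);", ids[1])
      tree <- ape::read.tree(text = nwk)
      pd <- matrix(0, 1, 1, dimnames = list(ids, ids))
    } else {
      root <- build(seq_len(n_otus), 1)
      nwk <- sprintf("%s;", root$str)
      tree <- ape::read.tree(text = nwk)
      pd <- as.matrix(stats::cophenetic(tree))[ids, ids]
    }
    structure(list(otu_id = ids, ranks = ranks, tree = tree, pd = pd),
              class = "taxonomy_set")
  })
}

#' @export
print.taxonomy_set <- function(x, ...) {
  cat(sprintf("taxonomy_set: %d OTUs, %d phyla\n",
              length(x$otu_id), length(unique(x$ranks$phylum))))
  invisible(x)
}

#' Plant a signed ground-truth interaction network
#'
#' Samples `n_edges` unordered OTU pairs as planted interactions, each
#' with a sign and a coupling strength, plus the per-OTU parameters of
#' the latent abundance model (baseline log abundance, seasonal
#' amplitude and phase). With `assortative_bias > 0`, within-phylum
#' pairs are oversampled with probability proportional to
#' `exp(assortative_bias)`, planting taxonomic assortativity.
#'
#' @param taxa A `taxonomy_set`.
#' @param n_edges Number of planted edges (0 allowed).
#' @param frac_negative Expected fraction of negative edges.
#' @param strength Coupling strength in (0, 1] shared by all edges.
#' @param assortative_bias Log odds-ratio favouring within-phylum pairs.
#' @param seed Integer seed.
#' @param base_sd SD of baseline log abundances.
#' @param amplitude_range Range of per-OTU seasonal amplitudes (log
#'   units); use `c(0, 0)` for a season-free community.
#' @return List of class `truth_network`: `edges` (data frame `otu_i`,
#'   `otu_j`, `sign`, `strength`; `otu_i < otu_j` by index),
#'   `base_log_abundance`, `seasonal_amplitude`, `seasonal_phase`.
#' @export
make_truth_network <- function(taxa, n_edges, frac_negative = 0.25,
                               strength = 0.8, assortative_bias = 0,
                               seed = 1L, base_sd = 1,
                               amplitude_range = c(0.2, 0.6)) {
  n <- length(taxa$otu_id)
  max_edges <- n * (n - 1) / 2
  if (n_edges > max_edges) {
    stop("requested ", n_edges, " edges but only ", max_edges,
         " unordered pairs exist")
  }
  stopifnot(frac_negative >= 0, frac_negative <= 1,
            strength > 0, strength <= 1)
  withr::with_seed(seed, {
    if (n_edges > 0) {
      pairs <- t(utils::combn(n, 2))
      same_phylum <- taxa$ranks$phylum[pairs[, 1]] ==
        taxa$ranks$phylum[pairs[, 2]]
      w <- exp(assortative_bias * same_phylum)
      sel <- sample.int(nrow(pairs), n_edges, prob = w)
      edges <- data.frame(
        otu_i = taxa$otu_id[pairs[sel, 1]],
        otu_j = taxa$otu_id[pairs[sel, 2]],
        sign = ifelse(stats::runif(n_edges) < frac_negative, "-", "+"),
        strength = rep(strength, n_edges),
        stringsAsFactors = FALSE
      )
    } else {
      edges <- data.frame(otu_i = character(), otu_j = character(),
                          sign = character(), strength = numeric(),
                          stringsAsFactors = FALSE)
    }
    structure(list(
      edges = edges,
      base_log_abundance = stats::setNames(stats::rnorm(n, 0, base_sd),
                                           taxa$otu_id),
      seasonal_amplitude = stats::setNames(
        stats::runif(n, amplitude_range[1], amplitude_range[2]), taxa$otu_id),
      seasonal_phase = stats::setNames(stats::runif(n, 0, 2 * pi),
                                       taxa$otu_id)
    ), class = "truth_network")
  })
}

#' @export
print.truth_network <- function(x, ...) {
  cat(sprintf("truth_network: %d planted edges (%d negative) over %d OTUs\n",
              nrow(x$edges), sum(x$edges$sign == "-"),
              length(x$base_log_abundance)))
  invisible(x)
}

phase_from_date <- function(dates) {
  month <- as.integer(format(dates, "%m"))
  phase <- character(length(dates))
  phase[month %in% c(12, 1, 2)] <- "winter"
  phase[month %in% 3:5] <- "spring"
  phase[month %in% 9:11] <- "autumn"
  summer <- which(month %in% 6:8)
  # stratified summer samples cycle through the three lake layers
  layers <- c("epilimnion", "metalimnion", "hypolimnion")
  phase[summer] <- layers[(seq_along(summer) - 1L) %% 3L + 1L]
  phase
}

#' Simulate a seasonal time-series OTU table
#'
#' Latent per-sample log abundances are baseline + seasonal sinusoid +
#' interaction coupling + Gaussian noise; counts are drawn multinomially
#' at an even depth, emulating a rarefied amplicon table. Each planted
#' edge contributes a shared standard-normal latent factor scaled by
#' `strength * coupling_sd` added to both partners (anti-phase for
#' negative edges), so edge strength maps directly onto the pairwise
#' correlation the estimators are asked to recover.
#'
#' @param taxa A `taxonomy_set`.
#' @param truth A `truth_network` over the same OTUs.
#' @param n_samples Number of samples (>= 2).
#' @param depth Reads per sample (default 1500, the time-series
#'   rarefaction depth).
#' @param noise_sd SD of the per-OTU, per-sample Gaussian noise on the
#'   latent log abundance.
#' @param seed Integer seed.
#' @param coupling_sd Scale of the shared latent factor per edge.
#' @param start_date First sampling date; samples follow every
#'   `interval_days` days.
#' @param interval_days Days between consecutive samples.
#' @return An `otu_table` tagged `dataset = "TS"`, with `date` and a
#'   six-level `phase` label (spring, autumn, winter, and the three
#'   summer stratification layers) per sample.
#' @export
simulate_timeseries <- function(taxa, truth, n_samples, depth = 1500,
                                noise_sd = 1, seed = 1L, coupling_sd = 2,
                                start_date = as.Date("2011-01-10"),
                                interval_days = 7) {
  stopifnot(depth >= 1, n_samples >= 2)
  withr::with_seed(seed, {
    n <- length(taxa$otu_id)
    dates <- start_date + (seq_len(n_samples) - 1L) * interval_days
    yearfrac <- as.integer(format(dates, "%j")) / 365
    eta <- matrix(rep(truth$base_log_abundance, each = n_samples),
                  n_samples, n, dimnames = list(NULL, taxa$otu_id))
    seas <- sin(sweep(outer(2 * pi * yearfrac, rep(1, n)), 2,
                      truth$seasonal_phase, "+"))
    eta <- eta + sweep(seas, 2, truth$seasonal_amplitude, "*")
    if (nrow(truth$edges) > 0) {
      for (e in seq_len(nrow(truth$edges))) {
        z <- stats::rnorm(n_samples)
        s <- truth$edges$strength[e] * coupling_sd
        i <- truth$edges$otu_i[e]
        j <- truth$edges$otu_j[e]
        eta[, i] <- eta[, i] + s * z
        eta[, j] <- eta[, j] + (if (truth$edges$sign[e] == "+") s else -s) * z
      }
    }
    if (noise_sd > 0) {
      eta <- eta + matrix(stats::rnorm(n_samples * n, 0, noise_sd),
                          n_samples, n)
    }
    p <- exp(eta - apply(eta, 1, max))
    p <- p / rowSums(p)
    counts <- t(apply(p, 1, function(pr) stats::rmultinom(1, depth, pr)))
    dimnames(counts) <- list(sprintf("TS_%03d", seq_len(n_samples)),
                             taxa$otu_id)
    meta <- data.frame(
      sample_id = rownames(counts),
      date = dates,
      phase = phase_from_date(dates),
      dataset = "TS",
      row.names = rownames(counts),
      stringsAsFactors = FALSE
    )
    otu_table(counts, taxonomy = taxa$ranks, sample_data = meta)
  })
}

#' Simulate dilution mixed cultures founded by a few cells
#'
#' Emulates the dilution-to-few-cells design: each of `n_cultures`
#' cultures is founded by a Poisson(`founder_mean`) number of cells
#' assigned to OTUs by the lake composition. Founded OTUs grow by a
#' lognormal growth factor unless an obligate positive-edge partner is
#' absent (when `dependency_rule = TRUE`), in which case they stay at
#' founder level. Reads are drawn multinomially from the final biomass
#' at `depth`; cultures whose total grown biomass (times a lognormal
#' culture-level yield) falls below `detection_fraction` of the
#' expected biomass are flagged not detected, emulating the visible-band
#' censoring that retained about 60 of 98 cultures.
#'
#' @param taxa A `taxonomy_set`.
#' @param truth A `truth_network`; only its positive edges matter, as
#'   candidates for obligate dependencies.
#' @param lake_composition Named probability vector over the OTUs
#'   (founder sampling weights); must sum to 1.
#' @param n_cultures Number of cultures (default 98).
#' @param founder_mean Mean founder cells per culture (default 10).
#' @param depth Reads per culture (default 500, the mixed-culture
#'   rarefaction depth).
#' @param detection_fraction Detection threshold as a fraction of the
#'   expected per-culture biomass; the default 0.67 was calibrated once
#'   so that roughly 60/98 cultures pass at default settings.
#' @param seed Integer seed.
#' @param dependency_rule If `TRUE`, a fraction `obligate_frac` of the
#'   positive planted edges is marked obligate and both partners must be
#'   co-founded for either to grow.
#' @param obligate_frac Fraction of positive edges marked obligate.
#' @param growth_factor Multiplicative growth of a founded, growing OTU.
#' @param growth_log_sd Lognormal SD of per-OTU growth.
#' @param yield_log_sd Lognormal SD of the culture-level yield.
#' @return An `otu_table` tagged `dataset = "MC"` whose `sample_data`
#'   carries a logical `detected` column; attributes `founders` (the
#'   cultures x OTUs founder-cell matrix) and `obligate_edges`.
#' @export
simulate_cultures <- function(taxa, truth, lake_composition,
                              n_cultures = 98, founder_mean = 10,
                              depth = 500, detection_fraction = 0.67,
                              seed = 1L, dependency_rule = FALSE,
                              obligate_frac = 0.5, growth_factor = 1000,
                              growth_log_sd = 0.5, yield_log_sd = 1.5) {
  n <- length(taxa$otu_id)
  if (length(lake_composition) != n) {
    stop("lake_composition must have one entry per OTU")
  }
  if (abs(sum(lake_composition) - 1) > 1e-8 || any(lake_composition < 0)) {
    stop("lake_composition must be a probability vector summing to 1")
  }
  stopifnot(founder_mean > 0, depth >= 1)
  withr::with_seed(seed, {
    obligate <- truth$edges[truth$edges$sign == "+", , drop = FALSE]
    if (dependency_rule && nrow(obligate) > 0) {
      keep <- sample.int(nrow(obligate),
                         round(obligate_frac * nrow(obligate)))
      obligate <- obligate[keep, , drop = FALSE]
    } else {
      obligate <- obligate[0, , drop = FALSE]
    }
    founders <- matrix(0L, n_cultures, n,
                       dimnames = list(sprintf("MC_%03d", seq_len(n_cultures)),
                                       taxa$otu_id))
    counts <- matrix(0L, n_cultures, n, dimnames = dimnames(founders))
    detected <- logical(n_cultures)
    threshold <- detection_fraction * founder_mean * growth_factor
    for (cidx in seq_len(n_cultures)) {
      nf <- stats::rpois(1, founder_mean)
      if (nf > 0) {
        founders[cidx, ] <- as.integer(
          stats::rmultinom(1, nf, lake_composition))
      }
      founded <- founders[cidx, ] > 0
      grows <- founded
      if (nrow(obligate) > 0) {
        for (e in seq_len(nrow(obligate))) {
          i <- obligate$otu_i[e]; j <- obligate$otu_j[e]
          if (founded[i] && !founded[j]) grows[i] <- FALSE
          if (founded[j] && !founded[i]) grows[j] <- FALSE
        }
      }
      biomass <- as.numeric(founders[cidx, ])
      if (any(grows)) {
        biomass[grows] <- biomass[grows] * growth_factor *
          exp(stats::rnorm(sum(grows), 0, growth_log_sd))
      }
      yield <- exp(stats::rnorm(1, 0, yield_log_sd))
      detected[cidx] <- sum(biomass[grows]) * yield >= threshold
      if (sum(biomass) > 0) {
        counts[cidx, ] <- as.integer(
          stats::rmultinom(1, depth, biomass / sum(biomass)))
      }
    }
    meta <- data.frame(
      sample_id = rownames(counts),
      date = as.Date(NA),
      phase = NA_character_,
      dataset = "MC",
      detected = detected,
      row.names = rownames(counts),
      stringsAsFactors = FALSE
    )
    out <- otu_table(counts, taxonomy = taxa$ranks, sample_data = meta)
    attr(out, "founders") <- founders
    attr(out, "obligate_edges") <- obligate
    out
  })
}

#' Simulate an environmental-parameter table
#'
#' Parameters are seasonal sinusoids plus AR(1) noise. For each OTU in
#' `linked_otus` one parameter is constructed with target Pearson
#' correlation `link_r` to that OTU's relative-abundance series in
#' `table`. Cells go missing independently at rate `missing_frac`.
#'
#' @param n_samples Number of samples; must match `table` if given.
#' @param n_params Total number of parameters (default 14, the size of
#'   the collinearity-pruned predictor set).
#' @param linked_otus Character vector of OTU ids to link (may be empty).
#' @param link_r Target correlation for linked parameters, |r| < 1.
#' @param missing_frac Missingness rate in \[0, 1).
#' @param seed Integer seed.
#' @param table An `otu_table` supplying the linked OTUs' abundance
#'   series (required when `linked_otus` is non-empty).
#' @return A data frame of class `env_table` (samples x parameters) with
#'   `NA` for missing cells; linked parameters are named
#'   `env_<otu id>`.
#' @export
simulate_env <- function(n_samples, n_params = 14, linked_otus = character(),
                         link_r = 0.6, missing_frac = 0.1, seed = 1L,
                         table = NULL) {
  if (abs(link_r) >= 1) stop("|link_r| must be < 1")
  stopifnot(missing_frac >= 0, missing_frac < 1)
  if (length(linked_otus) > 0) {
    if (is.null(table)) stop("linked_otus requires `table`")
    if (n_samples != n_samples(table)) {
      stop("n_samples must match the linked table")
    }
    if (length(linked_otus) > n_params) {
      stop("more linked OTUs than parameters")
    }
  }
  withr::with_seed(seed, {
    t_idx <- seq_len(n_samples)
    make_param <- function() {
      amp <- stats::runif(1, 0.5, 2)
      ph <- stats::runif(1, 0, 2 * pi)
      ar <- stats::arima.sim(list(ar = 0.6), n_samples,
                             sd = stats::runif(1, 0.3, 1))
      amp * sin(2 * pi * t_idx / 52 + ph) + as.numeric(ar)
    }
    env <- matrix(NA_real_, n_samples, n_params)
    nm <- sprintf("param_%02d", seq_len(n_params))
    k <- length(linked_otus)
    if (k > 0) {
      ra <- rel_abundance(table)[, linked_otus, drop = FALSE]
      for (i in seq_len(k)) {
        y <- as.numeric(scale(ra[, i]))
        env[, i] <- link_r * y +
          sqrt(1 - link_r^2) * stats::rnorm(n_samples)
      }
      nm[seq_len(k)] <- paste0("env_", linked_otus)
    }
    if (n_params > k) {
      for (i in (k + 1):n_params) env[, i] <- make_param()
    }
    if (missing_frac > 0) {
      env[stats::runif(length(env)) < missing_frac] <- NA_real_
    }
    env <- as.data.frame(env)
    names(env) <- nm
    rownames(env) <- if (!is.null(table)) sample_ids(table) else
      sprintf("S%03d", t_idx)
    class(env) <- c("env_table", "data.frame")
    env
  })
}
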