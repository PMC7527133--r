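pearson_pair <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3) return(list(r = NA_real_, p = NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- if (abs(r) >= 1 - 1e-15) 0 else 2 * stats::pt(-abs(tt), df = n - 2)
  list(r = r, p = p, n = n)
}

clade_ra <- function(clades) {
  if (inherits(clades, "clade_table")) clades$ra else as.matrix(clades)
}

#' Prune collinear environmental parameters
#'
#' Stage 1 removes parameters whose missingness exceeds
#' `missing_cutoff`. Stage 2 iteratively removes, among parameters with
#' VIF above `vif_cutoff` or involved in a pairwise |correlation| above
#' `corr_cutoff`, the one with the most missing values (ties broken by
#' higher VIF, then name order), until the retained set satisfies both
#' constraints. VIF is 1/(1 - R^2) of a parameter regressed on all other
#' retained parameters over complete cases.
#'
#' @param env An `env_table` (or data frame) of numeric parameters,
#'   missing values allowed; >= 2 parameters.
#' @param missing_cutoff Maximum tolerated missing fraction (default
#'   0.4).
#' @param vif_cutoff Maximum tolerated VIF (default 10).
#' @param corr_cutoff Maximum tolerated pairwise |correlation|
#'   (default 0.7).
#' @return List of class `collinearity_report`: `removed` (data frame
#'   `parameter`, `reason`, `n_missing`, `order`), `retained`, and the
#'   final `vif` vector.
#' @export
prune_collinear <- function(env, missing_cutoff = 0.4, vif_cutoff = 10,
                            corr_cutoff = 0.7) {
  env <- as.data.frame(env)
  if (ncol(env) < 2) stop("need at least 2 parameters")
  n_missing <- colSums(is.na(env))
  removed <- data.frame(parameter = character(), reason = character(),
                        n_missing = integer(), order = integer(),
                        stringsAsFactors = FALSE)
  ord <- 0L
  frac_missing <- colMeans(is.na(env))
  for (p in names(env)[frac_missing > missing_cutoff]) {
    ord <- ord + 1L
    removed <- rbind(removed, data.frame(
      parameter = p, reason = "missingness", n_missing = n_missing[[p]],
      order = ord, stringsAsFactors = FALSE))
  }
  retained <- setdiff(names(env), removed$parameter)
  compute_vif <- function(params) {
    sub <- env[, params, drop = FALSE]
    cc <- sub[stats::complete.cases(sub), , drop = FALSE]
    if (nrow(cc) < 2) stop("fewer than 2 complete-case rows")
    vapply(params, function(p) {
      others <- setdiff(params, p)
      if (length(others) == 0) return(1)
      fit <- stats::lm(stats::reformulate(others, response = p), data = cc)
      # near-perfect fits are exactly what the VIF cutoff is after
      r2 <- suppressWarnings(summary(fit)$r.squared)
      1 / max(1 - r2, 1e-12)
    }, numeric(1))
  }
  vif <- NULL
  while (length(retained) >= 2) {
    vif <- compute_vif(retained)
    cm <- abs(stats::cor(env[, retained, drop = FALSE],
                         use = "pairwise.complete.obs"))
    diag(cm) <- 0
    max_corr <- apply(cm, 1, max, na.rm = TRUE)
    viol <- vif > vif_cutoff | max_corr > corr_cutoff
    if (!any(viol)) break
    cand <- retained[viol]
    pick <- cand[order(-n_missing[cand], -vif[cand], cand)][1]
    reason <- paste(c(if (vif[[pick]] > vif_cutoff) "vif",
                      if (max_corr[[pick]] > corr_cutoff) "corr"),
                    collapse = "+")
    ord <- ord + 1L
    removed <- rbind(removed, data.frame(
      parameter = pick, reason = reason, n_missing = n_missing[[pick]],
      order = ord, stringsAsFactors = FALSE))
    retained <- setdiff(retained, pick)
  }
  if (length(retained) >= 2) vif <- compute_vif(retained)
  rownames(removed) <- NULL
  structure(list(removed = removed, retained = retained, vif = vif),
            class = "collinearity_report")
}

#' Screen clade abundances against environmental parameters
#'
#' Pearson correlation per clade x parameter over pairwise-complete
#' observations, BH-adjusted over all tests; a pair is flagged iff
#' |r| > `r_min` and adjusted p < `alpha`.
#'
#' @param clades A `clade_table` (or samples x clades abundance matrix).
#' @param env An `env_table` over the same samples (matched by
#'   rownames).
#' @param alpha Significance level on adjusted p (default 0.001).
#' @param r_min Display/retention threshold on |r| (default 0.3).
#' @return Data frame: `clade`, `parameter`, `r`, `n`, `p_raw`, `p_adj`,
#'   `flag_passed`.
#' @export
env_screen <- function(clades, env, alpha = 0.001, r_min = 0.3) {
  ra <- clade_ra(clades)
  env <- as.data.frame(env)
  shared <- intersect(rownames(ra), rownames(env))
  if (length(shared) < 3) stop("fewer than 3 shared samples")
  ra <- ra[shared, , drop = FALSE]
  env <- env[shared, , drop = FALSE]
  grid <- expand.grid(clade = colnames(ra), parameter = names(env),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    pearson_pair(ra[, grid$clade[i]], env[[grid$parameter[i]]])
  })
  grid$r <- vapply(res, `[[`, numeric(1), "r")
  grid$n <- vapply(res, `[[`, numeric(1), "n")
  grid$p_raw <- vapply(res, `[[`, numeric(1), "p")
  grid$p_adj <- NA_real_
  ok <- !is.na(grid$p_raw)
  grid$p_adj[ok] <- stats::p.adjust(grid$p_raw[ok], method = "BH")
  grid$flag_passed <- !is.na(grid$r) & abs(grid$r) > r_min &
    !is.na(grid$p_adj) & grid$p_adj < alpha
  grid
}

# Siegel-Castellan critical difference on mean rank sums
kw_posthoc <- function(values, groups, alpha) {
  rk <- rank(values)
  n_g <- tapply(rk, groups, length)
  mean_rk <- tapply(rk, groups, mean)
  levs <- names(n_g)
  k <- length(levs)
  N <- length(values)
  z <- stats::qnorm(1 - alpha / (k * (k - 1)))
  out <- NULL
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      crit <- z * sqrt(N * (N + 1) / 12 *
                         (1 / n_g[[a]] + 1 / n_g[[b]]))
      d <- abs(mean_rk[[a]] - mean_rk[[b]])
      out <- rbind(out, data.frame(
        phase_a = levs[a], phase_b = levs[b], diff = d,
        critical = crit, significant = d >= crit,
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Kruskal-Wallis screen of clade abundance across lake-cycle phases
#'
#' Per clade: the Kruskal-Wallis H test over phase groups; when
#' p < `alpha`, an all-pairs post hoc comparison of mean rank sums with
#' the normal-approximation critical difference at the same `alpha`
#' (Bonferroni-style over the k(k-1)/2 pairs). Phases differing from at
#' least two others are flagged.
#'
#' @param clades A `clade_table` (or samples x clades abundance matrix).
#' @param phases Character vector of phase labels, one per sample
#'   (aligned with rows); `NA` phases are dropped.
#' @param alpha Significance level (default 0.001).
#' @return List of class `phase_kw`: `tests` (clade, H, df, p_raw),
#'   `posthoc` (per significant clade, all phase pairs with the critical
#'   difference), `flagged` (clade x phase rows where a phase differs
#'   from >= 2 others).
#' @export
phase_kw <- function(clades, phases, alpha = 0.001) {
  ra <- clade_ra(clades)
  phases <- as.character(phases)
  stopifnot(length(phases) == nrow(ra))
  keep <- !is.na(phases)
  ra <- ra[keep, , drop = FALSE]
  phases <- phases[keep]
  tab <- table(phases)
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    warning("dropping phase group(s) with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !phases %in% small
    ra <- ra[keep, , drop = FALSE]
    phases <- phases[keep]
  }
  if (length(unique(phases)) < 2) {
    stop("need at least 2 phase groups with >= 2 observations")
  }
  g <- factor(phases)
  tests <- NULL
  posthoc <- NULL
  flagged <- NULL
  for (cl in colnames(ra)) {
    kw <- stats::kruskal.test(ra[, cl], g)
    tests <- rbind(tests, data.frame(
      clade = cl, H = unname(kw$statistic), df = unname(kw$parameter),
      p_raw = kw$p.value, stringsAsFactors = FALSE))
    if (!is.na(kw$p.value) && kw$p.value < alpha) {
      ph <- kw_posthoc(ra[, cl], g, alpha)
      ph$clade <- cl
      posthoc <- rbind(posthoc, ph)
      sig <- ph[ph$significant, , drop = FALSE]
      cnt <- table(c(sig$phase_a, sig$phase_b))
      hits <- names(cnt)[cnt >= 2]
      if (length(hits) > 0) {
        flagged <- rbind(flagged, data.frame(
          clade = cl, phase = hits, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(posthoc)) {
    posthoc <- data.frame(phase_a = character(), phase_b = character(),
                          diff = numeric(), critical = numeric(),
                          significant = logical(), clade = character(),
                          stringsAsFactors = FALSE)
  }
  if (is.null(flagged)) {
    flagged <- data.frame(clade = character(), phase = character(),
                          stringsAsFactors = FALSE)
  }
  rownames(tests) <- rownames(posthoc) <- rownames(flagged) <- NULL
  structure(list(tests = tests, posthoc = posthoc, flagged = flagged,
                 alpha = alpha),
            class = "phase_kw")
}

#' Phylogenetic distance versus co-occurrence strength within a cohort
#'
#' For every network-connected (target member, cohort member) pair, the
#' patristic distance is compared with the consensus edge weight (the
#' averaged correlation); Pearson r and p are reported over those pairs,
#' testing whether relatedness predicts co-occurrence.
#'
#' @param cohort A `cohort` from [first_neighbors()].
#' @param network The `consensus_network` the cohort came from.
#' @param pd Pairwise patristic distance matrix covering target and
#'   cohort OTUs.
#' @return List of class `pd_correlation`: `r`, `p`, `n` (NA r/p when
#'   n < 3 or PD is constant across pairs, noted in `note`), and
#'   `scatter` (data frame `target`, `member`, `pd`, `weight`).
#' @export
pd_vs_correlation <- function(cohort, network, pd) {
  ed <- network$edges
  sel <- (ed$otu_i %in% cohort$target & ed$otu_j %in% cohort$neighbors$otu) |
    (ed$otu_j %in% cohort$target & ed$otu_i %in% cohort$neighbors$otu)
  ed <- ed[sel, , drop = FALSE]
  tgt <- ifelse(ed$otu_i %in% cohort$target, ed$otu_i, ed$otu_j)
  mem <- ifelse(ed$otu_i %in% cohort$target, ed$otu_j, ed$otu_i)
  need <- unique(c(tgt, mem))
  miss <- setdiff(need, rownames(pd))
  if (length(miss) > 0) {
    stop("pd matrix missing OTUs: ", paste(miss, collapse = ", "))
  }
  scatter <- data.frame(target = tgt, member = mem,
                        pd = pd[cbind(tgt, mem)], weight = ed$weight,
                        stringsAsFactors = FALSE)
  scatter <- scatter[!is.na(scatter$weight), , drop = FALSE]
  note <- NA_character_
  if (nrow(scatter) < 3) {
    r <- p <- NA_real_
    note <- "fewer than 3 connected pairs"
  } else if (stats::sd(scatter$pd) == 0) {
    r <- p <- NA_real_
    note <- "constant phylogenetic distance across pairs"
  } else {
    pr <- pearson_pair(scatter$pd, scatter$weight)
    r <- pr$r; p <- pr$p
  }
  structure(list(r = r, p = p, n = nrow(scatter), note = note,
                 scatter = scatter),
            class = "pd_correlation")
}

#' Cross-dataset abundance and prevalence correlations
#'
#' Over OTUs shared by two tables (e.g. time series vs mixed cultures):
#' Pearson correlations of log10 mean relative abundance, of prevalence,
#' and the two cross combinations, BH-adjusted; optionally repeated
#' within designated taxon subsets. OTUs with zero mean abundance are
#' excluded from comparisons involving their log abundance.
#'
#' @param table_a,table_b Two `otu_table`s sharing >= 3 OTU ids.
#' @param subsets Optional named list of OTU id vectors; each subset is
#'   screened separately alongside the overall test.
#' @return Data frame: `subset`, `comparison`, `r`, `n`, `p_raw`,
#'   `p_adj`.
#' @export
cross_dataset_corr <- function(table_a, table_b, subsets = NULL) {
  shared <- intersect(otu_ids(table_a), otu_ids(table_b))
  if (length(shared) < 3) stop("fewer than 3 shared OTUs")
  stats_for <- function(ids) {
    a_ra <- av_ra(table_a)[ids]; b_ra <- av_ra(table_b)[ids]
    a_pr <- prevalence(table_a)[ids]; b_pr <- prevalence(table_b)[ids]
    log_a <- ifelse(a_ra > 0, log10(a_ra), NA_real_)
    log_b <- ifelse(b_ra > 0, log10(b_ra), NA_real_)
    specs <- list(
      log_avra_vs_log_avra = list(log_a, log_b),
      prevalence_vs_prevalence = list(a_pr, b_pr),
      log_avra_a_vs_prevalence_b = list(log_a, b_pr),
      prevalence_a_vs_log_avra_b = list(a_pr, log_b)
    )
    do.call(rbind, lapply(names(specs), function(nm) {
      pr <- pearson_pair(specs[[nm]][[1]], specs[[nm]][[2]])
      data.frame(comparison = nm, r = pr$r, n = pr$n, p_raw = pr$p,
                 stringsAsFactors = FALSE)
    }))
  }
  groups <- c(list(all = shared),
              lapply(subsets, function(s) intersect(s, shared)))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    cbind(subset = g, stats_for(groups[[g]]), stringsAsFactors = FALSE)
  }))
  out$p_adj <- NA_real_
  ok <- !is.na(out$p_raw)
  out$p_adj[ok] <- stats::p.adjust(out$p_raw[ok], method = "BH")
  rownames(out) <- NULL
  out
}
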