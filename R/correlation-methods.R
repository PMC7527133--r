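#' @name correlation_result
#' @title Per-method association results
#'
#' @description Every estimator returns a `correlation_result`: the
#' method name plus symmetric `coef`, `p_raw`, `p_adj` matrices where
#' applicable, and for the neighborhood-selection method a boolean
#' `support` adjacency with a `sign` matrix. Diagonals are never treated
#' as edges.
NULL

correlation_result <- function(method, coef = NULL, p_raw = NULL,
                               p_adj = NULL, support = NULL, sign = NULL) {
  structure(list(method = method, coef = coef, p_raw = p_raw,
                 p_adj = p_adj, support = support, sign = sign),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  d <- if (!is.null(x$coef)) ncol(x$coef) else ncol(x$support)
  cat(sprintf("correlation_result [%s] over %d OTUs\n", x$method, d))
  invisible(x)
}

# BH (or BY) adjustment over the upper triangle of a symmetric p matrix
adjust_sym <- function(p, method = "BH") {
  ut <- upper.tri(p)
  vals <- p[ut]
  ok <- !is.na(vals)
  adj <- rep(NA_real_, length(vals))
  adj[ok] <- stats::p.adjust(vals[ok], method = method)
  out <- p
  out[ut] <- adj
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

#' Pairwise Pearson correlation with multiple-testing adjustment
#'
#' Pearson r over relative abundances with two-sided p-values and
#' Benjamini-Hochberg adjustment over the upper triangle. Zero-variance
#' OTUs get `NA` and are excluded from the adjustment count.
#'
#' @param x An `otu_table` (>= 3 samples).
#' @param adjust `"BH"` (default) or `"BY"`.
#' @param on `"ra"` (relative abundances, default) or `"counts"`.
#' @return A `correlation_result` with `coef`, `p_raw`, `p_adj`.
#' @export
pearson_matrix <- function(x, adjust = "BH", on = c("ra", "counts")) {
  on <- match.arg(on)
  m <- if (on == "ra") rel_abundance(x) else x$counts
  n <- nrow(m)
  if (n < 3) stop("need at least 3 samples")
  sds <- apply(m, 2, stats::sd)
  r <- suppressWarnings(stats::cor(m))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1 - 1e-15] <- 0
  diag(r) <- 1
  diag(p) <- NA_real_
  correlation_result("pearson", coef = r, p_raw = p,
                     p_adj = adjust_sym(p, adjust))
}

#' Centered log-ratio transform
#'
#' Per sample: log(count + pseudocount) minus the sample's mean log,
#' mapping compositions to unconstrained coordinates (the input space of
#' the neighborhood-selection graph model).
#'
#' @param x An `otu_table`.
#' @param pseudocount Positive offset added to every count (default 1).
#' @return Numeric matrix (samples x OTUs); each row sums to 0.
#' @export
clr_transform <- function(x, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  lg <- log(x$counts + pseudocount)
  sweep(lg, 1, rowMeans(lg), "-")
}

# one Dirichlet(counts + 1) draw of fractions per sample
dirichlet_fractions <- function(counts) {
  g <- matrix(stats::rgamma(length(counts), shape = as.numeric(counts) + 1),
              nrow(counts), ncol(counts))
  g / rowSums(g)
}

solve_basis <- function(T_mat, M, T_full = T_mat) {
  t_i <- rowSums(T_mat)
  omega <- solve(M, t_i)
  flagged <- omega <= 0
  omega[flagged] <- 1e-10
  # rho always from the full variation matrix; exclusions only shape
  # the basis-variance solve
  rho <- (outer(omega, omega, "+") - T_full) /
    (2 * sqrt(outer(omega, omega, "*")))
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  list(omega = omega, rho = rho, flagged = flagged)
}

#' Solve the SparCC basis system for a log-ratio variance matrix
#'
#' Under the sparsity approximation (most basis correlations near 0),
#' t_ij = w_i + w_j - 2 rho_ij sqrt(w_i w_j) reduces to
#' t_ij = w_i + w_j, a linear system in the basis variances w with
#' matrix M = 1 1' + (D - 2) I. Solving it and back-substituting gives
#' rho_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j)), clipped to
#' \[-1, 1\]. For a 3-component closed system with all t_ij equal to
#' t0, the exact solution is w_i = t0/2 and rho = 0.
#'
#' @param T_mat Symmetric non-negative log-ratio variance matrix with
#'   zero diagonal (>= 3 components).
#' @return List with `omega` (basis variances), `rho` (basis
#'   correlations), and `flagged` (components whose solved variance was
#'   non-positive and got floored).
#' @export
sparcc_basis <- function(T_mat) {
  T_mat <- as.matrix(T_mat)
  D <- ncol(T_mat)
  if (D < 3) stop("basis solve needs at least 3 components")
  if (max(abs(T_mat - t(T_mat))) > 1e-12 || any(diag(T_mat) != 0)) {
    stop("T must be symmetric with zero diagonal")
  }
  M <- matrix(1, D, D)
  diag(M) <- D - 1
  solve_basis(T_mat, M)
}

#' SparCC basis correlations for compositional counts
#'
#' Estimates the log-ratio variance matrix t_ij = Var(log(x_i/x_j)) by
#' averaging over `max_iter` Dirichlet(counts + 1) posterior draws of
#' the underlying fractions, solves the sparse-basis linear system for
#' the basis variances, and forms basis correlations
#' rho_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j)), clipped to \[-1, 1\].
#' Up to `exiter` exclusion rounds remove the currently most correlated
#' pair with |rho| > `th` from the basis solve and re-estimate, refining
#' the sparsity assumption.
#'
#' @param x An `otu_table` with >= 4 OTUs.
#' @param max_iter Number of Dirichlet draws averaged (default 100).
#' @param th Exclusion threshold on |rho| (default 0.1).
#' @param exiter Maximum exclusion rounds (default 10).
#' @param seed Integer seed for the Dirichlet draws.
#' @return List with `result` (a `correlation_result`, method
#'   `"sparcc"`, p matrices unset — see [sparcc_pvalues()]) and `state`
#'   (class `sparcc_state`: `T`, `omega`, `rho`, `excluded_pairs`,
#'   `iterations_used`, `flagged_omega`).
#' @export
sparcc <- function(x, max_iter = 100, th = 0.1, exiter = 10, seed = 1L) {
  cts <- x$counts
  D <- ncol(cts)
  if (D < 4) stop("SparCC basis solve needs at least 4 OTUs")
  # fractions are estimated by averaging max_iter Dirichlet(counts + 1)
  # posterior draws (Bayesian smoothing of the composition); the
  # variation matrix t_ij = Var(log(f_i/f_j)) is then computed once
  T_mat <- withr::with_seed(seed, {
    facc <- matrix(0, nrow(cts), D)
    for (it in seq_len(max_iter)) {
      facc <- facc + dirichlet_fractions(cts)
    }
    Y <- log(facc / max_iter)
    V <- apply(Y, 2, stats::var)
    outer(V, V, "+") - 2 * stats::cov(Y)
  })
  T_mat[T_mat < 0] <- 0
  diag(T_mat) <- 0
  dimnames(T_mat) <- list(colnames(cts), colnames(cts))
  M <- matrix(1, D, D)
  diag(M) <- D - 1
  sol <- solve_basis(T_mat, M)
  excluded <- matrix(FALSE, D, D)
  iters <- 0L
  for (round in seq_len(exiter)) {
    masked <- abs(sol$rho)
    masked[excluded] <- 0
    diag(masked) <- 0
    mx <- max(masked)
    if (mx <= th) break
    idx <- which(masked == mx, arr.ind = TRUE)[1, ]
    i <- idx[1]; j <- idx[2]
    excluded[i, j] <- excluded[j, i] <- TRUE
    M[i, j] <- M[i, j] - 1
    M[j, i] <- M[j, i] - 1
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    T_x <- T_mat
    T_x[excluded] <- 0
    new_sol <- tryCatch(solve_basis(T_x, M, T_full = T_mat),
                        error = function(e) NULL)
    if (is.null(new_sol)) {
      # further exclusion makes the basis system singular; keep the
      # last solvable state
      excluded[i, j] <- excluded[j, i] <- FALSE
      M[i, j] <- M[i, j] + 1
      M[j, i] <- M[j, i] + 1
      M[i, i] <- M[i, i] + 1
      M[j, j] <- M[j, j] + 1
      break
    }
    sol <- new_sol
    iters <- iters + 1L
  }
  rho <- sol$rho
  dimnames(rho) <- dimnames(T_mat)
  state <- structure(list(T = T_mat, omega = sol$omega, rho = rho,
                          excluded_pairs = which(excluded & upper.tri(excluded),
                                                 arr.ind = TRUE),
                          iterations_used = iters,
                          flagged_omega = sol$flagged),
                     class = "sparcc_state")
  list(result = correlation_result("sparcc", coef = rho), state = state)
}

#' Bootstrap pseudo p-values for SparCC correlations
#'
#' Builds a no-association null by resampling each OTU's counts
#' independently across samples (with replacement), re-running SparCC on
#' each bootstrap table, and reporting the two-sided pseudo-p
#' `(#\{|rho_boot| >= |rho_obs|\} + 1) / (n_boot + 1)` per pair, with BH
#' adjustment over the upper triangle.
#'
#' @param x An `otu_table`.
#' @param n_boot Number of bootstrap tables (default 100).
#' @param seed Integer seed.
#' @param max_iter,th,exiter Passed to [sparcc()].
#' @param rho_obs Optional precomputed observed correlation matrix; if
#'   omitted, SparCC is run on `x` first.
#' @return List with `p_raw`, `p_adj`, `rho_obs`.
#' @export
sparcc_pvalues <- function(x, n_boot = 100, seed = 1L, max_iter = 100,
                           th = 0.1, exiter = 10, rho_obs = NULL) {
  stopifnot(n_boot >= 1)
  if (is.null(rho_obs)) {
    rho_obs <- sparcc(x, max_iter, th, exiter, seed = seed)$result$coef
  }
  cts <- x$counts
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1,
                                             n_boot + 1))
  count <- matrix(0, ncol(cts), ncol(cts))
  for (b in seq_len(n_boot)) {
    boot_cts <- withr::with_seed(seeds[b], {
      apply(cts, 2, function(col) sample(col, replace = TRUE))
    })
    rownames(boot_cts) <- rownames(cts)
    bt <- otu_table(boot_cts)
    rho_b <- sparcc(bt, max_iter, th, exiter, seed = seeds[n_boot + 1])$result$coef
    count <- count + (abs(rho_b) >= abs(rho_obs))
  }
  p <- (count + 1) / (n_boot + 1)
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(rho_obs)
  list(p_raw = p, p_adj = adjust_sym(p), rho_obs = rho_obs)
}

#' Dice-Sorensen similarity on presence/absence
#'
#' For OTUs A and B with presence sets a and b (count > 0):
#' `2 |a & b| / (|a| + |b|)`. Pairs where both OTUs are absent from every
#' sample are undefined (`NA`).
#'
#' @param x An `otu_table`.
#' @return A `correlation_result` (method `"dice"`) with `coef` in
#'   \[0, 1\].
#' @export
dice_sorensen <- function(x) {
  B <- x$counts > 0
  inter <- crossprod(B)
  sz <- colSums(B)
  denom <- outer(sz, sz, "+")
  coef <- ifelse(denom > 0, 2 * inter / denom, NA_real_)
  dimnames(coef) <- list(colnames(x$counts), colnames(x$counts))
  correlation_result("dice", coef = coef)
}

# glmnet neighborhoods for every node along a fixed lambda path;
# returns D x D x nlambda logical array, [j, i, l] = j in nbhd(i)
mb_neighborhoods <- function(X, lambda) {
  D <- ncol(X)
  nl <- length(lambda)
  adj <- array(FALSE, c(D, D, nl))
  coefs <- array(0, c(D, D, nl))
  for (i in seq_len(D)) {
    fit <- glmnet::glmnet(X[, -i, drop = FALSE], X[, i], family = "gaussian",
                          lambda = lambda, standardize = FALSE)
    b <- as.matrix(fit$beta)
    if (ncol(b) < nl) {  # pad if the solver stopped early
      b <- cbind(b, b[, rep(ncol(b), nl - ncol(b)), drop = FALSE])
    }
    coefs[-i, i, ] <- b[, seq_len(nl)]
    adj[-i, i, ] <- b[, seq_len(nl)] != 0
  }
  list(adj = adj, coefs = coefs)
}

#' Sparse neighborhood-selection network with StARS model selection
#'
#' The SPIEC-EASI-style "mb" graph: CLR-transform the counts, regress
#' each OTU on all others with an L1 penalty along a geometric lambda
#' path from lambda_max (the smallest penalty yielding all-empty
#' neighborhoods) down to `lambda_max * lambda_min_ratio`, and pick the
#' penalty by StARS stability selection: over `n_reps` random
#' subsamples, compute per-lambda mean edge instability
#' 2 theta (1 - theta) and select the densest lambda whose monotonized
#' (running-supremum along the path) instability stays at or below
#' `beta`. The final adjacency at the selected lambda is symmetrized
#' across the two neighborhood estimates; the edge sign is the sign of
#' the mean of the two regression coefficients.
#'
#' @param x An `otu_table` (>= 3 OTUs; >= 10 samples recommended).
#' @param nlambda Length of the penalty path (default 20).
#' @param lambda_min_ratio Smallest/largest penalty ratio (default 1e-2).
#' @param n_reps StARS subsampling repetitions (default 50).
#' @param beta StARS instability threshold (default 0.05).
#' @param seed Integer seed for the subsamples.
#' @param pseudocount Passed to [clr_transform()].
#' @param sym_rule `"or"` (default) or `"and"` symmetrization of the two
#'   per-node neighborhood estimates.
#' @return List with `result` (a `correlation_result`, method `"mb"`,
#'   carrying `support` and `sign`) and `state` (class `stars_state`:
#'   `lambda_path`, per-lambda `instability`, its running supremum
#'   `instability_sup`, `beta`, `selected_lambda`, `selected_index`,
#'   `subsample_size`, `n_reps`).
#' @export
mb_network <- function(x, nlambda = 20, lambda_min_ratio = 1e-2,
                       n_reps = 50, beta = 0.05, seed = 1L,
                       pseudocount = 1, sym_rule = c("or", "and")) {
  sym_rule <- match.arg(sym_rule)
  stopifnot(nlambda >= 2)
  X <- clr_transform(x, pseudocount)
  n <- nrow(X)
  D <- ncol(X)
  if (D < 3) stop("need at least 3 OTUs")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- abs(crossprod(Xc)) / n
  diag(S) <- 0
  lam_max <- max(S)
  lambda <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                    length.out = nlambda))
  b_sub <- if (n > 144) floor(10 * sqrt(n)) else floor(0.8 * n)
  if (b_sub < 3) {
    warning("too few samples for subsampling; using 0.8 n")
    b_sub <- max(3L, floor(0.8 * n))
  }
  freq <- array(0, c(D, D, nlambda))
  withr::with_seed(seed, {
    for (rep in seq_len(n_reps)) {
      idx <- sample.int(n, b_sub)
      nb <- mb_neighborhoods(X[idx, , drop = FALSE], lambda)
      edge <- nb$adj | aperm(nb$adj, c(2, 1, 3))
      freq <- freq + edge
    }
  })
  theta <- freq / n_reps
  xi <- 2 * theta * (1 - theta)
  n_pairs <- D * (D - 1) / 2
  instab <- apply(xi, 3, function(m) sum(m[upper.tri(m)]) / n_pairs)
  instab_sup <- cummax(instab)  # path runs sparse -> dense
  ok <- which(instab_sup <= beta)
  sel <- if (length(ok) > 0) max(ok) else 1L
  nb_full <- mb_neighborhoods(X, lambda)
  a1 <- nb_full$adj[, , sel]
  support <- if (sym_rule == "or") a1 | t(a1) else a1 & t(a1)
  diag(support) <- FALSE
  csum <- nb_full$coefs[, , sel] + t(nb_full$coefs[, , sel])
  signm <- matrix("", D, D)
  signm[support] <- ifelse(csum[support] >= 0, "+", "-")
  dimnames(support) <- dimnames(signm) <- list(colnames(x$counts),
                                               colnames(x$counts))
  state <- structure(list(lambda_path = lambda, instability = instab,
                          instability_sup = instab_sup, beta = beta,
                          selected_lambda = lambda[sel],
                          selected_index = sel, subsample_size = b_sub,
                          n_reps = n_reps),
                     class = "stars_state")
  list(result = correlation_result("mb", support = support, sign = signm),
       state = state)
}
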