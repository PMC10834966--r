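#' Coefficient of determination between a matrix and its reconstruction
#'
#' `R^2 = 1 - SSE/SST` with `SSE = sum((V - V_R)^2)` and
#' `SST = sum((V - mean(V))^2)`, both over all entries.
#'
#' @param V,V_R numeric matrices of identical shape.
#' @return scalar in `(-Inf, 1]`.
#' @examples
#' compute_r2(matrix(1:4, 2), matrix(c(1, 3, 2, 5), 2))  # 0.8
#' @export
compute_r2 <- function(V, V_R) {
  if (!identical(dim(V), dim(V_R))) stop("V and V_R must have the same shape")
  sst <- sum((V - mean(V))^2)
  if (sst <= 0) stop("V is constant (SST = 0); R^2 undefined")
  1 - sum((V - V_R)^2) / sst
}

#' Gaussian NMF by multiplicative updates
#'
#' Factorizes the non-negative cycle matrix `V` (muscles x time points) into
#' motor modules `W` (muscles x rank) and motor primitives `H`
#' (rank x time points) by alternating multiplicative updates
#' \deqn{H \leftarrow H \odot \frac{W^T V}{W^T W H}, \qquad
#'       W \leftarrow W \odot \frac{V H^T}{W H H^T}}
#' (element-wise products and divisions; a small epsilon guards the
#' denominators). `W` and `H` are initialized i.i.d. uniform from `seed`.
#' Iterations stop when the relative change of the reconstruction R^2
#' across a trailing window of 20 iterations falls below `tol` (0.01\%), or
#' at `max_iter`.
#'
#' For reporting, each column of `W` is scaled to maximum 1 and the inverse
#' scale moved into the rows of `H`, leaving the product `W H` unchanged.
#'
#' @param V non-negative matrix with at least one positive entry.
#' @param r rank (number of synergies), `1 <= r <= nrow(V)`.
#' @param seed integer seed for the random initialization.
#' @param tol relative R^2-change tolerance (default `1e-4`, i.e. 0.01%).
#' @param window trailing window in iterations (default 20).
#' @param max_iter safety cap on iterations (default 10000).
#' @param eps denominator guard (default `1e-12`).
#' @param relative compare R^2 changes relatively (default) or absolutely.
#' @return object of class `"synergy_nmf"`: list with `W`, `H`, `r`, `r2`,
#'   `n_iterations`, `seed` and the per-iteration `r2_trace`.
#' @export
nmf_factorize <- function(V, r, seed = 1L, tol = 1e-4, window = 20L,
                          max_iter = 10000L, eps = 1e-12, relative = TRUE) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be non-negative")
  if (all(V == 0)) stop("V must contain a positive entry")
  m <- nrow(V)
  n <- ncol(V)
  if (r < 1L || r > m) stop("rank must lie in [1, nrow(V)]")
  sst <- sum((V - mean(V))^2)
  with_seed(seed, {
    W <- matrix(runif(m * r), m, r)
    H <- matrix(runif(r * n), r, n)
  })
  trace <- numeric(0)
  it <- 0L
  repeat {
    it <- it + 1L
    WtV <- crossprod(W, V)
    H <- H * WtV / (crossprod(W) %*% H + eps)
    VHt <- tcrossprod(V, H)
    W <- W * VHt / (W %*% tcrossprod(H) + eps)
    r2 <- 1 - sum((V - W %*% H)^2) / sst
    trace[it] <- r2
    if (it >= window + 1L) {
      prev <- trace[it - window]
      delta <- abs(r2 - prev)
      if (relative) delta <- delta / max(abs(prev), eps)
      if (delta < tol) break
    }
    if (it >= max_iter) break
  }
  # move scale so each W column peaks at 1 (product unchanged)
  cmax <- apply(W, 2, max)
  cmax[cmax <= 0] <- 1
  W <- sweep(W, 2, cmax, "/")
  H <- sweep(H, 1, cmax, "*")
  rownames(W) <- rownames(V)
  structure(list(W = W, H = H, r = as.integer(r), r2 = trace[it],
                 n_iterations = it,
                 seed = as.integer(seed), r2_trace = trace),
            class = "synergy_nmf")
}

#' Best factorization over random restarts
#'
#' Repeats [nmf_factorize()] `n_restarts` times (default 5) with restart
#' seeds derived deterministically from `base_seed`, and returns the
#' solution with the highest reconstruction R^2.
#'
#' @inheritParams nmf_factorize
#' @param n_restarts number of random restarts (default 5).
#' @param base_seed integer seed from which the restart seeds are derived.
#' @param ... further arguments to [nmf_factorize()].
#' @return the winning `"synergy_nmf"` object, with an extra `restart_r2`
#'   field holding all restart R^2 values.
#' @export
best_of_restarts <- function(V, r, n_restarts = 5L, base_seed = 1L, ...) {
  if (n_restarts < 1L) stop("n_restarts must be at least 1")
  fits <- lapply(seq_len(n_restarts), function(i) {
    nmf_factorize(V, r, seed = derive_seed(base_seed, r, i), ...)
  })
  r2s <- vapply(fits, `[[`, numeric(1), "r2")
  best <- fits[[which.max(r2s)]]
  best$restart_r2 <- r2s
  best
}

#' Reconstruction-quality curve over candidate ranks
#'
#' Runs [best_of_restarts()] for every rank from 1 to `r_max` and collects
#' the best R^2 per rank. By default `r_max = round(0.75 * m)` (75% of the
#' number of muscles), since extracting as many synergies as muscles would
#' not reduce dimensionality.
#'
#' @inheritParams best_of_restarts
#' @param r_max largest candidate rank; default `round(0.75 * nrow(V))`.
#' @return object of class `"rank_curve"`: list with `ranks`, `r2_values`
#'   and the per-rank `fits`.
#' @export
rank_curve <- function(V, r_max = NULL, n_restarts = 5L, base_seed = 1L,
                       ...) {
  V <- as.matrix(V)
  m <- nrow(V)
  if (is.null(r_max)) r_max <- max(1L, round(0.75 * m))
  if (r_max > m) stop("r_max cannot exceed the number of muscles")
  fits <- lapply(seq_len(r_max), function(r) {
    best_of_restarts(V, r, n_restarts = n_restarts, base_seed = base_seed,
                     ...)
  })
  structure(list(ranks = seq_len(r_max),
                 r2_values = vapply(fits, `[[`, numeric(1), "r2"),
                 fits = fits),
            class = "rank_curve")
}

# Iterative linearity pruning shared by rank selection and cluster-count
# selection: fit y ~ x by least squares; if the mean squared residual is
# below `threshold` stop, otherwise drop the lowest-abscissa point and
# refit, until 2 points remain. Returns the lowest abscissa of the
# surviving (most linear) section.
prune_linear_section <- function(x, y, threshold = 1e-4) {
  if (length(x) < 2L) stop("need at least 2 points")
  while (length(x) > 2L) {
    fit <- lm(y ~ x)
    if (mean(residuals(fit)^2) < threshold) break
    x <- x[-1L]
    y <- y[-1L]
  }
  min(x)
}

#' Select the minimum number of synergies from an R^2 curve
#'
#' Fits a simple linear regression to the R^2-vs-rank curve; if its mean
#' squared error is below `mse_threshold` the curve is considered linear
#' and the lowest remaining rank is returned, otherwise the lowest-rank
#' point is removed and the fit repeated, until two points remain. This
#' finds the most linear (plateau) section of the curve, whose first rank
#' is the minimum number of synergies needed for a satisfactory
#' reconstruction.
#'
#' @param curve a `"rank_curve"` object (or a list with `ranks` and
#'   `r2_values`).
#' @param mse_threshold linearity threshold on the regression MSE
#'   (default `1e-4`).
#' @return the selected rank (integer).
#' @export
select_rank <- function(curve, mse_threshold = 1e-4) {
  as.integer(prune_linear_section(curve$ranks, curve$r2_values,
                                  mse_threshold))
}

#' @export
print.rank_curve <- function(x, ...) {
  cat("Rank curve (best-of-restarts R^2):\n")
  print(round(stats::setNames(x$r2_values, paste0("r", x$ranks)), 4))
  invisible(x)
}
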