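#' Fit a muscle-synergy model to a cycle matrix
#'
#' The central estimator of the package. Given the non-negative cycle
#' matrix `V` (muscles x time points, typically 11 x 12000 for 60 cycles of
#' 200 points), `synergy_fit()` extracts motor modules and motor primitives
#' by Gaussian non-negative matrix factorization with multiplicative
#' updates and best-of-5 random restarts. When `rank` is `NULL`, candidate
#' ranks 1 to `round(0.75 * m)` are fitted and the minimum number of
#' synergies is chosen by the linearity-pruning rule on the R^2 curve
#' ([select_rank()]).
#'
#' @param V non-negative matrix, or an `"emg_cycles"` tensor (its matrix
#'   view is used).
#' @param rank number of synergies; `NULL` (default) selects it from the
#'   R^2-vs-rank curve.
#' @param r_max largest candidate rank when `rank` is `NULL`.
#' @param n_restarts random restarts per rank (default 5).
#' @param seed master seed for all restarts.
#' @param n_points points per cycle used by downstream per-cycle methods
#'   (default 200).
#' @param ... further arguments to [nmf_factorize()] (`tol`, `window`,
#'   `max_iter`, ...).
#' @return object of class `"synergy_fit"` with components `W` (muscles x
#'   rank, column max 1), `H` (rank x time), `rank`, `r2`, `curve` (the
#'   `"rank_curve"` when rank selection ran, else `NULL`), `V`, `n_points`,
#'   `seed`.
#' @seealso [primitive_metrics()], [fractal_metrics()],
#'   [co_contribution_index()], [classify_synergies()]
#' @examples
#' rec <- generate_recording(default_truth(n_cycles = 20, seed = 2))
#' pp <- preprocess_recording(rec, keep_cycles = 20)
#' fit <- synergy_fit(pp$tensor, rank = 4, seed = 1)
#' fit
#' @export
synergy_fit <- function(V, rank = NULL, r_max = NULL, n_restarts = 5L,
                        seed = 1L, n_points = 200L, ...) {
  if (inherits(V, "emg_cycles")) {
    n_points <- dim(V$values)[2L]
    V <- as.matrix(V)
  }
  V <- as.matrix(V)
  curve <- NULL
  if (is.null(rank)) {
    curve <- rank_curve(V, r_max = r_max, n_restarts = n_restarts,
                        base_seed = seed, ...)
    rank <- select_rank(curve)
    best <- curve$fits[[rank]]
  } else {
    best <- best_of_restarts(V, rank, n_restarts = n_restarts,
                             base_seed = seed, ...)
  }
  structure(list(W = best$W, H = best$H, rank = as.integer(best$r),
                 r2 = best$r2,
                 n_iterations = best$n_iterations,
                 restart_r2 = best$restart_r2, curve = curve, V = V,
                 n_points = as.integer(n_points), seed = as.integer(seed)),
            class = "synergy_fit")
}

#' @export
print.synergy_fit <- function(x, digits = 4, ...) {
  cat("Muscle synergy model (Gaussian NMF)\n")
  cat(sprintf("  %d muscles x %d time points, %d synergies, R^2 = %.*f\n",
              nrow(x$W), ncol(x$H), x$rank, digits, x$r2))
  if (!is.null(x$curve)) {
    cat("  rank selected from R^2 curve: ",
        paste(sprintf("%.3f", x$curve$r2_values), collapse = " "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
summary.synergy_fit <- function(object, ...) {
  pm <- primitive_metrics(object)
  structure(list(fit = object, metrics = pm), class = "summary.synergy_fit")
}

#' @export
print.summary.synergy_fit <- function(x, ...) {
  print(x$fit)
  cat("\nMotor modules (muscle weights):\n")
  print(round(x$fit$W, 3))
  cat("\nPrimitive metrics (cycle average):\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' @export
coef.synergy_fit <- function(object, ...) object$W

#' @export
fitted.synergy_fit <- function(object, ...) object$W %*% object$H

#' @export
residuals.synergy_fit <- function(object, ...) object$V - fitted(object)

#' Predict (reconstruct) muscle activity from a synergy model
#'
#' With `newdata = NULL`, returns the reconstruction `W H` of the training
#' matrix. With a new non-negative matrix (same muscles), the modules `W`
#' are held fixed and new primitives are estimated by running the `H`
#' multiplicative update to convergence, then `W H_new` is returned.
#'
#' @param object a `"synergy_fit"`.
#' @param newdata optional non-negative muscles x time matrix.
#' @param ... passed on (`tol`, `max_iter`).
#' @export
predict.synergy_fit <- function(object, newdata = NULL, tol = 1e-8,
                                max_iter = 2000L, ...) {
  if (is.null(newdata)) return(fitted(object))
  V <- as.matrix(newdata)
  if (any(V < 0)) stop("newdata must be non-negative")
  W <- object$W
  H <- matrix(mean(V) / max(mean(W), 1e-12), nrow = ncol(W), ncol = ncol(V))
  WtW <- crossprod(W)
  WtV <- crossprod(W, V)
  sse_old <- Inf
  for (i in seq_len(max_iter)) {
    H <- H * WtV / (WtW %*% H + 1e-12)
    sse <- sum((V - W %*% H)^2)
    if (abs(sse_old - sse) < tol * max(sse, 1e-12)) break
    sse_old <- sse
  }
  W %*% H
}

#' Simulate new cycle matrices from a fitted synergy model
#'
#' Parametric bootstrap on the reconstruction: each simulated matrix is
#' `W H` plus Gaussian noise matched to the residual standard deviation,
#' clipped at zero to preserve non-negativity.
#'
#' @param object a `"synergy_fit"`.
#' @param nsim number of simulated matrices (default 1).
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `nsim` non-negative matrices shaped like the data.
#' @export
simulate.synergy_fit <- function(object, nsim = 1, seed = 1L, ...) {
  fit <- fitted(object)
  s <- sd(residuals(object))
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      pmax(fit + rnorm(length(fit), sd = s), 0)
    })
  })
}

#' Plot motor modules and motor primitives
#'
#' One row per synergy: muscle-weight bar plot (left) and the cycle-averaged
#' motor primitive on the 200-point grid (right), with the stance/flight
#' boundary marked.
#'
#' @param x a `"synergy_fit"`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.synergy_fit <- function(x, ...) {
  r <- x$rank
  P <- mean_primitives(x)
  op <- par(mfrow = c(r, 2), mar = c(2.5, 3.5, 1.5, 0.5), mgp = c(2, 0.6, 0))
  on.exit(par(op))
  for (s in seq_len(r)) {
    barplot(x$W[, s], las = 2, ylim = c(0, 1), col = "grey40",
            main = paste("Synergy", s), cex.names = 0.7, ...)
    plot(P[s, ], type = "l", lwd = 2, xlab = "cycle point",
         ylab = "activation", main = "")
    abline(v = 100.5, lty = 2, col = "grey60")
  }
  invisible(x)
}

#' Per-cycle motor primitives of one synergy
#'
#' Splits the concatenated primitive row of `H` back into cycles.
#'
#' @param fit a `"synergy_fit"`.
#' @param synergy synergy index.
#' @return numeric matrix, points x cycles.
#' @export
primitive_cycles <- function(fit, synergy) {
  stopifnot(inherits(fit, "synergy_fit"))
  h <- fit$H[synergy, ]
  p <- fit$n_points
  if (length(h) %% p != 0L) stop("primitive length is not a multiple of ",
                                 p)
  matrix(h, nrow = p)
}

#' Cycle-averaged motor primitives
#'
#' @param fit a `"synergy_fit"`.
#' @return matrix, synergies x points.
#' @export
mean_primitives <- function(fit) {
  t(vapply(seq_len(fit$rank),
           function(s) rowMeans(primitive_cycles(fit, s)),
           numeric(fit$n_points)))
}
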