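# Higuchi curve lengths L_k for k in ks; standard normalization with
# floor((n - t0)/k) increments and the (n - 1)/(floor((n - t0)/k) * k)
# correction factor
higuchi_lengths <- function(series, ks) {
  n <- length(series)
  vapply(ks, function(k) {
    lk <- vapply(seq_len(k), function(t0) {
      m <- (n - t0) %/% k
      if (m < 1L) return(NA_real_)
      idx <- t0 + (0:m) * k
      (sum(abs(diff(series[idx]))) * (n - 1) / (m * k)) / k
    }, numeric(1))
    mean(lk, na.rm = TRUE)
  }, numeric(1))
}

#' Higuchi's fractal dimension
#'
#' Measures the local complexity (roughness) of a series: for each
#' subsampling interval `k` from 2 to `k_max`, `k` decimated sub-series are
#' built, their normalized curve lengths averaged into `L_k`, and the HFD
#' is the least-squares slope of `log(L_k)` versus `log(1/k)`. A straight
#' line gives exactly 1; rougher signals give larger values (up to 2 for a
#' curve filling the plane).
#'
#' @param series finite numeric vector, length at least `2 * k_max`.
#' @param k_max largest subsampling interval (default 10).
#' @return scalar HFD, with attributes `k_max`, `log_k` (log(1/k)),
#'   `log_L` and `fit_mse`.
#' @examples
#' higuchi_fd(seq_len(1200))  # ramp: exactly 1
#' @export
higuchi_fd <- function(series, k_max = 10L) {
  n <- length(series)
  if (k_max < 2L) stop("k_max must be at least 2")
  if (n < 2L * k_max) stop("series too short for k_max = ", k_max)
  if (any(!is.finite(series))) stop("series must be finite")
  ks <- 2:k_max
  Lk <- higuchi_lengths(series, ks)
  if (any(Lk <= 0)) stop("constant series: curve length is zero")
  x <- log(1 / ks)
  y <- log(Lk)
  fit <- lm(y ~ x)
  structure(unname(coef(fit)[2L]),
            k_max = as.integer(k_max), log_k = x, log_L = y,
            fit_mse = mean(residuals(fit)^2))
}

#' Select the largest linear Higuchi scale
#'
#' Computes the Higuchi log-log curve up to `k_limit` (capped at half the
#' series length) and returns the largest `k` for which the curve over
#' `2..k` is still linear: the relative fit MSE (regression MSE divided by
#' the variance of the log-lengths) stays below `tol`. When no `k >= 4`
#' satisfies the criterion the pipeline default `default` is returned with
#' a warning.
#'
#' @param series finite numeric vector.
#' @param k_limit upper bound on the candidate scales (default 300).
#' @param tol relative linearity tolerance (default `1e-3`).
#' @param default fallback scale (default 10).
#' @return integer `k_max`.
#' @export
select_kmax <- function(series, k_limit = 300L, tol = 1e-3, default = 10L) {
  n <- length(series)
  k_limit <- min(as.integer(k_limit), n %/% 2L)
  if (k_limit < 4L) stop("series too short to select a scale")
  ks <- 2:k_limit
  Lk <- higuchi_lengths(series, ks)
  y <- log(Lk)
  x <- log(1 / ks)
  for (k in rev(ks)) {
    keep <- ks <= k
    if (sum(keep) < 3L) break
    fit <- lm(y[keep] ~ x[keep])
    rel <- mean(residuals(fit)^2) / max(var(y[keep]), .Machine$double.eps)
    if (rel < tol) return(as.integer(k))
  }
  warning("no linear section found; falling back to k_max = ", default)
  as.integer(default)
}

# rescaled-range curve: prefix windows of length q halving from n to >= 2;
# per window, center, cumulative-sum, range over standard deviation of the
# raw window
rs_curve <- function(series) {
  n <- length(series)
  qs <- integer(0)
  q <- n
  while (q >= 2L) {
    qs <- c(qs, q)
    q <- q %/% 2L
  }
  rs <- vapply(qs, function(q) {
    h <- series[seq_len(q)]
    s <- sd(h)
    if (s == 0) stop("constant prefix window (q = ", q,
                     "): rescaled range undefined")
    y <- cumsum(h - mean(h))
    (max(y) - min(y)) / s
  }, numeric(1))
  list(q = qs, rs = rs)
}

#' Rescaled-range Hurst exponent
#'
#' Measures the global complexity (persistence) of a series by rescaled-
#' range analysis: prefix windows of length `q = n, n/2, n/4, ...` down to
#' 2 are centred and cumulatively summed, the range of the cumulative
#' series is divided by the window's standard deviation, and the Hurst
#' exponent is the least-squares slope of `log(R_q/S_q)` versus `log(q)`
#' over `q` in `[q_min, q_inflex]`. Values above 0.5 indicate persistence,
#' below 0.5 anti-persistence. The raw slope is reported without clipping
#' to `[0, 1]`.
#'
#' @param series numeric vector, `length(series) >= q_inflex`.
#' @param q_min smallest window entering the slope fit (default 2).
#' @param q_inflex largest window entering the slope fit (default 200, the
#'   pipeline's fixed scale; see [select_qinflex()]).
#' @return scalar HE with attributes `q`, `rs` (the full curve),
#'   `q_inflex` and `fit_mse`.
#' @export
hurst_exponent <- function(series, q_min = 2L, q_inflex = 200L) {
  n <- length(series)
  if (n < q_inflex) stop("series shorter than q_inflex = ", q_inflex)
  cv <- rs_curve(series)
  keep <- cv$q >= q_min & cv$q <= q_inflex
  if (sum(keep) < 2L) stop("fewer than 2 windows in [q_min, q_inflex]")
  x <- log(cv$q[keep])
  y <- log(cv$rs[keep])
  fit <- lm(y ~ x)
  structure(unname(coef(fit)[2L]),
            q = cv$q, rs = cv$rs, q_inflex = as.integer(q_inflex),
            fit_mse = mean(residuals(fit)^2))
}

#' Locate the inflexion window of a rescaled-range curve
#'
#' Finds the window length `q` at which the log-log rescaled-range curve
#' changes slope most strongly (maximal discrete curvature, i.e. the
#' largest change of slope between adjacent segments). When the curve is
#' linear throughout (no slope change above `tol`), the largest `q` is
#' returned with a warning.
#'
#' @param q,rs the rescaled-range curve (window lengths and R/S values),
#'   e.g. the `q`/`rs` attributes of [hurst_exponent()].
#' @param tol minimal slope change treated as an inflexion (default 0.05).
#' @return the selected `q_inflex` (integer).
#' @export
select_qinflex <- function(q, rs, tol = 0.05) {
  if (length(q) < 4L) {
    warning("fewer than 4 points; falling back to the largest window")
    return(as.integer(max(q)))
  }
  o <- order(q)
  x <- log(q[o])
  y <- log(rs[o])
  slopes <- diff(y) / diff(x)
  curv <- abs(diff(slopes))
  if (max(curv) < tol) {
    warning("curve linear throughout; falling back to the largest window")
    return(as.integer(max(q)))
  }
  as.integer(q[o][which.max(curv) + 1L])
}

#' Fractal metrics of all primitives of a fitted synergy model
#'
#' Computes Higuchi's fractal dimension and the rescaled-range Hurst
#' exponent of each synergy's full concatenated primitive (all cycles,
#' `n_points * C` samples) — the across-cycle structure is what the Hurst
#' exponent quantifies, so the cycle average is deliberately not used.
#'
#' @param fit a `"synergy_fit"`.
#' @param k_max Higuchi scale (default 10).
#' @param q_inflex rescaled-range fit bound (default 200).
#' @return data.frame with columns `synergy`, `hfd`, `k_max`, `hurst`,
#'   `q_inflex`.
#' @export
fractal_metrics <- function(fit, k_max = 10L, q_inflex = 200L) {
  data.frame(
    synergy = seq_len(fit$rank),
    hfd = vapply(seq_len(fit$rank), function(s) {
      as.numeric(higuchi_fd(fit$H[s, ], k_max = k_max))
    }, numeric(1)),
    k_max = as.integer(k_max),
    hurst = vapply(seq_len(fit$rank), function(s) {
      as.numeric(hurst_exponent(fit$H[s, ], q_inflex = q_inflex))
    }, numeric(1)),
    q_inflex = as.integer(q_inflex))
}
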