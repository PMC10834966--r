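#' Anterior/posterior muscle map of the lower-limb joints
#'
#' For each joint, which of the 11 recorded muscles mobilize it anteriorly
#' and posteriorly: hip — RF vs GM; knee — RF, VL, VM vs STSM, BF; ankle —
#' TA vs GaM, GaL, SOL, PL.
#'
#' @return named list; each element has `anterior` and `posterior` label
#'   vectors.
#' @export
default_joint_map <- function() {
  list(
    hip = list(anterior = "RF", posterior = "GM"),
    knee = list(anterior = c("RF", "VL", "VM"),
                posterior = c("STSM", "BF")),
    ankle = list(anterior = "TA",
                 posterior = c("GaM", "GaL", "SOL", "PL")))
}

#' Co-contribution index of a motor module at a joint
#'
#' `CI = mean(anterior weights) / (mean(anterior) + mean(posterior))`:
#' 1 when only the anterior muscles contribute, 0 when only the posterior
#' muscles contribute, 0.5 when both groups contribute equally. The index
#' is invariant to rescaling the module by any positive constant.
#'
#' @param module_column named numeric vector of non-negative muscle weights
#'   (one column of `W`).
#' @param joint_map joint map as returned by [default_joint_map()].
#' @param joint joint name, one of `names(joint_map)`.
#' @return scalar in `[0, 1]`.
#' @examples
#' w <- c(RF = 0.4, VL = 0.8, VM = 0.6, STSM = 0.6, BF = 0.6)
#' co_contribution_index(w, default_joint_map(), "knee")  # 0.5
#' @export
co_contribution_index <- function(module_column, joint_map = default_joint_map(),
                                  joint) {
  jm <- joint_map[[joint]]
  if (is.null(jm)) stop("unknown joint: ", joint)
  missing <- setdiff(c(jm$anterior, jm$posterior), names(module_column))
  if (length(missing)) {
    stop("module lacks muscle(s): ", paste(missing, collapse = ", "))
  }
  ant <- mean(module_column[jm$anterior])
  post <- mean(module_column[jm$posterior])
  if (ant + post <= 0) stop("both muscle-group means are zero at the ", joint)
  ant / (ant + post)
}

#' Center of activity of a motor primitive
#'
#' Treats the cycle-averaged primitive as a circular mass distribution on
#' the gait cycle (0 deg at touchdown, 360 deg at the next touchdown) and
#' returns the angle of its center of mass:
#' \eqn{A = \sum_t \cos\theta_t \bar H_t}, \eqn{B = \sum_t \sin\theta_t
#' \bar H_t}, with \eqn{\theta_t = 360 (t-1)/p}, and CoA the quadrant-aware
#' arctangent of `(B, A)` mapped to `[0, 360)`.
#'
#' @param mean_primitive non-negative numeric vector (cycle average).
#' @return angle in degrees, in `[0, 360)`.
#' @examples
#' h <- numeric(200); h[101] <- 1
#' center_of_activity(h)  # 180 (start of flight)
#' @export
center_of_activity <- function(mean_primitive) {
  h <- mean_primitive
  if (any(h < 0)) stop("primitive must be non-negative")
  if (all(h == 0)) stop("all-zero primitive has no center of activity")
  p <- length(h)
  theta <- 2 * pi * (seq_len(p) - 1) / p
  A <- sum(cos(theta) * h)
  B <- sum(sin(theta) * h)
  (atan2(B, A) * 180 / pi) %% 360
}

#' Full width at half maximum of a motor primitive
#'
#' After subtracting the minimum, counts the cycle points strictly
#' exceeding half the (min-subtracted) maximum. Invariant to affine
#' amplitude transforms `a * H + b`, `a > 0`.
#'
#' @param mean_primitive numeric vector with `max > min`.
#' @return integer count in `[0, length(mean_primitive)]`.
#' @export
full_width_half_max <- function(mean_primitive) {
  x <- mean_primitive - min(mean_primitive)
  if (max(x) <= 0) stop("constant primitive has no width")
  sum(x > max(x) / 2)
}

# per-cycle half-maximum indicator matrix (points x cycles); each cycle
# uses its own min-subtracted half-maximum, strict ">"
half_max_indicators <- function(per_cycle) {
  per_cycle <- as.matrix(per_cycle)
  apply(per_cycle, 2, function(h) {
    x <- h - min(h)
    if (max(x) <= 0) stop("constant cycle: half maximum undefined")
    x > max(x) / 2
  })
}

#' Per-point half-maximum exceedance frequency
#'
#' For each cycle the min-subtracted half-maximum rule is applied within
#' that cycle; the frequency at a cycle point is the fraction of cycles in
#' which the primitive exceeds its half maximum there.
#'
#' @param per_cycle_primitives numeric matrix, points x cycles (see
#'   [primitive_cycles()]).
#' @return numeric vector (length = points) of frequencies in `[0, 1]`.
#' @export
exceedance_frequency <- function(per_cycle_primitives) {
  rowMeans(half_max_indicators(per_cycle_primitives))
}

#' Per-point overlap frequency of several synergies
#'
#' Overlap occurs at a cycle point, within a cycle, when at least two
#' primitives simultaneously exceed their half maxima. The returned
#' frequency is the fraction of cycles with overlap at each point.
#'
#' @param per_cycle_list list (length >= 2) of points x cycles matrices,
#'   one per synergy, on the same grid.
#' @return numeric vector of frequencies in `[0, 1]`.
#' @export
overlap_frequency <- function(per_cycle_list) {
  if (length(per_cycle_list) < 2L) {
    stop("overlap needs at least two synergies")
  }
  ind <- lapply(per_cycle_list, half_max_indicators)
  d <- dim(ind[[1L]])
  if (!all(vapply(ind, function(x) identical(dim(x), d), logical(1)))) {
    stop("all synergies must share the same points x cycles grid")
  }
  counts <- Reduce(`+`, lapply(ind, function(x) x * 1L))
  rowMeans(counts >= 2L)
}

# number of circular runs of TRUE in the half-max indicator of a cycle
# average; > 1 flags a bimodal primitive
n_half_max_runs <- function(mean_primitive) {
  x <- mean_primitive - min(mean_primitive)
  ind <- x > max(x) / 2
  if (!any(ind)) return(0L)
  if (all(ind)) return(1L)
  # count rising edges on the circle
  prev <- c(ind[length(ind)], ind[-length(ind)])
  sum(ind & !prev)
}

#' Linear metrics of all primitives of a fitted synergy model
#'
#' Computes, per synergy: the center of activity and the FWHM of the
#' cycle-averaged primitive, and the bimodality flag (more than one
#' circular half-maximum run).
#'
#' @param fit a `"synergy_fit"`.
#' @return data.frame with columns `synergy`, `coa_deg`, `fwhm_points`,
#'   `bimodal`.
#' @export
primitive_metrics <- function(fit) {
  P <- mean_primitives(fit)
  data.frame(
    synergy = seq_len(fit$rank),
    coa_deg = apply(P, 1, center_of_activity),
    fwhm_points = apply(P, 1, full_width_half_max),
    bimodal = apply(P, 1, n_half_max_runs) > 1L)
}

#' Co-contribution indices of all modules at all joints
#'
#' @param fit a `"synergy_fit"` whose `W` has muscle row names.
#' @param joint_map see [default_joint_map()].
#' @return data.frame with columns `synergy`, `joint`, `ci`.
#' @export
module_ci <- function(fit, joint_map = default_joint_map()) {
  out <- expand.grid(synergy = seq_len(fit$rank),
                     joint = names(joint_map),
                     stringsAsFactors = FALSE)
  out$ci <- mapply(function(s, j) {
    co_contribution_index(fit$W[, s], joint_map, j)
  }, out$synergy, out$joint)
  out[order(out$synergy), ]
}

#' Exceedance and overlap frequency curves of a fitted model
#'
#' @param fit a `"synergy_fit"`.
#' @return list with `exceedance` (points x synergies matrix) and `overlap`
#'   (length-`n_points` vector; `NULL` for a single synergy).
#' @export
frequency_curves <- function(fit) {
  per_cycle <- lapply(seq_len(fit$rank), function(s) primitive_cycles(fit, s))
  exc <- vapply(per_cycle, exceedance_frequency, numeric(fit$n_points))
  ovl <- if (fit$rank >= 2L) overlap_frequency(per_cycle) else NULL
  list(exceedance = exc, overlap = ovl)
}
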