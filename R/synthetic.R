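#' Build a bump-shaped motor primitive on the 200-point cycle grid
#'
#' A motor primitive is modelled as a sum of Gaussian bumps wrapped circularly
#' on the normalized gait cycle, so activity centred near touchdown spills
#' over the cycle boundary instead of being clipped. The width parameter is
#' the full width at half maximum (FWHM) in cycle points, which makes the
#' generating shape directly comparable to the FWHM metric measured on
#' extracted primitives.
#'
#' @param bumps list of bumps, each a list/vector with elements `center`
#'   (cycle point in `[1, n_points]`), `width` (FWHM in points, in
#'   `[2, n_points - 1]`) and `amplitude` (non-negative peak height).
#' @param n_points number of points on the cycle grid (default 200).
#' @return numeric vector of length `n_points`, non-negative.
#' @examples
#' h <- make_primitive(list(list(center = 50, width = 40, amplitude = 1)))
#' full_width_half_max(h)
#' @export
make_primitive <- function(bumps, n_points = 200L) {
  if (length(bumps) < 1L) stop("at least one bump is required")
  t <- seq_len(n_points)
  out <- numeric(n_points)
  for (b in bumps) {
    b <- as.list(b)
    center <- as.numeric(b$center)
    width <- as.numeric(b$width)
    amp <- as.numeric(b$amplitude)
    if (!is.finite(width) || width <= 0) stop("bump width must be positive")
    if (center < 1 || center > n_points) {
      stop("bump center must lie in [1, ", n_points, "]")
    }
    if (amp < 0) stop("bump amplitude must be non-negative")
    sigma <- width / (2 * sqrt(2 * log(2)))
    # circular distance between grid point and bump center
    d <- abs(t - center)
    d <- pmin(d, n_points - d)
    out <- out + amp * exp(-d^2 / (2 * sigma^2))
  }
  out
}

#' Fractional Gaussian noise by circulant embedding
#'
#' Generates exact zero-mean fractional Gaussian noise (fGn) with Hurst
#' parameter `H` using the Davies–Harte circulant-embedding construction:
#' the fGn autocovariance \eqn{\gamma(k) = (|k+1|^{2H} - 2|k|^{2H} +
#' |k-1|^{2H})/2} is embedded in a circulant matrix whose eigenvalues are
#' obtained by FFT; negative eigenvalues (possible for small `H` at finite
#' `n`) are truncated at zero, a standard practical correction.
#'
#' Used both to drive cycle-to-cycle amplitude persistence in
#' [generate_recording()] and as the calibration oracle for the
#' rescaled-range Hurst estimator ([hurst_exponent()]).
#'
#' @param n series length.
#' @param H Hurst parameter, strictly between 0 and 1.
#' @param seed integer seed; the same seed reproduces the series exactly.
#' @return numeric vector of length `n` with unit marginal variance.
#' @examples
#' x <- make_fgn(4096, H = 0.8, seed = 1)
#' # lag-1 autocorrelation approaches 2^(2 * 0.8 - 1) - 1
#' @export
make_fgn <- function(n, H, seed) {
  if (!is.finite(H) || H <= 0 || H >= 1) stop("H must lie strictly in (0, 1)")
  n <- as.integer(n)
  if (n < 2L) stop("n must be at least 2")
  k <- 0:(n - 1)
  g <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  ev <- Re(fft(c(g, 0, rev(g[-1]))))
  ev[ev < 0] <- 0
  m <- length(ev)
  with_seed(seed, {
    z <- complex(real = rnorm(m), imaginary = rnorm(m))
    Re(fft(sqrt(ev / (2 * m)) * z))[seq_len(n)]
  })
}

#' Ground truth for a synthetic running recording
#'
#' Bundles and validates the generating parameters of a synthetic sEMG
#' recording: the time-invariant motor modules `W` (muscles x synergies,
#' each column scaled to max 1), the bump parameters of each synergy's motor
#' primitive, the number of cycles, the additive noise level, and the target
#' Hurst exponent of the cycle-to-cycle amplitude modulation.
#'
#' @param modules non-negative numeric matrix, muscles x synergies; row names
#'   are taken as muscle names.
#' @param primitives list of length `ncol(modules)`; element `s` is the bump
#'   list for synergy `s` as accepted by [make_primitive()].
#' @param n_cycles number of running cycles to generate.
#' @param noise_sigma additive Gaussian noise s.d. as a fraction of the
#'   clean-signal maximum (default 0).
#' @param persistence_H target Hurst exponent in (0,1) of the per-cycle
#'   amplitude modulation (default 0.5, i.e. memoryless).
#' @param modulation_amp s.d. of the per-cycle multiplicative amplitude
#'   factor around 1 (default 0.1; 0 disables modulation).
#' @param seed master integer seed for all randomness in the recording.
#' @return object of class `"synergy_truth"`.
#' @export
synthetic_truth <- function(modules, primitives, n_cycles = 60L,
                            noise_sigma = 0, persistence_H = 0.5,
                            modulation_amp = 0.1, seed = 1L) {
  modules <- as.matrix(modules)
  if (any(modules < 0)) stop("module weights must be non-negative")
  if (length(primitives) != ncol(modules)) {
    stop("need one primitive bump list per module column")
  }
  cmax <- apply(modules, 2, max)
  if (any(cmax <= 0)) stop("every module column needs a positive weight")
  modules <- sweep(modules, 2, cmax, "/")
  if (is.null(rownames(modules))) {
    rownames(modules) <- paste0("m", seq_len(nrow(modules)))
  }
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stop("n_cycles must be at least 1")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (persistence_H <= 0 || persistence_H >= 1) {
    stop("persistence_H must lie strictly in (0, 1)")
  }
  structure(
    list(modules = modules, primitives = primitives, n_cycles = n_cycles,
         noise_sigma = noise_sigma, persistence_H = persistence_H,
         modulation_amp = modulation_amp, seed = as.integer(seed)),
    class = "synergy_truth")
}

#' Canonical four-synergy ground truth
#'
#' A preset emulating the modular organization commonly reported for human
#' running: a braking synergy (knee extensors, early stance), a push-off
#' synergy (plantarflexors, late stance), an early-flight synergy (ankle
#' dorsiflexor) and a late-flight synergy (hamstrings and gluteus) over the
#' 11 routinely recorded lower-limb muscles.
#'
#' @param n_cycles,noise_sigma,persistence_H,modulation_amp,seed passed to
#'   [synthetic_truth()].
#' @param bimodal_s4 if `TRUE` the late-flight primitive gets a second bump
#'   near touchdown, emulating a bimodal fourth synergy.
#' @return a `"synergy_truth"` object with 11 muscles and 4 synergies.
#' @export
default_truth <- function(n_cycles = 60L, noise_sigma = 0.05,
                          persistence_H = 0.5, modulation_amp = 0.1,
                          seed = 1L, bimodal_s4 = FALSE) {
  muscles <- c("TA", "GaM", "GaL", "SOL", "PL", "VM", "VL", "RF", "BF",
               "STSM", "GM")
  W <- matrix(0, nrow = 11, ncol = 4, dimnames = list(muscles, NULL))
  W[c("VM", "VL", "RF", "GM", "TA"), 1] <- c(0.90, 1.00, 0.70, 0.40, 0.25)
  W[c("GaM", "GaL", "SOL", "PL"), 2] <- c(1.00, 0.80, 0.90, 0.70)
  W[c("TA", "RF", "PL"), 3] <- c(1.00, 0.45, 0.20)
  W[c("BF", "STSM", "GM", "TA"), 4] <- c(0.90, 1.00, 0.55, 0.35)
  prim <- list(
    list(list(center = 30, width = 45, amplitude = 1)),    # braking
    list(list(center = 70, width = 45, amplitude = 1)),    # push-off
    list(list(center = 120, width = 40, amplitude = 1)),   # early flight
    list(list(center = 180, width = 35, amplitude = 1)))   # late flight
  if (bimodal_s4) {
    # two clearly separated lobes: the late-flight bump is narrowed so the
    # trough between it and the touchdown bump falls below half maximum
    prim[[4]] <- list(list(center = 175, width = 22, amplitude = 1),
                      list(center = 25, width = 22, amplitude = 0.8))
  }
  synthetic_truth(W, prim, n_cycles = n_cycles, noise_sigma = noise_sigma,
                  persistence_H = persistence_H,
                  modulation_amp = modulation_amp, seed = seed)
}

#' Generate a synthetic force + sEMG running recording
#'
#' Renders the ground truth into synchronized signals: a ground-reaction
#' force trace made of half-sine stance pulses (peak ~1.5 kN) separated by
#' zero-force flight phases, and envelope-level sEMG obtained as
#' `V = W H` where each cycle's primitive is scaled by a multiplicative
#' amplitude factor `1 + modulation_amp * fGn(persistence_H)` and additive
#' truncated Gaussian noise is applied. Stance occupies the first 100 and
#' flight the last 100 points of each cycle, mapped onto wall-clock time via
#' the stance/flight durations. The recording starts exactly at the first
#' touchdown and ends at the end of the last flight phase.
#'
#' @param truth a `"synergy_truth"` object.
#' @param emg_rate sEMG sampling rate in Hz (default 2000).
#' @param force_rate force sampling rate in Hz (default 100).
#' @param stance_time stance-phase duration in seconds (default 0.20).
#' @param flight_time flight-phase duration in seconds (default 0.15).
#' @param peak_force stance peak force in Newtons (default 1500).
#' @param lead_time zero-force lead-in in seconds before the first
#'   touchdown (default 0.05), so the first upward threshold crossing is
#'   observable.
#' @return object of class `"synergy_recording"`: list with `emg` (muscles x
#'   samples matrix), `force` (numeric vector), `emg_rate`, `force_rate`,
#'   `muscle_names`, `cycle_boundaries` (force-sample touchdown/toe-off
#'   indices) and `truth`.
#' @export
generate_recording <- function(truth, emg_rate = 2000, force_rate = 100,
                               stance_time = 0.20, flight_time = 0.15,
                               peak_force = 1500, lead_time = 0.05) {
  stopifnot(inherits(truth, "synergy_truth"))
  W <- truth$modules
  r <- ncol(W)
  C <- truth$n_cycles
  n_st_f <- round(stance_time * force_rate)
  n_fl_f <- round(flight_time * force_rate)
  n_st_e <- round(stance_time * emg_rate)
  n_fl_e <- round(flight_time * emg_rate)
  if (n_st_f < 2 || n_fl_f < 2) stop("phases too short for the force rate")

  lead_f <- round(lead_time * force_rate)
  lead_e <- round(lead_time * emg_rate)

  # force: half-sine stance pulse, zero-force flight
  pulse <- peak_force * sin(pi * (seq_len(n_st_f) - 0.5) / n_st_f)
  force <- c(numeric(lead_f), rep(c(pulse, numeric(n_fl_f)), C))
  per_cycle_f <- n_st_f + n_fl_f
  touchdowns <- 1L + lead_f + per_cycle_f * (seq_len(C) - 1L)
  toeoffs <- touchdowns + n_st_f

  # per-cycle primitive amplitude modulation (fGn-driven persistence)
  base <- vapply(truth$primitives, make_primitive, numeric(200))  # 200 x r
  if (truth$modulation_amp > 0 && C >= 2) {
    fac <- vapply(seq_len(r), function(s) {
      g <- make_fgn(max(C, 16L), truth$persistence_H,
                    derive_seed(truth$seed, 101L, s))[seq_len(C)]
      pmax(1 + truth$modulation_amp * g, 0)
    }, numeric(C))                                               # C x r
  } else {
    fac <- matrix(1, nrow = C, ncol = r)
  }

  # envelope-level EMG on the wall-clock grid; each cycle's 200-point curve
  # is linearly interpolated so that stance samples map to points [1, 101)
  # and flight samples to points [101, 201)
  u_st <- 1 + (seq_len(n_st_e) - 1) / n_st_e * 100
  u_fl <- 101 + (seq_len(n_fl_e) - 1) / n_fl_e * 100
  u <- c(u_st, u_fl)
  m <- nrow(W)
  emg <- matrix(0, nrow = m, ncol = (n_st_e + n_fl_e) * C,
                dimnames = list(rownames(W), NULL))
  per_cycle_e <- n_st_e + n_fl_e
  for (ci in seq_len(C)) {
    Hc <- base * rep(fac[ci, ], each = 200)                      # 200 x r
    Vc <- W %*% t(Hc)                                            # m x 200
    # wrap point 201 to the first point of the cycle for interpolation
    cols <- (ci - 1L) * per_cycle_e + seq_len(per_cycle_e)
    for (mu in seq_len(m)) {
      emg[mu, cols] <- approx(x = 1:201, y = c(Vc[mu, ], Vc[mu, 1]),
                              xout = u)$y
    }
  }
  if (lead_e > 0) {
    # periodic continuation: the lead-in shows the tail of the flight phase
    emg <- cbind(emg[, seq.int(per_cycle_e - lead_e + 1L, per_cycle_e),
                     drop = FALSE], emg)
  }
  if (truth$noise_sigma > 0) {
    sd_noise <- truth$noise_sigma * max(emg)
    noise <- with_seed(derive_seed(truth$seed, 202L),
                       rnorm(length(emg), sd = sd_noise))
    emg <- pmax(emg + noise, 0)
  }
  structure(
    list(emg = emg, force = force, emg_rate = emg_rate,
         force_rate = force_rate, muscle_names = rownames(W),
         cycle_boundaries = list(touchdown = touchdowns, toeoff = toeoffs),
         truth = truth),
    class = "synergy_recording")
}

#' @export
print.synergy_recording <- function(x, ...) {
  cat("Synthetic running recording\n")
  cat(sprintf("  %d muscles x %d sEMG samples @ %g Hz\n", nrow(x$emg),
              ncol(x$emg), x$emg_rate))
  cat(sprintf("  force: %d samples @ %g Hz, %d cycles\n", length(x$force),
              x$force_rate, x$truth$n_cycles))
  invisible(x)
}

#' Write a recording to delimited text files
#'
#' Writes the same delimited-text format that [read_recording()] loads:
#' `emg.csv` (column `time_s` plus one column per muscle), `force.csv`
#' (`time_s`, `force_n`), `meta.yaml` (sampling rates, muscle order,
#' condition label) and, for synthetic recordings, `truth.yaml` with the
#' generating parameters.
#'
#' @param recording a `"synergy_recording"` object.
#' @param dir output directory (created if needed).
#' @param condition condition label stored in the metadata.
#' @return `dir`, invisibly.
#' @export
write_recording <- function(recording, dir, condition = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emg <- data.frame(time_s = (seq_len(ncol(recording$emg)) - 1) /
                      recording$emg_rate,
                    t(recording$emg), check.names = FALSE)
  write.csv(emg, file.path(dir, "emg.csv"), row.names = FALSE)
  force <- data.frame(time_s = (seq_len(length(recording$force)) - 1) /
                        recording$force_rate,
                      force_n = recording$force)
  write.csv(force, file.path(dir, "force.csv"), row.names = FALSE)
  meta <- list(emg_rate = recording$emg_rate,
               force_rate = recording$force_rate,
               muscles = as.list(recording$muscle_names),
               condition = condition)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  if (!is.null(recording$truth)) {
    tr <- recording$truth
    yaml::write_yaml(
      list(modules = apply(tr$modules, 2, as.list),
           muscles = as.list(rownames(tr$modules)),
           primitives = tr$primitives, n_cycles = tr$n_cycles,
           noise_sigma = tr$noise_sigma, persistence_H = tr$persistence_H,
           modulation_amp = tr$modulation_amp, seed = tr$seed),
      file.path(dir, "truth.yaml"))
  }
  invisible(dir)
}

#' Read a recording from delimited text files
#'
#' @param dir directory written by [write_recording()] (or hand-assembled in
#'   the same layout).
#' @return a `"synergy_recording"` object; `truth` is `NULL` when no
#'   `truth.yaml` sidecar is present.
#' @export
read_recording <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  emg_df <- read.csv(file.path(dir, "emg.csv"), check.names = FALSE)
  force_df <- read.csv(file.path(dir, "force.csv"))
  muscles <- unlist(meta$muscles)
  missing <- setdiff(muscles, names(emg_df))
  if (length(missing)) {
    stop("emg.csv lacks muscle column(s): ", paste(missing, collapse = ", "))
  }
  emg <- t(as.matrix(emg_df[, muscles, drop = FALSE]))
  if (any(!is.finite(emg)) || any(!is.finite(force_df$force_n))) {
    stop("non-finite samples in input files")
  }
  truth <- NULL
  tf <- file.path(dir, "truth.yaml")
  if (file.exists(tf)) {
    ty <- yaml::read_yaml(tf)
    W <- do.call(cbind, lapply(ty$modules, unlist))
    rownames(W) <- unlist(ty$muscles)
    truth <- synthetic_truth(W, ty$primitives, n_cycles = ty$n_cycles,
                             noise_sigma = ty$noise_sigma,
                             persistence_H = ty$persistence_H,
                             modulation_amp = ty$modulation_amp,
                             seed = ty$seed)
  }
  structure(
    list(emg = emg, force = force_df$force_n, emg_rate = meta$emg_rate,
         force_rate = meta$force_rate, muscle_names = muscles,
         cycle_boundaries = NULL, truth = truth,
         condition = meta$condition),
    class = "synergy_recording")
}
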