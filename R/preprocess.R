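#' Detect touchdown and toe-off from the vertical ground-reaction force
#'
#' A touchdown is reported at the first force sample at-or-above the
#' threshold after the trace was below it; a toe-off at the first sample
#' back below the threshold. Incomplete leading stance phases (trace starts
#' above threshold) and trailing stance phases without a toe-off are
#' dropped, so events always come in alternating touchdown/toe-off pairs.
#'
#' @param force non-negative numeric vector (Newtons).
#' @param threshold_N detection threshold in Newtons (default 50).
#' @param rate force sampling rate in Hz; only needed when `debounce_s > 0`.
#' @param debounce_s stance or flight segments shorter than this duration
#'   are treated as threshold chatter and merged away (default 0, disabled).
#' @return object of class `"gait_events"`: list with integer vectors
#'   `touchdown` and `toeoff` of equal length.
#' @examples
#' f <- c(rep(0, 36), rep(100, 20), rep(0, 15))
#' detect_gait_events(f)$touchdown  # 37
#' @export
detect_gait_events <- function(force, threshold_N = 50, rate = NULL,
                               debounce_s = 0) {
  if (length(force) < 2L) stop("force trace too short")
  if (any(!is.finite(force))) stop("non-finite force samples")
  above <- force >= threshold_N
  if (!any(above) || all(above)) {
    stop("force never crosses the ", threshold_N, " N threshold")
  }
  d <- diff(above)
  td <- which(d == 1L) + 1L   # first sample at-or-above
  to <- which(d == -1L) + 1L  # first sample below again
  to <- to[to > if (length(td)) td[1L] else Inf]
  n <- min(length(td), length(to))
  if (n == 0L) stop("force never completes a stance phase")
  td <- td[seq_len(n)]
  to <- to[seq_len(n)]
  if (debounce_s > 0) {
    if (is.null(rate)) stop("debouncing needs the sampling rate")
    min_gap <- round(debounce_s * rate)
    repeat {
      flight <- if (length(td) > 1L) td[-1L] - to[-length(to)] else integer()
      short_fl <- which(flight < min_gap)
      if (length(short_fl)) {      # merge chattering stance phases
        i <- short_fl[1L]
        to <- to[-i]
        td <- td[-(i + 1L)]
        next
      }
      short_st <- which(to - td < min_gap)
      if (length(short_st)) {      # drop spuriously short stance
        i <- short_st[1L]
        td <- td[-i]
        to <- to[-i]
        next
      }
      break
    }
    if (length(td) == 0L) stop("all events removed by debouncing")
  }
  structure(list(touchdown = td, toeoff = to), class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("Gait events: %d stance phases (touchdown -> toe-off)\n",
              length(x$touchdown)))
  invisible(x)
}

#' Spatiotemporal parameters of running
#'
#' Per complete cycle: stance time (touchdown to toe-off), flight time
#' (toe-off to next touchdown) and stride frequency (reciprocal of the
#' stance + flight period). A cycle is complete when its next touchdown was
#' observed, so `n - 1` rows are returned for `n` stance phases.
#'
#' @param events a `"gait_events"` object.
#' @param rate force sampling rate in Hz.
#' @return data.frame with columns `cycle`, `stance_time`, `flight_time`,
#'   `stride_frequency` (s, s, Hz).
#' @export
spatiotemporal_params <- function(events, rate) {
  stopifnot(inherits(events, "gait_events"))
  n <- length(events$touchdown)
  if (n < 2L) stop("at least 2 complete cycles are required")
  i <- seq_len(n - 1L)
  stance <- (events$toeoff[i] - events$touchdown[i]) / rate
  flight <- (events$touchdown[i + 1L] - events$toeoff[i]) / rate
  data.frame(cycle = i, stance_time = stance, flight_time = flight,
             stride_frequency = 1 / (stance + flight))
}

#' sEMG envelope extraction
#'
#' Applies the standard running-sEMG conditioning cascade to each muscle
#' channel: 4th-order Butterworth band-pass (10–500 Hz), 4th-order
#' Butterworth high-pass (50 Hz), full-wave rectification, then a 4th-order
#' Butterworth low-pass (20 Hz). Every filter is applied forward and
#' backward (zero-phase). Occasional small negative excursions of the final
#' low-pass are clipped at zero so the envelope is non-negative.
#'
#' @param raw_emg numeric matrix, muscles in rows, samples in columns (a
#'   vector is treated as one muscle).
#' @param rate sampling rate in Hz; must exceed 1000 Hz so the 500 Hz band
#'   edge is below Nyquist.
#' @return matrix of the same shape holding the non-negative envelope.
#' @export
filter_emg <- function(raw_emg, rate) {
  if (rate <= 1000) stop("sampling rate must exceed 1000 Hz")
  if (is.vector(raw_emg)) raw_emg <- matrix(raw_emg, nrow = 1L)
  if (any(!is.finite(raw_emg))) stop("non-finite sEMG samples")
  nyq <- rate / 2
  bp <- signal::butter(4, c(10, 500) / nyq, type = "pass")
  hp <- signal::butter(4, 50 / nyq, type = "high")
  lp <- signal::butter(4, 20 / nyq, type = "low")
  out <- raw_emg
  for (i in seq_len(nrow(raw_emg))) {
    x <- signal::filtfilt(bp, raw_emg[i, ])
    x <- signal::filtfilt(hp, x)
    x <- abs(x)
    x <- signal::filtfilt(lp, x)
    out[i, ] <- pmax(x, 0)
  }
  out
}

#' Min-max amplitude normalization per muscle
#'
#' Subtracts each muscle's minimum and divides by its maximum so every
#' channel spans exactly `[0, 1]` within the condition being analysed.
#'
#' @param envelope muscles x samples matrix (or an [emg_cycles] tensor, in
#'   which case each muscle is normalized over all points and cycles).
#' @return object of the same class with per-muscle values in `[0, 1]`.
#' @export
normalize_amplitude <- function(envelope) UseMethod("normalize_amplitude")

#' @export
normalize_amplitude.default <- function(envelope) {
  env <- as.matrix(envelope)
  mins <- apply(env, 1, min)
  maxs <- apply(env, 1, max)
  flat <- maxs - mins <= 0
  if (any(flat)) {
    nm <- rownames(env)[flat]
    if (is.null(nm)) nm <- which(flat)
    stop("constant (degenerate) channel(s): ", paste(nm, collapse = ", "))
  }
  sweep(sweep(env, 1, mins, "-"), 1, maxs - mins, "/")
}

#' @export
normalize_amplitude.emg_cycles <- function(envelope) {
  v <- envelope$values
  m <- dim(v)[1L]
  for (i in seq_len(m)) {
    x <- v[i, , ]
    rng <- range(x)
    if (diff(rng) <= 0) {
      stop("constant (degenerate) channel: ", dimnames(v)[[1L]][i])
    }
    v[i, , ] <- (x - rng[1L]) / diff(rng)
  }
  envelope$values <- v
  envelope
}

#' Time-normalize an envelope onto the 200-point cycle grid
#'
#' Each stance phase (touchdown to toe-off) is resampled by linear
#' interpolation to 100 points and each flight phase (toe-off to next
#' touchdown) to 100 points, giving 200 points per cycle with point 1 at
#' touchdown. Phases are treated as half-open intervals so the grid tiles
#' the cycle without duplicating boundary samples. If the signal ends
#' during the final flight phase, the end of the recording is used as that
#' cycle's closing boundary (relevant for recordings trimmed at a full
#' cycle).
#'
#' @param envelope muscles x samples matrix on the sEMG timebase.
#' @param events `"gait_events"` on the force timebase.
#' @param emg_rate,force_rate sampling rates in Hz.
#' @param n_stance,n_flight points per phase (defaults 100 and 100).
#' @return an object of class `"emg_cycles"`: list with `values`
#'   (muscles x 200 x cycles array), `n_stance`, `muscle_names`.
#' @export
time_normalize <- function(envelope, events, emg_rate, force_rate,
                           n_stance = 100L, n_flight = 100L) {
  stopifnot(inherits(events, "gait_events"))
  if (is.vector(envelope)) envelope <- matrix(envelope, nrow = 1L)
  n_samp <- ncol(envelope)
  # force-sample index -> (fractional) emg-sample position
  pos <- function(idx) (idx - 1) / force_rate * emg_rate + 1
  td <- pos(events$touchdown)
  to <- pos(events$toeoff)
  C <- length(td)
  if (C < 1L) stop("no complete cycles")
  ends <- c(td[-1L], n_samp + 1)  # exclusive end of each flight phase
  if (max(to) > n_samp + 1 || ends[C] > n_samp + 1) {
    stop("events fall outside the sEMG span")
  }
  m <- nrow(envelope)
  vals <- array(NA_real_, dim = c(m, n_stance + n_flight, C),
                dimnames = list(rownames(envelope), NULL, NULL))
  xs <- seq_len(n_samp)
  for (ci in seq_len(C)) {
    if (to[ci] - td[ci] < 2 || ends[ci] - to[ci] < 2) {
      stop("stance or flight segment shorter than 2 samples in cycle ", ci)
    }
    u_st <- td[ci] + (seq_len(n_stance) - 1) * (to[ci] - td[ci]) / n_stance
    u_fl <- to[ci] + (seq_len(n_flight) - 1) * (ends[ci] - to[ci]) / n_flight
    u <- c(u_st, u_fl)
    for (mu in seq_len(m)) {
      vals[mu, , ci] <- approx(xs, envelope[mu, ], xout = u, rule = 2)$y
    }
  }
  structure(list(values = vals, n_stance = n_stance,
                 muscle_names = rownames(envelope)),
            class = "emg_cycles")
}

#' @export
print.emg_cycles <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "EMG cycle tensor: %d muscles x %d points x %d cycles (stance 1-%d)\n",
    d[1L], d[2L], d[3L], x$n_stance))
  invisible(x)
}

#' Matrix view of a cycle tensor
#'
#' Concatenates the cycles column-wise into the muscles x (points * cycles)
#' matrix `V` that is factorized by [synergy_fit()].
#'
#' @param x an `"emg_cycles"` object.
#' @param ... unused.
#' @export
as.matrix.emg_cycles <- function(x, ...) {
  d <- dim(x$values)
  out <- matrix(x$values, nrow = d[1L], ncol = d[2L] * d[3L])
  rownames(out) <- dimnames(x$values)[[1L]]
  out
}

#' Keep the last k cycles of a tensor
#'
#' @param tensor an `"emg_cycles"` object with at least `k` cycles.
#' @param k number of trailing cycles to keep (default 60).
#' @return an `"emg_cycles"` object with `k` cycles, order preserved.
#' @export
select_last_cycles <- function(tensor, k = 60L) {
  stopifnot(inherits(tensor, "emg_cycles"))
  C <- dim(tensor$values)[3L]
  if (C < k) stop("only ", C, " cycles available, need ", k)
  tensor$values <- tensor$values[, , seq.int(C - k + 1L, C), drop = FALSE]
  tensor
}

#' Full preprocessing of a recording
#'
#' Runs the conditioning chain on a `"synergy_recording"`: optional envelope
#' extraction ([filter_emg()]), gait-event detection, time normalization to
#' the 200-point grid, selection of the last `k` cycles and per-muscle
#' min-max amplitude normalization over the retained cycles.
#'
#' @param recording a `"synergy_recording"` (from [generate_recording()] or
#'   [read_recording()]).
#' @param filter apply the Butterworth envelope cascade first? Use `FALSE`
#'   for inputs that are already envelope-level (e.g. synthetic data).
#' @param threshold_N force threshold in Newtons (default 50).
#' @param keep_cycles how many trailing cycles to retain (default 60; `NULL`
#'   keeps all).
#' @param normalize apply amplitude normalization (default TRUE).
#' @return list with `tensor` (`"emg_cycles"`), `events` (`"gait_events"`)
#'   and `spatiotemporal` (data.frame).
#' @export
preprocess_recording <- function(recording, filter = FALSE, threshold_N = 50,
                                 keep_cycles = 60L, normalize = TRUE) {
  stopifnot(inherits(recording, "synergy_recording"))
  env <- if (filter) filter_emg(recording$emg, recording$emg_rate) else
    recording$emg
  events <- detect_gait_events(recording$force, threshold_N,
                               rate = recording$force_rate)
  st <- spatiotemporal_params(events, recording$force_rate)
  tensor <- time_normalize(env, events, recording$emg_rate,
                           recording$force_rate)
  if (!is.null(keep_cycles)) tensor <- select_last_cycles(tensor, keep_cycles)
  if (normalize) tensor <- normalize_amplitude(tensor)
  list(tensor = tensor, events = events, spatiotemporal = st)
}
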