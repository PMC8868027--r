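#' Detect action potentials and measure waveform metrics
#'
#' Threshold is the first point where dV/dt reaches `dvdt_threshold`
#' (linearly interpolated) preceding a local maximum that exceeds the
#' threshold voltage by at least `min_peak_above` mV (noise-blip
#' rejection). Per event: base width (time between rising and falling
#' crossings of the threshold voltage), amplitude (peak minus
#' threshold), repolarization duration (peak to falling crossing), AHP
#' amplitude (threshold voltage minus the post-spike minimum within
#' `ahp_window` ms, bounded by the next AP) and AHP duration (falling
#' crossing until recovery to the threshold voltage, bounded by the
#' next AP onset).
#'
#' @param sweep A [sweep_trace()] with a voltage channel sampled at
#'   `dt <= 0.1` ms.
#' @param dvdt_threshold Detection slope criterion (mV/ms).
#' @param min_peak_above Minimum peak height above threshold (mV).
#' @param ahp_window AHP search window after the spike (ms).
#' @param slope_span_ms Span of the backward-difference slope estimate
#'   (ms); `NULL` (default) adapts it to the trace's noise level so
#'   the per-sample derivative stays usable at 50 kHz.
#' @return Data frame of class `"ap_events"`, one row per AP:
#'   `threshold_time`, `threshold_voltage`, `peak_time`,
#'   `peak_voltage`, `end_time`, `width`, `amplitude`,
#'   `repol_duration`, `ahp_amplitude`, `ahp_duration` (times s,
#'   durations ms, voltages mV).
#' @export
detect_aps <- function(sweep, dvdt_threshold = 10, min_peak_above = 10,
                       ahp_window = 100, slope_span_ms = NULL) {
  stopifnot(inherits(sweep, "sweep_trace"))
  if (is.null(sweep$voltage)) stop("no voltage channel")
  if (sweep$dt > 1e-4 + 1e-12) stop("dt too coarse for AP detection")
  t <- sweep_times(sweep)
  dt_ms <- sweep$dt * 1000
  v <- sweep$voltage
  if (is.null(slope_span_ms)) {
    # span such that the slope estimate's noise SD stays well under
    # the detection criterion (sigma * sqrt(2) / span <= 2.5 mV/ms)
    sigma <- stats::mad(diff(v)) / sqrt(2)
    slope_span_ms <- min(0.2, sigma * sqrt(2) / 2.5)
  }
  k <- max(1L, round(slope_span_ms / dt_ms))
  dvdt <- c(rep(0, k), (v[-seq_len(k)] - v[seq_len(length(v) - k)])) /
    (k * dt_ms)
  up <- which(dvdt[-1] >= dvdt_threshold & dvdt[-length(dvdt)] <
                dvdt_threshold) + 1L
  empty <- data.frame(threshold_time = numeric(0),
                      threshold_voltage = numeric(0),
                      peak_time = numeric(0), peak_voltage = numeric(0),
                      end_time = numeric(0), width = numeric(0),
                      amplitude = numeric(0),
                      repol_duration = numeric(0),
                      ahp_amplitude = numeric(0),
                      ahp_duration = numeric(0))
  class(empty) <- c("ap_events", "data.frame")
  if (!length(up)) return(empty)
  n <- length(v)
  peak_win <- round(8 / dt_ms)     # threshold-to-peak search window
  min_fall <- 8                    # required post-peak drop (mV)
  # pass 1: candidate events (threshold, peak, threshold crossings)
  cand <- list()
  last_end_idx <- 0L
  look <- max(1L, round(0.3 / dt_ms))  # peak-climb lookahead
  for (i in up) {
    if (i <= last_end_idx) next
    # climb from the anchor past noise-scale apexes to the first local
    # peak (a bounded-window argmax could skip to a later, taller AP)
    peak_idx <- i
    repeat {
      ahead <- (peak_idx + 1):min(peak_idx + look, n)
      if (peak_idx >= n - 1 || max(v[ahead]) <= v[peak_idx]) break
      peak_idx <- ahead[which.max(v[ahead])]
    }
    if (peak_idx - i > peak_win) next  # runaway ramp, not an AP
    # threshold: walk back from the steep rise to where dV/dt falls
    # below the criterion
    seg <- max(i - 1, 1):peak_idx
    mx <- max(dvdt[seg])
    # a genuine upstroke clearly exceeds the detection criterion;
    # noise riding on slow ramps (e.g. AHP recovery) does not
    if (mx < 1.5 * dvdt_threshold) next
    # anchor at the upstroke maximum, then walk back to where dV/dt
    # first drops below the criterion
    m <- seg[which.max(dvdt[seg])]
    while (m > 1 && dvdt[m - 1] >= dvdt_threshold) m <- m - 1
    f <- if (dvdt[m] != dvdt[m - 1])
      (dvdt_threshold - dvdt[m - 1]) / (dvdt[m] - dvdt[m - 1]) else 0
    f <- min(1, max(0, f))
    thr_t <- t[m - 1] + f * sweep$dt
    thr_v <- v[m - 1] + f * (v[m] - v[m - 1])
    if (v[peak_idx] < thr_v + min_peak_above) next
    # must actually fall after the peak (rejects charging plateaus)
    after <- peak_idx:min(peak_idx + peak_win, n)
    if (min(v[after]) > v[peak_idx] - min_fall) next
    # falling crossing of the threshold voltage
    k <- peak_idx
    kmax <- min(peak_idx + round(ahp_window / dt_ms), n - 1L)
    while (k < kmax && v[k + 1] > thr_v) k <- k + 1
    fall_t <- cross_time(t, v, k, thr_v)
    # rising crossing of the threshold voltage (walk back from peak)
    m <- peak_idx
    while (m > 1 && v[m - 1] > thr_v) m <- m - 1
    rise_t <- if (m > 1) cross_time(t, v, m - 1, thr_v) else thr_t
    cand[[length(cand) + 1]] <- list(
      thr_t = thr_t, thr_v = thr_v, peak_idx = peak_idx,
      fall_idx = k, fall_t = fall_t, rise_t = rise_t)
    last_end_idx <- k
  }
  if (!length(cand)) return(empty)
  # pass 2: AHP metrics bounded by the next accepted event
  events <- vector("list", length(cand))
  for (e in seq_along(cand)) {
    cd <- cand[[e]]
    next_onset <- if (e < length(cand))
      which(t >= cand[[e + 1]]$thr_t)[1] - 1L else n
    lim <- min(cd$fall_idx + round(ahp_window / dt_ms), next_onset, n)
    ahp_amp <- ahp_dur <- NA_real_
    end_idx <- cd$fall_idx
    if (lim > cd$fall_idx + 1) {
      seg <- (cd$fall_idx + 1):lim
      min_i <- seg[which.min(v[seg])]
      ahp_amp <- cd$thr_v - v[min_i]
      rec <- if (min_i < lim)
        min_i + which(v[(min_i + 1):lim] >= cd$thr_v) else integer(0)
      if (length(rec)) {
        rec_t <- cross_time(t, v, rec[1] - 1L, cd$thr_v)
        ahp_dur <- (rec_t - cd$fall_t) * 1000
        end_idx <- rec[1]
      } else {
        ahp_dur <- (t[lim] - cd$fall_t) * 1000
        end_idx <- lim
      }
      if (ahp_amp <= 0) { ahp_amp <- NA_real_; ahp_dur <- NA_real_ }
    }
    events[[e]] <- data.frame(
      threshold_time = cd$thr_t, threshold_voltage = cd$thr_v,
      peak_time = t[cd$peak_idx], peak_voltage = v[cd$peak_idx],
      end_time = t[end_idx],
      width = (cd$fall_t - cd$rise_t) * 1000,
      amplitude = v[cd$peak_idx] - cd$thr_v,
      repol_duration = (cd$fall_t - t[cd$peak_idx]) * 1000,
      ahp_amplitude = ahp_amp, ahp_duration = ahp_dur)
  }
  out <- do.call(rbind, events)
  class(out) <- c("ap_events", "data.frame")
  out
}

#' Firing-frequency versus injected current (F-I curve)
#'
#' Counts APs within the step window of each sweep of a long-step
#' family; with the standard 1-s steps the count equals the rate in Hz.
#'
#' @param sweepset A long-step [sweep_set()].
#' @param ... Passed to [detect_aps()].
#' @return Data frame with `current` (pA) and `rate` (Hz), ordered by
#'   amplitude.
#' @export
fi_curve <- function(sweepset, ...) {
  stopifnot(inherits(sweepset, "sweep_set"))
  prot <- sweepset$protocol
  if (prot$kind != "long_step") stop("need a long_step protocol")
  dur <- prot$step_offset - prot$step_onset
  rates <- vapply(sweepset$sweeps, function(sw) {
    ev <- detect_aps(sw, ...)
    sum(ev$threshold_time >= prot$step_onset &
          ev$threshold_time <= prot$step_offset) / dur
  }, numeric(1))
  out <- data.frame(current = prot$step_amplitude, rate = rates)
  out[order(out$current), ]
}

#' Seven clustering features of the firing pattern
#'
#' Computes, on the maximal-firing sweep (highest AP count, ties broken
#' toward the larger current), the seven features used for e-typing:
#' maximal firing rate, adaptation index (mean of normalized
#' consecutive-ISI differences), ISI coefficient of variation
#' (sample SD / mean), accommodation (fractional first-to-last AP
#' amplitude decline) and binary burst, pause and delay flags; plus
#' rheobase (lowest step with at least one AP) and mean waveform
#' metrics for summary tables.
#'
#' Flag rules (configurable): burst if the mean of the first two ISIs
#' is below `burst_factor` times the median ISI with at least four
#' APs; pause if any ISI exceeds `pause_factor` times the median ISI;
#' delay if the first-spike latency at rheobase exceeds
#' `delay_latency_ms`.
#'
#' @param sweepset A long-step [sweep_set()].
#' @param burst_factor,pause_factor,delay_latency_ms Flag thresholds.
#' @param ... Passed to [detect_aps()].
#' @return One-row data frame of class `"cell_features"` (`NA`s and
#'   `firing = FALSE` when no sweep elicits an AP).
#' @export
firing_pattern_features <- function(sweepset, burst_factor = 0.5,
                                    pause_factor = 3,
                                    delay_latency_ms = 100, ...) {
  stopifnot(inherits(sweepset, "sweep_set"))
  prot <- sweepset$protocol
  if (prot$kind != "long_step") stop("need a long_step protocol")
  evs <- lapply(sweepset$sweeps, detect_aps, ...)
  counts <- vapply(evs, function(e)
    sum(e$threshold_time >= prot$step_onset &
          e$threshold_time <= prot$step_offset), numeric(1))
  out <- data.frame(cell_id = sweepset$cell_id, firing = FALSE,
                    max_rate = NA_real_, adaptation_index = NA_real_,
                    isi_cv = NA_real_, accommodation = NA_real_,
                    burst = NA_real_, pause = NA_real_, delay = NA_real_,
                    rheobase = NA_real_, latency_rheobase = NA_real_,
                    ap_width = NA_real_, ap_amplitude = NA_real_,
                    ap_threshold = NA_real_, repol_duration = NA_real_,
                    ahp_amplitude = NA_real_, ahp_duration = NA_real_)
  class(out) <- c("cell_features", "data.frame")
  if (all(counts == 0)) return(out)
  ord <- order(prot$step_amplitude)
  firing <- which(counts > 0)
  rheo_idx <- firing[which.min(prot$step_amplitude[firing])]
  # maximal-firing sweep; ties -> larger current
  best <- which(counts == max(counts))
  best <- best[which.max(prot$step_amplitude[best])]
  ev <- evs[[best]]
  ev <- ev[ev$threshold_time >= prot$step_onset &
             ev$threshold_time <= prot$step_offset, ]
  dur <- prot$step_offset - prot$step_onset
  st <- ev$threshold_time
  isi <- diff(st)
  out$firing <- TRUE
  out$max_rate <- nrow(ev) / dur
  out$adaptation_index <- if (length(isi) >= 2)
    mean(diff(isi) / (isi[-1] + isi[-length(isi)])) else 0
  out$isi_cv <- if (length(isi) >= 2) stats::sd(isi) / mean(isi) else 0
  out$accommodation <- if (nrow(ev) >= 2)
    (ev$amplitude[1] - ev$amplitude[nrow(ev)]) / ev$amplitude[1] else 0
  med <- stats::median(isi)
  out$burst <- as.numeric(length(isi) >= 3 && nrow(ev) >= 4 &&
                            mean(isi[1:2]) < burst_factor * med)
  out$pause <- as.numeric(length(isi) >= 2 && any(isi > pause_factor * med))
  ev_rheo <- evs[[rheo_idx]]
  lat <- (ev_rheo$threshold_time[1] - prot$step_onset) * 1000
  out$delay <- as.numeric(lat > delay_latency_ms)
  out$rheobase <- prot$step_amplitude[rheo_idx]
  out$latency_rheobase <- lat
  for (f in c("width", "amplitude", "repol_duration",
              "ahp_amplitude", "ahp_duration"))
    out[[if (f %in% c("width", "amplitude")) paste0("ap_", f) else f]] <-
      mean(ev[[f]], na.rm = TRUE)
  out$ap_threshold <- mean(ev$threshold_voltage)
  out
}

#' Pulse-train failure rate
#'
#' A pulse fails when no AP threshold crossing occurs within
#' `[pulse onset, onset + pulse width + grace]`.
#'
#' @param sweepset A pulse-train [sweep_set()].
#' @param grace_ms Post-pulse grace period (ms).
#' @param ... Passed to [detect_aps()].
#' @return Data frame with `rate` (Hz), `amplitude` (pA), `n_pulses`,
#'   `n_failures` and `failure_pct` per sweep.
#' @export
failure_rate <- function(sweepset, grace_ms = 3, ...) {
  stopifnot(inherits(sweepset, "sweep_set"))
  prot <- sweepset$protocol
  if (prot$kind != "pulse_train") stop("need a pulse_train protocol")
  period <- 1 / prot$pulse_rate
  onsets <- prot$onset + (seq_len(prot$n_pulses) - 1) * period
  win <- (prot$pulse_width + grace_ms) / 1000
  res <- lapply(seq_along(sweepset$sweeps), function(k) {
    ev <- detect_aps(sweepset$sweeps[[k]], ...)
    hit <- vapply(onsets, function(o)
      any(ev$threshold_time >= o & ev$threshold_time <= o + win),
      logical(1))
    data.frame(rate = prot$pulse_rate,
               amplitude = prot$step_amplitude[k],
               n_pulses = length(onsets), n_failures = sum(!hit),
               failure_pct = 100 * sum(!hit) / length(onsets))
  })
  do.call(rbind, res)
}

#' Passive membrane properties from a hyperpolarizing pulse
#'
#' Least-squares single-exponential fit of the voltage relaxation after
#' a small hyperpolarizing step: input resistance from the steady-state
#' deflection, membrane time constant from the fit, capacitance as
#' tau / R.
#'
#' @param sweep A [sweep_trace()] containing the pulse (no spikes in
#'   the fit window).
#' @param pulse_amplitude Pulse amplitude (pA, negative for the
#'   standard -50 pA monitor pulse).
#' @param pulse_onset,pulse_offset Pulse timing (s).
#' @return List with `input_resistance` (MOhm), `membrane_tau` (ms),
#'   `capacitance` (pF).
#' @export
passive_properties <- function(sweep, pulse_amplitude = -50,
                               pulse_onset, pulse_offset) {
  stopifnot(inherits(sweep, "sweep_trace"), !is.null(sweep$voltage))
  t <- sweep_times(sweep)
  v <- sweep$voltage
  pre <- v[t < pulse_onset & t > pulse_onset - 0.05]
  if (!length(pre)) pre <- v[t < pulse_onset]
  v0 <- mean(pre)
  inwin <- t >= pulse_onset & t < pulse_offset
  tt <- t[inwin] - pulse_onset
  vv <- v[inwin]
  vss0 <- mean(vv[tt > max(tt) * 0.8])
  # log-linear estimate of tau as a starting value
  dv <- (vv - vss0) / (v0 - vss0)
  ok <- dv > 0.05 & tt < max(tt) * 0.5
  tau0 <- if (sum(ok) > 5)
    unname(-1 / stats::coef(stats::lm(log(dv[ok]) ~ tt[ok]))[2])
  else max(tt) / 5
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(tt) / 5
  fit <- try(minpack.lm::nlsLM(vv ~ vss + (v0 - vss) * exp(-tt / tau),
                               start = list(vss = vss0, tau = tau0),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error")) stop("passive fit did not converge")
  cf <- stats::coef(fit)
  r_mohm <- (cf[["vss"]] - v0) / pulse_amplitude * 1000  # mV/pA -> MOhm
  tau_ms <- cf[["tau"]] * 1000
  list(input_resistance = r_mohm, membrane_tau = tau_ms,
       capacitance = tau_ms / r_mohm * 1000)  # ms/MOhm -> nF -> pF
}
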