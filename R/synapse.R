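# Evoked and spontaneous postsynaptic current analysis. Amplitudes are
# reported as positive magnitudes with polarity determined by the
# holding potential (outward IPSCs at 0 mV, inward EPSCs at -56 mV) so
# the IPSC and EPSC code paths are identical.

psc_sign <- function(holding) if (holding > -20) 1 else -1

# Fit a single-exponential decay to the segment after a PSC peak and
# return a function extrapolating it; used to correct the baseline of
# overlapping later events.
fit_decay_fun <- function(t, i, t_peak, t_end, baseline, sgn) {
  win <- t > t_peak + 0.002 & t < t_end
  if (sum(win) < 5) return(function(tt) rep(baseline, length(tt)))
  y <- sgn * (i[win] - baseline)
  tt <- t[win] - t_peak
  pos <- y > max(y) * 1e-3
  if (sum(pos) < 5) return(function(tt) rep(baseline, length(tt)))
  cf <- stats::coef(stats::lm(log(y[pos]) ~ tt[pos]))
  a <- exp(cf[1]); tau <- -1 / cf[2]
  if (!is.finite(tau) || tau <= 0)
    return(function(tt) rep(baseline, length(tt)))
  function(tq) baseline + sgn * a * exp(-(tq - t_peak) / tau)
}

measure_pulse <- function(t, i, stim, holding, baseline_fun,
                          baseline_window, peak_window, blank) {
  sgn <- psc_sign(holding)
  pre <- t >= stim - baseline_window & t < stim
  base0 <- if (is.null(baseline_fun)) mean(i[pre])
           else NA  # dynamic baseline from the previous decay
  win <- t >= stim + blank & t <= stim + peak_window
  tw <- t[win]; iw <- i[win]
  bw <- if (is.null(baseline_fun)) rep(base0, length(tw))
        else baseline_fun(tw)
  dev <- sgn * (iw - bw)
  k <- which.max(dev)
  list(amplitude = max(0, dev[k]), peak_time = tw[k],
       onset_time = stim, baseline = bw[k])
}

#' Evoked PSC amplitudes and paired-pulse ratio
#'
#' Baseline for the first pulse is the mean over `baseline_window`
#' before the stimulus; the amplitude is the extremum (outward at
#' 0 mV, inward at -56 mV) within `peak_window` after the stimulus,
#' measured after an artifact blank. For the second and later pulses
#' the baseline is the extrapolated single-exponential decay of the
#' preceding PSC, so overlapping responses are decay-corrected.
#'
#' @param sweep A [sweep_trace()] with a current channel.
#' @param stim_times Stimulus times (s), within the sweep.
#' @param holding Holding potential (mV), 0 or -56.
#' @param baseline_window,peak_window,blank Measurement windows (s).
#' @param decay_correct Apply the exponential baseline extrapolation.
#' @return List with `events` (data frame: `onset_time`, `peak_time`,
#'   `amplitude` in pA magnitude, `polarity`, `evoked`, `pulse_index`)
#'   and `ppr` (A2/A1, `NA` with a single pulse).
#' @export
evoked_psc_metrics <- function(sweep, stim_times, holding = 0,
                               baseline_window = 0.005,
                               peak_window = 0.020, blank = 0.001,
                               decay_correct = TRUE) {
  stopifnot(inherits(sweep, "sweep_trace"), !is.null(sweep$current))
  t <- sweep_times(sweep)
  if (any(stim_times < min(t) | stim_times > max(t)))
    stop("stim_times outside sweep")
  if (blank >= peak_window)
    stop("artifact blank period covers the whole measurement window")
  i <- sweep$current
  sgn <- psc_sign(holding)
  events <- list()
  decay <- NULL
  for (k in seq_along(stim_times)) {
    m <- measure_pulse(t, i, stim_times[k], holding,
                       if (decay_correct) decay else NULL,
                       baseline_window, peak_window, blank)
    events[[k]] <- data.frame(
      onset_time = m$onset_time, peak_time = m$peak_time,
      amplitude = m$amplitude,
      polarity = if (sgn > 0) "outward" else "inward",
      evoked = TRUE, pulse_index = k)
    t_next <- if (k < length(stim_times)) stim_times[k + 1] else max(t)
    decay <- fit_decay_fun(t, i, m$peak_time, t_next, m$baseline, sgn)
  }
  ev <- do.call(rbind, events)
  ppr <- if (nrow(ev) >= 2) ev$amplitude[2] / ev$amplitude[1] else NA_real_
  list(events = ev, ppr = ppr)
}

#' Train response amplitudes and linear gradient
#'
#' Per-pulse decay-corrected amplitudes for a stimulation train
#' (10 Hz in the standard protocol) and the ordinary least-squares
#' slope of amplitude versus pulse number (pA/pulse).
#'
#' @inheritParams evoked_psc_metrics
#' @return List with `amplitudes` (data frame `pulse`, `amplitude`)
#'   and `gradient` (pA/pulse).
#' @export
train_metrics <- function(sweep, stim_times, holding = 0, ...) {
  if (length(stim_times) < 5) stop("need >= 5 pulses")
  em <- evoked_psc_metrics(sweep, stim_times, holding, ...)
  amp <- em$events$amplitude
  pulse <- seq_along(amp)
  grad <- unname(stats::coef(stats::lm(amp ~ pulse))[2])
  list(amplitudes = data.frame(pulse = pulse, amplitude = amp),
       gradient = grad)
}

#' Threshold-based detection of spontaneous PSCs
#'
#' The trace is lightly smoothed (boxcar, `smooth_ms`) so that
#' sample-level noise does not masquerade as events; events are then
#' deviations from the robust baseline (median) exceeding
#' `threshold_sd` robust SDs (MAD of the smoothed trace) in the
#' polarity of the holding potential, with a 10-90 percent rise time
#' of at most `max_rise_ms` and a half-amplitude duration of at least
#' `min_half_ms` (a synaptic event outlives a noise excursion). Peaks
#' closer than `merge_ms` are merged (overlap split at local minima).
#' On a noiseless trace the MAD is zero and the threshold falls back
#' to an absolute 5 pA.
#'
#' @param sweep A [sweep_trace()] with a current channel (stimulus-free
#'   segment of at least 1 s).
#' @param holding Holding potential (mV).
#' @param threshold_sd Detection threshold in robust SDs.
#' @param max_rise_ms Maximum 10-90 percent rise time (ms).
#' @param merge_ms Minimum peak separation (ms).
#' @param smooth_ms Boxcar smoothing width (ms).
#' @param min_half_ms Minimum duration above half amplitude (ms).
#' @return Data frame: `onset_time`, `peak_time`, `amplitude` (pA
#'   magnitude), `rise_time_ms`, `polarity`, `evoked = FALSE`.
#' @export
detect_spontaneous_pscs <- function(sweep, holding = 0,
                                    threshold_sd = 3, max_rise_ms = 5,
                                    merge_ms = 2, smooth_ms = 1,
                                    min_half_ms = 3) {
  stopifnot(inherits(sweep, "sweep_trace"), !is.null(sweep$current))
  t <- sweep_times(sweep)
  if (max(t) - min(t) < 1) stop("need >= 1 s of recording")
  sgn <- psc_sign(holding)
  y <- sgn * (sweep$current - stats::median(sweep$current))
  # threshold in units of the raw trace's robust SD; smoothing is only
  # used to stabilize peak finding
  s <- stats::mad(y)
  thr <- if (s > 0) threshold_sd * s else 5
  w <- max(1L, round(smooth_ms / (sweep$dt * 1000)))
  if (w > 1) {
    ys <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
    ys[is.na(ys)] <- y[is.na(ys)]
    y <- ys
  }
  n <- length(y)
  # local maxima above threshold
  pk <- which(y[-c(1, n)] >= thr &
                y[-c(1, n)] >= y[-c(n - 1, n)] &
                y[-c(1, n)] > y[-c(1, 2)]) + 1L
  if (!length(pk)) return(empty_psc_events())
  # merge peaks closer than merge_ms, keep the larger
  keep <- logical(length(pk))
  last <- 1L; keep[1] <- TRUE
  if (length(pk) > 1) for (j in 2:length(pk)) {
    if ((t[pk[j]] - t[pk[last]]) * 1000 < merge_ms) {
      if (y[pk[j]] > y[pk[last]]) { keep[last] <- FALSE
                                    keep[j] <- TRUE; last <- j }
    } else { keep[j] <- TRUE; last <- j }
  }
  pk <- pk[keep]
  look_b <- max(1L, round(2e-3 / sweep$dt))
  out <- lapply(pk, function(p) {
    a <- y[p]
    # walk back to the local minimum bounding this event, descending
    # past noise-scale upticks
    b <- p
    repeat {
      prev <- max(1, b - look_b):max(1, b - 1)
      if (b <= 1 || min(y[prev]) >= y[b]) break
      b <- prev[which.min(y[prev])]
    }
    base <- y[b]
    amp <- a - base
    if (amp < thr) return(NULL)
    y10 <- base + 0.1 * amp; y90 <- base + 0.9 * amp
    seg <- b:p
    i10 <- seg[which(y[seg] >= y10)[1]]
    i90 <- seg[which(y[seg] >= y90)[1]]
    rise <- (t[i90] - t[i10]) * 1000
    if (!is.finite(rise) || rise > max_rise_ms) return(NULL)
    # a synaptic event stays above half amplitude through its decay;
    # noise excursions collapse within a sample or two
    half <- base + 0.5 * amp
    j <- p
    n_all <- length(y)
    while (j < n_all && y[j + 1] >= half) j <- j + 1
    if ((t[j] - t[p]) * 1000 < min_half_ms) return(NULL)
    data.frame(onset_time = t[b], peak_time = t[p], amplitude = amp,
               rise_time_ms = rise,
               polarity = if (sgn > 0) "outward" else "inward",
               evoked = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_psc_events() else out
}

empty_psc_events <- function()
  data.frame(onset_time = numeric(0), peak_time = numeric(0),
             amplitude = numeric(0), rise_time_ms = numeric(0),
             polarity = character(0), evoked = logical(0))

#' Two-sample Kolmogorov-Smirnov comparison of amplitude distributions
#'
#' Exact D = sup |F_a - F_b| from the sorted samples with the
#' asymptotic p value, plus cumulative and relative-frequency tables
#' binned for plotting.
#'
#' @param sample_a,sample_b Numeric amplitude samples (n >= 5 each).
#' @param bin_width Histogram bin width (pA); defaults to a tenth of
#'   the pooled range.
#' @return List with `D`, `p`, and `tables` (data frame per bin:
#'   `mid`, `rel_a`, `rel_b`, `cum_a`, `cum_b`).
#' @export
compare_amplitude_distributions <- function(sample_a, sample_b,
                                            bin_width = NULL) {
  if (!length(sample_a) || !length(sample_b)) stop("empty sample")
  if (length(sample_a) < 5 || length(sample_b) < 5)
    stop("need n >= 5 per sample")
  ks <- suppressWarnings(stats::ks.test(sample_a, sample_b,
                                        exact = FALSE))
  rng <- range(c(sample_a, sample_b))
  if (is.null(bin_width)) bin_width <- diff(rng) / 10
  if (bin_width <= 0) bin_width <- 1
  breaks <- seq(floor(rng[1] / bin_width) * bin_width,
                ceiling(rng[2] / bin_width) * bin_width + bin_width,
                by = bin_width)
  ha <- graphics::hist(sample_a, breaks = breaks, plot = FALSE)
  hb <- graphics::hist(sample_b, breaks = breaks, plot = FALSE)
  tables <- data.frame(
    mid = ha$mids,
    rel_a = ha$counts / length(sample_a),
    rel_b = hb$counts / length(sample_b),
    cum_a = cumsum(ha$counts) / length(sample_a),
    cum_b = cumsum(hb$counts) / length(sample_b))
  list(D = unname(ks$statistic), p = ks$p.value, tables = tables)
}
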