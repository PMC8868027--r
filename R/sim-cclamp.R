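# Phenomenological current-clamp simulator: stereotyped AP templates
# inserted on a passive subthreshold trajectory. The analyses consume
# waveforms and spike times, not channel mechanisms, so spike insertion
# keeps ground truth exact (spike times and template parameters are
# returned in sweep-set metadata).

# Evaluate the AP template relative to the rising threshold crossing
# (t = 0, ms). Phases: quadratic pre-depolarization from the local
# baseline reaching dV/dt = 10 mV/ms exactly at threshold (so the
# detector's interpolated threshold lands on the parameterized value),
# quarter-sine rise (threshold -> peak over width - repol), cosine
# fall through threshold at t = width down to the AHP minimum, cosine
# recovery crossing threshold at t = width + ahp_duration (slight
# overshoot so the discrete trace does reach it), then an ease back
# down to the inter-spike ride potential.
ap_template <- function(t_ms, width, amplitude, threshold,
                        repol, ahp_amplitude, ahp_duration,
                        v_start, v_ride, t_pre = 1, t_ease = 1.5) {
  t_rise <- width - repol
  # fall duration chosen so the falling threshold crossing is at t = width
  s_star <- (2 / pi) * acos(ahp_amplitude / (amplitude + ahp_amplitude))
  t_fall <- repol / s_star
  t_end <- width + ahp_duration
  over <- 0.5  # recovery overshoot above threshold (mV)
  v <- rep(NA_real_, length(t_ms))
  i0 <- t_ms >= -t_pre & t_ms < 0
  u0 <- (t_ms[i0] + t_pre) / t_pre
  v[i0] <- v_start + (threshold - v_start) * u0^2
  i1 <- t_ms >= 0 & t_ms < t_rise
  v[i1] <- threshold + amplitude * sin(pi * t_ms[i1] / (2 * t_rise))
  i2 <- t_ms >= t_rise & t_ms < t_rise + t_fall
  s <- (t_ms[i2] - t_rise) / t_fall
  v[i2] <- (threshold - ahp_amplitude) +
    (amplitude + ahp_amplitude) * cos(pi * s / 2)
  i3 <- t_ms >= t_rise + t_fall & t_ms < t_end
  u <- (t_ms[i3] - t_rise - t_fall) / (t_end - t_rise - t_fall)
  v[i3] <- (threshold + over) - (ahp_amplitude + over) * cos(pi * u / 2)
  i4 <- t_ms >= t_end & t_ms <= t_end + t_ease
  u4 <- (t_ms[i4] - t_end) / t_ease
  v[i4] <- v_ride + (threshold + over - v_ride) * cos(pi * u4 / 2)
  v
}

ap_template_duration <- function(width, ahp_duration)
  width + ahp_duration + 1.5

# Spike-time pattern for a 1-s step: exactly n spikes in
# [onset + latency, offset], archetype-patterned. Multiplicative ISI
# jitter is rescaled so the count is exact at any noise level.
pattern_spike_times <- function(arch, n, onset, offset, rheobase_sweep) {
  if (n <= 0) return(numeric(0))
  # minimum 20-ms latency keeps the sub-threshold charging ramp slower
  # than the spike-detection dV/dt criterion
  lat <- max(0.02, if (arch$delay_latency > 0.02 || rheobase_sweep)
    arch$delay_latency else 0.005)
  t_avail <- (offset - onset) - lat
  # hard refractory: the spike itself plus a small margin; the AHP may
  # be cut short by the next spike (burst regime)
  refr <- (arch$ap_width + 2.5) / 1000
  if (n == 1) return(onset + lat)
  # geometric ISI slowdown with bounded total range: adaptation is the
  # fractional slowdown over the train (last/first ISI = 1 + 4a)
  slow <- 1 + 4 * arch$adaptation
  r <- slow^(1 / max(1, n - 2))
  isi <- r^(seq_len(n - 1) - 1)
  if (arch$burst_prob >= stats::runif(1) && n >= 4) {
    nb <- min(3, n - 1)
    isi[seq_len(nb)] <- isi[seq_len(nb)] * 0.25
  }
  if (arch$pause_prob >= stats::runif(1) && n >= 5) {
    k <- sample(seq(2, n - 2), 1)
    isi[k] <- isi[k] * 4
  }
  if (arch$isi_cv > 0)
    isi <- isi * rlnorm_ms(n - 1, 1, arch$isi_cv)
  isi <- pmax(isi, 1e-6)
  isi <- isi / sum(isi) * (t_avail * 0.96)
  isi <- pmax(isi, refr)
  if (sum(isi) > t_avail)  # refractory floor overflowed the window
    isi <- isi / sum(isi) * (t_avail * 0.96)
  onset + lat + c(0, cumsum(isi))
}

#' Simulate a current-clamp sweep set
#'
#' Renders long current steps or brief pulse trains for one firing
#' archetype. For long steps the spike count on each suprathreshold
#' sweep is `round(fi_gain * (I - fi_rheobase))` over the 1-s step;
#' spike times follow the archetype pattern (regular / adapting /
#' initial-burst / delayed onset) and each spike is a stereotyped
#' waveform template. The subthreshold trajectory relaxes exponentially
#' toward `holding + R * I`. For pulse trains, one template AP is
#' inserted per successful pulse with a per-pulse logistic success
#' probability in (rate, amplitude).
#'
#' Ground truth is stored in `metadata`: `spike_times` (list per sweep)
#' and, for pulse trains, `success` (logical list per sweep).
#'
#' @param archetype An [archetype_spec()].
#' @param protocol A `long_step` or `pulse_train` [protocols] object.
#' @param noise_sd Gaussian voltage noise SD (mV), must be >= 0.
#' @param seed Optional RNG seed (local to this call).
#' @param dt Sampling interval (s); default 50 kHz.
#' @param condition `"control"`, `"TEA"` or `"DTX"`; TEA scales the
#'   suprathreshold rate by the archetype's `tea_rate_factor`.
#' @return A [sweep_set()] with voltage and stimulus channels.
#' @export
simulate_current_clamp <- function(archetype, protocol, noise_sd = 0,
                                   seed = NULL, dt = 2e-5,
                                   condition = "control") {
  stopifnot(inherits(archetype, "archetype_spec"),
            inherits(protocol, "protocol"))
  if (noise_sd < 0) stop("negative noise_sd")
  if (!protocol$kind %in% c("long_step", "pulse_train"))
    stop("protocol/archetype mismatch: need long_step or pulse_train")
  with_seed(seed, {
    if (protocol$kind == "long_step")
      sim_long_step(archetype, protocol, noise_sd, dt, condition)
    else
      sim_pulse_train(archetype, protocol, noise_sd, dt, condition)
  })
}

sim_long_step <- function(arch, prot, noise_sd, dt, condition) {
  amps <- prot$step_amplitude
  dur <- prot$step_offset + 0.2
  n_samp <- round(dur / dt)
  t <- dt * (seq_len(n_samp) - 1)
  rate_fac <- if (condition == "TEA") arch$tea_rate_factor else 1
  hold <- prot$holding
  tau <- arch$membrane_tau / 1000
  rheo <- arch$fi_rheobase
  gt <- vector("list", length(amps))
  sweeps <- vector("list", length(amps))
  for (k in seq_along(amps)) {
    I <- amps[k]
    n_ap <- if (I > rheo)
      round(arch$fi_gain * rate_fac * (I - rheo) *
              (prot$step_offset - prot$step_onset)) else 0
    # physiological ceiling: ISIs cannot shrink below the refractory
    # period, and a bursting cell must keep its burst ISIs clearly
    # shorter than its regular ones
    t_avail <- 0.96 * (prot$step_offset - prot$step_onset - 0.02)
    refr <- (arch$ap_width + 2.5) / 1000
    n_cap <- floor(t_avail / refr)
    if (arch$burst_prob > 0.5) n_cap <- floor(0.4 * t_avail / refr)
    n_ap <- min(n_ap, n_cap)
    v_inf <- hold + I * arch$input_resistance / 1000
    spk <- pattern_spike_times(arch, n_ap, prot$step_onset,
                               prot$step_offset,
                               rheobase_sweep = n_ap > 0 &&
                                 (k == 1 || all(amps[seq_len(k - 1)] <= rheo)))
    spk <- spk[spk + (arch$ap_width + arch$ahp_duration) / 1000 <
                 prot$step_offset]
    # spiking sweeps ride just below threshold, charging fast enough
    # that the baseline is settled before the first spike
    ride <- if (length(spk)) arch$ap_threshold - 5 else v_inf
    tau_eff <- if (length(spk))
      min(tau, (spk[1] - prot$step_onset) / 4) else tau
    v <- rep(hold, n_samp)
    on <- t >= prot$step_onset & t < prot$step_offset
    v[on] <- ride + (hold - ride) *
      exp(-(t[on] - prot$step_onset) / tau_eff)
    post <- t >= prot$step_offset
    v_off <- ride + (hold - ride) *
      exp(-(prot$step_offset - prot$step_onset) / tau_eff)
    v[post] <- hold + (v_off - hold) * exp(-(t[post] - prot$step_offset) / tau)
    v <- insert_spikes(v, t, spk, arch, ride)
    if (noise_sd > 0) v <- v + stats::rnorm(n_samp, 0, noise_sd)
    stim <- numeric(n_samp); stim[on] <- I
    sweeps[[k]] <- sweep_trace(0, dt, voltage = v, stimulus = stim,
                               condition = condition, ljp_corrected = TRUE)
    gt[[k]] <- spk
  }
  sweep_set(sweeps, prot, metadata = list(
    generator = "simulate_current_clamp", archetype = arch$name,
    condition = condition, spike_times = gt))
}

insert_spikes <- function(v, t, spk, arch, ride = NULL, t_pre = 1) {
  if (!length(spk)) return(v)
  if (is.null(ride)) ride <- arch$ap_threshold - 5
  dur_ms <- ap_template_duration(arch$ap_width, arch$ahp_duration)
  n_spk <- length(spk)
  # amplitude accommodation across the train
  amp <- arch$ap_amplitude *
    seq(1, 1 - arch$accommodation, length.out = n_spk)
  for (j in seq_len(n_spk)) {
    idx <- which(t >= spk[j] - t_pre / 1000 & t <= spk[j] + dur_ms / 1000)
    if (!length(idx)) next
    tm <- (t[idx] - spk[j]) * 1000
    v_start <- v[idx[1]]
    # when a burst spike interrupts the previous AHP, depolarize from
    # at most 8 mV below threshold so the upstroke stays template-like
    if (v_start < ride)
      v_start <- max(v_start, arch$ap_threshold - 8)
    tv <- ap_template(tm, arch$ap_width, amp[j], arch$ap_threshold,
                      arch$repol_duration, arch$ahp_amplitude,
                      arch$ahp_duration, v_start = v_start,
                      v_ride = ride, t_pre = t_pre)
    ok <- !is.na(tv)
    v[idx[ok]] <- tv[ok]
  }
  v
}

sim_pulse_train <- function(arch, prot, noise_sd, dt, condition) {
  amps <- prot$step_amplitude
  period <- 1 / prot$pulse_rate
  dur <- prot$onset + prot$n_pulses * period + 0.1
  n_samp <- round(dur / dt)
  t <- dt * (seq_len(n_samp) - 1)
  hold <- prot$holding
  gt_t <- vector("list", length(amps))
  gt_s <- vector("list", length(amps))
  sweeps <- vector("list", length(amps))
  for (k in seq_along(amps)) {
    A <- amps[k]
    a50 <- arch$pulse_a50_base + arch$pulse_a50_per_hz * prot$pulse_rate
    p_succ <- stats::plogis((A - a50) / arch$pulse_slope)
    pulse_on <- prot$onset + (seq_len(prot$n_pulses) - 1) * period
    success <- stats::runif(prot$n_pulses) < p_succ
    v <- rep(hold, n_samp)
    stim <- numeric(n_samp)
    for (p in seq_len(prot$n_pulses)) {
      on <- t >= pulse_on[p] & t < pulse_on[p] + prot$pulse_width / 1000
      stim[on] <- A
      if (!success[p])  # subthreshold RC blip
        v[on] <- v[on] + A * arch$input_resistance / 1000 * 0.15 *
          (1 - exp(-(t[on] - pulse_on[p]) / 0.003))
    }
    spk <- pulse_on[success] + 0.001
    v <- insert_spikes(v, t, spk, arch, ride = hold)
    if (noise_sd > 0) v <- v + stats::rnorm(n_samp, 0, noise_sd)
    sweeps[[k]] <- sweep_trace(0, dt, voltage = v, stimulus = stim,
                               condition = condition, ljp_corrected = TRUE)
    gt_t[[k]] <- spk
    gt_s[[k]] <- success
  }
  sweep_set(sweeps, prot, metadata = list(
    generator = "simulate_current_clamp", archetype = arch$name,
    condition = condition, spike_times = gt_t, success = gt_s,
    pulse_onsets = lapply(seq_along(amps), function(k)
      prot$onset + (seq_len(prot$n_pulses) - 1) * period)))
}
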