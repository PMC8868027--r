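#' Firing archetype specification
#'
#' Phenomenological description of one of the four Lamina VII firing
#' phenotypes (e-types): steady regular (E1), continuous adapting (E2),
#' fast bursting (E3) and steady delayed (E4). Waveform parameters
#' (width, amplitude, threshold, repolarization, AHP) carry the
#' population means and SDs of the corresponding published waveform
#' statistics; F-I parameters for the fast type are anchored to the
#' printed control/TEA firing rates at 140 pA, the remaining types are
#' calibrated qualitatively (slower, mutually similar F-I).
#'
#' @param name One of `"steady_regular"`, `"continuous_adapting"`,
#'   `"fast_bursting"`, `"steady_delayed"`.
#' @param fi_gain F-I slope above rheobase (Hz/pA).
#' @param fi_rheobase Rheobase (pA).
#' @param adaptation Adaptation index target in `[0, 1]` (mean of
#'   normalized consecutive-ISI differences).
#' @param isi_cv Interspike-interval coefficient of variation target.
#' @param burst_prob,pause_prob Per-sweep probability of an initial
#'   burst / an intercalated pause.
#' @param delay_latency First-spike latency at rheobase (s).
#' @param ap_width AP base width (ms): time between rising and falling
#'   crossings of the threshold voltage.
#' @param ap_amplitude Peak minus threshold voltage (mV).
#' @param ap_threshold Threshold voltage (mV).
#' @param repol_duration Peak to falling threshold crossing (ms).
#' @param ahp_amplitude Threshold minus AHP minimum (mV).
#' @param ahp_duration Falling threshold crossing to recovery (ms).
#' @param accommodation Fractional decline of AP amplitude from first
#'   to last spike on the maximal-firing sweep.
#' @param sd Named list of between-cell SDs for waveform parameters
#'   (same names as the waveform arguments).
#' @param tea_rate_factor Multiplicative effect of 0.5 mM TEA on the
#'   suprathreshold firing rate (1 = no effect).
#' @param input_resistance,membrane_tau Passive properties (MOhm, ms).
#' @param pulse_a50_base,pulse_a50_per_hz,pulse_slope Logistic
#'   pulse-success model: success probability for a 10-ms pulse of
#'   amplitude A at rate r is `plogis((A - a50) / slope)` with
#'   `a50 = pulse_a50_base + pulse_a50_per_hz * r`.
#' @return An object of class `"archetype_spec"`.
#' @export
archetype_spec <- function(name, fi_gain, fi_rheobase, adaptation, isi_cv,
                           burst_prob = 0, pause_prob = 0,
                           delay_latency = 0.005,
                           ap_width, ap_amplitude, ap_threshold,
                           repol_duration, ahp_amplitude, ahp_duration,
                           accommodation = 0.05, sd = list(),
                           tea_rate_factor = 1,
                           input_resistance = 200, membrane_tau = 20,
                           pulse_a50_base = 150, pulse_a50_per_hz = 1.5,
                           pulse_slope = 30) {
  name <- match.arg(name, c("steady_regular", "continuous_adapting",
                            "fast_bursting", "steady_delayed"))
  stopifnot(ap_width > 0, adaptation >= 0, adaptation <= 1,
            repol_duration > 0, repol_duration < ap_width,
            ap_amplitude > 0, ahp_amplitude > 0, ahp_duration > 0)
  structure(list(name = name, fi_gain = fi_gain,
                 fi_rheobase = fi_rheobase, adaptation = adaptation,
                 isi_cv = isi_cv, burst_prob = burst_prob,
                 pause_prob = pause_prob, delay_latency = delay_latency,
                 ap_width = ap_width, ap_amplitude = ap_amplitude,
                 ap_threshold = ap_threshold,
                 repol_duration = repol_duration,
                 ahp_amplitude = ahp_amplitude,
                 ahp_duration = ahp_duration,
                 accommodation = accommodation, sd = sd,
                 tea_rate_factor = tea_rate_factor,
                 input_resistance = input_resistance,
                 membrane_tau = membrane_tau,
                 pulse_a50_base = pulse_a50_base,
                 pulse_a50_per_hz = pulse_a50_per_hz,
                 pulse_slope = pulse_slope),
            class = "archetype_spec")
}

#' Default archetype parameters for the four e-types
#'
#' Waveform means and SDs follow the published per-e-type AP statistics
#' (width, amplitude, threshold, repolarization duration, AHP duration
#' and amplitude). The fast-bursting type's F-I is anchored so that its
#' control firing rate at 140 pA is 60.25 Hz (rheobase 20 pA) and its
#' rate under 0.5 mM TEA is 35.75 Hz; the other types have no TEA
#' effect on firing.
#'
#' @return Named list of four [archetype_spec()] objects
#'   (`E1` ... `E4`).
#' @export
archetype_defaults <- function() {
  tbl <- list(
    E1 = list(name = "steady_regular", width = 3.3, width_sd = 1.4,
              amp = 55.2, amp_sd = 11.9, repol = 2.4, repol_sd = 1.1,
              thr = -29.6, thr_sd = 6.7, ahp_dur = 29.6, ahp_dur_sd = 18.5,
              ahp = 19.5, ahp_sd = 5.3,
              gain = 0.17, rheo = 30, adapt = 0.02, cv = 0.05,
              burst = 0, delay = 0.005, accom = 0.03, tea = 1,
              a50 = 170, a50hz = 1.6),
    E2 = list(name = "continuous_adapting", width = 4.0, width_sd = 1.8,
              amp = 52.0, amp_sd = 13.9, repol = 2.9, repol_sd = 1.2,
              thr = -28.8, thr_sd = 6.7, ahp_dur = 28.8, ahp_dur_sd = 16.3,
              ahp = 20.6, ahp_sd = 5.7,
              gain = 0.15, rheo = 30, adapt = 0.50, cv = 0.08,
              burst = 0, delay = 0.005, accom = 0.15, tea = 1,
              a50 = 180, a50hz = 1.8),
    E3 = list(name = "fast_bursting", width = 1.3, width_sd = 0.4,
              amp = 54.6, amp_sd = 9.3, repol = 0.8, repol_sd = 0.3,
              thr = -34.7, thr_sd = 4.7, ahp_dur = 8.9, ahp_dur_sd = 7.5,
              ahp = 21.6, ahp_sd = 5.9,
              gain = 60.25 / 120, rheo = 20, adapt = 0.05, cv = 0.12,
              burst = 1, delay = 0.003, accom = 0.05,
              tea = 35.75 / 60.25,
              a50 = 100, a50hz = 0.3),
    E4 = list(name = "steady_delayed", width = 3.5, width_sd = 2.0,
              amp = 45.4, amp_sd = 10.4, repol = 2.4, repol_sd = 1.6,
              thr = -30.3, thr_sd = 5.1, ahp_dur = 27.1, ahp_dur_sd = 20.6,
              ahp = 19.8, ahp_sd = 6.2,
              gain = 0.10, rheo = 60, adapt = 0.05, cv = 0.05,
              burst = 0, delay = 0.15, accom = 0.25, tea = 1,
              a50 = 190, a50hz = 2.0))
  lapply(tbl, function(p)
    archetype_spec(p$name, fi_gain = p$gain, fi_rheobase = p$rheo,
                   adaptation = p$adapt, isi_cv = p$cv,
                   burst_prob = p$burst, delay_latency = p$delay,
                   ap_width = p$width, ap_amplitude = p$amp,
                   ap_threshold = p$thr, repol_duration = p$repol,
                   ahp_amplitude = p$ahp, ahp_duration = p$ahp_dur,
                   accommodation = p$accom,
                   sd = list(ap_width = p$width_sd,
                             ap_amplitude = p$amp_sd,
                             ap_threshold = p$thr_sd,
                             repol_duration = p$repol_sd,
                             ahp_amplitude = p$ahp_sd,
                             ahp_duration = p$ahp_dur_sd),
                   tea_rate_factor = p$tea,
                   pulse_a50_base = p$a50, pulse_a50_per_hz = p$a50hz))
}

#' Voltage-gated conductance mixture specification
#'
#' Each component is a Boltzmann-activated conductance
#' `g(V) = gmax / (1 + exp((v50 - V) / slope))` with common reversal
#' potential. TEA and DTX sensitivity flags drive the pharmacological
#' block applied by [simulate_vclamp_family()].
#'
#' @param components Data frame with columns `gmax` (nS), `v50` (mV),
#'   `slope` (mV, > 0), `tea_sensitive`, `dtx_sensitive` (logical).
#' @param reversal Reversal potential (mV), potassium by default.
#' @param block_fraction_tea Fraction of each TEA-sensitive component
#'   blocked by 0.5 mM TEA; the default 0.5 reflects the partial
#'   (about 50 percent) block of Kv3 channels at that concentration.
#' @param block_fraction_dtx Fraction of DTX-sensitive components
#'   blocked by 10 nM dendrotoxin (Kv1-specific, full block).
#' @return An object of class `"conductance_spec"`.
#' @export
conductance_spec <- function(components, reversal = -90,
                             block_fraction_tea = 0.5,
                             block_fraction_dtx = 1) {
  stopifnot(is.data.frame(components), nrow(components) >= 1,
            all(c("gmax", "v50", "slope", "tea_sensitive",
                  "dtx_sensitive") %in% names(components)),
            all(components$slope > 0),
            block_fraction_tea >= 0, block_fraction_tea <= 1,
            block_fraction_dtx >= 0, block_fraction_dtx <= 1)
  structure(list(components = components, reversal = reversal,
                 block_fraction_tea = block_fraction_tea,
                 block_fraction_dtx = block_fraction_dtx),
            class = "conductance_spec")
}

#' Default conductance mixture for the fast-bursting e-type
#'
#' A high-voltage-activated TEA-sensitive (Kv3-like) component with
#' half-activation at -10.66 mV, a TEA/DTX-insensitive delayed
#' rectifier (Kv2-like), and a small DTX-sensitive (Kv1-like)
#' component. The Kv3-like `gmax` is set so that its plateau current at
#' a +14 mV step equals 3760 pA, the published mean TEA-sensitive
#' current for this type; the delayed-rectifier conductance is
#' calibrated so the single-Boltzmann fit of the control (summed)
#' tails lands near the published control half-activation of
#' -28.18 mV.
#'
#' @param reversal Potassium reversal potential (mV).
#' @return A [conductance_spec()].
#' @export
etype3_conductances <- function(reversal = -90) {
  po14 <- 1 / (1 + exp((-10.66 - 14) / 8))
  g_kv3 <- 3760 / (po14 * (14 - reversal))  # nS; pA = nS * mV
  conductance_spec(data.frame(
    gmax = c(g_kv3, 50, 5),
    v50 = c(-10.66, -40, -35),
    slope = c(8, 10, 6),
    tea_sensitive = c(TRUE, FALSE, FALSE),
    dtx_sensitive = c(FALSE, FALSE, TRUE)), reversal = reversal)
}

#' Postsynaptic-current specification
#'
#' Defaults describe the evoked IPSC measurements: control amplitude
#' 94.93 pA with the TEA condition scaling amplitude by 210/94.93
#' (the published greater-than-100-percent potentiation), paired-pulse
#' interval 100 ms, 10-Hz trains depressing linearly at -2.66 pA per
#' pulse.
#'
#' @param evoked_amplitude First evoked PSC amplitude (pA, magnitude).
#' @param ppr Paired-pulse ratio A2/A1.
#' @param rise,decay Kernel time constants (ms), `rise < decay`.
#' @param spont_rate Spontaneous event rate (Hz).
#' @param spont_amp_mean,spont_amp_sd Spontaneous amplitude moments (pA).
#' @param depression_per_pulse Linear train slope (pA/pulse).
#' @param holding Holding potential (mV): 0 isolates outward IPSCs,
#'   -56 inward EPSCs.
#' @param tea_amplitude_factor Multiplicative TEA effect on evoked
#'   amplitude.
#' @return An object of class `"psc_spec"`.
#' @export
psc_spec <- function(evoked_amplitude = 94.93, ppr = 1.564,
                     rise = 1.5, decay = 12, spont_rate = 2,
                     spont_amp_mean = 30, spont_amp_sd = 10,
                     depression_per_pulse = -2.66, holding = 0,
                     tea_amplitude_factor = 210 / 94.93) {
  stopifnot(rise < decay, spont_rate >= 0, evoked_amplitude >= 0)
  polarity <- if (holding > -20) "outward" else "inward"
  structure(list(evoked_amplitude = evoked_amplitude, ppr = ppr,
                 rise = rise, decay = decay, spont_rate = spont_rate,
                 spont_amp_mean = spont_amp_mean,
                 spont_amp_sd = spont_amp_sd,
                 depression_per_pulse = depression_per_pulse,
                 holding = holding, polarity = polarity,
                 tea_amplitude_factor = tea_amplitude_factor),
            class = "psc_spec")
}
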