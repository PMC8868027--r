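# Voltage-clamp family generator. Plateau current at a step voltage V
# is the sum over Boltzmann components of gmax * Po(V) * (V - Erev)
# with Po(V) = 1 / (1 + exp((v50 - V) / slope)); activation follows a
# single exponential onto the plateau and tails deactivate
# exponentially at the post-step voltage from an instantaneous-Po
# initial value. Pharmacological conditions scale sensitive components
# by (1 - block_fraction). Per-component plateau/tail ground truth is
# stored in metadata.

boltzmann_po <- function(v, v50, slope) 1 / (1 + exp((v50 - v) / slope))

component_block <- function(spec, condition) {
  comp <- spec$components
  fac <- rep(1, nrow(comp))
  if (condition == "TEA")
    fac[comp$tea_sensitive] <- 1 - spec$block_fraction_tea
  if (condition == "DTX")
    fac[comp$dtx_sensitive] <- 1 - spec$block_fraction_dtx
  fac
}

#' Simulate a voltage-step current family
#'
#' @param spec A [conductance_spec()].
#' @param protocol A `vstep_family` [protocols] object.
#' @param condition `"control"`, `"TEA"` or `"DTX"`; sensitive
#'   components are scaled by the spec's block fractions.
#' @param noise_sd Gaussian current noise SD (pA).
#' @param seed Optional RNG seed (local to this call).
#' @param dt Sampling interval (s); 10 kHz default is ample for
#'   plateau/tail measurement.
#' @param tau_act,tau_deact Activation / deactivation time constants
#'   (ms). Deactivation is common to all steps so normalized tail
#'   amplitudes preserve the activation curve shape.
#' @return A [sweep_set()] with current and (voltage-command) stimulus
#'   channels; metadata carries the closed-form plateau and tail of
#'   every component at every step.
#' @export
simulate_vclamp_family <- function(spec, protocol, condition = "control",
                                   noise_sd = 0, seed = NULL, dt = 1e-4,
                                   tau_act = 3, tau_deact = 15) {
  stopifnot(inherits(spec, "conductance_spec"),
            inherits(protocol, "protocol"))
  if (protocol$kind != "vstep_family") stop("need a vstep_family protocol")
  comp <- spec$components
  if (!nrow(comp)) stop("empty components")
  condition <- match.arg(condition, c("control", "TEA", "DTX"))
  fac <- component_block(spec, condition)
  vs <- protocol$step_voltages
  on <- protocol$step_onset
  off <- on + protocol$step_duration
  dur <- off + 0.08
  n_samp <- round(dur / dt)
  t <- dt * (seq_len(n_samp) - 1)
  vpost <- protocol$post_voltage
  with_seed(seed, {
    plat_gt <- tail_gt <- matrix(0, length(vs), nrow(comp))
    sweeps <- vector("list", length(vs))
    for (k in seq_along(vs)) {
      V <- vs[k]
      i <- numeric(n_samp)
      during <- t >= on & t < off
      post <- t >= off
      for (c in seq_len(nrow(comp))) {
        g <- comp$gmax[c] * fac[c]
        po_step <- boltzmann_po(V, comp$v50[c], comp$slope[c])
        po_post <- boltzmann_po(vpost, comp$v50[c], comp$slope[c])
        i_plat <- g * po_step * (V - spec$reversal)
        i_hold <- g * po_post * (vpost - spec$reversal)
        i[during] <- i[during] + i_plat +
          (0 - i_plat) * exp(-(t[during] - on) * 1000 / tau_act)
        # instantaneous-Po tail at the post-step driving force
        i_tail0 <- g * po_step * (vpost - spec$reversal)
        i[post] <- i[post] + i_hold +
          (i_tail0 - i_hold) * exp(-(t[post] - off) * 1000 / tau_deact)
        plat_gt[k, c] <- i_plat
        tail_gt[k, c] <- i_tail0
      }
      if (noise_sd > 0) i <- i + stats::rnorm(n_samp, 0, noise_sd)
      stim <- rep(protocol$holding, n_samp)
      stim[during] <- V
      stim[post] <- vpost
      sweeps[[k]] <- sweep_trace(0, dt, current = i, stimulus = stim,
                                 condition = condition)
    }
    sweep_set(sweeps, protocol, metadata = list(
      generator = "simulate_vclamp_family", condition = condition,
      component_plateau = plat_gt, component_tail = tail_gt,
      block_factors = fac, tau_deact = tau_deact))
  })
}

#' Simulate a postsynaptic-current recording
#'
#' Evoked events are rendered as difference-of-exponential kernels at
#' the protocol's stimulation times: for paired pulses the second
#' amplitude is `ppr * A1`; for trains amplitudes depress linearly at
#' `depression_per_pulse`. Spontaneous events arrive as a Poisson
#' process with Gaussian (positive-truncated) amplitudes. Polarity
#' follows the holding potential (outward at 0 mV, inward at -56 mV).
#'
#' @param spec A [psc_spec()].
#' @param protocol An `evoked_psc` or `train_psc` [protocols] object.
#' @param seed Optional RNG seed (local to this call).
#' @param noise_sd Gaussian current noise SD (pA).
#' @param condition `"control"`, `"TEA"` or `"DTX"`; TEA scales evoked
#'   and spontaneous amplitudes by `tea_amplitude_factor`.
#' @param amplitude_jitter_cv CV of multiplicative log-normal jitter on
#'   per-event evoked amplitudes (0 = deterministic amplitudes).
#' @param dt Sampling interval (s).
#' @return A [sweep_set()]; metadata carries ground-truth evoked and
#'   spontaneous event times and amplitudes.
#' @export
simulate_psc_recording <- function(spec, protocol, seed = NULL,
                                   noise_sd = 0, condition = "control",
                                   amplitude_jitter_cv = 0, dt = 1e-4) {
  stopifnot(inherits(spec, "psc_spec"), inherits(protocol, "protocol"))
  if (!protocol$kind %in% c("evoked_psc", "train_psc"))
    stop("need an evoked_psc or train_psc protocol")
  st <- protocol$stim_times
  if (any(st >= protocol$duration)) stop("stim_times outside sweep")
  sgn <- if (spec$polarity == "outward") 1 else -1
  amp_fac <- if (condition == "TEA") spec$tea_amplitude_factor else 1
  n_samp <- round(protocol$duration / dt)
  t <- dt * (seq_len(n_samp) - 1)
  tr <- spec$rise / 1000; td <- spec$decay / 1000
  tpk <- tr * td / (td - tr) * log(td / tr)
  knorm <- exp(-tpk / td) - exp(-tpk / tr)
  with_seed(seed, {
    amps <- if (protocol$kind == "evoked_psc" && length(st) >= 2)
      spec$evoked_amplitude * c(1, rep(spec$ppr, length(st) - 1))
    else
      pmax(0, spec$evoked_amplitude +
             spec$depression_per_pulse * (seq_along(st) - 1))
    amps <- amps * amp_fac
    if (amplitude_jitter_cv > 0)
      amps <- amps * rlnorm_ms(length(amps), 1, amplitude_jitter_cv)
    i <- numeric(n_samp)
    for (k in seq_along(st)) {
      idx <- t >= st[k]
      u <- t[idx] - st[k]
      i[idx] <- i[idx] + sgn * amps[k] *
        (exp(-u / td) - exp(-u / tr)) / knorm
    }
    n_spont <- stats::rpois(1, spec$spont_rate * protocol$duration)
    sp_t <- sort(stats::runif(n_spont, 0, protocol$duration - 5 * td))
    sp_a <- pmax(1, stats::rnorm(n_spont, spec$spont_amp_mean * amp_fac,
                                 spec$spont_amp_sd))
    for (k in seq_len(n_spont)) {
      idx <- t >= sp_t[k]
      u <- t[idx] - sp_t[k]
      i[idx] <- i[idx] + sgn * sp_a[k] *
        (exp(-u / td) - exp(-u / tr)) / knorm
    }
    if (noise_sd > 0) i <- i + stats::rnorm(n_samp, 0, noise_sd)
    stim <- numeric(n_samp)
    stim[findInterval(st, t)] <- 1
    sw <- sweep_trace(0, dt, current = i, stimulus = stim,
                      condition = condition)
    sweep_set(list(sw), protocol, metadata = list(
      generator = "simulate_psc_recording", condition = condition,
      evoked_amplitudes = amps, stim_times = st,
      spont_times = sp_t, spont_amplitudes = sp_a))
  })
}
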