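# Population generator: draws per-cell archetype parameters around the
# archetype means and renders a current-clamp step family per cell,
# returning ground-truth type labels for clustering validation.

# Per-cell parameter draw. Positive-valued waveform parameters are
# jittered log-normally with the archetype's between-cell SDs
# (threshold, the one signed parameter, is jittered normally);
# draws are winsorized at +/- 2 SD so tail draws stay physiological
# (an AP's upstroke must outrun its own AHP recovery);
# repolarization is scaled with the drawn width so repol < width is
# preserved. F-I parameters get a modest log-normal CV.
draw_cell_archetype <- function(arch, waveform_jitter = TRUE,
                                fi_cv = 0.12) {
  a <- arch
  wins <- function(x, mean, sd)
    min(max(x, mean - 2 * sd), mean + 2 * sd)
  if (waveform_jitter && length(arch$sd)) {
    w <- wins(rlnorm_ms(1, arch$ap_width, arch$sd$ap_width %||% 0),
              arch$ap_width, arch$sd$ap_width %||% 0)
    a$ap_width <- w
    a$repol_duration <- arch$repol_duration * w / arch$ap_width
    a$ap_amplitude <- wins(rlnorm_ms(1, arch$ap_amplitude,
                                     arch$sd$ap_amplitude %||% 0),
                           arch$ap_amplitude,
                           arch$sd$ap_amplitude %||% 0)
    a$ap_threshold <- stats::rnorm(1, arch$ap_threshold,
                                   arch$sd$ap_threshold %||% 0)
    a$ahp_amplitude <- wins(rlnorm_ms(1, arch$ahp_amplitude,
                                      arch$sd$ahp_amplitude %||% 0),
                            arch$ahp_amplitude,
                            arch$sd$ahp_amplitude %||% 0)
    a$ahp_duration <- max(1.2 * (a$ap_width - a$repol_duration),
                          wins(rlnorm_ms(1, arch$ahp_duration,
                                         arch$sd$ahp_duration %||% 0),
                               arch$ahp_duration,
                               arch$sd$ahp_duration %||% 0))
  }
  if (fi_cv > 0) {
    a$fi_gain <- rlnorm_ms(1, arch$fi_gain, fi_cv * arch$fi_gain)
    a$fi_rheobase <- rlnorm_ms(1, arch$fi_rheobase,
                               fi_cv * arch$fi_rheobase)
  }
  a
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Pull a parameter set toward the across-type mean; separation = 1
# leaves archetypes untouched, 0 collapses all types onto the mean
# (null-structure control for clustering).
blend_archetypes <- function(archs, separation) {
  if (separation >= 1) return(archs)
  fields <- c("fi_gain", "fi_rheobase", "adaptation", "isi_cv",
              "burst_prob", "pause_prob", "delay_latency",
              "accommodation", "ap_width", "ap_amplitude",
              "ap_threshold", "repol_duration", "ahp_amplitude",
              "ahp_duration")
  means <- lapply(fields, function(f)
    mean(vapply(archs, `[[`, numeric(1), f)))
  names(means) <- fields
  lapply(archs, function(a) {
    for (f in fields)
      a[[f]] <- means[[f]] + separation * (a[[f]] - means[[f]])
    a$repol_duration <- min(a$repol_duration, 0.9 * a$ap_width)
    a
  })
}

#' Simulate a labelled population of current-clamp recordings
#'
#' Draws per-cell parameters around the four archetype means and
#' renders a long-step family per cell, returning the sweep sets
#' together with ground-truth type labels. Defaults reproduce the study
#' population size: 96 neurons, 24 per e-type.
#'
#' @param n_per_type Integer vector of four counts (E1..E4).
#' @param seed Optional RNG seed (local to this call).
#' @param archetypes List of four [archetype_spec()]s; defaults to
#'   [archetype_defaults()].
#' @param protocol Long-step protocol shared by all cells; the default
#'   covers 0-200 pA in 20-pA increments.
#' @param noise_sd Voltage noise SD (mV).
#' @param dt Sampling interval (s); 10 kHz default keeps a 96-cell
#'   population quick to render while staying well inside the
#'   detector's resolution requirement.
#' @param separation Scalar in `[0, 1]`: 1 = archetypes as specified,
#'   0 = all types collapsed onto their mean (null control).
#' @return List of class `"l7_population"` with elements `cells`
#'   (list of [sweep_set()]s), `labels` (factor E1..E4) and
#'   `archetypes`.
#' @export
simulate_population <- function(n_per_type = c(24, 24, 24, 24),
                                seed = NULL, archetypes = NULL,
                                protocol = NULL, noise_sd = 0.3,
                                dt = 1e-4, separation = 1) {
  stopifnot(length(n_per_type) == 4, all(n_per_type >= 1))
  if (is.null(archetypes)) archetypes <- archetype_defaults()
  archetypes <- blend_archetypes(archetypes, separation)
  if (is.null(protocol))
    protocol <- protocol_long_step(seq(0, 200, by = 20))
  with_seed(seed, {
    labels <- factor(rep(names(archetypes), n_per_type),
                     levels = names(archetypes))
    cells <- vector("list", length(labels))
    for (i in seq_along(labels)) {
      arch <- draw_cell_archetype(archetypes[[as.character(labels[i])]])
      ss <- simulate_current_clamp(arch, protocol, noise_sd = noise_sd,
                                   dt = dt)
      ss$cell_id <- sprintf("cell%03d", i)
      ss$metadata$true_type <- as.character(labels[i])
      cells[[i]] <- ss
    }
    structure(list(cells = cells, labels = labels,
                   archetypes = archetypes),
              class = "l7_population")
  })
}

#' @export
print.l7_population <- function(x, ...) {
  cat("<l7_population>", length(x$cells), "cells:",
      paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
            collapse = ", "), "\n")
  invisible(x)
}
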