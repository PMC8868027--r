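#' Run configuration for the e-typing pipeline
#'
#' @param seed RNG seed used by every stochastic stage.
#' @param out_dir Output directory (created if missing).
#' @param n_per_type Population composition (four counts).
#' @param k_max Largest k scanned for the elbow curve.
#' @param stages Stages to run, a subset of
#'   `c("simulate", "features", "cluster", "summarize")` (in order).
#' @param noise_sd Voltage noise SD (mV) for the simulation stage.
#' @param separation Archetype separation scalar (see
#'   [simulate_population()]).
#' @param archetype_overrides Named list of archetype field overrides,
#'   e.g. `list(E3 = list(fi_gain = 0.6))`.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("l7run"),
                       n_per_type = c(24, 24, 24, 24), k_max = 8,
                       stages = c("simulate", "features", "cluster",
                                  "summarize"),
                       noise_sd = 0.3, separation = 1,
                       archetype_overrides = list()) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(seed = seed, out_dir = out_dir,
                 n_per_type = n_per_type, k_max = k_max,
                 stages = stages, noise_sd = noise_sd,
                 separation = separation,
                 archetype_overrides = archetype_overrides),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Fields mirror the arguments of [run_config()]; absent fields take
#' the defaults.
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, y)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

apply_overrides <- function(archs, overrides) {
  for (nm in names(overrides))
    for (f in names(overrides[[nm]]))
      archs[[nm]][[f]] <- overrides[[nm]][[f]]
  archs
}

#' Run the e-type classification pipeline end to end
#'
#' Simulates (or accepts) a labelled population, extracts the seven
#' firing features per cell, fits the e-type model with elbow-selected
#' k and writes the feature table, model summary, per-e-type waveform
#' aggregate (Table-2-style), and a provenance record (config hash,
#' seed, package version) into the run directory. Deterministic under
#' a fixed seed.
#'
#' @param config A [run_config()].
#' @param population Optional pre-built `"l7_population"`; when absent
#'   and the `"simulate"` stage is requested one is generated.
#' @return Invisibly, a list with `population`, `features`, `model`,
#'   `summary` and `paths` of the written files.
#' @export
run_etype_pipeline <- function(config = run_config(),
                               population = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  prov <- list(config_hash = hash, seed = config$seed,
               package_version = as.character(
                 utils::packageVersion("l7ephys")))
  paths <- list()
  if ("simulate" %in% config$stages && is.null(population)) {
    archs <- apply_overrides(archetype_defaults(),
                             config$archetype_overrides)
    population <- simulate_population(config$n_per_type,
                                      seed = config$seed,
                                      archetypes = archs,
                                      noise_sd = config$noise_sd,
                                      separation = config$separation)
  }
  if (is.null(population)) stop("no population provided or simulated")
  features <- model <- summ <- NULL
  if ("features" %in% config$stages) {
    features <- do.call(rbind, lapply(population$cells,
                                      firing_pattern_features))
    paths$features <- file.path(config$out_dir, "features.tsv")
    write_feature_table(features, paths$features)
  }
  if ("cluster" %in% config$stages) {
    if (is.null(features)) stop("cluster stage requires features stage")
    seven <- features[, c("cell_id", "max_rate", "adaptation_index",
                          "isi_cv", "accommodation", "burst", "pause",
                          "delay")]
    model <- fit_etype_model(seven, k_max = config$k_max,
                             seed = config$seed)
    paths$model <- file.path(config$out_dir, "etype_model.json")
    jsonlite::write_json(
      c(prov, list(k = model$k, labels = model$labels,
                   centroids = model$centroids,
                   inertia_curve = model$inertia_curve,
                   explained_variance = model$explained_variance)),
      paths$model, auto_unbox = TRUE, digits = NA)
  }
  if ("summarize" %in% config$stages) {
    if (is.null(model)) stop("summarize stage requires cluster stage")
    summ <- etype_summary_table(features, model$labels)
    paths$summary <- file.path(config$out_dir, "etype_summary.tsv")
    write_feature_table(summ, paths$summary)
  }
  paths$provenance <- file.path(config$out_dir, "provenance.json")
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE)
  invisible(list(population = population, features = features,
                 model = model, summary = summ, paths = paths,
                 provenance = prov))
}

#' Per-e-type aggregate of waveform and firing metrics
#'
#' Mean and SD per cluster of the waveform metrics (width, amplitude,
#' threshold, repolarization, AHP) and firing features, the same
#' shape as the published per-e-type AP statistics table.
#'
#' @param features Per-cell feature data frame (from
#'   [firing_pattern_features()]).
#' @param labels Cluster label per cell.
#' @return Data frame, one row per cluster.
#' @export
etype_summary_table <- function(features, labels) {
  stopifnot(nrow(features) == length(labels))
  num <- names(features)[vapply(features, is.numeric, TRUE)]
  num <- setdiff(num, "firing")
  res <- lapply(sort(unique(labels)), function(l) {
    sub <- features[labels == l, num, drop = FALSE]
    row <- data.frame(cluster = l, n = nrow(sub))
    for (f in num) {
      row[[paste0(f, "_mean")]] <- mean(sub[[f]], na.rm = TRUE)
      row[[paste0(f, "_sd")]] <- stats::sd(sub[[f]], na.rm = TRUE)
    }
    row
  })
  do.call(rbind, res)
}

check_same_run <- function(provenances) {
  h <- vapply(provenances, `[[`, character(1), "config_hash")
  if (length(unique(h)) > 1)
    stop("refusing to mix outputs from different run configurations")
  invisible(h[1])
}

#' Paired control-versus-drug comparison report
#'
#' Collates, for matched cells recorded in control and drug
#' conditions: per-current-step paired F-I differences with two-sided
#' paired t tests (Bonferroni-corrected across steps), an optional
#' V50 comparison by the extra-sum-of-squares F test, and an optional
#' PSC amplitude-distribution comparison by the two-sample KS test.
#'
#' @param control_fi,drug_fi Named lists (by cell id) of F-I data
#'   frames from [fi_curve()]; ids must match.
#' @param control_family,drug_family Optional `"current_family"`
#'   objects for the activation-curve comparison.
#' @param control_amps,drug_amps Optional PSC amplitude samples.
#' @param alpha Significance level (applied after correction).
#' @return Object of class `"paired_report"` with `fi` (per-step data
#'   frame: mean delta, SD, t, raw and Bonferroni-corrected p),
#'   `activation` (F-test output or `NULL`), `ks` (or `NULL`) and
#'   `n_cells`.
#' @export
paired_condition_report <- function(control_fi, drug_fi,
                                    control_family = NULL,
                                    drug_family = NULL,
                                    control_amps = NULL,
                                    drug_amps = NULL, alpha = 0.05) {
  ids <- names(control_fi)
  if (!identical(sort(ids), sort(names(drug_fi))))
    stop("unmatched cell ids between conditions")
  steps <- control_fi[[1]]$current
  delta <- sapply(ids, function(id) {
    a <- control_fi[[id]]; b <- drug_fi[[id]]
    if (!identical(a$current, b$current)) stop("current grids differ")
    b$rate - a$rate
  })
  delta <- matrix(delta, nrow = length(steps))
  tt <- apply(delta, 1, function(d) {
    if (stats::sd(d) == 0)
      return(c(t = NA_real_, p = if (all(d == 0)) 1 else NA_real_))
    ht <- stats::t.test(d)
    c(t = unname(ht$statistic), p = ht$p.value)
  })
  fi <- data.frame(current = steps,
                   mean_delta = rowMeans(delta),
                   sd_delta = apply(delta, 1, stats::sd),
                   t = tt["t", ], p = tt["p", ])
  fi$p_bonferroni <- pmin(1, fi$p * length(steps))
  fi$significant <- !is.na(fi$p_bonferroni) & fi$p_bonferroni < alpha
  act <- if (!is.null(control_family) && !is.null(drug_family))
    compare_activation_fits(control_family, drug_family) else NULL
  ks <- if (!is.null(control_amps) && !is.null(drug_amps))
    compare_amplitude_distributions(control_amps, drug_amps) else NULL
  structure(list(fi = fi, activation = act, ks = ks,
                 n_cells = length(ids),
                 correction_factor = length(steps)),
            class = "paired_report")
}

#' @export
print.paired_report <- function(x, ...) {
  cat(sprintf("<paired_report> %d matched cells, %d current steps\n",
              x$n_cells, nrow(x$fi)))
  sig <- x$fi[x$fi$significant & !is.na(x$fi$significant), ]
  if (nrow(sig))
    for (r in seq_len(nrow(sig)))
      cat(sprintf("  %g pA: mean delta %.2f Hz (corrected p = %.3g)\n",
                  sig$current[r], sig$mean_delta[r],
                  sig$p_bonferroni[r]))
  else cat("  no significant F-I differences after correction\n")
  if (!is.null(x$activation))
    cat(sprintf("  V50 shift %.2f mV (F = %.2f, p = %.3g)\n",
                x$activation$v50_shift, x$activation$F,
                x$activation$p))
  if (!is.null(x$ks))
    cat(sprintf("  amplitude KS D = %.3f, p = %.3g\n",
                x$ks$D, x$ks$p))
  invisible(x)
}

#' Serialize a paired report as JSON
#'
#' @param report A `"paired_report"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paired_report <- function(report, path) {
  out <- list(fi = report$fi, n_cells = report$n_cells,
              correction_factor = report$correction_factor)
  if (!is.null(report$activation))
    out$activation <- list(F = report$activation$F,
                           p = report$activation$p,
                           v50_shift = report$activation$v50_shift)
  if (!is.null(report$ks))
    out$ks <- list(D = report$ks$D, p = report$ks$p)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
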