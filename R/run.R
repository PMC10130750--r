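# Config-driven entry points tying the pipeline together. Each runner
# takes a YAML/JSON config file (or an equivalent named list), validates
# it, writes its outputs plus a provenance JSON sufficient to re-run the
# command, and refuses to overwrite an existing output directory unless
# `force` is set.

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s",
                                           config))
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a file path or a named list")
  config
}

require_fields <- function(config, fields) {
  miss <- setdiff(fields, names(config))
  if (length(miss))
    stop(sprintf("config is missing required field(s): %s",
                 paste(miss, collapse = ", ")))
}

params_from_config <- function(config) {
  p <- config$params %||% list()
  defaults <- formals(model_parameters)
  known <- names(defaults)
  unknown <- setdiff(names(p), known)
  if (length(unknown))
    stop(sprintf("unknown parameter field(s): %s",
                 paste(unknown, collapse = ", ")))
  do.call(model_parameters, p)
}

prepare_out_dir <- function(out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !isTRUE(force))
    stop(sprintf("output directory '%s' exists and is not empty; use force = TRUE",
                 out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out_dir
}

write_provenance <- function(out_dir, subcommand, config) {
  prov <- list(subcommand = subcommand,
               config = config,
               config_hash = .fnv1a(deparse(config)),
               package_version = as.character(
                 utils::packageVersion("kip2traffic")),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prov)
}

#' Run a traffic simulation from a configuration
#'
#' Wraps [gillespie_simulate()] / [simulate_kymograph()]. Required config
#' fields: `out_dir`, `length_nm`, `seed`; optional: `params` (a list of
#' [model_parameters()] fields), `n_frames`, `frame_interval`,
#' `mean_field` (also solve the deterministic steady state), `force`.
#' Writes `kymograph.csv` (frames x sites), `mean_occupancy.csv`, and a
#' provenance JSON.
#'
#' @param config path to a YAML/JSON file or a named list.
#' @return Invisibly, a list with the kymograph and occupancy results.
#' @export
run_simulate <- function(config) {
  config <- read_run_config(config)
  require_fields(config, c("out_dir", "length_nm", "seed"))
  params <- params_from_config(config)
  lattice <- build_lattice(config$length_nm,
                           config$site_size_nm %||% 8)
  out_dir <- prepare_out_dir(config$out_dir, config$force %||% FALSE)
  kymo <- simulate_kymograph(params, lattice,
                             n_frames = config$n_frames %||% 80L,
                             frame_interval = config$frame_interval %||% 1.07,
                             seed = config$seed)
  write.csv(as.data.frame(kymo), file.path(out_dir, "kymograph.csv"),
            row.names = FALSE)
  run <- attr(kymo, "run")
  out <- list(kymograph = kymo, mean_occupancy = run$mean_occupancy)
  if (isTRUE(config$mean_field)) {
    mf <- mean_field_steady_state(params, lattice)
    out$mean_field <- mf
    write.csv(data.frame(site = seq_along(mf$mean_occupancy),
                         occupancy = mf$mean_occupancy),
              file.path(out_dir, "mean_field_occupancy.csv"),
              row.names = FALSE)
  }
  write.csv(data.frame(site = seq_along(run$mean_occupancy),
                       occupancy = run$mean_occupancy),
            file.path(out_dir, "mean_occupancy.csv"), row.names = FALSE)
  write_provenance(out_dir, "simulate", config)
  invisible(out)
}

#' Fit the traffic model to a directory of line-scan CSVs
#'
#' Wraps the profile pipeline end to end: read per-cell line scans, align
#' to the SPB marker peak, bin by length, and sample the likelihood.
#' Required config fields: `input_dir`, `out_dir`, `seed`; optional:
#' `ranges`, `n_samples`, `params` (fixed parameters), `bin_width_nm`,
#' `force`. Writes `samples.csv` (one row per draw), `summary.json`, and
#' provenance.
#'
#' @param config path to a YAML/JSON file or a named list.
#' @return Invisibly, the `genotype_fit`.
#' @export
run_fit <- function(config) {
  config <- read_run_config(config)
  require_fields(config, c("input_dir", "out_dir", "seed"))
  files <- list.files(config$input_dir, pattern = "\\.csv$",
                      full.names = TRUE)
  files <- files[!grepl("truth", basename(files))]
  if (!length(files))
    stop(sprintf("no line-scan CSV files in '%s'", config$input_dir))
  profiles <- lapply(files, read_line_scan_csv)
  aligned <- lapply(profiles, align_to_reference_peak)
  dataset <- bin_by_length(aligned,
                           bin_width_nm = config$bin_width_nm %||% 266.7)
  ranges <- config$ranges %||% default_parameter_ranges()
  ranges <- lapply(ranges, as.numeric)
  fit <- fit_genotype(dataset, list(
    ranges = ranges, n_samples = config$n_samples %||% 20000L,
    seed = config$seed, fixed_params = params_from_config(config),
    n_walkers = config$n_walkers %||% 32L,
    burn_in = config$burn_in %||% 150L))
  out_dir <- prepare_out_dir(config$out_dir, config$force %||% FALSE)
  write.csv(as.data.frame(fit$samples$draws),
            file.path(out_dir, "samples.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(summary = fit$summary$table, ranges = ranges,
         rhat = as.list(fit$samples$rhat),
         acceptance = fit$samples$acceptance,
         provenance = fit$provenance),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, dataframe = "rows")
  write_provenance(out_dir, "fit", config)
  invisible(fit)
}

#' Quantify dynamic instability for a directory of track CSVs
#'
#' Wraps the dynamics pipeline over every track file. Required config
#' fields: `input_dir`, `out_dir`; optional: `limit_nm`,
#' `frame_interval_s`, `min_displacement_um`, `min_duration_frames`,
#' `force`. Writes a per-track TSV of summaries (tracks whose length never
#' exceeds the detection limit are reported with 0 um, not skipped) and a
#' cohort aggregate JSON.
#'
#' @param config path to a YAML/JSON file or a named list.
#' @return Invisibly, the list of per-track `dynamics_summary` objects.
#' @export
run_quantify <- function(config) {
  config <- read_run_config(config)
  require_fields(config, c("input_dir", "out_dir"))
  files <- list.files(config$input_dir, pattern = "\\.csv$",
                      full.names = TRUE)
  files <- files[!grepl("truth", basename(files))]
  if (!length(files))
    stop(sprintf("no track CSV files in '%s'", config$input_dir))
  summaries <- lapply(files, function(f) {
    summarize_track(read_track_csv(f),
                    limit_nm = config$limit_nm %||% 666.7,
                    frame_interval_s = config$frame_interval_s %||% 1.07,
                    min_displacement_um = config$min_displacement_um %||% 0.3,
                    min_duration_frames = config$min_duration_frames %||% 3L)
  })
  tab <- do.call(rbind, lapply(summaries, function(s) data.frame(
    track_id = s$track_id, kept = s$kept,
    max_length_um = s$max_length_um, lifetime_s = s$lifetime_s,
    n_phases = if (is.null(s$phases)) 0L else nrow(s$phases),
    n_catastrophes = if (is.null(s$frequencies)) 0L else
      s$frequencies$n_catastrophes,
    n_rescues = if (is.null(s$frequencies)) 0L else
      s$frequencies$n_rescues,
    catastrophe_per_min = if (is.null(s$frequencies)) NA_real_ else
      s$frequencies$catastrophe_per_min,
    rescue_per_min = if (is.null(s$frequencies)) NA_real_ else
      s$frequencies$rescue_per_min)))
  out_dir <- prepare_out_dir(config$out_dir, config$force %||% FALSE)
  utils::write.table(tab, file.path(out_dir, "dynamics_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  kept <- tab[tab$kept, , drop = FALSE]
  aggregate <- list(
    n_tracks = nrow(tab), n_kept = nrow(kept),
    detectable_fraction = mean(kept$max_length_um > 0),
    max_length_um = list(mean = mean(kept$max_length_um),
                         sd = sd(kept$max_length_um)),
    lifetime_s = list(mean = mean(kept$lifetime_s),
                      sd = sd(kept$lifetime_s)),
    max_length_histogram_um = as.list(table(cut(kept$max_length_um,
                                                seq(0, 5, by = 0.5)))))
  jsonlite::write_json(aggregate, file.path(out_dir, "aggregate.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_provenance(out_dir, "quantify", config)
  invisible(summaries)
}

#' Generate synthetic datasets from a configuration
#'
#' Wraps [generate_profiles()] and [generate_tracks()]. Required config
#' fields: `out_dir`, `kind` ("profiles" or "tracks"), `seed`; remaining
#' fields are forwarded to the matching generator config.
#'
#' @param config path to a YAML/JSON file or a named list.
#' @return Invisibly, the generator result.
#' @export
run_generate <- function(config) {
  config <- read_run_config(config)
  require_fields(config, c("out_dir", "kind", "seed"))
  out_dir <- prepare_out_dir(config$out_dir, config$force %||% FALSE)
  res <- if (config$kind == "profiles") {
    extra <- config[intersect(names(config),
                              names(formals(profile_generator_config)))]
    extra$params <- params_from_config(config)
    extra$seed <- config$seed
    generate_profiles(do.call(profile_generator_config, extra), out_dir)
  } else if (config$kind == "tracks") {
    extra <- config[intersect(names(config),
                              names(formals(track_generator_config)))]
    extra$seed <- config$seed
    generate_tracks(do.call(track_generator_config, extra), out_dir)
  } else stop("kind must be 'profiles' or 'tracks'")
  write_provenance(out_dir, "generate", config)
  invisible(res)
}
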