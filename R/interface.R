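#' Read a progress-curve CSV
#'
#' Expects columns `time_s` and `conc_mM` (comment lines starting with `#`
#' are ignored), the exchange format for the fitting routines.
#'
#' @param path Path to the CSV file.
#' @return Data frame with `time_s`, `conc_mM`.
#' @export
read_progress_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time_s", "conc_mM")
  if (!all(need %in% names(df))) {
    stop(sprintf("CSV must contain columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  df[need]
}

#' Write a time course as CSV with a JSON metadata sidecar
#'
#' The CSV carries a `# units:` comment header; the sidecar
#' (`<path>.meta.json`) records the units, the generating parameters and the
#' package version.
#'
#' @param tc A `time_course` from [simulate_network()].
#' @param path Output CSV path.
#' @param overwrite Allow replacing an existing file (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tc, path, overwrite = FALSE) {
  stopifnot(inherits(tc, "time_course"))
  .check_overwrite(path, overwrite)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# units: time_s = s; species = mM; ee, yield, oxidized_fraction = dimensionless",
             con)
  utils::write.csv(as.data.frame(tc), con, row.names = FALSE)
  spec <- attr(tc, "spec")
  meta <- list(units = list(time = "s", concentration = "mM"),
               topology = spec$topology,
               parameters = spec[setdiff(names(spec), "topology")],
               package_version = as.character(utils::packageVersion("redoxmotor")))
  sidecar <- paste0(path, ".meta.json")
  .check_overwrite(sidecar, overwrite)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a rate fit as a JSON record
#'
#' @param fit A `rate_fit`.
#' @param path Optional output path; if `NULL`, returns the JSON string.
#' @param overwrite Allow replacing an existing file.
#' @return The JSON string (invisibly if written to a file).
#' @export
fit_to_json <- function(fit, path = NULL, overwrite = FALSE) {
  stopifnot(inherits(fit, "rate_fit"))
  rec <- list(estimate = fit$estimate, stderr = fit$stderr, n = fit$n,
              r_squared = fit$r_squared, method = fit$method,
              flagged = fit$flagged)
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  .check_overwrite(path, overwrite)
  writeLines(js, path)
  invisible(js)
}

.check_overwrite <- function(path, overwrite) {
  if (file.exists(path) && !overwrite) {
    stop(sprintf("refusing to overwrite existing output '%s' (set overwrite = TRUE)",
                 path), call. = FALSE)
  }
  invisible(TRUE)
}

# stable per-stage seed derived from the run seed and the stage label, so
# adding a stage never perturbs another stage's draws
stage_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

.pipeline_stages <- c("generate", "fit_rates", "simulate_network",
                      "simulate_motor", "estimate_ee", "report")

#' Run the demonstration analysis pipeline
#'
#' Executes the package's stages end to end on a configuration: generate
#' synthetic measurements, fit the elementary rates, simulate the
#' deterministic network, run the stochastic motor ensemble, estimate the
#' oxidation ee/KIE from isotopomer integrals, and write a report manifest.
#' Every output records its units and the seed that produced it; per-stage
#' seeds are derived from the run seed and the stage label, so the pipeline
#' is bit-reproducible and stages are independent of one another's draws.
#'
#' @param config A YAML/JSON file path or a list. Required keys: `seed`,
#'   `output_dir`. Optional: `stages` (subset of
#'   generate, fit_rates, simulate_network, simulate_motor, estimate_ee,
#'   report), `n_molecules`, `hours`,
#'   `overwrite`.
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json` in the output directory): inputs, parameters, seeds,
#'   package version, output file MD5 hashes and per-stage timings.
#' @examples
#' \donttest{
#' out <- file.path(tempdir(), "motor-demo")
#' run_pipeline(list(seed = 1, output_dir = out, n_molecules = 1e4))
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("`config` must be a list or a YAML/JSON path",
                             call. = FALSE)
  required <- c("seed", "output_dir")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop(sprintf("config is missing required key(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  stages <- config$stages %||% .pipeline_stages
  bad <- setdiff(stages, .pipeline_stages)
  if (length(bad)) {
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  seed <- as.integer(config$seed)
  out_dir <- config$output_dir
  overwrite <- isTRUE(config$overwrite)
  n_mol <- config$n_molecules %||% 1e4
  hours <- config$hours %||% 48
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- rate_parameters()
  outputs <- character()
  timings <- list()
  artifacts <- list()
  run_stage <- function(label, fn) {
    if (!label %in% stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    fn(stage_seed(seed, label))
    timings[[label]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }

  run_stage("generate", function(s) {
    red <- gen_reduction_progress(seed = s)
    ox <- gen_oxidation_progress(seed = s + 1L)
    nmr <- gen_nmr_integrals(noise_sd = 0.02, seed = s + 2L)
    for (nm in c("reduction_progress", "oxidation_progress")) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      .check_overwrite(p, overwrite)
      d <- if (nm == "reduction_progress") red else ox
      con <- file(p, "w"); writeLines("# units: time_s = s; conc_mM = mM", con)
      utils::write.csv(d, con, row.names = FALSE); close(con)
      outputs <<- c(outputs, p)
    }
    p <- file.path(out_dir, "nmr_integrals.csv")
    .check_overwrite(p, overwrite)
    utils::write.csv(nmr, p, row.names = FALSE)
    outputs <<- c(outputs, p)
    artifacts$generated <<- list(reduction = red, oxidation = ox, nmr = nmr)
  })

  run_stage("fit_rates", function(s) {
    g <- artifacts$generated
    red <- g$reduction %||% gen_reduction_progress(seed = stage_seed(seed, "generate"))
    ox <- g$oxidation %||% gen_oxidation_progress(seed = stage_seed(seed, "generate") + 1L)
    fit_red <- fit_pseudo_first_order_reduction(red$time_s, red$conc_mM,
                                                fuel_conc = 100)
    fit_ox <- fit_pseudo_zero_order(ox$time_s, ox$conc_mM)
    for (nm in c("fit_k_red2", "fit_v_ox")) {
      p <- file.path(out_dir, paste0(nm, ".json"))
      fit_to_json(if (nm == "fit_k_red2") fit_red else fit_ox, p,
                  overwrite = overwrite)
      outputs <<- c(outputs, p)
    }
    artifacts$fits <<- list(k_red2 = fit_red, v_ox = fit_ox)
  })

  run_stage("simulate_network", function(s) {
    sp <- network_spec("deracemization", selectivity_s = 30)
    st <- network_state(sp, conc_total = 10, fuel0 = 100)
    tc <- simulate_network(sp, st, seq(0, hours * 3600, length.out = 49))
    p <- file.path(out_dir, "deracemization_timecourse.csv")
    write_timecourse_csv(tc, p, overwrite = overwrite)
    outputs <<- c(outputs, p, paste0(p, ".meta.json"))
    artifacts$network <<- tc
  })

  run_stage("simulate_motor", function(s) {
    cfg <- motor_sim_config(n_mol, t_end = hours * 3600, seed = s)
    res <- simulate_motor(params, cfg)
    p <- file.path(out_dir, "motor_summary.json")
    .check_overwrite(p, overwrite)
    jsonlite::write_json(
      list(mean_rotations = res$mean_rotations, sd = res$sd_rotations,
           se = res$se_rotations, n_cycles_mean = res$n_cycles_mean,
           n_molecules = res$n_molecules, seed = cfg$seed,
           racemization = cfg$racemization, fuel_model = cfg$fuel_model,
           units = list(rotations = "full 360 turns", time = "s")),
      p, auto_unbox = TRUE, digits = NA)
    ph <- file.path(out_dir, "motor_histogram.csv")
    .check_overwrite(ph, overwrite)
    utils::write.csv(res$histogram, ph, row.names = FALSE)
    outputs <<- c(outputs, p, ph)
    artifacts$motor <<- res
  })

  run_stage("estimate_ee", function(s) {
    nmr <- artifacts$generated$nmr %||%
      gen_nmr_integrals(noise_sd = 0.02, seed = stage_seed(seed, "generate") + 2L)
    obs <- collapse_nmr_replicates(nmr)
    est <- bootstrap_ci(obs$Sa, obs$Ra, n_boot = 2000, seed = s)
    p <- file.path(out_dir, "ee_estimate.json")
    .check_overwrite(p, overwrite)
    jsonlite::write_json(
      list(selectivity_s = est$selectivity_s, ee = est$ee, kie = est$kie,
           ci_ee = as.numeric(est$ci_ee), conf = attr(est$ci_ee, "conf"),
           method = est$method, seed = s),
      p, auto_unbox = TRUE, digits = NA)
    outputs <<- c(outputs, p)
    artifacts$ee <<- est
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("redoxmotor")),
    seed = seed,
    stage_seeds = stats::setNames(
      lapply(stages, function(st) stage_seed(seed, st)), stages),
    parameters = unclass(params),
    stages = stages,
    outputs = as.list(tools::md5sum(outputs)),
    timings = timings
  )
  p <- file.path(out_dir, "manifest.json")
  .check_overwrite(p, overwrite)
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
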