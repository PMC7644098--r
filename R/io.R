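#' Load and validate a simulation configuration file
#'
#' Reads a YAML configuration with blocks `kinetics`, `expression`,
#' `environment`, `schedule`, `population`, `logging` and `seed`, applies
#' package defaults for anything omitted, validates every field, and
#' returns a [sim_config()] object. Unknown keys are rejected so typos
#' cannot silently fall back to defaults. Units are normalised internally
#' to hours, grams, mM and mmol per gram; the scheduler interval is given
#' in minutes in the file.
#'
#' @param path path to the YAML file.
#' @return a `craswitch_config` with the attribute `seed` (or `NA`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- yaml::read_yaml(path)
  known_blocks <- c("kinetics", "expression", "environment", "schedule",
                    "population", "logging", "seed")
  bad <- setdiff(names(doc), known_blocks)
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))

  kin_over <- doc$kinetics %||% list()
  kin <- do.call(default_kinetics, kin_over)

  expr <- take_keys(doc$expression %||% list(),
                    c("eta2_constitutive", "mean_copies", "gamma_p_ai"),
                    "expression")
  env <- take_keys(doc$environment %||% list(),
                   c("substrate_start", "S_in_glucose", "S_in_acetate", "D",
                     "kappa"), "environment")
  sch <- take_keys(doc$schedule %||% list(),
                   c("mode", "switch_time", "period", "random_mean", "t_end",
                     "stop_on_fixation"), "schedule")
  if (!is.null(sch$mode)) { sch$schedule <- sch$mode; sch$mode <- NULL }
  pop <- doc$population %||% list()
  logging <- take_keys(doc$logging %||% list(), c("log_every_min"), "logging")

  groups <- if (!is.null(pop$groups)) {
    do.call(rbind, lapply(pop$groups, function(g) {
      as.data.frame(take_keys(g, c("n0", "K_cra_fbp", "eta2_cra", "label"),
                              "population$groups"))
    }))
  } else {
    data.frame(n0 = pop$n0 %||% 2000, K_cra_fbp = pop$K_cra_fbp %||% 0.1,
               eta2_cra = pop$eta2_cra %||% 0.2)
  }

  args <- c(list(kinetics = kin, groups = groups), expr, env, sch, logging)
  cfg <- do.call(sim_config, args)
  attr(cfg, "seed") <- doc$seed %||% NA_integer_
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

take_keys <- function(block, allowed, where) {
  bad <- setdiff(names(block), allowed)
  if (length(bad))
    stop("unknown key(s) in [", where, "]: ", paste(bad, collapse = ", "))
  block
}

#' Write a configuration to a YAML file
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, f))` restores
#' an identical configuration.
#'
#' @param config a `craswitch_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  cfg <- config
  doc <- list(
    kinetics = unclass(cfg$kinetics),
    expression = list(eta2_constitutive = cfg$eta2_constitutive,
                      mean_copies = cfg$mean_copies,
                      gamma_p_ai = cfg$gamma_p_ai),
    environment = list(substrate_start = cfg$substrate_start,
                       S_in_glucose = cfg$S_in_glucose,
                       S_in_acetate = cfg$S_in_acetate,
                       D = cfg$D, kappa = cfg$kappa),
    schedule = list(mode = cfg$schedule, switch_time = cfg$switch_time,
                    period = cfg$period, random_mean = cfg$random_mean,
                    t_end = cfg$t_end,
                    stop_on_fixation = cfg$stop_on_fixation),
    population = list(groups = lapply(seq_len(nrow(cfg$groups)), function(i)
      as.list(cfg$groups[i, c("n0", "K_cra_fbp", "eta2_cra", "label")]))),
    logging = list(log_every_min = cfg$log_every * cfg$dt * 60))
  seed <- attr(cfg, "seed")
  if (!is.null(seed) && !is.na(seed)) doc$seed <- seed
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Write run outputs to a directory
#'
#' Writes the trajectory log as a tidy CSV (one row per logged time), each
#' per-cell snapshot as its own CSV, and a JSON manifest carrying the full
#' resolved parameter set, the seed, and the stop reason, so a run can be
#' replayed bit-identically from its manifest.
#'
#' @param run a `craswitch_run`.
#' @param out_dir output directory (created if missing).
#' @param seed the seed the run was started with (stored in the manifest).
#' @param prefix file-name prefix.
#' @return named character vector of the files written.
#' @export
write_run_outputs <- function(run, out_dir, seed = NA_integer_,
                              prefix = "run") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- c(log = file.path(out_dir, paste0(prefix, "_log.csv")),
             manifest = file.path(out_dir, paste0(prefix, "_manifest.json")))
  write.csv(run$log, files[["log"]], row.names = FALSE)
  cfg <- run$config
  manifest <- list(
    package = "craswitch",
    version = as.character(utils::packageVersion("craswitch")),
    seed = seed,
    kinetics = unclass(cfg$kinetics),
    groups = cfg$groups,
    environment = list(substrate_start = cfg$substrate_start,
                       S_in_glucose = cfg$S_in_glucose,
                       S_in_acetate = cfg$S_in_acetate, D = cfg$D,
                       kappa = cfg$kappa, dt = cfg$dt),
    schedule = list(mode = cfg$schedule, switch_time = cfg$switch_time,
                    period = cfg$period, t_end = cfg$t_end),
    stop_reason = run$stop_reason,
    t_stop = run$t_stop)
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (i in seq_along(run$snapshots)) {
    s <- run$snapshots[[i]]
    f <- file.path(out_dir, sprintf("%s_snapshot_%03d.csv", prefix, i))
    df <- data.frame(time = s$time, group = s$group, B = s$B, pep = s$pep,
                     fbp = s$fbp, mu = s$mu)
    df <- cbind(df, as.data.frame(s$counts))
    write.csv(df, f, row.names = FALSE)
    files[[paste0("snapshot_", i)]] <- f
  }
  files
}
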