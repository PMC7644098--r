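#' Relative fitness from a competition
#'
#' The log change in frequency of the focal population relative to the
#' reference over a competition: `w = ln((N1/N0) / (N1'/N0'))`. Zero means
#' equal growth; the measure is antisymmetric under swapping focal and
#' reference.
#'
#' @param N0,N1 focal population counts at start and end.
#' @param N0p,N1p reference counts at start and end.
#' @return relative fitness (dimensionless).
#' @export
#' @examples
#' competitive_fitness(1000, 2000, 1000, 1000)  # log(2)
competitive_fitness <- function(N0, N1, N0p, N1p) {
  counts <- c(N0 = N0, N1 = N1, N0p = N0p, N1p = N1p)
  if (any(!is.finite(counts)))
    stop("all four counts must be finite")
  if (any(counts <= 0)) {
    zero <- names(counts)[counts <= 0][1]
    side <- if (zero %in% c("N0", "N1")) "focal" else "reference"
    stop("fitness undefined: ", side, " population count ", zero, " is ",
         counts[[zero]])
  }
  log((N1 / N0) / (N1p / N0p))
}

#' Competitive fitness assay between two populations
#'
#' Mixes a focal and a reference subpopulation (1000 cells each by default)
#' in one chemostat, grows them for two days on glucose followed by two days
#' on acetate, and measures the relative fitness of the focal group from the
#' change in frequency over the four days.
#'
#' @param focal,reference lists with `K_cra_fbp` and `eta2_cra` describing
#'   the two competitors.
#' @param replicates number of replicate competitions.
#' @param n0 starting cells per competitor.
#' @param kinetics,eta2_constitutive,mean_copies,kappa,D shared model
#'   settings (see [sim_config()]).
#' @param t_glucose,t_acetate phase durations (h).
#' @return data.frame with one row per replicate: start/end counts for both
#'   groups, the fitness `w`, and an `extinct` flag (such replicates have
#'   `w = NA` and are excluded from summary means with a warning).
#' @export
run_competition_assay <- function(focal, reference = list(K_cra_fbp = 0.1,
                                                          eta2_cra = 0.2),
                                  replicates = 10, n0 = 1000,
                                  kinetics = default_kinetics(),
                                  eta2_constitutive = 0.2, mean_copies = 100,
                                  kappa = 3.4e8, D = 0.08,
                                  t_glucose = 48, t_acetate = 48) {
  groups <- data.frame(
    n0 = c(n0, n0),
    K_cra_fbp = c(focal$K_cra_fbp, reference$K_cra_fbp),
    eta2_cra = c(focal$eta2_cra, reference$eta2_cra),
    label = c("focal", "reference"))
  cfg <- sim_config(kinetics = kinetics, groups = groups,
                    eta2_constitutive = eta2_constitutive,
                    mean_copies = mean_copies, kappa = kappa, D = D,
                    schedule = "single_switch", switch_time = t_glucose,
                    t_end = t_glucose + t_acetate, log_every_min = 60)
  out <- lapply(seq_len(replicates), function(r) {
    run <- run_simulation(cfg)
    log <- run$log
    N0 <- log$n_focal[1]; N1 <- log$n_focal[nrow(log)]
    N0p <- log$n_reference[1]; N1p <- log$n_reference[nrow(log)]
    extinct <- N1 == 0 || N1p == 0
    w <- if (extinct) NA_real_ else competitive_fitness(N0, N1, N0p, N1p)
    data.frame(replicate = r, N0 = N0, N1 = N1, N0p = N0p, N1p = N1p,
               w = w, extinct = extinct)
  })
  res <- do.call(rbind, out)
  if (any(res$extinct))
    warning(sum(res$extinct), " replicate(s) lost one competitor; their w is NA")
  res
}

#' Bottleneck and recovery statistics after a substrate switch
#'
#' From a logged trajectory, extracts the smallest population size after the
#' switch to acetate and the time needed to rebound to carrying capacity.
#' Carrying capacity is defined as the mean population size over the last
#' `cc_window` hours of the trajectory, and recovery as the first
#' post-minimum time the size enters the band capacity * (1 - cc_tol).
#'
#' @param run a `craswitch_run`, or a data.frame with columns `time` and
#'   `n_total`.
#' @param switch_time time of the glucose-to-acetate switch (h); defaults to
#'   the run's first acetate epoch.
#' @param cc_window window for the carrying-capacity estimate (h).
#' @param cc_tol relative half-width of the carrying-capacity band.
#' @param column which population-size column to analyse.
#' @return list with `min_size`, `t_min`, `carrying_capacity`, `t_recover`
#'   (h after the switch; `NA` with `censored = TRUE` if the trajectory
#'   never re-enters the band).
#' @export
bottleneck_stats <- function(run, switch_time = NULL, cc_window = 12,
                             cc_tol = 0.05, column = "n_total") {
  log <- if (inherits(run, "craswitch_run")) run$log else run
  if (is.null(switch_time)) {
    if (inherits(run, "craswitch_run")) {
      win <- first_acetate_window(run$substrate_in, run$config$dt)
      switch_time <- win[1]
    } else stop("switch_time must be given for a bare trajectory")
  }
  if (!all(c("time", column) %in% names(log)))
    stop("trajectory must have columns 'time' and '", column, "'")
  n <- log[[column]]
  after <- log$time > switch_time
  if (!any(after)) stop("trajectory does not span the switch")
  min_size <- min(n[after])
  t_min <- log$time[after][which.min(n[after])]
  cc_idx <- log$time >= max(log$time) - cc_window
  cc <- mean(n[cc_idx])
  rec <- after & log$time >= t_min & n >= cc * (1 - cc_tol)
  if (any(rec)) {
    t_recover <- log$time[rec][1] - switch_time
    censored <- FALSE
  } else {
    t_recover <- NA_real_
    censored <- TRUE
  }
  list(min_size = min_size, t_min = t_min, carrying_capacity = cc,
       t_recover = t_recover, censored = censored)
}

#' Growth-rate distribution of a population snapshot
#'
#' Returns per-cell specific growth rates and classifies the snapshot as
#' unimodal or bimodal by occupancy of the two basins of the deterministic
#' circuit: cells are assigned to the growing mode if their growth rate
#' exceeds `threshold_frac` of the deterministic growing-state rate on the
#' snapshot's substrate, and the distribution is called bimodal when both
#' modes hold at least `min_occupancy` of the cells.
#'
#' @param snapshot one element of a run's `snapshots` list (needs `mu`), or
#'   a numeric vector of growth rates.
#' @param mu_growing deterministic growing-state growth rate used for the
#'   threshold; compute it with [find_steady_states()].
#' @param threshold_frac fraction of `mu_growing` separating the modes.
#' @param min_occupancy minimum fraction per mode to call bimodality.
#' @return list with `mu`, `threshold`, `frac_growing`, `frac_nongrowing`,
#'   `bimodal`.
#' @export
growth_rate_distribution <- function(snapshot, mu_growing,
                                     threshold_frac = 0.1,
                                     min_occupancy = 0.01) {
  mu <- if (is.list(snapshot)) snapshot$mu else snapshot
  if (!length(mu)) stop("empty snapshot")
  thr <- threshold_frac * mu_growing
  fg <- mean(mu > thr)
  list(mu = mu, threshold = thr, frac_growing = fg, frac_nongrowing = 1 - fg,
       bimodal = fg >= min_occupancy && (1 - fg) >= min_occupancy)
}

#' Dwell times of lineages in the growing and nongrowing states
#'
#' Classifies each time point of each lineage growth-rate series as growing
#' (`mu > threshold`) or nongrowing, extracts maximal runs, and drops the
#' first and last run of every lineage (both are censored by the observation
#' window).
#'
#' @param mu matrix of growth rates (rows = times, columns = lineages) as
#'   returned by [run_lineages()], or a single numeric series.
#' @param time time points (h) matching the rows of `mu`.
#' @param threshold growth-rate threshold (h^-1) separating the states.
#' @return list with vectors `growing` and `nongrowing` of completed dwell
#'   times (h), and the per-state means (`NA` if no completed runs).
#' @export
lineage_dwell_times <- function(mu, time, threshold) {
  if (is.null(dim(mu))) mu <- matrix(mu, ncol = 1)
  if (length(time) != nrow(mu)) stop("time must match rows of mu")
  dt <- diff(time)
  if (length(unique(round(dt, 9))) > 1) stop("time must be evenly spaced")
  step <- dt[1]
  growing <- numeric(0); nongrowing <- numeric(0)
  for (j in seq_len(ncol(mu))) {
    state <- mu[, j] > threshold
    r <- rle(state)
    if (length(r$lengths) <= 2) next   # only censored runs
    keep <- 2:(length(r$lengths) - 1)
    dur <- r$lengths[keep] * step
    grow <- r$values[keep]
    growing <- c(growing, dur[grow])
    nongrowing <- c(nongrowing, dur[!grow])
  }
  list(growing = growing, nongrowing = nongrowing,
       mean_growing = if (length(growing)) mean(growing) else NA_real_,
       mean_nongrowing = if (length(nongrowing)) mean(nongrowing) else NA_real_,
       threshold = threshold)
}

#' Competition of two Cra alleles to fixation
#'
#' Simulates populations in which all cells share one Cra expression noise
#' level but carry one of two alleles (Cra-fbp dissociation constants),
#' starting at a given frequency, in an environment that switches between
#' glucose and acetate every two days. Runs until one allele fixes (or a
#' hard time cap). Records the relative fitness of the beneficial allele
#' over the first four days, the per-allele bottleneck minima during the
#' first acetate epoch, and the fixation outcome.
#'
#' @param wildtype_K,beneficial_K the two dissociation constants (mmol/g).
#' @param eta2 shared Cra expression noise.
#' @param start_frequency initial frequency of the beneficial allele.
#' @param replicates number of replicate runs.
#' @param n_total total starting cells.
#' @param period environment switching period (h).
#' @param max_days hard cap on the run length (days).
#' @param kinetics,eta2_constitutive,mean_copies,kappa,D model settings.
#' @return data.frame, one row per replicate: `w4` (fitness over the first
#'   four days), `min_wt`, `min_ben` (first-acetate bottleneck minima),
#'   `log_ratio` (log of beneficial/wild-type minima), `outcome`
#'   (`"fixed"`, `"lost"` or `"censored"`), `t_fix_days`,
#'   `survived_first_switch`.
#' @export
run_allele_competition <- function(wildtype_K = 0.05, beneficial_K = 0.07,
                                   eta2 = 0.2, start_frequency = 0.5,
                                   replicates = 10, n_total = 2000,
                                   period = 48, max_days = 100,
                                   kinetics = default_kinetics(),
                                   eta2_constitutive = 0.2, mean_copies = 100,
                                   kappa = 3.4e8, D = 0.08) {
  if (start_frequency <= 0 || start_frequency >= 1)
    stop("start_frequency must be in (0, 1)")
  n_ben <- round(n_total * start_frequency)
  groups <- data.frame(n0 = c(n_total - n_ben, n_ben),
                       K_cra_fbp = c(wildtype_K, beneficial_K),
                       eta2_cra = eta2,
                       label = c("wt", "ben"))
  cfg <- sim_config(kinetics = kinetics, groups = groups,
                    eta2_constitutive = eta2_constitutive,
                    mean_copies = mean_copies, kappa = kappa, D = D,
                    schedule = "periodic", period = period,
                    t_end = max_days * 24, stop_on_fixation = TRUE,
                    log_every_min = 60)
  out <- lapply(seq_len(replicates), function(r) {
    run <- run_simulation(cfg)
    log <- run$log
    i4 <- which(log$time >= 96)[1]
    if (is.na(i4)) i4 <- nrow(log)
    w4 <- if (log$n_ben[i4] > 0 && log$n_wt[i4] > 0)
      competitive_fitness(n_ben, log$n_ben[i4], n_total - n_ben, log$n_wt[i4])
    else NA_real_
    min_wt <- run$min_first_acetate[["wt"]]
    min_ben <- run$min_first_acetate[["ben"]]
    lr <- if (isTRUE(min_wt > 0) && isTRUE(min_ben > 0))
      log(min_ben / min_wt) else NA_real_
    outcome <- if (run$stop_reason != "fixation") "censored"
    else if (identical(run$winner, "ben")) "fixed" else "lost"
    first_ace_end <- first_acetate_window(run$substrate_in, cfg$dt)[2]
    ben_after <- log$n_ben[log$time >= min(first_ace_end, max(log$time))]
    data.frame(replicate = r, w4 = w4, min_wt = min_wt, min_ben = min_ben,
               log_ratio = lr, outcome = outcome,
               t_fix_days = if (outcome == "fixed") run$t_fix / 24 else NA_real_,
               survived_first_switch = length(ben_after) > 0 && ben_after[1] > 0)
  })
  do.call(rbind, out)
}

#' Fixation of a beneficial allele starting from a single mutant
#'
#' Repeats the allele competition with the beneficial allele starting as a
#' single cell in a population of `n_total`, and estimates the fixation
#' probability as the fraction of replicates in which it fixes.
#'
#' @inheritParams run_allele_competition
#' @return list with `p_fix`, `n_fixed`, `n_survived_first_switch`, and the
#'   per-replicate data.frame `results`.
#' @export
run_fixation_experiment <- function(wildtype_K = 0.05, beneficial_K = 0.07,
                                    eta2 = 0.2, replicates = 20,
                                    n_total = 2000, period = 48,
                                    max_days = 100,
                                    kinetics = default_kinetics(),
                                    eta2_constitutive = 0.2,
                                    mean_copies = 100,
                                    kappa = 3.4e8, D = 0.08) {
  if (replicates < 1) stop("replicates must be >= 1")
  res <- run_allele_competition(wildtype_K, beneficial_K, eta2,
                                start_frequency = 1 / n_total,
                                replicates = replicates, n_total = n_total,
                                period = period, max_days = max_days,
                                kinetics = kinetics,
                                eta2_constitutive = eta2_constitutive,
                                mean_copies = mean_copies, kappa = kappa,
                                D = D)
  list(p_fix = mean(res$outcome == "fixed"),
       n_fixed = sum(res$outcome == "fixed"),
       n_survived_first_switch = sum(res$survived_first_switch),
       results = res)
}

#' Fitness landscape over noise and Cra-fbp binding strength
#'
#' Competes every combination of Cra expression noise and Cra-fbp
#' dissociation constant against one fixed reference (by default
#' intermediate noise 0.2 and intermediate dissociation constant 0.125
#' mmol/g) and returns the mean and sd of relative fitness per grid cell.
#'
#' @param eta2_levels noise levels of the focal populations.
#' @param K_values Cra-fbp dissociation constants of the focal populations.
#' @param reference list with the reference `K_cra_fbp` and `eta2_cra`.
#' @param replicates replicates per grid cell.
#' @param ... further arguments passed to [run_competition_assay()].
#' @return data.frame with `eta2`, `K`, `mean_w`, `sd_w`, `n_ok`.
#' @export
fitness_landscape <- function(eta2_levels = c(0.01, 0.2, 10),
                              K_values = c(0.05, 0.1, 0.125),
                              reference = list(K_cra_fbp = 0.125,
                                               eta2_cra = 0.2),
                              replicates = 5, ...) {
  grid <- expand.grid(eta2 = eta2_levels, K = K_values)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    res <- run_competition_assay(
      focal = list(K_cra_fbp = grid$K[i], eta2_cra = grid$eta2[i]),
      reference = reference, replicates = replicates, ...)
    ok <- !is.na(res$w)
    data.frame(eta2 = grid$eta2[i], K = grid$K[i],
               mean_w = mean(res$w[ok]), sd_w = sd(res$w[ok]),
               n_ok = sum(ok))
  })
  do.call(rbind, out)
}

#' Ai copy-number distribution of an equilibrated population
#'
#' Grows a population on one substrate long enough to equilibrate, then
#' records the acetate-enzyme copy number of every cell.
#'
#' @param eta2_cra Cra expression noise.
#' @param K_cra_fbp Cra-fbp dissociation constant.
#' @param substrate substrate fed throughout.
#' @param t_equilibrate equilibration time (h).
#' @param n0 starting cells.
#' @param ... further settings passed to [sim_config()].
#' @return list with `ai` (per-cell Ai counts), `mu` (per-cell growth
#'   rates) and `n_cells`.
#' @export
protein_snapshot <- function(eta2_cra = 0.2, K_cra_fbp = 0.1,
                             substrate = "acetate", t_equilibrate = 100,
                             n0 = 500, ...) {
  if (t_equilibrate <= 0) stop("t_equilibrate must be > 0")
  cfg <- sim_config(groups = data.frame(n0 = n0, K_cra_fbp = K_cra_fbp,
                                        eta2_cra = eta2_cra),
                    substrate_start = substrate, schedule = "constant",
                    t_end = t_equilibrate, log_every_min = 60, ...)
  run <- run_simulation(cfg, snapshot_times = t_equilibrate)
  snap <- run$snapshots[[length(run$snapshots)]]
  list(ai = snap$counts[, "Ai"], mu = snap$mu, n_cells = length(snap$mu))
}
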