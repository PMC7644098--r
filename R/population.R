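#' Create an initial population for a configuration
#'
#' Builds the agent table: one cell per row of size `n0` per group, with
#' masses spread over the cell cycle (`B0 * 2^U`), protein counts drawn from
#' the stationary negative binomial and scaled to cell mass, and metabolite
#' pools at the configured initial concentrations. When the run starts on
#' glucose the acetate enzyme Ai starts at zero copies (the Cra regulon is
#' off in glucose); a 48 h equilibration phase is part of every standard
#' experiment design, so initial details are quickly forgotten.
#'
#' @param config a [sim_config()] object.
#' @return population list with `B`, `pep`, `fbp`, `counts`, `group`,
#'   `lineage`.
#' @export
new_population <- function(config) {
  cfg <- config
  kin <- cfg$kinetics
  tabs <- group_tables(cfg)
  ntot <- sum(cfg$groups$n0)
  on_glc <- cfg$substrate_start == "glucose"
  init_pep <- if (is.null(cfg$init_pep)) (if (on_glc) 0.01 else 0.4) else cfg$init_pep
  init_fbp <- if (is.null(cfg$init_fbp)) (if (on_glc) 2.0 else 0.05) else cfg$init_fbp

  B <- pep <- fbp <- lineage <- numeric(ntot)
  group <- integer(ntot)
  counts <- matrix(0, ntot, length(GENES), dimnames = list(NULL, GENES))
  i0 <- 0
  for (g in seq_len(nrow(cfg$groups))) {
    n <- cfg$groups$n0[g]
    if (n == 0) next
    idx <- i0 + seq_len(n)
    B[idx] <- kin$B0 * 2^runif(n)
    pep[idx] <- init_pep
    fbp[idx] <- init_fbp
    group[idx] <- g - 1L   # 0-based for the engine
    for (gene in GENES) {
      if (gene == "Ai" && on_glc) next   # regulon off in glucose
      a <- tabs$alpha[g, gene]; b <- tabs$beta[g, gene]
      nb <- rnbinom(n, size = a, prob = 1 / (1 + b))
      counts[idx, gene] <- round(nb * B[idx] / kin$B0)
    }
    i0 <- i0 + n
  }
  lineage <- seq_len(ntot)
  list(B = B, pep = pep, fbp = fbp, counts = counts, group = group,
       lineage = lineage)
}

# inflow identity per scheduler step: 0 = glucose, 1 = acetate
schedule_vector <- function(cfg) {
  n_steps <- as.integer(round(cfg$t_end / cfg$dt))
  start <- if (cfg$substrate_start == "glucose") 0L else 1L
  other <- 1L - start
  if (n_steps == 0) return(integer(0))
  tmid <- (seq_len(n_steps)) * cfg$dt   # state during step s applies at t in ((s-1)dt, s dt]
  switch(cfg$schedule,
    constant = rep(start, n_steps),
    single_switch = ifelse(tmid <= cfg$switch_time + 1e-9, start, other),
    periodic = ifelse(((ceiling(tmid / cfg$period - 1e-9) - 1) %% 2) == 0,
                      start, other),
    random = {
      # exponential epoch lengths, mean random_mean, alternating substrates
      out <- integer(n_steps)
      t <- 0; cur <- start; i <- 1
      while (i <= n_steps) {
        len <- stats::rexp(1, 1 / cfg$random_mean)
        upto <- min(n_steps, as.integer(ceiling((t + len) / cfg$dt)))
        if (upto >= i) out[i:upto] <- cur
        t <- t + len; cur <- 1L - cur; i <- upto + 1L
      }
      out
    })
}

# first interval of acetate inflow, used for bottleneck statistics
first_acetate_window <- function(substrate_in, dt) {
  ia <- which(substrate_in == 1L)
  if (!length(ia)) return(c(NA_real_, NA_real_))
  from <- (ia[1] - 1) * dt
  iend <- ia[1]
  while (iend < length(substrate_in) && substrate_in[iend + 1] == 1L)
    iend <- iend + 1
  c(from, iend * dt)
}

#' Update the chemostat substrate pool over one interval
#'
#' Applies the through-flow balance for one substrate pool: exponential
#' relaxation toward the influx concentration (exact for the linear
#' inflow/outflow part) minus the debit of the summed cellular uptake,
#' `S <- S_in + (S - S_in) exp(-D dt) - kappa * uptake`.
#'
#' @param S current concentration (mM).
#' @param S_in influx concentration of this substrate (0 if the inflowing
#'   medium carries the other carbon source).
#' @param D dilution rate (h^-1).
#' @param kappa mM change per mmol taken up.
#' @param uptake summed cellular uptake over the interval (mmol).
#' @param dt interval (h).
#' @return updated concentration; an error if uptake overdraws the pool by
#'   more than 1% (the step is too coarse), clipped at zero below that.
#' @export
substrate_step <- function(S, S_in, D, kappa, uptake, dt = 1 / 60) {
  check_nonneg(S = S, S_in = S_in, D = D, uptake = uptake)
  out <- S_in + (S - S_in) * exp(-D * dt) - kappa * uptake
  if (out < 0) {
    if (-out > 0.01 * (S + 1e-12))
      stop("substrate overshoot: uptake exceeds pool by more than 1% in one step")
    warning("substrate pool clipped at 0 (uptake slightly overshot)")
    out <- 0
  }
  out
}

#' Random washout of cells
#'
#' Each cell is independently flushed out with probability
#' `1 - exp(-D dt)`, blind to allele, state and mass.
#'
#' @param pop population list (see [new_population()]).
#' @param D dilution rate (h^-1).
#' @param dt interval (h).
#' @return surviving population.
#' @export
washout_cells <- function(pop, D, dt = 1 / 60) {
  if (D * dt >= 1) stop("D * dt must be < 1")
  n <- length(pop$B)
  if (n == 0 || D <= 0) return(pop)
  keep <- runif(n) < exp(-D * dt)
  subset_pop(pop, keep)
}

#' Divide all cells that have doubled their mass
#'
#' Every cell with `B >= 2 B0` is replaced by two daughters of half its
#' mass. Metabolite concentrations are per-mass quantities and are inherited
#' unchanged; each protein is assigned to a daughter by a fair coin
#' ([partition_proteins()]); allele and noise group are inherited; the new
#' daughter receives a fresh lineage id.
#'
#' @param pop population list.
#' @param B0 newborn mass (g).
#' @return population after division.
#' @export
divide_cells <- function(pop, B0) {
  div <- which(pop$B >= 2 * B0)
  if (!length(div)) return(pop)
  lin0 <- max(pop$lineage)
  add <- list(B = pop$B[div] / 2, pep = pop$pep[div], fbp = pop$fbp[div],
              counts = matrix(0, length(div), ncol(pop$counts),
                              dimnames = list(NULL, colnames(pop$counts))),
              group = pop$group[div],
              lineage = lin0 + seq_along(div))
  for (i in seq_along(div)) {
    sp <- partition_proteins(pop$counts[div[i], ])
    pop$counts[div[i], ] <- sp$daughter1
    add$counts[i, ] <- sp$daughter2
  }
  pop$B[div] <- pop$B[div] / 2
  list(B = c(pop$B, add$B), pep = c(pop$pep, add$pep),
       fbp = c(pop$fbp, add$fbp), counts = rbind(pop$counts, add$counts),
       group = c(pop$group, add$group), lineage = c(pop$lineage, add$lineage))
}

subset_pop <- function(pop, keep) {
  list(B = pop$B[keep], pep = pop$pep[keep], fbp = pop$fbp[keep],
       counts = pop$counts[keep, , drop = FALSE], group = pop$group[keep],
       lineage = pop$lineage[keep])
}

#' One scheduler step of the full population model
#'
#' Applies, in order: (i) per-cell ODE integration and the substrate
#' balance, (ii) stochastic protein production (and active degradation if
#' configured), (iii) random washout, (iv) division at doubled mass. The
#' order matters and is part of the model definition.
#'
#' @param pop population list.
#' @param env list with `glucose`, `acetate` (mM) and `substrate_in`
#'   (`"glucose"` or `"acetate"`, the inflowing source).
#' @param config a [sim_config()].
#' @return list with updated `pop`, `env`, and the step audit counters
#'   `n_washed`, `n_divided`, `uptake_glucose`, `uptake_acetate`.
#' @export
step_population <- function(pop, env, config) {
  cfg <- config
  tabs <- group_tables(cfg)
  S_in_glc <- if (env$substrate_in == "glucose") cfg$S_in_glucose else 0
  S_in_ace <- if (env$substrate_in == "acetate") cfg$S_in_acetate else 0
  res <- cpp_step(pop, unclass(cfg$kinetics), tabs, env$glucose, env$acetate,
                  S_in_glc, S_in_ace, cfg$D, cfg$kappa, cfg$dt,
                  max(pop$lineage, 0))
  env$glucose <- res$glucose
  env$acetate <- res$acetate
  list(pop = res$pop, env = env, n_washed = res$n_washed,
       n_divided = res$n_divided, uptake_glucose = res$uptake_glucose,
       uptake_acetate = res$uptake_acetate)
}

#' Run a population simulation
#'
#' Executes the configured schedule with the one-minute scheduler. The run
#' is deterministic given the R random seed (`set.seed()` before calling).
#'
#' @param config a [sim_config()].
#' @param population optional starting population; defaults to
#'   [new_population()] from the configuration.
#' @param snapshot_times times (h) at which to record per-cell snapshots
#'   (mass, metabolites, growth rate, protein counts).
#' @return object of class `craswitch_run`: a list with
#'   \describe{
#'     \item{log}{data.frame of time, per-group population sizes
#'       (`n_<label>`), total size, substrate concentrations, washout and
#'       division counters.}
#'     \item{snapshots}{list of per-cell snapshots.}
#'     \item{final_pop}{the final population.}
#'     \item{stop_reason}{`"horizon"`, `"fixation"` or `"extinction"`.}
#'     \item{t_stop, t_fix, winner}{stopping time, fixation time and the
#'       label of the fixed group (if any).}
#'     \item{min_first_acetate, min_overall}{per-group minimum sizes, per
#'       scheduler step, during the first acetate epoch / the whole run.}
#'   }
#' @export
#' @examples
#' \donttest{
#' cfg <- sim_config(groups = data.frame(n0 = 200, K_cra_fbp = 0.1,
#'                                       eta2_cra = 0.2),
#'                   kappa = 8.3e9, t_end = 2)
#' set.seed(1)
#' run <- run_simulation(cfg)
#' tail(run$log)
#' }
run_simulation <- function(config, population = NULL,
                           snapshot_times = numeric(0)) {
  cfg <- config
  pop <- if (is.null(population)) new_population(cfg) else population
  subs <- schedule_vector(cfg)
  tabs <- group_tables(cfg)
  win <- first_acetate_window(subs, cfg$dt)
  glc0 <- if (cfg$substrate_start == "glucose") cfg$S_in_glucose else 0
  ace0 <- if (cfg$substrate_start == "acetate") cfg$S_in_acetate else 0
  snap_steps <- round(snapshot_times / cfg$dt) * cfg$dt
  res <- cpp_run(pop, unclass(cfg$kinetics), tabs, subs, glc0, ace0,
                 cfg$S_in_glucose, cfg$S_in_acetate, cfg$D, cfg$kappa,
                 cfg$dt, cfg$log_every, snap_steps, cfg$stop_on_fixation,
                 if (is.na(win[1])) Inf else win[1],
                 if (is.na(win[2])) Inf else win[2])
  labels <- cfg$groups$label
  log <- as.data.frame(res$log)
  nmat <- res$n_by_group
  colnames(nmat) <- paste0("n_", labels)
  log <- cbind(log[, "time", drop = FALSE], as.data.frame(nmat),
               n_total = rowSums(nmat),
               log[, c("glucose", "acetate", "n_washed", "n_divided")])
  structure(list(
    log = log,
    snapshots = res$snapshots,
    final_pop = res$final_pop,
    stop_reason = res$stop_reason,
    t_stop = res$t_stop,
    t_fix = res$t_fix,
    winner = if (!is.na(res$winner_group)) labels[res$winner_group] else NA_character_,
    min_first_acetate = setNames(as.numeric(res$min_bottleneck), labels),
    min_overall = setNames(as.numeric(res$min_overall), labels),
    substrate_in = subs,
    config = cfg), class = "craswitch_run")
}

#' @export
print.craswitch_run <- function(x, ...) {
  n <- nrow(x$log)
  cat("craswitch run:", format(x$t_stop), "h simulated,",
      x$log$n_total[n], "cells at end, stop reason:", x$stop_reason, "\n")
  invisible(x)
}

#' Follow single cell lineages on a fixed substrate
#'
#' Simulates a fixed cohort of independent lineages at a constant substrate
#' concentration: no washout is applied, and at every division one daughter
#' is retained uniformly at random. Used for dwell-time analysis of the
#' growing and nongrowing states on acetate.
#'
#' @param n_lineages number of lineages.
#' @param substrate `"acetate"` or `"glucose"`.
#' @param concentration substrate concentration (mM), held constant.
#' @param t_end duration (h).
#' @param eta2_cra Cra expression noise.
#' @param K_cra_fbp Cra-fbp dissociation constant (allele).
#' @param kinetics kinetic parameters.
#' @param eta2_constitutive noise of the constitutive enzymes.
#' @param mean_copies mean copies per newborn.
#' @param log_every_min cadence of the growth-rate log (minutes).
#' @param dt_min scheduler interval (minutes).
#' @return list with `time` (h) and `mu`, a matrix of specific growth rates
#'   with one column per lineage.
#' @export
run_lineages <- function(n_lineages = 100, substrate = "acetate",
                         concentration = 20, t_end = 500,
                         eta2_cra = 0.2, K_cra_fbp = NULL,
                         kinetics = default_kinetics(),
                         eta2_constitutive = 0.2, mean_copies = 100,
                         log_every_min = 60, dt_min = 1) {
  if (n_lineages < 1) stop("n_lineages must be >= 1")
  if (is.null(K_cra_fbp)) K_cra_fbp <- kinetics$K_Cra_fbp
  cfg <- sim_config(kinetics = kinetics,
                    groups = data.frame(n0 = n_lineages,
                                        K_cra_fbp = K_cra_fbp,
                                        eta2_cra = eta2_cra),
                    eta2_constitutive = eta2_constitutive,
                    mean_copies = mean_copies,
                    substrate_start = "glucose",  # glucose-like initial state
                    dt_min = dt_min, t_end = t_end, schedule = "constant")
  pop <- new_population(cfg)
  tabs <- group_tables(cfg)
  glc <- if (substrate == "glucose") concentration else 0
  ace <- if (substrate == "acetate") concentration else 0
  n_steps <- as.integer(round(t_end / cfg$dt))
  log_every <- max(1L, as.integer(round(log_every_min / dt_min)))
  res <- cpp_run_lineages(pop, unclass(cfg$kinetics), tabs, glc, ace,
                          cfg$dt, n_steps, log_every)
  list(time = res$time, mu = res$mu, final_pop = res$final_pop)
}
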