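GENES <- c("Gi", "Ai", "Lg", "An", "Cra")

#' Default kinetic parameter set
#'
#' Returns the calibrated default kinetic constants of the four-reaction
#' metabolic model and the Cra circuit. Units: rates in mmol g^-1 h^-1,
#' extracellular half-saturation constants in mM, intracellular ones in
#' mmol g^-1, masses in g, `K_CraA_DNA` in molecules g^-1. The set is a
#' calibration: it is chosen so that the deterministic circuit is bistable on
#' acetate and monostable on glucose, and so that population bottleneck and
#' lag behaviour after a glucose-to-acetate switch falls in realistic ranges
#' (see the methods vignette for the calibration rationale).
#'
#' @param ... named overrides of individual constants.
#' @return A named list of class `craswitch_kinetics`.
#' @export
#' @examples
#' kin <- default_kinetics()
#' kin$c  # biomass yield, g per mmol fbp
default_kinetics <- function(...) {
  kin <- list(
    B0 = 3e-13,          # newborn dry mass (g)
    c = 0.0896,          # biomass yield (g per mmol fbp)
    e_ref = 100,         # reference enzyme copies per newborn cell
    V_Gi = 10, K_Gi = 1.5,      # glucose incorporation (K in mM)
    V_Ai = 36, K_Ai = 0.8,       # acetate incorporation (K in mM)
    V_Lg = 12, K_Lg = 0.5,       # lower glycolysis (K in mmol/g pep)
    V_An = 1773,                 # anabolism max rate at reference enzyme
    K_fbp_An = 3,                # MWC fbp scale (mmol/g)
    K_pep_An = 0.035,            # pep activation scale (mmol/g)
    n_An = 2,                    # MWC cooperativity in fbp
    m_pep_An = 3,                # pep-activation exponent (tense->relaxed)
    L_An = 5000,                 # MWC allosteric constant (tense bias)
    K_Cra_fbp = 0.1,             # Cra-fbp dissociation constant (mmol/g)
    n_Cra = 2,                   # Hill coefficient of Cra repression
    K_CraA_DNA = 6.5e14,         # active-Cra/promoter dissociation (molec/g)
    alpha_Ai_on = 20,            # Ai mRNA rate when Cra-bound (per half-life)
    alpha_Ai_off = 0             # Ai mRNA rate when unbound ("off" state)
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(kin))
    if (length(bad)) stop("unknown kinetic parameter(s): ",
                          paste(bad, collapse = ", "))
    kin[names(over)] <- over
  }
  validate_kinetics(kin)
  structure(kin, class = "craswitch_kinetics")
}

validate_kinetics <- function(kin) {
  pos <- setdiff(names(kin), "alpha_Ai_off")
  for (nm in pos) {
    v <- kin[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("kinetic parameter '", nm, "' must be a single positive number, got ",
           format(v))
  }
  if (kin$alpha_Ai_off < 0) stop("alpha_Ai_off must be >= 0")
  if (kin$n_Cra < 1) stop("n_Cra must be >= 1")
  if (kin$n_An < 1) stop("n_An must be >= 1")
  invisible(kin)
}

#' Per-gene expression parameters
#'
#' Burst parameterisation of stochastic expression for one gene. The
#' stationary copy-number distribution is negative binomial with `alpha`
#' bursts per protein half-life and mean burst size `beta`, so the newborn
#' mean is `alpha * beta` and the nominal expression noise (squared
#' coefficient of variation) is `eta2 = 1/alpha`.
#'
#' @param mean_newborn mean copy number in a newborn cell.
#' @param eta2 nominal expression noise (squared CV), must be > 0.
#' @param gamma_p active degradation rate (h^-1), default 0.
#' @return list with `mean_newborn`, `eta2`, `alpha`, `beta`, `gamma_p`.
#' @export
#' @examples
#' expression_params(100, 0.2)   # alpha = 5, beta = 20
expression_params <- function(mean_newborn = 100, eta2 = 0.2, gamma_p = 0) {
  ab <- nb_parameters(mean_newborn, eta2)
  if (gamma_p < 0) stop("gamma_p must be >= 0")
  list(mean_newborn = mean_newborn, eta2 = eta2,
       alpha = ab[["alpha"]], beta = ab[["beta"]], gamma_p = gamma_p)
}

#' Simulation configuration
#'
#' Assembles a fully validated configuration for [run_simulation()] and the
#' experiment drivers. Groups (subpopulations) differ in their Cra-fbp
#' dissociation constant (the allele) and/or their Cra expression noise.
#'
#' @param kinetics kinetic parameter set, see [default_kinetics()].
#' @param groups data.frame with one row per subpopulation and columns
#'   `n0` (initial cells), `K_cra_fbp` (allele), `eta2_cra` (Cra noise);
#'   optional `label`.
#' @param eta2_constitutive expression noise of the constitutive enzymes
#'   Gi, Lg, An (and the Ai burst size via `mean * eta2`).
#' @param mean_copies mean copy number per newborn cell for every gene.
#' @param gamma_p_ai active degradation rate of Ai (h^-1), default 0.
#' @param substrate_start inflowing carbon source at t = 0.
#' @param S_in_glucose,S_in_acetate influx concentrations (mM).
#' @param D dilution rate (h^-1).
#' @param kappa conversion from cellular uptake (mmol) to medium
#'   concentration change (mM per mmol; the inverse culture volume).
#' @param dt_min scheduler interval in minutes.
#' @param schedule one of `"constant"`, `"single_switch"`, `"periodic"`,
#'   `"random"`.
#' @param switch_time time of the single switch (h).
#' @param period switching period of the periodic schedule (h).
#' @param random_mean mean epoch length of the random schedule (h).
#' @param t_end simulation horizon (h).
#' @param stop_on_fixation stop when only one group remains.
#' @param log_every_min logging cadence in minutes.
#' @param init_pep,init_fbp initial intracellular concentrations (mmol/g);
#'   defaults are near the glucose growth state so that the standard 48 h
#'   glucose equilibration starts close to equilibrium.
#' @return list of class `craswitch_config`.
#' @export
sim_config <- function(kinetics = default_kinetics(),
                       groups = data.frame(n0 = 2000, K_cra_fbp = 0.1,
                                           eta2_cra = 0.2),
                       eta2_constitutive = 0.2,
                       mean_copies = 100,
                       gamma_p_ai = 0,
                       substrate_start = c("glucose", "acetate"),
                       S_in_glucose = 10, S_in_acetate = 20,
                       D = 0.08, kappa = 3.4e8,
                       dt_min = 1,
                       schedule = c("single_switch", "constant", "periodic",
                                    "random"),
                       switch_time = 48, period = 48, random_mean = 48,
                       t_end = 96,
                       stop_on_fixation = FALSE,
                       log_every_min = 1,
                       init_pep = NULL, init_fbp = NULL) {
  substrate_start <- match.arg(substrate_start)
  schedule <- match.arg(schedule)
  validate_kinetics(kinetics)
  if (!is.data.frame(groups) || nrow(groups) < 1)
    stop("groups must be a data.frame with at least one row")
  needed <- c("n0", "K_cra_fbp", "eta2_cra")
  miss <- setdiff(needed, names(groups))
  if (length(miss)) stop("groups is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(groups$n0 < 0) || any(groups$n0 != round(groups$n0)))
    stop("groups$n0 must be nonnegative integers")
  if (any(groups$K_cra_fbp <= 0)) stop("K_cra_fbp must be > 0")
  if (any(groups$eta2_cra <= 0))
    stop("eta2_cra must be > 0 (alpha = 1/eta2 is undefined at 0)")
  if (is.null(groups$label))
    groups$label <- paste0("group", seq_len(nrow(groups)))
  if (eta2_constitutive <= 0) stop("eta2_constitutive must be > 0")
  if (mean_copies <= 0) stop("mean_copies must be > 0")
  if (gamma_p_ai < 0) stop("gamma_p_ai must be >= 0")
  for (nm in c("S_in_glucose", "S_in_acetate")) {
    v <- get(nm)
    if (v < 0) stop(nm, " must be >= 0")
  }
  if (D < 0) stop("dilution rate D must be >= 0")
  if (kappa <= 0) stop("kappa must be > 0")
  if (dt_min <= 0) stop("dt_min must be > 0")
  if (t_end < 0) stop("t_end must be >= 0")
  if (period <= 0) stop("period must be > 0")
  if (random_mean <= 0) stop("random_mean must be > 0")
  if (log_every_min < dt_min) stop("log_every_min must be >= dt_min")

  cfg <- list(kinetics = kinetics, groups = groups,
              eta2_constitutive = eta2_constitutive,
              mean_copies = mean_copies, gamma_p_ai = gamma_p_ai,
              substrate_start = substrate_start,
              S_in_glucose = S_in_glucose, S_in_acetate = S_in_acetate,
              D = D, kappa = kappa, dt = dt_min / 60,
              schedule = schedule, switch_time = switch_time,
              period = period, random_mean = random_mean, t_end = t_end,
              stop_on_fixation = stop_on_fixation,
              log_every = max(1L, as.integer(round(log_every_min / dt_min))),
              init_pep = init_pep, init_fbp = init_fbp)
  structure(cfg, class = "craswitch_config")
}

# per-group expression tables in the layout the C++ engine expects
group_tables <- function(cfg) {
  ng <- nrow(cfg$groups)
  alpha <- beta <- gamma <- matrix(0, ng, length(GENES),
                                   dimnames = list(NULL, GENES))
  for (i in seq_len(ng)) {
    const <- expression_params(cfg$mean_copies, cfg$eta2_constitutive)
    cra <- expression_params(cfg$mean_copies, cfg$groups$eta2_cra[i])
    for (g in c("Gi", "Lg", "An")) {
      alpha[i, g] <- const$alpha; beta[i, g] <- const$beta
    }
    alpha[i, "Cra"] <- cra$alpha; beta[i, "Cra"] <- cra$beta
    # Ai: alpha is regulated at run time (alpha_Ai_on * P_bound); only the
    # burst size is taken from here
    alpha[i, "Ai"] <- cfg$kinetics$alpha_Ai_on
    beta[i, "Ai"] <- cfg$mean_copies / cfg$kinetics$alpha_Ai_on
    gamma[i, "Ai"] <- cfg$gamma_p_ai
  }
  list(K_cra_fbp = cfg$groups$K_cra_fbp, alpha = alpha, beta = beta,
       gamma = gamma)
}
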