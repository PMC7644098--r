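#' Specific reaction rates of the four-reaction metabolic model
#'
#' Computes the specific rates (mmol g^-1 h^-1) of glucose incorporation
#' (Gi), acetate incorporation (Ai), lower glycolysis (Lg) and anabolism
#' (An), plus the specific growth rate `mu = c * J_An`. Gi, Ai and Lg follow
#' Michaelis-Menten kinetics in extracellular glucose, extracellular acetate
#' and intracellular pep respectively; An follows two-state MWC kinetics in
#' fbp, with pep shifting the tense-to-relaxed equilibrium. Every rate scales
#' with the catalysing enzyme's copy-number concentration (count / B)
#' relative to the reference of `e_ref` copies per newborn mass.
#'
#' @param pep,fbp intracellular concentrations (mmol g^-1).
#' @param B cell dry mass (g).
#' @param counts named numeric vector of protein copies with entries
#'   `Gi`, `Ai`, `Lg`, `An`, `Cra`.
#' @param glucose,acetate extracellular concentrations (mM).
#' @param kinetics kinetic parameter set.
#' @return list with `J_Gi`, `J_Ai`, `J_Lg`, `J_An`, `mu`.
#' @export
#' @examples
#' kin <- default_kinetics()
#' cnt <- c(Gi = 100, Ai = 100, Lg = 100, An = 100, Cra = 100)
#' reaction_rates(0.1, 0.05, kin$B0, cnt, glucose = 10, acetate = 0, kin)
reaction_rates <- function(pep, fbp, B, counts, glucose, acetate,
                           kinetics = default_kinetics()) {
  check_nonneg(pep = pep, fbp = fbp, glucose = glucose, acetate = acetate)
  if (B <= 0) stop("cell mass B must be > 0")
  counts <- as_gene_counts(counts)
  if (any(counts < 0)) stop("protein counts must be >= 0")
  cpp_reaction_rates(pep, fbp, B, counts, glucose, acetate,
                     unclass(kinetics))
}

#' Active Cra amount under fbp repression
#'
#' Hill repression of Cra by fbp: `Cra_A = Cra * K^n / (fbp^n + K^n)` with
#' `K = K_Cra_fbp` and `n = n_Cra`. The result is continuous (a time average
#' over fast binding/unbinding), strictly decreasing in fbp, and bounded by
#' the total Cra copy number.
#'
#' @param cra_count total Cra copies in the cell.
#' @param fbp intracellular fbp concentration (mmol g^-1).
#' @param kinetics kinetic parameter set.
#' @param K_cra_fbp allele-specific dissociation constant; defaults to the
#'   value in `kinetics`.
#' @return active Cra amount (continuous, in molecules).
#' @export
#' @examples
#' cra_activity(100, 0.1)  # fbp at the dissociation constant -> 50
cra_activity <- function(cra_count, fbp, kinetics = default_kinetics(),
                         K_cra_fbp = kinetics$K_Cra_fbp) {
  check_nonneg(cra_count = cra_count, fbp = fbp)
  Kn <- K_cra_fbp^kinetics$n_Cra
  cra_count * Kn / (fbp^kinetics$n_Cra + Kn)
}

#' Occupancy of the Ai promoter by active Cra
#'
#' Fraction of time active Cra is bound to the Ai promoter, using the
#' active-Cra concentration (amount divided by cell mass):
#' `P_bound = (Cra_A/B) / (Cra_A/B + K_CraA_DNA)`.
#'
#' @param cra_A active Cra amount (molecules).
#' @param B cell mass (g).
#' @param kinetics kinetic parameter set.
#' @return occupancy in `[0, 1]`.
#' @export
promoter_occupancy <- function(cra_A, B, kinetics = default_kinetics()) {
  check_nonneg(cra_A = cra_A)
  if (any(B <= 0)) stop("cell mass B must be > 0")
  conc <- cra_A / B
  conc / (conc + kinetics$K_CraA_DNA)
}

#' Regulated transcription rate of the acetate uptake enzyme
#'
#' Time-averaged mRNA production rate per protein half-life for Ai:
#' `alpha_Ai = alpha_Ai_off * (1 - P_bound) + alpha_Ai_on * P_bound`.
#' With the default `alpha_Ai_off = 0` the unbound promoter is fully off.
#'
#' @param p_bound promoter occupancy in `[0, 1]`.
#' @param kinetics kinetic parameter set.
#' @return expected mRNA count per protein half-life.
#' @export
ai_transcription_rate <- function(p_bound, kinetics = default_kinetics()) {
  if (any(p_bound < 0 | p_bound > 1)) stop("p_bound must be in [0, 1]")
  kinetics$alpha_Ai_off * (1 - p_bound) + kinetics$alpha_Ai_on * p_bound
}

#' Time derivatives of one cell's state
#'
#' The stoichiometry of the condensed network: two acetate make one pep
#' (minus one CO2), two pep make one fbp, one glucose makes one fbp, and fbp
#' is drained into biomass; intracellular pools are additionally diluted by
#' growth.
#'
#' @param pep,fbp intracellular concentrations (mmol g^-1).
#' @param B cell mass (g).
#' @param rates list with `J_Gi`, `J_Ai`, `J_Lg`, `J_An`, `mu` as returned
#'   by [reaction_rates()].
#' @return list with `dpep`, `dfbp`, `dB`.
#' @export
cell_derivatives <- function(pep, fbp, B, rates) {
  list(dpep = 0.5 * rates$J_Ai - rates$J_Lg - rates$mu * pep,
       dfbp = rates$J_Gi + 0.5 * rates$J_Lg - rates$J_An - rates$mu * fbp,
       dB = rates$mu * B)
}

#' Advance one cell over a scheduler interval
#'
#' Integrates the cell's ODEs (pep, fbp, mass) over `dt` with protein counts
#' and extracellular concentrations held fixed, using an adaptive explicit
#' Runge-Kutta scheme (Cash-Karp 4/5). Also returns the integrated substrate
#' uptake over the interval so the environment pool can be debited.
#'
#' @inheritParams reaction_rates
#' @param dt interval length (h); the scheduler default is 1 minute.
#' @return list with updated `pep`, `fbp`, `B` and `uptake_glucose`,
#'   `uptake_acetate` (mmol).
#' @export
integrate_cell <- function(pep, fbp, B, counts, glucose, acetate, dt = 1 / 60,
                           kinetics = default_kinetics()) {
  check_nonneg(pep = pep, fbp = fbp, glucose = glucose, acetate = acetate)
  if (B <= 0) stop("cell mass B must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  counts <- as_gene_counts(counts)
  cpp_integrate_cell(pep, fbp, B, counts, glucose, acetate, dt,
                     unclass(kinetics))
}

#' Deterministic steady states of the single-cell circuit
#'
#' Finds the fixed points of the deterministic (pep, fbp) subsystem of a cell
#' at newborn mass with enzymes at their mean copy numbers. The Cra-to-Ai
#' feedback is closed by setting the Ai copy number to its regulated
#' quasi-steady mean, `alpha_Ai_on * P_bound(fbp) * beta_Ai`, so the
#' regulatory loop (fbp represses Cra, Cra induces Ai) is retained in the
#' reduction. Roots are located by multi-start damped Newton iteration and
#' classified by the eigenvalues of the numerical Jacobian.
#'
#' @param substrate `"glucose"` or `"acetate"`.
#' @param concentration extracellular substrate concentration (mM).
#' @param kinetics kinetic parameter set.
#' @param K_cra_fbp allele (Cra-fbp dissociation constant, mmol g^-1).
#' @param mean_copies mean enzyme copy number per newborn cell.
#' @param beta_ai mean Ai burst size used for the quasi-steady Ai mean;
#'   defaults to `mean_copies / alpha_Ai_on`, the engine's parameterisation
#'   (full promoter occupancy then gives a mean of `mean_copies`).
#' @param n_starts number of multi-start grid points per axis.
#' @return data.frame with columns `pep`, `fbp`, `mu`, `ai_mean`, `stable`,
#'   ordered by `mu`. Zero rows (with a warning) if no steady state is found.
#' @export
#' @examples
#' find_steady_states("glucose", 10)   # one stable growing state
find_steady_states <- function(substrate = c("acetate", "glucose"),
                               concentration = 20,
                               kinetics = default_kinetics(),
                               K_cra_fbp = kinetics$K_Cra_fbp,
                               mean_copies = 100,
                               beta_ai = mean_copies / kinetics$alpha_Ai_on,
                               n_starts = 8) {
  substrate <- match.arg(substrate)
  glc <- if (substrate == "glucose") concentration else 0
  ace <- if (substrate == "acetate") concentration else 0
  kin <- kinetics
  B <- kin$B0

  ai_mean <- function(fbp) {
    craA <- cra_activity(mean_copies, fbp, kin, K_cra_fbp)
    pb <- promoter_occupancy(craA, B, kin)
    kin$alpha_Ai_on * pb * beta_ai
  }
  fun <- function(x) {
    pep <- max(x[1], 0); fbp <- max(x[2], 0)
    cnt <- c(Gi = mean_copies, Ai = ai_mean(fbp), Lg = mean_copies,
             An = mean_copies, Cra = mean_copies)
    r <- cpp_reaction_rates(pep, fbp, B, cnt, glc, ace, unclass(kin))
    c(0.5 * r$J_Ai - r$J_Lg - r$mu * pep,
      r$J_Gi + 0.5 * r$J_Lg - r$J_An - r$mu * fbp)
  }

  # multi-start on a log-spaced grid spanning the physiological range
  pep_grid <- c(0, 10^seq(-4, 0.5, length.out = n_starts))
  fbp_grid <- c(1e-4, 10^seq(-3, 1.2, length.out = n_starts))
  roots <- list()
  for (p0 in pep_grid) for (f0 in fbp_grid) {
    sol <- try(newton2(fun, c(p0, f0)), silent = TRUE)
    if (inherits(sol, "try-error") || is.null(sol)) next
    if (any(!is.finite(sol)) || any(sol < -1e-8)) next
    sol <- pmax(sol, 0)
    if (max(abs(fun(sol))) > 1e-6) next
    dup <- FALSE
    for (r in roots)
      if (max(abs(r - sol)) < 1e-4 * (1 + max(abs(sol)))) { dup <- TRUE; break }
    if (!dup) roots[[length(roots) + 1]] <- sol
  }
  if (!length(roots)) {
    warning("no steady state found for ", substrate, " at ", concentration,
            " mM")
    return(data.frame(pep = numeric(0), fbp = numeric(0), mu = numeric(0),
                      ai_mean = numeric(0), stable = logical(0)))
  }
  out <- do.call(rbind, lapply(roots, function(x) {
    J <- num_jacobian(fun, x)
    ev <- eigen(J, only.values = TRUE)$values
    cnt <- c(Gi = mean_copies, Ai = ai_mean(x[2]), Lg = mean_copies,
             An = mean_copies, Cra = mean_copies)
    r <- cpp_reaction_rates(x[1], x[2], B, cnt, glc, ace, unclass(kin))
    data.frame(pep = x[1], fbp = x[2], mu = r$mu, ai_mean = cnt[["Ai"]],
               stable = all(Re(ev) < 0))
  }))
  out[order(out$mu), , drop = FALSE]
}

# damped Newton with numerical Jacobian for the 2-d subsystem
newton2 <- function(fun, x0, tol = 1e-12, maxit = 200) {
  x <- x0
  for (i in seq_len(maxit)) {
    fx <- fun(x)
    if (max(abs(fx)) < tol) return(x)
    J <- num_jacobian(fun, x)
    step <- try(solve(J, fx), silent = TRUE)
    if (inherits(step, "try-error")) return(NULL)
    lam <- 1
    repeat {
      xn <- x - lam * step
      xn <- pmax(xn, 0)
      if (max(abs(fun(xn))) < max(abs(fx)) || lam < 1e-6) break
      lam <- lam / 2
    }
    if (max(abs(xn - x)) < 1e-14 * (1 + max(abs(x)))) return(xn)
    x <- xn
  }
  if (max(abs(fun(x))) < 1e-8) x else NULL
}

num_jacobian <- function(fun, x, h = NULL) {
  n <- length(x)
  f0 <- fun(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    hj <- if (is.null(h)) 1e-7 * (abs(x[j]) + 1e-7) else h
    xp <- x; xp[j] <- xp[j] + hj
    J[, j] <- (fun(xp) - f0) / hj
  }
  J
}

# ---- shared input checks --------------------------------------------------

check_nonneg <- function(...) {
  vals <- list(...)
  for (nm in names(vals))
    if (any(!is.finite(vals[[nm]])) || any(vals[[nm]] < 0))
      stop("'", nm, "' must be finite and >= 0")
  invisible(TRUE)
}

as_gene_counts <- function(counts) {
  if (is.null(names(counts))) {
    if (length(counts) != length(GENES))
      stop("counts must be named or of length ", length(GENES))
    names(counts) <- GENES
  }
  miss <- setdiff(GENES, names(counts))
  if (length(miss)) stop("counts is missing gene(s): ",
                         paste(miss, collapse = ", "))
  as.numeric(counts[GENES])
}
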