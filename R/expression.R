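#' Negative-binomial burst parameters from mean and noise
#'
#' Maps a newborn mean copy number and a nominal expression noise level
#' (squared coefficient of variation) to the burst parameters of the
#' stationary negative-binomial copy-number distribution:
#' `alpha = 1/eta2` bursts per protein half-life and `beta = mean * eta2`
#' proteins per burst. The implied NB standard deviation is
#' `sqrt(alpha * beta * (beta + 1))`.
#'
#' @param mean_newborn mean copies in a newborn cell (> 0).
#' @param eta2 nominal noise, squared CV (> 0).
#' @return named vector with `alpha`, `beta`, `sd`.
#' @export
#' @examples
#' nb_parameters(100, 0.01)  # sd ~ 14
#' nb_parameters(100, 10)    # sd ~ 316
nb_parameters <- function(mean_newborn, eta2) {
  if (!is.numeric(mean_newborn) || any(mean_newborn <= 0))
    stop("mean_newborn must be > 0")
  if (!is.numeric(eta2) || any(eta2 <= 0))
    stop("eta2 must be > 0 (alpha = 1/eta2 is undefined otherwise)")
  alpha <- 1 / eta2
  beta <- mean_newborn * eta2
  c(alpha = alpha, beta = beta, sd = sqrt(alpha * beta * (beta + 1)))
}

#' Growth-coupled transcription rate
#'
#' The transcription rate that keeps the mean protein amount per unit mass
#' constant while the cell grows: `k1 = alpha * (mu * B / B0 + gamma_p)`.
#' The dilution term `mu * B / B0` equals `mu` in a newborn and `2 mu` in a
#' cell about to divide, so production compensates the faster dilution late
#' in the cell cycle.
#'
#' @param alpha bursts per protein half-life.
#' @param mu specific growth rate (h^-1).
#' @param B current cell mass (g).
#' @param B0 newborn mass (g).
#' @param gamma_p active degradation rate (h^-1).
#' @return transcription rate k1 (mRNAs h^-1).
#' @export
transcription_rate <- function(alpha, mu, B, B0, gamma_p = 0) {
  check_nonneg(alpha = alpha, mu = mu, B = B, gamma_p = gamma_p)
  if (any(B0 <= 0)) stop("B0 must be > 0")
  alpha * (mu * B / B0 + gamma_p)
}

#' Sample a protein production increment
#'
#' Draws the number of proteins made over `dt`: mRNAs arrive as a Poisson
#' process at rate `k1`, and each mRNA yields a geometric burst on
#' {0, 1, 2, ...} with mean `beta` (success probability `1/(1+beta)`).
#' This burst law is the one under which the stationary copy-number
#' distribution of the production/dilution balance is exactly negative
#' binomial with mean `alpha*beta` and variance `alpha*beta*(beta+1)`.
#'
#' @param k1 transcription rate (mRNAs h^-1).
#' @param beta mean proteins per mRNA.
#' @param dt interval (h).
#' @param n number of independent draws.
#' @return integer vector of production increments.
#' @export
sample_production <- function(k1, beta, dt = 1 / 60, n = 1) {
  check_nonneg(k1 = k1, beta = beta)
  if (dt <= 0) stop("dt must be > 0")
  m <- rpois(n, k1 * dt)
  vapply(m, function(mi) {
    if (mi == 0) return(0)
    sum(rgeom(mi, 1 / (1 + beta)))
  }, numeric(1))
}

#' Stochastic protein decay over an interval
#'
#' Binomial survival: each protein independently survives `dt` with
#' probability `exp(-gamma_p * dt)`.
#'
#' @param count current copy number (nonnegative integer, vectorised).
#' @param gamma_p active degradation rate (h^-1).
#' @param dt interval (h).
#' @return surviving copy number(s).
#' @export
degrade_proteins <- function(count, gamma_p, dt = 1 / 60) {
  check_nonneg(count = count, gamma_p = gamma_p)
  if (any(count != round(count))) stop("count must be integer-valued")
  if (gamma_p == 0) return(count)
  rbinom(length(count), count, exp(-gamma_p * dt))
}

#' Binomial partitioning of proteins at division
#'
#' Each protein molecule is independently assigned to one of the two
#' daughters with probability 1/2; the two daughters always sum exactly to
#' the parent.
#'
#' @param counts named vector of parent copy numbers.
#' @return list with `daughter1` and `daughter2` count vectors.
#' @export
partition_proteins <- function(counts) {
  check_nonneg(counts = counts)
  if (any(counts != round(counts))) stop("counts must be integer-valued")
  d1 <- rbinom(length(counts), counts, 0.5)
  names(d1) <- names(counts)
  list(daughter1 = d1, daughter2 = counts - d1)
}

#' Draw newborn protein counts from the stationary distribution
#'
#' Initialisation helper: draws each gene's copy number from the stationary
#' negative binomial NB(alpha, beta) with mean `alpha * beta`. Only used to
#' seed cells at t = 0; afterwards the production/partitioning dynamics take
#' over.
#'
#' @param mean_newborn mean copies (scalar or per-gene vector).
#' @param eta2 noise level (scalar or per-gene vector).
#' @param n number of cells to draw.
#' @return matrix of counts, `n` rows, one column per gene entry.
#' @export
sample_newborn_proteins <- function(mean_newborn, eta2, n = 1) {
  k <- max(length(mean_newborn), length(eta2))
  mean_newborn <- rep_len(mean_newborn, k)
  eta2 <- rep_len(eta2, k)
  out <- matrix(0L, n, k)
  for (j in seq_len(k)) {
    ab <- nb_parameters(mean_newborn[j], eta2[j])
    # NB(size = alpha, prob = 1/(1+beta)) has mean alpha*beta
    out[, j] <- rnbinom(n, size = ab[["alpha"]], prob = 1 / (1 + ab[["beta"]]))
  }
  if (!is.null(names(mean_newborn))) colnames(out) <- names(mean_newborn)
  out
}
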