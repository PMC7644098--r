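# shared fixtures: everything is generated in code at test time

ref_counts <- function(Ai = 100, Cra = 100) {
  c(Gi = 100, Ai = Ai, Lg = 100, An = 100, Cra = Cra)
}

# small chemostat configuration scaled to a given cell count: kappa is scaled
# so the glucose carrying capacity stays proportional to n0
small_config <- function(n0 = 150, eta2 = 0.2, K = 0.1, scale = 2000 / n0,
                         ...) {
  sim_config(groups = data.frame(n0 = n0, K_cra_fbp = K, eta2_cra = eta2),
             kappa = 3.4e8 * scale, ...)
}

# single-lineage expression simulator at fixed growth rate: the minimal model
# of one gene under growth-coupled bursty production, exponential mass growth
# and binomial partitioning at doubling. Returns newborn copy numbers and
# (count, mass) samples across the cycle.
simulate_expression_lineage <- function(n_generations, mean_newborn = 100,
                                        eta2 = 0.2, mu = 0.7, dt = 1 / 60,
                                        B0 = 3e-13) {
  ab <- nb_parameters(mean_newborn, eta2)
  alpha <- ab[["alpha"]]; beta <- ab[["beta"]]
  B <- B0
  x <- sample_newborn_proteins(mean_newborn, eta2)[1, 1]
  newborn <- numeric(0)
  phase <- count <- numeric(0)
  while (length(newborn) < n_generations) {
    k1 <- transcription_rate(alpha, mu, B, B0)
    x <- x + sample_production(k1, beta, dt)
    B <- B * exp(mu * dt)
    phase <- c(phase, B / B0)
    count <- c(count, x)
    if (B >= 2 * B0) {
      d <- rbinom(1, x, 0.5)
      x <- d
      B <- B / 2
      newborn <- c(newborn, x)
    }
  }
  list(newborn = newborn, phase = phase, count = count)
}
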