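kin <- default_kinetics()

test_that("no substrate and empty pools give zero flux and zero growth", {
  r <- reaction_rates(0, 0, kin$B0, ref_counts(), 0, 0, kin)
  expect_equal(r$J_Gi, 0)
  expect_equal(r$J_Ai, 0)
  expect_equal(r$J_Lg, 0)
  expect_equal(r$J_An, 0)
  expect_equal(r$mu, 0)
})

test_that("growth rate is exactly the biomass yield times the anabolic flux", {
  set.seed(1)
  for (i in 1:25) {
    r <- reaction_rates(runif(1, 0, 1), runif(1, 0, 10), kin$B0 * runif(1, 1, 2),
                        ref_counts(Ai = rpois(1, 100), Cra = rpois(1, 100)),
                        runif(1, 0, 10), runif(1, 0, 20), kin)
    expect_identical(r$mu, kin$c * r$J_An)
  }
  # a unit anabolic flux converts to growth at 0.0896 g per mmol fbp
  f1 <- uniroot(function(f)
    reaction_rates(0.5, f, kin$B0, ref_counts(), 10, 0, kin)$J_An - 1,
    c(1e-4, 50), tol = 1e-12)$root
  r1 <- reaction_rates(0.5, f1, kin$B0, ref_counts(), 10, 0, kin)
  expect_equal(r1$mu, 0.0896, tolerance = 1e-6)
})

test_that("specific rates depend on enzyme concentration, not copy number", {
  r1 <- reaction_rates(0.2, 0.5, kin$B0, ref_counts(), 5, 5, kin)
  r2 <- reaction_rates(0.2, 0.5, 2 * kin$B0, 2 * ref_counts(), 5, 5, kin)
  for (nm in c("J_Gi", "J_Ai", "J_Lg", "J_An", "mu"))
    expect_equal(r1[[nm]], r2[[nm]], tolerance = 1e-12)
})

test_that("anabolic MWC rate is nondecreasing in fbp and in pep", {
  fb <- seq(0, 6, length.out = 20)
  pp <- seq(0, 1, length.out = 20)
  J <- outer(fb, pp, Vectorize(function(f, p)
    reaction_rates(p, f, kin$B0, ref_counts(), 0, 20, kin)$J_An))
  expect_true(all(diff(J) >= -1e-12))        # along fbp
  expect_true(all(t(diff(t(J))) >= -1e-12))  # along pep
})

test_that("negative inputs are rejected with a validation error", {
  expect_error(reaction_rates(-0.1, 0, kin$B0, ref_counts(), 0, 0, kin),
               "finite and >= 0")
  expect_error(reaction_rates(0, 0, 0, ref_counts(), 0, 0, kin), "B must be")
  expect_error(integrate_cell(0, 0, kin$B0, ref_counts(), -1, 0), "finite")
})

test_that("Cra activity follows Hill repression by fbp", {
  expect_equal(cra_activity(100, 0, kin), 100)
  expect_equal(cra_activity(100, kin$K_Cra_fbp, kin), 50)
  expect_equal(cra_activity(0, 0.02, kin), 0)
  f <- seq(0, 2, length.out = 50)
  expect_true(all(diff(cra_activity(100, f, kin)) < 0))
  # linear in the copy number
  expect_equal(cra_activity(250, 0.3, kin), 2.5 * cra_activity(100, 0.3, kin))
})

test_that("promoter occupancy is Michaelis-Menten in active-Cra concentration", {
  expect_equal(promoter_occupancy(0, kin$B0, kin), 0)
  half <- kin$K_CraA_DNA * kin$B0   # amount whose concentration equals K
  expect_equal(promoter_occupancy(half, kin$B0, kin), 0.5)
  expect_equal(promoter_occupancy(1e25, kin$B0, kin), 1, tolerance = 1e-6)
  expect_error(promoter_occupancy(10, 0, kin), "B must be")
  # increasing in cra_A, decreasing in B
  expect_gt(promoter_occupancy(2 * half, kin$B0, kin), 0.5)
  expect_lt(promoter_occupancy(half, 2 * kin$B0, kin), 0.5)
})

test_that("regulated Ai transcription interpolates the on and off rates", {
  expect_equal(ai_transcription_rate(0, kin), 0)  # off state is fully off
  expect_equal(ai_transcription_rate(1, kin), kin$alpha_Ai_on)
  expect_equal(ai_transcription_rate(0.5, kin), kin$alpha_Ai_on / 2)
  expect_error(ai_transcription_rate(1.2, kin), "p_bound")
})

test_that("cell derivatives implement the network stoichiometry", {
  d <- cell_derivatives(0.5, 0.5, kin$B0,
                        list(J_Gi = 0, J_Ai = 2, J_Lg = 1, J_An = 0, mu = 0))
  expect_equal(d$dpep, 0)   # half of the acetate flux feeds pep
  d <- cell_derivatives(0, 0, kin$B0,
                        list(J_Gi = 1, J_Ai = 0, J_Lg = 0, J_An = 0, mu = 0))
  expect_equal(d$dfbp, 1)   # glucose converts 1:1 to fbp
  # steady gluconeogenic flux: 4 acetate -> 2 pep -> 1 fbp -> biomass
  d <- cell_derivatives(0, 0, kin$B0,
                        list(J_Gi = 0, J_Ai = 4, J_Lg = 2, J_An = 1, mu = 0))
  expect_equal(d$dpep, 0)
  expect_equal(d$dfbp, 0)
})

test_that("integration at a fixed point gives closed-form exponential growth", {
  ss <- find_steady_states("glucose", 10, kin)
  g <- ss[ss$stable, ][1, ]
  out <- integrate_cell(g$pep, g$fbp, kin$B0,
                        ref_counts(Ai = g$ai_mean), 10, 0, dt = 1 / 60, kin)
  expect_equal(out$B, kin$B0 * exp(g$mu / 60), tolerance = 1e-7)
  expect_equal(out$fbp, g$fbp, tolerance = 1e-4)
})

test_that("zero substrate and empty pools leave a cell unchanged", {
  out <- integrate_cell(0, 0, kin$B0, ref_counts(), 0, 0, dt = 1 / 60, kin)
  expect_equal(out$B, kin$B0)
  expect_equal(out$pep, 0)
  expect_equal(out$fbp, 0)
  expect_equal(out$uptake_glucose, 0)
  expect_equal(out$uptake_acetate, 0)
})

test_that("reported uptake matches a fine-step oracle and carbon balances", {
  cnt <- ref_counts()
  y <- c(pep = 0.05, fbp = 1.5, B = kin$B0)
  out <- integrate_cell(y[1], y[2], y[3], cnt, 8, 0, dt = 1 / 60, kin)
  # forward-Euler oracle at a 2000x finer step
  h <- (1 / 60) / 2000
  st <- y; up <- 0
  for (i in 1:2000) {
    r <- reaction_rates(st[1], st[2], st[3], cnt, 8, 0, kin)
    up <- up + r$J_Gi * st[3] * h
    st <- st + h * c(0.5 * r$J_Ai - r$J_Lg - r$mu * st[1],
                     r$J_Gi + 0.5 * r$J_Lg - r$J_An - r$mu * st[2],
                     r$mu * st[3])
  }
  expect_equal(out$uptake_glucose, as.numeric(up), tolerance = 1e-3)
  # glucose-only carbon balance: uptake = pool change (in fbp equivalents,
  # pep counts half) + biomass gain / yield
  lhs <- out$uptake_glucose
  rhs <- (out$B * (out$fbp + out$pep / 2) - y[3] * (y[2] + y[1] / 2)) +
    (out$B - y[3]) / kin$c
  expect_equal(as.numeric(lhs), as.numeric(rhs), tolerance = 0.01)
})

test_that("deterministic circuit is monostable on glucose, bistable on acetate", {
  g <- find_steady_states("glucose", 10, kin)
  expect_equal(sum(g$stable), 1)
  expect_gt(g$mu[g$stable], 0.2)

  a <- find_steady_states("acetate", 20, kin)
  st <- a[a$stable, ]
  expect_gte(nrow(st), 2)
  expect_lt(min(st$mu), 0.05)              # nongrowing: high fbp, low pep
  expect_gt(max(st$mu), 0.15)              # growing: low fbp, high pep
  off <- st[which.min(st$mu), ]; on <- st[which.max(st$mu), ]
  expect_gt(off$fbp, on$fbp)
  expect_lt(off$pep, on$pep)
})

test_that("weakening Cra-fbp binding collapses the nongrowing state", {
  sweep <- sapply(c(0.05, 0.1, 0.4), function(K) {
    ss <- find_steady_states("acetate", 20, kin, K_cra_fbp = K)
    sum(ss$stable)
  })
  expect_gte(sweep[1], 2)
  expect_gte(sweep[2], 2)
  expect_equal(sweep[3], 1)   # only the growing state survives weak binding
})
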