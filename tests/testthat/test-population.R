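test_that("substrate pool relaxes to the influx concentration without cells", {
  # inflow balances outflow at S = S_in
  expect_equal(substrate_step(10, 10, D = 0.08, kappa = 3.4e8, uptake = 0), 10)
  # closed-form filling from an empty pool
  S <- 0
  for (i in 1:240) S <- substrate_step(S, 20, 0.08, 3.4e8, 0, dt = 1 / 60)
  expect_equal(S, 20 * (1 - exp(-0.08 * 4)), tolerance = 1e-9)
})

test_that("substrate overdraw is clipped near zero and fatal beyond 1%", {
  expect_warning(out <- substrate_step(1, 0, 0.08, 1, uptake = 1.0005,
                                       dt = 1 / 60), "clipped")
  expect_equal(out, 0)
  expect_error(substrate_step(1, 0, 0.08, 1, uptake = 1.2, dt = 1 / 60),
               "overshoot")
})

test_that("washout is exponential thinning, blind to allele", {
  cfg <- small_config(n0 = 150)
  pop <- new_population(cfg)
  expect_identical(washout_cells(pop, D = 0, dt = 1), pop)
  # survival frequency over many thinning rounds
  set.seed(13)
  big <- sim_config(groups = data.frame(n0 = c(2000, 2000),
                                        K_cra_fbp = c(0.05, 0.1),
                                        eta2_cra = 0.2))
  bp <- new_population(big)
  surv <- washout_cells(bp, D = 0.5, dt = 1)
  p <- exp(-0.5)
  expect_lt(abs(length(surv$B) - 4000 * p), 3 * sqrt(4000 * p * (1 - p)))
  # allele-blind: surviving fraction similar in both groups
  f1 <- mean(surv$group == 0); f2 <- mean(surv$group == 1)
  expect_lt(abs(f1 - f2), 3 * sqrt(0.5 * 0.5 * 2 / length(surv$B)))
})

test_that("cells divide at doubled mass into equal halves", {
  cfg <- small_config(n0 = 20)
  pop <- new_population(cfg)
  pop$B[1:5] <- 2 * cfg$kinetics$B0 * c(1, 1, 1.05, 1, 1)
  tot_before <- colSums(pop$counts)
  set.seed(14)
  out <- divide_cells(pop, cfg$kinetics$B0)
  expect_equal(length(out$B), 25)
  expect_equal(out$B[1], cfg$kinetics$B0)
  expect_equal(out$B[3], 1.05 * cfg$kinetics$B0)  # overshoot mass retained
  expect_equal(colSums(out$counts), tot_before)   # proteins conserved
  # per-mass metabolite concentrations inherited unchanged
  expect_equal(out$pep[21], pop$pep[1])
  expect_equal(out$fbp[21], pop$fbp[1])
})

test_that("runs are deterministic given the seed", {
  cfg <- small_config(n0 = 60, t_end = 3, log_every_min = 1)
  set.seed(99); r1 <- run_simulation(cfg)
  set.seed(99); r2 <- run_simulation(cfg)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$final_pop, r2$final_pop)
})

test_that("cell count changes only through washout and division", {
  cfg <- small_config(n0 = 80, t_end = 4, log_every_min = 1)
  set.seed(15)
  run <- run_simulation(cfg)
  log <- run$log
  n <- log$n_total
  expect_identical(n[-1], n[-length(n)] - log$n_washed[-1] + log$n_divided[-1])
})

test_that("a zero horizon returns only the initial state", {
  cfg <- small_config(n0 = 30, t_end = 0)
  set.seed(16)
  run <- run_simulation(cfg)
  expect_equal(nrow(run$log), 1)
  expect_equal(run$log$n_total, 30)
})

test_that("an empty population leaves substrate-only dynamics", {
  cfg <- sim_config(groups = data.frame(n0 = 0, K_cra_fbp = 0.1,
                                        eta2_cra = 0.2),
                    schedule = "constant", t_end = 2, log_every_min = 30)
  set.seed(17)
  run <- run_simulation(cfg)
  expect_equal(run$stop_reason, "extinction")
  expect_equal(tail(run$log$n_total, 1), 0)
})

test_that("the periodic schedule switches substrate every period", {
  cfg <- small_config(n0 = 5, schedule = "periodic", period = 48, t_end = 150)
  subs <- run_simulation(cfg, population = new_population(cfg))$substrate_in
  dt <- cfg$dt
  expect_true(all(subs[seq_len(48 / dt)] == 0L))
  expect_true(all(subs[(48 / dt + 1):(96 / dt)] == 1L))
  expect_true(all(subs[(96 / dt + 1):(144 / dt)] == 0L))
})

test_that("a glucose population reaches a stable carrying capacity", {
  set.seed(18)
  cfg <- small_config(n0 = 150, schedule = "constant", t_end = 40,
                      log_every_min = 60)
  run <- run_simulation(cfg)
  late <- run$log$n_total[run$log$time >= 28]
  expect_gt(mean(late), 100)
  # fluctuates around a constant: late-phase drift is small
  expect_lt(abs(mean(late[seq_len(6)]) - mean(tail(late, 6))),
            0.2 * mean(late))
})

test_that("at capacity, total uptake balances the chemostat inflow", {
  set.seed(19)
  cfg <- small_config(n0 = 150, schedule = "constant", t_end = 30,
                      log_every_min = 60, dt_min = 0.2)
  run <- run_simulation(cfg)
  env <- list(glucose = tail(run$log$glucose, 1),
              acetate = tail(run$log$acetate, 1), substrate_in = "glucose")
  step <- step_population(run$final_pop, env, cfg)
  uptake_rate <- step$uptake_glucose / cfg$dt
  expect_equal(uptake_rate, cfg$D * (cfg$S_in_glucose - env$glucose) / cfg$kappa,
               tolerance = 0.05)
})

test_that("identical alleles drift symmetrically around frequency one half", {
  set.seed(20)
  devs <- replicate(30, {
    cfg <- sim_config(groups = data.frame(n0 = c(50, 50), K_cra_fbp = 0.1,
                                          eta2_cra = 0.2,
                                          label = c("a", "b")),
                      kappa = 3.4e8 * 40, schedule = "constant", t_end = 8,
                      log_every_min = 120)
    run <- run_simulation(cfg)
    last <- nrow(run$log)
    run$log$n_a[last] / run$log$n_total[last] - 0.5
  })
  expect_lt(abs(mean(devs)), 3 * sd(devs) / sqrt(length(devs)))
})
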