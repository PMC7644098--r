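test_that("relative fitness is the log frequency change", {
  expect_equal(competitive_fitness(1000, 1500, 1000, 1500), 0)
  expect_equal(competitive_fitness(1000, 2000, 1000, 1000), log(2))
  w <- competitive_fitness(812, 1290, 930, 401)
  expect_equal(competitive_fitness(930, 401, 812, 1290), -w)  # antisymmetry
  expect_error(competitive_fitness(1000, 0, 1000, 500), "focal")
  expect_error(competitive_fitness(1000, 500, 1000, 0), "reference")
})

test_that("bottleneck statistics recover a synthetic trajectory exactly", {
  tr <- data.frame(time = 0:100,
                   n_total = c(rep(2000, 49),
                               round(2000 * exp(-0.25 * (0:11))),
                               round(pmin(120 * exp(0.18 * (1:40)), 1900))))
  bs <- bottleneck_stats(tr, switch_time = 48)
  expect_equal(bs$min_size, min(tr$n_total[tr$time > 48]))
  expect_equal(bs$carrying_capacity, mean(tail(tr$n_total, 13)))
  # first post-minimum entry into the 95% band, measured from the switch
  expect_equal(bs$t_recover,
               tr$time[tr$time >= bs$t_min &
                       tr$n_total >= 0.95 * bs$carrying_capacity][1] - 48)
  expect_equal(bs$t_recover, 28)
  # never-recovering trace is censored
  dead <- data.frame(time = 0:60, n_total = round(2000 * exp(-0.1 * (0:60))))
  expect_true(bottleneck_stats(dead, switch_time = 10)$censored)
})

test_that("dwell times are maximal runs with censored ends dropped", {
  # square wave: 5 h on, 3 h off, sampled hourly
  mu <- rep(c(rep(0.3, 5), rep(0, 3)), 6)
  dw <- lineage_dwell_times(mu, seq_along(mu) - 1, threshold = 0.025)
  expect_true(all(dw$growing == 5))
  expect_true(all(dw$nongrowing == 3))
  # constant series has only one (censored) run
  dw0 <- lineage_dwell_times(rep(0.3, 50), 0:49, threshold = 0.025)
  expect_length(dw0$growing, 0)
  expect_length(dw0$nongrowing, 0)
})

test_that("bimodality is judged by occupancy of the two growth basins", {
  flat <- growth_rate_distribution(rep(0, 500), mu_growing = 0.25)
  expect_false(flat$bimodal)
  expect_equal(flat$frac_growing, 0)
  mixed <- growth_rate_distribution(c(rep(0.005, 300), rep(0.24, 200)),
                                    mu_growing = 0.25)
  expect_true(mixed$bimodal)
  expect_equal(mixed$frac_growing, 0.4)
  lop <- growth_rate_distribution(c(rep(0.005, 1), rep(0.24, 499)),
                                  mu_growing = 0.25)
  expect_false(lop$bimodal)   # nongrowing mode below 1% occupancy
})

test_that("self-competition is fitness-neutral", {
  set.seed(23)
  res <- run_competition_assay(focal = list(K_cra_fbp = 0.1, eta2_cra = 0.2),
                               replicates = 4, n0 = 150, kappa = 3.4e8 * 6)
  w <- res$w[!is.na(res$w)]
  expect_gte(length(w), 3)
  expect_lt(abs(mean(w)), 2 * sd(w) / sqrt(length(w)) + 0.05)
})

test_that("the acetate enzyme stays off in glucose-grown cells", {
  set.seed(24)
  snap <- protein_snapshot(eta2_cra = 0.2, substrate = "glucose",
                           t_equilibrate = 24, n0 = 120, kappa = 3.4e8 * 16)
  expect_gt(snap$n_cells, 30)
  expect_lt(mean(snap$ai), 2)           # Cra repressed: regulon silent
  # at carrying capacity cells grow near the dilution rate; all are growing
  expect_gt(mean(snap$mu > 0.02), 0.95)
})

test_that("fixation runs require at least one replicate", {
  expect_error(run_fixation_experiment(replicates = 0), "replicates")
})
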