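test_that("Dirichlet ratio variants have the requested moments and are feasible", {
  prof <- generate_ratio_variants("P3", concentration = 50, n_profiles = 8,
                                  seed = 1)
  expect_equal(nrow(prof), 8)
  expect_equal(prof$tsc + prof$vacancy + prof$axon, rep(1, 8))
  for (i in 1:8) {
    expect_s3_class(solve_stationary_probs(
      area_ratios(prof$tsc[i], prof$vacancy[i], prof$axon[i]), 0.6),
      "nmj_vm_probs")
  }
  expect_identical(generate_ratio_variants("P3", 50, 8, seed = 1), prof)
  # moment check over a larger draw
  big <- generate_ratio_variants("P3", concentration = 50, n_profiles = 200,
                                 seed = 2)
  mc_sd <- sqrt(0.57 * 0.43 / 51 / 200)
  expect_lt(abs(mean(big$tsc) - 0.57), 4 * mc_sd)
  # concentration limit collapses onto the mean
  tight <- generate_ratio_variants("P3", concentration = 1e7, n_profiles = 3,
                                   seed = 3)
  expect_equal(tight$tsc, rep(0.57, 3), tolerance = 1e-2)
  expect_error(generate_ratio_variants("P3", concentration = -1), "positive")
})

test_that("ratio sweep recovers a perfect inverse ranking from a stubbed engine", {
  profiles <- data.frame(label = letters[1:5],
                         tsc = c(0.50, 0.52, 0.54, 0.56, 0.58),
                         vacancy = c(0.10, 0.14, 0.18, 0.22, 0.26),
                         axon = c(0.40, 0.34, 0.28, 0.22, 0.16))
  comp <- profiles$tsc * profiles$vacancy / profiles$axon
  expect_true(all(diff(comp) > 0))   # monotone composite areas
  stub <- function(model, n_reps, seed) {
    rep(1e6 / composite_area(model$stationary), 3)
  }
  rs <- ratio_sweep(profiles, model = nmj_model("P3"), n_reps = 3,
                    base_seed = 1, runner = stub)
  expect_equal(unname(rs$cor$estimate), -1)
  expect_lt(rs$cor$p.value, 0.05)
})

test_that("degenerate and infeasible sweep inputs are handled", {
  same <- data.frame(label = 1:3, tsc = 0.57, vacancy = 0.18, axon = 0.25)
  rs <- ratio_sweep(same, model = nmj_model("P3"), n_reps = 2, base_seed = 1,
                    runner = function(model, n_reps, seed) c(5, 5))
  expect_null(rs$cor)    # zero rank variance: correlation undefined
  mixed <- data.frame(label = 1:4,
                      tsc = c(0.57, 0.05, 0.50, 0.45),
                      vacancy = c(0.18, 0.60, 0.20, 0.25),
                      axon = c(0.25, 0.35, 0.30, 0.30))
  expect_warning(
    rs2 <- ratio_sweep(mixed, model = nmj_model("P3"), n_reps = 2,
                       base_seed = 1,
                       runner = function(model, n_reps, seed) {
                         rep(1 / composite_area(model$stationary), 2)
                       }),
    "skipped")
  expect_equal(nrow(rs2$table), 3)   # the infeasible profile is dropped
})

test_that("stage comparison returns per-stage summaries and pairwise tests", {
  sc <- stage_comparison(c("P3", "P7"), model = nmj_model(n_sites = 30),
                         n_reps = 6, base_seed = 2, max_iter = 500000)
  expect_equal(sc$summaries$stage, c("P3", "P7"))
  expect_equal(nrow(sc$tests), 1)
  expect_true(sc$tests$p_value >= 0 && sc$tests$p_value <= 1)
  expect_equal(sc$summaries$composite_area,
               c(composite_area(stage_ratios("P3")),
                 composite_area(stage_ratios("P7"))))
})

test_that("activity sweep reports the win probability of the active set", {
  m <- nmj_model("P3", n_sites = 30, max_iter = 500000)
  sw <- activity_sweep(m, n_active = c(0, 1), n_reps = 30, base_seed = 4)
  expect_equal(sw$table$n_active, c(0, 1))
  expect_true(all(sw$table$completion_rate == 1))
  # a designated but unbiased axon wins ~1/9 of the time; a protected one
  # wins far more often (the advantage is milder on these small endplates)
  expect_lt(sw$table$p_active_win[1], sw$table$p_active_win[2])
  expect_gt(sw$table$p_active_win[2], 0.3)
})

test_that("summaries recompute identically from persisted raw results", {
  m <- nmj_model("P3", n_sites = 30, max_iter = 200000)
  b <- batch_run(m, n_reps = 8, base_seed = 6, label = "persist")
  path <- tempfile(fileext = ".csv")
  write_sims_csv(b, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 8)
  expect_equal(back$condition, rep("persist", 8))
  sm <- summary(b)
  expect_equal(mean(back$iterations[back$completed]), sm$mean_iterations)
  expect_equal(sd(back$iterations[back$completed]), sm$sd_iterations)
  expect_equal(mean(back$completed), sm$completion_rate)
  unlink(path)
})

test_that("exponential decline fit reports its goodness of fit", {
  m <- nmj_model("P3", n_sites = 30, max_iter = 500000)
  b <- simulate(m, nsim = 8, seed = 7, record_series = TRUE,
                series_stride = 100)
  f <- axon_decline_fit(b)
  expect_true(f$r_squared >= 0 && f$r_squared <= 1)
  expect_gt(f$rate, 0)
  expect_equal(f$mean_axons[1], 9)
  expect_error(axon_decline_fit(simulate(m, nsim = 2, seed = 8)), "record_series")
})
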