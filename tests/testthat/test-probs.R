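test_that("stationary solver gives the closed-form probabilities", {
  p <- solve_stationary_probs(area_ratios(0.57, 0.18, 0.25), p_vs = 0.6)
  expect_equal(p$p_sv, 0.18 * 0.6 / 0.57)       # ~0.18947
  expect_equal(p$p_av, 0.18 * 0.4 / 0.25)       # 0.288
  expect_equal(p$p_aa, 1 - p$p_av)
  expect_equal(p$p_va, 0.4)
  # fully symmetric composition
  ps <- solve_stationary_probs(area_ratios(rep(1 / 3, 3)), p_vs = 0.5)
  expect_equal(ps$p_sv, 0.5)
  expect_equal(ps$p_av, 0.5)
})

test_that("infeasible compositions raise a typed error", {
  err <- tryCatch(solve_stationary_probs(area_ratios(0.05, 0.60, 0.35), 0.6),
                  condition = identity)
  expect_s3_class(err, "nmj_infeasible")
  expect_match(conditionMessage(err), "p_SV = 7.2")
  expect_error(solve_stationary_probs(area_ratios(0, 0.5, 0.5)), "positive")
  expect_error(solve_stationary_probs(stage_ratios("P3"), p_vs = 1.2), "0, 1")
})

test_that("solver and stationary-vector oracle agree over a grid", {
  for (r in list(c(0.57, 0.18, 0.25), c(0.55, 0.05, 0.40), c(0.41, 0.06, 0.53),
                 c(0.2, 0.1, 0.7), c(0.45, 0.35, 0.20))) {
    for (pv in c(0.2, 0.5, 0.6, 0.8)) {
      ratios <- area_ratios(r)
      feasible <- ratios[["vacancy"]] * pv <= ratios[["tsc"]] &&
        ratios[["vacancy"]] * (1 - pv) <= ratios[["axon"]]
      if (feasible) {
        probs <- solve_stationary_probs(ratios, pv)
        expect_equal(as.numeric(stationary_vector(probs)), as.numeric(ratios),
                     tolerance = 1e-8)
      } else {
        expect_error(solve_stationary_probs(ratios, pv),
                     class = "nmj_infeasible")
      }
    }
  }
})

test_that("stationary vector solves hand-computable chains", {
  # p_SV = 1, p_AV = 1, p_VS = 0.5: balance gives (1/4, 1/2, 1/4);
  # the chain is periodic, which the lazy-chain iteration must handle
  expect_equal(as.numeric(stationary_vector(vm_probs(1, 1, 0.5))),
               c(0.25, 0.5, 0.25), tolerance = 1e-10)
  expect_equal(as.numeric(stationary_vector(vm_probs(0.5, 0.5, 0.5))),
               rep(1 / 3, 3), tolerance = 1e-10)
  # p_SV = 0 isolates S: reducible, no unique stationary vector
  expect_error(stationary_vector(vm_probs(0.5, 0, 0.5)), "reducible")
})

test_that("equal probabilities are one third everywhere", {
  ep <- equal_probs()
  m <- transition_matrix(ep)
  expect_equal(unname(m), matrix(1 / 3, 3, 3))
  expect_equal(as.numeric(stationary_vector(ep)), rep(1 / 3, 3),
               tolerance = 1e-10)
})

test_that("random probability rows are uniform on the simplex", {
  set.seed(42)
  draws <- replicate(200, {
    gp <- sample_random_probs()
    m <- transition_matrix(gp)
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(unname(rowSums(m)), rep(1, 3))
    m["A", "V"]
  })
  set.seed(99)
  p_av <- replicate(10000, sample_random_probs()$p_av)
  # Dirichlet(1,1,1) marginal: mean 1/3, var 1/18
  mc_sd <- sqrt(1 / 18 / 10000)
  expect_lt(abs(mean(p_av) - 1 / 3), 4 * mc_sd)
  # determinism under a fixed seed
  set.seed(7); a <- sample_random_probs()
  set.seed(7); b <- sample_random_probs()
  expect_identical(a, b)
})

test_that("transition matrix encodes the vacancy-mediated structure", {
  m <- transition_matrix(p3_probs)
  expect_equal(m["S", "A"], 0)   # no direct tSC -> axon
  expect_equal(m["A", "S"], 0)   # no direct axon -> tSC
  expect_equal(m["V", "V"], 0)   # vacancies always transition
  expect_equal(unname(rowSums(m)), rep(1, 3))
})
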