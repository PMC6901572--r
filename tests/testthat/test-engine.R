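# empirical one-step frequencies from repeated fresh states
step_freq <- function(lay, n_trials, seed, stepper) {
  set.seed(seed)
  out <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    st <- sim_state(lay)
    out[[t]] <- stepper(st)
  }
  out
}

test_that("site selection is uniform without activity and weighted with it", {
  lay <- manual_layout(x = seq(0, 90, by = 10), y = rep(0, 10),
                       occ = c(1L, 1L, 2L, 2L, 3L, -1L, -1L, 0L, 0L, 0L),
                       n_axons = 3, neighbor_distance = 15)
  st <- sim_state(lay)
  set.seed(1)
  picks <- replicate(20000, select_site(st))
  expect_equal(unname(table(factor(picks, levels = 1:10))) / 20000,
               rep(0.1, 10), tolerance = 0.1, ignore_attr = TRUE)
  # axon 1 active (sites 1 and 2): weight 0.5 each, total weight 9
  st2 <- sim_state(lay, active = 1L, selection_divisor = 2)
  set.seed(2)
  picks2 <- replicate(50000, select_site(st2))
  freq <- tabulate(picks2, nbins = 10) / 50000
  expected <- c(0.5 / 9, 0.5 / 9, rep(1 / 9, 8))
  mc_sd <- sqrt(expected * (1 - expected) / 50000)
  expect_true(all(abs(freq - expected) < 4 * mc_sd))
})

test_that("vacancy takeover is weighted by adjacent site counts", {
  # diamond: central vacancy adjacent to two axon-1 sites and one axon-2 site
  lay <- manual_layout(x = c(0, 1, -1, 0), y = c(0, 0, 0, 1),
                       occ = c(0L, 1L, 1L, 2L), n_axons = 2,
                       neighbor_distance = 1.1)
  probs <- vm_probs(p_av = 0, p_sv = 0, p_vs = 0)  # only V -> A can happen
  events <- step_freq(lay, 4000, 11, function(st) {
    repeat {
      ev <- step_vacancy_mediated(st, probs)
      if (!is.null(ev)) return(ev[["new"]])
    }
  })
  ids <- unlist(events)
  expect_setequal(unique(ids), c(1L, 2L))
  p1 <- mean(ids == 1L)
  expect_lt(abs(p1 - 2 / 3), 4 * sqrt(2 / 9 / 4000))
})

test_that("takeover falls back to global counts for isolated vacancies", {
  # vacancy out of reach of every axon; axon 1 holds 3 sites, axon 2 holds 1
  lay <- manual_layout(x = c(0, 100, 110, 120, 130), y = rep(0, 5),
                       occ = c(0L, 1L, 1L, 1L, 2L), n_axons = 2,
                       neighbor_distance = 15)
  probs <- vm_probs(p_av = 0, p_sv = 0, p_vs = 0)
  ids <- unlist(step_freq(lay, 3000, 12, function(st) {
    repeat {
      ev <- step_vacancy_mediated(st, probs)
      if (!is.null(ev)) return(ev[["new"]])
    }
  }))
  expect_lt(abs(mean(ids == 1L) - 3 / 4), 4 * sqrt(3 / 16 / 3000))
})

test_that("extinct axons never reclaim and empty worlds stay vacant", {
  # no axon 2 sites anywhere: only axon 1 can ever be drawn
  lay <- manual_layout(x = c(0, 1), y = c(0, 0), occ = c(0L, 1L),
                       n_axons = 9, neighbor_distance = 1.5)
  probs <- vm_probs(0, 0, 0)
  ids <- unlist(step_freq(lay, 500, 13, function(st) {
    repeat {
      ev <- step_vacancy_mediated(st, probs)
      if (!is.null(ev)) return(ev[["new"]])
    }
  }))
  expect_true(all(ids == 1L))
  # no axon sites at all: the vacancy must remain vacant, iterations advance
  lay2 <- manual_layout(x = c(0, 1), y = c(0, 0), occ = c(0L, -1L),
                        n_axons = 9, neighbor_distance = 1.5)
  st <- sim_state(lay2)
  set.seed(14)
  for (k in 1:50) step_vacancy_mediated(st, probs)
  expect_identical(st$occ, c(0L, -1L))
  expect_equal(st$iteration, 50L)
})

test_that("no-transition branches leave occupants unchanged", {
  lay <- manual_layout(x = c(0, 1), y = c(0, 0), occ = c(-1L, 1L),
                       n_axons = 1, neighbor_distance = 1.5)
  st <- sim_state(lay)
  set.seed(15)
  for (k in 1:100) step_vacancy_mediated(st, vm_probs(0, 0, 1))
  expect_identical(st$occ, c(-1L, 1L))   # p_SV = 0, p_AV = 0: nothing moves
  expect_equal(st$iteration, 100L)
})

test_that("completion criteria distinguish the model classes", {
  # single surviving axon with tSCs and vacancies co-present
  lay <- manual_layout(x = 1:4, y = rep(0, 4), occ = c(3L, 3L, -1L, 0L),
                       n_axons = 9)
  st <- sim_state(lay)
  cc <- is_complete(st, "vacancy_mediated")
  expect_true(cc$complete)
  expect_equal(cc$winner, 3L)
  expect_false(is_complete(st, "neighbor_adoption")$complete)
  # two axon identities: incomplete under the vacancy-mediated rule
  st2 <- sim_state(manual_layout(x = 1:3, y = rep(0, 3),
                                 occ = c(1L, 2L, 0L), n_axons = 9))
  expect_false(is_complete(st2, "vacancy_mediated")$complete)
  # homogeneous layouts complete the neighbour-adoption models
  st3 <- sim_state(manual_layout(x = 1:3, y = rep(0, 3),
                                 occ = rep(-1L, 3), n_axons = 9))
  cc3 <- is_complete(st3, "neighbor_adoption")
  expect_true(cc3$complete)
  expect_equal(cc3$terminal, "all_tsc")
  st4 <- sim_state(manual_layout(x = 1:3, y = rep(0, 3),
                                 occ = rep(0L, 3), n_axons = 9))
  expect_equal(is_complete(st4, "neighbor_adoption")$terminal, "all_vacant")
})

test_that("runs terminate immediately or at the cap as specified", {
  mono <- endplate_layout(area_ratios(0.3, 0.2, 0.5), n_axons = 1,
                          n_sites = 20, seed = 4)
  r <- run_simulation(mono, p3_probs, seed = 1, max_iter = 1000)
  expect_true(r$completed)
  expect_equal(r$iterations, 0)
  expect_equal(r$winner, 1L)
  poly <- small_layout(seed = 5, n_sites = 30)
  r2 <- run_simulation(poly, p3_probs, seed = 2, max_iter = 10)
  expect_false(r2$completed)
  expect_true(is.na(r2$winner))
  expect_equal(r2$terminal, "none")
  expect_equal(r2$iters_run, 10)
})

test_that("compiled and reference engines produce identical trajectories", {
  lay <- small_layout(seed = 2, n_sites = 40)
  cases <- list(
    list(variant = "vacancy_mediated", active = integer()),
    list(variant = "vacancy_mediated", active = c(2L, 5L)),
    list(variant = "random", active = integer()),
    list(variant = "equal", active = integer()))
  for (cs in cases) {
    for (dr in c("adjacent", "axon_only")) {
      a <- run_simulation(lay, p3_probs, variant = cs$variant,
                          active = cs$active, seed = 77, max_iter = 2000,
                          terminate = FALSE, record_events = TRUE,
                          engine = "cpp", donor_rule = dr)
      b <- run_simulation(lay, p3_probs, variant = cs$variant,
                          active = cs$active, seed = 77, max_iter = 2000,
                          terminate = FALSE, record_events = TRUE,
                          engine = "r", donor_rule = dr)
      expect_identical(a$final_occ, b$final_occ)
      expect_equal(a$events, b$events)
      expect_equal(a$iterations, b$iterations)
      expect_equal(a$mean_composition, b$mean_composition, tolerance = 1e-12)
    }
  }
})

test_that("vacancy-mediated event logs contain no direct axon-tSC exchange", {
  lay <- small_layout(seed = 6, n_sites = 50)
  r <- run_simulation(lay, p3_probs, seed = 3, max_iter = 20000,
                      record_events = TRUE)
  ev <- r$events
  expect_gt(nrow(ev), 0)
  expect_false(any(ev$old_kind == "axon" & ev$new_kind == "tsc"))
  expect_false(any(ev$old_kind == "tsc" & ev$new_kind == "axon"))
  # conservation: only occupants change
  expect_length(r$final_occ, 50)
})

test_that("axon extinction is absorbing along the event log", {
  lay <- small_layout(seed = 7, n_sites = 50)
  r <- run_simulation(lay, p3_probs, seed = 4, max_iter = 50000,
                      record_events = TRUE)
  expect_true(r$completed)
  occ <- lay$occ
  alive_prev <- length(unique(occ[occ >= 1L]))
  extinct <- integer(0)
  monotone <- TRUE
  resurrection <- FALSE
  for (k in seq_len(nrow(r$events))) {
    ev <- r$events[k, ]
    occ[ev$site_id] <- if (ev$new_kind == "axon") ev$new_axon
                       else if (ev$new_kind == "tsc") -1L else 0L
    ids <- unique(occ[occ >= 1L])
    if (any(extinct %in% ids)) resurrection <- TRUE
    if (length(ids) > alive_prev) monotone <- FALSE
    extinct <- setdiff(1:9, ids)
    alive_prev <- length(ids)
  }
  expect_false(resurrection)    # extinct identities never reappear
  expect_true(monotone)         # distinct-axon count is non-increasing
  expect_equal(alive_prev, 1L)
})

test_that("marginal composition converges to the solved stationary ratios", {
  m <- nmj_model("P3", init = "P3")
  sims <- simulate(m, nsim = 3, seed = 31, max_iter = 30000, terminate = FALSE)
  mc <- rowMeans(sapply(attr(sims, "runs"), function(r) r$mean_composition))
  expect_equal(unname(mc), c(0.57, 0.18, 0.25), tolerance = 0.12)
  expect_lt(max(abs(mc - c(0.57, 0.18, 0.25))), 0.03)
})

test_that("neighbour-copy one-step kernel matches hand-computed probabilities", {
  # path A1 - V - S with unit spacing; equal scheme, adjacent donor rule:
  #   P(site1 A->V) = 1/3 * 1 * 1/3 = 1/9
  #   P(site2 V->A) = 1/3 * 1/2 * 1/3 = 1/18 ; P(site2 V->S) = 1/18
  #   P(site3 S->V) = 1/9
  lay <- manual_layout(x = c(0, 1, 2), y = rep(0, 3), occ = c(1L, 0L, -1L),
                       n_axons = 1, neighbor_distance = 1.1)
  evs <- step_freq(lay, 20000, 21, function(st) {
    ev <- step_neighbor_adoption(st, "equal", "adjacent")
    if (is.null(ev)) NA else paste(ev[["site_id"]], ev[["new"]])
  })
  tab <- table(unlist(evs), useNA = "ifany")
  n <- 20000
  freq <- function(key) if (key %in% names(tab)) tab[[key]] / n else 0
  expect_lt(abs(freq("1 0") - 1 / 9), 4 * sqrt((1 / 9) * (8 / 9) / n))
  expect_lt(abs(freq("2 1") - 1 / 18), 4 * sqrt((1 / 18) * (17 / 18) / n))
  expect_lt(abs(freq("2 -1") - 1 / 18), 4 * sqrt((1 / 18) * (17 / 18) / n))
  expect_lt(abs(freq("3 0") - 1 / 9), 4 * sqrt((1 / 9) * (8 / 9) / n))
  # no other transitions are possible on this path
  expect_setequal(setdiff(names(tab), NA),
                  c("1 0", "2 1", "2 -1", "3 0"))
})

test_that("row-outcome donor rule applies tSC/vacancy outcomes unconditionally", {
  # same path, axon_only rule: every site can move to either other kind
  # with probability 1/3 * 1/3, and V->A adopts the only axon neighbour
  lay <- manual_layout(x = c(0, 1, 2), y = rep(0, 3), occ = c(1L, 0L, -1L),
                       n_axons = 1, neighbor_distance = 1.1)
  evs <- step_freq(lay, 20000, 22, function(st) {
    ev <- step_neighbor_adoption(st, "equal", "axon_only")
    if (is.null(ev)) NA else paste(ev[["site_id"]], ev[["new"]])
  })
  tab <- table(unlist(evs), useNA = "ifany")
  n <- 20000
  freq <- function(key) if (key %in% names(tab)) tab[[key]] / n else 0
  mc <- 4 * sqrt((1 / 9) * (8 / 9) / n)
  expect_lt(abs(freq("1 0") - 1 / 9), mc)   # A -> V unconditionally
  expect_lt(abs(freq("1 -1") - 1 / 9), mc)  # A -> S unconditionally
  expect_lt(abs(freq("2 1") - 1 / 9), mc)   # V -> A via the axon donor
  expect_lt(abs(freq("2 -1") - 1 / 9), mc)
  expect_lt(abs(freq("3 0") - 1 / 9), mc)
  # the tSC end of the path has no adjacent axon site: S -> A never fires
  expect_equal(freq("3 1"), 0)
})

test_that("homogeneous all-vacant layouts are absorbing for neighbour adoption", {
  lay <- manual_layout(x = 1:5, y = rep(0, 5), occ = rep(0L, 5), n_axons = 9,
                       neighbor_distance = 1.5)
  r <- run_simulation(lay, variant = "equal", seed = 5, max_iter = 200,
                      terminate = FALSE, record_events = TRUE)
  expect_equal(nrow(r$events), 0)
  expect_identical(r$final_occ, rep(0L, 5))
  expect_equal(r$iterations, 0)   # already complete at iteration zero
})
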