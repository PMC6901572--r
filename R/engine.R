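## Per-iteration competition dynamics.
##
## The batch path runs a compiled loop (src/engine.cpp).  The step-level
## operations below are a pure-R reference implementation that consumes
## R's RNG draw-for-draw identically to the compiled loop, so trajectories
## from the two engines agree exactly under a shared seed (this is tested).

#' Create a mutable simulation state
#'
#' Wraps a layout (whose occupants will mutate in place), the activity
#' configuration, the iteration counter, occupancy bookkeeping and an
#' optional event log into an environment used by the step functions.
#'
#' @param layout An `nmj_layout`; its occupant vector is copied into the
#'   state, site geometry is shared.
#' @param active Integer vector of active axon identities (possibly
#'   empty).  Sites of active axons are selected for transition with
#'   probability reduced by `selection_divisor`.
#' @param selection_divisor Factor (>= 1) dividing the selection weight
#'   of active-axon sites (default 2: "two times less").
#' @param record_events Keep a per-change event log?
#' @return An environment of class `nmj_state` with fields `occ`,
#'   `iteration`, `axon_cnt`, `extinct_axons`, `events`, ...
#' @export
sim_state <- function(layout, active = integer(), selection_divisor = 2,
                      record_events = FALSE) {
  stopifnot(inherits(layout, "nmj_layout"))
  active <- as.integer(active)
  if (length(active) && (any(active < 1L) || any(active > layout$n_axons))) {
    stop("active axon ids must lie in 1..n_axons")
  }
  if (selection_divisor < 1) stop("selection_divisor must be >= 1")
  st <- new.env(parent = emptyenv())
  st$layout <- layout
  st$occ <- layout$occ
  st$adj <- layout$adjacency
  st$n_axons <- layout$n_axons
  st$n <- length(layout$occ)
  st$active <- logical(layout$n_axons)
  st$active[active] <- TRUE
  st$divisor <- selection_divisor
  st$iteration <- 0L
  st$axon_cnt <- tabulate(st$occ[st$occ >= 1L], nbins = layout$n_axons)
  st$n_tsc <- sum(st$occ == OCC_TSC)
  st$n_vac <- sum(st$occ == OCC_VAC)
  st$record_events <- record_events
  st$events <- list()
  class(st) <- c("nmj_state", "environment")
  st
}

#' @export
print.nmj_state <- function(x, ...) {
  cat(sprintf("simulation state: iteration %d, %d/%d/%d tSC/vacancy/axon sites, %d axons alive\n",
              x$iteration, x$n_tsc, x$n_vac, x$n - x$n_tsc - x$n_vac,
              sum(x$axon_cnt > 0)))
  invisible(x)
}

state_extinct <- function(state) which(state$axon_cnt == 0L)

state_apply <- function(state, i, new_occ) {
  old <- state$occ[i]
  if (old == new_occ) return(invisible(NULL))
  if (old >= 1L) state$axon_cnt[old] <- state$axon_cnt[old] - 1L
  else if (old == OCC_TSC) state$n_tsc <- state$n_tsc - 1L
  else state$n_vac <- state$n_vac - 1L
  if (new_occ >= 1L) state$axon_cnt[new_occ] <- state$axon_cnt[new_occ] + 1L
  else if (new_occ == OCC_TSC) state$n_tsc <- state$n_tsc + 1L
  else state$n_vac <- state$n_vac + 1L
  state$occ[i] <- new_occ
  ev <- c(iteration = state$iteration, site_id = i, old = old, new = new_occ)
  if (state$record_events) state$events[[length(state$events) + 1L]] <- ev
  invisible(ev)
}

site_weight <- function(state, i) {
  o <- state$occ[i]
  if (o >= 1L && state$active[o]) 1 / state$divisor else 1
}

#' Select a site for transition
#'
#' Chooses the site that will undergo this iteration's transition.  With
#' no activity bias the choice is uniform; sites occupied by an active
#' axon carry selection weight `1/selection_divisor` instead of 1.
#'
#' @param state An [sim_state()] environment.
#' @return A site index.  Advances R's RNG by one uniform draw.
#' @export
select_site <- function(state) {
  u <- stats::runif(1)
  if (!any(state$active)) {
    return(min(as.integer(u * state$n) + 1L, state$n))
  }
  total <- 0
  for (j in seq_len(state$n)) total <- total + site_weight(state, j)
  thr <- u * total
  acc <- 0
  for (j in seq_len(state$n)) {
    acc <- acc + site_weight(state, j)
    if (thr <= acc) return(j)
  }
  state$n
}

#' One iteration of the vacancy-mediated competition
#'
#' Selects a site and applies the vacancy-mediated kernel: an axon site
#' becomes vacant with probability `p_av`; a tSC site becomes vacant with
#' probability `p_sv`; a vacant site becomes a tSC with probability
#' `p_vs`, otherwise it is reclaimed by an axon whose identity is drawn
#' with probability proportional to the number of adjacent sites each
#' non-extinct axon holds (falling back to global site counts when the
#' vacancy has no axon neighbour).  Extinct axons can never be drawn; if
#' no axon site exists anywhere, the vacancy stays vacant.  Direct
#' axon-tSC transitions are structurally impossible.
#'
#' @param state An [sim_state()] environment (mutated in place).
#' @param probs An [vm_probs()] object.
#' @return The event record (named vector) if the occupant changed,
#'   otherwise `NULL`, invisibly.  Increments `state$iteration` by 1.
#' @export
step_vacancy_mediated <- function(state, probs) {
  stopifnot(inherits(probs, "nmj_vm_probs"))
  i <- select_site(state)
  state$iteration <- state$iteration + 1L
  o <- state$occ[i]
  if (o >= 1L) {
    if (stats::runif(1) < probs$p_av) return(invisible(state_apply(state, i, OCC_VAC)))
  } else if (o == OCC_TSC) {
    if (stats::runif(1) < probs$p_sv) return(invisible(state_apply(state, i, OCC_VAC)))
  } else {
    if (stats::runif(1) < probs$p_vs) return(invisible(state_apply(state, i, OCC_TSC)))
    nb <- state$occ[state$adj[[i]]]
    w <- tabulate(nb[nb >= 1L], nbins = state$n_axons)
    tot <- sum(w)
    if (tot == 0L) { w <- state$axon_cnt; tot <- sum(w) }
    if (tot > 0L) {
      thr <- stats::runif(1) * tot
      acc <- 0
      chosen <- state$n_axons
      for (k in seq_len(state$n_axons)) {
        acc <- acc + w[k]
        if (thr <= acc) { chosen <- k; break }
      }
      return(invisible(state_apply(state, i, chosen)))
    }
    # no non-extinct axon holds any site: the vacancy remains vacant
  }
  invisible(NULL)
}

#' One iteration of a neighbour-adoption competition scheme
#'
#' The random- and equal-probability schemes.  Under the default
#' `donor_rule = "adjacent"` the selected site transitions into a site
#' adjacent to it: a uniformly chosen neighbour is adopted — occupant
#' kind and, for axons, identity — with the probability the transition
#' row assigns to that neighbour's kind.  The row over the target kinds
#' (tSC, vacancy, axon) is drawn fresh from the uniform simplex each
#' step (`"random"`) or fixed at (1/3, 1/3, 1/3) (`"equal"`).  Because
#' each class spreads only from sites that already hold it, the three
#' homogeneous endplates (all one axon, all tSC, all vacant) are genuine
#' absorbing states of this scheme.
#'
#' Under `donor_rule = "axon_only"` the outcome kind is instead drawn
#' directly from the row; tSC and vacancy outcomes apply
#' unconditionally, and only a transition to the axon kind requires (and
#' adopts the identity of) a uniformly chosen adjacent axon site, the
#' step being a no-op without one.  Note that under this reading the
#' class composition is mean-reverting (the outcome kind is redrawn
#' regardless of the current composition), so homogeneous endplates are
#' effectively never reached.
#'
#' @param state An [sim_state()] environment (mutated in place).
#' @param probs_source `"random"` or `"equal"`.
#' @param donor_rule `"adjacent"` (default) or `"axon_only"`; see
#'   Details.
#' @return As [step_vacancy_mediated()].
#' @export
step_neighbor_adoption <- function(state, probs_source = c("random", "equal"),
                                   donor_rule = c("adjacent", "axon_only")) {
  probs_source <- match.arg(probs_source)
  donor_rule <- match.arg(donor_rule)
  u <- stats::runif(1)
  i <- min(as.integer(u * state$n) + 1L, state$n)
  state$iteration <- state$iteration + 1L
  if (donor_rule == "adjacent") {
    nb <- state$adj[[i]]
    deg <- length(nb)
    if (deg == 0L) return(invisible(NULL))
    pick <- min(as.integer(stats::runif(1) * deg) + 1L, deg)
    j <- nb[pick]
    if (probs_source == "random") {
      e <- -log(stats::runif(3))
      s <- (e[1] + e[2]) + e[3]
      oj <- state$occ[j]
      kj <- if (oj >= 1L) 3L else if (oj == OCC_TSC) 1L else 2L
      p <- e[kj] / s
    } else {
      p <- 1 / 3
    }
    if (stats::runif(1) < p) {
      return(invisible(state_apply(state, i, state$occ[j])))
    }
    return(invisible(NULL))
  }
  if (probs_source == "random") {
    e <- -log(stats::runif(3))
    s <- (e[1] + e[2]) + e[3]
    p_s <- e[1] / s; p_v <- e[2] / s
  } else {
    p_s <- 1 / 3; p_v <- 1 / 3
  }
  uo <- stats::runif(1)
  target <- if (uo < p_s) 0L else if (uo < p_s + p_v) 1L else 2L  # S, V, A
  o <- state$occ[i]
  cur <- if (o >= 1L) 2L else if (o == OCC_TSC) 0L else 1L
  if (target == cur) return(invisible(NULL))
  if (target == 0L) return(invisible(state_apply(state, i, OCC_TSC)))
  if (target == 1L) return(invisible(state_apply(state, i, OCC_VAC)))
  donors <- state$adj[[i]][state$occ[state$adj[[i]]] >= 1L]
  m <- length(donors)
  if (m == 0L) return(invisible(NULL))
  pick <- min(as.integer(stats::runif(1) * m) + 1L, m)
  invisible(state_apply(state, i, state$occ[donors[pick]]))
}

#' Completion test
#'
#' Under the vacancy-mediated model the run is complete when exactly one
#' axon identity still holds at least one site (tSCs and vacancies
#' co-present at completion).  Under the neighbour-adoption schemes the
#' run is complete when the layout is homogeneous: all one axon identity,
#' all tSC, or all vacant.
#'
#' @param state An [sim_state()] environment.
#' @param model `"vacancy_mediated"` or `"neighbor_adoption"`.
#' @return A list with `complete` (logical), `winner` (axon id or `NA`)
#'   and `terminal` (`"axon"`, `"all_tsc"`, `"all_vacant"` or `"none"`).
#' @export
is_complete <- function(state, model = c("vacancy_mediated", "neighbor_adoption")) {
  model <- match.arg(model)
  if (model == "vacancy_mediated") {
    live <- which(state$axon_cnt > 0L)
    if (length(live) == 1L) {
      return(list(complete = TRUE, winner = live, terminal = "axon"))
    }
    return(list(complete = FALSE, winner = NA_integer_, terminal = "none"))
  }
  if (state$n_tsc == state$n) {
    return(list(complete = TRUE, winner = NA_integer_, terminal = "all_tsc"))
  }
  if (state$n_vac == state$n) {
    return(list(complete = TRUE, winner = NA_integer_, terminal = "all_vacant"))
  }
  full <- which(state$axon_cnt == state$n)
  if (length(full) == 1L) {
    return(list(complete = TRUE, winner = full, terminal = "axon"))
  }
  list(complete = FALSE, winner = NA_integer_, terminal = "none")
}

variant_code <- function(variant) {
  match(variant, c("vacancy_mediated", "random", "equal")) - 1L
}

winner_terminal <- function(code) {
  if (code >= 1L) "axon" else if (code == -1L) "all_tsc"
  else if (code == -2L) "all_vacant" else "none"
}

#' Run a competition simulation
#'
#' Iterates the chosen competition scheme on a layout until completion or
#' `max_iter`, whichever comes first.  `iterations` in the result is the
#' least iteration index at which the completion condition held (0 when
#' the initial layout is already complete).
#'
#' @param layout An `nmj_layout`.
#' @param probs An [vm_probs()] object (required for
#'   `variant = "vacancy_mediated"`, ignored otherwise).
#' @param variant `"vacancy_mediated"`, `"random"` or `"equal"`.
#' @param active Integer vector of active axon identities.
#' @param selection_divisor Selection-weight divisor for active-axon
#'   sites (default 2).
#' @param max_iter Iteration cap; reaching it yields `completed = FALSE`
#'   and `winner = NA`, never an error.
#' @param seed Optional integer seed (`set.seed`) making the run
#'   reproducible.
#' @param record_series Log the composition time series?
#' @param series_stride Iterations between series samples (default 50).
#' @param record_events Log per-change events?
#' @param max_events Event-log capacity.
#' @param terminate If `FALSE`, always run the full `max_iter`
#'   iterations (used to probe the stationary regime); the least
#'   completion iteration is still reported.
#' @param donor_rule Donor requirement of the neighbour-adoption
#'   schemes; see [step_neighbor_adoption()].
#' @param engine `"cpp"` (compiled loop, default) or `"r"` (reference
#'   step functions); both produce identical trajectories for a given
#'   seed.
#' @return A list of class `nmj_run`: `completed`, `iterations`,
#'   `iters_run`, `winner` (axon id or `NA`), `terminal`, `seed`,
#'   `final_occ`, `mean_composition` (time-averaged tSC/vacancy/axon
#'   fractions over the executed iterations), and optionally `series`
#'   and `events` data frames.
#' @examples
#' lay <- endplate_layout(stage_ratios("P0"), n_sites = 40, seed = 1)
#' pr <- solve_stationary_probs(stage_ratios("P3"))
#' run_simulation(lay, pr, seed = 2)
#' @export
run_simulation <- function(layout, probs = NULL,
                           variant = c("vacancy_mediated", "random", "equal"),
                           active = integer(), selection_divisor = 2,
                           max_iter = 50000L, seed = NULL,
                           record_series = FALSE, series_stride = 50L,
                           record_events = FALSE, max_events = 200000L,
                           terminate = TRUE, engine = c("cpp", "r"),
                           donor_rule = c("adjacent", "axon_only")) {
  variant <- match.arg(variant)
  engine <- match.arg(engine)
  donor_rule <- match.arg(donor_rule)
  stopifnot(inherits(layout, "nmj_layout"), max_iter > 0)
  if (variant == "vacancy_mediated" && !inherits(probs, "nmj_vm_probs")) {
    stop("the vacancy-mediated variant needs an nmj_vm_probs object")
  }
  active <- as.integer(active)
  if (!is.null(seed)) set.seed(seed)
  if (engine == "cpp") {
    act <- logical(layout$n_axons); act[active] <- TRUE
    res <- engine_run(layout$occ, layout$adjacency, layout$n_axons,
                      variant_code(variant),
                      if (is.null(probs)) 0 else probs$p_av,
                      if (is.null(probs)) 0 else probs$p_sv,
                      if (is.null(probs)) 0 else probs$p_vs,
                      act, selection_divisor, as.integer(max_iter), terminate,
                      if (record_series) as.integer(series_stride) else 0L,
                      record_events, as.integer(max_events),
                      donor_rule == "adjacent")
    winner_code <- res$winner
    out <- list(completed = res$completed, iterations = res$iterations,
                iters_run = res$iters_run,
                winner = if (winner_code >= 1L) winner_code else NA_integer_,
                terminal = winner_terminal(winner_code),
                seed = if (is.null(seed)) NA_integer_ else seed,
                final_occ = res$occ,
                mean_composition = stats::setNames(res$mean_composition,
                                                   c("tsc", "vacancy", "axon")))
    if (record_series) {
      out$series <- as.data.frame(res$series)
      names(out$series) <- c("iteration", "frac_tsc", "frac_vac", "frac_axon",
                             "n_axon_types")
    }
    if (record_events) {
      out$events <- events_to_df(res$events)
      out$events_truncated <- res$events_truncated
    }
  } else {
    out <- run_simulation_r(layout, probs, variant, active, selection_divisor,
                            max_iter, record_series, series_stride,
                            record_events, terminate, donor_rule)
    out$seed <- if (is.null(seed)) NA_integer_ else seed
  }
  class(out) <- "nmj_run"
  out
}

# pure-R driver over the reference step functions
run_simulation_r <- function(layout, probs, variant, active, selection_divisor,
                             max_iter, record_series, series_stride,
                             record_events, terminate,
                             donor_rule = "adjacent") {
  st <- sim_state(layout, active = active,
                  selection_divisor = selection_divisor,
                  record_events = record_events)
  model <- if (variant == "vacancy_mediated") "vacancy_mediated" else "neighbor_adoption"
  series <- list()
  push_series <- function() {
    series[[length(series) + 1L]] <<- c(st$iteration, st$n_tsc / st$n,
                                        st$n_vac / st$n,
                                        (st$n - st$n_tsc - st$n_vac) / st$n,
                                        sum(st$axon_cnt > 0L))
  }
  comp_sum <- c(0, 0, 0)
  cc <- is_complete(st, model)
  completed_iter <- if (cc$complete) 0L else -1L
  winner <- cc$winner
  terminal <- cc$terminal
  if (record_series) push_series()
  while (!(terminate && completed_iter >= 0L) && st$iteration < max_iter) {
    if (variant == "vacancy_mediated") step_vacancy_mediated(st, probs)
    else step_neighbor_adoption(st, variant, donor_rule)
    comp_sum <- comp_sum + c(st$n_tsc, st$n_vac, st$n - st$n_tsc - st$n_vac) / st$n
    if (record_series && st$iteration %% series_stride == 0L) push_series()
    if (completed_iter < 0L) {
      cc <- is_complete(st, model)
      if (cc$complete) {
        completed_iter <- st$iteration
        winner <- cc$winner
        terminal <- cc$terminal
      }
    }
  }
  if (record_series && length(series) &&
      series[[length(series)]][1] != st$iteration) push_series()
  out <- list(completed = completed_iter >= 0L,
              iterations = if (completed_iter >= 0L) completed_iter else st$iteration,
              iters_run = st$iteration,
              winner = winner,
              terminal = if (completed_iter >= 0L) terminal else "none",
              final_occ = st$occ,
              mean_composition = stats::setNames(
                if (st$iteration > 0L) comp_sum / st$iteration else rep(NA_real_, 3),
                c("tsc", "vacancy", "axon")))
  if (record_series) {
    s <- do.call(rbind, series)
    out$series <- data.frame(iteration = s[, 1], frac_tsc = s[, 2],
                             frac_vac = s[, 3], frac_axon = s[, 4],
                             n_axon_types = s[, 5])
  }
  if (record_events) {
    out$events <- events_to_df(do.call(rbind, c(st$events, list(NULL))))
    out$events_truncated <- FALSE
  }
  out
}

events_to_df <- function(m) {
  if (is.null(m) || nrow(m) == 0L) {
    return(data.frame(iteration = integer(), site_id = integer(),
                      old_kind = character(), old_axon = integer(),
                      new_kind = character(), new_axon = integer()))
  }
  data.frame(iteration = m[, 1], site_id = m[, 2],
             old_kind = occ_kind(m[, 3]),
             old_axon = ifelse(m[, 3] >= 1L, m[, 3], NA_integer_),
             new_kind = occ_kind(m[, 4]),
             new_axon = ifelse(m[, 4] >= 1L, m[, 4], NA_integer_))
}

#' @export
print.nmj_run <- function(x, ...) {
  if (x$completed) {
    lab <- switch(x$terminal,
                  axon = sprintf("single axon %d remains", x$winner),
                  all_tsc = "endplate filled with tSCs",
                  all_vacant = "endplate completely vacant")
    cat(sprintf("competition complete at iteration %d: %s\n", x$iterations, lab))
  } else {
    cat(sprintf("competition incomplete after %d iterations (%d axon identities remain)\n",
                x$iters_run, length(unique(x$final_occ[x$final_occ >= 1L]))))
  }
  invisible(x)
}
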