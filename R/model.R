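#' Fit a stochastic endplate competition model
#'
#' Constructs the site-competition model of developmental synapse
#' elimination at the neuromuscular junction.  For the vacancy-mediated
#' variant the model is calibrated by solving the three-state chain over
#' (tSC, vacancy, axon) for the unique transition probabilities whose
#' stationary distribution equals the target area-ratio vector
#' (`stationary`), given the one free parameter `p_vs`; the `"random"`
#' and `"equal"` variants need no calibration.  The returned object
#' bundles the solved probabilities with the endplate geometry, the
#' initial composition and the activity configuration, and is simulated
#' with [simulate()].
#'
#' @param stationary Target stationary area ratios (an [area_ratios()]
#'   object, a length-3 vector, or a stage label such as `"P3"`).
#'   Defaults to the measured P3 stage average.
#' @param p_vs Free vacancy-to-tSC transition probability (default 0.6).
#' @param variant Competition scheme: `"vacancy_mediated"` (calibrated,
#'   default), `"random"` (per-step uniform-simplex probability rows) or
#'   `"equal"` (all rows 1/3).
#' @param init Initial endplate composition used to build layouts
#'   (default the measured P0 stage average; also accepts a stage
#'   label).
#' @param n_axons Number of axon identities at initialisation (default
#'   9).
#' @param n_sites Number of contact sites per endplate (default 100).
#' @param region_diameter,site_diameter Endplate and site diameters in
#'   pixels (defaults 300 and 30).
#' @param min_separation_factor Minimum pairwise centre separation as a
#'   fraction of the site diameter (default 0.8).
#' @param neighbor_distance Adjacency threshold in pixels (default
#'   `1.25 * site_diameter`).
#' @param active Integer vector of active axon identities, or `NULL`.
#' @param n_active Alternative to `active`: number of active axons to be
#'   drawn uniformly at random, afresh in each simulated replicate.
#' @param selection_divisor Selection-weight divisor for active-axon
#'   sites (default 2).
#' @param max_iter Default iteration cap for simulations: 50,000 for the
#'   vacancy-mediated and random variants, 200,000 for the equal
#'   variant.
#' @param donor_rule Donor requirement of the neighbour-adoption
#'   variants (see [step_neighbor_adoption()]); ignored by the
#'   vacancy-mediated variant.
#' @return An object of class `nmj_model` with components `probs`
#'   (solved [vm_probs()], or `NULL`), `stationary`, `variant`, the
#'   geometry/composition/activity settings, and `max_iter`.
#' @examples
#' m <- nmj_model("P3")
#' coef(m)
#' predict(m)
#' @export
nmj_model <- function(stationary = "P3", p_vs = 0.6,
                      variant = c("vacancy_mediated", "random", "equal"),
                      init = "P0", n_axons = 9L, n_sites = 100L,
                      region_diameter = 300, site_diameter = 30,
                      min_separation_factor = 0.8,
                      neighbor_distance = 1.25 * site_diameter,
                      active = NULL, n_active = NULL, selection_divisor = 2,
                      max_iter = NULL,
                      donor_rule = c("adjacent", "axon_only")) {
  variant <- match.arg(variant)
  donor_rule <- match.arg(donor_rule)
  if (is.character(init)) init <- stage_ratios(init)
  init <- as_ratios(init)
  probs <- NULL
  if (variant == "vacancy_mediated") {
    if (is.character(stationary)) stationary <- stage_ratios(stationary)
    stationary <- as_ratios(stationary)
    probs <- solve_stationary_probs(stationary, p_vs = p_vs)
  } else {
    stationary <- NULL
  }
  if (!is.null(active) && !is.null(n_active)) {
    stop("give either `active` or `n_active`, not both")
  }
  if (is.null(max_iter)) {
    max_iter <- if (variant == "equal") 200000L else 50000L
  }
  structure(list(variant = variant, probs = probs, stationary = stationary,
                 p_vs = p_vs, init = init, n_axons = as.integer(n_axons),
                 n_sites = as.integer(n_sites),
                 region_diameter = region_diameter,
                 site_diameter = site_diameter,
                 min_separation_factor = min_separation_factor,
                 neighbor_distance = neighbor_distance,
                 active = if (is.null(active)) NULL else as.integer(active),
                 n_active = if (is.null(n_active)) NULL else as.integer(n_active),
                 selection_divisor = selection_divisor,
                 max_iter = as.integer(max_iter), donor_rule = donor_rule),
            class = "nmj_model")
}

new_model_layout <- function(model, seed = NULL) {
  endplate_layout(model$init, n_axons = model$n_axons,
                  n_sites = model$n_sites,
                  region_diameter = model$region_diameter,
                  site_diameter = model$site_diameter,
                  min_separation_factor = model$min_separation_factor,
                  neighbor_distance = model$neighbor_distance, seed = seed)
}

#' @export
print.nmj_model <- function(x, ...) {
  cat(sprintf("endplate competition model (%s variant)\n", x$variant))
  cat(sprintf("  geometry: %d sites of %g px in a %g px disc, %d axon identities\n",
              x$n_sites, x$site_diameter, x$region_diameter, x$n_axons))
  cat(sprintf("  initial composition: tSC %.2f, vacancy %.2f, axon %.2f\n",
              x$init[["tsc"]], x$init[["vacancy"]], x$init[["axon"]]))
  if (!is.null(x$probs)) {
    cat(sprintf("  stationary target: tSC %.2f, vacancy %.2f, axon %.2f (p_VS = %g)\n",
                x$stationary[["tsc"]], x$stationary[["vacancy"]],
                x$stationary[["axon"]], x$p_vs))
    cat(sprintf("  solved: p_AV = %.4f, p_SV = %.4f, p_VA = %.4f\n",
                x$probs$p_av, x$probs$p_sv, x$probs$p_va))
  }
  n_act <- if (!is.null(x$active)) length(x$active)
           else if (!is.null(x$n_active)) x$n_active else 0L
  if (n_act > 0) {
    cat(sprintf("  activity: %d active axon(s), selection divisor %g\n",
                n_act, x$selection_divisor))
  }
  invisible(x)
}

#' @export
coef.nmj_model <- function(object, ...) {
  if (object$variant == "vacancy_mediated") {
    with(object$probs, c(p_AV = p_av, p_SV = p_sv, p_VS = p_vs,
                         p_AA = p_aa, p_SS = p_ss, p_VA = p_va))
  } else if (object$variant == "equal") {
    unlist(equal_probs())[c("p_av", "p_as", "p_sa", "p_sv", "p_va", "p_vs")]
  } else {
    c(p_av = NA_real_, p_as = NA_real_, p_sa = NA_real_,
      p_sv = NA_real_, p_va = NA_real_, p_vs = NA_real_)  # redrawn each step
  }
}

#' Predicted long-run composition of a competition model
#'
#' @param object An [nmj_model()].
#' @param type `"stationary"` for the stationary (tSC, vacancy, axon)
#'   fractions of the calibrated chain, or `"composite"` for their
#'   composite area `r_S * r_V / r_A`.
#' @param ... Unused.
#' @return An [area_ratios()] vector, or a single number.
#' @export
predict.nmj_model <- function(object, type = c("stationary", "composite"), ...) {
  type <- match.arg(type)
  probs <- if (object$variant == "random") {
    stop("the random variant redraws its probabilities each step; no single stationary chain exists")
  } else if (object$variant == "equal") equal_probs() else object$probs
  pi_hat <- stationary_vector(probs)
  if (type == "stationary") pi_hat else composite_area(pi_hat)
}

#' Simulate replicate endplates under a competition model
#'
#' Runs `nsim` independent replicates of the model: each replicate draws
#' a fresh random initial layout, (when `n_active` is set) a fresh
#' uniformly drawn active-axon set, and a fresh run stream, all derived
#' deterministically from `seed`.
#'
#' @param object An [nmj_model()].
#' @param nsim Number of replicates (default 1).
#' @param seed Optional integer root seed; per-replicate layout and run
#'   seeds are derived from it and recorded in the result.
#' @param max_iter Iteration cap (default the model's).
#' @param record_series,series_stride,record_events,terminate Passed to
#'   [run_simulation()].
#' @param ... Unused.
#' @return A data frame of class `nmj_sims` with one row per replicate:
#'   `rep`, `seed_layout`, `seed_run`, `completed`, `iterations`,
#'   `winner`, `terminal`, `n_active`, `active` (comma-separated ids)
#'   and `composite_area` of the stationary target (or `NA`).  The full
#'   [run_simulation()] results are kept in `attr(, "runs")`.
#' @export
simulate.nmj_model <- function(object, nsim = 1, seed = NULL, max_iter = NULL,
                               record_series = FALSE, series_stride = 50L,
                               record_events = FALSE, terminate = TRUE, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(max_iter)) max_iter <- object$max_iter
  seeds <- matrix(sample.int(.Machine$integer.max, 2L * nsim), ncol = 2L)
  comp <- if (object$variant == "vacancy_mediated") {
    composite_area(object$stationary)
  } else NA_real_
  runs <- vector("list", nsim)
  rows <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    lay <- new_model_layout(object, seed = seeds[r, 1L])
    set.seed(seeds[r, 2L])
    act <- if (!is.null(object$active)) {
      object$active
    } else if (!is.null(object$n_active) && object$n_active > 0L) {
      sample.int(object$n_axons, object$n_active)
    } else integer()
    res <- run_simulation(lay, probs = object$probs, variant = object$variant,
                          active = act,
                          selection_divisor = object$selection_divisor,
                          max_iter = max_iter, seed = NULL,
                          record_series = record_series,
                          series_stride = series_stride,
                          record_events = record_events,
                          terminate = terminate,
                          donor_rule = object$donor_rule %||% "adjacent")
    res$seed <- seeds[r, 2L]
    res$active <- act
    runs[[r]] <- res
    rows[[r]] <- data.frame(rep = r, seed_layout = seeds[r, 1L],
                            seed_run = seeds[r, 2L], completed = res$completed,
                            iterations = res$iterations,
                            winner = res$winner, terminal = res$terminal,
                            n_active = length(act),
                            active = paste(act, collapse = ","),
                            composite_area = comp)
  }
  out <- do.call(rbind, rows)
  attr(out, "runs") <- runs
  attr(out, "model") <- object
  class(out) <- c("nmj_sims", "data.frame")
  out
}

#' Plot simulated composition trajectories
#'
#' With a series-recording simulation result, draws the tSC (green),
#' vacancy (black) and pooled-axon (blue) coverage fractions against the
#' iteration index, plus the distinct-axon count on a second axis.
#'
#' @param x An `nmj_model`.
#' @param sims Optional `nmj_sims` result with recorded series; when
#'   missing a single replicate is simulated on the fly.
#' @param seed Seed for the on-the-fly replicate.
#' @param ... Unused.
#' @return The series data frame, invisibly.
#' @export
plot.nmj_model <- function(x, sims = NULL, seed = 1L, ...) {
  if (is.null(sims)) {
    sims <- simulate(x, nsim = 1, seed = seed, record_series = TRUE)
  }
  s <- attr(sims, "runs")[[1L]]$series
  if (is.null(s)) stop("simulation was run without record_series = TRUE")
  graphics::plot(s$iteration, s$frac_tsc, type = "l", col = "forestgreen",
                 ylim = c(0, 1), xlab = "iteration", ylab = "coverage fraction",
                 main = sprintf("%s competition", x$variant))
  graphics::lines(s$iteration, s$frac_vac, col = "black")
  graphics::lines(s$iteration, s$frac_axon, col = "blue")
  graphics::legend("topright", c("tSC", "vacancy", "axon (pooled)"),
                   col = c("forestgreen", "black", "blue"), lty = 1, bty = "n")
  invisible(s)
}

#' @export
summary.nmj_model <- function(object, ...) {
  print(object)
  if (object$variant != "random") {
    pi_hat <- predict(object, "stationary")
    cat(sprintf("  stationary check: tSC %.4f, vacancy %.4f, axon %.4f\n",
                pi_hat[["tsc"]], pi_hat[["vacancy"]], pi_hat[["axon"]]))
    if (object$variant == "vacancy_mediated") {
      cat(sprintf("  composite area r_S*r_V/r_A = %.4f\n",
                  composite_area(object$stationary)))
    }
  }
  invisible(object)
}
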