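## Batch experiments: repeated simulations, activity sweeps, ratio sweeps
## and stage comparisons, with the associated summary statistics.

#' Summarise a batch of simulated replicates
#'
#' @param object An `nmj_sims` data frame from [simulate.nmj_model()] or
#'   [batch_run()].
#' @param ... Unused.
#' @return A list of class `nmj_summary`: `label`, `n_reps`,
#'   `n_completed`, `completion_rate`, `mean_iterations` and
#'   `sd_iterations` (sample SD over completed runs; `NA` for a single
#'   run), `win_table` (per-axon win probabilities over all runs, so the
#'   table sums to the completion rate for the vacancy-mediated model),
#'   and `p_active_win` (fraction of completed runs whose winner was in
#'   that replicate's active set; `NA` when no run had an active set).
#' @export
summary.nmj_sims <- function(object, ...) {
  model <- attr(object, "model")
  n_axons <- if (!is.null(model)) model$n_axons else
    max(1L, object$winner[!is.na(object$winner)], 9L)
  done <- object[object$completed, , drop = FALSE]
  wins <- tabulate(done$winner[!is.na(done$winner)], nbins = n_axons)
  act_runs <- done[done$n_active > 0L, , drop = FALSE]
  p_active <- if (nrow(act_runs)) {
    hit <- mapply(function(w, a) {
      !is.na(w) && w %in% as.integer(strsplit(a, ",")[[1]])
    }, act_runs$winner, act_runs$active)
    mean(hit)
  } else NA_real_
  structure(list(
    label = attr(object, "label") %||% "",
    n_reps = nrow(object),
    n_completed = nrow(done),
    completion_rate = nrow(done) / nrow(object),
    mean_iterations = if (nrow(done)) mean(done$iterations) else NA_real_,
    sd_iterations = if (nrow(done) > 1L) stats::sd(done$iterations) else NA_real_,
    win_table = wins / nrow(object),
    p_active_win = p_active,
    iterations = done$iterations), class = "nmj_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.nmj_summary <- function(x, ...) {
  cat(sprintf("%s%d replicates, %.0f%% complete\n",
              if (nzchar(x$label)) paste0(x$label, ": ") else "",
              x$n_reps, 100 * x$completion_rate))
  if (!is.na(x$mean_iterations)) {
    cat(sprintf("  least iterations to completion: %.0f +/- %.0f (SD)\n",
                x$mean_iterations, x$sd_iterations))
  }
  if (!is.na(x$p_active_win)) {
    cat(sprintf("  active axon won %.1f%% of completed runs\n",
                100 * x$p_active_win))
  }
  invisible(x)
}

#' Run a repeated-simulation experiment
#'
#' Runs `n_reps` independent replicates of a model (fresh layout, active
#' set and run stream per replicate, all derived from `base_seed`) and
#' summarises them.
#'
#' @param model An [nmj_model()].
#' @param n_reps Number of replicates (default 100).
#' @param base_seed Integer root seed.
#' @param label Condition label carried into the summary.
#' @param ... Passed to [simulate.nmj_model()].
#' @return An `nmj_sims` data frame (with `label` attribute); call
#'   [summary()] for the batch statistics.
#' @examples
#' \donttest{
#' b <- batch_run(nmj_model("P3"), n_reps = 5, base_seed = 1)
#' summary(b)
#' }
#' @export
batch_run <- function(model, n_reps = 100L, base_seed = 1L, label = "", ...) {
  sims <- simulate(model, nsim = n_reps, seed = base_seed, ...)
  attr(sims, "label") <- label
  sims
}

#' Activity sweep
#'
#' Repeats the batch experiment as the number of active axons increases.
#' For each condition the active set is a fresh uniform draw per
#' replicate; for `n_active = 0` a "designated" axon is still drawn per
#' replicate (with no weight change) so the symmetry baseline win
#' probability of about 1/9 can be read off the same column.
#'
#' @param model A vacancy-mediated [nmj_model()] without preset activity.
#' @param n_active Integer vector of active-axon counts (default `0:9`).
#' @param n_reps Replicates per condition (default 100).
#' @param base_seed Integer root seed; condition seeds are derived.
#' @param ... Passed to [simulate.nmj_model()].
#' @return A list of class `nmj_sweep`: `table` (per-condition data
#'   frame with `n_active`, `mean_iterations`, `sd_iterations`,
#'   `completion_rate`, `p_active_win`) and `sims` (per-condition raw
#'   results).
#' @export
activity_sweep <- function(model, n_active = 0:9, n_reps = 100L,
                           base_seed = 1L, ...) {
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max, length(n_active))
  sims <- vector("list", length(n_active))
  rows <- vector("list", length(n_active))
  for (j in seq_along(n_active)) {
    k <- n_active[j]
    m <- model
    m$active <- NULL
    m$n_active <- max(1L, as.integer(k))  # designated axon even at k = 0
    if (k == 0L) m$selection_divisor <- 1
    s <- batch_run(m, n_reps = n_reps, base_seed = seeds[j],
                   label = sprintf("%d active", k), ...)
    sm <- summary(s)
    sims[[j]] <- s
    rows[[j]] <- data.frame(n_active = k,
                            mean_iterations = sm$mean_iterations,
                            sd_iterations = sm$sd_iterations,
                            completion_rate = sm$completion_rate,
                            p_active_win = sm$p_active_win)
  }
  structure(list(table = do.call(rbind, rows), sims = sims),
            class = "nmj_sweep")
}

#' @export
print.nmj_sweep <- function(x, ...) {
  cat("activity sweep\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot an activity sweep
#'
#' Bar chart of the mean least iterations to completion against the
#' number of active axons, with the zero-active condition as the
#' reference line.
#'
#' @param x An `nmj_sweep`.
#' @param ... Passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.nmj_sweep <- function(x, ...) {
  tab <- x$table
  bp <- graphics::barplot(tab$mean_iterations,
                          names.arg = tab$n_active,
                          xlab = "number of active axons",
                          ylab = "mean least iterations", ...)
  ref <- tab$mean_iterations[tab$n_active == 0]
  if (length(ref)) graphics::abline(h = ref, lty = 2)
  invisible(x)
}

#' Ratio sweep with the composite-area correlation
#'
#' Runs the batch experiment for a collection of per-endplate ratio
#' profiles and computes the two-tailed Spearman rank correlation between
#' each profile's composite area and its mean least iterations to
#' completion.  Profiles infeasible at the configured `p_vs` are skipped
#' with a warning.
#'
#' @param profiles A data frame with columns `label`, `tsc`, `vacancy`,
#'   `axon` (e.g. from [generate_ratio_variants()]).
#' @param model Template [nmj_model()]; each profile replaces its
#'   stationary target.
#' @param n_reps Replicates per profile.
#' @param base_seed Integer root seed.
#' @param runner Function `(model, n_reps, seed)` returning the vector
#'   of per-replicate completion iterations; the default runs
#'   [batch_run()].  Exposed so the statistical pipeline can be exercised
#'   with a deterministic stub.
#' @return A list of class `nmj_ratio_sweep`: `table` (per-profile
#'   composite area and iteration summary), `cor` (the
#'   [stats::cor.test()] result, or `NULL` when fewer than 3 profiles
#'   survive or the ranks are degenerate).
#' @export
ratio_sweep <- function(profiles, model = nmj_model(), n_reps = 100L,
                        base_seed = 1L, runner = NULL) {
  stopifnot(is.data.frame(profiles),
            all(c("tsc", "vacancy", "axon") %in% names(profiles)))
  if (is.null(profiles$label)) profiles$label <- seq_len(nrow(profiles))
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max, nrow(profiles))
  if (is.null(runner)) {
    runner <- function(model, n_reps, seed) {
      s <- summary(batch_run(model, n_reps = n_reps, base_seed = seed))
      s$iterations
    }
  }
  rows <- list()
  for (i in seq_len(nrow(profiles))) {
    r <- area_ratios(profiles$tsc[i], profiles$vacancy[i], profiles$axon[i])
    m <- tryCatch({
      mm <- model
      mm$stationary <- r
      mm$probs <- solve_stationary_probs(r, p_vs = model$p_vs)
      mm
    }, nmj_infeasible = function(e) {
      warning(sprintf("profile '%s' skipped: %s", profiles$label[i],
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(m)) next
    iters <- runner(m, n_reps, seeds[i])
    rows[[length(rows) + 1L]] <- data.frame(
      label = as.character(profiles$label[i]),
      tsc = r[["tsc"]], vacancy = r[["vacancy"]], axon = r[["axon"]],
      composite_area = composite_area(r),
      mean_iterations = mean(iters), sd_iterations = stats::sd(iters),
      n = length(iters))
  }
  tab <- do.call(rbind, rows)
  ct <- NULL
  if (!is.null(tab) && nrow(tab) >= 3L &&
      length(unique(tab$composite_area)) > 1L &&
      length(unique(tab$mean_iterations)) > 1L) {
    ct <- suppressWarnings(stats::cor.test(tab$composite_area,
                                           tab$mean_iterations,
                                           method = "spearman",
                                           alternative = "two.sided"))
  }
  structure(list(table = tab, cor = ct), class = "nmj_ratio_sweep")
}

#' @export
print.nmj_ratio_sweep <- function(x, ...) {
  cat("ratio sweep\n")
  print(x$table, row.names = FALSE, digits = 4)
  if (!is.null(x$cor)) {
    cat(sprintf("Spearman rho = %.3f, two-tailed p = %.4g\n",
                unname(x$cor$estimate), x$cor$p.value))
  } else {
    cat("Spearman correlation undefined (fewer than 3 profiles or degenerate ranks)\n")
  }
  invisible(x)
}

#' Developmental-stage comparison
#'
#' Runs the baseline batch experiment with transition probabilities
#' solved from each stage's measured average area ratios (initial layouts
#' always at the P0 composition) and compares the per-stage iteration
#' samples with pairwise two-tailed t-tests (Welch by default).
#'
#' @param stages Stage labels with bundled ratios (default
#'   `c("P3", "P7", "P16")`).
#' @param model Template [nmj_model()].
#' @param n_reps Replicates per stage (default 100).
#' @param base_seed Integer root seed.
#' @param var_equal Use the pooled-variance t-test instead of Welch?
#' @param ... Passed to [simulate.nmj_model()].
#' @return A list of class `nmj_stage_cmp`: `summaries` (per-stage data
#'   frame), `tests` (pairwise data frame with `t`, `df`, `p_value`),
#'   `sims` (raw per-stage results).
#' @export
stage_comparison <- function(stages = c("P3", "P7", "P16"),
                             model = nmj_model(), n_reps = 100L,
                             base_seed = 1L, var_equal = FALSE, ...) {
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max, length(stages))
  sims <- list(); iters <- list(); rows <- list()
  for (j in seq_along(stages)) {
    st <- stages[j]
    m <- model
    m$stationary <- stage_ratios(st)
    m$probs <- solve_stationary_probs(m$stationary, p_vs = model$p_vs)
    s <- batch_run(m, n_reps = n_reps, base_seed = seeds[j], label = st, ...)
    sm <- summary(s)
    sims[[st]] <- s
    iters[[st]] <- sm$iterations
    rows[[j]] <- data.frame(stage = st,
                            composite_area = composite_area(m$stationary),
                            n_reps = sm$n_reps,
                            completion_rate = sm$completion_rate,
                            mean_iterations = sm$mean_iterations,
                            sd_iterations = sm$sd_iterations)
  }
  pairs <- utils::combn(stages, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(p) {
    tt <- stats::t.test(iters[[p[1]]], iters[[p[2]]],
                        alternative = "two.sided", var.equal = var_equal)
    data.frame(stage_a = p[1], stage_b = p[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value)
  }))
  structure(list(summaries = do.call(rbind, rows), tests = tests,
                 sims = sims), class = "nmj_stage_cmp")
}

#' @export
print.nmj_stage_cmp <- function(x, ...) {
  cat("stage comparison\n")
  print(x$summaries, row.names = FALSE, digits = 4)
  cat("pairwise two-tailed t-tests\n")
  print(x$tests, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Generate synthetic per-endplate ratio profiles
#'
#' Draws ratio triplets from a Dirichlet distribution with the given mean
#' and concentration, emulating the endplate-to-endplate variability of
#' measured area ratios around a stage average.  Draws infeasible at the
#' configured `p_vs` (i.e. for which no valid transition probabilities
#' exist) are rejected and redrawn.
#'
#' @param mean_ratios Dirichlet mean ([area_ratios()] or stage label).
#' @param concentration Dirichlet concentration (sum of the shape
#'   parameters; default 50, giving visible spread while keeping draws
#'   feasible).
#' @param n_profiles Number of profiles (default 8, matching the number
#'   of measured P3 endplates the synthetic profiles stand in for).
#' @param seed Optional integer seed.
#' @param p_vs Feasibility is checked at this free parameter.
#' @param max_attempts Total draw budget before giving up.
#' @return A data frame with columns `label`, `tsc`, `vacancy`, `axon`,
#'   `composite_area`.
#' @examples
#' generate_ratio_variants("P3", n_profiles = 4, seed = 1)
#' @export
generate_ratio_variants <- function(mean_ratios = "P3", concentration = 50,
                                    n_profiles = 8L, seed = NULL, p_vs = 0.6,
                                    max_attempts = 1000L) {
  if (is.character(mean_ratios)) mean_ratios <- stage_ratios(mean_ratios)
  m <- as_ratios(mean_ratios)
  if (concentration <= 0) stop("concentration must be positive")
  if (n_profiles < 1L) stop("n_profiles must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  shape <- as.numeric(m) * concentration
  out <- vector("list", n_profiles)
  got <- 0L
  for (a in seq_len(max_attempts)) {
    g <- stats::rgamma(3, shape = shape)
    r <- area_ratios(g / sum(g), tol = 1)
    ok <- tryCatch({ solve_stationary_probs(r, p_vs = p_vs); TRUE },
                   error = function(e) FALSE)
    if (ok) {
      got <- got + 1L
      out[[got]] <- data.frame(label = sprintf("profile_%d", got),
                               tsc = r[["tsc"]], vacancy = r[["vacancy"]],
                               axon = r[["axon"]],
                               composite_area = composite_area(r))
      if (got == n_profiles) break
    }
  }
  if (got < n_profiles) {
    stop(sprintf(paste0("only %d of %d feasible profiles drawn in %d attempts; ",
                        "increase `concentration` (tighter spread) or the budget"),
                 got, n_profiles, max_attempts))
  }
  do.call(rbind, out)
}

#' Exponential fit to the mean distinct-axon decline
#'
#' Across a batch of series-recording replicates, computes the mean
#' number of surviving axon identities at each sampled iteration (runs
#' that finished early are held at their final value) and fits the
#' exponential relaxation `N(t) = 1 + A * exp(-b * t)` toward the
#' absorbing single-survivor count, as a log-linear regression of the
#' excess `N(t) - 1` over the declining phase (mean count above
#' `floor_count`).
#'
#' @param sims An `nmj_sims` object simulated with
#'   `record_series = TRUE`.
#' @param floor_count Mean-count cutoff ending the fitted phase
#'   (default 1.1, just above the single-survivor floor).
#' @return A list with `iteration`, `mean_axons`, the fitted `lm` (of
#'   `log(mean - 1)` on iteration), the decay `rate` (per iteration) and
#'   `r_squared`.
#' @export
axon_decline_fit <- function(sims, floor_count = 1.1) {
  runs <- attr(sims, "runs")
  if (is.null(runs) || is.null(runs[[1L]]$series)) {
    stop("simulate with record_series = TRUE first")
  }
  grid <- sort(unique(unlist(lapply(runs, function(r) r$series$iteration))))
  mat <- sapply(runs, function(r) {
    s <- r$series
    stats::approx(s$iteration, s$n_axon_types, xout = grid, method = "constant",
                  rule = 2, f = 0)$y
  })
  mean_axons <- rowMeans(mat)
  keep <- mean_axons > floor_count
  it <- grid[keep]
  fit <- stats::lm(log(mean_axons[keep] - 1) ~ it)
  list(iteration = grid, mean_axons = mean_axons, fit = fit,
       rate = -unname(stats::coef(fit)[2L]),
       r_squared = summary(fit)$r.squared)
}
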