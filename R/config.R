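## Run configuration and the command-line interface.
##
## A run config is a nested list (YAML on disk; JSON accepted) with the
## blocks geometry / composition / model / activity / execution / output.
## Every field defaults to the baseline study conditions: a 300 px
## endplate of 100 sites of 30 px, 9 axons starting at the P0
## composition, vacancy-mediated probabilities solved from the P3 ratios
## at p_VS = 0.6, selection divisor 2, 100 replicates.

#' Default run configuration
#'
#' @return A nested list with blocks `geometry`, `composition`, `model`,
#'   `activity`, `execution`, `output`.
#' @export
default_config <- function() {
  list(
    geometry = list(region_diameter = 300, site_diameter = 30, n_sites = 100,
                    min_separation_factor = 0.8, neighbor_distance = 37.5),
    composition = list(init = "P0", n_axons = 9),
    model = list(variant = "vacancy_mediated", stationary = "P3", p_vs = 0.6,
                 donor_rule = "adjacent"),
    activity = list(n_active = 0, active = NULL, selection_divisor = 2),
    execution = list(max_iter = NULL, n_reps = 100, base_seed = 1,
                     series_stride = 0),
    output = list(dir = ".", prefix = "run")
  )
}

#' Read a run configuration file
#'
#' Reads a YAML (or JSON) run configuration, overlays it on
#' [default_config()] and validates the result.  Unknown blocks or
#' fields are rejected before any computation.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return The resolved config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  resolve_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A (possibly partial) config list.
#' @export
resolve_config <- function(cfg = list()) {
  def <- default_config()
  bad <- setdiff(names(cfg), names(def))
  if (length(bad)) {
    stop(sprintf("unknown config block(s): %s", paste(bad, collapse = ", ")))
  }
  for (blk in names(cfg)) {
    badf <- setdiff(names(cfg[[blk]]), names(def[[blk]]))
    if (length(badf)) {
      stop(sprintf("unknown field(s) in config block '%s': %s", blk,
                   paste(badf, collapse = ", ")))
    }
    def[[blk]][names(cfg[[blk]])] <- cfg[[blk]]
  }
  if (!def$model$variant %in% c("vacancy_mediated", "random", "equal")) {
    stop("model.variant must be vacancy_mediated, random or equal")
  }
  def
}

config_ratios <- function(x) {
  if (is.character(x) && length(x) == 1L) stage_ratios(x) else area_ratios(x)
}

#' Build a model from a run configuration
#'
#' @param cfg A resolved config list (see [read_run_config()]).
#' @return An [nmj_model()].
#' @export
config_to_model <- function(cfg) {
  cfg <- resolve_config(cfg)
  n_active <- cfg$activity$n_active
  active <- cfg$activity$active
  nmj_model(
    stationary = if (cfg$model$variant == "vacancy_mediated")
      config_ratios(cfg$model$stationary) else "P3",
    p_vs = cfg$model$p_vs, variant = cfg$model$variant,
    init = config_ratios(cfg$composition$init),
    n_axons = cfg$composition$n_axons, n_sites = cfg$geometry$n_sites,
    region_diameter = cfg$geometry$region_diameter,
    site_diameter = cfg$geometry$site_diameter,
    min_separation_factor = cfg$geometry$min_separation_factor,
    neighbor_distance = cfg$geometry$neighbor_distance,
    active = if (length(active)) as.integer(active) else NULL,
    n_active = if (length(active)) NULL else
      if (n_active > 0) as.integer(n_active) else NULL,
    selection_divisor = cfg$activity$selection_divisor,
    max_iter = cfg$execution$max_iter, donor_rule = cfg$model$donor_rule)
}

#' Write per-run records as CSV
#'
#' @param sims An `nmj_sims` data frame.
#' @param path Output CSV path.
#' @param label Condition label written into every row.
#' @return `path`, invisibly.
#' @export
write_sims_csv <- function(sims, path, label = attr(sims, "label") %||% "") {
  df <- cbind(condition = label, as.data.frame(sims))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

summary_to_list <- function(sm) {
  list(label = sm$label, n_reps = sm$n_reps, n_completed = sm$n_completed,
       completion_rate = sm$completion_rate,
       mean_iterations = sm$mean_iterations,
       sd_iterations = sm$sd_iterations,
       win_table = as.list(stats::setNames(sm$win_table,
                                           paste0("axon_", seq_along(sm$win_table)))),
       p_active_win = sm$p_active_win)
}

write_summary_json <- function(x, cfg, path) {
  payload <- list(package = "nmjelim",
                  version = as.character(utils::packageVersion("nmjelim")),
                  config = cfg, results = x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}

## ---- command-line interface -------------------------------------------

cli_usage <- function() {
  paste(
    "usage: nmjsim <command> [options]",
    "",
    "commands:",
    "  solve-probs   --ratios S,V,A [--pvs 0.6]",
    "  simulate      --config FILE [--n-reps N] [--base-seed N] [--out-dir DIR]",
    "  sweep         activity|stages|ratios --config FILE [--n-reps N]",
    "                [--base-seed N] [--n-active 0..9] [--stages P3,P7,P16]",
    "                [--n-profiles N] [--concentration C] [--out-dir DIR]",
    "  export-layout --out FILE [--config FILE] [--seed N]",
    sep = "\n")
}

parse_cli_args <- function(args) {
  opts <- list(); pos <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3))
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        opts[[key]] <- TRUE; i <- i + 1L
      } else {
        opts[[key]] <- args[i + 1L]; i <- i + 2L
      }
    } else {
      pos <- c(pos, a); i <- i + 1L
    }
  }
  list(opts = opts, pos = pos)
}

opt_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

cli_load_config <- function(opts) {
  cfg <- if (!is.null(opts$config)) read_run_config(opts$config) else resolve_config()
  if (!is.null(opts$n_reps)) cfg$execution$n_reps <- as.integer(opts$n_reps)
  if (!is.null(opts$base_seed)) cfg$execution$base_seed <- as.integer(opts$base_seed)
  if (!is.null(opts$max_iter)) cfg$execution$max_iter <- as.integer(opts$max_iter)
  if (!is.null(opts$model)) cfg$model$variant <- opts$model
  if (!is.null(opts$out_dir)) cfg$output$dir <- opts$out_dir
  cfg
}

cli_solve_probs <- function(opts) {
  if (is.null(opts$ratios)) stop("solve-probs needs --ratios S,V,A")
  r <- area_ratios(as.numeric(strsplit(opts$ratios, ",")[[1]]))
  p <- solve_stationary_probs(r, p_vs = opt_num(opts, "pvs", 0.6))
  print(p)
  invisible(p)
}

cli_simulate <- function(opts) {
  cfg <- cli_load_config(opts)
  model <- config_to_model(cfg)
  stride <- cfg$execution$series_stride
  sims <- batch_run(model, n_reps = cfg$execution$n_reps,
                    base_seed = cfg$execution$base_seed,
                    label = cfg$output$prefix,
                    record_series = stride > 0,
                    series_stride = max(1L, as.integer(stride)))
  dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(cfg$output$dir, cfg$output$prefix)
  write_sims_csv(sims, paste0(base, "_runs.csv"))
  sm <- summary(sims)
  write_summary_json(summary_to_list(sm), cfg, paste0(base, "_summary.json"))
  message(sprintf("wrote %s_runs.csv and %s_summary.json", base, base))
  print(sm)
  invisible(sims)
}

cli_sweep <- function(opts, what) {
  cfg <- cli_load_config(opts)
  model <- config_to_model(cfg)
  dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(cfg$output$dir, cfg$output$prefix)
  n_reps <- cfg$execution$n_reps
  seed <- cfg$execution$base_seed
  if (what == "activity") {
    rng <- if (!is.null(opts$n_active)) {
      lim <- as.integer(strsplit(gsub("\\.\\.", ",", opts$n_active), ",")[[1]])
      if (length(lim) == 2L) lim[1]:lim[2] else lim
    } else 0:model$n_axons
    sw <- activity_sweep(model, n_active = rng, n_reps = n_reps, base_seed = seed)
    for (j in seq_along(sw$sims)) {
      write_sims_csv(sw$sims[[j]],
                     sprintf("%s_activity_%d_runs.csv", base, sw$table$n_active[j]))
    }
    write_summary_json(sw$table, cfg, paste0(base, "_activity_summary.json"))
    print(sw)
    return(invisible(sw))
  }
  if (what == "stages") {
    stages <- if (!is.null(opts$stages)) strsplit(opts$stages, ",")[[1]]
              else c("P3", "P7", "P16")
    sc <- stage_comparison(stages, model = model, n_reps = n_reps,
                           base_seed = seed)
    for (st in names(sc$sims)) {
      write_sims_csv(sc$sims[[st]], sprintf("%s_stage_%s_runs.csv", base, st))
    }
    write_summary_json(list(summaries = sc$summaries, t_tests = sc$tests), cfg,
                       paste0(base, "_stages_summary.json"))
    print(sc)
    return(invisible(sc))
  }
  if (what == "ratios") {
    profiles <- generate_ratio_variants(
      model$stationary %||% "P3",
      concentration = opt_num(opts, "concentration", 50),
      n_profiles = as.integer(opt_num(opts, "n_profiles", 8)),
      seed = seed, p_vs = model$p_vs)
    rs <- ratio_sweep(profiles, model = model, n_reps = n_reps,
                      base_seed = seed)
    write_summary_json(list(
      table = rs$table,
      spearman = if (is.null(rs$cor)) NULL else
        list(rho = unname(rs$cor$estimate), p_value = rs$cor$p.value)),
      cfg, paste0(base, "_ratios_summary.json"))
    print(rs)
    return(invisible(rs))
  }
  stop(sprintf("unknown sweep '%s'; expected activity, stages or ratios", what))
}

cli_export_layout <- function(opts) {
  if (is.null(opts$out)) stop("export-layout needs --out FILE")
  cfg <- cli_load_config(opts)
  model <- config_to_model(cfg)
  lay <- new_model_layout(model, seed = as.integer(opt_num(opts, "seed", 1)))
  write_layout(lay, opts$out)
  message(sprintf("wrote %s", opts$out))
  invisible(lay)
}

#' Command-line entry point
#'
#' Dispatches the `nmjsim` subcommands (`solve-probs`, `simulate`,
#' `sweep`, `export-layout`).  The installed script
#' `system.file("cli", "nmjsim.R", package = "nmjelim")` is a thin
#' wrapper around this function.
#'
#' @param args Character vector of command-line arguments (default: the
#'   trailing arguments of the calling `Rscript`).
#' @return Integer exit status (0 on success), invisibly.
#' @export
nmj_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message(cli_usage())
    return(invisible(1L))
  }
  cmd <- args[1]
  parsed <- parse_cli_args(args[-1])
  status <- tryCatch({
    switch(cmd,
           "solve-probs" = cli_solve_probs(parsed$opts),
           "simulate" = cli_simulate(parsed$opts),
           "sweep" = {
             if (length(parsed$pos) < 1L) stop("sweep needs a kind: activity, stages or ratios")
             cli_sweep(parsed$opts, parsed$pos[1])
           },
           "export-layout" = cli_export_layout(parsed$opts),
           stop(sprintf("unknown command '%s'\n%s", cmd, cli_usage())))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
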