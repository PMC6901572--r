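## Endplate geometry: circular contact sites randomly placed in a disc.
## Occupant codes used throughout (and in the C++ engine):
##   -1 = tSC, 0 = vacancy, k >= 1 = axon identity k.

OCC_TSC <- -1L
OCC_VAC <- 0L

#' Apportion site counts to occupant classes
#'
#' Converts an area-ratio triplet into integer site counts for a layout of
#' `n_sites` identically sized sites, by largest-remainder apportionment
#' over the three classes (ties broken in the order tSC, vacancy, axon).
#' The axon pool is then split as evenly as possible across the
#' `n_axons` identities, with remainders assigned to the lowest ids
#' (identities are exchangeable, so this is bias-free once occupants are
#' shuffled over positions).
#'
#' @param ratios Target composition ([area_ratios()]).
#' @param n_axons Number of distinct axon identities (default 9, the
#'   maximum number of different axons observed per endplate at P0).
#' @param n_sites Total number of contact sites (default 100).
#' @return A list of class `nmj_counts`: `tsc`, `vacancy` (integers) and
#'   `axon` (integer vector of length `n_axons`, per-identity counts).
#' @examples
#' apportion_site_counts(area_ratios(30, 16, 54))
#' @export
apportion_site_counts <- function(ratios, n_axons = 9L, n_sites = 100L) {
  r <- as_ratios(ratios)
  n_axons <- as.integer(n_axons)
  n_sites <- as.integer(n_sites)
  if (n_axons < 1L) stop("n_axons must be at least 1")
  if (n_sites < n_axons + 2L) {
    stop(sprintf("n_sites = %d is too small for %d axons plus tSC and vacancy classes",
                 n_sites, n_axons))
  }
  quota <- as.numeric(r) * n_sites
  base <- floor(quota)
  left <- n_sites - sum(base)
  if (left > 0) {
    # largest fractional remainder; ties resolved by class order (S, V, A)
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  counts <- as.integer(base)
  if (r[["axon"]] > 0 && counts[3] < n_axons) {
    stop(sprintf(paste0("configuration error: %d axon sites cannot give each of ",
                        "%d axons at least one site; increase n_sites"),
                 counts[3], n_axons))
  }
  per <- counts[3] %/% n_axons
  extra <- counts[3] %% n_axons
  axon <- rep(per, n_axons) + as.integer(seq_len(n_axons) <= extra)
  structure(list(tsc = counts[1], vacancy = counts[2], axon = axon),
            class = "nmj_counts")
}

counts_total <- function(counts) counts$tsc + counts$vacancy + sum(counts$axon)

# occupant code vector implied by a counts object, in class order
counts_to_occ <- function(counts) {
  c(rep(OCC_TSC, counts$tsc), rep(OCC_VAC, counts$vacancy),
    rep(seq_along(counts$axon), counts$axon))
}

#' Place contact sites randomly in the endplate disc
#'
#' Random sequential placement of `n` identical circular sites inside a
#' round endplate region: candidate centres are drawn uniformly over the
#' disc that keeps sites fully inside, and a candidate is accepted when
#' its centre is at least `min_separation_factor * site_diameter` from
#' every accepted centre.  Because sequential insertion jams well below
#' the densest feasible packing, a site that finds no admissible
#' candidate within its attempt budget keeps its best (max-min-distance)
#' candidate, and a pairwise-repulsion relaxation then nudges violating
#' pairs apart until every separation constraint holds (or errors when
#' the demanded density is genuinely unpackable).  Occupants are finally
#' assigned to the placed positions in a uniformly random permutation,
#' so all classes are spatially interleaved at the start.
#'
#' Sites are allowed to overlap mildly (the default separation factor is
#' 0.8): at the default density of 100 sites of diameter 30 px in a
#' 300 px region, strictly non-overlapping packing is geometrically
#' impossible.
#'
#' @param counts Site counts from [apportion_site_counts()].
#' @param region_diameter Endplate disc diameter in pixels (default 300).
#' @param site_diameter Contact-site diameter in pixels (default 30).
#' @param min_separation_factor Minimum pairwise centre distance as a
#'   fraction of `site_diameter`, in (0, 1] (default 0.8).
#' @param seed Optional integer; when given, `set.seed(seed)` is called
#'   so the layout is reproducible.
#' @param max_attempts Rejection-sampling attempt cap per site.
#' @param relax_sweeps Cap on pairwise-repulsion relaxation sweeps.
#' @param neighbor_distance Centre-distance threshold defining adjacent
#'   sites, in pixels (default `1.25 * site_diameter`).
#' @return An object of class `nmj_layout`; see Details.
#' @details The layout object is a list with elements `region_diameter`,
#'   `site_diameter`, `neighbor_distance`, `n_axons`, `x`, `y` (site
#'   centres, origin at the disc centre), `occ` (occupant codes: -1 tSC,
#'   0 vacancy, k >= 1 axon k) and `adjacency` (list of neighbour index
#'   vectors).  `as.data.frame()` gives the per-site table.
#' @examples
#' lay <- place_sites(apportion_site_counts(stage_ratios("P0")), seed = 1)
#' lay
#' @export
place_sites <- function(counts, region_diameter = 300, site_diameter = 30,
                        min_separation_factor = 0.8, seed = NULL,
                        max_attempts = 200L, relax_sweeps = 2000L,
                        neighbor_distance = 1.25 * site_diameter) {
  stopifnot(inherits(counts, "nmj_counts"))
  if (min_separation_factor <= 0 || min_separation_factor > 1) {
    stop("min_separation_factor must lie in (0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- counts_total(counts)
  if (n < 1L) stop("cannot place an empty layout")
  r_max <- region_diameter / 2 - site_diameter / 2
  if (r_max < 0) stop("site_diameter exceeds region_diameter")
  min_sep <- min_separation_factor * site_diameter
  density <- n * (site_diameter / region_diameter)^2  # site area / region area
  geom_err <- function(what) {
    stop(sprintf(paste0("geometry error: %s (n = %d, site-to-region area ratio ",
                        "%.2f, min separation %.1f px); reduce n_sites or ",
                        "min_separation_factor"), what, n, density, min_sep))
  }
  # provably unpackable demand: centres separated by min_sep in a disc of
  # radius r_max are disks of radius min_sep/2 inside radius r_max + min_sep/2,
  # whose density cannot exceed the hexagonal bound
  if (n * (min_sep / 2)^2 > 0.9069 * (r_max + min_sep / 2)^2) {
    geom_err("demanded density exceeds the hexagonal packing bound")
  }
  x <- numeric(n); y <- numeric(n)
  clean <- TRUE
  for (i in seq_len(n)) {
    best <- -Inf
    for (a in seq_len(max_attempts)) {
      rad <- r_max * sqrt(stats::runif(1))
      th <- 2 * pi * stats::runif(1)
      cx <- rad * cos(th); cy <- rad * sin(th)
      d2 <- if (i == 1L) Inf else
        min((x[seq_len(i - 1L)] - cx)^2 + (y[seq_len(i - 1L)] - cy)^2)
      if (d2 > best) { best <- d2; x[i] <- cx; y[i] <- cy }
      if (d2 >= min_sep^2) break
    }
    if (best < min_sep^2) clean <- FALSE  # keep best candidate; relax below
  }
  if (!clean) {
    # sequential insertion jams below the feasible packing density, so
    # push violating pairs apart until every separation constraint holds;
    # relaxing against a slightly inflated target keeps the deficit-
    # proportional pushes from stalling just below the bound
    target <- min_sep * 1.002
    converged <- FALSE
    for (sweep in seq_len(relax_sweeps)) {
      d <- as.matrix(stats::dist(cbind(x, y)))
      dd <- d; diag(dd) <- Inf
      if (min(dd) >= min_sep) { converged <- TRUE; break }
      viol <- which(d < target & upper.tri(d), arr.ind = TRUE)
      fx <- numeric(n); fy <- numeric(n)
      for (v in seq_len(nrow(viol))) {
        i <- viol[v, 1L]; j <- viol[v, 2L]
        dx <- x[j] - x[i]; dy <- y[j] - y[i]
        dij <- max(d[i, j], 1e-9)
        if (d[i, j] < 1e-9) {  # coincident centres: random push direction
          th <- 2 * pi * stats::runif(1)
          dx <- cos(th); dy <- sin(th)
        }
        push <- 0.6 * (target - dij) / dij
        fx[i] <- fx[i] - push * dx; fy[i] <- fy[i] - push * dy
        fx[j] <- fx[j] + push * dx; fy[j] <- fy[j] + push * dy
      }
      x <- x + fx; y <- y + fy
      rad <- sqrt(x * x + y * y)
      out <- rad > r_max
      if (any(out)) {
        x[out] <- x[out] * r_max / rad[out]
        y[out] <- y[out] * r_max / rad[out]
      }
    }
    if (!converged) geom_err("site packing did not converge")
  }
  occ <- counts_to_occ(counts)
  occ <- occ[sample.int(n)]
  layout <- structure(
    list(region_diameter = region_diameter, site_diameter = site_diameter,
         neighbor_distance = neighbor_distance, n_axons = length(counts$axon),
         x = x, y = y, occ = as.integer(occ), adjacency = NULL),
    class = "nmj_layout")
  layout$adjacency <- build_adjacency(layout, neighbor_distance)
  layout
}

#' Adjacency relation of a layout
#'
#' Two distinct sites are adjacent when their centre distance does not
#' exceed `neighbor_distance`.  The default threshold, 1.25 site
#' diameters, captures touching and slightly separated circles under the
#' permitted overlap.
#'
#' @param layout An `nmj_layout`.
#' @param neighbor_distance Centre-distance threshold in pixels.
#' @return A list (one element per site) of sorted neighbour indices;
#'   the relation is symmetric and irreflexive.
#' @export
build_adjacency <- function(layout, neighbor_distance = layout$neighbor_distance) {
  stopifnot(inherits(layout, "nmj_layout"), neighbor_distance > 0)
  n <- length(layout$x)
  d <- as.matrix(stats::dist(cbind(layout$x, layout$y)))
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    adj[[i]] <- as.integer(unname(which(d[i, ] <= neighbor_distance &
                                          seq_len(n) != i)))
  }
  adj
}

#' Occupancy fractions of a layout
#'
#' All sites have identical area, so class count fractions equal class
#' area fractions.
#'
#' @param layout An `nmj_layout` (or a bare occupant-code vector).
#' @param n_axons Number of axon identities (taken from the layout when
#'   one is given).
#' @return A list with `ratios` (an [area_ratios()] triplet) and
#'   `axon_fractions` (per-identity site fractions, length `n_axons`).
#' @export
layout_ratios <- function(layout, n_axons = NULL) {
  if (inherits(layout, "nmj_layout")) {
    occ <- layout$occ
    n_axons <- layout$n_axons
  } else {
    occ <- as.integer(layout)
    if (is.null(n_axons)) n_axons <- max(0L, occ)
  }
  n <- length(occ)
  if (n == 0L) stop("layout is empty")
  ax <- tabulate(occ[occ >= 1L], nbins = n_axons)
  list(ratios = area_ratios(sum(occ == OCC_TSC) / n, sum(occ == OCC_VAC) / n,
                            sum(occ >= 1L) / n, tol = 1),
       axon_fractions = ax / n)
}

#' @export
print.nmj_layout <- function(x, ...) {
  lr <- layout_ratios(x)
  cat(sprintf("endplate layout: %d sites (%d px) in a %d px disc, %d axon identities\n",
              length(x$occ), round(x$site_diameter), round(x$region_diameter),
              x$n_axons))
  cat(sprintf("  composition: tSC %.2f, vacancy %.2f, axon %.2f (%d identities present)\n",
              lr$ratios[["tsc"]], lr$ratios[["vacancy"]], lr$ratios[["axon"]],
              sum(lr$axon_fractions > 0)))
  invisible(x)
}

#' @export
as.data.frame.nmj_layout <- function(x, ...) {
  data.frame(site_id = seq_along(x$occ), x = x$x, y = x$y,
             kind = occ_kind(x$occ),
             axon_id = ifelse(x$occ >= 1L, x$occ, NA_integer_))
}

occ_kind <- function(occ) {
  ifelse(occ >= 1L, "axon", ifelse(occ == OCC_TSC, "tsc", "vacancy"))
}

kind_to_occ <- function(kind, axon_id) {
  occ <- integer(length(kind))
  occ[kind == "tsc"] <- OCC_TSC
  occ[kind == "vacancy"] <- OCC_VAC
  is_ax <- kind == "axon"
  occ[is_ax] <- as.integer(axon_id[is_ax])
  occ
}

#' Export / import a layout snapshot
#'
#' Writes the full layout (geometry parameters plus the per-site records)
#' as structured JSON; `read_layout()` reconstructs an identical layout,
#' recomputing the adjacency relation from the stored coordinates and
#' threshold.
#'
#' @param layout An `nmj_layout`.
#' @param path File path for the JSON snapshot.
#' @return `write_layout()` returns `path` invisibly; `read_layout()`
#'   returns the reconstructed `nmj_layout`.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "nmj_layout"))
  rec <- list(region_diameter = layout$region_diameter,
              site_diameter = layout$site_diameter,
              neighbor_distance = layout$neighbor_distance,
              n_axons = layout$n_axons,
              sites = as.data.frame(layout))
  jsonlite::write_json(rec, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  sites <- rec$sites
  if (is.null(sites$axon_id)) sites$axon_id <- NA_integer_
  layout <- structure(
    list(region_diameter = rec$region_diameter, site_diameter = rec$site_diameter,
         neighbor_distance = rec$neighbor_distance, n_axons = rec$n_axons,
         x = as.numeric(sites$x), y = as.numeric(sites$y),
         occ = kind_to_occ(sites$kind, sites$axon_id), adjacency = NULL),
    class = "nmj_layout")
  layout$adjacency <- build_adjacency(layout)
  layout
}

#' Plot an endplate layout
#'
#' Draws the contact sites as circles coloured by occupant: green tSCs,
#' black vacancies, other colours for the axon identities.
#'
#' @param x An `nmj_layout`.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.nmj_layout <- function(x, main = "endplate layout", ...) {
  pal <- c("blue", "red", "darkblue", "yellow", "pink", "purple",
           "darkgreen", "grey", "brown")
  pal <- rep_len(pal, max(1L, x$n_axons))
  col <- ifelse(x$occ >= 1L, pal[pmax(x$occ, 1L)],
                ifelse(x$occ == OCC_TSC, "forestgreen", "black"))
  r_half <- x$region_diameter / 2
  graphics::plot(NA, xlim = c(-r_half, r_half), ylim = c(-r_half, r_half),
                 asp = 1, xlab = "x (px)", ylab = "y (px)", main = main, ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(r_half * cos(th), r_half * sin(th), col = "grey60")
  graphics::symbols(x$x, x$y, circles = rep(x$site_diameter / 2, length(x$x)),
                    inches = FALSE, add = TRUE, bg = col, fg = "grey30")
  invisible(x)
}

#' Build a complete initial endplate layout
#'
#' Convenience wrapper chaining [apportion_site_counts()],
#' [place_sites()] and [build_adjacency()].
#'
#' @inheritParams apportion_site_counts
#' @inheritParams place_sites
#' @return An `nmj_layout`.
#' @examples
#' endplate_layout(stage_ratios("P0"), seed = 1)
#' @export
endplate_layout <- function(ratios, n_axons = 9L, n_sites = 100L,
                            region_diameter = 300, site_diameter = 30,
                            min_separation_factor = 0.8,
                            neighbor_distance = 1.25 * site_diameter,
                            seed = NULL, max_attempts = 200L,
                            relax_sweeps = 2000L) {
  counts <- apportion_site_counts(ratios, n_axons = n_axons, n_sites = n_sites)
  place_sites(counts, region_diameter = region_diameter,
              site_diameter = site_diameter,
              min_separation_factor = min_separation_factor, seed = seed,
              max_attempts = max_attempts, relax_sweeps = relax_sweeps,
              neighbor_distance = neighbor_distance)
}
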