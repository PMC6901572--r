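# shared fixtures: small layouts and solved probabilities

p3_probs <- solve_stationary_probs(stage_ratios("P3"), p_vs = 0.6)

small_layout <- function(seed = 1L, n_sites = 30L, ratios = stage_ratios("P0"),
                         n_axons = 9L) {
  endplate_layout(ratios, n_axons = n_axons, n_sites = n_sites, seed = seed)
}

# hand-built layout: explicit coordinates and occupants, unit geometry
manual_layout <- function(x, y, occ, n_axons = max(1L, occ),
                          neighbor_distance = 1.5, site_diameter = 1,
                          region_diameter = 1e6) {
  lay <- structure(
    list(region_diameter = region_diameter, site_diameter = site_diameter,
         neighbor_distance = neighbor_distance, n_axons = as.integer(n_axons),
         x = x, y = y, occ = as.integer(occ), adjacency = NULL),
    class = "nmj_layout")
  lay$adjacency <- build_adjacency(lay)
  lay
}

# independent O(n^2) adjacency oracle
adjacency_oracle <- function(lay, nd = lay$neighbor_distance) {
  n <- length(lay$x)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- integer(0)
    for (j in seq_len(n)) {
      if (i != j &&
          sqrt((lay$x[i] - lay$x[j])^2 + (lay$y[i] - lay$y[j])^2) <= nd) {
        nb <- c(nb, j)
      }
    }
    out[[i]] <- nb
  }
  out
}
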