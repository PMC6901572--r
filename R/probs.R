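## Transition-probability structures for the site competition chain.
## State order everywhere: S (tSC), V (vacancy), A (axon, identities pooled).

#' Vacancy-mediated transition probabilities
#'
#' In the vacancy-mediated competition scheme, axon and tSC sites never
#' exchange directly: an axon site can only become a vacancy (probability
#' `p_av`, else it stays), a tSC site can only become a vacancy (`p_sv`,
#' else it stays), and a vacant site always transitions, to a tSC with
#' probability `p_vs` or to an axon with probability `1 - p_vs`.
#'
#' @param p_av Probability that a selected axon site becomes vacant.
#' @param p_sv Probability that a selected tSC site becomes vacant.
#' @param p_vs Probability that a selected vacant site becomes a tSC
#'   (complement: it is reclaimed by an axon).
#' @return An object of class `nmj_vm_probs` with the three free
#'   probabilities and their complements `p_aa`, `p_ss`, `p_va`.
#' @seealso [solve_stationary_probs()], [stationary_vector()]
#' @export
vm_probs <- function(p_av, p_sv, p_vs) {
  p <- c(p_av = p_av, p_sv = p_sv, p_vs = p_vs)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p_av, p_sv and p_vs must all lie in [0, 1]")
  }
  structure(list(p_av = unname(p_av), p_sv = unname(p_sv), p_vs = unname(p_vs),
                 p_aa = 1 - unname(p_av), p_ss = 1 - unname(p_sv),
                 p_va = 1 - unname(p_vs)),
            class = "nmj_vm_probs")
}

#' @export
print.nmj_vm_probs <- function(x, digits = 5, ...) {
  cat("vacancy-mediated transition probabilities\n")
  cat(sprintf("  p_AV = %.*g (p_AA = %.*g)\n", digits, x$p_av, digits, x$p_aa))
  cat(sprintf("  p_SV = %.*g (p_SS = %.*g)\n", digits, x$p_sv, digits, x$p_ss))
  cat(sprintf("  p_VS = %.*g (p_VA = %.*g)\n", digits, x$p_vs, digits, x$p_va))
  invisible(x)
}

#' General (six-parameter) transition probabilities
#'
#' The general competition scheme allows every class-to-class transition:
#' each row of the chain over (tSC, vacancy, axon) has two free
#' off-diagonal probabilities and a stay probability fixed by
#' normalisation.
#'
#' @param p_av,p_as Axon row: probability of becoming a vacancy / a tSC.
#' @param p_sa,p_sv tSC row: probability of becoming an axon / a vacancy.
#' @param p_va,p_vs Vacancy row: probability of becoming an axon / a tSC.
#' @return An object of class `nmj_general_probs` carrying all nine row
#'   entries (stay probabilities `p_aa`, `p_ss`, `p_vv` derived).
#' @export
general_probs <- function(p_av, p_as, p_sa, p_sv, p_va, p_vs) {
  p <- c(p_av = p_av, p_as = p_as, p_sa = p_sa,
         p_sv = p_sv, p_va = p_va, p_vs = p_vs)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("all six transition probabilities must lie in [0, 1]")
  }
  stay <- c(p_aa = 1 - p_av - p_as, p_ss = 1 - p_sa - p_sv,
            p_vv = 1 - p_va - p_vs)
  if (any(stay < -1e-12)) {
    stop("row sums exceed 1: each pair of off-diagonal probabilities must sum to <= 1")
  }
  stay <- pmax(stay, 0)
  structure(c(as.list(p), as.list(stay)), class = "nmj_general_probs")
}

#' @export
print.nmj_general_probs <- function(x, digits = 4, ...) {
  cat("general transition probabilities (rows: from S, V, A)\n")
  print(round(transition_matrix(x), digits))
  invisible(x)
}

#' Equal transition probabilities
#'
#' The equal-probability competition scheme: every one of the six
#' class-to-class transition probabilities equals one third, so every row
#' of the chain is (1/3, 1/3, 1/3).
#'
#' @return An `nmj_general_probs` object.
#' @export
equal_probs <- function() {
  general_probs(p_av = 1/3, p_as = 1/3, p_sa = 1/3,
                p_sv = 1/3, p_va = 1/3, p_vs = 1/3)
}

#' Random transition probabilities
#'
#' Draws a fresh set of general transition probabilities in which each row
#' triple (stay plus the two moves) is uniform on the probability simplex,
#' i.e. Dirichlet(1, 1, 1) per row.  This is the per-step randomisation
#' used by the random-probability competition scheme.
#'
#' @return An `nmj_general_probs` object.  Uses (and advances) R's RNG.
#' @export
sample_random_probs <- function() {
  row <- function() {
    e <- -log(stats::runif(3))
    e / ((e[1] + e[2]) + e[3])
  }
  s <- row(); v <- row(); a <- row()
  # row order matches the transition-matrix column order (S, V, A)
  general_probs(p_av = a[2], p_as = a[1], p_sa = s[3],
                p_sv = s[2], p_va = v[3], p_vs = v[1])
}

#' Transition matrix of a probability structure
#'
#' @param probs An `nmj_vm_probs` or `nmj_general_probs` object.
#' @return The 3x3 row-stochastic matrix over states (S, V, A):
#'   rows/columns ordered tSC, vacancy, axon.
#' @export
transition_matrix <- function(probs) {
  if (inherits(probs, "nmj_vm_probs")) {
    m <- rbind(c(probs$p_ss, probs$p_sv, 0),
               c(probs$p_vs, 0,          probs$p_va),
               c(0,          probs$p_av, probs$p_aa))
  } else if (inherits(probs, "nmj_general_probs")) {
    m <- rbind(c(probs$p_ss, probs$p_sv, probs$p_sa),
               c(probs$p_vs, probs$p_vv, probs$p_va),
               c(probs$p_as, probs$p_av, probs$p_aa))
  } else {
    stop("probs must be an nmj_vm_probs or nmj_general_probs object")
  }
  dimnames(m) <- list(from = c("S", "V", "A"), to = c("S", "V", "A"))
  m
}

#' Solve vacancy-mediated probabilities from a stationary composition
#'
#' Given a target stationary ratio vector (the long-run tSC/vacancy/axon
#' coverage) and the one free parameter `p_vs`, the stationarity balance
#' of the vacancy-mediated chain has the unique closed-form solution
#' `p_sv = r_V * p_vs / r_S` and `p_av = r_V * (1 - p_vs) / r_A`.
#'
#' @param ratios Target stationary composition ([area_ratios()]), with
#'   nonzero tSC and axon fractions.
#' @param p_vs Free parameter, the vacancy-to-tSC probability (default
#'   0.6, which keeps all stage-average compositions feasible).
#' @return An [vm_probs()] object whose chain has `ratios` as its
#'   stationary distribution.
#' @examples
#' solve_stationary_probs(stage_ratios("P3"), p_vs = 0.6)
#' @export
solve_stationary_probs <- function(ratios, p_vs = 0.6) {
  r <- as_ratios(ratios)
  if (is.na(p_vs) || p_vs < 0 || p_vs > 1) stop("p_vs must lie in [0, 1]")
  if (r[["tsc"]] <= 0 || r[["axon"]] <= 0) {
    stop("stationary tSC and axon fractions must both be positive")
  }
  p_sv <- r[["vacancy"]] * p_vs / r[["tsc"]]
  p_av <- r[["vacancy"]] * (1 - p_vs) / r[["axon"]]
  bad <- character(0)
  if (p_sv > 1) bad <- c(bad, sprintf("p_SV = %.4g > 1", p_sv))
  if (p_av > 1) bad <- c(bad, sprintf("p_AV = %.4g > 1", p_av))
  if (length(bad)) {
    stop(infeasible_condition(sprintf(
      "no valid transition probabilities stabilise (%.3f, %.3f, %.3f) at p_VS = %.3g: %s",
      r[["tsc"]], r[["vacancy"]], r[["axon"]], p_vs, paste(bad, collapse = "; "))))
  }
  vm_probs(p_av = p_av, p_sv = p_sv, p_vs = p_vs)
}

infeasible_condition <- function(msg) {
  structure(class = c("nmj_infeasible", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Stationary distribution of a competition chain
#'
#' Computes the unique stationary distribution of the 3-state chain over
#' (tSC, vacancy, axon).  The primary route is a direct linear solve of
#' the balance equations; a lazy-chain power iteration (tolerance 1e-12)
#' is run as an independent cross-check and the two must agree.
#'
#' @param probs An `nmj_vm_probs` or `nmj_general_probs` object.
#' @return An [area_ratios()] vector with the stationary fractions.
#' @export
stationary_vector <- function(probs) {
  m <- transition_matrix(probs)
  if (!chain_irreducible(m)) {
    stop("chain is reducible on (S, V, A); the stationary vector is not unique")
  }
  a <- rbind(t(m) - diag(3), rep(1, 3))
  pi_solve <- qr.solve(a, c(0, 0, 0, 1))
  # lazy chain (M + I)/2 shares the stationary vector but is aperiodic,
  # so plain power iteration converges even for periodic chains
  lazy <- (m + diag(3)) / 2
  x <- rep(1/3, 3)
  for (i in seq_len(100000L)) {
    x_new <- as.numeric(x %*% lazy)
    if (max(abs(x_new - x)) < 1e-12) { x <- x_new; break }
    x <- x_new
  }
  if (max(abs(x - pi_solve)) > 1e-8) {
    stop("internal error: power-iteration and linear-solve stationary vectors disagree")
  }
  area_ratios(pi_solve)
}

# reachability check on the positive support of a 3x3 transition matrix
chain_irreducible <- function(m) {
  reach <- (m > 0) | diag(3) > 0
  for (k in 1:2) reach <- reach | (reach %*% reach) > 0
  all(reach)
}
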