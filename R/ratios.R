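#' Endplate area-ratio triplets
#'
#' An `nmj_ratios` object holds the relative endplate coverage of the three
#' occupant classes: terminal Schwann cells (tSCs), vacancies, and axons
#' (all axon identities pooled).  Ratios may be given as fractions summing
#' to 1 or as percentages summing to 100; both are normalised to fractions.
#'
#' @param tsc,vacancy,axon Nonnegative coverage of each class, either all
#'   fractions (sum 1) or all percentages (sum 100).  Alternatively `tsc`
#'   may be a length-3 numeric vector `c(tsc, vacancy, axon)`.
#' @param tol Relative tolerance on the sum before normalisation.
#' @return A named numeric vector of class `nmj_ratios` with components
#'   `tsc`, `vacancy`, `axon` summing to exactly 1.
#' @examples
#' area_ratios(57, 18, 25)          # P3 percentages
#' area_ratios(c(0.31, 0.17, 0.52)) # P0 fractions
#' @export
area_ratios <- function(tsc, vacancy = NULL, axon = NULL, tol = 0.025) {
  if (is.null(vacancy) && is.null(axon) && length(tsc) == 3L) {
    r <- as.numeric(tsc)
  } else {
    r <- c(as.numeric(tsc), as.numeric(vacancy), as.numeric(axon))
  }
  if (length(r) != 3L || anyNA(r)) {
    stop("ratios must be three non-missing numbers (tsc, vacancy, axon)")
  }
  if (any(r < 0)) stop("area ratios must be nonnegative")
  s <- sum(r)
  if (abs(s - 1) <= tol) {
    r <- r / s
  } else if (abs(s - 100) <= 100 * tol) {
    r <- r / s
  } else {
    stop(sprintf("ratios sum to %.4g; expected ~1 (fractions) or ~100 (percent)", s))
  }
  structure(stats::setNames(r, c("tsc", "vacancy", "axon")), class = "nmj_ratios")
}

#' @export
print.nmj_ratios <- function(x, ...) {
  cat(sprintf("endplate area ratios: tSC %.3f, vacancy %.3f, axon %.3f\n",
              x[["tsc"]], x[["vacancy"]], x[["axon"]]))
  invisible(x)
}

is_ratios <- function(x) inherits(x, "nmj_ratios")

as_ratios <- function(x) {
  if (is_ratios(x)) x else area_ratios(x)
}

#' Measured stage-average area ratios
#'
#' Returns the bundled measured average contact-area ratios of tSCs,
#' vacancies and axons at mouse sternomastoid endplates for postnatal
#' days P0, P3, P7 and P16.
#'
#' @param stage One of `"P0"`, `"P3"`, `"P7"`, `"P16"`, or `NULL` to get
#'   the full table.
#' @return For a single stage, an [area_ratios()] object; otherwise a
#'   data frame with columns `stage`, `tsc`, `vacancy`, `axon`,
#'   `n_endplates` (percent units, as measured).
#' @examples
#' stage_ratios("P3")
#' stage_ratios()
#' @export
stage_ratios <- function(stage = NULL) {
  path <- system.file("extdata", "stage_ratios.csv", package = "nmjelim",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(stage)) return(tab)
  stage <- toupper(stage)
  i <- match(stage, tab$stage)
  if (is.na(i)) {
    stop(sprintf("unknown stage '%s'; available: %s", stage,
                 paste(tab$stage, collapse = ", ")))
  }
  area_ratios(tab$tsc[i], tab$vacancy[i], tab$axon[i])
}

#' Composite area of an endplate composition
#'
#' The composite area combines the three relative areas into a single
#' scalar, the product of the tSC and vacancy fractions divided by the
#' axon fraction, `r_S * r_V / r_A`.  Across endplates it is negatively
#' rank-correlated with the number of iterations needed to complete
#' synapse elimination (i.e. positively with the elimination rate).
#'
#' @param ratios An [area_ratios()] object or coercible length-3 vector.
#' @return A single nonnegative number.
#' @examples
#' composite_area(stage_ratios("P3"))  # 0.57 * 0.18 / 0.25
#' @export
composite_area <- function(ratios) {
  r <- as_ratios(ratios)
  if (r[["axon"]] <= 0) {
    stop("composite area is undefined when the axon fraction is zero")
  }
  unname(r[["tsc"]] * r[["vacancy"]] / r[["axon"]])
}
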