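#' Mitral valve morphological parameters
#'
#' Bundle of the six scalar measurements that parameterize one valve: the
#' anterior mitral leaflet depth (AML), the three posterior scallop depths
#' (P1, P2, P3), and the two annular diameters (aorto-mural and
#' intercommissural). All values are in millimetres.
#'
#' @param aml Anterior mitral leaflet depth, annulus to free edge (mm).
#' @param p1,p2,p3 Posterior scallop depths: lateral, middle, medial (mm).
#' @param d_am Aorto-mural annular diameter (mm).
#' @param d_ic Intercommissural annular diameter (mm).
#'
#' @return An object of class `mv_parameters`: a named numeric vector with
#'   elements `aml`, `p1`, `p2`, `p3`, `d_am`, `d_ic`.
#' @examples
#' mv_parameters(aml = 13.63, p1 = 6.85, p2 = 8.25, p3 = 6.08,
#'               d_am = 21.5, d_ic = 17.65)
#' @export
mv_parameters <- function(aml, p1, p2, p3, d_am, d_ic) {
  x <- c(aml = aml, p1 = p1, p2 = p2, p3 = p3, d_am = d_am, d_ic = d_ic)
  validate_mv_parameters(x)
  structure(x, class = "mv_parameters")
}

#' @rdname mv_parameters
#' @param x Object to validate or test.
#' @export
validate_mv_parameters <- function(x) {
  nm <- c("aml", "p1", "p2", "p3", "d_am", "d_ic")
  if (!is.numeric(x) || length(x) != 6L || !all(nm %in% names(x)))
    stop("mv_parameters requires the six named values: ",
         paste(nm, collapse = ", "), call. = FALSE)
  x <- x[nm]
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all six valve parameters must be finite and strictly positive",
         call. = FALSE)
  b <- mv_parameter_bounds()
  for (p in nm) {
    if (x[[p]] < b[p, "lower"] || x[[p]] > b[p, "upper"])
      stop(sprintf("parameter '%s' = %g mm outside admissible range [%g, %g] mm",
                   p, x[[p]], b[p, "lower"], b[p, "upper"]), call. = FALSE)
  }
  invisible(x)
}

#' @rdname mv_parameters
#' @export
is_mv_parameters <- function(x) inherits(x, "mv_parameters")

#' Admissible ranges for the six valve parameters
#'
#' Leaflet/scallop depths are admissible in \[1, 40\] mm and annular diameters
#' in \[5, 60\] mm, a generous envelope around published adult morphometry.
#'
#' @return A data frame with rownames `aml`, `p1`, `p2`, `p3`, `d_am`, `d_ic`
#'   and columns `lower`, `upper` (mm).
#' @export
mv_parameter_bounds <- function() {
  data.frame(
    lower = c(aml = 1, p1 = 1, p2 = 1, p3 = 1, d_am = 5, d_ic = 5),
    upper = c(aml = 40, p1 = 40, p2 = 40, p3 = 40, d_am = 60, d_ic = 60)
  )
}

#' Default template parameters
#'
#' The fixed leaflet values and first diameter levels of the literature
#' morphometry table; used as the template's nominal anatomy.
#'
#' @return An `mv_parameters` object.
#' @export
mv_default_parameters <- function() {
  mv_parameters(aml = 13.63, p1 = 6.85, p2 = 8.25, p3 = 6.08,
                d_am = 21.5, d_ic = 17.65)
}

#' @export
print.mv_parameters <- function(x, ...) {
  cat("Mitral valve parameters (mm):\n")
  print(round(unclass(x), 4))
  invisible(x)
}
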