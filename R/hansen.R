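#' Construct a Hansen solubility parameter vector
#'
#' A point in 3D Hansen space. The three components are the dispersion
#' (\code{dD}), dipolar (\code{dP}) and hydrogen-bonding (\code{dH})
#' cohesive-energy parameters, each in MPa^(1/2).
#'
#' Components must be finite and non-negative. Negative components never occur
#' for real substances; optimizer intermediates are clamped before they reach
#' user code, so a negative input here is almost always a data error. Set
#' \code{allow_negative = TRUE} to downgrade the rejection to a warning (used
#' internally for unclamped iterates).
#'
#' @param dD dispersion parameter, MPa^(1/2)
#' @param dP dipolar parameter, MPa^(1/2)
#' @param dH hydrogen-bonding parameter, MPa^(1/2)
#' @param allow_negative tolerate negative components with a warning
#' @return a named numeric vector of class \code{"hsp"}
#' @examples
#' thf <- hsp(16.80, 5.70, 8.00)
#' hildebrand_total(thf)
#' @export
hsp <- function(dD, dP, dH, allow_negative = FALSE) {
  v <- c(dD = as.numeric(dD)[1], dP = as.numeric(dP)[1], dH = as.numeric(dH)[1])
  if (!all(is.finite(v)))
    stop_invalid("all three Hansen components must be finite")
  if (any(v < 0)) {
    if (allow_negative)
      warning("negative Hansen component(s) tolerated for intermediate value")
    else
      stop_invalid("Hansen components must be non-negative, got (",
                   paste(format(v), collapse = ", "), ")")
  }
  structure(v, class = "hsp")
}

#' Coerce to an HSP vector
#'
#' @param x an \code{hsp} object or a numeric vector of length 3 (dD, dP, dH)
#' @param allow_negative passed to [hsp()]
#' @return an object of class \code{"hsp"}
#' @export
as_hsp <- function(x, allow_negative = FALSE) {
  if (inherits(x, "hsp")) return(x)
  x <- as.numeric(x)
  if (length(x) != 3L)
    stop_invalid("an HSP vector needs exactly 3 components, got ", length(x))
  hsp(x[1], x[2], x[3], allow_negative = allow_negative)
}

#' @export
print.hsp <- function(x, digits = 2, ...) {
  cat(sprintf("<hsp> dD = %.*f, dP = %.*f, dH = %.*f MPa^1/2\n",
              digits, x[["dD"]], digits, x[["dP"]], digits, x[["dH"]]))
  invisible(x)
}

#' Hansen distance between two points in Hansen space
#'
#' \code{R = sqrt(4 (dD1 - dD2)^2 + (dP1 - dP2)^2 + (dH1 - dH2)^2)}. The
#' conventional factor of 4 on the dispersion axis makes the space
#' anisotropic; a smaller R indicates better solvent-solute compatibility.
#'
#' @param a,b HSP vectors (or length-3 numerics)
#' @return distance in MPa^(1/2)
#' @examples
#' hansen_distance(hsp(16.81, 5.78, 7.96), hsp(16.80, 5.70, 8.00))
#' @export
hansen_distance <- function(a, b) {
  a <- as_hsp(a); b <- as_hsp(b)
  d <- unclass(a) - unclass(b)
  sqrt(4 * d[[1]]^2 + d[[2]]^2 + d[[3]]^2)
}

# Vectorized Hansen distances from one point to the rows of an n x 3 matrix.
# No validation: hot path for the optimizer and the grid oracle.
.hansen_dist_rows <- function(x, S) {
  sqrt(4 * (x[1] - S[, 1])^2 + (x[2] - S[, 2])^2 + (x[3] - S[, 3])^2)
}

#' Component-wise Hansen differences
#'
#' Absolute per-axis differences (delta dD, delta dP, delta dH) between two
#' points, the standard decomposition used to attribute an overall Hansen
#' distance to individual interaction types.
#'
#' @inheritParams hansen_distance
#' @return named numeric vector \code{c(ddD, ddP, ddH)}, MPa^(1/2)
#' @export
component_deltas <- function(a, b) {
  a <- as_hsp(a); b <- as_hsp(b)
  d <- abs(unclass(a) - unclass(b))
  c(ddD = d[[1]], ddP = d[[2]], ddH = d[[3]])
}

#' Hildebrand (total) solubility parameter of an HSP vector
#'
#' \code{dT^2 = dD^2 + dP^2 + dH^2}.
#'
#' @param h an HSP vector
#' @return total parameter dT, MPa^(1/2)
#' @export
hildebrand_total <- function(h) {
  h <- as_hsp(h)
  sqrt(sum(unclass(h)^2))
}

#' Absolute difference of two Hildebrand parameters
#'
#' @param dT1,dT2 total solubility parameters, MPa^(1/2), both >= 0
#' @return |dT1 - dT2|, MPa^(1/2)
#' @export
hildebrand_delta <- function(dT1, dT2) {
  if (!is.finite(dT1) || !is.finite(dT2) || dT1 < 0 || dT2 < 0)
    stop_invalid("Hildebrand parameters must be finite and non-negative")
  abs(dT1 - dT2)
}

#' Map Hansen coordinates to an isometric Euclidean space
#'
#' Returns \code{(2 dD, dP, dH)}: the Euclidean distance between mapped
#' points equals the Hansen distance between the originals. Useful for
#' reasoning about the estimator as a plain weighted geometric median.
#'
#' @param h an HSP vector
#' @return plain numeric 3-vector in scaled coordinates
#' @export
to_scaled_space <- function(h) {
  h <- as_hsp(h)
  unname(c(2 * h[[1]], h[[2]], h[[3]]))
}
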