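#' Build a measurement set from solvents and absorbances
#'
#' The measurement set is the estimator's input: one UV/vis maximum
#' absorbance per solvent, all read consistently from the same absorption
#' band, paired with each solvent's known HSPs. Absorbances act directly as
#' the weight vector; they are dimensionless (AU) and must be non-negative,
#' with at least one strictly positive.
#'
#' @param solvent character vector of solvent labels (pairwise distinct)
#' @param absorbance numeric vector of maximum absorbances, AU, >= 0
#' @param hsps numeric matrix (n x 3) or data frame with columns
#'   \code{dD, dP, dH}, one row per solvent
#' @param lambda_max optional numeric vector of band positions, nm
#'   (metadata only; never used in the computation)
#' @return an object of class \code{"measurement_set"}: a data frame with
#'   columns \code{solvent, absorbance, lambda_max, dD, dP, dH}
#' @examples
#' ms <- measurement_set(c("a", "b"), c(1, 0.5),
#'                       rbind(c(16, 2, 4), c(18, 6, 10)))
#' @export
measurement_set <- function(solvent, absorbance, hsps, lambda_max = NULL) {
  solvent <- as.character(solvent)
  n <- length(solvent)
  if (n < 1L) stop_invalid("a measurement set needs at least one solvent")
  if (anyDuplicated(tolower(solvent)))
    stop_invalid("solvents must be pairwise distinct")
  absorbance <- as.numeric(absorbance)
  if (length(absorbance) != n)
    stop_invalid("absorbance length (", length(absorbance),
                 ") does not match solvent count (", n, ")")
  if (any(!is.finite(absorbance)) || any(absorbance < 0))
    stop_invalid("absorbances must be finite and >= 0")
  if (all(absorbance == 0))
    stop_degenerate("all absorbances are zero; the weight vector is degenerate")
  H <- as.matrix(as.data.frame(hsps))
  if (all(c("dD", "dP", "dH") %in% colnames(H)))
    H <- H[, c("dD", "dP", "dH"), drop = FALSE]
  if (nrow(H) != n || ncol(H) != 3L)
    stop_invalid("hsps must be an n x 3 matrix of (dD, dP, dH) rows")
  storage.mode(H) <- "double"
  if (any(!is.finite(H)) || any(H < 0))
    stop_invalid("solvent HSPs must be finite and non-negative")
  if (is.null(lambda_max)) lambda_max <- rep(NA_real_, n)
  df <- data.frame(solvent = solvent, absorbance = absorbance,
                   lambda_max = as.numeric(lambda_max),
                   dD = H[, 1], dP = H[, 2], dH = H[, 3],
                   stringsAsFactors = FALSE)
  structure(df, class = c("measurement_set", "data.frame"))
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("<measurement_set> %d solvent(s)\n", nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read a measurement panel from CSV
#'
#' The file needs columns \code{solvent} and \code{absorbance}; optional
#' columns are \code{lambda_max} and inline \code{dD, dP, dH} overrides.
#' Rows without a full inline HSP triple are resolved against \code{db} by
#' CAS number, name or synonym.
#'
#' @param path CSV path
#' @param db a \code{solvent_db} used to resolve solvents without inline HSPs
#'   (defaults to the bundled database)
#' @return a [measurement_set()]
#' @export
read_measurements <- function(path, db = default_solvent_db()) {
  if (!file.exists(path)) stop_io("measurement file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (col in c("solvent", "absorbance")) {
    if (!col %in% names(df))
      stop_schema("measurement file is missing required column: ", col)
  }
  n <- nrow(df)
  if (!n) stop_invalid("measurement file contains no rows")
  has_inline <- all(c("dD", "dP", "dH") %in% names(df))
  H <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("dD", "dP", "dH")))
  if (has_inline) H[] <- as.matrix(df[, c("dD", "dP", "dH")])
  for (i in seq_len(n)) {
    if (any(is.na(H[i, ]))) {
      rec <- get_solvent(db, df$solvent[i])
      H[i, ] <- unclass(rec$hsp)
    }
  }
  measurement_set(df$solvent, df$absorbance, H,
                  lambda_max = if ("lambda_max" %in% names(df)) df$lambda_max)
}

#' The bundled case-study absorbance panel
#'
#' UV/vis maximum absorbances (benzenoid band) of suspensions of a
#' carboxylic-acid-functionalized polytriphenylamine porous organic polymer
#' in 14 test solvents, together with each solvent's HSPs. This panel drives
#' the worked examples and the package's validation suite.
#'
#' @return a [measurement_set()] of 14 solvents
#' @export
case_study_panel <- function() {
  read_measurements(
    system.file("extdata", "case_study_panel.csv", package = "hsploc",
                mustWork = TRUE))
}
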