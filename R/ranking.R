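#' Rank panel solvents by Hansen distance from a material
#'
#' Produces the standard solvent-ranking table: one row per panel solvent
#' with its absorbance, band position, HSPs, Hansen distance \code{R} from
#' the material and the per-axis differences. Rows are sorted ascending by
#' \code{R}; exact ties are broken alphabetically by solvent name.
#'
#' @param material the material's HSP vector (typically
#'   \code{locate_hsp(ms)$estimate})
#' @param ms a [measurement_set()]
#' @return an object of class \code{"solvent_ranking"}: a data frame with
#'   columns \code{solvent, absorbance, lambda_max, dD, dP, dH, R, ddD, ddP,
#'   ddH} and the material stored in attribute \code{"material"}
#' @examples
#' ms <- case_study_panel()
#' rank_solvents(locate_hsp(ms)$estimate, ms)
#' @export
rank_solvents <- function(material, ms) {
  material <- as_hsp(material)
  if (!nrow(ms)) stop_invalid("empty measurement set")
  m <- unclass(material)
  df <- as.data.frame(ms)
  df$R <- .hansen_dist_rows(m, as.matrix(df[, c("dD", "dP", "dH")]))
  df$ddD <- abs(df$dD - m[[1]])
  df$ddP <- abs(df$dP - m[[2]])
  df$ddH <- abs(df$dH - m[[3]])
  df <- df[order(df$R, tolower(df$solvent), method = "radix"), ]
  rownames(df) <- NULL
  structure(df, class = c("solvent_ranking", "data.frame"), material = material)
}

#' @export
print.solvent_ranking <- function(x, digits = 2, ...) {
  m <- attr(x, "material")
  cat(sprintf("<solvent_ranking> %d solvent(s) vs material (%.2f, %.2f, %.2f) MPa^1/2\n",
              nrow(x), m[["dD"]], m[["dP"]], m[["dH"]]))
  shown <- as.data.frame(x)
  for (col in c("R", "ddD", "ddP", "ddH"))
    shown[[col]] <- round_half_up(shown[[col]], digits)
  print.data.frame(shown, ...)
  invisible(x)
}

#' Hansen distance decomposition table
#'
#' For each solvent of interest, the Hansen distance from the material and
#' its attribution to the three interaction axes (delta dD, delta dP,
#' delta dH). This is the table used to reason about which interaction
#' dominates a solvent's mismatch.
#'
#' @param material the material's HSP vector
#' @param solvents a named list of HSP vectors, or a data frame with columns
#'   \code{solvent, dD, dP, dH} (a [measurement_set()] works)
#' @return data frame with columns \code{solvent, R, ddD, ddP, ddH}
#' @export
decomposition_table <- function(material, solvents) {
  material <- as_hsp(material)
  if (is.data.frame(solvents)) {
    nm <- solvents$solvent
    H <- as.matrix(solvents[, c("dD", "dP", "dH")])
  } else {
    nm <- names(solvents)
    if (is.null(nm)) stop_invalid("solvents list must be named")
    H <- do.call(rbind, lapply(solvents, function(h) unclass(as_hsp(h))))
  }
  if (!length(nm)) stop_invalid("no solvents supplied")
  m <- unclass(material)
  data.frame(solvent = nm,
             R = .hansen_dist_rows(m, H),
             ddD = abs(H[, 1] - m[[1]]),
             ddP = abs(H[, 2] - m[[2]]),
             ddH = abs(H[, 3] - m[[3]]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Scatter records for a 3D Hansen-space plot
#'
#' One record per panel solvent plus one record for the material itself
#' (\code{role = "material"}, \code{R = 0}), carrying everything a plotting
#' layer needs: coordinates, label, role and distance. Rendering is left to
#' the caller (or [plot_hansen_space()]).
#'
#' @param material the material's HSP vector
#' @param ranking a [rank_solvents()] result
#' @return data frame with columns \code{dD, dP, dH, label, role, R}
#' @export
plot_data <- function(material, ranking) {
  material <- as_hsp(material)
  df <- as.data.frame(ranking)
  rbind(
    data.frame(dD = material[["dD"]], dP = material[["dP"]],
               dH = material[["dH"]], label = "material", role = "material",
               R = 0, stringsAsFactors = FALSE),
    data.frame(dD = df$dD, dP = df$dP, dH = df$dH, label = df$solvent,
               role = "solvent", R = df$R, stringsAsFactors = FALSE))
}

#' Pairwise-projection plot of a Hansen-space panel
#'
#' Draws the three 2D projections (dD-dP, dD-dH, dP-dH) of the panel
#' solvents and the located material (star). A deliberately thin layer over
#' [plot_data()]; publication figures are expected to be styled elsewhere.
#'
#' @param pd a [plot_data()] data frame
#' @param ... passed to [graphics::plot()]
#' @return \code{pd}, invisibly
#' @export
plot_hansen_space <- function(pd, ...) {
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  pairs <- list(c("dD", "dP"), c("dD", "dH"), c("dP", "dH"))
  for (ax in pairs) {
    sol <- pd[pd$role == "solvent", ]
    mat <- pd[pd$role == "material", ]
    graphics::plot(sol[[ax[1]]], sol[[ax[2]]],
                   xlab = paste0(ax[1], " / MPa^1/2"),
                   ylab = paste0(ax[2], " / MPa^1/2"), pch = 19, ...)
    graphics::points(mat[[ax[1]]], mat[[ax[2]]], pch = 8, cex = 2, col = 2)
  }
  invisible(pd)
}

#' Export a run report to CSV files
#'
#' Writes three diff-friendly CSV artifacts into \code{dir}:
#' \describe{
#'   \item{report_summary.csv}{estimate, init, iterations, convergence flag,
#'     objective, the rounding-derived global error and a config echo}
#'   \item{report_ranking.csv}{the ranking table, numeric fields at full
#'     precision so re-loading reproduces the in-memory values exactly}
#'   \item{plot_data.csv}{the [plot_data()] records}
#' }
#'
#' @param result a [locate_hsp()] result
#' @param ranking a [rank_solvents()] result
#' @param dir output directory (created if absent)
#' @param decimals display rounding used in the summary, default 2
#' @return named character vector of the written paths, invisibly
#' @export
export_report <- function(result, ranking, dir, decimals = 2) {
  if (!dir.exists(dir)) {
    ok <- tryCatch(dir.create(dir, recursive = TRUE), warning = function(w) FALSE)
    if (!isTRUE(ok) && !dir.exists(dir)) stop_io("cannot create directory: ", dir)
  }
  paths <- c(summary = file.path(dir, "report_summary.csv"),
             ranking = file.path(dir, "report_ranking.csv"),
             plot = file.path(dir, "plot_data.csv"))
  est <- result$estimate; ini <- result$init
  summ <- data.frame(
    field = c("dD", "dP", "dH", "global_error",
              "init_dD", "init_dP", "init_dH",
              "iterations", "converged", "objective",
              "alpha", "tol", "max_iter", "init_mode"),
    value = c(round_half_up(est[["dD"]], decimals),
              round_half_up(est[["dP"]], decimals),
              round_half_up(est[["dH"]], decimals),
              result$global_error,
              round_half_up(ini[["dD"]], decimals),
              round_half_up(ini[["dP"]], decimals),
              round_half_up(ini[["dH"]], decimals),
              result$iterations, result$converged,
              format(result$objective_value),
              result$config$alpha, result$config$tol, result$config$max_iter,
              result$config$init_mode),
    stringsAsFactors = FALSE)
  write_csv_precise <- function(df, path) {
    out <- df
    for (col in names(out))
      if (is.numeric(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
    tryCatch(utils::write.csv(out, path, row.names = FALSE,
                              fileEncoding = "UTF-8"),
             error = function(e) stop_io("cannot write ", path, ": ",
                                         conditionMessage(e)))
  }
  tryCatch(utils::write.csv(summ, paths[["summary"]], row.names = FALSE,
                            fileEncoding = "UTF-8"),
           error = function(e) stop_io("cannot write ", paths[["summary"]],
                                       ": ", conditionMessage(e)))
  write_csv_precise(as.data.frame(ranking), paths[["ranking"]])
  write_csv_precise(plot_data(attr(ranking, "material"), ranking),
                    paths[["plot"]])
  invisible(paths)
}

#' Serialize a locate result to JSON
#'
#' @param result a [locate_hsp()] result
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_locate_result <- function(result, path) {
  doc <- list(
    estimate = as.list(unclass(result$estimate)),
    init = as.list(unclass(result$init)),
    iterations = result$iterations,
    converged = result$converged,
    objective = result$objective_value,
    global_error = result$global_error,
    config = list(alpha = result$config$alpha, tol = result$config$tol,
                  max_iter = result$config$max_iter,
                  eps_guard = result$config$eps_guard,
                  init_mode = result$config$init_mode))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
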