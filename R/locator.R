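#' Optimizer settings for the HSP locator
#'
#' @param alpha learning rate of the fixed-step gradient descent
#'   (dimensionless), default 0.01
#' @param tol convergence threshold on the Euclidean norm of the update
#'   vector, MPa^(1/2), default 0.005
#' @param max_iter iteration cap, default 10000
#' @param eps_guard distance floor below which a solvent's gradient term is
#'   dropped (a valid subgradient at the kink), MPa^(1/2), default 1e-9
#' @param init \code{"analytic"} (squared-cost closed form, the default),
#'   \code{"random"} (uniform draw in \code{bounds}, seeded by \code{seed}),
#'   or an explicit HSP vector / length-3 numeric
#' @param bounds 3 x 2 matrix of (min, max) rows for dD, dP, dH used by
#'   random initialization; default [default_hansen_bounds()]
#' @param seed integer seed for random initialization
#' @return an object of class \code{"locator_config"}
#' @export
locator_config <- function(alpha = 0.01, tol = 0.005, max_iter = 10000L,
                           eps_guard = 1e-9, init = "analytic",
                           bounds = default_hansen_bounds(), seed = NULL) {
  if (!is.finite(alpha) || alpha <= 0) stop_invalid("alpha must be > 0")
  if (!is.finite(tol) || tol <= 0) stop_invalid("tol must be > 0")
  if (!is.finite(max_iter) || max_iter < 1) stop_invalid("max_iter must be >= 1")
  if (!is.finite(eps_guard) || eps_guard <= 0) stop_invalid("eps_guard must be > 0")
  if (is.character(init)) {
    init_mode <- match.arg(init, c("analytic", "random"))
    init_value <- NULL
  } else {
    init_mode <- "explicit"
    init_value <- as_hsp(init)
  }
  bounds <- check_bounds(bounds)
  structure(list(alpha = alpha, tol = tol, max_iter = as.integer(max_iter),
                 eps_guard = eps_guard, init_mode = init_mode,
                 init_value = init_value, bounds = bounds, seed = seed),
            class = "locator_config")
}

#' Default search box in Hansen space
#'
#' Spans the practical solvent region covered by common test-solvent panels:
#' dD in [14, 20], dP in [0, 19], dH in [0, 43] MPa^(1/2).
#'
#' @return 3 x 2 numeric matrix with rows dD, dP, dH and columns min, max
#' @export
default_hansen_bounds <- function() {
  matrix(c(14, 20, 0, 19, 0, 43), nrow = 3, byrow = TRUE,
         dimnames = list(c("dD", "dP", "dH"), c("min", "max")))
}

check_bounds <- function(bounds) {
  bounds <- matrix(as.numeric(bounds), nrow = 3,
                   dimnames = list(c("dD", "dP", "dH"), c("min", "max")))
  if (any(!is.finite(bounds)) || any(bounds[, 2] < bounds[, 1]))
    stop_invalid("bounds must be finite with max >= min on every axis")
  bounds
}

#' Extract the raw weight vector from a measurement set
#'
#' Weights are the raw absorbances in input order. No normalization is
#' applied: the location of the weighted-distance minimum is invariant to
#' uniform positive scaling of the weights, so the raw values are canonical.
#'
#' @param ms a [measurement_set()]
#' @return numeric weight vector, AU
#' @export
build_weights <- function(ms) {
  w <- ms$absorbance
  if (any(!is.finite(w)) || any(w < 0))
    stop_invalid("absorbances must be finite and >= 0")
  if (all(w == 0))
    stop_degenerate("all-zero absorbances give a degenerate weight vector")
  w
}

#' Analytic initial guess for the locator
#'
#' Closed-form minimizer of the squared-distance cost
#' \code{sum(w_i^2 R_i^2)}: the component-wise squared-weight average
#' \code{sum(w_i^2 d_i) / sum(w_i^2)} of the solvent HSPs. Squaring the cost
#' removes the distance from the denominator of the gradient, which makes
#' the minimizer expressible in solvent coordinates alone; squaring the
#' weights preserves their ordering. The result always lies inside the
#' component-wise min/max box of the panel solvents.
#'
#' @param weights numeric weight vector (raw absorbances)
#' @param solvent_hsps n x 3 matrix of solvent HSP rows
#' @return an [hsp()] vector
#' @export
analytic_init <- function(weights, solvent_hsps) {
  S <- as.matrix(solvent_hsps); storage.mode(S) <- "double"
  if (length(weights) != nrow(S))
    stop_invalid("weights and solvent_hsps disagree in length")
  if (all(weights == 0)) stop_degenerate("all-zero weights")
  w2 <- weights^2
  v <- colSums(w2 * S) / sum(w2)
  hsp(v[1], v[2], v[3])
}

#' Total weighted Hansen distance objective
#'
#' \code{sum_i w_i R_i(point)}, the convex objective whose minimizer is the
#' absorbance-weighted geometric median of the panel in (scaled) Hansen
#' space.
#'
#' @param point candidate material location (HSP vector or length-3 numeric)
#' @param weights numeric weight vector
#' @param solvent_hsps n x 3 matrix of solvent HSP rows
#' @return objective value, MPa^(1/2) (weighted, unnormalized)
#' @export
hsp_objective <- function(point, weights, solvent_hsps) {
  x <- as.numeric(point)
  S <- as.matrix(solvent_hsps)
  if (length(weights) != nrow(S))
    stop_invalid("weights and solvent_hsps disagree in length")
  sum(weights * .hansen_dist_rows(x, S))
}

#' Gradient of the weighted-distance objective
#'
#' Returns \code{sum_i w_i (4 (dD - dD_i), (dP - dP_i), (dH - dH_i)) / R_i}.
#' Terms with \code{R_i < eps_guard} contribute the zero vector: a valid
#' subgradient choice at the kink that also makes a solvent carrying the
#' majority of the weight an exact fixed point of the descent.
#'
#' @inheritParams hsp_objective
#' @param eps_guard distance floor, MPa^(1/2)
#' @return numeric 3-vector
#' @export
hsp_gradient <- function(point, weights, solvent_hsps, eps_guard = 1e-9) {
  x <- as.numeric(point)
  if (any(!is.finite(x))) stop_invalid("non-finite iterate")
  S <- as.matrix(solvent_hsps)
  if (length(weights) != nrow(S))
    stop_invalid("weights and solvent_hsps disagree in length")
  R <- .hansen_dist_rows(x, S)
  keep <- R >= eps_guard
  if (!any(keep)) return(c(0, 0, 0))
  D <- cbind(4 * (x[1] - S[, 1]), x[2] - S[, 2], x[3] - S[, 3]) / R
  colSums(weights[keep] * D[keep, , drop = FALSE])
}

#' Locate a material in Hansen space from an absorbance panel
#'
#' The estimator: minimizes the total absorbance-weighted Hansen distance
#' between a candidate material location and the panel solvents by
#' fixed-step gradient descent. Each step applies
#' \code{x <- x - alpha * gradient(x)}, clamps all components to the
#' non-negative orthant (keeping candidates physically meaningful), and
#' stops when the Euclidean norm of the update drops below \code{tol}
#' (converged) or after \code{max_iter} steps (not converged; the last
#' iterate is still returned).
#'
#' Measurements are re-ordered internally into a canonical (byte-wise
#' solvent-name) order before any floating-point reduction, so the result is
#' bit-for-bit independent of input row order.
#'
#' Note that with the default step size the stopping rule triggers once the
#' gradient norm falls below \code{tol/alpha}; the reported estimate is the
#' threshold-crossing iterate, which for flat or kinked objectives can sit a
#' perceptible distance from the exact minimizer. See the package vignette.
#'
#' @param ms a [measurement_set()]
#' @param config a [locator_config()]
#' @param trajectory record the full iterate path (matrix of
#'   \code{dD, dP, dH, step_norm} rows)?
#' @param log_every if > 0, emit a \code{message()} with the objective every
#'   this many iterations
#' @return an object of class \code{"locate_result"} with fields
#'   \code{estimate}, \code{init}, \code{iterations}, \code{converged},
#'   \code{objective_value}, \code{global_error}, \code{trajectory},
#'   \code{config}
#' @examples
#' res <- locate_hsp(case_study_panel())
#' res$estimate
#' @export
locate_hsp <- function(ms, config = locator_config(), trajectory = FALSE,
                       log_every = 0L) {
  if (!inherits(config, "locator_config"))
    stop_invalid("config must be a locator_config()")
  ord <- order(ms$solvent, method = "radix")
  w <- build_weights(ms)[ord]
  S <- as.matrix(ms[ord, c("dD", "dP", "dH")])
  x0 <- switch(config$init_mode,
    analytic = unclass(analytic_init(w, S)),
    explicit = unclass(config$init_value),
    random = {
      if (!is.null(config$seed)) set.seed(config$seed)
      b <- config$bounds
      stats::runif(3, b[, 1], b[, 2])
    })
  x <- as.numeric(x0)
  alpha <- config$alpha; tol <- config$tol
  traj <- if (trajectory) matrix(NA_real_, config$max_iter, 4,
                                 dimnames = list(NULL, c("dD", "dP", "dH",
                                                         "step_norm")))
  converged <- FALSE
  it <- 0L
  s1 <- S[, 1]; s2 <- S[, 2]; s3 <- S[, 3]
  eps <- config$eps_guard
  while (it < config$max_iter) {
    it <- it + 1L
    # inline gradient (same arithmetic as hsp_gradient, kept loop-hot)
    R <- sqrt(4 * (x[1] - s1)^2 + (x[2] - s2)^2 + (x[3] - s3)^2)
    cf <- ifelse(R >= eps, w / R, 0)
    g <- c(4 * sum(cf * (x[1] - s1)), sum(cf * (x[2] - s2)),
           sum(cf * (x[3] - s3)))
    step <- -alpha * g
    x <- pmax(x + step, 0)
    sn <- sqrt(sum(step^2))
    if (trajectory) traj[it, ] <- c(x, sn)
    if (log_every > 0L && it %% log_every == 0L)
      message(sprintf("iter %6d  objective %.6f  |step| %.3g", it,
                      hsp_objective(x, w, S), sn))
    if (sn < tol) { converged <- TRUE; break }
  }
  est <- hsp(x[1], x[2], x[3])
  structure(list(
    estimate = est,
    init = hsp(x0[1], x0[2], x0[3]),
    iterations = it,
    converged = converged,
    objective_value = hsp_objective(x, w, S),
    global_error = round_half_up(config$tol, 2),
    trajectory = if (trajectory) traj[seq_len(it), , drop = FALSE],
    config = config
  ), class = "locate_result")
}

#' @export
print.locate_result <- function(x, digits = 2, ...) {
  e <- x$estimate
  cat(sprintf("<locate_result> dD = %.*f, dP = %.*f, dH = %.*f MPa^1/2 (+/- %.2f)\n",
              digits, e[["dD"]], digits, e[["dP"]], digits, e[["dH"]],
              x$global_error))
  cat(sprintf("  %s after %d iteration(s); objective %.4f\n",
              if (x$converged) "converged" else "NOT converged", x$iterations,
              x$objective_value))
  invisible(x)
}

#' Brute-force grid minimizer of the weighted-distance objective
#'
#' Independent oracle for testing the gradient-descent locator: evaluates
#' the objective on a regular grid over a bounding box and returns the best
#' grid point. Ties are broken by lexicographic order of (dD, dP, dH).
#' Evaluation is chunked by dD slice so memory stays proportional to one
#' slice.
#'
#' @inheritParams hsp_objective
#' @param bounds 3 x 2 matrix of (min, max) rows for dD, dP, dH
#' @param step grid spacing, MPa^(1/2)
#' @param cell_cap refuse grids larger than this many points
#' @return the minimizing grid point as an [hsp()] vector, with the attained
#'   objective attached as attribute \code{"objective"}
#' @export
grid_oracle <- function(weights, solvent_hsps, bounds, step, cell_cap = 5e6) {
  bounds <- check_bounds(bounds)
  if (!is.finite(step) || step <= 0) stop_invalid("step must be > 0")
  S <- as.matrix(solvent_hsps); storage.mode(S) <- "double"
  if (length(weights) != nrow(S))
    stop_invalid("weights and solvent_hsps disagree in length")
  gd <- seq(bounds[1, 1], bounds[1, 2], by = step)
  gp <- seq(bounds[2, 1], bounds[2, 2], by = step)
  gh <- seq(bounds[3, 1], bounds[3, 2], by = step)
  ncells <- as.numeric(length(gd)) * length(gp) * length(gh)
  if (ncells > cell_cap)
    stop_resource("grid has ", format(ncells, big.mark = ","),
                  " cells, exceeding the cap of ", format(cell_cap, big.mark = ","))
  # within a slice, rows are ordered (dP asc, dH asc); which.min takes the
  # first minimum, and strict < across ascending dD slices keeps the earliest
  # -> overall lexicographic (dD, dP, dH) tie-break
  slice <- cbind(dP = rep(gp, each = length(gh)),
                 dH = rep(gh, times = length(gp)))
  best_val <- Inf
  best_pt <- c(NA_real_, NA_real_, NA_real_)
  for (d in gd) {
    obj <- numeric(nrow(slice))
    for (i in seq_len(nrow(S))) {
      obj <- obj + weights[i] * sqrt(4 * (d - S[i, 1])^2 +
                                       (slice[, 1] - S[i, 2])^2 +
                                       (slice[, 2] - S[i, 3])^2)
    }
    k <- which.min(obj)
    if (obj[k] < best_val) {
      best_val <- obj[k]
      best_pt <- c(d, slice[k, 1], slice[k, 2])
    }
  }
  out <- hsp(best_pt[1], best_pt[2], best_pt[3])
  attr(out, "objective") <- best_val
  out
}

#' Validate the locator by multistart optimization
#'
#' Runs [locate_hsp()] from \code{n_starts} uniform random initial points in
#' a bounding box (seeded, reproducible) and reports per-start outcomes plus
#' the dispersion of the converged estimates. Because the objective is
#' convex the exact minimizer is unique; the spread of the returned
#' estimates therefore measures the width of the stopping-rule shell, not
#' multimodality.
#'
#' @param ms a [measurement_set()]
#' @param config a [locator_config()] (its init settings are overridden per
#'   start)
#' @param n_starts number of random starts
#' @param bounds 3 x 2 sampling box
#' @param seed integer seed
#' @return an object of class \code{"multistart_report"}: a list with
#'   \code{starts} (a data frame of per-start init, estimate, iterations and
#'   convergence flag), \code{max_pairwise} (maximum pairwise Hansen
#'   distance among converged estimates), \code{agree}
#'   (\code{max_pairwise <= 2 tol}), \code{n_converged}, \code{tol},
#'   \code{seed}
#' @export
multistart_validate <- function(ms, config = locator_config(), n_starts = 100L,
                                bounds = default_hansen_bounds(), seed = 1L) {
  if (n_starts < 1L) stop_invalid("n_starts must be >= 1")
  bounds <- check_bounds(bounds)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  set.seed(seed)
  inits <- cbind(stats::runif(n_starts, bounds[1, 1], bounds[1, 2]),
                 stats::runif(n_starts, bounds[2, 1], bounds[2, 2]),
                 stats::runif(n_starts, bounds[3, 1], bounds[3, 2]))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  rows <- vector("list", n_starts)
  for (k in seq_len(n_starts)) {
    cfg <- config
    cfg$init_mode <- "explicit"
    cfg$init_value <- hsp(inits[k, 1], inits[k, 2], inits[k, 3])
    res <- locate_hsp(ms, cfg)
    rows[[k]] <- data.frame(
      start = k,
      init_dD = inits[k, 1], init_dP = inits[k, 2], init_dH = inits[k, 3],
      dD = res$estimate[["dD"]], dP = res$estimate[["dP"]],
      dH = res$estimate[["dH"]],
      iterations = res$iterations, converged = res$converged)
  }
  starts <- do.call(rbind, rows)
  conv <- starts[starts$converged, c("dD", "dP", "dH"), drop = FALSE]
  max_pairwise <- 0
  if (nrow(conv) >= 2L) {
    E <- as.matrix(conv); E[, 1] <- 2 * E[, 1]  # scaled space
    max_pairwise <- max(stats::dist(E))
  }
  structure(list(starts = starts,
                 n_converged = nrow(conv),
                 max_pairwise = max_pairwise,
                 agree = max_pairwise <= 2 * config$tol,
                 tol = config$tol,
                 seed = seed),
            class = "multistart_report")
}

#' @export
print.multistart_report <- function(x, ...) {
  cat(sprintf("<multistart_report> %d/%d start(s) converged; max pairwise distance %.4f MPa^1/2 (2*tol = %.4f); %s\n",
              x$n_converged, nrow(x$starts), x$max_pairwise, 2 * x$tol,
              if (x$agree) "estimates agree" else "estimates do NOT agree within 2*tol"))
  invisible(x)
}
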