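#' Absorbance response model for synthetic panels
#'
#' The generator's working hypothesis, mirroring what the estimator assumes
#' of real suspensions: absorbance decays monotonically with the Hansen
#' distance between solvent and material,
#' \code{abs_i = max(floor, amplitude * exp(-R_i / tau) + noise_i)} with
#' Gaussian noise truncated from below by the floor (absorbance cannot be
#' negative).
#'
#' Defaults emulate a typical benzenoid-band panel: peak absorbance 0.8 AU
#' for a perfectly matched solvent (printed panels top out near 0.7),
#' decay scale 5 MPa^(1/2) (absorbance drops to ~1/e across the spread of a
#' well-chosen panel), measurement noise 0.02 AU (routine UV/vis
#' repeatability) and a 0.01 AU baseline floor.
#'
#' @param amplitude absorbance of a solvent exactly at the material, AU
#' @param tau decay scale of absorbance with Hansen distance, MPa^(1/2)
#' @param noise_sd measurement noise standard deviation, AU
#' @param floor baseline absorbance, AU (must be < amplitude)
#' @return an object of class \code{"absorbance_model"}
#' @export
absorbance_model <- function(amplitude = 0.8, tau = 5, noise_sd = 0.02,
                             floor = 0.01) {
  if (!all(is.finite(c(amplitude, tau, noise_sd, floor))))
    stop_invalid("model parameters must be finite")
  if (amplitude <= 0 || tau <= 0 || noise_sd < 0 || floor < 0)
    stop_invalid("need amplitude > 0, tau > 0, noise_sd >= 0, floor >= 0")
  if (amplitude <= floor)
    stop_invalid("amplitude must exceed the baseline floor")
  structure(list(amplitude = amplitude, tau = tau, noise_sd = noise_sd,
                 floor = floor), class = "absorbance_model")
}

#' Draw a synthetic material location in Hansen space
#'
#' Uniform draw inside a bounding box; reproducible for a fixed seed.
#'
#' @param seed integer seed
#' @param bounds 3 x 2 (min, max) box, default [default_hansen_bounds()]
#' @return an [hsp()] vector
#' @export
make_material <- function(seed, bounds = default_hansen_bounds()) {
  bounds <- check_bounds(bounds)
  set.seed(seed)
  v <- stats::runif(3, bounds[, 1], bounds[, 2])
  hsp(v[1], v[2], v[3])
}

#' Simulate an absorbance panel for a known material
#'
#' Applies an [absorbance_model()] to the Hansen distances between a ground
#' truth material and a solvent list, producing a [measurement_set()] the
#' locator can consume.
#'
#' @param truth the material's true HSP vector
#' @param solvents data frame with columns \code{solvent, dD, dP, dH} (a
#'   [measurement_set()] or \code{solvent_db$records} slice works)
#' @param model an [absorbance_model()]
#' @param seed integer seed for the noise draws (ignored when
#'   \code{noise_sd = 0})
#' @return a [measurement_set()]
#' @export
simulate_absorbance <- function(truth, solvents, model = absorbance_model(),
                                seed = 1L) {
  if (!inherits(model, "absorbance_model"))
    stop_invalid("model must be an absorbance_model()")
  truth <- as_hsp(truth)
  df <- as.data.frame(solvents)
  if (!all(c("dD", "dP", "dH") %in% names(df)) || !nrow(df))
    stop_invalid("solvents must be a non-empty data frame with dD, dP, dH")
  nm <- if ("solvent" %in% names(df)) df$solvent else
    if ("name" %in% names(df)) df$name else paste0("solvent_", seq_len(nrow(df)))
  H <- as.matrix(df[, c("dD", "dP", "dH")])
  R <- .hansen_dist_rows(unclass(truth), H)
  set.seed(seed)
  noise <- if (model$noise_sd > 0) stats::rnorm(nrow(H), 0, model$noise_sd)
  else numeric(nrow(H))
  ab <- pmax(model$floor, model$amplitude * exp(-R / model$tau) + noise)
  measurement_set(nm, ab, H)
}

#' Parameter-recovery experiment on synthetic panels
#'
#' For each trial: draw a ground-truth material, sample a solvent panel from
#' the database, optionally anchor the panel with one solvent placed exactly
#' at the truth, simulate absorbances through \code{model}, run
#' [locate_hsp()], and record the signed per-component estimation error.
#' The summary is deterministic for a fixed seed.
#'
#' With no solvent near the truth the estimate is pulled into the convex
#' hull of the panel in scaled Hansen space: the experiment quantifies that
#' inherent bias rather than hiding it.
#'
#' @param n_trials number of trials
#' @param panel_size solvents per panel (drawn without replacement)
#' @param model an [absorbance_model()]
#' @param config a [locator_config()]
#' @param seed integer master seed
#' @param db solvent database to sample panels from
#' @param anchor_at_truth include one synthetic solvent exactly at the
#'   truth (default TRUE)
#' @param truth_bounds box the truth is drawn from, default
#'   [default_hansen_bounds()]
#' @return an object of class \code{"recovery_summary"}: list with
#'   \code{errors} (n_trials x 3 signed errors), \code{bias}, \code{rmse},
#'   \code{max_abs} (per-component), \code{n_trials}, \code{seed}
#' @export
recovery_experiment <- function(n_trials, panel_size = 8L,
                                model = absorbance_model(),
                                config = locator_config(), seed = 1L,
                                db = default_solvent_db(),
                                anchor_at_truth = TRUE,
                                truth_bounds = default_hansen_bounds()) {
  if (n_trials < 1L) stop_invalid("n_trials must be >= 1")
  panel_size <- min(panel_size, nrow(db$records))
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max, 2L * n_trials)
  errors <- matrix(NA_real_, n_trials, 3,
                   dimnames = list(NULL, c("dD", "dP", "dH")))
  for (t in seq_len(n_trials)) {
    truth <- make_material(trial_seeds[2L * t - 1L], truth_bounds)
    set.seed(trial_seeds[2L * t])
    idx <- sample.int(nrow(db$records), panel_size)
    pool <- db$records[idx, c("name", "dD", "dP", "dH")]
    names(pool)[1] <- "solvent"
    if (anchor_at_truth) {
      pool <- rbind(pool, data.frame(solvent = "anchor",
                                     dD = truth[["dD"]], dP = truth[["dP"]],
                                     dH = truth[["dH"]]))
    }
    ms <- simulate_absorbance(truth, pool, model, seed = trial_seeds[2L * t])
    est <- locate_hsp(ms, config)$estimate
    errors[t, ] <- unclass(est) - unclass(truth)
  }
  structure(list(errors = errors,
                 bias = colMeans(errors),
                 rmse = sqrt(colMeans(errors^2)),
                 max_abs = apply(abs(errors), 2, max),
                 n_trials = n_trials, seed = seed),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("<recovery_summary> %d trial(s)\n", x$n_trials))
  print(round(rbind(bias = x$bias, rmse = x$rmse, max_abs = x$max_abs), 4))
  invisible(x)
}
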