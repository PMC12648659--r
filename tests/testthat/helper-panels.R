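# Shared fixtures, all built in code.

# Case-study panel printed values: absorbance, solvent HSPs, the published
# material estimate, and the published distance column (in printed order).
printed_material <- c(dD = 16.81, dP = 5.78, dH = 7.96)
printed_R <- c(0.09, 2.21, 4.03, 5.39, 5.95, 6.06, 6.15, 7.00, 7.78, 8.68,
               10.56, 12.00, 12.72, 35.92)
printed_order <- c("tetrahydrofuran (THF)", "ethyl acetate", "chloroform",
                   "acetone", "1,4-dioxane", "diethyl ether",
                   "1,2-dichloroethane", "xylene", "toluene", "isopropanol",
                   "hexane", "ethanol", "acetonitrile", "water")

# Eq-style closed-form init of the case panel, frozen from independent
# spreadsheet arithmetic on the printed Abs and HSP columns.
frozen_analytic_init <- c(16.9862105125, 6.9213986106, 9.2600668502)

# A compact random panel whose solvents sit in a tight box, so a 0.05-step
# grid oracle over the box stays small.
random_panel <- function(seed, n = 5, box = rbind(c(15, 18), c(2, 8), c(2, 8))) {
  set.seed(seed)
  H <- cbind(runif(n, box[1, 1], box[1, 2]),
             runif(n, box[2, 1], box[2, 2]),
             runif(n, box[3, 1], box[3, 2]))
  measurement_set(sprintf("s%02d", seq_len(n)), runif(n, 0.05, 1), H)
}

panel_bounds <- function(ms, pad = 0.1) {
  H <- as.matrix(ms[, c("dD", "dP", "dH")])
  cbind(pmax(apply(H, 2, min) - pad, 0), apply(H, 2, max) + pad)
}

# half-up rounding at two decimals, the tables' display convention
round_2dp <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100

random_hsp <- function(bounds = default_hansen_bounds()) {
  hsp(runif(1, bounds[1, 1], bounds[1, 2]),
      runif(1, bounds[2, 1], bounds[2, 2]),
      runif(1, bounds[3, 1], bounds[3, 2]))
}

# High-accuracy optimizer settings used when a test needs the iterate to sit
# close to the exact minimizer (small step so the stopping shell and the
# near-vertex chatter both shrink well below a grid cell).
accurate_config <- function(max_iter = 200000L)
  locator_config(alpha = 1e-3, tol = 1e-6, max_iter = max_iter)

# write a temporary solvent db CSV from a data frame
write_db_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  path
}

db_frame <- function(...) {
  data.frame(..., stringsAsFactors = FALSE)
}
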