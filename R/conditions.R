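# Structured error conditions. Every user-facing failure carries a class so
# callers (and the CLI exit-code mapping) can react without string matching.

.hsploc_stop <- function(class, ...) {
  stop(structure(
    class = c(class, "hsploc_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_invalid    <- function(...) .hsploc_stop("hsploc_invalid", ...)
stop_not_found  <- function(...) .hsploc_stop("hsploc_not_found", ...)
stop_ambiguous  <- function(...) .hsploc_stop("hsploc_ambiguous", ...)
stop_schema     <- function(...) .hsploc_stop("hsploc_schema", ...)
stop_validation <- function(...) .hsploc_stop("hsploc_validation", ...)
stop_degenerate <- function(...) .hsploc_stop("hsploc_degenerate", ...)
stop_resource   <- function(...) .hsploc_stop("hsploc_resource", ...)
stop_io         <- function(...) .hsploc_stop("hsploc_io", ...)

# Round half away from zero at d decimals (base round() is half-to-even;
# tables and the reported global error follow the half-up convention).
round_half_up <- function(x, d = 2) {
  sign(x) * floor(abs(x) * 10^d + 0.5) / 10^d
}
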