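#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a classed ddigip error
#'
#' All package errors carry class `ddigip_error` plus a specific subclass
#' (e.g. `ddigip_error_degenerate_network`) so callers can match on them.
#' @noRd
ddigip_abort <- function(msg, class) {
  stop(errorCondition(msg,
    class = c(paste0("ddigip_error_", class), "ddigip_error")))
}

ddigip_warn <- function(msg, class) {
  warning(warningCondition(msg,
    class = c(paste0("ddigip_warning_", class), "ddigip_warning")))
}

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    ddigip_abort(sprintf("`%s` must be a single finite number", name),
                 "invalid_parameter")
  }
  if (positive && x <= 0) {
    ddigip_abort(sprintf("`%s` must be > 0 (got %g)", name, x),
                 "invalid_parameter")
  }
  invisible(x)
}
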