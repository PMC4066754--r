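# Internal helpers: classed conditions and seed-scoped RNG.

px_error <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "primext_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

# domain error: a parameter is outside its mathematical domain
px_domain <- function(message) px_error(message, "primext_domain_error")
# input error: malformed data object / file
px_input <- function(message) px_error(message, "primext_input_error")
# configuration error: unknown mode / switch value
px_config <- function(message) px_error(message, "primext_config_error")
# fit failure: optimiser did not converge
px_fit_failure <- function(message) px_error(message, "primext_fit_error")

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    px_domain(sprintf("`%s` must be a positive finite number (got %s)",
                      name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    px_domain(sprintf("`%s` must be a nonnegative finite number (got %s)",
                      name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so generators are deterministic without side effects.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Convert a first-order rate constant to a half-life
#'
#' @param k positive rate constant (any reciprocal-time unit).
#' @return Half-life `log(2)/k` in the reciprocal unit of `k`.
#' @examples
#' halflife(0.16)            # hours, ~4.33 h
#' halflife_to_rate(2)       # a 2-min half-life -> 0.347 min^-1
#' @export
halflife <- function(k) {
  check_positive(k, "k")
  log(2) / k
}

#' @rdname halflife
#' @param t_half positive half-life.
#' @export
halflife_to_rate <- function(t_half) {
  check_positive(t_half, "t_half")
  log(2) / t_half
}

#' @rdname halflife
#' @param minutes time in minutes.
#' @export
minutes_to_hours <- function(minutes) minutes / 60

#' @rdname halflife
#' @param hours time in hours.
#' @export
hours_to_minutes <- function(hours) hours * 60
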