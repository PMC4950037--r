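#' Error-spending functions
#'
#' Parses a spending-function identifier into an object that maps an
#' information fraction `t` to the cumulative error spent, reaching the full
#' `level` at `t >= 1`. Two families ship:
#'
#' * `"pow:kappa"` — power family, `f(t) = level * min(t, 1)^kappa`
#'   (`"pow"` alone means `kappa = 1`, the linear Pocock-like spend);
#' * `"obf"` — O'Brien-Fleming-type Lan-DeMets spend,
#'   `f(t) = 2 level' (1 - Phi(z / sqrt(t)))` scaled so `f(1) = level`,
#'   which spends very little error early.
#'
#' @param id Identifier string, e.g. `"pow:2"` or `"obf"`.
#' @return An `"rb_spending"` list with the parsed family, parameter, and a
#'   `spend(t, level)` function, monotone increasing with `spend(0) = 0`.
#' @examples
#' f <- spending_function("pow:2")
#' f$spend(c(0, 0.5, 1), level = 0.05)  # 0, 0.0125, 0.05
#' @export
spending_function <- function(id) {
  if (inherits(id, "rb_spending")) return(id)
  stopifnot(is.character(id), length(id) == 1)
  parts <- strsplit(id, ":", fixed = TRUE)[[1]]
  family <- parts[1]
  if (family == "pow") {
    kappa <- if (length(parts) > 1) as.numeric(parts[2]) else 1
    if (!is.finite(kappa) || kappa <= 0)
      stop("power-family spending needs a positive exponent", call. = FALSE)
    spend <- function(t, level) level * pmin(pmax(t, 0), 1)^kappa
    par <- kappa
  } else if (family == "obf") {
    spend <- function(t, level) {
      t <- pmin(pmax(t, 0), 1)
      z <- stats::qnorm(1 - level / 2)
      ifelse(t > 0, 2 * (1 - stats::pnorm(z / sqrt(t))), 0)
    }
    par <- NA_real_
  } else {
    stop("unknown spending family: ", family, call. = FALSE)
  }
  structure(list(id = id, family = family, parameter = par, spend = spend),
            class = "rb_spending")
}
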