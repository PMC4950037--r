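#' Specify a risk-benefit MAMS design
#'
#' Collects every user-chosen parameter of a multi-arm multi-stage trial with
#' a bivariate normal (efficacy, safety) endpoint: `K` experimental arms are
#' compared with a shared control, the arm with the best weighted risk-benefit
#' trade-off among those clearing a minimum safety requirement is selected at
#' the first analysis, and the selected arm is then tested against stopping
#' boundaries calibrated to control the familywise error rate (FWER) in the
#' strong sense.
#'
#' Treatment effects `theta_Tk = mu_Tk - mu_T0` (T in E, S) are differences
#' versus control, so control means are fixed at zero without loss of
#' generality. Variances `sigma_E^2`, `sigma_S^2` and the within-subject
#' correlation `rho` are treated as known. With `n` responses per arm under
#' 1:1 allocation, Fisher's information per comparison is
#' `I_T = n / (2 sigma_T^2)` and accumulated data are summarised by score
#' statistics `Z_Tk = I_T (muhat_Tk - muhat_T0)` with `Var(Z_Tk) = I_T`.
#'
#' @param K Number of experimental arms (positive integer).
#' @param alpha FWER level in (0, 1).
#' @param power Target disjunctive power `1 - beta` in (0, 1).
#' @param delta Desirable standardised efficacy effect used for sizing.
#' @param delta0 Minimum clinically important efficacy effect.
#' @param w_E,w_S Non-negative selection weights with `w_E^2 + w_S^2 = 1`
#'   (checked to 1e-10). `w_S` defaults to `sqrt(1 - w_E^2)`.
#' @param rho Within-subject correlation between the efficacy and safety
#'   responses, in `[-1, 1]`.
#' @param sigma_E,sigma_S Positive response standard deviations.
#' @param c Minimum-safety threshold on the safety score-statistic scale.
#'   An arm is eligible for selection only if `Z_Sk > c`. The default 0
#'   selects only arms looking at least as safe as control; `-Inf` disables
#'   the gate (co-primary efficacy use).
#' @param J Number of analyses (1 = single-stage).
#' @param spend_upper,spend_lower Spending-function identifiers for the
#'   multi-stage extension, e.g. `"pow:2"` (power family, exponent 2) or
#'   `"obf"` (O'Brien-Fleming-type). See [spending_function()].
#' @param gamma_surrogate Large positive number standing in for an infinite
#'   effect in the limiting configurations used for calibration and in
#'   worst-case simulations. Default `1e6`.
#'
#' @return An object of class `"rb_design"`: a validated list of the above.
#' @examples
#' des <- rb_design(K = 4, alpha = 0.05, power = 0.9,
#'                  delta = 0.545, delta0 = 0.178, rho = 0.4)
#' des
#' @seealso [solve_information()], [solve_boundaries()], [solve_max_information()]
#' @export
rb_design <- function(K = 4, alpha = 0.05, power = 0.9,
                      delta = 0.545, delta0 = 0.178,
                      w_E = sqrt(0.5), w_S = sqrt(1 - w_E^2),
                      rho = 0.4, sigma_E = 1, sigma_S = 1,
                      c = 0, J = 1,
                      spend_upper = "pow:2", spend_lower = "pow:2",
                      gamma_surrogate = 1e6) {
  stopifnot(
    length(K) == 1, K >= 1, K == as.integer(K),
    alpha > 0, alpha < 1,
    power > 0, power < 1,
    w_E >= 0, w_S >= 0,
    abs(rho) <= 1,
    sigma_E > 0, sigma_S > 0,
    J >= 1, J == as.integer(J),
    gamma_surrogate > 0
  )
  if (abs(w_E^2 + w_S^2 - 1) > 1e-10)
    stop("selection weights must satisfy w_E^2 + w_S^2 = 1", call. = FALSE)
  # parse early so malformed identifiers fail at construction
  spending_function(spend_upper)
  spending_function(spend_lower)
  structure(
    list(K = as.integer(K), alpha = alpha, beta = 1 - power,
         delta = delta, delta0 = delta0,
         w_E = w_E, w_S = w_S, rho = rho,
         sigma_E = sigma_E, sigma_S = sigma_S,
         c = c, J = as.integer(J),
         spend_upper = spend_upper, spend_lower = spend_lower,
         gamma_surrogate = gamma_surrogate),
    class = "rb_design"
  )
}

#' @export
print.rb_design <- function(x, ...) {
  cat("Risk-benefit MAMS design specification\n")
  cat(sprintf("  arms: %d experimental vs shared control; analyses J = %d\n",
              x$K, x$J))
  cat(sprintf("  FWER alpha = %g, target power = %g\n", x$alpha, 1 - x$beta))
  cat(sprintf("  efficacy effects: delta = %g, delta0 = %g\n",
              x$delta, x$delta0))
  cat(sprintf("  selection weights (w_E, w_S) = (%.4f, %.4f), safety gate c = %g\n",
              x$w_E, x$w_S, x$c))
  cat(sprintf("  rho = %g, sigma_E = %g, sigma_S = %g\n",
              x$rho, x$sigma_E, x$sigma_S))
  if (x$J > 1)
    cat(sprintf("  spending: upper %s, lower %s\n",
                x$spend_upper, x$spend_lower))
  invisible(x)
}

#' Read or write a design configuration file
#'
#' A design round-trips to a flat key-value YAML file whose keys are exactly
#' the arguments of [rb_design()] (with `power` in place of `beta`). Values
#' given in `...` override values read from the file, so a config can act as
#' a template.
#'
#' @param path File path.
#' @param ... For `read_design_config()`, named [rb_design()] arguments that
#'   override the file's entries.
#' @return `read_design_config()` returns an `rb_design`;
#'   `write_design_config()` returns `path` invisibly.
#' @export
read_design_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(rb_design))
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  raw[c("c", "gamma_surrogate")] <- lapply(raw[c("c", "gamma_surrogate")],
                                           function(v) if (is.character(v)) as.numeric(v) else v)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  over <- list(...)
  raw[names(over)] <- over
  do.call(rb_design, raw)
}

#' @param design An [rb_design()] object.
#' @rdname read_design_config
#' @export
write_design_config <- function(design, path) {
  stopifnot(inherits(design, "rb_design"))
  out <- design[setdiff(names(design), "beta")]
  out$power <- 1 - design$beta
  class(out) <- NULL
  # -Inf etc. survive the YAML round trip as strings; coerced back on read
  yaml::write_yaml(lapply(out, function(v) if (is.infinite(v)) as.character(v) else v),
                   path, precision = 15)
  invisible(path)
}

# Derived constants of the selection geometry. Score statistics decompose as
# X_Tk = (A_k - A_0)/sqrt(2) + sqrt(I_T) theta_Tk on the standardised scale,
# with (A_k, B_k) iid bivariate standard normal, corr rho, per arm. The
# selection score is C_k = w_E A_k + w_S B_k.
sel_params <- function(design) {
  wE <- design$w_E; wS <- design$w_S; rho <- design$rho
  s2 <- 1 + 2 * wE * wS * rho           # Var(C_k)
  list(
    s2 = s2, s = sqrt(s2),
    covAC = wE + wS * rho,              # Cov(A_k, C_k)
    covBC = wS + wE * rho               # Cov(B_k, C_k)
  )
}

# Information per comparison from n responses per arm
info_from_n <- function(n, sigma) n / (2 * sigma^2)
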