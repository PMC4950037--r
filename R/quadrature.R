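# Gauss-Legendre machinery shared by the limiting-probability integrals.
# All integrands here are analytic with Gaussian tails, so fixed-order rules
# on +-8 sd ranges converge far below the 1e-6 absolute tolerance documented
# for the integration route (stable to < 1e-8 between 64 and 192 nodes).

.gl_env <- new.env(parent = emptyenv())

# nodes/weights on [-1, 1], cached by order
gl_base <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_env[[key]])) {
    g <- pracma::gaussLegendre(n, -1, 1)
    .gl_env[[key]] <- list(x = g$x, w = g$w)
  }
  .gl_env[[key]]
}

gl_rule <- function(n, a, b) {
  g <- gl_base(n)
  list(x = (a + b) / 2 + (b - a) / 2 * g$x, w = (b - a) / 2 * g$w)
}

# default order for the limiting-probability quadratures
.NGL <- 96L

#' Bivariate normal upper-orthant probability
#'
#' `P(X > h, Y > k)` for standard bivariate normal `(X, Y)` with correlation
#' `r`, vectorised over `h` and `k` (recycled). Computed by Gauss-Legendre
#' integration of the conditional tail,
#' `int_h phi(x) Phibar((k - r x) / sqrt(1 - r^2)) dx`,
#' with exact handling of the degenerate cases `r = +-1`. Used by the
#' safety-boundary criterion, where the joint tail of an arm's safety
#' statistic and selection score is needed; no such primitive ships with the
#' installed packages.
#'
#' @param h,k Lower limits (numeric vectors, recycled to common length).
#' @param r Correlation, scalar in `[-1, 1]`.
#' @return Vector of probabilities.
#' @keywords internal
#' @export
pbvnorm_upper <- function(h, k, r) {
  stopifnot(length(r) == 1, abs(r) <= 1)
  n <- max(length(h), length(k))
  h <- rep_len(h, n); k <- rep_len(k, n)
  if (r >= 1 - 1e-12)
    return(stats::pnorm(pmax(h, k), lower.tail = FALSE))
  if (r <= -1 + 1e-12)
    return(pmax(0, stats::pnorm(-k) - stats::pnorm(h)))
  lo <- pmax(h, -9)
  hi <- pmax(lo + 1e-12, 9)
  g <- gl_base(.NGL)
  # node matrix: .NGL x n, column j spans [lo_j, hi_j]
  half <- (hi - lo) / 2
  x <- outer(g$x, half) + rep(lo + half, each = .NGL)
  w <- outer(g$w, half)
  intg <- stats::dnorm(x) *
    stats::pnorm((rep(k, each = .NGL) - r * x) / sqrt(1 - r^2),
                 lower.tail = FALSE)
  colSums(w * intg)
}
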