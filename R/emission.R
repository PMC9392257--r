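#' Negative-binomial dispersion model learned from diploid cells
#'
#' Read-count variance is modelled as a quadratic function of the mean,
#' `sigma^2 = a*lambda^2 + b*lambda + c`, with coefficients estimated from
#' matched diploid cells (see [fit_dispersion]). `epsilon` is a small
#' constant sequencing-error term (in reads) added to every expected count
#' so that copy number 0 still has positive emission probability.
#'
#' @param a,b,c variance-function coefficients; `a >= 0`, `c >= 0`.
#' @param epsilon constant error term in reads (default 0.01).
#' @return An object of class `dispersion_model`.
#' @export
dispersion_model <- function(a, b, c, epsilon = 0.01) {
  if (a < 0 || c < 0) stop("require a >= 0 and c >= 0")
  if (epsilon < 0) stop("epsilon must be >= 0")
  structure(list(a = a, b = b, c = c, epsilon = epsilon),
            class = "dispersion_model")
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat(sprintf(
    "<dispersion_model> var = %.4g*mean^2 + %.4g*mean + %.4g, epsilon = %g\n",
    x$a, x$b, x$c, x$epsilon))
  invisible(x)
}

#' Per-cell emission context
#'
#' Bundles everything needed to evaluate read-count emission probabilities
#' for one cell: the library-size scaling factor `s` (coverage relative to
#' the average diploid library), the per-window mean diploid depth `mu`,
#' and the dispersion model.
#'
#' @param s library-size scaling factor (> 0).
#' @param mu numeric vector of per-window mean diploid read depth.
#' @param dispersion a [dispersion_model].
#' @return An object of class `emission_context`.
#' @export
emission_context <- function(s, mu, dispersion) {
  if (s <= 0) stop("s must be > 0")
  if (any(mu < 0)) stop("mu must be >= 0")
  stopifnot(inherits(dispersion, "dispersion_model"))
  structure(list(s = s, mu = as.numeric(mu), dispersion = dispersion),
            class = "emission_context")
}

# mean/variance -> NB log pmf; variance floored just above the mean so that
# fitted {a,b,c} dipping below the Poisson line stay usable (near-Poisson)
nb_logpmf_mv <- function(x, lambda, sigma2) {
  floor_v <- lambda * (1 + 1e-6)
  sigma2 <- pmax(sigma2, floor_v)
  size <- lambda^2 / (sigma2 - lambda)
  stats::dnbinom(x, size = size, mu = lambda, log = TRUE)
}

#' Emission log-probability of an observed count
#'
#' Given copy number `cn` in window `i`, the expected count is
#' `lambda = (cn * mu_i / 2) * s + epsilon` and the count follows a
#' negative binomial with that mean and variance
#' `a*lambda^2 + b*lambda + c`. If the fitted variance falls at or below
#' the mean it is floored to `lambda * (1 + 1e-6)` (near-Poisson) with a
#' warning.
#'
#' @param x observed read count (non-negative integer; vectorised).
#' @param cn copy number state (0..k).
#' @param ctx an [emission_context].
#' @param i window index (1-based).
#' @return Log probability (finite for all valid inputs).
#' @export
emission_logpmf <- function(x, cn, ctx, i) {
  stopifnot(inherits(ctx, "emission_context"))
  if (any(x < 0) || any(x != floor(x))) stop("x must be non-negative integer")
  if (cn < 0) stop("cn must be >= 0")
  mu_i <- ctx$mu[i]
  if (is.na(mu_i)) stop("mu undefined for window ", i)
  d <- ctx$dispersion
  lambda <- (cn * mu_i / 2) * ctx$s + d$epsilon
  sigma2 <- d$a * lambda^2 + d$b * lambda + d$c
  if (any(sigma2 <= lambda * (1 + 1e-6)))
    warning("variance at or below mean; floored to near-Poisson")
  nb_logpmf_mv(x, lambda, sigma2)
}

#' Joint emission log-probability for a pair of cells
#'
#' Conditional on the paired copy-number state, counts in the two cells are
#' independent, so the joint log probability is the sum of the two
#' single-cell terms.
#'
#' @param xA,xB observed counts in cells A and B.
#' @param cnA,cnB copy numbers in cells A and B.
#' @param ctxA,ctxB [emission_context]s for the two cells.
#' @param i window index.
#' @return Log probability.
#' @export
pair_emission_logpmf <- function(xA, xB, cnA, cnB, ctxA, ctxB, i) {
  emission_logpmf(xA, cnA, ctxA, i) + emission_logpmf(xB, cnB, ctxB, i)
}

# (k+1) x N matrix of log emissions for one cell across all windows and all
# copy-number states; windows with mu == 0 are masked (log-prob 0 in every
# state, i.e. uninformative)
emission_logmat <- function(counts, ctx, k) {
  N <- length(counts)
  d <- ctx$dispersion
  out <- matrix(0, k + 1L, N)
  ok <- ctx$mu > 0
  for (cn in 0:k) {
    lambda <- (cn * ctx$mu / 2) * ctx$s + d$epsilon
    sigma2 <- d$a * lambda^2 + d$b * lambda + d$c
    out[cn + 1L, ok] <- nb_logpmf_mv(counts[ok], lambda[ok], sigma2[ok])
  }
  out
}

# (k+1)^2 x N paired log-emission matrix; paired state (cA,cB) at row
# cA*(k+1)+cB+1
pair_emission_logmat <- function(countsA, countsB, ctxA, ctxB, k) {
  EA <- emission_logmat(countsA, ctxA, k)
  EB <- emission_logmat(countsB, ctxB, k)
  EA[rep(1:(k + 1L), each = k + 1L), , drop = FALSE] +
    EB[rep(1:(k + 1L), times = k + 1L), , drop = FALSE]
}
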