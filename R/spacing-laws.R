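#' Circular spacing law for uniform sites
#'
#' For \eqn{N} sites drawn independently and uniformly on a circle of unit
#' perimeter, the arc length between two sites separated by exactly \eqn{i}
#' intermediate sites follows
#' \deqn{\rho_i^N(x) = (N-1)\,\binom{N-2}{i}\, x^i (1-x)^{N-2-i},}
#' which is the Beta\eqn{(i+1,\,N-1-i)} density. This law is the building
#' block of both the spectrum score (through its two-sided tails) and the
#' positional score (through its lower tail).
#'
#' @param N total number of sites on the circle (>= 2).
#' @param i number of intermediate sites strictly between the pair
#'   (0 <= i <= N-2).
#' @return an object of class \code{"spacing_law"}.
#' @examples
#' law <- spacing_law(N = 11, i = 3)
#' spacing_pdf(law, 0.3)
#' spacing_cdf(law, 0.3)
#' @export
spacing_law <- function(N, i) {
  N <- check_scalar(N, "N"); i <- check_scalar(i, "i")
  if (N != floor(N) || N < 2) stop_param("N must be an integer >= 2, got %g", N)
  if (i != floor(i) || i < 0) stop_param("i must be an integer >= 0, got %g", i)
  if (i > N - 2) stop_param("i must satisfy i <= N - 2 (got i = %g, N = %g)", i, N)
  structure(list(N = as.integer(N), i = as.integer(i)), class = "spacing_law")
}

#' @export
print.spacing_law <- function(x, ...) {
  cat(sprintf("Circular spacing law: N = %d uniform sites, %d intermediate site(s)\n",
              x$N, x$i))
  cat(sprintf("  equals Beta(%d, %d) on [0, 1]\n", x$i + 1L, x$N - 1L - x$i))
  invisible(x)
}

#' Density of a circular spacing law
#'
#' @param law a \code{\link{spacing_law}}.
#' @param x normalized distance(s) in [0, 1] (distance divided by the
#'   circle perimeter, i.e. by the period).
#' @return density values (dimensionless).
#' @export
spacing_pdf <- function(law, x) {
  stopifnot(inherits(law, "spacing_law"))
  if (any(x < 0 | x > 1)) stop_param("normalized distance x must lie in [0, 1]")
  stats::dbeta(x, law$i + 1, law$N - 1 - law$i)
}

#' Repartition (cumulative distribution) of a circular spacing law
#'
#' Computed as the regularized incomplete Beta function
#' \eqn{I_x(i+1, N-1-i)}.
#'
#' @inheritParams spacing_pdf
#' @param lower.tail if \code{FALSE}, return the upper tail probability.
#'   The upper tail is computed directly (not as \code{1 - cdf}) so that
#'   very small tail probabilities keep full relative precision.
#' @return probabilities in [0, 1].
#' @export
spacing_cdf <- function(law, x, lower.tail = TRUE) {
  stopifnot(inherits(law, "spacing_law"))
  if (any(x < 0 | x > 1)) stop_param("normalized distance x must lie in [0, 1]")
  stats::pbeta(x, law$i + 1, law$N - 1 - law$i, lower.tail = lower.tail)
}

#' Two-sided spacing p-value for j-th nearest neighbors
#'
#' The probability of a spacing at least as extreme (as small, for dense
#' regions; as large, for empty regions) as \code{x} between the j-th
#' nearest neighbors on each side of a site, for \eqn{N} uniform sites.
#' Those two neighbors are separated by \eqn{2j-1} sites, so the relevant
#' law is \code{spacing_law(N, 2j-1)}; the p-value is approximated by
#' \deqn{p_j^N(x) = \min\big(F_{2j-1}^N(x),\; 1 - F_{2j-1}^N(x)\big),}
#' exact in both tails, at most 0.5 at the distribution median.
#'
#' @param j neighbor order (>= 1); requires \eqn{2j - 1 \le N - 2}.
#' @param N number of sites.
#' @param x normalized circular distance(s) in [0, 1].
#' @param eps lower floor on the returned p-value so its logarithm stays
#'   finite even for exactly coincident sites.
#' @return p-values in [eps, 0.5].
#' @export
pair_pvalue <- function(j, N, x, eps = 1e-300) {
  j <- check_scalar(j, "j"); N <- check_scalar(N, "N")
  if (j < 1 || j != floor(j)) stop_param("neighbor order j must be an integer >= 1")
  if (2 * j - 1 > N - 2)
    stop_param("too few sites for neighbor order j = %g: need 2j - 1 <= N - 2 (N = %g)",
               j, N)
  law <- spacing_law(N, 2 * j - 1)
  pmax(pmin(spacing_cdf(law, x), spacing_cdf(law, x, lower.tail = FALSE)), eps)
}

#' Lower-tail spacing p-value for a pair spanning g gaps
#'
#' The probability that two uniform sites on the circle, in a circular
#' order relation spanning \code{g} gaps (i.e. with \eqn{g - 1} sites
#' strictly between them), are closer than \code{y}. This is the lower
#' tail of \code{spacing_law(N, g - 1)}, i.e. the Beta\eqn{(g, N-g)} CDF.
#' It is the building block of the per-site positional score, which
#' rewards sites sitting in dense regions of the solenoid face view.
#'
#' The index convention (a distance spanning \eqn{g} gaps follows
#' Beta\eqn{(g, N-g)}) is pinned down by a direct sampling experiment in
#' the package tests.
#'
#' @param y normalized circular distance(s) in [0, 1].
#' @param g number of spanned gaps, 1 <= g <= N - 1.
#' @param N number of sites.
#' @param eps lower p-value floor (see \code{\link{pair_pvalue}}).
#' @return probabilities in [eps, 1].
#' @export
pair_less_pvalue <- function(y, g, N, eps = 1e-300) {
  g <- check_scalar(g, "g"); N <- check_scalar(N, "N")
  if (g < 1 || g > N - 1 || g != floor(g))
    stop_param("spanned gap count g must be an integer in [1, N - 1] (got g = %g, N = %g)",
               g, N)
  if (any(y < 0 | y > 1)) stop_param("normalized distance y must lie in [0, 1]")
  pmax(stats::pbeta(y, g, N - g), eps)
}
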