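#' Project sites onto the face view of a P-periodic solenoid
#'
#' Wrapping the support around a solenoid of period \code{P} and projecting
#' onto its face view maps a site at position \eqn{x} to the angle
#' \eqn{(x \bmod P)/P} on the unit circle. Sites of a P-periodic pattern
#' align on the solenoid and therefore cluster on the face view; uniform
#' sites stay uniform for every period.
#'
#' @param sites a \code{\link{site_sequence}}.
#' @param period candidate period \code{P}, in positions; \code{1 < P <= L}.
#' @return an object of class \code{"projected_sites"}: list with
#'   \code{period}, sorted angles \code{theta} in [0, 1), and \code{order},
#'   the permutation mapping sorted angles back to the input sites
#'   (\code{theta[k]} comes from \code{sites$positions[order[k]]}).
#' @examples
#' comb <- dirac_comb(10000, 80000)
#' project_modulo(comb, 10000)$theta   # all aligned at 0
#' @export
project_modulo <- function(sites, period) {
  stopifnot(inherits(sites, "site_sequence"))
  period <- check_scalar(period, "period")
  if (period <= 1 || period > sites$L)
    stop_param("period must satisfy 1 < period <= L (got %g, L = %g)",
               period, sites$L)
  theta <- (sites$positions %% period) / period
  o <- order(theta)
  structure(list(period = period, theta = theta[o], order = o),
            class = "projected_sites")
}

#' Normalized circular distance between the j-th neighbors around a site
#'
#' On the solenoid face view, the j-th nearest neighbor counterclockwise
#' and the j-th nearest neighbor clockwise of site \code{i} are separated
#' by \eqn{2j - 1} sites (\code{i} among them). This function returns the
#' circular arc between those two neighbors, normalized by the period.
#'
#' @param proj a \code{\link{project_modulo}} result.
#' @param i site index in sorted (clockwise) order, 1-based.
#' @param j neighbor order; requires \eqn{2j - 1 \le N - 2}.
#' @return normalized arc length in [0, 1].
#' @export
neighbor_distance <- function(proj, i, j) {
  stopifnot(inherits(proj, "projected_sites"))
  N <- length(proj$theta)
  i <- check_scalar(i, "i"); j <- check_scalar(j, "j")
  if (i < 1 || i > N || i != floor(i))
    stop_param("site index i must be an integer in [1, N]")
  if (j < 1 || j != floor(j) || 2 * j - 1 > N - 2)
    stop_param("neighbor order j = %g exceeds available sites (N = %d)", j, N)
  up <- proj$theta[((i - 1 + j) %% N) + 1]
  dn <- proj$theta[((i - 1 - j) %% N) + 1]
  (up - dn) %% 1
}

#' Default neighbor depth J
#'
#' The number of neighbor orders summed in the spectrum score grows with
#' the number of sites as \code{max(floor(N / 16), 1)}, additionally capped
#' so that \eqn{2J - 1 \le N - 2}. Detection is insensitive to the precise
#' rule; larger J costs proportionally more time.
#'
#' @param N number of sites (scoring requires N >= 3).
#' @return integer neighbor depth.
#' @examples
#' default_J(90)  # 5
#' default_J(16)  # 1
#' @export
default_J <- function(N) {
  N <- check_scalar(N, "N")
  if (N < 2 || N != floor(N)) stop_param("N must be an integer >= 2")
  J <- max(N %/% 16, 1)
  max(min(J, (N - 1) %/% 2), 1)
}

# Core scoring kernel. theta: sorted angles. Returns both the plain score
# (continuous spacing laws, zero distances capped through the p-value floor
# eps) and the lattice-corrected score, where normalized distances are
# floored at resolution/(2 * period): positions live on an integer lattice,
# so distances below one position are unresolved and a coincidence is "half
# a position" away rather than infinitely surprising. The correction leaves
# non-degenerate configurations untouched but restores the period
# dependence of coincidence surprise, which ranks a fundamental above its
# exact divisors. Upper tails use lower.tail = FALSE to keep precision.
fold_scores <- function(theta, J, eps = 1e-300, floor_x = 0) {
  N <- length(theta)
  idx <- seq_len(N)
  sp <- 0; sl <- 0
  for (j in seq_len(J)) {
    x <- (theta[((idx - 1 + j) %% N) + 1] - theta[((idx - 1 - j) %% N) + 1]) %% 1
    a <- 2 * j; b <- N - 2 * j
    xf <- pmax(x, floor_x)
    pl <- pmax(pmin(stats::pbeta(xf, a, b),
                    stats::pbeta(xf, a, b, lower.tail = FALSE)), eps)
    sl <- sl + sum(-log(pl))
    pp <- pl
    low <- which(x < xf)
    if (length(low))
      pp[low] <- pmax(pmin(stats::pbeta(x[low], a, b),
                           stats::pbeta(x[low], a, b, lower.tail = FALSE)), eps)
    sp <- sp + sum(-log(pp))
  }
  c(score = sp / (2 * J * N), lattice_score = sl / (2 * J * N))
}

#' Solenoidal coordinate score at one period
#'
#' The score of a site set at a candidate period \code{P} sums the
#' self-information of the nearest-neighbor spacings on the P-solenoid
#' face view:
#' \deqn{S_{scs}(P) = -\frac{1}{2JN} \sum_{i=0}^{N-1} \sum_{j=1}^{J}
#'   \log p_j^N\!\big(x_{i,j}^P\big),}
#' where \eqn{x_{i,j}^P} is the normalized circular distance between the
#' j-th neighbors on each side of site i (see
#' \code{\link{neighbor_distance}}) and \eqn{p_j^N} the two-sided spacing
#' p-value (see \code{\link{pair_pvalue}}; natural logarithm). Both very
#' small spacings (dense clusters) and very large ones (empty arcs) carry
#' high information, so P-periodic patterns score high at P.
#'
#' @param sites a \code{\link{site_sequence}} with at least 3 sites.
#' @param period candidate period in positions.
#' @param J neighbor depth; defaults to \code{\link{default_J}}.
#' @param eps p-value floor (see \code{\link{pair_pvalue}}).
#' @param resolution if non-\code{NULL}, the position lattice spacing:
#'   normalized spacings are floored at \code{resolution / (2 * period)}
#'   before scoring, the continuity correction of the discrete uniform
#'   null. With the default \code{NULL} the continuous-law score is
#'   returned, in which exactly coincident sites are capped only by
#'   \code{eps}.
#' @return the score (dimensionless scalar).
#' @examples
#' comb <- dirac_comb(10000, 200000)
#' scs_score(comb, 10000) > scs_score(comb, 6180)
#' @export
scs_score <- function(sites, period, J = NULL, eps = 1e-300, resolution = NULL) {
  stopifnot(inherits(sites, "site_sequence"))
  N <- n_sites(sites)
  if (N < 3) stop_param("scoring needs at least 3 sites (got N = %d)", N)
  if (is.null(J)) J <- default_J(N)
  J <- check_scalar(J, "J")
  if (J < 1 || J != floor(J) || 2 * J - 1 > N - 2)
    stop_param("invalid neighbor depth J = %g for N = %d (need 2J - 1 <= N - 2)",
               J, N)
  proj <- project_modulo(sites, period)
  if (all(proj$theta == proj$theta[1]))
    warning("all positions identical modulo the period; score capped by the p-value floor")
  floor_x <- if (is.null(resolution)) 0 else resolution / (2 * period)
  s <- fold_scores(proj$theta, J, eps, floor_x)
  unname(if (is.null(resolution)) s["score"] else s["lattice_score"])
}
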