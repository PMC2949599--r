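#' Per-site clustering statistic on the solenoid face view
#'
#' For a site \code{i}, consider every pair made of one of its \code{J}
#' nearest neighbors counterclockwise and one of its \code{J} nearest
#' neighbors clockwise on the face view of the P-solenoid (so \code{i}
#' lies strictly inside the arc joining the pair). Each pair spanning
#' \code{g} gaps is assigned the probability \eqn{p_<} that two uniform
#' sites in that order relation are closer than the observed arc
#' (\code{\link{pair_less_pvalue}}). The statistic is the largest
#' information content over those pairs,
#' \deqn{S'(i, P) = \max_{\langle a, b\rangle_J} \{-\log p_<\},}
#' large when \code{i} sits inside a dense cluster.
#'
#' @param sites a \code{\link{site_sequence}} with at least 3 sites.
#' @param period candidate period.
#' @param i optional site index (in input position order); default all.
#' @param J neighbor depth per side; default \code{\link{default_J}},
#'   capped at \code{floor((N - 1) / 2)}.
#' @param eps p-value floor.
#' @return numeric vector of S' values (for all sites, in input order) or
#'   a single value when \code{i} is given.
#' @export
site_statistic <- function(sites, period, i = NULL, J = NULL, eps = 1e-300) {
  stopifnot(inherits(sites, "site_sequence"))
  N <- n_sites(sites)
  if (N < 3) stop_param("positional statistics need at least 3 sites")
  if (is.null(J)) J <- default_J(N)
  J <- min(J, (N - 1) %/% 2)
  proj <- project_modulo(sites, period)
  S_sorted <- sprime_from_theta(proj$theta, J, eps)
  S <- numeric(N)
  S[proj$order] <- S_sorted
  if (is.null(i)) return(S)
  if (i < 1 || i > N || i != floor(i))
    stop_param("site index i must be an integer in [1, N]")
  S[i]
}

# S' for sorted angles; returns values in sorted order. Sites with exactly
# equal angles are indistinguishable (their clockwise order is arbitrary),
# so all members of a coincident cluster share the cluster maximum.
sprime_from_theta <- function(theta, J, eps = 1e-300) {
  N <- length(theta)
  idx <- seq_len(N)
  S <- rep(-Inf, N)
  for (a in seq_len(J)) {
    up_a <- theta[((idx - 1 - a) %% N) + 1]  # a-th neighbor counterclockwise
    for (b in seq_len(J)) {
      g <- a + b
      if (g > N - 1) next
      y <- (theta[((idx - 1 + b) %% N) + 1] - up_a) %% 1
      S <- pmax(S, -log(pmax(stats::pbeta(y, g, N - g), eps)))
    }
  }
  if (anyDuplicated(theta)) S <- stats::ave(S, match(theta, theta), FUN = max)
  S
}

# Null ensemble for S': R uniform configurations of N sites; by
# exchangeability the statistic of one designated site is representative.
# The designated site is drawn uniformly: anchoring at a fixed rank (e.g.
# the smallest angle) would size-bias the arc containing the origin.
sprime_null <- function(N, J, R = 1000, seed = NULL, eps = 1e-300) {
  if (R < 100) warning("R < 100 gives poor p-value resolution (1 / (R + 1))")
  scores <- with_seed(seed, vapply(seq_len(R), function(r)
    sprime_from_theta(sort(stats::runif(N)), J, eps)[sample.int(N, 1L)],
    numeric(1)))
  structure(list(scores = scores, N = as.integer(N), J = as.integer(J),
                 R = as.integer(R), seed = seed),
            class = "sprime_null")
}

#' Positional scores: which sites follow a given periodicity
#'
#' The positional score of site \code{i} at period \code{P} is
#' \deqn{S_{pos}(i, P) = -\log_{10} p_v\big(S'(i, P)\big),}
#' where \eqn{p_v} is the Monte-Carlo probability of an equal or higher
#' clustering statistic \code{\link{site_statistic}} for a site in a
#' uniform-random configuration of the same size (add-one estimator).
#' High scores single out the sites that participate in the P-periodic
#' pattern; scores are bounded by \eqn{\log_{10}(R + 1)}.
#'
#' @inheritParams site_statistic
#' @param null_reps Monte-Carlo replicates for the null of S'.
#' @param seed RNG seed (caller's RNG state preserved).
#' @param null optional precomputed internal null (as returned in the
#'   \code{null} attribute of a previous result for the same N and J);
#'   mainly used by \code{\link{two_period_scatter}}.
#' @return an object of class \code{"positional_score"}: a data frame
#'   with columns \code{site_index}, \code{position}, \code{period},
#'   \code{S_prime}, \code{p_v}, \code{S_pos}, one row per site.
#' @examples
#' comb <- dirac_comb(500, 5000)
#' ps <- positional_score(comb, 500, null_reps = 200, seed = 1)
#' all(ps$S_pos == max(ps$S_pos))  # every comb site maximally scored
#' @export
positional_score <- function(sites, period, J = NULL, null_reps = 1000,
                             seed = NULL, null = NULL, eps = 1e-300) {
  stopifnot(inherits(sites, "site_sequence"))
  N <- n_sites(sites)
  if (N < 3) stop_param("positional scores need at least 3 sites")
  if (is.null(J)) J <- default_J(N)
  J <- min(J, (N - 1) %/% 2)
  if (is.null(null)) {
    null <- sprime_null(N, J, R = null_reps, seed = seed, eps = eps)
  } else {
    stopifnot(inherits(null, "sprime_null"))
    if (null$N != N || null$J != J)
      stop_param("supplied null (N = %d, J = %d) does not match (N = %d, J = %d)",
                 null$N, null$J, N, J)
  }
  S <- site_statistic(sites, period, J = J, eps = eps)
  sorted <- sort(null$scores)
  n_ge <- null$R - findInterval(S, sorted, left.open = TRUE)
  p_v <- (1 + n_ge) / (null$R + 1)
  out <- data.frame(site_index = seq_len(N), position = sites$positions,
                    period = period, S_prime = S, p_v = p_v,
                    S_pos = -log10(p_v))
  if (!is.null(sites$labels)) out$label <- sites$labels
  attr(out, "null") <- null
  attr(out, "J") <- null$J
  structure(out, class = c("positional_score", "data.frame"))
}

#' @export
plot.positional_score <- function(x, ...) {
  graphics::plot(x$position, x$S_pos, xlab = "position",
                 ylab = expression(S[pos]),
                 main = sprintf("Positional scores at period %g", x$period[1]),
                 ...)
  invisible(x)
}

#' Write a positional score table to TSV
#'
#' Columns \code{site_index}, \code{position}, \code{period},
#' \code{S_prime}, \code{p_v}, \code{S_pos} (plus \code{label} when
#' present), full float precision.
#'
#' @param x a \code{\link{positional_score}} (or
#'   \code{\link{two_period_scatter}}) table.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_positional <- function(x, path) {
  stopifnot(is.data.frame(x))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-period positional scatter
#'
#' For each site, the pair \eqn{(10^{-S_{pos}(P_1)}, 10^{-S_{pos}(P_2)})}
#' of positional p-values at two candidate periods. In a superposition of
#' two periodic trains, the sites of the \eqn{P_1} train fall below the
#' bisector (more significant at \eqn{P_1}) and the sites of the
#' \eqn{P_2} train above it, so the scatter disentangles the trains; at
#' periods unrelated to the data the points show no separation.
#'
#' Both coordinates are calibrated against a single null ensemble of the
#' clustering statistic (its distribution does not depend on the period).
#' A site is assigned to \eqn{P_1} when its \eqn{P_1} coordinate is
#' smaller; exact p-value ties (both saturated) are broken by the larger
#' raw statistic, remaining ties go to \eqn{P_2}.
#'
#' @inheritParams positional_score
#' @param period1,period2 the two candidate periods.
#' @return an object of class \code{"two_period_scatter"}: data frame
#'   with columns \code{site_index}, \code{position}, \code{pv1},
#'   \code{pv2} (the two plotted p-values), \code{assigned} (1 or 2) and
#'   \code{label} when the input carries train labels; periods stored in
#'   the \code{periods} attribute.
#' @export
two_period_scatter <- function(sites, period1, period2, J = NULL,
                               null_reps = 1000, seed = NULL, eps = 1e-300) {
  stopifnot(inherits(sites, "site_sequence"))
  N <- n_sites(sites)
  if (is.null(J)) J <- default_J(N)
  J <- min(J, (N - 1) %/% 2)
  null <- sprime_null(N, J, R = null_reps, seed = seed, eps = eps)
  t1 <- positional_score(sites, period1, J = J, null = null, eps = eps)
  t2 <- positional_score(sites, period2, J = J, null = null, eps = eps)
  assigned <- ifelse(t1$p_v < t2$p_v, 1L,
              ifelse(t1$p_v > t2$p_v, 2L,
              ifelse(t1$S_prime > t2$S_prime, 1L, 2L)))
  out <- data.frame(site_index = t1$site_index, position = t1$position,
                    pv1 = t1$p_v, pv2 = t2$p_v, assigned = assigned)
  if (!is.null(sites$labels)) out$label <- sites$labels
  attr(out, "periods") <- c(period1, period2)
  structure(out, class = c("two_period_scatter", "data.frame"))
}

#' @export
plot.two_period_scatter <- function(x, ...) {
  pp <- attr(x, "periods")
  col <- if (!is.null(x$label)) as.integer(factor(x$label)) + 1L else 1L
  graphics::plot(x$pv1, x$pv2,
                 xlab = bquote(10^{-S[pos]} ~ "at P =" ~ .(pp[1])),
                 ylab = bquote(10^{-S[pos]} ~ "at P =" ~ .(pp[2])),
                 col = col, ...)
  graphics::abline(0, 1, col = "red")
  invisible(x)
}
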