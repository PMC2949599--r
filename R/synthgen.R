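# Synthetic site generators: the study scenarios (combs, motif trains,
# jitter, contamination, two-train mixtures) used throughout the tests and
# the worked examples.

#' Dirac comb
#'
#' Sites at 0, P, 2P, ... below L: the idealized periodic pattern.
#'
#' @param period comb spacing P, 0 < P <= L.
#' @param L support length.
#' @return a \code{\link{site_sequence}}.
#' @examples
#' n_sites(dirac_comb(10000, 80000))  # 8
#' @export
dirac_comb <- function(period, L) {
  period <- check_scalar(period, "period"); L <- check_scalar(L, "L")
  if (period <= 0 || period > L) stop_param("need 0 < period <= L")
  site_sequence(seq(0, L - 1, by = period), L = L)
}

#' Periodic train of a complex motif
#'
#' Repeats a motif (a set of offsets inside one period) every
#' \code{period} positions: the union of \code{offsets + k * period} for
#' \code{k = 0, ..., repeats - 1}, truncated to the support.
#'
#' @param offsets motif site offsets, each in [0, period).
#' @param period repeat distance P.
#' @param repeats number of repeats (>= 1).
#' @param L support length; default \code{repeats * period}. Sites at or
#'   beyond L are dropped.
#' @return a \code{\link{site_sequence}}.
#' @export
motif_train <- function(offsets, period, repeats, L = NULL) {
  period <- check_scalar(period, "period")
  repeats <- check_scalar(repeats, "repeats")
  if (repeats < 1 || repeats != floor(repeats)) stop_param("repeats must be an integer >= 1")
  if (any(offsets < 0 | offsets >= period))
    stop_param("all offsets must lie in [0, period)")
  if (is.null(L)) L <- repeats * period
  pos <- as.vector(outer(offsets, (seq_len(repeats) - 1) * period, "+"))
  pos <- pos[pos < L]
  site_sequence(pos, L = L)
}

#' Check that a motif has no common internal near-spacing
#'
#' A repeated motif is a clean test of fundamental-period recovery only
#' when the motif itself is aperiodic. Three failure modes are screened:
#' \itemize{
#'   \item a repeated internal spacing -- two pairwise circular offset
#'     differences agreeing within 1 percent of the period -- makes two
#'     site pairs co-align when folding at some submultiple (near-evenly
#'     spaced offsets are the extreme case, an internal comb);
#'   \item offsets that (nearly) coincide, or concentrate, modulo a
#'     submultiple P/k (k = 2..5) hand genuine clustering to that
#'     subharmonic: projections modulo P/2 through P/5 must be pairwise
#'     separated (by at least 5, 5, 4, 4 percent of the submultiple) with
#'     the largest empty arc at most 65 percent;
#'   \item offsets closer than 10 percent of the period itself, whose
#'     clusters would merge under positional noise of that order.
#' }
#'
#' @param offsets candidate motif offsets in [0, period).
#' @param period repeat distance.
#' @return \code{TRUE} or \code{FALSE}.
#' @seealso \code{\link{draw_motif_offsets}}
#' @export
is_aperiodic_motif <- function(offsets, period) {
  ok <- function(q, min_sep, max_gap) {
    th <- sort((offsets %% q) / q)
    gaps <- diff(c(th, th[1] + 1))
    min(gaps) >= min_sep && max(gaps) <= max_gap
  }
  d <- as.vector(stats::dist(offsets))
  d <- pmin(d, period - d)                 # circular internal spacings
  if (length(d) > 1 && min(stats::dist(d)) < 0.01 * period) return(FALSE)
  ok(period, 0.10, 0.80) && ok(period / 2, 0.05, 0.65) &&
    ok(period / 3, 0.05, 0.65) && ok(period / 4, 0.04, 0.65) &&
    ok(period / 5, 0.04, 0.65)
}

#' Draw random aperiodic motif offsets
#'
#' Samples \code{n} distinct integer offsets uniformly in [0, period)
#' and redraws (advancing the seed) until
#' \code{\link{is_aperiodic_motif}} accepts them.
#'
#' @param n number of motif sites.
#' @param period repeat distance.
#' @param seed RNG seed (required for reproducibility; the caller's RNG
#'   state is preserved).
#' @param max_tries redraw budget.
#' @return sorted integer offsets.
#' @export
draw_motif_offsets <- function(n, period, seed, max_tries = 100000) {
  for (k in seq_len(max_tries)) {
    off <- with_seed(derive_seed(seed, k),
                     sort(sample.int(period, n) - 1))
    if (is_aperiodic_motif(off, period)) return(off)
  }
  stop_param("could not draw an aperiodic motif in %d tries", max_tries)
}

#' Add uniform positional jitter to sites
#'
#' Displaces each site by an independent uniform draw. The amplitude
#' \code{A} is the full width of the uniform law: displacements lie in
#' \code{[-A/2, +A/2]} (so "10\% of the period" means a window of width
#' 0.1 P centered on each site). \code{half_width = TRUE} reads \code{A}
#' as the half width instead, i.e. displacements in \code{[-A, +A]}.
#' Jittered positions are rounded to the integer lattice and clipped to
#' the support; collisions, if any, are deduplicated with a warning by
#' the \code{\link{site_sequence}} constructor.
#'
#' @param sites a \code{\link{site_sequence}}.
#' @param amplitude jitter amplitude A >= 0, in positions.
#' @param seed RNG seed.
#' @param half_width interpret A as half width (default \code{FALSE}).
#' @return a jittered \code{\link{site_sequence}} (labels preserved
#'   unless collisions removed sites).
#' @export
add_jitter <- function(sites, amplitude, seed = NULL, half_width = FALSE) {
  stopifnot(inherits(sites, "site_sequence"))
  amplitude <- check_scalar(amplitude, "amplitude")
  if (amplitude < 0) stop_param("amplitude must be >= 0")
  if (amplitude == 0) return(sites)
  half <- if (half_width) amplitude else amplitude / 2
  N <- length(sites$positions)
  pos <- with_seed(seed,
                   sites$positions + round(stats::runif(N, -half, half)))
  pos <- pmin(pmax(pos, 0), sites$L - 1)
  site_sequence(pos, L = sites$L, labels = sites$labels)
}

#' Contaminate a site sequence
#'
#' Deletes \code{n_delete} sites chosen uniformly without replacement
#' (false negatives) and adds \code{n_add} sites at uniform random
#' positions on the support (false positives; positions colliding with
#' an existing site are resampled).
#'
#' @param sites a \code{\link{site_sequence}}.
#' @param n_delete number of sites to remove (<= N).
#' @param n_add number of random sites to add.
#' @param seed RNG seed.
#' @return a \code{\link{site_sequence}}; added sites carry the label
#'   \code{"added"} when the input is labeled.
#' @export
contaminate <- function(sites, n_delete = 0, n_add = 0, seed = NULL) {
  stopifnot(inherits(sites, "site_sequence"))
  N <- length(sites$positions)
  if (n_delete > N) stop_param("cannot delete %g of %d sites", n_delete, N)
  with_seed(seed, {
    keep <- if (n_delete > 0) sort(sample.int(N, N - n_delete)) else seq_len(N)
    pos <- sites$positions[keep]
    lab <- if (!is.null(sites$labels)) sites$labels[keep]
    if (n_add > 0) {
      new <- integer(0)
      while (length(new) < n_add) {
        cand <- sample.int(sites$L, n_add - length(new)) - 1
        new <- c(new, setdiff(cand, c(pos, new)))
      }
      pos <- c(pos, new)
      if (!is.null(lab)) lab <- c(lab, rep("added", n_add))
    }
    site_sequence(pos, L = sites$L, labels = lab)
  })
}

#' Superpose two site sequences
#'
#' The sorted union of two trains on the same support, with labels
#' recording the train of origin so downstream classification (e.g.
#' \code{\link{two_period_scatter}}) can be checked against the truth.
#'
#' @param a,b \code{\link{site_sequence}} objects with equal \code{L}.
#' @param labels length-2 labels for the two trains.
#' @return a labeled \code{\link{site_sequence}}; positions present in
#'   both trains are kept once (with \code{a}'s label, and a warning).
#' @export
mixture <- function(a, b, labels = c("train1", "train2")) {
  stopifnot(inherits(a, "site_sequence"), inherits(b, "site_sequence"))
  if (a$L != b$L) stop_param("mixture requires equal support lengths")
  site_sequence(c(a$positions, b$positions), L = a$L,
                labels = c(rep(labels[1], length(a$positions)),
                           rep(labels[2], length(b$positions))))
}
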