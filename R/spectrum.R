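#' Default period grid for a support
#'
#' Integer periods from \code{pmin} to \code{pmax} (default
#' \code{min(L/2, 40000)}) with a step keeping the grid at roughly 4000
#' points.
#'
#' @param L support length.
#' @param pmin,pmax grid limits in positions.
#' @param step grid step; default \code{max(1, (pmax - pmin) / 4000)},
#'   rounded to an integer.
#' @return numeric vector of candidate periods.
#' @export
period_grid <- function(L, pmin = 10, pmax = min(L / 2, 40000), step = NULL) {
  if (pmax <= pmin) stop_param("pmax must exceed pmin")
  if (is.null(step)) step <- max(1, round((pmax - pmin) / 4000))
  seq(pmin, pmax, by = step)
}

#' Raw solenoidal spectrum over a period grid
#'
#' Evaluates \code{\link{scs_score}} at every candidate period.
#' Deterministic given the sites.
#'
#' @inheritParams scs_score
#' @param periods vector of candidate periods, each in (1, L].
#' @return numeric vector of scores, one per period.
#' @export
compute_sos <- function(sites, periods, J = NULL, eps = 1e-300,
                        resolution = NULL) {
  if (length(periods) == 0L) stop_param("empty period grid")
  vapply(periods, function(P) scs_score(sites, P, J, eps, resolution),
         numeric(1))
}

#' Monte-Carlo null ensemble of spectrum scores
#'
#' Draws \code{R} uniform-random site configurations and scores each with
#' the same machinery as the observed spectrum. Because uniform angles
#' modulo any period are uniform on the circle, the null distribution does
#' not depend on the period: one ensemble per (N, J) pair calibrates the
#' whole period grid. The default therefore samples N angles directly on
#' the continuous unit circle. \code{method = "discrete"} instead draws
#' integer positions on \code{\{0, ..., L-1\}} and projects them modulo
#' \code{period}, for exactness studies on short supports.
#'
#' @param N number of sites of the observed sequence.
#' @param J neighbor depth used for the observed spectrum.
#' @param R number of replicates (>= 100 recommended; the p-value
#'   resolution is 1 / (R + 1)).
#' @param seed optional RNG seed; the caller's RNG state is preserved.
#' @param method \code{"circle"} (continuous, period-free, default) or
#'   \code{"discrete"} (integer lattice; requires \code{period} and
#'   \code{L}).
#' @param period,L required for \code{method = "discrete"}.
#' @param eps p-value floor.
#' @return an object of class \code{"scm_null"}: list with \code{scores}
#'   (length R), \code{N}, \code{J}, \code{R}, \code{seed}, \code{method}.
#' @export
null_ensemble <- function(N, J = NULL, R = 1000, seed = NULL,
                          method = c("circle", "discrete"),
                          period = NULL, L = NULL, eps = 1e-300) {
  method <- match.arg(method)
  N <- check_scalar(N, "N")
  if (N < 3) stop_param("null ensemble needs N >= 3")
  if (is.null(J)) J <- default_J(N)
  if (2 * J - 1 > N - 2) stop_param("invalid J = %g for N = %g", J, N)
  if (R < 100) warning("R < 100 gives poor p-value resolution (1 / (R + 1))")
  draw <- if (method == "circle") {
    function() sort(stats::runif(N))
  } else {
    if (is.null(period) || is.null(L))
      stop_param("method = \"discrete\" requires `period` and `L`")
    function() sort((sample.int(L, N, replace = TRUE) - 1) %% period) / period
  }
  scores <- with_seed(seed, vapply(seq_len(R), function(r)
    fold_scores(draw(), J, eps)[["score"]], numeric(1)))
  structure(list(scores = scores, N = as.integer(N), J = as.integer(J),
                 R = as.integer(R), seed = seed, method = method),
            class = "scm_null")
}

#' @export
print.scm_null <- function(x, ...) {
  cat(sprintf("SCM null ensemble: R = %d replicates, N = %d, J = %d (%s sampling)\n",
              x$R, x$N, x$J, x$method))
  cat(sprintf("  score mean %.4f, sd %.4f, max %.4f\n",
              mean(x$scores), stats::sd(x$scores), max(x$scores)))
  invisible(x)
}

#' Null-calibrated p-values for spectrum scores
#'
#' The p-value of an observed score is the probability of an equal or
#' higher score under the uniform-random null, estimated with the add-one
#' rule \code{(1 + #\{null >= observed\}) / (R + 1)}, which is never zero
#' and never below \code{1 / (R + 1)}.
#'
#' @param scores observed score vector (from \code{\link{compute_sos}}).
#' @param null a \code{\link{null_ensemble}} built with the same N and J
#'   as the observed sequence.
#' @param N,J if supplied, checked against the null ensemble metadata; a
#'   mismatch is an error since the score distribution depends on both.
#' @return p-values in (0, 1], one per score.
#' @export
compute_psos <- function(scores, null, N = NULL, J = NULL) {
  stopifnot(inherits(null, "scm_null"))
  if (!is.null(N) && N != null$N)
    stop_param("null ensemble was built for N = %d, observed N = %g", null$N, N)
  if (!is.null(J) && J != null$J)
    stop_param("null ensemble was built for J = %d, observed J = %g", null$J, J)
  sorted <- sort(null$scores)
  n_ge <- null$R - findInterval(scores, sorted, left.open = TRUE)
  (1 + n_ge) / (null$R + 1)
}

#' Family-wise significance of the best spectrum peak
#'
#' Treating the spectrum as \code{n_peaks} independent peaks, the
#' probability that at least one of them reaches a p-value as low as
#' \code{p_star} by chance is \eqn{1 - (1 - p^*)^{N_p}}.
#'
#' @param p_star best per-peak p-value, in [0, 1].
#' @param n_peaks number of independent peaks \eqn{N_p \ge 1}.
#' @return the corrected probability.
#' @examples
#' family_correction(0.01, 10)
#' @export
family_correction <- function(p_star, n_peaks) {
  if (any(p_star < 0 | p_star > 1)) stop_param("p_star must lie in [0, 1]")
  n_peaks <- check_scalar(n_peaks, "n_peaks")
  if (n_peaks < 1) stop_param("n_peaks must be >= 1")
  1 - (1 - p_star)^n_peaks
}

#' Compute a p-valued solenoidal spectrum
#'
#' The main entry point of the package: sweeps the candidate periods,
#' scores each with \code{\link{scs_score}}, and calibrates the scores
#' against a uniform-random Monte-Carlo null to obtain per-period
#' p-values (the pSoS) and their \eqn{-\log_{10}} values. Peaks of the
#' pSoS reveal planted periodicities; see \code{\link{find_peaks}},
#' \code{\link{dominant_period}} and \code{\link{fundamental_periods}}
#' for the post-processing.
#'
#' Alongside the score of the defining formula, a lattice-corrected score
#' (\code{\link{scs_score}} with \code{resolution}) is stored; it is used
#' to rank saturated peaks, where exact integer coincidences otherwise
#' make a fundamental and its divisors indistinguishable.
#'
#' @param sites a \code{\link{site_sequence}} with at least 3 sites.
#' @param periods candidate period grid; defaults to
#'   \code{\link{period_grid}} on the support.
#' @param J neighbor depth; default \code{\link{default_J}}.
#' @param null optional precomputed \code{\link{null_ensemble}} (must
#'   match N and J); useful when scoring many sequences of the same size.
#' @param null_reps Monte-Carlo replicates for the null when \code{null}
#'   is not supplied.
#' @param seed RNG seed for the null ensemble.
#' @param resolution position lattice spacing for the secondary score
#'   (default 1; \code{NULL} disables the correction and copies the plain
#'   score).
#' @param eps p-value floor.
#' @return an object of class \code{"solenoid_spectrum"}: a list with
#'   \code{periods}, \code{score}, \code{lattice_score}, \code{pvalue},
#'   \code{neglog10p}, the \code{null} ensemble and metadata. Supports
#'   \code{print}, \code{summary}, \code{plot} and \code{as.data.frame}.
#' @examples
#' train <- motif_train(c(316, 1409, 2277, 3235, 7598), 10000, 8)
#' sp <- solenoid_spectrum(train, seq(2000, 40000, 50), null_reps = 200,
#'                         seed = 1)
#' dominant_period(sp)
#' @export
solenoid_spectrum <- function(sites, periods = NULL, J = NULL, null = NULL,
                              null_reps = 1000, seed = NULL,
                              resolution = 1, eps = 1e-300) {
  stopifnot(inherits(sites, "site_sequence"))
  N <- n_sites(sites)
  if (N < 3) stop_param("spectrum needs at least 3 sites")
  if (is.null(J)) J <- default_J(N)
  if (is.null(periods)) periods <- period_grid(sites$L)
  if (length(periods) == 0L) stop_param("empty period grid")
  if (any(periods <= 1 | periods > sites$L))
    stop_param("all periods must lie in (1, L]")

  both <- vapply(periods, function(P) {
    theta <- sort((sites$positions %% P) / P)
    floor_x <- if (is.null(resolution)) 0 else resolution / (2 * P)
    fold_scores(theta, J, eps, floor_x)
  }, c(score = 0, lattice_score = 0))

  if (is.null(null)) {
    null <- null_ensemble(N, J, R = null_reps, seed = seed, eps = eps)
  } else {
    stopifnot(inherits(null, "scm_null"))
    if (null$N != N || null$J != J)
      stop_param("supplied null ensemble (N = %d, J = %d) does not match the sequence (N = %d, J = %g)",
                 null$N, null$J, N, J)
  }
  pvalue <- compute_psos(both["score", ], null, N = N, J = J)

  structure(list(periods = as.numeric(periods),
                 score = unname(both["score", ]),
                 lattice_score = unname(both["lattice_score", ]),
                 pvalue = pvalue,
                 neglog10p = -log10(pvalue),
                 null = null,
                 N = N, J = J, L = sites$L,
                 resolution = resolution, eps = eps),
            class = "solenoid_spectrum")
}

#' @export
as.data.frame.solenoid_spectrum <- function(x, ...) {
  data.frame(period = x$periods, score = x$score,
             lattice_score = x$lattice_score,
             pvalue = x$pvalue, neglog10p = x$neglog10p)
}

#' @export
print.solenoid_spectrum <- function(x, ...) {
  cat(sprintf("Solenoidal spectrum: %d periods in [%g, %g], N = %d sites, J = %d\n",
              length(x$periods), min(x$periods), max(x$periods), x$N, x$J))
  cat(sprintf("  null: R = %d replicates; p-value floor %.2g\n",
              x$null$R, 1 / (x$null$R + 1)))
  cat(sprintf("  dominant period: %g (score %.3f, -log10 p = %.2f)\n",
              dominant_period(x),
              x$score[which.max(x$score)],
              x$neglog10p[which.max(x$score)]))
  invisible(x)
}

#' @export
summary.solenoid_spectrum <- function(object, min_neglog10p = 2, ...) {
  pk <- find_peaks(object, min_neglog10p = min_neglog10p)
  cat(sprintf("Solenoidal spectrum of %d sites (J = %d), %d periods\n",
              object$N, object$J, length(object$periods)))
  cat(sprintf("Peaks with -log10 p >= %g: %d, in %d harmonic group(s)\n",
              min_neglog10p, nrow(pk),
              if (nrow(pk)) max(pk$group) else 0L))
  if (nrow(pk)) {
    cat("Fundamental periods by group significance:\n")
    fp <- fundamental_periods(pk)
    for (k in seq_along(fp)) cat(sprintf("  %d: %g\n", k, fp[k]))
  }
  invisible(pk)
}

#' Period at the global spectrum maximum
#'
#' Returns the candidate period with the highest raw score. Exact score
#' ties occur for degenerate inputs (a noise-free comb projects to a
#' single point at its spacing and at every divisor of it, producing
#' bitwise-equal capped scores); among exactly tied periods the largest
#' is returned, which is the generator of such a tie set.
#'
#' @param spectrum a \code{\link{solenoid_spectrum}}.
#' @return the dominant period (positions).
#' @export
dominant_period <- function(spectrum) {
  stopifnot(inherits(spectrum, "solenoid_spectrum"))
  m <- max(spectrum$score)
  max(spectrum$periods[spectrum$score == m])
}

#' Detect and group spectrum peaks into harmonic families
#'
#' Peaks are strict local maxima of the raw score whose \eqn{-\log_{10}}
#' p-value reaches \code{min_neglog10p}. A genuinely periodic pattern
#' produces a peak at its period P and harmonics at integer multiples
#' k\,P, so peaks are grouped: processing peaks in decreasing
#' significance (\code{neglog10p}, ties broken by the lattice-corrected
#' score), a peak at period Q joins the group with fundamental P when
#' \eqn{|Q/(kP) - 1| \le tol} for some integer \eqn{k \ge 1}, otherwise
#' it starts a new group. The fundamental of a group is its most
#' significant member at harmonic order one (jitter can split a peak
#' into near-duplicate local maxima within \code{tol}; all of them count
#' as order one). Group significance is the maximum (\code{neglog10p},
#' \code{lattice_score}) over members; the lattice-corrected score
#' separates saturated groups, demoting the exact divisor foldings that
#' integer-lattice patterns produce alongside the true period.
#'
#' One degenerate case is handled first: when all sites project onto a
#' single point (a noise-free comb at its spacing), the capped score
#' takes its maximal attainable value, bitwise identically at the
#' spacing and at every grid divisor of it. Those completely aligned
#' peaks form one group whose fundamental is the LARGEST member -- the
#' generator of the tie set, since each smaller member is an exact
#' refolding of it -- and that group outranks all others (complete
#' alignment cannot be beaten).
#'
#' @param spectrum a \code{\link{solenoid_spectrum}}.
#' @param min_neglog10p significance threshold (default 2, i.e.
#'   p <= 0.01).
#' @param tol relative tolerance for harmonic matching (default 0.02).
#' @return an object of class \code{"scm_peaks"}: a data frame with one
#'   row per peak (\code{period}, \code{score}, \code{lattice_score},
#'   \code{neglog10p}, \code{group}, \code{fundamental},
#'   \code{is_fundamental}), ordered by decreasing significance; groups
#'   are numbered by decreasing group significance. May have zero rows.
#' @export
find_peaks <- function(spectrum, min_neglog10p = 2, tol = 0.02) {
  stopifnot(inherits(spectrum, "solenoid_spectrum"))
  s <- spectrum$score
  n <- length(s)
  if (n < 2) stop_param("need at least 2 grid periods to detect peaks")
  left <- c(-Inf, s[-n]); right <- c(s[-1], -Inf)
  is_max <- s > left & s > right
  keep <- is_max & spectrum$neglog10p >= min_neglog10p
  empty <- data.frame(period = numeric(0), score = numeric(0),
                      lattice_score = numeric(0), neglog10p = numeric(0),
                      group = integer(0), fundamental = numeric(0),
                      is_fundamental = logical(0))
  if (!any(keep)) return(structure(empty, class = c("scm_peaks", "data.frame")))

  pk <- data.frame(period = spectrum$periods[keep], score = s[keep],
                   lattice_score = spectrum$lattice_score[keep],
                   neglog10p = spectrum$neglog10p[keep])
  pk <- pk[order(-pk$neglog10p, -pk$lattice_score, pk$period), , drop = FALSE]

  # completely aligned foldings (all sites on one point) reach the maximal
  # capped score bitwise-identically; they are one family generated by the
  # largest tied period
  smax <- -log(spectrum$eps %||% 1e-300) / 2
  degen <- pk$score >= smax * (1 - 1e-12)
  fundamentals <- numeric(0)
  group <- integer(nrow(pk))
  if (any(degen)) {
    fundamentals <- max(pk$period[degen])
    group[degen] <- 1L
  }
  for (r in which(group == 0L)) {
    q <- pk$period[r]
    assigned <- 0L
    for (g in seq_along(fundamentals)) {
      k <- round(q / fundamentals[g])
      if (k >= 1 && abs(q / (k * fundamentals[g]) - 1) <= tol) {
        assigned <- g
        if (k == 1 && q < fundamentals[g] &&
            !(g == 1L && any(degen))) fundamentals[g] <- q
        break
      }
    }
    if (assigned == 0L) {
      fundamentals <- c(fundamentals, q)
      assigned <- length(fundamentals)
    }
    group[r] <- assigned
  }
  # within each ordinary group the fundamental is the strongest member at
  # harmonic order one: under jitter a peak can split into near-duplicate
  # local maxima within tol, and the smallest of those would bias the
  # fundamental downward
  if (length(fundamentals) > (if (any(degen)) 1L else 0L)) {
    for (g in setdiff(seq_along(fundamentals), if (any(degen)) 1L)) {
      m <- which(group == g)
      k1 <- m[abs(pk$period[m] / fundamentals[g] - 1) <= tol]
      best <- k1[order(-pk$neglog10p[k1], -pk$lattice_score[k1])][1L]
      fundamentals[g] <- pk$period[best]
    }
  }
  # groups ranked by best member: degenerate family first, then
  # significance with the lattice-corrected tie-break
  info <- data.frame(g = seq_along(fundamentals))
  info$degen <- info$g == 1L & any(degen)
  info$nlp <- vapply(info$g, function(g) max(pk$neglog10p[group == g]), 0)
  info$lat <- vapply(info$g, function(g) max(pk$lattice_score[group == g]), 0)
  rank <- info$g[order(-info$degen, -info$nlp, -info$lat)]
  remap <- match(seq_along(fundamentals), rank)
  group <- remap[group]
  fundamentals <- fundamentals[rank]

  pk$group <- group
  pk$fundamental <- fundamentals[group]
  pk$is_fundamental <- abs(pk$period - pk$fundamental) < 1e-9
  pk <- pk[order(pk$group, -pk$neglog10p, -pk$lattice_score), , drop = FALSE]
  rownames(pk) <- NULL
  structure(pk, class = c("scm_peaks", "data.frame"))
}

#' @export
print.scm_peaks <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("No spectrum peaks above threshold\n")
    return(invisible(x))
  }
  cat(sprintf("%d spectrum peak(s) in %d harmonic group(s)\n",
              nrow(x), max(x$group)))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Fundamental periods of the harmonic groups, most significant first
#'
#' @param x a \code{\link{solenoid_spectrum}} or a
#'   \code{\link{find_peaks}} result.
#' @param n maximum number of fundamentals to return.
#' @param ... passed on to \code{\link{find_peaks}} when \code{x} is a
#'   spectrum.
#' @return numeric vector of fundamental periods, ordered by decreasing
#'   group significance.
#' @export
fundamental_periods <- function(x, n = Inf, ...) {
  pk <- if (inherits(x, "solenoid_spectrum")) find_peaks(x, ...) else x
  stopifnot(inherits(pk, "scm_peaks"))
  if (nrow(pk) == 0L) return(numeric(0))
  fp <- pk$fundamental[!duplicated(pk$group)]  # rows already sorted
  utils::head(fp, n)
}

#' Plot a solenoidal spectrum
#'
#' Two stacked panels: the raw score and the p-valued spectrum
#' (\eqn{-\log_{10} p}) against the candidate period.
#'
#' @param x a \code{\link{solenoid_spectrum}}.
#' @param ... further graphical parameters passed to
#'   \code{\link[graphics]{plot}}.
#' @export
plot.solenoid_spectrum <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$periods, x$score, type = "l", xlab = "period (positions)",
                 ylab = expression(S[scs]), ...)
  graphics::plot(x$periods, x$neglog10p, type = "l",
                 xlab = "period (positions)",
                 ylab = expression(-log[10] ~ p), ...)
  graphics::abline(h = -log10(0.05), lty = 2, col = "grey")
  invisible(x)
}
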