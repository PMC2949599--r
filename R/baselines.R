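# Comparison methods: pair-distance histogram and smoothed autocorrelation,
# each read through a discrete Fourier transform.

#' Histogram of pairwise site distances
#'
#' Counts the \eqn{N(N-1)/2} unordered pairwise distances in bins of the
#' given width. The classic first step for periodicity detection in
#' sparse boolean sequences: a P-periodic pattern enriches distances near
#' multiples of P.
#'
#' @param sites a \code{\link{site_sequence}} with at least 2 sites.
#' @param bin bin width in positions (default 50).
#' @return an object of class \code{"pair_histogram"}: list with
#'   \code{bin}, integer \code{counts} (bin k covers distances in
#'   \code{[(k-1) * bin, k * bin)}) and \code{mids}.
#' @export
pair_distance_histogram <- function(sites, bin = 50) {
  stopifnot(inherits(sites, "site_sequence"))
  if (n_sites(sites) < 2) stop_param("need at least 2 sites")
  bin <- check_scalar(bin, "bin")
  if (bin < 1) stop_param("bin width must be >= 1")
  d <- as.vector(stats::dist(sites$positions))
  nb <- floor(max(d) / bin) + 1L
  counts <- tabulate(floor(d / bin) + 1L, nbins = nb)
  structure(list(bin = bin, counts = counts,
                 mids = (seq_len(nb) - 0.5) * bin),
            class = "pair_histogram")
}

#' @export
print.pair_histogram <- function(x, ...) {
  cat(sprintf("Pair-distance histogram: %d bins of width %g, %d pairs\n",
              length(x$counts), x$bin, sum(x$counts)))
  invisible(x)
}

# Magnitude spectrum of a regularly sampled curve, reported on a period
# axis. Mean-subtracted, zero-padded for peak readability; padding does
# not move peak locations materially.
period_dft <- function(values, spacing, zero_pad = 4) {
  y <- values - mean(values)
  n <- stats::nextn(zero_pad * length(y), 2)
  mag <- Mod(stats::fft(c(y, numeric(n - length(y)))))
  k <- seq_len(n %/% 2)           # positive frequencies only
  data.frame(period = (n * spacing) / k, magnitude = mag[k + 1L])
}

#' Fourier spectrum of a pair-distance histogram
#'
#' @param hist a \code{\link{pair_distance_histogram}}.
#' @param zero_pad zero-padding factor before the transform.
#' @param min_period drop periods below this value (the period axis
#'   diverges at low frequency index; default twice the bin width).
#' @return data frame with columns \code{period} (positions, decreasing
#'   resolution toward long periods) and \code{magnitude}.
#' @seealso \code{\link{spectral_peak}}
#' @export
dft_of_histogram <- function(hist, zero_pad = 4, min_period = NULL) {
  stopifnot(inherits(hist, "pair_histogram"))
  if (is.null(min_period)) min_period <- 2 * hist$bin
  out <- period_dft(hist$counts, hist$bin, zero_pad)
  out[out$period >= min_period, , drop = FALSE]
}

#' Period of the largest Fourier magnitude
#'
#' @param dft a data frame with \code{period} and \code{magnitude}
#'   columns (\code{\link{dft_of_histogram}} or
#'   \code{\link{dft_of_autocorrelation}} output).
#' @param max_period optional upper bound on the period considered.
#' @return the period of the maximum magnitude.
#' @export
spectral_peak <- function(dft, max_period = Inf) {
  keep <- dft$period <= max_period
  if (!any(keep)) stop_param("no spectrum point below max_period")
  dft$period[keep][which.max(dft$magnitude[keep])]
}

#' Harmonic-series fundamental of a Fourier magnitude spectrum
#'
#' A periodic point pattern gives a Fourier spectrum whose peaks sit at
#' the fundamental period and its integer submultiples (the frequency
#' harmonics), with comparable magnitudes, so the raw magnitude argmax is
#' an unstable reader of the period. This helper formalizes the usual
#' visual reading: the largest period, within the stated range, whose
#' magnitude reaches a fraction of the range maximum.
#'
#' @inheritParams spectral_peak
#' @param frac magnitude threshold as a fraction of the in-range maximum.
#' @param min_period,max_period period range considered.
#' @return the fundamental period estimate.
#' @export
spectral_fundamental <- function(dft, frac = 0.5, min_period = -Inf,
                                 max_period = Inf) {
  keep <- which(dft$period >= min_period & dft$period <= max_period)
  if (length(keep) == 0L) stop_param("no spectrum point in the period range")
  per <- dft$period[keep]; mag <- dft$magnitude[keep]
  o <- order(per)
  per <- per[o]; mag <- mag[o]
  above <- mag >= frac * max(mag)
  # contiguous runs above threshold; the longest-period run is one peak
  # (including its shoulders): report the magnitude maximum inside it
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  top <- max(which(runs$values))
  idx <- starts[top]:ends[top]
  per[idx][which.max(mag[idx])]
}

#' Smooth a sparse boolean sequence
#'
#' Expands each site into a pulse so that the product terms of an
#' autocorrelation are not almost always zero. The square kernel marks
#' every position within \code{window / 2} of a site with 1; the
#' Gaussian kernel superposes bumps with standard deviation
#' \code{window / 4}.
#'
#' @param sites a \code{\link{site_sequence}}.
#' @param window kernel width in positions (default 1000).
#' @param kernel \code{"square"} (default) or \code{"gaussian"}.
#' @return numeric vector of length L: the smoothed sequence on
#'   positions 0, ..., L-1.
#' @export
smooth_boolean <- function(sites, window = 1000, kernel = c("square", "gaussian")) {
  stopifnot(inherits(sites, "site_sequence"))
  kernel <- match.arg(kernel)
  window <- check_scalar(window, "window")
  if (window < 1) stop_param("window must be >= 1")
  L <- sites$L
  x <- numeric(L)
  if (kernel == "square") {
    half <- floor(window / 2)
    for (s in sites$positions) {
      lo <- max(0, s - half); hi <- min(L - 1, s + half)
      x[(lo:hi) + 1] <- 1
    }
  } else {
    sd <- window / 4
    span <- ceiling(4 * sd)
    for (s in sites$positions) {
      lo <- max(0, s - span); hi <- min(L - 1, s + span)
      l <- lo:hi
      x[l + 1] <- x[l + 1] + exp(-((l - s)^2) / (2 * sd^2))
    }
  }
  x
}

#' Finite-length normalized autocorrelation
#'
#' \deqn{C(x) = \frac{\mathcal{N}}{L - x} \sum_{i=0}^{L-1-x}
#'   \tilde{X}(i)\,\tilde{X}(i + x),}
#' with the normalization constant chosen so that \eqn{C(0) = 1}.
#' Computed by FFT cross-correlation, so long supports are cheap.
#'
#' @param x numeric vector: the (smoothed) sequence on positions
#'   0, ..., L-1 (see \code{\link{smooth_boolean}}).
#' @param max_lag largest lag computed; must be < length(x).
#' @return an object of class \code{"autocorrelation_curve"}: list with
#'   \code{lags} (0..max_lag) and \code{values} (C, with C(0) = 1).
#' @export
autocorrelation <- function(x, max_lag) {
  if (!is.numeric(x) || length(x) < 2) stop_param("x must be a numeric sequence")
  max_lag <- check_scalar(max_lag, "max_lag")
  L <- length(x)
  if (max_lag >= L) stop_param("max_lag must be smaller than the sequence length")
  if (all(x == 0))
    stop_param("all-zero sequence: autocorrelation normalization undefined")
  n <- stats::nextn(2 * L, 2)
  f <- stats::fft(c(x, numeric(n - L)))
  raw <- Re(stats::fft(f * Conj(f), inverse = TRUE))[1:(max_lag + 1)] / n
  lags <- 0:max_lag
  values <- raw / (L - lags)          # per-overlap average
  values <- values / values[1]        # C(0) = 1
  structure(list(lags = lags, values = values),
            class = "autocorrelation_curve")
}

#' @export
print.autocorrelation_curve <- function(x, ...) {
  cat(sprintf("Autocorrelation curve: lags 0..%d, C(0) = %g\n",
              max(x$lags), x$values[1]))
  invisible(x)
}

#' Fourier spectrum of an autocorrelation curve
#'
#' @param ac an \code{\link{autocorrelation_curve}}.
#' @param zero_pad zero-padding factor.
#' @param min_period drop the diverging low-frequency end of the period
#'   axis (default 2 lags).
#' @return data frame with \code{period} and \code{magnitude} columns.
#' @export
dft_of_autocorrelation <- function(ac, zero_pad = 4, min_period = 2) {
  stopifnot(inherits(ac, "autocorrelation_curve"))
  out <- period_dft(ac$values, spacing = 1, zero_pad = zero_pad)
  out[out$period >= min_period, , drop = FALSE]
}
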