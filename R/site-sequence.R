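#' Create a site sequence
#'
#' A site sequence is the sparse representation of a boolean signal
#' \eqn{X(l)} on a linear support of length \eqn{L}: it stores the sorted
#' integer positions of the 1's (the "sites", e.g. transcription starts of
#' genes along a chromosome). All periodicity machinery in this package
#' operates on this container.
#'
#' Positions are 0-based, in \eqn{[0, L)}. Duplicated positions are removed
#' with a warning; the positions are sorted on construction.
#'
#' @param positions integer vector of site positions (0-based).
#' @param L support length in positions. Defaults to \code{max(positions)+1},
#'   with a warning, since the true support usually extends past the last
#'   site.
#' @param labels optional vector (same length as \code{positions}, before
#'   deduplication) tagging each site, e.g. with the generating train in a
#'   mixture. Retained through sorting.
#' @return an object of class \code{"site_sequence"} with elements
#'   \code{positions} (sorted integer vector) and \code{L}.
#' @examples
#' site_sequence(c(0, 10000, 20000), L = 50000)
#' @export
site_sequence <- function(positions, L = NULL, labels = NULL) {
  if (length(positions) == 0L)
    stop_param("a site sequence needs at least one position")
  if (!is.numeric(positions) || any(!is.finite(positions)))
    stop_param("`positions` must be finite numbers")
  if (any(positions != floor(positions)))
    stop_param("`positions` must be integers (whole numbers)")
  positions <- as.numeric(positions)
  if (any(positions < 0))
    stop_param("`positions` must be >= 0")
  if (!is.null(labels) && length(labels) != length(positions))
    stop_param("`labels` must have one entry per position")

  o <- order(positions)
  positions <- positions[o]
  if (!is.null(labels)) labels <- labels[o]
  dup <- duplicated(positions)
  if (any(dup)) {
    warning(sprintf("removed %d duplicated position(s)", sum(dup)))
    positions <- positions[!dup]
    if (!is.null(labels)) labels <- labels[!dup]
  }

  if (is.null(L)) {
    L <- max(positions) + 1
    warning("support length L not given; using max(position) + 1")
  }
  L <- check_scalar(L, "L")
  if (L < max(positions) + 1)
    stop_param("L = %g is smaller than max(position) + 1 = %g",
               L, max(positions) + 1)

  structure(list(positions = positions, L = L, labels = labels),
            class = "site_sequence")
}

#' Number of sites in a site sequence
#' @param x a \code{site_sequence}.
#' @return integer count of sites.
#' @export
n_sites <- function(x) {
  stopifnot(inherits(x, "site_sequence"))
  length(x$positions)
}

#' @export
print.site_sequence <- function(x, ...) {
  n <- length(x$positions)
  cat(sprintf("Site sequence: %d site(s) on a support of length %g\n",
              n, x$L))
  shown <- utils::head(x$positions, 8L)
  cat("  positions: ", paste(shown, collapse = ", "),
      if (n > 8L) ", ..." else "", "\n", sep = "")
  if (!is.null(x$labels))
    cat("  labels: ", paste(utils::head(x$labels, 8L), collapse = ", "),
        if (n > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.site_sequence <- function(x, ...) {
  d <- data.frame(position = x$positions)
  if (!is.null(x$labels)) d$label <- x$labels
  d
}
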