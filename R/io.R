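# Readers and writers. Plain position lists are parsed directly; BED and
# GFF3 go through rtracklayer.

#' Read site positions from a file
#'
#' Supported formats:
#' \describe{
#'   \item{positions}{plain text, one integer position per line (0-based);
#'     blank lines and \code{#} comments ignored.}
#'   \item{bed}{BED intervals; the site is the 0-based interval start.}
#'   \item{gff3}{GFF3 records; the site is the strand-aware transcription
#'     start (the \code{start} of + features, the \code{end} of -
#'     features), converted to 0-based. The support length is taken from
#'     the \code{##sequence-region} pragma when present.}
#' }
#' All positions are 0-based internally. Multi-sequence BED/GFF3 inputs
#' are split per sequence name (the modular projection is only meaningful
#' within one support): a named list of site sequences is returned unless
#' \code{seqname} selects one.
#'
#' @param path input file.
#' @param format \code{"positions"}, \code{"bed"}, \code{"gff3"}, or
#'   \code{"auto"} (by file extension, default).
#' @param L support length override; otherwise from format metadata when
#'   available, else \code{max(position) + 1} with a warning.
#' @param seqname for multi-sequence inputs, the sequence to extract.
#' @return a \code{\link{site_sequence}}, or a named list of them.
#' @export
read_sites <- function(path, format = c("auto", "positions", "bed", "gff3"),
                       L = NULL, seqname = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_param("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", gff = "gff3", gff3 = "gff3",
                     "positions")
  }
  switch(format,
         positions = read_positions_file(path, L),
         bed = read_ranges_file(path, "bed", L, seqname),
         gff3 = read_ranges_file(path, "gff3", L, seqname))
}

read_positions_file <- function(path, L) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  vals <- suppressWarnings(as.numeric(lines[keep]))
  if (anyNA(vals))
    stop_param("cannot parse position at line %d of %s",
               keep[which(is.na(vals))[1]], path)
  if (!is.null(L) && any(vals >= L))
    stop_param("position %g at line %d is >= L = %g",
               max(vals), keep[which.max(vals)], L)
  site_sequence(vals, L = L)
}

# ##sequence-region <name> <start> <end> pragmas give the support length.
gff_pragma_lengths <- function(path) {
  hdr <- grep("^##sequence-region", readLines(path), value = TRUE)
  if (length(hdr) == 0L) return(NULL)
  parts <- strsplit(trimws(hdr), "\\s+")
  stats::setNames(vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
                  vapply(parts, function(p) p[2], character(1)))
}

read_ranges_file <- function(path, kind, L, seqname) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop_param("reading %s files requires the rtracklayer package", kind)
  pragma <- if (kind == "gff3") gff_pragma_lengths(path)
  gr <- if (kind == "bed") rtracklayer::import.bed(path)
        else rtracklayer::import.gff3(path)
  if (length(gr) == 0L) stop_param("no records in %s", path)
  seqs <- as.character(GenomicRanges::seqnames(gr))
  if (!is.null(seqname)) {
    if (!seqname %in% seqs) stop_param("sequence %s not present in %s", seqname, path)
    gr <- gr[seqs == seqname]
    seqs <- seqs[seqs == seqname]
  }
  one <- function(g, nm) {
    strand <- as.character(GenomicRanges::strand(g))
    # BED import is 1-based in GRanges; start - 1 restores the 0-based start.
    pos <- ifelse(strand == "-" & kind == "gff3",
                  GenomicRanges::end(g) - 1,
                  GenomicRanges::start(g) - 1)
    Lk <- L
    if (is.null(Lk) && !is.null(pragma) && nm %in% names(pragma))
      Lk <- unname(pragma[nm])
    if (is.null(Lk)) {
      sl <- GenomicRanges::seqinfo(g)
      known <- GenomeInfoDb::seqlengths(sl)[nm]
      if (!is.na(known)) Lk <- unname(known)
    }
    if (!is.null(Lk) && any(pos >= Lk))
      stop_param("position %g is >= L = %g in %s", max(pos), Lk, nm)
    site_sequence(pos, L = Lk)
  }
  names <- unique(seqs)
  if (length(names) == 1L) return(one(gr, names))
  out <- lapply(names, function(nm) one(gr[seqs == nm], nm))
  names(out) <- names
  out
}

#' Write a solenoidal spectrum to TSV
#'
#' Columns \code{period}, \code{score}, \code{pvalue}, \code{neglog10p},
#' one row per grid period in ascending order, at full float precision so
#' that \code{\link{read_spectrum}} round-trips exactly.
#'
#' @param spectrum a \code{\link{solenoid_spectrum}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "solenoid_spectrum"))
  o <- order(spectrum$periods)
  df <- data.frame(period = sprintf("%.17g", spectrum$periods[o]),
                   score = sprintf("%.17g", spectrum$score[o]),
                   pvalue = sprintf("%.17g", spectrum$pvalue[o]),
                   neglog10p = sprintf("%.17g", spectrum$neglog10p[o]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum TSV written by \code{\link{write_spectrum}}
#'
#' @param path input file.
#' @return data frame with numeric columns \code{period}, \code{score},
#'   \code{pvalue}, \code{neglog10p}.
#' @export
read_spectrum <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = "numeric")
}

# Reproducibility manifest written next to CLI outputs.
write_manifest <- function(dir, config) {
  manifest <- list(
    config = config,
    package = as.character(utils::packageVersion("solenoidal")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
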