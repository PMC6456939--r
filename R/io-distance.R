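#' Read positions, inter-read distances and GC tracks
#'
#' The raw input to a distance-based copy-number analysis is the sorted list
#' of first-aligned-base positions of mapped reads on one chromosome. The
#' distance series is the vector of gaps between adjacent positions;
#' artificial right censoring then flags gaps above a threshold \code{T}
#' (unmappable regions, assembly gaps) so they enter the likelihood only as
#' "greater than \code{T}".
#'
#' @name io-distance
#' @keywords internal
NULL

#' Load first-aligned-base read positions for one chromosome
#'
#' Accepts a BAM/SAM alignment file (leftmost mapped position of each read,
#' requires the \pkg{Rsamtools} package) or a two-column tab-separated text
#' file \code{chromosome<TAB>position}. Positions are 1-based; duplicates
#' are retained; unsorted input is sorted.
#'
#' @param source path to a BAM, SAM or TSV file. Files ending in
#'   \code{.bam}/\code{.sam} are treated as alignments, anything else as TSV.
#' @param chromosome chromosome (reference sequence) name to extract.
#' @param min_mapping_quality drop alignment records below this MAPQ
#'   (alignment input only; default 0 keeps everything).
#' @return object of class \code{"read_positions"}: list with
#'   \code{chromosome} and sorted integer vector \code{positions}.
#' @export
load_read_positions <- function(source, chromosome, min_mapping_quality = 0) {
  if (!file.exists(source)) stop("input file not found: ", source)
  ext <- tolower(tools::file_ext(source))
  if (ext %in% c("bam", "sam")) {
    pos <- read_alignment_positions(source, chromosome, min_mapping_quality)
  } else {
    tab <- utils::read.table(source, header = FALSE, sep = "\t",
                             colClasses = c("character", "numeric"),
                             col.names = c("chrom", "pos"))
    pos <- tab$pos[tab$chrom == chromosome]
  }
  if (length(pos) == 0L)
    stop("no reads on chromosome '", chromosome, "' in ", source)
  if (any(pos < 1)) stop("positions must be >= 1 (1-based coordinates)")
  structure(list(chromosome = chromosome, positions = as.numeric(sort(pos))),
            class = "read_positions")
}

# BAM via Rsamtools; SAM converted to a temporary BAM first.
read_alignment_positions <- function(source, chromosome, min_mapping_quality) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading alignment files requires the 'Rsamtools' package; ",
         "use two-column TSV input otherwise")
  ext <- tolower(tools::file_ext(source))
  if (ext == "sam") {
    source <- Rsamtools::asBam(source, tempfile(), overwrite = TRUE,
                               indexDestination = FALSE)
  }
  bam <- Rsamtools::sortBam(source, tempfile())
  Rsamtools::indexBam(bam)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!chromosome %in% names(hdr))
    stop("chromosome '", chromosome, "' not present in alignment header")
  param <- Rsamtools::ScanBamParam(
    what = c("pos", "mapq"),
    which = GenomicRanges::GRanges(chromosome,
                                   IRanges::IRanges(1, hdr[[chromosome]])),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- is.na(res$mapq) | res$mapq >= min_mapping_quality
  res$pos[keep & !is.na(res$pos)]
}

#' Inter-read distances from sorted read positions
#'
#' The distance attached to an adjacent read pair is the difference of their
#' first-aligned-base positions, so reads starting at the same coordinate
#' give distance 0 (allowed by the geometric support). Each distance is
#' anchored at the left read of the pair.
#'
#' @param reads a \code{read_positions} object (or a sorted numeric vector).
#' @return object of class \code{"distance_series"}: data.frame-like list
#'   with \code{anchor_positions}, \code{y}, \code{delta} (all 1: no
#'   censoring yet), \code{x} (NA until \code{\link{attach_gc}}), and
#'   attributes \code{chromosome} and \code{T} (NA until
#'   \code{\link{apply_censoring}}).
#' @export
compute_distances <- function(reads) {
  if (is.numeric(reads)) reads <- structure(
    list(chromosome = NA_character_, positions = sort(reads)),
    class = "read_positions")
  stopifnot(inherits(reads, "read_positions"))
  pos <- reads$positions
  if (length(pos) < 2L) stop("at least 2 reads are required to form a distance")
  n <- length(pos) - 1L
  new_distance_series(anchor_positions = pos[seq_len(n)],
                      y = diff(pos),
                      delta = rep(1L, n),
                      x = rep(NA_real_, n),
                      chromosome = reads$chromosome,
                      T = NA_real_)
}

new_distance_series <- function(anchor_positions, y, delta, x, chromosome, T) {
  structure(list(anchor_positions = anchor_positions,
                 y = as.numeric(y), delta = as.integer(delta),
                 x = as.numeric(x)),
            chromosome = chromosome, T = as.numeric(T),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  T <- attr(x, "T")
  cat(sprintf("Distance series: %d pairs on %s; censoring T = %s (%d censored); GC attached: %s\n",
              length(x$y), attr(x, "chromosome"),
              ifelse(is.na(T), "none", format(T)), sum(x$delta == 0),
              ifelse(all(is.na(x$x)), "no", "yes")))
  invisible(x)
}

#' Artificially right-censor a distance series
#'
#' Distances strictly greater than \code{T} are flagged censored
#' (\code{delta = 0}); a distance equal to \code{T} is observed. The raw
#' values of censored entries are retained for diagnostics, but all
#' likelihood computations use only the flag and \code{T}, with censored
#' mass \eqn{(1-p)^{T+1} = P(Y > T)} -- the convention under which the
#' censored geometric sums exactly to one over \{0..T\} plus the censored
#' state.
#'
#' @param series a \code{distance_series}.
#' @param T censoring constant in bp (>= 1).
#' @return the series with updated \code{delta} and \code{T} recorded.
#' @export
apply_censoring <- function(series, T) {
  stopifnot(inherits(series, "distance_series"))
  if (!is.numeric(T) || length(T) != 1L || T < 1) stop("'T' must be a single value >= 1")
  series$delta <- as.integer(series$y <= T)
  attr(series, "T") <- as.numeric(T)
  series
}

#' Load a fixed-width window GC-content track
#'
#' Expects three tab-separated columns: chromosome, window start (bp) and GC
#' fraction in [0, 1] (missing values as NA or empty). Window width is
#' inferred from consecutive starts and must be constant.
#'
#' @param source path to the track file.
#' @param chromosome optional: restrict to one chromosome.
#' @return object of class \code{"gc_track"}: list with \code{chromosome},
#'   sorted \code{window_start}, \code{window_width} and \code{gc}.
#' @export
load_gc_track <- function(source, chromosome = NULL) {
  if (!file.exists(source)) stop("GC track file not found: ", source)
  tab <- utils::read.table(source, header = FALSE, sep = "\t",
                           colClasses = c("character", "numeric", "numeric"),
                           col.names = c("chrom", "start", "gc"),
                           na.strings = c("NA", ""))
  if (!is.null(chromosome)) tab <- tab[tab$chrom == chromosome, ]
  if (nrow(tab) == 0L) stop("GC track is empty",
                            if (!is.null(chromosome)) paste0(" for chromosome '", chromosome, "'"))
  tab <- tab[order(tab$start), ]
  if (nrow(tab) >= 2L) {
    widths <- unique(diff(tab$start))
    if (length(widths) != 1L)
      stop("inconsistent window widths in GC track: ", paste(widths, collapse = ", "))
    width <- widths
  } else {
    stop("cannot infer window width from a single-window track")
  }
  bad <- !is.na(tab$gc) & (tab$gc < 0 | tab$gc > 1)
  if (any(bad)) stop("GC fractions must lie in [0, 1]")
  structure(list(chromosome = tab$chrom[1], window_start = tab$start,
                 window_width = width, gc = tab$gc),
            class = "gc_track")
}

#' Attach window GC fractions to a distance series
#'
#' Each distance is assigned the GC fraction of the half-open window
#' \code{[start, start + width)} containing its anchor (left-read) position.
#' Distances falling in uncovered windows or windows with missing GC are
#' dropped, with a message reporting the count.
#'
#' @param series a \code{distance_series}.
#' @param track a \code{gc_track}.
#' @return the filtered series with covariate column \code{x} filled in.
#' @export
attach_gc <- function(series, track) {
  stopifnot(inherits(series, "distance_series"), inherits(track, "gc_track"))
  idx <- findInterval(series$anchor_positions, track$window_start)
  x <- rep(NA_real_, length(idx))
  inside <- idx >= 1L &
    series$anchor_positions < track$window_start[pmax(idx, 1L)] + track$window_width
  x[inside] <- track$gc[idx[inside]]
  keep <- !is.na(x)
  if (!any(keep)) stop("no distance falls in a covered GC window")
  dropped <- sum(!keep)
  if (dropped > 0L)
    message(dropped, " distance(s) dropped: anchor outside covered GC windows")
  new_distance_series(series$anchor_positions[keep], series$y[keep],
                      series$delta[keep], x[keep],
                      chromosome = attr(series, "chromosome"), T = attr(series, "T"))
}

#' Write / read a distance series as TSV
#'
#' Plain four-column TSV (\code{anchor}, \code{y}, \code{delta}, \code{x})
#' with header; chromosome and censoring constant stored in '#'-prefixed
#' header lines.
#'
#' @param series a \code{distance_series}.
#' @param path file path.
#' @return \code{read_distances} returns the reconstructed series.
#' @export
write_distances <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# chromosome=%s", attr(series, "chromosome")), con)
  writeLines(sprintf("# T=%s", format(attr(series, "T"), digits = 15)), con)
  utils::write.table(
    data.frame(anchor = series$anchor_positions, y = series$y,
               delta = series$delta, x = series$x),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distances
#' @export
read_distances <- function(path) {
  hdr <- readLines(path, n = 2L)
  chrom <- sub("^# chromosome=", "", hdr[1])
  T <- suppressWarnings(as.numeric(sub("^# T=", "", hdr[2])))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  new_distance_series(tab$anchor, tab$y, tab$delta, tab$x,
                      chromosome = chrom, T = T)
}
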