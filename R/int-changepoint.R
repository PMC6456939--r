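#' Inverse normal transformation and change-point segmentation
#'
#' After a mixture model has been fitted, each uncensored distance is
#' mapped through the fitted mixture CDF and the standard-normal quantile
#' function, z = \eqn{\Phi^{-1}(F(y; x))}. If the model is adequate this is
#' a probability integral transform, so the z-values are approximately
#' standard normal and a Gaussian change-point analysis applies directly;
#' the covariate in the CDF removes the GC-content trend at the same time.
#' Censored distances (no exact value) are given a fixed sentinel z-value
#' larger than any finite z, so they remain visible in plots but are kept
#' out of the test statistics.
#'
#' @name int-changepoint
#' @keywords internal
NULL

#' Inverse normal transformation through the fitted mixture CDF
#'
#' @param series a \code{distance_series} (with covariate \code{x} attached
#'   when \code{params} is covariate-adjusted).
#' @param params \code{\link{glm_mixture_params}} or
#'   \code{\link{mixture_params}} fitted on compatible data.
#' @param sentinel value assigned to censored entries; must exceed every
#'   finite transformed value (default 10).
#' @param rank_based if \code{TRUE}, use a rank-based (Blom) transform of
#'   the uncensored distances instead of the model CDF: an alternative that
#'   enforces normality by construction but forfeits the GC adjustment.
#' @return object of class \code{"z_series"}: list with
#'   \code{anchor_positions}, \code{z}, \code{censored} flag; attributes
#'   \code{chromosome} and \code{sentinel}.
#' @export
int_transform <- function(series, params = NULL, sentinel = 10,
                          rank_based = FALSE) {
  stopifnot(inherits(series, "distance_series"))
  if (is.null(params) && !rank_based)
    stop("the model-based transform requires fitted mixture parameters")
  obs <- series$delta == 1L
  z <- rep(NA_real_, length(series$y))
  if (rank_based) {
    r <- rank(series$y[obs], ties.method = "average")
    m <- sum(obs)
    z[obs] <- stats::qnorm((r - 3 / 8) / (m + 1 / 4))
  } else {
    Fv <- if (inherits(params, "glm_mixture_params")) {
      if (any(is.na(series$x[obs])))
        stop("covariate-adjusted transform requires GC values; run attach_gc() first")
      mixture_cdf_glm(series$y[obs], series$x[obs], params)
    } else {
      mixture_cdf(series$y[obs], params)
    }
    eps <- 1e-12
    z[obs] <- stats::qnorm(pmin(pmax(Fv, eps), 1 - eps))
  }
  if (any(obs) && sentinel <= max(z[obs]))
    stop("sentinel (", sentinel, ") does not exceed the largest finite z (",
         format(max(z[obs])), ")")
  z[!obs] <- sentinel
  structure(list(anchor_positions = series$anchor_positions, z = z,
                 censored = !obs),
            chromosome = attr(series, "chromosome"), sentinel = sentinel,
            class = "z_series")
}

#' @export
print.z_series <- function(x, ...) {
  cat(sprintf("z-series: %d values on %s (%d censored at sentinel %g)\n",
              length(x$z), attr(x, "chromosome"), sum(x$censored),
              attr(x, "sentinel")))
  invisible(x)
}

#' Group z-values into fixed-width genomic bins
#'
#' Bins are half-open windows \code{[start, start + bin_width)} tiling the
#' covered coordinate range; empty bins are dropped with a message.
#' Censored sentinel values stay bin members (they are counted) but are
#' excluded from all downstream test statistics.
#'
#' @param zseries a \code{z_series}.
#' @param bin_width bin width in bp (default 50000).
#' @return object of class \code{"z_bins"}: list with \code{start},
#'   \code{end}, \code{values} (list of finite z per bin),
#'   \code{n_censored} per bin; attribute \code{bin_width}.
#' @export
bin_z <- function(zseries, bin_width = 50000) {
  stopifnot(inherits(zseries, "z_series"), bin_width >= 1)
  pos <- zseries$anchor_positions
  origin <- floor(min(pos) / bin_width) * bin_width
  idx <- floor((pos - origin) / bin_width)
  all_bins <- seq(0L, max(idx))
  occupied <- sort(unique(idx))
  n_empty <- length(all_bins) - length(occupied)
  if (n_empty > 0L) message(n_empty, " empty bin(s) dropped")
  values <- lapply(occupied, function(b)
    zseries$z[idx == b & !zseries$censored])
  n_cens <- vapply(occupied, function(b)
    sum(idx == b & zseries$censored), integer(1))
  structure(list(start = origin + occupied * bin_width,
                 end = origin + (occupied + 1) * bin_width,
                 values = values, n_censored = n_cens),
            bin_width = bin_width, chromosome = attr(zseries, "chromosome"),
            class = "z_bins")
}

#' Bonferroni-style significance level for the recursive combination
#'
#' With \code{m} bins there are \code{m(m-1)/2} potential two-sample
#' comparisons, so the per-test level is \eqn{\alpha_C = 0.05 / (m(m-1)/2)}.
#'
#' @param m number of bins (>= 2).
#' @return the per-comparison significance level.
#' @export
alpha_c <- function(m) {
  if (any(m < 2)) stop("'m' must be at least 2")
  0.05 / (m * (m - 1) / 2)
}

# Pooled-variance two-sample t-test p-value on two numeric vectors.
# Degenerate cases: too few values for a t-statistic -> p = 1 (cannot
# distinguish, blocks are mergeable); zero pooled variance -> p = 1 if
# means equal else p = 0.
pooled_t_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  df <- n1 + n2 - 2L
  if (n1 < 1L || n2 < 1L || df < 1L) return(1)
  m1 <- mean(a); m2 <- mean(b)
  ss <- sum((a - m1)^2) + sum((b - m2)^2)
  if (ss <= 0) return(if (isTRUE(all.equal(m1, m2))) 1 else 0)
  s2 <- ss / df
  tstat <- (m1 - m2) / sqrt(s2 * (1 / n1 + 1 / n2))
  2 * stats::pt(-abs(tstat), df)
}

# Gaussian log-likelihood of all values under blockwise means and a single
# pooled variance: -N/2 * (log(2*pi*sigma2) + 1) with sigma2 = RSS/N.
blocks_loglik <- function(rss, n_total) {
  if (n_total == 0L) return(0)
  sigma2 <- max(rss / n_total, 1e-300)
  -n_total / 2 * (log(2 * pi * sigma2) + 1)
}

#' Recursive-combination change-point segmentation
#'
#' Starts from one block per bin and repeatedly merges adjacent blocks: in
#' each round, every adjacent pair is compared by a pooled-variance
#' two-sample t-test on the blocks' (finite) z-values; among the pairs
#' whose p-value exceeds \code{alpha}, the merge producing the largest
#' overall Gaussian likelihood (blockwise means, one pooled variance) is
#' applied, leftmost pair on ties. The recursion stops when every adjacent
#' pair differs significantly at level \code{alpha}.
#'
#' @param bins a \code{z_bins} object (or a plain list of numeric vectors).
#' @param alpha per-comparison significance level; default
#'   \code{\link{alpha_c}} of the bin count.
#' @return object of class \code{"segmentation"}: data.frame with one row
#'   per block: \code{start_bin}, \code{end_bin} (half-open bin-index
#'   range), \code{start}, \code{end} (bp, when coordinates available),
#'   \code{mean_z}, \code{n_bins}, \code{n_values}; attribute
#'   \code{alpha_c}.
#' @export
recursive_combination <- function(bins, alpha = NULL) {
  if (inherits(bins, "z_bins")) {
    vals <- bins$values
    starts <- bins$start; ends <- bins$end
  } else {
    vals <- lapply(bins, as.numeric)
    starts <- ends <- rep(NA_real_, length(vals))
  }
  m <- length(vals)
  if (m == 0L) stop("no bins to segment")
  if (is.null(alpha)) alpha <- if (m >= 2L) alpha_c(m) else 0.05
  ## blocks as index ranges [from, to] over bins
  from <- seq_len(m); to <- seq_len(m)
  block_vals <- vals
  repeat {
    k <- length(block_vals)
    if (k == 1L) break
    pvals <- vapply(seq_len(k - 1L), function(i)
      pooled_t_p(block_vals[[i]], block_vals[[i + 1L]]), numeric(1))
    cand <- which(pvals > alpha)
    if (length(cand) == 0L) break
    ## evaluate overall likelihood for each candidate merge
    ns <- lengths(block_vals)
    mus <- vapply(block_vals, function(v) if (length(v)) mean(v) else 0, numeric(1))
    rss0 <- vapply(block_vals, function(v)
      if (length(v)) sum((v - mean(v))^2) else 0, numeric(1))
    total_rss <- sum(rss0)
    n_total <- sum(ns)
    best_i <- NA_integer_; best_ll <- -Inf
    for (i in cand) {
      merged <- c(block_vals[[i]], block_vals[[i + 1L]])
      rss_m <- if (length(merged)) sum((merged - mean(merged))^2) else 0
      ll <- blocks_loglik(total_rss - rss0[i] - rss0[i + 1L] + rss_m, n_total)
      if (ll > best_ll + 1e-12) { best_ll <- ll; best_i <- i }  # leftmost tie-break
    }
    i <- best_i
    block_vals[[i]] <- c(block_vals[[i]], block_vals[[i + 1L]])
    block_vals[[i + 1L]] <- NULL
    to[i] <- to[i + 1L]
    from <- from[-(i + 1L)]; to <- to[-(i + 1L)]
  }
  out <- data.frame(
    start_bin = from, end_bin = to + 1L,
    start = starts[from], end = ends[to],
    mean_z = vapply(block_vals, function(v)
      if (length(v)) mean(v) else NA_real_, numeric(1)),
    n_bins = to - from + 1L,
    n_values = lengths(block_vals))
  structure(out, alpha_c = alpha, chromosome = if (inherits(bins, "z_bins"))
    attr(bins, "chromosome") else NA_character_, class = c("segmentation", "data.frame"))
}

#' Quantile-quantile data for checking normality of z-values
#'
#' Randomly samples genomic regions of a given length and pairs the sorted
#' finite z-values in each with standard-normal quantiles, supporting the
#' visual normality check that justifies Gaussian (rather than
#' permutation-based) p-values in the segmentation.
#'
#' @param zseries a \code{z_series}.
#' @param region_length region length in bp (default 100000).
#' @param n_regions number of regions to sample.
#' @param rng_seed optional seed.
#' @return list of data.frames (one per region) with columns
#'   \code{theoretical} and \code{sample}; regions with fewer than 3 finite
#'   z-values are skipped.
#' @export
qq_check <- function(zseries, region_length = 1e5, n_regions = 10,
                     rng_seed = NULL) {
  stopifnot(inherits(zseries, "z_series"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  pos <- zseries$anchor_positions
  lo <- min(pos); hi <- max(pos)
  if (hi - lo < region_length) stop("series shorter than 'region_length'")
  out <- list()
  for (r in seq_len(n_regions)) {
    s <- stats::runif(1, lo, hi - region_length)
    inr <- pos >= s & pos < s + region_length & !zseries$censored
    zz <- sort(zseries$z[inr])
    if (length(zz) < 3L) next
    out[[length(out) + 1L]] <- data.frame(
      theoretical = stats::qnorm(stats::ppoints(length(zz))),
      sample = zz, region_start = s)
  }
  out
}

#' Write a segmentation as a BED-like table
#'
#' Columns: chrom, start, end, mean_z, n_bins (tab-separated, no header).
#'
#' @param seg a \code{segmentation}.
#' @param path output file.
#' @export
write_segments <- function(seg, path) {
  chrom <- attr(seg, "chromosome")
  utils::write.table(
    data.frame(chrom = if (is.null(chrom) || is.na(chrom)) "." else chrom,
               start = seg$start, end = seg$end,
               mean_z = signif(seg$mean_z, 6), n_bins = seg$n_bins),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
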