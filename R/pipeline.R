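#' End-to-end tumor/normal copy-number pipeline
#'
#' Runs the full distance-based workflow on a pair of samples: extract and
#' censor inter-read distances, attach GC fractions, fit the mixture GLM on
#' the normal sample with a free GC slope, refit the tumor sample with the
#' slope frozen at the normal-sample estimate (pseudo-maximum-likelihood:
#' the GC effect is a reference-genome property shared by both samples),
#' transform both samples to z-values, and segment the binned z-values by
#' recursive combination.
#'
#' @param normal,tumor read-position inputs: \code{read_positions} objects
#'   or file paths accepted by \code{\link{load_read_positions}}.
#' @param gc a \code{gc_track} or path to a GC track file.
#' @param chromosome chromosome name (used when inputs are file paths).
#' @param T artificial right-censoring constant in bp (default 5000,
#'   chosen so that only a small percentage of distances is censored).
#' @param g number of mixture components (default 4).
#' @param bin_width z-value bin width for segmentation (default 50000).
#' @param config EM configuration for the normal-sample fit; the tumor fit
#'   reuses it with \code{fixed_beta1} set.
#' @param min_mapping_quality passed to \code{\link{load_read_positions}}.
#' @return list with per-sample sublists (\code{distances}, \code{fit},
#'   \code{z}, \code{bins}, \code{segments}) under \code{$normal} and
#'   \code{$tumor}, plus \code{$beta1} (the shared GC slope).
#' @export
run_pipeline <- function(normal, tumor, gc, chromosome = NULL, T = 5000,
                         g = 4, bin_width = 50000, config = fit_config(),
                         min_mapping_quality = 0) {
  get_reads <- function(src) {
    if (inherits(src, "read_positions")) return(src)
    load_read_positions(src, chromosome, min_mapping_quality)
  }
  track <- if (inherits(gc, "gc_track")) gc else load_gc_track(gc, chromosome)
  prep <- function(src) {
    d <- compute_distances(get_reads(src))
    d <- apply_censoring(d, T)
    attach_gc(d, track)
  }
  dn <- prep(normal)
  dt <- prep(tumor)

  fit_n <- fit_mixture_glm(dn, g, config)
  cfg_t <- config
  cfg_t$fixed_beta1 <- fit_n$params$beta1
  fit_t <- fit_mixture_glm(dt, g, cfg_t)

  finish <- function(d, fit) {
    z <- int_transform(d, fit$params)
    bins <- bin_z(z, bin_width)
    seg <- recursive_combination(bins)
    list(distances = d, fit = fit, z = z, bins = bins, segments = seg)
  }
  list(normal = finish(dn, fit_n), tumor = finish(dt, fit_t),
       beta1 = fit_n$params$beta1)
}
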