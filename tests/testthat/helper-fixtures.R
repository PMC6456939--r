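# Small programmatic fixtures shared across test files.

# Two-column chromosome/position TSV.
write_positions_tsv <- function(positions, chrom = "chr9",
                                path = tempfile(fileext = ".tsv")) {
  utils::write.table(data.frame(chrom = rep(chrom, length(positions)),
                                pos = positions),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

# Three-column GC track TSV (chrom, window start, gc fraction).
write_gc_tsv <- function(starts, gc, chrom = "chr9",
                         path = tempfile(fileext = ".tsv")) {
  utils::write.table(data.frame(chrom = chrom, start = starts, gc = gc),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

# Minimal single-chromosome SAM file with reads at the given 1-based
# positions (MAPQ per read, default 60).
write_sam <- function(positions, mapq = rep(60L, length(positions)),
                      chrom = "chr9", path = tempfile(fileext = ".sam")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom,
                       as.integer(max(positions) + 1000L))), con)
  for (i in seq_along(positions)) {
    writeLines(sprintf("r%03d\t0\t%s\t%d\t%d\t10M\t*\t0\t0\tACGTACGTAC\t*",
                       i, chrom, as.integer(positions[i]),
                       as.integer(mapq[i])), con)
  }
  path
}

# Distance series built directly from values (bypasses position IO).
make_series <- function(y, delta = rep(1L, length(y)),
                        x = rep(NA_real_, length(y)),
                        anchors = cumsum(c(1, head(y, -1) + 1)),
                        T = NA_real_, chrom = "sim") {
  structure(list(anchor_positions = anchors, y = as.numeric(y),
                 delta = as.integer(delta), x = as.numeric(x)),
            chromosome = chrom, T = as.numeric(T),
            class = "distance_series")
}

# Printed parameter sets used across tests: the two plain-mixture
# simulation scenarios and the two covariate-adjusted (GLM) scenarios.
scenario1_plain <- function(T = NA_real_)
  mixture_params(c(0.3, 0.5, 0.2), c(0.002, 0.02, 0.2), T)
scenario2_plain <- function(T = NA_real_)
  mixture_params(c(0.008, 0.754, 0.238), c(0.999, 0.011, 0.0006), T)
scenario1_glm <- function(T = NA_real_)
  glm_mixture_params(c(0.3, 0.5, 0.2), c(6.0, 3.6, 1.1), 2.0, T)
scenario2_glm <- function(T = NA_real_)
  glm_mixture_params(c(0.3, 0.5, 0.2), c(6.2, 3.9, 1.4), 0.1, T)

# Application-style 4-component model (normal-sample column of the fitted
# tumor/normal pair) used where a realistic coverage model is needed.
application_glm <- function(T = 5000)
  glm_mixture_params(pi = c(0.0064, 0.0359, 0.5763, 0.3814),
                     beta0 = c(-2.021, 6.691, 8.681, 9.457),
                     beta1 = -4.428, T = T)
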