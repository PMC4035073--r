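# fixture builders shared across test files

toy_markers <- function(n, chrom = rep("chr1", n),
                        pos = seq(100L, by = 100L, length.out = n),
                        ref = rep("A", n), alt = rep("G", n)) {
  tibble::tibble(marker_id = sprintf("m%02d", seq_len(n)), chromosome = chrom,
                 position_bp = as.integer(pos), ref = ref, alt = alt)
}

# calls given as a cultivar x marker matrix of dosages
toy_geno <- function(calls, markers = NULL,
                     cultivar_ids = sprintf("cv%02d", seq_len(nrow(calls)))) {
  calls <- as.matrix(calls)
  colnames(calls) <- NULL
  if (is.null(markers)) markers <- toy_markers(ncol(calls))
  geno_matrix(calls, markers, cultivar_ids)
}

# a small two-pool + admixed population for pipeline-level tests
small_sim_config <- function(...) {
  args <- list(
    n_chromosomes = 4, chromosome_length_bp = 20e6, n_markers = 240,
    n_po_indica = 8, n_pd = 10, n_hy = 40,
    skew_regions = tibble::tibble(
      chromosome = c("chr02", "chr03"),
      start_bp = c(4e6, 10e6), end_bp = c(9e6, 15e6),
      target_indica = 0.9),
    qtl = tibble::tibble(trait = c("trait_a", "trait_b"),
                         chromosome = c("chr02", "chr03"),
                         position_bp = c(6.5e6, 12.5e6),
                         effect = c(1, 1)))
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(sim_config, args)
}

# independent linear-interpolation quantile oracle (type-7 definition,
# implemented from scratch: sort, fractional rank, interpolate)
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# brute-force PIC by explicit double sum over allele pairs
pic_oracle <- function(p) {
  s <- 1 - sum(p^2)
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      if (i < j) s <- s - 2 * p[i]^2 * p[j]^2
    }
  }
  s
}

# delta^2 oracle: squared Pearson correlation of haploid 0/1 dosage vectors
# over cultivars homozygous and non-missing at both markers
delta_sq_oracle <- function(a, b) {
  keep <- !is.na(a) & !is.na(b) & a %in% c(0L, 2L) & b %in% c(0L, 2L)
  x <- a[keep] / 2
  y <- b[keep] / 2
  if (length(x) < 2 || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
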