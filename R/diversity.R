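#' Per-marker allele frequencies in a cultivar subset
#'
#' Frequencies are computed over allele counts: a homozygote contributes two
#' copies of its allele, a heterozygote one copy of each, and missing calls
#' are excluded from the denominator. A marker with no non-missing call in
#' the subset gets `NA` frequencies (undefined, never zero).
#'
#' @param geno A [geno_matrix()].
#' @param cultivar_ids Cultivars to use (default: all).
#' @param marker_ids Markers to report (default: all).
#' @return Tibble `marker_id`, `ref`, `alt`, `n_called` (non-missing
#'   cultivars), `freq_ref`, `freq_alt`.
#' @export
allele_frequency <- function(geno, cultivar_ids = NULL, marker_ids = NULL) {
  d <- dosage(geno, cultivar_ids, marker_ids)
  n_called <- colSums(!is.na(d))
  alt_copies <- colSums(d, na.rm = TRUE)
  freq_alt <- ifelse(n_called > 0, alt_copies / (2 * n_called), NA_real_)
  mk <- filter(geno$markers, .data$marker_id %in% colnames(d))
  tibble(marker_id = colnames(d)) |>
    left_join(select(mk, "marker_id", "ref", "alt"), by = "marker_id") |>
    mutate(n_called = as.integer(n_called[.data$marker_id]),
           freq_alt = unname(freq_alt[.data$marker_id]),
           freq_ref = 1 - .data$freq_alt) |>
    select("marker_id", "ref", "alt", "n_called", "freq_ref", "freq_alt")
}

#' Marker informativeness statistics from allele frequencies
#'
#' For a frequency vector `p` over the alleles of one locus:
#' minor allele frequency `MAF = min(p)` (biallelic: `min(p, 1 - p)`),
#' expected heterozygosity (gene diversity) `He = 1 - sum(p_i^2)`, and
#' polymorphism information content
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @param freqs Numeric vector of per-allele frequencies summing to 1.
#' @return A single number.
#' @export
maf <- function(freqs) {
  check_freq_vector(freqs)
  min(freqs)
}

#' @rdname maf
#' @export
expected_heterozygosity <- function(freqs) {
  check_freq_vector(freqs)
  1 - sum(freqs^2)
}

#' @rdname maf
#' @export
pic <- function(freqs) {
  check_freq_vector(freqs)
  s2 <- sum(freqs^2)
  # sum_{i<j} 2 p_i^2 p_j^2 == (sum p^2)^2 - sum p^4
  1 - s2 - (s2^2 - sum(freqs^4))
}

check_freq_vector <- function(freqs) {
  if (!is.numeric(freqs) || anyNA(freqs) || any(freqs < 0) ||
      abs(sum(freqs) - 1) > 1e-8) {
    abort("freqs must be non-negative and sum to 1")
  }
  invisible(freqs)
}

#' Per-marker diversity statistics for one cultivar subset
#'
#' @param geno A [geno_matrix()].
#' @param cultivar_ids Cultivars to use (default: all).
#' @return Tibble `marker_id`, `maf`, `het` (expected heterozygosity),
#'   `pic`; `NA` where the marker has no call in the subset.
#' @export
marker_diversity <- function(geno, cultivar_ids = NULL) {
  fr <- allele_frequency(geno, cultivar_ids)
  p <- fr$freq_alt
  mutate(select(fr, "marker_id"),
    maf = pmin(p, 1 - p),
    het = 1 - p^2 - (1 - p)^2,
    pic = 1 - p^2 - (1 - p)^2 - 2 * p^2 * (1 - p)^2
  )
}

#' Sample-size-adjusted diversity summary by resampling
#'
#' Recomputes mean MAF, expected heterozygosity and PIC as the average over
#' `reps` random subsets of `n_sub` cultivars drawn without replacement,
#' removing the dependence of the means on unequal population sizes.
#'
#' @param geno A [geno_matrix()].
#' @param cultivar_ids Cultivars forming the population.
#' @param n_sub Subset size (default 14, the smallest study population).
#' @param reps Number of resampled subsets (default 10).
#' @param seed Optional integer seed; fixes the draw.
#' @return One-row tibble `n_sub`, `reps`, `maf`, `het`, `pic` (adjusted
#'   means). The per-replicate means are attached as attribute
#'   `"replicates"` (tibble `replicate`, `maf`, `het`, `pic`).
#' @export
size_adjusted_summary <- function(geno, cultivar_ids = NULL, n_sub = 14,
                                  reps = 10, seed = NULL) {
  if (is.null(cultivar_ids)) cultivar_ids <- cultivars(geno)
  check_scalar_number(n_sub, "n_sub", 1)
  if (length(cultivar_ids) < n_sub) {
    abort(sprintf(
      "population has %d cultivars < n_sub = %d; skip the size adjustment for it",
      length(cultivar_ids), n_sub))
  }
  per_rep <- with_seed(seed, {
    map(seq_len(reps), function(r) {
      sub <- sample(cultivar_ids, n_sub)
      d <- marker_diversity(geno, sub)
      tibble(replicate = r,
             maf = mean(d$maf, na.rm = TRUE),
             het = mean(d$het, na.rm = TRUE),
             pic = mean(d$pic, na.rm = TRUE))
    }) |> list_rbind()
  })
  out <- tibble(n_sub = as.integer(n_sub), reps = as.integer(reps),
                maf = mean(per_rep$maf), het = mean(per_rep$het),
                pic = mean(per_rep$pic))
  attr(out, "replicates") <- per_rep
  out
}

#' Population diversity table
#'
#' Mean MAF, expected heterozygosity and PIC per analysis group, with the
#' resampling-based sample-size adjustment where the group is large enough.
#' Markers monomorphic within a group are included (contributing zero);
#' markers with no call in the group are dropped from that group's means.
#'
#' @param geno A [geno_matrix()].
#' @param panel Tibble `cultivar_id`, `group` (see [read_panel()]).
#' @param groups Group labels to report; default: every group present.
#' @param include_all Prepend an `All` row pooling every panel cultivar.
#' @param adjust_n,adjust_reps Resampling parameters for the adjusted means
#'   (defaults 14 and 10); groups smaller than `adjust_n` get `NA` adjusted
#'   values.
#' @param seed Optional integer seed for the resampling.
#' @return Tibble with one row per population: `population`, `n_cultivars`,
#'   `mean_maf`, `mean_het`, `mean_pic`, `adj_maf`, `adj_het`, `adj_pic`.
#' @export
diversity_summary <- function(geno, panel, groups = NULL, include_all = TRUE,
                              adjust_n = 14, adjust_reps = 10, seed = NULL) {
  panel <- filter(panel, .data$cultivar_id %in% cultivars(geno))
  if (is.null(groups)) groups <- unique(panel$group)
  pops <- setNames(map(groups, ~ panel$cultivar_id[panel$group == .x]), groups)
  if (include_all) pops <- c(list(All = panel$cultivar_id), pops)
  seeds <- if (is.null(seed)) rep(list(NULL), length(pops)) else
    as.list(seed + seq_along(pops))
  imap(pops, function(ids, pop) {
    i <- which(names(pops) == pop)[1]
    d <- marker_diversity(geno, ids)
    adj <- if (length(ids) >= adjust_n) {
      size_adjusted_summary(geno, ids, n_sub = adjust_n, reps = adjust_reps,
                            seed = seeds[[i]])
    } else {
      tibble(maf = NA_real_, het = NA_real_, pic = NA_real_)
    }
    tibble(population = pop, n_cultivars = length(ids),
           mean_maf = mean(d$maf, na.rm = TRUE),
           mean_het = mean(d$het, na.rm = TRUE),
           mean_pic = mean(d$pic, na.rm = TRUE),
           adj_maf = adj$maf, adj_het = adj$het, adj_pic = adj$pic)
  }) |> list_rbind()
}
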