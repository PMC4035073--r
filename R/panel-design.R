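#' Informative-marker filter for a small core cultivar set
#'
#' Keeps markers with no missing call in the core set and whose minor allele
#' is carried by at least `min_carriers` of the core cultivars (a cultivar
#' carries an allele if it is homozygous or heterozygous for it).
#'
#' @param geno A [geno_matrix()] restricted (via `cultivar_ids`) to the core
#'   set; the study screened 14 high-yielding or primary ancestral cultivars.
#' @param cultivar_ids Core cultivars (default: all in `geno`).
#' @param min_carriers Minimum number of core cultivars carrying the minor
#'   allele (default 3).
#' @return Character vector of retained marker ids, in map order.
#' @export
filter_core_informative <- function(geno, cultivar_ids = NULL, min_carriers = 3) {
  d <- dosage(geno, cultivar_ids)
  no_missing <- colSums(is.na(d)) == 0
  carriers_alt <- colSums(d >= 1, na.rm = TRUE)   # cultivars carrying alt
  carriers_ref <- colSums(d <= 1, na.rm = TRUE)   # cultivars carrying ref
  alt_copies <- colSums(d, na.rm = TRUE)
  ref_copies <- 2 * colSums(!is.na(d)) - alt_copies
  minor_carriers <- ifelse(alt_copies <= ref_copies, carriers_alt, carriers_ref)
  keep <- no_missing & minor_carriers >= min_carriers
  colnames(d)[keep]
}

#' Informative-marker filter over the full accession set
#'
#' Drops markers that (1) lack a map position, (2) are heterozygous or
#' missing in more than `max_het_missing` of the accessions, or (3) have a
#' minor allele frequency at or below `min_maf` (the frequency rule is
#' inclusive: MAF exactly at the threshold is excluded).
#'
#' @param geno A [geno_matrix()] over all accessions.
#' @param max_het_missing Maximum tolerated (het + missing) fraction
#'   (default 0.05).
#' @param min_maf MAF threshold; markers with MAF `<= min_maf` are dropped
#'   (default 0.02).
#' @return Character vector of retained marker ids, in map order.
#' @export
filter_panel_informative <- function(geno, max_het_missing = 0.05,
                                     min_maf = 0.02) {
  d <- geno$calls
  n <- nrow(d)
  has_pos <- !is.na(geno$markers$position_bp)
  het_missing <- (colSums(d == 1L, na.rm = TRUE) + colSums(is.na(d))) / n
  fr <- allele_frequency(geno)
  m <- pmin(fr$freq_alt, fr$freq_ref)
  keep <- has_pos & het_missing <= max_het_missing & !is.na(m) & m > min_maf
  colnames(d)[keep]
}

#' Pairwise linkage disequilibrium between two markers
#'
#' The squared correlation of parental-type indicators across inbred
#' cultivars: with haplotypes read directly from homozygous genotypes,
#' `delta^2 = (p_AB - p_A p_B)^2 / (p_A (1 - p_A) p_B (1 - p_B))`.
#' Cultivars that are heterozygous or missing at either marker are excluded
#' pairwise (phase is unknown there).
#'
#' @param geno A [geno_matrix()].
#' @param marker_a,marker_b Marker ids.
#' @param cultivar_ids Cultivars to use (default: all).
#' @return Scalar in `[0, 1]`, or `NA` if either marker is monomorphic in
#'   the homozygous-complete subset or fewer than 2 cultivars remain.
#' @export
delta_squared <- function(geno, marker_a, marker_b, cultivar_ids = NULL) {
  d <- dosage(geno, cultivar_ids, c(marker_a, marker_b))
  delta_squared_dosage(d[, 1], d[, 2])
}

# core on two dosage vectors; hets (1) and NA dropped pairwise
delta_squared_dosage <- function(a, b) {
  use <- !is.na(a) & !is.na(b) & a != 1L & b != 1L
  if (sum(use) < 2) return(NA_real_)
  x <- a[use] / 2   # 0/1 haplotype indicator
  y <- b[use] / 2
  pa <- mean(x); pb <- mean(y)
  va <- pa * (1 - pa); vb <- pb * (1 - pb)
  if (va == 0 || vb == 0) return(NA_real_)
  pab <- mean(x * y)
  (pab - pa * pb)^2 / (va * vb)
}

#' Adjacent-pair LD for a marker subset
#'
#' Sorts the chosen markers by map position, forms every within-chromosome
#' adjacent pair (chromosome boundaries contribute no pair) and returns the
#' pairwise `delta^2` values.
#'
#' @param geno A [geno_matrix()].
#' @param marker_ids Markers forming the subset.
#' @param cultivar_ids Cultivars to use (default: all).
#' @return Tibble `chromosome`, `marker_a`, `marker_b`, `delta_sq`.
#' @export
adjacent_pair_ld <- function(geno, marker_ids, cultivar_ids = NULL) {
  mk <- filter(geno$markers, .data$marker_id %in% marker_ids) |> sort_markers()
  d <- dosage(geno, cultivar_ids, mk$marker_id)
  mk |>
    group_by(.data$chromosome) |>
    filter(n() >= 2) |>
    reframe(marker_a = .data$marker_id[-length(.data$marker_id)],
            marker_b = .data$marker_id[-1]) |>
    mutate(delta_sq = map_dbl(seq_len(n()), function(i) {
      delta_squared_dosage(d[, .data$marker_a[i]], d[, .data$marker_b[i]])
    })) |>
    select("chromosome", "marker_a", "marker_b", "delta_sq")
}

#' Mean complete LD across random marker subsets of increasing size
#'
#' For each panel size and replicate, draws a uniform random subset of the
#' informative markers, computes adjacent-pair `delta^2` within chromosomes
#' and averages over the "complete LD" pairs, i.e. pairs with
#' `0 < delta^2 < 1` (`mean_mode = "open-interval"`, the default) or over
#' all defined pairs (`mean_mode = "all"`). As marker density grows the
#' curve rises and flattens once the inter-marker spacing falls well below
#' the LD decay length — the plateau used to size a working panel.
#'
#' @param geno A [geno_matrix()].
#' @param sizes Integer vector of panel sizes.
#' @param marker_ids Markers to draw from (default: all).
#' @param cultivar_ids Cultivars to use (default: all).
#' @param reps Replicates per size (default 10).
#' @param mean_mode `"open-interval"` or `"all"`.
#' @param seed Optional integer seed.
#' @return Tibble of class `ld_curve` with one row per (size, replicate):
#'   `panel_size`, `replicate`, `mean_complete_ld`, `n_pairs_used`,
#'   `n_pairs_total`. The per-size mean and standard error over replicates
#'   are attached as attribute `"summary"` (`panel_size`, `mean_ld`, `se_ld`,
#'   `n_reps_used`).
#' @export
ld_subset_curve <- function(geno, sizes, marker_ids = NULL, cultivar_ids = NULL,
                            reps = 10, mean_mode = c("open-interval", "all"),
                            seed = NULL) {
  mean_mode <- match.arg(mean_mode)
  if (is.null(marker_ids)) marker_ids <- geno$markers$marker_id
  if (any(sizes > length(marker_ids))) {
    abort("a requested panel size exceeds the available informative markers")
  }
  pts <- with_seed(seed, {
    map(sizes, function(sz) {
      map(seq_len(reps), function(r) {
        sub <- if (sz == length(marker_ids)) marker_ids else sample(marker_ids, sz)
        ld <- adjacent_pair_ld(geno, sub, cultivar_ids)
        v <- ld$delta_sq[!is.na(ld$delta_sq)]
        use <- if (mean_mode == "open-interval") v[v > 0 & v < 1] else v
        if (!length(use)) {
          warn(sprintf("size %d replicate %d: no pairs with 0 < delta^2 < 1; replicate flagged", sz, r))
        }
        tibble(panel_size = sz, replicate = r,
               mean_complete_ld = if (length(use)) mean(use) else NA_real_,
               n_pairs_used = length(use), n_pairs_total = nrow(ld))
      }) |> list_rbind()
    }) |> list_rbind()
  })
  summ <- pts |>
    filter(!is.na(.data$mean_complete_ld)) |>
    group_by(panel_size = .data$panel_size) |>
    summarise(mean_ld = mean(.data$mean_complete_ld),
              se_ld = if (n() > 1) sd(.data$mean_complete_ld) / sqrt(n()) else NA_real_,
              n_reps_used = n(), .groups = "drop")
  attr(pts, "summary") <- summ
  class(pts) <- c("ld_curve", class(pts))
  pts
}

#' Draw a working panel of markers at random
#'
#' @param marker_map Tibble with `marker_id`, `chromosome`, `position_bp`
#'   (e.g. [marker_map()] filtered to the informative set), or a character
#'   vector of marker ids (then output order follows the input).
#' @param target_size Number of markers to select.
#' @param seed Optional integer seed.
#' @return Character vector of selected marker ids, ordered by map position.
#' @export
select_panel <- function(marker_map, target_size, seed = NULL) {
  if (is.character(marker_map)) {
    ids <- marker_map
    if (target_size > length(ids)) abort("target_size exceeds available markers")
    sel <- with_seed(seed, if (target_size == length(ids)) ids else sample(ids, target_size))
    return(ids[ids %in% sel])
  }
  mk <- sort_markers(as_tibble(marker_map))
  if (target_size > nrow(mk)) abort("target_size exceeds available markers")
  sel <- with_seed(seed, if (target_size == nrow(mk)) mk$marker_id else
    sample(mk$marker_id, target_size))
  mk$marker_id[mk$marker_id %in% sel]
}
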