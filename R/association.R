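#' Intersect significant associations with introgression-skewed regions
#'
#' Keeps markers with family-wise permutation P strictly below `alpha`
#' whose window skew call is not `NEUTRAL` — the markers whose trait
#' association co-locates with a region dominated by one parental genome
#' type. Markers outside every discriminating-SNP window carry no skew
#' call and are excluded.
#'
#' @param scan An [mlm_scan()] object after [permutation_p()], or its
#'   `tidy()` tibble with a `perm_p` column.
#' @param profile An [ancestry_profile()].
#' @param alpha Strict significance cutoff on `perm_p` (default 0.01).
#' @return Tibble of retained markers with their statistics, `skew` and
#'   `adjusted_hy`.
#' @export
intersect_with_skew <- function(scan, profile, alpha = 0.01) {
  res <- if (inherits(scan, "mlm_scan")) scan$results else as_tibble(scan)
  if (!"perm_p" %in% names(res)) abort("run permutation_p() first: no perm_p column")
  stopifnot(inherits(profile, "ancestry_profile"))
  res |>
    left_join(select(profile$snps, "marker_id", "adjusted_hy", "skew"),
              by = "marker_id") |>
    filter(!is.na(.data$perm_p), .data$perm_p < alpha,
           !is.na(.data$skew), .data$skew != "NEUTRAL")
}

#' Candidate gene/QTL lookup around significant markers
#'
#' For each marker, searches a window of `window_bp` centered on the SNP
#' (default 4 Mb; closed interval, clipped at the chromosome start) for
#' `GENE` features in the matching trait category; when none overlap, falls
#' back to `QTL` features. Reports every overlap with the distance from the
#' SNP to the feature (0 when the SNP lies inside it).
#'
#' @param hits Tibble with `marker_id`, `chromosome`, `position_bp`
#'   (e.g. the output of [intersect_with_skew()]).
#' @param features Feature catalog (see [read_features()]).
#' @param trait_category Category to match; `NULL` or a category absent
#'   from the catalog disables the filter (the latter with a warning).
#' @param window_bp Full window width in bp (default 4e6).
#' @return Tibble `marker_id`, `chromosome`, `position_bp`, `window_start`,
#'   `window_end`, `feature_id`, `feature_kind`, `feature_start`,
#'   `feature_end`, `feature_category`, `distance_bp`. Markers with no
#'   overlapping feature appear once with `NA` feature columns.
#' @export
candidate_lookup <- function(hits, features, trait_category = NULL,
                             window_bp = 4e6) {
  hits <- as_tibble(hits)
  features <- as_tibble(features)
  if (!is.null(trait_category) &&
      !trait_category %in% features$trait_category) {
    warn(sprintf("trait category '%s' not in the catalog; searching all categories",
                 trait_category))
    trait_category <- NULL
  }
  half <- window_bp / 2
  map(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    ws <- max(1, h$position_bp - half)
    we <- h$position_bp + half
    cand <- filter(features, .data$chromosome == h$chromosome,
                   .data$start_bp <= we, .data$end_bp >= ws)
    if (!is.null(trait_category)) {
      cand <- filter(cand, .data$trait_category == !!trait_category)
    }
    genes <- filter(cand, .data$feature_kind == "GENE")
    found <- if (nrow(genes)) genes else filter(cand, .data$feature_kind == "QTL")
    base <- tibble(marker_id = h$marker_id, chromosome = h$chromosome,
                   position_bp = h$position_bp,
                   window_start = as.integer(ws), window_end = as.integer(we))
    if (!nrow(found)) {
      return(mutate(base, feature_id = NA_character_,
                    feature_kind = NA_character_, feature_start = NA_integer_,
                    feature_end = NA_integer_, feature_category = NA_character_,
                    distance_bp = NA_integer_))
    }
    bind_cols(base[rep(1, nrow(found)), ],
              tibble(feature_id = found$feature_id,
                     feature_kind = found$feature_kind,
                     feature_start = found$start_bp,
                     feature_end = found$end_bp,
                     feature_category = found$trait_category,
                     distance_bp = as.integer(pmax(
                       0, pmax(found$start_bp - h$position_bp,
                               h$position_bp - found$end_bp)))))
  }) |> list_rbind()
}

#' Per-allele trait means at association markers
#'
#' Groups the phenotyped cultivars by their genotype class at each marker —
#' indica-allele homozygotes versus japonica-allele homozygotes when a
#' discriminating-SNP table supplies the orientation, otherwise
#' alternate- versus reference-allele homozygotes. Heterozygotes are
#' excluded. Reports mean and sample standard deviation per class
#' (`NA` when the class holds fewer than 2 cultivars).
#'
#' @param pheno Long phenotype tibble `cultivar_id`, `trait`, `value`.
#' @param geno A [geno_matrix()].
#' @param marker_ids Markers to summarise.
#' @param trait Trait name (may be omitted for a single-trait table).
#' @param disc Optional [find_discriminating_snps()] table giving the
#'   indica-allele orientation.
#' @return Tibble `marker_id`, `allele_class`, `allele`, `n`, `mean`, `sd`.
#' @export
allele_effect_table <- function(pheno, geno, marker_ids, trait = NULL,
                                disc = NULL) {
  pheno <- as_tibble(pheno)
  if (is.null(trait)) {
    tr <- unique(pheno$trait)
    if (length(tr) != 1) abort("pheno holds several traits; pass `trait`")
    trait <- tr
  }
  ph <- filter(pheno, .data$trait == !!trait, !is.na(.data$value),
               .data$cultivar_id %in% cultivars(geno))
  d <- dosage(geno, ph$cultivar_id, marker_ids)
  mk <- filter(geno$markers, .data$marker_id %in% marker_ids)
  map(marker_ids, function(m) {
    dos <- d[, m]
    info <- filter(mk, .data$marker_id == m)
    if (!is.null(disc) && m %in% disc$marker_id) {
      ind_alt <- disc$indica_is_alt[disc$marker_id == m]
      classes <- tibble(
        allele_class = c("indica", "japonica"),
        allele = if (ind_alt) c(info$alt, info$ref) else c(info$ref, info$alt),
        dos_value = if (ind_alt) c(2L, 0L) else c(0L, 2L))
    } else {
      classes <- tibble(allele_class = c("alt", "ref"),
                        allele = c(info$alt, info$ref), dos_value = c(2L, 0L))
    }
    map(seq_len(2), function(k) {
      v <- ph$value[!is.na(dos) & dos == classes$dos_value[k]]
      tibble(marker_id = m, allele_class = classes$allele_class[k],
             allele = classes$allele[k], n = length(v),
             mean = if (length(v)) mean(v) else NA_real_,
             sd = if (length(v) >= 2) sd(v) else NA_real_)
    }) |> list_rbind()
  }) |> list_rbind()
}
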