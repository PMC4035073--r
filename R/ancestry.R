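#' Find genome-type-discriminating SNPs
#'
#' A marker discriminates the two parental pools when the frequency of a
#' fixed allele differs by strictly more than `threshold` (default 0.7)
#' between the domestic japonica parents (`PD`) and the overseas indica
#' parents (`PO_INDICA`). For strongly diverged markers this coincides with
#' the major-allele-frequency difference. The indica allele is the major
#' allele in the `PO_INDICA` pool; an exact 0.5/0.5 tie is broken towards
#' the alphabetically smaller base with a warning.
#'
#' @param geno A [geno_matrix()].
#' @param panel Tibble `cultivar_id`, `group` (see [read_panel()]).
#' @param threshold Strict frequency-difference cutoff (default 0.7).
#' @param marker_ids Markers to consider (default: all).
#' @return Tibble `marker_id`, `chromosome`, `position_bp`, `indica_allele`,
#'   `freq_po_indica`, `freq_pd`, `freq_hy` (indica-allele frequencies) and
#'   `freq_diff` (the absolute difference that passed the threshold).
#' @export
find_discriminating_snps <- function(geno, panel, threshold = 0.7,
                                     marker_ids = NULL) {
  panel <- filter(panel, .data$cultivar_id %in% cultivars(geno))
  ids <- function(g) panel$cultivar_id[panel$group == g]
  for (g in c("PD", "PO_INDICA", "HY")) {
    if (!length(ids(g))) abort(sprintf("panel group %s is empty", g))
  }
  f_pd <- allele_frequency(geno, ids("PD"), marker_ids)
  f_po <- allele_frequency(geno, ids("PO_INDICA"), marker_ids)
  f_hy <- allele_frequency(geno, ids("HY"), marker_ids)
  undefined <- is.na(f_pd$freq_alt) | is.na(f_po$freq_alt)
  if (any(undefined)) {
    inform(sprintf("%d marker(s) with undefined parental frequency excluded",
                   sum(undefined)))
  }
  diff <- abs(f_pd$freq_alt - f_po$freq_alt)
  keep <- !undefined & diff > threshold
  tie <- keep & f_po$freq_alt == 0.5
  if (any(tie)) {
    warn(sprintf("%d marker(s) with a 0.5/0.5 indica-pool tie; indica allele set alphabetically",
                 sum(tie)))
  }
  indica_is_alt <- f_po$freq_alt > 0.5 |
    (f_po$freq_alt == 0.5 & f_po$alt < f_po$ref)
  orient <- function(fr) ifelse(indica_is_alt, fr$freq_alt, 1 - fr$freq_alt)
  out <- tibble(
    marker_id = f_pd$marker_id,
    indica_allele = ifelse(indica_is_alt, f_po$alt, f_po$ref),
    indica_is_alt = indica_is_alt,
    freq_po_indica = orient(f_po),
    freq_pd = orient(f_pd),
    freq_hy = orient(f_hy),
    freq_diff = diff
  )[keep, ]
  geno$markers |>
    select("marker_id", "chromosome", "position_bp") |>
    inner_join(out, by = "marker_id")
}

#' Parental-frequency-adjusted indica-allele frequency
#'
#' The introgression statistic for high-yielding (HY) cultivars:
#' `adjusted_hy = freq_hy - freq_pd - (1 - freq_po_indica)`, where all three
#' arguments are indica-allele frequencies. The subtraction corrects the HY
#' frequency for residual indica alleles in the japonica parents and for
#' incomplete fixation in the indica parents; values near 1 indicate strong
#' indica introgression, values near or below 0 a japonica background. The
#' result is unclamped (range `[-2, 1]`).
#'
#' @param freq_hy,freq_pd,freq_po_indica Indica-allele frequencies in
#'   `[0, 1]` (vectorised).
#' @return Numeric vector.
#' @export
adjusted_hy_frequency <- function(freq_hy, freq_pd, freq_po_indica) {
  stopifnot(all(freq_hy >= 0 & freq_hy <= 1, na.rm = TRUE),
            all(freq_pd >= 0 & freq_pd <= 1, na.rm = TRUE),
            all(freq_po_indica >= 0 & freq_po_indica <= 1, na.rm = TRUE))
  freq_hy - freq_pd - (1 - freq_po_indica)
}

#' Five-SNP window summaries of the adjusted-HY profile
#'
#' Windows are consecutive runs of `window` discriminating SNPs in map
#' order within each chromosome (non-overlapping tiling by default;
#' `sliding = TRUE` advances one SNP at a time). A terminal remainder
#' window shorter than `window` is summarised and flagged `partial`.
#' Quantiles use linear interpolation (`stats::quantile` type 7).
#'
#' @param snps Tibble with `marker_id`, `chromosome`, `position_bp` and
#'   `adjusted_hy` (e.g. the output of [ancestry_profile()]'s `$snps`).
#' @param window Number of SNPs per window (default 5).
#' @param sliding Use sliding instead of tiling windows.
#' @return Tibble `chromosome`, `window_id`, `start_bp`, `end_bp`, `n_snps`,
#'   `partial`, `q25`, `median`, `q75` plus `marker_ids` (list column).
#' @export
window_summary <- function(snps, window = 5, sliding = FALSE) {
  check_scalar_number(window, "window", 1)
  snps <- sort_markers(as_tibble(snps))
  snps |>
    group_by(chromosome = .data$chromosome) |>
    reframe({
      n <- length(adjusted_hy)
      starts <- if (sliding && n >= window) seq_len(n - window + 1) else
        seq(1, n, by = window)
      map(starts, function(s) {
        e <- min(s + window - 1, n)
        v <- adjusted_hy[s:e]
        qs <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
        tibble(start_bp = position_bp[s], end_bp = position_bp[e],
               n_snps = e - s + 1L, partial = (e - s + 1L) < window,
               q25 = qs[1], median = qs[2], q75 = qs[3],
               marker_ids = list(marker_id[s:e]))
      }) |> list_rbind()
    }) |>
    group_by(.data$chromosome) |>
    mutate(window_id = paste0(.data$chromosome, "_w", row_number())) |>
    ungroup() |>
    select("chromosome", "window_id", "start_bp", "end_bp", "n_snps",
           "partial", "q25", "median", "q75", "marker_ids")
}

#' Call introgression-skewed windows against the genome-wide quantile band
#'
#' The genome-wide band is the 25th-75th percentile range of the window
#' medians (`band_on = "windows"`, default) or of all per-SNP adjusted-HY
#' values (`band_on = "snps"`). A window whose median lies strictly above
#' the 75th percentile is `INDICA_SKEWED`, strictly below the 25th
#' `JAPONICA_SKEWED`, otherwise `NEUTRAL`. Runs of adjacent same-class
#' skewed windows are merged into intervals bounded by their first and last
#' member SNPs.
#'
#' @param windows Output of [window_summary()].
#' @param snps The per-SNP profile (required when `band_on = "snps"`).
#' @param band Optional numeric `c(q25, q75)` overriding the genome-wide
#'   band.
#' @param band_on `"windows"` or `"snps"`.
#' @return The `windows` tibble with a `skew` column; the band is attached
#'   as attribute `"band"` (named `q25`/`median`/`q75`) and the merged
#'   intervals as attribute `"intervals"` (tibble `chromosome`, `start_bp`,
#'   `end_bp`, `skew`, `n_windows`).
#' @export
call_skewed_regions <- function(windows, snps = NULL, band = NULL,
                                band_on = c("windows", "snps")) {
  band_on <- match.arg(band_on)
  if (is.null(band)) {
    src <- if (band_on == "windows") windows$median else {
      if (is.null(snps)) abort("band_on = \"snps\" needs the `snps` table")
      snps$adjusted_hy
    }
    qs <- quantile(src, c(0.25, 0.5, 0.75), names = FALSE)
  } else {
    qs <- c(band[1], NA_real_, band[2])
  }
  out <- mutate(windows, skew = dplyr::case_when(
    .data$median > qs[3] ~ "INDICA_SKEWED",
    .data$median < qs[1] ~ "JAPONICA_SKEWED",
    TRUE ~ "NEUTRAL"
  ))
  skewed <- out |>
    group_by(.data$chromosome) |>
    mutate(.run = cumsum(.data$skew != dplyr::lag(.data$skew,
                                                  default = "__none__"))) |>
    ungroup() |>
    filter(.data$skew != "NEUTRAL")
  runs <- if (nrow(skewed)) {
    skewed |>
      group_by(.data$chromosome, .data$.run, .data$skew) |>
      summarise(start_bp = min(.data$start_bp), end_bp = max(.data$end_bp),
                n_windows = n(), .groups = "drop") |>
      select("chromosome", "start_bp", "end_bp", "skew", "n_windows")
  } else {
    tibble(chromosome = character(), start_bp = integer(),
           end_bp = integer(), skew = character(), n_windows = integer())
  }
  attr(out, "band") <- c(q25 = qs[1], median = qs[2], q75 = qs[3])
  attr(out, "intervals") <- runs
  out
}

#' Full adjusted-HY ancestry scan
#'
#' Convenience pipeline: discriminating-SNP selection, per-SNP adjusted-HY
#' values, window summaries and skew calls in one object.
#'
#' @inheritParams find_discriminating_snps
#' @inheritParams window_summary
#' @inheritParams call_skewed_regions
#' @return Object of class `ancestry_profile`: list with `snps` (per-marker
#'   profile incl. `adjusted_hy` and the window skew call), `windows`,
#'   `intervals`, `band` and `params`.
#' @export
ancestry_profile <- function(geno, panel, threshold = 0.7, window = 5,
                             sliding = FALSE, band_on = c("windows", "snps")) {
  band_on <- match.arg(band_on)
  snps <- find_discriminating_snps(geno, panel, threshold) |>
    mutate(adjusted_hy = adjusted_hy_frequency(.data$freq_hy, .data$freq_pd,
                                               .data$freq_po_indica))
  wins <- window_summary(snps, window = window, sliding = sliding)
  wins <- call_skewed_regions(wins, snps = snps, band_on = band_on)
  marker_skew <- wins |>
    select("window_id", "skew", "marker_ids") |>
    tidyr::unnest(cols = "marker_ids") |>
    rename(marker_id = "marker_ids")
  snps <- left_join(snps, marker_skew, by = "marker_id")
  structure(
    list(snps = snps, windows = wins, intervals = attr(wins, "intervals"),
         band = attr(wins, "band"),
         params = list(threshold = threshold, window = window,
                       sliding = sliding, band_on = band_on)),
    class = "ancestry_profile"
  )
}

#' @export
print.ancestry_profile <- function(x, ...) {
  cat(sprintf(
    "<ancestry_profile> %d discriminating SNPs, %d windows (%d skewed) on %d chromosome(s)\n",
    nrow(x$snps), nrow(x$windows),
    sum(x$windows$skew != "NEUTRAL"), length(unique(x$windows$chromosome))
  ))
  cat(sprintf("  genome-wide band: q25 = %.3f, median = %.3f, q75 = %.3f\n",
              x$band["q25"], x$band["median"], x$band["q75"]))
  invisible(x)
}

#' Classify cultivar genome types from discriminating SNPs
#'
#' Each cultivar's `indica_fraction` is the fraction of its non-missing
#' discriminating-SNP calls carrying the indica allele (heterozygotes count
#' one half). Cultivars at or below `ja_max` are japonica-dominant (`JA`),
#' at or above `in_min` indica-dominant (`IN`), otherwise mixed (`MX`). The
#' thresholds are reporting conventions, not estimates; they default to
#' 0.3/0.7 and are echoed in the output.
#'
#' @param geno A [geno_matrix()].
#' @param disc Discriminating-SNP table from [find_discriminating_snps()].
#' @param cultivar_ids Cultivars to classify (default: all in `geno`).
#' @param ja_max,in_min Class thresholds on `indica_fraction`.
#' @return Tibble `cultivar_id`, `n_used`, `n_missing`, `indica_fraction`,
#'   `class`, `low_confidence` (more than half the discriminating SNPs
#'   missing). Thresholds are attached as attribute `"thresholds"`.
#' @export
classify_genome_types <- function(geno, disc, cultivar_ids = NULL,
                                  ja_max = 0.3, in_min = 0.7) {
  if (!nrow(disc)) abort("no discriminating SNPs supplied")
  d <- dosage(geno, cultivar_ids, disc$marker_id)
  # score per call: fraction of the two gametes that are indica
  sc <- sweep(d, 2, ifelse(disc$indica_is_alt, 1, -1), `*`)
  sc <- sweep(sc, 2, ifelse(disc$indica_is_alt, 0, -2), `-`) / 2
  n_missing <- rowSums(is.na(d))
  n_used <- ncol(d) - n_missing
  frac <- rowMeans(sc, na.rm = TRUE)
  out <- tibble(
    cultivar_id = rownames(d),
    n_used = as.integer(n_used), n_missing = as.integer(n_missing),
    indica_fraction = ifelse(n_used > 0, frac, NA_real_),
    class = dplyr::case_when(
      n_used == 0 ~ NA_character_,
      frac <= ja_max ~ "JA",
      frac >= in_min ~ "IN",
      TRUE ~ "MX"
    ),
    low_confidence = n_missing > ncol(d) / 2
  )
  if (any(out$low_confidence)) {
    warn(sprintf("%d cultivar(s) classified with > 50%% missing discriminating SNPs",
                 sum(out$low_confidence)))
  }
  attr(out, "thresholds") <- c(ja_max = ja_max, in_min = in_min)
  out
}

#' Graphical-genotype matrix of parental origin
#'
#' Per-cultivar, per-discriminating-SNP parental-origin call for plotting
#' chromosome-long origin tracks.
#'
#' @inheritParams classify_genome_types
#' @return Long tibble `cultivar_id`, `marker_id`, `chromosome`,
#'   `position_bp`, `origin` (`INDICA`/`JAPONICA`/`HET`/`MISSING`).
#' @export
graphical_genotype <- function(geno, disc, cultivar_ids = NULL) {
  d <- dosage(geno, cultivar_ids, disc$marker_id)
  ind <- matrix(disc$indica_is_alt, nrow = nrow(d), ncol = ncol(d), byrow = TRUE)
  origin <- matrix("MISSING", nrow = nrow(d), ncol = ncol(d), dimnames = dimnames(d))
  origin[!is.na(d) & d == 1L] <- "HET"
  origin[!is.na(d) & ((d == 2L & ind) | (d == 0L & !ind))] <- "INDICA"
  origin[!is.na(d) & ((d == 0L & ind) | (d == 2L & !ind))] <- "JAPONICA"
  as_tibble(origin, rownames = "cultivar_id") |>
    pivot_longer(-"cultivar_id", names_to = "marker_id", values_to = "origin") |>
    left_join(select(disc, "marker_id", "chromosome", "position_bp"),
              by = "marker_id") |>
    select("cultivar_id", "marker_id", "chromosome", "position_bp", "origin")
}
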