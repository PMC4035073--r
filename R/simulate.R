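#' Simulation settings for an admixed breeding population
#'
#' Defaults describe the study system the scan targets: a 12-chromosome,
#' 30-Mb-per-chromosome genome scored at 1200 SNPs; two diverged homozygous
#' parental pools (14 overseas indica, 20 domestic japonica cultivars) with
#' 70% of markers at a fixed allele-frequency difference and the rest
#' partially diverged; 60 high-yielding mosaic progeny with a genome-wide
#' background indica fraction of 0.3, recombination blocks of mean 5 Mb,
#' and three selection-skewed regions driven to indica frequency 0.9; and
#' one yield trait controlled by two QTLs planted inside skew regions plus
#' a polygenic term.
#'
#' @param n_chromosomes,chromosome_length_bp,n_markers Genome layout.
#' @param n_po_indica,n_pd,n_hy Pool sizes.
#' @param prop_fixed_diff Fraction of markers with a fixed (|diff| = 1)
#'   parental frequency difference; the remainder draw their difference
#'   from `Beta(partial_shape[1], partial_shape[2])`.
#' @param partial_shape Beta shape parameters for partial divergence.
#' @param background_indica Stationary indica fraction of the ancestry
#'   mosaic outside skew regions.
#' @param block_length_mean_bp Mean recombination-block length (exponential
#'   inter-switch distances).
#' @param skew_regions Tibble `chromosome`, `start_bp`, `end_bp`,
#'   `target_indica` of selection-skewed intervals.
#' @param qtl Tibble `trait`, `chromosome`, `position_bp`, `effect`; each
#'   QTL is planted at the nearest fixed-difference marker.
#' @param h2 Narrow-sense heritability per trait (realised empirically);
#'   `0` gives a pure-noise trait.
#' @param qtl_frac Fraction of the genetic variance carried by the planted
#'   QTLs (the rest is polygenic).
#' @param het_rate,missing_rate Per-call rates of heterozygous and missing
#'   calls applied to the progeny genotypes last.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 12, chromosome_length_bp = 30e6,
                       n_markers = 1200, n_po_indica = 14, n_pd = 20,
                       n_hy = 60, prop_fixed_diff = 0.7,
                       partial_shape = c(2, 2), background_indica = 0.3,
                       block_length_mean_bp = 5e6,
                       skew_regions = NULL, qtl = NULL,
                       h2 = 0.85, qtl_frac = 0.9,
                       het_rate = 0.01, missing_rate = 0.01) {
  if (n_markers < n_chromosomes) abort("n_markers must be >= n_chromosomes")
  if (any(h2 < 0 | h2 > 1)) abort("heritability must lie in [0, 1]")
  chroms <- sprintf("chr%02d", seq_len(n_chromosomes))
  if (is.null(skew_regions)) {
    skew_regions <- tibble(
      chromosome = chroms[c(2, 7, 11) [c(2, 7, 11) <= n_chromosomes]],
      start_bp = c(6e6, 8e6, 18e6)[seq_along(chromosome)],
      end_bp = c(12e6, 14e6, 24e6)[seq_along(chromosome)],
      target_indica = 0.9)
  }
  if (is.null(qtl)) {
    # one major gene per trait, each inside a skew region — the trait
    # architecture of cloned large-effect rice loci (heading date, blast
    # resistance)
    qtl <- tibble(trait = c("heading_date", "blast_resistance"),
                  chromosome = skew_regions$chromosome[c(2, 3)],
                  position_bp = with(skew_regions[c(2, 3), ],
                                     (start_bp + end_bp) / 2),
                  effect = c(1, 1))
  }
  bad <- skew_regions$end_bp > chromosome_length_bp | skew_regions$start_bp < 1
  if (any(bad)) abort("skew region outside chromosome bounds")
  structure(list(
    n_chromosomes = n_chromosomes, chromosome_length_bp = chromosome_length_bp,
    n_markers = n_markers, n_po_indica = n_po_indica, n_pd = n_pd, n_hy = n_hy,
    prop_fixed_diff = prop_fixed_diff, partial_shape = partial_shape,
    background_indica = background_indica,
    block_length_mean_bp = block_length_mean_bp,
    skew_regions = as_tibble(skew_regions), qtl = as_tibble(qtl),
    h2 = h2, qtl_frac = qtl_frac,
    het_rate = het_rate, missing_rate = missing_rate,
    chromosomes = chroms
  ), class = "sim_config")
}

#' Simulate the two diverged homozygous parental pools
#'
#' Marker positions are placed uniformly at random (then sorted) along each
#' chromosome. Per marker, the two pools get alternate-allele frequencies
#' with either a fixed difference (one pool at 0, the other at 1) or a
#' Beta-distributed partial difference; each parent cultivar is homozygous,
#' drawn from its pool frequency.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return List with `geno` (a [geno_matrix()] of the parents), `panel`
#'   (`PO_INDICA`/`PD` assignments) and `truth` (per-marker pool
#'   frequencies and the fixed-difference flag).
#' @export
simulate_parents <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    n_chr <- config$n_chromosomes
    per_chr <- rep(config$n_markers %/% n_chr, n_chr)
    extra <- config$n_markers %% n_chr
    if (extra) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1L
    markers <- map(seq_len(n_chr), function(c) {
      pos <- sort(sample.int(config$chromosome_length_bp, per_chr[c]))
      tibble(chromosome = config$chromosomes[c], position_bp = pos)
    }) |> list_rbind() |>
      mutate(marker_id = sprintf("snp_%05d", row_number()))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nrow(markers), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    markers <- mutate(markers, ref = ref, alt = unname(alt)) |>
      select("marker_id", "chromosome", "position_bp", "ref", "alt")

    m <- nrow(markers)
    fixed <- runif(m) < config$prop_fixed_diff
    d_part <- rbeta(m, config$partial_shape[1], config$partial_shape[2])
    lo <- runif(m) * (1 - d_part)
    p_po <- ifelse(fixed, 1, lo + d_part)
    p_pd <- ifelse(fixed, 0, lo)
    swap <- runif(m) < 0.5
    tmp <- p_po[swap]; p_po[swap] <- p_pd[swap]; p_pd[swap] <- tmp

    po_ids <- sprintf("PO%02d", seq_len(config$n_po_indica))
    pd_ids <- sprintf("PD%02d", seq_len(config$n_pd))
    draw_pool <- function(ids, p) {
      calls <- vapply(p, function(pj) 2L * rbinom(length(ids), 1, pj),
                      integer(length(ids)))
      matrix(calls, nrow = length(ids), dimnames = list(ids, markers$marker_id))
    }
    geno <- geno_matrix(rbind(draw_pool(po_ids, p_po), draw_pool(pd_ids, p_pd)),
                        markers, c(po_ids, pd_ids))
    panel <- tibble(cultivar_id = c(po_ids, pd_ids),
                    group = rep(c("PO_INDICA", "PD"),
                                c(length(po_ids), length(pd_ids))))
    truth <- tibble(marker_id = markers$marker_id, fixed_diff = fixed,
                    p_alt_po_indica = p_po, p_alt_pd = p_pd)
    list(geno = geno, panel = panel, truth = truth)
  })
}

# piecewise origin track for one chromosome: switch points at exponential
# spacings, origin redrawn Bernoulli(bg) per block, then blocks inside skew
# regions are split at region bounds and redrawn at the region target
sim_origin_track <- function(chrom_len, bg, block_mean, regions, init = NULL) {
  cuts <- c(0)
  while (tail(cuts, 1) < chrom_len) {
    cuts <- c(cuts, tail(cuts, 1) + rexp(1, 1 / block_mean))
  }
  cuts <- unique(c(pmin(cuts, chrom_len), chrom_len))
  if (nrow(regions)) {
    cuts <- sort(unique(c(cuts, regions$start_bp - 1, regions$end_bp)))
    cuts <- cuts[cuts >= 0 & cuts <= chrom_len]
    if (tail(cuts, 1) < chrom_len) cuts <- c(cuts, chrom_len)
  }
  start <- head(cuts, -1) + 1
  end <- tail(cuts, -1)
  origin <- rbinom(length(start), 1, bg)
  if (!is.null(init)) origin[1] <- init
  if (nrow(regions)) {
    for (r in seq_len(nrow(regions))) {
      inside <- start >= regions$start_bp[r] & end <= regions$end_bp[r]
      origin[inside] <- rbinom(sum(inside), 1, regions$target_indica[r])
    }
  }
  tibble(start_bp = as.integer(ceiling(start)), end_bp = as.integer(floor(end)),
         origin = ifelse(origin == 1, "INDICA", "JAPONICA"))
}

#' Simulate mosaic admixed progeny from the parental pools
#'
#' Each high-yielding (HY) progeny genome is a parental-origin mosaic with
#' exponentially distributed block lengths and a Bernoulli origin per block
#' (stationary indica fraction `background_indica`); blocks inside the
#' configured skew regions are redrawn at the region's target indica
#' frequency, emulating selection. The genotype at a marker copies the call
#' of a random cultivar from the origin pool; heterozygous and missing
#' calls are sprinkled in last at the configured rates.
#'
#' @param parents Output of [simulate_parents()].
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return List with `geno` (parents + HY combined), `panel` (parents'
#'   groups plus `HY`) and `truth` (the parents' truth plus `origin_tracks`,
#'   a tibble `cultivar_id`, `chromosome`, `start_bp`, `end_bp`, `origin`).
#' @export
simulate_admixed <- function(parents, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  bad <- config$skew_regions$end_bp > config$chromosome_length_bp
  if (any(bad)) abort("skew region outside chromosome bounds")
  with_seed(seed, {
    mk <- parents$geno$markers
    po_ids <- parents$panel$cultivar_id[parents$panel$group == "PO_INDICA"]
    pd_ids <- parents$panel$cultivar_id[parents$panel$group == "PD"]
    po_calls <- dosage(parents$geno, po_ids)
    pd_calls <- dosage(parents$geno, pd_ids)
    hy_ids <- sprintf("HY%03d", seq_len(config$n_hy))
    m <- nrow(mk)
    calls <- matrix(NA_integer_, nrow = config$n_hy, ncol = m,
                    dimnames = list(hy_ids, mk$marker_id))
    tracks <- vector("list", config$n_hy)
    for (i in seq_len(config$n_hy)) {
      # the ancestry chain carries its state across chromosome boundaries, so
      # in the long-block limit a cultivar is single-origin genome-wide
      state <- rbinom(1, 1, config$background_indica)
      chr_tracks <- map(config$chromosomes, function(ch) {
        regions <- filter(config$skew_regions, .data$chromosome == ch)
        tr <- sim_origin_track(config$chromosome_length_bp,
                               config$background_indica,
                               config$block_length_mean_bp, regions,
                               init = state)
        state <<- as.integer(tr$origin[nrow(tr)] == "INDICA")
        mutate(tr, chromosome = ch)
      }) |> list_rbind()
      tracks[[i]] <- mutate(chr_tracks, cultivar_id = hy_ids[i])
      for (ch in unique(mk$chromosome)) {
        idx <- which(mk$chromosome == ch)
        tr <- filter(chr_tracks, .data$chromosome == ch)
        seg <- findInterval(mk$position_bp[idx], tr$start_bp)
        is_ind <- tr$origin[pmax(seg, 1)] == "INDICA"
        donor_po <- sample.int(length(po_ids), length(idx), replace = TRUE)
        donor_pd <- sample.int(length(pd_ids), length(idx), replace = TRUE)
        calls[i, idx] <- ifelse(is_ind,
                                po_calls[cbind(donor_po, idx)],
                                pd_calls[cbind(donor_pd, idx)])
      }
    }
    n_cells <- length(calls)
    calls[runif(n_cells) < config$het_rate] <- 1L
    calls[runif(n_cells) < config$missing_rate] <- NA_integer_
    geno_all <- geno_matrix(rbind(dosage(parents$geno), calls), mk,
                            c(cultivars(parents$geno), hy_ids))
    panel <- bind_rows(parents$panel,
                       tibble(cultivar_id = hy_ids, group = "HY"))
    truth <- list(markers = parents$truth,
                  origin_tracks = list_rbind(tracks) |>
                    select("cultivar_id", "chromosome", "start_bp",
                           "end_bp", "origin"),
                  skew_regions = config$skew_regions)
    list(geno = geno_all, panel = panel, truth = truth)
  })
}

#' Simulate QTL-driven phenotypes for the progeny
#'
#' Each trait is `sum(effect * dosage(QTL)) + polygenic + noise`, with QTL
#' effects applied to standardized dosages (units: trait change per dosage
#' standard deviation, so equal effects contribute equal variance): the
#' polygenic term is drawn from the marker-based kinship of the progeny and
#' scaled so the planted QTLs carry `qtl_frac` of the genetic variance, and
#' the noise is scaled so the realised narrow-sense heritability equals
#' `h2` in the simulated sample. `h2 = 0` yields a pure-noise trait.
#'
#' @param hy_geno A [geno_matrix()] of the progeny (HY cultivars only).
#' @param config A [sim_config()]; QTLs are planted at the fixed-difference
#'   marker nearest each configured position.
#' @param seed Optional integer seed.
#' @param marker_truth Optional `truth` marker tibble from
#'   [simulate_parents()]; when given, QTLs snap to fixed-difference
#'   markers only.
#' @return List with `pheno` (long tibble `cultivar_id`, `trait`, `value`)
#'   and `qtl_truth` (tibble `trait`, `marker_id`, `chromosome`,
#'   `position_bp`, `effect`, `var_explained`).
#' @export
simulate_phenotypes <- function(hy_geno, config, seed = NULL,
                                marker_truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$h2 < 0 | config$h2 > 1)) abort("heritability must lie in [0, 1]")
  with_seed(seed, {
    mk <- hy_geno$markers
    qtl <- config$qtl |>
      mutate(marker_id = map_chr(seq_len(n()), function(i) {
        cand <- mk
        if (!is.null(marker_truth)) {
          cand <- filter(mk, .data$marker_id %in%
                           marker_truth$marker_id[marker_truth$fixed_diff])
        }
        cand <- filter(cand, .data$chromosome == config$qtl$chromosome[i])
        if (!nrow(cand)) abort("no marker available on the QTL chromosome")
        cand$marker_id[which.min(abs(cand$position_bp - config$qtl$position_bp[i]))]
      }))
    traits <- unique(qtl$trait)
    n <- length(cultivars(hy_geno))
    h2s <- if (length(config$h2) == 1) setNames(rep(config$h2, length(traits)),
                                                traits) else config$h2
    K <- kinship(hy_geno)
    L <- chol(K + diag(1e-6, n))
    out <- map(traits, function(tr) {
      h2 <- h2s[[tr]]
      qt <- filter(qtl, .data$trait == tr)
      if (h2 == 0 || !nrow(qt)) {
        g_qtl <- rep(0, n); v_q <- 0
      } else {
        # effects act on standardized dosages, so each QTL's variance share
        # is set by its effect size, not by the realised allele frequency
        M <- dosage(hy_geno, marker_ids = qt$marker_id)
        M <- apply(M, 2, function(x) {
          x[is.na(x)] <- mean(x, na.rm = TRUE)
          s <- sd(x)
          if (is.na(s) || s == 0) {
            warn("monomorphic QTL marker contributes no variance")
            rep(0, length(x))
          } else (x - mean(x)) / s
        })
        g_qtl <- drop(M %*% qt$effect)
        v_q <- var(g_qtl)
      }
      g_poly <- drop(crossprod(L, rnorm(n)))
      v_p_target <- if (v_q > 0) v_q * (1 - config$qtl_frac) / config$qtl_frac
        else if (h2 > 0) 1 else 0
      g_poly <- if (v_p_target > 0 && var(g_poly) > 0)
        g_poly * sqrt(v_p_target / var(g_poly)) else rep(0, n)
      g <- g_qtl + g_poly
      v_g <- var(g)
      e <- rnorm(n)
      v_e_target <- if (h2 > 0 && v_g > 0) v_g * (1 - h2) / h2 else 1
      e <- if (v_e_target > 0) e * sqrt(v_e_target / var(e)) else e * 0
      value <- g + e
      list(
        pheno = tibble(cultivar_id = cultivars(hy_geno), trait = tr,
                       value = unname(value)),
        qtl_truth = mutate(qt, var_explained = if (v_g + v_e_target > 0)
          v_q / (v_g + v_e_target) else 0) |>
          left_join(select(mk, "marker_id", qtl_position_bp = "position_bp"),
                    by = "marker_id") |>
          select("trait", "marker_id", "chromosome",
                 position_bp = "qtl_position_bp", "effect", "var_explained")
      )
    })
    list(pheno = list_rbind(map(out, "pheno")),
         qtl_truth = list_rbind(map(out, "qtl_truth")))
  })
}

#' Simulate a complete study population
#'
#' Runs [simulate_parents()], [simulate_admixed()] and
#' [simulate_phenotypes()] with sub-seeds derived from `seed`, and builds a
#' candidate-feature catalog holding one `GENE` at each planted QTL (in the
#' trait's category) plus decoy features elsewhere.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return List `geno`, `panel`, `pheno`, `features`, `truth` (markers,
#'   origin tracks, skew regions, QTLs, seed).
#' @export
simulate_population <- function(config = sim_config(), seed = NULL) {
  seeds <- if (is.null(seed)) rep(list(NULL), 4) else as.list(seed %% 2e9 + 1:4)
  parents <- simulate_parents(config, seeds[[1]])
  adm <- simulate_admixed(parents, config, seeds[[2]])
  hy_ids <- adm$panel$cultivar_id[adm$panel$group == "HY"]
  hy_geno <- geno_subset(adm$geno, hy_ids)
  ph <- simulate_phenotypes(hy_geno, config, seeds[[3]],
                            marker_truth = parents$truth)
  features <- with_seed(seeds[[4]], {
    planted <- ph$qtl_truth |>
      mutate(feature_id = paste0("gene_at_", .data$marker_id),
             feature_kind = "GENE",
             start_bp = pmax(1L, as.integer(.data$position_bp - 10e3)),
             end_bp = as.integer(.data$position_bp + 10e3),
             trait_category = .data$trait) |>
      select("feature_id", "feature_kind", "chromosome", "start_bp",
             "end_bp", "trait_category")
    n_decoy <- 20
    decoy_chr <- sample(config$chromosomes, n_decoy, replace = TRUE)
    decoy_start <- sample.int(config$chromosome_length_bp - 2e5, n_decoy)
    decoys <- tibble(
      feature_id = sprintf("decoy_%02d", seq_len(n_decoy)),
      feature_kind = sample(c("GENE", "QTL"), n_decoy, replace = TRUE),
      chromosome = decoy_chr,
      start_bp = decoy_start,
      end_bp = decoy_start + sample.int(2e5, n_decoy),
      trait_category = sample(c("decoy_category", unique(ph$pheno$trait)),
                              n_decoy, replace = TRUE))
    bind_rows(planted, decoys)
  })
  list(geno = adm$geno, panel = adm$panel, pheno = ph$pheno,
       features = features,
       truth = c(adm$truth, list(qtls = ph$qtl_truth, seed = seed)))
}

#' Write a simulated fixture bundle to disk
#'
#' Writes `genotypes.tsv`, `panel.csv`, `phenotypes.csv`, `features.bed`
#' and `truth.json` so the whole pipeline can be exercised from files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @param seed Optional integer seed.
#' @param force Overwrite an existing directory.
#' @return Invisibly, the `simulate_population()` result.
#' @export
generate_fixture <- function(config = sim_config(), dir, seed = NULL,
                             force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force) {
    abort(sprintf("output directory '%s' exists; use force = TRUE", dir))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_population(config, seed)
  write_genotypes_tabular(sim$geno, file.path(dir, "genotypes.tsv"))
  write_panel(sim$panel, file.path(dir, "panel.csv"))
  write_phenotypes(sim$pheno, file.path(dir, "phenotypes.csv"))
  write_features_bed(sim$features, file.path(dir, "features.bed"))
  truth <- list(
    seed = seed,
    skew_regions = sim$truth$skew_regions,
    qtls = sim$truth$qtls,
    origin_tracks = sim$truth$origin_tracks,
    markers = sim$truth$markers
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sim)
}
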