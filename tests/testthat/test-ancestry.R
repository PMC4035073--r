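# builds a parents+HY genotype set with exact group frequencies per marker:
# freqs given as alt-allele fractions; pool sizes chosen so counts are whole
freq_geno <- function(f_pd, f_po, f_hy, n_pd = 20, n_po = 20, n_hy = 20) {
  m <- length(f_pd)
  mk <- toy_markers(m)
  col <- function(f, n) c(rep(2L, round(f * n)), rep(0L, n - round(f * n)))
  calls <- rbind(
    vapply(f_pd, col, integer(n_pd), n = n_pd),
    vapply(f_po, col, integer(n_po), n = n_po),
    vapply(f_hy, col, integer(n_hy), n = n_hy)
  )
  ids <- c(sprintf("pd%02d", 1:n_pd), sprintf("po%02d", 1:n_po),
           sprintf("hy%02d", 1:n_hy))
  list(geno = geno_matrix(calls, mk, ids),
       panel = tibble::tibble(
         cultivar_id = ids,
         group = rep(c("PD", "PO_INDICA", "HY"), c(n_pd, n_po, n_hy))))
}

test_that("discriminating SNPs require a strictly > 0.7 frequency difference", {
  fx <- freq_geno(f_pd = c(0.95, 0.00, 0.10),
                  f_po = c(0.10, 0.70, 0.90),
                  f_hy = c(0.50, 0.50, 0.50))
  disc <- find_discriminating_snps(fx$geno, fx$panel)
  # m01: diff 0.85 -> in, indica allele is the PO-major (= ref here)
  # m02: diff exactly 0.70 -> out (strict); m03: diff 0.80 -> in
  expect_setequal(disc$marker_id, c("m01", "m03"))
  m1 <- disc[disc$marker_id == "m01", ]
  expect_equal(m1$indica_allele, "A")           # ref, since PO alt freq 0.10
  expect_equal(m1$freq_po_indica, 0.90)         # indica-allele frequency
  expect_equal(m1$freq_pd, 0.05)
  expect_equal(m1$freq_hy, 0.50)
})

test_that("discriminating set equals a brute-force per-marker oracle", {
  sim <- simulate_population(small_sim_config(), seed = 6)
  disc <- find_discriminating_snps(sim$geno, sim$panel)
  pd <- sim$panel$cultivar_id[sim$panel$group == "PD"]
  po <- sim$panel$cultivar_id[sim$panel$group == "PO_INDICA"]
  f_pd <- allele_frequency(sim$geno, pd)
  f_po <- allele_frequency(sim$geno, po)
  keep <- !is.na(f_pd$freq_alt) & !is.na(f_po$freq_alt) &
    abs(f_pd$freq_alt - f_po$freq_alt) > 0.7
  expect_setequal(disc$marker_id, f_pd$marker_id[keep])
})

test_that("adjusted-HY arithmetic follows the formula exactly", {
  expect_equal(adjusted_hy_frequency(1, 0, 1), 1)
  expect_equal(adjusted_hy_frequency(0, 0, 1), 0)
  expect_equal(adjusted_hy_frequency(0.5, 0.1, 0.9), 0.3)
  # unclamped lower range
  expect_equal(adjusted_hy_frequency(0, 1, 0), -2)
  # with fully fixed parents the indica- and japonica-oriented statistics
  # are complements: adj_indica + adj_japonica = 1
  withr::local_seed(31)
  for (i in 1:50) {
    hy <- runif(1)
    adj_ind <- adjusted_hy_frequency(hy, 0, 1)
    adj_jap <- adjusted_hy_frequency(1 - hy, 0, 1)
    expect_equal(adj_ind + adj_jap, 1, tolerance = 1e-12)
  }
})

test_that("window summaries tile the map and match a quantile oracle", {
  snps <- tibble::tibble(marker_id = sprintf("s%02d", 1:5),
                         chromosome = "chr1",
                         position_bp = seq(100L, 500L, by = 100L),
                         adjusted_hy = c(0.1, 0.2, 0.3, 0.4, 0.5))
  w <- window_summary(snps, window = 5)
  expect_equal(nrow(w), 1L)
  expect_equal(w$median, 0.3)
  expect_false(w$partial)
  same <- dplyr::mutate(snps, adjusted_hy = 0.7)
  w2 <- window_summary(same, window = 5)
  expect_equal(c(w2$q25, w2$median, w2$q75), c(0.7, 0.7, 0.7))
  # remainder window flagged partial; fewer markers than the window too
  snps7 <- tibble::tibble(marker_id = sprintf("s%02d", 1:7), chromosome = "chr1",
                          position_bp = seq(100L, 700L, by = 100L),
                          adjusted_hy = rnorm(7))
  w3 <- window_summary(snps7, window = 5)
  expect_equal(w3$n_snps, c(5L, 2L))
  expect_equal(w3$partial, c(FALSE, TRUE))
  withr::local_seed(17)
  for (i in 1:20) {
    v <- rnorm(5)
    w4 <- window_summary(dplyr::mutate(snps, adjusted_hy = v), window = 5)
    expect_equal(w4$q25, quantile_oracle(v, 0.25), tolerance = 1e-12)
    expect_equal(w4$median, quantile_oracle(v, 0.5), tolerance = 1e-12)
    expect_equal(w4$q75, quantile_oracle(v, 0.75), tolerance = 1e-12)
  }
})

test_that("skew calls are strict, constant-shift invariant and mergeable", {
  mkw <- function(vals) {
    n <- length(vals)
    tibble::tibble(marker_id = sprintf("s%02d", seq_len(5 * n)),
                   chromosome = "chr1",
                   position_bp = seq(100L, by = 100L, length.out = 5 * n),
                   adjusted_hy = rep(vals, each = 5))
  }
  # all windows identical: degenerate band, everything NEUTRAL
  w <- call_skewed_regions(window_summary(mkw(rep(0.4, 6)), 5))
  expect_true(all(w$skew == "NEUTRAL"))
  # one window at +1 among windows at zero
  vals <- c(0, 0, 0, 0, 0, 1)
  w2 <- call_skewed_regions(window_summary(mkw(vals), 5))
  expect_equal(sum(w2$skew == "INDICA_SKEWED"), 1L)
  expect_equal(sum(w2$skew == "JAPONICA_SKEWED"), 0L)
  expect_equal(w2$skew[which.max(w2$median)], "INDICA_SKEWED")
  # adding a constant to every adjusted value leaves calls unchanged
  w3 <- call_skewed_regions(window_summary(mkw(vals + 5), 5))
  expect_equal(w2$skew, w3$skew)
  # adjacent same-class windows merge into one interval
  vals4 <- c(0, 0.01, 1, 1.1, -0.01, 0.02)
  w4 <- call_skewed_regions(window_summary(mkw(vals4), 5))
  iv <- attr(w4, "intervals")
  expect_equal(nrow(iv[iv$skew == "INDICA_SKEWED", ]), 1L)
  expect_equal(iv$n_windows[iv$skew == "INDICA_SKEWED"], 2L)
})

test_that("skew caller recovers planted introgression regions", {
  sim <- simulate_population(small_sim_config(), seed = 9)
  prof <- ancestry_profile(sim$geno, sim$panel)
  reg <- sim$truth$skew_regions
  iv <- prof$intervals
  for (r in seq_len(nrow(reg))) {
    expect_true(any(iv$chromosome == reg$chromosome[r] &
                      iv$skew == "INDICA_SKEWED" &
                      iv$start_bp <= reg$end_bp[r] &
                      iv$end_bp >= reg$start_bp[r]),
                label = sprintf("planted region %d overlapped", r))
  }
  # band quantiles are ordered
  expect_lte(prof$band["q25"], prof$band["median"])
  expect_lte(prof$band["median"], prof$band["q75"])
})

test_that("genome-type classification follows the indica fraction", {
  fx <- freq_geno(f_pd = rep(0, 10), f_po = rep(1, 10), f_hy = rep(0.5, 10))
  disc <- find_discriminating_snps(fx$geno, fx$panel)
  expect_equal(nrow(disc), 10L)
  po1 <- fx$panel$cultivar_id[fx$panel$group == "PO_INDICA"][1]
  cls <- classify_genome_types(fx$geno, disc,
                               cultivar_ids = c(po1, "pd01", "hy01"))
  expect_equal(cls$class[cls$cultivar_id == po1], "IN")
  expect_equal(cls$indica_fraction[cls$cultivar_id == po1], 1)
  expect_equal(cls$class[cls$cultivar_id == "pd01"], "JA")
  # hets count one half
  calls <- dosage(fx$geno)
  calls["hy01", ] <- 1L
  g2 <- geno_matrix(calls, marker_map(fx$geno), cultivars(fx$geno))
  cls2 <- classify_genome_types(g2, disc, cultivar_ids = "hy01")
  expect_equal(cls2$indica_fraction, 0.5)
  expect_equal(cls2$class, "MX")
  # classification invariant to marker order
  disc_shuffled <- disc[sample(nrow(disc)), ]
  cls3 <- classify_genome_types(fx$geno, disc_shuffled,
                                cultivar_ids = c(po1, "pd01", "hy01"))
  expect_equal(dplyr::arrange(cls3, cultivar_id)$class,
               dplyr::arrange(cls, cultivar_id)$class)
})

test_that("classes partition the HY set and track planted mosaics", {
  sim <- simulate_population(small_sim_config(het_rate = 0, missing_rate = 0),
                             seed = 10)
  disc <- find_discriminating_snps(sim$geno, sim$panel)
  hy <- sim$panel$cultivar_id[sim$panel$group == "HY"]
  cls <- classify_genome_types(sim$geno, disc, cultivar_ids = hy)
  expect_equal(sum(table(cls$class)), length(hy))
  # indica fraction tracks the truth origin fraction at discriminating SNPs
  tr <- sim$truth$origin_tracks
  for (cv in hy[1:5]) {
    cvtr <- tr[tr$cultivar_id == cv, ]
    at <- dplyr::inner_join(disc, cvtr,
                            by = dplyr::join_by(chromosome,
                                                position_bp >= start_bp,
                                                position_bp <= end_bp))
    truth_frac <- mean(at$origin == "INDICA")
    got <- cls$indica_fraction[cls$cultivar_id == cv]
    expect_lt(abs(got - truth_frac), 0.1)
  }
})

test_that("graphical genotype encodes origin per call", {
  fx <- freq_geno(f_pd = rep(0, 4), f_po = rep(1, 4), f_hy = c(1, 1, 0, 0.5))
  disc <- find_discriminating_snps(fx$geno, fx$panel)
  gg <- graphical_genotype(fx$geno, disc, cultivar_ids = "hy01")
  expect_setequal(gg$origin[gg$marker_id %in% c("m01", "m02")], "INDICA")
  expect_equal(gg$origin[gg$marker_id == "m03"], "JAPONICA")
})
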