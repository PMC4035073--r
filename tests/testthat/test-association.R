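test_that("kinship matches limits and the textbook formula", {
  # two identical inbred cultivars: off-diagonal equals diagonal
  calls <- rbind(c(0L, 2L, 0L, 2L), c(0L, 2L, 0L, 2L),
                 c(2L, 0L, 2L, 0L), c(0L, 0L, 2L, 2L))
  g <- toy_geno(calls)
  K <- kinship(g)
  expect_equal(K[1, 2], K[1, 1], tolerance = 1e-12)
  expect_equal(K, t(K))
  # single marker at p = 0.5: proportional to outer product of centered dosages
  g1 <- toy_geno(cbind(c(0L, 2L, 0L, 2L)))
  z <- c(-1, 1, -1, 1)
  expect_equal(unname(kinship(g1)), outer(z, z) / 0.5, tolerance = 1e-12)
  # random matrix vs direct double-loop oracle
  withr::local_seed(41)
  n <- 12; m <- 80
  calls2 <- matrix(sample(c(0L, 1L, 2L, NA), n * m, TRUE, c(.4, .1, .4, .1)), n, m)
  g2 <- toy_geno(calls2, markers = toy_markers(m))
  K2 <- kinship(g2)
  p <- colMeans(calls2, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  d <- calls2[, poly, drop = FALSE]
  pj <- p[poly]
  for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- 2 * pj[j]
  oracle <- matrix(0, n, n)
  for (i in 1:n) for (k in 1:n) {
    oracle[i, k] <- sum((d[i, ] - 2 * pj) * (d[k, ] - 2 * pj))
  }
  oracle <- oracle / sum(2 * pj * (1 - pj))
  expect_equal(unname(K2), oracle, tolerance = 1e-10)
})

make_scan_fixture <- function(seed, n = 40, m = 30, beta = 0, noise = 1) {
  withr::with_seed(seed, {
    calls <- matrix(sample(c(0L, 2L), n * m, TRUE), n, m)
    g <- toy_geno(calls, markers = toy_markers(m))
    y <- beta * calls[, ceiling(m / 2)] + rnorm(n, sd = noise)
    pheno <- tibble::tibble(cultivar_id = cultivars(g), trait = "t", value = y)
    list(geno = g, pheno = pheno, target = sprintf("m%02d", ceiling(m / 2)))
  })
}

test_that("with identity kinship the MLM scan collapses to OLS", {
  fx <- make_scan_fixture(51)
  scan <- suppressMessages(
    mlm_scan(fx$pheno, fx$geno, K = diag(nrow(fx$pheno)), maf_min = 0))
  res <- tidy(scan)
  for (i in seq_len(nrow(res))) {
    if (is.na(res$p_value[i])) next
    d <- dosage(fx$geno)[, res$marker_id[i]]
    ols <- summary(lm(fx$pheno$value ~ d))$coefficients
    expect_equal(res$p_value[i], ols["d", "Pr(>|t|)"],
                 tolerance = 1e-6)
    expect_equal(res$beta[i], ols["d", "Estimate"], tolerance = 1e-6)
  }
})

test_that("a constant phenotype yields no signal", {
  fx <- make_scan_fixture(52)
  fx$pheno$value <- 7
  scan <- suppressMessages(mlm_scan(fx$pheno, fx$geno, K = diag(nrow(fx$pheno)),
                                    maf_min = 0))
  res <- tidy(scan)
  expect_true(all(abs(res$beta) < 1e-8, na.rm = TRUE))
  expect_true(all(res$p_value > 0.99 | is.na(res$p_value)))
})

test_that("a planted additive signal attains the genome-wide minimum P", {
  fx <- make_scan_fixture(53, beta = 2, noise = 0.5)
  scan <- suppressMessages(mlm_scan(fx$pheno, fx$geno, maf_min = 0.05))
  res <- tidy(scan)
  expect_equal(res$marker_id[which.min(res$p_value)], fx$target)
})

test_that("nominal P is invariant under affine phenotype transformation", {
  fx <- make_scan_fixture(54, beta = 1)
  s1 <- suppressMessages(mlm_scan(fx$pheno, fx$geno, maf_min = 0))
  fx$pheno$value <- 3.7 * fx$pheno$value - 11
  s2 <- suppressMessages(mlm_scan(fx$pheno, fx$geno, maf_min = 0))
  expect_equal(tidy(s1)$p_value, tidy(s2)$p_value, tolerance = 1e-8)
})

test_that("the GLS scan approaches OLS as lambda vanishes", {
  fx <- make_scan_fixture(55, beta = 1)
  scan <- suppressMessages(mlm_scan(fx$pheno, fx$geno, maf_min = 0))
  eng <- scan$engine
  ols_p <- introscan:::gls_scan(eng, 1e-12)$p_value
  lams <- 10^seq(-8, 1, by = 1)
  prev <- introscan:::gls_scan(eng, lams[1])$p_value
  expect_equal(prev, ols_p, tolerance = 1e-6)
  # continuity: successive lambda values give smoothly changing P
  for (l in lams[-1]) {
    cur <- introscan:::gls_scan(eng, l)$p_value
    expect_true(all(is.finite(cur[!is.na(cur)])))
    prev <- cur
  }
})

test_that("permutation P uses the add-one family-wise estimator", {
  fx <- make_scan_fixture(56, n = 30, m = 15, beta = 3, noise = 0.1)
  scan <- suppressMessages(mlm_scan(fx$pheno, fx$geno, maf_min = 0.05))
  scan <- permutation_p(scan, n_perm = 999, seed = 2)
  res <- tidy(scan)
  # the planted marker dominates every permuted maximum
  expect_equal(min(res$perm_p, na.rm = TRUE), 1 / 1000)
  expect_true(all(res$perm_p >= 1 / 1000, na.rm = TRUE))
  # monotone: larger F never gets larger perm P
  ord <- order(res$f_stat, decreasing = TRUE)
  pp <- res$perm_p[ord]
  expect_true(all(diff(pp[!is.na(pp)]) >= 0))
  # determinism under a fixed seed
  s2 <- permutation_p(scan, n_perm = 199, seed = 77)
  s3 <- permutation_p(scan, n_perm = 199, seed = 77)
  expect_equal(tidy(s2)$perm_p, tidy(s3)$perm_p)
  expect_warning(permutation_p(scan, n_perm = 50, seed = 1), "coarse")
})

test_that("skew intersection keeps strictly significant, skewed markers only", {
  sim <- simulate_population(small_sim_config(), seed = 12)
  prof <- ancestry_profile(sim$geno, sim$panel)
  scan <- suppressMessages(mlm_scan(sim$pheno, sim$geno, trait = "trait_a"))
  scan <- permutation_p(scan, n_perm = 199, seed = 5)
  hits <- intersect_with_skew(scan, prof, alpha = 0.01)
  # brute-force oracle over the joined tables
  joined <- dplyr::left_join(tidy(scan),
                             prof$snps[, c("marker_id", "skew")], "marker_id")
  oracle <- joined$marker_id[!is.na(joined$perm_p) & joined$perm_p < 0.01 &
                               !is.na(joined$skew) & joined$skew != "NEUTRAL"]
  expect_setequal(hits$marker_id, oracle)
  # boundary: perm_p exactly at alpha is excluded
  doctored <- tidy(scan)
  sk_marker <- prof$snps$marker_id[prof$snps$skew == "INDICA_SKEWED"][1]
  doctored$perm_p <- ifelse(doctored$marker_id == sk_marker, 0.01, 0.5)
  expect_equal(nrow(intersect_with_skew(doctored, prof, alpha = 0.01)), 0L)
  doctored$perm_p <- ifelse(doctored$marker_id == sk_marker, 0.00999, 0.5)
  expect_equal(intersect_with_skew(doctored, prof, alpha = 0.01)$marker_id,
               sk_marker)
})

test_that("candidate lookup uses a closed 4-Mb window with gene-first fallback", {
  hits <- tibble::tibble(marker_id = "q1", chromosome = "chr1",
                         position_bp = 10e6)
  feats <- tibble::tibble(
    feature_id = c("at_snp", "edge", "far", "qtl_near"),
    feature_kind = c("GENE", "GENE", "GENE", "QTL"),
    chromosome = "chr1",
    start_bp = as.integer(c(10e6, 12e6, 12e6 + 1, 9e6)),
    end_bp = as.integer(c(10e6, 12.5e6, 13e6, 11e6)),
    trait_category = "yield")
  rep <- candidate_lookup(hits, feats, trait_category = "yield")
  expect_setequal(na.omit(rep$feature_id), c("at_snp", "edge"))
  expect_equal(rep$distance_bp[rep$feature_id == "at_snp"], 0L)
  # gene at exactly pos + 2 Mb is inside the closed window
  expect_true("edge" %in% rep$feature_id)
  # QTL fallback fires only when no gene overlaps
  feats_qtl <- feats[feats$feature_kind == "QTL", ]
  rep2 <- candidate_lookup(hits, feats_qtl, trait_category = "yield")
  expect_equal(na.omit(rep2$feature_id), "qtl_near", ignore_attr = TRUE)
  expect_warning(candidate_lookup(hits, feats, trait_category = "nonesuch"),
                 "not in the catalog")
})

test_that("candidate lookup equals a brute-force interval oracle", {
  withr::local_seed(61)
  for (i in 1:20) {
    hits <- tibble::tibble(marker_id = "h", chromosome = "chrX",
                           position_bp = sample.int(30e6, 1))
    nf <- 30
    st <- sample.int(30e6, nf)
    feats <- tibble::tibble(
      feature_id = sprintf("f%02d", seq_len(nf)),
      feature_kind = sample(c("GENE", "QTL"), nf, TRUE),
      chromosome = sample(c("chrX", "chrY"), nf, TRUE),
      start_bp = st, end_bp = st + sample.int(5e5, nf),
      trait_category = "c")
    rep <- candidate_lookup(hits, feats, trait_category = "c")
    ws <- max(1, hits$position_bp - 2e6); we <- hits$position_bp + 2e6
    ov <- feats[feats$chromosome == "chrX" & feats$start_bp <= we &
                  feats$end_bp >= ws, ]
    oracle <- if (any(ov$feature_kind == "GENE")) {
      ov$feature_id[ov$feature_kind == "GENE"]
    } else ov$feature_id[ov$feature_kind == "QTL"]
    if (!length(oracle)) {
      expect_true(all(is.na(rep$feature_id)))
    } else {
      expect_setequal(rep$feature_id, oracle)
    }
  }
})

test_that("allele-effect tables report per-class means and sds", {
  calls <- cbind(c(0L, 0L, 0L, 2L, 2L, 2L))
  g <- toy_geno(calls, cultivar_ids = letters[1:6])
  pheno <- tibble::tibble(cultivar_id = letters[1:6], trait = "t",
                          value = c(1, 2, 3, 4, 5, 6))
  tab <- allele_effect_table(pheno, g, "m01")
  expect_equal(tab$mean[tab$allele_class == "ref"], 2)
  expect_equal(tab$mean[tab$allele_class == "alt"], 5)
  expect_equal(tab$sd, c(1, 1), ignore_attr = TRUE)
  # a single-cultivar class has undefined sd; an absent class is empty
  g2 <- toy_geno(cbind(c(0L, 0L, 0L, 0L, 0L, 2L)), cultivar_ids = letters[1:6])
  tab2 <- allele_effect_table(pheno, g2, "m01")
  expect_true(is.na(tab2$sd[tab2$allele_class == "alt"]))
  expect_equal(tab2$n[tab2$allele_class == "alt"], 1L)
  # hets are excluded from the table
  g3 <- toy_geno(cbind(c(0L, 0L, 1L, 1L, 2L, 2L)), cultivar_ids = letters[1:6])
  tab3 <- allele_effect_table(pheno, g3, "m01")
  expect_equal(tab3$n, c(2L, 2L), ignore_attr = TRUE)
  # additive QTL: homozygote class means differ by about 2 beta
  fx <- make_scan_fixture(62, n = 60, m = 20, beta = 1.5, noise = 0.3)
  scan <- suppressMessages(mlm_scan(fx$pheno, fx$geno, maf_min = 0))
  b <- tidy(scan)$beta[tidy(scan)$marker_id == fx$target]
  tab4 <- allele_effect_table(fx$pheno, fx$geno, fx$target)
  gap <- abs(diff(tab4$mean))
  expect_lt(abs(gap - 2 * b), 0.5)
})

test_that("tidy and glance summarise a scan", {
  fx <- make_scan_fixture(63)
  scan <- suppressMessages(mlm_scan(fx$pheno, fx$geno, maf_min = 0))
  expect_s3_class(tidy(scan), "tbl_df")
  gl <- glance(scan)
  expect_equal(gl$n, 40L)
  expect_equal(gl$n_markers, nrow(tidy(scan)))
  expect_true(gl$h2 >= 0 && gl$h2 <= 1)
})
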