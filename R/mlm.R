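#' Marker-based kinship matrix (VanRaden)
#'
#' Centered-dosage cross-product scaled by `sum(2 p (1 - p))` over
#' polymorphic markers. Missing dosages are mean-imputed per marker for
#' this computation only.
#'
#' @param geno A [geno_matrix()].
#' @param cultivar_ids,marker_ids Optional subsets.
#' @return Symmetric positive semi-definite cultivar x cultivar matrix.
#' @export
kinship <- function(geno, cultivar_ids = NULL, marker_ids = NULL) {
  d <- dosage(geno, cultivar_ids, marker_ids)
  if (nrow(d) < 2) abort("kinship needs at least 2 cultivars")
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) abort("no polymorphic markers for kinship")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- 2 * p[j]
  z <- sweep(d, 2, 2 * p)
  tcrossprod(z) / sum(2 * p * (1 - p))
}

# P3D/EMMAX engine: one REML fit of the null model y = mu (+ covariates) + u + e
# with u ~ (0, sg2 K), then per-marker GLS F-tests at the fitted variance
# ratio. Built once so permutation scans can reuse the eigendecomposition.
mlm_engine <- function(y, M, K, covariates = NULL) {
  n <- length(y)
  X0 <- cbind(`(Intercept)` = rep(1, n), covariates)
  eig <- eigen(K, symmetric = TRUE)
  dvals <- pmax(eig$values, 0)
  U <- eig$vectors
  list(n = n, p0 = ncol(X0),
       Uty = crossprod(U, y), UtX0 = crossprod(U, X0),
       UtM = crossprod(U, M), U = U, d = dvals,
       marker_id = colnames(M))
}

# restricted log-likelihood (up to a constant) at variance ratio
# lambda = sg2/se2, profiled over se2 and the fixed effects
reml_ll <- function(log_lambda, eng, Uty = eng$Uty) {
  h <- exp(log_lambda) * eng$d + 1
  w <- 1 / sqrt(h)
  ys <- Uty * w
  Xs <- eng$UtX0 * w
  xtx <- crossprod(Xs)
  b <- solve(xtx, crossprod(Xs, ys))
  rss <- max(sum((ys - Xs %*% b)^2), 1e-300)
  df <- eng$n - eng$p0
  -0.5 * (df * log(rss / df) + sum(log(h)) + determinant(xtx)$modulus[1])
}

fit_lambda <- function(eng, Uty = eng$Uty, interval = c(-10, 10)) {
  opt <- optimize(reml_ll, interval = interval, eng = eng, Uty = Uty,
                  maximum = TRUE, tol = 1e-6)
  exp(opt$maximum)
}

# vectorised GLS scan at a fixed lambda; returns beta, se, F and the
# residual df, with NA where the marker has no variance after projection
gls_scan <- function(eng, lambda, Uty = eng$Uty) {
  w <- 1 / sqrt(lambda * eng$d + 1)
  ys <- drop(Uty) * w
  Xs <- eng$UtX0 * w
  Ms <- eng$UtM * w
  q <- qr(Xs)
  ry <- qr.resid(q, ys)
  # phenotype fully explained by the null model: no marker carries signal
  if (sum(ry^2) < 1e-12 * (sum(ys^2) + 1e-12)) {
    m <- ncol(eng$UtM)
    return(list(beta = rep(0, m), se = rep(NA_real_, m),
                f_stat = rep(0, m), df = eng$n - eng$p0 - 1,
                p_value = rep(1, m)))
  }
  rM <- qr.resid(q, Ms)
  mm <- colSums(rM^2)
  my <- colSums(rM * ry)
  rss0 <- sum(ry^2)
  df <- eng$n - eng$p0 - 1
  beta <- unname(ifelse(mm > 1e-10, my / mm, NA_real_))
  rss1 <- unname(rss0 - ifelse(mm > 1e-10, my^2 / mm, 0))
  sigma2 <- rss1 / df
  # a zero-residual fit with a zero slope carries no evidence, not infinite
  fstat <- ifelse(unname(mm) > 1e-10,
                  ifelse(sigma2 > 0, beta^2 * unname(mm) / sigma2,
                         ifelse(abs(beta) < 1e-12, 0, Inf)),
                  NA_real_)
  list(beta = beta, se = unname(sqrt(sigma2 / mm)), f_stat = fstat, df = df,
       p_value = pf(fstat, 1, df, lower.tail = FALSE))
}

#' Mixed-linear-model association scan
#'
#' Fits `y = mu + x b + u + e` with polygenic effect `u ~ (0, sg2 K)` and
#' residual `e ~ (0, se2 I)`. The variance ratio `lambda = sg2/se2` is
#' estimated once on the null (no-marker) model by REML over `log(lambda)`
#' in `[-10, 10]` (P3D/EMMAX), then every marker is tested by a
#' generalised-least-squares F-test at that ratio. With `K` equal to the
#' identity the model collapses to ordinary least squares.
#'
#' @param pheno Long phenotype tibble `cultivar_id`, `trait`, `value`.
#' @param geno A [geno_matrix()].
#' @param trait Trait name; may be omitted when `pheno` holds one trait.
#' @param K Kinship matrix (default: [kinship()] on the phenotyped
#'   cultivars over all markers).
#' @param marker_ids Markers to test. Default: markers with MAF >= `maf_min`
#'   and call rate >= `call_rate_min` among the phenotyped lines; the count
#'   is reported.
#' @param covariates Optional numeric matrix of fixed covariates (rows
#'   named by cultivar).
#' @param maf_min,call_rate_min Default marker-set filters (0.05, 0.95).
#' @return Object of class `mlm_scan` with `$results` (tibble `marker_id`,
#'   `chromosome`, `position_bp`, `maf`, `beta`, `se`, `f_stat`, `p_value`,
#'   `neglog10_p`), `$trait`, `$lambda`, `$h2` (`lambda/(1+lambda)`), `$n`.
#'   Monomorphic markers among the phenotyped lines are reported with `NA`
#'   statistics.
#' @export
mlm_scan <- function(pheno, geno, trait = NULL, K = NULL, marker_ids = NULL,
                     covariates = NULL, maf_min = 0.05, call_rate_min = 0.95) {
  pheno <- as_tibble(pheno)
  if (is.null(trait)) {
    tr <- unique(pheno$trait)
    if (length(tr) != 1) abort("pheno holds several traits; pass `trait`")
    trait <- tr
  }
  ph <- filter(pheno, .data$trait == !!trait, !is.na(.data$value),
               .data$cultivar_id %in% cultivars(geno))
  if (nrow(ph) < 10) abort("need >= 10 cultivars with phenotype and genotype")
  ids <- ph$cultivar_id
  y <- setNames(ph$value, ids)
  if (is.null(marker_ids)) {
    fr <- allele_frequency(geno, ids)
    m <- pmin(fr$freq_alt, fr$freq_ref)
    cr <- fr$n_called / length(ids)
    marker_ids <- fr$marker_id[!is.na(m) & m >= maf_min & cr >= call_rate_min]
    inform(sprintf("association marker set: %d markers (MAF >= %g, call rate >= %g)",
                   length(marker_ids), maf_min, call_rate_min))
  }
  M <- dosage(geno, ids, marker_ids)
  pm <- colMeans(M, na.rm = TRUE)
  for (j in seq_len(ncol(M))) M[is.na(M[, j]), j] <- pm[j]
  mono <- apply(M, 2, function(x) var(x) < 1e-12)
  if (any(mono)) {
    inform(sprintf("%d monomorphic marker(s) among phenotyped lines skipped",
                   sum(mono)))
  }
  if (is.null(K)) K <- kinship(geno, ids)
  if (is.null(dimnames(K))) {
    if (!all(dim(K) == length(ids))) abort("unnamed K must match the phenotyped lines")
  } else {
    K <- K[ids, ids]
  }
  if (!is.null(covariates)) covariates <- as.matrix(covariates)[ids, , drop = FALSE]
  eng <- mlm_engine(y, M[, !mono, drop = FALSE], K, covariates)
  lambda <- fit_lambda(eng)
  sc <- gls_scan(eng, lambda)
  res <- tibble(marker_id = eng$marker_id, beta = sc$beta, se = sc$se,
                f_stat = sc$f_stat, p_value = sc$p_value) |>
    mutate(neglog10_p = -log10(.data$p_value))
  res <- tibble(marker_id = marker_ids) |>
    left_join(res, by = "marker_id") |>
    left_join(select(geno$markers, "marker_id", "chromosome", "position_bp"),
              by = "marker_id") |>
    mutate(maf = unname(pmin(pm[.data$marker_id], 2 - pm[.data$marker_id]) / 2)) |>
    select("marker_id", "chromosome", "position_bp", "maf", "beta", "se",
           "f_stat", "p_value", "neglog10_p")
  structure(
    list(results = res, trait = trait, lambda = lambda,
         h2 = lambda / (1 + lambda), n = length(ids), cultivar_ids = ids,
         engine = eng),
    class = "mlm_scan"
  )
}

#' @export
print.mlm_scan <- function(x, ...) {
  cat(sprintf(
    "<mlm_scan> trait '%s': %d markers, %d lines; lambda = %.3g (pseudo-h2 = %.2f)\n",
    x$trait, nrow(x$results), x$n, x$lambda, x$h2))
  top <- dplyr::slice_min(x$results, .data$p_value, n = 3, with_ties = FALSE)
  cat(sprintf("  top: %s\n", paste0(top$marker_id, " (-log10 P = ",
                                    sprintf("%.2f", top$neglog10_p), ")",
                                    collapse = ", ")))
  if (!is.null(x$n_perm)) {
    cat(sprintf("  permutation P from %d permutations (family-wise max-F)\n",
                x$n_perm))
  }
  invisible(x)
}

#' Family-wise permutation P-values for an association scan
#'
#' Permutes the phenotype vector across cultivars `n_perm` times; each
#' permutation re-estimates the variance ratio and records the genome-wide
#' maximum F. The empirical P for a marker is
#' `(1 + number of permutations whose max F >= its observed F) / (n_perm + 1)`
#' — a family-wise (experiment-wise) error rate in the spirit of
#' max-statistic permutation tests.
#'
#' @param scan An [mlm_scan()] object.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @return The scan with a `perm_p` column added to `$results` and fields
#'   `$n_perm`, `$perm_max_f` (the null max-F sample).
#' @export
permutation_p <- function(scan, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(scan, "mlm_scan"))
  if (n_perm < 100) warn("n_perm < 100: permutation P resolution is coarse")
  eng <- scan$engine
  y <- drop(eng$U %*% eng$Uty)   # original phenotype, reconstructed
  max_f <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      Uty_b <- crossprod(eng$U, sample(y))
      lam_b <- fit_lambda(eng, Uty = Uty_b)
      sc <- gls_scan(eng, lam_b, Uty = Uty_b)
      max(sc$f_stat, na.rm = TRUE)
    }, numeric(1))
  })
  obs <- scan$results$f_stat
  perm_p <- vapply(obs, function(f) {
    if (is.na(f)) return(NA_real_)
    (1 + sum(max_f >= f)) / (n_perm + 1)
  }, numeric(1))
  scan$results$perm_p <- perm_p
  scan$n_perm <- n_perm
  scan$perm_max_f <- max_f
  scan
}

#' @describeIn mlm_scan `tidy()` returns the per-marker result tibble.
#' @param x An `mlm_scan` object.
#' @param ... Unused.
#' @method tidy mlm_scan
#' @export
tidy.mlm_scan <- function(x, ...) x$results

#' @describeIn mlm_scan `glance()` returns a one-row model summary.
#' @method glance mlm_scan
#' @export
glance.mlm_scan <- function(x, ...) {
  tibble(trait = x$trait, n = x$n, n_markers = nrow(x$results),
         lambda = x$lambda, h2 = x$h2,
         min_p = min(x$results$p_value, na.rm = TRUE),
         n_perm = if (is.null(x$n_perm)) NA_integer_ else x$n_perm)
}
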