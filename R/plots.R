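#' Plot the LD subset-size curve
#'
#' Mean complete LD per panel size with standard-error bars across
#' replicates; the plateau indicates the panel size beyond which extra
#' markers add little adjacent-pair LD information.
#'
#' @param object An [ld_subset_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ld_curve
#' @export
autoplot.ld_curve <- function(object, ...) {
  summ <- attr(object, "summary")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$panel_size, y = .data$mean_ld)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_ld - .data$se_ld,
                                        ymax = .data$mean_ld + .data$se_ld),
                           width = 0, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Panel size (SNPs)",
                  y = expression("Mean complete LD (0 < " * Delta^2 * " < 1)")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ld_curve
#' @param curve An [ld_subset_curve()] result.
#' @export
plot_ld_curve <- function(curve, ...) autoplot.ld_curve(curve, ...)

#' Plot the adjusted-HY ancestry profile
#'
#' Window medians along each chromosome with the genome-wide 25th-75th
#' percentile band; windows outside the band are the skewed-region calls.
#'
#' @param object An [ancestry_profile()].
#' @param ... Unused.
#' @return A ggplot faceted by chromosome.
#' @method autoplot ancestry_profile
#' @export
autoplot.ancestry_profile <- function(object, ...) {
  w <- mutate(object$windows, mid_bp = (.data$start_bp + .data$end_bp) / 2)
  band <- object$band
  ggplot2::ggplot(w, ggplot2::aes(x = .data$mid_bp / 1e6, y = .data$median)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = band["q25"], ymax = band["q75"],
                      alpha = 0.25, fill = "grey50") +
    ggplot2::geom_hline(yintercept = band["median"], linetype = "dashed") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.3, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$skew), size = 0.8) +
    ggplot2::scale_colour_manual(values = c(INDICA_SKEWED = "firebrick",
                                            JAPONICA_SKEWED = "navy",
                                            NEUTRAL = "grey40")) +
    ggplot2::facet_wrap(~chromosome, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "Adjusted HY (window median)",
                  colour = "Skew call") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ancestry_profile
#' @param profile An [ancestry_profile()].
#' @export
plot_ancestry_profile <- function(profile, ...) autoplot.ancestry_profile(profile, ...)

#' Graphical-genotype tile plot
#'
#' One row per cultivar, one tile per discriminating SNP, coloured by
#' parental origin — the chromosome-long origin tracks used to eyeball
#' genome types and introgressed regions.
#'
#' @param gg Output of [graphical_genotype()].
#' @param ... Unused.
#' @return A ggplot faceted by chromosome.
#' @export
plot_graphical_genotype <- function(gg, ...) {
  ggplot2::ggplot(gg, ggplot2::aes(x = .data$position_bp / 1e6,
                                   y = .data$cultivar_id,
                                   fill = .data$origin)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(INDICA = "firebrick",
                                          JAPONICA = "navy",
                                          HET = "goldenrod", MISSING = "grey85")) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chromosome),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = NULL, fill = "Origin") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}

#' Manhattan plot of an association scan
#'
#' @param object An [mlm_scan()] object; when permutation P-values are
#'   present, markers below `alpha` are highlighted and the implied
#'   family-wise threshold drawn.
#' @param alpha Permutation-P significance cutoff (default 0.01).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mlm_scan
#' @export
autoplot.mlm_scan <- function(object, alpha = 0.01, ...) {
  res <- filter(object$results, !is.na(.data$p_value)) |>
    mutate(chrom_f = chrom_order(.data$chromosome))
  p <- ggplot2::ggplot(res, ggplot2::aes(x = .data$position_bp / 1e6,
                                         y = .data$neglog10_p)) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom_f),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = expression(-log[10](italic(P))),
                  title = object$trait) +
    ggplot2::theme_minimal()
  if ("perm_p" %in% names(res)) {
    thr <- quantile(object$perm_max_f, 1 - alpha, names = FALSE)
    thr_p <- -log10(pf(thr, 1, object$engine$n - object$engine$p0 - 1,
                       lower.tail = FALSE))
    p <- p +
      ggplot2::geom_point(ggplot2::aes(colour = .data$perm_p < alpha), size = 0.8) +
      ggplot2::geom_hline(yintercept = thr_p, linetype = "dashed") +
      ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                              `FALSE` = "grey30"),
                                   guide = "none")
  } else {
    p <- p + ggplot2::geom_point(size = 0.8, colour = "grey30")
  }
  p
}

#' @rdname autoplot.mlm_scan
#' @param scan An [mlm_scan()] object.
#' @export
plot_manhattan <- function(scan, alpha = 0.01, ...) autoplot.mlm_scan(scan, alpha = alpha, ...)
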