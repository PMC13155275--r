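#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_hline
#'   geom_errorbarh geom_vline scale_fill_gradient2 labs theme_minimal
#'   facet_wrap
#' @export
ggplot2::autoplot

#' Effect-size heatmap for a phenotypic association battery
#'
#' Tiles of standardised beta per (trait, smoking predictor); cells passing
#' the FDR threshold are marked.
#'
#' @param object A `pheno_battery` result.
#' @param alpha Significance threshold on q-values.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pheno_battery <- function(object, alpha = attr(object, "alpha"), ...) {
  d <- as_tibble(object)
  d$sig <- !is.na(d$qval) & d$qval < (alpha %||% 0.05)
  ggplot(d, aes(x = .data$predictor, y = .data$trait, fill = .data$beta)) +
    geom_tile() +
    geom_point(data = d[d$sig, ], shape = 8, size = 1.5) +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B") +
    labs(x = NULL, y = NULL, fill = expression(beta),
         title = "Smoking-striatal iron associations",
         subtitle = "* = FDR-significant") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-gene significance plot for a cross-GWAS scan
#'
#' -log10 p per gene along the genome, with the Bonferroni threshold line.
#'
#' @param object A `gene_scan` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gene_scan <- function(object, ...) {
  pcol <- if (attr(object, "test") == "coherence") "p_coherent" else "p_fwd"
  d <- as_tibble(object)
  d$neglogp <- -log10(d[[pcol]])
  d$idx <- seq_len(nrow(d))
  ggplot(d, aes(x = .data$idx, y = .data$neglogp)) +
    geom_point() +
    geom_hline(yintercept = -log10(attr(object, "threshold")),
               linetype = "dashed", colour = "red") +
    labs(x = "gene", y = expression(-log[10](P)),
         title = paste("Gene-level", attr(object, "test"), "scan")) +
    theme_minimal()
}

#' Forest plot of IVW causal estimates
#'
#' IVW estimates with 95% confidence intervals per trait pair and direction.
#'
#' @param object An `mr_battery` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_battery <- function(object, ...) {
  d <- as_tibble(object)
  d <- d[d$method == "ivw", ]
  d$pair <- paste(d$exposure, "→", d$outcome)
  ggplot(d, aes(x = .data$beta, y = .data$pair)) +
    geom_vline(xintercept = 0, linetype = "dotted") +
    geom_errorbarh(aes(xmin = .data$beta - 1.96 * .data$se,
                       xmax = .data$beta + 1.96 * .data$se), height = 0.2) +
    geom_point() +
    facet_wrap(~ .data$direction, scales = "free_y", ncol = 1) +
    labs(x = "IVW causal estimate (95% CI)", y = NULL,
         title = "Bidirectional Mendelian randomisation") +
    theme_minimal()
}
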