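#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidy.smokiron
#' @export
tidy.ldsc_fit <- function(x, ...) {
  tibble(
    term = c("h2_1", "h2_2", "intercept_1", "intercept_2", "gencov",
             "cross_intercept", "rg"),
    estimate = c(x$h2_1, x$h2_2, x$intercept_1, x$intercept_2, x$gencov,
                 x$cross_intercept, x$rg),
    std.error = c(x$se_h2_1, x$se_h2_2, NA, NA, x$se_gencov,
                  x$se_cross_intercept, x$se_rg)
  )
}

#' @rdname glance.smokiron
#' @export
glance.ldsc_fit <- function(x, ...) {
  tibble(rg = x$rg, se_rg = x$se_rg, p_rg = x$p_rg,
         cross_intercept = x$cross_intercept, n_snps = x$m,
         n_blocks = x$n_blocks)
}

#' Tidy methods for smokiron result objects
#'
#' Coefficient-level summaries in the broom convention: one row per term
#' with `estimate`, `std.error`, `p.value` columns where they apply.
#'
#' @param x A fitted smokiron object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy.smokiron
NULL

#' Glance methods for smokiron result objects
#'
#' One-row model-level summaries in the broom convention.
#'
#' @param x A fitted smokiron object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @name glance.smokiron
NULL

#' @rdname tidy.smokiron
#' @export
tidy.pheno_battery <- function(x, ...) {
  dplyr::rename(as_tibble(x), term = "predictor", estimate = "beta",
                std.error = "se", p.value = "pval", q.value = "qval")
}

#' @rdname glance.smokiron
#' @export
glance.pheno_battery <- function(x, ...) {
  alpha <- attr(x, "alpha") %||% 0.05
  tibble(n_tests = nrow(x),
         n_significant = sum(x$qval < alpha, na.rm = TRUE),
         alpha = alpha)
}

#' @rdname tidy.smokiron
#' @export
tidy.mr_battery <- function(x, ...) {
  dplyr::rename(as_tibble(x), term = "method", estimate = "beta",
                std.error = "se", p.value = "pval")
}

#' @rdname glance.smokiron
#' @export
glance.mr_battery <- function(x, ...) {
  ivw_rows <- x[x$method == "ivw", ]
  tibble(n_pairs = nrow(ivw_rows),
         n_ivw_significant = sum(ivw_rows$qval < 0.05, na.rm = TRUE),
         min_qval = suppressWarnings(min(ivw_rows$qval, na.rm = TRUE)))
}

#' @rdname tidy.smokiron
#' @export
tidy.gene_scan <- function(x, ...) as_tibble(x)

#' @rdname glance.smokiron
#' @export
glance.gene_scan <- function(x, ...) {
  pcol <- if (attr(x, "test") == "coherence") "p_coherent" else "p_fwd"
  tibble(test = attr(x, "test"), n_genes = nrow(x),
         n_untested = length(attr(x, "untested")),
         threshold = attr(x, "threshold"),
         n_significant = sum(x[[pcol]] < attr(x, "threshold"), na.rm = TRUE),
         rho_ov = attr(x, "rho_ov"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
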