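#' Per-SNP LD scores from a haplotype panel
#'
#' \eqn{\ell_j = \sum_k r^2_{adj}(j,k)} over SNPs k within `window_bp` of
#' SNP j (including j itself), with the small-sample adjustment
#' \eqn{r^2_{adj} = r^2 - (1 - r^2)/(n_{panel} - 2)} so that null pairs
#' contribute zero in expectation.
#'
#' @param panel A `haplotype_panel`, SNPs sorted by position.
#' @param window_bp Window half-width in bp.
#' @return Tibble (snp_id, chrom, pos, ldscore) with attributes `window_bp`
#'   and `n_panel`.
#' @export
ld_scores <- function(panel, window_bp = 1e6) {
  stopifnot(inherits(panel, "haplotype_panel"))
  n_panel <- panel$n_haplotypes
  if (n_panel < 3) stop("panel must contain at least 3 haplotypes")
  map <- panel$map
  if (is.unsorted(order(map$chrom, map$pos))) stop("panel SNPs must be sorted")
  m <- nrow(map)
  r <- stats::cor(t(panel$haps))
  r[is.na(r)] <- 0
  r2adj <- r^2 - (1 - r^2) / (n_panel - 2)
  same_chr <- outer(map$chrom, map$chrom, "==")
  in_win <- abs(outer(map$pos, map$pos, "-")) <= window_bp & same_chr
  ell <- rowSums(r2adj * in_win)
  structure(
    tibble(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
           ldscore = ell),
    window_bp = window_bp, n_panel = n_panel
  )
}

# weighted least squares of y on ell with intercept; returns c(intercept, slope)
.ldsc_wls <- function(ell, y, w) {
  sw <- sqrt(w)
  X <- cbind(1, ell) * sw
  stats::lm.fit(X, y * sw)$coefficients
}

# contiguous equal-count jackknife block ids
.jk_blocks <- function(m, n_blocks) {
  sort(rep_len(seq_len(n_blocks), m))
}

#' Univariate LD-score regression
#'
#' Fits \eqn{E[z_j^2] = intercept + n h^2 \ell_j / M} by two-step weighted
#' least squares: a first unweighted pass estimates the slope, and the second
#' pass weights each SNP by \eqn{1/[\max(\ell_j, 1) \cdot 2 (E[z_j^2])^2]}
#' (LD redundancy times the chi-square variance of the fitted mean).
#' Standard errors come from a delete-one block jackknife over contiguous
#' SNP blocks.
#'
#' @param ss A [sumstats] object.
#' @param ld LD scores from [ld_scores()].
#' @param M Number of SNPs the heritability is spread over (defaults to the
#'   number of matched SNPs).
#' @param n_blocks Jackknife blocks (default 20, sized for toy genomes).
#' @return List with h2, intercept, their ses, and the matched SNP count.
#' @export
fit_univariate <- function(ss, ld, M = NULL, n_blocks = 20) {
  d <- dplyr::inner_join(
    tibble(snp_id = ss$snp_id, z = ss$beta / ss$se, n = ss$n),
    ld[, c("snp_id", "ldscore")], by = "snp_id"
  )
  m <- nrow(d)
  if (m < 2 * n_blocks) stop("need at least ", 2 * n_blocks, " matched SNPs")
  if (is.null(M)) M <- m
  stopifnot(M >= m)
  nbar <- mean(d$n)
  x <- d$ldscore * nbar / M
  y <- d$z^2
  slope0 <- stats::cov(x, y) / stats::var(x)
  pred <- pmax(1 + slope0 * x, 0.1)
  w <- 1 / (pmax(d$ldscore, 1) * 2 * pred^2)
  co <- .ldsc_wls(x, y, w)
  blk <- .jk_blocks(m, n_blocks)
  jk <- vapply(seq_len(n_blocks), function(b) {
    keep <- blk != b
    .ldsc_wls(x[keep], y[keep], w[keep])
  }, numeric(2))
  ses <- sqrt((n_blocks - 1) / n_blocks * rowSums((jk - rowMeans(jk))^2))
  list(h2 = unname(co[2]), intercept = unname(co[1]),
       se_h2 = ses[2], se_intercept = ses[1], m = m, M = M,
       n = nbar, n_blocks = n_blocks)
}

#' Bivariate LD-score regression: genetic covariance and correlation
#'
#' Regresses the z-score product \eqn{z_{1j} z_{2j}} on the LD score: the
#' slope estimates \eqn{\sqrt{n_1 n_2}\, \rho_g / M} and the intercept
#' estimates the test-statistic correlation induced by overlapping
#' participants (`cross_intercept`). The genetic correlation
#' \eqn{r_g = \rho_g / \sqrt{h^2_1 h^2_2}} is assembled from the two
#' univariate fits and clipped to [-1.5, 1.5]; when either heritability
#' estimate is non-positive, rg is reported missing with a warning. All
#' standard errors use the same contiguous block jackknife, and the rg
#' p-value is the normal test of the jackknifed rg.
#'
#' @param ss1,ss2 [sumstats] for the two traits (matched SNP ids).
#' @param ld LD scores from [ld_scores()].
#' @param M SNP count for the heritability scale (default: matched SNPs).
#' @param n_blocks Jackknife blocks.
#' @return Object of class `ldsc_fit`.
#' @export
fit_bivariate <- function(ss1, ss2, ld, M = NULL, n_blocks = 20) {
  f1 <- fit_univariate(ss1, ld, M = M, n_blocks = n_blocks)
  f2 <- fit_univariate(ss2, ld, M = M, n_blocks = n_blocks)
  d <- dplyr::inner_join(
    dplyr::inner_join(
      tibble(snp_id = ss1$snp_id, z1 = ss1$beta / ss1$se, n1 = ss1$n),
      tibble(snp_id = ss2$snp_id, z2 = ss2$beta / ss2$se, n2 = ss2$n),
      by = "snp_id"),
    ld[, c("snp_id", "ldscore")], by = "snp_id"
  )
  m <- nrow(d)
  if (m < 2 * n_blocks) stop("need at least ", 2 * n_blocks, " matched SNPs")
  if (is.null(M)) M <- m
  nn <- sqrt(mean(d$n1) * mean(d$n2))
  x <- d$ldscore * nn / M
  y <- d$z1 * d$z2
  slope0 <- stats::cov(x, y) / stats::var(x)
  # variance of z1 z2 under the fitted means: v1 v2 + (cross mean)^2
  v1 <- pmax(1 + f1$h2 * d$ldscore * mean(d$n1) / M, 0.1)
  v2 <- pmax(1 + f2$h2 * d$ldscore * mean(d$n2) / M, 0.1)
  cmean <- slope0 * x
  w <- 1 / (pmax(d$ldscore, 1) * (v1 * v2 + cmean^2))
  co <- .ldsc_wls(x, y, w)
  gencov <- unname(co[2]); cross_int <- unname(co[1])

  blk <- .jk_blocks(m, n_blocks)
  rg_of <- function(gc, h1, h2) {
    if (h1 <= 0 || h2 <= 0) return(NA_real_)
    max(min(gc / sqrt(h1 * h2), 1.5), -1.5)
  }
  # per-block delete-one re-fits of all three regressions (fixed weights)
  d1 <- dplyr::inner_join(tibble(snp_id = ss1$snp_id, z = ss1$beta / ss1$se),
                          ld[, c("snp_id", "ldscore")], by = "snp_id")
  d2 <- dplyr::inner_join(tibble(snp_id = ss2$snp_id, z = ss2$beta / ss2$se),
                          ld[, c("snp_id", "ldscore")], by = "snp_id")
  x1 <- d1$ldscore * mean(d$n1) / M; y1 <- d1$z^2
  x2 <- d2$ldscore * mean(d$n2) / M; y2 <- d2$z^2
  w1 <- 1 / (pmax(d1$ldscore, 1) * 2 * v1^2)
  w2 <- 1 / (pmax(d2$ldscore, 1) * 2 * v2^2)
  blk1 <- .jk_blocks(nrow(d1), n_blocks); blk2 <- .jk_blocks(nrow(d2), n_blocks)
  jk <- vapply(seq_len(n_blocks), function(b) {
    k <- blk != b; k1 <- blk1 != b; k2 <- blk2 != b
    cb <- .ldsc_wls(x[k], y[k], w[k])
    h1b <- .ldsc_wls(x1[k1], y1[k1], w1[k1])[2]
    h2b <- .ldsc_wls(x2[k2], y2[k2], w2[k2])[2]
    c(cb[1], cb[2], rg_of(cb[2], h1b, h2b))
  }, numeric(3))
  nb_eff <- colSums(!apply(jk, 2, is.na)) # rg blocks may be NA
  jkse <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3) return(NA_real_)
    sqrt((length(v) - 1) / length(v) * sum((v - mean(v))^2))
  }
  rg <- rg_of(gencov, f1$h2, f2$h2)
  if (is.na(rg)) warning("non-positive heritability estimate; rg missing")
  se_rg <- jkse(jk[3, ])
  p_rg <- if (is.na(rg) || is.na(se_rg) || se_rg == 0) NA_real_ else
    2 * stats::pnorm(-abs(rg / se_rg))
  structure(list(
    h2_1 = f1$h2, h2_2 = f2$h2, se_h2_1 = f1$se_h2, se_h2_2 = f2$se_h2,
    intercept_1 = f1$intercept, intercept_2 = f2$intercept,
    gencov = gencov, se_gencov = jkse(jk[2, ]),
    cross_intercept = cross_int, se_cross_intercept = jkse(jk[1, ]),
    rg = rg, se_rg = se_rg, p_rg = p_rg,
    trait_1 = attr(ss1, "trait_name"), trait_2 = attr(ss2, "trait_name"),
    m = m, M = M, n_blocks = n_blocks
  ), class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat("<ldsc_fit> ", x$trait_1, " ~ ", x$trait_2, " (", x$m, " SNPs)\n",
      sprintf("  h2: %.3f (%.3f), %.3f (%.3f)\n",
              x$h2_1, x$se_h2_1, x$h2_2, x$se_h2_2),
      sprintf("  gencov: %.3f (%.3f)  rg: %.3f (%.3f)  p = %.3g\n",
              x$gencov, x$se_gencov, x$rg, x$se_rg, x$p_rg),
      sprintf("  cross-intercept: %.3f (%.3f)\n",
              x$cross_intercept, x$se_cross_intercept), sep = "")
  invisible(x)
}

#' FDR over a battery of genetic-correlation fits
#'
#' Benjamini-Hochberg adjustment of the rg p-values across a list of
#' bivariate fits (one per brain trait in study mode).
#'
#' @param fits List of `ldsc_fit` objects.
#' @param alpha FDR threshold recorded as attribute.
#' @return Tibble with one row per fit: traits, rg, se, p, q.
#' @export
fdr_over_traits <- function(fits, alpha = 0.05) {
  res <- purrr::map_dfr(fits, function(f) {
    tibble(trait_1 = f$trait_1, trait_2 = f$trait_2, rg = f$rg,
           se_rg = f$se_rg, pval = f$p_rg)
  })
  ok <- !is.na(res$pval)
  res$qval <- NA_real_
  res$qval[ok] <- bh_fdr(res$pval[ok])
  structure(res, alpha = alpha)
}
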