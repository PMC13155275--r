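#' Harmonise two summary-statistics tables to a shared SNP set
#'
#' Restricts both tables to their common SNP ids and aligns the second
#' trait's effects to the first trait's effect allele: swapped alleles flip
#' the sign of beta and fold eaf; SNPs whose allele pairs do not match at
#' all are dropped with a message.
#'
#' @param ss1,ss2 [sumstats] objects.
#' @return List with harmonised `ss1` and `ss2` over identical SNPs.
#' @export
harmonise_sumstats <- function(ss1, ss2) {
  common <- intersect(ss1$snp_id, ss2$snp_id)
  a <- ss1[match(common, ss1$snp_id), ]
  b <- ss2[match(common, ss2$snp_id), ]
  same <- a$allele_effect == b$allele_effect & a$allele_other == b$allele_other
  swap <- a$allele_effect == b$allele_other & a$allele_other == b$allele_effect
  if (any(swap)) {
    b$beta[swap] <- -b$beta[swap]
    b$eaf[swap] <- 1 - b$eaf[swap]
    tmp <- b$allele_effect[swap]
    b$allele_effect[swap] <- b$allele_other[swap]
    b$allele_other[swap] <- tmp
  }
  keep <- same | swap
  if (any(!keep)) message(sum(!keep), " SNP(s) dropped: incompatible alleles")
  list(ss1 = sumstats(a[keep, ], attr(ss1, "trait_name")),
       ss2 = sumstats(b[keep, ], attr(ss2, "trait_name")))
}

#' Signed rank-normalised z-scores
#'
#' Replaces each SNP's p-value magnitude by its genome-wide rank-uniform
#' score \eqn{u_i = (rank(p_i) - 1/2)/M} (average ranks for ties) and
#' reconstructs a signed z as \eqn{z_i = sign(\beta_i)\,
#' \Phi^{-1}(1 - u_i/2)}. Rank normalisation makes the gene tests robust to
#' mis-calibrated p-value tails at the cost of some power. SNPs below the
#' minor-allele-frequency floor are removed first.
#'
#' @param ss A [sumstats] object (allele-harmonised if two traits are
#'   compared).
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @return Tibble (snp_id, chrom, pos, z) of class `signed_z`.
#' @export
signed_rank_z <- function(ss, maf_min = 0.01) {
  keep <- pmin(ss$eaf, 1 - ss$eaf) >= maf_min
  d <- ss[keep, ]
  M <- nrow(d)
  if (M < 2) stop("fewer than 2 SNPs after MAF filter")
  if (length(unique(d$pval)) == 1L) {
    stop("all p-values identical; ranks are degenerate")
  }
  u <- (rank(d$pval, ties.method = "average") - 0.5) / M
  z <- ifelse(d$beta < 0, -1, 1) * stats::qnorm(1 - u / 2)
  structure(
    tibble(snp_id = d$snp_id, chrom = d$chrom, pos = d$pos, z = z),
    class = c("signed_z", "tbl_df", "tbl", "data.frame"),
    maf_min = maf_min, M = M
  )
}

#' Build flanked gene windows with LD matrices
#'
#' Each gene is expanded by `flank_bp` on both sides (1-based inclusive,
#' clipped at 1); the window collects the analysed SNPs falling inside it
#' and the regularised LD correlation matrix of those SNPs estimated from
#' the panel haplotypes. Genes whose window contains no analysed SNP are
#' reported untested.
#'
#' @param annotation Gene-annotation tibble.
#' @param snps Tibble with snp_id, chrom, pos (typically a [signed_rank_z()]
#'   result); only SNPs also present in the panel are usable.
#' @param panel A `haplotype_panel`.
#' @param flank_bp Window flank (default 50 kb).
#' @param ld_eps Ridge regularisation weight for the LD matrix.
#' @return List with `windows` (a list of per-gene records: gene_id, chrom,
#'   win_start, win_end, snp_id, sigma) and `untested` (gene ids).
#' @export
build_windows <- function(annotation, snps, panel, flank_bp = 50000,
                          ld_eps = 1e-3) {
  usable <- dplyr::inner_join(
    snps[, c("snp_id", "chrom", "pos")],
    tibble(snp_id = panel$map$snp_id,
           panel_row = seq_len(nrow(panel$map))),
    by = "snp_id"
  )
  windows <- list()
  untested <- character()
  for (g in seq_len(nrow(annotation))) {
    ws <- max(annotation$start[g] - flank_bp, 1)
    we <- annotation$end[g] + flank_bp
    hit <- usable[usable$chrom == annotation$chrom[g] &
                    usable$pos >= ws & usable$pos <= we, ]
    if (nrow(hit) == 0L) {
      untested <- c(untested, annotation$gene_id[g])
      next
    }
    rows <- hit$panel_row
    sig <- stats::cor(t(panel$haps[rows, , drop = FALSE]))
    sig[is.na(sig)] <- 0
    diag(sig) <- 1
    sig <- (1 - ld_eps) * sig + ld_eps * diag(nrow(hit))
    windows[[annotation$gene_id[g]]] <- list(
      gene_id = annotation$gene_id[g], chrom = annotation$chrom[g],
      win_start = ws, win_end = we, snp_id = hit$snp_id, sigma = sig
    )
  }
  list(windows = windows, untested = untested)
}

# eigenvalues of the regularised LD matrix, tiny ones truncated
.win_eigen <- function(sigma, tol = 1e-8) {
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  ev[ev > tol]
}

.z_in_window <- function(zs, win) {
  idx <- match(win$snp_id, zs$snp_id)
  if (anyNA(idx)) stop("window SNPs missing from the z-score table")
  zs$z[idx]
}

#' Gene-level cross-GWAS coherence test
#'
#' The statistic is the cross-trait scalar product
#' \eqn{D = \sum_{i \in win} z^A_i z^B_i}. Under the null the two z-vectors
#' are jointly Gaussian with common LD covariance \eqn{\Sigma} and
#' cross-covariance \eqn{\rho_{ov}\Sigma} (sample overlap); on the
#' eigen-basis of \eqn{\Sigma}, D is a weighted sum of products of
#' correlated standard normal pairs, i.e. a difference of two weighted
#' chi-square sums with weights \eqn{\lambda_k (1 \pm \rho_{ov})/2}, whose
#' tails the characteristic-function engine evaluates. `p_coherent` is the
#' upper tail at D (same-direction effects), `p_anticoherent` the upper tail
#' of -D; negating one trait's z-scores swaps the two exactly.
#'
#' @param zA,zB [signed_rank_z()] tables for the two traits.
#' @param win One window record from [build_windows()].
#' @param rho_ov Sample-overlap correlation (LDSC cross-trait intercept),
#'   clipped to (-0.99, 0.99).
#' @param trait_sign +1 or -1; -1 flips trait B before testing (the T2*
#'   iron-direction flip, since lower T2* means more iron). Flipping a trait
#'   also flips the sign of its overlap correlation, so `rho_ov` is negated
#'   together with the scores.
#' @return One-row tibble: gene_id, n_snps, statistic, p_coherent,
#'   p_anticoherent, method, rho_ov.
#' @export
coherence_test <- function(zA, zB, win, rho_ov = 0, trait_sign = 1) {
  stopifnot(trait_sign %in% c(-1, 1))
  rho_ov <- trait_sign * max(min(rho_ov, 0.99), -0.99)
  a <- .z_in_window(zA, win)
  b <- trait_sign * .z_in_window(zB, win)
  D <- sum(a * b)
  lam <- .win_eigen(win$sigma)
  wp <- lam * (1 + rho_ov) / 2
  wn <- lam * (1 - rho_ov) / 2
  p_coh <- weighted_chisq_tail(wp, wn, D)
  p_anti <- weighted_chisq_tail(wn, wp, -D)
  tibble(
    gene_id = win$gene_id, n_snps = length(a), statistic = D,
    p_coherent = as.numeric(p_coh), p_anticoherent = as.numeric(p_anti),
    method = attr(p_coh, "method"), rho_ov = rho_ov
  )
}

#' Gene-level directional ratio test
#'
#' The statistic \eqn{R = \sum_i z^A_i z^B_i / \sum_i (z^B_i)^2} normalises
#' the cross-trait product by the outcome trait's squared effects, so only
#' genes where the exposure carries large effects relative to the outcome
#' score highly -- the summary-statistic analogue of requiring strong
#' instruments. Since the denominator is positive,
#' \eqn{P(R \ge r) = P(w' A(r) w \ge 0)} for the stacked vector
#' \eqn{w = (z^A, z^B)} with \eqn{A(r) = [[0, I/2], [I/2, -rI]]} and joint
#' covariance \eqn{\Omega = [[\Sigma, \rho\Sigma], [\rho\Sigma, \Sigma]]};
#' the eigenvalues of \eqn{\Omega^{1/2} A \Omega^{1/2}} feed the weighted
#' chi-square tail at zero.
#'
#' @param zA Exposure-trait [signed_rank_z()] table.
#' @param zB Outcome-trait table (carries `trait_sign` if the iron-direction
#'   flip applies).
#' @param win One window record from [build_windows()].
#' @param rho_ov Sample-overlap correlation, clipped to (-0.99, 0.99).
#' @param trait_sign +1 or -1 applied to the outcome trait (and, as in
#'   [coherence_test()], to the overlap correlation).
#' @return One-row tibble: gene_id, n_snps, statistic, p_fwd, method,
#'   rho_ov.
#' @export
ratio_test <- function(zA, zB, win, rho_ov = 0, trait_sign = 1) {
  stopifnot(trait_sign %in% c(-1, 1))
  rho_ov <- trait_sign * max(min(rho_ov, 0.99), -0.99)
  a <- .z_in_window(zA, win)
  b <- trait_sign * .z_in_window(zB, win)
  den <- sum(b^2)
  if (den == 0) stop("outcome z-scores are all zero in window ", win$gene_id)
  r_obs <- sum(a * b) / den
  m <- length(a)
  eo <- eigen(win$sigma, symmetric = TRUE)
  dpos <- pmax(eo$values, 1e-10)
  shalf <- eo$vectors %*% (sqrt(dpos) * t(eo$vectors))
  Om_half <- rbind(cbind(sqrt((1 + rho_ov) / 2) * shalf,
                         sqrt((1 - rho_ov) / 2) * shalf),
                   cbind(sqrt((1 + rho_ov) / 2) * shalf,
                         -sqrt((1 - rho_ov) / 2) * shalf))
  # Om_half %*% t(Om_half) == Omega (2x2 block square root via +/- mixing)
  A <- rbind(cbind(matrix(0, m, m), diag(m) / 2),
             cbind(diag(m) / 2, -r_obs * diag(m)))
  lam <- eigen(t(Om_half) %*% A %*% Om_half, symmetric = TRUE,
               only.values = TRUE)$values
  lam <- lam[abs(lam) > 1e-10]
  p <- weighted_chisq_tail(lam[lam > 0], -lam[lam < 0], 0)
  tibble(
    gene_id = win$gene_id, n_snps = m, statistic = r_obs,
    p_fwd = as.numeric(p), method = attr(p, "method"), rho_ov = rho_ov
  )
}

#' Bonferroni significance threshold over tested genes
#'
#' @param n_genes Number of genes tested.
#' @param alpha Family-wise error rate.
#' @return `alpha / n_genes`.
#' @export
bonferroni_threshold <- function(n_genes, alpha = 0.05) {
  stopifnot(n_genes >= 1)
  alpha / n_genes
}

#' Merge significant genes with overlapping windows into clusters
#'
#' When neighbouring genes are closer than twice the window flank their
#' test windows share SNPs and a single underlying signal can light up all
#' of them; such genes are reported as one cluster (connected components of
#' the window-overlap graph) rather than as independent hits.
#'
#' @param results Gene-test tibble containing `gene_id` and the p-value
#'   column named by `p_col`.
#' @param annotation Gene-annotation tibble.
#' @param threshold Significance threshold (e.g. [bonferroni_threshold()]).
#' @param p_col Name of the p-value column (default "p_coherent").
#' @param flank_bp Window flank used by the scan.
#' @return Tibble with one row per cluster: cluster id, chrom, member gene
#'   ids (list-column and comma-joined label), n_genes, min p.
#' @export
cluster_significant <- function(results, annotation, threshold,
                                p_col = "p_coherent", flank_bp = 50000) {
  sig <- results$gene_id[!is.na(results[[p_col]]) &
                           results[[p_col]] < threshold]
  ann <- annotation[annotation$gene_id %in% sig, ]
  if (nrow(ann) == 0L) {
    return(tibble(cluster = integer(), chrom = character(),
                  genes = list(), label = character(),
                  n_genes = integer(), p_min = numeric()))
  }
  ann <- arrange(ann, .data$chrom, .data$start)
  ws <- pmax(ann$start - flank_bp, 1)
  we <- ann$end + flank_bp
  comp <- integer(nrow(ann))
  comp[1] <- 1L
  if (nrow(ann) > 1) {
    hi <- we[1]
    for (i in 2:nrow(ann)) {
      new_comp <- ann$chrom[i] != ann$chrom[i - 1] || ws[i] > hi
      comp[i] <- comp[i - 1] + new_comp
      hi <- if (new_comp) we[i] else max(hi, we[i])
    }
  }
  pv <- results[[p_col]][match(ann$gene_id, results$gene_id)]
  tibble(gene_id = ann$gene_id, chrom = ann$chrom, comp = comp, p = pv) %>%
    dplyr::group_by(.data$comp, .data$chrom) %>%
    dplyr::summarise(genes = list(.data$gene_id),
                     label = paste(.data$gene_id, collapse = ","),
                     n_genes = dplyr::n(), p_min = min(.data$p),
                     .groups = "drop") %>%
    dplyr::rename(cluster = "comp")
}

#' Candidate-gene mode: restrict and re-threshold
#'
#' Restricts a gene-test result to a candidate list and applies Bonferroni
#' over the number of candidates actually tested (e.g. 0.05/5 = 0.01 for a
#' five-gene dopamine panel).
#'
#' @param results Gene-test tibble.
#' @param gene_list Candidate gene ids.
#' @param alpha Family-wise error rate.
#' @return Filtered tibble with attribute `threshold`; absent candidates
#'   trigger a warning.
#' @export
candidate_mode <- function(results, gene_list, alpha = 0.05) {
  absent <- setdiff(gene_list, results$gene_id)
  if (length(absent)) {
    warning("candidate gene(s) not tested: ", paste(absent, collapse = ", "))
  }
  tested <- intersect(gene_list, results$gene_id)
  out <- results[results$gene_id %in% tested, ]
  structure(out, threshold = bonferroni_threshold(max(length(tested), 1), alpha),
            tested_genes = tested)
}

#' Drop genes from a result table (confounder sensitivity analysis)
#'
#' @param results Gene-test tibble.
#' @param exclusion_list Gene ids to drop (e.g. genes previously associated
#'   with alcohol consumption or serum iron).
#' @return The filtered tibble; idempotent.
#' @export
exclude_genes <- function(results, exclusion_list) {
  results[!results$gene_id %in% exclusion_list, ]
}

#' Estimate the sample-overlap correlation from summary statistics
#'
#' Runs bivariate LD-score regression and returns the cross-trait intercept
#' clipped to (-0.99, 0.99); this is the `rho_ov` the gene tests consume.
#'
#' @param ss1,ss2 Harmonised [sumstats].
#' @param panel A `haplotype_panel`.
#' @param window_bp LD-score window.
#' @return Scalar rho_ov.
#' @export
estimate_rho_ov <- function(ss1, ss2, panel, window_bp = 1e6) {
  fit <- fit_bivariate(ss1, ss2, ld_scores(panel, window_bp))
  max(min(fit$cross_intercept, 0.99), -0.99)
}

#' Genome-wide gene-level cross-GWAS scan
#'
#' Convenience pipeline: harmonise the two tables, rank-normalise, build
#' flanked windows, and run the coherence or ratio test on every testable
#' gene, with Bonferroni threshold over the tested genes.
#'
#' @param ss1,ss2 [sumstats] for the two traits; for `test = "ratio"`, ss1
#'   is the exposure and ss2 the outcome.
#' @param panel A `haplotype_panel`.
#' @param annotation Gene-annotation tibble.
#' @param test `"coherence"` or `"ratio"`.
#' @param rho_ov Numeric overlap correlation, or `"auto"` to estimate it
#'   with [estimate_rho_ov()].
#' @param trait_sign +1/-1 flip applied to trait 2 (T2* convention).
#' @param flank_bp,maf_min,alpha Scan parameters.
#' @return Tibble of class `gene_scan` (one row per tested gene) with
#'   attributes `threshold`, `untested`, `rho_ov`.
#' @export
gene_scan <- function(ss1, ss2, panel, annotation,
                      test = c("coherence", "ratio"), rho_ov = 0,
                      trait_sign = 1, flank_bp = 50000, maf_min = 0.01,
                      alpha = 0.05) {
  test <- match.arg(test)
  h <- harmonise_sumstats(ss1, ss2)
  if (identical(rho_ov, "auto")) {
    rho_ov <- estimate_rho_ov(h$ss1, h$ss2, panel)
  }
  zA <- signed_rank_z(h$ss1, maf_min = maf_min)
  zB <- signed_rank_z(h$ss2, maf_min = maf_min)
  bw <- build_windows(annotation, zA, panel, flank_bp = flank_bp)
  res <- purrr::map_dfr(bw$windows, function(w) {
    if (test == "coherence") {
      coherence_test(zA, zB, w, rho_ov = rho_ov, trait_sign = trait_sign)
    } else {
      ratio_test(zA, zB, w, rho_ov = rho_ov, trait_sign = trait_sign)
    }
  })
  structure(res,
            threshold = bonferroni_threshold(max(nrow(res), 1), alpha),
            untested = bw$untested, rho_ov = rho_ov, test = test,
            class = c("gene_scan", class(res)))
}
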