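#' Select LD-independent genetic instruments for an exposure
#'
#' Greedy clumping: candidate SNPs with p below the selection threshold are
#' sorted by ascending p; each is kept unless its panel r-squared with an
#' already-kept SNP exceeds `clump_r2`. When fewer than `min_iv` instruments
#' survive at p < 5e-8, selection is rerun at the fallback threshold
#' p < 1e-5; the threshold actually used is recorded.
#'
#' @param ss_exposure Exposure [sumstats].
#' @param panel A `haplotype_panel` covering the exposure SNPs.
#' @param cfg A [pipeline_config()].
#' @return Tibble of instrument rows (class `instrument_set`) with
#'   attributes `selection_pthresh` and `clump_r2`.
#' @export
select_instruments <- function(ss_exposure, panel, cfg = pipeline_config()) {
  pick <- function(pthresh) {
    cand <- ss_exposure[ss_exposure$pval < pthresh, ]
    cand <- cand[cand$snp_id %in% panel$map$snp_id, ]
    if (nrow(cand) == 0L) return(cand)
    cand <- cand[order(cand$pval, cand$snp_id), ]
    rows <- match(cand$snp_id, panel$map$snp_id)
    kept <- integer()
    for (i in seq_len(nrow(cand))) {
      if (length(kept)) {
        r <- suppressWarnings(stats::cor(
          panel$haps[rows[i], ],
          t(panel$haps[rows[kept], , drop = FALSE])
        ))
        r[is.na(r)] <- 0
        if (any(r^2 > cfg$clump_r2)) next
      }
      kept <- c(kept, i)
    }
    cand[kept, ]
  }
  iv <- pick(cfg$iv_pthresh)
  used <- cfg$iv_pthresh
  if (nrow(iv) < cfg$min_iv) {
    iv <- pick(cfg$iv_fallback_pthresh)
    used <- cfg$iv_fallback_pthresh
    message("fallback instrument threshold ", format(used), " used (",
            nrow(iv), " instruments)")
  }
  if (nrow(iv) == 0L) {
    stop("no instruments available even at the fallback threshold")
  }
  structure(as_tibble(unclass(iv)[.SUMSTATS_COLS]),
            selection_pthresh = used, clump_r2 = cfg$clump_r2,
            class = c("instrument_set", "tbl_df", "tbl", "data.frame"))
}

.is_palindromic <- function(a1, a2) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(comp[a1]) & comp[a1] == a2
}

#' Harmonise instruments with the outcome summary statistics
#'
#' Aligns outcome effects to the exposure's effect allele (swapped alleles
#' flip the outcome beta), drops instruments missing from the outcome, and
#' drops palindromic (A/T, C/G) instruments whose allele frequency is too
#' close to 0.5 (min(eaf, 1-eaf) > 0.42 in either study) to resolve strand;
#' otherwise palindromes are aligned by frequency.
#'
#' @param iv An `instrument_set` from [select_instruments()].
#' @param ss_outcome Outcome [sumstats].
#' @return Tibble of class `mr_data` with per-instrument columns snp_id,
#'   beta_exp, se_exp, beta_out, se_out.
#' @export
harmonize <- function(iv, ss_outcome) {
  idx <- match(iv$snp_id, ss_outcome$snp_id)
  if (anyNA(idx)) {
    message(sum(is.na(idx)), " instrument(s) absent from outcome, dropped")
    iv <- iv[!is.na(idx), ]
    idx <- idx[!is.na(idx)]
  }
  out <- ss_outcome[idx, ]
  pal <- .is_palindromic(iv$allele_effect, iv$allele_other)
  drop <- rep(FALSE, nrow(iv))
  flip <- rep(FALSE, nrow(iv))
  same <- iv$allele_effect == out$allele_effect &
    iv$allele_other == out$allele_other
  swap <- iv$allele_effect == out$allele_other &
    iv$allele_other == out$allele_effect
  flip[!pal & swap] <- TRUE
  drop[!pal & !same & !swap] <- TRUE
  if (any(pal)) {
    ambiguous <- pal & (pmin(iv$eaf, 1 - iv$eaf) > 0.42 |
                          pmin(out$eaf, 1 - out$eaf) > 0.42)
    drop[ambiguous] <- TRUE
    # align remaining palindromes by which side of 0.5 the frequency falls
    rest <- pal & !ambiguous
    flip[rest] <- (iv$eaf[rest] > 0.5) != (out$eaf[rest] > 0.5)
  }
  if (any(drop)) message(sum(drop), " palindromic/incompatible SNP(s) dropped")
  beta_out <- ifelse(flip, -out$beta, out$beta)
  structure(
    tibble(snp_id = iv$snp_id,
           beta_exp = iv$beta, se_exp = iv$se,
           beta_out = beta_out, se_out = out$se)[!drop, ],
    selection_pthresh = attr(iv, "selection_pthresh"),
    class = c("mr_data", "tbl_df", "tbl", "data.frame")
  )
}

.mr_row <- function(method, beta, se, pval, n_iv, ...) {
  tibble(method = method, beta = beta, se = se, pval = pval,
         n_iv = n_iv, ...)
}

#' Inverse-variance weighted causal estimate
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights \eqn{1/se_{out}^2}; multiplicative random effects
#' inflate the standard error by \eqn{\max(1, \sqrt{Q/(n_{iv}-1)})} when the
#' instruments are heterogeneous.
#'
#' @param hd An `mr_data` table with at least 2 instruments.
#' @return One-row tibble: method, beta, se, pval, n_iv, Q, Q_df, Q_p.
#' @export
ivw <- function(hd) {
  n <- nrow(hd)
  if (n < 2) stop("IVW needs at least 2 instruments")
  w <- 1 / hd$se_out^2
  beta <- sum(w * hd$beta_exp * hd$beta_out) / sum(w * hd$beta_exp^2)
  se_fixed <- sqrt(1 / sum(w * hd$beta_exp^2))
  Q <- sum(w * (hd$beta_out - beta * hd$beta_exp)^2)
  se <- se_fixed * max(1, sqrt(Q / (n - 1)))
  .mr_row("ivw", beta, se, 2 * stats::pnorm(-abs(beta / se)), n,
          Q = Q, Q_df = n - 1,
          Q_p = stats::pchisq(Q, n - 1, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with a free intercept,
#' after orienting all exposure effects positive. The slope is the causal
#' estimate; a non-zero intercept indicates directional pleiotropy.
#'
#' @param hd An `mr_data` table with at least 3 instruments.
#' @return One-row tibble with slope beta/se/p plus egger_intercept, its se
#'   and p.
#' @export
egger <- function(hd) {
  n <- nrow(hd)
  if (n < 3) stop("MR-Egger needs at least 3 instruments")
  sgn <- ifelse(hd$beta_exp < 0, -1, 1)
  bx <- hd$beta_exp * sgn
  by <- hd$beta_out * sgn
  fit <- stats::lm(by ~ bx, weights = 1 / hd$se_out^2)
  co <- summary(fit)$coefficients
  infl <- 1 / min(summary(fit)$sigma, 1) # multiplicative RE floor
  se_b <- co["bx", 2] * infl
  se_a <- co["(Intercept)", 2] * infl
  .mr_row("egger", co["bx", 1], se_b,
          2 * stats::pt(-abs(co["bx", 1] / se_b), df = n - 2), n,
          egger_intercept = co["(Intercept)", 1],
          egger_intercept_se = se_a,
          egger_intercept_p = 2 * stats::pt(-abs(co["(Intercept)", 1] / se_a),
                                            df = n - 2))
}

.weighted_median_est <- function(ratio, w) {
  ord <- order(ratio)
  ratio <- ratio[ord]
  w <- w[ord] / sum(w)
  cs <- cumsum(w) - w / 2
  below <- max(which(cs < 0.5))
  ratio[below] + (ratio[below + 1] - ratio[below]) *
    (0.5 - cs[below]) / (cs[below + 1] - cs[below])
}

#' Weighted-median causal estimate
#'
#' Weighted median of the per-instrument Wald ratios (weights inverse to the
#' squared first-order ratio se); consistent when at least half the weight
#' comes from valid instruments. The se comes from a parametric bootstrap
#' with a recorded seed.
#'
#' @param hd An `mr_data` table with at least 3 instruments.
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return One-row tibble.
#' @export
weighted_median <- function(hd, n_boot = 1000, seed = 1) {
  n <- nrow(hd)
  if (n < 3) stop("weighted median needs at least 3 instruments")
  ratio <- hd$beta_out / hd$beta_exp
  w <- (hd$beta_exp / hd$se_out)^2
  est <- .weighted_median_est(ratio, w)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(n, hd$beta_exp, hd$se_exp)
    by <- stats::rnorm(n, hd$beta_out, hd$se_out)
    .weighted_median_est(by / bx, (bx / hd$se_out)^2)
  }, numeric(1))
  se <- stats::sd(boots)
  .mr_row("weighted_median", est, se, 2 * stats::pnorm(-abs(est / se)), n)
}

.weighted_mode_est <- function(ratio, w, bandwidth_factor) {
  s <- 0.9 * min(stats::sd(ratio), stats::mad(ratio)) *
    length(ratio)^(-1 / 5)
  if (!is.finite(s) || s <= 0) s <- stats::sd(ratio) * length(ratio)^(-1 / 5)
  if (!is.finite(s) || s <= 0) return(ratio[which.max(w)])
  h <- bandwidth_factor * s
  wn <- w / sum(w)
  grid <- seq(min(ratio) - h, max(ratio) + h, length.out = 512)
  dens <- vapply(grid, function(g) sum(wn * stats::dnorm(g, ratio, h)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Weighted-mode causal estimate
#'
#' Mode of the kernel-smoothed weighted Wald-ratio distribution (normal
#' kernel, Silverman-type bandwidth scaled by `bandwidth_factor`);
#' consistent when the largest group of instruments sharing a ratio is
#' valid. The se comes from a parametric bootstrap.
#'
#' @param hd An `mr_data` table with at least 3 instruments.
#' @param bandwidth_factor Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return One-row tibble.
#' @export
weighted_mode <- function(hd, bandwidth_factor = 1, n_boot = 1000, seed = 1) {
  n <- nrow(hd)
  if (n < 3) stop("weighted mode needs at least 3 instruments")
  ratio <- hd$beta_out / hd$beta_exp
  w <- (hd$beta_exp / hd$se_out)^2
  est <- .weighted_mode_est(ratio, w, bandwidth_factor)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(n, hd$beta_exp, hd$se_exp)
    by <- stats::rnorm(n, hd$beta_out, hd$se_out)
    .weighted_mode_est(by / bx, (bx / hd$se_out)^2, bandwidth_factor)
  }, numeric(1))
  se <- stats::sd(boots)
  .mr_row("weighted_mode", est, se, 2 * stats::pnorm(-abs(est / se)), n)
}

#' Cochran's Q heterogeneity test over instrument ratios
#'
#' @param hd An `mr_data` table.
#' @param beta_ivw Optional IVW estimate; computed if missing.
#' @return One-row tibble: Q, df, pval.
#' @export
cochran_q <- function(hd, beta_ivw = NULL) {
  if (is.null(beta_ivw)) beta_ivw <- ivw(hd)$beta
  w <- (hd$beta_exp / hd$se_out)^2
  ratio <- hd$beta_out / hd$beta_exp
  Q <- sum(w * (ratio - beta_ivw)^2)
  df <- nrow(hd) - 1
  tibble(Q = Q, df = df, pval = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Per-instrument and mean F-statistics
#'
#' \eqn{F_i = (\beta_{exp,i}/se_{exp,i})^2}; values above ~10 are the usual
#' bar for instrument strength.
#'
#' @param hd An `mr_data` table.
#' @return Tibble (snp_id, F) with attribute `mean_F`.
#' @export
f_statistics <- function(hd) {
  stopifnot(all(hd$se_exp > 0))
  f <- (hd$beta_exp / hd$se_exp)^2
  structure(tibble(snp_id = hd$snp_id, F = f), mean_F = mean(f))
}

#' Leave-one-out IVW sensitivity analysis
#'
#' Re-estimates IVW dropping each instrument in turn and flags omissions
#' that flip the sign of the estimate or cross nominal significance
#' relative to the full fit.
#'
#' @param hd An `mr_data` table with at least 3 instruments.
#' @return Tibble with one row per omitted instrument plus flag columns.
#' @export
leave_one_out <- function(hd) {
  n <- nrow(hd)
  if (n < 3) stop("leave-one-out needs at least 3 instruments")
  full <- ivw(hd)
  purrr::map_dfr(seq_len(n), function(i) {
    fit <- ivw(hd[-i, ])
    tibble(omitted = hd$snp_id[i], beta = fit$beta, se = fit$se,
           pval = fit$pval,
           sign_flip = sign(fit$beta) != sign(full$beta),
           sig_change = (fit$pval < 0.05) != (full$pval < 0.05))
  })
}

#' Remove instruments previously associated with confounders
#'
#' @param hd An `mr_data` table.
#' @param snp_list SNP ids to remove (e.g. alcohol- or serum-iron-associated
#'   variants).
#' @return Filtered `mr_data`; removal is idempotent and errors if nothing
#'   is left.
#' @export
exclude_confounder_snps <- function(hd, snp_list) {
  out <- hd[!hd$snp_id %in% snp_list, ]
  removed <- nrow(hd) - nrow(out)
  if (removed > 0) message(removed, " confounder-associated SNP(s) removed")
  if (nrow(out) == 0L) stop("all instruments removed by exclusion list")
  out
}

#' Bidirectional MR battery across methods
#'
#' For each outcome trait, runs both causal directions (exposure to trait
#' and trait to exposure): instrument selection with fallback, harmonisation
#' and the four estimators, plus heterogeneity and mean instrument strength.
#' BH-FDR is applied across the IVW estimates of the run (the other methods
#' are reported nominally). Directions that cannot be instrumented are
#' skipped with a message.
#'
#' @param exposure_ss Exposure [sumstats].
#' @param outcome_ss A single [sumstats] or a list of them (one per trait).
#' @param panel A `haplotype_panel`.
#' @param cfg A [pipeline_config()].
#' @param seed Seed for the bootstrap-based estimators.
#' @return Tibble of class `mr_battery` with one row per
#'   direction x method x trait.
#' @export
mr_battery <- function(exposure_ss, outcome_ss, panel,
                       cfg = pipeline_config(), seed = 1) {
  if (inherits(outcome_ss, "sumstats")) outcome_ss <- list(outcome_ss)
  one_direction <- function(exp_ss, out_ss, direction) {
    hd <- tryCatch(
      harmonize(select_instruments(exp_ss, panel, cfg), out_ss),
      error = function(e) {
        message("direction ", direction, " skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(hd) || nrow(hd) < 3) {
      if (!is.null(hd)) message("direction ", direction,
                                " skipped: fewer than 3 usable instruments")
      return(NULL)
    }
    ests <- dplyr::bind_rows(
      ivw(hd), egger(hd),
      weighted_median(hd, seed = seed), weighted_mode(hd, seed = seed)
    )
    ests$exposure <- attr(exp_ss, "trait_name")
    ests$outcome <- attr(out_ss, "trait_name")
    ests$direction <- direction
    ests$mean_F <- attr(f_statistics(hd), "mean_F")
    ests$threshold_used <- attr(hd, "selection_pthresh")
    ests
  }
  res <- purrr::map_dfr(outcome_ss, function(out_ss) {
    dplyr::bind_rows(
      one_direction(exposure_ss, out_ss, "forward"),
      one_direction(out_ss, exposure_ss, "reverse")
    )
  })
  if (nrow(res)) {
    res$qval <- NA_real_
    is_ivw <- res$method == "ivw"
    res$qval[is_ivw] <- bh_fdr(res$pval[is_ivw])
  }
  structure(res, class = c("mr_battery", class(res)))
}
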