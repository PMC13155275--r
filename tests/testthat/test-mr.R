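.mk_panel6 <- function() {
  # large panel so that null-pair r^2 sampling noise (~1/n_hap) sits well
  # below the 0.001 clumping threshold
  pan <- generate_panel(10000, ld_block_spec(6, ar_rho = 0,
                                             maf_range = c(0.2, 0.5)), seed = 17)
  pan$haps[2, ] <- pan$haps[1, ] # SNPs 1-3 in perfect LD
  pan$haps[3, ] <- pan$haps[1, ]
  pan$map$maf <- pmin(rowMeans(pan$haps), 1 - rowMeans(pan$haps))
  pan
}

.mk_exposure6 <- function(pvals) {
  sumstats(tibble::tibble(
    snp_id = sprintf("rs%06d", 1:6), chrom = "1", pos = (1:6) * 1000L,
    allele_effect = "G", allele_other = "A", eaf = 0.3,
    beta = c(0.05, 0.04, 0.045, 0.03, 0.02, 0.06), se = 0.005,
    pval = pvals, n = 50000L
  ), trait_name = "exposure")
}

test_that("clumping keeps one lead SNP per LD clump", {
  pan <- .mk_panel6()
  ss <- .mk_exposure6(c(1e-10, 1e-12, 1e-9, 1e-10, 1e-11, 0.5))
  iv <- quiet(select_instruments(ss, pan, pipeline_config(min_iv = 1L)))
  # SNPs 1-3 collapse to the smallest p (rs000002); 4 and 5 independent
  expect_setequal(iv$snp_id, c("rs000002", "rs000004", "rs000005"))
  expect_identical(attr(iv, "selection_pthresh"), 5e-8)
})

test_that("instrument selection falls back to 1e-5 when too few survive", {
  pan <- .mk_panel6()
  ss <- .mk_exposure6(c(1e-10, 0.5, 0.5, 1e-6, 1e-6, 1e-6))
  expect_message(
    iv <- select_instruments(ss, pan, pipeline_config(min_iv = 4L)),
    "fallback"
  )
  expect_identical(attr(iv, "selection_pthresh"), 1e-5)
  expect_identical(nrow(iv), 4L)
  # nothing even at the fallback: hard error
  ss0 <- .mk_exposure6(rep(0.5, 6))
  expect_error(quiet(select_instruments(ss0, pan, pipeline_config())),
               "no instruments")
})

test_that("clumping is invariant to input row order", {
  pan <- .mk_panel6()
  ss <- .mk_exposure6(c(1e-10, 1e-12, 1e-9, 1e-10, 1e-11, 1e-8))
  ref <- quiet(select_instruments(ss, pan, pipeline_config(min_iv = 1L)))
  for (i in 1:12) {
    perm <- sumstats(tibble::as_tibble(ss)[sample(6), ], "exposure")
    out <- quiet(select_instruments(perm, pan, pipeline_config(min_iv = 1L)))
    expect_identical(sort(out$snp_id), sort(ref$snp_id))
  }
})

.mk_hd <- function(bx, by, sx = 0.01, sy = 0.01) {
  structure(tibble::tibble(
    snp_id = sprintf("iv%02d", seq_along(bx)),
    beta_exp = bx, se_exp = sx, beta_out = by, se_out = sy
  ), class = c("mr_data", "tbl_df", "tbl", "data.frame"))
}

test_that("harmonisation flips swapped alleles and drops ambiguous palindromes", {
  iv <- structure(tibble::tibble(
    snp_id = c("a", "b", "c", "d"), chrom = "1", pos = 1:4 * 1000L,
    allele_effect = c("G", "G", "A", "A"),
    allele_other = c("A", "A", "T", "T"),
    eaf = c(0.3, 0.3, 0.5, 0.2), beta = c(0.05, 0.05, 0.05, 0.05),
    se = 0.005, pval = 1e-10, n = 1000L
  ), selection_pthresh = 5e-8,
  class = c("instrument_set", "tbl_df", "tbl", "data.frame"))
  out <- sumstats(tibble::tibble(
    snp_id = c("a", "b", "c", "d"), chrom = "1", pos = 1:4 * 1000L,
    allele_effect = c("G", "A", "A", "T"),
    allele_other = c("A", "G", "T", "A"),
    eaf = c(0.3, 0.7, 0.5, 0.8), beta = c(0.02, 0.02, 0.02, 0.02),
    se = 0.004, pval = 0.01, n = 1000L
  ), "outcome")
  hd <- quiet(harmonize(iv, out))
  # c is an ambiguous palindrome (eaf 0.5) -> dropped
  expect_setequal(hd$snp_id, c("a", "b", "d"))
  expect_equal(hd$beta_out[hd$snp_id == "a"], 0.02)   # matching: identity
  expect_equal(hd$beta_out[hd$snp_id == "b"], -0.02)  # swapped: sign flip
  # d: palindrome aligned by frequency (0.2 vs 0.8 -> opposite strands)
  expect_equal(hd$beta_out[hd$snp_id == "d"], -0.02)
  # instruments missing from the outcome are dropped with a message
  expect_message(harmonize(iv, out[-2, ]), "absent")
})

test_that("IVW reproduces the weighted normal-equations oracle", {
  hd <- .mk_hd(c(0.1, 0.2, 0.3), c(0.02, 0.04, 0.09), sy = c(0.01, 0.01, 0.02))
  fit <- ivw(hd)
  oracle <- lm(beta_out ~ 0 + beta_exp, data = hd, weights = 1 / hd$se_out^2)
  expect_equal(fit$beta, unname(coef(oracle)))
  # equal Wald ratios: beta = ratio, Q = 0
  hd0 <- .mk_hd(c(0.1, 0.2, 0.4), c(0.03, 0.06, 0.12))
  f0 <- ivw(hd0)
  expect_equal(f0$beta, 0.3)
  expect_equal(f0$Q, 0)
  expect_error(ivw(hd0[1, ]), "2 instruments")
})

test_that("IVW is equivariant and invariant under joint allele flips", {
  set.seed(31)
  hd <- .mk_hd(runif(8, 0.05, 0.2), rnorm(8, 0.02, 0.01))
  f <- ivw(hd)
  hd2 <- hd; hd2$beta_out <- 3 * hd2$beta_out; hd2$se_out <- 3 * hd2$se_out
  expect_equal(ivw(hd2)$beta, 3 * f$beta)
  flip <- sample(8, 3)
  hd3 <- hd
  hd3$beta_exp[flip] <- -hd3$beta_exp[flip]
  hd3$beta_out[flip] <- -hd3$beta_out[flip]
  expect_equal(ivw(hd3)$beta, f$beta)
  expect_equal(egger(hd3)$beta, egger(hd)$beta) # egger orients internally
})

test_that("egger separates slope from directional pleiotropy", {
  bx <- c(0.08, 0.12, 0.2, 0.15, 0.3)
  by <- 0.01 + 0.25 * bx # exact pleiotropic intercept
  fit <- egger(.mk_hd(bx, by))
  expect_equal(fit$beta, 0.25, tolerance = 1e-8)
  expect_equal(fit$egger_intercept, 0.01, tolerance = 1e-8)
  expect_error(egger(.mk_hd(bx[1:2], by[1:2])), "3 instruments")
  # intercept-free fit nests back to IVW
  hd <- .mk_hd(bx, by)
  origin <- lm(beta_out ~ 0 + beta_exp, data = hd, weights = 1 / hd$se_out^2)
  expect_equal(unname(coef(origin)), ivw(hd)$beta)
})

test_that("weighted median agrees with IVW for symmetric valid instruments", {
  set.seed(5)
  bx <- runif(20, 0.1, 0.3)
  by <- 0.2 * bx + rnorm(20, 0, 0.002)
  hd <- .mk_hd(bx, by, sx = 0.005, sy = 0.005)
  wm <- weighted_median(hd, seed = 3)
  expect_lt(abs(wm$beta - ivw(hd)$beta), 0.02)
  expect_identical(weighted_median(hd, seed = 3)$se, wm$se) # deterministic
  expect_error(weighted_median(hd[1:2, ]), "3 instruments")
})

test_that("weighted median resists a minority of invalid instruments", {
  recovered <- sapply(1:10, function(s) {
    set.seed(1300 + s)
    bx <- runif(20, 0.1, 0.3)
    by <- 0.1 * bx + rnorm(20, 0, 0.002)
    bad <- 1:8 # 40% invalid with shifted ratios
    by[bad] <- by[bad] + 0.05
    hd <- .mk_hd(bx, by, sy = 0.005)
    c(weighted_median(hd, seed = s)$beta, ivw(hd)$beta)
  })
  expect_lt(abs(mean(recovered[1, ]) - 0.1), 0.05)
  expect_gt(mean(recovered[2, ]) - 0.1, 0.05) # IVW dragged by invalid IVs
  expect_gt(mean(recovered[2, ]), mean(recovered[1, ]))
})

test_that("weighted mode finds the majority ratio cluster", {
  hd <- .mk_hd(rep(0.2, 5), rep(0.2 * 0.3, 5))
  expect_equal(weighted_mode(hd, seed = 1)$beta, 0.3, tolerance = 1e-6)
  set.seed(9)
  bx <- runif(20, 0.15, 0.3)
  ratio <- c(rep(0.1, 12), rep(0.5, 8)) + rnorm(20, 0, 0.005)
  hd2 <- .mk_hd(bx, bx * ratio, sy = 0.004)
  wm <- weighted_mode(hd2, seed = 2)
  expect_lt(abs(wm$beta - 0.1), 0.04)
  expect_identical(weighted_mode(hd2, seed = 2)$beta, wm$beta)
})

test_that("cochran's Q matches direct arithmetic", {
  hd <- .mk_hd(c(0.1, 0.2, 0.25), c(0.02, 0.05, 0.03), sy = c(0.01, 0.02, 0.01))
  b <- ivw(hd)$beta
  w <- (hd$beta_exp / hd$se_out)^2
  expected <- sum(w * (hd$beta_out / hd$beta_exp - b)^2)
  q <- cochran_q(hd)
  expect_equal(q$Q, expected)
  expect_identical(q$df, 2)
  expect_equal(q$pval, pchisq(expected, 2, lower.tail = FALSE))
  # homogeneous ratios: Q = 0, p = 1
  hd0 <- .mk_hd(c(0.1, 0.2, 0.4), c(0.03, 0.06, 0.12))
  expect_equal(cochran_q(hd0)$Q, 0)
  expect_equal(cochran_q(hd0)$pval, 1)
})

test_that("F-statistics follow the squared-z formula", {
  hd <- .mk_hd(0.1, 0.05, sx = 0.01)
  f <- f_statistics(rbind(hd, hd, hd))
  expect_equal(f$F, rep(100, 3))
  expect_equal(attr(f, "mean_F"), 100)
  # a SNP exactly at the genome-wide line
  z_gw <- qnorm(1 - 5e-8 / 2)
  hd2 <- .mk_hd(z_gw * 0.01, 0.01, sx = 0.01)
  expect_equal(f_statistics(hd2)$F, 29.7168, tolerance = 1e-3)
  # allele flip leaves F unchanged
  hd3 <- hd; hd3$beta_exp <- -hd3$beta_exp
  expect_equal(f_statistics(hd3)$F, f_statistics(hd)$F)
})

test_that("leave-one-out flags a single driving instrument", {
  set.seed(6)
  bx <- runif(9, 0.1, 0.3)
  by <- 0.05 * bx + rnorm(9, 0, 0.001)
  bx <- c(bx, 0.3); by <- c(by, 0.3 * 0.6) # gross outlier IV
  hd <- .mk_hd(bx, by, sy = 0.004)
  loo <- leave_one_out(hd)
  expect_identical(nrow(loo), 10L)
  expect_true(loo$sig_change[10] || loo$sign_flip[10] ||
                abs(loo$beta[10] - 0.05) < abs(ivw(hd)$beta - 0.05))
  # homogeneous instruments stay within one se of the full estimate
  hdh <- .mk_hd(bx[1:9], by[1:9], sy = 0.004)
  looh <- leave_one_out(hdh)
  full <- ivw(hdh)
  expect_true(all(abs(looh$beta - full$beta) < full$se))
})

test_that("confounder-SNP exclusion commutes with estimation", {
  set.seed(8)
  hd <- .mk_hd(runif(6, 0.1, 0.3), rnorm(6, 0.03, 0.01))
  expect_identical(exclude_confounder_snps(hd, character(0)), hd)
  kept <- quiet(exclude_confounder_snps(hd, c("iv02", "iv05")))
  expect_identical(quiet(exclude_confounder_snps(kept, "iv02")), kept)
  expect_equal(ivw(kept)$beta, ivw(hd[-c(2, 5), ])$beta)
  expect_error(quiet(exclude_confounder_snps(hd, hd$snp_id)), "all instruments")
})

test_that("the battery reports both directions across all methods", {
  pan <- fx_mr_panel(); ann <- fx_mr_genes()
  cls <- setNames(c(rep("causal_fwd", 10), rep("private_2", 10)),
                  ann$gene_id[1:20])
  arch <- architecture_spec(cls, tau2 = 3e-4, gamma = 0.2, bg_var = 0)
  sim <- simulate_summary_pair(pan, ann, arch, 5e4, 5e4, seed = 41)
  bat <- quiet(mr_battery(sim$ss1, sim$ss2, pan, seed = 2))
  expect_identical(nrow(bat), 8L) # 2 directions x 4 methods
  expect_setequal(unique(bat$direction), c("forward", "reverse"))
  expect_true(all(is.na(bat$qval[bat$method != "ivw"])))
  expect_true(all(!is.na(bat$qval[bat$method == "ivw"])))
  expect_true(all(bat$mean_F > 10))
  fwd <- bat[bat$method == "ivw" & bat$direction == "forward", ]
  expect_lt(abs(fwd$beta - 0.2), 0.1)
})
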