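test_that("imputation uses means, modes and the sorted-first tie rule", {
  tab <- tibble::tibble(x = c(1, NA, 3), g = c("a", "a", NA),
                        t = c("a", "b", NA))
  out <- quiet(impute_missing(tab, c("x", "g", "t")))
  expect_equal(out$x, c(1, 2, 3))
  expect_identical(out$g[3], "a")
  expect_identical(out$t[3], "a") # tie a/b -> sorted first
  expect_error(impute_missing(tibble::tibble(x = c(NA_real_, NA)), "x"),
               "entirely missing")
})

test_that("MAD filter applies the unscaled five-deviation rule", {
  keep <- mad_filter(c(1, 2, 3, 4, 100), k = 5)
  # median 3, MAD 1 -> bound 5: only 100 excluded
  expect_identical(keep, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(mad_filter(rep(7, 5))))      # MAD 0, all at median
  expect_identical(mad_filter(c(7, 7, 7, 8)), c(TRUE, TRUE, TRUE, FALSE))
  expect_error(mad_filter(c(1, NA, NA)), "3 non-missing")
})

test_that("MAD mask agrees with direct evaluation on random vectors", {
  set.seed(21)
  for (i in 1:200) {
    x <- rnorm(sample(5:50, 1)) * sample(c(1, 10, 100), 1)
    k <- sample(c(2, 5), 1)
    med <- median(x)
    mad_raw <- median(abs(x - med))
    expected <- if (mad_raw == 0) x == med else abs(x - med) <= k * mad_raw
    expect_identical(mad_filter(x, k), expected)
  }
})

test_that("log transforms anchor their shift at zero", {
  expect_equal(log_transform(c(0, 19), "one")[1], 0) # pack-years zero -> ln 1
  x <- c(-6, 0, 4) # deprivation-like with negative support
  out <- log_transform(x, "min")
  expect_equal(out[1], 0) # s = 1 - (-6) = 7 -> ln(1)
  expect_equal(out[2], log(7))
  set.seed(1)
  v <- rnorm(50)
  expect_identical(order(log_transform(v, "min")), order(v)) # monotone
  expect_error(log_transform(c(-2, 1), "one"), "non-positive")
})

test_that("pack-years follows the cigarettes/20 x years formula", {
  expect_equal(pack_years(20, 10), 10)
  expect_equal(pack_years(0, 30), 0)
  expect_equal(pack_years(10, 30), 15)
  expect_error(pack_years(-1, 5), "non-negative")
})

test_that("residualisation is exact and orthogonal to the design", {
  set.seed(5)
  X <- data.frame(a = rnorm(100), b = rnorm(100), g = factor(sample(letters[1:3], 100, TRUE)))
  # exact linear response -> zero residuals
  y <- 2 + 3 * X$a - X$b
  expect_lt(max(abs(deconfound(y, X))), 1e-10)
  # intercept-only behaviour for orthogonal covariates
  y2 <- rnorm(100)
  mm <- model.matrix(~ ., X)
  for (i in 1:20) {
    yy <- rnorm(100)
    r <- deconfound(yy, X)
    expect_lt(max(abs(crossprod(mm, r))), 1e-8 * 100)
  }
  # collinear design errors with the offending column named
  X2 <- data.frame(a = X$a, b = X$a)
  expect_error(deconfound(y2, X2), "collinear.*b")
})

test_that("inverse normal transform follows Blom scoring then z-scores", {
  out <- int_transform(c(10, 50, 20))
  raw <- qnorm((rank(c(10, 50, 20)) - 3 / 8) / (3 + 1 / 4))
  expect_equal(out, (raw - mean(raw)) / sd(raw))
  expect_equal(out, c(-1, 1, 0)) # symmetric 3-point case z-scores to -1,0,1
  set.seed(2)
  v <- rexp(500)
  t <- int_transform(v)
  expect_lt(abs(mean(t)), 1e-10)
  expect_lt(abs(sd(t) - 1), 1e-10)
  expect_identical(order(t), order(v))
  expect_error(int_transform(rep(3, 4)), "distinct")
  # ties get equal scores
  t2 <- int_transform(c(1, 1, 5))
  expect_equal(t2[1], t2[2])
})

test_that("benjamini-hochberg matches the brute-force step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_error(bh_fdr(c(0.5, 0)), "0")
})

test_that("asymmetry z-test reproduces the printed convention", {
  # formula: z = (bL - bR) / sqrt(seL^2 + seR^2)
  res <- asymmetry_z(1.74, 1, 0, 1)
  expect_equal(res$z, 1.74 / sqrt(2))
  # equal betas give z = 0, p = 0.5
  eq <- asymmetry_z(0.3, 0.1, 0.3, 0.2)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_one_sided, 0.5)
  # doubling both ses halves z
  a <- asymmetry_z(0.4, 0.1, 0.1, 0.2)
  b <- asymmetry_z(0.4, 0.2, 0.1, 0.4)
  expect_equal(b$z, a$z / 2)
  # printed value: upper tail at z = 1.74 rounds to 0.04
  expect_equal(round(pnorm(1.74, lower.tail = FALSE), 2), 0.04)
})

test_that("association battery recovers simulated effects", {
  est <- sapply(1:3, function(s) {
    sp <- cohort_spec(n = 5000, delta_current = 0.3)
    tab <- quiet(simulate_cohort(sp, seed = 400 + s))
    pre <- quiet(pheno_preprocess(tab))
    fit_association(pre, "qsm_caudate_l", "current_vs_never")$beta
  })
  expect_lt(abs(mean(est) - 0.3), 0.1)
})

test_that("null predictors give uniform association p-values", {
  pv <- sapply(1:40, function(s) {
    sp <- cohort_spec(n = 400, missing_rate = 0, outlier_rate = 0)
    tab <- quiet(simulate_cohort(sp, seed = 500 + s))
    pre <- quiet(pheno_preprocess(tab))
    fit_association(pre, "t2s_accumbens_r", "ever_smoked")$pval
  })
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("contrasts drop the excluded group", {
  sp <- cohort_spec(n = 800, status_probs = c(current = 0.2, former = 0.3,
                                              never = 0.5))
  tab <- quiet(simulate_cohort(sp, seed = 6))
  pre <- quiet(pheno_preprocess(tab))
  f <- fit_association(pre, "qsm_putamen_r", "current_vs_never")
  expect_identical(f$n_used,
                   sum(tab$smoking_status != "former" &
                         !is.na(pre$qsm_putamen_r)))
  # with no former smokers, current-vs-never equals ever-smoked
  tab2 <- tab[tab$smoking_status != "former", ]
  pre2 <- quiet(pheno_preprocess(tab2))
  f1 <- fit_association(pre2, "qsm_putamen_r", "current_vs_never")
  f2 <- fit_association(pre2, "qsm_putamen_r", "ever_smoked")
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$pval, f2$pval, tolerance = 1e-6)
})

test_that("interaction fits add the product-term row", {
  sp <- cohort_spec(n = 2000, delta_current = 0.2, interaction_sex = 0.5)
  tab <- quiet(simulate_cohort(sp, seed = 8))
  pre <- quiet(pheno_preprocess(tab))
  f <- fit_association(pre, "qsm_putamen_l", "current_smoking",
                       interaction = "sex")
  expect_identical(nrow(f), 2L)
  expect_true(any(grepl(":", f$predictor)))
})

test_that("former-smoker model recovers the cessation slope and is shift-invariant", {
  est <- sapply(1:3, function(s) {
    sp <- cohort_spec(n = 5000, beta_cessation = -0.1)
    tab <- quiet(simulate_cohort(sp, seed = 700 + s))
    pre <- quiet(pheno_preprocess(tab))
    fm <- former_smoker_model(pre)
    fm$beta[fm$trait == "qsm_putamen_l" & fm$predictor == "cessation_years"]
  })
  expect_lt(abs(mean(est) + 0.1), 0.05)
  # INT makes the fit invariant to adding a constant to cessation years
  sp <- cohort_spec(n = 2000)
  tab <- quiet(simulate_cohort(sp, seed = 9))
  pre <- quiet(pheno_preprocess(tab))
  pre2 <- pre
  pre2$cessation_years <- pre2$cessation_years + 7
  expect_equal(former_smoker_model(pre)$beta, former_smoker_model(pre2)$beta)
  # small samples warn but still fit
  small <- quiet(simulate_cohort(cohort_spec(n = 120), seed = 10))
  pres <- quiet(pheno_preprocess(small))
  expect_warning(former_smoker_model(pres), "former smokers")
})

test_that("robustness metrics follow the set arithmetic", {
  resA <- tibble::tibble(trait = letters[1:5], predictor = "p",
                         beta = c(1, 2, 3, 4, 5) / 10,
                         qval = c(0.01, 0.2, 0.03, 0.8, 0.04))
  resB <- resA
  r <- robustness(resA, resB)
  expect_equal(r$beta_correlation, 1)
  expect_equal(r$jaccard, 1)
  resC <- resA
  resC$qval <- c(0.9, 0.01, 0.9, 0.01, 0.9) # disjoint significant sets
  expect_equal(robustness(resA, resC)$jaccard, 0)
  # hand-built example: A sig {a,c,e}, B sig {a,e,b} -> jaccard 2/4
  resD <- resA
  resD$qval <- c(0.02, 0.04, 0.5, 0.9, 0.01)
  expect_equal(robustness(resA, resD)$jaccard, 0.5)
  # both empty -> undefined
  resE <- resA; resE$qval <- rep(1, 5)
  expect_true(is.na(robustness(resE, resE)$jaccard))
  expect_error(robustness(resA, resA[c(2:5, 1), c(1, 2, 3, 4)][-1, ]), "aligned")
})

test_that("de-confounding removes a shared confounder signal", {
  est <- sapply(1:20, function(s) {
    sp <- cohort_spec(n = 1500, confounding_smoking = 0.8,
                      confounding_trait = 0.5)
    tab <- quiet(simulate_cohort(sp, seed = 800 + s))
    pre <- quiet(pheno_preprocess(tab))
    f <- fit_association(pre, "qsm_accumbens_l", "ever_smoked")
    c(f$beta, f$se)
  })
  expect_lt(abs(mean(est[1, ])), 2 * mean(est[2, ]) / sqrt(20) * 3)
  # and without de-confounding the raw association is visibly non-zero
  sp <- cohort_spec(n = 4000, confounding_smoking = 0.8, confounding_trait = 0.5)
  tab <- quiet(simulate_cohort(sp, seed = 999))
  raw <- lm(scale(qsm_accumbens_l) ~ I(smoking_status != "never"), data = tab)
  expect_gt(abs(coef(raw)[2]), 0.1)
})

test_that("effect-size grid is ordered correctly by the estimates", {
  ok <- sapply(1:10, function(s) {
    b <- sapply(c(0, 0.1, 0.3), function(d) {
      sp <- cohort_spec(n = 5000, delta_current = d, delta_former = d)
      tab <- quiet(simulate_cohort(sp, seed = 1200 + s))
      pre <- quiet(pheno_preprocess(tab))
      fit_association(pre, "qsm_putamen_l", "ever_smoked")$beta
    })
    all(diff(b) > 0)
  })
  expect_gte(mean(ok), 0.9)
})
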