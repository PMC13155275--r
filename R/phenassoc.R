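#' Impute missing values with the group mean or mode
#'
#' Continuous columns receive the mean of the non-missing values; categorical
#' columns receive the mode, with ties broken by the first level in sorted
#' order. Counts of imputed cells are reported via `message()`.
#'
#' @param table A data frame.
#' @param columns Character vector of columns to impute.
#' @return The table with the named columns imputed.
#' @export
impute_missing <- function(table, columns) {
  stopifnot(all(columns %in% names(table)))
  n_imputed <- 0L
  for (col in columns) {
    x <- table[[col]]
    miss <- is.na(x)
    if (!any(miss)) next
    if (all(miss)) stop("column '", col, "' is entirely missing")
    if (is.numeric(x)) {
      x[miss] <- mean(x, na.rm = TRUE)
    } else {
      tabul <- table(as.character(x[!miss]))
      mode_val <- sort(names(tabul)[tabul == max(tabul)])[1]
      x[miss] <- mode_val
    }
    table[[col]] <- x
    n_imputed <- n_imputed + sum(miss)
  }
  if (n_imputed > 0) message(n_imputed, " value(s) imputed")
  table
}

#' Median-absolute-deviation outlier mask
#'
#' Keeps values within `k` absolute median deviations of the median, with
#' MAD = median(|x - median|) unscaled (no consistency factor). If MAD is
#' zero the rule degenerates to keeping exact-median values only. Missing
#' values are passed through as kept (there is nothing to exclude).
#'
#' @param values Numeric vector with at least 3 non-missing values.
#' @param k Multiplier (default 5).
#' @return Logical mask, TRUE = keep.
#' @export
mad_filter <- function(values, k = 5) {
  if (sum(!is.na(values)) < 3) stop("need at least 3 non-missing values")
  med <- stats::median(values, na.rm = TRUE)
  mad_raw <- stats::median(abs(values - med), na.rm = TRUE)
  keep <- if (mad_raw == 0) values == med else abs(values - med) <= k * mad_raw
  keep[is.na(keep)] <- TRUE
  keep
}

#' Shifted log transform for skewed variables
#'
#' `y = ln(x + s)` with `s = 1` for count-like variables with zeros
#' (pack-years) and `s = 1 - min(x)` for variables with negative support
#' (deprivation-index-like), so that the minimum maps to ln(1) = 0.
#'
#' @param values Numeric vector.
#' @param shift_policy `"one"` (s = 1) or `"min"` (s = 1 - min).
#' @return Transformed vector.
#' @export
log_transform <- function(values, shift_policy = c("one", "min")) {
  shift_policy <- match.arg(shift_policy)
  s <- switch(shift_policy, one = 1, min = 1 - min(values, na.rm = TRUE))
  if (any(values + s <= 0, na.rm = TRUE)) {
    stop("non-positive values after shift; transform undefined")
  }
  out <- log(values + s)
  if (any(!is.finite(out) & !is.na(out))) stop("non-finite values after log transform")
  out
}

#' Lifetime smoking dose in pack-years
#'
#' Cigarettes per day divided by 20 (a pack) times years smoked.
#'
#' @param cigs_per_day,years_smoked Non-negative numeric vectors.
#' @return Pack-years.
#' @export
pack_years <- function(cigs_per_day, years_smoked) {
  if (any(cigs_per_day < 0, na.rm = TRUE) || any(years_smoked < 0, na.rm = TRUE)) {
    stop("inputs must be non-negative")
  }
  cigs_per_day / 20 * years_smoked
}

#' Residualise a variable on a covariate set
#'
#' Ordinary least squares of `y` on an intercept plus the covariates; the
#' residuals become the de-confounded variable. Factors are expanded to
#' treatment contrasts. Rows with any missing value get a missing residual.
#'
#' @param y Numeric response vector.
#' @param covariates Data frame or matrix of covariates.
#' @return Residual vector, same length as `y`.
#' @export
deconfound <- function(y, covariates) {
  covariates <- as.data.frame(covariates)
  stopifnot(length(y) == nrow(covariates))
  mm <- stats::model.matrix(~ ., data = covariates)
  ok <- !is.na(y) & stats::complete.cases(covariates)
  if (sum(ok) <= ncol(mm)) stop("fewer complete rows than model columns")
  fit <- stats::lm.fit(mm[ok, , drop = FALSE], y[ok])
  if (fit$rank < ncol(mm)) {
    bad <- colnames(mm)[is.na(fit$coefficients)]
    stop("collinear covariate column(s): ", paste(bad, collapse = ", "))
  }
  out <- rep(NA_real_, length(y))
  out[ok] <- fit$residuals
  out
}

#' Rank-based inverse normal transformation
#'
#' Maps values through \eqn{\Phi^{-1}((r - 3/8)/(n + 1/4))} using Blom
#' offsets with average ranks for ties, then z-scores the result to mean 0,
#' SD 1. Missing values are preserved.
#'
#' @param values Numeric vector with at least 2 distinct non-missing values.
#' @return Transformed vector.
#' @export
int_transform <- function(values) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(unique(x)) < 2) stop("need at least 2 distinct values")
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  z <- (z - mean(z)) / stats::sd(z)
  out <- rep(NA_real_, length(values))
  out[ok] <- z
  out
}

.SMOKING_PREDICTORS <- c("ever_smoked", "current_smoking", "current_vs_never",
                         "current_vs_former", "former_vs_never", "pack_years")

#' Prepare a phenotype table for the association battery
#'
#' Applies the cleaning and transformation cascade: covariate imputation
#' (mean/mode); MAD-based outlier exclusion on the brain traits (excluded
#' values become missing); log transforms of pack-years (+1) and the
#' deprivation index (min-shift); residualisation of brain traits and
#' smoking variables on the full covariate set; rank-based inverse normal
#' transformation of the continuous variables. Binary smoking contrasts are
#' residualised but not rank-transformed.
#'
#' @param table Raw phenotype tibble (see [simulate_cohort()] for the
#'   column layout).
#' @param covariate_cols Covariate columns; defaults to the standard set
#'   (age and its square, sex and interactions, deprivation, income,
#'   education, alcohol, blood pressures, BMI, all `imaging_*` columns).
#' @param mad_k MAD multiplier for outlier exclusion.
#' @return Tibble with processed traits and the six smoking predictors, plus
#'   `cessation_years` (former smokers), raw `smoking_status`, `sex`,
#'   `age_z`.
#' @export
pheno_preprocess <- function(table, covariate_cols = NULL, mad_k = 5) {
  base_cov <- c("age", "sex", "townsend", "income", "education", "alcohol",
                "dbp", "sbp", "bmi")
  imaging_cols <- grep("^imaging_", names(table), value = TRUE)
  if (is.null(covariate_cols)) covariate_cols <- c(base_cov, imaging_cols)
  stopifnot(all(covariate_cols %in% names(table)),
            "smoking_status" %in% names(table))
  traits <- intersect(.BRAIN_TRAITS, names(table))
  if (!length(traits)) stop("no brain-trait columns found")

  table <- impute_missing(table, covariate_cols)
  n_excl <- 0L
  for (tr in traits) {
    keep <- mad_filter(table[[tr]], k = mad_k)
    n_excl <- n_excl + sum(!keep, na.rm = TRUE)
    table[[tr]][!keep] <- NA
  }
  if (n_excl > 0) message(n_excl, " outlier value(s) excluded (", mad_k, " MADs)")

  cov <- table[, covariate_cols, drop = FALSE]
  if ("townsend" %in% names(cov)) {
    cov$townsend <- log_transform(cov$townsend, "min")
  }
  if (all(c("age", "sex") %in% names(cov))) {
    cov$age2 <- cov$age^2
    male <- as.integer(cov$sex == levels(factor(cov$sex))[2])
    cov$age_x_sex <- cov$age * male
    cov$age2_x_sex <- cov$age2 * male
  }

  status <- table$smoking_status
  ind <- function(one, zero) {
    out <- rep(NA_real_, nrow(table))
    out[status %in% one] <- 1
    out[status %in% zero] <- 0
    out
  }
  preds <- tibble(
    ever_smoked = ind(c("current", "former"), "never"),
    current_smoking = ind("current", c("former", "never")),
    current_vs_never = ind("current", "never"),
    current_vs_former = ind("current", "former"),
    former_vs_never = ind("former", "never")
  )
  py <- table$pack_years
  py_t <- rep(NA_real_, nrow(table))
  ever <- status != "never" & !is.na(py)
  if (sum(ever) >= 3) {
    py_t[ever] <- int_transform(deconfound(log_transform(py, "one"),
                                           cov)[ever])
  }
  cess_t <- rep(NA_real_, nrow(table))
  former <- status == "former" & !is.na(table$cessation_years)
  if (sum(former) >= 3) {
    cess_t[former] <- int_transform(deconfound(table$cessation_years,
                                               cov)[former])
  }

  out <- tibble(participant_id = table$participant_id,
                smoking_status = status,
                sex = table$sex,
                age_z = as.numeric(scale(table$age)))
  for (tr in traits) {
    out[[tr]] <- int_transform(deconfound(table[[tr]], cov))
  }
  for (p in names(preds)) {
    out[[p]] <- deconfound(preds[[p]], cov)
  }
  out$pack_years <- py_t
  out$cessation_years <- cess_t
  structure(out, traits = traits)
}

#' Fit one smoking-brain trait association model
#'
#' Ordinary least squares of the processed brain trait on the processed
#' smoking predictor, optionally with a sex or age interaction. Rows where
#' the contrast is undefined (the excluded smoking group) drop out through
#' missingness.
#'
#' @param table Preprocessed table from [pheno_preprocess()].
#' @param trait Brain-trait column name.
#' @param smoking_var One of the six smoking predictors.
#' @param interaction `"none"`, `"sex"` or `"age"`.
#' @return Tibble with one row per coefficient (the smoking term and, with
#'   interaction, the product term): trait, predictor, beta, se, pval,
#'   n_used.
#' @export
fit_association <- function(table, trait, smoking_var,
                            interaction = c("none", "sex", "age")) {
  interaction <- match.arg(interaction)
  stopifnot(trait %in% names(table), smoking_var %in% names(table))
  df <- tibble(y = table[[trait]], x = table[[smoking_var]],
               sex = table$sex, age_z = table$age_z)
  df <- df[stats::complete.cases(df[c("y", "x")]), ]
  if (nrow(df) < 3) stop("empty contrast subset for ", smoking_var)
  form <- switch(interaction,
                 none = y ~ x,
                 sex = y ~ x * sex,
                 age = y ~ x * age_z)
  fit <- stats::lm(form, data = df)
  co <- summary(fit)$coefficients
  rows <- rownames(co)[grepl("^x", rownames(co))]
  tibble(
    trait = trait,
    predictor = sub("^x", smoking_var, rows),
    beta = co[rows, 1], se = co[rows, 2], pval = co[rows, 4],
    n_used = nrow(df)
  )
}

#' Full smoking-iron association battery with FDR control
#'
#' Runs the six smoking predictors against the twelve brain traits on a
#' preprocessed table and applies Benjamini-Hochberg correction across the
#' 72 main-effect tests.
#'
#' @param table Preprocessed table from [pheno_preprocess()].
#' @param alpha FDR threshold recorded in the result.
#' @param interaction Passed to [fit_association()]; q-values are computed
#'   on the main smoking terms only.
#' @return Tibble of class `pheno_battery` with columns trait, predictor,
#'   beta, se, pval, qval, n_used.
#' @export
pheno_battery <- function(table, alpha = 0.05, interaction = "none") {
  traits <- attr(table, "traits")
  if (is.null(traits)) traits <- intersect(.BRAIN_TRAITS, names(table))
  grid <- tidyr::expand_grid(trait = traits, predictor = .SMOKING_PREDICTORS)
  res <- purrr::pmap_dfr(grid, function(trait, predictor) {
    fit_association(table, trait, predictor, interaction = interaction)
  })
  main <- res$predictor %in% .SMOKING_PREDICTORS
  res$qval <- NA_real_
  res$qval[main] <- bh_fdr(res$pval[main])
  structure(res, alpha = alpha, class = c("pheno_battery", class(res)))
}

#' Cessation, dose and their interaction among former smokers
#'
#' For each brain trait, fits the former-smoker model with years since
#' cessation, pack-years and their interaction as joint predictors (both
#' predictors rank-inverse-normal transformed within the former-smoker
#' subset, so the fit is invariant to monotone shifts of either).
#'
#' @param table Preprocessed table from [pheno_preprocess()].
#' @return Tibble with three coefficient rows per trait.
#' @export
former_smoker_model <- function(table) {
  traits <- attr(table, "traits")
  if (is.null(traits)) traits <- intersect(.BRAIN_TRAITS, names(table))
  sub <- table[table$smoking_status == "former", ]
  sub <- sub[!is.na(sub$cessation_years) & !is.na(sub$pack_years), ]
  if (nrow(sub) < 50) {
    warning("only ", nrow(sub), " former smokers; estimates will be unstable")
  }
  cess <- int_transform(sub$cessation_years)
  py <- int_transform(sub$pack_years)
  purrr::map_dfr(traits, function(tr) {
    df <- tibble(y = sub[[tr]], cess = cess, py = py)
    df <- df[stats::complete.cases(df), ]
    fit <- stats::lm(y ~ cess * py, data = df)
    co <- summary(fit)$coefficients
    rows <- c("cess", "py", "cess:py")
    tibble(trait = tr,
           predictor = c("cessation_years", "pack_years",
                         "cessation_x_pack_years"),
           beta = co[rows, 1], se = co[rows, 2], pval = co[rows, 4],
           n_used = nrow(df))
  })
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Step-up adjusted q-values.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(all(pvals > 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Left-right asymmetry z-test for paired coefficients
#'
#' Compares hemispheric regression coefficients with
#' \eqn{z = (\beta_L - \beta_R)/\sqrt{se_L^2 + se_R^2}} and reports the
#' one-sided (upper-tail) normal probability; the left-greater direction is
#' the tested alternative. The test treats the two hemispheric errors as
#' independent (no L-R covariance term).
#'
#' @param beta_L,se_L,beta_R,se_R Coefficients and standard errors.
#' @return Tibble with columns z and p_one_sided.
#' @export
asymmetry_z <- function(beta_L, se_L, beta_R, se_R) {
  stopifnot(all(se_L > 0), all(se_R > 0))
  z <- (beta_L - beta_R) / sqrt(se_L^2 + se_R^2)
  tibble(z = z, p_one_sided = stats::pnorm(z, lower.tail = FALSE))
}

#' Robustness of one analysis against another
#'
#' Pearson correlation of the aligned effect estimates plus the Jaccard
#' index of significance concordance (significant in both / significant in
#' either, at `alpha` on q-values). When neither analysis finds anything
#' significant the Jaccard index is undefined and reported missing.
#'
#' @param resA,resB Association tables aligned on (trait, predictor) with
#'   columns beta and qval.
#' @param alpha Significance threshold on q-values.
#' @return Tibble with beta_correlation and jaccard.
#' @export
robustness <- function(resA, resB, alpha = 0.05) {
  keyA <- paste(resA$trait, resA$predictor)
  keyB <- paste(resB$trait, resB$predictor)
  if (length(keyA) != length(keyB) || !all(sort(keyA) == sort(keyB))) {
    stop("result sets are not aligned on (trait, predictor)")
  }
  resB <- resB[match(keyA, keyB), ]
  sigA <- which(resA$qval < alpha)
  sigB <- which(resB$qval < alpha)
  un <- length(union(sigA, sigB))
  tibble(
    beta_correlation = stats::cor(resA$beta, resB$beta),
    jaccard = if (un == 0) NA_real_ else length(intersect(sigA, sigB)) / un
  )
}
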