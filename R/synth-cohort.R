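.BRAIN_TRAITS <- as.vector(outer(
  c("t2s", "qsm"),
  as.vector(outer(c("putamen", "caudate", "accumbens"), c("l", "r"),
                  paste, sep = "_")),
  paste, sep = "_"
))

#' Names of the twelve striatal iron traits
#'
#' T2* and QSM in left and right putamen, caudate and accumbens. Higher iron
#' shortens T2* and raises QSM, so the two markers carry opposite sign
#' conventions for the same biology.
#'
#' @return Character vector of 12 trait column names.
#' @export
brain_trait_names <- function() .BRAIN_TRAITS

#' Specification of a synthetic imaging cohort
#'
#' Defines the generative model for a phenotype table: smoking-status mix
#' (defaults 3.3% current / 33.9% former / 62.8% never, 52.9% female, mean
#' age 64.2, SD 7.7), true standardised effects of the smoking variables on
#' each brain trait, confounding acting on both smoking and the traits,
#' interaction coefficients, and missingness/outlier injection rates.
#'
#' Effect arguments accept a scalar (applied to all 12 traits) or a named
#' vector over [brain_trait_names()].
#'
#' @param n Number of participants.
#' @param status_probs Probabilities of (current, former, never).
#' @param p_female Probability of female sex.
#' @param delta_current,delta_former Mean shift of each brain trait (in
#'   residual-SD units) for current/former relative to never smokers.
#' @param beta_pack_years Slope per SD of log pack-years (ever smokers).
#' @param beta_cessation Slope per SD of years since cessation (former
#'   smokers).
#' @param beta_cess_x_pack Interaction coefficient (former smokers).
#' @param interaction_sex,interaction_age Modulation of `delta_current` by
#'   sex (male = 1) and by age z-score.
#' @param confounding_smoking Log-odds shift of current/former membership per
#'   unit of the confounder index (age/deprivation composite).
#' @param confounding_trait Effect of the confounder index on every trait.
#' @param missing_rate Fraction of covariate and trait cells set missing.
#' @param outlier_rate Fraction of brain-trait cells replaced by gross
#'   outliers (10 SD), to exercise the MAD filter.
#' @param n_imaging_covars Number of opaque imaging covariates.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 1000L,
                        status_probs = c(current = 0.033, former = 0.339,
                                         never = 0.628),
                        p_female = 0.529,
                        delta_current = 0, delta_former = 0,
                        beta_pack_years = 0, beta_cessation = 0,
                        beta_cess_x_pack = 0,
                        interaction_sex = 0, interaction_age = 0,
                        confounding_smoking = 0, confounding_trait = 0,
                        missing_rate = 0.02, outlier_rate = 0.002,
                        n_imaging_covars = 5L) {
  stopifnot(n >= 10, length(status_probs) == 3,
            abs(sum(status_probs) - 1) < 1e-8,
            p_female >= 0, p_female <= 1,
            missing_rate >= 0, missing_rate < 1,
            outlier_rate >= 0, outlier_rate < 1)
  expand <- function(x) {
    if (length(x) == 1L && is.null(names(x))) {
      return(stats::setNames(rep(x, 12L), .BRAIN_TRAITS))
    }
    out <- stats::setNames(rep(0, 12L), .BRAIN_TRAITS)
    out[names(x)] <- x
    out
  }
  structure(list(
    n = as.integer(n), status_probs = status_probs, p_female = p_female,
    delta_current = expand(delta_current), delta_former = expand(delta_former),
    beta_pack_years = expand(beta_pack_years),
    beta_cessation = expand(beta_cessation),
    beta_cess_x_pack = expand(beta_cess_x_pack),
    interaction_sex = interaction_sex, interaction_age = interaction_age,
    confounding_smoking = confounding_smoking,
    confounding_trait = confounding_trait,
    missing_rate = missing_rate, outlier_rate = outlier_rate,
    n_imaging_covars = as.integer(n_imaging_covars)
  ), class = "cohort_spec")
}

#' Simulate an imaging-cohort phenotype table
#'
#' Covariates are drawn first; smoking status is assigned by a multinomial
#' logit whose log-odds may depend on a confounder index; pack-years come
#' from cigarettes/day and years smoked via the standard formula; former
#' smokers receive years since cessation; each brain trait is a linear
#' combination of confounders, the configured smoking effects and unit
#' Gaussian noise, shifted/scaled into marker-typical units. Missing values
#' and gross outliers are injected last.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A tibble with one row per participant: id, covariates, smoking
#'   variables and the 12 brain traits. The generative truth is attached as
#'   attribute `"truth"`.
#' @export
simulate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- spec$n
  z <- function(x) (x - mean(x)) / stats::sd(x)

  age <- pmin(pmax(stats::rnorm(n, 64.2, 7.7), 44), 85)
  sex <- factor(ifelse(stats::runif(n) < spec$p_female, "female", "male"),
                levels = c("female", "male"))
  townsend <- stats::rgamma(n, shape = 2, scale = 1.5) - 3
  income <- factor(sample(1:5, n, replace = TRUE,
                          prob = c(0.15, 0.25, 0.3, 0.2, 0.1)), ordered = TRUE)
  education <- factor(sample(c("basic", "secondary", "degree"), n,
                             replace = TRUE, prob = c(0.2, 0.4, 0.4)))
  alcohol <- factor(sample(1:6, n, replace = TRUE), ordered = TRUE)
  dbp <- stats::rnorm(n, 78, 10)
  sbp <- stats::rnorm(n, 135, 17)
  bmi <- stats::rnorm(n, 26.5, 4.2)
  imaging <- matrix(stats::rnorm(n * spec$n_imaging_covars), nrow = n)
  colnames(imaging) <- paste0("imaging_", seq_len(spec$n_imaging_covars))

  conf_index <- 0.5 * z(age) + 0.5 * z(townsend)
  lp_c <- log(spec$status_probs[["current"]] / spec$status_probs[["never"]]) +
    spec$confounding_smoking * conf_index
  lp_f <- log(spec$status_probs[["former"]] / spec$status_probs[["never"]]) +
    spec$confounding_smoking * conf_index
  den <- 1 + exp(lp_c) + exp(lp_f)
  u <- stats::runif(n)
  status <- factor(ifelse(u < exp(lp_c) / den, "current",
                   ifelse(u < (exp(lp_c) + exp(lp_f)) / den, "former",
                          "never")),
                   levels = c("current", "former", "never"))

  ever <- status != "never"
  cigs_per_day <- ifelse(ever, pmax(1, stats::rlnorm(n, log(12), 0.6)), NA)
  years_smoked <- ifelse(ever, pmin(stats::runif(n, 2, 40), age - 16), NA)
  py <- ifelse(ever, pack_years(ifelse(ever, cigs_per_day, 0),
                                ifelse(ever, years_smoked, 0)), NA)
  cess <- ifelse(status == "former",
                 pmax(0.5, age - 16 - years_smoked) * stats::runif(n), NA)

  # standardised smoking drivers used for the trait model (0 off-group)
  z_py <- rep(0, n)
  if (any(ever)) z_py[ever] <- z(log1p(py[ever]))
  z_cess <- rep(0, n)
  former <- status == "former"
  if (sum(former) > 2) z_cess[former] <- z(cess[former])
  z_age <- z(age)
  male <- as.integer(sex == "male")

  traits <- matrix(NA_real_, nrow = n, ncol = 12,
                   dimnames = list(NULL, .BRAIN_TRAITS))
  unit <- list(t2s = c(mu = 30, sd = 4), qsm = c(mu = 0.03, sd = 0.012))
  for (tr in .BRAIN_TRAITS) {
    dc <- spec$delta_current[[tr]] *
      (1 + spec$interaction_sex * male + spec$interaction_age * z_age)
    signal <- dc * (status == "current") +
      spec$delta_former[[tr]] * (status == "former") +
      spec$beta_pack_years[[tr]] * z_py +
      spec$beta_cessation[[tr]] * z_cess +
      spec$beta_cess_x_pack[[tr]] * z_cess * z_py +
      spec$confounding_trait * conf_index
    std <- signal + stats::rnorm(n)
    un <- unit[[substr(tr, 1, 3)]]
    traits[, tr] <- un[["mu"]] + un[["sd"]] * std
  }
  if (spec$outlier_rate > 0) {
    hit <- which(matrix(stats::runif(n * 12) < spec$outlier_rate, n, 12))
    for (k in hit) {
      tr <- .BRAIN_TRAITS[(k - 1) %/% n + 1]
      un <- unit[[substr(tr, 1, 3)]]
      traits[k] <- traits[k] + sample(c(-1, 1), 1) * 10 * un[["sd"]]
    }
  }

  tab <- tibble(
    participant_id = sprintf("P%06d", seq_len(n)),
    age = age, sex = sex, townsend = townsend, income = income,
    education = education, alcohol = alcohol, dbp = dbp, sbp = sbp,
    bmi = bmi
  )
  tab <- dplyr::bind_cols(tab, as_tibble(imaging))
  tab$smoking_status <- status
  tab$pack_years <- py
  tab$cessation_years <- cess
  tab <- dplyr::bind_cols(tab, as_tibble(traits))

  if (spec$missing_rate > 0) {
    missable <- c("townsend", "income", "education", "alcohol", "dbp", "sbp",
                  "bmi", .BRAIN_TRAITS)
    for (col in missable) {
      drop <- stats::runif(n) < spec$missing_rate
      tab[[col]][drop] <- NA
    }
  }
  attr(tab, "truth") <- c(unclass(spec), list(seed = seed))
  tab
}
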