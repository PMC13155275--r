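#' Cross-trait genetic architecture for the summary-statistic simulator
#'
#' Assigns each gene one of five classes describing how its SNP effects act
#' on the two traits: `null` (no local effect), `coherent` (identical effect
#' vectors), `anticoherent` (negated), `causal_fwd` (trait-2 effects are
#' `gamma` times trait-1 effects, the signature of an exposure-to-outcome
#' causal path), `causal_rev` (the mirror image), or `private_1` /
#' `private_2` (effects on one trait only -- the trait-specific loci real
#' traits always carry, needed so that both causal directions can be
#' instrumented independently). A polygenic background
#' with optional cross-trait correlation sits underneath, and participant
#' overlap between the two GWAS enters as a correlated noise term.
#'
#' @param classes Named character vector mapping gene_id to class; genes not
#'   named are `null`.
#' @param tau2 Per-SNP effect-size variance inside non-null genes, on the
#'   standardised scale.
#' @param gamma Causal coefficient for the `causal_*` classes.
#' @param bg_var Total polygenic background variance per trait (spread over
#'   all SNPs).
#' @param bg_cross_corr Correlation of the background effects across the two
#'   traits; this is the simulator's true genome-wide genetic correlation
#'   when all genes are null.
#' @param overlap_n Number of participants shared by the two GWAS.
#' @param env_corr Phenotypic correlation of the two traits among shared
#'   participants; together with `overlap_n` it sets the test-statistic
#'   cross-correlation `rho_ov = overlap_n * env_corr / sqrt(n1 * n2)`.
#' @return A list of class `architecture_spec`.
#' @export
architecture_spec <- function(classes = character(), tau2 = 0.001,
                              gamma = 0, bg_var = 0, bg_cross_corr = 0,
                              overlap_n = 0L, env_corr = 0) {
  valid <- c("null", "coherent", "anticoherent", "causal_fwd", "causal_rev",
             "private_1", "private_2")
  if (length(classes) && (is.null(names(classes)) || !all(classes %in% valid))) {
    stop("classes must be a named vector with values in: ",
         paste(valid, collapse = ", "))
  }
  stopifnot(tau2 >= 0, is.finite(gamma), bg_var >= 0, bg_var <= 1,
            abs(bg_cross_corr) <= 1, overlap_n >= 0,
            env_corr > -1, env_corr < 1)
  structure(list(classes = classes, tau2 = tau2, gamma = gamma,
                 bg_var = bg_var, bg_cross_corr = bg_cross_corr,
                 overlap_n = as.integer(overlap_n), env_corr = env_corr),
            class = "architecture_spec")
}

# block sizes for a panel: stored by generate_panel, overridable, else one
# block for small panels
.panel_blocks <- function(panel, blocks = NULL) {
  if (is.null(blocks)) blocks <- attr(panel, "blocks")
  m <- nrow(panel$map)
  if (is.null(blocks)) {
    if (m > 4000) stop("large external panel: supply LD `blocks` explicitly")
    blocks <- m
  }
  stopifnot(sum(blocks) == m)
  as.integer(blocks)
}

# per-block regularised LD correlation: (1-eps) * Sigma + eps * I
.block_sigma <- function(panel, blocks, eps = 1e-3) {
  offset <- 0L
  lapply(blocks, function(sz) {
    idx <- offset + seq_len(sz)
    offset <<- offset + sz
    s <- stats::cor(t(panel$haps[idx, , drop = FALSE]))
    s[is.na(s)] <- 0
    diag(s) <- 1
    (1 - eps) * s + eps * diag(sz)
  })
}

#' Simulate paired GWAS summary statistics with known architecture
#'
#' Draws true per-SNP effects according to the gene classes in `arch`, then
#' simulates the two GWAS z-score vectors from the standard summary-statistic
#' model \eqn{z = \sqrt{n}\,\Sigma b + \epsilon}, \eqn{\epsilon \sim
#' N(0, \Sigma)} per LD block, with cross-trait noise covariance
#' \eqn{\rho_{ov}\Sigma} induced by participant overlap. Betas are reported
#' on the standardised scale with \eqn{se = 1/\sqrt{n}}.
#'
#' @param panel A `haplotype_panel` (from [generate_panel()] or
#'   [read_panel_vcf()]).
#' @param annotation Gene-annotation tibble.
#' @param arch An [architecture_spec()].
#' @param n1,n2 GWAS sample sizes for the two traits.
#' @param seed Integer seed.
#' @param trait_names Length-2 character vector of trait labels.
#' @param blocks Optional LD block sizes for external panels.
#' @return A list with elements `ss1`, `ss2` (both [sumstats]) and `truth`
#'   (per-gene class table plus `gamma`, `rho_ov`, `bg_cross_corr`).
#' @export
simulate_summary_pair <- function(panel, annotation, arch, n1, n2, seed,
                                  trait_names = c("exposure", "outcome"),
                                  blocks = NULL) {
  stopifnot(inherits(arch, "architecture_spec"), n1 >= 1, n2 >= 1)
  if (arch$overlap_n > min(n1, n2)) {
    stop("overlap_n cannot exceed the smaller GWAS sample size")
  }
  ord <- order(panel$map$chrom, panel$map$pos)
  panel$haps <- panel$haps[ord, , drop = FALSE]
  panel$map <- panel$map[ord, ]
  m <- nrow(panel$map)
  blocks <- .panel_blocks(panel, blocks)
  sig <- .block_sigma(panel, blocks)
  chol_list <- lapply(sig, function(s) {
    ch <- tryCatch(chol(s), error = function(e) NULL)
    if (is.null(ch)) stop("LD matrix not positive definite after regularisation")
    ch
  })

  set.seed(seed)
  # true standardised effects: polygenic background with cross-trait corr
  sd_bg <- sqrt(arch$bg_var / m)
  b1 <- stats::rnorm(m, 0, sd_bg)
  b2 <- arch$bg_cross_corr * b1 +
    sqrt(1 - arch$bg_cross_corr^2) * stats::rnorm(m, 0, sd_bg)
  # gene-local shared/causal components
  gene_cls <- stats::setNames(rep("null", nrow(annotation)), annotation$gene_id)
  gene_cls[names(arch$classes)] <- arch$classes
  for (g in seq_len(nrow(annotation))) {
    cls <- gene_cls[[annotation$gene_id[g]]]
    if (cls == "null") next
    in_gene <- which(panel$map$chrom == annotation$chrom[g] &
                       panel$map$pos >= annotation$start[g] &
                       panel$map$pos <= annotation$end[g])
    if (!length(in_gene)) next
    u <- stats::rnorm(length(in_gene), 0, sqrt(arch$tau2))
    inc <- switch(cls,
      coherent     = list(u, u),
      anticoherent = list(u, -u),
      causal_fwd   = list(u, arch$gamma * u),
      causal_rev   = list(arch$gamma * u, u),
      private_1    = list(u, 0),
      private_2    = list(0, u)
    )
    b1[in_gene] <- b1[in_gene] + inc[[1]]
    b2[in_gene] <- b2[in_gene] + inc[[2]]
  }
  if (sum(b1^2) > 1 || sum(b2^2) > 1) {
    stop("total genetic variance exceeds 1 on the standardised scale")
  }

  rho_ov <- arch$overlap_n * arch$env_corr / sqrt(n1 * n2)
  z1 <- numeric(m); z2 <- numeric(m)
  offset <- 0L
  for (b in seq_along(blocks)) {
    idx <- offset + seq_len(blocks[b]); offset <- offset + blocks[b]
    mu1 <- sqrt(n1) * drop(sig[[b]] %*% b1[idx])
    mu2 <- sqrt(n2) * drop(sig[[b]] %*% b2[idx])
    g1 <- stats::rnorm(blocks[b]); g2 <- stats::rnorm(blocks[b])
    e1 <- drop(crossprod(chol_list[[b]], g1))
    e2 <- drop(crossprod(chol_list[[b]],
                         rho_ov * g1 + sqrt(1 - rho_ov^2) * g2))
    z1[idx] <- mu1 + e1
    z2[idx] <- mu2 + e2
  }

  eaf <- rowMeans(panel$haps) # frequency of the alt (effect) allele
  mk <- function(z, n, trait) {
    sumstats(tibble(
      snp_id = panel$map$snp_id, chrom = panel$map$chrom,
      pos = panel$map$pos,
      allele_effect = panel$map$alt, allele_other = panel$map$ref,
      eaf = eaf, beta = z / sqrt(n), se = 1 / sqrt(n),
      pval = pmax(2 * stats::pnorm(-abs(z)), 1e-300), n = as.integer(n)
    ), trait_name = trait)
  }
  list(
    ss1 = mk(z1, n1, trait_names[1]),
    ss2 = mk(z2, n2, trait_names[2]),
    truth = list(
      genes = tibble(gene_id = names(gene_cls), class = unname(gene_cls)),
      gamma = arch$gamma, rho_ov = rho_ov,
      bg_cross_corr = arch$bg_cross_corr, tau2 = arch$tau2,
      seed = seed
    )
  )
}
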