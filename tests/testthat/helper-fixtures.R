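# Shared synthetic fixtures, built once per test run on first use.
.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# 600-SNP genome in 40 AR(0.6) blocks of 20; used by the MR suite.
# 2000 haplotypes keep null-pair r^2 noise below the clumping threshold.
fx_mr_panel <- function() fx("mr_panel", function() {
  generate_panel(2000, ld_block_spec(rep(20, 40), ar_rho = 0.6,
                                     maf_range = c(0.1, 0.5)),
                 spacing_bp = 1000, seed = 7)
})

# genes tiling the MR genome one-per-block
fx_mr_genes <- function() fx("mr_genes", function() {
  generate_annotation(40, gene_len_bp = 19001, gap_bp = 999, seed = 2)
})

# 2000-SNP genome with heterogeneous LD for the LDSC suite, plus LD scores
fx_ldsc_panel <- function() fx("ldsc_panel", function() {
  generate_panel(4000,
                 ld_block_spec(rep(25, 80), ar_rho = rep(c(0, 0.4, 0.7, 0.9), 20),
                               maf_range = c(0.05, 0.5)),
                 spacing_bp = 2000, seed = 3)
})

fx_ldsc_ld <- function() fx("ldsc_ld", function() {
  ld_scores(fx_ldsc_panel(), window_bp = 1e5)
})

fx_ldsc_genes <- function() fx("ldsc_genes", function() {
  generate_annotation(5, 10000, 500000, seed = 1)
})

# gene-test genome: one 10-SNP AR(0.8) block per gene, windows == blocks
fx_gene_panel <- function(ngene = 1000) fx(paste0("gene_panel_", ngene), function() {
  generate_panel(400, ld_block_spec(rep(10, ngene), ar_rho = 0.8,
                                    maf_range = c(0.05, 0.5)),
                 spacing_bp = 1000, seed = 5)
})

fx_gene_ann <- function(ngene = 1000) fx(paste0("gene_ann_", ngene), function() {
  generate_annotation(ngene, gene_len_bp = 9001, gap_bp = 999, seed = 1)
})

# null z-scores + windows on the gene-test genome
fx_null_scan <- function(seed = 21, rho_ov_n = 0) {
  key <- paste0("null_scan_", seed, "_", rho_ov_n)
  fx(key, function() {
    pan <- fx_gene_panel(); ann <- fx_gene_ann()
    n <- 1e4
    arch <- architecture_spec(tau2 = 0, bg_var = 0,
                              overlap_n = rho_ov_n, env_corr = 0.5)
    sim <- simulate_summary_pair(pan, ann, arch, n, n, seed = seed)
    h <- harmonise_sumstats(sim$ss1, sim$ss2)
    zA <- signed_rank_z(h$ss1); zB <- signed_rank_z(h$ss2)
    bw <- build_windows(ann, zA, pan, flank_bp = 0)
    list(zA = zA, zB = zB, bw = bw, truth = sim$truth)
  })
}

# tiny deterministic sumstats table for IO tests
fx_toy_sumstats <- function(m = 10, seed = 99) {
  set.seed(seed)
  sumstats(tibble::tibble(
    snp_id = sprintf("rs%03d", seq_len(m)), chrom = "1",
    pos = seq_len(m) * 100L,
    allele_effect = "G", allele_other = "A",
    eaf = runif(m, 0.05, 0.95),
    beta = rnorm(m, 0, 0.05), se = runif(m, 0.01, 0.05),
    pval = runif(m), n = 5000L
  ), trait_name = "toy")
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
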