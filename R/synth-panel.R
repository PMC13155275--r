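#' LD block specification for the synthetic reference panel
#'
#' The toy genome is a sequence of independent LD blocks; within a block,
#' haplotypes are generated by thresholding a latent AR(1) Gaussian process
#' with autocorrelation `ar_rho`, which yields decaying pairwise LD of the
#' kind LD-score regression and the gene tests must handle.
#'
#' @param block_sizes Integer vector; SNPs per block.
#' @param ar_rho Latent AR(1) correlation per block, in [0, 1); recycled.
#' @param maf_range Interval within (0.01, 0.5] from which population minor
#'   allele frequencies are drawn uniformly.
#' @return A list of class `ld_block_spec`.
#' @export
ld_block_spec <- function(block_sizes, ar_rho = 0, maf_range = c(0.05, 0.5)) {
  stopifnot(all(block_sizes >= 1), all(ar_rho >= 0), all(ar_rho < 1),
            length(maf_range) == 2, maf_range[1] < maf_range[2])
  if (maf_range[1] < 0.01 || maf_range[2] > 0.5) {
    stop("maf_range must lie within (0.01, 0.5]")
  }
  ar_rho <- rep_len(ar_rho, length(block_sizes))
  structure(list(block_sizes = as.integer(block_sizes), ar_rho = ar_rho,
                 maf_range = maf_range),
            class = "ld_block_spec")
}

#' Generate a synthetic phased haplotype panel with block LD
#'
#' Haplotypes are drawn by thresholding a blockwise AR(1) latent Gaussian at
#' the quantile matching each SNP's sampled minor allele frequency, so that
#' adjacent SNPs within a block are in LD while blocks are independent.
#' Columns that come out monomorphic at the realised sample size are patched
#' by flipping a single haplotype, so no monomorphic SNP is ever emitted.
#'
#' @param n_haplotypes Even number of haplotypes (two per sample), >= 50.
#' @param spec An [ld_block_spec()].
#' @param chrom Chromosome label for the SNP map.
#' @param start_pos Position of the first SNP (1-based).
#' @param spacing_bp Distance between adjacent SNPs in bp.
#' @param seed Integer RNG seed; same seed, same panel.
#' @return A `haplotype_panel` whose block boundaries are retained for the
#'   summary-statistic simulator.
#' @export
generate_panel <- function(n_haplotypes, spec, chrom = "1", start_pos = 1L,
                           spacing_bp = 1000L, seed) {
  stopifnot(inherits(spec, "ld_block_spec"), n_haplotypes >= 50,
            n_haplotypes %% 2 == 0, spacing_bp >= 1)
  set.seed(seed)
  m <- sum(spec$block_sizes)
  haps <- matrix(0L, nrow = m, ncol = n_haplotypes)
  maf <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
  offset <- 0L
  for (b in seq_along(spec$block_sizes)) {
    sz <- spec$block_sizes[b]
    rho <- spec$ar_rho[b]
    lat <- matrix(0, nrow = sz, ncol = n_haplotypes)
    lat[1, ] <- stats::rnorm(n_haplotypes)
    if (sz > 1) {
      for (j in 2:sz) {
        lat[j, ] <- rho * lat[j - 1, ] +
          sqrt(1 - rho^2) * stats::rnorm(n_haplotypes)
      }
    }
    idx <- offset + seq_len(sz)
    haps[idx, ] <- (lat < stats::qnorm(maf[idx])) + 0L
    offset <- offset + sz
  }
  # patch monomorphic draws (possible at small n and low MAF)
  mono <- which(rowSums(haps) %in% c(0L, n_haplotypes))
  for (j in mono) haps[j, sample.int(n_haplotypes, 1)] <- 1L - haps[j, 1]
  map <- tibble(
    snp_id = sprintf("rs%06d", seq_len(m)),
    chrom = as.character(chrom),
    pos = as.integer(start_pos + (seq_len(m) - 1L) * spacing_bp),
    ref = "A", alt = "G",
    maf = pmin(rowMeans(haps), 1 - rowMeans(haps))
  )
  new_panel(haps, map, blocks = spec$block_sizes)
}

#' Generate a non-overlapping gene annotation tiling a chromosome
#'
#' Genes of fixed length separated by a fixed gap tile the chromosome from
#' `start_pos`. Choosing `gap_bp` smaller than twice the window flank makes
#' adjacent gene windows overlap, which is what the gene-cluster reporting
#' has to handle.
#'
#' @param n_genes Number of genes.
#' @param gene_len_bp Gene length in bp.
#' @param gap_bp Gap between consecutive genes in bp.
#' @param chrom Chromosome label.
#' @param start_pos Start of the first gene (1-based).
#' @param seed Integer seed (used for strand assignment only; geometry is
#'   deterministic).
#' @return A gene-annotation tibble (gene_id, chrom, start, end, strand).
#' @export
generate_annotation <- function(n_genes, gene_len_bp, gap_bp, chrom = "1",
                                start_pos = 1L, seed = 1L) {
  stopifnot(n_genes >= 1, gene_len_bp >= 1, gap_bp >= 0)
  set.seed(seed)
  starts <- as.integer(start_pos + (seq_len(n_genes) - 1L) *
                         (gene_len_bp + gap_bp))
  tibble(
    gene_id = sprintf("G%04d", seq_len(n_genes)),
    chrom = as.character(chrom),
    start = starts,
    end = as.integer(starts + gene_len_bp - 1L),
    strand = sample(c("+", "-"), n_genes, replace = TRUE)
  )
}
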