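#' @importFrom dplyr %>% arrange mutate filter select all_of across
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

.SUMSTATS_COLS <- c("snp_id", "chrom", "pos", "allele_effect", "allele_other",
                    "eaf", "beta", "se", "pval", "n")

#' Construct a GWAS summary-statistics table
#'
#' A `sumstats` object is a tibble with one row per SNP and the canonical
#' columns `snp_id, chrom, pos, allele_effect, allele_other, eaf, beta, se,
#' pval, n`, sorted by (chrom, pos), carrying the trait name as an attribute.
#'
#' @param df Data frame with the canonical columns.
#' @param trait_name Name of the trait the statistics describe.
#' @return A `sumstats` tibble sorted by (chrom, pos).
#' @export
sumstats <- function(df, trait_name = "trait") {
  df <- as_tibble(df)
  missing_cols <- setdiff(.SUMSTATS_COLS, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, .SUMSTATS_COLS]
  if (anyDuplicated(df$snp_id)) stop("duplicated snp_id in summary statistics")
  if (any(df$se <= 0, na.rm = TRUE)) stop("se must be > 0")
  if (any(df$pval <= 0 | df$pval > 1, na.rm = TRUE)) stop("pval must be in (0, 1]")
  if (any(df$allele_effect == df$allele_other)) {
    stop("effect and other allele must differ")
  }
  if (any(!nzchar(df$allele_effect)) || any(!nzchar(df$allele_other))) {
    stop("alleles must be non-empty")
  }
  df <- arrange(df, .data$chrom, .data$pos)
  structure(df, trait_name = trait_name, n_total = max(df$n, 0L),
            class = c("sumstats", class(df)))
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Public summary statistics use varying header names; `dialect` maps the
#' canonical name to the name found in the file, e.g.
#' `c(snp_id = "SNP", pval = "P")`. Rows with missing beta, se or p are
#' dropped (with a message giving the count); p-values of exactly zero are
#' clamped to 1e-300 with a warning so that downstream normal quantiles stay
#' finite.
#'
#' @param path Path to a tab-separated file with a header row; "." denotes
#'   missing values.
#' @param dialect Named character vector mapping canonical column names to
#'   file column names; unnamed defaults assume canonical headers.
#' @param trait_name Trait label to attach.
#' @return A [sumstats] tibble.
#' @export
read_sumstats <- function(path, dialect = NULL, trait_name = "trait") {
  raw <- readr::read_tsv(path, na = c("", "NA", "."), show_col_types = FALSE,
                         progress = FALSE)
  nm <- stats::setNames(.SUMSTATS_COLS, .SUMSTATS_COLS)
  if (!is.null(dialect)) nm[names(dialect)] <- dialect
  missing_cols <- setdiff(unname(nm), names(raw))
  if (length(missing_cols)) {
    stop("input lacks required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- raw[, unname(nm)]
  names(df) <- names(nm)
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    if (!is.numeric(df[[col]])) {
      bad <- which(!is.na(df[[col]]) & is.na(suppressWarnings(as.numeric(df[[col]]))))
      if (length(bad)) {
        stop("non-numeric value in column '", col, "' at data line ", bad[1])
      }
      df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    }
  }
  df$chrom <- as.character(df$chrom)
  keep <- !(is.na(df$beta) | is.na(df$se) | is.na(df$pval))
  if (any(!keep)) {
    message(sum(!keep), " row(s) dropped for missing beta/se/pval")
    df <- df[keep, ]
  }
  if (any(df$pval == 0)) {
    warning("p-values of 0 clamped to 1e-300")
    df$pval[df$pval == 0] <- 1e-300
  }
  sumstats(df, trait_name = trait_name)
}

#' Write summary statistics to a tab-separated file
#'
#' The inverse of [read_sumstats()]: rows are written sorted by (chrom, pos)
#' with the canonical header, missing values as ".", so that
#' `read_sumstats(write_sumstats(ss, f))` reproduces `ss` field for field.
#'
#' @param ss A [sumstats] object (or data frame with the canonical columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  if (!inherits(ss, "sumstats")) ss <- sumstats(ss)
  out <- as_tibble(unclass(ss)[.SUMSTATS_COLS])
  readr::write_tsv(out, path, na = ".", progress = FALSE)
  invisible(path)
}

#' Read a phased haplotype reference panel from VCF
#'
#' Parses a VCF with phased genotypes into a 0/1 haplotype matrix (SNPs in
#' rows, one column per haplotype, i.e. two per sample) plus a SNP map.
#' Multiallelic sites are skipped with a message; unphased genotypes are a
#' hard error because the panel is the source of haplotype-level LD.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return A `haplotype_panel`: list with `haps` (SNPs x haplotypes 0/1
#'   matrix), `map` (tibble: snp_id, chrom, pos, ref, alt, maf) and
#'   `n_haplotypes`.
#' @export
read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L || ncol(v@gt) < 2L) stop("VCF contains no samples or no sites")
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT) | nchar(fix$ALT) == 0
  if (any(multi)) {
    message(sum(multi), " multiallelic/invalid site(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  if (nrow(fix) == 0L) stop("no biallelic sites in VCF")
  if (any(grepl("/", gt, fixed = TRUE))) {
    stop("unphased genotypes in panel VCF; a phased panel is required")
  }
  a1 <- suppressWarnings(as.integer(substr(gt, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3, 3)))
  if (anyNA(a1) || anyNA(a2)) stop("missing or malformed GT fields in panel VCF")
  m <- nrow(gt)
  haps <- matrix(0L, nrow = m, ncol = 2L * ncol(gt))
  haps[, seq(1, 2 * ncol(gt), by = 2)] <- a1
  haps[, seq(2, 2 * ncol(gt), by = 2)] <- a2
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  map <- tibble(
    snp_id = ids, chrom = as.character(fix$CHROM),
    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    maf = pmin(rowMeans(haps), 1 - rowMeans(haps))
  )
  new_panel(haps, map)
}

new_panel <- function(haps, map, blocks = NULL) {
  stopifnot(nrow(haps) == nrow(map))
  structure(
    list(haps = haps, map = map, n_haplotypes = ncol(haps)),
    blocks = blocks, class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> ", nrow(x$map), " SNPs x ", x$n_haplotypes,
      " haplotypes\n", sep = "")
  invisible(x)
}

#' Write a haplotype panel as a phased VCF
#'
#' @param panel A `haplotype_panel`.
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  n_s <- panel$n_haplotypes / 2
  gt <- matrix(paste0(panel$haps[, seq(1, 2 * n_s, by = 2), drop = FALSE], "|",
                      panel$haps[, seq(2, 2 * n_s, by = 2), drop = FALSE]),
               nrow = nrow(panel$map))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=smokiron",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("S%04d", seq_len(n_s))), collapse = "\t")
  )
  body <- paste(panel$map$chrom, panel$map$pos, panel$map$snp_id,
                panel$map$ref, panel$map$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a gene annotation from a BED4 file
#'
#' BED intervals are 0-based half-open; they are converted to the package's
#' 1-based inclusive convention on read (a BED line `chr1 999 2000 G` becomes
#' start 1000, end 2000). Strand is set to "+" when absent (BED4); windowing
#' is strand-symmetric so this is inert.
#'
#' @param path Path to a BED file with at least 4 columns
#'   (chrom, start, end, name).
#' @return A tibble with columns gene_id, chrom, start, end, strand.
#' @export
read_genes_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty gene annotation")
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  parts <- strsplit(lines, "\t| +")
  if (any(lengths(parts) < 4L)) {
    stop("BED line ", which(lengths(parts) < 4L)[1], " has fewer than 4 fields")
  }
  chrom <- vapply(parts, `[[`, "", 1)
  start0 <- as.integer(vapply(parts, `[[`, "", 2))
  end0 <- as.integer(vapply(parts, `[[`, "", 3))
  gene_id <- vapply(parts, `[[`, "", 4)
  strand <- vapply(parts, function(p) if (length(p) >= 6) p[[6]] else "+", "")
  bad <- which(end0 <= start0)
  if (length(bad)) {
    stop("BED line ", bad[1], ": end (", end0[bad[1]], ") <= start (",
         start0[bad[1]], ")")
  }
  if (anyDuplicated(gene_id)) {
    stop("duplicated gene_id in annotation: ",
         gene_id[duplicated(gene_id)][1])
  }
  tibble(gene_id = gene_id, chrom = chrom, start = start0 + 1L, end = end0,
         strand = ifelse(strand %in% c("+", "-"), strand, "+")) %>%
    arrange(.data$chrom, .data$start)
}

#' Write a gene annotation as BED4
#'
#' @param genes Tibble as returned by [read_genes_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_bed <- function(genes, path) {
  writeLines(paste(genes$chrom, genes$start - 1L, genes$end, genes$gene_id,
                   0L, genes$strand, sep = "\t"), path)
  invisible(path)
}

#' Pipeline configuration with study defaults
#'
#' Collects the analysis constants in one place: the 50-kb gene flank, the
#' MAF >= 0.01 SNP filter, alpha = 0.05, the 5-MAD outlier rule, instrument
#' selection p < 5e-8 with fallback p < 1e-5 when fewer than five
#' instruments survive clumping at r-squared > 0.001.
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    flank_bp = 50000L, maf_min = 0.01, alpha = 0.05, mad_k = 5,
    iv_pthresh = 5e-8, iv_fallback_pthresh = 1e-5, clump_r2 = 0.001,
    min_iv = 5L, seed = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$flank_bp >= 0, cfg$maf_min > 0, cfg$maf_min < 0.5,
            cfg$alpha > 0, cfg$alpha < 1, cfg$mad_k > 0,
            cfg$iv_pthresh > 0, cfg$iv_fallback_pthresh >= cfg$iv_pthresh,
            cfg$clump_r2 >= 0, cfg$clump_r2 <= 1, cfg$min_iv >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Write a JSON run manifest
#'
#' Records inputs, configuration, seed and package version next to a result
#' file so that any output can be re-executed exactly.
#'
#' @param path Path of the manifest file to write.
#' @param inputs Named list or character vector of input descriptions.
#' @param config A [pipeline_config()] or named list.
#' @param seed The RNG seed used by the stage (may be NULL for
#'   deterministic stages).
#' @return `path`, invisibly.
#' @export
run_manifest <- function(path, inputs = list(), config = list(), seed = NULL) {
  manifest <- list(
    package = "smokiron",
    version = as.character(utils::packageVersion("smokiron")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    inputs = inputs,
    config = unclass(config)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
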