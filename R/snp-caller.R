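#' Caller parameters for putative-SNP identification
#'
#' A putative SNP requires a minimum read depth in both pools and either a
#' wildtype-pool major allele fraction (MAF) inside the heterozygous band,
#' or differing major alleles between the pools. The mutant pool is classed
#' homozygous when its MAF reaches `hom_threshold`.
#'
#' @param min_depth minimum mapped reads required in each pool (default 10).
#' @param wt_maf_lo,wt_maf_hi inclusive wildtype MAF band (defaults 0.50 and
#'   0.75) marking a site heterozygous in the wildtype pool.
#' @param hom_threshold mutant-pool MAF at or above which the site is
#'   classed homozygous (default 0.90).
#' @return list of class `caller_params`.
#' @export
caller_params <- function(min_depth = 10L, wt_maf_lo = 0.50, wt_maf_hi = 0.75,
                          hom_threshold = 0.90) {
  stopifnot(min_depth >= 1, wt_maf_lo >= 0, wt_maf_lo <= wt_maf_hi,
            wt_maf_hi <= 1, hom_threshold > 0, hom_threshold <= 1)
  structure(list(min_depth = as.integer(min_depth), wt_maf_lo = wt_maf_lo,
                 wt_maf_hi = wt_maf_hi, hom_threshold = hom_threshold),
            class = "caller_params")
}

#' Major allele of a base-count vector
#'
#' Ties are broken in fixed alphabetical order A < C < G < T so that calls
#' are deterministic; the tie is flagged.
#'
#' @param counts named numeric vector with entries `A`, `C`, `G`, `T`.
#' @return list with `base`, `frac` (share of the summed counts) and `tie`.
#' @examples
#' major_allele(c(A = 12, C = 0, G = 10, T = 0))
#' @export
major_allele <- function(counts) {
  counts <- counts[BASES]
  tot <- sum(counts)
  if (tot <= 0) stop("major_allele: all-zero counts (filter by depth first)")
  k <- which.max(counts)               # first max = alphabetical tie-break
  list(base = BASES[k], frac = counts[[k]] / tot,
       tie = sum(counts == counts[[k]]) > 1)
}

#' Call putative SNPs from position-matched pool counts
#'
#' Applies the pooled-BSA criteria site by site: positions with fewer than
#' `min_depth` reads in either pool are skipped; the rest are called
#' putative SNPs when (i) the wildtype-pool MAF lies inside
#' `[wt_maf_lo, wt_maf_hi]`, or (ii) the two pools' major alleles differ
#' (a pure OR; the `criterion` column records which held). Mutant-pool
#' zygosity is `homozygous` when the mutant MAF is at or above
#' `hom_threshold`. Skipped symbols (deletions, reference skips, N calls)
#' never enter a MAF denominator.
#'
#' @param pooled data.frame from [join_pools()].
#' @param params a [caller_params()] object.
#' @param quiet suppress the examined/called/homozygous summary message.
#' @return data.frame with one row per call: `chrom`, `pos`, `ref`,
#'   `wt_major`, `wt_maf`, `wt_depth`, `mut_major`, `mut_maf`, `mut_depth`,
#'   `criterion` (one of `wt_het_band`, `major_allele_differs`, `both`),
#'   `zygosity` (`homozygous`/`heterozygous`) and `tie` (TRUE when either
#'   pool's major allele was a broken tie). The summary counts are attached
#'   as attribute `summary`.
#' @export
call_snps <- function(pooled, params = caller_params(), quiet = FALSE) {
  stopifnot(inherits(params, "caller_params"))
  n <- nrow(pooled)
  wt_m <- as.matrix(pooled[, c("wt_A", "wt_C", "wt_G", "wt_T")])
  mut_m <- as.matrix(pooled[, c("mut_A", "mut_C", "mut_G", "mut_T")])
  wt_depth <- rowSums(wt_m)
  mut_depth <- rowSums(mut_m)
  deep <- wt_depth >= params$min_depth & mut_depth >= params$min_depth
  wt_k <- max.col(wt_m, ties.method = "first")
  mut_k <- max.col(mut_m, ties.method = "first")
  wt_max <- wt_m[cbind(seq_len(n), wt_k)]
  mut_max <- mut_m[cbind(seq_len(n), mut_k)]
  wt_maf <- ifelse(wt_depth > 0, wt_max / wt_depth, NA_real_)
  mut_maf <- ifelse(mut_depth > 0, mut_max / mut_depth, NA_real_)
  band <- deep & wt_maf >= params$wt_maf_lo & wt_maf <= params$wt_maf_hi
  differs <- deep & wt_k != mut_k
  keep <- which(band | differs)
  criterion <- ifelse(band[keep] & differs[keep], "both",
                      ifelse(band[keep], "wt_het_band", "major_allele_differs"))
  wt_tie <- rowSums(wt_m == wt_max) > 1
  mut_tie <- rowSums(mut_m == mut_max) > 1
  calls <- data.frame(
    chrom = pooled$chrom[keep], pos = pooled$pos[keep], ref = pooled$ref[keep],
    wt_major = BASES[wt_k[keep]], wt_maf = wt_maf[keep],
    wt_depth = as.integer(wt_depth[keep]),
    mut_major = BASES[mut_k[keep]], mut_maf = mut_maf[keep],
    mut_depth = as.integer(mut_depth[keep]),
    criterion = criterion,
    zygosity = ifelse(mut_maf[keep] >= params$hom_threshold,
                      "homozygous", "heterozygous"),
    tie = wt_tie[keep] | mut_tie[keep],
    stringsAsFactors = FALSE
  )
  rownames(calls) <- NULL
  summary <- c(examined = n, called = nrow(calls),
               homozygous = sum(calls$zygosity == "homozygous"))
  attr(calls, "summary") <- summary
  if (!quiet) {
    message(sprintf("call_snps: %d sites examined, %d putative SNPs, %d homozygous in MUT",
                    summary[["examined"]], summary[["called"]], summary[["homozygous"]]))
  }
  calls
}

#' Call one position-matched site
#'
#' Single-site convenience wrapper around the same criteria as
#' [call_snps()].
#'
#' @param wt,mut named count vectors over `A`, `C`, `G`, `T`.
#' @param params a [caller_params()] object.
#' @param chrom,pos,ref site annotation carried into the call.
#' @return one-row call data.frame, or `NULL` if the site is not called.
#' @export
call_site <- function(wt, mut, params = caller_params(),
                      chrom = "NA", pos = 0L, ref = "N") {
  pooled <- data.frame(chrom = chrom, pos = pos, ref = ref,
                       wt_A = wt[["A"]], wt_C = wt[["C"]], wt_G = wt[["G"]],
                       wt_T = wt[["T"]], wt_skipped = 0L,
                       mut_A = mut[["A"]], mut_C = mut[["C"]], mut_G = mut[["G"]],
                       mut_T = mut[["T"]], mut_skipped = 0L,
                       stringsAsFactors = FALSE)
  out <- call_snps(pooled, params, quiet = TRUE)
  if (nrow(out) == 0) NULL else out
}

#' Write SNP calls as TSV
#' @param calls data.frame from [call_snps()].
#' @param file path.
#' @export
write_snp_tsv <- function(calls, file) {
  utils::write.table(calls, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read SNP calls written by [write_snp_tsv()]
#' @param file path.
#' @return calls data.frame.
#' @export
read_snp_tsv <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' Write SNP calls as a minimal sites-only VCF 4.2
#'
#' ALT is the mutant-pool major allele, or the non-reference major allele
#' when the mutant major equals the reference; INFO carries both pools'
#' depths and major-allele fractions and the mutant zygosity class.
#'
#' @param calls data.frame from [call_snps()].
#' @param file path.
#' @export
write_snp_vcf <- function(calls, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=bsamap",
    '##INFO=<ID=WTD,Number=1,Type=Integer,Description="WT pool depth over A/C/G/T">',
    '##INFO=<ID=WTMAF,Number=1,Type=Float,Description="WT pool major allele fraction">',
    '##INFO=<ID=MUTD,Number=1,Type=Integer,Description="MUT pool depth over A/C/G/T">',
    '##INFO=<ID=MUTMAF,Number=1,Type=Float,Description="MUT pool major allele fraction">',
    '##INFO=<ID=ZYG,Number=1,Type=String,Description="MUT pool zygosity class">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls) > 0) {
    alt <- ifelse(calls$mut_major != calls$ref, calls$mut_major,
                  ifelse(calls$wt_major != calls$ref, calls$wt_major, "."))
    info <- sprintf("WTD=%d;WTMAF=%.4f;MUTD=%d;MUTMAF=%.4f;ZYG=%s",
                    calls$wt_depth, calls$wt_maf, calls$mut_depth,
                    calls$mut_maf, calls$zygosity)
    writeLines(paste(calls$chrom, calls$pos, ".", calls$ref, alt, ".", ".",
                     info, sep = "\t"), con)
  }
  invisible(NULL)
}
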