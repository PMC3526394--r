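#' Informative meioses in a phenotype-sorted bulk
#'
#' In a het x het intercross scored on homozygous-mutant progeny both of an
#' embryo's chromosomes are informative meiotic products, so a bulk of `n`
#' embryos carries `2n` meioses.
#'
#' @param n_embryos number of embryos in the bulk.
#' @param chromosomes_per_embryo informative chromosomes per embryo
#'   (default 2; configurable for other designs).
#' @return integer meiosis count.
#' @examples
#' meioses_from_embryos(650)  # 1300
#' @export
meioses_from_embryos <- function(n_embryos, chromosomes_per_embryo = 2L) {
  if (n_embryos < 1) stop("need at least one embryo")
  as.integer(n_embryos) * as.integer(chromosomes_per_embryo)
}

#' Genetic distance from recombinant counts
#'
#' Direct recombination-fraction estimate: `100 * recombinants / meioses`
#' centimorgans. No map function is applied; at the sub-centimorgan
#' distances of fine mapping the recombination fraction and the map
#' distance agree to well within counting error.
#'
#' @param recombinants recombinant chromosome count.
#' @param meioses total meioses scored.
#' @return distance in cM.
#' @examples
#' genetic_distance(13, 1300)  # 1 cM
#' @export
genetic_distance <- function(recombinants, meioses) {
  if (meioses < 1) stop("meioses must be >= 1")
  if (any(recombinants < 0) || any(recombinants > meioses)) {
    stop("recombinants must lie in [0, meioses]")
  }
  100 * recombinants / meioses
}

#' Score recombinants from a per-embryo genotype table
#'
#' Genotypes are scored on mutant embryos (N-homozygous at the causal
#' locus): at a linked marker, a `het` embryo carries one recombinant
#' chromosome and a `mapcross_hom` embryo two; `N_hom` embryos carry none.
#'
#' @param genotypes data.frame with columns `embryo_id`, `marker_id`,
#'   `genotype` (one of `N_hom`, `het`, `mapcross_hom`).
#' @return data.frame per marker: `marker_id`, `recombinants`, `meioses`,
#'   `distance_cM`.
#' @export
score_recombinants <- function(genotypes) {
  stopifnot(all(c("embryo_id", "marker_id", "genotype") %in% names(genotypes)))
  bad <- setdiff(unique(genotypes$genotype), c("N_hom", "het", "mapcross_hom"))
  if (length(bad) > 0) stop(sprintf("unknown genotype code '%s'", bad[1]))
  rec_per <- c(N_hom = 0L, het = 1L, mapcross_hom = 2L)
  out <- do.call(rbind, lapply(split(genotypes, genotypes$marker_id), function(g) {
    rec <- sum(rec_per[g$genotype])
    mei <- meioses_from_embryos(length(unique(g$embryo_id)))
    data.frame(marker_id = g$marker_id[1], recombinants = rec, meioses = mei,
               distance_cM = genetic_distance(rec, mei),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Flag candidate genome misassembly from multi-scaffold LOH signal
#'
#' A single recessive locus should produce high homozygosity ratios on one
#' scaffold only; non-excluded regions at or above the threshold ratio on
#' more than one scaffold indicate that part of some scaffold is
#' misassembled (or a second linked locus).
#'
#' @param stats `loh_scan` data.frame from [region_stats()].
#' @param threshold ratio at or above which a region counts (default 0.9).
#' @return list of class `misassembly_flag` with `flag` (logical),
#'   `scaffolds` (character) and `threshold`.
#' @export
flag_misassembly <- function(stats, threshold = 0.9) {
  hits <- stats[!stats$excluded & !is.na(stats$ratio) &
                  stats$ratio >= threshold, , drop = FALSE]
  scaffolds <- sort(unique(hits$chrom))
  structure(list(flag = length(scaffolds) > 1, scaffolds = scaffolds,
                 threshold = threshold),
            class = "misassembly_flag")
}

#' @export
print.misassembly_flag <- function(x, ...) {
  if (x$flag) {
    cat(sprintf(
      "Possible misassembly: LOH ratio >= %.2f on %d scaffolds: %s\n",
      x$threshold, length(x$scaffolds), paste(x$scaffolds, collapse = ", ")))
  } else if (length(x$scaffolds) == 1) {
    cat(sprintf("LOH signal confined to one scaffold (%s); no misassembly flag\n",
                x$scaffolds))
  } else {
    cat("No region reaches the LOH threshold; no misassembly flag\n")
  }
  invisible(x)
}
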