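#' Scan parameters for the homozygosity-ratio scan
#'
#' @param window_size window width in bp for long scaffolds (default 0.5 Mb).
#' @param min_region_snps regions with fewer total SNPs than this are
#'   excluded from ranking (default 20; a region with exactly 20 is kept).
#' @param long_scaffold_cutoff scaffolds at or below this length form a
#'   single scaffold-mode region; longer ones are tiled into windows
#'   (default: the window size).
#' @return list of class `scan_params`.
#' @export
scan_params <- function(window_size = 500000L, min_region_snps = 20L,
                        long_scaffold_cutoff = window_size) {
  stopifnot(window_size >= 1, min_region_snps >= 1, long_scaffold_cutoff >= 1)
  structure(list(window_size = as.numeric(window_size),
                 min_region_snps = as.integer(min_region_snps),
                 long_scaffold_cutoff = as.numeric(long_scaffold_cutoff)),
            class = "scan_params")
}

#' Partition scaffolds into scan regions
#'
#' Short scaffolds become one whole-scaffold region; scaffolds longer than
#' the cutoff are tiled with consecutive non-overlapping windows
#' `[1, W], [W+1, 2W], ...`, the last window truncated at the scaffold end.
#'
#' @param scaffold_lengths named vector of scaffold lengths in bp.
#' @param params a [scan_params()] object.
#' @return data.frame with columns `chrom`, `start`, `end` (1-based,
#'   inclusive) and `mode` (`scaffold` or `window`).
#' @export
make_regions <- function(scaffold_lengths, params = scan_params()) {
  stopifnot(inherits(params, "scan_params"))
  if (anyDuplicated(names(scaffold_lengths))) {
    stop("duplicate scaffold names in length table")
  }
  if (any(scaffold_lengths < 1)) stop("scaffold lengths must be >= 1")
  pieces <- lapply(names(scaffold_lengths), function(nm) {
    len <- scaffold_lengths[[nm]]
    if (len <= params$long_scaffold_cutoff) {
      data.frame(chrom = nm, start = 1L, end = as.integer(len),
                 mode = "scaffold", stringsAsFactors = FALSE)
    } else {
      starts <- seq(1, len, by = params$window_size)
      data.frame(chrom = nm, start = as.integer(starts),
                 end = as.integer(pmin(starts + params$window_size - 1, len)),
                 mode = "window", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Homozygosity-ratio statistics per region
#'
#' Assigns every SNP call to the unique region containing its position and
#' computes, per region, the total SNP count `nt`, the mutant-pool
#' homozygous count `nh`, and the homozygosity ratio `ratio = nh / nt`
#' (NA when `nt` is 0). Regions with `nt < min_region_snps` are marked
#' `excluded`.
#'
#' @param calls SNP-call data.frame from [call_snps()].
#' @param regions region data.frame from [make_regions()].
#' @param params a [scan_params()] object.
#' @return `regions` extended with `nt`, `nh`, `ratio`, `excluded`, of class
#'   `loh_scan`.
#' @export
region_stats <- function(calls, regions, params = scan_params()) {
  stopifnot(inherits(params, "scan_params"))
  nt <- integer(nrow(regions))
  nh <- integer(nrow(regions))
  if (nrow(calls) > 0) {
    unknown <- setdiff(unique(calls$chrom), unique(regions$chrom))
    if (length(unknown) > 0) {
      stop(sprintf("SNP call on unknown scaffold '%s'", unknown[1]))
    }
    hom <- calls$zygosity == "homozygous"
    for (chrom in unique(calls$chrom)) {
      ri <- which(regions$chrom == chrom)
      ci <- which(calls$chrom == chrom)
      # regions tile [1, len] consecutively, so findInterval on starts works
      idx <- findInterval(calls$pos[ci], regions$start[ri])
      bad <- idx < 1 | calls$pos[ci] > regions$end[ri][pmax(idx, 1)]
      if (any(bad)) {
        k <- ci[which(bad)[1]]
        stop(sprintf("SNP call at %s:%d outside every region", chrom, calls$pos[k]))
      }
      tab <- tabulate(idx, nbins = length(ri))
      htab <- tabulate(idx[hom[ci]], nbins = length(ri))
      nt[ri] <- nt[ri] + tab
      nh[ri] <- nh[ri] + htab
    }
  }
  out <- regions
  out$nt <- nt
  out$nh <- nh
  out$ratio <- ifelse(nt > 0, nh / nt, NA_real_)
  out$excluded <- nt < params$min_region_snps
  class(out) <- c("loh_scan", "data.frame")
  out
}

#' Rank candidate LOH regions
#'
#' Non-excluded regions sorted by homozygosity ratio (descending), ties by
#' total SNP count (descending), then coordinates; excluded regions are
#' omitted.
#'
#' @param stats `loh_scan` data.frame from [region_stats()].
#' @return ranked `loh_scan` data.frame.
#' @export
rank_regions <- function(stats) {
  keep <- stats[!stats$excluded & stats$nt > 0, , drop = FALSE]
  ord <- order(-keep$ratio, -keep$nt, keep$chrom, keep$start)
  out <- keep[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("loh_scan", "data.frame")
  out
}

#' @export
print.loh_scan <- function(x, ...) {
  cat(sprintf("LOH scan: %d regions (%d excluded by the SNP-count filter)\n",
              nrow(x), sum(x$excluded)))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("... and %d more regions\n", nrow(x) - 10))
  invisible(x)
}

#' Fraction of the genome excluded by the SNP-count filter
#'
#' @param stats `loh_scan` data.frame.
#' @return fraction of total scaffold bp lying in excluded regions.
#' @export
excluded_genome_fraction <- function(stats) {
  width <- stats$end - stats$start + 1
  sum(width[stats$excluded]) / sum(width)
}

#' Write region statistics as TSV
#' @param stats `loh_scan` data.frame.
#' @param file path.
#' @export
write_region_tsv <- function(stats, file) {
  utils::write.table(as.data.frame(stats), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Write region statistics as BED
#'
#' Coordinates convert to 0-based half-open; the score column is
#' `round(1000 * ratio)` (0 when the ratio is undefined).
#'
#' @param stats `loh_scan` data.frame.
#' @param file path.
#' @export
write_region_bed <- function(stats, file) {
  score <- ifelse(is.na(stats$ratio), 0, round(1000 * stats$ratio))
  name <- sprintf("%s_%d_%s", stats$chrom, stats$start,
                  ifelse(stats$excluded, "excluded", "ok"))
  lines <- paste(stats$chrom, format(stats$start - 1, scientific = FALSE, trim = TRUE),
                 format(stats$end, scientific = FALSE, trim = TRUE), name, score,
                 sep = "\t")
  writeLines(lines, file)
  invisible(NULL)
}
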