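# Independent brute-force re-evaluation of the putative-SNP criteria,
# written naively site by site (no shared code with the caller).
oracle_call_one <- function(wt, mut, min_depth = 10, lo = 0.5, hi = 0.75,
                            hom = 0.9) {
  bases <- c("A", "C", "G", "T")
  wt <- wt[bases]; mut <- mut[bases]
  if (sum(wt) < min_depth || sum(mut) < min_depth) return(NULL)
  wt_sorted <- sort(wt, decreasing = TRUE)
  # alphabetical tie-break: among bases with maximal count, pick first in A<C<G<T
  wt_major <- bases[which(wt == max(wt))][1]
  mut_major <- bases[which(mut == max(mut))][1]
  wt_maf <- wt[[wt_major]] / sum(wt)
  mut_maf <- mut[[mut_major]] / sum(mut)
  band <- (wt_maf >= lo) && (wt_maf <= hi)
  differs <- wt_major != mut_major
  if (!band && !differs) return(NULL)
  list(wt_major = wt_major, wt_maf = wt_maf, mut_major = mut_major,
       mut_maf = mut_maf,
       criterion = if (band && differs) "both"
                   else if (band) "wt_het_band" else "major_allele_differs",
       zygosity = if (mut_maf >= hom) "homozygous" else "heterozygous")
}

random_pooled_sites <- function(n, max_count = 40) {
  cnt <- function() matrix(rpois(4 * n, lambda = sample(0:12, 1) + 2), n, 4)
  wt <- cnt(); mut <- cnt()
  data.frame(
    chrom = rep("z", n), pos = seq_len(n), ref = sample(c("A", "C", "G", "T"), n, TRUE),
    wt_A = wt[, 1], wt_C = wt[, 2], wt_G = wt[, 3], wt_T = wt[, 4],
    wt_skipped = 0L,
    mut_A = mut[, 1], mut_C = mut[, 2], mut_G = mut[, 3], mut_T = mut[, 4],
    mut_skipped = 0L, stringsAsFactors = FALSE
  )
}

random_site_counts <- function(n, chrom = "s1") {
  cnt <- matrix(rpois(4 * n, 3), n, 4)
  skipped <- rpois(n, 0.5)
  keep <- rowSums(cnt) + skipped > 0
  cnt <- cnt[keep, , drop = FALSE]
  skipped <- skipped[keep]
  m <- nrow(cnt)
  data.frame(
    chrom = chrom, pos = sort(sample.int(n * 10, m)),
    ref = sample(c("A", "C", "G", "T"), m, TRUE),
    A = cnt[, 1], C = cnt[, 2], G = cnt[, 3], T = cnt[, 4],
    skipped = skipped, depth = rowSums(cnt) + skipped,
    stringsAsFactors = FALSE
  )
}

# Small shared simulation for cross-module tests.
tiny_sim_config <- function(seed = 1, ...) {
  sim_config(
    scaffolds = stats::setNames(rep(5e5, 3), c("a", "b", "c")),
    causal = list(chrom = "b", pos = 250000),
    n_mut_embryos = 20L, n_wt_embryos = 20L,
    seed = seed, ...
  )
}

sim_to_calls <- function(sim, params = caller_params()) {
  pooled <- join_pools(sim$wt[sim$wt$depth > 0, , drop = FALSE],
                       sim$mut[sim$mut$depth > 0, , drop = FALSE])
  call_snps(pooled, params, quiet = TRUE)
}
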