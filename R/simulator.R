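#' Haldane map function
#'
#' Converts map distance to recombination fraction assuming no crossover
#' interference: `theta = (1 - exp(-2 m)) / 2` with `m` in Morgans.
#'
#' @param d_cm map distance in centimorgans.
#' @return recombination fraction in `[0, 0.5)`.
#' @examples
#' haldane_theta(1)  # ~0.0099
#' @export
haldane_theta <- function(d_cm) {
  (1 - exp(-2 * d_cm / 100)) / 2
}

#' Configuration of a simulated BSA intercross
#'
#' Describes a het x het mapcross — a mutagenized-strain (N) carrier
#' crossed to a divergent mapcross strain — whose progeny are
#' phenotype-sorted into a homozygous-mutant bulk and a wildtype bulk and
#' pooled-sequenced at finite depth. The defaults define the package's
#' standard desk-scale study: 10 scaffolds of 2 Mb, informative markers
#' every 10 kb on average, a recessive causal locus at the midpoint of
#' scaffold `s05`, 50 embryos per bulk, mean depth 30, per-base miscall
#' rate 0.002 and map density 1.2 cM/Mb.
#'
#' @param scaffolds named vector of scaffold lengths in bp.
#' @param snp_spacing_bp mean spacing of informative heterozygous markers
#'   (exponential inter-marker gaps).
#' @param causal list/vector with `chrom` and `pos` of the recessive locus.
#' @param n_mut_embryos,n_wt_embryos bulk sizes.
#' @param depth_mean mean sequencing depth per marker per pool (Poisson).
#' @param error_rate per-base miscall probability (uniform to the three
#'   other bases).
#' @param cm_per_mb genetic map density.
#' @param seed integer seed governing all randomness.
#' @param emit_invariant_sites also emit monomorphic reference positions
#'   between markers (parser stress; default FALSE).
#' @param relocate optional misassembly fixture: list with `chrom`,
#'   `start`, `end`, `to`, `at` — markers in `[start, end]` of `chrom` are
#'   re-addressed to scaffold `to` starting at position `at` (genotypes
#'   unchanged), emulating a block placed on the wrong scaffold.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(scaffolds = stats::setNames(rep(2e6, 10), sprintf("s%02d", 1:10)),
                       snp_spacing_bp = 10000,
                       causal = list(chrom = "s05", pos = 1e6),
                       n_mut_embryos = 50L, n_wt_embryos = 50L,
                       depth_mean = 30, error_rate = 0.002,
                       cm_per_mb = 1.2, seed = 1L,
                       emit_invariant_sites = FALSE,
                       relocate = NULL) {
  causal <- as.list(causal)
  stopifnot(!is.null(names(scaffolds)), all(scaffolds >= 1),
            snp_spacing_bp > 0, n_mut_embryos >= 1, n_wt_embryos >= 1,
            depth_mean > 0, error_rate >= 0, error_rate <= 1, cm_per_mb >= 0)
  if (!(causal$chrom %in% names(scaffolds))) {
    stop("causal scaffold not in scaffold table")
  }
  causal$pos <- as.numeric(causal$pos)
  if (causal$pos < 1 || causal$pos > scaffolds[[causal$chrom]]) {
    stop("causal position outside its scaffold")
  }
  structure(list(scaffolds = scaffolds, snp_spacing_bp = snp_spacing_bp,
                 causal = causal, n_mut_embryos = as.integer(n_mut_embryos),
                 n_wt_embryos = as.integer(n_wt_embryos),
                 depth_mean = depth_mean, error_rate = error_rate,
                 cm_per_mb = cm_per_mb, seed = as.integer(seed),
                 emit_invariant_sites = isTRUE(emit_invariant_sites),
                 relocate = relocate),
            class = "sim_config")
}

#' Place informative markers along the simulated genome
#'
#' Inter-marker gaps are exponential with mean `snp_spacing_bp`; each
#' marker carries distinct N-strain and mapcross-strain alleles drawn
#' uniformly. The causal position is always included as a marker. Uses the
#' current RNG state (seed management happens in [simulate_bsa()]).
#'
#' @param config a [sim_config()].
#' @return data.frame: `chrom`, `pos`, `N_allele`, `mapcross_allele`,
#'   `is_causal`.
#' @export
place_markers <- function(config) {
  pieces <- lapply(names(config$scaffolds), function(nm) {
    len <- config$scaffolds[[nm]]
    n_max <- stats::qpois(1 - 1e-12, lambda = len / config$snp_spacing_bp) + 10
    gaps <- stats::rexp(n_max, rate = 1 / config$snp_spacing_bp)
    pos <- floor(cumsum(gaps)) + 1
    pos <- unique(pos[pos <= len])
    if (nm == config$causal$chrom) pos <- sort(unique(c(pos, config$causal$pos)))
    if (length(pos) == 0) return(NULL)
    data.frame(chrom = nm, pos = pos, stringsAsFactors = FALSE)
  })
  mk <- do.call(rbind, pieces)
  mk$pos <- as.integer(mk$pos)
  n <- nrow(mk)
  n_idx <- sample.int(4, n, replace = TRUE)
  shift <- sample.int(3, n, replace = TRUE)
  m_idx <- ((n_idx - 1 + shift) %% 4) + 1
  mk$N_allele <- BASES[n_idx]
  mk$mapcross_allele <- BASES[m_idx]
  mk$is_causal <- mk$chrom == config$causal$chrom & mk$pos == config$causal$pos
  rownames(mk) <- NULL
  mk
}

#' Simulate one gamete's parental origins along a scaffold
#'
#' Sequential Markov walk: the first marker's origin is a fair coin;
#' between adjacent markers `d` bp apart the origin switches with Haldane
#' probability `theta(d * cm_per_mb / 1e6)`.
#'
#' @param positions sorted marker positions (bp) on one scaffold.
#' @param cm_per_mb map density.
#' @return logical vector, TRUE where the gamete carries the N allele.
#' @export
simulate_gamete <- function(positions, cm_per_mb) {
  n <- length(positions)
  if (n == 0) return(logical(0))
  theta <- haldane_theta(diff(positions) * cm_per_mb / 1e6)
  flips <- c(stats::rbinom(1, 1, 0.5), stats::rbinom(n - 1, 1, theta))
  (cumsum(flips) %% 2) == 1
}

# Batch gamete simulation: one logical matrix (markers x gametes) per call.
simulate_gametes_matrix <- function(markers, cm_per_mb, n_gametes) {
  mats <- lapply(split(seq_len(nrow(markers)), markers$chrom), function(idx) {
    pos <- markers$pos[idx]        # already sorted within scaffold
    n <- length(pos)
    theta <- haldane_theta(diff(pos) * cm_per_mb / 1e6)
    flips <- matrix(0L, nrow = n, ncol = n_gametes)
    flips[1, ] <- stats::rbinom(n_gametes, 1, 0.5)
    if (n > 1) {
      flips[-1, ] <- stats::rbinom((n - 1) * n_gametes, 1, rep(theta, n_gametes))
    }
    (apply(flips, 2, cumsum) %% 2) == 1
  })
  out <- matrix(FALSE, nrow = nrow(markers), ncol = n_gametes)
  for (chrom in names(mats)) {
    out[markers$chrom == chrom, ] <- mats[[chrom]]
  }
  out
}

#' Simulate the phenotype-sorted cross
#'
#' Embryos are drawn as two independent gametes from N/mapcross F1
#' parents; an embryo is mutant iff it is N-homozygous at the causal
#' marker. Drawing continues (rejection sampling) until the mutant bulk
#' holds `n_mut_embryos` mutant embryos and the wildtype bulk
#' `n_wt_embryos` non-mutant embryos, whose causal-locus genotypes then
#' follow the conditional Mendelian 2:1 het : mapcross-hom ratio.
#'
#' @param config a [sim_config()].
#' @param markers marker table from [place_markers()] (placed if missing).
#' @return list of class `bsa_truth`: `markers`, gamete origin matrices
#'   `mut_g1`, `mut_g2`, `wt_g1`, `wt_g2` (TRUE = N allele), and an
#'   `expectations` data.frame carrying the analytic per-marker allele
#'   frequencies (`theta` to the causal locus, `exp_mut_n_freq = 1 - theta`,
#'   `exp_wt_n_freq = 1/3 + theta/3`, with `theta = 0.5` off the causal
#'   scaffold).
#' @export
simulate_cross <- function(config, markers = NULL) {
  if (is.null(markers)) markers <- place_markers(config)
  causal_idx <- which(markers$is_causal)
  stopifnot(length(causal_idx) == 1)
  need_mut <- config$n_mut_embryos
  need_wt <- config$n_wt_embryos
  mut_g1 <- mut_g2 <- matrix(FALSE, nrow(markers), 0)
  wt_g1 <- wt_g2 <- matrix(FALSE, nrow(markers), 0)
  batch <- 4L * (need_mut + need_wt)
  for (iter in seq_len(100L)) {
    if (ncol(mut_g1) >= need_mut && ncol(wt_g1) >= need_wt) break
    g1 <- simulate_gametes_matrix(markers, config$cm_per_mb, batch)
    g2 <- simulate_gametes_matrix(markers, config$cm_per_mb, batch)
    is_mut <- g1[causal_idx, ] & g2[causal_idx, ]
    take_mut <- which(is_mut)[seq_len(min(sum(is_mut), need_mut - ncol(mut_g1)))]
    take_wt <- which(!is_mut)[seq_len(min(sum(!is_mut), need_wt - ncol(wt_g1)))]
    mut_g1 <- cbind(mut_g1, g1[, take_mut, drop = FALSE])
    mut_g2 <- cbind(mut_g2, g2[, take_mut, drop = FALSE])
    wt_g1 <- cbind(wt_g1, g1[, take_wt, drop = FALSE])
    wt_g2 <- cbind(wt_g2, g2[, take_wt, drop = FALSE])
  }
  if (ncol(mut_g1) < need_mut || ncol(wt_g1) < need_wt) {
    stop("rejection-sampling budget exceeded; pathological config")
  }
  d_bp <- ifelse(markers$chrom == config$causal$chrom,
                 abs(markers$pos - config$causal$pos), NA)
  theta <- ifelse(is.na(d_bp), 0.5, haldane_theta(d_bp * config$cm_per_mb / 1e6))
  expectations <- data.frame(
    chrom = markers$chrom, pos = markers$pos, theta = theta,
    exp_mut_n_freq = 1 - theta,
    exp_wt_n_freq = 1 / 3 + theta / 3,
    stringsAsFactors = FALSE
  )
  structure(list(markers = markers, mut_g1 = mut_g1, mut_g2 = mut_g2,
                 wt_g1 = wt_g1, wt_g2 = wt_g2, expectations = expectations,
                 causal = config$causal),
            class = "bsa_truth")
}

# Distribute miscalls from each true-allele read count to the other bases.
add_errors <- function(true_counts, allele_idx, error_rate) {
  # true_counts: n x 1 reads carrying allele allele_idx (1..4)
  n <- length(true_counts)
  out <- matrix(0L, n, 4)
  n_err <- stats::rbinom(n, true_counts, error_rate)
  out[cbind(seq_len(n), allele_idx)] <- true_counts - n_err
  nz <- which(n_err > 0)
  for (i in nz) {
    others <- setdiff(1:4, allele_idx[i])
    spread <- stats::rmultinom(1, n_err[i], rep(1 / 3, 3))[, 1]
    out[i, others] <- out[i, others] + spread
  }
  out
}

pool_site_counts <- function(truth, g1, g2, config) {
  mk <- truth$markers
  n <- nrow(mk)
  n_chrom <- 2L * ncol(g1)
  k_n <- rowSums(g1) + rowSums(g2)            # N-allele chromosomes per marker
  depth <- stats::rpois(n, config$depth_mean)
  reads_n <- stats::rbinom(n, depth, k_n / n_chrom)
  reads_m <- depth - reads_n
  n_idx <- match(mk$N_allele, BASES)
  m_idx <- match(mk$mapcross_allele, BASES)
  counts <- add_errors(reads_n, n_idx, config$error_rate) +
    add_errors(reads_m, m_idx, config$error_rate)
  df <- data.frame(
    chrom = mk$chrom, pos = mk$pos, ref = mk$mapcross_allele,
    A = counts[, 1], C = counts[, 2], G = counts[, 3], T = counts[, 4],
    skipped = 0L, depth = as.integer(depth),
    stringsAsFactors = FALSE
  )
  df
}

#' Pooled sequencing of the two bulks
#'
#' Per marker and pool, depth is Poisson(`depth_mean`); each read samples a
#' chromosome uniformly from the bulk's `2n` chromosomes and reports its
#' allele, miscalled to a uniform other base with probability
#' `error_rate`. The emitted reference base is the mapcross-strain allele
#' (the reads are imagined aligned to a mapcross-derived assembly).
#' Non-marker positions are not emitted (exome sparsity) unless
#' `emit_invariant_sites` is set.
#'
#' @param truth a `bsa_truth` from [simulate_cross()].
#' @param config the [sim_config()] used.
#' @return list with `wt` and `mut` site-counts data.frames (the
#'   [read_pileup()] layout).
#' @export
sequence_pools <- function(truth, config) {
  wt <- pool_site_counts(truth, truth$wt_g1, truth$wt_g2, config)
  mut <- pool_site_counts(truth, truth$mut_g1, truth$mut_g2, config)
  if (config$emit_invariant_sites) {
    inv <- lapply(names(config$scaffolds), function(nm) {
      len <- config$scaffolds[[nm]]
      pos <- seq(1, len, by = config$snp_spacing_bp * 2)
      pos <- setdiff(pos, truth$markers$pos[truth$markers$chrom == nm])
      if (length(pos) == 0) return(NULL)
      ref <- sample(BASES, length(pos), replace = TRUE)
      d <- stats::rpois(length(pos), config$depth_mean)
      cnt <- matrix(0L, length(pos), 4)
      cnt[cbind(seq_along(pos), match(ref, BASES))] <- d
      data.frame(chrom = nm, pos = pos, ref = ref,
                 A = cnt[, 1], C = cnt[, 2], G = cnt[, 3], T = cnt[, 4],
                 skipped = 0L, depth = d, stringsAsFactors = FALSE)
    })
    inv <- do.call(rbind, inv)
    inv <- inv[inv$depth > 0, , drop = FALSE]
    wt <- sort_sites(rbind(wt, inv), names(config$scaffolds))
    mut <- sort_sites(rbind(mut, inv), names(config$scaffolds))
  }
  list(wt = wt, mut = mut)
}

sort_sites <- function(sites, chrom_order) {
  ord <- order(match(sites$chrom, chrom_order), sites$pos)
  out <- sites[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Misassembly fixture: re-address a marker block to another scaffold.
apply_relocation <- function(truth, config) {
  r <- config$relocate
  if (is.null(r)) return(truth)
  stopifnot(all(c("chrom", "start", "end", "to", "at") %in% names(r)),
            r$to %in% names(config$scaffolds))
  mk <- truth$markers
  mk$orig_chrom <- mk$chrom
  mk$orig_pos <- mk$pos
  sel <- mk$chrom == r$chrom & mk$pos >= r$start & mk$pos <= r$end
  if (!any(sel)) return(truth)
  landing_end <- r$at + (r$end - r$start)
  if (landing_end > config$scaffolds[[r$to]]) {
    stop("relocated block extends past the recipient scaffold")
  }
  mk$chrom[sel] <- r$to
  mk$pos[sel] <- as.integer(r$at + (mk$pos[sel] - r$start))
  # the misplaced chunk IS the assembly sequence over its landing interval:
  # native recipient markers there are displaced along with the true sequence
  drop <- !sel & mk$chrom == r$to & mk$pos >= r$at & mk$pos <= landing_end
  keep <- which(!drop)
  mk <- mk[keep, , drop = FALSE]
  for (f in c("mut_g1", "mut_g2", "wt_g1", "wt_g2")) {
    truth[[f]] <- truth[[f]][keep, , drop = FALSE]
  }
  truth$expectations <- truth$expectations[keep, , drop = FALSE]
  ord <- order(match(mk$chrom, names(config$scaffolds)), mk$pos)
  truth$markers <- mk[ord, , drop = FALSE]
  rownames(truth$markers) <- NULL
  truth$mut_g1 <- truth$mut_g1[ord, , drop = FALSE]
  truth$mut_g2 <- truth$mut_g2[ord, , drop = FALSE]
  truth$wt_g1 <- truth$wt_g1[ord, , drop = FALSE]
  truth$wt_g2 <- truth$wt_g2[ord, , drop = FALSE]
  truth$expectations <- truth$expectations[ord, , drop = FALSE]
  truth$expectations$chrom <- truth$markers$chrom
  truth$expectations$pos <- truth$markers$pos
  rownames(truth$expectations) <- NULL
  truth
}

#' Run a full in-memory simulation
#'
#' Seeds the RNG from the config, places markers, simulates the cross,
#' applies the optional misassembly relocation, and sequences both pools.
#'
#' @param config a [sim_config()].
#' @return list: `config`, `truth` (a `bsa_truth`), `wt`, `mut` (site-count
#'   data.frames).
#' @export
simulate_bsa <- function(config) {
  set.seed(config$seed)
  truth <- simulate_cross(config)
  truth <- apply_relocation(truth, config)
  pools <- sequence_pools(truth, config)
  list(config = config, truth = truth, wt = pools$wt, mut = pools$mut)
}

#' Run a simulation and write its standard files
#'
#' Writes `wt.pileup` and `mut.pileup` (via [write_pileup()], so they parse
#' back losslessly), `truth_markers.tsv` (marker table with analytic
#' allele-frequency expectations), `truth_genotypes.tsv` (per-embryo
#' N-allele counts per marker), `scaffolds.tsv` and a JSON parameter
#' manifest. Outputs are reproducible bit-for-bit from the seed.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if missing).
#' @return invisibly, the file paths.
#' @export
run_simulation <- function(config, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  sim <- simulate_bsa(config)
  paths <- list(
    wt = file.path(outdir, "wt.pileup"),
    mut = file.path(outdir, "mut.pileup"),
    markers = file.path(outdir, "truth_markers.tsv"),
    genotypes = file.path(outdir, "truth_genotypes.tsv"),
    scaffolds = file.path(outdir, "scaffolds.tsv"),
    manifest = file.path(outdir, "manifest.json")
  )
  write_pileup(sim$wt[sim$wt$depth > 0, , drop = FALSE], paths$wt)
  write_pileup(sim$mut[sim$mut$depth > 0, , drop = FALSE], paths$mut)
  truth_tab <- cbind(sim$truth$markers,
                     sim$truth$expectations[, c("theta", "exp_mut_n_freq",
                                                "exp_wt_n_freq")])
  utils::write.table(truth_tab, paths$markers, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  geno <- cbind(
    sim$truth$markers[, c("chrom", "pos")],
    as.data.frame(sim$truth$mut_g1 + sim$truth$mut_g2) |>
      stats::setNames(sprintf("mut_%03d", seq_len(ncol(sim$truth$mut_g1)))),
    as.data.frame(sim$truth$wt_g1 + sim$truth$wt_g2) |>
      stats::setNames(sprintf("wt_%03d", seq_len(ncol(sim$truth$wt_g1))))
  )
  utils::write.table(geno, paths$genotypes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(name = names(config$scaffolds), length = unname(config$scaffolds)),
    paths$scaffolds, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  manifest <- config
  class(manifest) <- NULL
  manifest$scaffolds <- as.list(manifest$scaffolds)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
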