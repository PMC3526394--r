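#' IUPAC-aware match of a recognition site at one position
#'
#' @param site IUPAC nucleotide string (e.g. `"GANTC"`).
#' @param seq subject sequence (plain A/C/G/T string).
#' @param start 1-based start position in `seq`.
#' @return TRUE iff every site symbol's IUPAC set contains the
#'   corresponding sequence base.
#' @examples
#' iupac_match("GANTC", "GATTC", 1)
#' @export
iupac_match <- function(site, seq, start = 1L) {
  site <- toupper(site)
  seq <- toupper(seq)
  if (start < 1 || start + nchar(site) - 1 > nchar(seq)) {
    stop("iupac_match: site does not fit in sequence at this start")
  }
  map <- Biostrings::IUPAC_CODE_MAP
  s <- strsplit(site, "")[[1]]
  q <- strsplit(substr(seq, start, start + nchar(site) - 1), "")[[1]]
  if (!all(s %in% names(map))) {
    stop(sprintf("iupac_match: non-IUPAC symbol '%s' in site",
                 s[!(s %in% names(map))][1]))
  }
  all(mapply(function(code, base) grepl(base, map[[code]], fixed = TRUE), s, q))
}

is_palindromic_site <- function(site) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(site)))
  identical(toupper(site), rc)
}

#' Find all occurrences of a recognition site in a sequence
#'
#' The given strand is scanned with IUPAC-aware matching; for
#' non-palindromic sites the reverse complement of the site is also
#' scanned, and its hits reported in given-strand coordinates. A
#' palindromic site is counted once per position.
#'
#' @param seq plain A/C/G/T string.
#' @param site IUPAC recognition site.
#' @return sorted integer vector of 1-based match start positions.
#' @export
find_sites <- function(seq, site) {
  site <- toupper(site)
  seq <- toupper(seq)
  if (nchar(seq) < nchar(site)) return(integer(0))
  subj <- Biostrings::DNAString(seq)
  hits <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(site), subj, fixed = "subject"))
  if (!is_palindromic_site(site)) {
    rc <- Biostrings::reverseComplement(Biostrings::DNAString(site))
    hits <- c(hits, Biostrings::start(Biostrings::matchPattern(
      rc, subj, fixed = "subject")))
  }
  sort(unique(hits))
}

#' A SNP with flanking sequence for marker design
#'
#' @param chrom,pos site coordinates (1-based).
#' @param flank flanking sequence containing the SNP.
#' @param offset 0-based index of the SNP within `flank`.
#' @param allele_a,allele_b the two alleles; `flank[offset]` must equal one
#'   of them.
#' @return list of class `snp_context`.
#' @export
snp_context <- function(chrom, pos, flank, offset, allele_a, allele_b) {
  flank <- toupper(flank)
  allele_a <- toupper(allele_a)
  allele_b <- toupper(allele_b)
  stopifnot(offset >= 0, offset < nchar(flank),
            allele_a %in% BASES, allele_b %in% BASES, allele_a != allele_b)
  at <- substr(flank, offset + 1, offset + 1)
  if (!(at %in% c(allele_a, allele_b))) {
    stop(sprintf("flank base '%s' at the SNP offset matches neither allele", at))
  }
  structure(list(chrom = chrom, pos = pos, flank = flank,
                 offset = as.integer(offset),
                 allele_a = allele_a, allele_b = allele_b),
            class = "snp_context")
}

#' Load a restriction-enzyme table
#'
#' A REBASE-like TSV with columns `name`, `site` (IUPAC) and optionally
#' `cut_offset` (0-based position of cleavage within the site; when absent
#' the site midpoint is used for fragment-length triage). The built-in
#' panel of common 4- and 6-cutters ships with the package.
#'
#' @param file path; default is the built-in table.
#' @return data.frame with `name`, `site`, `cut_offset`.
#' @export
load_enzymes <- function(file = system.file("extdata", "enzymes.tsv",
                                            package = "bsamap")) {
  tab <- utils::read.table(file, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("name", "site") %in% names(tab))) {
    stop("enzyme table needs 'name' and 'site' columns")
  }
  if (is.null(tab$cut_offset)) tab$cut_offset <- NA_integer_
  tab
}

substitute_base <- function(flank, offset, base) {
  paste0(substr(flank, 1, offset), base,
         substr(flank, offset + 2, nchar(flank)))
}

cut_positions <- function(sites, site_len, cut_offset) {
  off <- if (is.na(cut_offset)) floor(site_len / 2) else cut_offset
  sites + off - 1L   # cut after this base (1-based): fragment boundary
}

digest_lengths <- function(flank_len, cuts) {
  cuts <- sort(unique(cuts[cuts >= 1 & cuts < flank_len]))
  diff(c(0L, cuts, flank_len))
}

#' Enzymes whose recognition site is created or abolished by a SNP
#'
#' For each enzyme, the recognition-site positions are computed on the two
#' allelic versions of the flank; every site present in exactly one
#' allele's flank yields a CAPS/RFLP candidate. Fragment lengths come from
#' digesting the cutting allele's flank at all of its sites (differential
#' and constitutive) and likewise for the non-cutting allele, so the
#' reported patterns are the ones a gel would show.
#'
#' @param snp a [snp_context()].
#' @param enzymes enzyme data.frame from [load_enzymes()].
#' @param end_margin minimum distance (bp) from the differential site to
#'   either flank end for a practical PCR amplicon (default 50); reported
#'   as the logical `amplicon_ok`.
#' @return data.frame with one row per differential site: `chrom`, `pos`,
#'   `enzyme`, `site`, `cutting_allele`, `site_position` (1-based within
#'   the flank), `fragments_cut` and `fragments_uncut`
#'   (comma-separated bp), `amplicon_ok`.
#' @export
differential_enzymes <- function(snp, enzymes = load_enzymes(), end_margin = 50L) {
  stopifnot(inherits(snp, "snp_context"))
  flank_a <- substitute_base(snp$flank, snp$offset, snp$allele_a)
  flank_b <- substitute_base(snp$flank, snp$offset, snp$allele_b)
  flank_len <- nchar(snp$flank)
  rows <- list()
  for (i in seq_len(nrow(enzymes))) {
    site <- enzymes$site[i]
    len <- nchar(site)
    sa <- find_sites(flank_a, site)
    sb <- find_sites(flank_b, site)
    diff_sites <- c(setdiff(sa, sb), setdiff(sb, sa))
    for (sp in diff_sites) {
      cutting <- if (sp %in% sa) "a" else "b"
      stopifnot(sp <= snp$offset + 1 && sp + len - 1 >= snp$offset + 1)
      cut_flank_sites <- if (cutting == "a") sa else sb
      uncut_flank_sites <- if (cutting == "a") sb else sa
      fc <- digest_lengths(flank_len,
                           cut_positions(cut_flank_sites, len, enzymes$cut_offset[i]))
      fu <- digest_lengths(flank_len,
                           cut_positions(uncut_flank_sites, len, enzymes$cut_offset[i]))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = snp$chrom, pos = snp$pos, enzyme = enzymes$name[i],
        site = site,
        cutting_allele = if (cutting == "a") snp$allele_a else snp$allele_b,
        site_position = sp,
        fragments_cut = paste(fc, collapse = ","),
        fragments_uncut = paste(fu, collapse = ","),
        amplicon_ok = sp > end_margin & (sp + len - 1) <= flank_len - end_margin,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      enzyme = character(0), site = character(0),
                      cutting_allele = character(0), site_position = integer(0),
                      fragments_cut = character(0), fragments_uncut = character(0),
                      amplicon_ok = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Design RFLP markers for a set of SNP calls from a reference FASTA
#'
#' Flanks are extracted around each call; the two alleles tested are the
#' wildtype-pool and mutant-pool major alleles (skipping calls where these
#' agree).
#'
#' @param calls SNP-call data.frame from [call_snps()].
#' @param fasta path to the reference FASTA.
#' @param flank_bp flank taken on each side of the SNP (default 250).
#' @param enzymes enzyme data.frame.
#' @param end_margin see [differential_enzymes()].
#' @return row-bound data.frame of [differential_enzymes()] results.
#' @export
design_markers <- function(calls, fasta, flank_bp = 250L,
                           enzymes = load_enzymes(), end_margin = 50L) {
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*", "", names(genome))
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    a <- calls$wt_major[i]
    b <- calls$mut_major[i]
    if (a == b) next
    chrom <- calls$chrom[i]
    if (!(chrom %in% names(genome))) {
      stop(sprintf("scaffold '%s' not in FASTA", chrom))
    }
    len <- Biostrings::width(genome[chrom])
    lo <- max(1L, calls$pos[i] - flank_bp)
    hi <- min(len, calls$pos[i] + flank_bp)
    flank <- as.character(Biostrings::subseq(genome[[chrom]], lo, hi))
    offset <- calls$pos[i] - lo
    base_at <- substr(flank, offset + 1, offset + 1)
    if (!(base_at %in% c(a, b))) {
      # reference carries a third allele; substitute allele a for testing
      flank <- substitute_base(flank, offset, a)
    }
    ctx <- snp_context(chrom, calls$pos[i], flank, offset, a, b)
    rows[[length(rows) + 1L]] <- differential_enzymes(ctx, enzymes, end_margin)
  }
  if (length(rows) == 0) return(differential_enzymes(
    snp_context("x", 1L, "AAAA", 1L, "A", "C"),
    enzymes[0, , drop = FALSE]))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
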