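BASES <- c("A", "C", "G", "T")

empty_sites <- function() {
  data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    A = integer(0), C = integer(0), G = integer(0), T = integer(0),
    skipped = integer(0), depth = integer(0),
    stringsAsFactors = FALSE
  )
}

#' Decode a pileup base string into per-base allele counts
#'
#' Walks the samtools pileup base-column grammar: `.`/`,` are reference
#' matches on the forward/reverse strand, `ACGTacgt` are substitutions
#' (strand case merged), `^` starts a read and consumes the following
#' mapping-quality character, `$` ends a read, `+n`/`-n` introduce an indel
#' whose n sequence characters are consumed without counting, and `*`
#' (deleted base), `<`/`>` (reference skips) and `N`/`n` calls contribute to
#' `skipped` rather than to any allele.
#'
#' @param bases the pileup base column for one position.
#' @param ref reference base at the position (`A`, `C`, `G`, `T` or `N`).
#' @param line_num line number used in error messages.
#' @return list with `counts` (named integer vector over A/C/G/T) and
#'   `skipped` (integer).
#' @keywords internal
decode_bases <- function(bases, ref, line_num = NA) {
  ref <- toupper(ref)
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  skipped <- 0L
  ch <- strsplit(bases, "", fixed = TRUE)[[1]]
  n <- length(ch)
  i <- 1L
  while (i <= n) {
    c0 <- ch[i]
    if (c0 == "^") {
      i <- i + 2L                      # '^' + mapping quality char
    } else if (c0 == "$") {
      i <- i + 1L
    } else if (c0 == "." || c0 == ",") {
      if (ref %in% BASES) counts[ref] <- counts[ref] + 1L else skipped <- skipped + 1L
      i <- i + 1L
    } else if (c0 == "+" || c0 == "-") {
      j <- i + 1L
      while (j <= n && grepl("^[0-9]$", ch[j])) j <- j + 1L
      if (j == i + 1L) {
        stop(sprintf("pileup parse error%s: indel length not an integer after '%s'",
                     if (is.na(line_num)) "" else sprintf(" at line %d", line_num), c0))
      }
      len <- as.integer(paste0(ch[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len                     # skip the indel sequence
    } else if (c0 %in% c("*", "<", ">", "N", "n")) {
      skipped <- skipped + 1L
      i <- i + 1L
    } else {
      b <- toupper(c0)
      if (b %in% BASES) {
        counts[b] <- counts[b] + 1L
        i <- i + 1L
      } else {
        stop(sprintf("pileup parse error%s: unexpected symbol '%s' in base column",
                     if (is.na(line_num)) "" else sprintf(" at line %d", line_num), c0))
      }
    }
  }
  list(counts = counts, skipped = skipped)
}

#' Parse one samtools pileup line into site allele counts
#'
#' Accepts the 6-column pileup dialect (chrom, 1-based position, reference
#' base, depth, base string, base qualities); extra columns are ignored.
#' If the decoded symbols disagree with the depth column the decoded counts
#' are trusted and the discrepancy reported as a warning, not an error.
#'
#' @param line one pileup record.
#' @param line_num line number for error messages.
#' @return one-row data.frame with columns `chrom`, `pos`, `ref`, `A`, `C`,
#'   `G`, `T`, `skipped`, `depth`.
#' @examples
#' parse_pileup_line("s1\t100\tA\t5\t..,,.\tIIIII")
#' @export
parse_pileup_line <- function(line, line_num = NA) {
  f <- strsplit(trimws(line, which = "right"), "[ \t]+")[[1]]
  if (length(f) < 6) {
    stop(sprintf("pileup parse error%s: expected >= 6 columns, got %d",
                 if (is.na(line_num)) "" else sprintf(" at line %d", line_num), length(f)))
  }
  pos <- suppressWarnings(as.integer(f[2]))
  depth <- suppressWarnings(as.integer(f[4]))
  if (is.na(pos) || pos < 1L) {
    stop(sprintf("pileup parse error%s: malformed position '%s'",
                 if (is.na(line_num)) "" else sprintf(" at line %d", line_num), f[2]))
  }
  if (is.na(depth) || depth < 0L) {
    stop(sprintf("pileup parse error%s: malformed depth '%s'",
                 if (is.na(line_num)) "" else sprintf(" at line %d", line_num), f[4]))
  }
  dec <- decode_bases(f[5], f[3], line_num)
  decoded <- sum(dec$counts) + dec$skipped
  if (decoded != depth) {
    warning(sprintf(
      "pileup depth mismatch%s at %s:%d: depth column %d, decoded %d symbols; using decoded counts",
      if (is.na(line_num)) "" else sprintf(" (line %d)", line_num), f[1], pos, depth, decoded))
  }
  data.frame(
    chrom = f[1], pos = pos, ref = toupper(f[3]),
    A = dec$counts[["A"]], C = dec$counts[["C"]], G = dec$counts[["G"]],
    T = dec$counts[["T"]], skipped = dec$skipped, depth = depth,
    stringsAsFactors = FALSE
  )
}

check_sorted_sites <- function(sites, what = "pileup") {
  if (nrow(sites) < 2) return(invisible(sites))
  chrom_rle <- rle(sites$chrom)
  if (anyDuplicated(chrom_rle$values)) {
    bad <- chrom_rle$values[duplicated(chrom_rle$values)][1]
    stop(sprintf("%s not sorted: scaffold '%s' appears in non-contiguous blocks", what, bad))
  }
  same <- sites$chrom[-1] == sites$chrom[-nrow(sites)]
  dpos <- diff(sites$pos)
  if (any(same & dpos == 0)) {
    k <- which(same & dpos == 0)[1] + 1L
    stop(sprintf("%s has duplicate position %s:%d", what, sites$chrom[k], sites$pos[k]))
  }
  if (any(same & dpos < 0)) {
    k <- which(same & dpos < 0)[1] + 1L
    stop(sprintf("%s not sorted at %s:%d", what, sites$chrom[k], sites$pos[k]))
  }
  invisible(sites)
}

#' Read a samtools pileup file into a site-counts table
#'
#' Plain or gzip-compressed text is accepted. Records must be sorted by
#' (scaffold, position); duplicate positions are rejected.
#'
#' @param file path or connection.
#' @return data.frame of site counts, one row per position (see
#'   [parse_pileup_line()]).
#' @export
read_pileup <- function(file) {
  lines <- if (inherits(file, "connection")) readLines(file) else readLines(con <- gzfile(file))
  if (!inherits(file, "connection")) close(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_sites())
  rows <- lapply(seq_along(lines), function(i) parse_pileup_line(lines[i], i))
  sites <- do.call(rbind, rows)
  rownames(sites) <- NULL
  check_sorted_sites(sites, what = if (is.character(file)) file else "pileup")
  sites
}

#' Write a site-counts table as a samtools pileup file
#'
#' Reference matches are emitted as `.`, substitutions as upper-case bases,
#' skipped symbols as `*`; the quality column is a constant placeholder so
#' that [read_pileup()] round-trips the allele counts exactly.
#'
#' @param sites site-counts data.frame, sorted by (chrom, pos).
#' @param file path or connection; `.gz` paths are compressed.
#' @export
write_pileup <- function(sites, file) {
  check_sorted_sites(sites, what = "sites to write")
  con <- if (inherits(file, "connection")) file
         else if (grepl("\\.gz$", file)) gzfile(file, "w") else file(file, "w")
  if (!inherits(file, "connection")) on.exit(close(con))
  if (nrow(sites) == 0) {
    writeLines(character(0), con)
    return(invisible(NULL))
  }
  depth <- sites$A + sites$C + sites$G + sites$T + sites$skipped
  if (any(depth == 0)) stop("cannot write a pileup record with zero decoded symbols")
  bases_col <- vapply(seq_len(nrow(sites)), function(i) {
    ref <- sites$ref[i]
    cnt <- c(A = sites$A[i], C = sites$C[i], G = sites$G[i], T = sites$T[i])
    out <- character(0)
    for (b in BASES) {
      if (cnt[[b]] == 0) next
      sym <- if (b == ref) "." else b
      out <- c(out, strrep(sym, cnt[[b]]))
    }
    if (sites$skipped[i] > 0) out <- c(out, strrep("*", sites$skipped[i]))
    paste0(out, collapse = "")
  }, character(1))
  qual <- strrep("I", depth)
  writeLines(paste(sites$chrom, sites$pos, sites$ref, depth, bases_col, qual,
                   sep = "\t"), con)
  invisible(NULL)
}

#' Join wildtype- and mutant-pool site counts by position
#'
#' Inner join on (scaffold, position): positions covered in only one pool
#' are dropped, since they cannot satisfy the joint minimum-depth
#' requirement of the caller. Scaffolds shared by the two files must appear
#' in the same relative order.
#'
#' @param wt,mut site-counts data.frames from [read_pileup()].
#' @return data.frame with columns `chrom`, `pos`, `ref` and per-pool counts
#'   `wt_A` ... `wt_T`, `wt_skipped`, `mut_A` ... `mut_T`, `mut_skipped`.
#' @export
join_pools <- function(wt, mut) {
  check_sorted_sites(wt, "WT pileup")
  check_sorted_sites(mut, "MUT pileup")
  wt_ord <- unique(wt$chrom)
  mut_ord <- unique(mut$chrom)
  shared <- intersect(wt_ord, mut_ord)  # in wt order
  if (length(shared) > 1 && any(diff(match(shared, mut_ord)) < 0)) {
    stop("inconsistent scaffold ordering between WT and MUT pileups")
  }
  key_wt <- paste(wt$chrom, wt$pos)
  key_mut <- paste(mut$chrom, mut$pos)
  iw <- which(key_wt %in% key_mut)
  im <- match(key_wt[iw], key_mut)
  out <- data.frame(
    chrom = wt$chrom[iw], pos = wt$pos[iw], ref = wt$ref[iw],
    wt_A = wt$A[iw], wt_C = wt$C[iw], wt_G = wt$G[iw], wt_T = wt$T[iw],
    wt_skipped = wt$skipped[iw],
    mut_A = mut$A[im], mut_C = mut$C[im], mut_G = mut$G[im], mut_T = mut$T[im],
    mut_skipped = mut$skipped[im],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Read a scaffold-length table
#'
#' Accepts a FASTA `.fai` index or any TSV whose first two columns are
#' scaffold name and length.
#'
#' @param file path.
#' @return named integer vector of scaffold lengths.
#' @export
read_scaffold_lengths <- function(file) {
  tab <- utils::read.table(file, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop("scaffold-length table needs at least two columns (name, length)")
  len <- suppressWarnings(as.numeric(tab[[2]]))
  if (anyNA(len)) stop("non-numeric scaffold length in table")
  if (anyDuplicated(tab[[1]])) stop("duplicate scaffold names in length table")
  stats::setNames(len, tab[[1]])
}
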