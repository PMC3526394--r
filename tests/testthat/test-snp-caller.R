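test_that("major_allele returns the maximal base, its fraction, and the alphabetical tie rule", {
  m <- major_allele(c(A = 12, C = 0, G = 10, T = 0))
  expect_equal(m$base, "A")
  expect_equal(m$frac, 12 / 22)
  expect_false(m$tie)

  expect_equal(major_allele(c(A = 0, C = 10, G = 0, T = 0)),
               list(base = "C", frac = 1.0, tie = FALSE))

  tie <- major_allele(c(A = 5, C = 0, G = 0, T = 5))
  expect_equal(tie$base, "A")
  expect_equal(tie$frac, 0.5)
  expect_true(tie$tie)

  expect_error(major_allele(c(A = 0, C = 0, G = 0, T = 0)), "all-zero")
})

test_that("single sites are called per the WT-band / differing-majors criteria", {
  # wt maf 0.5 in band, mut maf ~0.917 homozygous
  x <- call_site(c(A = 6, C = 0, G = 6, T = 0), c(A = 11, C = 0, G = 1, T = 0))
  expect_equal(x$criterion, "wt_het_band")
  expect_equal(x$zygosity, "homozygous")

  # wt maf exactly 0.75: inclusive band end
  y <- call_site(c(A = 9, C = 0, G = 3, T = 0), c(A = 5, C = 0, G = 5, T = 0))
  expect_equal(y$zygosity, "heterozygous")
  expect_equal(y$criterion, "wt_het_band")

  # maf 0.9 with equal majors: fails both criteria
  expect_null(call_site(c(A = 9, C = 0, G = 1, T = 0),
                        c(A = 10, C = 0, G = 0, T = 0)))

  # depth gate: 9 reads in WT
  expect_null(call_site(c(A = 5, C = 0, G = 4, T = 0),
                        c(A = 11, C = 0, G = 1, T = 0)))
})

test_that("band endpoints, depth gate and homozygosity threshold are exact", {
  hom_at <- function(mut) call_site(c(A = 6, G = 6, C = 0, T = 0), mut)$zygosity
  # MUT MAF exactly 0.90 is homozygous; just below is not
  expect_equal(hom_at(c(A = 18, G = 2, C = 0, T = 0)), "homozygous")
  expect_equal(hom_at(c(A = 17, G = 3, C = 0, T = 0)), "heterozygous")

  maf_call <- function(a, b) call_site(c(A = a, G = b, C = 0, T = 0),
                                       c(A = 30, G = 10, C = 0, T = 0))
  # wt maf 0.50 and 0.75 called via the band
  expect_equal(maf_call(50, 50)$criterion, "wt_het_band")
  expect_equal(maf_call(75, 25)$criterion, "wt_het_band")
  # 0.76: band fails; called only when the majors differ
  differing <- call_site(c(A = 76, G = 24, C = 0, T = 0),
                         c(A = 10, G = 30, C = 0, T = 0))
  expect_equal(differing$criterion, "major_allele_differs")
  # 0.76 with equal majors: not called
  expect_null(call_site(c(A = 76, G = 24, C = 0, T = 0),
                        c(A = 40, G = 0, C = 0, T = 0)))

  # depth 10 passes, 9 does not, in either pool
  deep <- c(A = 5, G = 5, C = 0, T = 0)
  shallow <- c(A = 5, G = 4, C = 0, T = 0)
  expect_false(is.null(call_site(deep, deep)))
  expect_null(call_site(shallow, deep))
  expect_null(call_site(deep, shallow))
})

test_that("call_snps matches an independent brute-force evaluation on randomized sites", {
  set.seed(11)
  pooled <- random_pooled_sites(1500)
  calls <- call_snps(pooled, quiet = TRUE)
  got <- split(calls, calls$pos)
  n_called <- 0
  for (i in seq_len(nrow(pooled))) {
    wt <- c(A = pooled$wt_A[i], C = pooled$wt_C[i], G = pooled$wt_G[i], T = pooled$wt_T[i])
    mut <- c(A = pooled$mut_A[i], C = pooled$mut_C[i], G = pooled$mut_G[i], T = pooled$mut_T[i])
    exp <- oracle_call_one(wt, mut)
    row <- got[[as.character(pooled$pos[i])]]
    if (is.null(exp)) {
      expect_null(row)
    } else {
      n_called <- n_called + 1
      expect_equal(row$wt_major, exp$wt_major)
      expect_equal(row$mut_major, exp$mut_major)
      expect_equal(row$wt_maf, exp$wt_maf)
      expect_equal(row$mut_maf, exp$mut_maf)
      expect_equal(row$criterion, exp$criterion)
      expect_equal(row$zygosity, exp$zygosity)
    }
  }
  expect_equal(nrow(calls), n_called)
  expect_gt(n_called, 0)
})

test_that("identical inputs give identical call sets", {
  set.seed(5)
  pooled <- random_pooled_sites(300)
  expect_identical(call_snps(pooled, quiet = TRUE), call_snps(pooled, quiet = TRUE))
})

test_that("raising thresholds never increases calls (monotonicity)", {
  set.seed(8)
  pooled <- random_pooled_sites(800)
  n_hom <- function(h) sum(call_snps(pooled, caller_params(hom_threshold = h),
                                     quiet = TRUE)$zygosity == "homozygous")
  homs <- vapply(c(0.7, 0.8, 0.9, 0.95, 1.0), n_hom, numeric(1))
  expect_true(all(diff(homs) <= 0))

  n_call <- function(d) nrow(call_snps(pooled, caller_params(min_depth = d),
                                       quiet = TRUE))
  ncalls <- vapply(c(5, 10, 15, 25), n_call, numeric(1))
  expect_true(all(diff(ncalls) <= 0))
})

test_that("heterozygous-marker recovery improves with depth on error-free unlinked sites", {
  # truly 50/50 pools; a het marker is recovered when called non-homozygous
  gen <- function(depth, n = 400) {
    wt <- rbinom(n, depth, 0.5); mut <- rbinom(n, depth, 0.5)
    pooled <- data.frame(
      chrom = "u", pos = 1:n, ref = "A",
      wt_A = wt, wt_C = depth - wt, wt_G = 0L, wt_T = 0L, wt_skipped = 0L,
      mut_A = mut, mut_C = depth - mut, mut_G = 0L, mut_T = 0L, mut_skipped = 0L)
    calls <- call_snps(pooled, quiet = TRUE)
    sum(calls$zygosity == "heterozygous") / n
  }
  set.seed(13)
  expect_gt(gen(50), gen(10))
})

test_that("TSV and VCF exports round-trip / carry the call fields", {
  set.seed(3)
  calls <- call_snps(random_pooled_sites(200), quiet = TRUE)
  f <- tempfile(fileext = ".tsv")
  write_snp_tsv(calls, f)
  back <- read_snp_tsv(f)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$criterion, calls$criterion)
  expect_equal(back$wt_maf, calls$wt_maf, tolerance = 1e-12)

  v <- tempfile(fileext = ".vcf")
  write_snp_vcf(calls, v)
  lines <- readLines(v)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(calls))
  expect_true(all(grepl("WTD=\\d+;WTMAF=", body)))
})
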