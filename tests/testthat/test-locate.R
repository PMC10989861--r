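test_that("backtracking selects exactly the reads carrying significant k-mers", {
  set.seed(41)
  sig <- "ACGTTGCAAGGTCCA" # 15-mer
  reads <- c(paste0(random_dna(40), sig, random_dna(40)),   # embedded
             paste0(random_dna(30), naive_revcomp(sig)),    # via revcomp
             random_dna(90), random_dna(90))
  hit <- backtrack_reads(reads, sig, k = 15)
  expect_equal(hit[1:2], c(TRUE, TRUE))
  # selection equals a brute-force substring scan (canonical both ways)
  brute <- vapply(reads, function(r)
    grepl(sig, r, fixed = TRUE) | grepl(naive_revcomp(sig), r, fixed = TRUE),
    logical(1))
  expect_equal(unname(hit), unname(brute))
  expect_warning(none <- backtrack_reads(reads, character(0), k = 15),
                 "empty")
  expect_false(any(none))
})

test_that("backtrack counts match the naive scan on a random fixture", {
  set.seed(42)
  reads <- replicate(200, random_dna(80))
  sig <- canonicalize(substring(reads[1:30], 11, 31)) # 21-mers from reads
  hit <- backtrack_reads(reads, sig, k = 21)
  brute <- vapply(reads, function(r) {
    wins <- substring(r, 1:(80 - 20), 21:80)
    any(naive_canonical(wins) %in% sig)
  }, logical(1))
  expect_equal(unname(hit), unname(brute))
})

test_that("alignments land in half-open bins by leftmost base", {
  cl <- c(chrA = 5e5)
  aln <- data.table::data.table(
    chrom = "chrA", pos = c(10L, 199999L, 200000L, 200001L),
    mapq = 60L, flag = 0L)
  b <- bin_reads(aln, bin_config(bin_size = 200000), cl)
  expect_equal(b[bin_start == 0, count], 3L)       # 1-based 200000 is still bin 1
  expect_equal(b[bin_start == 200000, count], 1L)  # 200001 opens the next bin
  expect_equal(b[bin_start == 400000, count], 0L)  # empty bins are explicit
  expect_equal(sum(b$count), nrow(aln))            # conservation
})

test_that("binning honors MAPQ and flag filters", {
  cl <- c(chrA = 1e5)
  aln <- data.table::data.table(
    chrom = "chrA", pos = c(5L, 6L, 7L, 8L),
    mapq = c(60L, 39L, 60L, 60L),
    flag = c(0L, 0L, 256L, 4L)) # low MAPQ, secondary, unmapped
  b <- bin_reads(aln, bin_config(bin_size = 1e5, min_mapq = 40), cl)
  expect_equal(sum(b$count), 1L)
  expect_error(bin_reads(data.table::data.table(chrom = "chrA", pos = 2e5,
                                                mapq = 60L, flag = 0L),
                         bin_config(), cl), "beyond")
  expect_error(bin_reads(aln, bin_config()), "lengths")
  empty <- bin_reads(aln[0], bin_config(bin_size = 1e4), cl)
  expect_true(all(empty$count == 0))
  expect_equal(nrow(empty), 10)
})

test_that("SAM files round-trip through the binning stage", {
  skip_if_not_installed("Rsamtools")
  haps <- sim_haplotypes(c(chr01 = 2e4), 1 / 500, seed = 44)
  ped <- simulate_pedigree(haps, 2, 1, seed = 45)
  sims <- simulate_reads(ped["F2_01"], haps, coverage = 2, read_len = 100,
                         error_rate = 0, seed = 46)
  f <- tempfile(fileext = ".sam")
  write_truth_sam(sims$F2_01$truth, haps, f)
  cfg <- bin_config(bin_size = 5e3)
  from_sam <- bin_reads(f, cfg)
  from_truth <- bin_reads(sims$F2_01$truth[, .(chrom, pos = start)], cfg,
                          haps$chrom_lengths)
  expect_equal(from_sam, from_truth)
  # and equals direct interval arithmetic on the truth table
  brute <- table(cut(sims$F2_01$truth$start, breaks = seq(0, 2e4, 5e3)))
  expect_equal(from_truth$count, as.integer(brute))
})

test_that("normalization is per-bin within-bulk and the ratio uses a pseudocount", {
  grid <- data.table::data.table(chrom = "chrA", bin_start = c(0L, 100L))
  mk <- function(cnt) data.table::data.table(grid, count = cnt)
  cfg <- bin_config(bin_size = 100, ratio_pseudocount = 1e-6)
  tr <- normalize_and_ratio(mk(c(10, 0)), mk(c(100, 0)),
                            mk(c(1, 0)), mk(c(100, 0)), cfg)
  expect_equal(tr$ratio[1], (0.1 + 1e-6) / (0.01 + 1e-6), tolerance = 1e-9)
  expect_equal(tr$ratio[2], 1) # empty bins sit at neutral 1
  # scaling one bulk's sig and total together leaves its norm unchanged
  tr2 <- normalize_and_ratio(mk(c(20, 0)), mk(c(200, 0)),
                             mk(c(1, 0)), mk(c(100, 0)), cfg)
  expect_equal(tr2$norm_A, tr$norm_A)
  bad <- data.table::data.table(chrom = "chrA", bin_start = 50L, count = 1L)
  expect_error(normalize_and_ratio(mk(c(1, 1)), mk(c(1, 1)),
                                   bad, mk(c(1, 1)), cfg), "grids")
})

test_that("peak calling seeds at the maximum and extends at half height", {
  tr <- data.table::data.table(
    chrom = "chrA", bin_start = seq(0L, 900L, 100L),
    ratio = c(1, 1, 2, 6, 10, 7, 4, 1, 1, 1))
  pk <- call_peak(tr, frac = 0.5, bin_size = 100)
  expect_equal(pk$chrom, "chrA")
  expect_equal(pk$start, 301L) # 6 >= 5 extends left, 2 < 5 stops
  expect_equal(pk$end, 600L)   # 7 extends right, 4 < 5 stops
  expect_equal(pk$score, mean(c(6, 10, 7)))

  flat <- data.table::data.table(chrom = "chrA", bin_start = c(0L, 100L),
                                 ratio = c(2, 2))
  expect_equal(nrow(call_peak(flat)), 0)

  ties <- data.table::data.table(chrom = "chrA", bin_start = c(0L, 100L, 200L),
                                 ratio = c(5, 1, 5))
  expect_equal(call_peak(ties, bin_size = 100)$start, 1L) # lowest coordinate
})

test_that("bin tracks serialize as bedGraph-style TSV", {
  grid <- data.table::data.table(chrom = "chrA", bin_start = c(0L, 100L))
  mk <- function(cnt) data.table::data.table(grid, count = cnt)
  tr <- normalize_and_ratio(mk(c(5, 1)), mk(c(10, 10)), mk(c(1, 1)),
                            mk(c(10, 10)), bin_config(bin_size = 100))
  f <- tempfile(fileext = ".tsv")
  write_bin_track(tr, f, bin_size = 100)
  back <- data.table::fread(f)
  expect_equal(back$start, c(0L, 100L))
  expect_equal(back$end, c(100L, 200L))
  expect_equal(back$ratio, tr$ratio)
})
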