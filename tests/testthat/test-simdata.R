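test_that("simulated genomes respect their invariants", {
  haps <- sim_haplotypes(c(chr01 = 2e4, chr02 = 1e4), 1 / 500, seed = 1)
  expect_s3_class(haps, "haplotype_set")
  expect_equal(nrow(haps$snp), 60)
  expect_true(all(haps$snp$pos <= haps$chrom_lengths[haps$snp$chrom]))
  # at least two distinct bases across haplotypes at every site
  n_distinct <- apply(haps$snp[, c("A", "B", "C", "D")], 1,
                      function(x) length(unique(x)))
  expect_true(all(n_distinct >= 2))
  # ref matches the backbone
  chars <- strsplit(haps$reference[["chr01"]], "")[[1]]
  s1 <- haps$snp[chrom == "chr01"]
  expect_equal(chars[s1$pos], s1$ref)
  expect_error(sim_haplotypes(c(chr01 = 0)), "positive")
})

test_that("pedigrees are reproducible and mosaics tile chromosomes", {
  haps <- sim_haplotypes(c(chr01 = 5e4), 1 / 1000, seed = 2)
  p1 <- simulate_pedigree(haps, 6, 10, seed = 7)
  p2 <- simulate_pedigree(haps, 6, 10, seed = 7)
  expect_identical(p1, p2) # determinism
  for (ind in p1) {
    for (hom in ind$mosaic$chr01) {
      expect_equal(hom$start[1], 1)
      expect_equal(hom$end[nrow(hom)], 5e4)
      if (nrow(hom) > 1)
        expect_equal(hom$start[-1], hom$end[-nrow(hom)] + 1) # no gaps/overlap
    }
  }
  # F1 homolog 1 only from {A,B}, homolog 2 only from {C,D}
  f1 <- p1[grepl("^F1", names(p1))]
  for (ind in f1) {
    expect_true(all(ind$mosaic$chr01[[1]]$hap %in% c("A", "B")))
    expect_true(all(ind$mosaic$chr01[[2]]$hap %in% c("C", "D")))
  }
  expect_error(simulate_pedigree(haps, 1, 5), "intercross")
})

test_that("without recombination each homolog is one pure haplotype", {
  haps <- sim_haplotypes(c(chr01 = 5e4), 1 / 1000, seed = 3)
  ped <- simulate_pedigree(haps, 200, 200, recomb_rate = 0, seed = 4)
  f2 <- ped[grepl("^F2", names(ped))]
  segs <- unlist(lapply(f2, function(i)
    lapply(i$mosaic$chr01, function(h) nrow(h))))
  expect_true(all(segs == 1))
  labs <- unlist(lapply(f2, function(i)
    vapply(i$mosaic$chr01, function(h) h$hap, character(1))))
  tab <- table(factor(labs, levels = c("A", "B", "C", "D"))) / length(labs)
  expect_true(all(abs(tab - 0.25) < 3 * sqrt(0.25 * 0.75 / length(labs)) + 0.02))
})

test_that("crossover counts follow the requested Poisson rate", {
  haps <- sim_haplotypes(c(chr01 = 1e5), 1 / 5000, seed = 5)
  ped <- simulate_pedigree(haps, 2, 0, seed = 6)
  h1 <- ped$P1$mosaic$chr01[[1]]
  h2 <- ped$P1$mosaic$chr01[[2]]
  set.seed(11)
  # P gametes alternate pure A and pure B, so every crossover is a visible
  # segment boundary
  nx <- replicate(3000, nrow(kbsa:::.gamete(h1, h2, 1e5, 1)) - 1)
  se <- sd(nx) / sqrt(length(nx))
  expect_lt(abs(mean(nx) - 1), 3 * se)
})

test_that("trait assignment follows dominant and recessive rules", {
  haps <- sim_haplotypes(c(chr01 = 1e4), 1 / 1000, seed = 8)
  mk_ind <- function(h1, h2) list(
    id = "x", generation = "F2",
    mosaic = list(chr01 = list(
      data.table::data.table(start = 1L, end = 1e4L, hap = h1),
      data.table::data.table(start = 1L, end = 1e4L, hap = h2))),
    trait_values = list())
  loc_dom <- causal_locus("chr01", 5000, "A", "dominant")
  loc_rec <- causal_locus("chr01", 5000, "A", "recessive")
  ac <- mk_ind("A", "C")
  expect_true(assign_traits(list(ac), loc_dom)[[1]]$trait_values$trait)
  expect_false(assign_traits(list(ac), loc_rec)[[1]]$trait_values$trait)
  expect_true(assign_traits(list(mk_ind("A", "A")), loc_rec)[[1]]$trait_values$trait)
  expect_false(assign_traits(list(mk_ind("B", "C")), loc_dom)[[1]]$trait_values$trait)
})

test_that("error-free reads are exact homolog substrings at the right depth", {
  haps <- sim_haplotypes(c(chr01 = 2e4, chr02 = 2e4), 1 / 500, seed = 12)
  ped <- simulate_pedigree(haps, 2, 1, seed = 13)
  sims <- simulate_reads(ped["F2_01"], haps, coverage = 2, read_len = 100,
                         error_rate = 0, seed = 14)
  s <- sims$F2_01
  genome_len <- sum(haps$chrom_lengths)
  expect_lt(abs(sum(nchar(s$reads)) - 2 * genome_len) / (2 * genome_len),
            0.01) # coverage accounting
  # each read matches its truth slice of the homolog sequence exactly
  hs <- hap_sequences(haps)
  ind <- ped$F2_01
  for (i in sample(nrow(s$truth), 50)) {
    tr <- s$truth[i]
    hom <- kbsa:::.homolog_sequence(hs[[tr$chrom]],
                                    ind$mosaic[[tr$chrom]][[tr$homolog]])
    want <- substring(hom, tr$start, tr$end)
    if (tr$strand == "-") want <- naive_revcomp(want)
    expect_equal(unname(s$reads[i]), want)
  }
})

test_that("substitution errors appear at the requested rate", {
  haps <- sim_haplotypes(c(chr01 = 2e4), 1 / 500, seed = 15)
  ped <- simulate_pedigree(haps, 2, 1, seed = 16)
  er <- 0.01
  sims <- simulate_reads(ped["F2_01"], haps, coverage = 4, read_len = 100,
                         error_rate = er, seed = 17)
  s <- sims$F2_01
  hs <- hap_sequences(haps)
  ind <- ped$F2_01
  mism <- 0; tot <- 0
  for (i in seq_len(nrow(s$truth))) {
    tr <- s$truth[i]
    hom <- kbsa:::.homolog_sequence(hs[[tr$chrom]],
                                    ind$mosaic[[tr$chrom]][[tr$homolog]])
    want <- substring(hom, tr$start, tr$end)
    if (tr$strand == "-") want <- naive_revcomp(want)
    got <- unname(s$reads[i])
    mism <- mism + sum(strsplit(got, "")[[1]] != strsplit(want, "")[[1]])
    tot <- tot + nchar(got)
  }
  se <- sqrt(er * (1 - er) / tot)
  expect_lt(abs(mism / tot - er), 4 * se)
  expect_error(simulate_reads(ped["F2_01"], haps, error_rate = 0.5),
               "error_rate")
  expect_error(simulate_reads(ped["F2_01"], haps, coverage = 1,
                              read_len = 3e4), "shortest")
})

test_that("identical seeds give identical FASTQ bytes", {
  haps <- sim_haplotypes(c(chr01 = 1e4), 1 / 500, seed = 18)
  ped <- simulate_pedigree(haps, 2, 1, seed = 19)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(ped["F2_01"], haps, coverage = 2,
                             seed = 20)$F2_01$reads, f1)
  write_fastq(simulate_reads(ped["F2_01"], haps, coverage = 2,
                             seed = 20)$F2_01$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(length(readLines(f1)) %% 4, 0)
  # and the FASTQ round-trips through the counting reader
  back <- count_kmers(f1, k = 15)
  direct <- count_kmers(simulate_reads(ped["F2_01"], haps, coverage = 2,
                                       seed = 20)$F2_01$reads, k = 15)
  expect_equal(back$entries, direct$entries)
})

test_that("paired mode emits proper mate pairs", {
  haps <- sim_haplotypes(c(chr01 = 2e4), 1 / 500, seed = 21)
  ped <- simulate_pedigree(haps, 2, 1, seed = 22)
  sims <- simulate_reads(ped["F2_01"], haps, coverage = 2, read_len = 100,
                         error_rate = 0, paired = TRUE, seed = 23)
  s <- sims$F2_01
  expect_true(all(grepl("/[12]$", names(s$reads))))
  # mate 2 is the reverse complement of the fragment end
  tr <- s$truth
  r1 <- tr[grepl("/1$", qname)][1]
  mate <- sub("/1$", "/2", r1$qname)
  r2 <- tr[qname == mate]
  expect_equal(r2$end - r1$start + 1L, 250L) # insert = 2*100 + 50
  expect_equal(r2$strand, "-")
})

test_that("truth VCF encodes parental genotypes correctly", {
  mk_haps <- function(A, B, C, D) {
    structure(list(
      chrom_lengths = c(chr01 = 100L),
      reference = c(chr01 = paste(rep("G", 100), collapse = "")),
      snp = data.table::data.table(chrom = "chr01", pos = 50L, ref = "G",
                                   alt = "T", A = A, B = B, C = C, D = D)),
      class = "haplotype_set")
  }
  f <- tempfile(fileext = ".vcf")
  emit_truth_vcf(mk_haps("G", "G", "T", "T"), f)
  rec <- strsplit(grep("^chr", readLines(f), value = TRUE), "\t")[[1]]
  expect_equal(rec[2], "50")
  expect_equal(sub(":.*", "", rec[10]), "0/0") # P1 homozygous ref
  expect_equal(sub(":.*", "", rec[11]), "1/1") # P2 homozygous alt

  emit_truth_vcf(mk_haps("G", "T", "T", "T"), f)
  rec <- strsplit(grep("^chr", readLines(f), value = TRUE), "\t")[[1]]
  expect_equal(sub(":.*", "", rec[10]), "0/1") # P1 heterozygous

  # no SNPs -> header-only
  empty <- mk_haps("G", "G", "T", "T")
  empty$snp <- empty$snp[0]
  emit_truth_vcf(empty, f)
  expect_length(grep("^chr", readLines(f)), 0)
  expect_true(any(grepl("fileformat=VCFv4.2", readLines(f))))

  # multi-allelic site skipped with a warning
  expect_warning(emit_truth_vcf(mk_haps("G", "T", "A", "A"), f),
                 "multi-allelic")
  expect_length(grep("^chr", readLines(f)), 0)
})

test_that("truth SAM is a valid single-end alignment file", {
  haps <- sim_haplotypes(c(chr01 = 1e4), 1 / 500, seed = 24)
  ped <- simulate_pedigree(haps, 2, 1, seed = 25)
  sims <- simulate_reads(ped["F2_01"], haps, coverage = 1, read_len = 80,
                         error_rate = 0, seed = 26)
  f <- tempfile(fileext = ".sam")
  write_truth_sam(sims$F2_01$truth, haps, f)
  lines <- readLines(f)
  expect_true(any(grepl("^@SQ\tSN:chr01\tLN:10000$", lines)))
  recs <- strsplit(grep("^[^@]", lines, value = TRUE), "\t")
  expect_equal(length(recs), nrow(sims$F2_01$truth))
  flags <- vapply(recs, function(r) as.integer(r[2]), integer(1))
  expect_true(all(flags %in% c(0L, 16L)))
  expect_equal(mean(flags == 16L), mean(sims$F2_01$truth$strand == "-"))
})
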