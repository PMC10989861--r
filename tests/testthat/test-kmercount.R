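test_that("counting slides a canonical window over every read", {
  tab <- count_kmers("ACGGA", k = 3)
  expect_equal(tab$entries$kmer, c("ACG", "CCG", "GGA"))
  expect_equal(tab$entries$count, c(1, 1, 1))

  expect_equal(nrow(count_kmers(character(0), k = 3)$entries), 0)

  # a read and its exact reverse complement double every count
  r <- random_dna(200, seed = 1)
  one <- count_kmers(r, k = 7)
  two <- count_kmers(c(r, naive_revcomp(r)), k = 7)
  expect_equal(two$entries$kmer, one$entries$kmer)
  expect_equal(two$entries$count, 2 * one$entries$count)
})

test_that("counting equals the naive substring dictionary on fixtures", {
  set.seed(7)
  for (k in c(5, 15, 31)) {
    reads <- vapply(sample(40:160, 60, replace = TRUE), function(n)
      random_dna(n), character(1))
    got <- count_kmers(reads, k = k)$entries
    want <- naive_count(reads, k)
    expect_equal(got$kmer, want$kmer)
    expect_equal(got$count, want$count)
  }
  # non-ACGT characters break windows instead of casting
  got <- count_kmers("ACGTNACGTT", k = 3)$entries
  want <- naive_count(c("ACGT", "ACGTT"), 3)
  expect_equal(got$kmer, want$kmer)
  expect_equal(got$count, want$count)
})

test_that("canonicalization is idempotent and strand-collapsing", {
  set.seed(8)
  kms <- substring(random_dna(4000), seq(1, 3970, by = 31), seq(31, 4000, by = 31))
  expect_equal(canonicalize(kms), naive_canonical(kms))
  expect_equal(canonicalize(canonicalize(kms)), canonicalize(kms))
  r <- random_dna(500)
  expect_equal(count_kmers(r, k = 31)$entries,
               count_kmers(naive_revcomp(r), k = 31)$entries)
})

test_that("reads shorter than k are skipped and tallied", {
  tab <- count_kmers(c("ACGTACGTA", "ACG", "GT"), k = 5)
  expect_equal(attr(tab, "n_too_short"), 2)
  expect_equal(sum(tab$entries$count), 5)
})

test_that("per-sample singleton filtering drops exactly the low counts", {
  tab <- kmer_table(data.table::data.table(kmer = c("ACG", "CCG"),
                                           count = c(1, 5)), k = 3)
  expect_equal(filter_singletons(tab, 2)$entries$kmer, "CCG")
  expect_equal(filter_singletons(tab, 1)$entries, tab$entries)
  all1 <- kmer_table(data.table::data.table(kmer = c("ACG", "CCG"),
                                            count = c(1, 1)), k = 3)
  expect_equal(nrow(filter_singletons(all1)$entries), 0)
})

test_that("bulk merging sums counts and is order-invariant", {
  t1 <- kmer_table(data.table::data.table(kmer = "AAC", count = 2), k = 3)
  t2 <- kmer_table(data.table::data.table(kmer = c("AAC", "AAG"),
                                          count = c(3, 4)), k = 3)
  m <- merge_bulk(list(t1, t2), "b")
  expect_equal(m$entries[order(kmer), count], c(5, 4))
  expect_equal(merge_bulk(list(t2))$entries, t2$entries)
  expect_equal(merge_bulk(list(t1, t2))$entries,
               merge_bulk(list(t2, t1))$entries)
  expect_equal(kt_total(m), kt_total(t1) + kt_total(t2)) # conservation
  t3 <- kmer_table(data.table::data.table(kmer = "AACGT", count = 1), k = 5)
  expect_error(merge_bulk(list(t1, t3)), "different k")
})

test_that("histogram threshold finds the error/genomic valley", {
  # abundance histogram 1:1000, 2:300, 3:50, 4:20, 5:30, 6:60 -> valley at 4
  counts <- rep(1:6, times = c(1000, 300, 50, 20, 30, 60))
  tab <- kmer_table(data.table::data.table(kmer = int_kmers(length(counts)),
                                           count = counts),
                    k = 7, canonical = FALSE)
  expect_equal(histogram_threshold(tab), 4L)
  # monotone decreasing -> fallback
  mono <- kmer_table(data.table::data.table(
    kmer = int_kmers(1110), count = rep(1:3, times = c(1000, 100, 10))),
    k = 7, canonical = FALSE)
  expect_equal(histogram_threshold(mono), 5L)
  expect_equal(histogram_threshold(mono, default_min = 1), 2L) # never below 2
  expect_error(histogram_threshold(
    kmer_table(data.table::data.table(kmer = character(), count = numeric()),
               k = 7, canonical = FALSE)), "empty")
})

test_that("bulk abundance thresholding matches the min-count rule", {
  tab <- kmer_table(data.table::data.table(kmer = c("AAC", "AAG"),
                                           count = c(4, 5)), k = 3)
  expect_equal(apply_bulk_threshold(tab, 5)$entries$kmer, "AAG")
  expect_equal(apply_bulk_threshold(tab, 0)$entries, tab$entries)
})

test_that("joining bulks takes the key union with explicit zeros", {
  a <- kmer_table(data.table::data.table(kmer = "AAC", count = 5), k = 3,
                  owner = "A")
  b <- kmer_table(data.table::data.table(kmer = c("AAC", "AAT"),
                                         count = c(2, 9)), k = 3,
                  owner = "B")
  j <- join_bulks(a, b)
  expect_equal(j$kmer, c("AAC", "AAT"))
  expect_equal(j$K_A, c(5, 0))
  expect_equal(j$K_B, c(2, 9))
  expect_equal(attr(j, "N_A"), 5)
  expect_equal(attr(j, "N_B"), 11)
  # swap mirrors the columns
  j2 <- join_bulks(b, a)
  expect_equal(j2$K_A, j$K_B)
  expect_equal(j2$K_B, j$K_A)
  # disjoint tables have one zero per row
  c_tab <- kmer_table(data.table::data.table(kmer = "GGG", count = 3), k = 3)
  jd <- join_bulks(a, c_tab)
  expect_true(all((jd$K_A == 0) != (jd$K_B == 0)))
})

test_that("fused bulk pipeline equals the composed operations", {
  set.seed(11)
  mk_sample <- function() {
    base <- random_dna(800)
    c(substring(base, 1:20 * 30, 1:20 * 30 + 59), # repeated genome windows
      vapply(1:10, function(i) random_dna(60), character(1)))
  }
  ra <- list(mk_sample(), mk_sample(), mk_sample())
  rb <- list(mk_sample(), mk_sample())
  fused <- count_and_join_bulks(ra, rb, k = 17, min_sample_count = 2,
                                min_bulk_count = 3)
  composed <- join_bulks(
    apply_bulk_threshold(count_bulk_kmers(ra, k = 17, min_sample_count = 2), 3),
    apply_bulk_threshold(count_bulk_kmers(rb, k = 17, min_sample_count = 2), 3))
  expect_equal(fused$kmer, composed$kmer)
  expect_equal(fused$K_A, composed$K_A)
  expect_equal(fused$K_B, composed$K_B)
  expect_equal(attr(fused, "N_A"), attr(composed, "N_A"))
  expect_equal(attr(fused, "N_B"), attr(composed, "N_B"))
  # and the bulk counter equals composing the per-sample operations
  by_hand <- merge_bulk(lapply(ra, function(r)
    filter_singletons(count_kmers(r, k = 17), 2)))
  expect_equal(count_bulk_kmers(ra, k = 17)$entries, by_hand$entries)
})

test_that("count lookup restricted to queries matches the full table", {
  set.seed(12)
  reads <- replicate(30, random_dna(90))
  full <- count_kmers(reads, k = 15)
  q <- c(full$entries$kmer[c(3, 10, 50)], "AAAAAAAAAAAAAAA")
  sub <- count_kmer_subset(reads, q, k = 15)
  expect_equal(sub$entries$count,
               full$entries[match(sub$entries$kmer, kmer), count])
  expect_false("AAAAAAAAAAAAAAA" %in% sub$entries$kmer)
})

test_that("count tables round-trip through TSV", {
  tab <- count_kmers(random_dna(300, seed = 3), k = 9, owner = "s1")
  f <- tempfile(fileext = ".tsv")
  write_kmer_table(tab, f)
  back <- read_kmer_table(f, owner = "s1")
  expect_equal(back$entries, tab$entries)
  expect_equal(back$k, 9L)
})

test_that("k is validated", {
  expect_error(count_kmers("ACGT", k = 33), "31")
  expect_error(count_kmers("ACGT", k = 4), "odd")
  expect_silent(count_kmers("ACGTACGT", k = 4, canonical = FALSE))
})
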