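mk_psite <- function(...) {
  base <- data.table::data.table(
    chrom = "chr10", pos = 5e5, ref = "A", alt = "G", qual = 999,
    depth_p1 = 25, depth_p2 = 30, alt_frac_p1 = 0.5, alt_frac_p2 = 0)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}
iv <- list(chrom = "chr10", start = 1, end = 1e6)

test_that("phasing site selection applies all filters conjunctively", {
  keep <- select_phasing_sites(mk_psite(), iv)
  expect_equal(keep$category, "het_focal")
  expect_equal(keep$focal_allele, "G") # focal het, other hom-ref -> alt
  expect_equal(nrow(select_phasing_sites(mk_psite(depth_p1 = 9), iv)), 0)
  expect_equal(nrow(select_phasing_sites(mk_psite(depth_p1 = 51), iv)), 0)
  expect_equal(nrow(select_phasing_sites(mk_psite(depth_p2 = 17), iv)), 0)
  expect_equal(nrow(select_phasing_sites(mk_psite(alt_frac_p2 = 0.10), iv)), 0)
  expect_equal(nrow(select_phasing_sites(mk_psite(qual = 998), iv)), 0)
  expect_equal(nrow(select_phasing_sites(mk_psite(alt_frac_p1 = 0.3), iv)), 0)
  expect_equal(nrow(select_phasing_sites(mk_psite(ref = "AT"), iv)), 0)
  expect_equal(nrow(select_phasing_sites(mk_psite(pos = 2e6), iv)), 0)
  # homozygous in both parents for different alleles
  hb <- select_phasing_sites(mk_psite(alt_frac_p1 = 1, alt_frac_p2 = 0.01), iv)
  expect_equal(hb$category, "hom_both")
  expect_equal(hb$focal_allele, "G")
  # homozygous for the same allele in both parents is dropped
  expect_equal(nrow(select_phasing_sites(
    mk_psite(alt_frac_p1 = 0.01, alt_frac_p2 = 0.01), iv)), 0)
  expect_error(select_phasing_sites(mk_psite(),
                                    list("chr10", 100, 50)), "empty")
})

test_that("bulk allele fractions are simple pileup ratios with a depth floor", {
  p <- data.table::data.table(chrom = "chr10", pos = c(1, 2, 3),
                              n_focal = c(30, 0, 3),
                              n_other = c(30, 40, 2))
  f <- bulk_allele_fraction(p, min_depth = 10)
  expect_equal(f$frac_focal, c(0.5, 0, NA))
})

test_that("hand-tallied pileup fractions match on a printed fixture", {
  # ten sites, written out long-hand
  pil <- data.table::data.table(
    chrom = "chr10",
    pos = 1:10 * 100L,
    n_focal = c(12, 0, 25, 7, 40, 3, 18, 30, 0, 22),
    n_other = c(12, 36, 25, 21, 0, 37, 18, 10, 28, 22))
  f <- bulk_allele_fraction(pil, min_depth = 10)
  expect_equal(f$frac_focal,
               c(12 / 24, 0 / 36, 25 / 50, 7 / 28, 40 / 40, 3 / 40,
                 18 / 36, 30 / 40, 0 / 28, 22 / 44))
})

test_that("haplotype grouping splits trait-linked from balanced sites", {
  calls <- data.table::data.table(
    frac_focal_bulk_a = c(0.45, 0.50, 0.40, NA),
    frac_focal_bulk_b = c(0.05, 0.52, 0.22, 0.2))
  g <- assign_haplotype_groups(calls)
  expect_equal(g$category, c("hap1", "hap2", "unclear", NA))
  expect_error(assign_haplotype_groups(calls, delta_min = 0.05,
                                       similar_max = 0.1), "delta_min")
})

test_that("density tracks count categorized sites per window", {
  sites <- data.table::data.table(
    chrom = "chr10", pos = c(5e3, 1.5e4, 1.6e4, 4.5e4),
    category = c("hap1", "hap1", "hap2", "hom_both"))
  tr <- haplotype_density_track(sites, window = 1e4,
                                chrom_lengths = c(chr10 = 5e4))
  expect_equal(nrow(tr), 5)
  expect_equal(tr$hap1, c(1L, 1L, 0L, 0L, 0L))
  expect_equal(tr$hap2, c(0L, 1L, 0L, 0L, 0L))
  expect_equal(tr$hom_both, c(0L, 0L, 0L, 0L, 1L))
  zero <- haplotype_density_track(sites[0], window = 1e4,
                                  chrom_lengths = c(chr10 = 2e4))
  expect_true(all(zero$hap1 == 0))
})

test_that("trait-linked haplotype sites are recovered from bulk fractions", {
  # tight linkage (0.2 crossovers per meiosis over one 200-kb chromosome)
  # keeps the whole chromosome inside the causal interval, so the grouping
  # operation is tested at its nominal contrast (~4/7 vs ~0 on haplotype A)
  sc <- bsa_scenario(seed = 77, chrom_lengths = c(chr01 = 2e5),
                     n_f1_pool = 40, n_f1_seq = 6, n_f2 = 32, coverage = 6,
                     parent_coverage = 15, causal_chrom = "chr01",
                     causal_pos = 1e5, recomb_rate = 0.2)
  sites_all <- truth_variant_sites(sc$haps, seed = 99)
  interval <- list(chrom = "chr01", start = 1, end = 2e5)
  sel <- select_phasing_sites(sites_all, interval)
  het <- sel[category == "het_focal"]
  expect_gt(nrow(het), 30)
  pa <- bulk_allele_fraction(bulk_pileup(sc$sims, sc$bulk_pos, het))
  pb <- bulk_allele_fraction(bulk_pileup(sc$sims, sc$bulk_neg, het))
  calls <- data.table::data.table(
    het, frac_focal_bulk_a = pa$frac_focal, frac_focal_bulk_b = pb$frac_focal)
  calls <- assign_haplotype_groups(calls)
  # truth: is the focal-specific allele on the causal haplotype A?
  truth <- sc$haps$snp[calls[, .(chrom, pos)], on = c("chrom", "pos")]
  on_A <- truth$A == calls$focal_allele & truth$B != calls$focal_allele
  ok <- !is.na(calls$category)
  # A-carried specific alleles contrast at ~4/7 vs ~0 and separate as hap1;
  # B-carried ones sit at the much weaker (and opposite-signed) 1/7 vs 1/3
  # contrast, so their hap1 rate must fall well below the A rate
  rate_A <- mean(calls$category[ok & on_A] == "hap1")
  rate_B <- mean(calls$category[ok & !on_A] == "hap1")
  expect_gt(rate_A, 0.9)
  expect_gt(rate_A, rate_B + 0.3)
  # and the sign of the contrast tracks the haplotype
  d <- calls$frac_focal_bulk_a - calls$frac_focal_bulk_b
  expect_gt(mean(d[ok & on_A]), 0.25)
  expect_lt(mean(d[ok & !on_A]), 0)
})
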