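#' Reference base carried by each read over a set of sites
#'
#' Intersects one individual's simulated reads with single-base sites and
#' reports, per overlapping (read, site) pair, the base the read carries at
#' that reference position (complemented back for minus-strand reads, so
#' bases are always on the reference strand). Sequencing errors show up as
#' third alleles or as the other parent's base, exactly as in a pileup.
#'
#' @param sample_sim one element of a [simulate_reads()] result
#'   (`list(reads, truth)`).
#' @param sites `data.table` with columns `chrom`, `pos` (1-based).
#' @return `data.table` with columns `chrom`, `pos`, `base`.
#' @export
site_read_bases <- function(sample_sim, sites) {
  tr <- copy(sample_sim$truth)
  tr[, read_idx := .I]
  si <- as.data.table(sites)[, .(chrom, pos, start = pos, end = pos)]
  if (!nrow(si) || !nrow(tr))
    return(data.table(chrom = character(), pos = integer(),
                      base = character()))
  setkey(tr, chrom, start, end)
  ov <- foverlaps(si, tr, type = "within", nomatch = NULL)
  if (!nrow(ov))
    return(data.table(chrom = character(), pos = integer(),
                      base = character()))
  # stored read sequences are already reverse-complemented for minus-strand
  # placements: read offset and base both need flipping back
  off <- fifelse(ov$strand == "-", ov$end - ov$pos + 1L,
                 ov$pos - ov$start + 1L)
  b <- substring(sample_sim$reads[ov$read_idx], off, off)
  minus <- ov$strand == "-"
  b[minus] <- chartr("ACGT", "TGCA", b[minus])
  data.table(chrom = ov$chrom, pos = ov$pos, base = b)
}

#' Informative-read counts at parental SNPs for one individual
#'
#' An informative read covers a selected parental SNP and matches one of
#' the two (homozygous, different) parental alleles exactly; mismatching
#' reads are ignored.
#' @param sample_sim one element of a [simulate_reads()] result.
#' @param snps selected parental SNPs from [select_parental_snps()]
#'   (needs `chrom, pos, p1_allele, p2_allele`).
#' @return `data.table` with columns `chrom, pos, n_p1, n_p2`.
#' @export
count_parental_alleles <- function(sample_sim, snps) {
  bases <- site_read_bases(sample_sim, snps)
  if (!nrow(bases))
    return(data.table(chrom = character(), pos = integer(),
                      n_p1 = integer(), n_p2 = integer()))
  m <- snps[, .(chrom, pos, p1_allele, p2_allele)][bases, on = c("chrom", "pos")]
  m[, .(n_p1 = sum(base == p1_allele), n_p2 = sum(base == p2_allele)),
    by = .(chrom, pos)]
}

#' Pooled bulk pileup of the focal-specific allele at phasing sites
#'
#' Pools the reads of all bulk members and counts, per site, reads
#' carrying the focal-parent-specific allele versus the alternative
#' parental allele (other bases are excluded as error).
#' @param sims a [simulate_reads()] result.
#' @param members ids of the bulk's individuals.
#' @param sites categorized sites from [select_phasing_sites()] (needs
#'   `chrom, pos, ref, alt, focal_allele`).
#' @return `data.table` with `chrom, pos, n_focal, n_other`.
#' @export
bulk_pileup <- function(sims, members, sites) {
  sites <- as.data.table(sites)
  sites[, other_allele := fifelse(focal_allele == ref, alt, ref)]
  bases <- rbindlist(lapply(sims[members], site_read_bases, sites = sites))
  base_sites <- sites[, .(chrom, pos, focal_allele, other_allele)]
  if (nrow(bases)) {
    m <- base_sites[bases, on = c("chrom", "pos")]
    cnt <- m[, .(n_focal = sum(base == focal_allele),
                 n_other = sum(base == other_allele)), by = .(chrom, pos)]
  } else {
    cnt <- data.table(chrom = character(), pos = integer(),
                      n_focal = integer(), n_other = integer())
  }
  out <- cnt[base_sites[, .(chrom, pos)], on = c("chrom", "pos")]
  out[is.na(n_focal), `:=`(n_focal = 0L, n_other = 0L)]
  out[]
}

#' All genomic k-mers of each parent
#'
#' Canonical k-mer sets of the parental haplotype sequences (P1 = A and B,
#' P2 = C and D); the simulation truth against which read-based origin
#' calls can be validated.
#' @param haps a `haplotype_set`.
#' @param k k-mer length.
#' @return list with character vectors `p1` and `p2`.
#' @export
parent_genome_kmers <- function(haps, k = 31) {
  hs <- hap_sequences(haps)
  seqs_of <- function(labels)
    unlist(lapply(hs, function(ch) unlist(ch[labels])), use.names = FALSE)
  list(p1 = count_kmers(seqs_of(c("A", "B")), k = k)$entries$kmer,
       p2 = count_kmers(seqs_of(c("C", "D")), k = k)$entries$kmer)
}

#' Simulate a complete bulked-segregant study
#'
#' Generates the study conditions end to end: a four-haplotype parental
#' genome, an F1 intercross pedigree, a planted causal haplotype with
#' dominant or recessive action on a binary trait, and error-bearing short
#' reads for both parents and every progeny individual. Progeny are split
#' into a phenotype-positive and a phenotype-negative bulk.
#'
#' Defaults describe the desk-scale study design used throughout the
#' package: 2 chromosomes of 1 Mb, SNPs every 500 bp on average, a pool of
#' 52 F1 plants intercrossed to give 48 F2, with 8 F1 and all 48 F2
#' individuals sequenced at 4x coverage, parents at 20x, 150-bp reads with
#' a 0.2% substitution rate, one crossover per chromosome per meiosis, and
#' a dominant parent-1 haplotype A allele planted at 625 kb of
#' chromosome 1 (mid-bin on the default 50-kb dosage grid, so bin-distance
#' statements about the locus are unambiguous).
#'
#' @param seed integer seed driving every random choice.
#' @param mode `"dominant"` or `"recessive"` causal action.
#' @param causal_hap,causal_chrom,causal_pos the planted allele.
#' @param n_f1_pool number of F1 plants in the intercross pool.
#' @param n_f1_seq number of F1 individuals sequenced (drawn at random
#'   from the pool).
#' @param n_f2 number of F2 individuals (all sequenced).
#' @param chrom_lengths,snp_density genome shape.
#' @param coverage,parent_coverage fold coverages (progeny / parents).
#' @param read_len,error_rate,recomb_rate read and meiosis parameters.
#' @return a `bsa_scenario` list: `haps`, `locus`, `pedigree` (traits
#'   assigned), `sims` (reads + truth per sequenced individual),
#'   `bulk_pos` / `bulk_neg` (sequenced progeny ids by phenotype), and the
#'   parameters.
#' @export
bsa_scenario <- function(seed = 1, mode = c("dominant", "recessive"),
                         causal_hap = "A", causal_chrom = "chr01",
                         causal_pos = 6.25e5, n_f1_pool = 52, n_f1_seq = 8,
                         n_f2 = 48,
                         chrom_lengths = c(chr01 = 1e6, chr02 = 1e6),
                         snp_density = 1 / 500, coverage = 4,
                         parent_coverage = 20, read_len = 150,
                         error_rate = 0.002, recomb_rate = 1) {
  mode <- match.arg(mode)
  stopifnot(n_f1_seq <= n_f1_pool)
  haps <- sim_haplotypes(chrom_lengths, snp_density, seed = seed)
  locus <- causal_locus(causal_chrom, causal_pos, causal_hap, mode)
  ped <- simulate_pedigree(haps, n_f1 = n_f1_pool, n_f2 = n_f2,
                           recomb_rate = recomb_rate, seed = seed + 1L)
  ped <- assign_traits(ped, locus)
  gen <- vapply(ped, `[[`, character(1), "generation")
  f1_seq <- sample(names(ped)[gen == "F1"], n_f1_seq)
  progeny <- c(f1_seq, names(ped)[gen == "F2"])
  parents <- names(ped)[gen == "P"]
  sims <- c(simulate_reads(ped[parents], haps, coverage = parent_coverage,
                           read_len = read_len, error_rate = error_rate,
                           seed = seed + 2L),
            simulate_reads(ped[progeny], haps, coverage = coverage,
                           read_len = read_len, error_rate = error_rate,
                           seed = seed + 3L))
  pos <- vapply(ped[progeny], function(i) isTRUE(i$trait_values[[locus$trait_name]]),
                logical(1))
  structure(list(haps = haps, locus = locus, pedigree = ped, sims = sims,
                 bulk_pos = progeny[pos], bulk_neg = progeny[!pos],
                 params = list(seed = seed, mode = mode, coverage = coverage,
                               parent_coverage = parent_coverage,
                               read_len = read_len, error_rate = error_rate,
                               recomb_rate = recomb_rate)),
            class = "bsa_scenario")
}

#' Run the k-mer bulked-segregant pipeline on a simulated scenario
#'
#' Executes counting (per-sample singleton removal, bulk aggregation, bulk
#' min-count), the bulk join, the nested-Poisson differential test,
#' parental-origin classification of the enriched k-mers, read
#' backtracking, binned dosage with per-bin normalization, and peak
#' calling. Bulk A is the phenotype-positive bulk throughout, so track
#' ratios read positive-over-negative.
#'
#' @param scenario a [bsa_scenario()].
#' @param k k-mer length (default 31).
#' @param min_sample_count per-sample count filter (default 2).
#' @param min_bulk_count bulk abundance threshold (default 5).
#' @param cfg a [test_config()].
#' @param bin_size dosage bin width (default 50 kb, matched to the
#'   megabase-scale chromosomes of the default scenario).
#' @param presence_min parental presence threshold for origin calls.
#' @param track_set which enriched set drives the dosage track:
#'   `"positive"` (default; the trait-associated bulk's enriched k-mers,
#'   backtracked in both bulks, so the ratio reads as that set's bulk
#'   specificity), `"negative"`, or `"union"`.
#' @return list with `diff` (records + enriched sets), `origin` (calls for
#'   all enriched k-mers), `origin_summary`, `track` (per-bin dosage and
#'   ratio), `peaks`, `totals`, and the thresholded bulk tables' sizes.
#' @export
run_bsa <- function(scenario, k = 31, min_sample_count = 2,
                    min_bulk_count = 5, cfg = test_config(),
                    bin_size = 5e4, presence_min = 2,
                    track_set = c("positive", "negative", "union")) {
  track_set <- match.arg(track_set)
  stopifnot(inherits(scenario, "bsa_scenario"))
  if (!length(scenario$bulk_pos) || !length(scenario$bulk_neg))
    stop("both phenotype bulks must be non-empty; this scenario draw left ",
         "one bulk without individuals")
  sims <- scenario$sims
  reads_of <- function(ids) lapply(sims[ids], `[[`, "reads")
  merged <- count_and_join_bulks(reads_of(scenario$bulk_pos),
                                 reads_of(scenario$bulk_neg),
                                 k = k, min_sample_count = min_sample_count,
                                 min_bulk_count = min_bulk_count,
                                 bulk_a_id = "positive",
                                 bulk_b_id = "negative")
  diff <- call_differential(merged, cfg)
  enriched <- c(diff$enriched_in_A, diff$enriched_in_B)
  # parental presence tables restricted to the enriched k-mers, with the
  # same per-sample singleton removal applied to the parental read sets
  p_tab <- function(id) count_kmer_subset(sims[[id]]$reads, enriched, k = k,
                                          min_count = min_sample_count,
                                          owner = id)
  p1 <- p_tab("P1"); p2 <- p_tab("P2")
  origin <- classify_origin(enriched, p1, p2, presence_min = presence_min)
  enriched_in <- c(rep("positive", length(diff$enriched_in_A)),
                   rep("negative", length(diff$enriched_in_B)))
  osum <- origin_summary(origin, enriched_in)
  # localization from truth placements (MAPQ 60, primary)
  track_kmers <- switch(track_set,
                        positive = diff$enriched_in_A,
                        negative = diff$enriched_in_B,
                        union = enriched)
  bcfg <- bin_config(bin_size = bin_size)
  aln_of <- function(ids, sel = NULL) {
    rbindlist(lapply(ids, function(id) {
      tr <- sims[[id]]$truth[, .(chrom, pos = start)]
      if (!is.null(sel)) tr <- tr[sel[[id]]]
      tr
    }))
  }
  sel_pos <- lapply(scenario$bulk_pos, function(id)
    backtrack_reads(sims[[id]]$reads, track_kmers, k = k))
  names(sel_pos) <- scenario$bulk_pos
  sel_neg <- lapply(scenario$bulk_neg, function(id)
    backtrack_reads(sims[[id]]$reads, track_kmers, k = k))
  names(sel_neg) <- scenario$bulk_neg
  cl <- scenario$haps$chrom_lengths
  sig_a <- bin_reads(aln_of(scenario$bulk_pos, sel_pos), bcfg, cl)
  tot_a <- bin_reads(aln_of(scenario$bulk_pos), bcfg, cl)
  sig_b <- bin_reads(aln_of(scenario$bulk_neg, sel_neg), bcfg, cl)
  tot_b <- bin_reads(aln_of(scenario$bulk_neg), bcfg, cl)
  track <- normalize_and_ratio(sig_a, tot_a, sig_b, tot_b, bcfg)
  peaks <- call_peak(track, bin_size = bin_size)
  list(diff = diff, origin = origin, origin_summary = osum, track = track,
       peaks = peaks, bin_size = bin_size,
       totals = c(N_A = attr(merged, "N_A"), N_B = attr(merged, "N_B")),
       n_tested = nrow(merged))
}

#' Parental-SNP genotype matrix of the progeny
#'
#' The conventional-mapping comparator's genotyping stage: informative-read
#' counts per selected parental SNP per individual, pooled into bins.
#' @param scenario a [bsa_scenario()].
#' @param snps selected parental SNPs ([select_parental_snps()]).
#' @param cfg a [genotype_config()].
#' @param individuals ids to genotype (default: all F2).
#' @return list with `genotypes` (character matrix individuals x bins) and
#'   `trait` (logical vector aligned with rows).
#' @export
genotype_progeny <- function(scenario, snps, cfg = genotype_config(),
                             individuals = NULL) {
  ped <- scenario$pedigree
  if (is.null(individuals)) {
    gen <- vapply(ped, `[[`, character(1), "generation")
    individuals <- names(ped)[gen == "F2"]
  }
  cl <- scenario$haps$chrom_lengths
  rows <- lapply(individuals, function(id) {
    ac <- count_parental_alleles(scenario$sims[[id]], snps)
    gb <- genotype_bins(ac, snps, cfg, cl)
    setNames(gb$genotype, paste(gb$chrom, gb$bin_start, sep = ":"))
  })
  g <- do.call(rbind, rows)
  rownames(g) <- individuals
  trait <- vapply(ped[individuals], function(i)
    isTRUE(i$trait_values[[scenario$locus$trait_name]]), logical(1))
  list(genotypes = g, trait = trait)
}
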