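#' Configuration of parental-SNP bin genotyping
#'
#' Defaults follow conventional short-read practice for a ~10x F2 panel:
#' sites kept at call quality >= 100 and pooled depth within 25-70 (about
#' 0.8x-2.3x the genomic average, excluding repeats and dropouts); bins of
#' 100 kb genotyped from >= 50 informative reads, called homozygous when
#' more than 95% of informative reads come from one parent.
#'
#' @param bin_size genotyping bin width (default 100 kb).
#' @param min_informative_reads minimum informative reads per bin
#'   (default 50).
#' @param hom_fraction homozygosity threshold (default 0.95, strict).
#' @param qual_min minimum variant quality (default 100).
#' @param depth_min,depth_max pooled parental depth window (default 25-70).
#' @return a `genotype_config` list.
#' @export
genotype_config <- function(bin_size = 100000, min_informative_reads = 50,
                            hom_fraction = 0.95, qual_min = 100,
                            depth_min = 25, depth_max = 70) {
  stopifnot(hom_fraction > 0.5, hom_fraction < 1, depth_min < depth_max)
  structure(list(bin_size = as.integer(bin_size),
                 min_informative_reads = min_informative_reads,
                 hom_fraction = hom_fraction, qual_min = qual_min,
                 depth_min = depth_min, depth_max = depth_max),
            class = "genotype_config")
}

# VCF (path or vcfR object) -> VariantSite data.table; expects exactly two
# sample columns, parent 1 first
.as_variant_sites <- function(variants) {
  if (is.data.frame(variants)) return(as.data.table(variants))
  if (is.character(variants) && length(variants) == 1) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("vcfR is required to read VCF files")
    variants <- vcfR::read.vcfR(variants, verbose = FALSE)
  }
  if (!methods::is(variants, "vcfR")) stop("unsupported variant input")
  fix <- as.data.table(vcfR::getFIX(variants))
  gt <- vcfR::extract.gt(variants)
  dp <- suppressWarnings(vcfR::extract.gt(variants, element = "DP",
                                          as.numeric = TRUE))
  if (ncol(gt) < 2) stop("VCF must contain both parent columns")
  code_gt <- function(g) {
    g <- sub("\\|", "/", g)
    fcase(g %in% c("0/0"), "hom_ref",
          g %in% c("1/1"), "hom_alt",
          g %in% c("0/1", "1/0"), "het",
          default = NA_character_)
  }
  data.table(chrom = fix$CHROM, pos = as.integer(fix$POS),
             ref = fix$REF, alt = fix$ALT,
             qual = as.numeric(fix$QUAL),
             gt_p1 = code_gt(gt[, 1]), gt_p2 = code_gt(gt[, 2]),
             depth_p1 = dp[, 1], depth_p2 = dp[, 2])
}

#' Select parental SNPs for conventional genotyping
#'
#' Retains biallelic sites that pass quality (`qual >= qual_min`), pooled
#' parental depth (`depth_min <= depth_p1 + depth_p2 <= depth_max` scaled;
#' see Details) and are homozygous for different alleles in the two
#' parents — the only sites at which a read can be assigned to a parent
#' unambiguously.
#'
#' @details The depth window is applied to the summed parental depths.
#'
#' @param variants a VCF path, a `vcfR` object, or a `data.frame` of
#'   variant sites (columns `chrom, pos, ref, alt, qual, gt_p1, gt_p2,
#'   depth_p1, depth_p2`).
#' @param cfg a [genotype_config()].
#' @return `data.table` of retained sites, with a `p1_allele` /
#'   `p2_allele` column giving each parent's (homozygous) base.
#' @export
select_parental_snps <- function(variants, cfg = genotype_config()) {
  v <- .as_variant_sites(variants)
  need <- c("chrom", "pos", "ref", "alt", "qual", "gt_p1", "gt_p2",
            "depth_p1", "depth_p2")
  if (!all(need %in% names(v)))
    stop("missing variant columns: ", paste(setdiff(need, names(v)),
                                            collapse = ", "))
  depth <- v$depth_p1 + v$depth_p2
  keep <- !is.na(v$qual) & v$qual >= cfg$qual_min &
    !is.na(depth) & depth >= cfg$depth_min & depth <= cfg$depth_max &
    !is.na(v$gt_p1) & !is.na(v$gt_p2) &
    v$gt_p1 %in% c("hom_ref", "hom_alt") &
    v$gt_p2 %in% c("hom_ref", "hom_alt") &
    v$gt_p1 != v$gt_p2 &
    nchar(v$ref) == 1 & nchar(v$alt) == 1
  out <- v[keep]
  out[, p1_allele := fifelse(gt_p1 == "hom_ref", ref, alt)]
  out[, p2_allele := fifelse(gt_p2 == "hom_ref", ref, alt)]
  out[]
}

#' Genotype one individual in genomic bins from parental-SNP read counts
#'
#' Pools, within each consecutive nonoverlapping bin, the individual's
#' informative reads over all selected parental SNPs in the bin (an
#' informative read covers a selected SNP and matches one parental allele
#' exactly). Bins with fewer than `min_informative_reads` are `NA`;
#' otherwise, with `f` the fraction of informative reads carrying the
#' parent-1 allele: `f > hom_fraction` is `hom_P1`, `f < 1 - hom_fraction`
#' is `hom_P2`, anything in between `het`.
#'
#' @param allele_counts `data.table` of per-site informative read counts
#'   for one individual: columns `chrom, pos, n_p1, n_p2`.
#' @param snps selected parental SNPs (see [select_parental_snps()]);
#'   only their positions are used to place bins, via `chrom_lengths`.
#' @param cfg a [genotype_config()].
#' @param chrom_lengths named vector of chromosome lengths for the bin
#'   grid.
#' @return `data.table` with columns `chrom, bin_start, n_informative,
#'   genotype` (`hom_P1`, `hom_P2`, `het`, or `NA`).
#' @export
genotype_bins <- function(allele_counts, snps, cfg = genotype_config(),
                          chrom_lengths) {
  ac <- as.data.table(allele_counts)
  stopifnot(all(c("chrom", "pos", "n_p1", "n_p2") %in% names(ac)))
  grid <- rbindlist(lapply(names(chrom_lengths), function(ch) {
    data.table(chrom = ch,
               bin_start = seq(0L, as.integer(chrom_lengths[[ch]]) - 1L,
                               by = cfg$bin_size))
  }))
  if (nrow(ac)) {
    ac <- ac[snps[, .(chrom, pos)], on = c("chrom", "pos"), nomatch = NULL]
  }
  if (!nrow(ac)) {
    grid[, `:=`(n_informative = 0L, genotype = NA_character_)]
    return(grid[])
  }
  ac[, bin_start := (as.integer(pos) - 1L) %/% cfg$bin_size * cfg$bin_size]
  agg <- ac[, .(n1 = sum(n_p1), n2 = sum(n_p2)), by = .(chrom, bin_start)]
  out <- agg[grid, on = c("chrom", "bin_start")]
  out[is.na(n1), `:=`(n1 = 0, n2 = 0)]
  out[, n_informative := as.integer(n1 + n2)]
  out[, genotype := fcase(
    n_informative < cfg$min_informative_reads, NA_character_,
    n1 / n_informative > cfg$hom_fraction, "hom_P1",
    n1 / n_informative < 1 - cfg$hom_fraction, "hom_P2",
    default = "het")]
  out[, c("n1", "n2") := NULL]
  out[order(chrom, bin_start)]
}

#' Per-bin binary-trait association scan with a permutation threshold
#'
#' A per-bin 2x3 contingency chi-square of trait class against bin
#' genotype (`hom_P1` / `het` / `hom_P2`), with individuals whose bin is
#' `NA` dropped per bin, as a simple parent-level association scan. The
#' genome-wide significance threshold is the 95th percentile of the
#' maximum bin statistic over `n_perm` random permutations of the trait,
#' which controls the family-wise error across bins without assuming
#' independence between them.
#'
#' @param genotypes matrix or `data.frame` of bin genotypes, individuals
#'   in rows, bins in columns (values `hom_P1`/`het`/`hom_P2`/`NA`).
#' @param trait logical or 0/1 vector, one value per individual; must have
#'   both classes.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @param level quantile of the max-statistic null distribution
#'   (default 0.95).
#' @return list with `stats` (`data.table`: `bin`, `stat`, `n_used`),
#'   `threshold`, `significant` (bins with `stat > threshold`) and
#'   `perm_max` (the permutation max-statistic draws).
#' @export
association_scan <- function(genotypes, trait, n_perm = 1000, seed = NULL,
                             level = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  g <- as.matrix(genotypes)
  trait <- as.logical(trait)
  if (length(unique(trait[!is.na(trait)])) < 2)
    stop("trait is constant: association is undefined")
  stopifnot(nrow(g) == length(trait))
  lv <- c("hom_P1", "het", "hom_P2")
  gi <- matrix(match(g, lv), nrow = nrow(g)) # integer codes, NA kept
  chisq_bin <- function(code, tr) {
    ok <- !is.na(code) & !is.na(tr)
    n <- sum(ok)
    if (n == 0) return(c(0, 0))
    tab <- matrix(tabulate(code[ok] + 3L * tr[ok], nbins = 6L),
                  nrow = 2, byrow = TRUE)
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2 || min(rowSums(tab)) == 0) return(c(0, n))
    e <- outer(rowSums(tab), colSums(tab)) / n
    c(sum((tab - e)^2 / e), n)
  }
  obs <- apply(gi, 2, chisq_bin, tr = trait)
  stats <- data.table(bin = colnames(g), stat = obs[1, ], n_used = obs[2, ])
  perm_max <- vapply(seq_len(n_perm), function(i) {
    tr <- sample(trait)
    max(apply(gi, 2, function(col) chisq_bin(col, tr)[1]))
  }, numeric(1))
  threshold <- unname(quantile(perm_max, level, type = 7))
  list(stats = stats, threshold = threshold,
       significant = stats[stat > threshold, bin], perm_max = perm_max)
}
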