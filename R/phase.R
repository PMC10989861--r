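#' Filters for pseudo-phasing site selection
#'
#' Strict variant-level filters applied before pseudo-phasing a candidate
#' interval. The focal parent is the one whose heterozygous haplotypes are
#' being separated; the other parent must be cleanly homozygous. Defaults
#' correspond to a ~30x other parent and ~10x focal parent: other-parent
#' depth 18-64 with alt fraction <= 0.05 or >= 0.95; focal depth 10-50
#' with alt fraction <= 0.05, >= 0.95, or in [0.4, 0.6] (credible
#' heterozygote); caller-capped quality (999); single-base alleles only.
#'
#' @param other_depth_range,focal_depth_range inclusive depth windows.
#' @param other_hom_max alt-fraction bound for the other parent to count
#'   as homozygous (<= this, or >= 1 minus it).
#' @param focal_hom_max as above for the focal parent.
#' @param focal_het_range alt-fraction window for a credible focal
#'   heterozygote.
#' @param qual_required minimum QUAL (default 999, the caller cap).
#' @param snv_only drop indels / multi-base alleles (default `TRUE`).
#' @return a `phasing_filters` list.
#' @export
phasing_filters <- function(other_depth_range = c(18, 64),
                            focal_depth_range = c(10, 50),
                            other_hom_max = 0.05, focal_hom_max = 0.05,
                            focal_het_range = c(0.4, 0.6),
                            qual_required = 999, snv_only = TRUE) {
  stopifnot(other_depth_range[1] < other_depth_range[2],
            focal_depth_range[1] < focal_depth_range[2],
            other_hom_max >= 0, other_hom_max < 0.5)
  structure(list(other_depth_range = other_depth_range,
                 focal_depth_range = focal_depth_range,
                 other_hom_max = other_hom_max,
                 focal_hom_max = focal_hom_max,
                 focal_het_range = focal_het_range,
                 qual_required = qual_required, snv_only = snv_only),
            class = "phasing_filters")
}

#' Select and categorize sites for pseudo-phasing
#'
#' Restricts parental variant sites to a candidate interval and keeps, under
#' the conjunction of all filters, sites that are either homozygous in both
#' parents for different alleles (`hom_both`) or heterozygous in the focal
#' parent and homozygous in the other (`het_focal`). For `het_focal` sites
#' the `focal_allele` column records the focal-parent-specific base — the
#' focal allele absent from the other parent — whose per-bulk read fraction
#' drives the haplotype grouping.
#'
#' @param variants VCF path, `vcfR` object or `data.frame` as in
#'   [select_parental_snps()] (columns `chrom, pos, ref, alt, qual,
#'   depth_p1, depth_p2, alt_frac_p1, alt_frac_p2`; parent 1 is the focal
#'   parent by default).
#' @param interval list or vector `(chrom, start, end)`, 1-based inclusive.
#' @param filters a [phasing_filters()].
#' @param focal `"p1"` or `"p2"`: which parent's haplotypes to phase.
#' @return `data.table` of retained sites with columns `category`
#'   (`hom_both` / `het_focal`) and `focal_allele`.
#' @export
select_phasing_sites <- function(variants, interval,
                                 filters = phasing_filters(),
                                 focal = c("p1", "p2")) {
  focal <- match.arg(focal)
  v <- .as_variant_sites(variants)
  need <- c("chrom", "pos", "ref", "alt", "qual",
            "depth_p1", "depth_p2", "alt_frac_p1", "alt_frac_p2")
  if (!all(need %in% names(v)))
    stop("missing variant columns: ", paste(setdiff(need, names(v)),
                                            collapse = ", "))
  if (is.list(interval) || length(interval) == 3) {
    interval <- list(chrom = as.character(interval[[1]]),
                     start = as.numeric(interval[[2]]),
                     end = as.numeric(interval[[3]]))
  }
  if (interval$end < interval$start) stop("empty interval")
  v <- v[chrom == interval$chrom & pos >= interval$start &
           pos <= interval$end]
  if (focal == "p1") {
    fd <- v$depth_p1; ff <- v$alt_frac_p1
    od <- v$depth_p2; of <- v$alt_frac_p2
  } else {
    fd <- v$depth_p2; ff <- v$alt_frac_p2
    od <- v$depth_p1; of <- v$alt_frac_p1
  }
  flt <- filters
  in_range <- function(x, r) !is.na(x) & x >= r[1] & x <= r[2]
  other_hom <- !is.na(of) & (of <= flt$other_hom_max |
                               of >= 1 - flt$other_hom_max)
  focal_hom <- !is.na(ff) & (ff <= flt$focal_hom_max |
                               ff >= 1 - flt$focal_hom_max)
  focal_het <- in_range(ff, flt$focal_het_range)
  keep <- in_range(od, flt$other_depth_range) &
    in_range(fd, flt$focal_depth_range) &
    other_hom & (focal_hom | focal_het) &
    !is.na(v$qual) & v$qual >= flt$qual_required
  if (flt$snv_only) keep <- keep & nchar(v$ref) == 1 & nchar(v$alt) == 1
  # resolve each parent's allele content from the alt fractions
  other_allele <- fifelse(of >= 0.5, v$alt, v$ref)
  # hom_both requires the parents to be homozygous for different alleles
  hom_both <- focal_hom & fifelse(ff >= 0.5, v$alt, v$ref) != other_allele
  het_focal <- focal_het
  keep <- keep & (hom_both | het_focal)
  out <- v[keep]
  out[, category := fifelse(hom_both[keep], "hom_both", "het_focal")]
  # the focal-specific allele: at het_focal sites, the focal base the other
  # parent does not carry; at hom_both sites, the focal parent's base
  out[, focal_allele := fifelse(other_allele[keep] == alt, ref, alt)]
  out[]
}

#' Fraction of reads carrying the focal-parent-specific allele
#'
#' For each retained site, the fraction of bulk reads that carry the
#' focal-parent-specific allele among reads carrying either parental
#' allele (third-allele reads are treated as sequencing error and
#' excluded). Sites below `min_depth` parental-allele reads are undefined
#' (`NA`).
#'
#' @param pileup `data.table` of pooled bulk pileup counts at the sites:
#'   columns `chrom, pos, n_focal, n_other` (reads carrying the
#'   focal-specific vs the alternative parental allele).
#' @param min_depth minimum parental-allele reads for a defined fraction
#'   (default 10).
#' @return the pileup with an added `frac_focal` column.
#' @export
bulk_allele_fraction <- function(pileup, min_depth = 10) {
  p <- as.data.table(pileup)
  stopifnot(all(c("chrom", "pos", "n_focal", "n_other") %in% names(p)))
  p[, frac_focal := fifelse(n_focal + n_other >= min_depth,
                            n_focal / (n_focal + n_other), NA_real_)]
  p[]
}

#' Group heterozygous focal-parent sites into haplotypes
#'
#' At a site whose focal-specific allele rides the trait-linked haplotype,
#' the allele's read fraction differs strongly between the two phenotypic
#' bulks; on the other haplotype it is similar in both. Sites with
#' `|frac_a - frac_b| >= delta_min` are labeled `hap1` (trait-linked),
#' sites with the difference `<= similar_max` are `hap2`, anything between
#' is `unclear`.
#'
#' @param calls `data.table` with per-site fractions `frac_focal_bulk_a`
#'   and `frac_focal_bulk_b` (e.g. two [bulk_allele_fraction()] results
#'   joined on site).
#' @param delta_min minimum between-bulk contrast for `hap1`
#'   (default 0.25).
#' @param similar_max maximum contrast for `hap2` (default 0.10).
#' @return the calls with an added `category` column (`hap1` / `hap2` /
#'   `unclear`; `NA` fractions give `NA`).
#' @export
assign_haplotype_groups <- function(calls, delta_min = 0.25,
                                    similar_max = 0.10) {
  stopifnot(delta_min > similar_max)
  d <- abs(calls$frac_focal_bulk_a - calls$frac_focal_bulk_b)
  calls <- as.data.table(calls)
  calls[, category := fcase(is.na(d), NA_character_,
                            d >= delta_min, "hap1",
                            d <= similar_max, "hap2",
                            default = "unclear")]
  calls[]
}

#' Windowed density of categorized phasing sites
#'
#' Counts sites per category in consecutive nonoverlapping windows —
#' the spatial pattern compared against the enriched-k-mer track.
#' @param sites `data.table` with `chrom`, `pos`, `category`.
#' @param window window width in bp.
#' @param chrom_lengths named vector of chromosome lengths for the grid.
#' @param categories categories to tabulate (default the four site
#'   classes).
#' @return `data.table`: `chrom, window_start`, one count column per
#'   category.
#' @export
haplotype_density_track <- function(sites, window = 100000, chrom_lengths,
                                    categories = c("hom_both", "hap1",
                                                   "hap2", "unclear")) {
  grid <- rbindlist(lapply(names(chrom_lengths), function(ch) {
    data.table(chrom = ch,
               window_start = seq(0L, as.integer(chrom_lengths[[ch]]) - 1L,
                                  by = as.integer(window)))
  }))
  s <- as.data.table(sites)
  for (cat in categories) {
    if (nrow(s)) {
      cnt <- s[category == cat,
               .(n = .N),
               by = .(chrom,
                      window_start = (as.integer(pos) - 1L) %/%
                        as.integer(window) * as.integer(window))]
      grid[cnt, on = c("chrom", "window_start"), (cat) := i.n]
    }
    if (!cat %in% names(grid)) grid[, (cat) := 0L]
    grid[is.na(get(cat)), (cat) := 0L]
  }
  grid[order(chrom, window_start)]
}
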