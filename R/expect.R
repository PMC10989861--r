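#' F2 genotype distribution of a four-haplotype intercross
#'
#' Two heterozygous diploid parents contribute haplotypes A/B and C/D; F1
#' gametes carry each of the four with probability 1/4, so an F2 unordered
#' genotype has probability 1/16 (homozygous) or 2/16 (heterozygous).
#' @return `data.table` with columns `genotype` (e.g. `"AB"`, alphabetical
#'   within pair) and `prob`; probabilities sum to 1 over the 10 unordered
#'   genotypes.
#' @export
f2_genotype_distribution <- function() {
  haps <- c("A", "B", "C", "D")
  g <- CJ(h1 = haps, h2 = haps)
  g[, genotype := paste0(pmin(h1, h2), pmax(h1, h2))]
  out <- g[, .(prob = .N / 16), by = genotype][order(genotype)]
  out[]
}

.ordered_f2 <- function() {
  haps <- c("A", "B", "C", "D")
  CJ(h1 = haps, h2 = haps)[, prob := 1 / 16][]
}

.carries <- function(g, hap, mode) {
  n <- (g$h1 == hap) + (g$h2 == hap)
  if (mode == "dominant") n >= 1 else n == 2
}

#' Expected within-bulk haplotype allele frequencies
#'
#' Conditions the F2 genotype distribution on the phenotype implied by a
#' single causal haplotype acting dominantly (positive iff at least one
#' copy) or recessively (positive iff two copies) and tallies, within each
#' phenotypic bulk, the frequency of each of the four haplotype alleles
#' among the bulk's homologs. These are the closed-form enrichment
#' expectations that anchor the interpretation of bulk-specific k-mers:
#' under dominance the causal allele is exclusive to the positive bulk
#' while the three non-causal alleles sit at 1/7 (~14%) vs 1/3 (~33%);
#' under recessivity the causal allele is at 100% vs 20%.
#'
#' @param mode `"dominant"` or `"recessive"`.
#' @param causal_haplotype one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return list with elements `positive` and `negative`, each a
#'   `bulk_expectation` (fields `mode`, `bulk`, `freq` over A-D,
#'   `enrichment_ratio` = own-bulk / other-bulk frequency), plus
#'   `positive_fraction`, the expected fraction of individuals in the
#'   positive bulk (7/16 dominant, 1/16 recessive).
#' @export
#' @examples
#' e <- bulk_allele_frequencies("dominant", "A")
#' e$positive$freq["B"] # 1/7
#' e$negative$freq["B"] # 1/3
bulk_allele_frequencies <- function(mode = c("dominant", "recessive"),
                                    causal_haplotype = "A") {
  mode <- match.arg(mode)
  stopifnot(causal_haplotype %in% c("A", "B", "C", "D"))
  g <- .ordered_f2()
  pos <- .carries(g, causal_haplotype, mode)
  haps <- c("A", "B", "C", "D")
  tally <- function(sub) {
    # each individual contributes its two homologs
    n <- vapply(haps, function(h) sum((sub$h1 == h) + (sub$h2 == h)),
                numeric(1))
    n / sum(n)
  }
  freq_pos <- tally(g[pos])
  freq_neg <- tally(g[!pos])
  mk <- function(bulk, freq, other) {
    structure(list(mode = mode, bulk = bulk, freq = freq,
                   enrichment_ratio = freq / other),
              class = "bulk_expectation")
  }
  list(positive = mk("positive", freq_pos, freq_neg),
       negative = mk("negative", freq_neg, freq_pos),
       positive_fraction = sum(g$prob[pos]))
}

#' @export
print.bulk_expectation <- function(x, ...) {
  cat(sprintf("%s bulk, %s model:\n", x$bulk, x$mode))
  print(round(x$freq, 4))
  invisible(x)
}

#' Which haplotypes are detectable in which bulk
#'
#' A haplotype's k-mers are flagged detectable in a bulk when the ratio of
#' its expected allele frequency in that bulk over the other bulk meets the
#' fold threshold (the enrichment reasoning is on the plain fold scale;
#' default 2.5-fold). Alleles private to one bulk (other-bulk frequency 0)
#' are always detectable there. Under dominance only the causal allele is
#' detectable (positive bulk); the non-causal alleles sit at 7/3 ~= 2.33 <
#' 2.5 and are flagged `below_threshold`. Under recessivity the causal
#' allele is detectable in the positive bulk (5-fold) and the other three
#' are exclusive to the negative bulk.
#'
#' @inheritParams bulk_allele_frequencies
#' @param fold_threshold minimum between-bulk frequency ratio (default 2.5).
#' @return `data.table` with columns `haplotype`, `ratio_pos_over_neg`,
#'   `flag` (`detectable_in_positive`, `detectable_in_negative`,
#'   `below_threshold`).
#' @export
detectability <- function(mode = c("dominant", "recessive"),
                          causal_haplotype = "A", fold_threshold = 2.5) {
  mode <- match.arg(mode)
  e <- bulk_allele_frequencies(mode, causal_haplotype)
  ratio <- e$positive$freq / e$negative$freq # may be Inf or 0
  flag <- rep("below_threshold", 4)
  flag[ratio > 1 & ratio >= fold_threshold] <- "detectable_in_positive"
  flag[ratio < 1 & 1 / ratio >= fold_threshold] <- "detectable_in_negative"
  data.table(haplotype = names(ratio), ratio_pos_over_neg = unname(ratio),
             flag = flag)
}

#' Presentation rounding of bulk expectations
#'
#' Rounds frequencies to whole percentages and reports the between-bulk
#' ratio of a non-causal (dominant) or causal (recessive) allele to one
#' decimal, computed from the rounded percentages — the convention used
#' when quoting "14% vs 33%, ~2.4x" for the dominant model.
#' @inheritParams bulk_allele_frequencies
#' @return list with `pct_positive`, `pct_negative`, `ratio` (all scalars,
#'   for the focal allele), and `focal` (`"non_causal"` or `"causal"`).
#' @export
format_expectation <- function(mode = c("dominant", "recessive"),
                               causal_haplotype = "A") {
  mode <- match.arg(mode)
  e <- bulk_allele_frequencies(mode, causal_haplotype)
  other <- setdiff(c("A", "B", "C", "D"), causal_haplotype)[1]
  focal <- if (mode == "dominant") other else causal_haplotype
  pp <- round(100 * e$positive$freq[[focal]])
  pn <- round(100 * e$negative$freq[[focal]])
  ratio <- round(max(pp, pn) / min(pp, pn), 1)
  list(pct_positive = pp, pct_negative = pn, ratio = ratio,
       focal = if (mode == "dominant") "non_causal" else "causal")
}
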