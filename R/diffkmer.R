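#' Configuration of the differential k-mer call
#'
#' @param alpha_adjusted Bonferroni-adjusted P-value cutoff; a k-mer must
#'   fall strictly below it (default 0.01).
#' @param min_abs_log2fc minimum absolute log2 fold change between the two
#'   bulks' normalized rates, strict (default 2.5).
#' @param pseudocount additive constant applied to both bulk counts before
#'   the test and the fold change, preventing zero rates (default 1).
#' @param pseudocount_fc_only if `TRUE`, the pseudocount enters the fold
#'   change but the test is run on raw counts.
#' @return a `test_config` list.
#' @export
test_config <- function(alpha_adjusted = 0.01, min_abs_log2fc = 2.5,
                        pseudocount = 1, pseudocount_fc_only = FALSE) {
  stopifnot(alpha_adjusted > 0, alpha_adjusted < 1,
            min_abs_log2fc >= 0, pseudocount >= 0)
  structure(list(alpha_adjusted = alpha_adjusted,
                 min_abs_log2fc = min_abs_log2fc,
                 pseudocount = pseudocount,
                 pseudocount_fc_only = pseudocount_fc_only),
            class = "test_config")
}

.check_rates <- function(K_A, K_B, N_A, N_B) {
  if (any(N_A <= 0) || any(N_B <= 0)) stop("bulk totals N_A, N_B must be > 0")
  if (any(K_A < 0) || any(K_B < 0)) stop("k-mer counts must be nonnegative")
}

#' Nested-Poisson log-likelihood-ratio test for one k-mer
#'
#' A k-mer seen `K_A` times among `N_A` total k-mer occurrences in bulk A
#' and `K_B` of `N_B` in bulk B is modeled as Poisson with per-bulk rates
#' `K_A/N_A` and `K_B/N_B`; the null constrains both bulks to the pooled
#' rate `(K_A+K_B)/(N_A+N_B)`. With a pseudocount added to both counts, the
#' statistic is the Wilks deviance
#' `G = 2 * [l(k_A; r_A N_A) + l(k_B; r_B N_B) - l(k_A; r_0 N_A) - l(k_B; r_0 N_B)]`
#' (`l` the Poisson log-probability), which is chi-square with 1 degree of
#' freedom under the null; `p` is its upper tail. Because the alternative
#' rates are the per-bulk maximum-likelihood estimates, `G >= 0` always,
#' with equality exactly when the normalized rates agree.
#'
#' All arguments are vectorized.
#'
#' @param K_A,K_B raw bulk counts (>= 0).
#' @param N_A,N_B total k-mer occurrences per bulk (> 0).
#' @param pseudocount additive constant (default 1).
#' @return list with vectors `G` and `p`.
#' @export
#' @examples
#' poisson_llr_test(50, 5, 1e6, 1e6)   # G ~= 40.7
#' poisson_llr_test(10, 10, 1e6, 1e6)  # G = 0, p = 1
poisson_llr_test <- function(K_A, K_B, N_A, N_B, pseudocount = 1) {
  .check_rates(K_A, K_B, N_A, N_B)
  a <- K_A + pseudocount
  b <- K_B + pseudocount
  # null means; alternative means are exactly a and b, so the linear parts
  # of the Poisson log-likelihoods cancel and only the log terms remain
  mu0_a <- (a + b) * N_A / (N_A + N_B)
  mu0_b <- (a + b) * N_B / (N_A + N_B)
  term <- function(k, mu0) {
    out <- k * log(k / mu0)
    out[k == 0] <- 0 # limit k*log(k) -> 0
    out
  }
  G <- 2 * (term(a, mu0_a) + term(b, mu0_b))
  G <- pmax(G, 0) # clamp float dust at the null
  list(G = G, p = pchisq(G, df = 1, lower.tail = FALSE))
}

#' Signed log2 fold change of normalized k-mer rates
#'
#' `log2(((K_A + pc)/N_A) / ((K_B + pc)/N_B))`; positive values mean
#' enrichment in bulk A. Antisymmetric under swapping the bulks.
#' @inheritParams poisson_llr_test
#' @return numeric vector.
#' @export
log2_fold_change <- function(K_A, K_B, N_A, N_B, pseudocount = 1) {
  .check_rates(K_A, K_B, N_A, N_B)
  log2(((K_A + pseudocount) / N_A) / ((K_B + pseudocount) / N_B))
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)` with `m = length(p_values)` (or an explicit
#' family size), the classical family-wise error control used for the
#' k-mer-scale testing burden.
#' @param p_values raw P-values in `[0, 1]`.
#' @param m family size; defaults to `length(p_values)`.
#' @return adjusted P-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("P-values must lie in [0, 1]")
  pmin(1, m * p_values)
}

#' Call differentially enriched k-mers between two bulks
#'
#' Runs the nested-Poisson LLR test on every k-mer of a merged bulk table,
#' Bonferroni-corrects over the `m` k-mers actually tested (the rows of the
#' merged table), computes the signed log2 fold change, and labels a k-mer
#' enriched in bulk A when `p_adj < alpha_adjusted` and
#' `log2fc > min_abs_log2fc` (symmetrically for bulk B; both inequalities
#' strict). The enriched sets are disjoint by construction.
#'
#' @param merged a `merged_bulk_table` from [join_bulks()] (or a
#'   `data.table` with `kmer`, `K_A`, `K_B` plus `N_A`/`N_B` attributes or
#'   arguments).
#' @param cfg a [test_config()].
#' @param N_A,N_B bulk totals; default to the table attributes.
#' @return list with `records` (a `data.table`: `kmer K_A K_B G p p_adj
#'   log2fc enriched_in`), `enriched_in_A` and `enriched_in_B` (character
#'   vectors of k-mers).
#' @export
call_differential <- function(merged, cfg = test_config(),
                              N_A = attr(merged, "N_A"),
                              N_B = attr(merged, "N_B")) {
  if (!nrow(merged)) stop("empty merged bulk table")
  if (is.null(N_A) || is.null(N_B)) stop("bulk totals N_A/N_B are required")
  pc_test <- if (isTRUE(cfg$pseudocount_fc_only)) 0 else cfg$pseudocount
  res <- poisson_llr_test(merged$K_A, merged$K_B, N_A, N_B, pc_test)
  lfc <- log2_fold_change(merged$K_A, merged$K_B, N_A, N_B, cfg$pseudocount)
  p_adj <- bonferroni(res$p, m = nrow(merged))
  enriched <- rep("none", nrow(merged))
  sig <- p_adj < cfg$alpha_adjusted & abs(lfc) > cfg$min_abs_log2fc
  enriched[sig & lfc > 0] <- "bulk_A"
  enriched[sig & lfc < 0] <- "bulk_B"
  records <- data.table(kmer = merged$kmer, K_A = merged$K_A,
                        K_B = merged$K_B, G = res$G, p = res$p,
                        p_adj = p_adj, log2fc = lfc, enriched_in = enriched)
  list(records = records,
       enriched_in_A = records[enriched_in == "bulk_A", kmer],
       enriched_in_B = records[enriched_in == "bulk_B", kmer])
}
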