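# Independent brute-force oracles and shared fixtures.

naive_revcomp <- function(s) {
  vapply(strsplit(chartr("ACGT", "TGCA", s), ""), function(x)
    paste(rev(x), collapse = ""), character(1))
}

naive_canonical <- function(kmers) pmin(kmers, naive_revcomp(kmers))

# dictionary-of-substrings counter
naive_count <- function(reads, k, canonical = TRUE) {
  kms <- unlist(lapply(reads, function(r) {
    n <- nchar(r)
    if (n < k) return(character(0))
    substring(r, 1:(n - k + 1), k:n)
  }))
  kms <- kms[!grepl("[^ACGT]", kms)]
  if (canonical) kms <- naive_canonical(kms)
  tab <- table(kms)
  data.table::data.table(kmer = names(tab), count = as.numeric(tab),
                         key = "kmer")
}

# direct Poisson log-pmf evaluation of the nested-model deviance
oracle_G <- function(K_A, K_B, N_A, N_B, pseudocount = 1) {
  a <- K_A + pseudocount
  b <- K_B + pseudocount
  lam_a <- a / N_A
  lam_b <- b / N_B
  lam_0 <- (a + b) / (N_A + N_B)
  2 * (dpois(a, lam_a * N_A, log = TRUE) + dpois(b, lam_b * N_B, log = TRUE) -
         dpois(a, lam_0 * N_A, log = TRUE) - dpois(b, lam_0 * N_B, log = TRUE))
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# distinct k-mer strings (forward only) for building synthetic tables
int_kmers <- function(n, k = 7) {
  stopifnot(4^k >= n)
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n) - 1L, function(i) {
    out <- character(k)
    for (j in k:1) { out[j] <- bases[i %% 4L + 1L]; i <- i %/% 4L }
    paste(out, collapse = "")
  }, character(1))
}

# one moderately sized simulated study shared by the module tests that
# need reads (built once per test run)
.fixtures <- new.env()
small_study <- function() {
  if (is.null(.fixtures$sc)) {
    .fixtures$sc <- bsa_scenario(
      seed = 42, chrom_lengths = c(chr01 = 3e5, chr02 = 3e5),
      n_f1_pool = 40, n_f1_seq = 6, n_f2 = 32, coverage = 4,
      parent_coverage = 15, causal_pos = 1.95e5)
    .fixtures$run <- run_bsa(.fixtures$sc, bin_size = 3e4)
  }
  .fixtures
}
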