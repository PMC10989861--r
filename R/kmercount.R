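#' k-mer count tables
#'
#' A `kmer_table` holds canonical k-mer counts for one sample or one
#' phenotypic bulk: a `data.table` with columns `kmer` (character, all of
#' length `k`) and `count` (numeric, all >= 1 after counting), plus the
#' counting parameters as attributes. Canonical counting collapses a k-mer
#' and its reverse complement onto the lexicographically smaller of the two,
#' so counts are strand-independent; `k` must be odd for canonical counting
#' so that no k-mer equals its own reverse complement.
#'
#' @param entries `data.table` (or coercible) with columns `kmer`, `count`.
#' @param k k-mer length, an integer in `[1, 31]` (2-bit packable).
#' @param canonical logical; were counts collapsed over strands?
#' @param owner sample or bulk identifier.
#' @return A `kmer_table` object.
#' @export
kmer_table <- function(entries, k, canonical = TRUE, owner = NA_character_) {
  entries <- as.data.table(entries)
  if (!all(c("kmer", "count") %in% names(entries)))
    stop("entries must have columns 'kmer' and 'count'")
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 31L) stop("k must be an integer in [1, 31]")
  if (canonical && k %% 2L == 0L)
    stop("k must be odd for canonical counting (even k-mers can be their own reverse complement)")
  if (nrow(entries) && any(nchar(entries$kmer) != k))
    stop("all k-mers must have length k = ", k)
  entries[, count := as.numeric(count)]
  structure(
    list(owner = owner, k = k, canonical = canonical,
         entries = entries[order(kmer)]),
    class = "kmer_table")
}

# trusted fast path: entries already sorted and validated (compiled counters)
.kmer_table_sorted <- function(entries, k, canonical, owner) {
  structure(list(owner = owner, k = as.integer(k), canonical = canonical,
                 entries = entries),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("kmer_table [%s]: %s distinct %d-mers, %s total occurrences%s\n",
              x$owner, format(nrow(x$entries), big.mark = ","), x$k,
              format(kt_total(x), big.mark = ","),
              if (x$canonical) " (canonical)" else ""))
  if (nrow(x$entries)) print(head(x$entries, 5))
  invisible(x)
}

#' Total k-mer occurrences in a table
#'
#' Sum of counts (total k-mer instances, not distinct k-mers). This is the
#' `N` entering the per-bulk Poisson rates of [poisson_llr_test()].
#' @param table a `kmer_table`.
#' @return numeric scalar.
#' @export
kt_total <- function(table) {
  stopifnot(inherits(table, "kmer_table"))
  sum(table$entries$count)
}

.check_same_params <- function(a, b) {
  if (a$k != b$k) stop("k-mer tables have different k (", a$k, " vs ", b$k, ")")
  if (a$canonical != b$canonical)
    stop("k-mer tables have different canonical settings")
}

#' Canonicalize k-mer sequences
#'
#' Returns, for each input sequence, the lexicographic minimum of the
#' sequence and its reverse complement. Sequences containing non-ACGT
#' characters return `NA`.
#' @param kmers character vector of equal-length DNA strings (length <= 31).
#' @return character vector.
#' @export
#' @examples
#' canonicalize(c("CGG", "ACG", "GGA")) # "CCG" "ACG" "GGA"
canonicalize <- function(kmers) .cpp_canonicalize(as.character(kmers))

#' Count canonical k-mers in sequencing reads
#'
#' Every length-`k` window of every read contributes exactly one count to
#' its (canonical) k-mer. Windows containing non-ACGT characters are
#' skipped; reads shorter than `k` are skipped and tallied in the
#' `n_too_short` attribute of the result.
#'
#' @param reads a character vector of read sequences, a
#'   [Biostrings::DNAStringSet], or the path of a FASTQ file (optionally
#'   gzipped).
#' @param k k-mer length (default 31).
#' @param canonical collapse each k-mer with its reverse complement
#'   (default `TRUE`).
#' @param owner sample identifier stored on the table.
#' @return A [kmer_table].
#' @export
#' @examples
#' count_kmers("ACGGA", k = 3)$entries  # ACG:1, CCG:1, GGA:1
count_kmers <- function(reads, k = 31, canonical = TRUE,
                        owner = NA_character_) {
  k <- as.integer(k)
  if (canonical && k %% 2L == 0L)
    stop("k must be odd for canonical counting")
  reads <- .as_read_vector(reads)
  res <- .cpp_count_kmers(reads, k, canonical)
  tab <- .kmer_table_sorted(data.table(kmer = res$kmer, count = res$count),
                            k = k, canonical = canonical, owner = owner)
  attr(tab, "n_too_short") <- res$n_too_short
  tab
}

# Accept character vectors, DNAStringSet, or FASTQ file paths. A short
# character vector whose elements all carry FASTQ extensions is treated as
# paths; anything else is sequence data.
.as_read_vector <- function(reads) {
  if (methods::is(reads, "DNAStringSet"))
    return(unname(as.character(reads)))
  if (!is.character(reads)) stop("reads must be sequences or FASTQ paths")
  if (length(reads) >= 1 && length(reads) <= 1000 &&
      all(grepl("\\.(fq|fastq)(\\.gz)?$", reads)) && all(file.exists(reads))) {
    reads <- unlist(lapply(reads, function(f) {
      as.character(Biostrings::readDNAStringSet(f, format = "fastq"))
    }), use.names = FALSE)
  }
  unname(reads)
}

#' Remove low-count k-mers from a per-sample table
#'
#' k-mers seen only once in a sample are overwhelmingly sequencing errors;
#' the default drops exactly the singletons.
#' @param table a [kmer_table].
#' @param min_count minimum count to keep (default 2).
#' @return the filtered [kmer_table].
#' @export
filter_singletons <- function(table, min_count = 2) {
  stopifnot(inherits(table, "kmer_table"), min_count >= 1)
  table$entries <- table$entries[count >= min_count]
  table
}

#' Aggregate per-sample k-mer tables into one bulk table
#'
#' Counts are summed per k-mer over all member samples; the result is
#' invariant to the ordering of the inputs.
#' @param tables list of [kmer_table]s sharing `k` and `canonical`.
#' @param bulk_id identifier for the combined bulk.
#' @return a [kmer_table] owned by `bulk_id`.
#' @export
merge_bulk <- function(tables, bulk_id = "bulk") {
  stopifnot(is.list(tables), length(tables) >= 1,
            all(vapply(tables, inherits, TRUE, "kmer_table")))
  for (t in tables[-1]) .check_same_params(tables[[1]], t)
  merged <- rbindlist(lapply(tables, `[[`, "entries"))
  merged <- merged[, .(count = sum(count)), by = kmer]
  kmer_table(merged, k = tables[[1]]$k, canonical = tables[[1]]$canonical,
             owner = bulk_id)
}

#' Fused per-sample counting and bulk aggregation
#'
#' Equivalent to `merge_bulk(lapply(samples, function(r)
#' filter_singletons(count_kmers(r, k), min_sample_count)))` but performed
#' in one compiled pass, which matters at tens of millions of read windows.
#' The equivalence is asserted in the test suite.
#'
#' @param reads_by_sample list with one character vector (or FASTQ path /
#'   `DNAStringSet`) of reads per sample.
#' @param k,canonical as in [count_kmers()].
#' @param min_sample_count per-sample minimum count applied before
#'   aggregation (default 2 = singleton removal).
#' @param bulk_id identifier for the bulk.
#' @return a [kmer_table] owned by `bulk_id`.
#' @export
count_bulk_kmers <- function(reads_by_sample, k = 31, canonical = TRUE,
                             min_sample_count = 2, bulk_id = "bulk") {
  k <- as.integer(k)
  if (canonical && k %% 2L == 0L)
    stop("k must be odd for canonical counting")
  reads_by_sample <- lapply(reads_by_sample, .as_read_vector)
  res <- .cpp_count_bulk(reads_by_sample, k, canonical, min_sample_count)
  tab <- .kmer_table_sorted(data.table(kmer = res$kmer, count = res$count),
                            k = k, canonical = canonical, owner = bulk_id)
  attr(tab, "n_too_short") <- res$n_too_short
  tab
}

#' Abundance-histogram threshold for a bulk
#'
#' Bulk k-mer abundance histograms are bimodal: an error peak at low counts
#' and one or more genomic peaks at the bulk's modal coverage. The
#' threshold is the count at the first interior local minimum (the valley
#' between the two), or `default_min` when the histogram has no interior
#' minimum (e.g. monotone decreasing); it is never below 2.
#'
#' @param table a [kmer_table] (typically a merged bulk).
#' @param default_min fallback threshold (default 5).
#' @return integer threshold.
#' @export
histogram_threshold <- function(table, default_min = 5) {
  stopifnot(inherits(table, "kmer_table"))
  if (!nrow(table$entries)) stop("empty k-mer table has no abundance histogram")
  # histogram of abundances, capped at 1000: the error/genomic valley sits
  # at low counts and capping bounds the scan
  h <- tabulate(pmin(as.integer(table$entries$count), 1000L))
  # first interior strict valley: h falls then rises
  if (length(h) >= 3) {
    for (i in 2:(length(h) - 1)) {
      if (h[i] <= h[i - 1] && h[i] < h[i + 1]) return(max(2L, i))
    }
  }
  max(2L, as.integer(default_min))
}

#' Apply a bulk-level abundance threshold
#'
#' Drops k-mers seen fewer than `min_count` times in the bulk (the study
#' design uses 5).
#' @param table a [kmer_table].
#' @param min_count minimum bulk count to keep.
#' @return the filtered [kmer_table].
#' @export
apply_bulk_threshold <- function(table, min_count = 5) {
  stopifnot(inherits(table, "kmer_table"))
  table$entries <- table$entries[count >= min_count]
  table
}

#' Join two bulk k-mer tables into a single count table
#'
#' Outer join on the k-mer: every k-mer present in either bulk gets a row
#' with its count in each (0 where absent). The totals `N_A`/`N_B` are the
#' sums of the input tables' counts (total k-mer instances) and are stored
#' as attributes; they become the rate denominators of the differential
#' test.
#'
#' @param bulk_a,bulk_b [kmer_table]s for the two bulks (same `k`,
#'   `canonical`).
#' @return a `merged_bulk_table`: a `data.table` with columns
#'   `kmer`, `K_A`, `K_B` and attributes `N_A`, `N_B`, `bulk_a_id`,
#'   `bulk_b_id`, `k`, `canonical`.
#' @export
join_bulks <- function(bulk_a, bulk_b) {
  stopifnot(inherits(bulk_a, "kmer_table"), inherits(bulk_b, "kmer_table"))
  .check_same_params(bulk_a, bulk_b)
  res <- .cpp_join_counts(bulk_a$entries$kmer, bulk_a$entries$count,
                          bulk_b$entries$kmer, bulk_b$entries$count,
                          bulk_a$k)
  merged <- data.table(kmer = res$kmer, K_A = res$K_A, K_B = res$K_B)
  setattr(merged, "N_A", kt_total(bulk_a))
  setattr(merged, "N_B", kt_total(bulk_b))
  setattr(merged, "bulk_a_id", bulk_a$owner)
  setattr(merged, "bulk_b_id", bulk_b$owner)
  setattr(merged, "k", bulk_a$k)
  setattr(merged, "canonical", bulk_a$canonical)
  setattr(merged, "class", c("merged_bulk_table", class(merged)))
  merged[]
}

#' Fused counting, thresholding and joining of two bulks
#'
#' Equivalent to running [count_bulk_kmers()] on each bulk,
#' [apply_bulk_threshold()] on each result, and [join_bulks()] on the pair,
#' but in one compiled pass that materializes only the final merged table
#' (the per-bulk tables at full scale hold millions of entries each). The
#' equivalence is asserted in the test suite.
#'
#' @param reads_a,reads_b lists of per-sample read vectors (or FASTQ paths)
#'   for the two bulks.
#' @inheritParams count_bulk_kmers
#' @param min_bulk_count bulk abundance threshold applied to each bulk
#'   before the join (default 5).
#' @param bulk_a_id,bulk_b_id bulk identifiers.
#' @return a `merged_bulk_table` as from [join_bulks()].
#' @export
count_and_join_bulks <- function(reads_a, reads_b, k = 31, canonical = TRUE,
                                 min_sample_count = 2, min_bulk_count = 5,
                                 bulk_a_id = "bulk_A", bulk_b_id = "bulk_B") {
  k <- as.integer(k)
  if (canonical && k %% 2L == 0L)
    stop("k must be odd for canonical counting")
  reads_a <- lapply(reads_a, .as_read_vector)
  reads_b <- lapply(reads_b, .as_read_vector)
  res <- .cpp_bulk_join(reads_a, reads_b, k, canonical,
                        min_sample_count, min_bulk_count)
  merged <- data.table(kmer = res$kmer, K_A = res$K_A, K_B = res$K_B)
  setattr(merged, "N_A", res$N_A)
  setattr(merged, "N_B", res$N_B)
  setattr(merged, "bulk_a_id", bulk_a_id)
  setattr(merged, "bulk_b_id", bulk_b_id)
  setattr(merged, "k", k)
  setattr(merged, "canonical", canonical)
  setattr(merged, "class", c("merged_bulk_table", class(merged)))
  merged[]
}

#' Count specific k-mers in a read set
#'
#' Returns a [kmer_table] restricted to the queried k-mers (zero-count
#' queries are dropped, like any absent k-mer), without building the full
#' count table — the practical way to probe a deep parental read set for
#' just the enriched k-mers.
#'
#' @param reads character vector of reads, FASTQ path(s) or `DNAStringSet`.
#' @param kmers query k-mers (length `k` each; canonicalized consistently
#'   with `canonical`).
#' @inheritParams count_kmers
#' @param min_count minimum count to keep in the returned table
#'   (default 1).
#' @return a [kmer_table] whose entries are the queried k-mers found at
#'   least `min_count` times.
#' @export
count_kmer_subset <- function(reads, kmers, k = 31, canonical = TRUE,
                              min_count = 1, owner = NA_character_) {
  k <- as.integer(k)
  kmers <- unique(as.character(kmers))
  if (canonical) kmers <- canonicalize(kmers)
  reads <- .as_read_vector(reads)
  cnt <- .cpp_count_lookup(list(reads), kmers, k, canonical)
  keep <- cnt >= min_count
  kmer_table(data.table(kmer = kmers[keep], count = cnt[keep]),
             k = k, canonical = canonical, owner = owner)
}

#' Write / read a k-mer count table as TSV
#'
#' Plain two-column `kmer<TAB>count` text, lexicographically sorted.
#' @param table a [kmer_table].
#' @param file path to write to / read from.
#' @param k,canonical,owner counting parameters to attach on read.
#' @return `write_kmer_table` returns `file` invisibly; `read_kmer_table`
#'   returns a [kmer_table].
#' @export
write_kmer_table <- function(table, file) {
  stopifnot(inherits(table, "kmer_table"))
  fwrite(table$entries[order(kmer)], file, sep = "\t")
  invisible(file)
}

#' @rdname write_kmer_table
#' @export
read_kmer_table <- function(file, k = NULL, canonical = TRUE,
                            owner = NA_character_) {
  entries <- fread(file, sep = "\t", colClasses = list(character = "kmer"))
  if (is.null(k)) k <- if (nrow(entries)) nchar(entries$kmer[1]) else 31L
  kmer_table(entries, k = k, canonical = canonical, owner = owner)
}
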