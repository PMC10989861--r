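#' Parental origin of enriched k-mers
#'
#' A significantly enriched k-mer is parent-specific when it is present in
#' one parent's k-mer table (count at or above `presence_min`) and
#' completely absent (raw count 0) from the other's. The four labels
#' partition the input:
#' * `p1_specific`: `count_p1 >= presence_min` and `count_p2 == 0`;
#' * `p2_specific`: symmetric;
#' * `absent`: below `presence_min` in both (possible F2-novel or error
#'   k-mers);
#' * `shared`: everything else (fails "completely absent").
#'
#' @param enriched character vector of enriched (canonical) k-mers.
#' @param p1_table,p2_table parental [kmer_table]s built with the same `k`
#'   and `canonical` settings as the bulks.
#' @param presence_min minimum parental count to count as present
#'   (default 2, mirroring the per-sample singleton filter).
#' @return `data.table` with columns `kmer`, `count_p1`, `count_p2`,
#'   `origin`.
#' @export
classify_origin <- function(enriched, p1_table, p2_table, presence_min = 2) {
  stopifnot(inherits(p1_table, "kmer_table"), inherits(p2_table, "kmer_table"))
  .check_same_params(p1_table, p2_table)
  if (length(enriched) && any(nchar(enriched) != p1_table$k))
    stop("enriched k-mers do not match the parental tables' k")
  calls <- data.table(kmer = enriched)
  lookup <- function(tab) {
    m <- tab$entries[calls, on = "kmer"]
    fifelse(is.na(m$count), 0, m$count)
  }
  calls[, count_p1 := lookup(p1_table)]
  calls[, count_p2 := lookup(p2_table)]
  calls[, origin := fcase(
    count_p1 < presence_min & count_p2 < presence_min, "absent",
    count_p1 >= presence_min & count_p2 == 0, "p1_specific",
    count_p2 >= presence_min & count_p1 == 0, "p2_specific",
    default = "shared")]
  calls[]
}

#' Contingency summary of origin calls by enriched bulk
#'
#' Cross-tabulates origin labels against the bulk each k-mer was enriched
#' in — the layout used to read off the bulk asymmetry (under a dominant
#' causal allele, the positive bulk carries the large excess of
#' causal-parent-specific k-mers).
#'
#' @param calls output of [classify_origin()].
#' @param enriched_in character vector parallel to `calls` giving each
#'   k-mer's enriched bulk (e.g. `"bulk_A"`/`"bulk_B"`).
#' @return `data.table` with one row per `(bulk, origin)` cell and column
#'   `n`; cells sum to the number of enriched k-mers per bulk.
#' @export
origin_summary <- function(calls, enriched_in) {
  if (nrow(calls) == 0)
    return(data.table(bulk = character(), origin = character(),
                      n = integer()))
  stopifnot(length(enriched_in) == nrow(calls))
  dt <- data.table(bulk = enriched_in, origin = calls$origin)
  cells <- CJ(bulk = unique(enriched_in),
              origin = c("p1_specific", "p2_specific", "shared", "absent"))
  dt <- dt[, .(n = .N), by = .(bulk, origin)]
  out <- dt[cells, on = c("bulk", "origin")]
  out[is.na(n), n := 0L]
  out[order(bulk, origin)]
}
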