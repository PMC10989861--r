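#' Bin configuration for the dosage tracks
#'
#' @param bin_size bin width in bp (default 200 kb).
#' @param min_mapq minimum mapping quality for an alignment to count
#'   (default 40).
#' @param ratio_pseudocount additive constant for the per-bin ratio of
#'   normalized signals; `NULL` (default) auto-scales to `1e-6` of the
#'   genome-wide mean normalized signal.
#' @return a `bin_config` list.
#' @export
bin_config <- function(bin_size = 200000, min_mapq = 40,
                       ratio_pseudocount = NULL) {
  stopifnot(bin_size > 0, min_mapq >= 0)
  structure(list(bin_size = as.integer(bin_size),
                 min_mapq = as.integer(min_mapq),
                 ratio_pseudocount = ratio_pseudocount),
            class = "bin_config")
}

#' Backtrack enriched k-mers to their source reads
#'
#' Selects every read containing at least one significant k-mer in any of
#' its length-`k` windows, matching canonically (a read carrying the
#' reverse complement of a significant k-mer is selected). Each read is
#' reported at most once.
#'
#' @param reads character vector of read sequences (or FASTQ path /
#'   `DNAStringSet`).
#' @param sig_kmers character vector of significant k-mers (canonicalized
#'   internally when `canonical`).
#' @param k k-mer length.
#' @param canonical match canonically (default `TRUE`).
#' @return logical vector: which reads were selected.
#' @export
backtrack_reads <- function(reads, sig_kmers, k = 31, canonical = TRUE) {
  reads <- .as_read_vector(reads)
  if (!length(sig_kmers)) {
    warning("empty significant k-mer set: no reads selected")
    return(rep(FALSE, length(reads)))
  }
  if (canonical) sig_kmers <- canonicalize(sig_kmers)
  .cpp_select_reads(reads, sig_kmers, as.integer(k), canonical)
}

# normalize alignments to a data.table(chrom, pos, mapq, flag)
.as_alignments <- function(alignments) {
  if (is.character(alignments) && length(alignments) == 1 &&
      file.exists(alignments)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("Rsamtools is required to read SAM/BAM files")
    path <- alignments
    if (grepl("\\.sam$", path)) {
      path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                               indexDestination = FALSE)
    }
    hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
    if (!length(hdr)) stop("SAM/BAM header with @SQ lines is required")
    b <- Rsamtools::scanBam(
      path, param = Rsamtools::ScanBamParam(
        what = c("rname", "pos", "mapq", "flag")))[[1]]
    aln <- data.table(chrom = as.character(b$rname), pos = b$pos,
                      mapq = b$mapq, flag = b$flag)
    attr(aln, "chrom_lengths") <- hdr
    return(aln)
  }
  aln <- as.data.table(alignments)
  need <- c("chrom", "pos")
  if (!all(need %in% names(aln)))
    stop("alignments need at least columns 'chrom' and 'pos'")
  if (!"mapq" %in% names(aln)) aln[, mapq := 60L]
  if (!"flag" %in% names(aln)) aln[, flag := 0L]
  aln
}

#' Count alignments per consecutive, nonoverlapping genomic bin
#'
#' Each primary, mapped alignment with `MAPQ >= min_mapq` adds one to the
#' bin containing its leftmost aligned base (bins are half-open
#' `[start, start + bin_size)`, 0-based internally). Unmapped, secondary
#' (flag 0x100) and supplementary (flag 0x800) records are ignored. The
#' returned grid tiles every chromosome completely, so empty bins are
#' explicit zeroes.
#'
#' @param alignments a SAM/BAM path, or a `data.frame`/`data.table` with
#'   columns `chrom`, `pos` (1-based leftmost), and optionally `mapq`,
#'   `flag`.
#' @param cfg a [bin_config()].
#' @param chrom_lengths named vector of chromosome lengths; required for
#'   `data.frame` input (taken from the header for SAM/BAM).
#' @return `data.table` with columns `chrom`, `bin_start` (0-based),
#'   `count`.
#' @export
bin_reads <- function(alignments, cfg = bin_config(), chrom_lengths = NULL) {
  aln <- .as_alignments(alignments)
  if (is.null(chrom_lengths)) chrom_lengths <- attr(aln, "chrom_lengths")
  if (is.null(chrom_lengths))
    stop("chromosome lengths are required (SAM header or chrom_lengths)")
  keep <- !is.na(aln$pos) & !is.na(aln$chrom) &
    aln$mapq >= cfg$min_mapq &
    bitwAnd(aln$flag, 0x4L) == 0L &   # mapped
    bitwAnd(aln$flag, 0x100L) == 0L & # primary
    bitwAnd(aln$flag, 0x800L) == 0L   # not supplementary
  aln <- aln[keep]
  if (nrow(aln) && any(!aln$chrom %in% names(chrom_lengths)))
    stop("alignment on a chromosome absent from the header")
  if (nrow(aln) && any(aln$pos > chrom_lengths[aln$chrom] | aln$pos < 1))
    stop("alignment position beyond the stated chromosome length")
  grid <- rbindlist(lapply(names(chrom_lengths), function(ch) {
    data.table(chrom = ch,
               bin_start = seq(0L, as.integer(chrom_lengths[[ch]]) - 1L,
                               by = cfg$bin_size))
  }))
  if (!nrow(aln)) { grid[, count := 0L]; return(grid[]) }
  aln[, bin_start := (as.integer(pos) - 1L) %/% cfg$bin_size * cfg$bin_size]
  cnt <- aln[, .(count = .N), by = .(chrom, bin_start)]
  out <- cnt[grid, on = c("chrom", "bin_start")]
  out[is.na(count), count := 0L]
  out[order(chrom, bin_start)]
}

#' Per-bin normalized signal and bulk ratio
#'
#' For each bulk, the per-bin signal (reads containing enriched k-mers) is
#' normalized to the total reads of the same bulk in the same bin
#' (`norm = sig / total`; 0 where the bin has no reads). The track's
#' `ratio` column is `(norm_A + eps) / (norm_B + eps)` with a small
#' pseudocount so empty bins sit at a neutral 1.
#'
#' @param sig_a,sig_b per-bin counts of enriched-k-mer reads per bulk
#'   (from [bin_reads()]).
#' @param total_a,total_b per-bin counts of all reads per bulk, on the same
#'   bin grid.
#' @param cfg a [bin_config()]; its `ratio_pseudocount` (or the auto
#'   scale) sets `eps`.
#' @return a `bin_track` `data.table`: `chrom, bin_start, sig_A, total_A,
#'   norm_A, sig_B, total_B, norm_B, ratio`.
#' @export
normalize_and_ratio <- function(sig_a, total_a, sig_b, total_b,
                                cfg = bin_config()) {
  key <- c("chrom", "bin_start")
  same_grid <- function(x, y) identical(x[, ..key][order(chrom, bin_start)],
                                        y[, ..key][order(chrom, bin_start)])
  if (!same_grid(sig_a, total_a) || !same_grid(sig_a, sig_b) ||
      !same_grid(sig_a, total_b))
    stop("bin grids do not match across the four inputs")
  track <- copy(sig_a)[order(chrom, bin_start)]
  setnames(track, "count", "sig_A")
  track[, total_A := total_a[order(chrom, bin_start), count]]
  track[, sig_B := sig_b[order(chrom, bin_start), count]]
  track[, total_B := total_b[order(chrom, bin_start), count]]
  track[, norm_A := fifelse(total_A > 0, sig_A / total_A, 0)]
  track[, norm_B := fifelse(total_B > 0, sig_B / total_B, 0)]
  eps <- cfg$ratio_pseudocount
  if (is.null(eps)) {
    eps <- 1e-6 * mean(c(track$norm_A, track$norm_B))
    if (!is.finite(eps) || eps <= 0) eps <- 1e-12
  }
  track[, ratio := (norm_A + eps) / (norm_B + eps)]
  setattr(track, "ratio_pseudocount", eps)
  setattr(track, "class", c("bin_track", class(track)))
  track[]
}

#' Call the peak of a bulk-ratio track
#'
#' Seeds at the maximum-ratio bin (ties broken toward the lowest
#' coordinate on the first chromosome in order) and extends in both
#' directions while the bin ratio stays at or above `frac` of the seed
#' ratio; reports the merged interval and its mean ratio. A flat track
#' (max equals min) yields no peak.
#'
#' @param track a `bin_track` from [normalize_and_ratio()] (needs
#'   `chrom`, `bin_start`, `ratio`).
#' @param frac extension threshold as a fraction of the seed ratio
#'   (default 0.5).
#' @param bin_size bin width; inferred from the grid when `NULL`.
#' @return `data.table` with columns `chrom, start, end, score` (1-based
#'   inclusive interval; score = mean ratio), or no rows for a flat track.
#' @export
call_peak <- function(track, frac = 0.5, bin_size = NULL) {
  if (!nrow(track)) stop("empty track")
  if (is.null(bin_size)) {
    starts <- sort(unique(track$bin_start))
    bin_size <- if (length(starts) > 1) min(diff(starts)) else starts + 1L
  }
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), score = numeric())
  if (max(track$ratio) == min(track$ratio)) return(empty)
  tr <- track[order(chrom, bin_start)]
  seed <- tr[which.max(ratio)] # which.max: first index = lowest coordinate
  ch <- tr[chrom == seed$chrom]
  i0 <- which(ch$bin_start == seed$bin_start)
  thresh <- frac * seed$ratio
  lo <- i0
  while (lo > 1 && ch$ratio[lo - 1] >= thresh) lo <- lo - 1
  hi <- i0
  while (hi < nrow(ch) && ch$ratio[hi + 1] >= thresh) hi <- hi + 1
  data.table(chrom = seed$chrom, start = ch$bin_start[lo] + 1L,
             end = as.integer(ch$bin_start[hi] + bin_size),
             score = mean(ch$ratio[lo:hi]))
}

#' Write a bin track as bedGraph-style TSV
#' @param track a `bin_track`.
#' @param file output path.
#' @param bin_size bin width used for the `end` column; inferred when
#'   `NULL`.
#' @return `file`, invisibly.
#' @export
write_bin_track <- function(track, file, bin_size = NULL) {
  if (is.null(bin_size)) {
    starts <- sort(unique(track$bin_start))
    bin_size <- if (length(starts) > 1) min(diff(starts)) else starts + 1L
  }
  out <- copy(track)
  out[, `:=`(start = bin_start, end = bin_start + bin_size)]
  out[, bin_start := NULL]
  setcolorder(out, c("chrom", "start", "end"))
  fwrite(out, file, sep = "\t")
  invisible(file)
}
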