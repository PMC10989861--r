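#' Simulate a four-haplotype parental genome
#'
#' Builds the genomic truth for a cross between two heterozygous diploid
#' parents: a random reference backbone per chromosome, SNP positions at a
#' given density, and per-haplotype alleles. Parent 1 carries haplotypes
#' A/B, parent 2 carries C/D. At every SNP each haplotype independently
#' carries the reference or a single alternate base (probability 1/2 each),
#' conditioned on at least two distinct bases across the four haplotypes,
#' so heterozygous-in-one-parent sites, homozygous-different sites and
#' haplotype-private alleles all arise at their natural frequencies.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param snp_density expected SNPs per bp (default 1/500, so that 31-mers
#'   overlapping a SNP are common).
#' @param seed integer seed; identical seeds give identical genomes.
#' @return a `haplotype_set`: list with `chrom_lengths`, `reference`
#'   (named character vector of backbone sequences) and `snp` (a
#'   `data.table`: `chrom`, `pos` (1-based), `ref`, `alt`, and allele
#'   columns `A`, `B`, `C`, `D`).
#' @export
sim_haplotypes <- function(chrom_lengths = c(chr01 = 1e6, chr02 = 1e6),
                           snp_density = 1 / 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- sprintf("chr%02d", seq_along(chrom_lengths))
  bases <- c("A", "C", "G", "T")
  reference <- vapply(chrom_lengths, function(len) {
    paste(sample(bases, len, replace = TRUE), collapse = "")
  }, character(1))
  snp <- rbindlist(lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    n <- round(len * snp_density)
    if (n == 0) return(NULL)
    pos <- sort(sample.int(len, n))
    ref <- strsplit(reference[[ch]], "")[[1]][pos]
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    # each haplotype ref/alt with p = 1/2, conditioned on polymorphism
    carry <- matrix(sample(c(TRUE, FALSE), 4 * n, replace = TRUE), nrow = n)
    bad <- which(rowSums(carry) %in% c(0L, 4L))
    while (length(bad)) {
      carry[bad, ] <- sample(c(TRUE, FALSE), 4 * length(bad), replace = TRUE)
      bad <- bad[rowSums(carry[bad, , drop = FALSE]) %in% c(0L, 4L)]
    }
    al <- function(j) ifelse(carry[, j], alt, ref)
    data.table(chrom = ch, pos = pos, ref = ref, alt = alt,
               A = al(1), B = al(2), C = al(3), D = al(4))
  }))
  out <- structure(list(chrom_lengths = chrom_lengths,
                        reference = reference, snp = snp),
                   class = "haplotype_set")
  # cache the four haplotype sequences: every read-simulation call needs
  # them and rebuilding costs seconds at megabase scale
  out$seqs <- hap_sequences(out)
  out
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d chromosome(s), %s bp, %s SNPs\n",
              length(x$chrom_lengths),
              format(sum(x$chrom_lengths), big.mark = ","),
              format(nrow(x$snp), big.mark = ",")))
  invisible(x)
}

#' Full sequences of the four parental haplotypes
#'
#' The reference backbone with each haplotype's SNP alleles substituted.
#' @param haps a `haplotype_set`.
#' @return nested list: `[[chrom]][[haplotype]]` character sequence.
#' @export
hap_sequences <- function(haps) {
  stopifnot(inherits(haps, "haplotype_set"))
  if (!is.null(haps$seqs)) return(haps$seqs)
  out <- list()
  for (ch in names(haps$chrom_lengths)) {
    chars <- strsplit(haps$reference[[ch]], "")[[1]]
    s <- haps$snp[chrom == ch]
    out[[ch]] <- lapply(setNames(nm = c("A", "B", "C", "D")), function(h) {
      v <- chars
      if (nrow(s)) v[s$pos] <- s[[h]]
      paste(v, collapse = "")
    })
  }
  out
}

#' Specify a causal locus
#'
#' @param chrom chromosome id.
#' @param position 1-based coordinate within the chromosome.
#' @param causal_haplotype the haplotype (A-D) carrying the causal allele.
#' @param mode `"dominant"` (one copy suffices) or `"recessive"` (two
#'   copies required).
#' @param trait_name label for the binary trait.
#' @return a `causal_locus` list.
#' @export
causal_locus <- function(chrom, position, causal_haplotype = "A",
                         mode = c("dominant", "recessive"),
                         trait_name = "trait") {
  mode <- match.arg(mode)
  stopifnot(causal_haplotype %in% c("A", "B", "C", "D"), position >= 1)
  structure(list(chrom = chrom, position = as.integer(position),
                 causal_haplotype = causal_haplotype, mode = mode,
                 trait_name = trait_name),
            class = "causal_locus")
}

# clip segments of one homolog to [s, e]
.slice_segs <- function(segs, s, e) {
  out <- segs[end >= s & start <= e]
  out[, `:=`(start = pmax(start, s), end = pmin(end, e))]
  out
}

# one gamete from a pair of homolog mosaics: Poisson number of crossovers,
# uniform breakpoints, no interference; alternates source homolog
.gamete <- function(h1, h2, len, recomb_rate) {
  n_x <- rpois(1, recomb_rate)
  src <- sample(1:2, 1)
  if (n_x == 0) return(copy(if (src == 1) h1 else h2))
  # crossover after position b: breakpoints in [1, len - 1]
  bp <- sort(unique(1 + floor(runif(n_x) * (len - 1))))
  bounds <- c(0, bp, len)
  pieces <- vector("list", length(bounds) - 1)
  for (i in seq_len(length(bounds) - 1)) {
    segs <- if (src == 1) h1 else h2
    pieces[[i]] <- .slice_segs(segs, bounds[i] + 1, bounds[i + 1])
    src <- 3 - src
  }
  g <- rbindlist(pieces)
  # merge adjacent segments with the same haplotype label
  g[, grp := cumsum(c(TRUE, hap[-1] != hap[-.N]))]
  g <- g[, .(start = min(start), end = max(end), hap = hap[1]), by = grp]
  g[, grp := NULL]
  g[]
}

.new_individual <- function(id, generation, mosaic) {
  list(id = id, generation = generation, mosaic = mosaic,
       trait_values = list())
}

#' Simulate an F1 intercross pedigree
#'
#' Parent 1 (homologs A and B) and parent 2 (C and D) are crossed to
#' produce `n_f1` F1 individuals; each F1 carries a recombinant A/B mosaic
#' and a recombinant C/D mosaic. F2 individuals are produced by drawing two
#' distinct F1 parents uniformly at random (emulating a pooled-pollen
#' intercross with self-incompatibility; no selfing) and taking one gamete
#' from each. Recombination is a Poisson number of crossovers per
#' chromosome per meiosis with uniform breakpoints and no interference.
#'
#' @param haps a `haplotype_set` from [sim_haplotypes()].
#' @param n_f1 number of F1 individuals (>= 2).
#' @param n_f2 number of F2 individuals.
#' @param recomb_rate expected crossovers per chromosome per meiosis
#'   (default 1).
#' @param seed integer seed; identical seeds give identical pedigrees.
#' @return named list of individuals (`P1`, `P2`, `F1_*`, `F2_*`), each a
#'   list with `id`, `generation`, `mosaic` (per-chromosome list of two
#'   `data.table`s of `(start, end, hap)` segments, 1-based inclusive,
#'   tiling the chromosome) and empty `trait_values`.
#' @export
simulate_pedigree <- function(haps, n_f1 = 8, n_f2 = 48, recomb_rate = 1,
                              seed = NULL) {
  stopifnot(inherits(haps, "haplotype_set"))
  if (!is.null(seed)) set.seed(seed)
  if (n_f1 < 2) stop("n_f1 must be >= 2: an intercross needs two distinct F1 parents")
  if (any(haps$chrom_lengths <= 0)) stop("zero-length chromosome")
  if (recomb_rate < 0) stop("recomb_rate must be >= 0")
  chroms <- names(haps$chrom_lengths)
  whole <- function(ch, h) data.table(start = 1L,
                                      end = as.integer(haps$chrom_lengths[[ch]]),
                                      hap = h)
  p_mosaic <- function(h1, h2)
    setNames(lapply(chroms, function(ch) list(whole(ch, h1), whole(ch, h2))),
             chroms)
  inds <- list(P1 = .new_individual("P1", "P", p_mosaic("A", "B")),
               P2 = .new_individual("P2", "P", p_mosaic("C", "D")))
  gamete_from <- function(ind) {
    setNames(lapply(chroms, function(ch) {
      .gamete(ind$mosaic[[ch]][[1]], ind$mosaic[[ch]][[2]],
              haps$chrom_lengths[[ch]], recomb_rate)
    }), chroms)
  }
  f1 <- vector("list", n_f1)
  for (i in seq_len(n_f1)) {
    g1 <- gamete_from(inds$P1) # A/B mosaic
    g2 <- gamete_from(inds$P2) # C/D mosaic
    mosaic <- setNames(lapply(chroms, function(ch) list(g1[[ch]], g2[[ch]])),
                       chroms)
    f1[[i]] <- .new_individual(sprintf("F1_%02d", i), "F1", mosaic)
  }
  names(f1) <- vapply(f1, `[[`, character(1), "id")
  f2 <- vector("list", n_f2)
  for (i in seq_len(n_f2)) {
    parents <- sample.int(n_f1, 2, replace = FALSE) # two distinct F1s
    g1 <- gamete_from(f1[[parents[1]]])
    g2 <- gamete_from(f1[[parents[2]]])
    mosaic <- setNames(lapply(chroms, function(ch) list(g1[[ch]], g2[[ch]])),
                       chroms)
    f2[[i]] <- .new_individual(sprintf("F2_%02d", i), "F2", mosaic)
  }
  names(f2) <- vapply(f2, `[[`, character(1), "id")
  c(inds, f1, f2)
}

#' Haplotype labels carried by an individual at a position
#'
#' @param individual an individual from [simulate_pedigree()].
#' @param chrom,position locus coordinates.
#' @return character vector of length 2 (one label per homolog).
#' @export
hap_at <- function(individual, chrom, position) {
  vapply(individual$mosaic[[chrom]], function(segs) {
    segs[start <= position & end >= position, hap]
  }, character(1))
}

#' Assign a binary trait from a causal locus
#'
#' Dominant mode: an individual is phenotype-positive iff at least one
#' homolog carries the causal haplotype at the locus. Recessive mode: both
#' homologs must carry it.
#' @param individuals list of individuals from [simulate_pedigree()].
#' @param locus a [causal_locus()].
#' @return the individuals, with `trait_values[[trait_name]]` set to
#'   `TRUE`/`FALSE`.
#' @export
assign_traits <- function(individuals, locus) {
  stopifnot(inherits(locus, "causal_locus"))
  lapply(individuals, function(ind) {
    h <- hap_at(ind, locus$chrom, locus$position)
    n <- sum(h == locus$causal_haplotype)
    ind$trait_values[[locus$trait_name]] <-
      if (locus$mode == "dominant") n >= 1 else n == 2
    ind
  })
}

# sequence of one homolog: hap-labelled segments stitched from the
# precomputed haplotype sequences
.homolog_sequence <- function(hseqs_chrom, segs) {
  paste(vapply(seq_len(nrow(segs)), function(i) {
    substring(hseqs_chrom[[segs$hap[i]]], segs$start[i], segs$end[i])
  }, character(1)), collapse = "")
}

# substitution errors, vectorized over the concatenation of all reads
.add_errors <- function(reads, error_rate) {
  if (error_rate == 0 || !length(reads)) return(reads)
  big <- paste(reads, collapse = "")
  raw <- charToRaw(big)
  n <- length(raw)
  n_err <- rbinom(1, n, error_rate)
  if (n_err > 0) {
    idx <- sample.int(n, n_err)
    codes <- match(raw[idx], charToRaw("ACGT")) - 1L
    new_codes <- (codes + sample.int(3, n_err, replace = TRUE)) %% 4L
    raw[idx] <- charToRaw("ACGT")[new_codes + 1L]
  }
  lens <- nchar(reads)
  ends <- cumsum(lens)
  substring(rawToChar(raw), ends - lens + 1, ends)
}

#' Simulate error-bearing short reads for a set of individuals
#'
#' Reads are drawn uniformly from each individual's two homolog sequences
#' (the haplotype mosaic applied to the SNP alleles), on either strand with
#' equal probability, with independent per-base substitution errors. The
#' returned truth table records each read's source homolog and coordinates
#' so that downstream binning can be validated without an external aligner.
#'
#' @param individuals list of individuals (from [simulate_pedigree()]).
#' @param haps the `haplotype_set` they were bred from.
#' @param coverage target fold coverage per individual (total bases =
#'   `coverage * genome length`).
#' @param read_len read length in bp (default 150).
#' @param error_rate per-base substitution rate, in `[0, 0.1]`
#'   (default 0.002, a typical post-QC short-read substitution rate).
#' @param paired emit read pairs from opposite fragment ends
#'   (insert = `2 * read_len + 50`) instead of single reads.
#' @param seed integer seed; identical seeds give identical reads.
#' @return named list (one element per individual) of
#'   `list(reads = character, truth = data.table(qname, chrom, homolog,
#'   start, end, strand))`; truth coordinates are 1-based inclusive on the
#'   reference.
#' @export
simulate_reads <- function(individuals, haps, coverage = 4, read_len = 150,
                           error_rate = 0.002, paired = FALSE, seed = NULL) {
  stopifnot(inherits(haps, "haplotype_set"))
  if (!is.null(seed)) set.seed(seed)
  if (coverage <= 0) stop("coverage must be > 0")
  if (error_rate < 0 || error_rate > 0.1)
    stop("error_rate must be in [0, 0.1]")
  if (read_len > min(haps$chrom_lengths))
    stop("read_len exceeds the shortest chromosome")
  hseqs <- hap_sequences(haps)
  chroms <- names(haps$chrom_lengths)
  genome_len <- sum(haps$chrom_lengths)
  frag_len <- if (paired) 2L * read_len + 50L else read_len
  out <- lapply(individuals, function(ind) {
    n_frag <- max(1L, round(coverage * genome_len /
                              (if (paired) 2L * read_len else read_len)))
    # fragments over (chrom, homolog) proportional to length
    units <- CJ(chrom = chroms, homolog = 1:2)
    units[, len := haps$chrom_lengths[chrom]]
    n_units <- as.vector(rmultinom(1, n_frag, units$len))
    reads <- character(0)
    truth <- vector("list", nrow(units))
    for (u in seq_len(nrow(units))) {
      cnt <- n_units[u]
      if (cnt == 0) next
      ch <- units$chrom[u]; hom <- units$homolog[u]
      len <- units$len[u]
      if (frag_len > len) stop("fragment length exceeds chromosome ", ch)
      seq_u <- .homolog_sequence(hseqs[[ch]], ind$mosaic[[ch]][[hom]])
      starts <- sample.int(len - frag_len + 1L, cnt, replace = TRUE)
      if (!paired) {
        minus <- as.logical(rbinom(cnt, 1, 0.5))
        # substitution errors presampled here (R side owns the RNG), read
        # slicing and mutation done in compiled code; minus-strand reads
        # are sliced from one reverse complement of the whole homolog
        n_err <- rbinom(1, cnt * read_len, error_rate)
        err_pos <- if (n_err > 0) sample.int(cnt * read_len, n_err) else integer(0)
        err_shift <- if (n_err > 0) sample.int(3L, n_err, replace = TRUE) else integer(0)
        rc <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(seq_u)))
        rd <- .cpp_extract_reads(seq_u, rc, starts, minus, read_len,
                                 err_pos, err_shift)
        qn <- paste0(ind$id, "_", ch, "_h", hom, "_r", seq_len(cnt))
        reads <- c(reads, setNames(rd, qn))
        truth[[u]] <- data.table(qname = qn, chrom = ch, homolog = hom,
                                 start = starts,
                                 end = starts + read_len - 1L,
                                 strand = ifelse(minus, "-", "+"))
      } else {
        r1 <- substring(seq_u, starts, starts + read_len - 1L)
        e2 <- starts + frag_len - 1L
        r2 <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(substring(seq_u, e2 - read_len + 1L, e2))))
        qn <- sprintf("%s_%s_h%d_f%06d", ind$id, ch, hom, seq_len(cnt))
        reads <- c(reads, setNames(r1, paste0(qn, "/1")),
                   setNames(r2, paste0(qn, "/2")))
        truth[[u]] <- data.table(
          qname = c(paste0(qn, "/1"), paste0(qn, "/2")),
          chrom = ch, homolog = hom,
          start = c(starts, e2 - read_len + 1L),
          end = c(starts + read_len - 1L, e2),
          strand = rep(c("+", "-"), each = cnt))
      }
    }
    if (paired) { # single-end errors are applied during extraction
      mutated <- .add_errors(unname(reads), error_rate)
      reads <- setNames(mutated, names(reads))
    }
    list(reads = reads, truth = rbindlist(truth))
  })
  setNames(out, vapply(individuals, `[[`, character(1), "id"))
}

#' Write simulated reads as FASTQ
#'
#' Four-line records with constant quality; `.gz` paths are compressed.
#' @param reads named character vector (names become read ids).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_fastq <- function(reads, file) {
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(paste0("@", names(reads)), unname(reads),
                           "+", qual))
  con <- if (grepl("\\.gz$", file)) gzfile(file, "w") else file(file, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(file)
}

#' Write truth placements as SAM
#'
#' Emits each simulated read as a primary alignment at its true position
#' (full-length match, MAPQ 60, flag 16 for minus-strand reads), with a
#' proper `@SQ` header, so the localization stage can be exercised without
#' an external aligner.
#' @param truth a truth `data.table` from [simulate_reads()] (rows
#'   `qname, chrom, start, end, strand`), or a list of them.
#' @param haps the `haplotype_set` (for header chromosome lengths).
#' @param file output path.
#' @param mapq mapping quality to report (default 60).
#' @return `file`, invisibly.
#' @export
write_truth_sam <- function(truth, haps, file, mapq = 60) {
  if (is.list(truth) && !is.data.frame(truth)) truth <- rbindlist(truth)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(haps$chrom_lengths),
                      as.integer(haps$chrom_lengths)))
  cigar <- paste0(truth$end - truth$start + 1L, "M")
  recs <- paste(truth$qname, ifelse(truth$strand == "-", 16L, 0L),
                truth$chrom, truth$start, mapq, cigar,
                "*", 0L, 0L, "*", "*", sep = "\t")
  writeLines(c(header, recs), file)
  invisible(file)
}

#' Write the parental truth genotypes as VCF
#'
#' One biallelic record per simulated SNP, positions 1-based, VCF 4.2.
#' Parental genotypes follow from the haplotype alleles (P1 = A/B,
#' P2 = C/D); per-parent depths are drawn Poisson around `mean_depth` and
#' reported in the `DP` FORMAT field. Sites whose haplotype alleles span
#' more than two distinct bases are skipped with a warning (or emitted
#' multi-allelic when `skip_multiallelic = FALSE`).
#'
#' @param haps a `haplotype_set`.
#' @param file output path.
#' @param qual QUAL column value (default 999, the cap used by common
#'   callers).
#' @param mean_depth mean simulated per-parent depth (default 40).
#' @param skip_multiallelic drop sites with > 2 alleles (default `TRUE`).
#' @param seed integer seed for the depth draws.
#' @return `file`, invisibly.
#' @export
emit_truth_vcf <- function(haps, file, qual = 999, mean_depth = 40,
                           skip_multiallelic = TRUE, seed = NULL) {
  stopifnot(inherits(haps, "haplotype_set"))
  if (!is.null(seed)) set.seed(seed)
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>",
                      names(haps$chrom_lengths),
                      as.integer(haps$chrom_lengths)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tP1\tP2")
  s <- haps$snp
  if (!nrow(s)) { writeLines(header, file); return(invisible(file)) }
  recs <- character(0)
  n_multi <- 0L
  for (i in seq_len(nrow(s))) {
    alleles <- c(s$A[i], s$B[i], s$C[i], s$D[i])
    alts <- setdiff(unique(alleles), s$ref[i])
    if (length(alts) > 1 && skip_multiallelic) { n_multi <- n_multi + 1L; next }
    idx <- match(alleles, c(s$ref[i], alts)) - 1L
    gt <- function(a1, a2) paste(min(a1, a2), max(a1, a2), sep = "/")
    dp <- rpois(2, mean_depth)
    recs <- c(recs, paste(
      s$chrom[i], s$pos[i], ".", s$ref[i], paste(alts, collapse = ","),
      qual, "PASS", ".", "GT:DP",
      paste0(gt(idx[1], idx[2]), ":", dp[1]),
      paste0(gt(idx[3], idx[4]), ":", dp[2]), sep = "\t"))
  }
  if (n_multi > 0)
    warning(n_multi, " multi-allelic site(s) skipped")
  writeLines(c(header, recs), file)
  invisible(file)
}

#' Tabulate the simulated parental variant sites
#'
#' The `VariantSite`-style truth table consumed by the parental-SNP
#' genotyping comparator and the pseudo-phasing stage: per-site parental
#' genotypes derived from the haplotype alleles, plus simulated per-parent
#' depths and binomially sampled alternate-allele fractions around the
#' genotype truth.
#'
#' @param haps a `haplotype_set`.
#' @param mean_depth named vector `c(p1 = , p2 = )` of mean depths; the
#'   defaults (25x and 35x) emulate a moderately covered focal parent and
#'   a deeper other parent, with pooled depth well inside a 25-70 QC
#'   window.
#' @param qual QUAL to report (default 999).
#' @param seed integer seed.
#' @return `data.table` with columns `chrom, pos, ref, alt, gt_p1, gt_p2,
#'   qual, depth_p1, depth_p2, alt_frac_p1, alt_frac_p2`.
#' @export
truth_variant_sites <- function(haps, mean_depth = c(p1 = 25, p2 = 35),
                                qual = 999, seed = NULL) {
  stopifnot(inherits(haps, "haplotype_set"))
  if (!is.null(seed)) set.seed(seed)
  s <- copy(haps$snp)
  gt_of <- function(a1, a2, alt) {
    n_alt <- (a1 == alt) + (a2 == alt)
    c("hom_ref", "het", "hom_alt")[n_alt + 1L]
  }
  s[, gt_p1 := gt_of(A, B, alt)]
  s[, gt_p2 := gt_of(C, D, alt)]
  s[, qual := qual]
  s[, depth_p1 := rpois(.N, mean_depth[["p1"]])]
  s[, depth_p2 := rpois(.N, mean_depth[["p2"]])]
  true_frac <- function(gt) c(hom_ref = 0, het = 0.5, hom_alt = 1)[gt]
  s[, alt_frac_p1 := ifelse(depth_p1 > 0,
                            rbinom(.N, depth_p1, true_frac(gt_p1)) / depth_p1,
                            NA_real_)]
  s[, alt_frac_p2 := ifelse(depth_p2 > 0,
                            rbinom(.N, depth_p2, true_frac(gt_p2)) / depth_p2,
                            NA_real_)]
  s[, c("A", "B", "C", "D") := NULL]
  s[]
}

#' Write a truth table as TSV
#' @param truth any `data.table` (read truth, variant truth, ...).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_truth_tsv <- function(truth, file) {
  fwrite(truth, file, sep = "\t")
  invisible(file)
}
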