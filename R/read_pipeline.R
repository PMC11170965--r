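# read_pipeline: reconstruct the encoded string set from noisy sequencing
# reads and hand off to the codec for decoding.
#
# Stages (each a pure function of its input):
#   filter_by_flank   assign reads to files by their flanking handles,
#                     reorienting reverse-strand reads
#   quality_filter    remove reads dominated by low-quality calls
#   length_mode_filter keep the modal read length
#   rank_reads        deduplicate; sort by quality, then abundance
#   cluster_and_select greedy clustering; best-ranked member represents
#                     each cluster
# The representatives then flow into decode_file().

#' Construct a read set
#'
#' @param sequence character vector of read sequences
#' @param quality Phred+33 quality strings (same lengths as `sequence`)
#' @param read_id optional ids (generated when NULL)
#' @return a `read_set` data.frame with columns `read_id`, `sequence`,
#'   `quality`
#' @export
read_set <- function(sequence, quality, read_id = NULL) {
  stopifnot(length(sequence) == length(quality),
            all(nchar(sequence) == nchar(quality)))
  if (is.null(read_id)) read_id <- sprintf("read_%06d", seq_along(sequence))
  structure(data.frame(read_id = read_id, sequence = sequence, quality = quality,
                       stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}

#' Write / read a read set as FASTQ (Phred+33)
#'
#' @param reads a `read_set`
#' @param path file path
#' @return `write_fastq` returns `path` invisibly; `read_fastq` returns a
#'   `read_set`.
#' @export
write_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- reads$read_id
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  read_set(as.character(x), as.character(Biostrings::quality(x)),
           read_id = if (is.null(names(x))) NULL else names(x))
}

# per-read mismatch counts of equal-length string vector vs one reference
.mismatch_counts <- function(strs, ref) {
  if (length(strs) == 0L) return(integer(0))
  m <- .seq_to_codes(strs)
  refc <- .base_lookup()[as.integer(charToRaw(ref)) + 1L]
  rowSums(m != matrix(refc, nrow(m), length(refc), byrow = TRUE), na.rm = FALSE) +
    rowSums(is.na(m))  # non-ACGT counts as mismatch
}

#' Assign reads to files by their flanking sequences
#'
#' A read belongs to a file when its 5' end matches the file's forward
#' flank and its 3' end matches the file's 3' flank, each within
#' `max_mismatch` mismatches - in either orientation. Reverse-orientation
#' reads are reverse-complemented (and their qualities reversed); reads
#' matching no file in either orientation are dropped (counted in the
#' `dropped` attribute). Ties go to the lowest total mismatch count.
#'
#' @param reads a `read_set`
#' @param flanks a `flank_pairs` data.frame (`file_id`, `forward`,
#'   `reverse`), or an `oligocodec_manifest` (single file 0)
#' @param max_mismatch per-flank mismatch tolerance (default 2)
#' @return the assigned reads (reoriented), with a `file_id` column and
#'   attribute `n_dropped`
#' @export
filter_by_flank <- function(reads, flanks, max_mismatch = 2L) {
  if (inherits(flanks, "oligocodec_manifest")) {
    if (!nzchar(flanks$flank_5p)) stop("manifest carries no flanking sequences")
    flanks <- data.frame(file_id = 0L, forward = flanks$flank_5p,
                         reverse = flanks$flank_3p, stringsAsFactors = FALSE)
  }
  Fl <- unique(nchar(c(flanks$forward, flanks$reverse)))
  if (length(Fl) != 1L) stop("all flanks must have equal length")
  long <- nchar(reads$sequence) >= 2L * Fl
  rs <- reads[long, , drop = FALSE]
  n <- nrow(rs)
  pre <- substr(rs$sequence, 1L, Fl)
  suf <- substr(rs$sequence, nchar(rs$sequence) - Fl + 1L, nchar(rs$sequence))
  best_mm <- rep(Inf, n)
  best_file <- rep(NA_integer_, n)
  best_revflag <- rep(FALSE, n)
  for (i in seq_len(nrow(flanks))) {
    f5 <- flanks$forward[i]
    f3 <- flanks$reverse[i]
    fwd5 <- .mismatch_counts(pre, f5)
    fwd3 <- .mismatch_counts(suf, f3)
    rev5 <- .mismatch_counts(pre, .revcomp_chr(f3))
    rev3 <- .mismatch_counts(suf, .revcomp_chr(f5))
    fok <- fwd5 <= max_mismatch & fwd3 <= max_mismatch
    rok <- rev5 <= max_mismatch & rev3 <= max_mismatch
    ftot <- ifelse(fok, fwd5 + fwd3, Inf)
    rtot <- ifelse(rok, rev5 + rev3, Inf)
    tot <- pmin(ftot, rtot)
    upd <- tot < best_mm
    best_mm[upd] <- tot[upd]
    best_file[upd] <- flanks$file_id[i]
    best_revflag[upd] <- (rtot < ftot)[upd]
  }
  keep <- is.finite(best_mm)
  out <- rs[keep, , drop = FALSE]
  revsel <- best_revflag[keep]
  if (any(revsel)) {
    out$sequence[revsel] <- .revcomp_chr(out$sequence[revsel])
    out$quality[revsel] <- .rev_string(out$quality[revsel])
  }
  out$file_id <- best_file[keep]
  attr(out, "n_dropped") <- nrow(reads) - nrow(out)
  class(out) <- c("read_set", "data.frame")
  out
}

.quality_intlist <- function(reads) {
  methods::as(Biostrings::PhredQuality(reads$quality), "IntegerList")
}

#' Remove low-quality reads
#'
#' Eliminates reads in which more than `max_low_frac` of the bases fall
#' below Phred `q_threshold`. The default (strictly more than 80% of bases
#' below Q30) applies the published rule literally; pass a smaller
#' `max_low_frac` for a stricter filter.
#'
#' @param reads a `read_set`
#' @param q_threshold Phred threshold (default 30)
#' @param max_low_frac maximum tolerated fraction of sub-threshold bases;
#'   a read with exactly this fraction is kept (default 0.80)
#' @return the filtered `read_set`
#' @export
quality_filter <- function(reads, q_threshold = 30L, max_low_frac = 0.80) {
  if (nrow(reads) == 0L) return(reads)
  il <- .quality_intlist(reads)
  frac <- sum(il < q_threshold) / lengths(il)
  out <- reads[frac <= max_low_frac + 1e-12, , drop = FALSE]
  class(out) <- c("read_set", "data.frame")
  out
}

#' Keep reads of the modal length
#'
#' Retains only reads whose length equals the most frequent length in the
#' set; ties are broken toward `expected_length` when it is among the tied
#' modes, otherwise toward the shortest tied length.
#'
#' @param reads a `read_set` (non-empty)
#' @param expected_length the string length the manifest promises
#' @return the filtered `read_set`
#' @export
length_mode_filter <- function(reads, expected_length = NULL) {
  if (nrow(reads) == 0L) stop("pipeline error: no reads to length-filter")
  tab <- table(nchar(reads$sequence))
  modes <- as.integer(names(tab)[tab == max(tab)])
  pick <- if (!is.null(expected_length) && expected_length %in% modes)
    as.integer(expected_length) else min(modes)
  out <- reads[nchar(reads$sequence) == pick, , drop = FALSE]
  class(out) <- c("read_set", "data.frame")
  out
}

#' Rank unique sequences by abundance and quality
#'
#' Deduplicates the reads to unique sequences, scoring each by its copy
#' number and its mean Phred quality over all bases of all copies, sorted
#' by quality and then by quantity in the multi-pass stable-sort sense:
#' the final (primary) key is the count, with mean quality breaking ties
#' and the sequence itself (lexicographic) breaking the rest. The order
#' score is the 1-based rank; lower is better. Abundance must dominate
#' for the rank to be informative: per-read mean quality varies by more
#' (sampling noise across a few hundred bases) than a single erroneous
#' base depresses it, so a quality-primary sort would order error-free
#' reads essentially at random while copy number separates true strings
#' from error variants sharply.
#'
#' @param reads a `read_set`
#' @return a `ranked_reads` data.frame: `sequence`, `count`,
#'   `mean_quality`, `order_score`, in rank order
#' @export
rank_reads <- function(reads) {
  stopifnot(nrow(reads) > 0L)
  il <- .quality_intlist(reads)
  tot <- sum(il)
  len <- lengths(il)
  qsum <- rowsum(tot, reads$sequence)
  bsum <- rowsum(len, reads$sequence)
  cnt <- rowsum(rep(1L, nrow(reads)), reads$sequence)
  seqs <- rownames(qsum)
  meanq <- as.numeric(qsum) / as.numeric(bsum)
  counts <- as.integer(cnt)
  o <- order(-counts, -meanq, seqs)
  structure(data.frame(sequence = seqs[o], count = counts[o],
                       mean_quality = meanq[o],
                       order_score = seq_along(o),
                       stringsAsFactors = FALSE),
            class = c("ranked_reads", "data.frame"))
}

#' Cluster ranked sequences and select representatives
#'
#' Greedy clustering in order-score order: a sequence joins the cluster of
#' the best-ranked earlier sequence within `radius` (edit distance;
#' Hamming distance for the usual equal-length input, where it upper-bounds
#' the edit distance), otherwise it founds a new cluster. Each cluster is
#' represented by its lowest-order-score member.
#'
#' For equal-length inputs the search is accelerated by an exact-match
#' block index: candidate neighbors are sequences sharing at least one of
#' `n_blocks` disjoint substring blocks, which is guaranteed to find every
#' sequence within `n_blocks - 1` mismatches of an earlier one.
#'
#' @param ranked a `ranked_reads` data.frame (or character vector, treated
#'   as already ranked)
#' @param radius clustering radius in mismatches; default 10% of the
#'   string length
#' @param n_blocks number of index blocks (default 8)
#' @return a data.frame `representative`, `order_score`, `n_members`
#'   (unique sequences), `n_reads` (total read count), in rank order
#' @export
cluster_and_select <- function(ranked, radius = NULL, n_blocks = 8L) {
  if (is.character(ranked))
    ranked <- data.frame(sequence = ranked, count = 1L,
                         order_score = seq_along(ranked), stringsAsFactors = FALSE)
  stopifnot(nrow(ranked) > 0L)
  seqs <- ranked$sequence
  n <- length(seqs)
  Ls <- nchar(seqs)
  if (length(unique(Ls)) > 1L) {
    # variable-length fallback: plain sequential greedy on edit distance
    L0 <- stats::median(Ls)
    if (is.null(radius)) radius <- max(1L, round(0.1 * L0))
    reps <- integer(0)
    cluster <- integer(n)
    for (i in seq_len(n)) {
      hit <- 0L
      if (length(reps)) {
        d <- utils::adist(seqs[i], seqs[reps])
        w <- which(d <= radius)
        if (length(w)) hit <- reps[w[1]]
      }
      if (hit == 0L) { reps <- c(reps, i); cluster[i] <- i } else cluster[i] <- hit
    }
  } else {
    L <- Ls[1]
    if (is.null(radius)) radius <- max(1L, round(0.1 * L))
    nb <- min(n_blocks, L)
    bnd <- round(seq(0L, L, length.out = nb + 1L))
    R <- matrix(charToRaw(paste(seqs, collapse = "")), nrow = L)
    chunk <- 400000L %/% max(1L, L) + 1L
    cand <- matrix(0L, n, nb)
    for (b in seq_len(nb)) {
      key <- substring(seqs, bnd[b] + 1L, bnd[b + 1L])
      cb <- match(key, key)  # first occurrence = best-ranked block mate
      # a block mate only counts as a candidate parent when the *whole*
      # sequences are within the clustering radius (a block shared by the
      # fixed flanks, say, links unrelated strings otherwise)
      for (s in seq(1L, n, chunk)) {
        ii <- s:min(s + chunk - 1L, n)
        d <- colSums(R[, ii, drop = FALSE] != R[, cb[ii], drop = FALSE])
        cb[ii][d > radius] <- ii[d > radius]
      }
      cand[, b] <- cb
    }
    p <- do.call(pmin, lapply(seq_len(nb), function(b) cand[, b]))
    # path-compress candidate chains to their founders (edges are all
    # within the radius, so chains stay inside one variant group)
    repeat {
      p2 <- p[p]
      if (identical(p2, p)) break
      p <- p2
    }
    cluster <- p
  }
  reads_per_cluster <- rowsum(as.numeric(ranked$count), cluster)
  members_per_cluster <- rowsum(rep(1, n), cluster)
  rep_idx <- as.integer(rownames(reads_per_cluster))
  o <- order(rep_idx)
  rep_idx <- rep_idx[o]
  structure(data.frame(representative = seqs[rep_idx],
                       order_score = ranked$order_score[rep_idx],
                       n_members = as.integer(members_per_cluster[o]),
                       n_reads = as.integer(reads_per_cluster[o]),
                       stringsAsFactors = FALSE),
            class = c("read_clusters", "data.frame"))
}

#' Recover a stored file from sequencing reads
#'
#' Runs the full chain: [filter_by_flank()] -> [quality_filter()] ->
#' [length_mode_filter()] -> [rank_reads()] -> [cluster_and_select()] ->
#' [decode_file()]. The report combines per-stage read counts, the
#' per-cluster depth table, and the decode report (RS corrections, XOR
#' recoveries, recovery fraction, checksum state).
#'
#' @param reads a `read_set` (e.g. from [read_fastq()] or
#'   [simulate_reads()])
#' @param manifest the job manifest
#' @param pin the codec pin used at encode time
#' @param radius clustering radius (default 10% of string length)
#' @param max_mismatch per-flank mismatch tolerance (default 2)
#' @param file_id which file to recover when several flank pairs share the
#'   pool (default 0)
#' @param flanks optional `flank_pairs` table overriding the manifest's
#' @return list with `data` (raw vector) and `report` (stage counts,
#'   `depth` data.frame, and all [decode_file()] report fields)
#' @export
recover_file <- function(reads, manifest, pin, radius = NULL,
                         max_mismatch = 2L, file_id = 0L, flanks = NULL) {
  if (is.null(flanks)) flanks <- manifest
  fb <- filter_by_flank(reads, flanks, max_mismatch = max_mismatch)
  n_flank_dropped <- attr(fb, "n_dropped")
  fb <- fb[fb$file_id == file_id, , drop = FALSE]
  class(fb) <- c("read_set", "data.frame")
  qf <- quality_filter(fb)
  lf <- length_mode_filter(qf, expected_length = manifest$string_length)
  rk <- rank_reads(lf)
  cl <- cluster_and_select(rk, radius = radius)
  dec <- decode_file(cl$representative, pin, manifest)
  report <- c(list(n_reads_in = nrow(reads),
                   n_flank_dropped = n_flank_dropped,
                   n_after_flank = nrow(fb),
                   n_after_quality = nrow(qf),
                   n_after_length = nrow(lf),
                   n_unique = nrow(rk),
                   n_clusters = nrow(cl),
                   depth = cl[, c("representative", "n_reads")]),
              dec$report)
  list(data = dec$data, report = report)
}
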