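# simulate: synthetic oligo pools and sequencing reads with controlled
# depth, substitution/indel noise, and whole-string dropout, so every
# downstream claim is testable without sequencing data. Read counts per
# surviving string are Poisson(depth); erroneous bases are biased toward
# lower Phred scores; strand orientation is random.

#' Sequencing noise model
#'
#' @param substitution_rate per-base substitution probability (default
#'   0.005, the regime of chip-synthesized oligo pools read on short-read
#'   sequencers after paired-end merging)
#' @param insertion_rate,deletion_rate per-base indel probabilities
#'   (default 0; indel-bearing reads are expected to be removed by the
#'   pipeline's length-mode filter)
#' @param dropout_strings whole strings removed before sampling: a count
#'   (>= 1) or a fraction (< 1)
#' @param depth mean reads per surviving string (Poisson)
#' @param mean_quality,quality_sd Phred profile of correct bases
#' @param error_quality mean Phred assigned to erroneous bases
#' @param seed RNG seed; identical models give identical read sets
#' @return an object of class `noise_model`
#' @export
noise_model <- function(substitution_rate = 0.005,
                        insertion_rate = 0, deletion_rate = 0,
                        dropout_strings = 0, depth = 30,
                        mean_quality = 36, quality_sd = 4,
                        error_quality = 20, seed = 1L) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            insertion_rate >= 0, deletion_rate >= 0, depth > 0)
  structure(list(substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate, deletion_rate = deletion_rate,
                 dropout_strings = dropout_strings, depth = depth,
                 mean_quality = mean_quality, quality_sd = quality_sd,
                 error_quality = error_quality, seed = as.integer(seed)),
            class = "noise_model")
}

.rev_string <- function(x) {
  vapply(x, function(s) rawToChar(rev(charToRaw(s))), character(1), USE.NAMES = FALSE)
}

#' Simulate sequencing reads from an encoded pool
#'
#' Removes `dropout_strings` strings entirely, draws a Poisson(depth) read
#' count for each survivor, applies per-base substitutions (and optional
#' indels), assigns Phred qualities (erroneous bases biased lower), and
#' flips each read to the reverse strand with probability 1/2.
#' Deterministic under the model seed.
#'
#' @param strings an `encoded_pool` or a (preferably named) character
#'   vector of strings
#' @param model a [noise_model()]
#' @return a `read_set` data.frame (`read_id`, `sequence`, `quality`) with
#'   attributes `truth` (data.frame `read_id`, `source`) and `dropped`
#'   (ids of the strings removed entirely)
#' @export
simulate_reads <- function(strings, model) {
  if (inherits(strings, "encoded_pool")) strings <- strings$sequences
  stopifnot(length(strings) >= 1L)
  ids <- names(strings)
  if (is.null(ids)) ids <- sprintf("string_%d", seq_along(strings) - 1L)
  with_seed(model$seed, {
    n <- length(strings)
    ndrop <- if (model$dropout_strings >= 1) as.integer(model$dropout_strings)
             else as.integer(round(model$dropout_strings * n))
    drop_idx <- if (ndrop > 0L) sample.int(n, ndrop) else integer(0)
    surv <- setdiff(seq_len(n), drop_idx)
    counts <- stats::rpois(length(surv), model$depth)
    src <- rep(surv, counts)
    N <- length(src)
    if (N == 0L) stop("no reads drawn; increase depth")
    seq_out <- character(N)
    qual_out <- character(N)
    for (L in unique(nchar(strings[src]))) {
      rows <- which(nchar(strings[src]) == L)
      B <- .seq_to_codes(strings[src[rows]])
      M <- length(rows) * L
      err <- stats::runif(M) < model$substitution_rate
      if (any(err)) {
        B[err] <- (B[err] + sample(1:3, sum(err), replace = TRUE)) %% 4L
      }
      Q <- as.integer(round(stats::rnorm(M, model$mean_quality, model$quality_sd)))
      if (any(err)) Q[err] <- as.integer(round(stats::rnorm(sum(err), model$error_quality, 3)))
      Q <- pmin(pmax(Q, 2L), 40L)
      dim(Q) <- dim(B)
      seqs <- .codes_to_seq(B)
      qraw <- as.raw(t(Q) + 33L)
      big <- rawToChar(qraw)
      quals <- substring(big, (seq_along(rows) - 1L) * L + 1L, seq_along(rows) * L)
      if (model$insertion_rate > 0 || model$deletion_rate > 0) {
        for (i in seq_along(seqs)) {
          ch <- strsplit(seqs[i], "")[[1]]
          qh <- strsplit(quals[i], "")[[1]]
          del <- stats::runif(length(ch)) < model$deletion_rate
          ch <- ch[!del]; qh <- qh[!del]
          ins <- which(stats::runif(length(ch)) < model$insertion_rate)
          for (p in rev(ins)) {
            ch <- append(ch, sample(.BASES, 1L), after = p)
            qh <- append(qh, rawToChar(as.raw(model$error_quality + 33L)), after = p)
          }
          seqs[i] <- paste(ch, collapse = "")
          quals[i] <- paste(qh, collapse = "")
        }
      }
      seq_out[rows] <- seqs
      qual_out[rows] <- quals
    }
    flip <- stats::runif(N) < 0.5
    if (any(flip)) {
      seq_out[flip] <- .revcomp_chr(seq_out[flip])
      qual_out[flip] <- .rev_string(qual_out[flip])
    }
    ord <- sample.int(N)
    rid <- sprintf("read_%06d", seq_len(N))
    rs <- read_set(seq_out[ord], qual_out[ord], rid)
    attr(rs, "truth") <- data.frame(read_id = rid, source = ids[src[ord]],
                                    stringsAsFactors = FALSE)
    attr(rs, "dropped") <- ids[drop_idx]
    rs
  })
}

#' Substitute a controlled number of bases in one string
#'
#' Test instrument for the error-correction bounds: substitutes exactly
#' `k_bases` positions. With `aligned = TRUE` all substitutions fall inside
#' one `frame_nt`-wide frame aligned to the coding grid; because the codec
#' interleaves fragments at the coding-unit level, a 4-nt aligned burst
#' damages at most one byte in each member fragment.
#'
#' @param seq DNA string
#' @param k_bases number of substitutions (0 returns the input)
#' @param aligned confine the damage to one aligned frame
#' @param seed optional seed; when NULL the current RNG stream is used
#' @param frame_nt frame width for `aligned` (default 4)
#' @param positions optional explicit 1-based positions (overrides the
#'   random choice; length must equal `k_bases`)
#' @return the corrupted string
#' @export
corrupt_string <- function(seq, k_bases, aligned = FALSE, seed = NULL,
                           frame_nt = 4L, positions = NULL) {
  stopifnot(k_bases <= nchar(seq))
  if (k_bases == 0L) return(seq)
  doit <- function() {
    L <- nchar(seq)
    if (is.null(positions)) {
      if (aligned) {
        stopifnot(k_bases <= frame_nt)
        f <- sample.int(L %/% frame_nt, 1L)
        positions <- (f - 1L) * frame_nt + sample.int(frame_nt, k_bases)
      } else {
        positions <- sample.int(L, k_bases)
      }
    }
    stopifnot(length(positions) == k_bases)
    ch <- strsplit(seq, "")[[1]]
    for (p in positions) {
      ch[p] <- sample(setdiff(.BASES, ch[p]), 1L)
    }
    paste(ch, collapse = "")
  }
  if (is.null(seed)) doit() else with_seed(seed, doit())
}
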