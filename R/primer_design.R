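# primer_design: PCR random-access flanking sequences.
#
# Candidates are windows of random templates kept when they satisfy the
# primer acceptance ranges (length 20-25 nt, GC 40-60%, nearest-neighbor
# melting temperature 58-70 degC, homopolymer runs <= 4 nt). Screens
# against the encoded payload pool remove candidates whose 3'-terminal
# hexamer could prime inside a payload and rank the rest by their maximum
# local-alignment score against the pool (match +1, mismatch -1, gap -2);
# the selected pairs are the lowest-scoring mutually compatible candidates.

# Allawi & SantaLucia unified nearest-neighbor parameters, indexed by
# dinucleotide code (AA,AC,...,TT): dH kcal/mol, dS cal/(mol K)
.NN_DH <- c(-7.9, -8.4, -7.8, -7.2, -8.5, -8.0, -10.6, -7.8,
            -8.2, -9.8, -8.0, -8.4, -7.2, -8.2, -8.5, -7.9)
.NN_DS <- c(-22.2, -22.4, -21.0, -20.4, -22.7, -19.9, -27.2, -21.0,
            -22.2, -24.4, -19.9, -22.4, -21.3, -22.2, -22.7, -22.2)

#' Nearest-neighbor melting temperature of DNA oligos
#'
#' Two-state nearest-neighbor model with the unified duplex parameters,
#' entropic salt correction `0.368 (N-1) ln[Na+]`, and hybridization
#' free-energy balance at total strand concentration `ct` (non-self-
#' complementary annealing, CT/4).
#'
#' @param seqs character vector of A/C/G/T oligo sequences
#' @param ct total oligo concentration in mol/L (default 0.25 uM)
#' @param na monovalent cation concentration in mol/L (default 50 mM)
#' @return numeric vector of melting temperatures in degrees Celsius
#' @export
oligo_tm <- function(seqs, ct = 0.25e-6, na = 0.05) {
  out <- numeric(length(seqs))
  for (L in unique(nchar(seqs))) {
    sel <- which(nchar(seqs) == L)
    codes <- .seq_to_codes(seqs[sel])
    stack <- 4L * codes[, -L, drop = FALSE] + codes[, -1L, drop = FALSE]
    dH <- matrix(.NN_DH[stack + 1L], ncol = L - 1L)
    dS <- matrix(.NN_DS[stack + 1L], ncol = L - 1L)
    dHs <- rowSums(dH)
    dSs <- rowSums(dS)
    for (term in list(codes[, 1L], codes[, L])) {
      gcterm <- term == 1L | term == 2L
      dHs <- dHs + ifelse(gcterm, 0.1, 2.3)
      dSs <- dSs + ifelse(gcterm, -2.8, 4.1)
    }
    dSs <- dSs + 0.368 * (L - 1) * log(na)
    out[sel] <- 1000 * dHs / (dSs + 1.987 * log(ct / 4)) - 273.15
  }
  out
}

#' GC fraction of sequences
#'
#' @param seqs character vector of A/C/G/T sequences
#' @return numeric vector of GC fractions
#' @export
gc_fraction <- function(seqs) {
  vapply(strsplit(seqs, ""), function(ch) mean(ch %in% c("C", "G")), numeric(1))
}

.has_homopolymer <- function(seqs, cap) {
  pat <- paste(vapply(.BASES, function(b) strrep(b, cap + 1L), ""), collapse = "|")
  grepl(pat, seqs)
}

#' Generate flanking-sequence candidates
#'
#' Slides 20-25-nt windows over random sequence templates and keeps those
#' satisfying the primer acceptance ranges: GC within `[min_gc, max_gc]`,
#' melting temperature within `[min_tm, max_tm]`, no homopolymer run over
#' `max_homopolymer`. Deterministic under `seed`.
#'
#' @param n number of candidates to return
#' @param seed RNG seed
#' @param min_len,max_len window lengths considered (defaults 20 and 25)
#' @param fixed_length if given, only windows of exactly this length
#' @param min_gc,max_gc GC bounds (defaults 0.40-0.60)
#' @param min_tm,max_tm melting-temperature bounds in degC (defaults 58-70)
#' @param max_homopolymer homopolymer cap (default 4 nt)
#' @return an object of class `flank_candidates`: data.frame with columns
#'   `sequence`, `length`, `gc`, `tm`, `source`
#' @export
generate_flank_candidates <- function(n = 100L, seed = 1L,
                                      min_len = 20L, max_len = 25L,
                                      fixed_length = NULL,
                                      min_gc = 0.4, max_gc = 0.6,
                                      min_tm = 58, max_tm = 70,
                                      max_homopolymer = 4L) {
  stopifnot(n >= 1L)
  lens <- if (is.null(fixed_length)) min_len:max_len else as.integer(fixed_length)
  acc <- character(0)
  with_seed(seed, {
    for (batch in 1:40) {
      tmpl <- vapply(seq_len(100L), function(i)
        paste(sample(.BASES, 80L, replace = TRUE), collapse = ""), character(1))
      wins <- unlist(lapply(lens, function(L) {
        starts <- seq_len(80L - L + 1L)
        unlist(lapply(tmpl, function(tp) substring(tp, starts, starts + L - 1L)))
      }))
      wins <- unique(wins)
      gc <- gc_fraction(wins)
      keep <- gc >= min_gc - 1e-9 & gc <= max_gc + 1e-9 &
        !.has_homopolymer(wins, max_homopolymer)
      wins <- wins[keep]
      tm <- oligo_tm(wins)
      wins <- wins[tm >= min_tm & tm <= max_tm]
      acc <- unique(c(acc, wins))
      if (length(acc) >= n) break
    }
  })
  if (length(acc) < n)
    warning(sprintf("only %d of %d requested flank candidates found", length(acc), n))
  acc <- acc[seq_len(min(n, length(acc)))]
  structure(data.frame(sequence = acc, length = nchar(acc),
                       gc = gc_fraction(acc), tm = oligo_tm(acc),
                       source = rep("generated", length(acc)),
                       stringsAsFactors = FALSE),
            class = c("flank_candidates", "data.frame"))
}

#' Remove candidates that could prime inside the encoded pool
#'
#' Drops every candidate whose 3'-terminal hexamer equals the 5'-terminal
#' hexamer of any encoded payload or of any payload's reverse complement
#' (these could extend off a payload during PCR).
#'
#' @param candidates a `flank_candidates` data.frame (or character vector)
#' @param pool character vector of encoded payload sequences (possibly
#'   empty, in which case all candidates are retained)
#' @return the filtered candidates
#' @export
screen_3prime <- function(candidates, pool) {
  df <- if (is.character(candidates)) {
    data.frame(sequence = candidates, stringsAsFactors = FALSE)
  } else candidates
  if (length(pool) == 0L) return(df)
  ends5 <- unique(c(substr(pool, 1L, 6L), substr(.revcomp_chr(pool), 1L, 6L)))
  hex3 <- substr(df$sequence, nchar(df$sequence) - 5L, nchar(df$sequence))
  out <- df[!hex3 %in% ends5, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("design error: every flank candidate shares a 3' hexamer with the pool; regenerate candidates")
  rownames(out) <- NULL
  out
}

.align_sub_matrix <- function() {
  if (is.null(.oc_env$sub_matrix))
    .oc_env$sub_matrix <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE)
  .oc_env$sub_matrix
}

.local_scores <- function(patterns, subject) {
  Biostrings::score(Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(patterns),
    subject = Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = .align_sub_matrix(),
    gapOpening = 0, gapExtension = 2))
}

#' Cross-homology score of candidates against the encoded pool
#'
#' Maximum local-alignment score (match +1, mismatch -1, gap -2) of each
#' candidate - on either strand - against any pool sequence. Lower scores
#' mean less risk of unspecific annealing. Large pools are subsampled
#' (evenly spaced, deterministic) to `max_pool` sequences.
#'
#' @param candidates character vector of candidate sequences
#' @param pool character vector of payload sequences
#' @param max_pool subsample cap (default 200)
#' @return integer vector of scores, one per candidate
#' @export
cross_homology_score <- function(candidates, pool, max_pool = 200L) {
  if (is.data.frame(candidates)) candidates <- candidates$sequence
  stopifnot(length(pool) >= 1L)
  if (length(pool) > max_pool)
    pool <- pool[round(seq(1L, length(pool), length.out = max_pool))]
  both <- c(candidates, .revcomp_chr(candidates))
  best <- rep(-Inf, length(both))
  for (s in pool) best <- pmax(best, .local_scores(both, s))
  as.integer(pmax(best[seq_along(candidates)], best[-seq_along(candidates)]))
}

#' Select mutually compatible flank pairs
#'
#' Greedily assigns, per file, the two unused candidates with the lowest
#' cross-homology scores (ties broken lexicographically), requiring every
#' chosen candidate to stay below `dimer_threshold` in local-alignment
#' score against all other chosen candidates (both strands; guards against
#' primer cross-pairing) and to carry a 3' hexamer distinct from every
#' other chosen candidate's.
#'
#' @param candidates a `flank_candidates` data.frame; a `score` column (as
#'   added by [cross_homology_score()]) is used for ranking when present
#' @param n_files number of flank pairs needed
#' @param dimer_threshold maximum tolerated candidate-vs-candidate local
#'   alignment score (default 8)
#' @return an object of class `flank_pairs`: data.frame with one row per
#'   file (`file_id`, `forward`, `reverse`, per-flank GC/Tm/score)
#' @export
select_flank_pairs <- function(candidates, n_files = 1L, dimer_threshold = 8L) {
  df <- candidates
  if (!"score" %in% names(df)) df$score <- 0L
  if (nrow(df) < 2L * n_files)
    stop("design error: fewer candidates than 2 * n_files")
  df <- df[order(df$score, df$sequence), , drop = FALSE]
  chosen <- integer(0)
  hex3 <- substr(df$sequence, nchar(df$sequence) - 5L, nchar(df$sequence))
  for (i in seq_len(nrow(df))) {
    if (length(chosen) == 2L * n_files) break
    if (length(chosen)) {
      if (hex3[i] %in% hex3[chosen]) next
      prev <- df$sequence[chosen]
      dimer <- max(vapply(prev, function(p)
        max(.local_scores(c(df$sequence[i], .revcomp_chr(df$sequence[i])), p)),
        numeric(1)))
      if (dimer > dimer_threshold) next
    }
    chosen <- c(chosen, i)
  }
  if (length(chosen) < 2L * n_files)
    stop("design error: not enough mutually compatible flank candidates")
  fwd <- chosen[seq(1L, 2L * n_files, 2L)]
  rev <- chosen[seq(2L, 2L * n_files, 2L)]
  structure(data.frame(file_id = seq_len(n_files) - 1L,
                       forward = df$sequence[fwd], reverse = df$sequence[rev],
                       forward_gc = df$gc[fwd], forward_tm = df$tm[fwd],
                       reverse_gc = df$gc[rev], reverse_tm = df$tm[rev],
                       forward_score = df$score[fwd], reverse_score = df$score[rev],
                       stringsAsFactors = FALSE),
            class = c("flank_pairs", "data.frame"))
}

#' Write a primer sheet
#'
#' TSV with one row per file: id, forward and reverse flank, their GC and
#' Tm. The companion of an encoded library heading to synthesis.
#'
#' @param pairs a `flank_pairs` data.frame
#' @param path output path
#' @export
write_primer_sheet <- function(pairs, path) {
  utils::write.table(as.data.frame(pairs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

.FLANK_POOL_SEED <- 97301L
.FLANK_POOL_SIZE <- 20000L
.FLANK_POOL_HAMMING <- 3L

#' The prebuilt flanking-sequence pool
#'
#' A pool of ~20,000 validated flanking sequences, regenerated
#' deterministically on first use from the documented seed (and cached for
#' the session): candidates from [generate_flank_candidates()] are accepted
#' only when their Hamming distance to every equal-length member already in
#' the pool is at least `hamming_min`. The screens that matter at selection
#' time (3'-hexamer and cross-homology against a concrete encoded pool)
#' are applied per job.
#'
#' @param n pool size (default 20,000)
#' @param seed generation seed (default 97301, the documented pool seed)
#' @param hamming_min minimum mutual Hamming distance between equal-length
#'   members (default 3)
#' @return a `flank_candidates` data.frame with attributes `seed`,
#'   `hamming_min`
#' @export
prebuilt_flank_pool <- function(n = .FLANK_POOL_SIZE, seed = .FLANK_POOL_SEED,
                                hamming_min = .FLANK_POOL_HAMMING) {
  key <- sprintf("pool_%d_%d_%d", n, seed, hamming_min)
  if (!is.null(.oc_env[[key]])) return(.oc_env[[key]])
  raw <- generate_flank_candidates(n = 4L * n, seed = seed)
  envs <- list()
  keep <- logical(nrow(raw))
  seqs <- raw$sequence
  n_acc <- 0L
  for (i in seq_len(nrow(raw))) {
    if (n_acc >= n) break
    s <- seqs[i]
    L <- nchar(s)
    lk <- as.character(L)
    if (is.null(envs[[lk]])) envs[[lk]] <- new.env(parent = emptyenv(), hash = TRUE)
    # pigeonhole: distance < hamming_min (<= hamming_min - 1 mismatches over
    # `hamming_min` blocks) forces one exactly matching block
    bnd <- round(seq(0L, L, length.out = hamming_min + 1L))
    keys <- substring(s, bnd[-length(bnd)] + 1L, bnd[-1L])
    conflict <- unique(unlist(lapply(seq_len(hamming_min), function(b)
      envs[[lk]][[paste0(b, "_", keys[b])]])))
    ok <- TRUE
    if (length(conflict)) {
      for (j in conflict) {
        if (sum(charToRaw(s) != charToRaw(seqs[j])) < hamming_min) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    keep[i] <- TRUE
    n_acc <- n_acc + 1L
    for (b in seq_len(hamming_min)) {
      kk <- paste0(b, "_", keys[b])
      envs[[lk]][[kk]] <- c(envs[[lk]][[kk]], i)
    }
  }
  pool <- raw[keep, , drop = FALSE]
  rownames(pool) <- NULL
  pool$source <- "prebuilt-pool"
  attr(pool, "seed") <- seed
  attr(pool, "hamming_min") <- hamming_min
  class(pool) <- c("flank_candidates", "data.frame")
  .oc_env[[key]] <- pool
  pool
}

#' Write / read a flank pool as FASTA
#'
#' Descriptions carry `gc=...;tm=...`; the first line is a comment header
#' documenting the pool size, seed and Hamming threshold.
#'
#' @param pool a `flank_candidates` data.frame
#' @param path file path
#' @export
write_flank_pool <- function(pool, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("; flank_pool n=%d;seed=%s;hamming_min=%s", nrow(pool),
                     format(attr(pool, "seed")), format(attr(pool, "hamming_min"))), con)
  writeLines(sprintf(">flank_%d gc=%.3f;tm=%.2f\n%s", seq_len(nrow(pool)) - 1L,
                     pool$gc, pool$tm, pool$sequence), con)
  invisible(path)
}

#' @rdname write_flank_pool
#' @export
read_flank_pool <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  structure(data.frame(sequence = unname(seqs), length = nchar(unname(seqs)),
                       gc = gc_fraction(unname(seqs)), tm = oligo_tm(unname(seqs)),
                       source = "prebuilt-pool", stringsAsFactors = FALSE),
            class = c("flank_candidates", "data.frame"))
}
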