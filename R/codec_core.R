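# codec_core: segment byte streams into indexed fragments, merge and
# transcode them into DNA under biochemical constraints, and invert the
# whole process.
#
# Wire format of one encoded string:
#
#   flank_5p | transcode( interleave( frag_1, ..., frag_k ) ) | flank_3p
#
# where each frag is serialized as index || payload || rs_parity (all
# nibble-aligned) and interleave() round-robins the k serialized nibble
# streams (slot order free; the decoder reads each stream's own index
# field). Interleaving at the
# coding-unit level makes every homopolymer run >= 3 nt and every GC window
# depend jointly on all k drawn fragments, which is what lets the
# draw/screen/redraw loop converge: no fragment owns a fixed, possibly
# constraint-violating stretch of the emitted sequence.
#
# Transcoding maps the i-th 4-bit coding unit of the merged stream through
# the pin's odd rule when i is odd and the even rule when i is even
# (1-based), two nucleotides per unit.

#' Encoding configuration
#'
#' Bundles every parameter of an encoding job. The defaults reproduce the
#' oligo-pool setup: 200-nt strings, 20-nt flanks at both ends, two
#' fragments per string, 2 bytes of Reed-Solomon parity per fragment,
#' GC 40-60% / homopolymer <= 4 screening.
#'
#' @param pin a [codec_pin()] (required)
#' @param string_length_nt total emitted string length (default 200)
#' @param rs_bytes Reed-Solomon parity bytes per fragment (default 2)
#' @param redundancy logical; add one-third XOR redundancy (default FALSE)
#' @param fragments_per_string k, fragments merged per string (2, 3 or 4)
#' @param constraints a [constraint_spec()]
#' @param flank_length_nt flank length at each end (default 20; 0 disables)
#' @param flank_5p,flank_3p optional fixed flanking sequences of
#'   `flank_length_nt` nt; designed automatically when NULL
#' @param retry_limit consecutive failed screens a fragment may accumulate
#'   before it is routed to virtual-fragment pairing (default 30)
#' @param seed RNG seed governing every random draw of the job
#' @param job_cap_bytes input size cap (default 20 MiB)
#' @param jobname id stem used for FASTA record names
#' @return an object of class `encode_config`
#' @export
encode_config <- function(pin,
                          string_length_nt = 200L,
                          rs_bytes = 2L,
                          redundancy = FALSE,
                          fragments_per_string = 2L,
                          constraints = constraint_spec(),
                          flank_length_nt = 20L,
                          flank_5p = NULL,
                          flank_3p = NULL,
                          retry_limit = 30L,
                          seed = 1L,
                          job_cap_bytes = 20L * 1024L^2,
                          jobname = "job") {
  stopifnot(inherits(pin, "codec_pin"), inherits(constraints, "constraint_spec"))
  k <- as.integer(fragments_per_string)
  if (!k %in% 2:4) stop("fragments_per_string must be 2, 3 or 4")
  L <- as.integer(string_length_nt)
  Fl <- as.integer(flank_length_nt)
  if (L - 2L * Fl <= 0L) stop("configuration error: string too short for overheads (no payload region)")
  if ((L - 2L * Fl) %% (2L * k) != 0L)
    stop("payload region (string_length_nt - 2*flank_length_nt) must be a multiple of 2*fragments_per_string nt")
  if (!is.null(flank_5p) && nchar(flank_5p) != Fl) stop("flank_5p must have flank_length_nt characters")
  if (!is.null(flank_3p) && nchar(flank_3p) != Fl) stop("flank_3p must have flank_length_nt characters")
  stopifnot(rs_bytes >= 0L, retry_limit >= 1L)
  structure(list(pin = pin, string_length_nt = L, rs_bytes = as.integer(rs_bytes),
                 redundancy = isTRUE(redundancy), k = k, constraints = constraints,
                 flank_length_nt = Fl, flank_5p = flank_5p, flank_3p = flank_3p,
                 retry_limit = as.integer(retry_limit), seed = as.integer(seed),
                 job_cap_bytes = job_cap_bytes, jobname = jobname),
            class = "encode_config")
}

#' @export
print.encode_config <- function(x, ...) {
  cat(sprintf("<encode_config> %d-nt strings, %d-nt flanks, k=%d, rs_bytes=%d, redundancy=%s, seed=%d\n",
              x$string_length_nt, x$flank_length_nt, x$k, x$rs_bytes, x$redundancy, x$seed))
  print(x$constraints)
  invisible(x)
}

#' Per-fragment bit allocation for an encoding job
#'
#' Divides the string's information capacity among the k fragments it
#' carries. The payload region holds `string_length_nt - 2*flank_length_nt`
#' nucleotides = twice that many bits; each fragment receives an equal
#' share, split into an index field (the smallest nibble-aligned width that
#' addresses all data, pad, parity and virtual fragments implied by
#' `data_bytes`), the Reed-Solomon parity field, and the data payload.
#' All three widths are multiples of 4 bits so coding units never straddle
#' fields. Messages too long for one RS block are chunked and the parity
#' field sized accordingly.
#'
#' @param config an [encode_config()]
#' @param data_bytes input size in bytes
#' @return a list: `per_fragment_bits`, `index_bits`, `payload_bits`,
#'   `rs_bits` (total parity bits per fragment), `rs_chunks`,
#'   `rs_pad_bits`, `n_fragments` (data), `n_pad`, `n_parity`,
#'   `n_total` (data+pad+parity), `virtual_start` (first virtual index),
#'   plus `rs_bytes`, `k`
#' @export
length_budget <- function(config, data_bytes) {
  stopifnot(data_bytes >= 1)
  S <- 2L * (config$string_length_nt - 2L * config$flank_length_nt) %/% config$k
  data_bits <- 8 * as.numeric(data_bytes)
  ib <- 4L
  repeat {
    # payload/rs fixpoint at this index width (rs chunk count depends on
    # message length which depends on payload width)
    chunks <- 1L
    repeat {
      rs_bits <- 8L * config$rs_bytes * chunks
      payload_bits <- S - ib - rs_bits
      if (payload_bits <= 0L)
        stop("configuration error: string too short for overheads")
      msg_bytes <- ceiling((ib + payload_bits) / 8)
      need <- if (config$rs_bytes > 0L) ceiling(msg_bytes / (255L - config$rs_bytes)) else 1L
      if (need == chunks) break
      chunks <- need
    }
    n_frag <- ceiling(data_bits / payload_bits)
    n_pad <- if (config$redundancy && n_frag %% 2 == 1) 1L else 0L
    n_parity <- if (config$redundancy) (n_frag + n_pad) %/% 2L else 0L
    n_total <- n_frag + n_pad + n_parity
    # leave headroom above the real fragments for virtual indices
    if (2^ib >= n_total * 1.05 + 8) break
    ib <- ib + 4L
    if (ib > 64L) stop("index width exploded; input too large for this geometry")
  }
  list(per_fragment_bits = S, index_bits = ib, payload_bits = payload_bits,
       rs_bits = rs_bits, rs_chunks = chunks,
       rs_pad_bits = (8L - (ib + payload_bits) %% 8L) %% 8L,
       n_fragments = n_frag, n_pad = n_pad, n_parity = n_parity,
       n_total = n_total, virtual_start = n_total,
       rs_bytes = config$rs_bytes, k = config$k)
}

## ---- fragment construction -------------------------------------------------

#' Segment a byte stream into indexed binary fragments
#'
#' Converts the bytes to a bit stream, splits it into fragments of the
#' payload size implied by the configuration (zero-padding the final
#' fragment), and assigns sequential indices from 0. The true byte length
#' is recorded so decoding can strip the padding.
#'
#' @param data raw vector (non-empty, at most the job cap)
#' @param config an [encode_config()]
#' @return an object of class `fragment_set`: list with `payload` (integer
#'   nibble matrix, one fragment per row), `index` (0-based), `byte_length`
#'   and `budget`
#' @export
segment_payload <- function(data, config) {
  if (!is.raw(data) || length(data) == 0L)
    stop("size error: input must be a non-empty raw vector")
  if (length(data) > config$job_cap_bytes)
    stop(sprintf("size error: input of %d bytes exceeds the %d-byte job cap",
                 length(data), config$job_cap_bytes))
  budget <- length_budget(config, length(data))
  pn <- budget$payload_bits %/% 4L
  nib <- bytes_to_nibbles(data)
  need <- budget$n_fragments * pn
  if (length(nib) < need) nib <- c(nib, integer(need - length(nib)))
  payload <- matrix(nib, nrow = budget$n_fragments, ncol = pn, byrow = TRUE)
  structure(list(payload = payload, index = 0:(budget$n_fragments - 1L),
                 byte_length = length(data), budget = budget),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> %d fragments x %d payload bits (%d input bytes; index %d bits, rs %d bits)\n",
              nrow(x$payload), x$budget$payload_bits, x$byte_length,
              x$budget$index_bits, x$budget$rs_bits))
  invisible(x)
}

# serialize fragments: index||payload||rs_parity as a nibble matrix
.serialize_rows <- function(index, payload, budget) {
  ib_nib <- budget$index_bits %/% 4L
  msg <- cbind(.int_to_nibble_mat(index, ib_nib), payload)
  if (budget$rs_bytes == 0L) return(msg)
  m2 <- if (budget$rs_pad_bits > 0L) cbind(msg, 0L) else msg
  nc <- ncol(m2)
  bytes <- m2[, seq(1L, nc, 2L), drop = FALSE] * 16L + m2[, seq(2L, nc, 2L), drop = FALSE]
  kmax <- 255L - budget$rs_bytes
  par_nib <- NULL
  for (ci in seq_len(budget$rs_chunks)) {
    cols <- ((ci - 1L) * kmax + 1L):min(ci * kmax, ncol(bytes))
    par <- .rs_parity_mat(bytes[, cols, drop = FALSE], budget$rs_bytes)
    pm <- matrix(0L, nrow(par), 2L * ncol(par))
    pm[, seq(1L, ncol(pm), 2L)] <- par %/% 16L
    pm[, seq(2L, ncol(pm), 2L)] <- par %% 16L
    par_nib <- cbind(par_nib, pm)
  }
  cbind(msg, par_nib)
}

## ---- merge / transcode -----------------------------------------------------

# interleave serialized nibble rows (matrix k x Snib stacked as rows) into
# one merged nibble vector / matrix
.interleave_rows <- function(mat_rows) {
  k <- nrow(mat_rows)
  S <- ncol(mat_rows)
  out <- integer(k * S)
  for (j in seq_len(k)) out[seq(j, k * S, k)] <- mat_rows[j, ]
  out
}

#' Merge serialized fragments into one bit string
#'
#' Interleaves the k serialized fragments (index || payload || rs_parity
#' each) at the 4-bit coding-unit level, taking members in ascending-index
#' order: merged unit j comes from member ((j-1) mod k)+1. The merged
#' length is a multiple of 4 bits.
#'
#' @param members list of k equal-length integer bit vectors
#' @param k number of fragments (defaults to `length(members)`)
#' @param index_bits if given, members are first sorted by the integer
#'   value of their leading `index_bits` bits
#' @return integer bit vector of length `k * length(members[[1]])`
#' @seealso [unmerge_fragments()]
#' @export
merge_fragments <- function(members, k = length(members), index_bits = NULL) {
  stopifnot(length(members) == k, k >= 1L)
  lens <- lengths(members)
  if (length(unique(lens)) != 1L) stop("validation error: member bit lengths unequal")
  if (lens[1] %% 4L != 0L) stop("validation error: member bit length not a multiple of 4")
  if (!is.null(index_bits) && k > 1L) {
    idx <- vapply(members, function(b) {
      sum(as.integer(b[seq_len(index_bits)]) * 2^((index_bits - 1):0))
    }, numeric(1))
    members <- members[order(idx)]
  }
  nib <- do.call(rbind, lapply(members, bits_to_nibbles))
  nibbles_to_bits(.interleave_rows(nib))
}

#' Split a merged bit string back into its fragments
#'
#' Inverse of [merge_fragments()].
#'
#' @param bits merged integer bit vector
#' @param k number of interleaved fragments
#' @return list of k serialized fragment bit vectors
#' @export
unmerge_fragments <- function(bits, k) {
  nib <- bits_to_nibbles(bits)
  stopifnot(length(nib) %% k == 0L)
  lapply(seq_len(k), function(j) nibbles_to_bits(nib[seq(j, length(nib), k)]))
}

#' Transcode bits to DNA through a codec pin
#'
#' Splits `bits` into consecutive 4-bit coding units; units at odd ordinal
#' positions (1st, 3rd, ...) map to dinucleotides through the pin's odd
#' rule, even ordinals through the even rule. Two nucleotides per unit.
#'
#' @param bits integer vector of 0/1 (or a "0101..." character string);
#'   length must be a multiple of 4
#' @param pin a [codec_pin()]
#' @return a DNA string of `length(bits)/2` characters
#' @export
transcode <- function(bits, pin) {
  if (is.character(bits)) bits <- as.integer(strsplit(bits, "")[[1]])
  bits <- as.integer(bits)
  if (length(bits) %% 4L != 0L) stop("validation error: bit length not a multiple of 4")
  if (length(bits) == 0L) return("")
  nib <- bits_to_nibbles(bits)
  d <- integer(length(nib))
  odd <- seq(1L, length(nib), 2L)
  d[odd] <- pin$rule_odd$forward[nib[odd] + 1L]
  if (length(nib) > 1L) {
    even <- seq(2L, length(nib), 2L)
    d[even] <- pin$rule_even$forward[nib[even] + 1L]
  }
  paste(paste0(.BASES[d %/% 4L + 1L], .BASES[d %% 4L + 1L]), collapse = "")
}

#' Decode DNA back to bits through a codec pin
#'
#' Inverse of [transcode()] under the same pin. Decoding with a different
#' pin yields different bits, which downstream index/RS/checksum validation
#' rejects.
#'
#' @param seq DNA string (A/C/G/T, even length)
#' @param pin a [codec_pin()]
#' @return integer vector of bits
#' @export
untranscode <- function(seq, pin) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return(integer(0))
  if (nchar(seq) %% 2L != 0L) stop("validation error: sequence length must be even")
  codes <- .base_lookup()[as.integer(charToRaw(seq)) + 1L]
  if (anyNA(codes)) stop("validation error: sequence contains non-ACGT characters")
  d <- 4L * codes[seq(1L, length(codes), 2L)] + codes[seq(2L, length(codes), 2L)]
  nib <- integer(length(d))
  odd <- seq(1L, length(d), 2L)
  nib[odd] <- pin$rule_odd$reverse[d[odd] + 1L]
  if (length(d) > 1L) {
    even <- seq(2L, length(d), 2L)
    nib[even] <- pin$rule_even$reverse[d[even] + 1L]
  }
  nibbles_to_bits(nib)
}

## ---- batch encode machinery ------------------------------------------------

# merged serial rows -> base-code matrix (one emitted payload per row)
.transcode_matrix <- function(M, pin) {
  n <- nrow(M)
  D <- M
  oddc <- seq(1L, ncol(M), 2L)
  D[, oddc] <- matrix(pin$rule_odd$forward[M[, oddc, drop = FALSE] + 1L], n)
  if (ncol(M) > 1L) {
    evenc <- seq(2L, ncol(M), 2L)
    D[, evenc] <- matrix(pin$rule_even$forward[M[, evenc, drop = FALSE] + 1L], n)
  }
  B <- matrix(0L, n, 2L * ncol(M))
  B[, seq(1L, ncol(B), 2L)] <- D %/% 4L
  B[, seq(2L, ncol(B), 2L)] <- D %% 4L
  B
}

# Draw/merge/transcode/screen loop over a pool of serial rows.
# mat: serial nibble matrix (rows indexed by row id); frag_index maps row ->
# fragment index. Virtual rows are appended on demand in the singles phase.
# Returns members (list of fragment-index vectors), payload base-code rows,
# updated mat/frag_index, and counters. Runs inside the caller's seeded RNG.
.encode_pool_loop <- function(mat, frag_index, pool, pin, k, spec, retry_limit,
                              pre_ctx, post_ctx, budget, next_virtual,
                              payload_nib) {
  Snib <- ncol(mat)
  fails <- integer(nrow(mat))
  stubborn <- integer(0)
  members <- list()
  payload_rows <- list()
  attempts <- 0L
  global_budget <- 1000 * max(1, length(pool) %/% k) + 10000
  while (length(pool) >= k) {
    nk <- length(pool) %/% k
    perm <- sample.int(length(pool))
    sel <- pool[perm[seq_len(nk * k)]]
    rest <- pool[perm[-seq_len(nk * k)]]
    # slot order = the draw order. The decoder reads every de-interleaved
    # stream's own index field, so no canonical order is needed on the
    # wire - and fixing one would doom fragments whose leading index
    # nibbles transcode badly in a particular slot (e.g. the universal
    # hi-nibble-zero prefix under near-identity rules).
    tuples <- matrix(sel, nrow = k)
    M <- matrix(0L, nk, k * Snib)
    for (j in seq_len(k)) M[, seq(j, k * Snib, k)] <- mat[tuples[j, ], , drop = FALSE]
    B <- .transcode_matrix(M, pin)
    pass <- .screen_matrix(B, spec, pre_ctx, post_ctx)
    attempts <- attempts + nk
    if (attempts > global_budget)
      stop("encoding error: global attempt budget exhausted (constraints too strict for this pin/geometry)")
    if (any(pass)) {
      acc <- which(pass)
      seqs <- B[acc, , drop = FALSE]
      for (i in seq_along(acc)) {
        members[[length(members) + 1L]] <- frag_index[tuples[, acc[i]]]
      }
      payload_rows[[length(payload_rows) + 1L]] <- seqs
    }
    failed_members <- as.vector(tuples[, !pass, drop = FALSE])
    if (length(failed_members)) fails[failed_members] <- fails[failed_members] + 1L
    now_stubborn <- failed_members[fails[failed_members] >= retry_limit]
    stubborn <- c(stubborn, now_stubborn)
    pool <- c(rest, setdiff(failed_members, now_stubborn))
  }
  # endgame: leftover (< k) and stubborn fragments are paired with freshly
  # generated virtual fragments (random payload, index from the reserved
  # range above the real fragments) and retried until they screen clean.
  # Virtual payload sampling starts uniform and escalates toward the GC
  # complement of the stuck fragment: a low-entropy fragment (e.g. a run
  # of zero bytes) transcodes to a GC-extreme half of the sequence that
  # only a counter-biased partner can pull back into the GC window.
  singles <- c(pool, stubborn)
  n_virtual <- 0L
  gdin <- function(d) (d %/% 4L == 1L | d %/% 4L == 2L) + (d %% 4L == 1L | d %% 4L == 2L)
  g_odd <- gdin(pin$rule_odd$forward)   # GC bases per dinucleotide image, 0..2
  g_even <- gdin(pin$rule_even$forward)
  ib_nib <- budget$index_bits %/% 4L
  # per-nibble sampling weights for a grid of target GC fractions; a
  # virtual nibble drawn at level q has expected image GC exactly q
  q_levels <- seq(0.05, 0.95, by = 0.05)
  w_odd_lv <- vapply(q_levels, function(q) {
    w <- q^g_odd * (1 - q)^(2 - g_odd); w / sum(w)
  }, numeric(16))
  w_even_lv <- vapply(q_levels, function(q) {
    w <- q^g_even * (1 - q)^(2 - g_even); w / sum(w)
  }, numeric(16))
  # centred running mean at the scale of one constraint window's share of
  # a single fragment (window_nt nucleotides / 2k nt per serial position)
  halfspan <- max(3L, as.integer(ceiling(spec$window_nt / (4L * k))))
  run_mean <- function(x) {
    n <- length(x)
    cs <- c(0, cumsum(x))
    lo <- pmax(seq_len(n) - halfspan, 1L)
    hi <- pmin(seq_len(n) + halfspan, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  for (r in singles) {
    done <- FALSE
    nibr <- mat[r, ]
    for (att in seq_len(50L * retry_limit)) {
      # advance the virtual index every few attempts: the index nibbles sit
      # in the emitted sequence, so a violation overlapping them cannot be
      # cleared by payload redraws alone; skipped indices stay unused and
      # are discarded at decode like any virtual index
      vidx <- next_virtual + (k - 1L) * ((att - 1L) %/% 4L) + seq_len(k - 1L) - 1L
      if (any(vidx >= 2^budget$index_bits))
        stop("encoding error: virtual index space exhausted")
      # slot order: ascending on odd attempts, shuffled on even ones. The
      # data fragment's index nibbles are immutable, so a junction/flank
      # conflict overlapping them can only be cleared by moving the
      # fragment out of that slot - legal, because the decoder reads each
      # de-interleaved stream's own index field and never relies on order.
      ord <- if (att %% 2L == 0L) sample.int(k) else seq_len(k)
      # local GC profile of the stuck fragment along its serial positions,
      # under the rules its slot actually meets. The virtual payload is
      # biased per position toward the complement: a fragment can be
      # GC-extreme in one stretch (a run of zero bytes images to a
      # constant dinucleotide) and balanced elsewhere, and no single
      # global bias satisfies both regions at once.
      real_pos <- which(ord == 1L)
      real_units <- (seq_len(Snib) - 1L) * k + real_pos
      g_img <- ifelse(real_units %% 2L == 1L, g_odd[nibr + 1L], g_even[nibr + 1L]) / 2
      gs <- run_mean(g_img)
      esc <- min(1, (att - 1L) / 8)
      qs <- 0.5 + (pmin(0.95, pmax(0.05, 1 - gs)) - 0.5) * esc
      lv <- pmin(length(q_levels), pmax(1L, as.integer(round((qs - 0.05) / 0.05)) + 1L))
      pay_s <- ib_nib + seq_len(payload_nib)
      vpay <- matrix(0L, k - 1L, payload_nib)
      for (jj in seq_len(k - 1L)) {
        vslot <- which(ord == jj + 1L)
        vodd <- ((pay_s - 1L) * k + vslot) %% 2L == 1L
        v <- integer(payload_nib)
        for (lev in unique(lv[pay_s])) {
          sel <- lv[pay_s] == lev
          a <- sel & vodd
          b <- sel & !vodd
          if (any(a)) v[a] <- sample(0:15, sum(a), replace = TRUE, prob = w_odd_lv[, lev])
          if (any(b)) v[b] <- sample(0:15, sum(b), replace = TRUE, prob = w_even_lv[, lev])
        }
        vpay[jj, ] <- v
      }
      vser <- .serialize_rows(vidx, vpay, budget)
      rows <- rbind(mat[r, , drop = FALSE], vser)[ord, , drop = FALSE]
      Mv <- matrix(.interleave_rows(rows), nrow = 1L)
      Bv <- .transcode_matrix(Mv, pin)
      if (.screen_matrix(Bv, spec, pre_ctx, post_ctx)) {
        mat <- rbind(mat, vser)
        frag_index <- c(frag_index, vidx)
        members[[length(members) + 1L]] <- c(frag_index[r], vidx)[order(c(frag_index[r], vidx))]
        payload_rows[[length(payload_rows) + 1L]] <- Bv
        next_virtual <- max(vidx) + 1L
        n_virtual <- n_virtual + (k - 1L)
        done <- TRUE
        break
      }
      attempts <- attempts + 1L
    }
    if (!done)
      stop(sprintf("encoding error: fragment %s could not be emitted within the virtual-fragment budget",
                   format(frag_index[r])))
  }
  list(members = members,
       payload_codes = if (length(payload_rows)) do.call(rbind, payload_rows) else matrix(integer(0), 0L, 0L),
       mat = mat, frag_index = frag_index, next_virtual = next_virtual,
       n_virtual = n_virtual, attempts = attempts)
}

.flank_context <- function(flank, spec, side) {
  if (is.null(flank) || nchar(flank) == 0L) return(integer(0))
  codes <- .base_lookup()[as.integer(charToRaw(flank)) + 1L]
  cap <- spec$max_homopolymer
  if (side == "pre") utils::tail(codes, cap) else utils::head(codes, cap)
}

## ---- encode_file -----------------------------------------------------------

#' Encode a byte stream into constraint-satisfying DNA strings
#'
#' The full encoding pipeline: segment the input into indexed fragments,
#' optionally expand them with one-third XOR redundancy, protect each
#' fragment with Reed-Solomon parity, then repeatedly draw k fragments at
#' random from the pool, merge, transcode with the codec pin and screen
#' against the biochemical constraints; passing draws are emitted and
#' removed from the pool, failing draws are returned to it. A fragment that
#' keeps failing (`retry_limit` consecutive screens) is paired with freshly
#' generated virtual fragments drawn from the reserved top slice of index
#' space. Flanking sequences are attached afterwards; if none are supplied
#' they are designed against the emitted pool (3'-hexamer and
#' cross-homology screens), and any string whose flank/payload junction
#' would create a homopolymer violation is re-encoded with the junction
#' context included in its screen.
#'
#' Deterministic: a fixed `config` (including `seed`) yields bit-identical
#' output.
#'
#' @param data raw vector to store
#' @param config an [encode_config()]
#' @return an object of class `encoded_pool`: list with `sequences` (named
#'   character vector, full strings), `payloads`, `members` (fragment
#'   indices per string), `manifest`, `flank_5p`, `flank_3p`, `n_virtual`,
#'   `attempts`
#' @export
encode_file <- function(data, config) {
  frags <- segment_payload(data, config)
  budget <- frags$budget
  pin <- config$pin
  spec <- config$constraints
  payload_nib <- budget$payload_bits %/% 4L
  # pad + XOR parity payload rows
  payload <- frags$payload
  if (budget$n_pad) payload <- rbind(payload, integer(payload_nib))
  if (config$redundancy && budget$n_parity > 0L) {
    oddr <- payload[seq(1L, budget$n_fragments + budget$n_pad, 2L), , drop = FALSE]
    evenr <- payload[seq(2L, budget$n_fragments + budget$n_pad, 2L), , drop = FALSE]
    payload <- rbind(payload, matrix(bitwXor(oddr, evenr), nrow = nrow(oddr)))
  }
  mat <- .serialize_rows(0:(budget$n_total - 1L), payload, budget)
  frag_index <- 0:(budget$n_total - 1L)

  flank_5p <- config$flank_5p
  flank_3p <- config$flank_3p
  have_flanks <- config$flank_length_nt > 0L && !is.null(flank_5p) && !is.null(flank_3p)

  res <- with_seed(config$seed, {
    pre <- if (have_flanks) .flank_context(flank_5p, spec, "pre") else integer(0)
    post <- if (have_flanks) .flank_context(flank_3p, spec, "post") else integer(0)
    first <- .encode_pool_loop(mat, frag_index, seq_len(nrow(mat)), pin, config$k,
                               spec, config$retry_limit, pre, post, budget,
                               budget$virtual_start, payload_nib)
    members <- first$members
    codes <- first$payload_codes
    n_virtual <- first$n_virtual
    attempts <- first$attempts
    if (config$flank_length_nt > 0L && !have_flanks) {
      payload_seqs <- .codes_to_seq(codes)
      cand <- generate_flank_candidates(n = 120L, seed = config$seed + 1000003L,
                                        fixed_length = config$flank_length_nt)
      # on very large pools every hexamer occurs at some payload 5' end and
      # the screen stops discriminating; fall back to homology ranking alone
      cand <- tryCatch(screen_3prime(cand, payload_seqs), error = function(e) cand)
      cand$score <- cross_homology_score(cand$sequence, payload_seqs, max_pool = 120L)
      # choose the lowest-scoring pair whose junctions stay clean: the
      # slot-1 fragment's leading index nibbles give every payload in a
      # job the same first bases, so an unlucky flank tail can conflict
      # with the whole pool at once; candidate pairs are tried in score
      # order and the one with the fewest junction violations wins
      n_try <- min(6L, nrow(cand) %/% 2L)
      pairs <- select_flank_pairs(cand, n_files = n_try)
      best <- 1L
      best_viol <- Inf
      okj <- NULL
      for (pi in seq_len(nrow(pairs))) {
        ok_pi <- .screen_matrix(codes, spec,
                                .flank_context(pairs$forward[pi], spec, "pre"),
                                .flank_context(pairs$reverse[pi], spec, "post"))
        if (sum(!ok_pi) < best_viol) {
          best <- pi
          best_viol <- sum(!ok_pi)
          okj <- ok_pi
        }
        if (best_viol <= 0.02 * nrow(codes)) break
      }
      flank_5p <- pairs$forward[best]
      flank_3p <- pairs$reverse[best]
      # re-encode any string whose flank junction still violates the cap
      pre <- .flank_context(flank_5p, spec, "pre")
      post <- .flank_context(flank_3p, spec, "post")
      if (!all(okj)) {
        redo_rows <- which(!okj)
        redo_frag_idx <- unlist(members[redo_rows])
        redo_real <- redo_frag_idx[redo_frag_idx < budget$virtual_start]
        rows <- match(redo_real, first$frag_index)
        second <- .encode_pool_loop(first$mat, first$frag_index, rows, pin, config$k,
                                    spec, config$retry_limit, pre, post, budget,
                                    first$next_virtual, payload_nib)
        members <- c(members[okj], second$members)
        codes <- rbind(codes[okj, , drop = FALSE], second$payload_codes)
        n_virtual <- n_virtual + second$n_virtual
        attempts <- attempts + second$attempts
      }
    }
    list(members = members, codes = codes, n_virtual = n_virtual,
         attempts = attempts, flank_5p = flank_5p, flank_3p = flank_3p)
  })

  payloads <- .codes_to_seq(res$codes)
  f5 <- if (config$flank_length_nt > 0L) res$flank_5p else ""
  f3 <- if (config$flank_length_nt > 0L) res$flank_3p else ""
  sequences <- paste0(f5, payloads, f3)
  ids <- sprintf("%s_%d", config$jobname, seq_along(sequences) - 1L)
  names(sequences) <- ids
  names(payloads) <- ids
  manifest <- new_manifest(config, budget, length(data), crc32(data), f5, f3)
  structure(list(sequences = sequences, payloads = payloads, members = res$members,
                 manifest = manifest, flank_5p = f5, flank_3p = f3,
                 n_virtual = res$n_virtual, attempts = res$attempts),
            class = "encoded_pool")
}

#' @export
print.encoded_pool <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<encoded_pool> %d strings x %d nt (%d input bytes; k=%d, rs=%d, redundancy=%s, %d virtual fragment%s)\n",
              length(x$sequences), m$string_length, m$byte_length, m$k, m$rs_bytes,
              m$redundancy, x$n_virtual, if (x$n_virtual == 1L) "" else "s"))
  invisible(x)
}

## ---- decode ----------------------------------------------------------------

# batch RS check of fragment serial nibble rows; returns corrected message
# nibbles, ok flags and per-row correction counts
.rs_check_rows <- function(fmat, budget) {
  n <- nrow(fmat)
  ib_nib <- budget$index_bits %/% 4L
  pn <- budget$payload_bits %/% 4L
  msg_nib <- fmat[, seq_len(ib_nib + pn), drop = FALSE]
  if (budget$rs_bytes == 0L)
    return(list(msg_nib = msg_nib, ok = rep(TRUE, n), nerr = integer(n)))
  par_nib <- fmat[, -seq_len(ib_nib + pn), drop = FALSE]
  m2 <- if (budget$rs_pad_bits > 0L) cbind(msg_nib, 0L) else msg_nib
  nc <- ncol(m2)
  msg_bytes <- m2[, seq(1L, nc, 2L), drop = FALSE] * 16L + m2[, seq(2L, nc, 2L), drop = FALSE]
  ncp <- ncol(par_nib)
  par_bytes <- par_nib[, seq(1L, ncp, 2L), drop = FALSE] * 16L + par_nib[, seq(2L, ncp, 2L), drop = FALSE]
  kmax <- 255L - budget$rs_bytes
  ok <- rep(TRUE, n)
  nerr <- integer(n)
  for (ci in seq_len(budget$rs_chunks)) {
    cols <- ((ci - 1L) * kmax + 1L):min(ci * kmax, ncol(msg_bytes))
    pcols <- ((ci - 1L) * budget$rs_bytes + 1L):(ci * budget$rs_bytes)
    code <- cbind(msg_bytes[, cols, drop = FALSE], par_bytes[, pcols, drop = FALSE])
    syn <- .rs_syndromes_mat(code, budget$rs_bytes)
    dirty <- which(rowSums(syn != 0L) > 0L)
    for (r in dirty) {
      res <- .rs_decode_row(code[r, ], budget$rs_bytes, syn = syn[r, ])
      if (!res$ok) ok[r] <- FALSE
      else {
        nerr[r] <- nerr[r] + res$nerr
        msg_bytes[r, cols] <- res$code[seq_along(cols)]
      }
    }
  }
  out <- matrix(0L, n, 2L * ncol(msg_bytes))
  out[, seq(1L, ncol(out), 2L)] <- msg_bytes %/% 16L
  out[, seq(2L, ncol(out), 2L)] <- msg_bytes %% 16L
  list(msg_nib = out[, seq_len(ib_nib + pn), drop = FALSE], ok = ok, nerr = nerr)
}

#' Decode DNA strings back to the stored byte stream
#'
#' Inverse of [encode_file()]: untranscodes each string with the pin,
#' de-interleaves the k serialized fragments, Reed-Solomon-corrects each
#' fragment (uncorrectable fragments become erasures), discards virtual
#' fragments by their reserved index range, reconstructs missing fragments
#' through the XOR groups, orders data fragments by index, strips the
#' padding using the manifest byte length and verifies the CRC-32 checksum.
#'
#' A decode attempted with the wrong pin collapses at the RS/index
#' validation stage and is reported through `crc_ok = FALSE` and a low
#' recovery fraction rather than an exception.
#'
#' @param strings character vector of encoded strings (with or without
#'   flanks; full-length strings are stripped using the manifest geometry)
#' @param pin the [codec_pin()] used at encode time
#' @param manifest the job manifest (from the `encoded_pool` or the FASTA
#'   header)
#' @return list with `data` (raw vector; zero-filled where unrecoverable)
#'   and `report`: `recovery_fraction` (fraction of original payload bytes
#'   recovered), `unrecoverable_indices` (data fragment indices still
#'   missing), `n_rs_corrected`, `n_rs_failed`, `n_xor_recovered`,
#'   `n_virtual_discarded`, `n_strings_dropped`, `n_duplicates`, `crc_ok`
#' @export
decode_file <- function(strings, pin, manifest) {
  stopifnot(inherits(pin, "codec_pin"))
  budget <- .budget_from_manifest(manifest)
  L <- manifest$string_length
  Fl <- manifest$flank_length
  plen <- L - 2L * Fl
  k <- manifest$k
  nc <- nchar(strings)
  if (Fl > 0L) {
    isfull <- nc == L
    strings[isfull] <- substr(strings[isfull], Fl + 1L, L - Fl)
    nc <- nchar(strings)
  }
  dropped <- sum(nc != plen)
  strings <- strings[nc == plen]
  if (length(strings) == 0L) stop("no strings of the expected payload length to decode")
  B <- .seq_to_codes(strings)
  badchar <- rowSums(is.na(B)) > 0L
  dropped <- dropped + sum(badchar)
  B <- B[!badchar, , drop = FALSE]
  n <- nrow(B)
  # untranscode
  d <- 4L * B[, seq(1L, ncol(B), 2L), drop = FALSE] + B[, seq(2L, ncol(B), 2L), drop = FALSE]
  M <- d
  oddc <- seq(1L, ncol(d), 2L)
  M[, oddc] <- matrix(pin$rule_odd$reverse[d[, oddc, drop = FALSE] + 1L], n)
  evenc <- seq(2L, ncol(d), 2L)
  M[, evenc] <- matrix(pin$rule_even$reverse[d[, evenc, drop = FALSE] + 1L], n)
  # de-interleave k fragment streams
  Snib <- ncol(M) %/% k
  fmat <- matrix(0L, n * k, Snib)
  for (j in seq_len(k)) fmat[(j - 1L) * n + seq_len(n), ] <- M[, seq(j, ncol(M), k), drop = FALSE]
  chk <- .rs_check_rows(fmat, budget)
  ib_nib <- budget$index_bits %/% 4L
  idx <- .nibble_mat_to_int(chk$msg_nib[, seq_len(ib_nib), drop = FALSE])
  pn <- budget$payload_bits %/% 4L
  cutoff <- budget$n_total
  ok <- chk$ok
  n_virtual_discarded <- sum(ok & idx >= cutoff)
  usable <- which(ok & idx < cutoff)
  # when an index is claimed by several fragments, trust the one that
  # needed the fewest RS corrections (a miscorrected fragment can land on
  # a foreign index; the clean copy always reports zero corrections)
  usable <- usable[order(chk$nerr[usable], usable)]
  dup <- duplicated(idx[usable])
  n_duplicates <- sum(dup)
  usable <- usable[!dup]
  # assemble payload matrix over all real fragment slots
  P <- matrix(0L, cutoff, pn)
  present <- rep(FALSE, cutoff)
  P[idx[usable] + 1L, ] <- chk$msg_nib[usable, ib_nib + seq_len(pn), drop = FALSE]
  present[idx[usable] + 1L] <- TRUE
  if (budget$n_pad) present[budget$n_fragments + 1L] <- TRUE  # pad payload is known zero
  # XOR recovery
  n_xor <- 0L
  if (budget$n_parity > 0L) {
    nd <- budget$n_fragments + budget$n_pad
    for (i in seq_len(budget$n_parity)) {
      trio <- c(2L * i - 1L, 2L * i, nd + i)  # 1-based rows
      m <- !present[trio]
      if (sum(m) == 1L) {
        hole <- trio[m]; oth <- trio[!m]
        P[hole, ] <- bitwXor(P[oth[1], ], P[oth[2], ])
        present[hole] <- TRUE
        n_xor <- n_xor + 1L
      }
    }
  }
  data_present <- present[seq_len(budget$n_fragments)]
  unrec <- which(!data_present) - 1L
  nib_stream <- as.vector(t(P[seq_len(budget$n_fragments), , drop = FALSE]))
  bl <- manifest$byte_length
  bytes <- nibbles_to_bytes(nib_stream[seq_len(2L * bl)])
  # byte-level recovery accounting (a byte may straddle two fragments)
  pb <- budget$payload_bits
  b0 <- 8 * (seq_len(bl) - 1)
  f1 <- b0 %/% pb
  f2 <- (b0 + 7) %/% pb
  rec <- data_present[f1 + 1L] & data_present[pmin(f2, budget$n_fragments - 1L) + 1L]
  crc_ok <- identical(crc32(bytes), manifest$crc32)
  frac <- mean(rec)
  if (frac < 1) warning(sprintf("partial recovery: %.2f%% of payload bytes recovered", 100 * frac))
  else if (!crc_ok) warning("checksum mismatch on fully recovered payload - wrong codec pin?")
  list(data = bytes,
       report = list(recovery_fraction = frac,
                     unrecoverable_indices = unrec,
                     n_rs_corrected = sum(chk$nerr[ok]),
                     n_rs_failed = sum(!ok),
                     n_xor_recovered = n_xor,
                     n_virtual_discarded = n_virtual_discarded,
                     n_strings_dropped = dropped,
                     n_duplicates = n_duplicates,
                     crc_ok = crc_ok))
}

## ---- manifest + FASTA interface -------------------------------------------

new_manifest <- function(config, budget, byte_length, crc, flank_5p, flank_3p) {
  structure(list(algorithm = "pairrule", version = 1L,
                 jobname = config$jobname,
                 string_length = config$string_length_nt,
                 flank_length = config$flank_length_nt,
                 k = config$k, rs_bytes = config$rs_bytes,
                 redundancy = config$redundancy,
                 index_bits = budget$index_bits,
                 payload_bits = budget$payload_bits,
                 rs_pad_bits = budget$rs_pad_bits,
                 rs_chunks = budget$rs_chunks,
                 n_fragments = budget$n_fragments,
                 n_pad = budget$n_pad,
                 n_parity = budget$n_parity,
                 byte_length = byte_length,
                 crc32 = crc,
                 min_gc = config$constraints$min_gc,
                 max_gc = config$constraints$max_gc,
                 max_homopolymer = config$constraints$max_homopolymer,
                 window_nt = config$constraints$window_nt,
                 flank_5p = flank_5p, flank_3p = flank_3p),
            class = "oligocodec_manifest")
}

.budget_from_manifest <- function(m) {
  list(per_fragment_bits = m$index_bits + m$payload_bits + 8L * m$rs_bytes * m$rs_chunks,
       index_bits = m$index_bits, payload_bits = m$payload_bits,
       rs_bits = 8L * m$rs_bytes * m$rs_chunks, rs_chunks = m$rs_chunks,
       rs_pad_bits = m$rs_pad_bits, n_fragments = m$n_fragments,
       n_pad = m$n_pad, n_parity = m$n_parity,
       n_total = m$n_fragments + m$n_pad + m$n_parity,
       virtual_start = m$n_fragments + m$n_pad + m$n_parity,
       rs_bytes = m$rs_bytes, k = m$k)
}

#' @export
print.oligocodec_manifest <- function(x, ...) {
  cat("<oligocodec_manifest>\n")
  for (f in names(x)) cat(sprintf("  %-16s %s\n", f, as.character(x[[f]])))
  invisible(x)
}

.MANIFEST_NUMERIC <- c("version", "string_length", "flank_length", "k", "rs_bytes",
                       "index_bits", "payload_bits", "rs_pad_bits", "rs_chunks",
                       "n_fragments", "n_pad", "n_parity", "byte_length",
                       "min_gc", "max_gc", "max_homopolymer", "window_nt")

#' Manifest serialization
#'
#' A manifest travels as a single `key=value;...` line. It contains
#' everything needed to decode *except* the codec pin, which the user must
#' supply separately.
#'
#' @param manifest an `oligocodec_manifest`
#' @return `manifest_to_header` returns a character scalar;
#'   `header_to_manifest` parses one back (unknown keys are ignored with a
#'   warning).
#' @export
manifest_to_header <- function(manifest) {
  vals <- vapply(manifest, function(v) {
    if (is.logical(v)) as.character(as.integer(v))
    else if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE)
    else if (!nzchar(v)) "-" else as.character(v)
  }, character(1))
  paste(paste0(names(manifest), "=", vals), collapse = ";")
}

#' @rdname manifest_to_header
#' @param header a header line (leading ";" and whitespace tolerated)
#' @export
header_to_manifest <- function(header) {
  header <- sub("^[;[:space:]]+", "", header)
  parts <- strsplit(strsplit(header, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  keys <- vapply(parts, `[`, "", 1L)
  vals <- vapply(parts, function(p) paste(p[-1L], collapse = "="), "")
  known <- c("algorithm", "jobname", "redundancy", "crc32", "flank_5p", "flank_3p",
             .MANIFEST_NUMERIC)
  unknown <- setdiff(keys, known)
  if (length(unknown))
    warning("ignoring unknown manifest keys: ", paste(unknown, collapse = ", "))
  m <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% known) next
    m[[k]] <- if (k %in% .MANIFEST_NUMERIC) as.numeric(vals[i])
              else if (k == "redundancy") vals[i] == "1"
              else if (vals[i] == "-") "" else vals[i]
  }
  for (f in c("string_length", "flank_length", "k", "rs_bytes", "index_bits",
              "payload_bits", "rs_pad_bits", "rs_chunks", "n_fragments",
              "n_pad", "n_parity", "max_homopolymer", "window_nt", "version"))
    if (!is.null(m[[f]])) m[[f]] <- as.integer(m[[f]])
  class(m) <- "oligocodec_manifest"
  m
}

#' Write / read an encoded pool as FASTA
#'
#' The first line of the file is a `;`-prefixed comment holding the
#' manifest header (decoding parameters minus the pin); records follow as
#' plain FASTA. Reading uses `Biostrings::readDNAStringSet`, which skips
#' the comment line; the manifest is parsed separately.
#'
#' @param pool an `encoded_pool`
#' @param path output path
#' @return `write_encoded_fasta` returns `path` invisibly;
#'   `read_encoded_fasta` returns a list with `sequences` (named character
#'   vector) and `manifest` (NULL when the file has no header).
#' @export
write_encoded_fasta <- function(pool, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("; ", manifest_to_header(pool$manifest)), con)
  writeLines(paste0(">", names(pool$sequences), "\n", pool$sequences), con)
  invisible(path)
}

#' @rdname write_encoded_fasta
#' @export
read_encoded_fasta <- function(path) {
  first <- readLines(path, n = 1L)
  manifest <- if (startsWith(first, ";")) header_to_manifest(first) else NULL
  ss <- Biostrings::readDNAStringSet(path)
  sequences <- as.character(ss)
  names(sequences) <- names(ss)
  list(sequences = sequences, manifest = manifest)
}
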