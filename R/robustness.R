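# robustness: byte-level Reed-Solomon protection per fragment and XOR
# erasure redundancy across fragments.
#
# The RS code works over GF(2^8) with the primitive polynomial 0x11d and
# generator roots alpha^0..alpha^(n-1) (the convention of the widely used
# byte-oriented RS codecs). n parity bytes detect up to n byte errors and
# correct up to floor(n/2). One byte equates to four nucleotides on the
# wire, so an n-byte code can detect up to 4n substituted bases and fix up
# to 2n of them when the damage is confined to whole code symbols.
#
# Encoding is vectorised across fragments: the systematic LFSR runs once
# per message byte *position*, operating on all fragments at once. Decoding
# computes syndromes the same way and only runs the per-fragment
# Berlekamp-Massey / Chien / Forney machinery on fragments whose syndromes
# are non-zero.

.gf_tables <- function() {
  if (is.null(.oc_env$gf_exp)) {
    exp_t <- integer(512L)
    log_t <- integer(256L)
    x <- 1L
    for (i in 0:254) {
      exp_t[i + 1L] <- x
      log_t[x + 1L] <- i
      x <- bitwShiftL(x, 1L)
      if (x >= 256L) x <- bitwAnd(bitwXor(x, 0x11dL), 255L)
    }
    exp_t[256:510] <- exp_t[1:255]  # wrap so exponent sums need no modulo
    .oc_env$gf_exp <- exp_t
    .oc_env$gf_log <- log_t
  }
  list(exp = .oc_env$gf_exp, log = .oc_env$gf_log)
}

# vectorised GF(256) product (a, b integer vectors, zero-safe)
.gf_mul <- function(a, b) {
  t <- .gf_tables()
  r <- integer(max(length(a), length(b)))
  a <- rep_len(a, length(r)); b <- rep_len(b, length(r))
  nz <- a != 0L & b != 0L
  if (any(nz)) r[nz] <- t$exp[t$log[a[nz] + 1L] + t$log[b[nz] + 1L] + 1L]
  r
}

.gf_inv <- function(a) {
  t <- .gf_tables()
  if (any(a == 0L)) stop("GF(256) inverse of zero")
  t$exp[255L - t$log[a + 1L] + 1L]
}

.gf_pow <- function(p) { # alpha^p, p >= 0
  t <- .gf_tables()
  t$exp[(p %% 255L) + 1L]
}

# polynomial product over GF(256); coefficients high-order first
.gf_poly_mul <- function(p, q) {
  r <- integer(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    if (p[i] == 0L) next
    r[i:(i + length(q) - 1L)] <- bitwXor(r[i:(i + length(q) - 1L)], .gf_mul(p[i], q))
  }
  r
}

.rs_generator <- function(npar) {
  key <- as.character(npar)
  if (is.null(.oc_env$rs_gen)) .oc_env$rs_gen <- list()
  g <- .oc_env$rs_gen[[key]]
  if (is.null(g)) {
    g <- 1L
    for (i in 0:(npar - 1L)) g <- .gf_poly_mul(g, c(1L, .gf_pow(i)))
    .oc_env$rs_gen[[key]] <- g
  }
  g
}

# parity for a message byte matrix (rows = fragments): n x npar
.rs_parity_mat <- function(msg, npar) {
  n <- nrow(msg)
  gen <- .rs_generator(npar)[-1L]  # drop the leading 1
  rem <- matrix(0L, n, npar)
  for (j in seq_len(ncol(msg))) {
    f <- bitwXor(msg[, j], rem[, 1L])
    rem <- cbind(rem[, -1L, drop = FALSE], 0L)
    for (tt in seq_len(npar)) {
      rem[, tt] <- bitwXor(rem[, tt], .gf_mul(f, gen[tt]))
    }
  }
  rem
}

# syndromes of received codeword matrix (message||parity): n x npar
.rs_syndromes_mat <- function(code, npar) {
  n <- nrow(code)
  syn <- matrix(0L, n, npar)
  for (i in 0:(npar - 1L)) {
    a <- .gf_pow(i)
    s <- integer(n)
    for (j in seq_len(ncol(code))) {
      s <- bitwXor(.gf_mul(s, a), code[, j])
    }
    syn[, i + 1L] <- s
  }
  syn
}

# scalar Berlekamp-Massey + Chien + Forney for one codeword.
# Returns list(code, nerr, ok).
.rs_decode_row <- function(code, npar, syn = NULL) {
  if (is.null(syn)) syn <- as.integer(.rs_syndromes_mat(matrix(code, 1L), npar))
  if (all(syn == 0L)) return(list(code = code, nerr = 0L, ok = TRUE))
  N <- length(code)
  # Berlekamp-Massey (coefficients low-order first: Lambda[1] = 1)
  Lam <- 1L; B <- 1L; L <- 0L; m <- 1L; b <- 1L
  for (n0 in 0:(npar - 1L)) {
    d <- syn[n0 + 1L]
    if (L > 0L) {
      for (i in seq_len(min(L, length(Lam) - 1L))) {
        if (n0 - i >= 0L) d <- bitwXor(d, .gf_mul(Lam[i + 1L], syn[n0 - i + 1L]))
      }
    }
    if (d == 0L) {
      m <- m + 1L
    } else if (2L * L <= n0) {
      Told <- Lam
      scale <- .gf_mul(d, .gf_inv(b))
      shifted <- c(integer(m), .gf_mul(B, rep(scale, length(B))))
      len <- max(length(Lam), length(shifted))
      Lam <- bitwXor(c(Lam, integer(len - length(Lam))),
                     c(shifted, integer(len - length(shifted))))
      B <- Told; L <- n0 + 1L - L; b <- d; m <- 1L
    } else {
      scale <- .gf_mul(d, .gf_inv(b))
      shifted <- c(integer(m), .gf_mul(B, rep(scale, length(B))))
      len <- max(length(Lam), length(shifted))
      Lam <- bitwXor(c(Lam, integer(len - length(Lam))),
                     c(shifted, integer(len - length(shifted))))
      m <- m + 1L
    }
  }
  while (length(Lam) > 1L && Lam[length(Lam)] == 0L) Lam <- Lam[-length(Lam)]
  L <- length(Lam) - 1L
  if (L == 0L || L > npar %/% 2L) return(list(code = code, nerr = NA_integer_, ok = FALSE))
  # Chien search: error positions i (0 = last byte), Xi = alpha^i
  pos <- integer(0)
  for (i in 0:(N - 1L)) {
    xinv <- .gf_pow(255L - (i %% 255L))
    v <- 0L; xp <- 1L
    for (cfi in seq_along(Lam)) {
      v <- bitwXor(v, .gf_mul(Lam[cfi], xp))
      xp <- .gf_mul(xp, xinv)
    }
    if (v == 0L) pos <- c(pos, i)
  }
  if (length(pos) != L) return(list(code = code, nerr = NA_integer_, ok = FALSE))
  # Omega = S(x) * Lambda(x) mod x^npar   (S low-order first)
  Sx <- syn
  conv <- integer(npar)
  for (i in seq_along(Sx)) {
    for (j in seq_along(Lam)) {
      k <- i + j - 1L
      if (k <= npar) conv[k] <- bitwXor(conv[k], .gf_mul(Sx[i], Lam[j]))
    }
  }
  # Forney with first root alpha^0: e_i = Xi * Omega(Xi^-1) / Lambda'(Xi^-1)
  out <- code
  for (i in pos) {
    xi <- .gf_pow(i)
    xinv <- .gf_inv(xi)
    om <- 0L; xp <- 1L
    for (cfi in seq_along(conv)) {
      om <- bitwXor(om, .gf_mul(conv[cfi], xp))
      xp <- .gf_mul(xp, xinv)
    }
    dl <- 0L; xp <- 1L  # Lambda'(x) keeps odd-power terms only
    for (cfi in seq(2L, length(Lam), by = 2L)) {
      dl <- bitwXor(dl, .gf_mul(Lam[cfi], xp))
      xp <- .gf_mul(xp, .gf_mul(xinv, xinv))
    }
    if (dl == 0L) return(list(code = code, nerr = NA_integer_, ok = FALSE))
    mag <- .gf_mul(xi, .gf_mul(om, .gf_inv(dl)))
    col <- N - i
    out[col] <- bitwXor(out[col], mag)
  }
  if (any(.rs_syndromes_mat(matrix(out, 1L), npar) != 0L))
    return(list(code = code, nerr = NA_integer_, ok = FALSE))
  list(code = out, nerr = L, ok = TRUE)
}

#' Append Reed-Solomon parity to a fragment bit string
#'
#' Computes `rs_bytes` parity bytes over the fragment's serialized bits
#' (index and payload) and appends them. Bit strings whose length is not a
#' multiple of 8 are zero-padded up to a byte boundary for the parity
#' computation only; the pad is implicit and must be re-applied by
#' [rs_correct()] (the codec records the pad width in its job manifest).
#' Messages longer than `255 - rs_bytes` bytes are transparently chunked.
#'
#' @param bits integer vector of 0/1 (length a multiple of 4)
#' @param rs_bytes number of parity bytes n (0 disables protection)
#' @return integer bit vector: `bits` followed by `8*rs_bytes` parity bits
#'   per chunk
#' @export
rs_append <- function(bits, rs_bytes) {
  stopifnot(rs_bytes >= 0L)
  if (rs_bytes == 0L) return(as.integer(bits))
  pad <- (8L - length(bits) %% 8L) %% 8L
  padded <- c(as.integer(bits), integer(pad))
  msg <- as.integer(nibbles_to_bytes(bits_to_nibbles(padded)))
  kmax <- 255L - rs_bytes
  out_bits <- as.integer(bits)
  for (s in seq(1L, length(msg), by = kmax)) {
    chunk <- msg[s:min(s + kmax - 1L, length(msg))]
    par <- .rs_parity_mat(matrix(chunk, 1L), rs_bytes)
    out_bits <- c(out_bits, nibbles_to_bits(bytes_to_nibbles(as.raw(par))))
  }
  out_bits
}

#' Correct a Reed-Solomon protected fragment
#'
#' Inverse of [rs_append()]: checks and, when possible, corrects the
#' protected bits. Up to `floor(rs_bytes/2)` byte errors per chunk are
#' corrected; uncorrectable chunks set `ok = FALSE` (no exception), letting
#' the caller treat the fragment as an erasure for XOR recovery.
#'
#' @param bits integer bit vector as produced by [rs_append()]
#' @param rs_bytes number of parity bytes used at encode time
#' @param message_bits length of the protected message in bits (defaults to
#'   `length(bits) - 8*rs_bytes` for single-chunk fragments)
#' @return list with `bits` (corrected message bits, parity stripped),
#'   `n_corrected` (bytes fixed, NA when `ok` is FALSE) and `ok`
#' @export
rs_correct <- function(bits, rs_bytes, message_bits = NULL) {
  bits <- as.integer(bits)
  if (rs_bytes == 0L) return(list(bits = bits, n_corrected = 0L, ok = TRUE))
  if (is.null(message_bits)) message_bits <- length(bits) - 8L * rs_bytes
  stopifnot(message_bits > 0L)
  msg_bits <- bits[seq_len(message_bits)]
  par_bits <- bits[-seq_len(message_bits)]
  pad <- (8L - message_bits %% 8L) %% 8L
  msg <- as.integer(nibbles_to_bytes(bits_to_nibbles(c(msg_bits, integer(pad)))))
  par <- as.integer(nibbles_to_bytes(bits_to_nibbles(par_bits)))
  kmax <- 255L - rs_bytes
  n_chunks <- ceiling(length(msg) / kmax)
  stopifnot(length(par) == n_chunks * rs_bytes)
  fixed <- integer(0)
  nerr <- 0L
  ok <- TRUE
  for (ci in seq_len(n_chunks)) {
    chunk <- msg[(((ci - 1L) * kmax + 1L):min(ci * kmax, length(msg)))]
    p <- par[((ci - 1L) * rs_bytes + 1L):(ci * rs_bytes)]
    res <- .rs_decode_row(c(chunk, p), rs_bytes)
    if (!res$ok) { ok <- FALSE; fixed <- c(fixed, chunk) }
    else { nerr <- nerr + res$nerr; fixed <- c(fixed, res$code[seq_along(chunk)]) }
  }
  out_bits <- nibbles_to_bits(bytes_to_nibbles(as.raw(fixed)))
  out_bits <- out_bits[seq_len(message_bits)]
  list(bits = out_bits, n_corrected = if (ok) nerr else NA_integer_, ok = ok)
}

## ---- XOR erasure redundancy ------------------------------------------------

#' Expand fragments with XOR parity
#'
#' For each consecutive pair of payloads, emits a parity payload equal to
#' their bitwise XOR, generating one-third redundancy in the total data. An
#' odd payload count is padded with an all-zero payload (recorded in the
#' returned object and discarded at decode). Parity fragments are peers of
#' data fragments: the codec gives them their own indices (a contiguous
#' block after the data indices) and their own RS parity.
#'
#' @param payloads list of equal-length integer bit vectors, or an integer
#'   matrix with one payload per row
#' @return list with `payloads` (input plus pad, then parity payloads, as a
#'   list), `groups` (data.frame `member_a`, `member_b`, `parity`; 0-based
#'   positions into the expanded list) and `n_pad` (0 or 1)
#' @export
xor_expand <- function(payloads) {
  if (is.matrix(payloads)) payloads <- lapply(seq_len(nrow(payloads)), function(i) payloads[i, ])
  stopifnot(length(payloads) >= 1L)
  lens <- lengths(payloads)
  if (length(unique(lens)) != 1L) stop("payloads must all have the same bit length")
  n0 <- length(payloads)
  n_pad <- n0 %% 2L
  if (n_pad) payloads <- c(payloads, list(integer(lens[1])))
  n <- length(payloads)
  parity <- vector("list", n %/% 2L)
  for (i in seq_len(n %/% 2L)) {
    parity[[i]] <- bitwXor(as.integer(payloads[[2L * i - 1L]]),
                           as.integer(payloads[[2L * i]]))
  }
  groups <- data.frame(member_a = seq(0L, n - 1L, 2L),
                       member_b = seq(1L, n - 1L, 2L),
                       parity = n + seq_len(n %/% 2L) - 1L)
  list(payloads = c(payloads, parity), groups = groups, n_pad = n_pad)
}

#' Recover missing fragments through XOR groups
#'
#' For each (member_a, member_b, parity) triple with exactly one member
#' missing, reconstructs it as the XOR of the two present members. Triples
#' with two or more missing members are reported unrecoverable.
#'
#' @param payloads list of integer bit vectors with `NULL` for missing
#'   entries (positions match the 0-based indices in `groups`)
#' @param groups group table as returned by [xor_expand()]
#' @return list with `payloads` (completed where possible) and
#'   `unrecoverable` (0-based positions that remain missing)
#' @export
xor_recover <- function(payloads, groups) {
  miss <- vapply(payloads, is.null, logical(1))
  for (r in seq_len(nrow(groups))) {
    trio <- c(groups$member_a[r], groups$member_b[r], groups$parity[r]) + 1L
    m <- miss[trio]
    if (sum(m) == 1L) {
      hole <- trio[m]
      others <- trio[!m]
      payloads[[hole]] <- bitwXor(as.integer(payloads[[others[1]]]),
                                  as.integer(payloads[[others[2]]]))
      miss[hole] <- FALSE
    }
  }
  list(payloads = payloads, unrecoverable = which(miss) - 1L)
}
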