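# Internal helpers shared across modules: bit/nibble packing, seeded
# evaluation, CRC-32, and base-code conversions.
#
# Conventions used throughout the package:
#   * bases are coded 0=A, 1=C, 2=G, 3=T (alphabetical order)
#   * a dinucleotide code d in 0..15 is 4*first_base + second_base, so the
#     canonical dinucleotide order AA,AC,AG,AT,CA,...,TT is d = 0..15
#   * a nibble is an integer 0..15 holding four bits, most significant first

.oc_env <- new.env(parent = emptyenv())

.BASES <- c("A", "C", "G", "T")

#' @noRd
.base_lookup <- function() {
  if (is.null(.oc_env$base_lookup)) {
    lk <- rep(NA_integer_, 256L)
    lk[as.integer(charToRaw("A")) + 1L] <- 0L
    lk[as.integer(charToRaw("C")) + 1L] <- 1L
    lk[as.integer(charToRaw("G")) + 1L] <- 2L
    lk[as.integer(charToRaw("T")) + 1L] <- 3L
    .oc_env$base_lookup <- lk
  }
  .oc_env$base_lookup
}

# character vector of equal-length sequences -> integer base-code matrix
# (one row per sequence); NA codes flag non-ACGT symbols
.seq_to_codes <- function(seqs) {
  n <- length(seqs)
  if (n == 0L) return(matrix(integer(0), 0L, 0L))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must have equal length")
  rw <- charToRaw(paste(seqs, collapse = ""))
  codes <- .base_lookup()[as.integer(rw) + 1L]
  matrix(codes, nrow = n, ncol = L, byrow = TRUE)
}

# integer base-code matrix (rows = sequences) -> character vector
.codes_to_seq <- function(mat) {
  if (nrow(mat) == 0L) return(character(0))
  rawmap <- charToRaw(paste(.BASES, collapse = ""))
  rw <- rawmap[t(mat) + 1L]
  big <- rawToChar(rw)
  L <- ncol(mat)
  substring(big, (seq_len(nrow(mat)) - 1L) * L + 1L, seq_len(nrow(mat)) * L)
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

## ---- bit / nibble packing --------------------------------------------------

bytes_to_nibbles <- function(bytes) {
  v <- as.integer(bytes)
  as.vector(rbind(v %/% 16L, v %% 16L))
}

nibbles_to_bytes <- function(nib) {
  stopifnot(length(nib) %% 2L == 0L)
  hi <- nib[seq(1L, length(nib), 2L)]
  lo <- nib[seq(2L, length(nib), 2L)]
  as.raw(hi * 16L + lo)
}

bits_to_nibbles <- function(bits) {
  stopifnot(length(bits) %% 4L == 0L)
  m <- matrix(as.integer(bits), nrow = 4L)
  as.integer(m[1L, ] * 8L + m[2L, ] * 4L + m[3L, ] * 2L + m[4L, ])
}

nibbles_to_bits <- function(nib) {
  nib <- as.integer(nib)
  as.vector(rbind(nib %/% 8L, (nib %/% 4L) %% 2L, (nib %/% 2L) %% 2L, nib %% 2L))
}

# integers (0-based, possibly > 2^31 as doubles) -> nibble matrix, one row
# per value, `width` nibbles, most significant first
.int_to_nibble_mat <- function(x, width) {
  out <- matrix(0L, nrow = length(x), ncol = width)
  v <- as.numeric(x)
  for (j in seq(width, 1L)) {
    out[, j] <- as.integer(v %% 16)
    v <- v %/% 16
  }
  out
}

.nibble_mat_to_int <- function(mat) {
  v <- numeric(nrow(mat))
  for (j in seq_len(ncol(mat))) v <- v * 16 + mat[, j]
  v
}

## ---- CRC-32 ----------------------------------------------------------------

.crc_table <- function() {
  if (is.null(.oc_env$crc_table)) {
    poly <- -306674912L  # 0xEDB88320 as a signed 32-bit pattern
    tab <- integer(256L)
    for (i in 0:255) {
      c <- i
      for (k in 1:8) {
        c <- if (bitwAnd(c, 1L) != 0L) bitwXor(bitwShiftR(c, 1L), poly) else bitwShiftR(c, 1L)
      }
      tab[i + 1L] <- c
    }
    .oc_env$crc_table <- tab
  }
  .oc_env$crc_table
}

#' CRC-32 checksum of a raw vector
#'
#' Standard IEEE CRC-32 (reflected, polynomial 0xEDB88320), returned as an
#' 8-character lowercase hex string. Used as the payload checksum in job
#' manifests so that a decode with the wrong codec pin is detected even when
#' no Reed-Solomon parity is present.
#'
#' @param bytes raw vector
#' @return character scalar, 8 hex digits
#' @export
crc32 <- function(bytes) {
  stopifnot(is.raw(bytes))
  tab <- .crc_table()
  crc <- -1L
  v <- as.integer(bytes)
  for (b in v) {
    crc <- bitwXor(bitwShiftR(crc, 8L), tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  crc <- bitwXor(crc, -1L)
  u <- as.numeric(crc)
  if (u < 0) u <- u + 4294967296
  sprintf("%04x%04x", u %/% 65536, u %% 65536)
}
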