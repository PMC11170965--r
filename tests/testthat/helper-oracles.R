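# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: a recursive factorial-number-system unranker, a
# bit-by-bit ("peasant") GF(256) multiplier with long-division RS parity and
# an exhaustive single-error decoder, a quadratic Smith-Waterman DP, and a
# brute-force hexamer screen.

# recursive Lehmer unranking over symbols 0..n-1 (lexicographic)
oracle_unrank <- function(idx, n) {
  if (n == 1L) return(0L)
  f <- factorial(n - 1)
  d <- idx %/% f
  rest <- oracle_unrank(idx %% f, n - 1L)
  symbols <- 0:(n - 1L)
  first <- symbols[d + 1]
  remaining <- symbols[-(d + 1)]
  c(first, remaining[rest + 1L])
}

# all permutations of 0:(n-1) in lexicographic order (tiny n only)
oracle_all_perms <- function(n) {
  if (n == 1L) return(matrix(0L, 1L, 1L))
  sub <- oracle_all_perms(n - 1L)
  out <- NULL
  symbols <- 0:(n - 1L)
  for (d in seq_len(n)) {
    first <- symbols[d]
    remaining <- symbols[-d]
    block <- cbind(first, matrix(remaining[sub + 1L], nrow(sub), n - 1L))
    out <- rbind(out, block)
  }
  unname(out)
}

## ---- GF(256) / Reed-Solomon oracle ----------------------------------------

oracle_gf_mul <- function(a, b) {
  r <- 0L
  while (b > 0L) {
    if (bitwAnd(b, 1L) == 1L) r <- bitwXor(r, a)
    a <- bitwShiftL(a, 1L)
    if (a >= 256L) a <- bitwAnd(bitwXor(a, 0x11dL), 255L)
    b <- bitwShiftR(b, 1L)
  }
  r
}

oracle_gf_pow_alpha <- function(p) {
  r <- 1L
  for (i in seq_len(p)) r <- oracle_gf_mul(r, 2L)
  r
}

oracle_rs_generator <- function(npar) {
  g <- 1L
  for (i in 0:(npar - 1L)) {
    root <- oracle_gf_pow_alpha(i)
    # multiply g by (x + root)
    g2 <- integer(length(g) + 1L)
    for (j in seq_along(g)) {
      g2[j] <- bitwXor(g2[j], g[j])
      g2[j + 1L] <- bitwXor(g2[j + 1L], oracle_gf_mul(g[j], root))
    }
    g <- g2
  }
  g
}

# parity by polynomial long division of msg * x^npar by the generator
oracle_rs_parity <- function(msg, npar) {
  gen <- oracle_rs_generator(npar)
  buf <- c(as.integer(msg), integer(npar))
  for (i in seq_len(length(msg))) {
    lead <- buf[i]
    if (lead == 0L) next
    for (j in seq_along(gen)) {
      buf[i + j - 1L] <- bitwXor(buf[i + j - 1L], oracle_gf_mul(gen[j], lead))
    }
  }
  utils::tail(buf, npar)
}

oracle_rs_valid <- function(code, npar) {
  msg <- code[seq_len(length(code) - npar)]
  identical(as.integer(oracle_rs_parity(msg, npar)),
            as.integer(utils::tail(code, npar)))
}

# exhaustive nearest-codeword search for single-byte errors (t = 1)
oracle_rs_decode1 <- function(code, npar) {
  if (oracle_rs_valid(code, npar)) return(list(code = code, nerr = 0L, ok = TRUE))
  for (p in seq_along(code)) {
    orig <- code[p]
    for (v in 0:255) {
      if (v == orig) next
      cand <- code
      cand[p] <- v
      if (oracle_rs_valid(cand, npar)) return(list(code = cand, nerr = 1L, ok = TRUE))
    }
  }
  list(code = code, nerr = NA_integer_, ok = FALSE)
}

## ---- alignment / screening oracles ----------------------------------------

# quadratic local-alignment DP: match +1, mismatch -1, gap -2
oracle_smith_waterman <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  H <- matrix(0, length(A) + 1L, length(B) + 1L)
  best <- 0
  for (i in seq_along(A)) {
    for (j in seq_along(B)) {
      sc <- max(0,
                H[i, j] + if (A[i] == B[j]) 1 else -1,
                H[i, j + 1L] - 2,
                H[i + 1L, j] - 2)
      H[i + 1L, j + 1L] <- sc
      if (sc > best) best <- sc
    }
  }
  best
}

oracle_hexamer_survivors <- function(candidates, pool) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(pool)))
  forbidden <- unique(c(substr(pool, 1, 6), substr(rc, 1, 6)))
  keep <- !substr(candidates, nchar(candidates) - 5, nchar(candidates)) %in% forbidden
  candidates[keep]
}

## ---- misc helpers ----------------------------------------------------------

random_bytes <- function(n, seed) {
  set.seed(seed)
  as.raw(sample(0:255, n, replace = TRUE))
}

# a uniformly random pin (distant rules with overwhelming probability)
random_pin <- function(seed) {
  set.seed(seed)
  codec_pin(index_of_rule(sample(0:15)), index_of_rule(sample(0:15)))
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
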