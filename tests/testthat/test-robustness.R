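test_that("table-driven GF(256) arithmetic matches the peasant-multiplication oracle", {
  set.seed(31)
  a <- sample(0:255, 300, TRUE)
  b <- sample(0:255, 300, TRUE)
  want <- mapply(oracle_gf_mul, a, b)
  expect_identical(oligocodec:::.gf_mul(a, b), as.integer(want))
})

test_that("RS parity matches independent long-division encoding", {
  set.seed(32)
  for (npar in c(2L, 4L)) {
    for (trial in 1:10) {
      msg <- sample(0:255, sample(5:25, 1), TRUE)
      got <- as.integer(oligocodec:::.rs_parity_mat(matrix(msg, 1), npar))
      expect_identical(got, as.integer(oracle_rs_parity(msg, npar)))
    }
  }
})

test_that("rs_append with zero parity is the identity", {
  bits <- sample(0:1, 64, TRUE)
  expect_identical(rs_append(bits, 0L), as.integer(bits))
})

test_that("RS corrects exactly up to n/2 byte errors and never restores past it", {
  set.seed(33)
  for (npar in c(2L, 4L, 6L)) {
    t <- npar %/% 2L
    for (trial in 1:15) {
      bits <- sample(0:1, 8L * sample(6:20, 1), TRUE)
      prot <- rs_append(bits, npar)
      clean <- rs_correct(prot, npar)
      expect_true(clean$ok)
      expect_identical(clean$n_corrected, 0L)
      expect_identical(clean$bits, as.integer(bits))
      # corrupt exactly t whole bytes
      nb <- length(prot) %/% 8L
      pos <- sample(nb, t)
      bad <- prot
      for (p in pos) {
        span <- ((p - 1L) * 8L + 1L):(p * 8L)
        repeat {
          newbits <- sample(0:1, 8L, TRUE)
          if (!identical(as.integer(newbits), as.integer(bad[span]))) break
        }
        bad[span] <- newbits
      }
      fixed <- rs_correct(bad, npar)
      expect_true(fixed$ok)
      expect_identical(fixed$bits, as.integer(bits))
      expect_identical(fixed$n_corrected, t)
      # t+1 byte errors can never be silently corrected back to the original
      pos2 <- sample(nb, t + 1L)
      bad2 <- prot
      for (p in pos2) {
        span <- ((p - 1L) * 8L + 1L):(p * 8L)
        bad2[span] <- bitwXor(as.integer(bad2[span]),
                              c(1L, sample(0:1, 7L, TRUE)))
      }
      over <- rs_correct(bad2, npar)
      expect_false(over$ok && identical(over$bits, as.integer(bits)))
    }
  }
})

test_that("package decoding agrees with the exhaustive single-error oracle", {
  set.seed(34)
  for (trial in 1:12) {
    msg <- sample(0:255, 10, TRUE)
    par <- as.integer(oligocodec:::.rs_parity_mat(matrix(msg, 1), 2L))
    code <- c(msg, par)
    p <- sample(length(code), 1)
    bad <- code
    bad[p] <- bitwXor(bad[p], sample(1:255, 1))
    got <- oligocodec:::.rs_decode_row(bad, 2L)
    want <- oracle_rs_decode1(bad, 2L)
    expect_true(got$ok)
    expect_identical(got$code, as.integer(want$code))
    expect_identical(got$code, code)
  }
})

test_that("xor_expand produces the arithmetic parity and one-third redundancy", {
  out <- xor_expand(list(c(1L, 0L, 1L, 0L), c(0L, 1L, 1L, 0L)))
  expect_identical(out$payloads[[3]], c(1L, 1L, 0L, 0L))
  expect_identical(out$n_pad, 0L)
  set.seed(35)
  pls <- lapply(1:10, function(i) sample(0:1, 16, TRUE))
  out2 <- xor_expand(pls)
  expect_length(out2$payloads, 15L)   # 2N data -> N parity, total 3N
  expect_identical(nrow(out2$groups), 5L)
  # odd counts get one zero pad
  out3 <- xor_expand(pls[1:9])
  expect_identical(out3$n_pad, 1L)
  expect_identical(out3$payloads[[10]], integer(16))
})

test_that("xor_recover restores any single missing member per triple", {
  set.seed(36)
  pls <- lapply(1:12, function(i) sample(0:1, 20, TRUE))
  ex <- xor_expand(pls)
  for (rep in 1:10) {
    holes <- vapply(seq_len(nrow(ex$groups)), function(g) {
      sample(c(ex$groups$member_a[g], ex$groups$member_b[g], ex$groups$parity[g]), 1)
    }, numeric(1))
    broken <- ex$payloads
    for (h in holes) broken[h + 1] <- list(NULL)
    rec <- xor_recover(broken, ex$groups)
    expect_length(rec$unrecoverable, 0L)
    expect_identical(rec$payloads, ex$payloads)
  }
  # both data members of one triple missing -> only that pair unrecoverable
  broken <- ex$payloads
  broken[ex$groups$member_a[2] + 1] <- list(NULL)
  broken[ex$groups$member_b[2] + 1] <- list(NULL)
  broken[ex$groups$parity[4] + 1] <- list(NULL)
  rec <- xor_recover(broken, ex$groups)
  expect_setequal(rec$unrecoverable, c(ex$groups$member_a[2], ex$groups$member_b[2]))
})

test_that("nothing-missing recovery is the identity", {
  pls <- lapply(1:4, function(i) rep(c(0L, 1L), 8))
  ex <- xor_expand(pls)
  rec <- xor_recover(ex$payloads, ex$groups)
  expect_identical(rec$payloads, ex$payloads)
  expect_length(rec$unrecoverable, 0L)
})
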