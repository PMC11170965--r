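# a tiny encoded pool shared by the pipeline tests
local_pool <- local({
  pin <- codec_pin(31337, 271828)
  cfg <- encode_config(pin, redundancy = TRUE, seed = 91, jobname = "pl")
  data <- random_bytes(6000, 92)
  pool <- encode_file(data, cfg)
  list(pin = pin, data = data, pool = pool)
})

test_that("flank filtering assigns, reorients, and drops by mismatch count", {
  pool <- local_pool$pool
  man <- pool$manifest
  f5 <- man$flank_5p; f3 <- man$flank_3p
  payload <- substr(pool$sequences[1], 21, 180)
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  fwd <- paste0(f5, payload, f3)
  rev <- rc(fwd)
  # three mismatches in the 5' flank
  broken <- paste0(corrupt_string(f5, 3, seed = 93), payload, f3)
  q <- strrep("I", 200)
  reads <- read_set(c(fwd, rev, broken), c(q, q, q))
  out <- filter_by_flank(reads, man)
  expect_identical(nrow(out), 2L)
  expect_identical(attr(out, "n_dropped"), 1L)
  expect_true(all(out$sequence == fwd))   # reverse read reoriented
  expect_true(all(out$file_id == 0L))
})

test_that("the quality filter applies the literal over-80%-below-Q30 rule", {
  L <- 100L
  mk_q <- function(n_low) {
    paste0(strrep(rawToChar(as.raw(20 + 33)), n_low),      # Q20
           strrep(rawToChar(as.raw(40 + 33)), L - n_low))  # Q40
  }
  reads <- read_set(rep(random_dna(L, seed = 94), 3),
                    c(mk_q(81L), mk_q(80L), mk_q(0L)))
  kept <- quality_filter(reads)
  expect_identical(nrow(kept), 2L)              # 81% low removed
  expect_true(all(kept$quality %in% c(mk_q(80L), mk_q(0L))))  # exactly 80% kept
})

test_that("the length filter keeps the modal length, ties toward the manifest", {
  seqs <- c(vapply(1:9, function(i) random_dna(200), ""),
            vapply(1:5, function(i) random_dna(199), ""),
            vapply(1:5, function(i) random_dna(201), ""))
  reads <- read_set(seqs, vapply(nchar(seqs), function(n) strrep("I", n), ""))
  out <- length_mode_filter(reads)
  expect_true(all(nchar(out$sequence) == 200L))
  # bimodal tie resolved toward the expected length
  seqs2 <- c(vapply(1:5, function(i) random_dna(200), ""),
             vapply(1:5, function(i) random_dna(150), ""))
  reads2 <- read_set(seqs2, vapply(nchar(seqs2), function(n) strrep("I", n), ""))
  out2 <- length_mode_filter(reads2, expected_length = 200L)
  expect_true(all(nchar(out2$sequence) == 200L))
  expect_error(length_mode_filter(read_set(character(0), character(0))), "pipeline error")
})

test_that("ranking is count-primary with quality tiebreak and is stable", {
  s1 <- random_dna(50, seed = 95)
  s2 <- random_dna(50, seed = 96)
  q <- strrep("I", 50)
  reads <- read_set(c(rep(s1, 10), rep(s2, 2)), rep(q, 12))
  rk <- rank_reads(reads)
  expect_identical(rk$sequence[1], s1)
  expect_identical(rk$order_score[1], 1L)
  expect_identical(rk$count, c(10L, 2L))
  # single sequence -> score 1
  rk1 <- rank_reads(read_set(s1, q))
  expect_identical(rk1$order_score, 1L)
  # equal counts ranked by quality
  qhi <- strrep(rawToChar(as.raw(40 + 33)), 50)
  qlo <- strrep(rawToChar(as.raw(30 + 33)), 50)
  rk2 <- rank_reads(read_set(c(s1, s2), c(qlo, qhi)))
  expect_identical(rk2$sequence[1], s2)
  expect_identical(rank_reads(reads), rk)   # deterministic
})

test_that("clustering joins near-duplicates and separates distant sequences", {
  s <- random_dna(200, seed = 97)
  cl <- cluster_and_select(rep(s, 5))
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$representative, s)
  far <- random_dna(200, seed = 98)
  cl2 <- cluster_and_select(c(s, far))
  expect_identical(nrow(cl2), 2L)
  # variants within the radius join their true string's cluster
  variants <- vapply(1:8, function(i) corrupt_string(s, i %% 4 + 1, seed = 990 + i), "")
  rk <- data.frame(sequence = c(s, variants, far), count = c(10L, rep(1L, 8), 4L),
                   order_score = 1:10, stringsAsFactors = FALSE)
  cl3 <- cluster_and_select(rk)
  expect_identical(nrow(cl3), 2L)
  expect_setequal(cl3$representative, c(s, far))
  expect_identical(cl3$n_reads[cl3$representative == s], 18L)
})

test_that("representatives recover the true strings from simulated reads", {
  pool <- local_pool$pool
  model <- noise_model(substitution_rate = 0.005, depth = 30, seed = 99)
  reads <- simulate_reads(pool, model)
  fb <- filter_by_flank(reads, pool$manifest)
  lf <- length_mode_filter(quality_filter(fb), 200L)
  cl <- cluster_and_select(rank_reads(lf))
  hits <- cl$representative %in% pool$sequences
  expect_gte(sum(hits), length(pool$sequences) - 1L)
  expect_identical(nrow(cl), length(pool$sequences))
})

test_that("recover_file survives noise, dropout and low depth", {
  pin <- local_pool$pin
  pool <- local_pool$pool
  # noiseless at 5x
  m0 <- noise_model(substitution_rate = 0, depth = 5, seed = 101)
  r0 <- recover_file(simulate_reads(pool, m0), pool$manifest, pin)
  expect_identical(r0$data, local_pool$data)
  expect_identical(r0$report$recovery_fraction, 1)
  # noisy, three strings missing, redundancy on
  m3 <- noise_model(substitution_rate = 0.005, depth = 30, dropout_strings = 3, seed = 102)
  r3 <- recover_file(simulate_reads(pool, m3), pool$manifest, pin)
  expect_identical(r3$data, local_pool$data)
  expect_true(r3$report$crc_ok)
  expect_gte(r3$report$n_xor_recovered, 1L)
})

test_that("recovery is non-decreasing in sequencing depth", {
  pin <- local_pool$pin
  pool <- local_pool$pool
  byte_acc <- function(depth, seed) {
    m <- noise_model(substitution_rate = 0.005, depth = depth, seed = seed)
    r <- tryCatch(
      suppressWarnings(recover_file(simulate_reads(pool, m), pool$manifest, pin)),
      error = function(e) NULL)
    if (is.null(r)) return(0)
    mean(r$data == local_pool$data)
  }
  acc <- vapply(c(2, 5, 10, 30), function(d) {
    mean(vapply(1:2, function(s) byte_acc(d, 200 + s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(acc) >= -0.005))
  expect_gte(acc[4], 0.999)
})

test_that("recovering with the wrong pin fails the checksum", {
  pool <- local_pool$pool
  wrong <- random_pin(103)
  m <- noise_model(substitution_rate = 0, depth = 10, seed = 104)
  r <- suppressWarnings(recover_file(simulate_reads(pool, m), pool$manifest, wrong))
  expect_false(r$report$crc_ok)
})

test_that("FASTQ files round-trip through the Biostrings reader", {
  pool <- local_pool$pool
  m <- noise_model(substitution_rate = 0.01, depth = 3, seed = 105)
  reads <- simulate_reads(pool, m)
  path <- tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_identical(back$sequence, reads$sequence)
  expect_identical(back$quality, reads$quality)
  expect_identical(back$read_id, reads$read_id)
})
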