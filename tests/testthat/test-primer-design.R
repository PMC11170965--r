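test_that("nearest-neighbor Tm reproduces frozen reference values", {
  # reference values computed with an independent implementation of the
  # same unified nearest-neighbor model (0.25 uM oligo, 50 mM Na+)
  ref <- c(ACGTTGCAACGTTGCAACGT = 59.0226,
           ATGCATGCATGCATGCATGCATGCA = 63.4362,
           GGCCAATTGGCCAATTGGCC = 59.5437,
           TATATATATACGCGCGCGCG = 55.0115)
  got <- oligo_tm(names(ref))
  expect_true(all(abs(got - unname(ref)) < 0.5))
  expect_true(all(abs(got - unname(ref)) < 0.01))
})

test_that("generated candidates satisfy every primer acceptance range", {
  cand <- generate_flank_candidates(n = 150, seed = 12)
  expect_gte(nrow(cand), 100L)
  expect_true(all(cand$length >= 20 & cand$length <= 25))
  expect_true(all(cand$gc >= 0.4 - 1e-9 & cand$gc <= 0.6 + 1e-9))
  expect_true(all(cand$tm >= 58 & cand$tm <= 70))
  expect_false(any(grepl("AAAAA|CCCCC|GGGGG|TTTTT", cand$sequence)))
  expect_false(any(duplicated(cand$sequence)))
  # extremes are impossible by construction
  expect_false(strrep("GC", 10) %in% cand$sequence)   # GC = 1
  expect_false(strrep("AT", 10) %in% cand$sequence)   # GC = 0
  cand2 <- generate_flank_candidates(n = 150, seed = 12)
  expect_identical(cand, cand2)
})

test_that("the 3' hexamer screen matches the brute-force set oracle", {
  set.seed(14)
  pool <- vapply(1:40, function(i) random_dna(80), "")
  cand <- generate_flank_candidates(n = 80, seed = 15)
  got <- screen_3prime(cand, pool)
  expect_identical(got$sequence, oracle_hexamer_survivors(cand$sequence, pool))
  # a candidate whose 3' hexamer starts a pool sequence is removed
  planted <- paste0(substr(cand$sequence[1], 1, nchar(cand$sequence[1]) - 6),
                    "ACGTAC")
  survivor <- got$sequence[1]
  pool2 <- c(pool, paste0("ACGTAC", random_dna(60)))
  got2 <- screen_3prime(data.frame(sequence = c(planted, survivor)), pool2)
  expect_false(planted %in% got2$sequence)
  expect_true(survivor %in% got2$sequence)
  # empty pool retains everything
  expect_identical(screen_3prime(cand, character(0)), cand)
})

test_that("cross-homology scoring matches a Smith-Waterman oracle", {
  set.seed(16)
  pool <- vapply(1:6, function(i) random_dna(60), "")
  cands <- vapply(1:5, function(i) random_dna(20), "")
  # plant a perfect 20-mer substring match
  cands[1] <- substr(pool[2], 11, 30)
  scores <- cross_homology_score(cands, pool)
  expect_identical(scores[1], 20L)
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  for (i in seq_along(cands)) {
    want <- max(vapply(pool, function(s)
      max(oracle_smith_waterman(cands[i], s),
          oracle_smith_waterman(rc(cands[i]), s)), numeric(1)))
    expect_identical(scores[i], as.integer(want))
  }
  # strand symmetry: scoring against the reverse-complemented pool is identical
  expect_identical(cross_homology_score(cands, rc(pool)), scores)
})

test_that("selected flank pairs are mutually compatible and within range", {
  cand <- generate_flank_candidates(n = 120, seed = 17, fixed_length = 20)
  set.seed(18)
  pool <- vapply(1:30, function(i) random_dna(160), "")
  cand <- screen_3prime(cand, pool)
  cand$score <- cross_homology_score(cand$sequence, pool)
  pairs <- select_flank_pairs(cand, n_files = 3)
  expect_identical(nrow(pairs), 3L)
  chosen <- c(pairs$forward, pairs$reverse)
  expect_identical(anyDuplicated(chosen), 0L)
  hex3 <- substr(chosen, nchar(chosen) - 5, nchar(chosen))
  expect_identical(anyDuplicated(hex3), 0L)
  expect_true(all(gc_fraction(chosen) >= 0.4 & gc_fraction(chosen) <= 0.6))
  expect_true(all(oligo_tm(chosen) >= 58 & oligo_tm(chosen) <= 70))
  # two mutually compatible candidates, one file -> exactly that pair
  two <- cand[cand$sequence %in% c(pairs$forward[1], pairs$reverse[1]), ]
  p1 <- select_flank_pairs(two, n_files = 1)
  expect_setequal(c(p1$forward, p1$reverse), two$sequence)
  expect_error(select_flank_pairs(cand[1, , drop = FALSE], n_files = 1), "design error")
})

test_that("a small prebuilt pool passes its invariants and distance floor", {
  pool <- prebuilt_flank_pool(n = 400, seed = 424201, hamming_min = 3)
  expect_identical(nrow(pool), 400L)
  expect_true(all(pool$length >= 20 & pool$length <= 25))
  expect_true(all(pool$gc >= 0.4 - 1e-9 & pool$gc <= 0.6 + 1e-9))
  expect_true(all(pool$tm >= 58 & pool$tm <= 70))
  # pairwise Hamming floor among equal-length members (direct scan)
  for (L in unique(pool$length)) {
    seqs <- pool$sequence[pool$length == L]
    if (length(seqs) < 2) next
    m <- matrix(charToRaw(paste(seqs, collapse = "")), nrow = L)
    for (i in seq_len(ncol(m) - 1)) {
      d <- colSums(m[, (i + 1):ncol(m), drop = FALSE] != m[, i])
      expect_gte(min(d), 3)
    }
  }
  # serialization round trip
  path <- tempfile(fileext = ".fasta")
  write_flank_pool(pool, path)
  back <- read_flank_pool(path)
  expect_identical(back$sequence, pool$sequence)
})
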