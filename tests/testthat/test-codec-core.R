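test_that("length_budget reproduces the default oligo geometry", {
  pin <- codec_pin(666, 888)
  cfg <- encode_config(pin)
  b <- length_budget(cfg, 1024L)
  # 200-nt string minus two 20-nt flanks, two fragments: 160 bits each,
  # of which 16 are the two RS parity bytes
  expect_identical(b$per_fragment_bits, 160L)
  expect_identical(b$rs_bits, 16L)
  expect_identical(b$index_bits %% 4L, 0L)
  expect_identical(b$payload_bits, 160L - b$index_bits - 16L)
  expect_identical(b$payload_bits %% 4L, 0L)
  expect_error(encode_config(pin, string_length_nt = 40L, flank_length_nt = 20L),
               "too short")
})

test_that("index width is the smallest nibble-aligned field with virtual headroom", {
  pin <- codec_pin(666, 888)
  cfg <- encode_config(pin, flank_length_nt = 0L, rs_bytes = 0L)
  for (bytes in c(10, 5000, 2e6)) {
    b <- length_budget(cfg, bytes)
    # independent arithmetic: smallest multiple of 4 addressing the
    # fragments with the documented 5% + 8 headroom
    ib <- 4L
    repeat {
      pb <- b$per_fragment_bits - ib
      n <- ceiling(8 * bytes / pb)
      if (2^ib >= n * 1.05 + 8) break
      ib <- ib + 4L
    }
    expect_identical(b$index_bits, ib)
    expect_identical(b$n_fragments, ceiling(8 * bytes / b$payload_bits))
  }
})

test_that("segment_payload pads only the final fragment and enforces the job cap", {
  pin <- codec_pin(666, 888)
  cfg <- encode_config(pin)
  expect_error(segment_payload(raw(0), cfg), "size error")
  expect_error(segment_payload(as.raw(1:10), encode_config(pin, job_cap_bytes = 5)),
               "size error")
  b <- length_budget(cfg, 1024L)
  # choose a byte count that exactly fills fragments (payload_bits is a
  # multiple of 4, so 2*payload_bits bits = payload_bits/4 bytes works)
  nfill <- 4L * (b$payload_bits %/% 8L) * 2L
  if (b$payload_bits %% 8L == 0L) {
    data <- random_bytes(nfill, 1)
    fs <- segment_payload(data, cfg)
    expect_identical(nrow(fs$payload) * fs$budget$payload_bits, 8L * nfill)
  }
  data <- random_bytes(1024, 2)
  fs <- segment_payload(data, cfg)
  expect_identical(nrow(fs$payload), as.integer(ceiling(8 * 1024 / fs$budget$payload_bits)))
  expect_identical(fs$index, 0:(nrow(fs$payload) - 1L))
})

test_that("merge and unmerge are inverse and order members by index", {
  set.seed(41)
  for (k in 2:4) {
    members <- lapply(1:k, function(i) sample(0:1, 48, TRUE))
    merged <- merge_fragments(members, k)
    expect_identical(length(merged), 48L * k)
    back <- unmerge_fragments(merged, k)
    expect_identical(back, lapply(members, as.integer))
  }
  # ascending-index ordering from the leading index field (8 bits)
  m1 <- c(nibbles_to_bits(c(0L, 5L)), sample(0:1, 32, TRUE))   # index 5
  m2 <- c(nibbles_to_bits(c(0L, 2L)), sample(0:1, 32, TRUE))   # index 2
  merged <- merge_fragments(list(m1, m2), index_bits = 8L)
  expect_identical(unmerge_fragments(merged, 2L)[[1]], as.integer(m2))
  expect_error(merge_fragments(list(m1, m2[-1])), "unequal")
})

test_that("transcode maps 4-bit units to dinucleotides through alternating rules", {
  pin <- codec_pin(666, 888)
  expect_identical(nchar(transcode(sample(0:1, 16, TRUE), pin)), 8L)
  expect_identical(transcode(integer(0), pin), "")
  expect_error(transcode(c(1L, 0L, 1L), pin), "multiple of 4")
  # explicit first two units: nibble -> forward map, odd then even rule
  bits <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)
  seq <- transcode(bits, pin)
  d1 <- pin$rule_odd$forward[1]
  d2 <- pin$rule_even$forward[16]
  bases <- c("A", "C", "G", "T")
  expect_identical(seq, paste0(bases[d1 %/% 4 + 1], bases[d1 %% 4 + 1],
                               bases[d2 %/% 4 + 1], bases[d2 %% 4 + 1]))
})

test_that("untranscode inverts transcode and validates its input", {
  set.seed(42)
  mismatches <- 0L
  for (i in 1:200) {
    pin <- random_pin(i)
    bits <- sample(0:1, 4L * sample(1:40, 1), TRUE)
    seq <- transcode(bits, pin)
    expect_identical(untranscode(seq, pin), as.integer(bits))
    other <- random_pin(i + 5000)
    if (!identical(untranscode(seq, other), as.integer(bits))) mismatches <- mismatches + 1L
  }
  expect_gte(mismatches, 195L)  # wrong pin disagrees with overwhelming frequency
  expect_error(untranscode("ACG", codec_pin(1, 2)), "even")
  expect_error(untranscode("ACGN", codec_pin(1, 2)), "non-ACGT")
})

test_that("encode/decode round-trips across k, RS and redundancy settings", {
  # string/flank geometry per k so the payload region divides 2k nt
  grid <- list(list(k = 2L, rs = 2L, red = FALSE, L = 200L),
               list(k = 2L, rs = 0L, red = TRUE, L = 200L),
               list(k = 3L, rs = 2L, red = TRUE, L = 196L),
               list(k = 4L, rs = 4L, red = FALSE, L = 200L))
  for (g in seq_along(grid)) {
    p <- grid[[g]]
    pin <- random_pin(400 + g)
    L <- p$L
    cfg <- encode_config(pin, string_length_nt = L, rs_bytes = p$rs,
                         redundancy = p$red, fragments_per_string = p$k,
                         flank_length_nt = 20L, seed = 500 + g, jobname = "grid")
    data <- random_bytes(1500 + 97 * g, 600 + g)
    pool <- encode_file(data, cfg)
    expect_true(all(nchar(pool$sequences) == L))
    dec <- decode_file(pool$sequences, pin, pool$manifest)
    expect_identical(dec$data, data)
    expect_identical(dec$report$recovery_fraction, 1)
    expect_true(dec$report$crc_ok)
  }
})

test_that("a file dominated by zero bytes still encodes and round-trips", {
  pin <- random_pin(77)
  data <- as.raw(c(rep(0L, 1500), sample(0:255, 200, TRUE), rep(0L, 500)))
  cfg <- encode_config(pin, redundancy = TRUE, seed = 13, jobname = "zeros")
  pool <- encode_file(data, cfg)
  expect_true(all(nchar(pool$sequences) == 200L))
  dec <- decode_file(pool$sequences, pin, pool$manifest)
  expect_identical(dec$data, data)
})

test_that("every emitted payload passes the screen, junctions included", {
  pin <- random_pin(55)
  cfg <- encode_config(pin, redundancy = TRUE, seed = 9, jobname = "scr")
  pool <- encode_file(random_bytes(4000, 10), cfg)
  spec <- cfg$constraints
  for (s in pool$payloads) expect_true(screen_sequence(s, spec)$pass)
  # flank junctions never create a homopolymer violation
  cap <- spec$max_homopolymer
  f5tail <- substr(pool$flank_5p, nchar(pool$flank_5p) - cap + 1L, nchar(pool$flank_5p))
  f3head <- substr(pool$flank_3p, 1L, cap)
  for (s in pool$payloads) {
    joined <- paste0(f5tail, s, f3head)
    runs <- rle(strsplit(joined, "")[[1]])
    expect_lte(max(runs$lengths), cap)
  }
})

test_that("encoding is bit-identical under a fixed seed and config", {
  pin <- codec_pin(10, 20)
  cfg <- encode_config(pin, seed = 77, jobname = "det")
  data <- random_bytes(3000, 8)
  p1 <- encode_file(data, cfg)
  p2 <- encode_file(data, cfg)
  expect_identical(p1$sequences, p2$sequences)
  expect_identical(p1$members, p2$members)
})

test_that("decoding tolerates string loss up to the XOR erasure bound", {
  pin <- random_pin(60)
  cfg <- encode_config(pin, redundancy = TRUE, seed = 21, jobname = "loss")
  data <- random_bytes(5000, 22)
  pool <- encode_file(data, cfg)
  # drop strings while keeping every XOR triple at <= 1 missing member:
  # deleting any 3 random strings almost always satisfies this; verify via
  # the report instead of assuming
  set.seed(23)
  for (trial in 1:3) {
    drop <- sample(length(pool$sequences), 3)
    dec <- suppressWarnings(decode_file(pool$sequences[-drop], pin, pool$manifest))
    if (dec$report$recovery_fraction == 1) {
      expect_identical(dec$data, data)
      expect_true(dec$report$crc_ok)
      expect_gte(dec$report$n_xor_recovered, 1L)
    } else {
      # two losses fell into one triple; the report must say so
      expect_gt(length(dec$report$unrecoverable_indices), 0L)
    }
  }
})

test_that("decoding with a distant wrong pin fails the checksum", {
  pin <- random_pin(70)
  wrong <- random_pin(71)
  cfg <- encode_config(pin, seed = 31, jobname = "wp")
  data <- random_bytes(1024, 30)
  pool <- encode_file(data, cfg)
  dec <- suppressWarnings(decode_file(pool$sequences, wrong, pool$manifest))
  expect_false(dec$report$crc_ok)
  expect_false(identical(dec$data, data))
})

test_that("manifest headers round-trip and unknown keys warn", {
  pin <- codec_pin(666, 888)
  cfg <- encode_config(pin, seed = 3, jobname = "mh")
  pool <- encode_file(random_bytes(600, 40), cfg)
  h <- manifest_to_header(pool$manifest)
  m2 <- header_to_manifest(h)
  for (f in names(pool$manifest)) expect_equal(m2[[f]], pool$manifest[[f]], info = f)
  expect_warning(header_to_manifest(paste0(h, ";mystery=1")), "mystery")
})

test_that("FASTA round trip preserves strings and manifest", {
  pin <- codec_pin(666, 888)
  cfg <- encode_config(pin, seed = 4, jobname = "fa")
  data <- random_bytes(900, 41)
  pool <- encode_file(data, cfg)
  path <- tempfile(fileext = ".fasta")
  write_encoded_fasta(pool, path)
  fa <- read_encoded_fasta(path)
  expect_identical(unname(fa$sequences), unname(pool$sequences))
  dec <- decode_file(fa$sequences, pin, fa$manifest)
  expect_identical(dec$data, data)
})
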