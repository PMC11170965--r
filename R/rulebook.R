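# rulebook: the 16!-sized codec-rule space, codec pins, and the pin library.
#
# A codec rule is a bijection between the 16 four-bit values (nibbles) and
# the 16 dinucleotides. Rules are addressed by their Lehmer-code rank in
# [0, 16!) over the canonical orders: nibbles ascending 0000..1111,
# dinucleotides lexicographic AA,AC,AG,AT,CA,...,TT (A<C<G<T). The pool is
# never enumerated; rules are materialized lazily from their index.

.RULE_SYMBOLS <- 16L

#' Number of addressable codec rules
#'
#' Computed as 16! (the number of bijections between the sixteen 4-bit
#' coding units and the sixteen dinucleotides), not hard-coded.
#'
#' @return a double, exactly representable (16! < 2^53)
#' @export
n_codec_rules <- function() factorial(.RULE_SYMBOLS)

#' Materialize a codec rule from its index
#'
#' Unranks `index` in the factorial number system (Lehmer code) over the
#' canonical dinucleotide order, yielding the permutation that maps each
#' nibble to a dinucleotide. `rule_from_index(0)` is the identity
#' permutation; `rule_from_index(n_codec_rules() - 1)` is the fully
#' reversed one.
#'
#' @param index integer-valued scalar in `[0, 16!)`; may be a double
#'   (all rule indices are exactly representable).
#' @return an object of class `codec_rule` with fields `index`,
#'   `forward` (nibble -> dinucleotide code, a permutation of 0:15) and
#'   `reverse` (its inverse).
#' @seealso [index_of_rule()], [codec_pin()]
#' @export
rule_from_index <- function(index) {
  index <- as.numeric(index)
  if (length(index) != 1L || is.na(index) || index != floor(index))
    stop("rule index must be a single integer-valued number")
  if (index < 0 || index >= n_codec_rules())
    stop("rule index out of range [0, 16!)")
  avail <- 0:15
  forward <- integer(16L)
  rem <- index
  for (i in 1:16) {
    f <- factorial(16L - i)
    d <- rem %/% f
    rem <- rem %% f
    forward[i] <- avail[d + 1]
    avail <- avail[-(d + 1)]
  }
  new_codec_rule(index, forward)
}

new_codec_rule <- function(index, forward) {
  reverse <- integer(16L)
  reverse[forward + 1L] <- 0:15
  structure(list(index = index, forward = as.integer(forward), reverse = reverse),
            class = "codec_rule")
}

#' Rank a codec rule back to its index
#'
#' Inverse of [rule_from_index()]: computes the Lehmer-code rank of the
#' rule's forward permutation.
#'
#' @param rule a `codec_rule`, or a bare integer vector of length 16 giving
#'   the forward map (a permutation of 0:15, dinucleotide codes).
#' @return the index as a double in `[0, 16!)`
#' @export
index_of_rule <- function(rule) {
  forward <- if (inherits(rule, "codec_rule")) rule$forward else as.integer(rule)
  if (length(forward) != 16L || anyNA(forward) || !setequal(forward, 0:15))
    stop("forward map must be a permutation of the 16 dinucleotide codes")
  avail <- 0:15
  idx <- 0
  for (i in 1:16) {
    d <- match(forward[i], avail) - 1L
    idx <- idx + d * factorial(16L - i)
    avail <- avail[-(d + 1L)]
  }
  idx
}

#' @export
print.codec_rule <- function(x, ...) {
  dinucs <- paste0(rep(.BASES, each = 4L), rep(.BASES, 4L))
  cat("<codec_rule> index", format(x$index, scientific = FALSE), "\n")
  cat("  nibble:", sprintf("%4d", 0:15), "\n")
  cat("  dinuc :", sprintf("%4s", dinucs[x$forward + 1L]), "\n")
  invisible(x)
}

# dinucleotide images (character) of a rule's forward map
.rule_dinucs <- function(rule) {
  paste0(.BASES[rule$forward %/% 4L + 1L], .BASES[rule$forward %% 4L + 1L])
}

## ---- codec pins ------------------------------------------------------------

#' Construct a codec pin from two distinct rules
#'
#' A codec pin is an ordered pair of codec rules and is the user-held key of
#' the codec: the first rule transcodes the odd-numbered 4-bit coding units,
#' the second the even-numbered ones. Pins are obscurity keys, not
#' cryptography.
#'
#' @param rule_odd,rule_even `codec_rule` objects or bare rule indices.
#' @param pin_id optional non-negative integer identifier.
#' @return an object of class `codec_pin`
#' @export
codec_pin <- function(rule_odd, rule_even, pin_id = NA_integer_) {
  if (!inherits(rule_odd, "codec_rule")) rule_odd <- rule_from_index(rule_odd)
  if (!inherits(rule_even, "codec_rule")) rule_even <- rule_from_index(rule_even)
  if (rule_odd$index == rule_even$index)
    stop("the two rules of a codec pin must be distinct")
  structure(list(pin_id = pin_id, rule_odd = rule_odd, rule_even = rule_even),
            class = "codec_pin")
}

#' @export
print.codec_pin <- function(x, ...) {
  cat("<codec_pin>", if (!is.na(x$pin_id)) paste0("id ", x$pin_id) else "(unnumbered)",
      "\n  rule_odd  index:", format(x$rule_odd$index, scientific = FALSE),
      "\n  rule_even index:", format(x$rule_even$index, scientific = FALSE), "\n")
  invisible(x)
}

# concatenated 32-entry mapping table (dinucleotide codes)
.pin_table <- function(pin) c(pin$rule_odd$forward, pin$rule_even$forward)

#' Distance between two codec pins
#'
#' Hamming distance between the concatenated 32-dinucleotide mapping tables
#' (odd-rule table followed by even-rule table): the number of table
#' positions whose dinucleotide images differ. Symmetric, and zero exactly
#' when the two pins are identical. This table-level distance lower-bounds
#' the per-unit disagreement of sequences encoded with the two pins and is
#' computable without encoding anything.
#'
#' @param a,b `codec_pin` objects
#' @return integer in 0..32
#' @export
pin_distance <- function(a, b) {
  stopifnot(inherits(a, "codec_pin"), inherits(b, "codec_pin"))
  sum(.pin_table(a) != .pin_table(b))
}

## ---- pin library -----------------------------------------------------------

.PIN_LIBRARY_SEED <- 1729L
.PIN_LIBRARY_MIN_DISTANCE <- 8L
.PIN_LIBRARY_SIZE <- 30000L

# Pigeonhole screen: distance < min_distance (= 8) over 32 positions forces
# at least 25 agreeing positions, hence at least one of the eight disjoint
# 4-position blocks agrees exactly. Hashing each block therefore finds every
# candidate pair that could violate the threshold; only those pairs get an
# exact distance computation. This keeps library generation O(n).
.pin_block_keys <- function(tbl) {
  vapply(seq(1L, 32L, 4L),
         function(s) paste(tbl[s:(s + 3L)], collapse = ","),
         character(1))
}

#' Generate a screened codec-pin library
#'
#' Samples rule pairs uniformly from the 16! x 16! pin space (distinct
#' members), rejecting any candidate whose [pin_distance()] to an already
#' accepted pin falls below `min_distance`, until `n_pins` pins are
#' collected. Deterministic for a given `seed`. The default parameters
#' reproduce the library shipped conceptually with the codec: 30,000 pins,
#' minimum table distance 8.
#'
#' @param n_pins number of pins to generate (default 30,000)
#' @param min_distance minimum pairwise [pin_distance()] (default 8)
#' @param seed RNG seed (default 1729, the documented library seed)
#' @param max_attempts rejection-sampling budget; exceeding it raises a
#'   configuration error reporting the achieved count.
#' @return a `pin_library`: a data.frame with columns `pin_id`,
#'   `rule_odd_index`, `rule_even_index` and attributes `seed`,
#'   `min_distance`.
#' @export
generate_pin_library <- function(n_pins = .PIN_LIBRARY_SIZE,
                                 min_distance = .PIN_LIBRARY_MIN_DISTANCE,
                                 seed = .PIN_LIBRARY_SEED,
                                 max_attempts = 50L * n_pins + 1000L) {
  stopifnot(n_pins >= 1L, min_distance >= 0L)
  tables <- matrix(0L, nrow = n_pins, ncol = 32L)
  odd_idx <- numeric(n_pins)
  even_idx <- numeric(n_pins)
  block_env <- lapply(1:8, function(i) new.env(parent = emptyenv(), hash = TRUE))
  pair_env <- new.env(parent = emptyenv(), hash = TRUE)
  accepted <- 0L
  attempts <- 0L
  with_seed(seed, {
    while (accepted < n_pins) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf("pin library generation exhausted its attempt budget (%d of %d pins accepted)",
                     accepted, n_pins))
      p_odd <- sample(0:15)
      p_even <- sample(0:15)
      if (identical(p_odd, p_even)) next
      pair_key <- paste(c(p_odd, p_even), collapse = ",")
      if (!is.null(pair_env[[pair_key]])) next
      tbl <- c(p_odd, p_even)
      keys <- .pin_block_keys(tbl)
      conflict <- integer(0)
      for (b in 1:8) {
        hit <- block_env[[b]][[keys[b]]]
        if (!is.null(hit)) conflict <- c(conflict, hit)
      }
      if (length(conflict)) {
        conflict <- unique(conflict)
        d <- rowSums(tables[conflict, , drop = FALSE] !=
                       matrix(tbl, nrow = length(conflict), ncol = 32L, byrow = TRUE))
        if (any(d < min_distance)) next
      }
      accepted <- accepted + 1L
      tables[accepted, ] <- tbl
      odd_idx[accepted] <- index_of_rule(p_odd)
      even_idx[accepted] <- index_of_rule(p_even)
      pair_env[[pair_key]] <- TRUE
      for (b in 1:8) {
        block_env[[b]][[keys[b]]] <- c(block_env[[b]][[keys[b]]], accepted)
      }
    }
  })
  lib <- data.frame(pin_id = 0:(n_pins - 1L),
                    rule_odd_index = odd_idx,
                    rule_even_index = even_idx)
  attr(lib, "seed") <- seed
  attr(lib, "min_distance") <- min_distance
  class(lib) <- c("pin_library", "data.frame")
  lib
}

#' Look a pin up in a library
#'
#' @param library a `pin_library`
#' @param pin_id pin identifier (0-based, as stored in the library)
#' @return a `codec_pin`
#' @export
pin_from_library <- function(library, pin_id) {
  i <- match(pin_id, library$pin_id)
  if (is.na(i)) stop("pin_id ", pin_id, " not present in the library")
  codec_pin(rule_from_index(library$rule_odd_index[i]),
            rule_from_index(library$rule_even_index[i]),
            pin_id = library$pin_id[i])
}

#' The default codec-pin library (cached)
#'
#' Generates (once per session) the default 30,000-pin library from the
#' documented seed and distance threshold.
#'
#' @return a `pin_library`
#' @export
default_pin_library <- function() {
  if (is.null(.oc_env$default_pin_library))
    .oc_env$default_pin_library <- generate_pin_library()
  .oc_env$default_pin_library
}

#' Serialize / read a pin library
#'
#' Plain-text TSV with columns `pin_id`, `rule_odd_index`,
#' `rule_even_index`; the first line is a `#`-prefixed header recording the
#' generation seed and distance threshold.
#'
#' @param library a `pin_library`
#' @param path file path
#' @return `write_pin_library` returns `path` invisibly;
#'   `read_pin_library` returns a `pin_library`.
#' @export
write_pin_library <- function(library, path) {
  header <- sprintf("# pin_library seed=%d min_distance=%d n=%d",
                    attr(library, "seed"), attr(library, "min_distance"), nrow(library))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines("pin_id\trule_odd_index\trule_even_index", con)
  writeLines(sprintf("%d\t%s\t%s", library$pin_id,
                     format(library$rule_odd_index, scientific = FALSE, trim = TRUE),
                     format(library$rule_even_index, scientific = FALSE, trim = TRUE)), con)
  invisible(path)
}

#' @rdname write_pin_library
#' @export
read_pin_library <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("seed=(-?[0-9]+) min_distance=([0-9]+)", first))[[1]]
  if (length(m) != 3L) stop("not a pin library file (missing header): ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                          colClasses = c("integer", "numeric", "numeric"))
  attr(df, "seed") <- as.integer(m[2])
  attr(df, "min_distance") <- as.integer(m[3])
  class(df) <- c("pin_library", "data.frame")
  df
}

#' Verify the invariants of a pin library
#'
#' Recomputes every pin's mapping table and checks pin-id uniqueness, rule
#' distinctness within each pin, pair uniqueness, and the pairwise distance
#' floor (via the exact block-hash screen).
#'
#' @param library a `pin_library`
#' @return TRUE invisibly; stops with a message on the first violation
#' @export
verify_pin_library <- function(library) {
  n <- nrow(library)
  if (anyDuplicated(library$pin_id)) stop("duplicate pin_id")
  if (any(library$rule_odd_index == library$rule_even_index))
    stop("a pin pairs a rule with itself")
  key <- paste(library$rule_odd_index, library$rule_even_index)
  if (anyDuplicated(key)) stop("duplicate (rule_odd, rule_even) pair")
  min_distance <- attr(library, "min_distance")
  tables <- matrix(0L, n, 32L)
  for (i in seq_len(n)) {
    tables[i, ] <- c(rule_from_index(library$rule_odd_index[i])$forward,
                     rule_from_index(library$rule_even_index[i])$forward)
  }
  block_env <- lapply(1:8, function(i) new.env(parent = emptyenv(), hash = TRUE))
  for (i in seq_len(n)) {
    keys <- .pin_block_keys(tables[i, ])
    conflict <- integer(0)
    for (b in 1:8) {
      hit <- block_env[[b]][[keys[b]]]
      if (!is.null(hit)) conflict <- c(conflict, hit)
      block_env[[b]][[keys[b]]] <- c(block_env[[b]][[keys[b]]], i)
    }
    if (length(conflict)) {
      conflict <- unique(conflict)
      d <- rowSums(tables[conflict, , drop = FALSE] !=
                     matrix(tables[i, ], nrow = length(conflict), ncol = 32L, byrow = TRUE))
      if (any(d < min_distance))
        stop(sprintf("pins %d and %d are at distance %d < %d",
                     library$pin_id[conflict[which.min(d)]], library$pin_id[i],
                     min(d), min_distance))
    }
  }
  invisible(TRUE)
}

#' @export
print.pin_library <- function(x, ...) {
  cat(sprintf("<pin_library> %d pins (seed %d, min table distance %d)\n",
              nrow(x), attr(x, "seed"), attr(x, "min_distance")))
  print.data.frame(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("  ...\n")
  invisible(x)
}
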