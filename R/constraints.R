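# Biochemical constraint specification and sequence screening.
#
# Screening is the encode-time guarantee: the GC window slides at step 1 so
# that *every* window of the payload satisfies the bounds; the analysis
# geometry used for reporting (150-nt windows stepped by 140) lives in
# seqstats and is a separate setting.

#' Biochemical constraint specification
#'
#' Bounds applied to every encoded payload region: GC fraction within
#' sliding windows of `window_nt` (sequences shorter than the window are
#' evaluated whole) and a cap on homopolymer run length anywhere in the
#' sequence.
#'
#' @param min_gc,max_gc GC-fraction bounds in `[0,1]` (defaults 0.40-0.60)
#' @param max_homopolymer maximum allowed run of identical nucleotides
#'   (default 4 nt)
#' @param window_nt GC window width in nt (default 150)
#' @param window_step_nt step used when *screening* (default 1, i.e. the
#'   bounds hold everywhere); analysis code may use a coarser step.
#' @return an object of class `constraint_spec`
#' @export
constraint_spec <- function(min_gc = 0.4, max_gc = 0.6, max_homopolymer = 4L,
                            window_nt = 150L, window_step_nt = 1L) {
  stopifnot(min_gc >= 0, max_gc <= 1, min_gc <= max_gc,
            max_homopolymer >= 1L, window_nt >= 1L, window_step_nt >= 1L)
  structure(list(min_gc = min_gc, max_gc = max_gc,
                 max_homopolymer = as.integer(max_homopolymer),
                 window_nt = as.integer(window_nt),
                 window_step_nt = as.integer(window_step_nt)),
            class = "constraint_spec")
}

#' @export
print.constraint_spec <- function(x, ...) {
  cat(sprintf("<constraint_spec> GC %.0f-%.0f%% per %d-nt window (screen step %d), homopolymer <= %d nt\n",
              100 * x$min_gc, 100 * x$max_gc, x$window_nt, x$window_step_nt, x$max_homopolymer))
  invisible(x)
}

#' Screen one sequence against a constraint specification
#'
#' Pure predicate: fails if any homopolymer run exceeds
#' `spec$max_homopolymer`, or if any `window_nt` window (sliding at step 1;
#' the whole sequence if shorter than the window) has a GC fraction outside
#' `[min_gc, max_gc]`. The first violation (leftmost position; homopolymer
#' checked first at equal position) is reported.
#'
#' @param seq a single DNA string (A/C/G/T)
#' @param spec a [constraint_spec()]
#' @return list with elements `pass` (logical) and `violation` (NULL, or a
#'   list with `kind` ("homopolymer" or "gc_window"), `position` (1-based
#'   start) and `value`)
#' @export
screen_sequence <- function(seq, spec = constraint_spec()) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  chars <- strsplit(seq, "")[[1]]
  runs <- rle(chars)
  viol <- NULL
  bad <- which(runs$lengths > spec$max_homopolymer)
  if (length(bad)) {
    pos <- sum(runs$lengths[seq_len(bad[1] - 1L)]) + 1L
    viol <- list(kind = "homopolymer", position = pos, value = runs$lengths[bad[1]])
  }
  gc <- as.integer(chars %in% c("C", "G"))
  L <- length(gc)
  w <- min(spec$window_nt, L)
  cs <- c(0L, cumsum(gc))
  starts <- seq(1L, L - w + 1L)
  counts <- cs[starts + w] - cs[starts]
  fr <- counts / w
  out <- which(fr < spec$min_gc - 1e-9 | fr > spec$max_gc + 1e-9)
  if (length(out)) {
    gviol <- list(kind = "gc_window", position = starts[out[1]], value = fr[out[1]])
    if (is.null(viol) || gviol$position < viol$position) viol <- gviol
  }
  list(pass = is.null(viol), violation = viol)
}

# Batch screen over a base-code matrix (rows = candidate payloads).
# pre/post are integer base-code vectors giving fixed flanking context for
# the homopolymer check only (GC bounds apply to the payload region alone,
# matching the convention that GC excludes the flanking sequence).
.screen_matrix <- function(mat, spec, pre = integer(0), post = integer(0)) {
  n <- nrow(mat)
  if (n == 0L) return(logical(0))
  # homopolymer: a run of (cap+1) bases = cap consecutive equal adjacent pairs
  hmat <- mat
  if (length(pre)) hmat <- cbind(matrix(rep(pre, each = n), nrow = n), hmat)
  if (length(post)) hmat <- cbind(hmat, matrix(rep(post, each = n), nrow = n))
  Lh <- ncol(hmat)
  cap <- spec$max_homopolymer
  eq <- hmat[, -1L, drop = FALSE] == hmat[, -Lh, drop = FALSE]
  m <- ncol(eq)
  hp_fail <- rep(FALSE, n)
  if (m >= cap) {
    acc <- eq[, 1:(m - cap + 1L), drop = FALSE]
    if (cap > 1L) {
      for (o in 1:(cap - 1L)) {
        acc <- acc & eq[, (1L + o):(m - cap + 1L + o), drop = FALSE]
      }
    }
    hp_fail <- rowSums(acc) > 0L
  }
  # GC windows at step 1 over the payload region
  L <- ncol(mat)
  w <- min(spec$window_nt, L)
  g <- (mat == 1L) | (mat == 2L)
  mode(g) <- "integer"
  cs <- cbind(0L, g)
  for (j in seq(2L, ncol(cs))) cs[, j] <- cs[, j] + cs[, j - 1L]
  lo <- spec$min_gc * w - 1e-9
  hi <- spec$max_gc * w + 1e-9
  gc_fail <- rep(FALSE, n)
  for (s in seq(1L, L - w + 1L)) {
    cnt <- cs[, s + w] - cs[, s]
    gc_fail <- gc_fail | cnt < lo | cnt > hi
  }
  !(hp_fail | gc_fail)
}
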