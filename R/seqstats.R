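# seqstats: windowed GC / homopolymer evaluation of encoded pools and
# practical coding density. This is the independent verifier of the
# encoder's screening: it recounts with its own (simpler, per-sequence)
# machinery and the analysis window geometry (150-nt windows stepped by
# 140 by default) rather than the screening geometry (step 1).

#' Windowed GC and homopolymer statistics of a pool
#'
#' Tiles each payload with windows of `window_nt` stepped by `step_nt`
#' (a final partial window is included when it covers at least half a
#' window) and reports the GC fraction and maximum homopolymer run of each
#' window.
#'
#' @param pool an `encoded_pool` (payload regions are analyzed) or a
#'   character vector of sequences
#' @param window_nt window width (default 150)
#' @param step_nt window step (default 140)
#' @return a `window_report` data.frame: `seq_id`, `start`, `width`, `gc`,
#'   `max_homopolymer`; attribute `summary` holds the medians, extremes
#'   and a GC histogram
#' @export
window_stats <- function(pool, window_nt = 150L, step_nt = 140L) {
  seqs <- if (inherits(pool, "encoded_pool")) pool$payloads else pool
  stopifnot(length(seqs) >= 1L)
  window_nt <- as.integer(window_nt)
  step_nt <- as.integer(step_nt)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq_%d", seq_along(seqs) - 1L)
  res <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "")[[1]]
    L <- length(ch)
    gc_cum <- c(0L, cumsum(ch %in% c("C", "G")))
    r <- rle(ch)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    starts <- if (L <= window_nt) 1L else seq(1L, L, by = step_nt)
    ends <- pmin(starts + window_nt - 1L, L)
    widths <- ends - starts + 1L
    keep <- widths >= ceiling(window_nt / 2) | seq_along(starts) == 1L
    starts <- starts[keep]; ends <- ends[keep]; widths <- widths[keep]
    gc <- (gc_cum[ends + 1L] - gc_cum[starts]) / widths
    maxh <- vapply(seq_along(starts), function(w) {
      ov <- pmin(run_end, ends[w]) - pmax(run_start, starts[w]) + 1L
      max(ov[ov > 0L])
    }, integer(1))
    res[[i]] <- data.frame(seq_id = ids[i], start = starts, width = widths,
                           gc = gc, max_homopolymer = maxh,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    n_windows = nrow(out),
    median_gc = stats::median(out$gc), min_gc = min(out$gc), max_gc = max(out$gc),
    max_homopolymer = max(out$max_homopolymer),
    gc_hist = table(cut(out$gc, breaks = seq(0, 1, 0.05), include.lowest = TRUE)))
  class(out) <- c("window_report", "data.frame")
  out
}

#' @export
print.window_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<window_report> %d windows; GC median %.3f [%.3f, %.3f]; max homopolymer %d nt\n",
              s$n_windows, s$median_gc, s$min_gc, s$max_gc, s$max_homopolymer))
  invisible(x)
}

#' Practical coding density of an encoded pool
#'
#' The density of a pool is the amount of coded data divided by the number
#' of bases carrying it. Three variants are reported:
#' \describe{
#'   \item{density_total}{data bits / all emitted nucleotides, flanks
#'     included - the physical cost of the pool}
#'   \item{density_payload_region}{data bits / payload-region nucleotides
#'     (flanks excluded; index, RS and any redundancy still included)}
#'   \item{net_payload_rate}{data bits / payload-field nucleotides of the
#'     data-bearing fragment slots (index, RS, redundancy and flanks all
#'     excluded; virtual and pad fragments count in the denominator only).
#'     2.0 bits/nt is the ceiling; the shortfall measures padding and
#'     virtual-fragment overhead.}
#' }
#'
#' @param pool an `encoded_pool`
#' @param manifest defaults to `pool$manifest`
#' @return list with the three densities plus the raw bit/nt counts
#' @export
practical_density <- function(pool, manifest = pool$manifest) {
  data_bits <- 8 * as.numeric(manifest$byte_length)
  total_nt <- sum(nchar(pool$sequences))
  payload_nt <- sum(nchar(pool$payloads))
  slots <- manifest$n_fragments + manifest$n_pad + pool$n_virtual
  net_nt <- slots * manifest$payload_bits / 2
  list(density_total = data_bits / total_nt,
       density_payload_region = data_bits / payload_nt,
       net_payload_rate = data_bits / net_nt,
       data_bits = data_bits, total_nt = total_nt, payload_nt = payload_nt,
       n_payload_slots = slots)
}

#' Write a window report as TSV
#'
#' @param report a `window_report`
#' @param path output path
#' @export
write_window_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
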