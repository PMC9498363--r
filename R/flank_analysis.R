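#' GC fraction of a DNA string
#'
#' `(G + C) / (A + C + G + T)`; `N` bases are excluded from the denominator
#' (gap-rich assemblies would otherwise be biased toward 0). Returns `NA`
#' when no unambiguous base remains.
#'
#' @param seq character vector of DNA strings (or `DNAStringSet`).
#' @return numeric vector of GC fractions in \[0, 1\] (or `NA`).
#' @export
gc_content <- function(seq) {
  s <- as_seq_chr(seq)
  vapply(s, function(x) {
    if (nchar(x) == 0) return(NA_real_)
    counts <- Biostrings::letterFrequency(Biostrings::DNAString(x),
                                          letters = c("A", "C", "G", "T"))
    denom <- sum(counts)
    if (denom == 0) NA_real_ else (counts[["C"]] + counts[["G"]]) / denom
  }, 0.0, USE.NAMES = FALSE)
}

#' Extract the two flanking sequences of an insertion
#'
#' Left flank is `[max(0, sstart - size), sstart)`, right flank is
#' `[send, min(L, send + size))`; clipping at chromosome ends is flagged and
#' the realized extents are reported.
#'
#' @param insertion one-row data.frame (or list) with `sstart`, `send`.
#' @param chrom_seq the chromosome sequence (character or `DNAString(Set)`).
#' @param size requested flank width in bases.
#' @return list with elements `left` and `right`, each
#'   `list(start, end, seq, clipped)` (0-based half-open).
#' @export
extract_flanks <- function(insertion, chrom_seq, size) {
  s <- as_seq_chr(chrom_seq)[[1]]
  L <- nchar(s)
  ls <- max(0, insertion$sstart - size)
  le <- insertion$sstart
  rs <- insertion$send
  re <- min(L, insertion$send + size)
  list(left = list(start = ls, end = le,
                   seq = substr(s, ls + 1, le), clipped = (le - ls) < size),
       right = list(start = rs, end = re,
                    seq = substr(s, rs + 1, re), clipped = (re - rs) < size))
}

longest_n_run <- function(x) {
  if (nchar(x) == 0) return(0L)
  runs <- regmatches(x, gregexpr("N+", x))[[1]]
  if (length(runs) == 0) 0L else max(nchar(runs))
}

#' GC and TE profile of one insertion and its flanks
#'
#' Internal GC/TE are computed on the insertion span. For each flank size,
#' the two flanks are pooled into a single GC value (per-side values are in
#' [flank_table()]'s output); TE features overlapping a flank window by at
#' least 1 bp count once per window, and TE bases use self-merged TEs.
#' Profiles where either flank's longest `N` run exceeds half the requested
#' size are flagged low-confidence.
#'
#' @param insertion one-row data.frame with `sid, sstart, send`.
#' @param chrom_seq sequence of the insertion's chromosome.
#' @param te_raw,te_merged TE `IRanges` for that chromosome (may be empty).
#' @param sizes flank sizes in bases.
#' @return list of class `flank_profile`: `internal_gc`,
#'   `internal_te_count`, `internal_te_bases`, and per size a list with
#'   `left`/`right` extents and clip flags, `flank_gc`, `flank_te_count`,
#'   `flank_te_bases`, `low_confidence`.
#' @export
flank_profile <- function(insertion, chrom_seq, te_raw = IRanges::IRanges(),
                          te_merged = IRanges::reduce(te_raw),
                          sizes = c(100, 500, 1000, 2000)) {
  s <- as_seq_chr(chrom_seq)[[1]]
  span <- substr(s, insertion$sstart + 1, insertion$send)
  internal_te <- te_overlap(ir0(insertion$sstart, insertion$send),
                            te_raw, te_merged)
  out <- list(internal_gc = gc_content(span),
              internal_te_count = internal_te[["count"]],
              internal_te_bases = internal_te[["bases"]],
              flanks = list())
  for (size in sizes) {
    fl <- extract_flanks(insertion, s, size)
    pooled <- paste0(fl$left$seq, fl$right$seq)
    windows <- list(ir0(fl$left$start, fl$left$end),
                    ir0(fl$right$start, fl$right$end))
    te_count <- 0; te_bases <- 0
    for (w in windows) {
      if (sum_width(w) == 0) next
      ov <- te_overlap(w, te_raw, te_merged)
      te_count <- te_count + ov[["count"]]
      te_bases <- te_bases + ov[["bases"]]
    }
    out$flanks[[as.character(size)]] <- list(
      size = size,
      left_start = fl$left$start, left_end = fl$left$end,
      right_start = fl$right$start, right_end = fl$right$end,
      left_clipped = fl$left$clipped, right_clipped = fl$right$clipped,
      left_gc = gc_content(fl$left$seq), right_gc = gc_content(fl$right$seq),
      flank_gc = gc_content(pooled),
      flank_te_count = te_count, flank_te_bases = te_bases,
      low_confidence = longest_n_run(fl$left$seq) > size / 2 ||
        longest_n_run(fl$right$seq) > size / 2)
  }
  class(out) <- "flank_profile"
  out
}

#' Flank profiles for a whole insertion table
#'
#' One row per insertion x flank size, with the internal (insertion-span)
#' GC/TE columns repeated on each row for convenience.
#'
#' @param insertions insertion data.frame from [merge_hits()].
#' @param genome `DNAStringSet` (or named character) of chromosomes.
#' @param index optional `annotation_index` carrying TE intervals; without
#'   it TE columns are `NA`.
#' @param sizes flank sizes in bases.
#' @return data.frame with columns `insertion, sid, sstart, send, size_class,
#'   id_bin, flank_size, internal_gc, internal_te_count, internal_te_bases,
#'   left_gc, right_gc, flank_gc, flank_te_count, flank_te_bases,
#'   left_clipped, right_clipped, low_confidence`.
#' @export
flank_table <- function(insertions, genome, index = NULL,
                        sizes = c(100, 500, 1000, 2000)) {
  seqs <- as_seq_chr(genome)
  rows <- list()
  has_te <- !is.null(index) && isTRUE(index$has_te)
  for (i in seq_len(nrow(insertions))) {
    chrom <- insertions$sid[i]
    te_raw <- if (has_te) index$chroms[[chrom]]$te_raw else IRanges::IRanges()
    te_merged <- if (has_te) index$chroms[[chrom]]$te_merged else IRanges::IRanges()
    pr <- flank_profile(insertions[i, ], seqs[[chrom]], te_raw, te_merged, sizes)
    for (fs in pr$flanks) {
      rows[[length(rows) + 1L]] <- data.frame(
        insertion = i, sid = chrom,
        sstart = insertions$sstart[i], send = insertions$send[i],
        size_class = insertions$size_class[i], id_bin = insertions$id_bin[i],
        flank_size = fs$size,
        internal_gc = pr$internal_gc,
        internal_te_count = if (has_te) pr$internal_te_count else NA_real_,
        internal_te_bases = if (has_te) pr$internal_te_bases else NA_real_,
        left_gc = fs$left_gc, right_gc = fs$right_gc, flank_gc = fs$flank_gc,
        flank_te_count = if (has_te) fs$flank_te_count else NA_real_,
        flank_te_bases = if (has_te) fs$flank_te_bases else NA_real_,
        left_clipped = fs$left_clipped, right_clipped = fs$right_clipped,
        low_confidence = fs$low_confidence, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(insertion = integer(0), sid = character(0),
                      sstart = numeric(0), send = numeric(0),
                      size_class = character(0), id_bin = character(0),
                      flank_size = numeric(0), internal_gc = numeric(0),
                      internal_te_count = numeric(0),
                      internal_te_bases = numeric(0), left_gc = numeric(0),
                      right_gc = numeric(0), flank_gc = numeric(0),
                      flank_te_count = numeric(0), flank_te_bases = numeric(0),
                      left_clipped = logical(0), right_clipped = logical(0),
                      low_confidence = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
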