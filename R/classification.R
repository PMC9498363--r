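#' @name bins
#' @title Identity bins and size classes
#'
#' @description
#' Hits and insertions are classified on two axes. Percent identity splits
#' into an older bin (`mid80_95`, identity in \[80, 95)) and a recent bin
#' (`hi95`, identity >= 95); identity below 80 falls outside the analysis and
#' maps to `NA`. Length splits into four classes: `lt100` (\[1, 100)),
#' `s100_500` (\[100, 500)), `s500_1000` (\[500, 1000)), `ge1000` (>= 1000 bp).
#' Edge membership (left-closed, with 1000 bp in `ge1000`) is fixed by these
#' defaults but both edge sets are arguments.
NULL

#' @rdname bins
#' @param identity percent identity values in \[0, 100\].
#' @param edges two identity edges (lower bound of the older bin, split point
#'   of the recent bin).
#' @return `assign_id_bin`: character vector over `mid80_95`, `hi95`, `NA`.
#' @export
assign_id_bin <- function(identity, edges = c(80, 95)) {
  stopifnot(length(edges) == 2, edges[1] < edges[2],
            all(identity >= 0 & identity <= 100, na.rm = TRUE))
  out <- rep(NA_character_, length(identity))
  out[identity >= edges[1] & identity < edges[2]] <- "mid80_95"
  out[identity >= edges[2]] <- "hi95"
  out
}

#' @rdname bins
#' @param length span lengths in bases (>= 1).
#' @param breaks three internal size-class breakpoints.
#' @return `assign_size_class`: character vector over the four class labels.
#' @export
assign_size_class <- function(length, breaks = c(100, 500, 1000)) {
  stopifnot(length(breaks) == 3, all(diff(breaks) > 0), all(length >= 1))
  cls <- size_class_levels()
  out <- rep(cls[4], length(length))
  out[length < breaks[3]] <- cls[3]
  out[length < breaks[2]] <- cls[2]
  out[length < breaks[1]] <- cls[1]
  out
}

size_class_levels <- function() c("lt100", "s100_500", "s500_1000", "ge1000")
id_bin_levels <- function() c("mid80_95", "hi95")

#' Turn hits into insertions, optionally merging overlapping subject spans
#'
#' Hits below the lower identity edge are excluded. Under
#' `policy = "per_hit"` every hit becomes one insertion. Under
#' `policy = "merge_overlaps"` hits in the same identity bin whose subject
#' spans overlap are unioned (identity bins never merge with each other);
#' the merged identity is the span-length-weighted mean of the members and
#' the strand is kept when unambiguous, else `"."`.
#'
#' @param hits hit data.frame from [nupt_search()] or [hits_from_table()].
#' @param policy `"merge_overlaps"` (default) or `"per_hit"`.
#' @param edges,breaks bin edges, see [assign_id_bin()]/[assign_size_class()].
#' @return insertion data.frame with columns `sid, sstart, send, strand,
#'   identity, length, size_class, id_bin, members` (`members` holds
#'   comma-joined row indices into `hits`).
#' @export
merge_hits <- function(hits, policy = c("merge_overlaps", "per_hit"),
                       edges = c(80, 95), breaks = c(100, 500, 1000)) {
  policy <- match.arg(policy)
  empty <- data.frame(sid = character(0), sstart = numeric(0),
                      send = numeric(0), strand = character(0),
                      identity = numeric(0), length = numeric(0),
                      size_class = character(0), id_bin = character(0),
                      members = character(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(empty)
  bin <- assign_id_bin(hits$identity, edges)
  keep <- which(!is.na(bin))
  if (length(keep) == 0) return(empty)
  h <- hits[keep, , drop = FALSE]
  h$id_bin <- bin[keep]
  h$row <- keep

  if (policy == "per_hit") {
    out <- data.frame(sid = h$sid, sstart = h$sstart, send = h$send,
                      strand = h$strand, identity = h$identity,
                      length = h$send - h$sstart,
                      size_class = assign_size_class(h$send - h$sstart, breaks),
                      id_bin = h$id_bin, members = as.character(h$row),
                      stringsAsFactors = FALSE)
  } else {
    groups <- split(h, paste(h$sid, h$id_bin, sep = "\r"))
    out <- do.call(rbind, lapply(groups, function(g) {
      red <- IRanges::reduce(ir0(g$sstart, g$send), with.revmap = TRUE)
      revmap <- S4Vectors::mcols(red)$revmap
      w <- g$send - g$sstart
      ident <- vapply(revmap, function(ii) sum(g$identity[ii] * w[ii]) / sum(w[ii]),
                      0.0)
      strand <- vapply(revmap, function(ii) {
        u <- unique(g$strand[ii]); if (length(u) == 1) u else "."
      }, "")
      members <- vapply(revmap, function(ii)
        paste(sort(g$row[ii]), collapse = ","), "")
      len <- IRanges::width(red)
      data.frame(sid = g$sid[1], sstart = ir0_start(red), send = ir0_end(red),
                 strand = strand, identity = ident, length = len,
                 size_class = assign_size_class(len, breaks),
                 id_bin = g$id_bin[1], members = members,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- out[order(out$sid, out$sstart, out$send), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-chromosome counts and relative lengths by identity bin and size class
#'
#' For every `(chromosome, id_bin, size_class)` cell: the number of
#' insertions, their summed length, and the relative length as a percent of
#' the chromosome. To avoid double-counting nuclear bases, `rel_len_pct` is
#' computed on the union of the cell's spans regardless of the merge policy
#' the insertions were built with.
#'
#' @param insertions insertion data.frame from [merge_hits()].
#' @param chrom_lens named numeric vector of chromosome lengths; every
#'   insertion chromosome must be present. Chromosomes with no insertions get
#'   all-zero rows.
#' @return data.frame with columns `sid, id_bin, size_class, count,
#'   total_len, rel_len_pct`.
#' @export
summarize_by_chromosome <- function(insertions, chrom_lens) {
  missing <- setdiff(unique(insertions$sid), names(chrom_lens))
  if (length(missing) > 0)
    stop("insertion chromosome(s) absent from chrom_lens: ",
         paste(missing, collapse = ", "))
  grid <- expand.grid(sid = names(chrom_lens), id_bin = id_bin_levels(),
                      size_class = size_class_levels(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(a, b, c) paste(a, b, c, sep = "\r")
  ik <- key(insertions$sid, insertions$id_bin, insertions$size_class)
  grid$count <- 0L
  grid$total_len <- 0
  grid$rel_len_pct <- 0
  gk <- key(grid$sid, grid$id_bin, grid$size_class)
  for (kk in unique(ik)) {
    sel <- ik == kk
    gi <- which(gk == kk)
    grid$count[gi] <- sum(sel)
    grid$total_len[gi] <- sum(insertions$length[sel])
    union_len <- sum_width(IRanges::reduce(
      ir0(insertions$sstart[sel], insertions$send[sel])))
    grid$rel_len_pct[gi] <-
      100 * union_len / chrom_lens[[grid$sid[gi]]]
  }
  grid <- grid[order(grid$sid, grid$id_bin, grid$size_class), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Filter alignments for link-table display
#'
#' Keeps spans of length >= `min_len` with identity >= `min_identity`
#' (defaults 100 bp and 80 percent), the filter used for ideogram/link
#' rendering. Summaries over all bins are unaffected by this filter.
#'
#' @param x hit or insertion table with `sstart, send, identity`.
#' @param min_len minimum subject-span length in bases.
#' @param min_identity minimum percent identity.
#' @return the filtered table.
#' @export
display_filter <- function(x, min_len = 100, min_identity = 80) {
  keep <- (x$send - x$sstart) >= min_len & x$identity >= min_identity
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
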