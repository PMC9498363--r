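#' Derive exon / intron / intergenic interval sets from gene annotation
#'
#' Introns are the gene-span bases not covered by any exon (so where isoforms
#' disagree, exon wins per base); intergenic space is the chromosome
#' complement of the merged gene spans. The three sets partition every
#' chromosome exactly, which is asserted before returning. TE features, when
#' provided, are carried both raw (for feature counts) and self-merged (for
#' base counts).
#'
#' @param features feature data.frame (see [read_gff3()]) containing `gene`
#'   and `exon` records; every exon must lie within some gene span.
#' @param chrom_lens named numeric vector of chromosome lengths.
#' @param te_features optional TE feature data.frame (`ftype = "TE"`).
#' @return object of class `annotation_index`: per-chromosome list of
#'   `IRanges` sets `exon`, `intron`, `intergenic`, `te_raw`, `te_merged`,
#'   plus `chrom_lens`.
#' @export
derive_regions <- function(features, chrom_lens, te_features = NULL) {
  if (!any(features$ftype == "gene") || !any(features$ftype == "exon"))
    stop("annotation must contain gene and exon records")
  per <- list()
  for (chrom in names(chrom_lens)) {
    L <- chrom_lens[[chrom]]
    f <- features[features$chrom == chrom, , drop = FALSE]
    genes <- f[f$ftype == "gene", , drop = FALSE]
    exons <- f[f$ftype == "exon", , drop = FALSE]
    gene_ir <- ir0(genes$start, genes$end)
    exon_ir <- ir0(exons$start, exons$end)
    if (length(exon_ir) > 0) {
      within <- IRanges::countOverlaps(exon_ir, gene_ir, type = "within") > 0
      if (any(!within)) {
        bad <- which(!within)[1]
        stop("exon ", exons$id[bad] %||% "?", " (", chrom, ":",
             exons$start[bad], "-", exons$end[bad],
             ") lies outside every gene span")
      }
    }
    gene_red <- IRanges::reduce(gene_ir)
    exon_red <- IRanges::reduce(exon_ir)
    chrom_ir <- ir0(0, L)
    intron <- IRanges::setdiff(gene_red, exon_red)
    intergenic <- IRanges::setdiff(chrom_ir, gene_red)
    covered <- sum_width(exon_red) + sum_width(intron) + sum_width(intergenic)
    stopifnot(covered == L)
    te <- if (is.null(te_features)) NULL else
      te_features[te_features$chrom == chrom, , drop = FALSE]
    per[[chrom]] <- list(
      exon = exon_red, intron = intron, intergenic = intergenic,
      te_raw = if (is.null(te)) IRanges::IRanges() else ir0(te$start, te$end),
      te_merged = if (is.null(te)) IRanges::IRanges() else
        IRanges::reduce(ir0(te$start, te$end)))
  }
  structure(list(chroms = per, chrom_lens = chrom_lens,
                 has_te = !is.null(te_features)),
            class = "annotation_index")
}

#' Per-base breakdown of insertions over exon / intron / intergenic space
#'
#' For each insertion, the number of bases overlapping each of the three
#' mutually exclusive region sets (they always sum to the insertion length),
#' plus flags naming every region overlapped by at least one base.
#'
#' @param insertions insertion data.frame (or any table with `sid, sstart,
#'   send`), chromosomes must be present in `index`.
#' @param index an `annotation_index` from [derive_regions()].
#' @return data.frame with columns `exon_bp, intron_bp, intergenic_bp,
#'   region_flags` (comma-joined subset of `exon,intron,inter`), one row per
#'   insertion.
#' @export
classify_insertion <- function(insertions, index) {
  stopifnot(inherits(index, "annotation_index"))
  n <- nrow(insertions)
  out <- data.frame(exon_bp = numeric(n), intron_bp = numeric(n),
                    intergenic_bp = numeric(n),
                    region_flags = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    chrom <- insertions$sid[i]
    cx <- index$chroms[[chrom]]
    if (is.null(cx)) stop("chromosome ", chrom, " absent from annotation index")
    span <- ir0(insertions$sstart[i], insertions$send[i])
    bp <- c(exon = sum_width(IRanges::intersect(span, cx$exon)),
            intron = sum_width(IRanges::intersect(span, cx$intron)),
            inter = sum_width(IRanges::intersect(span, cx$intergenic)))
    out$exon_bp[i] <- bp[["exon"]]
    out$intron_bp[i] <- bp[["intron"]]
    out$intergenic_bp[i] <- bp[["inter"]]
    out$region_flags[i] <- paste(names(bp)[bp > 0], collapse = ",")
  }
  out
}

#' Count and total TE bases overlapping a set of intervals
#'
#' Feature counts are raw (every TE feature overlapping any interval by at
#' least 1 bp counts once); base counts use self-merged TEs so nested or
#' overlapping TE annotations are not double-counted.
#'
#' @param intervals an `IRanges` (internally 1-based closed as produced by
#'   the package's helpers) or a data.frame with `sstart`/`send` 0-based
#'   half-open columns.
#' @param te_raw,te_merged raw and self-merged TE `IRanges` for one
#'   chromosome (as stored in an `annotation_index`).
#' @return named numeric vector `c(count = ..., bases = ...)`.
#' @export
te_overlap <- function(intervals, te_raw, te_merged = IRanges::reduce(te_raw)) {
  if (is.data.frame(intervals)) intervals <- ir0(intervals$sstart, intervals$send)
  cnt <- sum(IRanges::countOverlaps(te_raw, intervals) > 0)
  bases <- sum_width(IRanges::intersect(te_merged, IRanges::reduce(intervals)))
  c(count = cnt, bases = bases)
}

#' Region-by-size-class summary of insertions (with TE content)
#'
#' Restricted to one identity bin (default the recent, >= 95\% bin). Counts
#' follow `count_mode`: under `"any_overlap"` an insertion contributes one
#' count to every region it touches (intersect-style semantics); under
#' `"majority"` it counts only toward the region holding most of its bases.
#' Bases are always split exactly. TE content is computed on the portions of
#' the insertions attributed to each region.
#'
#' @param insertions insertion data.frame from [merge_hits()].
#' @param index an `annotation_index` with TE features.
#' @param id_bin_filter identity bin to keep (`"hi95"`, `"mid80_95"`, or
#'   `NULL` for all).
#' @param count_mode `"any_overlap"` (default) or `"majority"`.
#' @return data.frame with columns `region, size_class, count, bases,
#'   te_count, te_bases`.
#' @export
region_summary <- function(insertions, index, id_bin_filter = "hi95",
                           count_mode = c("any_overlap", "majority")) {
  count_mode <- match.arg(count_mode)
  ins <- insertions
  if (!is.null(id_bin_filter))
    ins <- ins[ins$id_bin == id_bin_filter, , drop = FALSE]
  regions <- c("exon", "intron", "inter")
  grid <- expand.grid(region = regions, size_class = size_class_levels(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$count <- 0L
  grid$bases <- 0
  grid$te_count <- if (index$has_te) 0 else NA_real_
  grid$te_bases <- if (index$has_te) 0 else NA_real_
  if (nrow(ins) == 0) return(grid)
  bd <- classify_insertion(ins, index)
  bp <- cbind(exon = bd$exon_bp, intron = bd$intron_bp, inter = bd$intergenic_bp)
  region_set <- function(cx, r) switch(r, exon = cx$exon, intron = cx$intron,
                                       inter = cx$intergenic)
  for (g in seq_len(nrow(grid))) {
    r <- grid$region[g]
    sel <- ins$size_class == grid$size_class[g]
    if (!any(sel)) next
    counted <- if (count_mode == "any_overlap") bp[sel, r] > 0 else
      max.col(bp[sel, , drop = FALSE], ties.method = "first") == match(r, regions) &
        bp[sel, r] > 0
    grid$count[g] <- sum(counted)
    grid$bases[g] <- sum(bp[sel, r])
    if (index$has_te) {
      tec <- 0; teb <- 0
      for (chrom in unique(ins$sid[sel])) {
        cx <- index$chroms[[chrom]]
        csel <- sel & ins$sid == chrom
        pieces <- IRanges::intersect(
          IRanges::reduce(ir0(ins$sstart[csel], ins$send[csel])),
          region_set(cx, r))
        if (length(pieces) == 0) next
        ov <- te_overlap(pieces, cx$te_raw, cx$te_merged)
        tec <- tec + ov[["count"]]
        teb <- teb + ov[["bases"]]
      }
      grid$te_count[g] <- tec
      grid$te_bases[g] <- teb
    }
  }
  grid
}
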