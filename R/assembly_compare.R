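#' NUPT-based assembly recovery index (bp/Mb)
#'
#' Summed length of the union of insertion spans with identity >=
#' `min_identity` and length >= `min_len`, per megabase of assembly:
#' `index = sum(len) / (genome_size / 1e6)`. Rationale: recent (>= 95\%
#' identity), non-trivial (>= 100 bp) organelle insertions are concentrated
#' in the repeat-rich regions that fragmented assemblies drop, so a more
#' complete assembly of the same genotype recovers at least as many such
#' bases. The formula is this package's operationalization of using NUPT
#' content as an assembly-completeness signal; the thresholds mirror the
#' headline identity/length bin and are overridable.
#'
#' @param insertions insertion data.frame from [merge_hits()].
#' @param genome_size assembly length in bases (> 0).
#' @param min_identity,min_len qualification thresholds.
#' @return index in bp per Mb (>= 0).
#' @export
igt_index <- function(insertions, genome_size, min_identity = 95,
                      min_len = 100) {
  stopifnot(genome_size > 0)
  sel <- insertions$identity >= min_identity & insertions$length >= min_len
  if (!any(sel)) return(0)
  tot <- 0
  ins <- insertions[sel, , drop = FALSE]
  for (chrom in unique(ins$sid)) {
    csel <- ins$sid == chrom
    tot <- tot + sum_width(IRanges::reduce(ir0(ins$sstart[csel],
                                               ins$send[csel])))
  }
  tot / (genome_size / 1e6)
}

#' Per-version NUPT report
#'
#' Bundles the quantities compared across assembly versions: genome size,
#' ambiguous-base count, the per-chromosome bin summary, and the
#' [igt_index()].
#'
#' @param label version label (e.g. accession or release name).
#' @param genome `DNAStringSet` (or named character) of the assembly.
#' @param insertions insertion data.frame from [merge_hits()].
#' @param date optional assembly date (used for ordering in comparisons).
#' @return list of class `version_report`.
#' @export
version_report <- function(label, genome, insertions, date = NA) {
  seqs <- as_seq_chr(genome)
  chrom_lens <- nchar(seqs)
  n_count <- sum(vapply(seqs, function(s)
    sum(Biostrings::letterFrequency(Biostrings::DNAString(s), "N")), 0.0))
  structure(list(label = label, date = date,
                 genome_size = sum(chrom_lens),
                 n_count = n_count,
                 summary = summarize_by_chromosome(insertions, chrom_lens),
                 igt_index = igt_index(insertions, sum(chrom_lens))),
            class = "version_report")
}

#' Cell-wise differences between two version reports
#'
#' Deltas (`B - A`) of count, total length and relative length per
#' `(chromosome, id_bin, size_class)` cell. Chromosome names must agree, or
#' be reconciled through `name_map` (applied to report `b`'s names);
#' unmapped chromosomes are an error listing the offenders.
#'
#' @param a,b `version_report` objects (conventionally `a` the older
#'   version, so positive deltas mean the newer assembly recovers more).
#' @param name_map optional data.frame with columns `from`, `to` renaming
#'   `b`'s chromosomes into `a`'s namespace.
#' @return data.frame with columns `sid, id_bin, size_class, d_count,
#'   d_total_len, d_rel_len_pct`.
#' @export
compare_versions <- function(a, b, name_map = NULL) {
  stopifnot(inherits(a, "version_report"), inherits(b, "version_report"))
  sa <- a$summary
  sb <- b$summary
  if (!is.null(name_map)) {
    idx <- match(sb$sid, name_map$from)
    sb$sid[!is.na(idx)] <- name_map$to[idx[!is.na(idx)]]
  }
  only_a <- setdiff(unique(sa$sid), unique(sb$sid))
  only_b <- setdiff(unique(sb$sid), unique(sa$sid))
  if (length(only_a) + length(only_b) > 0)
    stop("unmapped chromosome names; only in '", a$label, "': [",
         paste(only_a, collapse = ", "), "]; only in '", b$label, "': [",
         paste(only_b, collapse = ", "), "]")
  key <- function(s) paste(s$sid, s$id_bin, s$size_class, sep = "\r")
  m <- match(key(sa), key(sb))
  stopifnot(!anyNA(m))
  data.frame(sid = sa$sid, id_bin = sa$id_bin, size_class = sa$size_class,
             d_count = sb$count[m] - sa$count,
             d_total_len = sb$total_len[m] - sa$total_len,
             d_rel_len_pct = sb$rel_len_pct[m] - sa$rel_len_pct,
             stringsAsFactors = FALSE)
}
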