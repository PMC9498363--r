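# Independent oracles and shared fixtures.

# Quadratic-DP local alignment score from Biostrings (independent of the
# package's own extension code); same scoring scheme as search_params().
oracle_local <- function(q, s, params = search_params()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = TRUE)
  Biostrings::pairwiseAlignment(q, s, substitutionMatrix = mat,
                                gapOpening = -params$gap_open,
                                gapExtension = -params$gap_extend,
                                type = "local")
}

# TRUE when the oracle's optimal alignment contains an exact match run of at
# least k columns (i.e. the optimum passes through a seed the heuristic can
# find).
oracle_has_seed <- function(pa, k) {
  a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  eq <- a == b & a != "-"
  if (!any(eq)) return(FALSE)
  r <- rle(eq)
  max(r$lengths[r$values]) >= k
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Per-base region lookup, independent of the IRanges-based implementation:
# label every base from the raw feature table, then count over a span.
brute_region_bp <- function(features, chrom, chrom_len, sstart, send) {
  lab <- rep("inter", chrom_len)
  f <- features[features$chrom == chrom, , drop = FALSE]
  g <- f[f$ftype == "gene", , drop = FALSE]
  for (i in seq_len(nrow(g))) lab[(g$start[i] + 1):g$end[i]] <- "intron"
  e <- f[f$ftype == "exon", , drop = FALSE]
  for (i in seq_len(nrow(e))) lab[(e$start[i] + 1):e$end[i]] <- "exon"
  span <- lab[(sstart + 1):send]
  c(exon = sum(span == "exon"), intron = sum(span == "intron"),
    inter = sum(span == "inter"))
}

# Base fraction of the truth implants covered by insertions in a given bin.
recovered_fraction <- function(truth, insertions, bin = "hi95") {
  tot <- 0
  for (i in seq_len(nrow(truth))) {
    sel <- insertions$sid == truth$chrom[i] & insertions$id_bin == bin
    if (!any(sel)) next
    tot <- tot + sum(IRanges::width(IRanges::intersect(
      IRanges::IRanges(truth$sstart[i] + 1, truth$send[i]),
      IRanges::IRanges(insertions$sstart[sel] + 1, insertions$send[sel]))))
  }
  tot / sum(truth$length)
}

# Small fast worlds for stress tests; the package defaults stay untouched.
small_gp <- function(...) genome_params(n_chrom = 1, chrom_len = 120000,
                                        gene_count = 10, te_count = 20,
                                        plastome_len = 15000, ...)

.world_cache <- new.env(parent = emptyenv())
cached_default_world <- function() {
  if (is.null(.world_cache$w)) .world_cache$w <- build_world()
  .world_cache$w
}
cached_default_hits <- function() {
  if (is.null(.world_cache$h))
    .world_cache$h <- nupt_search(cached_default_world()$plastome,
                                  cached_default_world()$chromosomes)
  .world_cache$h
}
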