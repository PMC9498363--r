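#' Search parameters for the seed-and-extend aligner
#'
#' The scoring scheme defaults to the classic megablast-like values
#' (+2 match, -3 mismatch, gap of length L costing `gap_open + L*gap_extend`
#' = -5 - 2L) with an x-drop of 20; `lambda` and `K` are the Karlin-Altschul
#' parameters used for E-values and default to 0.625 nats per score unit and
#' 0.41. The E-value cutoff defaults to 1e-6.
#'
#' @param word_size exact-seed length in bases (4-31).
#' @param match,mismatch,gap_open,gap_extend alignment scores (penalties
#'   negative).
#' @param x_drop extension stops when the score drops more than this below
#'   the running maximum.
#' @param evalue_cutoff maximum E-value for a reported hit.
#' @param lambda,K Karlin-Altschul parameters for `E = K m n exp(-lambda S)`.
#' @param max_pos_per_kmer seed positions per k-mer are subsampled above this
#'   count (0 = no subsampling); guards against pathological repeats.
#' @param collapse_ir collapse hits sharing an identical subject span and
#'   strand (e.g. the two inverted-repeat copies of a plastome hitting one
#'   nuclear locus) to the single best-scoring hit, so downstream statistics
#'   do not double-count nuclear bases.
#' @return a list of class `search_params`.
#' @export
search_params <- function(word_size = 11L, match = 2L, mismatch = -3L,
                          gap_open = -5L, gap_extend = -2L, x_drop = 20L,
                          evalue_cutoff = 1e-6, lambda = 0.625, K = 0.41,
                          max_pos_per_kmer = 0L, collapse_ir = TRUE) {
  stopifnot(word_size >= 4, word_size <= 31,
            match > 0, mismatch < 0, gap_open <= 0, gap_extend < 0,
            x_drop > 0, evalue_cutoff > 0, lambda > 0, K > 0)
  structure(list(word_size = as.integer(word_size), match = as.integer(match),
                 mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 x_drop = as.integer(x_drop), evalue_cutoff = evalue_cutoff,
                 lambda = lambda, K = K,
                 max_pos_per_kmer = as.integer(max_pos_per_kmer),
                 collapse_ir = isTRUE(collapse_ir)),
            class = "search_params")
}

#' Build an exact-match k-mer index over subject sequences
#'
#' Maps every k-mer to its 0-based positions; k-mers containing `N` are
#' excluded. This is the reference indexing utility; [nupt_search()] uses an
#' equivalent native-code index internally.
#'
#' @param chromosomes `DNAStringSet` or named character vector.
#' @param word_size k-mer length.
#' @return object of class `seed_index`: an environment mapping k-mer strings
#'   to data.frames with columns `sid`, `pos` (0-based).
#' @export
build_seed_index <- function(chromosomes, word_size = 11L) {
  seqs <- as_seq_chr(chromosomes)
  if (length(seqs) == 0) stop("no subject sequences")
  if (word_size > min(nchar(seqs)))
    stop("word_size (", word_size, ") exceeds the shortest chromosome (",
         min(nchar(seqs)), " bp)")
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (sid in names(seqs)) {
    s <- seqs[[sid]]
    L <- nchar(s)
    n <- L - word_size + 1L
    if (n < 1) next
    kmers <- substring(s, 1:n, word_size:L)
    ok <- !grepl("N", kmers, fixed = TRUE)
    pos <- which(ok) - 1L
    for (i in seq_along(pos)) {
      km <- kmers[pos[i] + 1L]
      cur <- if (exists(km, envir = env)) get(km, envir = env) else NULL
      rec <- data.frame(sid = sid, pos = pos[i], stringsAsFactors = FALSE)
      assign(km, rbind(cur, rec), envir = env)
    }
  }
  structure(list(index = env, word_size = as.integer(word_size),
                 sids = names(seqs)), class = "seed_index")
}

#' Look up a k-mer in a seed index
#' @param index a `seed_index` from [build_seed_index()].
#' @param kmer k-mer string of the index's word size.
#' @return data.frame with columns `sid`, `pos` (possibly zero rows).
#' @export
lookup_seed <- function(index, kmer) {
  stopifnot(inherits(index, "seed_index"), nchar(kmer) == index$word_size)
  if (exists(kmer, envir = index$index)) get(kmer, envir = index$index)
  else data.frame(sid = character(0), pos = integer(0), stringsAsFactors = FALSE)
}

#' Gapped x-drop extension of one exact seed
#'
#' Extends left and right from an exact `word_size` match at
#' `query[qpos..]`/`subject[spos..]` until the score drops more than
#' `x_drop` below the running maximum, then rescores the clipped spans with
#' a banded global alignment to obtain the match/gap column counts behind
#' percent identity. Returns `NULL` when the best local score is negative.
#'
#' @param query,subject sequences (character or `DNAString(Set)`).
#' @param qpos,spos 0-based seed start positions; the precondition is
#'   `query[qpos, qpos+k) == subject[spos, spos+k)`.
#' @param params a [search_params()] object.
#' @param qid,sid labels for the returned hit.
#' @return a one-row hit data.frame, or `NULL`.
#' @export
extend_seed <- function(query, subject, qpos, spos, params = search_params(),
                        qid = "query", sid = "subject") {
  q <- as_seq_chr(query)[[1]]
  s <- as_seq_chr(subject)[[1]]
  k <- params$word_size
  if (substr(q, qpos + 1, qpos + k) != substr(s, spos + 1, spos + k))
    stop("seed mismatch: query[", qpos, ", ", qpos + k, ") != subject[",
         spos, ", ", spos + k, ")")
  ext <- cpp_extend_seed(q, s, qpos, spos, k, params$match, params$mismatch,
                         params$gap_open, params$gap_extend, params$x_drop)
  if (ext$score < 0) return(NULL)
  hit_stats(data.frame(qid = qid, sid = sid,
                       qstart = ext$qstart, qend = ext$qend,
                       sstart = ext$sstart, send = ext$send,
                       strand = "+", score = ext$score,
                       stringsAsFactors = FALSE),
            q, setNames(s, sid), params,
            n_total = nchar(s))
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)` for a local alignment of score `S`
#' between a query of length `m` and a subject database of total length `n`.
#'
#' @param score alignment score(s) (non-negative).
#' @param query_len query length `m` in bases.
#' @param subject_total_len summed subject length `n` in bases.
#' @param params a [search_params()] supplying `lambda` and `K`.
#' @return E-value(s).
#' @export
karlin_evalue <- function(score, query_len, subject_total_len,
                          params = search_params()) {
  stopifnot(all(score >= 0), query_len > 0, subject_total_len > 0)
  params$K * query_len * subject_total_len * exp(-params$lambda * score)
}

# smallest integer score with E <= cutoff
min_significant_score <- function(query_len, subject_total_len, params) {
  ceiling(log(params$K * query_len * subject_total_len /
                params$evalue_cutoff) / params$lambda)
}

# Rescore raw extension spans with banded global alignment; fills aln_len,
# matches, gaps, identity, score, evalue. Strand-space sequences expected.
hit_stats <- function(raw, qseq, sseqs, params, n_total) {
  n <- nrow(raw)
  out <- cbind(raw, aln_len = numeric(n), matches = numeric(n),
               gaps = numeric(n), identity = numeric(n))
  for (i in seq_len(n)) {
    a <- substr(qseq, raw$qstart[i] + 1, raw$qend[i])
    b <- substr(sseqs[[raw$sid[i]]], raw$sstart[i] + 1, raw$send[i])
    band <- max(32L, abs(nchar(a) - nchar(b)) + 32L)
    st <- cpp_align_stats(a, b, params$match, params$mismatch,
                          params$gap_open, params$gap_extend, band)
    out$score[i] <- max(st$score, raw$score[i])
    out$aln_len[i] <- st$aln_len
    out$matches[i] <- st$matches
    out$gaps[i] <- st$gap_cols
    out$identity[i] <- if (st$aln_len > 0) 100 * st$matches / st$aln_len else 0
  }
  out$evalue <- karlin_evalue(pmax(out$score, 0), nchar(qseq), n_total, params)
  out[, c("qid", "sid", "qstart", "qend", "sstart", "send", "strand",
          "aln_len", "matches", "gaps", "identity", "score", "evalue")]
}

#' Search an organellar genome against nuclear chromosomes
#'
#' Both strands of the query are searched (minus-strand hits are reported on
#' subject forward coordinates with `strand = "-"`). Hits are E-value
#' filtered, optionally collapsed when they share an identical subject span
#' and strand (inverted-repeat duplicates), and sorted by subject position.
#' The query is treated as linear; rotate it if alignments across the
#' circular origin matter.
#'
#' @param plastome single organellar query (`DNAStringSet` of length 1 or a
#'   one-element character vector); a mitogenome works identically.
#' @param chromosomes nuclear sequences (`DNAStringSet` or named character).
#' @param params a [search_params()] object.
#' @return hit data.frame with columns `qid, sid, qstart, qend, sstart, send,
#'   strand, aln_len, matches, gaps, identity, score, evalue` (coordinates
#'   0-based half-open on the forward strands).
#' @export
nupt_search <- function(plastome, chromosomes, params = search_params()) {
  q <- as_seq_chr(plastome)
  s <- as_seq_chr(chromosomes)
  if (length(q) != 1) stop("expected a single organellar query sequence")
  if (length(s) == 0) stop("no nuclear sequences")
  if (nchar(q[[1]]) == 0 || any(nchar(s) == 0)) stop("empty sequence")
  qid <- names(q) %||% "query"
  if (is.null(names(s))) names(s) <- paste0("chr", seq_along(s))
  qlen <- nchar(q[[1]])
  n_total <- sum(nchar(s))
  smin <- min_significant_score(qlen, n_total, params)
  min_keep <- max(params$word_size * params$match, smin - 10)
  qf <- q[[1]]
  qr <- revcomp_chr(qf)

  res <- list()
  for (sid in names(s)) {
    for (strand in c("+", "-")) {
      qs <- if (strand == "+") qf else qr
      raw <- cpp_search_pair(qs, s[[sid]], params$word_size, params$match,
                             params$mismatch, params$gap_open,
                             params$gap_extend, params$x_drop,
                             as.integer(min_keep), params$max_pos_per_kmer)
      raw <- as.data.frame(raw)
      if (nrow(raw) == 0) next
      raw <- raw[!duplicated(raw[, c("qstart", "qend", "sstart", "send")]), ,
                 drop = FALSE]
      raw$qid <- qid
      raw$sid <- sid
      raw$strand <- strand
      h <- hit_stats(raw, qs, s[sid], params, n_total)
      if (strand == "-") {
        qs0 <- qlen - h$qend
        h$qend <- qlen - h$qstart
        h$qstart <- qs0
      }
      res[[length(res) + 1L]] <- h
    }
  }
  hits <- if (length(res)) do.call(rbind, res) else empty_hits()
  hits <- hits[hits$evalue <= params$evalue_cutoff, , drop = FALSE]
  if (nrow(hits) > 0 && params$collapse_ir) {
    key <- paste(hits$sid, hits$sstart, hits$send, hits$strand)
    hits <- hits[order(key, -hits$score, hits$qstart), , drop = FALSE]
    hits <- hits[!duplicated(paste(hits$sid, hits$sstart, hits$send,
                                   hits$strand)), , drop = FALSE]
  }
  hits <- hits[order(hits$sid, hits$sstart, hits$send, hits$strand,
                     hits$qstart), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Convert externally computed tabular alignments to internal hits
#'
#' Rows from [read_hit_table()] (1-based inclusive, `sstart > send` encoding
#' the minus strand) are converted to 0-based half-open forward-strand
#' coordinates, and the E-value cutoff is applied. Identity and E-value are
#' copied verbatim; the alignment path is not available externally, so
#' `matches` and `gaps` are `NA` and `score` carries the bit score.
#'
#' @param rows data.frame from [read_hit_table()].
#' @param params a [search_params()] (supplies the E-value cutoff).
#' @return internal hit data.frame as in [nupt_search()].
#' @export
hits_from_table <- function(rows, params = search_params()) {
  if (nrow(rows) == 0) return(empty_hits())
  minus <- rows$sstart > rows$send
  hits <- data.frame(
    qid = rows$qid, sid = rows$sid,
    qstart = rows$qstart - 1, qend = rows$qend,
    sstart = ifelse(minus, rows$send, rows$sstart) - 1,
    send = ifelse(minus, rows$sstart, rows$send),
    strand = ifelse(minus, "-", "+"),
    aln_len = rows$length, matches = NA_real_, gaps = NA_real_,
    identity = rows$pident, score = rows$bitscore, evalue = rows$evalue,
    stringsAsFactors = FALSE)
  hits <- hits[hits$evalue <= params$evalue_cutoff, , drop = FALSE]
  hits <- hits[order(hits$sid, hits$sstart, hits$send, hits$strand,
                     hits$qstart), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
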