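#' Read a FASTA file of DNA sequences
#'
#' Sequences are uppercased, `U` is mapped to `T`, and any character outside
#' `{A,C,G,T,N}` (IUPAC ambiguity codes, gaps, ...) is mapped to `N` with a
#' warning. Record ids are the first whitespace-delimited token of each
#' header and must be unique.
#'
#' @param path path to a FASTA file (multi-record allowed).
#' @return a [Biostrings::DNAStringSet] over the alphabet `{A,C,G,T,N}`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(raw))
  seqs <- chartr("U", "T", seqs)
  bad <- gsub("[ACGTN]", "", seqs)
  n_bad <- sum(nchar(bad))
  if (n_bad > 0) {
    warning(n_bad, " non-ACGTN character(s) mapped to N in ", path)
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), "",
                   USE.NAMES = FALSE)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs a `DNAStringSet` or named character vector.
#' @param path output path.
#' @param desc optional description appended to every header line (e.g. a
#'   simulation seed), since FASTA has no comment syntax.
#' @export
write_fasta <- function(seqs, path, desc = NULL) {
  x <- Biostrings::DNAStringSet(as_seq_chr(seqs))
  if (!is.null(desc)) names(x) <- paste(names(x), desc)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a GFF3 annotation into a normalized feature table
#'
#' GFF3 coordinates (1-based inclusive) are converted to the package-internal
#' 0-based half-open convention. Feature types are normalized through
#' `type_map`; unmapped types are retained with `ftype = "other"`. When
#' `type_map` is `NULL`, every feature is assigned `all_to` (used for TE
#' annotation files, where each record is a transposable element regardless
#' of its family-specific type string).
#'
#' @param path path to a GFF3 file.
#' @param type_map named character vector mapping source types to one of
#'   `gene`, `exon`, `TE`, `other`; or `NULL` to map everything to `all_to`.
#' @param all_to ftype assigned to all records when `type_map` is `NULL`.
#' @return data.frame with columns `chrom, start, end, strand, ftype, id,
#'   attrs` (`start`/`end` 0-based half-open).
#' @export
read_gff3 <- function(path, type_map = c(gene = "gene", exon = "exon"),
                      all_to = "TE") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      ftype = character(0), id = character(0),
                      attrs = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc < 8))
    stop("malformed GFF3 line ", lineno[which(nc < 8)[1]], " in ", path)
  chrom <- vapply(parts, `[[`, "", 1L)
  stype <- vapply(parts, `[[`, "", 3L)
  start1 <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 4L)))
  end1 <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 5L)))
  strand <- vapply(parts, `[[`, "", 7L)
  attrs <- vapply(parts, function(p) if (length(p) >= 9) p[[9]] else "", "")
  if (anyNA(start1) || anyNA(end1))
    stop("non-numeric coordinates at GFF3 line ",
         lineno[which(is.na(start1) | is.na(end1))[1]], " in ", path)
  bad <- which(end1 < start1)
  if (length(bad) > 0)
    stop("end < start at GFF3 line ", lineno[bad[1]], " in ", path)
  strand[!strand %in% c("+", "-")] <- "."
  ftype <- if (is.null(type_map)) rep(all_to, length(stype)) else {
    f <- unname(type_map[stype])
    f[is.na(f)] <- "other"
    f
  }
  id <- ifelse(grepl("ID=", attrs),
               sub(".*ID=([^;]+).*", "\\1", attrs), NA_character_)
  data.frame(chrom = chrom, start = start1 - 1, end = end1,
             strand = strand, ftype = ftype, id = id, attrs = attrs,
             stringsAsFactors = FALSE)
}

#' Read a BED interval file into a normalized feature table
#'
#' BED is already 0-based half-open, so coordinates pass through unchanged.
#' Columns beyond the first three (name, score, strand) are used when present.
#'
#' @param path path to a BED file (3-6 columns).
#' @param ftype ftype assigned to every record (default `"TE"`; BED input is
#'   the TE-annotation path).
#' @return data.frame as in [read_gff3()].
#' @export
read_bed <- function(path, ftype = "TE") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      ftype = character(0), id = character(0),
                      attrs = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3)) stop("BED line with fewer than 3 columns in ", path)
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- as.numeric(vapply(parts, `[[`, "", 2L))
  end <- as.numeric(vapply(parts, `[[`, "", 3L))
  id <- vapply(parts, function(p) if (length(p) >= 4) p[[4]] else NA_character_, "")
  strand <- vapply(parts, function(p) if (length(p) >= 6) p[[6]] else ".", "")
  strand[!strand %in% c("+", "-")] <- "."
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             ftype = ftype, id = id, attrs = NA_character_,
             stringsAsFactors = FALSE)
}

#' Read a TE annotation, auto-detecting GFF3 vs BED by file extension
#'
#' Every record in the file is treated as a transposable element.
#'
#' @param path path to a `.gff`/`.gff3` or `.bed` file.
#' @return data.frame as in [read_gff3()], all rows with `ftype = "TE"`.
#' @export
read_te_annotation <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) read_bed(path, ftype = "TE")
  else read_gff3(path, type_map = NULL, all_to = "TE")
}

#' Write a feature table as GFF3
#'
#' Internal 0-based half-open coordinates are emitted 1-based inclusive.
#'
#' @param features feature data.frame (see [read_gff3()]).
#' @param path output path.
#' @param comments character vector of `#`-comment lines (e.g. seed).
#' @export
write_gff3 <- function(features, path, comments = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (cm in comments) writeLines(paste0("# ", cm), con)
  if (nrow(features) > 0) {
    attrs <- ifelse(is.na(features$id), ".", paste0("ID=", features$id))
    writeLines(paste(features$chrom, "nuptscan", features$ftype,
                     format(features$start + 1, scientific = FALSE, trim = TRUE),
                     format(features$end, scientific = FALSE, trim = TRUE),
                     ".", features$strand, ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a 12-column tabular alignment file (BLAST outfmt 6 dialect)
#'
#' Rows are parsed verbatim: coordinates stay 1-based inclusive and
#' `s.start > s.end` (minus-strand) is preserved. No filtering is applied;
#' use [hits_from_table()] to convert to internal hits.
#'
#' @param path path to a tab-separated 12-column file.
#' @return data.frame with the standard columns `qid, sid, pident, length,
#'   mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore`.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  cols <- c("qid", "sid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (length(lines) == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), 12), cols),
                         stringsAsFactors = FALSE)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12)
  if (length(bad) > 0)
    stop("expected 12 tab-separated columns at line ", lineno[bad[1]],
         " in ", path, " (found ", lengths(parts)[bad[1]], ")")
  m <- do.call(rbind, parts)
  out <- data.frame(m, stringsAsFactors = FALSE)
  colnames(out) <- cols
  for (k in c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
              "sstart", "send", "evalue", "bitscore")) {
    v <- out[[k]]
    v[v %in% c("NA", ".")] <- NA  # emitters without path-level counts
    out[[k]] <- as.numeric(v)
  }
  out
}

#' Write hits as a 12-column tabular alignment file
#'
#' Internal 0-based half-open hits are emitted in the outfmt-6 convention:
#' 1-based inclusive, with minus-strand hits encoded by `sstart > send`.
#'
#' @param hits internal hit table (see [nupt_search()]).
#' @param path output path.
#' @param comments `#`-comment lines written before the data.
#' @export
write_hit_table <- function(hits, path, comments = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  if (nrow(hits) > 0) {
    minus <- hits$strand == "-"
    s1 <- ifelse(minus, hits$send, hits$sstart + 1)
    s2 <- ifelse(minus, hits$sstart + 1, hits$send)
    mism <- hits$aln_len - hits$matches - hits$gaps
    writeLines(paste(hits$qid, hits$sid, sprintf("%.2f", hits$identity),
                     hits$aln_len, mism, NA, hits$qstart + 1, hits$qend,
                     s1, s2, format(hits$evalue, digits = 3),
                     hits$score, sep = "\t"), con)
  }
  invisible(path)
}

#' Write a links table for synteny/ideogram visualization
#'
#' One line per alignment: query chrom/start/end, subject chrom/start/end,
#' percent identity, and a highlight flag set for identity >= `highlight_min`
#' (recent transfers). Coordinates are emitted 1-based inclusive to match the
#' convention of Circos/LINKVIEW-style link files.
#'
#' @param x hit or insertion table carrying `qid, qstart, qend, sid, sstart,
#'   send, identity` (0-based half-open).
#' @param path output path.
#' @param highlight_min identity threshold for the highlight flag (percent).
#' @param comments `#`-comment lines written before the header.
#' @export
write_links_table <- function(x, path, highlight_min = 95,
                              comments = character(0)) {
  df <- data.frame(
    qid = as.character(x$qid %||% character(0)),
    qstart = x$qstart + 1, qend = x$qend,
    sid = x$sid, sstart = x$sstart + 1, send = x$send,
    identity = sprintf("%.1f", x$identity),
    highlight = as.integer(x$identity >= highlight_min),
    stringsAsFactors = FALSE)
  write_tsv(df, path, comments = comments)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
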