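# shared internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Coerce sequences to a named character vector of uppercase DNA.
as_seq_chr <- function(x) {
  if (is(x, "DNAStringSet") || is(x, "BStringSet"))
    return(setNames(as.character(x), names(x)))
  if (is(x, "DNAString") || is(x, "BString"))
    return(as.character(x))
  if (is.character(x)) return(toupper(x))
  stop("expected a DNAStringSet or character vector of sequences")
}

seq_lengths <- function(x) {
  s <- as_seq_chr(x)
  setNames(nchar(s), names(s))
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# IRanges helpers on 0-based half-open (start0, end0) spans
ir0 <- function(start0, end0) IRanges::IRanges(start = start0 + 1L, end = end0)
ir0_start <- function(ir) IRanges::start(ir) - 1L
ir0_end <- function(ir) IRanges::end(ir)

sum_width <- function(ir) sum(IRanges::width(ir))

# TSV writer with "#"-prefixed comment lines before the header
write_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df) > 0) {
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(qid = character(0), sid = character(0),
             qstart = numeric(0), qend = numeric(0),
             sstart = numeric(0), send = numeric(0),
             strand = character(0), aln_len = numeric(0),
             matches = numeric(0), gaps = numeric(0),
             identity = numeric(0), score = numeric(0),
             evalue = numeric(0), stringsAsFactors = FALSE)
}
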