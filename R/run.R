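default_config <- function() {
  list(query = NULL, genome = NULL, genes = NULL, te = NULL,
       hit_table = NULL, outdir = "nuptscan_out",
       evalue = 1e-6, word_size = 11L, match = 2L, mismatch = -3L,
       gap_open = -5L, gap_extend = -2L, x_drop = 20L,
       lambda = 0.625, K = 0.41, max_pos_per_kmer = 0L, collapse_ir = TRUE,
       id_bin_edges = c(80, 95), size_breaks = c(100, 500, 1000),
       flank_sizes = c(100, 500, 1000, 2000),
       merge_policy = "merge_overlaps", region_count_mode = "any_overlap",
       display_min_len = 100, display_min_identity = 80,
       seed = 1L, log_level = "info")
}

#' Validate a run configuration
#'
#' Accepts a YAML file path or a named list; unknown keys are rejected (no
#' silent typos), missing keys are filled from the documented defaults
#' (E-value cutoff 1e-6, identity edges 80/95, size breakpoints
#' 100/500/1000, flank sizes 100/500/1000/2000), and numeric fields are
#' range-checked.
#'
#' @param config YAML path or named list (an empty/NULL config yields the
#'   full defaults).
#' @return list of class `nupt_config`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  cfg[names(config)] <- config
  with(cfg, {
    stopifnot(evalue > 0, word_size >= 4, word_size <= 31,
              match > 0, mismatch < 0, gap_open <= 0, gap_extend < 0,
              x_drop > 0, lambda > 0, K > 0,
              length(id_bin_edges) == 2, id_bin_edges[1] < id_bin_edges[2],
              length(size_breaks) == 3, all(diff(size_breaks) > 0),
              all(flank_sizes > 0),
              merge_policy %in% c("merge_overlaps", "per_hit"),
              region_count_mode %in% c("any_overlap", "majority"))
  })
  for (key in c("query", "genome", "genes", "te", "hit_table")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("config path for '", key, "' does not exist: ", cfg[[key]])
  }
  class(cfg) <- "nupt_config"
  cfg
}

config_search_params <- function(cfg) {
  search_params(word_size = cfg$word_size, match = cfg$match,
                mismatch = cfg$mismatch, gap_open = cfg$gap_open,
                gap_extend = cfg$gap_extend, x_drop = cfg$x_drop,
                evalue_cutoff = cfg$evalue, lambda = cfg$lambda, K = cfg$K,
                max_pos_per_kmer = cfg$max_pos_per_kmer,
                collapse_ir = cfg$collapse_ir)
}

# Stable hash of the effective configuration (drives reproducibility checks;
# no timestamps anywhere in outputs, so equal hash + seed => equal bytes).
# Where outputs land and how chatty the run is do not affect results, so
# outdir/log_level are excluded.
config_hash <- function(cfg) {
  canon <- cfg[setdiff(sort(names(cfg)), c("outdir", "log_level"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(lapply(canon, function(x)
    if (is.null(x)) "" else x)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full detection pipeline
#'
#' Stages: homology search (or import of an external hit table), insertion
#' classification and per-chromosome summary, genic-region attribution (when
#' gene annotation is given), flank GC/TE profiling, link-table export, and
#' a JSON report. All TSVs carry the seed and config hash in header
#' comments; reruns with an identical config are byte-identical. Without a
#' TE annotation, TE columns are emitted as `NA` with a warning. On a stage
#' failure, outputs written so far are moved to `outdir/partial` and the
#' error names the stage.
#'
#' @param config a [validate_config()] result, a list, or a YAML path.
#' @return list with the computed tables (`hits`, `insertions`,
#'   `chrom_summary`, `region_summary`, `flanks`, `igt_index`, paths).
#' @export
run_all <- function(config) {
  cfg <- if (inherits(config, "nupt_config")) config else validate_config(config)
  if (is.null(cfg$genome)) stop("config must name a genome FASTA")
  if (is.null(cfg$query) && is.null(cfg$hit_table))
    stop("config must name an organellar query FASTA or a hit_table")
  hash <- config_hash(cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$outdir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    if (identical(cfg$log_level, "debug")) message(msg)
  }
  comments <- c(paste0("nuptscan ",
                       as.character(utils::packageVersion("nuptscan"))),
                paste0("seed=", cfg$seed), paste0("config=", hash))
  logmsg("nuptscan run; seed=", cfg$seed, "; config=", hash)

  stage <- "init"
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(cfg$outdir, name)
    write_tsv(df, p, comments = comments)
    written <<- c(written, p)
    p
  }
  result <- tryCatch({
    stage <- "read_inputs"
    genome <- read_fasta(cfg$genome)
    chrom_lens <- seq_lengths(genome)
    te <- NULL
    if (!is.null(cfg$te)) te <- read_te_annotation(cfg$te)
    else warning("no TE annotation supplied; TE columns will be NA")
    genes <- if (!is.null(cfg$genes)) read_gff3(cfg$genes) else NULL
    params <- config_search_params(cfg)

    stage <- "scan"
    hits <- if (!is.null(cfg$hit_table))
      hits_from_table(read_hit_table(cfg$hit_table), params)
    else nupt_search(read_fasta(cfg$query), genome, params)
    logmsg("scan: ", nrow(hits), " hits at E<=", cfg$evalue)
    p <- file.path(cfg$outdir, "hits.outfmt6.tsv")
    write_hit_table(hits, p, comments = comments)
    written <- c(written, p)
    emit(hits, "hits.tsv")

    stage <- "classify"
    insertions <- merge_hits(hits, policy = cfg$merge_policy,
                             edges = cfg$id_bin_edges,
                             breaks = cfg$size_breaks)
    chrom_summary <- summarize_by_chromosome(insertions, chrom_lens)
    logmsg("classify: ", nrow(insertions), " insertions (",
           cfg$merge_policy, ")")
    emit(insertions, "insertions.tsv")
    emit(chrom_summary, "chrom_summary.tsv")

    stage <- "links"
    shown <- display_filter(hits, cfg$display_min_len,
                            cfg$display_min_identity)
    p <- file.path(cfg$outdir, "links.tsv")
    write_links_table(shown, p, highlight_min = cfg$id_bin_edges[2],
                      comments = comments)
    written <- c(written, p)

    stage <- "context"
    region_sum <- NULL
    index <- NULL
    if (!is.null(genes)) {
      index <- derive_regions(genes, chrom_lens, te)
      region_sum <- region_summary(insertions, index,
                                   id_bin_filter = "hi95",
                                   count_mode = cfg$region_count_mode)
      emit(region_sum, "region_summary.tsv")
    } else if (!is.null(te)) {
      index <- structure(list(
        chroms = lapply(setNames(nm = names(chrom_lens)), function(cn) {
          tt <- te[te$chrom == cn, , drop = FALSE]
          list(te_raw = ir0(tt$start, tt$end),
               te_merged = IRanges::reduce(ir0(tt$start, tt$end)))
        }),
        chrom_lens = chrom_lens, has_te = TRUE),
        class = "annotation_index")
    }

    stage <- "flanks"
    flanks <- flank_table(insertions, genome, index, sizes = cfg$flank_sizes)
    emit(flanks, "flanks.tsv")

    stage <- "report"
    idx_val <- igt_index(insertions, sum(chrom_lens))
    report <- list(version = as.character(utils::packageVersion("nuptscan")),
                   seed = cfg$seed, config = hash,
                   genome_size = sum(chrom_lens),
                   n_hits = nrow(hits), n_insertions = nrow(insertions),
                   igt_index = idx_val)
    jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    logmsg("done; igt_index=", format(idx_val))
    list(hits = hits, insertions = insertions,
         chrom_summary = chrom_summary, region_summary = region_sum,
         flanks = flanks, igt_index = idx_val, config = cfg,
         outdir = cfg$outdir)
  }, error = function(e) {
    part <- file.path(cfg$outdir, "partial")
    dir.create(part, showWarnings = FALSE)
    for (p in written) if (file.exists(p))
      file.rename(p, file.path(part, basename(p)))
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  result
}
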