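# Synthetic test worlds: random plastome + nuclear chromosomes carrying
# implanted plastome fragments of controlled identity/length/placement, with
# matching gene and TE annotations and a ground-truth table. Implants replace
# background bases in place, so annotation coordinates stay valid.

rand_dna <- function(n, gc) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a plastome-like random sequence
#'
#' Uniform-random DNA at a target GC fraction (real plastomes are ~0.37 GC
#' and 120-160 kb; any length is allowed). Deterministic per seed.
#'
#' @param length sequence length in bases.
#' @param gc target GC fraction.
#' @param seed RNG seed.
#' @return `DNAStringSet` of length 1 named `"plastome"`.
#' @export
simulate_plastome <- function(length, gc = 0.37, seed = 1) {
  s <- with_seed(seed, rand_dna(length, gc))
  out <- Biostrings::DNAStringSet(s)
  names(out) <- "plastome"
  out
}

# Mutate under the caller's RNG: n_mut = round(L * (100-target)/100) events,
# an indel_fraction of them 1-bp indels (half insertions, half deletions),
# the rest substitutions to a different base at distinct positions.
mutate_core <- function(fragment, target_identity, indel_fraction = 0) {
  L <- nchar(fragment)
  n_mut <- round(L * (100 - target_identity) / 100)
  if (n_mut == 0) return(fragment)
  n_indel <- round(n_mut * indel_fraction)
  n_sub <- n_mut - n_indel
  chars <- strsplit(fragment, "")[[1]]
  pos <- sample.int(L, n_sub)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  if (n_indel > 0) {
    at <- sort(sample.int(length(chars), n_indel), decreasing = TRUE)
    ins <- runif(n_indel) < 0.5
    for (t in seq_len(n_indel)) {
      p <- at[t]
      if (ins[t]) {
        chars <- append(chars, sample(c("A", "C", "G", "T"), 1), after = p)
      } else if (length(chars) > 1) {
        chars <- chars[-p]
      }
    }
  }
  paste(chars, collapse = "")
}

#' Mutate a fragment to a target percent identity
#'
#' Substitutions (and optionally a fraction of 1-bp indels) are placed
#' uniformly so that realigning the mutated fragment against the original
#' yields approximately `target_identity`; the realized identity is computed
#' with the package's own global realignment and returned alongside.
#' With `indel_fraction = 0` the arithmetic is exact: a 1000 bp fragment at
#' target 95 receives exactly 50 substitutions and realizes 95.0.
#'
#' @param fragment DNA string.
#' @param target_identity percent in \[80, 100\].
#' @param indel_fraction fraction of mutation events that are 1-bp indels.
#' @param seed RNG seed.
#' @param params [search_params()] supplying the realignment scoring scheme.
#' @return list with `seq` (mutated string) and `realized_identity`.
#' @export
mutate_to_identity <- function(fragment, target_identity, indel_fraction = 0,
                               seed = 1, params = search_params()) {
  stopifnot(target_identity >= 0, target_identity <= 100)
  fragment <- as_seq_chr(fragment)[[1]]
  mut <- with_seed(seed, mutate_core(fragment, target_identity, indel_fraction))
  list(seq = mut, realized_identity = realign_identity(mut, fragment, params))
}

realign_identity <- function(a, b, params = search_params()) {
  if (nchar(a) == 0 && nchar(b) == 0) return(100)
  band <- max(32L, abs(nchar(a) - nchar(b)) + 32L)
  st <- cpp_align_stats(a, b, params$match, params$mismatch, params$gap_open,
                        params$gap_extend, band)
  if (st$aln_len == 0) 0 else 100 * st$matches / st$aln_len
}

#' Implant specification for [build_world()]
#'
#' Defaults describe the package's reference world: 30 implants split evenly
#' across the three size classes of at least 100 bp (lengths 120-3000 bp,
#' kept clear of the class boundaries so end-trimming during recovery cannot
#' flip a class), identities drawn uniformly from 96-100 percent (recent
#' transfers), both strands equally likely, placement unconstrained
#' (`uniform`), implants mutually separated and kept `end_margin` bases from
#' chromosome ends so that 2000-bp flanks are never clipped.
#'
#' @param class_counts named integer vector of implant counts per size class
#'   (`lt100, s100_500, s500_1000, ge1000`).
#' @param identity_range range for uniform identity targets (percent).
#' @param identity_targets optional explicit identity targets, recycled
#'   across fragments (overrides `identity_range`).
#' @param indel_fraction fraction of mutation events that are 1-bp indels.
#' @param placement named weights over `uniform`, `exon`, `intron`,
#'   `intergenic`: per fragment, the placement mode is drawn from these and
#'   the implant is required to lie entirely inside a window of that type.
#' @param strand_weights named weights for `+` / `-` implants.
#' @param te_adjacency_bias probability that a fragment is constrained to lie
#'   within `te_adjacency_dist` of an annotated TE.
#' @param te_adjacency_dist adjacency distance in bases.
#' @param length_ranges per-class sampling ranges for implant lengths.
#' @param end_margin minimum distance from chromosome ends in bases.
#' @param min_separation minimum gap between implants in bases.
#' @param seed RNG seed used by [build_world()].
#' @return list of class `implant_spec`.
#' @export
implant_spec <- function(class_counts = c(lt100 = 0, s100_500 = 10,
                                          s500_1000 = 10, ge1000 = 10),
                         identity_range = c(96, 100),
                         identity_targets = NULL,
                         indel_fraction = 0,
                         placement = c(uniform = 1),
                         strand_weights = c("+" = 0.5, "-" = 0.5),
                         te_adjacency_bias = 0, te_adjacency_dist = 500,
                         length_ranges = list(lt100 = c(40, 90),
                                              s100_500 = c(120, 450),
                                              s500_1000 = c(550, 950),
                                              ge1000 = c(1050, 3000)),
                         end_margin = 4000, min_separation = 200,
                         seed = 42) {
  stopifnot(all(class_counts >= 0),
            all(names(class_counts) %in% size_class_levels()),
            all(names(placement) %in% c("uniform", "exon", "intron",
                                        "intergenic")),
            all(placement >= 0), sum(placement) > 0,
            te_adjacency_bias >= 0, te_adjacency_bias <= 1)
  if (!is.null(identity_targets))
    stopifnot(all(identity_targets >= 0 & identity_targets <= 100))
  structure(list(class_counts = class_counts,
                 identity_range = identity_range,
                 identity_targets = identity_targets,
                 indel_fraction = indel_fraction,
                 placement = placement, strand_weights = strand_weights,
                 te_adjacency_bias = te_adjacency_bias,
                 te_adjacency_dist = te_adjacency_dist,
                 length_ranges = length_ranges, end_margin = end_margin,
                 min_separation = min_separation, seed = seed),
            class = "implant_spec")
}

#' Genome parameters for [build_world()]
#'
#' Defaults give a desk-scale world: two 300 kb chromosomes at 0.36 GC with
#' 25 multi-exon genes and 50 TE intervals each, and a 30 kb plastome at
#' 0.37 GC - small enough for fast tests, large enough that random seed
#' matches stay far below the E-value cutoff.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length in bases (recycled).
#' @param gene_count genes per chromosome.
#' @param gene_len gene length range in bases.
#' @param exons_per_gene range of exon counts per gene (>= 2).
#' @param te_count TE intervals per chromosome.
#' @param te_len TE length range in bases.
#' @param gc background nuclear GC fraction.
#' @param plastome_len,plastome_gc plastome length and GC.
#' @return list of class `genome_params`.
#' @export
genome_params <- function(n_chrom = 2, chrom_len = 300000, gene_count = 25,
                          gene_len = c(1000, 5000), exons_per_gene = c(2, 5),
                          te_count = 50, te_len = c(200, 3000), gc = 0.36,
                          plastome_len = 30000, plastome_gc = 0.37) {
  stopifnot(n_chrom >= 1, all(chrom_len > 0), exons_per_gene[1] >= 2)
  structure(list(n_chrom = n_chrom,
                 chrom_len = rep_len(chrom_len, n_chrom),
                 gene_count = gene_count, gene_len = gene_len,
                 exons_per_gene = exons_per_gene, te_count = te_count,
                 te_len = te_len, gc = gc, plastome_len = plastome_len,
                 plastome_gc = plastome_gc), class = "genome_params")
}

place_genes <- function(chrom, L, gp) {
  rows <- list()
  occupied <- IRanges::IRanges()
  attempts <- 0
  placed <- 0
  while (placed < gp$gene_count && attempts < gp$gene_count * 50) {
    attempts <- attempts + 1
    glen <- sample(gp$gene_len[1]:gp$gene_len[2], 1)
    if (glen + 2 > L) next
    gs <- sample.int(L - glen, 1) - 1L
    span <- ir0(gs - 100, gs + glen + 100)
    if (sum(IRanges::countOverlaps(span, occupied)) > 0) next
    occupied <- c(occupied, span)
    placed <- placed + 1
    gid <- sprintf("gene_%s_%03d", chrom, placed)
    k <- sample(gp$exons_per_gene[1]:gp$exons_per_gene[2], 1)
    cuts <- sort(sample.int(glen - 1, 2 * (k - 1)))
    bounds <- c(0, cuts, glen)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, start = gs, end = gs + glen, strand = "+",
      ftype = "gene", id = gid, attrs = paste0("ID=", gid),
      stringsAsFactors = FALSE)
    for (e in seq_len(k)) {
      es <- gs + bounds[2 * e - 1]
      ee <- gs + bounds[2 * e]
      eid <- sprintf("%s.e%d", gid, e)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = es, end = ee, strand = "+", ftype = "exon",
        id = eid, attrs = paste0("ID=", eid, ";Parent=", gid),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

place_tes <- function(chrom, L, gp) {
  rows <- list()
  occupied <- IRanges::IRanges()
  attempts <- 0
  placed <- 0
  while (placed < gp$te_count && attempts < gp$te_count * 50) {
    attempts <- attempts + 1
    tlen <- sample(gp$te_len[1]:gp$te_len[2], 1)
    if (tlen + 1 > L) next
    ts <- sample.int(L - tlen, 1) - 1L
    span <- ir0(ts - 10, ts + tlen + 10)
    if (sum(IRanges::countOverlaps(span, occupied)) > 0) next
    occupied <- c(occupied, span)
    placed <- placed + 1
    tid <- sprintf("te_%s_%03d", chrom, placed)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, start = ts, end = ts + tlen, strand = ".",
      ftype = "TE", id = tid, attrs = paste0("ID=", tid),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Build a fully specified synthetic world
#'
#' Generates a random plastome and nuclear chromosomes, lays down
#' non-overlapping multi-exon genes and TE intervals, then implants plastome
#' fragments per the [implant_spec()]: each fragment is cut from the
#' plastome, mutated to its identity target, reverse-complemented according
#' to its strand draw, and written over background bases at a position
#' satisfying the placement constraints (never overlapping another implant).
#' The returned truth table records, for every implant, its plastome source
#' span, nuclear target span, strand, target and realized identity, size
#' class, the genic region it landed in (`mixed` when straddling a
#' boundary), and the distance to the nearest TE.
#'
#' @param spec an [implant_spec()].
#' @param gp a [genome_params()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return list of class `nupt_world` with elements `plastome`,
#'   `chromosomes` (both `DNAStringSet`), `features`, `te`, `truth`
#'   (data.frames), `index` (annotation index), `chrom_lens`, `seed`,
#'   `spec`, `gp`.
#' @export
build_world <- function(spec = implant_spec(), gp = genome_params(),
                        seed = spec$seed) {
  with_seed(seed, {
    plastome_chr <- rand_dna(gp$plastome_len, gp$plastome_gc)
    chrom_names <- paste0("chr", seq_len(gp$n_chrom))
    chroms <- lapply(seq_len(gp$n_chrom),
                     function(i) rand_dna(gp$chrom_len[i], gp$gc))
    names(chroms) <- chrom_names
    chrom_lens <- setNames(as.numeric(gp$chrom_len), chrom_names)

    features <- do.call(rbind, lapply(chrom_names, function(cn)
      place_genes(cn, chrom_lens[[cn]], gp)))
    te <- do.call(rbind, lapply(chrom_names, function(cn)
      place_tes(cn, chrom_lens[[cn]], gp)))
    index <- derive_regions(features, chrom_lens, te)

    classes <- rep(names(spec$class_counts), times = spec$class_counts)
    n_frag <- length(classes)
    occupied <- lapply(chrom_names, function(x) IRanges::IRanges())
    names(occupied) <- chrom_names
    truth <- list()
    mutated_seqs <- list()

    for (f in seq_len(n_frag)) {
      cls <- classes[f]
      rng <- spec$length_ranges[[cls]]
      len_src <- sample(rng[1]:rng[2], 1)
      qstart <- sample.int(gp$plastome_len - len_src, 1) - 1L
      fragment <- substr(plastome_chr, qstart + 1, qstart + len_src)
      target_id <- if (!is.null(spec$identity_targets))
        spec$identity_targets[(f - 1) %% length(spec$identity_targets) + 1]
      else runif(1, spec$identity_range[1], spec$identity_range[2])
      mut <- mutate_core(fragment, target_id, spec$indel_fraction)
      realized <- realign_identity(mut, fragment)
      strand <- sample(names(spec$strand_weights), 1,
                       prob = spec$strand_weights)
      ins_seq <- if (strand == "-") revcomp_chr(mut) else mut
      len_ins <- nchar(ins_seq)

      mode <- sample(names(spec$placement), 1, prob = spec$placement)
      use_te_adj <- runif(1) < spec$te_adjacency_bias

      placed <- FALSE
      fails <- c(overlap = 0, region = 0)
      for (attempt in 1:200) {
        chrom <- sample(chrom_names, 1)
        L <- chrom_lens[[chrom]]
        allowed <- ir0(spec$end_margin, L - spec$end_margin)
        if (mode != "uniform") {
          rset <- switch(mode, exon = index$chroms[[chrom]]$exon,
                         intron = index$chroms[[chrom]]$intron,
                         intergenic = index$chroms[[chrom]]$intergenic)
          allowed <- IRanges::intersect(allowed, rset)
        }
        if (use_te_adj && length(index$chroms[[chrom]]$te_merged) > 0) {
          near_te <- IRanges::reduce(
            ir0(ir0_start(index$chroms[[chrom]]$te_merged) -
                  spec$te_adjacency_dist,
                pmin(L, ir0_end(index$chroms[[chrom]]$te_merged) +
                       spec$te_adjacency_dist)))
          allowed <- IRanges::intersect(allowed, near_te)
        }
        free <- IRanges::setdiff(allowed, occupied[[chrom]])
        free <- free[IRanges::width(free) >= len_ins]
        if (length(free) == 0) { fails["region"] <- fails["region"] + 1; next }
        iv <- free[sample.int(length(free), 1,
                              prob = IRanges::width(free) - len_ins + 1)]
        off <- sample.int(IRanges::width(iv) - len_ins + 1, 1) - 1L
        sstart <- ir0_start(iv) + off
        send <- sstart + len_ins
        substr(chroms[[chrom]], sstart + 1, send) <- ins_seq
        occupied[[chrom]] <- c(occupied[[chrom]],
                               ir0(sstart - spec$min_separation,
                                   send + spec$min_separation))
        bd <- classify_insertion(
          data.frame(sid = chrom, sstart = sstart, send = send), index)
        region <- if (bd$exon_bp == len_ins) "exon" else
          if (bd$intron_bp == len_ins) "intron" else
            if (bd$intergenic_bp == len_ins) "inter" else "mixed"
        te_raw <- index$chroms[[chrom]]$te_raw
        te_dist <- if (length(te_raw) == 0) NA_real_ else {
          span <- ir0(sstart, send)
          min(IRanges::distance(rep(span, length(te_raw)), te_raw))
        }
        truth[[f]] <- data.frame(
          frag_id = sprintf("frag%03d", f), qid = "plastome",
          qstart = qstart, qend = qstart + len_src,
          chrom = chrom, sstart = sstart, send = send, strand = strand,
          target_identity = target_id, realized_identity = realized,
          length = len_ins, size_class = assign_size_class(len_ins),
          region = region, nearest_te_dist = te_dist,
          stringsAsFactors = FALSE)
        mutated_seqs[[f]] <- ins_seq
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place fragment ", f, " (class ", cls, ", mode ",
             mode, ") after 200 attempts; failures: region=", fails["region"],
             " overlap=", fails["overlap"])
    }

    truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
      frag_id = character(0), qid = character(0), qstart = numeric(0),
      qend = numeric(0), chrom = character(0), sstart = numeric(0),
      send = numeric(0), strand = character(0), target_identity = numeric(0),
      realized_identity = numeric(0), length = numeric(0),
      size_class = character(0), region = character(0),
      nearest_te_dist = numeric(0), stringsAsFactors = FALSE)

    plastome <- Biostrings::DNAStringSet(plastome_chr)
    names(plastome) <- "plastome"
    chromosomes <- Biostrings::DNAStringSet(unlist(chroms))
    names(chromosomes) <- chrom_names
    structure(list(plastome = plastome, chromosomes = chromosomes,
                   features = features, te = te, truth = truth,
                   index = index, chrom_lens = chrom_lens, seed = seed,
                   spec = spec, gp = gp), class = "nupt_world")
  })
}

#' Gap-policy constructor for [mask_with_gaps()]
#'
#' `target_implants` puts one central N-run inside every implant of at least
#' `min_implant_len` bases (emulating an assembly that failed to resolve the
#' insertion); `random` places `n_gaps` runs anywhere; `outside_implants`
#' places them only clear of implants.
#'
#' @param mode one of `target_implants`, `random`, `outside_implants`.
#' @param n_gaps number of gap runs for the random modes.
#' @param gap_len gap run length in bases.
#' @param min_implant_len smallest implant targeted by `target_implants`.
#' @param gap_frac when set, targeted gaps cover this fraction of the
#'   implant instead of `gap_len` bases.
#' @return list of class `gap_policy`.
#' @export
gap_policy <- function(mode = c("target_implants", "random",
                                "outside_implants"),
                       n_gaps = 10, gap_len = 200, min_implant_len = 1000,
                       gap_frac = NULL) {
  mode <- match.arg(mode)
  structure(list(mode = mode, n_gaps = n_gaps, gap_len = gap_len,
                 min_implant_len = min_implant_len, gap_frac = gap_frac),
            class = "gap_policy")
}

#' Degrade chromosomes with assembly-gap N runs
#'
#' Bases are replaced (never inserted or deleted), so all coordinates remain
#' valid. Used to emulate older short-read assembly versions in which long
#' insertions are broken by gaps.
#'
#' @param chromosomes `DNAStringSet` or named character vector.
#' @param truth truth table from [build_world()] (implant locations).
#' @param policy a [gap_policy()].
#' @param seed RNG seed.
#' @return degraded `DNAStringSet`.
#' @export
mask_with_gaps <- function(chromosomes, truth, policy = gap_policy(),
                           seed = 1) {
  seqs <- as_seq_chr(chromosomes)
  with_seed(seed, {
    if (policy$mode == "target_implants") {
      sel <- which(truth$length >= policy$min_implant_len)
      for (i in sel) {
        glen <- if (!is.null(policy$gap_frac))
          max(1L, round(truth$length[i] * policy$gap_frac)) else policy$gap_len
        glen <- min(glen, truth$length[i])
        gs <- truth$sstart[i] + floor((truth$length[i] - glen) / 2)
        substr(seqs[[truth$chrom[i]]], gs + 1, gs + glen) <-
          strrep("N", glen)
      }
    } else {
      forbidden <- lapply(split(truth, truth$chrom), function(tt)
        IRanges::reduce(ir0(tt$sstart - 50, tt$send + 50)))
      for (g in seq_len(policy$n_gaps)) {
        chrom <- sample(names(seqs), 1)
        L <- nchar(seqs[[chrom]])
        for (attempt in 1:100) {
          gs <- sample.int(L - policy$gap_len, 1) - 1L
          if (policy$mode == "outside_implants" &&
              !is.null(forbidden[[chrom]]) &&
              sum(IRanges::countOverlaps(ir0(gs, gs + policy$gap_len),
                                         forbidden[[chrom]])) > 0) next
          substr(seqs[[chrom]], gs + 1, gs + policy$gap_len) <-
            strrep("N", policy$gap_len)
          break
        }
      }
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- names(seqs)
    out
  })
}

#' Write a world's files to a directory
#'
#' Emits `plastome.fa`, `nuclear.fa`, `genes.gff3`, `te.gff3`, `truth.tsv`
#' and `world.yaml`; the seed is recorded in every file (FASTA headers carry
#' it as a description, the others as comments / fields).
#'
#' @param world a `nupt_world` from [build_world()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_world <- function(world, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tag <- paste0("seed=", world$seed)
  write_fasta(world$plastome, file.path(outdir, "plastome.fa"), desc = tag)
  write_fasta(world$chromosomes, file.path(outdir, "nuclear.fa"), desc = tag)
  write_gff3(world$features, file.path(outdir, "genes.gff3"), comments = tag)
  write_gff3(world$te, file.path(outdir, "te.gff3"), comments = tag)
  write_tsv(world$truth, file.path(outdir, "truth.tsv"), comments = tag)
  yaml::write_yaml(list(seed = world$seed,
                        spec = unclass(world$spec),
                        genome_params = unclass(world$gp)),
                   file.path(outdir, "world.yaml"))
  invisible(outdir)
}
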