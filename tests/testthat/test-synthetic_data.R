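test_that("simulated plastomes hit their GC target and are reproducible", {
  p1 <- simulate_plastome(150000, gc = 0.37, seed = 1)
  expect_equal(nchar(as.character(p1[[1]])), 150000)
  expect_lt(abs(gc_content(as.character(p1[[1]])) - 0.37), 0.01)
  p2 <- simulate_plastome(150000, gc = 0.37, seed = 1)
  expect_identical(as.character(p1), as.character(p2))
  at_only <- simulate_plastome(5000, gc = 0, seed = 2)
  expect_equal(gc_content(as.character(at_only[[1]])), 0)
})

test_that("mutating to a target identity has exact substitution arithmetic", {
  frag <- random_dna(1000)
  m <- mutate_to_identity(frag, 95, indel_fraction = 0, seed = 3)
  expect_equal(m$realized_identity, 95.0)
  diffs <- sum(strsplit(frag, "")[[1]] != strsplit(m$seq, "")[[1]])
  expect_equal(diffs, 50)

  m100 <- mutate_to_identity(frag, 100, seed = 4)
  expect_identical(m100$seq, frag)
  expect_equal(m100$realized_identity, 100)
})

test_that("indel mutations realize identities near target by realignment", {
  set.seed(44)
  frag <- random_dna(1000)
  for (target in c(98, 92, 85)) {
    m <- mutate_to_identity(frag, target, indel_fraction = 0.2, seed = target)
    expect_lt(abs(m$realized_identity - target), 1.5)
  }
})

test_that("worlds honor class counts, keep implants apart and clear of ends", {
  spec <- implant_spec(class_counts = c(lt100 = 2, s100_500 = 3,
                                        s500_1000 = 3, ge1000 = 2), seed = 19)
  w <- build_world(spec, small_gp())
  expect_equal(nrow(w$truth), 10)
  counts <- table(w$truth$size_class)
  expect_equal(unname(counts[c("lt100", "s100_500", "s500_1000", "ge1000")]),
               c(2L, 3L, 3L, 2L), ignore_attr = TRUE)
  # implant sequence really is in the chromosome
  for (i in seq_len(nrow(w$truth))) {
    tr <- w$truth[i, ]
    span <- substr(as.character(w$chromosomes[[tr$chrom]]),
                   tr$sstart + 1, tr$send)
    src <- substr(as.character(w$plastome[[1]]), tr$qstart + 1, tr$qend)
    if (tr$strand == "-")
      span <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(span)))
    expect_gte(100 * sum(strsplit(span, "")[[1]] == strsplit(src, "")[[1]]) /
                 nchar(src), tr$target_identity - 1)
  }
  # non-overlap and end margins
  by_chrom <- split(w$truth, w$truth$chrom)
  for (tt in by_chrom) {
    ir <- IRanges::IRanges(tt$sstart + 1, tt$send)
    expect_equal(length(IRanges::reduce(ir)), nrow(tt))
    expect_true(all(tt$sstart >= spec$end_margin))
    expect_true(all(tt$send <= w$chrom_lens[[tt$chrom[1]]] - spec$end_margin))
  }
  # realized identity within a point of target for fragments >= 200 bp
  big <- w$truth[w$truth$length >= 200, ]
  expect_true(all(abs(big$realized_identity - big$target_identity) <= 1.0))
  # determinism
  w2 <- build_world(spec, small_gp())
  expect_identical(as.character(w$chromosomes), as.character(w2$chromosomes))
  expect_equal(w$truth, w2$truth)
})

test_that("a zero-implant world stays a null world", {
  w <- build_world(implant_spec(class_counts = c(s100_500 = 0), seed = 7),
                   genome_params(n_chrom = 1, chrom_len = 20000,
                                 gene_count = 3, te_count = 5,
                                 plastome_len = 10000))
  expect_equal(nrow(w$truth), 0)
  hits <- nupt_search(w$plastome, w$chromosomes)
  expect_equal(nrow(hits), 0)
})

test_that("explicit identity targets are honored and recycled", {
  w <- build_world(implant_spec(class_counts = c(s500_1000 = 4),
                                identity_targets = c(85, 99), seed = 20),
                   small_gp())
  expect_equal(w$truth$target_identity, c(85, 99, 85, 99))
  expect_equal(assign_id_bin(w$truth$realized_identity),
               c("mid80_95", "hi95", "mid80_95", "hi95"))
})

test_that("gap masking preserves coordinates and honors its mode", {
  w <- build_world(implant_spec(class_counts = c(ge1000 = 3), seed = 21),
                   small_gp())
  # zero-gap policy: identity
  same <- mask_with_gaps(w$chromosomes, w$truth,
                         gap_policy("random", n_gaps = 0), seed = 1)
  expect_identical(as.character(same), as.character(w$chromosomes))
  # targeted gaps land inside every long implant
  deg <- mask_with_gaps(w$chromosomes, w$truth,
                        gap_policy("target_implants", gap_len = 200), seed = 1)
  expect_equal(nchar(as.character(deg)), nchar(as.character(w$chromosomes)),
               ignore_attr = TRUE)
  for (i in which(w$truth$length >= 1000)) {
    tr <- w$truth[i, ]
    span <- substr(as.character(deg[[tr$chrom]]), tr$sstart + 1, tr$send)
    expect_true(grepl("N", span))
  }
  # gaps placed outside implants leave every implant untouched
  out <- mask_with_gaps(w$chromosomes, w$truth,
                        gap_policy("outside_implants", n_gaps = 5,
                                   gap_len = 300), seed = 2)
  expect_true(grepl("N", paste(as.character(out), collapse = "")))
  for (i in seq_len(nrow(w$truth))) {
    tr <- w$truth[i, ]
    span <- substr(as.character(out[[tr$chrom]]), tr$sstart + 1, tr$send)
    expect_false(grepl("N", span))
  }
})

test_that("worlds round-trip through their emitted files", {
  w <- build_world(implant_spec(class_counts = c(s100_500 = 2), seed = 22),
                   small_gp())
  d <- withr::local_tempdir()
  write_world(w, d)
  expect_true(all(file.exists(file.path(
    d, c("plastome.fa", "nuclear.fa", "genes.gff3", "te.gff3",
         "truth.tsv", "world.yaml")))))
  nuc <- read_fasta(file.path(d, "nuclear.fa"))
  expect_identical(as.character(nuc), as.character(w$chromosomes))
  genes <- read_gff3(file.path(d, "genes.gff3"))
  expect_equal(genes[, c("chrom", "start", "end", "ftype")],
               w$features[, c("chrom", "start", "end", "ftype")],
               ignore_attr = TRUE)
  truth <- read.delim(file.path(d, "truth.tsv"), comment.char = "#")
  expect_equal(nrow(truth), 2)
  meta <- yaml::read_yaml(file.path(d, "world.yaml"))
  expect_equal(meta$seed, 22)
})
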