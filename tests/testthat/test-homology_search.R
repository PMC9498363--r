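test_that("seed index enumerates k-mer positions and excludes N", {
  ix <- build_seed_index(c(c1 = "ACGTACGT"), word_size = 4)
  expect_equal(lookup_seed(ix, "ACGT")$pos, c(0, 4))
  expect_equal(lookup_seed(ix, "CGTA")$pos, 1)
  expect_equal(lookup_seed(ix, "GTAC")$pos, 2)
  expect_equal(lookup_seed(ix, "TACG")$pos, 3)

  ixn <- build_seed_index(c(c1 = "ANGT"), word_size = 4)
  expect_equal(nrow(lookup_seed(ixn, "ANGT")), 0)
  expect_length(ls(ixn$index), 0)

  ix2 <- build_seed_index(c(a = "ACGTAA", b = "TTACGT"), word_size = 4)
  hit <- lookup_seed(ix2, "ACGT")
  expect_equal(hit$sid, c("a", "b"))
  expect_equal(hit$pos, c(0, 2))

  expect_error(build_seed_index(c(a = "ACG"), word_size = 4), "word_size")
})

test_that("seed extension recovers embedded copies with correct identity", {
  set.seed(11)
  core <- random_dna(100)
  # query is exactly the embedded copy, so the alignment cannot extend past
  # it and the identity arithmetic is exact
  s <- paste0(random_dna(80), core, random_dna(80))
  hit <- extend_seed(core, s, qpos = 20, spos = 100, search_params())
  expect_equal(hit$identity, 100)
  expect_equal(hit$aln_len, 100)
  expect_equal(hit$matches, 100)
  expect_equal(hit$sstart, 80)
  expect_equal(hit$send, 180)

  # five substitutions -> 95%
  core2 <- core
  for (p in c(5, 40, 60, 80, 95))  # clear of the seed at core offsets 21-31
    substr(core2, p, p) <- setdiff(c("A", "C", "G", "T"),
                                   substr(core2, p, p))[1]
  s2 <- paste0(random_dna(80), core2, random_dna(80))
  hit2 <- extend_seed(core, s2, qpos = 20, spos = 100, search_params())
  expect_equal(hit2$identity, 95)
  expect_equal(hit2$aln_len, 100)
  expect_error(extend_seed(core, s2, qpos = 0, spos = 0), "seed mismatch")
})

test_that("ungapped alignment scores equal the rescored match/mismatch sum", {
  set.seed(12)
  params <- search_params()
  for (r in 1:20) {
    core <- random_dna(80)
    nmut <- sample(0:6, 1)
    core2 <- core
    if (nmut > 0) {
      for (p in sample(15:65, nmut))
        substr(core2, p, p) <- setdiff(c("A", "C", "G", "T"),
                                       substr(core2, p, p))[1]
    }
    q <- paste0(random_dna(30), core, random_dna(30))
    s <- paste0(random_dna(30), core2, random_dna(30))
    hit <- extend_seed(q, s, qpos = 30, spos = 30, params)
    if (hit$gaps == 0) {
      mism <- hit$aln_len - hit$matches
      expect_equal(hit$score,
                   params$match * hit$matches + params$mismatch * mism)
    }
  }
})

test_that("Karlin-Altschul E-values follow the closed form", {
  p <- search_params(lambda = 0.625, K = 0.41)
  # direct evaluation of E = K m n exp(-lambda S)
  expect_equal(karlin_evalue(60, 1000, 1e6, p),
               0.41 * 1000 * 1e6 * exp(-0.625 * 60))
  # monotone decreasing in S, toward zero
  s <- seq(0, 150, by = 10)
  ev <- karlin_evalue(s, 1000, 1e6, p)
  expect_true(all(diff(ev) < 0))
  expect_lt(ev[length(ev)], 1e-25)
  expect_equal(karlin_evalue(1e6, 1000, 1e6, p), 0)  # limit S -> Inf
  # doubling n doubles E
  expect_equal(karlin_evalue(60, 1000, 2e6, p),
               2 * karlin_evalue(60, 1000, 1e6, p))
})

test_that("search finds a verbatim implant as one full-span perfect hit", {
  set.seed(13)
  pt <- c(pt = random_dna(10000, gc = 0.37))
  chrom <- random_dna(100000, gc = 0.36)
  frag <- substr(pt[[1]], 2001, 2300)
  substr(chrom, 50001, 50300) <- frag
  hits <- nupt_search(pt, c(c1 = chrom))
  expect_equal(nrow(hits), 1)
  # the hit covers the implant span; local extension may absorb a few
  # chance-matching flank bases (as any local aligner does), never > x_drop/2
  expect_lte(hits$sstart, 50000)
  expect_gte(hits$send, 50300)
  expect_lte(50000 - hits$sstart, 10)
  expect_lte(hits$send - 50300, 10)
  expect_gte(hits$identity, 99)
  expect_gte(hits$matches, 300)
  expect_equal(hits$strand, "+")

  # same implant reverse-complemented: same span, minus strand
  chrom2 <- random_dna(100000, gc = 0.36)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
  substr(chrom2, 50001, 50300) <- rc
  hits2 <- nupt_search(pt, c(c1 = chrom2))
  expect_equal(nrow(hits2), 1)
  expect_lte(hits2$sstart, 50000)
  expect_gte(hits2$send, 50300)
  expect_gte(hits2$identity, 99)
  expect_equal(hits2$strand, "-")
})

test_that("search is deterministic and strand-symmetric", {
  w <- cached_default_world()
  h1 <- cached_default_hits()
  h2 <- nupt_search(w$plastome, w$chromosomes)
  expect_identical(h1, h2)

  rc <- as.character(Biostrings::reverseComplement(w$plastome[[1]]))
  h3 <- nupt_search(c(plastome = rc), w$chromosomes)
  k1 <- h1[order(h1$sid, h1$sstart), c("sid", "sstart", "send")]
  k3 <- h3[order(h3$sid, h3$sstart), c("sid", "sstart", "send")]
  expect_equal(k1, k3, ignore_attr = TRUE)
  m <- match(paste(h3$sid, h3$sstart), paste(h1$sid, h1$sstart))
  expect_true(all(h3$strand != h1$strand[m]))
})

test_that("external tabular rows convert coordinates, strand, and cutoff", {
  rows <- data.frame(qid = "pt", sid = "c1", pident = c(98, 97, 96),
                     length = 100, mismatch = 2, gapopen = 0,
                     qstart = 1, qend = 100,
                     sstart = c(300, 201, 500), send = c(201, 300, 599),
                     evalue = c(1e-40, 1e-5, 1e-7), bitscore = 180)
  hits <- hits_from_table(rows, search_params(evalue_cutoff = 1e-6))
  # the 1e-5 row is dropped by the cutoff; 1e-7 retained
  expect_equal(nrow(hits), 2)
  minus <- hits[hits$strand == "-", ]
  expect_equal(minus$sstart, 200)
  expect_equal(minus$send, 300)
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$sstart, 499)
  expect_equal(plus$send, 599)
  expect_equal(plus$qstart, 0)
  expect_equal(plus$qend, 100)
})

test_that("best-hit scores match the quadratic DP oracle on planted seeds", {
  set.seed(14)
  params <- search_params(word_size = 11, x_drop = 100, evalue_cutoff = 1e30)
  checked <- 0
  for (r in 1:40) {
    q <- random_dna(sample(80:200, 1))
    s <- random_dna(sample(200:400, 1))
    core_len <- sample(30:60, 1)
    cq <- sample(seq_len(nchar(q) - core_len), 1)
    cs <- sample(seq_len(nchar(s) - core_len), 1)
    substr(s, cs, cs + core_len - 1) <- substr(q, cq, cq + core_len - 1)
    pa <- oracle_local(q, s, params)
    if (!oracle_has_seed(pa, params$word_size)) next
    hits <- nupt_search(c(q = q), c(s = s), params)
    best <- if (nrow(hits)) max(hits$score) else 0
    expect_equal(best, Biostrings::score(pa))
    checked <- checked + 1
  }
  expect_gte(checked, 30)
})
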