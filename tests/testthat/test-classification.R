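test_that("identity bins split at 80 and 95 with inclusive lower edges", {
  expect_equal(assign_id_bin(95.0), "hi95")
  expect_equal(assign_id_bin(100.0), "hi95")
  expect_equal(assign_id_bin(80.0), "mid80_95")
  expect_equal(assign_id_bin(94.999), "mid80_95")
  expect_true(is.na(assign_id_bin(79.99)))
  expect_equal(assign_id_bin(c(85, 97, 50)), c("mid80_95", "hi95", NA))
})

test_that("size classes are left-closed with 1000 bp in the top class", {
  expect_equal(assign_size_class(c(1, 99, 100, 499, 500, 999, 1000, 5000)),
               c("lt100", "lt100", "s100_500", "s100_500", "s500_1000",
                 "s500_1000", "ge1000", "ge1000"))
})

mk_hits <- function(sid, sstart, send, identity, strand = "+") {
  n <- length(sstart)
  data.frame(qid = "pt", sid = rep_len(sid, n), qstart = 0, qend = send - sstart,
             sstart = sstart, send = send, strand = rep_len(strand, n),
             aln_len = send - sstart, matches = send - sstart, gaps = 0,
             identity = identity, score = 2 * (send - sstart),
             evalue = 1e-20, stringsAsFactors = FALSE)
}

test_that("overlapping hits union within a bin; bins never merge", {
  h <- mk_hits("c1", c(100, 150), c(200, 250), c(96, 98))
  m <- merge_hits(h, "merge_overlaps")
  expect_equal(nrow(m), 1)
  expect_equal(m$sstart, 100)
  expect_equal(m$send, 250)
  expect_equal(m$members, "1,2")
  # length-weighted mean identity
  expect_equal(m$identity, (96 * 100 + 98 * 100) / 200)

  p <- merge_hits(h, "per_hit")
  expect_equal(nrow(p), 2)

  # different bins stay apart even when spans overlap
  h2 <- mk_hits("c1", c(100, 150), c(200, 250), c(85, 98))
  m2 <- merge_hits(h2, "merge_overlaps")
  expect_equal(nrow(m2), 2)
  expect_setequal(m2$id_bin, c("mid80_95", "hi95"))

  # identity below 80 is excluded entirely
  h3 <- mk_hits("c1", 100, 200, 70)
  expect_equal(nrow(merge_hits(h3)), 0)
})

test_that("merging overlaps is idempotent and never increases total length", {
  set.seed(21)
  for (r in 1:20) {
    n <- sample(5:25, 1)
    st <- sample(0:5000, n)
    h <- mk_hits("c1", st, st + sample(50:800, n, replace = TRUE),
                 runif(n, 80, 100))
    h <- h[order(h$sstart), ]
    m1 <- merge_hits(h, "merge_overlaps")
    # re-merging the merged insertions (as pseudo-hits) changes nothing
    h2 <- mk_hits("c1", m1$sstart, m1$send, m1$identity)
    m2 <- merge_hits(h2, "merge_overlaps")
    expect_equal(m2[, c("sstart", "send")], m1[, c("sstart", "send")],
                 ignore_attr = TRUE)
    expect_lte(sum(m1$length), sum(h$send - h$sstart))
    # partition property: every insertion in exactly one cell, totals add up
    expect_false(any(is.na(m1$id_bin)) || any(is.na(m1$size_class)))
    s <- summarize_by_chromosome(m1, c(c1 = 10000))
    expect_equal(sum(s$count), nrow(m1))
    expect_equal(sum(s$total_len), sum(m1$length))
  }
})

test_that("per-chromosome summary computes counts and relative lengths", {
  h <- mk_hits("c1", 1000, 2000, 97)
  m <- merge_hits(h)
  s <- summarize_by_chromosome(m, c(c1 = 1e6))
  cell <- s[s$id_bin == "hi95" & s$size_class == "ge1000", ]
  expect_equal(cell$count, 1L)
  expect_equal(cell$total_len, 1000)
  expect_equal(cell$rel_len_pct, 0.1)
  expect_equal(sum(s$count), 1L)

  # zero insertions: full grid of zero cells
  s0 <- summarize_by_chromosome(m[0, ], c(c1 = 1e6, c2 = 2e6))
  expect_equal(nrow(s0), 16)
  expect_true(all(s0$count == 0 & s0$total_len == 0 & s0$rel_len_pct == 0))

  # rel_len scales as 1/chrom_len
  s2 <- summarize_by_chromosome(m, c(c1 = 2e6))
  expect_equal(s2$rel_len_pct[s2$size_class == "ge1000" & s2$id_bin == "hi95"],
               cell$rel_len_pct / 2)

  expect_error(summarize_by_chromosome(m, c(cX = 1e6)), "absent")
})

test_that("summary cell counts on a synthetic world equal the truth table", {
  w <- cached_default_world()
  ins <- merge_hits(cached_default_hits())
  s <- summarize_by_chromosome(ins, w$chrom_lens)
  truth_counts <- table(w$truth$chrom, w$truth$size_class)
  for (chrom in rownames(truth_counts)) {
    for (cls in colnames(truth_counts)) {
      got <- sum(s$count[s$sid == chrom & s$size_class == cls])
      expect_equal(got, unname(truth_counts[chrom, cls]))
    }
  }
})

test_that("display filter keeps length >= 100 and identity >= 80", {
  x <- data.frame(sstart = c(0, 0, 0), send = c(99, 100, 5000),
                  identity = c(99, 80, 79))
  f <- display_filter(x)
  expect_equal(nrow(f), 1)
  expect_equal(f$send, 100)
})
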