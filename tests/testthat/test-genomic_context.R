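mk_features <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r[[1]], start = as.numeric(r[[2]]),
               end = as.numeric(r[[3]]), strand = "+", ftype = r[[4]],
               id = r[[5]], attrs = NA_character_, stringsAsFactors = FALSE)))
}

test_that("introns and intergenic space are exact complements", {
  f <- mk_features(list("c1", 100, 1000, "gene", "g1"),
                   list("c1", 100, 300, "exon", "e1"),
                   list("c1", 700, 1000, "exon", "e2"))
  ix <- derive_regions(f, c(c1 = 5000))
  cx <- ix$chroms$c1
  expect_equal(as.data.frame(cx$intron)[, c("start", "end")],
               data.frame(start = 301, end = 700))  # [300,700) internally
  ig <- as.data.frame(cx$intergenic)
  expect_equal(ig$start, c(1, 1001))
  expect_equal(ig$end, c(100, 5000))
})

test_that("intronless genes and isoform conflicts resolve exon-first", {
  f <- mk_features(list("c1", 100, 400, "gene", "g1"),
                   list("c1", 100, 400, "exon", "e1"),
                   list("c1", 1000, 2000, "gene", "g2"),
                   list("c1", 1000, 1200, "exon", "g2e1"),
                   list("c1", 1800, 2000, "exon", "g2e2"),
                   # isoform exon overlapping g2's intron
                   list("c1", 1100, 1500, "exon", "g2b.e1"))
  ix <- derive_regions(f, c(c1 = 3000))
  cx <- ix$chroms$c1
  # g1 contributes no intron bases
  expect_equal(sum(IRanges::width(cx$intron)), 300)  # only 1500-1800 of g2
  # bases 1200-1500 are exon (isoform priority), not intron
  ov <- IRanges::intersect(cx$exon, IRanges::IRanges(1201, 1500))
  expect_equal(sum(IRanges::width(ov)), 300)
})

test_that("an exon outside every gene span is an error naming the exon", {
  f <- mk_features(list("c1", 100, 400, "gene", "g1"),
                   list("c1", 500, 600, "exon", "stray"))
  expect_error(derive_regions(f, c(c1 = 1000)), "stray")
})

test_that("insertion breakdowns split bases exactly across regions", {
  f <- mk_features(list("c1", 100, 1000, "gene", "g1"),
                   list("c1", 100, 300, "exon", "e1"),
                   list("c1", 700, 1000, "exon", "e2"))
  ix <- derive_regions(f, c(c1 = 5000))
  bd <- classify_insertion(data.frame(sid = "c1", sstart = 150, send = 250), ix)
  expect_equal(bd$exon_bp, 100)
  expect_equal(bd$intron_bp + bd$intergenic_bp, 0)
  expect_equal(bd$region_flags, "exon")

  bd2 <- classify_insertion(data.frame(sid = "c1", sstart = 250, send = 350), ix)
  expect_equal(bd2$exon_bp, 50)
  expect_equal(bd2$intron_bp, 50)
  expect_equal(bd2$region_flags, "exon,intron")
})

test_that("interval classification equals per-base brute force", {
  set.seed(31)
  for (r in 1:30) {
    L <- 3000
    n_genes <- sample(1:3, 1)
    rows <- list()
    pos <- 0
    for (g in seq_len(n_genes)) {
      gs <- pos + sample(50:200, 1)
      glen <- sample(300:800, 1)
      if (gs + glen > L - 100) break
      gid <- paste0("g", g)
      rows[[length(rows) + 1]] <- list("c1", gs, gs + glen, "gene", gid)
      cuts <- sort(sample(seq_len(glen - 1), 2))
      rows[[length(rows) + 1]] <- list("c1", gs, gs + cuts[1], "exon",
                                       paste0(gid, "e1"))
      rows[[length(rows) + 1]] <- list("c1", gs + cuts[2], gs + glen, "exon",
                                       paste0(gid, "e2"))
      pos <- gs + glen
    }
    if (length(rows) == 0) next
    f <- do.call(mk_features, rows)
    ix <- derive_regions(f, c(c1 = L))
    # region partition is exact (also asserted inside derive_regions)
    cx <- ix$chroms$c1
    expect_equal(sum(IRanges::width(cx$exon)) + sum(IRanges::width(cx$intron)) +
                   sum(IRanges::width(cx$intergenic)), L)
    for (t in 1:5) {
      ss <- sample(0:(L - 400), 1)
      se <- ss + sample(50:400, 1)
      bd <- classify_insertion(data.frame(sid = "c1", sstart = ss, send = se), ix)
      brute <- brute_region_bp(f, "c1", L, ss, se)
      expect_equal(c(bd$exon_bp, bd$intron_bp, bd$intergenic_bp),
                   unname(brute))
      expect_equal(bd$exon_bp + bd$intron_bp + bd$intergenic_bp, se - ss)
    }
  }
})

test_that("TE overlap counts raw features but merges bases", {
  te_raw <- IRanges::IRanges(51, 80)  # [50,80)
  te_raw <- c(te_raw, IRanges::IRanges(71, 90))  # [70,90)
  ov <- te_overlap(data.frame(sstart = 0, send = 100), te_raw)
  expect_equal(ov[["count"]], 2)
  expect_equal(ov[["bases"]], 40)

  ov0 <- te_overlap(data.frame(sstart = 0, send = 100), IRanges::IRanges())
  expect_equal(unname(ov0), c(0, 0))
})

test_that("region summaries attribute counts and bases per size class", {
  f <- mk_features(list("c1", 2000, 3000, "gene", "g1"),
                   list("c1", 2000, 2400, "exon", "e1"),
                   list("c1", 2600, 3000, "exon", "e2"))
  te <- data.frame(chrom = "c1", start = 500, end = 900, strand = ".",
                   ftype = "TE", id = "t1", attrs = NA)
  ix <- derive_regions(f, c(c1 = 10000), te)
  ins <- data.frame(sid = "c1", sstart = c(400, 2300), send = c(1600, 2700),
                    strand = "+", identity = c(97, 98),
                    length = c(1200, 400),
                    size_class = c("ge1000", "s100_500"),
                    id_bin = "hi95", members = "1", stringsAsFactors = FALSE)
  rs <- region_summary(ins, ix)
  inter_ge <- rs[rs$region == "inter" & rs$size_class == "ge1000", ]
  expect_equal(inter_ge$count, 1L)
  expect_equal(inter_ge$bases, 1200)
  expect_equal(inter_ge$te_count, 1)
  expect_equal(inter_ge$te_bases, 400)
  # boundary-spanning insertion counts once per touched region, bases split
  exon_s <- rs[rs$region == "exon" & rs$size_class == "s100_500", ]
  intron_s <- rs[rs$region == "intron" & rs$size_class == "s100_500", ]
  expect_equal(exon_s$count, 1L)
  expect_equal(intron_s$count, 1L)
  expect_equal(exon_s$bases + intron_s$bases, 400)
  # majority mode counts it only in its majority region
  rs2 <- region_summary(ins, ix, count_mode = "majority")
  expect_equal(sum(rs2$count[rs2$size_class == "s100_500"]), 1L)
  # conservation: attributed bases equal summed insertion lengths
  expect_equal(sum(rs$bases), sum(ins$length))
})

test_that("implants placed only in intergenic space are flagged intergenic", {
  w <- build_world(implant_spec(class_counts = c(s100_500 = 4),
                                placement = c(intergenic = 1), seed = 9),
                   small_gp())
  expect_true(all(w$truth$region == "inter"))
  bd <- classify_insertion(
    data.frame(sid = w$truth$chrom, sstart = w$truth$sstart,
               send = w$truth$send), w$index)
  expect_true(all(bd$intergenic_bp == w$truth$length))
})
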