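test_that("substitutions are normalized to the pyrimidine representation", {
  gc <- genomeContext(c(c1 = "AAGCA"))
  ## G>T with reference 5'-A G C-3' reverse complements to G[C>A]T
  expect_equal(classifySBS(gc, "c1", 3, "G", "T"), "G[C>A]T")
  gc2 <- genomeContext(c(c1 = "AACAA"))
  expect_equal(classifySBS(gc2, "c1", 3, "C", "T"), "A[C>T]A")
})

test_that("stranded classification prefixes transcribed, untranscribed, intergenic", {
  seqStr <- paste(rep("ACGT", 750), collapse = "")
  genes <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(101, 1001), c(500, 1400)), strand = c("+", "-"))
  names(genes) <- c("gp", "gm")
  gc <- genomeContext(c(c1 = seqStr), genes)
  ## intergenic
  p <- 2002
  ref <- genomeBase(gc, "c1", p)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  expect_match(classifySBS(gc, "c1", p, ref, alt, stranded = TRUE), "^N:")
  ## pyrimidine on plus strand inside a plus-strand gene: untranscribed
  pc <- 202  # position with C on plus strand (seq repeats ACGT; pos %% 4 == 2)
  expect_equal(genomeBase(gc, "c1", pc), "C")
  expect_match(classifySBS(gc, "c1", pc, "C", "T", stranded = TRUE), "^U:")
  ## purine on plus strand inside a plus-strand gene: pyrimidine on template
  pg <- 203
  expect_equal(genomeBase(gc, "c1", pg), "G")
  expect_match(classifySBS(gc, "c1", pg, "G", "A", stranded = TRUE), "^T:")
  ## same bases inside a minus-strand gene flip the prefix
  expect_match(classifySBS(gc, "c1", 1202, "C", "T", stranded = TRUE), "^T:")
  expect_match(classifySBS(gc, "c1", 1203, "G", "A", stranded = TRUE), "^U:")
})

test_that("both-strand gene overlap resolves by longest interval deterministically", {
  set.seed(41)
  gc <- strandedGenome()
  ## 1951..2100 overlapped by gPlusLong (width 500) and gMinusShort (width 150)
  expect_equal(transcribedStrand(gc, "chr1", 2000), "plus")
  ## equal widths fall back to lexicographic gene id
  genes <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(10, 10), c(90, 90)), strand = c("-", "+"))
  names(genes) <- c("bGene", "aGene")
  gcTie <- genomeContext(c(c1 = paste(rep("ACGT", 30), collapse = "")), genes)
  expect_equal(transcribedStrand(gcTie, "c1", 50), "plus")  # aGene wins
})

test_that("classification errors are raised for mismatches and ambiguity", {
  gc <- genomeContext(c(c1 = "AANCA"))
  expect_error(classifySBS(gc, "c1", 4, "G", "T"), "mismatch")
  expect_error(classifySBS(gc, "c1", 4, "C", "T"), "mbiguous")
  expect_error(classifySBS(gc, "c1", 2, "A", "A"), "substitution")
  gc2 <- genomeContext(c(c1 = "AAGTTTTCA"))
  ## deletion of the second T in a T-run is not left-aligned
  expect_error(classifyIndel(gc2, "c1", 4, "TT", "T"), "left-aligned")
})

test_that("doublet classification canonicalizes by reverse complement", {
  gc <- genomeContext(c(c1 = "ACCTA"))
  expect_equal(classifyDBS(gc, "c1", 2, "CC", "TT"), "CC>TT")
  gc2 <- genomeContext(c(c1 = "AGGTA"))
  expect_equal(classifyDBS(gc2, "c1", 2, "GG", "AA"), "CC>TT")
  expect_error(classifyDBS(gc, "c1", 2, "CC", "TC"), "both bases")
})

test_that("indel classification follows the 83-category rules", {
  ## deletion of one T from a run of exactly 4 Ts
  gc <- genomeContext(c(c1 = "AGTTTTCA"))
  expect_equal(classifyIndel(gc, "c1", 2, "GT", "G"), "1:Del:T:3")
  ## insertion of one C next to zero existing Cs
  gc2 <- genomeContext(c(c1 = "AGATAG"))
  expect_equal(classifyIndel(gc2, "c1", 2, "G", "GC"), "1:Ins:C:0")
  ## 5-bp deletion whose 3-bp suffix recurs immediately downstream, without a
  ## full tandem copy: junction-homology category, length 5+, homology 3
  gc3 <- genomeContext(c(c1 = "ATCAGTGGTGATCC"))
  expect_equal(classifyIndel(gc3, "c1", 2, "TCAGTG", "T"), "5:Del:M:3")
  ## tandem duplication deletion: 2-bp unit with one extra copy downstream
  gc4 <- genomeContext(c(c1 = "TTACACGTT"))
  expect_equal(classifyIndel(gc4, "c1", 2, "TAC", "T"), "2:Del:R:1")
})

test_that("copy-number and SV classification respect the configured bins", {
  expect_equal(classifyCN(2, 1, 5e6), "2:het:1Mb-10Mb")
  hd50k <- classifyCN(0, 0, 5e4)
  hd150k <- classifyCN(0, 0, 1.5e5)
  expect_match(hd50k, "^0:homdel:10kb-100kb$")
  expect_false(hd50k == hd150k)  # sub-100kb resolution is kept for homdels
  expect_equal(classifyCN(3, 0, 5e3), "3-4:LOH:0-10kb")
  expect_error(classifyCN(2, 1, 0), "positive")
  expect_error(classifyCN(1, 2, 100), "total_cn")
  expect_equal(classifySV("DEL", 500, FALSE), "non-clustered:del:<1kb")
  expect_equal(classifySV("del", 1500, TRUE), "clustered:del:1kb-10kb")
  expect_equal(classifySV("TRA", clustered = TRUE), "clustered:tra")
  expect_error(classifySV("INV", NA, FALSE), "size")
})

test_that("default CN and SV schemas enumerate to 68 and 38 categories", {
  cn <- schemaCN()
  expect_length(categories(cn), 68)
  expect_false(anyDuplicated(categories(cn)) > 0)
  ## every generated label is reachable: 5 homdel + 5x7 LOH + 4x7 het
  expect_length(grep(":homdel:", categories(cn)), 5)
  expect_length(grep(":LOH:", categories(cn)), 35)
  expect_length(grep(":het:", categories(cn)), 28)
  sv <- schemaSV()
  expect_length(categories(sv), 38)
  expect_length(grep("^clustered:", categories(sv)), 19)
})

test_that("catalogs conserve event counts and honor sample order", {
  gc <- genomeContext(c(c1 = "AACAAACAAACAA"))
  recs <- data.frame(sample = "T1", chrom = "c1", pos = c(3, 7, 11),
                     ref = "C", alt = "T", stringsAsFactors = FALSE)
  cat1 <- buildCatalog(recs, schemaSBS96(), gc)
  expect_equal(sum(catalogCounts(cat1)), 3)
  expect_equal(unname(catalogCounts(cat1)["A[C>T]A", "T1"]), 3)

  set.seed(7)
  gcr <- randomGenome(6000)
  recs2 <- randomSbsRecords(gcr, 200, samples = paste0("P", 1:5))
  cat2 <- buildCatalog(recs2, schemaSBS96(), gcr)
  tallies <- table(recs2$sample)
  expect_equal(colSums(catalogCounts(cat2))[names(tallies)],
               unclass(c(tallies))[names(tallies)],
               ignore_attr = TRUE)
  ## column order follows first appearance
  expect_equal(sampleIds(cat2), unique(recs2$sample))
  ## empty input: zero-sample catalog, not an error
  expect_equal(ncol(catalogCounts(buildCatalog(recs2[0, ], schemaSBS96(), gcr))), 0)
})

test_that("strand collapse reproduces the unstranded catalog", {
  set.seed(13)
  gc <- strandedGenome(6000)
  recs <- randomSbsRecords(gc, 300, samples = c("A", "B", "C"))
  c288 <- buildCatalog(recs, schemaSBS288(), gc)
  c96 <- buildCatalog(recs, schemaSBS96(), gc)
  collapsed <- collapseStrand(c288)
  expect_equal(catalogCounts(collapsed), catalogCounts(c96))
  expect_equal(colSums(catalogCounts(collapsed)), colSums(catalogCounts(c288)))
  expect_error(collapseStrand(c96), "SBS288")
})

test_that("classification is strand symmetric and deterministic", {
  set.seed(19)
  gc <- randomGenome(4000)
  seqStr <- as.character(gc@sequences[["chr1"]])
  n <- nchar(seqStr)
  rcStr <- chartr("ACGT", "TGCA",
                  paste(rev(strsplit(seqStr, "")[[1]]), collapse = ""))
  gcRC <- genomeContext(c(chr1 = rcStr))
  recs <- randomSbsRecords(gc, 100)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nrow(recs))) {
    lab <- classifySBS(gc, "chr1", recs$pos[i], recs$ref[i], recs$alt[i])
    labRC <- classifySBS(gcRC, "chr1", n - recs$pos[i] + 1,
                         comp[[recs$ref[i]]], comp[[recs$alt[i]]])
    expect_equal(labRC, lab)
  }
  ## re-running yields identical catalogs
  c1 <- buildCatalog(recs, schemaSBS96(), gc)
  c2 <- buildCatalog(recs, schemaSBS96(), gc)
  expect_identical(catalogCounts(c1), catalogCounts(c2))
})

test_that("mixed variant classes inconsistent with the schema are logged", {
  gc <- genomeContext(c(c1 = "AACAAACAAACAA"))
  recs <- data.frame(sample = "T1", chrom = "c1", pos = c(3, 5),
                     ref = c("C", "A"), alt = c("T", "AGG"),
                     stringsAsFactors = FALSE)
  expect_message(cat1 <- buildCatalog(recs, schemaSBS96(), gc),
                 "could not be classified")
  expect_equal(sum(catalogCounts(cat1)), 1)
  expect_equal(unname(cat1@unclassified["T1"]), 1)
})

test_that("genome aberration fraction matches a per-base oracle", {
  segs <- data.frame(chrom = "c1", start = c(1, 51), end = c(50, 100),
                     total_cn = c(2, 3), minor_cn = c(1, 1))
  expect_equal(genomeAberrationFraction(segs), 0.5)
  segsDiploid <- transform(segs, total_cn = 2, minor_cn = 1)
  expect_equal(genomeAberrationFraction(segsDiploid), 0)
  expect_error(genomeAberrationFraction(
    data.frame(chrom = "c1", start = c(1, 40), end = c(50, 90),
               total_cn = 2, minor_cn = 1)), "overlap")

  set.seed(3)
  for (rep in 1:5) {
    cuts <- sort(sample(2:9999, 20))
    starts <- c(1, cuts)
    ends <- c(cuts - 1, 10000)
    keep <- sort(sample(length(starts), 12))
    segs <- data.frame(chrom = "c1", start = starts[keep], end = ends[keep],
                       total_cn = sample(0:4, 12, replace = TRUE),
                       minor_cn = 0)
    segs$minor_cn <- pmin(segs$total_cn %/% 2,
                          sample(0:1, 12, replace = TRUE))
    ## per-base tally on the 10 kb toy genome
    state <- rep(NA, 10000)
    aberr <- rep(FALSE, 10000)
    for (i in seq_len(nrow(segs))) {
      idx <- segs$start[i]:segs$end[i]
      state[idx] <- TRUE
      aberr[idx] <- !(segs$total_cn[i] == 2 & segs$minor_cn[i] == 1)
    }
    expected <- sum(aberr[!is.na(state)]) / sum(!is.na(state))
    expect_equal(genomeAberrationFraction(segs), expected)
  }
})
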