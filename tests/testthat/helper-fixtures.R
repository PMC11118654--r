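## Programmatic fixtures shared across test files. All randomness is driven
## by the caller's seed.

randomGenomeString <- function(len = 5000) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

randomGenome <- function(len = 5000, genes = NULL) {
  genomeContext(c(chr1 = randomGenomeString(len)), genes)
}

## random SBS records on a genome; returns a data.frame usable by buildCatalog
randomSbsRecords <- function(genome, n, samples = "S1") {
  seqStr <- as.character(genome@sequences[["chr1"]])
  len <- nchar(seqStr)
  pos <- sample(2:(len - 1), n, replace = TRUE)
  ref <- substring(seqStr, pos, pos)
  alt <- vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1),
    USE.NAMES = FALSE)
  data.frame(sample = sample(samples, n, replace = TRUE), chrom = "chr1",
             pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
}

randomDbsRecords <- function(genome, n, samples = "S1") {
  seqStr <- as.character(genome@sequences[["chr1"]])
  len <- nchar(seqStr)
  pos <- sample(2:(len - 2), n, replace = TRUE)
  ref <- substring(seqStr, pos, pos + 1)
  alt <- vapply(ref, function(d) {
    paste0(sample(setdiff(c("A", "C", "G", "T"), substr(d, 1, 1)), 1),
           sample(setdiff(c("A", "C", "G", "T"), substr(d, 2, 2)), 1))
  }, character(1), USE.NAMES = FALSE)
  data.frame(sample = sample(samples, n, replace = TRUE), chrom = "chr1",
             pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
}

## random left-aligned indel records; draws are rejected until the VCF
## left-alignment condition holds (anchor differs from the event's last base)
randomIndelRecords <- function(genome, n, samples = "S1", maxLen = 6L) {
  seqStr <- as.character(genome@sequences[["chr1"]])
  len <- nchar(seqStr)
  out <- vector("list", n)
  i <- 0L
  while (i < n) {
    L <- sample(seq_len(maxLen), 1)
    pos <- sample(50:(len - 50 - 8 * L), 1)
    anchor <- substr(seqStr, pos, pos)
    if (runif(1) < 0.5) {                      # deletion
      del <- substr(seqStr, pos + 1, pos + L)
      if (anchor == substr(del, L, L)) next
      rec <- list(ref = paste0(anchor, del), alt = anchor)
    } else {                                   # insertion
      ins <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                   collapse = "")
      if (anchor == substr(ins, L, L)) next
      rec <- list(ref = anchor, alt = paste0(anchor, ins))
    }
    i <- i + 1L
    out[[i]] <- data.frame(sample = sample(samples, 1), chrom = "chr1",
                           pos = pos, ref = rec$ref, alt = rec$alt,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## small genome whose annotation has genes on both strands for strand tests
strandedGenome <- function(len = 3000) {
  genes <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(101, 1001, 1901, 1951), c(900, 1800, 2400, 2100)),
    strand = c("+", "-", "+", "-"))
  names(genes) <- c("gPlusA", "gMinusA", "gPlusLong", "gMinusShort")
  genomeContext(c(chr1 = randomGenomeString(len)), genes)
}

## deterministic subject table for association-model unit tests
nullCohort <- function(n) {
  data.frame(
    age = rnorm(n, 64, 10),
    sex = factor(sample(c("female", "male"), n, replace = TRUE)),
    purity = runif(n, 0.2, 0.9),
    exposure = rnorm(n, 20, 8),
    stringsAsFactors = FALSE)
}
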