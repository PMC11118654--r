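## Category systems for the five somatic variant classes.

.SBS_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

.sbs96Labels <- function() {
  out <- character(0)
  for (sub in .SBS_SUBS)
    for (f in .BASES)
      for (t in .BASES)
        out <- c(out, paste0(f, "[", sub, "]", t))
  out
}

.sbs288Labels <- function() {
  base <- .sbs96Labels()
  c(paste0("T:", base), paste0("U:", base), paste0("N:", base))
}

## Canonical doublet categories. Non-canonical reference doublets are
## represented by the reverse complement of both alleles; for palindromic
## reference doublets the canonical alternate of each reverse-complement pair
## is fixed by this list.
.DBS78_LABELS <- c(
  "AC>CA", "AC>CG", "AC>CT", "AC>GA", "AC>GG", "AC>GT", "AC>TA", "AC>TG", "AC>TT",
  "AT>CA", "AT>CC", "AT>CG", "AT>GA", "AT>GC", "AT>TA",
  "CC>AA", "CC>AG", "CC>AT", "CC>GA", "CC>GG", "CC>GT", "CC>TA", "CC>TG", "CC>TT",
  "CG>AT", "CG>GC", "CG>GT", "CG>TA", "CG>TC", "CG>TT",
  "CT>AA", "CT>AC", "CT>AG", "CT>GA", "CT>GC", "CT>GG", "CT>TA", "CT>TC", "CT>TG",
  "GC>AA", "GC>AG", "GC>AT", "GC>CA", "GC>CG", "GC>TA",
  "TA>AT", "TA>CG", "TA>CT", "TA>GC", "TA>GG", "TA>GT",
  "TC>AA", "TC>AG", "TC>AT", "TC>CA", "TC>CG", "TC>CT", "TC>GA", "TC>GG", "TC>GT",
  "TG>AA", "TG>AC", "TG>AT", "TG>CA", "TG>CC", "TG>CT", "TG>GA", "TG>GC", "TG>GT",
  "TT>AA", "TT>AC", "TT>AG", "TT>CA", "TT>CC", "TT>CG", "TT>GA", "TT>GC", "TT>GG")

## full lookup from any (ref, alt) doublet with both bases substituted to its
## canonical label
.dbsLookup <- function() {
  canon <- .DBS78_LABELS
  map <- character(0)
  for (r1 in .BASES) for (r2 in .BASES)
    for (a1 in setdiff(.BASES, r1)) for (a2 in setdiff(.BASES, r2)) {
      ref <- paste0(r1, r2); alt <- paste0(a1, a2)
      lab <- paste0(ref, ">", alt)
      rc <- paste0(.revcomp(ref), ">", .revcomp(alt))
      map[[paste0(ref, alt)]] <-
        if (lab %in% canon) lab
        else if (rc %in% canon) rc
        else stop("doublet lookup construction failed for ", lab)
    }
  map
}

.DBS_LOOKUP <- NULL  # built lazily at first use

.id83Labels <- function() {
  lab <- character(0)
  for (b in c("C", "T")) lab <- c(lab, paste0("1:Del:", b, ":", 0:5))
  for (b in c("C", "T")) lab <- c(lab, paste0("1:Ins:", b, ":", 0:5))
  for (L in 2:5) lab <- c(lab, paste0(L, ":Del:R:", 0:5))
  for (L in 2:5) lab <- c(lab, paste0(L, ":Ins:R:", 0:5))
  lab <- c(lab, "2:Del:M:1",
           paste0("3:Del:M:", 1:2),
           paste0("4:Del:M:", 1:3),
           paste0("5:Del:M:", 1:5))
  lab
}

#' Context schemas
#'
#' Constructors for the shipped classification schemas: the 96 and 288
#' trinucleotide substitution categories, the 78 doublet categories, the 83
#' indel categories, and configurable copy-number and structural-variant bin
#' systems.
#'
#' The copy-number schema crosses an allele state (homozygous deletion, loss
#' of heterozygosity, heterozygous) with total-copy-number bins and segment
#' length bins, including two sub-100 kb bins to resolve short segments; the
#' defaults enumerate to 68 categories. The structural-variant schema crosses
#' clustered status with event type and size bins (including a sub-1 kb bin),
#' enumerating to 38 categories by default. Both bin systems are reconstructions
#' and can be overridden through their arguments.
#'
#' @param lengthBreaks Upper boundaries (bp) of all but the last segment-length
#'   bin for heterozygous and LOH states.
#' @param homdelLengthBreaks As above, for homozygous deletions.
#' @param sizeBreaks Upper boundaries (bp) of all but the last SV size bin.
#' @return A [ContextSchema].
#' @export
schemaSBS96 <- function() {
  new("ContextSchema", schemaId = "SBS96", categories = .sbs96Labels(),
      parameters = list())
}

#' @rdname schemaSBS96
#' @export
schemaSBS288 <- function() {
  new("ContextSchema", schemaId = "SBS288", categories = .sbs288Labels(),
      parameters = list())
}

#' @rdname schemaSBS96
#' @export
schemaDBS78 <- function() {
  new("ContextSchema", schemaId = "DBS78", categories = .DBS78_LABELS,
      parameters = list())
}

#' @rdname schemaSBS96
#' @export
schemaID83 <- function() {
  new("ContextSchema", schemaId = "ID83", categories = .id83Labels(),
      parameters = list())
}

.lengthBinLabels <- function(breaks) {
  fmt <- function(x) {
    if (x >= 1e6) paste0(x / 1e6, "Mb") else paste0(x / 1e3, "kb")
  }
  labs <- character(length(breaks) + 1)
  prev <- "0"
  for (i in seq_along(breaks)) {
    labs[i] <- paste0(prev, "-", fmt(breaks[i]))
    prev <- fmt(breaks[i])
  }
  labs[length(breaks) + 1] <- paste0(">", fmt(breaks[length(breaks)]))
  labs
}

.CN_TCN_BINS <- list(
  LOH = list(labels = c("1", "2", "3-4", "5-8", "9+"),
             upper = c(1, 2, 4, 8, Inf)),
  het = list(labels = c("2", "3-4", "5-8", "9+"),
             upper = c(2, 4, 8, Inf)))

#' @rdname schemaSBS96
#' @export
schemaCN <- function(lengthBreaks = c(1e4, 1e5, 5e5, 1e6, 1e7, 4e7),
                     homdelLengthBreaks = c(1e4, 1e5, 1e6, 1e7)) {
  lenLabs <- .lengthBinLabels(lengthBreaks)
  hdLabs <- .lengthBinLabels(homdelLengthBreaks)
  cats <- paste0("0:homdel:", hdLabs)
  for (tcn in .CN_TCN_BINS$LOH$labels)
    cats <- c(cats, paste0(tcn, ":LOH:", lenLabs))
  for (tcn in .CN_TCN_BINS$het$labels)
    cats <- c(cats, paste0(tcn, ":het:", lenLabs))
  new("ContextSchema", schemaId = "CN_CONFIG", categories = cats,
      parameters = list(lengthBreaks = lengthBreaks,
                        homdelLengthBreaks = homdelLengthBreaks,
                        lengthLabels = lenLabs, homdelLengthLabels = hdLabs))
}

#' @rdname schemaSBS96
#' @export
schemaSV <- function(sizeBreaks = c(1e3, 1e4, 1e5, 1e6, 1e7)) {
  fmt <- function(x) if (x >= 1e6) paste0(x / 1e6, "Mb") else paste0(x / 1e3, "kb")
  labs <- character(length(sizeBreaks) + 1)
  labs[1] <- paste0("<", fmt(sizeBreaks[1]))
  for (i in seq_along(sizeBreaks)[-1])
    labs[i] <- paste0(fmt(sizeBreaks[i - 1]), "-", fmt(sizeBreaks[i]))
  labs[length(sizeBreaks) + 1] <- paste0(">", fmt(sizeBreaks[length(sizeBreaks)]))
  cats <- character(0)
  for (cl in c("clustered", "non-clustered")) {
    for (ty in c("del", "dup", "inv"))
      cats <- c(cats, paste(cl, ty, labs, sep = ":"))
    cats <- c(cats, paste(cl, "tra", sep = ":"))
  }
  new("ContextSchema", schemaId = "SV_CONFIG", categories = cats,
      parameters = list(sizeBreaks = sizeBreaks, sizeLabels = labs))
}
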