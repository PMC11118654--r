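## Independent brute-force oracles. These deliberately avoid the package's
## code paths: classification oracles work on plain strings with explicit
## complement tables and exhaustive label dictionaries; statistical oracles
## enumerate directly.

.ocomp <- c(A = "T", C = "G", G = "C", T = "A")

## dictionary mapping (5', ref, 3', alt) -> one of the 96 labels, built by
## enumerating every label together with its purine-strand representation
oracleSbsDict <- local({
  dict <- new.env(parent = emptyenv())
  for (refPy in c("C", "T"))
    for (alt in setdiff(c("A", "C", "G", "T"), refPy))
      for (f in c("A", "C", "G", "T"))
        for (t in c("A", "C", "G", "T")) {
          lab <- paste0(f, "[", refPy, ">", alt, "]", t)
          assign(paste(f, refPy, t, alt, sep = "|"), lab, envir = dict)
          assign(paste(.ocomp[[t]], .ocomp[[refPy]], .ocomp[[f]],
                       .ocomp[[alt]], sep = "|"), lab, envir = dict)
        }
  dict
})

oracleClassifySbs <- function(seqStr, pos, ref, alt) {
  f <- substr(seqStr, pos - 1, pos - 1)
  t <- substr(seqStr, pos + 1, pos + 1)
  get(paste(f, ref, t, alt, sep = "|"), envir = oracleSbsDict)
}

## doublet oracle: membership in the canonical label set, otherwise the
## reverse complement of both alleles (explicit string reversal + table)
oracleRevcompDoublet <- function(d) {
  paste0(.ocomp[[substr(d, 2, 2)]], .ocomp[[substr(d, 1, 1)]])
}

oracleClassifyDbs <- function(ref, alt, canonical) {
  lab <- paste0(ref, ">", alt)
  if (lab %in% canonical) return(lab)
  rc <- paste0(oracleRevcompDoublet(ref), ">", oracleRevcompDoublet(alt))
  stopifnot(rc %in% canonical)
  rc
}

## indel oracle: manual application of the published 83-category rules on a
## plain character string (anchor-base VCF records, left-aligned)
oracleClassifyIndel <- function(seqStr, pos, ref, alt) {
  del <- nchar(ref) > nchar(alt)
  unit <- if (del) substr(ref, 2, nchar(ref)) else substr(alt, 2, nchar(alt))
  L <- nchar(unit)
  downStart <- if (del) pos + nchar(ref) else pos + 1
  down <- substr(seqStr, downStart, nchar(seqStr))
  copies <- 0
  while (copies < 6 &&
         substr(down, copies * L + 1, (copies + 1) * L) == unit)
    copies <- copies + 1
  kind <- if (del) "Del" else "Ins"
  if (L == 1) {
    b <- if (unit %in% c("C", "T")) unit else .ocomp[[unit]]
    field <- if (del) min(copies, 5) else min(copies, 5)
    return(paste0("1:", kind, ":", b, ":", field))
  }
  Lr <- min(L, 5)
  if (!del || copies >= 1)
    return(paste0(Lr, ":", kind, ":R:", min(copies, 5)))
  ## deletion, no tandem copy: junction homology with either flank
  up <- substr(seqStr, 1, pos)
  mh <- 0
  for (k in seq_len(L - 1)) {
    pre <- substr(unit, 1, k)
    suf <- substr(unit, L - k + 1, L)
    dwn <- substr(down, 1, k)
    upk <- substr(up, nchar(up) - k + 1, nchar(up))
    if (nchar(dwn) == k && (dwn == pre || dwn == suf)) mh <- k
    else if (nchar(upk) == k && upk == suf) mh <- k
  }
  if (mh >= 1) {
    cap <- if (Lr == 5) 5 else Lr - 1
    return(paste0(Lr, ":Del:M:", min(mh, cap)))
  }
  paste0(Lr, ":Del:R:0")
}

## exhaustive support enumeration + NNLS with the addition-penalty window:
## among supports within `addPenalty` of the best achievable cosine, the
## smallest support wins, ties by cosine then lexicographic support
oracleSparseFit <- function(profile, W, addPenalty) {
  labs <- sort(colnames(W))
  p <- length(labs)
  subs <- unlist(lapply(0:p, function(s) combn(labs, s, simplify = FALSE)),
                 recursive = FALSE)
  fits <- lapply(subs, function(S) {
    if (!length(S))
      return(list(S = S, cos = 0, x = stats::setNames(numeric(p), labs)))
    xs <- pracma::lsqnonneg(W[, S, drop = FALSE], profile)$x
    x <- stats::setNames(numeric(p), labs)
    x[S] <- xs
    list(S = S, x = x,
         cos = cosineSimilarity(profile, W[, S, drop = FALSE] %*% xs))
  })
  best <- max(vapply(fits, `[[`, numeric(1), "cos"))
  ok <- fits[vapply(fits, `[[`, numeric(1), "cos") >= best - addPenalty]
  sz <- vapply(ok, function(f) length(f$S), integer(1))
  ok <- ok[sz == min(sz)]
  key <- vapply(ok, function(f) paste(f$S, collapse = ","), character(1))
  ok[[order(-vapply(ok, `[[`, numeric(1), "cos"), key)[1]]]
}

## hand-applied step-up adjustment
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

## two-sided Fisher p by hypergeometric enumeration over all tables with the
## observed margins
oracleFisherP <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  as <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(as, function(a)
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1), numeric(1))
  obs <- probs[as == tab[1, 1]]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

## two-sided rank-sum p by full permutation enumeration (tie-averaged ranks)
.allPerms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(.allPerms(v[-i]), function(rest) c(v[i], rest)))
  out
}

oracleRankSumP <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  mu <- length(x) * (n + 1) / 2
  obs <- abs(sum(r[seq_along(x)]) - mu)
  perms <- .allPerms(seq_len(n))
  stats <- vapply(perms, function(p)
    abs(sum(r[p[seq_along(x)]]) - mu), numeric(1))
  mean(stats >= obs - 1e-12)
}
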