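## Tandem and segmental duplication detection, collinearity chaining and
## Nei-Gojobori (1986) Ka/Ks estimation.

#' Find tandem duplication events
#'
#' Maximal same-chromosome clusters in which consecutive family genes lie
#' within \code{window} bp of each other (start-to-start); every cluster of
#' two or more genes emits one event per adjacent pair. The 200-kb window
#' is the conventional tandem-duplication criterion.
#'
#' @param loci data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}.
#' @param window clustering window in bp (default 200000).
#' @return data.frame (gene_a, gene_b, chrom, distance, cluster_id)
#' @export
findTandemEvents <- function(loci, window = 200000) {
  out <- list()
  cl_id <- 0L
  for (chrom in unique(loci$chrom)) {
    sub <- loci[loci$chrom == chrom, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) < 2L) next
    gapnew <- c(TRUE, diff(sub$start) > window)
    cluster <- cumsum(gapnew)
    for (cl in unique(cluster)) {
      members <- which(cluster == cl)
      if (length(members) < 2L) next
      cl_id <- cl_id + 1L
      for (k in seq_len(length(members) - 1L)) {
        i <- members[k]; j <- members[k + 1L]
        out[[length(out) + 1L]] <- data.frame(
          gene_a = sub$gene_id[i], gene_b = sub$gene_id[j], chrom = chrom,
          distance = sub$start[j] - sub$start[i], cluster_id = cl_id,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      chrom = character(0), distance = numeric(0),
                      cluster_id = integer(0)))
  do.call(rbind, out)
}

#' All-against-all protein similarity anchors
#'
#' BLASTP-like all-vs-all scoring via local alignment with BLOSUM62 and
#' affine gaps; for each query the \code{topK} best non-self matches above
#' \code{scoreThreshold} are kept, and symmetric duplicates are collapsed
#' for within-proteome comparisons.
#'
#' @param proteomeA named \code{AAStringSet}/character vector.
#' @param proteomeB optional second proteome; NULL compares A to itself.
#' @param topK matches kept per query.
#' @param scoreThreshold minimum alignment score.
#' @param minCoverage minimum fraction of the shorter protein spanned by
#'   the local alignment (0 disables). Coverage filtering is the usual way
#'   to keep whole-gene homologs while discarding matches confined to a
#'   single shared domain.
#' @param minIdentity minimum percent-identity fraction of the local
#'   alignment (0 disables); standard homolog-anchor filtering.
#' @param gapOpening,gapExtension affine gap parameters.
#' @return data.frame (gene_a, gene_b, score)
#' @export
findAnchorPairs <- function(proteomeA, proteomeB = NULL, topK = 5L,
                            scoreThreshold = 60, minCoverage = 0,
                            minIdentity = 0, gapOpening = 10,
                            gapExtension = 0.5) {
  A <- Biostrings::AAStringSet(.as_named_chr(proteomeA))
  self <- is.null(proteomeB)
  B <- if (self) A else Biostrings::AAStringSet(.as_named_chr(proteomeB))
  if (!length(A) || !length(B)) stop("proteomes must be non-empty")
  if (is.null(names(A))) names(A) <- paste0("a", seq_along(A))
  if (is.null(names(B))) names(B) <- if (self) names(A) else
    paste0("b", seq_along(B))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  blosum <- get("BLOSUM62", envir = environment())
  out <- list()
  for (i in seq_along(A)) {
    sc <- Biostrings::pairwiseAlignment(
      pattern = rep(A[i], length(B)), subject = B,
      substitutionMatrix = blosum, gapOpening = gapOpening,
      gapExtension = gapExtension, type = "local", scoreOnly = TRUE)
    if (self) sc[i] <- -Inf
    ok <- which(sc >= scoreThreshold)
    if (!length(ok)) next
    ok <- ok[order(sc[ok], decreasing = TRUE)][seq_len(min(topK, length(ok)))]
    if (minCoverage > 0 || minIdentity > 0) {
      pass <- vapply(ok, function(j) {
        al <- Biostrings::pairwiseAlignment(
          A[[i]], B[[j]], substitutionMatrix = blosum,
          gapOpening = gapOpening, gapExtension = gapExtension,
          type = "local")
        cov <- IRanges::width(Biostrings::pattern(al)@range) /
          min(length(A[[i]]), length(B[[j]]))
        cov >= minCoverage && Biostrings::pid(al) / 100 >= minIdentity
      }, TRUE)
      ok <- ok[pass]
      if (!length(ok)) next
    }
    out[[length(out) + 1L]] <- data.frame(
      gene_a = names(A)[i], gene_b = names(B)[ok], score = sc[ok],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0)))
  res <- do.call(rbind, out)
  if (self) {
    key <- ifelse(res$gene_a < res$gene_b,
                  paste(res$gene_a, res$gene_b),
                  paste(res$gene_b, res$gene_a))
    res <- res[!duplicated(key), , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Gene rank coordinates along chromosomes
#'
#' @param loci data.frame with \code{gene_id}, \code{chrom}, \code{start}.
#' @return data.frame (gene_id, chrom, rank) with rank = order index along
#'   each chromosome
#' @export
geneRanks <- function(loci) {
  out <- lapply(split(loci, loci$chrom), function(sub) {
    sub <- sub[order(sub$start), , drop = FALSE]
    data.frame(gene_id = sub$gene_id, chrom = sub$chrom,
               rank = seq_len(nrow(sub)), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## longest monotone chain under the gap constraint; anchors df must have
## rank_a, rank_b; direction +1 (same) or -1 (inverted)
.best_chain <- function(anchors, max_gap, direction) {
  n <- nrow(anchors)
  if (!n) return(integer(0))
  o <- order(anchors$rank_a, direction * anchors$rank_b)
  ra <- anchors$rank_a[o]; rb <- anchors$rank_b[o] * direction
  len <- rep(1L, n); prev <- rep(0L, n)
  for (j in seq_len(n)) for (i in seq_len(j - 1L)) {
    if (ra[j] > ra[i] && rb[j] > rb[i] &&
        ra[j] - ra[i] <= max_gap + 1L && rb[j] - rb[i] <= max_gap + 1L &&
        len[i] + 1L > len[j]) {
      len[j] <- len[i] + 1L
      prev[j] <- i
    }
  }
  end <- which.max(len)
  chain <- integer(0)
  while (end != 0L) { chain <- c(end, chain); end <- prev[end] }
  o[chain]
}

#' Chain anchors into collinear blocks
#'
#' Dynamic-programming longest chains of anchor pairs whose rank gaps on
#' both chromosomes are at most \code{maxGap}, in the same or inverted
#' orientation (MCScanX-style defaults: at least 5 anchors, gap 25). Chains
#' are extracted greedily best-first; each anchor is used in at most one
#' block per chromosome pair.
#'
#' @param anchors data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{chrom_a}, \code{chrom_b}, \code{rank_a}, \code{rank_b}.
#' @param minAnchors minimum anchors per reported block.
#' @param maxGap maximum rank gap on either axis.
#' @return data.frame of block members with columns of \code{anchors} plus
#'   \code{block_id} and \code{orientation} ("same"/"inverted")
#' @export
chainCollinearBlocks <- function(anchors, minAnchors = 5L, maxGap = 25L) {
  empty <- cbind(anchors[0, , drop = FALSE],
                 data.frame(block_id = integer(0), orientation = character(0)))
  if (!nrow(anchors)) return(empty)
  blocks <- list()
  bid <- 0L
  for (key in unique(paste(anchors$chrom_a, anchors$chrom_b))) {
    sub <- anchors[paste(anchors$chrom_a, anchors$chrom_b) == key, ,
                   drop = FALSE]
    repeat {
      fwd <- .best_chain(sub, maxGap, +1L)
      rev <- .best_chain(sub, maxGap, -1L)
      use_fwd <- length(fwd) >= length(rev)
      chain <- if (use_fwd) fwd else rev
      if (length(chain) < minAnchors) break
      bid <- bid + 1L
      blk <- sub[chain, , drop = FALSE]
      blk$block_id <- bid
      blk$orientation <- if (use_fwd) "same" else "inverted"
      blocks[[length(blocks) + 1L]] <- blk
      sub <- sub[-chain, , drop = FALSE]
      if (!nrow(sub)) break
    }
  }
  if (!length(blocks)) return(empty)
  res <- do.call(rbind, blocks)
  rownames(res) <- NULL
  res
}

#' Classify family duplications as tandem or segmental
#'
#' Family gene pairs co-occurring as anchors in a collinear block are
#' segmental; pairs in tandem clusters are tandem; a pair qualifying as
#' both is reported once, as tandem.
#'
#' @param blocks block table from \code{\link{chainCollinearBlocks}}.
#' @param tandemEvents table from \code{\link{findTandemEvents}}.
#' @param familyIds character vector of family gene ids.
#' @return data.frame (gene_a, gene_b, class, evidence)
#' @export
classifyFamilyDuplications <- function(blocks, tandemEvents, familyIds) {
  norm <- function(a, b) ifelse(a < b, paste(a, b), paste(b, a))
  out <- list()
  seen <- character(0)
  if (nrow(tandemEvents)) {
    td <- tandemEvents[tandemEvents$gene_a %in% familyIds &
                       tandemEvents$gene_b %in% familyIds, , drop = FALSE]
    for (i in seq_len(nrow(td))) {
      key <- norm(td$gene_a[i], td$gene_b[i])
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- data.frame(
        gene_a = td$gene_a[i], gene_b = td$gene_b[i], class = "tandem",
        evidence = paste0("cluster_", td$cluster_id[i], ":",
                          td$distance[i], "bp"),
        stringsAsFactors = FALSE)
    }
  }
  if (nrow(blocks)) {
    seg <- blocks[blocks$gene_a %in% familyIds &
                  blocks$gene_b %in% familyIds, , drop = FALSE]
    for (i in seq_len(nrow(seg))) {
      key <- norm(seg$gene_a[i], seg$gene_b[i])
      if (key %in% seen) next      # tandem takes precedence
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- data.frame(
        gene_a = seg$gene_a[i], gene_b = seg$gene_b[i], class = "segmental",
        evidence = paste0("block_", seg$block_id[i]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      class = character(0), evidence = character(0)))
  do.call(rbind, out)
}

## --- Nei-Gojobori 1986 -----------------------------------------------------

## memoized per-codon and per-pair tallies (the per-codon quantities are
## fixed by the genetic code, so computing them once is enough)
.ng86_env <- new.env(parent = emptyenv())

## per-codon synonymous site count: for each position, the fraction of the
## three single-nucleotide changes that are synonymous; substitutions
## creating stop codons count as nonsynonymous
.ng86_syn_sites <- function(codon) {
  hit <- .ng86_env[[paste0("s_", codon)]]
  if (!is.null(hit)) return(hit)
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  s <- 0
  cs <- strsplit(codon, "")[[1]]
  for (pos in 1:3) for (alt in setdiff(.DNA, cs[pos])) {
    mut <- cs; mut[pos] <- alt
    mc <- paste(mut, collapse = "")
    if (gc[[mc]] != "*" && gc[[mc]] == aa) s <- s + 1 / 3
  }
  .ng86_env[[paste0("s_", codon)]] <- s
  s
}

## synonymous/nonsynonymous differences between two codons, averaged over
## all substitution pathways; pathways passing through stop codons are
## excluded (all pathways used if every one is blocked)
.ng86_diffs <- function(ca, cb) {
  key <- paste0("d_", ca, cb)
  hit <- .ng86_env[[key]]
  if (!is.null(hit)) return(hit)
  gc <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1L) list(pos) else {
    pm <- list()
    idx <- seq_len(nd)
    permute <- function(v) if (length(v) <= 1L) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(permute(v[-i]), function(r) c(v[i], r))))
    lapply(permute(idx), function(ord) pos[ord])
  }
  tally <- function(order_pos, allow_stop) {
    cur <- strsplit(ca, "")[[1]]
    tgt <- strsplit(cb, "")[[1]]
    sd <- 0; nd_ <- 0
    for (p in order_pos) {
      prev <- paste(cur, collapse = "")
      cur[p] <- tgt[p]
      nxt <- paste(cur, collapse = "")
      if (gc[[nxt]] == "*" && !allow_stop) return(NULL)
      if (gc[[nxt]] == gc[[prev]]) sd <- sd + 1 else nd_ <- nd_ + 1
    }
    c(sd = sd, nd = nd_)
  }
  res <- Filter(Negate(is.null), lapply(perms, tally, allow_stop = FALSE))
  if (!length(res)) res <- lapply(perms, tally, allow_stop = TRUE)
  cm <- do.call(rbind, res)
  out <- c(sd = mean(cm[, "sd"]), nd = mean(cm[, "nd"]))
  .ng86_env[[key]] <- out
  out
}

## Jukes-Cantor multiple-hit correction
.jc_correct <- function(p) {
  if (p >= 3 / 4) return(NA_real_)      # saturated
  -(3 / 4) * log(1 - (4 / 3) * p)
}

#' Nei-Gojobori (1986) Ka/Ks for an aligned codon pair
#'
#' Counts synonymous and nonsynonymous sites per codon (averaged over both
#' sequences), counts differences with pathway averaging for codons
#' differing at more than one position (stop-codon pathways excluded),
#' forms the proportions pS = Sd/S and pN = Nd/N and applies the
#' Jukes-Cantor correction \code{d = -(3/4) ln(1 - (4/3) p)}.
#'
#' @param cds_a,cds_b equal-length, gap-free, in-frame aligned CDS (no
#'   internal stops; a single terminal stop is trimmed).
#' @return one-row data.frame: \code{ka}, \code{ks}, \code{ratio},
#'   \code{undefined} (TRUE when Ks = 0), \code{saturated} (TRUE when a
#'   proportion exceeds the correctable range), plus the site and
#'   difference tallies \code{s_sites}, \code{n_sites}, \code{sd_diff},
#'   \code{nd_diff}.
#' @examples
#' kaksNG86("TTT", "TTC")  # one synonymous difference
#' @export
kaksNG86 <- function(cds_a, cds_b) {
  a <- toupper(as.character(cds_a)); b <- toupper(as.character(cds_b))
  if (nchar(a) != nchar(b)) stop("aligned CDS lengths differ")
  if (nchar(a) %% 3 != 0) stop("CDS length not a multiple of 3")
  gc <- Biostrings::GENETIC_CODE
  split3 <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  ca <- split3(a); cb <- split3(b)
  ## trim a shared terminal stop; error on internal stops
  if (gc[[ca[length(ca)]]] == "*" && gc[[cb[length(cb)]]] == "*") {
    ca <- ca[-length(ca)]; cb <- cb[-length(cb)]
  }
  if (any(vapply(c(ca, cb), function(x) gc[[x]] == "*", TRUE)))
    stop("internal stop codon in aligned CDS")

  S <- mean(c(sum(vapply(ca, .ng86_syn_sites, 0)),
              sum(vapply(cb, .ng86_syn_sites, 0))))
  N <- 3 * length(ca) - S
  d <- mapply(function(x, y) .ng86_diffs(x, y), ca, cb)
  Sd <- sum(d["sd", ]); Nd <- sum(d["nd", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  ks <- .jc_correct(pS); ka <- .jc_correct(pN)
  saturated <- is.na(ks) || is.na(ka)
  undefined <- !saturated && ks == 0
  ratio <- if (saturated || undefined) NA_real_ else ka / ks
  data.frame(ka = ka, ks = ks, ratio = ratio, undefined = undefined,
             saturated = saturated, s_sites = S, n_sites = N,
             sd_diff = Sd, nd_diff = Nd)
}

#' Codon-aware alignment of a CDS pair via their proteins
#'
#' Globally aligns the translated proteins (BLOSUM62, affine gaps) and
#' back-threads the codons; aligned positions where either sequence is
#' gapped are dropped, yielding the equal-length, gap-free codon alignment
#' that \code{\link{kaksNG86}} expects.
#'
#' @param cds_a,cds_b in-frame CDS (terminal stop allowed).
#' @return list(cds_a, cds_b) of aligned, gap-free CDS
#' @export
alignCodonPair <- function(cds_a, cds_b) {
  trim <- function(x) {
    x <- toupper(as.character(x))
    if (nchar(x) %% 3 != 0) stop("CDS length not a multiple of 3")
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(x),
                                             if.fuzzy.codon = "solve"))
    if (endsWith(aa, "*")) {
      aa <- substr(aa, 1, nchar(aa) - 1)
      x <- substr(x, 1, nchar(x) - 3)
    }
    list(cds = x, aa = aa)
  }
  A <- trim(cds_a); B <- trim(cds_b)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  blosum <- get("BLOSUM62", envir = environment())
  al <- Biostrings::pairwiseAlignment(A$aa, B$aa,
                                      substitutionMatrix = blosum,
                                      gapOpening = 10, gapExtension = 0.5,
                                      type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ia <- 0L; ib <- 0L
  outa <- character(0); outb <- character(0)
  for (k in seq_along(pa)) {
    if (pa[k] != "-") ia <- ia + 1L
    if (pb[k] != "-") ib <- ib + 1L
    if (pa[k] != "-" && pb[k] != "-") {
      outa <- c(outa, substr(A$cds, 3 * ia - 2, 3 * ia))
      outb <- c(outb, substr(B$cds, 3 * ib - 2, 3 * ib))
    }
  }
  list(cds_a = paste(outa, collapse = ""), cds_b = paste(outb, collapse = ""))
}
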