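## Poisson-corrected distances, neighbor joining with bootstrap, and
## marker-anchored subfamily classification.

#' Poisson-corrected protein distance matrix
#'
#' For each pair, \code{p} is the mismatch proportion over mutually
#' ungapped columns (pairwise deletion) and \code{d = -ln(1 - p)}. A pair
#' with \code{p = 1} is flagged saturated and capped at a large finite
#' distance.
#'
#' @param alignment named character vector or \code{AAStringSet} of
#'   equal-length gapped sequences.
#' @param pairwiseDeletion compute p only over mutually ungapped columns.
#' @param cap finite distance substituted for saturated pairs.
#' @return symmetric distance matrix with attributes \code{"sites"}
#'   (shared ungapped column counts) and \code{"saturated"} (logical matrix)
#' @export
poissonDistance <- function(alignment, pairwiseDeletion = TRUE, cap = 10) {
  aln <- .as_named_chr(alignment)
  if (length(aln) < 2L) stop("need at least 2 aligned sequences")
  if (length(unique(nchar(aln))) != 1L)
    stop("aligned sequences must have equal length")
  ids <- names(aln)
  if (is.null(ids)) ids <- paste0("t", seq_along(aln))
  mat <- do.call(rbind, strsplit(toupper(aln), ""))
  mat[mat == "."] <- "-"
  if (!pairwiseDeletion) {
    keep <- colSums(mat == "-") == 0L
    mat <- mat[, keep, drop = FALSE]
  }
  n <- length(aln)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  sites <- matrix(ncol(mat), n, n, dimnames = list(ids, ids))
  sat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    m <- sum(ok)
    if (m == 0L) stop("no shared ungapped columns for pair ",
                      ids[i], " / ", ids[j])
    p <- sum(mat[i, ok] != mat[j, ok]) / m
    if (p >= 1) {
      D[i, j] <- D[j, i] <- cap
      sat[i, j] <- sat[j, i] <- TRUE
    } else D[i, j] <- D[j, i] <- -log(1 - p)
    sites[i, j] <- sites[j, i] <- m
  }
  attr(D, "sites") <- sites
  attr(D, "saturated") <- sat
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with a deterministic tie-break (the pair
#' earliest in matrix order among minimal-Q pairs). Negative branch lengths
#' are clamped to zero with the deficit moved to the sister edge, which
#' preserves path lengths. Exact on additive matrices.
#'
#' @param D symmetric distance matrix with row/column names.
#' @return an unrooted \code{ape::phylo} tree
#' @export
neighborJoining <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  nodes <- labels                      # newick fragment per active node

  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    merged <- sprintf("(%s:%.10g,%s:%.10g)", nodes[i], bi, nodes[j], bj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    nodes <- c(nodes[keep], merged)
  }
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  b1 <- max((d12 + d13 - d23) / 2, 0)
  b2 <- max((d12 + d23 - d13) / 2, 0)
  b3 <- max((d13 + d23 - d12) / 2, 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nodes[1], b1, nodes[2], b2, nodes[3], b3)
  ape::read.tree(text = nwk)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement; a Poisson-distance NJ
#' tree is built per replicate and the percentage of replicates containing
#' each internal bipartition of the original tree is attached as node
#' labels.
#'
#' @param alignment named gapped alignment (character/\code{AAStringSet}).
#' @param replicates bootstrap replicate count (0 = no supports).
#' @param seed RNG seed.
#' @param pairwiseDeletion passed to \code{\link{poissonDistance}}.
#' @return \code{phylo} tree; when \code{replicates > 0},
#'   \code{node.label} holds supports in [0, 100]
#' @export
bootstrapSupport <- function(alignment, replicates = 1000L, seed = 1L,
                             pairwiseDeletion = TRUE) {
  aln <- .as_named_chr(alignment)
  if (is.null(names(aln))) names(aln) <- paste0("t", seq_along(aln))
  ncols <- unique(nchar(aln))
  if (length(ncols) != 1L || ncols < 2L)
    stop("alignment must have >= 2 equal-length columns")
  tree <- neighborJoining(poissonDistance(aln, pairwiseDeletion))
  if (replicates <= 0L) return(tree)
  set.seed(seed)
  mat <- do.call(rbind, strsplit(aln, ""))
  boots <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    cols <- sample.int(ncols, ncols, replace = TRUE)
    rep_aln <- setNames(apply(mat[, cols, drop = FALSE], 1L, paste,
                              collapse = ""), names(aln))
    boots[[b]] <- neighborJoining(poissonDistance(rep_aln, pairwiseDeletion))
  }
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tree$node.label <- as.character(round(100 * counts / replicates))
  tree
}

#' Assign subfamily labels from marker taxa
#'
#' Each unlabeled gene takes the label of the smallest bipartition side
#' containing it whose markers belong to exactly one subfamily; when no
#' pure side exists the gene falls back to the label of the nearest marker
#' by patristic distance and is flagged ambiguous.
#'
#' @param tree \code{phylo} tree containing genes and marker taxa.
#' @param markerMap data.frame with columns \code{taxon}, \code{subfamily}
#'   (e.g. SIP1, GTgamma, GT, SH4, GTdelta), or a named character vector.
#' @return data.frame (gene_id, subfamily, method, ambiguous)
#' @export
assignSubfamilies <- function(tree, markerMap) {
  if (is.character(markerMap) && !is.null(names(markerMap)))
    markerMap <- data.frame(taxon = names(markerMap),
                            subfamily = unname(markerMap),
                            stringsAsFactors = FALSE)
  markers <- markerMap$taxon[markerMap$taxon %in% tree$tip.label]
  if (!length(markers)) stop("tree contains no marker taxa")
  lab_of <- setNames(markerMap$subfamily, markerMap$taxon)
  tips <- tree$tip.label
  genes <- setdiff(tips, markers)

  parts <- ape::prop.part(tree)
  sides <- list(seq_along(tips))
  for (p in parts) {
    sides[[length(sides) + 1L]] <- as.integer(p)
    sides[[length(sides) + 1L]] <- setdiff(seq_along(tips), as.integer(p))
  }
  sides <- unique(Filter(length, sides))
  pat <- ape::cophenetic.phylo(tree)

  out <- lapply(genes, function(g) {
    gi <- match(g, tips)
    best <- NULL
    for (s in sides) {
      if (!(gi %in% s)) next
      mk <- intersect(tips[s], markers)
      if (!length(mk)) next
      subs <- unique(lab_of[mk])
      if (length(subs) != 1L) next
      if (is.null(best) || length(s) < best$size)
        best <- list(size = length(s), label = subs)
    }
    if (!is.null(best)) {
      data.frame(gene_id = g, subfamily = best$label, method = "clade",
                 ambiguous = FALSE, stringsAsFactors = FALSE)
    } else {
      nearest <- markers[which.min(pat[g, markers])]
      data.frame(gene_id = g, subfamily = lab_of[[nearest]],
                 method = "nearest", ambiguous = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Align sequences to a profile's match coordinates
#'
#' Convenience fixed-length alignment: each sequence's best local hit is
#' threaded onto the profile's match positions (deletions and uncovered
#' positions as gaps, insertions dropped). Useful for building the domain
#' alignment that the phylogeny stage consumes; no parity with a full
#' progressive aligner is claimed.
#'
#' @param profile a \code{ProfileModel}.
#' @param sequences named character vector/\code{AAStringSet}.
#' @return named character vector of equal-length aligned strings
#' @export
profileAlign <- function(profile, sequences) {
  seqs <- .as_named_chr(sequences)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  out <- vapply(seq_along(seqs), function(i)
    attr(scoreLocal(profile, seqs[i], id = ids[i]), "model_alignment"), "")
  setNames(out, ids)
}
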