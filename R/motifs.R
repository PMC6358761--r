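## Promoter extraction, IUPAC cis-element scanning, shared-element
## intersection, and ZOOPS EM motif discovery (a simplified stand-in for
## MEME; no parity claimed).

#' Extract upstream promoter sequences
#'
#' Plus-strand genes: \code{[start - length, start - 1]}; minus-strand
#' genes: the reverse complement of \code{[end + 1, end + length]}.
#' Windows are truncated at chromosome edges and flagged.
#'
#' @param genome \code{DNAStringSet} of chromosomes.
#' @param genes data.frame with \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand} (or a \code{GRanges} of gene features with
#'   an \code{ID} column).
#' @param length upstream window in nt (default 1500).
#' @return \code{DNAStringSet} of promoters named by gene id, with a
#'   \code{truncated} logical in its metadata columns
#' @export
extractPromoters <- function(genome, genes, length = 1500L) {
  if (is(genes, "GRanges")) {
    md <- S4Vectors::mcols(genes)
    if (!is.null(md$type)) genes <- genes[md$type == "gene"]
    genes <- data.frame(
      gene_id = S4Vectors::mcols(genes)$ID,
      chrom = as.character(GenomicRanges::seqnames(genes)),
      start = GenomicRanges::start(genes), end = GenomicRanges::end(genes),
      strand = as.character(GenomicRanges::strand(genes)),
      stringsAsFactors = FALSE)
  }
  seqs <- character(nrow(genes))
  trunc <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    chrom <- genes$chrom[i]
    if (!chrom %in% names(genome))
      stop("gene ", genes$gene_id[i], " absent from genome (", chrom, ")")
    clen <- Biostrings::width(genome[chrom])
    if (genes$strand[i] == "-") {
      from <- genes$end[i] + 1L
      to <- min(genes$end[i] + length, clen)
      if (from > to) { seqs[i] <- ""; trunc[i] <- TRUE; next }
      s <- as.character(Biostrings::subseq(genome[[chrom]], from, to))
      seqs[i] <- .revcomp_chr(s)
      trunc[i] <- (to - from + 1L) < length
    } else {
      to <- genes$start[i] - 1L
      from <- max(genes$start[i] - length, 1L)
      if (from > to) { seqs[i] <- ""; trunc[i] <- TRUE; next }
      seqs[i] <- as.character(Biostrings::subseq(genome[[chrom]], from, to))
      trunc[i] <- (to - from + 1L) < length
    }
    if (trunc[i])
      warning("promoter of ", genes$gene_id[i],
              " truncated at chromosome edge", call. = FALSE)
  }
  out <- Biostrings::DNAStringSet(setNames(seqs, genes$gene_id))
  S4Vectors::mcols(out)$truncated <- trunc
  out
}

#' Scan a sequence for an IUPAC consensus element
#'
#' Reports every position where each consensus symbol's nucleotide set
#' contains the sequence base; reverse-strand hits are reported in forward
#' coordinates with a strand flag.
#'
#' @param sequence DNA sequence (character or \code{DNAString}).
#' @param consensus IUPAC consensus string.
#' @param elementId id carried into the result.
#' @param bothStrands scan the reverse strand too (default TRUE).
#' @param promoterId promoter id carried into the result.
#' @return data.frame (promoter_id, element_id, start, end, strand, match)
#' @export
iupacScan <- function(sequence, consensus, elementId = consensus,
                      bothStrands = TRUE, promoterId = "seq") {
  if (!all(strsplit(toupper(consensus), "")[[1]] %in%
           names(Biostrings::IUPAC_CODE_MAP)))
    stop("invalid IUPAC character in consensus: ", consensus)
  s <- Biostrings::DNAString(toupper(as.character(sequence)))
  empty <- data.frame(promoter_id = character(0), element_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), match = character(0))
  if (length(s) < nchar(consensus)) return(empty)
  pat <- Biostrings::DNAString(toupper(consensus))
  hit_df <- function(m, strand) {
    if (!length(m)) return(empty)
    data.frame(promoter_id = promoterId, element_id = elementId,
               start = Biostrings::start(m), end = Biostrings::end(m),
               strand = strand,
               match = as.character(Biostrings::extractAt(
                 s, IRanges::IRanges(Biostrings::start(m),
                                     Biostrings::end(m)))),
               stringsAsFactors = FALSE)
  }
  fw <- hit_df(Biostrings::matchPattern(pat, s, fixed = "subject"), "+")
  out <- fw
  if (bothStrands) {
    rv <- hit_df(Biostrings::matchPattern(
      Biostrings::reverseComplement(pat), s, fixed = "subject"), "-")
    out <- rbind(fw, rv)
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a cis-element library
#'
#' TSV with columns \code{id}, \code{consensus} (IUPAC) and
#' \code{annotation}. The shipped library
#' (\code{system.file("extdata", "cis_elements.tsv", package =
#' "trihelixr")}) holds the five PLACE elements used for trihelix promoter
#' analysis (GATABOX, ACGTATERD1, GT1CONSENSUS, INRNTPSADB, GT1GMSCAM4).
#'
#' @param path TSV path; default the shipped library.
#' @return data.frame (id, consensus, annotation)
#' @export
readElementLibrary <- function(path = system.file("extdata",
                                                  "cis_elements.tsv",
                                                  package = "trihelixr")) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("id", "consensus") %in% names(df)))
  df
}

#' Scan a promoter set against an element library
#'
#' @param promoters named \code{DNAStringSet}/character vector.
#' @param library element library data.frame (\code{id}, \code{consensus}).
#' @param bothStrands scan both strands.
#' @return data.frame of matches (promoter_id, element_id, start, end,
#'   strand, match)
#' @export
scanElementLibrary <- function(promoters, library, bothStrands = TRUE) {
  seqs <- .as_named_chr(promoters)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("promoter", seq_along(seqs))
  out <- list()
  for (i in seq_along(seqs)) for (k in seq_len(nrow(library))) {
    out[[length(out) + 1L]] <- iupacScan(seqs[i], library$consensus[k],
                                         elementId = library$id[k],
                                         bothStrands = bothStrands,
                                         promoterId = ids[i])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Elements shared by every promoter
#'
#' The intersection: elements with at least one match (either strand) in
#' every promoter of the set.
#'
#' @param promoters named \code{DNAStringSet}/character vector (>= 1).
#' @param library element library data.frame.
#' @param bothStrands scan both strands.
#' @return character vector of shared element ids
#' @export
sharedElements <- function(promoters, library, bothStrands = TRUE) {
  seqs <- .as_named_chr(promoters)
  if (!length(seqs)) stop("need at least one promoter")
  matches <- scanElementLibrary(seqs, library, bothStrands)
  shared <- character(0)
  for (eid in library$id) {
    carriers <- unique(matches$promoter_id[matches$element_id == eid])
    if (length(carriers) == length(seqs)) shared <- c(shared, eid)
  }
  shared
}

## --- ZOOPS EM motif discovery ---------------------------------------------

.seq_matrix <- function(seqs, alphabet) {
  lapply(seqs, function(s) .encode_seq(toupper(s), alphabet))
}

## one EM fit of a single ZOOPS motif; returns list(pwm, gamma, loglik,
## posteriors)
.zoops_em_once <- function(enc, width, alphabet, bg, init_sites,
                           max_iter = 200L, tol = 1e-6) {
  A <- length(alphabet)
  pwm <- matrix(0.5 / A, A, width)
  for (k in seq_along(enc)) {
    site <- enc[[k]][init_sites[k]:(init_sites[k] + width - 1L)]
    for (w in seq_len(width)) pwm[site[w], w] <- pwm[site[w], w] + 1
  }
  pwm <- sweep(pwm, 2L, colSums(pwm), "/")
  gamma <- 0.5
  ll_old <- -Inf
  post <- vector("list", length(enc))
  for (iter in seq_len(max_iter)) {
    ll <- 0
    counts <- matrix(0.25, A, width)    # pseudocount
    gsum <- 0
    for (k in seq_along(enc)) {
      x <- enc[[k]]
      n_off <- length(x) - width + 1L
      logw <- vapply(seq_len(n_off), function(t) {
        idx <- x[t:(t + width - 1L)]
        sum(log(pwm[cbind(idx, seq_len(width))]) - log(bg[idx]))
      }, 0)
      w_site <- (gamma / n_off) * exp(logw)
      denom <- (1 - gamma) + sum(w_site)
      ll <- ll + log(denom) + sum(log(bg[x]))
      p_site <- w_site / denom
      post[[k]] <- p_site
      gsum <- gsum + sum(p_site)
      for (t in seq_len(n_off)) {
        if (p_site[t] < 1e-12) next
        idx <- x[t:(t + width - 1L)]
        counts[cbind(idx, seq_len(width))] <-
          counts[cbind(idx, seq_len(width))] + p_site[t]
      }
    }
    pwm <- sweep(counts, 2L, colSums(counts), "/")
    gamma <- min(max(gsum / length(enc), 1e-3), 1 - 1e-3)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(pwm = pwm, gamma = gamma, loglik = ll, posteriors = post)
}

#' ZOOPS EM motif discovery
#'
#' Expectation-maximization over a zero-or-one-occurrence-per-sequence
#' mixture: each sequence carries at most one motif site against an i.i.d.
#' background. Motifs are discovered sequentially; after a motif converges
#' its maximum-posterior sites are masked and the next motif is fitted.
#' Multiple random restarts are run per motif and the best log-likelihood
#' kept. A didactic stand-in for MEME, with no parity claim.
#'
#' @param sequences character vector (>= 2) of DNA or protein sequences.
#' @param width motif width (<= shortest sequence).
#' @param nMotifs number of motifs to discover (<= 10).
#' @param nRestarts random restarts per motif.
#' @param seed RNG seed (results are deterministic given the seed).
#' @param alphabet residue alphabet; inferred (DNA vs protein) when NULL.
#' @return list of motif models, each with \code{pwm} (columns sum to 1),
#'   \code{consensus}, \code{gamma}, \code{loglik}, \code{sites}
#'   (data.frame sequence, start, posterior), \code{information} (bits)
#' @export
discoverMotifsEM <- function(sequences, width, nMotifs = 1L, nRestarts = 5L,
                             seed = 1L, alphabet = NULL) {
  seqs <- .as_named_chr(sequences)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (nMotifs > 10L) stop("nMotifs must be <= 10")
  if (width > min(nchar(seqs))) stop("width exceeds the shortest sequence")
  if (is.null(alphabet)) {
    chars <- unique(strsplit(paste(toupper(seqs), collapse = ""), "")[[1]])
    alphabet <- if (all(chars %in% .DNA)) .DNA else .AA
  }
  set.seed(seed)
  A <- length(alphabet)
  enc <- .seq_matrix(seqs, alphabet)
  bg <- rep(1 / A, A)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))

  motifs <- list()
  for (m in seq_len(nMotifs)) {
    best <- NULL
    for (r in seq_len(nRestarts)) {
      init <- vapply(enc, function(x)
        sample.int(length(x) - width + 1L, 1L), 1L)
      fit <- .zoops_em_once(enc, width, alphabet, bg, init)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    ## phase refinement: EM converges readily to a register shifted by a
    ## position or two; re-seed from shifted maximum-posterior sites and
    ## keep the best likelihood
    map_sites <- vapply(best$posteriors, which.max, 1L)
    for (shift in c(-2L, -1L, 1L, 2L)) {
      init <- vapply(seq_along(enc), function(k)
        as.integer(min(max(map_sites[k] + shift, 1L),
                       length(enc[[k]]) - width + 1L)), 1L)
      fit <- .zoops_em_once(enc, width, alphabet, bg, init)
      if (fit$loglik > best$loglik) best <- fit
    }
    sites <- do.call(rbind, lapply(seq_along(enc), function(k) {
      p <- best$posteriors[[k]]
      t <- which.max(p)
      if (p[t] > 0.5)
        data.frame(sequence = ids[k], start = t, posterior = p[t],
                   stringsAsFactors = FALSE)
      else NULL
    }))
    ic <- sum(apply(best$pwm, 2L, function(col)
      sum(col * log2(pmax(col, 1e-12) / bg))))
    motifs[[m]] <- list(
      pwm = best$pwm,
      consensus = paste(alphabet[apply(best$pwm, 2L, which.max)],
                        collapse = ""),
      gamma = best$gamma, loglik = best$loglik,
      sites = if (is.null(sites))
        data.frame(sequence = character(0), start = integer(0),
                   posterior = numeric(0)) else sites,
      information = ic)
    ## mask discovered sites before fitting the next motif
    if (m < nMotifs && !is.null(sites)) {
      for (row in seq_len(nrow(sites))) {
        k <- match(sites$sequence[row], ids)
        t <- sites$start[row]
        enc[[k]][t:(t + width - 1L)] <-
          sample.int(A, width, replace = TRUE)
      }
    }
  }
  motifs
}
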