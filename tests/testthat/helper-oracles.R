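## Independent brute-force oracles used across the suite. These deliberately
## re-derive each quantity by enumeration or direct definition, never by
## calling the implementation under test.

## all local alignments of seq against a small profile, enumerated
## recursively; alignments start and end with a match column, affine gaps
bf_profile_score <- function(em, seq_idx, gap_open, gap_extend) {
  L <- nrow(em); n <- length(seq_idx)
  best <- 0
  recurse <- function(i, j, score, state) {
    ## state: 1 = last column was match, 2 = gap-in-model, 3 = gap-in-seq
    if (state == 1L) best <<- max(best, score)
    if (i > n || j > L) return(invisible())
    ## match
    recurse(i + 1L, j + 1L, score + em[j, seq_idx[i]], 1L)
    ## insertion (consume sequence)
    if (state != 3L)
      recurse(i + 1L, j,
              score - if (state == 2L) gap_extend else gap_open, 2L)
    ## deletion (consume model)
    if (state != 2L)
      recurse(i, j + 1L,
              score - if (state == 3L) gap_extend else gap_open, 3L)
    invisible()
  }
  for (i in seq_len(n)) for (j in seq_len(L)) recurse(i, j, 0, 0L)
  best
}

## tandem events by all-pairs definition: (a, b) on the same chromosome with
## no family gene strictly between them and start distance <= window
bf_tandem_events <- function(loci, window) {
  out <- list()
  for (chrom in unique(loci$chrom)) {
    sub <- loci[loci$chrom == chrom, , drop = FALSE]
    if (nrow(sub) < 2L) next
    for (i in seq_len(nrow(sub))) for (j in seq_len(nrow(sub))) {
      if (i == j) next
      lo <- min(sub$start[i], sub$start[j])
      hi <- max(sub$start[i], sub$start[j])
      if (hi - lo > window) next
      between <- any(sub$start > lo & sub$start < hi)
      if (between) next
      if (sub$start[i] < sub$start[j])
        out[[length(out) + 1L]] <- c(sub$gene_id[i], sub$gene_id[j])
    }
  }
  if (!length(out)) return(character(0))
  sort(vapply(out, paste, "", collapse = "|"))
}

## longest monotone chain (same or inverted) with rank gaps <= max_gap on
## both axes, by exhaustive subset enumeration (feasible for <= 12 anchors)
bf_longest_chain <- function(rank_a, rank_b, max_gap) {
  n <- length(rank_a)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(sel) <= best) next
    o <- order(rank_a[sel])
    ra <- rank_a[sel][o]; rb <- rank_b[sel][o]
    for (dir in c(1L, -1L)) {
      rbd <- rb * dir
      ok <- all(diff(ra) > 0) && all(diff(rbd) > 0) &&
        all(diff(ra) <= max_gap + 1L) && all(diff(rbd) <= max_gap + 1L)
      if (ok) { best <- length(sel); break }
    }
  }
  best
}

## expand an IUPAC consensus into all concrete words
bf_expand_iupac <- function(consensus) {
  map <- Biostrings::IUPAC_CODE_MAP
  sets <- lapply(strsplit(consensus, "")[[1]],
                 function(s) strsplit(map[[s]], "")[[1]])
  words <- ""
  for (s in sets) words <- as.vector(outer(words, s, paste0))
  words
}

## all match starts of a degenerate word in a sequence via expansion +
## fixed substring search, forward strand
bf_iupac_starts <- function(sequence, consensus) {
  words <- bf_expand_iupac(consensus)
  n <- nchar(sequence); w <- nchar(consensus)
  if (n < w) return(integer(0))
  subs <- substring(sequence, seq_len(n - w + 1L),
                    seq_len(n - w + 1L) + w - 1L)
  sort(which(subs %in% words))
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

## small calibrated profile + proteome used by several search tests
make_seed_profile <- function(seed = 42L)
  buildProfile(syntheticSeedAlignment(seed = seed))
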