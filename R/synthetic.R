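## Synthetic-data generators: every input the pipeline consumes, with a
## ground-truth table, so each stage is verifiable without downloads.

.SENSE_CODONS <- NULL

.sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

.stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == "*"]
}

#' Synthetic seed domain alignment
#'
#' A small gapless alignment emulating a trihelix-like (Myb/SANT-type)
#' domain family: a random consensus with conserved tryptophans at regular
#' spacing, diverged per sequence at a fixed per-position substitution rate
#' (conserved anchor positions held fixed). Synthetic stand-in for a curated
#' seed alignment such as a Pfam family seed.
#'
#' @param n number of sequences (>= 2).
#' @param length alignment columns.
#' @param divergence per-position substitution probability off-consensus.
#' @param seed RNG seed.
#' @return named character vector of aligned sequences
#' @export
syntheticSeedAlignment <- function(n = 12L, length = 60L, divergence = 0.15,
                                   seed = 42L) {
  stopifnot(n >= 2L, length >= 10L)
  set.seed(seed)
  cons <- sample(.AA, length, replace = TRUE)
  anchors <- seq(5L, length, by = 15L)        # conserved W spacing
  cons[anchors] <- "W"
  out <- character(n)
  for (i in seq_len(n)) {
    s <- cons
    mut <- which(runif(length) < divergence)
    mut <- setdiff(mut, anchors)
    if (length(mut)) s[mut] <- sample(.AA, length(mut), replace = TRUE)
    out[i] <- paste(s, collapse = "")
  }
  names(out) <- sprintf("seed%02d", seq_len(n))
  out
}

## Sample one domain instance from a profile (emission probabilities or the
## consensus argmax). Optionally biased toward a subfamily variant.
.sample_domain <- function(profile, mode = c("emission", "consensus"),
                           variant = NULL, variant_noise = 0.05) {
  mode <- match.arg(mode)
  L <- profileLength(profile)
  if (!is.null(variant)) {
    s <- strsplit(variant, "")[[1]]
    mut <- which(runif(L) < variant_noise)
    if (length(mut)) s[mut] <- sample(profile@alphabet, length(mut),
                                      replace = TRUE)
    return(paste(s, collapse = ""))
  }
  if (mode == "consensus") return(profileConsensus(profile))
  probs <- profile@background * 2^t(profile@emissions)   # A x L
  probs <- sweep(probs, 2L, colSums(probs), "/")
  paste(vapply(seq_len(L), function(j)
    sample(profile@alphabet, 1L, prob = probs[, j]), ""), collapse = "")
}

## Diverged subfamily consensus sequences derived from a profile consensus.
.subfamily_variants <- function(profile, k, divergence = 0.35) {
  cons <- strsplit(profileConsensus(profile), "")[[1]]
  vapply(seq_len(k), function(i) {
    s <- cons
    mut <- which(runif(length(s)) < divergence)
    if (length(mut)) s[mut] <- sample(profile@alphabet, length(mut),
                                      replace = TRUE)
    paste(s, collapse = "")
  }, "")
}

#' Generate a synthetic proteome with implanted domains
#'
#' Family proteins carry one domain instance sampled from the profile,
#' embedded in i.i.d. background residues; decoys are pure background.
#' With \code{subfamilies > 1}, family members are drawn around diverged
#' subfamily consensus sequences (truth records the subfamily), which gives
#' the downstream phylogeny a recoverable clade structure.
#'
#' @param spec a \code{\link{familyGenomeSpec}}.
#' @param profile seed \code{ProfileModel} to sample domains from.
#' @param subfamilies number of subfamily variants (1 = none).
#' @param lengthRange protein length range (aa).
#' @param sampleMode \code{"emission"} (sample per-position emission
#'   probabilities) or \code{"consensus"} (implant the profile consensus).
#' @return list with \code{proteome} (\code{AAStringSet}) and \code{truth}
#'   (data.frame: gene_id, is_family, subfamily, domain_start, domain_end).
#' @export
generateProteome <- function(spec, profile, subfamilies = 1L,
                             lengthRange = c(200L, 400L),
                             sampleMode = c("emission", "consensus")) {
  stopifnot(is(spec, "FamilyGenomeSpec"), is(profile, "ProfileModel"))
  validObject(spec)
  sampleMode <- match.arg(sampleMode)
  set.seed(spec@seed)
  n_fam <- spec@nFamily; n_dec <- spec@nDecoy
  variants <- if (subfamilies > 1L && n_fam > 0L)
    .subfamily_variants(profile, subfamilies) else NULL

  ids <- c(if (n_fam) sprintf("FAM%03d", seq_len(n_fam)),
           if (n_dec) sprintf("DEC%03d", seq_len(n_dec)))
  seqs <- character(n_fam + n_dec)
  truth <- data.frame(gene_id = ids, is_family = rep(c(TRUE, FALSE),
                                                     c(n_fam, n_dec)),
                      subfamily = NA_character_,
                      domain_start = NA_integer_, domain_end = NA_integer_,
                      stringsAsFactors = FALSE)
  L <- profileLength(profile)
  for (i in seq_len(n_fam)) {
    sub <- if (!is.null(variants)) ((i - 1L) %% subfamilies) + 1L else NA
    dom <- .sample_domain(profile, mode = sampleMode,
                          variant = if (!is.null(variants)) variants[sub])
    plen <- sample(lengthRange[1]:lengthRange[2], 1L)
    pos <- sample.int(plen - L + 1L, 1L)
    bg <- sample(.AA, plen, replace = TRUE)
    s <- c(bg[seq_len(pos - 1L)], strsplit(dom, "")[[1]],
           bg[seq_len(plen - L - pos + 1L) + pos + L - 1L])
    seqs[i] <- paste(s, collapse = "")
    truth$subfamily[i] <- if (!is.na(sub)) paste0("SF", sub) else NA_character_
    truth$domain_start[i] <- pos
    truth$domain_end[i] <- pos + L - 1L
  }
  for (i in seq_len(n_dec)) {
    plen <- sample(lengthRange[1]:lengthRange[2], 1L)
    seqs[n_fam + i] <- paste(sample(.AA, plen, replace = TRUE), collapse = "")
  }
  proteome <- Biostrings::AAStringSet(setNames(seqs, ids))
  list(proteome = proteome, truth = truth)
}

## reverse-translate a protein into a CDS (uniform synonymous codon choice),
## appending one stop codon
.reverse_translate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(a) {
    cand <- names(gc)[gc == a]
    cand[sample.int(length(cand), 1L)]
  }, "")
  paste0(paste(codons, collapse = ""),
         sample(.stop_codons(), 1L))
}

## point-mutate a CDS at per-site probability p, rejecting internal stops
.mutate_cds <- function(cds, p) {
  if (p <= 0) return(cds)
  s <- strsplit(cds, "")[[1]]
  n <- length(s)
  sites <- which(runif(n) < p)
  stops <- .stop_codons()
  for (i in sites) {
    old <- s[i]
    for (try in 1:4) {
      new <- sample(setdiff(.DNA, old), 1L)
      cod_idx <- ((i - 1L) %/% 3L) * 3L
      codon <- s[(cod_idx + 1L):(cod_idx + 3L)]
      codon[i - cod_idx] <- new
      internal <- cod_idx + 3L < n
      if (!internal || !(paste(codon, collapse = "") %in% stops)) {
        s[i] <- new
        break
      }
    }
  }
  paste(s, collapse = "")
}

.revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Generate a synthetic genome with tandem and segmental duplications
#'
#' Builds per-chromosome sequences in which each gene (family genes carrying
#' a domain-encoding CDS reverse-translated from the synthetic proteome) has
#' a 1-3 exon structure on a random strand. Tandem clusters place the stated
#' number of family genes within the stated span on one chromosome;
#' segmental blocks copy an ordered run of genes onto another chromosome
#' with per-site CDS divergence. Coordinates are 1-based inclusive (GFF3).
#'
#' @param spec a \code{\link{familyGenomeSpec}}.
#' @param profile seed \code{ProfileModel} used for the proteome.
#' @param subfamilies subfamily variant count passed to
#'   \code{\link{generateProteome}}.
#' @param lengthRange protein length range (aa) for the encoded proteins.
#' @return list: \code{genome} (\code{DNAStringSet}), \code{annotation}
#'   (\code{GRanges} with gene/mRNA/exon/CDS features), \code{proteome}
#'   (\code{AAStringSet}), \code{cds} (\code{DNAStringSet}), \code{truth}
#'   (data.frame with chrom, start, end, strand, is_family,
#'   tandem_cluster_id, segmental_block_id, source_gene).
#' @export
generateDuplicatedGenome <- function(spec, profile, subfamilies = 1L,
                                     lengthRange = c(200L, 400L)) {
  stopifnot(is(spec, "FamilyGenomeSpec"))
  validObject(spec)
  prot <- generateProteome(spec, profile, subfamilies = subfamilies,
                           lengthRange = lengthRange)
  truth0 <- prot$truth
  n <- nrow(truth0)
  if (n == 0L) stop("spec generates zero genes")

  ## per-gene structure: CDS (from protein for all genes), exons, introns
  genes <- vector("list", n)
  for (i in seq_len(n)) {
    cds <- .reverse_translate(as.character(prot$proteome[[i]]))
    n_ex <- sample(1:3, 1L)
    len <- nchar(cds)
    cuts <- if (n_ex > 1L) sort(sample(seq(10L, len - 10L), n_ex - 1L)) else integer(0)
    bounds <- c(0L, cuts, len)
    exon_len <- diff(bounds)
    intron_len <- if (n_ex > 1L) sample(60:200, n_ex - 1L, replace = TRUE) else integer(0)
    genes[[i]] <- list(id = truth0$gene_id[i], cds = cds,
                       exon_len = exon_len, intron_len = intron_len,
                       strand = sample(c("+", "-"), 1L),
                       footprint = sum(exon_len) + sum(intron_len))
  }

  ## chromosome assignment: tandem-cluster genes (family) first, rest spread
  chrom_of <- integer(n)
  tandem_id <- rep(NA_integer_, n)
  fam_idx <- which(truth0$is_family)
  pool <- seq_len(n)
  tc <- spec@tandemClusters
  cluster_members <- list()
  if (nrow(tc)) {
    for (k in seq_len(nrow(tc))) {
      take <- head(intersect(pool, fam_idx), tc$size[k])
      if (length(take) < tc$size[k])
        stop("not enough family genes for tandem cluster ", k)
      chrom_of[take] <- tc$chrom[k]
      tandem_id[take] <- k
      cluster_members[[k]] <- take
      pool <- setdiff(pool, take)
    }
  }
  chrom_of[pool] <- rep(seq_len(spec@nChromosomes), length.out = length(pool))

  ## ordered gene lists per chromosome: clusters kept contiguous
  order_on <- vector("list", spec@nChromosomes)
  for (cc in seq_len(spec@nChromosomes)) {
    loose <- setdiff(which(chrom_of == cc), unlist(cluster_members))
    members <- loose
    if (nrow(tc)) for (k in which(tc$chrom == cc)) {
      at <- if (length(members)) sample(0:length(members), 1L) else 0L
      members <- append(members, cluster_members[[k]], after = at)
    }
    order_on[[cc]] <- members
  }

  ## segmental blocks: duplicate a run of genes onto another chromosome
  sb <- spec@segmentalBlocks
  seg_id <- rep(NA_integer_, n)
  dup_entries <- list()
  if (nrow(sb)) {
    for (b in seq_len(nrow(sb))) {
      src_chr <- ((b - 1L) %% spec@nChromosomes) + 1L
      tgt_chr <- (b %% spec@nChromosomes) + 1L
      src_genes <- order_on[[src_chr]]
      free <- src_genes[is.na(seg_id[src_genes]) & is.na(tandem_id[src_genes])]
      if (length(free) < sb$anchors[b])
        stop("not enough genes on chromosome ", src_chr,
             " for segmental block ", b)
      ## take a contiguous run (in chromosome order) of free genes
      run <- free[seq_len(sb$anchors[b])]
      seg_id[run] <- b
      for (g in run) {
        src <- genes[[g]]
        dup <- src
        dup$id <- paste0(src$id, "d")
        dup$cds <- .mutate_cds(src$cds, sb$divergence[b])
        dup_entries[[length(dup_entries) + 1L]] <-
          list(gene = dup, chrom = tgt_chr, block = b, source = src$id,
               src_index = g)
      }
    }
  }

  ## append duplicates to their target chromosomes (in run order)
  genes_all <- genes
  truth <- truth0
  truth$tandem_cluster_id <- tandem_id
  truth$segmental_block_id <- seg_id
  truth$source_gene <- NA_character_
  for (d in dup_entries) {
    genes_all[[length(genes_all) + 1L]] <- d$gene
    idx <- length(genes_all)
    order_on[[d$chrom]] <- c(order_on[[d$chrom]], idx)
    src_row <- truth0[d$src_index, ]
    truth <- rbind(truth, data.frame(
      gene_id = d$gene$id, is_family = src_row$is_family,
      subfamily = src_row$subfamily, domain_start = src_row$domain_start,
      domain_end = src_row$domain_end, tandem_cluster_id = NA_integer_,
      segmental_block_id = d$block, source_gene = d$source,
      stringsAsFactors = FALSE))
  }
  m <- length(genes_all)
  truth$chrom <- NA_character_; truth$start <- NA_integer_
  truth$end <- NA_integer_; truth$strand <- NA_character_

  ## assemble chromosomes and per-gene coordinates
  chrom_seqs <- character(spec@nChromosomes)
  feat <- list()
  for (cc in seq_len(spec@nChromosomes)) {
    parts <- character(0)
    cursor <- 0L
    lead <- 2500L                    # room for full-length promoters
    members <- order_on[[cc]]
    k_in_cluster <- NA_integer_
    for (gi in seq_along(members)) {
      g <- genes_all[[members[gi]]]
      tid <- if (members[gi] <= n) tandem_id[members[gi]] else NA_integer_
      prev <- if (gi > 1L && members[gi - 1L] <= n)
        tandem_id[members[gi - 1L]] else NA_integer_
      gap <- if (!is.na(tid) && !is.na(prev) && tid == prev) {
        ## inside a tandem cluster: keep starts within the stated span
        cl <- cluster_members[[tid]]
        foot <- sum(vapply(genes_all[cl], function(x) x$footprint, 0)) +
          200L * (length(cl) - 1L)
        if (spec@tandemClusters$span[tid] <= foot)
          stop("span smaller than minimal gene footprint in tandem cluster ",
               tid)
        avail <- floor((spec@tandemClusters$span[tid] - foot) /
                         (length(cl) - 1L))
        200L + sample.int(max(avail, 1L), 1L)
      } else sample(250000:500000, 1L)   # beyond the 200-kb tandem window
      lead_gap <- if (gi == 1L) lead else gap
      parts <- c(parts, paste(sample(.DNA, lead_gap, replace = TRUE),
                              collapse = ""))
      cursor <- cursor + lead_gap
      gstart <- cursor + 1L

      ## transcript-orientation gene sequence: exon1 intron1 exon2 ...
      cds <- g$cds
      off <- cumsum(c(0L, g$exon_len))
      exon_seq <- substring(cds, off[-length(off)] + 1L, off[-1L])
      pieces <- character(0)
      intr <- vapply(seq_along(g$intron_len), function(j)
        paste(sample(.DNA, g$intron_len[j], replace = TRUE), collapse = ""),
        "")
      for (e in seq_along(exon_seq)) {
        pieces <- c(pieces, exon_seq[e])
        if (e <= length(intr)) pieces <- c(pieces, intr[e])
      }
      gseq <- paste(pieces, collapse = "")
      glen <- nchar(gseq)
      gend <- gstart + glen - 1L

      ## exon genomic intervals
      piece_len <- nchar(pieces)
      ends_t <- cumsum(piece_len)
      starts_t <- ends_t - piece_len + 1L
      is_exon <- rep(c(TRUE, FALSE), length.out = length(pieces))
      ## GFF3 CDS phase per exon, in transcript order
      prior <- c(0L, cumsum(g$exon_len))[seq_along(g$exon_len)]
      ph_tr <- (3L - (prior %% 3L)) %% 3L
      if (g$strand == "+") {
        ex_start <- gstart + starts_t[is_exon] - 1L
        ex_end <- gstart + ends_t[is_exon] - 1L
        ph_gen <- ph_tr
        chrom_piece <- gseq
      } else {
        ex_start <- gend - ends_t[is_exon] + 1L
        ex_end <- gend - starts_t[is_exon] + 1L
        o <- order(ex_start)
        ex_start <- ex_start[o]; ex_end <- ex_end[o]
        ph_gen <- rev(ph_tr)
        chrom_piece <- .revcomp_chr(gseq)
      }
      parts <- c(parts, chrom_piece)
      cursor <- cursor + glen

      ti <- match(g$id, truth$gene_id)
      truth$chrom[ti] <- paste0("Chr", cc)
      truth$start[ti] <- gstart; truth$end[ti] <- gend
      truth$strand[ti] <- g$strand
      feat[[length(feat) + 1L]] <- data.frame(
        chrom = paste0("Chr", cc), start = c(gstart, gstart, ex_start, ex_start),
        end = c(gend, gend, ex_end, ex_end),
        strand = g$strand,
        type = c("gene", "mRNA", rep("exon", length(ex_start)),
                 rep("CDS", length(ex_start))),
        ID = c(g$id, paste0(g$id, ".1"),
               paste0(g$id, ".1.exon", seq_along(ex_start)),
               paste0(g$id, ".1.cds", seq_along(ex_start))),
        Parent = c(NA, g$id, rep(paste0(g$id, ".1"), 2L * length(ex_start))),
        phase = c(NA, NA, rep(NA_integer_, length(ex_start)), ph_gen),
        stringsAsFactors = FALSE)
    }
    parts <- c(parts, paste(sample(.DNA, 1000L, replace = TRUE), collapse = ""))
    chrom_seqs[cc] <- paste(parts, collapse = "")
  }

  fdf <- do.call(rbind, feat)
  gr <- GenomicRanges::GRanges(
    seqnames = fdf$chrom,
    ranges = IRanges::IRanges(fdf$start, fdf$end),
    strand = fdf$strand)
  S4Vectors::mcols(gr)$type <- fdf$type
  S4Vectors::mcols(gr)$ID <- fdf$ID
  S4Vectors::mcols(gr)$Parent <- fdf$Parent
  S4Vectors::mcols(gr)$phase <- as.integer(fdf$phase)

  proteome_all <- Biostrings::AAStringSet(setNames(
    vapply(genes_all, function(g) {
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(g$cds), if.fuzzy.codon = "solve"))
      sub("\\*$", "", aa)
    }, ""),
    vapply(genes_all, `[[`, "", "id")))

  cds_all <- Biostrings::DNAStringSet(setNames(
    vapply(genes_all, `[[`, "", "cds"),
    vapply(genes_all, `[[`, "", "id")))

  list(genome = Biostrings::DNAStringSet(
         setNames(chrom_seqs, paste0("Chr", seq_len(spec@nChromosomes)))),
       annotation = gr, proteome = proteome_all, cds = cds_all,
       truth = truth)
}

#' Evolve a pair of coding sequences under a codon model with selection
#'
#' A random sense-codon ancestor is evolved along two lineages: point
#' mutations are proposed (site uniform, transition:transversion bias
#' \code{kappa}), mutations creating stop codons are rejected, and
#' nonsynonymous changes are accepted with relative probability
#' \code{omega} (synonymous changes always accepted). \code{branchLength}
#' is the expected number of proposed mutations per codon separating the
#' two sequences.
#'
#' @param nCodons number of codons (>= 30).
#' @param omega dN/dS acceptance ratio (>= 0).
#' @param kappa transition/transversion rate ratio.
#' @param branchLength expected proposals per codon between the sequences.
#' @param seed RNG seed.
#' @return list(cds_a, cds_b, true_omega)
#' @export
evolveCodonPair <- function(nCodons, omega, kappa = 2, branchLength = 0.6,
                            seed = 1L) {
  if (nCodons < 30L) stop("nCodons must be >= 30")
  if (omega < 0) stop("omega must be >= 0")
  if (branchLength < 0) stop("branchLength must be >= 0")
  set.seed(seed)
  sense <- .sense_codons()
  stops <- .stop_codons()
  gc <- Biostrings::GENETIC_CODE
  anc <- sample(sense, nCodons, replace = TRUE)
  transition <- c(A = "G", G = "A", C = "T", T = "C")

  evolve <- function(codons, n_prop) {
    for (e in seq_len(n_prop)) {
      ci <- sample.int(length(codons), 1L)
      pos <- sample.int(3L, 1L)
      old_codon <- strsplit(codons[ci], "")[[1]]
      base <- old_codon[pos]
      others <- setdiff(.DNA, base)
      w <- ifelse(others == transition[[base]], kappa, 1)
      new_base <- sample(others, 1L, prob = w)
      new_codon <- old_codon; new_codon[pos] <- new_base
      nc <- paste(new_codon, collapse = "")
      if (nc %in% stops) next
      if (gc[[nc]] != gc[[codons[ci]]] && runif(1) >= omega) next
      codons[ci] <- nc
    }
    codons
  }
  half <- branchLength * nCodons / 2
  a <- evolve(anc, rpois(1L, half))
  b <- evolve(anc, rpois(1L, half))
  list(cds_a = paste(a, collapse = ""), cds_b = paste(b, collapse = ""),
       true_omega = omega)
}

#' Generate promoters with implanted IUPAC cis-elements
#'
#' Each promoter is \code{length} nt of i.i.d. background; for every
#' element, a carrier subset of promoters (per-element fraction) receives
#' one concrete instantiation of the IUPAC consensus at a random recorded
#' position, on the reverse strand with probability 0.5 when
#' \code{bothStrands} is TRUE.
#'
#' @param n number of promoters.
#' @param elements named character vector, element id -> IUPAC consensus.
#' @param fractions named numeric carrier fractions (default 1 for all).
#' @param length promoter length in nt (default 1500, the upstream window).
#' @param bothStrands allow reverse-strand implants.
#' @param seed RNG seed.
#' @return list: \code{promoters} (\code{DNAStringSet}), \code{truth}
#'   (data.frame: promoter_id, element_id, start, strand, instance).
#' @export
generatePromoters <- function(n, elements, fractions = NULL, length = 1500L,
                              bothStrands = TRUE, seed = 1L) {
  iupac <- Biostrings::IUPAC_CODE_MAP
  if (n == 0L)
    return(list(promoters = Biostrings::DNAStringSet(),
                truth = data.frame(promoter_id = character(0),
                                   element_id = character(0),
                                   start = integer(0), strand = character(0),
                                   instance = character(0))))
  for (e in elements) {
    if (!all(strsplit(e, "")[[1]] %in% names(iupac)))
      stop("invalid IUPAC consensus: ", e)
    if (nchar(e) > length) stop("element longer than promoter: ", e)
  }
  if (is.null(fractions)) fractions <- setNames(rep(1, length(elements)),
                                                names(elements))
  set.seed(seed)
  ids <- sprintf("PRO%03d", seq_len(n))
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(.DNA, length, replace = TRUE), collapse = ""), "")
  truth <- list()
  for (eid in names(elements)) {
    pat <- strsplit(elements[[eid]], "")[[1]]
    carriers <- which(runif(n) <= fractions[[eid]])
    for (i in carriers) {
      inst <- paste(vapply(pat, function(sym) {
        opts <- strsplit(iupac[[sym]], "")[[1]]
        opts[sample.int(length(opts), 1L)]
      }, ""), collapse = "")
      strand <- if (bothStrands && runif(1) < 0.5) "-" else "+"
      placed <- if (strand == "-") .revcomp_chr(inst) else inst
      pos <- sample.int(length - nchar(inst) + 1L, 1L)
      substr(seqs[i], pos, pos + nchar(inst) - 1L) <- placed
      truth[[length(truth) + 1L]] <- data.frame(
        promoter_id = ids[i], element_id = eid, start = pos,
        strand = strand, instance = inst, stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(promoter_id = character(0), element_id = character(0),
               start = integer(0), strand = character(0),
               instance = character(0))
  list(promoters = Biostrings::DNAStringSet(setNames(seqs, ids)),
       truth = truth)
}

#' Generate a qPCR Ct table with known fold changes
#'
#' Reference-gene Ct is centred at 20 and the target's baseline offset at
#' +6 cycles; at each timepoint the noiseless target Ct is shifted by
#' \code{-true_log2_fc}, so the noiseless ddCt equals \code{-true_log2_fc}
#' and 2^-ddCt recovers the fold change. Gaussian noise with sd
#' \code{noiseSd} is added per well.
#'
#' @param trueLog2FC matrix (genes x timepoints) of true log2 fold changes
#'   relative to the first (baseline) timepoint; its dimnames name genes
#'   and timepoints. The baseline column must be zero.
#' @param replicates wells per gene x timepoint (>= 2).
#' @param noiseSd Gaussian well noise sd in Ct cycles (>= 0).
#' @param seed RNG seed.
#' @return data.frame (gene, condition, replicate, ct_target, ct_reference)
#' @export
generateCtTable <- function(trueLog2FC, replicates = 3L, noiseSd = 0.2,
                            seed = 1L) {
  if (replicates < 2L) stop("replicates must be >= 2")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (is.null(dimnames(trueLog2FC)))
    stop("trueLog2FC needs gene and timepoint dimnames")
  set.seed(seed)
  genes <- rownames(trueLog2FC); tps <- colnames(trueLog2FC)
  rows <- list()
  for (g in genes) for (t in tps) for (r in seq_len(replicates)) {
    ref <- 20 + rnorm(1L, 0, noiseSd)
    tgt <- 26 - trueLog2FC[g, t] + rnorm(1L, 0, noiseSd)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, condition = t, replicate = r,
      ct_target = tgt, ct_reference = ref, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate an expression matrix with group structure
#'
#' Genes belong to one of \code{nGroups} archetype profiles over the
#' conditions; values are archetype means plus Gaussian noise, emulating
#' Atlas-scale expression summaries with cluster structure.
#'
#' @param nGenes number of genes.
#' @param conditions condition names.
#' @param nGroups archetype count.
#' @param noiseSd within-group noise sd.
#' @param seed RNG seed.
#' @return list: \code{matrix} (genes x conditions), \code{truth}
#'   (data.frame gene, group).
#' @export
generateExpressionMatrix <- function(nGenes = 40L,
                                     conditions = c("root", "stem", "leaf",
                                                    "sheath"),
                                     nGroups = 5L, noiseSd = 0.3, seed = 1L) {
  set.seed(seed)
  arche <- matrix(runif(nGroups * length(conditions), 0, 8),
                  nGroups, length(conditions))
  grp <- rep(seq_len(nGroups), length.out = nGenes)
  ids <- sprintf("GENE%03d", seq_len(nGenes))
  m <- arche[grp, , drop = FALSE] +
    matrix(rnorm(nGenes * length(conditions), 0, noiseSd), nGenes)
  dimnames(m) <- list(ids, conditions)
  list(matrix = m, truth = data.frame(gene = ids, group = grp,
                                      stringsAsFactors = FALSE))
}

#' Write synthetic artifacts to standard formats
#'
#' FASTA wrapped at 60 columns, GFF3 via rtracklayer, TSV truth tables and
#' CSV Ct tables.
#'
#' @param x object to write (XStringSet, GRanges annotation or data.frame).
#' @param path output file.
#' @return invisibly, the path
#' @export
writeArtifact <- function(x, path) {
  if (is(x, "XStringSet")) {
    Biostrings::writeXStringSet(x, path, width = 60L)
  } else if (is(x, "GRanges")) {
    md <- S4Vectors::mcols(x)
    if (!is.null(md$Parent) && !methods::is(md$Parent, "CharacterList")) {
      p <- as.character(md$Parent)
      S4Vectors::mcols(x)$Parent <- IRanges::CharacterList(
        lapply(p, function(z) if (is.na(z)) character(0) else z))
    }
    rtracklayer::export(x, path, format = "gff3")
  } else if (is.data.frame(x)) {
    if (grepl("\\.csv$", path)) {
      utils::write.csv(x, path, row.names = FALSE)
    } else {
      write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else stop("unsupported artifact type: ", class(x)[1])
  invisible(path)
}
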