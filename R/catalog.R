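## Per-gene catalog: protein length, molecular weight, isoelectric point,
## exon counts, chromosomal distribution, transcript accounting.

## ExPASy-style average residue masses (Da) and the mass of water
.AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0513, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.0153

## Bjellqvist-style pKa values (ExPASy-compatible); sidechains with sign
.DEFAULT_PKA <- data.frame(
  group = c("Nterm", "Cterm", "D", "E", "C", "Y", "H", "K", "R"),
  pka = c(7.5, 3.55, 4.05, 4.45, 9.0, 10.0, 5.98, 10.0, 12.0),
  charge = c(1, -1, -1, -1, -1, -1, 1, 1, 1),
  stringsAsFactors = FALSE)

#' Protein length implied by an ORF length
#'
#' The ORF includes the stop codon, so the encoded protein has
#' \code{orf_nt / 3 - 1} residues.
#'
#' @param orf_nt ORF length(s) in nucleotides (divisible by 3, >= 6).
#' @return integer protein length(s) in amino acids
#' @examples
#' proteinLengthFromOrf(801)  # 266
#' @export
proteinLengthFromOrf <- function(orf_nt) {
  if (any(orf_nt %% 3 != 0))
    stop("ORF length not divisible by 3: annotation problem at ",
         paste(orf_nt[orf_nt %% 3 != 0], collapse = ", "))
  if (any(orf_nt < 6)) stop("ORF must be at least 6 nt (start + stop)")
  as.integer(orf_nt / 3 - 1)
}

#' Molecular weight of a protein (kDa)
#'
#' Sum of average residue masses plus one water, ExPASy convention.
#'
#' @param sequence protein sequence over the 20 standard residues.
#' @return molecular weight in kDa
#' @export
molecularWeight <- function(sequence) {
  s <- strsplit(toupper(as.character(sequence)), "")[[1]]
  if (!length(s)) stop("empty protein sequence")
  bad <- setdiff(unique(s), names(.AA_AVG_MASS))
  if (length(bad))
    stop("nonstandard residue(s): ", paste(bad, collapse = ", "))
  (sum(.AA_AVG_MASS[s]) + .WATER_MASS) / 1000
}

## net charge at a given pH for tallied ionizable groups
.net_charge <- function(pH, groups) {
  q <- ifelse(groups$charge > 0,
              groups$n / (1 + 10^(pH - groups$pka)),
              -groups$n / (1 + 10^(groups$pka - pH)))
  sum(q)
}

#' Isoelectric point by bisection
#'
#' Finds the pH where the Henderson-Hasselbalch net charge of the ionizable
#' sidechains (D, E, C, Y, H, K, R) plus the termini crosses zero, by
#' bisection on pH 0-14 to |Q| < 1e-4.
#'
#' @param sequence protein sequence.
#' @param pka_table data.frame (group, pka, charge) covering the ionizable
#'   sidechains and \code{Nterm}/\code{Cterm}; defaults to Bjellqvist-style
#'   values (also shipped as \code{extdata/pka_bjellqvist.tsv}).
#' @return pI in pH units
#' @export
isoelectricPoint <- function(sequence, pka_table = .DEFAULT_PKA) {
  s <- strsplit(toupper(as.character(sequence)), "")[[1]]
  if (!length(s)) stop("empty protein sequence")
  need <- c("Nterm", "Cterm", "D", "E", "C", "Y", "H", "K", "R")
  if (!all(need %in% pka_table$group))
    stop("pka_table must cover D,E,C,Y,H,K,R and both termini")
  counts <- table(factor(s, levels = pka_table$group))
  groups <- pka_table
  groups$n <- as.numeric(counts[groups$group])
  groups$n[groups$group %in% c("Nterm", "Cterm")] <- 1
  groups <- groups[groups$n > 0, ]
  lo <- 0; hi <- 14
  qlo <- .net_charge(lo, groups); qhi <- .net_charge(hi, groups)
  if (qlo < 0 || qhi > 0) stop("no isoelectric point in pH 0-14")
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    q <- .net_charge(mid, groups)
    if (abs(q) < 1e-4) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  stop("bisection did not converge")
}

#' Build a per-gene catalog from annotation and sequences
#'
#' Computes, per gene: chromosome, strand, exon count, ORF length, protein
#' length, molecular weight and isoelectric point; a localization column is
#' carried through from the supplied annotation (never predicted).
#'
#' @param annotation \code{GRanges} with gene/mRNA/exon/CDS features (as
#'   produced by \code{\link{generateDuplicatedGenome}} or imported GFF3).
#' @param genome \code{DNAStringSet} of chromosome sequences.
#' @param localization optional named character vector, gene id -> label.
#' @return data.frame catalog (one row per transcript)
#' @export
buildCatalog <- function(annotation, genome, localization = NULL) {
  md <- S4Vectors::mcols(annotation)
  parent <- if (methods::is(md$Parent, "CharacterList"))
    vapply(md$Parent, function(p) if (length(p)) p[1] else NA_character_, "")
  else as.character(md$Parent)
  mrna <- which(md$type == "mRNA")
  rows <- list()
  for (i in mrna) {
    tid <- md$ID[i]; gid <- parent[i]
    cds_idx <- which(md$type == "CDS" & parent == tid)
    cds_gr <- annotation[cds_idx]
    o <- order(GenomicRanges::start(cds_gr))
    cds_gr <- cds_gr[o]
    chrom <- as.character(GenomicRanges::seqnames(annotation[i]))
    strand <- as.character(GenomicRanges::strand(annotation[i]))
    segs <- vapply(seq_along(cds_gr), function(k)
      as.character(Biostrings::subseq(genome[[chrom]],
                                      GenomicRanges::start(cds_gr)[k],
                                      GenomicRanges::end(cds_gr)[k])), "")
    cds <- paste(segs, collapse = "")
    if (strand == "-") cds <- .revcomp_chr(cds)
    prot <- sub("\\*$", "", as.character(Biostrings::translate(
      Biostrings::DNAString(cds), if.fuzzy.codon = "solve")))
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gid, transcript_id = tid, chrom = chrom, strand = strand,
      orf_bp = nchar(cds), exon_n = length(cds_idx),
      length_aa = nchar(prot), mw_kda = molecularWeight(prot),
      pi = isoelectricPoint(prot),
      localization = if (!is.null(localization)) localization[[gid]]
                     else NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a catalog table (TSV)
#'
#' Reads a pre-built Table-1-style catalog with columns including gene,
#' chromosome, ORF length, exon count, protein length, MW, pI and
#' localization. Column names are normalized to the internal convention.
#'
#' @param path TSV path.
#' @return data.frame catalog
#' @export
readCatalogTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  map <- c("Gene Name" = "gene_id", "Gene Locus" = "locus", "Chr" = "chrom",
           "ORF (bp)" = "orf_bp", "Exon No." = "exon_n",
           "Length (aa)" = "length_aa", "MW (kD)" = "mw_kda", "pI" = "pi",
           "Localization" = "localization")
  hit <- names(df) %in% names(map)
  names(df)[hit] <- map[names(df)[hit]]
  df
}

#' Summary statistics over a gene catalog
#'
#' Per-chromosome gene counts, localization counts, ranges of protein
#' length, molecular weight, isoelectric point and exon count, plus gene
#' and transcript totals.
#'
#' @param catalog data.frame from \code{\link{buildCatalog}} or
#'   \code{\link{readCatalogTable}}.
#' @param isoforms optional named integer vector, gene id -> isoform count
#'   (defaults to 1 per catalog row for rows sharing a gene id).
#' @return list of summaries
#' @export
summarizeCatalog <- function(catalog, isoforms = NULL) {
  if (!nrow(catalog))
    return(list(n_genes = 0L, n_transcripts = 0L,
                per_chromosome = table(character(0)),
                localization = table(character(0)),
                length_aa = c(NA_real_, NA_real_), mw_kda = c(NA, NA),
                pi = c(NA, NA), exon_n = c(NA, NA)))
  genes <- unique(catalog$gene_id)
  n_tr <- if (!is.null(isoforms)) {
    sum(vapply(genes, function(g)
      if (g %in% names(isoforms)) isoforms[[g]] else 1L, 1L))
  } else nrow(catalog)
  per_gene <- catalog[!duplicated(catalog$gene_id), , drop = FALSE]
  list(
    n_genes = length(genes),
    n_transcripts = as.integer(n_tr),
    per_chromosome = table(per_gene$chrom),
    localization = table(per_gene$localization),
    length_aa = range(catalog$length_aa),
    mw_kda = range(catalog$mw_kda),
    pi = range(catalog$pi),
    exon_n = range(catalog$exon_n))
}
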