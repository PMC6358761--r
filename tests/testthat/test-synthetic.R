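test_that("proteome generation honours spec counts, truth and determinism", {
  pm <- make_seed_profile()

  empty_fam <- generateProteome(familyGenomeSpec(nFamily = 0, nDecoy = 5,
                                                 seed = 1), pm)
  expect_length(empty_fam$proteome, 5L)
  expect_false(any(empty_fam$truth$is_family))

  spec <- familyGenomeSpec(nFamily = 6, nDecoy = 4, seed = 9)
  a <- generateProteome(spec, pm)
  b <- generateProteome(spec, pm)
  expect_identical(as.character(a$proteome), as.character(b$proteome))
  expect_identical(a$truth, b$truth)

  cons <- generateProteome(spec, pm, sampleMode = "consensus")
  for (i in which(cons$truth$is_family))
    expect_true(grepl(profileConsensus(pm),
                      as.character(cons$proteome[[i]]), fixed = TRUE))
  ## recorded domain coordinates point at the implant
  i <- which(cons$truth$is_family)[1]
  expect_identical(substr(as.character(cons$proteome[[i]]),
                          cons$truth$domain_start[i],
                          cons$truth$domain_end[i]),
                   profileConsensus(pm))
})

test_that("spec validation names the offending field", {
  expect_error(familyGenomeSpec(nFamily = -1), "nFamily")
  expect_error(familyGenomeSpec(tandemClusters = data.frame(
    chrom = 1, size = 2, span = -5)), "span")
  expect_error(familyGenomeSpec(segmentalBlocks = data.frame(
    anchors = 4, divergence = 1.5)), "divergence")
})

test_that("duplicated genome implants tandem clusters and ordered blocks", {
  pm <- make_seed_profile()
  spec <- familyGenomeSpec(
    nFamily = 8, nDecoy = 10, nChromosomes = 2,
    tandemClusters = data.frame(chrom = 1, size = 2, span = 150000),
    segmentalBlocks = data.frame(anchors = 6, divergence = 0),
    seed = 21)
  sim <- generateDuplicatedGenome(spec, pm)
  tr <- sim$truth

  cl <- tr[!is.na(tr$tandem_cluster_id), ]
  expect_identical(nrow(cl), 2L)
  expect_identical(unique(cl$chrom), "Chr1")
  expect_lt(diff(range(cl$start)), 150000)

  ## divergence 0: duplicated CDS identical to source
  dups <- tr[!is.na(tr$source_gene), ]
  expect_identical(nrow(dups), 6L)
  for (i in seq_len(nrow(dups)))
    expect_identical(as.character(sim$cds[[dups$gene_id[i]]]),
                     as.character(sim$cds[[dups$source_gene[i]]]))

  ## block copies preserve rank order on the target chromosome
  src <- tr[tr$gene_id %in% dups$source_gene, ]
  src <- src[order(src$start), ]
  copies <- dups[match(src$gene_id, dups$source_gene), ]
  expect_false(is.unsorted(copies$start))

  ## genome/annotation round trip: CDS re-extracted from the genome
  ## translates to the recorded proteome
  cat <- buildCatalog(sim$annotation, sim$genome)
  w <- Biostrings::width(sim$proteome)[match(cat$gene_id,
                                             names(sim$proteome))]
  expect_identical(cat$length_aa, as.integer(w))

  ## too-small tandem span is rejected
  bad <- familyGenomeSpec(
    nFamily = 4, nDecoy = 2,
    tandemClusters = data.frame(chrom = 1, size = 2, span = 500),
    seed = 3)
  expect_error(generateDuplicatedGenome(bad, pm), "footprint")
})

test_that("codon pair evolution respects omega and branch length", {
  p0 <- evolveCodonPair(40, omega = 0.5, branchLength = 0, seed = 4)
  expect_identical(p0$cds_a, p0$cds_b)

  ## omega = 0: every fixed difference is synonymous
  p <- evolveCodonPair(100, omega = 0, branchLength = 1, seed = 5)
  expect_false(identical(p$cds_a, p$cds_b))
  r <- kaksNG86(p$cds_a, p$cds_b)
  expect_identical(r$nd_diff, 0)
  expect_gt(r$sd_diff, 0)

  expect_error(evolveCodonPair(10, omega = 0.5), "nCodons")
  expect_error(evolveCodonPair(40, omega = -1), "omega")
})

test_that("promoter generation implants elements at recorded positions", {
  g0 <- generatePromoters(0, c(E = "GATA"))
  expect_length(g0$promoters, 0L)
  expect_identical(nrow(g0$truth), 0L)

  expect_error(generatePromoters(2, c(E = "GAXA")), "IUPAC")
  expect_error(generatePromoters(2, c(E = "GATA"), length = 3), "longer")

  g <- generatePromoters(6, c(E1 = "GRWAAW", E2 = "ACGT"), seed = 11)
  expect_true(all(Biostrings::width(g$promoters) == 1500L))
  for (i in seq_len(nrow(g$truth))) {
    row <- g$truth[i, ]
    s <- as.character(g$promoters[[row$promoter_id]])
    placed <- substr(s, row$start, row$start + nchar(row$instance) - 1L)
    expected <- if (row$strand == "-") revcomp(row$instance) else row$instance
    expect_identical(placed, expected)
    ## a brute-force scanner finds a hit at the recorded position
    strand_seq <- if (row$strand == "-") revcomp(s) else s
    eid <- row$element_id
    cons <- c(E1 = "GRWAAW", E2 = "ACGT")[[eid]]
    hits_fwd <- bf_iupac_starts(s, cons)
    hits_rev <- bf_iupac_starts(revcomp(s), cons)
    hits_rev_fwdcoord <- nchar(s) - hits_rev - nchar(cons) + 2L
    expect_true(row$start %in% c(hits_fwd, hits_rev_fwdcoord))
  }
})

test_that("Ct table generation encodes the stated fold changes", {
  expect_error(generateCtTable(matrix(0, 1, 1,
                                      dimnames = list("g", "t0")),
                               replicates = 1), "replicates")
  lfc <- matrix(c(0, 2), 1, 2, dimnames = list("g1", c("t0", "t24")))
  ct <- generateCtTable(lfc, noiseSd = 0, seed = 2)
  fc <- ddctFoldChange(ct, "t0")
  expect_equal(fc$fold_change[fc$condition == "t24"], 4)
  expect_equal(fc$fold_change[fc$condition == "t0"], 1)
})

test_that("artifacts are written in standard formats and round-trip", {
  pm <- make_seed_profile()
  spec <- familyGenomeSpec(nFamily = 3, nDecoy = 3, nChromosomes = 1,
                           seed = 13)
  sim <- generateDuplicatedGenome(spec, pm)
  dir <- withr::local_tempdir()

  fa <- file.path(dir, "prot.fa")
  writeArtifact(sim$proteome, fa)
  back <- Biostrings::readAAStringSet(fa)
  expect_identical(as.character(back), as.character(sim$proteome))

  gff <- file.path(dir, "ann.gff3")
  writeArtifact(sim$annotation, gff)
  back_gr <- rtracklayer::import(gff)
  genes_in <- sim$annotation[S4Vectors::mcols(sim$annotation)$type == "gene"]
  genes_out <- back_gr[S4Vectors::mcols(back_gr)$type == "gene"]
  expect_identical(sort(GenomicRanges::start(genes_out)),
                   sort(GenomicRanges::start(genes_in)))

  tsv <- file.path(dir, "truth.tsv")
  writeArtifact(sim$truth, tsv)
  expect_identical(read.delim(tsv, stringsAsFactors = FALSE)$gene_id,
                   sim$truth$gene_id)
})
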