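test_that("tandem detection matches the all-pairs definition", {
  two <- data.frame(gene_id = c("a", "b"), chrom = "Chr1",
                    start = c(1e5, 2.5e5))
  expect_identical(nrow(findTandemEvents(two)), 1L)
  two$start <- c(1e5, 3.6e5)
  expect_identical(nrow(findTandemEvents(two)), 0L)

  set.seed(99)
  for (rep in 1:100) {
    n <- sample(3:12, 1)
    loci <- data.frame(
      gene_id = paste0("g", seq_len(n)),
      chrom = paste0("Chr", sample(1:3, n, replace = TRUE)),
      start = sample.int(2e6, n))
    got <- findTandemEvents(loci, window = 2e5)
    got_keys <- sort(paste(got$gene_a, got$gene_b, sep = "|"))
    expect_identical(got_keys, bf_tandem_events(loci, 2e5))
  }
})

test_that("anchor search finds duplicates and rejects unrelated proteins", {
  ## hand-checked optimum: identical ungapped peptides score the BLOSUM62
  ## diagonal sum
  pep <- "MKVLWAAL"
  a <- findAnchorPairs(setNames(c(pep, pep), c("x", "y")),
                       scoreThreshold = 1)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  diag_sum <- sum(B62[cbind(strsplit(pep, "")[[1]], strsplit(pep, "")[[1]])])
  expect_identical(nrow(a), 1L)
  expect_equal(a$score, diag_sum)

  ## duplicated genome: every duplicate's best non-self match is its copy
  pm <- make_seed_profile()
  spec <- familyGenomeSpec(nFamily = 5, nDecoy = 5, nChromosomes = 2,
                           segmentalBlocks = data.frame(anchors = 4,
                                                        divergence = 0.05),
                           seed = 23)
  sim <- generateDuplicatedGenome(spec, pm)
  anchors <- findAnchorPairs(sim$proteome, topK = 1,
                             scoreThreshold = 100, minCoverage = 0.5,
                             minIdentity = 0.6)
  dups <- sim$truth[!is.na(sim$truth$source_gene), ]
  key <- paste(pmin(anchors$gene_a, anchors$gene_b),
               pmax(anchors$gene_a, anchors$gene_b))
  for (i in seq_len(nrow(dups)))
    expect_true(paste(pmin(dups$source_gene[i], dups$gene_id[i]),
                      pmax(dups$source_gene[i], dups$gene_id[i])) %in% key)

  ## unrelated random proteins score below the threshold in the median
  set.seed(31)
  null_scores <- vapply(1:50, function(i) {
    p <- Biostrings::AAStringSet(setNames(
      c(paste(sample(trihelixr:::.AA, 100, replace = TRUE), collapse = ""),
        paste(sample(trihelixr:::.AA, 100, replace = TRUE), collapse = "")),
      c("u", "v")))
    r <- findAnchorPairs(p, scoreThreshold = -Inf)
    r$score[1]
  }, 0)
  expect_lt(median(null_scores), 60)
})

test_that("collinear chaining equals the exhaustive longest chain", {
  mk <- function(ra, rb) data.frame(
    gene_a = paste0("a", seq_along(ra)), gene_b = paste0("b", seq_along(ra)),
    chrom_a = "Chr1", chrom_b = "Chr2", rank_a = ra, rank_b = rb)

  ## a preserved 6-anchor run is one block containing all six
  b <- chainCollinearBlocks(mk(1:6, 11:16))
  expect_identical(nrow(b), 6L)
  expect_identical(unique(b$block_id), 1L)
  expect_identical(unique(b$orientation), "same")

  ## scrambled order with no monotone run of length 5 gives nothing
  b0 <- chainCollinearBlocks(mk(1:6, c(4, 1, 5, 2, 6, 3)))
  expect_identical(nrow(b0), 0L)

  ## an inverted run is reported and flagged
  bi <- chainCollinearBlocks(mk(1:6, 16:11))
  expect_identical(unique(bi$orientation), "inverted")
  expect_identical(nrow(bi), 6L)

  ## rank gaps above the limit break the chain
  bg <- chainCollinearBlocks(mk(c(1:4, 40), c(1:4, 40)), minAnchors = 5)
  expect_identical(nrow(bg), 0L)

  set.seed(47)
  for (rep in 1:30) {
    n <- sample(4:10, 1)
    ra <- sample.int(30, n); rb <- sample.int(30, n)
    got <- chainCollinearBlocks(mk(ra, rb), minAnchors = 2, maxGap = 25)
    got_best <- if (nrow(got)) max(table(got$block_id)) else 0L
    expect_identical(as.integer(got_best),
                     as.integer(max(bf_longest_chain(ra, rb, 25), 0L)))
  }
})

test_that("family duplication classes follow the evidence and precedence", {
  blocks <- data.frame(gene_a = c("f1", "f2"), gene_b = c("f3", "f4"),
                       block_id = 1L, orientation = "same")
  tandem <- data.frame(gene_a = "f1", gene_b = "f3", chrom = "Chr1",
                       distance = 1000, cluster_id = 1L)
  ev <- classifyFamilyDuplications(blocks, tandem,
                                   c("f1", "f2", "f3", "f4"))
  ## the pair supported by both lines of evidence is reported once, tandem
  expect_identical(ev$class[ev$gene_a == "f1" & ev$gene_b == "f3"], "tandem")
  expect_identical(sum(ev$gene_a == "f1" & ev$gene_b == "f3"), 1L)
  expect_identical(ev$class[ev$gene_a == "f2"], "segmental")
  ## non-family anchors never classify
  ev2 <- classifyFamilyDuplications(blocks, tandem, c("f1", "f3"))
  expect_identical(nrow(ev2), 1L)
})

test_that("NG86 tallies and corrections match hand calculations", {
  ## identical sequences: zero rates, ratio undefined
  r0 <- kaksNG86("ATGAAA", "ATGAAA")
  expect_identical(c(r0$ka, r0$ks), c(0, 0))
  expect_true(r0$undefined)

  ## third-position Phe/Phe change is purely synonymous
  r1 <- kaksNG86("TTT", "TTC")
  expect_identical(r1$sd_diff, 1)
  expect_identical(r1$nd_diff, 0)

  ## two-position codon: pathway-averaged differences
  r2 <- kaksNG86("GGT", "GAC")
  expect_equal(r2$sd_diff, 1)
  expect_equal(r2$nd_diff, 1)

  ## hand-tallied 20-codon pair (sites: s(GGT)=s(GGC)=1, s(TTT)=s(AAA)=1/3,
  ## s(TTA)=2/3, all by direct enumeration of the genetic code)
  a <- paste(c(rep("GGT", 10), rep("TTT", 5), rep("AAA", 5)), collapse = "")
  b <- paste(c("GGC", rep("GGT", 9), "TTA", rep("TTT", 4), rep("AAA", 5)),
             collapse = "")
  S_a <- 10 * 1 + 5 / 3 + 5 / 3
  S_b <- 9 + 1 + 4 / 3 + 2 / 3 + 5 / 3
  S <- (S_a + S_b) / 2
  N <- 60 - S
  r <- kaksNG86(a, b)
  expect_equal(r$s_sites, S)
  expect_equal(r$n_sites, N)
  expect_equal(r$sd_diff, 1)
  expect_equal(r$nd_diff, 1)
  expect_equal(r$ks, -(3 / 4) * log(1 - (4 / 3) * (1 / S)))
  expect_equal(r$ka, -(3 / 4) * log(1 - (4 / 3) * (1 / N)))
  expect_equal(r$ratio, r$ka / r$ks)

  ## symmetry
  p <- evolveCodonPair(60, omega = 0.5, branchLength = 0.8, seed = 6)
  expect_equal(kaksNG86(p$cds_a, p$cds_b), kaksNG86(p$cds_b, p$cds_a))

  ## guards
  expect_error(kaksNG86("ATG", "ATGA"), "lengths differ")
  expect_error(kaksNG86("ATGA", "ATGA"), "multiple of 3")
  expect_error(kaksNG86("TAAATG", "TAAATG"), "internal stop")
})

test_that("codon-aware pair alignment back-threads the proteins", {
  p <- evolveCodonPair(50, omega = 0.3, branchLength = 0.4, seed = 12)
  al <- alignCodonPair(p$cds_a, p$cds_b)
  expect_identical(nchar(al$cds_a), nchar(al$cds_b))
  expect_identical(nchar(al$cds_a) %% 3L, 0L)
  ## identical inputs come back unchanged (minus the terminal stop)
  cds <- paste(c(rep("ATG", 10), "TAA"), collapse = "")
  al2 <- alignCodonPair(cds, cds)
  expect_identical(al2$cds_a, paste(rep("ATG", 10), collapse = ""))
})
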