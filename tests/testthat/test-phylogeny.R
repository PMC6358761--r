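test_that("Poisson distances follow the closed form under pairwise deletion", {
  expect_equal(poissonDistance(c(a = "AAAA", b = "AAAA"))["a", "b"], 0)

  ## p = 0.5 gives ln 2
  D <- poissonDistance(c(a = "AACC", b = "AATT"))
  expect_equal(D["a", "b"], log(2), tolerance = 1e-12)

  ## gapped pair: p counted only over mutually ungapped columns
  ## shared columns: 2, 3, 5 -> mismatches at column 5 only, p = 1/3
  D2 <- poissonDistance(c(a = "-ACGT", b = "KAC-A"))
  expect_equal(D2["a", "b"], -log(1 - 1 / 3), tolerance = 1e-12)
  expect_identical(attr(D2, "sites")["a", "b"], 3L)

  ## saturation is capped and flagged
  D3 <- poissonDistance(c(a = "AAAA", b = "CCCC"), cap = 10)
  expect_identical(D3["a", "b"], 10)
  expect_true(attr(D3, "saturated")["a", "b"])

  expect_error(poissonDistance("A"), "at least 2")
})

test_that("neighbor joining is exact on additive matrices", {
  expect_error(neighborJoining(matrix(0, 2, 2)), "at least 3")

  ## hand-built additive 4-taxon matrix for ((A,B),(C,D)) with internal
  ## branch 1 and pendant branches 1, 2, 1.5, 2.5
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  D["A", "B"] <- D["B", "A"] <- 3
  D["C", "D"] <- D["D", "C"] <- 4
  D["A", "C"] <- D["C", "A"] <- 1 + 1 + 1.5
  D["A", "D"] <- D["D", "A"] <- 1 + 1 + 2.5
  D["B", "C"] <- D["C", "B"] <- 2 + 1 + 1.5
  D["B", "D"] <- D["D", "B"] <- 2 + 1 + 2.5
  tr <- neighborJoining(D)
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  ## the AB|CD split is present and all path lengths are recovered
  parts <- ape::prop.part(tr)
  sides <- lapply(parts, function(p) sort(tr$tip.label[p]))
  expect_true(any(vapply(sides, identical, TRUE, c("A", "B"))) ||
              any(vapply(sides, identical, TRUE, c("C", "D"))))
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)

  ## ultrametric 3-taxon input resolves as a star with exact lengths
  D3 <- matrix(2, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  diag(D3) <- 0
  tr3 <- neighborJoining(D3)
  expect_identical(tr3$Nnode, 1L)
  expect_equal(sort(tr3$edge.length), rep(1, 3))

  ## random additive matrices: tree metric reproduced exactly
  set.seed(15)
  for (rep in 1:50) {
    src <- ape::rtree(6)
    D6 <- ape::cophenetic.phylo(src)
    out <- neighborJoining(D6)
    expect_equal(ape::cophenetic.phylo(out)[rownames(D6), colnames(D6)],
                 D6, tolerance = 1e-8)
  }
})

test_that("bootstrap supports are reproducible and reflect the signal", {
  aln <- c(A = "AAAAAAAAAAC", B = "AAAAAAAAAAG",
           C = "TTTTTTTTTTA", D = "TTTTTTTTTTG")
  t0 <- bootstrapSupport(aln, replicates = 0)
  expect_null(t0$node.label)

  t1 <- bootstrapSupport(aln, replicates = 100, seed = 5)
  t2 <- bootstrapSupport(aln, replicates = 100, seed = 5)
  expect_identical(t1$node.label, t2$node.label)
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  ## ten perfectly segregating columns: the AB|CD split is in every replicate
  expect_true(any(sup == 100))
})

test_that("subfamily assignment uses clades then nearest-marker fallback", {
  ## gene sister to a single marker inherits its label
  tr <- ape::read.tree(text = "((g1:1,mSIP1:1):2,(mGT:1,mSH4:1):2,g2:4);")
  mm <- c(mSIP1 = "SIP1", mGT = "GT", mSH4 = "SH4")
  asg <- assignSubfamilies(tr, mm)
  expect_identical(asg$subfamily[asg$gene_id == "g1"], "SIP1")
  expect_false(asg$ambiguous[asg$gene_id == "g1"])

  ## every side holding g2 mixes two subfamilies: nearest-marker fallback
  tr2 <- ape::read.tree(
    text = "((mGT:1,mSH4:1):1,(g2:1,(mGT2:1.5,mSH42:1):1):1);")
  mm2 <- c(mGT = "GT", mGT2 = "GT", mSH4 = "SH4", mSH42 = "SH4")
  g2 <- assignSubfamilies(tr2, mm2)
  expect_true(g2$ambiguous[g2$gene_id == "g2"])
  expect_identical(g2$method[g2$gene_id == "g2"], "nearest")
  ## the nearest marker (patristic) is mSH42 at distance 3 vs mGT2 at 3.5
  expect_identical(g2$subfamily[g2$gene_id == "g2"], "SH4")

  expect_error(assignSubfamilies(tr, c(zzz = "SIP1")), "no marker")

  ## simulated five-subfamily domain set: high label accuracy
  pm <- make_seed_profile()
  correct <- 0L; total <- 0L
  for (s in 1:5) {
    pr <- generateProteome(familyGenomeSpec(nFamily = 15, nDecoy = 0,
                                            seed = 100 + s), pm,
                           subfamilies = 5)
    aln <- profileAlign(pm, pr$proteome)
    tree <- neighborJoining(poissonDistance(aln))
    markers <- tapply(pr$truth$gene_id, pr$truth$subfamily, `[`, 1L)
    asg <- assignSubfamilies(tree, setNames(names(markers),
                                            unlist(markers)))
    truth_lab <- pr$truth$subfamily[match(asg$gene_id, pr$truth$gene_id)]
    correct <- correct + sum(asg$subfamily == truth_lab)
    total <- total + nrow(asg)
  }
  expect_gte(correct / total, 0.95)
})

test_that("profile-anchored alignment threads hits onto match positions", {
  pm <- make_seed_profile()
  cons <- profileConsensus(pm)
  aln <- profileAlign(pm, c(x = paste0("MMM", cons, "KKK"), y = cons))
  expect_identical(unname(aln["y"]), cons)
  expect_identical(unname(aln["x"]), cons)
  expect_identical(unique(nchar(aln)), profileLength(pm))
})
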