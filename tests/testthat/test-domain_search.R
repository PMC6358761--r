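test_that("profile emissions match the pseudocounted log-odds formula", {
  ## identical sequences, vanishing pseudocount: argmax = observed residue
  pm <- buildProfile(c("ACDE", "ACDE"), pseudocount = 1e-9)
  expect_identical(profileConsensus(pm), "ACDE")

  ## hand-computed pseudocounted log-odds for a 3-sequence toy alignment
  aln <- c("AC", "AC", "AD")
  pm <- buildProfile(aln, pseudocount = 1)
  bg <- 1 / 20
  expect_equal(unname(pm@emissions[1, "A"]), log2(((3 + bg) / 4) / bg))
  expect_equal(unname(pm@emissions[2, "C"]), log2(((2 + bg) / 4) / bg))
  expect_equal(unname(pm@emissions[2, "D"]), log2(((1 + bg) / 4) / bg))
  expect_equal(unname(pm@emissions[1, "W"]), log2(((0 + bg) / 4) / bg))

  ## a column whose frequencies equal the background has log-odds 0
  pm20 <- buildProfile(Biostrings::AA_STANDARD, pseudocount = 0)
  expect_true(all(abs(pm20@emissions) < 1e-12))

  ## majority-gap columns are dropped from the match states
  gapped <- c("A-CD", "A-CD", "AEC-")
  expect_identical(profileLength(buildProfile(gapped)), 3L)

  expect_error(buildProfile(character(0)), "2 sequences")
  expect_error(buildProfile(c("AB", "ABC")), "equal gapped length")
})

test_that("local scoring is exact against exhaustive enumeration", {
  ## consensus scores the sum of per-position maxima at full coverage
  pm <- make_seed_profile()
  h <- scoreLocal(pm, profileConsensus(pm))
  expect_equal(h$score, sum(apply(pm@emissions, 1, max)))
  expect_equal(h$model_coverage, 1)

  ## a sequence with no positive-scoring residue yields the null hit
  neg <- buildProfile(c("AAAA", "AAAA"))
  h0 <- scoreLocal(neg, "CCCC")
  expect_identical(h0$score, 0)
  expect_true(is.na(h0$seq_start))

  ## oracle equivalence on all small instances over a 4-letter alphabet
  letters4 <- c("A", "C", "D", "E")
  set.seed(7)
  for (rep in 1:40) {
    L <- sample(2:4, 1); n <- sample(2:6, 1)
    aln <- vapply(1:3, function(i)
      paste(sample(letters4, L, replace = TRUE), collapse = ""), "")
    pm <- buildProfile(aln)
    s <- paste(sample(letters4, n, replace = TRUE), collapse = "")
    got <- scoreLocal(pm, s)$score
    want <- bf_profile_score(pm@emissions,
                             match(strsplit(s, "")[[1]], pm@alphabet),
                             pm@gapOpen, pm@gapExtend)
    expect_equal(got, max(want, 0), tolerance = 1e-9)
  }
})

test_that("Gumbel calibration behaves like an extreme-value fit", {
  pm <- make_seed_profile()
  cal <- calibrateEvalue(pm, decoyCount = 400, seed = 1)
  mu <- cal@calibration[["mu"]]; lam <- cal@calibration[["lambda"]]
  expect_gt(lam, 0)

  ## E-value at the location parameter, db size 1
  expect_equal(eValue(cal, mu, dbSize = 1), 1 - exp(-1), tolerance = 1e-12)
  ## monotone decreasing in score
  sc <- seq(mu - 5, mu + 15, length.out = 50)
  expect_false(is.unsorted(rev(eValue(cal, sc, dbSize = 100))))

  ## location equivariance of the ML fit
  set.seed(3)
  x <- mu + rexp(500, rate = lam)  # arbitrary positive-skew scores
  f1 <- trihelixr:::.fit_gumbel(x)
  f2 <- trihelixr:::.fit_gumbel(x + 7)
  expect_equal(f2[["mu"]], f1[["mu"]] + 7, tolerance = 1e-6)
  expect_equal(f2[["lambda"]], f1[["lambda"]], tolerance = 1e-6)

  ## empirical tail within 2x of the fitted tail at the 95th percentile
  set.seed(11)
  decoys <- replicate(600, paste(sample(trihelixr:::.AA, 200,
                                        replace = TRUE), collapse = ""))
  scores <- vapply(decoys, function(d) scoreLocal(pm, d)$score, 0)
  fit <- trihelixr:::.fit_gumbel(scores)
  q95 <- quantile(scores, 0.95)
  p_fit <- 1 - exp(-exp(-fit[["lambda"]] * (q95 - fit[["mu"]])))
  p_emp <- mean(scores >= q95)
  expect_lt(max(p_fit / p_emp, p_emp / p_fit), 2)

  expect_error(calibrateEvalue(pm, decoyCount = 10), "decoyCount")
  expect_error(trihelixr:::.fit_gumbel(rep(5, 200)), "degenerate")
})

test_that("two-pass identification filters at the E-value and coverage", {
  pm <- make_seed_profile()
  spec <- familyGenomeSpec(nFamily = 10, nDecoy = 30, seed = 8)
  pr <- generateProteome(spec, pm)
  cfg <- searchConfig(nCalibrationShuffles = 200, seed = 2)
  res <- twoPassIdentify(pm, pr$proteome, cfg)

  fam <- pr$truth$gene_id[pr$truth$is_family]
  expect_true(all(res$hits$e_value < cfg$eThreshold))
  expect_true(all(res$hits$model_coverage >= cfg$minModelCoverage))
  expect_gte(sum(res$hits$id %in% fam), 9L)
  expect_identical(sum(!(res$hits$id %in% fam)), 0L)

  ## threshold monotonicity: lowering the E cutoff never adds hits
  tight <- twoPassIdentify(pm, pr$proteome,
                           searchConfig(eThreshold = 1e-4,
                                        nCalibrationShuffles = 200,
                                        seed = 2))
  expect_true(all(tight$hits$id %in% res$hits$id))

  ## idempotence: rescanning with the species profile keeps every hit
  p2 <- trihelixr:::.score_proteome(res$profile,
                                    as.character(pr$proteome),
                                    names(pr$proteome))
  again <- p2$id[p2$e_value < cfg$eThreshold &
                 p2$model_coverage >= cfg$minModelCoverage]
  expect_true(all(res$hits$id %in% again))

  ## the seed domain sequences themselves are retained at full coverage
  seeds <- syntheticSeedAlignment(seed = 42L)
  res_seed <- twoPassIdentify(pm, seeds,
                              searchConfig(nCalibrationShuffles = 200))
  expect_identical(sort(res_seed$hits$id), sort(names(seeds)))
  expect_true(all(res_seed$hits$model_coverage == 1))

  ## zero pass-1 hits is a pipeline error
  set.seed(55)
  decoy_only <- setNames(
    vapply(1:5, function(i)
      paste(sample(trihelixr:::.AA, 80, replace = TRUE), collapse = ""), ""),
    paste0("d", 1:5))
  expect_error(
    twoPassIdentify(make_seed_profile(), decoy_only,
                    searchConfig(pass1EThreshold = 1e-12,
                                 nCalibrationShuffles = 200)),
    "no candidates")
})
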