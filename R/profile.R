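## Profile construction, local alignment scoring, Gumbel E-value calibration
## and the two-pass family identification procedure.

#' Build a profile model from an aligned domain set
#'
#' Per-position log2-odds emissions are computed from pseudocounted column
#' frequencies against the background:
#' \code{log2(((counts + pc * bg) / (total + pc)) / bg)}.
#' Columns with more than 50\% gaps are dropped from the match states.
#'
#' @param alignment \code{AAStringSet} or character vector of equal-length
#'   gapped sequences ("-" or "." for gaps).
#' @param pseudocount total pseudocount weight distributed as the background.
#' @param background named residue frequencies; default uniform.
#' @param gapOpen,gapExtend affine gap penalties in bits.
#' @param alphabet residue alphabet (default the 20 standard amino acids).
#' @return a \code{\linkS4class{ProfileModel}}
#' @examples
#' pm <- buildProfile(c("ACDE", "ACDE", "ACDF"))
#' profileConsensus(pm)
#' @export
buildProfile <- function(alignment, pseudocount = 1,
                         background = NULL,
                         gapOpen = 4, gapExtend = 1,
                         alphabet = .AA) {
  aln <- .as_named_chr(alignment)
  if (length(aln) < 2L) stop("alignment must contain at least 2 sequences")
  lens <- nchar(aln)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must have equal gapped length")
  if (lens[1] == 0L) stop("alignment is empty")
  if (is.null(background))
    background <- setNames(rep(1 / length(alphabet), length(alphabet)), alphabet)
  background <- background[alphabet]

  mat <- do.call(rbind, strsplit(toupper(aln), ""))
  mat[mat == "."] <- "-"
  gap_frac <- colMeans(mat == "-")
  keep <- which(gap_frac <= 0.5)
  if (!length(keep)) stop("all alignment columns are >50% gaps")

  L <- length(keep)
  em <- matrix(0, L, length(alphabet), dimnames = list(NULL, alphabet))
  for (k in seq_len(L)) {
    col <- mat[, keep[k]]
    col <- col[col != "-"]
    bad <- setdiff(unique(col), alphabet)
    if (length(bad)) stop("non-alphabet residue(s) in alignment: ",
                          paste(bad, collapse = ", "))
    counts <- table(factor(col, levels = alphabet))
    freq <- (as.numeric(counts) + pseudocount * background) /
      (length(col) + pseudocount)
    em[k, ] <- log2(freq / background)
  }
  new("ProfileModel", emissions = em, background = background,
      alphabet = alphabet, gapOpen = gapOpen, gapExtend = gapExtend,
      calibration = numeric(0))
}

#' Best local alignment of a sequence against a profile
#'
#' Smith-Waterman-style dynamic programming of the sequence against the
#' position-specific emission scores with affine gaps; the score floor is 0
#' (a sequence with no positive-scoring alignment yields a null hit).
#'
#' @param profile a \code{ProfileModel}.
#' @param sequence a single protein sequence (character or \code{AAString}).
#' @param id sequence identifier carried into the hit.
#' @return one-row data.frame with columns \code{id}, \code{score} (bits),
#'   \code{e_value} (NA until calibrated), \code{seq_start}, \code{seq_end},
#'   \code{model_start}, \code{model_end}, \code{model_coverage}; the
#'   model-coordinate alignment is attached as attribute
#'   \code{"model_alignment"} (residue per model position, "-" = deletion).
#' @examples
#' pm <- buildProfile(c("ACDE", "ACDE"))
#' scoreLocal(pm, "GGACDEGG")
#' @export
scoreLocal <- function(profile, sequence, id = "seq") {
  stopifnot(is(profile, "ProfileModel"))
  s <- as.character(sequence)
  if (!nzchar(s)) stop("sequence must be non-empty")
  enc <- .encode_seq(toupper(s), profile@alphabet)
  r <- .profile_sw(profile@emissions, enc, profile@gapOpen, profile@gapExtend,
                   traceback = TRUE)
  L <- profileLength(profile)
  cov <- if (is.na(r$model_start)) 0 else
    (r$model_end - r$model_start + 1) / L
  hit <- data.frame(id = id, score = r$score, e_value = NA_real_,
                    seq_start = r$seq_start, seq_end = r$seq_end,
                    model_start = r$model_start, model_end = r$model_end,
                    model_coverage = cov, stringsAsFactors = FALSE)
  maln <- rep("-", L)
  if (!is.na(r$model_start) && length(r$model_alignment)) {
    seg <- ifelse(r$model_alignment == 0L, "-",
                  profile@alphabet[pmax(r$model_alignment, 1L)])
    maln[r$model_start:r$model_end] <- seg
  }
  attr(hit, "model_alignment") <- paste(maln, collapse = "")
  hit
}

## Maximum-likelihood Gumbel fit (location mu, scale 1/lambda) for maxima.
.fit_gumbel <- function(x) {
  if (length(x) < 10L) stop("too few scores for a Gumbel fit")
  if (sd(x) < 1e-8)
    stop("degenerate score variance; increase the number of decoys")
  xm <- min(x)
  xbar <- mean(x)
  f <- function(lam) {
    w <- exp(-lam * (x - xm))
    xbar - sum(x * w) / sum(w) - 1 / lam
  }
  lo <- 1e-4; hi <- 1e4
  while (f(hi) < 0 && hi < 1e8) hi <- hi * 10
  lam <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  mu <- xm - (1 / lam) * log(mean(exp(-lam * (x - xm))))
  c(mu = mu, lambda = lam)
}

#' Calibrate a profile's E-value model on background sequences
#'
#' Scores a set of decoy sequences with the profile and fits a Gumbel
#' distribution (mu, lambda) to the local-alignment score maxima by maximum
#' likelihood. Decoys are per-sequence permutations of supplied sequences
#' (composition-preserving shuffles) or, when none are supplied, i.i.d.
#' draws from the profile background.
#'
#' @param profile a \code{ProfileModel}.
#' @param sequences optional character vector/\code{AAStringSet} to shuffle.
#' @param decoyCount number of decoys (>= 100).
#' @param decoyLength decoy length when sampling from the background.
#' @param seed RNG seed.
#' @return the profile with its \code{calibration} slot set.
#' @export
calibrateEvalue <- function(profile, sequences = NULL, decoyCount = 1000L,
                            decoyLength = 350L, seed = 1L) {
  stopifnot(is(profile, "ProfileModel"))
  if (decoyCount < 100L) stop("decoyCount must be >= 100")
  set.seed(seed)
  A <- length(profile@alphabet)
  decoys <- vector("list", decoyCount)
  if (!is.null(sequences)) {
    src <- lapply(as.character(sequences), .encode_seq,
                  alphabet = profile@alphabet)
    pick <- sample.int(length(src), decoyCount, replace = TRUE)
    for (i in seq_len(decoyCount)) decoys[[i]] <- sample(src[[pick[i]]])
  } else {
    for (i in seq_len(decoyCount))
      decoys[[i]] <- sample.int(A, decoyLength, replace = TRUE,
                                prob = profile@background)
  }
  scores <- .profile_sw_scores(profile@emissions, decoys,
                               profile@gapOpen, profile@gapExtend)
  cal <- .fit_gumbel(scores)
  attr(cal, "calibration_seed") <- NULL
  profile@calibration <- cal
  validObject(profile)
  profile
}

#' E-value of an alignment score under a calibrated profile
#'
#' \code{E = dbSize * P(S >= s)} with \code{P(S >= s) =
#' 1 - exp(-exp(-lambda * (s - mu)))} under the fitted Gumbel.
#'
#' @param profile a calibrated \code{ProfileModel}.
#' @param score numeric score(s) in bits.
#' @param dbSize number of sequences searched.
#' @return numeric E-value(s), monotone decreasing in score.
#' @export
eValue <- function(profile, score, dbSize = 1) {
  if (!isCalibrated(profile)) stop("profile is not calibrated")
  mu <- profile@calibration[["mu"]]
  lam <- profile@calibration[["lambda"]]
  dbSize * (1 - exp(-exp(-lam * (score - mu))))
}

#' Search configuration for family identification
#'
#' @param eThreshold final-pass E-value cutoff (default 0.01, the family
#'   inclusion threshold).
#' @param minModelCoverage minimum fraction of model positions spanned by a
#'   hit, the "complete domain" check (default 0.8).
#' @param pass1EThreshold permissive first-pass E-value cutoff.
#' @param nCalibrationShuffles decoys per calibration.
#' @param seed RNG seed for shuffling.
#' @return list of class \code{search_config}
#' @export
searchConfig <- function(eThreshold = 0.01, minModelCoverage = 0.8,
                         pass1EThreshold = 1, nCalibrationShuffles = 1000L,
                         seed = 1L) {
  if (eThreshold <= 0 || minModelCoverage <= 0 || pass1EThreshold <= 0)
    stop("thresholds must be positive")
  structure(list(eThreshold = eThreshold,
                 minModelCoverage = minModelCoverage,
                 pass1EThreshold = pass1EThreshold,
                 nCalibrationShuffles = as.integer(nCalibrationShuffles),
                 seed = as.integer(seed)),
            class = "search_config")
}

.score_proteome <- function(profile, proteome, ids) {
  hits <- vector("list", length(proteome))
  alns <- character(length(proteome))
  for (i in seq_along(proteome)) {
    h <- scoreLocal(profile, proteome[[i]], id = ids[i])
    alns[i] <- attr(h, "model_alignment")
    hits[[i]] <- h
  }
  out <- do.call(rbind, hits)
  out$e_value <- eValue(profile, out$score, dbSize = length(proteome))
  attr(out, "model_alignments") <- alns
  out
}

#' Two-pass profile identification of family members
#'
#' Pass 1 searches the proteome with the seed profile at a permissive
#' E-value threshold; the aligned hit segments (in model coordinates) are
#' used to rebuild a species-specific profile, which is recalibrated and
#' run over the full proteome in pass 2. Final members must satisfy
#' \code{e_value < eThreshold} and \code{model_coverage >=
#' minModelCoverage}; pass-1-only candidates that fail pass 2 are dropped.
#'
#' @param seedProfile seed domain \code{ProfileModel}.
#' @param proteome \code{AAStringSet} or named character vector.
#' @param config a \code{\link{searchConfig}}.
#' @return list with elements \code{hits} (final hit data.frame),
#'   \code{profile} (species-specific calibrated profile), \code{pass1}
#'   (pass-1 candidate table).
#' @export
twoPassIdentify <- function(seedProfile, proteome, config = searchConfig()) {
  seqs <- .as_named_chr(proteome)
  if (!length(seqs)) stop("proteome is empty")
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))

  seed_cal <- if (isCalibrated(seedProfile)) seedProfile else
    calibrateEvalue(seedProfile, sequences = seqs,
                    decoyCount = config$nCalibrationShuffles,
                    seed = config$seed)
  p1 <- .score_proteome(seed_cal, seqs, ids)
  alns <- attr(p1, "model_alignments")
  cand <- which(p1$e_value < config$pass1EThreshold & p1$score > 0)
  if (!length(cand)) stop("no candidates: pass 1 produced zero hits")

  species <- if (length(cand) >= 2L) {
    buildProfile(alns[cand], background = seedProfile@background,
                 gapOpen = seedProfile@gapOpen,
                 gapExtend = seedProfile@gapExtend,
                 alphabet = seedProfile@alphabet)
  } else seedProfile
  species <- calibrateEvalue(species, sequences = seqs,
                             decoyCount = config$nCalibrationShuffles,
                             seed = config$seed + 1L)

  p2 <- .score_proteome(species, seqs, ids)
  keep <- p2$e_value < config$eThreshold &
    p2$model_coverage >= config$minModelCoverage
  hits <- p2[keep, , drop = FALSE]
  attr(hits, "model_alignments") <- attr(p2, "model_alignments")[keep]
  rownames(hits) <- NULL
  list(hits = hits, profile = species,
       pass1 = p1[cand, , drop = FALSE])
}
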