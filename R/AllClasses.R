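#' ProfileModel: position-specific scoring model of a protein domain
#'
#' A profile over an alphabet (typically the 20 amino acids): per-position
#' log2-odds emission scores against a background composition, affine gap
#' penalties in the same score units, and optional Gumbel calibration
#' parameters (mu, lambda) fitted on background score distributions so that
#' E-values can be attached to alignment scores.
#'
#' @slot emissions numeric matrix, model positions x alphabet, log2-odds.
#' @slot background named numeric, background residue frequencies (sums to 1).
#' @slot alphabet character vector of residue symbols (column order).
#' @slot gapOpen,gapExtend numeric gap penalties (bits).
#' @slot calibration named numeric of length 0 (uncalibrated) or 2
#'   (\code{mu}, \code{lambda} of the fitted Gumbel score distribution).
#'
#' @exportClass ProfileModel
setClass("ProfileModel",
  representation(
    emissions  = "matrix",
    background = "numeric",
    alphabet   = "character",
    gapOpen    = "numeric",
    gapExtend  = "numeric",
    calibration = "numeric"
  )
)

setValidity("ProfileModel", function(object) {
  msg <- character(0)
  if (nrow(object@emissions) < 1L) msg <- c(msg, "model length must be >= 1")
  if (!all(is.finite(object@emissions))) msg <- c(msg, "emissions must be finite")
  if (ncol(object@emissions) != length(object@alphabet))
    msg <- c(msg, "emission columns must match alphabet length")
  if (length(object@background) != length(object@alphabet) ||
      abs(sum(object@background) - 1) > 1e-6)
    msg <- c(msg, "background must be frequencies over the alphabet summing to 1")
  if (object@gapOpen < 0 || object@gapExtend < 0)
    msg <- c(msg, "gap penalties must be nonnegative")
  if (length(object@calibration) > 0) {
    if (!all(c("mu", "lambda") %in% names(object@calibration)))
      msg <- c(msg, "calibration must be named (mu, lambda)")
    else if (object@calibration[["lambda"]] <= 0)
      msg <- c(msg, "calibrated lambda must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ProfileModel number of match positions in the model
#' @param x,object a \code{ProfileModel}
#' @export
profileLength <- function(x) nrow(x@emissions)

#' @describeIn ProfileModel TRUE when Gumbel calibration parameters are set
#' @export
isCalibrated <- function(x) length(x@calibration) == 2L

#' @describeIn ProfileModel consensus string (per-position emission argmax)
#' @export
profileConsensus <- function(x) {
  paste(x@alphabet[apply(x@emissions, 1L, which.max)], collapse = "")
}

setMethod("show", "ProfileModel", function(object) {
  cat("ProfileModel of length", profileLength(object),
      "over", length(object@alphabet), "symbols\n")
  cat("  gap open/extend:", object@gapOpen, "/", object@gapExtend, "bits\n")
  if (isCalibrated(object)) {
    cat(sprintf("  calibration: mu = %.3f, lambda = %.3f\n",
                object@calibration[["mu"]], object@calibration[["lambda"]]))
  } else cat("  calibration: none\n")
  cat("  consensus:", profileConsensus(object), "\n")
})

#' FamilyGenomeSpec: parameters of a synthetic gene-family genome
#'
#' Describes the synthetic study system the generators emulate: how many
#' domain-bearing family genes and background decoys, how many chromosomes,
#' which tandem clusters and segmental duplicated blocks to implant, which
#' cis-elements to implant into promoters at what carrier fraction, and the
#' RNG seed that makes every artifact reproducible.
#'
#' @slot nFamily,nDecoy,nChromosomes nonnegative integer counts.
#' @slot tandemClusters data.frame with columns \code{chrom} (integer
#'   chromosome index), \code{size} (genes per cluster, >= 2) and
#'   \code{span} (maximum cluster span, bp).
#' @slot segmentalBlocks data.frame with columns \code{anchors} (genes per
#'   duplicated block, >= 2) and \code{divergence} (per-site substitution
#'   probability applied to the copy, in [0, 1]).
#' @slot promoterImplants named numeric, element id -> fraction of promoters
#'   carrying it (in [0, 1]).
#' @slot seed integer RNG seed.
#'
#' @exportClass FamilyGenomeSpec
setClass("FamilyGenomeSpec",
  representation(
    nFamily = "integer", nDecoy = "integer", nChromosomes = "integer",
    tandemClusters = "data.frame", segmentalBlocks = "data.frame",
    promoterImplants = "numeric", seed = "integer"
  )
)

setValidity("FamilyGenomeSpec", function(object) {
  msg <- character(0)
  if (object@nFamily < 0L) msg <- c(msg, "nFamily must be >= 0")
  if (object@nDecoy < 0L) msg <- c(msg, "nDecoy must be >= 0")
  if (object@nChromosomes < 1L) msg <- c(msg, "nChromosomes must be >= 1")
  tc <- object@tandemClusters
  if (nrow(tc)) {
    if (!all(c("chrom", "size", "span") %in% names(tc)))
      msg <- c(msg, "tandemClusters needs columns chrom, size, span")
    else {
      if (any(tc$span <= 0)) msg <- c(msg, "tandemClusters$span must be > 0")
      if (any(tc$size < 2)) msg <- c(msg, "tandemClusters$size must be >= 2")
      if (any(tc$chrom < 1 | tc$chrom > object@nChromosomes))
        msg <- c(msg, "tandemClusters$chrom out of range")
    }
  }
  sb <- object@segmentalBlocks
  if (nrow(sb)) {
    if (!all(c("anchors", "divergence") %in% names(sb)))
      msg <- c(msg, "segmentalBlocks needs columns anchors, divergence")
    else {
      if (any(sb$anchors < 2)) msg <- c(msg, "segmentalBlocks$anchors must be >= 2")
      if (any(sb$divergence < 0 | sb$divergence > 1))
        msg <- c(msg, "segmentalBlocks$divergence must be in [0, 1]")
    }
  }
  pi <- object@promoterImplants
  if (length(pi) && (any(pi < 0 | pi > 1) || is.null(names(pi))))
    msg <- c(msg, "promoterImplants must be named fractions in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a FamilyGenomeSpec
#'
#' @param nFamily,nDecoy,nChromosomes counts (see class docs).
#' @param tandemClusters data.frame (chrom, size, span) or NULL.
#' @param segmentalBlocks data.frame (anchors, divergence) or NULL.
#' @param promoterImplants named numeric of carrier fractions or NULL.
#' @param seed integer RNG seed.
#' @return a validated \code{FamilyGenomeSpec}
#' @examples
#' spec <- familyGenomeSpec(nFamily = 20, nDecoy = 80, seed = 1)
#' @export
familyGenomeSpec <- function(nFamily = 20L, nDecoy = 80L, nChromosomes = 3L,
                             tandemClusters = NULL, segmentalBlocks = NULL,
                             promoterImplants = NULL, seed = 1L) {
  if (is.null(tandemClusters))
    tandemClusters <- data.frame(chrom = integer(0), size = integer(0),
                                 span = numeric(0))
  if (is.null(segmentalBlocks))
    segmentalBlocks <- data.frame(anchors = integer(0), divergence = numeric(0))
  if (is.null(promoterImplants)) promoterImplants <- setNames(numeric(0), character(0))
  new("FamilyGenomeSpec",
      nFamily = as.integer(nFamily), nDecoy = as.integer(nDecoy),
      nChromosomes = as.integer(nChromosomes),
      tandemClusters = tandemClusters, segmentalBlocks = segmentalBlocks,
      promoterImplants = promoterImplants, seed = as.integer(seed))
}

setMethod("show", "FamilyGenomeSpec", function(object) {
  cat("FamilyGenomeSpec:", object@nFamily, "family +", object@nDecoy,
      "decoy genes on", object@nChromosomes, "chromosome(s)\n")
  cat("  tandem clusters:", nrow(object@tandemClusters),
      " segmental blocks:", nrow(object@segmentalBlocks),
      " promoter implants:", length(object@promoterImplants), "\n")
  cat("  seed:", object@seed, "\n")
})
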