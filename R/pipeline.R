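## End-to-end orchestration: synthetic simulate -> identify -> catalog ->
## duplication/synteny + phylogeny + elements -> expression, with
## provenance logging and deterministic per-stage seeds.

.CONFIG_KEYS <- c("spec", "subfamilies", "eThreshold", "pass1EThreshold",
                  "minModelCoverage", "nCalibrationShuffles",
                  "tandemWindow", "minAnchors", "maxGap", "anchorScore",
                  "promoterLength", "bootstrapReplicates", "kGroups",
                  "bins", "seed", "stages")

.ALL_STAGES <- c("identify", "catalog", "duplications", "phylogeny",
                 "elements", "expression")

#' Pipeline configuration
#'
#' Stage parameters default to the study settings: E-value threshold 0.01,
#' tandem window 200 kb, promoter length 1500 nt, expression bin edges
#' {0, 2, 4, 6}. The bootstrap default is 100 replicates (desk scale);
#' 1000 matches the full published setting.
#'
#' @param spec a \code{\link{familyGenomeSpec}} describing the synthetic
#'   study system.
#' @param subfamilies subfamily variants implanted into the family.
#' @param eThreshold,pass1EThreshold,minModelCoverage,nCalibrationShuffles
#'   identification parameters (see \code{\link{searchConfig}}).
#' @param tandemWindow tandem clustering window (bp).
#' @param minAnchors,maxGap collinearity chaining parameters.
#' @param anchorScore minimum anchor alignment score.
#' @param promoterLength upstream promoter window (nt).
#' @param bootstrapReplicates phylogeny bootstrap count.
#' @param kGroups expression cluster count.
#' @param bins expression bin edges.
#' @param seed root RNG seed; per-stage seeds are derived from it.
#' @param stages character vector of stages to run.
#' @param ... unknown keys raise a validation error naming the key.
#' @return list of class \code{pipeline_config}
#' @export
pipelineConfig <- function(spec = familyGenomeSpec(), subfamilies = 5L,
                           eThreshold = 0.01, pass1EThreshold = 1,
                           minModelCoverage = 0.8,
                           nCalibrationShuffles = 400L,
                           tandemWindow = 200000, minAnchors = 5L,
                           maxGap = 25L, anchorScore = 60,
                           promoterLength = 1500L,
                           bootstrapReplicates = 100L, kGroups = 5L,
                           bins = c(0, 2, 4, 6), seed = 1L,
                           stages = .ALL_STAGES, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown config key(s): ", paste(names(extra), collapse = ", "))
  bad <- setdiff(stages, .ALL_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg <- list(spec = spec, subfamilies = as.integer(subfamilies),
              eThreshold = eThreshold, pass1EThreshold = pass1EThreshold,
              minModelCoverage = minModelCoverage,
              nCalibrationShuffles = as.integer(nCalibrationShuffles),
              tandemWindow = tandemWindow,
              minAnchors = as.integer(minAnchors),
              maxGap = as.integer(maxGap), anchorScore = anchorScore,
              promoterLength = as.integer(promoterLength),
              bootstrapReplicates = as.integer(bootstrapReplicates),
              kGroups = as.integer(kGroups), bins = bins,
              seed = as.integer(seed), stages = stages)
  structure(cfg, class = "pipeline_config")
}

.stage_seed <- function(root, k) as.integer((root * 131L + k * 7919L) %% .Machine$integer.max)

#' Run the full synthetic pipeline
#'
#' Stages run in dependency order (identify -> catalog -> duplications +
#' phylogeny + elements -> expression); disabled stages are skipped and a
#' stage missing its upstream artifact raises an error naming the stage.
#' Identical config and seed produce byte-identical artifacts.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory for the artifact bundle (created).
#' @return invisible list ("report_bundle"): computed objects plus the
#'   paths of every written artifact and a run log
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("run")) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("trihelixr pipeline, seed=%d", config$seed),
                 sprintf("stages: %s", paste(config$stages, collapse = ",")),
                 sprintf("parameters: eThreshold=%g coverage=%g tandemWindow=%g promoterLength=%d bootstrap=%d kGroups=%d",
                         config$eThreshold, config$minModelCoverage,
                         config$tandemWindow, config$promoterLength,
                         config$bootstrapReplicates, config$kGroups))
  bundle <- list(paths = character(0))
  emit <- function(x, file) {
    p <- file.path(outDir, file)
    writeArtifact(x, p)
    bundle$paths[[file]] <<- p
  }

  ## -- simulate (always needed in synthetic mode)
  spec <- config$spec
  spec@seed <- .stage_seed(config$seed, 1L)
  seed_aln <- syntheticSeedAlignment(seed = .stage_seed(config$seed, 2L))
  seed_profile <- buildProfile(seed_aln)
  sim <- generateDuplicatedGenome(spec, seed_profile,
                                  subfamilies = config$subfamilies)
  bundle$simulation <- sim
  emit(sim$genome, "genome.fa")
  emit(sim$proteome, "proteome.fa")
  emit(sim$annotation, "annotation.gff3")
  emit(sim$truth, "truth.tsv")
  log_lines <- c(log_lines, sprintf("simulated %d genes (%d family) on %d chromosomes",
                                    nrow(sim$truth), sum(sim$truth$is_family),
                                    spec@nChromosomes))

  hits <- NULL
  if ("identify" %in% config$stages) {
    sc <- searchConfig(eThreshold = config$eThreshold,
                       minModelCoverage = config$minModelCoverage,
                       pass1EThreshold = config$pass1EThreshold,
                       nCalibrationShuffles = config$nCalibrationShuffles,
                       seed = .stage_seed(config$seed, 3L))
    ident <- twoPassIdentify(seed_profile, sim$proteome, sc)
    hits <- ident$hits
    bundle$hits <- hits
    bundle$profile <- ident$profile
    emit(hits, "hits.tsv")
    log_lines <- c(log_lines, sprintf("identify: %d family members", nrow(hits)))
  }

  if ("catalog" %in% config$stages) {
    catalog <- buildCatalog(sim$annotation, sim$genome)
    bundle$catalog <- catalog
    emit(catalog, "catalog.tsv")
    log_lines <- c(log_lines, sprintf("catalog: %d transcripts", nrow(catalog)))
  }

  if ("duplications" %in% config$stages) {
    if (is.null(hits)) stop("stage 'duplications' requires stage 'identify'")
    fam_ids <- hits$id
    loci <- sim$truth[, c("gene_id", "chrom", "start")]
    tandem <- findTandemEvents(loci[loci$gene_id %in% fam_ids, , drop = FALSE],
                               window = config$tandemWindow)
    anchors <- findAnchorPairs(sim$proteome, topK = 5L,
                               scoreThreshold = config$anchorScore,
                               minCoverage = 0.5, minIdentity = 0.6)
    ranks <- geneRanks(loci)
    anchors$chrom_a <- ranks$chrom[match(anchors$gene_a, ranks$gene_id)]
    anchors$chrom_b <- ranks$chrom[match(anchors$gene_b, ranks$gene_id)]
    anchors$rank_a <- ranks$rank[match(anchors$gene_a, ranks$gene_id)]
    anchors$rank_b <- ranks$rank[match(anchors$gene_b, ranks$gene_id)]
    blocks <- chainCollinearBlocks(anchors, minAnchors = config$minAnchors,
                                   maxGap = config$maxGap)
    events <- classifyFamilyDuplications(blocks, tandem, fam_ids)
    kaks <- do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
      al <- alignCodonPair(as.character(sim$cds[[events$gene_a[i]]]),
                           as.character(sim$cds[[events$gene_b[i]]]))
      cbind(events[i, c("gene_a", "gene_b", "class")],
            kaksNG86(al$cds_a, al$cds_b))
    }))
    if (is.null(kaks))
      kaks <- data.frame(gene_a = character(0), gene_b = character(0),
                         class = character(0), ka = numeric(0),
                         ks = numeric(0), ratio = numeric(0))
    bundle$tandem <- tandem; bundle$anchors <- anchors
    bundle$blocks <- blocks; bundle$events <- events; bundle$kaks <- kaks
    emit(anchors, "anchors.tsv"); emit(blocks, "blocks.tsv")
    emit(events, "events.tsv"); emit(kaks, "kaks.tsv")
    log_lines <- c(log_lines,
                   sprintf("duplications: %d tandem events, %d blocks, %d classified pairs",
                           nrow(tandem), length(unique(blocks$block_id)),
                           nrow(events)))
  }

  if ("phylogeny" %in% config$stages) {
    if (is.null(hits)) stop("stage 'phylogeny' requires stage 'identify'")
    fam <- hits$id
    aln <- profileAlign(bundle$profile, sim$proteome[fam])
    tree <- bootstrapSupport(aln, replicates = config$bootstrapReplicates,
                             seed = .stage_seed(config$seed, 4L))
    truth_sub <- sim$truth$subfamily[match(fam, sim$truth$gene_id)]
    markers <- tapply(fam[!is.na(truth_sub)], truth_sub[!is.na(truth_sub)],
                      `[`, 1L)
    assign <- if (length(markers))
      assignSubfamilies(tree, setNames(names(markers), unlist(markers)))
    else data.frame(gene_id = character(0), subfamily = character(0),
                    method = character(0), ambiguous = logical(0))
    bundle$tree <- tree; bundle$assignments <- assign
    tree_path <- file.path(outDir, "tree.nwk")
    ape::write.tree(tree, tree_path)
    bundle$paths[["tree.nwk"]] <- tree_path
    emit(assign, "assignments.tsv")
    log_lines <- c(log_lines, sprintf("phylogeny: %d taxa, %d bootstrap replicates",
                                      length(tree$tip.label),
                                      config$bootstrapReplicates))
  }

  if ("elements" %in% config$stages) {
    if (is.null(hits)) stop("stage 'elements' requires stage 'identify'")
    promoters <- extractPromoters(sim$genome, sim$annotation,
                                  length = config$promoterLength)
    promoters <- promoters[names(promoters) %in% hits$id]
    lib <- readElementLibrary()
    matches <- scanElementLibrary(promoters, lib)
    shared <- sharedElements(promoters, lib)
    bundle$element_matches <- matches; bundle$shared_elements <- shared
    emit(matches, "element_matches.tsv")
    shared_path <- file.path(outDir, "shared_elements.txt")
    writeLines(shared, shared_path)
    bundle$paths[["shared_elements.txt"]] <- shared_path
    log_lines <- c(log_lines, sprintf("elements: %d matches, %d shared",
                                      nrow(matches), length(shared)))
  }

  if ("expression" %in% config$stages) {
    if (is.null(hits)) stop("stage 'expression' requires stage 'identify'")
    fam <- hits$id
    expr <- generateExpressionMatrix(nGenes = length(fam),
                                     nGroups = min(config$kGroups,
                                                   length(fam)),
                                     seed = .stage_seed(config$seed, 5L))
    rownames(expr$matrix) <- fam
    bins <- apply(expr$matrix, 2L, function(col)
      as.character(binExpression(col)))
    rownames(bins) <- fam
    cl <- clusterGenes(expr$matrix, k = min(config$kGroups, length(fam)))
    tp <- c("0h", "6h", "24h")
    lfc <- matrix(0, length(fam), length(tp),
                  dimnames = list(fam, tp))
    set.seed(.stage_seed(config$seed, 6L))
    lfc[, -1] <- round(runif(length(fam) * (length(tp) - 1L), -3, 3), 2)
    ct <- generateCtTable(lfc, seed = .stage_seed(config$seed, 7L))
    fc <- ddctFoldChange(ct, baseline = "0h")
    sig <- ddctSignificance(ct, baseline = "0h")
    bundle$expression <- expr; bundle$bins <- bins
    bundle$clusters <- cl$labels
    bundle$ct <- ct; bundle$fold_changes <- fc; bundle$significance <- sig
    emit(data.frame(gene = rownames(expr$matrix), expr$matrix,
                    check.names = FALSE), "expression.tsv")
    emit(data.frame(gene = rownames(bins), bins, check.names = FALSE),
         "expression_bins.tsv")
    emit(data.frame(gene = names(cl$labels), group = cl$labels),
         "expression_clusters.tsv")
    emit(ct, "ct_table.csv")
    emit(merge(fc, sig, all.x = TRUE), "fold_changes.tsv")
    log_lines <- c(log_lines, sprintf("expression: %d genes binned and clustered",
                                      length(fam)))
  }

  log_path <- file.path(outDir, "run_log.txt")
  writeLines(log_lines, log_path)
  bundle$paths[["run_log.txt"]] <- log_path
  bundle$log <- log_lines
  class(bundle) <- "report_bundle"
  invisible(bundle)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("trihelixr report bundle\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  cat("artifacts:", paste(names(x$paths), collapse = ", "), "\n")
  invisible(x)
}
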