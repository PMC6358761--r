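## Expression binning at the printed thresholds, group clustering, and
## 2^-ddCt qPCR quantification with replicate significance.

.BIN_LEVELS <- c("none", "low", "medium", "high", "extremely_high")

#' Bin expression values at the standard thresholds
#'
#' \code{> 6} extremely_high; \code{(4, 6]} high; \code{(2, 4]} medium;
#' \code{(0, 2]} low; \code{<= 0} none (the printed bins leave 0 itself
#' unclassified; it maps to the distinct "none" category).
#'
#' @param value finite numeric vector.
#' @return factor with levels none < low < medium < high < extremely_high
#' @export
binExpression <- function(value) {
  if (any(is.na(value))) stop("expression values must be finite (no NaN/NA)")
  if (any(!is.finite(value))) stop("expression values must be finite")
  out <- ifelse(value > 6, "extremely_high",
         ifelse(value > 4, "high",
         ifelse(value > 2, "medium",
         ifelse(value > 0, "low", "none"))))
  factor(out, levels = .BIN_LEVELS, ordered = TRUE)
}

#' Cluster genes by expression profile
#'
#' Agglomerative clustering (Euclidean distance, average linkage by
#' default) cut to \code{k} groups, mirroring heatmap group assignment.
#' Rows are ordered by id before clustering so the partition is
#' deterministic and invariant to input row order.
#'
#' @param mat genes x conditions numeric matrix with rownames.
#' @param k number of groups.
#' @param linkage \code{hclust} method.
#' @return list: \code{labels} (named integer vector), \code{hclust}
#'   (dendrogram), \code{group_means} (k x conditions matrix)
#' @export
clusterGenes <- function(mat, k = 5L, linkage = "average") {
  if (is.null(rownames(mat))) stop("matrix needs gene rownames")
  if (k > nrow(mat)) stop("k exceeds the number of genes")
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  hc <- hclust(dist(mat, method = "euclidean"), method = linkage)
  labels <- cutree(hc, k = k)
  gm <- do.call(rbind, lapply(seq_len(k), function(g)
    colMeans(mat[labels == g, , drop = FALSE])))
  rownames(gm) <- paste0("group", seq_len(k))
  list(labels = labels, hclust = hc, group_means = gm)
}

.delta_ct <- function(ct) ct$ct_target - ct$ct_reference

#' Relative quantification by 2^-ddCt
#'
#' Per replicate, dCt = Ct_target - Ct_reference; ddCt is taken against
#' the gene's mean baseline dCt; the fold change is 2^-ddCt. Per gene and
#' timepoint the mean ddCt (and its fold change) plus the mean and SD of
#' per-replicate fold changes are reported.
#'
#' @param ct data.frame with columns \code{gene}, \code{condition},
#'   \code{replicate}, \code{ct_target}, \code{ct_reference}.
#' @param baseline baseline condition label (time 0).
#' @return data.frame (gene, condition, ddct, fold_change, fc_mean, fc_sd,
#'   n_replicates)
#' @export
ddctFoldChange <- function(ct, baseline) {
  need <- c("gene", "condition", "replicate", "ct_target", "ct_reference")
  if (!all(need %in% names(ct)))
    stop("ct table needs columns: ", paste(need, collapse = ", "))
  ct$dct <- .delta_ct(ct)
  out <- list()
  for (g in unique(ct$gene)) {
    sub <- ct[ct$gene == g, , drop = FALSE]
    base <- sub$dct[sub$condition == baseline]
    if (!length(base)) stop("missing baseline '", baseline, "' for gene ", g)
    base_mean <- mean(base)
    for (cond in unique(sub$condition)) {
      ddct <- sub$dct[sub$condition == cond] - base_mean
      fc <- 2^(-ddct)
      out[[length(out) + 1L]] <- data.frame(
        gene = g, condition = cond, ddct = mean(ddct),
        fold_change = 2^(-mean(ddct)), fc_mean = mean(fc), fc_sd = sd(fc),
        n_replicates = length(ddct), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Replicate significance of qPCR changes vs baseline
#'
#' Two-sample equal-variance two-sided Student's t-test on replicate dCt
#' values at each condition against the baseline replicates; stars at the
#' conventional thresholds (* p < 0.05, ** p < 0.01). When both groups
#' have zero variance the p-value is 1 for equal means and 0 otherwise.
#'
#' @param ct Ct table (see \code{\link{ddctFoldChange}}).
#' @param baseline baseline condition label.
#' @return data.frame (gene, condition, p_value, stars)
#' @export
ddctSignificance <- function(ct, baseline) {
  ct$dct <- .delta_ct(ct)
  out <- list()
  for (g in unique(ct$gene)) {
    sub <- ct[ct$gene == g, , drop = FALSE]
    base <- sub$dct[sub$condition == baseline]
    if (length(base) < 2L) stop("need >= 2 baseline replicates for ", g)
    for (cond in setdiff(unique(sub$condition), baseline)) {
      x <- sub$dct[sub$condition == cond]
      if (length(x) < 2L) stop("need >= 2 replicates for ", g, " / ", cond)
      p <- if (sd(x) == 0 && sd(base) == 0) {
        if (isTRUE(all.equal(mean(x), mean(base)))) 1 else 0
      } else t.test(x, base, var.equal = TRUE)$p.value
      stars <- if (p < 0.01) "**" else if (p < 0.05) "*" else ""
      out[[length(out) + 1L]] <- data.frame(
        gene = g, condition = cond, p_value = p, stars = stars,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a Ct table (CSV)
#'
#' Columns: gene, condition, replicate, ct_target, ct_reference.
#'
#' @param path CSV path.
#' @return data.frame
#' @export
readCtTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "condition", "replicate", "ct_target", "ct_reference")
  if (!all(need %in% names(df)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$ct_target)) || any(!is.finite(df$ct_reference)))
    stop("Ct values must be finite")
  df
}

#' Read an expression matrix (TSV, genes x conditions)
#'
#' @param path TSV path with a header row; first column holds gene ids.
#' @return numeric matrix with gene rownames
#' @export
readExpressionMatrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("expression values must be finite")
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids")
  m
}
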