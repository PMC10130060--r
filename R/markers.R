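## One-vs-rest Wilcoxon rank-sum marker statistics with BH adjustment
## and the top-K selection variants used for genes and for accessibility
## peaks.

#' One-vs-rest Wilcoxon rank-sum marker statistics
#'
#' For every feature, computes the Mann-Whitney U statistic of the cells
#' in `cluster` against all remaining cells, a tie-corrected and
#' continuity-corrected (0.5) normal-approximation z score, the two-sided
#' p value, its Benjamini-Hochberg adjustment across features, and a
#' natural-log fold-change of mean normalized expression with a small
#' pseudocount.
#'
#' @param normalized cells x features normalized matrix (dense or
#'   sparse) with feature names.
#' @param labels per-cell cluster labels (named by barcode or aligned to
#'   rows).
#' @param cluster label of the foreground cluster (>= 2 cells; the
#'   complement must also have >= 2 cells).
#' @param eps pseudocount in the fold-change ratio (default 1e-9).
#' @return `data.frame` of class `marker_stats` with columns `feature`,
#'   `U`, `z`, `p`, `p_adj`, `logFC`, plus attributes `cluster`, `n1`,
#'   `n2`.
#' @export
wilcoxon_one_vs_rest <- function(normalized, labels, cluster,
                                 eps = 1e-9) {
  if (!is.null(names(labels)) && !is.null(rownames(normalized)))
    labels <- labels[rownames(normalized)]
  stopifnot(length(labels) == nrow(normalized))
  in_grp <- labels == cluster
  n1 <- sum(in_grp); n2 <- sum(!in_grp)
  if (n1 < 2L || n2 < 2L)
    stop("degenerate group sizes for cluster '", cluster, "': ",
         n1, " vs ", n2)
  m <- as.matrix(normalized)
  n <- n1 + n2
  ## per-feature midranks and tie correction
  U <- numeric(ncol(m)); tiecor <- numeric(ncol(m))
  for (jj in seq_len(ncol(m))) {
    r <- rank(m[, jj])
    U[jj] <- sum(r[in_grp]) - n1 * (n1 + 1) / 2
    tab <- table(m[, jj])
    tiecor[jj] <- sum(tab^3 - tab)
  }
  mu <- n1 * n2 / 2
  sigma <- sqrt((n1 * n2 / 12) * ((n + 1) - tiecor / (n * (n - 1))))
  diffU <- U - mu
  z <- ifelse(sigma > 0,
              (diffU - sign(diffU) * 0.5) / sigma,  # continuity correction
              0)
  z[sigma > 0 & abs(diffU) <= 0.5] <- 0  # correction may not cross zero
  p <- pmin(1, 2 * stats::pnorm(-abs(z)))
  mean_in <- colMeans(m[in_grp, , drop = FALSE])
  mean_out <- colMeans(m[!in_grp, , drop = FALSE])
  logFC <- log((mean_in + eps) / (mean_out + eps))
  out <- data.frame(feature = colnames(m), U = U, z = z, p = p,
                    p_adj = adjust_bh(p), logFC = logFC,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "cluster") <- cluster
  attr(out, "n1") <- n1
  attr(out, "n2") <- n2
  class(out) <- c("marker_stats", class(out))
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, named wrapper around `stats::p.adjust(method = "BH")`: monotone
#' along the sorted p values and capped at 1.
#'
#' @param p vector of raw p values in (0, 1].
#' @return adjusted p values, same order as input.
#' @export
adjust_bh <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Select top markers from rank-sum statistics
#'
#' `genes` mode ranks by p ascending with ties broken by `|logFC|`
#' descending and takes the top `k` (default 30). `peaks` mode keeps
#' features with adjusted p < `alpha`, ranks by logFC descending and
#' takes the top `k` (default 1000). If fewer features qualify, all of
#' them are returned with a warning.
#'
#' @param stats a `marker_stats` table from [wilcoxon_one_vs_rest()].
#' @param k number of features to return (default 30 for genes, 1000 for
#'   peaks).
#' @param mode `"genes"` or `"peaks"`.
#' @param alpha adjusted-p threshold for peaks mode (default 0.05).
#' @return character vector of selected feature ids in rank order.
#' @export
top_k_markers <- function(stats, k = NULL, mode = c("genes", "peaks"),
                          alpha = 0.05) {
  mode <- match.arg(mode)
  if (is.null(k)) k <- if (mode == "genes") 30L else 1000L
  if (mode == "genes") {
    ord <- order(stats$p, -abs(stats$logFC))
    pool <- stats$feature[ord]
  } else {
    keep <- stats$p_adj < alpha
    ord <- order(-stats$logFC[keep])
    pool <- stats$feature[keep][ord]
  }
  if (length(pool) < k) {
    warning("only ", length(pool), " feature(s) available for k = ", k)
    return(pool)
  }
  pool[seq_len(k)]
}

#' Marker statistics for every apex cluster
#'
#' Convenience wrapper running [wilcoxon_one_vs_rest()] once per apex
#' cluster of an [apex_spec()].
#'
#' @param normalized cells x features normalized matrix.
#' @param labels per-cell cluster labels.
#' @param apex an [apex_spec()].
#' @return named list of `marker_stats`, one per fate.
#' @export
apex_marker_stats <- function(normalized, labels, apex) {
  stopifnot(inherits(apex, "apex_spec"))
  stats::setNames(
    lapply(apex$clusters, function(cl)
      wilcoxon_one_vs_rest(normalized, labels, cl)),
    names(apex$clusters))
}

#' Write a combined markers table
#' @param stats_list named list of `marker_stats` (e.g. from
#'   [apex_marker_stats()]).
#' @param selected named list of selected feature-id vectors, matching
#'   `stats_list` names.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_markers <- function(stats_list, selected, path) {
  rows <- lapply(names(stats_list), function(nm) {
    st <- stats_list[[nm]]
    data.frame(cluster = attr(st, "cluster"), fate = nm,
               st[, c("feature", "U", "z", "p", "p_adj", "logFC")],
               selected = st$feature %in% selected[[nm]])
  })
  df <- do.call(rbind, rows)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
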