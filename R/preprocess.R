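## Preprocessing: count filtering, median-total normalization,
## dispersion-based variable-feature selection, non-centered scaling,
## ATAC gene-activity counting and the PCA/KNN neighbor graph.

#' Filter genes by total spliced count
#'
#' Genes whose total spliced count reaches `min_counts` are retained
#' (inclusive boundary); all layers are subset identically.
#'
#' @param bundle an [expression_bundle()] with a `spliced` layer (or a
#'   single layer, used as-is).
#' @param min_counts minimum total count to keep a gene (default 10).
#' @return filtered `expression_bundle`.
#' @export
filter_genes <- function(bundle, min_counts = 10) {
  stopifnot(inherits(bundle, "expression_bundle"))
  layer <- if ("spliced" %in% names(bundle$layers)) "spliced"
           else names(bundle$layers)[1L]
  totals <- Matrix::colSums(bundle$layers[[layer]])
  keep <- bundle$genes[totals >= min_counts]
  if (length(keep) == 0L)
    stop("no genes pass min_counts = ", min_counts)
  subset_genes(bundle, keep)
}

#' Median-total normalization with log1p transform
#'
#' Each cell's counts are scaled so its total equals the median per-cell
#' total, then `log(1 + x)` is applied. Cells with zero total are removed
#' with a warning.
#'
#' @param bundle an [expression_bundle()].
#' @param layer layer to normalize (default `"spliced"`, or the sole
#'   layer).
#' @param log apply `log1p` after scaling (default `TRUE`).
#' @return sparse cells x genes matrix of normalized values.
#' @export
normalize_and_log <- function(bundle, layer = NULL, log = TRUE) {
  stopifnot(inherits(bundle, "expression_bundle"))
  if (is.null(layer))
    layer <- if ("spliced" %in% names(bundle$layers)) "spliced"
             else names(bundle$layers)[1L]
  m <- bundle$layers[[layer]]
  totals <- Matrix::rowSums(m)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " zero-total cell(s) removed")
    m <- m[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  sf <- stats::median(totals) / totals
  out <- Matrix::Diagonal(x = sf) %*% m
  dimnames(out) <- list(names(totals), bundle$genes)
  if (log) out@x <- log1p(out@x)
  methods::as(out, "CsparseMatrix")
}

#' Normalize spliced and unspliced layers with shared cell size factors
#'
#' Both layers are scaled by the size factors derived from the spliced
#' totals (median-total convention, no log), so the per-cell
#' unspliced/spliced ratio -- the quantity the steady-state velocity model
#' reads -- is left untouched.
#'
#' @param bundle an [expression_bundle()] with `spliced` and `unspliced`
#'   layers.
#' @return list of sparse matrices `spliced`, `unspliced`.
#' @export
normalize_layers <- function(bundle) {
  stopifnot(inherits(bundle, "expression_bundle"),
            all(c("spliced", "unspliced") %in% names(bundle$layers)))
  s <- bundle$layers$spliced
  totals <- Matrix::rowSums(s)
  if (any(totals == 0)) stop("zero-total cell(s); filter cells first")
  sf <- stats::median(totals) / totals
  D <- Matrix::Diagonal(x = sf)
  out <- lapply(bundle$layers[c("spliced", "unspliced")], function(m) {
    r <- methods::as(D %*% m, "CsparseMatrix")
    dimnames(r) <- dimnames(m)
    r
  })
  out
}

#' Select highly variable features by dispersion
#'
#' Features are ranked by the variance-to-mean dispersion of their
#' normalized values and the top `n_target` returned. If fewer
#' informative (nonzero-dispersion) features exist, all of them are
#' returned with a warning.
#'
#' @param normalized cells x genes normalized matrix (dense or sparse)
#'   with gene ids as column names.
#' @param n_target number of features to select (default 3000).
#' @return character vector of selected feature ids.
#' @export
select_variable_features <- function(normalized, n_target = 3000) {
  mu <- Matrix::colMeans(normalized)
  ## column variance for sparse input: E[x^2] - mu^2, n-1 denominator
  n <- nrow(normalized)
  ex2 <- Matrix::colMeans(normalized^2)
  v <- (ex2 - mu^2) * n / (n - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  informative <- which(disp > 0)
  if (length(informative) < n_target) {
    warning("only ", length(informative),
            " informative features available (requested ", n_target, ")")
  }
  ord <- informative[order(disp[informative], decreasing = TRUE)]
  colnames(normalized)[utils::head(ord, n_target)]
}

#' Scale features by root-mean-square without centering
#'
#' Each selected feature is divided by its RMS with an `n - 1`
#' denominator: `factor_g = sqrt(sum(x_g^2) / (n - 1))`. Values keep
#' their sign (nonnegative input stays nonnegative). An all-zero feature
#' gets factor 1 with a warning.
#'
#' @param normalized cells x genes normalized matrix.
#' @param features feature ids to keep and scale (default: all columns).
#' @return list of class `scaled_matrix`: `values` (cells x features),
#'   `scale_factors`, `features`.
#' @export
scale_no_center <- function(normalized, features = colnames(normalized)) {
  idx <- match(features, colnames(normalized))
  if (anyNA(idx)) stop("unknown features: ",
                       paste(features[is.na(idx)], collapse = ", "))
  m <- normalized[, idx, drop = FALSE]
  n <- nrow(m)
  fac <- sqrt(Matrix::colSums(m^2) / (n - 1))
  zero <- fac == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero feature(s); scale factor set to 1")
    fac[zero] <- 1
  }
  vals <- methods::as(m %*% Matrix::Diagonal(x = 1 / fac),
                      "CsparseMatrix")
  dimnames(vals) <- list(rownames(m), features)
  structure(list(values = vals, scale_factors = stats::setNames(fac, features),
                 features = features),
            class = "scaled_matrix")
}

#' Gene-activity matrix from ATAC fragments
#'
#' Counts, per cell and gene, the fragments overlapping the gene's
#' accessibility window -- gene body plus `upstream_bp` upstream of the
#' transcription start site, strand-aware: `[start - upstream_bp, end)`
#' on the + strand, `[start, end + upstream_bp)` on the - strand. A
#' fragment contributes its duplicate count to every gene whose window it
#' overlaps by at least 1 bp. Fragments on contigs absent from the
#' annotation are ignored (a message reports how many).
#'
#' @param fragments fragment record `data.frame` (`contig`, `start`,
#'   `end`, `barcode`, `count`; 0-based half-open).
#' @param annotation gene interval `data.frame` from
#'   [read_gene_annotation()].
#' @param upstream_bp promoter window size in bp (default 3000).
#' @param barcodes optional barcode universe fixing row order; default
#'   sorted unique fragment barcodes.
#' @return sparse integer cells x genes matrix.
#' @export
gene_activity_from_fragments <- function(fragments, annotation,
                                         upstream_bp = 3000,
                                         barcodes = NULL) {
  stopifnot(all(annotation$strand %in% c("+", "-")))
  if (is.null(barcodes)) barcodes <- sort(unique(fragments$barcode))
  genes <- annotation$gene_id
  out <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(length(barcodes), length(genes)),
                              dimnames = list(barcodes, genes))
  if (nrow(fragments) == 0L || nrow(annotation) == 0L) return(out)
  known <- fragments$contig %in% annotation$contig
  if (!all(known))
    message(sum(!known), " fragment(s) on contigs absent from annotation",
            " ignored")
  fragments <- fragments[known, , drop = FALSE]
  if (nrow(fragments) == 0L) return(out)
  ## strand-aware windows, clipped at contig start, as 1-based closed
  ## GRanges: 0-based half-open [a, b) == 1-based closed [a + 1, b]
  wstart <- ifelse(annotation$strand == "+",
                   pmax(0L, annotation$start - upstream_bp),
                   annotation$start)
  wend <- ifelse(annotation$strand == "+",
                 annotation$end, annotation$end + upstream_bp)
  gene_gr <- GenomicRanges::GRanges(
    annotation$contig, IRanges::IRanges(start = wstart + 1L, end = wend))
  frag_gr <- GenomicRanges::GRanges(
    fragments$contig,
    IRanges::IRanges(start = fragments$start + 1L, end = fragments$end))
  hits <- GenomicRanges::findOverlaps(frag_gr, gene_gr, minoverlap = 1L)
  if (length(hits) == 0L) return(out)
  fi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  ci <- match(fragments$barcode[fi], barcodes)
  if (anyNA(ci)) stop("fragment barcode(s) outside the barcode universe")
  out + Matrix::sparseMatrix(i = ci, j = gi, x = fragments$count[fi],
                             dims = dim(out), dimnames = dimnames(out))
}

#' PCA embedding and exact K-nearest-neighbor graph
#'
#' Computes `n_pcs` principal-component scores of the scaled matrix (PCA
#' centers internally; the upstream scaling deliberately does not) and an
#' exact Euclidean KNN on the scores. Ties are broken by smallest cell
#' index so the graph is deterministic.
#'
#' @param scaled a `scaled_matrix` from [scale_no_center()] (or a plain
#'   matrix).
#' @param n_pcs number of principal components (default 30, capped at the
#'   available rank).
#' @param k neighbors per cell (default 30; must be `< n`).
#' @return list of class `neighbor_graph`: `idx` (n x k neighbor
#'   indices), `dist` (n x k Euclidean distances), `embedding` (PCA
#'   scores).
#' @export
pca_knn_graph <- function(scaled, n_pcs = 30, k = 30) {
  m <- if (inherits(scaled, "scaled_matrix")) scaled$values else scaled
  n <- nrow(m)
  if (k >= n) stop("k (", k, ") must be smaller than the number of cells (",
                   n, ")")
  n_pcs <- min(n_pcs, n - 1L, ncol(m))
  pc <- stats::prcomp(as.matrix(m), center = TRUE, scale. = FALSE,
                      rank. = n_pcs)
  emb <- pc$x
  d <- as.matrix(stats::dist(emb))
  diag(d) <- Inf  # exclude self-edges
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    ## order() is stable: equal distances resolve to the smaller index
    o <- order(d[i, ])[seq_len(k)]
    idx[i, ] <- o
    dst[i, ] <- d[i, o]
  }
  rownames(idx) <- rownames(dst) <- rownames(m)
  structure(list(idx = idx, dist = dst, embedding = emb, k = k),
            class = "neighbor_graph")
}
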