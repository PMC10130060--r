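#' Expression bundle: cell x gene count layers with identifiers
#'
#' Lightweight container for one or more sparse count layers (e.g.
#' `spliced`, `unspliced`, `total`) sharing the same cells-by-genes
#' orientation, barcodes and gene identifiers.
#'
#' @param layers named list of cells x genes matrices (coerced to sparse
#'   `dgCMatrix`), all sharing one shape.
#' @param barcodes character vector of cell barcodes (unique, length
#'   `nrow`).
#' @param genes character vector of gene ids (unique, length `ncol`).
#' @return object of class `expression_bundle`.
#' @export
expression_bundle <- function(layers, barcodes, genes) {
  if (length(layers) == 0L || is.null(names(layers)) ||
      any(!nzchar(names(layers))))
    stop("layers must be a non-empty named list")
  layers <- lapply(layers, function(m) {
    if (!methods::is(m, "sparseMatrix"))
      m <- Matrix::Matrix(as.matrix(m) * 1, sparse = TRUE)
    methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  })
  dims <- unique(lapply(layers, dim))
  if (length(dims) != 1L)
    stop("all layers must share one shape; got ",
         paste(vapply(dims, paste, "", collapse = "x"), collapse = " vs "))
  if (nrow(layers[[1L]]) != length(barcodes))
    stop("barcodes length (", length(barcodes), ") != layer rows (",
         nrow(layers[[1L]]), ")")
  if (ncol(layers[[1L]]) != length(genes))
    stop("genes length (", length(genes), ") != layer cols (",
         ncol(layers[[1L]]), ")")
  if (anyDuplicated(barcodes)) stop("duplicate barcodes")
  if (anyDuplicated(genes)) stop("duplicate gene ids")
  layers <- lapply(layers, function(m) {
    dimnames(m) <- list(barcodes, genes); m
  })
  structure(list(layers = layers, barcodes = as.character(barcodes),
                 genes = as.character(genes)),
            class = "expression_bundle")
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat("expression_bundle:", length(x$barcodes), "cells x",
      length(x$genes), "genes; layers:",
      paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_bundle <- function(x) {
  c(length(x$barcodes), length(x$genes))
}

#' Subset a bundle to a gene set (all layers identically)
#' @param bundle an [expression_bundle()].
#' @param genes character vector of gene ids to keep (order preserved).
#' @return a new `expression_bundle`.
#' @export
subset_genes <- function(bundle, genes) {
  stopifnot(inherits(bundle, "expression_bundle"))
  idx <- match(genes, bundle$genes)
  if (anyNA(idx)) stop("unknown genes: ",
                       paste(genes[is.na(idx)], collapse = ", "))
  expression_bundle(lapply(bundle$layers, function(m) m[, idx, drop = FALSE]),
                    bundle$barcodes, bundle$genes[idx])
}
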