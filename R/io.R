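## On-disk formats: MatrixMarket layers + features/barcodes TSV, BED/GTF
## gene annotation, fragments TSV, labels, simplex coordinate and arrow
## tables, and sparse velocity-graph triplets. Integer count I/O is
## lossless; floating-point TSV is written at 6 significant digits.

.open_read <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read an expression bundle from MatrixMarket layers
#'
#' Each layer is an MTX file accompanied by shared `features.tsv` and
#' `barcodes.tsv`. Orientation is normalized to cells x genes no matter
#' how the MTX was stored: a matrix whose rows match the number of
#' features and columns the number of barcodes is transposed on load.
#'
#' @param mtx_paths named character vector of MTX paths, one per layer.
#' @param features_path path to features.tsv (one gene id per line, first
#'   column used).
#' @param barcodes_path path to barcodes.tsv (one barcode per line).
#' @return an [expression_bundle()].
#' @export
read_expression <- function(mtx_paths, features_path, barcodes_path) {
  if (is.null(names(mtx_paths)) || any(!nzchar(names(mtx_paths))))
    stop("mtx_paths must be named by layer")
  genes <- utils::read.delim(features_path, header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  barcodes <- utils::read.delim(barcodes_path, header = FALSE,
                                stringsAsFactors = FALSE)[[1L]]
  if (anyDuplicated(barcodes))
    stop("duplicate barcodes in ", barcodes_path)
  layers <- lapply(mtx_paths, function(p) {
    m <- Matrix::readMM(p)
    if (nrow(m) == length(barcodes) && ncol(m) == length(genes)) {
      m
    } else if (nrow(m) == length(genes) && ncol(m) == length(barcodes)) {
      Matrix::t(m)
    } else {
      stop("dimension mismatch in ", p, ": matrix ", nrow(m), "x", ncol(m),
           " vs ", length(barcodes), " barcodes x ", length(genes),
           " features")
    }
  })
  expression_bundle(layers, barcodes, genes)
}

#' Write an expression bundle as MatrixMarket layers
#'
#' Emits `<layer>.mtx` per layer (cells x genes orientation) plus
#' `features.tsv` and `barcodes.tsv` under `dir`.
#'
#' @param bundle an [expression_bundle()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_expression <- function(bundle, dir) {
  stopifnot(inherits(bundle, "expression_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(features = file.path(dir, "features.tsv"),
             barcodes = file.path(dir, "barcodes.tsv"))
  writeLines(bundle$genes, paths["features"])
  writeLines(bundle$barcodes, paths["barcodes"])
  for (nm in names(bundle$layers)) {
    p <- file.path(dir, paste0(nm, ".mtx"))
    Matrix::writeMM(bundle$layers[[nm]], p)
    paths[nm] <- p
  }
  invisible(paths)
}

#' Read gene intervals from BED or GTF
#'
#' Returns one interval per gene in 0-based half-open coordinates. BED
#' input is taken verbatim (already 0-based half-open); GTF (1-based
#' closed) is converted with `start - 1`. For GTF, gene-level records
#' (`type == "gene"`) are used where present, otherwise the first record
#' per `gene_id`. Records with undefined strand are dropped with a
#' warning; duplicate gene ids keep the first occurrence with a warning.
#'
#' @param path BED6 or GTF file (optionally gzipped).
#' @param dialect `"bed"` or `"gtf"`.
#' @return `data.frame` with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_annotation <- function(path, dialect = c("bed", "gtf")) {
  dialect <- match.arg(dialect)
  gr <- rtracklayer::import(path, format = dialect)
  if (length(gr) == 0L)
    return(data.frame(gene_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character()))
  if (dialect == "gtf") {
    md <- S4Vectors::mcols(gr)
    if ("type" %in% names(md) && any(md$type == "gene"))
      gr <- gr[md$type == "gene"]
    ids <- S4Vectors::mcols(gr)$gene_id
  } else {
    ids <- S4Vectors::mcols(gr)$name
  }
  if (is.null(ids)) stop("no gene identifiers found in ", path)
  ## GRanges is 1-based closed regardless of source dialect; back to
  ## 0-based half-open: start - 1, end unchanged.
  out <- data.frame(gene_id = as.character(ids),
                    contig = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  bad <- !(out$strand %in% c("+", "-"))
  if (any(bad)) {
    warning(sum(bad), " record(s) with undefined strand dropped")
    out <- out[!bad, , drop = FALSE]
  }
  dup <- duplicated(out$gene_id)
  if (any(dup)) {
    warning("duplicate gene_id(s): ",
            paste(unique(out$gene_id[dup]), collapse = ", "),
            "; first occurrence retained")
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read a fragments file (5-column TSV dialect)
#'
#' Columns: contig, start, end, barcode, count; 0-based half-open.
#' Gzip is handled transparently by extension.
#'
#' @param path fragments TSV(.gz).
#' @return `data.frame` of fragment records.
#' @export
read_fragments <- function(path) {
  con <- .open_read(path)
  on.exit(close(con))
  df <- utils::read.delim(con, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("contig", "start", "end",
                                        "barcode", "count"))
  if (nrow(df) > 0 && any(df$start >= df$end))
    stop("invalid fragment intervals (start >= end) in ", path)
  if (nrow(df) > 0 && any(df$count < 1))
    stop("fragment counts must be >= 1 in ", path)
  df
}

#' Write a fragments file
#' @param fragments fragment record `data.frame`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_fragments <- function(fragments, path) {
  utils::write.table(fragments[, c("contig", "start", "end", "barcode",
                                   "count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a cluster-label table (barcode, cluster)
#' @param path TSV with two columns and a header.
#' @return named character vector of cluster labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2L]]), df[[1L]])
}

#' Write a cluster-label table
#' @param labels named character vector (names = barcodes).
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(barcode = names(labels),
                                cluster = unname(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.fmt_num <- function(x) signif(x, 6)

#' Write simplex coordinates and binned arrow field
#'
#' `coords.tsv` holds barcode, the three barycentric weights and the 2-D
#' projection, barcode-sorted. `arrows.tsv` holds one row per grid bin in
#' row-major order: bin id, centroid, member-cell count and the three
#' mean arrow lengths.
#'
#' @param coords a `simplex_coordinates` object (see
#'   [simplex_coordinates()]).
#' @param arrows a `binned_arrow_field` from [bin_arrows()], or `NULL` to
#'   skip the arrow table.
#' @param dir output directory.
#' @return invisibly, named vector of written paths.
#' @export
write_simplex_outputs <- function(coords, arrows, dir) {
  stopifnot(inherits(coords, "simplex_coordinates"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fates <- colnames(coords$barycentric)
  W <- .fmt_num(coords$barycentric)
  colnames(W) <- paste0("w_", fates)
  cdf <- cbind(data.frame(barcode = rownames(coords$barycentric),
                          stringsAsFactors = FALSE),
               as.data.frame(W),
               data.frame(x = .fmt_num(coords$cartesian[, 1L]),
                          y = .fmt_num(coords$cartesian[, 2L])))
  if (nrow(cdf) == 0L)
    cdf <- stats::setNames(
      as.data.frame(lapply(c("barcode", colnames(W), "x", "y"),
                           function(.) character(0))),
      c("barcode", colnames(W), "x", "y"))
  cdf <- cdf[order(cdf$barcode), , drop = FALSE]
  paths <- c(coords = file.path(dir, "coords.tsv"))
  utils::write.table(cdf, paths["coords"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(arrows)) {
    stopifnot(inherits(arrows, "binned_arrow_field"))
    adf <- arrows$bins
    adf[-1L] <- lapply(adf[-1L], .fmt_num)
    paths["arrows"] <- file.path(dir, "arrows.tsv")
    utils::write.table(adf, paths["arrows"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

#' Read simplex coordinates written by [write_simplex_outputs()]
#' @param path coords.tsv path.
#' @return a `simplex_coordinates` object.
#' @export
read_simplex_coords <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  fates <- sub("^w_", "", names(df)[2:4])
  bary <- as.matrix(df[, 2:4])
  dimnames(bary) <- list(df$barcode, fates)
  xy <- as.matrix(df[, c("x", "y")])
  rownames(xy) <- df$barcode
  structure(list(barycentric = bary, cartesian = xy, fates = fates),
            class = "simplex_coordinates")
}

#' Write a sparse velocity graph as (i, j, w) triplets
#' @param graph a `velocity_graph` object (see [velocity_graph()]).
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_velocity_graph <- function(graph, path) {
  stopifnot(inherits(graph, "velocity_graph"))
  tr <- Matrix::summary(graph$weights)
  tr <- tr[order(tr$i, tr$j), , drop = FALSE]
  utils::write.table(data.frame(i = tr$i, j = tr$j, w = .fmt_num(tr$x)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sparse velocity graph from (i, j, w) triplets
#' @param path triplet TSV path.
#' @param n number of cells (graph dimension).
#' @param barcodes optional barcode names for the rows/columns.
#' @return a `velocity_graph` object.
#' @export
read_velocity_graph <- function(path, n, barcodes = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  w <- Matrix::sparseMatrix(i = df$i, j = df$j, x = df$w, dims = c(n, n))
  if (!is.null(barcodes)) dimnames(w) <- list(barcodes, barcodes)
  structure(list(weights = w), class = "velocity_graph")
}
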