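## Three-fate simplex scoring: per-cell mean Euclidean distance to the
## apex clusters, -log10 + per-fate min-max similarity transform,
## per-cell renormalization to barycentric coordinates, and the 2-D
## ternary projection.

#' Apex specification: three fates and their defining clusters
#'
#' Fixes the three simplex vertices. Vertex order is fate1 = top,
#' fate2 = bottom-left, fate3 = bottom-right in the 2-D projection.
#'
#' @param clusters named character vector of length 3 mapping fate names
#'   to cluster labels, e.g.
#'   `c(osteoblast = "Osteoblast_1", chondrocyte = "Chondrocyte_1",
#'   reticular = "Reticular_1")`. Labels must be distinct.
#' @return object of class `apex_spec`.
#' @export
apex_spec <- function(clusters) {
  if (length(clusters) != 3L || is.null(names(clusters)) ||
      any(!nzchar(names(clusters))))
    stop("clusters must be 3 named fate -> cluster-label pairs")
  if (anyDuplicated(clusters)) stop("apex cluster labels must be distinct")
  if (anyDuplicated(names(clusters))) stop("fate names must be distinct")
  structure(list(clusters = as.character(stats::setNames(clusters,
                                                         names(clusters))),
                 fates = names(clusters)),
            class = "apex_spec")
}

#' @export
print.apex_spec <- function(x, ...) {
  cat("apex_spec:", paste(x$fates, x$clusters, sep = " = ",
                          collapse = "; "), "\n")
  invisible(x)
}

.apex_cells <- function(apex, labels) {
  cells <- lapply(apex$clusters, function(cl) names(labels)[labels == cl])
  names(cells) <- apex$fates
  sizes <- lengths(cells)
  if (any(sizes == 0L))
    stop("empty apex cluster(s): ",
         paste(apex$clusters[sizes == 0L], collapse = ", "))
  cells
}

#' Union of top-k marker features of the three apex clusters
#'
#' Deduplicated in stable order (fate1's ranked list first, then new
#' features from fate2, then fate3).
#'
#' @param stats_list named list of `marker_stats`, one per fate (see
#'   [apex_marker_stats()]).
#' @param k top-k per cluster (default 30).
#' @param mode passed to [top_k_markers()].
#' @return character vector of feature ids (at most `3 * k`).
#' @export
fate_feature_space <- function(stats_list, k = 30, mode = "genes") {
  stopifnot(length(stats_list) == 3L)
  lists <- lapply(stats_list, top_k_markers, k = k, mode = mode)
  feats <- unique(unlist(lists, use.names = FALSE))
  if (length(feats) == 0L) stop("empty fate feature union")
  feats
}

#' Mean Euclidean distance from every cell to each apex cluster
#'
#' `D[i, f]` is the average distance between cell i and all cells of
#' apex cluster f. A cell belonging to cluster f contributes its own
#' zero self-distance to that average unless `exclude_self = TRUE`.
#'
#' @param scaled a `scaled_matrix` (restricted to the fate feature
#'   space) or plain cells x features matrix with barcode rownames.
#' @param apex an [apex_spec()].
#' @param labels per-cell cluster labels named by barcode.
#' @param exclude_self drop a cell's own zero term from its cluster's
#'   average (default `FALSE`: all cells included).
#' @return n x 3 matrix of mean distances, columns in fate order.
#' @export
mean_distance_to_apex <- function(scaled, apex, labels,
                                  exclude_self = FALSE) {
  stopifnot(inherits(apex, "apex_spec"))
  m <- if (inherits(scaled, "scaled_matrix")) scaled$values else scaled
  m <- as.matrix(m)
  cells <- .apex_cells(apex, labels)
  sq <- rowSums(m^2)
  D <- matrix(0, nrow(m), 3L,
              dimnames = list(rownames(m), apex$fates))
  for (f in seq_len(3L)) {
    ai <- match(cells[[f]], rownames(m))
    if (anyNA(ai)) stop("apex cells missing from matrix for fate ",
                        apex$fates[f])
    A <- m[ai, , drop = FALSE]
    ## pairwise distances via the expansion |x - a|^2 = |x|^2 - 2x.a + |a|^2
    cross <- m %*% t(A)
    d2 <- pmax(outer(sq, rowSums(A^2), `+`) - 2 * cross, 0)
    dd <- sqrt(d2)
    if (exclude_self) {
      self <- cbind(ai, seq_along(ai))
      dd[self] <- NA
      D[, f] <- rowMeans(dd, na.rm = TRUE)
    } else {
      D[, f] <- rowMeans(dd)
    }
  }
  D
}

#' Distance-to-similarity transform: -log10 then per-fate min-max
#'
#' Distances are floored at `floor` (so zero self-distances stay
#' finite), transformed with `-log10`, and min-max rescaled to \[0, 1\]
#' within each fate column; larger means more similar. A constant column
#' is set to 0.5 with a warning.
#'
#' @param D n x 3 nonnegative distance matrix.
#' @param floor lower floor applied before the log (default 1e-12).
#' @return n x 3 similarity matrix in \[0, 1\].
#' @export
similarity_transform <- function(D, floor = 1e-12) {
  stopifnot(all(D >= 0))
  S <- -log10(pmax(D, floor))
  for (f in seq_len(ncol(S))) {
    rng <- range(S[, f])
    if (rng[1] == rng[2]) {
      warning("constant distance column ", f, "; similarity set to 0.5")
      S[, f] <- 0.5
    } else {
      S[, f] <- (S[, f] - rng[1]) / (rng[2] - rng[1])
    }
  }
  S
}

#' Renormalize similarity rows to barycentric weights
#'
#' Each cell's three similarities are divided by their sum so the
#' coordinates sum to unity (100%). An all-zero row falls back to the
#' centroid (1/3, 1/3, 1/3) and is flagged.
#'
#' @param S n x 3 nonnegative similarity matrix.
#' @return n x 3 barycentric matrix with attribute `flagged` (logical,
#'   cells that had zero total similarity).
#' @export
renormalize_rows <- function(S) {
  stopifnot(all(S >= 0))
  tot <- rowSums(S)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total similarity set to the",
            " simplex centroid")
    S[zero, ] <- 1
    tot[zero] <- 3
  }
  W <- S / tot
  attr(W, "flagged") <- zero
  W
}

## reference triangle: fate1 top, fate2 bottom-left, fate3 bottom-right
.simplex_vertices <- function() {
  matrix(c(0.5, sqrt(3) / 2,
           0,   0,
           1,   0), nrow = 3L, byrow = TRUE)
}

#' Project barycentric weights to 2-D ternary coordinates
#'
#' Vertices sit at fate1 = (0.5, sqrt(3)/2), fate2 = (0, 0),
#' fate3 = (1, 0); a point is the weight-convex combination of the
#' vertices.
#'
#' @param barycentric n x 3 matrix with rows summing to 1.
#' @return n x 2 matrix of Cartesian coordinates.
#' @export
to_cartesian <- function(barycentric) {
  stopifnot(ncol(barycentric) == 3L)
  if (nrow(barycentric) > 0 &&
      max(abs(rowSums(barycentric) - 1)) > 1e-6)
    stop("barycentric rows must sum to 1")
  xy <- barycentric %*% .simplex_vertices()
  colnames(xy) <- c("x", "y")
  xy
}

#' Full simplex scoring: distances to similarities to coordinates
#'
#' Runs [mean_distance_to_apex()], [similarity_transform()],
#' [renormalize_rows()] and [to_cartesian()] over the fate feature
#' space and returns the assembled coordinate object.
#'
#' @param scaled a `scaled_matrix` over all selected features.
#' @param features fate feature space (from [fate_feature_space()]);
#'   intersected with the available columns.
#' @param apex an [apex_spec()].
#' @param labels per-cell cluster labels named by barcode.
#' @param exclude_self passed to [mean_distance_to_apex()].
#' @param floor passed to [similarity_transform()].
#' @return object of class `simplex_coordinates`: `barycentric` (n x 3),
#'   `cartesian` (n x 2), `fates`, `distances`, `flagged`.
#' @export
simplex_coordinates <- function(scaled, features, apex, labels,
                                exclude_self = FALSE, floor = 1e-12) {
  m <- if (inherits(scaled, "scaled_matrix")) scaled$values else scaled
  feats <- intersect(features, colnames(m))
  if (length(feats) == 0L) stop("no fate features present in the matrix")
  D <- mean_distance_to_apex(m[, feats, drop = FALSE], apex, labels)
  S <- similarity_transform(D, floor = floor)
  W <- renormalize_rows(S)
  flagged <- attr(W, "flagged")
  attr(W, "flagged") <- NULL
  xy <- to_cartesian(W)
  rownames(xy) <- rownames(W)
  structure(list(barycentric = W, cartesian = xy, fates = apex$fates,
                 distances = D, flagged = flagged),
            class = "simplex_coordinates")
}

#' @export
print.simplex_coordinates <- function(x, ...) {
  cat("simplex_coordinates:", nrow(x$barycentric), "cells; fates:",
      paste(x$fates, collapse = ", "), "\n")
  invisible(x)
}
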