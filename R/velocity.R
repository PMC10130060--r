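## Steady-state RNA velocity: extreme-quantile through-origin regression
## for per-gene degradation ratios, the residual velocity field, the
## clipped-cosine velocity graph over the KNN, the per-apex averaged fate
## potential, and the binned simplex arrow field.

#' First-order KNN moments of expression layers
#'
#' Replaces each cell's value by the mean over the cell and its K
#' nearest neighbors, per layer. This is the moment-smoothing step the
#' steady-state fit operates on: averaging over the neighborhood
#' suppresses the count noise that would otherwise attenuate the
#' through-origin slope (errors-in-variables bias).
#'
#' @param layers named list of cells x genes matrices (e.g. from
#'   [normalize_layers()]).
#' @param knn a `neighbor_graph` from [pca_knn_graph()] over the same
#'   cells.
#' @return named list of smoothed dense matrices.
#' @export
knn_smooth_layers <- function(layers, knn) {
  stopifnot(inherits(knn, "neighbor_graph"))
  n <- nrow(knn$idx); k <- ncol(knn$idx)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1L),
                            j = c(seq_len(n), as.vector(knn$idx)),
                            x = 1 / (k + 1), dims = c(n, n))
  lapply(layers, function(m) {
    stopifnot(nrow(m) == n)
    out <- as.matrix(A %*% m)
    dimnames(out) <- dimnames(m)
    out
  })
}

#' Fit per-gene degradation ratios under the steady-state model
#'
#' For each gene, cells in the top and bottom `extreme_quantile` of
#' spliced + unspliced abundance are assumed to sit on the steady-state
#' line u = gamma * s (splicing rate fixed at 1); gamma is the
#' through-origin least-squares slope `sum(u*s) / sum(s^2)` over those
#' cells. Genes with no spliced signal on the extreme set are flagged
#' `NA` and excluded downstream.
#'
#' @param spliced,unspliced cells x genes normalized (log-free) matrices
#'   of equal shape.
#' @param extreme_quantile fraction in (0, 0.5) of cells taken from each
#'   end (default 0.05).
#' @return named numeric vector of gamma per gene (`NA` = undefined).
#' @export
fit_gamma_steady_state <- function(spliced, unspliced,
                                   extreme_quantile = 0.05) {
  stopifnot(all(dim(spliced) == dim(unspliced)),
            extreme_quantile > 0, extreme_quantile < 0.5)
  s <- as.matrix(spliced); u <- as.matrix(unspliced)
  n <- nrow(s)
  n_ext <- max(1L, ceiling(extreme_quantile * n))
  gamma <- vapply(seq_len(ncol(s)), function(jj) {
    tot <- s[, jj] + u[, jj]
    o <- order(tot)
    sel <- c(utils::head(o, n_ext), utils::tail(o, n_ext))
    ss <- s[sel, jj]; uu <- u[sel, jj]
    den <- sum(ss^2)
    if (den == 0) NA_real_ else sum(uu * ss) / den
  }, numeric(1))
  names(gamma) <- colnames(s)
  gamma
}

#' Velocity field from the steady-state residual
#'
#' `v = u - gamma * s` on the normalized, log-free layers. Genes with
#' undefined gamma are flagged and carry zero velocity.
#'
#' @param spliced,unspliced cells x genes normalized matrices.
#' @param gamma per-gene degradation ratios from
#'   [fit_gamma_steady_state()].
#' @return list of class `velocity_field`: `velocity` (cells x genes),
#'   `gamma`, `valid` (logical per gene).
#' @export
compute_velocity <- function(spliced, unspliced, gamma) {
  s <- as.matrix(spliced); u <- as.matrix(unspliced)
  stopifnot(ncol(s) == length(gamma))
  valid <- !is.na(gamma)
  g0 <- ifelse(valid, gamma, 0)
  v <- u - sweep(s, 2L, g0, `*`)
  v[, !valid] <- 0
  dimnames(v) <- dimnames(s)
  structure(list(velocity = v, gamma = gamma, valid = valid),
            class = "velocity_field")
}

#' Cosine velocity graph over the KNN
#'
#' For each cell i and neighbor j, the edge weight is the cosine between
#' i's velocity vector and the expression displacement `x_j - x_i`,
#' clipped below at 0 so weights lie in \[0, 1\]; the cosine against a
#' zero vector is defined as 0. Only velocity-valid genes enter the
#' cosines.
#'
#' @param field a `velocity_field` from [compute_velocity()].
#' @param expression cells x genes normalized spliced matrix (same gene
#'   order as the field).
#' @param knn a `neighbor_graph` from [pca_knn_graph()] over the same
#'   cells.
#' @return list of class `velocity_graph`: `weights`, a sparse n x n
#'   matrix with zero diagonal and nonzeros only on KNN edges.
#' @export
velocity_graph <- function(field, expression, knn) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(knn, "neighbor_graph"))
  x <- as.matrix(expression)[, field$valid, drop = FALSE]
  v <- field$velocity[, field$valid, drop = FALSE]
  n <- nrow(x)
  stopifnot(nrow(knn$idx) == n)
  k <- ncol(knn$idx)
  ii <- rep(seq_len(n), each = k)
  jj <- as.vector(t(knn$idx))
  w <- numeric(length(ii))
  vnorm <- sqrt(rowSums(v^2))
  for (i in seq_len(n)) {
    if (vnorm[i] == 0) next
    nb <- knn$idx[i, ]
    delta <- x[nb, , drop = FALSE] -
      matrix(x[i, ], k, ncol(x), byrow = TRUE)
    dnorm <- sqrt(rowSums(delta^2))
    cosv <- as.vector(delta %*% v[i, ]) / (dnorm * vnorm[i])
    cosv[dnorm == 0] <- 0
    w[(i - 1L) * k + seq_len(k)] <- pmax(0, cosv)
  }
  keep <- w > 0
  weights <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = w[keep],
                                  dims = c(n, n),
                                  dimnames = list(rownames(x), rownames(x)))
  structure(list(weights = weights), class = "velocity_graph")
}

#' Fate potential: averaged velocity-graph weight toward each apex
#'
#' `P[i, f]` is the mean velocity-graph edge weight from cell i to all
#' cells of apex cluster f; edges absent from the KNN contribute 0
#' (dense-mean semantics). With `edge_mean = TRUE` the mean runs over
#' existing edges only. Rows are then normalized within each cell; a
#' cell with zero total potential is flagged instead.
#'
#' @param graph a `velocity_graph`.
#' @param apex an [apex_spec()].
#' @param labels per-cell cluster labels named by barcode, aligned with
#'   the graph.
#' @param edge_mean average over existing KNN edges only (default
#'   `FALSE`).
#' @return list of class `fate_potential`: `raw` (n x 3), `normalized`
#'   (n x 3; flagged rows NA), `flagged` (logical).
#' @export
fate_potential <- function(graph, apex, labels, edge_mean = FALSE) {
  stopifnot(inherits(graph, "velocity_graph"),
            inherits(apex, "apex_spec"))
  W <- graph$weights
  n <- nrow(W)
  if (!is.null(rownames(W)) && !is.null(names(labels)))
    labels <- labels[rownames(W)]
  stopifnot(length(labels) == n)
  member <- sapply(apex$clusters, function(cl) as.numeric(labels == cl))
  sizes <- colSums(member)
  if (any(sizes == 0))
    stop("empty apex cluster(s): ",
         paste(apex$clusters[sizes == 0], collapse = ", "))
  num <- as.matrix(W %*% member)
  if (edge_mean) {
    present <- W
    present@x <- rep(1, length(present@x))
    den <- as.matrix(present %*% member)
    P <- ifelse(den > 0, num / den, 0)
  } else {
    P <- sweep(num, 2L, sizes, `/`)
  }
  colnames(P) <- apex$fates
  rownames(P) <- rownames(W)
  tot <- rowSums(P)
  flagged <- tot == 0
  Pn <- P / ifelse(tot > 0, tot, NA)
  structure(list(raw = P, normalized = Pn, flagged = flagged),
            class = "fate_potential")
}

## factor pair of n_bins closest to an 8:5 aspect (nx columns, ny rows)
.bin_grid_shape <- function(n_bins) {
  divs <- which(n_bins %% seq_len(n_bins) == 0)
  pairs <- cbind(nx = divs, ny = n_bins / divs)
  score <- abs(log(pairs[, "nx"] / pairs[, "ny"]) - log(8 / 5))
  pairs[which.min(score), ]
}

#' Bin the simplex into a grid and average fate potentials per bin
#'
#' Lays a rectangular grid over the bounding box of the projected
#' triangle -- 8 x 5 = 40 locations by default; other `n_bins` use the
#' factor pair nearest an 8:5 aspect -- assigns every cell to one bin by
#' its Cartesian point (right/top edges inclusive in the last
#' column/row), and sets each bin's three arrow lengths to the mean
#' normalized fate potential of its member cells. Flagged
#' (zero-potential) cells are excluded from the means but still counted
#' as members of their bin.
#'
#' @param coords a `simplex_coordinates` object.
#' @param potential a `fate_potential` over the same cells.
#' @param n_bins total number of grid locations (default 40).
#' @return list of class `binned_arrow_field`: `bins` (data.frame with
#'   `bin_id`, `bin_x`, `bin_y`, `n_cells`, one `len_<fate>` column per
#'   fate; row-major order), `shape` (nx, ny), `assignment` (per-cell
#'   bin id).
#' @export
bin_arrows <- function(coords, potential, n_bins = 40) {
  stopifnot(inherits(coords, "simplex_coordinates"),
            inherits(potential, "fate_potential"))
  if (n_bins < 1) stop("n_bins must be >= 1")
  xy <- coords$cartesian
  stopifnot(nrow(xy) == nrow(potential$normalized))
  shape <- .bin_grid_shape(n_bins)
  nx <- shape[["nx"]]; ny <- shape[["ny"]]
  ## bounding box of the reference triangle, fixed across runs
  vx <- .simplex_vertices()
  xr <- range(vx[, 1L]); yr <- range(vx[, 2L])
  ix <- pmin(nx, 1L + floor((xy[, 1L] - xr[1L]) / diff(xr) * nx))
  iy <- pmin(ny, 1L + floor((xy[, 2L] - yr[1L]) / diff(yr) * ny))
  ix <- pmax(1L, ix); iy <- pmax(1L, iy)
  bin <- (iy - 1L) * nx + ix  # row-major, bottom row first
  cx <- xr[1L] + (seq_len(nx) - 0.5) / nx * diff(xr)
  cy <- yr[1L] + (seq_len(ny) - 0.5) / ny * diff(yr)
  fates <- coords$fates
  bins <- data.frame(bin_id = seq_len(n_bins),
                     bin_x = rep(cx, times = ny),
                     bin_y = rep(cy, each = nx),
                     n_cells = 0L)
  for (f in fates) bins[[paste0("len_", f)]] <- 0
  cnt <- table(factor(bin, levels = seq_len(n_bins)))
  bins$n_cells <- as.integer(cnt)
  use <- !potential$flagged
  if (any(use)) {
    Pn <- potential$normalized[use, , drop = FALSE]
    bu <- factor(bin[use], levels = seq_len(n_bins))
    for (f in seq_along(fates)) {
      mn <- tapply(Pn[, f], bu, mean)
      mn[is.na(mn)] <- 0
      bins[[paste0("len_", fates[f])]] <- as.numeric(mn)
    }
  }
  structure(list(bins = bins, shape = c(nx = nx, ny = ny),
                 assignment = stats::setNames(bin, rownames(xy))),
            class = "binned_arrow_field")
}
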