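test_that("steady-state fit recovers a noiseless slope exactly", {
  set.seed(6)
  s <- matrix(runif(40 * 3, 1, 10), 40, 3)
  u <- s * 0.7
  g <- fit_gamma_steady_state(s, u, extreme_quantile = 0.1)
  expect_equal(unname(g), rep(0.7, 3), tolerance = 1e-12)
  ## a silent gene is flagged undefined
  s2 <- cbind(s[, 1], 0)
  u2 <- cbind(u[, 1], runif(40))
  g2 <- fit_gamma_steady_state(s2, u2)
  expect_false(is.na(g2[1]))
  expect_true(is.na(g2[2]))
})

test_that("velocity is the residual u - gamma * s with flagged genes zeroed", {
  s <- rbind(c(2, 1), c(4, 3))
  u <- rbind(c(2, 5), c(4, 6))
  f <- compute_velocity(s, u, c(0.5, NA))
  expect_equal(f$velocity[, 1], c(1, 2))   # u = 2, gamma = 0.5, s = 2 -> 1
  expect_equal(f$velocity[, 2], c(0, 0))   # undefined gamma -> zero, flagged
  expect_equal(f$valid, c(TRUE, FALSE))
  ## u = gamma * s everywhere -> identically zero velocity
  f0 <- compute_velocity(s, s * 0.3, c(0.3, 0.3))
  expect_equal(max(abs(f0$velocity)), 0)
  ## linearity check on random matrices: v(2u) = 2 v(u) + gamma * s
  set.seed(13)
  ss <- matrix(runif(20), 5, 4); uu <- matrix(runif(20), 5, 4)
  gg <- runif(4, 0.2, 1)
  v1 <- compute_velocity(ss, uu, gg)$velocity
  v2 <- compute_velocity(ss, 2 * uu, gg)$velocity
  expect_equal(v2, 2 * v1 + sweep(ss, 2, gg, `*`), tolerance = 1e-12)
})

toy_knn <- function(idx, emb = NULL) {
  structure(list(idx = idx,
                 dist = matrix(1, nrow(idx), ncol(idx)),
                 embedding = emb, k = ncol(idx)),
            class = "neighbor_graph")
}

test_that("velocity graph is the clipped cosine against neighbor displacements", {
  x <- rbind(c(0, 0), c(1, 0), c(0, 1))
  rownames(x) <- paste0("c", 1:3)
  v <- rbind(c(1, 0), c(0, 0), c(0, -1))
  field <- structure(list(velocity = v, gamma = c(1, 1),
                          valid = c(TRUE, TRUE)),
                     class = "velocity_field")
  knn <- toy_knn(rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L)))
  g <- velocity_graph(field, x, knn)
  w <- as.matrix(g$weights)
  ## v_1 points exactly at cell 2 -> weight 1; orthogonal-ish to cell 3
  expect_equal(w[1, 2], 1)
  expect_equal(w[1, 3], 0)  # cos 135 deg clipped at 0
  ## zero velocity -> all weights zero for that cell
  expect_equal(sum(w[2, ]), 0)
  ## cell 3 moving away from both neighbors gets clipped weights
  expect_true(all(w >= 0 & w <= 1))
  expect_equal(unname(diag(w)), rep(0, 3))
  ## sparsity never exceeds n * K
  expect_lte(length(g$weights@x), 3 * 2)
})

test_that("fate potential averages edge weights with dense-mean semantics", {
  ## 5-cell toy: clusters A = {1, 2}, B = {3, 4}, C = {5}; hand weights
  w <- Matrix::sparseMatrix(i = c(5, 5, 5, 1, 2),
                            j = c(1, 3, 4, 3, 5),
                            x = c(0.8, 0.4, 0.2, 0.6, 1.0),
                            dims = c(5, 5))
  dimnames(w) <- list(paste0("c", 1:5), paste0("c", 1:5))
  g <- structure(list(weights = w), class = "velocity_graph")
  labels <- setNames(c("A", "A", "B", "B", "C"), paste0("c", 1:5))
  ap <- apex_spec(c(a = "A", b = "B", c = "C"))
  pot <- fate_potential(g, ap, labels)
  ## dense brute force: mean over cluster members incl. structural zeros
  dense <- as.matrix(w)
  for (i in 1:5) {
    expect_equal(unname(pot$raw[i, "a"]), mean(dense[i, 1:2]))
    expect_equal(unname(pot$raw[i, "b"]), mean(dense[i, 3:4]))
    expect_equal(unname(pot$raw[i, "c"]), dense[i, 5])
  }
  ## cell 5: raw (0.4, 0.3, 0) -> normalized (4/7, 3/7, 0)
  expect_equal(unname(pot$normalized["c5", ]), c(4, 3, 0) / 7)
  ## unflagged rows sum to one; all-zero rows are flagged
  sums <- rowSums(pot$normalized[!pot$flagged, , drop = FALSE])
  expect_equal(unname(sums), rep(1, sum(!pot$flagged)), tolerance = 1e-12)
  expect_true(pot$flagged[["c4"]])
  ## the empty graph flags every cell
  g0 <- structure(list(weights = w * 0), class = "velocity_graph")
  pot0 <- fate_potential(g0, ap, labels)
  expect_true(all(pot0$flagged))
  expect_equal(max(pot0$raw), 0)
  ## edge-mean semantics divide by existing edges only
  pot_e <- fate_potential(g, ap, labels, edge_mean = TRUE)
  expect_equal(unname(pot_e$raw["c5", "b"]), mean(c(0.4, 0.2)))
  expect_equal(unname(pot_e$raw["c1", "b"]), 0.6)
})

test_that("default binning has 40 locations and matches brute-force grouping", {
  r <- small_sim(seed = 14)
  norm <- normalize_and_log(r$bundle)
  sc <- scale_no_center(norm)
  stats <- apex_marker_stats(norm, r$labels, default_apex())
  feats <- fate_feature_space(stats, k = 30)
  co <- simplex_coordinates(sc, feats, default_apex(), r$labels)
  n <- nrow(co$barycentric)
  set.seed(1)
  P <- matrix(runif(n * 3), n, 3, dimnames = list(rownames(co$barycentric),
                                                  co$fates))
  P <- P / rowSums(P)
  pot <- structure(list(raw = P, normalized = P,
                        flagged = rep(FALSE, n)),
                   class = "fate_potential")
  arr <- bin_arrows(co, pot, n_bins = 40)
  expect_equal(nrow(arr$bins), 40L)
  expect_equal(unname(arr$shape), c(8L, 5L))
  ## independent floor-arithmetic binning oracle
  expect_equal(unname(arr$assignment),
               unname(brute_bin_assign(co$cartesian, 8, 5)))
  for (b in seq_len(40)) {
    members <- which(arr$assignment == b)
    expect_equal(arr$bins$n_cells[b], length(members))
    if (length(members) > 0)
      expect_equal(unname(as.numeric(arr$bins[b, 5:7])),
                   unname(colMeans(P[members, , drop = FALSE])))
    else
      expect_equal(sum(arr$bins[b, 5:7]), 0)
  }
  ## conservation: count-weighted bin arrows equal the summed potentials
  tot <- colSums(arr$bins$n_cells * as.matrix(arr$bins[, 5:7]))
  expect_equal(unname(tot), unname(colSums(P)), tolerance = 1e-9)
  ## a single-cell bin carries exactly that cell's potential
  singles <- which(arr$bins$n_cells == 1)
  if (length(singles) > 0) {
    b <- singles[1]
    cell <- names(arr$assignment)[arr$assignment == b]
    expect_equal(unname(as.numeric(arr$bins[b, 5:7])),
                 unname(P[cell, ]))
  }
  ## non-default sizes keep the nearest-8:5 factorization rule
  expect_equal(unname(bin_arrows(co, pot, 12)$shape), c(4L, 3L))
  expect_error(bin_arrows(co, pot, 0), "n_bins")
})

test_that("stronger induction does not weaken the destined-fate potential", {
  mean_destined <- function(delta) {
    sim <- sim_params(induction_delta = delta, seed = 1)
    res <- suppressWarnings(run_pipeline(pipeline_config(sim = sim,
                                                         seed = 1),
                                         write = FALSE))
    tr <- res$truth
    trans <- names(tr$destined_fate)[!is.na(tr$destined_fate)]
    trans <- intersect(trans, rownames(res$potential$raw))
    mean(res$potential$raw[cbind(trans,
                                 tr$destined_fate[trans])])
  }
  m <- vapply(c(0.1, 0.5, 0.9), mean_destined, numeric(1))
  expect_true(all(diff(m) > -1e-6))
})
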