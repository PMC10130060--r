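make_bundle <- function(m, u = NULL) {
  dimnames(m) <- list(sprintf("c%02d", seq_len(nrow(m))),
                      sprintf("g%02d", seq_len(ncol(m))))
  layers <- list(spliced = m)
  if (!is.null(u)) { dimnames(u) <- dimnames(m); layers$unspliced <- u }
  expression_bundle(layers, rownames(m), colnames(m))
}

test_that("gene filtering keeps the inclusive >= 10 boundary", {
  m <- cbind(c(4, 5), c(5, 5), c(6, 5))  # totals 9, 10, 11
  b <- filter_genes(make_bundle(m), min_counts = 10)
  expect_equal(b$genes, c("g02", "g03"))
  ## min_counts = 0 is the identity
  expect_equal(filter_genes(make_bundle(m), 0)$genes,
               c("g01", "g02", "g03"))
  expect_error(filter_genes(make_bundle(m), 1e6), "min_counts")
})

test_that("filtering matches the brute-force column-sum rule and subsets all layers", {
  set.seed(1)
  m <- matrix(rpois(50 * 20, 0.8), 50, 20)
  u <- matrix(rpois(50 * 20, 0.5), 50, 20)
  b <- make_bundle(m, u)
  f <- filter_genes(b, 10)
  keep <- which(colSums(m) >= 10)
  expect_equal(f$genes, sprintf("g%02d", keep))
  expect_equal(as.matrix(f$layers$unspliced),
               matrix(u[, keep], 50,
                      dimnames = list(b$barcodes, f$genes)))
})

test_that("median-total normalization matches the hand computation", {
  m <- rbind(c(10, 90), c(40, 160))  # totals 100, 200; median 150
  norm <- normalize_and_log(make_bundle(m))
  expect_equal(norm[1, 1], log1p(10 * 1.5))
  expect_equal(norm[2, 2], log1p(160 * 0.75))
  ## equal totals => factor 1; zeros stay zero
  m2 <- rbind(c(5, 5, 0), c(4, 6, 0))
  n2 <- normalize_and_log(make_bundle(m2), log = FALSE)
  expect_equal(as.matrix(n2), m2, ignore_attr = TRUE)
  expect_true(all(n2[, 3] == 0))
  ## zero-total cell removed with a warning
  m3 <- rbind(c(1, 2), c(0, 0))
  expect_warning(n3 <- normalize_and_log(make_bundle(m3)), "zero-total")
  expect_equal(nrow(n3), 1L)
})

test_that("variable features rank by variance-to-mean dispersion", {
  m <- cbind(c(0, 0, 8), c(2, 2, 2), c(1, 2, 3), c(0, 4, 8), c(5, 5, 5))
  dimnames(m) <- list(paste0("c", 1:3), paste0("g", 1:5))
  mu <- colMeans(m); v <- apply(m, 2, var)
  hand <- names(sort(v / mu, decreasing = TRUE))
  ## only the three informative (nonzero-dispersion) features come back
  expect_warning(got <- select_variable_features(m, 5), "informative")
  expect_equal(got, hand[1:3])
  ## constants are never selected while informative features remain
  expect_false("g2" %in% select_variable_features(m, 3))
  expect_false("g5" %in% select_variable_features(m, 3))
})

test_that("non-centered scaling divides by the n-1 RMS and is idempotent", {
  m <- matrix(c(3, 4), 2, 1, dimnames = list(c("c1", "c2"), "gA"))
  sc <- scale_no_center(m)
  expect_equal(unname(sc$scale_factors), 5)  # sqrt(25 / 1)
  expect_equal(as.numeric(sc$values), c(0.6, 0.8))
  ## second application changes nothing beyond 1e-12
  sc2 <- scale_no_center(as.matrix(sc$values))
  expect_equal(as.matrix(sc2$values), as.matrix(sc$values),
               tolerance = 1e-12)
  ## nonnegative input stays nonnegative; zero feature gets factor 1
  m2 <- cbind(a = c(2, 1), b = c(0, 0))
  rownames(m2) <- c("c1", "c2")
  expect_warning(sc3 <- scale_no_center(m2), "all-zero")
  expect_equal(unname(sc3$scale_factors["b"]), 1)
  expect_true(all(as.matrix(sc3$values) >= 0))
})

test_that("promoter window boundaries follow the 3 kb upstream rule", {
  ann <- data.frame(gene_id = "gA", contig = "chr1",
                    start = 10000L, end = 12000L, strand = "+")
  fr <- data.frame(contig = "chr1",
                   start = c(7001L, 6900L),
                   end = c(7050L, 6999L),
                   barcode = "b1", count = c(1L, 1L))
  ga <- gene_activity_from_fragments(fr, ann)
  ## window [7000, 12000): first fragment overlaps, second ends at 6999
  expect_equal(as.numeric(ga["b1", "gA"]), 1)
  ## empty fragment list -> all-zero matrix
  ga0 <- gene_activity_from_fragments(fr[0, ], ann, barcodes = "b1")
  expect_equal(sum(ga0), 0)
  expect_equal(dim(ga0), c(1L, 1L))
})

test_that("gene activity equals the brute-force overlap oracle", {
  set.seed(99)
  for (rep in 1:20) {
    n_genes <- sample(2:4, 1)
    ann <- data.frame(
      gene_id = paste0("g", seq_len(n_genes)),
      contig = sample(c("chr1", "chr2"), n_genes, replace = TRUE),
      start = as.integer(sample(3000:20000, n_genes)),
      strand = sample(c("+", "-"), n_genes, replace = TRUE))
    ann$end <- ann$start + as.integer(sample(500:5000, n_genes))
    fr <- data.frame(
      contig = sample(c("chr1", "chr2", "chr3"), 20, replace = TRUE),
      start = as.integer(sample(0:25000, 20)),
      barcode = sample(c("b1", "b2", "b3"), 20, replace = TRUE))
    fr$end <- fr$start + as.integer(sample(20:200, 20, replace = TRUE))
    fr$count <- sample(1:3, 20, replace = TRUE)
    bcs <- c("b1", "b2", "b3")
    got <- suppressMessages(
      gene_activity_from_fragments(fr, ann, barcodes = bcs))
    expect_equal(as.matrix(got), brute_gene_activity(fr, ann, 3000, bcs),
                 ignore_attr = TRUE)
  }
})

test_that("permuting fragment rows leaves gene activity unchanged", {
  set.seed(4)
  ann <- toy_annotation()
  fr <- data.frame(contig = sample(c("chr1", "chr2"), 30, replace = TRUE),
                   start = as.integer(sample(4000:54000, 30)),
                   barcode = sample(c("b1", "b2"), 30, replace = TRUE))
  fr$end <- fr$start + 100L
  fr$count <- 1L
  a <- suppressMessages(gene_activity_from_fragments(fr, ann,
                                                     barcodes = c("b1", "b2")))
  b <- suppressMessages(gene_activity_from_fragments(fr[sample(30), ], ann,
                                                     barcodes = c("b1", "b2")))
  expect_equal(as.matrix(a), as.matrix(b))
})

test_that("KNN on collinear points matches the hand distance table", {
  m <- matrix(c(0, 1, 3, 7), 4, 1)
  m <- cbind(m, 0)  # 2nd dim so PCA has rank
  rownames(m) <- paste0("c", 1:4)
  g <- pca_knn_graph(m, n_pcs = 1, k = 1)
  expect_equal(as.integer(g$idx), c(2L, 1L, 2L, 3L))
  ## k = n - 1 gives the complete graph minus self-loops
  g3 <- pca_knn_graph(m, n_pcs = 1, k = 3)
  for (i in 1:4) expect_setequal(g3$idx[i, ], setdiff(1:4, i))
  expect_error(pca_knn_graph(m, k = 4), "smaller")
})
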