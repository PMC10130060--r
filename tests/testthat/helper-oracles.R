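## Independent oracles used across test files. Each is a deliberately
## naive implementation (enumeration / O(n*m) loops) that never shares
## code with the package path it checks.

## Exact two-sided Mann-Whitney p by enumeration of all C(n, n1) group
## assignments of the pooled values (ties handled via midranks).
exact_wilcox_p <- function(x1, x2) {
  pooled <- c(x1, x2)
  n1 <- length(x1)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2L, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

## O(fragments x genes) gene-activity counter by direct interval checks.
brute_gene_activity <- function(fragments, annotation, upstream_bp = 3000,
                                barcodes = sort(unique(fragments$barcode))) {
  out <- matrix(0, length(barcodes), nrow(annotation),
                dimnames = list(barcodes, annotation$gene_id))
  if (nrow(fragments) == 0L) return(out)
  for (r in seq_len(nrow(fragments))) {
    for (g in seq_len(nrow(annotation))) {
      if (fragments$contig[r] != annotation$contig[g]) next
      if (annotation$strand[g] == "+") {
        w0 <- max(0, annotation$start[g] - upstream_bp)
        w1 <- annotation$end[g]
      } else {
        w0 <- annotation$start[g]
        w1 <- annotation$end[g] + upstream_bp
      }
      ## 0-based half-open intervals overlap by >= 1 bp
      if (fragments$start[r] < w1 && fragments$end[r] > w0) {
        ci <- match(fragments$barcode[r], barcodes)
        out[ci, g] <- out[ci, g] + fragments$count[r]
      }
    }
  }
  out
}

## Row-major rectangular binning of points over the triangle bounding
## box by plain floor arithmetic.
brute_bin_assign <- function(xy, nx, ny) {
  xr <- c(0, 1); yr <- c(0, sqrt(3) / 2)
  ix <- 1 + floor((xy[, 1] - xr[1]) / diff(xr) * nx)
  iy <- 1 + floor((xy[, 2] - yr[1]) / diff(yr) * ny)
  ix <- pmin(pmax(ix, 1), nx)
  iy <- pmin(pmax(iy, 1), ny)
  (iy - 1) * nx + ix
}

## Small, quick simulation shared by several files.
small_sim <- function(seed = 7, ...) {
  simulate_fate_landscape(sim_params(n_cells = 150, n_genes = 300,
                                     n_markers_per_fate = 30,
                                     seed = seed, ...))
}

default_apex <- function() {
  apex_spec(c(osteoblast = "osteoblast", chondrocyte = "chondrocyte",
              reticular = "reticular"))
}

## Tiny gene annotation table in 0-based half-open coordinates.
toy_annotation <- function() {
  data.frame(gene_id = c("geneA", "geneB", "geneC"),
             contig = c("chr1", "chr1", "chr2"),
             start = c(10000L, 50000L, 8000L),
             end = c(12000L, 53000L, 9000L),
             strand = c("+", "-", "+"),
             stringsAsFactors = FALSE)
}
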