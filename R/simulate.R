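#' Simulation parameters for a three-fate landscape
#'
#' Bundles every knob of the synthetic single-cell generator. The defaults
#' describe a sorted bone-marrow-stromal-like experiment: three terminal
#' ("apex") populations -- osteoblast-like, chondrocyte-like and
#' reticular-like -- of equal size plus an equally sized pool of
#' transitional cells with intermediate identity, profiled deeply enough
#' that marker structure and splicing kinetics are recoverable.
#'
#' @param n_cells total number of cells (default 500).
#' @param n_genes total number of genes (default 1000).
#' @param fate_fractions length-4 proportions: apex fate 1..3, then the
#'   transitional pool. Must sum to 1 (tolerance 1e-9).
#' @param archetype_scale positive scale of mean expression; archetype gene
#'   means are drawn log-normal with meanlog `log(archetype_scale)` and
#'   sdlog 1.
#' @param n_markers_per_fate number of genes upregulated in each fate
#'   (disjoint blocks; `3 * n_markers_per_fate <= n_genes`).
#' @param marker_fold fold-change applied to a fate's marker genes in its
#'   archetype (default 8).
#' @param dispersion negative-binomial inverse-dispersion (`size`); larger
#'   means less noise. `Inf` disables sampling entirely and returns the
#'   exact means (a noiseless run, used by tests).
#' @param induction_delta multiplicative velocity offset in \[0, 1\]: the
#'   unspliced mean of a transitional cell is inflated by
#'   `(1 + induction_delta)` on its destined fate's marker genes, so the
#'   steady-state velocity points toward that fate.
#' @param gamma_range length-2 interval from which per-gene degradation
#'   rates are drawn uniformly.
#' @param seed RNG seed for the whole simulation.
#' @return object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_cells = 500L,
                       n_genes = 1000L,
                       fate_fractions = c(0.25, 0.25, 0.25, 0.25),
                       archetype_scale = 5,
                       n_markers_per_fate = 50L,
                       marker_fold = 8,
                       dispersion = 10,
                       induction_delta = 0.5,
                       gamma_range = c(0.1, 2.0),
                       seed = 1L) {
  if (length(fate_fractions) != 4L || any(fate_fractions < 0))
    stop("fate_fractions must be 4 nonnegative proportions")
  if (abs(sum(fate_fractions) - 1) > 1e-9)
    stop("fate_fractions must sum to 1 (got ", sum(fate_fractions), ")")
  if (n_cells < 1 || n_genes < 1)
    stop("n_cells and n_genes must be positive")
  if (archetype_scale <= 0) stop("archetype_scale must be positive")
  if (3L * n_markers_per_fate > n_genes)
    stop("3 * n_markers_per_fate must not exceed n_genes")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (induction_delta < 0 || induction_delta > 1)
    stop("induction_delta must lie in [0, 1]")
  if (length(gamma_range) != 2L || gamma_range[1] <= 0 ||
      gamma_range[2] < gamma_range[1])
    stop("gamma_range must be an increasing positive interval")
  structure(list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    fate_fractions = as.numeric(fate_fractions),
    archetype_scale = archetype_scale,
    n_markers_per_fate = as.integer(n_markers_per_fate),
    marker_fold = marker_fold, dispersion = dispersion,
    induction_delta = induction_delta,
    gamma_range = as.numeric(gamma_range), seed = as.integer(seed)),
    class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("sim_params:", x$n_cells, "cells x", x$n_genes, "genes;",
      "fractions", paste(signif(x$fate_fractions, 3), collapse = "/"),
      "\n  dispersion", x$dispersion, "| induction_delta",
      x$induction_delta, "| seed", x$seed, "\n")
  invisible(x)
}

.fate_names <- c("osteoblast", "chondrocyte", "reticular")

## Dirichlet(alpha) draws via normalized gammas
.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

.rcounts <- function(mu, size) {
  if (is.infinite(size)) return(mu)  # noiseless limit: exact means
  matrix(stats::rnbinom(length(mu), mu = as.vector(mu), size = size),
         nrow = nrow(mu), dimnames = dimnames(mu))
}

#' Simulate a three-fate single-cell landscape with velocity kinetics
#'
#' Draws three fate archetypes (log-normal gene means with a marker block
#' per fate), places apex cells exactly at their archetype and transitional
#' cells at Dirichlet-weighted mixtures biased 60/40 toward a destined
#' fate, and samples spliced/unspliced negative-binomial counts whose
#' kinetics encode that destiny: apex cells sit at the splicing steady
#' state (unspliced mean = gamma * spliced mean with splicing rate fixed
#' at 1), while a transitional cell's unspliced means are inflated by
#' `(1 + induction_delta)` on its destined fate's markers, so the
#' steady-state velocity residual u - gamma * s is positive there.
#'
#' @param params a [sim_params()] object.
#' @return list with `bundle` (an [expression_bundle()] with `spliced` and
#'   `unspliced` layers), `labels` (per-cell cluster label: the fate name
#'   for apex cells, `"Transitional"` otherwise) and `truth` (a list with
#'   `true_barycentric`, `destined_fate`, `true_gamma`, `apex_label`,
#'   `archetypes`, `marker_genes`, and the noiseless `spliced_mean` /
#'   `unspliced_mean` matrices).
#' @export
simulate_fate_landscape <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  p <- params
  n <- p$n_cells; g <- p$n_genes

  gene_ids <- sprintf("gene%04d", seq_len(g))
  barcodes <- sprintf("cell%05d", seq_len(n))

  ## archetypes: shared log-normal base, fate-specific marker blocks x fold
  base <- stats::rlnorm(g, meanlog = log(p$archetype_scale), sdlog = 1)
  marker_genes <- lapply(seq_len(3L), function(f) {
    idx <- ((f - 1L) * p$n_markers_per_fate + 1L):(f * p$n_markers_per_fate)
    gene_ids[idx]
  })
  names(marker_genes) <- .fate_names
  archetypes <- sapply(seq_len(3L), function(f) {
    a <- base
    a[match(marker_genes[[f]], gene_ids)] <-
      a[match(marker_genes[[f]], gene_ids)] * p$marker_fold
    a
  })
  rownames(archetypes) <- gene_ids
  colnames(archetypes) <- .fate_names

  ## cell assignment: apex blocks then transitional pool
  n_apex <- floor(p$fate_fractions[1:3] * n)
  n_trans <- n - sum(n_apex)
  apex_label <- c(rep(.fate_names, times = n_apex), rep(NA, n_trans))
  labels <- ifelse(is.na(apex_label), "Transitional", apex_label)

  W <- matrix(0, n, 3, dimnames = list(barcodes, .fate_names))
  for (f in seq_len(3L)) W[which(apex_label == .fate_names[f]), f] <- 1
  destined <- rep(NA_character_, n)
  if (n_trans > 0) {
    ti <- which(is.na(apex_label))
    destined[ti] <- sample(.fate_names, n_trans, replace = TRUE)
    D <- .rdirichlet(n_trans, c(2, 2, 2))
    onehot <- diag(3)[match(destined[ti], .fate_names), , drop = FALSE]
    W[ti, ] <- 0.6 * onehot + 0.4 * D
  }

  gamma <- stats::runif(g, p$gamma_range[1], p$gamma_range[2])
  names(gamma) <- gene_ids

  s_mean <- W %*% t(archetypes)                 # cells x genes
  u_mean <- sweep(s_mean, 2L, gamma, `*`)       # steady state, beta = 1
  if (n_trans > 0 && p$induction_delta > 0) {
    for (f in .fate_names) {
      ci <- which(destined == f)
      gi <- match(marker_genes[[f]], gene_ids)
      u_mean[ci, gi] <- u_mean[ci, gi] * (1 + p$induction_delta)
    }
  }

  spliced <- .rcounts(s_mean, p$dispersion)
  unspliced <- .rcounts(u_mean, p$dispersion)

  bundle <- expression_bundle(
    layers = list(spliced = Matrix::Matrix(spliced, sparse = TRUE),
                  unspliced = Matrix::Matrix(unspliced, sparse = TRUE)),
    barcodes = barcodes, genes = gene_ids)

  list(bundle = bundle,
       labels = stats::setNames(labels, barcodes),
       truth = list(true_barycentric = W,
                    destined_fate = stats::setNames(destined, barcodes),
                    true_gamma = gamma,
                    apex_label = stats::setNames(apex_label, barcodes),
                    archetypes = archetypes,
                    marker_genes = marker_genes,
                    spliced_mean = s_mean,
                    unspliced_mean = u_mean))
}

#' Simulate ATAC fragment records from a gene-activity matrix
#'
#' For every cell/gene pair, draws a Poisson number of fragments with the
#' given mean activity and places each one uniformly inside the gene's
#' accessibility window: gene body plus 3 kb (by default) upstream of the
#' transcription start site, strand-aware. Windows underflowing the contig
#' start are clipped at 0. Identical (contig, start, end, barcode) records
#' are collapsed with their duplicate counts summed, as in the standard
#' fragments-file dialect.
#'
#' @param params a [sim_params()] object (supplies the seed).
#' @param activity cells x genes matrix of mean fragment counts; dimnames
#'   give barcodes and gene ids.
#' @param annotation `data.frame` of gene intervals as returned by
#'   [read_gene_annotation()]: `gene_id`, `contig`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @param upstream_bp upstream promoter window size in bp (default 3000).
#' @param frag_len fragment length in bp (default 50).
#' @return `data.frame` of fragment records (`contig`, `start`, `end`,
#'   `barcode`, `count`), 0-based half-open, sorted by contig/start.
#' @export
simulate_fragments <- function(params, activity, annotation,
                               upstream_bp = 3000L, frag_len = 50L) {
  stopifnot(inherits(params, "sim_params"),
            !is.null(rownames(activity)), !is.null(colnames(activity)))
  set.seed(params$seed + 104729L)  # independent stream from the RNA draw
  ann <- annotation[match(colnames(activity), annotation$gene_id), ,
                    drop = FALSE]
  if (anyNA(ann$gene_id))
    stop("annotation missing genes: ",
         paste(setdiff(colnames(activity), annotation$gene_id),
               collapse = ", "))
  counts <- matrix(stats::rpois(length(activity), as.vector(activity)),
                   nrow = nrow(activity), dimnames = dimnames(activity))
  keep <- which(counts > 0, arr.ind = TRUE)
  if (nrow(keep) == 0L)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), barcode = character(),
                      count = integer()))
  recs <- lapply(seq_len(nrow(keep)), function(r) {
    ci <- keep[r, 1L]; gi <- keep[r, 2L]; k <- counts[ci, gi]
    gs <- ann$start[gi]; ge <- ann$end[gi]
    if (ann$strand[gi] == "+") {
      w0 <- max(0L, gs - upstream_bp); w1 <- ge
    } else {
      w0 <- gs; w1 <- ge + upstream_bp
    }
    len <- min(frag_len, w1 - w0)
    starts <- w0 + floor(stats::runif(k) * max(1L, (w1 - w0 - len)))
    data.frame(contig = ann$contig[gi], start = as.integer(starts),
               end = as.integer(starts + len),
               barcode = rownames(activity)[ci], count = 1L)
  })
  out <- do.call(rbind, recs)
  ## collapse duplicates into the count column
  key <- paste(out$contig, out$start, out$end, out$barcode, sep = "\r")
  agg <- rowsum(out$count, key)
  first <- out[match(rownames(agg), key), c("contig", "start", "end",
                                            "barcode")]
  out <- cbind(first, count = as.integer(agg[, 1L]))
  out <- out[order(out$contig, out$start, out$end, out$barcode), ]
  rownames(out) <- NULL
  out
}
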