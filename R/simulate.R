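#' Simulation configuration
#'
#' Describes a synthetic single-cell count dataset with the statistical
#' structure the analysis assumes: a handful of cell types, per-type marker
#' genes with elevated means, negative-binomial overdispersion, and designated
#' low-dispersion ("strict", dosage-sensitive) versus high-dispersion
#' ("tolerant") gene classes with known ground truth. Counts for gene g in a
#' cell of type t are NB with mean
#' `baseline_mean * marker_fold^(g is a marker of t) * depth_factor(cell)` and
#' size parameter `theta_g` (variance `m + m^2/theta`; larger theta = tighter).
#' Per-cell depth factors are log-normal with log-scale SD `depth_variation`,
#' mean 1.
#'
#' @param n_cell_types number of cell types.
#' @param cells_per_type cells per type (scalar, or length-2 range sampled
#'   uniformly per type).
#' @param n_genes total genes.
#' @param n_markers_per_type markers assigned to each type (from the
#'   background-dispersion class).
#' @param marker_fold mean multiplier for a marker in its own type; 1 turns
#'   marker structure off (a null dataset).
#' @param baseline_mean expected counts per gene per cell at depth factor 1.
#' @param dispersion_strict,dispersion_tolerant,dispersion_background NB size
#'   (theta) for the three gene classes; must satisfy
#'   `dispersion_strict > dispersion_tolerant > 0`.
#' @param n_strict_genes,n_tolerant_genes sizes of the two ground-truth
#'   classes.
#' @param depth_variation log-normal sigma of per-cell library-size factors
#'   (0 = constant depth).
#' @param seed RNG seed used by [simulate_cells()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cell_types = 10L,
                       cells_per_type = 200L,
                       n_genes = 2000L,
                       n_markers_per_type = 25L,
                       marker_fold = 4,
                       baseline_mean = 5,
                       dispersion_strict = 50,
                       dispersion_tolerant = 1,
                       dispersion_background = 10,
                       n_strict_genes = 100L,
                       n_tolerant_genes = 100L,
                       depth_variation = 0.3,
                       seed = 1L) {
  cfg <- list(n_cell_types = as.integer(n_cell_types),
              cells_per_type = as.integer(cells_per_type),
              n_genes = as.integer(n_genes),
              n_markers_per_type = as.integer(n_markers_per_type),
              marker_fold = marker_fold,
              baseline_mean = baseline_mean,
              dispersion_strict = dispersion_strict,
              dispersion_tolerant = dispersion_tolerant,
              dispersion_background = dispersion_background,
              n_strict_genes = as.integer(n_strict_genes),
              n_tolerant_genes = as.integer(n_tolerant_genes),
              depth_variation = depth_variation,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_cell_types < 1L || n_genes < 1L || any(cells_per_type < 1L))
      stop("counts in the configuration must be >= 1")
    if (length(cells_per_type) > 2L)
      stop("cells_per_type must be a scalar or a length-2 range")
    if (marker_fold < 1) stop("marker_fold must be >= 1 (1 = null, no marker signal)")
    if (!(dispersion_strict > dispersion_tolerant && dispersion_tolerant > 0))
      stop("need dispersion_strict > dispersion_tolerant > 0")
    if (dispersion_background <= 0) stop("dispersion_background must be > 0")
    if (baseline_mean <= 0) stop("baseline_mean must be > 0")
    if (depth_variation < 0) stop("depth_variation must be >= 0")
    if (n_strict_genes + n_tolerant_genes +
        n_markers_per_type * n_cell_types > n_genes)
      stop("gene classes (strict + tolerant + markers) exceed n_genes")
  })
  invisible(cfg)
}

#' Simulate an annotated single-cell count dataset with known ground truth
#'
#' Gene identifiers encode nothing about class; the returned `truth` object is
#' the only record of marker assignment, strict/tolerant membership and each
#' gene's true dispersion. Strict and tolerant genes are never markers, so the
#' two ground truths stay orthogonal. A fixed seed gives bit-identical output.
#'
#' @param config a [sim_config()].
#' @param truth optional `truth` from a previous call with a compatible config:
#'   reuses the gene classes and marker assignment so that a second dataset
#'   shares the same underlying biology (a replication dataset) while drawing
#'   fresh cells and noise.
#' @return list with `store` (a `SingleCellExperiment`, `counts` assay) and
#'   `truth` (list: `marker_assignment` named character, `strict_genes`,
#'   `tolerant_genes`, `theta` named numeric per gene, `depth_factors`).
#' @export
simulate_cells <- function(config, truth = NULL) {
  validate_sim_config(config)
  set.seed(config$seed)
  ng <- config$n_genes
  nt <- config$n_cell_types
  genes <- sprintf("G%05d", seq_len(ng))
  types <- sprintf("CT%02d", seq_len(nt))

  if (is.null(truth)) {
    # gene classes: strict, tolerant, then markers drawn from the remainder
    strict_genes <- genes[seq_len(config$n_strict_genes)]
    tolerant_genes <- genes[config$n_strict_genes + seq_len(config$n_tolerant_genes)]
    background <- setdiff(genes, c(strict_genes, tolerant_genes))
    marker_pool <- sample(background, config$n_markers_per_type * nt)
    marker_of <- stats::setNames(rep(types, each = config$n_markers_per_type),
                                 marker_pool)
    theta <- stats::setNames(rep(config$dispersion_background, ng), genes)
    theta[strict_genes] <- config$dispersion_strict
    theta[tolerant_genes] <- config$dispersion_tolerant
  } else {
    if (!setequal(names(truth$theta), genes))
      stop("supplied truth does not cover this config's gene set")
    strict_genes <- truth$strict_genes
    tolerant_genes <- truth$tolerant_genes
    marker_of <- truth$marker_assignment
    theta <- truth$theta[genes]
  }

  n_per_type <- if (length(config$cells_per_type) == 2L)
    sample(seq(config$cells_per_type[1L], config$cells_per_type[2L]), nt,
           replace = TRUE)
  else rep(config$cells_per_type, nt)
  cell_type <- rep(types, times = n_per_type)
  nc <- length(cell_type)
  cells <- sprintf("C%06d", seq_len(nc))

  sv <- config$depth_variation
  depth <- if (sv > 0) exp(rnorm(nc, -sv^2 / 2, sv)) else rep(1, nc)

  # per-gene base mean, boosted marker_fold-times in the marker's own type
  base <- rep(config$baseline_mean, ng)
  counts <- matrix(0L, nrow = ng, ncol = nc, dimnames = list(genes, cells))
  for (t in seq_len(nt)) {
    jj <- which(cell_type == types[t])
    mu_g <- base
    mk <- names(marker_of)[marker_of == types[t]]
    mu_g[match(mk, genes)] <- mu_g[match(mk, genes)] * config$marker_fold
    mu_mat <- outer(mu_g, depth[jj])
    counts[, jj] <- rnbinom(length(mu_mat), mu = mu_mat,
                            size = rep(theta, times = length(jj)))
  }
  store <- expression_store(methods::as(counts, "CsparseMatrix"),
                            stats::setNames(cell_type, cells))
  truth <- list(marker_assignment = marker_of,
                strict_genes = strict_genes,
                tolerant_genes = tolerant_genes,
                theta = theta,
                depth_factors = stats::setNames(depth, cells))
  list(store = store, truth = truth)
}

#' Marker panel for one simulated cell type
#'
#' Convenience accessor: the ground-truth markers of `cell_type` as a
#' [gene_panel], e.g. to feed the enrichment test in power checks.
#'
#' @param truth the `truth` element of [simulate_cells()].
#' @param cell_type simulated type label (e.g. `"CT01"`).
#' @return a [gene_panel].
#' @export
marker_panel <- function(truth, cell_type) {
  g <- names(truth$marker_assignment)[truth$marker_assignment == cell_type]
  if (length(g) == 0L) stop("no markers assigned to '", cell_type, "'")
  gene_panel(g, name = paste0("markers_", cell_type), source = "simulation truth")
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Emits `matrix.mtx` (genes x cells MatrixMarket triplet), `genes.txt`,
#' `cells.txt`, `annotation.tsv` (cell_id, cell_type) and the ground-truth
#' tables `truth_markers.tsv`, `truth_strict.txt`, `truth_tolerant.txt`,
#' `truth_dispersion.tsv`. Loading the files back through [read_expression()]
#' reproduces the store exactly.
#'
#' @param store,truth as returned by [simulate_cells()].
#' @param out_dir output directory, created if missing.
#' @return invisibly, the named vector of file paths.
#' @export
write_fixture <- function(store, truth, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(out_dir, x)
  m <- assay(store, "counts")
  writeMM(m, f("matrix.mtx"))
  writeLines(rownames(m), f("genes.txt"))
  writeLines(colnames(m), f("cells.txt"))
  write.table(data.frame(cell_id = colnames(m),
                         cell_type = colData(store)$cell_type),
              f("annotation.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = names(truth$marker_assignment),
                         cell_type = unname(truth$marker_assignment)),
              f("truth_markers.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(truth$strict_genes, f("truth_strict.txt"))
  writeLines(truth$tolerant_genes, f("truth_tolerant.txt"))
  write.table(data.frame(gene = names(truth$theta),
                         theta = unname(truth$theta)),
              f("truth_dispersion.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(matrix = f("matrix.mtx"), genes = f("genes.txt"),
              cells = f("cells.txt"), annotation = f("annotation.tsv"),
              markers = f("truth_markers.tsv"), strict = f("truth_strict.txt"),
              tolerant = f("truth_tolerant.txt"),
              dispersion = f("truth_dispersion.tsv")))
}
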