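# Shared in-code fixtures: tiny stores and specificity matrices built fresh at
# test time, plus the exhaustive-enumeration oracle for the bootstrap test.

suppressPackageStartupMessages({
  library(Matrix)
  library(SummarizedExperiment)
})

# small annotated store from a dense genes x cells matrix
tiny_store <- function(counts, cell_types) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%02d", seq_len(ncol(counts)))
  expression_store(methods::as(counts, "CsparseMatrix"),
                   stats::setNames(cell_types, colnames(counts)))
}

# random celltype_means object (cell types x genes)
random_ctm <- function(n_types = 3L, n_genes = 12L, seed = 42L) {
  set.seed(seed)
  m <- matrix(stats::rgamma(n_types * n_genes, shape = 2, rate = 0.5),
              nrow = n_types,
              dimnames = list(sprintf("T%d", seq_len(n_types)),
                              sprintf("g%02d", seq_len(n_genes))))
  structure(list(means = m,
                 n_cells = stats::setNames(rep(5L, n_types), rownames(m))),
            class = "celltype_means")
}

# exact upper-tail enrichment p by enumerating every same-size subset of the
# universe (ties count toward the tail); independent of the bootstrap path
exact_enrichment_p <- function(spec_obj, target_genes, size = length(target_genes)) {
  universe <- rownames(spec_obj$spec)[spec_obj$usable]
  sp <- spec_obj$spec[universe, , drop = FALSE]
  obs <- colSums(sp[match(target_genes, universe), , drop = FALSE])
  subsets <- utils::combn(length(universe), size)
  sums <- apply(subsets, 2L, function(ix) colSums(sp[ix, , drop = FALSE]))
  # sums: cell types x n_subsets
  apply(sums >= obs, 1L, mean)
}

# default-condition simulation used by the heavier acceptance checks
power_sim_config <- function(seed) sim_config(seed = seed)

null_sim_config <- function(seed, n_genes = 1500L, n_cell_types = 6L,
                            cells_per_type = 80L) {
  sim_config(n_cell_types = n_cell_types, cells_per_type = cells_per_type,
             n_genes = n_genes, n_markers_per_type = 0L, marker_fold = 1,
             baseline_mean = 5, dispersion_background = 10,
             n_strict_genes = 0L, n_tolerant_genes = 0L,
             depth_variation = 0, seed = seed)
}
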