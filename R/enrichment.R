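#' Gene by cell-type specificity matrix
#'
#' Specificity of gene g in cell type t is its mean expression in t divided by
#' the sum of its mean expression over all cell types, so each usable gene's
#' row sums to one and the entry is the proportion of the gene's expression
#' "budget" spent in that type. Genes with zero mean everywhere cannot be
#' apportioned; their rows are zero and they are flagged unusable (excluded
#' from enrichment targets and from the bootstrap null universe).
#'
#' @param means a [celltype_means] object.
#' @return An object of class `specificity_matrix`: list with `spec` (genes x
#'   cell types matrix in `[0,1]`), `usable` (named logical), `cell_types`.
#' @examples
#' ctm <- structure(list(means = rbind(A = c(g1 = 3), B = c(g1 = 1)),
#'                       n_cells = c(A = 2L, B = 2L)), class = "celltype_means")
#' specificity_matrix(ctm)$spec  # 0.75, 0.25
#' @export
specificity_matrix <- function(means) {
  stopifnot(inherits(means, "celltype_means"))
  m <- means$means                      # cell types x genes
  tot <- colSums(m)
  usable <- tot > 0
  spec <- t(m) # genes x cell types
  spec[usable, ] <- spec[usable, , drop = FALSE] / tot[usable]
  spec[!usable, ] <- 0
  structure(list(spec = spec,
                 usable = stats::setNames(usable, colnames(m)),
                 cell_types = rownames(m)),
            class = "specificity_matrix")
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat("specificity_matrix: ", nrow(x$spec), " genes (", sum(x$usable),
      " usable) x ", length(x$cell_types), " cell types\n", sep = "")
  invisible(x)
}

# n_draws x size matrix of gene indices sampled without replacement within
# each row from n_universe genes
sample_gene_sets <- function(n_universe, size, n_draws) {
  t(vapply(seq_len(n_draws),
           function(i) sample.int(n_universe, size),
           integer(size)))
}

#' Bootstrap cell-type enrichment of a gene panel
#'
#' For each cell type, the observed statistic is the summed specificity of the
#' panel's genes. The null distribution is the same sum for `n_boot` random
#' gene lists of the same size, sampled without replacement from all usable
#' genes (panel genes included). The upper-tail p-value uses the standard
#' pseudo-count correction, `p = (1 + #(null >= observed)) / (n_boot + 1)`,
#' ties counting to the tail, so p is never zero and never exceeds 1.
#' Benjamini-Hochberg adjustment is applied across the cell types of this call
#' (one dataset, one panel).
#'
#' @param spec a [specificity_matrix].
#' @param panel a [gene_panel]; symbols not in the usable universe are dropped
#'   via [restrict_to_universe()].
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed RNG seed; set for reproducibility of the null draws.
#' @return data.frame with one row per cell type: `panel`, `cell_type`,
#'   `n_target`, `observed`, `boot_mean`, `boot_sd`, `p`, `p_fdr`, `n_boot`.
#' @export
bootstrap_enrichment <- function(spec, panel, n_boot = 10000L, seed = 1L) {
  stopifnot(inherits(spec, "specificity_matrix"), inherits(panel, "gene_panel"))
  universe <- rownames(spec$spec)[spec$usable]
  panel <- restrict_to_universe(panel, universe)$panel
  s <- length(panel$genes)
  if (s < 2L) stop("target too small: need >= 2 panel genes in the universe")
  if (!is.null(seed)) set.seed(seed)
  sp <- spec$spec[universe, , drop = FALSE]
  t_idx <- match(panel$genes, universe)
  observed <- colSums(sp[t_idx, , drop = FALSE])
  idx <- sample_gene_sets(length(universe), s, n_boot)
  ind <- sparseMatrix(i = as.vector(t(idx)),
                      j = rep(seq_len(n_boot), each = s),
                      x = 1, dims = c(length(universe), n_boot))
  null_sums <- as.matrix(Matrix::t(ind) %*% sp)   # n_boot x cell types
  # ties count toward the tail; the epsilon absorbs summation-order round-off
  tol <- 1e-9 * pmax(1, abs(observed))
  exceed <- colSums(null_sums >= rep(observed - tol, each = n_boot))
  p <- (1 + exceed) / (n_boot + 1)
  data.frame(panel = panel$name,
             cell_type = colnames(sp),
             n_target = s,
             observed = observed,
             boot_mean = colMeans(null_sums),
             boot_sd = apply(null_sums, 2L, sd),
             p = p,
             p_fdr = fdr_adjust(p),
             n_boot = as.integer(n_boot),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`: the step-up
#' procedure with monotonicity enforcement, the family being whatever vector is
#' passed (here: the cell types of one dataset x panel).
#'
#' @param p numeric p-values in `(0, 1]`.
#' @return adjusted p-values, same length.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Significance as a function of gene-set size
#'
#' Draws `n_rep` random subsets of each requested size from a source panel,
#' runs the bootstrap enrichment test on each, and reports the fraction of
#' subsets reaching FDR significance per cell type — the power (or, on a null
#' dataset, type-I error) profile over panel sizes.
#'
#' @param spec a [specificity_matrix].
#' @param source_panel panel to subsample (restricted to the usable universe
#'   first).
#' @param sizes integer vector of subset sizes, each in `[2, |panel|]`.
#' @param n_rep subsets per size.
#' @param n_boot bootstrap replicates per test.
#' @param seed RNG seed.
#' @param alpha FDR threshold counted as significant (default 0.05).
#' @return data.frame: `size`, `cell_type`, `prop_significant`, `n_rep`.
#' @export
size_power_scan <- function(spec, source_panel, sizes, n_rep = 20L,
                            n_boot = 1000L, seed = 1L, alpha = 0.05) {
  stopifnot(inherits(spec, "specificity_matrix"))
  universe <- rownames(spec$spec)[spec$usable]
  source_panel <- restrict_to_universe(source_panel, universe)$panel
  n_src <- length(source_panel$genes)
  if (any(sizes < 2L) || any(sizes > n_src))
    stop("sizes must lie in [2, ", n_src, "]")
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(sizes, function(s) {
    hits <- matrix(0L, nrow = n_rep, ncol = length(spec$cell_types))
    for (r in seq_len(n_rep)) {
      sub <- gene_panel(sample(source_panel$genes, s),
                        name = paste0(source_panel$name, "_s", s, "_r", r))
      res <- bootstrap_enrichment(spec, sub, n_boot = n_boot, seed = NULL)
      hits[r, ] <- as.integer(res$p_fdr < alpha)
    }
    data.frame(size = s, cell_type = spec$cell_types,
               prop_significant = colMeans(hits), n_rep = n_rep,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
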