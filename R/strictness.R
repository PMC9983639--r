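#' Per-cell fold changes of one gene
#'
#' The fold change of cell i is the gene's expression in that cell divided by a
#' reference mean (by default the gene's mean over all cells of the dataset).
#' Fold change removes the gene's overall expression scale, so downstream
#' strictness is invariant to multiplying a gene's expression by any positive
#' constant.
#'
#' @param expression numeric vector, the gene's expression per cell.
#' @param reference_mean the mean expression used as denominator; must be > 0.
#' @return numeric vector of per-cell fold changes.
#' @examples
#' fold_change(c(1, 2, 3), 2)  # 0.5 1.0 1.5
#' @export
fold_change <- function(expression, reference_mean) {
  if (!is.finite(reference_mean) || reference_mean <= 0)
    stop("gene unusable: reference mean expression must be > 0")
  expression / reference_mean
}

#' Strictness of a fold-change vector
#'
#' Strictness is the inverse of the sample standard deviation (n-1 denominator)
#' of per-cell fold changes: S = 1 / sqrt(sum((C_i - Cbar)^2) / (n - 1)).
#' A gene whose expression is tightly controlled across cells has fold changes
#' clustered near 1, a small SD, and a high S — the signature of a
#' dosage-sensitive gene. Zero-variance fold changes would give infinite S; the
#' value is reported as `1/eps` with the `degenerate` flag set, and degenerate
#' genes are excluded from gene-set tests.
#'
#' @param C numeric vector of fold changes over the cells of one population.
#' @param eps variance floor below which the gene is flagged degenerate.
#' @return list with `S`, `n_cells`, `degenerate`.
#' @examples
#' strictness(c(0.5, 1, 1.5))$S  # 2
#' @export
strictness <- function(C, eps = 1e-12) {
  n <- length(C)
  if (n < 2L) stop("strictness needs >= 2 cells")
  s <- sd(C)
  if (!is.finite(s) || s < eps)
    return(list(S = 1 / eps, n_cells = n, degenerate = TRUE))
  list(S = 1 / s, n_cells = n, degenerate = FALSE)
}

#' Strictness of every gene in a cell population
#'
#' Computes per-gene strictness over the cells of one cell type (or all cells).
#' Two reference scopes are available for the fold-change denominator:
#' `"global-ref"` (default) divides by the gene's mean over *all* cells of the
#' dataset while the SD is taken over the queried population's cells, so a
#' marker gene sitting far above its global mean in its own type shows up as
#' lax there; `"within-type"` divides by the mean over the population itself,
#' making strictness a purely within-population dispersion measure. The scope
#' is recorded on the result.
#'
#' @param store a `SingleCellExperiment` (the `cpm` assay is used when
#'   present).
#' @param cell_type population label, or `NULL` for all cells (labelled
#'   `"all"`).
#' @param scope fold-change reference, see above.
#' @param eps degeneracy floor passed to the per-gene computation.
#' @return data.frame with columns `gene`, `cell_type`, `S`, `n_cells`,
#'   `degenerate`, `usable`; attribute `scope`. Unusable genes (reference mean
#'   zero) carry `S = NA`.
#' @export
gene_strictness <- function(store, cell_type = NULL,
                            scope = c("global-ref", "within-type"),
                            eps = 1e-12) {
  scope <- match.arg(scope)
  m <- values_assay(store)
  if (is.null(cell_type)) {
    pop <- seq_len(ncol(m))
    label <- "all"
  } else {
    pop <- which(colData(store)$cell_type == cell_type)
    if (length(pop) == 0L) stop("no cells of type '", cell_type, "'")
    label <- cell_type
  }
  n <- length(pop)
  if (n < 2L) stop("population '", label, "' has < 2 cells")
  mp <- m[, pop, drop = FALSE]
  ref <- if (scope == "global-ref") rowMeans(m) else rowMeans(mp)
  usable <- ref > 0
  # SD of C = SD(E)/ref computed from raw moments, row-wise on the sparse slice
  mu_pop <- rowMeans(mp)
  ss <- rowSums(mp^2)
  var_e <- (ss - n * mu_pop^2) / (n - 1)
  var_e <- pmax(var_e, 0)              # guard tiny negative round-off
  sd_c <- rep(NA_real_, nrow(m))
  sd_c[usable] <- sqrt(var_e[usable]) / ref[usable]
  degenerate <- usable & sd_c < eps
  S <- ifelse(usable, ifelse(degenerate, 1 / eps, 1 / sd_c), NA_real_)
  out <- data.frame(gene = rownames(m), cell_type = label, S = S,
                    n_cells = n, degenerate = degenerate, usable = usable,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "scope") <- scope
  out
}

#' CLT-based gene-set strictness test
#'
#' Tests whether a panel's mean strictness in a population is higher than
#' expected for a random same-size gene set. The observed statistic is the
#' panel's mean strictness x. The null is built by drawing `n_boot` random
#' gene sets of the same size (without replacement within each set) from all
#' usable, non-degenerate genes and taking each set's mean strictness; by the
#' Central Limit Theorem these means are approximately normal, so their
#' maximum-likelihood normal fit (mean mu; SD sigma with the 1/N denominator)
#' yields the upper-tail p-value `p = 1 - pnorm((x - mu)/sigma)`.
#'
#' @param S_all either the data.frame from [gene_strictness()] or a named
#'   numeric vector of per-gene strictness values; degenerate/unusable entries
#'   are removed from target and universe symmetrically.
#' @param panel a [gene_panel], restricted to the usable universe internally.
#' @param n_boot null resamples (default 10000).
#' @param seed RNG seed.
#' @param keep_null keep the vector of null sample means on the result (for
#'   diagnostics of the normal approximation).
#' @return one-row data.frame: `panel`, `cell_type`, `scope`, `n_genes`,
#'   `observed_mean`, `null_mu`, `null_sigma`, `p`, `p_bonf` (`NA`, filled by
#'   [panel_compare()]), `n_boot`. With `keep_null`, attribute `null_means`.
#' @export
geneset_strictness_test <- function(S_all, panel, n_boot = 10000L, seed = 1L,
                                    keep_null = FALSE) {
  stopifnot(inherits(panel, "gene_panel"))
  if (is.data.frame(S_all)) {
    keep <- S_all$usable & !S_all$degenerate
    S <- stats::setNames(S_all$S[keep], S_all$gene[keep])
    label <- if (nrow(S_all)) S_all$cell_type[1L] else "all"
    scope <- attr(S_all, "scope") %||% NA_character_
  } else {
    S <- S_all[is.finite(S_all)]
    label <- "all"
    scope <- NA_character_
  }
  if (length(S) < 2L) stop("degenerate null: fewer than 2 usable genes")
  panel <- restrict_to_universe(panel, names(S))$panel
  s <- length(panel$genes)
  if (s < 2L) stop("target too small: need >= 2 panel genes with strictness")
  if (!is.null(seed)) set.seed(seed)
  x <- mean(S[panel$genes])
  idx <- sample_gene_sets(length(S), s, n_boot)
  null_means <- rowMeans(matrix(S[as.vector(idx)], nrow = n_boot))
  mu <- mean(null_means)
  sigma <- sqrt(mean((null_means - mu)^2))   # MLE: 1/N denominator
  if (sigma == 0) stop("degenerate null: zero variance of resampled means")
  p <- pnorm((x - mu) / sigma, lower.tail = FALSE)
  out <- data.frame(panel = panel$name, cell_type = label, scope = scope,
                    n_genes = s, observed_mean = x, null_mu = mu,
                    null_sigma = sigma, p = p, p_bonf = NA_real_,
                    n_boot = as.integer(n_boot),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (keep_null) attr(out, "null_means") <- null_means
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bonferroni adjustment of a p-value
#'
#' @param p p-value in `(0, 1]`.
#' @param n_tests number of tests in the family (>= 1).
#' @return `min(1, p * n_tests)`.
#' @examples
#' bonferroni_adjust(0.001, 56)  # 0.056
#' @export
bonferroni_adjust <- function(p, n_tests) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  if (n_tests < 1L) stop("n_tests must be >= 1")
  pmin(1, p * n_tests)
}

#' Strictness tests for several panels across cell populations
#'
#' Runs [geneset_strictness_test()] for every panel x population combination
#' and Bonferroni-adjusts within each panel over the number of populations
#' tested (recorded in the output).
#'
#' @param store a `SingleCellExperiment`.
#' @param panels list of [gene_panel] objects.
#' @param cell_types population labels to test; `NULL` means every annotated
#'   type.
#' @param scope,n_boot,seed passed through.
#' @return data.frame, one row per panel x population, with `p_bonf` filled and
#'   an `n_tests` column.
#' @export
panel_compare <- function(store, panels, cell_types = NULL,
                          scope = c("global-ref", "within-type"),
                          n_boot = 10000L, seed = 1L) {
  scope <- match.arg(scope)
  if (inherits(panels, "gene_panel")) panels <- list(panels)
  stopifnot(length(panels) >= 1L)
  if (is.null(cell_types))
    cell_types <- sort(unique(as.character(colData(store)$cell_type)))
  n_tests <- length(cell_types)
  S_by_type <- lapply(cell_types, function(ct)
    gene_strictness(store, cell_type = ct, scope = scope))
  names(S_by_type) <- cell_types
  rows <- list()
  for (pn in seq_along(panels)) {
    for (ct in cell_types) {
      r <- geneset_strictness_test(S_by_type[[ct]], panels[[pn]],
                                   n_boot = n_boot,
                                   seed = if (is.null(seed)) NULL
                                          else seed + pn * 1000L + match(ct, cell_types))
      r$p_bonf <- bonferroni_adjust(r$p, n_tests)
      r$n_tests <- n_tests
      rows[[length(rows) + 1L]] <- r
    }
  }
  do.call(rbind, rows)
}
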