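#' Combine one-sided p-values across datasets
#'
#' Stouffer's method (default): each p is mapped to a z-score
#' `z_k = qnorm(1 - p_k)`, the weighted sum `sum(w_k z_k) / sqrt(sum(w_k^2))`
#' is again standard normal under the joint null, and the combined p is its
#' upper tail. Appropriate for one-sided, direction-consistent tests such as
#' the bootstrap enrichment p-values. Fisher's method
#' (`-2 sum(log p) ~ chi^2_{2k}`) is available as an alternative.
#'
#' @param p numeric vector of one-sided p-values, one per dataset; values of
#'   exactly 0 or 1 are clamped to `[1e-15, 1 - 1e-15]` with a warning.
#' @param weights optional per-dataset weights (Stouffer only); default equal.
#' @param method `"stouffer"` or `"fisher"`.
#' @return combined p-value (scalar). A single p is returned unchanged with a
#'   warning.
#' @examples
#' combine_p(c(0.05, 0.05))  # ~0.0101
#' @export
combine_p <- function(p, weights = NULL, method = c("stouffer", "fisher")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  if (any(p == 0 | p == 1)) {
    warning("p-values of exactly 0 or 1 clamped to [1e-15, 1 - 1e-15]")
    p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  }
  if (length(p) == 1L) {
    warning("single p-value: returned unchanged, nothing to combine")
    return(p)
  }
  if (method == "fisher") {
    stat <- -2 * sum(log(p))
    return(stats::pchisq(stat, df = 2 * length(p), lower.tail = FALSE))
  }
  if (is.null(weights)) weights <- rep(1, length(p))
  stopifnot(length(weights) == length(p), all(weights > 0))
  z <- qnorm(p, lower.tail = FALSE)
  zc <- sum(weights * z) / sqrt(sum(weights^2))
  pnorm(zc, lower.tail = FALSE)
}

#' Meta-analysis table over per-dataset enrichment results
#'
#' Combines the per-dataset p-values of each (cell type, panel) pair seen in at
#' least two datasets and Bonferroni-adjusts the combined p over the pooled
#' cell-type count — by default the sum of the number of distinct cell types
#' contributed by each dataset, mirroring a two-level correction where FDR ran
#' within each dataset and Bonferroni runs once across the pooled family.
#' Cell-type labels must already be harmonized across datasets by the caller
#' (see `mapping` below).
#'
#' @param results named list (one element per dataset) of data.frames carrying
#'   at least `cell_type`, `panel`, `p` — e.g. outputs of
#'   [bootstrap_enrichment()].
#' @param n_tests pooled cell-type count for the Bonferroni family; default
#'   computed as described above.
#' @param mapping optional data.frame (dataset, local_label, harmonized_label)
#'   applied to `cell_type` before pooling.
#' @param method combination method, see [combine_p()].
#' @return data.frame: `cell_type`, `panel`, `dataset_ps` (semicolon-joined
#'   `dataset=p`), `n_datasets`, `combined_p`, `n_tests`, `p_bonf`, `method`.
#' @export
meta_table <- function(results, n_tests = NULL, mapping = NULL,
                       method = c("stouffer", "fisher")) {
  method <- match.arg(method)
  stopifnot(is.list(results), length(results) >= 2L)
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop("results must be a named list (one name per dataset)")
  tabs <- lapply(names(results), function(ds) {
    d <- results[[ds]]
    stopifnot(all(c("cell_type", "panel", "p") %in% names(d)))
    d <- d[, c("cell_type", "panel", "p")]
    if (!is.null(mapping)) {
      mp <- mapping[mapping[[1L]] == ds, , drop = FALSE]
      hit <- match(d$cell_type, mp[[2L]])
      d$cell_type <- ifelse(is.na(hit), d$cell_type, mp[[3L]][hit])
    }
    if (anyDuplicated(d[, c("cell_type", "panel")]))
      stop("dataset '", ds, "' contributes more than one p for a ",
           "(cell type, panel) pair")
    d$dataset <- ds
    d
  })
  all_rows <- do.call(rbind, tabs)
  if (is.null(n_tests))
    n_tests <- sum(vapply(tabs, function(d) length(unique(d$cell_type)),
                          integer(1)))
  key <- interaction(all_rows$cell_type, all_rows$panel, drop = TRUE)
  groups <- split(all_rows, key)
  groups <- Filter(function(g) nrow(g) >= 2L, groups)
  if (length(groups) == 0L)
    stop("no (cell type, panel) pair is present in >= 2 datasets")
  n_dropped <- length(unique(key)) - length(groups)
  if (n_dropped > 0)
    warning(n_dropped, " (cell type, panel) pair(s) present in a single ",
            "dataset excluded from the meta-analysis")
  rows <- lapply(groups, function(g) {
    cp <- combine_p(g$p, method = method)
    data.frame(cell_type = g$cell_type[1L], panel = g$panel[1L],
               dataset_ps = paste(sprintf("%s=%g", g$dataset, g$p),
                                  collapse = ";"),
               n_datasets = nrow(g),
               combined_p = cp, n_tests = n_tests,
               p_bonf = bonferroni_adjust(cp, n_tests),
               method = method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$combined_p), ]
}
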