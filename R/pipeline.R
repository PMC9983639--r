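#' Read a pipeline run configuration from YAML
#'
#' Expected keys: `datasets` (list of `label`, `matrix`, `annotation`,
#' optional `genes`, `cells`, `orientation`, `normalize`), `panels` (list of
#' paths or `label: path` pairs), and optional `n_boot` (default 10000, must
#' be >= 100), `seed` (default 1), `min_cells_per_type` (default 10),
#' `strictness_scope`, `output_dir`, `harmonization_map` (TSV: dataset,
#' local_label, harmonized_label).
#'
#' @param path YAML file.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg, base_dir = dirname(path))
}

as_run_config <- function(cfg, base_dir = ".") {
  if (is.null(cfg$datasets) || length(cfg$datasets) < 1L)
    stop("run config needs >= 1 dataset")
  if (is.null(cfg$panels) || length(cfg$panels) < 1L)
    stop("run config needs >= 1 panel")
  cfg$n_boot <- as.integer(cfg$n_boot %||% 10000L)
  if (cfg$n_boot < 100L) stop("n_boot must be >= 100")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$min_cells_per_type <- as.integer(cfg$min_cells_per_type %||% 10L)
  cfg$strictness_scope <- cfg$strictness_scope %||% "global-ref"
  cfg$output_dir <- cfg$output_dir %||% "strictscreen_out"
  resolve <- function(p) if (is.null(p) || file.exists(p)) p
                         else file.path(base_dir, p)
  cfg$datasets <- lapply(cfg$datasets, function(d) {
    if (is.null(d$label)) stop("every dataset needs a label")
    d$matrix <- resolve(d$matrix); d$annotation <- resolve(d$annotation)
    d$genes <- resolve(d$genes); d$cells <- resolve(d$cells)
    d$orientation <- d$orientation %||% "genes-as-rows"
    d$normalize <- d$normalize %||% TRUE
    d
  })
  cfg$panels <- lapply(cfg$panels, resolve)
  cfg$harmonization_map <- resolve(cfg$harmonization_map)
  structure(cfg, class = "run_config")
}

load_config_panels <- function(cfg) {
  nms <- names(cfg$panels)
  panels <- lapply(seq_along(cfg$panels), function(i) {
    path <- cfg$panels[[i]]
    nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else NULL
    read_gene_panel(path, name = nm)
  })
  panels
}

#' Run the full screening pipeline from a configuration
#'
#' Stages: load panels (+ pairwise overlap report), load each dataset,
#' CPM-normalize (unless disabled per dataset), enrichment test per dataset x
#' panel with per-dataset FDR, strictness panel comparison per dataset, and —
#' when two or more datasets are present — a Stouffer meta-analysis of the
#' enrichment p-values with Bonferroni correction over the pooled cell-type
#' count. All tables are written as TSV under `output_dir` together with a
#' JSON manifest (package version, seed, per-stage timings). Deterministic
#' under a fixed seed.
#'
#' @param config a `run_config` (see [read_run_config()]) or a list coercible
#'   to one.
#' @return invisibly, a list with `enrichment`, `strictness`, `meta` (or
#'   `NULL`), `overlaps`, `manifest`.
#' @export
run_all <- function(config) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "strictscreen",
                   version = as.character(packageVersion("strictscreen")),
                   seed = config$seed, n_boot = config$n_boot,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    el <- round(proc.time()[["elapsed"]] - t0, 2)
    manifest$stages[[stage]] <<- el
    message("[", stage, "] done in ", el, "s")
    out
  }

  panels <- tick("panels", load_config_panels(config))
  overlaps <- if (length(panels) >= 2L)
    tick("overlap_report",
         overlap_report(panels, file.path(config$output_dir, "panel_overlaps.tsv")))

  mapping <- if (!is.null(config$harmonization_map))
    read.delim(config$harmonization_map, colClasses = "character")

  enrich_tables <- list()
  strict_tables <- list()
  for (d in config$datasets) {
    store <- tick(paste0("load_", d$label),
                  read_expression(d$matrix, d$annotation, d$genes, d$cells,
                                  orientation = d$orientation))
    if (isTRUE(d$normalize))
      store <- tick(paste0("normalize_", d$label), normalize_cpm(store))
    ctm <- celltype_means(store, min_cells = config$min_cells_per_type)
    spec <- specificity_matrix(ctm)
    enr <- tick(paste0("enrich_", d$label), {
      res <- lapply(seq_along(panels), function(i)
        bootstrap_enrichment(spec, panels[[i]], n_boot = config$n_boot,
                             seed = config$seed + i))
      do.call(rbind, res)
    })
    enrich_tables[[d$label]] <- enr
    write.table(enr, file.path(config$output_dir,
                               paste0("enrichment_", d$label, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    str_tab <- tick(paste0("strictness_", d$label),
                    panel_compare(store, panels,
                                  cell_types = rownames(ctm$means),
                                  scope = config$strictness_scope,
                                  n_boot = config$n_boot, seed = config$seed))
    strict_tables[[d$label]] <- str_tab
    write.table(str_tab, file.path(config$output_dir,
                                   paste0("strictness_", d$label, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  meta <- NULL
  if (length(enrich_tables) >= 2L) {
    meta <- tick("meta", meta_table(enrich_tables, mapping = mapping))
    write.table(meta, file.path(config$output_dir, "meta.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    warning("single dataset: meta-analysis stage skipped")
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(enrichment = enrich_tables, strictness = strict_tables,
                 meta = meta, overlaps = overlaps, manifest = manifest))
}
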