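#' Construct a gene panel
#'
#' A gene panel is a named, ordered set of gene symbols with free-text
#' provenance. Symbols are whitespace-trimmed and uppercased; duplicates (after
#' normalization) are dropped keeping the first occurrence, with a warning,
#' since curated lists commonly carry aliases in both cases.
#'
#' @param genes character vector of gene symbols.
#' @param name panel label.
#' @param source free-text provenance (e.g. a database accession or "GWAS").
#' @return An object of class `gene_panel`: a list with elements `name`,
#'   `genes` (normalized symbols) and `source`.
#' @examples
#' gene_panel(c("Sod1", "FUS", "TARDBP"), name = "demo")
#' @export
gene_panel <- function(genes, name, source = NA_character_) {
  stopifnot(is.character(genes), length(name) == 1L)
  genes <- toupper(trimws(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop("empty panel: '", name, "' has no gene symbols")
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("panel '", name, "': dropped ", length(dup),
            " duplicate symbol(s) after normalization: ",
            paste(dup, collapse = ", "))
    genes <- genes[!duplicated(genes)]
  }
  structure(list(name = as.character(name), genes = genes,
                 source = as.character(source)),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("gene_panel '", x$name, "': ", length(x$genes), " genes",
      if (!is.na(x$source)) paste0(" [", x$source, "]"), "\n", sep = "")
  cat("  ", paste(utils::head(x$genes, 8L), collapse = ", "),
      if (length(x$genes) > 8L) ", ...", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_panel <- function(x) length(x$genes)

#' Read a gene panel from a plain-text or GMT file
#'
#' Plain-text panels hold one symbol per line; lines starting with `#` are
#' comments. GMT rows are tab-separated: set name, description, then symbols.
#' The format is chosen by file extension (`.gmt` = GMT) unless given.
#'
#' @param path file path.
#' @param name panel label; defaults to the file stem (plain text) or the GMT
#'   set name.
#' @param format `"auto"`, `"txt"` or `"gmt"`.
#' @param source provenance recorded on the panel; defaults to the path.
#' @return A [gene_panel]. A multi-row GMT file returns a list of panels.
#' @export
read_gene_panel <- function(path, name = NULL, format = c("auto", "txt", "gmt"),
                            source = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read panel file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "txt"
  if (is.null(source)) source <- path
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s*#", lines)]
  if (length(lines) == 0L) stop("empty panel: no symbols in ", path)
  if (format == "txt") {
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
    return(gene_panel(lines, name = name, source = source))
  }
  panels <- lapply(lines, function(row) {
    f <- strsplit(row, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT row (need name, description, genes): ", path)
    gene_panel(f[-(1:2)], name = f[1L], source = source)
  })
  if (!is.null(name) && length(panels) == 1L) panels[[1L]]$name <- name
  if (length(panels) == 1L) panels[[1L]] else panels
}

#' Overlap between two gene panels
#'
#' Set intersection under normalized symbols, with the counts needed for a
#' Venn-style report.
#'
#' @param a,b [gene_panel] objects.
#' @return An object of class `panel_overlap`: list with `panel_a`, `panel_b`,
#'   `shared` (character), `count_a`, `count_b`, `count_shared`.
#' @examples
#' p <- gene_panel(c("SOD1", "FUS"), "a")
#' q <- gene_panel(c("SOD1", "TBK1"), "b")
#' panel_overlap(p, q)$shared
#' @export
panel_overlap <- function(a, b) {
  stopifnot(inherits(a, "gene_panel"), inherits(b, "gene_panel"))
  shared <- intersect(a$genes, b$genes)
  structure(list(panel_a = a$name, panel_b = b$name, shared = shared,
                 count_a = length(a$genes), count_b = length(b$genes),
                 count_shared = length(shared)),
            class = "panel_overlap")
}

#' @export
print.panel_overlap <- function(x, ...) {
  cat("panel_overlap: ", x$panel_a, " (", x$count_a, ") x ", x$panel_b,
      " (", x$count_b, "): ", x$count_shared, " shared\n", sep = "")
  if (x$count_shared) cat("  ", paste(x$shared, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Restrict a panel to a dataset's gene universe
#'
#' Human disease symbols are scored in mouse datasets (and vice versa), so
#' matching is case-insensitive on symbols; an optional two-column ortholog map
#' (panel symbol, dataset symbol) overrides symbol equality. Retained genes are
#' renamed to the dataset's spelling so they index the expression matrix
#' directly.
#'
#' @param panel a [gene_panel].
#' @param universe character vector of dataset gene identifiers.
#' @param ortholog_map optional `data.frame`/matrix with two columns: panel
#'   symbol, dataset symbol.
#' @return list with `panel` (a [gene_panel] using dataset spellings) and
#'   `dropped` (panel symbols without a match).
#' @export
restrict_to_universe <- function(panel, universe, ortholog_map = NULL) {
  stopifnot(inherits(panel, "gene_panel"))
  if (length(universe) == 0L) stop("empty gene universe")
  uni_key <- toupper(trimws(universe))
  keys <- panel$genes
  if (!is.null(ortholog_map)) {
    ortholog_map <- as.data.frame(ortholog_map)
    stopifnot(ncol(ortholog_map) >= 2L)
    from <- toupper(trimws(as.character(ortholog_map[[1L]])))
    to <- toupper(trimws(as.character(ortholog_map[[2L]])))
    hit <- match(keys, from)
    keys <- ifelse(is.na(hit), keys, to[hit])
  }
  pos <- match(keys, uni_key)
  dropped <- panel$genes[is.na(pos)]
  kept <- universe[pos[!is.na(pos)]]
  if (length(kept) == 0L)
    stop("panel disjoint from dataset: no symbol of '", panel$name,
         "' matches the gene universe")
  if (length(dropped))
    message("panel '", panel$name, "': ", length(dropped),
            " symbol(s) not in gene universe, dropped")
  # keep the dataset's own spelling so genes index the matrix directly;
  # bypass gene_panel(), whose normalization would re-uppercase them
  out <- structure(list(name = panel$name, genes = unique(kept),
                        source = panel$source),
                   class = "gene_panel")
  list(panel = out, dropped = dropped)
}

#' Pairwise overlap report for a set of panels
#'
#' @param panels list of [gene_panel] objects.
#' @param path optional path; when given the table is written as TSV.
#' @return data.frame with columns panel_a, panel_b, count_a, count_b,
#'   count_shared, shared (comma-joined).
#' @export
overlap_report <- function(panels, path = NULL) {
  stopifnot(length(panels) >= 2L)
  cmb <- utils::combn(length(panels), 2L)
  rows <- apply(cmb, 2L, function(ij) {
    ov <- panel_overlap(panels[[ij[1L]]], panels[[ij[2L]]])
    data.frame(panel_a = ov$panel_a, panel_b = ov$panel_b,
               count_a = ov$count_a, count_b = ov$count_b,
               count_shared = ov$count_shared,
               shared = paste(ov$shared, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
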