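test_that("store construction enforces the annotation contract", {
  m <- matrix(1:12, nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2", "c3", "c4")))
  st <- tiny_store(m, c(c1 = "A", c2 = "A", c3 = "B", c4 = "B"))
  expect_identical(ncol(st), 4L)
  expect_identical(sort(unique(colData(st)$cell_type)), c("A", "B"))

  # cells lacking annotation are dropped with a message
  expect_message(
    st3 <- expression_store(methods::as(m, "CsparseMatrix"),
                            c(c1 = "A", c2 = "A", c3 = "B")),
    "dropping 1")
  expect_identical(ncol(st3), 3L)
  expect_error(expression_store(methods::as(m, "CsparseMatrix"),
                                c(c1 = NA, c2 = NA, c3 = NA, c4 = NA)),
               "no annotated cells")
})

test_that("file round trip: mtx + ids + annotation load to an identical store", {
  sim <- simulate_cells(sim_config(n_cell_types = 3, cells_per_type = 15,
                                   n_genes = 60, n_markers_per_type = 5,
                                   n_strict_genes = 5, n_tolerant_genes = 5,
                                   seed = 11))
  d <- withr::local_tempdir()
  write_fixture(sim$store, sim$truth, d)
  st2 <- read_expression(file.path(d, "matrix.mtx"),
                         file.path(d, "annotation.tsv"),
                         genes_path = file.path(d, "genes.txt"),
                         cells_path = file.path(d, "cells.txt"))
  expect_identical(dim(st2), dim(sim$store))
  expect_equal(as.matrix(assay(st2, "counts")),
               as.matrix(assay(sim$store, "counts")))
  expect_identical(colData(st2)$cell_type, colData(sim$store)$cell_type)
})

test_that("mismatched identifier files error out", {
  sim <- simulate_cells(sim_config(n_cell_types = 2, cells_per_type = 5,
                                   n_genes = 20, n_markers_per_type = 2,
                                   n_strict_genes = 2, n_tolerant_genes = 2,
                                   seed = 3))
  d <- withr::local_tempdir()
  write_fixture(sim$store, sim$truth, d)
  writeLines(c("only", "four", "gene", "ids"), file.path(d, "genes.txt"))
  expect_error(read_expression(file.path(d, "matrix.mtx"),
                               file.path(d, "annotation.tsv"),
                               genes_path = file.path(d, "genes.txt"),
                               cells_path = file.path(d, "cells.txt")),
               "genes file length")
})

test_that("dense delimited input (cells x genes) loads", {
  d <- withr::local_tempdir()
  tab <- data.frame(cell = c("c1", "c2"), g1 = c(1L, 0L), g2 = c(2L, 5L))
  write.table(tab, file.path(d, "m.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(c("cell_id\tcell_type", "c1\tA", "c2\tA"),
             file.path(d, "ann.tsv"))
  st <- read_expression(file.path(d, "m.tsv"), file.path(d, "ann.tsv"))
  expect_identical(dim(st), c(2L, 2L))
  expect_equal(as.numeric(assay(st)["g2", ]), c(2, 5))
})

test_that("CPM rows sum to 1e6, zero cells drop, and it is idempotent", {
  m <- matrix(c(1, 1, 2,
                0, 0, 0,
                10, 30, 60), nrow = 3, byrow = FALSE,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  st <- tiny_store(m, c("A", "A", "B"))
  expect_message(stn <- normalize_cpm(st), "zero total")
  cpm <- assay(stn, "cpm")
  expect_identical(ncol(cpm), 2L)
  # cell c1 held counts (1, 1, 2) -> proportions times a million
  expect_equal(as.numeric(cpm[, "c1"]), c(250000, 250000, 500000))
  expect_equal(unname(Matrix::colSums(cpm)), rep(1e6, 2), tolerance = 1e-9)
  # renormalizing already-CPM values changes nothing
  st2 <- tiny_store(as.matrix(cpm), c("A", "B"))
  expect_equal(as.matrix(assay(normalize_cpm(st2), "cpm")), as.matrix(cpm),
               tolerance = 1e-12)
})

test_that("celltype means equal the brute-force per-type loop", {
  set.seed(9)
  m <- matrix(rpois(6 * 20, 4), nrow = 6,
              dimnames = list(paste0("g", 1:6), paste0("c", 1:20)))
  ct <- sample(c("A", "B", "C"), 20, replace = TRUE)
  st <- tiny_store(m, ct)
  ctm <- celltype_means(st, min_cells = 1L)
  for (t in c("A", "B", "C")) {
    for (g in rownames(m)) {
      expect_equal(ctm$means[t, g], mean(m[g, ct == t]), tolerance = 1e-12)
    }
  }
  expect_identical(unname(ctm$n_cells[c("A", "B", "C")]),
                   as.integer(table(ct)[c("A", "B", "C")]))
  # cell-count-weighted average of type means recovers the global gene mean
  w <- ctm$n_cells / sum(ctm$n_cells)
  expect_equal(as.numeric(w %*% ctm$means), unname(rowMeans(m)),
               tolerance = 1e-12)
})

test_that("small cell types are dropped by the min_cells filter", {
  m <- matrix(1, nrow = 2, ncol = 5,
              dimnames = list(c("g1", "g2"), paste0("c", 1:5)))
  st <- tiny_store(m, c("A", "A", "A", "A", "B"))
  expect_message(ctm <- celltype_means(st, min_cells = 2L), "dropping 1")
  expect_identical(rownames(ctm$means), "A")
  expect_error(celltype_means(st, min_cells = 10L), "no cell type")
})
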