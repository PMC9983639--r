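test_that("fold change divides by the reference mean and rejects zero reference", {
  expect_equal(fold_change(c(1, 2, 3), 2), c(0.5, 1.0, 1.5))
  expect_equal(fold_change(rep(4, 3), 4), rep(1, 3))
  expect_error(fold_change(c(0, 0), 0), "unusable")
})

test_that("strictness is the inverse sample SD of fold changes", {
  # hand computation: C = (0.5, 1, 1.5), sum sq dev 0.5, var 0.25, SD 0.5
  expect_equal(strictness(c(0.5, 1.0, 1.5))$S, 2.0)
  expect_true(strictness(rep(1, 10))$degenerate)
  expect_error(strictness(1), ">= 2 cells")
  # strictly decreasing in the SD of C
  sds <- c(0.2, 0.5, 1, 2)
  S <- vapply(sds, function(s) strictness(c(1 - s, 1 + s))$S, numeric(1))
  expect_true(all(diff(S) < 0))
})

test_that("strictness is invariant to scaling a gene's raw expression", {
  set.seed(31)
  e <- rpois(50, 8)
  k <- 7.3
  s1 <- strictness(fold_change(e, mean(e)))$S
  s2 <- strictness(fold_change(k * e, mean(k * e)))$S
  expect_equal(s1, s2, tolerance = 1e-12)

  # and through the matrix path, on raw counts
  m <- matrix(rpois(40 * 30, 6), nrow = 40,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("c%02d", 1:30)))
  st1 <- tiny_store(m, rep(c("A", "B"), each = 15))
  m2 <- m; m2[5, ] <- m2[5, ] * 11
  st2 <- tiny_store(m2, rep(c("A", "B"), each = 15))
  S1 <- gene_strictness(st1, cell_type = "A")
  S2 <- gene_strictness(st2, cell_type = "A")
  expect_equal(S1$S, S2$S, tolerance = 1e-12)
})

test_that("matrix-path strictness equals the per-gene loop under both scopes", {
  set.seed(17)
  m <- matrix(rpois(10 * 24, 5), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("c%02d", 1:24)))
  ct <- rep(c("A", "B"), each = 12)
  st <- tiny_store(m, ct)
  for (scope in c("global-ref", "within-type")) {
    Sdf <- gene_strictness(st, cell_type = "A", scope = scope)
    for (g in rownames(m)) {
      ref <- if (scope == "global-ref") mean(m[g, ]) else mean(m[g, ct == "A"])
      if (ref == 0) {
        expect_false(Sdf$usable[Sdf$gene == g])
      } else {
        expected <- strictness(fold_change(m[g, ct == "A"], ref))$S
        expect_equal(Sdf$S[Sdf$gene == g], expected, tolerance = 1e-9,
                     label = paste(scope, g))
      }
    }
  }
})

test_that("unusable and degenerate genes are flagged and excluded from the test", {
  m <- rbind(zero = rep(0, 6), flat = rep(3, 6),
             ok1 = c(1, 2, 3, 4, 5, 6), ok2 = c(2, 2, 3, 3, 4, 4),
             ok3 = c(5, 1, 4, 2, 6, 3))
  colnames(m) <- paste0("c", 1:6)
  st <- tiny_store(m, rep("A", 6))
  S <- gene_strictness(st, cell_type = "A")
  expect_false(S$usable[S$gene == "zero"])
  expect_true(S$degenerate[S$gene == "flat"])
  r <- geneset_strictness_test(S, gene_panel(c("ok1", "ok2"), "p"),
                               n_boot = 200L, seed = 1)
  expect_identical(r$n_genes, 2L)  # universe held ok1..ok3 only
  expect_error(
    suppressMessages(
      geneset_strictness_test(S, gene_panel(c("ok1", "flat"), "p2"),
                              n_boot = 200L, seed = 1)),
    "target too small")
})

test_that("CLT test returns the normal upper tail of the fitted null", {
  set.seed(23)
  S <- stats::setNames(rgamma(400, 5, 2), sprintf("g%03d", 1:400))
  pan <- gene_panel(names(S)[1:25], "p")
  r <- geneset_strictness_test(S, pan, n_boot = 5000L, seed = 7,
                               keep_null = TRUE)
  nm <- attr(r, "null_means")
  expect_equal(r$null_mu, mean(nm), tolerance = 1e-12)
  expect_equal(r$null_sigma, sqrt(mean((nm - mean(nm))^2)), tolerance = 1e-12)
  expect_equal(r$p,
               pnorm((r$observed_mean - r$null_mu) / r$null_sigma,
                     lower.tail = FALSE), tolerance = 1e-12)
  # an observed mean at mu + 1.645 sigma would sit at p ~ 0.05
  expect_equal(pnorm(1.6449, lower.tail = FALSE), 0.05, tolerance = 1e-4)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.001, 56), 0.056)
  expect_equal(bonferroni_adjust(0.02, 1), 0.02)
  expect_equal(bonferroni_adjust(0.5, 10), 1)
  expect_error(bonferroni_adjust(0, 3), "0, 1")
})

test_that("panel_compare separates strict from tolerant panels with ground truth", {
  sim <- simulate_cells(sim_config(n_cell_types = 4, cells_per_type = 200,
                                   n_genes = 800, n_markers_per_type = 10,
                                   n_strict_genes = 60, n_tolerant_genes = 60,
                                   seed = 41))
  st <- normalize_cpm(sim$store)
  panels <- list(gene_panel(sim$truth$strict_genes, "strict_like"),
                 gene_panel(sim$truth$tolerant_genes, "tolerant_like"))
  res <- panel_compare(st, panels, cell_types = c("CT01", "CT02"),
                       n_boot = 2000L, seed = 5)
  expect_identical(nrow(res), 4L)
  expect_identical(unique(res$n_tests), 2L)
  expect_equal(res$p_bonf, pmin(1, res$p * 2))
  strict_p <- res$p_bonf[res$panel == "strict_like"]
  tol_p <- res$p[res$panel == "tolerant_like"]
  expect_true(all(strict_p < 0.05))
  expect_true(all(tol_p > 0.05))
})
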