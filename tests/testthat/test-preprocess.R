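test_that("cells strictly below the UMI threshold are removed, genes without counts dropped", {
  m <- toy_counts(c(199, 200, 5000))
  m <- rbind(m, Zero = rep(0L, 3))
  res <- qc_filter(m, 200)
  expect_identical(res$report$removed_ids, "cell1")
  expect_equal(ncol(res$counts), 2)
  expect_false("Zero" %in% rownames(res$counts))
  expect_equal(res$report$n_cells_in, 3)
  expect_equal(res$report$n_cells_removed, 1)
})

test_that("QC report medians are computed over retained cells", {
  m <- toy_counts(c(100, 300, 500))
  res <- qc_filter(m, 50)
  expect_equal(res$report$median_total_umi, 300)
  res2 <- qc_filter(m, 200)
  expect_equal(res2$report$median_total_umi, 400)  # mid-mean of (300, 500)
})

test_that("qc_filter is idempotent and errors when nothing passes", {
  sim <- simulate_sc_counts(sc_sim_spec(n_cells_per_condition = 80L,
                                        n_genes = 400L, rng_seed = 21L))
  once <- qc_filter(sim$counts, 200)
  twice <- qc_filter(once$counts, 200)
  expect_identical(unname(as.matrix(once$counts)), unname(as.matrix(twice$counts)))
  expect_equal(twice$report$n_cells_removed, 0)
  expect_error(qc_filter(toy_counts(c(10, 20)), 100), "no cells pass QC")
})

test_that("size factors scale totals to the median, with mid-mean even-count convention", {
  expect_equal(unname(compute_size_factors(toy_counts(c(100, 200, 400)))),
               c(0.5, 1.0, 2.0), ignore_attr = TRUE)
  expect_equal(unname(compute_size_factors(toy_counts(c(300, 300, 300)))),
               c(1, 1, 1), ignore_attr = TRUE)
  f <- compute_size_factors(toy_counts(c(100, 200, 300, 400)))
  expect_equal(unname(f), c(0.4, 0.8, 1.2, 1.6), ignore_attr = TRUE)
  expect_equal(median(f), 1)
})

test_that("normalization matches the log10(count/factor + 1) contract", {
  m <- matrix(c(9L, 0L), 1, 2, dimnames = list("g", c("c1", "c2")))
  f <- stats::setNames(c(1, 0.5), c("c1", "c2"))
  e <- normalize_log10(m, f)
  expect_equal(e["g", "c1"], 1.0)
  m2 <- matrix(c(0L, 9L), 1, 2, dimnames = list("g", c("c1", "c2")))
  e2 <- normalize_log10(m2, f)
  expect_equal(e2["g", "c1"], 0)
  expect_equal(e2["g", "c2"], log10(19))
  expect_identical(attr(e, "transform")$log_base, 10)
  expect_error(normalize_log10(m, f[1]), "not aligned")
})

test_that("normalization preserves within-cell rank order of counts", {
  sim <- simulate_sc_counts(sc_sim_spec(n_cells_per_condition = 30L,
                                        n_genes = 300L, rng_seed = 22L))
  qc <- qc_filter(sim$counts, 200)
  e <- normalize_log10(qc$counts, compute_size_factors(qc$counts))
  for (j in c(1, 10, ncol(e))) {
    expect_equal(order(e[, j], seq_len(nrow(e))),
                 order(qc$counts[, j], seq_len(nrow(e))))
  }
})

test_that("class exclusions keep ribosomal and cell-cycle genes out of selection", {
  set.seed(23)
  n_cells <- 100
  genes <- c("Rpl13", "Rps6", "Mrpl12", "Mki67", paste0("G", 1:96))
  m <- matrix(rpois(length(genes) * n_cells, 5), nrow = length(genes),
              dimnames = list(genes, paste0("c", 1:n_cells)))
  storage.mode(m) <- "integer"
  e <- normalize_log10(m, compute_size_factors(m))
  vg <- select_variable_genes(e, 20, cell_cycle_genes = "Mki67")
  expect_setequal(vg$excluded_by_class, c("Rpl13", "Rps6", "Mrpl12", "Mki67"))
  expect_length(intersect(vg$selected, vg$excluded_by_class), 0)
})

test_that("genes with planted excess dispersion are recovered by the noise model", {
  set.seed(24)
  n_genes <- 2000; n_cells <- 300
  mu <- rgamma(n_genes, shape = 2, rate = 1) + 0.5
  m <- matrix(rpois(n_genes * n_cells, rep(mu, n_cells)), nrow = n_genes)
  planted <- sample(n_genes, 20)
  # overdispersed: variance 8x the Poisson variance at the same mean
  m[planted, ] <- rnbinom(20 * n_cells, mu = rep(mu[planted], n_cells),
                          size = rep(mu[planted] / 7, n_cells))
  dimnames(m) <- list(sprintf("G%04d", seq_len(n_genes)), paste0("c", seq_len(n_cells)))
  storage.mode(m) <- "integer"
  e <- normalize_log10(m, compute_size_factors(m))
  vg <- select_variable_genes(e, 100)
  expect_gte(length(intersect(vg$selected, sprintf("G%04d", planted))), 18)
})

test_that("score ties are broken lexicographically by gene id", {
  row <- c(1L, 3L, 0L, 2L, 5L, 1L, 0L, 4L)
  m <- rbind(b = row, d = row, a = row, c = row)
  colnames(m) <- paste0("c", seq_along(row))
  e <- normalize_log10(m, stats::setNames(rep(1, ncol(m)), colnames(m)))
  vg <- select_variable_genes(e, 2)
  expect_identical(vg$selected, c("a", "b"))
})

test_that("variable-gene scores are invariant to rescaling one cell by a constant", {
  set.seed(25)
  m <- matrix(rpois(200 * 51, 4), nrow = 200,
              dimnames = list(sprintf("G%03d", 1:200), paste0("c", 1:51)))
  storage.mode(m) <- "integer"
  m2 <- m
  m2[, 1] <- m2[, 1] * 3L  # scales that cell's factor; normalized values match
  e1 <- normalize_log10(m, compute_size_factors(m))
  e2 <- normalize_log10(m2, compute_size_factors(m2))
  v1 <- select_variable_genes(e1, 50)
  v2 <- select_variable_genes(e2, 50)
  expect_equal(v1$stats$score, v2$stats$score, tolerance = 1e-12)
  expect_identical(v1$selected, v2$selected)
})

test_that("requesting more variable genes than eligible is an error", {
  m <- toy_counts(c(300, 400, 500), n_genes = 10)
  e <- normalize_log10(m, compute_size_factors(m))
  expect_error(select_variable_genes(e, 50), "eligible")
})
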