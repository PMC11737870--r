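test_that("bulk preparation floors log2 values and honours exclusions", {
  md <- toy_bulk_metadata(c(3, 14), 2)
  genes <- c("low", "high")
  counts <- matrix(0, 2, nrow(md), dimnames = list(genes, md$column_id))
  counts["low", ] <- 3    # log2(4) ~ 2 -> floored at 3
  counts["high", ] <- 63  # log2(64) = 6
  tc <- prepare_bulk(counts, md, floor = 3)
  expect_true(all(tc$values["low", ] == 3))
  expect_equal(unname(tc$values["high", 1]), 6)
  expect_true(all(tc$values >= tc$floor_applied))

  tc2 <- prepare_bulk(counts, md, floor = 3, exclusions = "control_d03_r2")
  expect_false("control_d03_r2" %in% colnames(tc2$values))
  expect_identical(tc2$exclusions$column_id, "control_d03_r2")
  # dropping every sample of a condition x timepoint cell is fatal
  expect_error(prepare_bulk(counts, md, floor = 3,
                            exclusions = c("control_d03_r1", "control_d03_r2")),
               "zero samples")
})

test_that("excluding a replicate recomputes averages over the remainder", {
  md <- toy_bulk_metadata(c(3, 14), 3)
  # a dominant anchor gene keeps library factors near 1 so the variable
  # gene's averages respond to the exclusion, not to renormalization
  counts <- matrix(100, 2, nrow(md),
                   dimnames = list(c("g", "anchor"), md$column_id))
  counts["anchor", ] <- 100000
  counts["g", "trained_d03_r1"] <- 900
  tc_all <- prepare_bulk(counts, md, floor = 0)
  tc_excl <- prepare_bulk(counts, md, floor = 0, exclusions = "trained_d03_r1")
  avg_all <- average_replicates(tc_all)
  avg_excl <- average_replicates(tc_excl)
  expect_gt(avg_all$mean_log2$trained["g", "3"], avg_excl$mean_log2$trained["g", "3"])
  cols <- paste0("trained_d03_r", 2:3)
  expect_equal(unname(avg_excl$mean_log2$trained["g", "3"]),
               mean(tc_excl$values["g", cols]))
})

test_that("replicate averaging is the arithmetic mean and rejects missing data", {
  md <- toy_bulk_metadata(c(3, 14), 2)
  vals <- matrix(5, 1, nrow(md), dimnames = list("g", md$column_id))
  vals["g", c("control_d03_r1", "control_d03_r2")] <- c(3, 5)
  tc <- structure(list(values = vals, samples = md, floor_applied = 0,
                       exclusions = data.frame()), class = "timecourse")
  avg <- average_replicates(tc)
  expect_equal(unname(avg$mean_log2$control["g", "3"]), 4)
  vals["g", 1] <- NaN
  tc$values <- vals
  expect_error(average_replicates(tc), "missing values")
})

test_that("integral difference matches hand-worked trapezoids and closed forms", {
  mk_avg <- function(timepoints, control, trained) {
    structure(list(mean_log2 = list(control = matrix(control, 1,
                                                     dimnames = list("g", NULL)),
                                    trained = matrix(trained, 1,
                                                     dimnames = list("g", NULL))),
                   timepoints_days = timepoints,
                   conditions = c("control", "trained")),
              class = "avg_trajectories")
  }
  # identical trajectories
  expect_equal(unname(integral_difference(mk_avg(c(3, 14, 30), c(1, 2, 3), c(1, 2, 3)))), 0)
  # hand-worked toy: treated integral 4, control 2
  expect_equal(unname(integral_difference(mk_avg(c(0, 1, 2), c(1, 1, 1), c(1, 3, 1)))), 2)
  # constant offset delta over [3, 60]: D = delta * 57
  base <- c(4, 5, 6, 5, 4)
  expect_equal(unname(integral_difference(mk_avg(c(3, 14, 30, 45, 60), base, base + 2))),
               2 * 57)
  expect_error(integral_difference(mk_avg(c(3), 1, 2)), "2 timepoints")
})

test_that("trapezoid weights agree with pracma::trapz on random trajectories", {
  skip_if_not_installed("pracma")
  set.seed(41)
  for (i in 1:20) {
    t <- sort(sample(1:100, sample(2:8, 1)))
    y <- rnorm(length(t))
    expect_equal(sum(trapezoid_weights(t) * y), pracma::trapz(t, y), tolerance = 1e-12)
  }
})

test_that("integral difference is affine-equivariant", {
  set.seed(42)
  t <- c(3, 14, 30, 45, 60)
  ctrl <- matrix(rnorm(50 * 5, 6), 50, dimnames = list(paste0("g", 1:50), NULL))
  trt <- ctrl + matrix(rnorm(50 * 5, 0, 0.5), 50)
  mk <- function(a, b) structure(list(mean_log2 = list(control = a, trained = b),
                                      timepoints_days = t,
                                      conditions = c("control", "trained")),
                                 class = "avg_trajectories")
  D1 <- integral_difference(mk(ctrl, trt))
  D2 <- integral_difference(mk(3 * ctrl + 7, 3 * trt + 7))
  expect_equal(D2, 3 * D1, tolerance = 1e-10)
})

test_that("the 3-SD rule calls strict exceedances of the moment-fitted null", {
  D <- stats::setNames(c(rep(0, 999), 100), c(paste0("g", 1:999), "hit"))
  cl <- call_training_genes(D, 3)
  expect_equal(cl$null_mean, 0.1)
  expect_equal(cl$null_sd, sd(D))
  expect_identical(cl$upregulated, "hit")

  expect_warning(cl0 <- call_training_genes(stats::setNames(rep(2, 10), paste0("g", 1:10))),
                 "SD = 0")
  expect_length(cl0$upregulated, 0)
  expect_error(call_training_genes(c(g = 1)), "at least 2")
})

test_that("calling is scale-equivariant and supports robust/down-call variants", {
  set.seed(43)
  D <- stats::setNames(rnorm(5000), paste0("g", 1:5000))
  up1 <- call_training_genes(D, 3)$upregulated
  up2 <- call_training_genes(D * 17, 3)$upregulated
  expect_identical(up1, up2)

  rob <- call_training_genes(D, 3, robust = TRUE)
  expect_equal(rob$null_mean, median(D))
  expect_equal(rob$null_sd, mad(D))

  down <- call_training_genes(c(D, low = -100), 3, call_downregulated = TRUE)
  expect_true("low" %in% down$downregulated)
  expect_null(call_training_genes(D, 3)$downregulated)
})

test_that("bulk PCA z-scores genes and separates shifted sample groups", {
  set.seed(44)
  vals <- matrix(rnorm(100 * 10, 6, 0.3), 100,
                 dimnames = list(paste0("g", 1:100), paste0("s", 1:10)))
  vals[1:40, 6:10] <- vals[1:40, 6:10] + 4
  emb <- bulk_pca(vals)
  z <- (vals - rowMeans(vals)) / apply(vals, 1, sd)
  expect_lt(max(abs(rowMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-9)
  pc1 <- emb$coordinates[, 1]
  expect_true(max(pc1[1:5]) < min(pc1[6:10]) || min(pc1[1:5]) > max(pc1[6:10]))

  # duplicated sample lands on coincident coordinates
  dup <- cbind(vals, s11 = vals[, 10])
  emb2 <- bulk_pca(dup)
  expect_equal(emb2$coordinates["s11", ], emb2$coordinates["s10", ], tolerance = 1e-9)

  # zero-variance genes dropped with a warning; all-constant is an error
  vals0 <- vals
  vals0[1, ] <- 3
  expect_warning(bulk_pca(vals0), "zero-variance")
  expect_error(bulk_pca(matrix(3, 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))),
               "zero variance")
})
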