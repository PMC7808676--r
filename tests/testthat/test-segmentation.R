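# segmentation: scaled Otsu, the morphological pipeline, QC overlays.

test_that("scaled Otsu maximizes between-class variance (exhaustive oracle)", {
  # bimodal deltas: cut must land strictly between the modes
  v <- c(rep(10, 500), rep(100, 500))
  g <- voxel_grid(array(v, c(10, 10, 10)), c(1, 1, 1))
  t1 <- scaled_otsu_threshold(g, 1.0)
  expect_gt(t1, 10); expect_lt(t1, 100)
  expect_equal(otsu_between_var(v, t1), otsu_best_var(v))

  # random small integer images: achieved variance equals exhaustive best
  set.seed(21)
  for (i in 1:20) {
    v <- sample(0:30, 200, replace = TRUE)
    g <- voxel_grid(array(v, c(2, 10, 10)), c(1, 1, 1))
    t0 <- scaled_otsu_threshold(g, 1.0)
    expect_equal(otsu_between_var(v, t0), otsu_best_var(v), tolerance = 1e-12)
  }

  expect_equal(scaled_otsu_threshold(g, 0), 0)        # scaling identity
  const <- voxel_grid(array(7, c(3, 3, 3)), c(1, 1, 1))
  expect_error(scaled_otsu_threshold(const, 1), "degenerate")
})

test_that("segment_cell recovers a rendered ellipsoid (analytic oracle)", {
  sp <- c(0.3, 0.1, 0.1)
  semi <- c(6, 5, 4)
  n <- 2L * as.integer(ceiling((semi + 1) / sp)) + 1L
  truth <- analytic_ellipsoid(n, sp, semi)
  g <- voxel_grid(array(100 * truth, dim = n), sp)
  m <- segment_cell(g)
  jac <- sum(m & truth) / sum(m | truth)
  expect_gte(jac, 0.95)
  lab <- cytoshell:::label_components(array(as.logical(m), dim = dim(m)), 26L)
  expect_identical(max(lab), 1L)  # exactly one component
})

test_that("objects below the minimum volume are deleted", {
  sp <- c(0.3, 0.2, 0.2)
  n <- c(40L, 80L, 120L)
  ball <- function(c0, vol_um3) {
    r <- (vol_um3 * 3 / (4 * pi))^(1 / 3)
    zc <- ((seq_len(n[1]) - c0[1]) * sp[1] / r)^2
    yc <- ((seq_len(n[2]) - c0[2]) * sp[2] / r)^2
    xc <- ((seq_len(n[3]) - c0[3]) * sp[3] / r)^2
    array(outer(outer(zc, yc, "+"), xc, "+") <= 1, dim = n)
  }
  big <- ball(c(20, 40, 40), 50)
  small <- ball(c(20, 40, 100), 4)
  g <- voxel_grid(array(100 * (big | small), dim = n), sp)
  m <- segment_cell(g, min_volume_um3 = 10)
  expect_gt(sum(m & big), 0)
  expect_identical(sum(m & small), 0L)
  expect_gte(mask_volume_um3(m), 10)
})

test_that("mask is invariant under positive intensity scaling", {
  set.seed(22)
  sp <- c(0.3, 0.25, 0.25)
  truth <- analytic_ellipsoid(c(15L, 21L, 21L), sp, c(1.8, 2.2, 2.0))
  base <- 50 * truth + array(stats::rexp(15 * 21 * 21, 1 / 5), dim(truth))
  g1 <- voxel_grid(array(base, dim = dim(truth)), sp)
  for (const in c(0.25, 3, 117)) {
    g2 <- voxel_grid(array(base * const, dim = dim(truth)), sp)
    m1 <- segment_cell(g1, min_volume_um3 = 1)
    m2 <- segment_cell(g2, min_volume_um3 = 1)
    expect_identical(as.vector(m1), as.vector(m2))
  }
})

test_that("degenerate inputs error; redilation is extensive on pruned stage", {
  expect_error(segment_cell(voxel_grid(array(0, c(4, 8, 8)) + 0,
                                       c(1, 1, 1))), "degenerate|foreground")
  sp <- c(0.3, 0.25, 0.25)
  truth <- analytic_ellipsoid(c(15L, 21L, 21L), sp, c(1.8, 2.2, 2.0))
  g <- voxel_grid(array(100 * truth, dim = dim(truth)), sp)
  res <- segment_cell(g, min_volume_um3 = 1, keep_stages = TRUE)
  expect_true(all(res$mask[res$stages$pruned]))  # final mask superset
})

test_that("qc_overlay writes a deterministic nonempty PNG", {
  sp <- c(0.3, 0.25, 0.25)
  truth <- analytic_ellipsoid(c(9L, 15L, 15L), sp, c(1.0, 1.4, 1.2))
  g <- voxel_grid(array(100 * truth + 5, dim = dim(truth)), sp)
  m <- cell_mask(truth, sp)
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  qc_overlay(g, m, f1)
  qc_overlay(g, m, f2)
  expect_gt(file.size(f1), 0)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # PNG magic bytes
  expect_identical(readBin(f1, "raw", 8),
                   as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)))
  empty <- cell_mask(array(FALSE, dim(truth)), sp)
  expect_error(qc_overlay(g, empty, tempfile()), "no foreground")
  expect_error(qc_overlay(g, cell_mask(truth[, , 1:10], sp), tempfile()),
               "shapes")
})
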