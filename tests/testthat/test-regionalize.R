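# regionalize: exact EDT vs brute force, shell partition, volume bisection.

test_that("distance_map matches the voxel-center convention on hand cases", {
  # a single voxel: nearest background is one x-step (0.1 um) away
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  dm <- distance_map(cell_mask(m, c(0.3, 0.1, 0.1)))
  expect_equal(dm[2, 2, 2], 0.1)

  # 5^3 cube centered in 7^3, isotropic: center 3.0, face voxels 1.0
  m <- array(FALSE, c(7, 7, 7)); m[2:6, 2:6, 2:6] <- TRUE
  dm <- distance_map(cell_mask(m, c(1, 1, 1)))
  expect_equal(dm[4, 4, 4], 3)
  expect_equal(dm[2, 4, 4], 1)
  expect_equal(unclass(dm)[!m], array(0, sum(!m)), ignore_attr = TRUE)

  expect_error(distance_map(cell_mask(array(FALSE, c(3, 3, 3)), c(1, 1, 1))),
               "empty")
})

test_that("distance_map equals the brute-force oracle on random masks", {
  set.seed(31)
  for (i in 1:50) {
    m <- random_test_mask(16L)
    sp <- stats::runif(3, 0.05, 0.5)
    dm <- distance_map(cell_mask(m, sp))
    expect_lt(max(abs(unclass(dm) - brute_force_edt(m, sp))), 1e-9)
  }
})

test_that("distance_map is 1-Lipschitz along voxel steps", {
  set.seed(32)
  m <- analytic_ellipsoid(c(13L, 19L, 17L), c(0.3, 0.2, 0.2), c(1.5, 1.6, 1.4))
  sp <- c(0.3, 0.2, 0.2)
  d <- unclass(distance_map(cell_mask(m, sp)))
  for (ax in 1:3) {
    steps <- apply(d, setdiff(1:3, ax), diff)
    expect_lte(max(abs(steps)), sp[ax] + 1e-12)
  }
})

test_that("shell partition covers the mask exactly with half-open cuts", {
  m <- analytic_ellipsoid(c(21L, 37L, 37L), c(0.3, 0.15, 0.15),
                          c(2.5, 2.2, 2.4))
  mask <- cell_mask(m, c(0.3, 0.15, 0.15))
  dmap <- distance_map(mask)
  part <- assign_regions(dmap, c(0.6, 1.5))
  expect_identical(sum(part$label > 0), sum(m))          # exact cover
  expect_equal(sum(part$region_volumes), part$cell_volume)
  expect_identical(sum(part$label == 1 & !m), 0L)

  # the stated interval convention at the cut points
  d <- c(0.5, 1.0, 2.0, 4.0)
  lab <- findInterval(d, c(1, 3)) + 1L  # same convention the package uses
  expect_identical(lab, c(1L, 2L, 2L, 3L))
  da <- structure(array(c(0, d, 0, 0, 0) , c(2, 2, 2)),
                  spacing = c(1, 1, 1), class = c("distance_map", "array"))
  p <- assign_regions(da, c(1, 3))
  expect_identical(as.integer(p$label[2:5]), c(1L, 2L, 2L, 3L))

  # thin sheet: no peripheral or deep volume
  sheet <- array(FALSE, c(5, 9, 9)); sheet[3, 2:8, 2:8] <- TRUE
  psheet <- assign_regions(distance_map(cell_mask(sheet, c(0.3, 0.1, 0.1))),
                           c(1, 3))
  expect_equal(unname(psheet$region_volumes[c("peripheral", "deep")]), c(0, 0))
  expect_error(assign_regions(dmap, c(3, 1)), "b1 < b2")
})

test_that("membrane volume is monotone in b1", {
  m <- analytic_ellipsoid(c(15L, 25L, 25L), c(0.3, 0.2, 0.2), c(2, 2.2, 2.1))
  dmap <- distance_map(cell_mask(m, c(0.3, 0.2, 0.2)))
  vols <- vapply(seq(0.2, 1.8, by = 0.2), function(b1)
    assign_regions(dmap, c(b1, 2))$region_volumes[["membrane"]], numeric(1))
  expect_true(all(diff(vols) >= 0))
})

test_that("split_halves bisects in-mask volume and is deterministic", {
  sphere <- analytic_ellipsoid(c(15L, 21L, 21L), c(0.3, 0.2, 0.2),
                               c(1.9, 1.9, 1.9))
  mask <- cell_mask(sphere, c(0.3, 0.2, 0.2))
  for (ax in c("+z", "-z", "+y", "-x")) {
    hs <- split_halves(mask, ax)
    plane_max <- max(apply(unclass(mask), cytoshell:::axis_table()[[ax]][1], sum))
    expect_lte(abs(hs$ventral_voxels - hs$dorsal_voxels), plane_max)
    expect_identical(hs$ventral_voxels + hs$dorsal_voxels, sum(mask))
    hs2 <- split_halves(mask, ax)
    expect_identical(hs$plane_offset, hs2$plane_offset)
  }
  # orientation: ventral lies on the annotated positive side
  hs <- split_halves(mask, "+y")
  ys <- slice.index(unclass(mask), 2)
  expect_gt(mean(ys[hs$half_label == 1L]), mean(ys[hs$half_label == 2L]))
  expect_error(split_halves(cell_mask(array(FALSE, c(3, 3, 3)), c(1, 1, 1)),
                            "+y"), "empty")
  expect_error(split_halves(mask, "up"), "axis")
})
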