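# quantify: percentile thresholding, enrichment, Manders overlap, polarity.

test_that("nearest-rank percentile keeps the stated voxel fraction", {
  set.seed(41)
  sp <- c(0.3, 0.2, 0.2)
  m <- array(TRUE, c(10, 40, 25))                  # 10,000 in-mask voxels
  g <- voxel_grid(array(sample(1:10000), c(10, 40, 25)), sp)
  p <- threshold_puncta(g, cell_mask(m, sp), sigma_um = 0, percentile = 95)
  expect_lte(abs(sum(p) - 500), 1)                  # nearest-rank count oracle
  frac <- sum(p) / sum(m)
  expect_gte(frac, 0.049); expect_lte(frac, 0.051)

  # constant in-mask intensity: warning and empty mask, not an error
  gc <- voxel_grid(array(7, c(4, 6, 6)), sp)
  expect_warning(pc <- threshold_puncta(gc, cell_mask(array(TRUE, c(4, 6, 6)), sp)),
                 "constant")
  expect_identical(sum(pc), 0L)

  # sigma 0 on a delta spike: puncta = the spike voxel only
  gs <- array(10, c(4, 10, 10)); gs[2, 5, 5] <- 100
  ps <- threshold_puncta(voxel_grid(gs, sp),
                         cell_mask(array(TRUE, c(4, 10, 10)), sp),
                         sigma_um = 0, percentile = 95)
  expect_identical(which(ps), which(gs == 100))
  expect_error(threshold_puncta(g, cell_mask(array(FALSE, c(10, 40, 25)), sp)),
               "empty")
  expect_error(threshold_puncta(g, cell_mask(m, sp), percentile = 100),
               "percentile")
})

test_that("regional enrichment reproduces direct formula arithmetic", {
  sp <- c(0.1, 0.1, 0.1)
  # 1000 voxels: regions of 200/300/500 with 30/10/10 puncta
  lab <- array(rep(1:3, times = c(200, 300, 500)), c(10, 10, 10))
  part <- manual_partition(lab, sp)
  pm <- array(FALSE, c(10, 10, 10))
  pm[c(1:30, 201:210, 501:510)] <- TRUE
  enr <- regional_enrichment(puncta_mask(pm, sp), part)
  expect_equal(enr$E, c(3.0, 2 / 3, 0.4))
  expect_equal(attr(enr, "V_cell_um3"), 1000 * prod(sp))

  # uniform density: E = 1 everywhere
  pu <- array(seq_len(1000) %% 10 == 0, c(10, 10, 10))
  expect_equal(regional_enrichment(puncta_mask(pu, sp), part)$E, rep(1, 3))

  # all puncta in a membrane shell of 20% volume: E = 5, others 0
  lab2 <- array(rep(1:3, times = c(200, 300, 500)), c(10, 10, 10))
  pm2 <- array(FALSE, c(10, 10, 10)); pm2[1:50] <- TRUE
  e2 <- regional_enrichment(puncta_mask(pm2, sp), manual_partition(lab2, sp))
  expect_equal(e2$E, c(5, 0, 0))

  expect_error(regional_enrichment(puncta_mask(array(FALSE, c(10, 10, 10)), sp),
                                   part), "no puncta")
  # puncta outside the cell are rejected
  bad <- array(FALSE, c(10, 10, 10)); bad[1] <- TRUE
  lab3 <- lab; lab3[1] <- 0L
  expect_error(regional_enrichment(puncta_mask(bad, sp),
                                   manual_partition(lab3, sp)), "subset")
})

test_that("enrichment conservation holds on random configurations", {
  set.seed(42)
  for (i in 1:100) {
    d <- sample(4:8, 3, replace = TRUE)
    lab <- array(sample(0:3, prod(d), TRUE), d)
    if (sum(lab > 0) < 4) next
    pm <- array(stats::runif(prod(d)) < 0.3 & lab > 0, d)
    if (!any(pm)) { pm[which(lab > 0)[1]] <- TRUE }
    sp <- stats::runif(3, 0.05, 0.4)
    part <- manual_partition(lab, sp)
    enr <- regional_enrichment(puncta_mask(pm, sp), part)
    ok <- !is.na(enr$E)
    expect_equal(sum(enr$E[ok] * enr$V_region_um3[ok]), part$cell_volume,
                 tolerance = 1e-9)
    # single-region partition (whole cell): enrichment identically 1
    lab1 <- array((lab > 0) * 1L, d)
    e1 <- regional_enrichment(puncta_mask(pm, sp), manual_partition(lab1, sp))
    expect_equal(e1$E[1], 1)
  }
})

test_that("Manders overlap: identity, disjointness, asymmetry, decomposition", {
  sp <- c(0.2, 0.2, 0.2)
  lab <- array(rep(1:3, times = c(200, 300, 500)), c(10, 10, 10))
  part <- manual_partition(lab, sp)
  a <- array(FALSE, c(10, 10, 10)); a[c(5:54, 220:260, 600:608)] <- TRUE
  same <- manders_overlap(puncta_mask(a, sp), puncta_mask(a, sp), part)
  expect_equal(same$moc_cell, 1)
  expect_equal(unname(same$moc_region[!is.na(same$moc_region)]),
               rep(1, sum(!is.na(same$moc_region))))

  b <- array(FALSE, c(10, 10, 10)); b[c(100:120, 400:420)] <- TRUE
  disj <- manders_overlap(puncta_mask(a, sp), puncta_mask(b, sp), part)
  expect_equal(disj$moc_cell, 0)

  # V(A)=100, V(A&B)=25, V(B)=50 -> moc(A,B)=0.25, moc(B,A)=0.5
  a2 <- array(FALSE, c(10, 10, 10)); a2[1:100] <- TRUE
  b2 <- array(FALSE, c(10, 10, 10)); b2[76:125] <- TRUE
  expect_equal(manders_overlap(puncta_mask(a2, sp), puncta_mask(b2, sp),
                               part)$moc_cell, 0.25)
  expect_equal(manders_overlap(puncta_mask(b2, sp), puncta_mask(a2, sp),
                               part)$moc_cell, 0.5)
})

test_that("whole-cell MOC decomposes over shells (100 random configurations)", {
  set.seed(43)
  for (i in 1:100) {
    d <- sample(4:8, 3, replace = TRUE)
    lab <- array(sample(0:3, prod(d), TRUE), d)
    inm <- which(lab > 0)
    if (length(inm) < 6) next
    a <- array(FALSE, d); a[sample(inm, max(1, length(inm) %/% 3))] <- TRUE
    b <- array(FALSE, d); b[sample(inm, max(1, length(inm) %/% 3))] <- TRUE
    sp <- stats::runif(3, 0.05, 0.4)
    part <- manual_partition(lab, sp)
    cr <- manders_overlap(puncta_mask(a, sp), puncta_mask(b, sp), part)
    ok <- !is.na(cr$moc_region)
    lhs <- sum((cr$V_A_region_um3[ok] / cr$V_A_um3) * cr$moc_region[ok])
    expect_equal(cr$moc_cell, lhs, tolerance = 1e-12)
  }
})

test_that("ventral/dorsal ratio follows the volume quotient", {
  sp <- c(0.3, 0.2, 0.2)
  sphere <- analytic_ellipsoid(c(15L, 21L, 21L), sp, c(1.9, 1.9, 1.9))
  mask <- cell_mask(sphere, sp)
  hs <- split_halves(mask, "+y")

  # mirror-symmetric puncta about the bisection plane -> ratio ~ 1
  ny <- dim(sphere)[2]
  pm <- sphere & (slice.index(sphere, 2) %in% c(3, ny - 2))
  r <- ventral_dorsal_ratio(puncta_mask(pm, sp), hs)
  expect_equal(r$vd_ratio, 1.0)

  # 60 ventral vs 40 dorsal voxels -> 1.5
  iv <- which(hs$half_label == 1L); id <- which(hs$half_label == 2L)
  pm2 <- array(FALSE, dim(sphere)); pm2[iv[1:60]] <- TRUE; pm2[id[1:40]] <- TRUE
  expect_equal(ventral_dorsal_ratio(puncta_mask(pm2, sp), hs)$vd_ratio, 1.5)

  # dorsal empty: flagged undefined, not an exception
  pm3 <- array(FALSE, dim(sphere)); pm3[iv[1:10]] <- TRUE
  r3 <- ventral_dorsal_ratio(puncta_mask(pm3, sp), hs)
  expect_true(r3$undefined)
  expect_true(is.na(r3$vd_ratio))
})

test_that("quantify_cell composes the statistics deterministically", {
  sim <- simulate_cell(small_sim_spec(seed = 9, tier = "image"))
  cfg <- small_config()
  row1 <- quantify_cell(sim$channels, sim$record, cfg)
  row2 <- quantify_cell(sim$channels, sim$record, cfg)
  expect_identical(row1, row2)
  expect_true(all(is.finite(c(row1$E_membrane, row1$E_peripheral,
                              row1$E_deep, row1$moc_cell, row1$vd_ratio))))

  # without the endosome channel: colocalization absent, enrichment present
  row3 <- quantify_cell(sim$channels["receptor"], sim$record, cfg)
  expect_true(is.na(row3$moc_cell))
  expect_true(is.finite(row3$E_membrane))
})
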