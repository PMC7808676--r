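# synthetic_data: determinism, truth bookkeeping, self-consistency, recovery.

test_that("simulation is deterministic given a seed", {
  s1 <- simulate_cell(small_sim_spec(seed = 5, tier = "image"))
  s2 <- simulate_cell(small_sim_spec(seed = 5, tier = "image"))
  expect_identical(as.vector(s1$channels$receptor),
                   as.vector(s2$channels$receptor))
  expect_identical(as.vector(s1$channels$rab), as.vector(s2$channels$rab))
  expect_identical(s1$truth$E, s2$truth$E)
  s3 <- simulate_cell(small_sim_spec(seed = 6, tier = "image"))
  expect_false(identical(as.vector(s1$channels$receptor),
                         as.vector(s3$channels$receptor)))
})

test_that("stored truth equals brute-force counting on the truth masks", {
  sim <- simulate_cell(small_sim_spec(seed = 7, tier = "mask"))
  tr <- sim$truth
  lab <- tr$partition_label
  a <- as.logical(tr$puncta_a); dim(a) <- dim(lab)
  n_reg <- vapply(1:3, function(k) sum(lab == k), numeric(1))
  n_a <- vapply(1:3, function(k) sum(a & lab == k), numeric(1))
  E_oracle <- (n_a / n_reg) / (sum(n_a) / sum(n_reg))
  expect_equal(unname(tr$E), E_oracle)

  # truth self-consistency: the quantify module reproduces the stored truth
  part <- assign_regions(distance_map(tr$mask), small_sim_spec()$boundaries)
  enr <- regional_enrichment(tr$puncta_a, part)
  expect_identical(stats::setNames(enr$E, enr$region), tr$E)
  cr <- manders_overlap(tr$puncta_a, tr$puncta_b, part)
  expect_identical(cr$moc_cell, tr$moc_cell)
  expect_identical(cr$moc_region, tr$moc_region)
  vd <- ventral_dorsal_ratio(tr$puncta_a,
                             split_halves(tr$mask, "+y"))
  expect_identical(vd$vd_ratio, tr$vd_ratio)
})

test_that("overlap construction forces moc(A,B) = f on the truth masks", {
  spec <- small_sim_spec(seed = 8, tier = "mask",
                         overlap_f = 0.3, occupancy_b_only = 0)
  sim <- simulate_cell(spec)
  nA <- sum(sim$truth$puncta_a)
  expect_equal(sim$truth$moc_cell, round(0.3 * nA) / nA)
  expect_lt(abs(sim$truth$moc_cell - 0.3), 1e-3)
  # with no B-only puncta, B is a subset of A
  expect_true(all(sim$truth$puncta_a[sim$truth$puncta_b]))
})

test_that("membrane occupancy monotonically drives truth enrichment", {
  Es <- vapply(c(0.05, 0.10, 0.20), function(occ) {
    spec <- small_sim_spec(seed = 10, tier = "mask",
                           occupancy_a = c(occ, 0.05, 0.05))
    simulate_cell(spec)$truth$E[["membrane"]]
  }, numeric(1))
  expect_true(all(diff(Es) > 0))
})

test_that("spec validation enforces geometry and probability ranges", {
  expect_error(simulation_spec(occupancy_a = c(1.5, 0, 0)), "occupancies")
  expect_error(simulation_spec(overlap_f = 2), "overlap_f")
  expect_error(simulation_spec(semi_axes_um = c(5, 7, 7)), "deep region")
})

test_that("mask-tier recovery is exact for every seed tested", {
  rep <- recovery_suite(3, tier = "mask", seed = 17,
                        spec_base = small_sim_spec(),
                        config = small_config())
  expect_identical(rep$E_membrane, rep$E_membrane_true)
  expect_identical(rep$E_peripheral, rep$E_peripheral_true)
  expect_identical(rep$E_deep, rep$E_deep_true)
  expect_identical(rep$moc_cell, rep$moc_cell_true)
  expect_identical(rep$vd_ratio, rep$vd_ratio_true)
  expect_identical(rep$jaccard, rep(1, 3))
})

test_that("noise-free, PSF-free image tier segments close to truth", {
  rep <- recovery_suite(2, tier = "image", seed = 19,
                        spec_base = small_sim_spec(psf_sigma_um = 0, snr = Inf),
                        config = small_config())
  expect_true(all(rep$jaccard >= 0.9))
})
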