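# Independent oracles and fixture builders shared across the suite.
# These deliberately use brute-force / enumeration formulations that share
# no code with the package's computational paths.

# All-pairs exact EDT: for every in-mask voxel, the minimum physical
# distance to any background voxel center, including a one-voxel background
# pad outside the array (the package's border convention).
brute_force_edt <- function(mask, sp) {
  d <- dim(mask)
  all3 <- as.matrix(expand.grid(z = 0:(d[1] + 1), y = 0:(d[2] + 1),
                                x = 0:(d[3] + 1)))
  ins <- all3[, 1] >= 1 & all3[, 1] <= d[1] &
         all3[, 2] >= 1 & all3[, 2] <= d[2] &
         all3[, 3] >= 1 & all3[, 3] <= d[3]
  inside <- all3[ins, , drop = FALSE]
  bg <- rbind(all3[!ins, , drop = FALSE],
              inside[!mask[inside], , drop = FALSE])
  out <- array(0, d)
  fg <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    dd <- (bg[, 1] - fg[i, 1])^2 * sp[1]^2 +
          (bg[, 2] - fg[i, 2])^2 * sp[2]^2 +
          (bg[, 3] - fg[i, 3])^2 * sp[3]^2
    out[fg[i, 1], fg[i, 2], fg[i, 3]] <- sqrt(min(dd))
  }
  out
}

# exhaustive Otsu: best between-class variance over every candidate cut
# (midpoints of consecutive distinct values); returns the variance achieved
# by an arbitrary threshold t for comparison
otsu_between_var <- function(v, t) {
  w0 <- mean(v <= t)
  if (w0 == 0 || w0 == 1) return(0)
  w0 * (1 - w0) * (mean(v[v <= t]) - mean(v[v > t]))^2
}
otsu_best_var <- function(v) {
  uv <- sort(unique(v))
  cuts <- (uv[-1] + uv[-length(uv)]) / 2
  max(vapply(cuts, function(t) otsu_between_var(v, t), numeric(1)))
}

# analytic ellipsoid membership on the voxel-center lattice, grid centered
analytic_ellipsoid <- function(n, spacing, semi_axes) {
  ctr <- (n + 1) / 2
  zc <- ((seq_len(n[1]) - ctr[1]) * spacing[1] / semi_axes[1])^2
  yc <- ((seq_len(n[2]) - ctr[2]) * spacing[2] / semi_axes[2])^2
  xc <- ((seq_len(n[3]) - ctr[3]) * spacing[3] / semi_axes[3])^2
  array(outer(outer(zc, yc, "+"), xc, "+") <= 1, dim = n)
}

# two-sided Fisher exact p for a 2x2 table by full hypergeometric
# enumeration: sum of probabilities of all tables with the same margins
# whose probability does not exceed the observed one
fisher_enum_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hand-assembled region partition (no distance transform involved):
# label vector of 0/1/2/3 reshaped to a 3D array
manual_partition <- function(label_arr, spacing) {
  counts <- vapply(1:3, function(k) sum(label_arr == k), numeric(1))
  nm <- c("membrane", "peripheral", "deep")
  structure(list(
    label = label_arr, region_names = nm,
    region_volumes = stats::setNames(counts * prod(spacing), nm),
    region_voxels = stats::setNames(counts, nm),
    cell_volume = sum(counts) * prod(spacing),
    cell_voxels = sum(counts),
    boundaries = c(1, 3), spacing = spacing
  ), class = "region_partition")
}

# fast small-geometry simulation spec for pipeline-level tests
small_sim_spec <- function(seed = 1L, tier = "image", ...) {
  simulation_spec(semi_axes_um = c(3.2, 3.4, 3.1),
                  spacing = c(0.3, 0.25, 0.25),
                  boundaries = c(0.6, 1.5),
                  pad_um = 0.8, seed = seed, tier = tier, ...)
}

small_config <- function() {
  cfg <- default_config()
  cfg$spacing <- c(0.3, 0.25, 0.25)
  cfg$boundaries <- c(0.6, 1.5)
  cfg
}

random_test_mask <- function(max_side = 16L, p = 0.5) {
  d <- sample(4:max_side, 3, replace = TRUE)
  m <- array(stats::runif(prod(d)) < p, dim = d)
  if (!any(m)) m[1, 1, 1] <- TRUE
  m
}
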