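test_that("empty, invalid and degenerate inputs are handled", {
  g <- generate_nucleus_stack(0, modality_profile("confocal"),
                              nucleus = list(semi_axes_nm = c(2000, 2000, 800)),
                              seed = 1)
  expect_equal(g$truth$count, 0)
  # pure background: mean close to the background level, no structure
  expect_lt(abs(mean(g$stack$data) - 10), 1)
  expect_error(generate_nucleus_stack(-3, modality_profile("sim")),
               "non-negative")
  expect_error(
    generate_nucleus_stack(5, modality_profile("sim"),
                           nucleus = list(semi_axes_nm = c(9000, 9000, 3000)),
                           stack_dim = c(32, 32, 8), seed = 1),
    "does not fit")
})

test_that("generators are pure functions of their arguments (seed determinism)", {
  a <- small_separated_world(10, seed = 7)
  b <- small_separated_world(10, seed = 7)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$centroids_nm, b$truth$centroids_nm)
  c <- small_separated_world(10, seed = 8)
  expect_false(identical(a$stack$data, c$stack$data))
})

test_that("ground truth obeys count conservation and stays inside the nucleus", {
  g <- small_separated_world(20, seed = 3)
  expect_equal(nrow(g$truth$centroids_nm), g$truth$count)
  expect_equal(g$truth$count, 20)
  rel <- sweep(g$truth$centroids_nm, 2, g$truth$centre_nm, `-`)
  r2 <- rowSums(sweep(rel, 2, g$truth$semi_axes_nm, `/`)^2)
  expect_true(all(r2 <= 1 + 1e-9))
  # nuclear mask covers every centroid's voxel
  expect_equal(dim(g$truth$nuclear_mask), dim(g$stack$data))
})

test_that("minimum separation placement respects the exclusion ellipsoid", {
  g <- small_separated_world(15, seed = 5)
  cen <- g$truth$centroids_nm
  for (i in seq_len(nrow(cen) - 1)) {
    d <- sweep(cen[-seq_len(i), , drop = FALSE], 2, cen[i, ], `-`)
    m <- (d[, 1]^2 + d[, 2]^2) / 1040^2 + d[, 3]^2 / 2830^2
    expect_true(all(m >= 1))
  }
})

test_that("clustered placement produces the requested cluster structure", {
  g <- clustered_world(50, cluster_size = 5, seed = 2)
  expect_equal(g$truth$count, 50)
  expect_equal(length(unique(g$truth$cluster)), 10)
  expect_true(all(table(g$truth$cluster) == 5))
  # members stay near their cluster centre
  for (cl in unique(g$truth$cluster)) {
    m <- g$truth$centroids_nm[g$truth$cluster == cl, , drop = FALSE]
    ctr <- colMeans(m)
    expect_lt(max(sqrt(rowSums(sweep(m, 2, ctr, `-`)^2))), 600)
  }
})

test_that("resolution ordering: sim recovers at least as many foci as confocal", {
  # moderately clustered truths rendered at both modalities; higher
  # resolution can only split, never merge, the same geometry
  for (s in 1:6) {
    g <- clustered_world(40, cluster_size = 4, seed = s)
    n_sim <- count_sim_rfi(g$stack)$count
    conf <- render_foci_stack(g$truth, modality_profile("confocal"),
                              seed = s + 100)
    n_conf <- count_confocal_rfi(conf)$count
    expect_gte(n_sim, n_conf)
  }
})

test_that("modality profiles keep the documented resolution ordering", {
  expect_lt(modality_profile("sim")$lateral_psf_sigma,
            modality_profile("confocal")$lateral_psf_sigma)
  expect_error(modality_profile("sim", voxel_xy = -4), "positive")
})
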