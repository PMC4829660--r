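test_that("mean filter matches a brute-force disk average", {
  set.seed(42)
  m <- matrix(runif(20 * 16), 20, 16)
  st <- slice_stack(m)
  out <- mean_filter_slices(st, 1.5)$data[, , 1]
  # independent oracle: direct double loop over the disk
  offs <- expand.grid(di = -1:1, dj = -1:1)
  offs <- offs[offs$di^2 + offs$dj^2 <= 1.5^2, ]
  for (i in c(1, 7, 20)) for (j in c(1, 9, 16)) {
    ii <- i + offs$di; jj <- j + offs$dj
    ok <- ii >= 1 & ii <= 20 & jj >= 1 & jj <= 16
    expect_equal(out[i, j], mean(m[cbind(ii[ok], jj[ok])]), tolerance = 1e-12)
  }
})

test_that("mean filter trivial properties hold", {
  st <- slice_stack(matrix(3.5, 10, 10))
  expect_equal(mean_filter_slices(st)$data, st$data)
  # single bright pixel spreads to V/9 at the centre
  m <- matrix(0, 11, 11); m[6, 6] <- 9
  expect_equal(mean_filter_slices(slice_stack(m))$data[6, 6, 1], 1)
  # output range never exceeds input range
  set.seed(1)
  m2 <- matrix(rnorm(100), 10, 10)
  out <- mean_filter_slices(slice_stack(m2))$data
  expect_gte(min(out), min(m2))
  expect_lte(max(out), max(m2))
})

test_that("normalize_stack is an order-preserving affine map onto [0,1]", {
  st <- slice_stack(matrix(c(2, 4, 6, 2), 2, 2))
  nm <- normalize_stack(st)
  expect_equal(sort(unique(as.vector(nm$data))), c(0, 0.5, 1))
  expect_equal(normalize_stack(nm)$data, nm$data)
  set.seed(2)
  m <- matrix(runif(64), 8, 8)
  expect_equal(order(normalize_stack(slice_stack(m))$data), order(m))
  expect_error(normalize_stack(slice_stack(matrix(1, 4, 4))), "dynamic range")
})

test_that("find_stack_maxima marks blob summits once and flat slices never", {
  b <- gauss_blob(32, 32, 16, 16, 3)
  mx <- find_stack_maxima(slice_stack(b), 0.1)
  expect_equal(sum(mx$data), 1)
  expect_equal(which(mx$data == 1, arr.ind = TRUE)[1, 1:2],
               c(dim1 = 16, dim2 = 16))
  # two blobs further apart than 2 sigma: both marked
  b2 <- gauss_blob(32, 32, 10, 10, 3) + gauss_blob(32, 32, 24, 24, 3)
  mx2 <- find_stack_maxima(slice_stack(b2 / max(b2)), 0.1)
  expect_equal(sum(mx2$data), 2)
  # flat slice: no maxima
  expect_equal(sum(find_stack_maxima(slice_stack(matrix(0.3, 16, 16)),
                                     0.1)$data), 0)
  # a small bump within tolerance of a higher maximum is merged
  b3 <- gauss_blob(32, 32, 16, 10, 3) + 0.04 * gauss_blob(32, 32, 16, 26, 2)
  mx3 <- find_stack_maxima(slice_stack(b3 / max(b3)), 0.1)
  expect_equal(sum(mx3$data), 1)
})

test_that("reconstruct_focal_objects is linear in the number of maxima", {
  z <- slice_stack(matrix(0, 24, 24))
  expect_equal(sum(reconstruct_focal_objects(z)$data), 0)
  one <- matrix(0, 24, 24); one[12, 12] <- 1
  r1 <- reconstruct_focal_objects(slice_stack(one), 1.0)
  expect_equal(sum(r1$data), 1, tolerance = 1e-9)  # normalized kernel
  three <- matrix(0, 24, 24)
  # markers deep enough that all blurred mass stays in fully interior pixels
  three[cbind(c(8, 8, 16), c(8, 16, 12))] <- 1
  r3 <- reconstruct_focal_objects(slice_stack(three), 1.0)
  expect_equal(sum(r3$data), 3, tolerance = 1e-9)
  expect_error(reconstruct_focal_objects(slice_stack(matrix(0.5, 4, 4))),
               "binary")
})

test_that("count_objects_3d uses 26-connectivity and size/threshold rules", {
  a <- array(0, dim = c(6, 6, 2))
  # two 4-voxel bars touching only diagonally across slices -> 1 object
  a[2, 2:5, 1] <- 1
  a[3, 2:5, 2] <- 1
  st <- voxel_stack(a, 40, 125, "test")
  expect_equal(count_objects_3d(st, 0.5, min_voxels = 4)$count, 1)
  expect_equal(count_objects_3d(st, 2, min_voxels = 1)$count, 0)
  # min_voxels prunes small components
  a2 <- array(0, dim = c(8, 8, 1)); a2[2, 2, 1] <- 1; a2[6, 5:8, 1] <- 1
  st2 <- voxel_stack(a2, 40, 125, "test")
  expect_equal(count_objects_3d(st2, 0.5, min_voxels = 4)$count, 1)
  expect_equal(count_objects_3d(st2, 0.5, min_voxels = 1)$count, 2)
  expect_error(count_objects_3d(st2, 0.5, min_voxels = 0), ">= 1")
})

test_that("triangle threshold equals an exhaustive geometric oracle", {
  # independent oracle: for every bin between the peak and the far tail end,
  # compute the point-to-line distance from first principles via projection
  oracle <- function(counts, mids) {
    p <- which.max(counts)
    ne <- which(counts > 0)
    e <- if ((ne[length(ne)] - p) >= (p - ne[1])) ne[length(ne)] else ne[1]
    a <- c(p, counts[p]); b <- c(e, counts[e])
    ab <- b - a
    best <- -Inf; best_i <- NA
    for (i in if (e > p) p:e else e:p) {
      v <- c(i, counts[i]) - a
      proj <- a + sum(v * ab) / sum(ab^2) * ab
      d <- sqrt(sum((c(i, counts[i]) - proj)^2))
      if (d > best + 1e-12) { best <- d; best_i <- i }
    }
    mids[best_i]
  }
  set.seed(99)
  for (rep in 1:40) {
    counts <- round(rgamma(1, 5) * 800 * dnorm(1:40, sample(5:12, 1), 2) +
                      rgamma(40, 2) * 5)
    if (sum(counts > 0) < 2) next
    expect_equal(triangle_threshold(counts), oracle(counts, seq_along(counts)))
  }
})

test_that("triangle threshold is translation-equivariant and validates input", {
  counts <- c(0, 2, 30, 80, 40, 12, 6, 4, 3, 2, 1, 1, 0, 0, 1, 0)
  thr <- triangle_threshold(counts, mids = 1:16)
  expect_equal(triangle_threshold(counts, mids = 1:16 + 7.5), thr + 7.5)
  # threshold falls on the longer-tail side of the peak
  expect_gt(thr, 4)
  expect_error(triangle_threshold(c(0, 5, 0)), "2 nonempty")
})

test_that("separate_touching_objects splits dumbbells and never merges", {
  sig <- 2.5
  # one spherical blob: untouched
  a <- array(0, dim = c(24, 24, 7))
  for (k in 1:7) a[, , k] <- gauss_blob(24, 24, 12, 12, sig,
                                        amp = exp(-(k - 4)^2 / 4))
  st <- voxel_stack(a, 40, 125, "test")
  lab <- count_objects_3d(st, 0.05, min_voxels = 4)$labels
  expect_equal(max(lab), 1)
  out <- separate_touching_objects(lab, st)
  expect_equal(max(out), 1)
  # dumbbell: two equal blobs with summits 3 sigma apart -> split into 2
  b <- array(0, dim = c(32, 32, 7))
  for (k in 1:7) {
    zf <- exp(-(k - 4)^2 / 4)
    b[, , k] <- gauss_blob(32, 32, 16, 12, sig, amp = zf) +
      gauss_blob(32, 32, 16, 12 + 3 * sig, sig, amp = zf)
  }
  st2 <- voxel_stack(b, 40, 125, "test")
  lab2 <- count_objects_3d(st2, 0.05, min_voxels = 4)$labels
  expect_equal(max(lab2), 1)  # fused at this threshold
  out2 <- separate_touching_objects(lab2, st2)
  expect_equal(max(out2), 2)
  # split never crosses the original object boundary
  expect_true(all(out2[lab2 == 0] == 0))
})
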