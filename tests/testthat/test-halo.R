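test_that("alternating cross/cube dilation matches the set-union oracle", {
  # single interior voxel: cross -> 7 voxels, then cube -> 81 voxels
  v <- array(FALSE, c(9, 9, 9)); v[5, 5, 5] <- TRUE
  bv <- binary_volume(v, 1)
  s1 <- rhombicuboctahedral_step(bv, 1)
  expect_equal(sum(s1$voxels), 7)
  s2 <- rhombicuboctahedral_step(s1, 2)
  expect_equal(sum(s2$voxels), 81)
  expect_identical(s2$voxels, oracle_dilate(s1$voxels, cube_offsets))

  # all-foreground is absorbing
  full <- binary_volume(array(TRUE, c(4, 4, 4)), 1)
  expect_identical(rhombicuboctahedral_step(full, 1)$voxels, full$voxels)
  expect_error(rhombicuboctahedral_step(bv, 0), "cycle_index")

  # random volumes: both parities equal the brute-force oracle, with border
  # clipping
  for (seed in 1:12) {
    r <- random_volume(c(12, 12, 12), 0.08, seed = seed)
    rv <- binary_volume(r, 1)
    expect_identical(rhombicuboctahedral_step(rv, 1)$voxels,
                     oracle_dilate(r, cross_offsets))
    expect_identical(rhombicuboctahedral_step(rv, 2)$voxels,
                     oracle_dilate(r, cube_offsets))
  }

  # monotone: A within B implies step(A) within step(B)
  set.seed(31)
  b <- random_volume(c(10, 10, 10), 0.2, seed = 31)
  a <- b & random_volume(c(10, 10, 10), 0.5, seed = 32)
  for (cyc in 1:2) {
    da <- rhombicuboctahedral_step(binary_volume(a, 1), cyc)$voxels
    db <- rhombicuboctahedral_step(binary_volume(b, 1), cyc)$voxels
    expect_true(all(db[da]))
  }
})

test_that("fill curve and Halo index reproduce the hand-enumerated center-voxel case", {
  v <- array(FALSE, c(3, 3, 3)); v[2, 2, 2] <- TRUE
  fc <- fill_curve(binary_volume(v, 1))
  expect_equal(fc$cycle, 0:2)
  expect_equal(fc$count, c(1, 7, 27))
  expect_equal(fc$fraction, c(1, 7, 27) / 27)
  hv <- halo_index(fc)
  expect_equal(hv, 1 + (0.9 - 7 / 27) / (1 - 7 / 27))
  expect_equal(round(hv, 3), 1.865)

  # already above target: degenerate single-point curve, Hv = 0
  w <- array(TRUE, c(3, 3, 3)); w[1, 1, 1] <- FALSE
  fcw <- fill_curve(binary_volume(w, 1))
  expect_equal(nrow(fcw), 1)
  expect_equal(halo_index(fcw), 0)

  # hitting the target exactly at a recorded cycle gives an integer Hv
  curve <- structure(data.frame(cycle = 0:2, count = c(10, 50, 90),
                                fraction = c(0.1, 0.5, 0.9)),
                     total = 100, target_fraction = 0.9,
                     cross_first = TRUE,
                     class = c("fill_curve", "data.frame"))
  expect_equal(halo_index(curve), 2.0)

  # non-monotone curves signal an upstream bug
  bad <- curve; bad$fraction <- c(0.5, 0.4, 0.95)
  expect_error(halo_index(bad), "non-decreasing")

  # fractions strictly increase until the target for any proper subset
  set.seed(41)
  r <- random_volume(c(15, 15, 15), 0.02, seed = 41)
  fr <- fill_curve(binary_volume(r, 1))
  expect_true(all(diff(fr$fraction) > 0))
  expect_gte(fr$fraction[nrow(fr)], 0.9)
  expect_error(fill_curve(binary_volume(array(FALSE, c(3, 3, 3)), 1)),
               "no foreground")
})

test_that("Hv never increases when foreground is added", {
  set.seed(51)
  base <- random_volume(c(15, 15, 15), 0.03, seed = 51)
  extra <- base | random_volume(c(15, 15, 15), 0.03, seed = 52)
  hv_base <- halo_index(fill_curve(binary_volume(base, 1)))
  hv_extra <- halo_index(fill_curve(binary_volume(extra, 1)))
  expect_lte(hv_extra, hv_base)
})

test_that("cohort normalization takes the largest initial volume and checks shapes", {
  mk <- function(n) {
    v <- array(FALSE, c(10, 10, 10)); v[seq_len(n)] <- TRUE
    binary_volume(v, 1)
  }
  expect_equal(cohort_normalization_count(list(mk(200), mk(800), mk(950))), 950)
  expect_equal(cohort_normalization_count(list(mk(7))), 7)
  odd <- binary_volume(array(TRUE, c(5, 5, 5)), 1)
  expect_error(cohort_normalization_count(list(mk(3), odd)), "dimensions")
})

test_that("nHv normalization subtracts growth-to-count cycles", {
  set.seed(61)
  v <- random_volume(c(12, 12, 12), 0.05, seed = 61)
  bv <- binary_volume(v, 1)
  # the cohort's largest sample: norm_cycles 0, nHv == Hv
  r <- normalized_halo(bv, sum(v))
  expect_equal(r$norm_cycles, 0)
  expect_equal(r$nHv, r$Hv)
  # a larger normalization count lowers nHv below Hv
  r2 <- normalized_halo(bv, sum(v) + 100)
  expect_gt(r2$norm_cycles, 0)
  expect_lt(r2$nHv, r2$Hv)
  expect_equal(r2$Hv, r$Hv)
  # invalid normalization counts
  expect_error(normalized_halo(bv, sum(v) - 1), "below")
  expect_error(normalized_halo(bv, length(v)), "fill target")

  # duplicating the cohort's largest sample changes no nHv
  samples <- list(bv, binary_volume(v & random_volume(c(12, 12, 12), 0.6, seed = 62), 1))
  nc1 <- cohort_normalization_count(samples)
  nc2 <- cohort_normalization_count(c(samples, samples[1]))
  expect_equal(nc1, nc2)
})

test_that("clustered layouts disperse worse than homogeneous ones", {
  # deterministic 2D-limit case on a single slice: evenly spread voxels vs
  # one compact blob with the same count
  even <- array(FALSE, c(21, 21, 1))
  even[seq(3, 21, by = 5), seq(3, 21, by = 5), 1] <- TRUE   # 16 spread voxels
  blob <- array(FALSE, c(21, 21, 1))
  blob[9:12, 9:12, 1] <- TRUE                                # 16 clustered voxels
  nc <- 16L
  nhv_even <- normalized_halo(binary_volume(even, 1), nc)$nHv
  nhv_blob <- normalized_halo(binary_volume(blob, 1), nc)$nHv
  expect_gt(nhv_blob, nhv_even)

  # seeded phantom pairs at matched counts: the median nHv of Thomas-cluster
  # layouts exceeds the homogeneous median
  pairs <- sapply(1:6, function(s) {
    hom <- generate_phantom(phantom_spec(dims = c(64, 64, 48), n_tubes = 8,
                                         radii = 2L, wall = Inf, layout = "homogeneous",
                                         fg_sd = 0, bg_sd = 0, seed = s))
    clu <- generate_phantom(phantom_spec(dims = c(64, 64, 48), n_tubes = 8,
                                         radii = 2L, wall = Inf, layout = "clustered",
                                         cluster_parents = 2L, cluster_sd = 5,
                                         fg_sd = 0, bg_sd = 0, seed = s))
    vh <- binary_volume(hom$wall_mask, 0.54)
    vc <- binary_volume(clu$wall_mask, 0.54)
    ncm <- max(sum(vh$voxels), sum(vc$voxels))
    c(normalized_halo(vh, ncm)$nHv, normalized_halo(vc, ncm)$nHv)
  })
  expect_gt(median(pairs[2, ]), median(pairs[1, ]))
})
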