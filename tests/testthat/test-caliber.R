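test_that("pixel-to-um2 conversion reproduces the caliber bin labels", {
  expect_equal(px_to_um2(128, 0.54), 37)
  expect_equal(px_to_um2(64, 0.54), 19)
  expect_equal(px_to_um2(0, 0.54), 0)
  b <- caliber_bins("set1", pitch = 0.54)
  expect_equal(b$lower_px, c(4, 8, 16, 32, 64, 128))
  expect_equal(b$upper_px, c(8, 16, 32, 64, 128, 256))
  expect_equal(b$lower_um2, c(1, 2, 5, 9, 19, 37))
  expect_equal(b$upper_um2, c(2, 5, 9, 19, 37, 75))
  expect_error(px_to_um2(-1), "non-negative")
  # all four presets exist and set_all collects 21 classes
  expect_equal(nrow(caliber_bins("set_all")), 21)
})

test_that("particle filter removes specks but keeps thin filaments", {
  a <- array(FALSE, c(12, 12, 12))
  a[2, 2, 2] <- TRUE              # isolated voxel: max cross-section 1 px
  a[6:7, 6:7, 6:7] <- TRUE        # 2x2x2 cube: max cross-section 4 px
  out <- remove_small_particles(binary_volume(a, 1), min_area_px = 4)
  expect_false(out$voxels[2, 2, 2])
  expect_equal(sum(out$voxels), 8)        # 4 is not < 4: retained

  # 1-voxel-thick filament of 50 voxels: yz section is 1 px but the
  # longitudinal sections reach 50 px
  f <- array(FALSE, c(8, 60, 8))
  f[4, 6:55, 4] <- TRUE
  keep <- remove_small_particles(binary_volume(f, 1), min_area_px = 4)
  expect_equal(sum(keep$voxels), 50)
  expect_equal(max(oracle_max_cross(f)), 50)  # oracle agrees on the criterion

  # never splits or creates components; empty passes through
  set.seed(5)
  r <- random_volume(c(14, 14, 14), 0.15, seed = 5)
  rv <- binary_volume(r, 1)
  out2 <- remove_small_particles(rv)
  expect_true(all(r[out2$voxels]))
  expect_lte(n_components(out2$voxels), n_components(r))
  empty <- binary_volume(array(FALSE, c(4, 4, 4)), 1)
  expect_equal(sum(remove_small_particles(empty)$voxels), 0)
})

test_that("vessel fill closes lumina in any orientation and is extensive + idempotent", {
  # hollow axis-aligned square tube, open ends along z
  a <- array(FALSE, c(9, 9, 12))
  a[3:7, 3:7, ] <- TRUE
  a[4:6, 4:6, ] <- FALSE
  f <- fill_vessels(binary_volume(a, 1))
  expect_true(all(f$voxels[3:7, 3:7, ]))
  expect_equal(sum(f$voxels), 25 * 12)

  # solid box unchanged
  b <- array(FALSE, c(6, 6, 6)); b[2:5, 2:5, 2:5] <- TRUE
  expect_identical(fill_vessels(binary_volume(b, 1))$voxels, b)

  # tube tilted 45 degrees in the xz-plane: z-slices show open "C" profiles
  # but the y-orientation slices close it; equals the brute-force
  # three-orientation fill oracle
  d <- c(9, 20, 20)
  tilted <- array(FALSE, d)
  for (i in 1:9) for (j in 1:20) for (k in 1:20) {
    # distance from voxel to the line through (5,3,3) with direction (0,1,1)/sqrt(2)
    p <- c(i - 5, j - 3, k - 3); u <- c(0, 1, 1) / sqrt(2)
    dist <- sqrt(sum((p - sum(p * u) * u)^2))
    if (dist <= 3.2 && dist > 1.8) tilted[i, j, k] <- TRUE
  }
  tv <- binary_volume(tilted, 1)
  ff <- fill_vessels(tv)
  expect_identical(ff$voxels, oracle_fill(tilted))
  expect_gt(sum(ff$voxels), sum(tilted))   # the lumen was filled
  expect_true(all(ff$voxels[tilted]))      # extensive
  expect_identical(fill_vessels(ff)$voxels, ff$voxels)     # idempotent

  set.seed(9)
  r <- random_volume(c(10, 10, 10), 0.25, seed = 9)
  fr <- fill_vessels(binary_volume(r, 1))
  expect_true(all(fr$voxels[r]))
  expect_identical(fr$voxels, oracle_fill(r))
})

test_that("minimal Cartesian cross-section matches geometry and the flood-fill oracle", {
  # solid box 3 (x) x 5 (y) x 7 (z): areas 5*7 / 3*7 / 3*5 -> min 15
  box <- array(FALSE, c(7, 5, 9))
  box[2:6, 2:4, 2:8] <- TRUE   # y extent 5, x extent 3, z extent 7
  mc <- min_cartesian_cross_section(binary_volume(box, 1))
  expect_equal(unique(mc[box]), 15)
  expect_equal(unique(mc[!box]), 0)

  # single voxel
  s <- array(FALSE, c(3, 3, 3)); s[2, 2, 2] <- TRUE
  expect_equal(min_cartesian_cross_section(binary_volume(s, 1))[2, 2, 2], 1)

  # digital cylinder radius 3 along z, long enough that the longitudinal
  # slivers exceed the disc area: every voxel reports the disc area
  cyl <- solid_cylinder_z(c(11, 11, 40), c(6, 6), 3)
  mcc <- min_cartesian_cross_section(binary_volume(cyl, 1))
  expect_equal(unique(mcc[cyl]), digital_disc_area(3))

  # random fixture vs the brute-force per-voxel flood-fill oracle
  set.seed(13)
  r <- random_volume(c(9, 9, 9), 0.3, seed = 13)
  expect_identical(min_cartesian_cross_section(binary_volume(r, 1)),
                   oracle_min_cross(r))
})

test_that("voxel classification bins by filled-vessel caliber and excludes out-of-range", {
  bins <- caliber_bins()
  # hollow 5x5 tube, wall 1: filled section 25 px -> class 3 (16-32 px);
  # wall voxels inherit the class of the filled tube, not of their thin wall
  a <- array(FALSE, c(9, 9, 12))
  a[3:7, 3:7, ] <- TRUE; a[4:6, 4:6, ] <- FALSE
  av <- binary_volume(a, 1)
  cls <- classify_voxels(av, bins = bins)
  expect_equal(unique(cls$map[a]), 3L)
  expect_equal(cls$volumes$wall_count[3], sum(a))
  expect_equal(cls$volumes$filled_count[3], 25 * 12)
  expect_equal(cls$volumes$lumen_count[3], (25 - 16) * 12)

  # min cross-section 15 px -> class 2 (8-16 px)
  b15 <- array(FALSE, c(7, 5, 9)); b15[2:6, 2:4, 2:8] <- TRUE
  c15 <- classify_voxels(binary_volume(b15, 1), bins = bins)
  expect_equal(unique(c15$map[b15]), 2L)

  # min cross-section 300 px -> excluded (label 0), absent from all classes
  big <- array(FALSE, c(27, 27, 30))
  big[2:21, 2:16, ] <- TRUE      # areas: x*z=450, y*z=600, x*y=300 -> min 300
  cbig <- classify_voxels(binary_volume(big, 1), bins = bins)
  expect_equal(unique(cbig$map[big]), 0L)
  expect_equal(sum(cbig$volumes$wall_count), 0)

  # partition: class wall masks are disjoint and union to input minus excluded
  set.seed(17)
  ph <- generate_phantom(phantom_spec(n_tubes = 6, seed = 17))
  vol <- binary_volume(ph$wall_mask, 0.54)
  cl <- classify_voxels(vol, bins = bins)
  stacked <- Reduce(`+`, lapply(cl$wall_masks, function(m) m * 1L))
  expect_lte(max(stacked), 1)    # pairwise disjoint
  in_class <- array(stacked > 0, dim(stacked))
  excluded <- vol$voxels & (cl$map == 0L)
  expect_identical(in_class | excluded, vol$voxels)

  # mismatched shapes error
  expect_error(
    classify_voxels(av, binary_volume(array(TRUE, c(3, 3, 3)), 1), bins),
    "shape")
})
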