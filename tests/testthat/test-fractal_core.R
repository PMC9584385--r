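test_that("occupied box counts match closed forms on exact shapes", {
  cube8 <- make_primitive("cube", 8)
  res <- occupied_box_count(cube8, 2)
  expect_equal(res$count, 64)
  expect_true(all(res$masses == 8))

  one <- voxel_mask(array(1L, c(1, 1, 1)))
  res1 <- occupied_box_count(one, 4)
  expect_equal(res1$count, 1)
  expect_equal(res1$masses, 1L)

  sponge2 <- make_menger_sponge(2)
  expect_equal(occupied_box_count(sponge2, 3)$count, 20)
  expect_equal(brute_box_count(sponge2$grid, 3)$count, 20)
})

test_that("box counts agree with brute-force enumeration on random masks", {
  for (seed in 1:50) {
    m <- random_test_mask(seed)
    for (r in c(2L, 3L, 5L, 8L)) {
      got <- occupied_box_count(m, r)
      want <- brute_box_count(m$grid, r)
      expect_equal(got$count, want$count,
                   info = sprintf("seed %d r %d", seed, r))
      expect_equal(sort(got$masses), want$masses,
                   info = sprintf("seed %d r %d", seed, r))
    }
  }
})

test_that("box-count curves obey mass bookkeeping and scale skipping", {
  m <- make_menger_sponge(4)
  curve <- box_count_curve(m, c(3, 9, 27))
  expect_equal(curve$counts, c(8000, 400, 20))
  for (i in seq_along(curve$box_sizes)) {
    r <- curve$box_sizes[i]
    expect_equal(length(curve$masses[[i]]), curve$counts[i])
    expect_true(all(curve$masses[[i]] >= 1 & curve$masses[[i]] <= r^3))
    expect_equal(sum(curve$masses[[i]]), curve$n_foreground)
  }

  small <- voxel_mask(array(1L, c(20, 20, 20)))
  c2 <- box_count_curve(small)
  expect_equal(c2$skipped$box_size, c(32, 64, 128))
  expect_true(all(c2$skipped$reason == "exceeds-bounding-box"))

  solid64 <- make_primitive("cube", 64)
  c3 <- box_count_curve(solid64)
  expect_equal(c3$counts, (64 / c3$box_sizes)^3)

  expect_error(box_count_curve(voxel_mask(array(1L, c(1, 1, 1))), c(2, 4)),
               "usable box sizes")
})

test_that("N(r) is non-increasing in r on random masks", {
  for (seed in 1:20) {
    m <- random_test_mask(seed + 100)
    curve <- box_count_curve(m, c(2, 3, 4, 6, 8))
    expect_true(all(diff(curve$counts) <= 0), info = sprintf("seed %d", seed))
  }
})

test_that("fractal dimension is exact for solid cube, slab, and Menger sponge", {
  fd_cube <- fractal_dimension(box_count_curve(make_primitive("cube", 64)))
  expect_equal(fd_cube$fd, 3, tolerance = 1e-9)
  expect_equal(fd_cube$fit$r_squared, 1, tolerance = 1e-9)

  slab <- make_primitive("slab", 64)
  fd_slab <- fractal_dimension(box_count_curve(slab, c(2, 4, 8, 16, 32)))
  expect_equal(fd_slab$fd, 2, tolerance = 1e-9)

  line <- make_primitive("line", 64)
  fd_line <- fractal_dimension(box_count_curve(line, c(2, 4, 8, 16, 32)))
  expect_equal(fd_line$fd, 1, tolerance = 1e-9)

  curve <- box_count_curve(make_menger_sponge(4), c(3, 9, 27))
  expect_equal(fractal_dimension(curve)$fd, log(20) / log(3), tolerance = 1e-9)
  expect_equal(fractal_dimension(curve, "mean-local-slope")$fd,
               log(20) / log(3), tolerance = 1e-9)
})

test_that("ols and mean-local-slope agree on exact power laws", {
  for (m in list(make_primitive("cube", 32), make_menger_sponge(3))) {
    sizes <- if (dim(m$grid)[1] == 32) c(2, 4, 8, 16) else c(3, 9, 27)
    curve <- box_count_curve(m, sizes)
    expect_equal(fractal_dimension(curve, "ols")$fd,
                 fractal_dimension(curve, "mean-local-slope")$fd,
                 tolerance = 1e-9)
  }
})

test_that("fd lies in [0,3], is exactly permutation-invariant, and stable under rotation", {
  permutations <- list(identity,
                       function(g) aperm(g, c(2, 3, 1)),
                       function(g) aperm(g, c(3, 1, 2)),
                       function(g) aperm(g, c(2, 1, 3)))
  # reflections move the lattice anchor to the opposite bounding-box corner,
  # so a 90-degree rotation perturbs counts slightly unless the box size
  # divides the bounding box; fd must still be stable to within a few percent
  rotations <- list(
    function(g) aperm(g[dim(g)[1]:1, , , drop = FALSE], c(2, 1, 3)),  # 90 deg z
    function(g) g[dim(g)[1]:1, , dim(g)[3]:1, drop = FALSE]           # 180 deg y
  )
  for (seed in 1:8) {
    m <- make_blob(10, irregularity = 0.5, gap_fraction = 0.2, seed = seed)
    fds <- vapply(permutations, function(rot) {
      mm <- voxel_mask(rot(m$grid))
      fractal_dimension(box_count_curve(mm, c(2, 4, 8)))$fd
    }, numeric(1))
    expect_true(all(fds >= 0 & fds <= 3))
    expect_equal(max(fds) - min(fds), 0, tolerance = 1e-12,
                 info = sprintf("seed %d", seed))
    fd_rot <- vapply(rotations, function(rot) {
      mm <- voxel_mask(rot(m$grid))
      fractal_dimension(box_count_curve(mm, c(2, 4, 8)))$fd
    }, numeric(1))
    expect_true(all(abs(fd_rot - fds[1]) < 0.15),
                info = sprintf("seed %d", seed))
  }
})

test_that("lacunarity closed forms hold and padding does not change it", {
  cube <- make_primitive("cube", 32)
  curve <- box_count_curve(cube, c(2, 4, 8, 16))
  expect_equal(lacunarity(curve, "across-box-cv")$lacunarity, 0)
  expect_equal(lacunarity(curve, "within-box-cv")$lacunarity, 0)

  # only occupied r=2 boxes have masses 2 and 6
  g <- array(0L, c(4, 2, 2))
  g[1, 1, 1] <- 1L; g[2, 1, 1] <- 1L                    # mass 2
  g[3:4, 1:2, 1] <- 1L; g[3:4, 1, 2] <- 1L              # mass 6
  m26 <- voxel_mask(g)
  res <- occupied_box_count(m26, 2)
  expect_equal(sort(res$masses), c(2L, 6L))
  curve26 <- box_count_curve(m26, c(1, 2))
  expect_equal(lacunarity(curve26)$per_size[["2"]], 0.25, tolerance = 1e-12)

  # within-box closed form (1-p)/p for a single voxel in an r=2 box
  single <- voxel_mask(array(c(1L, rep(0L, 7)), c(2, 2, 2)))
  c1 <- box_count_curve(single, c(1, 2), skip_oversized = FALSE)
  wb <- lacunarity(c1, "within-box-cv")
  expect_equal(wb$per_size[["2"]], 7, tolerance = 1e-12)

  # degenerate: single voxel under the across-box default
  expect_error(lacunarity(c1, "across-box-cv"), "undefined")
  expect_error(box_count_curve(single, c(2, 4)), "usable box sizes")

  # zero padding cannot create occupied boxes
  gp <- array(0L, dim(g) + 6L)
  gp[3 + seq_len(4), 3 + seq_len(2), 3 + seq_len(2)] <- g
  curve_p <- box_count_curve(voxel_mask(gp), c(1, 2))
  expect_equal(lacunarity(curve_p)$lacunarity, lacunarity(curve26)$lacunarity)
})

test_that("sizes with fewer than two occupied boxes are excluded from lacunarity", {
  m <- make_primitive("cube", 8)
  curve <- box_count_curve(m, c(2, 8))   # r=8: a single full box
  res <- lacunarity(curve)
  expect_equal(res$excluded_sizes, 8)
  expect_equal(names(res$per_size), "2")
})

test_that("max diameter matches brute force and analytic cases", {
  single <- voxel_mask(array(1L, c(1, 1, 1)))
  expect_equal(max_diameter(single), 0)

  g <- array(0L, c(10, 10, 10))
  g[1, 1, 1] <- 1L; g[10, 10, 10] <- 1L
  two <- voxel_mask(g)
  expect_equal(max_diameter(two), sqrt(3) * 9 / 10, tolerance = 1e-12)

  ball <- make_primitive("ball", 15)
  expect_true(abs(max_diameter(ball) - 3.0) <= 0.1 * sqrt(3))  # one voxel

  for (seed in c(7, 11, 13)) {
    m <- random_test_mask(seed, max_side = 12L)
    expect_equal(max_diameter(m), brute_max_diameter_cm(m), tolerance = 1e-12)
  }

  # anisotropic spacing enters the distance
  g2 <- array(0L, c(5, 1, 5)); g2[1, 1, 1] <- 1L; g2[5, 1, 5] <- 1L
  m2 <- voxel_mask(g2, spacing = c(1, 1, 2))
  expect_equal(max_diameter(m2), sqrt(4^2 + 8^2) / 10, tolerance = 1e-12)
})

test_that("sphericity is near 1 for balls, analytic for cubes, lower for slabs", {
  expect_gte(sphericity(make_primitive("ball", 20)), 0.95)
  # corner rounding by the pre-smoothing biases the cube upward by ~0.05
  cube_s <- sphericity(make_primitive("cube", 30))
  expect_lt(abs(cube_s - (pi / 6)^(1 / 3)), 0.055)
  slab <- voxel_mask(array(1L, c(64, 64, 2)))
  expect_lt(sphericity(slab), cube_s)
  # spacing-aware: same ball at 2 mm spacing, same sphericity
  expect_equal(sphericity(make_primitive("ball", 12, spacing = 2)),
               sphericity(make_primitive("ball", 12)), tolerance = 1e-9)
})

test_that("feature extraction composes deterministically", {
  cube <- make_primitive("cube", 64)
  f <- extract_features(cube)
  expect_equal(f$fd, 3, tolerance = 1e-9)
  expect_equal(f$lacunarity, 0)
  expect_equal(f$volume_mm3, 64^3)
  expect_identical(extract_features(cube), f)   # bit-identical rerun

  aniso <- voxel_mask(array(1L, c(8, 8, 4)), spacing = c(1, 1, 2))
  expect_error(extract_features(aniso), "anisotropic")

  cfg <- feature_config(c(3, 9, 27))
  fm <- extract_features(make_menger_sponge(4), cfg)
  expect_equal(fm$fd, log(20) / log(3), tolerance = 1e-9)
})

test_that("offset averaging keeps counts within the fixed-lattice bounds", {
  m <- make_blob(10, irregularity = 0.4, seed = 3)
  c_fixed <- box_count_curve(m, c(2, 4, 8))
  c_avg <- box_count_curve(m, c(2, 4, 8), offset_averaging = TRUE)
  # averaged counts stay within a box of the achievable lattice range
  expect_true(all(c_avg$counts > 0))
  expect_true(all(abs(c_avg$counts - c_fixed$counts) / c_fixed$counts < 0.5))
})
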