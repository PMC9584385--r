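test_that("primitives have exact or analytic voxel counts", {
  expect_equal(sum(make_primitive("cube", 64)$grid), 64^3)
  expect_equal(sum(make_primitive("slab", 64)$grid), 4096)
  expect_equal(sum(make_primitive("line", 9)$grid), 9)
  v <- sum(make_primitive("ball", 10)$grid)
  expect_lt(abs(v - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.05)
  expect_error(make_primitive("cube", 0), "positive")
})

test_that("Menger sponge construction is exact", {
  expect_equal(sum(make_menger_sponge(1)$grid), 20)
  expect_equal(dim(make_menger_sponge(1)$grid), c(3L, 3L, 3L))
  expect_equal(sum(make_menger_sponge(3)$grid), 8000)
  expect_equal(occupied_box_count(make_menger_sponge(2), 3)$count, 20)
  expect_error(make_menger_sponge(6), "refusing")
})

test_that("blob generator is seed-deterministic and degenerates to a ball", {
  plain <- make_blob(10, irregularity = 0, gap_fraction = 0, seed = 4)
  ball <- make_primitive("ball", 10)
  # grids share content up to background margins
  expect_identical(voxfract:::crop_to_foreground(plain$grid),
                   voxfract:::crop_to_foreground(ball$grid))

  b1 <- make_blob(10, irregularity = 0.6, gap_fraction = 0.2, seed = 9)
  b2 <- make_blob(10, irregularity = 0.6, gap_fraction = 0.2, seed = 9)
  expect_identical(b1$grid, b2$grid)
  b3 <- make_blob(10, irregularity = 0.6, gap_fraction = 0.2, seed = 10)
  expect_false(identical(b1$grid, b3$grid))
  expect_error(make_blob(10, gap_fraction = 0.96), "0.95")
})

test_that("blob volume decreases monotonically with gap fraction", {
  v <- vapply(c(0, 0.2, 0.4, 0.6), function(q)
    sum(make_blob(12, gap_fraction = q, gap_size_vox = 2, seed = 3)$grid),
    numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("border irregularity raises the measured fractal dimension", {
  wins <- 0L
  for (s in 1:10) {
    f0 <- fractal_dimension(box_count_curve(
      make_blob(16, irregularity = 0, seed = s), c(2, 4, 8, 16)))$fd
    f8 <- fractal_dimension(box_count_curve(
      make_blob(16, irregularity = 0.8, seed = s), c(2, 4, 8, 16)))$fd
    wins <- wins + (f8 > f0)
  }
  expect_gte(wins, 9L)
})

test_that("cohort generation hits exact group sizes and is deterministic", {
  co <- generate_cohort(cohort_spec(seed = 11))
  expect_equal(nrow(co), 48)
  expect_equal(sum(co$mutant), 7)
  expect_equal(levels(co$group), c("wildtype", "mutant"))
  expect_identical(co, generate_cohort(cohort_spec(seed = 11)))
  expect_false(identical(co, generate_cohort(cohort_spec(seed = 12))))
  binaries <- c("female", "recurrent", "skull_base", "heterogeneous_enhancement",
                "capsular_enhancement", "necrosis", "cystic_change",
                "hyperostosis", "skull_invasion")
  for (b in binaries) expect_true(all(co[[b]] %in% 0:1))
  expect_true(all(is.finite(co$fd) & co$fd >= 1 & co$fd <= 3))
  expect_true(all(co$lacunarity > 0))

  # identical CSV bytes for the same seed
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(generate_cohort(cohort_spec(seed = 5)), p1, row.names = FALSE)
  write.csv(generate_cohort(cohort_spec(seed = 5)), p2, row.names = FALSE)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("large-sample cohort moments recover the published group parameters", {
  co <- generate_cohort(cohort_spec(n_total = 200000L, n_mutant = 100000L, seed = 2))
  mut <- co[co$mutant == 1, ]; wt <- co[co$mutant == 0, ]
  # 3-SE tolerance at n = 1e5, and within 0.01 for the headline values
  expect_lt(abs(mean(mut$lacunarity) - 6.01), 0.01)
  expect_lt(abs(mean(wt$fd) - 1.74), 0.01)
  expect_lt(abs(mean(mut$fd) - 1.88), 3 * 0.16 / sqrt(1e5) + 1e-3)
  expect_lt(abs(sd(wt$lacunarity) - 0.41), 0.01)
  expect_lt(abs(mean(wt$age) - 56.29), 3 * 14.95 / sqrt(1e5) + 0.05)
  expect_lt(abs(mean(mut$heterogeneous_enhancement) - 6 / 7),
            3 * sqrt(6 / 7 * 1 / 7 / 1e5))
})

test_that("fd-lacunarity correlation knob is honoured", {
  co <- generate_cohort(cohort_spec(n_total = 40000L, n_mutant = 20000L,
                                    fd_lac_correlation = 0.6, seed = 3))
  wt <- co[co$mutant == 0, ]
  expect_lt(abs(cor(wt$fd, wt$lacunarity) - 0.6), 0.03)
  co0 <- generate_cohort(cohort_spec(n_total = 40000L, n_mutant = 20000L, seed = 3))
  wt0 <- co0[co0$mutant == 0, ]
  expect_lt(abs(cor(wt0$fd, wt0$lacunarity)), 0.03)
})

test_that("infeasible cohort specs are rejected", {
  expect_error(cohort_spec(n_total = 0), "n_total")
  expect_error(cohort_spec(n_mutant = 48, n_total = 48), "n_mutant")
  expect_error(cohort_spec(fd_lac_correlation = 1), "correlation")
  bad <- cohort_spec()$continuous
  bad$fd$mutant <- c(1.8, -1)
  expect_error(cohort_spec(continuous = bad), "sd > 0")
})
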