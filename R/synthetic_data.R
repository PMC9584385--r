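#' Exact geometric primitives as voxel masks
#'
#' Analytic fixtures with known box-counting behaviour: a solid cube has
#' fractal dimension 3 and lacunarity 0, a one-voxel-thick slab has
#' dimension 2, a line has dimension 1, and a digital ball approaches
#' sphericity 1.
#'
#' @param kind one of \code{"cube"}, \code{"slab"}, \code{"line"},
#'   \code{"ball"}.
#' @param size edge length in voxels (cube, slab, line) or radius in voxels
#'   (ball).
#' @param spacing isotropic voxel edge length in mm.
#' @param subject_id label for the mask.
#' @return A \code{\link{voxel_mask}}: \code{cube} is size^3 solid;
#'   \code{slab} is size x size x 1; \code{line} is size x 1 x 1;
#'   \code{ball} is centre-distance thresholded (\code{<= r}) on a
#'   (2r+1)^3 grid.
#' @export
make_primitive <- function(kind = c("cube", "slab", "line", "ball"), size,
                           spacing = 1, subject_id = NULL) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (length(size) != 1L || is.na(size) || size < 1L)
    stop("`size` must be a positive integer", call. = FALSE)
  if (is.null(subject_id)) subject_id <- sprintf("%s%d", kind, size)
  g <- switch(kind,
    cube = array(1L, rep(size, 3)),
    slab = array(1L, c(size, size, 1L)),
    line = array(1L, c(size, 1L, 1L)),
    ball = {
      n <- 2L * size + 1L
      ax <- seq_len(n) - 1L - size
      d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
      array(as.integer(d2 <= size^2), rep(n, 3))
    })
  voxel_mask(g, spacing = rep(spacing, 3), subject_id = subject_id)
}

#' Menger sponge voxel phantom
#'
#' Recursive construction on a 3^level grid: each cube is split 3x3x3 and
#' the 20 sub-cubes that are not at a face-centre or body-centre position
#' (those with fewer than two middle coordinates) are kept. The foreground
#' voxel count is exactly 20^level and the box-counting dimension is
#' log(20)/log(3) = 2.7268...
#'
#' @param level recursion depth, 1..5 (side length 3^level).
#' @param spacing isotropic voxel edge length in mm.
#' @return A \code{\link{voxel_mask}}.
#' @export
make_menger_sponge <- function(level, spacing = 1) {
  level <- as.integer(level)
  if (length(level) != 1L || is.na(level) || level < 1L)
    stop("`level` must be a positive integer", call. = FALSE)
  if (level > 5L)
    stop("`level` > 5 would allocate a >14M voxel grid; refusing", call. = FALSE)
  mid <- function(i) as.integer(i == 2L)
  pat <- array(0L, c(3L, 3L, 3L))
  for (i in 1:3) for (j in 1:3) for (k in 1:3)
    pat[i, j, k] <- as.integer(mid(i) + mid(j) + mid(k) < 2L)
  g <- array(1L, c(1L, 1L, 1L))
  for (l in seq_len(level)) {
    n <- dim(g)[1]
    coarse <- rep(seq_len(n), each = 3L)
    fine <- rep(1:3, times = n)
    g <- g[coarse, coarse, coarse, drop = FALSE] *
      pat[fine, fine, fine, drop = FALSE]
  }
  voxel_mask(g, spacing = rep(spacing, 3),
             subject_id = sprintf("menger%d", level))
}

#' Tumour-like blob phantom with tunable irregularity and gappiness
#'
#' A digital ball whose border is carved by a fine-scale (1.5-voxel
#' bandwidth) random field, mimicking the irregular borders of highly
#' proliferative tumours, and whose interior is punctured by randomly
#' seeded spherical gaps, mimicking necrotic or cystic change. The carving
#' acts inward only, so the coarse-scale envelope of the ball is preserved
#' while the border gains fine-scale detail; this makes the box-counting
#' dimension increase with \code{irregularity}, and \code{gap_fraction}
#' raises lacunarity. The largest connected component is returned, so the
#' mask is always connected, and the generator is a pure function of its
#' arguments including \code{seed}.
#'
#' @param radius_mm nominal ball radius in mm.
#' @param irregularity boundary perturbation amplitude in [0, 1]; 0 gives a
#'   plain digital ball.
#' @param gap_fraction approximate fraction of the volume removed as gaps,
#'   in [0, 0.95).
#' @param gap_size_vox radius of each spherical gap in voxels.
#' @param seed integer seed; the global RNG state is left untouched.
#' @param spacing isotropic voxel edge length in mm.
#' @param subject_id label for the mask.
#' @return A \code{\link{voxel_mask}}.
#' @export
make_blob <- function(radius_mm, irregularity = 0, gap_fraction = 0,
                      gap_size_vox = 3, seed = 1, spacing = 1,
                      subject_id = NULL) {
  if (irregularity < 0 || irregularity > 1)
    stop("`irregularity` must lie in [0, 1]", call. = FALSE)
  if (gap_fraction < 0 || gap_fraction >= 0.95)
    stop("`gap_fraction` must lie in [0, 0.95)", call. = FALSE)
  if (is.null(subject_id))
    subject_id <- sprintf("blob_r%g_i%g_g%g_s%d", radius_mm, irregularity,
                          gap_fraction, seed)
  r_vox <- radius_mm / spacing
  half <- as.integer(ceiling(r_vox) + 2L)
  n <- 2L * half + 1L
  ax <- seq_len(n) - 1L - half
  g <- withr::with_seed(as.integer(seed), {
    dist <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
    if (irregularity > 0) {
      noise <- smooth_noise_field(n, sigma = 1.5)
      radius_field <- r_vox * (1 - 0.35 * irregularity * pmax(noise, 0))
    } else {
      radius_field <- r_vox
    }
    m <- array(as.integer(dist <= radius_field), rep(n, 3))
    m[half + 1L, half + 1L, half + 1L] <- 1L   # keep the centre
    if (gap_fraction > 0) {
      target <- gap_fraction * sum(m)
      removed <- 0
      guard <- 0L
      while (removed < target && guard < 10000L) {
        guard <- guard + 1L
        fg <- which(m == 1L)
        c0 <- arrayInd(fg[sample.int(length(fg), 1L)], dim(m))
        lo <- pmax(c0 - gap_size_vox, 1L)
        hi <- pmin(c0 + gap_size_vox, n)
        sub <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
        d2 <- outer(outer((lo[1]:hi[1] - c0[1])^2, (lo[2]:hi[2] - c0[2])^2, "+"),
                    (lo[3]:hi[3] - c0[3])^2, "+")
        hit <- sub == 1L & d2 <= gap_size_vox^2
        removed <- removed + sum(hit)
        sub[hit] <- 0L
        m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
      }
    }
    largest_component(m)
  })
  voxel_mask(g, spacing = rep(spacing, 3), subject_id = subject_id)
}

# zero-mean, unit-variance smooth Gaussian random field via FFT filtering
smooth_noise_field <- function(n, sigma) {
  w <- array(rnorm(n^3), rep(n, 3))
  ax <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  k1 <- exp(-0.5 * (ax * sigma * 2 * pi / n)^2)
  ker <- outer(outer(k1, k1), k1)
  f <- Re(fft(fft(w) * ker, inverse = TRUE)) / length(w)
  f <- f - mean(f)
  f / sd(f)
}

# largest 6-connected foreground component (vectorised frontier BFS)
largest_component <- function(g) {
  d <- dim(g)
  fg <- g == 1L
  if (!any(fg)) return(g)
  visited <- array(FALSE, d)
  nxy <- d[1] * d[2]
  best <- integer(0)
  remaining <- which(fg & !visited)
  while (length(remaining)) {
    comp <- integer(0)
    frontier <- remaining[1]
    visited[frontier] <- TRUE
    while (length(frontier)) {
      comp <- c(comp, frontier)
      ci <- arrayInd(frontier, d)
      cand <- c(
        frontier[ci[, 1] > 1L] - 1L,
        frontier[ci[, 1] < d[1]] + 1L,
        frontier[ci[, 2] > 1L] - d[1],
        frontier[ci[, 2] < d[2]] + d[1],
        frontier[ci[, 3] > 1L] - nxy,
        frontier[ci[, 3] < d[3]] + nxy)
      cand <- unique(cand[fg[cand] & !visited[cand]])
      visited[cand] <- TRUE
      frontier <- cand
    }
    if (length(comp) > length(best)) best <- comp
    remaining <- which(fg & !visited)
  }
  out <- array(0L, d)
  out[best] <- 1L
  out
}
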