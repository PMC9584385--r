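#' Sphericity of a mask
#'
#' Sphericity compares the mask's surface area with that of a sphere of
#' equal volume: \code{pi^(1/3) * (6 V)^(2/3) / S}, with \code{V} the
#' foreground volume in mm^3 and \code{S} the area in mm^2 of the 0.5
#' iso-surface. It equals 1 for a perfect ball and decreases as the surface
#' becomes less regular.
#'
#' @details
#' The iso-surface is triangulated by marching tetrahedra: each 2x2x2 voxel
#' cell is split into six tetrahedra around the main diagonal and the 0.5
#' level set is linearly interpolated along tetrahedron edges. Meshing the
#' raw 0/1 field would trace the voxel staircase and overestimate curved
#' surfaces by several percent (voxel-face counting is worse still, up to
#' 50 percent), so the binary field is first smoothed with a small Gaussian
#' (sigma of one voxel), a standard anti-aliasing step that recovers the
#' underlying smooth surface; a digital ball of radius 20 voxels then
#' measures within about 1 percent of its analytic area. Masks so small or
#' thin that smoothing leaves no 0.5 crossing fall back to the unsmoothed
#' binary mesh.
#'
#' @param mask a non-empty \code{\link{voxel_mask}}.
#' @return Sphericity in (0, 1] up to voxelisation tolerance.
#' @export
sphericity <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  stop_if_empty(mask, "sphericity")
  v <- mask_volume(mask)
  s <- surface_area(mask)
  pi^(1 / 3) * (6 * v)^(2 / 3) / s
}

#' Iso-surface area of a mask
#'
#' Area in mm^2 of the 0.5 iso-surface of the (smoothed) binary field, from
#' the marching-tetrahedra mesh described in \code{\link{sphericity}}.
#'
#' @param mask a non-empty \code{\link{voxel_mask}}.
#' @param smooth_sigma Gaussian pre-smoothing bandwidth in voxels; 0
#'   disables smoothing and meshes the raw binary field.
#' @return Surface area in mm^2.
#' @export
surface_area <- function(mask, smooth_sigma = 1) {
  stopifnot(inherits(mask, "voxel_mask"))
  stop_if_empty(mask, "surface_area")
  g <- crop_to_foreground(mask$grid)
  d <- dim(g)
  pad <- as.integer(max(2, ceiling(4 * smooth_sigma) + 1))
  gp <- array(0, d + 2L * pad)
  gp[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- g
  field <- gp
  if (smooth_sigma > 0) {
    field <- gaussian_smooth3d(gp, smooth_sigma)
    if (max(field) <= 0.5) field <- gp   # too small/thin to survive smoothing
  }
  mesh_area_mt(field, mask$spacing, level = 0.5)
}

# separable Gaussian smoothing by circular FFT convolution (the array is
# already zero-padded beyond the kernel reach, so wrap-around is harmless)
gaussian_smooth3d <- function(x, sigma) {
  d <- dim(x)
  h <- as.integer(ceiling(4 * sigma))
  k <- dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  kf <- lapply(d, function(n) {
    k1 <- numeric(n)
    k1[1:(h + 1)] <- k[(h + 1):(2 * h + 1)]
    k1[(n - h + 1):n] <- k[1:h]
    fft(k1)
  })
  ker <- outer(outer(kf[[1]], kf[[2]]), kf[[3]])
  Re(fft(fft(x) * ker, inverse = TRUE)) / length(x)
}

# Marching-tetrahedra area of the `level` iso-surface of a scalar field
# sampled on the voxel grid, with physical spacing per axis. Cells are
# 2x2x2 vertex blocks; each is split into 6 tetrahedra around the main
# diagonal; intersections are linearly interpolated along tet edges.
mesh_area_mt <- function(field, spacing, level = 0.5) {
  d <- dim(field)
  nc <- d - 1L
  vb <- vector("list", 8L)   # vertex b offsets are the bits of b
  for (b in 0:7) {
    dx <- bitwAnd(b, 1L); dy <- bitwAnd(bitwShiftR(b, 1L), 1L)
    dz <- bitwAnd(bitwShiftR(b, 2L), 1L)
    vb[[b + 1L]] <- as.vector(field[dx + seq_len(nc[1]), dy + seq_len(nc[2]),
                                    dz + seq_len(nc[3])])
  }
  inside <- lapply(vb, function(v) v >= level)
  n_in <- Reduce(`+`, inside)
  mixed <- which(n_in > 0L & n_in < 8L)
  if (!length(mixed)) return(0)
  geo <- tet_topology()
  total <- 0
  for (t in seq_len(6L)) {
    ids <- geo$tets[t, ] + 1L
    pts <- geo$vert[ids, , drop = FALSE] * rep(spacing, each = 4L)
    vals <- cbind(vb[[ids[1]]][mixed], vb[[ids[2]]][mixed],
                  vb[[ids[3]]][mixed], vb[[ids[4]]][mixed])
    case <- (vals[, 1] >= level) + 2L * (vals[, 2] >= level) +
      4L * (vals[, 3] >= level) + 8L * (vals[, 4] >= level)
    for (cs in 1:14) {
      sel <- which(case == cs)
      if (!length(sel)) next
      for (tri in geo$topo[[cs]]) {
        # tri: 3 rows of (inside-vertex, outside-vertex) tet-local edges
        va <- vals[sel, , drop = FALSE]
        corner <- lapply(1:3, function(q) {
          i <- tri[q, 1]; j <- tri[q, 2]
          u <- (level - va[, i]) / (va[, j] - va[, i])
          cbind(pts[i, 1] + u * (pts[j, 1] - pts[i, 1]),
                pts[i, 2] + u * (pts[j, 2] - pts[i, 2]),
                pts[i, 3] + u * (pts[j, 3] - pts[i, 3]))
        })
        e1 <- corner[[2]] - corner[[1]]
        e2 <- corner[[3]] - corner[[1]]
        cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
        cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
        cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
        total <- total + 0.5 * sum(sqrt(cx^2 + cy^2 + cz^2))
      }
    }
  }
  total
}

# six-tetrahedra cube decomposition and per-case triangle topology
# (cached after first call; geometry is independent of the data)
tet_topology <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    vert <- cbind(x = bitwAnd(0:7, 1L),
                  y = bitwAnd(bitwShiftR(0:7, 1L), 1L),
                  z = bitwAnd(bitwShiftR(0:7, 2L), 1L))
    perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                   c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    tets <- t(apply(perms, 1, function(p) {
      a <- integer(3); a[p[1]] <- 1L
      b <- a; b[p[2]] <- 1L
      c(0L, a[1] + 2L * a[2] + 4L * a[3], b[1] + 2L * b[2] + 4L * b[3], 7L)
    }))
    topo <- vector("list", 14L)
    for (cs in 1:14) {
      in_v <- which(as.logical(bitwAnd(cs, c(1L, 2L, 4L, 8L))))
      out_v <- setdiff(1:4, in_v)
      tris <- list()
      if (length(in_v) == 1L || length(in_v) == 3L) {
        p <- if (length(in_v) == 1L) in_v else out_v
        o <- setdiff(1:4, p)
        tris[[1]] <- rbind(c(p, o[1]), c(p, o[2]), c(p, o[3]))
      } else {
        s <- in_v; q <- out_v
        # quad m11-m12-m22-m21 split into two triangles
        tris[[1]] <- rbind(c(s[1], q[1]), c(s[1], q[2]), c(s[2], q[2]))
        tris[[2]] <- rbind(c(s[1], q[1]), c(s[2], q[2]), c(s[2], q[1]))
      }
      topo[[cs]] <- tris
    }
    cache <<- list(vert = vert, tets = tets, topo = topo)
    cache
  }
})
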