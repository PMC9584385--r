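#' Box occupancy at a single box size
#'
#' Crops the mask to the tight bounding box of its foreground, zero-pads
#' each axis to a multiple of \code{r}, partitions the result with a fixed
#' non-overlapping lattice of r-cubes anchored at the bounding-box corner,
#' and returns the number of occupied boxes together with the foreground
#' voxel count (mass) of each occupied box. Zero-padding never creates an
#' occupied box, so counts are invariant to background margins.
#'
#' @param mask a non-empty \code{\link{voxel_mask}}.
#' @param r box edge length in voxels (positive integer).
#' @param offset optional 0-based lattice offset per axis (each in
#'   \code{[0, r)}); used by offset averaging.
#' @return A list with \code{count} (number of boxes containing at least one
#'   foreground voxel) and \code{masses} (integer vector, one entry per
#'   occupied box, each in \code{[1, r^3]}).
#' @export
occupied_box_count <- function(mask, r, offset = c(0L, 0L, 0L)) {
  stopifnot(inherits(mask, "voxel_mask"))
  stop_if_empty(mask, "occupied_box_count")
  r <- as.integer(r)
  if (length(r) != 1L || is.na(r) || r < 1L)
    stop("`r` must be a positive integer box size", call. = FALSE)
  g <- crop_to_foreground(mask$grid)
  offset <- as.integer(offset) %% r
  if (any(offset > 0L)) {
    d0 <- dim(g)
    gp <- array(0L, d0 + offset)
    gp[offset[1] + seq_len(d0[1]), offset[2] + seq_len(d0[2]),
       offset[3] + seq_len(d0[3])] <- g
    g <- gp
  }
  masses <- block_masses(g, r)
  masses <- masses[masses > 0L]
  list(count = length(masses), masses = as.integer(masses))
}

# tight bounding box crop of the foreground
crop_to_foreground <- function(g) {
  idx <- which(g == 1L, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  g[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
}

# per-box foreground sums over a fixed r-lattice (pads to multiples of r)
block_masses <- function(g, r) {
  d <- dim(g)
  pd <- as.integer(ceiling(d / r) * r)
  if (any(pd != d)) {
    gp <- array(0L, pd)
    gp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- g
    g <- gp
  }
  nb <- pd %/% r
  dim(g) <- c(r, nb[1], r, nb[2], r, nb[3])
  g <- aperm(g, c(1L, 3L, 5L, 2L, 4L, 6L))
  dim(g) <- c(r^3, prod(nb))
  colSums(g)
}

#' Box-count curve across a ladder of box sizes
#'
#' Computes occupied-box counts and masses for each requested size. The
#' default ladder is dyadic, 2^1 ... 2^7 isotropic voxels. Sizes larger than
#' the longest axis of the foreground bounding box cannot tile the object
#' and are skipped with a reason code rather than failing.
#'
#' @param mask a non-empty, isotropic \code{\link{voxel_mask}}.
#' @param box_sizes integer vector of box edge lengths in voxels.
#' @param offset_averaging if \code{TRUE}, counts and masses at each size
#'   are pooled over \code{min(r, 4)} diagonal lattice offsets, a mild
#'   variance reduction for masks that are small relative to \code{r}.
#' @param skip_oversized if \code{TRUE} (default) sizes exceeding the
#'   longest bounding-box axis are skipped: they always yield a single
#'   occupied box, which carries no scaling information and flattens the
#'   log-log fit. Set to \code{FALSE} to keep such degenerate scales, e.g.
#'   to evaluate within-box occupancy statistics of very small masks.
#' @return A \code{box_count_curve}: list with \code{box_sizes} (usable
#'   sizes), \code{counts} (N(r), averaged over offsets when pooling),
#'   \code{masses} (list of per-box masses per size), \code{skipped} (data
#'   frame of skipped sizes and reasons), \code{n_foreground}.
#' @export
box_count_curve <- function(mask, box_sizes = c(2L, 4L, 8L, 16L, 32L, 64L, 128L),
                            offset_averaging = FALSE, skip_oversized = TRUE) {
  stopifnot(inherits(mask, "voxel_mask"))
  stop_if_empty(mask, "box_count_curve")
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (any(box_sizes < 1L)) stop("box sizes must be positive integers", call. = FALSE)
  bbox <- dim(crop_to_foreground(mask$grid))
  drop_size <- if (skip_oversized) box_sizes > max(bbox) else rep(FALSE, length(box_sizes))
  usable <- box_sizes[!drop_size]
  skipped <- data.frame(
    box_size = box_sizes[drop_size],
    reason = if (any(drop_size)) "exceeds-bounding-box" else character(0),
    stringsAsFactors = FALSE)
  if (length(usable) < 2L)
    stop(sprintf("fewer than 2 usable box sizes for a %s bounding box",
                 paste(bbox, collapse = "x")), call. = FALSE)
  counts <- numeric(length(usable))
  masses <- vector("list", length(usable))
  for (i in seq_along(usable)) {
    r <- usable[i]
    if (offset_averaging) {
      offs <- unique(as.integer(round(seq(0, r - 1, length.out = min(r, 4L)))))
      res <- lapply(offs, function(o) occupied_box_count(mask, r, offset = rep(o, 3)))
      counts[i] <- mean(vapply(res, `[[`, numeric(1), "count"))
      masses[[i]] <- unlist(lapply(res, `[[`, "masses"))
    } else {
      res <- occupied_box_count(mask, r)
      counts[i] <- res$count
      masses[[i]] <- res$masses
    }
  }
  structure(list(box_sizes = usable, counts = counts,
                 masses = setNames(masses, usable), skipped = skipped,
                 n_foreground = n_foreground(mask)),
            class = "box_count_curve")
}

#' @export
print.box_count_curve <- function(x, ...) {
  cat("<box_count_curve>\n")
  print(data.frame(box_size = x$box_sizes, n_boxes = x$counts))
  if (nrow(x$skipped))
    cat("skipped:", paste(x$skipped$box_size, collapse = ", "),
        sprintf("(%s)\n", x$skipped$reason[1]))
  invisible(x)
}

#' Box-counting fractal dimension from a count curve
#'
#' The default estimator is the ordinary-least-squares slope of
#' \code{log N(r)} against \code{log(1/r)} across all usable sizes. The
#' alternative \code{"mean-local-slope"} estimator averages the slopes
#' \code{log(N_j/N_{j+1}) / log(r_{j+1}/r_j)} of consecutive size pairs; the
#' two agree exactly whenever N(r) follows an exact power law.
#'
#' @param curve a \code{\link{box_count_curve}} with at least 2 sizes.
#' @param method \code{"ols"} (default) or \code{"mean-local-slope"}.
#' @return A list with \code{fd} and \code{fit} (OLS slope, intercept and
#'   R-squared of the log-log regression).
#' @export
fractal_dimension <- function(curve, method = c("ols", "mean-local-slope")) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "box_count_curve"))
  r <- curve$box_sizes
  n <- curve$counts
  if (length(r) < 2L) stop("need at least 2 box sizes", call. = FALSE)
  if (any(n <= 0)) stop("internal error: zero box count for a non-empty mask", call. = FALSE)
  x <- log(1 / r)
  y <- log(n)
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot <= 0) 1 else max(0, 1 - sum(fit$residuals^2) / ss_tot)
  fd <- if (method == "ols") {
    slope
  } else {
    mean(diff(y) / diff(x))
  }
  list(fd = fd,
       fit = list(slope = slope, intercept = unname(coef(fit)[1]), r_squared = r2),
       method = method)
}

#' Gliding-box lacunarity from a count curve
#'
#' Two literal readings of "the squared coefficients of variation of the
#' occupied boxes, averaged" are provided.
#'
#' \describe{
#'   \item{\code{"across-box-cv"} (default)}{At each size r with at least 2
#'     occupied boxes, \code{CV^2(r)} is the squared (population SD / mean)
#'     of the occupied-box masses; the summary lacunarity is the mean of
#'     \code{CV^2(r)} over contributing sizes. This is the standard
#'     gliding-box quantity \code{Lambda(r) - 1} restricted to occupied
#'     boxes. Sizes with a single occupied box are excluded and reported.}
#'   \item{\code{"within-box-cv"}}{Each occupied box with fill fraction
#'     \code{p = m / r^3} contributes \code{CV^2 = (1 - p) / p} (the closed
#'     form for 0/1 voxel values under population variance); the per-size
#'     value is the mean over occupied boxes and the summary is the mean
#'     over sizes.}
#' }
#'
#' A solid object yields 0 under both methods.
#'
#' @param curve a \code{\link{box_count_curve}}.
#' @param method \code{"across-box-cv"} or \code{"within-box-cv"}.
#' @return A list with \code{lacunarity}, \code{per_size} (named numeric,
#'   one value per contributing size) and \code{excluded_sizes}.
#' @export
lacunarity <- function(curve, method = c("across-box-cv", "within-box-cv")) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "box_count_curve"))
  per_size <- numeric(0)
  excluded <- integer(0)
  for (i in seq_along(curve$box_sizes)) {
    r <- curve$box_sizes[i]
    m <- as.numeric(curve$masses[[i]])
    if (method == "across-box-cv") {
      if (length(m) < 2L) { excluded <- c(excluded, r); next }
      mu <- mean(m)
      sig <- sqrt(mean((m - mu)^2))   # population SD
      per_size[as.character(r)] <- (sig / mu)^2
    } else {
      p <- m / r^3
      per_size[as.character(r)] <- mean((1 - p) / p)
    }
  }
  if (!length(per_size))
    stop("lacunarity undefined: no box size has enough occupied boxes ",
         "(mask too small for the requested sizes)", call. = FALSE)
  list(lacunarity = mean(per_size), per_size = per_size,
       excluded_sizes = excluded, method = method)
}

#' Maximum diameter of a mask
#'
#' Maximum Euclidean distance in physical units between any two foreground
#' voxel centres, reported in cm. The diameter-attaining pair consists of
#' convex-hull vertices, and every hull vertex is the first or last
#' foreground voxel of its grid column (a column-interior voxel is a convex
#' combination of two mask points), so the search space is reduced to the
#' per-column extremes along each axis before the pairwise scan.
#'
#' @param mask a non-empty \code{\link{voxel_mask}}.
#' @return Maximum diameter in cm (0 for a single voxel).
#' @export
max_diameter <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  stop_if_empty(mask, "max_diameter")
  pts <- extreme_voxel_coords(mask)    # mm, voxel centres
  if (nrow(pts) == 1L) return(0)
  # lower-bound the diameter by double farthest-point search, then prune:
  # an endpoint x of a pair with |xy| >= d0 must satisfy |xc| >= d0 - R,
  # since |xy| <= |xc| + |yc| <= |xc| + R; the optimal pair survives
  ctr <- colMeans(pts)
  dc <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  r_max <- max(dc)
  p <- pts[which.max(dc), ]
  dp <- sqrt(rowSums(sweep(pts, 2, p)^2))
  d0 <- max(dp)
  pts <- pts[dc >= d0 - r_max - 1e-9, , drop = FALSE]
  n <- nrow(pts)
  best <- d0^2
  chunk <- 512L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    block <- pts[s:e, , drop = FALSE]
    d2 <- outer(block[, 1], pts[, 1], "-")^2 +
          outer(block[, 2], pts[, 2], "-")^2 +
          outer(block[, 3], pts[, 3], "-")^2
    best <- max(best, max(d2))
  }
  sqrt(best) / 10   # mm -> cm
}

# candidate diameter endpoints: per-column first/last foreground voxel
# along each of the three axes (a superset of the convex hull vertices)
extreme_voxel_coords <- function(mask) {
  idx <- which(mask$grid == 1L, arr.ind = TRUE)
  keep <- logical(nrow(idx))
  for (ax in 1:3) {
    other <- setdiff(1:3, ax)
    col_id <- paste(idx[, other[1]], idx[, other[2]], sep = ",")
    ord <- order(col_id, idx[, ax])
    first <- !duplicated(col_id[ord])
    last <- !duplicated(col_id[ord], fromLast = TRUE)
    keep[ord[first | last]] <- TRUE
  }
  sweep(idx[keep, , drop = FALSE] - 1L, 2, mask$spacing, "*")   # 0-based -> mm
}

#' Volume of a mask in cubic millimetres
#'
#' @param mask a \code{\link{voxel_mask}}.
#' @return foreground voxel count times voxel volume, in mm^3.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  n_foreground(mask) * prod(mask$spacing)
}

#' Extract all fractal and shape features from a mask
#'
#' Composes \code{\link{box_count_curve}}, \code{\link{fractal_dimension}},
#' \code{\link{lacunarity}}, \code{\link{sphericity}},
#' \code{\link{max_diameter}} and \code{\link{mask_volume}} into one
#' per-subject feature set. Deterministic for a fixed mask and
#' configuration. Anisotropic masks must be resampled first (see
#' \code{\link{resample_isotropic}}).
#'
#' @param mask a non-empty isotropic \code{\link{voxel_mask}}.
#' @param config a \code{\link{feature_config}}.
#' @return An object of class \code{fractal_features}: list with \code{fd},
#'   \code{fd_fit}, \code{lacunarity}, \code{per_size_lacunarity},
#'   \code{sphericity}, \code{max_diameter_cm}, \code{volume_mm3},
#'   \code{n_voxels}, \code{box_sizes_used}, \code{skipped_sizes},
#'   \code{subject_id}.
#' @export
extract_features <- function(mask, config = feature_config()) {
  stopifnot(inherits(mask, "voxel_mask"))
  stop_if_empty(mask, "extract_features")
  if (!is_isotropic(mask))
    stop(sprintf("mask '%s' is anisotropic; call resample_isotropic() first",
                 mask$subject_id), call. = FALSE)
  curve <- box_count_curve(mask, box_sizes = config$box_sizes,
                           offset_averaging = config$offset_averaging)
  fdres <- fractal_dimension(curve, method = config$fd_method)
  lac <- lacunarity(curve, method = config$lacunarity_method)
  structure(
    list(subject_id = mask$subject_id,
         fd = fdres$fd, fd_fit = fdres$fit,
         lacunarity = lac$lacunarity, per_size_lacunarity = lac$per_size,
         sphericity = sphericity(mask),
         max_diameter_cm = max_diameter(mask),
         volume_mm3 = mask_volume(mask),
         n_voxels = n_foreground(mask),
         box_sizes_used = curve$box_sizes,
         skipped_sizes = curve$skipped),
    class = "fractal_features")
}

#' @export
print.fractal_features <- function(x, ...) {
  cat(sprintf("<fractal_features> %s\n", x$subject_id))
  cat(sprintf("  fd %.4f (R2 %.4f)  lacunarity %.4f  sphericity %.4f\n",
              x$fd, x$fd_fit$r_squared, x$lacunarity, x$sphericity))
  cat(sprintf("  max diameter %.2f cm  volume %.0f mm3  (%d voxels)\n",
              x$max_diameter_cm, x$volume_mm3, x$n_voxels))
  invisible(x)
}

#' Feature extraction configuration
#'
#' @param box_sizes box-size ladder in voxels; default dyadic 2..128.
#' @param fd_method \code{"ols"} or \code{"mean-local-slope"}; see
#'   \code{\link{fractal_dimension}}.
#' @param lacunarity_method \code{"across-box-cv"} or
#'   \code{"within-box-cv"}; see \code{\link{lacunarity}}.
#' @param offset_averaging pool counts over diagonal lattice offsets.
#' @return A list of class \code{feature_config}.
#' @export
feature_config <- function(box_sizes = c(2L, 4L, 8L, 16L, 32L, 64L, 128L),
                           fd_method = "ols",
                           lacunarity_method = "across-box-cv",
                           offset_averaging = FALSE) {
  fd_method <- match.arg(fd_method, c("ols", "mean-local-slope"))
  lacunarity_method <- match.arg(lacunarity_method,
                                 c("across-box-cv", "within-box-cv"))
  structure(list(box_sizes = as.integer(box_sizes), fd_method = fd_method,
                 lacunarity_method = lacunarity_method,
                 offset_averaging = isTRUE(offset_averaging)),
            class = "feature_config")
}
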