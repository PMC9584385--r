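# Independent oracles, deliberately naive: plain triple loops and pairwise
# enumerations that share no code with the package implementations.

# fixed-lattice box counting by explicit box loops on the cropped grid
brute_box_count <- function(grid, r) {
  idx <- which(grid == 1L, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  g <- grid[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d <- dim(g)
  masses <- integer(0)
  for (bi in seq_len(ceiling(d[1] / r))) {
    for (bj in seq_len(ceiling(d[2] / r))) {
      for (bk in seq_len(ceiling(d[3] / r))) {
        xs <- ((bi - 1) * r + 1):min(bi * r, d[1])
        ys <- ((bj - 1) * r + 1):min(bj * r, d[2])
        zs <- ((bk - 1) * r + 1):min(bk * r, d[3])
        m <- sum(g[xs, ys, zs])
        if (m > 0) masses <- c(masses, m)
      }
    }
  }
  list(count = length(masses), masses = sort(masses))
}

# maximum pairwise centre distance over every foreground voxel pair
brute_max_diameter_cm <- function(mask) {
  idx <- (which(mask$grid == 1L, arr.ind = TRUE) - 1)
  pts <- sweep(idx, 2, mask$spacing, "*")
  best <- 0
  n <- nrow(pts)
  for (i in seq_len(n)) {
    d2 <- (pts[i, 1] - pts[, 1])^2 + (pts[i, 2] - pts[, 2])^2 +
      (pts[i, 3] - pts[, 3])^2
    best <- max(best, max(d2))
  }
  sqrt(best) / 10
}

# AUC as the mean pairwise comparison over all (positive, negative) pairs
brute_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) tot <- tot + sum(a > s0) + 0.5 * sum(a == s0)
  tot / (length(s1) * length(s0))
}

# seeded random blob-ish mask: thresholded smooth noise, never empty
random_test_mask <- function(seed, max_side = 32L) {
  withr::with_seed(seed, {
    d <- sample(8:max_side, 3, replace = TRUE)
    g <- array(as.integer(runif(prod(d)) > runif(1, 0.4, 0.9)), d)
    if (!any(g == 1L)) g[sample(length(g), 3)] <- 1L
    voxel_mask(g, subject_id = sprintf("rand%d", seed))
  })
}

# cohort spec in which every variable has identical distributions in the
# two groups: the global null for the univariable screen
null_cohort_spec <- function(seed, n_total = 48L, n_mutant = 7L) {
  base <- cohort_spec()
  cont <- lapply(base$continuous, function(v) list(wildtype = v$wildtype,
                                                   mutant = v$wildtype))
  bin <- lapply(base$binary, function(p) c(wildtype = unname(p["wildtype"]),
                                           mutant = unname(p["wildtype"])))
  cohort_spec(n_total = n_total, n_mutant = n_mutant, continuous = cont,
              binary = bin, seed = seed)
}
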