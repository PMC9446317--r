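# Independent reference implementations used to cross-check the package.
# Deliberately naive: correctness over speed, and no shared code with R/.

# component count by breadth-first flood fill over explicit voxel
# coordinates (O(n^2) adjacency tests)
flood_fill_count <- function(arr, connectivity = 26) {
  idx <- which(arr == 1, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(0L)
  visited <- rep(FALSE, n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (visited[s]) next
    comps <- comps + 1L
    queue <- s
    visited[s] <- TRUE
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      d <- abs(sweep(idx, 2, idx[cur, ], `-`))
      cheb <- pmax(d[, 1], pmax(d[, 2], d[, 3]))
      manh <- d[, 1] + d[, 2] + d[, 3]
      adj <- switch(as.character(connectivity),
                    "6"  = manh == 1,
                    "18" = cheb == 1 & manh <= 2,
                    "26" = cheb == 1)
      nxt <- which(adj & !visited)
      visited[nxt] <- TRUE
      queue <- c(queue, nxt)
    }
  }
  comps
}

random_small_mask <- function(dim3 = c(10, 10, 10), p = 0.2) {
  array(as.integer(runif(prod(dim3)) < p), dim3)
}

dice_overlap <- function(a, b) {
  2 * sum(a == 1 & b == 1) / (sum(a == 1) + sum(b == 1))
}

# exact permutation p-value of the chi-squared statistic for a 2x2 table
# with both margins fixed (hypergeometric enumeration)
chisq_stat_2x2 <- function(a, r1, r2, c1) {
  tab <- matrix(c(a, c1 - a, r1 - a, r2 - (c1 - a)), 2, 2)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

exact_chisq_p_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  obs <- chisq_stat_2x2(tab[1, 1], r1, r2, c1)
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(ks, r1, r2, c1)
  stats <- vapply(ks, chisq_stat_2x2, numeric(1), r1 = r1, r2 = r2, c1 = c1)
  min(1, sum(probs[stats >= obs - 1e-9]))
}

# rasterize an arbitrarily rotated ellipsoid (voxel centres inside)
rasterize_ellipsoid_oracle <- function(dim3, radii_mm, angles_deg,
                                       spacing = 1) {
  ctr <- dim3 * spacing / 2
  a <- angles_deg * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]),
                 0, -sin(a[1]), cos(a[1])), 3, 3)
  Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0,
                 sin(a[2]), 0, cos(a[2])), 3, 3)
  Rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0,
                 0, 0, 1), 3, 3)
  R <- Rz %*% Ry %*% Rx
  idx <- as.matrix(expand.grid(seq_len(dim3[1]), seq_len(dim3[2]),
                               seq_len(dim3[3])))
  world <- sweep((idx - 0.5) * spacing, 2, ctr, `-`)
  body <- world %*% R
  inside <- rowSums(sweep(body, 2, radii_mm, `/`)^2) <= 1
  lesion_mask(array(inside, dim3), rep(spacing, 3))
}

# brute-force axis-projection volume (validates extents bookkeeping)
box_volume_for_axes <- function(pts, axes) {
  proj <- pts %*% t(axes)
  prod(apply(proj, 2, function(v) diff(range(v))))
}
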