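# Independent oracles used by the tests. These deliberately re-derive
# quantities with naive loops so they share no code with the package
# implementation.

# Longhand two-way ANOVA variance-components ICC (loops over cells).
icc_oracle <- function(m, variant = c("agreement", "consistency")) {
  variant <- match.arg(variant)
  n <- nrow(m); k <- ncol(m)
  gm <- sum(m) / (n * k)
  rowm <- numeric(n); colm <- numeric(k)
  for (i in seq_len(n)) rowm[i] <- sum(m[i, ]) / k
  for (j in seq_len(k)) colm[j] <- sum(m[, j]) / n
  ssr <- 0; ssc <- 0; sse <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (rowm[i] - gm)^2
  for (j in seq_len(k)) ssc <- ssc + n * (colm[j] - gm)^2
  for (i in seq_len(n)) for (j in seq_len(k))
    sse <- sse + (m[i, j] - rowm[i] - colm[j] + gm)^2
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (variant == "consistency")
    (msr - mse) / (msr + (k - 1) * mse)
  else
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Even-odd ray-casting point-in-polygon test.
point_in_polygon_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly$x[i]; yi <- poly$y[i]
    xj <- poly$x[j]; yj <- poly$y[j]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# Enumerated disk-kernel pixel count for a given radius in pixels.
disk_pixel_count_oracle <- function(r) {
  cnt <- 0L
  for (dx in -r:r) for (dy in -r:r)
    if (dx * dx + dy * dy <= r * r) cnt <- cnt + 1L
  cnt
}

# Naive per-pixel recomputation of the nucleus feature vector.
naive_features <- function(rgb_image, stain_maps, segmentation, k,
                           microns_per_pixel = 0.5, k_neighbours = 5L,
                           density_radius_um = 25) {
  lab <- segmentation$labeled_mask
  h <- stain_maps$hematoxylin
  pix <- which(lab == k, arr.ind = TRUE)
  r <- pix[, 1]; cc <- pix[, 2]
  mpp <- microns_per_pixel
  out <- c()
  for (ch in 1:3) {
    v <- numeric(nrow(pix))
    for (i in seq_len(nrow(pix))) v[i] <- rgb_image[r[i], cc[i], ch] / 255
    out <- c(out, mean(v), sd(v))
  }
  hv <- numeric(nrow(pix))
  for (i in seq_len(nrow(pix))) hv[i] <- h[r[i], cc[i]]
  out <- c(out, mean(hv), sd(hv))
  names(out) <- c("mean_r", "sd_r", "mean_g", "sd_g", "mean_b", "sd_b",
                  "mean_h", "sd_h")
  # morphology
  area_um2 <- nrow(pix) * mpp^2
  mr <- mean(r); mc <- mean(cc)
  s11 <- mean((r - mr)^2); s22 <- mean((cc - mc)^2)
  s12 <- mean((r - mr) * (cc - mc))
  tr <- s11 + s22; dt <- s11 * s22 - s12^2
  l1 <- tr / 2 + sqrt(max(0, tr^2 / 4 - dt))
  l2 <- tr / 2 - sqrt(max(0, tr^2 / 4 - dt))
  ecc <- if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
  # perimeter: exposed 4-neighbour edges, counted pixel by pixel
  inset <- matrix(FALSE, max(r) + 2L, max(cc) + 2L)
  inset[cbind(r + 1L, cc + 1L)] <- TRUE
  per <- 0L
  for (i in seq_len(nrow(pix))) {
    ri <- r[i] + 1L; ci <- cc[i] + 1L
    per <- per + sum(!inset[ri - 1L, ci], !inset[ri + 1L, ci],
                     !inset[ri, ci - 1L], !inset[ri, ci + 1L])
  }
  # solidity: lattice points inside the convex hull (inclusive), loops
  pts <- unique(cbind(cc, r))
  sol <- 1
  if (nrow(pts) >= 3L) {
    hull <- pts[rev(chull(pts)), , drop = FALSE]
    if (nrow(hull) >= 3L) {
      nhull <- 0L
      for (x in min(cc):max(cc)) for (y in min(r):max(r)) {
        ok <- TRUE
        for (i in seq_len(nrow(hull))) {
          j <- if (i == nrow(hull)) 1L else i + 1L
          cr <- (hull[j, 1] - hull[i, 1]) * (y - hull[i, 2]) -
            (hull[j, 2] - hull[i, 2]) * (x - hull[i, 1])
          if (cr < -1e-9) { ok <- FALSE; break }
        }
        if (ok) nhull <- nhull + 1L
      }
      sol <- nrow(pix) / max(nrow(pix), nhull)
    }
  }
  out <- c(out, area_um2 = area_um2, eccentricity = ecc, solidity = sol,
           perimeter_area_ratio = per * mpp / area_um2)
  # texture: symmetric GLCM over right and down neighbours within mask
  qlev <- function(x) min(floor(x * 8), 7) + 1L
  di <- c(); dj <- c()
  for (i in seq_len(nrow(pix))) {
    ri <- r[i]; ci <- cc[i]
    if (any(r == ri & cc == ci + 1L)) {
      di <- c(di, qlev(h[ri, ci])); dj <- c(dj, qlev(h[ri, ci + 1L]))
    }
    if (any(r == ri + 1L & cc == ci)) {
      di <- c(di, qlev(h[ri, ci])); dj <- c(dj, qlev(h[ri + 1L, ci]))
    }
  }
  if (length(di) == 0L) {
    out <- c(out, glcm_contrast = 0, glcm_homogeneity = 1)
  } else {
    dd <- c(di - dj, dj - di)
    out <- c(out, glcm_contrast = mean(dd^2),
             glcm_homogeneity = mean(1 / (1 + dd^2)))
  }
  lv <- numeric(nrow(pix))
  for (i in seq_len(nrow(pix))) {
    ri <- r[i]; ci <- cc[i]
    acc <- 0; cnt <- 0
    for (a in -1:1) for (b in -1:1) {
      rr <- ri + a; cj <- ci + b
      if (rr >= 1 && rr <= nrow(h) && cj >= 1 && cj <= ncol(h)) {
        acc <- acc + h[rr, cj]; cnt <- cnt + 1
      }
    }
    lv[i] <- (h[ri, ci] - acc / cnt)^2
  }
  out <- c(out, local_variance = mean(lv))
  # spatial
  cent <- segmentation$centroids
  n <- nrow(cent)
  if (n == 1L) {
    diag_um <- sqrt(nrow(lab)^2 + ncol(lab)^2) * mpp
    out <- c(out, nn_dist_um = diag_um, knn_dist_um = diag_um,
             density_per_100um2 = 100 / (pi * density_radius_um^2))
  } else {
    dvec <- numeric(0)
    for (j in seq_len(n)) if (j != k)
      dvec <- c(dvec, sqrt((cent$x[j] - cent$x[k])^2 +
                             (cent$y[j] - cent$y[k])^2) * mpp)
    kk <- min(k_neighbours, n - 1L)
    out <- c(out, nn_dist_um = min(dvec),
             knn_dist_um = mean(sort(dvec)[seq_len(kk)]),
             density_per_100um2 =
               (1 + sum(dvec <= density_radius_um)) /
               (pi * density_radius_um^2) * 100)
  }
  out
}
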