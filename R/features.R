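# Per-nucleus feature extraction: appearance (RGB and hematoxylin
# statistics), morphology (area, eccentricity, solidity, perimeter-to-area
# ratio), texture (grey-level co-occurrence contrast/homogeneity, local
# intensity variance), and spatial context (neighbour distances, local
# density). Every feature has a simple per-pixel definition so it can be
# recomputed by a naive independent implementation.

feature_group_names <- function() {
  list(appearance = c("mean_r", "sd_r", "mean_g", "sd_g", "mean_b", "sd_b",
                      "mean_h", "sd_h"),
       morphology = c("area_um2", "eccentricity", "solidity",
                      "perimeter_area_ratio"),
       texture = c("glcm_contrast", "glcm_homogeneity", "local_variance"),
       spatial = c("nn_dist_um", "knn_dist_um", "density_per_100um2"))
}

# Eccentricity from second central moments of pixel coordinates:
# sqrt(1 - lambda_min/lambda_max) of the covariance eigenvalues; 0 for a
# disk, -> 1 for elongated shapes.
pixel_eccentricity <- function(rows, cols) {
  if (length(rows) < 2L) return(0)
  cv <- cov(cbind(rows, cols)) * (length(rows) - 1) / length(rows)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(0)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

# Solidity = pixel count / number of lattice points inside (or on) the
# convex hull of the pixel centres. Convexity of the hull gives an exact
# inclusive test via half-plane checks.
pixel_solidity <- function(rows, cols) {
  n <- length(rows)
  if (n < 4L) return(1)
  pts <- unique(cbind(cols, rows))
  if (nrow(pts) < 3L) return(1)
  hull <- pts[rev(chull(pts)), , drop = FALSE]   # counter-clockwise
  if (nrow(hull) < 3L) return(1)
  gx <- min(cols):max(cols); gy <- min(rows):max(rows)
  px <- rep(gx, times = length(gy)); py <- rep(gy, each = length(gx))
  inside <- rep(TRUE, length(px))
  nh <- nrow(hull)
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    ex <- hull[j, 1] - hull[i, 1]; ey <- hull[j, 2] - hull[i, 2]
    inside <- inside &
      (ex * (py - hull[i, 2]) - ey * (px - hull[i, 1])) >= -1e-9
  }
  n / max(n, sum(inside))
}

# Perimeter as exposed pixel-edge count (4-connectivity), in pixels.
pixel_perimeter <- function(mask) {
  m <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  core <- m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
  up <- m[1:nrow(mask), 2:(ncol(mask) + 1L)]
  dn <- m[3:(nrow(mask) + 2L), 2:(ncol(mask) + 1L)]
  lf <- m[2:(nrow(mask) + 1L), 1:ncol(mask)]
  rt <- m[2:(nrow(mask) + 1L), 3:(ncol(mask) + 2L)]
  sum(core & !up) + sum(core & !dn) + sum(core & !lf) + sum(core & !rt)
}

# Symmetric normalised grey-level co-occurrence matrix over horizontal and
# vertical unit offsets, restricted to pixel pairs inside the nucleus.
glcm_stats <- function(qmat, inmask) {
  pairs_i <- integer(0); pairs_j <- integer(0)
  nr <- nrow(qmat); nc <- ncol(qmat)
  if (nc > 1L) {
    ok <- inmask[, -nc] & inmask[, -1L]
    pairs_i <- c(pairs_i, qmat[, -nc][ok]); pairs_j <- c(pairs_j, qmat[, -1L][ok])
  }
  if (nr > 1L) {
    ok <- inmask[-nr, ] & inmask[-1L, ]
    pairs_i <- c(pairs_i, qmat[-nr, ][ok]); pairs_j <- c(pairs_j, qmat[-1L, ][ok])
  }
  if (length(pairs_i) == 0L)
    return(c(glcm_contrast = 0, glcm_homogeneity = 1))
  d <- c(pairs_i - pairs_j, pairs_j - pairs_i)   # symmetrised
  c(glcm_contrast = mean(d^2), glcm_homogeneity = mean(1 / (1 + d^2)))
}

#' Extract appearance, morphology, texture and spatial features per nucleus
#'
#' @param rgb_image The patch, height x width x 3, values 0--255.
#' @param stain_maps Matching \code{\link{separate_stains}} result.
#' @param segmentation Matching \code{\link{segment_nuclei}} result.
#' @param microns_per_pixel Physical pixel size (default taken from the
#'   segmentation parameters).
#' @param k_neighbours Number of nearest neighbours averaged for the
#'   k-nearest-neighbour distance (default 5; truncated when fewer nuclei
#'   are available).
#' @param density_radius_um Radius of the local-density disk (default 25).
#' @param groups Character vector of feature groups to include; any subset
#'   of \code{c("appearance","morphology","texture","spatial")}.
#' @return Data frame, one row per nucleus in label order: \code{nucleus_id}
#'   followed by the feature columns. For a single-nucleus patch the
#'   neighbour distances are set to the patch diagonal (in micrometres) as
#'   a documented sentinel. RGB statistics are on the 0--1 scale;
#'   hematoxylin statistics use the stretched map.
#' @export
extract_features <- function(rgb_image, stain_maps, segmentation,
                             microns_per_pixel =
                               segmentation$params$microns_per_pixel,
                             k_neighbours = 5L, density_radius_um = 25,
                             groups = c("appearance", "morphology",
                                        "texture", "spatial")) {
  check_rgb_image(rgb_image)
  stopifnot(inherits(segmentation, "nucleus_segmentation"))
  groups <- match.arg(groups, several.ok = TRUE)
  n <- segmentation$n
  cols_wanted <- unlist(feature_group_names()[groups], use.names = FALSE)
  if (n == 0L) {
    out <- as.data.frame(c(list(nucleus_id = integer()),
                           setNames(rep(list(numeric()), length(cols_wanted)),
                                    cols_wanted)))
    return(out)
  }
  lab <- segmentation$labeled_mask
  h <- stain_maps$hematoxylin
  mpp <- microns_per_pixel
  q <- pmin(floor(h * 8), 7) + 1L              # 8 grey levels on [0,1]
  # 3x3 local mean of the hematoxylin map (zero-padded borders averaged
  # over the in-image neighbourhood)
  onepad <- function(x) {
    p <- matrix(0, nrow(x) + 2L, ncol(x) + 2L)
    p[2:(nrow(x) + 1L), 2:(ncol(x) + 1L)] <- x
    p
  }
  hp <- onepad(h); cp <- onepad(matrix(1, nrow(h), ncol(h)))
  acc <- matrix(0, nrow(h), ncol(h)); cnt <- matrix(0, nrow(h), ncol(h))
  for (di in 0:2) for (dj in 0:2) {
    acc <- acc + hp[(1:nrow(h)) + di, (1:ncol(h)) + dj]
    cnt <- cnt + cp[(1:nrow(h)) + di, (1:ncol(h)) + dj]
  }
  local_mean <- acc / cnt

  idx <- which(lab > 0L)
  ids <- lab[idx]
  rws <- (idx - 1L) %% nrow(lab) + 1L
  cls <- (idx - 1L) %/% nrow(lab) + 1L
  ord <- order(ids)
  split_rows <- split(rws[ord], ids[ord])
  split_cols <- split(cls[ord], ids[ord])
  cent <- segmentation$centroids

  res <- vector("list", n)
  sdp <- function(x) if (length(x) < 2L) 0 else sd(x)
  for (k in seq_len(n)) {
    r <- split_rows[[k]]; cc <- split_cols[[k]]
    pix <- cbind(r, cc)
    f <- c(nucleus_id = k)
    if ("appearance" %in% groups) {
      rv <- rgb_image[cbind(r, cc, 1)] / 255
      gv <- rgb_image[cbind(r, cc, 2)] / 255
      bv <- rgb_image[cbind(r, cc, 3)] / 255
      hv <- h[pix]
      f <- c(f, mean_r = mean(rv), sd_r = sdp(rv), mean_g = mean(gv),
             sd_g = sdp(gv), mean_b = mean(bv), sd_b = sdp(bv),
             mean_h = mean(hv), sd_h = sdp(hv))
    }
    if ("morphology" %in% groups) {
      r0 <- min(r); c0 <- min(cc)
      msk <- matrix(FALSE, max(r) - r0 + 1L, max(cc) - c0 + 1L)
      msk[cbind(r - r0 + 1L, cc - c0 + 1L)] <- TRUE
      per_um <- pixel_perimeter(msk) * mpp
      area_um2 <- length(r) * mpp^2
      f <- c(f, area_um2 = area_um2,
             eccentricity = pixel_eccentricity(r, cc),
             solidity = pixel_solidity(r, cc),
             perimeter_area_ratio = per_um / area_um2)
    }
    if ("texture" %in% groups) {
      r0 <- min(r); c0 <- min(cc)
      qm <- q[r0:max(r), c0:max(cc), drop = FALSE]
      im <- matrix(FALSE, nrow(qm), ncol(qm))
      im[cbind(r - r0 + 1L, cc - c0 + 1L)] <- TRUE
      f <- c(f, glcm_stats(qm, im),
             local_variance = mean((h[pix] - local_mean[pix])^2))
    }
    res[[k]] <- f
  }
  out <- as.data.frame(do.call(rbind, res))
  if ("spatial" %in% groups) {
    diag_um <- sqrt(nrow(lab)^2 + ncol(lab)^2) * mpp
    if (n == 1L) {
      out$nn_dist_um <- diag_um
      out$knn_dist_um <- diag_um
      out$density_per_100um2 <- 100 / (pi * density_radius_um^2)
    } else {
      d <- as.matrix(dist(cbind(cent$x, cent$y))) * mpp
      diag(d) <- Inf
      kk <- min(k_neighbours, n - 1L)
      out$nn_dist_um <- apply(d, 1L, min)
      out$knn_dist_um <- apply(d, 1L, function(z) mean(sort(z)[seq_len(kk)]))
      out$density_per_100um2 <- apply(d, 1L, function(z)
        (1 + sum(z <= density_radius_um)) / (pi * density_radius_um^2) * 100)
    }
  }
  rownames(out) <- NULL
  out$nucleus_id <- as.integer(out$nucleus_id)
  out[, c("nucleus_id", cols_wanted)]
}

#' Match segmented nuclei to synthetic ground-truth classes
#'
#' Assigns each segmented nucleus the majority ground-truth nucleus class
#' (lymphocyte / epithelial / malignant) over its pixels; nuclei whose
#' pixels contain no true nucleus class get \code{NA}.
#'
#' @param segmentation A \code{\link{segment_nuclei}} result.
#' @param truth The \code{truth} component of \code{\link{generate_patch}}.
#' @return Factor of length \code{segmentation$n} with levels
#'   \code{lymphocyte, epithelial, malignant}.
#' @export
match_nuclei_to_truth <- function(segmentation, truth) {
  stopifnot(inherits(segmentation, "nucleus_segmentation"))
  lab <- segmentation$labeled_mask
  lv <- c("lymphocyte", "epithelial", "malignant")
  if (segmentation$n == 0L) return(factor(character(), levels = lv))
  tl <- truth$label_map
  stopifnot(all(dim(tl) == dim(lab)))
  out <- rep(NA_integer_, segmentation$n)
  idx <- which(lab > 0L)
  ids <- lab[idx]
  tv <- tl[idx]
  for (k in seq_len(segmentation$n)) {
    cnts <- tabulate(tv[ids == k], nbins = 3L)
    if (sum(cnts) > 0L) out[k] <- which.max(cnts)
  }
  factor(lv[out], levels = lv)
}
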