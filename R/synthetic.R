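# Synthetic H&E patch and slide generator with per-pixel ground truth.
#
# Appearance model: each nucleus is a textured ellipse whose hematoxylin
# optical density (OD) is drawn per nucleus and perturbed per pixel; the
# patch is rendered by Beer-Lambert mixing of two stain vectors, so the
# downstream colour-deconvolution stage sees physically plausible colours.
# Malignant cytoplasm is an explicit halo label so "area occupied by
# malignant cells" has an unambiguous ground truth.

# Per-class morphology/appearance defaults. Radii are realistic for breast
# tissue at 0.5 um/px: lymphocytes are small, dark and round; benign
# epithelial nuclei intermediate; malignant nuclei large, pleomorphic and
# coarsely textured.
default_class_params <- function() {
  list(
    lymphocyte = list(radius_um_mean = 2.75, radius_um_sd = 0.25,
                      ecc_range = c(0.0, 0.3), od_mean = 1.00,
                      od_sd = 0.06, texture_amp = 0.03),
    epithelial = list(radius_um_mean = 4.0, radius_um_sd = 0.4,
                      ecc_range = c(0.3, 0.7), od_mean = 0.55,
                      od_sd = 0.05, texture_amp = 0.08),
    malignant  = list(radius_um_mean = 6.0, radius_um_sd = 0.6,
                      ecc_range = c(0.2, 0.8), od_mean = 0.75,
                      od_sd = 0.07, texture_amp = 0.20)
  )
}

#' Specification for a synthetic H&E patch
#'
#' Describes the geometry, composition and appearance of one synthetic
#' patch. Identical specs with identical seeds produce bit-identical
#' output.
#'
#' @param width_px,height_px Patch dimensions in pixels (default 512).
#' @param microns_per_pixel Physical pixel size in micrometres (default
#'   0.5, i.e. 20x magnification).
#' @param n_lymphocyte,n_epithelial,n_malignant Requested nucleus counts
#'   per class. Realised counts can be lower when rejection sampling fails
#'   to place a nucleus without overlap (rejections are reported).
#' @param class_params Per-class morphology list as produced by the
#'   default; each entry holds \code{radius_um_mean}, \code{radius_um_sd},
#'   \code{ecc_range}, \code{od_mean}, \code{od_sd}, \code{texture_amp}.
#' @param cytoplasm_halo_radius_um Radius of the malignant cytoplasm
#'   annulus (default 2.5 um); halo pixels count towards true cellularity.
#' @param stain_vectors 3 x 2 matrix of RGB stain vectors
#'   (hematoxylin-like, eosin-like); must be non-collinear.
#' @param background_noise_sd Additive optical-density noise (default
#'   0.015).
#' @param fill_fraction_cap Maximum requested nucleus-area fraction before
#'   placement is declared infeasible (default 0.75).
#' @param max_place_attempts Rejection-sampling cap per nucleus (default
#'   200).
#' @param seed Integer RNG seed.
#' @return An object of class \code{"synthetic_patch_spec"}.
#' @seealso \code{\link{generate_patch}}
#' @export
synthetic_patch_spec <- function(width_px = 512L, height_px = 512L,
                                 microns_per_pixel = 0.5,
                                 n_lymphocyte = 15L, n_epithelial = 15L,
                                 n_malignant = 15L,
                                 class_params = default_class_params(),
                                 cytoplasm_halo_radius_um = 2.5,
                                 stain_vectors = he_stain_vectors(),
                                 background_noise_sd = 0.015,
                                 fill_fraction_cap = 0.75,
                                 max_place_attempts = 200L,
                                 seed = 1L) {
  spec <- list(width_px = as.integer(width_px),
               height_px = as.integer(height_px),
               microns_per_pixel = microns_per_pixel,
               n_lymphocyte = as.integer(n_lymphocyte),
               n_epithelial = as.integer(n_epithelial),
               n_malignant = as.integer(n_malignant),
               class_params = class_params,
               cytoplasm_halo_radius_um = cytoplasm_halo_radius_um,
               stain_vectors = stain_vectors,
               background_noise_sd = background_noise_sd,
               fill_fraction_cap = fill_fraction_cap,
               max_place_attempts = as.integer(max_place_attempts),
               seed = as.integer(seed))
  class(spec) <- "synthetic_patch_spec"
  validate_patch_spec(spec)
  spec
}

validate_patch_spec <- function(spec) {
  stopifnot(spec$width_px >= 16L, spec$height_px >= 16L,
            spec$microns_per_pixel > 0,
            spec$n_lymphocyte >= 0L, spec$n_epithelial >= 0L,
            spec$n_malignant >= 0L,
            spec$cytoplasm_halo_radius_um >= 0,
            spec$background_noise_sd >= 0)
  for (p in spec$class_params)
    stopifnot(p$radius_um_mean > 0, p$radius_um_sd >= 0,
              all(p$ecc_range >= 0), all(p$ecc_range < 1))
  sv <- spec$stain_vectors
  if (!is.matrix(sv) || any(dim(sv) != c(3L, 2L)))
    stop("stain_vectors must be a 3 x 2 matrix")
  cosang <- abs(sum(sv[, 1] * sv[, 2])) /
    (sqrt(sum(sv[, 1]^2)) * sqrt(sum(sv[, 2]^2)))
  if (cosang > 0.999) stop("stain vectors must be non-collinear")
  invisible(spec)
}

# Label codes of the ground-truth map.
LABEL_BACKGROUND <- 0L
LABEL_LYMPHOCYTE <- 1L
LABEL_EPITHELIAL <- 2L
LABEL_MALIGNANT  <- 3L
LABEL_HALO       <- 4L

#' Generate one synthetic H&E patch with per-pixel ground truth
#'
#' Places textured elliptical nuclei by rejection sampling (no nucleus
#' overlaps another), adds a cytoplasm halo around malignant nuclei, and
#' renders the patch by Beer-Lambert stain mixing plus Gaussian
#' optical-density noise. The true cellularity fraction is the exact
#' fraction of pixels labelled malignant nucleus or halo.
#'
#' @param spec A \code{\link{synthetic_patch_spec}}.
#' @return A list with components \code{image} (height x width x 3 numeric
#'   array, integer values 0--255) and \code{truth}, itself a list with
#'   \code{label_map} (integer matrix; 0 background/stroma, 1 lymphocyte,
#'   2 epithelial, 3 malignant nucleus, 4 malignant cytoplasm halo),
#'   \code{nucleus_records} (data frame: \code{nucleus_id}, \code{class},
#'   \code{x}, \code{y} 0-based centroid pixels, \code{area_px}),
#'   \code{true_tc_fraction}, and \code{n_rejected} (named per-class
#'   rejection counts).
#' @examples
#' p <- generate_patch(synthetic_patch_spec(width_px = 128, height_px = 128,
#'   n_lymphocyte = 4, n_epithelial = 4, n_malignant = 4, seed = 7))
#' p$truth$true_tc_fraction
#' @export
generate_patch <- function(spec) {
  validate_patch_spec(spec)
  H <- spec$height_px; W <- spec$width_px
  mpp <- spec$microns_per_pixel
  counts <- c(malignant = spec$n_malignant, epithelial = spec$n_epithelial,
              lymphocyte = spec$n_lymphocyte)
  req_area <- sum(vapply(names(counts), function(cl) {
    counts[[cl]] * pi * (spec$class_params[[cl]]$radius_um_mean / mpp)^2
  }, numeric(1)))
  if (req_area > spec$fill_fraction_cap * H * W)
    stop(sprintf(paste0("infeasible packing: requested nucleus area fraction",
                        " %.2f exceeds fill_fraction_cap %.2f"),
                 req_area / (H * W), spec$fill_fraction_cap))

  with_seed(spec$seed, {
    label_map <- matrix(LABEL_BACKGROUND, H, W)
    od_h_nuc <- matrix(0, H, W)      # per-nucleus hematoxylin OD draw
    rec_class <- character(0); rec_x <- numeric(0); rec_y <- numeric(0)
    rec_area <- integer(0)
    rejected <- c(lymphocyte = 0L, epithelial = 0L, malignant = 0L)
    class_code <- c(lymphocyte = LABEL_LYMPHOCYTE,
                    epithelial = LABEL_EPITHELIAL,
                    malignant = LABEL_MALIGNANT)
    nid <- 0L
    # large classes first: packs dense malignant sheets before the small
    # lymphocytes fill residual gaps
    for (cl in names(counts)) {
      pp <- spec$class_params[[cl]]
      n_req <- counts[[cl]]
      if (n_req == 0L) next
      code <- class_code[[cl]]
      for (i in seq_len(n_req)) {
        placed <- FALSE
        for (att in seq_len(spec$max_place_attempts)) {
          r_um <- max(0.75, rnorm(1, pp$radius_um_mean, pp$radius_um_sd))
          r_px <- r_um / mpp
          ecc <- runif(1, pp$ecc_range[1], pp$ecc_range[2])
          th <- runif(1, 0, pi)
          # equal-area semi-axes: a*b = r_px^2
          s <- (1 - ecc^2)^0.25
          a <- r_px / s; b <- r_px * s
          cth <- cos(th); sth <- sin(th)
          ext_c <- sqrt((a * cth)^2 + (b * sth)^2) # col extent
          ext_r <- sqrt((a * sth)^2 + (b * cth)^2) # row extent
          if (2 * ext_c + 2 > W || 2 * ext_r + 2 > H) next
          cc <- runif(1, 1 + ext_c, W - ext_c)
          cr <- runif(1, 1 + ext_r, H - ext_r)
          # cheap pre-reject: centre pixel already occupied
          if (label_map[round(cr), round(cc)] != LABEL_BACKGROUND) next
          r0 <- max(1L, floor(cr - ext_r)); r1 <- min(H, ceiling(cr + ext_r))
          c0 <- max(1L, floor(cc - ext_c)); c1 <- min(W, ceiling(cc + ext_c))
          dr <- (r0:r1) - cr; dc <- (c0:c1) - cc
          # ellipse interior in rotated frame (rows = y, cols = x)
          u <- outer(dr * (sth / a), dc * (cth / a), "+")
          v <- outer(dr * (cth / b), dc * (-sth / b), "+")
          inside <- u * u + v * v <= 1
          if (!any(inside)) next
          sub <- label_map[r0:r1, c0:c1]
          if (any(sub[inside] != LABEL_BACKGROUND)) next
          sub[inside] <- code
          label_map[r0:r1, c0:c1] <- sub
          od <- max(0.2, rnorm(1, pp$od_mean, pp$od_sd))
          sub_od <- od_h_nuc[r0:r1, c0:c1]
          sub_od[inside] <- od
          od_h_nuc[r0:r1, c0:c1] <- sub_od
          rows <- rep.int(r0:r1, times = ncol(inside))[inside]
          cols <- rep(c0:c1, each = nrow(inside))[inside]
          nid <- nid + 1L
          rec_class[nid] <- cl
          rec_x[nid] <- mean(cols) - 1
          rec_y[nid] <- mean(rows) - 1
          rec_area[nid] <- length(rows)
          placed <- TRUE
          break
        }
        if (!placed) rejected[[cl]] <- rejected[[cl]] + 1L
      }
    }

    # malignant cytoplasm halo: dilate malignant nuclei, label uncovered
    # background pixels
    if (spec$cytoplasm_halo_radius_um > 0 &&
        any(label_map == LABEL_MALIGNANT)) {
      r_halo <- round(spec$cytoplasm_halo_radius_um / mpp)
      if (r_halo > 0) {
        halo <- binary_dilate(label_map == LABEL_MALIGNANT,
                              disk_kernel(r_halo))
        label_map[halo & label_map == LABEL_BACKGROUND] <- LABEL_HALO
      }
    }

    # render: per-pixel stain OD = class base + nucleus draw + texture
    base_h <- c(0.10, 0, 0, 0, 0.16)[label_map + 1L]
    base_e <- c(0.32, 0.10, 0.16, 0.16, 0.52)[label_map + 1L]
    tex_amp <- c(0, spec$class_params$lymphocyte$texture_amp,
                 spec$class_params$epithelial$texture_amp,
                 spec$class_params$malignant$texture_amp, 0)[label_map + 1L]
    z_tex <- matrix(rnorm(H * W), H, W)
    od_h <- matrix(base_h, H, W) + od_h_nuc + tex_amp * z_tex
    od_e <- matrix(base_e, H, W) + 0.04 * z_tex
    if (spec$background_noise_sd > 0) {
      od_h <- od_h + matrix(rnorm(H * W, 0, spec$background_noise_sd), H, W)
      od_e <- od_e + matrix(rnorm(H * W, 0, spec$background_noise_sd), H, W)
    }
    od_h <- pmax(od_h, 0); od_e <- pmax(od_e, 0)
    sv <- spec$stain_vectors
    img <- array(0, c(H, W, 3))
    for (ch in 1:3)
      img[, , ch] <- round(255 * 10^-(od_h * sv[ch, 1] + od_e * sv[ch, 2]))
    img <- clip(img, 0, 255)

    nucleus_records <- data.frame(nucleus_id = seq_len(nid),
                                  class = rec_class, x = rec_x, y = rec_y,
                                  area_px = rec_area,
                                  stringsAsFactors = FALSE)
    truth <- list(label_map = label_map,
                  nucleus_records = nucleus_records,
                  true_tc_fraction =
                    sum(label_map == LABEL_MALIGNANT |
                          label_map == LABEL_HALO) / (H * W),
                  n_rejected = rejected)
    list(image = img, truth = truth)
  })
}

#' Specification for a synthetic slide mosaic
#'
#' A grid of patch specs assembled into one flat mosaic with a tumour-bed
#' polygon annotation. The default polygon is the rectangle covering the
#' whole mosaic.
#'
#' @param patch_specs A list of \code{\link{synthetic_patch_spec}} objects,
#'   length \code{n_rows * n_cols}, in row-major order.
#' @param n_rows,n_cols Grid dimensions (each >= 1).
#' @param tumour_bed_polygon Data frame of vertices \code{x,y} in slide
#'   pixels (0-based), or \code{NULL} for the full-mosaic rectangle. Must
#'   be a simple (non-self-intersecting) polygon.
#' @return An object of class \code{"synthetic_slide_spec"}.
#' @export
synthetic_slide_spec <- function(patch_specs, n_rows, n_cols,
                                 tumour_bed_polygon = NULL) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L,
            length(patch_specs) == n_rows * n_cols)
  lapply(patch_specs, validate_patch_spec)
  w <- unique(vapply(patch_specs, `[[`, integer(1), "width_px"))
  h <- unique(vapply(patch_specs, `[[`, integer(1), "height_px"))
  if (length(w) != 1L || length(h) != 1L)
    stop("all patch specs in a slide must share dimensions")
  if (is.null(tumour_bed_polygon)) {
    W <- n_cols * w; H <- n_rows * h
    tumour_bed_polygon <- data.frame(x = c(0, W, W, 0), y = c(0, 0, H, H))
  }
  if (!is_simple_polygon(tumour_bed_polygon))
    stop("tumour_bed_polygon must be a simple polygon")
  structure(list(patch_specs = patch_specs, n_rows = n_rows,
                 n_cols = n_cols, patch_width = w, patch_height = h,
                 tumour_bed_polygon = tumour_bed_polygon),
            class = "synthetic_slide_spec")
}

# Simple-polygon check: no two non-adjacent edges intersect.
is_simple_polygon <- function(poly) {
  x <- poly$x; y <- poly$y; n <- length(x)
  if (n < 3L) return(FALSE)
  seg <- cbind(x, y, c(x[-1], x[1]), c(y[-1], y[1]))
  inter <- function(a, b) {
    d <- function(p, q, r)
      sign((q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1]))
    p1 <- a[1:2]; p2 <- a[3:4]; p3 <- b[1:2]; p4 <- b[3:4]
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (d1 != d2 && d3 != d4) && (d1 * d2 < 0 && d3 * d4 < 0)
  }
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (j > i + 1L && !(i == 1L && j == n))
        if (inter(seg[i, ], seg[j, ])) return(FALSE)
  TRUE
}

#' Generate a synthetic slide mosaic with per-patch ground truth
#'
#' Assembles per-patch images and label maps into one flat mosaic and
#' returns the per-cell truth table used by tiling and agreement tests.
#'
#' @param spec A \code{\link{synthetic_slide_spec}}.
#' @return A list with \code{image} (mosaic RGB array), \code{label_map}
#'   (mosaic integer label matrix), \code{tumour_bed_polygon}, and
#'   \code{truth_table} (data frame \code{patch_id,row,col,true_tc_percent};
#'   \code{row}/\code{col} are 0-based grid indices).
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  H <- spec$n_rows * spec$patch_height
  W <- spec$n_cols * spec$patch_width
  img <- array(0, c(H, W, 3))
  lab <- matrix(LABEL_BACKGROUND, H, W)
  rows <- list()
  k <- 0L
  for (i in seq_len(spec$n_rows)) {
    for (j in seq_len(spec$n_cols)) {
      k <- k + 1L
      p <- generate_patch(spec$patch_specs[[k]])
      r0 <- (i - 1L) * spec$patch_height + 1L
      c0 <- (j - 1L) * spec$patch_width + 1L
      img[r0:(r0 + spec$patch_height - 1L),
          c0:(c0 + spec$patch_width - 1L), ] <- p$image
      lab[r0:(r0 + spec$patch_height - 1L),
          c0:(c0 + spec$patch_width - 1L)] <- p$truth$label_map
      rows[[k]] <- data.frame(
        patch_id = sprintf("r%02d_c%02d", i - 1L, j - 1L),
        row = i - 1L, col = j - 1L,
        true_tc_percent = 100 * p$truth$true_tc_fraction,
        stringsAsFactors = FALSE)
    }
  }
  list(image = img, label_map = lab,
       tumour_bed_polygon = spec$tumour_bed_polygon,
       truth_table = do.call(rbind, rows))
}

#' Simulate pathologist TC scoring of known-truth patches
#'
#' Adds Gaussian rater noise to the true cellularity percentage, clips to
#' 0--100 and rounds to the rater's reporting step. Patches with zero true
#' cellularity are always scored 0, matching the convention that patches
#' without any tumour cells receive a TC score of 0\%.
#'
#' @param truth_table Data frame with columns \code{patch_id} and
#'   \code{true_tc_percent}.
#' @param rater_noise_sd Standard deviation of rater noise in percentage
#'   points (>= 0).
#' @param rounding_step \code{"continuous"}, \code{5} or \code{10}
#'   (pathologists commonly round to the nearest 5 or 10 percent).
#' @param seed Integer RNG seed.
#' @return Data frame \code{patch_id,score}.
#' @export
sample_manual_scores <- function(truth_table, rater_noise_sd = 5,
                                 rounding_step = 5, seed = 1L) {
  stopifnot(rater_noise_sd >= 0,
            all(c("patch_id", "true_tc_percent") %in% names(truth_table)))
  step_ok <- identical(rounding_step, "continuous") ||
    (is.numeric(rounding_step) && rounding_step %in% c(5, 10))
  if (!step_ok) stop("rounding_step must be \"continuous\", 5 or 10")
  with_seed(seed, {
    tc <- truth_table$true_tc_percent
    s <- clip(tc + rnorm(length(tc), 0, rater_noise_sd), 0, 100)
    if (!identical(rounding_step, "continuous"))
      s <- rounding_step * round(s / rounding_step)
    s[tc == 0] <- 0
    data.frame(patch_id = truth_table$patch_id, score = s,
               stringsAsFactors = FALSE)
  })
}
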