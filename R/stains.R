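# Stain separation: optical-density colour deconvolution onto configurable
# hematoxylin/eosin vectors, followed by percentile contrast stretch. This
# suppresses global stain-intensity variation (a brightness rescale of the
# input shifts optical density by a constant, which the stretch removes).

#' Separate hematoxylin and eosin stain intensities
#'
#' Converts an RGB patch to optical density, projects each pixel onto two
#' stain colour vectors (least-squares colour deconvolution), and contrast-
#' stretches each stain map between the given percentiles to \code{[0,1]}.
#'
#' @param rgb_image Height x width x 3 array, values 0--255.
#' @param stain_vectors 3 x 2 matrix of RGB stain vectors (columns:
#'   hematoxylin-like, eosin-like); must be non-collinear. Default
#'   \code{\link{he_stain_vectors}()}.
#' @param stretch_percentiles Length-2 numeric in [0,1]; default
#'   \code{c(0.01, 0.99)} (1st--99th percentile stretch).
#' @return An object of class \code{"stain_maps"}: list with
#'   \code{hematoxylin} and \code{eosin} matrices in \code{[0,1]}, plus the
#'   vectors and percentiles used. A degenerate (all-white/all-black) image
#'   yields zero maps with a warning.
#' @export
separate_stains <- function(rgb_image, stain_vectors = he_stain_vectors(),
                            stretch_percentiles = c(0.01, 0.99)) {
  check_rgb_image(rgb_image)
  if (!is.matrix(stain_vectors) || any(dim(stain_vectors) != c(3L, 2L)))
    stop("stain_vectors must be a 3 x 2 matrix")
  cosang <- abs(sum(stain_vectors[, 1] * stain_vectors[, 2])) /
    prod(sqrt(colSums(stain_vectors^2)))
  if (cosang > 0.999) stop("stain vectors must be non-collinear")
  stopifnot(length(stretch_percentiles) == 2L,
            stretch_percentiles[1] < stretch_percentiles[2])

  od <- -log10(pmax(rgb_image, 1) / 255)
  m <- stain_vectors
  proj <- solve(crossprod(m), t(m))          # 2 x 3 pseudo-inverse
  h <- proj[1, 1] * od[, , 1] + proj[1, 2] * od[, , 2] + proj[1, 3] * od[, , 3]
  e <- proj[2, 1] * od[, , 1] + proj[2, 2] * od[, , 2] + proj[2, 3] * od[, , 3]
  stretch <- function(x, what) {
    q <- quantile(x, stretch_percentiles, names = FALSE)
    if (diff(q) < 1e-8) {
      warning(sprintf("degenerate %s channel: contrast stretch undefined, returning zeros",
                      what))
      return(matrix(0, nrow(x), ncol(x)))
    }
    clip((x - q[1]) / (q[2] - q[1]), 0, 1)
  }
  structure(list(hematoxylin = stretch(h, "hematoxylin"),
                 eosin = stretch(e, "eosin"),
                 hematoxylin_raw = h, eosin_raw = e,
                 stain_vectors = stain_vectors,
                 stretch_percentiles = stretch_percentiles),
            class = "stain_maps")
}

#' Nucleus segmentation parameters
#'
#' @param threshold_method \code{"otsu"} (default) or \code{"fixed"}.
#' @param fixed_threshold Threshold on the stretched hematoxylin map when
#'   \code{threshold_method = "fixed"}.
#' @param min_area_um2,max_area_um2 Area bounds for emitted nuclei
#'   (defaults 8 and 250 square micrometres).
#' @param split_method \code{"watershed"} (default; distance-transform
#'   watershed splits touching nuclei) or \code{"none"}.
#' @param min_od Absolute foreground floor on the raw (unstretched)
#'   hematoxylin concentration (default 0.25 optical-density units).
#'   Prevents the contrast stretch from promoting background noise to
#'   foreground on nucleus-free patches.
#' @param watershed_tolerance Minimum object-depth separation in the
#'   distance map before two catchment basins are kept distinct (default 1).
#' @param smooth_sigma Gaussian pre-smoothing of the hematoxylin map in
#'   pixels (default 1; 0 disables).
#' @param microns_per_pixel Physical pixel size (default 0.5).
#' @return A list of class \code{"segmentation_params"}.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = 0.5,
                                min_area_um2 = 8, max_area_um2 = 250,
                                split_method = c("watershed", "none"),
                                min_od = 0.25,
                                watershed_tolerance = 1,
                                smooth_sigma = 1,
                                microns_per_pixel = 0.5) {
  structure(list(threshold_method = match.arg(threshold_method),
                 fixed_threshold = fixed_threshold,
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 split_method = match.arg(split_method), min_od = min_od,
                 watershed_tolerance = watershed_tolerance,
                 smooth_sigma = smooth_sigma,
                 microns_per_pixel = microns_per_pixel),
            class = "segmentation_params")
}

#' Segment nucleus boundaries from stain maps
#'
#' Thresholds the hematoxylin map (Otsu by default), fills holes, splits
#' touching nuclei by a distance-transform watershed, and filters objects
#' by physical area. Deterministic for fixed inputs.
#'
#' @param stain_maps A \code{\link{separate_stains}} result.
#' @param params A \code{\link{segmentation_params}} list.
#' @return An object of class \code{"nucleus_segmentation"}: list with
#'   \code{labeled_mask} (integer matrix, 0 background, k = nucleus k with
#'   contiguous labels), \code{n}, \code{areas_px}, \code{areas_um2},
#'   \code{centroids} (data frame \code{nucleus_id,x,y}, 0-based pixels),
#'   \code{boundaries} (list of closed x,y contour matrices), and
#'   \code{params}. An empty foreground yields an empty segmentation.
#' @export
segment_nuclei <- function(stain_maps, params = segmentation_params()) {
  stopifnot(inherits(stain_maps, "stain_maps"))
  h <- stain_maps$hematoxylin
  if (params$smooth_sigma > 0)
    h <- EBImage::imageData(EBImage::gblur(h, sigma = params$smooth_sigma))
  thr <- if (params$threshold_method == "otsu") {
    if (diff(range(h)) < 1e-8) Inf else EBImage::otsu(EBImage::Image(h))
  } else params$fixed_threshold
  mask <- h > thr
  if (!is.null(stain_maps$hematoxylin_raw) && params$min_od > 0)
    mask <- mask & stain_maps$hematoxylin_raw > params$min_od
  empty <- function() {
    structure(list(labeled_mask = matrix(0L, nrow(h), ncol(h)), n = 0L,
                   areas_px = integer(), areas_um2 = numeric(),
                   centroids = data.frame(nucleus_id = integer(),
                                          x = numeric(), y = numeric()),
                   boundaries = list(), params = params),
              class = "nucleus_segmentation")
  }
  if (!any(mask)) return(empty())
  mask <- EBImage::imageData(EBImage::fillHull(matrix(as.numeric(mask),
                                                      nrow(h)))) > 0
  if (params$split_method == "watershed") {
    dm <- EBImage::distmap(matrix(as.numeric(mask), nrow(h)))
    lab <- EBImage::imageData(EBImage::watershed(dm,
                                                 tolerance =
                                                   params$watershed_tolerance,
                                                 ext = 1))
  } else {
    lab <- EBImage::imageData(EBImage::bwlabel(matrix(as.numeric(mask),
                                                      nrow(h))))
  }
  lab <- matrix(as.integer(lab), nrow(h))
  areas <- tabulate(lab[lab > 0L])
  mpp2 <- params$microns_per_pixel^2
  keep <- which(areas * mpp2 >= params$min_area_um2 &
                  areas * mpp2 <= params$max_area_um2)
  if (length(keep) == 0L) return(empty())
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)              # contiguous labels, old order
  out <- matrix(0L, nrow(h), ncol(h))
  pos <- lab > 0L
  out[pos] <- relab[lab[pos]]
  idx <- which(out > 0L)
  ids <- out[idx]
  rows <- (idx - 1L) %% nrow(out) + 1L
  cols <- (idx - 1L) %/% nrow(out) + 1L
  cx <- tapply(cols, ids, mean) - 1
  cy <- tapply(rows, ids, mean) - 1
  areas_px <- as.integer(tabulate(ids, nbins = length(keep)))
  bnds <- EBImage::ocontour(EBImage::Image(out))
  boundaries <- lapply(seq_along(keep), function(k) {
    b <- bnds[[k]]
    # EBImage indexes (x, y) over the matrix as given; 0-based already
    m <- cbind(x = b[, 2], y = b[, 1])
    rbind(m, m[1, , drop = FALSE])            # close the contour
  })
  structure(list(labeled_mask = out, n = length(keep),
                 areas_px = areas_px, areas_um2 = areas_px * mpp2,
                 centroids = data.frame(nucleus_id = seq_along(keep),
                                        x = as.numeric(cx),
                                        y = as.numeric(cy)),
                 boundaries = boundaries, params = params),
            class = "nucleus_segmentation")
}

#' @export
print.nucleus_segmentation <- function(x, ...) {
  cat(sprintf("nucleus segmentation: %d nuclei, area %s-%s um^2 (%s threshold, %s split)\n",
              x$n, x$params$min_area_um2, x$params$max_area_um2,
              x$params$threshold_method, x$params$split_method))
  invisible(x)
}

#' Write a labeled nucleus mask as 16-bit TIFF
#'
#' @param segmentation A \code{\link{segment_nuclei}} result.
#' @param path Output file path.
#' @export
write_segmentation_mask <- function(segmentation, path) {
  stopifnot(inherits(segmentation, "nucleus_segmentation"))
  tiff::writeTIFF(segmentation$labeled_mask / 65535,
                  path, bits.per.sample = 16L)
  invisible(path)
}

#' Write nucleus boundary polygons as CSV
#'
#' One row per contour vertex with columns \code{nucleus_id,x,y} (0-based
#' pixels).
#'
#' @param segmentation A \code{\link{segment_nuclei}} result.
#' @param path Output CSV path.
#' @export
write_boundaries <- function(segmentation, path) {
  stopifnot(inherits(segmentation, "nucleus_segmentation"))
  rows <- lapply(seq_along(segmentation$boundaries), function(k) {
    b <- segmentation$boundaries[[k]]
    data.frame(nucleus_id = k, x = b[, "x"], y = b[, "y"])
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(nucleus_id = integer(), x = numeric(), y = numeric())
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
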