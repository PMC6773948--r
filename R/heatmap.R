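# Whole-slide tiling over a tumour-bed polygon, patch scoring with any
# scorer, and blue-to-red heatmap overlays (blue = 0% TC, red = 100% TC).

#' Tile a slide over a tumour-bed polygon
#'
#' Candidate windows are laid on a stride grid starting at the origin;
#' windows extending beyond the slide are excluded (never clipped). A
#' window is included iff its centre lies inside the polygon. Windows are
#' half-open \code{[x, x+size) x [y, y+size)} in 0-based slide pixels.
#'
#' @param slide_dims \code{c(height, width)} of the slide in pixels
#'   (matching \code{dim(image)[1:2]}).
#' @param polygon Data frame of vertices \code{x,y} in slide pixels
#'   (simple polygon).
#' @param patch_size_px Window edge length.
#' @param stride_px Grid stride (>= 1).
#' @return Data frame \code{x,y,size} of included window origins. Empty
#'   (with a warning) when the polygon lies outside the slide.
#' @export
tile_tumour_bed <- function(slide_dims, polygon, patch_size_px = 512L,
                            stride_px = patch_size_px) {
  stopifnot(length(slide_dims) == 2L, stride_px >= 1,
            patch_size_px >= 1,
            all(c("x", "y") %in% names(polygon)))
  if (!is_simple_polygon(polygon))
    stop("polygon must be simple (non-self-intersecting)")
  H <- slide_dims[1]; W <- slide_dims[2]
  xs <- seq(0L, W - patch_size_px, by = stride_px)
  ys <- seq(0L, H - patch_size_px, by = stride_px)
  if (length(xs) == 0L || length(ys) == 0L || W < patch_size_px ||
      H < patch_size_px)
    return(data.frame(x = integer(), y = integer(), size = integer()))
  grid <- expand.grid(x = xs, y = ys)
  bnd <- rbind(as.matrix(polygon[, c("x", "y")]),
               as.matrix(polygon[1L, c("x", "y")]))
  centres <- cbind(grid$x + patch_size_px / 2, grid$y + patch_size_px / 2)
  inside <- mgcv::in.out(bnd, centres)
  out <- data.frame(x = as.integer(grid$x[inside]),
                    y = as.integer(grid$y[inside]),
                    size = rep(as.integer(patch_size_px), sum(inside)))
  if (nrow(out) == 0L)
    warning("no window centres fall inside the tumour-bed polygon")
  out
}

#' Score every tiled window of a slide
#'
#' Applies a scorer function to each window's pixels. A scorer failure on
#' one window marks that window unscored (\code{NA}) and the run
#' continues; the error messages are attached as the \code{"errors"}
#' attribute. Windows are scored independently, so the result does not
#' depend on their order.
#'
#' @param scorer Function taking an RGB patch array and returning either a
#'   numeric score in [0,100] or a \code{\link{tc_score}}.
#' @param slide_image Slide RGB array (values 0--255).
#' @param windows Window table from \code{\link{tile_tumour_bed}}.
#' @param method Provenance tag recorded per window (default
#'   \code{"custom"}).
#' @return Object of class \code{"slide_score_grid"}: data frame
#'   \code{x,y,size,score,method,stage}.
#' @export
score_slide <- function(scorer, slide_image, windows, method = "custom") {
  check_rgb_image(slide_image, "slide_image")
  stopifnot(is.function(scorer))
  n <- nrow(windows)
  scores <- rep(NA_real_, n)
  stages <- rep(NA_character_, n)
  errs <- character(0)
  for (i in seq_len(n)) {
    x0 <- windows$x[i]; y0 <- windows$y[i]; sz <- windows$size[i]
    patch <- slide_image[(y0 + 1L):(y0 + sz), (x0 + 1L):(x0 + sz), ,
                         drop = FALSE]
    res <- tryCatch(scorer(patch), error = function(e) e)
    if (inherits(res, "error")) {
      errs <- c(errs, sprintf("window (%d,%d): %s", x0, y0,
                              conditionMessage(res)))
      next
    }
    if (inherits(res, "tc_score")) {
      scores[i] <- res$value
      stages[i] <- if (!is.null(res$stage)) res$stage else res$method
    } else if (inherits(res, "cascade_prediction")) {
      scores[i] <- res$tc
      stages[i] <- res$stage
    } else {
      scores[i] <- as.numeric(res)
    }
  }
  out <- data.frame(x = windows$x, y = windows$y, size = windows$size,
                    score = scores, method = method, stage = stages,
                    stringsAsFactors = FALSE)
  attr(out, "errors") <- errs
  class(out) <- c("slide_score_grid", "data.frame")
  if (length(errs) > 0L)
    warning(sprintf("%d window(s) unscored (see attr(., \"errors\"))",
                    length(errs)))
  out
}

#' Heatmap colour for a TC score
#'
#' Linear interpolation between the healthy endpoint (pure blue, 0\% TC)
#' and the maximal endpoint (pure red, 100\% TC).
#'
#' @param score Numeric scores in [0,100].
#' @param low,high Endpoint colours (any form \code{col2rgb} accepts).
#' @return Matrix with columns r,g,b in [0,1], one row per score.
#' @export
heatmap_colour <- function(score, low = "blue", high = "red") {
  stopifnot(all(score >= 0), all(score <= 100))
  lo <- col2rgb(low)[, 1] / 255
  hi <- col2rgb(high)[, 1] / 255
  t <- score / 100
  out <- cbind(r = (1 - t) * lo[1] + t * hi[1],
               g = (1 - t) * lo[2] + t * hi[2],
               b = (1 - t) * lo[3] + t * hi[3])
  out
}

#' Render a heatmap overlay of per-window TC scores
#'
#' Tints each scored window with its \code{\link{heatmap_colour}} at the
#' given opacity; unscored windows are left untinted. Rendering is
#' deterministic: identical inputs give byte-identical output.
#'
#' @param grid A \code{\link{score_slide}} result.
#' @param slide_image Slide RGB array (values 0--255).
#' @param low,high Endpoint colours (defaults blue and red).
#' @param alpha Tint opacity in [0,1] (default 0.4).
#' @return Object of class \code{"tc_heatmap"}: list with \code{overlay}
#'   (RGB array in [0,1], ready for \code{png::writePNG}) and
#'   \code{legend} (vertical colour ramp strip, 0\% at the bottom).
#' @export
render_heatmap <- function(grid, slide_image, low = "blue", high = "red",
                           alpha = 0.4) {
  check_rgb_image(slide_image, "slide_image")
  stopifnot(alpha >= 0, alpha <= 1)
  ov <- slide_image / 255
  for (i in seq_len(nrow(grid))) {
    s <- grid$score[i]
    if (is.na(s)) next
    col <- heatmap_colour(s, low, high)
    x0 <- grid$x[i]; y0 <- grid$y[i]; sz <- grid$size[i]
    rows <- (y0 + 1L):(y0 + sz); cols <- (x0 + 1L):(x0 + sz)
    for (ch in 1:3)
      ov[rows, cols, ch] <- (1 - alpha) * ov[rows, cols, ch] +
        alpha * col[1, ch]
  }
  ramp <- heatmap_colour(seq(100, 0, length.out = 256L), low, high)
  legend <- array(0, c(256L, 24L, 3L))
  for (ch in 1:3) legend[, , ch] <- matrix(ramp[, ch], 256L, 24L)
  structure(list(overlay = clip(ov, 0, 1), legend = legend),
            class = "tc_heatmap")
}

#' Write a rendered heatmap (and optional legend) to PNG
#'
#' @param heatmap A \code{\link{render_heatmap}} result.
#' @param path Output PNG path for the overlay.
#' @param legend_path Optional PNG path for the legend strip.
#' @export
write_heatmap <- function(heatmap, path, legend_path = NULL) {
  stopifnot(inherits(heatmap, "tc_heatmap"))
  png::writePNG(heatmap$overlay, path)
  if (!is.null(legend_path)) png::writePNG(heatmap$legend, legend_path)
  invisible(path)
}
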