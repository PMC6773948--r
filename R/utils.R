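# Internal helpers shared across modules.

# Evaluate expr with a temporarily-seeded RNG, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Disk structuring element: pixels with dx^2 + dy^2 <= r^2, r in pixels.
disk_kernel <- function(radius_px) {
  r <- as.integer(round(radius_px))
  if (r < 0L) stop("disk radius must be non-negative")
  if (r == 0L) return(matrix(1, 1L, 1L))
  d <- -r:r
  k <- outer(d, d, function(a, b) as.numeric(a * a + b * b <= r * r))
  k
}

# Binary dilation of a logical/0-1 matrix by an arbitrary brush.
binary_dilate <- function(mask, kernel) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (all(dim(kernel) == 1L)) return(mask > 0)
  EBImage::imageData(EBImage::dilate(m, kernel)) > 0
}

binary_erode <- function(mask, kernel) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (all(dim(kernel) == 1L)) return(mask > 0)
  EBImage::imageData(EBImage::erode(m, kernel)) > 0
}

# Default H&E stain colour vectors (unit RGB absorption directions).
#' Default hematoxylin/eosin stain vectors
#'
#' Unit RGB optical-density direction vectors for hematoxylin (nuclei,
#' blue-purple) and eosin (cytoplasm/stroma, pink), as commonly used for
#' colour deconvolution of H&E images.
#'
#' @return A 3 x 2 matrix with columns \code{hematoxylin} and \code{eosin}.
#' @export
he_stain_vectors <- function() {
  h <- c(0.650, 0.704, 0.286)
  e <- c(0.072, 0.990, 0.105)
  m <- cbind(hematoxylin = h / sqrt(sum(h^2)), eosin = e / sqrt(sum(e^2)))
  rownames(m) <- c("r", "g", "b")
  m
}

check_rgb_image <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("%s must be a height x width x 3 RGB array", what))
  invisible(TRUE)
}

# Stage-tagged error propagation for pipeline composition.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}
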