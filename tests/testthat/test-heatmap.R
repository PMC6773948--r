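# Slide tiling over a tumour-bed polygon, window scoring, heatmap
# rendering.

rect_poly <- function(x0, y0, x1, y1)
  data.frame(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))

test_that("a polygon covering a 2048x2048 slide at size/stride 512 gives 16 windows", {
  w <- tile_tumour_bed(c(2048L, 2048L), rect_poly(0, 0, 2048, 2048),
                       512L, 512L)
  expect_identical(nrow(w), 16L)
  expect_identical(sort(unique(w$x)), c(0L, 512L, 1024L, 1536L))
  expect_identical(sort(unique(w$y)), c(0L, 512L, 1024L, 1536L))
  expect_true(all(w$size == 512L))
  # full-stride tiling partitions the covered rectangle: no duplicate
  # origins, no overlaps, total area = slide area
  expect_identical(anyDuplicated(w[, c("x", "y")]), 0L)
  expect_identical(sum(as.numeric(w$size)^2), 2048^2)
})

test_that("degenerate and off-slide polygons follow the centre rule", {
  # polygon smaller than a patch, away from any window centre
  expect_warning(
    w0 <- tile_tumour_bed(c(1024L, 1024L), rect_poly(10, 10, 40, 40),
                          512L, 512L),
    "no window centres")
  expect_identical(nrow(w0), 0L)
  # same small polygon containing the first window centre
  w1 <- tile_tumour_bed(c(1024L, 1024L), rect_poly(250, 250, 260, 260),
                        512L, 512L)
  expect_identical(nrow(w1), 1L)
  expect_identical(c(w1$x, w1$y), c(0L, 0L))
  # polygon entirely outside the slide
  expect_warning(
    wo <- tile_tumour_bed(c(512L, 512L), rect_poly(5000, 5000, 6000, 6000),
                          256L, 256L),
    "no window centres")
  expect_identical(nrow(wo), 0L)
})

test_that("included window centres agree with a ray-casting oracle", {
  set.seed(6)
  for (rep in 1:5) {
    # random simple star-shaped polygon around a centre
    nv <- sample(5:9, 1)
    ang <- sort(runif(nv, 0, 2 * pi))
    rad <- runif(nv, 150, 480)
    poly <- data.frame(x = 512 + rad * cos(ang), y = 512 + rad * sin(ang))
    w <- tile_tumour_bed(c(1024L, 1024L), poly, 128L, 64L)
    expect_gt(nrow(w), 0L)
    for (i in seq_len(nrow(w)))
      expect_true(point_in_polygon_oracle(w$x[i] + 64, w$y[i] + 64, poly))
    # and windows whose centres the oracle rejects are not included
    all_x <- seq(0L, 1024L - 128L, 64L)
    grid <- expand.grid(x = all_x, y = all_x)
    excluded <- !(paste(grid$x, grid$y) %in% paste(w$x, w$y))
    ex <- grid[excluded, ][1:25, ]
    oracle_in <- mapply(function(x, y)
      point_in_polygon_oracle(x + 64, y + 64, poly), ex$x, ex$y)
    expect_false(any(oracle_in))
  }
})

test_that("windows never extend beyond the slide and are half-open", {
  w <- tile_tumour_bed(c(700L, 900L), rect_poly(0, 0, 900, 700),
                       256L, 128L)
  expect_true(all(w$x + w$size <= 900L))
  expect_true(all(w$y + w$size <= 700L))
})

test_that("a constant scorer fills the grid with that constant", {
  slide <- array(128, c(256L, 256L, 3L))
  w <- tile_tumour_bed(c(256L, 256L), rect_poly(0, 0, 256, 256), 128L)
  g <- score_slide(function(p) 40, slide, w)
  expect_true(all(g$score == 40))
  expect_identical(nrow(g), 4L)
})

test_that("an oracle scorer reproduces the mosaic truth table", {
  specs <- lapply(1:4, function(i)
    small_spec(seed = i, size = 128L, nm = c(0L, 4L, 10L, 18L)[i],
               ne = 3L, nl = 3L))
  slide <- generate_slide(synthetic_slide_spec(specs, 2L, 2L))
  lm <- slide$label_map
  w <- tile_tumour_bed(dim(slide$image)[1:2], slide$tumour_bed_polygon,
                       128L, 128L)
  # per-window truth from the mosaic label map
  truth_scores <- vapply(seq_len(nrow(w)), function(i) {
    rows <- (w$y[i] + 1L):(w$y[i] + w$size[i])
    cols <- (w$x[i] + 1L):(w$x[i] + w$size[i])
    100 * mean(lm[rows, cols] %in% c(3L, 4L))
  }, numeric(1))
  # feed the truth through as an identity scorer keyed by window order
  i <- 0L
  g2 <- score_slide(function(patch) {
    i <<- i + 1L
    truth_scores[i]
  }, slide$image, w)
  tt <- slide$truth_table
  expect_equal(sort(g2$score), sort(tt$true_tc_percent))
  # the high-cellularity cell receives the grid maximum
  expect_equal(max(g2$score), max(tt$true_tc_percent))
})

test_that("a failing scorer marks its window unscored and continues", {
  slide <- array(100, c(256L, 256L, 3L))
  w <- tile_tumour_bed(c(256L, 256L), rect_poly(0, 0, 256, 256), 128L)
  i <- 0L
  expect_warning(
    g <- score_slide(function(p) {
      i <<- i + 1L
      if (i == 2L) stop("scorer exploded")
      25
    }, slide, w),
    "unscored")
  expect_identical(sum(is.na(g$score)), 1L)
  expect_identical(sum(g$score == 25, na.rm = TRUE), 3L)
  expect_match(attr(g, "errors"), "scorer exploded")
})

test_that("heatmap colours interpolate from pure blue to pure red", {
  expect_equal(heatmap_colour(0)[1, ], c(r = 0, g = 0, b = 1))
  expect_equal(heatmap_colour(100)[1, ], c(r = 1, g = 0, b = 0))
  expect_equal(heatmap_colour(50)[1, ], c(r = 0.5, g = 0, b = 0.5))
  expect_error(heatmap_colour(101))
})

test_that("rendering tints scored windows, skips unscored, and is idempotent", {
  slide <- array(255, c(128L, 128L, 3L))
  g <- data.frame(x = c(0L, 64L), y = c(0L, 0L), size = 64L,
                  score = c(0, NA), method = "custom", stage = NA)
  hm <- render_heatmap(g, slide, alpha = 1)
  # alpha 1: the scored window is exactly the endpoint colour
  expect_true(all(hm$overlay[1:64, 1:64, 3] == 1))
  expect_true(all(hm$overlay[1:64, 1:64, 1] == 0))
  # unscored window untouched
  expect_true(all(hm$overlay[1:64, 65:128, ] == 1))
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  write_heatmap(hm, f1)
  write_heatmap(render_heatmap(g, slide, alpha = 1), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
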