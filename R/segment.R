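SEG_METHODS <- c("C1", "C2", "T1", "T2", "E1", "E2", "E3", "E4")

#' Segmentation configuration
#'
#' All operator thresholds, with defaults as used in the field protocol the
#' pipeline implements. Range bounds are inclusive. Scalar thresholds of the
#' form "set at x" are applied as strictly-greater-than x, except `e2`
#' where the comparison is `>= 230`: the E2 response is clipped to
#' \[0, 255\] before thresholding, which makes 255 a mass point, and an
#' exclusive comparison at 230 would be indistinguishable anyway.
#'
#' @param c1_h,c1_s,c1_v Inclusive (lo, hi) windows on the 0-255 scaled
#'   H, S, V channels for the HSV colour threshold C1. Defaults (35, 100),
#'   (50, 255), (40, 226): greenish ryegrass foliage falls inside these
#'   windows across light conditions.
#' @param c2_ratio_max Blue/green ratio below which a pixel is plant (C2);
#'   default 0.625.
#' @param t1_radius Half-amplitude radius, in frequency pixels, of the
#'   raised-cosine low-pass used by T1; default 25.
#' @param t1_threshold Intensity threshold on the low-passed S channel
#'   (exclusive); default 110.
#' @param t2_window Side, in pixels, of the square neighbourhood for the
#'   entropy operator T2; default 100.
#' @param t2_threshold Entropy threshold in bits (exclusive); default 4.7.
#' @param t2_stride Stride of the entropy filter; 1 (default) is exact,
#'   larger values compute the entropy on a decimated grid and upsample by
#'   nearest neighbour (a speed approximation).
#' @param gauss_size,gauss_sigma Size and sigma of the Gaussian
#'   pre-smoothing used by the edge operators; defaults 5 and 1.
#' @param e1_threshold Prewitt L2 gradient-magnitude threshold (exclusive);
#'   default 29.
#' @param e2_center Centre weight of the 3 x 3 high-boost kernel; default 15.
#' @param e2_scale Divisor applied after the convolution; default 13.
#' @param e2_threshold Intensity threshold (inclusive, see above);
#'   default 230.
#' @param e3_threshold Prewitt L1 gradient threshold (exclusive); default 27.
#' @param e4_threshold Gradient threshold before edge thinning (exclusive);
#'   default 15.
#' @param e4_binarize Intensity at or above which a thinned-edge pixel is
#'   foreground; default 1.
#' @param min_votes Number of the eight method masks that must agree for a
#'   pixel to enter the composite mask; default 4.
#' @param pixels_per_cm Image scale at the soil surface; default 74.36 (the
#'   35 mm-lens protocol value). Used to convert areas and to scale the
#'   structuring element.
#' @param element_radius Disc radius, in pixels, of the structuring element
#'   of the mask clean-up. `NULL` (default) scales a 5 px radius at
#'   74.36 px/cm proportionally with `pixels_per_cm` (minimum 1 px).
#' @param iou_min,border_frac_max,frame_frac_max Plausibility thresholds
#'   used by [validate_detection()].
#' @param score_empty_as_zero If `TRUE` (default) an evaluation against an
#'   empty mask scores 0 and the image is counted; if `FALSE` such images
#'   are excluded from aggregation.
#' @return A `seg_config` list.
#' @export
seg_config <- function(c1_h = c(35, 100), c1_s = c(50, 255), c1_v = c(40, 226),
                       c2_ratio_max = 0.625,
                       t1_radius = 25, t1_threshold = 110,
                       t2_window = 100, t2_threshold = 4.7, t2_stride = 1,
                       gauss_size = 5, gauss_sigma = 1,
                       e1_threshold = 29,
                       e2_center = 15, e2_scale = 13, e2_threshold = 230,
                       e3_threshold = 27,
                       e4_threshold = 15, e4_binarize = 1,
                       min_votes = 4,
                       pixels_per_cm = 74.36, element_radius = NULL,
                       iou_min = 0.8, border_frac_max = 0.25,
                       frame_frac_max = 0.6,
                       score_empty_as_zero = TRUE) {
  if (is.null(element_radius))
    element_radius <- max(1L, as.integer(round(5 * pixels_per_cm / 74.36)))
  cfg <- list(c1_h = c1_h, c1_s = c1_s, c1_v = c1_v,
              c2_ratio_max = c2_ratio_max,
              t1_radius = t1_radius, t1_threshold = t1_threshold,
              t2_window = t2_window, t2_threshold = t2_threshold,
              t2_stride = t2_stride,
              gauss_size = gauss_size, gauss_sigma = gauss_sigma,
              e1_threshold = e1_threshold,
              e2_center = e2_center, e2_scale = e2_scale,
              e2_threshold = e2_threshold,
              e3_threshold = e3_threshold,
              e4_threshold = e4_threshold, e4_binarize = e4_binarize,
              min_votes = min_votes,
              pixels_per_cm = pixels_per_cm, element_radius = element_radius,
              iou_min = iou_min, border_frac_max = border_frac_max,
              frame_frac_max = frame_frac_max,
              score_empty_as_zero = score_empty_as_zero)
  for (nm in c("c1_h", "c1_s", "c1_v"))
    if (cfg[[nm]][1] > cfg[[nm]][2])
      stop(nm, ": lower bound exceeds upper bound", call. = FALSE)
  scalars <- cfg[!names(cfg) %in% c("c1_h", "c1_s", "c1_v",
                                    "score_empty_as_zero")]
  if (any(unlist(scalars) < 0))
    stop("thresholds must be non-negative", call. = FALSE)
  structure(cfg, class = "seg_config")
}

#' @export
print.seg_config <- function(x, ...) {
  cat("<seg_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-18s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

#' Read / write a flat key-value configuration file
#'
#' One `key = value` pair per line; vector values are comma-separated;
#' lines starting with `#` are ignored. Unknown keys are rejected.
#'
#' @param path File path.
#' @param cfg A `seg_config` (for writing).
#' @return `read_seg_config()` returns a `seg_config`;
#'   `write_seg_config()` the path, invisibly.
#' @export
read_seg_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "), call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- lapply(kv, function(p) {
    v <- trimws(strsplit(p[2], ",", fixed = TRUE)[[1]])
    if (all(v %in% c("TRUE", "FALSE"))) as.logical(v) else as.numeric(v)
  })
  known <- names(formals(seg_config))
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(seg_config, setNames(vals, keys))
}

#' @rdname read_seg_config
#' @export
write_seg_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "seg_config"))
  lines <- vapply(names(cfg), function(nm)
    sprintf("%s = %s", nm, paste(format(cfg[[nm]], scientific = FALSE),
                                 collapse = ", ")), "")
  writeLines(lines, path)
  invisible(path)
}

#' Local Shannon entropy image
#'
#' Entropy in bits of the 256-bin histogram of 8-bit pixel values in a
#' square window centred on each pixel, reflect-padded at the borders.
#' High intensity changes within a limited area — the transition from plant
#' to background, or the fine leaf texture itself — give the plant region a
#' higher entropy than the smoother soil.
#'
#' @param img A single-channel `raster_image` or matrix (values 0-255).
#' @param window Window side in pixels (>= 2).
#' @param stride Stride of the filter; values > 1 compute a decimated grid
#'   and upsample by nearest neighbour.
#' @return A `raster_image` with channel model `FLOAT` (bits).
#' @export
local_entropy <- function(img, window = 100, stride = 1) {
  if (window < 2) stop("entropy window must be >= 2", call. = FALSE)
  x <- if (inherits(img, "raster_image")) img_data(img) else img
  e <- cpp_entropy_filter(x, as.integer(window), as.integer(stride))
  if (stride > 1) {
    ri <- floor((seq_len(nrow(x)) - 1) / stride) + 1
    ci <- floor((seq_len(ncol(x)) - 1) / stride) + 1
    e <- e[ri, ci, drop = FALSE]
  }
  raster_image(e, "FLOAT")
}

#' Prewitt gradient image
#'
#' Horizontal and vertical Prewitt responses combined by the L2 norm
#' (gradient magnitude) or the L1 norm (sum of absolute responses), with
#' reflect padding.
#'
#' @param img A single-channel `raster_image` or matrix.
#' @param norm `"L2"` or `"L1"`.
#' @return A `raster_image` with channel model `FLOAT`.
#' @export
prewitt_gradient <- function(img, norm = c("L2", "L1")) {
  norm <- match.arg(norm)
  x <- if (inherits(img, "raster_image")) img_data(img) else img
  kh <- matrix(c(1, 1, 1, 0, 0, 0, -1, -1, -1), 3, 3)   # columns: 1,0,-1
  gx <- conv2_reflect(x, kh)
  gy <- conv2_reflect(x, t(kh))
  g <- if (norm == "L2") sqrt(gx^2 + gy^2) else abs(gx) + abs(gy)
  raster_image(g, "FLOAT")
}

# S channel (0-255) from an HSV8 image
s_channel <- function(hsv) {
  assert_model(hsv, "HSV8")
  a <- img_data(hsv)
  matrix(a[, , 2], dim(a)[1], dim(a)[2])
}

as_gray <- function(img) {
  if (inherits(img, "raster_image")) {
    if (!channel_model(img) %in% c("GRAY8", "FLOAT"))
      stop("expected a single-channel image", call. = FALSE)
    img_data(img)
  } else img
}

#' Colour-threshold segmentation in HSV (C1)
#'
#' Raw mask: pixels with H, S and V simultaneously inside the configured
#' inclusive windows; then the standard mask clean-up.
#'
#' @param hsv A `raster_image` with channel model `HSV8`.
#' @param cfg A [seg_config()].
#' @return A cleaned 0/1 mask matrix.
#' @export
segment_c1 <- function(hsv, cfg = seg_config()) {
  assert_model(hsv, "HSV8")
  a <- img_data(hsv)
  raw <- (a[, , 1] >= cfg$c1_h[1] & a[, , 1] <= cfg$c1_h[2]) &
         (a[, , 2] >= cfg$c1_s[1] & a[, , 2] <= cfg$c1_s[2]) &
         (a[, , 3] >= cfg$c1_v[1] & a[, , 3] <= cfg$c1_v[2])
  clean_mask(as_mask(raw), cfg$element_radius)
}

#' Blue/green ratio segmentation (C2)
#'
#' In the B/G ratio image the plant appears darker than the soil; the raw
#' mask keeps pixels with ratio strictly below the threshold.
#'
#' @param rgb A `raster_image` with channel model `RGB8`.
#' @inheritParams segment_c1
#' @return A cleaned 0/1 mask matrix.
#' @export
segment_c2 <- function(rgb, cfg = seg_config()) {
  ratio <- img_data(blue_green_ratio(rgb))
  clean_mask(as_mask(ratio < cfg$c2_ratio_max), cfg$element_radius)
}

# Raised-cosine radial low-pass transfer function on the unshifted FFT grid:
# gain 1 at DC, 1/2 at radius R, 0 at and beyond 2R.
raised_cosine_lowpass <- function(nr, nc, radius) {
  fi <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1)
  if (nr == 1) fi <- 0
  fj <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1)
  if (nc == 1) fj <- 0
  r <- sqrt(outer(fi^2, fj^2, `+`))
  h <- 0.5 * (1 + cos(pi * r / (2 * radius)))
  h[r >= 2 * radius] <- 0
  h
}

#' Frequency-domain texture segmentation (T1)
#'
#' Forward 2-D FFT of the saturation channel, radial raised-cosine low-pass
#' (half amplitude at the configured radius, DC preserved at gain 1),
#' inverse FFT; the raw mask keeps pixels whose low-passed intensity
#' exceeds the threshold. The low-pass keeps the rough plant contour while
#' suppressing fine background speckle.
#'
#' @param s A single-channel `raster_image` or matrix (the S channel).
#' @inheritParams segment_c1
#' @return A cleaned 0/1 mask matrix.
#' @export
segment_t1 <- function(s, cfg = seg_config()) {
  x <- as_gray(s)
  h <- raised_cosine_lowpass(nrow(x), ncol(x), cfg$t1_radius)
  lp <- Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / length(x)
  clean_mask(as_mask(lp > cfg$t1_threshold), cfg$element_radius)
}

#' Entropy texture segmentation (T2)
#'
#' Raw mask: pixels whose local entropy ([local_entropy()]) exceeds the
#' configured threshold in bits.
#'
#' @inheritParams segment_t1
#' @return A cleaned 0/1 mask matrix.
#' @export
segment_t2 <- function(s, cfg = seg_config()) {
  e <- img_data(local_entropy(as_gray(s), cfg$t2_window, cfg$t2_stride))
  clean_mask(as_mask(e > cfg$t2_threshold), cfg$element_radius)
}

smooth_for_edges <- function(s, cfg) {
  img_data(gaussian_smooth(as_gray(s), cfg$gauss_size, cfg$gauss_sigma))
}

#' Prewitt gradient-magnitude edge segmentation (E1)
#'
#' Gaussian pre-smoothing, L2 Prewitt gradient magnitude, threshold; the
#' clean-up's dilation and hole filling turn the closed edge ring into a
#' filled object.
#'
#' @inheritParams segment_t1
#' @return A cleaned 0/1 mask matrix.
#' @export
segment_e1 <- function(s, cfg = seg_config()) {
  g <- img_data(prewitt_gradient(smooth_for_edges(s, cfg), "L2"))
  clean_mask(as_mask(g > cfg$e1_threshold), cfg$element_radius)
}

#' High-boost convolution segmentation (E2)
#'
#' Gaussian pre-smoothing, 3 x 3 convolution with all-ones weights except a
#' large centre weight, division by a scale factor, clipping to \[0, 255\],
#' threshold (inclusive, see [seg_config()]).
#'
#' @inheritParams segment_t1
#' @return A cleaned 0/1 mask matrix.
#' @export
segment_e2 <- function(s, cfg = seg_config()) {
  k <- matrix(1, 3, 3); k[2, 2] <- cfg$e2_center
  v <- conv2_reflect(smooth_for_edges(s, cfg), k) / cfg$e2_scale
  v <- pmin(pmax(v, 0), 255)
  clean_mask(as_mask(v >= cfg$e2_threshold), cfg$element_radius)
}

#' Prewitt L1 edge segmentation (E3)
#'
#' Gaussian pre-smoothing, L1 Prewitt gradient (sum of absolute horizontal
#' and vertical responses), threshold.
#'
#' @inheritParams segment_t1
#' @return A cleaned 0/1 mask matrix.
#' @export
segment_e3 <- function(s, cfg = seg_config()) {
  g <- img_data(prewitt_gradient(smooth_for_edges(s, cfg), "L1"))
  clean_mask(as_mask(g > cfg$e3_threshold), cfg$element_radius)
}

#' Refined-edge segmentation (E4)
#'
#' Gaussian pre-smoothing, L2 Prewitt gradient, low threshold, morphological
#' thinning of the edge bands to 1-px-wide curves, binarisation at the
#' configured intensity, then clean-up (which fills the closed thin
#' contours back to a solid object).
#'
#' @inheritParams segment_t1
#' @return A cleaned 0/1 mask matrix.
#' @export
segment_e4 <- function(s, cfg = seg_config()) {
  g <- img_data(prewitt_gradient(smooth_for_edges(s, cfg), "L2"))
  edges <- as_mask(g > cfg$e4_threshold)
  thin <- cpp_thin(edges)
  clean_mask(as_mask(thin >= cfg$e4_binarize), cfg$element_radius)
}

#' Morphologically thin a binary mask to 1-px curves
#'
#' @param mask A 0/1 matrix.
#' @return A 0/1 matrix containing no 2 x 2 all-foreground block.
#' @export
thin_mask <- function(mask) cpp_thin(as_mask(mask))

#' A set of the eight method masks for one image
#'
#' @param masks Named list of eight 0/1 matrices (names C1, C2, T1, T2,
#'   E1-E4), all of one shape.
#' @param image_id Identifier string.
#' @return A `mask_set` object.
#' @export
mask_set <- function(masks, image_id = "image") {
  if (!setequal(names(masks), SEG_METHODS) || length(masks) != 8L)
    stop("a mask_set needs exactly the 8 named method masks", call. = FALSE)
  masks <- masks[SEG_METHODS]
  dims <- vapply(masks, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all masks in a mask_set must share one shape", call. = FALSE)
  masks <- lapply(masks, check_mask)
  structure(list(masks = masks, image_id = image_id), class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  d <- dim(x$masks[[1]])
  cat(sprintf("<mask_set '%s' %d x %d, %d masks>\n",
              x$image_id, d[1], d[2], length(x$masks)))
  invisible(x)
}

#' Run all eight segmentation operators on one image
#'
#' Converts the RGB image to scaled HSV, extracts the saturation channel,
#' and applies C1 (HSV windows), C2 (B/G ratio on RGB), and T1, T2, E1-E4
#' on the S channel. A single operator failure never aborts the image: the
#' failing method's mask is returned empty with a warning.
#'
#' @param rgb A `raster_image` with channel model `RGB8`.
#' @param cfg A [seg_config()].
#' @param image_id Identifier carried into the returned `mask_set`.
#' @return A [mask_set()] of eight cleaned masks.
#' @export
segment_all <- function(rgb, cfg = seg_config(), image_id = "image") {
  assert_model(rgb, "RGB8")
  hsv <- rgb_to_hsv255(rgb)
  s <- s_channel(hsv)
  runners <- list(
    C1 = function() segment_c1(hsv, cfg),
    C2 = function() segment_c2(rgb, cfg),
    T1 = function() segment_t1(s, cfg),
    T2 = function() segment_t2(s, cfg),
    E1 = function() segment_e1(s, cfg),
    E2 = function() segment_e2(s, cfg),
    E3 = function() segment_e3(s, cfg),
    E4 = function() segment_e4(s, cfg)
  )
  empty <- matrix(0L, nrow(s), ncol(s))
  masks <- lapply(names(runners), function(nm) {
    tryCatch(runners[[nm]](), error = function(e) {
      warning(sprintf("method %s failed on '%s' (%s); empty mask used",
                      nm, image_id, conditionMessage(e)), call. = FALSE)
      empty
    })
  })
  mask_set(setNames(masks, names(runners)), image_id)
}
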