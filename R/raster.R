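#' Raster image container
#'
#' A thin container around a pixel grid with a declared channel model.
#' `RGB8` and `HSV8` images are rows x cols x 3 arrays with values in
#' \[0, 255\]; `GRAY8` images are matrices in \[0, 255\]; `FLOAT` images are
#' matrices of finite doubles. Row-major convention: the first array index
#' is the image row (top to bottom), the second the column (left to right).
#'
#' @param pixels A matrix (GRAY8, FLOAT) or rows x cols x 3 array
#'   (RGB8, HSV8).
#' @param channel_model One of `"RGB8"`, `"HSV8"`, `"GRAY8"`, `"FLOAT"`.
#' @return A `raster_image` object.
#' @export
raster_image <- function(pixels, channel_model = c("RGB8", "HSV8", "GRAY8", "FLOAT")) {
  channel_model <- match.arg(channel_model)
  if (channel_model %in% c("RGB8", "HSV8")) {
    if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
      stop("RGB8/HSV8 images need a rows x cols x 3 array", call. = FALSE)
  } else {
    if (!is.matrix(pixels))
      stop("GRAY8/FLOAT images need a matrix", call. = FALSE)
  }
  if (any(!is.finite(pixels)))
    stop("pixel values must be finite", call. = FALSE)
  if (channel_model != "FLOAT" && (min(pixels) < 0 || max(pixels) > 255))
    stop("8-bit channel values must lie in [0, 255]", call. = FALSE)
  structure(pixels, channel_model = channel_model, class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<raster_image %s %d x %d>\n", channel_model(x), d[1], d[2]))
  invisible(x)
}

#' Channel model of a raster image
#' @param img A `raster_image`.
#' @return The channel model string.
#' @export
channel_model <- function(img) {
  attr(img, "channel_model") %||% "FLOAT"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_model <- function(img, model) {
  if (!identical(channel_model(img), model))
    stop(sprintf("expected a %s image, got %s", model, channel_model(img)),
         call. = FALSE)
  invisible(img)
}

img_data <- function(img) {
  attributes(img)[c("channel_model", "class")] <- NULL
  img
}

#' Convert an RGB image to 8-bit-scaled HSV
#'
#' Standard hue/saturation/value conversion with all three channels rescaled
#' to \[0, 255\]: hue in degrees is multiplied by 255/360 and rounded half
#' up, saturation and value fractions are multiplied by 255 and rounded half
#' up. Achromatic pixels (S = 0) get hue 0.
#'
#' @param img A `raster_image` with channel model `RGB8`.
#' @return A `raster_image` with channel model `HSV8`.
#' @export
rgb_to_hsv255 <- function(img) {
  assert_model(img, "RGB8")
  a <- img_data(img)
  hsv01 <- grDevices::rgb2hsv(r = as.vector(a[, , 1]), g = as.vector(a[, , 2]),
                              b = as.vector(a[, , 3]), maxColorValue = 255)
  out <- array(0, dim(a))
  out[, , 1] <- floor(hsv01["h", ] * 255 + 0.5)
  out[, , 2] <- floor(hsv01["s", ] * 255 + 0.5)
  out[, , 3] <- floor(hsv01["v", ] * 255 + 0.5)
  raster_image(out, "HSV8")
}

#' Blue/green ratio image
#'
#' Per-pixel ratio of the blue to the green channel. Plant foliage has a
#' markedly lower B/G ratio than soil. Pixels with G = 0 cannot be foliage
#' and are assigned a large sentinel (1e6) so that any plausible threshold
#' classifies them as background.
#'
#' @param img A `raster_image` with channel model `RGB8`.
#' @return A `raster_image` with channel model `FLOAT`.
#' @export
blue_green_ratio <- function(img) {
  assert_model(img, "RGB8")
  a <- img_data(img)
  g <- matrix(a[, , 2], dim(a)[1], dim(a)[2])
  b <- matrix(a[, , 3], dim(a)[1], dim(a)[2])
  ratio <- ifelse(g == 0, 1e6, b / pmax(g, 1e-12))
  raster_image(ratio, "FLOAT")
}

# Reflect (symmetric, edge included) padding of a matrix by (ri, rj) pixels.
pad_reflect <- function(x, ri, rj = ri) {
  nr <- nrow(x); nc <- ncol(x)
  ridx <- c(rev(seq_len(min(ri, nr))), seq_len(nr),
            nr + 1 - seq_len(min(ri, nr)))
  if (ri > nr) stop("padding wider than image", call. = FALSE)
  cidx <- c(rev(seq_len(min(rj, nc))), seq_len(nc),
            nc + 1 - seq_len(min(rj, nc)))
  x[ridx, cidx, drop = FALSE]
}

# 2-D correlation of a matrix with an odd-sized kernel, reflect padding.
conv2_reflect <- function(x, k) {
  kr <- nrow(k); kc <- ncol(k)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  ri <- (kr - 1) / 2; rj <- (kc - 1) / 2
  p <- pad_reflect(x, ri, rj)
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (a in seq_len(kr)) {
    for (b in seq_len(kc)) {
      if (k[a, b] == 0) next
      out <- out + k[a, b] * p[a:(a + nr - 1), b:(b + nc - 1), drop = FALSE]
    }
  }
  out
}

gaussian_kernel <- function(size, sigma) {
  half <- (size - 1) / 2
  g1 <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

#' Gaussian smoothing
#'
#' Convolution with a normalised 2-D Gaussian kernel, reflect-padded at the
#' borders so that the image mean is preserved. The default 5 x 5 kernel
#' with sigma 1 is the pre-smoothing step shared by the edge operators.
#'
#' @param img A `raster_image` (GRAY8 or FLOAT) or a plain matrix.
#' @param size Odd kernel size >= 3.
#' @param sigma Gaussian standard deviation in pixels.
#' @return A `raster_image` with channel model `FLOAT`.
#' @export
gaussian_smooth <- function(img, size = 5, sigma = 1) {
  if (size %% 2 == 0 || size < 3)
    stop("Gaussian kernel size must be odd and >= 3", call. = FALSE)
  x <- if (inherits(img, "raster_image")) {
    if (!channel_model(img) %in% c("GRAY8", "FLOAT"))
      stop("gaussian_smooth needs a single-channel image", call. = FALSE)
    img_data(img)
  } else img
  raster_image(conv2_reflect(x, gaussian_kernel(size, sigma)), "FLOAT")
}

as_mask <- function(x) {
  m <- matrix(as.integer(x != 0), nrow(x), ncol(x))
  m
}

check_mask <- function(m) {
  if (!is.matrix(m) || !all(m %in% c(0L, 1L)))
    stop("a binary mask must be a 0/1 matrix", call. = FALSE)
  invisible(m)
}

#' Largest connected component of a binary mask
#'
#' Retains the single 8-connected foreground component with the most pixels.
#' Ties are broken by the component whose top-left pixel (smallest row, then
#' smallest column) comes first. An empty mask is returned unchanged.
#'
#' @param mask A 0/1 matrix.
#' @return A 0/1 matrix with at most one connected component.
#' @export
largest_component <- function(mask) {
  mask <- as_mask(mask)
  if (sum(mask) == 0) return(mask)
  lab <- cpp_label8(mask)
  wh <- which(lab > 0)
  labv <- lab[wh]
  sizes <- tabulate(labv)
  cands <- which(sizes == max(sizes))
  if (length(cands) > 1L) {
    nr <- nrow(mask); nc <- ncol(mask)
    rows <- (wh - 1L) %% nr
    cols <- (wh - 1L) %/% nr
    key <- rows * nc + cols            # row-major scan order
    firsts <- vapply(cands, function(l) min(key[labv == l]), numeric(1))
    keep <- cands[which.min(firsts)]
  } else {
    keep <- cands
  }
  matrix(as.integer(lab == keep), nrow(mask), ncol(mask))
}

#' Fill holes in a binary mask
#'
#' Background regions (4-connected) that are not connected to the image
#' border become foreground.
#'
#' @param mask A 0/1 matrix.
#' @return A 0/1 matrix.
#' @export
fill_holes <- function(mask) {
  cpp_fill_holes(as_mask(mask))
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

#' Standard mask clean-up
#'
#' The clean-up sequence applied to every operator's raw mask: dilation with
#' a disc structuring element, hole filling, erosion with the same element,
#' and selection of the largest 8-connected component. An empty raw mask
#' yields an empty clean mask.
#'
#' @param raw A 0/1 matrix (raw mask).
#' @param element_radius Disc radius in pixels (>= 1).
#' @return A cleaned 0/1 matrix with at most one connected component.
#' @export
clean_mask <- function(raw, element_radius = 5) {
  raw <- as_mask(raw)
  if (element_radius < 1) stop("element_radius must be >= 1", call. = FALSE)
  if (sum(raw) == 0) return(raw)
  brush <- disc_brush(element_radius)
  d <- as_mask(EBImage::dilate(raw, brush))
  f <- cpp_fill_holes(d)
  e <- as_mask(EBImage::erode(f, brush))
  largest_component(e)
}

#' Read an 8-bit RGB image
#'
#' Reads a JPG or PNG image into an `RGB8` raster image (values 0-255,
#' row-major). Grayscale files are replicated across the three channels.
#'
#' @param path Path to a JPG or PNG file.
#' @return A `raster_image` with channel model `RGB8`.
#' @export
read_plant_image <- function(path) {
  im <- EBImage::readImage(path)
  a <- EBImage::imageData(im)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]   # drop alpha
  a <- aperm(a, c(2, 1, 3))                           # (x, y, c) -> (row, col, c)
  raster_image(floor(pmin(pmax(a, 0), 1) * 255 + 0.5), "RGB8")
}

#' Write a binary mask as a PNG
#'
#' Foreground is written as white (255), background as black (0).
#'
#' @param mask A 0/1 matrix.
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  EBImage::writeImage(t(as_mask(mask)), path)
  invisible(path)
}

#' Write an RGB raster image as PNG or JPG
#'
#' @param img A `raster_image` with channel model `RGB8`.
#' @param path Output path (`.png` or `.jpg`).
#' @return The path, invisibly.
#' @export
write_rgb_image <- function(img, path) {
  assert_model(img, "RGB8")
  a <- aperm(img_data(img) / 255, c(2, 1, 3))
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}
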