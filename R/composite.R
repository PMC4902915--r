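#' Majority-vote composite mask
#'
#' Counts, per pixel, how many of the eight method masks contain the pixel
#' and keeps pixels reaching at least `min_votes` votes; of the resulting
#' foreground only the largest connected component is retained as the
#' plant. Integer vote counting is used; it is exactly equivalent to the
#' weighted-intensity formulation in which each mask contributes 1/8 of an
#' intensity of 255 and the sum is thresholded at 128, evaluated in exact
#' arithmetic (votes >= 4 iff votes * 255 / 8 >= 127.5, and the first
#' integer intensity at or above that is 128).
#'
#' @param masks A [mask_set()].
#' @param min_votes Votes required for composite membership (1-8);
#'   default 4.
#' @return A `plant_detection` object with elements `vote_image` (integer
#'   matrix 0-8), `composite` (0/1 matrix), `area_px`, `outline` (two-column
#'   matrix of boundary row/col indices), `status` (`"ok"` or `"empty"`)
#'   and `image_id`.
#' @export
composite_vote <- function(masks, min_votes = 4) {
  stopifnot(inherits(masks, "mask_set"))
  if (min_votes < 1 || min_votes > 8)
    stop("min_votes must be in 1..8", call. = FALSE)
  votes <- Reduce(`+`, masks$masks)
  comp <- largest_component(as_mask(votes >= min_votes))
  area <- sum(comp)
  structure(list(vote_image = votes,
                 composite = comp,
                 area_px = area,
                 outline = mask_boundary(comp),
                 status = if (area == 0) "empty" else "ok",
                 image_id = masks$image_id),
            class = "plant_detection")
}

#' @export
print.plant_detection <- function(x, ...) {
  cat(sprintf("<plant_detection '%s': %s, area %d px>\n",
              x$image_id, x$status, x$area_px))
  invisible(x)
}

# Boundary pixels of a mask: foreground pixels with a 4-neighbour outside
# the mask (image border counts as outside). Returns a 2-column matrix of
# (row, col) indices.
mask_boundary <- function(mask) {
  mask <- as_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  interior <- core == 1L &
    pad[1:nr, 2:(nc + 1)] == 1L & pad[3:(nr + 2), 2:(nc + 1)] == 1L &
    pad[2:(nr + 1), 1:nc] == 1L & pad[2:(nr + 1), 3:(nc + 2)] == 1L
  which(core == 1L & !interior, arr.ind = TRUE)
}

#' Superimpose the detection outline on the source image
#'
#' Recolours the boundary pixels of the composite mask (default pure red);
#' every non-boundary pixel is returned unchanged.
#'
#' @param rgb A `raster_image` with channel model `RGB8`.
#' @param det A `plant_detection` from [composite_vote()].
#' @param colour Length-3 RGB vector in 0-255; default `c(255, 0, 0)`.
#' @return A `raster_image` with channel model `RGB8`.
#' @export
overlay_outline <- function(rgb, det, colour = c(255, 0, 0)) {
  assert_model(rgb, "RGB8")
  a <- img_data(rgb)
  if (!identical(dim(a)[1:2], dim(det$composite)))
    stop("image and detection shapes differ", call. = FALSE)
  b <- det$outline
  if (nrow(b) > 0)
    for (ch in 1:3)
      a[cbind(b, ch)] <- colour[ch]
  raster_image(a, "RGB8")
}

#' Intersection over union of two masks
#'
#' @param a,b 0/1 matrices of one shape.
#' @return IoU in \[0, 1\]; 0 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  if (!identical(dim(a), dim(b))) stop("shape mismatch", call. = FALSE)
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Flag implausible detections
#'
#' With a ground-truth mask the detection is `"ok"` iff its
#' intersection-over-union with the truth reaches `iou_min`. Without ground
#' truth a heuristic stands in for the visual inspection of the field
#' protocol: a detection is `"implausible"` if it touches more than
#' `border_frac_max` of the image border or covers more than
#' `frame_frac_max` of the frame. An empty composite is `"empty"`.
#'
#' @param det A `plant_detection`.
#' @param truth Optional 0/1 ground-truth mask.
#' @param iou_min IoU at or above which a detection is correct; default 0.8.
#' @param border_frac_max,frame_frac_max Heuristic plausibility limits;
#'   defaults 0.25 and 0.6.
#' @return The detection with `status` updated, invisibly classed as before.
#' @export
validate_detection <- function(det, truth = NULL, iou_min = 0.8,
                               border_frac_max = 0.25, frame_frac_max = 0.6) {
  stopifnot(inherits(det, "plant_detection"))
  comp <- det$composite
  if (sum(comp) == 0) {
    det$status <- "empty"
    return(det)
  }
  if (!is.null(truth)) {
    det$status <- if (mask_iou(comp, truth) >= iou_min) "ok" else "implausible"
    return(det)
  }
  nr <- nrow(comp); nc <- ncol(comp)
  border <- c(comp[1, ], comp[nr, ], comp[, 1], comp[, nc])
  det$status <- if (mean(border) > border_frac_max ||
                    sum(comp) / (nr * nc) > frame_frac_max)
    "implausible" else "ok"
  det
}

#' @exportS3Method generics::tidy
tidy.plant_detection <- function(x, ...) {
  vh <- tabulate(as.vector(x$vote_image) + 1L, nbins = 9L)
  out <- tibble::tibble(image_id = x$image_id, area_px = x$area_px,
                        status = x$status)
  votes <- tibble::as_tibble(as.list(setNames(vh, paste0("votes_", 0:8))))
  dplyr::bind_cols(out, votes)
}
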