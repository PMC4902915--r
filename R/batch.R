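#' Parse a batch manifest
#'
#' Accepts either a CSV with columns `image_path`, `genotype_id`,
#' `replicate`, `timepoint` (`Y#C#`), `week` (`W0`/`W1`) and optionally
#' `pixels_per_cm`, or a directory of images whose file names follow
#' `<genotype>_<rep>_<Y#C#>_<W#>.(jpg|png)`. Malformed rows (missing file,
#' bad labels) are collected in the `problems` attribute; duplicate
#' (genotype, replicate, timepoint, week) keys keep the first row and flag
#' the rest. Zero valid rows is an error.
#'
#' @param path Manifest CSV path or image directory.
#' @param default_pixels_per_cm Scale used for rows without their own
#'   `pixels_per_cm` column/value.
#' @return A tibble manifest with attribute `problems` (tibble of rejected
#'   rows and reasons).
#' @export
parse_manifest <- function(path, default_pixels_per_cm = 74.36) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(jpe?g|png)$", ignore.case = TRUE,
                        full.names = TRUE)
    files <- files[!grepl("_truth\\.png$", files)]
    pat <- "^(.+)_([0-9]+)_(Y[0-9]+C[0-9]+)_(W[0-9]+)$"
    stem <- sub("\\.[^.]+$", "", basename(files))
    ok <- grepl(pat, stem)
    man <- tibble::tibble(
      image_path = files[ok],
      genotype_id = sub(pat, "\\1", stem[ok]),
      replicate = as.integer(sub(pat, "\\2", stem[ok])),
      timepoint = sub(pat, "\\3", stem[ok]),
      week = sub(pat, "\\4", stem[ok]),
      pixels_per_cm = default_pixels_per_cm)
    problems <- tibble::tibble(row = files[!ok],
                               reason = "file name does not follow <genotype>_<rep>_<Y#C#>_<W#>")
  } else {
    raw <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
    need <- c("image_path", "genotype_id", "replicate", "timepoint", "week")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols))
      stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    if (!"pixels_per_cm" %in% names(raw))
      raw$pixels_per_cm <- default_pixels_per_cm
    raw$pixels_per_cm[is.na(raw$pixels_per_cm)] <- default_pixels_per_cm
    bad <- !file.exists(raw$image_path) |
      !grepl("^Y[0-9]+C[0-9]+$", raw$timepoint) |
      !grepl("^W[0-9]+$", raw$week) |
      is.na(suppressWarnings(as.integer(raw$replicate)))
    problems <- tibble::tibble(row = raw$image_path[bad],
                               reason = "missing file or malformed labels")
    man <- raw[!bad, c(need, "pixels_per_cm")]
    man$replicate <- as.integer(man$replicate)
  }
  key <- paste(man$genotype_id, man$replicate, man$timepoint, man$week)
  dup <- duplicated(key)
  if (any(dup)) {
    problems <- dplyr::bind_rows(problems,
      tibble::tibble(row = man$image_path[dup], reason = "duplicate key"))
    man <- man[!dup, ]
  }
  if (nrow(man) == 0)
    stop("no valid manifest rows", call. = FALSE)
  attr(man, "problems") <- problems
  man
}

#' Run the full pipeline over a batch of images
#'
#' For every manifest row the image is read, segmented by the eight
#' operators, fused into the composite mask and validated by the
#' plausibility heuristic (or against a ground-truth mask when one is
#' supplied). A failure on one image never aborts the batch: the row is
#' recorded with status `"failed"`. Output is deterministic for
#' deterministic input.
#'
#' @param manifest Tibble from [parse_manifest()] (or of the same shape).
#' @param cfg A [seg_config()].
#' @param output_dir Optional directory; when given, per-image composite
#'   masks and outline overlays plus `detections.csv`, `summary.csv` and a
#'   `config.txt` snapshot are written there.
#' @param truths Optional named list of ground-truth 0/1 masks keyed by
#'   image id (file stem), used by the validator instead of the heuristic.
#' @return A `batch_result` list: `detections` (per-image tibble),
#'   `summary` (ok fraction per timepoint and week), `config`.
#' @export
run_batch <- function(manifest, cfg = seg_config(), output_dir = NULL,
                      truths = NULL) {
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_seg_config(cfg, file.path(output_dir, "config.txt"))
  }
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    id <- sub("\\.[^.]+$", "", basename(r$image_path))
    ppcm <- r$pixels_per_cm %||% cfg$pixels_per_cm
    res <- tryCatch({
      img <- read_plant_image(r$image_path)
      ms <- segment_all(img, cfg, image_id = id)
      det <- composite_vote(ms, cfg$min_votes)
      det <- validate_detection(det, truth = truths[[id]],
                                iou_min = cfg$iou_min,
                                border_frac_max = cfg$border_frac_max,
                                frame_frac_max = cfg$frame_frac_max)
      if (!is.null(output_dir)) {
        write_mask_png(det$composite,
                       file.path(output_dir, paste0(id, "_composite.png")))
        write_rgb_image(overlay_outline(img, det),
                        file.path(output_dir, paste0(id, "_overlay.png")))
      }
      dplyr::mutate(tidy(det),
                    area_cm2 = pixels_to_area(.data$area_px, ppcm))
    }, error = function(e) {
      tibble::tibble(image_id = id, area_px = NA_integer_,
                     status = "failed", area_cm2 = NA_real_)
    })
    rows[[i]] <- dplyr::bind_cols(
      r[c("genotype_id", "replicate", "timepoint", "week")], res)
  }
  detections <- dplyr::bind_rows(rows)
  summary <- detections |>
    dplyr::group_by(.data$timepoint, .data$week) |>
    dplyr::summarise(n = dplyr::n(),
                     n_ok = sum(.data$status == "ok"),
                     ok_fraction = mean(.data$status == "ok"),
                     .groups = "drop")
  if (!is.null(output_dir)) {
    utils::write.csv(detections, file.path(output_dir, "detections.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(output_dir, "summary.csv"),
                     row.names = FALSE)
  }
  structure(list(detections = detections, summary = summary, config = cfg),
            class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("<batch_result: %d image(s), %.1f%% ok>\n",
              nrow(x$detections),
              100 * mean(x$detections$status == "ok")))
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.batch_result <- function(x, ...) {
  tibble::tibble(n_images = nrow(x$detections),
                 n_ok = sum(x$detections$status == "ok"),
                 ok_fraction = mean(x$detections$status == "ok"),
                 mean_area_cm2 = mean(x$detections$area_cm2[
                   x$detections$status == "ok"]))
}

#' Detections as plant observations
#'
#' Converts a batch result into the observation table consumed by the
#' trait functions ([regrowth()], [lateral_expansion()]): one row per
#' image with `area_cm2` and `valid = (status == "ok")`.
#'
#' @param batch A `batch_result`.
#' @return A tibble of plant observations.
#' @export
as_observations <- function(batch) {
  stopifnot(inherits(batch, "batch_result"))
  batch$detections |>
    dplyr::transmute(.data$genotype_id, .data$replicate, .data$timepoint,
                     .data$week, .data$area_cm2,
                     valid = .data$status == "ok")
}
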