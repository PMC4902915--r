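#' Parameters of a synthetic top-view field scene
#'
#' Describes a field-like scene: a tuft of thin curved leaves radiating
#' from a crown, rendered over brown soil with multi-octave lightness
#' noise, an optional moisture gradient, algae patches (green hue, fine
#' texture) and small weeds, under a global illumination gain and
#' white-balance shift. Scenes are drawn at a reduced 512 x 512 default
#' frame with the pixel scale reduced proportionally relative to the field
#' protocol, which keeps test suites fast while preserving the geometry of
#' the plant relative to the frame.
#'
#' @param size Frame side in pixels.
#' @param pixels_per_cm Pixel scale; default 28 (so the 512 px frame spans
#'   about 18 cm of soil and a just-cut tuft fills a similar fraction of the
#'   frame as in the field protocol).
#' @param centre Plant centre `(row, col)` in pixels; `NULL` = frame centre
#'   with a small random jitter.
#' @param leaf_count Number of leaves (>= 1).
#' @param leaf_length_cm Mean and sd of leaf length in cm.
#' @param leaf_width_cm Mean and sd of leaf width in cm.
#' @param leaf_curvature Sd of the per-leaf bending angle (radians over the
#'   leaf length).
#' @param crown_radius_cm Radius of the crown disc from which leaves
#'   emerge.
#' @param green_hue Inclusive hue window (0-255 scale) from which leaf hues
#'   are drawn; lies inside the colour-threshold window of the pipeline, as
#'   ryegrass foliage does.
#' @param leaf_saturation,leaf_value Ranges (0-255) for per-leaf saturation
#'   and value.
#' @param brown_sector_fraction Fraction of the tuft (an angular wedge)
#'   recoloured yellow-brown, emulating post-cut discoloured sectors.
#' @param specular_highlight_rate Fraction of leaf pixels turned into
#'   near-white specular spots (waxy-leaf reflections).
#' @param soil_rgb Base soil colour (RGB, 0-255).
#' @param soil_roughness Amplitude of the multiplicative soil lightness
#'   noise.
#' @param moisture_gradient Relative darkening across the frame along a
#'   random direction.
#' @param algae_patch_fraction Fraction of the soil margin covered by green
#'   algae patches.
#' @param weed_count Number of small green weed blobs.
#' @param gain Global illumination gain in \[0.7, 1.3\].
#' @param white_balance Per-channel multiplicative white-balance shift.
#' @param seed Integer seed fixing all randomness of the scene.
#' @return A `scene_params` list.
#' @export
scene_params <- function(size = 512, pixels_per_cm = 28, centre = NULL,
                         leaf_count = 240,
                         leaf_length_cm = c(3.0, 0.5),
                         leaf_width_cm = c(0.5, 0.06),
                         leaf_curvature = 0.35,
                         crown_radius_cm = 2.2,
                         green_hue = c(55, 90),
                         leaf_saturation = c(140, 210),
                         leaf_value = c(120, 200),
                         brown_sector_fraction = 0.1,
                         specular_highlight_rate = 0.01,
                         soil_rgb = c(145, 130, 115),
                         soil_roughness = 0.12,
                         moisture_gradient = 0.12,
                         algae_patch_fraction = 0.03,
                         weed_count = 3,
                         gain = 1.0,
                         white_balance = c(1, 1, 1),
                         seed = 1L) {
  p <- as.list(environment())
  fracs <- c(brown_sector_fraction, specular_highlight_rate,
             algae_patch_fraction)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (leaf_count < 1) stop("leaf_count must be >= 1", call. = FALSE)
  if (gain < 0.5 || gain > 1.5)
    stop("gain outside the supported range", call. = FALSE)
  if (size < 64) stop("frame too small", call. = FALSE)
  structure(p, class = "scene_params")
}

# Independent deterministic sub-streams per scene component, so that the
# truth-only rasterization used by the area solver reproduces the leaf
# geometry without replaying the soil/weed draws.
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 10007) %% 2147483629)
}

# Bilinear upsampling of a coarse matrix to nr x nc.
bilinear_upsample <- function(m, nr, nc) {
  xi <- seq(1, nrow(m), length.out = nr)
  yi <- seq(1, ncol(m), length.out = nc)
  i0 <- pmax(1L, pmin(as.integer(floor(xi)), nrow(m) - 1L)); i1 <- i0 + 1L
  j0 <- pmax(1L, pmin(as.integer(floor(yi)), ncol(m) - 1L)); j1 <- j0 + 1L
  fx <- xi - i0; fy <- yi - j0
  if (nrow(m) == 1) { i0 <- i1 <- rep(1L, nr); fx <- rep(0, nr) }
  if (ncol(m) == 1) { j0 <- j1 <- rep(1L, nc); fy <- rep(0, nc) }
  m[i0, j0] * outer(1 - fx, 1 - fy) + m[i1, j0] * outer(fx, 1 - fy) +
    m[i0, j1] * outer(1 - fx, fy) + m[i1, j1] * outer(fx, fy)
}

# Multi-octave Gaussian noise field, roughly unit variance; consumes RNG.
octave_noise <- function(nr, nc, scales = c(64, 16), weights = c(1, 0.4)) {
  acc <- matrix(0, nr, nc)
  for (k in seq_along(scales)) {
    s <- scales[k]
    coarse <- matrix(rnorm((ceiling(nr / s) + 2) * (ceiling(nc / s) + 2)),
                     ceiling(nr / s) + 2)
    acc <- acc + weights[k] * bilinear_upsample(coarse, nr, nc)
  }
  acc / sqrt(sum(weights^2))
}

scene_centre <- function(p) {
  p$centre %||% withr::with_seed(sub_seed(p$seed, 1),
    c(p$size, p$size) / 2 + runif(2, -0.03, 0.03) * p$size)
}

# Sample the leaf geometry of a tuft. Consumes RNG.
sample_leaf_geometry <- function(p) {
  ppcm <- p$pixels_per_cm
  n <- p$leaf_count
  ang_origin <- runif(n, 0, 2 * pi)
  r_origin <- sqrt(runif(n)) * p$crown_radius_cm * ppcm
  dir <- ang_origin + rnorm(n, 0, 0.35)
  len <- pmax(1, rnorm(n, p$leaf_length_cm[1], p$leaf_length_cm[2])) * ppcm
  wid <- pmax(0.12, rnorm(n, p$leaf_width_cm[1], p$leaf_width_cm[2])) * ppcm
  curv <- rnorm(n, 0, p$leaf_curvature)
  droop <- runif(n, 0.5, 1)          # foreshortening of non-flat leaves
  list(ang_origin = ang_origin, r_origin = r_origin, dir = dir,
       len = len, wid = wid, curv = curv, droop = droop, n = n)
}

# Flattened polyline stamps (per-step centre, radius, arc fraction, leaf
# id) for a tuft; rasterized by cpp_stamp_strokes.
tuft_strokes <- function(geo, centre, length_scale = 1) {
  n <- geo$n
  xs <- ys <- rad <- tt_all <- leaf <- vector("list", n)
  wfac <- min(1, sqrt(length_scale))
  for (k in seq_len(n)) {
    len <- geo$len[k] * length_scale * geo$droop[k]
    w2 <- geo$wid[k] * wfac / 2
    n_steps <- max(3L, ceiling(len / 1.25))
    tt <- seq(0, 1, length.out = n_steps)
    ang <- geo$dir[k] + geo$curv[k] * tt
    ds <- len / (n_steps - 1)
    x0 <- centre[2] + sin(geo$ang_origin[k]) * geo$r_origin[k]
    y0 <- centre[1] + cos(geo$ang_origin[k]) * geo$r_origin[k]
    xs[[k]] <- x0 + c(0, cumsum(sin(ang[-1]) * ds))
    ys[[k]] <- y0 + c(0, cumsum(cos(ang[-1]) * ds))
    rad[[k]] <- pmax(0.7, w2 * (1 - 0.65 * tt))
    tt_all[[k]] <- tt
    leaf[[k]] <- rep(k, n_steps)
  }
  list(x = unlist(xs), y = unlist(ys), r = unlist(rad),
       t = unlist(tt_all), leaf = unlist(leaf))
}

# Rasterize the leaves of a tuft into a leaf-id image and an arc-length
# fraction image (painting order: later leaves overwrite earlier ones).
rasterize_leaves <- function(geo, centre, nr, nc, length_scale = 1) {
  st <- tuft_strokes(geo, centre, length_scale)
  cpp_stamp_strokes(st$x, st$y, st$r, st$t, st$leaf, nr, nc)
}

hsv255_to_rgb <- function(h, s, v) {
  col <- grDevices::hsv(pmin(h, 255) / 255, pmin(s, 255) / 255,
                        pmin(v, 255) / 255)
  grDevices::col2rgb(col)
}

#' Generate a synthetic field scene with ground truth
#'
#' Deterministic given the seed in its parameters: the same parameters give
#' a bit-identical image and mask. The ground-truth mask is the rasterised
#' union of the drawn leaves (including brown-sector leaves); algae patches
#' and weeds are rendered in the image but excluded from the truth.
#' Illumination gain and white balance are applied last and consume no
#' randomness, so re-rendering the same seed under a different gain changes
#' only the illumination, not the scene.
#'
#' @param params A [scene_params()].
#' @param length_scale Internal multiplier on leaf lengths, used by the
#'   growth-series solver to hit a target area; default 1.
#' @return A `synthetic_scene`: `image` (RGB8 `raster_image`), `truth`
#'   (0/1 matrix), `params`, `true_area_cm2`.
#' @export
generate_scene <- function(params = scene_params(), length_scale = 1) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  nr <- nc <- p$size
  centre <- scene_centre(p)

  # --- soil ---------------------------------------------------------------
  withr::with_seed(sub_seed(p$seed, 2), {
    light <- 1 + p$soil_roughness * octave_noise(nr, nc)
    light <- pmin(pmax(light, 0.55), 1.45)
    theta <- runif(1, 0, 2 * pi)
    proj <- outer(seq_len(nr) * cos(theta), seq_len(nc) * sin(theta), `+`)
    proj <- (proj - min(proj)) / max(1e-9, diff(range(proj)))
    shade <- 1 - p$moisture_gradient * proj
    R <- p$soil_rgb[1] * light * shade + rnorm(nr * nc, 0, 2.5)
    G <- p$soil_rgb[2] * light * shade + rnorm(nr * nc, 0, 2.5)
    B <- p$soil_rgb[3] * light * shade + rnorm(nr * nc, 0, 2.5)
  })

  # --- algae patches on the soil margin ------------------------------------
  if (p$algae_patch_fraction > 0) {
    withr::with_seed(sub_seed(p$seed, 3), {
      field <- octave_noise(nr, nc, scales = 48, weights = 1)
      d <- sqrt(outer((seq_len(nr) - centre[1])^2,
                      (seq_len(nc) - centre[2])^2, `+`))
      margin <- d > 0.42 * nr
      thr <- stats::quantile(field[margin],
                             1 - min(1, p$algae_patch_fraction /
                                       max(1e-9, mean(margin))))
      algae <- margin & field > thr
      if (any(algae)) {
        n_a <- sum(algae)
        fine <- rnorm(n_a, 0, 14)                    # fine-scale texture
        acol <- hsv255_to_rgb(72, 120, 120)
        R[algae] <- acol[1] + fine + rnorm(n_a, 0, 4)
        G[algae] <- acol[2] + fine + rnorm(n_a, 0, 4)
        B[algae] <- acol[3] + fine + rnorm(n_a, 0, 4)
      }
    })
  }

  # --- weeds ---------------------------------------------------------------
  if (p$weed_count > 0) {
    withr::with_seed(sub_seed(p$seed, 4), {
      for (w in seq_len(p$weed_count)) {
        ang <- runif(1, 0, 2 * pi)
        dist <- runif(1, 0.35, 0.47) * nr
        wc <- centre + dist * c(cos(ang), sin(ang))
        rad <- runif(1, 3, 7)
        rr <- max(1, round(wc[1] - rad)):min(nr, round(wc[1] + rad))
        cc <- max(1, round(wc[2] - rad)):min(nc, round(wc[2] + rad))
        if (!length(rr) || !length(cc)) next
        hit <- outer((rr - wc[1])^2, (cc - wc[2])^2, `+`) <= rad^2
        wcol <- hsv255_to_rgb(runif(1, 55, 90), 170, 150)
        lin <- (rep(rr, times = length(cc)) +
                  (rep(cc, each = length(rr)) - 1L) * nr)[hit]
        jit <- rnorm(length(lin), 0, 6)
        R[lin] <- wcol[1] + jit; G[lin] <- wcol[2] + jit
        B[lin] <- wcol[3] + jit
      }
    })
  }

  # --- plant ---------------------------------------------------------------
  withr::with_seed(sub_seed(p$seed, 5), {
    geo <- sample_leaf_geometry(p)
    ras <- rasterize_leaves(geo, centre, nr, nc, length_scale)
    wedge_centre <- runif(1, 0, 2 * pi)
    ang_dist <- abs(((geo$dir - wedge_centre + pi) %% (2 * pi)) - pi)
    is_brown <- ang_dist < pi * p$brown_sector_fraction
    hue <- runif(geo$n, p$green_hue[1], p$green_hue[2])
    sat <- runif(geo$n, p$leaf_saturation[1], p$leaf_saturation[2])
    val <- runif(geo$n, p$leaf_value[1], p$leaf_value[2])
    hue[is_brown] <- runif(sum(is_brown), 16, 30)
    sat[is_brown] <- runif(sum(is_brown), 120, 170)
    val[is_brown] <- runif(sum(is_brown), 110, 160)
    cols <- hsv255_to_rgb(hue, sat, val)          # 3 x n_leaves
    idx <- which(ras$id > 0L)
    k <- ras$id[idx]
    shade <- (1 - 0.18 * ras$tfrac[idx]) *
      (1 + rnorm(length(idx), 0, 0.05))           # hue-preserving jitter
    R[idx] <- cols[1, k] * shade
    G[idx] <- cols[2, k] * shade
    B[idx] <- cols[3, k] * shade
  })
  truth <- matrix(0L, nr, nc)
  truth[idx] <- 1L

  # --- specular highlights -------------------------------------------------
  if (p$specular_highlight_rate > 0) {
    withr::with_seed(sub_seed(p$seed, 6), {
      leaf_px <- which(truth == 1L)
      n_spec <- round(p$specular_highlight_rate * length(leaf_px))
      if (n_spec > 0) {
        sp <- sample(leaf_px, n_spec)
        R[sp] <- 250; G[sp] <- 250; B[sp] <- 240
      }
    })
  }

  # --- illumination last ---------------------------------------------------
  img <- array(0, c(nr, nc, 3))
  img[, , 1] <- R * p$gain * p$white_balance[1]
  img[, , 2] <- G * p$gain * p$white_balance[2]
  img[, , 3] <- B * p$gain * p$white_balance[3]
  img <- floor(pmin(pmax(img, 0), 255) + 0.5)

  structure(list(image = raster_image(img, "RGB8"),
                 truth = truth,
                 params = p,
                 true_area_cm2 = sum(truth) / p$pixels_per_cm^2),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene %d x %d, true area %.1f cm2, seed %d>\n",
              nrow(x$truth), ncol(x$truth), x$true_area_cm2, x$params$seed))
  invisible(x)
}

# Truth-only rasterization used by the growth-series area solver; exactly
# the leaf geometry of generate_scene for the same params.
truth_area_px <- function(p, length_scale = 1) {
  centre <- scene_centre(p)
  ras <- withr::with_seed(sub_seed(p$seed, 5), {
    geo <- sample_leaf_geometry(p)
    rasterize_leaves(geo, centre, p$size, p$size, length_scale)
  })
  sum(ras$id > 0L)
}

#' Default first-season cutting schedule
#'
#' Four cuts on a cumulative thermal-time axis with roughly six-week
#' spacing in a temperate growing season, plus the thermal time of each
#' one-week regrowth window.
#'
#' @return A tibble with columns `label`, `gdd`, `gdd_week`.
#' @export
default_cuts <- function() {
  tibble::tibble(label = c("Y1C2", "Y1C3", "Y1C4", "Y1C5"),
                 gdd = c(0, 550, 1150, 1700),
                 gdd_week = c(105, 115, 110, 95))
}

# Solve the leaf length scale that hits a target truth area within 5%:
# bisection on the monotone rendered-area curve, early exit at 4%.
solve_length_scale <- function(sp, target_cm2) {
  target_px <- target_cm2 * sp$pixels_per_cm^2
  lo <- 0.05; hi <- 6
  a_lo <- truth_area_px(sp, lo)
  if (a_lo >= target_px) {
    if ((a_lo - target_px) / target_px <= 0.05) return(lo)
    stop("target area infeasible for this tuft", call. = FALSE)
  }
  if (truth_area_px(sp, hi) < target_px * 0.95)
    stop("target area infeasible for this tuft", call. = FALSE)
  s <- 1
  for (it in 1:14) {
    s <- (lo + hi) / 2
    a <- truth_area_px(sp, s)
    if (abs(a - target_px) / target_px <= 0.04) return(s)
    if (a < target_px) lo <- s else hi <- s
  }
  s
}

#' Generate a synthetic growth time series for one plant
#'
#' Produces, for each cut of the first growing season, a base-area scene
#' (`W0`, taken directly after cutting) and optionally an outgrowth-area
#' scene (`W1`, one week later), together with the table of intended and
#' realised areas. `W0` true areas follow
#' `base_area + slope * gdd + noise` (floored at a minimum plant size);
#' `W1` areas add `regrowth_rate * gdd_week`. Leaf count grows with the
#' target area and leaf lengths are solved by bisection so that each
#' rendered ground-truth area matches its target within 5 percent.
#'
#' @param slope Lateral-expansion slope in cm2 per degree-day.
#' @param regrowth_rate Regrowth in cm2 per degree-day of the regrowth
#'   week.
#' @param noise_sd Standard deviation (cm2) of the Gaussian noise on `W0`
#'   target areas.
#' @param base_area_cm2 Base area at the first cut.
#' @param cuts Data frame with columns `label` (timepoint, e.g. `"Y1C2"`),
#'   `gdd` (cumulative thermal time at the cut, strictly increasing) and
#'   `gdd_week` (thermal time of the regrowth week); see [default_cuts()].
#' @param weeks Which weeks to render; subset of `c("W0", "W1")`.
#' @param scene Template [scene_params()] (seed and leaf count are
#'   overridden per scene).
#' @param genotype_id,replicate Identifiers carried into the observation
#'   table.
#' @param seed Integer seed for the series.
#' @return A list with `scenes` (named `"<label><week>"`) and
#'   `observations` (tibble: identifiers, `gdd`, `gdd_week`,
#'   `target_area_cm2`, `true_area_cm2`, `valid`).
#' @export
generate_growth_series <- function(slope = 0.059, regrowth_rate = 0.15,
                                   noise_sd = 0, base_area_cm2 = 25,
                                   cuts = default_cuts(),
                                   weeks = c("W0", "W1"),
                                   scene = scene_params(),
                                   genotype_id = "G001", replicate = 1L,
                                   seed = 1L) {
  stopifnot(all(weeks %in% c("W0", "W1")))
  if (any(diff(cuts$gdd) <= 0))
    stop("cut thermal times must be strictly increasing", call. = FALSE)
  n_cut <- nrow(cuts)
  withr::with_seed(seed, {
    w0 <- base_area_cm2 + slope * cuts$gdd + rnorm(n_cut, 0, noise_sd)
    w0 <- pmax(w0, 4)                       # minimum plausible plant size
    w1 <- w0 + regrowth_rate * cuts$gdd_week
    scene_seeds <- matrix(sample.int(2147483646L, 2L * n_cut), n_cut, 2)
  })
  max_area <- 0.65 * (scene$size / scene$pixels_per_cm)^2
  targets <- c(if ("W0" %in% weeks) w0, if ("W1" %in% weeks) w1)
  if (any(targets > max_area))
    stop("target area infeasible for the frame size", call. = FALSE)

  scenes <- list()
  obs <- list()
  for (i in seq_len(n_cut)) {
    for (wk in intersect(c("W0", "W1"), weeks)) {
      target <- if (wk == "W0") w0[i] else w1[i]
      sp <- scene
      sp$seed <- scene_seeds[i, match(wk, c("W0", "W1"))]
      sp$leaf_count <- max(10L, as.integer(round(scene$leaf_count *
                                                   target / 25)))
      s <- solve_length_scale(sp, target)
      sc <- generate_scene(sp, length_scale = s)
      id <- paste0(cuts$label[i], wk)
      scenes[[id]] <- sc
      obs[[id]] <- tibble::tibble(
        genotype_id = genotype_id, replicate = replicate,
        timepoint = cuts$label[i], week = wk,
        gdd = cuts$gdd[i], gdd_week = cuts$gdd_week[i],
        target_area_cm2 = target, true_area_cm2 = sc$true_area_cm2,
        valid = TRUE)
    }
  }
  list(scenes = scenes, observations = dplyr::bind_rows(obs))
}

#' Generate a synthetic daily temperature series
#'
#' A seasonal sinusoid of the daily mean temperature over the series, with
#' a fixed diurnal range and Gaussian noise; `tmin <= tmax` is guaranteed.
#'
#' @param n_days Number of days (>= 1).
#' @param start_date First day (Date or string).
#' @param mean_temp Seasonal mean of the daily mean temperature (degrees C).
#' @param amplitude Amplitude of the seasonal sinusoid.
#' @param diurnal_range Mean difference between tmax and tmin.
#' @param noise_sd Sd of the day-to-day noise.
#' @param seed Integer seed.
#' @return A tibble with columns `date`, `tmin`, `tmax`.
#' @export
generate_temperature_series <- function(n_days, start_date = "2010-03-17",
                                        mean_temp = 13, amplitude = 6,
                                        diurnal_range = 8, noise_sd = 1.5,
                                        seed = 1L) {
  if (n_days < 1) stop("n_days must be >= 1", call. = FALSE)
  withr::with_seed(seed, {
    t <- seq_len(n_days)
    tmid <- mean_temp + amplitude * sin(pi * (t - 1) / max(1, n_days - 1)) +
      rnorm(n_days, 0, noise_sd)
    a <- tmid - diurnal_range / 2 + rnorm(n_days, 0, noise_sd / 2)
    b <- tmid + diurnal_range / 2 + rnorm(n_days, 0, noise_sd / 2)
    tibble::tibble(date = as.Date(start_date) + t - 1,
                   tmin = pmin(a, b), tmax = pmax(a, b))
  })
}

#' Write a synthetic scene to disk
#'
#' Writes the image (`<id>.png`), the ground-truth mask (`<id>_truth.png`)
#' and the generator parameters (`<id>_params.txt`, flat key = value).
#'
#' @param scene A `synthetic_scene`.
#' @param dir Output directory (created if needed).
#' @param id File stem.
#' @return A tibble row describing the written image (a manifest fragment).
#' @export
write_scene <- function(scene, dir, id) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(id, ".png"))
  write_rgb_image(scene$image, img_path)
  write_mask_png(scene$truth, file.path(dir, paste0(id, "_truth.png")))
  par_lines <- vapply(names(scene$params), function(nm) {
    v <- scene$params[[nm]]
    sprintf("%s = %s", nm,
            paste(format(v %||% "NULL", scientific = FALSE), collapse = ", "))
  }, "")
  writeLines(par_lines, file.path(dir, paste0(id, "_params.txt")))
  tibble::tibble(image_path = img_path, image_id = id,
                 pixels_per_cm = scene$params$pixels_per_cm,
                 true_area_cm2 = scene$true_area_cm2)
}
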