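#' Convert a pixel count to an area
#'
#' @param count Pixel count(s).
#' @param pixels_per_cm Image scale at the soil surface (> 0).
#' @return Area in cm2: `count / pixels_per_cm^2`.
#' @export
pixels_to_area <- function(count, pixels_per_cm) {
  if (any(pixels_per_cm <= 0))
    stop("pixels_per_cm must be positive", call. = FALSE)
  count / pixels_per_cm^2
}

#' Thermal time from daily minimum / maximum temperatures
#'
#' Accumulates the daily mean temperature `(tmin + tmax) / 2` above the
#' base temperature, clipping negative contributions to zero, over all rows
#' of the temperature table.
#'
#' @param temps Data frame with columns `tmin` and `tmax` (degrees C), one
#'   row per day.
#' @param t_base Base temperature in degrees C; default 0.
#' @return Thermal time in degree-days (°C·day).
#' @export
thermal_time <- function(temps, t_base = 0) {
  sum(daily_gdd(temps, t_base))
}

daily_gdd <- function(temps, t_base = 0) {
  if (is.null(temps) || nrow(temps) == 0)
    stop("temperature table is empty", call. = FALSE)
  if (!all(c("tmin", "tmax") %in% names(temps)))
    stop("temperature table needs tmin and tmax columns", call. = FALSE)
  if (any(temps$tmin > temps$tmax))
    stop("tmin exceeds tmax on some day(s)", call. = FALSE)
  pmax(0, (temps$tmin + temps$tmax) / 2 - t_base)
}

#' Cumulative thermal time per day
#'
#' @inheritParams thermal_time
#' @return The input tibble with added columns `gdd_day` (that day's
#'   contribution) and `gdd_cum` (running total).
#' @export
gdd_cumulative <- function(temps, t_base = 0) {
  g <- daily_gdd(temps, t_base)
  dplyr::mutate(tibble::as_tibble(temps), gdd_day = g, gdd_cum = cumsum(g))
}

# Resolve a timepoint -> value mapping given a scalar, a named vector or a
# two-column data frame.
lookup_by_timepoint <- function(x, timepoints, value_col) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) x <- setNames(x[[value_col]], x$timepoint)
  if (is.null(names(x))) {
    if (length(x) != 1)
      stop("unnamed ", value_col, " must be a single value", call. = FALSE)
    return(rep(unname(x), length(timepoints)))
  }
  out <- unname(x[timepoints])
  if (any(is.na(out)))
    stop("missing ", value_col, " for timepoint(s): ",
         paste(unique(timepoints[is.na(out)]), collapse = ", "),
         call. = FALSE)
  out
}

ensure_valid_col <- function(obs) {
  if (!"valid" %in% names(obs)) obs$valid <- TRUE
  obs
}

#' Regrowth after cutting
#'
#' Pairs, per plant and cut, the base-area observation taken directly after
#' cutting (week `W0`) with the outgrowth-area observation taken one week
#' later (`W1`) and computes regrowth as outgrowth area minus base area.
#' When the thermal time of the regrowth week is supplied, the difference
#' is also expressed per growing degree day. Negative regrowth (cut damage,
#' segmentation noise) is retained but reported via a message. A pair with
#' an invalid member yields an invalid result row.
#'
#' @param obs Tibble of plant observations with columns `genotype_id`,
#'   `replicate`, `timepoint`, `week` (`"W0"`/`"W1"`), `area_cm2` and
#'   optionally `valid` (default `TRUE`).
#' @param gdd_week Thermal time of the regrowth week in degree-days: a
#'   single value, a named vector keyed by timepoint, or a data frame with
#'   columns `timepoint` and `gdd_week`. `NULL` skips the rate.
#' @return A tibble with one row per (genotype, replicate, timepoint):
#'   `w0_cm2`, `w1_cm2`, `regrowth_cm2`, optionally `regrowth_rate`
#'   (cm2 per degree-day), and `valid`.
#' @export
regrowth <- function(obs, gdd_week = NULL) {
  obs <- ensure_valid_col(tibble::as_tibble(obs))
  wide <- obs |>
    dplyr::filter(.data$week %in% c("W0", "W1")) |>
    tidyr::pivot_wider(id_cols = c("genotype_id", "replicate", "timepoint"),
                       names_from = "week",
                       values_from = c("area_cm2", "valid"))
  for (col in c("area_cm2_W0", "area_cm2_W1", "valid_W0", "valid_W1"))
    if (!col %in% names(wide)) wide[[col]] <- NA
  out <- wide |>
    dplyr::mutate(
      valid = !is.na(.data$valid_W0) & !is.na(.data$valid_W1) &
        .data$valid_W0 & .data$valid_W1,
      regrowth_cm2 = ifelse(.data$valid,
                            .data$area_cm2_W1 - .data$area_cm2_W0, NA_real_)
    ) |>
    dplyr::select("genotype_id", "replicate", "timepoint",
                  w0_cm2 = "area_cm2_W0", w1_cm2 = "area_cm2_W1",
                  "regrowth_cm2", "valid")
  if (!is.null(gdd_week)) {
    g <- lookup_by_timepoint(gdd_week, out$timepoint, "gdd_week")
    out$regrowth_rate <- out$regrowth_cm2 / g
  }
  n_neg <- sum(out$regrowth_cm2 < 0, na.rm = TRUE)
  if (n_neg > 0)
    message(n_neg, " plant-cut pair(s) with negative regrowth retained")
  out
}

#' First-year lateral expansion
#'
#' Ordinary least-squares slope of the base area (`W0`) against cumulative
#' thermal time over the season's cuts, fitted per plant (genotype x
#' replicate). Plants with fewer than three valid observations get no
#' estimate (`NA` slope) rather than an error.
#'
#' @param obs Tibble of `W0` observations (`genotype_id`, `replicate`,
#'   `timepoint`, `area_cm2`, optional `valid`).
#' @param gdd Cumulative thermal time at each timepoint: named vector keyed
#'   by timepoint or a data frame with columns `timepoint` and `gdd`.
#' @return A tibble with one row per plant: `genotype_id`, `replicate`,
#'   `n_obs` (valid observations), `slope` (cm2 per degree-day, `NA` when
#'   `n_obs < 3`) and `intercept`.
#' @export
lateral_expansion <- function(obs, gdd) {
  obs <- ensure_valid_col(tibble::as_tibble(obs))
  if ("week" %in% names(obs)) obs <- dplyr::filter(obs, .data$week == "W0")
  obs$gdd <- lookup_by_timepoint(gdd, obs$timepoint, "gdd")
  obs |>
    dplyr::group_by(.data$genotype_id, .data$replicate) |>
    dplyr::group_modify(function(d, key) {
      d <- d[d$valid & !is.na(d$area_cm2), ]
      if (nrow(d) < 3)
        return(tibble::tibble(n_obs = nrow(d), slope = NA_real_,
                              intercept = NA_real_))
      fit <- stats::lm(area_cm2 ~ gdd, data = d)
      tibble::tibble(n_obs = nrow(d),
                     slope = unname(coef(fit)[2]),
                     intercept = unname(coef(fit)[1]))
    }) |>
    dplyr::ungroup()
}

#' Leaf growth per growing degree day
#'
#' @param height_cm Plant height (longest leaf, stretched vertically) two
#'   weeks after the cut, in cm.
#' @param gdd_two_weeks Thermal time of the two-week window in degree-days
#'   (> 0).
#' @return Leaf growth in cm per degree-day.
#' @export
leaf_growth <- function(height_cm, gdd_two_weeks) {
  if (any(gdd_two_weeks <= 0))
    stop("gdd_two_weeks must be positive", call. = FALSE)
  height_cm / gdd_two_weeks
}

#' Genotype means over clonal replicates
#'
#' Averages every numeric trait column over the valid replicates of each
#' genotype (and of any further grouping column supplied, e.g. the
#' timepoint). Invalid rows are dropped before averaging; genotypes (or
#' genotype-group cells) left with no valid replicate are excluded and
#' reported via a message.
#'
#' @param records Tibble with `genotype_id`, optional `valid`, and numeric
#'   trait columns.
#' @param ... Additional grouping columns (tidy-select), e.g. `timepoint`.
#' @return A tibble of per-genotype means with an `n_reps` column.
#' @export
genotype_means <- function(records, ...) {
  records <- ensure_valid_col(tibble::as_tibble(records))
  groups <- dplyr::select(records, "genotype_id", ...)
  all_keys <- dplyr::distinct(groups)
  kept <- records |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(names(all_keys)))) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      dplyr::across(dplyr::where(is.numeric) & !dplyr::any_of("replicate"),
                    ~ mean(.x, na.rm = TRUE)),
      .groups = "drop")
  n_lost <- nrow(all_keys) - nrow(kept)
  if (n_lost > 0)
    message(n_lost, " genotype cell(s) without a valid replicate excluded")
  kept
}

#' Pearson correlation with significance test
#'
#' Product-moment correlation over pairwise-complete observations with the
#' standard two-sided t test.
#'
#' @param x,y Numeric vectors of equal length (typically genotype means).
#' @return A one-row tibble: `r`, `p_value`, `n` (complete pairs).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}

#' Correlation table between two traits, optionally per group
#'
#' Convenience wrapper producing a cut-by-cut correlation layout between an
#' image-derived trait and a manual measurement.
#'
#' @param data A tibble containing the two trait columns.
#' @param x,y Column names (strings) of the two traits.
#' @param by Optional character vector of grouping columns (e.g.
#'   `"timepoint"`).
#' @return A tibble of group keys plus `r`, `p_value`, `n`.
#' @export
correlation_table <- function(data, x, y, by = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(by))
    return(pearson_correlation(data[[x]], data[[y]]))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(~ pearson_correlation(.x[[x]], .x[[y]])) |>
    dplyr::ungroup()
}

#' @importFrom stats complete.cases
NULL
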