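#' Heatmap of the pairwise agreement matrix
#'
#' @param object An `agreement_matrix` from [pairwise_f_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.agreement_matrix <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame.table(object$mean_f * 100,
                                              responseName = "f_pct",
                                              stringsAsFactors = FALSE))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$Var2, y = .data$Var1,
                                   fill = .data$f_pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f", .data$f_pct)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "darkgreen",
                                 limits = c(0, 100), name = "mean F (%)") +
    ggplot2::scale_y_discrete(limits = rev(object$methods)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Pairwise mask agreement (n = %d)",
                                  object$n_images)) +
    ggplot2::theme_minimal()
}

#' Vote image and composite outline of a detection
#'
#' @param object A `plant_detection` from [composite_vote()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.plant_detection <- function(object, ...) {
  v <- object$vote_image
  df <- tibble::tibble(row = rep(seq_len(nrow(v)), times = ncol(v)),
                       col = rep(seq_len(ncol(v)), each = nrow(v)),
                       votes = as.vector(v))
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$votes)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 8), name = "votes") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("'%s': %s, %d px", object$image_id,
                                  object$status, object$area_px),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (nrow(object$outline) > 0) {
    odf <- tibble::tibble(row = object$outline[, 1],
                          col = object$outline[, 2])
    g <- g + ggplot2::geom_point(data = odf,
                                 ggplot2::aes(x = .data$col, y = .data$row),
                                 inherit.aes = FALSE,
                                 colour = "red", size = 0.1)
  }
  g
}

#' Fraction of correctly analysed images per timepoint
#'
#' @param object A `batch_result` from [run_batch()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.batch_result <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$timepoint, y = 100 * .data$ok_fraction,
                               fill = .data$week)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_grey(start = 0.2, end = 0.6) +
    ggplot2::labs(x = "time point", y = "correctly analysed (%)") +
    ggplot2::theme_minimal()
}

#' Per-method precision / recall / F bars
#'
#' @param scores A tibble from [methods_vs_reference()].
#' @return A ggplot object.
#' @export
plot_method_scores <- function(scores) {
  long <- scores |>
    tidyr::pivot_longer(dplyr::ends_with("_mean"),
                        names_to = "metric", values_to = "mean") |>
    dplyr::mutate(metric = sub("_mean$", "", .data$metric))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = 100 * .data$mean,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(x = NULL, y = "%", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Render a synthetic scene (image or truth) for inspection
#'
#' @param object A `synthetic_scene`.
#' @param what `"image"` or `"truth"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.synthetic_scene <- function(object, what = c("image", "truth"), ...) {
  what <- match.arg(what)
  if (what == "truth") {
    m <- object$truth
    df <- tibble::tibble(row = rep(seq_len(nrow(m)), times = ncol(m)),
                         col = rep(seq_len(ncol(m)), each = nrow(m)),
                         v = as.vector(m))
    return(ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                            fill = factor(.data$v))) +
             ggplot2::geom_raster() +
             ggplot2::scale_fill_manual(values = c("black", "white"),
                                        guide = "none") +
             ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
             ggplot2::theme_void())
  }
  a <- img_data(object$image) / 255
  df <- tibble::tibble(row = rep(seq_len(nrow(a)), times = ncol(a)),
                       col = rep(seq_len(ncol(a)), each = nrow(a)),
                       hex = grDevices::rgb(as.vector(a[, , 1]),
                                            as.vector(a[, , 2]),
                                            as.vector(a[, , 3])))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$hex)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
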