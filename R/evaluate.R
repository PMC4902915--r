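#' Precision, recall and F of a mask against a reference
#'
#' Precision is the fraction of predicted-mask pixels that belong to the
#' reference object; recall is the fraction of reference pixels captured by
#' the prediction; F is their harmonic mean `2PR/(P+R)`. Degenerate cases
#' score 0: an empty prediction has P = 0, an empty reference has R = 0,
#' and F is 0 whenever P + R = 0.
#'
#' @param pred,truth 0/1 matrices of one shape.
#' @return A one-row tibble with columns `precision`, `recall`, `f_value`.
#' @export
precision_recall_f <- function(pred, truth) {
  pred <- as_mask(pred); truth <- as_mask(truth)
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and reference shapes differ", call. = FALSE)
  tp <- sum(pred & truth)
  p <- if (sum(pred) == 0) 0 else tp / sum(pred)
  r <- if (sum(truth) == 0) 0 else tp / sum(truth)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  tibble::tibble(precision = p, recall = r, f_value = f)
}

#' Pairwise mean-F agreement matrix of the eight methods
#'
#' For every unordered pair of methods, the F value of one method's mask
#' scored against the other's is computed per image and averaged over
#' images — 28 informative comparisons (8 x 7 / 2) per image. F is
#' invariant to which mask of the pair is treated as the reference (P and R
#' swap roles), so the matrix is symmetric by construction; the diagonal is
#' 1 by convention.
#'
#' @param sets A list of [mask_set()] objects.
#' @return An `agreement_matrix` object: `methods` (the 8 names), `mean_f`
#'   (8 x 8 symmetric matrix), `n_images`.
#' @export
pairwise_f_matrix <- function(sets) {
  if (length(sets) == 0) stop("need at least one mask_set", call. = FALSE)
  stopifnot(all(vapply(sets, inherits, TRUE, "mask_set")))
  m <- length(SEG_METHODS)
  acc <- matrix(0, m, m, dimnames = list(SEG_METHODS, SEG_METHODS))
  for (ms in sets) {
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        f <- precision_recall_f(ms$masks[[SEG_METHODS[i]]],
                                ms$masks[[SEG_METHODS[j]]])$f_value
        acc[i, j] <- acc[i, j] + f
      }
    }
  }
  mean_f <- acc / length(sets)
  mean_f <- mean_f + t(mean_f)
  diag(mean_f) <- 1
  structure(list(methods = SEG_METHODS, mean_f = mean_f,
                 n_images = length(sets)),
            class = "agreement_matrix")
}

#' @export
print.agreement_matrix <- function(x, ...) {
  cat(sprintf("<agreement_matrix over %d image(s); mean F (%%)>\n",
              x$n_images))
  print(round(x$mean_f * 100, 1))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.agreement_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$mean_f,
                                        responseName = "mean_f",
                                        stringsAsFactors = FALSE)) |>
    dplyr::rename(method_a = "Var1", method_b = "Var2") |>
    dplyr::filter(.data$method_a < .data$method_b) |>
    dplyr::mutate(n_images = x$n_images)
}

#' @exportS3Method generics::glance
glance.agreement_matrix <- function(x, ...) {
  up <- x$mean_f[upper.tri(x$mean_f)]
  tibble::tibble(n_images = x$n_images, n_pairs = length(up),
                 min_f = min(up), mean_f = mean(up), max_f = max(up))
}

#' Score the eight methods against per-image reference masks
#'
#' Computes P, R and F of every method's mask against the image's reference
#' mask (typically the composite mask of a correctly analysed image) and
#' aggregates per method: mean and standard error of the mean over scored
#' images, optionally stratified by a per-image label (for example the W0 /
#' W1 week). Images whose reference mask is empty are never scored; images
#' where a method scores 0 against a non-empty reference are counted unless
#' `cfg$score_empty_as_zero` is `FALSE`, in which case empty-prediction
#' images are dropped for that method.
#'
#' @param sets List of [mask_set()] objects.
#' @param refs List of 0/1 reference masks, aligned with `sets`.
#' @param strata Optional character vector of per-image labels, aligned
#'   with `sets`.
#' @param cfg A [seg_config()] (controls the empty-mask convention).
#' @return A tibble with columns `method`, `stratum`, `n`, and mean / se of
#'   `precision`, `recall`, `f_value`.
#' @export
methods_vs_reference <- function(sets, refs, strata = NULL,
                                 cfg = seg_config()) {
  if (length(sets) != length(refs))
    stop("sets and refs must have equal length", call. = FALSE)
  if (!is.null(strata) && length(strata) != length(sets))
    stop("strata must align with sets", call. = FALSE)
  if (is.null(strata)) strata <- rep("all", length(sets))
  rows <- purrr::imap(sets, function(ms, i) {
    ref <- refs[[i]]
    if (sum(as_mask(ref)) == 0) return(NULL)
    purrr::map(SEG_METHODS, function(nm) {
      pred <- ms$masks[[nm]]
      if (!cfg$score_empty_as_zero && sum(pred) == 0) return(NULL)
      dplyr::mutate(precision_recall_f(pred, ref),
                    method = nm, stratum = strata[[i]])
    }) |> purrr::compact() |> dplyr::bind_rows()
  }) |> purrr::compact() |> dplyr::bind_rows()
  if (nrow(rows) == 0)
    stop("no image with a non-empty reference mask", call. = FALSE)
  se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  rows |>
    tidyr::pivot_longer(c("precision", "recall", "f_value"),
                        names_to = "metric") |>
    dplyr::group_by(.data$method, .data$stratum, .data$metric) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     se = se(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "metric",
                       values_from = c("mean", "se"),
                       names_glue = "{metric}_{.value}") |>
    dplyr::arrange(match(.data$method, SEG_METHODS), .data$stratum)
}
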