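#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an error matrix into one row per cell
#'
#' @param x An [error_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `reference`, `mapped`, `n`.
#' @method tidy error_matrix
#' @export
tidy.error_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame(as.table(x$counts), responseName = "n")) |>
    dplyr::mutate(dplyr::across(c("reference", "mapped"), as.character))
}

#' One-row accuracy summary of an error matrix
#'
#' @param x An [error_matrix()].
#' @param ... Unused.
#' @return A one-row tibble: `oa`, `pa_lodged`, `pa_nonlodged`, `ua_lodged`,
#'   `ua_nonlodged`, `n`, `excluded` (percentages, 2 decimals).
#' @method glance error_matrix
#' @export
glance.error_matrix <- function(x, ...) {
  tibble::tibble(
    oa = x$oa, pa_lodged = x$pa[["lodged"]], pa_nonlodged = x$pa[["non-lodged"]],
    ua_lodged = x$ua[["lodged"]], ua_nonlodged = x$ua[["non-lodged"]],
    n = sum(x$counts), excluded = x$excluded
  )
}

#' Tidy a lodging result into its area accounting
#'
#' @param x A `lodging_result`.
#' @param ... Unused.
#' @return The `area_report` tibble with the threshold attached.
#' @method tidy lodging_result
#' @export
tidy.lodging_result <- function(x, ...) {
  dplyr::mutate(x$areas, threshold = x$threshold, .before = 1)
}

#' One-row summary of a lodging result
#'
#' @param x A `lodging_result`.
#' @param ... Unused.
#' @return A one-row tibble: `threshold`, `lodged_kha`, `maize_kha`,
#'   `lodged_pct`.
#' @method glance lodging_result
#' @export
glance.lodging_result <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, lodged_kha = x$areas$lodged_kha,
                 maize_kha = x$areas$maize_kha, lodged_pct = x$areas$lodged_pct)
}

#' Tidy a validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return A long tibble with columns `check`, `metric`, `value` covering
#'   whichever of the three validation methods ran.
#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) {
  rows <- list()
  if (!is.null(x$error_matrix)) {
    g <- glance(x$error_matrix)
    rows$em <- tibble::tibble(check = "error_matrix",
                              metric = names(g), value = as.character(unlist(g)))
  }
  if (!is.null(x$cross_comparison)) {
    cc <- x$cross_comparison
    rows$cc <- tibble::tibble(
      check = "cross_comparison",
      metric = c("s_coarse_kha", "s_fine_kha", "d_pct"),
      value = as.character(c(cc$s_coarse, cc$s_fine, cc$d_pct)))
  }
  if (!is.null(x$survey)) {
    sv <- x$survey
    rows$sv <- tibble::tibble(
      check = "survey",
      metric = c("modal_grade", "mapped_grade", "agreement"),
      value = c(sv$modal_grade, sv$mapped_grade, as.character(sv$agreement)))
  }
  dplyr::bind_rows(rows)
}

grid_tibble <- function(values, cell_size, origin) {
  d <- dim(values)
  idx <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  tibble::tibble(
    x = origin[1] + (idx$col - 0.5) * cell_size,
    y = origin[2] - (idx$row - 0.5) * cell_size,
    value = as.vector(values)
  )
}

#' Plot an index map
#'
#' @param object An `index_map`.
#' @param ... Unused.
#' @return A ggplot raster of the index values (nodata blank).
#' @method autoplot index_map
#' @export
autoplot.index_map <- function(object, ...) {
  df <- grid_tibble(object$values, object$cell_size, object$origin)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$index_name, na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)") +
    ggplot2::theme_minimal()
}

#' Plot a lodging map
#'
#' @param object A `lodging_map`.
#' @param ... Unused.
#' @return A ggplot raster of the three states.
#' @method autoplot lodging_map
#' @export
autoplot.lodging_map <- function(object, ...) {
  df <- grid_tibble(object$states, object$cell_size, object$origin)
  df$state <- factor(c("non-maize / nodata", "non-lodged maize", "lodged maize")[df$value + 1],
                     levels = c("lodged maize", "non-lodged maize", "non-maize / nodata"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$state)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c("lodged maize" = "#d95f02",
                                          "non-lodged maize" = "#1b9e77",
                                          "non-maize / nodata" = "grey85"),
                               name = NULL) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)") +
    ggplot2::theme_minimal()
}

#' Box plot of index values per class at sample points
#'
#' The visual behind threshold selection: the lodged and non-lodged SSI
#' distributions with an optional horizontal line at the threshold.
#'
#' @param index An `index_map`.
#' @param points A `sample_points` tibble.
#' @param threshold Optional threshold to draw.
#' @return A ggplot box plot.
#' @export
plot_index_distribution <- function(index, points, threshold = NULL) {
  df <- tibble::tibble(label = points$label,
                       value = index_values_at(index, points))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$value,
                                        fill = .data$label)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = index$index_name) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                                 colour = "blue")
  }
  p
}

#' @importFrom rlang .data
NULL
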