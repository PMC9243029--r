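#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line labs
#'   scale_colour_viridis_c theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot an embedded pipeline space
#'
#' @param object An `embedded_space`.
#' @param colour Optional vector (length P) to colour pipelines by, e.g. a
#'   factor level or a landscape score.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot embedded_space
#' @export
autoplot.embedded_space <- function(object, colour = NULL, ...) {
  df <- as_tibble(object)
  p <- if (is.null(colour)) {
    ggplot(df, aes(x = .data$dim1, y = .data$dim2))
  } else {
    df$colour <- colour
    ggplot(df, aes(x = .data$dim1, y = .data$dim2, colour = .data$colour))
  }
  p + geom_point(size = 1.6) + theme_minimal() +
    labs(x = "dimension 1", y = "dimension 2",
         title = sprintf("Pipeline space (%s)", attr(object, "method")))
}

#' Plot the evolution of a search trace
#'
#' Scores per iteration, with the burn-in phase distinguished and the running
#' best overlaid.
#' @param object A `search_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot search_trace
#' @export
autoplot.search_trace <- function(object, ...) {
  df <- object$trace
  df$best <- cummax(df$score)
  ggplot(df, aes(x = .data$iteration, y = .data$score)) +
    geom_point(aes(colour = .data$phase), size = 1.8) +
    geom_line(aes(y = .data$best), linetype = "dashed", colour = "grey40") +
    theme_minimal() +
    labs(y = sprintf("score (%s)", object$config$objective),
         title = sprintf("Active search, kappa = %g", object$config$kappa))
}

#' Plot an estimated or empirical performance landscape over the space
#'
#' @param space An `embedded_space`.
#' @param landscape A `landscape_estimate` (plots `mu`) or
#'   `empirical_landscape` (plots `score`).
#' @param what For estimates, `"mu"` or `"sigma"`.
#' @return A ggplot.
#' @export
plot_landscape <- function(space, landscape, what = c("mu", "sigma")) {
  what <- match.arg(what)
  df <- dplyr::left_join(as_tibble(space), as_tibble(landscape),
                         by = "pipeline_id")
  value <- if ("score" %in% names(df)) df$score else df[[what]]
  df$value <- value
  ggplot(df, aes(x = .data$dim1, y = .data$dim2, colour = .data$value)) +
    geom_point(size = 2) + scale_colour_viridis_c() + theme_minimal() +
    labs(colour = if ("score" %in% names(df)) "empirical score" else what,
         x = "dimension 1", y = "dimension 2")
}

#' @importFrom rlang .data
NULL
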