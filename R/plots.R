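#' Plot the retention profile of a stringency cascade
#'
#' Phylotype and read retention (percent of the baseline) across the filter
#' levels, the at-a-glance view of how much diversity each stringency step
#' costs against how little read mass it removes.
#'
#' @param object A [filter_cascade()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.filter_report <- function(object, ...) {
  df <- object$report |>
    tidyr::pivot_longer(c("pct_phylotypes", "pct_reads"),
                        names_to = "quantity", values_to = "pct") |>
    dplyr::mutate(
      level = factor(.data$level, levels = object$report$level),
      quantity = dplyr::recode(.data$quantity,
                               pct_phylotypes = "phylotypes",
                               pct_reads = "reads")
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$pct,
                                   group = .data$quantity,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "stringency level", y = "% retained vs baseline",
                  colour = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot Venn region sizes
#'
#' Bar chart of the disjoint region cardinalities of a [venn_partition()],
#' ordered by how many sets each region spans.
#'
#' @param object A [venn_partition()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.venn_partition <- function(object, ...) {
  df <- tibble::tibble(region = object$region, size = object$size,
                       span = lengths(object$sets))
  df$region <- factor(df$region, levels = df$region[order(df$span, df$region)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$size)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "phylotypes") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Plot a superkingdom profile
#'
#' @param profile A tibble from [superkingdom_profile()].
#' @return A ggplot bar chart of percentages per superkingdom.
#' @export
plot_superkingdom_profile <- function(profile) {
  profile$superkingdom <- factor(profile$superkingdom,
                                 levels = rev(profile$superkingdom))
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$superkingdom, y = .data$pct)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of annotated queries") +
    ggplot2::theme_minimal()
}
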