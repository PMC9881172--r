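# ggplot2 display methods for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_step scale_x_log10 scale_y_log10 labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Rank-abundance plot of a tallied pool
#'
#' @param object A `tallied_pool`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tallied_pool <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$rank, y = .data$percent)) +
    geom_step() +
    scale_x_log10() +
    scale_y_log10() +
    labs(x = "rank", y = "% of pool",
         title = attr(object, "generation_label")) +
    theme_minimal()
}

#' Class-abundance trajectories across selection generations
#'
#' @param object A `generation_track` from [track_classes()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.generation_track <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$generation, y = .data$percent,
             colour = .data$class, group = .data$class)) +
    geom_line() +
    geom_point() +
    labs(x = "generation", y = "% of pool", colour = "class") +
    theme_minimal()
}

#' Elution-profile bar plot
#'
#' @param object An `elution_summary` from [summarize_elution()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.elution_summary <- function(object, ...) {
  df <- as_tibble(object)
  df$label <- factor(df$label, levels = df$label)
  ggplot(df, aes(x = .data$label, y = .data$percent,
                 fill = .data$is_compound)) +
    geom_col(show.legend = FALSE) +
    labs(x = NULL, y = "% of total signal") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Titration points and fitted binding isotherm
#'
#' @param object A `binding_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.binding_fit <- function(object, ...) {
  df <- object$data
  nz <- df$concentration_M[df$concentration_M > 0]
  grid <- 10^seq(log10(min(nz)) - 0.5, log10(max(nz)) + 0.5,
                 length.out = 200)
  curve <- tibble(
    concentration_M = grid,
    fraction_modulated = object$f0 +
      object$amplitude * grid^object$hill /
      (object$kd^object$hill + grid^object$hill)
  )
  ggplot(df, aes(x = .data$concentration_M, y = .data$fraction_modulated)) +
    geom_point(aes(shape = .data$site_id)) +
    geom_line(data = curve) +
    scale_x_log10() +
    labs(x = "ligand concentration (M)", y = "fraction modulated",
         shape = "site",
         title = sprintf("Kd = %.3g ± %.3g M", object$kd, object$kd_se)) +
    theme_minimal()
}
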