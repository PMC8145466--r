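#' Plot median and IQR of the probability of adequacy
#'
#' Pointrange of per-nutrient PA (median, quartiles) by age bin, faceted by
#' nutrient, coloured by site. A group collapsing to a single filled point at
#' 0 or 1 means every child shared that PA.
#'
#' @param pa_summary tibble from [summarize_pa()].
#' @return a ggplot object.
#' @export
plot_pa <- function(pa_summary) {
  df <- dplyr::filter(pa_summary, is.na(.data$zinc_class))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$age_bin, y = .data$median,
    ymin = .data$q1, ymax = .data$q3, colour = .data$site_code
  )) +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(width = 0.5), size = 0.3) +
    ggplot2::facet_wrap(~nutrient) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "age period (months)", y = "probability of adequacy",
      colour = "site"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the distribution of mean probability of adequacy
#'
#' @param adequacy tibble from [compute_adequacy()].
#' @return a ggplot object.
#' @export
plot_mpa <- function(adequacy) {
  ggplot2::ggplot(adequacy, ggplot2::aes(
    x = .data$age_bin, y = .data$mpa, fill = .data$site_code
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "age period (months)", y = "mean probability of adequacy", fill = "site") +
    ggplot2::theme_minimal()
}

#' Plot complementary-food nutrient densities per 100 kcal
#'
#' @param adequacy tibble from [compute_adequacy()].
#' @param nutrients nutrients to show.
#' @return a ggplot object.
#' @export
plot_nutrient_density <- function(adequacy, nutrients = micronutrients()) {
  df <- adequacy |>
    select("child_id", "site_code", "age_bin", all_of(paste0("density_", nutrients))) |>
    tidyr::pivot_longer(
      starts_with("density_"),
      names_to = "nutrient", names_prefix = "density_", values_to = "density"
    ) |>
    group_by(.data$site_code, .data$age_bin, .data$nutrient) |>
    summarise(mean_density = mean(.data$density, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$age_bin, y = .data$mean_density,
    colour = .data$site_code, group = .data$site_code
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~nutrient, scales = "free_y") +
    ggplot2::labs(
      x = "age period (months)", y = "mean density per 100 kcal", colour = "site"
    ) +
    ggplot2::theme_minimal()
}
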