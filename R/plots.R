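# ggplot2 views of the study results

#' Plot species trajectories
#'
#' Concentration and collagen-density trajectories of a species study,
#' one panel per quantity, colored by the damage value.
#'
#' @param df Data frame from [run_species_study()].
#' @param quantities Columns to show.
#' @return A ggplot object.
#' @export
plot_species_study <- function(df, quantities = c("M", "G", "rho_c")) {
  long <- do.call(rbind, lapply(quantities, function(q)
    data.frame(t_days = df$t / SECONDS_PER_DAY, d = factor(df$d),
               quantity = q, value = df[[q]])))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_days, y = .data$value,
                                     color = .data$d)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time [days]", y = NULL, color = "damage d")
}

#' Plot a biaxial report
#'
#' Damage-phase stress-stretch response and healing-phase thickness,
#' elastic collagen stretch and fiber stress over time.
#'
#' @param report A [run_biaxial()] report.
#' @param which `"damage"` or `"healing"`.
#' @return A ggplot object.
#' @export
plot_biaxial <- function(report, which = c("healing", "damage")) {
  which <- match.arg(which)
  h <- report$history
  if (which == "damage") {
    hd <- h[h$t >= report$schedule$t0 & h$t <= report$schedule$t_star, ]
    return(ggplot2::ggplot(hd, ggplot2::aes(x = .data$lambda_x,
                                            y = .data$sigma_xx / 1e3)) +
             ggplot2::geom_path() +
             ggplot2::labs(x = "tissue stretch in x",
                           y = "Cauchy stress [kPa]"))
  }
  hh <- h[h$t >= report$schedule$t_star, ]
  hh$t_days <- (hh$t - report$schedule$t_star) / SECONDS_PER_DAY
  long <- rbind(
    data.frame(t_days = hh$t_days, quantity = "thickness change [%]",
               value = 100 * (hh$thickness / report$thickness_star - 1)),
    data.frame(t_days = hh$t_days, quantity = "elastic collagen stretch",
               value = hh$lambda_e),
    data.frame(t_days = hh$t_days, quantity = "fiber Cauchy stress [kPa]",
               value = hh$sigma_xx / 1e3))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_days, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "healing time [days]", y = NULL)
}

#' Plot indentation probe strains
#'
#' Nominal strains at the three probe points during healing, referenced to
#' the end-of-damage configuration.
#'
#' @param report A [run_indentation()] report.
#' @return A ggplot object.
#' @export
plot_indentation_strains <- function(report) {
  h <- report$history
  h$t_days <- (h$t - report$schedule$t_star) / SECONDS_PER_DAY
  long <- rbind(
    data.frame(t_days = h$t_days, probe = "A (x)",
               value = h$strain_A_x_pct),
    data.frame(t_days = h$t_days, probe = "B (y)",
               value = h$strain_B_y_pct),
    data.frame(t_days = h$t_days, probe = "C (z)",
               value = h$strain_C_z_pct))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_days, y = .data$value,
                                     color = .data$probe)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "healing time [days]", y = "nominal strain [%]",
                  color = "probe")
}
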