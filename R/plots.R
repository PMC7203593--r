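#' Plot a fitted ligament force-strain curve with its calibration points
#'
#' @param object a `"ligament_fit"`.
#' @param points optional tibble (`strain_pct`, `force_n`) of calibration
#'   points to overlay.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ligament_fit <- function(object, points = NULL, ...) {
  rng <- if (!is.null(points)) range(points$strain_pct) else c(-5, 30)
  grid <- tibble::tibble(strain_pct = seq(rng[1] - 2, rng[2] + 2,
                                          length.out = 200))
  grid$force_n <- ligament_spring_force(object$char, grid$strain_pct)
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$strain_pct, .data$force_n)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "strain (%)", y = "force (N)") +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(data = points, colour = "firebrick")
  }
  p
}

#' Plot a fitted disk torque-angle curve
#'
#' @param object a `"disk_fit"`.
#' @param points optional tibble (`phi_rad`, `torque_nm`) to overlay.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.disk_fit <- function(object, points = NULL, ...) {
  rng <- if (!is.null(points)) range(points$phi_rad) else c(0, 0.35)
  grid <- tibble::tibble(phi_deg = seq(0, max(rng) * 180 / pi * 1.1,
                                       length.out = 200))
  phi <- grid$phi_deg * pi / 180
  grid$torque_nm <- tanh_cubic(phi, object$p1, object$p2, object$p3)
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$phi_deg, .data$torque_nm)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "rotation (deg)", y = "torque (Nm)",
                  title = object$direction) +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    pts <- dplyr::mutate(points, phi_deg = .data$phi_rad * 180 / pi)
    p <- p + ggplot2::geom_point(data = pts,
                                 ggplot2::aes(.data$phi_deg,
                                              .data$torque_nm),
                                 colour = "firebrick")
  }
  p
}

#' Plot all calibrated ligament curves of a model
#'
#' Facetted softplus curves with the extracted deficit-torque points, the
#' calibration analogue of the classic per-ligament characteristic panels.
#'
#' @param object a `"calibrated_model"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.calibrated_model <- function(object, ...) {
  curves <- list()
  pts <- list()
  for (nm in names(object$diagnostics$ligaments)) {
    ex <- object$diagnostics$ligaments[[nm]]
    if (is.null(ex$fit)) next
    rng <- range(ex$points$strain_pct)
    g <- tibble::tibble(
      ligament = nm,
      strain_pct = seq(rng[1] - 1, rng[2] + 1, length.out = 120))
    g$force_n <- ligament_spring_force(ex$fit$char, g$strain_pct)
    curves[[nm]] <- g
    pts[[nm]] <- dplyr::mutate(ex$points, ligament = nm)
  }
  ggplot2::ggplot(dplyr::bind_rows(curves),
                  ggplot2::aes(.data$strain_pct, .data$force_n)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dplyr::bind_rows(pts), colour = "firebrick",
                        size = 0.9) +
    ggplot2::facet_wrap(~ligament, scales = "free") +
    ggplot2::labs(x = "strain (%)", y = "force (N)") +
    ggplot2::theme_minimal()
}

#' Compare a ROM table with model output
#'
#' Bar chart of the experimental mean ROM with min-to-max error bars,
#' overlaid with the model's values as points, facetted by direction; the
#' layout mirrors the standard presentation of stepwise-reduction results.
#'
#' @param reference ROM table ([simulate_eds1()] layout).
#' @param model_values tibble with `stage`, `direction`, `torque_nm`,
#'   `rom_deg`.
#' @return A ggplot object.
#' @export
plot_rom_comparison <- function(reference, model_values) {
  ref <- dplyr::filter(reference, .data$torque_nm > 0)
  mv <- dplyr::filter(model_values, .data$torque_nm > 0)
  ref$stage <- factor(ref$stage, levels = rom_stages())
  mv$stage <- factor(mv$stage, levels = rom_stages())
  ggplot2::ggplot(ref, ggplot2::aes(x = factor(.data$torque_nm),
                                    y = .data$rom_mean_deg,
                                    fill = .data$stage)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$rom_min_deg, ymax = .data$rom_max_deg),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3,
      linewidth = 0.3) +
    ggplot2::geom_point(
      data = mv,
      ggplot2::aes(x = factor(.data$torque_nm), y = .data$rom_deg,
                   group = .data$stage),
      position = ggplot2::position_dodge(width = 0.9), shape = 21,
      fill = "white", size = 1.4) +
    ggplot2::facet_wrap(~direction, scales = "free_y") +
    ggplot2::labs(x = "applied torque (Nm)", y = "ROM (deg)",
                  fill = "stage") +
    ggplot2::theme_minimal()
}
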