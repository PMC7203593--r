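#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a disk torque-angle fit
#'
#' @param x a `"disk_fit"` from [fit_disk_characteristic()].
#' @param ... unused.
#' @return Tibble with `direction`, `term`, `estimate`.
#' @export
tidy.disk_fit <- function(x, ...) {
  tibble::tibble(direction = x$direction, term = c("p1", "p2", "p3"),
                 estimate = c(x$p1, x$p2, x$p3))
}

#' @rdname tidy.disk_fit
#' @export
glance.disk_fit <- function(x, ...) {
  tibble::tibble(direction = x$direction, rmse = x$rmse, n = x$n)
}

#' Tidy a ligament force-strain fit
#'
#' @param x a `"ligament_fit"` from [fit_ligament_characteristic()].
#' @param ... unused.
#' @return Tibble with `term`, `estimate`.
#' @export
tidy.ligament_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c", "d"),
                 estimate = c(x$a, x$b, x$c, x$d))
}

#' @rdname tidy.ligament_fit
#' @export
glance.ligament_fit <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, n = x$n)
}

#' Tidy a calibrated model
#'
#' One row per fitted parameter: the four disk direction rows (`p1`-`p3`),
#' the facet contact stiffness and each calibrated ligament's softplus
#' parameters, all at full precision (print methods round to the four
#' significant digits the characteristic tables are conventionally reported
#' at).
#'
#' @param x a `"calibrated_model"` from [run_backward_calibration()].
#' @param ... unused.
#' @return Tibble with `element`, `term`, `estimate`.
#' @export
tidy.calibrated_model <- function(x, ...) {
  rows <- list()
  for (d in names(x$disk$rot)) {
    p <- x$disk$rot[[d]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      element = paste0("disk_", d), term = c("p1", "p2", "p3"),
      estimate = c(p$p1, p$p2, p$p3))
  }
  rows[[length(rows) + 1L]] <- tibble::tibble(
    element = "facet", term = "stiffness", estimate = x$facets$stiffness)
  for (nm in names(x$diagnostics$ligaments)) {
    f <- x$diagnostics$ligaments[[nm]]$fit
    if (is.null(f)) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      element = nm, term = c("a", "b", "c", "d"),
      estimate = c(f$a, f$b, f$c, f$d))
  }
  dplyr::bind_rows(rows)
}

#' @rdname tidy.calibrated_model
#' @export
glance.calibrated_model <- function(x, ...) {
  lig_rmse <- vapply(x$diagnostics$ligaments, function(l) {
    if (is.null(l$fit)) NA_real_ else l$fit$rmse
  }, numeric(1))
  disk_rmse <- vapply(x$diagnostics$disk_fits, `[[`, numeric(1), "rmse")
  tibble::tibble(
    n_ligaments = length(x$diagnostics$ligaments),
    facet_stiffness = x$facets$stiffness,
    max_disk_rmse_nm = max(disk_rmse),
    max_ligament_rmse_n = max(lig_rmse, na.rm = TRUE))
}
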