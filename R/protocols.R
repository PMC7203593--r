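#' Scenario grid of the stepwise-reduction ROM protocol
#'
#' Eight reduction stages by four bending directions by six applied torques,
#' 192 scenarios of which 160 carry nonzero torque.
#'
#' @return Tibble with columns `stage`, `direction`, `torque_nm`.
#' @export
rom_protocol_grid <- function() {
  tidyr::expand_grid(
    stage = rom_stages(),
    direction = c("flexion", "extension", "lateral", "axial"),
    torque_nm = c(0, 1, 2.5, 5, 7.5, 10))
}

#' Scenario grid of the intradiscal-pressure protocol
#'
#' Seven muscle configurations (no cables, each of the five pairs alone, all
#' pairs jointly) by seven load cases (neutral plus +/- 3.75 Nm about each
#' anatomical axis): 49 scenarios.
#'
#' @return Tibble with columns `muscle_config`, `load_case`, `direction`,
#'   `torque_nm`.
#' @export
idp_protocol_grid <- function() {
  cases <- tibble::tibble(
    load_case = c("neutral", "flexion", "extension", "lateral_pos",
                  "lateral_neg", "axial_pos", "axial_neg"),
    direction = c("neutral", "flexion", "extension", "lateral",
                  "lateral_neg", "axial", "axial_neg"),
    torque_nm = c(0, rep(3.75, 6)))
  tidyr::expand_grid(muscle_config = c("none", muscle_groups(), "all"),
                     cases)
}

active_groups <- function(config) {
  if (config == "none") character(0)
  else if (config == "all") muscle_groups()
  else config
}

#' Forward simulation of the whole stepwise-reduction experiment
#'
#' For each of the eight reduction stages, solves the 0 Nm neutral
#' equilibrium and then ramps each bending direction through the protocol
#' torque set with warm starts, recording the segment ROM relative to the
#' stage's solved neutral pose. Solver failures are recorded per scenario
#' (`converged = FALSE`, ROM `NA`) without aborting the batch.
#'
#' @param chars characteristic set (e.g. a calibration result or
#'   [default_characteristics()]).
#' @param geom a [segment_geometry()].
#' @param control solver control overrides, see [solve_equilibrium()].
#' @return Tibble with columns `stage`, `direction`, `torque_nm`, `rom_deg`,
#'   `converged` (192 rows).
#' @export
run_stepwise_forward <- function(chars, geom, control = list()) {
  stopifnot(inherits(geom, "segment_geometry"))
  torques <- c(1, 2.5, 5, 7.5, 10)
  dirs <- c("flexion", "extension", "lateral", "axial")
  rows <- list()
  for (stage in rom_stages()) {
    model <- build_model(geom, chars, stage = stage)
    # each stage's neutral is solved from the undeformed state: stages with
    # few elements have near-degenerate directions (the tension-free axial
    # disk branch) in which a compressed warm start would drift
    neutral <- tryCatch(
      solve_equilibrium(model, load_case("neutral"), control = control),
      error = function(e) NULL)
    if (is.null(neutral)) {
      # a neutral failure voids the whole stage
      for (d in dirs) for (tq in c(0, torques)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          stage = stage, direction = d, torque_nm = tq, rom_deg = NA_real_,
          converged = FALSE)
      }
      next
    }
    x_neutral_prev <- neutral$state
    for (d in dirs) {
      ax <- load_axis(d)
      rom0 <- segment_rotation_deg(model, neutral$state, 1L, ax$axis)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        stage = stage, direction = d, torque_nm = 0, rom_deg = 0,
        converged = TRUE)
      x <- neutral$state
      for (tq in torques) {
        res <- tryCatch(
          solve_equilibrium(model, load_case(d, tq), init = x,
                            control = control),
          error = function(e) NULL)
        if (is.null(res)) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            stage = stage, direction = d, torque_nm = tq,
            rom_deg = NA_real_, converged = FALSE)
          next
        }
        x <- res$state
        rom <- (segment_rotation_deg(model, x, 1L, ax$axis) - rom0) * ax$sign
        rows[[length(rows) + 1L]] <- tibble::tibble(
          stage = stage, direction = d, torque_nm = tq, rom_deg = rom,
          converged = TRUE)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Intradiscal-pressure protocol on a lumbar spine chain
#'
#' For each of the seven muscle configurations and seven pure-moment load
#' cases (+/- 3.75 Nm about each anatomical axis applied to the topmost
#' vertebra, sacrum fixed), solves the chain equilibrium, takes the L4-L5
#' disk's axial compressive spring force and converts it to intradiscal
#' pressure via [idp_from_force()].
#'
#' @param spine a [spine_geometry()].
#' @param chars characteristic set.
#' @param control solver control overrides.
#' @return Tibble with columns `muscle_config`, `load_case`, `idp_mpa`,
#'   `converged` (49 rows).
#' @export
run_idp_protocol <- function(spine, chars, control = list()) {
  stopifnot(inherits(spine, "spine_geometry"))
  seg_names <- vapply(spine$segments, function(s) s$cranial$name, "")
  seg_idx <- match("L4", seg_names)
  if (is.na(seg_idx)) seg_idx <- max(1L, length(spine$segments) - 1L)
  grid <- idp_protocol_grid()
  rows <- list()
  for (config in unique(grid$muscle_config)) {
    model <- build_model(spine, chars, stage = "intact",
                         muscle_groups = active_groups(config))
    sub <- grid[grid$muscle_config == config, ]
    neutral <- tryCatch(
      solve_equilibrium(model, load_case("neutral"), control = control),
      error = function(e) NULL)
    for (i in seq_len(nrow(sub))) {
      d <- sub$direction[i]
      if (d == "neutral") {
        res <- neutral
      } else if (is.null(neutral)) {
        res <- NULL
      } else {
        res <- tryCatch(
          solve_equilibrium(model, load_case(d, sub$torque_nm[i]),
                            init = neutral$state, control = control),
          error = function(e) NULL)
      }
      idp <- NA_real_
      if (!is.null(res)) {
        f <- disk_axial_force(model, res$state, segment = seg_idx)
        idp <- idp_from_force(f, spine$segments[[seg_idx]]$csa) / 1e6
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        muscle_config = config, load_case = sub$load_case[i], idp_mpa = idp,
        converged = !is.null(res))
    }
  }
  dplyr::bind_rows(rows)
}

#' Count model outliers against an experimental table
#'
#' `mode = "range"` compares model ROM against the min-to-max experimental
#' range (closed interval: a value exactly at the boundary is inside; 0 Nm
#' rows are excluded because no ranges are given in the neutral position).
#' `mode = "sd"` flags values farther than one standard deviation from the
#' experimental mean.
#'
#' @param model_values tibble of model output: `stage`, `direction`,
#'   `torque_nm`, `rom_deg` for ROM; `muscle_config`, `load_case`, `idp_mpa`
#'   for IDP.
#' @param reference experimental table: a ROM table ([simulate_eds1()]
#'   layout) or an IDP table ([simulate_eds2()] layout).
#' @param mode `"range"` or `"sd"`.
#' @return List with `count` and `outliers` (tibble of offending keys and
#'   values).
#' @export
count_outliers <- function(model_values, reference,
                           mode = c("range", "sd")) {
  mode <- match.arg(mode)
  if (mode == "range") {
    keys <- c("stage", "direction", "torque_nm")
    stopifnot(all(keys %in% names(model_values)),
              all(c(keys, "rom_min_deg", "rom_max_deg") %in% names(reference)))
    mv <- dplyr::filter(model_values, .data$torque_nm > 0)
    mv <- mv[, c(keys, "rom_deg")]
    joined <- dplyr::inner_join(mv, reference, by = keys)
    if (nrow(joined) != nrow(mv)) {
      stop("count_outliers(): model scenarios missing from the reference table",
           call. = FALSE)
    }
    out <- dplyr::filter(joined,
                         .data$rom_deg < .data$rom_min_deg |
                           .data$rom_deg > .data$rom_max_deg)
    out <- dplyr::select(out, dplyr::all_of(keys), "rom_deg", "rom_min_deg",
                         "rom_max_deg")
  } else {
    keys <- c("muscle_config", "load_case")
    stopifnot(all(keys %in% names(model_values)),
              all(c(keys, "idp_mean_mpa", "idp_sd_mpa") %in% names(reference)))
    model_values <- model_values[, c(keys, "idp_mpa")]
    joined <- dplyr::inner_join(model_values, reference, by = keys)
    if (nrow(joined) != nrow(model_values)) {
      stop("count_outliers(): model scenarios missing from the reference table",
           call. = FALSE)
    }
    out <- dplyr::filter(joined,
                         abs(.data$idp_mpa - .data$idp_mean_mpa) >
                           .data$idp_sd_mpa)
    out <- dplyr::select(out, dplyr::all_of(keys), "idp_mpa", "idp_mean_mpa",
                         "idp_sd_mpa")
  }
  list(count = nrow(out), outliers = out)
}
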