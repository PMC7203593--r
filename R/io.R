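# Readers and writers: geometry JSON, characteristic parameter YAML/JSON,
# ROM/IDP CSV, run manifests. All lengths in metres except facet-local
# coordinates (mm, flagged by the units field); tables carry degrees, the
# solver works in radians.

fail_path <- function(cond, path) {
  if (!cond) stop(sprintf("schema violation at %s", path), call. = FALSE)
}

num3 <- function(x, path) {
  fail_path(is.numeric(unlist(x)) && length(unlist(x)) == 3, path)
  as.numeric(unlist(x))
}

body_to_list <- function(b) {
  list(name = b$name, com = b$com, points = b$points)
}

facet_to_list <- function(fs) {
  if (is.null(fs)) return(NULL)
  list(coef = fs$coef,
       frame = list(origin = fs$frame$origin,
                    axes = lapply(1:3, function(j) fs$frame$axes[, j])),
       stiffness = fs$stiffness, damping = fs$damping,
       probe_points = if (is.null(fs$probe_points)) NULL else
         lapply(seq_len(nrow(fs$probe_points)),
                function(i) as.numeric(fs$probe_points[i, ])),
       xy_domain = if (is.null(fs$xy_domain)) NULL else
         lapply(1:2, function(i) as.numeric(fs$xy_domain[i, ])))
}

segment_to_list <- function(sg) {
  list(cranial = sg$cranial$name, caudal = sg$caudal$name,
       disk_centre = sg$disk_centre, csa = sg$csa,
       ligaments = lapply(sg$ligaments, function(l) {
         list(name = l$name, side = l$side, cranial_point = l$cranial_point,
              caudal_point = l$caudal_point, prestrain = l$prestrain)
       }),
       facets = if (is.null(sg$facets)) NULL else
         lapply(sg$facets, facet_to_list))
}

#' Write a geometry to a schema'd JSON file
#'
#' @param geom a [segment_geometry()] or [spine_geometry()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geom, path) {
  if (inherits(geom, "segment_geometry")) {
    obj <- list(type = "segment",
                units = list(length = "m", facet_local = "mm"),
                bodies = lapply(list(geom$cranial, geom$caudal),
                                body_to_list),
                segments = list(segment_to_list(geom)))
  } else if (inherits(geom, "spine_geometry")) {
    obj <- list(type = "spine",
                units = list(length = "m", facet_local = "mm"),
                bodies = lapply(geom$bodies, body_to_list),
                segments = lapply(geom$segments, segment_to_list),
                muscles = lapply(geom$muscles, function(m) {
                  list(group = m$group, body = m$body,
                       point = as.numeric(m$point),
                       direction = m$direction, force = m$force)
                }))
  } else {
    stop("write_geometry(): unsupported object", call. = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

list_to_facet <- function(l, path) {
  fail_path(!is.null(l$coef) && !is.null(l$frame), path)
  axes <- do.call(cbind, lapply(l$frame$axes, function(a) num3(a, path)))
  facet_surface_def(
    coef = l$coef,
    frame = list(origin = num3(l$frame$origin, paste0(path, "/frame/origin")),
                 axes = axes),
    stiffness = l$stiffness, damping = l$damping,
    probe_points = if (is.null(l$probe_points)) NULL else
      do.call(rbind, lapply(l$probe_points, function(p) num3(p, path))),
    xy_domain = if (is.null(l$xy_domain)) NULL else
      do.call(rbind, lapply(l$xy_domain, as.numeric)))
}

#' Read a geometry JSON file
#'
#' Validates the schema and every geometric invariant (unique point labels,
#' positive cross-sectional area, disk centre between the centres of mass,
#' prestrain bounds) on load; violations name the failing path.
#'
#' @param path JSON file written by [write_geometry()].
#' @return A [segment_geometry()] or [spine_geometry()].
#' @export
read_geometry <- function(path) {
  obj <- jsonlite::read_json(path)
  fail_path(!is.null(obj$type) && obj$type %in% c("segment", "spine"),
            "/type")
  fail_path(identical(obj$units$length, "m"), "/units/length")
  bodies <- lapply(obj$bodies, function(b) {
    fail_path(!is.null(b$name), "/bodies/name")
    rigid_body(b$name, num3(b$com, paste0("/bodies/", b$name, "/com")),
               points = lapply(b$points, function(p)
                 num3(p, paste0("/bodies/", b$name, "/points"))))
  })
  names(bodies) <- vapply(bodies, `[[`, "", "name")
  make_segment <- function(sl, i) {
    base <- sprintf("/segments/%d", i)
    fail_path(!is.null(sl$cranial) && sl$cranial %in% names(bodies),
              paste0(base, "/cranial"))
    fail_path(!is.null(sl$caudal) && sl$caudal %in% names(bodies),
              paste0(base, "/caudal"))
    fail_path(is.numeric(sl$csa %||% NULL) || is.numeric(unlist(sl$csa)),
              paste0(base, "/csa"))
    if (as.numeric(sl$csa) <= 0) {
      stop(sprintf("schema violation at %s/csa: csa must be positive", base),
           call. = FALSE)
    }
    ligs <- lapply(sl$ligaments, function(l) {
      ligament_def(l$name, l$side, unlist(l$cranial_point),
                   unlist(l$caudal_point), prestrain = l$prestrain)
    })
    facets <- if (is.null(sl$facets)) NULL else
      lapply(stats::setNames(names(sl$facets), names(sl$facets)),
             function(s) list_to_facet(sl$facets[[s]],
                                       paste0(base, "/facets/", s)))
    segment_geometry(bodies[[sl$cranial]], bodies[[sl$caudal]],
                     num3(sl$disk_centre, paste0(base, "/disk_centre")),
                     ligaments = ligs, facets = facets,
                     csa = as.numeric(sl$csa))
  }
  segs <- lapply(seq_along(obj$segments),
                 function(i) make_segment(obj$segments[[i]], i))
  if (obj$type == "segment") {
    fail_path(length(segs) == 1, "/segments")
    return(segs[[1]])
  }
  muscles <- lapply(obj$muscles, function(m) {
    muscle_cable(m$body, num3(m$point, "/muscles/point"),
                 num3(m$direction, "/muscles/direction"),
                 force = m$force, group = m$group)
  })
  spine_geometry(unname(bodies), segs, muscles)
}

lig_char_to_list <- function(ch) {
  out <- list(a = ch$a, b = ch$b, c = ch$c, d = ch$d,
              damping_factor = ch$damping_factor)
  if (!is.null(ch$neg_branch)) out$neg_branch <- ch$neg_branch
  out
}

#' Write a characteristic parameter set to YAML or JSON
#'
#' @param chars a characteristic set (e.g. [default_characteristics()] or a
#'   calibration result).
#' @param path output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_characteristics <- function(chars, path) {
  obj <- list(
    disk = c(chars$disk$rot,
             list(axial_quad = chars$disk$axial_quad,
                  axial_lin = chars$disk$axial_lin,
                  shear_stiffness = chars$disk$shear_stiffness,
                  d_damp_tra = chars$disk$d_damp_tra,
                  d_damp_rot = chars$disk$d_damp_rot)),
    ligaments = lapply(chars$ligaments, lig_char_to_list),
    facets = chars$facets,
    prestrains = as.list(chars$prestrains))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path, precision = 15)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a characteristic parameter set
#'
#' Loads the packaged default set or any alternative set in the same schema.
#' Required blocks: the four disk direction rows plus axial/shear constants,
#' the six calibrated ligaments, facet stiffness and surface coefficients,
#' prestrains. A zero `d` in any ligament row is a validation error.
#'
#' @param path YAML or JSON file in the [write_characteristics()] schema.
#' @return A `"characteristic_set"`.
#' @export
read_characteristics <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  fail_path(!is.null(obj$disk), "/disk")
  for (d in c("flexion", "extension", "lateral", "axial")) {
    fail_path(!is.null(obj$disk[[d]]), paste0("/disk/", d))
  }
  disk <- disk_characteristic(
    rot = obj$disk[c("flexion", "extension", "lateral", "axial")],
    axial_quad = obj$disk$axial_quad, axial_lin = obj$disk$axial_lin,
    shear_stiffness = obj$disk$shear_stiffness,
    d_damp_tra = obj$disk$d_damp_tra, d_damp_rot = obj$disk$d_damp_rot)
  required <- c("ALL", "PLL", "FL", "CL", "ISL", "SSL")
  for (nm in required) {
    fail_path(!is.null(obj$ligaments[[nm]]), paste0("/ligaments/", nm))
  }
  ligaments <- lapply(obj$ligaments, function(l) {
    if (!is.null(l$d) && l$d == 0) {
      stop("schema violation at /ligaments: d must be nonzero", call. = FALSE)
    }
    ligament_characteristic(l$a, l$b, l$c, l$d,
                            neg_branch = l$neg_branch,
                            damping_factor = l$damping_factor %||% 10)
  })
  if (is.null(ligaments$ITL)) ligaments$ITL <- zero_ligament_characteristic()
  fail_path(!is.null(obj$facets$stiffness), "/facets/stiffness")
  structure(list(disk = disk, ligaments = ligaments,
                 facets = obj$facets,
                 prestrains = unlist(obj$prestrains)),
            class = "characteristic_set")
}

#' Read / write ROM tables as CSV
#'
#' Comma-separated, UTF-8, header row, `.` decimal; ROM in degrees. Columns:
#' `stage`, `direction`, `torque_nm`, `rom_mean_deg`, `rom_min_deg`,
#' `rom_max_deg` (min/max empty at 0 Nm).
#'
#' @param rom ROM table tibble.
#' @param path CSV path.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_rom_table <- function(rom, path) {
  utils::write.csv(rom, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_rom_table
#' @export
read_rom_table <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("stage", "direction", "torque_nm", "rom_mean_deg")
  fail_path(all(need %in% names(df)), "/columns")
  bad <- setdiff(unique(df$stage), rom_stages())
  if (length(bad) > 0) {
    stop(sprintf("read_rom_table(): unknown stage label(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (all(c("rom_min_deg", "rom_max_deg") %in% names(df))) {
    ok <- is.na(df$rom_min_deg) | is.na(df$rom_max_deg) |
      (df$rom_min_deg <= df$rom_mean_deg & df$rom_mean_deg <= df$rom_max_deg)
    if (!all(ok)) {
      stop("read_rom_table(): rows violate min <= mean <= max", call. = FALSE)
    }
  }
  df
}

#' Read / write IDP tables as CSV
#'
#' Columns: `muscle_config`, `load_case`, `idp_mean_mpa`, `idp_sd_mpa`.
#'
#' @param idp IDP table tibble.
#' @param path CSV path.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_idp_table <- function(idp, path) {
  utils::write.csv(idp, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_idp_table
#' @export
read_idp_table <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  fail_path(all(c("muscle_config", "load_case", "idp_mean_mpa",
                  "idp_sd_mpa") %in% names(df)), "/columns")
  if (any(df$idp_sd_mpa < 0, na.rm = TRUE)) {
    stop("read_idp_table(): negative standard deviations", call. = FALSE)
  }
  df
}

#' Write a run manifest
#'
#' Records input-file digests, the seed, solver tolerances, the package
#' version and a timestamp for a batch run, as YAML.
#'
#' @param path output YAML path.
#' @param inputs character vector of input file paths (digested with MD5).
#' @param seed integer seed of the run.
#' @param tolerances named list of solver tolerances.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, inputs = character(0), seed = NA,
                               tolerances = solver_control()) {
  obj <- list(
    package = "spinewise",
    version = as.character(utils::packageVersion("spinewise")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    tolerances = tolerances[c("tol_force", "tol_torque")],
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }))
  yaml::write_yaml(obj, path)
  invisible(path)
}
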