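# Configuration loading (YAML with unit conversion and strict key checking)
# and field/report writers (legacy VTK, CSV, JSON).

.cfg_keys <- list(
  top = c("name", "length_unit", "domain", "mesh", "default_region",
          "regions", "optics", "thermal", "beam", "boundary", "model",
          "run", "concentration", "output"),
  domain = c("r_max", "z_max"),
  mesh = c("nr", "nz"),
  region = c("label", "r", "z"),
  optic = c("mu_a", "mu_s", "g", "n"),
  thermal = c("rho", "cp", "k", "qm", "wb", "cb", "ta"),
  beam = c("kind", "irradiance", "radius", "power", "peak", "fwhm", "waist"),
  run = c("dt", "duration", "t0", "seed", "photons", "probes"),
  probe = c("r", "z", "region", "label"),
  boundary = c("optical", "thermal"),
  concentration = c("base_region", "loaded_region")
)

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown config key(s) in ", where, ": ", paste(bad, collapse = ", "))
}

#' Load and validate a simulation configuration
#'
#' Reads a YAML case description, rejects unknown keys, converts all lengths
#' to SI meters (`length_unit: mm` or `m`) and optical coefficients to m^-1
#' (`optics: unit: per_m` or `per_mm`), and checks that every referenced
#' region exists.
#'
#' @param path Path to a YAML configuration (see the presets under
#'   `system.file("extdata", package = "phototherm")`).
#' @return A validated `ptt_config` list in SI units.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, .cfg_keys$top, "top level")
  for (req in c("domain", "mesh", "optics", "beam"))
    if (is.null(cfg[[req]])) stop("missing required config key: ", req)
  unit <- cfg$length_unit %||% "m"
  lscale <- switch(unit, m = 1, mm = 1e-3,
                   stop("unsupported length_unit: ", unit))
  check_keys(cfg$domain, .cfg_keys$domain, "domain")
  check_keys(cfg$mesh, .cfg_keys$mesh, "mesh")
  cfg$domain <- lapply(cfg$domain, function(v) v * lscale)
  regions <- list()
  for (rg in cfg$regions %||% list()) {
    check_keys(rg, .cfg_keys$region, paste0("region '", rg$label %||% "?", "'"))
    regions[[length(regions) + 1L]] <-
      region_spec(rg$label, unlist(rg$r) * lscale, unlist(rg$z) * lscale)
  }
  cfg$regions <- regions
  cfg$default_region <- cfg$default_region %||% "tissue"

  ounit <- cfg$optics$unit %||% "per_m"
  oscale <- switch(ounit, per_m = 1, per_mm = 1e3,
                   stop("unsupported optical unit: ", ounit))
  onames <- setdiff(names(cfg$optics), "unit")
  optics <- lapply(onames, function(nm) {
    o <- cfg$optics[[nm]]
    check_keys(o, .cfg_keys$optic, paste0("optics '", nm, "'"))
    optical_properties(o$mu_a * oscale, o$mu_s * oscale,
                       g = o$g %||% 0, n = o$n %||% 1.33)
  })
  names(optics) <- onames
  cfg$optics <- optics

  reg_labels <- c(vapply(regions, `[[`, character(1), "label"),
                  cfg$default_region)
  miss <- setdiff(reg_labels, names(optics))
  if (length(miss))
    stop("no optical properties for region(s): ", paste(miss, collapse = ", "))

  if (!is.null(cfg$thermal)) {
    cfg$thermal <- lapply(stats::setNames(names(cfg$thermal), names(cfg$thermal)),
      function(nm) {
        th <- cfg$thermal[[nm]]
        check_keys(th, .cfg_keys$thermal, paste0("thermal '", nm, "'"))
        thermal_properties(th$rho, th$cp, th$k, qm = th$qm %||% 0,
                           wb = th$wb %||% 0, cb = th$cb %||% 0,
                           ta = th$ta %||% 37)
      })
  }

  bm <- cfg$beam
  check_keys(bm, .cfg_keys$beam, "beam")
  cfg$beam <- if (identical(bm$kind, "flat")) {
    beam_flat(bm$irradiance, bm$radius * lscale)
  } else if (identical(bm$kind, "gaussian")) {
    beam_gaussian(power = bm$power, peak = bm$peak,
                  fwhm = if (!is.null(bm$fwhm)) bm$fwhm * lscale,
                  waist = if (!is.null(bm$waist)) bm$waist * lscale)
  } else stop("unknown beam kind: ", bm$kind %||% "<missing>")

  if (!is.null(cfg$run)) {
    check_keys(cfg$run, .cfg_keys$run, "run")
    probes <- cfg$run$probes
    if (!is.null(probes)) {
      probes <- lapply(probes, function(p) {
        check_keys(p, .cfg_keys$probe, "probe")
        if (!is.null(p$region) && !(p$region %in% reg_labels))
          stop("probe references undefined region: ", p$region)
        list(r = if (!is.null(p$r)) p$r * lscale,
             z = if (!is.null(p$z)) p$z * lscale,
             region = p$region, label = p$label)
      })
      cfg$run$probes <- probes
    }
  }
  if (!is.null(cfg$model) &&
      !cfg$model %in% c("bl", "sda", "deltap1", "mc"))
    stop("unknown model: ", cfg$model)
  if (!is.null(cfg$concentration)) {
    check_keys(cfg$concentration, .cfg_keys$concentration, "concentration")
    for (nm in unlist(cfg$concentration))
      if (!nm %in% reg_labels) stop("concentration references undefined region: ", nm)
  }
  class(cfg) <- "ptt_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a nodal scalar field as a legacy VTK unstructured grid
#'
#' ASCII legacy VTK, one POINT_DATA scalar array named after the field label
#' (`fluence_W_per_m2` or `temperature_C`). Deterministic byte output for
#' fixed inputs.
#'
#' @param field A `scalar_field`.
#' @param path Output file path (.vtk).
#' @export
write_field_vtk <- function(field, path) {
  m <- field$mesh
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con, sep = "\n")
  wl("# vtk DataFile Version 3.0", "phototherm scalar field", "ASCII",
     "DATASET UNSTRUCTURED_GRID",
     sprintf("POINTS %d double", nrow(m$nodes)))
  wl(sprintf("%.17g %.17g 0", m$nodes[, 1], m$nodes[, 2]))
  nt <- nrow(m$tri)
  wl(sprintf("CELLS %d %d", nt, 4L * nt))
  wl(sprintf("3 %d %d %d", m$tri[, 1] - 1L, m$tri[, 2] - 1L, m$tri[, 3] - 1L))
  wl(sprintf("CELL_TYPES %d", nt))
  wl(rep("5", nt))
  wl(sprintf("POINT_DATA %d", nrow(m$nodes)))
  wl(sprintf("SCALARS %s double 1", field$label), "LOOKUP_TABLE default")
  wl(sprintf("%.17g", field$values))
  invisible(path)
}

#' Read back a legacy VTK field written by [write_field_vtk()]
#' @param path Path to the .vtk file.
#' @return `list(points, triangles, values, label)`.
#' @export
read_field_vtk <- function(path) {
  ln <- readLines(path)
  np <- as.integer(sub("POINTS (\\d+) .*", "\\1", grep("^POINTS", ln, value = TRUE)))
  ip <- grep("^POINTS", ln)
  pts <- do.call(rbind, lapply(strsplit(ln[(ip + 1):(ip + np)], " "), as.numeric))
  ic <- grep("^CELLS", ln)
  nt <- as.integer(sub("CELLS (\\d+) .*", "\\1", ln[ic]))
  tri <- do.call(rbind, lapply(strsplit(ln[(ic + 1):(ic + nt)], " "),
                               function(v) as.integer(v[2:4]) + 1L))
  is <- grep("^SCALARS", ln)
  label <- strsplit(ln[is], " ")[[1]][2]
  vals <- as.numeric(ln[(is + 2):(is + 1 + np)])
  list(points = pts[, 1:2, drop = FALSE], triangles = tri,
       values = vals, label = label)
}

#' Write probe time series as CSV
#'
#' One `time_s` column plus one column per probe; `duration/dt + 1` rows
#' (including t = 0).
#'
#' @param run A `bioheat_run` with probes.
#' @param path Output CSV path.
#' @export
write_probe_csv <- function(run, path) {
  if (is.null(run$probe_trace)) stop("run has no probe traces")
  labs <- if (!is.null(run$probes$label)) run$probes$label
          else sprintf("probe_r%g_z%g", run$probes$r, run$probes$z)
  df <- data.frame(time_s = run$times, run$probe_trace)
  names(df) <- c("time_s", labs)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass_deep(cfg), auto_unbox = TRUE,
                              digits = NA, force = TRUE), tf)
  unname(tools::md5sum(tf))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Write a comparison report as JSON (with config hash) and CSV
#'
#' @param report A `comparison_report` (or any data frame).
#' @param path Output path without extension, or ending in .json/.csv.
#' @param config Optional configuration whose md5 hash is recorded for
#'   provenance.
#' @export
write_report <- function(report, path, config = NULL) {
  base <- sub("\\.(json|csv)$", "", path)
  utils::write.csv(report, paste0(base, ".csv"), row.names = FALSE)
  payload <- list(
    axis = attr(report, "axis"),
    reference = attr(report, "reference"),
    config_hash = if (!is.null(config)) config_hash(config) else NULL,
    rows = as.data.frame(report)
  )
  jsonlite::write_json(payload, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paste0(base, c(".json", ".csv")))
}
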