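#' Read a run configuration from a YAML file
#'
#' Accepts a nested key-value file with top-level sections `geometry`, `cpm`,
#' `field`, `damage`, `run` and scalars `seed`, `replicates`. Unknown keys and
#' out-of-range values (for example a propagation constant violating the
#' explicit-scheme stability bound) are rejected with an error naming the
#' key. Defaults are materialized so the returned object echoes the full
#' configuration.
#'
#' @param path YAML file path.
#' @return a [sim_config()]; the `replicates` count (default 1) is attached
#'   as an attribute.
#' @examples
#' cfg <- read_config(system.file("extdata", "example_config.yaml",
#'                                package = "bnctsim"))
#' cfg$geometry$mode
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_top <- c("geometry", "cpm", "field", "damage", "run", "seed",
                 "replicates")
  bad <- setdiff(names(raw), known_top)
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  take <- function(section, allowed, fun) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), allowed)
    if (length(bad)) stop("unknown key(s) in '", section, "': ",
                          paste(bad, collapse = ", "))
    do.call(fun, args)
  }
  geometry <- take("geometry", c("mode", "n_cells", "dims", "margin",
                                 "f_dose"), geometry_config)
  cpm <- take("cpm", c("J", "lam_area", "temperature", "neighborhood_order"),
              cpm_params)
  field <- take("field", c("D", "mu", "s", "substeps", "persist_sources"),
                field_params)
  damage <- take("damage", c("theta", "eps_floor"), damage_params)
  run <- raw$run
  if (is.null(run)) run <- list()
  bad <- setdiff(names(run), c("max_mcs", "plateau_eps", "plateau_window",
                               "snapshot_every"))
  if (length(bad)) stop("unknown key(s) in 'run': ",
                        paste(bad, collapse = ", "))
  cfg <- sim_config(geometry = geometry, cpm = cpm, field = field,
                    damage = damage, run = run,
                    seed = if (is.null(raw$seed)) 1L else raw$seed)
  attr(cfg, "replicates") <- if (is.null(raw$replicates)) 1L
                             else as.integer(raw$replicates)
  cfg
}

#' Write a configuration back to YAML
#' @param config a [sim_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- list(
    geometry = config$geometry[c("mode", "n_cells", "dims", "margin",
                                 "f_dose")],
    cpm = list(J = unname(as.vector(config$cpm$J)),
               lam_area = config$cpm$lam_area,
               temperature = config$cpm$temperature,
               neighborhood_order = config$cpm$neighborhood_order),
    field = config$field[c("D", "mu", "s", "substeps", "persist_sources")],
    damage = config$damage[c("theta", "eps_floor")],
    run = config$run,
    seed = config$seed,
    replicates = if (is.null(attr(config, "replicates"))) 1L
                 else attr(config, "replicates")
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Write a 3D volume as a legacy-VTK structured-points file
#'
#' ASCII legacy VTK, readable by ParaView and other standard consumers.
#'
#' @param vol 3D array (integer cell ids or numeric field values).
#' @param path output file.
#' @param name scalar field name.
#' @param type `"int"` or `"float"`.
#' @return `path`, invisibly.
#' @export
write_vtk_points <- function(vol, path, name = "cell_id",
                             type = c("int", "float")) {
  type <- match.arg(type)
  dims <- dim(vol)
  vals <- as.vector(vol)
  if (type == "int") vals <- format(as.integer(vals))
  else vals <- format(as.numeric(vals), digits = 9, trim = TRUE,
                      scientific = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "bnctsim lattice snapshot",
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    paste("DIMENSIONS", dims[1], dims[2], dims[3]),
    "ORIGIN 0 0 0",
    "SPACING 1 1 1",
    paste("POINT_DATA", prod(dims)),
    paste("SCALARS", name, type, "1"),
    "LOOKUP_TABLE default"
  ), con)
  writeLines(trimws(vals), con)
  invisible(path)
}

#' Read back a legacy-VTK structured-points volume
#' @param path VTK file written by [write_vtk_points()].
#' @return list with `dims`, `name`, `type` and the data array `vol`.
#' @export
read_vtk_points <- function(path) {
  lines <- readLines(path)
  dl <- grep("^DIMENSIONS", lines, value = TRUE)[1]
  dims <- as.integer(strsplit(trimws(dl), "\\s+")[[1]][2:4])
  sl <- grep("^SCALARS", lines)[1]
  sc <- strsplit(trimws(lines[sl]), "\\s+")[[1]]
  vals <- lines[(sl + 2):length(lines)]
  vals <- vals[nzchar(trimws(vals))]
  num <- as.numeric(vals)
  vol <- array(if (sc[3] == "int") as.integer(num) else num, dim = dims)
  list(dims = dims, name = sc[2], type = sc[3], vol = vol)
}

#' Write the full output set of a run
#'
#' Produces `series.csv`, `death_events.csv`, `cells.json` (id, kind,
#' centroid), final-state VTK volumes (`cells_final.vtk`, `field_final.vtk`),
#' any intermediate snapshots recorded during the run, and a `manifest.json`
#' that echoes the configuration, seed, package version and per-file MD5
#' checksums — enough to re-run the condition bit-identically.
#'
#' @param result a `bnct_run`.
#' @param outdir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  p <- function(f) file.path(outdir, f)
  write.csv(result$series, p("series.csv"), row.names = FALSE)
  files <- c(files, p("series.csv"))
  write.csv(result$death_events, p("death_events.csv"), row.names = FALSE)
  files <- c(files, p("death_events.csv"))
  cen <- cell_centroids(result$lattice, result$cells)
  cells_json <- lapply(seq_len(nrow(result$cells)), function(i) {
    list(id = result$cells$id[i], kind = result$cells$kind[i],
         is_source = result$cells$is_source[i],
         centroid = as.numeric(cen[i, ]))
  })
  jsonlite::write_json(cells_json, p("cells.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, p("cells.json"))
  write_vtk_points(result$lattice$spin, p("cells_final.vtk"), "cell_id",
                   "int")
  files <- c(files, p("cells_final.vtk"))
  for (nm in names(result$snapshots)) {
    fc <- p(sprintf("cells_%s.vtk", nm))
    ff <- p(sprintf("field_%s.vtk", nm))
    write_vtk_points(result$snapshots[[nm]]$spin, fc, "cell_id", "int")
    write_vtk_points(result$snapshots[[nm]]$field, ff, "alpha_density",
                     "float")
    files <- c(files, fc, ff)
  }
  manifest <- list(
    package = "bnctsim",
    version = as.character(utils::packageVersion("bnctsim")),
    seed = result$seed,
    eps_floor = result$config_echo$damage$eps_floor,
    E_ref_rate = result$E_ref_rate,
    plateau_mcs = result$plateau_mcs,
    death_fraction_pct = result$death_fraction_pct,
    config = config_as_list(result$config_echo),
    checksums = as.list(tools::md5sum(files))
  )
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, p("manifest.json"))
  invisible(files)
}

config_as_list <- function(config) {
  list(
    geometry = config$geometry[c("mode", "n_cells", "dims", "margin",
                                 "f_dose")],
    cpm = list(J = as.vector(config$cpm$J), lam_area = config$cpm$lam_area,
               temperature = config$cpm$temperature,
               neighborhood_order = config$cpm$neighborhood_order),
    field = config$field[c("D", "mu", "s", "substeps", "persist_sources")],
    damage = config$damage[c("theta", "eps_floor")],
    run = config$run,
    seed = config$seed
  )
}

#' Deterministic small test configurations
#'
#' Tiny lattice/cell/field fixtures used by the unit tests; repeated calls
#' return identical objects (the global RNG state is preserved).
#'
#' \describe{
#'   \item{two_cells_2d}{two 5 x 5 tumor cells side by side on 12 x 12 x 1.}
#'   \item{single_source_3d}{one 25-voxel BPA source cell centered in 11^3.}
#'   \item{mini_spheroid}{8-cell spheroid in 12^3.}
#'   \item{mini_sheet}{4-cell monolayer on 12 x 12 x 7.}
#' }
#'
#' @param name fixture name.
#' @return list with `lattice`, `cells` and a zero `field`.
#' @export
make_fixture <- function(name) {
  had_seed <- exists(".Random.seed", envir = globalenv())
  if (had_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(20240601L)
  out <- switch(
    name,
    two_cells_2d = {
      v1 <- as.matrix(expand.grid(x = 2:6, y = 4:8, z = 1))
      v2 <- as.matrix(expand.grid(x = 7:11, y = 4:8, z = 1))
      build_lattice(c(12, 12, 1), list(list(id = 1, voxels = v1),
                                       list(id = 2, voxels = v2)))
    },
    single_source_3d = {
      dims <- c(11L, 11L, 11L)
      g <- as.matrix(expand.grid(x = 1:11, y = 1:11, z = 1:11))
      d2 <- (g[, 1] - 6)^2 + (g[, 2] - 6)^2 + (g[, 3] - 6)^2
      ord <- order(d2, g[, 3], g[, 2], g[, 1])
      build_lattice(dims, list(list(id = 1, kind = "BPA_TUMOR",
                                    voxels = g[ord[1:25], ])))
    },
    mini_spheroid = init_spheroid(
      geometry_config("spheroid", n_cells = 8, dims = c(12, 12, 12),
                      margin = 1)),
    mini_sheet = init_monolayer(
      geometry_config("monolayer", n_cells = 4, dims = c(12, 12, 7),
                      margin = 1)),
    stop("unknown fixture name: ", name)
  )
  out$field <- init_field(out$lattice$dims)
  out
}
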