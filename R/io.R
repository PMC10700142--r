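#' Write a synthetic world to disk
#'
#' Plain-text serialization: each raster layer as a TSV matrix (north-up),
#' the tree inventory as CSV with the documented column order, and the
#' configuration as YAML. Deterministic: the same world writes
#' byte-identical files.
#'
#' @param world A [synthesize_world()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wl <- function(m, name) {
    utils::write.table(format(m, digits = 10, trim = TRUE, scientific = FALSE),
                       file.path(dir, paste0(name, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  st <- world$stack
  for (nm in names(st$env)) wl(st$env[[nm]], nm)
  for (nm in names(st$human)) wl(st$human[[nm]], paste0("human_", nm))
  wl(st$minimal_disturbance + 0, "minimal_disturbance")
  for (nm in names(st$landcover)) wl(st$landcover[[nm]], paste0("landcover_", nm))
  wl(st$rmf, "root_mass_fraction")
  wl(st$soil_delta, "soil_potential")
  wl(st$soil_error, "soil_error")
  tr <- world$truth
  for (nm in c("potential_agc", "current_agc", "potential_canopy",
               "current_canopy")) wl(tr[[nm]], nm)

  trees <- world$trees[, c("plot_id", "lat", "lon", "year", "area_m2",
                           "tree_id", "dbh_cm", "wood_density")]
  utils::write.csv(format(trees, digits = 10, trim = TRUE),
                   file.path(dir, "trees.csv"), row.names = FALSE, quote = FALSE)
  cfg <- unclass(world$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yml"))
  invisible(dir)
}

#' Read a raster layer written by [write_world()]
#'
#' @param path Path to a `.tsv` layer file.
#' @return Numeric matrix.
#' @export
read_layer <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' Write an allometric equation registry as YAML
#'
#' @param equations Named list of [allometric_equation()] per biome.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_equation_registry <- function(equations, path) {
  reg <- lapply(equations, function(e)
    list(beta0 = e$beta0, beta1 = e$beta1,
         dbh_min = e$dbh_range[1], dbh_max = e$dbh_range[2]))
  yaml::write_yaml(reg, path)
  invisible(path)
}

#' Read an allometric equation registry from YAML
#'
#' @param path YAML file as written by [write_equation_registry()].
#' @return Named list of [allometric_equation()] objects.
#' @export
read_equation_registry <- function(path) {
  reg <- yaml::read_yaml(path)
  out <- lapply(names(reg), function(b)
    allometric_equation(reg[[b]]$beta0, reg[[b]]$beta1,
                        dbh_range = c(reg[[b]]$dbh_min, reg[[b]]$dbh_max),
                        biome = b))
  names(out) <- names(reg)
  out
}
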