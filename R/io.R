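# File-format plumbing: GeoJSON vector layers, CSV tables, YAML configs.
# All coordinates are projected meters (a GeoJSON CRS is deliberately not
# interpreted; inputs must share one projected system).

ring_close <- function(m) rbind(m, m[1, , drop = FALSE])
coords_list <- function(m) lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))

geojson_feature <- function(type, coords, properties = list()) {
  list(type = "Feature",
       properties = properties,
       geometry = list(type = type, coordinates = coords))
}

write_geojson <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10,
                       pretty = FALSE, null = "null")
  invisible(path)
}

read_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection: ", path)
  }
  gj$features
}

coords_to_matrix <- function(coords) {
  do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
}

# outer ring of a GeoJSON Polygon, unclosed; holes are not supported.
polygon_outer_ring <- function(geometry, what = "polygon") {
  rings <- geometry$coordinates
  if (length(rings) > 1) warning(what, " has holes; only the outer ring is used")
  m <- coords_to_matrix(rings[[1]])
  if (all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

#' Write a synthetic scene to standard files
#'
#' Vector layers go to GeoJSON (roads as LineStrings with a `class`
#' property; point sources as Points; industrial parcels and block groups
#' as Polygons, block groups carrying population, shares and national
#' predictions as properties), the grid and truth surfaces to CSV, and the
#' configuration to YAML.
#'
#' @param scene an `ld_scene`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  p <- function(f) file.path(dir, f)

  write_geojson(lapply(seq_len(nrow(scene$roads)), function(i) {
    geojson_feature("LineString", coords_list(scene$roads$geometry[[i]]),
                    list(road_id = scene$roads$road_id[i],
                         class = scene$roads$class[i]))
  }), p("roads.geojson"))
  for (nm in c("food_service", "gas_stations")) {
    pts <- scene[[nm]]
    write_geojson(lapply(seq_len(nrow(pts)), function(i) {
      geojson_feature("Point", c(pts$x[i], pts$y[i]), list(id = i))
    }), p(paste0(nm, ".geojson")))
  }
  write_geojson(lapply(seq_len(nrow(scene$industrial)), function(i) {
    r <- scene$industrial[i, ]
    geojson_feature("Polygon",
                    list(coords_list(ring_close(rect_poly(r$x0, r$y0, r$x1, r$y1)))),
                    list(id = i))
  }), p("industrial.geojson"))

  bg <- scene$block_groups
  props <- setdiff(names(bg), c("geometry"))
  write_geojson(lapply(seq_len(nrow(bg)), function(i) {
    geojson_feature("Polygon",
                    list(coords_list(ring_close(bg$geometry[[i]]))),
                    as.list(bg[i, props]))
  }), p("block_groups.geojson"))

  gtab <- scene$grid
  if (!is.null(scene$truth_ufp)) {
    gtab$truth_ufp <- scene$truth_ufp
    gtab$truth_no2 <- scene$truth_no2
  }
  utils::write.csv(gtab, p("grid.csv"), row.names = FALSE)
  write_scene_config(scene$config, p("config.yaml"))
  paths <- c(roads = p("roads.geojson"), food_service = p("food_service.geojson"),
             gas_stations = p("gas_stations.geojson"),
             industrial = p("industrial.geojson"),
             block_groups = p("block_groups.geojson"),
             grid = p("grid.csv"), config = p("config.yaml"))
  invisible(paths)
}

#' @rdname write_scene
#' @param config an `ld_scene_config`.
#' @param path YAML path.
#' @export
write_scene_config <- function(config, path) {
  x <- unclass(config)
  x$source_strengths <- list(
    types = rownames(config$source_strengths),
    ufp = unname(config$source_strengths[, "ufp"]),
    no2 = unname(config$source_strengths[, "no2"])
  )
  # yaml serializes named atomic vectors as bare sequences; keep names via maps
  for (nm in c("road_grid_spacing_m", "decay_length_m", "noise_sd",
               "lur_bias")) {
    x[[nm]] <- as.list(x[[nm]])
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene_config <- function(path) {
  x <- yaml::read_yaml(path)
  ss <- cbind(ufp = unlist(x$source_strengths$ufp),
              no2 = unlist(x$source_strengths$no2))
  rownames(ss) <- unlist(x$source_strengths$types)
  x$source_strengths <- ss
  for (nm in c("road_grid_spacing_m", "decay_length_m", "noise_sd", "lur_bias")) {
    x[[nm]] <- unlist(x[[nm]])
  }
  do.call(scene_config, x[names(x) %in% names(formals(scene_config))])
}

#' Read scene layers back from a directory of standard files
#'
#' Inverse of [write_scene()] for the layers the feature and harmonize
#' stages need.
#'
#' @param dir directory written by [write_scene()].
#' @return list with `grid` (and truth columns if present), `roads`,
#'   `food_service`, `gas_stations`, `industrial`, `block_groups`.
#' @export
read_scene_layers <- function(dir) {
  grid <- tibble::as_tibble(utils::read.csv(file.path(dir, "grid.csv")))
  feats <- read_geojson(file.path(dir, "roads.geojson"))
  roads <- tibble::tibble(
    road_id = vapply(feats, function(f) as.integer(f$properties$road_id), 1L),
    class = vapply(feats, function(f) f$properties$class, ""),
    geometry = lapply(feats, function(f) coords_to_matrix(f$geometry$coordinates))
  )
  read_points <- function(f) {
    feats <- read_geojson(f)
    tibble::tibble(
      x = vapply(feats, function(g) g$geometry$coordinates[[1]], 1),
      y = vapply(feats, function(g) g$geometry$coordinates[[2]], 1)
    )
  }
  feats <- read_geojson(file.path(dir, "industrial.geojson"))
  industrial <- lapply(feats, function(f) polygon_outer_ring(f$geometry,
                                                             "industrial parcel"))
  list(grid = grid,
       roads = roads,
       food_service = read_points(file.path(dir, "food_service.geojson")),
       gas_stations = read_points(file.path(dir, "gas_stations.geojson")),
       industrial = industrial,
       block_groups = read_block_groups(file.path(dir, "block_groups.geojson")))
}

#' Read block groups from a GeoJSON file
#'
#' Every feature must be a Polygon; declared property names map file fields
#' to the canonical columns (national predictions, population, the five
#' shares).  Missing declared fields become NA columns.
#'
#' @param path GeoJSON file of block-group polygons.
#' @param fields named character vector mapping canonical names
#'   (`lur_ufp`, `lur_no2`, `pop`, `share_asian`, ..., `share_hispanic`)
#'   to the property names used in the file; defaults to identical names.
#' @return tibble with `bg_id`, `geometry` (list of vertex matrices) and
#'   the mapped columns.
#' @export
read_block_groups <- function(path, fields = NULL) {
  canonical <- c("lur_ufp", "lur_no2", "pop", SHARE_COLS)
  if (is.null(fields)) fields <- stats::setNames(canonical, canonical)
  feats <- read_geojson(path)
  geoms <- lapply(seq_along(feats), function(i) {
    g <- feats[[i]]$geometry
    if (!identical(g$type, "Polygon")) {
      stop("block-group feature ", i, " is not a Polygon")
    }
    polygon_outer_ring(g, paste("block group", i))
  })
  out <- tibble::tibble(bg_id = seq_along(feats), geometry = geoms)
  for (cn in names(fields)) {
    fn <- fields[[cn]]
    out[[cn]] <- vapply(feats, function(f) {
      v <- f$properties[[fn]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  }
  out
}

#' Map OSM-style tags to the seven source classes
#'
#' The importer for externally sourced layers: a GeoJSON file whose
#' features carry OSM-style properties is split into the package's source
#' classes using an explicit, configurable tag mapping (the defaults cover
#' the usual residential/primary/secondary/tertiary/motorway road tags,
#' restaurant/fast food/cafe food service, fuel stations and industrial
#' land use).  Live downloads are out of scope; any OSM extract exported
#' to GeoJSON works.
#'
#' @return named list mapping `property=value` tags to class names.
#' @export
osm_class_map <- function() {
  list("highway=residential" = "residential",
       "highway=primary" = "arterial",
       "highway=secondary" = "arterial",
       "highway=tertiary" = "arterial",
       "highway=motorway" = "highway",
       "highway=motorway_link" = "onramp",
       "amenity=restaurant" = "food_service",
       "amenity=fast_food" = "food_service",
       "amenity=cafe" = "food_service",
       "amenity=fuel" = "gas_station",
       "landuse=industrial" = "industrial")
}

#' @rdname osm_class_map
#' @param path GeoJSON file with OSM-style properties.
#' @param mapping tag-to-class mapping (default [osm_class_map()]).
#' @return layer list as accepted by [build_feature_matrix()].
#' @export
read_osm_layers <- function(path, mapping = osm_class_map()) {
  feats <- read_geojson(path)
  roads <- list(); road_cls <- character(0)
  fs_x <- fs_y <- gas_x <- gas_y <- numeric(0)
  industrial <- list()
  for (f in feats) {
    cls <- NULL
    for (key in c("highway", "amenity", "landuse")) {
      v <- f$properties[[key]]
      if (!is.null(v)) {
        cls <- mapping[[paste0(key, "=", v)]]
        if (!is.null(cls)) break
      }
    }
    if (is.null(cls)) next
    gt <- f$geometry$type
    if (cls %in% c("residential", "arterial", "highway", "onramp")) {
      if (gt != "LineString") next
      roads[[length(roads) + 1L]] <- coords_to_matrix(f$geometry$coordinates)
      road_cls <- c(road_cls, cls)
    } else if (cls %in% c("food_service", "gas_station")) {
      if (gt != "Point") next
      if (cls == "food_service") {
        fs_x <- c(fs_x, f$geometry$coordinates[[1]])
        fs_y <- c(fs_y, f$geometry$coordinates[[2]])
      } else {
        gas_x <- c(gas_x, f$geometry$coordinates[[1]])
        gas_y <- c(gas_y, f$geometry$coordinates[[2]])
      }
    } else if (cls == "industrial") {
      if (gt != "Polygon") next
      industrial[[length(industrial) + 1L]] <-
        polygon_outer_ring(f$geometry, "industrial parcel")
    }
  }
  list(roads = tibble::tibble(road_id = seq_along(roads), class = road_cls,
                              geometry = roads),
       food_service = tibble::tibble(x = fs_x, y = fs_y),
       gas_stations = tibble::tibble(x = gas_x, y = gas_y),
       industrial = industrial)
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_table <- function(path) tibble::as_tibble(utils::read.csv(path))
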