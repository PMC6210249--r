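#' Read and write polygon sets as GeoJSON
#'
#' Coordinates are kept in the planar metric CRS the package works in;
#' rings are closed on write and unclosed on read.
#'
#' @param polys list of ring matrices.
#' @param path file path.
#' @param properties optional data.frame of per-feature properties.
#' @export
write_geojson <- function(polys, path, properties = NULL) {
  feats <- lapply(seq_along(polys), function(i) {
    ring <- polys[[i]]
    ring <- rbind(ring, ring[1, ]) # close
    f <- list(type = "Feature",
              properties = if (is.null(properties)) stats::setNames(list(), character(0))
                           else as.list(properties[i, , drop = FALSE]),
              geometry = list(type = "Polygon",
                              coordinates = list(lapply(seq_len(nrow(ring)),
                                                        function(k) ring[k, ]))))
    f
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' @rdname write_geojson
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], function(pt)
      c(pt[[1]], pt[[2]])))
    ring[-nrow(ring), , drop = FALSE] # unclose
  })
}

#' Write / read a greenspace layer as one GeoJSON file per class
#'
#' @param layer a `greenspace_layer`.
#' @param dir directory receiving `vegetation.geojson`, `pa_sites.geojson`,
#'   `greenspaces.geojson`.
#' @export
write_layer_geojson <- function(layer, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cl in c("vegetation", "pa_sites", "greenspaces"))
    write_geojson(layer[[cl]], file.path(dir, paste0(cl, ".geojson")))
  invisible(dir)
}

#' @rdname write_layer_geojson
#' @export
read_layer_geojson <- function(dir) {
  greenspace_layer(
    vegetation = read_geojson(file.path(dir, "vegetation.geojson")),
    pa_sites = read_geojson(file.path(dir, "pa_sites.geojson")),
    greenspaces = read_geojson(file.path(dir, "greenspaces.geojson")))
}

#' Write an activity space as GeoJSON with time-weight properties
#'
#' Stay buffers become one feature each (with `weight`, `activity_class`);
#' the merged travel buffer's capsules share the single travel weight.
#'
#' @param space an `activity_space`.
#' @param path file path.
#' @export
write_activity_space_geojson <- function(space, path) {
  polys <- lapply(space$stay_buffers, function(b) b$ring)
  props <- data.frame(
    kind = rep("stay", length(polys)),
    weight = vapply(space$stay_buffers, function(b) b$weight, numeric(1)),
    activity_class = vapply(space$stay_buffers, function(b) b$activity_class,
                            character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(space$travel)) {
    polys <- c(polys, space$travel$capsules)
    props <- rbind(props, data.frame(
      kind = rep("travel", length(space$travel$capsules)),
      weight = rep(space$travel$weight, length(space$travel$capsules)),
      activity_class = rep("travel", length(space$travel$capsules)),
      stringsAsFactors = FALSE))
  }
  write_geojson(polys, path, props)
}

#' Load a cohort configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [cohort_config()].
#'
#' @param path YAML file.
#' @return a `cohort_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(cohort_config)))]
  if (!is.null(args$time_budget_means))
    args$time_budget_means <- unlist(args$time_budget_means)
  if (!is.null(args$study_window))
    args$study_window <- as.numeric(unlist(args$study_window))
  do.call(cohort_config, args)
}
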