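#' Read vector features from GeoJSON
#'
#' Supports FeatureCollections of LineString, MultiLineString, Polygon and
#' MultiPolygon geometries. Feature properties `class`
#' (`roads`/`water`/`fire`), `year` (fire ignition year) and `unit_id`
#' (management-unit label) are carried through. Multi-part geometries are
#' split into one feature per part. Polygon holes are not supported and
#' raise an error.
#'
#' @param path path to a GeoJSON file.
#' @return list of features: each `list(type, coords, class, year,
#'   unit_id)`.
#' @export
read_features_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  out <- list()
  for (ft in gj$features) {
    geom <- ft$geometry
    props <- ft$properties
    mk <- function(type, coords) {
      co <- do.call(rbind, lapply(coords, function(p)
        c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
      list(type = type, coords = co,
           class = props$class, year = props$year,
           unit_id = props$unit_id)
    }
    switch(geom$type,
      LineString = { out[[length(out) + 1L]] <- mk("line", geom$coordinates) },
      MultiLineString = for (part in geom$coordinates)
        out[[length(out) + 1L]] <- mk("line", part),
      Polygon = {
        if (length(geom$coordinates) > 1L)
          stop("polygon holes are not supported")
        out[[length(out) + 1L]] <- mk("polygon", geom$coordinates[[1]])
      },
      MultiPolygon = for (part in geom$coordinates) {
        if (length(part) > 1L) stop("polygon holes are not supported")
        out[[length(out) + 1L]] <- mk("polygon", part[[1]])
      },
      stop("unsupported geometry type: ", geom$type))
  }
  out
}

#' Write features to GeoJSON
#'
#' Inverse of [read_features_geojson()] for the package's plain feature
#' lists; output is deterministic (fixed 6-decimal coordinates), so
#' identical inputs produce byte-identical files.
#'
#' @param features list of feature lists (`type`, `coords`, optional
#'   `class`, `year`, `unit_id`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_geojson <- function(features, path) {
  fmt <- function(v) sprintf("%.6f", v)
  feat_json <- vapply(features, function(f) {
    co <- as.matrix(f$coords)
    if (identical(f$type, "polygon") &&
        !all(co[1, ] == co[nrow(co), ]))
      co <- rbind(co, co[1, , drop = FALSE])
    pts <- paste0("[", fmt(co[, 1]), ",", fmt(co[, 2]), "]",
                  collapse = ",")
    gtype <- if (identical(f$type, "line")) "LineString" else "Polygon"
    coords <- if (gtype == "Polygon") paste0("[[", pts, "]]")
              else paste0("[", pts, "]")
    props <- character(0)
    if (!is.null(f$class))
      props <- c(props, paste0('"class":"', f$class, '"'))
    if (!is.null(f$year))
      props <- c(props, paste0('"year":', as.integer(f$year)))
    if (!is.null(f$unit_id))
      props <- c(props, paste0('"unit_id":"', f$unit_id, '"'))
    paste0('{"type":"Feature","properties":{',
           paste(props, collapse = ","),
           '},"geometry":{"type":"', gtype,
           '","coordinates":', coords, "}}")
  }, "")
  txt <- paste0('{"type":"FeatureCollection","features":[',
                paste(feat_json, collapse = ","), "]}")
  writeLines(txt, path)
  invisible(path)
}

#' Export a resistance surface as a plain-text grid
#'
#' Writes the cost raster in ESRI ASCII-grid layout (header with `ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, then rows north to
#' south), a text format readable by standard GIS tools.
#'
#' @param surface a `resistance_surface`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surface_ascii <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(surface$cost)),
               paste("nrows", nrow(surface$cost)),
               paste("xllcorner", surface$origin[1]),
               paste("yllcorner", surface$origin[2]),
               paste("cellsize", surface$cell_size)), con)
  for (r in rev(seq_len(nrow(surface$cost))))
    writeLines(paste(surface$cost[r, ], collapse = " "), con)
  invisible(path)
}
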