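#' Read and write point fields as CSV
#'
#' CSV with header `x_um,y_um`; ROI stored in a JSON sidecar
#' (`<file>.json`) and recovered from the data extent if the sidecar is
#' missing.
#'
#' @param field a [point_field()].
#' @param path CSV file path.
#' @return `write_point_field` returns `path` invisibly;
#'   `read_point_field` returns a [point_field()].
#' @export
write_point_field <- function(field, path) {
  stopifnot(inherits(field, "point_field"))
  df <- data.frame(x_um = field$points[, 1], y_um = field$points[, 2])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(roi_um = field$roi), paste0(path, ".json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_point_field
#' @export
read_point_field <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("x_um", "y_um") %in% names(df)))
  side <- paste0(path, ".json")
  roi <- if (file.exists(side))
    as.numeric(jsonlite::read_json(side, simplifyVector = TRUE)$roi_um)
  else c(max(df$x_um), max(df$y_um))
  point_field(cbind(df$x_um, df$y_um), roi)
}

#' Read and write height maps as plain-text CSV with a JSON sidecar
#'
#' The height grid is stored as a headerless CSV of nm values; the
#' sidecar (`<file>.json`) records `pixel_size_nm` and the label.
#'
#' @param map a [height_map()].
#' @param path CSV file path.
#' @return `write_height_map` returns `path` invisibly; `read_height_map`
#'   returns a [height_map()].
#' @export
write_height_map <- function(map, path) {
  stopifnot(inherits(map, "height_map"))
  utils::write.table(map$heights, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(pixel_size_nm = map$pixel_size,
                            name = map$name),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_height_map
#' @export
read_height_map <- function(path) {
  z <- as.matrix(read.csv(path, header = FALSE))
  dimnames(z) <- NULL
  side <- paste0(path, ".json")
  meta <- if (file.exists(side))
    jsonlite::read_json(side, simplifyVector = TRUE)
  else list(pixel_size_nm = 1, name = "")
  height_map(z, meta$pixel_size_nm, meta$name %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write trace sets as CSV (frames x neurons) with a sidecar
#'
#' Columns are neurons (`n1`, `n2`, ...), rows are frames; the JSON
#' sidecar records `frame_interval_s` and any planted onsets.
#'
#' @param t a [trace_set()].
#' @param path CSV file path.
#' @return `write_trace_set` returns `path` invisibly; `read_trace_set`
#'   returns a [trace_set()].
#' @export
write_trace_set <- function(t, path) {
  stopifnot(inherits(t, "trace_set"))
  m <- t(t$traces)
  colnames(m) <- paste0("n", seq_len(ncol(m)))
  write.csv(m, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(frame_interval_s = t$frame_interval,
         planted_onsets_s = t$planted_onsets),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace_set
#' @export
read_trace_set <- function(path) {
  m <- as.matrix(read.csv(path))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side))
    jsonlite::read_json(side, simplifyVector = TRUE)
  else list(frame_interval_s = 0.1)
  onsets <- meta$planted_onsets_s
  if (!is.null(onsets)) onsets <- lapply(onsets, as.numeric)
  trace_set(t(m), meta$frame_interval_s, planted_onsets = onsets)
}

#' Write a spatial graph as an edge-list CSV (and optionally GraphML)
#'
#' Edge list columns: `i,j,length_um` (1-based node indices); node
#' coordinates go to a companion point-field CSV when `nodes_path` is
#' given.  GraphML output (via igraph) preserves coordinates and lengths
#' in one file.
#'
#' @param g a `spatial_graph`.
#' @param path output file; extension `.graphml` selects GraphML.
#' @param nodes_path optional CSV for node coordinates.
#' @return `path`, invisibly.
#' @export
write_spatial_graph <- function(g, path, nodes_path = NULL) {
  stopifnot(inherits(g, "spatial_graph"))
  if (grepl("\\.graphml$", path)) {
    igraph::write_graph(as_igraph(g), path, format = "graphml")
  } else {
    df <- data.frame(i = g$edges[, 1], j = g$edges[, 2],
                     length_um = g$lengths)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(nodes_path)) write_point_field(g$field, nodes_path)
  invisible(path)
}
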