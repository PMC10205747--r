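#' Read and write sampled time series as CSV
#'
#' RFC-4180 CSV with a mandatory header; columns `time_s`, `value`. The unit
#' and cycle period travel in `# key: value` comment lines above the header
#' and are restored on read.
#'
#' @param x a [hemo_series()].
#' @param path file path.
#' @return `read_series_csv` returns a [hemo_series()];
#'   `write_series_csv` returns `path` invisibly.
#' @export
write_series_csv <- function(x, path) {
  stopifnot(inherits(x, "hemo_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit: %s", series_unit(x)), con)
  if (!is.na(series_period(x)))
    writeLines(sprintf("# period: %.17g", series_period(x)), con)
  df <- data.frame(time_s = sprintf("%.17g", x$time_s),
                   value = sprintf("%.17g", x$value))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  unit <- sub("^# unit:\\s*", "", grep("^# unit:", meta, value = TRUE)[1])
  if (is.na(unit)) unit <- ""
  per_line <- grep("^# period:", meta, value = TRUE)
  period <- if (length(per_line))
    as.numeric(sub("^# period:\\s*", "", per_line[1])) else NA_real_
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  if (!all(c("time_s", "value") %in% names(df)))
    stop("series CSV must have columns time_s, value", call. = FALSE)
  hemo_series(df$time_s, df$value, unit = unit, period = period)
}

#' Read and write field series as long-format CSV
#'
#' One row per (time, point): columns `time_s`, `point`, `x`, `y`, `z`,
#' `vx`, `vy`, `vz`, plus `nx`, `ny`, `nz` for wall fields. Lossless at
#' full double precision.
#'
#' @param field a [field_series()].
#' @param path file path.
#' @return `read_field_csv` returns a [field_series()].
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "field_series"))
  nt <- length(field$times); np <- nrow(field$points)
  df <- data.frame(
    time_s = rep(field$times, each = np),
    point = rep(seq_len(np), nt),
    x = rep(field$points[, 1], nt),
    y = rep(field$points[, 2], nt),
    z = rep(field$points[, 3], nt),
    vx = as.vector(t(field$vectors[, , 1])),
    vy = as.vector(t(field$vectors[, , 2])),
    vz = as.vector(t(field$vectors[, , 3])))
  if (!is.null(field$normals)) {
    df$nx <- rep(field$normals[, 1], nt)
    df$ny <- rep(field$normals[, 2], nt)
    df$nz <- rep(field$normals[, 3], nt)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", field$kind), con)
  if (!is.na(field$period))
    writeLines(sprintf("# period: %.17g", field$period), con)
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     con, row.names = FALSE, quote = FALSE, sep = ",")
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  kind <- sub("^# kind:\\s*", "", grep("^# kind:", meta, value = TRUE)[1])
  per_line <- grep("^# period:", meta, value = TRUE)
  period <- if (length(per_line))
    as.numeric(sub("^# period:\\s*", "", per_line[1])) else NA_real_
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  times <- sort(unique(df$time_s))
  df <- df[order(df$time_s, df$point), ]
  np <- length(unique(df$point))
  if (nrow(df) != np * length(times))
    stop("point count drifts across time steps", call. = FALSE)
  first <- df[df$time_s == times[1], ]
  pts <- as.matrix(first[, c("x", "y", "z")])
  dimnames(pts) <- NULL
  vec <- array(0, dim = c(length(times), np, 3))
  vec[, , 1] <- matrix(df$vx, length(times), np, byrow = TRUE)
  vec[, , 2] <- matrix(df$vy, length(times), np, byrow = TRUE)
  vec[, , 3] <- matrix(df$vz, length(times), np, byrow = TRUE)
  normals <- NULL
  if (all(c("nx", "ny", "nz") %in% names(df))) {
    normals <- as.matrix(first[, c("nx", "ny", "nz")])
    dimnames(normals) <- NULL
  }
  if (identical(kind, "wall_shear") && is.null(normals))
    stop("wall_shear field file lacks surface normals", call. = FALSE)
  field_series(pts, times, vec,
               kind = if (identical(kind, "wall_shear")) "wall_shear" else "velocity",
               normals = normals, period = period)
}

# ---- minimal VTK XML (.vtu / .pvd) point-cloud support -----------------

fmt_floats <- function(x) paste(sprintf("%.17g", x), collapse = " ")

#' Write a point cloud with point-data arrays as VTK XML (.vtu)
#'
#' Minimal ASCII `UnstructuredGrid` writer (points stored as vertex cells)
#' sufficient for inspecting package outputs in ParaView-class viewers.
#' `write_pvd` writes the matching time-series manifest.
#'
#' @param points n x 3 coordinates.
#' @param data named list of per-point arrays: numeric vectors (scalars) or
#'   n x 3 matrices (vectors).
#' @param path output path.
#' @return `path`, invisibly. `read_vtu` returns `list(points, data)`.
#' @export
write_vtu <- function(points, data = list(), path) {
  points <- as.matrix(points)
  n <- nrow(points)
  lines <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '  <UnstructuredGrid>',
    sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, n),
    '      <Points>',
    '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">',
    paste0('          ', fmt_floats(as.vector(t(points)))),
    '        </DataArray>',
    '      </Points>')
  if (length(data)) {
    lines <- c(lines, '      <PointData>')
    for (nm in names(data)) {
      arr <- data[[nm]]
      if (is.matrix(arr)) {
        stopifnot(nrow(arr) == n, ncol(arr) == 3)
        lines <- c(lines,
          sprintf('        <DataArray type="Float64" Name="%s" NumberOfComponents="3" format="ascii">', nm),
          paste0('          ', fmt_floats(as.vector(t(arr)))),
          '        </DataArray>')
      } else {
        stopifnot(length(arr) == n)
        lines <- c(lines,
          sprintf('        <DataArray type="Float64" Name="%s" format="ascii">', nm),
          paste0('          ', fmt_floats(arr)),
          '        </DataArray>')
      }
    }
    lines <- c(lines, '      </PointData>')
  }
  lines <- c(lines,
    '      <Cells>',
    '        <DataArray type="Int64" Name="connectivity" format="ascii">',
    paste0('          ', paste(seq_len(n) - 1L, collapse = " ")),
    '        </DataArray>',
    '        <DataArray type="Int64" Name="offsets" format="ascii">',
    paste0('          ', paste(seq_len(n), collapse = " ")),
    '        </DataArray>',
    '        <DataArray type="UInt8" Name="types" format="ascii">',
    paste0('          ', paste(rep(1L, n), collapse = " ")),
    '        </DataArray>',
    '      </Cells>',
    '    </Piece>',
    '  </UnstructuredGrid>',
    '</VTKFile>')
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_vtu
#' @export
read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  parse_array <- function(node) {
    vals <- as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
    nc <- xml2::xml_attr(node, "NumberOfComponents")
    if (!is.na(nc) && as.integer(nc) == 3)
      matrix(vals, ncol = 3, byrow = TRUE) else vals
  }
  pts_node <- xml2::xml_find_first(piece, "./Points/DataArray")
  points <- parse_array(pts_node)
  data_nodes <- xml2::xml_find_all(piece, "./PointData/DataArray")
  data <- stats::setNames(
    lapply(data_nodes, parse_array),
    vapply(data_nodes, function(n) xml2::xml_attr(n, "Name"), character(1)))
  list(points = points, data = data)
}

#' @rdname write_vtu
#' @param files character vector of .vtu paths (relative to the .pvd).
#' @param times matching time stamps, s.
#' @export
write_pvd <- function(files, times, path) {
  stopifnot(length(files) == length(times))
  lines <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="Collection" version="0.1" byte_order="LittleEndian">',
    '  <Collection>',
    sprintf('    <DataSet timestep="%.17g" group="" part="0" file="%s"/>',
            times, files),
    '  </Collection>',
    '</VTKFile>')
  writeLines(lines, path)
  invisible(path)
}

#' Write a field series as a VTK time series (.pvd + .vtu per step)
#'
#' @param field a [field_series()].
#' @param dir output directory (created if missing).
#' @param basename file stem for the series.
#' @return path of the .pvd manifest, invisibly.
#' @export
write_field_vtk <- function(field, dir, basename = "field") {
  stopifnot(inherits(field, "field_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(field$times))
  for (j in seq_along(field$times)) {
    files[j] <- sprintf("%s_%04d.vtu", basename, j - 1L)
    data <- list(vector = field_at(field, j))
    if (!is.null(field$normals)) data$normals <- field$normals
    write_vtu(field$points, data, file.path(dir, files[j]))
  }
  pvd <- file.path(dir, paste0(basename, ".pvd"))
  write_pvd(files, field$times, pvd)
  invisible(pvd)
}

#' @rdname write_field_vtk
#' @param path path to a .pvd manifest written by [write_field_vtk()].
#' @param kind field kind to restore (`"velocity"` or `"wall_shear"`).
#' @param period cycle period to attach, s.
#' @export
read_field_vtk <- function(path, kind = "velocity", period = NA_real_) {
  doc <- xml2::read_xml(path)
  sets <- xml2::xml_find_all(doc, ".//DataSet")
  times <- as.numeric(xml2::xml_attr(sets, "timestep"))
  files <- xml2::xml_attr(sets, "file")
  ord <- order(times)                      # manifest order may be shuffled
  times <- times[ord]; files <- files[ord]
  base <- dirname(path)
  first <- read_vtu(file.path(base, files[1]))
  np <- nrow(first$points)
  vec <- array(0, dim = c(length(times), np, 3))
  normals <- first$data$normals
  for (j in seq_along(files)) {
    step <- if (j == 1) first else read_vtu(file.path(base, files[j]))
    if (nrow(step$points) != np)
      stop(sprintf("point count drifts at step %d (%d vs %d)",
                   j, nrow(step$points), np), call. = FALSE)
    vec[j, , ] <- step$data$vector
  }
  if (identical(kind, "wall_shear") && is.null(normals))
    stop("wall_shear VTK series lacks a normals array", call. = FALSE)
  field_series(first$points, times, vec, kind = kind, normals = normals,
               period = period)
}

#' Write a WSS index map
#'
#' Persists a [wss_index_map()] as CSV (columns `x,y,z,tawss,osi,holmes`)
#' or as a .vtu point cloud with the three arrays attached.
#'
#' @param map a `wss_index_map`.
#' @param path output path.
#' @param format `"csv"` or `"vtu"`.
#' @return `path` invisibly; `read_index_map` (CSV only) restores the map.
#' @export
write_index_map <- function(map, path, format = c("csv", "vtu")) {
  format <- match.arg(format)
  stopifnot(inherits(map, "wss_index_map"))
  if (!length(map$tawss)) stop("empty index map", call. = FALSE)
  if (format == "vtu")
    return(write_vtu(map$points,
                     list(tawss = map$tawss, osi = map$osi,
                          holmes = map$holmes), path))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cycle_period: %.17g", map$cycle_period), con)
  df <- data.frame(x = map$points[, 1], y = map$points[, 2],
                   z = map$points[, 3], tawss = map$tawss, osi = map$osi,
                   holmes = map$holmes)
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     con, row.names = FALSE, quote = FALSE, sep = ",")
  invisible(path)
}

#' @rdname write_index_map
#' @export
read_index_map <- function(path) {
  lines <- readLines(path)
  per <- as.numeric(sub("^# cycle_period:\\s*", "",
                        grep("^# cycle_period:", lines, value = TRUE)[1]))
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  structure(list(points = as.matrix(df[, c("x", "y", "z")]),
                 tawss = df$tawss, osi = df$osi, holmes = df$holmes,
                 cycle_period = per),
            class = "wss_index_map")
}
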