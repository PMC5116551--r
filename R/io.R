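UNITS_TAG <- "length=mm velocity=mm/s time=s"

fmt_nums <- function(x, per_line = 6L) {
  s <- sprintf("%.17g", x)
  n <- length(s)
  grp <- ceiling(seq_len(n) / per_line)
  paste(tapply(s, grp, paste, collapse = " "), collapse = "\n")
}

#' Write arrays on a voxel grid to a VTK XML ImageData (.vti) file
#'
#' Plain ASCII encoding; point-data arrays are written in x-fastest order.
#' A `units` field-data string records the package unit policy (lengths mm,
#' time s, velocity mm/s) and is checked on read.
#'
#' @param path output file path.
#' @param grid a [voxel_grid()].
#' @param arrays named list of arrays: 3-D arrays of `grid$dims` (scalars),
#'   4-D arrays `c(grid$dims, k)` or n-voxel x k matrices (k components).
#'   Logical arrays are written as `UInt8`.
#' @return `path`, invisibly.
#' @export
write_vti <- function(path, grid, arrays) {
  stopifnot(inherits(grid, "voxel_grid"), is.list(arrays), length(names(arrays)) == length(arrays))
  n <- prod(grid$dims)
  ext <- sprintf("0 %d 0 %d 0 %d", grid$dims[1] - 1L, grid$dims[2] - 1L, grid$dims[3] - 1L)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="ImageData" version="0.1" byte_order="LittleEndian">')
  w('  <ImageData WholeExtent="%s" Origin="%.17g %.17g %.17g" Spacing="%.17g %.17g %.17g">',
    ext, grid$origin[1], grid$origin[2], grid$origin[3],
    grid$spacing[1], grid$spacing[2], grid$spacing[3])
  w('    <FieldData>')
  w('      <Array type="String" Name="units" format="ascii" NumberOfTuples="1">%s</Array>', UNITS_TAG)
  w('    </FieldData>')
  w('    <Piece Extent="%s">', ext)
  w('      <PointData>')
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    logical_in <- is.logical(a)
    if (is.matrix(a)) {
      if (nrow(a) != n) format_error(sprintf("array '%s' has wrong length", nm))
      k <- ncol(a); vals <- as.vector(t(a))      # interleave components
    } else {
      d <- dim(a)
      if (identical(d, grid$dims)) { k <- 1L; vals <- as.vector(a) }
      else if (length(d) == 4L && identical(d[1:3], grid$dims)) {
        k <- d[4]; vals <- as.vector(aperm(a, c(4, 1, 2, 3)))
      } else format_error(sprintf("array '%s' has wrong dimensions", nm))
    }
    type <- if (logical_in) "UInt8" else "Float64"
    if (logical_in) vals <- as.integer(vals)
    w('        <DataArray type="%s" Name="%s" NumberOfComponents="%d" format="ascii">', type, nm, k)
    writeLines(fmt_nums(vals), con)
    w('        </DataArray>')
  }
  w('      </PointData>')
  w('    </Piece>')
  w('  </ImageData>')
  w('</VTKFile>')
  invisible(path)
}

#' Read a VTK image-data file (.vti XML or legacy structured points)
#'
#' @param path file to read.
#' @return list with `grid` (a [voxel_grid()]) and `arrays` (named list;
#'   multi-component arrays come back as 4-D `c(dims, k)` arrays, scalars as
#'   3-D arrays).
#' @export
read_vti <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  head <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^# vtk DataFile", head)) return(read_vtk_legacy(path))
  doc <- xml2::read_xml(path)
  img <- xml2::xml_find_first(doc, ".//ImageData")
  if (inherits(img, "xml_missing")) format_error("not a VTK ImageData file")
  ext <- as.integer(strsplit(trimws(xml2::xml_attr(img, "WholeExtent")), "\\s+")[[1]])
  dims <- c(ext[2] - ext[1], ext[4] - ext[3], ext[6] - ext[5]) + 1L
  origin <- as.numeric(strsplit(trimws(xml2::xml_attr(img, "Origin")), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(trimws(xml2::xml_attr(img, "Spacing")), "\\s+")[[1]])
  grid <- voxel_grid(origin, spacing, dims)
  units <- xml2::xml_find_first(doc, ".//FieldData/Array[@Name='units']")
  if (!inherits(units, "xml_missing")) {
    u <- trimws(xml2::xml_text(units))
    if (u != UNITS_TAG)
      format_error(sprintf("unit policy mismatch in %s: found '%s', expected '%s'",
                           path, u, UNITS_TAG))
  }
  das <- xml2::xml_find_all(doc, ".//PointData/DataArray")
  if (length(das) == 0L) format_error("no point-data arrays in file")
  n <- prod(dims)
  arrays <- list()
  for (da in das) {
    nm <- xml2::xml_attr(da, "Name")
    k <- xml2::xml_attr(da, "NumberOfComponents")
    k <- if (is.na(k)) 1L else as.integer(k)
    fmt <- xml2::xml_attr(da, "format")
    if (!is.na(fmt) && fmt != "ascii")
      format_error("only ascii-encoded DataArray payloads are supported")
    vals <- scan(text = xml2::xml_text(da), what = double(), quiet = TRUE)
    if (length(vals) != n * k)
      format_error(sprintf("array '%s' has %d values, expected %d", nm, length(vals), n * k))
    arrays[[nm]] <- if (k == 1L) array(vals, dim = dims)
      else aperm(array(vals, dim = c(k, dims)), c(2, 3, 4, 1))
  }
  list(grid = grid, arrays = arrays)
}

# legacy ASCII STRUCTURED_POINTS reader
read_vtk_legacy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(key) {
    i <- grep(paste0("^", key, "\\b"), lines)
    if (!length(i)) format_error(sprintf("legacy VTK file lacks %s", key))
    strsplit(trimws(lines[i[1]]), "\\s+")[[1]][-1]
  }
  if (!any(grepl("STRUCTURED_POINTS", lines)))
    format_error("legacy VTK reader supports only STRUCTURED_POINTS datasets")
  dims <- as.integer(grab("DIMENSIONS"))
  origin <- as.numeric(grab("ORIGIN"))
  spacing <- as.numeric(grab("SPACING"))
  grid <- voxel_grid(origin, spacing, dims)
  n <- prod(dims)
  arrays <- list()
  i <- grep("^(VECTORS|SCALARS)\\b", lines)
  for (ix in i) {
    hdr <- strsplit(trimws(lines[ix]), "\\s+")[[1]]
    nm <- hdr[2]
    k <- if (hdr[1] == "VECTORS") 3L else 1L
    start <- ix + if (hdr[1] == "SCALARS") 2L else 1L   # skip LOOKUP_TABLE
    vals <- double(0); j <- start
    while (length(vals) < n * k && j <= length(lines)) {
      vals <- c(vals, scan(text = lines[j], what = double(), quiet = TRUE))
      j <- j + 1L
    }
    if (length(vals) < n * k)
      format_error(sprintf("legacy array '%s' truncated", nm))
    arrays[[nm]] <- if (k == 1L) array(vals, dim = dims)
      else aperm(array(vals, dim = c(k, dims)), c(2, 3, 4, 1))
  }
  if (!length(arrays)) format_error("no point-data arrays in legacy file")
  list(grid = grid, arrays = arrays)
}

#' Save a velocity series as one .vti file per cardiac phase
#'
#' Each file carries a 3-component `velocity` array and a `mask` array (the
#' validity mask as UInt8).
#'
#' @param series a [velocity_series()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of written paths, invisibly.
#' @export
save_velocity_series <- function(series, dir, prefix = "phase") {
  stopifnot(inherits(series, "velocity_series"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%02d.vti", prefix, seq_len(series$n_phases)))
  for (k in seq_len(series$n_phases)) {
    f <- series$phases[[k]]
    write_vti(paths[k], f$grid, list(velocity = f$velocity, mask = f$valid))
  }
  invisible(paths)
}

#' Load a velocity series from per-phase image files
#'
#' Phase order follows the input order. All files must hold a 3-component
#' `velocity` array on one common uniform grid; a `mask` array, when present,
#' becomes the validity mask.
#'
#' @param paths character vector of .vti (or legacy .vtk) files, one per phase.
#' @param cycle_duration cardiac cycle length (s).
#' @return a [velocity_series()].
#' @export
load_velocity_series <- function(paths, cycle_duration = 1) {
  if (length(paths) < 2L)
    grid_error("a velocity series needs at least 2 phase files")
  phases <- vector("list", length(paths))
  grid <- NULL
  for (k in seq_along(paths)) {
    d <- read_vti(paths[k])
    if (is.null(d$arrays$velocity) || length(dim(d$arrays$velocity)) != 4L)
      format_error(sprintf("%s lacks a 3-component 'velocity' array", paths[k]))
    if (is.null(grid)) grid <- d$grid
    else stopifnot_same_grid(grid, d$grid, sprintf("files 1 and %d", k))
    valid <- if (!is.null(d$arrays$mask)) d$arrays$mask != 0 else NULL
    phases[[k]] <- velocity_field(d$grid, d$arrays$velocity, valid = valid)
  }
  velocity_series(phases, cycle_duration = cycle_duration)
}

#' Write a surface mesh to ASCII STL or PLY
#'
#' Format is chosen by file extension. PLY preserves shared vertices and an
#' optional per-face ostium-cap label; STL stores independent triangles.
#'
#' @param mesh a [surface_mesh()].
#' @param path output path ending in `.stl` or `.ply`.
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") {
    v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
    v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
    v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
    e1 <- v2 - v1; e2 <- v3 - v1
    nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
    nrm <- nrm / len
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid vortexstab", con)
    for (i in seq_len(nrow(mesh$faces))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
      writeLines("    outer loop", con)
      writeLines(sprintf("      vertex %.17g %.17g %.17g",
                         c(v1[i, 1], v2[i, 1], v3[i, 1]),
                         c(v1[i, 2], v2[i, 2], v3[i, 2]),
                         c(v1[i, 3], v2[i, 3], v3[i, 3])), con)
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid vortexstab", con)
  } else if (ext == "ply") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(mesh$vertices)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(mesh$faces)),
                 "property list uchar int vertex_indices",
                 if (!is.null(mesh$cap)) "property uchar cap",
                 "end_header"), con)
    writeLines(sprintf("%.17g %.17g %.17g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
    capcol <- if (!is.null(mesh$cap)) sprintf(" %d", as.integer(mesh$cap)) else ""
    writeLines(sprintf("3 %d %d %d%s", mesh$faces[, 1] - 1L,
                       mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L, capcol), con)
  } else stop("unsupported surface format: ", ext)
  invisible(path)
}

#' Read an ASCII STL or PLY surface mesh
#' @param path path ending in `.stl` or `.ply`.
#' @return a [surface_mesh()] (PLY restores the cap labels when present).
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  if (ext == "stl") {
    vl <- grep("^\\s*vertex\\b", lines, value = TRUE)
    nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                     function(s) as.numeric(s[2:4]), numeric(3)))
    if (nrow(nums) %% 3 != 0) format_error("malformed STL: vertex count not divisible by 3")
    key <- paste(sprintf("%.17g", nums[, 1]), sprintf("%.17g", nums[, 2]),
                 sprintf("%.17g", nums[, 3]))
    uk <- !duplicated(key)
    ids <- match(key, key[uk])
    verts <- nums[uk, , drop = FALSE]
    faces <- matrix(ids, ncol = 3, byrow = TRUE)
    surface_mesh(verts, faces)
  } else if (ext == "ply") {
    hdr_end <- grep("^end_header", lines)[1]
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
    nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1]))
    has_cap <- any(grepl("^property uchar cap", lines[seq_len(hdr_end)]))
    vlines <- lines[hdr_end + seq_len(nv)]
    verts <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                      function(s) as.numeric(s[1:3]), numeric(3)))
    flines <- lines[hdr_end + nv + seq_len(nf)]
    ftok <- strsplit(trimws(flines), "\\s+")
    faces <- t(vapply(ftok, function(s) as.integer(s[2:4]) + 1L, integer(3)))
    cap <- if (has_cap) vapply(ftok, function(s) s[5] != "0", TRUE) else NULL
    surface_mesh(verts, faces, cap = cap)
  } else stop("unsupported surface format: ", ext)
}

#' Write / read a wall-shear-stress series as tidy CSV
#'
#' Long format, one row per (vertex, phase): columns `vertex_id`, `phase`,
#' `x`, `y`, `z` (vertex position, mm) and `tx`, `ty`, `tz` (WSS vector, Pa).
#'
#' @param w a [wall_series()].
#' @param path CSV path.
#' @return `path` invisibly (`write_wall_series`); a [wall_series()]
#'   (`read_wall_series`).
#' @export
write_wall_series <- function(w, path) {
  stopifnot(inherits(w, "wall_series"))
  nv <- dim(w$tau)[1]; np <- dim(w$tau)[2]
  df <- data.frame(vertex_id = rep(seq_len(nv), times = np),
                   phase = rep(seq_len(np), each = nv),
                   x = rep(w$vertices[, 1], times = np),
                   y = rep(w$vertices[, 2], times = np),
                   z = rep(w$vertices[, 3], times = np),
                   tx = as.vector(w$tau[, , 1]),
                   ty = as.vector(w$tau[, , 2]),
                   tz = as.vector(w$tau[, , 3]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wall_series
#' @param path CSV path.
#' @export
read_wall_series <- function(path) {
  df <- utils::read.csv(path)
  need <- c("vertex_id", "phase", "tx", "ty", "tz")
  if (!all(need %in% names(df)))
    format_error("wall-series CSV must have columns vertex_id, phase, tx, ty, tz")
  vids <- sort(unique(df$vertex_id)); phs <- sort(unique(df$phase))
  nv <- length(vids); np <- length(phs)
  tau <- array(NA_real_, dim = c(nv, np, 3))
  iv <- match(df$vertex_id, vids); ip <- match(df$phase, phs)
  tau[cbind(iv, ip, 1L)] <- df$tx
  tau[cbind(iv, ip, 2L)] <- df$ty
  tau[cbind(iv, ip, 3L)] <- df$tz
  if (anyNA(tau)) format_error("wall-series CSV is missing (vertex, phase) rows")
  verts <- matrix(0, nv, 3)
  if (all(c("x", "y", "z") %in% names(df))) {
    first <- !duplicated(df$vertex_id)
    verts[match(df$vertex_id[first], vids), ] <-
      as.matrix(df[first, c("x", "y", "z")])
  }
  wall_series(verts, tau)
}
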