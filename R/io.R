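# Mesh, selection and plane I/O.
#
# Vertex ORDER is never changed on read or write and duplicate-vertex
# welding is off: index correspondence between a mesh and its mirrored
# duplicate is the backbone of the whole method, so I/O must be a strict
# bijection on vertex indices.  PLY is the colour-bearing dialect (STL and
# OBJ cannot carry per-vertex attributes); selections and planes travel as
# JSON sidecars with 0-based indices.

#' Read a triangle mesh (STL, PLY or OBJ)
#'
#' Vertex order is preserved exactly as stored and no welding is
#' performed.  Polygon faces (OBJ/PLY) with more than three vertices are
#' fan-triangulated with a warning.  OBJ's 1-based indices and the 0-based
#' indices of PLY are both mapped to R's 1-based convention.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format `"auto"`, `"stl"`, `"ply"` or `"obj"`.
#' @return a `surface_mesh`; for PLY files with a per-vertex `quality`
#'   property the values are attached as attribute `"quality"`.
#' @export
read_mesh <- function(path, format = c("auto", "stl", "ply", "obj")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("stl", "ply", "obj"))
      stop("unknown mesh format: ", format, call. = FALSE)
  }
  switch(format, stl = read_stl(path), ply = read_ply(path),
         obj = read_obj(path))
}

#' Write a triangle mesh (STL, PLY or OBJ)
#'
#' PLY output can carry a per-vertex scalar (stored as the `quality`
#' property, single precision) and 8-bit RGB colours obtained by mapping
#' the scalar through a diverging palette -- the format used for
#' colour-coded distance maps.  STL and OBJ silently drop scalars (with a
#' warning).
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @param format `"auto"` (from extension), `"stl"`, `"ply"` or `"obj"`.
#' @param vertex_scalars optional numeric vector, one value per vertex (mm).
#' @param colour_scale optional `list(limits = c(min, max), palette =
#'   colours)` used to colour `vertex_scalars`; defaults to a blue-white-red
#'   diverging palette over ±2 mm when scalars are given.
#' @param binary write binary STL / binary little-endian PLY (default) or
#'   ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply", "obj"),
                       vertex_scalars = NULL, colour_scale = NULL,
                       binary = TRUE) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  if (!format %in% c("stl", "ply", "obj"))
    stop("unknown mesh format: ", format, call. = FALSE)
  if (!is.null(vertex_scalars) &&
      length(vertex_scalars) != n_vertices(mesh))
    stop("vertex_scalars must have one value per vertex", call. = FALSE)
  if (format != "ply" && !is.null(vertex_scalars)) {
    warning(format, " cannot store per-vertex scalars; dropping them")
    vertex_scalars <- NULL
  }
  switch(format,
         stl = write_stl(mesh, path, binary),
         ply = write_ply(mesh, path, vertex_scalars, colour_scale, binary),
         obj = write_obj(mesh, path))
  invisible(path)
}

# ---- STL ------------------------------------------------------------------

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  expected <- 84 + 50 * as.numeric(ntri)
  if (!is.na(ntri) && length(ntri) == 1L && file.size(path) == expected) {
    raw <- readBin(con, "raw", 50L * ntri)
    m <- matrix(raw, nrow = 50L)
    vals <- readBin(as.vector(m[1:48, ]), "numeric", size = 4L,
                    n = 12L * ntri, endian = "little")
    vm <- matrix(vals, nrow = 12L)          # nrml xyz, v1 xyz, v2 xyz, v3 xyz
    verts <- matrix(as.vector(vm[4:12, ]), ncol = 3L, byrow = TRUE)
    faces <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
    return(surface_mesh(verts, faces))
  }
  # fall back to ASCII
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("unparseable STL file: ", path, call. = FALSE)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(p) as.numeric(p[2:4])))
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  surface_mesh(verts, faces)
}

write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  fn <- face_normals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(fn[i, ], t(v[f[i, ], ]))), con, size = 4L,
               endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid facesym", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("facet normal %.9g %.9g %.9g",
                         fn[i, 1], fn[i, 2], fn[i, 3]), con)
      writeLines("  outer loop", con)
      for (k in 1:3) {
        p <- v[f[i, k], ]
        writeLines(sprintf("    vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
      }
      writeLines("  endloop", con)
      writeLines("endfacet", con)
    }
    writeLines("endsolid facesym", con)
  }
  invisible(path)
}

# ---- PLY ------------------------------------------------------------------

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, 1L)
    if (length(ln) == 0L) stop("unparseable PLY header", call. = FALSE)
    header <- c(header, ln)
    if (identical(trimws(ln), "end_header")) break
    if (length(header) > 200L) stop("unparseable PLY header", call. = FALSE)
  }
  fmt <- sub("^format\\s+", "", grep("^format", header, value = TRUE)[1])
  fmt <- strsplit(trimws(fmt), "\\s+")[[1]][1]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt, call. = FALSE)

  # parse element/property structure
  elems <- list()
  cur <- NULL
  for (ln in header) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elems[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list")
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      else
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
    }
  }
  if (!is.null(cur)) elems[[cur$name]] <- cur
  if (is.null(elems$vertex) || is.null(elems$face))
    stop("PLY lacks vertex/face elements", call. = FALSE)

  type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L, short = 2L,
                 ushort = 2L, int16 = 2L, uint16 = 2L, int = 4L, uint = 4L,
                 int32 = 4L, uint32 = 4L, float = 4L, float32 = 4L,
                 double = 8L, float64 = 8L)
  read_scalar <- function(type, n = 1L) {
    sz <- type_size[[type]]
    if (type %in% c("float", "float32", "double", "float64"))
      readBin(con, "numeric", n, size = sz, endian = "little")
    else
      readBin(con, "integer", n, size = sz, endian = "little",
              signed = !(sz < 4L && grepl("^u", type)))
  }

  nv <- elems$vertex$count
  vprops <- elems$vertex$props
  pnames <- vapply(vprops, `[[`, "", "name")
  nf <- elems$face$count
  if (fmt == "ascii") {
    rest <- readLines(con)
    vtok <- strsplit(trimws(rest[seq_len(nv)]), "\\s+")
    vdat <- do.call(rbind, lapply(vtok, as.numeric))
    colnames(vdat) <- pnames[seq_len(ncol(vdat))]
    ftok <- strsplit(trimws(rest[nv + seq_len(nf)]), "\\s+")
    polys <- lapply(ftok, function(p) as.integer(p[-1]) + 1L)
  } else {
    vdat <- matrix(NA_real_, nv, length(vprops))
    colnames(vdat) <- pnames
    for (i in seq_len(nv))
      for (j in seq_along(vprops))
        vdat[i, j] <- read_scalar(vprops[[j]]$type)
    fprop <- elems$face$props[[1]]
    polys <- vector("list", nf)
    for (i in seq_len(nf)) {
      k <- read_scalar(fprop$count_type)
      polys[[i]] <- read_scalar(fprop$type, k) + 1L
    }
  }
  faces <- triangulate_polys(polys, "PLY")
  mesh <- surface_mesh(vdat[, c("x", "y", "z"), drop = FALSE], faces)
  if ("quality" %in% pnames) attr(mesh, "quality") <- vdat[, "quality"]
  mesh
}

triangulate_polys <- function(polys, what) {
  sizes <- lengths(polys)
  if (any(sizes < 3L)) stop("degenerate polygon in ", what, call. = FALSE)
  if (any(sizes > 3L)) {
    warning(what, " contains non-triangle faces; fan-triangulating")
    polys <- unlist(lapply(polys, function(p) {
      if (length(p) == 3L) list(p)
      else lapply(seq_len(length(p) - 2L), function(i) p[c(1L, i + 1L, i + 2L)])
    }), recursive = FALSE)
  }
  matrix(unlist(polys), ncol = 3L, byrow = TRUE)
}

write_ply <- function(mesh, path, vertex_scalars = NULL, colour_scale = NULL,
                      binary = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  has_q <- !is.null(vertex_scalars)
  rgb <- NULL
  if (has_q) {
    if (is.null(colour_scale))
      colour_scale <- list(limits = c(-2, 2), palette = diverging_palette())
    rgb <- colourize(vertex_scalars, scale = colour_scale$limits,
                     palette = colour_scale$palette)
  }
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           "comment facesym distance map" ,
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z")
  if (has_q) hdr <- c(hdr, "property float quality",
                      "property uchar red", "property uchar green",
                      "property uchar blue")
  hdr <- c(hdr, sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (binary) {
    for (i in seq_len(nrow(v))) {
      writeBin(as.numeric(v[i, ]), con, size = 4L, endian = "little")
      if (has_q) {
        writeBin(as.numeric(vertex_scalars[i]), con, size = 4L,
                 endian = "little")
        writeBin(as.raw(rgb[i, ]), con)
      }
    }
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4L, endian = "little")
    }
  } else {
    if (has_q)
      writeLines(sprintf("%.9g %.9g %.9g %.9g %d %d %d", v[, 1], v[, 2],
                         v[, 3], vertex_scalars, rgb[, 1], rgb[, 2],
                         rgb[, 3]), con)
    else
      writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
               con)
  }
  invisible(path)
}

# ---- OBJ ------------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(fl) == 0L)
    stop("unparseable OBJ file: ", path, call. = FALSE)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(p) as.numeric(p[2:4])))
  polys <- lapply(strsplit(trimws(fl), "\\s+"), function(p) {
    as.integer(vapply(strsplit(p[-1], "/"), `[[`, "", 1L))
  })
  surface_mesh(verts, triangulate_polys(polys, "OBJ"))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# facesym OBJ export", con)
  v <- mesh$vertices
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  f <- mesh$faces
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

# ---- selections and planes ------------------------------------------------

#' Read and write vertex-selection sidecar files
#'
#' Selections are stored as a JSON sidecar next to the mesh file: the mesh
#' name plus one 0-based, strictly increasing index array per named
#' measurement area.  In memory indices are 1-based; conversion happens
#' here at the boundary.
#'
#' @param path JSON file path.
#' @param selections list of `vertex_selection`s.
#' @param mesh_name name recorded in the file.
#' @param mesh optional `surface_mesh`; when given, loaded indices are
#'   validated against its vertex count.
#' @return `load_selections()` returns a named list of
#'   `vertex_selection`s with attribute `"mesh_name"`.
#' @export
save_selections <- function(selections, path, mesh_name = "mesh") {
  payload <- list(
    mesh = mesh_name,
    selections = lapply(unname(selections), function(s)
      list(name = s$name, indices = as.integer(s$indices - 1L))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_selections
#' @export
load_selections <- function(path, mesh = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  sels <- payload$selections
  out <- list()
  if (length(sels)) {
    if (is.data.frame(sels)) {
      nm <- sels$name
      idx <- sels$indices
    } else {
      nm <- vapply(sels, `[[`, "", "name")
      idx <- lapply(sels, `[[`, "indices")
    }
    for (i in seq_along(nm)) {
      ind <- as.integer(idx[[i]])
      if (length(ind) && any(ind < 0L))
        stop("negative index in selection '", nm[i], "'", call. = FALSE)
      if (length(ind) && any(diff(ind) <= 0L))
        stop("indices of selection '", nm[i],
             "' must be strictly increasing", call. = FALSE)
      out[[nm[i]]] <- vertex_selection(nm[i], ind + 1L, mesh)
    }
  }
  attr(out, "mesh_name") <- payload$mesh
  out
}

#' Planes: construction and JSON round trip
#'
#' A plane is stored as a unit normal `n` and offset `d` with
#' `n . x = d` (mm).  The constructed midsagittal plane and ground-truth
#' symmetry planes both use this record.
#'
#' @param normal 3-vector; normalised on construction.
#' @param offset scalar `d` (mm).
#' @param note provenance note.
#' @return an object of class `plane3`.
#' @export
plane3 <- function(normal, offset, note = "") {
  normal <- as.numeric(normal)
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop("plane normal must be non-zero", call. = FALSE)
  # scale the offset with the normal so n . x = d still holds
  structure(list(normal = normal / nn, offset = as.numeric(offset) / nn,
                 note = note), class = "plane3")
}

#' @export
print.plane3 <- function(x, ...) {
  cat(sprintf("<plane3> n = (%.6f, %.6f, %.6f), d = %.6f mm\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  if (nzchar(x$note)) cat("  ", x$note, "\n", sep = "")
  invisible(x)
}

#' @rdname plane3
#' @param plane a `plane3`.
#' @param path JSON file path.
#' @export
save_plane <- function(plane, path) {
  jsonlite::write_json(list(normal = plane$normal, offset = plane$offset,
                            note = plane$note),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname plane3
#' @export
load_plane <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$normal) || is.null(p$offset) || length(p$normal) != 3L)
    stop("malformed plane file: ", path, call. = FALSE)
  n <- as.numeric(p$normal)
  if (abs(sqrt(sum(n^2)) - 1) > 1e-9)
    warning("plane normal not unit length; re-normalizing")
  plane3(n, as.numeric(p$offset), if (is.null(p$note)) "" else p$note)
}

# signed point-plane distances along the normal
plane_distance <- function(plane, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  as.numeric(points %*% plane$normal - plane$offset)
}
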