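# Triangle-mesh container and PLY/OBJ input/output for molar crown scans.

#' Construct a triangle mesh
#'
#' @param vertices Numeric n-by-3 matrix of coordinates in mm.
#' @param faces Integer m-by-3 matrix of 1-based vertex indices.
#' @param up_axis Which axis is occlusal "up": `"z"` (default), `"y"`, or
#'   `"x"`. Crown meshes are assumed pre-oriented with the occlusal plane
#'   perpendicular to this axis.
#' @return An object of class `tooth_mesh`.
#' @export
tooth_mesh <- function(vertices, faces, up_axis = c("z", "y", "x")) {
  up_axis <- match.arg(up_axis)
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3L) stop_input("vertices must be n x 3")
  if (!is.numeric(vertices) || any(!is.finite(vertices))) {
    stop_input("vertex coordinates must be finite (no NaN/Inf)")
  }
  if (nrow(faces) < 1L) stop_input("mesh has no faces")
  if (anyNA(faces) || any(faces < 1L) || any(faces > nrow(vertices))) {
    stop_input("face indices out of range 1..", nrow(vertices))
  }
  m <- structure(list(vertices = vertices, faces = faces, up_axis = up_axis),
                 class = "tooth_mesh")
  if (all(triangle_areas(m) == 0)) {
    stop_input("mesh has no non-degenerate triangle")
  }
  m
}

#' @export
print.tooth_mesh <- function(x, ...) {
  cat("tooth_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces, up axis", x$up_axis, "\n")
  invisible(x)
}

# Per-face 3D areas (degenerate faces contribute 0).
triangle_areas <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  u <- V[F[, 2], , drop = FALSE] - a
  w <- V[F[, 3], , drop = FALSE] - a
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Column order that puts the two planar axes first and the up axis third.
axis_order <- function(up_axis) {
  switch(up_axis, z = c(1L, 2L, 3L), y = c(1L, 3L, 2L), x = c(2L, 3L, 1L))
}

# Vertex heights along the up axis.
mesh_heights <- function(mesh) mesh$vertices[, axis_order(mesh$up_axis)[3]]

#' Read a triangle mesh from PLY or OBJ
#'
#' Supports ASCII and binary-little-endian PLY with `vertex` (x, y, z) and
#' `face` (vertex index list) elements, and Wavefront OBJ `v`/`f` records.
#' Polygons with more than three vertices are triangulated by a fan split
#' from the first vertex.
#'
#' @param path Path to a `.ply` or `.obj` file.
#' @param up_axis Occlusal up axis of the stored coordinates.
#' @return A [tooth_mesh()].
#' @export
read_mesh <- function(path, up_axis = "z") {
  if (!file.exists(path)) stop_input("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  first <- readBin(path, "raw", n = 4L)
  looks_ply <- identical(rawToChar(first[1:3]), "ply")
  if (ext == "ply" || looks_ply) {
    read_ply(path, up_axis)
  } else if (ext == "obj") {
    read_obj(path, up_axis)
  } else {
    stop_input("unrecognized mesh format: ", path)
  }
}

fan_split <- function(idx) {
  # polygon vertex indices -> fan triangles from the first vertex
  k <- length(idx)
  if (k < 3L) stop_input("face with fewer than 3 vertices")
  cbind(idx[1], idx[2:(k - 1)], idx[3:k])
}

read_ply <- function(path, up_axis) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_hline <- function() {
    chars <- raw(0)
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (length(b) == 0L || b == as.raw(10L)) break
      chars <- c(chars, b)
    }
    sub("\r$", "", rawToChar(chars))
  }
  if (read_hline() != "ply") stop_input("not a PLY file (missing 'ply' magic): ", path)
  fmt <- NULL; elements <- list(); cur <- NULL
  lineno <- 1L
  repeat {
    line <- read_hline(); lineno <- lineno + 1L
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    } else {
      stop_input("PLY header line ", lineno, " not understood: ", line)
    }
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian")) {
    stop_input("unsupported PLY format '", fmt,
               "' (ascii or binary_little_endian only)")
  }
  if (!all(c("vertex", "face") %in% names(elements))) {
    stop_input("PLY file lacks vertex/face elements")
  }
  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                 short = 2, ushort = 2, int16 = 2, uint16 = 2,
                 int = 4, uint = 4, int32 = 4, uint32 = 4,
                 float = 4, float32 = 4, double = 8, float64 = 8)
  read_scalar <- function(type, n = 1L) {
    if (fmt == "ascii") stop("internal")
    sz <- type_size[[type]]
    what <- if (type %in% c("float", "float32", "double", "float64"))
      "numeric" else "integer"
    readBin(con, what, n = n, size = sz, endian = "little",
            signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
  }
  verts <- NULL; faces <- NULL
  if (fmt == "ascii") {
    for (el in elements) {
      rows <- vapply(seq_len(el$count), function(i) read_hline(), character(1))
      toks <- strsplit(trimws(rows), "\\s+")
      if (el$name == "vertex") {
        pnames <- vapply(el$props, `[[`, character(1), "name")
        xyz <- match(c("x", "y", "z"), pnames)
        if (anyNA(xyz)) stop_input("PLY vertex element lacks x/y/z")
        num <- t(vapply(toks, function(t) as.numeric(t[xyz]), numeric(3)))
        verts <- num
      } else if (el$name == "face") {
        faces <- do.call(rbind, lapply(seq_along(toks), function(i) {
          t <- as.integer(toks[[i]])
          k <- t[1]
          if (length(t) < k + 1L) {
            stop_input("PLY face row ", i, " truncated")
          }
          fan_split(t[2:(k + 1)] + 1L)
        }))
      }
    }
  } else {
    for (el in elements) {
      if (el$name == "vertex") {
        pnames <- vapply(el$props, `[[`, character(1), "name")
        vals <- matrix(NA_real_, el$count, length(el$props))
        for (i in seq_len(el$count)) {
          for (j in seq_along(el$props)) {
            vals[i, j] <- read_scalar(el$props[[j]]$type)
          }
        }
        xyz <- match(c("x", "y", "z"), pnames)
        if (anyNA(xyz)) stop_input("PLY vertex element lacks x/y/z")
        verts <- vals[, xyz, drop = FALSE]
      } else if (el$name == "face") {
        fl <- vector("list", el$count)
        p <- el$props[[1]]
        for (i in seq_len(el$count)) {
          k <- read_scalar(p$count_type)
          fl[[i]] <- fan_split(read_scalar(p$type, k) + 1L)
        }
        faces <- do.call(rbind, fl)
      } else {
        # skip unknown fixed-size element
        sz <- sum(vapply(el$props, function(p) type_size[[p$type]], numeric(1)))
        invisible(readBin(con, "raw", n = el$count * sz))
      }
    }
  }
  tooth_mesh(verts, faces, up_axis)
}

read_obj <- function(path, up_axis) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines_idx <- grep("^f\\s", lines)
  if (!length(vlines) || !length(flines_idx)) {
    stop_input("OBJ file lacks v/f records: ", path)
  }
  verts <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                    function(t) as.numeric(t[2:4]), numeric(3)))
  faces <- do.call(rbind, lapply(flines_idx, function(li) {
    tok <- strsplit(trimws(lines[li]), "\\s+")[[1]][-1]
    idx <- suppressWarnings(as.integer(sub("/.*", "", tok)))
    if (anyNA(idx)) stop_input("OBJ line ", li, " has a non-numeric face index")
    idx[idx < 0] <- nrow(verts) + 1L + idx[idx < 0]
    fan_split(idx)
  }))
  tooth_mesh(verts, faces, up_axis)
}

#' Write a triangle mesh to PLY (ascii) or OBJ
#'
#' @param mesh A [tooth_mesh()].
#' @param path Output path; format chosen by extension (`.ply` or `.obj`).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "tooth_mesh"))
  ext <- tolower(tools::file_ext(path))
  V <- mesh$vertices; F <- mesh$faces
  if (ext == "ply") {
    header <- c("ply", "format ascii 1.0",
                paste("element vertex", nrow(V)),
                "property float x", "property float y", "property float z",
                paste("element face", nrow(F)),
                "property list uchar int vertex_indices", "end_header")
    vrows <- sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3])
    frows <- sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L)
    writeLines(c(header, vrows, frows), path)
  } else if (ext == "obj") {
    vrows <- sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3])
    frows <- sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3])
    writeLines(c(vrows, frows), path)
  } else {
    stop_input("unrecognized output extension: ", path)
  }
  invisible(path)
}
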