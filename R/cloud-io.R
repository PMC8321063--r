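# PLY / OBJ / XYZ readers and writers.
# Internal unit is centimetres; PLY/OBJ carry no units, so readers accept an
# optional `scale` factor. Face indices are 0-based on disk (PLY) or 1-based
# (OBJ) and 1-based in memory (R convention).

PLY_TYPE_SIZE <- c(
  char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
  short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
  int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
  float = 4L, float32 = 4L, double = 8L, float64 = 8L
)

ply_read_scalar <- function(con, type, n = 1L) {
  size <- PLY_TYPE_SIZE[[type]]
  if (type %in% c("float", "float32", "double", "float64")) {
    readBin(con, "double", n = n, size = size, endian = "little")
  } else if (type %in% c("uchar", "uint8", "ushort", "uint16")) {
    readBin(con, "integer", n = n, size = size, signed = FALSE, endian = "little")
  } else if (type %in% c("uint", "uint32")) {
    readBin(con, "integer", n = n, size = 4L, endian = "little")
  } else {
    readBin(con, "integer", n = n, size = size, endian = "little")
  }
}

parse_ply_header <- function(con, path) {
  magic <- readLines(con, n = 1)
  if (!identical(magic, "ply")) abort(sprintf("%s: not a PLY file (line 1).", path))
  fmt <- NULL
  elements <- list()
  cur <- NULL
  lineno <- 1L
  repeat {
    line <- readLines(con, n = 1)
    lineno <- lineno + 1L
    if (length(line) == 0) abort(sprintf("%s: header ended before end_header.", path))
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0) abort(sprintf("%s: blank header line %d.", path, lineno))
    kw <- tok[1]
    if (kw == "comment" || kw == "obj_info") next
    if (kw == "format") {
      if (length(tok) != 3 || !tok[2] %in% c("ascii", "binary_little_endian")) {
        abort(sprintf("%s: unsupported format line %d: '%s'.", path, lineno, line))
      }
      fmt <- tok[2]
    } else if (kw == "element") {
      if (length(tok) != 3 || is.na(suppressWarnings(as.integer(tok[3])))) {
        abort(sprintf("%s: malformed element line %d.", path, lineno))
      }
      cur <- tok[2]
      elements[[cur]] <- list(count = as.integer(tok[3]),
                              props = character(), types = character(),
                              list_count_type = character())
    } else if (kw == "property") {
      if (is.null(cur)) abort(sprintf("%s: property before element, line %d.", path, lineno))
      if (tok[2] == "list") {
        if (length(tok) != 5 || !tok[3] %in% names(PLY_TYPE_SIZE) ||
            !tok[4] %in% names(PLY_TYPE_SIZE)) {
          abort(sprintf("%s: malformed list property, line %d.", path, lineno))
        }
        elements[[cur]]$props <- c(elements[[cur]]$props, tok[5])
        elements[[cur]]$types <- c(elements[[cur]]$types, paste0("list:", tok[4]))
        elements[[cur]]$list_count_type <- c(elements[[cur]]$list_count_type, tok[3])
      } else {
        if (length(tok) != 3 || !tok[2] %in% names(PLY_TYPE_SIZE)) {
          abort(sprintf("%s: unknown property type, line %d: '%s'.", path, lineno, line))
        }
        elements[[cur]]$props <- c(elements[[cur]]$props, tok[3])
        elements[[cur]]$types <- c(elements[[cur]]$types, tok[2])
        elements[[cur]]$list_count_type <- c(elements[[cur]]$list_count_type, NA_character_)
      }
    } else if (kw == "end_header") {
      break
    } else {
      abort(sprintf("%s: unknown header keyword '%s', line %d.", path, kw, lineno))
    }
  }
  if (is.null(fmt)) abort(sprintf("%s: missing format line.", path))
  list(format = fmt, elements = elements)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- parse_ply_header(con, path)
  out <- list()
  for (name in names(hdr$elements)) {
    el <- hdr$elements[[name]]
    is_list <- startsWith(el$types, "list:")
    if (hdr$format == "ascii") {
      rows <- readLines(con, n = el$count)
      if (length(rows) < el$count) {
        abort(sprintf("%s: element '%s' truncated (row %d).", path, name, length(rows) + 1L))
      }
      parsed <- lapply(seq_along(rows), function(i) {
        v <- suppressWarnings(as.numeric(strsplit(trimws(rows[i]), "\\s+")[[1]]))
        if (anyNA(v)) abort(sprintf("%s: non-numeric token in element '%s' row %d.", path, name, i))
        v
      })
      if (any(is_list)) {
        if (length(el$props) != 1) {
          abort(sprintf("%s: mixed list/scalar element '%s' unsupported.", path, name))
        }
        lists <- lapply(seq_along(parsed), function(i) {
          v <- parsed[[i]]
          k <- v[1]
          if (length(v) != k + 1) {
            abort(sprintf("%s: list length mismatch in '%s' row %d.", path, name, i))
          }
          v[-1]
        })
        out[[name]] <- list(lists = lists)
      } else {
        np <- length(el$props)
        bad <- which(vapply(parsed, length, 1L) != np)
        if (length(bad) > 0) {
          abort(sprintf("%s: wrong field count in element '%s' row %d.", path, name, bad[1]))
        }
        m <- do.call(rbind, parsed)
        colnames(m) <- el$props
        out[[name]] <- list(table = m)
      }
    } else {
      if (any(is_list)) {
        if (length(el$props) != 1) {
          abort(sprintf("%s: mixed list/scalar element '%s' unsupported.", path, name))
        }
        ct <- el$list_count_type[1]
        vt <- sub("^list:", "", el$types[1])
        lists <- vector("list", el$count)
        for (i in seq_len(el$count)) {
          k <- ply_read_scalar(con, ct, 1L)
          if (length(k) == 0) abort(sprintf("%s: element '%s' truncated at row %d.", path, name, i))
          vals <- ply_read_scalar(con, vt, as.integer(k))
          if (length(vals) != k) abort(sprintf("%s: element '%s' truncated at row %d.", path, name, i))
          lists[[i]] <- vals
        }
        out[[name]] <- list(lists = lists)
      } else {
        types <- el$types
        if (length(unique(types)) == 1) {
          vals <- ply_read_scalar(con, types[1], el$count * length(el$props))
          if (length(vals) != el$count * length(el$props)) {
            abort(sprintf("%s: element '%s' truncated.", path, name))
          }
          m <- matrix(as.numeric(vals), nrow = el$count, byrow = TRUE)
        } else {
          m <- matrix(NA_real_, el$count, length(el$props))
          for (i in seq_len(el$count)) {
            for (j in seq_along(types)) {
              v <- ply_read_scalar(con, types[j], 1L)
              if (length(v) == 0) abort(sprintf("%s: element '%s' truncated.", path, name))
              m[i, j] <- as.numeric(v)
            }
          }
        }
        colnames(m) <- el$props
        out[[name]] <- list(table = m)
      }
    }
  }
  out
}

#' Read a point cloud
#'
#' Supported formats: PLY (ascii or binary little-endian) and whitespace-
#' delimited XYZ text (3 columns, or 6 with RGB). Coordinates are interpreted
#' as centimetres after multiplication by `scale`. Per-point RGB colour is
#' preserved when present.
#'
#' @param path File path.
#' @param format `"ply"`, `"xyz"`, or `"auto"` (by file extension).
#' @param scale Unit conversion factor applied to coordinates (default 1).
#' @return A tibble with columns `x`, `y`, `z` (and `r`, `g`, `b` in
#'   `[0, 255]` when colour is present).
#' @export
read_point_cloud <- function(path, format = c("auto", "ply", "xyz"), scale = 1) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "xyz" || ext == "txt") "xyz" else "ply"
  }
  if (format == "xyz") {
    m <- tryCatch(as.matrix(utils::read.table(path)),
                  error = function(e) abort(sprintf("%s: %s", path, conditionMessage(e))))
    if (!ncol(m) %in% c(3L, 6L)) abort(sprintf("%s: expected 3 or 6 columns.", path))
    if (!is.numeric(m) || !all(is.finite(m))) abort(sprintf("%s: non-numeric coordinates.", path))
    cloud <- tibble::tibble(x = m[, 1] * scale, y = m[, 2] * scale, z = m[, 3] * scale)
    if (ncol(m) == 6) {
      cloud$r <- m[, 4]; cloud$g <- m[, 5]; cloud$b <- m[, 6]
    }
  } else {
    parsed <- read_ply(path)
    if (is.null(parsed$vertex)) abort(sprintf("%s: no vertex element.", path))
    vt <- parsed$vertex$table
    if (!all(c("x", "y", "z") %in% colnames(vt))) {
      abort(sprintf("%s: vertex element lacks x/y/z.", path))
    }
    cloud <- tibble::tibble(x = vt[, "x"] * scale, y = vt[, "y"] * scale,
                            z = vt[, "z"] * scale)
    if (all(c("red", "green", "blue") %in% colnames(vt))) {
      cloud$r <- vt[, "red"]; cloud$g <- vt[, "green"]; cloud$b <- vt[, "blue"]
    }
  }
  if (nrow(cloud) == 0) abort(sprintf("%s: empty point cloud.", path))
  cloud
}

#' Write a point cloud
#'
#' @param cloud A tibble/data frame with `x`, `y`, `z` (optional `r`, `g`,
#'   `b`).
#' @param path Output path.
#' @param format `"ply"` or `"xyz"`.
#' @param binary For PLY: write binary little-endian (bit-exact round trip,
#'   default) or ascii.
#' @return The path, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = c("ply", "xyz"), binary = TRUE) {
  format <- match.arg(format)
  m <- as_xyz_matrix(cloud)
  has_rgb <- is.data.frame(cloud) && all(c("r", "g", "b") %in% names(cloud))
  if (format == "xyz") {
    tab <- if (has_rgb) cbind(m, cloud$r, cloud$g, cloud$b) else m
    utils::write.table(tab, path, row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply",
           sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", nrow(m)),
           "property double x", "property double y", "property double z")
  if (has_rgb) {
    hdr <- c(hdr, "property uchar red", "property uchar green", "property uchar blue")
  }
  hdr <- c(hdr, "end_header")
  writeLines(hdr, con, sep = "\n")
  if (binary) {
    for (i in seq_len(nrow(m))) {
      writeBin(as.numeric(m[i, ]), con, size = 8, endian = "little")
      if (has_rgb) {
        writeBin(as.raw(c(cloud$r[i], cloud$g[i], cloud$b[i])), con)
      }
    }
  } else {
    rows <- apply(m, 1, function(r) paste(format(r, digits = 17), collapse = " "))
    if (has_rgb) {
      rows <- paste(rows, as.integer(cloud$r), as.integer(cloud$g), as.integer(cloud$b))
    }
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}

#' Construct a triangle mesh
#'
#' @param vertices A tibble/matrix of vertex coordinates (`x`, `y`, `z`, cm).
#' @param faces An integer matrix with 3 columns of 1-based vertex indices.
#' @return A `triangle_mesh` object: list with `$vertices` (tibble) and
#'   `$faces` (integer matrix).
#' @export
triangle_mesh <- function(vertices, faces) {
  vm <- as_xyz_matrix(vertices, "vertices")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3) abort("`faces` must have 3 columns.")
  if (any(faces < 1) || any(faces > nrow(vm))) {
    abort(sprintf("Face index out of range [1, %d].", nrow(vm)))
  }
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] | faces[, 1] == faces[, 3]
  if (any(degen)) {
    abort(sprintf("Degenerate face (repeated vertex index) at row %d.", which(degen)[1]))
  }
  dimnames(faces) <- NULL
  structure(list(vertices = xyz_tibble(vm), faces = faces),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("Triangle mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

fan_triangulate <- function(idx) {
  k <- length(idx)
  if (k < 3) abort("Face with fewer than 3 vertices.")
  if (k == 3) return(matrix(idx, 1, 3))
  cbind(idx[1], idx[2:(k - 1)], idx[3:k])
}

#' Read a triangle mesh
#'
#' Supported formats: PLY (ascii / binary little-endian) and OBJ (geometry
#' only). OBJ indices are converted from 1-based at the boundary; polygonal
#' faces with more than 3 vertices are fan-triangulated.
#'
#' @inheritParams read_point_cloud
#' @param format `"ply"`, `"obj"`, or `"auto"`.
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "ply", "obj"), scale = 1) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "obj") "obj" else "ply"
  }
  if (format == "obj") {
    lines <- readLines(path)
    vlines <- lines[startsWith(lines, "v ")]
    flines <- lines[startsWith(lines, "f ")]
    if (length(vlines) == 0) abort(sprintf("%s: no vertices.", path))
    verts <- t(vapply(strsplit(trimws(sub("^v", "", vlines)), "\\s+"), function(tok) {
      v <- suppressWarnings(as.numeric(tok[1:3]))
      if (anyNA(v)) abort(sprintf("%s: malformed vertex line.", path))
      v
    }, numeric(3)))
    faces <- do.call(rbind, lapply(flines, function(ln) {
      tok <- strsplit(trimws(sub("^f", "", ln)), "\\s+")[[1]]
      idx <- suppressWarnings(as.integer(vapply(strsplit(tok, "/"), `[`, "", 1)))
      if (anyNA(idx) || any(idx < 1)) abort(sprintf("%s: malformed face line '%s'.", path, ln))
      fan_triangulate(idx)
    }))
    if (is.null(faces)) abort(sprintf("%s: no faces.", path))
    return(triangle_mesh(verts * scale, faces))
  }
  parsed <- read_ply(path)
  if (is.null(parsed$vertex) || is.null(parsed$face)) {
    abort(sprintf("%s: PLY mesh needs vertex and face elements.", path))
  }
  vt <- parsed$vertex$table
  verts <- cbind(vt[, "x"], vt[, "y"], vt[, "z"]) * scale
  faces <- do.call(rbind, lapply(parsed$face$lists, function(v) {
    fan_triangulate(as.integer(v) + 1L)  # PLY is 0-based on disk
  }))
  triangle_mesh(verts, faces)
}

#' Write a triangle mesh
#'
#' @param mesh A [triangle_mesh()].
#' @param path Output path.
#' @param format `"ply"` or `"obj"`.
#' @param binary For PLY: binary little-endian (default) or ascii.
#' @return The path, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("ply", "obj"), binary = TRUE) {
  format <- match.arg(format)
  vm <- as_xyz_matrix(mesh$vertices, "vertices")
  faces <- mesh$faces
  if (format == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.17g %.17g %.17g", vm[, 1], vm[, 2], vm[, 3]), con)
    writeLines(sprintf("f %d %d %d", faces[, 1], faces[, 2], faces[, 3]), con)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply",
           sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", nrow(vm)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(faces)),
           "property list uchar int vertex_indices",
           "end_header")
  writeLines(hdr, con, sep = "\n")
  if (binary) {
    for (i in seq_len(nrow(vm))) {
      writeBin(as.numeric(vm[i, ]), con, size = 8, endian = "little")
    }
    for (i in seq_len(nrow(faces))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(faces[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    writeLines(sprintf("%.17g %.17g %.17g", vm[, 1], vm[, 2], vm[, 3]), con)
    writeLines(sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L), con)
  }
  invisible(path)
}

#' Read reference anthropometric measurements
#'
#' Reads the gold-standard tape measurements taken by anthropometrists.
#'
#' @param path CSV with columns `subject_id`, `height_cm`, `waist_cm`,
#'   `hip_cm`.
#' @return A tibble with those columns.
#' @export
read_reference_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "height_cm", "waist_cm", "hip_cm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing columns %s.", path, paste(missing_cols, collapse = ", ")))
  }
  for (col in c("height_cm", "waist_cm", "hip_cm")) {
    if (!is.numeric(df[[col]]) || any(!is.finite(df[[col]])) || any(df[[col]] <= 0)) {
      abort(sprintf("%s: column %s must be positive and finite.", path, col))
    }
  }
  tibble::as_tibble(df[need])
}
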