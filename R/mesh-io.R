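#' Load a colored triangle mesh from PLY or OBJ
#'
#' Supports ascii and binary-little-endian PLY with per-vertex `uchar` or
#' float colors, and Wavefront OBJ with the common `v x y z r g b` color
#' extension. 8-bit color channels are rescaled to `[0, 1]`; meshes without
#' colors default to mid-gray (0.5, 0.5, 0.5).
#'
#' @param path file path.
#' @param format `"ply"`, `"obj"`, or `NULL` to infer from the extension.
#' @return a [surface_mesh()].
#' @export
load_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) {
    stop_facesim("cannot read mesh file: ", path, class = "facesim_io_error")
  }
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
    ply = read_ply(path),
    obj = read_obj(path),
    stop_facesim("unsupported mesh format: ", format, class = "facesim_io_error")
  )
}

#' Save a mesh to PLY or OBJ
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param format `"ply"`, `"obj"`, or `NULL` to infer from the extension.
#' @param binary write binary-little-endian PLY instead of ascii.
#' @export
save_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
    ply = write_ply(mesh, path, binary = binary),
    obj = write_obj(mesh, path),
    stop_facesim("unsupported mesh format: ", format, class = "facesim_io_error")
  )
  invisible(path)
}

ply_type_size <- c(
  char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
  short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
  int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
  float = 4L, float32 = 4L, double = 8L, float64 = 8L
)

ply_read_prop <- function(payload, offsets, type) {
  size <- ply_type_size[[type]]
  idx <- as.vector(outer(seq_len(size), offsets, `+`))
  what <- if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
  signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16"))
  readBin(payload[idx], what,
    n = length(offsets), size = size,
    signed = signed, endian = "little"
  )
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) {
      stop_facesim("PLY header not terminated", class = "facesim_io_error")
    }
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
  }
  if (!startsWith(header[1], "ply")) {
    stop_facesim("not a PLY file: ", path, class = "facesim_io_error")
  }
  fmt_line <- grep("^format ", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop_facesim("unsupported PLY format: ", fmt, class = "facesim_io_error")
  }

  # parse element/property structure
  elements <- list()
  cur <- NULL
  for (ln in header) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[5], type = "list", count_type = tok[3], item_type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1]] <- list(name = tok[3], type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (!all(c("vertex", "face") %in% names(elements))) {
    stop_facesim("PLY file lacks vertex/face elements", class = "facesim_io_error")
  }
  ve <- elements[["vertex"]]
  fe <- elements[["face"]]
  vprop_names <- vapply(ve$props, `[[`, "", "name")

  if (fmt == "ascii") {
    lines <- readLines(con)
    lines <- lines[nzchar(trimws(lines))]
    vlines <- lines[seq_len(ve$count)]
    flines <- lines[ve$count + seq_len(fe$count)]
    vdat <- matrix(
      as.numeric(unlist(strsplit(trimws(vlines), "\\s+"))),
      nrow = ve$count, byrow = TRUE
    )
    colnames(vdat) <- vprop_names
    ftok <- strsplit(trimws(flines), "\\s+")
    cnts <- vapply(ftok, function(t) as.integer(t[1]), integer(1))
    if (any(cnts != 3L)) {
      stop_facesim("non-triangular face at index ", which(cnts != 3L)[1],
        class = "facesim_format_error"
      )
    }
    faces <- t(vapply(ftok, function(t) as.integer(t[2:4]), integer(3))) + 1L
  } else {
    payload <- readBin(con, "raw", n = file.size(path))
    sizes <- vapply(ve$props, function(p) ply_type_size[[p$type]], integer(1))
    stride <- sum(sizes)
    offs <- cumsum(c(0L, sizes[-length(sizes)]))
    base <- (seq_len(ve$count) - 1L) * stride
    vdat <- matrix(0, ve$count, length(ve$props))
    colnames(vdat) <- vprop_names
    for (i in seq_along(ve$props)) {
      vdat[, i] <- ply_read_prop(payload, base + offs[i], ve$props[[i]]$type)
    }
    fp <- fe$props[[1]]
    if (fp$type != "list") {
      stop_facesim("PLY face element must be a list property", class = "facesim_io_error")
    }
    csize <- ply_type_size[[fp$count_type]]
    isize <- ply_type_size[[fp$item_type]]
    fstride <- csize + 3L * isize
    fbase <- ve$count * stride + (seq_len(fe$count) - 1L) * fstride
    cnts <- ply_read_prop(payload, fbase, fp$count_type)
    if (any(cnts != 3L)) {
      stop_facesim("non-triangular face at index ", which(cnts != 3L)[1],
        class = "facesim_format_error"
      )
    }
    faces <- matrix(0L, fe$count, 3)
    for (k in 1:3) {
      faces[, k] <- ply_read_prop(payload, fbase + csize + (k - 1L) * isize, fp$item_type)
    }
    faces <- faces + 1L
  }

  verts <- vdat[, c("x", "y", "z"), drop = FALSE]
  colors <- NULL
  col_names <- intersect(c("red", "green", "blue"), vprop_names)
  if (length(col_names) == 3) {
    colors <- vdat[, c("red", "green", "blue"), drop = FALSE]
    ctypes <- vapply(ve$props, `[[`, "", "type")[match(col_names, vprop_names)]
    if (all(ctypes %in% c("uchar", "uint8", "char", "int8"))) colors <- colors / 255
    colors <- clamp(colors, 0, 1)
  }
  surface_mesh(verts, faces, colors)
}

write_ply <- function(mesh, path, binary = FALSE) {
  n <- nrow(mesh$vertices)
  m <- nrow(mesh$faces)
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    paste("element vertex", n),
    "property float x", "property float y", "property float z",
    "property uchar red", "property uchar green", "property uchar blue",
    paste("element face", m),
    "property list uchar int vertex_indices",
    "end_header"
  )
  col8 <- round(clamp(mesh$colors, 0, 1) * 255)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    vraw <- writeBin(as.vector(t(mesh$vertices)), raw(), size = 4, endian = "little")
    craw <- as.raw(as.vector(t(col8)))
    block <- rbind(matrix(vraw, nrow = 12), matrix(craw, nrow = 3))
    writeBin(as.vector(block), con)
    if (m > 0) {
      fraw <- writeBin(as.integer(t(mesh$faces) - 1L), raw(), size = 4, endian = "little")
      fblock <- rbind(matrix(as.raw(3L), nrow = 1, ncol = m), matrix(fraw, nrow = 12))
      writeBin(as.vector(fblock), con)
    }
  } else {
    vl <- sprintf(
      "%.6f %.6f %.6f %d %d %d",
      mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3],
      col8[, 1], col8[, 2], col8[, 3]
    )
    fl <- if (m > 0) {
      sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L)
    } else {
      character(0)
    }
    writeLines(c(header, vl, fl), path)
  }
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  vtok <- strsplit(sub("^v\\s+", "", vlines), "\\s+")
  nums <- lapply(vtok, as.numeric)
  lens <- lengths(nums)
  verts <- t(vapply(nums, function(x) x[1:3], numeric(3)))
  colors <- NULL
  if (all(lens >= 6)) {
    colors <- clamp(t(vapply(nums, function(x) x[4:6], numeric(3))), 0, 1)
  }
  ftok <- strsplit(sub("^f\\s+", "", flines), "\\s+")
  nfv <- lengths(ftok)
  if (any(nfv != 3L)) {
    stop_facesim("non-triangular face at index ", which(nfv != 3L)[1],
      class = "facesim_format_error"
    )
  }
  faces <- t(vapply(ftok, function(t) {
    as.integer(vapply(strsplit(t, "/", fixed = TRUE), `[[`, "", 1))
  }, integer(3)))
  surface_mesh(verts, faces, colors)
}

write_obj <- function(mesh, path) {
  vl <- sprintf(
    "v %.6f %.6f %.6f %.6f %.6f %.6f",
    mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3],
    mesh$colors[, 1], mesh$colors[, 2], mesh$colors[, 3]
  )
  fl <- sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  writeLines(c("# facesim OBJ export", vl, fl), path)
  invisible(path)
}
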