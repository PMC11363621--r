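#' Read a triangulated surface mesh from STL or PLY
#'
#' Reads binary and ASCII STL, and ASCII / binary-little-endian PLY
#' (vertex and face elements). Coordinates are taken to be millimetres;
#' no unit metadata is trusted from the file. On load, duplicate vertices
#' within `1e-6` mm are merged (binary STL stores every triangle
#' independently) and zero-area faces are dropped; if the mesh still
#' violates a `surface_mesh` invariant afterwards the failed invariant is
#' named in the error.
#'
#' @param path File path.
#' @param format `"auto"` (sniff from content/extension), `"stl"` or `"ply"`.
#' @return A [surface_mesh()].
#' @seealso [write_mesh()], [validate_mesh()]
#' @export
read_mesh <- function(path, format = c("auto", "stl", "ply")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mesh: no such file: ", path,
                               call. = FALSE)
  if (format == "auto") format <- sniff_mesh_format(path)
  raw <- switch(format,
    stl = read_stl(path),
    ply = read_ply(path)
  )
  w <- weld_mesh(raw$vertices, raw$faces, tol = 1e-6)
  surface_mesh(w$vertices, w$faces)
}

#' Write a surface mesh to STL or PLY
#'
#' @param mesh A [surface_mesh()].
#' @param path Output file path.
#' @param format `"auto"` (from extension), `"stl"` or `"ply"`.
#' @param ascii Write the ASCII dialect instead of binary. Binary STL stores
#'   float32 coordinates (the de-facto standard), so round-trip agreement is
#'   limited to about 1.2e-7 relative; ASCII STL and both PLY dialects are
#'   written with full double precision.
#' @return Invisibly, `path`.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply"),
                       ascii = FALSE) {
  if (!inherits(mesh, "surface_mesh")) {
    rep <- validate_mesh(mesh)
    bad <- rep$check[!rep$pass & rep$invariant]
    if (length(bad) > 0) {
      stop("refusing to write invalid mesh; failed check(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    mesh <- surface_mesh(mesh$vertices, mesh$faces)
  }
  if (!dir.exists(dirname(path))) {
    stop("cannot write mesh: directory '", dirname(path),
         "' does not exist", call. = FALSE)
  }
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, stl = "stl", ply = "ply",
                     stop("cannot infer mesh format from extension '.", ext,
                          "'; pass format=", call. = FALSE))
  }
  switch(format,
    stl = if (ascii) write_stl_ascii(mesh, path) else write_stl_binary(mesh, path),
    ply = if (ascii) write_ply_ascii(mesh, path) else write_ply_binary(mesh, path)
  )
  invisible(path)
}

sniff_mesh_format <- function(path) {
  head <- readBin(path, "raw", n = 16)
  if (length(head) >= 3 && rawToChar(head[1:3]) == "ply") return("ply")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("stl", "ply")) return(ext)
  "stl"
}

# ---- STL ------------------------------------------------------------------

read_stl <- function(path) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 80)
  is_binary <- FALSE
  if (size >= 84) {
    ntri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && size == 84 + 50 * as.double(ntri)) {
      is_binary <- TRUE
    }
  }
  if (is_binary) {
    ntri <- as.integer(ntri)
    if (ntri < 1) stop("binary STL contains no triangles", call. = FALSE)
    rec <- readBin(con, "raw", n = 50 * ntri)
    # each record: 12 float32 (normal + 3 vertices) + uint16 attribute
    idx <- rep(seq(0, by = 50, length.out = ntri), each = 48) +
      rep(1:48, times = ntri)
    vals <- readBin(rec[idx], "double", n = 12 * ntri, size = 4,
                    endian = "little")
    vals <- matrix(vals, ncol = 12, byrow = TRUE)
    verts <- rbind_vertices(vals[, 4:6, drop = FALSE],
                            vals[, 7:9, drop = FALSE],
                            vals[, 10:12, drop = FALSE])
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0) {
      stop("cannot parse ASCII STL: vertex count not a multiple of 3",
           call. = FALSE)
    }
    nums <- vapply(strsplit(trimws(vl), "\\s+"), function(p) {
      as.numeric(p[2:4])
    }, numeric(3))
    verts <- t(nums)
  }
  ntri <- nrow(verts) / 3
  list(vertices = verts,
       faces = matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE))
}

rbind_vertices <- function(v1, v2, v3) {
  n <- nrow(v1)
  out <- matrix(0, 3 * n, 3)
  out[seq(1, 3 * n, by = 3), ] <- v1
  out[seq(2, 3 * n, by = 3), ] <- v2
  out[seq(3, 3 * n, by = 3), ] <- v3
  out
}

face_normals <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
             ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
             ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  len <- sqrt(rowSums(n^2))
  len[len < 1e-30] <- 1
  n / len
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(f)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(n), con, size = 4, endian = "little")
  nrm <- face_normals(v, f)
  # 12 float32 per triangle, row-per-triangle
  block <- cbind(nrm, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                 v[f[, 3], , drop = FALSE])
  vals <- as.numeric(t(block))
  payload <- writeBin(vals, raw(), size = 4, endian = "little")
  payload <- matrix(payload, nrow = 48)
  attr_bytes <- matrix(as.raw(0), nrow = 2, ncol = n)
  writeBin(as.vector(rbind(payload, attr_bytes)), con)
  invisible(path)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  nrm <- face_normals(v, f)
  fmt <- function(m) sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3])
  lines <- c(
    "solid ulnadiff",
    as.vector(rbind(
      paste0("  facet normal ", fmt(nrm)),
      "    outer loop",
      paste0("      vertex ", fmt(v[f[, 1], , drop = FALSE])),
      paste0("      vertex ", fmt(v[f[, 2], , drop = FALSE])),
      paste0("      vertex ", fmt(v[f[, 3], , drop = FALSE])),
      "    endloop",
      "  endfacet")),
    "endsolid ulnadiff")
  writeLines(lines, path)
  invisible(path)
}

# ---- PLY ------------------------------------------------------------------

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is ASCII lines terminated by "end_header"
  header <- character()
  repeat {
    line <- read_bin_line(con)
    if (is.null(line)) stop("cannot parse PLY: unterminated header",
                            call. = FALSE)
    header <- c(header, line)
    if (identical(trimws(line), "end_header")) break
    if (length(header) > 1000) stop("cannot parse PLY header", call. = FALSE)
  }
  if (!identical(trimws(header[1]), "ply")) {
    stop("cannot parse PLY: missing 'ply' magic", call. = FALSE)
  }
  fmt_line <- grep("^format ", trimws(header), value = TRUE)
  if (length(fmt_line) != 1) stop("cannot parse PLY: missing format line",
                                  call. = FALSE)
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop("unsupported PLY format: ", fmt, call. = FALSE)
  }

  # element/property layout (vertex and face only)
  elems <- list()
  cur <- NULL
  for (line in trimws(header)) {
    tok <- strsplit(line, "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elems[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      cur$props[[length(cur$props) + 1]] <-
        if (tok[2] == "list") list(kind = "list", count_type = tok[3],
                                   item_type = tok[4], name = tok[5])
        else list(kind = "scalar", type = tok[2], name = tok[3])
    }
  }
  if (!is.null(cur)) elems[[cur$name]] <- cur
  if (is.null(elems$vertex) || is.null(elems$face)) {
    stop("cannot parse PLY: need vertex and face elements", call. = FALSE)
  }

  if (fmt == "ascii") {
    body <- readLines(con, warn = FALSE)
    body <- body[nzchar(trimws(body))]
    nv <- elems$vertex$count
    nf <- elems$face$count
    if (length(body) < nv + nf) stop("truncated ASCII PLY", call. = FALSE)
    vt <- utils::read.table(text = body[seq_len(nv)])
    pnames <- vapply(elems$vertex$props, `[[`, "", "name")
    verts <- as.matrix(vt[, match(c("x", "y", "z"), pnames), drop = FALSE])
    fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    faces <- do.call(rbind, lapply(fl, function(tok) {
      n <- as.integer(tok[1])
      if (n != 3) stop("PLY face is not a triangle", call. = FALSE)
      as.integer(tok[2:4]) + 1L
    }))
  } else {
    nv <- elems$vertex$count
    pr <- elems$vertex$props
    sizes <- vapply(pr, function(p) ply_type_size(p$type), 1L)
    verts <- matrix(NA_real_, nv, 3)
    pnames <- vapply(pr, `[[`, "", "name")
    for (i in seq_len(nv)) {
      row <- numeric(length(pr))
      for (j in seq_along(pr)) {
        row[j] <- read_ply_scalar(con, pr[[j]]$type)
      }
      verts[i, ] <- row[match(c("x", "y", "z"), pnames)]
    }
    nf <- elems$face$count
    fp <- elems$face$props[[1]]
    faces <- matrix(NA_integer_, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- read_ply_scalar(con, fp$count_type)
      if (cnt != 3) stop("PLY face is not a triangle", call. = FALSE)
      faces[i, ] <- as.integer(c(read_ply_scalar(con, fp$item_type),
                                 read_ply_scalar(con, fp$item_type),
                                 read_ply_scalar(con, fp$item_type))) + 1L
    }
  }
  list(vertices = verts, faces = faces)
}

read_bin_line <- function(con) {
  out <- raw()
  repeat {
    b <- readBin(con, "raw", n = 1)
    if (length(b) == 0) return(if (length(out)) rawToChar(out) else NULL)
    if (b == as.raw(10)) return(rawToChar(out))
    if (b != as.raw(13)) out <- c(out, b)
  }
}

ply_type_size <- function(type) {
  switch(type,
         char = , uchar = , int8 = , uint8 = 1L,
         short = , ushort = , int16 = , uint16 = 2L,
         int = , uint = , int32 = , uint32 = , float = , float32 = 4L,
         double = , float64 = 8L,
         stop("unknown PLY type: ", type, call. = FALSE))
}

read_ply_scalar <- function(con, type) {
  switch(type,
    char = , int8 = readBin(con, "integer", 1, size = 1, signed = TRUE),
    uchar = , uint8 = readBin(con, "integer", 1, size = 1, signed = FALSE),
    short = , int16 = readBin(con, "integer", 1, size = 2, signed = TRUE,
                              endian = "little"),
    ushort = , uint16 = readBin(con, "integer", 1, size = 2, signed = FALSE,
                                endian = "little"),
    int = , int32 = readBin(con, "integer", 1, size = 4, endian = "little"),
    uint = , uint32 = readBin(con, "integer", 1, size = 4, endian = "little"),
    float = , float32 = readBin(con, "double", 1, size = 4, endian = "little"),
    double = , float64 = readBin(con, "double", 1, size = 8, endian = "little"),
    stop("unknown PLY type: ", type, call. = FALSE))
}

ply_header <- function(mesh, fmt) {
  c("ply",
    paste("format", fmt, "1.0"),
    "comment ulnadiff surface mesh (mm)",
    paste("element vertex", nrow(mesh$vertices)),
    "property double x", "property double y", "property double z",
    paste("element face", nrow(mesh$faces)),
    "property list uchar int vertex_indices",
    "end_header")
}

write_ply_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  lines <- c(ply_header(mesh, "ascii"),
             sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
             sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]))
  writeLines(lines, path)
  invisible(path)
}

write_ply_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(ply_header(mesh, "binary_little_endian"),
                                  collapse = "\n"), "\n")), con)
  writeBin(as.numeric(t(mesh$vertices)), con, size = 8, endian = "little")
  f <- mesh$faces - 1L
  for (i in seq_len(nrow(f))) {
    writeBin(as.raw(3), con)
    writeBin(as.integer(f[i, ]), con, size = 4, endian = "little")
  }
  invisible(path)
}
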