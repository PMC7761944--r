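# STL (binary/ASCII) and PLY (ascii/binary_little_endian) readers and writers.
# STL binary little-endian is the canonical interchange format; PLY carries a
# per-vertex float property "quality" when a scalar field (distance map) must
# persist, since STL cannot store per-vertex scalars.

#' Read a surface mesh
#'
#' Reads STL (binary or ASCII) or PLY (ascii or binary_little_endian).
#' STL stores a triangle soup, so exact-duplicate vertices (within 1e-9 mm)
#' are welded on import. Degenerate faces are dropped with a message.
#'
#' @param path file path.
#' @param format "auto" (default; sniffed from extension and content),
#'   "stl_binary", "stl_ascii" or "ply".
#' @return a \linkS4class{TriangleMesh}; PLY "quality" becomes the vertex
#'   field.
#' @export
readMesh <- function(path, format = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "ply") "ply" else sniffStlFormat(path)
  }
  mesh <- switch(format,
    stl_binary = readStlBinary(path),
    stl_ascii = readStlAscii(path),
    ply = readPly(path),
    stop("unknown mesh format: ", format))
  if (!nFaces(mesh)) stop("invalid input: mesh '", path, "' has no triangles")
  mesh
}

sniffStlFormat <- function(path) {
  head <- readBin(path, "raw", n = 512L)
  if (length(head) >= 5 && rawToChar(head[1:5]) == "solid") {
    # binary files may also start with "solid"; check size consistency
    sz <- file.size(path)
    if (sz >= 84) {
      ntri <- readBin(head[81:84], "integer", size = 4, endian = "little")
      if (!is.na(ntri) && sz == 84 + 50 * as.numeric(ntri) && ntri > 0)
        return("stl_binary")
    }
    return("stl_ascii")
  }
  "stl_binary"
}

readStlBinary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  ntri <- readBin(con, "integer", size = 4, endian = "little")
  if (is.na(ntri) || ntri < 0) stop("corrupt STL: bad triangle count")
  if (ntri == 0) return(TriangleMesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  rec <- readBin(con, "raw", n = 50L * ntri)
  if (length(rec) < 50L * ntri) stop("corrupt STL: truncated records")
  m <- matrix(rec, nrow = 50L)
  coordRaw <- as.raw(m[13:48, ])  # 9 floats per triangle (after 3-float normal)
  vals <- readBin(coordRaw, "numeric", n = 9L * ntri, size = 4,
                  endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  faces <- matrix(seq_len(3L * ntri), ncol = 3, byrow = TRUE)
  weldVertices(TriangleMesh(pts, faces))
}

readStlAscii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (!length(vl)) return(TriangleMesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  parts <- strsplit(trimws(vl), "\\s+")
  bad <- vapply(parts, length, integer(1)) != 4L
  if (any(bad)) stop("corrupt ASCII STL: malformed vertex line")
  pts <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(pts)) stop("corrupt ASCII STL: non-numeric coordinates")
  if (nrow(pts) %% 3L != 0L) stop("corrupt ASCII STL: vertex count not a multiple of 3")
  faces <- matrix(seq_len(nrow(pts)), ncol = 3, byrow = TRUE)
  weldVertices(TriangleMesh(pts, faces))
}

#' Write a surface mesh
#'
#' @param mesh a \linkS4class{TriangleMesh}; open meshes are allowed (no
#'   watertightness requirement for I/O).
#' @param path output file path.
#' @param format "stl_binary" (default), "stl_ascii", "ply_ascii" or
#'   "ply_binary". Both PLY variants persist the vertex field as property
#'   "quality" when present.
#' @return the path, invisibly.
#' @export
writeMesh <- function(mesh, path, format = "stl_binary") {
  switch(format,
    stl_binary = writeStlBinary(mesh, path),
    stl_ascii = writeStlAscii(mesh, path),
    ply_ascii = writePly(mesh, path, binary = FALSE),
    ply_binary = writePly(mesh, path, binary = TRUE),
    stop("unknown mesh format: ", format))
  invisible(path)
}

writeStlBinary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  f <- mesh@faces
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  v <- mesh@vertices
  n <- faceNormals(mesh)
  # 12 floats + uint16 attribute per record
  tri <- cbind(n, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
               v[f[, 3], , drop = FALSE])
  floats <- writeBin(as.numeric(t(tri)), raw(), size = 4, endian = "little")
  fm <- matrix(floats, nrow = 48L)
  rec <- rbind(fm, matrix(raw(2L * nrow(f)), nrow = 2L))
  writeBin(as.raw(rec), con)
}

writeStlAscii <- function(mesh, path) {
  f <- mesh@faces
  v <- mesh@vertices
  n <- faceNormals(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]), con)
    writeLines("    outer loop", con)
    for (j in 1:3) {
      p <- v[f[i, j], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid mesh", con)
}

writePly <- function(mesh, path, binary = FALSE) {
  v <- mesh@vertices
  f <- mesh@faces
  hasQ <- length(mesh@field) > 0
  hdr <- c("ply",
           paste("format", if (binary) "binary_little_endian" else "ascii", "1.0"),
           paste("element vertex", nrow(v)),
           "property double x", "property double y", "property double z",
           if (hasQ) "property double quality",
           paste("element face", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    vd <- if (hasQ) cbind(v, mesh@field) else v
    writeBin(as.numeric(t(vd)), con, size = 8, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    if (hasQ) {
      writeLines(sprintf("%.17g %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3],
                         mesh@field), con)
    } else {
      writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    }
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
}

readPly <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readPlyLine(con)
    hdr <- c(hdr, line)
    if (line == "end_header") break
    if (length(hdr) > 200) stop("corrupt PLY: header not terminated")
  }
  if (hdr[1] != "ply") stop("corrupt PLY: missing magic")
  fmt <- sub("^format\\s+", "", grep("^format", hdr, value = TRUE)[1])
  binary <- grepl("binary_little_endian", fmt)
  nv <- as.integer(sub(".*vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*face\\s+", "", grep("^element face", hdr, value = TRUE)[1]))
  # vertex property names/types in declared order
  vi <- grep("^element vertex", hdr)
  fi <- grep("^element face", hdr)
  vprops <- hdr[(vi + 1):(fi - 1)]
  vprops <- vprops[grepl("^property\\s", vprops)]
  ptype <- vapply(strsplit(vprops, "\\s+"), `[`, "", 2L)
  pname <- vapply(strsplit(vprops, "\\s+"), `[`, "", 3L)
  sizes <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  if (!all(ptype %in% names(sizes)))
    stop("unsupported PLY vertex property type")
  if (binary) {
    np <- length(pname)
    if (length(unique(ptype)) == 1L) {
      vals <- readBin(con, "numeric", n = nv * np, size = sizes[[ptype[1]]],
                      endian = "little")
      vd <- matrix(vals, ncol = np, byrow = TRUE)
    } else {
      vd <- matrix(0, nv, np)
      for (i in seq_len(nv))
        for (j in seq_len(np))
          vd[i, j] <- readBin(con, "numeric", n = 1L, size = sizes[[ptype[j]]],
                              endian = "little")
    }
    faces <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", n = 1L))
      idx <- readBin(con, "integer", n = cnt, size = 4, endian = "little")
      if (cnt != 3L) stop("only triangle PLY faces are supported")
      faces[i, ] <- idx + 1L
    }
  } else {
    txt <- readLines(con, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt) < nv + nf) stop("corrupt PLY: truncated body")
    vd <- do.call(rbind, lapply(strsplit(trimws(txt[seq_len(nv)]), "\\s+"),
                                as.numeric))
    fl <- lapply(strsplit(trimws(txt[nv + seq_len(nf)]), "\\s+"), as.numeric)
    if (any(vapply(fl, `[`, 0, 1L) != 3)) stop("only triangle PLY faces are supported")
    faces <- do.call(rbind, lapply(fl, function(x) as.integer(x[2:4]) + 1L))
  }
  xyz <- match(c("x", "y", "z"), pname)
  if (anyNA(xyz)) stop("corrupt PLY: missing x/y/z properties")
  q <- match("quality", pname)
  TriangleMesh(vd[, xyz, drop = FALSE], faces,
               field = if (!is.na(q)) vd[, q] else numeric(0))
}

readPlyLine <- function(con) {
  out <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (!length(b)) stop("corrupt PLY: unexpected end of file")
    if (b == as.raw(10L)) break
    out <- c(out, b)
  }
  sub("\r$", "", rawToChar(out))
}

#' Save a mesh with its scalar field
#'
#' Convenience wrapper writing a PLY with the per-vertex "quality" property
#' (e.g. a signed distance map in mm).
#'
#' @param mesh a \linkS4class{TriangleMesh} with a vertex field.
#' @param path output path.
#' @param binary write binary_little_endian (default) or ascii.
#' @return the path, invisibly.
#' @export
saveScalarField <- function(mesh, path, binary = TRUE) {
  if (!length(mesh@field)) stop("mesh has no per-vertex field to save")
  writeMesh(mesh, path, if (binary) "ply_binary" else "ply_ascii")
}
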