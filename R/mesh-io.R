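#' Export a valve mesh to standard surface formats
#'
#' Writers for STL (ASCII or binary), PLY (ASCII), Wavefront OBJ, and legacy
#' ASCII VTK. Region tags are exported as a per-face scalar where the format
#' allows (VTK `CELL_DATA`, PLY face property); STL and OBJ carry geometry
#' only (OBJ groups faces by region). Chordae are included as line cells in
#' VTK; surface-only formats export the leaflet triangles.
#'
#' @param mesh A `valve_mesh`.
#' @param path Output file path; the extension selects the format unless
#'   `format` is given.
#' @param format One of `"stl"`, `"stl_binary"`, `"ply"`, `"obj"`, `"vtk"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path,
                       format = c("auto", "stl", "stl_binary", "ply", "obj",
                                  "vtk")) {
  validate_valve_mesh(mesh)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, stl = "stl", ply = "ply", obj = "obj", vtk = "vtk",
                     stop("cannot infer mesh format from extension '.", ext,
                          "'", call. = FALSE))
  }
  switch(format,
         stl = .write_stl_ascii(mesh, path),
         stl_binary = .write_stl_binary(mesh, path),
         ply = .write_ply(mesh, path),
         obj = .write_obj(mesh, path),
         vtk = .write_vtk(mesh, path))
  invisible(path)
}

.face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

.write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces; n <- .face_normals(mesh)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("solid valve", con)
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                       n[i, 1L], n[i, 2L], n[i, 3L]), con)
    writeLines("    outer loop", con)
    for (k in 1:3)
      writeLines(sprintf("      vertex %.9g %.9g %.9g",
                         v[f[i, k], 1L], v[f[i, k], 2L], v[f[i, k], 3L]), con)
    writeLines(c("    endloop", "  endfacet"), con)
  }
  writeLines("endsolid valve", con)
}

.write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces; n <- .face_normals(mesh)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(f))) {
    writeBin(as.numeric(c(n[i, ], t(v[f[i, ], ]))), con, size = 4L,
             endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
}

.write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  regions <- c(ANT = 0L, P1 = 1L, P2 = 2L, P3 = 3L)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "property int region",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]), con)
  writeLines(sprintf("3 %d %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L,
                     f[, 3L] - 1L,
                     regions[mesh$face_region]), con)
}

.write_obj <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# valve mesh", con)
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]), con)
  for (reg in unique(mesh$face_region)) {
    writeLines(sprintf("g %s", reg), con)
    fr <- f[mesh$face_region == reg, , drop = FALSE]
    writeLines(sprintf("f %d %d %d", fr[, 1L], fr[, 2L], fr[, 3L]), con)
  }
}

.write_vtk <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces; ch <- mesh$chordae
  regions <- c(ANT = 0L, P1 = 1L, P2 = 2L, P3 = 3L)
  ncell <- nrow(f) + nrow(ch)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "valve mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]), con)
  writeLines(sprintf("CELLS %d %d", ncell, 4L * nrow(f) + 3L * nrow(ch)), con)
  writeLines(sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L),
             con)
  if (nrow(ch))
    writeLines(sprintf("2 %d %d", ch[, 1L] - 1L, ch[, 2L] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", ncell), con)
  writeLines(as.character(c(rep(5L, nrow(f)), rep(3L, nrow(ch)))), con)
  writeLines(c(sprintf("CELL_DATA %d", ncell), "SCALARS region int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(c(regions[mesh$face_region],
                            rep(-1L, nrow(ch)))), con)
}

#' Export landmarks as JSON
#'
#' Writes `{landmark name: [x, y, z], ...}` in millimetres.
#'
#' @param mesh A `valve_mesh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks_json <- function(mesh, path) {
  validate_valve_mesh(mesh)
  pts <- lapply(seq_along(mesh$landmarks), function(i)
    as.numeric(mesh$vertices[mesh$landmarks[i], ]))
  names(pts) <- names(mesh$landmarks)
  jsonlite::write_json(pts, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Export a solver input deck
#'
#' Plain-text node/element listing for downstream structural solvers, with
#' named node sets. Fixed column layout:
#' \preformatted{
#' *NODE            id, x, y, z            (mm, comma-separated)
#' *ELEMENT_SHELL   id, n1, n2, n3, region
#' *ELEMENT_TRUSS   id, n1, n2             (chordae)
#' *NSET <name>     one node id per line   (ANNULUS, FREE_EDGE, and one
#'                                          CLIP_<k> set per station)
#' }
#'
#' @param mesh A `valve_mesh`.
#' @param path Output path.
#' @param clip_stations Named station fractions used to define per-station
#'   candidate node sets; default [default_clip_stations()].
#' @return `path`, invisibly.
#' @export
write_solver_deck <- function(mesh, path,
                              clip_stations = default_clip_stations()) {
  validate_valve_mesh(mesh)
  con <- file(path, "w"); on.exit(close(con))
  v <- mesh$vertices
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.9g, %.9g, %.9g", seq_len(nrow(v)),
                     v[, 1L], v[, 2L], v[, 3L]), con)
  writeLines("*ELEMENT_SHELL", con)
  f <- mesh$faces
  writeLines(sprintf("%d, %d, %d, %d, %s", seq_len(nrow(f)),
                     f[, 1L], f[, 2L], f[, 3L], mesh$face_region), con)
  if (nrow(mesh$chordae)) {
    writeLines("*ELEMENT_TRUSS", con)
    writeLines(sprintf("%d, %d, %d", seq_len(nrow(mesh$chordae)),
                       mesh$chordae[, 1L], mesh$chordae[, 2L]), con)
  }
  info <- mesh$free_edge_info
  n_rows <- mesh$meta$n_rows
  annulus <- if (!is.null(n_rows))
    (seq_along(mesh$meta$theta) - 1L) * n_rows + 1L
  else unname(mesh$landmarks[c("COMM_A", "COMM_P", "AM_ANT", "AM_POST")])
  writeLines("*NSET ANNULUS", con)
  writeLines(as.character(annulus), con)
  writeLines("*NSET FREE_EDGE", con)
  writeLines(as.character(unlist(mesh$free_edge)), con)
  for (k in seq_along(clip_stations)) {
    s <- clip_stations[k]
    ant <- info[info$side == "ANT", ]
    post <- info[info$side == "POST", ]
    writeLines(sprintf("*NSET CLIP_%d", k), con)
    writeLines(as.character(c(ant$vertex[which.min(abs(ant$s - s))],
                              post$vertex[which.min(abs(post$s - s))])), con)
  }
  invisible(path)
}
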