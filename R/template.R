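#' Construct the parametric template mitral valve mesh
#'
#' Builds a triangulated valve surface from the six morphological scalars.
#' The annulus is a planar ellipse in z = 0 with the intercommissural axis
#' along x (semi-axis `d_ic/2`) and the aorto-mural axis along y (semi-axis
#' `d_am/2`); the origin is the annulus centroid. Leaflets descend from the
#' annulus along straight "columns" tilted toward the valve centerline, so
#' the surface geodesic from an annulus station to its free-edge tip equals
#' the prescribed leaflet depth exactly. The posterior side is split into the
#' three scallops P1, P2, P3 over equal annular arcs; the anterior leaflet
#' spans the remaining half.
#'
#' Chordae tendineae are modeled as line (truss) elements connecting
#' free-edge vertices to one of two papillary anchor points placed below the
#' annulus plane; the chord count is configurable (chords may share an
#' attachment vertex, mimicking branching).
#'
#' @param params An [mv_parameters()] object.
#' @param resolution Integer >= 4; number of element rows through the leaflet
#'   depth and half the number of arc intervals per region. Landmark
#'   distances are resolution-independent.
#' @param n_chordae Number of chordal elements (>= 0).
#' @param dip_angle_deg Angle below the annulus plane at which leaflet
#'   columns descend (degrees, in (0, 90]); default 60.
#' @param papillary_depth Depth of the two papillary anchor points below the
#'   annulus plane (mm).
#'
#' @return A `valve_mesh` object: a list with elements
#'   \describe{
#'     \item{vertices}{N x 3 numeric matrix (mm).}
#'     \item{faces}{F x 3 integer matrix of triangle vertex indices.}
#'     \item{face_region}{character vector of length F, values in
#'       `ANT`, `P1`, `P2`, `P3`.}
#'     \item{chordae}{C x 2 integer matrix (leaflet vertex, papillary anchor
#'       vertex).}
#'     \item{landmarks}{named integer vector mapping landmark names
#'       (`AM_ANT`, `AM_POST`, `COMM_A`, `COMM_P`, `ANT_TIP`, `P2_TIP`,
#'       `P1_BASE`, `P1_TIP`, `P3_BASE`, `P3_TIP`) to vertex indices.}
#'     \item{free_edge}{list of integer vectors; ordered closed loop(s) of
#'       the coaptation (free) edge.}
#'     \item{free_edge_info}{data frame with the coaptation-line station of
#'       every free-edge vertex: columns `vertex`, `side` (`ANT`/`POST`/
#'       `COMM`), `s` (fraction of the coaptation span from the anterior
#'       commissure).}
#'     \item{tied_pairs}{k x 2 integer matrix of clip-tied vertex pairs
#'       (empty for a fresh template).}
#'     \item{meta}{construction record (parameters, resolution, angles).}
#'   }
#' @examples
#' m <- build_template(mv_default_parameters(), resolution = 6)
#' measure_parameters(m)
#' @export
build_template <- function(params, resolution = 8L,
                           n_chordae = 4971L,
                           dip_angle_deg = 60,
                           papillary_depth = 25) {
  validate_mv_parameters(params)
  resolution <- as.integer(resolution)
  if (is.na(resolution) || resolution < 4L)
    stop("resolution must be an integer >= 4", call. = FALSE)
  if (n_chordae < 0) stop("n_chordae must be >= 0", call. = FALSE)
  if (dip_angle_deg <= 0 || dip_angle_deg > 90)
    stop("dip_angle_deg must lie in (0, 90]", call. = FALSE)

  R <- resolution
  a_ic <- params[["d_ic"]] / 2   # semi-axis along x
  b_am <- params[["d_am"]] / 2   # semi-axis along y

  ## ring angles: anterior arc [0, pi] in 2R steps, each posterior scallop
  ## arc of pi/3 in 2R steps -> every region mid-angle is a mesh column
  th_ant  <- seq(0, pi, length.out = 2L * R + 1L)
  th_post <- seq(pi, 2 * pi, length.out = 6L * R + 1L)
  theta <- c(th_ant[-(2L * R + 1L)], th_post[-(6L * R + 1L)])
  n_ring <- length(theta)                      # 8R columns

  region_mid <- c(ANT = pi / 2, P1 = 7 * pi / 6, P2 = 3 * pi / 2,
                  P3 = 11 * pi / 6)
  depth_at_mid <- c(ANT = params[["aml"]], P1 = params[["p1"]],
                    P2 = params[["p2"]], P3 = params[["p3"]])

  d_theta <- .depth_profile(theta, region_mid, depth_at_mid)

  ## straight columns: annulus point + t * depth * unit direction
  phi <- dip_angle_deg * pi / 180
  px <- a_ic * cos(theta); py <- b_am * sin(theta)
  rn <- sqrt(px^2 + py^2)
  ux <- -cos(phi) * px / rn
  uy <- -cos(phi) * py / rn
  uz <- rep(-sin(phi), n_ring)

  n_rows <- R + 1L
  t_row <- seq(0, 1, length.out = n_rows)
  ## vertex index: column-major by ring station, rows annulus -> free edge
  vid <- function(i_ring, j_row) (i_ring - 1L) * n_rows + j_row
  nv <- n_ring * n_rows
  vertices <- matrix(0, nv, 3L)
  for (i in seq_len(n_ring)) {
    idx <- vid(i, seq_len(n_rows))
    vertices[idx, 1L] <- px[i] + t_row * d_theta[i] * ux[i]
    vertices[idx, 2L] <- py[i] + t_row * d_theta[i] * uy[i]
    vertices[idx, 3L] <- t_row * d_theta[i] * uz[i]
  }

  ## faces: quad strip between adjacent columns (wrapping), two triangles
  faces <- matrix(0L, 2L * n_ring * R, 3L)
  face_region <- character(2L * n_ring * R)
  f <- 0L
  for (i in seq_len(n_ring)) {
    i2 <- if (i == n_ring) 1L else i + 1L
    mid_ang <- .mid_angle(theta[i], if (i == n_ring) 2 * pi else theta[i2])
    reg <- .region_of_angle(mid_ang)
    for (j in seq_len(R)) {
      a <- vid(i, j);  b <- vid(i, j + 1L)
      c <- vid(i2, j); d <- vid(i2, j + 1L)
      faces[f + 1L, ] <- c(a, c, b)
      faces[f + 2L, ] <- c(b, c, d)
      face_region[f + 1L] <- reg
      face_region[f + 2L] <- reg
      f <- f + 2L
    }
  }

  ring_index_of <- function(ang) which.min(abs(theta - ang))
  landmarks <- c(
    COMM_A  = vid(ring_index_of(0), 1L),
    COMM_P  = vid(ring_index_of(pi), 1L),
    AM_ANT  = vid(ring_index_of(pi / 2), 1L),
    AM_POST = vid(ring_index_of(3 * pi / 2), 1L),
    ANT_TIP = vid(ring_index_of(pi / 2), n_rows),
    P2_TIP  = vid(ring_index_of(3 * pi / 2), n_rows),
    P1_BASE = vid(ring_index_of(7 * pi / 6), 1L),
    P1_TIP  = vid(ring_index_of(7 * pi / 6), n_rows),
    P3_BASE = vid(ring_index_of(11 * pi / 6), 1L),
    P3_TIP  = vid(ring_index_of(11 * pi / 6), n_rows)
  )

  free_vertices <- vid(seq_len(n_ring), n_rows)
  side <- ifelse(theta %in% c(0, pi), "COMM",
                 ifelse(theta < pi, "ANT", "POST"))
  s <- ifelse(theta <= pi, theta / pi, (2 * pi - theta) / pi)
  free_edge_info <- data.frame(vertex = free_vertices, side = side, s = s,
                               stringsAsFactors = FALSE)

  ## papillary anchors: anterolateral (x > 0) and posteromedial (x < 0)
  anchors <- rbind(c( a_ic / 2, 0, -papillary_depth),
                   c(-a_ic / 2, 0, -papillary_depth))
  vertices <- rbind(vertices, anchors)
  anchor_ids <- nv + 1:2

  chordae <- matrix(integer(0), 0L, 2L)
  if (n_chordae > 0) {
    leaf <- free_vertices[((seq_len(n_chordae) - 1L) %% n_ring) + 1L]
    anchor <- ifelse(vertices[leaf, 1L] >= 0, anchor_ids[1L], anchor_ids[2L])
    chordae <- cbind(leaf, as.integer(anchor))
  }
  dimnames(chordae) <- NULL

  mesh <- structure(list(
    vertices = vertices,
    faces = faces,
    face_region = face_region,
    chordae = chordae,
    landmarks = landmarks,
    free_edge = list(free_vertices),
    free_edge_info = free_edge_info,
    tied_pairs = matrix(integer(0), 0L, 2L),
    meta = list(params = unclass(params), resolution = R,
                dip_angle_deg = dip_angle_deg,
                papillary_depth = papillary_depth,
                theta = theta, n_rows = n_rows,
                anchor_ids = anchor_ids)
  ), class = "valve_mesh")
  validate_valve_mesh(mesh)
  mesh
}

## piecewise-linear periodic depth profile through the four region
## mid-angle knots (exact at each knot)
.depth_profile <- function(theta, mid, depth) {
  knots_th <- c(mid - 2 * pi, mid, mid + 2 * pi)
  knots_d <- rep(unname(depth), 3L)
  o <- order(knots_th)
  stats::approx(knots_th[o], knots_d[o], xout = theta)$y
}

.mid_angle <- function(a, b) (a + b) / 2

.region_of_angle <- function(ang) {
  ang <- ang %% (2 * pi)
  if (ang < pi) "ANT"
  else if (ang < 4 * pi / 3) "P1"
  else if (ang < 5 * pi / 3) "P2"
  else "P3"
}

#' Validate a valve mesh
#'
#' Checks index integrity (faces, chordae, landmarks, free edge all refer to
#' existing vertices), landmark completeness, and that free-edge chains have
#' no repeated consecutive vertices.
#'
#' @param mesh A `valve_mesh`.
#' @return Invisibly `TRUE`; stops with a message on violation.
#' @export
validate_valve_mesh <- function(mesh) {
  if (!inherits(mesh, "valve_mesh")) stop("not a valve_mesh", call. = FALSE)
  nv <- nrow(mesh$vertices)
  idx_ok <- function(i) length(i) == 0L || (all(i >= 1L) && all(i <= nv))
  if (!idx_ok(mesh$faces)) stop("face index out of range", call. = FALSE)
  if (!idx_ok(mesh$chordae)) stop("chord index out of range", call. = FALSE)
  if (!idx_ok(unlist(mesh$free_edge)))
    stop("free-edge index out of range", call. = FALSE)
  need <- c("AM_ANT", "AM_POST", "COMM_A", "COMM_P", "ANT_TIP", "P2_TIP")
  missing <- setdiff(need, names(mesh$landmarks))
  if (length(missing))
    stop("missing landmark(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!idx_ok(mesh$landmarks)) stop("landmark index out of range", call. = FALSE)
  for (loop in mesh$free_edge) {
    if (length(loop) > 1L && any(diff(loop) == 0L))
      stop("free-edge chain repeats a vertex consecutively", call. = FALSE)
  }
  invisible(TRUE)
}

#' Number of chordal elements in a mesh
#' @param mesh A `valve_mesh`.
#' @return Integer chord count.
#' @export
n_chordae <- function(mesh) nrow(mesh$chordae)

#' Remove chordal elements at random
#'
#' Deterministically (given `seed`) selects `n_remove` chordal elements and
#' drops them; vertices, faces and all other mesh content are untouched.
#' Used to weaken leaflet tethering so that some template-derived geometries
#' exhibit regurgitation.
#'
#' @param mesh A `valve_mesh`.
#' @param n_remove Number of chords to remove (0 <= n_remove <= chord count).
#' @param seed Integer seed controlling the selection.
#' @return The pruned `valve_mesh`.
#' @examples
#' m <- build_template(mv_default_parameters(), resolution = 4, n_chordae = 4971)
#' n_chordae(prune_chordae(m, 888, seed = 1))  # 4083
#' @export
prune_chordae <- function(mesh, n_remove, seed = 1L) {
  validate_valve_mesh(mesh)
  nc <- n_chordae(mesh)
  n_remove <- as.integer(n_remove)
  if (is.na(n_remove) || n_remove < 0L)
    stop("n_remove must be a non-negative integer", call. = FALSE)
  if (n_remove > nc)
    stop(sprintf("cannot remove %d chords from a mesh with only %d",
                 n_remove, nc), call. = FALSE)
  if (n_remove == 0L) return(mesh)
  drop <- with_local_seed(seed, sample.int(nc, n_remove))
  mesh$chordae <- mesh$chordae[-drop, , drop = FALSE]
  mesh$meta$pruned <- c(mesh$meta$pruned, list(list(seed = seed, removed = sort(drop))))
  mesh
}

#' Measure the six morphological parameters of a valve mesh
#'
#' Inverse of [build_template()]: annular diameters are the Euclidean
#' distances between the commissural and aorto-mural landmark pairs; leaflet
#' and scallop depths are surface geodesics (shortest paths over the mesh
#' edge graph) from each region's annular base landmark to its free-edge tip
#' landmark. `depth_mode = "chordal"` uses the straight base-to-tip distance
#' instead (identical on the straight-column template).
#'
#' @param mesh A `valve_mesh` with a complete landmark map.
#' @param depth_mode `"geodesic"` (default) or `"chordal"`.
#' @return An [mv_parameters()] object.
#' @export
measure_parameters <- function(mesh, depth_mode = c("geodesic", "chordal")) {
  depth_mode <- match.arg(depth_mode)
  need <- c("COMM_A", "COMM_P", "AM_ANT", "AM_POST", "ANT_TIP", "P2_TIP",
            "P1_BASE", "P1_TIP", "P3_BASE", "P3_TIP")
  for (nm in need)
    if (!nm %in% names(mesh$landmarks))
      stop("missing landmark: ", nm, call. = FALSE)
  lm <- function(nm) mesh$vertices[mesh$landmarks[[nm]], ]
  d_ic <- sqrt(sum((lm("COMM_A") - lm("COMM_P"))^2))
  d_am <- sqrt(sum((lm("AM_ANT") - lm("AM_POST"))^2))

  pairs <- list(aml = c("AM_ANT", "ANT_TIP"), p1 = c("P1_BASE", "P1_TIP"),
                p2 = c("AM_POST", "P2_TIP"), p3 = c("P3_BASE", "P3_TIP"))
  if (depth_mode == "chordal") {
    depths <- vapply(pairs, function(p)
      sqrt(sum((lm(p[1L]) - lm(p[2L]))^2)), numeric(1))
  } else {
    g <- .mesh_graph(mesh)
    from <- vapply(pairs, function(p) mesh$landmarks[[p[1L]]], integer(1))
    to <- vapply(pairs, function(p) mesh$landmarks[[p[2L]]], integer(1))
    dmat <- igraph::distances(g, v = from, to = to,
                              weights = igraph::E(g)$weight)
    depths <- diag(dmat)
    names(depths) <- names(pairs)
  }
  mv_parameters(aml = depths[["aml"]], p1 = depths[["p1"]],
                p2 = depths[["p2"]], p3 = depths[["p3"]],
                d_am = d_am, d_ic = d_ic)
}

## undirected weighted graph over the leaflet surface edges
.mesh_graph <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- t(apply(e, 1L, sort))
  e <- unique(e)
  w <- sqrt(rowSums((mesh$vertices[e[, 1L], , drop = FALSE] -
                     mesh$vertices[e[, 2L], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  ## pad isolated vertices (chordal anchors) so indices align
  nv <- nrow(mesh$vertices)
  if (igraph::vcount(g) < nv)
    g <- igraph::add_vertices(g, nv - igraph::vcount(g))
  igraph::E(g)$weight <- w
  g
}

#' @export
print.valve_mesh <- function(x, ...) {
  cat(sprintf(
    "valve_mesh: %d vertices, %d faces, %d chordae, %d free-edge loop(s), %d tied pair(s)\n",
    nrow(x$vertices), nrow(x$faces), nrow(x$chordae),
    length(x$free_edge), nrow(x$tied_pairs)))
  p <- tryCatch(measure_parameters(x, depth_mode = "chordal"),
                error = function(e) NULL)
  if (!is.null(p)) {
    cat("measured (chordal):\n")
    print(round(unclass(p), 3))
  }
  invisible(x)
}

#' Run code with a temporary RNG state
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded operations never disturb the session RNG.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  force(seed)   # must precede the RNG snapshot: evaluating `seed` may draw
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
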