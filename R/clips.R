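#' Default clip stations on the coaptation line
#'
#' Six stations expressed as fractions of the coaptation span measured from
#' the anterior commissure. Stations 1, 3, 4, 5 spread across the line;
#' stations 2 and 6 sit adjacent to each other in the posterior-commissure
#' half. Fractions are configuration values, not anatomical constants.
#'
#' @return Named numeric vector `loc1`..`loc6` of fractions in (0, 1).
#' @export
default_clip_stations <- function() {
  c(loc1 = 0.20, loc2 = 0.70, loc3 = 0.35, loc4 = 0.50, loc5 = 0.62,
    loc6 = 0.80)
}

#' Enumerate MitraClip scenarios
#'
#' Default scenario set: the untreated valve plus one scenario per clip
#' station (7 scenarios); optional multi-clip scenarios are appended.
#' Ordering and ids are deterministic.
#'
#' @param singles Include the six single-clip scenarios (default `TRUE`).
#' @param pairs List of length-2 integer vectors of station indices (1..6).
#' @param triples List of length-3 integer vectors of station indices.
#' @param stations Named station fractions; default
#'   [default_clip_stations()].
#' @return List of `clip_scenario` objects (fields `id`, `indices`, `s`).
#' @examples
#' length(enumerate_scenarios())  # 7
#' @export
enumerate_scenarios <- function(singles = TRUE, pairs = list(),
                                triples = list(),
                                stations = default_clip_stations()) {
  mk <- function(idx) {
    idx <- as.integer(idx)
    if (any(idx < 1L | idx > length(stations)))
      stop("clip station indices must lie in 1..", length(stations),
           call. = FALSE)
    if (anyDuplicated(idx))
      stop("duplicate clip station in one scenario: ",
           paste(idx, collapse = ","), call. = FALSE)
    structure(list(
      id = if (length(idx) == 0L) "no_clip"
           else paste0("clip_", paste(sort(idx), collapse = "_")),
      indices = sort(idx),
      s = unname(stations[sort(idx)])
    ), class = "clip_scenario")
  }
  out <- list(mk(integer(0)))
  if (singles) out <- c(out, lapply(seq_along(stations), mk))
  out <- c(out, lapply(pairs, function(p) {
    if (length(p) != 2L) stop("pairs must have 2 indices", call. = FALSE); mk(p)
  }))
  out <- c(out, lapply(triples, function(p) {
    if (length(p) != 3L) stop("triples must have 3 indices", call. = FALSE); mk(p)
  }))
  ids <- vapply(out, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate scenario: ", paste(ids[duplicated(ids)], collapse = ", "),
         call. = FALSE)
  out
}

#' Apply a clip at a coaptation-line station
#'
#' Emulates edge-to-edge repair on the open geometry: the anterior-edge and
#' posterior-edge free-edge vertices nearest to coaptation fraction `s` are
#' moved to their common midpoint and recorded as a tied pair. Topology is
#' unchanged; re-applying the same station is idempotent.
#'
#' @param mesh A `valve_mesh` whose `free_edge_info` labels anterior and
#'   posterior chains.
#' @param s Fraction of the coaptation span in (0, 1), measured from the
#'   anterior commissure.
#' @return The clipped `valve_mesh` (with `tied_pairs` extended).
#' @export
apply_clip <- function(mesh, s) {
  validate_valve_mesh(mesh)
  info <- mesh$free_edge_info
  if (is.null(info) || !all(c("vertex", "side", "s") %in% names(info)))
    stop("mesh free edge does not identify anterior/posterior chains",
         call. = FALSE)
  if (s <= 0 || s >= 1)
    stop("clip fraction s must lie strictly inside (0, 1)", call. = FALSE)
  ant <- info[info$side == "ANT", ]
  post <- info[info$side == "POST", ]
  if (nrow(ant) == 0L || nrow(post) == 0L)
    stop("mesh free edge does not identify anterior/posterior chains",
         call. = FALSE)
  va <- ant$vertex[which.min(abs(ant$s - s))]
  vp <- post$vertex[which.min(abs(post$s - s))]
  mid <- (mesh$vertices[va, ] + mesh$vertices[vp, ]) / 2
  mesh$vertices[va, ] <- mid
  mesh$vertices[vp, ] <- mid
  pair <- c(min(va, vp), max(va, vp))
  if (!any(mesh$tied_pairs[, 1L] == pair[1L] &
           mesh$tied_pairs[, 2L] == pair[2L]))
    mesh$tied_pairs <- rbind(mesh$tied_pairs, pair)
  dimnames(mesh$tied_pairs) <- NULL
  mesh
}

#' Apply a whole clip scenario
#'
#' @param mesh A `valve_mesh`.
#' @param scenario A `clip_scenario` from [enumerate_scenarios()].
#' @return The mesh with all of the scenario's clips applied.
#' @export
apply_scenario <- function(mesh, scenario) {
  stopifnot(inherits(scenario, "clip_scenario"))
  for (s in scenario$s) mesh <- apply_clip(mesh, s)
  mesh
}

#' Orifice-area report for a (possibly clipped) valve
#'
#' Splits the free-edge loop at the tied clip pairs into sub-loops (k ties
#' on one loop give k + 1 openings), projects each sub-loop onto the
#' best-fit annulus plane, and measures its polygon area with the shoelace
#' formula (orientation-normalized, so areas are non-negative). A
#' self-intersecting projected polygon triggers a warning and is replaced by
#' its largest simple sub-polygon, flagged in the report.
#'
#' @param mesh A `valve_mesh`.
#' @param tied_pairs Optional k x 2 matrix of tied vertex pairs; defaults to
#'   `mesh$tied_pairs`.
#' @return An `orifice_report`: list with `openings` (numeric areas, mm^2),
#'   `total_area`, `n_openings`, `flagged` (logical per opening).
#' @export
orifice_area <- function(mesh, tied_pairs = mesh$tied_pairs) {
  validate_valve_mesh(mesh)
  loops <- mesh$free_edge
  if (!is.null(tied_pairs) && nrow(tied_pairs) > 0L) {
    for (i in seq_len(nrow(tied_pairs)))
      loops <- .split_loops_at_tie(loops, tied_pairs[i, 1L],
                                   tied_pairs[i, 2L], mesh$vertices)
  }
  plane <- .annulus_plane(mesh)
  areas <- numeric(0); flagged <- logical(0)
  for (loop in loops) {
    uv <- .project_to_plane(mesh$vertices[loop, , drop = FALSE], plane)
    res <- .simple_polygon_area(uv)
    areas <- c(areas, res$area)
    flagged <- c(flagged, res$flagged)
  }
  structure(list(openings = areas, total_area = sum(areas),
                 n_openings = length(areas), flagged = flagged),
            class = "orifice_report")
}

#' @export
print.orifice_report <- function(x, ...) {
  cat(sprintf("orifice: %d opening(s), total %.2f mm^2\n",
              x$n_openings, x$total_area))
  invisible(x)
}

## split whichever loop contains both tie vertices into two sub-loops at
## the tie; ties whose vertices sit on different loops are ignored (cannot
## occur for clips applied to one coaptation loop)
.split_loops_at_tie <- function(loops, va, vb, vertices) {
  out <- list()
  for (loop in loops) {
    ia <- match(va, loop); ib <- match(vb, loop)
    if (is.na(ia) || is.na(ib)) { out <- c(out, list(loop)); next }
    i1 <- min(ia, ib); i2 <- max(ia, ib)
    if (i2 - i1 < 2L || (i1 == 1L && i2 == length(loop))) {
      out <- c(out, list(loop)); next          # adjacent: nothing to split
    }
    out <- c(out, list(loop[i1:i2]), list(loop[c(i2:length(loop), 1:i1)]))
  }
  out
}

## best-fit plane through the annulus (row-0) ring, via PCA of the
## landmark-bearing annulus vertices; falls back to all free-edge vertices
.annulus_plane <- function(mesh) {
  ann <- mesh$landmarks[intersect(c("COMM_A", "COMM_P", "AM_ANT", "AM_POST",
                                    "P1_BASE", "P3_BASE"),
                                  names(mesh$landmarks))]
  pts <- mesh$vertices[ann, , drop = FALSE]
  if (nrow(pts) < 3L) pts <- mesh$vertices[unlist(mesh$free_edge), , drop = FALSE]
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, ctr))
  list(origin = ctr, u = sv$v[, 1L], v = sv$v[, 2L])
}

.project_to_plane <- function(pts, plane) {
  rel <- sweep(pts, 2L, plane$origin)
  cbind(rel %*% plane$u, rel %*% plane$v)
}

## shoelace area of an ordered closed polygon given as 2-D vertices; if the
## polygon self-intersects, take the largest simple sub-polygon and flag
.simple_polygon_area <- function(uv) {
  n <- nrow(uv)
  if (n < 3L) return(list(area = 0, flagged = FALSE))
  shoelace <- function(p) {
    i2 <- c(2:nrow(p), 1L)
    abs(sum(p[, 1L] * p[i2, 2L] - p[i2, 1L] * p[, 2L])) / 2
  }
  if (!.polygon_self_intersects(uv)) {
    return(list(area = shoelace(uv), flagged = FALSE))
  }
  warning("self-intersecting projected orifice polygon; reporting largest simple sub-polygon",
          call. = FALSE)
  best <- 0
  ## greedy: drop vertices until simple, track best simple sub-polygon area
  sub <- uv
  while (nrow(sub) > 3L && .polygon_self_intersects(sub)) {
    sub <- sub[-1L, , drop = FALSE]
    if (!.polygon_self_intersects(sub)) best <- max(best, shoelace(sub))
  }
  if (best == 0 && !.polygon_self_intersects(sub)) best <- shoelace(sub)
  list(area = best, flagged = TRUE)
}

.polygon_self_intersects <- function(uv) {
  n <- nrow(uv)
  if (n < 4L) return(FALSE)
  nxt <- c(2:n, 1L)
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next          # shared endpoint around the wrap
      if (seg_int(uv[i, ], uv[nxt[i], ], uv[j, ], uv[nxt[j], ])) return(TRUE)
    }
  }
  FALSE
}

#' Sweep a set of clip scenarios over one valve
#'
#' Applies each scenario to a fresh copy of the mesh, measures the orifice
#' report, and tabulates the relative area reduction versus the untreated
#' (no-clip) configuration.
#'
#' @param mesh A `valve_mesh`.
#' @param scenarios List of `clip_scenario` objects; default the 7-scenario
#'   set of [enumerate_scenarios()].
#' @return Data frame with one row per scenario: `id`, `n_clips`,
#'   `n_openings`, `total_area_mm2`, `reduction` (1 - area/area(no-clip)),
#'   `flagged`.
#' @export
scenario_sweep <- function(mesh, scenarios = enumerate_scenarios()) {
  if (length(scenarios) == 0L) stop("scenarios must be non-empty", call. = FALSE)
  rows <- lapply(scenarios, function(sc) {
    m <- apply_scenario(mesh, sc)
    rep_ <- orifice_area(m)
    data.frame(id = sc$id, n_clips = length(sc$indices),
               n_openings = rep_$n_openings,
               total_area_mm2 = rep_$total_area,
               flagged = any(rep_$flagged),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  base <- out$total_area_mm2[match("no_clip", out$id)]
  if (is.na(base)) base <- orifice_area(mesh)$total_area
  out$reduction <- 1 - out$total_area_mm2 / base
  out[, c("id", "n_clips", "n_openings", "total_area_mm2", "reduction",
          "flagged")]
}
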