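#' Fit a landmark-driven radial basis function deformation
#'
#' Solves the standard RBF interpolation system with a full degree-1
#' polynomial (affine) term and the usual side constraints that the radial
#' part carries no net affine component. With `regularization = 0` the fitted
#' deformation interpolates: it maps every source landmark exactly onto its
#' target. Positive regularization trades interpolation for smoothness
#' (useful with noisy, hand-digitized patient landmarks).
#'
#' Supported kernels: `"tps"` (thin-plate spline, the triharmonic
#' \eqn{\varphi(r) = r^3} appropriate in 3-D; parameter-free),
#' `"gaussian"` (\eqn{e^{-(r/c)^2}}) and `"multiquadric"`
#' (\eqn{\sqrt{r^2 + c^2}}), with `shape_parameter` \eqn{c}.
#'
#' @param source K x 3 matrix of source landmark coordinates (mm), K >= 4.
#' @param target K x 3 matrix of target landmark coordinates (mm).
#' @param names Optional character vector of K unique landmark labels.
#' @param kernel One of `"tps"`, `"gaussian"`, `"multiquadric"`.
#' @param shape_parameter Positive kernel width (ignored for `"tps"`).
#' @param regularization Ridge weight lambda >= 0 added to the kernel matrix
#'   diagonal; 0 gives pure interpolation.
#' @return An `rbf_deformation` object holding the kernel spec, the K x 3
#'   radial weights, the 4 x 3 affine coefficients (row 1 = translation),
#'   and the control points.
#' @examples
#' src <- matrix(rnorm(18), 6, 3)
#' tgt <- src + 1.5                      # rigid translation
#' d <- fit_rbf(src, tgt)
#' max(abs(apply_deformation(d, src) - tgt))  # ~1e-12
#' @export
fit_rbf <- function(source, target, names = NULL,
                    kernel = c("tps", "gaussian", "multiquadric"),
                    shape_parameter = 1, regularization = 0) {
  kernel <- match.arg(kernel)
  source <- as.matrix(source); target <- as.matrix(target)
  if (ncol(source) != 3L || ncol(target) != 3L)
    stop("source and target must be K x 3 matrices", call. = FALSE)
  K <- nrow(source)
  if (nrow(target) != K)
    stop("source and target must have the same number of points", call. = FALSE)
  if (K < 4L) stop("at least 4 landmark correspondences required", call. = FALSE)
  if (!is.null(names)) {
    if (length(names) != K) stop("names length mismatch", call. = FALSE)
    if (anyDuplicated(names))
      stop("landmark names must be unique", call. = FALSE)
  }
  if (shape_parameter <= 0) stop("shape_parameter must be > 0", call. = FALSE)
  if (regularization < 0) stop("regularization must be >= 0", call. = FALSE)

  D <- as.matrix(stats::dist(source))
  dup <- which(D < 1e-9 & upper.tri(D), arr.ind = TRUE)
  if (nrow(dup)) {
    lab <- if (is.null(names)) apply(dup, 1L, paste, collapse = "/")
           else paste(names[dup[, 1L]], names[dup[, 2L]], sep = "/")
    stop("duplicate control points (interpolation system singular): ",
         paste(unique(lab), collapse = ", "), call. = FALSE)
  }

  Phi <- .rbf_kernel(D, kernel, shape_parameter)
  P <- cbind(1, source)                       # K x 4
  A <- rbind(cbind(Phi + diag(regularization, K), P),
             cbind(t(P), matrix(0, 4L, 4L)))
  rhs <- rbind(target, matrix(0, 4L, 3L))
  sol <- tryCatch(solve(A, rhs), error = function(e)
    stop("RBF interpolation system is singular: ", conditionMessage(e),
         call. = FALSE))
  structure(list(
    kernel = kernel, shape_parameter = shape_parameter,
    regularization = regularization,
    weights = sol[seq_len(K), , drop = FALSE],
    affine = sol[K + 1:4, , drop = FALSE],
    control_points = source, control_names = names
  ), class = "rbf_deformation")
}

.rbf_kernel <- function(r, kernel, c) {
  switch(kernel,
         tps = r^3,
         gaussian = exp(-(r / c)^2),
         multiquadric = sqrt(r^2 + c^2),
         stop("unsupported kernel '", kernel,
              "'; supported: tps, gaussian, multiquadric", call. = FALSE))
}

#' Apply a fitted RBF deformation to points
#'
#' @param def An `rbf_deformation` from [fit_rbf()].
#' @param points N x 3 matrix of points (mm); N may be 0.
#' @return N x 3 matrix of deformed points, same order as the input.
#' @export
apply_deformation <- function(def, points) {
  stopifnot(inherits(def, "rbf_deformation"))
  points <- as.matrix(points)
  if (length(points) == 0L) return(matrix(numeric(0), 0L, 3L))
  if (ncol(points) != 3L) stop("points must be N x 3", call. = FALSE)
  cp <- def$control_points
  ## cross-distance N x K
  d2 <- outer(rowSums(points^2), rowSums(cp^2), "+") -
    2 * points %*% t(cp)
  d2[d2 < 0] <- 0
  Phi <- .rbf_kernel(sqrt(d2), def$kernel, def$shape_parameter)
  cbind(1, points) %*% def$affine + Phi %*% def$weights
}

#' The affine component of an RBF deformation
#'
#' Far from the control-point cloud a thin-plate-spline deformation tends to
#' its affine part; this helper evaluates that part alone.
#'
#' @inheritParams apply_deformation
#' @return N x 3 matrix.
#' @export
affine_part <- function(def, points) {
  stopifnot(inherits(def, "rbf_deformation"))
  cbind(1, as.matrix(points)) %*% def$affine
}

#' @export
print.rbf_deformation <- function(x, ...) {
  cat(sprintf("rbf_deformation: %s kernel, %d control points, lambda = %g\n",
              x$kernel, nrow(x$control_points), x$regularization))
  invisible(x)
}

#' Morph the template mesh to target morphological parameters
#'
#' Builds the parametric valve with the target parameters at the template's
#' resolution, fits an RBF deformation from the template's control stations
#' (the named landmarks, a ring of annulus anchors, and a mid-depth anchor on
#' each region's central column) onto the corresponding target stations, and
#' applies it to every template vertex. Topology (faces, chordae, free-edge
#' ordering) is copied from the template unchanged. The anchor stations are
#' recorded in the output metadata.
#'
#' @param template A `valve_mesh` from [build_template()].
#' @param target An [mv_parameters()] object.
#' @param kernel,shape_parameter,regularization Passed to [fit_rbf()].
#' @param n_annulus_anchors Number of extra annulus control stations spread
#'   around the ring (default 8) to prevent far-field drift.
#' @return A `valve_mesh` with morphed vertices; `meta$morph` records the
#'   control-point configuration and the deformation object.
#' @export
morph_to_parameters <- function(template, target,
                                kernel = "tps", shape_parameter = 1,
                                regularization = 0,
                                n_annulus_anchors = 8L) {
  validate_valve_mesh(template)
  validate_mv_parameters(target)
  ref <- build_template(target,
                        resolution = template$meta$resolution,
                        n_chordae = 0L,
                        dip_angle_deg = template$meta$dip_angle_deg,
                        papillary_depth = template$meta$papillary_depth)
  ctrl <- .morph_control_indices(template, n_annulus_anchors)
  src <- template$vertices[ctrl$index, , drop = FALSE]
  tgt <- ref$vertices[ctrl$index, , drop = FALSE]
  def <- fit_rbf(src, tgt, names = ctrl$name, kernel = kernel,
                 shape_parameter = shape_parameter,
                 regularization = regularization)
  out <- template
  out$vertices <- apply_deformation(def, template$vertices)
  out$meta$params <- unclass(target)
  out$meta$morph <- list(kernel = kernel,
                         shape_parameter = shape_parameter,
                         regularization = regularization,
                         control_stations = ctrl,
                         deformation = def)
  out
}

## control stations: named landmarks + annulus anchor ring + mid-depth
## anchors on the four region mid-columns (all identified by vertex index,
## so the same stations exist on any same-resolution parametric build)
.morph_control_indices <- function(mesh, n_annulus_anchors) {
  R <- mesh$meta$resolution
  n_rows <- mesh$meta$n_rows
  n_ring <- length(mesh$meta$theta)
  vid <- function(i_ring, j_row) (i_ring - 1L) * n_rows + j_row
  idx <- mesh$landmarks
  nm <- names(mesh$landmarks)
  if (n_annulus_anchors > 0L) {
    ring_i <- unique(round(seq(1L, n_ring, length.out = n_annulus_anchors + 1L))[-(n_annulus_anchors + 1L)])
    idx <- c(idx, vid(ring_i, 1L))
    nm <- c(nm, paste0("ANN_ANCHOR_", seq_along(ring_i)))
  }
  ## interior anchors along each region's measured column keep the morphed
  ## column straight, so surface geodesics track the requested depths
  theta <- mesh$meta$theta
  mids <- vapply(c(pi / 2, 7 * pi / 6, 3 * pi / 2, 11 * pi / 6),
                 function(a) which.min(abs(theta - a)), integer(1))
  interior <- unique(pmax(2L, pmin(n_rows - 1L,
    as.integer(round(n_rows * c(0.25, 0.5, 0.75))))))
  for (r in interior) {
    idx <- c(idx, vid(mids, r))
    nm <- c(nm, paste0("COL_ANCHOR_", c("ANT", "P1", "P2", "P3"), "_", r))
  }
  keep <- !duplicated(idx)
  list(index = unname(idx[keep]), name = nm[keep])
}

#' Morph the template so its landmarks meet reconstructed patient landmarks
#'
#' The patient path: only the named key points are known in 3-D, so the
#' control set is those landmarks alone (optionally with positive
#' regularization for noisy digitizations). Topology is preserved.
#'
#' @param template A `valve_mesh`.
#' @param target_landmarks Named list or 3-column matrix (rownames = landmark
#'   names) of target positions for a subset of the template's landmarks.
#' @inheritParams morph_to_parameters
#' @return A morphed `valve_mesh`.
#' @export
morph_to_landmarks <- function(template, target_landmarks,
                               kernel = "tps", shape_parameter = 1,
                               regularization = 0) {
  validate_valve_mesh(template)
  tgt <- .as_point_matrix(target_landmarks)
  nm <- rownames(tgt)
  unknown <- setdiff(nm, names(template$landmarks))
  if (length(unknown))
    stop("unknown landmark(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  src <- template$vertices[template$landmarks[nm], , drop = FALSE]
  def <- fit_rbf(src, tgt, names = nm, kernel = kernel,
                 shape_parameter = shape_parameter,
                 regularization = regularization)
  out <- template
  out$vertices <- apply_deformation(def, template$vertices)
  out$meta$morph <- list(kernel = kernel, control_stations = nm,
                         regularization = regularization, deformation = def)
  out
}

.as_point_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    m <- do.call(rbind, x)
    rownames(m) <- names(x)
    x <- m
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L || is.null(rownames(x)))
    stop("landmarks must be a named list of xyz points or a 3-column matrix with rownames",
         call. = FALSE)
  storage.mode(x) <- "double"
  x
}
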