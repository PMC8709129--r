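#' Echocardiographic view definitions
#'
#' A view is an imaging plane with an in-plane orthonormal basis and a pixel
#' spacing; projecting a 3-D landmark into the view yields the pixel
#' coordinates a manual digitization would record.
#'
#' @param view_id Character label.
#' @param plane_origin 3-D point on the plane (mm).
#' @param basis_u,basis_v Orthonormal in-plane direction vectors.
#' @param pixel_spacing mm per pixel (> 0).
#' @return An `echo_view` object.
#' @export
echo_view <- function(view_id, plane_origin, basis_u, basis_v,
                      pixel_spacing = 0.5) {
  basis_u <- as.numeric(basis_u); basis_v <- as.numeric(basis_v)
  if (abs(sqrt(sum(basis_u^2)) - 1) > 1e-8 ||
      abs(sqrt(sum(basis_v^2)) - 1) > 1e-8)
    stop("basis vectors must be unit length", call. = FALSE)
  if (abs(sum(basis_u * basis_v)) > 1e-8)
    stop("basis vectors must be orthogonal", call. = FALSE)
  if (pixel_spacing <= 0) stop("pixel_spacing must be > 0", call. = FALSE)
  structure(list(view_id = view_id,
                 plane_origin = as.numeric(plane_origin),
                 basis_u = basis_u, basis_v = basis_v,
                 pixel_spacing = pixel_spacing),
            class = "echo_view")
}

#' Default three-view geometry
#'
#' Three mutually orthogonal imaging planes through a common origin
#' (nominally the annulus centroid): xy, yz and zx. Orthogonal views give
#' the best-conditioned triangulation and make the zero-noise reconstruction
#' exact.
#'
#' @param origin Common plane origin (mm).
#' @param pixel_spacing mm per pixel, shared by the three views.
#' @return List of three `echo_view` objects.
#' @export
default_views <- function(origin = c(0, 0, 0), pixel_spacing = 0.5) {
  ex <- c(1, 0, 0); ey <- c(0, 1, 0); ez <- c(0, 0, 1)
  list(echo_view("xy", origin, ex, ey, pixel_spacing),
       echo_view("yz", origin, ey, ez, pixel_spacing),
       echo_view("zx", origin, ez, ex, pixel_spacing))
}

#' Project 3-D landmarks into an echo view as pixel observations
#'
#' Forward model of manual key-point digitization: each landmark is
#' orthogonally projected into the view plane, converted to pixel units, and
#' perturbed by isotropic Gaussian click noise.
#'
#' @param landmarks Named list of xyz points, or 3-column matrix with
#'   rownames (mm).
#' @param view An [echo_view()].
#' @param noise_sd Click-noise standard deviation in pixels (>= 0).
#' @param seed Integer seed; the draw is a deterministic function of it.
#' @return Data frame with columns `view_id`, `landmark`, `u_px`, `v_px`.
#' @export
project_landmarks <- function(landmarks, view, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(view, "echo_view"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  pts <- .as_point_matrix(landmarks)
  rel <- sweep(pts, 2L, view$plane_origin)
  u <- (rel %*% view$basis_u) / view$pixel_spacing
  v <- (rel %*% view$basis_v) / view$pixel_spacing
  if (noise_sd > 0) {
    eps <- with_local_seed(seed, matrix(stats::rnorm(2L * nrow(pts),
                                                     sd = noise_sd),
                                        ncol = 2L))
    u <- u + eps[, 1L]; v <- v + eps[, 2L]
  }
  data.frame(view_id = view$view_id, landmark = rownames(pts),
             u_px = as.numeric(u), v_px = as.numeric(v),
             stringsAsFactors = FALSE)
}

#' Triangulate landmarks from multi-view pixel observations
#'
#' Each pixel observation constrains the two in-plane coordinates of the
#' landmark; stacking the constraints from all views in which the landmark
#' was seen gives an overdetermined linear system solved by least squares.
#' With zero noise and three orthogonal views the recovery is exact.
#'
#' @param observations Data frame as returned by [project_landmarks()]
#'   (possibly row-bound over views).
#' @param views List of [echo_view()] objects covering every `view_id`.
#' @return List with `points` (L x 3 matrix, rownames = landmark names) and
#'   `residuals` (named vector, per-landmark RMS equation residual in mm).
#' @export
reconstruct_landmarks <- function(observations, views) {
  vmap <- stats::setNames(views, vapply(views, `[[`, "", "view_id"))
  miss <- setdiff(unique(observations$view_id), names(vmap))
  if (length(miss))
    stop("no view definition for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  lms <- unique(observations$landmark)
  points <- matrix(NA_real_, length(lms), 3L,
                   dimnames = list(lms, c("x", "y", "z")))
  residuals <- stats::setNames(numeric(length(lms)), lms)
  for (lm in lms) {
    obs <- observations[observations$landmark == lm, , drop = FALSE]
    if (length(unique(obs$view_id)) < 2L)
      stop(sprintf("landmark '%s' observed in fewer than 2 views", lm),
           call. = FALSE)
    A <- NULL; b <- NULL
    for (i in seq_len(nrow(obs))) {
      vw <- vmap[[obs$view_id[i]]]
      A <- rbind(A, vw$basis_u, vw$basis_v)
      b <- c(b,
             obs$u_px[i] * vw$pixel_spacing + sum(vw$basis_u * vw$plane_origin),
             obs$v_px[i] * vw$pixel_spacing + sum(vw$basis_v * vw$plane_origin))
    }
    if (qr(A)$rank < 3L)
      stop(sprintf("views observing landmark '%s' are parallel (rank-deficient)",
                   lm), call. = FALSE)
    fit <- stats::lsfit(A, b, intercept = FALSE)
    points[lm, ] <- fit$coefficients
    residuals[lm] <- sqrt(mean(fit$residuals^2))
  }
  list(points = points, residuals = residuals)
}

#' Generate a synthetic digitized-patient cohort
#'
#' Emulates the patient workflow end-to-end: per patient, draw a true
#' parameter set from a truncated normal around a base valve, build the
#' valve, project its six key points into three echo views with pixel click
#' noise, triangulate the key points back to 3-D, and recover a parameter
#' set from the reconstructed key points. Fully deterministic given `seed`.
#'
#' From six key points the annular diameters and the anterior/P2 depths are
#' measured directly (chordal base-to-tip distances); the P1/P3 depths are
#' not spanned by the key-point set and are scaled from the recovered P2
#' depth by the base valve's ratios.
#'
#' @param n_patients Cohort size (>= 1); 29 mirrors a typical single-center
#'   echo series.
#' @param base An [mv_parameters()] object, the cohort's central anatomy.
#' @param variation Named numeric vector of per-parameter standard
#'   deviations (mm), recycled from a scalar; draws are truncated at the
#'   admissible parameter bounds.
#' @param noise_sd Digitization noise in pixels.
#' @param pixel_spacing mm per pixel for the three default views.
#' @param resolution Mesh resolution used per patient.
#' @param seed Integer master seed.
#' @return List of `n_patients` records, each with elements `id`, `true`
#'   (`mv_parameters`), `observations` (pixel data frame over the 3 views),
#'   `reconstructed_landmarks`, `reconstructed` (`mv_parameters`), and
#'   `residuals`.
#' @examples
#' cohort <- generate_patient_cohort(3, seed = 7)
#' cohort[[1]]$reconstructed
#' @export
generate_patient_cohort <- function(n_patients = 29L,
                                    base = mv_default_parameters(),
                                    variation = 1.5,
                                    noise_sd = 1,
                                    pixel_spacing = 0.5,
                                    resolution = 4L,
                                    seed = 1L) {
  if (n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  validate_mv_parameters(base)
  nm <- c("aml", "p1", "p2", "p3", "d_am", "d_ic")
  if (length(variation) == 1L)
    variation <- stats::setNames(rep(as.numeric(variation), 6L), nm)
  if (any(variation < 0)) stop("variation sds must be >= 0", call. = FALSE)
  key_points <- c("AM_ANT", "AM_POST", "COMM_A", "COMM_P", "ANT_TIP", "P2_TIP")
  views <- default_views(pixel_spacing = pixel_spacing)
  bounds <- mv_parameter_bounds()

  with_local_seed(seed, {
    lapply(seq_len(n_patients), function(i) {
      true <- stats::setNames(vapply(nm, function(p)
        .rtruncnorm1(base[[p]], variation[[p]],
                     bounds[p, "lower"], bounds[p, "upper"]),
        numeric(1)), nm)
      true <- do.call(mv_parameters, as.list(true))
      mesh <- build_template(true, resolution = resolution, n_chordae = 0L)
      lmk <- mesh$vertices[mesh$landmarks[key_points], , drop = FALSE]
      rownames(lmk) <- key_points
      obs <- do.call(rbind, lapply(views, function(vw)
        project_landmarks(lmk, vw, noise_sd = noise_sd,
                          seed = sample.int(.Machine$integer.max, 1L))))
      rec <- reconstruct_landmarks(obs, views)
      est <- .parameters_from_key_points(rec$points, base)
      list(id = sprintf("patient_%03d", i), true = true,
           observations = obs, reconstructed_landmarks = rec$points,
           reconstructed = est, residuals = rec$residuals)
    })
  })
}

## one truncated-normal draw by rejection (sd = 0 returns the mean)
.rtruncnorm1 <- function(mean, sd, lower, upper) {
  if (sd == 0) return(mean)
  repeat {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
}

.parameters_from_key_points <- function(pts, base) {
  d <- function(a, b) sqrt(sum((pts[a, ] - pts[b, ])^2))
  p2 <- d("AM_POST", "P2_TIP")
  mv_parameters(aml = d("AM_ANT", "ANT_TIP"),
                p1 = base[["p1"]] * p2 / base[["p2"]],
                p2 = p2,
                p3 = base[["p3"]] * p2 / base[["p2"]],
                d_am = d("AM_ANT", "AM_POST"),
                d_ic = d("COMM_A", "COMM_P"))
}

#' Write / read pixel observations as CSV
#'
#' The CSV mirrors a hand-made measurement export: columns `view_id`,
#' `landmark`, `u_px`, `v_px`.
#'
#' @param observations Data frame of pixel observations.
#' @param path File path.
#' @return `write_observations_csv` returns `path` invisibly;
#'   `read_observations_csv` returns the data frame.
#' @export
write_observations_csv <- function(observations, path) {
  utils::write.csv(observations[, c("view_id", "landmark", "u_px", "v_px")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations_csv
#' @export
read_observations_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
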