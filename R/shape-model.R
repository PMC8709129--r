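#' Fit a PCA point-distribution shape model
#'
#' Fits the linear statistical shape model
#' \deqn{X \approx \bar X + \sum_{m=1}^{M} \alpha_m \sqrt{\lambda_m}\, W_m}
#' to a cohort of corresponding shape vectors (flattened landmark or vertex
#' coordinates in a shared ordering). The mean is the arithmetic mean; the
#' eigenvectors \eqn{W_m} and eigenvalues \eqn{\lambda_m} of the sample
#' covariance (denominator \eqn{n-1}) are obtained from the SVD of the
#' centered data matrix. Each eigenvector's sign is fixed so its
#' largest-magnitude entry is positive, making fits reproducible across
#' platforms.
#'
#' @param cohort n x d numeric matrix (one shape vector per row), or a list
#'   of equal-length numeric vectors.
#' @param n_components Number of retained modes M,
#'   `1 <= M <= min(n - 1, d)` and at most the rank of the centered data.
#' @return A `pca_shape_model`: list with `mean` (length d), `eigenvectors`
#'   (d x M, orthonormal columns), `eigenvalues` (length M, descending),
#'   `n_components`, `total_variance` (sum of *all* covariance eigenvalues),
#'   `rank`.
#' @examples
#' x <- matrix(rnorm(50 * 6), 50, 6)
#' m <- fit_shape_model(x, 3)
#' explained_variance_ratio(m, 3)
#' @export
fit_shape_model <- function(cohort, n_components) {
  X <- .as_shape_matrix(cohort)
  n <- nrow(X); d <- ncol(X)
  if (n < 2L) stop("cohort must contain at least 2 shapes", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc)
  lambda_all <- sv$d^2 / (n - 1)
  rank_cap <- min(n - 1L, d)
  rank <- sum(sv$d > max(sv$d[1L], 1) * 1e-12 * sqrt(n))
  M <- as.integer(n_components)
  if (is.na(M) || M < 1L)
    stop("n_components must be a positive integer", call. = FALSE)
  if (M > rank_cap)
    stop(sprintf("n_components = %d exceeds min(n - 1, d); at most %d components are attainable",
                 M, rank_cap), call. = FALSE)
  W <- sv$v[, seq_len(M), drop = FALSE]
  ## deterministic sign: largest-|entry| of each mode positive
  for (m in seq_len(M)) {
    j <- which.max(abs(W[, m]))
    if (W[j, m] < 0) W[, m] <- -W[, m]
  }
  structure(list(mean = mu, eigenvectors = W,
                 eigenvalues = lambda_all[seq_len(M)],
                 n_components = M,
                 total_variance = sum(lambda_all),
                 rank = rank),
            class = "pca_shape_model")
}

.as_shape_matrix <- function(cohort) {
  if (is.list(cohort) && !is.data.frame(cohort)) {
    len <- lengths(cohort)
    if (length(unique(len)) != 1L)
      stop("all shape vectors must have the same length", call. = FALSE)
    cohort <- do.call(rbind, cohort)
  }
  X <- as.matrix(cohort)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("shape vectors contain NA", call. = FALSE)
  X
}

#' Reconstruct a shape from its shape code
#'
#' Evaluates \eqn{\bar X + \sum_m \alpha_m \sqrt{\lambda_m} W_m}.
#'
#' @param model A `pca_shape_model`.
#' @param alpha Numeric shape code of length `n_components`.
#' @return Numeric shape vector (length d).
#' @export
reconstruct_shape <- function(model, alpha) {
  stopifnot(inherits(model, "pca_shape_model"))
  if (length(alpha) != model$n_components)
    stop(sprintf("alpha has length %d; model retains %d components",
                 length(alpha), model$n_components), call. = FALSE)
  as.numeric(model$mean +
    model$eigenvectors %*% (alpha * sqrt(model$eigenvalues)))
}

#' Encode a shape as its shape code
#'
#' Orthogonal projection onto the retained modes,
#' \eqn{\alpha_m = W_m^{\top}(X - \bar X)/\sqrt{\lambda_m}}; this is the
#' least-squares shape code.
#'
#' @param model A `pca_shape_model` with strictly positive retained
#'   eigenvalues.
#' @param shape Numeric shape vector of length d.
#' @return Numeric shape code (length `n_components`).
#' @export
encode_shape <- function(model, shape) {
  stopifnot(inherits(model, "pca_shape_model"))
  if (length(shape) != length(model$mean))
    stop("shape vector length mismatch", call. = FALSE)
  if (any(model$eigenvalues <= 0))
    stop("a retained eigenvalue is zero; reduce n_components", call. = FALSE)
  as.numeric(crossprod(model$eigenvectors, shape - model$mean) /
               sqrt(model$eigenvalues))
}

#' Cumulative explained variance ratio
#'
#' @param model A `pca_shape_model`.
#' @param k Number of leading modes, `1 <= k <= n_components`.
#' @return Fraction in \[0, 1\]: sum of the k leading eigenvalues over the
#'   total covariance variance.
#' @export
explained_variance_ratio <- function(model, k) {
  stopifnot(inherits(model, "pca_shape_model"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > model$n_components)
    stop(sprintf("k must lie in 1..%d", model$n_components), call. = FALSE)
  if (model$total_variance == 0) return(1)
  sum(model$eigenvalues[seq_len(k)]) / model$total_variance
}

#' Sample virtual valve shapes from the model
#'
#' Draws shape codes i.i.d. from a standard normal truncated to
#' `[-alpha_bound, alpha_bound]` per component (plausibility box) and
#' reconstructs; deterministic given `seed`.
#'
#' @param model A `pca_shape_model`.
#' @param n Number of virtual shapes (>= 1).
#' @param seed Integer seed.
#' @param alpha_bound Truncation half-width in mode standard deviations
#'   (default 3); 0 collapses every draw to the mean shape.
#' @return List with `shapes` (n x d matrix) and `codes` (n x M matrix).
#' @export
sample_virtual_shapes <- function(model, n, seed = 1L, alpha_bound = 3) {
  stopifnot(inherits(model, "pca_shape_model"))
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (alpha_bound < 0) stop("alpha_bound must be >= 0", call. = FALSE)
  M <- model$n_components
  codes <- with_local_seed(seed, {
    matrix(vapply(seq_len(n * M), function(i)
      .rtruncnorm1(0, if (alpha_bound == 0) 0 else 1,
                   -alpha_bound, alpha_bound), numeric(1)),
      nrow = n, ncol = M)
  })
  shapes <- t(apply(codes, 1L, function(a) reconstruct_shape(model, a)))
  list(shapes = shapes, codes = codes)
}

#' @export
print.pca_shape_model <- function(x, ...) {
  cat(sprintf("pca_shape_model: %d modes over %d-dim shape vectors (rank %d)\n",
              x$n_components, length(x$mean), x$rank))
  evr <- vapply(seq_len(x$n_components), function(k)
    explained_variance_ratio(x, k), numeric(1))
  cat("cumulative explained variance:",
      paste(sprintf("%.1f%%", 100 * evr), collapse = ", "), "\n")
  invisible(x)
}

#' Extract the shape vector of a valve mesh
#'
#' Default shape representation: the concatenated xyz coordinates of the six
#' key landmarks (18 numbers), mirroring the key-point digitization
#' pipeline; `mode = "vertices"` flattens all mesh vertices instead.
#'
#' @param mesh A `valve_mesh`.
#' @param mode `"landmarks"` (default) or `"vertices"`.
#' @return Numeric vector.
#' @export
shape_vector <- function(mesh, mode = c("landmarks", "vertices")) {
  mode <- match.arg(mode)
  if (mode == "landmarks") {
    key <- c("AM_ANT", "AM_POST", "COMM_A", "COMM_P", "ANT_TIP", "P2_TIP")
    as.numeric(t(mesh$vertices[mesh$landmarks[key], , drop = FALSE]))
  } else {
    as.numeric(t(mesh$vertices))
  }
}

#' Simulate a shape cohort from a low-rank linear latent model
#'
#' Generates shape vectors as \eqn{\mu + \sum_{m=1}^{q} z_m w_m +
#' \varepsilon} with standard-normal latent coefficients \eqn{z_m}, fixed
#' orthogonal mode vectors \eqn{w_m}, and isotropic Gaussian noise whose
#' per-coordinate standard deviation is `noise_frac` times the root of the
#' average per-coordinate mode variance. This is the ground-truth generator
#' used to validate shape-model recovery.
#'
#' @param n Cohort size.
#' @param dim Shape-vector dimension (default 18, six xyz landmarks).
#' @param n_modes Number of generating modes q.
#' @param mode_sd Standard deviations (mm) of the q modes along their
#'   directions (descending).
#' @param noise_frac Noise level as a fraction of the overall mode standard
#'   deviation (default 0.05).
#' @param seed Integer seed.
#' @return List with `shapes` (n x dim matrix), `mean`, `modes`
#'   (dim x q orthonormal), `mode_sd`, `noise_sd`.
#' @export
simulate_shape_cohort <- function(n = 180L, dim = 18L, n_modes = 3L,
                                  mode_sd = c(8, 4, 2), noise_frac = 0.05,
                                  seed = 1L) {
  stopifnot(n >= 2L, n_modes >= 1L, length(mode_sd) == n_modes)
  with_local_seed(seed, {
    mu <- stats::rnorm(dim, sd = 10)
    basis <- qr.Q(qr(matrix(stats::rnorm(dim * n_modes), dim, n_modes)))
    z <- matrix(stats::rnorm(n * n_modes), n, n_modes)
    signal_var_per_coord <- sum(mode_sd^2) / dim
    noise_sd <- noise_frac * sqrt(signal_var_per_coord)
    shapes <- tcrossprod(sweep(z, 2L, mode_sd, "*"), basis) +
      matrix(stats::rnorm(n * dim, sd = noise_sd), n, dim)
    shapes <- sweep(shapes, 2L, mu, "+")
    list(shapes = shapes, mean = mu, modes = basis, mode_sd = mode_sd,
         noise_sd = noise_sd)
  })
}

#' Principal angles between two subspaces
#'
#' Largest principal angle (degrees) between the column spaces of `A` and
#' `B`; used to check that fitted shape modes align with generating modes.
#'
#' @param A,B Matrices with the same number of rows.
#' @return Largest principal angle in degrees.
#' @export
max_principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  s <- pmin(pmax(s, -1), 1)
  max(acos(s)) * 180 / pi
}
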