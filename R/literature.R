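#' Normal-distribution percentile levels for a morphological parameter
#'
#' Published valve morphometry is summarized as normal distributions; atlas
#' levels are taken at population percentiles,
#' \eqn{v_p = \mu + \sigma\,\Phi^{-1}(p)}.
#'
#' @param mean,sd Distribution parameters (mm), `sd > 0`.
#' @param probs Probabilities strictly inside (0, 1).
#' @return Numeric vector of percentile values, one per probability.
#' @examples
#' sd_aml <- (20.6 - 13.63) / qnorm(0.95)
#' normal_percentiles(20.6, sd_aml, c(0.05, 0.5, 0.95))  # 13.63 20.60 27.57
#' @export
normal_percentiles <- function(mean, sd, probs = c(0.05, 0.5, 0.95)) {
  if (sd <= 0) stop("sd must be > 0", call. = FALSE)
  if (any(probs <= 0 | probs >= 1))
    stop("probabilities must lie strictly inside (0, 1)", call. = FALSE)
  mean + sd * stats::qnorm(probs)
}

#' The literature enumeration plan
#'
#' Parameter levels for the literature-driven portion of the atlas: each of
#' the four leaflet/scallop depths at its 5th/50th/95th population
#' percentile, and five uniformly spaced levels for each annular diameter.
#' During the diameter sweep the leaflet depths stay fixed at the listed
#' `fixed_leaflet_values`; during the leaflet factorial the diameters stay
#' fixed at `fixed_diameter_values`.
#'
#' @param leaflet_levels Named list (`aml`, `p1`, `p2`, `p3`) of ascending
#'   3-vectors (mm).
#' @param diameter_levels Named list (`d_am`, `d_ic`) of ascending,
#'   uniformly spaced 5-vectors (mm).
#' @param fixed_leaflet_values Named 4-vector used while diameters vary.
#' @param fixed_diameter_values Named 2-vector used while leaflets vary
#'   (defaults to the first diameter levels).
#' @return An `enumeration_plan` object.
#' @export
enumeration_plan <- function(leaflet_levels, diameter_levels,
                             fixed_leaflet_values,
                             fixed_diameter_values =
                               vapply(diameter_levels, `[`, numeric(1), 1L)) {
  stopifnot(is.list(leaflet_levels), is.list(diameter_levels))
  for (nm in c("aml", "p1", "p2", "p3")) {
    lv <- leaflet_levels[[nm]]
    if (is.null(lv) || is.unsorted(lv, strictly = FALSE))
      stop("leaflet_levels$", nm, " must be an ascending vector", call. = FALSE)
  }
  for (nm in c("d_am", "d_ic")) {
    lv <- diameter_levels[[nm]]
    if (is.null(lv) || is.unsorted(lv))
      stop("diameter_levels$", nm, " must be ascending", call. = FALSE)
    if (length(lv) > 2L && max(abs(diff(diff(lv)))) > 1e-9)
      stop("diameter_levels$", nm, " must be uniformly spaced", call. = FALSE)
  }
  structure(list(leaflet_levels = leaflet_levels,
                 diameter_levels = diameter_levels,
                 fixed_leaflet_values = fixed_leaflet_values,
                 fixed_diameter_values = fixed_diameter_values),
            class = "enumeration_plan")
}

#' Default literature plan
#'
#' The bundled morphometry levels: 5/50/95 percentile depths for AML and the
#' three posterior scallops, and five levels for each annular diameter, with
#' the 5th-percentile depths held fixed during the diameter sweep.
#'
#' @return An `enumeration_plan`.
#' @export
default_literature_plan <- function() {
  lev <- literature_parameter_levels()
  leaf <- split(lev$value_mm, lev$parameter)
  enumeration_plan(
    leaflet_levels = leaf[c("aml", "p1", "p2", "p3")],
    diameter_levels = leaf[c("d_am", "d_ic")],
    fixed_leaflet_values = c(aml = 13.63, p1 = 6.85, p2 = 8.25, p3 = 6.08)
  )
}

#' Bundled literature morphometry levels
#'
#' The parameter levels shipped with the package (also available as the CSV
#' `extdata/literature_levels.csv`): per-parameter percentile or sweep
#' values in millimetres.
#'
#' @return Data frame with columns `parameter`, `level`, `value_mm`.
#' @export
literature_parameter_levels <- function() {
  data.frame(
    parameter = c(rep("aml", 3), rep("p1", 3), rep("p2", 3), rep("p3", 3),
                  rep("d_am", 5), rep("d_ic", 5)),
    level = c(rep(c("p05", "p50", "p95"), 4), rep(paste0("L", 1:5), 2)),
    value_mm = c(13.63, 20.6, 27.57,
                 6.85, 11, 15.15,
                 8.25, 12.9, 17.55,
                 6.08, 10.4, 14.72,
                 21.5, 22.0, 22.5, 23.0, 23.5,
                 17.65, 18.15, 18.65, 19.15, 19.65),
    stringsAsFactors = FALSE
  )
}

#' Enumerate the literature parameter grid
#'
#' Two portions: (a) the full factorial of the four leaflet depths at their
#' three percentile levels with the diameters fixed (81 sets for the default
#' plan), and (b) the 5 x 5 grid over the two diameters with the leaflet
#' depths fixed (25 sets). Ordering is deterministic (lexicographic in
#' aml, p1, p2, p3, d_am, d_ic within each portion).
#'
#' The two portions are separate enumeration arms and by default each is
#' deduplicated internally (`dedupe = "portion"`), matching how such grids
#' are counted in atlas studies even when one combination coincides across
#' arms; `dedupe = "all"` additionally removes cross-portion coincidences
#' (values compared after rounding to 1e-6 mm).
#'
#' @param plan An [enumeration_plan()].
#' @param dedupe `"portion"` (default) or `"all"`.
#' @return Data frame with columns `id`, `portion`
#'   (`"leaflet_factorial"` / `"diameter_grid"`), and the six parameters.
#' @examples
#' nrow(enumerate_parameter_sets(default_literature_plan()))  # 106
#' @export
enumerate_parameter_sets <- function(plan, dedupe = c("portion", "all")) {
  stopifnot(inherits(plan, "enumeration_plan"))
  dedupe <- match.arg(dedupe)
  fl <- plan$fixed_leaflet_values
  fd <- plan$fixed_diameter_values
  fact <- expand.grid(aml = plan$leaflet_levels$aml,
                      p1 = plan$leaflet_levels$p1,
                      p2 = plan$leaflet_levels$p2,
                      p3 = plan$leaflet_levels$p3,
                      KEEP.OUT.ATTRS = FALSE)
  fact$d_am <- fd[["d_am"]]; fact$d_ic <- fd[["d_ic"]]
  fact <- fact[order(fact$aml, fact$p1, fact$p2, fact$p3), , drop = FALSE]
  fact$portion <- "leaflet_factorial"

  grid <- expand.grid(d_am = plan$diameter_levels$d_am,
                      d_ic = plan$diameter_levels$d_ic,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$d_am, grid$d_ic), , drop = FALSE]
  grid$aml <- fl[["aml"]]; grid$p1 <- fl[["p1"]]
  grid$p2 <- fl[["p2"]]; grid$p3 <- fl[["p3"]]
  grid$portion <- "diameter_grid"

  cols <- c("aml", "p1", "p2", "p3", "d_am", "d_ic", "portion")
  out <- rbind(fact[, cols], grid[, cols])
  key <- apply(round(out[, 1:6] * 1e6), 1L, paste, collapse = "|")
  keep <- if (dedupe == "all") !duplicated(key)
          else !duplicated(paste(out$portion, key))
  out <- out[keep, , drop = FALSE]
  out$id <- sprintf("lit_%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("id", "portion", "aml", "p1", "p2", "p3", "d_am", "d_ic")]
}

#' Build the literature atlas: one morphed mesh per parameter set
#'
#' Morphs the template onto every enumerated parameter set and re-measures
#' each output; the manifest records requested and measured parameters and
#' the worst absolute discrepancy (`residual_mm`). A morph failure is
#' recorded in the manifest row (`status`) and processing continues.
#'
#' @param template A `valve_mesh`.
#' @param plan An [enumeration_plan()]; default [default_literature_plan()].
#' @param ... Passed to [morph_to_parameters()].
#' @return List with `meshes` (named list of `valve_mesh`) and `manifest`
#'   (data frame: id, portion, requested and measured parameters,
#'   residual_mm, status).
#' @export
build_literature_atlas <- function(template, plan = default_literature_plan(),
                                   ...) {
  sets <- enumerate_parameter_sets(plan)
  meshes <- vector("list", nrow(sets))
  names(meshes) <- sets$id
  rows <- vector("list", nrow(sets))
  for (i in seq_len(nrow(sets))) {
    p <- mv_parameters(aml = sets$aml[i], p1 = sets$p1[i], p2 = sets$p2[i],
                       p3 = sets$p3[i], d_am = sets$d_am[i],
                       d_ic = sets$d_ic[i])
    res <- tryCatch({
      m <- morph_to_parameters(template, p, ...)
      meas <- measure_parameters(m)
      meshes[[i]] <- m
      list(meas = unclass(meas),
           residual = max(abs(unclass(meas) - unclass(p))),
           status = "ok")
    }, error = function(e)
      list(meas = rep(NA_real_, 6L), residual = NA_real_,
           status = paste("error:", conditionMessage(e))))
    rows[[i]] <- data.frame(
      id = sets$id[i], portion = sets$portion[i],
      aml = sets$aml[i], p1 = sets$p1[i], p2 = sets$p2[i], p3 = sets$p3[i],
      d_am = sets$d_am[i], d_ic = sets$d_ic[i],
      meas_aml = res$meas[[1L]], meas_p1 = res$meas[[2L]],
      meas_p2 = res$meas[[3L]], meas_p3 = res$meas[[4L]],
      meas_d_am = res$meas[[5L]], meas_d_ic = res$meas[[6L]],
      residual_mm = res$residual, status = res$status,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  n_fail <- sum(manifest$status != "ok")
  if (n_fail > 0)
    warning(n_fail, " of ", nrow(manifest), " morphs failed; see manifest",
            call. = FALSE)
  list(meshes = meshes, manifest = manifest)
}
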