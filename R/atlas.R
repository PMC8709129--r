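#' Default full-atlas configuration
#'
#' The study-scale configuration: a 29-patient synthetic digitized cohort,
#' the full literature enumeration (106 geometries), 20 PCA-sampled virtual
#' valves, and the 7-scenario clip sweep per geometry.
#'
#' @param n_patients Synthetic patient count.
#' @param n_pca Number of PCA-sampled virtual valves.
#' @param resolution Mesh resolution for all geometries.
#' @param seed Master seed.
#' @param mesh_format Export format for [write_mesh()].
#' @return Named list understood by [build_full_atlas()].
#' @export
default_atlas_config <- function(n_patients = 29L, n_pca = 20L,
                                 resolution = 4L, seed = 1L,
                                 mesh_format = "ply") {
  list(version = 1L,
       n_patients = n_patients,
       n_pca = n_pca,
       resolution = resolution,
       seed = seed,
       mesh_format = mesh_format,
       noise_sd = 1,
       pixel_spacing = 0.5,
       variation = 1.5,
       pca_alpha_bound = 3,
       include_literature = TRUE,
       scenarios = list(singles = TRUE, pairs = list(), triples = list()))
}

#' Read / validate an atlas configuration from YAML
#'
#' Unknown keys are rejected (fail-fast) and the schema version checked.
#'
#' @param path YAML file path.
#' @return Config list merged over [default_atlas_config()].
#' @export
read_atlas_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_atlas_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(cfg$version) && cfg$version != base$version)
    stop("unsupported config schema version: ", cfg$version, call. = FALSE)
  utils::modifyList(base, cfg)
}

#' Build the full shape atlas
#'
#' Runs the complete generation workflow: (1) synthetic digitized patient
#' cohort, morphed from reconstructed parameters; (2) literature enumeration
#' morphs; (3) PCA shape model fitted on the union of the patient and
#' literature key-point vectors, sampled for virtual valves, each morphed
#' from its sampled key points; (4) the clip scenario sweep on every
#' geometry. Writes meshes, landmark JSONs, per-geometry scenario reports,
#' and a manifest CSV; fully deterministic given the config seed.
#'
#' @param config List as from [default_atlas_config()] or
#'   [read_atlas_config()].
#' @param out_dir Output directory (created; one subdirectory per source).
#' @return Invisibly, a list with `manifest` (data frame) and `n_failed`.
#'   Rows that fail are recorded with their error message and the function
#'   warns; geometry ids are unique and every written file is referenced by
#'   exactly one row.
#' @export
build_full_atlas <- function(config = default_atlas_config(),
                             out_dir = tempfile("mv_atlas_")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  template <- build_template(mv_default_parameters(),
                             resolution = config$resolution)
  scen <- enumerate_scenarios(singles = config$scenarios$singles,
                              pairs = config$scenarios$pairs,
                              triples = config$scenarios$triples)
  rows <- list()
  shape_bank <- list()

  emit <- function(source, id, mesh, params, residual, status, seed) {
    src_dir <- file.path(out_dir, source)
    dir.create(src_dir, showWarnings = FALSE)
    mesh_path <- lm_path <- scen_path <- NA_character_
    if (status == "ok") {
      mesh_path <- file.path(src_dir, paste0(source, "_", id, ".",
                                             config$mesh_format))
      write_mesh(mesh, mesh_path, format = config$mesh_format)
      lm_path <- file.path(src_dir, paste0(source, "_", id, "_landmarks.json"))
      write_landmarks_json(mesh, lm_path)
      sweep <- scenario_sweep(mesh, scen)
      scen_path <- file.path(src_dir, paste0(source, "_", id, "_scenarios.csv"))
      utils::write.csv(sweep, scen_path, row.names = FALSE)
    }
    data.frame(id = paste0(source, "_", id), source = source,
               aml = params[["aml"]], p1 = params[["p1"]], p2 = params[["p2"]],
               p3 = params[["p3"]], d_am = params[["d_am"]],
               d_ic = params[["d_ic"]],
               residual_mm = residual, n_scenarios = length(scen),
               mesh_file = mesh_path, landmarks_file = lm_path,
               scenarios_file = scen_path,
               seed = seed, status = status,
               tool_version = as.character(utils::packageVersion("mvatlas")),
               stringsAsFactors = FALSE)
  }

  ## 1. synthetic digitized patients
  if (config$n_patients > 0) {
    cohort <- generate_patient_cohort(config$n_patients,
                                      variation = config$variation,
                                      noise_sd = config$noise_sd,
                                      pixel_spacing = config$pixel_spacing,
                                      resolution = config$resolution,
                                      seed = config$seed)
    for (rec in cohort) {
      row <- tryCatch({
        m <- morph_to_parameters(template, rec$reconstructed)
        meas <- measure_parameters(m)
        shape_bank[[length(shape_bank) + 1L]] <- shape_vector(m)
        emit("patient-synthetic", rec$id, m, rec$reconstructed,
             max(abs(unclass(meas) - unclass(rec$reconstructed))), "ok",
             config$seed)
      }, error = function(e)
        emit("patient-synthetic", rec$id, NULL, rec$reconstructed, NA,
             paste("error:", conditionMessage(e)), config$seed))
      rows[[length(rows) + 1L]] <- row
    }
  }

  ## 2. literature enumeration
  lit <- if (isTRUE(config$include_literature)) build_literature_atlas(template)
         else list(manifest = data.frame(), meshes = list())
  for (i in seq_len(nrow(lit$manifest))) {
    r <- lit$manifest[i, ]
    p <- c(aml = r$aml, p1 = r$p1, p2 = r$p2, p3 = r$p3, d_am = r$d_am,
           d_ic = r$d_ic)
    m <- lit$meshes[[r$id]]
    if (!is.null(m)) shape_bank[[length(shape_bank) + 1L]] <- shape_vector(m)
    rows[[length(rows) + 1L]] <-
      emit("literature", r$id, m, p, r$residual_mm, r$status, config$seed)
  }

  ## 3. PCA virtual valves from the pooled key-point vectors
  if (config$n_pca > 0 && length(shape_bank) >= 2L) {
    X <- do.call(rbind, shape_bank)
    M <- min(3L, nrow(X) - 1L)
    model <- fit_shape_model(X, M)
    samp <- sample_virtual_shapes(model, config$n_pca,
                                  seed = config$seed + 1L,
                                  alpha_bound = config$pca_alpha_bound)
    key <- c("AM_ANT", "AM_POST", "COMM_A", "COMM_P", "ANT_TIP", "P2_TIP")
    for (i in seq_len(config$n_pca)) {
      tgt <- matrix(samp$shapes[i, ], ncol = 3L, byrow = TRUE,
                    dimnames = list(key, NULL))
      id <- sprintf("pca_%03d", i)
      row <- tryCatch({
        m <- morph_to_landmarks(template, tgt)
        meas <- measure_parameters(m, depth_mode = "chordal")
        lm_err <- max(abs(m$vertices[m$landmarks[key], ] - tgt))
        shape_bank[[length(shape_bank) + 1L]] <- shape_vector(m)
        emit("pca", id, m, unclass(meas), lm_err, "ok", config$seed + 1L)
      }, error = function(e)
        emit("pca", id, NULL, stats::setNames(rep(NA_real_, 6L),
                                              c("aml", "p1", "p2", "p3",
                                                "d_am", "d_ic")),
             NA, paste("error:", conditionMessage(e)), config$seed + 1L))
      rows[[length(rows) + 1L]] <- row
    }
  }

  manifest <- do.call(rbind, rows)
  if (!is.null(manifest)) rownames(manifest) <- NULL
  else manifest <- data.frame()
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  n_failed <- if (nrow(manifest)) sum(manifest$status != "ok") else 0L
  if (n_failed > 0)
    warning(n_failed, " atlas row(s) failed; see manifest", call. = FALSE)
  invisible(list(manifest = manifest, n_failed = n_failed,
                 out_dir = out_dir))
}

#' Validate an atlas manifest
#'
#' Checks id uniqueness, referenced-file existence, parameter-bound
#' compliance, and the morph residual threshold; returns a structured
#' report.
#'
#' @param manifest Data frame (as written by [build_full_atlas()]) or a
#'   path to the manifest CSV.
#' @param residual_threshold Maximum acceptable morph residual (mm).
#' @return List with `pass` (logical), `checks` (named logical vector) and
#'   `flagged_rows` (data frame of offending rows with a `reason` column).
#' @export
validate_manifest <- function(manifest, residual_threshold = 0.1) {
  if (is.character(manifest)) {
    if (!file.exists(manifest))
      stop("manifest not readable: ", manifest, call. = FALSE)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  flagged <- list()
  flag <- function(rows, reason) {
    if (length(rows))
      flagged[[length(flagged) + 1L]] <<- data.frame(
        id = manifest$id[rows], reason = reason, stringsAsFactors = FALSE)
  }
  dup <- which(duplicated(manifest$id))
  flag(dup, "duplicate id")
  file_cols <- intersect(c("mesh_file", "landmarks_file", "scenarios_file"),
                         names(manifest))
  for (col in file_cols) {
    bad <- which(!is.na(manifest[[col]]) & !file.exists(manifest[[col]]))
    flag(bad, paste("missing file:", col))
  }
  b <- mv_parameter_bounds()
  for (p in rownames(b)) {
    if (!p %in% names(manifest)) next
    bad <- which(!is.na(manifest[[p]]) &
                   (manifest[[p]] < b[p, "lower"] | manifest[[p]] > b[p, "upper"]))
    flag(bad, paste("parameter out of bounds:", p))
  }
  if ("residual_mm" %in% names(manifest))
    flag(which(!is.na(manifest$residual_mm) &
                 manifest$residual_mm > residual_threshold),
         sprintf("morph residual > %g mm", residual_threshold))
  if ("status" %in% names(manifest))
    flag(which(manifest$status != "ok"), "build failure recorded")
  flagged <- if (length(flagged)) do.call(rbind, flagged)
             else data.frame(id = character(0), reason = character(0))
  checks <- c(unique_ids = length(dup) == 0L,
              files_exist = !any(grepl("missing file", flagged$reason)),
              parameters_in_bounds = !any(grepl("out of bounds", flagged$reason)),
              residuals_ok = !any(grepl("residual", flagged$reason)),
              all_rows_ok = !any(grepl("failure", flagged$reason)))
  list(pass = all(checks), checks = checks, flagged_rows = flagged)
}
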