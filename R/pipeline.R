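# Cohort orchestration: a single run configuration covering every module,
# validation of configuration files, and the end-to-end cohort runner with
# QC-exclusion accounting.

.run_config_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "pronelung_out",
    qc_dice_threshold = 0.80,
    exclude_failed = TRUE,
    movement_percentile = 100,
    cube_side = 96L,
    attenuation_divisor = 3000,
    clip_hu = c(-1024, 600),
    lung_hu_threshold = -320,
    min_component_ml = 100,
    closing_radius_mm = 3,
    qc_min_lung_ml = 1000,
    qc_max_lung_ml = 9000,
    levels = 3L,
    iterations_per_level = c(100L, 60L, 30L),
    update_sigma_mm = 2.0,
    field_sigma_mm = 3.0,
    max_step_mm = 2.0,
    convergence_tol = 1e-4,
    simulate = NULL,   # list(n =, shape =, spacing_mm =) for phantom cohorts
    subjects = NULL    # data.frame of per-subject input paths
  )
}

#' Build a validated run configuration
#'
#' Collects every module's tunables into one flat list; unknown keys are
#' rejected with a nearest-match suggestion, and field-level validation is
#' delegated to the module config constructors.
#'
#' @param ... Overrides of the defaults (see [validate_config()] for the
#'   full key list).
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- .run_config_defaults()
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == "")))
    stop("run_config: all overrides must be named")
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    sugg <- vapply(unknown, function(u) {
      cand <- names(cfg)[which.min(utils::adist(u, names(cfg)))]
      sprintf("'%s' (did you mean '%s'?)", u, cand)
    }, character(1))
    stop("run_config: unknown keys: ", paste(sugg, collapse = ", "))
  }
  cfg[names(over)] <- over
  # field validation through the module constructors
  pp <- preprocess_config(cfg$cube_side, cfg$attenuation_divisor, cfg$clip_hu)
  sg <- segmentation_config(cfg$lung_hu_threshold, cfg$min_component_ml,
                            cfg$closing_radius_mm, cfg$qc_min_lung_ml,
                            cfg$qc_max_lung_ml)
  dm <- demons_config(cfg$levels, cfg$iterations_per_level,
                      cfg$update_sigma_mm, cfg$field_sigma_mm,
                      cfg$max_step_mm, cfg$convergence_tol)
  if (cfg$qc_dice_threshold < 0 || cfg$qc_dice_threshold > 1)
    stop("run_config: qc_dice_threshold must lie in [0, 1]")
  structure(c(cfg, list(preprocess_cfg = pp, segmentation_cfg = sg,
                        demons_cfg = dm)),
            class = "run_config")
}

#' Validate a configuration file
#'
#' Reads a YAML or JSON configuration, rejects unknown keys (with a
#' suggestion for likely typos) and invalid field values, and returns the
#' full validated configuration.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [run_config()].
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("validate_config: file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  do.call(run_config, raw)
}

#' Run the pipeline over a cohort
#'
#' Processes every subject through [analyze_subject()], writes per-subject
#' JSON results, a cohort CSV, report tables and a manifest, and accounts
#' for every subject as passed, registration failure, segmentation failure,
#' or errored. QC failures and per-subject errors are data, not run errors:
#' the run completes and the manifest carries the disposition counts
#' (`subjects_in = passed + registration_failures + segmentation_failures +
#' errored`).
#'
#' Inputs come either from `config$simulate` (a phantom cohort generated on
#' the fly) or from `config$subjects`, a data.frame with columns
#' `subject_id`, `supine`, `prone` (NIfTI paths) and optionally
#' `supine_labels`, `prone_labels`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `results`, `subjects`, `tables` (when >= 3
#'   subjects pass QC), and `manifest`.
#' @export
run_cohort <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    coh <- generate_cohort(n = sim$n, seed = config$seed,
                           shape = sim$shape %||% c(64, 64, 64),
                           spacing_mm = sim$spacing_mm %||% c(4.5, 4.5, 4.5))
    subjects <- coh$subjects
    loaders <- lapply(seq_along(coh$pairs), function(i) {
      p <- coh$pairs[[i]]
      # lobes come from the phantom's own fissure planes; adopting the
      # ground-truth label maps as "external" masks would make the
      # segmentation QC self-referential
      function() list(supine = p$supine_vol, prone = p$prone_vol,
                      supine_labels = NULL, prone_labels = NULL,
                      fissures = p$fissures)
    })
    ids <- vapply(subjects, function(s) s$subject_id, character(1))
  } else if (!is.null(config$subjects)) {
    tab <- config$subjects
    need <- c("subject_id", "supine", "prone")
    if (!all(need %in% names(tab)))
      stop("run_cohort: config$subjects needs columns ",
           paste(need, collapse = ", "))
    subjects <- NULL
    ids <- as.character(tab$subject_id)
    loaders <- lapply(seq_len(nrow(tab)), function(i) {
      function() {
        list(supine = read_volume(tab$supine[i]),
             prone = read_volume(tab$prone[i]),
             supine_labels = if (!is.null(tab$supine_labels) &&
                                 nzchar(tab$supine_labels[i]))
               read_labelmap(tab$supine_labels[i]) else NULL,
             prone_labels = if (!is.null(tab$prone_labels) &&
                                nzchar(tab$prone_labels[i]))
               read_labelmap(tab$prone_labels[i]) else NULL,
             fissures = NULL)
      }
    })
  } else {
    stop("run_cohort: config must set either 'simulate' or 'subjects'")
  }

  results <- vector("list", length(loaders))
  disposition <- character(length(loaders))
  for (i in seq_along(loaders)) {
    res <- tryCatch({
      inp <- loaders[[i]]()
      analyze_subject(inp$supine, inp$prone,
                      supine_labels = inp$supine_labels,
                      prone_labels = inp$prone_labels,
                      fissures = inp$fissures,
                      subject_id = ids[i],
                      preprocess_cfg = config$preprocess_cfg,
                      segmentation_cfg = config$segmentation_cfg,
                      demons_cfg = config$demons_cfg,
                      qc_dice_threshold = config$qc_dice_threshold,
                      movement_percentile = config$movement_percentile)
    }, error = function(e) {
      structure(list(subject_id = ids[i],
                     qc = list(pass = FALSE,
                               reasons = paste0("error: ", conditionMessage(e))),
                     volume_report = NULL, movement = NULL,
                     dice_whole = NA_real_, dice_right = NA_real_,
                     dice_left = NA_real_, affine = NULL, field = NULL,
                     masks = NULL),
                class = "subject_result")
    })
    results[[i]] <- res
    disposition[i] <- if (isTRUE(res$qc$pass)) "passed"
      else if (any(grepl("^error", res$qc$reasons))) "errored"
      else if (any(grepl("registration_failure", res$qc$reasons))) "registration_failure"
      else "segmentation_failure"
    # per-subject JSON (geometry-free summary)
    js <- list(subject_id = res$subject_id, qc = res$qc,
               volume_report = res$volume_report,
               movement = res$movement[c("max_abs_x_cm", "max_abs_y_cm",
                                         "max_abs_z_cm", "max_3d_cm")],
               dice = list(whole = res$dice_whole, right = res$dice_right,
                           left = res$dice_left))
    jsonlite::write_json(js, file.path(out_dir, paste0(ids[i], ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }

  df <- results_to_df(results)
  utils::write.csv(df, file.path(out_dir, "cohort.csv"), row.names = FALSE)

  tables <- NULL
  if (!is.null(subjects) && sum(disposition == "passed") >= 3) {
    tables <- cohort_tables(results, subjects,
                            include_failed = !config$exclude_failed)
    utils::write.csv(tables$volume_table,
                     file.path(out_dir, "volume_table.csv"), row.names = FALSE)
    for (nm in names(tables$movement_tables))
      utils::write.csv(tables$movement_tables[[nm]],
                       file.path(out_dir, paste0("movement_", nm, ".csv")),
                       row.names = FALSE)
    utils::write.csv(tables$correlations,
                     file.path(out_dir, "correlations.csv"), row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("pronelung")),
    seed = config$seed,
    config_hash = .config_hash(config),
    subjects_in = length(loaders),
    counts = as.list(table(factor(disposition,
                                  levels = c("passed", "registration_failure",
                                             "segmentation_failure", "errored")))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(results = results, subjects = subjects, tables = tables,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_hash <- function(config) {
  keep <- config[setdiff(names(config),
                         c("preprocess_cfg", "segmentation_cfg", "demons_cfg",
                           "subjects"))]
  txt <- jsonlite::toJSON(keep, auto_unbox = TRUE, digits = 10, force = TRUE)
  # small deterministic polynomial hash; avoids a digest dependency
  bytes <- utf8ToInt(as.character(txt))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
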