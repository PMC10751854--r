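# End-to-end orchestration: phantom/patient mapping runs and cohort analysis
# from a single configuration, with per-stage logging and a config audit echo.

#' Build a run configuration
#'
#' Defaults reproduce the published analysis parameters: inFAT HU range
#' [-194, -5] split at -50, and a 5 mm distal-PV exclusion.
#'
#' @param volume,endo,epi,landmarks input file paths (NIfTI / PLY / JSON);
#'   alternatively supply `phantom` to generate inputs.
#' @param phantom a [phantom_spec()] (takes precedence over paths).
#' @param thresholds a [hu_thresholds()].
#' @param exclusion_mm PV exclusion distance (mm).
#' @param seed integer seed for phantom randomness.
#' @param out_dir output directory for reports.
#' @return list of class `run_config`.
#' @export
run_config <- function(volume = NULL, endo = NULL, epi = NULL,
                       landmarks = NULL, phantom = NULL,
                       thresholds = hu_thresholds(), exclusion_mm = 5,
                       seed = 1L, out_dir = tempfile("lafat_run_")) {
  structure(list(volume = volume, endo = endo, epi = epi,
                 landmarks = landmarks, phantom = phantom,
                 thresholds = thresholds, exclusion_mm = exclusion_mm,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file; recognised keys mirror [run_config()] arguments,
#'   with `thresholds: [infat_low, dense_high, infat_high]` as a list and
#'   `phantom:` as a list of [phantom_spec()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  thr <- if (!is.null(y$thresholds))
    do.call(hu_thresholds, as.list(y$thresholds)) else hu_thresholds()
  ph <- if (!is.null(y$phantom)) do.call(phantom_spec, y$phantom) else NULL
  run_config(volume = y$volume, endo = y$endo, epi = y$epi,
             landmarks = y$landmarks, phantom = ph, thresholds = thr,
             exclusion_mm = y$exclusion_mm %||% 5,
             seed = y$seed %||% 1L,
             out_dir = y$out_dir %||% tempfile("lafat_run_"))
}

stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message(sprintf("[%s] %.1fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the per-patient mapping pipeline
#'
#' Executes wall thickness -> wall mask + exclusions -> fat classification ->
#' metrics -> parcellation -> regional distribution, and writes the per-
#' patient metrics CSV, the 19-row segment CSV, the thickness CSV and a JSON
#' echo of every threshold used.
#'
#' @param config a [run_config()].
#' @return list with `metrics`, `regional`, `thickness`, `paths` (invisible
#'   file locations) and the parcellation.
#' @export
run_patient <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$phantom)) {
    spec <- config$phantom
    spec$seed <- config$seed
    ph <- stage("phantom", make_phantom(spec))
    ct <- ph$ct; endo <- ph$truth$endo; epi <- ph$truth$epi
    lms <- ph$truth$landmarks
  } else {
    if (is.null(config$volume) || is.null(config$endo) || is.null(config$epi))
      stop("config needs either a phantom spec or volume/endo/epi paths")
    ct <- stage("read volume", read_ct_volume(config$volume))
    endo <- stage("read endo", read_mesh(config$endo, role = "endo"))
    epi <- stage("read epi", read_mesh(config$epi, role = "epi"))
    lms <- if (!is.null(config$landmarks))
      stage("read landmarks", read_landmarks(config$landmarks, epi)) else NULL
  }

  tm <- stage("wall thickness", compute_lawt(endo, epi))
  wall <- stage("wall mask",
                build_wall_mask(ct, endo, epi, landmarks = lms,
                                exclusion_mm = config$exclusion_mm))
  classes <- stage("fat classification",
                   classify_fat(ct, wall, config$thresholds))
  metrics <- stage("metrics", compute_metrics(classes, ct, wall, endo = endo))
  metrics$mean_lawt_mm <- tm$mean_thickness_mm

  regional <- NULL
  seg <- NULL
  if (!is.null(lms)) {
    seg <- stage("parcellation", parcellate(epi, lms,
                                            exclusion_mm = config$exclusion_mm))
    labels <- stage("voxel labels", label_wall_voxels(seg, wall, ct))
    regional <- stage("regional stats",
                      regional_distribution(classes, labels, wall))
  }

  paths <- list(metrics = file.path(config$out_dir, "patient_metrics.csv"),
                thickness = file.path(config$out_dir, "thickness.csv"),
                config = file.path(config$out_dir, "config_echo.json"))
  write_patient_report(metrics, paths$metrics)
  write_thickness_map(tm, paths$thickness)
  if (!is.null(regional)) {
    paths$segments <- file.path(config$out_dir, "segments.csv")
    write_segment_report(regional, paths$segments)
  }
  echo <- list(thresholds = unclass(config$thresholds),
               exclusion_mm = config$exclusion_mm, seed = config$seed,
               mean_lawt_mm = tm$mean_thickness_mm)
  jsonlite::write_json(echo, paths$config, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(metrics = metrics, regional = regional, thickness = tm,
                 segments = seg, paths = paths))
}

#' Run the cohort analysis
#'
#' Builds or loads a cohort table (synthetic generator, CSV path, or in-memory
#' data.frame), runs the full statistics battery and writes the cohort report
#' CSVs.
#'
#' @param cohort a `cohort_table`, a CSV path, or `NULL` to generate one.
#' @param n_per_group,effect_spec,seed passed to [make_cohort()] when
#'   `cohort` is `NULL`.
#' @param metrics metric columns to compare (default: the standard set).
#' @param covariates ANCOVA covariates.
#' @param out_dir output directory.
#' @return the `group_comparison`, invisibly, with `$paths` attached.
#' @export
run_cohort <- function(cohort = NULL,
                       n_per_group = c(paroxysmal = 30, persistent = 30,
                                       control = 20),
                       effect_spec = default_effect_spec(), seed = 1L,
                       metrics = NULL, covariates = "bmi",
                       out_dir = tempfile("lafat_cohort_")) {
  if (is.null(cohort)) {
    cohort <- make_cohort(n_per_group, effect_spec, seed)
  } else if (is.character(cohort)) {
    cohort <- read.csv(cohort, stringsAsFactors = FALSE)
    cohort$group <- factor(cohort$group,
                           levels = c("control", "paroxysmal", "persistent"))
  }
  grp <- droplevels(as.factor(cohort$group))
  if (nlevels(grp) < 2) stop("cohort must contain at least 2 groups")
  if (any(table(grp) < 2))
    stop("each group needs at least 2 patients for the statistics stage")
  if (is.null(metrics)) {
    std <- c("sex", "age", "bmi", "la_vol_ml", "lawt_mm", "wall_vol_ml",
             "infat_ml", "dense_ml", "admix_ml", "infat_hu", "dense_hu",
             "admix_hu", "infat_lavol_au", "dense_lavol_au", "admix_lavol_au",
             "infat_wallvol_au", "dense_wallvol_au", "admix_wallvol_au")
    metrics <- intersect(std, names(cohort))
  }
  cmp <- stage("cohort statistics",
               compare_groups(cohort, metrics, covariates))
  cmp$paths <- write_cohort_report(cmp, out_dir)
  invisible(cmp)
}
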