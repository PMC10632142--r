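#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

pipeline_stages <- c("synth", "dff", "tune", "dsmap", "mosaic", "classify", "morpho")

pipeline_keys <- c("seed", "out_dir", "stages", "schedule", "cells", "movie",
                   "mosaic", "classify", "morpho", "dsmap", "write_tiff")

#' Run the synthetic end-to-end analysis pipeline
#'
#' Orchestrates a full run from one configuration: generate a synthetic
#' drifting-bar movie, extract and background-correct traces, compute
#' delta-F/F, tuning statistics and the pixel vector-sum map, plus the
#' mosaic, marker-classification and morphometry stages on their own
#' synthetic inputs. Every stage's outputs are written under `out_dir`
#' together with a manifest recording package version, seeds, parameters
#' and output files; re-running the same configuration reproduces the
#' outputs and manifest exactly.
#'
#' @param config A named list, or path to a JSON file holding one. Keys:
#'   `seed` (integer, required), `out_dir` (required), `stages` (subset of
#'   `r paste(pipeline_stages, collapse = ", ")`; default all), and
#'   optional parameter lists `schedule`, `cells`, `movie`, `dsmap`,
#'   `mosaic`, `classify`, `morpho` passed to the respective generators and
#'   analyses. Unknown keys are an error.
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  unknown <- setdiff(names(config), pipeline_keys)
  if (length(unknown)) {
    abort(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  if (is.null(config$seed) || is.null(config$out_dir)) {
    abort("config must provide `seed` and `out_dir`")
  }
  stages <- config$stages %||% pipeline_stages
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) abort(sprintf("unknown stages: %s", paste(bad, collapse = ", ")))
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    if (is.data.frame(obj)) {
      utils::write.csv(obj, path, row.names = FALSE)
    } else {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    outputs <<- c(outputs, name)
    path
  }
  imaging_state <- NULL

  if (any(c("synth", "dff", "tune", "dsmap") %in% stages)) {
    sched <- do.call(stim_schedule, c(config$schedule %||% list(),
                                      list(seed = derive_seed(seed, 1))))
    cells <- do.call(synth_cells, c(config$cells %||% list(),
                                    list(seed = derive_seed(seed, 2))))
    bundle <- do.call(synth_movie, c(list(cells = cells, schedule = sched,
                                          seed = derive_seed(seed, 3)),
                                     config$movie %||% list()))
    imaging_state <- list(bundle = bundle)
    if ("synth" %in% stages) {
      emit(as.data.frame(sched), "schedule.csv")
      emit(as.data.frame(cells), "cells_truth.csv")
      if (isTRUE(config$write_tiff)) {
        write_movie_tiff(bundle, file.path(out_dir, "movie.tif"))
        outputs <- c(outputs, "movie.tif", "movie.tif.json")
      }
    }
  }
  if (any(c("dff", "tune") %in% stages)) {
    bundle <- imaging_state$bundle
    rois <- truth_rois(bundle$cells, bundle$movie)
    traces <- extract_traces(bundle$movie, rois) |>
      subtract_background(rep(bundle$background_f, dim(bundle$movie$stack)[1])) |>
      compute_dff(bundle$schedule)
    imaging_state$traces <- traces
    if ("dff" %in% stages) emit(as.data.frame(traces), "dff_traces.csv")
  }
  if ("tune" %in% stages) {
    resp <- epoch_responses(imaging_state$traces, imaging_state$bundle$schedule)
    prof <- tuning_profiles(resp, traces = imaging_state$traces,
                            schedule = imaging_state$bundle$schedule)
    emit(as.data.frame(resp), "epoch_responses.csv")
    emit(as.data.frame(dplyr::select(prof, -"vm_fit")), "tuning_profiles.csv")
  }
  if ("dsmap" %in% stages) {
    bundle <- imaging_state$bundle
    pars <- config$dsmap %||% list()
    vm <- pixel_vector_sum_map(bundle$movie, bundle$schedule,
                               sigma_px = pars$sigma_px %||% 2)
    cand <- detect_candidates(vm, threshold = pars$threshold %||% 0.995,
                              min_area_px = pars$min_area_px %||% 4)
    metrics <- ds_detection_metrics(cand, bundle$cells)
    emit(as.data.frame(cand), "ds_candidates.csv")
    emit(as.list(metrics), "ds_detection_metrics.json")
  }
  if ("mosaic" %in% stages) {
    pars <- config$mosaic %||% list()
    region <- pars$region %||% c(0, 2000, 0, 2000)
    mos <- synth_mosaic(pars$kind %||% "exclusion",
                        density_per_mm2 = pars$density_per_mm2 %||% 30,
                        region = region,
                        d_min_um = pars$d_min_um %||% 100,
                        seed = derive_seed(seed, 4))
    vr <- voronoi_regularity(mos)
    null <- random_null_vdri(nrow(mos), region,
                             n_sims = pars$n_sims %||% 100,
                             seed = derive_seed(seed, 5),
                             observed = attr(vr, "vdri"))
    drp <- density_recovery_profile(mos)
    emit(as.data.frame(mos), "mosaic_points.csv")
    emit(as.data.frame(drp), "drp_profile.csv")
    emit(c(as.list(glance(vr)), as.list(glance(null)),
           convergence_pct = attr(drp, "convergence_pct")),
         "mosaic_summary.json")
  }
  if ("classify" %in% stages) {
    pars <- config$classify %||% list()
    tbl <- synth_marker_table(
      n_cells = pars$n_cells %||% 500,
      class_fractions = c(double_pos = 0.5, single_pos = 0.5),
      channel_means = matrix(c(10, 10, 10, 4), 2, 2,
                             dimnames = list(c("double_pos", "single_pos"),
                                             c("bnc2", "foxp2"))),
      channel_sds = 1, seed = derive_seed(seed, 6)
    )
    tbl <- zscore_channels(tbl, c("bnc2", "foxp2"))
    tbl <- kmeans_classify(tbl, c("bnc2", "foxp2"), k = 2,
                           labels = c("double_pos", "single_pos"),
                           seed = derive_seed(seed, 7))
    emit(as.data.frame(tbl), "marker_classification.csv")
    emit(list(kmeans_truth_agreement = mean(tbl$assigned_label == tbl$true_class)),
         "classification_summary.json")
  }
  if ("morpho" %in% stages) {
    vols <- synth_dendrite_volumes(seed = derive_seed(seed, 8))
    cf <- contact_fraction(vols$ref, vols$partner)
    emit(list(total_overlap_pct = cf$total_overlap_pct,
              rotated_overlap_pct = cf$rotated_overlap_pct),
         "contact_summary.json")
  }

  manifest <- list(
    package = "retinads",
    version = as.character(utils::packageVersion("retinads")),
    seed = seed,
    stages = stages,
    parameters = config[setdiff(names(config), c("out_dir"))],
    outputs = sort(unique(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
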