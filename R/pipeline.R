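#' Load a pipeline run configuration
#'
#' One YAML file drives all pipeline stages; values omitted from the file
#' take the defaults below. See the package vignette for the schema.
#'
#' @param config Path to a YAML file, or a named list with the same
#'   structure (returned unchanged apart from default filling).
#' @return A `run_config` list.
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    output_dir = "tlsdyn_out",
    master_seed = 1L,
    scene = list(density = 120000, stem_density = 2e6,
                 sphere_density = 150000, noise_sigma = 0.001,
                 dropout = 0, n_dai = 41L, interval_s = 1200, a_tip = 0.15,
                 intensity = NULL),
    input = list(paths = NULL, timestamps = NULL),
    filters = list(min_intensity = 650, iso_radius = 0.01,
                   iso_min_neighbors = 2L),
    clustering = list(d_min = 0.15, min_size = 100L),
    tracking = list(mode = "chain", reference = "initial"),
    axis = list(origin = c(0, 0, 0), direction = c(0, 0, 1)),
    map = list(cell = 2, dai = NULL, running_max = FALSE),
    annotations = list(sunset_s = 2280, sunrise_s = 35400)
  )
  merged <- utils::modifyList(defaults, config)
  class(merged) <- "run_config"
  merged
}

config_fparams <- function(cfg) {
  filter_params(min_intensity = cfg$filters$min_intensity,
                iso_radius = cfg$filters$iso_radius,
                iso_min_neighbors = cfg$filters$iso_min_neighbors)
}

config_cparams <- function(cfg) {
  cluster_params(d_min = cfg$clustering$d_min,
                 min_size = cfg$clustering$min_size,
                 rng_seed = cfg$master_seed)
}

write_manifest <- function(cfg, command, artifacts, extra = list()) {
  manifest <- c(list(
    command = command,
    package_version = as.character(utils::packageVersion("tlsdyn")),
    master_seed = cfg$master_seed,
    config = unclass(cfg),
    artifacts = artifacts,
    artifact_md5 = as.list(tools::md5sum(file.path(cfg$output_dir, artifacts)))
  ), extra)
  jsonlite::write_json(manifest,
                       file.path(cfg$output_dir,
                                 sprintf("manifest_%s.json", command)),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

#' Run a pipeline stage
#'
#' Stages of the end-to-end workflow, each writing its documented artifacts
#' plus a machine-readable manifest (parameters, seed, artifact digests)
#' into `output_dir`:
#' \describe{
#'   \item{`simulate`}{Generate the synthetic DAI series; writes one
#'     `dai_###.xyz` cloud per epoch and `ground_truth.csv`.}
#'   \item{`track`}{Preprocess, cluster the first epoch, propagate labels
#'     and write `tracks.csv` + `displacements.csv`. Inputs are either
#'     `input$paths` (one cloud file per epoch) or, when those are absent,
#'     a simulation run from this same config.}
#'   \item{`aggregate`}{Read `tracks.csv`/`displacements.csv` and write the
#'     height-normalized maximum-displacement map (`map_dai<k>.csv`) and
#'     percentile summaries (`summary.json`).}
#'   \item{`report`}{Write per-cluster time-series CSV and a displacement
#'     figure (`timeseries.png`).}
#' }
#' Every run is deterministic given the config and `master_seed`; all CSV
#' headers name their units.
#'
#' @param command One of `"simulate"`, `"track"`, `"aggregate"`, `"report"`.
#' @param config A YAML path or config list (see [load_config()]).
#' @return Invisibly, a list of artifact paths.
#' @export
run_pipeline <- function(command = c("simulate", "track", "aggregate", "report"),
                         config = list()) {
  command <- match.arg(command)
  cfg <- load_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  switch(command,
         simulate = stage_simulate(cfg),
         track = stage_track(cfg),
         aggregate = stage_aggregate(cfg),
         report = stage_report(cfg))
}

default_scene_objects <- function(cfg) {
  list(scene = scene_model(),
       deform = deformation_config(A_tip = cfg$scene$a_tip))
}

simulate_series <- function(cfg) {
  so <- default_scene_objects(cfg)
  generate_time_series(
    scene = so$scene, deform = so$deform,
    n_dai = cfg$scene$n_dai, interval_s = cfg$scene$interval_s,
    master_seed = cfg$master_seed,
    density = cfg$scene$density, stem_density = cfg$scene$stem_density,
    sphere_density = cfg$scene$sphere_density,
    noise_sigma = cfg$scene$noise_sigma, dropout = cfg$scene$dropout,
    intensity = cfg$scene$intensity)
}

stage_simulate <- function(cfg) {
  sim <- simulate_series(cfg)
  arts <- character(0)
  for (i in seq_along(sim$dais$clouds)) {
    f <- sprintf("dai_%03d.xyz", i - 1L)
    write_cloud(sim$dais$clouds[[i]], file.path(cfg$output_dir, f))
    arts <- c(arts, f)
    message(sprintf("simulate: DAI %d, %d points, s = %.3f",
                    i - 1L, n_points(sim$dais$clouds[[i]]), sim$s[i]))
  }
  gt <- do.call(rbind, lapply(seq_along(sim$dais$clouds), function(i) {
    cl <- sim$dais$clouds[[i]]
    data.frame(dai = i - 1L, timestamp_s = sim$timestamps[i],
               component = cl$component, surface_id = cl$surface_id,
               true_disp_m = cl$true_disp_m)
  }))
  utils::write.csv(gt, file.path(cfg$output_dir, "ground_truth.csv"),
                   row.names = FALSE)
  arts <- c(arts, "ground_truth.csv")
  if (!is.null(sim$tip_truth)) {
    utils::write.csv(sim$tip_truth,
                     file.path(cfg$output_dir, "tip_truth.csv"),
                     row.names = FALSE)
    arts <- c(arts, "tip_truth.csv")
  }
  write_manifest(cfg, "simulate", arts,
                 extra = list(n_dai = length(sim$dais$clouds)))
  invisible(file.path(cfg$output_dir, arts))
}

load_input_sequence <- function(cfg) {
  if (!is.null(cfg$input$paths)) {
    clouds <- lapply(cfg$input$paths, read_cloud)
    ts <- cfg$input$timestamps
    if (is.null(ts)) ts <- (seq_along(clouds) - 1L) * cfg$scene$interval_s
    dai_sequence(clouds, ts)
  } else {
    simulate_series(cfg)$dais
  }
}

stage_track <- function(cfg) {
  dais <- load_input_sequence(cfg)
  n_in <- vapply(dais$clouds, n_points, numeric(1))
  fp <- config_fparams(cfg)
  clouds <- lapply(dais$clouds, preprocess_cloud, params = fp)
  n_out <- vapply(clouds, n_points, numeric(1))
  message(sprintf("track: filters kept %d of %d points over %d DAIs",
                  sum(n_out), sum(n_in), length(clouds)))
  dais_f <- dai_sequence(clouds, dais$timestamps)
  tracks <- track_sequence(dais_f, params = config_cparams(cfg),
                           fparams = fp, mode = cfg$tracking$mode,
                           preprocess = FALSE)
  disp <- displacements(tracks, reference = cfg$tracking$reference)
  tt <- tracks_table(tracks)
  dt <- displacement_table(disp)
  utils::write.csv(tt, file.path(cfg$output_dir, "tracks.csv"), row.names = FALSE)
  utils::write.csv(dt, file.path(cfg$output_dir, "displacements.csv"),
                   row.names = FALSE)
  message(sprintf("track: %d clusters, %d cluster-DAI cells missing",
                  tracks$K, sum(tracks$missing)))
  write_manifest(cfg, "track", c("tracks.csv", "displacements.csv"),
                 extra = list(n_clusters = tracks$K,
                              points_in = sum(n_in), points_kept = sum(n_out)))
  invisible(file.path(cfg$output_dir, c("tracks.csv", "displacements.csv")))
}

#' Rebuild cluster tracks from an exported table
#'
#' Inverse of [tracks_table()], so aggregation stages can run from CSV
#' artifacts without re-tracking.
#'
#' @param df Data frame with the [tracks_table()] columns.
#' @param mode Propagation mode recorded with the run.
#' @return A `cluster_tracks`.
#' @export
tracks_from_table <- function(df, mode = "chain") {
  K <- max(df$cluster_id)
  daiv <- sort(unique(df$dai))
  nd <- length(daiv)
  centers <- array(NA_real_, c(K, 3, nd))
  counts <- matrix(0L, K, nd)
  ts <- numeric(nd)
  for (i in seq_len(nd)) {
    o <- df[df$dai == daiv[i], , drop = FALSE]
    centers[o$cluster_id, 1L, i] <- o$cx_m
    centers[o$cluster_id, 2L, i] <- o$cy_m
    centers[o$cluster_id, 3L, i] <- o$cz_m
    counts[o$cluster_id, i] <- o$n
    ts[i] <- o$timestamp_s[1L]
  }
  structure(list(centers = centers, counts = counts, missing = counts == 0L,
                 timestamps = ts, K = K, mode = mode,
                 labels0 = NULL, cloud0 = NULL, params = NULL),
            class = "cluster_tracks")
}

stage_aggregate <- function(cfg) {
  tt <- utils::read.csv(file.path(cfg$output_dir, "tracks.csv"))
  tracks <- tracks_from_table(tt, mode = cfg$tracking$mode)
  disp <- displacements(tracks, reference = "initial")
  axis <- principal_axis(unlist(cfg$axis$origin), unlist(cfg$axis$direction))
  nd <- ncol(disp$disp)
  dai <- if (is.null(cfg$map$dai)) nd - 1L else cfg$map$dai
  map <- max_displacement_map(tracks, disp, axis, dai = dai,
                              cell = cfg$map$cell,
                              running_max = isTRUE(cfg$map$running_max))
  mf <- sprintf("map_dai%03d.csv", dai)
  write_map_csv(map, file.path(cfg$output_dir, mf))
  summ <- list(
    n_clusters = tracks$K,
    p99_overall_max_disp_m = unname(percentile_summary(disp, 99, "overall-max")),
    p50_overall_max_disp_m = unname(percentile_summary(disp, 50, "overall-max")),
    max_disp_m = max(disp$disp, na.rm = TRUE),
    map_dai = dai
  )
  jsonlite::write_json(summ, file.path(cfg$output_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(sprintf("aggregate: 99th-percentile overall-max displacement %.4f m",
                  summ$p99_overall_max_disp_m))
  write_manifest(cfg, "aggregate", c(mf, "summary.json"))
  invisible(file.path(cfg$output_dir, c(mf, "summary.json")))
}

stage_report <- function(cfg) {
  tt <- utils::read.csv(file.path(cfg$output_dir, "tracks.csv"))
  tracks <- tracks_from_table(tt, mode = cfg$tracking$mode)
  disp <- displacements(tracks, reference = cfg$tracking$reference)
  ids <- if (!is.null(cfg$report$cluster_ids)) {
    as.integer(unlist(cfg$report$cluster_ids))
  } else {
    # default: a spread of clusters by overall maximum displacement
    mx <- apply(disp$disp, 1, function(v) if (all(is.na(v))) NA else max(v, na.rm = TRUE))
    ok <- which(!is.na(mx))
    ok[order(mx[ok])][unique(pmax(1L, round(seq(1, length(ok), length.out = 7))))]
  }
  ann <- c(sunset = cfg$annotations$sunset_s, sunrise = cfg$annotations$sunrise_s)
  ts <- cluster_timeseries(tracks, disp, ids, annotations = ann)
  utils::write.csv(ts, file.path(cfg$output_dir, "timeseries.csv"),
                   row.names = FALSE)
  grDevices::png(file.path(cfg$output_dir, "timeseries.png"),
                 width = 900, height = 520)
  on.exit(grDevices::dev.off())
  plot(NA, xlim = range(ts$timestamp_s) / 3600,
       ylim = c(0, max(ts$displacement_m) * 1.05),
       xlab = "time since sequence start (h)",
       ylab = "cluster displacement from initial DAI (m)",
       main = "Cluster center displacement over the night")
  for (a in ann) abline(v = a / 3600, lty = 3, col = "grey40")
  cols <- grDevices::hcl.colors(length(ids), "Dark 3")
  for (j in seq_along(ids)) {
    o <- ts[ts$cluster_id == ids[j], ]
    lines(o$timestamp_s / 3600, o$displacement_m, col = cols[j], lwd = 2)
  }
  legend("topleft", legend = paste("cluster", ids), col = cols, lwd = 2,
         cex = 0.8, bty = "n")
  write_manifest(cfg, "report", c("timeseries.csv", "timeseries.png"),
                 extra = list(cluster_ids = ids))
  invisible(file.path(cfg$output_dir, c("timeseries.csv", "timeseries.png")))
}
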