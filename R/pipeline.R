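# End-to-end orchestration: YAML study configuration, the per-cohort
# analysis chain (orient -> landmarks -> GPA -> TPS -> fuse -> intensity ->
# inference), staged execution with persisted state, and the command-line
# front-end.

default_config <- function() {
  list(
    input = list(type = "synthetic", n_nuclei = 20, model = "csr",
                 n_points = 8, render = FALSE, dims = c(20, 250, 250)),
    channel_map = list(envelope = 1, compartment = 2),
    spacing = c(0.5, 0.1, 0.1),
    threshold_method = "otsu",
    min_size = 4,
    component_connectivity = 26,
    n_rings = 9, n_per_ring = 16,
    grid_target = 64^3,
    M = 499, alpha = 0.05,
    cluster_connectivity = 6,
    statistic = "tfce",
    tps_ridge = 0,
    smooth_intensity = FALSE,
    seed = 1,
    out_dir = "nucleomap_out"
  )
}

#' Validate and complete a study configuration
#'
#' Unknown keys fail fast; every value is checked before any computation.
#'
#' @param config named list (e.g. from [yaml::read_yaml()]); missing keys
#'   take defaults.
#' @return The completed configuration list, classed `study_config`.
#' @export
study_config <- function(config = list()) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(base, config)
  chk <- function(ok, key, what)
    if (!ok) stop(sprintf("config error: '%s' %s", key, what))
  chk(cfg$input$type %in% c("synthetic", "stacks"), "input.type",
      "must be 'synthetic' or 'stacks'")
  if (cfg$input$type == "synthetic") {
    chk(isTRUE(cfg$input$n_nuclei >= 2), "input.n_nuclei", "must be >= 2")
    chk(cfg$input$model %in% c("csr", "central", "annular", "shell_excluded"),
        "input.model", "must name a pattern model")
  } else {
    chk(is.character(cfg$input$manifest %||% NA), "input.manifest",
        "must point to a cohort manifest CSV")
  }
  chk(length(cfg$spacing) == 3 && all(cfg$spacing > 0), "spacing",
      "must be three positive (z, y, x) lengths")
  chk(cfg$min_size >= 1, "min_size", "must be >= 1")
  chk(cfg$component_connectivity %in% c(6, 18, 26), "component_connectivity",
      "must be 6, 18 or 26")
  chk(cfg$n_rings >= 1 && cfg$n_per_ring >= 3, "n_rings/n_per_ring",
      "must give at least one ring of >= 3 landmarks")
  chk(cfg$grid_target >= 100, "grid_target", "must be >= 100")
  chk(cfg$M >= 1, "M", "must be >= 1")
  chk(cfg$alpha > 0 && cfg$alpha <= 0.5, "alpha", "must lie in (0, 0.5]")
  chk(cfg$cluster_connectivity %in% c(6, 18, 26), "cluster_connectivity",
      "must be 6, 18 or 26")
  chk(cfg$statistic %in% c("cluster_size", "tfce"), "statistic",
      "must be 'cluster_size' or 'tfce'")
  structure(cfg, class = "study_config")
}

# segment one stack into a boundary + compartment centres
segment_stack <- function(stack, cfg, replicate_id) {
  env_mask <- threshold_channel(stack, "envelope", cfg$threshold_method)
  bnd <- boundary_hull(env_mask, stack$spacing, replicate_id)
  comp_mask <- threshold_channel(stack, "compartment", cfg$threshold_method)
  pat <- compartment_centres(comp_mask, stack$spacing, bnd,
                             min_size = cfg$min_size,
                             connectivity = cfg$component_connectivity,
                             replicate_id = replicate_id)
  list(boundary = bnd, pattern = pat, replicate_id = replicate_id)
}

#' Analyse a cohort of segmented replicates
#'
#' Runs the whole statistical chain on (boundary, point pattern) pairs:
#' ovoid-tip orientation, landmark placement, GPA mean shape, TPS
#' registration and fusion, voxelization, intensity estimation, CSR null
#' simulation and family-wise significance maps.
#'
#' @param replicates list of lists with fields `boundary`
#'   (`convex_boundary`), `pattern` ([point_pattern()]) and `replicate_id`.
#' @param n_rings,n_per_ring landmark layout.
#' @param grid_target bounding-grid voxel budget for [voxelize()].
#' @param M,alpha Monte-Carlo iterations and test level.
#' @param connectivity cluster connectivity (6, 18 or 26).
#' @param statistic `"cluster_size"` or `"tfce"`.
#' @param seed master seed for the null simulation.
#' @param tps_ridge,smooth passed to the registration / intensity stages.
#' @param tip_overrides optional named list of manual in-plane tip
#'   directions per replicate id.
#' @return A list with all intermediate objects: `oriented_boundaries`,
#'   `landmark_sets`, `oriented_patterns`, `mean`, `am`, `grid`,
#'   `intensity`, `observed`, `null`, `sig`.
#' @export
analyse_cohort <- function(replicates, n_rings = 9, n_per_ring = 16,
                           grid_target = 64^3, M = 499, alpha = 0.05,
                           connectivity = 6L, statistic = "tfce",
                           seed = 1L, tps_ridge = 0, smooth = FALSE,
                           tip_overrides = NULL) {
  oriented <- orient_cohort(replicates, n_rings, n_per_ring, tip_overrides)
  mean_shape <- gpa_mean_shape(oriented$landmark_sets)
  am <- build_aggregate_map(oriented$landmark_sets, oriented$patterns,
                            mean_shape, ridge = tps_ridge)
  grid <- voxelize(mean_shape, grid_target)
  observed <- observed_enhanced(am, grid, connectivity, statistic,
                                smooth = smooth)
  null <- simulate_null(am, oriented$boundaries, grid, M = M, seed = seed,
                        connectivity = connectivity, mode = statistic,
                        smooth = smooth)
  sig <- significance_maps(observed, null, alpha)
  list(oriented_boundaries = oriented$boundaries,
       landmark_sets = oriented$landmark_sets,
       oriented_patterns = oriented$patterns,
       mean = mean_shape, am = am, grid = grid,
       intensity = observed$intensity, observed = observed,
       null = null, sig = sig)
}

# orientation + landmark placement for every replicate
orient_cohort <- function(replicates, n_rings, n_per_ring,
                          tip_overrides = NULL) {
  boundaries <- list(); sets <- list(); patterns <- list()
  for (rep in replicates) {
    id <- rep$replicate_id
    tip <- find_ovoid_tip(rep$boundary, tip_override = tip_overrides[[id]])
    ori <- orient_nucleus(rep$boundary, tip$direction)
    boundaries[[id]] <- ori$boundary
    lm <- place_landmarks(ori$boundary, n_rings, n_per_ring, id)
    lm$orientation <- ori[c("rotation", "translation")]
    sets[[id]] <- lm
    pat <- rep$pattern
    if (nrow(pat$points) > 0)
      pat$points <- apply_orientation(ori, pat$points)
    patterns[[id]] <- pat
  }
  list(boundaries = boundaries, landmark_sets = sets, patterns = patterns)
}

# ---- staged pipeline ------------------------------------------------------

pipeline_stages <- c("segment", "landmarks", "meanshape", "register",
                     "intensity", "test", "project")

state_path <- function(out_dir) file.path(out_dir, "state.rds")

load_state <- function(out_dir, needed_stage) {
  p <- state_path(out_dir)
  if (!file.exists(p))
    stop(sprintf("data error: no pipeline state in '%s'; run earlier stages first (missing before '%s')",
                 out_dir, needed_stage))
  readRDS(p)
}

run_stage <- function(state, stage, out_dir) {
  cfg <- state$config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(stage,
    segment = {
      reps <- if (cfg$input$type == "synthetic") {
        cohort <- generate_cohort(
          cfg$input$n_nuclei,
          pattern = pattern_spec(cfg$input$model,
                                 n_points = cfg$input$n_points),
          imaging = imaging_params(dims = cfg$input$dims %||% c(20, 250, 250),
                                   spacing = cfg$spacing),
          seed = cfg$seed, render = isTRUE(cfg$input$render))
        if (isTRUE(cfg$input$render)) {
          lapply(cohort, function(r)
            segment_stack(r$stack, cfg, r$replicate_id))
        } else {
          lapply(cohort, function(r) r[c("boundary", "pattern", "replicate_id")])
        }
      } else {
        man <- read_table(cfg$input$manifest)
        lapply(seq_len(nrow(man)), function(i) {
          stk <- read_stack(man$path[i], unlist(cfg$channel_map), cfg$spacing)
          segment_stack(stk, cfg, as.character(man$replicate_id[i]))
        })
      }
      centres <- do.call(rbind, lapply(reps, function(r)
        if (nrow(r$pattern$points))
          data.frame(replicate_id = r$replicate_id, x = r$pattern$points[, 1],
                     y = r$pattern$points[, 2], z = r$pattern$points[, 3],
                     size = r$pattern$source_sizes)
        else NULL))
      write_table(centres %||% data.frame(replicate_id = character(0),
                                          x = numeric(0), y = numeric(0),
                                          z = numeric(0), size = numeric(0)),
                  file.path(out_dir, "centres.csv"))
      state$replicates <- reps
      state
    },
    landmarks = {
      state$oriented <- orient_cohort(state$replicates, cfg$n_rings,
                                      cfg$n_per_ring)
      lm_tab <- do.call(rbind, lapply(state$oriented$landmark_sets, function(s)
        data.frame(replicate_id = s$replicate_id,
                   index = seq_len(nrow(s$landmarks)) - 1L,
                   ring = s$ring, azimuth = s$azimuth,
                   x = s$landmarks[, 1], y = s$landmarks[, 2],
                   z = s$landmarks[, 3])))
      write_table(lm_tab, file.path(out_dir, "landmarks.csv"))
      state
    },
    meanshape = {
      state$mean <- gpa_mean_shape(state$oriented$landmark_sets)
      write_table(data.frame(index = seq_len(nrow(state$mean$mean_landmarks)) - 1L,
                             x = state$mean$mean_landmarks[, 1],
                             y = state$mean$mean_landmarks[, 2],
                             z = state$mean$mean_landmarks[, 3]),
                  file.path(out_dir, "mean_landmarks.csv"))
      write_ply(file.path(out_dir, "mean_shape.ply"),
                state$mean$mean_hull$vertices, state$mean$mean_hull$faces)
      state
    },
    register = {
      state$am <- build_aggregate_map(state$oriented$landmark_sets,
                                      state$oriented$patterns, state$mean,
                                      ridge = cfg$tps_ridge)
      pts <- state$am$points
      write_table(data.frame(replicate_id = state$am$replicate_id,
                             x = pts[, 1], y = pts[, 2], z = pts[, 3],
                             clipped = state$am$clipped),
                  file.path(out_dir, "fused_points.csv"))
      state
    },
    intensity = {
      state$grid <- voxelize(state$mean, cfg$grid_target)
      state$observed <- observed_enhanced(state$am, state$grid,
                                          cfg$cluster_connectivity,
                                          cfg$statistic,
                                          smooth = cfg$smooth_intensity)
      write_array(state$observed$intensity$values, state$grid$origin,
                  state$grid$voxel_size, file.path(out_dir, "intensity"),
                  meta = list(csr_level = state$observed$intensity$csr_level))
      state
    },
    test = {
      if (is.null(state$observed))
        stop("data error: 'test' requires the 'intensity' stage outputs")
      state$null <- simulate_null(state$am, state$oriented$boundaries,
                                  state$grid, M = cfg$M, seed = cfg$seed,
                                  connectivity = cfg$cluster_connectivity,
                                  mode = cfg$statistic,
                                  smooth = cfg$smooth_intensity)
      state$sig <- significance_maps(state$observed, state$null, cfg$alpha)
      for (dir in c("aggregated", "dispersed"))
        write_array(state$sig[[paste0("reject_", dir)]] + 0,
                    state$grid$origin, state$grid$voxel_size,
                    file.path(out_dir, paste0("reject_", dir)))
      state
    },
    project = {
      for (dir in c("aggregated", "dispersed")) {
        pr <- project_proportion(state$sig, dir)
        utils::write.csv(pr$pixels,
                         file.path(out_dir, sprintf("projection_%s.csv", dir)),
                         row.names = FALSE)
        plot_projection(pr, file.path(out_dir, sprintf("projection_%s.png", dir)))
        export_3d(state$sig, state$mean$mean_hull,
                  file.path(out_dir, dir), dir,
                  cutaway = c(1, 1, 1))
      }
      pr <- project_mean_intensity(state$observed$intensity)
      utils::write.csv(pr$pixels, file.path(out_dir, "projection_intensity.csv"),
                       row.names = FALSE)
      state
    },
    stop("unknown stage: ", stage))
}

write_manifest <- function(state, out_dir) {
  man <- list(
    package = "nucleomap",
    version = as.character(utils::packageVersion("nucleomap")),
    seed = state$config$seed,
    n_replicates = if (!is.null(state$am)) state$am$R else length(state$replicates),
    n_i = if (!is.null(state$am)) as.list(state$am$n_i) else NULL,
    clip_count = state$am$clip_count %||% NULL,
    gpa_converged = state$mean$converged %||% NULL,
    gpa_iterations = state$mean$n_iter %||% NULL,
    csr_level = state$observed$intensity$csr_level %||% NULL,
    n_null = state$null$M %||% NULL,
    alpha = state$config$alpha,
    reject_aggregated = if (!is.null(state$sig)) sum(state$sig$reject_aggregated) else NULL,
    reject_dispersed = if (!is.null(state$sig)) sum(state$sig$reject_dispersed) else NULL)
  jsonlite::write_json(man[!vapply(man, is.null, TRUE)],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the full aggregate-map pipeline from a configuration
#'
#' Executes segment -> landmarks -> meanshape -> register -> intensity ->
#' test -> project, writing per-stage outputs, persisted state and a JSON
#' run manifest into the output directory. Re-running with the same
#' configuration reproduces all stochastic outputs exactly.
#'
#' @param config a [study_config()], a named list, or a YAML file path.
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @param stages subset of stages to run (in order), defaulting to all.
#' @return The final pipeline state, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL,
                         stages = pipeline_stages) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- if (inherits(config, "study_config")) config else study_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  state <- if (identical(stages[1], "segment")) list(config = cfg)
           else { s <- load_state(out_dir, stages[1]); s$config <- cfg; s }
  for (stage in stages) {
    state <- tryCatch(run_stage(state, stage, out_dir),
                      error = function(e)
                        stop(sprintf("stage '%s' failed: %s", stage,
                                     conditionMessage(e)), call. = FALSE))
    saveRDS(state, state_path(out_dir))
  }
  write_manifest(state, out_dir)
  invisible(state)
}

#' Command-line entry point
#'
#' Dispatches `nucleomap <subcommand> --config study.yaml [--out DIR]`.
#' Subcommands: `run` (all stages), `simulate` (write a rendered synthetic
#' cohort + manifest), or any single stage name. Exit codes: 0 success,
#' 2 configuration error, 3 data error.
#'
#' @param args character vector (defaults to the process arguments).
#' @return Exit status, invisibly.
#' @export
nucleomap_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: nucleomap <run|simulate|segment|landmarks|meanshape|register|intensity|test|project> --config study.yaml [--out DIR] [--seed N]"
  status <- tryCatch({
    if (length(args) < 1) stop("config error: no subcommand\n", usage)
    cmd <- args[1]
    opt <- function(flag) {
      i <- which(args == flag)
      if (length(i) == 1 && i < length(args)) args[i + 1] else NULL
    }
    cfg_path <- opt("--config")
    cfg <- if (is.null(cfg_path)) list() else yaml::read_yaml(cfg_path)
    if (!is.null(opt("--seed"))) cfg$seed <- as.integer(opt("--seed"))
    cfg <- study_config(cfg)
    out <- opt("--out") %||% cfg$out_dir
    if (cmd == "run") run_pipeline(cfg, out)
    else if (cmd == "simulate") simulate_cohort_cmd(cfg, out)
    else if (cmd %in% pipeline_stages) run_pipeline(cfg, out, stages = cmd)
    else stop("config error: unknown subcommand '", cmd, "'\n", usage)
    0L
  }, error = function(e) {
    message(conditionMessage(e))
    if (grepl("config error", conditionMessage(e))) 2L else 3L
  })
  invisible(status)
}

# write a rendered synthetic cohort as TIFFs + manifest CSV
simulate_cohort_cmd <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(cfg$input$n_nuclei,
                            pattern = pattern_spec(cfg$input$model,
                                                   n_points = cfg$input$n_points),
                            imaging = imaging_params(dims = cfg$input$dims %||% c(20, 250, 250),
                                                     spacing = cfg$spacing),
                            seed = cfg$seed, render = TRUE)
  rows <- lapply(cohort, function(r) {
    p <- file.path(out_dir, paste0(r$replicate_id, ".tif"))
    write_stack(r$stack, p)
    data.frame(replicate_id = r$replicate_id, path = p, seed = cfg$seed,
               model = cfg$input$model, n_points = nrow(r$pattern$points))
  })
  write_table(do.call(rbind, rows), file.path(out_dir, "cohort_manifest.csv"))
  invisible(out_dir)
}
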