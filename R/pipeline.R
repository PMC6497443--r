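# End-to-end orchestration: simulate or load, then run the enabled analysis
# stages in dependency order, writing delimited outputs and a reproducibility
# manifest. All randomness flows from one master seed, split per stage.

stage_seed <- function(master, stage) {
  offsets <- c(simulate = 11L, groups = 23L, density = 37L,
               network = 41L, ihpp = 53L, sde = 67L)
  as.integer((master + offsets[[stage]]) %% .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' @param config List with elements:
#'   * `mode`: `"synthetic"` or `"files"`.
#'   * `out_dir`: output directory (created if needed).
#'   * `seed`: master seed.
#'   * `stages`: subset of `c("groups", "density", "network", "ihpp",
#'     "sde")` (default all).
#'   * synthetic mode: `scenario` — arguments for [colony_scenario()].
#'   * files mode: `tracks`, `events` (paths), `nest` (config list or path).
#'   * options: `radius` (mm, 15), `density_interval` (s, 1500),
#'     `density_stride` (s, 1), `perturb_reps` (0 = skip), `sde_grid_mm` (5).
#' @return The run manifest (list), invisibly; outputs and `manifest.json`
#'   are written under `out_dir`.
#' @export
run_pipeline <- function(config) {
  required <- c("mode", "out_dir", "seed")
  missing_fields <- setdiff(required, names(config))
  if (length(missing_fields)) {
    abort(paste("config is missing fields:",
                paste(missing_fields, collapse = ", ")),
          class = "antnest_config_error")
  }
  mode <- match.arg(config$mode, c("synthetic", "files"))
  stages <- config$stages %||% c("groups", "density", "network", "ihpp", "sde")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)

  manifest <- list(
    package = as.character(utils::packageVersion("antnest")),
    r_version = R.version.string,
    seed = seed, mode = mode, stages = stages,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    status = list(), outputs = list(), inputs = list()
  )
  finish <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
  }
  record <- function(stage, status) manifest$status[[stage]] <<- status
  save_tbl <- function(tbl, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(tbl, path)
    manifest$outputs[[name]] <<- unname(tools::md5sum(path))
    path
  }

  # ---- inputs ----
  if (mode == "synthetic") {
    sc <- do.call(colony_scenario, config$scenario %||% list())
    nest <- sc$nest
    sim <- simulate_colony(sc, seed = stage_seed(seed, "simulate"))
    tracks <- sim$tracks; events <- sim$events
    save_tbl(tracks, "tracks.csv")
    save_tbl(events, "events.csv")
    save_tbl(sim$truth$groups, "truth_groups.csv")
    record("simulate", "ok")
  } else {
    for (f in c("tracks", "nest")) {
      if (is.null(config[[f]])) {
        abort(paste("files mode requires config field:", f),
              class = "antnest_config_error")
      }
    }
    if (is.character(config$tracks) && !file.exists(config$tracks)) {
      abort(paste("missing input file:", config$tracks),
            class = "antnest_config_error")
    }
    nest <- if (inherits(config$nest, "nest_geometry")) config$nest else
      build_nest(config$nest)
    tracks <- read_tracks(config$tracks)
    manifest$inputs$tracks <- unname(tools::md5sum(config$tracks))
    events <- if (!is.null(config$events)) {
      manifest$inputs$events <- unname(tools::md5sum(config$events))
      read_events(config$events)
    } else tibble(ant_i = character(), ant_j = character(),
                  start = numeric(), end = numeric())
  }
  duration_s <- max(tracks$t)

  run_stage <- function(stage, fn) {
    if (!stage %in% stages) return(invisible(NULL))
    result <- tryCatch({ fn(); record(stage, "ok") },
                       error = function(e) {
                         record(stage, paste("failed:", conditionMessage(e)))
                         warn(sprintf("stage '%s' failed: %s", stage,
                                      conditionMessage(e)))
                       })
    invisible(result)
  }

  partition <- NULL
  run_stage("groups", function() {
    partition <<- spatial_partition(tracks, nest,
                                    seed = stage_seed(seed, "groups"))
    save_tbl(as_tibble(partition), "partition.csv")
    reps <- config$perturb_reps %||% 0
    if (reps > 0) {
      sig <- spatial_signatures(tracks, nest)
      net <- build_similarity_network(sig)
      ref <- detect_groups(net, seed = stage_seed(seed, "groups"))
      save_tbl(perturb_and_score(net, ref, n_reps = reps,
                                 seed = stage_seed(seed, "groups")),
               "perturbation.csv")
    }
  })

  run_stage("density", function() {
    stride <- config$density_stride %||% 1
    dens <- local_density(tracks, nest,
                          times = seq(0, duration_s, by = stride),
                          radius = config$radius %||% 15)
    dec <- decorrelate(dens, interval = config$density_interval %||% 1500,
                       seed = stage_seed(seed, "density"))
    save_tbl(dec$mean_series, "density_mean.csv")
    save_tbl(dec$subsampled, "density_subsampled.csv")
  })

  run_stage("network", function() {
    if (!nrow(events)) abort("network stage needs events")
    counts <- interaction_count_series(events, duration_s)
    save_tbl(counts, "interaction_counts.csv")
    if (!is.null(partition)) {
      g <- build_network(events, roster = unique(tracks$ant_id))
      save_tbl(as_tibble(assortativity_groups(g, partition)),
               "assortativity.csv")
    }
  })

  run_stage("ihpp", function() {
    if (!nrow(events)) abort("ihpp stage needs events")
    rec <- pair_covariates(tracks, events, nest)
    fit <- fit_ihpp(rec)
    save_tbl(fit$coefficients, "ihpp_coefficients.csv")
    save_tbl(rate_effects(fit), "ihpp_rate_effects.csv")
  })

  run_stage("sde", function() {
    recs <- build_regression(tracks)
    fit <- fit_sde(recs, nest, grid_mm = config$sde_grid_mm %||% 5)
    rep_out <- surface_report(fit)
    save_tbl(rep_out$surfaces, "sde_surfaces.csv")
    save_tbl(rep_out$chamber_motility, "sde_chamber_motility.csv")
    save_tbl(tibble(beta = fit$beta, sigma2 = fit$sigma2,
                    n_records = fit$n_records), "sde_beta.csv")
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  finish()
}
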