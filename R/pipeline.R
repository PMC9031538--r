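#' Pipeline configuration
#'
#' Builds the full configuration for [run_pipeline()] from a YAML file or a
#' nested list, filling unspecified values with the package defaults. The
#' configuration has blocks `input` (either `simulate:` with `n_dyads`,
#' `duration_s` and optional overrides, or `manifest:` pointing at a CSV
#' with columns `path, dyad_id, participant_id, condition, fps`),
#' `preprocessing` (`exclusion_threshold`, `median_window`), `kinematics`
#' (`sd_mode`, `butterworth_cutoff_hz`, `butterworth_order`), `embedding`
#' (`delay`, `dim`), `crqa` (`target_rr`, `lmin`, `vmin`), `stats`
#' (`grouping_mobility`, `grouping_rqa`) and a top-level `seed`.
#'
#' @param x Path to a YAML file, or a list of overrides (possibly empty).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  defaults <- list(
    input = list(simulate = list(n_dyads = 6, duration_s = 60)),
    preprocessing = list(exclusion_threshold = 0.10, median_window = 5),
    kinematics = list(sd_mode = "sample", butterworth_cutoff_hz = 2,
                      butterworth_order = 2),
    embedding = list(delay = 7, dim = 4),
    crqa = list(target_rr = 0.10, lmin = 10, vmin = 10),
    stats = list(grouping_mobility = "participant", grouping_rqa = "dyad"),
    seed = 1L
  )
  cfg <- utils::modifyList(defaults, x)
  structure(cfg, class = "pipeline_config")
}

# map condition label -> generator scenario
condition_scenario <- function(condition) {
  if (startsWith(condition, "remote")) "remote" else "face_to_face"
}

#' Simulate a full study
#'
#' Generates `n_dyads` dyads in each of the four conditions, using the
#' `"remote"` generator preset for the two video-mediated conditions and
#' `"face_to_face"` for the two live ones. Each dyad-condition gets its own
#' sub-seed derived from `seed`, so the whole study is reproducible from a
#' single integer.
#'
#' @param n_dyads Number of dyads.
#' @param seed Master seed.
#' @param duration_s Recording length per condition, seconds.
#' @param ... Further overrides for [dyad_sim_config()].
#' @return Tibble with columns `dyad_id`, `condition`, `participant_id`,
#'   `track` (list column of [keypoint_track]s).
#' @export
simulate_study <- function(n_dyads = 6, seed = 1L, duration_s = 60, ...) {
  grid <- tidyr::expand_grid(dyad = seq_len(n_dyads),
                             condition = dyad_conditions())
  rows <- purrr::pmap(grid, function(dyad, condition) {
    sub_seed <- (seed * 1000L + dyad * 10L +
                   match(condition, dyad_conditions())) %% .Machine$integer.max
    cfg <- scenario_preset(condition_scenario(condition),
                           duration_s = duration_s, seed = sub_seed, ...)
    pair <- simulate_dyad(cfg, dyad_id = paste0("dyad", dyad),
                          condition = condition)
    tibble::tibble(dyad_id = paste0("dyad", dyad), condition = condition,
                   participant_id = c("A", "B"), track = list(pair$a, pair$b))
  })
  dplyr::bind_rows(rows)
}

read_manifest <- function(manifest) {
  mf <- if (is.character(manifest)) {
    readr::read_csv(manifest, show_col_types = FALSE)
  } else {
    tibble::as_tibble(manifest)
  }
  needed <- c("path", "dyad_id", "participant_id", "condition", "fps")
  if (!all(needed %in% names(mf))) {
    rlang::abort(paste0("manifest must have columns: ",
                        paste(needed, collapse = ", ")))
  }
  counts <- dplyr::count(mf, .data$dyad_id, .data$condition)
  if (any(counts$n != 2)) {
    rlang::abort("every dyad-condition must have exactly two participant recordings")
  }
  mf$track <- purrr::pmap(mf[needed], function(path, dyad_id, participant_id,
                                               condition, fps) {
    read_keypoints(path, fps = fps, dyad_id = dyad_id,
                   participant_id = participant_id, condition = condition)
  })
  mf[c("dyad_id", "condition", "participant_id", "track")]
}

#' Run the full coordination pipeline
#'
#' End to end: acquire the recordings (simulated study or manifest of
#' keypoint files), drop recordings failing the missing-value exclusion
#' check (a dyad-condition loses both recordings if either fails),
#' preprocess, compute the per-participant mobility table and the per-dyad
#' cross-recurrence table, and fit the mixed-effects condition contrasts
#' plus the paired vertical-mobility test between the two remote
#' conditions. Deterministic given the configuration and seed; excluded
#' recordings appear in the log and as absent rows, never as silent zeros.
#'
#' @param config A [pipeline_config()] (or list / YAML path coerced by it).
#' @param out_dir Optional output directory; when given, writes
#'   `mobility.csv`, `rqa.csv`, `models/<response>.csv`, `run.log` and
#'   `provenance.json`.
#' @return List with `mobility`, `rqa` (tibbles), `models` (named list of
#'   `dyad_mixed_fit`), `model_table` (tidy long table over all models),
#'   `t_vertical_remote` (paired test or NULL), `log` (character vector),
#'   `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    rlang::inform(msg)
  }

  recs <- if (!is.null(config$input$manifest)) {
    say("reading manifest")
    read_manifest(config$input$manifest)
  } else {
    sim <- config$input$simulate
    say("simulating study: %d dyads x 4 conditions, %g s each",
        sim$n_dyads, sim$duration_s)
    args <- c(list(n_dyads = sim$n_dyads, seed = config$seed,
                   duration_s = sim$duration_s),
              sim[setdiff(names(sim), c("n_dyads", "duration_s"))])
    do.call(simulate_study, args)
  }

  # exclusion bookkeeping: a dyad-condition needs both partners
  recs$keep <- purrr::map_lgl(recs$track, check_exclusion,
                              threshold = config$preprocessing$exclusion_threshold)
  for (i in which(!recs$keep)) {
    say("excluded %s %s participant %s (missing fraction above %.2f)",
        recs$dyad_id[i], recs$condition[i], recs$participant_id[i],
        config$preprocessing$exclusion_threshold)
  }
  recs <- recs |>
    dplyr::group_by(.data$dyad_id, .data$condition) |>
    dplyr::filter(all(.data$keep)) |>
    dplyr::ungroup()

  say("preprocessing %d recordings", nrow(recs))
  recs$processed <- purrr::map(recs$track, preprocess_track,
                               median_window = config$preprocessing$median_window)

  mobility_tbl <- purrr::map_dfr(recs$processed, mobility,
                                 sd_mode = config$kinematics$sd_mode)

  say("cross-recurrence per dyad-condition")
  rqa_tbl <- recs |>
    dplyr::group_by(.data$dyad_id, .data$condition) |>
    dplyr::group_map(function(g, key) {
      emb <- purrr::map(g$processed, function(p) {
        direction_field(p) |>
          lowpass(cutoff = config$kinematics$butterworth_cutoff_hz,
                  order = config$kinematics$butterworth_order) |>
          embed_direction(delay = config$embedding$delay,
                          dim = config$embedding$dim)
      })
      rm <- recurrence_matrix(emb[[1]], emb[[2]],
                              target_rr = config$crqa$target_rr)
      st <- rqa_stats(rm, lmin = config$crqa$lmin, vmin = config$crqa$vmin)
      st$dyad_id <- key$dyad_id
      st$condition <- key$condition
      st
    }) |>
    dplyr::bind_rows()

  say("fitting condition contrasts")
  models <- list()
  for (resp in c("horizontal", "vertical", "hv_ratio")) {
    tbl <- build_table(mobility_tbl[!is.na(mobility_tbl[[resp]]), ], resp)
    models[[paste0("mobility_", resp)]] <-
      fit_mixed_model(tbl, grouping = config$stats$grouping_mobility)
  }
  for (resp in c("DET", "ENTR", "L", "Lmax", "LAM", "TT")) {
    tbl <- build_table(rqa_tbl[!is.na(rqa_tbl[[resp]]), ], resp)
    models[[paste0("rqa_", resp)]] <-
      fit_mixed_model(tbl, grouping = config$stats$grouping_rqa)
  }
  model_table <- purrr::imap_dfr(models, function(m, nm) {
    dplyr::mutate(tidy(m), model = nm, .before = 1)
  })

  t_vert <- tryCatch({
    wide <- mobility_tbl |>
      dplyr::filter(startsWith(.data$condition, "remote")) |>
      tidyr::pivot_wider(id_cols = c("dyad_id", "participant_id"),
                         names_from = "condition", values_from = "vertical") |>
      tidyr::drop_na()
    if (nrow(wide) >= 2) {
      paired_t(wide$remote_mirror, wide$remote_no_mirror)
    } else NULL
  }, error = function(e) NULL)

  provenance <- list(
    package_version = as.character(utils::packageVersion("dyadcoord")),
    seed = config$seed,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    n_recordings = nrow(recs)
  )

  result <- list(mobility = mobility_tbl, rqa = rqa_tbl, models = models,
                 model_table = model_table, t_vertical_remote = t_vert,
                 log = log, provenance = provenance)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(file.path(out_dir, "models"), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$mobility, file.path(out_dir, "mobility.csv"))
  readr::write_csv(result$rqa, file.path(out_dir, "rqa.csv"))
  for (nm in names(result$models)) {
    m <- result$models[[nm]]
    out <- dplyr::mutate(tidy(m), sigma_group = m$sigma_group,
                         sigma_resid = m$sigma_resid)
    readr::write_csv(out, file.path(out_dir, "models", paste0(nm, ".csv")))
  }
  writeLines(result$log, file.path(out_dir, "run.log"))
  jsonlite::write_json(result$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
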