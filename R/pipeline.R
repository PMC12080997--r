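#' Pipeline configuration
#'
#' A declarative bundle of everything a full run needs: the simulation (or
#' input) settings, the analysis windows, and the statistics parameters.
#' All minute-based windows are half-open `[start, end)`; all tables are
#' position-ordered; all randomness flows from the single top-level seed.
#'
#' @param sim A `sim_config` describing the synthetic cohort (the pipeline's
#'   input source).
#' @param discard_min,knot_interval_min Detrending parameters (see
#'   [discard_and_detrend()]).
#' @param windows Named list of minute windows: `baseline`, `early`, `late`,
#'   `analysis` (ICA window).
#' @param sliding Named list: `window_len_min`, `start_min`, `end_min`,
#'   `step_min`.
#' @param alpha Significance level for FWE/FDR procedures.
#' @param density,n_rand Small-world parameters.
#' @param n_components ICA model order.
#' @param seed Top-level seed (propagated to the simulation config).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(sim = sim_config(seed = seed),
                            discard_min = 20, knot_interval_min = 20,
                            windows = list(baseline = c(30, 40),
                                           early = c(50, 60),
                                           late = c(70, 80),
                                           analysis = c(30, 80)),
                            sliding = list(window_len_min = 20,
                                           start_min = 20, end_min = 80,
                                           step_min = 5),
                            alpha = 0.05, density = 0.25, n_rand = 100,
                            n_components = 2, seed = 1L) {
  for (w in windows) {
    if (w[1] < 0 || w[2] > sim$scan_min || w[1] >= w[2]) {
      stop("window [", w[1], ", ", w[2], ") outside the scan")
    }
  }
  structure(list(sim = sim, discard_min = discard_min,
                 knot_interval_min = knot_interval_min,
                 windows = windows, sliding = sliding, alpha = alpha,
                 density = density, n_rand = n_rand,
                 n_components = n_components, seed = as.integer(seed)),
            class = "pipeline_config")
}

# md5 of the serialized config; used in provenance headers
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::serializeJSON(strip_env(config)), tmp)
  unname(tools::md5sum(tmp))
}

# drop environments (closures in network defs etc.) for stable serialization
strip_env <- function(x) {
  if (is.list(x)) lapply(x, strip_env)
  else if (is.function(x) || is.environment(x)) NULL
  else x
}

pipeline_stages <- c("simulate", "extract", "bp", "connectome", "graph",
                     "ica", "challenge", "report")

#' Run the analysis pipeline on a synthetic cohort
#'
#' Executes the requested stages in dependency order
#' (simulate, extract, bp, connectome, graph, ica, challenge, report),
#' writing position-ordered tables, JSON summaries, and NIfTI volumes into
#' `outdir`. Every text output carries a provenance header (package version,
#' config hash, seed). Reruns with an identical config produce byte-identical
#' numeric outputs.
#'
#' The `ica` and `challenge` stages operate on voxel data and therefore
#' require `sim$make_images = TRUE`; the `challenge` stage additionally
#' requires a configured challenge time.
#'
#' @param config A `pipeline_config`.
#' @param stages Character subset of the stages to run (prerequisites must
#'   either be included or have been run into the same `outdir` previously
#'   in the same session via the returned state).
#' @param outdir Output directory (created if needed).
#' @param state Optional state list returned by a previous call, to continue
#'   a partial run.
#' @param verbose Print one line per stage.
#' @return Invisibly, a list with `outdir` and the accumulated `state`
#'   (cohort, bp series, connectomes, metrics, summaries).
#' @export
run_pipeline <- function(config, stages = pipeline_stages,
                         outdir = tempfile("molconn_run_"),
                         state = list(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- sprintf("# molconn=%s config_hash=%s seed=%d",
                  as.character(utils::packageVersion("molconn")),
                  config_hash(config), config$seed)
  say <- function(...) if (verbose) message("[molconn] ", ...)
  need <- function(what, stage, from) {
    if (is.null(state[[what]])) {
      stop("stage '", stage, "' requires '", from,
           "' to have been run first")
    }
    state[[what]]
  }

  if ("simulate" %in% stages) {
    say("simulate: ", config$sim$n_subjects, " subjects")
    state$cohort <- simulate_cohort(config$sim)
    truth <- state$cohort$truth
    jsonlite::write_json(
      list(provenance = prov,
           member_of = truth$member_of,
           occupancy_amplitude = truth$occupancy_amplitude,
           occupancy_onset = truth$occupancy_onset,
           subject_seeds = truth$subject_seeds),
      file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }

  if ("extract" %in% stages) {
    cohort <- need("cohort", "extract", "simulate")
    say("extract: regional time series")
    state$pet_ts <- if (!is.null(cohort$pet_images)) {
      lapply(cohort$pet_images, extract_regional_timeseries,
             atlas = cohort$atlas)
    } else {
      cohort$pet
    }
    state$bold_ts <- cohort$bold
    for (s in seq_along(state$pet_ts)) {
      ts <- state$pet_ts[[s]]
      df <- data.frame(position = ts$region_positions,
                       abbreviation = rownames(ts$values), ts$values,
                       check.names = FALSE)
      f <- file.path(outdir, sprintf("pet_tac_sub%02d.tsv", s))
      con <- file(f, "w"); writeLines(prov, con)
      utils::write.table(df, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      close(con)
    }
  }

  if ("bp" %in% stages) {
    pet_ts <- need("pet_ts", "bp", "extract")
    say("bp: framewise DVR-1 + detrend")
    state$bp_raw <- lapply(pet_ts, framewise_bpnd)
    state$bp <- lapply(state$bp_raw, discard_and_detrend,
                       discard_min = config$discard_min,
                       knot_interval_min = config$knot_interval_min)
    for (s in seq_along(state$bp)) {
      write_bp_series(state$bp[[s]],
                      file.path(outdir, sprintf("bp_sub%02d.tsv", s)),
                      provenance = prov)
    }
  }

  if ("connectome" %in% stages) {
    bp <- need("bp", "connectome", "bp")
    say("connectome: subject + group Fisher-z matrices")
    state$mc <- lapply(seq_along(bp), function(s) {
      subject_connectome(bp[[s]], subject_id = sprintf("sub%02d", s))
    })
    state$fc <- lapply(seq_along(state$bold_ts), function(s) {
      subject_connectome(state$bold_ts[[s]],
                         window_min = c(config$discard_min,
                                        config$sim$scan_min),
                         subject_id = sprintf("sub%02d", s))
    })
    state$mc_group <- group_connectome(state$mc, alpha = config$alpha)
    state$fc_group <- group_connectome(state$fc, alpha = config$alpha)
    for (s in seq_along(state$mc)) {
      write_connectome(state$mc[[s]],
                       file.path(outdir, sprintf("mc_sub%02d.tsv", s)),
                       provenance = prov)
    }
    group_edge_table(state$mc_group, file.path(outdir, "mc_group_edges.tsv"))
    group_edge_table(state$fc_group, file.path(outdir, "fc_group_edges.tsv"))
  }

  if ("graph" %in% stages) {
    mc <- need("mc", "graph", "connectome")
    say("graph: small-world metrics")
    metrics <- function(conns, modality) {
      do.call(rbind, lapply(seq_along(conns), function(s) {
        gm <- small_world_coefficient(conns[[s]], density = config$density,
                                      n_rand = config$n_rand,
                                      seed = config$seed + s)
        data.frame(subject_id = sprintf("sub%02d", s), modality = modality,
                   C = gm$clustering_C, L = gm$path_length_L,
                   sigma = gm$sigma, density = config$density,
                   seed = config$seed + s)
      }))
    }
    state$graph_metrics <- rbind(metrics(mc, "MC"),
                                 metrics(state$fc, "FC"))
    f <- file.path(outdir, "small_world.tsv")
    con <- file(f, "w"); writeLines(prov, con)
    utils::write.table(state$graph_metrics, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }

  if ("ica" %in% stages) {
    cohort <- need("cohort", "ica", "simulate")
    if (is.null(cohort$pet_images)) {
      stop("stage 'ica' requires voxel images; set sim_config(make_images = TRUE)")
    }
    say("ica: ", config$n_components, " spatial components")
    mask <- cohort$atlas$label_volume > 0
    state$ica <- group_spatial_ica(cohort$pet_images, mask = mask,
                                   n_components = config$n_components,
                                   seed = config$seed,
                                   analysis_window_min = config$windows$analysis)
    scores <- regional_component_scores(state$ica, cohort$atlas)
    state$ica_scores <- scores
    f <- file.path(outdir, "ica_regional_scores.tsv")
    con <- file(f, "w"); writeLines(prov, con)
    utils::write.table(scores, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    # component maps as one 4D NIfTI, component axis last
    arr <- array(0, dim = c(dim(mask), config$n_components))
    flat <- matrix(arr, nrow = length(mask))
    for (ic in seq_len(config$n_components)) {
      v <- numeric(length(mask))
      v[as.vector(mask)] <- state$ica$maps[, ic]
      flat[, ic] <- v
    }
    RNifti::writeNifti(RNifti::asNifti(array(flat,
                                             c(dim(mask),
                                               config$n_components))),
                       file.path(outdir, "ica_maps.nii.gz"))
  }

  if ("challenge" %in% stages) {
    cohort <- need("cohort", "challenge", "simulate")
    if (is.null(cohort$pet_images)) {
      stop("stage 'challenge' requires voxel images; set sim_config(make_images = TRUE)")
    }
    if (is.null(config$sim$challenge_min)) {
      stop("stage 'challenge' requires a configured challenge_min")
    }
    say("challenge: static windows + effect t-maps")
    mask <- cohort$atlas$label_volume > 0
    stat <- function(win) lapply(cohort$pet_images, static_uptake,
                                 window_min = win, mask = mask)
    base <- stat(config$windows$baseline)
    early <- stat(config$windows$early)
    late <- stat(config$windows$late)
    state$early_map <- effect_tmap(early, base, alpha = config$alpha,
                                   contrast = "early_vs_baseline",
                                   mask = mask)
    state$late_map <- effect_tmap(late, early, alpha = config$alpha,
                                  contrast = "late_vs_early", mask = mask)
    for (nm in c("early_map", "late_map")) {
      em <- state[[nm]]
      RNifti::writeNifti(RNifti::asNifti(em$t_volume),
                         file.path(outdir, paste0(nm, "_t.nii.gz")))
      scores <- regional_effect_scores(em, cohort$atlas)
      f <- file.path(outdir, paste0(nm, "_regions.tsv"))
      con <- file(f, "w"); writeLines(prov, con)
      utils::write.table(scores, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      close(con)
      state[[paste0(nm, "_regions")]] <- scores
    }
  }

  if ("report" %in% stages) {
    say("report: summary panel numbers")
    mc_g <- need("mc_group", "report", "connectome")
    fc_g <- state$fc_group
    sl <- config$sliding
    win_sim <- function(series_list) {
      wins <- lapply(series_list, sliding_window_connectomes,
                     window_len_min = sl$window_len_min,
                     start_min = sl$start_min, end_min = sl$end_min,
                     step_min = sl$step_min)
      starts <- attr(wins[[1]], "window_starts")
      n_win <- length(starts)
      group_w <- lapply(seq_len(n_win), function(w) {
        group_connectome(lapply(wins, `[[`, w), alpha = config$alpha)
      })
      adj <- vapply(seq_len(n_win - 1L), function(w) {
        edge_similarity(group_w[[w]], group_w[[w + 1L]])
      }, numeric(1))
      list(windows = wins, starts = starts, adjacent_similarity = adj)
    }
    mc_sl <- win_sim(state$bp)
    early_g <- group_connectome(lapply(state$bp, subject_connectome,
                                       window_min = c(20, 40)),
                                alpha = config$alpha)
    late_g <- group_connectome(lapply(state$bp, subject_connectome,
                                      window_min = c(60, 80)),
                               alpha = config$alpha)
    sw <- state$graph_metrics
    summary <- list(
      provenance = prov,
      n_subjects = config$sim$n_subjects,
      mc_fc_edge_r = edge_similarity(mc_g, fc_g),
      mc_early_late_r = edge_similarity(early_g, late_g),
      mc_sliding_adjacent_r = mc_sl$adjacent_similarity,
      mc_fwe_surviving_edges = sum(mc_g$fwe_mask) / 2,
      fc_fwe_surviving_edges = sum(fc_g$fwe_mask) / 2,
      small_world = if (!is.null(sw)) {
        lapply(split(sw, sw$modality), function(d) {
          gt <- group_small_world_test(d$sigma)
          list(mean_sigma = gt$mean, sd_sigma = gt$sd, t = gt$t, p = gt$p)
        })
      } else NULL
    )
    state$report <- summary
    jsonlite::write_json(summary, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(outdir = outdir, state = state))
}
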