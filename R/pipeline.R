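#' Configuration for the end-to-end contrast suite
#'
#' Collects every analysis setting: the simulation parameters (or a cohort
#' directory to load instead), frequency bands and their baselines, the
#' test windows of each contrast, and the cluster-test settings.
#'
#' Defaults follow the study design: alpha 8-12 Hz against a 400-ms precue
#' baseline (-2.2 to -1.8 s, ending 100 ms before the earliest possible
#' cue onset at -1.7 s); theta 4-6 Hz against a -700 to -300 ms pretarget
#' baseline (the wider theta windows would leak cue/post-target activity
#' into a precue baseline); pretarget lateralization tested -1500..0 ms,
#' the cue-by-lateralization interaction -1050..0 ms, post-target contrasts
#' 0..1500 ms; 1000 permutations at alpha 0.05.
#'
#' @param params A [sim_params()] object.
#' @param seed Master seed: drives cohort generation and the permutation
#'   draws.
#' @param alpha_band,theta_band Frequency bands, Hz (averaged over a 1-Hz
#'   grid inside the closed band).
#' @param alpha_baseline,theta_baseline Baseline windows, s.
#' @param pretarget_window,interaction_window,posttarget_window Test
#'   windows, s.
#' @param n_perm Permutations per cluster test.
#' @param cluster_alpha Cluster significance level.
#' @param time_step TFR output step, s.
#' @param index_selection `"cluster"` (channels/window of the significant
#'   uncued/low-similarity post-target cluster, as in the original
#'   analysis -- note the selection is circular by construction and shared
#'   with it) or a list `list(channels = ..., window = c(t0, t1))` for an
#'   independent a-priori selection.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(params = sim_params(),
                            seed = 7,
                            alpha_band = c(8, 12),
                            theta_band = c(4, 6),
                            alpha_baseline = c(-2.2, -1.8),
                            theta_baseline = c(-0.7, -0.3),
                            pretarget_window = c(-1.5, 0),
                            interaction_window = c(-1.05, 0),
                            posttarget_window = c(0, 1.5),
                            n_perm = 1000,
                            cluster_alpha = 0.05,
                            time_step = 0.05,
                            index_selection = "cluster") {
  structure(
    list(params = params, seed = seed, alpha_band = alpha_band,
         theta_band = theta_band, alpha_baseline = alpha_baseline,
         theta_baseline = theta_baseline,
         pretarget_window = pretarget_window,
         interaction_window = interaction_window,
         posttarget_window = posttarget_window, n_perm = n_perm,
         cluster_alpha = cluster_alpha, time_step = time_step,
         index_selection = index_selection),
    class = "analysis_config"
  )
}

#' Run the full contrast suite on a synthetic (or loaded) cohort
#'
#' End-to-end pipeline: simulate or load the cohort, reject trials
#' (incorrect or eye movement), screen participants, compute per-trial
#' Hann-taper power, baseline-normalize per subject and condition, average
#' the alpha and theta bands, flip-and-pool hemispheres, and run the
#' spatio-temporal cluster permutation tests:
#' \enumerate{
#'   \item pretarget alpha lateralization, cued trials (-1500..0 ms);
#'   \item pretarget alpha lateralization, uncued trials (expected null);
#'   \item cued-vs-uncued interaction in lateralized alpha (-1050..0 ms),
#'     as the paired test on the difference of lateralized-minus-mirrored
#'     maps per cue type;
#'   \item post-target alpha lateralization in the four cue-by-similarity
#'     conditions (0..1500 ms);
#'   \item midfrontal theta, uncued high- vs low-similarity (0..1500 ms,
#'     hemispheres pooled without flipping);
#'   \item the same theta contrast for cued trials (expected null).
#' }
#' The per-subject alpha lateralization index is then extracted from the
#' uncued/low-similarity cluster and correlated (Spearman) with the
#' behavioral distractor cost, alongside the behavioral RM-ANOVAs and
#' chance tests.
#'
#' @param config An [analysis_config()].
#' @param cohort Optional pre-built cohort (list as returned by
#'   [simulate_cohort()]); `NULL` simulates from `config$params` one
#'   subject at a time.
#' @param verbose Print stage progress.
#' @return An object of class `run_report`; see [tidy.run_report()].
#' @export
run_contrast_suite <- function(config, cohort = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  params <- config$params
  say <- function(...) if (verbose) message(...)
  layout <- build_layout(params$n_channels)
  seeds <- child_seeds(config$seed, 2 + params$n_subjects)
  plan <- cohort_plan(params, seeds[[1]])

  # --- behavior first: trial rejection + participant screening ----------
  say("stage: behavior")
  behaviors <- if (is.null(cohort)) {
    lapply(seq_len(nrow(plan)), function(i) {
      eff <- subject_effects(params, plan[i, ])
      sched <- generate_schedule(params, plan$seed_schedule[i])
      b <- simulate_behavior(sched, params, plan$seed_behavior[i],
                             rt_shift_ms = eff$rt_shift)
      b$subject <- plan$subject_id[i]
      b
    })
  } else {
    lapply(seq_along(cohort), function(i) {
      b <- cohort[[i]]$behavior
      if (!"subject" %in% names(b)) {
        b$subject <- cohort[[i]]$epochs$subject_id
      }
      b
    })
  }
  behavior_all <- dplyr::bind_rows(behaviors)
  exclusion <- exclude_subjects(behavior_all)
  included <- exclusion$subject[exclusion$final_included]
  if (length(included) < 2) stop("stage behavior: fewer than 2 subjects survive screening")
  behavior_inc <- behavior_all[behavior_all$subject %in% included, ]

  # --- behavioral statistics -------------------------------------------
  cm <- subject_cell_means(behavior_inc)
  anova_rt <- rm_anova_2x4(cm, value = "rt_ms")
  anova_acc <- rm_anova_2x4(cm, value = "accuracy")
  benefit <- cm |>
    tidyr::pivot_wider(id_cols = c("subject", "distractor"),
                       names_from = "cue_presence", values_from = "rt_ms") |>
    dplyr::mutate(value = .data$uncued - .data$cued, cell = .data$distractor)
  pairwise_benefit <- pairwise_bonferroni(benefit)
  chance <- dplyr::bind_rows(lapply(split(cm, paste(cm$cue_presence,
                                                    cm$distractor)), function(g) {
    out <- t_vs_chance(g$accuracy, chance = chance_level())
    out$condition <- paste(g$cue_presence[1], g$distractor[1])
    out
  }))
  chance$p.adjusted <- pmin(1, chance$p.value * nrow(chance))

  # --- EEG stage: per-subject condition maps ---------------------------
  say("stage: time-frequency")
  freq_grid <- sort(unique(c(
    seq(config$theta_band[1], config$theta_band[2]),
    seq(config$alpha_band[1], config$alpha_band[2])
  )))
  cfg <- tfr_config(freqs = freq_grid, time_step = config$time_step)
  mi <- mirror_index(layout)

  alpha_conds <- c("cued", "uncued", "cued.low", "cued.high",
                   "uncued.low", "uncued.high")
  theta_conds <- c("cued.low", "cued.high", "uncued.low", "uncued.high")
  alpha_maps <- list(); theta_maps <- list()

  inc_rows <- which(plan$subject_id %in% included)
  for (i in inc_rows) {
    sid <- plan$subject_id[i]
    say("  subject ", sid)
    epochs <- if (is.null(cohort)) {
      eff <- subject_effects(params, plan[i, ])
      simulate_subject(
        schedule = behaviors[[i]], layout = layout, params = params,
        seed = plan$seed_eeg[i], subject_id = sid,
        alpha_effects = eff$alpha_effects, theta_amp = eff$theta_amp
      )
    } else {
      cohort[[i]]$epochs
    }
    keep <- reject_trials(epochs$trials)
    ep <- eeg_epochs(epochs$data[keep, , , drop = FALSE], epochs$times,
                     epochs$srate, layout, epochs$trials[keep, ],
                     epochs$subject_id)
    maps <- subject_condition_maps(ep, cfg, config, layout, mi)
    alpha_maps[[sid]] <- maps$alpha
    theta_maps[[sid]] <- maps$theta
    rm(epochs, ep); gc(FALSE)
  }
  t_alpha <- alpha_maps[[1]]$times
  t_theta <- theta_maps[[1]]$times

  stack <- function(maps_list, cond, times) {
    arr <- vapply(maps_list, function(m) m$maps[[cond]],
                  matrix(0, nrow(layout$channels), length(times)))
    aperm(arr, c(3, 1, 2)) # subjects x channels x times
  }

  # --- cluster permutation tests ---------------------------------------
  say("stage: cluster tests")
  perm_seeds <- child_seeds(seeds[[2]], 9)
  in_win <- function(grid, w) {
    which(grid >= w[1] - 1e-9 & grid <= w[2] + 1e-9)
  }
  run_lat <- function(cond, window, seed) {
    ts <- in_win(t_alpha, window)
    a <- stack(alpha_maps, cond, t_alpha)[, , ts, drop = FALSE]
    permutation_test(a, a[, mi, , drop = FALSE], layout$adjacency,
                     n_perm = config$n_perm, alpha = config$cluster_alpha,
                     seed = seed, channels = layout$channels$name,
                     times = t_alpha[ts])
  }
  ts_int <- in_win(t_alpha, config$interaction_window)
  a_c <- stack(alpha_maps, "cued", t_alpha)
  a_u <- stack(alpha_maps, "uncued", t_alpha)
  d_c <- (a_c - a_c[, mi, , drop = FALSE])[, , ts_int, drop = FALSE]
  d_u <- (a_u - a_u[, mi, , drop = FALSE])[, , ts_int, drop = FALSE]
  run_theta <- function(cond_a, cond_b, window, seed) {
    ts <- in_win(t_theta, window)
    permutation_test(
      stack(theta_maps, cond_a, t_theta)[, , ts, drop = FALSE],
      stack(theta_maps, cond_b, t_theta)[, , ts, drop = FALSE],
      layout$adjacency, n_perm = config$n_perm,
      alpha = config$cluster_alpha, seed = seed,
      channels = layout$channels$name, times = t_theta[ts]
    )
  }
  contrasts <- list(
    pretarget_cued = run_lat("cued", config$pretarget_window,
                             perm_seeds[[1]]),
    pretarget_uncued = run_lat("uncued", config$pretarget_window,
                               perm_seeds[[2]]),
    interaction_cued_uncued = permutation_test(
      d_c, d_u, layout$adjacency, n_perm = config$n_perm,
      alpha = config$cluster_alpha, seed = perm_seeds[[3]],
      channels = layout$channels$name, times = t_alpha[ts_int]
    ),
    posttarget_cued_low = run_lat("cued.low", config$posttarget_window,
                                  perm_seeds[[4]]),
    posttarget_cued_high = run_lat("cued.high", config$posttarget_window,
                                   perm_seeds[[5]]),
    posttarget_uncued_low = run_lat("uncued.low", config$posttarget_window,
                                    perm_seeds[[6]]),
    posttarget_uncued_high = run_lat("uncued.high",
                                     config$posttarget_window,
                                     perm_seeds[[7]]),
    theta_uncued_high_vs_low = run_theta("uncued.high", "uncued.low",
                                         config$posttarget_window,
                                         perm_seeds[[8]]),
    theta_cued_high_vs_low = run_theta("cued.high", "cued.low",
                                       config$posttarget_window,
                                       perm_seeds[[9]])
  )

  # --- lateralization index and brain-behavior correlation -------------
  say("stage: lateralization index")
  sel <- index_selection_from(config, contrasts$posttarget_uncued_low,
                              layout)
  idx_of <- function(cond) {
    arr <- stack(alpha_maps, cond, t_alpha)
    pm <- power_map(array(arr, c(dim(arr)[1], dim(arr)[2], 1,
                                 dim(arr)[3])),
                    freqs = mean(config$alpha_band), times = t_alpha,
                    channels = layout$channels$name, units = "relative")
    out <- lateralization_index(pm, layout, sel$channels, sel$window)
    out$subject <- names(alpha_maps)
    out
  }
  idx_high <- idx_of("uncued.high")
  idx_low <- idx_of("uncued.low")
  lat_diff <- lateralization_difference(idx_high, idx_low)
  cost <- distractor_cost(behavior_inc)
  lat_tab <- dplyr::left_join(
    tibble::tibble(subject = lat_diff$subject,
                   index_high = idx_high$index, index_low = idx_low$index,
                   difference = lat_diff$difference),
    cost, by = "subject"
  )
  correlation <- if (nrow(lat_tab) >= 5) {
    spearman_corr(lat_tab$cost_ms, lat_tab$difference)
  } else {
    NULL
  }

  structure(
    list(
      config = config,
      exclusion = exclusion,
      behavior = list(anova_rt = anova_rt, anova_accuracy = anova_acc,
                      pairwise_cue_benefit = pairwise_benefit,
                      chance = chance, cell_means = cm),
      contrasts = contrasts,
      index_selection = sel,
      lateralization = lat_tab,
      correlation = correlation,
      n_subjects_included = length(included),
      fingerprint = list(package_version =
                           as.character(utils::packageVersion("alphalat")),
                         seed = config$seed)
    ),
    class = "run_report"
  )
}

# Channels/window used for the lateralization index: either the significant
# ipsi>contra cluster of the uncued/low post-target contrast, or the
# configured a-priori selection; falls back to posterior channels in the
# 0.5-0.9 s window when no cluster is significant.
index_selection_from <- function(config, test, layout) {
  if (is.list(config$index_selection)) {
    return(list(channels = config$index_selection$channels,
                window = config$index_selection$window,
                source = "config"))
  }
  cl <- test$clusters
  sig <- cl[cl$p_mc < config$cluster_alpha & cl$sign > 0, ]
  if (nrow(sig) > 0) {
    top <- sig[which.max(abs(sig$mass)), ]
    return(list(
      channels = layout$channels$name[top$channels[[1]]],
      window = range(test$times[top$time_idx[[1]]]),
      source = "uncued_low_cluster"
    ))
  }
  list(channels = layout$posterior, window = c(0.5, 0.9),
       source = "fallback_posterior")
}

# Per-subject baseline-normalized band-averaged condition maps.
# Returns channels x times matrices: alpha maps are flip-and-pooled
# (contra/ipsi frame), theta maps are pooled without flipping. The two
# bands run on their own restricted time grids (each spanning its baseline
# and the widest test window) to avoid computing unused timepoints.
subject_condition_maps <- function(ep, cfg, config, layout, mi) {
  sim <- ifelse(ep$trials$distractor %in% c("D1", "D2"), "high", "low")
  cond <- paste(ep$trials$cue_presence, sim, sep = ".")

  cfg_alpha <- tfr_config(
    freqs = cfg$freqs[cfg$freqs >= config$alpha_band[1] &
                        cfg$freqs <= config$alpha_band[2]],
    n_cycles = cfg$n_cycles, time_step = cfg$time_step,
    tmin = min(config$alpha_baseline[1], config$pretarget_window[1]),
    tmax = max(config$posttarget_window[2], config$alpha_baseline[2])
  )
  alpha_raw <- compute_power(ep, cfg_alpha)
  alpha_rel <- baseline_relative(alpha_raw, config$alpha_baseline,
                                 groups = cond)
  alpha <- band_average(alpha_rel, config$alpha_band)
  alpha_flip <- flip_pool(alpha, ep$trials$target_side, layout)

  cfg_theta <- tfr_config(
    freqs = cfg$freqs[cfg$freqs >= config$theta_band[1] &
                        cfg$freqs <= config$theta_band[2]],
    n_cycles = cfg$n_cycles, time_step = cfg$time_step,
    tmin = config$theta_baseline[1],
    tmax = max(config$posttarget_window[2], config$theta_baseline[2])
  )
  theta_raw <- compute_power(ep, cfg_theta)
  theta_rel <- baseline_relative(theta_raw, config$theta_baseline,
                                 groups = cond)
  theta <- band_average(theta_rel, config$theta_band)

  take <- function(pm, rows) {
    block <- pm$values[rows, , 1, , drop = FALSE]
    dim(block) <- c(length(rows), dim(pm$values)[2], dim(pm$values)[4])
    colMeans(block)
  }
  alpha_list <- list(
    cued = take(alpha_flip, which(ep$trials$cue_presence == "cued")),
    uncued = take(alpha_flip, which(ep$trials$cue_presence == "uncued"))
  )
  for (cc in c("cued.low", "cued.high", "uncued.low", "uncued.high")) {
    alpha_list[[cc]] <- take(alpha_flip, which(cond == cc))
  }
  theta_list <- lapply(
    stats::setNames(nm = c("cued.low", "cued.high", "uncued.low",
                           "uncued.high")),
    function(cc) take(theta, which(cond == cc))
  )
  list(alpha = list(maps = alpha_list, times = alpha$times),
       theta = list(maps = theta_list, times = theta$times))
}

# Restrict a power map to grid frequencies inside a closed band.
subset_freqs <- function(power, band) {
  sel <- power$freqs >= band[1] - 1e-9 & power$freqs <= band[2] + 1e-9
  if (!any(sel)) stop("no grid frequencies inside the band")
  power_map(power$values[, , sel, , drop = FALSE], power$freqs[sel],
            power$times, power$channels, units = power$units,
            trials = power$trials)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", x$n_subjects_included, " subjects included (",
      nrow(x$exclusion), " simulated), seed ", x$config$seed, "\n", sep = "")
  print(tidy(x), n = 25)
  if (!is.null(x$correlation)) {
    cat("\nbrain-behavior correlation:\n")
    print(x$correlation)
  }
  invisible(x)
}

#' Tidy a pipeline run report
#'
#' @param x A `run_report`.
#' @param ... Unused.
#' @return One row per configured contrast: `contrast`, `significant`
#'   (any cluster below the configured alpha), `n_clusters`, `min_p`, and
#'   the time extent (`window_start`/`window_end`, s) of the most extreme
#'   significant cluster (NA when none).
#' @export
tidy.run_report <- function(x, ...) {
  rows <- lapply(names(x$contrasts), function(nm) {
    ct <- x$contrasts[[nm]]
    cl <- ct$clusters
    sig <- cl[cl$p_mc < x$config$cluster_alpha, ]
    top <- if (nrow(sig)) sig[which.max(abs(sig$mass)), ] else NULL
    tibble::tibble(
      contrast = nm,
      significant = nrow(sig) > 0,
      n_clusters = nrow(cl),
      min_p = if (nrow(cl)) min(cl$p_mc) else NA_real_,
      window_start = if (!is.null(top)) ct$times[min(top$time_idx[[1]])]
        else NA_real_,
      window_end = if (!is.null(top)) ct$times[max(top$time_idx[[1]])]
        else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Write machine-readable pipeline reports
#'
#' Serializes a [run_contrast_suite()] report: `clusters.json` (per
#' contrast: cluster masses, extents, Monte Carlo p-values),
#' `behavior_stats.json` (ANOVA tables, pairwise cue-benefit tests, chance
#' tests, exclusion report), `correlation.json` (Spearman rho/p with and
#' without flagged outliers) and `lateralization.tsv` (per-subject indices
#' and distractor cost). Output is stable under re-running with the same
#' seed.
#'
#' @param report A `run_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  clusters <- lapply(report$contrasts, function(ct) {
    tab <- tidy(ct)
    list(n_perm = ct$n_perm, threshold = ct$threshold,
         exhaustive = ct$exhaustive, clusters = tab)
  })
  jsonlite::write_json(
    list(seed = report$config$seed, contrasts = clusters),
    file.path(dir, "clusters.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    list(
      anova_rt = tidy(report$behavior$anova_rt),
      anova_accuracy = tidy(report$behavior$anova_accuracy),
      pairwise_cue_benefit = report$behavior$pairwise_cue_benefit,
      chance = report$behavior$chance,
      exclusion = report$exclusion
    ),
    file.path(dir, "behavior_stats.json"), auto_unbox = TRUE, digits = NA
  )
  if (!is.null(report$correlation)) {
    jsonlite::write_json(
      c(tidy(report$correlation),
        list(outliers = report$correlation$outliers,
             index_selection = report$index_selection)),
      file.path(dir, "correlation.json"), auto_unbox = TRUE, digits = NA
    )
  }
  utils::write.table(report$lateralization,
                     file.path(dir, "lateralization.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read an analysis configuration from YAML or JSON
#'
#' Thin front-end used by the command-line interface: top-level keys
#' matching [analysis_config()] arguments override its defaults, and the
#' `params` block is passed to [sim_params()].
#'
#' @param path YAML (`.yaml`/`.yml`, requires the yaml package) or JSON
#'   file.
#' @return An [analysis_config()].
#' @export
read_config <- function(path) {
  raw <- if (grepl("[.]ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  p_args <- raw$params %||% list()
  params <- do.call(sim_params, p_args)
  cfg_args <- raw[setdiff(names(raw), "params")]
  do.call(analysis_config, c(list(params = params), cfg_args))
}
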