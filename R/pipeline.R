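# End-to-end orchestration: simulate -> rank -> classify -> feeding metrics
# -> statistics -> microbiome biomarkers, with a machine-readable report.
#
# Per-stage seeds are derived from the global seed with child_seed() and
# fixed counters (bouts: 10 + phase; weights: 20; feeding: 30; abundances:
# 40; rarefaction: 41; SparCC dominant/subordinate/combined: 42/43/44;
# cross-validation: 45), so any stage reproduces in isolation.

#' Tournament, ranking and classification for one phase
#'
#' Schedules a round robin in every pen (membership as of the phase),
#' simulates the bouts and classifies the hierarchy.
#'
#' @param cohort a [generate_cohort()] result.
#' @param phase phase 1, 2 or 3.
#' @param seed bout seed (default derived from the cohort seed).
#' @return list with `bouts`, `scores`, `assignment`.
#' @export
phase_hierarchy <- function(cohort, phase,
                            seed = child_seed(cohort$config$seed,
                                              10 + phase)) {
  cfg <- cohort$config
  roster <- phase_roster(cohort, phase)
  sched <- do.call(rbind, lapply(split(roster$animal_id, roster$pen_id),
                                 function(ids) {
                                   s <- round_robin_schedule(sort(ids))
                                   s
                                 }))
  sched$pen_id <- sub("\\..*$", "", rownames(sched))
  rownames(sched) <- NULL
  bouts <- generate_bouts(roster, sched, phase, p_draw = cfg$p_draw,
                          p_inconclusive = cfg$p_inconclusive,
                          p_confirm = cfg$p_confirm, seed = seed)
  scores <- ranking_scores(bouts, phase)
  assignment <- classify_hierarchy(scores, roster)
  list(bouts = bouts, scores = scores, assignment = assignment)
}

# dominant-vs-submissive contrast of one phase metric. Absolute metrics get
# pen as a fixed covariate factor (pen nests treatment, which would be
# aliased if both entered); relative metrics are already pen-scaled and get
# treatment instead.
contrast_metric <- function(metrics, hierarchy, roster, phase, metric,
                            with_pen) {
  h <- hierarchy[hierarchy$phase == phase &
                   hierarchy$class %in% c("dominant", "submissive"), ]
  d <- metrics[metrics$phase == phase &
                 metrics$animal_id %in% h$animal_id, ]
  d$class <- h$class[match(d$animal_id, h$animal_id)]
  d$treatment <- roster$treatment[match(d$animal_id, roster$animal_id)]
  d$pen_id <- roster$pen_id[match(d$animal_id, roster$animal_id)]
  d <- d[!is.na(d[[metric]]), ]
  factors <- if (with_pen) {
    list(class = "dominant", pen_id = sort(unique(d$pen_id))[1])
  } else {
    list(class = "dominant", treatment = "control")
  }
  fit <- fit_linear_model(d, model_spec(metric, factors = factors))
  cf <- fit$coefficients
  row <- cf[cf$term == "classsubmissive", ]
  data.frame(phase = phase, metric = metric,
             estimate = row$estimate, se = row$se, p = row$p, n = fit$n,
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes: cohort generation; per-phase tournaments, ranking scores and
#' 2/4/2 classification; hierarchy-change accounting with chi-square tests;
#' weight simulation and the phase-3 random-intercept weight model; feeder
#' event simulation, daily summaries, pen-relative normalization, phase
#' aggregation and dominant-vs-submissive contrasts; and the microbiome
#' stage (rarefaction, diversity, per-condition SparCC networks, module
#' detection, transition scores, biomarker calls, cross-validated panel
#' AUC).
#'
#' @param config a [cohort_config()]; its `seed` drives every stage.
#' @param out_dir optional directory; when given, every intermediate table
#'   and the report (JSON) are written there.
#' @return a `run_report` list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- config$seed
  cohort <- generate_cohort(config)

  phases <- lapply(1:3, function(p) phase_hierarchy(cohort, p))
  hierarchy <- do.call(rbind, lapply(phases, `[[`, "assignment"))
  class_counts <- with(hierarchy, table(phase, factor(
    class, levels = c("dominant", "intermediate", "submissive"))))

  # hierarchy-change accounting
  trans <- list(
    p1_p2 = transition_table(phases[[1]]$assignment, phases[[2]]$assignment),
    p2_p3 = transition_table(phases[[2]]$assignment, phases[[3]]$assignment),
    p1_p3 = transition_table(phases[[1]]$assignment, phases[[3]]$assignment))
  treatment <- setNames(cohort$animals$treatment, cohort$animals$animal_id)
  change_tests <- lapply(trans, function(tr) {
    tab <- table(factor(tr$changes$change,
                        levels = c("Better", "Same", "Worse")),
                 treatment[tr$changes$animal_id])
    chi_square_counts(unclass(tab))
  })

  # growth: phase-3 weights, random intercept per animal
  weights <- generate_weights(cohort$animals, hierarchy, config,
                              seed = child_seed(seed, 20))
  w3 <- weights[phase_of_day(weights$day, config) == 3, ]
  h3 <- phases[[3]]$assignment
  w3$class <- h3$class[match(w3$animal_id, h3$animal_id)]
  w3$treatment <- treatment[w3$animal_id]
  weight_fit <- fit_random_intercept_model(
    w3, model_spec("weight",
                   factors = list(class = "dominant",
                                  treatment = "control"),
                   covariates = "day", random_intercept = "animal_id"))

  # feeding behaviour
  events <- generate_feeding_events(cohort$animals, hierarchy,
                                    seq_len(config$study_days), config,
                                    seed = child_seed(seed, 30))
  daily <- daily_summaries(events)
  daily <- normalize_by_pen(daily, cohort)
  metrics <- phase_aggregate(daily, config)
  contrast_defs <- rbind(
    expand.grid(phase = 2:3, metric = c("intake_g", "rel_intake_g"),
                stringsAsFactors = FALSE),
    data.frame(phase = 3, metric = c("rel_n_visits", "rel_total_duration_s",
                                     "slot3_pct", "rel_slot3_pct",
                                     "median_session_s")))
  contrasts <- do.call(rbind, lapply(seq_len(nrow(contrast_defs)), function(i) {
    ph <- contrast_defs$phase[i]
    contrast_metric(metrics, hierarchy, phase_roster(cohort, ph), ph,
                    contrast_defs$metric[i],
                    with_pen = !startsWith(contrast_defs$metric[i], "rel_"))
  }))

  # microbiome
  sheet <- sample_sheet(hierarchy, 3)
  abundance <- generate_abundances(sheet, n_genera = config$n_genera,
                                   planted = config$planted_log2fc,
                                   seed = child_seed(seed, 40),
                                   depth_range = config$depth_range)
  micro <- biomarker_analysis(abundance$counts, sheet$class, seed = seed,
                              depth = config$rarefaction_depth)

  report <- list(
    package_version = as.character(utils::packageVersion("herdrank")),
    config = unclass(config),
    class_counts = unclass(class_counts),
    transitions = lapply(trans, `[[`, "counts"),
    change_tests = lapply(change_tests, function(x)
      x[c("statistic", "df", "p")]),
    weight_fit = weight_fit$coefficients,
    feeding_contrasts = contrasts,
    diversity = micro$diversity,
    biomarkers = micro$biomarkers,
    auc = micro$auc
  )
  class(report) <- "run_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, out_dir)
    write.csv(do.call(rbind, lapply(phases, `[[`, "bouts")),
              file.path(out_dir, "bouts.csv"), row.names = FALSE)
    write.csv(hierarchy, file.path(out_dir, "hierarchy.csv"),
              row.names = FALSE)
    write.csv(weights, file.path(out_dir, "weights.csv"), row.names = FALSE)
    write_feeding_events(events, file.path(out_dir, "feeding_events.csv"))
    write.csv(daily, file.path(out_dir, "daily_summaries.csv"),
              row.names = FALSE)
    write.csv(metrics, file.path(out_dir, "phase_metrics.csv"),
              row.names = FALSE)
    write_abundance(abundance, out_dir)
    write.csv(contrasts, file.path(out_dir, "feeding_contrasts.csv"),
              row.names = FALSE)
    write.csv(micro$biomarkers, file.path(out_dir, "biomarkers.csv"),
              row.names = FALSE)
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

report_to_json <- function(report) {
  lapply(unclass(report), function(x) {
    if (is.matrix(x)) as.data.frame.matrix(x) else x
  })
}

#' @export
print.run_report <- function(x, ...) {
  cat("herdrank run report\n")
  cat("  class counts by phase:\n")
  print(x$class_counts)
  cat("  phase-3 biomarkers:",
      paste(x$biomarkers$genus[x$biomarkers$biomarker], collapse = ", "),
      "\n  panel AUC:", round(x$auc, 3), "\n")
  invisible(x)
}

#' Microbiome stage: diversity, networks, biomarkers, AUC
#'
#' Runs rarefaction and diversity, infers the per-condition and combined
#' SparCC networks from the raw counts, detects modules, computes the
#' transition scores, calls biomarkers, and evaluates the panel by
#' stratified 5-fold cross-validated AUC.
#'
#' @param counts genera x samples raw count matrix.
#' @param classes per-sample class vector ("dominant"/"submissive").
#' @param seed global seed (stage seeds derived with [child_seed()]).
#' @param depth rarefaction depth.
#' @param edge_threshold network edge cutoff; the default NULL uses a
#'   sample-size-aware cutoff `tanh(3.89/sqrt(n - 3))` per network (the
#'   Fisher-z critical value of a correlation at two-sided alpha = 1e-4,
#'   clamped to [0.3, 0.95]), so every network keeps the same, very low
#'   spurious-edge rate regardless of how many samples it was estimated
#'   from.
#' @param score_threshold,fdr_threshold biomarker thresholds.
#' @return list: diversity (Shannon by class + test, mean Bray-Curtis,
#'   Whittaker by class), networks, scores, biomarkers, panel, auc.
#' @export
biomarker_analysis <- function(counts, classes, seed = 1L, depth = 31731L,
                               edge_threshold = NULL, score_threshold = 0.25,
                               fdr_threshold = 0.05) {
  is_sub <- classes == "submissive"
  # default edge rule: Fisher-z critical correlation at per-pair
  # alpha = 1e-4, so every network keeps the same (very low) spurious-edge
  # rate whatever its sample size
  thr <- function(n) {
    if (is.null(edge_threshold)) min(max(tanh(3.89 / sqrt(n - 3)), 0.3), 0.95)
    else edge_threshold
  }
  rare <- rarefy(counts, depth, seed = child_seed(seed, 41))
  kept <- colnames(rare)
  keep_sub <- is_sub[match(kept, colnames(counts))]
  shannon <- shannon_alpha(rare)
  sh_test <- suppressWarnings(
    wilcox.test(shannon[keep_sub], shannon[!keep_sub]))
  bc <- beta_diversity(rare, "bray_curtis")
  diversity <- list(
    shannon_dominant = mean(shannon[!keep_sub]),
    shannon_submissive = mean(shannon[keep_sub]),
    shannon_p = sh_test$p.value,
    bray_curtis_mean = mean(bc),
    whittaker_dominant = beta_diversity(rare[, !keep_sub, drop = FALSE],
                                        "whittaker"),
    whittaker_submissive = beta_diversity(rare[, keep_sub, drop = FALSE],
                                          "whittaker"))

  net_dom <- build_network(
    sparcc_correlations(counts[, !is_sub, drop = FALSE],
                        seed = child_seed(seed, 42)), thr(sum(!is_sub)))
  net_sub <- build_network(
    sparcc_correlations(counts[, is_sub, drop = FALSE],
                        seed = child_seed(seed, 43)), thr(sum(is_sub)))
  net_all <- build_network(
    sparcc_correlations(counts, seed = child_seed(seed, 44)),
    thr(length(is_sub)))
  scores <- netmoss_scores(net_dom, net_sub, net_all)
  biomarkers <- differential_biomarkers(counts, classes, scores,
                                        score_threshold, fdr_threshold)
  panel <- biomarkers$genus[biomarkers$biomarker]
  auc <- if (length(panel)) {
    cv_auc(counts, classes, panel, k = 5L,
           seed = child_seed(seed, 45))$auc
  } else NA_real_
  list(diversity = diversity,
       networks = list(dominant = net_dom, subordinate = net_sub,
                       combined = net_all),
       scores = scores, biomarkers = biomarkers, panel = panel, auc = auc)
}

#' Replicate the study across seeds and summarize recovery
#'
#' Runs [run_pipeline()] `n_replicates` times with deterministically derived
#' seeds and aggregates the directions of the key contrasts and the
#' biomarker recovery against the planted truth.
#'
#' @param config a [cohort_config()] template.
#' @param n_replicates number of replicates (>= 1).
#' @param seed master seed; replicate r uses `child_seed(seed, r)`.
#' @return list with `per_replicate` (data.frame) and `summary`.
#' @export
replicate_study <- function(config, n_replicates = 20L, seed = config$seed) {
  stopifnot(n_replicates >= 1)
  planted <- config$planted_log2fc
  rows <- lapply(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- child_seed(seed, r)
    rep_r <- run_pipeline(cfg)
    fc <- rep_r$feeding_contrasts
    i3 <- fc[fc$phase == 3 & fc$metric == "intake_g", ]
    bm <- rep_r$biomarkers
    called <- bm$genus[bm$biomarker]
    dir_ok <- all(vapply(intersect(called, names(planted)), function(g) {
      bm$direction[bm$genus == g] ==
        if (planted[[g]] > 0) "submissive" else "dominant"
    }, logical(1)))
    wf <- rep_r$weight_fit
    data.frame(replicate = r, seed = cfg$seed,
               intake3_submissive_lower = i3$estimate < 0,
               intake3_p = i3$p,
               weight3_submissive_lower =
                 wf$estimate[wf$term == "classsubmissive"] < 0,
               n_biomarkers = length(called),
               panel_exact = setequal(called, names(planted)) && dir_ok,
               auc = rep_r$auc, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  list(per_replicate = per,
       summary = list(
         intake_sign_agreement = mean(per$intake3_submissive_lower),
         weight_sign_agreement = mean(per$weight3_submissive_lower),
         exact_panel_rate = mean(per$panel_exact),
         median_auc = median(per$auc, na.rm = TRUE)))
}

#' Replicate the planted-biomarker design only
#'
#' Lightweight variant of [replicate_study()] that regenerates just the
#' phase-3 abundance design (16 dominant vs 16 submissive samples, 5
#' planted genera among `n_genera`) and runs the biomarker stage, for
#' recovery-rate and AUC studies.
#'
#' @param n_replicates number of replicates.
#' @param seed master seed; replicate r uses `child_seed(seed, 100 + r)`.
#' @param n_per_class samples per class (default 16).
#' @param config a [cohort_config()] supplying the planted panel and depths.
#' @return data.frame: replicate, n_biomarkers, panel_exact, directions_ok,
#'   auc.
#' @export
replicate_biomarkers <- function(n_replicates = 20L, seed = 1L,
                                 n_per_class = 16L,
                                 config = cohort_config(seed = seed)) {
  planted <- config$planted_log2fc
  rows <- lapply(seq_len(n_replicates), function(r) {
    s <- child_seed(seed, 100 + r)
    sheet <- data.frame(
      sample_id = sprintf("S%02d", seq_len(2 * n_per_class)),
      animal_id = sprintf("A%02d", seq_len(2 * n_per_class)),
      class = rep(c("dominant", "submissive"), each = n_per_class),
      stringsAsFactors = FALSE)
    ab <- generate_abundances(sheet, n_genera = config$n_genera,
                              planted = planted, seed = s,
                              depth_range = config$depth_range)
    res <- biomarker_analysis(ab$counts, sheet$class, seed = s,
                              depth = config$rarefaction_depth)
    called <- res$panel
    dir_ok <- all(vapply(intersect(called, names(planted)), function(g) {
      res$biomarkers$direction[res$biomarkers$genus == g] ==
        if (planted[[g]] > 0) "submissive" else "dominant"
    }, logical(1)))
    data.frame(replicate = r, seed = s, n_biomarkers = length(called),
               panel_exact = setequal(called, names(planted)),
               directions_ok = dir_ok, auc = res$auc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Null phase-3 intake contrast p-values
#'
#' Simulates light cohorts with every class effect zeroed and returns the
#' p-value of the phase-3 dominant-vs-submissive intake contrast for each
#' replicate; used to check the test's type-I error. Each replicate
#' simulates `days` phase-3 feeder days (a scaled-down phase; the contrast's
#' null distribution does not depend on the phase length).
#'
#' @param n_replicates number of replicates.
#' @param seed master seed.
#' @param days number of simulated phase-3 days (default 10).
#' @param n_pens pens (default 8).
#' @return numeric vector of p-values.
#' @export
null_intake_pvalues <- function(n_replicates = 1000L, seed = 1L,
                                days = 10L, n_pens = 8L) {
  vapply(seq_len(n_replicates), function(r) {
    s <- child_seed(seed, 200 + r)
    cfg <- cohort_config(n_pens = n_pens, seed = s,
                         intake_mult = 1, visit_mult = 1, midday_shift = 0,
                         weight_gap_kg = 0)
    cohort <- generate_cohort(cfg)
    ph <- phase_hierarchy(cohort, 3, seed = child_seed(s, 13))
    day_range <- cfg$mix_days[2] + seq_len(days) - 1L
    events <- generate_feeding_events(cohort$animals, ph$assignment,
                                      day_range, cfg,
                                      seed = child_seed(s, 30))
    daily <- daily_summaries(events)
    metrics <- phase_aggregate(daily, cfg)
    roster <- phase_roster(cohort, 3)
    contrast_metric(metrics, ph$assignment, roster, 3, "intake_g",
                    with_pen = TRUE)$p
  }, numeric(1))
}
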