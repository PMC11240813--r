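#' Cohort configuration for the synthetic study
#'
#' Bundles the design of the emulated growing-pig study: pen structure,
#' treatment split, the two mixing events of the stress treatment, study
#' phases, slaughter days, and all planted effect sizes used by the
#' generators. Defaults reproduce the reference design: 8 pens of 8 animals
#' (4 castrated males, 4 females), mixing of females on day 61 and males on
#' day 83, slaughter on days 141/148, and dominant/submissive contrasts in
#' intake, feeder visits, midday feeding share, growth and five planted
#' differential genera.
#'
#' @param n_pens even number of pens (default 8; half control, half stress).
#' @param animals_per_pen animals per pen (default 8: 4 females + 4 castrated
#'   males).
#' @param mix_days strictly increasing study days of the two mixing events
#'   (females first, then males); default `c(61, 83)`.
#' @param study_days last study day with feeder data (default 140).
#' @param slaughter_days the two slaughter days; half the animals each
#'   (default `c(141, 148)`).
#' @param weigh_days scheduled weighing days (default `c(0, 21, 77, 103, 134)`;
#'   a final weight is added at each animal's slaughter day).
#' @param seed integer seed; mandatory, drives all generators.
#' @param intake_mult dominant intake multiplier at phase 3 (submissive gets
#'   the reciprocal), default `sqrt(3387/2870)` so the phase-3
#'   dominant/submissive intake ratio is 3387/2870.
#' @param intake_phase_ramp exponent applied to `log(intake_mult)` per phase;
#'   default `c(0, 0.62, 1)`: no class effect in phase 1, and a phase-2
#'   effect matching the 2745/2476 phase-2 intake ratio.
#' @param visit_mult dominant feeder-visit rate multiplier at phase 3,
#'   default `sqrt(117/95.1)` (pen-relative visit contrast).
#' @param midday_shift additive shift of the submissive share of feeding time
#'   in the 10:00-13:59 window, default 0.041 (0.200 vs 0.241).
#' @param weight_gap_kg phase-3 dominant minus submissive weight gap in kg
#'   (default 6, i.e. 126 vs 120 kg class means).
#' @param planted_log2fc named vector of planted genus log2 fold-changes,
#'   submissive over dominant. Default: Oliverpabstia, Peptococcus and
#'   Faecalibacterium at -4 (up in dominants), Holdemanella and
#'   Acetitomaculum at +4 (up in submissives).
#' @param p_draw,p_inconclusive,p_confirm dominance-bout outcome
#'   probabilities (defaults 0.10, 0.05, 0.70).
#' @param visits_per_day baseline Poisson mean of feeder visits per
#'   animal-day (default 6).
#' @param n_genera number of genera in the synthetic abundance table
#'   (default 40).
#' @param rarefaction_depth target rarefaction depth (default 31731).
#' @param depth_range sequencing-depth range, uniform integer draw (default
#'   `c(32000, 60000)` so rarefaction at the default depth never fails).
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_pens = 8,
                          animals_per_pen = 8,
                          mix_days = c(61L, 83L),
                          study_days = 140L,
                          slaughter_days = c(141L, 148L),
                          weigh_days = c(0L, 21L, 77L, 103L, 134L),
                          seed = 1L,
                          intake_mult = sqrt(3387 / 2870),
                          intake_phase_ramp = c(0, 0.62, 1),
                          visit_mult = sqrt(117 / 95.1),
                          midday_shift = 0.041,
                          weight_gap_kg = 6,
                          planted_log2fc = c(Oliverpabstia = -4,
                                             Peptococcus = -4,
                                             Faecalibacterium = -4,
                                             Holdemanella = 4,
                                             Acetitomaculum = 4),
                          p_draw = 0.10,
                          p_inconclusive = 0.05,
                          p_confirm = 0.70,
                          visits_per_day = 6,
                          n_genera = 40L,
                          rarefaction_depth = 31731L,
                          depth_range = c(32000L, 60000L)) {
  if (n_pens %% 2 != 0) {
    stop_config("n_pens must be even (half control, half stress), got ", n_pens)
  }
  if (length(mix_days) && any(diff(mix_days) <= 0)) {
    stop_config("mix_days must be strictly increasing")
  }
  if (intake_mult <= 0 || visit_mult <= 0) {
    stop_config("effect multipliers must be > 0")
  }
  if (p_draw < 0 || p_inconclusive < 0 || p_draw + p_inconclusive >= 1 + 1e-12) {
    if (p_draw + p_inconclusive > 1) {
      stop_config("p_draw + p_inconclusive must be <= 1")
    }
  }
  if (n_genera < length(planted_log2fc)) {
    stop_config("n_genera must be at least the number of planted genera")
  }
  cfg <- list(
    n_pens = as.integer(n_pens),
    animals_per_pen = as.integer(animals_per_pen),
    mix_days = as.integer(mix_days),
    study_days = as.integer(study_days),
    slaughter_days = as.integer(slaughter_days),
    weigh_days = as.integer(weigh_days),
    seed = as.integer(seed),
    intake_mult = intake_mult,
    intake_phase_ramp = intake_phase_ramp,
    visit_mult = visit_mult,
    midday_shift = midday_shift,
    weight_gap_kg = weight_gap_kg,
    planted_log2fc = planted_log2fc,
    p_draw = p_draw,
    p_inconclusive = p_inconclusive,
    p_confirm = p_confirm,
    visits_per_day = visits_per_day,
    n_genera = as.integer(n_genera),
    rarefaction_depth = as.integer(rarefaction_depth),
    depth_range = as.integer(depth_range)
  )
  class(cfg) <- "cohort_config"
  cfg
}

#' Study phase of a day
#'
#' Phase 1 runs up to (but not including) the first mixing day, phase 2 up to
#' the second, phase 3 afterwards.
#'
#' @param day integer vector of study days.
#' @param config a [cohort_config()].
#' @return integer vector of phases (1, 2 or 3).
#' @export
phase_of_day <- function(day, config) {
  findInterval(day, config$mix_days) + 1L
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("cohort_config:", x$n_pens, "pens x", x$animals_per_pen,
      "animals; mixing on days", paste(x$mix_days, collapse = ", "),
      "; seed", x$seed, "\n")
  invisible(x)
}
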