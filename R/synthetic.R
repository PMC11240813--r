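# Synthetic cohort generators.
#
# The generators emulate the reference study design: 8 pens x 8 growing pigs
# (4 females, 4 castrated males), control vs stress treatment with two mixing
# events (females on day 61, males on day 83), growth from ~18 kg at arrival
# to ~140 kg at slaughter, dominance bouts following a Bradley-Terry model on
# a latent ability, electronic-feeder event logs with planted class effects
# on intake / visit rate / midday feeding share, and a genus-level abundance
# table with five planted differential genera.

#' Generate a synthetic cohort roster, treatment split and mixing plan
#'
#' Animals get a latent Bradley-Terry ability (standard normal) that drives
#' bout outcomes and serves as the size proxy when choosing which animal is
#' exempt from mixing. The first half of the pens are control, the second
#' half stress. At each mixing event the stress pens exchange animals of one
#' sex (females at the first event, males at the second): the
#' lowest-latent-ability animal of that sex stays, the others are
#' redistributed round-robin so each stress pen keeps its size.
#'
#' @param config a [cohort_config()].
#' @return an object of class `cohort`: list with `animals` (animal_id, sex,
#'   pen_id, treatment, latent_ability), `mixing_plan` (animal_id, day,
#'   from_pen, to_pen) and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_pens <- config$n_pens
  app <- config$animals_per_pen
  if (app %% 2 != 0) stop_config("animals_per_pen must be even (half per sex)")

  local_seed(config$seed, {
    pens <- sprintf("P%d", seq_len(n_pens))
    treatment <- rep(c("control", "stress"), each = n_pens / 2)
    animals <- data.table::rbindlist(lapply(seq_len(n_pens), function(i) {
      sexes <- rep(c("female", "castrated_male"), each = app / 2)
      tag <- ifelse(sexes == "female", "F", "M")
      idx <- stats::ave(seq_len(app), sexes, FUN = seq_along)
      data.table::data.table(
        animal_id = sprintf("%s_%s%d", pens[i], tag, idx),
        sex = sexes,
        pen_id = pens[i],
        treatment = treatment[i],
        latent_ability = rnorm(app)
      )
    }))

    stress_pens <- pens[treatment == "stress"]
    plan <- list()
    sex_at_mix <- c("female", "castrated_male")   # females first, then males
    for (m in seq_along(config$mix_days)) {
      if (length(stress_pens) < 2 || m > 2) break
      day <- config$mix_days[m]
      movers <- list()
      for (p in stress_pens) {
        sub <- animals[animals$pen_id == p & animals$sex == sex_at_mix[m], ]
        sub <- sub[order(sub$latent_ability), ]
        movers[[p]] <- sub$animal_id[-1L]   # smallest (lowest ability) stays
      }
      k <- length(stress_pens)
      for (i in seq_len(k)) {
        ids <- movers[[stress_pens[i]]]
        for (j in seq_along(ids)) {
          dest <- stress_pens[((i - 1 + j) %% k) + 1L]
          plan[[length(plan) + 1L]] <- data.table::data.table(
            animal_id = ids[j], day = day,
            from_pen = stress_pens[i], to_pen = dest)
        }
      }
      # apply moves so the second mix sees post-first-mix membership
      mv <- data.table::rbindlist(plan)
      mv <- mv[mv$day == day, ]
      animals$pen_id[match(mv$animal_id, animals$animal_id)] <- mv$to_pen
    }
    mixing_plan <- if (length(plan)) data.table::rbindlist(plan) else
      data.table::data.table(animal_id = character(), day = integer(),
                             from_pen = character(), to_pen = character())

    # restore initial pens in the roster; current pens come from pen_assignment()
    if (nrow(mixing_plan)) {
      first_moves <- mixing_plan[!duplicated(mixing_plan$animal_id), ]
      animals$pen_id[match(first_moves$animal_id, animals$animal_id)] <-
        first_moves$from_pen
    }

    out <- list(animals = data.table::setDF(animals),
                mixing_plan = data.table::setDF(mixing_plan),
                config = config)
    class(out) <- "cohort"
    out
  })
}

#' Pen membership on a given study day
#'
#' Applies the mixing plan up to `day` to the initial roster.
#'
#' @param cohort a [generate_cohort()] result.
#' @param day study day.
#' @return data.frame with `animal_id` and `pen_id` valid on that day.
#' @export
pen_assignment <- function(cohort, day) {
  stopifnot(inherits(cohort, "cohort"))
  pens <- cohort$animals[, c("animal_id", "pen_id")]
  mp <- cohort$mixing_plan
  if (nrow(mp)) {
    mp <- mp[mp$day <= day, ]
    if (nrow(mp)) {
      mp <- mp[order(mp$day), ]
      for (i in seq_len(nrow(mp))) {
        pens$pen_id[pens$animal_id == mp$animal_id[i]] <- mp$to_pen[i]
      }
    }
  }
  pens
}

#' Roster with pen membership of a given phase
#'
#' Phase 1 membership is the initial one; phases 2 and 3 reflect the first
#' and second mixing respectively.
#'
#' @inheritParams pen_assignment
#' @param phase study phase (1, 2 or 3).
#' @return the animals data.frame with `pen_id` as of that phase.
#' @export
phase_roster <- function(cohort, phase) {
  stopifnot(phase %in% 1:3)
  day <- if (phase == 1) 0L else cohort$config$mix_days[phase - 1L]
  pens <- pen_assignment(cohort, day)
  roster <- cohort$animals
  roster$pen_id <- pens$pen_id[match(roster$animal_id, pens$animal_id)]
  roster
}

#' Simulate dominance-test bouts for a schedule
#'
#' Bout outcomes follow a Bradley-Terry model: among decisive bouts the
#' winner is drawn with probability `plogis(ability_a - ability_b)`. Each
#' scheduled pairing is independently a draw with probability `p_draw`,
#' inconclusive (non-evaluable) with probability `p_inconclusive`, otherwise
#' decisive; a decisive outcome is confirmed in the second test stage with
#' probability `p_confirm`.
#'
#' @param roster data.frame with `animal_id`, `pen_id`, `latent_ability`.
#' @param schedule data.frame with `pen_id`, `day`, `animal_a`, `animal_b`
#'   (see [round_robin_schedule()]).
#' @param phase integer phase label stored on each record.
#' @param p_draw,p_inconclusive,p_confirm outcome probabilities.
#' @param seed integer seed.
#' @return data.frame of bout records: pen_id, phase, day, animal_a,
#'   animal_b, outcome, winner (NA unless decisive), confirmed.
#' @export
generate_bouts <- function(roster, schedule, phase,
                           p_draw = 0.1, p_inconclusive = 0.05,
                           p_confirm = 0.7, seed = 1L) {
  assert_has_cols(roster, c("animal_id", "latent_ability"))
  assert_has_cols(schedule, c("day", "animal_a", "animal_b"))
  stopifnot(p_draw >= 0, p_inconclusive >= 0, p_draw + p_inconclusive <= 1,
            p_confirm >= 0, p_confirm <= 1)
  unknown <- setdiff(c(schedule$animal_a, schedule$animal_b), roster$animal_id)
  if (length(unknown)) {
    stop_config("schedule references unknown animals: ",
                paste(unique(unknown), collapse = ", "))
  }
  ability <- setNames(roster$latent_ability, roster$animal_id)
  pen <- if ("pen_id" %in% names(schedule)) schedule$pen_id else
    setNames(roster$pen_id, roster$animal_id)[schedule$animal_a]

  local_seed(seed, {
    n <- nrow(schedule)
    u <- runif(n)
    outcome <- ifelse(u < p_draw, "draw",
                      ifelse(u < p_draw + p_inconclusive, "inconclusive",
                             "decisive"))
    gap <- ability[schedule$animal_a] - ability[schedule$animal_b]
    a_wins <- runif(n) < plogis(gap)
    winner <- ifelse(outcome == "decisive",
                     ifelse(a_wins, schedule$animal_a, schedule$animal_b),
                     NA_character_)
    confirmed <- outcome == "decisive" & runif(n) < p_confirm
    data.frame(pen_id = pen, phase = as.integer(phase), day = schedule$day,
               animal_a = schedule$animal_a, animal_b = schedule$animal_b,
               outcome = outcome, winner = unname(winner),
               confirmed = confirmed, stringsAsFactors = FALSE)
  })
}

# piecewise-linear baseline daily intake (g/day) vs study day, anchored to
# the phase-2 and phase-3 class-mean geometric midpoints; flat after day 112
intake_baseline <- function(day) {
  stats::approx(x = c(0, 72, 112),
                y = c(800, sqrt(2745 * 2476), sqrt(3387 * 2870)),
                xout = pmin(day, 112), rule = 2)$y
}

# per-phase signed log-multiplier for a class effect
class_sign <- function(class) {
  c(dominant = 1, intermediate = 0, submissive = -1)[class]
}

# six 4-h slot start hours, anchored at 02:00 so slot 3 is [10:00, 14:00)
slot_start_hours <- function(anchor = 2L) (anchor + 4L * 0:5) %% 24L

#' Simulate electronic-feeder event logs
#'
#' Per animal-day: the number of feeder visits is Poisson with a
#' class-dependent rate; total daily intake follows an age-dependent baseline
#' times class, animal and day multipliers and is split over visits; session
#' durations are log-normal; session start times are drawn from a six-slot
#' (4 h) day partition whose midday component is raised for submissive
#' animals. Class effects ramp over phases via `config$intake_phase_ramp`
#' (zero in phase 1, full in phase 3).
#'
#' @param roster animals data.frame (animal_id at minimum).
#' @param hierarchy data.frame with `animal_id`, `phase`, `class`.
#' @param day_range integer vector of study days to simulate.
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return data.frame of feeding events: animal_id, day, start_time
#'   (POSIXct, UTC, day 1 = 2022-06-01), duration_s, intake_g.
#' @export
generate_feeding_events <- function(roster, hierarchy, day_range, config,
                                    seed = config$seed) {
  if (length(day_range) == 0) stop_config("day_range must not be empty")
  assert_has_cols(hierarchy, c("animal_id", "phase", "class"))
  ids <- roster$animal_id
  ramp <- config$intake_phase_ramp

  local_seed(seed, {
    animal_mult <- setNames(rlnorm(length(ids), 0, 0.11), ids)
    grid <- expand.grid(animal_id = ids, day = as.integer(day_range),
                        stringsAsFactors = FALSE)
    grid$phase <- phase_of_day(grid$day, config)
    key <- paste(hierarchy$animal_id, hierarchy$phase)
    cls <- hierarchy$class[match(paste(grid$animal_id, grid$phase), key)]
    cls[is.na(cls)] <- "intermediate"
    sgn <- class_sign(cls)
    r <- ramp[grid$phase]

    lambda <- config$visits_per_day * exp(sgn * r * log(config$visit_mult))
    n_visits <- rpois(nrow(grid), lambda)
    day_intake <- intake_baseline(grid$day) *
      exp(sgn * r * log(config$intake_mult)) *
      animal_mult[grid$animal_id] * rlnorm(nrow(grid), 0, 0.15)
    day_intake[n_visits == 0] <- 0

    keep <- n_visits > 0
    grid <- grid[keep, ]; n_visits <- n_visits[keep]
    day_intake <- day_intake[keep]; sgn <- sgn[keep]; r <- r[keep]

    idx <- rep.int(seq_len(nrow(grid)), n_visits)
    n_ev <- length(idx)
    # intake split over a day's visits by normalized Gamma(4) weights
    w <- rgamma(n_ev, shape = 4)
    wsum <- stats::ave(w, idx, FUN = sum)
    intake_g <- day_intake[idx] * w / wsum

    # slot mixture: baseline shares per 4-h window [02,06,10,14,18,22];
    # submissive midday share raised by config$midday_shift at full ramp
    base_p <- c(0.04, 0.24, 0.20, 0.21, 0.26, 0.05)
    mid <- base_p[3] + pmax(-sgn[idx], 0) * r[idx] * config$midday_shift
    scale_other <- (1 - mid) / (1 - base_p[3])
    pm <- outer(rep(1, n_ev), base_p) * scale_other
    pm[, 3] <- mid
    cum <- t(apply(pm, 1, cumsum))
    u <- runif(n_ev)
    slot <- 1L + rowSums(u > cum[, -6, drop = FALSE] - 1e-12)
    slot <- pmin(slot, 6L)
    start_sec <- (slot_start_hours()[slot] * 3600 + runif(n_ev, 0, 4 * 3600 - 1))
    duration_s <- pmax(30, rlnorm(n_ev, log(850), 0.6))

    origin <- as.POSIXct("2022-05-31 00:00:00", tz = "UTC")  # day 1 = June 1
    ev <- data.frame(
      animal_id = grid$animal_id[idx],
      day = grid$day[idx],
      start_time = origin + grid$day[idx] * 86400 + start_sec,
      duration_s = duration_s,
      intake_g = intake_g,
      stringsAsFactors = FALSE
    )
    ev[order(ev$animal_id, ev$start_time), ]
  })
}

#' Simulate the weight-record schedule
#'
#' Growth is linear from arrival (~18.8 kg females, 18.6 kg castrated males)
#' with an animal-specific growth-rate multiplier, sampled at the scheduled
#' weighing days plus each animal's slaughter day (half on each slaughter
#' day). The dominant/submissive gap ramps linearly with age so that the
#' phase-3 class means differ by `config$weight_gap_kg`.
#'
#' @inheritParams generate_feeding_events
#' @return data.frame of weight records: animal_id, day, weight.
#' @export
generate_weights <- function(roster, hierarchy, config, seed = config$seed) {
  assert_has_cols(roster, c("animal_id", "sex"))
  assert_has_cols(hierarchy, c("animal_id", "phase", "class"))
  ids <- roster$animal_id
  local_seed(seed, {
    gm <- setNames(rnorm(length(ids), 1, 0.06), ids)
    slaughter <- setNames(rep(config$slaughter_days,
                              length.out = length(ids)), ids)
    recs <- do.call(rbind, lapply(ids, function(a) {
      data.frame(animal_id = a,
                 day = c(config$weigh_days, slaughter[[a]]),
                 stringsAsFactors = FALSE)
    }))
    recs$phase <- phase_of_day(recs$day, config)
    key <- paste(hierarchy$animal_id, hierarchy$phase)
    cls <- hierarchy$class[match(paste(recs$animal_id, recs$phase), key)]
    cls[is.na(cls)] <- "intermediate"
    base0 <- ifelse(roster$sex[match(recs$animal_id, roster$animal_id)] ==
                      "female", 18.8, 18.6)
    ramp_day <- mean(config$weigh_days[config$weigh_days >= config$mix_days[2]])
    ramp <- pmin(recs$day, ramp_day) / ramp_day
    recs$weight <- base0 + 0.88 * gm[recs$animal_id] * recs$day +
      class_sign(cls) * (config$weight_gap_kg / 2) * ramp +
      rnorm(nrow(recs), 0, 0.8)
    recs$weight <- pmax(recs$weight, 1)
    recs[, c("animal_id", "day", "weight")]
  })
}

#' Simulate a genus-level abundance count matrix with planted biomarkers
#'
#' Counts are Dirichlet-multinomial per sample: each sample draws its genus
#' proportions from a Dirichlet with concentration `theta` around
#' sample-specific mean proportions, then a multinomial at the sample's
#' sequencing depth. Mean proportions carry (a) the planted class-dependent
#' fold-changes, (b) class-independent background co-occurrence factors that
#' give the network stable modules, and (c) condition-dependent guild
#' associations: each planted genus co-varies with a background block only
#' in the class where it is abundant. Planted genera therefore genuinely
#' change their network neighbourhood between conditions -- in a condition
#' network they integrate with the core community, while in the pooled
#' network the class-driven covariation binds the guild together and
#' detaches it from the blocks. This is the transition-driver structure the
#' differential-network scoring assumes.
#'
#' @param samples data.frame with `sample_id`, `animal_id`, `class`
#'   (dominant/submissive).
#' @param n_genera number of genera (>= number of planted genera).
#' @param planted named numeric vector: genus name -> log2 fold-change of
#'   submissive over dominant mean relative abundance. Numeric names are
#'   treated as genus indices.
#' @param depth_distribution function(n) returning n integer depths; default
#'   uniform on `depth_range`.
#' @param seed integer seed.
#' @param theta Dirichlet concentration (overdispersion; default 2000).
#' @param depth_range default depth range when `depth_distribution` is NULL.
#' @return an `abundance_matrix`: list with `counts` (genera x samples
#'   integer matrix), `samples` (metadata), `planted`.
#' @export
generate_abundances <- function(samples, n_genera = 40L,
                                planted = c(Oliverpabstia = -4,
                                            Peptococcus = -4,
                                            Faecalibacterium = -4,
                                            Holdemanella = 4,
                                            Acetitomaculum = 4),
                                depth_distribution = NULL, seed = 1L,
                                theta = 2000,
                                depth_range = c(32000L, 60000L)) {
  assert_has_cols(samples, c("sample_id", "class"))
  if (anyDuplicated(samples$sample_id)) stop_config("sample ids must be unique")
  if (n_genera < length(planted)) {
    stop_config("n_genera must be >= number of planted genera")
  }
  # planted given as indices?
  pl_names <- names(planted)
  if (is.null(pl_names) || any(pl_names == "")) {
    idx <- seq_along(planted)
    pl_names <- sprintf("Genus%02d", idx)
    names(planted) <- pl_names
  }
  suppressWarnings({
    as_idx <- as.integer(names(planted))
    if (!anyNA(as_idx)) {
      if (any(as_idx < 1 | as_idx > n_genera)) {
        stop_config("planted genus index out of range 1..", n_genera)
      }
      names(planted) <- sprintf("Genus%02d", as_idx)
    }
  })
  genera <- c(names(planted),
              sprintf("Genus%02d", seq_len(n_genera))[
                !sprintf("Genus%02d", seq_len(n_genera)) %in% names(planted)])
  genera <- genera[seq_len(n_genera)]
  n_s <- nrow(samples)
  if (is.null(depth_distribution)) {
    depth_distribution <- function(n) {
      sample.int(depth_range[2] - depth_range[1] + 1L, n, replace = TRUE) +
        depth_range[1] - 1L
    }
  }

  local_seed(seed, {
    n_pl <- length(planted)
    # planted genera sit at a typical-genus base abundance (mu = -1) so the
    # guild's class swing stays a small fraction of total mass and does not
    # couple compositionally into the null genera. Background log-mean
    # abundances are truncated below at -1.3: the table emulates the top
    # genera of a prevalence-filtered study, and ultra-rare taxa would make
    # compositional correlation estimates arbitrarily unstable.
    mu <- c(rep(-1, n_pl), pmax(rnorm(n_genera - n_pl, 0, 1.2), -1.3))
    names(mu) <- genera
    # balance the total planted mass between classes so the planted shifts
    # do not leak a systematic compositional signal into every null genus
    n_up_dom <- sum(planted < 0)
    n_up_sub <- sum(planted > 0)
    if (n_up_dom > 0 && n_up_sub > 0) {
      mu[names(planted)[planted > 0]] <- -1 + log(n_up_dom / n_up_sub)
    }
    is_sub <- samples$class == "submissive"
    shift <- matrix(0, n_genera, n_s, dimnames = list(genera, samples$sample_id))
    for (g in names(planted)) {
      shift[g, ] <- 0.5 * log(2) * planted[[g]] * ifelse(is_sub, 1, -1)
    }
    # background co-occurrence blocks (class-independent). Factors are
    # centred within each class so that finite-sample factor imbalance
    # cannot masquerade as a class effect or couple the planted shifts to
    # the background community.
    bg <- setdiff(genera, names(planted))
    n_blocks <- max(1L, min(3L, length(bg) %/% 8L))
    block_of <- rep(seq_len(n_blocks), length.out = length(bg))
    fac <- matrix(rnorm(n_blocks * n_s), n_blocks, n_s)
    for (b in seq_len(n_blocks)) {
      fac[b, is_sub] <- fac[b, is_sub] - mean(fac[b, is_sub])
      fac[b, !is_sub] <- fac[b, !is_sub] - mean(fac[b, !is_sub])
    }
    load_bg <- matrix(0, n_genera, n_s, dimnames = dimnames(shift))
    for (b in seq_len(n_blocks)) {
      load_bg[bg[block_of == b], ] <-
        matrix(0.75 * fac[b, ], sum(block_of == b), n_s, byrow = TRUE)
    }
    # condition-dependent guild association: planted genera track a core
    # background block's factor only in the class where they are abundant
    # (dominant markers with block 1 in dominant samples, submissive
    # markers with block 2 in submissive samples); pooling the classes
    # halves the covariance while the planted class shift inflates the
    # variance, so the guild detaches from its block in the combined
    # network
    load_cl <- matrix(0, n_genera, n_s, dimnames = dimnames(shift))
    dom_pl <- names(planted)[planted < 0]
    sub_pl <- names(planted)[planted > 0]
    if (length(dom_pl) && n_blocks >= 1) {
      load_cl[dom_pl, !is_sub] <-
        matrix(0.75 * fac[1, !is_sub], length(dom_pl), sum(!is_sub),
               byrow = TRUE)
    }
    if (length(sub_pl) && n_blocks >= 2) {
      load_cl[sub_pl, is_sub] <-
        matrix(0.75 * fac[2, is_sub], length(sub_pl), sum(is_sub),
               byrow = TRUE)
    }

    logm <- mu + shift + load_bg + load_cl
    m <- apply(exp(logm), 2, function(v) v / sum(v))
    depths <- as.integer(depth_distribution(n_s))
    counts <- vapply(seq_len(n_s), function(s) {
      gam <- rgamma(n_genera, shape = theta * m[, s])
      p <- gam / sum(gam)
      as.integer(stats::rmultinom(1, depths[s], p))
    }, integer(n_genera))
    dimnames(counts) <- list(genera, samples$sample_id)
    out <- list(counts = counts, samples = samples, planted = planted,
                depths = setNames(depths, samples$sample_id))
    class(out) <- "abundance_matrix"
    out
  })
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("abundance_matrix:", nrow(x$counts), "genera x", ncol(x$counts),
      "samples;", length(x$planted), "planted genera\n")
  invisible(x)
}

#' Phase-3 microbiome sample sheet for a hierarchy
#'
#' One faecal sample per dominant or submissive animal of the given phase
#' (the two extreme classes compared in the biomarker analysis).
#'
#' @param hierarchy data.frame with animal_id, phase, class.
#' @param phase phase to sample (default 3).
#' @return data.frame with sample_id, animal_id, phase, class.
#' @export
sample_sheet <- function(hierarchy, phase = 3L) {
  h <- hierarchy[hierarchy$phase == phase &
                   hierarchy$class %in% c("dominant", "submissive"), ]
  data.frame(sample_id = paste0("S_", h$animal_id),
             animal_id = h$animal_id,
             phase = phase,
             class = h$class,
             stringsAsFactors = FALSE)
}
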