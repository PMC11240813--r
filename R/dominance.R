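# Dominance test: round-robin tournament, bout scoring, ranking scores,
# hierarchy classification and hierarchy-change accounting.
#
# Scoring follows the two-stage food-competition test: the first animal to
# eat (or the winner of a displacement) is "Dominant"; if it also displaces
# the other animal in the second stage it is "Dominant Confirmed". A bout
# contributes +1 to the winner's tally and -0.5 to the loser's; a draw
# contributes 0; inconclusive bouts are non-evaluable and excluded from the
# per-animal means.

#' Round-robin schedule for a pen (1-factorization, circle method)
#'
#' Produces `n - 1` test days with `n/2` disjoint pairs per day, covering
#' every unordered pair exactly once, so each animal is tested once per day.
#' For a pen of 8: 7 days x 4 pairs = 28 distinct pairings.
#'
#' @param animal_ids character vector, even length.
#' @param pairs_per_day pairs per day; must equal `length(animal_ids)/2`.
#' @return data.frame with columns day, animal_a, animal_b.
#' @export
round_robin_schedule <- function(animal_ids,
                                 pairs_per_day = length(animal_ids) / 2) {
  n <- length(animal_ids)
  if (n < 2 || n %% 2 != 0) {
    stop_config("round_robin_schedule needs an even number of animals, got ", n)
  }
  if (pairs_per_day != n / 2) {
    stop_config("pairs_per_day must be n/2 = ", n / 2)
  }
  # circle method: fix the first id, rotate the rest
  fixed <- animal_ids[1]
  rot <- animal_ids[-1]
  out <- vector("list", n - 1)
  for (d in seq_len(n - 1)) {
    circle <- c(fixed, rot)
    a <- circle[seq_len(n / 2)]
    b <- rev(circle)[seq_len(n / 2)]
    out[[d]] <- data.frame(day = d, animal_a = a, animal_b = b,
                           stringsAsFactors = FALSE)
    rot <- c(rot[-1], rot[1])
  }
  do.call(rbind, out)
}

#' Score a single bout
#'
#' Decisive: winner +1, loser -0.5 on the Dominant tally; the Confirmed
#' tally receives the same +1/-0.5 only when the bout was confirmed in the
#' second stage, otherwise 0 for both. Draws contribute (0, 0). Inconclusive
#' bouts are non-evaluable: no contribution, and they are not counted in the
#' per-animal means.
#'
#' @param bout one-row data.frame (or list) with animal_a, animal_b,
#'   outcome, winner, confirmed.
#' @return data.frame with animal_id, dominant_contribution,
#'   confirmed_contribution, counted.
#' @export
score_bout <- function(bout) {
  a <- bout$animal_a; b <- bout$animal_b
  if (a == b) stop_config("bout pairs an animal with itself: ", a)
  if (bout$outcome == "inconclusive") {
    return(data.frame(animal_id = c(a, b), dominant_contribution = 0,
                      confirmed_contribution = 0, counted = FALSE,
                      stringsAsFactors = FALSE))
  }
  if (bout$outcome == "draw") {
    return(data.frame(animal_id = c(a, b), dominant_contribution = 0,
                      confirmed_contribution = 0, counted = TRUE,
                      stringsAsFactors = FALSE))
  }
  w <- bout$winner
  if (is.na(w) || !w %in% c(a, b)) {
    stop_config("decisive bout winner must be one of the paired animals")
  }
  l <- if (w == a) b else a
  conf <- isTRUE(bout$confirmed)
  data.frame(animal_id = c(w, l),
             dominant_contribution = c(1, -0.5),
             confirmed_contribution = if (conf) c(1, -0.5) else c(0, 0),
             counted = TRUE, stringsAsFactors = FALSE)
}

#' Ranking scores from bout records
#'
#' For each animal, the Dominant and Dominant-Confirmed contributions are
#' averaged over its counted (non-inconclusive) bouts of the phase, and the
#' ranking score is `dominant_mean / 2 + confirmed_mean`. Higher scores mean
#' higher positions in the dominance hierarchy.
#'
#' @param bouts data.frame of bout records (see [generate_bouts()]).
#' @param phase phase to score; NULL scores all records together.
#' @return data.frame with animal_id, pen_id, phase, n_bouts, dominant_mean,
#'   confirmed_mean, ranking_score. Animals appearing only in inconclusive
#'   bouts get NA means and score (explicit missing marker).
#' @export
ranking_scores <- function(bouts, phase = NULL) {
  assert_has_cols(bouts, c("animal_a", "animal_b", "outcome"))
  if (!is.null(phase)) bouts <- bouts[bouts$phase == phase, ]
  if (!nrow(bouts)) stop_config("no bouts to score")
  decisive <- bouts$outcome == "decisive"
  if (any(decisive & (is.na(bouts$winner) |
                      !(bouts$winner == bouts$animal_a |
                        bouts$winner == bouts$animal_b)))) {
    stop_config("decisive bout winner must be one of the paired animals")
  }
  win_a <- decisive & bouts$winner == bouts$animal_a
  conf <- decisive & bouts$confirmed %in% TRUE
  # vectorized form of score_bout() over both animals of every bout
  dc_a <- ifelse(decisive, ifelse(win_a, 1, -0.5), 0)
  dc_b <- ifelse(decisive, ifelse(win_a, -0.5, 1), 0)
  pen <- if ("pen_id" %in% names(bouts)) bouts$pen_id else NA
  dt <- data.table::data.table(
    animal_id = c(bouts$animal_a, bouts$animal_b),
    pen_id = c(pen, pen),
    dominant_contribution = c(dc_a, dc_b),
    confirmed_contribution = c(ifelse(conf, dc_a, 0), ifelse(conf, dc_b, 0)),
    counted = rep(bouts$outcome != "inconclusive", 2)
  )
  counted <- NULL  # NSE note for R CMD check
  agg <- dt[, list(
    pen_id = pen_id[1],
    n_bouts = sum(counted),
    dominant_mean = if (sum(counted) > 0)
      sum(dominant_contribution[counted]) / sum(counted) else NA_real_,
    confirmed_mean = if (sum(counted) > 0)
      sum(confirmed_contribution[counted]) / sum(counted) else NA_real_
  ), by = "animal_id"]
  agg$ranking_score <- agg$dominant_mean / 2 + agg$confirmed_mean
  agg$phase <- if (is.null(phase)) bouts$phase[1] %||% NA_integer_ else
    as.integer(phase)
  data.table::setDF(agg)
  agg[order(agg$pen_id, -xtfrm(agg$ranking_score)),
      c("animal_id", "pen_id", "phase", "n_bouts",
        "dominant_mean", "confirmed_mean", "ranking_score")]
}

#' Assign hierarchy classes within pens
#'
#' Per pen, animals are ranked by ranking score (descending); the top
#' `n_top` are dominant, the bottom `n_bottom` submissive, the rest
#' intermediate (2/4/2 for a pen of 8). Ties are broken deterministically by
#' higher confirmed mean, then higher dominant mean, then animal id.
#'
#' @param table a [ranking_scores()] result.
#' @param roster data.frame with animal_id and pen_id (pen membership of the
#'   scored phase); defaults to the pens recorded in `table`.
#' @param n_top,n_bottom class sizes (defaults 2 and 2).
#' @return data.frame with animal_id, pen_id, phase, class, ranking_score.
#' @export
classify_hierarchy <- function(table, roster = NULL, n_top = 2L,
                               n_bottom = 2L) {
  assert_has_cols(table, c("animal_id", "ranking_score",
                           "confirmed_mean", "dominant_mean"))
  if (!is.null(roster)) {
    table$pen_id <- roster$pen_id[match(table$animal_id, roster$animal_id)]
  }
  if (anyNA(table$ranking_score)) {
    stop_config("missing ranking scores for: ",
                paste(table$animal_id[is.na(table$ranking_score)],
                      collapse = ", "))
  }
  res <- lapply(split(table, table$pen_id), function(p) {
    if (nrow(p) < n_top + n_bottom) {
      stop_config("pen ", p$pen_id[1], " has fewer animals (", nrow(p),
                  ") than n_top + n_bottom")
    }
    o <- order(-p$ranking_score, -p$confirmed_mean, -p$dominant_mean,
               p$animal_id)
    p <- p[o, ]
    p$class <- c(rep("dominant", n_top),
                 rep("intermediate", nrow(p) - n_top - n_bottom),
                 rep("submissive", n_bottom))
    p
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[, c("animal_id", "pen_id", "phase", "class", "ranking_score")]
}

hierarchy_levels <- c("submissive", "intermediate", "dominant")

#' Label a hierarchy-class change
#'
#' Classes are ordered submissive < intermediate < dominant. A strict
#' increase is "Better" (e.g. submissive to intermediate or dominant), a
#' strict decrease "Worse", otherwise "Same".
#'
#' @param before,after character vectors of classes.
#' @return character vector of labels.
#' @export
classify_change <- function(before, after) {
  rb <- match(before, hierarchy_levels)
  ra <- match(after, hierarchy_levels)
  if (anyNA(rb) || anyNA(ra)) stop_config("unknown hierarchy class")
  ifelse(ra > rb, "Better", ifelse(ra < rb, "Worse", "Same"))
}

#' Transition table between two phase assignments
#'
#' Counts every (from-class, to-class) pair for the animals present in both
#' assignments. Animals missing from one phase are excluded with a warning.
#'
#' @param from,to classification data.frames (animal_id, class).
#' @return list with `counts` (3x3 matrix, rows = from), and `changes`
#'   (per-animal data.frame with change label).
#' @export
transition_table <- function(from, to) {
  common <- intersect(from$animal_id, to$animal_id)
  if (!length(common)) stop_config("assignments share no animals")
  dropped <- setdiff(union(from$animal_id, to$animal_id), common)
  if (length(dropped)) {
    warning("excluding animals missing in one phase: ",
            paste(dropped, collapse = ", "))
  }
  f <- from$class[match(common, from$animal_id)]
  t_ <- to$class[match(common, to$animal_id)]
  lv <- rev(hierarchy_levels)  # dominant, intermediate, submissive
  counts <- table(factor(f, levels = lv), factor(t_, levels = lv))
  counts <- unclass(counts)
  names(dimnames(counts)) <- c("from", "to")
  changes <- data.frame(animal_id = common, from = f, to = t_,
                        change = classify_change(f, t_),
                        stringsAsFactors = FALSE)
  list(counts = counts, changes = changes)
}
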