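test_that("round robin schedule is a 1-factorization", {
  # pen of 8: the reference design
  s <- round_robin_schedule(sprintf("a%d", 1:8))
  expect_equal(nrow(s), 28)
  expect_equal(length(unique(s$day)), 7)
  expect_true(all(table(s$day) == 4))

  # property: coverage and per-day disjointness for a range of pen sizes
  for (n in c(2, 4, 6, 8, 10)) {
    ids <- sprintf("x%02d", seq_len(n))
    s <- round_robin_schedule(ids)
    key <- paste(pmin(s$animal_a, s$animal_b), pmax(s$animal_a, s$animal_b))
    expect_equal(sort(key), sort(apply(combn(ids, 2), 2, paste,
                                       collapse = " ")))
    for (d in unique(s$day)) {
      day_ids <- c(s$animal_a[s$day == d], s$animal_b[s$day == d])
      expect_equal(anyDuplicated(day_ids), 0L)
    }
  }
  expect_error(round_robin_schedule(c("a", "b", "c")), "even")
})

test_that("score_bout follows the two-stage scoring rules", {
  # confirmed win: both tallies
  s <- score_bout(bout_row(confirmed = TRUE))
  expect_equal(s$dominant_contribution, c(1, -0.5))
  expect_equal(s$confirmed_contribution, c(1, -0.5))
  # unconfirmed decisive win: confirmed tally neutral
  s <- score_bout(bout_row(confirmed = FALSE))
  expect_equal(s$dominant_contribution, c(1, -0.5))
  expect_equal(s$confirmed_contribution, c(0, 0))
  # draw: all neutral but counted
  s <- score_bout(bout_row(outcome = "draw"))
  expect_equal(s$dominant_contribution, c(0, 0))
  expect_true(all(s$counted))
  # inconclusive: excluded
  s <- score_bout(bout_row(outcome = "inconclusive"))
  expect_false(any(s$counted))
  # invalid winner
  bad <- bout_row(); bad$winner <- "z"
  expect_error(score_bout(bad), "winner")
  # score conservation: each decisive bout adds +0.5 net
  s <- score_bout(bout_row())
  expect_equal(sum(s$dominant_contribution), 0.5)
})

test_that("ranking_scores reproduces hand-worked sequences", {
  # 7 bouts for animal A: 3 confirmed wins, 2 unconfirmed wins,
  # 1 loss of a confirmed bout, 1 draw
  bouts <- rbind(
    bout_row("A", "b1", confirmed = TRUE),
    bout_row("A", "b2", confirmed = TRUE),
    bout_row("A", "b3", confirmed = TRUE),
    bout_row("A", "b4", confirmed = FALSE),
    bout_row("A", "b5", confirmed = FALSE),
    bout_row("A", "b6", winner = "b6", confirmed = TRUE),
    bout_row("A", "b7", outcome = "draw"))
  rs <- ranking_scores(bouts, phase = 1)
  a <- rs[rs$animal_id == "A", ]
  expect_equal(a$dominant_mean, (5 * 1 - 0.5 + 0) / 7, tolerance = 1e-12)
  expect_equal(a$confirmed_mean, (3 * 1 - 0.5) / 7, tolerance = 1e-12)
  expect_equal(a$ranking_score, a$dominant_mean / 2 + a$confirmed_mean,
               tolerance = 1e-12)
  expect_equal(a$ranking_score, 0.6785714285714286, tolerance = 1e-9)

  # extremes: all confirmed wins / all losses
  wins <- do.call(rbind, lapply(1:7, function(i)
    bout_row("W", paste0("o", i), confirmed = TRUE)))
  rs <- ranking_scores(wins, phase = 1)
  expect_equal(rs$ranking_score[rs$animal_id == "W"], 1.5)
  losses <- do.call(rbind, lapply(1:7, function(i)
    bout_row("L", paste0("o", i), winner = paste0("o", i), confirmed = TRUE)))
  rs <- ranking_scores(losses, phase = 1)
  expect_equal(rs$ranking_score[rs$animal_id == "L"], -0.75)

  # animal seen only in inconclusive bouts gets an explicit missing score
  inc <- bout_row("U", "V", outcome = "inconclusive")
  rs <- ranking_scores(rbind(inc, bout_row("V", "W")), phase = 1)
  expect_true(is.na(rs$ranking_score[rs$animal_id == "U"]))
})

test_that("classify_hierarchy yields the 2/4/2 split with deterministic ties", {
  tab <- data.frame(animal_id = sprintf("a%d", 1:8), pen_id = "P1",
                    phase = 1L, n_bouts = 7,
                    dominant_mean = (8:1) / 10, confirmed_mean = (8:1) / 10)
  tab$ranking_score <- tab$dominant_mean / 2 + tab$confirmed_mean
  cl <- classify_hierarchy(tab)
  expect_equal(as.vector(table(cl$class)[c("dominant", "intermediate",
                                           "submissive")]), c(2L, 4L, 2L))
  expect_equal(cl$class[cl$animal_id %in% c("a1", "a2")],
               rep("dominant", 2))

  # full tie: deterministic, reproducible split by animal_id
  tie <- tab
  tie$ranking_score <- 1; tie$dominant_mean <- 1; tie$confirmed_mean <- 1
  c1 <- classify_hierarchy(tie)
  c2 <- classify_hierarchy(tie[sample(8), ])
  expect_equal(c1[order(c1$animal_id), "class"],
               c2[order(c2$animal_id), "class"])
  expect_equal(c1$class[c1$animal_id == "a1"], "dominant")

  # permuting input rows never changes the assignment (pure function)
  p <- classify_hierarchy(tab[sample(8), ])
  expect_equal(p[order(p$animal_id), "class"],
               cl[order(cl$animal_id), "class"])

  # missing scores are an error naming the animal
  tab$ranking_score[3] <- NA
  expect_error(classify_hierarchy(tab), "a3")
})

test_that("classify_change orders the classes", {
  expect_equal(classify_change("submissive", "dominant"), "Better")
  expect_equal(classify_change("submissive", "intermediate"), "Better")
  expect_equal(classify_change("intermediate", "submissive"), "Worse")
  expect_equal(classify_change("dominant", "dominant"), "Same")
  expect_error(classify_change("boss", "dominant"), "unknown")
})

test_that("transition_table counts all class movements", {
  from <- data.frame(animal_id = sprintf("a%d", 1:8),
                     class = rep(c("dominant", "intermediate", "submissive"),
                                 c(2, 4, 2)))
  # identical assignments: diagonal
  tr <- transition_table(from, from)
  expect_equal(tr$counts, diag(c(2, 4, 2)), ignore_attr = TRUE)
  expect_equal(rowSums(tr$counts), c(from = 2, 4, 2), ignore_attr = TRUE)

  # random permutations vs a brute-force count oracle
  withr::with_seed(42, {
    for (rep in 1:5) {
      to <- from
      to$class <- sample(from$class)
      tr <- transition_table(from, to)
      lv <- c("dominant", "intermediate", "submissive")
      oracle <- matrix(0L, 3, 3, dimnames = list(lv, lv))
      for (i in seq_len(8)) {
        oracle[from$class[i], to$class[i]] <-
          oracle[from$class[i], to$class[i]] + 1L
      }
      expect_equal(unclass(tr$counts), oracle, ignore_attr = TRUE)
    }
  })

  # animals missing from one phase are excluded with a warning
  expect_warning(transition_table(from, from[1:6, ]), "excluding")
  expect_error(suppressWarnings(
    transition_table(from[1:2, ], from[5:6, ])), "no animals")
})

test_that("simulated tournaments recover strong latent hierarchies", {
  # deterministic regime: no draws, big ability gaps -> top-2/bottom-2 of
  # the latent order recovered in >= 95% of pens
  withr::with_seed(7, {
    hits <- 0L
    n_pens <- 40L
    for (p in seq_len(n_pens)) {
      ids <- sprintf("p%d_a%d", p, 1:8)
      roster <- data.frame(animal_id = ids, pen_id = paste0("P", p),
                           latent_ability = seq(0, 28, by = 4))
      sched <- round_robin_schedule(ids)
      sched$pen_id <- paste0("P", p)
      bouts <- generate_bouts(roster, sched, phase = 1, p_draw = 0,
                              p_inconclusive = 0, p_confirm = 1,
                              seed = p)
      cl <- classify_hierarchy(ranking_scores(bouts, 1), roster)
      true_top <- ids[order(-roster$latent_ability)][1:2]
      true_bot <- ids[order(roster$latent_ability)][1:2]
      ok <- setequal(cl$animal_id[cl$class == "dominant"], true_top) &&
        setequal(cl$animal_id[cl$class == "submissive"], true_bot)
      hits <- hits + ok
    }
    expect_gte(hits / n_pens, 0.95)
  })
})

test_that("expected ranking score is monotone in latent ability", {
  # raising one animal's ability (same seeds for everything else) never
  # decreases its average ranking score
  mean_score <- function(ability1, seeds) {
    roster <- data.frame(animal_id = sprintf("a%d", 1:8), pen_id = "P1",
                         latent_ability = c(ability1, rep(0, 7)))
    sched <- round_robin_schedule(roster$animal_id)
    sched$pen_id <- "P1"
    mean(vapply(seeds, function(s) {
      rs <- ranking_scores(generate_bouts(roster, sched, 1, seed = s), 1)
      rs$ranking_score[rs$animal_id == "a1"]
    }, numeric(1)))
  }
  seeds <- 1:150
  m <- vapply(c(-1, 0, 1, 2), mean_score, numeric(1), seeds = seeds)
  expect_true(all(diff(m) > 0))
})
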