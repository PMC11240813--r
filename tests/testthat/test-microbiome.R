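test_that("rarefy subsamples to exact depth", {
  withr::with_seed(1, {
    m <- matrix(rpois(80, 300), 8, 10,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
    r <- rarefy(m, 1000, seed = 4)
    expect_true(all(colSums(r) == 1000))
    expect_true(all(r <= m))
    # reproducible under the same seed
    expect_identical(r, rarefy(m, 1000, seed = 4))
    # depth equal to the sample total: counts unchanged
    one <- m[, 1, drop = FALSE]
    expect_equal(rarefy(one, sum(one), seed = 1)[, 1], one[, 1])
    # samples below depth dropped with a warning; all below -> empty
    expect_warning(r2 <- rarefy(m, sum(m[, 1]) + 1e6, seed = 1), "dropping")
    expect_equal(ncol(r2), 0)
    expect_error(rarefy(m, 0), "positive")
  })
})

test_that("shannon_alpha computes the natural-log index", {
  m <- cbind(single = c(100, 0, 0, 0),
             uniform = c(25, 25, 25, 25),
             mixed = c(50, 25, 25, 0))
  h <- shannon_alpha(m)
  expect_equal(unname(h["single"]), 0)
  expect_equal(unname(h["uniform"]), log(4), tolerance = 1e-12)
  expect_equal(unname(h["mixed"]), 1.0397, tolerance = 1e-4)
  # uniform over 16 genera -> ln 16
  m16 <- matrix(10, 16, 1)
  expect_equal(unname(shannon_alpha(m16)), log(16))
  expect_warning(h0 <- shannon_alpha(cbind(a = c(0, 0))), "all-zero")
  expect_true(is.na(h0["a"]))
  # range property: 0 <= H <= ln(richness); cross-check against vegan
  skip_if_not_installed("vegan")
  withr::with_seed(3, {
    m <- matrix(rpois(200, 20), 20, 10)
    h <- shannon_alpha(m)
    expect_true(all(h >= 0 & h <= log(20)))
    expect_equal(unname(h), unname(vegan::diversity(t(m), "shannon")),
                 tolerance = 1e-10)
  })
})

test_that("beta_diversity implements Bray-Curtis and Whittaker", {
  x <- c(2, 1, 0); y <- c(1, 1, 1)
  d <- beta_diversity(cbind(a = x, b = y), "bray_curtis")
  expect_equal(as.numeric(d), (1 + 0 + 1) / (3 + 2 + 1), tolerance = 1e-12)
  # identical samples -> 0; disjoint supports -> 1
  expect_equal(as.numeric(beta_diversity(cbind(x, x), "bray_curtis")), 0)
  expect_equal(as.numeric(beta_diversity(cbind(c(3, 0), c(0, 5)),
                                         "bray_curtis")), 1)
  # whittaker on the pair: gamma 3, mean richness 2.5 -> 0.2
  expect_equal(beta_diversity(cbind(a = x, b = y), "whittaker"), 0.2)
  expect_error(beta_diversity(cbind(x, y), "nope"))
  # symmetry + range, and agreement with vegan on random data
  skip_if_not_installed("vegan")
  withr::with_seed(9, {
    m <- matrix(rpois(60, 15), 6, 10)
    d <- as.matrix(beta_diversity(m, "bray_curtis"))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
    v <- as.matrix(vegan::vegdist(t(m), "bray"))
    expect_equal(unname(d), unname(v), tolerance = 1e-10)
  })
})

test_that("sparcc_correlations recovers proportional genera", {
  withr::with_seed(20, {
    n <- 40
    base <- matrix(exp(rnorm(8 * n, 0, 0.8)), 8, n)
    base[2, ] <- 2 * base[1, ]   # genus 2 proportional to genus 1
    p <- apply(base, 2, function(v) v / sum(v))
    counts <- vapply(seq_len(n), function(s)
      as.integer(rmultinom(1, 50000, p[, s])), integer(8))
    rownames(counts) <- paste0("g", 1:8)
    r <- sparcc_correlations(counts, seed = 2)
    expect_gt(r["g1", "g2"], 0.9)
    # symmetric, unit diagonal, bounded
    expect_equal(r, t(r))
    expect_equal(unname(diag(r)), rep(1, 8))
    expect_true(all(abs(r) <= 1))
    # permuting sample order leaves estimates unchanged
    r2 <- sparcc_correlations(counts[, sample(n)], seed = 2)
    expect_equal(r2["g1", "g2"], r["g1", "g2"], tolerance = 0.05)
  })
  expect_error(sparcc_correlations(matrix(1, 3, 5)), "4 genera")
})

test_that("build_network thresholds correlations", {
  corr <- diag(5)
  corr[1, 2] <- corr[2, 1] <- 0.8
  corr[3, 4] <- corr[4, 3] <- -0.5
  corr[1, 5] <- corr[5, 1] <- 0.1
  dimnames(corr) <- list(letters[1:5], letters[1:5])
  net <- build_network(corr, 0.3)
  expect_equal(sum(net$adjacency) / 2, 2)  # |0.8| and |-0.5| only
  expect_true(net$adjacency["a", "b"] && net$adjacency["c", "d"])
  # threshold 1 excludes imperfect correlations; near 0 keeps the rest
  expect_equal(sum(build_network(corr, 1)$adjacency), 0)
  expect_equal(sum(build_network(corr, 1e-6)$adjacency) / 2, 3)
  expect_error(build_network(corr, 0), "edge_threshold")
  # idempotent
  expect_identical(build_network(corr, 0.3)$adjacency, net$adjacency)
})

test_that("detect_modules recovers block structure", {
  # two disconnected cliques
  adj <- matrix(FALSE, 8, 8)
  adj[1:4, 1:4] <- TRUE; adj[5:8, 5:8] <- TRUE
  diag(adj) <- FALSE
  net <- net_from_adj(adj)
  mod <- detect_modules(net)
  expect_equal(length(unique(mod)), 2)
  expect_equal(length(unique(mod[1:4])), 1)
  expect_equal(length(unique(mod[5:8])), 1)
  # edgeless network: every node its own module
  none <- net_from_adj(matrix(FALSE, 5, 5))
  expect_equal(length(unique(detect_modules(none))), 5)
  # planted 3-block correlation structure recovered exactly
  withr::with_seed(17, {
    blocks <- rep(1:3, each = 6)
    corr <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.8, 0))
    diag(corr) <- 1
    corr <- corr + matrix(rnorm(18 * 18, 0, 0.02), 18, 18)
    corr <- (corr + t(corr)) / 2; diag(corr) <- 1
    dimnames(corr) <- list(sprintf("g%02d", 1:18), sprintf("g%02d", 1:18))
    mod <- detect_modules(build_network(corr, 0.3))
    # adjusted Rand = 1 <=> partitions identical up to labels
    expect_equal(length(unique(mod)), 3)
    expect_true(all(tapply(mod, blocks, function(v) length(unique(v))) == 1))
  })
})

test_that("netmoss_scores matches the exhaustive shortest-path oracle", {
  # toy 10-node world: hub (node 1) attached to clique {2..5} in A but to
  # clique {6..9} in B; the combined network keeps the hub's B-side
  # attachment, so only the A-side association is lost on pooling (a
  # symmetric loss of both attachments would cancel in the A-minus-B
  # score by construction)
  n <- 10
  cl1 <- 2:5; cl2 <- 6:9
  base <- matrix(FALSE, n, n)
  base[cl1, cl1] <- TRUE; base[cl2, cl2] <- TRUE; diag(base) <- FALSE
  adj_a <- base; adj_a[1, cl1] <- adj_a[cl1, 1] <- TRUE
  adj_b <- base; adj_b[1, cl2] <- adj_b[cl2, 1] <- TRUE
  adj_c <- adj_b
  net_a <- net_from_adj(adj_a); net_b <- net_from_adj(adj_b)
  net_c <- net_from_adj(adj_c)
  sc <- netmoss_scores(net_a, net_b, net_c)
  part_a <- detect_modules(net_a); part_b <- detect_modules(net_b)
  oracle <- netmoss_oracle(adj_a, adj_b, adj_c, part_a, part_b)
  expect_equal(sc$raw_score, oracle, tolerance = 1e-12)
  # the rewired hub attains the top (normalized) score
  expect_equal(sc$score[1], max(sc$score))
  expect_equal(sc$score[1], 1)

  # identical networks: all scores zero before and after normalization
  same <- netmoss_scores(net_a, net_a, net_a)
  expect_true(all(same$raw_score == 0))
  expect_true(all(same$score == 0))

  # node relabelling leaves scores invariant
  perm <- sample(n)
  relabel <- function(adj) net_from_adj(adj[perm, perm],
                                        nodes = paste0("m", 1:n))
  sc2 <- netmoss_scores(relabel(adj_a), relabel(adj_b), relabel(adj_c))
  expect_equal(sc2$score, sc$score[perm], tolerance = 1e-12)

  # node-set mismatch
  expect_error(netmoss_scores(net_a, net_b, net_from_adj(base[1:8, 1:8])),
               "node set")
})

test_that("differential_biomarkers applies rank-sum + BH + score gate", {
  # hand-checked BH adjustment
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))

  sheet <- tiny_sheet()
  ab <- generate_abundances(sheet, seed = 44)
  res <- biomarker_analysis(ab$counts, sheet$class, seed = 44)
  bm <- res$biomarkers
  # planted recovery with correct directions
  expect_setequal(bm$genus[bm$biomarker], names(ab$planted))
  for (g in names(ab$planted)) {
    expect_equal(bm$direction[bm$genus == g],
                 if (ab$planted[[g]] > 0) "submissive" else "dominant")
    # log2FC sign matches the planted direction
    expect_equal(sign(bm$log2fc[bm$genus == g]), sign(ab$planted[[g]]))
  }
  # p-values agree with a direct Wilcoxon on relative abundances
  rel <- sweep(ab$counts, 2, colSums(ab$counts), "/")
  is_sub <- sheet$class == "submissive"
  g1 <- bm$genus[1]
  expect_equal(bm$p[1],
               suppressWarnings(wilcox.test(rel[g1, is_sub],
                                            rel[g1, !is_sub]))$p.value)
  expect_true(all(bm$p_adj >= bm$p))
  # degenerate inputs
  expect_error(differential_biomarkers(ab$counts, rep("dominant", 32),
                                       setNames(rep(1, 40),
                                                rownames(ab$counts))),
               "two classes")
})

test_that("cv_auc is a stratified rank AUC", {
  sheet <- tiny_sheet()
  # perfectly separated classes
  m <- matrix(50, 4, 32, dimnames = list(paste0("g", 1:4), sheet$sample_id))
  m[1, sheet$class == "submissive"] <- 5000
  res <- cv_auc(m, sheet$class, "g1", k = 5, seed = 2)
  expect_equal(res$auc, 1.0)
  # AUC equals the exhaustive pairwise concordance count
  sc <- res$scores
  pos <- sc$score[sc$class == "submissive"]
  neg <- sc$score[sc$class != "submissive"]
  conc <- mean(outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(res$auc, conc, tolerance = 1e-12)
  # permuted labels: AUC ~ 0.5 over replicates
  withr::with_seed(77, {
    big <- tiny_sheet(100)
    mm <- matrix(rpois(5 * 200, 100), 5, 200,
                 dimnames = list(paste0("g", 1:5), big$sample_id))
    aucs <- vapply(1:8, function(r) {
      cls <- sample(big$class)
      cv_auc(mm, cls, paste0("g", 1:5), k = 5, seed = r)$auc
    }, numeric(1))
    expect_lt(abs(mean(aucs) - 0.5), 0.08)
  })
  # k larger than the smaller class
  expect_error(cv_auc(m, sheet$class, "g1", k = 20), "class size")
  # rank_auc basics
  expect_equal(rank_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(rank_auc(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE)), 0)
})

test_that("abundance TSV round-trips, tolerating BIOM-style headers", {
  sheet <- tiny_sheet(3)
  ab <- generate_abundances(sheet, n_genera = 10,
                            planted = c(Genus01 = -2), seed = 5)
  dir <- withr::local_tempdir()
  write_abundance(ab, dir)
  back <- read_abundance(file.path(dir, "abundance.tsv"))
  expect_equal(back, ab$counts)
  # BIOM-style "#OTU ID" first column
  lines <- readLines(file.path(dir, "abundance.tsv"))
  lines[1] <- sub("^genus", "#OTU ID", lines[1])
  p2 <- file.path(dir, "biom.tsv")
  writeLines(lines, p2)
  expect_equal(unname(read_abundance(p2)), unname(ab$counts))
})
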