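# Compositional co-occurrence network inference (SparCC), module detection
# (topological-overlap clustering), differential-network transition scores
# (NetMoss-style), biomarker calling and cross-validated panel AUC.

#' SparCC basis correlations from compositional counts
#'
#' Estimates correlations between latent absolute abundances from the
#' log-ratio variances `t_ij = var(log(x_i/x_j))` under the standard
#' sparsity approximation: basis variances solve the linear system implied
#' by `t_ij ~ w_i + w_j`, with iterative exclusion of the most strongly
#' correlated pair (above `exclusion_threshold`) from the equations for up
#' to `n_iter` rounds, so that a few strong correlations do not bias the
#' variance estimates. For stability the estimate is averaged over
#' `n_resample` Dirichlet pseudo-replicates of the sample fractions
#' (`Dirichlet(counts + pseudocount)`).
#'
#' @param matrix genera x samples count matrix (raw counts).
#' @param n_iter maximum exclusion rounds (default 20).
#' @param exclusion_threshold |correlation| above which the strongest pair
#'   is excluded from variance estimation (default 0.1).
#' @param seed integer seed.
#' @param n_resample number of Dirichlet pseudo-replicates (default 10).
#' @param pseudocount Dirichlet prior count (default 0.5).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
sparcc_correlations <- function(matrix, n_iter = 20L,
                                exclusion_threshold = 0.1, seed = 1L,
                                n_resample = 10L, pseudocount = 0.5) {
  m <- as_count_matrix(matrix)
  G <- nrow(m)
  if (G < 4) {
    stop_config("SparCC needs >= 4 genera; use a plain log-ratio ",
                "correlation for smaller tables")
  }
  local_seed(seed, {
    acc <- 0
    for (r in seq_len(n_resample)) {
      # posterior fractions per sample
      fr <- apply(m, 2, function(x) {
        g <- rgamma(G, shape = x + pseudocount)
        g / sum(g)
      })
      L <- log(fr)
      C <- cov(t(L))
      v <- diag(C)
      tmat <- outer(v, v, "+") - 2 * C   # t_ij = var(log(x_i/x_j))
      incl <- !diag(G)
      rho <- sparcc_basis(tmat, incl)
      for (it in seq_len(n_iter)) {
        cand <- abs(rho) * incl
        mx <- max(cand)
        if (mx < exclusion_threshold) break
        ij <- which(cand == mx, arr.ind = TRUE)[1, ]
        # exclusion stops once it would leave a genus with < 2 equations
        if (sum(incl[ij[1], ]) <= 2 || sum(incl[ij[2], ]) <= 2) break
        incl[ij[1], ij[2]] <- incl[ij[2], ij[1]] <- FALSE
        rho <- sparcc_basis(tmat, incl)
      }
      acc <- acc + rho
    }
    rho <- acc / n_resample
    rho <- (rho + t(rho)) / 2
    diag(rho) <- 1
    rho[] <- pmin(pmax(rho, -1), 1)
    dimnames(rho) <- list(rownames(m), rownames(m))
    rho
  })
}

# solve the sparsity-approximation linear system for basis variances over
# the included pairs and return the implied correlations
sparcc_basis <- function(tmat, incl = NULL) {
  G <- nrow(tmat)
  if (is.null(incl)) incl <- !diag(G)
  A <- incl * 1
  diag(A) <- rowSums(incl)
  T_i <- rowSums(tmat * incl)
  omega <- tryCatch(solve(A, T_i), error = function(e) rep(mean(T_i) / G, G))
  omega <- pmax(omega, 1e-8)
  rho <- (outer(omega, omega, "+") - tmat) /
    (2 * sqrt(outer(omega, omega)))
  pmin(pmax(rho, -1), 1)
}

#' Build a co-occurrence network from a correlation matrix
#'
#' Edges connect genus pairs with `|r| >= edge_threshold`; isolated nodes
#' are retained.
#'
#' @param corr symmetric correlation matrix.
#' @param edge_threshold absolute-correlation cutoff in (0, 1]; default 0.3.
#' @return a `cooccurrence_network`: list with `nodes`, `corr`, `adjacency`
#'   (logical), `threshold`.
#' @export
build_network <- function(corr, edge_threshold = 0.3) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (edge_threshold <= 0 || edge_threshold > 1) {
    stop_config("edge_threshold must be in (0, 1]")
  }
  adj <- abs(corr) >= edge_threshold
  diag(adj) <- FALSE
  out <- list(nodes = rownames(corr) %||% as.character(seq_len(nrow(corr))),
              corr = corr, adjacency = adj, threshold = edge_threshold)
  class(out) <- "cooccurrence_network"
  out
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("cooccurrence_network:", length(x$nodes), "nodes,",
      sum(x$adjacency) / 2, "edges (|r| >=", x$threshold, ")\n")
  invisible(x)
}

network_graph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency * 1, mode = "undirected",
                                      diag = FALSE)
}

#' Detect modules by topological-overlap clustering
#'
#' The signed adjacency `a_ij = |r_ij|` (restricted to network edges) is
#' turned into a topological overlap matrix; average-linkage hierarchical
#' clustering of the TOM dissimilarity is cut at a fixed height. A pure
#' function of the network: no randomness. Singleton modules are allowed;
#' an edgeless network yields one module per node.
#'
#' @param network a [build_network()] result.
#' @param cut_height dendrogram cut height on TOM dissimilarity
#'   (default 0.8).
#' @return named integer vector: genus -> module id.
#' @export
detect_modules <- function(network, cut_height = 0.8) {
  stopifnot(inherits(network, "cooccurrence_network"))
  n <- length(network$nodes)
  if (n == 1) return(setNames(1L, network$nodes))
  a <- abs(network$corr) * network$adjacency
  diag(a) <- 0
  L <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (L + a) / denom
  diag(tom) <- 1
  diss <- 1 - tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  setNames(as.integer(cl), network$nodes)
}

# mean shortest-path distance from each node to the members of each module;
# unreachable members contribute n_nodes, self excluded
module_distances <- function(graph, partition, n_nodes) {
  d <- igraph::distances(graph)
  d[!is.finite(d)] <- n_nodes
  mods <- sort(unique(partition))
  out <- matrix(0, n_nodes, length(mods),
                dimnames = list(rownames(d), as.character(mods)))
  for (j in seq_along(mods)) {
    members <- which(partition == mods[j])
    for (i in seq_len(n_nodes)) {
      mm <- setdiff(members, i)
      out[i, j] <- if (length(mm)) mean(d[i, mm]) else 0
    }
  }
  out
}

#' NetMoss-style transition scores
#'
#' Scores every genus for its driving force in the transition between the
#' condition-A (dominant) and condition-B (subordinate) networks:
#' `NMSS_i = sum_{j in Neighbors_A(i)} dD_ij - sum_{l in Neighbors_B(i)} dD_il`,
#' where `dD_ij` is the absolute change, between the combined network and
#' the condition network, of the mean shortest-path distance from node i to
#' the members of module j, and `Neighbors_A(i)` are the condition-A modules
#' containing at least one node adjacent to i in A (likewise for B).
#' Unreachable nodes contribute a distance equal to the node count. Raw
#' scores are mapped to [0, 1] by min-max over absolute values.
#'
#' @param net_a,net_b,net_combined [build_network()] results on the same
#'   node set (dominant, subordinate and pooled samples).
#' @param partition_a,partition_b module partitions of the two condition
#'   networks (see [detect_modules()]).
#' @return data.frame with genus, raw_score, score (normalized).
#' @export
netmoss_scores <- function(net_a, net_b, net_combined,
                           partition_a = detect_modules(net_a),
                           partition_b = detect_modules(net_b)) {
  nodes <- net_a$nodes
  if (!identical(nodes, net_b$nodes) || !identical(nodes, net_combined$nodes)) {
    stop_config("networks must share an identical node set")
  }
  n <- length(nodes)
  g_a <- network_graph(net_a)
  g_b <- network_graph(net_b)
  g_c <- network_graph(net_combined)

  d_a <- module_distances(g_a, partition_a, n)
  d_ca <- module_distances(g_c, partition_a, n)
  d_b <- module_distances(g_b, partition_b, n)
  d_cb <- module_distances(g_c, partition_b, n)
  dd_a <- abs(d_ca - d_a)
  dd_b <- abs(d_cb - d_b)

  raw <- vapply(seq_len(n), function(i) {
    nbr_a <- unique(partition_a[net_a$adjacency[i, ]])
    nbr_b <- unique(partition_b[net_b$adjacency[i, ]])
    sa <- if (length(nbr_a)) sum(dd_a[i, as.character(nbr_a)]) else 0
    sb <- if (length(nbr_b)) sum(dd_b[i, as.character(nbr_b)]) else 0
    sa - sb
  }, numeric(1))

  s <- abs(raw)
  rng <- range(s)
  score <- if (diff(rng) < 1e-15) rep(0, n) else (s - rng[1]) / diff(rng)
  data.frame(genus = nodes, raw_score = raw, score = score,
             stringsAsFactors = FALSE)
}

#' Call differential-abundance biomarkers
#'
#' Per genus: a two-sided Wilcoxon rank-sum test on relative abundances
#' between the two classes, Benjamini-Hochberg adjustment, and a biomarker
#' call iff the transition score passes `score_threshold` and the adjusted
#' p-value passes `fdr_threshold`. Direction follows the sign of the median
#' relative-abundance difference; the fold-change is submissive over
#' dominant medians (log2, with a pseudocount of half the smallest nonzero
#' relative abundance).
#'
#' @param matrix genera x samples count matrix (or `abundance_matrix`).
#' @param classes per-sample class vector ("dominant"/"submissive").
#' @param scores a [netmoss_scores()] data.frame, or a named numeric vector
#'   of scores per genus.
#' @param score_threshold minimum transition score (default 0.25).
#' @param fdr_threshold BH-adjusted significance level (default 0.05).
#' @return data.frame: genus, score, log2fc (submissive over dominant), p,
#'   p_adj, direction (dominant/submissive/none), biomarker (logical).
#' @export
differential_biomarkers <- function(matrix, classes, scores,
                                    score_threshold = 0.25,
                                    fdr_threshold = 0.05) {
  m <- as_count_matrix(matrix)
  classes <- as.character(classes)
  if (length(classes) != ncol(m)) {
    stop_config("classes must have one label per sample")
  }
  lv <- unique(classes)
  if (length(lv) != 2) stop_config("exactly two classes required, got ",
                                   length(lv))
  is_sub <- classes == "submissive"
  if (!any(is_sub) || all(is_sub)) {
    stop_config("classes must contain both dominant and submissive samples")
  }
  if (min(sum(is_sub), sum(!is_sub)) < 3) {
    stop_config("need >= 3 samples per class")
  }
  rel <- sweep(m, 2, colSums(m), "/")
  pc <- min(rel[rel > 0]) / 2
  if (is.data.frame(scores)) {
    scores <- setNames(scores$score, scores$genus)
  }
  res <- data.frame(genus = rownames(m), stringsAsFactors = FALSE)
  res$score <- as.numeric(scores[res$genus])
  res$p <- vapply(seq_len(nrow(m)), function(g) {
    suppressWarnings(wilcox.test(rel[g, is_sub], rel[g, !is_sub])$p.value)
  }, numeric(1))
  res$p_adj <- p.adjust(res$p, method = "BH")
  med_sub <- apply(rel[, is_sub, drop = FALSE], 1, median)
  med_dom <- apply(rel[, !is_sub, drop = FALSE], 1, median)
  res$log2fc <- log2((med_sub + pc) / (med_dom + pc))
  pass <- !is.na(res$score) & res$score >= score_threshold &
    res$p_adj < fdr_threshold
  res$direction <- ifelse(!pass | med_sub == med_dom, "none",
                          ifelse(med_sub > med_dom, "submissive", "dominant"))
  res$biomarker <- pass & res$direction != "none"
  res[order(-res$score), ]
}

# ridge-stabilized logistic regression by IRLS; intercept unpenalized
ridge_logistic <- function(X, y, lambda = 1e-3, max_iter = 50) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1)))
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X1 * w)
    new_beta <- solve(XtW %*% X1 + pen, XtW %*% z)
    if (max(abs(new_beta - beta)) < 1e-8) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  drop(beta)
}

#' Rank (Mann-Whitney) AUC
#'
#' Probability that a random positive outscores a random negative, computed
#' from midranks (ties count 1/2).
#'
#' @param scores numeric classifier scores.
#' @param labels logical or 0/1 vector, TRUE/1 = positive.
#' @return AUC in [0, 1].
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop_config("both classes needed for AUC")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Cross-validated AUC of a biomarker panel
#'
#' Stratified k-fold cross-validation of a ridge-stabilized logistic
#' classifier on the log-transformed relative abundances of the biomarker
#' genera; out-of-fold scores are pooled and the AUC computed by the rank
#' formula ("submissive" is the positive class).
#'
#' @param matrix genera x samples count matrix (or `abundance_matrix`).
#' @param classes per-sample class vector.
#' @param biomarkers character vector of genus names (the panel).
#' @param k folds (default 5); must not exceed the smaller class size.
#' @param seed integer seed for the fold split.
#' @return list with `auc` and `scores` (sample_id, class, fold, score).
#' @export
cv_auc <- function(matrix, classes, biomarkers, k = 5L, seed = 1L) {
  m <- as_count_matrix(matrix)
  classes <- as.character(classes)
  missing_bm <- setdiff(biomarkers, rownames(m))
  if (length(missing_bm)) {
    stop_config("biomarkers absent from matrix: ",
                paste(missing_bm, collapse = ", "))
  }
  if (!length(biomarkers)) stop_config("empty biomarker panel")
  y <- classes == "submissive"
  if (k > min(sum(y), sum(!y))) {
    stop_config("k exceeds the smaller class size")
  }
  rel <- sweep(m, 2, colSums(m), "/")
  pc <- min(rel[rel > 0]) / 2
  X <- t(log(rel[biomarkers, , drop = FALSE] + pc))

  local_seed(seed, {
    fold <- integer(length(y))
    for (cl in c(TRUE, FALSE)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    score <- rep(NA_real_, length(y))
    for (f in seq_len(k)) {
      tr <- fold != f
      mu <- colMeans(X[tr, , drop = FALSE])
      sdv <- apply(X[tr, , drop = FALSE], 2, sd)
      sdv[sdv < 1e-12] <- 1
      Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
      beta <- ridge_logistic(Xs[tr, , drop = FALSE], y[tr])
      score[!tr] <- drop(cbind(1, Xs[!tr, , drop = FALSE]) %*% beta)
    }
    list(auc = rank_auc(score, y),
         scores = data.frame(sample_id = colnames(m), class = classes,
                             fold = fold, score = score,
                             stringsAsFactors = FALSE))
  })
}
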