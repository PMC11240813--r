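# shared fixtures, all built in code

tiny_sheet <- function(n_per_class = 16L) {
  data.frame(
    sample_id = sprintf("S%02d", seq_len(2 * n_per_class)),
    animal_id = sprintf("A%02d", seq_len(2 * n_per_class)),
    class = rep(c("dominant", "submissive"), each = n_per_class),
    stringsAsFactors = FALSE)
}

# one bout record as a one-row data.frame
bout_row <- function(a = "x", b = "y", outcome = "decisive", winner = a,
                     confirmed = TRUE, pen = "P1", phase = 1L, day = 1L) {
  data.frame(pen_id = pen, phase = phase, day = day, animal_a = a,
             animal_b = b, outcome = outcome,
             winner = if (outcome == "decisive") winner else NA_character_,
             confirmed = confirmed & outcome == "decisive",
             stringsAsFactors = FALSE)
}

# feeding event with a concrete clock time on a given study day
event_at <- function(animal, day, hhmm, duration_s, intake_g = 100) {
  h <- as.integer(substr(hhmm, 1, 2))
  m <- as.integer(substr(hhmm, 4, 5))
  origin <- as.POSIXct("2022-05-31 00:00:00", tz = "UTC")
  data.frame(animal_id = animal, day = day,
             start_time = origin + day * 86400 + h * 3600 + m * 60,
             duration_s = duration_s, intake_g = intake_g,
             stringsAsFactors = FALSE)
}

# all-pairs shortest paths by Floyd-Warshall on a logical adjacency matrix;
# independent oracle for the igraph-based distances used by the package
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  d
}

# oracle for the transition score on explicit adjacency matrices, computed
# directly from the definition (mean module distances with n-node penalty)
netmoss_oracle <- function(adj_a, adj_b, adj_c, part_a, part_b) {
  n <- nrow(adj_a)
  mod_dist <- function(adj, part) {
    d <- fw_distances(adj)
    d[!is.finite(d)] <- n
    mods <- sort(unique(part))
    out <- matrix(0, n, length(mods))
    for (j in seq_along(mods)) {
      for (i in seq_len(n)) {
        mm <- setdiff(which(part == mods[j]), i)
        out[i, j] <- if (length(mm)) mean(d[i, mm]) else 0
      }
    }
    colnames(out) <- as.character(mods)
    out
  }
  da <- mod_dist(adj_a, part_a); dca <- mod_dist(adj_c, part_a)
  db <- mod_dist(adj_b, part_b); dcb <- mod_dist(adj_c, part_b)
  vapply(seq_len(n), function(i) {
    na_ <- unique(part_a[adj_a[i, ]])
    nb_ <- unique(part_b[adj_b[i, ]])
    sa <- if (length(na_)) sum(abs(dca[i, as.character(na_)] -
                                     da[i, as.character(na_)])) else 0
    sb <- if (length(nb_)) sum(abs(dcb[i, as.character(nb_)] -
                                     db[i, as.character(nb_)])) else 0
    sa - sb
  }, numeric(1))
}

# wrap an adjacency matrix as a cooccurrence_network (unit correlations on
# edges so |r| >= threshold holds)
net_from_adj <- function(adj, nodes = rownames(adj)) {
  if (is.null(nodes)) nodes <- sprintf("n%02d", seq_len(nrow(adj)))
  dimnames(adj) <- list(nodes, nodes)
  corr <- adj * 0.9
  diag(corr) <- 1
  build_network(corr, edge_threshold = 0.5)
}
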