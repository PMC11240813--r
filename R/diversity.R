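# Rarefaction and alpha/beta diversity on genus count tables.
# Counts are genera x samples throughout.

as_count_matrix <- function(x) {
  if (inherits(x, "abundance_matrix")) x$counts else as.matrix(x)
}

#' Rarefy samples to a common depth
#'
#' Each sample is subsampled without replacement to exactly `depth` reads;
#' samples with fewer total reads are dropped with a warning. Reproducible
#' under a fixed seed.
#'
#' @param matrix genera x samples count matrix or `abundance_matrix`.
#' @param depth target depth (default 31731 reads).
#' @param seed integer seed.
#' @return rarefied count matrix (same class as the input counts).
#' @export
rarefy <- function(matrix, depth = 31731L, seed = 1L) {
  if (depth <= 0) stop_config("rarefaction depth must be positive")
  m <- as_count_matrix(matrix)
  tot <- colSums(m)
  drop <- tot < depth
  if (any(drop)) {
    warning("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(colnames(m)[drop], collapse = ", "))
  }
  m <- m[, !drop, drop = FALSE]
  if (ncol(m) == 0) return(m[, 0, drop = FALSE])
  local_seed(seed, {
    out <- vapply(seq_len(ncol(m)), function(j) {
      reads <- rep.int(seq_len(nrow(m)), m[, j])
      tabulate(reads[sample.int(length(reads), depth)], nbins = nrow(m))
    }, integer(nrow(m)))
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Shannon alpha diversity per sample
#'
#' `H = -sum p_i * ln(p_i)` over the nonzero genus proportions of each
#' sample (natural logarithm). All-zero samples get NA with a warning.
#'
#' @param matrix genera x samples count (or proportion) matrix.
#' @return named numeric vector of per-sample indices.
#' @export
shannon_alpha <- function(matrix) {
  m <- as_count_matrix(matrix)
  tot <- colSums(m)
  if (any(tot == 0)) warning("all-zero sample(s) give NA Shannon index")
  h <- apply(m, 2, function(x) {
    s <- sum(x)
    if (s == 0) return(NA_real_)
    p <- x[x > 0] / s
    -sum(p * log(p))
  })
  setNames(as.numeric(h), colnames(m))
}

#' Beta diversity
#'
#' `bray_curtis`: pairwise dissimilarity `sum|x-y| / sum(x+y)` between
#' samples (a `dist` object). `whittaker`: the group-level index
#' `gamma / alpha-bar - 1` on presence/absence, where gamma is the number of
#' genera observed anywhere in the group and alpha-bar the mean per-sample
#' richness (a single number).
#'
#' @param matrix genera x samples count matrix.
#' @param metric "bray_curtis" or "whittaker".
#' @return a `dist` (bray_curtis) or a single numeric (whittaker).
#' @export
beta_diversity <- function(matrix, metric = c("bray_curtis", "whittaker")) {
  metric <- match.arg(metric)
  m <- as_count_matrix(matrix)
  if (ncol(m) < 2) stop_config("beta diversity needs >= 2 samples")
  if (metric == "bray_curtis") {
    n <- ncol(m)
    d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <-
          sum(abs(m[, i] - m[, j])) / sum(m[, i] + m[, j])
      }
    }
    stats::as.dist(d)
  } else {
    pres <- m > 0
    gamma <- sum(rowSums(pres) > 0)
    alpha_bar <- mean(colSums(pres))
    gamma / alpha_bar - 1
  }
}
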