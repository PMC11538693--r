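#' Jaccard similarity of two sets
#'
#' `|U1 n U2| / |U1 u U2|`. Two empty sets are defined as identical
#' (similarity 1, with a warning), so that a method that consistently returns
#' nothing is consistent rather than undefined.
#'
#' @param U1,U2 Vectors treated as sets.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard <- function(U1, U2) {
  U1 <- unique(U1); U2 <- unique(U2)
  if (!length(U1) && !length(U2)) {
    warning("both sets empty; Jaccard defined as 1")
    return(1)
  }
  length(intersect(U1, U2)) / length(union(U1, U2))
}

#' Subsampling reproducibility index
#'
#' Given the per-run, per-class species sets identified on K subsampled
#' datasets, computes the mean pairwise Jaccard similarity within each class
#' (`RJ_c`, over the K(K-1)/2 run pairs) and their average across classes
#' (`RJ`). Higher values mean the identified characteristics are more
#' reproducible under subsampling.
#'
#' @param feature_sets List of length K; each element is a named list of
#'   per-class species vectors (same class names across runs).
#' @return Object of class `"reproducibility_result"`: list with `RJ`,
#'   per-class `RJ_c`, the pairwise values, and `K`.
#' @export
reproducibility_index <- function(feature_sets) {
  K <- length(feature_sets)
  if (K < 2L) stop("need at least 2 runs (K >= 2)")
  classes <- names(feature_sets[[1L]])
  if (is.null(classes)) stop("per-run sets must be named by class")
  for (fs in feature_sets)
    if (!identical(sort(names(fs)), sort(classes)))
      stop("class names differ across runs")
  pairs <- utils::combn(K, 2L)
  pairwise <- sapply(classes, function(cl)
    apply(pairs, 2L, function(ij)
      suppressWarnings(jaccard(feature_sets[[ij[1L]]][[cl]],
                               feature_sets[[ij[2L]]][[cl]]))),
    simplify = FALSE)
  RJ_c <- vapply(pairwise, mean, 0)
  structure(list(RJ = mean(RJ_c), RJ_c = RJ_c, pairwise = pairwise, K = K),
            class = "reproducibility_result")
}

#' @export
print.reproducibility_result <- function(x, ...) {
  cat(sprintf("Reproducibility over %d runs: RJ = %.4f\n", x$K, x$RJ))
  print(round(x$RJ_c, 4))
  invisible(x)
}

#' Stratified subsampling reproducibility experiment
#'
#' Draws K stratified subsamples of the study (per-class counts rounded to
#' `round(r * U_c)`, minimum one sample per class), applies an
#' identification method to each, and aggregates the per-class Jaccard
#' similarities into the reproducibility index.
#'
#' @param A Species x sample abundance matrix.
#' @param labels A `"sample_labels"` aligned to `colnames(A)`.
#' @param method Callable `(A_sub, labels_sub, run)` returning a named list
#'   of per-class species vectors (e.g. a wrapper over [hgt_fit()] +
#'   [communities()]).
#' @param r Subsample fraction in (0, 1]; default 0.9.
#' @param K Number of repeats; default 50.
#' @param seed RNG seed for the subsample draws.
#' @return A `"reproducibility_result"` with the subsampling settings
#'   attached.
#' @export
subsample_experiment <- function(A, labels, method, r = 0.9, K = 50L,
                                 seed = 1L) {
  if (r <= 0 || r > 1) stop("r must be in (0, 1]")
  if (K < 2L) stop("K must be >= 2")
  cls <- factor(labels$labels, levels = labels$classes)
  U <- table(cls)
  take <- stats::setNames(pmax(1L, as.integer(round(r * U))), names(U))
  if (any(take < 2L) && r * min(U) < 2)
    stop("r too small: a class would keep fewer than 2 samples")
  set.seed(seed)
  sets <- vector("list", K)
  for (kk in seq_len(K)) {
    idx <- unlist(lapply(labels$classes, function(cl) {
      pool <- which(cls == cl)
      sort(sample(pool, take[[cl]]))
    }), use.names = FALSE)
    A_sub <- A[, idx, drop = FALSE]
    lab_sub <- encode_labels(stats::setNames(labels$labels[idx],
                                             labels$sample_ids[idx]),
                             classes = labels$classes)
    sets[[kk]] <- method(A_sub, lab_sub, kk)
  }
  out <- reproducibility_index(sets)
  out$r <- r
  out$seed <- seed
  out
}

#' Attention-rank distribution of species within a class
#'
#' For every sample of the class and every head, species are ranked by their
#' attention to the sample (rank 1 = highest attention; ties get average
#' ranks; species without an edge count as zero attention). Each
#' (species, sample) pair is then represented by its best rank across heads —
#' the head where the species matters most — and each species' collection of
#' representative ranks over the class's samples is returned.
#'
#' @param attention An [attention_tensor()].
#' @param labels A `"sample_labels"` aligned to the tensor's samples.
#' @param class Class name whose samples are ranked.
#' @param representative `"best"` (default, numerically smallest rank across
#'   heads) or `"worst"` (largest).
#' @return Object of class `"rank_distribution"`: list with the M x n_c
#'   matrix `ranks` (species x class samples) and the class label.
#' @export
attention_rank_distribution <- function(attention, labels, class,
                                        representative = c("best", "worst")) {
  representative <- match.arg(representative)
  stopifnot(class %in% labels$classes)
  idx <- which(labels$labels == class)
  if (!length(idx)) stop("class has no samples: ", class)
  M <- length(attention$species_ids)
  ranks <- matrix(NA_real_, M, length(idx),
                  dimnames = list(attention$species_ids,
                                  labels$sample_ids[idx]))
  for (jj in seq_along(idx)) {
    j <- idx[jj]
    rows <- attention$edges[, 2L] == j
    av <- matrix(0, M, attention$h)
    av[attention$edges[rows, 1L], ] <- attention$values[rows, , drop = FALSE]
    rk <- apply(av, 2L, function(v) rank(-v, ties.method = "average"))
    ranks[, jj] <- if (representative == "best")
      do.call(pmin, as.data.frame(rk)) else do.call(pmax, as.data.frame(rk))
  }
  structure(list(ranks = ranks, class = class,
                 representative = representative),
            class = "rank_distribution")
}

#' One-dimensional Wasserstein-1 distance
#'
#' Earth-mover distance between the empirical distributions of two real
#' sample collections, via the closed form: the integral of the absolute
#' difference of quantile functions. For equal-sized collections this is the
#' mean absolute difference of the sorted values.
#'
#' @param x,y Non-empty numeric vectors.
#' @return Non-negative distance; 0 iff the multisets coincide (equal sizes).
#' @export
wasserstein_1d <- function(x, y) {
  if (!length(x) || !length(y)) stop("both collections must be non-empty")
  m <- length(x); n <- length(y)
  x <- sort(x); y <- sort(y)
  if (m == n) return(mean(abs(x - y)))
  # integrate |F_x^{-1}(u) - F_y^{-1}(u)| over the union of probability breaks
  u <- sort(unique(c(seq_len(m) / m, seq_len(n) / n)))
  lo <- c(0, u[-length(u)])
  qx <- x[ceiling(u * m - 1e-12)]
  qy <- y[ceiling(u * n - 1e-12)]
  sum((u - lo) * abs(qx - qy))
}

#' Concordance of a rank profile with the identity line
#'
#' Goodness of fit of `y` against the fixed line `y = x`:
#' `1 - sum((y - x)^2) / sum((y - mean(y))^2)`. Unlike a fitted regression
#' this can be negative when agreement is worse than the constant predictor.
#'
#' @param x,y Equal-length numeric vectors (length >= 2); `y` must have
#'   non-zero variance.
#' @return The concordance R-squared.
#' @export
rank_fit_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  ssy <- sum((y - mean(y))^2)
  if (ssy == 0) stop("y has zero variance")
  1 - sum((y - x)^2) / ssy
}
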