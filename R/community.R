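#' Per-head, per-sample attention thresholds
#'
#' For each head k and sample j, the non-zero attention values of all species
#' to that sample are trimmed to their interquartile band (Q1 to Q3
#' inclusive, quartiles by linear interpolation, R's default type 7), and the
#' threshold is `mean + z_alpha * sd` of the retained values. Trimming to the
#' quartile band mitigates the influence of outlying attention values. The
#' standard deviation uses the n-1 denominator and is 0 for a single value.
#'
#' @param attention An [attention_tensor()].
#' @param z_alpha Confidence multiplier; default 1.96.
#' @param quartile_type Quantile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return Object of class `"threshold_set"`: list with the h x N matrix
#'   `thr`, the band statistics, and the parameters used.
#' @export
compute_thresholds <- function(attention, z_alpha = 1.96, quartile_type = 7) {
  stopifnot(inherits(attention, "attention_tensor"))
  h <- attention$h
  N <- length(attention$sample_ids)
  thr <- matrix(NA_real_, h, N, dimnames = list(NULL, attention$sample_ids))
  band_mean <- thr; band_sd <- thr; band_n <- thr
  by_sample <- split(seq_len(nrow(attention$edges)), attention$edges[, 2L])
  for (jc in names(by_sample)) {
    j <- as.integer(jc)
    rows <- by_sample[[jc]]
    for (k in seq_len(h)) {
      v <- attention$values[rows, k]
      v <- v[v > 0]
      if (!length(v)) next
      q <- stats::quantile(v, c(0.25, 0.75), type = quartile_type, names = FALSE)
      band <- v[v >= q[1L] & v <= q[2L]]
      s <- if (length(band) > 1L) stats::sd(band) else 0
      band_mean[k, j] <- mean(band)
      band_sd[k, j] <- s
      band_n[k, j] <- length(band)
      thr[k, j] <- mean(band) + z_alpha * s
    }
  }
  und <- colSums(is.na(thr)) > 0
  if (any(und))
    warning("threshold undefined (no non-zero attention) for ",
            sum(und), " sample/head combination(s)")
  structure(list(thr = thr, band_mean = band_mean, band_sd = band_sd,
                 band_n = band_n, z_alpha = z_alpha,
                 quartile_type = quartile_type),
            class = "threshold_set")
}

#' Call high-contribution species per sample
#'
#' Species i is a high-contribution species for sample j when its attention
#' exceeds the threshold `thr[k, j]` strictly in at least one head (OR over
#' heads). Species with zero attention to a sample are never called.
#'
#' @param attention An [attention_tensor()].
#' @param thr A `"threshold_set"` from [compute_thresholds()].
#' @return Binary M x N matrix (species x samples).
#' @export
call_high_contribution <- function(attention, thr) {
  stopifnot(inherits(thr, "threshold_set"))
  M <- length(attention$species_ids); N <- length(attention$sample_ids)
  contrib <- matrix(0L, M, N,
                    dimnames = list(attention$species_ids, attention$sample_ids))
  tj <- t(thr$thr)[attention$edges[, 2L], , drop = FALSE]  # n_e x h
  hit <- rowSums(attention$values > tj, na.rm = TRUE) > 0
  contrib[attention$edges[hit, , drop = FALSE]] <- 1L
  contrib
}

#' Count per-class species contributions
#'
#' @param contrib Binary species x sample matrix from
#'   [call_high_contribution()].
#' @param labels A `"sample_labels"` aligned to the columns of `contrib`.
#' @return List with `T` (C x M counts of class samples each species
#'   contributes to), `U` (class sizes), and `S_max`/`S_min` (largest and
#'   smallest per-sample contributing-species set within each class).
#' @export
count_contributions <- function(contrib, labels) {
  stopifnot(ncol(contrib) == length(labels$sample_ids))
  cls <- factor(labels$labels, levels = labels$classes)
  U <- as.integer(table(cls))
  if (any(U == 0)) stop("class with zero samples: ",
                        paste(labels$classes[U == 0], collapse = ", "))
  Tm <- t(rowsum(t(contrib), cls))                 # M x C
  per_sample <- colSums(contrib)
  S_max <- as.integer(tapply(per_sample, cls, max))
  S_min <- as.integer(tapply(per_sample, cls, min))
  list(T = t(Tm), U = stats::setNames(U, labels$classes),
       S_max = stats::setNames(S_max, labels$classes),
       S_min = stats::setNames(S_min, labels$classes))
}

#' Binomial tail probability for class association
#'
#' Approximate probability of a species contributing to at least `T_ci` of
#' the `U_c` samples of a class by chance alone, given that a sample's
#' contributing set has between `S_min` and `S_max` of the `M` species:
#' `P = sum_{t=T}^{U} C(U,t) (S_max/M)^t ((M - S_min)/M)^(U-t)`, using the
#' ratios `C(M-1,S-1)/C(M,S) = S/M` and `C(M-1,S)/C(M,S) = (M-S)/M`. Because
#' the success and failure probabilities come from different set sizes, the
#' terms need not sum to 1; the result is computed in log space and clamped
#' to `[0, 1]` (a warning is raised when clamping is triggered by
#' `S_max != S_min`).
#'
#' @param T_ci Number of class samples the species contributes to (may be a
#'   vector).
#' @param U_c Number of samples in the class.
#' @param M Total number of species.
#' @param S_max,S_min Largest / smallest per-sample contributing-set size in
#'   the class.
#' @return Tail probability in `[0, 1]`, vectorised over `T_ci`.
#' @export
species_pvalue <- function(T_ci, U_c, M, S_max, S_min) {
  if (S_min > S_max) stop("S_min must not exceed S_max")
  stopifnot(all(T_ci >= 0), all(T_ci <= U_c), S_max <= M, S_min >= 0)
  lp <- log(S_max / M)                   # log success prob (may be 0 -> -Inf ok)
  lq <- log((M - S_min) / M)
  t_all <- 0:U_c
  # 0 * log(0) counts as 0 (the factor is absent, x^0 = 1)
  lterm <- lchoose(U_c, t_all) +
    ifelse(t_all == 0L, 0, t_all * lp) +
    ifelse(t_all == U_c, 0, (U_c - t_all) * lq)
  logsum_from <- function(Tval) {
    lt <- lterm[t_all >= Tval]
    lt <- lt[is.finite(lt)]
    if (!length(lt)) return(-Inf)
    mx <- max(lt)
    mx + log(sum(exp(lt - mx)))
  }
  raw <- exp(vapply(T_ci, logsum_from, 0))
  if (any(raw > 1 + 1e-12) && S_max != S_min)
    warning("tail sum exceeded 1 (S_max != S_min); clamped to 1")
  pmin(pmax(raw, 0), 1)
}

#' Calibrate the threshold confidence multiplier to a target call rate
#'
#' The quartile-band threshold of [compute_thresholds()] sits at a fixed
#' percentile of each sample's attention distribution for any small
#' `z_alpha` (roughly `mean + 0.6 * sd` of the interquartile band lies near
#' the third quartile), so with a fixed multiplier about a quarter of a
#' sample's species exceed it in every head regardless of the data. On
#' densely observed matrices this floods the per-class tail test. This
#' function picks the smallest multiplier from a grid such that the average
#' fraction of species called high-contribution per sample (OR over heads)
#' is at most `target`, using only the attention tensor — no labels or
#' ground truth.
#'
#' @param attention An [attention_tensor()].
#' @param target Maximum average per-sample call fraction; default 0.1.
#' @param grid Candidate multipliers, tried in order.
#' @return The selected `z_alpha` (the grid maximum if none meets `target`).
#' @export
calibrate_z_alpha <- function(attention, target = 0.1,
                              grid = c(1.96, 2.5, 3, 4, 5, 6, 8, 10, 15, 20)) {
  M <- length(attention$species_ids)
  for (z in grid) {
    thr <- compute_thresholds(attention, z)
    rate <- mean(colSums(call_high_contribution(attention, thr)) / M)
    if (rate <= target) return(z)
  }
  grid[length(grid)]
}

#' Multiple-testing adjustment of community p-values
#'
#' `"bh"` applies Benjamini-Hochberg within each class over the candidate
#' species; `"none"` passes raw p-values through.
#'
#' @param pvals Numeric vector (one class's candidates) or matrix (classes x
#'   species; adjustment is per row).
#' @param method `"bh"` or `"none"`.
#' @return Adjusted values, same shape as `pvals`.
#' @export
adjust_pvalues <- function(pvals, method = c("bh", "none")) {
  method <- match.arg(method)
  if (method == "none") return(pvals)
  if (is.matrix(pvals)) t(apply(pvals, 1L, stats::p.adjust, method = "BH"))
  else stats::p.adjust(pvals, method = "BH")
}

#' Infer class-associated microbial communities from attention
#'
#' Runs the full inference chain: per-head/per-sample thresholds, the OR-rule
#' high-contribution calls, per-class contribution counts, the binomial tail
#' probability for each candidate species (those contributing to at least one
#' class sample), multiple-testing adjustment, and the significance cutoff.
#'
#' @param x An `"hgt_fit"` or an [attention_tensor()].
#' @param labels Required when `x` is an attention tensor; ignored (taken
#'   from the fit) otherwise.
#' @param z_alpha Threshold confidence multiplier: a number, or `"auto"`
#'   (default) to calibrate it to a bounded per-sample call rate with
#'   [calibrate_z_alpha()].
#' @param cutoff Significance cutoff on adjusted p-values; default 0.05.
#' @param adjust Adjustment method, `"bh"` (default) or `"none"`.
#' @param quartile_type Quartile convention for [compute_thresholds()].
#' @param ... Unused.
#' @return Object of class `"community_result"`: per class a data frame with
#'   `species_id`, `T` (contribution count), `U`, `p_raw`, `p_adjusted`,
#'   sorted by p then T descending; plus the count tables and thresholds.
#' @export
communities <- function(x, ...) UseMethod("communities")

#' @rdname communities
#' @export
communities.hgt_fit <- function(x, z_alpha = "auto", cutoff = 0.05,
                                adjust = c("bh", "none"), quartile_type = 7, ...) {
  communities.attention_tensor(x$attention, labels = x$labels,
                               z_alpha = z_alpha, cutoff = cutoff,
                               adjust = adjust, quartile_type = quartile_type)
}

#' @rdname communities
#' @export
communities.attention_tensor <- function(x, labels, z_alpha = "auto",
                                         cutoff = 0.05,
                                         adjust = c("bh", "none"),
                                         quartile_type = 7, ...) {
  adjust <- match.arg(adjust)
  if (identical(z_alpha, "auto")) z_alpha <- calibrate_z_alpha(x)
  thr <- compute_thresholds(x, z_alpha, quartile_type)
  contrib <- call_high_contribution(x, thr)
  cnt <- count_contributions(contrib, labels)
  classes <- labels$classes
  M <- length(x$species_ids)
  res <- stats::setNames(vector("list", length(classes)), classes)
  pmat <- matrix(NA_real_, length(classes), M,
                 dimnames = list(classes, x$species_ids))
  amat <- pmat
  for (c in seq_along(classes)) {
    cand <- which(cnt$T[c, ] >= 1L)
    if (!length(cand)) {
      res[[c]] <- data.frame(species_id = character(), T = integer(),
                             U = integer(), p_raw = numeric(),
                             p_adjusted = numeric())
      next
    }
    p <- species_pvalue(cnt$T[c, cand], cnt$U[c], M,
                        cnt$S_max[c], cnt$S_min[c])
    padj <- adjust_pvalues(p, adjust)
    pmat[c, cand] <- p
    amat[c, cand] <- padj
    keep <- padj < cutoff
    df <- data.frame(species_id = x$species_ids[cand][keep],
                     T = unname(cnt$T[c, cand][keep]),
                     U = rep(unname(cnt$U[c]), sum(keep)),
                     p_raw = unname(p[keep]),
                     p_adjusted = unname(padj[keep]),
                     stringsAsFactors = FALSE)
    res[[c]] <- df[order(df$p_adjusted, df$p_raw, -df$T), , drop = FALSE]
  }
  structure(list(communities = res, counts = cnt, thresholds = thr,
                 contrib = contrib, pvals = pmat, pvals_adjusted = amat,
                 cutoff = cutoff, adjust = adjust, z_alpha = z_alpha),
            class = "community_result")
}

#' @export
print.community_result <- function(x, ...) {
  cat("Class-associated microbial communities (adjusted p <",
      x$cutoff, ", method:", x$adjust, ")\n")
  for (cl in names(x$communities)) {
    df <- x$communities[[cl]]
    cat(sprintf("  %s: %d species\n", cl, nrow(df)))
    if (nrow(df)) {
      shown <- utils::head(df$species_id, 8L)
      cat("    ", paste(shown, collapse = ", "),
          if (nrow(df) > 8L) ", ..." else "", "\n", sep = "")
    }
  }
  invisible(x)
}

#' Community member sets
#'
#' @param x A `"community_result"`.
#' @return Named list of character vectors (species per class).
#' @export
community_sets <- function(x) {
  stopifnot(inherits(x, "community_result"))
  lapply(x$communities, function(df) df$species_id)
}

#' Write community inference results as TSVs
#'
#' One file per class plus a combined long-format table and the threshold
#' diagnostics.
#'
#' @param x A `"community_result"`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_communities <- function(x, dir) {
  stopifnot(inherits(x, "community_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all <- list()
  for (cl in names(x$communities)) {
    df <- x$communities[[cl]]
    utils::write.table(df, file.path(dir, paste0("community_", cl, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(df)) all[[cl]] <- cbind(class = cl, df)
  }
  comb <- if (length(all)) do.call(rbind, all) else
    data.frame(class = character(), species_id = character(), T = integer(),
               U = integer(), p_raw = numeric(), p_adjusted = numeric())
  utils::write.table(comb, file.path(dir, "communities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  th <- x$thresholds
  diag_df <- data.frame(head = rep(seq_len(nrow(th$thr)), ncol(th$thr)),
                        sample_id = rep(colnames(th$thr), each = nrow(th$thr)),
                        band_mean = as.vector(th$band_mean),
                        band_sd = as.vector(th$band_sd),
                        thr = as.vector(th$thr))
  utils::write.table(diag_df, file.path(dir, "thresholds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
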