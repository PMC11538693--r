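#' Specification of a synthetic microbiome study
#'
#' Defines the conditions the generator emulates: sparse compositional
#' abundance profiles over C classes, each with a planted community of
#' class-elevated species, block genus structure, and compound-mediated
#' metabolic links among planted within-class pairs.
#'
#' @param M Number of species; default 200.
#' @param N Number of samples; default 120.
#' @param C Number of classes; default 3.
#' @param community_size Planted species per class; default 15. Communities
#'   are disjoint unless `overlap > 0`.
#' @param effect Multiplicative abundance elevation of planted species in
#'   samples of their class (> 1); default 20.
#' @param sparsity Zero-inflation probability in `[0, 1)`; default 0.3.
#' @param genus_size Species per genus (consecutive blocks); default 5.
#' @param compound_link_prob Probability that a planted within-class species
#'   pair shares a compound (metabolic link); default 0.5.
#' @param overlap Number of species shared between consecutive planted
#'   communities (default 0, disjoint).
#' @param baseline `"lognormal"` (default) or `"dirichlet"` baseline
#'   abundance model.
#' @param seed RNG seed; the dataset is fully reproducible from the spec.
#' @return List of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(M = 200L, N = 120L, C = 3L, community_size = 15L,
                           effect = 20, sparsity = 0.3, genus_size = 5L,
                           compound_link_prob = 0.5, overlap = 0L,
                           baseline = c("lognormal", "dirichlet"), seed = 1L) {
  M <- as.integer(M); N <- as.integer(N); C <- as.integer(C)
  community_size <- as.integer(community_size)
  if (C * community_size - (C - 1L) * overlap > M)
    stop("infeasible spec: planted communities exceed the species pool")
  if (effect <= 1) stop("effect must be > 1")
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must be in [0, 1)")
  structure(list(M = M, N = N, C = C, community_size = community_size,
                 effect = effect, sparsity = sparsity,
                 genus_size = as.integer(genus_size),
                 compound_link_prob = compound_link_prob,
                 overlap = as.integer(overlap),
                 baseline = match.arg(baseline), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic microbiome dataset with planted communities
#'
#' Baseline abundances are drawn log-normally with a species-specific
#' location, multiplied by `effect` for planted species in samples of their
#' class, zeroed independently with probability `sparsity`, and column-
#' renormalised to relative abundance. Genera are consecutive blocks of
#' `genus_size` species; the compound table links planted within-class pairs
#' with probability `compound_link_prob`, drawing at random either a shared
#' consumed compound (competition) or a producer/consumer pair
#' (complementarity).
#'
#' @param spec A [synthetic_spec()].
#' @return Object of class `"synthetic_dataset"`: list with `abundance`
#'   (species x sample relative-abundance matrix), `labels`
#'   (`"sample_labels"`), `truth` (named list of planted species per class),
#'   `compound_table`, `taxonomy`, and the `spec`.
#' @export
simulate_microbiome <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  M <- spec$M; N <- spec$N; C <- spec$C
  species <- sprintf("s%03d", seq_len(M))
  samples <- sprintf("p%03d", seq_len(N))
  classes <- sprintf("class%d", seq_len(C))
  lab <- classes[(seq_len(N) - 1L) %% C + 1L]

  step <- spec$community_size - spec$overlap
  truth <- stats::setNames(lapply(seq_len(C), function(c)
    species[(c - 1L) * step + seq_len(spec$community_size)]), classes)

  loc <- stats::rnorm(M, mean = 0, sd = 1)
  X <- if (spec$baseline == "lognormal") {
    matrix(stats::rlnorm(M * N, meanlog = rep(loc, N), sdlog = 1), M, N)
  } else {
    g <- matrix(stats::rgamma(M * N, shape = exp(loc / 2)), M, N)
    sweep(g, 2L, colSums(g), "/") * M
  }
  for (c in seq_len(C)) {
    rows <- match(truth[[c]], species)
    cols <- which(lab == classes[c])
    X[rows, cols] <- X[rows, cols] * spec$effect
  }
  if (spec$sparsity > 0) {
    X[matrix(stats::runif(M * N) < spec$sparsity, M, N)] <- 0
  }
  cs <- colSums(X)
  if (any(cs == 0)) stop("a generated sample lost all species; lower sparsity")
  X <- sweep(X, 2L, cs, "/")
  dimnames(X) <- list(species, samples)

  taxonomy <- data.frame(
    species_id = species,
    genus_id = sprintf("g%03d", (seq_len(M) - 1L) %/% spec$genus_size + 1L),
    stringsAsFactors = FALSE)

  recs <- list()
  cid <- 0L
  for (c in seq_len(C)) {
    mem <- truth[[c]]
    if (length(mem) < 2L) next
    pr <- utils::combn(mem, 2L)
    linked <- stats::runif(ncol(pr)) < spec$compound_link_prob
    for (e in which(linked)) {
      cid <- cid + 1L
      comp <- sprintf("c%04d", cid)
      if (stats::runif(1) < 0.5) {           # competition: both consume
        recs[[length(recs) + 1L]] <- data.frame(
          species_id = pr[, e], compound_id = comp,
          direction = "consume", stringsAsFactors = FALSE)
      } else {                               # complementarity
        roles <- sample(c("produce", "consume"))
        recs[[length(recs) + 1L]] <- data.frame(
          species_id = pr[, e], compound_id = comp,
          direction = roles, stringsAsFactors = FALSE)
      }
    }
  }
  compound_table <- if (length(recs)) do.call(rbind, recs) else
    data.frame(species_id = character(), compound_id = character(),
               direction = character(), stringsAsFactors = FALSE)

  structure(list(abundance = X,
                 labels = encode_labels(stats::setNames(lab, samples),
                                        classes = classes),
                 truth = truth, compound_table = compound_table,
                 taxonomy = taxonomy, spec = spec),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Synthetic microbiome dataset: %d species x %d samples, %d classes\n",
              s$M, s$N, s$C))
  cat(sprintf("  planted: %d species/class, effect %gx, sparsity %.2f, seed %d\n",
              s$community_size, s$effect, s$sparsity, s$seed))
  invisible(x)
}

#' Write a synthetic dataset as TSVs plus a truth file
#'
#' @param x A `"synthetic_dataset"`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance(x$abundance, file.path(dir, "abundance.tsv"))
  utils::write.table(data.frame(sample_id = x$labels$sample_ids,
                                label = x$labels$labels),
                     file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$compound_table, file.path(dir, "compounds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$taxonomy, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth_lines <- vapply(names(x$truth), function(cl)
    paste0(cl, "\t", paste(x$truth[[cl]], collapse = ",")), "")
  writeLines(c("class\tspecies", truth_lines), file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Exchangeable null attention tensor
#'
#' Draws i.i.d. positive attention values for every (head, species, sample)
#' triple and normalises per head and sample so each sample's attention sums
#' to 1 — the null under which no species is preferentially attended. Used
#' for threshold and p-value calibration.
#'
#' @param M,N Species and sample counts.
#' @param h Number of heads; default 8.
#' @param seed RNG seed.
#' @return An [attention_tensor()] with all M x N edges.
#' @export
null_attention <- function(M, N, h = 8L, seed = 1L) {
  set.seed(seed)
  vals <- matrix(stats::rgamma(M * N * h, shape = 1), M * N, h)
  edges <- cbind(rep(seq_len(M), N), rep(seq_len(N), each = M))
  for (k in seq_len(h)) {
    sums <- rowsum(vals[, k], edges[, 2L])
    vals[, k] <- vals[, k] / sums[edges[, 2L]]
  }
  attention_tensor(sprintf("s%03d", seq_len(M)), sprintf("p%03d", seq_len(N)),
                   edges, vals, layer = "null")
}
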