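# Shared fixtures built in code. The trained toy fit is memoised so several
# test files can reuse one (cheap) training run.

.fixture_env <- new.env(parent = emptyenv())

toy_abundance <- function() {
  A <- matrix(c(1, 0, 2, 3, 0, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("p1", "p2")))
  A
}

random_abundance <- function(M, N, sparsity = 0.3, seed = 1) {
  set.seed(seed)
  A <- matrix(stats::rlnorm(M * N), M, N,
              dimnames = list(sprintf("s%02d", 1:M), sprintf("p%02d", 1:N)))
  A[matrix(stats::runif(M * N) < sparsity, M, N)] <- 0
  # keep every column non-empty
  for (j in which(colSums(A) == 0)) A[sample(M, 1), j] <- stats::rlnorm(1)
  A
}

small_sim <- function(seed = 1) {
  simulate_microbiome(synthetic_spec(M = 40, N = 30, C = 2,
                                     community_size = 6, effect = 20,
                                     sparsity = 0.2, genus_size = 4,
                                     seed = seed))
}

# One small trained model shared across test files.
toy_fit <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  sim <- small_sim(seed = 7)
  D1 <- metabolic_relations(sim$compound_table, rownames(sim$abundance))
  D2 <- phylogenetic_relations(sim$taxonomy, rownames(sim$abundance))
  ctl <- hgt_control(d = 16, h = 4, L = 2, epochs = 120, ae_epochs = 80,
                     seed = 1)
  fit <- hgt_fit(sim$abundance, sim$labels, D1, D2, control = ctl)
  .fixture_env$fit <- fit
  .fixture_env$sim <- sim
  fit
}

toy_fit_sim <- function() {
  toy_fit()
  .fixture_env$sim
}

# Reference-scale recovery study (generator defaults, seeds 1:3), memoised.
# Returns per-seed accuracy, per-class Jaccard against the planted truth,
# and a pooled Mann-Whitney p-value for planted-vs-other attention ranks.
full_scale_study <- function(epochs = 400) {
  if (!is.null(.fixture_env$study)) return(.fixture_env$study)
  seeds <- 1:3
  acc <- numeric(length(seeds))
  jac <- NULL
  wilcox_p <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    sim <- simulate_microbiome(synthetic_spec(seed = seeds[i]))
    D1 <- metabolic_relations(sim$compound_table, rownames(sim$abundance))
    D2 <- phylogenetic_relations(sim$taxonomy, rownames(sim$abundance))
    fit <- hgt_fit(sim$abundance, sim$labels, D1, D2,
                   control = hgt_control(epochs = epochs, seed = seeds[i]))
    acc[i] <- fit$accuracy
    comm <- suppressWarnings(communities(fit))
    cs <- community_sets(comm)
    jac <- rbind(jac, sapply(names(sim$truth), function(cl)
      jaccard(cs[[cl]], sim$truth[[cl]])))
    # pooled planted vs non-planted representative ranks across classes
    pl <- NULL; ot <- NULL
    for (cl in names(sim$truth)) {
      rd <- attention_rank_distribution(fit$attention, fit$labels, cl)
      planted <- rownames(rd$ranks) %in% sim$truth[[cl]]
      pl <- c(pl, rowMeans(rd$ranks[planted, , drop = FALSE]))
      ot <- c(ot, rowMeans(rd$ranks[!planted, , drop = FALSE]))
    }
    wilcox_p[i] <- stats::wilcox.test(pl, ot, alternative = "less")$p.value
  }
  .fixture_env$study <- list(accuracy = acc, jaccard = jac,
                             wilcox_p = wilcox_p)
  .fixture_env$study
}

# Direct evaluation of the tail sum with explicit choose() ratios, all T at once.
pvalue_choose_oracle <- function(U, M, Smax, Smin) {
  t <- 0:U
  term <- choose(U, t) * (choose(M - 1, Smax - 1) / choose(M, Smax))^t *
    (choose(M - 1, Smin) / choose(M, Smin))^(U - t)
  pmin(1, rev(cumsum(rev(term))))
}

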