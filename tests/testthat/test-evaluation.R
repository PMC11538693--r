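test_that("Jaccard handles the standard and degenerate cases", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_warning(j <- jaccard(character(), character()), "empty")
  expect_equal(j, 1)
})

test_that("reproducibility index averages pairwise Jaccard per class", {
  runs <- list(list(a = c("x", "y"), b = "z"),
               list(a = c("y", "w"), b = "z"))
  res <- reproducibility_index(runs)
  expect_equal(unname(res$RJ_c["a"]), 1 / 3)
  expect_equal(unname(res$RJ_c["b"]), 1)
  expect_equal(res$RJ, mean(c(1 / 3, 1)))
  # identical runs give RJ = 1; K = 3 gives 3 pairwise values per class
  runs3 <- rep(list(list(a = c("x", "y"))), 3)
  res3 <- reproducibility_index(runs3)
  expect_equal(res3$RJ, 1)
  expect_length(res3$pairwise$a, 3)
  expect_error(reproducibility_index(runs[1]), "K >= 2")
  # invariant to run order
  set.seed(8)
  runs_r <- lapply(1:4, function(i) list(a = sample(letters, 6)))
  expect_equal(reproducibility_index(runs_r)$RJ,
               reproducibility_index(rev(runs_r))$RJ)
})

test_that("stratified subsampling keeps class proportions and is seeded", {
  A <- random_abundance(15, 40, seed = 2)
  lab <- encode_labels(stats::setNames(rep(c("a", "b"), c(30, 10)),
                                       colnames(A)))
  seen <- list()
  method <- function(A_sub, lab_sub, run) {
    counts <- table(lab_sub$labels)
    seen[[length(seen) + 1]] <<- counts
    list(a = "s01", b = "s02")     # deterministic plug-in
  }
  res <- subsample_experiment(A, lab, method, r = 0.9, K = 3, seed = 5)
  expect_equal(res$RJ, 1)           # deterministic method reproduces exactly
  for (ct in seen) {
    expect_equal(unname(ct["a"]), round(0.9 * 30))
    expect_equal(unname(ct["b"]), round(0.9 * 10))
  }
  expect_error(subsample_experiment(A, lab, method, r = 1.2, K = 3), "r must")
})

test_that("random feature sets reproduce the expected chance-level Jaccard", {
  # two random 10-of-100 subsets: E|intersection| = 1, E[Jaccard] ~ 1/19
  pool <- sprintf("s%03d", 1:100)
  set.seed(33)
  method <- function(A_sub, lab_sub, run) list(a = sample(pool, 10))
  A <- random_abundance(5, 30, seed = 1)
  lab <- encode_labels(stats::setNames(rep("a", 30), colnames(A)))
  res <- subsample_experiment(A, lab, method, r = 0.9, K = 30, seed = 1)
  vals <- res$pairwise$a
  se <- stats::sd(vals) / sqrt(length(vals))
  # simulation oracle for the expectation
  sim <- replicate(4000, {
    i <- length(intersect(sample(100, 10), sample(100, 10)))
    i / (20 - i)
  })
  expect_lt(abs(mean(vals) - mean(sim)), 3 * se)
})

test_that("attention ranks pick the best head and average ties", {
  # 3 species, 1 sample, 2 heads with opposite orderings for species 1
  edges <- cbind(1:3, 1)
  vals <- cbind(c(0.6, 0.3, 0.1), c(0.1, 0.3, 0.6))
  att <- attention_tensor(paste0("s", 1:3), "p1", edges, vals)
  lab <- encode_labels(c(p1 = "a"))
  rd <- attention_rank_distribution(att, lab, "a")
  expect_equal(unname(rd$ranks[, 1]), c(1, 2, 1))  # best over heads
  rdw <- attention_rank_distribution(att, lab, "a", representative = "worst")
  expect_equal(unname(rdw$ranks[, 1]), c(3, 2, 3))
  # all-tied attention gives everyone the average rank (M + 1) / 2
  attt <- attention_tensor(paste0("s", 1:3), "p1", edges,
                           matrix(1 / 3, 3, 2))
  rdt <- attention_rank_distribution(attt, lab, "a")
  expect_equal(unname(rdt$ranks[, 1]), rep(2, 3))
})

test_that("1-D Wasserstein matches closed forms and the assignment oracle", {
  expect_equal(wasserstein_1d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wasserstein_1d(5, 9), 4)            # point masses
  expect_equal(wasserstein_1d(c(1, 2, 3), c(2, 3, 4)), 1)
  # brute-force optimal assignment oracle (equal sizes)
  perm_oracle <- function(x, y) {
    perms <- function(v) if (length(v) == 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    min(vapply(perms(seq_along(y)), function(p) mean(abs(x - y[p])), 0))
  }
  set.seed(4)
  for (rep in 1:5) {
    x <- round(rnorm(5), 2); y <- round(rnorm(5), 2)
    expect_equal(wasserstein_1d(x, y), perm_oracle(x, y), tolerance = 1e-12)
  }
  # CDF-integration oracle for unequal sizes
  cdf_oracle <- function(x, y) {
    br <- sort(unique(c(x, y)))
    Fx <- stats::ecdf(x); Fy <- stats::ecdf(y)
    mids <- utils::head(br, -1)
    sum(abs(Fx(mids) - Fy(mids)) * diff(br))
  }
  for (rep in 1:8) {
    x <- rnorm(sample(2:12, 1)); y <- rnorm(sample(2:12, 1))
    expect_equal(wasserstein_1d(x, y), cdf_oracle(x, y), tolerance = 1e-8)
    expect_equal(wasserstein_1d(x, y), wasserstein_1d(y, x))
  }
  expect_error(wasserstein_1d(numeric(), 1), "non-empty")
})

test_that("Wasserstein distance satisfies the triangle inequality", {
  set.seed(9)
  for (rep in 1:10) {
    x <- rnorm(6); y <- rnorm(9); z <- rnorm(4)
    expect_lte(wasserstein_1d(x, z),
               wasserstein_1d(x, y) + wasserstein_1d(y, z) + 1e-12)
  }
})

test_that("identity-line concordance matches its closed forms", {
  expect_equal(rank_fit_r2(1:10, 1:10), 1)
  expect_equal(rank_fit_r2(c(1, 2, 3), c(3, 2, 1)), 1 - 8 / 2)
  x <- 1:10
  for (c in c(1, 2.5)) {
    expect_equal(rank_fit_r2(x, x + c), 1 - 10 * c^2 / sum((x - mean(x))^2))
  }
  expect_error(rank_fit_r2(1:3, rep(2, 3)), "variance")
})
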