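# Tensor with a single head and fully specified values for threshold tests.
manual_attention <- function(vals_by_sample, h = 1) {
  M <- nrow(vals_by_sample[[1]]); N <- length(vals_by_sample)
  edges <- NULL; values <- NULL
  for (j in seq_len(N)) {
    v <- vals_by_sample[[j]]          # M x h matrix
    nz <- which(rowSums(v) > 0)
    edges <- rbind(edges, cbind(nz, j))
    values <- rbind(values, v[nz, , drop = FALSE])
  }
  attention_tensor(sprintf("s%02d", 1:M), sprintf("p%02d", 1:N),
                   edges, values)
}

test_that("thresholds use the interquartile band mean + z * sd", {
  v <- matrix(c(0.1, 0.2, 0.3, 0.4), 4, 1)
  att <- manual_attention(list(v))
  ts <- compute_thresholds(att, z_alpha = 1.96)
  q <- stats::quantile(c(0.1, 0.2, 0.3, 0.4), c(0.25, 0.75), type = 7)
  band <- c(0.1, 0.2, 0.3, 0.4)
  band <- band[band >= q[1] & band <= q[2]]
  expect_equal(unname(ts$thr[1, 1]), mean(band) + 1.96 * stats::sd(band))
  # z = 0 gives the band mean
  ts0 <- compute_thresholds(att, z_alpha = 0)
  expect_equal(unname(ts0$thr[1, 1]), mean(band))
  # all-equal attention: sd 0, threshold = value, nothing called (strict >)
  ve <- matrix(0.25, 4, 1)
  atte <- manual_attention(list(ve))
  tse <- compute_thresholds(atte)
  expect_equal(unname(tse$thr[1, 1]), 0.25)
  expect_equal(sum(call_high_contribution(atte, tse)), 0)
})

test_that("high-contribution calls follow the strict OR-over-heads rule", {
  # two heads: species 1 exceeds only in head 2
  v <- cbind(c(0.4, 0.2, 0.2, 0.2), c(0.7, 0.1, 0.1, 0.1))
  att <- manual_attention(list(v), h = 2)
  ts <- compute_thresholds(att, z_alpha = 1)
  contrib <- call_high_contribution(att, ts)
  hit_by_head <- att$values > t(ts$thr)[att$edges[, 2], ]
  expect_equal(unname(contrib[att$edges]),
               as.integer(rowSums(hit_by_head) > 0))
  # boundary: attention exactly equal to the threshold is not called
  vb <- matrix(c(0.5, 0.5, 0.5), 3, 1)
  attb <- manual_attention(list(vb))
  tsb <- compute_thresholds(attb, z_alpha = 0)
  expect_equal(sum(call_high_contribution(attb, tsb)), 0)
})

test_that("contribution counts aggregate by class and sample", {
  contrib <- matrix(c(1, 0, 1, 1,
                      0, 1, 1, 0,
                      1, 1, 0, 0), 3, 4, byrow = TRUE,
                    dimnames = list(paste0("s", 1:3), paste0("p", 1:4)))
  lab <- encode_labels(c(p1 = "a", p2 = "a", p3 = "b", p4 = "b"))
  cnt <- count_contributions(contrib, lab)
  expect_equal(unname(cnt$T["a", ]), c(1, 1, 2))
  expect_equal(unname(cnt$T["b", ]), c(2, 1, 0))
  expect_equal(unname(cnt$U), c(2, 2))
  per_sample <- colSums(contrib)
  expect_equal(unname(cnt$S_max), c(max(per_sample[1:2]), max(per_sample[3:4])))
  expect_equal(unname(cnt$S_min), c(min(per_sample[1:2]), min(per_sample[3:4])))
  # saturated and empty cases
  ones <- matrix(1L, 3, 4, dimnames = dimnames(contrib))
  cnt1 <- count_contributions(ones, lab)
  expect_true(all(cnt1$T == 2) && all(cnt1$S_max == 3) && all(cnt1$S_min == 3))
  zer <- matrix(0L, 3, 4, dimnames = dimnames(contrib))
  cnt0 <- count_contributions(zer, lab)
  expect_true(all(cnt0$T == 0) && all(cnt0$S_max == 0))
})

test_that("tail probability matches the exact binomial-coefficient oracle", {
  for (M in c(5, 13, 21)) {
    for (U in c(1, 4, 8)) {
      combos <- expand.grid(Smin = 1:M, Smax = 1:M)
      combos <- combos[combos$Smin <= combos$Smax, ]
      for (i in seq_len(nrow(combos))) {
        Smax <- combos$Smax[i]; Smin <- combos$Smin[i]
        got <- suppressWarnings(species_pvalue(0:U, U, M, Smax, Smin))
        expect_equal(got, pvalue_choose_oracle(U, M, Smax, Smin),
                     tolerance = 1e-10,
                     info = sprintf("M=%d U=%d Smax=%d Smin=%d", M, U, Smax, Smin))
      }
    }
  }
})

test_that("tail probability totals one at T = 0 when S_max = S_min", {
  expect_equal(species_pvalue(0, 7, 20, 5, 5), 1, tolerance = 1e-12)
  expect_equal(species_pvalue(4, 4, 10, 3, 3), 0.3^4, tolerance = 1e-12)
})

test_that("tail probability is non-increasing in T", {
  for (M in c(8, 15)) for (U in c(3, 6)) for (Smin in c(1, 3)) {
    Smax <- Smin + 2
    p <- suppressWarnings(species_pvalue(0:U, U, M, Smax, Smin))
    expect_true(all(diff(p) <= 1e-12))
  }
  expect_error(species_pvalue(1, 4, 10, 2, 5), "S_min")
})

test_that("Benjamini-Hochberg adjustment matches the step-up procedure", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_pvalues(rep(0.04, 5)), rep(0.04, 5))
  p <- c(0.001, 0.2, 0.8)
  expect_identical(adjust_pvalues(p, method = "none"), p)
  m <- rbind(a = c(0.01, 0.02, 0.03), b = c(0.5, 0.6, 0.7))
  expect_equal(unname(adjust_pvalues(m)[1, ]), rep(0.03, 3))
})

test_that("community inference returns planted species and honours the cutoff", {
  fit <- toy_fit()
  sim <- toy_fit_sim()
  comm <- suppressWarnings(communities(fit))
  sets <- community_sets(comm)
  # candidate set (T >= 1) is a superset of each community
  for (cl in names(sets)) {
    cand <- colnames(comm$counts$T)[comm$counts$T[cl, ] >= 1]
    expect_true(all(sets[[cl]] %in% cand))
    expect_true(all(comm$communities[[cl]]$p_adjusted < comm$cutoff))
  }
  # vacuous cutoff returns every candidate
  all_comm <- suppressWarnings(communities(fit, cutoff = 1.0000001))
  for (cl in names(sets)) {
    cand <- colnames(comm$counts$T)[comm$counts$T[cl, ] >= 1]
    expect_setequal(community_sets(all_comm)[[cl]], cand)
  }
})
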