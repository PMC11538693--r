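# Hand-checkable configuration: identity projections, one head, mu = 1.
identity_params <- function(d, L, C, theta = 1) {
  p <- microhgt:::init_params(d, 1L, L, C, seed = 1)
  for (l in seq_len(L)) {
    for (t in c("species", "sample")) {
      p$layers[[l]]$Wk[[t]] <- diag(d)
      p$layers[[l]]$Wq[[t]] <- diag(d)
      p$layers[[l]]$Wv[[t]] <- diag(d)
      p$layers[[l]]$theta[[t]] <- theta
    }
    for (e in c("metabolic", "phylogenetic", "abundance")) {
      p$layers[[l]]$Watt[[e]] <- diag(d)
      p$layers[[l]]$Wmsg[[e]] <- diag(d)
    }
    p$layers[[l]]$mu[] <- 1
  }
  p
}

two_node_setup <- function() {
  A <- matrix(c(0.5, 0, 0.5, 1), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("p1", "p2")))
  G <- build_graph(A)
  ctl <- hgt_control(d = 2, h = 1, L = 1, epochs = 1, seed = 1)
  comp <- microhgt:::compile_graph(G, ctl$softmax_scope)
  H0 <- list(species = rbind(c(1, 0), c(0, 1)),
             sample = rbind(c(1, 1), c(0.5, -0.5)))
  list(G = G, ctl = ctl, comp = comp, H0 = H0)
}

test_that("forward pass matches the hand-derived two-species/two-sample update", {
  s <- two_node_setup()
  par <- identity_params(2, 1, 2)$layers[[1]]
  out <- microhgt:::layer_forward(par, s$comp, s$H0, s$ctl)

  # sample p1 sees s1=(1,0), s2=(0,1); both scores (K.Q)/sqrt(2) are equal,
  # so attention is 1/2 each and the update is the message average.
  expect_equal(out$H$sample[1, ], c(0.5, 0.5), tolerance = 1e-6)
  # sample p2 has the single source s2
  expect_equal(out$H$sample[2, ], c(0, 1), tolerance = 1e-6)
  # species s1 aggregates only p1
  expect_equal(out$H$species[1, ], c(1, 1), tolerance = 1e-6)
  # species s2 aggregates p1 and p2 with softmax((1, -0.5)/sqrt(2)) weights
  w <- exp(c(1, -0.5) / sqrt(2)); w <- w / sum(w)
  expect_equal(out$H$species[2, ],
               pmax(w[1] * c(1, 1) + w[2] * c(0.5, -0.5), 0),
               tolerance = 1e-6)

  # raw attention score of an aligned unit Key/Query pair is mu / sqrt(d)
  cc <- out$cache$tt$sample
  expect_equal(cc$Sraw[2, 1], 1 / sqrt(2), tolerance = 1e-12) # s2 -> p1: K=Q=(0,1),(1,1)->dot 1
})

test_that("residual gate theta interpolates between identity and ReLU update", {
  s <- two_node_setup()
  par0 <- identity_params(2, 1, 2, theta = 0)$layers[[1]]
  out0 <- microhgt:::layer_forward(par0, s$comp, s$H0, s$ctl)
  expect_equal(out0$H$species, s$H0$species)
  expect_equal(out0$H$sample, s$H0$sample)

  par1 <- identity_params(2, 1, 2, theta = 1)$layers[[1]]
  out1 <- microhgt:::layer_forward(par1, s$comp, s$H0, s$ctl)
  expect_true(all(out1$H$species >= 0))   # pure ReLU of the aggregate

  # literal form: residual weight (theta - 1) flips the sign of the carry
  ctl_lit <- s$ctl; ctl_lit$literal_residual <- TRUE
  out_lit <- microhgt:::layer_forward(par0, s$comp, s$H0, ctl_lit)
  expect_equal(out_lit$H$sample, -s$H0$sample)
})

test_that("zero meta-relation prior yields uniform attention", {
  s <- two_node_setup()
  par <- identity_params(2, 1, 2)$layers[[1]]
  par$mu[] <- 0
  out <- microhgt:::layer_forward(par, s$comp, s$H0, s$ctl)
  att <- out$cache$tt$sample$att
  # p1 has two sources -> 0.5 each despite different embeddings
  expect_equal(att[s$comp$sample$tgt_idx == 1, 1], c(0.5, 0.5))
})

test_that("attention normalises to one per target and head on a trained model", {
  fit <- toy_fit()
  att <- fit$attention
  for (k in seq_len(att$h)) {
    sums <- tapply(att$values[, k], att$edges[, 2], sum)
    expect_true(all(abs(sums - 1) < 1e-6))
  }
  # species-target attention groups also normalise (mixed edge types)
  G <- fit$graph
  ctl <- fit$control
  comp <- microhgt:::compile_graph(G, ctl$softmax_scope)
  H0 <- list(species = unname(fit$initial_embeddings$species),
             sample = unname(fit$initial_embeddings$sample))
  fw <- microhgt:::hgt_forward(fit$params, comp, H0, ctl)
  for (l in seq_len(ctl$L)) {
    cc <- fw$caches[[l]]$tt$species
    for (k in seq_len(ctl$h)) {
      sums <- rowsum(cc$att[, k], comp$species$gmap)
      expect_true(all(abs(sums - 1) < 1e-6))
    }
  }
})

test_that("analytic gradients agree with finite differences", {
  set.seed(42)
  sim <- simulate_microbiome(synthetic_spec(M = 10, N = 8, C = 2,
                                            community_size = 3, effect = 5,
                                            sparsity = 0.2, genus_size = 3,
                                            seed = 3))
  D2 <- phylogenetic_relations(sim$taxonomy, rownames(sim$abundance))
  A <- preprocess_abundance(sim$abundance, 0)
  G <- build_graph(A, D2 = D2[rownames(A), rownames(A)])
  ctl <- hgt_control(d = 4, h = 2, L = 2, gamma = 2, reg_alpha = 0.01,
                     seed = 5)
  comp <- microhgt:::compile_graph(G, ctl$softmax_scope)
  H0 <- list(species = matrix(rnorm(nrow(A) * 4), ncol = 4),
             sample = matrix(rnorm(ncol(A) * 4), ncol = 4))
  onehot <- sim$labels$onehot
  alpha_c <- class_weights(onehot)
  Acol <- sweep(A, 2, colSums(A), "/")
  params <- microhgt:::init_params(4, 2, 2, 2, 7)
  bump <- function(x) if (is.list(x)) lapply(x, bump) else
    x + rnorm(length(x), sd = 0.05)
  params <- bump(params)
  lg <- microhgt:::hgt_loss_grad(params, comp, H0, onehot, alpha_c, Acol, ctl)
  th <- microhgt:::flatten_params(params)
  gan <- microhgt:::flatten_params(lg$grad)
  f <- function(v) microhgt:::hgt_loss_grad(
    microhgt:::unflatten_params(v, params), comp, H0, onehot, alpha_c,
    Acol, ctl, want_grad = FALSE)$loss
  set.seed(1)
  idx <- sample(length(th), 40)
  eps <- 1e-6
  gnum <- vapply(idx, function(i) {
    u <- th; u[i] <- u[i] + eps
    v <- th; v[i] <- v[i] - eps
    (f(u) - f(v)) / (2 * eps)
  }, 0)
  denom <- pmax(1e-6, abs(gnum) + abs(gan[idx]))
  expect_lt(max(abs(gnum - gan[idx]) / denom), 1e-4)
})

test_that("planted species rank above others in their class's attention", {
  res <- full_scale_study()
  # stochastically smaller representative ranks (rank 1 = most attended)
  expect_true(all(res$wilcox_p < 0.01),
              label = paste("Mann-Whitney p:",
                            paste(signif(res$wilcox_p, 3), collapse = " ")))
})

test_that("training is deterministic under a fixed seed", {
  sim <- simulate_microbiome(synthetic_spec(M = 20, N = 16, C = 2,
                                            community_size = 4, effect = 10,
                                            sparsity = 0.2, seed = 2))
  ctl <- hgt_control(d = 8, h = 2, L = 2, epochs = 15, ae_epochs = 20,
                     seed = 3)
  f1 <- hgt_fit(sim$abundance, sim$labels, control = ctl)
  f2 <- hgt_fit(sim$abundance, sim$labels, control = ctl)
  expect_identical(f1$predicted, f2$predicted)
  expect_identical(f1$attention$values, f2$attention$values)
  expect_identical(f1$loss_trace$total, f2$loss_trace$total)
})

test_that("softmax of logits behaves as a classifier head", {
  expect_equal(microhgt:::row_softmax(matrix(c(0, 0), 1)), matrix(0.5, 1, 2))
  expect_equal(microhgt:::row_softmax(matrix(c(log(2), 0), 1)),
               matrix(c(2/3, 1/3), 1), tolerance = 1e-12)
  fit <- toy_fit()
  expect_true(all(abs(rowSums(fit$probs) - 1) < 1e-6))
  expect_true(all(fit$probs >= 0 & fit$probs <= 1))
})
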