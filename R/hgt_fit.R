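# Full forward pass: L transformer layers then the classification head and
# the KL term. Returns everything backward() and attention extraction need.
hgt_forward <- function(params, comp, H0, ctl) {
  H <- H0
  caches <- vector("list", ctl$L)
  for (l in seq_len(ctl$L)) {
    st <- layer_forward(params$layers[[l]], comp, H, ctl)
    H <- st$H
    caches[[l]] <- st$cache
  }
  logits <- sweep(H$sample %*% params$classifier$W, 2L,
                  params$classifier$b, "+")
  list(H = H, caches = caches, logits = logits, P = row_softmax(logits))
}

hgt_loss_grad <- function(params, comp, H0, onehot, alpha_c, Acol,
                          ctl, want_grad = TRUE) {
  fw <- hgt_forward(params, comp, H0, ctl)
  P <- fw$P
  lf <- focal_loss(P, onehot, ctl$gamma, alpha_c)
  # KL(a_j || m_j) per sample, summed; m_j = softmax over species of the
  # embedding affinities, a_j = the sample's relative-abundance column
  Z <- fw$H$species %*% t(fw$H$sample)
  Zc <- sweep(Z, 2L, apply(Z, 2L, max))
  lsm <- sweep(Zc, 2L, log(colSums(exp(Zc))))
  a <- Acol
  iz <- which(a > 0)
  lkl <- sum(a[iz] * log(a[iz])) - sum(a[iz] * lsm[iz])
  out <- list(loss = total_loss(lf, lkl, ctl$reg_alpha),
              focal = lf, kl = lkl, forward = fw)
  if (!want_grad) return(out)

  dZ <- focal_grad_logits(P, onehot, ctl$gamma, alpha_c)
  gcls <- list(W = crossprod(fw$H$sample, dZ), b = colSums(dZ))
  dHp <- dZ %*% t(params$classifier$W)
  dHs <- matrix(0, nrow(fw$H$species), ctl$d)
  if (ctl$reg_alpha > 0) {
    dZ2 <- ctl$reg_alpha * (exp(lsm) - a)
    dHs <- dHs + dZ2 %*% fw$H$sample
    dHp <- dHp + crossprod(dZ2, fw$H$species)
  }
  dH <- list(species = dHs, sample = dHp)
  glayers <- vector("list", ctl$L)
  for (l in rev(seq_len(ctl$L))) {
    bk <- layer_backward(params$layers[[l]], comp, fw$caches[[l]], dH, ctl)
    glayers[[l]] <- bk$grad
    dH <- bk$dH_in
  }
  out$grad <- list(layers = glayers, classifier = gcls)
  out
}

# Extract the species->sample attention of the chosen layer(s) from the
# forward caches.
extract_attention <- function(caches, comp, species_ids, sample_ids, ctl) {
  ct <- comp$sample
  grab <- function(l) caches[[l]]$tt$sample$att
  values <- if (ctl$attention_layer == "final") grab(ctl$L) else
    Reduce(`+`, lapply(seq_len(ctl$L), grab)) / ctl$L
  attention_tensor(species_ids, sample_ids,
                   edges = cbind(ct$src_idx, ct$tgt_idx),
                   values = values,
                   layer = ctl$attention_layer)
}

#' Species-to-sample attention tensor
#'
#' Sparse container for the per-head attention on species-to-sample edges
#' (zero-abundance pairs carry no edge, hence zero attention). Per sample and
#' head, the values over its species sum to 1.
#'
#' @param species_ids,sample_ids Node identifiers.
#' @param edges Integer matrix (n_edges x 2): species index, sample index.
#' @param values n_edges x h matrix of attention values.
#' @param layer Label for which layer(s) the values come from.
#' @return Object of class `"attention_tensor"`.
#' @export
attention_tensor <- function(species_ids, sample_ids, edges, values,
                             layer = "final") {
  stopifnot(nrow(edges) == nrow(values), ncol(edges) == 2L)
  structure(list(species_ids = species_ids, sample_ids = sample_ids,
                 edges = edges, values = values, h = ncol(values),
                 layer = layer),
            class = "attention_tensor")
}

#' @export
print.attention_tensor <- function(x, ...) {
  cat(sprintf("Attention tensor: %d species, %d samples, %d heads, %d edges (layer: %s)\n",
              length(x$species_ids), length(x$sample_ids), x$h,
              nrow(x$edges), x$layer))
  invisible(x)
}

# Dense M x N attention matrix for one head (zeros where no edge).
attention_dense <- function(att, head) {
  A <- matrix(0, length(att$species_ids), length(att$sample_ids),
              dimnames = list(att$species_ids, att$sample_ids))
  A[att$edges] <- att$values[, head]
  A
}

#' Fit the heterogeneous graph transformer to a microbiome study
#'
#' Builds the species-sample heterogeneous graph, pre-trains autoencoder node
#' embeddings, and trains the typed multi-head attention transformer to
#' classify samples under a focal loss with a KL abundance regulariser.
#' Training is transductive on all labelled samples: the purpose of the model
#' is attention extraction, and the species-to-sample attention of the
#' trained model is the substrate for community inference (see
#' [communities()]).
#'
#' @param A Species x sample abundance matrix (raw or preprocessed; columns
#'   are renormalised via [preprocess_abundance()] when `preprocess = TRUE`).
#' @param labels A `"sample_labels"` object or a named character vector of
#'   class labels (names = sample ids).
#' @param D1 Optional binary metabolic relation matrix over the species of
#'   `A` (see [metabolic_relations()]); `NULL` drops metabolic edges.
#' @param D2 Optional binary phylogenetic relation matrix (see
#'   [phylogenetic_relations()]); `NULL` drops phylogenetic edges.
#' @param control A [hgt_control()] object.
#' @param preprocess Apply [preprocess_abundance()] first (default `TRUE`).
#' @param min_nonzero_frac Passed to [preprocess_abundance()].
#' @return An object of class `"hgt_fit"` with components `probs` (N x C
#'   predicted probabilities), `attention` (the species-to-sample
#'   [attention_tensor()]), `loss_trace`, `params`, `graph`, `labels`,
#'   `final_embeddings`, `accuracy`, `control`.
#' @examples
#' sim <- simulate_microbiome(synthetic_spec(M = 40, N = 30, C = 2,
#'                                           community_size = 5, seed = 1))
#' ctl <- hgt_control(d = 16, h = 4, epochs = 50, ae_epochs = 50, seed = 1)
#' fit <- hgt_fit(sim$abundance, sim$labels, control = ctl)
#' fit
#' @export
hgt_fit <- function(A, labels, D1 = NULL, D2 = NULL, control = hgt_control(),
                    preprocess = TRUE, min_nonzero_frac = 5e-4) {
  cl <- match.call()
  validate_abundance(A)
  if (preprocess) A <- preprocess_abundance(A, min_nonzero_frac)
  if (!inherits(labels, "sample_labels"))
    labels <- encode_labels(labels, sample_ids = colnames(A))
  if (!identical(labels$sample_ids, colnames(A)))
    labels <- encode_labels(stats::setNames(labels$labels, labels$sample_ids),
                            sample_ids = colnames(A), classes = labels$classes)
  C <- length(labels$classes)
  if (C < 2L) stop("need at least 2 classes to train a classifier")
  align <- function(D, kind) {
    if (is.null(D)) return(NULL)
    validate_relation_matrix(D, rownames(A), kind)
  }
  G <- build_graph(A, align(D1, "metabolic"), align(D2, "phylogenetic"))
  ctl <- control
  emb <- initial_embeddings(A, ae_config(hidden_dim = ctl$d,
                                         epochs = ctl$ae_epochs,
                                         learning_rate = ctl$learning_rate,
                                         seed = ctl$seed))
  tr <- train_hgt(G, labels, emb, ctl)
  structure(c(tr, list(call = cl, graph = G, labels = labels,
                       initial_embeddings = emb, control = ctl)),
            class = "hgt_fit")
}

#' Train the transformer on a prebuilt graph
#'
#' Lower-level entry point used by [hgt_fit()]; useful when the graph or the
#' initial embeddings are reused across runs.
#'
#' @param G A `"hetero_graph"`.
#' @param labels A `"sample_labels"` aligned to `G$sample_ids`.
#' @param embeddings List with `species` and `sample` initial embedding
#'   matrices (see [initial_embeddings()]).
#' @param ctl A [hgt_control()].
#' @return List with trained `params`, `loss_trace`, `probs`, `attention`,
#'   `final_embeddings`, `accuracy`.
#' @export
train_hgt <- function(G, labels, embeddings, ctl = hgt_control()) {
  stopifnot(inherits(G, "hetero_graph"))
  comp <- compile_graph(G, ctl$softmax_scope)
  onehot <- labels$onehot
  C <- ncol(onehot)
  alpha_c <- class_weights(onehot)
  H0 <- list(species = unname(embeddings$species),
             sample = unname(embeddings$sample))
  stopifnot(ncol(H0$species) == ctl$d, ncol(H0$sample) == ctl$d)
  cs <- colSums(G$abundance)
  if (any(cs == 0)) stop("sample(s) with all-zero abundance; preprocess first")
  Acol <- sweep(G$abundance, 2L, cs, "/")
  params <- init_params(ctl$d, ctl$h, ctl$L, C, ctl$seed)
  skel <- params
  theta <- flatten_params(params)
  adam <- adam_state(length(theta), lr = ctl$learning_rate)
  tr_focal <- numeric(ctl$epochs); tr_kl <- numeric(ctl$epochs)
  tr_total <- numeric(ctl$epochs)
  for (epoch in seq_len(ctl$epochs)) {
    lg <- hgt_loss_grad(params, comp, H0, onehot, alpha_c, Acol, ctl)
    if (!is.finite(lg$loss))
      stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
    tr_focal[epoch] <- lg$focal; tr_kl[epoch] <- lg$kl
    tr_total[epoch] <- lg$loss
    if (ctl$verbose > 0 && epoch %% ctl$verbose == 0)
      message(sprintf("epoch %4d  focal %.5f  kl %.4f  total %.5f",
                      epoch, lg$focal, lg$kl, lg$loss))
    theta <- adam_step(adam, theta, flatten_params(lg$grad))
    params <- unflatten_params(theta, skel)
  }
  trace <- data.frame(epoch = seq_len(ctl$epochs), focal = tr_focal,
                      kl = tr_kl, total = tr_total)
  fw <- hgt_forward(params, comp, H0, ctl)
  P <- fw$P
  dimnames(P) <- list(labels$sample_ids, labels$classes)
  pred <- labels$classes[max.col(P, ties.method = "first")]
  att <- extract_attention(fw$caches, comp, G$species_ids, G$sample_ids, ctl)
  list(params = params, loss_trace = trace, probs = P,
       attention = att,
       final_embeddings = list(
         species = structure(fw$H$species, dimnames = list(G$species_ids, NULL)),
         sample = structure(fw$H$sample, dimnames = list(G$sample_ids, NULL))),
       predicted = stats::setNames(pred, labels$sample_ids),
       accuracy = mean(pred == labels$labels))
}
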