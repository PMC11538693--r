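#' Control parameters for the heterogeneous graph transformer
#'
#' Defaults follow the method's stated settings where they exist (`h = 8`
#' attention heads, `L = 2` layers, KL regularisation weight
#' `reg_alpha = 0.003`, community cutoff elsewhere at 0.05); the remaining
#' values (embedding width, focal exponent, optimiser schedule) are package
#' defaults, all exposed here.
#'
#' @param d Node embedding dimension (must be divisible by `h`); default 64.
#' @param h Number of attention heads; default 8.
#' @param L Number of transformer layers; default 2.
#' @param gamma Focal-loss exponent (>= 0); default 2.
#' @param reg_alpha Weight of the KL abundance regulariser; default 0.003.
#' @param epochs Training epochs; default 500.
#' @param learning_rate Adam learning rate; default 1e-3.
#' @param seed RNG seed controlling initialisation (and autoencoders).
#' @param ae_epochs Autoencoder pre-training epochs; default 200.
#' @param attention_layer Which layer's species-to-sample attention feeds
#'   inference: `"final"` (default) or `"mean"` over layers.
#' @param softmax_scope `"all"` (default): all incoming edges of a target
#'   compete in one softmax per head; `"per_edge_type"`: normalise within
#'   each edge type.
#' @param literal_residual If `TRUE`, use `(theta - 1)` as the residual
#'   weight in the layer update instead of the gated `(1 - theta)`.
#' @param verbose Print the loss every `verbose` epochs (0 = silent).
#' @return List of class `"hgt_control"`.
#' @export
hgt_control <- function(d = 64L, h = 8L, L = 2L, gamma = 2, reg_alpha = 0.003,
                        epochs = 500L, learning_rate = 1e-3, seed = 1L,
                        ae_epochs = 200L,
                        attention_layer = c("final", "mean"),
                        softmax_scope = c("all", "per_edge_type"),
                        literal_residual = FALSE, verbose = 0L) {
  d <- as.integer(d); h <- as.integer(h); L <- as.integer(L)
  if (h < 1L) stop("h must be >= 1")
  if (L < 1L) stop("L must be >= 1")
  if (d %% h != 0L) stop("d must be divisible by h")
  if (gamma < 0) stop("gamma must be >= 0")
  if (reg_alpha < 0) stop("reg_alpha must be >= 0")
  structure(list(d = d, h = h, L = L, gamma = gamma, reg_alpha = reg_alpha,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed), ae_epochs = as.integer(ae_epochs),
                 attention_layer = match.arg(attention_layer),
                 softmax_scope = match.arg(softmax_scope),
                 literal_residual = isTRUE(literal_residual),
                 verbose = as.integer(verbose)),
            class = "hgt_control")
}

# ---- graph compilation ------------------------------------------------------
# Directed realisation of the heterogeneous graph, organised per TARGET node
# type. Each target type owns one edge table (src_idx, tgt_idx) concatenated
# from typed blocks in fixed order, plus the per-head softmax grouping.
compile_graph <- function(G, scope = "all") {
  M <- length(G$species_ids); N <- length(G$sample_ids)
  ab <- G$edges_abundance
  both_dirs <- function(e) if (nrow(e)) cbind(c(e[, 1L], e[, 2L]),
                                              c(e[, 2L], e[, 1L])) else e
  met <- both_dirs(G$edges_metabolic)
  phy <- both_dirs(G$edges_phylogenetic)

  make_tt <- function(blocks, n_tgt) {
    src <- unlist(lapply(blocks, function(b) b$edges[, 1L]), use.names = FALSE)
    tgt <- unlist(lapply(blocks, function(b) b$edges[, 2L]), use.names = FALSE)
    n_e <- length(src)
    if (n_e == 0L) return(NULL)
    offs <- 0L
    for (i in seq_along(blocks)) {
      ne <- nrow(blocks[[i]]$edges)
      blocks[[i]]$rows <- if (ne) offs + seq_len(ne) else integer()
      blocks[[i]]$edges <- NULL
      offs <- offs + ne
    }
    blocks <- Filter(function(b) length(b$rows) > 0L, blocks)
    gid <- tgt
    if (scope == "per_edge_type") {
      bid <- integer(n_e)
      for (i in seq_along(blocks)) bid[blocks[[i]]$rows] <- i
      gid <- tgt + n_tgt * (bid - 1L)
    }
    gpres <- sort(unique(gid))
    gmap <- match(gid, gpres)
    tpres <- sort(unique(tgt))
    list(src_idx = src, tgt_idx = tgt, n_e = n_e, n_tgt = n_tgt,
         blocks = blocks, gmap = gmap, n_groups = length(gpres),
         gsplit = split(seq_len(n_e), gmap), tgt_present = tpres)
  }

  list(
    species = make_tt(list(
      list(edge_type = "metabolic", src_type = "species",
           mu_name = "sp_met_sp", edges = met),
      list(edge_type = "phylogenetic", src_type = "species",
           mu_name = "sp_phy_sp", edges = phy),
      list(edge_type = "abundance", src_type = "sample",
           mu_name = "sa_ab_sp", edges = ab[, c(2L, 1L), drop = FALSE])
    ), M),
    sample = make_tt(list(
      list(edge_type = "abundance", src_type = "species",
           mu_name = "sp_ab_sa", edges = ab[, c(1L, 2L), drop = FALSE])
    ), N),
    M = M, N = N
  )
}

# ---- parameters -------------------------------------------------------------
EDGE_TYPES <- c("metabolic", "phylogenetic", "abundance")
MU_NAMES <- c("sp_met_sp", "sp_phy_sp", "sp_ab_sa", "sa_ab_sp")

# Projections start at identity plus small noise and the residual gates at 1
# (message-driven updates). With identity maps the attention score of an edge
# is the embedding inner product of its endpoints, the same affinity the KL
# regulariser couples to the abundance profile, so attention starts in and is
# trained within an abundance-anchored geometry instead of an arbitrary
# random one; the noise lets heads and layers diversify during training.
init_params <- function(d, h, L, C, seed, proj_noise = 0.02) {
  set.seed(seed)
  dh <- d %/% h
  glorot <- function(p, q) matrix(stats::rnorm(p * q, sd = sqrt(2 / (p + q))), p, q)
  near_id <- function() diag(d) + matrix(stats::rnorm(d * d, sd = proj_noise), d, d)
  proj <- function() list(species = near_id(), sample = near_id())
  eye <- function() stats::setNames(
    lapply(EDGE_TYPES, function(.) diag(dh)), EDGE_TYPES)
  layers <- lapply(seq_len(L), function(l) list(
    Wk = proj(), Wq = proj(), Wv = proj(),
    Watt = eye(), Wmsg = eye(),
    mu = stats::setNames(rep(1, 4L), MU_NAMES),
    theta = c(species = 1, sample = 1)))
  list(layers = layers,
       classifier = list(W = glorot(d, C), b = numeric(C)))
}

zero_like <- function(x) {
  if (is.list(x)) lapply(x, zero_like) else x * 0
}

flatten_params <- function(x) unlist(x, use.names = FALSE)

unflatten_params <- function(vec, skeleton) {
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    n <- length(x)
    out <- vec[pos + seq_len(n)]
    pos <<- pos + n
    attributes(out) <- attributes(x)
    out
  }
  walk(skeleton)
}

# ---- layer forward / backward ----------------------------------------------
head_cols <- function(d, h) {
  dh <- d %/% h
  lapply(seq_len(h), function(k) (k - 1L) * dh + seq_len(dh))
}

# The per-edge-type (d/h x d/h) attention and message matrices act
# independently on each head's column block; realising them as d x d block
# diagonals turns all per-head products into single BLAS calls.
block_diag_rep <- function(W, h) kronecker(diag(h), W)

# Sum the h diagonal blocks of a d x d gradient back onto the shared
# (d/h x d/h) matrix.
block_diag_sum <- function(G, dh, h) {
  out <- matrix(0, dh, dh)
  for (k in seq_len(h)) {
    ck <- (k - 1L) * dh + seq_len(dh)
    out <- out + G[ck, ck]
  }
  out
}

# 0/1 selector (d x h) summing each head's column block.
head_mask <- function(d, h) {
  dh <- d %/% h
  Hm <- matrix(0, d, h)
  for (k in seq_len(h)) Hm[(k - 1L) * dh + seq_len(dh), k] <- 1
  Hm
}

group_colmax <- function(S, gsplit) {
  out <- matrix(-Inf, length(gsplit), ncol(S))
  for (g in seq_along(gsplit)) {
    ix <- gsplit[[g]]
    if (length(ix) == 1L) out[g, ] <- S[ix, ]
    else for (k in seq_len(ncol(S))) out[g, k] <- max(S[ix, k])
  }
  out
}

# Head-wise softmax over each target's incoming edges (Eq. 6); per head the
# normalised values over a target's sources sum to 1.
softmax_by_group <- function(S, gmap, gsplit) {
  mx <- group_colmax(S, gsplit)
  E <- exp(S - mx[gmap, , drop = FALSE])
  denom <- rowsum(E, gmap)
  out <- E / denom[gmap, , drop = FALSE]
  dimnames(out) <- NULL
  out
}

layer_forward <- function(par, comp, H, ctl) {
  d <- ctl$d; h <- ctl$h; dh <- d %/% h
  exp_idx <- rep(seq_len(h), each = dh)
  Hm <- head_mask(d, h)
  K <- list(species = H$species %*% par$Wk$species,
            sample = H$sample %*% par$Wk$sample)
  Q <- list(species = H$species %*% par$Wq$species,
            sample = H$sample %*% par$Wq$sample)
  V <- list(species = H$species %*% par$Wv$species,
            sample = H$sample %*% par$Wv$sample)
  cache <- list(K = K, Q = Q, V = V, H_in = H, tt = list())
  Hnew <- list()
  for (tt in c("species", "sample")) {
    ct <- comp[[tt]]
    if (is.null(ct)) { Hnew[[tt]] <- H[[tt]]; next }
    Sraw <- matrix(0, ct$n_e, h)   # attention score before the mu scaling
    S <- matrix(0, ct$n_e, h)
    msg <- matrix(0, ct$n_e, d)
    kw <- vector("list", length(ct$blocks))
    for (i in seq_along(ct$blocks)) {
      b <- ct$blocks[[i]]
      r <- b$rows
      BDa <- block_diag_rep(par$Watt[[b$edge_type]], h)
      BDm <- block_diag_rep(par$Wmsg[[b$edge_type]], h)
      KW <- K[[b$src_type]][ct$src_idx[r], , drop = FALSE] %*% BDa   # Eq. 5
      Sraw[r, ] <- ((KW * Q[[tt]][ct$tgt_idx[r], , drop = FALSE]) %*% Hm) / sqrt(d)
      S[r, ] <- Sraw[r, , drop = FALSE] * par$mu[[b$mu_name]]
      msg[r, ] <- V[[b$src_type]][ct$src_idx[r], , drop = FALSE] %*% BDm  # Eq. 9
      kw[[i]] <- KW
    }
    att <- softmax_by_group(S, ct$gmap, ct$gsplit)                   # Eq. 6
    Htil <- matrix(0, ct$n_tgt, d)
    Htil[ct$tgt_present, ] <-
      rowsum(att[, exp_idx, drop = FALSE] * msg, ct$tgt_idx)         # Eq. 11
    th <- par$theta[[tt]]
    rw <- if (ctl$literal_residual) th - 1 else 1 - th
    Hnew[[tt]] <- th * pmax(Htil, 0) + rw * H[[tt]]                  # Eq. 12
    cache$tt[[tt]] <- list(att = att, msg = msg, Sraw = Sraw, kw = kw,
                           Htil = Htil)
  }
  list(H = Hnew, cache = cache)
}

layer_backward <- function(par, comp, cache, dH_out, ctl) {
  d <- ctl$d; h <- ctl$h; dh <- d %/% h
  exp_idx <- rep(seq_len(h), each = dh)
  Hm <- head_mask(d, h)
  g <- zero_like(par)
  dH_in <- list(species = matrix(0, nrow(cache$H_in$species), d),
                sample = matrix(0, nrow(cache$H_in$sample), d))
  dK <- list(species = dH_in$species, sample = dH_in$sample)
  dQ <- dK; dV <- dK
  index_add <- function(Mat, X, idx) {
    rs <- rowsum(X, idx)
    pres <- sort(unique(idx))
    Mat[pres, ] <- Mat[pres, , drop = FALSE] + rs
    Mat
  }
  for (tt in c("species", "sample")) {
    ct <- comp[[tt]]
    if (is.null(ct)) { dH_in[[tt]] <- dH_in[[tt]] + dH_out[[tt]]; next }
    cc <- cache$tt[[tt]]
    th <- par$theta[[tt]]
    rw <- if (ctl$literal_residual) th - 1 else 1 - th
    drw <- if (ctl$literal_residual) 1 else -1
    relu <- pmax(cc$Htil, 0)
    g$theta[[tt]] <- sum(dH_out[[tt]] * (relu + drw * cache$H_in[[tt]]))
    dHtil <- (dH_out[[tt]] * th) * (cc$Htil > 0)
    dH_in[[tt]] <- dH_in[[tt]] + rw * dH_out[[tt]]
    dwm <- dHtil[ct$tgt_idx, , drop = FALSE]
    att_exp <- cc$att[, exp_idx, drop = FALSE]
    dmsg <- att_exp * dwm
    datt <- (cc$msg * dwm) %*% Hm
    # softmax backward per group, head-wise
    gsum <- rowsum(cc$att * datt, ct$gmap)
    dS <- cc$att * (datt - gsum[ct$gmap, , drop = FALSE])
    for (i in seq_along(ct$blocks)) {
      b <- ct$blocks[[i]]
      r <- b$rows
      mu <- par$mu[[b$mu_name]]
      BDa <- block_diag_rep(par$Watt[[b$edge_type]], h)
      BDm <- block_diag_rep(par$Wmsg[[b$edge_type]], h)
      g$mu[[b$mu_name]] <- g$mu[[b$mu_name]] +
        sum(dS[r, , drop = FALSE] * cc$Sraw[r, , drop = FALSE])
      Qt <- cache$Q[[tt]][ct$tgt_idx[r], , drop = FALSE]
      cm <- (dS[r, , drop = FALSE] * (mu / sqrt(d)))[, exp_idx, drop = FALSE]
      dQe <- cm * cc$kw[[i]]
      dKW <- cm * Qt
      dKe <- dKW %*% t(BDa)
      g$Watt[[b$edge_type]] <- g$Watt[[b$edge_type]] + block_diag_sum(
        crossprod(cache$K[[b$src_type]][ct$src_idx[r], , drop = FALSE], dKW),
        dh, h)
      dme <- dmsg[r, , drop = FALSE]
      dVe <- dme %*% t(BDm)
      g$Wmsg[[b$edge_type]] <- g$Wmsg[[b$edge_type]] + block_diag_sum(
        crossprod(cache$V[[b$src_type]][ct$src_idx[r], , drop = FALSE], dme),
        dh, h)
      dK[[b$src_type]] <- index_add(dK[[b$src_type]], dKe, ct$src_idx[r])
      dV[[b$src_type]] <- index_add(dV[[b$src_type]], dVe, ct$src_idx[r])
      dQ[[tt]] <- index_add(dQ[[tt]], dQe, ct$tgt_idx[r])
    }
  }
  for (t in c("species", "sample")) {
    Hp <- cache$H_in[[t]]
    g$Wk[[t]] <- crossprod(Hp, dK[[t]])
    g$Wq[[t]] <- crossprod(Hp, dQ[[t]])
    g$Wv[[t]] <- crossprod(Hp, dV[[t]])
    dH_in[[t]] <- dH_in[[t]] + dK[[t]] %*% t(par$Wk[[t]]) +
      dQ[[t]] %*% t(par$Wq[[t]]) + dV[[t]] %*% t(par$Wv[[t]])
  }
  list(grad = g, dH_in = dH_in)
}

# ---- losses -----------------------------------------------------------------

row_softmax <- function(Z) {
  E <- exp(Z - apply(Z, 1L, max))
  E / rowSums(E)
}

#' Class weights for the focal loss
#'
#' `alpha_c = 1 - n_c / N`, the complement of each class's sample share, so
#' rarer classes weigh more. The weights always sum to `C - 1`.
#'
#' @param onehot N x C binary label matrix (one 1 per row).
#' @return Numeric C-vector.
#' @export
class_weights <- function(onehot) {
  if (!length(onehot)) stop("empty label matrix")
  stopifnot(all(rowSums(onehot) == 1))
  1 - colSums(onehot) / nrow(onehot)
}

#' Focal classification loss
#'
#' `-(1/N) sum_ic alpha_c (1 - p_ic)^gamma y_ic log(p_ic)`: cross-entropy
#' down-weighting well-classified samples. At `gamma = 0` it reduces exactly
#' to alpha-weighted cross-entropy. Probabilities at a true label are clamped
#' below at 1e-12.
#'
#' @param P N x C matrix of predicted class probabilities (rows sum to 1).
#' @param onehot N x C binary label matrix.
#' @param gamma Focusing exponent, >= 0.
#' @param alpha Class weight vector; default [class_weights()] of `onehot`.
#' @return Scalar loss.
#' @export
focal_loss <- function(P, onehot, gamma = 2, alpha = class_weights(onehot)) {
  stopifnot(gamma >= 0, identical(dim(P), dim(onehot)))
  ci <- max.col(onehot, ties.method = "first")
  p <- pmax(P[cbind(seq_len(nrow(P)), ci)], 1e-12)
  mean(-alpha[ci] * (1 - p)^gamma * log(p))
}

# Gradient of the focal loss w.r.t. the logits of a row-softmax P.
focal_grad_logits <- function(P, onehot, gamma, alpha) {
  n <- nrow(P)
  ci <- max.col(onehot, ties.method = "first")
  p <- pmax(P[cbind(seq_len(n), ci)], 1e-12)
  t1 <- if (gamma > 0) -gamma * (1 - p)^(gamma - 1) * log(p) else 0
  t1[p >= 1 - 1e-12] <- 0
  gp <- -(alpha[ci] / n) * (t1 + (1 - p)^gamma / p)   # dLoss/dp_true
  dZ <- (gp * p) * (onehot - P)
  dZ
}

#' KL regulariser between embedding products and abundance
#'
#' Measures how far the species-sample affinity implied by the final
#' embeddings deviates from the observed relative abundance. Each sample's
#' relative-abundance column is a distribution over species; the model's
#' counterpart is the per-sample softmax (over species) of
#' `S_encoder %*% t(P_encoder)`. Returns the sum over samples of
#' `KL(a_j || m_j)`, so attention and regulariser share the same per-sample
#' normalisation; columns of `A` summing to zero are excluded with a warning.
#'
#' @param S_encoder M x d species embedding matrix.
#' @param P_encoder N x d sample embedding matrix.
#' @param A Species x sample abundance matrix.
#' @return Scalar KL divergence (>= 0), 0 iff the distributions coincide.
#' @export
kl_regularizer <- function(S_encoder, P_encoder, A) {
  stopifnot(nrow(S_encoder) == nrow(A), nrow(P_encoder) == ncol(A),
            ncol(S_encoder) == ncol(P_encoder))
  cs <- colSums(A)
  if (any(cs == 0)) warning(sum(cs == 0), " all-zero sample column(s) excluded from KL")
  valid <- cs > 0
  a <- sweep(A[, valid, drop = FALSE], 2L, cs[valid], "/")
  Z <- S_encoder %*% t(P_encoder[valid, , drop = FALSE])
  Zc <- sweep(Z, 2L, apply(Z, 2L, max))
  lsm <- sweep(Zc, 2L, log(colSums(exp(Zc))))
  iz <- which(a > 0)
  sum(a[iz] * log(a[iz])) - sum(a[iz] * lsm[iz])
}

#' Combine classification and regularisation losses
#'
#' @param focal Focal loss value.
#' @param kl KL regulariser value.
#' @param reg_alpha Regularisation weight; default 0.003.
#' @return `focal + reg_alpha * kl`.
#' @export
total_loss <- function(focal, kl, reg_alpha = 0.003) focal + reg_alpha * kl
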