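#' Model configuration
#'
#' Hyperparameters of the dual-view residue-graph network: a pooled
#' subgraph convolutional channel (initial-residual / identity-mapping
#' propagation on the pooled graph) and an edge-aware graph attention
#' channel, fused by scaled dot-product attention and read out by a
#' three-layer MLP.
#'
#' @param d_hidden width of hidden node embeddings (default 64).
#' @param n_layers_sub layer count of the subgraph convolutional stack.
#' @param n_layers_agat layer count of the attention channel.
#' @param alpha_prop initial-residual weight alpha in (0, 1): each layer
#'   mixes `alpha` of the layer-0 embedding back in.
#' @param lambda_decay lambda controlling the identity-mapping schedule
#'   `beta_l = log(lambda / l + 1)`.
#' @param beta_form `"decay"` (default, decreasing in depth) or
#'   `"printed"` for `log(lambda * l + 1)`.
#' @param pool_ratio fraction of nodes kept by graph pooling, in (0, 1].
#' @param n_heads attention heads (outputs averaged).
#' @param leaky_slope LeakyReLU slope in attention logits.
#' @param d_edge_hidden width of the edge-feature embedding inside
#'   attention.
#' @param dropout dropout rate on node embeddings between layers
#'   (disabled in eval mode).
#' @param n_classes number of output classes (2).
#' @param use_subgraph_channel,use_agat_channel,use_att_fusion ablation
#'   switches; at least one channel must stay enabled. With fusion off,
#'   the two channels are plainly concatenated.
#' @param seed RNG seed for parameter initialisation.
#' @return object of class `ppis_config`.
#' @export
ppis_config <- function(d_hidden = 64L, n_layers_sub = 2L, n_layers_agat = 4L,
                        alpha_prop = 0.7, lambda_decay = 1.5,
                        beta_form = c("decay", "printed"),
                        pool_ratio = 0.5, n_heads = 2L, leaky_slope = 0.2,
                        d_edge_hidden = 8L, dropout = 0.1, n_classes = 2L,
                        use_subgraph_channel = TRUE, use_agat_channel = TRUE,
                        use_att_fusion = TRUE, seed = 1L) {
  beta_form <- match.arg(beta_form)
  stopifnot(d_hidden >= 1L, n_layers_sub >= 0L, n_layers_agat >= 0L,
            alpha_prop >= 0, alpha_prop <= 1,
            lambda_decay >= 0, pool_ratio > 0, pool_ratio <= 1,
            dropout >= 0, dropout < 1, n_heads >= 1L,
            use_subgraph_channel || use_agat_channel)
  structure(list(
    d_hidden = as.integer(d_hidden), n_layers_sub = as.integer(n_layers_sub),
    n_layers_agat = as.integer(n_layers_agat), alpha_prop = alpha_prop,
    lambda_decay = lambda_decay, beta_form = beta_form,
    pool_ratio = pool_ratio, n_heads = as.integer(n_heads),
    leaky_slope = leaky_slope, d_edge_hidden = as.integer(d_edge_hidden),
    dropout = dropout, n_classes = as.integer(n_classes),
    use_subgraph_channel = use_subgraph_channel,
    use_agat_channel = use_agat_channel,
    use_att_fusion = use_att_fusion,
    d_sub = as.integer(d_hidden),
    seed = as.integer(seed)
  ), class = "ppis_config")
}

#' Symmetrically normalised propagation matrix
#'
#' `P = D^{-1/2} A D^{-1/2}` for a symmetric adjacency with self-loops;
#' `P[i, j] = 1 / sqrt(d_i d_j)` on edges, 0 elsewhere.
#'
#' @param adjacency logical or 0/1 symmetric matrix with self-loops.
#' @return numeric `[n x n]` matrix.
#' @export
normalized_propagation <- function(adjacency) {
  A <- adjacency * 1
  deg <- rowSums(A)
  stopifnot(all(deg >= 1))
  dinv <- 1 / sqrt(deg)
  A * outer(dinv, dinv)
}

#' Identity-mapping strength schedule
#'
#' `beta_l = log(lambda / l + 1)` (decreasing in depth, so deep layers
#' stay close to the identity); the literal increasing form
#' `log(lambda * l + 1)` is available via `form = "printed"`.
#'
#' @param l layer index, `l >= 1`.
#' @param lambda_decay nonnegative schedule constant.
#' @param form `"decay"` or `"printed"`.
#' @return numeric `beta_l`.
#' @export
beta_schedule <- function(l, lambda_decay, form = c("decay", "printed")) {
  form <- match.arg(form)
  stopifnot(all(l >= 1), lambda_decay >= 0)
  if (form == "decay") log(lambda_decay / l + 1) else log(lambda_decay * l + 1)
}

# ---- parameter initialisation ----

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialise model parameters
#'
#' Glorot-uniform initialisation of every weight matrix, seeded from the
#' config. The returned flat named list is the parameter set consumed by
#' [ppis_forward()] and updated by [ppis_fit()].
#'
#' @param d_node input node-feature width (62 handcrafted or 1024
#'   language-model).
#' @param config a [ppis_config()].
#' @param d_edge edge-feature width (2).
#' @return named list of numeric matrices.
#' @export
init_parameters <- function(d_node, config, d_edge = 2L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  d <- config$d_hidden
  p <- list(
    W_in = glorot(d_node, d),
    b_in = matrix(0, 1L, d)
  )
  if (config$use_subgraph_channel) {
    p$pool_w <- glorot(d, 1L)
    for (l in seq_len(config$n_layers_sub)) {
      p[[sprintf("sub_W%d", l)]] <- glorot(d, d)
    }
  }
  if (config$use_agat_channel) {
    de <- config$d_edge_hidden
    for (l in seq_len(config$n_layers_agat)) {
      for (h in seq_len(config$n_heads)) {
        tag <- sprintf("agat%d_h%d_", l, h)
        p[[paste0(tag, "Wh")]] <- glorot(d, d)
        p[[paste0(tag, "a_src")]] <- glorot(d, 1L)
        p[[paste0(tag, "a_dst")]] <- glorot(d, 1L)
        p[[paste0(tag, "We")]] <- glorot(d_edge, de)
        p[[paste0(tag, "a_edge")]] <- glorot(de, 1L)
      }
      p[[sprintf("agat%d_W", l)]] <- glorot(2L * d, d)
    }
  }
  d_in_mlp <- if (config$use_subgraph_channel && config$use_agat_channel) 2L * d else d
  d2 <- max(2L, d %/% 2L)
  p$mlp_W1 <- glorot(d_in_mlp, d); p$mlp_b1 <- matrix(0, 1L, d)
  p$mlp_W2 <- glorot(d, d2); p$mlp_b2 <- matrix(0, 1L, d2)
  p$mlp_W3 <- glorot(d2, config$n_classes)
  p$mlp_b3 <- matrix(0, 1L, config$n_classes)
  p
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# ---- tape-level layers (internal) ----

# learnable-score top-k pooling with sigmoid gating.
# Returns selected indices (ascending), the gated embedding node and the
# induced adjacency.
tape_graph_pool <- function(tape, H, adjacency, pool_w, pool_ratio) {
  n <- nrow(H$value)
  k <- max(1L, ceiling(pool_ratio * n))
  ssq <- ad_sum(tape, ad_mul(tape, pool_w, pool_w))
  inv_norm <- ad_pow_scalar(tape, ssq, -0.5)
  s <- ad_mul_scalar(tape, ad_mm(tape, H, pool_w), inv_norm)
  sv <- as.vector(s$value)
  idx <- sort(order(-sv)[seq_len(k)])  # top-k, ties broken by lower index
  gate <- ad_sigmoid(tape, ad_rows(tape, s, idx))
  H_sel <- ad_mul_colvec(tape, ad_rows(tape, H, idx), gate)
  list(idx = idx, H = H_sel,
       adjacency = adjacency[idx, idx, drop = FALSE])
}

# one subgraph-convolution layer:
# H' = relu(((1-a) P H + a H0) ((1-b) I + b W))
tape_subgraph_conv <- function(tape, H, H0, P_const, W, alpha, beta) {
  M <- ad_add(tape, ad_scale(tape, ad_mm(tape, P_const, H), 1 - alpha),
              ad_scale(tape, H0, alpha))
  ad_relu(tape, ad_add(tape, ad_scale(tape, M, 1 - beta),
                       ad_scale(tape, ad_mm(tape, M, W), beta)))
}

# edge-aware attention for one head; returns the aggregated embedding.
tape_agat_head <- function(tape, H, mask, edge_feat_const, edge_index,
                           Wh, a_src, a_dst, We, a_edge, slope) {
  n <- nrow(H$value)
  WhH <- ad_mm(tape, H, Wh)
  s_src <- ad_mm(tape, WhH, a_src)                      # n x 1
  s_dst <- ad_mm(tape, WhH, a_dst)
  e_emb <- ad_mm(tape, edge_feat_const, We)             # E x de
  e_scal <- ad_mm(tape, e_emb, a_edge)                  # E x 1
  E_dense <- ad_edge_to_dense(tape, e_scal, edge_index, n)
  ones_row <- ad_const(tape, matrix(1, 1L, n))
  ones_col <- ad_const(tape, matrix(1, n, 1L))
  logits <- ad_add(tape,
                   ad_add(tape, ad_mm(tape, s_src, ones_row),
                          ad_mm(tape, ones_col, ad_transpose(tape, s_dst))),
                   E_dense)
  coef <- ad_row_softmax(tape, ad_leaky_relu(tape, logits, slope), mask = mask)
  list(H = ad_mm(tape, coef, WhH), coef = coef)
}

# GCNII-style combination:
# H' = relu((1-b)((1-a) H_in + a H0) + b (H_in || H0) W),  W: [2d x d]
tape_gcnii <- function(tape, H_in, H0, W, alpha, beta) {
  M <- ad_add(tape, ad_scale(tape, H_in, 1 - alpha),
              ad_scale(tape, H0, alpha))
  ad_relu(tape, ad_add(tape, ad_scale(tape, M, 1 - beta),
                       ad_scale(tape, ad_mm(tape, ad_cbind(tape, H_in, H0), W),
                                beta)))
}

# scaled dot-product fusion: softmax(Hs Hs^T / sqrt(d_sub)) H_agat
tape_att_fusion <- function(tape, H_sub_full, H_agat, d_sub) {
  scores <- ad_scale(tape,
                     ad_mm(tape, H_sub_full, ad_transpose(tape, H_sub_full)),
                     1 / sqrt(d_sub))
  coef <- ad_row_softmax(tape, scores)
  list(H = ad_mm(tape, coef, H_agat), coef = coef)
}

tape_mlp_head <- function(tape, Hcat, params, dropout, training) {
  Z1 <- ad_relu(tape, ad_add_bias(tape, ad_mm(tape, Hcat, params$mlp_W1),
                                  params$mlp_b1))
  Z1 <- ad_dropout(tape, Z1, dropout, training)
  Z2 <- ad_relu(tape, ad_add_bias(tape, ad_mm(tape, Z1, params$mlp_W2),
                                  params$mlp_b2))
  Z3 <- ad_add_bias(tape, ad_mm(tape, Z2, params$mlp_W3), params$mlp_b3)
  ad_row_softmax(tape, Z3)
}

# full forward pass on a tape. `leaves` is the named list of parameter
# nodes (ad_param or ad_const). Returns the probs node plus diagnostics.
tape_forward <- function(tape, graph, leaves, config, training = FALSE) {
  n <- graph$n_residues
  d <- config$d_hidden
  X <- ad_const(tape, graph$node_features)
  H0 <- ad_relu(tape, ad_add_bias(tape, ad_mm(tape, X, leaves$W_in),
                                  leaves$b_in))
  H0 <- ad_dropout(tape, H0, config$dropout, training)
  aux <- list()

  H_sub_full <- NULL
  if (config$use_subgraph_channel) {
    pool <- tape_graph_pool(tape, H0, graph$adjacency, leaves$pool_w,
                            config$pool_ratio)
    aux$pool_idx <- pool$idx
    P_sub <- ad_const(tape, normalized_propagation(pool$adjacency))
    Hs0 <- pool$H
    Hs <- Hs0
    for (l in seq_len(config$n_layers_sub)) {
      beta <- beta_schedule(l, config$lambda_decay, config$beta_form)
      Hs <- tape_subgraph_conv(tape, Hs, Hs0, P_sub,
                               leaves[[sprintf("sub_W%d", l)]],
                               config$alpha_prop, beta)
      Hs <- ad_dropout(tape, Hs, config$dropout, training)
    }
    H_sub_full <- ad_scatter_rows(tape, Hs, pool$idx, n)
  }

  H_agat <- NULL
  if (config$use_agat_channel) {
    mask <- graph$adjacency
    ef <- ad_const(tape, graph$edge_features)
    Ha0 <- H0
    Ha <- Ha0
    for (l in seq_len(config$n_layers_agat)) {
      beta <- beta_schedule(l, config$lambda_decay, config$beta_form)
      heads <- vector("list", config$n_heads)
      for (h in seq_len(config$n_heads)) {
        tag <- sprintf("agat%d_h%d_", l, h)
        heads[[h]] <- tape_agat_head(tape, Ha, mask, ef, graph$edge_index,
                                     leaves[[paste0(tag, "Wh")]],
                                     leaves[[paste0(tag, "a_src")]],
                                     leaves[[paste0(tag, "a_dst")]],
                                     leaves[[paste0(tag, "We")]],
                                     leaves[[paste0(tag, "a_edge")]],
                                     config$leaky_slope)$H
      }
      H_in <- heads[[1L]]
      if (config$n_heads > 1L) {
        for (h in 2L:config$n_heads) H_in <- ad_add(tape, H_in, heads[[h]])
        H_in <- ad_scale(tape, H_in, 1 / config$n_heads)
      }
      Ha <- tape_gcnii(tape, H_in, Ha0, leaves[[sprintf("agat%d_W", l)]],
                       config$alpha_prop, beta)
      Ha <- ad_dropout(tape, Ha, config$dropout, training)
    }
    H_agat <- Ha
  }

  if (!is.null(H_sub_full) && !is.null(H_agat)) {
    if (config$use_att_fusion) {
      fus <- tape_att_fusion(tape, H_sub_full, H_agat, config$d_sub)
      aux$fusion_coef <- fus$coef$value
      Hcat <- ad_cbind(tape, fus$H, H_agat)
    } else {
      Hcat <- ad_cbind(tape, H_sub_full, H_agat)
    }
  } else if (!is.null(H_agat)) {
    Hcat <- H_agat
  } else {
    Hcat <- H_sub_full
  }
  probs <- tape_mlp_head(tape, Hcat, leaves, config$dropout, training)
  list(probs = probs, aux = aux)
}

# ---- plain-matrix wrappers (single source of truth: the tape ops) ----

#' Graph pooling by learnable score with sigmoid gating
#'
#' Scores `s = H w / ||w||`, keeps the top `ceiling(pool_ratio * n)`
#' nodes (ties broken by lower index; at least one node is kept), gates
#' the kept rows by `sigmoid(s)` so the score vector stays trainable,
#' and induces the subgraph adjacency (self-loops retained).
#'
#' @param H numeric `[n x d]` embedding.
#' @param adjacency logical `[n x n]` with self-loops.
#' @param pool_w numeric `[d x 1]` score vector.
#' @param pool_ratio fraction of nodes kept.
#' @return list with `idx` (ascending), `H` (gated rows) and
#'   `adjacency` (induced).
#' @export
graph_pool <- function(H, adjacency, pool_w, pool_ratio) {
  tp <- ad_tape()
  out <- tape_graph_pool(tp, ad_const(tp, H), adjacency,
                         ad_const(tp, pool_w), pool_ratio)
  list(idx = out$idx, H = out$H$value, adjacency = out$adjacency)
}

#' One subgraph-convolution layer
#'
#' `H_next = relu(((1 - alpha) P H + alpha H0) ((1 - beta) I + beta W))`:
#' graph propagation with an initial-residual connection to the layer-0
#' embedding and an identity-mapped weight.
#'
#' @param H,H0 current and layer-0 embeddings `[k x d]`.
#' @param P normalised propagation matrix of the pooled graph.
#' @param W layer weight `[d x d]`.
#' @param alpha,beta layer hyperparameters.
#' @return numeric `[k x d]`.
#' @export
subgraph_conv_layer <- function(H, H0, P, W, alpha, beta) {
  tp <- ad_tape()
  tape_subgraph_conv(tp, ad_const(tp, H), ad_const(tp, H0), ad_const(tp, P),
                     ad_const(tp, W), alpha, beta)$value
}

#' Edge-aware graph attention aggregation (one head)
#'
#' Attention logits over the neighbourhood of each node (self included)
#' are `LeakyReLU(a_src' Wh h_i + a_dst' Wh h_j + a_edge' We e_ij)`,
#' softmax-normalised over the neighbours; the output is the
#' coefficient-weighted sum of transformed neighbour embeddings.
#'
#' @param H numeric `[n x d]`.
#' @param adjacency logical `[n x n]` with self-loops.
#' @param edge_index integer `[2 x E]` of ordered adjacent pairs.
#' @param edge_features numeric `[E x d_edge]`.
#' @param Wh,a_src,a_dst,We,a_edge head parameters.
#' @param slope LeakyReLU slope.
#' @return list with `H` (`[n x d]`) and `coef` (`[n x n]`, rows sum to
#'   1 over neighbourhoods).
#' @export
agat_attention_layer <- function(H, adjacency, edge_index, edge_features,
                                 Wh, a_src, a_dst, We, a_edge, slope = 0.2) {
  ne <- ncol(edge_index)
  have <- adjacency[t(edge_index)]
  if (!all(have)) stop("edge_index contains non-adjacent pairs")
  n_adj <- sum(adjacency)
  if (ne != n_adj) stop("missing edge feature for an adjacent pair")
  tp <- ad_tape()
  out <- tape_agat_head(tp, ad_const(tp, H), adjacency,
                        ad_const(tp, edge_features), edge_index,
                        ad_const(tp, Wh), ad_const(tp, a_src),
                        ad_const(tp, a_dst), ad_const(tp, We),
                        ad_const(tp, a_edge), slope)
  list(H = out$H$value, coef = out$coef$value)
}

#' GCNII-style layer with concatenated identity mapping
#'
#' `H_next = relu((1 - beta)((1 - alpha) H_in + alpha H0)
#'   + beta (H_in || H0) W)` with `W` of shape `[2d x d]`.
#'
#' @param H_in aggregated (attention-propagated) embedding `[n x d]`.
#' @param H0 layer-0 embedding `[n x d]`.
#' @param W weight `[2d x d]`.
#' @param alpha,beta layer hyperparameters.
#' @return numeric `[n x d]`.
#' @export
gcnii_layer <- function(H_in, H0, W, alpha, beta) {
  if (nrow(W) != 2L * ncol(H_in) || ncol(W) != ncol(H_in)) {
    stop(sprintf("W must be [2d x d] = [%d x %d], got [%d x %d]",
                 2L * ncol(H_in), ncol(H_in), nrow(W), ncol(W)))
  }
  tp <- ad_tape()
  tape_gcnii(tp, ad_const(tp, H_in), ad_const(tp, H0), ad_const(tp, W),
             alpha, beta)$value
}

#' Attention fusion of the two views
#'
#' `H_att = softmax(H_sub H_sub' / sqrt(d_sub)) H_agat` (row-wise
#' softmax): the subgraph embeddings, scattered back to all residues,
#' act as query/key and the full-graph embeddings as value.
#'
#' @param H_sub_full `[n x d_sub]` pooled-channel output scattered to all
#'   n residues (non-selected rows zero).
#' @param H_agat `[n x d]` attention-channel output.
#' @return list with `H` (`[n x d]`) and `coef` (`[n x n]`).
#' @export
att_fusion <- function(H_sub_full, H_agat) {
  if (nrow(H_sub_full) != nrow(H_agat)) stop("row-count mismatch")
  tp <- ad_tape()
  out <- tape_att_fusion(tp, ad_const(tp, H_sub_full), ad_const(tp, H_agat),
                         ncol(H_sub_full))
  list(H = out$H$value, coef = out$coef$value)
}

#' MLP readout head
#'
#' Three-layer MLP on the concatenated fused and attention-channel
#' embeddings; final width 2 with row-wise softmax.
#'
#' @param H_att,H_agat `[n x d]` embeddings to concatenate.
#' @param params parameter list holding `mlp_W1..3`, `mlp_b1..3`.
#' @param threshold call threshold on the positive class.
#' @return a `prediction_result`: list with `probs` (`[n x 2]`), `calls`
#'   (0/1) and `threshold`.
#' @export
mlp_head <- function(H_att, H_agat, params, threshold = 0.5) {
  if (nrow(H_att) != nrow(H_agat)) stop("row-count mismatch")
  tp <- ad_tape()
  probs <- tape_mlp_head(tp, ad_const(tp, cbind(H_att, H_agat)),
                         lapply(params, function(p) ad_const(tp, p)),
                         dropout = 0, training = FALSE)$value
  prediction_result(probs, threshold)
}

#' @noRd
prediction_result <- function(probs, threshold = 0.5) {
  structure(list(probs = probs,
                 calls = as.integer(probs[, 2L] >= threshold),
                 threshold = threshold),
            class = "prediction_result")
}

#' Run the full network on one residue graph
#'
#' Pipeline: shared input projection, then in parallel the pooled
#' subgraph convolutional channel (scattered back to all residues) and
#' the edge-aware attention channel, fused by scaled dot-product
#' attention and read out by the MLP head. Deterministic in eval mode.
#'
#' @param graph a [residue_graph()].
#' @param params parameter list from [init_parameters()].
#' @param config a [ppis_config()].
#' @param threshold call threshold.
#' @return a `prediction_result` (probs, calls, threshold).
#' @export
ppis_forward <- function(graph, params, config, threshold = 0.5) {
  tp <- ad_tape()
  leaves <- lapply(params, function(p) ad_const(tp, p))
  out <- tape_forward(tp, graph, leaves, config, training = FALSE)
  prediction_result(out$probs$value, threshold)
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result: %d residues, %d called interacting (threshold %g)\n",
              nrow(x$probs), sum(x$calls), x$threshold))
  invisible(x)
}
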