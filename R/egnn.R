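#' Configuration of the equivariant message-passing scorer
#'
#' Desk-scale defaults: 64-dimensional invariant node embeddings, 16-d edge
#' features, 3 stacked blocks, 4 attention heads. `coord_scale` bounds the
#' per-edge coordinate-update gate (tanh output times this factor) for
#' numerical stability of the equivariant coordinate stream.
#'
#' @param dim_h Node embedding dimension D (divisible by `n_heads`).
#' @param dim_e Edge feature dimension.
#' @param n_layers Number of stacked attention/message/update blocks T.
#' @param n_heads Attention heads.
#' @param head_hidden Hidden width of the scalar prediction head.
#' @param n_bins Number of distance bins one-hot encoded in edge inputs.
#' @param coord_scale Gate scale of the coordinate update.
#' @return List of configuration values.
#' @export
egnn_config <- function(dim_h = 64, dim_e = 16, n_layers = 3, n_heads = 4,
                        head_hidden = 32, n_bins = 16, coord_scale = 0.1) {
  stopifnot(dim_h %% n_heads == 0)
  list(dim_h = dim_h, dim_e = dim_e, n_layers = n_layers,
       n_heads = n_heads, head_hidden = head_hidden, n_bins = n_bins,
       coord_scale = coord_scale)
}

.eg_elements <- c("C", "N", "O", "S", "P", "F", "CL", "BR", "I", "X")
.eg_kinds <- c("protein", "ligand_atom", "aromatic_virtual")
.eg_edge_types <- c("contact", "prot_adj", "covalent", "ring_member",
                    "hbond", "pi_pi", "cation_pi", "salt_bridge")

one_hot <- function(x, levels) {
  m <- matrix(0, length(x), length(levels))
  hit <- match(x, levels)
  ok <- !is.na(hit)
  m[cbind(which(ok), hit[ok])] <- 1
  m
}

#' Encode a complex graph into numeric scorer inputs
#'
#' Node inputs: one-hot kind and element, scaled degree, aromaticity flag and
#' charge class. Edge inputs: one-hot channel, type and distance bin. The
#' directed edge list of the graph is used as-is (both directions present).
#'
#' @param graph A `complex_graph`.
#' @param config [egnn_config()].
#' @return List: `Fn` (node input matrix), `Fe` (edge input matrix), `src`,
#'   `dst`, `x0` (coordinates), `pool_ids` (ligand + virtual node ids).
#' @export
egnn_prepare <- function(graph, config = egnn_config()) {
  nd <- graph$nodes
  if (length(graph$ligand_node_ids) == 0L) stop("empty ligand")
  Fn <- cbind(
    one_hot(nd$kind, .eg_kinds),
    one_hot(toupper(nd$element), .eg_elements),
    (nd$degree %||% rep(0L, nrow(nd))) / 4,
    as.numeric(nd$aromatic %||% rep(FALSE, nrow(nd))),
    as.numeric(nd$charge %||% rep(0L, nrow(nd)))
  )
  ed <- graph$edges
  bin <- ifelse(is.na(ed$bin), -1L, pmin(ed$bin, config$n_bins - 1L))
  Fe <- cbind(
    one_hot(ed$channel, c("geometric", "structural")),
    one_hot(ed$type, .eg_edge_types),
    one_hot(bin, seq(0L, config$n_bins - 1L))
  )
  list(Fn = Fn, Fe = Fe, src = ed$src, dst = ed$dst,
       x0 = as.matrix(nd[, c("x", "y", "z")]),
       pool_ids = sort(c(graph$ligand_node_ids, graph$virtual_node_ids)))
}

#' Initialize scorer parameters
#'
#' Gaussian initialization (sd 0.1; the coordinate-gate weights at sd 0.01 to
#' start near the identity coordinate map). Parameters are a flat named list
#' of matrices; layer-specific blocks are prefixed `l<t>.`.
#'
#' @param n_node_feat,n_edge_feat Input feature widths (from
#'   [egnn_prepare()]: `ncol(Fn)`, `ncol(Fe)`).
#' @param config [egnn_config()].
#' @param seed RNG seed.
#' @return Named list of numeric matrices.
#' @export
egnn_init <- function(n_node_feat, n_edge_feat, config = egnn_config(),
                      seed = 1L) {
  set.seed(seed)
  D <- config$dim_h; E <- config$dim_e; H <- config$n_heads
  rnd <- function(r, c, sd = 0.1) matrix(stats::rnorm(r * c, 0, sd), r, c)
  p <- list(
    W_nembed = rnd(n_node_feat, D), b_nembed = matrix(0, 1, D),
    W_eembed = rnd(n_edge_feat, E), b_eembed = matrix(0, 1, E)
  )
  for (t in seq_len(config$n_layers)) {
    pre <- paste0("l", t, ".")
    lp <- list(
      Wq = rnd(D, D), Wk = rnd(D, D), Wv = rnd(D, D),
      wb = rnd(E, H), Wo = rnd(D, D), bo = matrix(0, 1, D),
      We1 = rnd(H, E), be1 = matrix(0, 1, E),
      We2 = rnd(E, E), be2 = matrix(0, 1, E),
      Wm1 = rnd(2 * D + 1 + E, D), bm1 = matrix(0, 1, D),
      Wm2 = rnd(D, D), bm2 = matrix(0, 1, D),
      wx = rnd(D, 1, 0.01), bx = matrix(0, 1, 1),
      Wh1 = rnd(2 * D, D), bh1 = matrix(0, 1, D),
      Wh2 = rnd(D, D), bh2 = matrix(0, 1, D)
    )
    names(lp) <- paste0(pre, names(lp))
    p <- c(p, lp)
  }
  p$Wp1 <- rnd(D, config$head_hidden); p$bp1 <- matrix(0, 1, config$head_hidden)
  p$wp2 <- rnd(config$head_hidden, 1); p$bp2 <- matrix(0, 1, 1)
  p
}

# two-layer MLP: relu(inp W1 + b1) W2 + b2
.eg_mlp2 <- function(tape, inp, W1, b1, W2, b2) {
  z <- tp_relu(tape, tp_addbias(tape, tp_matmul(tape, inp, W1), b1))
  tp_addbias(tape, tp_matmul(tape, z, W2), b2)
}

# Full tape forward pass. prep from egnn_prepare(); pn = named list of tape
# nodes for the parameters. Returns tape nodes (score, penultimate, coords).
.eg_forward_tp <- function(tape, prep, pn, config) {
  D <- config$dim_h; H <- config$n_heads; dk <- D / H
  n <- nrow(prep$Fn)
  nE <- length(prep$src)
  h <- tp_addbias(tape, tp_matmul(tape, tp_const(tape, prep$Fn),
                                  pn$W_nembed), pn$b_nembed)
  x <- tp_const(tape, prep$x0)
  a <- if (nE > 0) {
    tp_addbias(tape, tp_matmul(tape, tp_const(tape, prep$Fe),
                               pn$W_eembed), pn$b_eembed)
  } else NULL
  src_a <- c(prep$src, seq_len(n))   # attention includes self-loops
  dst_a <- c(prep$dst, seq_len(n))
  for (t in seq_len(config$n_layers)) {
    P <- function(nm) pn[[paste0("l", t, ".", nm)]]
    # --- information-aware attention ---
    q <- tp_matmul(tape, h, P("Wq"))
    k <- tp_matmul(tape, h, P("Wk"))
    v <- tp_matmul(tape, h, P("Wv"))
    heads <- list(); alphas_real <- list()
    for (hd in seq_len(H)) {
      cols <- ((hd - 1) * dk + 1):(hd * dk)
      sub <- function(m) tp_node(tape, m$val[, cols, drop = FALSE],
                                 list(m), local({
        cc <- cols; mm <- m
        function(g) {
          gm <- matrix(0, nrow(mm$val), ncol(mm$val))
          gm[, cc] <- g
          tp_acc(mm, gm)
        }
      }))
      qh <- sub(q); kh <- sub(k); vh <- sub(v)
      logits <- tp_scale(tape, tp_rowsums(tape, tp_mul(
        tape, tp_rows(tape, qh, dst_a), tp_rows(tape, kh, src_a))),
        1 / sqrt(dk))
      if (nE > 0) {
        wb_col <- tp_node(tape, P("wb")$val[, hd, drop = FALSE],
                          list(P("wb")), local({
          hh <- hd; wb <- P("wb")
          function(g) {
            gm <- matrix(0, nrow(wb$val), ncol(wb$val))
            gm[, hh] <- g
            tp_acc(wb, gm)
          }
        }))
        bias_real <- tp_matmul(tape, a, wb_col)
        bias <- tp_rbind(tape, bias_real, tp_const(tape, matrix(0, n, 1)))
        logits <- tp_add(tape, logits, bias)
      }
      alpha <- tp_group_softmax(tape, logits, dst_a, n)
      heads[[hd]] <- tp_scatter(
        tape, tp_colmul(tape, tp_rows(tape, vh, src_a), alpha), dst_a, n)
      if (nE > 0) alphas_real[[hd]] <- tp_rows(tape, alpha, seq_len(nE))
    }
    att <- tp_addbias(tape, tp_matmul(
      tape, do.call(tp_cbind, c(list(tape), heads)), P("Wo")), P("bo"))
    h <- tp_add(tape, h, att)
    if (nE > 0) {
      # --- edge update from projected attention values ---
      A <- do.call(tp_cbind, c(list(tape), alphas_real))
      upd <- .eg_mlp2(tape, A, P("We1"), P("be1"), P("We2"), P("be2"))
      a <- tp_add(tape, a, upd)
      # --- edge messages, Eq (1) ---
      xs <- tp_rows(tape, x, prep$src)
      xd <- tp_rows(tape, x, prep$dst)
      diff <- tp_sub(tape, xd, xs)              # x_i - x_j, i = dst
      dist <- tp_sqrt(tape, tp_add(
        tape, tp_rowsums(tape, tp_mul(tape, diff, diff)),
        tp_const(tape, matrix(1e-12, nE, 1))))
      m_e <- .eg_mlp2(tape, tp_cbind(
        tape, tp_rows(tape, h, prep$dst), tp_rows(tape, h, prep$src),
        dist, a), P("Wm1"), P("bm1"), P("Wm2"), P("bm2"))
      # --- coordinate update, Eq (2) ---
      gate <- tp_scale(tape, tp_tanh(tape, tp_addbias(
        tape, tp_matmul(tape, m_e, P("wx")), P("bx"))),
        config$coord_scale)
      x <- tp_add(tape, x,
                  tp_scatter(tape, tp_colmul(tape, diff, gate),
                             prep$dst, n))
      # --- aggregation, Eq (3) ---
      m_i <- tp_scatter(tape, m_e, prep$dst, n)
    } else {
      m_i <- tp_const(tape, matrix(0, n, D))
    }
    # --- node update, Eq (4) ---
    h <- tp_add(tape, h, .eg_mlp2(tape, tp_cbind(tape, h, m_i),
                                  P("Wh1"), P("bh1"), P("Wh2"), P("bh2")))
  }
  pool <- matrix(0, 1, n)
  pool[1, prep$pool_ids] <- 1 / length(prep$pool_ids)
  p_vec <- tp_matmul(tape, tp_const(tape, pool), h)
  z <- tp_relu(tape, tp_addbias(tape, tp_matmul(tape, p_vec, pn$Wp1),
                                pn$bp1))
  score <- tp_addbias(tape, tp_matmul(tape, z, pn$wp2), pn$bp2)
  list(score = score, penultimate = p_vec, coords = x)
}

#' Forward pass of the equivariant scorer
#'
#' Runs the stacked attention / message / coordinate / node-update blocks and
#' the scalar head on one complex graph. The score and penultimate feature
#' depend on coordinates only through interatomic distances, so they are
#' invariant under rigid motions, while the returned coordinates transform
#' equivariantly.
#'
#' @param graph A `complex_graph`, or a prepared input from
#'   [egnn_prepare()].
#' @param params Parameter list from [egnn_init()] (or a trained scorer's
#'   `$params`).
#' @param config [egnn_config()] matching `params`.
#' @return List: `score` (scalar, pre-sigmoid), `penultimate` (numeric
#'   vector, the pooled pre-head complex representation), `coords` (final
#'   equivariant coordinates).
#' @export
egnn_forward <- function(graph, params, config = egnn_config()) {
  prep <- if (inherits(graph, "complex_graph")) {
    egnn_prepare(graph, config)
  } else graph
  tape <- tape_new()
  pn <- lapply(params, function(v) tp_node(tape, v))
  out <- .eg_forward_tp(tape, prep, pn, config)
  list(score = out$score$val[1, 1],
       penultimate = as.vector(out$penultimate$val),
       coords = out$coords$val)
}

# loss and gradients of binary cross-entropy over a list of prepared graphs
.eg_loss_grads <- function(preps, labels, params, config) {
  grads <- lapply(params, function(v) matrix(0, nrow(v), ncol(v)))
  total <- 0
  for (i in seq_along(preps)) {
    tape <- tape_new()
    pn <- lapply(params, function(v) tp_node(tape, v))
    out <- .eg_forward_tp(tape, preps[[i]], pn, config)
    s <- out$score
    # BCE via softplus: log(1 + exp(s)) - y * s
    sp <- tp_log(tape, tp_add(tape, tp_const(tape, matrix(1, 1, 1)),
                              tp_exp(tape, s)))
    loss <- tp_sub(tape, sp, tp_scale(tape, s, labels[i]))
    tp_backward(tape, loss)
    total <- total + loss$val[1, 1]
    for (nm in names(params)) {
      if (!is.null(pn[[nm]]$grad)) {
        grads[[nm]] <- grads[[nm]] + pn[[nm]]$grad
      }
    }
  }
  list(loss = total / length(preps),
       grads = lapply(grads, function(g) g / length(preps)))
}

#' Train the equivariant scorer on labelled complex graphs
#'
#' Minimizes binary cross-entropy with Adam, full-batch, under a fixed seed.
#' Intended for desk-scale pretraining on synthetic complexes; the trained
#' trunk is then frozen and its penultimate features reused by the
#' transfer-learning head (see [train_tl_head()]).
#'
#' @param graphs List of `complex_graph` objects.
#' @param labels Binary labels (0/1), both classes present.
#' @param config [egnn_config()].
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param seed RNG seed for initialization.
#' @return An `egnn_scorer`: list with `params`, `config`, `loss_history`.
#' @export
train_scorer <- function(graphs, labels, config = egnn_config(),
                         epochs = 100, lr = 0.01, seed = 1L) {
  if (length(unique(labels)) < 2L) stop("need both classes present")
  preps <- lapply(graphs, egnn_prepare, config = config)
  params <- egnn_init(ncol(preps[[1]]$Fn), ncol(preps[[1]]$Fe), config,
                      seed = seed)
  opt <- adam_state(params)
  loss_hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    lg <- .eg_loss_grads(preps, labels, params, config)
    loss_hist[ep] <- lg$loss
    if (lr > 0) {
      upd <- adam_step(opt, params, lg$grads, lr)
      params <- upd$params; opt <- upd$state
    }
  }
  structure(list(params = params, config = config,
                 loss_history = loss_hist),
            class = "egnn_scorer")
}

#' @export
print.egnn_scorer <- function(x, ...) {
  cat(sprintf("<egnn_scorer> D=%d, E=%d, T=%d; final loss %.4f\n",
              x$config$dim_h, x$config$dim_e, x$config$n_layers,
              utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Score complexes and extract penultimate features with a trained scorer
#'
#' @param scorer An `egnn_scorer` from [train_scorer()].
#' @param graphs A `complex_graph` or list of them.
#' @return Tibble: `graph` (index), `score` (logit), `prob`
#'   (sigmoid), and a `penultimate` list-column of feature vectors.
#' @export
egnn_score <- function(scorer, graphs) {
  if (inherits(graphs, "complex_graph")) graphs <- list(graphs)
  rows <- lapply(seq_along(graphs), function(i) {
    out <- egnn_forward(graphs[[i]], scorer$params, scorer$config)
    tibble::tibble(graph = i, score = out$score,
                   prob = 1 / (1 + exp(-out$score)),
                   penultimate = list(out$penultimate))
  })
  dplyr::bind_rows(rows)
}

#' Save / load scorer weights as a portable JSON manifest
#' @param scorer An `egnn_scorer`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_scorer()` returns the scorer.
#' @export
write_scorer <- function(scorer, path) {
  jsonlite::write_json(list(
    config = scorer$config,
    params = lapply(scorer$params, function(m) {
      list(dim = dim(m), data = as.vector(m))
    }),
    loss_history = scorer$loss_history
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scorer
#' @export
read_scorer <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(x$params, function(p) {
    matrix(p$data, p$dim[1], p$dim[2])
  })
  structure(list(params = params, config = as.list(x$config),
                 loss_history = x$loss_history),
            class = "egnn_scorer")
}

adam_state <- function(params) {
  list(m = lapply(params, function(v) v * 0),
       v = lapply(params, function(v) v * 0), t = 0L)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- standalone operation surface (single implementation via the tape) ----

#' Single edge message (Eq-style building block)
#'
#' Computes the message m_ij = phi_e(h_i, h_j, ||x_i - x_j||, a_ij) for one
#' edge, with phi_e a two-layer ReLU MLP. Coordinates enter only through the
#' scalar distance, so the message is invariant under rigid motions.
#'
#' @param h_i,h_j Receiver / sender embeddings (numeric vectors, length D).
#' @param dist Scalar distance ||x_i - x_j||.
#' @param a_ij Edge feature vector (length E).
#' @param weights List `W1`, `b1`, `W2`, `b2` with `nrow(W1) = 2D + 1 + E`.
#' @return Numeric message vector.
#' @export
edge_message <- function(h_i, h_j, dist, a_ij, weights) {
  inp <- matrix(c(h_i, h_j, dist, a_ij), 1)
  if (nrow(weights$W1) != ncol(inp)) {
    stop("dimension mismatch: W1 expects ", nrow(weights$W1),
         " inputs, got ", ncol(inp))
  }
  tape <- tape_new()
  out <- .eg_mlp2(tape, tp_const(tape, inp),
                  tp_const(tape, weights$W1), tp_const(tape, weights$b1),
                  tp_const(tape, weights$W2), tp_const(tape, weights$b2))
  as.vector(out$val)
}

#' Equivariant coordinate update over a directed edge list (Eq-style)
#'
#' x_i' = x_i + sum_j (x_i - x_j) * phi_x(m_ij), where `gate[e]` holds the
#' already-evaluated scalar phi_x(m_ij) for edge e = (src j -> dst i).
#'
#' @param x Coordinates (n x 3).
#' @param src,dst Directed edge lists (j -> i).
#' @param gate Numeric vector of per-edge scalars phi_x(m_ij).
#' @return Updated coordinate matrix.
#' @export
coord_update <- function(x, src, dst, gate) {
  if (length(src) == 0L) return(x)
  diff <- x[dst, , drop = FALSE] - x[src, , drop = FALSE]
  contrib <- diff * gate
  agg <- rowsum(contrib, group = dst)
  out <- x
  rows <- as.integer(rownames(agg))
  out[rows, ] <- out[rows, ] + agg
  out
}

#' Aggregate directed edge messages per receiving node (Eq-style)
#'
#' m_i = sum over incoming edges of m_ij; elementwise, order-independent.
#'
#' @param messages Matrix (n_edges x D) of per-edge messages.
#' @param dst Receiving node index per edge.
#' @param n Number of nodes.
#' @return Matrix (n x D); zero rows for nodes without neighbors.
#' @export
aggregate_messages <- function(messages, dst, n) {
  out <- matrix(0, n, ncol(messages))
  if (length(dst)) {
    agg <- rowsum(messages, group = dst)
    out[as.integer(rownames(agg)), ] <- agg
  }
  out
}

#' Residual node update (Eq-style)
#'
#' h_i' = h_i + phi_h(h_i, m_i) with phi_h a two-layer ReLU MLP on the
#' concatenation.
#'
#' @param h Node embeddings (n x D).
#' @param m Aggregated messages (n x D).
#' @param weights List `W1` (2D x D), `b1`, `W2` (D x D), `b2`.
#' @return Updated embeddings (n x D).
#' @export
node_update <- function(h, m, weights) {
  inp <- cbind(h, m)
  if (nrow(weights$W1) != ncol(inp)) stop("dimension mismatch in node_update")
  tape <- tape_new()
  upd <- .eg_mlp2(tape, tp_const(tape, inp),
                  tp_const(tape, weights$W1), tp_const(tape, weights$b1),
                  tp_const(tape, weights$W2), tp_const(tape, weights$b2))
  h + upd$val
}

#' Neighborhood-masked attention mixing (standalone)
#'
#' Scaled-dot-product self-attention restricted to graph neighborhoods (plus
#' the self-loop), with an additive per-head edge-feature bias on the logits.
#' Returns the mixed embeddings and the row-stochastic attention weights.
#'
#' @param h Node embeddings (n x D).
#' @param src,dst Directed edge lists.
#' @param edge_feats Edge feature matrix (n_edges x E), or NULL.
#' @param params List with `Wq`, `Wk`, `Wv` (D x D), `wb` (E x n_heads),
#'   `Wo` (D x D), `bo` (1 x D).
#' @param n_heads Attention heads (D divisible by it).
#' @return List: `h` (updated, residual-added), `alpha` (matrix n_edges x
#'   n_heads of attention weights on the real edges), and `alpha_full` /
#'   `dst_full` covering the self-loops too; weights per query (real
#'   neighbors + self-loop) sum to 1.
#' @export
attention_block <- function(h, src, dst, edge_feats, params, n_heads = 4) {
  n <- nrow(h); D <- ncol(h); dk <- D / n_heads
  nE <- length(src)
  src_a <- c(src, seq_len(n)); dst_a <- c(dst, seq_len(n))
  heads <- list(); alphas <- matrix(NA_real_, nE, n_heads)
  alphas_full <- matrix(NA_real_, nE + n, n_heads)
  for (hd in seq_len(n_heads)) {
    cols <- ((hd - 1) * dk + 1):(hd * dk)
    q <- h %*% params$Wq[, cols, drop = FALSE]
    k <- h %*% params$Wk[, cols, drop = FALSE]
    v <- h %*% params$Wv[, cols, drop = FALSE]
    logits <- rowSums(q[dst_a, , drop = FALSE] *
                        k[src_a, , drop = FALSE]) / sqrt(dk)
    if (nE > 0 && !is.null(edge_feats)) {
      logits <- logits + c(edge_feats %*% params$wb[, hd], rep(0, n))
    }
    mx <- tapply(logits, dst_a, max)
    num <- exp(logits - mx[as.character(dst_a)])
    den <- tapply(num, dst_a, sum)
    alpha <- as.vector(num / den[as.character(dst_a)])
    mixed <- aggregate_messages(v[src_a, , drop = FALSE] * alpha, dst_a, n)
    heads[[hd]] <- mixed
    alphas_full[, hd] <- alpha
    if (nE > 0) alphas[, hd] <- alpha[seq_len(nE)]
  }
  out <- do.call(cbind, heads) %*% params$Wo +
    matrix(params$bo, n, D, byrow = TRUE)
  list(h = h + out, alpha = alphas, alpha_full = alphas_full,
       dst_full = dst_a)
}

#' Update edge features from projected attention values (standalone)
#'
#' a' = a + P2(relu(P1(alpha))): the per-edge vector of per-head attention
#' weights is projected into the edge-feature space through two projection
#' modules and residual-added. Zero projections leave edges unchanged.
#'
#' @param alpha Attention weights (n_edges x n_heads).
#' @param edge_feats Edge features (n_edges x E).
#' @param params List `We1` (n_heads x E), `be1`, `We2` (E x E), `be2`.
#' @return Updated edge feature matrix.
#' @export
edge_update <- function(alpha, edge_feats, params) {
  z <- pmax(alpha %*% params$We1 +
              matrix(params$be1, nrow(alpha), ncol(params$We1),
                     byrow = TRUE), 0)
  edge_feats + z %*% params$We2 +
    matrix(params$be2, nrow(alpha), ncol(params$We2), byrow = TRUE)
}
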