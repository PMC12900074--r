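test_that("edge messages depend on coordinates only through the distance", {
  D <- 4; E <- 3
  set.seed(41)
  w <- list(W1 = matrix(stats::rnorm((2 * D + 1 + E) * D, 0, 0.3),
                        2 * D + 1 + E, D),
            b1 = matrix(0.1, 1, D),
            W2 = matrix(stats::rnorm(D * D, 0, 0.3), D, D),
            b2 = matrix(-0.2, 1, D))
  h_i <- stats::rnorm(D); h_j <- stats::rnorm(D); a <- stats::rnorm(E)
  m1 <- edge_message(h_i, h_j, dist = 2.5, a, w)
  expect_length(m1, D)
  # all-zero weights give the bias path only
  w0 <- lapply(w, function(m) m * 0)
  w0$b2 <- matrix(7, 1, D)
  expect_equal(edge_message(h_i, h_j, 2.5, a, w0), rep(7, D))
  # same distance, different coordinates realizing it: identical message
  m2 <- edge_message(h_i, h_j, sqrt(sum((c(1.5, 2, 0) - c(0, 0, 0))^2)), a, w)
  m3 <- edge_message(h_i, h_j, 2.5, a, w)
  expect_identical(m3, m1)
  expect_equal(m2, m1)  # |(1.5,2,0)| = 2.5
  expect_error(edge_message(h_i[1:2], h_j, 2.5, a, w), "mismatch")
})

test_that("coordinate update matches the hand-expanded two-node case", {
  x <- rbind(c(0, 0, 0), c(1, 0, 0))
  # phi_x == 0 leaves coordinates untouched
  expect_equal(coord_update(x, src = c(2, 1), dst = c(1, 2),
                            gate = c(0, 0)), x)
  # two-node system with constant gate c: x1' = x1 + c (x1 - x2)
  cc <- 0.3
  out <- coord_update(x, src = 2, dst = 1, gate = cc)
  expect_equal(out[1, ], x[1, ] + cc * (x[1, ] - x[2, ]))
  expect_equal(out[2, ], x[2, ])
  # symmetric neighbors with equal gates cancel
  x3 <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0))
  out3 <- coord_update(x3, src = c(2, 3), dst = c(1, 1), gate = c(0.5, 0.5))
  expect_equal(out3[1, ], x3[1, ])
})

test_that("message aggregation is a permutation-invariant neighbor sum", {
  m <- rbind(c(1, 1), c(1, 1), c(2, 0))
  agg <- aggregate_messages(m, dst = c(1, 1, 3), n = 3)
  expect_equal(agg[1, ], c(2, 2))
  expect_equal(agg[2, ], c(0, 0))   # no neighbors -> zero vector
  expect_equal(agg[3, ], c(2, 0))
  perm <- c(3, 1, 2)
  expect_equal(aggregate_messages(m[perm, ], dst = c(1, 1, 3)[perm], n = 3),
               agg)
})

test_that("node update is residual: zero MLP output preserves h", {
  D <- 4
  h <- matrix(stats::rnorm(8), 2, D)
  m <- matrix(0, 2, D)
  w0 <- list(W1 = matrix(0, 2 * D, D), b1 = matrix(0, 1, D),
             W2 = matrix(0, D, D), b2 = matrix(0, 1, D))
  expect_equal(node_update(h, m, w0), h)
  # deterministic under fixed weights
  set.seed(42)
  w <- list(W1 = matrix(stats::rnorm(2 * D * D, 0, 0.3), 2 * D, D),
            b1 = matrix(0, 1, D),
            W2 = matrix(stats::rnorm(D * D, 0, 0.3), D, D),
            b2 = matrix(0, 1, D))
  expect_identical(node_update(h, m, w), node_update(h, m, w))
})

test_that("attention weights are row-stochastic and neighborhood-masked", {
  D <- 8; H <- 2
  set.seed(43)
  params <- list(Wq = matrix(stats::rnorm(D * D, 0, 0.3), D, D),
                 Wk = matrix(stats::rnorm(D * D, 0, 0.3), D, D),
                 Wv = matrix(stats::rnorm(D * D, 0, 0.3), D, D),
                 wb = matrix(stats::rnorm(3 * H, 0, 0.3), 3, H),
                 Wo = matrix(stats::rnorm(D * D, 0, 0.3), D, D),
                 bo = matrix(0, 1, D))
  h <- matrix(stats::rnorm(4 * D), 4, D)
  src <- c(2, 1, 3, 1); dst <- c(1, 2, 1, 3)
  ef <- matrix(stats::rnorm(12, 0, 0.2), 4, 3)
  out <- attention_block(h, src, dst, ef, params, n_heads = H)
  # per-query weights (neighbors + self) sum to 1
  for (hd in seq_len(H)) {
    sums <- tapply(out$alpha_full[, hd], out$dst_full, sum)
    expect_equal(as.vector(sums), rep(1, 4), tolerance = 1e-6)
  }
  # node 4 has no incoming real edge: all its weight is on the self-loop,
  # and non-neighbors get exactly zero (absent from the edge list)
  self4 <- out$alpha_full[out$dst_full == 4, 1]
  expect_equal(unname(self4), 1, tolerance = 1e-9)
  # single node: attention reduces to the identity mixing (weight 1 on self)
  out1 <- attention_block(h[1, , drop = FALSE], integer(0), integer(0),
                          NULL, params, n_heads = H)
  expect_equal(as.vector(out1$alpha_full), rep(1, H))
})

test_that("edge update projects attention and leaves edges fixed at zero", {
  E <- 5; H <- 2
  alpha <- matrix(stats::runif(6), 3, H)
  a <- matrix(stats::rnorm(15), 3, E)
  zero <- list(We1 = matrix(0, H, E), be1 = matrix(0, 1, E),
               We2 = matrix(0, E, E), be2 = matrix(0, 1, E))
  expect_equal(edge_update(alpha, a, zero), a)
  set.seed(44)
  params <- list(We1 = matrix(stats::rnorm(H * E, 0, 0.3), H, E),
                 be1 = matrix(0, 1, E),
                 We2 = matrix(stats::rnorm(E * E, 0, 0.3), E, E),
                 be2 = matrix(0, 1, E))
  out <- edge_update(alpha, a, params)
  expect_equal(dim(out), dim(a))
  expect_identical(out, edge_update(alpha, a, params))
})

test_that("forward pass is E(3)-invariant in score and equivariant in coords", {
  g <- toy_complex_graph()
  cfg <- small_egnn_config()
  prep <- egnn_prepare(g, cfg)
  params <- egnn_init(ncol(prep$Fn), ncol(prep$Fe), cfg, seed = 3)
  base <- egnn_forward(prep, params, cfg)
  set.seed(45)
  for (rep in 1:10) {
    rot <- random_rotation()
    trans <- stats::rnorm(3, 0, 10)
    out <- egnn_forward(transform_prep(prep, rot, trans), params, cfg)
    expect_lte(abs(out$score - base$score), 1e-5)
    expect_lte(max(abs(out$penultimate - base$penultimate)), 1e-5)
    expected_coords <- base$coords %*% t(rot) +
      matrix(trans, nrow(base$coords), 3, byrow = TRUE)
    expect_lte(max(abs(out$coords - expected_coords)), 1e-5)
  }
})

test_that("forward pass is invariant under node relabeling", {
  g <- toy_complex_graph()
  cfg <- small_egnn_config()
  prep <- egnn_prepare(g, cfg)
  params <- egnn_init(ncol(prep$Fn), ncol(prep$Fe), cfg, seed = 3)
  base <- egnn_forward(prep, params, cfg)
  set.seed(46)
  n <- nrow(prep$Fn)
  perm <- sample(n)
  inv <- order(perm)
  prep2 <- prep
  prep2$Fn <- prep$Fn[perm, , drop = FALSE]
  prep2$x0 <- prep$x0[perm, , drop = FALSE]
  prep2$src <- inv[prep$src]
  prep2$dst <- inv[prep$dst]
  prep2$pool_ids <- sort(inv[prep$pool_ids])
  out <- egnn_forward(prep2, params, cfg)
  expect_equal(out$score, base$score, tolerance = 1e-9)
})

test_that("a zero coordinate gate reduces the block to an invariant GNN", {
  g <- toy_complex_graph()
  cfg <- small_egnn_config()
  prep <- egnn_prepare(g, cfg)
  params <- egnn_init(ncol(prep$Fn), ncol(prep$Fe), cfg, seed = 3)
  for (t in seq_len(cfg$n_layers)) {
    params[[paste0("l", t, ".wx")]][] <- 0
    params[[paste0("l", t, ".bx")]][] <- 0
  }
  out <- egnn_forward(prep, params, cfg)
  expect_equal(out$coords, prep$x0)
})

test_that("analytic gradients match central finite differences", {
  g <- toy_complex_graph()
  cfg <- small_egnn_config()
  prep <- egnn_prepare(g, cfg)
  params <- egnn_init(ncol(prep$Fn), ncol(prep$Fe), cfg, seed = 3)
  lg <- dyneff:::.eg_loss_grads(list(prep), 1, params, cfg)
  set.seed(47)
  eps <- 1e-5
  for (trial in 1:20) {
    nm <- sample(names(params), 1)
    i <- sample(nrow(params[[nm]]), 1)
    j <- sample(ncol(params[[nm]]), 1)
    pp <- params; pp[[nm]][i, j] <- pp[[nm]][i, j] + eps
    pm <- params; pm[[nm]][i, j] <- pm[[nm]][i, j] - eps
    fd <- (dyneff:::.eg_loss_grads(list(prep), 1, pp, cfg)$loss -
             dyneff:::.eg_loss_grads(list(prep), 1, pm, cfg)$loss) /
      (2 * eps)
    an <- lg$grads[[nm]][i, j]
    expect_lte(abs(an - fd), 1e-4 * max(1, abs(fd)))
  }
})

test_that("training separates a linearly separable toy task", {
  graphs <- c(lapply(1:6, function(s) separable_graph(TRUE, s)),
              lapply(7:12, function(s) separable_graph(FALSE, s)))
  labels <- rep(c(1, 0), each = 6)
  cfg <- egnn_config(dim_h = 8, dim_e = 4, n_layers = 1, n_heads = 2,
                     head_hidden = 8)
  sc <- train_scorer(graphs, labels, cfg, epochs = 150, lr = 0.02,
                     seed = 2)
  preds <- egnn_score(sc, graphs)
  expect_gte(mean((preds$prob > 0.5) == (labels == 1)), 0.95)
  # loss decreases on average over the run
  half <- length(sc$loss_history) %/% 2
  expect_lt(mean(utils::tail(sc$loss_history, half)),
            mean(utils::head(sc$loss_history, half)))
  # zero learning rate leaves parameters at their initialization
  sc0 <- train_scorer(graphs[c(1, 7)], c(1, 0), cfg, epochs = 3, lr = 0,
                      seed = 2)
  prep <- egnn_prepare(graphs[[1]], cfg)
  init <- egnn_init(ncol(prep$Fn), ncol(prep$Fe), cfg, seed = 2)
  expect_identical(sc0$params, init)
  expect_error(train_scorer(graphs[1:2], c(1, 1), cfg), "both classes")
})

test_that("scorer weights round-trip through the JSON container", {
  graphs <- list(separable_graph(TRUE, 1), separable_graph(FALSE, 2))
  cfg <- egnn_config(dim_h = 8, dim_e = 4, n_layers = 1, n_heads = 2,
                     head_hidden = 8)
  sc <- train_scorer(graphs, c(1, 0), cfg, epochs = 3, lr = 0.01, seed = 5)
  tf <- tempfile(fileext = ".json")
  write_scorer(sc, tf)
  sc2 <- read_scorer(tf)
  expect_equal(sc2$params, sc$params)
  expect_equal(egnn_score(sc2, graphs[[1]])$score,
               egnn_score(sc, graphs[[1]])$score)
})
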