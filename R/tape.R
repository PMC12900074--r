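# Minimal reverse-mode automatic differentiation on dense matrices.
#
# The equivariant scorer needs exact analytic gradients of a composite of
# matrix products, gathers/scatters over graph edges, group softmax and
# elementwise nonlinearities. This tape records each operation as a node with
# a local backward rule; tp_backward() replays the tape in reverse to
# accumulate gradients. Values are base-R numeric matrices throughout.

tape_new <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env
}

tp_node <- function(tape, val, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  tape$nodes[[length(tape$nodes) + 1L]] <- nd
  nd
}

tp_const <- function(tape, val) tp_node(tape, as_mat(val))

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1)
}

tp_acc <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

tp_backward <- function(tape, out) {
  stopifnot(length(out$val) == 1L)
  out$grad <- matrix(1, 1, 1)
  for (i in rev(seq_along(tape$nodes))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd$grad)
  }
  invisible(NULL)
}

tp_add <- function(tape, a, b) {
  tp_node(tape, a$val + b$val, list(a, b), function(g) {
    tp_acc(a, g); tp_acc(b, g)
  })
}

tp_sub <- function(tape, a, b) {
  tp_node(tape, a$val - b$val, list(a, b), function(g) {
    tp_acc(a, g); tp_acc(b, -g)
  })
}

# matrix (n x d) + bias (1 x d), broadcast over rows
tp_addbias <- function(tape, a, bias) {
  val <- sweep(a$val, 2, as.vector(bias$val), "+")
  tp_node(tape, val, list(a, bias), function(g) {
    tp_acc(a, g)
    tp_acc(bias, matrix(colSums(g), 1))
  })
}

tp_mul <- function(tape, a, b) {  # same shape, elementwise
  tp_node(tape, a$val * b$val, list(a, b), function(g) {
    tp_acc(a, g * b$val); tp_acc(b, g * a$val)
  })
}

# matrix (n x d) scaled rowwise by a column vector (n x 1)
tp_colmul <- function(tape, a, v) {
  vv <- as.vector(v$val)
  tp_node(tape, a$val * vv, list(a, v), function(g) {
    tp_acc(a, g * vv)
    tp_acc(v, matrix(rowSums(g * a$val), ncol = 1))
  })
}

tp_div <- function(tape, a, b) {  # same shape, elementwise
  tp_node(tape, a$val / b$val, list(a, b), function(g) {
    tp_acc(a, g / b$val)
    tp_acc(b, -g * a$val / (b$val^2))
  })
}

tp_matmul <- function(tape, a, b) {
  tp_node(tape, a$val %*% b$val, list(a, b), function(g) {
    tp_acc(a, g %*% t(b$val))
    tp_acc(b, t(a$val) %*% g)
  })
}

tp_scale <- function(tape, a, s) {  # multiply by fixed scalar
  tp_node(tape, a$val * s, list(a), function(g) tp_acc(a, g * s))
}

tp_relu <- function(tape, a) {
  mask <- a$val > 0
  tp_node(tape, a$val * mask, list(a), function(g) tp_acc(a, g * mask))
}

tp_tanh <- function(tape, a) {
  y <- tanh(a$val)
  tp_node(tape, y, list(a), function(g) tp_acc(a, g * (1 - y^2)))
}

tp_sigmoid <- function(tape, a) {
  y <- 1 / (1 + exp(-a$val))
  tp_node(tape, y, list(a), function(g) tp_acc(a, g * y * (1 - y)))
}

tp_exp <- function(tape, a) {
  y <- exp(a$val)
  tp_node(tape, y, list(a), function(g) tp_acc(a, g * y))
}

tp_log <- function(tape, a) {
  tp_node(tape, log(a$val), list(a), function(g) tp_acc(a, g / a$val))
}

tp_sqrt <- function(tape, a) {
  y <- sqrt(a$val)
  tp_node(tape, y, list(a), function(g) tp_acc(a, g * 0.5 / y))
}

tp_sum <- function(tape, a) {
  tp_node(tape, matrix(sum(a$val), 1, 1), list(a), function(g) {
    tp_acc(a, matrix(g[1, 1], nrow(a$val), ncol(a$val)))
  })
}

# y (n x 1) = rowSums of a (n x d)
tp_rowsums <- function(tape, a) {
  tp_node(tape, matrix(rowSums(a$val), ncol = 1), list(a), function(g) {
    tp_acc(a, matrix(as.vector(g), nrow(a$val), ncol(a$val)))
  })
}

# gather rows: y = a[idx, ]
tp_rows <- function(tape, a, idx) {
  tp_node(tape, a$val[idx, , drop = FALSE], list(a), function(g) {
    ga <- matrix(0, nrow(a$val), ncol(a$val))
    agg <- rowsum(g, group = idx)
    rows <- as.integer(rownames(agg))
    ga[rows, ] <- agg
    tp_acc(a, ga)
  })
}

# scatter-sum rows of a (m x d) into n rows by group index (length m)
tp_scatter <- function(tape, a, idx, n) {
  agg <- rowsum(a$val, group = idx)
  val <- matrix(0, n, ncol(a$val))
  val[as.integer(rownames(agg)), ] <- agg
  tp_node(tape, val, list(a), function(g) {
    tp_acc(a, g[idx, , drop = FALSE])
  })
}

tp_rbind <- function(tape, a, b) {
  na <- nrow(a$val)
  tp_node(tape, rbind(a$val, b$val), list(a, b), function(g) {
    tp_acc(a, g[seq_len(na), , drop = FALSE])
    tp_acc(b, g[-seq_len(na), , drop = FALSE])
  })
}

tp_cbind <- function(tape, ...) {
  args <- list(...)
  widths <- vapply(args, function(a) ncol(a$val), 1L)
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  tp_node(tape, do.call(cbind, lapply(args, `[[`, "val")), args,
          function(g) {
            for (i in seq_along(args)) {
              tp_acc(args[[i]], g[, starts[i]:ends[i], drop = FALSE])
            }
          })
}

# numerically stable softmax over groups: for entries l (m x 1) grouped by
# idx, returns exp(l - max_group) / sum_group. The per-group max is treated
# as a constant (its subgradient contribution cancels exactly).
tp_group_softmax <- function(tape, l, idx, n) {
  mx <- tapply(as.vector(l$val), idx, max)
  shift <- tp_node(tape, matrix(as.vector(mx[as.character(idx)]), ncol = 1))
  num <- tp_exp(tape, tp_sub(tape, l, shift))
  den_per_group <- tp_scatter(tape, num, idx, n)
  den <- tp_rows(tape, den_per_group, idx)
  tp_div(tape, num, den)
}
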