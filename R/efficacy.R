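#' Label ligands as agonist or nonagonist from Emax
#'
#' A ligand is an agonist iff its maximal functional response Emax (percent
#' of a full agonist's response) strictly exceeds 50; Emax = 50 is a
#' nonagonist. Records with missing Emax are excluded with a log message.
#'
#' @param ligands Tibble with at least `ligand_id` and `emax` (percent;
#'   may exceed 100 for superagonists).
#' @return The tibble with a `label` column (`"agonist"`/`"nonagonist"`),
#'   missing-Emax rows dropped.
#' @export
#' @examples
#' label_ligands(tibble::tibble(ligand_id = c("a", "b"), emax = c(100, 10)))
label_ligands <- function(ligands) {
  miss <- is.na(ligands$emax)
  if (any(miss)) {
    message("excluding ", sum(miss), " ligand(s) with missing Emax: ",
            paste(ligands$ligand_id[miss], collapse = ", "))
    ligands <- ligands[!miss, , drop = FALSE]
  }
  if (any(ligands$emax < 0)) stop("negative Emax")
  dplyr::mutate(ligands,
                label = ifelse(.data$emax > 50, "agonist", "nonagonist"))
}

#' @rdname label_ligands
#' @param emax Numeric vector of Emax percentages.
#' @export
label_from_emax <- function(emax) {
  ifelse(emax > 50, "agonist", "nonagonist")
}

#' Concatenate a ligand's per-conformation features into one vector
#'
#' Flattens the `n_conformations x P` feature matrix in the recorded
#' conformation order (conformation 1 block first).
#'
#' @param feature_matrix Matrix, conformations (rows) x feature dims.
#' @return Numeric vector of length `n_conformations * P`.
#' @export
concat_features <- function(feature_matrix) {
  as.vector(t(feature_matrix))
}

#' Stack a feature ensemble into the model input matrix
#'
#' @param fe A `feature_ensemble` (see [gen_feature_ensemble()]): list with
#'   `features` (list of per-ligand conformation x P matrices, identical
#'   conformation ordering) and `labels`.
#' @return Matrix, ligands x (n_conformations * P).
#' @export
stack_features <- function(fe) {
  lens <- vapply(fe$features, length, 1L)
  if (length(unique(lens)) != 1L) {
    stop("ragged feature lengths across ligands")
  }
  do.call(rbind, lapply(fe$features, concat_features))
}

# ---- transfer-learning head: 64-32-1 MLP with Adam ----

mlp_init <- function(d_in, h1 = 64, h2 = 32, seed = 1L) {
  set.seed(seed)
  rnd <- function(r, c) matrix(stats::rnorm(r * c, 0, sqrt(2 / r)), r, c)
  list(W1 = rnd(d_in, h1), b1 = matrix(0, 1, h1),
       W2 = rnd(h1, h2), b2 = matrix(0, 1, h2),
       W3 = rnd(h2, 1), b3 = matrix(0, 1, 1))
}

mlp_forward <- function(p, X) {
  Z1 <- pmax(X %*% p$W1 + matrix(p$b1, nrow(X), ncol(p$W1), byrow = TRUE), 0)
  Z2 <- pmax(Z1 %*% p$W2 + matrix(p$b2, nrow(X), ncol(p$W2), byrow = TRUE), 0)
  logit <- Z2 %*% p$W3 + matrix(p$b3, nrow(X), 1, byrow = TRUE)
  list(Z1 = Z1, Z2 = Z2, logit = logit,
       prob = 1 / (1 + exp(-logit)))
}

mlp_grads <- function(p, X, y, fwd) {
  n <- nrow(X)
  dlogit <- (fwd$prob - y) / n              # d BCE / d logit
  gW3 <- t(fwd$Z2) %*% dlogit
  gb3 <- matrix(colSums(dlogit), 1)
  dZ2 <- (dlogit %*% t(p$W3)) * (fwd$Z2 > 0)
  gW2 <- t(fwd$Z1) %*% dZ2
  gb2 <- matrix(colSums(dZ2), 1)
  dZ1 <- (dZ2 %*% t(p$W2)) * (fwd$Z1 > 0)
  gW1 <- t(X) %*% dZ1
  gb1 <- matrix(colSums(dZ1), 1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

#' Train the transfer-learning classification head
#'
#' A fully connected 64-ReLU / 32-ReLU / 1-sigmoid network trained with
#' binary cross-entropy and Adam, batch size 32, 25 epochs (the defaults of
#' the multi-conformation efficacy classifier). Deterministic for a fixed
#' seed.
#'
#' @param X Feature matrix (ligands x concatenated feature dims), e.g. from
#'   [stack_features()].
#' @param labels Binary labels: 0/1, logical, or
#'   `"agonist"`/`"nonagonist"` (agonist = positive class).
#' @param epochs,batch_size,lr Training hyperparameters.
#' @param hidden Widths of the two hidden layers.
#' @param seed RNG seed (initialization and batch shuffling).
#' @return A `tl_head` classifier for [predict_tl()].
#' @export
train_tl_head <- function(X, labels, epochs = 25, batch_size = 32,
                          lr = 1e-2, hidden = c(64, 32), seed = 1L) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) stop("need both classes present")
  X <- as.matrix(X)
  mu <- colMeans(X)
  sdv <- pmax(apply(X, 2, stats::sd), 1e-8)
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  p <- mlp_init(ncol(X), hidden[1], hidden[2], seed = seed)
  opt <- adam_state(p)
  set.seed(seed + 1L)
  n <- nrow(Xs)
  loss_hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      fwd <- mlp_forward(p, Xs[idx, , drop = FALSE])
      yb <- matrix(y[idx], ncol = 1)
      eps <- 1e-12
      ep_loss <- ep_loss - sum(yb * log(fwd$prob + eps) +
                                 (1 - yb) * log(1 - fwd$prob + eps))
      g <- mlp_grads(p, Xs[idx, , drop = FALSE], yb, fwd)
      upd <- adam_step(opt, p, g, lr)
      p <- upd$params; opt <- upd$state
    }
    loss_hist[ep] <- ep_loss / n
  }
  structure(list(params = p, center = mu, scale = sdv,
                 loss_history = loss_hist, hidden = hidden),
            class = "tl_head")
}

#' @export
print.tl_head <- function(x, ...) {
  cat(sprintf("<tl_head> %d-%d-%d-1 MLP; final BCE %.4f\n",
              nrow(x$params$W1), x$hidden[1], x$hidden[2],
              utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Predict agonist probabilities with a trained head
#'
#' @param classifier A `tl_head` from [train_tl_head()].
#' @param X Feature matrix with the training dimensionality.
#' @param threshold Probability cutoff for the hard label.
#' @return Tibble with `prob` (in (0,1)) and `label`.
#' @export
predict_tl <- function(classifier, X, threshold = 0.5) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(classifier$params$W1)) {
    stop("feature dimension mismatch: got ", ncol(X), ", expected ",
         nrow(classifier$params$W1))
  }
  Xs <- sweep(sweep(X, 2, classifier$center), 2, classifier$scale, "/")
  prob <- as.vector(mlp_forward(classifier$params, Xs)$prob)
  tibble::tibble(prob = prob,
                 label = ifelse(prob > threshold, "agonist", "nonagonist"))
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("agonist", "nonagonist"))
    if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
    as.numeric(labels == "agonist")
  } else {
    as.numeric(labels)
  }
}

# ---- baselines ----

#' Static single-conformation score baseline
#'
#' Ranks ligands by the docking score of one conformation. Under the default
#' orientation a lower (better) docking score against an active-state
#' structure is treated as more agonist-like, so the ranking score is the
#' negated docking score.
#'
#' @param scores Named or plain numeric vector, one docking score per ligand
#'   (kcal/mol; lower = better). Missing scores are excluded with a message.
#' @param orientation `"lower_is_agonist"` (default) or its flip.
#' @return Tibble with `ligand` (index or name), `score`, `ranking`
#'   (higher = more agonist-like).
#' @export
static_classifier <- function(scores,
                              orientation = c("lower_is_agonist",
                                              "higher_is_agonist")) {
  orientation <- match.arg(orientation)
  lig <- names(scores) %||% as.character(seq_along(scores))
  miss <- is.na(scores)
  if (any(miss)) {
    message("excluding ", sum(miss), " ligand(s) with missing scores")
  }
  sgn <- if (orientation == "lower_is_agonist") -1 else 1
  tibble::tibble(ligand = lig[!miss], score = scores[!miss],
                 ranking = sgn * scores[!miss])
}

#' Two-states score-difference baseline
#'
#' Classifies by the active-minus-inactive docking-score difference: a more
#' negative difference (active state preferred) ranks more agonist-like.
#'
#' @param score_active,score_inactive Per-ligand docking scores against the
#'   first active / inactive conformation.
#' @param ligand_id Optional ligand identifiers.
#' @return Tibble with `ligand`, `delta` (= active - inactive) and `ranking`
#'   (= -delta; higher = more agonist-like). Ligands missing either score
#'   are excluded.
#' @export
two_states_classifier <- function(score_active, score_inactive,
                                  ligand_id = NULL) {
  lig <- ligand_id %||% as.character(seq_along(score_active))
  ok <- !is.na(score_active) & !is.na(score_inactive)
  if (any(!ok)) {
    message("excluding ", sum(!ok), " ligand(s) missing a state score")
  }
  delta <- score_active[ok] - score_inactive[ok]
  tibble::tibble(ligand = lig[ok], delta = delta, ranking = -delta)
}

#' Random-forest baseline on the full ensemble score vector
#'
#' Trains a random forest on each ligand's vector of docking scores across
#' all conformations and returns out-of-fold agonist probabilities under a
#' split plan. Columns that are entirely missing are dropped with a warning;
#' remaining missing scores are imputed with the training-fold column
#' median.
#'
#' @param score_matrix Matrix, ligands x conformations.
#' @param labels Binary labels (see [train_tl_head()]).
#' @param split_plan A [make_split()] plan (fold per ligand).
#' @param ntree Forest size.
#' @param seed RNG seed.
#' @return Tibble with `ligand` (row index), `fold`, `prob`.
#' @export
rf_ensemble_classifier <- function(score_matrix, labels, split_plan,
                                   ntree = 500, seed = 1L) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) stop("need both classes present")
  X <- as.matrix(score_matrix)
  all_na <- colSums(!is.na(X)) == 0L
  if (any(all_na)) {
    warning("dropping ", sum(all_na), " all-missing conformation column(s)")
    X <- X[, !all_na, drop = FALSE]
  }
  folds <- split_plan$fold
  out <- vector("list", length(unique(folds)))
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- folds == f
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    med <- apply(Xtr, 2, stats::median, na.rm = TRUE)
    for (j in seq_len(ncol(X))) {
      Xtr[is.na(Xtr[, j]), j] <- med[j]
      Xte[is.na(Xte[, j]), j] <- med[j]
    }
    set.seed(seed + f)
    rf <- randomForest::randomForest(
      x = Xtr, y = factor(y[tr], levels = c(0, 1)), ntree = ntree)
    prob <- stats::predict(rf, Xte, type = "prob")[, "1"]
    out[[f]] <- tibble::tibble(ligand = which(te), fold = f, prob = prob)
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$ligand)
}

#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided test of mean docking-score difference between two conformation
#' states, used to ask whether a ligand's score distribution differs between
#' its preferred and nonpreferred receptor states.
#'
#' @param samples_a,samples_b Numeric vectors, each n >= 2.
#' @return Tibble with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_test <- function(samples_a, samples_b) {
  stopifnot(length(samples_a) >= 2L, length(samples_b) >= 2L)
  if (stats::var(samples_a) == 0 && stats::var(samples_b) == 0) {
    same <- isTRUE(all.equal(mean(samples_a), mean(samples_b)))
    return(tibble::tibble(t = if (same) 0 else sign(mean(samples_a) -
                                                      mean(samples_b)) * Inf,
                          df = NA_real_, p_value = if (same) 1 else 0,
                          mean_a = mean(samples_a), mean_b = mean(samples_b)))
  }
  tt <- stats::t.test(samples_a, samples_b, var.equal = FALSE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 mean_a = mean(samples_a), mean_b = mean(samples_b))
}

# ---- split strategies ----

#' Pairwise Tanimoto similarity of binary fingerprints
#'
#' @param fp Binary matrix, ligands x bits.
#' @return Symmetric similarity matrix in \[0, 1\] (diagonal 1; two all-zero
#'   fingerprints have similarity 0 off-diagonal).
#' @export
tanimoto_matrix <- function(fp) {
  fp <- as.matrix(fp) * 1
  common <- fp %*% t(fp)
  on_bits <- rowSums(fp)
  union <- outer(on_bits, on_bits, "+") - common
  sim <- ifelse(union > 0, common / union, 0)
  diag(sim) <- 1
  sim
}

#' Assign ligands to cross-validation folds
#'
#' `"random"`: a seeded shuffle into k near-equal folds. `"tanimoto"`:
#' single-linkage clusters at Tanimoto similarity >= `threshold` (ECFP4-type
#' fingerprints), each cluster assigned whole to one fold, clusters placed
#' largest-first into the currently smallest fold so sizes stay balanced.
#' A scaffold cluster is never split across folds.
#'
#' @param n_ligands Number of ligands.
#' @param strategy `"random"` or `"tanimoto"`.
#' @param k Number of folds (default 3).
#' @param seed RNG seed.
#' @param fingerprints Binary matrix (ligands x bits) for the tanimoto
#'   strategy; alternatively supply `similarity` directly.
#' @param similarity Precomputed similarity matrix.
#' @param threshold Tanimoto clustering threshold (default 0.4).
#' @return A `split_plan` tibble: `ligand` (index), `fold`, and for the
#'   tanimoto strategy `cluster`; attribute `strategy` records the choice.
#' @export
make_split <- function(n_ligands, strategy = c("random", "tanimoto"), k = 3L,
                       seed = 1L, fingerprints = NULL, similarity = NULL,
                       threshold = 0.4) {
  strategy <- match.arg(strategy)
  if (strategy == "random") {
    set.seed(seed)
    fold <- sample(rep(seq_len(k), length.out = n_ligands))
    out <- tibble::tibble(ligand = seq_len(n_ligands), fold = fold)
  } else {
    sim <- similarity %||% tanimoto_matrix(fingerprints)
    stopifnot(nrow(sim) == n_ligands)
    d <- stats::as.dist(1 - sim)
    hc <- stats::hclust(d, method = "single")
    cluster <- stats::cutree(hc, h = 1 - threshold)
    sizes <- sort(table(cluster), decreasing = TRUE)
    if (max(sizes) > n_ligands / k) {
      warning("a scaffold cluster spans more than 1/k of the data; ",
              "folds will be unbalanced")
    }
    fold_of_cluster <- integer(length(sizes))
    names(fold_of_cluster) <- names(sizes)
    fold_sizes <- numeric(k)
    set.seed(seed)
    for (cl in names(sizes)) {
      target <- which.min(fold_sizes)
      fold_of_cluster[cl] <- target
      fold_sizes[target] <- fold_sizes[target] + sizes[[cl]]
    }
    out <- tibble::tibble(ligand = seq_len(n_ligands),
                          cluster = as.integer(cluster),
                          fold = fold_of_cluster[as.character(cluster)])
  }
  attr(out, "strategy") <- strategy
  class(out) <- c("split_plan", class(out))
  out
}

# ---- metrics ----

#' Midrank (Mann-Whitney) area under the ROC curve
#'
#' Equivalent to the TPR-FPR integral definition, with exact tie handling
#' via midranks.
#'
#' @param scores Numeric ranking scores (higher = more positive-like).
#' @param labels Binary labels.
#' @return Scalar AUC, or NA (with a warning) when one class is absent.
#' @export
auc_midrank <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    warning("AUC undefined with a single class")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion counts and the five classification metrics
#'
#' Computes AUC (midrank Mann-Whitney), and from the confusion counts at
#' `threshold`: accuracy, Matthews correlation coefficient, precision and
#' recall. A zero MCC denominator yields MCC = 0 (documented convention).
#'
#' @param scores Probabilities or ranking scores.
#' @param labels Binary labels (agonist = positive).
#' @param threshold Decision threshold on `scores`.
#' @return One-row tibble: `auc`, `acc`, `mcc`, `precision`, `recall`,
#'   `tp`, `tn`, `fp`, `fn`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  y <- as_binary_labels(labels)
  pred <- as.numeric(scores > threshold)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  dplyr::bind_cols(
    tibble::tibble(auc = auc_midrank(scores, y)),
    metrics_from_counts(tp, tn, fp, fn)
  )
}

#' @rdname compute_metrics
#' @param tp,tn,fp,fn Confusion counts.
#' @export
metrics_from_counts <- function(tp, tn, fp, fn) {
  acc <- (tp + tn) / (tp + tn + fp + fn)
  denom <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) *
    sqrt((tn + fn))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  tibble::tibble(acc = acc, mcc = mcc, precision = precision,
                 recall = recall, tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Cross-validated, repeated evaluation of the transfer-learning head
#'
#' For each of `n_rep` seeded repetitions, trains the head on each fold's
#' complement and predicts the held-out fold, then computes the five metrics
#' both pooled over folds and averaged per fold. Repetition seeds are
#' `base_seed + 0..(n_rep-1)`.
#'
#' @param X Feature matrix (see [stack_features()]).
#' @param labels Binary labels.
#' @param split_plan A [make_split()] plan.
#' @param n_rep Number of repetitions (default 5).
#' @param base_seed Base RNG seed.
#' @param ... Passed to [train_tl_head()].
#' @return A `metrics_report`: list with `per_rep` (pooled metrics per
#'   repetition), `per_fold`, and `summary` (mean and SD per metric).
#'   [tidy()] returns `per_rep`; [glance()] the summary.
#' @export
evaluate_tl <- function(X, labels, split_plan, n_rep = 5L, base_seed = 1L,
                        ...) {
  y <- as_binary_labels(labels)
  per_rep <- list(); per_fold <- list()
  for (rep in seq_len(n_rep)) {
    seed <- base_seed + rep - 1L
    prob <- rep(NA_real_, nrow(X))
    for (f in sort(unique(split_plan$fold))) {
      tr <- split_plan$fold != f
      cls <- train_tl_head(X[tr, , drop = FALSE], y[tr],
                           seed = seed + 1000L * f, ...)
      prob[!tr] <- predict_tl(cls, X[!tr, , drop = FALSE])$prob
      per_fold[[length(per_fold) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(rep = rep, fold = f),
        compute_metrics(prob[!tr], y[!tr]))
    }
    per_rep[[rep]] <- dplyr::bind_cols(tibble::tibble(rep = rep),
                                       compute_metrics(prob, y))
  }
  new_metrics_report(dplyr::bind_rows(per_rep), dplyr::bind_rows(per_fold))
}

new_metrics_report <- function(per_rep, per_fold = NULL) {
  metric_cols <- c("auc", "acc", "mcc", "precision", "recall")
  summary <- tidyr::pivot_longer(per_rep[, metric_cols], dplyr::everything(),
                                 names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value), .groups = "drop")
  structure(list(per_rep = per_rep, per_fold = per_fold, summary = summary),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d repetition(s)\n", nrow(x$per_rep)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' @rdname evaluate_tl
#' @param x A `metrics_report`.
#' @export
tidy.metrics_report <- function(x, ...) x$per_rep

#' @rdname evaluate_tl
#' @export
glance.metrics_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  wide
}
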