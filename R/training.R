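#' Per-cell label table
#'
#' Builds the tidy label table used throughout training: cell type, disease
#' state, optional donor, and the composite `cell_type x disease_state`
#' class (the 16-class task when there are 8 types and 2 states).
#'
#' @param cell_type,disease_state categorical vectors (one entry per cell).
#' @param donor_id optional categorical vector.
#' @param cell_id optional cell identifiers.
#' @return tibble with columns `cell_id`, `cell_type`, `disease_state`,
#'   `donor_id` (may be `NA`) and `composite`.
#' @export
label_set <- function(cell_type, disease_state, donor_id = NULL,
                      cell_id = NULL) {
  n <- length(cell_type)
  if (length(disease_state) != n) stop_hamgcn("label lengths differ")
  cell_id <- cell_id %||% paste0("cell_", seq_len(n))
  tibble::tibble(
    cell_id = as.character(cell_id),
    cell_type = factor(cell_type),
    disease_state = factor(disease_state),
    donor_id = if (is.null(donor_id)) factor(rep(NA_character_, n))
               else factor(donor_id),
    composite = factor(paste(cell_type, disease_state, sep = "."))
  )
}

#' Cross-entropy loss over labeled nodes
#'
#' Mean negative log softmax probability of the true class over the cells in
#' `labeled_mask`.
#'
#' @param logits N x C matrix.
#' @param labels integer class indices (1-based) or factor of length N.
#' @param labeled_mask logical mask or integer indices of labeled cells;
#'   defaults to all cells.
#' @return scalar loss.
#' @export
cross_entropy <- function(logits, labels, labeled_mask = NULL) {
  labels <- if (is.numeric(labels)) as.integer(labels)
            else as.integer(as.factor(labels))
  if (any(labels < 1 | labels > ncol(logits))) {
    stop_hamgcn("label index outside 1..C")
  }
  idx <- if (is.null(labeled_mask)) seq_len(nrow(logits))
         else resolve_index(labeled_mask, seq_len(nrow(logits)))
  if (length(idx) == 0) stop_hamgcn("labeled mask is empty")
  l <- logits[idx, , drop = FALSE]
  m <- apply(l, 1L, max)
  lse <- m + log(rowSums(exp(l - m)))
  true_logit <- l[cbind(seq_along(idx), labels[idx])]
  mean(lse - true_logit)
}

#' Weighted multi-task loss
#'
#' `alpha * loss_type + beta * loss_state`, the weighted combination of the
#' cell-type and disease-state losses (defaults 0.7 / 0.3).
#'
#' @param loss_type,loss_state scalar task losses.
#' @param alpha,beta non-negative weights.
#' @return scalar.
#' @export
multitask_loss <- function(loss_type, loss_state, alpha = 0.7, beta = 0.3) {
  if (alpha < 0 || beta < 0) stop_hamgcn("weights must be non-negative")
  alpha * loss_type + beta * loss_state
}

#' Train/validation/test split of cells
#'
#' `cell_level`: stratified by the composite class where possible, with
#' per-stratum rounding so overall fractions are honored. `donor_grouped`:
#' whole donors are assigned to partitions (greedy size balancing in a
#' seeded random donor order) so no donor spans two partitions — the split
#' that prevents donor-identity leakage. Deterministic given the seed.
#'
#' @param labels a [label_set()] tibble.
#' @param fractions numeric length-3 `(train, val, test)` summing to 1.
#' @param mode `"cell_level"` or `"donor_grouped"`.
#' @param seed integer seed.
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
split_cells <- function(labels, fractions = c(0.6, 0.2, 0.2),
                        mode = c("cell_level", "donor_grouped"), seed = 1) {
  mode <- match.arg(mode)
  if (abs(sum(fractions) - 1) > 1e-8) stop_hamgcn("fractions must sum to 1")
  n <- nrow(labels)
  set.seed(derive_seed(seed, "split"))
  if (mode == "cell_level") {
    parts <- list(train = integer(), val = integer(), test = integer())
    for (cls in levels(labels$composite)) {
      idx <- which(labels$composite == cls)
      idx <- idx[sample.int(length(idx))]
      m <- length(idx)
      n_tr <- round(fractions[1] * m)
      n_va <- round(fractions[2] * m)
      n_va <- min(n_va, m - n_tr)
      parts$train <- c(parts$train, idx[seq_len(n_tr)])
      if (n_va > 0) parts$val <- c(parts$val, idx[n_tr + seq_len(n_va)])
      if (m - n_tr - n_va > 0) {
        parts$test <- c(parts$test, idx[(n_tr + n_va + 1):m])
      }
    }
    lapply(parts, sort)
  } else {
    donors <- labels$donor_id
    if (all(is.na(donors))) stop_hamgcn("donor_grouped requires donor_id")
    dl <- levels(droplevels(donors))
    if (length(dl) < 3) stop_hamgcn("donor_grouped requires at least 3 donors")
    dl <- dl[sample.int(length(dl))]
    sizes <- table(donors)[dl]
    target <- fractions * n
    assigned <- list(train = character(), val = character(), test = character())
    filled <- c(train = 0, val = 0, test = 0)
    for (d in dl) {
      deficit <- target - filled
      part <- names(which.max(deficit))
      assigned[[part]] <- c(assigned[[part]], d)
      filled[part] <- filled[part] + sizes[[d]]
    }
    lapply(assigned, function(ds) sort(which(as.character(donors) %in% ds)))
  }
}

## ---- Adam optimizer ---------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- g + wd * params[[nm]]           # L2-in-gradient, Adam convention
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

## softmax-CE gradient restricted to a mask, scaled by a task weight
ce_grad <- function(logits, y, idx, weight) {
  d <- matrix(0, nrow(logits), ncol(logits))
  p <- softmax_rows(logits[idx, , drop = FALSE])
  p[cbind(seq_along(idx), y[idx])] <- p[cbind(seq_along(idx), y[idx])] - 1
  d[idx, ] <- p * (weight / length(idx))
  d
}

#' Fit the Hamiltonian GCN or the plain-GCN baseline
#'
#' Full-graph (transductive) training with Adam, weight decay, dropout after
#' the encoder layer, and early stopping on validation loss. Gradients flow
#' through the symplectic integrator via analytic Hessian-vector products of
#' the learnable energy. Fully seeded: identical seeds on identical data
#' reproduce bit-identical parameters.
#'
#' @param x N x F numeric feature matrix (cells in rows).
#' @param graph a [cell_graph()] over the same cells.
#' @param labels a [label_set()] tibble, or a plain factor/vector of class
#'   labels for single-task use.
#' @param split list of integer index vectors `train`, `val` (and optionally
#'   `test`), e.g. from [split_cells()].
#' @param config a [model_config()].
#' @param mode `"hgcn"` or `"gcn_baseline"`.
#' @return a `hamgcn_fit` object with elements `params`, `history` (tibble:
#'   epoch, train_loss, val_loss, val_accuracy), `energy_traces` (hgcn only;
#'   one per-step energy vector per epoch), `best_epoch`, `config`, `mode`.
#' @export
fit_hamgcn <- function(x, graph, labels, split, config = model_config(),
                       mode = c("hgcn", "gcn_baseline")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (is.atomic(labels) || is.factor(labels)) {
    labels <- tibble::tibble(composite = factor(labels))
  }
  tasks <- if (config$task == "multi") {
    list(list(y = as.integer(labels$cell_type),
              levels = levels(labels$cell_type), weight = config$alpha),
         list(y = as.integer(labels$disease_state),
              levels = levels(labels$disease_state), weight = config$beta))
  } else {
    list(list(y = as.integer(labels$composite),
              levels = levels(labels$composite), weight = 1))
  }
  n_classes <- vapply(tasks, function(t) length(t$levels), integer(1))
  s <- normalized_adjacency(graph)
  xs <- if (mode == "hgcn") as.matrix(s %*% x) else NULL
  params <- init_params(mode, ncol(x), config, n_classes)
  opt <- adam_init(params)
  tr <- split$train
  va <- split$val
  if (length(tr) == 0 || length(va) == 0) stop_hamgcn("empty train or val split")
  set.seed(derive_seed(config$seed, "train"))
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  history <- vector("list", config$epochs)
  energy_traces <- list()
  n_ran <- 0L
  for (epoch in seq_len(config$epochs)) {
    if (mode == "hgcn") {
      fw <- forward_hgcn(x, xs, params, config, training = TRUE,
                         record_energy = TRUE)
      energy_traces[[epoch]] <- fw$energies
    } else {
      fw <- forward_gcn(x, s, params, config, training = TRUE)
    }
    train_loss <- 0
    dlogits <- vector("list", length(tasks))
    for (k in seq_along(tasks)) {
      lk <- cross_entropy(fw$logits[[k]], tasks[[k]]$y, tr)
      train_loss <- train_loss + tasks[[k]]$weight * lk
      dlogits[[k]] <- ce_grad(fw$logits[[k]], tasks[[k]]$y, tr,
                              tasks[[k]]$weight)
    }
    if (!is.finite(train_loss)) {
      stop_hamgcn("training loss diverged (non-finite) at epoch ", epoch,
                  class = "hamgcn_divergence")
    }
    grads <- if (mode == "hgcn") {
      backward_hgcn(fw, xs, params, config, dlogits)
    } else {
      backward_gcn(fw, s, params, config, dlogits)
    }
    upd <- adam_step(params, grads, opt, config$learning_rate,
                     config$weight_decay)
    params <- upd$params
    opt <- upd$state
    ## eval-mode validation
    ev <- if (mode == "hgcn") {
      forward_hgcn(x, xs, params, config, training = FALSE)
    } else {
      forward_gcn(x, s, params, config, training = FALSE)
    }
    val_loss <- 0
    for (k in seq_along(tasks)) {
      val_loss <- val_loss +
        tasks[[k]]$weight * cross_entropy(ev$logits[[k]], tasks[[k]]$y, va)
    }
    pred_main <- max.col(ev$logits[[1]][va, , drop = FALSE], "first")
    val_acc <- mean(pred_main == tasks[[1]]$y[va])
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       train_loss = train_loss,
                                       val_loss = val_loss,
                                       val_accuracy = val_acc)
    n_ran <- epoch
    if (val_loss < best$loss - 1e-12) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  structure(list(
    mode = mode, params = best$params, best_epoch = best$epoch,
    history = dplyr::bind_rows(history[seq_len(n_ran)]),
    energy_traces = energy_traces, config = config, tasks = tasks,
    labels = labels, split = split, x = x, graph = graph
  ), class = "hamgcn_fit")
}

#' @export
print.hamgcn_fit <- function(x, ...) {
  cat(sprintf("<hamgcn_fit> mode=%s, %d epochs (best %d), val acc %.3f\n",
              x$mode, nrow(x$history), x$best_epoch,
              x$history$val_accuracy[x$best_epoch]))
  invisible(x)
}

#' Predictions from a fitted model
#'
#' @param object a `hamgcn_fit`.
#' @param type `"class"` (tibble of predicted labels per task) or `"prob"`
#'   (softmax probabilities for the primary task).
#' @param ... unused.
#' @return a tibble.
#' @export
predict.hamgcn_fit <- function(object, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  out <- hamgcn_forward(object$x, object$graph, object$params, object$config,
                        mode = object$mode)
  if (type == "prob") {
    pr <- softmax_rows(out$logits[[1]])
    colnames(pr) <- object$tasks[[1]]$levels
    return(tibble::as_tibble(pr))
  }
  res <- tibble::tibble(.row = seq_len(nrow(object$x)))
  task_names <- if (length(object$tasks) == 2) {
    c("cell_type", "disease_state")
  } else {
    "composite"
  }
  for (k in seq_along(object$tasks)) {
    idx <- max.col(out$logits[[k]], "first")
    res[[paste0(".pred_", task_names[k])]] <-
      factor(object$tasks[[k]]$levels[idx], levels = object$tasks[[k]]$levels)
  }
  res
}

#' Model embedding used by over-smoothing diagnostics
#'
#' `(q || p)` for the Hamiltonian model, the last hidden layer for the
#' baseline; evaluation mode.
#'
#' @param fit a `hamgcn_fit`.
#' @return N x D numeric matrix.
#' @export
model_embedding <- function(fit) {
  hamgcn_forward(fit$x, fit$graph, fit$params, fit$config,
                 mode = fit$mode)$embedding
}

#' Classification metrics from predictions and truth
#'
#' Accuracy (fraction correct) plus per-class precision, recall and F1 in a
#' one-vs-rest confusion decomposition, macro- and support-weighted-averaged.
#' Classes absent from both predictions and truth are excluded from the
#' macro mean with a warning.
#'
#' @param preds predicted labels (factor/character/integer).
#' @param labels true labels, same length.
#' @return list with `summary` (one-row tibble: accuracy, f1_macro,
#'   f1_weighted, n) and `per_class` (tibble: class, n_true, precision,
#'   recall, f1).
#' @export
evaluate_predictions <- function(preds, labels) {
  if (length(preds) != length(labels)) stop_hamgcn("length mismatch")
  lev <- union(levels(as.factor(labels)), levels(as.factor(preds)))
  truth <- factor(labels, levels = lev)
  pred <- factor(preds, levels = lev)
  acc <- mean(pred == truth)
  rows <- lapply(lev, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(class = cl, n_true = tp + fn, precision = prec,
                   recall = rec, f1 = f1, present = (tp + fp + fn) > 0)
  })
  per_class <- dplyr::bind_rows(rows)
  if (any(!per_class$present)) {
    warning(sum(!per_class$present),
            " class(es) absent from both predictions and truth excluded",
            " from macro averaging")
  }
  pc <- per_class[per_class$present, ]
  f1_macro <- mean(pc$f1)
  f1_weighted <- sum(pc$f1 * pc$n_true) / sum(pc$n_true)
  list(summary = tibble::tibble(accuracy = acc, f1_macro = f1_macro,
                                f1_weighted = f1_weighted,
                                n = length(truth)),
       per_class = per_class[, c("class", "n_true", "precision", "recall",
                                 "f1")])
}

#' Evaluate a fitted model on one split
#'
#' @param fit a `hamgcn_fit`.
#' @param which `"test"`, `"val"` or `"train"`.
#' @return as [evaluate_predictions()], on the primary task.
#' @export
evaluate_fit <- function(fit, which = "test") {
  idx <- fit$split[[which]]
  if (is.null(idx)) stop_hamgcn("split has no '", which, "' part")
  out <- hamgcn_forward(fit$x, fit$graph, fit$params, fit$config,
                        mode = fit$mode)
  pred <- max.col(out$logits[[1]][idx, , drop = FALSE], "first")
  evaluate_predictions(fit$tasks[[1]]$levels[pred],
                       fit$tasks[[1]]$levels[fit$tasks[[1]]$y[idx]])
}

#' Broom-style tidiers for fitted models
#'
#' `tidy()` returns the per-epoch training history; `glance()` a one-row
#' summary with the best validation epoch and, when a test split is present,
#' test-set metrics.
#'
#' @param x a `hamgcn_fit`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.hamgcn_fit <- function(x, ...) x$history

#' @rdname tidy.hamgcn_fit
#' @export
glance.hamgcn_fit <- function(x, ...) {
  out <- tibble::tibble(
    mode = x$mode, epochs_run = nrow(x$history), best_epoch = x$best_epoch,
    best_val_loss = min(x$history$val_loss),
    best_val_accuracy = x$history$val_accuracy[x$best_epoch]
  )
  if (!is.null(x$split$test) && length(x$split$test) > 0) {
    ev <- evaluate_fit(x, "test")
    out$test_accuracy <- ev$summary$accuracy
    out$test_f1_macro <- ev$summary$f1_macro
  }
  out
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
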