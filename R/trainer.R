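# Training loop: Adam, softmax cross-entropy, fixed hyperparameters, per-epoch
# history, seeded end-to-end determinism on CPU.

#' Training configuration
#'
#' Defaults follow the reference protocol: learning rate 1e-5, batch size 20
#' (groups), 20 epochs, Adam with standard moment settings, two-class
#' cross-entropy. Desk-scale property runs in this package use a larger
#' learning rate (see the methods vignette) because they take two orders of
#' magnitude fewer optimizer steps than a full-size cohort.
#'
#' @param lr learning rate.
#' @param batch_size groups per optimizer step (the last incomplete batch is
#'   kept).
#' @param epochs passes over the training set.
#' @param beta1,beta2,eps Adam moment/stability constants.
#' @param seed seed controlling shuffling and augmentation.
#' @param augment an [augment_policy()] applied to training batches only, or
#'   `NULL` to disable augmentation.
#' @param selection `"validation"` carves a validation subset out of the
#'   training groups for epoch selection; `"eval_set"` selects on the provided
#'   evaluation set (faithful to the original protocol, but methodologically
#'   leaky when that set is the test set).
#' @param val_fraction fraction of training groups carved off when
#'   `selection = "validation"`.
#' @export
train_config <- function(lr = 1e-5, batch_size = 20L, epochs = 20L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8, seed = 1L,
                         augment = augment_policy(),
                         selection = c("validation", "eval_set"),
                         val_fraction = 0.15) {
  stopifnot(lr >= 0, batch_size >= 1, epochs >= 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), beta1 = beta1, beta2 = beta2,
                 eps = eps, seed = as.integer(seed), augment = augment,
                 selection = match.arg(selection), val_fraction = val_fraction),
            class = "train_config")
}

#' Two-class cross-entropy
#'
#' `-log p(true class)`, with probabilities clipped at `clip` so degenerate
#' inputs stay finite; for a batch the value is the mean of per-sample values.
#'
#' @param probs probability matrix (classes x samples) or vector (one sample).
#' @param labels integer class indices (0-based).
#' @param clip probability floor.
#' @export
cross_entropy <- function(probs, labels, clip = 1e-12) {
  if (is.null(dim(probs))) probs <- matrix(probs, ncol = 1)
  p <- probs[cbind(labels + 1L, seq_along(labels))]
  mean(-log(pmax(p, clip)))
}

#' Best epoch under a selection criterion
#'
#' @param history a training history data.frame.
#' @param criterion history column to maximize (default evaluation accuracy).
#' @return 1-based epoch index; ties resolve to the earliest epoch.
#' @export
select_best_epoch <- function(history, criterion = "eval_acc") {
  if (is.null(history) || nrow(history) == 0)
    stop("select_best_epoch: empty history")
  which.max(history[[criterion]])
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params)
  list(t = 0L,
       m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))))

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g * g
    step <- cfg$lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + cfg$eps)
    params[[nm]] <- params[[nm]] - array(step, dim = dim(params[[nm]]) %||% length(step))
  }
  list(params = params, state = state)
}

# tie gradients across the three view branches for shared-weight models
tie_view_grads <- function(grads, n_views) {
  v1 <- grep("^v1\\.", names(grads), value = TRUE)
  for (nm in v1) {
    rest <- sub("^v1\\.", "", nm)
    for (k in seq_len(n_views)[-1]) {
      other <- paste0("v", k, ".", rest)
      grads[[nm]] <- grads[[nm]] + grads[[other]]
    }
  }
  grads
}

sync_view_params <- function(params, n_views) {
  v1 <- grep("^v1\\.", names(params), value = TRUE)
  for (nm in v1) {
    rest <- sub("^v1\\.", "", nm)
    for (k in seq_len(n_views)[-1])
      params[[paste0("v", k, ".", rest)]] <- params[[nm]]
  }
  params
}

# --- training loop ---------------------------------------------------------

#' Train a multi-view fusion classifier
#'
#' Runs the full protocol: seeded shuffling into batches of
#' `config$batch_size` groups, augmentation of training batches only,
#' softmax cross-entropy loss, Adam updates, and a per-epoch history of
#' training and evaluation loss/accuracy. The intensity normalizer is fitted
#' on the training groups and stored with the fit.
#'
#' @param model a built model (e.g. [build_fusion_model()]); its weights are
#'   the initialization.
#' @param train_groups list of `view_group`s with images.
#' @param eval_groups held-out groups tracked in the history. May be `NULL`
#'   under `selection = "validation"`, in which case the carved validation
#'   subset fills the evaluation columns.
#' @param config a [train_config()].
#' @return a `resmini_fit` object: trained model (final-epoch weights),
#'   `history`, `best_epoch`, the best epoch's parameters, the normalizer and
#'   the configuration. Methods: `print`, `summary`, `plot`, `predict`,
#'   `coef`.
#' @export
train_model <- function(model, train_groups, eval_groups = NULL,
                        config = train_config()) {
  stopifnot(inherits(config, "train_config"), length(train_groups) > 0)
  fcfg <- attr(model, "fusion_config")
  shared <- !is.null(fcfg) && isTRUE(fcfg$share_weights)
  n_views <- if (is.null(fcfg)) 3L else fcfg$n_views
  multi <- identical(model$kind, "multiview")

  if (length(eval_groups)) {
    tid <- vapply(train_groups, function(g) g$group_id, "")
    eid <- vapply(eval_groups, function(g) g$group_id, "")
    if (length(intersect(tid, eid)))
      stop("train_model: train and evaluation sets overlap")
  }

  with_seed(config$seed, {
    if (config$selection == "validation") {
      # carve at patient level so epoch selection rewards generalization to
      # unseen patients rather than patient memorization
      pid <- vapply(train_groups, function(g) g$patient_id, "")
      pats <- unique(pid)
      nval <- max(1L, floor(config$val_fraction * length(pats)))
      if (nval >= length(pats))
        stop("train_model: training set too small to carve validation data")
      vp <- sample(pats, nval)
      sel_groups <- train_groups[pid %in% vp]
      train_groups <- train_groups[!pid %in% vp]
      if (!length(train_groups))
        stop("train_model: training set too small to carve validation data")
    } else {
      if (!length(eval_groups))
        stop("train_model: selection = 'eval_set' requires eval_groups")
      sel_groups <- eval_groups
    }
    track_groups <- if (length(eval_groups)) eval_groups else sel_groups

    normalizer <- fit_normalizer(train_groups)
    params <- nn_params(model)
    state <- adam_init(params)
    n <- length(train_groups)
    hist <- data.frame(epoch = seq_len(config$epochs), train_loss = NA_real_,
                       train_acc = NA_real_, eval_loss = NA_real_,
                       eval_acc = NA_real_)
    best <- list(metric = -Inf, epoch = NA_integer_, params = NULL)

    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_hits <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        ba <- groups_to_arrays(train_groups[idx], normalizer, config$augment)
        xin <- if (multi) ba$x else ba$x[[1]]
        fw <- nn_forward(model, xin, training = TRUE)
        model <- fw$mod # batch-norm running statistics advanced
        p <- softmax(fw$out)
        loss <- cross_entropy(p, ba$y)
        if (!is.finite(loss))
          stop("train_model: non-finite loss at epoch ", ep,
               " (batch starting at ", start, ")")
        ep_loss <- ep_loss + loss * length(idx)
        ep_hits <- ep_hits + sum((p[2L, ] > p[1L, ]) == (ba$y == 1L))
        nb <- length(idx)
        Y <- matrix(0, nrow(p), nb); Y[cbind(ba$y + 1L, seq_len(nb))] <- 1
        bk <- nn_backward(model, fw$cache, (p - Y) / nb)
        grads <- bk$grads[names(params)]
        if (shared) grads <- tie_view_grads(grads, n_views)
        upd <- adam_step(params, grads, state, config)
        params <- upd$params; state <- upd$state
        if (shared) params <- sync_view_params(params, n_views)
        model <- nn_set_params(model, params)
      }
      ev <- eval_loss_acc(model, sel_groups, normalizer, config$batch_size, multi)
      hist$train_loss[ep] <- ep_loss / n
      hist$train_acc[ep] <- ep_hits / n
      hist$eval_loss[ep] <- ev$loss
      hist$eval_acc[ep] <- ev$acc
      if (ev$acc > best$metric) # strict: ties keep the earliest epoch
        best <- list(metric = ev$acc, epoch = ep, params = params,
                     model = model) # full state incl. BN running statistics
    }

    structure(list(model = model, history = hist, best_epoch = best$epoch,
                   best_params = best$params, best_state = best$model,
                   normalizer = normalizer,
                   config = config, fusion_config = fcfg,
                   n_train = n, selection_set = config$selection,
                   track_groups_n = length(track_groups)),
              class = "resmini_fit")
  })
}

eval_loss_acc <- function(model, groups, normalizer, batch_size, multi = TRUE) {
  n <- length(groups)
  loss <- 0; hits <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    ba <- groups_to_arrays(groups[idx], normalizer)
    xin <- if (multi) ba$x else ba$x[[1]]
    fw <- nn_forward(model, xin, training = FALSE)
    p <- softmax(fw$out)
    loss <- loss + cross_entropy(p, ba$y) * length(idx)
    hits <- hits + sum((p[2L, ] > p[1L, ]) == (ba$y == 1L))
  }
  list(loss = loss / n, acc = hits / n)
}

#' Restore the best-epoch state of a fit
#' @param fit a `resmini_fit`.
#' @return the model as it stood after the epoch selected by the criterion
#'   (weights and batch-norm running statistics).
#' @export
best_model <- function(fit) {
  stopifnot(inherits(fit, "resmini_fit"))
  if (!is.null(fit$best_state)) return(fit$best_state)
  nn_set_params(fit$model, fit$best_params)
}

#' @export
print.resmini_fit <- function(x, ...) {
  cat("Multi-view fusion fit\n")
  cat(sprintf("  trained on %d groups, %d epochs (batch %d, lr %g)\n",
              x$n_train, x$config$epochs, x$config$batch_size, x$config$lr))
  cat(sprintf("  best epoch %d by %s accuracy: %.4f\n", x$best_epoch,
              if (x$selection_set == "validation") "validation" else "evaluation",
              x$history$eval_acc[x$best_epoch]))
  invisible(x)
}

#' @export
summary.resmini_fit <- function(object, ...) {
  print(object)
  cat("\nHistory (first/last epochs):\n")
  h <- object$history
  print(h[unique(c(1L, nrow(h))), ], row.names = FALSE)
  invisible(object$history)
}

#' @export
plot.resmini_fit <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$eval_loss), type = "l",
                    lty = 1, col = c("black", "red3"), xlab = "epoch",
                    ylab = "cross-entropy loss", main = "Loss")
  graphics::legend("topright", c("train", "eval"), lty = 1,
                   col = c("black", "red3"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_acc, h$eval_acc), type = "l",
                    lty = 1, col = c("black", "red3"), xlab = "epoch",
                    ylab = "accuracy", main = "Accuracy")
  invisible(h)
}

#' @export
predict.resmini_fit <- function(object, newdata,
                                type = c("response", "class", "score"),
                                use_best = TRUE, ...) {
  type <- match.arg(type)
  model <- if (use_best) best_model(object) else object$model
  res <- model_predict(model, newdata, object$normalizer,
                       object$config$batch_size)
  switch(type, response = res, class = res$pred_label, score = res$score_eCRS)
}

#' @export
coef.resmini_fit <- function(object, ...) nn_params(object$model)

#' Write a training history as CSV
#' @param fit a `resmini_fit` (or a history data.frame).
#' @param path output file.
#' @export
write_history <- function(fit, path) {
  h <- if (inherits(fit, "resmini_fit")) fit$history else fit
  utils::write.csv(h, path, row.names = FALSE)
  invisible(path)
}
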