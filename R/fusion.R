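# Three-view late-fusion classifier: per-view extractors, channel-wise
# feature-map concatenation, global average pooling, dense softmax head.

LABEL_LEVELS <- c("non-eCRS", "eCRS") # class index 0 / 1; eCRS is positive

#' Fusion model configuration
#'
#' @param n_views number of views (axial, coronal, sagittal).
#' @param n_classes number of endotype classes.
#' @param share_weights tie the three per-view extractors. Default off: each
#'   view learns its own extractor, consistent with three-fold per-view
#'   parameter totals.
#' @param backbone a [backbone_config()] for the per-view extractors.
#' @param head_width hidden width of the dense head (0 = single dense layer).
#' @export
fusion_config <- function(n_views = 3L, n_classes = 2L, share_weights = FALSE,
                          backbone = reference_config(),
                          head_width = reference_head_width()) {
  stopifnot(inherits(backbone, "backbone_config"), n_views >= 1, n_classes >= 2)
  structure(list(n_views = as.integer(n_views), n_classes = as.integer(n_classes),
                 share_weights = isTRUE(share_weights), backbone = backbone,
                 head_width = as.integer(head_width)),
            class = "fusion_config")
}

#' Build the multi-view fusion classifier
#'
#' Per-view ResMini extractors feed a channel-wise concatenation of their
#' feature maps (`n_views * 8 * base_filters` channels), followed by global
#' average pooling and the dense head. The network emits logits; [softmax()]
#' maps them to class probabilities.
#'
#' With `share_weights = TRUE` all views start from (and, under [train_model()],
#' are kept at) identical extractor weights.
#'
#' @param config a [fusion_config()].
#' @return an internal network module with attributes `fusion_config`.
#' @export
build_fusion_model <- function(config = fusion_config()) {
  stopifnot(inherits(config, "fusion_config"))
  branches <- if (config$share_weights) {
    one <- build_resmini_extractor(config$backbone)
    rep(list(one), config$n_views)
  } else {
    lapply(seq_len(config$n_views), function(i) build_resmini_extractor(config$backbone))
  }
  feat <- config$n_views * 8L * config$backbone$base_filters
  head <- if (config$head_width > 0L)
    nn_seq(nn_gap(), nn_dense(feat, config$head_width), nn_relu(),
           nn_dense(config$head_width, config$n_classes))
  else
    nn_seq(nn_gap(), nn_dense(feat, config$n_classes))
  model <- nn_multiview(branches, head)
  attr(model, "fusion_config") <- config
  model
}

# assemble a list of view groups into per-view [H,W,1,N] arrays (+ labels)
groups_to_arrays <- function(groups, normalizer = NULL, policy = NULL) {
  n <- length(groups)
  stopifnot(n > 0)
  views <- names(groups[[1]]$images)
  d <- dim(groups[[1]]$images[[1]])
  xs <- lapply(views, function(v) array(0, dim = c(d[1], d[2], 1L, n)))
  names(xs) <- views
  y <- integer(n)
  for (i in seq_len(n)) {
    g <- if (is.null(policy)) groups[[i]] else augment_group(groups[[i]], policy)
    for (v in views) {
      img <- g$images[[v]] / 255
      if (!is.null(normalizer)) img <- (img - normalizer$mean) / normalizer$sd
      xs[[v]][, , 1L, i] <- img
    }
    y[i] <- g$label
  }
  list(x = unname(xs), y = y)
}

#' Predict endotype labels and scores for view groups
#'
#' @param model a built fusion model (or a single-view classifier, given
#'   single-view groups).
#' @param groups list of view groups with images.
#' @param normalizer intensity normalizer fitted on the training set (see
#'   [fit_normalizer()]), or `NULL` for raw `[0, 1]` scaling.
#' @param batch_size forward-pass batch size.
#' @return a data.frame with `group_id`, `pred_label`, `score_eCRS` and the
#'   full probability columns; ties go to class 0 (non-eCRS).
#' @export
model_predict <- function(model, groups, normalizer = NULL, batch_size = 20L) {
  n <- length(groups)
  probs <- matrix(NA_real_, 2L, n)
  multi <- identical(model$kind, "multiview")
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    ba <- groups_to_arrays(groups[idx], normalizer)
    r <- nn_forward(model, if (multi) ba$x else ba$x[[1]], training = FALSE)
    probs[, idx] <- softmax(r$out)
  }
  # strict inequality: a 0.5/0.5 tie stays at class index 0 (non-eCRS)
  pred <- as.integer(probs[2L, ] > probs[1L, ])
  data.frame(
    group_id = vapply(groups, function(g) g$group_id, ""),
    true_label = LABEL_LEVELS[vapply(groups, function(g) g$label, 0L) + 1L],
    pred_label = LABEL_LEVELS[pred + 1L],
    score_eCRS = probs[2L, ],
    prob_non_eCRS = probs[1L, ],
    stringsAsFactors = FALSE)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds a format version, the fusion configuration and the
#' full module tree (weights and batch-norm running statistics).
#'
#' @param model a built network module.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format_version = 1L,
               fusion_config = attr(model, "fusion_config"),
               model = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$format_version) || ck$format_version != 1L)
    stop("load_checkpoint: unsupported checkpoint format")
  model <- ck$model
  attr(model, "fusion_config") <- ck$fusion_config
  model
}
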