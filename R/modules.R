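# Minimal neural-network module system: each module is a small S3 object, with
# recursive forward / backward passes and a flat named parameter interface for
# the optimizer. Activations are dense arrays [H, W, C, N]; vector features
# (after global pooling) are matrices [F, N].

new_module <- function(kind, fields = list()) {
  structure(c(list(kind = kind), fields), class = c(paste0("nn_", kind), "nn_module"))
}

#' @title Convolution module
#' @description 2-D convolution with square kernel, He-initialized weights.
#' Weight layout is `[kh, kw, in, out]`.
#' @param in_ch,out_ch channel counts
#' @param kernel odd square kernel edge
#' @param stride,padding integer geometry
#' @param use_bias include an additive per-output-channel bias
#' @return an `nn_module`
#' @keywords internal
nn_conv <- function(in_ch, out_ch, kernel, stride = 1L, padding = 0L, use_bias = TRUE) {
  if (in_ch < 1 || out_ch < 1) stop("conv: channel counts must be positive")
  sd <- sqrt(2 / (kernel * kernel * in_ch))
  w <- array(stats::rnorm(kernel * kernel * in_ch * out_ch, sd = sd),
             dim = c(kernel, kernel, in_ch, out_ch))
  new_module("conv", list(
    w = w, b = if (use_bias) numeric(out_ch) else NULL,
    stride = as.integer(stride), padding = as.integer(padding),
    in_ch = as.integer(in_ch), out_ch = as.integer(out_ch), kernel = as.integer(kernel)))
}

#' Batch normalization over the channel axis
#' @param ch channel count
#' @param momentum running-statistics update weight (torch convention:
#'   `running <- (1 - momentum) * running + momentum * batch`)
#' @param eps variance floor
#' @keywords internal
nn_bn <- function(ch, momentum = 0.1, eps = 1e-5) {
  new_module("bn", list(
    gamma = rep(1, ch), beta = numeric(ch),
    rmean = numeric(ch), rvar = rep(1, ch),
    momentum = momentum, eps = eps, ch = as.integer(ch)))
}

nn_relu <- function() new_module("relu")

#' Fused batch normalization + ReLU (the BN/activation tail of a CBA block);
#' numerically identical to `nn_bn` followed by `nn_relu` but with one pass
#' and half the cached tensors.
#' @keywords internal
nn_bnrelu <- function(ch, momentum = 0.1, eps = 1e-5) {
  new_module("bnrelu", list(
    gamma = rep(1, ch), beta = numeric(ch),
    rmean = numeric(ch), rvar = rep(1, ch),
    momentum = momentum, eps = eps, ch = as.integer(ch)))
}
nn_maxpool <- function(kernel = 3L, stride = 2L, padding = 1L)
  new_module("maxpool", list(kernel = as.integer(kernel), stride = as.integer(stride),
                             padding = as.integer(padding)))
nn_gap <- function() new_module("gap")

#' Dense (fully connected) layer on pooled feature vectors
#' @keywords internal
nn_dense <- function(in_f, out_f, use_bias = TRUE) {
  w <- matrix(stats::rnorm(in_f * out_f, sd = sqrt(2 / in_f)), in_f, out_f)
  new_module("dense", list(w = w, b = if (use_bias) numeric(out_f) else NULL,
                           in_f = as.integer(in_f), out_f = as.integer(out_f)))
}

nn_seq <- function(...) {
  mods <- list(...)
  if (length(mods) == 1 && is.list(mods[[1]]) && !inherits(mods[[1]], "nn_module"))
    mods <- mods[[1]]
  new_module("seq", list(modules = mods))
}

#' Residual unit: elementwise sum of a main branch and a shortcut branch
#' (`NULL` shortcut = identity); no post-merge activation.
#' @keywords internal
nn_residual <- function(main, shortcut = NULL)
  new_module("residual", list(main = main, shortcut = shortcut))

# Parallel branches on a shared input, channel-concatenated (fire modules,
# grouped convolutions).
nn_parallel <- function(branches) new_module("parallel", list(branches = branches))
nn_slice <- function(channels) new_module("slice", list(channels = as.integer(channels)))
nn_permute <- function(perm) new_module("permute", list(perm = as.integer(perm)))

#' Multi-view container: one extractor per view, channel-wise feature-map
#' concatenation, then a shared classification head.
#' @keywords internal
nn_multiview <- function(branches, head)
  new_module("multiview", list(branches = branches, head = head))

# ---------------------------------------------------------------------------
# forward

nn_forward <- function(mod, x, training = FALSE) {
  switch(mod$kind,
    conv = {
      out <- conv2d_forward_cpp(x, mod$w, mod$b, mod$stride, mod$padding)
      list(out = out, cache = list(x = x), mod = mod)
    },
    bn = {
      if (training) {
        st <- bn_stats_cpp(x)
        m <- st$mean; v <- st$var
        mod$rmean <- (1 - mod$momentum) * mod$rmean + mod$momentum * m
        mod$rvar <- (1 - mod$momentum) * mod$rvar + mod$momentum * v
      } else {
        m <- mod$rmean; v <- mod$rvar
      }
      invstd <- 1 / sqrt(v + mod$eps)
      r <- bn_forward_cpp(x, mod$gamma, mod$beta, m, invstd)
      list(out = r$out, cache = list(xhat = r$xhat, invstd = invstd, training = training),
           mod = mod)
    },
    bnrelu = {
      if (training) {
        st <- bn_stats_cpp(x)
        m <- st$mean; v <- st$var
        mod$rmean <- (1 - mod$momentum) * mod$rmean + mod$momentum * m
        mod$rvar <- (1 - mod$momentum) * mod$rvar + mod$momentum * v
      } else {
        m <- mod$rmean; v <- mod$rvar
      }
      invstd <- 1 / sqrt(v + mod$eps)
      out <- bnrelu_forward_cpp(x, mod$gamma, mod$beta, m, invstd)
      list(out = out,
           cache = list(x = x, out = out, m = m, invstd = invstd, training = training),
           mod = mod)
    },
    relu = {
      out <- relu_forward_cpp(x)
      list(out = out, cache = list(out = out), mod = mod)
    },
    maxpool = {
      r <- maxpool_forward_cpp(x, mod$kernel, mod$stride, mod$padding)
      list(out = r$out, cache = list(argmax = r$argmax, xdim = dim(x)), mod = mod)
    },
    gap = {
      d <- dim(x)
      out <- matrix(colMeans(matrix(x, d[1] * d[2])), d[3], d[4])
      list(out = out, cache = list(xdim = d), mod = mod)
    },
    dense = {
      out <- crossprod(mod$w, x)
      if (!is.null(mod$b)) out <- out + mod$b
      list(out = out, cache = list(x = x), mod = mod)
    },
    seq = {
      caches <- vector("list", length(mod$modules))
      for (i in seq_along(mod$modules)) {
        r <- nn_forward(mod$modules[[i]], x, training)
        x <- r$out; caches[[i]] <- r$cache; mod$modules[[i]] <- r$mod
      }
      list(out = x, cache = caches, mod = mod)
    },
    residual = {
      rm_ <- nn_forward(mod$main, x, training)
      mod$main <- rm_$mod
      if (is.null(mod$shortcut)) {
        out <- rm_$out + x
        list(out = out, cache = list(main = rm_$cache, shortcut = NULL), mod = mod)
      } else {
        rs <- nn_forward(mod$shortcut, x, training)
        mod$shortcut <- rs$mod
        if (!identical(dim(rm_$out), dim(rs$out)))
          stop("residual: branch output shapes differ")
        list(out = rm_$out + rs$out,
             cache = list(main = rm_$cache, shortcut = rs$cache), mod = mod)
      }
    },
    parallel = {
      outs <- vector("list", length(mod$branches)); caches <- outs
      for (i in seq_along(mod$branches)) {
        r <- nn_forward(mod$branches[[i]], x, training)
        outs[[i]] <- r$out; caches[[i]] <- r$cache; mod$branches[[i]] <- r$mod
      }
      list(out = concat_channels(outs),
           cache = list(caches = caches, widths = vapply(outs, function(o) dim(o)[3], 0L)),
           mod = mod)
    },
    slice = list(out = x[, , mod$channels, , drop = FALSE],
                 cache = list(xdim = dim(x)), mod = mod),
    permute = list(out = x[, , mod$perm, , drop = FALSE], cache = NULL, mod = mod),
    multiview = {
      stopifnot(is.list(x), length(x) == length(mod$branches))
      outs <- vector("list", length(mod$branches)); caches <- outs
      for (i in seq_along(mod$branches)) {
        r <- nn_forward(mod$branches[[i]], x[[i]], training)
        outs[[i]] <- r$out; caches[[i]] <- r$cache; mod$branches[[i]] <- r$mod
      }
      cat_ <- concat_channels(outs)
      rh <- nn_forward(mod$head, cat_, training)
      mod$head <- rh$mod
      list(out = rh$out,
           cache = list(branches = caches, head = rh$cache,
                        widths = vapply(outs, function(o) dim(o)[3], 0L)),
           mod = mod)
    },
    stop("unknown module kind: ", mod$kind))
}

concat_channels <- function(outs) {
  d1 <- dim(outs[[1]])
  cs <- vapply(outs, function(o) dim(o)[3], 0L)
  for (o in outs)
    if (!identical(dim(o)[c(1, 2, 4)], d1[c(1, 2, 4)]))
      stop("concat: mismatched spatial dimensions across branches")
  out <- array(0, dim = c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (i in seq_along(outs)) {
    out[, , at + seq_len(cs[i]), ] <- outs[[i]]
    at <- at + cs[i]
  }
  out
}

split_channels <- function(x, widths) {
  at <- 0L
  lapply(widths, function(w) {
    s <- x[, , at + seq_len(w), , drop = FALSE]
    at <<- at + w
    s
  })
}

# ---------------------------------------------------------------------------
# backward: returns list(dx = ..., grads = flat named list matching nn_params)

nn_backward <- function(mod, cache, dout, prefix = "") {
  p <- function(nm) if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
  switch(mod$kind,
    conv = {
      r <- conv2d_backward_cpp(cache$x, mod$w, dout, !is.null(mod$b),
                               mod$stride, mod$padding)
      g <- stats::setNames(list(r$dw), p("w"))
      if (!is.null(mod$b)) g[[p("b")]] <- r$db
      list(dx = r$dx, grads = g)
    },
    bn = {
      r <- bn_backward_cpp(cache$xhat, cache$invstd, mod$gamma, dout, cache$training)
      g <- stats::setNames(list(r$dgamma, r$dbeta), c(p("gamma"), p("beta")))
      list(dx = r$dx, grads = g)
    },
    bnrelu = {
      r <- bnrelu_backward_cpp(cache$x, cache$out, cache$m, cache$invstd,
                               mod$gamma, dout, cache$training)
      g <- stats::setNames(list(r$dgamma, r$dbeta), c(p("gamma"), p("beta")))
      list(dx = r$dx, grads = g)
    },
    relu = list(dx = relu_backward_cpp(cache$out, dout), grads = list()),
    maxpool = list(dx = maxpool_backward_cpp(cache$argmax, dout, cache$xdim),
                   grads = list()),
    gap = {
      d <- cache$xdim
      dx <- rep(as.vector(dout), each = d[1] * d[2]) / (d[1] * d[2])
      dim(dx) <- d
      list(dx = dx, grads = list())
    },
    dense = {
      g <- stats::setNames(list(cache$x %*% t(dout)), p("w"))
      if (!is.null(mod$b)) g[[p("b")]] <- rowSums(dout)
      list(dx = mod$w %*% dout, grads = g)
    },
    seq = {
      grads <- list()
      for (i in rev(seq_along(mod$modules))) {
        r <- nn_backward(mod$modules[[i]], cache[[i]], dout, p(paste0("l", i)))
        dout <- r$dx
        grads <- c(r$grads, grads)
      }
      list(dx = dout, grads = grads)
    },
    residual = {
      rm_ <- nn_backward(mod$main, cache$main, dout, p("main"))
      if (is.null(mod$shortcut)) {
        list(dx = rm_$dx + dout, grads = rm_$grads)
      } else {
        rs <- nn_backward(mod$shortcut, cache$shortcut, dout, p("shortcut"))
        list(dx = rm_$dx + rs$dx, grads = c(rm_$grads, rs$grads))
      }
    },
    parallel = {
      parts <- split_channels(dout, cache$widths)
      dx <- NULL; grads <- list()
      for (i in seq_along(mod$branches)) {
        r <- nn_backward(mod$branches[[i]], cache$caches[[i]], parts[[i]], p(paste0("b", i)))
        dx <- if (is.null(dx)) r$dx else dx + r$dx
        grads <- c(grads, r$grads)
      }
      list(dx = dx, grads = grads)
    },
    slice = {
      dx <- array(0, dim = cache$xdim)
      dx[, , mod$channels, ] <- dout
      list(dx = dx, grads = list())
    },
    permute = {
      inv <- order(mod$perm)
      list(dx = dout[, , inv, , drop = FALSE], grads = list())
    },
    multiview = {
      rh <- nn_backward(mod$head, cache$head, dout, p("head"))
      parts <- split_channels(rh$dx, cache$widths)
      dxs <- vector("list", length(mod$branches)); grads <- rh$grads
      for (i in seq_along(mod$branches)) {
        r <- nn_backward(mod$branches[[i]], cache$branches[[i]], parts[[i]], p(paste0("v", i)))
        dxs[[i]] <- r$dx
        grads <- c(r$grads, grads)
      }
      list(dx = dxs, grads = grads)
    },
    stop("unknown module kind: ", mod$kind))
}

# ---------------------------------------------------------------------------
# flat parameter interface

nn_params <- function(mod, prefix = "") {
  p <- function(nm) if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
  switch(mod$kind,
    conv = {
      out <- stats::setNames(list(mod$w), p("w"))
      if (!is.null(mod$b)) out[[p("b")]] <- mod$b
      out
    },
    bn = stats::setNames(list(mod$gamma, mod$beta), c(p("gamma"), p("beta"))),
    bnrelu = stats::setNames(list(mod$gamma, mod$beta), c(p("gamma"), p("beta"))),
    dense = {
      out <- stats::setNames(list(mod$w), p("w"))
      if (!is.null(mod$b)) out[[p("b")]] <- mod$b
      out
    },
    seq = {
      out <- list()
      for (i in seq_along(mod$modules))
        out <- c(out, nn_params(mod$modules[[i]], p(paste0("l", i))))
      out
    },
    residual = c(nn_params(mod$main, p("main")),
                 if (!is.null(mod$shortcut)) nn_params(mod$shortcut, p("shortcut"))),
    parallel = {
      out <- list()
      for (i in seq_along(mod$branches))
        out <- c(out, nn_params(mod$branches[[i]], p(paste0("b", i))))
      out
    },
    multiview = {
      out <- list()
      for (i in seq_along(mod$branches))
        out <- c(out, nn_params(mod$branches[[i]], p(paste0("v", i))))
      c(out, nn_params(mod$head, p("head")))
    },
    list())
}

nn_set_params <- function(mod, flat, prefix = "") {
  p <- function(nm) if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
  switch(mod$kind,
    conv = {
      mod$w <- array(flat[[p("w")]], dim = dim(mod$w))
      if (!is.null(mod$b)) mod$b <- as.numeric(flat[[p("b")]])
      mod
    },
    bn = {
      mod$gamma <- as.numeric(flat[[p("gamma")]])
      mod$beta <- as.numeric(flat[[p("beta")]])
      mod
    },
    bnrelu = {
      mod$gamma <- as.numeric(flat[[p("gamma")]])
      mod$beta <- as.numeric(flat[[p("beta")]])
      mod
    },
    dense = {
      mod$w <- matrix(flat[[p("w")]], nrow(mod$w), ncol(mod$w))
      if (!is.null(mod$b)) mod$b <- as.numeric(flat[[p("b")]])
      mod
    },
    seq = {
      for (i in seq_along(mod$modules))
        mod$modules[[i]] <- nn_set_params(mod$modules[[i]], flat, p(paste0("l", i)))
      mod
    },
    residual = {
      mod$main <- nn_set_params(mod$main, flat, p("main"))
      if (!is.null(mod$shortcut))
        mod$shortcut <- nn_set_params(mod$shortcut, flat, p("shortcut"))
      mod
    },
    parallel = {
      for (i in seq_along(mod$branches))
        mod$branches[[i]] <- nn_set_params(mod$branches[[i]], flat, p(paste0("b", i)))
      mod
    },
    multiview = {
      for (i in seq_along(mod$branches))
        mod$branches[[i]] <- nn_set_params(mod$branches[[i]], flat, p(paste0("v", i)))
      mod$head <- nn_set_params(mod$head, flat, p("head"))
      mod
    },
    mod)
}

#' Column-wise softmax
#'
#' @param logits numeric matrix, one column per sample.
#' @return matrix of the same shape whose columns are probability vectors.
#' @export
softmax <- function(logits) {
  logits <- as.matrix(logits)
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}
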