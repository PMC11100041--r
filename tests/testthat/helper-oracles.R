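# Independent oracles and small fixture builders used across the suite.

# brute-force parameter enumeration: walk the raw list structure and count
# elements of every weight array, independently of count_parameters()
enumerate_params <- function(mod, include_bn_stats = TRUE) {
  total <- 0
  fields <- c("w", "b", "gamma", "beta")
  if (include_bn_stats) fields <- c(fields, "rmean", "rvar")
  for (f in fields) if (!is.null(mod[[f]])) total <- total + length(mod[[f]])
  for (f in c("modules", "branches")) if (!is.null(mod[[f]]))
    for (child in mod[[f]]) total <- total + enumerate_params(child, include_bn_stats)
  for (f in c("main", "shortcut", "head")) if (!is.null(mod[[f]]))
    total <- total + enumerate_params(mod[[f]], include_bn_stats)
  total
}

# O(n^2) pairwise-concordance AUC with half-credit for ties
auc_pairwise <- function(truth, scores) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# naive direct convolution (quadruple loop) for small inputs
naive_conv <- function(x, w, b, stride, pad) {
  d <- dim(x); wd <- dim(w)
  Ho <- (d[1] + 2 * pad - wd[1]) %/% stride + 1
  Wo <- (d[2] + 2 * pad - wd[2]) %/% stride + 1
  out <- array(0, c(Ho, Wo, wd[4], d[4]))
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  for (n in seq_len(d[4])) for (co in seq_len(wd[4]))
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- if (is.null(b)) 0 else b[co]
      for (ci in seq_len(d[3])) for (ki in seq_len(wd[1])) for (kj in seq_len(wd[2]))
        acc <- acc + xp[(ho - 1) * stride + ki, (wo - 1) * stride + kj, ci, n] *
          w[ki, kj, ci, co]
      out[ho, wo, co, n] <- acc
    }
  out
}

# small in-memory groups (any geometry) for fast trainer tests; bypasses the
# 224x224 cohort invariant on purpose
tiny_groups <- function(n, size = 32L, margin = 60, seed = 1L, n_views = 3L) {
  resmini:::with_seed(seed, lapply(seq_len(n), function(i) {
    cls <- as.integer(i %% 2L == 0L)
    imgs <- lapply(seq_len(n_views), function(v)
      pmin(pmax(round(80 + cls * margin +
                        matrix(rnorm(size^2, sd = 5), size, size)), 0), 255))
    names(imgs) <- resmini:::VIEW_NAMES[seq_len(n_views)]
    structure(list(group_id = sprintf("tiny_g%03d", i),
                   patient_id = sprintf("tiny_p%03d", i),
                   label = cls, images = imgs, flags = character()),
              class = "view_group")
  }))
}

# small fusion model for tiny geometries
tiny_fusion <- function(base = 4L, head_width = 8L, seed = 1L) {
  resmini:::with_seed(seed, build_fusion_model(fusion_config(
    backbone = backbone_config(base_filters = base), head_width = head_width)))
}
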