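# Training-time augmentations: panning (translation), flipping, rotating,
# scaling and cropping, as seeded composable transforms on 224x224 rasters.

#' Augmentation policy
#'
#' Magnitudes default to conservative ranges; all are config-exposed. Each
#' view of a group is transformed independently (a shared geometric transform
#' has no anatomical meaning across orthogonal planes). Out-of-frame pixels
#' are filled with 0 (air-equivalent background).
#'
#' @param translate maximum translation as a fraction of the image edge
#'   (sampled uniformly in `[-translate, translate]` per axis).
#' @param rotate maximum rotation in degrees (uniform in `[-rotate, rotate]`).
#' @param scale two-element range of isotropic scale factors.
#' @param flip_prob probability of a horizontal flip.
#' @param crop_pad zero-pad margin in pixels before randomly cropping back to
#'   the input geometry (0 disables cropping).
#' @export
augment_policy <- function(translate = 0.10, rotate = 15, scale = c(0.9, 1.1),
                           flip_prob = 0.5, crop_pad = 8L) {
  if (translate < 0 || rotate < 0 || crop_pad < 0)
    stop("augment_policy: ranges must be non-negative")
  if (length(scale) != 2 || scale[1] > scale[2] || scale[1] <= 0)
    stop("augment_policy: scale must be a valid (min, max) range")
  if (flip_prob < 0 || flip_prob > 1)
    stop("augment_policy: flip_prob must be in [0, 1]")
  structure(list(translate = translate, rotate = rotate, scale = scale,
                 flip_prob = flip_prob, crop_pad = as.integer(crop_pad)),
            class = "augment_policy")
}

#' The do-nothing policy (useful for tests and ablations)
#' @export
identity_policy <- function()
  augment_policy(translate = 0, rotate = 0, scale = c(1, 1),
                 flip_prob = 0, crop_pad = 0L)

# draw one parameter set from the policy using the current RNG stream
sample_augment_params <- function(policy, size) {
  list(theta = stats::runif(1, -policy$rotate, policy$rotate) * pi / 180,
       scale = stats::runif(1, policy$scale[1], policy$scale[2]),
       tx = stats::runif(1, -policy$translate, policy$translate) * size,
       ty = stats::runif(1, -policy$translate, policy$translate) * size,
       flip = stats::runif(1) < policy$flip_prob,
       crop = if (policy$crop_pad > 0)
         c(sample.int(2L * policy$crop_pad + 1L, 1L),
           sample.int(2L * policy$crop_pad + 1L, 1L)) else NULL)
}

# inverse-mapped bilinear warp: rotation theta + isotropic scale about the
# image center, then translation (tx, ty) pixels; zero fill outside the frame
warp_affine <- function(img, theta, scale, tx, ty) {
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ct <- cos(theta) / scale; st <- sin(theta) / scale
  yy <- matrix(seq_len(h) - cy - ty, h, w)
  xx <- matrix(rep(seq_len(w) - cx - tx, each = h), h, w)
  sy <- ct * yy - st * xx + cy
  sx <- st * yy + ct * xx + cx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  gather <- function(yi, xi) {
    ok <- yi >= 1 & yi <= h & xi >= 1 & xi <= w
    v <- numeric(length(yi))
    v[ok] <- img[(xi[ok] - 1) * h + yi[ok]]
    v
  }
  v <- gather(y0, x0) * (1 - fy) * (1 - fx) + gather(y0 + 1, x0) * fy * (1 - fx) +
    gather(y0, x0 + 1) * (1 - fy) * fx + gather(y0 + 1, x0 + 1) * fy * fx
  matrix(v, h, w)
}

apply_augment_params <- function(img, pars) {
  if (pars$theta != 0 || pars$scale != 1 || pars$tx != 0 || pars$ty != 0)
    img <- warp_affine(img, pars$theta, pars$scale, pars$tx, pars$ty)
  if (pars$flip) img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
  if (!is.null(pars$crop)) {
    h <- nrow(img); w <- ncol(img)
    pad <- attr(pars, "crop_pad")
    padded <- matrix(0, h + 2 * pad, w + 2 * pad)
    padded[pad + seq_len(h), pad + seq_len(w)] <- img
    img <- padded[pars$crop[1] + seq_len(h) - 1L, pars$crop[2] + seq_len(w) - 1L]
  }
  img
}

#' Augment one three-view group
#'
#' Each view is transformed independently with parameters drawn from the
#' seeded stream; geometry and label are preserved.
#'
#' @param group a `view_group` with images.
#' @param policy an [augment_policy()].
#' @param seed optional seed; if `NULL` the current RNG stream is consumed
#'   (as done inside the training loop, which is itself seeded).
#' @return the augmented `view_group`.
#' @export
augment_group <- function(group, policy = augment_policy(), seed = NULL) {
  stopifnot(inherits(policy, "augment_policy"))
  go <- function() {
    for (v in names(group$images)) {
      img <- group$images[[v]]
      pars <- sample_augment_params(policy, nrow(img))
      attr(pars, "crop_pad") <- policy$crop_pad
      group$images[[v]] <- apply_augment_params(img, pars)
    }
    group
  }
  if (is.null(seed)) go() else with_seed(seed, go())
}
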