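# Seeded generator of synthetic three-view sinus-CT-like cohorts. Each image
# is a head-like elliptical phantom with four dark sinus-like cavities; the
# eCRS class receives soft-intensity opacification in both anterior and
# posterior cavities, non-eCRS in the anterior pair only. No anatomical
# realism is claimed; the generator reproduces the *class structure* the
# classifier assumes (see the methods vignette).

#' Synthetic cohort specification
#'
#' The full-size cohort mirrors the study's class sizes (72 eCRS / 120
#' non-eCRS patients, ~37 groups per patient); the default is a desk-scale
#' cohort with the same 3:5 class ratio.
#'
#' @param n_ecrs,n_non_ecrs patients per class; `NULL` picks 12/20 at desk
#'   scale or 72/120 with `full_size = TRUE`.
#' @param groups_per_patient mean groups per patient (jittered +/- 25%);
#'   `NULL` picks 8 at desk scale, 37 at full size.
#' @param signal class-signal strength in `[0, 1]`: scales the intensity of
#'   the opacification blobs (0 removes them for both classes).
#' @param noise additive Gaussian pixel noise, standard deviation in
#'   intensity units (0-255 scale).
#' @param view_signal `"all"`: the discriminative posterior opacities appear
#'   in all three views; `"single_random"`: in exactly one view per group,
#'   chosen at random (the regime where fusion must beat any single view).
#' @param full_size use the study-scale cohort sizes.
#' @param seed generator seed; everything downstream is a pure function of
#'   (spec, seed).
#' @export
synthetic_spec <- function(n_ecrs = NULL, n_non_ecrs = NULL,
                           groups_per_patient = NULL, signal = 0.7,
                           noise = 8, view_signal = c("all", "single_random"),
                           full_size = FALSE, seed = 1L) {
  view_signal <- match.arg(view_signal)
  if (is.null(n_ecrs)) n_ecrs <- if (full_size) 72L else 12L
  if (is.null(n_non_ecrs)) n_non_ecrs <- if (full_size) 120L else 20L
  if (is.null(groups_per_patient)) groups_per_patient <- if (full_size) 37L else 8L
  if (n_ecrs < 1 || n_non_ecrs < 1)
    stop("synthetic_spec: at least one patient per class")
  stopifnot(signal >= 0, signal <= 1, noise >= 0, groups_per_patient >= 1)
  structure(list(n_ecrs = as.integer(n_ecrs), n_non_ecrs = as.integer(n_non_ecrs),
                 groups_per_patient = as.integer(groups_per_patient),
                 image_size = IMAGE_SIZE, signal = signal, noise = noise,
                 view_signal = view_signal, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# canonical cavity centers (dy, dx relative to head center) and radii per
# view; "anterior" = upper pair, "posterior" = lower pair of the phantom
CAVITY_LAYOUT <- list(
  axial = list(anterior = list(c(-38, -26), c(-38, 26)),
               posterior = list(c(26, -20), c(26, 20)), r = 16),
  coronal = list(anterior = list(c(-30, -30), c(-30, 30)),
                 posterior = list(c(30, -24), c(30, 24)), r = 15),
  sagittal = list(anterior = list(c(-34, -34), c(-10, -38)),
                  posterior = list(c(24, 24), c(2, 34)), r = 14))

draw_phantom <- function(size, view, pat, grp, label, signal, post_in_view, noise) {
  cy <- size / 2 + pat$cy; cx <- size / 2 + pat$cx
  yy <- matrix(seq_len(size), size, size) - cy
  xx <- matrix(rep(seq_len(size), each = size), size, size) - cx
  ry <- pat$ry; rx <- pat$rx
  rad2 <- (yy / ry)^2 + (xx / rx)^2
  img <- matrix(0, size, size)
  img[rad2 <= 1] <- 118 + 10 * (yy[rad2 <= 1] / ry) # soft tissue + mild gradient
  rim <- rad2 <= 1 & rad2 >= 0.88
  img[rim] <- 208 # skull
  lay <- CAVITY_LAYOUT[[view]]
  blob <- function(center, r, value, frac = 1) {
    dy <- yy + cy - (cy + center[1] + grp$jy)
    dx <- xx + cx - (cx + center[2] + grp$jx)
    m <- (dy / (r * frac))^2 + (dx / (r * frac))^2 <= 1
    img[m] <<- value
  }
  r <- lay$r + pat$dr
  for (ctr in lay$anterior) blob(ctr, r, 12) # air-filled cavity
  for (ctr in lay$posterior) blob(ctr, r, 12)
  opac <- 12 + signal * (118 - 12)
  if (signal > 0) {
    for (ctr in lay$anterior) blob(ctr, r, opac, frac = 0.85)
    if (label == 1L && post_in_view)
      for (ctr in lay$posterior) blob(ctr, r, opac, frac = 0.85)
  }
  if (noise > 0) img <- img + matrix(stats::rnorm(size * size, sd = noise), size, size)
  # integer storage halves the resident size of large cohorts
  matrix(as.integer(pmin(pmax(round(img), 0), 255)), size, size)
}

# generate all groups in memory; pure function of the spec (incl. its seed)
generate_cohort_groups <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    groups <- list()
    for (cls in c(1L, 0L)) {
      npat <- if (cls == 1L) spec$n_ecrs else spec$n_non_ecrs
      for (p in seq_len(npat)) {
        pid <- sprintf("%s_p%03d", if (cls == 1L) "ecrs" else "nonecrs", p)
        pat <- list(cy = stats::runif(1, -5, 5), cx = stats::runif(1, -5, 5),
                    ry = stats::runif(1, 90, 100), rx = stats::runif(1, 76, 86),
                    dr = stats::runif(1, -2, 2))
        ng <- max(1L, round(spec$groups_per_patient *
                              stats::runif(1, 0.75, 1.25)))
        for (g in seq_len(ng)) {
          gid <- sprintf("%s_g%03d", pid, g)
          grp <- list(jy = stats::runif(1, -3, 3), jx = stats::runif(1, -3, 3))
          sig_view <- if (spec$view_signal == "single_random")
            VIEW_NAMES[sample.int(3L, 1L)] else VIEW_NAMES
          imgs <- lapply(VIEW_NAMES, function(v)
            draw_phantom(spec$image_size, v, pat, grp, cls, spec$signal,
                         v %in% sig_view, spec$noise))
          names(imgs) <- VIEW_NAMES
          groups[[length(groups) + 1L]] <-
            view_group(gid, pid, cls, images = imgs)
        }
      }
    }
    groups
  })
}

#' Generate a synthetic three-view cohort
#'
#' With `dir = NULL` the cohort is returned in memory; otherwise 8-bit
#' grayscale PNGs, a manifest CSV conforming to the dataio schema, and the
#' spec (YAML, for provenance) are written under `dir`. The pixel content is
#' identical in both modes and byte-identical across runs with the same spec.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory, or `NULL` for in-memory generation.
#' @return invisibly, a list with `groups` and (when writing) `manifest`.
#' @export
generate_cohort <- function(spec = synthetic_spec(), dir = NULL) {
  groups <- generate_cohort_groups(spec)
  if (is.null(dir)) return(invisible(list(groups = groups, manifest = NULL)))
  imgdir <- file.path(dir, "images")
  dir.create(imgdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(imgdir)) stop("generate_cohort: cannot create ", imgdir)
  rows <- lapply(groups, function(g) {
    paths <- vapply(VIEW_NAMES, function(v) {
      f <- file.path("images", paste0(g$group_id, "_", v, ".png"))
      png::writePNG(g$images[[v]] / 255, file.path(dir, f))
      f
    }, "")
    data.frame(group_id = g$group_id, patient_id = g$patient_id,
               label = LABEL_LEVELS[g$label + 1L],
               axial_path = paths[["axial"]], coronal_path = paths[["coronal"]],
               sagittal_path = paths[["sagittal"]], stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  yaml::write_yaml(unclass(spec), file.path(dir, "spec.yaml"))
  invisible(list(groups = groups, manifest = manifest))
}

#' Trivially separable two-class three-view toy set
#'
#' Class 1 images are brighter than class 0 by `margin` intensity units, so a
#' threshold on mean intensity alone separates the classes; used for overfit
#' sanity runs.
#'
#' @param n number of groups (split evenly between classes).
#' @param margin intensity gap between the class means.
#' @param seed generator seed.
#' @export
make_separable_toyset <- function(n = 60L, margin = 60, seed = 1L) {
  stopifnot(n >= 2, margin > 0)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      cls <- as.integer(i > n / 2)
      base <- 80 + cls * margin
      imgs <- lapply(VIEW_NAMES, function(v) {
        img <- base + matrix(stats::rnorm(IMAGE_SIZE^2, sd = 5),
                             IMAGE_SIZE, IMAGE_SIZE)
        matrix(as.integer(pmin(pmax(round(img), 0), 255)), IMAGE_SIZE, IMAGE_SIZE)
      })
      names(imgs) <- VIEW_NAMES
      view_group(sprintf("toy_g%03d", i), sprintf("toy_p%03d", i), cls,
                 images = imgs)
    })
  })
}
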