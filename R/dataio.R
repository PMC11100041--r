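# Manifest-driven loading of three-view groups, intensity normalization and
# the split conventions (4:1 train/test, 5-fold CV, group- or patient-level).

VIEW_NAMES <- c("axial", "coronal", "sagittal")
MANIFEST_COLUMNS <- c("group_id", "patient_id", "label",
                      "axial_path", "coronal_path", "sagittal_path")
IMAGE_SIZE <- 224L

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a three-view group
#'
#' @param group_id unique group identifier.
#' @param patient_id patient the group belongs to.
#' @param label `"eCRS"` or `"non-eCRS"` (or the class index 1 / 0).
#' @param paths named character vector of the three view image paths.
#' @param images named list of three `224 x 224` numeric matrices with
#'   intensities in `[0, 255]`.
#' @return a `view_group` object; `label` is stored as the class index
#'   (0 = non-eCRS, 1 = eCRS).
#' @export
view_group <- function(group_id, patient_id, label, paths = NULL, images = NULL) {
  if (is.character(label)) {
    if (!label %in% LABEL_LEVELS)
      stop("view_group: unknown label '", label, "'")
    label <- match(label, LABEL_LEVELS) - 1L
  }
  g <- structure(list(group_id = as.character(group_id),
                      patient_id = as.character(patient_id),
                      label = as.integer(label), paths = paths,
                      images = images, flags = character()),
                 class = "view_group")
  if (!is.null(images)) validate_view_group(g)
  g
}

#' Validate a view group's invariants (three 224x224 views, intensities in
#' `[0, 255]`)
#' @param g a `view_group`.
#' @export
validate_view_group <- function(g) {
  stopifnot(inherits(g, "view_group"))
  if (!identical(sort(names(g$images)), sort(VIEW_NAMES)))
    stop("view_group: expected exactly the three views ",
         paste(VIEW_NAMES, collapse = ", "))
  for (v in VIEW_NAMES) {
    img <- g$images[[v]]
    if (!is.matrix(img) || !identical(dim(img), c(IMAGE_SIZE, IMAGE_SIZE)))
      stop("view_group ", g$group_id, ": view '", v, "' is not 224 x 224")
    if (anyNA(img) || min(img) < 0 || max(img) > 255)
      stop("view_group ", g$group_id, ": view '", v,
           "' intensities outside [0, 255]")
  }
  invisible(g)
}

#' Load a three-view manifest CSV
#'
#' Expected columns: `group_id, patient_id, label, axial_path, coronal_path,
#' sagittal_path`; labels must be `eCRS` or `non-eCRS`; `group_id` must be
#' unique.
#'
#' @param path CSV file.
#' @return a list of `view_group` stubs (paths, no pixel data).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(missing))
    stop("manifest: missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0) {
    warning("manifest: no rows in ", path)
    return(list())
  }
  bad <- which(!df$label %in% LABEL_LEVELS)
  if (length(bad))
    stop("manifest: unknown label '", df$label[bad[1]], "' in row ", bad[1])
  dup <- which(duplicated(df$group_id))
  if (length(dup))
    stop("manifest: duplicate group_id '", df$group_id[dup[1]], "' in row ", dup[1])
  base <- dirname(path)
  lapply(seq_len(nrow(df)), function(i) {
    p <- vapply(paste0(VIEW_NAMES, "_path"), function(col) {
      f <- df[[col]][i]
      if (file.exists(f)) f else file.path(base, f) # paths relative to manifest
    }, "")
    names(p) <- VIEW_NAMES
    view_group(df$group_id[i], df$patient_id[i], df$label[i], paths = p)
  })
}

# Rec. 601 luminance weights for RGB -> grayscale conversion
LUMA_WEIGHTS <- c(0.299, 0.587, 0.114)

#' Load the pixel data of a manifest stub
#'
#' Reads the three 8-bit grayscale PNGs. RGB inputs are collapsed with
#' Rec. 601 luminance weights and flagged; inputs that are not 224x224 are
#' resized with bilinear interpolation and flagged.
#'
#' @param stub a `view_group` from [load_manifest()].
#' @return the `view_group` with `images` filled in and `flags` recording any
#'   conversions.
#' @export
load_group_images <- function(stub) {
  stopifnot(inherits(stub, "view_group"), !is.null(stub$paths))
  imgs <- list(); flags <- character()
  for (v in VIEW_NAMES) {
    f <- stub$paths[[v]]
    if (!file.exists(f)) stop("load_group_images: file not found: ", f)
    raw <- tryCatch(png::readPNG(f, info = TRUE),
                    error = function(e) stop("load_group_images: cannot read ", f,
                                             ": ", conditionMessage(e)))
    info <- attr(raw, "info")
    if (!is.null(info$bit.depth) && info$bit.depth != 8)
      stop("load_group_images: ", f, " is not 8-bit (bit depth ",
           info$bit.depth, ")")
    if (length(dim(raw)) == 3) {
      nc <- dim(raw)[3]
      if (nc >= 3) {
        raw <- raw[, , 1] * LUMA_WEIGHTS[1] + raw[, , 2] * LUMA_WEIGHTS[2] +
          raw[, , 3] * LUMA_WEIGHTS[3]
        flags <- c(flags, paste0(v, ":grayscale_converted"))
      } else {
        raw <- raw[, , 1] # gray + alpha
        flags <- c(flags, paste0(v, ":alpha_dropped"))
      }
    }
    if (!identical(dim(raw), c(IMAGE_SIZE, IMAGE_SIZE))) {
      raw <- resize_bilinear(raw, IMAGE_SIZE, IMAGE_SIZE)
      flags <- c(flags, paste0(v, ":resized"))
    }
    imgs[[v]] <- matrix(as.integer(round(raw * 255)), nrow(raw), ncol(raw))
  }
  g <- stub
  g$images <- imgs
  g$flags <- flags
  validate_view_group(g)
  g
}

# bilinear resize of a numeric matrix (align-corners-free convention)
resize_bilinear <- function(img, h, w) {
  sh <- nrow(img) / h; sw <- ncol(img) / w
  ys <- pmin(pmax((seq_len(h) - 0.5) * sh + 0.5, 1), nrow(img))
  xs <- pmin(pmax((seq_len(w) - 0.5) * sw + 0.5, 1), ncol(img))
  y0 <- pmin(floor(ys), nrow(img) - 1L); x0 <- pmin(floor(xs), ncol(img) - 1L)
  fy <- ys - y0; fx <- xs - x0
  a <- img[y0, x0, drop = FALSE]; b <- img[y0 + 1, x0, drop = FALSE]
  c_ <- img[y0, x0 + 1, drop = FALSE]; d <- img[y0 + 1, x0 + 1, drop = FALSE]
  wa <- outer(1 - fy, 1 - fx); wb <- outer(fy, 1 - fx)
  wc <- outer(1 - fy, fx); wd <- outer(fy, fx)
  a * wa + b * wb + c_ * wc + d * wd
}

#' Fit the intensity normalizer on a training set
#'
#' Images are first scaled to `[0, 1]` (divide by 255); the normalizer stores
#' the mean and standard deviation of the training pixels on that scale, so
#' standardized training data has mean ~0 and deviation ~1.
#'
#' @param groups training `view_group`s with images.
#' @return an `intensity_normalizer` list with `mean` and `sd`.
#' @export
fit_normalizer <- function(groups) {
  stopifnot(length(groups) > 0)
  s <- 0; s2 <- 0; n <- 0
  for (g in groups) for (img in g$images) {
    x <- img / 255
    s <- s + sum(x); s2 <- s2 + sum(x * x); n <- n + length(x)
  }
  m <- s / n
  sd <- sqrt(max(s2 / n - m^2, 0))
  if (sd == 0) sd <- 1
  structure(list(mean = m, sd = sd, n_pixels = n), class = "intensity_normalizer")
}

#' Normalize one raster with a fitted normalizer
#' @param img matrix with intensities in `[0, 255]`.
#' @param normalizer an [fit_normalizer()] result, or `NULL` to stop at the
#'   `[0, 1]` scaling.
#' @export
normalize_image <- function(img, normalizer = NULL) {
  x <- img / 255
  if (is.null(normalizer)) return(x)
  (x - normalizer$mean) / normalizer$sd
}

#' Split configuration
#' @param ratio training fraction (the 4:1 convention = 0.8).
#' @param level `"group"` (the printed-count convention) or `"patient"`
#'   (leakage-safe: all of a patient's groups fall on one side).
#' @param seed shuffle seed.
#' @param k number of cross-validation folds.
#' @export
split_config <- function(ratio = 0.8, level = c("group", "patient"),
                         seed = 1L, k = 5L) {
  level <- match.arg(level)
  stopifnot(ratio > 0, ratio < 1, k >= 2)
  structure(list(ratio = ratio, level = level, seed = as.integer(seed),
                 k = as.integer(k)), class = "split_config")
}

#' Train/test split under the floor convention
#'
#' Group level: `floor(ratio * N)` groups train, remainder test, assignment by
#' seeded shuffle. Patient level: the floor rule is applied to patients and a
#' patient's groups always stay together.
#'
#' @param groups list of `view_group`s (stubs suffice).
#' @param config a [split_config()].
#' @return list with `train` and `test` group lists.
#' @export
split_train_test <- function(groups, config = split_config()) {
  n <- length(groups)
  if (n == 0) stop("split_train_test: empty group list")
  if (config$level == "group") {
    ord <- with_seed(config$seed, sample.int(n))
    ntr <- floor(config$ratio * n)
    list(train = groups[sort(ord[seq_len(ntr)])],
         test = groups[sort(ord[-seq_len(ntr)])])
  } else {
    pid <- vapply(groups, function(g) g$patient_id, "")
    pats <- unique(pid)
    ord <- with_seed(config$seed, sample(pats))
    ntr <- floor(config$ratio * length(pats))
    trp <- ord[seq_len(ntr)]
    list(train = groups[pid %in% trp], test = groups[!pid %in% trp])
  }
}

#' Seeded k-fold assignment
#'
#' Each group lands in exactly one test fold. Group level: fold sizes differ
#' by at most one. Patient level: patients are assigned to folds whole.
#'
#' @param groups list of `view_group`s.
#' @param config a [split_config()]; `config$k` folds.
#' @return integer vector of fold indices (1..k), one per group.
#' @export
kfold <- function(groups, config = split_config()) {
  n <- length(groups)
  if (n < config$k) stop("kfold: fewer groups than folds")
  if (config$level == "group") {
    ord <- with_seed(config$seed, sample.int(n))
    folds <- integer(n)
    folds[ord] <- rep_len(seq_len(config$k), n)
    folds
  } else {
    pid <- vapply(groups, function(g) g$patient_id, "")
    pats <- unique(pid)
    if (length(pats) < config$k) stop("kfold: fewer patients than folds")
    ord <- with_seed(config$seed, sample(pats))
    pf <- integer(length(pats))
    pf[match(ord, pats)] <- rep_len(seq_len(config$k), length(pats))
    pf[match(pid, pats)]
  }
}

#' Export a split or fold assignment as a data.frame (writable as CSV)
#' @param groups list of `view_group`s.
#' @param assignment character/integer vector, one entry per group.
#' @export
assignment_frame <- function(groups, assignment) {
  data.frame(group_id = vapply(groups, function(g) g$group_id, ""),
             partition = assignment, stringsAsFactors = FALSE)
}
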