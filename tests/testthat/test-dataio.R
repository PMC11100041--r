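# Manifest loading, normalization and split conventions.

write_mini_cohort <- function(dir, n_groups = 3L, size = 224L) {
  imgdir <- file.path(dir, "images")
  dir.create(imgdir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_len(n_groups), function(i) {
    paths <- vapply(resmini:::VIEW_NAMES, function(v) {
      f <- file.path("images", sprintf("g%02d_%s.png", i, v))
      img <- matrix(runif(size^2), size, size)
      png::writePNG(img, file.path(dir, f))
      f
    }, "")
    data.frame(group_id = sprintf("g%02d", i), patient_id = sprintf("p%02d", i),
               label = c("eCRS", "non-eCRS")[i %% 2 + 1],
               axial_path = paths[[1]], coronal_path = paths[[2]],
               sagittal_path = paths[[3]], stringsAsFactors = FALSE)
  })
  mf <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), mf, row.names = FALSE)
  mf
}

test_that("well-formed manifests load; malformed ones fail with row context", {
  dir <- withr::local_tempdir()
  mf <- write_mini_cohort(dir, 3L)
  stubs <- load_manifest(mf)
  expect_length(stubs, 3L)
  expect_s3_class(stubs[[1]], "view_group")

  df <- read.csv(mf, stringsAsFactors = FALSE)
  df$label[2] <- "fungal"
  bad <- file.path(dir, "bad.csv"); write.csv(df, bad, row.names = FALSE)
  expect_error(load_manifest(bad), "unknown label 'fungal' in row 2")

  df <- read.csv(mf, stringsAsFactors = FALSE)
  df$group_id[3] <- df$group_id[1]
  dup <- file.path(dir, "dup.csv"); write.csv(df, dup, row.names = FALSE)
  expect_error(load_manifest(dup), "duplicate group_id")

  df <- read.csv(mf, stringsAsFactors = FALSE)
  df$patient_id <- NULL
  mis <- file.path(dir, "mis.csv"); write.csv(df, mis, row.names = FALSE)
  expect_error(load_manifest(mis), "missing column")

  empty <- file.path(dir, "empty.csv")
  write.csv(read.csv(mf)[0, ], empty, row.names = FALSE)
  expect_warning(res <- load_manifest(empty), "no rows")
  expect_length(res, 0L)
})

test_that("image loading validates geometry and converts flagged inputs", {
  dir <- withr::local_tempdir()
  mf <- write_mini_cohort(dir, 1L)
  g <- load_group_images(load_manifest(mf)[[1]])
  expect_identical(dim(g$images$axial), c(224L, 224L))
  expect_length(g$flags, 0L)
  expect_true(all(g$images$axial >= 0 & g$images$axial <= 255))

  # oversized input: resized and flagged
  big <- file.path(dir, "images", "big.png")
  png::writePNG(matrix(runif(512^2), 512, 512), big)
  stub <- load_manifest(mf)[[1]]
  stub$paths[["axial"]] <- big
  g2 <- load_group_images(stub)
  expect_identical(dim(g2$images$axial), c(224L, 224L))
  expect_true("axial:resized" %in% g2$flags)

  # RGB input: collapsed by luminance weights and flagged
  rgb <- file.path(dir, "images", "rgb.png")
  png::writePNG(array(runif(224 * 224 * 3), c(224, 224, 3)), rgb)
  stub$paths[["axial"]] <- rgb
  g3 <- load_group_images(stub)
  expect_true("axial:grayscale_converted" %in% g3$flags)

  stub$paths[["axial"]] <- file.path(dir, "missing.png")
  expect_error(load_group_images(stub), "not found")
})

test_that("normalization standardizes the training partition to mean 0, sd 1", {
  groups <- make_separable_toyset(10, seed = 41)
  norm <- fit_normalizer(groups)
  vals <- unlist(lapply(groups, function(g)
    lapply(g$images, normalize_image, normalizer = norm)))
  expect_equal(mean(vals), 0, tolerance = 1e-8)
  # fit_normalizer uses the population deviation; recompute the same moment
  expect_equal(sqrt(mean((vals - mean(vals))^2)), 1, tolerance = 1e-8)
  # constant rasters map to the expected [0, 1] points before standardization
  expect_equal(normalize_image(matrix(0, 2, 2)), matrix(0, 2, 2))
  expect_equal(normalize_image(matrix(255, 2, 2)), matrix(1, 2, 2))
})

test_that("4:1 split follows the floor convention, including the printed counts", {
  stubs <- lapply(seq_len(7036), function(i)
    view_group(paste0("g", i), paste0("p", (i - 1) %/% 37 + 1), i %% 2))
  sp <- split_train_test(stubs, split_config(seed = 7))
  expect_length(sp$train, 5628L)
  expect_length(sp$test, 1408L)
  expect_identical(3L * length(sp$train), 16884L)
  expect_identical(3L * length(sp$test), 4224L)
  # tiny case
  sp5 <- split_train_test(stubs[1:5], split_config(seed = 7))
  expect_length(sp5$train, 4L)
  expect_length(sp5$test, 1L)
  expect_error(split_train_test(list(), split_config()), "empty")
})

test_that("patient-level splits never separate a patient's groups", {
  set.seed(42)
  for (rep in 1:5) {
    stubs <- lapply(seq_len(120), function(i)
      view_group(paste0("g", i), paste0("p", sample(12, 1)), 0L))
    sp <- split_train_test(stubs, split_config(level = "patient", seed = rep))
    tr <- vapply(sp$train, function(g) g$patient_id, "")
    te <- vapply(sp$test, function(g) g$patient_id, "")
    expect_length(intersect(unique(tr), unique(te)), 0L)
    expect_identical(length(sp$train) + length(sp$test), 120L)
  }
})

test_that("k-fold assignments partition the data reproducibly", {
  stubs <- lapply(seq_len(10), function(i)
    view_group(paste0("g", i), paste0("p", i), 0L))
  f <- kfold(stubs, split_config(seed = 5))
  expect_identical(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 2L))
  expect_identical(f, kfold(stubs, split_config(seed = 5)))
  expect_false(identical(f, kfold(stubs, split_config(seed = 6))))
  # patient-level folds keep patients whole
  stubs2 <- lapply(seq_len(60), function(i)
    view_group(paste0("g", i), paste0("p", (i - 1) %/% 6), i %% 2))
  f2 <- kfold(stubs2, split_config(level = "patient", seed = 2))
  pid <- vapply(stubs2, function(g) g$patient_id, "")
  expect_true(all(tapply(f2, pid, function(v) length(unique(v))) == 1L))
  expect_error(kfold(stubs[1:3], split_config()), "fewer groups")
})
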