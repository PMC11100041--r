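# Architecture construction and exact parameter accounting.

test_that("CBA parameter counts follow the closed form and the enumeration oracle", {
  set.seed(21)
  # 1x1 conv, 1->1, no bias, trainable-only: 1 weight + 2 BN = 3
  cba <- build_cba(cba_spec(1, 1, 1, use_bias = FALSE))
  expect_identical(count_parameters(cba, "trainable_only")$total, 3L)
  # 3x3 conv, 1->8, no bias, total convention: 72 + 32 = 104
  cba8 <- build_cba(cba_spec(1, 8, 3, use_bias = FALSE))
  expect_identical(count_parameters(cba8, "total")$total, 104L)
  # arbitrary specs agree with brute-force element enumeration
  for (i in 1:5) {
    sp <- cba_spec(sample(1:6, 1), sample(1:12, 1), sample(c(1L, 3L, 7L), 1),
                   use_bias = sample(c(TRUE, FALSE), 1))
    m <- build_cba(sp)
    expect_identical(count_parameters(m, "total")$total,
                     as.integer(enumerate_params(m, TRUE)))
    expect_identical(count_parameters(m, "trainable_only")$total,
                     as.integer(enumerate_params(m, FALSE)))
  }
  expect_error(cba_spec(0, 4), "positive")
  expect_error(count_parameters(cba8, "bogus"))
})

test_that("residual units keep branch shapes aligned and count exactly", {
  set.seed(22)
  u <- build_residual_unit(residual_unit_spec(8, 8, shortcut_kernel = 1L,
                                              stride = 1L, shortcut_bn = TRUE))
  expect_identical(count_parameters(u, "total")$total,
                   as.integer(enumerate_params(u, TRUE)))
  # stride-2 unit: 56x56 input -> 28x28 on both branches
  u2 <- build_residual_unit(residual_unit_spec(3, 6, stride = 2L))
  x <- array(rnorm(56 * 56 * 3 * 2), c(56, 56, 3, 2))
  r <- resmini:::nn_forward(u2, x)
  expect_identical(dim(r$out), c(28L, 28L, 6L, 2L))
  # identity-friendly shape contract: output finite
  expect_true(all(is.finite(r$out)))
})

test_that("ResMini widths double per stage and the classifier has depth 10", {
  cfg <- backbone_config(base_filters = 5L)
  expect_identical(cfg$stage_widths, c(5L, 10L, 20L, 40L))
  set.seed(23)
  ext <- build_resmini_extractor(cfg)
  expect_identical(depth_count(ext), 9L)
  clf <- build_single_view_classifier(cfg)
  expect_identical(depth_count(clf), 10L)
  # 224x224 grayscale input -> 14x14 map with 8*base channels
  x <- array(rnorm(224 * 224), c(224, 224, 1, 1))
  r <- resmini:::nn_forward(ext, x)
  expect_identical(dim(r$out), c(14L, 14L, 40L, 1L))
  # shape safety at the smallest supported side
  x32 <- array(rnorm(32 * 32), c(32, 32, 1, 1))
  expect_identical(dim(resmini:::nn_forward(ext, x32)$out), c(2L, 2L, 40L, 1L))
})

test_that("literal stem padding is available behind the config flag", {
  set.seed(24)
  ext <- build_resmini_extractor(backbone_config(base_filters = 4L,
                                                 literal_stem_padding = TRUE))
  x <- array(rnorm(64 * 64), c(64, 64, 1, 1))
  r <- resmini:::nn_forward(ext, x)
  # stem inflates 64 -> 68, pool halves to 34, stages stride to 34/17/9/5
  expect_identical(dim(r$out)[1:2], c(5L, 5L))
})

test_that("ResNet-18 matches its canonical depth, feature map and parameter count", {
  set.seed(25)
  ext <- build_resnet18_extractor(3L)
  clf <- build_resnet18_classifier()
  expect_identical(depth_count(clf), 18L)
  # canonical trainable parameter count of the 3-channel, headless 18-layer
  # design (convolutions + BN scale/shift)
  expect_identical(count_parameters(ext, "trainable_only")$total, 11176512L)
  expect_identical(count_parameters(ext, "total")$total,
                   as.integer(enumerate_params(ext, TRUE)))
  x <- array(rnorm(224 * 224 * 3), c(224, 224, 3, 1))
  r <- resmini:::nn_forward(ext, x)
  expect_identical(dim(r$out), c(7L, 7L, 512L, 1L))
})

test_that("comparison extractors build, run on 224x224x1 input and enumerate", {
  set.seed(26)
  x <- array(rnorm(224 * 224), c(224, 224, 1, 1))
  for (name in c("lenet5", "squeezenet", "shufflenet_v1")) {
    m <- build_comparison_extractor(name)
    r <- resmini:::nn_forward(m, x)
    expect_gte(min(dim(r$out)[1:2]), 1L)
    expect_identical(count_parameters(m, "total")$total,
                     as.integer(enumerate_params(m, TRUE)))
  }
  expect_error(build_comparison_extractor("alexnet"))
})

test_that("calibration returns the frozen reference and handles edge budgets", {
  cal <- calibrate_reference_config()
  expect_identical(cal$deviation, 0L)
  expect_identical(cal$total, 236552L)
  ref <- reference_config()
  expect_identical(cal$config$base_filters, ref$base_filters)
  expect_identical(cal$config$shortcut_kernel, ref$shortcut_kernel)
  expect_identical(cal$config$use_bias, ref$use_bias)
  expect_identical(cal$config$shortcut_bn, ref$shortcut_bn)
  expect_identical(cal$head_width, reference_head_width())
  # fixed point: a budget equal to a known configuration's total returns it
  known <- resmini:::fusion_total_arithmetic(5L, 1L, TRUE, TRUE,
                                             "trainable_only", 0L)
  cal2 <- calibrate_reference_config(known)
  expect_identical(cal2$deviation, 0L)
  # unreachable tiny budget: nearest match with recorded nonzero deviation
  cal3 <- calibrate_reference_config(10L)
  expect_true(cal3$deviation != 0L)
  expect_error(calibrate_reference_config(budget = 236552L,
                                          base_filters = integer(0)),
               "empty")
})

test_that("backbone configurations round-trip through the flat key-value file", {
  cfg <- backbone_config(base_filters = 9L, use_bias = TRUE,
                         shortcut_kernel = 1L, shortcut_bn = TRUE)
  f <- tempfile(fileext = ".yaml")
  write_backbone_config(cfg, f)
  back <- read_backbone_config(f)
  expect_identical(back[c("base_filters", "use_bias", "shortcut_kernel",
                          "shortcut_bn", "stage_widths")],
                   cfg[c("base_filters", "use_bias", "shortcut_kernel",
                         "shortcut_bn", "stage_widths")])
  writeLines("frobnicate: 3", f)
  expect_error(read_backbone_config(f), "unknown key")
})

test_that("parameter accounting equals enumeration on the reference fusion model", {
  set.seed(27)
  fm <- build_fusion_model(fusion_config())
  expect_identical(count_parameters(fm, "total")$total,
                   as.integer(enumerate_params(fm, TRUE)))
  expect_identical(count_parameters(fm, "trainable_only")$total,
                   as.integer(enumerate_params(fm, FALSE)))
  rep <- count_parameters(fm)
  expect_identical(rep$total, sum(rep$layers$count))
  js <- param_report_json(fm)
  parsed <- jsonlite::fromJSON(js)
  expect_setequal(parsed$convention,
                  c("total_including_bn_statistics", "trainable_only"))
})
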