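# Architecture builders: the ResMini feature extractor, the fusion reference
# configuration calibrated against the 236,552-parameter budget, a canonical
# ResNet-18, and the lightweight comparison extractors.

#' Specification of a CBA block (convolution -> batch norm -> ReLU)
#'
#' @param in_channels,out_channels positive channel counts.
#' @param kernel odd square kernel edge, one of 1, 3, 7.
#' @param stride,padding convolution geometry.
#' @param use_bias whether the convolution carries an additive bias. A bias
#'   immediately followed by batch normalization is redundant (BN subtracts the
#'   channel mean), which is why the reference configuration disables it.
#' @return a validated `cba_spec` list.
#' @export
cba_spec <- function(in_channels, out_channels, kernel = 3L, stride = 1L,
                     padding = 0L, use_bias = FALSE) {
  if (in_channels < 1 || out_channels < 1)
    stop("cba_spec: channel counts must be positive")
  if (!kernel %in% c(1L, 3L, 7L)) stop("cba_spec: kernel must be one of 1, 3, 7")
  if (stride < 1 || padding < 0) stop("cba_spec: invalid stride/padding")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 padding = as.integer(padding), use_bias = isTRUE(use_bias)),
            class = "cba_spec")
}

#' Build a CBA block
#'
#' @param spec a [cba_spec()].
#' @param bn include batch normalization (and the fused ReLU). With
#'   `bn = FALSE` the block degenerates to a bare convolution, which is how the
#'   reference configuration realizes its linear projection shortcuts.
#' @return an internal network module.
#' @export
build_cba <- function(spec, bn = TRUE) {
  stopifnot(inherits(spec, "cba_spec"))
  conv <- nn_conv(spec$in_channels, spec$out_channels, spec$kernel,
                  spec$stride, spec$padding, spec$use_bias)
  if (bn) nn_seq(conv, nn_bnrelu(spec$out_channels)) else nn_seq(conv)
}

#' Specification of a ResMini residual unit
#'
#' The main branch is two CBA blocks; the shortcut branch is a single
#' projection (a full CBA when `shortcut_bn = TRUE`, a bare linear convolution
#' otherwise). Both branches apply the same spatial stride so their outputs
#' merge elementwise; no activation follows the merge.
#'
#' @param in_channels,out_channels channel counts.
#' @param main_kernel kernel of the two main-branch convolutions.
#' @param shortcut_kernel 1 or 3.
#' @param stride spatial reduction applied by the first main CBA and the
#'   shortcut.
#' @param use_bias convolution bias flag for every convolution in the unit.
#' @param shortcut_bn whether the shortcut is a full CBA block.
#' @export
residual_unit_spec <- function(in_channels, out_channels, main_kernel = 3L,
                               shortcut_kernel = 3L, stride = 1L,
                               use_bias = FALSE, shortcut_bn = FALSE) {
  if (!shortcut_kernel %in% c(1L, 3L))
    stop("residual_unit_spec: shortcut kernel must be 1 or 3")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 main_kernel = as.integer(main_kernel),
                 shortcut_kernel = as.integer(shortcut_kernel),
                 stride = as.integer(stride), use_bias = isTRUE(use_bias),
                 shortcut_bn = isTRUE(shortcut_bn)),
            class = "residual_unit_spec")
}

#' Build a residual unit from its specification
#' @param spec a [residual_unit_spec()].
#' @export
build_residual_unit <- function(spec) {
  stopifnot(inherits(spec, "residual_unit_spec"))
  pad <- function(k) (k - 1L) %/% 2L
  main <- nn_seq(c(
    build_cba(cba_spec(spec$in_channels, spec$out_channels, spec$main_kernel,
                       spec$stride, pad(spec$main_kernel), spec$use_bias))$modules,
    build_cba(cba_spec(spec$out_channels, spec$out_channels, spec$main_kernel,
                       1L, pad(spec$main_kernel), spec$use_bias))$modules))
  shortcut <- build_cba(cba_spec(spec$in_channels, spec$out_channels,
                                 spec$shortcut_kernel, spec$stride,
                                 pad(spec$shortcut_kernel), spec$use_bias),
                        bn = spec$shortcut_bn)
  nn_residual(main = main, shortcut = shortcut)
}

#' ResMini backbone configuration
#'
#' Four residual stages whose filter widths double stage to stage
#' (`base_filters * c(1, 2, 4, 8)`), preceded by a 3x3 CBA stem and a 3x3/2
#' max pool. The printed stem padding of 3 inflates a 3x3 convolution's output;
#' the default keeps the stated kernel and stride but uses the size-preserving
#' padding 1 (`literal_stem_padding = TRUE` restores the printed value).
#'
#' @param base_filters width of the first stage.
#' @param input_channels 1 for grayscale CT slices.
#' @param stage_strides spatial strides of the four residual units.
#' @param use_bias convolution bias flag.
#' @param shortcut_kernel 1 or 3.
#' @param shortcut_bn whether shortcuts are full CBA blocks (`FALSE` in the
#'   calibrated reference configuration: linear projection shortcuts).
#' @param literal_stem_padding use the printed stem padding of 3.
#' @return a `backbone_config` list.
#' @export
backbone_config <- function(base_filters = 7L, input_channels = 1L,
                            stage_strides = c(1L, 2L, 2L, 2L),
                            use_bias = FALSE, shortcut_kernel = 3L,
                            shortcut_bn = FALSE, literal_stem_padding = FALSE) {
  if (base_filters < 1) stop("backbone_config: base_filters must be positive")
  if (length(stage_strides) != 4) stop("backbone_config: exactly 4 stage strides")
  structure(list(base_filters = as.integer(base_filters),
                 input_channels = as.integer(input_channels),
                 n_stages = 4L,
                 stage_widths = as.integer(base_filters * c(1L, 2L, 4L, 8L)),
                 stem = cba_spec(input_channels, base_filters, 3L, 1L,
                                 if (literal_stem_padding) 3L else 1L, use_bias),
                 maxpool = list(kernel = 3L, stride = 2L, padding = 1L),
                 stage_strides = as.integer(stage_strides),
                 use_bias = isTRUE(use_bias),
                 shortcut_kernel = as.integer(shortcut_kernel),
                 shortcut_bn = isTRUE(shortcut_bn)),
            class = "backbone_config")
}

#' Build the ResMini feature extractor
#'
#' Stem CBA, max pool, then four sequential residual units; emits a feature
#' map of `8 * base_filters` channels. Nine weighted layers on the main path;
#' a dense classification head brings the classifier to depth 10.
#'
#' @param config a [backbone_config()].
#' @return an internal network module.
#' @export
build_resmini_extractor <- function(config = reference_config()) {
  stopifnot(inherits(config, "backbone_config"))
  ins <- c(config$base_filters, config$stage_widths[-4])
  units <- lapply(seq_len(4), function(i)
    build_residual_unit(residual_unit_spec(
      ins[i], config$stage_widths[i], 3L, config$shortcut_kernel,
      config$stage_strides[i], config$use_bias, config$shortcut_bn)))
  nn_seq(c(build_cba(config$stem)$modules,
           list(nn_maxpool(config$maxpool$kernel, config$maxpool$stride,
                           config$maxpool$padding)),
           units))
}

#' Single-view ResMini classifier (extractor + GAP + dense head), depth 10
#' @param config a [backbone_config()].
#' @param n_classes number of output classes.
#' @export
build_single_view_classifier <- function(config = reference_config(),
                                         n_classes = 2L) {
  nn_seq(c(build_resmini_extractor(config)$modules,
           list(nn_gap(), nn_dense(8L * config$base_filters, n_classes))))
}

#' Canonical 18-layer residual network feature extractor
#'
#' The standard basic-block design (widths 64/128/256/512, two blocks per
#' stage, 7x7/2 stem, projection shortcuts on the stride-2 stage entries) with
#' the classification layers removed; emits a 512-channel feature map (7x7 for
#' 224x224 input).
#'
#' @param input_channels 1 for grayscale; 3 replicates the RGB convention.
#' @export
build_resnet18_extractor <- function(input_channels = 1L) {
  basic <- function(ic, oc, stride) {
    main <- nn_seq(nn_conv(ic, oc, 3L, stride, 1L, FALSE), nn_bnrelu(oc),
                   nn_conv(oc, oc, 3L, 1L, 1L, FALSE), nn_bn(oc))
    sc <- if (stride != 1L || ic != oc)
      nn_seq(nn_conv(ic, oc, 1L, stride, 0L, FALSE), nn_bn(oc)) else NULL
    # canonical design applies ReLU after the merge
    nn_seq(nn_residual(main, sc), nn_relu())
  }
  widths <- c(64L, 128L, 256L, 512L)
  mods <- list(nn_conv(input_channels, 64L, 7L, 2L, 3L, FALSE), nn_bnrelu(64L),
               nn_maxpool(3L, 2L, 1L))
  ic <- 64L
  for (s in seq_len(4)) {
    st <- if (s == 1L) 1L else 2L
    mods <- c(mods, list(basic(ic, widths[s], st), basic(widths[s], widths[s], 1L)))
    ic <- widths[s]
  }
  nn_seq(mods)
}

#' ResNet-18 single-view classifier (depth 18)
#' @param input_channels input channel count.
#' @param n_classes number of output classes.
#' @export
build_resnet18_classifier <- function(input_channels = 1L, n_classes = 2L) {
  nn_seq(c(build_resnet18_extractor(input_channels)$modules,
           list(nn_gap(), nn_dense(512L, n_classes))))
}

#' Comparison feature extractors (classification layers removed)
#'
#' Adaptations of three lightweight designs to single-channel 224x224 input.
#' They build and plug into the fusion frame; their parameter totals are
#' reported but are not claimed to match any published adaptation.
#'
#' @param name one of `"lenet5"`, `"shufflenet_v1"`, `"squeezenet"`.
#' @param input_channels input channel count.
#' @export
build_comparison_extractor <- function(name, input_channels = 1L) {
  switch(match.arg(name, c("lenet5", "shufflenet_v1", "squeezenet")),
    lenet5 = nn_seq(
      nn_conv(input_channels, 6L, 5L, 1L, 2L, TRUE), nn_relu(),
      nn_maxpool(2L, 2L, 0L),
      nn_conv(6L, 16L, 5L, 1L, 0L, TRUE), nn_relu(),
      nn_maxpool(2L, 2L, 0L)),
    squeezenet = {
      fire <- function(ic, sq, e1, e3) nn_seq(
        nn_conv(ic, sq, 1L, 1L, 0L, TRUE), nn_relu(),
        nn_parallel(list(
          nn_seq(nn_conv(sq, e1, 1L, 1L, 0L, TRUE), nn_relu()),
          nn_seq(nn_conv(sq, e3, 3L, 1L, 1L, TRUE), nn_relu()))))
      nn_seq(
        nn_conv(input_channels, 96L, 7L, 2L, 3L, TRUE), nn_relu(),
        nn_maxpool(3L, 2L, 0L),
        fire(96L, 16L, 64L, 64L), fire(128L, 16L, 64L, 64L),
        fire(128L, 32L, 128L, 128L), nn_maxpool(3L, 2L, 0L),
        fire(256L, 32L, 128L, 128L), fire(256L, 48L, 192L, 192L),
        fire(384L, 48L, 192L, 192L), fire(384L, 64L, 256L, 256L),
        nn_maxpool(3L, 2L, 0L), fire(512L, 64L, 256L, 256L))
    },
    shufflenet_v1 = {
      gconv <- function(ic, oc, groups, stride = 1L, kernel = 1L) {
        if (groups == 1L)
          return(nn_seq(nn_conv(ic, oc, kernel, stride, (kernel - 1L) %/% 2L, FALSE)))
        igs <- ic %/% groups; ogs <- oc %/% groups
        nn_parallel(lapply(seq_len(groups), function(g)
          nn_seq(nn_slice((g - 1L) * igs + seq_len(igs)),
                 nn_conv(igs, ogs, kernel, stride, (kernel - 1L) %/% 2L, FALSE))))
      }
      shuffle <- function(ch, groups)
        nn_permute(as.vector(matrix(seq_len(ch), nrow = groups, byrow = TRUE)))
      # depthwise 3x3 = grouped conv with groups = channels
      dwconv <- function(ch, stride) gconv(ch, ch, ch, stride, 3L)
      unit <- function(ic, oc, groups, stride) {
        mid <- oc %/% 4L
        main_oc <- if (stride == 1L) oc else oc - ic # concat shortcut when striding
        main <- nn_seq(gconv(ic, mid, groups), nn_bnrelu(mid), shuffle(mid, groups),
                       dwconv(mid, stride), nn_bn(mid),
                       gconv(mid, main_oc, groups), nn_bn(main_oc))
        if (stride == 1L) nn_seq(nn_residual(main, NULL), nn_relu())
        else nn_seq(nn_parallel(list(nn_seq(nn_maxpool(3L, 2L, 1L)), main)), nn_relu())
      }
      g <- 3L; widths <- c(240L, 480L, 960L); reps <- c(3L, 7L, 3L)
      mods <- list(nn_conv(input_channels, 24L, 3L, 2L, 1L, FALSE), nn_bnrelu(24L),
                   nn_maxpool(3L, 2L, 1L))
      ic <- 24L
      for (s in seq_len(3)) {
        mods <- c(mods, list(unit(ic, widths[s], g, 2L)))
        for (r in seq_len(reps[s]))
          mods <- c(mods, list(unit(widths[s], widths[s], g, 1L)))
        ic <- widths[s]
      }
      nn_seq(mods)
    })
}

# ---------------------------------------------------------------------------
# parameter accounting

PARAM_CONVENTIONS <- c("total_including_bn_statistics", "trainable_only")

#' Exact parameter accounting for a built model
#'
#' Walks the module tree and counts every weight-array element. Under the
#' `total_including_bn_statistics` convention each batch-norm channel
#' contributes 4 values (scale, shift, running mean, running variance) — the
#' convention of Keras "Total params"; under `trainable_only` it contributes 2.
#'
#' @param model a built network module.
#' @param convention counting convention (see above); `"total"` is accepted as
#'   shorthand for the default.
#' @return a `param_report` with a per-layer table and exact integer total.
#' @export
count_parameters <- function(model, convention = "total_including_bn_statistics") {
  if (identical(convention, "total")) convention <- "total_including_bn_statistics"
  convention <- match.arg(convention, PARAM_CONVENTIONS)
  bn_fac <- if (convention == "trainable_only") 2L else 4L
  rows <- list()
  walk <- function(mod, path) {
    kind <- mod$kind
    add <- function(count) rows[[length(rows) + 1L]] <<-
      data.frame(layer = path, kind = kind, count = count)
    switch(kind,
      conv = add(length(mod$w) + length(mod$b)),
      dense = add(length(mod$w) + length(mod$b)),
      bn = add(bn_fac * length(mod$gamma)),
      bnrelu = add(bn_fac * length(mod$gamma)),
      seq = for (i in seq_along(mod$modules))
        walk(mod$modules[[i]], paste0(path, ".l", i)),
      residual = {
        walk(mod$main, paste0(path, ".main"))
        if (!is.null(mod$shortcut)) walk(mod$shortcut, paste0(path, ".shortcut"))
      },
      parallel = for (i in seq_along(mod$branches))
        walk(mod$branches[[i]], paste0(path, ".b", i)),
      multiview = {
        for (i in seq_along(mod$branches))
          walk(mod$branches[[i]], paste0(path, ".v", i))
        walk(mod$head, paste0(path, ".head"))
      },
      invisible(NULL))
  }
  walk(model, "model")
  layers <- do.call(rbind, rows)
  structure(list(layers = layers, total = sum(layers$count),
                 convention = convention),
            class = "param_report")
}

#' @export
print.param_report <- function(x, ...) {
  cat(sprintf("Parameter report (%s): %d layers, total %s parameters\n",
              x$convention, nrow(x$layers), format(x$total, big.mark = ",")))
  invisible(x)
}

#' Serialize a parameter report (or both conventions for a model) to JSON
#' @param model a built network module.
#' @param path output file; omit to get the JSON string.
#' @export
param_report_json <- function(model, path = NULL) {
  reps <- lapply(PARAM_CONVENTIONS, function(cv) {
    r <- count_parameters(model, cv)
    list(convention = cv, total = r$total, layers = r$layers)
  })
  js <- jsonlite::toJSON(reps, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Weighted main-path depth of a network
#'
#' Counts convolutions on the main path plus dense layers; shortcut
#' projections are excluded. The single-view ResMini classifier has depth 10
#' (stem + 4 x 2 main convolutions + dense), ResNet-18 has 18.
#'
#' @param model a built network module.
#' @return integer depth.
#' @export
depth_count <- function(model) {
  switch(model$kind,
    conv = 1L, dense = 1L,
    seq = sum(vapply(model$modules, depth_count, 0L)),
    residual = depth_count(model$main),
    parallel = max(vapply(model$branches, depth_count, 0L)),
    multiview = max(vapply(model$branches, depth_count, 0L)) +
      depth_count(model$head),
    0L)
}

# closed-form fusion total for the calibration search; equivalence with
# count_parameters() on built models is asserted in the tests
fusion_total_arithmetic <- function(base, shortcut_kernel, use_bias, shortcut_bn,
                                    convention, head_width, input_channels = 1L) {
  g <- if (convention == "trainable_only") 2L else 4L
  b <- as.integer(use_bias)
  cba <- function(k, i, o, bn = TRUE) k * k * i * o + b * o + if (bn) g * o else 0L
  w <- base * c(1L, 2L, 4L, 8L); ins <- c(base, base, 2L * base, 4L * base)
  extr <- cba(3L, input_channels, base)
  for (u in 1:4)
    extr <- extr + cba(3L, ins[u], w[u]) + cba(3L, w[u], w[u]) +
      cba(shortcut_kernel, ins[u], w[u], bn = shortcut_bn)
  feat <- 24L * base
  head <- if (head_width == 0L) feat * 2L + 2L
          else feat * head_width + head_width + head_width * 2L + 2L
  3L * extr + head
}

#' Calibrate the reference configuration against a parameter budget
#'
#' Exhaustively searches the architecture freedoms the description of the
#' network leaves open — base filter width, shortcut kernel, convolution bias,
#' whether the projection shortcut carries batch norm, the counting
#' convention, and an optional hidden width in the fusion head — for the
#' three-view fusion total that matches `budget` exactly. If no exact match
#' exists the nearest configuration is returned with its recorded deviation.
#'
#' @param budget target parameter count (default: the printed 236,552).
#' @param base_filters,shortcut_kernel,use_bias,shortcut_bn,head_width search
#'   ranges.
#' @param conventions counting conventions to search.
#' @return a list with `config` ([backbone_config()]), `head_width`,
#'   `convention`, `total` and `deviation` (`total - budget`).
#' @export
calibrate_reference_config <- function(budget = 236552L,
                                       base_filters = 4:32,
                                       shortcut_kernel = c(1L, 3L),
                                       use_bias = c(FALSE, TRUE),
                                       shortcut_bn = c(FALSE, TRUE),
                                       conventions = PARAM_CONVENTIONS,
                                       head_width = 0:64) {
  grid <- expand.grid(base = base_filters, sk = shortcut_kernel, ub = use_bias,
                      sbn = shortcut_bn, cv = conventions, h = head_width,
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0) stop("calibrate_reference_config: empty search space")
  totals <- mapply(fusion_total_arithmetic, grid$base, grid$sk, grid$ub,
                   grid$sbn, grid$cv, grid$h)
  i <- which.min(abs(totals - budget))
  best <- grid[i, ]
  list(config = backbone_config(base_filters = best$base, use_bias = best$ub,
                                shortcut_kernel = best$sk, shortcut_bn = best$sbn),
       head_width = as.integer(best$h), convention = best$cv,
       total = as.integer(totals[i]),
       deviation = as.integer(totals[i] - budget))
}

#' The frozen reference backbone configuration
#'
#' Calibrated once against the 236,552-parameter three-view fusion budget:
#' base width 7, 3x3 linear (BN-free) projection shortcuts, no convolution
#' bias, fusion head hidden width 44, counted under the
#' `total_including_bn_statistics` convention.
#' [calibrate_reference_config()] reproduces it.
#'
#' @export
reference_config <- function() {
  backbone_config(base_filters = 7L, use_bias = FALSE,
                  shortcut_kernel = 3L, shortcut_bn = FALSE)
}

#' Hidden width of the reference fusion head
#' @export
reference_head_width <- function() 44L

#' Read / write a backbone configuration as a flat key-value (YAML) file
#'
#' Keys mirror the [backbone_config()] arguments (`base_filters`,
#' `input_channels`, `stage_strides`, `use_bias`, `shortcut_kernel`,
#' `shortcut_bn`, `literal_stem_padding`); unknown keys are rejected.
#'
#' @param path file to read or write.
#' @param config a `backbone_config` (for writing).
#' @return the `backbone_config` (reading) or `path`, invisibly (writing).
#' @export
read_backbone_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- c("base_filters", "input_channels", "stage_strides", "use_bias",
               "shortcut_kernel", "shortcut_bn", "literal_stem_padding")
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown))
    stop("read_backbone_config: unknown key(s): ", paste(unknown, collapse = ", "))
  do.call(backbone_config, vals)
}

#' @rdname read_backbone_config
#' @export
write_backbone_config <- function(config, path) {
  stopifnot(inherits(config, "backbone_config"))
  yaml::write_yaml(list(
    base_filters = config$base_filters, input_channels = config$input_channels,
    stage_strides = config$stage_strides, use_bias = config$use_bias,
    shortcut_kernel = config$shortcut_kernel, shortcut_bn = config$shortcut_bn,
    literal_stem_padding = config$stem$padding == 3L), path)
  invisible(path)
}
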