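#' Configure a 3D segmentation network
#'
#' Describes one of the three full field-of-view volumetric architectures:
#' a classic 3D U-Net (`unet3d`), an attention-based competitive dense
#' variant (`acd_unet3d`) in which the feature maps inside each block
#' compete through an element-wise maximum and the bottleneck carries a
#' channel-then-spatial attention gate, and an nnU-Net-like fixed
#' configuration (`nnunet_like`) with instance normalization, leaky ReLU
#' (slope 0.01), strided-convolution downsampling and widths starting at 32
#' that double per stage up to a cap of 320.
#'
#' @param arch One of `"unet3d"`, `"acd_unet3d"`, `"nnunet_like"`.
#' @param in_channels Number of input image contrasts (default 3:
#'   opposed-phase, water, fat).
#' @param n_classes Number of output classes (3: background, SAT, VAT).
#' @param encoder_filters Encoder widths for `unet3d`/`acd_unet3d`
#'   (default `c(64, 128, 256, 512)`); must be strictly increasing.
#' @param convs_per_block Number of 3x3x3 convolutions per resolution level
#'   (fixed default 2).
#' @param normalization `"batch"` or `"instance"`; defaults to batch for the
#'   U-Net variants and instance for `nnunet_like`.
#' @param nonlinearity `"relu"` or `"leaky_relu"`.
#' @param attention_bottleneck Add the attention gate at the bottleneck
#'   (default `TRUE` for `acd_unet3d`, `FALSE` otherwise).
#' @param attention_reduction Channel reduction ratio of the attention MLP.
#' @param initial_filters,filter_cap,n_stages `nnunet_like` width schedule.
#' @param seed Integer seed for random weight initialization.
#' @return A `network_config` list.
#' @export
network_config <- function(arch = c("unet3d", "acd_unet3d", "nnunet_like"),
                           in_channels = 3L,
                           n_classes = 3L,
                           encoder_filters = c(64L, 128L, 256L, 512L),
                           convs_per_block = 2L,
                           normalization = NULL,
                           nonlinearity = NULL,
                           attention_bottleneck = NULL,
                           attention_reduction = 8L,
                           initial_filters = 32L,
                           filter_cap = 320L,
                           n_stages = 6L,
                           seed = 1L) {
  arch <- match.arg(arch)
  if (arch == "nnunet_like") {
    encoder_filters <- pmin(initial_filters * 2L^(seq_len(n_stages) - 1L), filter_cap)
    normalization <- normalization %||% "instance"
    nonlinearity <- nonlinearity %||% "leaky_relu"
    downsample <- "strided_conv"
  } else {
    if (any(diff(encoder_filters) <= 0)) {
      stop("encoder_filters must strictly increase down the encoder")
    }
    normalization <- normalization %||% "batch"
    nonlinearity <- nonlinearity %||% "relu"
    downsample <- "maxpool"
  }
  if (length(encoder_filters) < 2L) stop("need at least two resolution levels")
  if (convs_per_block != 2L) stop("convs_per_block is fixed at 2 in this release")
  attention_bottleneck <- attention_bottleneck %||% (arch == "acd_unet3d")
  structure(list(
    arch = arch,
    in_channels = as.integer(in_channels),
    n_classes = as.integer(n_classes),
    encoder_filters = as.integer(encoder_filters),
    convs_per_block = 2L,
    normalization = match.arg(normalization, c("batch", "instance")),
    nonlinearity = match.arg(nonlinearity, c("relu", "leaky_relu")),
    downsample = downsample,
    attention_bottleneck = isTRUE(attention_bottleneck),
    attention_reduction = as.integer(attention_reduction),
    filter_cap = as.integer(filter_cap),
    default_norm = if (arch == "nnunet_like") "zscore" else "rescale_0_255",
    seed = as.integer(seed)
  ), class = "network_config")
}

# Parameter layout: named list of array dims, walked identically by the
# initializer, the counter and the forward pass.
net_layout <- function(config) {
  w <- config$encoder_filters
  L <- length(w)
  ci <- config$in_channels
  out <- list()
  add_conv <- function(name, cin, cout) {
    out[[paste0(name, ".W")]] <<- c(3L, 3L, 3L, cin, cout)
    out[[paste0(name, ".b")]] <<- cout
  }
  add_norm <- function(name, c) {
    out[[paste0(name, ".g")]] <<- c
    out[[paste0(name, ".b")]] <<- c
  }
  add_block <- function(prefix, cin, c) {
    add_conv(paste0(prefix, ".c1"), cin, c)
    add_norm(paste0(prefix, ".n1"), c)
    add_conv(paste0(prefix, ".c2"), c, c)
    add_norm(paste0(prefix, ".n2"), c)
  }
  for (i in seq_len(L)) {
    add_block(paste0("enc", i), if (i == 1L) ci else w[i - 1L], w[i])
  }
  if (config$attention_bottleneck) {
    cr <- max(1L, w[L] %/% config$attention_reduction)
    out[["att.ch1.W"]] <- c(cr, w[L])
    out[["att.ch1.b"]] <- cr
    out[["att.ch2.W"]] <- c(w[L], cr)
    out[["att.ch2.b"]] <- w[L]
    out[["att.sp.W"]] <- c(3L, 3L, 3L, 2L, 1L)
    out[["att.sp.b"]] <- 1L
  }
  for (i in seq.int(L - 1L, 1L)) {
    out[[paste0("dec", i, ".up.W")]] <- c(2L, 2L, 2L, w[i + 1L], w[i])
    out[[paste0("dec", i, ".up.b")]] <- w[i]
    add_block(paste0("dec", i), 2L * w[i], w[i])
  }
  out[["head.W"]] <- c(w[1L], config$n_classes)
  out[["head.b"]] <- config$n_classes
  out
}

#' Build a 3D segmentation network
#'
#' Allocates and randomly initializes (He scheme, seeded from the config)
#' all learnable parameters of the configured architecture.
#'
#' @param config A [network_config()].
#' @return A `seg3d_net` model handle holding the config, the parameter
#'   list and the normalization state.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  layout <- net_layout(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)
  params <- vector("list", length(layout))
  names(params) <- names(layout)
  for (nm in names(layout)) {
    d <- layout[[nm]]
    if (endsWith(nm, ".W") && length(d) == 5L) {
      fan_in <- prod(d[1:4])
      params[[nm]] <- array(stats::rnorm(prod(d), sd = sqrt(2 / fan_in)), d)
    } else if (endsWith(nm, ".W")) {
      fan_in <- d[length(d)]
      params[[nm]] <- matrix(stats::rnorm(prod(d), sd = sqrt(2 / fan_in)), d[1], d[2])
    } else if (endsWith(nm, ".g")) {
      params[[nm]] <- rep(1, d)
    } else {
      params[[nm]] <- rep(0, d)
    }
  }
  state <- new.env(parent = emptyenv())
  state$running_mean <- list()
  state$running_var <- list()
  structure(list(config = config, params = params, state = state),
            class = "seg3d_net")
}

#' Count trainable parameters
#'
#' Exact count of learnable scalars: convolution weights and biases plus
#' normalization scale/shift parameters. Running normalization statistics
#' are not trainable and are not counted.
#'
#' @param model A `seg3d_net` (or a `network_config`, in which case the
#'   count is taken from the parameter layout without allocating weights).
#' @return Integer-valued count.
#' @export
count_trainable_parameters <- function(model) {
  if (inherits(model, "network_config")) {
    return(sum(vapply(net_layout(model), prod, 0)))
  }
  stopifnot(inherits(model, "seg3d_net"))
  sum(vapply(model$params, length, 0))
}

# Per-axis pooling factors between resolution levels. In-plane is always
# halved; the slice axis is halved only while it still has >= 8 slices
# (anisotropy-aware, since abdominal stacks are much coarser in z).
net_pool_factors <- function(config, dims3) {
  L <- length(config$encoder_filters)
  fs <- vector("list", L - 1L)
  z <- dims3[3]
  for (i in seq_len(L - 1L)) {
    if (config$arch == "nnunet_like") {
      fz <- if (z >= 8L) 2L else 1L
    } else {
      fz <- 2L
    }
    fs[[i]] <- c(2L, 2L, fz)
    z <- ceiling(z / fz)
  }
  fs
}

net_block <- function(tape, x, model, prefix, training, stride = c(1L, 1L, 1L)) {
  cfg <- model$config
  h1 <- op_conv3(tape, x, model$params, paste0(prefix, ".c1"), stride)
  h1 <- op_norm(tape, h1, model$params, paste0(prefix, ".n1"),
                cfg$normalization, model$state, training)
  h1 <- op_act(tape, h1, cfg$nonlinearity)
  h2 <- op_conv3(tape, h1, model$params, paste0(prefix, ".c2"))
  h2 <- op_norm(tape, h2, model$params, paste0(prefix, ".n2"),
                cfg$normalization, model$state, training)
  h2 <- op_act(tape, h2, cfg$nonlinearity)
  if (cfg$arch == "acd_unet3d") op_maxout(tape, h1, h2) else h2
}

# Full forward pass to class logits. `x` is an (X, Y, Z, C) array.
net_forward <- function(model, x, tape = NULL, training = FALSE) {
  cfg <- model$config
  dims <- dim(x)
  if (length(dims) != 4L || dims[4] != cfg$in_channels) {
    stop(sprintf("input has %s channels but the network was configured for %d",
                 if (length(dims) == 4L) dims[4] else "?", cfg$in_channels))
  }
  L <- length(cfg$encoder_filters)
  fs <- net_pool_factors(cfg, dims[1:3])
  req <- Reduce(`*`, fs, accumulate = FALSE)
  target <- as.integer(ceiling(dims[1:3] / req) * req)
  lo <- (target - dims[1:3]) %/% 2L
  hi <- target - dims[1:3] - lo
  if (any(target %/% req < 2L)) {
    stop("input too small: bottleneck would have a spatial extent < 2 voxels")
  }
  xt <- op_input(tape, x)
  xt <- op_zeropad(tape, xt, lo, hi)
  skips <- vector("list", L - 1L)
  strided <- cfg$downsample == "strided_conv"
  for (i in seq_len(L)) {
    st <- if (strided && i > 1L) fs[[i - 1L]] else c(1L, 1L, 1L)
    if (!strided && i > 1L) xt <- op_maxpool(tape, xt, fs[[i - 1L]])
    xt <- net_block(tape, xt, model, paste0("enc", i), training, stride = st)
    if (i < L) skips[[i]] <- xt
  }
  if (cfg$attention_bottleneck) xt <- op_attention(tape, xt, model$params, "att")
  for (i in seq.int(L - 1L, 1L)) {
    xt <- op_tconv(tape, xt, model$params, paste0("dec", i, ".up"), fs[[i]])
    xt <- op_concat(tape, xt, skips[[i]])
    xt <- net_block(tape, xt, model, paste0("dec", i), training)
  }
  xt <- op_conv1(tape, xt, model$params, "head")
  op_crop(tape, xt, lo, dims[1:3])
}

# Numerically stable per-voxel softmax over the class axis (4th).
softmax4 <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, prod(d[1:3]), d[4])
  mx <- m[, 1L]
  for (j in seq_len(d[4])[-1L]) mx <- pmax(mx, m[, j])
  m <- m - mx
  e <- exp(m)
  p <- e / rowSums(e)
  dim(p) <- d
  p
}

# Probability map for one multi-channel array (inference mode).
net_predict_probs <- function(model, x) {
  softmax4(net_forward(model, x, tape = NULL, training = FALSE)$v)
}

#' Predict a 3-label segmentation mask
#'
#' Runs one full field-of-view forward pass (no patching or tiling) and
#' takes the per-voxel argmax over the three class probabilities.
#'
#' @param model A trained (or freshly built) `seg3d_net`.
#' @param vol A [multi_contrast_volume()] whose channel count matches the
#'   network configuration.
#' @param normalization Input normalization mode, `"rescale_0_255"` or
#'   `"zscore"`; defaults to the architecture's convention.
#' @return A [seg_mask()] on the same grid.
#' @export
predict_mask <- function(model, vol, normalization = NULL) {
  stopifnot(inherits(model, "seg3d_net"), inherits(vol, "mc_volume"))
  normalization <- normalization %||% model$config$default_norm
  if (length(vol$channels) != model$config$in_channels) {
    stop(sprintf("volume has %d channels but the network expects %d",
                 length(vol$channels), model$config$in_channels))
  }
  vn <- normalize_volume(vol, normalization)
  x <- array(unlist(vn$channels, use.names = FALSE),
             c(dim(vn$channels[[1]]), length(vn$channels)))
  probs <- net_predict_probs(model, x)
  lab <- apply_argmax_labels(probs)
  seg_mask(lab, voxel_size_mm = vol$voxel_size_mm, affine = vol$affine,
           subject_id = vol$subject_id, timepoint = vol$timepoint)
}

# argmax over the class axis, returned as labels 0..(K-1)
apply_argmax_labels <- function(probs) {
  d <- dim(probs)
  m <- matrix(probs, prod(d[1:3]), d[4])
  lab <- max.col(m, ties.method = "first") - 1L
  array(as.integer(lab), d[1:3])
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the full `network_config`, all parameters and the
#' running normalization statistics.
#' @param model A `seg3d_net`.
#' @param path File path for the checkpoint (RDS).
#' @export
save_model <- function(model, path) {
  obj <- list(config = model$config, params = model$params,
              running_mean = model$state$running_mean,
              running_var = model$state$running_var)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  state <- new.env(parent = emptyenv())
  state$running_mean <- obj$running_mean
  state$running_var <- obj$running_var
  structure(list(config = obj$config, params = obj$params, state = state),
            class = "seg3d_net")
}

#' @export
print.seg3d_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<seg3d_net> %s | in=%d classes=%d | filters: %s | norm=%s act=%s%s\n",
              cfg$arch, cfg$in_channels, cfg$n_classes,
              paste(cfg$encoder_filters, collapse = "/"),
              cfg$normalization, cfg$nonlinearity,
              if (cfg$attention_bottleneck) " | bottleneck attention" else ""))
  cat(sprintf("  trainable parameters: %s (%.3f M)\n",
              format(count_trainable_parameters(x), big.mark = ","),
              count_trainable_parameters(x) / 1e6))
  invisible(x)
}

#' Describe a network layer by layer
#'
#' Tabulates every parameter group of the configured architecture with its
#' shape and scalar count, plus the total.
#'
#' @param config A [network_config()].
#' @return Invisibly, a `data.frame` (printed) with columns `parameter`,
#'   `shape`, `count`.
#' @export
describe_network <- function(config) {
  layout <- net_layout(config)
  df <- data.frame(
    parameter = names(layout),
    shape = vapply(layout, function(d) paste(d, collapse = "x"), ""),
    count = vapply(layout, prod, 0),
    row.names = NULL)
  print(df, row.names = FALSE)
  cat(sprintf("total trainable parameters: %s (%.3f M)\n",
              format(sum(df$count), big.mark = ","), sum(df$count) / 1e6))
  invisible(df)
}
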