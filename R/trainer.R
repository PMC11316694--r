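# Cohort splitting, input normalization, the CPU training loop, and
# full-FOV inference orchestration.

#' Configure a training run
#'
#' @param loss A [loss_config()].
#' @param optimizer `"adam"` or `"sgd_nesterov"`. Conventions follow the
#'   emulated protocol: Adam for the U-Net variants, Nesterov momentum
#'   0.99 with initial learning rate 0.01 for the nnU-Net-like arm.
#' @param lr Learning rate (Adam default 1e-4; 1e-2 for Nesterov).
#' @param momentum Nesterov momentum.
#' @param epochs Number of epochs.
#' @param batch_size Volumes per optimizer step (gradient accumulation;
#'   normalization statistics are per-volume).
#' @param normalization `"rescale_0_255"` or `"zscore"`; `NULL` uses the
#'   architecture's convention. No data augmentation is ever applied.
#' @param seed Seed for shuffling (and any stochastic component).
#' @return A `train_config`.
#' @export
train_config <- function(loss = loss_config("WDL"),
                         optimizer = c("adam", "sgd_nesterov"),
                         lr = NULL, momentum = 0.99,
                         epochs = 10L, batch_size = 1L,
                         normalization = NULL, seed = 1L) {
  optimizer <- match.arg(optimizer)
  lr <- lr %||% if (optimizer == "adam") 1e-4 else 1e-2
  structure(list(loss = loss, optimizer = optimizer, lr = lr,
                 momentum = momentum, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 normalization = normalization, augmentation = "none",
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Normalize a volume for network input
#'
#' `rescale_0_255` maps each channel linearly so its minimum is 0 and its
#' maximum 255 (per-channel, so water and fat each occupy the full dynamic
#' range); `zscore` subtracts each channel's mean and divides by its
#' standard deviation. A constant channel maps to all zeros in either mode
#' (documented behaviour, not an error).
#'
#' @param vol A [multi_contrast_volume()] or plain numeric array.
#' @param mode `"rescale_0_255"` or `"zscore"`.
#' @return Same type as the input.
#' @export
normalize_volume <- function(vol, mode = c("rescale_0_255", "zscore")) {
  mode <- match.arg(mode)
  norm1 <- function(x) {
    if (mode == "rescale_0_255") {
      rng <- range(x)
      if (rng[2] == rng[1]) return(array(0, dim(x)))
      (x - rng[1]) / (rng[2] - rng[1]) * 255
    } else {
      s <- stats::sd(x)
      if (s == 0) return(array(0, dim(x)))
      (x - mean(x)) / s
    }
  }
  if (inherits(vol, "mc_volume")) {
    vol$channels <- lapply(vol$channels, norm1)
    # normalized intensities may be negative; bypass the magnitude check
    return(vol)
  }
  norm1(vol)
}

#' Stratified cohort splitting
#'
#' Assigns each subject to train/val/test with the requested fractions
#' (largest-remainder rounding of the subject counts), stratified by joint
#' quantile bins of the covariates; both time points of a subject inherit
#' its split. The balance report carries per-split covariate means and
#' Kruskal-Wallis p-values; if any covariate differs across splits at
#' p <= 0.05 the assignment is regenerated with a new sub-seed (bounded
#' retries).
#'
#' @param manifest Cohort manifest (one or two rows per subject).
#' @param fractions Named fractions summing to 1 (default 0.70/0.10/0.20).
#' @param covariates Manifest columns used for stratification and balance
#'   checking.
#' @param seed Integer seed.
#' @param max_retries Balance retries (default 20).
#' @return The manifest with a `split` column; the balance report is
#'   attached as attribute `"balance"`.
#' @export
split_cohort <- function(manifest, fractions = c(train = 0.7, val = 0.1, test = 0.2),
                         covariates = c("adiposity_score", "age_like"),
                         seed = 1L, max_retries = 20L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  subs <- manifest[!duplicated(manifest$subject_id), , drop = FALSE]
  n <- nrow(subs)
  if (n < 10L) stop("need at least 10 subjects to split")
  # largest-remainder target sizes
  raw <- fractions * n
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    o <- order(raw - sizes, decreasing = TRUE)
    sizes[o[seq_len(rem)]] <- sizes[o[seq_len(rem)]] + 1
  }
  covariates <- covariates[covariates %in% names(subs)]
  bins <- tryCatch({
    bl <- lapply(covariates, function(cv) {
      qs <- unique(stats::quantile(subs[[cv]], c(1, 2) / 3, type = 7))
      findInterval(subs[[cv]], qs)
    })
    interaction(as.data.frame(bl), drop = TRUE)
  }, error = function(e) NULL)
  if (is.null(bins) || min(table(bins)) < 1L) {
    warning("too few subjects per stratification bin; using a simple random split")
    bins <- factor(rep(1, n))
  }
  # systematic interleaving: lay the split labels out at evenly spread
  # fractional positions, then walk the subjects in covariate-bin order
  # (random within bins) so every bin receives near-proportional shares
  pos <- unlist(mapply(function(nm, k) if (k > 0) (seq_len(k) - 0.5) / k else numeric(0),
                       names(fractions), sizes, SIMPLIFY = FALSE))
  lab_seq <- rep(names(fractions), sizes)[order(pos)]
  assign_once <- function(s) {
    with_seed(s, {
      ord <- order(bins, stats::runif(n))     # group by bin, shuffle within
      out <- character(n)
      out[ord] <- lab_seq
      out
    })
  }
  attempt <- 0L
  repeat {
    sp <- assign_once(derive_seed(seed, attempt))
    pvals <- vapply(covariates, function(cv) {
      kruskal_wallis(split(subs[[cv]], sp))$p
    }, 0)
    if (all(pvals > 0.05) || attempt >= max_retries) break
    attempt <- attempt + 1L
  }
  manifest$split <- sp[match(manifest$subject_id, subs$subject_id)]
  report <- list(
    sizes = table(factor(sp, levels = names(fractions))),
    covariate_means = sapply(covariates, function(cv) {
      tapply(subs[[cv]], sp, mean)
    }),
    kruskal_wallis_p = pvals, retries = attempt)
  attr(manifest, "balance") <- report
  validate_manifest(manifest)
}

# ---- optimizers -----------------------------------------------------------

optimizer_new <- function(cfg, params) {
  st <- list(t = 0L)
  if (cfg$optimizer == "adam") {
    st$m <- lapply(params, function(p) p * 0)
    st$v <- st$m
  } else {
    st$u <- lapply(params, function(p) p * 0)
  }
  st
}

optimizer_step <- function(cfg, params, grads, st) {
  st$t <- st$t + 1L
  if (cfg$optimizer == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    for (nm in names(grads)) {
      g <- grads[[nm]]
      st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
      st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
      mh <- st$m[[nm]] / (1 - b1^st$t)
      vh <- st$v[[nm]] / (1 - b2^st$t)
      params[[nm]] <- params[[nm]] - cfg$lr * mh / (sqrt(vh) + eps)
    }
  } else {
    mu <- cfg$momentum
    for (nm in names(grads)) {
      g <- grads[[nm]]
      st$u[[nm]] <- mu * st$u[[nm]] - cfg$lr * g
      params[[nm]] <- params[[nm]] + mu * st$u[[nm]] - cfg$lr * g
    }
  }
  list(params = params, st = st)
}

# ---- training -------------------------------------------------------------

sample_to_input <- function(sample, mode, in_channels) {
  vn <- normalize_volume(sample$volume, mode)
  ch <- vn$channels[seq_len(in_channels)]
  array(unlist(ch, use.names = FALSE), c(dim(ch[[1]]), length(ch)))
}

dataset_class_freqs <- function(samples) {
  tot <- c(0, 0, 0)
  for (s in samples) tot <- tot + tabulate(s$mask$labels + 1L, 3L)
  tot / sum(tot)
}

#' Train a segmentation network
#'
#' Epoch loop with per-batch gradient reset, per-epoch validation-loss
#' tracking and best-on-validation checkpointing. The data pipeline applies
#' no stochastic transform (no augmentation); with a fixed seed the run is
#' reproducible on one device. A non-finite loss aborts with the offending
#' epoch reported.
#'
#' @param model A `seg3d_net` from [build_network()].
#' @param train_data,val_data Lists of samples, each
#'   `list(volume = mc_volume, mask = seg_mask)`.
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return List: `model` (weights from the epoch of minimum validation
#'   loss), `history` (data.frame epoch/train_loss/val_loss),
#'   `best_epoch`, and the resolved loss constants.
#' @export
train_network <- function(model, train_data, val_data, config = train_config(),
                          verbose = FALSE) {
  stopifnot(inherits(model, "seg3d_net"), length(train_data) >= 1,
            length(val_data) >= 1)
  cfg <- model$config
  mode <- config$normalization %||% cfg$default_norm
  dsf <- if (config$loss$type == "FBDL" &&
             config$loss$class_weight_mode == "inverse_frequency_dataset") {
    dataset_class_freqs(train_data)
  } else NULL
  xs <- lapply(train_data, sample_to_input, mode = mode, in_channels = cfg$in_channels)
  ys <- lapply(train_data, function(s) s$mask$labels)
  vx <- lapply(val_data, sample_to_input, mode = mode, in_channels = cfg$in_channels)
  vy <- lapply(val_data, function(s) s$mask$labels)
  opt <- optimizer_new(config, model$params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(val = Inf, params = model$params,
               rm = model$state$running_mean, rv = model$state$running_var,
               epoch = 0L)
  n <- length(xs)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      acc <- NULL; acc_k <- 0L
      for (ii in seq_along(ord)) {
        i <- ord[ii]
        tape <- tp_new()
        logits <- net_forward(model, xs[[i]], tape = tape, training = TRUE)
        P <- softmax4(logits$v)
        le <- loss_eval(P, ys[[i]], config$loss, dataset_freqs = dsf, grad = TRUE)
        if (!is.finite(le$loss)) {
          stop(sprintf("non-finite training loss at epoch %d (sample %d)", ep, i))
        }
        ep_loss <- ep_loss + le$loss
        dlog <- dlogits_from_dprobs(P, le$dprobs)
        wg <- tp_backward(tape, logits, dlog)
        if (is.null(acc)) acc <- wg
        else for (nm in names(wg)) acc[[nm]] <- acc[[nm]] + wg[[nm]]
        acc_k <- acc_k + 1L
        if (acc_k == config$batch_size || ii == n) {
          for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / acc_k
          stepped <- optimizer_step(config, model$params, acc, opt)
          model$params <- stepped$params
          opt <- stepped$st
          acc <- NULL; acc_k <- 0L       # gradients zeroed before each batch
        }
      }
      vloss <- mean(vapply(seq_along(vx), function(j) {
        Pv <- net_predict_probs(model, vx[[j]])
        loss_eval(Pv, vy[[j]], config$loss, dataset_freqs = dsf)$loss
      }, 0))
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = ep_loss / n, val_loss = vloss))
      if (vloss < best$val) {
        best <- list(val = vloss, params = model$params,
                     rm = model$state$running_mean, rv = model$state$running_var,
                     epoch = ep)
      }
      if (verbose) {
        message(sprintf("epoch %3d | train %.4f | val %.4f", ep, ep_loss / n, vloss))
      }
    }
  })
  model$params <- best$params
  model$state$running_mean <- best$rm
  model$state$running_var <- best$rv
  list(model = model, history = history, best_epoch = best$epoch,
       loss_constants = list(type = config$loss$type,
                             beta = config$loss$boundary_multiplier,
                             band = config$loss$boundary_band_voxels,
                             eps = config$loss$smoothing,
                             dataset_freqs = dsf))
}

#' Evaluate a model over a cohort
#'
#' Per-subject prediction and metric computation at one time point. Any
#' overlap between the evaluation subjects and the training subjects is a
#' hard error (split leakage); evaluation performs no weight update, so a
#' time point 2 cohort is scored by the time point 1 model as-is.
#'
#' @param model A trained `seg3d_net` (ignored when `predict_fn` is given).
#' @param test_data List of samples `list(volume, mask)`.
#' @param train_ids Character vector of training subject ids for the
#'   leakage guard.
#' @param predict_fn Optional override: function(volume) -> `seg_mask`
#'   (used e.g. for oracle pass-through checks).
#' @param normalization Input normalization override.
#' @return Data frame with one row per subject: `subject_id`, `timepoint`,
#'   `dice_sat`, `dice_vat`, `fp_pct`, `fn_pct`, reference and predicted
#'   SAT/VAT volumes (mL).
#' @export
evaluate_cohort <- function(model, test_data, train_ids = NULL,
                            predict_fn = NULL, normalization = NULL) {
  ids <- vapply(test_data, function(s) s$volume$subject_id, "")
  leak <- intersect(ids, train_ids %||% character(0))
  if (length(leak)) {
    stop("split leakage: evaluation subjects found in the training set: ",
         paste(unique(leak), collapse = ", "))
  }
  rows <- lapply(test_data, function(s) {
    pred <- if (is.null(predict_fn)) {
      predict_mask(model, s$volume, normalization = normalization)
    } else {
      predict_fn(s$volume)
    }
    r <- fp_fn_rates(pred, s$mask)
    data.frame(
      subject_id = s$volume$subject_id, timepoint = s$volume$timepoint,
      dice_sat = dice3d(pred, s$mask, 1L), dice_vat = dice3d(pred, s$mask, 2L),
      fp_pct = unname(r["fp_pct"]), fn_pct = unname(r["fn_pct"]),
      ref_sat_mL = mask_volume(s$mask, 1L), ref_vat_mL = mask_volume(s$mask, 2L),
      pred_sat_mL = mask_volume(pred, 1L), pred_vat_mL = mask_volume(pred, 2L),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
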