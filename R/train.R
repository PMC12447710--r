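#' Training configuration
#'
#' Defaults are the pipeline's reference protocol: 500 epochs of AdamW
#' (learning rate 1e-3, weight decay 1e-5) with poly learning-rate decay
#' (gamma 0.9), 96-voxel cubic training patches, CT windowing to
#' [-250, 550] HU, resampling to 1.5 mm isotropic, and the full
#' augmentation family. \code{iterations_per_epoch = NULL} means one
#' iteration per labeled training case. Desk-scale work shrinks
#' \code{epochs}, \code{patch_size} and \code{target_spacing} rather than
#' touching the optimiser.
#'
#' @param epochs Training epochs.
#' @param iterations_per_epoch Batches per epoch (NULL: number of labeled
#'   training cases).
#' @param batch_size Patches per optimisation step.
#' @param lr,weight_decay,poly_gamma AdamW and schedule hyperparameters.
#' @param patch_size Training patch edge (voxels); must be divisible by the
#'   backbone's cumulative downsampling.
#' @param window HU window for CT-like modalities.
#' @param target_spacing Working voxel spacing (mm).
#' @param crop_margin_mm Heart-crop margin (negative disables cropping).
#' @param augment_flip,augment_rot90,augment_rot_small,augment_intensity
#'   Augmentation toggles.
#' @param overlap Sliding-window overlap fraction for full-volume inference.
#' @param distill_temperature Self-distillation softening temperature.
#' @param seed Master seed for the whole run.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(epochs = 500L, iterations_per_epoch = NULL,
                         batch_size = 2L, lr = 1e-3, weight_decay = 1e-5,
                         poly_gamma = 0.9, patch_size = 96L,
                         window = c(-250, 550), target_spacing = c(1.5, 1.5, 1.5),
                         crop_margin_mm = 10, augment_flip = TRUE,
                         augment_rot90 = TRUE, augment_rot_small = TRUE,
                         augment_intensity = TRUE, overlap = 0.9,
                         distill_temperature = 3, seed = 1L) {
  stopifnot(epochs >= 1L, lr > 0, weight_decay > 0, batch_size >= 1L,
            overlap >= 0, overlap < 1)
  structure(list(epochs = as.integer(epochs),
                 iterations_per_epoch = iterations_per_epoch,
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay, poly_gamma = poly_gamma,
                 patch_size = as.integer(patch_size), window = window,
                 target_spacing = rep(as.numeric(target_spacing), length.out = 3),
                 crop_margin_mm = crop_margin_mm,
                 augment_flip = augment_flip, augment_rot90 = augment_rot90,
                 augment_rot_small = augment_rot_small,
                 augment_intensity = augment_intensity, overlap = overlap,
                 distill_temperature = distill_temperature,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Poly learning-rate schedule
#'
#' \code{lr(epoch) = lr0 * (1 - epoch/epochs)^gamma}: the configured rate at
#' epoch 0, decaying to 0 at the final epoch.
#'
#' @param epoch Epoch index in \code{0..epochs}.
#' @param config A \code{\link{train_config}}.
#' @return Learning rate.
#' @export
poly_lr <- function(epoch, config = train_config()) {
  if (epoch < 0 || epoch > config$epochs)
    stop("epoch out of range [0, ", config$epochs, "]")
  config$lr * (1 - epoch / config$epochs)^config$poly_gamma
}

#' Modality-balanced sampling of the next training case
#'
#' Draws the modality uniformly among modalities with training cases, then a
#' case uniformly within that modality — so modalities with more images do
#' not bias the model. Uses the current RNG stream (seed it for
#' reproducible draw sequences).
#'
#' @param manifest A \code{\link{dataset_manifest}}.
#' @return One manifest row (train split).
#' @export
sample_next <- function(manifest) {
  tr <- manifest_subset(manifest, split = "train")
  if (nrow(tr) == 0L) stop("empty training split")
  mods <- sort(unique(tr$modality))
  m <- mods[sample.int(length(mods), 1L)]
  rows <- which(tr$modality == m)
  tr[rows[sample.int(length(rows), 1L)], , drop = FALSE]
}

#' Initialise AdamW optimiser state over a model's full parameter set
#'
#' One state entry (first and second moment, step counter) per trainable
#' array — the single optimiser covers every encoder, the bottleneck and
#' every decoder exactly once.
#'
#' @param model A \code{magic_model}.
#' @return Optimiser state for \code{\link{train_step}}.
#' @export
optimizer_init <- function(model) adamw_init(model$params)

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = setNames(numeric(length(params)), names(params)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one decoupled-weight-decay Adam update; parameters without a gradient are
# left untouched (their step counters do not advance)
adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$t[[nm]] <- state$t[[nm]] + 1
    t <- state$t[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

#' One optimisation step
#'
#' Forward, hybrid loss (+ self-distillation), backward, and a single AdamW
#' update over the one shared parameter collection — all encoders, the
#' bottleneck and all decoders sit in the same optimiser, but only
#' parameters reached by this batch's modality receive gradient.
#'
#' @param model A \code{magic_model}.
#' @param batch List of cases, each \code{list(image, labels, modality)}
#'   with a patch-sized image and per-group integer labels.
#' @param opt_state AdamW state from \code{adamw_init}.
#' @param config A \code{\link{train_config}}.
#' @param lr Learning rate for this step (from \code{\link{poly_lr}}).
#' @return List: updated \code{model}, \code{opt_state}, and the batch-mean
#'   \code{report}.
#' @export
train_step <- function(model, batch, opt_state, config, lr = config$lr) {
  grads <- list()
  reports <- list()
  distill <- model$spec$backbone$self_distillation
  for (case in batch) {
    fw <- magic_forward(model, case$image, case$modality, training = TRUE)
    tl <- training_loss(fw, case$labels, config$target_spacing,
                        distill = distill,
                        temperature = config$distill_temperature)
    if (!is.finite(tl$report$total))
      stop("non-finite loss (", tl$report$total, ") on modality ",
           case$modality)
    G <- magic_backward(model, fw, tl$dheads, tl$dencproj)
    for (nm in names(G))
      grads[[nm]] <- if (is.null(grads[[nm]])) G[[nm]] else grads[[nm]] + G[[nm]]
    reports[[length(reports) + 1L]] <- tl$report
  }
  grads <- lapply(grads, function(g) g / length(batch))
  upd <- adamw_step(model$params, grads, opt_state, lr, config$weight_decay)
  model$params <- upd$params
  mean_of <- function(f) mean(vapply(reports, `[[`, numeric(1), f))
  report <- structure(list(dice = mean_of("dice"), boundary = mean_of("boundary"),
                           cross_entropy = mean_of("cross_entropy"),
                           distillation = mean_of("distillation"),
                           total = mean_of("total"), per_group = NULL),
                      class = "loss_report")
  list(model = model, opt_state = upd$state, report = report)
}

load_case <- function(row, config, catalog = structure_catalog()) {
  vol <- read_volume(row$image, row$modality)
  comp <- if (nzchar(row$labels)) read_composite(row$labels, catalog) else NULL
  preprocess_case(vol, comp, config)
}

validation_dsc <- function(model, cases, config) {
  # mean DSC over all structures and modalities; structures absent from a
  # case's (resampled) reference carry no information about quality and
  # are excluded from the mean
  vals <- c()
  for (case in cases) {
    pred <- sliding_window_predict(model, case$image, case$image$modality,
                                   patch_size = NULL, overlap = config$overlap)
    comp <- assemble_composite(pred, model$spec$catalog, case$image$spacing)
    for (nm in catalog_structures(model$spec$catalog)) {
      g <- structure_group(model$spec$catalog, nm)
      k <- match(nm, model$spec$catalog$groups[[g]])
      ref <- case$group_maps[[g]] == k
      if (any(ref)) vals <- c(vals, dsc(comp$masks[[nm]], ref))
    }
  }
  mean(vals)
}

#' Train the cascade
#'
#' The full optimisation loop: all labeled cases are preprocessed once
#' (window, heart crop, resample, normalise); each iteration draws
#' \code{batch_size} cases modality-balanced, augments them into training
#' patches and takes one AdamW step at the poly-scheduled rate; after every
#' epoch the validation split is segmented as full volumes and the mean
#' Dice over all structures and modalities decides the best checkpoint,
#' which is the returned model. Fully reproducible from
#' \code{config$seed}.
#'
#' @param manifest A \code{\link{dataset_manifest}} with labeled train and
#'   val entries.
#' @param spec A \code{\link{cascade_spec}} (must carry a catalog).
#' @param config A \code{\link{train_config}}.
#' @param verbose Print per-epoch progress.
#' @return The trained \code{magic_model} carrying \code{history} (per-epoch
#'   loss components, learning rate and validation DSC), \code{best_epoch},
#'   \code{best_val_dsc} and \code{config}.
#' @export
magic_train <- function(manifest, spec = cascade_spec(), config = train_config(),
                        verbose = TRUE) {
  if (is.null(spec$catalog)) stop("cascade_spec needs a structure catalog")
  if (config$patch_size %% 2L^spec$backbone$n_stages != 0L)
    stop("patch size must be divisible by ", 2L^spec$backbone$n_stages)
  tr_rows <- manifest_subset(manifest, split = "train")
  va_rows <- manifest_subset(manifest, split = "val")
  if (nrow(tr_rows) == 0L) stop("no training cases")
  if (nrow(va_rows) == 0L) stop("no validation cases")
  for (m in unique(manifest$modality))
    if (!m %in% spec$modalities) stop("manifest modality not in cascade: ", m)
  tr_cases <- lapply(seq_len(nrow(tr_rows)), function(i)
    load_case(tr_rows[i, ], config, spec$catalog))
  va_cases <- lapply(seq_len(nrow(va_rows)), function(i)
    load_case(va_rows[i, ], config, spec$catalog))
  model <- build_cascade(spec, seed = config$seed)
  opt <- adamw_init(model$params)
  iters <- config$iterations_per_epoch %||% nrow(tr_rows)
  history <- NULL
  best <- list(dsc = -Inf, epoch = NA_integer_, params = NULL)
  for (epoch in seq_len(config$epochs)) {
    lr <- poly_lr(epoch - 1L, config)
    ep_rep <- c(dice = 0, boundary = 0, cross_entropy = 0, distillation = 0,
                total = 0)
    for (it in seq_len(iters)) {
      iseed <- config$seed + 7L + 1009L * ((epoch - 1L) * iters + it)
      rows <- with_seed(iseed, {
        lapply(seq_len(config$batch_size), function(b) sample_next(manifest))
      })
      batch <- lapply(seq_along(rows), function(b) {
        ridx <- which(tr_rows$image == rows[[b]]$image)[1]
        case <- tr_cases[[ridx]]
        aug <- augment_case(case$image$data, case$group_maps,
                            seed = iseed + b,
                            patch_size = config$patch_size,
                            flip = config$augment_flip,
                            rot90 = config$augment_rot90,
                            rot_small = config$augment_rot_small,
                            intensity = config$augment_intensity)
        list(image = aug$image, labels = aug$labels,
             modality = rows[[b]]$modality)
      })
      st <- train_step(model, batch, opt, config, lr)
      model <- st$model
      opt <- st$opt_state
      ep_rep <- ep_rep + vapply(c("dice", "boundary", "cross_entropy",
                                  "distillation", "total"),
                                function(f) st$report[[f]], numeric(1))
    }
    ep_rep <- ep_rep / iters
    vdsc <- validation_dsc(model, va_cases, config)
    if (vdsc > best$dsc)
      best <- list(dsc = vdsc, epoch = epoch, params = model$params)
    history <- rbind(history,
                     data.frame(epoch = epoch, lr = lr, t(ep_rep),
                                val_dsc = vdsc))
    if (verbose)
      message(sprintf("epoch %3d/%d  lr %.2e  loss %.4f  val DSC %.4f%s",
                      epoch, config$epochs, lr, ep_rep[["total"]], vdsc,
                      if (epoch == best$epoch) "  *" else ""))
  }
  model$last_params <- model$params  # final-epoch weights, for resuming
  model$params <- best$params
  model$history <- history
  model$best_epoch <- best$epoch
  model$best_val_dsc <- best$dsc
  model$config <- config
  model
}

#' @export
summary.magic_model <- function(object, ...) {
  print(object)
  print(count_parameters(object))
  if (!is.null(object$history)) {
    cat("training history (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is self-describing: parameters, cascade specification,
#' catalog, training history and configuration in one file.
#'
#' @param model A \code{magic_model}.
#' @param path Checkpoint path (.rds).
#' @return \code{path} / the restored \code{magic_model}.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "magic_model"))
  model
}

#' Pseudo-label expansion of the training set
#'
#' Predicts composites for unlabeled manifest entries and admits accepted
#' cases to the training split with provenance \code{"pseudo"}. The visual
#' acceptance step of a human reviewer is replaced by a pluggable rule: the
#' default accepts a case when the mean winning-class probability over
#' predicted foreground voxels is at least \code{threshold}; explicit
#' \code{include}/\code{exclude} image lists override the rule either way.
#'
#' @param model A trained \code{magic_model}.
#' @param manifest Manifest with unlabeled entries.
#' @param rule \code{"threshold"}, \code{"all"}, \code{"none"}, or a
#'   function(composite, probs) -> logical.
#' @param threshold Mean foreground-probability acceptance threshold.
#' @param include,exclude Image paths to force-accept / force-reject.
#' @param config A \code{\link{train_config}}.
#' @return The expanded, validated \code{\link{dataset_manifest}}; accepted
#'   pseudo-composites are written next to their images
#'   (\code{*_plab.nii.gz}).
#' @export
pseudo_label <- function(model, manifest, rule = "threshold", threshold = 0.5,
                         include = character(), exclude = character(),
                         config = train_config()) {
  un <- manifest_subset(manifest, split = "unlabeled")
  if (nrow(un) == 0L) stop("no unlabeled entries in manifest")
  rows <- as.data.frame(manifest)
  for (i in seq_len(nrow(un))) {
    case <- load_case(un[i, ], config, model$spec$catalog)
    probs <- sliding_window_predict(model, case$image, un$modality[i],
                                    patch_size = NULL, overlap = config$overlap)
    comp <- assemble_composite(probs, model$spec$catalog, case$image$spacing)
    accept <- if (is.function(rule)) {
      isTRUE(rule(comp, probs))
    } else if (rule == "all") TRUE
    else if (rule == "none") FALSE
    else {
      conf <- foreground_confidence(probs)
      is.finite(conf) && conf >= threshold
    }
    if (un$image[i] %in% include) accept <- TRUE
    if (un$image[i] %in% exclude) accept <- FALSE
    if (accept) {
      lab <- sub("\\.nii(\\.gz)?$", "_plab.nii.gz", un$image[i])
      write_composite(comp, lab)
      k <- which(rows$image == un$image[i])
      rows$labels[k] <- lab
      rows$split[k] <- "train"
      rows$provenance[k] <- "pseudo"
    }
  }
  dataset_manifest(rows, modalities = model$spec$modalities)
}

# mean winning-class probability over voxels predicted as foreground
foreground_confidence <- function(probs) {
  conf <- c()
  for (g in names(probs)) {
    p <- probs[[g]]
    C <- dim(p)[1]
    pm <- matrix(p, C)
    win <- max.col(t(pm), ties.method = "first")
    fg <- win > 1L
    if (any(fg)) conf <- c(conf, pm[cbind(win[fg], which(fg))])
  }
  if (length(conf) == 0L) return(NaN)
  mean(conf)
}
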