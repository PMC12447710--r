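#' Window start positions along one axis
#'
#' Stride is \code{max(1, floor(patch * (1 - overlap)))}; windows start at
#' that stride from 1 and a final window is anchored at the end, so every
#' voxel is covered at least once.
#'
#' @param extent Axis length (voxels), at least \code{patch}.
#' @param patch Window length.
#' @param overlap Fractional overlap in [0, 1).
#' @return Integer vector of 1-based window start positions.
#' @export
sliding_window_positions <- function(extent, patch, overlap = 0.9) {
  stopifnot(extent >= patch, patch >= 1, overlap >= 0, overlap < 1)
  if (extent == patch) return(1L)
  stride <- max(1L, as.integer(floor(patch * (1 - overlap))))
  unique(c(seq(1L, extent - patch + 1L, stride), extent - patch + 1L))
}

#' Sliding-window inference
#'
#' Tiles the volume with cubic patches at stride
#' \code{max(1, floor(patch * (1 - overlap)))} per axis (90% overlap of a
#' 96 patch gives stride 9), guaranteeing every voxel is covered, and blends
#' window softmax probabilities by Gaussian importance weighting
#' (sigma = patch/8; uniform averaging available for oracle checks).
#' Volumes smaller than the patch are zero-padded, predicted and unpadded.
#'
#' @param model A \code{magic_model}.
#' @param vol A preprocessed \code{\link{as_volume}} (or bare 3-D array).
#' @param modality Which encoder to use (defaults to the volume's tag).
#' @param patch_size Window edge; NULL uses the whole (padded) volume as a
#'   single window.
#' @param overlap Fractional window overlap in [0, 1).
#' @param blend \code{"gaussian"} or \code{"uniform"}.
#' @return Per-group list of probability arrays \code{(classes, X, Y, Z)} on
#'   the input grid.
#' @export
sliding_window_predict <- function(model, vol, modality = NULL,
                                   patch_size = 96L, overlap = 0.9,
                                   blend = c("gaussian", "uniform")) {
  blend <- match.arg(blend)
  x <- if (inherits(vol, "volume")) vol$data else vol
  if (is.null(modality))
    modality <- if (inherits(vol, "volume")) vol$modality else
      stop("modality required for bare arrays")
  d <- dim(x)
  div <- 2L^model$spec$backbone$n_stages
  if (is.null(patch_size)) {
    ps <- as.integer(ceiling(d / div) * div)
  } else {
    stopifnot(patch_size %% div == 0L)
    ps <- rep(as.integer(patch_size), 3L)
  }
  pd <- pmax(d, ps)
  xp <- pad_to(x, pd, fill = min(x))  # pad with background, not mid-scale

  pos <- lapply(1:3, function(a) sliding_window_positions(pd[a], ps[a], overlap))
  w <- if (blend == "gaussian") {
    g1 <- function(n) exp(-(seq_len(n) - (n + 1) / 2)^2 / (2 * (n / 8)^2))
    outer(outer(g1(ps[1]), g1(ps[2]), "*"), g1(ps[3]), "*")
  } else {
    array(1, ps)
  }
  groups <- names(model$spec$class_counts)
  acc <- lapply(groups, function(g)
    array(0, c(model$spec$class_counts[[g]], pd)))
  names(acc) <- groups
  wsum <- array(0, pd)
  for (ix in pos[[1]]) for (iy in pos[[2]]) for (iz in pos[[3]]) {
    sl <- list(ix:(ix + ps[1] - 1L), iy:(iy + ps[2] - 1L), iz:(iz + ps[3] - 1L))
    patch <- xp[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
    fw <- magic_forward(model, patch, modality, training = FALSE,
                        with_projections = FALSE)
    for (g in groups) {
      z <- fw$groups[[g]]$heads[["1"]]
      C <- dim(z)[1]
      p <- array(softmax_cols(matrix(z, C)), dim(z))
      pw <- p * rep(w, each = C)
      acc[[g]][, sl[[1]], sl[[2]], sl[[3]]] <-
        acc[[g]][, sl[[1]], sl[[2]], sl[[3]]] + pw
    }
    wsum[sl[[1]], sl[[2]], sl[[3]]] <- wsum[sl[[1]], sl[[2]], sl[[3]]] + w
  }
  if (any(wsum == 0)) stop("internal error: uncovered voxels in tiling")
  out <- lapply(acc, function(a) {
    C <- dim(a)[1]
    a <- a / rep(wsum, each = C)
    a[, seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  })
  out
}

#' Assemble per-group probabilities into a composite segmentation
#'
#' Per-group voxelwise argmax (ties broken deterministically toward the
#' lower class index) produces each group's label map; encoding the four
#' maps yields the composite, in which cross-group overlap emerges
#' naturally while within-group exclusivity is guaranteed by the argmax.
#'
#' @param probs Per-group probability arrays \code{(classes, X, Y, Z)}.
#' @param catalog A \code{\link{structure_catalog}}.
#' @param spacing Grid spacing (mm).
#' @return A \code{\link{composite_segmentation}}.
#' @export
assemble_composite <- function(probs, catalog = structure_catalog(),
                               spacing = c(1, 1, 1)) {
  dims <- dim(probs[[1]])[2:4]
  gm <- list()
  for (g in names(catalog$groups)) {
    p <- probs[[g]]
    if (!identical(dim(p)[2:4], dims)) stop("grid mismatch across groups")
    C <- dim(p)[1]
    win <- max.col(t(matrix(p, C)), ties.method = "first")
    gm[[g]] <- group_label_map(array(as.integer(win - 1L), dims), g, catalog,
                               spacing)
  }
  encode_composite(gm, catalog)
}

#' Segment a new volume with a trained model
#'
#' Preprocesses the input exactly as during training (window, optional
#' intensity-based heart crop, resample to the working spacing, z-score),
#' runs Gaussian-blended sliding-window inference and assembles the
#' composite segmentation on the working grid.
#'
#' @param object A trained \code{magic_model}.
#' @param vol A \code{\link{as_volume}} or NIfTI path.
#' @param modality Modality tag (required for paths).
#' @param config Preprocessing/inference configuration (defaults to the
#'   model's training configuration).
#' @param patch_size Inference window (NULL: single whole-volume window).
#' @param probabilities Also attach the per-group probability fields.
#' @param ... Unused.
#' @return A \code{\link{composite_segmentation}}; if \code{probabilities},
#'   with attribute \code{"probs"}.
#' @export
predict.magic_model <- function(object, vol, modality = NULL, config = NULL,
                                patch_size = NULL, probabilities = FALSE, ...) {
  config <- config %||% object$config %||% train_config()
  if (is.character(vol)) vol <- read_volume(vol, modality %||% "SIM_CT")
  if (!is.null(modality)) vol$modality <- modality
  pp <- preprocess_case(vol, NULL, config)
  probs <- sliding_window_predict(object, pp$image, pp$image$modality,
                                  patch_size = patch_size,
                                  overlap = config$overlap)
  comp <- assemble_composite(probs, object$spec$catalog, pp$image$spacing)
  if (probabilities) attr(comp, "probs") <- probs
  comp
}
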