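# Hybrid segmentation loss: equally weighted Dice + boundary + cross-entropy,
# plus dual self-distillation terms added with weight 1. Scores are logits
# (C, X, Y, Z); integer references use 0 = background, k = k-th structure.

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

onehot_cols <- function(labels, C) {
  n <- length(labels)
  r <- matrix(0, C, n)
  r[cbind(as.integer(labels) + 1L, seq_len(n))] <- 1
  r
}

# soft Dice on probability columns; returns value and d/dprob
soft_dice_prob <- function(p, r, eps = 1e-5) {
  C <- nrow(p)
  fg <- seq_len(C)[-1]
  A <- rowSums(p[fg, , drop = FALSE] * r[fg, , drop = FALSE])
  B <- rowSums(p[fg, , drop = FALSE]) + rowSums(r[fg, , drop = FALSE])
  dice <- (2 * A + eps) / (B + eps)
  dp <- matrix(0, C, ncol(p))
  # d(1 - mean dice)/dp_c(v) = -(2 r_c(v) (B_c+eps) - (2A_c+eps)) / (B_c+eps)^2 / |fg|
  dp[fg, ] <- -(2 * r[fg, , drop = FALSE] * (B + eps) - (2 * A + eps)) /
    (B + eps)^2 / length(fg)
  list(value = 1 - mean(dice), dprob = dp)
}

# chain rule through a per-voxel softmax: dz = p * (dp - colsum(dp * p))
softmax_chain <- function(dp, p) {
  p * (dp - rep(colSums(dp * p), each = nrow(p)))
}

#' Soft Dice loss
#'
#' \code{1 -} soft Dice averaged over foreground classes (all classes but
#' the first). A smoothing epsilon (default \code{1e-5}) is added to
#' numerator and denominator, so a perfect prediction scores 0 up to
#' epsilon and empty reference classes do not divide by zero.
#'
#' @param prob Per-class probability array \code{(C, X, Y, Z)} summing to 1
#'   per voxel.
#' @param ref One-hot reference of the same shape.
#' @param eps Smoothing epsilon.
#' @return Scalar loss in \[0, 1\].
#' @export
dice_loss <- function(prob, ref, eps = 1e-5) {
  if (!identical(dim(prob), dim(ref))) stop("shape mismatch")
  C <- dim(prob)[1]
  soft_dice_prob(matrix(prob, C), matrix(ref, C), eps)$value
}

#' Signed distance field of a binary mask
#'
#' Exact Euclidean distance (mm) to the mask boundary, negated strictly
#' inside the mask: negative inside, zero on the boundary (border voxels),
#' positive outside. The boundary is the set of mask voxels with a
#' 6-neighbour outside the mask (the volume edge counts as outside). An
#' empty mask has no boundary; its field is all-positive, capped at the
#' physical grid diameter.
#'
#' @param mask Logical 3-D array.
#' @param spacing Voxel spacing (mm).
#' @return Numeric 3-D array of signed distances in mm.
#' @export
signed_distance <- function(mask, spacing = c(1, 1, 1)) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3L)
  diam <- sqrt(sum((dims * spacing)^2))
  if (!any(mask)) return(array(diam, dims))
  b <- border_voxels(mask)
  d <- array(cpp_edt(as.logical(b), as.integer(dims), as.numeric(spacing)), dims)
  d[mask] <- -d[mask]
  d[b] <- 0
  d
}

# mask voxels 6-adjacent to background (volume edge counts as background)
border_voxels <- function(mask) {
  dims <- dim(mask)
  inside <- array(TRUE, dims)
  shift_and <- function(m, axis, by) {
    out <- array(FALSE, dims)
    n <- dims[axis]
    if (n == 1L) return(out)  # everything shifts off a singleton axis
    idx_src <- lapply(dims, seq_len)
    idx_dst <- idx_src
    if (by == 1L) { idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1) }
    else { idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (axis in 1:3) for (by in c(1L, -1L))
    inside <- inside & shift_and(mask, axis, by)
  mask & !inside
}

#' Boundary (surface) loss
#'
#' Mean over voxels and foreground classes of predicted probability times
#' the reference signed distance. Probability mass inside the reference
#' (negative distances) lowers the loss, mass outside raises it, so the
#' value can be negative; over binary predictions it is minimised exactly by
#' the reference itself.
#'
#' @param prob Probability array \code{(C, X, Y, Z)}.
#' @param sdf Per-class signed distance array of the same shape (background
#'   channel is ignored).
#' @return Scalar (mm).
#' @export
boundary_loss <- function(prob, sdf) {
  if (!identical(dim(prob), dim(sdf))) stop("shape mismatch")
  C <- dim(prob)[1]
  if (C < 2) stop("need at least one foreground class")
  fg <- 2:C
  mean(prob[fg, , , , drop = FALSE] * sdf[fg, , , , drop = FALSE])
}

#' Multi-class cross-entropy
#'
#' Mean negative log-likelihood of the reference label under the softmax of
#' the scores.
#'
#' @param scores Logit array \code{(C, X, Y, Z)}.
#' @param labels Integer array \code{(X, Y, Z)} with values in
#'   \code{0..C-1}.
#' @return Scalar loss.
#' @export
cross_entropy <- function(scores, labels) {
  C <- dim(scores)[1]
  if (any(labels < 0L | labels > C - 1L)) stop("label outside class range")
  z <- matrix(scores, C)
  p <- softmax_cols(z)
  idx <- cbind(as.integer(labels) + 1L, seq_len(ncol(z)))
  -mean(log(pmax(p[idx], 1e-300)))
}

# combined (dice + boundary + ce)/3 for one head, with gradient wrt scores
hybrid_loss_grad <- function(scores, labels, spacing, eps = 1e-5) {
  C <- dim(scores)[1]
  nsp <- prod(dim(scores)[2:4])
  z <- matrix(scores, C)
  p <- softmax_cols(z)
  r <- onehot_cols(labels, C)
  # cross entropy
  idx <- cbind(as.integer(labels) + 1L, seq_len(nsp))
  ce <- -mean(log(pmax(p[idx], 1e-300)))
  dz_ce <- (p - r) / nsp
  # dice
  sd <- soft_dice_prob(p, r, eps)
  dz_dice <- softmax_chain(sd$dprob, p)
  # boundary
  fg <- 2:C
  sdfm <- matrix(0, C, nsp)
  lab3 <- array(as.integer(labels), dim(scores)[2:4])
  for (c in fg)
    sdfm[c, ] <- signed_distance(lab3 == (c - 1L), spacing)
  bd <- mean(p[fg, , drop = FALSE] * sdfm[fg, , drop = FALSE])
  dp_bd <- sdfm / (nsp * length(fg))
  dp_bd[1, ] <- 0
  dz_bd <- softmax_chain(dp_bd, p)
  list(dice = sd$value, boundary = bd, cross_entropy = ce,
       value = (sd$value + bd + ce) / 3,
       dscores = array((dz_dice + dz_bd + dz_ce) / 3, dim(scores)))
}

#' Primary hybrid loss over all groups and deep-supervision heads
#'
#' For each group and each head, the equally weighted combination
#' \code{(dice + boundary + cross_entropy)/3} is evaluated against the
#' group's reference labels, nearest-neighbour downsampled to the head's
#' resolution (signed distances are recomputed at that resolution with
#' scaled spacing); heads carry equal weight, and groups carry equal
#' weight. Reported component values are aggregated the same way, so
#' \code{total = (dice + boundary + cross_entropy)/3} exactly.
#'
#' @param scores_per_group Per group, a named list of head score arrays by
#'   decoder depth (\code{"1"} = full resolution), as returned in
#'   \code{magic_forward()$groups[[g]]$heads}.
#' @param ref_maps Per group, an integer label array (or
#'   \code{\link{group_label_map}}) at full resolution.
#' @param spacing Voxel spacing of the full-resolution grid (mm).
#' @param with_grad Also return gradients w.r.t. every head's scores.
#' @return List with \code{dice}, \code{boundary}, \code{cross_entropy},
#'   \code{total}, \code{per_group}, and (if \code{with_grad})
#'   \code{dheads}.
#' @export
primary_loss <- function(scores_per_group, ref_maps, spacing = c(1, 1, 1),
                         with_grad = FALSE) {
  groups <- names(scores_per_group)
  if (!setequal(groups, names(ref_maps)))
    stop("missing group: ", paste(setdiff(groups, names(ref_maps)), collapse = ", "))
  comp <- c(dice = 0, boundary = 0, cross_entropy = 0)
  per_group <- list()
  dheads <- list()
  nterm <- 0L
  for (g in groups) {
    ref <- ref_maps[[g]]
    if (inherits(ref, "group_label_map")) ref <- ref$labels
    gcomp <- c(dice = 0, boundary = 0, cross_entropy = 0)
    dheads[[g]] <- list()
    stages <- names(scores_per_group[[g]])
    for (s in stages) {
      f <- 2L^(as.integer(s) - 1L)
      refs <- subsample_nn(ref, f)
      hl <- hybrid_loss_grad(scores_per_group[[g]][[s]], refs, spacing * f)
      gcomp <- gcomp + c(hl$dice, hl$boundary, hl$cross_entropy)
      if (with_grad) dheads[[g]][[s]] <- hl$dscores / (length(stages) * length(groups))
      nterm <- nterm + 1L
    }
    per_group[[g]] <- gcomp / length(stages)
    comp <- comp + gcomp / length(stages)
  }
  comp <- comp / length(groups)
  out <- list(dice = comp[["dice"]], boundary = comp[["boundary"]],
              cross_entropy = comp[["cross_entropy"]],
              total = sum(comp) / 3, per_group = per_group)
  if (with_grad) out$dheads <- dheads
  out
}

# temperature-softened KL(teacher || student) on score columns;
# teacher is detached. Returns value and d/d(student scores).
kl_soft <- function(zt, zs, temperature) {
  pt <- softmax_cols(zt / temperature)
  ps <- softmax_cols(zs / temperature)
  v <- mean(colSums(pt * (log(pmax(pt, 1e-300)) - log(pmax(ps, 1e-300)))))
  dzs <- (ps - pt) / (temperature * ncol(zs))
  list(value = v, dzs = dzs)
}

#' Dual self-distillation loss
#'
#' Decoder side: the full-resolution head of each group is the teacher; each
#' deeper (auxiliary) head is a student penalised by the temperature-softened
#' Kullback-Leibler divergence to the teacher, nearest-neighbour downsampled
#' to the student's resolution. Encoder side: the deepest encoder stage's
#' feature projection teaches the shallower projections, likewise
#' downsampled. Teachers are detached (no gradient flows through them). All
#' student terms are averaged and the result is added to the primary loss
#' with weight 1.
#'
#' @param heads_per_group Per group, named list of head scores by depth
#'   (needs at least 2 heads).
#' @param encproj Optional per-stage encoder projections (deepest stage is
#'   the teacher).
#' @param temperature Softening temperature (default 3).
#' @param with_grad Also return gradients for the student heads/projections.
#' @return List with \code{value} and (if \code{with_grad}) \code{dheads},
#'   \code{dencproj}.
#' @export
distillation_loss <- function(heads_per_group, encproj = NULL, temperature = 3,
                              with_grad = FALSE) {
  terms <- 0
  total <- 0
  dheads <- list()
  dencproj <- NULL
  for (g in names(heads_per_group)) {
    hs <- heads_per_group[[g]]
    if (length(hs) < 2L)
      stop("self-distillation needs at least two heads per decoder")
    teach <- hs[["1"]]
    C <- dim(teach)[1]
    dheads[[g]] <- list()
    for (s in setdiff(names(hs), "1")) {
      f <- 2L^(as.integer(s) - 1L)
      zt <- matrix(subsample_nn(teach, f), C)
      zs <- matrix(hs[[s]], C)
      kl <- kl_soft(zt, zs, temperature)
      total <- total + kl$value
      terms <- terms + 1
      if (with_grad) dheads[[g]][[s]] <- array(kl$dzs, dim(hs[[s]]))
    }
  }
  if (!is.null(encproj) && length(encproj) >= 2L) {
    S <- max(as.integer(names(encproj)))
    teach <- encproj[[as.character(S)]]
    C <- dim(teach)[1]
    dencproj <- list()
    for (i in setdiff(as.integer(names(encproj)), S)) {
      f <- 2L^(S - i)
      zs_full <- encproj[[as.character(i)]]
      sub <- subsample_nn(zs_full, f)
      kl <- kl_soft(matrix(teach, C), matrix(sub, C), temperature)
      total <- total + kl$value
      terms <- terms + 1
      if (with_grad) {
        d <- zeros_like(zs_full)
        idx <- lapply(dim(zs_full)[2:4], function(n) seq(1L, n, f))
        d[, idx[[1]], idx[[2]], idx[[3]]] <- kl$dzs
        dencproj[[as.character(i)]] <- d
      }
    }
  }
  if (terms == 0) stop("no student terms")
  out <- list(value = total / terms)
  if (with_grad) {
    out$dheads <- lapply(dheads, function(l) lapply(l, function(a) a / terms))
    if (!is.null(dencproj))
      out$dencproj <- lapply(dencproj, function(a) a / terms)
  }
  out
}

#' Full training loss for one patch
#'
#' Primary hybrid loss plus (when the backbone enables it) the dual
#' self-distillation terms with weight 1. Returns a loss report and the
#' gradients feeding \code{\link{magic_backward}}.
#'
#' @param fw Output of \code{\link{magic_forward}}.
#' @param ref_maps Per-group integer reference labels at patch resolution.
#' @param spacing Patch voxel spacing (mm).
#' @param distill Include self-distillation terms.
#' @param temperature Distillation temperature.
#' @return List: \code{report} (class \code{loss_report}) and \code{dheads},
#'   \code{dencproj}.
#' @export
training_loss <- function(fw, ref_maps, spacing = c(1, 1, 1), distill = TRUE,
                          temperature = 3) {
  scores <- lapply(fw$groups, `[[`, "heads")
  pl <- primary_loss(scores, ref_maps, spacing, with_grad = TRUE)
  dheads <- pl$dheads
  dencproj <- NULL
  dl_value <- 0
  if (distill) {
    dl <- distillation_loss(scores, fw$encproj, temperature, with_grad = TRUE)
    dl_value <- dl$value
    for (g in names(dl$dheads))
      for (s in names(dl$dheads[[g]]))
        dheads[[g]][[s]] <- dheads[[g]][[s]] + dl$dheads[[g]][[s]]
    dencproj <- dl$dencproj
  }
  report <- structure(list(dice = pl$dice, boundary = pl$boundary,
                           cross_entropy = pl$cross_entropy,
                           distillation = dl_value,
                           total = pl$total + dl_value,
                           per_group = pl$per_group),
                      class = "loss_report")
  list(report = report, dheads = dheads, dencproj = dencproj)
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("loss: total %.4f (dice %.4f, boundary %.4f, CE %.4f, distill %.4f)\n",
              x$total, x$dice, x$boundary, x$cross_entropy, x$distillation))
  invisible(x)
}
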