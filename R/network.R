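#' Backbone hyperparameters
#'
#' Describes the single-modality U-shaped backbone: encoder stages with
#' stride-2 downsampling, a bottleneck, and a mirrored decoder with skip
#' connections, deep-supervision heads at every decoder depth and
#' self-distillation projections on the encoder side. Channel width doubles
#' per stage up to \code{width_cap}. Defaults follow common 3-D U-Net
#' practice (5 stages, base width 32, cap 320, 3x3x3 kernels, instance
#' normalisation, leaky ReLU); \code{tiny_backbone_spec()} is a desk-scale
#' preset for CPU work.
#'
#' @param n_stages Number of encoder stages (the bottleneck adds one more
#'   downsampling, so patches must be divisible by \code{2^n_stages}).
#' @param base_width Channels of the first stage.
#' @param width_cap Maximum channel width.
#' @param kernel Convolution kernel size (cubic).
#' @param deep_supervision Add auxiliary heads at every decoder depth.
#' @param self_distillation Add encoder feature projections and train
#'   shallow heads/features against the deepest ones.
#' @param distill_channels Channels of the encoder distillation projections.
#' @param in_channels Image channels (1 for scalar volumes).
#' @return An object of class \code{backbone_spec}.
#' @export
backbone_spec <- function(n_stages = 5L, base_width = 32L, width_cap = 320L,
                          kernel = 3L, deep_supervision = TRUE,
                          self_distillation = TRUE, distill_channels = 8L,
                          in_channels = 1L) {
  stopifnot(n_stages >= 2L, base_width >= 1L, width_cap >= base_width,
            kernel %in% c(1L, 3L, 5L))
  structure(list(n_stages = as.integer(n_stages),
                 base_width = as.integer(base_width),
                 width_cap = as.integer(width_cap), kernel = as.integer(kernel),
                 deep_supervision = isTRUE(deep_supervision),
                 self_distillation = isTRUE(self_distillation),
                 distill_channels = as.integer(distill_channels),
                 in_channels = as.integer(in_channels)),
            class = "backbone_spec")
}

#' @rdname backbone_spec
#' @export
tiny_backbone_spec <- function() {
  backbone_spec(n_stages = 3L, base_width = 8L, width_cap = 64L)
}

stage_widths <- function(bs) {
  pmin(bs$width_cap, bs$base_width * 2L^(seq_len(bs$n_stages) - 1L))
}

bottleneck_width <- function(bs) {
  min(bs$width_cap, bs$base_width * 2L^bs$n_stages)
}

#' Cascade specification
#'
#' Fully determines the multi-modality, multi-group model: one encoder per
#' modality, one shared bottleneck, one decoder per structure group, all on
#' the same backbone. Class counts per group are group size + 1
#' (background), (2, 10, 9, 3) for the default cardiac catalog.
#'
#' @param backbone A \code{\link{backbone_spec}}.
#' @param modalities Ordered modality tags (one encoder each).
#' @param class_counts Named integer vector of per-group class counts
#'   (structures + background), in decoder order.
#' @param catalog Optional \code{\link{structure_catalog}} consistent with
#'   \code{class_counts} (kept for label plumbing).
#' @return An object of class \code{cascade_spec}.
#' @export
cascade_spec <- function(backbone = backbone_spec(),
                         modalities = magic_modalities(),
                         class_counts = group_class_counts(structure_catalog()),
                         catalog = structure_catalog()) {
  stopifnot(length(modalities) >= 1L, length(class_counts) >= 1L,
            all(class_counts >= 2L))
  if (is.null(names(class_counts)))
    names(class_counts) <- paste0("G", seq_along(class_counts))
  cc <- as.integer(class_counts)
  names(cc) <- names(class_counts)
  if (!is.null(catalog) &&
      !identical(unname(group_class_counts(catalog)[names(cc)]), unname(cc)))
    catalog <- NULL
  structure(list(backbone = backbone, modalities = as.character(modalities),
                 class_counts = cc, catalog = catalog),
            class = "cascade_spec")
}

getp <- function(P, pre) {
  list(W = P[[paste0(pre, ".W")]], b = P[[paste0(pre, ".b")]],
       g = P[[paste0(pre, ".g")]], be = P[[paste0(pre, ".be")]])
}

put_conv <- function(P, pre, p) {
  P[[paste0(pre, ".W")]] <- p$W; P[[paste0(pre, ".b")]] <- p$b
  P[[paste0(pre, ".g")]] <- p$g; P[[paste0(pre, ".be")]] <- p$be
  P
}

put_head <- function(P, pre, p) {
  P[[paste0(pre, ".W")]] <- p$W; P[[paste0(pre, ".b")]] <- p$b
  P
}

init_encoder_params <- function(P, pre, bs, rng) {
  w <- stage_widths(bs)
  cin <- bs$in_channels
  for (i in seq_len(bs$n_stages)) {
    P <- put_conv(P, sprintf("%s.s%d.c1", pre, i),
                  init_conv(w[i], cin, bs$kernel, rng))
    P <- put_conv(P, sprintf("%s.s%d.c2", pre, i),
                  init_conv(w[i], w[i], bs$kernel, rng))
    cin <- w[i]
  }
  if (bs$self_distillation)
    for (i in seq_len(bs$n_stages))
      P <- put_head(P, sprintf("%s.p%d", pre, i),
                    init_head(bs$distill_channels, w[i], rng))
  P
}

init_bottleneck_params <- function(P, bs, rng) {
  w <- stage_widths(bs)
  wb <- bottleneck_width(bs)
  P <- put_conv(P, "bott.c1", init_conv(wb, w[bs$n_stages], bs$kernel, rng))
  put_conv(P, "bott.c2", init_conv(wb, wb, bs$kernel, rng))
}

init_decoder_params <- function(P, pre, bs, n_classes, rng) {
  w <- stage_widths(bs)
  wup <- c(w[-1], bottleneck_width(bs))  # channels arriving from below at stage j
  for (j in rev(seq_len(bs$n_stages))) {
    P <- put_conv(P, sprintf("%s.s%d.c1", pre, j),
                  init_conv(w[j], wup[j] + w[j], bs$kernel, rng))
    P <- put_conv(P, sprintf("%s.s%d.c2", pre, j),
                  init_conv(w[j], w[j], bs$kernel, rng))
  }
  hs <- if (bs$deep_supervision) seq_len(bs$n_stages) else 1L
  for (j in hs)
    P <- put_head(P, sprintf("%s.h%d", pre, j), init_head(n_classes, w[j], rng))
  P
}

#' Build the cascade
#'
#' Instantiates one encoder per modality (identical architecture,
#' independent parameters), exactly one shared bottleneck, and one decoder
#' per group with its own class count. Each component is initialised from
#' its own seed derived from \code{seed} and the component's position, so a
#' 1-modality / 1-group cascade is parameter-identical to the plain
#' backbone built with the same seed.
#'
#' @param spec A \code{\link{cascade_spec}}.
#' @param seed Integer seed for parameter initialisation.
#' @return An object of class \code{magic_model}.
#' @export
build_cascade <- function(spec, seed = 42L) {
  stopifnot(inherits(spec, "cascade_spec"))
  bs <- spec$backbone
  P <- list()
  for (m in seq_along(spec$modalities))
    P <- init_encoder_params(P, paste0("enc.", spec$modalities[m]), bs,
                             make_rng(seed + 1000L + m))
  P <- init_bottleneck_params(P, bs, make_rng(seed + 2000L))
  for (g in seq_along(spec$class_counts))
    P <- init_decoder_params(P, paste0("dec.", names(spec$class_counts)[g]),
                             bs, spec$class_counts[g],
                             make_rng(seed + 3000L + g))
  structure(list(spec = spec, params = P, seed = as.integer(seed)),
            class = "magic_model")
}

#' Build a plain single-modality backbone
#'
#' The degenerate cascade: one encoder, the bottleneck, one decoder. Used
#' for unimodal comparator models and as the reference for the cascade
#' degeneracy property.
#'
#' @param backbone A \code{\link{backbone_spec}}.
#' @param n_classes Segmentation classes (incl. background).
#' @param modality Modality tag of the single encoder.
#' @param group Name of the single decoder group.
#' @param seed Initialisation seed.
#' @return A \code{magic_model} with one encoder and one decoder.
#' @export
build_backbone <- function(backbone = backbone_spec(), n_classes = 2L,
                           modality = "M1", group = "G1", seed = 42L) {
  build_cascade(cascade_spec(backbone, modalities = modality,
                             class_counts = setNames(as.integer(n_classes), group),
                             catalog = NULL),
                seed = seed)
}

#' @export
print.magic_model <- function(x, ...) {
  acc <- count_parameters(x)
  cat(sprintf("magic_model: %d encoder(s) [%s], shared bottleneck, %d decoder(s) [%s]\n",
              length(x$spec$modalities), paste(x$spec$modalities, collapse = ", "),
              length(x$spec$class_counts),
              paste(sprintf("%s:%d", names(x$spec$class_counts),
                            x$spec$class_counts), collapse = ", ")))
  cat(sprintf("  backbone: %d stages, widths %s, bottleneck %d\n",
              x$spec$backbone$n_stages,
              paste(stage_widths(x$spec$backbone), collapse = "/"),
              bottleneck_width(x$spec$backbone)))
  cat(sprintf("  trainable parameters: %s\n", format(acc$total, big.mark = ",")))
  if (!is.null(x$best_epoch))
    cat(sprintf("  trained: best epoch %d, validation mean DSC %.4f\n",
                x$best_epoch, x$best_val_dsc))
  invisible(x)
}

#' Forward pass through the cascade
#'
#' Routes the patch through the selected modality's encoder, the shared
#' bottleneck, and all group decoders in one pass. Output scores (logits)
#' are returned for every group at every head resolution; the full-volume
#' head is \code{heads[["1"]]}. Deterministic: no stochastic layers.
#'
#' @param model A \code{magic_model}.
#' @param x 3-D array (or 4-D \code{(C, X, Y, Z)}) patch; spatial dims must
#'   be divisible by \code{2^n_stages}.
#' @param modality Which encoder to use.
#' @param training Keep caches for the backward pass.
#' @param with_projections Also emit encoder distillation projections.
#' @return List with \code{groups} (per group, \code{heads}: named list of
#'   score arrays \code{(classes, ...)} by decoder depth), optional
#'   \code{encproj}, and \code{cache} when \code{training}.
#' @export
magic_forward <- function(model, x, modality, training = FALSE,
                          with_projections = model$spec$backbone$self_distillation) {
  spec <- model$spec
  bs <- spec$backbone
  if (!modality %in% spec$modalities)
    stop("unknown modality: ", modality, " (registered: ",
         paste(spec$modalities, collapse = ", "), ")")
  if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
  if (any(dim(x)[2:4] %% 2L^bs$n_stages != 0L))
    stop("patch dims must be divisible by ", 2L^bs$n_stages)
  P <- model$params
  S <- bs$n_stages
  epre <- paste0("enc.", modality)
  enc <- vector("list", S)
  h <- x
  for (i in seq_len(S)) {
    b1 <- block_fwd(h, getp(P, sprintf("%s.s%d.c1", epre, i)),
                    stride = if (i == 1L) 1L else 2L, k = bs$kernel)
    b2 <- block_fwd(b1$y, getp(P, sprintf("%s.s%d.c2", epre, i)), 1L, bs$kernel)
    enc[[i]] <- list(b1 = b1$cache, b2 = b2$cache, xin = h, out = b2$y)
    h <- b2$y
  }
  bo1 <- block_fwd(h, getp(P, "bott.c1"), 2L, bs$kernel)
  bo2 <- block_fwd(bo1$y, getp(P, "bott.c2"), 1L, bs$kernel)
  bott <- list(b1 = bo1$cache, b2 = bo2$cache, out = bo2$y)
  encproj <- NULL
  if (with_projections && bs$self_distillation) {
    encproj <- setNames(vector("list", S), as.character(seq_len(S)))
    for (i in seq_len(S))
      encproj[[as.character(i)]] <-
        head_fwd(enc[[i]]$out, getp(P, sprintf("%s.p%d", epre, i)))
  }
  groups <- list()
  dec_cache <- list()
  hs <- if (bs$deep_supervision) seq_len(S) else 1L
  for (gi in seq_along(spec$class_counts)) {
    g <- names(spec$class_counts)[gi]
    dpre <- paste0("dec.", g)
    d <- bott$out
    stg <- vector("list", S)
    heads <- list()
    for (j in rev(seq_len(S))) {
      up <- up2_fwd(d)
      cat_in <- concat_ch(up, enc[[j]]$out)
      b1 <- block_fwd(cat_in, getp(P, sprintf("%s.s%d.c1", dpre, j)), 1L, bs$kernel)
      b2 <- block_fwd(b1$y, getp(P, sprintf("%s.s%d.c2", dpre, j)), 1L, bs$kernel)
      d <- b2$y
      stg[[j]] <- list(b1 = b1$cache, b2 = b2$cache, up_ch = dim(up)[1],
                       cat_in_dim = dim(cat_in), out = d)
      if (j %in% hs)
        heads[[as.character(j)]] <- head_fwd(d, getp(P, sprintf("%s.h%d", dpre, j)))
    }
    groups[[g]] <- list(heads = heads)
    dec_cache[[g]] <- stg
  }
  out <- list(groups = groups, encproj = encproj)
  if (training)
    out$cache <- list(x = x, enc = enc, bott = bott, dec = dec_cache,
                      modality = modality)
  out
}

zeros_like <- function(a) array(0, dim(a))

acc_grad <- function(G, nm, val) {
  G[[nm]] <- if (is.null(G[[nm]])) val else G[[nm]] + val
  G
}

acc_block <- function(G, pre, bb) {
  G <- acc_grad(G, paste0(pre, ".W"), bb$dW)
  G <- acc_grad(G, paste0(pre, ".b"), bb$db)
  G <- acc_grad(G, paste0(pre, ".g"), bb$dg)
  acc_grad(G, paste0(pre, ".be"), bb$dbe)
}

#' Backward pass through the cascade
#'
#' Propagates head-score gradients (and optionally encoder-projection
#' gradients) back to every parameter touched by the forward pass: the
#' active modality's encoder, the shared bottleneck and all decoders.
#' Parameters of inactive encoders do not appear in the result.
#'
#' @param model A \code{magic_model}.
#' @param fw Result of \code{\link{magic_forward}} with \code{training=TRUE}.
#' @param dheads Per group, named list (by decoder depth) of gradients with
#'   respect to the head scores; NULL entries are skipped.
#' @param dencproj Optional per-stage gradients w.r.t. encoder projections.
#' @return Named flat list of parameter gradients.
#' @export
magic_backward <- function(model, fw, dheads, dencproj = NULL) {
  spec <- model$spec
  bs <- spec$backbone
  S <- bs$n_stages
  P <- model$params
  cache <- fw$cache
  if (is.null(cache)) stop("forward pass must be run with training=TRUE")
  modality <- cache$modality
  epre <- paste0("enc.", modality)
  G <- list()
  dskip <- lapply(seq_len(S), function(i) zeros_like(cache$enc[[i]]$out))
  dbott_out <- zeros_like(cache$bott$out)
  for (g in names(spec$class_counts)) {
    dpre <- paste0("dec.", g)
    stg <- cache$dec[[g]]
    dd_next <- NULL
    for (j in seq_len(S)) {
      dd <- zeros_like(stg[[j]]$out)
      dh <- dheads[[g]][[as.character(j)]]
      if (!is.null(dh)) {
        hp <- getp(P, sprintf("%s.h%d", dpre, j))
        hb <- head_bwd(dh, stg[[j]]$out, hp)
        dd <- dd + hb$dx
        G <- acc_grad(G, sprintf("%s.h%d.W", dpre, j), hb$dW)
        G <- acc_grad(G, sprintf("%s.h%d.b", dpre, j), hb$db)
      }
      if (!is.null(dd_next)) dd <- dd + dd_next
      b2 <- block_bwd(dd, getp(P, sprintf("%s.s%d.c2", dpre, j)), stg[[j]]$b2)
      G <- acc_block(G, sprintf("%s.s%d.c2", dpre, j), b2)
      b1 <- block_bwd(b2$dx, getp(P, sprintf("%s.s%d.c1", dpre, j)), stg[[j]]$b1)
      G <- acc_block(G, sprintf("%s.s%d.c1", dpre, j), b1)
      uch <- stg[[j]]$up_ch
      dcat <- b1$dx
      dskip[[j]] <- dskip[[j]] + dcat[uch + seq_len(dim(dcat)[1] - uch), , , , drop = FALSE]
      dd_next <- up2_bwd(dcat[seq_len(uch), , , , drop = FALSE])
    }
    dbott_out <- dbott_out + dd_next
  }
  b2 <- block_bwd(dbott_out, getp(P, "bott.c2"), cache$bott$b2)
  G <- acc_block(G, "bott.c2", b2)
  b1 <- block_bwd(b2$dx, getp(P, "bott.c1"), cache$bott$b1)
  G <- acc_block(G, "bott.c1", b1)
  denc_above <- b1$dx
  for (i in rev(seq_len(S))) {
    de <- dskip[[i]] + denc_above
    dp <- if (!is.null(dencproj)) dencproj[[as.character(i)]] else NULL
    if (!is.null(dp)) {
      pp <- getp(P, sprintf("%s.p%d", epre, i))
      pb <- head_bwd(dp, cache$enc[[i]]$out, pp)
      de <- de + pb$dx
      G <- acc_grad(G, sprintf("%s.p%d.W", epre, i), pb$dW)
      G <- acc_grad(G, sprintf("%s.p%d.b", epre, i), pb$db)
    }
    b2 <- block_bwd(de, getp(P, sprintf("%s.s%d.c2", epre, i)), cache$enc[[i]]$b2)
    G <- acc_block(G, sprintf("%s.s%d.c2", epre, i), b2)
    b1 <- block_bwd(b2$dx, getp(P, sprintf("%s.s%d.c1", epre, i)), cache$enc[[i]]$b1)
    G <- acc_block(G, sprintf("%s.s%d.c1", epre, i), b1)
    denc_above <- b1$dx
  }
  G
}

#' Exact trainable-parameter account
#'
#' Counts every trainable array of the model, broken down into the
#' components of the cascade: one count per encoder (including its
#' distillation projections), the shared bottleneck, one count per decoder
#' (convolutions), and the output heads.
#'
#' @param model A \code{magic_model}.
#' @return An object of class \code{parameter_account} with fields
#'   \code{encoders}, \code{bottleneck}, \code{decoders}, \code{heads},
#'   \code{total}.
#' @export
count_parameters <- function(model) {
  P <- model$params
  n <- vapply(P, length, numeric(1))
  nm <- names(P)
  enc <- sapply(model$spec$modalities, function(m)
    sum(n[startsWith(nm, paste0("enc.", m, "."))]))
  dec_conv <- sapply(names(model$spec$class_counts), function(g)
    sum(n[startsWith(nm, paste0("dec.", g, ".s"))]))
  heads <- sum(n[grepl("^dec\\.[^.]+\\.h[0-9]+\\.", nm)])
  bott <- sum(n[startsWith(nm, "bott.")])
  acc <- list(encoders = enc, bottleneck = bott, decoders = dec_conv,
              heads = heads,
              total = sum(n))
  stopifnot(acc$total == sum(enc) + bott + sum(dec_conv) + heads)
  structure(acc, class = "parameter_account")
}

#' @export
print.parameter_account <- function(x, ...) {
  cat("trainable parameters:\n")
  for (m in names(x$encoders))
    cat(sprintf("  encoder %-9s %12s\n", m, format(x$encoders[[m]], big.mark = ",")))
  cat(sprintf("  bottleneck        %12s\n", format(x$bottleneck, big.mark = ",")))
  for (g in names(x$decoders))
    cat(sprintf("  decoder %-9s %12s\n", g, format(x$decoders[[g]], big.mark = ",")))
  cat(sprintf("  heads             %12s\n", format(x$heads, big.mark = ",")))
  cat(sprintf("  total             %12s\n", format(x$total, big.mark = ",")))
  invisible(x)
}

#' Parameter reduction of the cascade versus unimodal models
#'
#' The efficiency headline of the cascade design: one model with
#' modality-specific encoders and group-specific decoders replaces one
#' full backbone per (modality, group) pair. Returns
#' \code{100 * (1 - cascade_total / sum(unimodal totals))}.
#'
#' @param cascade A \code{parameter_account} (or \code{magic_model}) of the
#'   cascade.
#' @param unimodal List of \code{parameter_account}s (or models), one per
#'   (modality, group) pair.
#' @return Percentage reduction.
#' @export
parameter_reduction <- function(cascade, unimodal) {
  tot <- function(a) {
    if (inherits(a, "magic_model")) a <- count_parameters(a)
    a$total
  }
  if (length(unimodal) == 0L) stop("need at least one unimodal model")
  100 * (1 - tot(cascade) / sum(vapply(unimodal, tot, numeric(1))))
}

#' Build the twelve unimodal comparator models
#'
#' One single-encoder, single-decoder backbone per (modality, group) pair,
#' on the identical backbone configuration as the cascade.
#'
#' @param spec A \code{\link{cascade_spec}}.
#' @param seed Initialisation seed.
#' @return List of \code{magic_model}s, one per (modality, group) pair.
#' @export
build_unimodal_models <- function(spec, seed = 42L) {
  out <- list()
  for (m in spec$modalities)
    for (g in names(spec$class_counts))
      out[[paste(m, g, sep = ".")]] <-
        build_backbone(spec$backbone, spec$class_counts[[g]],
                       modality = m, group = g, seed = seed)
  out
}
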