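# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env()

# one small phantom anatomy per seed, memoised
fixture_anatomy <- function(seed = 1L, grid = 32L) {
  key <- paste0("anat_", seed, "_", grid)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_anatomy(phantom_spec(grid = rep(grid, 3)),
                                            seed = seed)
  .fixture_env[[key]]
}

# a tiny two-group cascade for network-level tests
fixture_tiny_model <- function() {
  if (is.null(.fixture_env$tiny_model)) {
    bs <- backbone_spec(n_stages = 2L, base_width = 2L, width_cap = 8L,
                        distill_channels = 2L)
    spec <- cascade_spec(bs, modalities = c("A", "B"),
                         class_counts = c(G1 = 2L, G2 = 3L), catalog = NULL)
    .fixture_env$tiny_model <- build_cascade(spec, seed = 7L)
  }
  .fixture_env$tiny_model
}

# brute-force all-pairs surface-distance oracle (<= 16^3 grids)
oracle_surface_metrics <- function(pred, ref, spacing, tol_mm) {
  surf <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    keep <- logical(nrow(idx))
    d <- dim(m)
    for (i in seq_len(nrow(idx))) {
      v <- idx[i, ]
      for (a in 1:3) for (s in c(-1L, 1L)) {
        w <- v; w[a] <- w[a] + s
        if (w[a] < 1 || w[a] > d[a] || !m[w[1], w[2], w[3]]) keep[i] <- TRUE
      }
    }
    idx[keep, , drop = FALSE]
  }
  sa <- surf(pred); sb <- surf(ref)
  d1 <- vapply(seq_len(nrow(sa)), function(i)
    min(sqrt(((sb[, 1] - sa[i, 1]) * spacing[1])^2 +
               ((sb[, 2] - sa[i, 2]) * spacing[2])^2 +
               ((sb[, 3] - sa[i, 3]) * spacing[3])^2)), numeric(1))
  d2 <- vapply(seq_len(nrow(sb)), function(i)
    min(sqrt(((sa[, 1] - sb[i, 1]) * spacing[1])^2 +
               ((sa[, 2] - sb[i, 2]) * spacing[2])^2 +
               ((sa[, 3] - sb[i, 3]) * spacing[3])^2)), numeric(1))
  pool <- c(d1, d2)
  list(hd95 = unname(quantile(pool, 0.95, type = 7)),
       msd = mean(pool),
       sdice = (sum(d1 <= tol_mm + 1e-12) + sum(d2 <= tol_mm + 1e-12)) /
         length(pool))
}

# the desk-scale training surrogate: 32^3 phantoms, 3 modalities x
# (5 train / 2 val / 3 test), tiny backbone, 30 epochs x 8 iterations x
# batch 2, 24^3 patches on the 1.25 mm working grid; trained once per
# session and shared by the tests that probe it
fixture_surrogate <- function() {
  if (is.null(.fixture_env$surrogate)) {
    dd <- file.path(tempdir(), "surrogate_ds")
    man <- generate_dataset(dd, split = c(train = 5, val = 2, test = 3),
                            spec = phantom_spec(grid = rep(32L, 3)),
                            seed = 11)
    cfg <- train_config(epochs = 30, iterations_per_epoch = 8,
                        batch_size = 2, patch_size = 24,
                        target_spacing = 1.25, crop_margin_mm = 3,
                        seed = 11)
    model <- magic_train(man, cascade_spec(tiny_backbone_spec()), cfg,
                         verbose = FALSE)
    te <- man[man$split == "test", ]
    recs <- NULL
    preds <- list()
    for (i in seq_len(nrow(te))) {
      case <- magicseg:::load_case(te[i, ], cfg)
      probs <- sliding_window_predict(model, case$image, te$modality[i],
                                      patch_size = NULL)
      pred <- assemble_composite(probs, model$spec$catalog,
                                 case$image$spacing)
      refm <- lapply(names(case$group_maps), function(g)
        group_label_map(case$group_maps[[g]], g, model$spec$catalog,
                        case$image$spacing))
      names(refm) <- names(case$group_maps)
      ref <- encode_composite(refm, model$spec$catalog)
      recs <- rbind(recs, evaluate_case(pred, ref,
                                        paste0(te$modality[i], "_", i)))
      preds[[i]] <- pred
    }
    .fixture_env$surrogate <- list(model = model, manifest = man,
                                   config = cfg, records = recs,
                                   preds = preds)
  }
  .fixture_env$surrogate
}

# build a composite from one group's label maps plus empty others
composite_from_maps <- function(maps_by_group, dims, catalog = structure_catalog(),
                                spacing = c(1, 1, 1)) {
  gm <- list()
  for (g in names(catalog$groups)) {
    lab <- if (g %in% names(maps_by_group)) maps_by_group[[g]]
           else array(0L, dims)
    gm[[g]] <- group_label_map(lab, g, catalog, spacing)
  }
  encode_composite(gm, catalog)
}
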