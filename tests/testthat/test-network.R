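test_that("backbone output shapes honour the contract", {
  bs <- backbone_spec(n_stages = 2L, base_width = 2L, width_cap = 8L,
                      deep_supervision = FALSE, self_distillation = FALSE)
  model <- build_backbone(bs, n_classes = 3L, seed = 1)
  fw <- magic_forward(model, array(0, c(16, 16, 16)), "M1")
  expect_named(fw$groups$G1$heads, "1")
  expect_identical(dim(fw$groups$G1$heads[["1"]]), c(3L, 16L, 16L, 16L))
})

test_that("deep supervision emits one head per decoder depth at halved resolutions", {
  bs <- backbone_spec(n_stages = 3L, base_width = 2L, width_cap = 8L,
                      deep_supervision = TRUE, self_distillation = FALSE)
  model <- build_backbone(bs, n_classes = 2L, seed = 1)
  fw <- magic_forward(model, array(0, c(16, 16, 16)), "M1")
  heads <- fw$groups$G1$heads
  expect_setequal(names(heads), c("1", "2", "3"))
  expect_identical(dim(heads[["1"]])[2:4], c(16L, 16L, 16L))
  expect_identical(dim(heads[["2"]])[2:4], c(8L, 8L, 8L))
  expect_identical(dim(heads[["3"]])[2:4], c(4L, 4L, 4L))
})

test_that("parameter count matches a hand-computed layer-by-layer sum", {
  # 2 stages, widths 3 and 6, bottleneck 12, kernel 3, classes 2, no heads
  # beyond the final one, no distillation projections
  bs <- backbone_spec(n_stages = 2L, base_width = 3L, width_cap = 12L,
                      deep_supervision = FALSE, self_distillation = FALSE)
  model <- build_backbone(bs, n_classes = 2L, seed = 1)
  conv_n <- function(cout, cin) cout * cin * 27 + cout + 2 * cout  # W+b+IN
  hand <- conv_n(3, 1) + conv_n(3, 3) +      # encoder stage 1
    conv_n(6, 3) + conv_n(6, 6) +            # encoder stage 2
    conv_n(12, 6) + conv_n(12, 12) +         # bottleneck
    conv_n(6, 12 + 6) + conv_n(6, 6) +       # decoder stage 2
    conv_n(3, 6 + 3) + conv_n(3, 3) +        # decoder stage 1
    (2 * 3 + 2)                              # 1x1x1 head
  acc <- count_parameters(model)
  expect_identical(acc$total, hand)
  # accounting identity and build determinism
  expect_identical(acc$total,
                   sum(unlist(acc$encoders)) + acc$bottleneck +
                     sum(unlist(acc$decoders)) + acc$heads)
  model2 <- build_backbone(bs, n_classes = 2L, seed = 1)
  expect_identical(count_parameters(model2), acc)
})

test_that("the cascade has one encoder per modality, one shared bottleneck, one decoder per group", {
  spec <- cascade_spec(tiny_backbone_spec())
  model <- build_cascade(spec, seed = 1)
  acc <- count_parameters(model)
  expect_length(acc$encoders, 3L)
  expect_length(acc$decoders, 4L)
  nm <- names(model$params)
  expect_identical(sum(startsWith(nm, "bott.")), 8L)  # 2 conv blocks
  # class counts (2, 10, 9, 3) appear as head output channels
  fw <- magic_forward(model, array(0, c(32, 32, 32)), "SIM_CT")
  expect_identical(vapply(fw$groups, function(g) dim(g$heads[["1"]])[1],
                          integer(1)),
                   c(A = 2L, B = 10L, C = 9L, D = 3L))
})

test_that("a 1-modality 1-group cascade is identical to the plain backbone", {
  bs <- backbone_spec(n_stages = 2L, base_width = 2L, width_cap = 8L,
                      distill_channels = 2L)
  backbone <- build_backbone(bs, n_classes = 4L, modality = "MR_LINAC",
                             group = "B", seed = 11)
  casc <- build_cascade(cascade_spec(bs, modalities = "MR_LINAC",
                                     class_counts = c(B = 4L), catalog = NULL),
                        seed = 11)
  expect_identical(backbone$params, casc$params)
  x <- array(rnorm(8^3), c(8, 8, 8))
  f1 <- magic_forward(backbone, x, "MR_LINAC")
  f2 <- magic_forward(casc, x, "MR_LINAC")
  expect_identical(f1$groups$B$heads, f2$groups$B$heads)
  expect_identical(count_parameters(backbone)$total,
                   count_parameters(casc)$total)
})

test_that("forward is deterministic and rejects unknown modalities", {
  model <- fixture_tiny_model()
  x <- array(rnorm(8^3), c(8, 8, 8))
  f1 <- magic_forward(model, x, "A")
  f2 <- magic_forward(model, x, "A")
  expect_identical(f1$groups, f2$groups)
  expect_error(magic_forward(model, x, "Z"), "unknown modality")
  expect_error(magic_forward(model, array(0, c(9, 8, 8)), "A"), "divisible")
})

test_that("gradients isolate the active encoder and flow to shared components", {
  model <- fixture_tiny_model()
  set.seed(3)
  x <- array(rnorm(8^3), c(8, 8, 8))
  labs <- list(G1 = array(sample(0:1, 512, TRUE), c(8, 8, 8)),
               G2 = array(sample(0:2, 512, TRUE), c(8, 8, 8)))
  fw <- magic_forward(model, x, "A", training = TRUE)
  tl <- training_loss(fw, labs, c(1, 1, 1))
  G <- magic_backward(model, fw, tl$dheads, tl$dencproj)
  nm <- names(G)
  expect_false(any(startsWith(nm, "enc.B.")))
  expect_true(any(abs(unlist(G[grep("^enc\\.A\\.", nm)])) > 0))
  expect_true(any(abs(unlist(G[grep("^bott\\.", nm)])) > 0))
  for (g in c("G1", "G2"))
    expect_true(any(abs(unlist(G[grep(paste0("^dec\\.", g, "\\."), nm)])) > 0))
})

test_that("a step on one modality leaves other encoders untouched but moves shared parts", {
  bs <- backbone_spec(n_stages = 2L, base_width = 2L, width_cap = 8L,
                      distill_channels = 2L)
  spec <- cascade_spec(bs, catalog = structure_catalog())
  model <- build_cascade(spec, seed = 2)
  cfg <- train_config(epochs = 2, patch_size = 8, seed = 1)
  opt <- optimizer_init(model)
  set.seed(5)
  labs <- lapply(group_class_counts(structure_catalog()), function(C)
    array(sample(0:(C - 1L), 512, TRUE), c(8, 8, 8)))
  batch <- list(list(image = array(rnorm(512), c(8, 8, 8)),
                     labels = labs, modality = "SIM_CT"))
  st <- train_step(model, batch, opt, cfg)
  before <- model$params
  after <- st$model$params
  pick <- function(p, re) unlist(p[grep(re, names(p))])
  expect_identical(pick(after, "^enc\\.MR_LINAC\\."),
                   pick(before, "^enc\\.MR_LINAC\\."))
  expect_identical(pick(after, "^enc\\.CCTA\\."), pick(before, "^enc\\.CCTA\\."))
  expect_false(isTRUE(all.equal(pick(after, "^enc\\.SIM_CT\\."),
                                pick(before, "^enc\\.SIM_CT\\."))))
  expect_false(isTRUE(all.equal(pick(after, "^bott\\."), pick(before, "^bott\\."))))
  for (g in names(spec$class_counts))
    expect_false(isTRUE(all.equal(pick(after, paste0("^dec\\.", g, "\\.")),
                                  pick(before, paste0("^dec\\.", g, "\\.")))))
  # the shared bottleneck seen from another modality changed too
  x <- array(rnorm(512), c(8, 8, 8))
  f_before <- magic_forward(model, x, "MR_LINAC")
  f_after <- magic_forward(st$model, x, "MR_LINAC")
  expect_false(identical(f_before$groups$A$heads[["1"]],
                         f_after$groups$A$heads[["1"]]))
  # optimizer state covers every trainable parameter exactly once
  expect_setequal(names(st$opt_state$t), names(model$params))
})

test_that("parameter reduction follows the closed form and exceeds 70% for the default cascade", {
  # closed form: E = D, B = 0.2 E over 3 modalities x 4 groups
  mk <- function(total) structure(list(total = total),
                                  class = "parameter_account")
  E <- 1e6
  casc <- mk(3 * E + 0.2 * E + 4 * E)
  uni <- replicate(12, mk(2.2 * E), simplify = FALSE)
  expect_equal(parameter_reduction(casc, uni), 100 * (1 - 7.2 / 26.4),
               tolerance = 1e-12)
  # degenerate single-pair comparison: no reduction
  bs <- backbone_spec(n_stages = 2L, base_width = 2L, width_cap = 8L)
  solo <- build_backbone(bs, 2L, seed = 1)
  expect_equal(parameter_reduction(solo, list(solo)), 0)
  expect_error(parameter_reduction(solo, list()), "at least one")
  # a tiny symmetric cascade already clears 70%
  spec <- cascade_spec(tiny_backbone_spec())
  red <- parameter_reduction(build_cascade(spec, 1),
                             build_unimodal_models(spec, 1))
  expect_gt(red, 70)
})
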