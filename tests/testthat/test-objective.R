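onehot_arr <- function(labels, C) {
  d <- dim(labels)
  r <- array(0, c(C, d))
  for (c in 0:(C - 1)) r[c + 1, , , ] <- (labels == c) + 0
  r
}

test_that("Dice loss: perfect, complementary and hand-summed cases", {
  labs <- array(c(rep(0L, 4), rep(1L, 4)), c(2, 2, 2))
  ref <- onehot_arr(labs, 2L)
  expect_lt(dice_loss(ref, ref), 1e-4)
  expect_gt(dice_loss(onehot_arr(1L - labs, 2L), ref), 0.999)
  # uniform 0.5 probabilities vs 4-of-8 mask: dice = (2*2+e)/(4+4+e)
  p <- array(0.5, c(2, 2, 2, 2))
  eps <- 1e-5
  expect_equal(dice_loss(p, ref, eps), 1 - (2 * 2 + eps) / (8 + eps),
               tolerance = 1e-12)
  expect_error(dice_loss(p, array(0, c(2, 2, 2, 1))), "shape")
})

test_that("signed distance is exact, signed, and spacing-aware", {
  m <- array(FALSE, c(7, 7, 7)); m[4, 4, 4] <- TRUE
  sdf <- signed_distance(m, c(1, 1, 1))
  expect_equal(sdf[4, 4, 4], 0)           # single voxel is its own boundary
  expect_equal(sdf[5, 4, 4], 1)
  expect_equal(sdf[5, 5, 4], sqrt(2))
  expect_equal(sdf[5, 5, 5], sqrt(3))
  sdf3 <- signed_distance(m, c(1, 1, 3))
  expect_equal(sdf3[4, 4, 5], 3)          # axial neighbour scaled by spacing
  # interior is negative, boundary zero, outside positive
  ball <- array(FALSE, c(9, 9, 9))
  for (i in 1:9) for (j in 1:9) for (k in 1:9)
    if ((i - 5)^2 + (j - 5)^2 + (k - 5)^2 <= 6) ball[i, j, k] <- TRUE
  s <- signed_distance(ball)
  expect_lt(s[5, 5, 5], 0)
  expect_gt(s[1, 1, 1], 0)
  b <- ball & !magicseg:::border_voxels(ball)
  # brute-force check of magnitudes against all-pairs distances to border
  border_idx <- which(magicseg:::border_voxels(ball), arr.ind = TRUE)
  for (v in list(c(5, 5, 5), c(1, 1, 1), c(5, 5, 8))) {
    bf <- min(sqrt(colSums((t(border_idx) - v)^2)))
    expect_equal(abs(s[v[1], v[2], v[3]]), bf, tolerance = 1e-9)
  }
  # empty mask: all-positive field capped at the grid diameter
  e <- signed_distance(array(FALSE, c(4, 4, 4)), c(1, 1, 1))
  expect_true(all(e == sqrt(48)))
})

test_that("boundary loss is minimised by the reference among binary predictions", {
  # 3x3x1 toy, exhaustive enumeration of all 2^9 binary predictions
  ref <- array(FALSE, c(3, 3, 1)); ref[2, 2, 1] <- TRUE; ref[1, 2, 1] <- TRUE
  sdf_fg <- signed_distance(ref, c(1, 1, 1))
  sdf <- array(0, c(2, 3, 3, 1)); sdf[2, , , ] <- sdf_fg
  loss_of <- function(bits) {
    fg <- array(bits, c(3, 3, 1))
    p <- array(0, c(2, 3, 3, 1)); p[1, , , ] <- 1 - fg; p[2, , , ] <- fg
    boundary_loss(p, sdf)
  }
  ref_loss <- loss_of(as.numeric(ref))
  losses <- vapply(0:511, function(code)
    loss_of(as.numeric(intToBits(code)[1:9])), numeric(1))
  expect_equal(min(losses), ref_loss, tolerance = 1e-12)
  # all-background prediction scores 0; any voxel outside raises the loss
  expect_equal(loss_of(rep(0, 9)), 0)
  near <- rep(0, 9); near[5] <- 1          # on the reference (negative)
  far <- rep(0, 9); far[9] <- 1            # far corner (positive)
  expect_lt(loss_of(near), loss_of(far))
})

test_that("cross-entropy matches closed forms", {
  d <- c(2L, 2L, 2L)
  labs <- array(0L, d)
  sure <- array(0, c(3, d)); sure[1, , , ] <- 50
  expect_lt(cross_entropy(sure, labs), 1e-10)
  unif <- array(1, c(3, d))
  expect_equal(cross_entropy(unif, labs), log(3), tolerance = 1e-12)
  # hand toy: probabilities (0.7, 0.2, 0.1), true class 0
  z <- array(log(c(0.7, 0.2, 0.1)), c(3, 1, 1, 1))
  expect_equal(cross_entropy(z, array(0L, c(1, 1, 1))), -log(0.7),
               tolerance = 1e-12)
  expect_error(cross_entropy(unif, array(3L, d)), "class range")
})

test_that("primary loss weights components equally and is group-order invariant", {
  model <- fixture_tiny_model()
  set.seed(4)
  x <- array(rnorm(8^3), c(8, 8, 8))
  labs <- list(G1 = array(sample(0:1, 512, TRUE), c(8, 8, 8)),
               G2 = array(sample(0:2, 512, TRUE), c(8, 8, 8)))
  fw <- magic_forward(model, x, "A")
  scores <- lapply(fw$groups, `[[`, "heads")
  pl <- primary_loss(scores, labs, c(1, 1, 1))
  expect_equal(pl$total, (pl$dice + pl$boundary + pl$cross_entropy) / 3,
               tolerance = 1e-12)
  pl2 <- primary_loss(scores[c("G2", "G1")], labs, c(1, 1, 1))
  expect_equal(pl2$total, pl$total, tolerance = 1e-12)
  expect_error(primary_loss(scores["G1"], labs["G1"], c(1, 1, 1)), NA)
  expect_error(primary_loss(scores, labs["G1"], c(1, 1, 1)), "missing group")
})

test_that("distillation loss: zero for identical heads, closed-form KL, nonnegative", {
  d <- c(4L, 4L, 4L)
  z <- array(rnorm(2 * 64), c(2, d))
  z2 <- z[, seq(1, 4, 2), seq(1, 4, 2), seq(1, 4, 2), drop = FALSE]
  heads <- list(G = list("1" = z, "2" = z2))
  # the student equals the subsampled teacher -> zero divergence
  expect_equal(distillation_loss(heads, temperature = 3)$value, 0,
               tolerance = 1e-12)
  # teacher uniform vs student (p, 1-p) at temperature 1:
  # KL = sum 0.5 * log(0.5 / s_c)
  zt <- array(0, c(2, 2, 2, 2))
  p <- 0.9
  zs <- array(log(c(p, 1 - p)), c(2, 1, 1, 1))
  heads2 <- list(G = list("1" = zt, "2" = zs))
  want <- 0.5 * log(0.5 / p) + 0.5 * log(0.5 / (1 - p))
  expect_equal(distillation_loss(heads2, temperature = 1)$value, want,
               tolerance = 1e-12)
  set.seed(9)
  for (i in 1:20) {
    hz <- list(G = list("1" = array(rnorm(2 * 64), c(2, d)),
                        "2" = array(rnorm(2 * 8), c(2, 2, 2, 2))))
    expect_gte(distillation_loss(hz, temperature = 3)$value, 0)
  }
  expect_error(distillation_loss(list(G = list("1" = z))), "at least two")
})

test_that("loss report totals are exact sums of their parts (no hidden reweighting)", {
  model <- fixture_tiny_model()
  set.seed(5)
  x <- array(rnorm(8^3), c(8, 8, 8))
  labs <- list(G1 = array(sample(0:1, 512, TRUE), c(8, 8, 8)),
               G2 = array(sample(0:2, 512, TRUE), c(8, 8, 8)))
  fw <- magic_forward(model, x, "A", training = TRUE)
  tl <- training_loss(fw, labs, c(1, 1, 1), distill = TRUE)
  r <- tl$report
  expect_equal(r$total,
               (r$dice + r$boundary + r$cross_entropy) / 3 + r$distillation,
               tolerance = 1e-12)
  expect_true(is.finite(r$total))
})
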