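test_that("volume construction validates shape and spacing", {
  expect_error(as_volume(matrix(0, 4, 4), c(1, 1, 1)), "3-D")
  expect_error(as_volume(array(0, c(4, 4, 4)), c(1, -1, 1)), "spacing")
  v <- as_volume(array(0, c(4, 4, 4)), c(1.5, 1.5, 1.5))
  expect_equal(v$spacing, c(1.5, 1.5, 1.5))
})

test_that("NIfTI write/read round-trips data, spacing and origin", {
  set.seed(4)
  v <- as_volume(array(rnorm(64 * 64 * 8), c(64, 64, 8)),
                 spacing = c(1.5, 1.5, 1.5), origin = c(3, -2, 10),
                 modality = "SIM_CT")
  tf <- tempfile(fileext = ".nii.gz")
  write_volume(v, tf)
  r <- read_volume(tf, "SIM_CT")
  expect_equal(r$data, v$data, tolerance = 1e-6)
  expect_equal(r$spacing, c(1.5, 1.5, 1.5), tolerance = 1e-6)
  expect_equal(r$origin, v$origin, tolerance = 1e-4)
  expect_error(read_volume(tempfile(), "SIM_CT"), "no such file")
})

test_that("reading a non-3-D image is rejected", {
  tf <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(rnorm(16), 4, 4)), tf)
  expect_error(read_volume(tf, "SIM_CT"), "3-D")
})

test_that("composite encode/decode round-trips phantom anatomies", {
  catalog <- structure_catalog()
  for (seed in 1:5) {
    anat <- fixture_anatomy(seed)
    for (g in names(catalog$groups)) {
      gm <- decode_group(anat, g)
      # counting oracle: label histogram equals per-structure voxel counts
      for (k in seq_along(catalog$groups[[g]])) {
        expect_identical(sum(gm$labels == k),
                         sum(anat$masks[[catalog$groups[[g]][k]]]))
      }
    }
    rebuilt <- encode_composite(setNames(
      lapply(names(catalog$groups), function(g) decode_group(anat, g)),
      names(catalog$groups)), catalog)
    expect_identical(rebuilt$masks, anat$masks)
  }
})

test_that("cross-group overlap is preserved; within-group overlap rejected", {
  catalog <- structure_catalog()
  dims <- c(6L, 6L, 6L)
  b <- array(0L, dims); b[3, 3, 3] <- 1L  # LA
  c3 <- array(0L, dims); c3[3, 3, 3] <- 7L  # V-MV, same voxel
  comp <- composite_from_maps(list(B = b, C = c3), dims)
  expect_true(comp$masks$LA[3, 3, 3] && comp$masks$`V-MV`[3, 3, 3])
  # all-background -> 20 empty masks
  empty <- composite_from_maps(list(), dims)
  expect_true(all(vapply(empty$masks, function(m) !any(m), logical(1))))
  # two group-D masks on one voxel violate the group invariant
  m <- empty$masks
  m[["N-SA"]][2, 2, 2] <- TRUE
  m[["N-AV"]][2, 2, 2] <- TRUE
  expect_error(composite_segmentation(m, c(1, 1, 1), catalog),
               "within-group overlap")
})

test_that("composite NIfTI + sidecar round-trips losslessly", {
  anat <- fixture_anatomy(2)
  tf <- tempfile(fileext = ".nii.gz")
  write_composite(anat, tf)
  r <- read_composite(tf)
  expect_identical(r$masks, anat$masks)
  expect_equal(r$spacing, anat$spacing)
})

test_that("manifest validation enforces modality, splits and label rules", {
  # per-modality 25 train / 5 val / 10 test
  df <- do.call(rbind, lapply(magic_modalities(), function(m)
    data.frame(image = sprintf("%s_%02d.nii.gz", m, 1:40),
               labels = sprintf("%s_%02d_lab.nii.gz", m, 1:40),
               modality = m,
               split = c(rep("train", 25), rep("val", 5), rep("test", 10)),
               provenance = "manual", stringsAsFactors = FALSE)))
  man <- dataset_manifest(df)
  expect_identical(nrow(man), 120L)
  counts <- table(man$modality, man$split)
  for (m in magic_modalities()) {
    expect_equal(unname(counts[m, "train"]), 25)
    expect_equal(unname(counts[m, "val"]), 5)
    expect_equal(unname(counts[m, "test"]), 10)
  }
  tf <- tempfile(fileext = ".csv")
  save_manifest(man, tf)
  man2 <- load_manifest(tf)
  expect_identical(as.data.frame(man), as.data.frame(man2))
  bad <- df; bad$modality[1] <- "PET"
  expect_error(dataset_manifest(bad), "unknown modality")
  bad2 <- df; bad2$labels[1] <- ""
  expect_error(dataset_manifest(bad2), "labels path")
  bad3 <- df; bad3$provenance[30] <- "pseudo"; bad3$split[30] <- "val"
  expect_error(dataset_manifest(bad3), "pseudo")
})

test_that("cascade and train configs round-trip through YAML", {
  spec <- cascade_spec(tiny_backbone_spec())
  tf <- tempfile(fileext = ".yaml")
  write_cascade_config(spec, tf)
  spec2 <- read_cascade_config(tf)
  expect_equal(spec2$class_counts, spec$class_counts)
  expect_equal(spec2$modalities, spec$modalities)
  expect_equal(spec2$backbone, spec$backbone)
  cfg <- train_config(epochs = 30, patch_size = 32)
  tf2 <- tempfile(fileext = ".yaml")
  write_train_config(cfg, tf2)
  expect_equal(read_train_config(tf2), cfg)
})
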