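test_that("every phantom seed yields 20 non-empty masks with the required overlap structure", {
  catalog <- structure_catalog()
  for (seed in 1:5) {
    anat <- fixture_anatomy(seed)
    expect_length(anat$masks, 20L)
    expect_true(all(vapply(anat$masks, any, logical(1))))
    # at least one voxel where a valve and a chamber or vessel coincide
    valves <- Reduce(`|`, anat$masks[c("V-AV", "V-PV", "V-MV", "V-TV")])
    bgroup <- Reduce(`|`, anat$masks[catalog$groups$B])
    expect_gt(sum(valves & bgroup), 0)
    # coronary arteries lie on the heart surface: cross-group overlap with WH
    cas <- Reduce(`|`, anat$masks[c("RCA", "LMCA", "LADA", "LCFX")])
    expect_gt(sum(cas & anat$masks$WH), 0)
  }
})

test_that("within-group masks are pairwise disjoint across seeds", {
  catalog <- structure_catalog()
  for (seed in 1:20) {
    anat <- fixture_anatomy(seed)
    for (g in names(catalog$groups)) {
      nm <- catalog$groups[[g]]
      if (length(nm) < 2) next
      counts <- Reduce(`+`, lapply(anat$masks[nm], function(m) m + 0L))
      expect_identical(sum(counts > 1L), 0L)
    }
  }
})

test_that("rendering is deterministic and respects modality intensity scales", {
  spec <- phantom_spec(grid = rep(32L, 3))
  anat <- fixture_anatomy(1)
  v1 <- render_modality(anat, "SIM_CT", spec, seed = 9)
  v2 <- render_modality(anat, "SIM_CT", spec, seed = 9)
  expect_identical(v1$data, v2$data)
  expect_equal(v1$spacing, spec$native_spacing$SIM_CT)
  # CT-like scales span beyond the [-250, 550] HU window on every seed
  for (seed in 1:5) {
    a <- fixture_anatomy(seed)
    for (m in c("SIM_CT", "CCTA")) {
      v <- render_modality(a, m, spec, seed = seed)
      expect_lt(min(v$data), -250)
      expect_gt(max(v$data), 550)
    }
  }
  expect_error(render_modality(anat, "PET", spec), "unregistered")
})

test_that("noise-free unsmoothed rendering is the intensity table lookup", {
  spec <- phantom_spec(grid = rep(24L, 3),
                       native_spacing = list(SIM_CT = c(1, 1, 1)),
                       noise_sd = c(SIM_CT = 0), smooth_sd = 0)
  anat <- generate_anatomy(spec, seed = 3)
  v <- render_modality(anat, "SIM_CT", spec, seed = 1)
  tab <- spec$intensity$SIM_CT
  expect_true(all(v$data %in% tab))
  # background voxels carry the background value
  fg <- Reduce(`|`, anat$masks)
  expect_true(all(v$data[!fg] == tab[["background"]]))
  # the smallest structure wins at overlapped voxels
  sizes <- vapply(anat$masks, sum, numeric(1))
  ow <- anat$masks$WH & anat$masks$RCA  # RCA is far smaller than WH
  expect_true(all(v$data[ow] == tab[["RCA"]]))
})

test_that("generate_dataset writes a valid, reproducible dataset", {
  spec <- phantom_spec(grid = rep(24L, 3))
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  m1 <- generate_dataset(d1, split = c(train = 1, val = 1, test = 0,
                                       unlabeled = 1),
                         modalities = c("SIM_CT", "MR_LINAC"),
                         spec = spec, seed = 5)
  m2 <- generate_dataset(d2, split = c(train = 1, val = 1, test = 0,
                                       unlabeled = 1),
                         modalities = c("SIM_CT", "MR_LINAC"),
                         spec = spec, seed = 5)
  expect_identical(nrow(m1), 6L)
  expect_identical(m1[c("modality", "split", "provenance")],
                   m2[c("modality", "split", "provenance")])
  # equal seeds give identical volumes
  v1 <- read_volume(m1$image[1], m1$modality[1])
  v2 <- read_volume(m2$image[1], m2$modality[1])
  expect_identical(v1$data, v2$data)
  # written composites satisfy all composite invariants on load
  lab <- m1$labels[nzchar(m1$labels)][1]
  expect_s3_class(read_composite(lab), "composite_segmentation")
  expect_error(load_manifest(file.path(d1, "manifest.csv"),
                             check_files = TRUE), NA)
})
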