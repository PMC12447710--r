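# Seeded generator of multi-modality cardiac-like phantoms. The geometry is
# schematic, not anatomical: what matters is that every group exhibits the
# structural pathology the pipeline must handle — cross-group overlap at
# every case (arteries on the heart surface, valves bridging chambers),
# within-group disjointness, thin tubular structures for centerline metrics,
# and modality-specific intensity scales and native anisotropic spacings.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  expr
}

#' Phantom specification
#'
#' Geometry is parameterised in fractions of the grid extent so one spec
#' scales from desk-size (32 voxels) to larger grids. The anatomy lives on
#' an isotropic reference grid; each modality is rendered at its own native
#' spacing with its own intensity table and noise, so preprocessing
#' (windowing, resampling) is exercised. CT-like tables are in
#' Hounsfield-like units spanning beyond the [-250, 550] window; MR-like
#' values are arbitrary positive intensities.
#'
#' @param grid Reference grid shape (isotropic, spacing 1 mm).
#' @param native_spacing Per-modality native voxel spacing (mm).
#' @param intensity Per-modality named intensity tables (one value per
#'   structure plus \code{background}).
#' @param noise_sd Per-modality additive Gaussian noise scale.
#' @param smooth_sd Gaussian smoothing (voxels) applied before noise.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid = c(64L, 64L, 64L),
                         native_spacing = list(SIM_CT = c(1.0, 1.0, 2.5),
                                               MR_LINAC = c(1.5, 1.5, 3.0),
                                               CCTA = c(0.6, 0.6, 0.6)),
                         intensity = NULL, noise_sd = NULL, smooth_sd = 0.7) {
  nm <- catalog_structures(structure_catalog())
  mk_tab <- function(...) {
    v <- c(...)
    stopifnot(all(c("background", nm) %in% names(v)))
    v
  }
  # per-structure values mimic differential contrast enhancement (left
  # heart brighter than right on CCTA first-pass, vessel opacification
  # varying with distance from injection), so structure identity is
  # inferable from appearance and not only from laterality
  if (is.null(intensity))
    intensity <- list(
      SIM_CT = mk_tab(background = -900, WH = 60,
                      LA = 20, RA = 45, LV = 90, RV = 120,
                      AA = 1000, SVC = 550, IVC = 350, PA = 800, PVs = 450,
                      RCA = 380, LMCA = 420, LADA = 460, LCFX = 340,
                      `V-AV` = 120, `V-PV` = 145, `V-MV` = 165, `V-TV` = 185,
                      `N-SA` = 95, `N-AV` = 105),
      MR_LINAC = mk_tab(background = 15, WH = 120,
                        LA = 230, RA = 200, LV = 260, RV = 180,
                        AA = 160, SVC = 190, IVC = 215, PA = 175, PVs = 150,
                        RCA = 80, LMCA = 95, LADA = 105, LCFX = 70,
                        `V-AV` = 150, `V-PV` = 158, `V-MV` = 166, `V-TV` = 174,
                        `N-SA` = 108, `N-AV` = 114),
      CCTA = mk_tab(background = -900, WH = 70,
                    LA = 420, RA = 150, LV = 480, RV = 190,
                    AA = 1000, SVC = 300, IVC = 250, PA = 350, PVs = 520,
                    RCA = 650, LMCA = 720, LADA = 800, LCFX = 600,
                    `V-AV` = 150, `V-PV` = 165, `V-MV` = 180, `V-TV` = 195,
                    `N-SA` = 95, `N-AV` = 105))
  if (is.null(noise_sd))
    noise_sd <- c(SIM_CT = 20, MR_LINAC = 8, CCTA = 25)
  structure(list(grid = as.integer(grid), native_spacing = native_spacing,
                 intensity = intensity, noise_sd = noise_sd,
                 smooth_sd = smooth_sd),
            class = "phantom_spec")
}

# voxel-centre coordinates in unit-cube fractions of the grid extent
phantom_coords <- function(grid) {
  list(x = (seq_len(grid[1]) - 0.5) / grid[1],
       y = (seq_len(grid[2]) - 0.5) / grid[2],
       z = (seq_len(grid[3]) - 0.5) / grid[3])
}

ellipsoid_mask <- function(co, centre, radii) {
  dx2 <- ((co$x - centre[1]) / radii[1])^2
  dy2 <- ((co$y - centre[2]) / radii[2])^2
  dz2 <- ((co$z - centre[3]) / radii[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

# capsule along a polyline: stamp balls at dense samples
tube_mask <- function(grid, pts, radius) {
  m <- array(FALSE, grid)
  rvox <- max(radius * max(grid), 1.05)
  for (i in seq_len(nrow(pts))) {
    c_vox <- pts[i, ] * grid + 0.5
    lo <- pmax(1L, floor(c_vox - rvox))
    hi <- pmin(grid, ceiling(c_vox + rvox))
    if (any(lo > hi)) next
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    d2 <- outer(outer((xs - c_vox[1])^2, (ys - c_vox[2])^2, "+"),
                (zs - c_vox[3])^2, "+")
    m[xs, ys, zs] <- m[xs, ys, zs] | (d2 <= rvox^2)
  }
  m
}

disk_mask <- function(co, grid, centre, normal, radius, thickness) {
  normal <- normal / sqrt(sum(normal^2))
  X <- outer(outer(co$x - centre[1], rep(0, grid[2]), "+"), rep(0, grid[3]), "+")
  Y <- outer(outer(rep(0, grid[1]), co$y - centre[2], "+"), rep(0, grid[3]), "+")
  Z <- outer(outer(rep(0, grid[1]), rep(0, grid[2]), "+"), co$z - centre[3], "+")
  ax <- X * normal[1] + Y * normal[2] + Z * normal[3]
  rad2 <- (X - ax * normal[1])^2 + (Y - ax * normal[2])^2 + (Z - ax * normal[3])^2
  # enforce at least one-voxel thickness and radius on the reference grid
  th <- max(thickness, 1.1 / max(grid))
  rr <- max(radius, 1.1 / max(grid))
  abs(ax) <= th / 2 & rad2 <= rr^2
}

arc_points <- function(centre, radii, lambda_deg, phi_deg, n = 80) {
  lam <- seq(lambda_deg[1], lambda_deg[2], length.out = n) * pi / 180
  phi <- seq(phi_deg[1], phi_deg[2], length.out = n) * pi / 180
  cbind(centre[1] + radii[1] * sin(phi) * cos(lam),
        centre[2] + radii[2] * sin(phi) * sin(lam),
        centre[3] + radii[3] * cos(phi))
}

phantom_geometry <- function(spec, jitter) {
  grid <- spec$grid
  co <- phantom_coords(grid)
  c0 <- c(0.5, 0.5, 0.48) + jitter$c0
  sc <- jitter$scale
  wh_r <- c(0.34, 0.32, 0.30) * sc
  j <- function(nm) jitter$st[[nm]]
  masks <- list()
  masks$WH <- ellipsoid_mask(co, c0, wh_r)
  ch <- list(
    LA = list(c = c(-0.13, -0.13, 0.05), r = c(0.10, 0.10, 0.09)),
    RA = list(c = c(0.13, -0.13, 0.05), r = c(0.10, 0.10, 0.09)),
    LV = list(c = c(-0.13, 0.10, -0.08), r = c(0.115, 0.105, 0.105)),
    RV = list(c = c(0.13, 0.10, -0.08), r = c(0.105, 0.105, 0.105)))
  for (nm in names(ch))
    masks[[nm]] <- ellipsoid_mask(co, c0 + ch[[nm]]$c * sc + j(nm),
                                  ch[[nm]]$r * sc)
  seg <- function(a, b, n = 60) cbind(seq(a[1], b[1], length.out = n),
                                      seq(a[2], b[2], length.out = n),
                                      seq(a[3], b[3], length.out = n))
  vr <- 0.042 * sc
  ves <- list(
    AA = seg(c0 + c(-0.06, -0.02, 0.14) * sc, c(c0[1] - 0.06 * sc, c0[2] - 0.02 * sc, 0.97)),
    SVC = seg(c0 + c(0.15, -0.05, 0.20) * sc, c(c0[1] + 0.15 * sc, c0[2] - 0.05 * sc, 0.97)),
    IVC = seg(c0 + c(0.20, 0.00, -0.23) * sc, c(c0[1] + 0.20 * sc, c0[2], 0.03)),
    PA = seg(c0 + c(0.04, 0.12, 0.15) * sc, c(c0[1] + 0.04 * sc, c0[2] + 0.12 * sc, 0.97)),
    PVs = seg(c0 + c(-0.26, -0.24, 0.00) * sc, c(0.03, c0[2] - 0.24 * sc, c0[3])))
  for (nm in names(ves))
    masks[[nm]] <- tube_mask(grid, sweep(ves[[nm]], 2, c(j(nm), 0)[1:3], "+"), vr)
  ar <- 0.022 * sc
  arcs <- list(
    RCA = list(l = c(-20, 100), p = c(55, 115)),
    LMCA = list(l = c(172, 196), p = c(68, 80)),
    LADA = list(l = c(205, 258), p = c(55, 130)),
    LCFX = list(l = c(130, 168), p = c(78, 122)))
  for (nm in names(arcs))
    masks[[nm]] <- tube_mask(grid, arc_points(c0, wh_r, arcs[[nm]]$l, arcs[[nm]]$p), ar)
  # valves sit at chamber/vessel interfaces: overlap group-B structures by
  # construction, stay inside the heart away from the surface arteries
  ctr <- function(nm) c0 + ch[[nm]]$c * sc + j(nm)
  vamid <- function(a, b, f) a + f * (b - a)
  valves <- list(
    `V-MV` = list(c = vamid(ctr("LA"), ctr("LV"), 0.35), n = ctr("LV") - ctr("LA")),
    `V-TV` = list(c = vamid(ctr("RA"), ctr("RV"), 0.35), n = ctr("RV") - ctr("RA")),
    # aortic/pulmonic valves sit on their vessel's axis at its entry point,
    # so they overlap a great vessel by construction
    `V-AV` = list(c = c0 + c(-0.06, -0.02, 0.14) * sc, n = c(0, 0, 1)),
    `V-PV` = list(c = c0 + c(0.04, 0.12, 0.15) * sc, n = c(0, 0, 1)))
  for (nm in names(valves))
    masks[[nm]] <- disk_mask(co, grid, valves[[nm]]$c, valves[[nm]]$n,
                             0.05 * sc, 0.028 * sc)
  nodes <- list(
    `N-SA` = list(c = ctr("RA") + c(0.07, -0.04, 0.07) * sc, r = 0.036 * sc),
    `N-AV` = list(c = ctr("RA") + c(-0.03, 0.09, -0.07) * sc, r = 0.032 * sc))
  for (nm in names(nodes)) {
    r <- max(nodes[[nm]]$r, 1.1 / max(grid))
    masks[[nm]] <- ellipsoid_mask(co, nodes[[nm]]$c, rep(r, 3))
  }
  masks
}

#' Generate a phantom composite segmentation
#'
#' Builds the 20-structure anatomy: the whole heart is a large ellipsoid;
#' the four chambers are disjoint interior ellipsoids; the five great
#' vessels are disjoint tubes entering the heart surface; the four coronary
#' arteries are thin curved tubes lying on the heart surface (overlapping
#' the whole heart across groups); the four valves are thin disks at
#' chamber interfaces (overlapping chambers across groups); the two
#' conduction nodes are small spheres near the right atrium. Seeded jitter
#' perturbs positions and scale; if a jitter draw violates within-group
#' disjointness the case is re-jittered (bounded retries).
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @param seed Integer seed.
#' @param max_retry Bounded retries for disjointness-violating jitter.
#' @return A \code{\link{composite_segmentation}} on the reference grid
#'   (isotropic 1 mm spacing).
#' @export
generate_anatomy <- function(spec = phantom_spec(), seed = 1L, max_retry = 10L) {
  catalog <- structure_catalog()
  nm <- catalog_structures(catalog)
  for (attempt in seq_len(max_retry)) {
    jitter <- with_seed(seed + 100003L * (attempt - 1L), {
      list(c0 = runif(3, -0.015, 0.015),
           scale = runif(1, 0.95, 1.05),
           st = setNames(lapply(nm, function(s) runif(3, -0.008, 0.008)), nm))
    })
    masks <- phantom_geometry(spec, jitter)
    ok <- all(vapply(masks, any, logical(1))) &&
      !inherits(try(composite_segmentation(masks, c(1, 1, 1), catalog),
                    silent = TRUE), "try-error")
    if (ok) return(composite_segmentation(masks, c(1, 1, 1), catalog))
  }
  stop("could not generate disjoint anatomy after ", max_retry, " retries")
}

gaussian_smooth <- function(x, sd_vox) {
  if (sd_vox <= 0) return(x)
  r <- max(1L, ceiling(2 * sd_vox))
  w <- exp(-(-r:r)^2 / (2 * sd_vox^2))
  w <- w / sum(w)
  dims <- dim(x)
  for (axis in 1:3) {
    y <- array(0, dims)
    n <- dims[axis]
    for (k in -r:r) {
      idx <- pmin(pmax(seq_len(n) + k, 1L), n)  # replicate edges
      xi <- switch(axis, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
                   x[, , idx, drop = FALSE])
      y <- y + w[k + r + 1L] * xi
    }
    x <- y
  }
  x
}

#' Render a phantom anatomy as a modality image
#'
#' Intensity is a per-(modality, structure) table lookup with
#' smallest-structure-wins precedence at overlapped voxels (thin
#' contrast-filled structures stay visible), followed by Gaussian smoothing,
#' additive Gaussian noise, and linear resampling to the modality's native
#' anisotropic spacing. Deterministic given (anatomy, modality, seed).
#'
#' @param anatomy A \code{\link{composite_segmentation}} from
#'   \code{\link{generate_anatomy}}.
#' @param modality Registered modality tag.
#' @param spec The \code{\link{phantom_spec}}.
#' @param seed Integer seed (noise only).
#' @return A \code{\link{as_volume}} at the modality's native spacing.
#' @export
render_modality <- function(anatomy, modality, spec = phantom_spec(), seed = 1L) {
  if (!modality %in% names(spec$native_spacing))
    stop("unregistered modality: ", modality)
  tab <- spec$intensity[[modality]]
  img <- array(tab[["background"]], dim(anatomy$masks[[1]]))
  vol <- vapply(anatomy$masks, sum, numeric(1))
  for (nm in names(sort(vol, decreasing = TRUE)))  # smallest stamped last
    img[anatomy$masks[[nm]]] <- tab[[nm]]
  img <- gaussian_smooth(img, spec$smooth_sd)
  noise <- spec$noise_sd[[modality]]
  if (noise > 0)
    img <- img + array(with_seed(seed, rnorm(length(img), 0, noise)), dim(img))
  v <- as_volume(img, anatomy$spacing, anatomy$origin, modality)
  resample_volume(v, spec$native_spacing[[modality]], "linear")
}

#' Generate a phantom dataset on disk
#'
#' Writes one rendered image and (for labeled cases) one composite per
#' (modality, case), plus a validated CSV manifest. Case seeds derive
#' deterministically from \code{seed}, so equal seeds give byte-identical
#' manifests and identical volumes.
#'
#' @param out_dir Output directory (created if missing).
#' @param split Named counts per modality:
#'   \code{c(train=, val=, test=, unlabeled=)}; unlabeled cases get no
#'   composite and feed the pseudo-label round.
#' @param modalities Modalities to render.
#' @param spec A \code{\link{phantom_spec}}.
#' @param seed Master seed.
#' @return The \code{\link{dataset_manifest}} (also saved as
#'   \code{manifest.csv}).
#' @export
generate_dataset <- function(out_dir, split = c(train = 25, val = 5, test = 10,
                                                unlabeled = 0),
                             modalities = magic_modalities(),
                             spec = phantom_spec(), seed = 1L) {
  stopifnot(sum(split) >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (m in modalities) {
    case <- 0L
    for (sp in names(split)) {
      nsp <- split[[sp]]
      if (nsp == 0) next
      for (k in seq_len(nsp)) {
        case <- case + 1L
        cseed <- seed + 7919L * case + 104729L * match(m, modalities)
        anat <- generate_anatomy(spec, cseed)
        img <- render_modality(anat, m, spec, cseed + 1L)
        base <- file.path(out_dir, sprintf("%s_%03d", m, case))
        write_volume(img, paste0(base, "_img.nii.gz"))
        lab <- ""
        if (sp != "unlabeled") {
          lab <- paste0(base, "_lab.nii.gz")
          write_composite(anat, lab)
        }
        rows[[length(rows) + 1L]] <-
          data.frame(image = paste0(base, "_img.nii.gz"), labels = lab,
                     modality = m, split = sp, provenance = "manual",
                     stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- dataset_manifest(do.call(rbind, rows), modalities)
  save_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
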