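# Training augmentations: random flips along each axis, 90-degree and small
# (-10..10 degree) rotations along each axis, intensity shift/scale within
# +-10%, and random cropping to the training patch. Geometric transforms are
# applied identically to the image and every group label map (nearest
# neighbour for labels); intensity transforms touch the image only.

flip_axis <- function(x, axis) {
  idx <- lapply(dim(x), seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

rot90_axis <- function(x, axis, k = 1L) {
  k <- k %% 4L
  if (k == 0L) return(x)
  perm <- switch(axis, c(1, 3, 2), c(3, 2, 1), c(2, 1, 3))
  revax <- switch(axis, 2L, 3L, 1L)
  for (i in seq_len(k)) x <- flip_axis(aperm(x, perm), revax)
  x
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3)
  ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3)
  rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3)
  rz %*% ry %*% rx
}

# gather x at arbitrary continuous indices (nx3 matrix), trilinear or nearest
warp_gather <- function(x, U, interp, fill = 0) {
  d <- dim(x)
  flat <- function(ix, iy, iz) ix + d[1] * (iy - 1L) + d[1] * d[2] * (iz - 1L)
  if (interp == "nearest") {
    I <- round(U)
    ok <- I[, 1] >= 1 & I[, 1] <= d[1] & I[, 2] >= 1 & I[, 2] <= d[2] &
      I[, 3] >= 1 & I[, 3] <= d[3]
    out <- rep(fill, nrow(U))
    Ic <- pmin(pmax(I, 1L), rep(d, each = nrow(U)))
    out[ok] <- x[flat(Ic[ok, 1], Ic[ok, 2], Ic[ok, 3])]
    return(out)
  }
  I0 <- pmin(pmax(floor(U), 1L), rep(d, each = nrow(U)))
  W <- pmin(pmax(U - I0, 0), 1)
  out <- numeric(nrow(U))
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    ix <- pmin(I0[, 1] + a, d[1]); iy <- pmin(I0[, 2] + b, d[2])
    iz <- pmin(I0[, 3] + cc, d[3])
    wt <- (if (a == 0) 1 - W[, 1] else W[, 1]) *
      (if (b == 0) 1 - W[, 2] else W[, 2]) *
      (if (cc == 0) 1 - W[, 3] else W[, 3])
    out <- out + wt * x[flat(ix, iy, iz)]
  }
  out
}

rotate_small <- function(x, angles_deg, interp) {
  d <- dim(x)
  ctr <- (d + 1) / 2
  g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                             z = seq_len(d[3])))
  R <- rotation_matrix(angles_deg)
  U <- sweep(sweep(g, 2, ctr) %*% R, 2, ctr, "+")  # pull-back coordinates
  array(warp_gather(x, U, interp), d)
}

pad_to <- function(x, size, fill = 0) {
  d <- dim(x)
  if (all(d >= size)) return(x)
  nd <- pmax(d, size)
  out <- array(fill, nd)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
  out
}

#' Augment one training case
#'
#' Applies, in order and with independently drawn seeded randomness: flips
#' (probability 1/2 per axis), 90-degree rotations (uniform k in 0..3 per
#' axis), small rotations (uniform in -10..10 degrees per axis, trilinear
#' for the image, nearest for labels), intensity scaling in [0.9, 1.1] and
#' shifting by up to +-10% of the intensity range (image only), and a random
#' crop to \code{patch_size} (volumes smaller than the patch are padded
#' with the minimum intensity first, i.e. with background).
#'
#' @param image 3-D numeric array (preprocessed).
#' @param labels Named list of integer group label arrays on the same grid.
#' @param seed Integer seed; equal seeds give identical augmentations.
#' @param patch_size Output patch edge (voxels), or NULL to keep the grid.
#' @param flip,rot90,rot_small,intensity Toggles for the transform families.
#' @return List with \code{image} and \code{labels}.
#' @export
augment_case <- function(image, labels, seed, patch_size = NULL, flip = TRUE,
                         rot90 = TRUE, rot_small = TRUE, intensity = TRUE) {
  stopifnot(all(vapply(labels, function(l) identical(dim(l), dim(image)),
                       logical(1))))
  draws <- with_seed(seed, list(
    flip = runif(3) < 0.5,
    k90 = sample(0:3, 3, replace = TRUE),
    ang = runif(3, -10, 10),
    s = runif(1, 0.9, 1.1),
    d = runif(1, -0.1, 0.1),
    corner = runif(3)))
  apply_geom <- function(x, interp) {
    if (flip) for (a in 1:3) if (draws$flip[a]) x <- flip_axis(x, a)
    if (rot90) for (a in 1:3) x <- rot90_axis(x, a, draws$k90[a])
    if (rot_small && any(draws$ang != 0)) x <- rotate_small(x, draws$ang, interp)
    x
  }
  image <- apply_geom(image, "linear")
  labels <- lapply(labels, function(l) {
    out <- apply_geom(l + 0, "nearest")
    array(as.integer(round(out)), dim(out))
  })
  if (intensity) {
    rng <- diff(range(image))
    image <- image * draws$s + draws$d * rng
  }
  if (!is.null(patch_size)) {
    ps <- rep(patch_size, length.out = 3)
    image <- pad_to(image, ps, fill = min(image))
    labels <- lapply(labels, function(l) {
      p <- pad_to(l, ps, 0L); array(as.integer(p), dim(p))
    })
    d <- dim(image)
    lo <- 1L + floor(draws$corner * (d - ps + 1) * 0.99999)
    image <- image[lo[1]:(lo[1] + ps[1] - 1), lo[2]:(lo[2] + ps[2] - 1),
                   lo[3]:(lo[3] + ps[3] - 1), drop = FALSE]
    labels <- lapply(labels, function(l)
      l[lo[1]:(lo[1] + ps[1] - 1), lo[2]:(lo[2] + ps[2] - 1),
        lo[3]:(lo[3] + ps[3] - 1), drop = FALSE])
  }
  list(image = image, labels = labels)
}
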