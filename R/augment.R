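#' Trilinear (or nearest-neighbour) resampling of a 3D volume
#'
#' Resamples a volume onto a new voxel grid, mapping the output grid onto
#' the input extent with aligned corners. Used to bring phantom volumes to
#' the network's input shape.
#'
#' @param vol 3D numeric array.
#' @param out_shape 3 integers.
#' @param method `"trilinear"` or `"nearest"`.
#' @return 3D array with dimensions `out_shape`.
#' @export
resample_volume <- function(vol, out_shape,
                            method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  ind <- dim(vol)
  out_shape <- as.integer(out_shape)
  if (all(ind == out_shape)) return(vol)
  coord <- function(m, n)  # output index -> fractional input index
    if (n == 1L) rep((m + 1) / 2, n) else (seq_len(n) - 1) * (m - 1) / (n - 1) + 1
  gx <- coord(ind[1], out_shape[1])
  gy <- coord(ind[2], out_shape[2])
  gz <- coord(ind[3], out_shape[3])
  if (method == "nearest") {
    return(vol[round(gx), round(gy), round(gz), drop = FALSE])
  }
  x0 <- pmin(floor(gx), ind[1] - 1L); fx <- gx - x0
  y0 <- pmin(floor(gy), ind[2] - 1L); fy <- gy - y0
  z0 <- pmin(floor(gz), ind[3] - 1L); fz <- gz - z0
  g <- expand.grid(i = seq_along(gx), j = seq_along(gy), k = seq_along(gz))
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- (if (dx) fx[g$i] else 1 - fx[g$i]) *
      (if (dy) fy[g$j] else 1 - fy[g$j]) *
      (if (dz) fz[g$k] else 1 - fz[g$k])
    acc <- acc + wgt * vol[cbind(x0[g$i] + dx, y0[g$j] + dy, z0[g$k] + dz)]
  }
  array(acc, out_shape)
}

rotate_axial <- function(vol, angle_deg, fill, interpolation) {
  d <- dim(vol)
  if (any(d[1:2] == 1L))
    abort("cannot rotate about a degenerate (size-1) axis",
          "atnprog_axis_error")
  th <- angle_deg * pi / 180
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  # inverse rotation of the in-plane coordinates about the image centre
  sx <- cos(th) * (g$x - cx) + sin(th) * (g$y - cy) + cx
  sy <- -sin(th) * (g$x - cx) + cos(th) * (g$y - cy) + cy
  out <- array(fill, d)
  if (interpolation == "nearest") {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2]
    for (z in seq_len(d[3])) {
      plane <- matrix(fill, d[1], d[2])
      plane[cbind(g$x[ok], g$y[ok])] <- vol[cbind(ix[ok], iy[ok], z)]
      out[, , z] <- plane
    }
  } else {
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    ok <- x0 >= 1 & x0 + 1 <= d[1] & y0 >= 1 & y0 + 1 <= d[2]
    for (z in seq_len(d[3])) {
      v <- (1 - fx[ok]) * (1 - fy[ok]) * vol[cbind(x0[ok], y0[ok], z)] +
        fx[ok] * (1 - fy[ok]) * vol[cbind(x0[ok] + 1, y0[ok], z)] +
        (1 - fx[ok]) * fy[ok] * vol[cbind(x0[ok], y0[ok] + 1, z)] +
        fx[ok] * fy[ok] * vol[cbind(x0[ok] + 1, y0[ok] + 1, z)]
      plane <- matrix(fill, d[1], d[2])
      plane[cbind(g$x[ok], g$y[ok])] <- v
      out[, , z] <- plane
    }
  }
  out
}

translate_volume <- function(vol, shift, fill) {
  d <- dim(vol)
  shift <- as.integer(round(shift))
  if (all(shift == 0L)) return(vol)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    s <- shift[a]
    if (abs(s) >= d[a]) return(out)
    if (s >= 0) { dst[[a]] <- (1 + s):d[a]; src[[a]] <- 1:(d[a] - s) }
    else { dst[[a]] <- 1:(d[a] + s); src[[a]] <- (1 - s):d[a] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

#' Randomly augment a 3D volume
#'
#' Applies, in order: rotation about the axial axis by an angle drawn
#' uniformly from the configured range, translation along each axis by a
#' random fraction of its extent (random direction), and a coin-flip mirror
#' along each configured flip axis. Voxels leaving the field of view are
#' filled with the background value; the output shape always equals the
#' input shape and the class label is unchanged by contract. With
#' zero angle, zero shift and no flips the input is returned bitwise
#' unchanged (nearest-neighbour path).
#'
#' @param vol 3D numeric array.
#' @param settings an [augment_settings()].
#' @param seed optional integer seed for the random draws.
#' @return augmented 3D array of identical shape.
#' @export
augment_volume <- function(vol, settings = augment_settings(), seed = NULL) {
  run <- function() {
    angle <- runif(1, settings$rotation_range[1], settings$rotation_range[2])
    frac <- runif(3, settings$translation_range[1],
                  settings$translation_range[2])
    sgn <- sample(c(-1, 1), 3L, replace = TRUE)
    flips <- settings$flip_axes[runif(length(settings$flip_axes)) < 0.5]
    out <- vol
    if (angle != 0)
      out <- rotate_axial(out, angle, settings$fill, settings$interpolation)
    shift <- sgn * round(frac * dim(vol))
    if (any(shift != 0L))
      out <- translate_volume(out, shift, settings$fill)
    for (a in flips)
      out <- flip_volume(out, a)
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

flip_volume <- function(vol, axis) {
  idx <- lapply(dim(vol), seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  do.call(`[`, c(list(vol), idx))
}
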