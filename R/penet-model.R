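#' Build an untrained PENet model
#'
#' Instantiates the layer parameters described by a [penet_spec()]:
#' He-initialised convolution and fully-connected weights, unit-gamma /
#' zero-beta batch normalisation. The model maps a (volume, scalar
#' biomarkers) batch to 2-class probabilities.
#'
#' @param spec a [penet_spec()].
#' @param seed integer seed for weight initialisation.
#' @return object of class `penet_model`.
#' @export
build_penet <- function(spec, seed = 1L) {
  validate_penet_spec(spec)
  withr::with_seed(seed, build_penet_impl(spec))
}

build_penet_impl <- function(spec) {
  k <- spec$kernel_size
  he <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)),
                                     dims)
  new_bn <- function(c) list(gamma = rep(1, c), beta = rep(0, c),
                             rmean = rep(0, c), rvar = rep(1, c))
  vol_layers <- NULL
  feat_dim <- 0L
  if ("mri" %in% spec$enabled_modalities) {
    vol_layers <- list()
    cin <- 1L
    for (i in seq_along(spec$conv_filters)) {
      f <- spec$conv_filters[i]
      vol_layers[[length(vol_layers) + 1L]] <- list(
        type = "conv", W = he(c(k, k, k, cin, f), k^3 * cin),
        b = rep(0, f), bn = new_bn(f), stride = spec$conv_strides[i])
      cin <- f
    }
    for (i in seq_along(spec$sepconv_filters)) {
      f <- spec$sepconv_filters[i]
      vol_layers[[length(vol_layers) + 1L]] <- list(
        type = "sepconv", Wd = he(c(k, k, k, cin), k^3),
        Wp = he(c(1, 1, 1, cin, f), cin), bp = rep(0, f),
        bn = new_bn(f), stride = spec$sepconv_strides[i])
      cin <- f
    }
    feat_dim <- prod(penet_block_shapes(spec)[[5L]]) * cin
  }
  scalar_mods <- setdiff(spec$enabled_modalities, "mri")
  fc <- function(p, q) list(W = matrix(rnorm(p * q, 0, sqrt(2 / p)), p, q),
                            b = rep(0, q))
  branches <- setNames(lapply(scalar_mods, function(m) {
    widths <- spec$scalar_branch_widths
    ins <- c(1L, head(widths, -1L))
    mapply(fc, ins, widths, SIMPLIFY = FALSE)
  }), scalar_mods)
  fusion_in <- feat_dim + length(scalar_mods) *
    spec$scalar_branch_widths[length(spec$scalar_branch_widths)]
  widths <- c(spec$fusion_widths, 2L)
  ins <- c(fusion_in, head(widths, -1L))
  fusion <- mapply(fc, ins, widths, SIMPLIFY = FALSE)
  structure(list(spec = spec, vol_layers = vol_layers, branches = branches,
                 fusion = fusion, feat_dim = feat_dim, trained = FALSE),
            class = "penet_model")
}

#' @export
print.penet_model <- function(x, ...) {
  pc <- penet_param_count(x$spec)
  cat(sprintf("PENet (%s): %d parameters (%svolume %d, fusion %d)%s\n",
              paste(x$spec$enabled_modalities, collapse = "+"), pc$total,
              if (length(pc$branches))
                sprintf("branches %d, ", sum(unlist(pc$branches))) else "",
              pc$volume, pc$fusion,
              if (x$trained) " [trained]" else " [untrained]"))
  invisible(x)
}

elu <- function(x) ifelse(x > 0, x, expm1(x))
elu_grad <- function(y, x) ifelse(x > 0, 1, y + 1)

# Batch norm over a (D,H,W,C,N) activation array, statistics per channel.
bn_fwd <- function(x, bn, training, eps = 1e-5, momentum = 0.9) {
  d <- dim(x)
  C <- d[4L]
  xp <- aperm(x, c(1L, 2L, 3L, 5L, 4L))
  m <- matrix(xp, ncol = C)
  if (training) {
    mu <- colMeans(m)
    v <- colMeans(m^2) - mu^2
    bn$rmean <- momentum * bn$rmean + (1 - momentum) * mu
    bn$rvar <- momentum * bn$rvar + (1 - momentum) * v
  } else {
    mu <- bn$rmean
    v <- bn$rvar
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(m, 2L, mu), 2L, invstd, `*`)
  y <- sweep(sweep(xhat, 2L, bn$gamma, `*`), 2L, bn$beta, `+`)
  ya <- aperm(array(y, dim(xp)), c(1L, 2L, 3L, 5L, 4L))
  list(y = ya, bn = bn,
       cache = list(xhat = xhat, invstd = invstd, gamma = bn$gamma,
                    dims = d, pdims = dim(xp), training = training))
}

bn_bwd <- function(dy, cache) {
  d <- cache$dims
  dyp <- matrix(aperm(dy, c(1L, 2L, 3L, 5L, 4L)), ncol = d[4L])
  xhat <- cache$xhat
  dgamma <- colSums(dyp * xhat)
  dbeta <- colSums(dyp)
  M <- nrow(dyp)
  dxhat <- sweep(dyp, 2L, cache$gamma, `*`)
  if (cache$training) {
    t1 <- sweep(dxhat, 2L, colMeans(dxhat))
    t2 <- sweep(xhat, 2L, colMeans(dxhat * xhat), `*`)
    dm <- sweep(t1 - t2, 2L, cache$invstd, `*`)
  } else {
    dm <- sweep(dxhat, 2L, cache$invstd, `*`)
  }
  dx <- aperm(array(dm, cache$pdims), c(1L, 2L, 3L, 5L, 4L))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

conv_pad <- function(k) (k - 1L) %/% 2L

# Forward pass over a batch. `batch` is a list with `vols` (D,H,W,1,N array
# or NULL) and `scalars` (named list of length-N numeric vectors).
penet_forward <- function(model, batch, training = FALSE,
                          dropout_masks = NULL) {
  spec <- model$spec
  k <- spec$kernel_size
  p <- conv_pad(k)
  caches <- list(vol = list(), branch = list(), fusion = list())
  feats <- NULL
  n <- NULL
  if (!is.null(model$vol_layers)) {
    a <- batch$vols
    n <- dim(a)[5L]
    for (i in seq_along(model$vol_layers)) {
      L <- model$vol_layers[[i]]
      cache <- list(x = a)
      if (L$type == "conv") {
        z <- cpp_conv3d_fwd(a, L$W, L$b, L$stride, p)
      } else {
        zd <- cpp_dwconv3d_fwd(a, L$Wd, L$stride, p)
        cache$zd <- zd
        z <- cpp_conv3d_fwd(zd, L$Wp, L$bp, 1L, 0L)
      }
      bnr <- bn_fwd(z, L$bn, training)
      model$vol_layers[[i]]$bn <- bnr$bn
      h <- elu(bnr$y)
      cache$bn <- bnr$cache
      cache$z_bn <- bnr$y
      cache$h <- h
      caches$vol[[i]] <- cache
      a <- h
    }
    feats <- t(matrix(a, ncol = n))
    caches$vol_out_dim <- dim(a)
  }
  seg <- list()
  if (!is.null(feats)) seg$mri <- ncol(feats)
  for (m in names(model$branches)) {
    x <- matrix(batch$scalars[[m]], ncol = 1L)
    n <- n %||% nrow(x)
    bc <- list()
    for (j in seq_along(model$branches[[m]])) {
      L <- model$branches[[m]][[j]]
      z <- sweep(x %*% L$W, 2L, L$b, `+`)
      h <- elu(z)
      bc[[j]] <- list(x = x, z = z, h = h)
      x <- h
    }
    caches$branch[[m]] <- bc
    seg[[m]] <- ncol(x)
    feats <- if (is.null(feats)) x else cbind(feats, x)
  }
  caches$seg <- seg
  x <- feats
  nf <- length(model$fusion)
  for (j in seq_len(nf)) {
    L <- model$fusion[[j]]
    z <- sweep(x %*% L$W, 2L, L$b, `+`)
    if (j < nf) {
      h <- elu(z)
      if (training && spec$dropout > 0) {
        mask <- dropout_masks[[j]] %||%
          (matrix(runif(length(h)) >= spec$dropout, nrow(h)) /
             (1 - spec$dropout))
        h <- h * mask
        caches$fusion[[j]] <- list(x = x, z = z, h = h, mask = mask)
      } else {
        caches$fusion[[j]] <- list(x = x, z = z, h = h)
      }
      x <- caches$fusion[[j]]$h
    } else {
      caches$fusion[[j]] <- list(x = x, z = z)
      logits <- z
    }
  }
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  list(probs = probs, caches = caches, model = model)
}

# Backward pass; returns gradients mirroring the parameter structure.
penet_backward <- function(model, caches, probs, y_onehot) {
  spec <- model$spec
  k <- spec$kernel_size
  p <- conv_pad(k)
  n <- nrow(probs)
  grads <- list(vol = NULL, branches = list(), fusion = list())
  dlog <- (probs - y_onehot) / n

  dx <- dlog
  nf <- length(model$fusion)
  for (j in rev(seq_len(nf))) {
    L <- model$fusion[[j]]
    cc <- caches$fusion[[j]]
    dz <- dx
    if (j < nf) {
      if (!is.null(cc$mask)) dz <- dz * cc$mask
      dz <- dz * elu_grad(elu(cc$z), cc$z)
    }
    grads$fusion[[j]] <- list(dW = crossprod(cc$x, dz), db = colSums(dz))
    dx <- dz %*% t(L$W)
  }
  dfeat <- dx
  off <- 0L
  seg <- caches$seg
  dmri <- NULL
  if (!is.null(seg$mri)) {
    dmri <- dfeat[, seq_len(seg$mri), drop = FALSE]
    off <- seg$mri
  }
  for (m in names(model$branches)) {
    w <- seg[[m]]
    dxb <- dfeat[, off + seq_len(w), drop = FALSE]
    off <- off + w
    bl <- model$branches[[m]]
    bc <- caches$branch[[m]]
    gb <- vector("list", length(bl))
    for (j in rev(seq_along(bl))) {
      cc <- bc[[j]]
      dz <- dxb * elu_grad(cc$h, cc$z)
      gb[[j]] <- list(dW = crossprod(cc$x, dz), db = colSums(dz))
      dxb <- dz %*% t(bl[[j]]$W)
    }
    grads$branches[[m]] <- gb
  }
  if (!is.null(model$vol_layers)) {
    da <- array(t(dmri), caches$vol_out_dim)
    gv <- vector("list", length(model$vol_layers))
    for (i in rev(seq_along(model$vol_layers))) {
      L <- model$vol_layers[[i]]
      cc <- caches$vol[[i]]
      dh <- da * elu_grad(cc$h, cc$z_bn)
      bb <- bn_bwd(dh, cc$bn)
      if (L$type == "conv") {
        cb <- cpp_conv3d_bwd(cc$x, L$W, bb$dx, L$stride, p)
        gv[[i]] <- list(dW = cb$dw, db = cb$db, dgamma = bb$dgamma,
                        dbeta = bb$dbeta)
        da <- cb$dx
      } else {
        pb <- cpp_conv3d_bwd(cc$zd, L$Wp, bb$dx, 1L, 0L)
        db_ <- cpp_dwconv3d_bwd(cc$x, L$Wd, pb$dx, L$stride, p)
        gv[[i]] <- list(dWd = db_$dw, dWp = pb$dw, dbp = pb$db,
                        dgamma = bb$dgamma, dbeta = bb$dbeta)
        da <- db_$dx
      }
    }
    grads$vol <- gv
  }
  grads
}

# SGD step with L2 weight decay on fully-connected weights only.
penet_sgd_step <- function(model, grads, lr, l2_fc) {
  if (!is.null(model$vol_layers)) {
    for (i in seq_along(model$vol_layers)) {
      g <- grads$vol[[i]]
      L <- model$vol_layers[[i]]
      if (L$type == "conv") {
        L$W <- L$W - lr * g$dW
        L$b <- L$b - lr * g$db
      } else {
        L$Wd <- L$Wd - lr * g$dWd
        L$Wp <- L$Wp - lr * g$dWp
        L$bp <- L$bp - lr * g$dbp
      }
      L$bn$gamma <- L$bn$gamma - lr * g$dgamma
      L$bn$beta <- L$bn$beta - lr * g$dbeta
      model$vol_layers[[i]] <- L
    }
  }
  for (m in names(model$branches))
    for (j in seq_along(model$branches[[m]])) {
      g <- grads$branches[[m]][[j]]
      L <- model$branches[[m]][[j]]
      L$W <- L$W - lr * (g$dW + l2_fc * L$W)
      L$b <- L$b - lr * g$db
      model$branches[[m]][[j]] <- L
    }
  for (j in seq_along(model$fusion)) {
    g <- grads$fusion[[j]]
    L <- model$fusion[[j]]
    L$W <- L$W - lr * (g$dW + l2_fc * L$W)
    L$b <- L$b - lr * g$db
    model$fusion[[j]] <- L
  }
  model
}

#' Predict class probabilities from a trained PENet
#'
#' @param object a `penet_model`.
#' @param batch list with `vols` (D,H,W,1,N array, already resampled and
#'   standardised) and `scalars` (named list of standardised vectors).
#' @param ... unused.
#' @return N x 2 matrix of class probabilities (columns MD, FD).
#' @exportS3Method stats::predict
predict.penet_model <- function(object, batch, ...) {
  out <- penet_forward(object, batch, training = FALSE)
  colnames(out$probs) <- c("MD", "FD")
  out$probs
}
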