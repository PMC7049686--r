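# Minimal 1D-convolutional network engine with exact analytic gradients.
#
# Activations are dense arrays dim (C, L, B) (channels, length, batch) for
# spatial layers and matrices dim (F, B) after global pooling.  Convolution
# is computed as an im2col matrix product so the heavy lifting is BLAS.
# Every layer implements forward (caching what backward needs) and backward
# (returning the gradient w.r.t. its input), which gives both parameter
# gradients for training and input gradients for attribution.

newLayer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$frozen <- FALSE
  e$params <- character(0)
  args <- list(...)
  for (nm in names(args)) assign(nm, args[[nm]], envir = e)
  e
}

layerConv1d <- function(cin, cout, k, dilation = 1L) {
  k <- as.integer(k)
  newLayer("conv",
           W = matrix(stats::rnorm(cout * cin * k, sd = sqrt(2 / (cin * k))),
                      cout, cin * k),
           b = numeric(cout),
           k = k, dil = as.integer(dilation), cin = as.integer(cin),
           cout = as.integer(cout), params = c("W", "b"))
}

layerDense <- function(fin, fout) {
  newLayer("dense",
           W = matrix(stats::rnorm(fout * fin, sd = sqrt(2 / fin)), fout, fin),
           b = numeric(fout),
           fin = as.integer(fin), fout = as.integer(fout),
           params = c("W", "b"))
}

layerBatchNorm <- function(c) {
  newLayer("bn", gamma = rep(1, c), beta = numeric(c),
           rmean = numeric(c), rvar = rep(1, c),
           momentum = 0.1, eps = 1e-5, c = as.integer(c),
           params = c("gamma", "beta"))
}

layerReLU     <- function() newLayer("relu")
# (C, 1, B) -> (C, B) adapter so dense stacks can follow spatial layers
layerSqueeze  <- function() newLayer("squeeze")
layerDropout  <- function(p) newLayer("dropout", p = p)
layerMaxPool  <- function(w) newLayer("maxpool", w = as.integer(w))
layerGAP      <- function() newLayer("gap")
# concatenated global max + average pooling (shallow-CNN pooling stage)
layerPoolConcat <- function() newLayer("poolconcat")
# hyper-residual dilation block: output of `sub` concatenated channel-wise
# onto the incoming representation
layerDilBlock <- function(sub) newLayer("dilblock", sub = sub)

layerForward <- function(ly, x, train = FALSE) {
  switch(ly$type,
    conv = {
      d <- dim(x); C <- d[1L]; L <- d[2L]; B <- d[3L]
      nc <- L * B
      if (is.null(ly$colbuf) || ncol(ly$colbuf) != nc)
        ly$colbuf <- matrix(0, C * ly$k, nc)
      conv_im2col_into(x, ly$colbuf, C, L, B, ly$k, ly$dil)
      y <- ly$W %*% ly$colbuf + ly$b
      ly$cache <- d
      dim(y) <- c(ly$cout, L, B)
      y
    },
    dense = {
      ly$cache <- x
      ly$W %*% x + ly$b
    },
    bn = {
      d <- dim(x); C <- d[1L]
      xm <- x; dim(xm) <- c(C, length(x) / C)
      if (train || isTRUE(ly$accum)) {
        mu <- rowMeans(xm)
        v <- rowMeans(xm * xm) - mu * mu
        if (isTRUE(ly$accum)) {      # precise-recalibration pass
          ly$accMean <- ly$accMean + mu
          ly$accVar <- ly$accVar + v
          ly$accN <- ly$accN + 1L
        } else {
          ly$rmean <- (1 - ly$momentum) * ly$rmean + ly$momentum * mu
          ly$rvar  <- (1 - ly$momentum) * ly$rvar + ly$momentum * v
        }
      } else {
        mu <- ly$rmean
        v <- ly$rvar
      }
      istd <- 1 / sqrt(v + ly$eps)
      xhat <- (xm - mu) * istd
      y <- ly$gamma * xhat + ly$beta
      ly$cache <- list(xhat = xhat, istd = istd, dimx = d,
                       train = train || isTRUE(ly$accum))
      dim(y) <- d
      y
    },
    relu = {
      m <- x > 0
      ly$cache <- m
      x * m
    },
    squeeze = {
      d <- dim(x)
      if (length(d) == 3L) {
        ly$cache <- d
        dim(x) <- c(d[1L] * d[2L], d[3L])
      } else ly$cache <- NULL
      x
    },
    dropout = {
      if (train && ly$p > 0) {
        m <- (stats::runif(length(x)) >= ly$p) / (1 - ly$p)
        dim(m) <- dim(x)
        ly$cache <- m
        x * m
      } else {
        ly$cache <- NULL
        x
      }
    },
    maxpool = {
      d <- dim(x); C <- d[1L]; L <- d[2L]; B <- d[3L]
      L2 <- L %/% ly$w
      if (L2 < 1L) stop("pooled length < 1")
      n2 <- C * L2 * B
      if (is.null(ly$ybuf) || length(ly$ybuf) != n2) {
        ly$ybuf <- array(0, c(C, L2, B))
        ly$argbuf <- array(0L, c(C, L2, B))
      }
      maxpool_fwd_into(x, ly$ybuf, ly$argbuf, C, L, B, ly$w)
      ly$cache <- d
      ly$ybuf
    },
    gap = {
      d <- dim(x); ly$cache <- d
      y <- colSums(aperm(x, c(2L, 1L, 3L))) / d[2L]
      dim(y) <- c(d[1L], d[3L])
      y
    },
    poolconcat = {
      d <- dim(x); C <- d[1L]; L <- d[2L]; B <- d[3L]
      m <- aperm(x, c(2L, 1L, 3L))
      dim(m) <- c(L, C * B)
      j <- max.col(t(m), ties.method = "first")
      mx <- m[cbind(j, seq_len(C * B))]
      av <- colSums(m) / L
      ly$cache <- list(arg = j, dimx = d)
      y <- matrix(0, 2L * C, B)
      y[seq_len(C), ] <- mx
      y[C + seq_len(C), ] <- av
      y
    },
    dilblock = {
      d <- dim(x)
      out <- netForward(ly$sub, x, train)
      do <- dim(out)
      y <- array(0, c(d[1L] + do[1L], d[2L], d[3L]))
      y[seq_len(d[1L]), , ] <- x
      y[d[1L] + seq_len(do[1L]), , ] <- out
      ly$cache <- list(cx = d[1L], cout = do[1L])
      y
    },
    stop("unknown layer type: ", ly$type))
}

layerBackward <- function(ly, dy) {
  switch(ly$type,
    conv = {
      d <- ly$cache; C <- d[1L]; L <- d[2L]; B <- d[3L]
      dim(dy) <- c(ly$cout, L * B)
      if (!ly$frozen) {
        ly$gW <- tcrossprod(dy, ly$colbuf)
        ly$gb <- rowSums(dy)
      }
      if (isTRUE(ly$skipDx)) return(NULL)   # first layer during training
      dcol <- crossprod(ly$W, dy)
      if (is.null(ly$dxbuf) || length(ly$dxbuf) != C * L * B)
        ly$dxbuf <- array(0, d)
      conv_col2im_into(dcol, ly$dxbuf, C, L, B, ly$k, ly$dil)
      ly$dxbuf
    },
    dense = {
      if (!ly$frozen) {
        ly$gW <- dy %*% t(ly$cache)
        ly$gb <- rowSums(dy)
      }
      crossprod(ly$W, dy)
    },
    bn = {
      cc <- ly$cache
      d <- cc$dimx; C <- d[1L]
      dim(dy) <- c(C, length(dy) / C)
      if (!ly$frozen) {
        ly$ggamma <- rowSums(dy * cc$xhat)
        ly$gbeta <- rowSums(dy)
      }
      if (cc$train) {
        dxhat <- dy * ly$gamma
        dx <- cc$istd * (dxhat - rowMeans(dxhat) -
                           cc$xhat * rowMeans(dxhat * cc$xhat))
      } else {
        dx <- dy * (ly$gamma * cc$istd)
      }
      dim(dx) <- d
      dx
    },
    relu = dy * ly$cache,
    squeeze = {
      if (!is.null(ly$cache)) dim(dy) <- ly$cache
      dy
    },
    dropout = if (is.null(ly$cache)) dy else dy * ly$cache,
    maxpool = {
      d <- ly$cache
      if (is.null(ly$dxbuf) || length(ly$dxbuf) != prod(d))
        ly$dxbuf <- array(0, d)
      maxpool_bwd_into(dy, ly$argbuf, ly$dxbuf, d[1L], d[2L], d[3L], ly$w)
      ly$dxbuf
    },
    gap = {
      d <- ly$cache
      dx <- aperm(array(dy / d[2L], c(d[1L], d[3L], d[2L])), c(1L, 3L, 2L))
      dx
    },
    poolconcat = {
      cc <- ly$cache
      d <- cc$dimx; C <- d[1L]; L <- d[2L]; B <- d[3L]
      dmx <- dy[seq_len(C), , drop = FALSE]
      dav <- dy[C + seq_len(C), , drop = FALSE]
      dm <- matrix(0, L, C * B)
      dm[cbind(cc$arg, seq_len(C * B))] <- as.vector(dmx)
      dm <- dm + rep(as.vector(dav) / L, each = L)
      dim(dm) <- c(L, C, B)
      aperm(dm, c(2L, 1L, 3L))
    },
    dilblock = {
      cc <- ly$cache
      dx1 <- dy[seq_len(cc$cx), , , drop = FALSE]
      dsub <- dy[cc$cx + seq_len(cc$cout), , , drop = FALSE]
      dx2 <- netBackward(ly$sub, dsub)
      dx1 + dx2
    },
    stop("unknown layer type: ", ly$type))
}

netForward <- function(layers, x, train = FALSE) {
  for (ly in layers) x <- layerForward(ly, x, train)
  x
}

netBackward <- function(layers, dy) {
  for (ly in rev(layers)) dy <- layerBackward(ly, dy)
  dy
}

# Precise batch-norm recalibration: replace the EMA running statistics
# with exact averages of the batch statistics under the *current*
# weights.  Run before any evaluation that follows weight updates (the
# EMA lags the fast-moving early training trajectory badly).
bnRecalibrate <- function(layers, X, batchSize = 128L, maxBatches = 24L) {
  # frozen batch-norms keep the statistics they were calibrated with
  bns <- Filter(function(l) l$type == "bn" && !l$frozen,
                flattenLayers(layers))
  if (length(bns) == 0L) return(invisible(NULL))
  for (b in bns) {
    b$accum <- TRUE
    b$accMean <- 0
    b$accVar <- 0
    b$accN <- 0L
  }
  n <- dim(X)[3L]
  i <- 1L
  nb <- 0L
  while (i <= n && nb < maxBatches) {
    j <- min(n, i + batchSize - 1L)
    netForward(layers, X[, , i:j, drop = FALSE], train = FALSE)
    i <- j + 1L
    nb <- nb + 1L
  }
  for (b in bns) {
    if (b$accN > 0L) {
      b$rmean <- b$accMean / b$accN
      b$rvar <- b$accVar / b$accN
    }
    b$accum <- FALSE
  }
  invisible(NULL)
}

# flatten nested layer lists (dilation blocks carry sub-layers)
flattenLayers <- function(layers) {
  out <- list()
  for (ly in layers) {
    out[[length(out) + 1L]] <- ly
    if (ly$type == "dilblock") out <- c(out, flattenLayers(ly$sub))
  }
  out
}

collectParams <- function(layers) {
  lapply(flattenLayers(layers), function(ly)
    stats::setNames(lapply(ly$params, function(p) get(p, envir = ly)),
                    ly$params))
}

restoreParams <- function(layers, snap) {
  fl <- flattenLayers(layers)
  stopifnot(length(fl) == length(snap))
  for (i in seq_along(fl))
    for (p in names(snap[[i]])) assign(p, snap[[i]][[p]], envir = fl[[i]])
  invisible(NULL)
}

adamInit <- function(layers) {
  for (ly in flattenLayers(layers)) {
    ly$adam <- lapply(stats::setNames(ly$params, ly$params), function(p) {
      v <- get(p, envir = ly)
      list(m = v * 0, v = v * 0)
    })
  }
  invisible(NULL)
}

adamStep <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  b1t <- 1 - beta1^t
  b2t <- 1 - beta2^t
  for (ly in flattenLayers(layers)) {
    if (ly$frozen || length(ly$params) == 0L) next
    for (p in ly$params) {
      g <- get(paste0("g", p), envir = ly)
      st <- ly$adam[[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      ly$adam[[p]] <- st
      val <- get(p, envir = ly) - lr * (st$m / b1t) / (sqrt(st$v / b2t) + eps)
      assign(p, val, envir = ly)
    }
  }
  invisible(NULL)
}

freezeLayers <- function(layers) {
  for (ly in flattenLayers(layers)) ly$frozen <- TRUE
  invisible(NULL)
}

# numerically stable softmax cross-entropy; y is an integer class index per
# column of logits.  Returns mean loss and gradient w.r.t. logits.
softmaxXent <- function(logits, y) {
  B <- ncol(logits)
  mx <- apply(logits, 2L, max)
  z <- sweep(logits, 2L, mx)
  ez <- exp(z)
  sz <- colSums(ez)
  p <- sweep(ez, 2L, sz, "/")
  loss <- -mean(z[cbind(y, seq_len(B))] - log(sz))
  d <- p
  d[cbind(y, seq_len(B))] <- d[cbind(y, seq_len(B))] - 1
  list(loss = loss, grad = d / B, probs = p)
}

softmaxProbs <- function(logits) {
  mx <- apply(logits, 2L, max)
  ez <- exp(sweep(logits, 2L, mx))
  sweep(ez, 2L, colSums(ez), "/")
}

mseLoss <- function(yhat, y) {
  r <- yhat - y
  list(loss = mean(r * r), grad = 2 * r / length(r))
}
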