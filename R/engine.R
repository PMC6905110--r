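# Internal sequential conv-net engine.
#
# A runnable net is a list of environments (one per layer) so that SGD and
# batch-norm running statistics update in place. Samples are (H, W, C)
# arrays and travel through the engine as lists (minibatches); conv weights
# are (kh*kw*Cin) x Cout matrices matching the im2col patch ordering in
# src/conv_ops.cpp. Batch normalization pools its statistics over the whole
# minibatch and all spatial positions — essential for patch-based training,
# where the deepest feature maps of a single 64x64 patch are 1x1 and would
# otherwise carry no variance.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1  # running <- (1 - m) * running + m * batch

# Improved Xavier (He) initialization: W ~ N(0, sqrt(2 / fan_in)).
# The final layer (the count read-out) gets a bias and no BN/ReLU.
init_net <- function(spec, seed) {
  n <- length(spec$layers)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(l) {
      ly <- spec$layers[[l]]
      e <- new.env(parent = emptyenv())
      e$name <- ly$name; e$kind <- ly$kind
      e$kh <- ly$kernel[1]; e$kw <- ly$kernel[2]
      e$stride <- ly$stride; e$pad <- ly$padding
      if (ly$kind == "conv") {
        fan_in <- e$kh * e$kw * ly$in_channels
        e$cin <- ly$in_channels; e$cout <- ly$out_channels
        e$W <- matrix(rnorm(fan_in * ly$out_channels, sd = sqrt(2 / fan_in)),
                      fan_in, ly$out_channels)
        last <- l == n
        e$bn <- !last
        e$relu <- !last
        if (last) e$b <- numeric(ly$out_channels)
        if (e$bn) {
          e$gamma <- rep(1, ly$out_channels)
          e$beta <- numeric(ly$out_channels)
          e$rmean <- numeric(ly$out_channels)
          e$rvar <- rep(1, ly$out_channels)
        }
      }
      e
    })
  })
}

as_channel_mat <- function(x) {
  d <- dim(x)
  matrix(x, d[1] * d[2], d[3])
}

# xs: list of (H, W, C) arrays (shapes may differ across the batch).
# Statistics pool over every spatial position of every sample.
bn_forward <- function(xs, ly, train) {
  mats <- lapply(xs, as_channel_mat)
  ns <- vapply(mats, nrow, integer(1))
  Ntot <- sum(ns)
  if (train) {
    mu <- Reduce(`+`, lapply(mats, colSums)) / Ntot
    v <- Reduce(`+`, lapply(mats, function(m) colSums(m^2))) / Ntot - mu^2
    v[v < 0] <- 0
    ly$rmean <- (1 - BN_MOMENTUM) * ly$rmean + BN_MOMENTUM * mu
    ly$rvar <- (1 - BN_MOMENTUM) * ly$rvar + BN_MOMENTUM * v
  } else {
    mu <- ly$rmean
    v <- ly$rvar
  }
  istd <- 1 / sqrt(v + BN_EPS)
  dims <- lapply(xs, dim)
  xhats <- lapply(mats, function(m)
    (m - rep(mu, each = nrow(m))) * rep(istd, each = nrow(m)))
  ys <- mapply(function(xh, d)
    array(xh * rep(ly$gamma, each = nrow(xh)) +
            rep(ly$beta, each = nrow(xh)), d),
    xhats, dims, SIMPLIFY = FALSE)
  list(ys = ys, cache = list(xhats = xhats, istd = istd, dims = dims,
                             Ntot = Ntot))
}

bn_backward <- function(dys, cache, gamma) {
  dmats <- lapply(dys, as_channel_mat)
  dxhats <- lapply(dmats, function(m) m * rep(gamma, each = nrow(m)))
  S1 <- Reduce(`+`, lapply(dxhats, colSums))
  S2 <- Reduce(`+`, mapply(function(dxh, xh) colSums(dxh * xh),
                           dxhats, cache$xhats, SIMPLIFY = FALSE))
  dgamma <- Reduce(`+`, mapply(function(dm, xh) colSums(dm * xh),
                               dmats, cache$xhats, SIMPLIFY = FALSE))
  dbeta <- Reduce(`+`, lapply(dmats, colSums))
  N <- cache$Ntot
  dxs <- mapply(function(dxh, xh, d) {
    m <- rep(cache$istd / N, each = nrow(dxh)) *
      (N * dxh - rep(S1, each = nrow(dxh)) - xh * rep(S2, each = nrow(xh)))
    array(m, d)
  }, dxhats, cache$xhats, cache$dims, SIMPLIFY = FALSE)
  list(dxs = dxs, dgamma = dgamma, dbeta = dbeta)
}

# xs: list of samples; returns outs (list) and per-layer caches
net_forward <- function(net, xs, train = FALSE) {
  caches <- vector("list", length(net))
  for (l in seq_along(net)) {
    ly <- net[[l]]
    if (ly$kind == "conv") {
      if (train) {
        rs <- lapply(xs, function(x)
          conv_forward_train_cpp(x, ly$W, ly$kh, ly$kw, ly$stride, ly$pad))
        cache <- list(cols = lapply(rs, `[[`, "cols"),
                      indims = lapply(xs, dim))
        xs <- lapply(rs, `[[`, "out")
      } else {
        cache <- list()
        xs <- lapply(xs, function(x)
          conv_forward_cpp(x, ly$W, ly$kh, ly$kw, ly$stride, ly$pad))
      }
      if (!is.null(ly$b))
        xs <- lapply(xs, function(x)
          x + rep(ly$b, each = dim(x)[1] * dim(x)[2]))
      if (isTRUE(ly$bn)) {
        r <- bn_forward(xs, ly, train)
        xs <- r$ys
        cache$bn <- r$cache
      }
      if (isTRUE(ly$relu)) {
        cache$masks <- lapply(xs, function(x) x > 0)
        xs <- mapply(`*`, xs, cache$masks, SIMPLIFY = FALSE)
      }
      caches[[l]] <- cache
    } else {
      cache <- list(indims = lapply(xs, dim))
      rs <- lapply(xs, function(x) maxpool_forward_cpp(x, ly$kh, ly$stride))
      xs <- lapply(rs, `[[`, "out")
      cache$argmax <- lapply(rs, `[[`, "argmax")
      caches[[l]] <- cache
    }
  }
  list(outs = xs, caches = caches)
}

# single-sample convenience wrapper (inference paths)
net_forward1 <- function(net, x, train = FALSE) {
  r <- net_forward(net, list(x), train = train)
  list(out = r$outs[[1]], caches = r$caches)
}

# douts: list matching the batch; parameter gradients are summed over the
# batch (callers scale douts by 1/B for an averaged step)
net_backward <- function(net, caches, douts) {
  grads <- vector("list", length(net))
  for (l in rev(seq_along(net))) {
    ly <- net[[l]]; cache <- caches[[l]]
    if (ly$kind == "conv") {
      g <- list()
      if (isTRUE(ly$relu))
        douts <- mapply(`*`, douts, cache$masks, SIMPLIFY = FALSE)
      if (isTRUE(ly$bn)) {
        r <- bn_backward(douts, cache$bn, ly$gamma)
        douts <- r$dxs
        g$dgamma <- r$dgamma; g$dbeta <- r$dbeta
      }
      if (!is.null(ly$b))
        g$db <- Reduce(`+`, lapply(douts, function(d) apply(d, 3L, sum)))
      dW <- NULL
      dxs <- vector("list", length(douts))
      for (s in seq_along(douts)) {
        id <- cache$indims[[s]]
        cb <- conv_backward_cpp(cache$cols[[s]], ly$W, douts[[s]],
                                id[1], id[2], id[3],
                                ly$kh, ly$kw, ly$stride, ly$pad)
        dW <- if (is.null(dW)) cb$dW else dW + cb$dW
        dxs[[s]] <- cb$dx
      }
      g$dW <- dW
      douts <- dxs
      grads[[l]] <- g
    } else {
      douts <- mapply(function(d, am, id)
        maxpool_backward_cpp(d, am, id[1], id[2], id[3]),
        douts, cache$argmax, cache$indims, SIMPLIFY = FALSE)
      grads[[l]] <- list()
    }
  }
  list(grads = grads, dxs = douts)
}

# Plain SGD, optional classical momentum (velocity buffers live in the layer
# environments). L2 weight decay applies to conv weights only — batch-norm
# scale/shift and the read-out bias are left unregularized, the usual
# convention.
sgd_step <- function(net, grads, lr, momentum = 0, weight_decay = 0) {
  for (l in seq_along(net)) {
    ly <- net[[l]]; g <- grads[[l]]
    if (is.null(g) || ly$kind != "conv") next
    if (weight_decay > 0 && !is.null(g$dW)) g$dW <- g$dW + weight_decay * ly$W
    upd <- function(pname, gval) {
      if (is.null(gval)) return()
      if (momentum > 0) {
        vname <- paste0("v_", pname)
        v <- if (exists(vname, envir = ly, inherits = FALSE)) ly[[vname]] else 0
        v <- momentum * v + gval
        ly[[vname]] <- v
        ly[[pname]] <- ly[[pname]] - lr * v
      } else {
        ly[[pname]] <- ly[[pname]] - lr * gval
      }
    }
    upd("W", g$dW)
    if (!is.null(ly$b)) upd("b", g$db)
    if (isTRUE(ly$bn)) { upd("gamma", g$dgamma); upd("beta", g$dbeta) }
  }
  invisible(net)
}

# deep copy of the parameter state (used to retain best-validation weights
# and for checkpoint serialization)
net_state <- function(net) {
  lapply(net, function(ly) as.list(ly))
}

net_from_state <- function(state) {
  lapply(state, function(s) list2env(s, envir = new.env(parent = emptyenv())))
}
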