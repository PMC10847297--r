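# Network engine: compiles a dpae_arch into parameter tensors and
# provides forward/backward passes and an Adam step. Activations flow as
# matrices (batch x width) for vector layers and 3-D arrays
# (batch x time x channels) for convolution/GRU stages.

SELU_ALPHA <- 1.6732632423543772
SELU_SCALE <- 1.0507009873554805

selu <- function(x) SELU_SCALE * ifelse(x > 0, x, SELU_ALPHA * (exp(x) - 1))
selu_grad <- function(x) SELU_SCALE * ifelse(x > 0, 1, SELU_ALPHA * exp(x))
sigmoid <- function(x) 1 / (1 + exp(-x))

# column-wise bias add for a batch x width matrix
addbias <- function(z, b) z + rep(b, each = nrow(z))

lecun_mat <- function(nin, nout, fan_in = nin)
  matrix(stats::rnorm(nin * nout, sd = 1 / sqrt(fan_in)), nin, nout)

#' Instantiate a trainable model from an architecture
#'
#' Allocates and initializes all parameter tensors (LeCun-normal weights,
#' the standard initialization for SeLU networks; zero biases; unit batch
#' normalization scale). Initialization is deterministic given the seed.
#'
#' @param spec a `dpae_arch` from [dpae_spec], [dpae_mlp_canonical] or
#'   [fcnn_spec].
#' @param seed integer seed controlling weight initialization.
#' @return A `dpae_model`: list with the `spec`, compiled `nodes`,
#'   parameter list `params` and batch-normalization `state`.
#' @export
build_model <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "dpae_arch"))
  shapes <- arch_shapes(spec)
  name2idx <- stats::setNames(seq_along(spec$layers), names(spec$layers))
  nodes <- vector("list", length(spec$layers))
  params <- list()
  state <- list()
  withr::with_seed(seed, {
    for (i in seq_along(spec$layers)) {
      l <- spec$layers[[i]]
      nd <- list(name = l$name, kind = l$kind,
                 inputs = unname(name2idx[l$inputs]),
                 activation = l$activation, shape = shapes[[l$name]])
      if (l$kind %in% c("dense", "output")) {
        w_in <- shapes[[l$inputs[1]]]$width
        nd$in_w <- w_in; nd$out_w <- l$width
        params[[paste0(l$name, ".W")]] <- lecun_mat(w_in, l$width)
        params[[paste0(l$name, ".b")]] <- numeric(l$width)
      } else if (l$kind == "batchnorm") {
        w <- shapes[[l$name]]$width
        nd$width <- w
        params[[paste0(l$name, ".gamma")]] <- rep(1, w)
        params[[paste0(l$name, ".beta")]] <- numeric(w)
        state[[paste0(l$name, ".mean")]] <- numeric(w)
        state[[paste0(l$name, ".var")]] <- rep(1, w)
      } else if (l$kind == "conv") {
        sh_in <- shapes[[l$inputs[1]]]
        nd$kernel <- l$kernel; nd$stride <- l$stride
        nd$cin <- sh_in$ch; nd$cout <- l$channels
        nd$in_len <- sh_in$len; nd$out_len <- shapes[[l$name]]$len
        params[[paste0(l$name, ".W")]] <-
          lecun_mat(l$kernel * sh_in$ch, l$channels)
        params[[paste0(l$name, ".b")]] <- numeric(l$channels)
      } else if (l$kind == "gru") {
        f <- shapes[[l$inputs[1]]]$ch; h <- l$units
        nd$f <- f; nd$h <- h; nd$T <- shapes[[l$name]]$len
        params[[paste0(l$name, ".Wx")]] <- lecun_mat(f, 3 * h, fan_in = f)
        params[[paste0(l$name, ".Wh")]] <- lecun_mat(h, 3 * h, fan_in = h)
        params[[paste0(l$name, ".bx")]] <- numeric(3 * h)
        params[[paste0(l$name, ".bh")]] <- numeric(3 * h)
      } else if (l$kind == "concat") {
        nd$in_widths <- vapply(l$inputs,
                               function(nm) shapes[[nm]]$width, numeric(1))
      }
      nodes[[i]] <- nd
    }
  })
  structure(list(spec = spec, nodes = nodes, params = params, state = state,
                 seed = seed),
            class = "dpae_model")
}

#' @export
print.dpae_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<dpae_model> backbone=%s, input_len=%d, %s parameters (seed %d)\n",
              x$spec$backbone, x$spec$input_len,
              format(np, big.mark = ","), x$seed))
  invisible(x)
}

# im2col for 1-D strided convolution: (n, L, Cin) -> (n * Lout, k * Cin)
im2col <- function(x, k, stride, out_len) {
  n <- dim(x)[1]; cin <- dim(x)[3]
  starts <- (seq_len(out_len) - 1L) * stride + 1L
  col <- array(0, c(n, out_len, k * cin))
  for (j in seq_len(k)) {
    col[, , ((j - 1L) * cin + 1L):(j * cin)] <- x[, starts + j - 1L, , drop = FALSE]
  }
  dim(col) <- c(n * out_len, k * cin)
  col
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# Forward pass. Returns the output matrix, per-node caches (when
# training) and updated batch-norm running statistics.
nn_forward <- function(model, X, training = FALSE) {
  nodes <- model$nodes; params <- model$params; state <- model$state
  n <- nrow(X)
  acts <- vector("list", length(nodes))
  caches <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    pfx <- nd$name
    if (nd$kind == "input") {
      acts[[i]] <- if (model$spec$backbone == "mlp") X
                   else array(X, c(n, ncol(X), 1L))
    } else if (nd$kind %in% c("dense", "output")) {
      xin <- acts[[nd$inputs[1]]]
      z <- addbias(xin %*% params[[paste0(pfx, ".W")]],
                   params[[paste0(pfx, ".b")]])
      a <- if (nd$activation == "selu") selu(z) else z
      if (training) caches[[i]] <- list(z = z)
      acts[[i]] <- a
    } else if (nd$kind == "batchnorm") {
      xin <- acts[[nd$inputs[1]]]
      g <- params[[paste0(pfx, ".gamma")]]
      be <- params[[paste0(pfx, ".beta")]]
      if (training) {
        mu <- colMeans(xin)
        xc <- xin - rep(mu, each = n)
        v <- colMeans(xc^2)
        inv <- 1 / sqrt(v + BN_EPS)
        xhat <- xc * rep(inv, each = n)
        state[[paste0(pfx, ".mean")]] <-
          BN_MOMENTUM * state[[paste0(pfx, ".mean")]] + (1 - BN_MOMENTUM) * mu
        state[[paste0(pfx, ".var")]] <-
          BN_MOMENTUM * state[[paste0(pfx, ".var")]] + (1 - BN_MOMENTUM) * v
        caches[[i]] <- list(xhat = xhat, inv = inv)
      } else {
        mu <- state[[paste0(pfx, ".mean")]]
        v <- state[[paste0(pfx, ".var")]]
        xhat <- (xin - rep(mu, each = n)) * rep(1 / sqrt(v + BN_EPS), each = n)
      }
      acts[[i]] <- xhat * rep(g, each = n) + rep(be, each = n)
    } else if (nd$kind == "concat") {
      acts[[i]] <- do.call(cbind, acts[nd$inputs])
    } else if (nd$kind == "add") {
      acts[[i]] <- acts[[nd$inputs[1]]] + acts[[nd$inputs[2]]]
    } else if (nd$kind == "flatten") {
      xin <- acts[[nd$inputs[1]]]
      d <- dim(xin)
      dim(xin) <- c(d[1], d[2] * d[3])
      acts[[i]] <- xin
    } else if (nd$kind == "last") {
      xin <- acts[[nd$inputs[1]]]
      a <- xin[, dim(xin)[2], , drop = FALSE]
      dim(a) <- c(dim(xin)[1], dim(xin)[3])
      acts[[i]] <- a
    } else if (nd$kind == "conv") {
      xin <- acts[[nd$inputs[1]]]
      col <- im2col(xin, nd$kernel, nd$stride, nd$out_len)
      z <- addbias(col %*% params[[paste0(pfx, ".W")]],
                   params[[paste0(pfx, ".b")]])
      a <- if (nd$activation == "selu") selu(z) else z
      if (training) caches[[i]] <- list(col = col, z = z)
      dim(a) <- c(n, nd$out_len, nd$cout)
      acts[[i]] <- a
    } else if (nd$kind == "gru") {
      xin <- acts[[nd$inputs[1]]]
      f <- nd$f; h <- nd$h; Tn <- nd$T
      Wx <- params[[paste0(pfx, ".Wx")]]; Wh <- params[[paste0(pfx, ".Wh")]]
      bx <- params[[paste0(pfx, ".bx")]]; bh <- params[[paste0(pfx, ".bh")]]
      xm <- xin; dim(xm) <- c(n * Tn, f)
      gx <- addbias(xm %*% Wx, bx)
      Y <- array(0, c(n, Tn, h))
      hs <- matrix(0, n, h)
      if (training) {
        Rr <- array(0, c(n, Tn, h)); Zz <- Rr; Nn <- Rr; Gn <- Rr
        Hprev <- array(0, c(n, Tn, h))
      }
      ir <- 1:h; iz <- (h + 1):(2 * h); inn <- (2 * h + 1):(3 * h)
      for (t in seq_len(Tn)) {
        gxt <- gx[(t - 1L) * n + seq_len(n), , drop = FALSE]
        gh <- addbias(hs %*% Wh, bh)
        r <- sigmoid(gxt[, ir, drop = FALSE] + gh[, ir, drop = FALSE])
        zg <- sigmoid(gxt[, iz, drop = FALSE] + gh[, iz, drop = FALSE])
        ghn <- gh[, inn, drop = FALSE]
        nn <- tanh(gxt[, inn, drop = FALSE] + r * ghn)
        if (training) {
          Rr[, t, ] <- r; Zz[, t, ] <- zg; Nn[, t, ] <- nn
          Gn[, t, ] <- ghn; Hprev[, t, ] <- hs
        }
        hs <- (1 - zg) * nn + zg * hs
        Y[, t, ] <- hs
      }
      if (training)
        caches[[i]] <- list(xm = xm, Rr = Rr, Zz = Zz, Nn = Nn, Gn = Gn,
                            Hprev = Hprev)
      acts[[i]] <- Y
    } else stop("unknown node kind: ", nd$kind)
  }
  list(output = acts[[length(nodes)]], acts = acts, caches = caches,
       state = state)
}

# Backward pass: returns gradients for every parameter, given the
# gradient of the loss w.r.t. the network output.
nn_backward <- function(model, fwd, dout) {
  nodes <- model$nodes; params <- model$params
  acts <- fwd$acts; caches <- fwd$caches
  grads <- list()
  dacts <- vector("list", length(nodes))
  dacts[[length(nodes)]] <- dout
  acc <- function(store, idx, g) {
    if (is.null(store[[idx]])) store[[idx]] <- g
    else store[[idx]] <- store[[idx]] + g
    store
  }
  for (i in rev(seq_along(nodes))) {
    nd <- nodes[[i]]
    dy <- dacts[[i]]
    if (is.null(dy) || nd$kind == "input") next
    pfx <- nd$name
    if (nd$kind %in% c("dense", "output")) {
      dz <- if (nd$activation == "selu") dy * selu_grad(caches[[i]]$z) else dy
      xin <- acts[[nd$inputs[1]]]
      grads[[paste0(pfx, ".W")]] <- crossprod(xin, dz)
      grads[[paste0(pfx, ".b")]] <- colSums(dz)
      dacts <- acc(dacts, nd$inputs[1],
                   tcrossprod(dz, params[[paste0(pfx, ".W")]]))
    } else if (nd$kind == "batchnorm") {
      n <- nrow(dy)
      ch <- caches[[i]]
      g <- params[[paste0(pfx, ".gamma")]]
      grads[[paste0(pfx, ".gamma")]] <- colSums(dy * ch$xhat)
      grads[[paste0(pfx, ".beta")]] <- colSums(dy)
      dxhat <- dy * rep(g, each = n)
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * ch$xhat)
      dx <- (dxhat - rep(s1 / n, each = n) -
               ch$xhat * rep(s2 / n, each = n)) * rep(ch$inv, each = n)
      dacts <- acc(dacts, nd$inputs[1], dx)
    } else if (nd$kind == "concat") {
      off <- 0L
      for (j in seq_along(nd$inputs)) {
        w <- nd$in_widths[j]
        dacts <- acc(dacts, nd$inputs[j], dy[, (off + 1L):(off + w),
                                             drop = FALSE])
        off <- off + w
      }
    } else if (nd$kind == "add") {
      dacts <- acc(dacts, nd$inputs[1], dy)
      dacts <- acc(dacts, nd$inputs[2], dy)
    } else if (nd$kind == "flatten") {
      xin <- acts[[nd$inputs[1]]]
      dim(dy) <- dim(xin)
      dacts <- acc(dacts, nd$inputs[1], dy)
    } else if (nd$kind == "last") {
      xin <- acts[[nd$inputs[1]]]
      dx <- array(0, dim(xin))
      dx[, dim(xin)[2], ] <- dy
      dacts <- acc(dacts, nd$inputs[1], dx)
    } else if (nd$kind == "conv") {
      n <- dim(dy)[1]
      dim(dy) <- c(n * nd$out_len, nd$cout)
      dz <- if (nd$activation == "selu") dy * selu_grad(caches[[i]]$z) else dy
      col <- caches[[i]]$col
      grads[[paste0(pfx, ".W")]] <- crossprod(col, dz)
      grads[[paste0(pfx, ".b")]] <- colSums(dz)
      dcol <- tcrossprod(dz, params[[paste0(pfx, ".W")]])
      dim(dcol) <- c(n, nd$out_len, nd$kernel * nd$cin)
      dx <- array(0, c(n, nd$in_len, nd$cin))
      starts <- (seq_len(nd$out_len) - 1L) * nd$stride + 1L
      for (j in seq_len(nd$kernel)) {
        idx <- starts + j - 1L
        dx[, idx, ] <- dx[, idx, , drop = FALSE] +
          dcol[, , ((j - 1L) * nd$cin + 1L):(j * nd$cin), drop = FALSE]
      }
      dacts <- acc(dacts, nd$inputs[1], dx)
    } else if (nd$kind == "gru") {
      ch <- caches[[i]]
      n <- dim(dy)[1]; h <- nd$h; Tn <- nd$T; f <- nd$f
      Wx <- params[[paste0(pfx, ".Wx")]]; Wh <- params[[paste0(pfx, ".Wh")]]
      dWh <- matrix(0, h, 3 * h)
      dAx <- matrix(0, n * Tn, 3 * h)
      dbh <- numeric(3 * h)
      dnext <- matrix(0, n, h)
      for (t in rev(seq_len(Tn))) {
        dh <- dy[, t, ] + dnext
        if (is.null(dim(dh))) dim(dh) <- c(n, h)
        r <- ch$Rr[, t, , drop = FALSE];  dim(r) <- c(n, h)
        zg <- ch$Zz[, t, , drop = FALSE]; dim(zg) <- c(n, h)
        nn <- ch$Nn[, t, , drop = FALSE]; dim(nn) <- c(n, h)
        ghn <- ch$Gn[, t, , drop = FALSE]; dim(ghn) <- c(n, h)
        hprev <- ch$Hprev[, t, , drop = FALSE]; dim(hprev) <- c(n, h)
        daz <- dh * (hprev - nn) * zg * (1 - zg)
        dan <- dh * (1 - zg) * (1 - nn^2)
        dar <- dan * ghn * r * (1 - r)
        dah <- cbind(dar, daz, dan * r)
        dAx[(t - 1L) * n + seq_len(n), ] <- cbind(dar, daz, dan)
        dWh <- dWh + crossprod(hprev, dah)
        dbh <- dbh + colSums(dah)
        dnext <- dh * zg + tcrossprod(dah, Wh)
      }
      grads[[paste0(pfx, ".Wx")]] <- crossprod(ch$xm, dAx)
      grads[[paste0(pfx, ".Wh")]] <- dWh
      grads[[paste0(pfx, ".bx")]] <- colSums(dAx)
      grads[[paste0(pfx, ".bh")]] <- dbh
      dxm <- tcrossprod(dAx, Wx)
      dim(dxm) <- c(n, Tn, f)
      dacts <- acc(dacts, nd$inputs[1], dxm)
    }
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(params = params, opt = opt)
}

#' Forward a batch of segments through a model
#'
#' Inference-mode forward pass (batch normalization uses running
#' statistics); deterministic.
#'
#' @param model a `dpae_model`.
#' @param X matrix with one segment per row (`input_len` columns).
#' @return Matrix of the same shape with the reconstructed segments.
#' @export
predict_segments <- function(model, X) {
  stopifnot(inherits(model, "dpae_model"))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != model$spec$input_len)
    stop("segment length ", ncol(X), " != model input length ",
         model$spec$input_len)
  if (isTRUE(model$rms_scale)) {
    # model was trained on per-segment RMS-scaled pairs; apply the same
    # scaling at inference and restore the amplitude afterwards
    sc <- sqrt(rowMeans(X^2))
    sc[sc == 0] <- 1
    return(nn_forward(model, X / sc, training = FALSE)$output * sc)
  }
  nn_forward(model, X, training = FALSE)$output
}
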