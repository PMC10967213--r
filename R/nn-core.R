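# Internal neural-network engine.
#
# Feature maps are stored as (n_samples * n_positions) x channels matrices,
# rows sample-major: row (i-1)*P + p holds sample i, grid position p, with
# positions numbered row-major over the grid. All convolutions reduce to
# BLAS matmuls or indexed adds on this representation.

# column-wise scale / shift without sweep()'s dispatch overhead
colscale <- function(x, v) x * rep(v, each = nrow(x))
colshift <- function(x, v) x + rep(v, each = nrow(x))

# activation with cached auxiliary value (GELU reuses Phi = pnorm(x) in the
# backward pass, which dominates otherwise)
act_forward <- function(name, x) {
  if (name == "gelu") {
    phi <- stats::pnorm(x)
    list(y = x * phi, aux = phi)
  } else if (name == "relu") {
    list(y = pmax(x, 0), aux = NULL)
  } else stop("unknown activation: ", name)
}

act_grad <- function(name, x, aux = NULL) {
  if (name == "gelu") {
    if (is.null(aux)) aux <- stats::pnorm(x)
    aux + x * stats::dnorm(x)
  } else if (name == "relu") {
    (x > 0) + 0
  } else stop("unknown activation: ", name)
}

act_fun <- function(name) {
  list(f = function(x) act_forward(name, x)$y,
       g = function(x) act_grad(name, x))
}

# ---- batch normalization (per channel over all rows) ----

bn_init <- function(channels) {
  list(gamma = rep(1, channels), beta = rep(0, channels),
       rm = rep(0, channels), rv = rep(1, channels))
}

bn_forward <- function(x, par, train, momentum = 0.1, eps = 1e-5) {
  if (train) {
    mu <- colMeans(x)
    v <- colMeans(x * x) - mu^2
    v[v < 0] <- 0
    invsd <- 1 / sqrt(v + eps)
    xhat <- colscale(colshift(x, -mu), invsd)
    out <- colshift(colscale(xhat, par$gamma), par$beta)
    par$rm <- (1 - momentum) * par$rm + momentum * mu
    par$rv <- (1 - momentum) * par$rv + momentum * v
    list(out = out, par = par, cache = list(xhat = xhat, invsd = invsd))
  } else {
    invsd <- 1 / sqrt(par$rv + eps)
    out <- colshift(colscale(colshift(x, -par$rm), par$gamma * invsd),
                    par$beta)
    list(out = out, par = par, cache = list(invsd = invsd))
  }
}

bn_backward <- function(dy, par, cache, train) {
  if (train) {
    xhat <- cache$xhat
    dgamma <- colSums(dy * xhat)
    dbeta <- colSums(dy)
    m <- nrow(dy)
    t1 <- colshift(dy, -dbeta / m)
    t2 <- colscale(xhat, dgamma / m)
    dx <- colscale(t1 - t2, par$gamma * cache$invsd)
    list(dx = dx, dgamma = dgamma, dbeta = dbeta)
  } else {
    dx <- colscale(dy, par$gamma * cache$invsd)
    list(dx = dx, dgamma = colSums(dy * 0), dbeta = colSums(dy))
  }
}

# ---- depthwise convolution (3x3 default, stride 1, same padding) ----
#
# For each channel c the convolution over the P = grid^2 positions is a
# linear map S_c = sum_k W[c,k] * S_k, where S_k is the 0/1 shift pattern
# of kernel tap k (row-major taps, out-of-grid neighbors contribute 0).
# The tap patterns are stacked as a (P^2 x k^2) matrix so every channel's
# S_c comes from one matmul, and the conv itself becomes C small BLAS
# products against the (P x n) per-channel slices.

expand_rows <- function(pos, n, P) {
  rep((0:(n - 1)) * P, each = length(pos)) + pos
}

dw_tapmat <- function(grid_side, kernel = 3L) {
  half <- (kernel - 1L) %/% 2L
  P <- grid_side^2
  p <- seq_len(P)
  r <- (p - 1L) %/% grid_side + 1L
  c <- (p - 1L) %% grid_side + 1L
  Tm <- matrix(0, P * P, kernel^2)
  k <- 0L
  for (dr in -half:half) for (dc in -half:half) {
    k <- k + 1L
    rs <- r + dr; cs <- c + dc
    ok <- rs >= 1L & rs <= grid_side & cs >= 1L & cs <= grid_side
    src <- (rs[ok] - 1L) * grid_side + cs[ok]   # column of S_k
    dst <- p[ok]                                # row of S_k
    Tm[dst + (src - 1L) * P, k] <- 1
  }
  Tm
}

dw_forward <- function(x, W, b, Tm, n, P) {
  C <- ncol(x)
  Svec <- Tm %*% t(W)                 # P^2 x C, vec(S_c) column-major
  out <- matrix(0, nrow(x), C)
  for (c in seq_len(C)) {
    Sc <- matrix(Svec[, c], P, P)
    out[, c] <- Sc %*% matrix(x[, c], P, n)
  }
  colshift(out, b)
}

dw_backward <- function(dy, x, W, Tm, n, P) {
  C <- ncol(x)
  Svec <- Tm %*% t(W)
  dx <- matrix(0, nrow(x), C)
  vecM <- matrix(0, P * P, C)
  for (c in seq_len(C)) {
    Sc <- matrix(Svec[, c], P, P)
    dYc <- matrix(dy[, c], P, n)
    dx[, c] <- crossprod(Sc, dYc)
    vecM[, c] <- dYc %*% t(matrix(x[, c], P, n))
  }
  list(dx = dx, dW = crossprod(vecM, Tm), db = colSums(dy))
}

# ---- image -> patch matrix ----

# column indices into the flattened (n x H*W) image matrix for each
# (position, within-patch pixel), both row-major
patch_col_index <- function(patch_side, grid_side) {
  ps <- patch_side; gs <- grid_side
  H <- ps * gs
  P <- gs^2; K <- ps^2
  idx <- matrix(0L, P, K)
  for (p in seq_len(P)) {
    r <- (p - 1L) %/% gs + 1L
    cc <- (p - 1L) %% gs + 1L
    for (k in seq_len(K)) {
      a <- (k - 1L) %/% ps + 1L
      b <- (k - 1L) %% ps + 1L
      R <- (r - 1L) * ps + a
      C <- (cc - 1L) * ps + b
      idx[p, k] <- R + (C - 1L) * H
    }
  }
  idx
}

images_to_patchmat <- function(images, patch_side, grid_side) {
  d <- dim(images)
  n <- d[1L]
  stopifnot(d[2L] == patch_side * grid_side, d[3L] == d[2L])
  flat <- matrix(images, n, d[2L] * d[3L])
  P <- grid_side^2; K <- patch_side^2
  idx <- patch_col_index(patch_side, grid_side)
  Xp <- matrix(0, n * P, K)
  for (p in seq_len(P))
    Xp[(0:(n - 1)) * P + p, ] <- flat[, idx[p, ], drop = FALSE]
  Xp
}

# rows of the feature matrix that fall in blank grid slots
blank_row_index <- function(layout, n) {
  P <- layout$grid_side^2
  if (length(layout$blank_slots) == 0L) return(integer(0))
  expand_rows(layout$blank_slots, n, P)
}

mask_rows <- function(m, rows) {
  if (length(rows)) m[rows, ] <- 0
  m
}

# feature matrix <-> [n, channels, grid, grid] array
fmap_to_array <- function(m, n, grid_side) {
  P <- grid_side^2
  C <- ncol(m)
  a <- array(0, dim = c(n, C, grid_side, grid_side))
  for (p in seq_len(P)) {
    r <- (p - 1L) %/% grid_side + 1L
    cc <- (p - 1L) %% grid_side + 1L
    a[, , r, cc] <- m[(0:(n - 1)) * P + p, , drop = FALSE]
  }
  a
}

array_to_fmap <- function(a) {
  d <- dim(a)
  if (length(d) == 3L) { a <- array(a, c(1L, d)); d <- dim(a) }
  n <- d[1L]; C <- d[2L]; gs <- d[3L]
  stopifnot(d[4L] == gs)
  P <- gs^2
  m <- matrix(0, n * P, C)
  for (p in seq_len(P)) {
    r <- (p - 1L) %/% gs + 1L
    cc <- (p - 1L) %% gs + 1L
    m[(0:(n - 1)) * P + p, ] <- a[, , r, cc]
  }
  m
}

# ---- parameter initialization ----

smx_init_params <- function(cfg, patch_side) {
  K <- patch_side^2
  C <- cfg$channels
  kk <- cfg$depthwise_kernel^2
  params <- list(
    We = matrix(stats::rnorm(C * K, 0, sqrt(2 / K)), C, K),
    be = rep(0, C),
    bn0 = bn_init(C),
    blocks = lapply(seq_len(cfg$n_blocks), function(b) list(
      Wd = matrix(stats::rnorm(C * kk, 0, sqrt(2 / kk)), C, kk),
      bd = rep(0, C),
      bnd = bn_init(C),
      Wp = matrix(stats::rnorm(C * C, 0, sqrt(2 / C)), C, C),
      bp = rep(0, C),
      bnp = bn_init(C)
    )),
    w = stats::rnorm(C, 0, 1 / sqrt(C)),
    b = 0
  )
  params
}

# ---- forward pass ----
# returns logits, probs, pooled features, per-stage outputs, and caches
smx_forward_mat <- function(params, Xp, n, layout, cfg, train = FALSE,
                            keep = FALSE) {
  gs <- layout$grid_side
  P <- gs^2
  an <- cfg$activation
  taps <- dw_tapmat(gs, cfg$depthwise_kernel)
  br <- blank_row_index(layout, n)

  Z1 <- colshift(Xp %*% t(params$We), params$be)
  a1 <- act_forward(an, Z1)
  bn1 <- bn_forward(a1$y, params$bn0, train)
  params$bn0 <- bn1$par
  E <- mask_rows(bn1$out, br)

  stages <- list(embed = E)
  caches <- if (keep) list(Xp = Xp, Z1 = Z1, phi1 = a1$aux,
                           bn1 = bn1$cache) else NULL
  Xin <- E
  for (b in seq_len(cfg$n_blocks)) {
    blk <- params$blocks[[b]]
    Zd <- dw_forward(Xin, blk$Wd, blk$bd, taps, n, P)
    ad <- act_forward(an, Zd)
    bnd <- bn_forward(ad$y, blk$bnd, train)
    params$blocks[[b]]$bnd <- bnd$par
    R <- Xin + bnd$out
    Zp <- colshift(R %*% blk$Wp, blk$bp)
    ap <- act_forward(an, Zp)
    bnp <- bn_forward(ap$y, blk$bnp, train)
    params$blocks[[b]]$bnp <- bnp$par
    out <- mask_rows(bnp$out, br)
    stages[[paste0("block", b)]] <- out
    if (keep)
      caches[[paste0("block", b)]] <-
        list(Xin = Xin, Zd = Zd, phid = ad$aux, bnd = bnd$cache, R = R,
             Zp = Zp, phip = ap$aux, bnp = bnp$cache)
    Xin <- out
  }

  div <- if (identical(cfg$gap, "nonblank")) P - length(layout$blank_slots) else P
  pooled <- rowsum(Xin, group = rep(seq_len(n), each = P), reorder = FALSE) / div
  z <- drop(pooled %*% params$w) + params$b
  list(z = z, prob = stats::plogis(z), pooled = pooled, stages = stages,
       caches = caches, params = params, div = div, n = n)
}

# ---- backward pass ----
# dz: per-sample gradient of the scalar objective w.r.t. the logit.
# upto: NULL -> full parameter gradients; or a stage name ("embed",
# "block1", ...) -> returns the gradient w.r.t. that stage's output.
smx_backward_mat <- function(params, fw, layout, cfg, dz, train = FALSE,
                             upto = NULL) {
  n <- fw$n
  gs <- layout$grid_side
  P <- gs^2
  an <- cfg$activation
  taps <- dw_tapmat(gs, cfg$depthwise_kernel)
  br <- blank_row_index(layout, n)
  ca <- fw$caches
  if (is.null(ca)) stop("forward pass was run without keep = TRUE")

  grads <- list()
  dzm <- matrix(dz, ncol = 1L)
  grads$w <- drop(t(fw$pooled) %*% dzm)
  grads$b <- sum(dz)
  dpooled <- dzm %*% matrix(params$w, nrow = 1L)
  dout <- dpooled[rep(seq_len(n), each = P), , drop = FALSE] / fw$div

  grads$blocks <- vector("list", cfg$n_blocks)
  for (b in rev(seq_len(cfg$n_blocks))) {
    # dout is the gradient w.r.t. this block's (masked) output
    if (identical(upto, paste0("block", b))) return(dout)
    blk <- params$blocks[[b]]
    cb <- ca[[paste0("block", b)]]
    d <- mask_rows(dout, br)                      # mask backward
    bb <- bn_backward(d, blk$bnp, cb$bnp, train)
    dZp <- bb$dx * act_grad(an, cb$Zp, cb$phip)
    gWp <- t(cb$R) %*% dZp
    gbp <- colSums(dZp)
    dR <- dZp %*% t(blk$Wp)
    dXin <- dR                                    # residual branch
    bd <- bn_backward(dR, blk$bnd, cb$bnd, train)
    dZd <- bd$dx * act_grad(an, cb$Zd, cb$phid)
    dwb <- dw_backward(dZd, cb$Xin, blk$Wd, taps, n, P)
    dXin <- dXin + dwb$dx
    grads$blocks[[b]] <- list(Wd = dwb$dW, bd = dwb$db,
                              bnd = list(gamma = bd$dgamma, beta = bd$dbeta),
                              Wp = gWp, bp = gbp,
                              bnp = list(gamma = bb$dgamma, beta = bb$dbeta))
    dout <- dXin
  }

  if (identical(upto, "embed")) return(dout)
  d <- mask_rows(dout, br)
  b0 <- bn_backward(d, params$bn0, ca$bn1, train)
  dZ1 <- b0$dx * act_grad(an, ca$Z1, ca$phi1)
  grads$We <- t(dZ1) %*% ca$Xp
  grads$be <- colSums(dZ1)
  grads$bn0 <- list(gamma = b0$dgamma, beta = b0$dbeta)
  grads
}

# ---- Adam optimizer over the nested parameter list ----

adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

# flat walk over trainable leaves (running stats rm/rv are not trained);
# decoupled weight decay applies to convolution/linear weight matrices only
# (We, Wd, Wp, head w), never to biases or normalization parameters
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v, wd) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    p <- p - lr * mhat / (sqrt(vhat) + eps)
    if (wd > 0) p <- p - lr * wd * p
    list(p = p, m = m, v = v)
  }
  decayed <- c("We", "Wd", "Wp", "w")
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      nms <- names(p)
      for (i in seq_along(p)) {
        nm <- if (is.null(nms)) "" else nms[i]
        if (nm %in% c("rm", "rv")) next
        # gradients match by name where named (structures may order
        # fields differently), by position inside unnamed block lists
        gi <- if (nzchar(nm)) g[[nm]] else g[[i]]
        if (is.null(gi)) next
        if (is.list(p[[i]])) {
          r <- walk(p[[i]], gi, m[[i]], v[[i]])
        } else {
          wd <- if (nm %in% decayed) weight_decay else 0
          r <- upd(p[[i]], gi, m[[i]], v[[i]], wd)
        }
        p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
      }
      list(p = p, m = m, v = v)
    } else stop("unexpected parameter leaf")
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

smx_count_params <- function(params) {
  count <- function(x, nm = "") {
    if (is.list(x)) {
      s <- 0
      for (i in seq_along(x)) {
        n <- names(x)[i]
        if (!is.null(n) && n %in% c("rm", "rv")) next
        s <- s + count(x[[i]])
      }
      s
    } else length(x)
  }
  count(params)
}
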