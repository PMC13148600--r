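# Residual U-Net baseline: a self-supervised encoder-decoder trained on a
# single hologram through the same ASM forward model as the neural field.
# All layers (3x3/1x1 convolutions, 2x2 average pooling, nearest
# upsampling, residual blocks) and their reverse-mode gradients are
# implemented here on plain H x W x C arrays.

# ---- elementary layers ------------------------------------------------

# 3x3 "same" convolution via im2col; returns output and the column matrix
# needed for the backward pass.
conv3_fwd <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; Cin <- d[3]
  xp <- array(0, c(H + 2L, Wd + 2L, Cin))
  xp[2:(H + 1L), 2:(Wd + 1L), ] <- x
  col <- matrix(0, H * Wd, 9L * Cin)
  k <- 0L
  for (c in seq_len(Cin)) for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    col[, k] <- xp[di + seq_len(H), dj + seq_len(Wd), c]
  }
  y <- sweep(col %*% W, 2L, b, "+")
  list(y = array(y, c(H, Wd, ncol(W))), col = col)
}

conv3_bwd <- function(cache, W, dY, dims_in) {
  H <- dims_in[1]; Wd <- dims_in[2]; Cin <- dims_in[3]
  dY2 <- matrix(dY, H * Wd, dim(dY)[3])
  dW <- crossprod(cache$col, dY2)
  db <- colSums(dY2)
  dcol <- dY2 %*% t(W)
  dxp <- array(0, c(H + 2L, Wd + 2L, Cin))
  k <- 0L
  for (c in seq_len(Cin)) for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    dxp[di + seq_len(H), dj + seq_len(Wd), c] <-
      dxp[di + seq_len(H), dj + seq_len(Wd), c] + matrix(dcol[, k], H, Wd)
  }
  list(dx = dxp[2:(H + 1L), 2:(Wd + 1L), , drop = FALSE], dW = dW, db = db)
}

conv1_fwd <- function(x, W, b) {
  d <- dim(x)
  y <- sweep(matrix(x, d[1] * d[2], d[3]) %*% W, 2L, b, "+")
  array(y, c(d[1], d[2], ncol(W)))
}

conv1_bwd <- function(x, W, dY) {
  d <- dim(x)
  x2 <- matrix(x, d[1] * d[2], d[3])
  dY2 <- matrix(dY, d[1] * d[2], dim(dY)[3])
  list(dx = array(dY2 %*% t(W), d), dW = crossprod(x2, dY2),
       db = colSums(dY2))
}

pool2_fwd <- function(x) {
  d <- dim(x)
  o1 <- seq(1L, d[1], by = 2L); o2 <- seq(1L, d[2], by = 2L)
  (x[o1, o2, , drop = FALSE] + x[o1 + 1L, o2, , drop = FALSE] +
     x[o1, o2 + 1L, , drop = FALSE] + x[o1 + 1L, o2 + 1L, , drop = FALSE]) / 4
}

pool2_bwd <- function(dY, dims_in) {
  dx <- array(0, dims_in)
  o1 <- seq(1L, dims_in[1], by = 2L); o2 <- seq(1L, dims_in[2], by = 2L)
  q <- dY / 4
  dx[o1, o2, ] <- q; dx[o1 + 1L, o2, ] <- q
  dx[o1, o2 + 1L, ] <- q; dx[o1 + 1L, o2 + 1L, ] <- q
  dx
}

up2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

up2_bwd <- function(dY) {
  d <- dim(dY)
  o1 <- seq(1L, d[1], by = 2L); o2 <- seq(1L, d[2], by = 2L)
  dY[o1, o2, , drop = FALSE] + dY[o1 + 1L, o2, , drop = FALSE] +
    dY[o1, o2 + 1L, , drop = FALSE] + dY[o1 + 1L, o2 + 1L, , drop = FALSE]
}

abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

unbind3 <- function(x, n_first) {
  list(a = x[, , seq_len(n_first), drop = FALSE],
       b = x[, , -seq_len(n_first), drop = FALSE])
}

# ---- residual block ---------------------------------------------------

rb_params <- function(Cin, Cout) {
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  p <- list(W1 = glorot(9L * Cin, Cout), b1 = rep(0, Cout),
            W2 = glorot(9L * Cout, Cout), b2 = rep(0, Cout))
  if (Cin != Cout) p$Ws <- glorot(Cin, Cout)
  p
}

rb_fwd <- function(x, p) {
  c1 <- conv3_fwd(x, p$W1, p$b1)
  s1 <- swish(c1$y)
  c2 <- conv3_fwd(s1$a, p$W2, p$b2)
  skip <- if (is.null(p$Ws)) x else conv1_fwd(x, p$Ws, rep(0, ncol(p$Ws)))
  s2 <- swish(c2$y + skip)
  list(out = s2$a,
       cache = list(x = x, c1 = c1, s1 = s1, c2 = c2, d2 = s2$d))
}

rb_bwd <- function(cache, p, dOut) {
  dz <- dOut * cache$d2
  b2 <- conv3_bwd(cache$c2, p$W2, dz, dim(cache$s1$a))
  dz1 <- b2$dx * cache$s1$d
  b1 <- conv3_bwd(cache$c1, p$W1, dz1, dim(cache$x))
  dx <- b1$dx
  g <- list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db)
  if (is.null(p$Ws)) {
    dx <- dx + dz
  } else {
    bs <- conv1_bwd(cache$x, p$Ws, dz)
    dx <- dx + bs$dx
    g$Ws <- bs$dW
  }
  list(dx = dx, g = g)
}

# ---- network ----------------------------------------------------------

#' Residual U-Net configuration
#'
#' @param channels Encoder channel widths for the three downsampling
#'   stages (decoder widths mirror them).
#' @param phase_scale Scale applied to the sigmoid phase head (0.3 for the
#'   synthetic regime, 0.278 for the experimental one); the head output
#'   is the phase-shift magnitude, mapped to negative phase in the
#'   forward model and the returned map.
#' @param absorb_scale Scale applied to the leaky-ReLU absorbance head
#'   (0.03 synthetic / 0.1 experimental).
#' @param epochs,lr Training schedule (reference: 3e4 epochs at 1e-6 for
#'   the synthetic holograms).
#' @param leaky_alpha Negative slope of the absorbance head activation.
#' @param seed Weight-initialization seed.
#' @return A list of class `resunet_config`.
#' @export
resunet_config <- function(channels = c(32L, 64L, 128L), phase_scale = 0.3,
                           absorb_scale = 0.03, epochs = 30000L, lr = 1e-6,
                           leaky_alpha = 0.2, seed = 1L) {
  stopifnot(length(channels) == 3L, phase_scale > 0, absorb_scale > 0,
            epochs >= 1, lr > 0)
  structure(list(channels = channels, phase_scale = phase_scale,
                 absorb_scale = absorb_scale, epochs = as.integer(epochs),
                 lr = lr, leaky_alpha = leaky_alpha, seed = seed),
            class = "resunet_config")
}

resunet_init <- function(cfg) {
  ch <- cfg$channels
  with_seed(cfg$seed, list(
    e1 = rb_params(1L, ch[1]),
    e2 = rb_params(ch[1], ch[2]),
    e3 = rb_params(ch[2], ch[3]),
    bott = rb_params(ch[3], ch[3]),
    d3 = rb_params(2L * ch[3], ch[2]),
    d2 = rb_params(2L * ch[2], ch[1]),
    d1 = rb_params(2L * ch[1], ch[1]),
    ra = rb_params(ch[1], ch[1]),
    head_p = list(W = matrix(stats::rnorm(ch[1], sd = 0.1), ch[1], 1L),
                  b = 0),
    head_a = list(W = matrix(stats::rnorm(ch[1], sd = 0.1), ch[1], 1L),
                  b = 0)
  ))
}

resunet_fwd <- function(params, cfg, x) {
  e1 <- rb_fwd(x, params$e1);   p1 <- pool2_fwd(e1$out)
  e2 <- rb_fwd(p1, params$e2);  p2 <- pool2_fwd(e2$out)
  e3 <- rb_fwd(p2, params$e3);  p3 <- pool2_fwd(e3$out)
  bo <- rb_fwd(p3, params$bott)
  d3 <- rb_fwd(abind3(up2_fwd(bo$out), e3$out), params$d3)
  d2 <- rb_fwd(abind3(up2_fwd(d3$out), e2$out), params$d2)
  d1 <- rb_fwd(abind3(up2_fwd(d2$out), e1$out), params$d1)
  zp <- conv1_fwd(d1$out, params$head_p$W, params$head_p$b)
  sp <- sigmoid(zp[, , 1L])
  ra <- rb_fwd(d1$out, params$ra)
  za <- conv1_fwd(ra$out, params$head_a$W, params$head_a$b)[, , 1L]
  list(phase_mag = cfg$phase_scale * sp,
       absorb = cfg$absorb_scale * ifelse(za > 0, za, cfg$leaky_alpha * za),
       cache = list(e1 = e1, e2 = e2, e3 = e3, bo = bo,
                    d3 = d3, d2 = d2, d1 = d1, ra = ra, sp = sp, za = za))
}

resunet_bwd <- function(params, cfg, fw, dPhase, dAbsorb) {
  cc <- fw$cache
  dza <- dAbsorb * cfg$absorb_scale * ifelse(cc$za > 0, 1, cfg$leaky_alpha)
  ba <- conv1_bwd(cc$ra$out, params$head_a$W, array(dza, c(dim(dza), 1L)))
  bra <- rb_bwd(cc$ra$cache, params$ra, ba$dx)
  dzp <- dPhase * cfg$phase_scale * cc$sp * (1 - cc$sp)
  bp <- conv1_bwd(cc$d1$out, params$head_p$W, array(dzp, c(dim(dzp), 1L)))
  b1 <- rb_bwd(cc$d1$cache, params$d1, bp$dx + bra$dx)
  sp1 <- unbind3(b1$dx, dim(cc$d2$out)[3])       # -> up(d2), skip e1
  b2 <- rb_bwd(cc$d2$cache, params$d2, up2_bwd(sp1$a))
  sp2 <- unbind3(b2$dx, dim(cc$d3$out)[3])       # -> up(d3), skip e2
  b3 <- rb_bwd(cc$d3$cache, params$d3, up2_bwd(sp2$a))
  sp3 <- unbind3(b3$dx, dim(cc$bo$out)[3])       # -> up(bott), skip e3
  bb <- rb_bwd(cc$bo$cache, params$bott, up2_bwd(sp3$a))
  be3 <- rb_bwd(cc$e3$cache, params$e3,
                pool2_bwd(bb$dx, dim(cc$e3$out)) + sp3$b)
  be2 <- rb_bwd(cc$e2$cache, params$e2,
                pool2_bwd(be3$dx, dim(cc$e2$out)) + sp2$b)
  be1 <- rb_bwd(cc$e1$cache, params$e1,
                pool2_bwd(be2$dx, dim(cc$e1$out)) + sp1$b)
  list(e1 = be1$g, e2 = be2$g, e3 = be3$g, bott = bb$g,
       d3 = b3$g, d2 = b2$g, d1 = b1$g, ra = bra$g,
       head_p = list(W = bp$dW, b = bp$db),
       head_a = list(W = ba$dW, b = ba$db))
}

flatten_params <- function(p) unlist(p, recursive = FALSE)

unflatten_params <- function(flat, template) {
  out <- template
  for (nm in names(template)) {
    for (sub in names(template[[nm]])) {
      out[[nm]][[sub]] <- flat[[paste(nm, sub, sep = ".")]]
    }
  }
  out
}

#' Self-supervised ResUNet reconstruction of a single hologram
#'
#' Trains the residual U-Net on one hologram: the predicted (scaled) phase
#' and absorbance maps at the object plane are forward-propagated to the
#' detector with the ASM and the MSE against the input hologram is
#' minimized with Adam.  The phase head predicts the phase-shift
#' magnitude; the returned phase map carries the negative sign of
#' refractive-index-decrement materials.
#'
#' @param H A [hologram()].
#' @param grid A [wavefield_grid()]; the hologram side lengths must be
#'   divisible by 8 (three 2x downsamplings).
#' @param distance Object-detector distance in metres.
#' @param cfg A [resunet_config()].
#' @param verbose Print the loss every 20 epochs.
#' @return A [reconstruction_result()] with the loss history in details.
#' @export
resunet_reconstruct <- function(H, grid, distance, cfg = resunet_config(),
                                verbose = FALSE) {
  Hmat <- hologram_intensity(H)
  d <- dim(Hmat)
  if (any(d %% 8L != 0L)) {
    stop("hologram sides must be divisible by 8 for three pooling stages",
         call. = FALSE)
  }
  params <- resunet_init(cfg)
  template <- params
  Kf <- asm_transfer(grid, distance)
  x_in <- array(Hmat - mean(Hmat), c(d, 1L))  # zero-centred input
  flat <- flatten_params(params)
  state <- adam_init(flat)
  npix <- length(Hmat)
  loss_hist <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    fw <- resunet_fwd(params, cfg, x_in)
    Tobj <- exp(-1i * fw$phase_mag - fw$absorb)
    U0 <- prop_apply(Tobj, Kf)
    resid <- Mod(U0)^2 - Hmat
    loss <- mean(resid^2)
    if (!is.finite(loss)) {
      stop(sprintf("ResUNet training diverged at epoch %d", ep), call. = FALSE)
    }
    loss_hist[ep] <- loss
    gT <- prop_apply((2 * resid / npix) * U0, Conj(Kf))  # dL/dT*
    dPhase <- 2 * Re(Conj(gT) * (-1i) * Tobj)
    dAbsorb <- -2 * Re(Conj(gT) * Tobj)
    g <- resunet_bwd(params, cfg, fw, dPhase, dAbsorb)
    gflat <- flatten_params(g)[names(flat)]
    upd <- adam_step(flat, gflat, state, cfg$lr)
    flat <- upd$params; state <- upd$state
    params <- unflatten_params(flat, template)
    if (verbose && ep %% 20L == 0L) {
      message(sprintf("[resunet] epoch %d  loss = %.3e", ep, loss))
    }
  }
  fw <- resunet_fwd(params, cfg, x_in)
  reconstruction_result(
    phase = -fw$phase_mag, absorbance = fw$absorb,
    method = "resunet",
    details = list(loss = loss_hist, epochs = cfg$epochs,
                   channels = cfg$channels, lr = cfg$lr)
  )
}
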