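# Atrous convolutional segmentation network (ACNN): a residual encoder whose
# later stage trades stride for dilation, followed by atrous spatial pyramid
# pooling (ASPP) and bilinear upsampling back to input resolution. Trained
# with pixel-wise binary cross-entropy and an adaptive-moment gradient
# descent variant. Widths are scaled by a config factor so that desk-scale
# runs (tests, demos) finish in minutes on one CPU; the architecture family,
# not the exact layer table, is what matters at that scale.

#' Segmentation network configuration
#'
#' @param input_size `(rows, cols)`; must be divisible by 4 (the encoder's
#'   total stride).
#' @param width_scale multiplier on the base channel widths (1 = full model;
#'   1/8 is a typical desk-scale setting).
#' @param base_widths named base channel counts for `stem`, `stage1`,
#'   `stage2` and the ASPP branches.
#' @param atrous_rates dilation rates of the three dilated ASPP branches
#'   (distinct, >= 1); a 1x1 branch and a global-pooling branch are always
#'   present.
#' @param learning_rate,epochs,batch_size training hyperparameters.
#' @param seed RNG seed for weight initialisation and batch shuffling.
#' @param threshold probability cut for binarising predictions, in (0, 1).
#' @return A `SegConfig`.
#' @export
seg_config <- function(input_size = c(112L, 112L), width_scale = 1,
                       base_widths = c(stem = 64, stage1 = 128, stage2 = 256,
                                       aspp = 256),
                       atrous_rates = c(2L, 4L, 8L),
                       learning_rate = 3e-3, epochs = 200L, batch_size = 10L,
                       seed = 1L, threshold = 0.5) {
  stop_if(any(input_size %% 4 != 0),
          "input_size must be divisible by the encoder's total stride (4)")
  stop_if(anyDuplicated(atrous_rates) > 0 || any(atrous_rates < 1),
          "atrous rates must be distinct and >= 1")
  stop_if(threshold <= 0 || threshold >= 1, "threshold must lie in (0, 1)")
  widths <- pmax(1L, as.integer(round(base_widths * width_scale)))
  names(widths) <- names(base_widths)
  structure(list(input_size = as.integer(input_size), width_scale = width_scale,
                 widths = widths, atrous_rates = as.integer(atrous_rates),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 threshold = threshold),
            class = "SegConfig")
}

he_init <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

new_conv <- function(kh, kw, cin, cout, stride = 1L, pad = 0L, dil = 1L) {
  list(w = he_init(kh, kw, cin, cout), b = numeric(cout),
       stride = as.integer(stride), pad = as.integer(pad), dil = as.integer(dil))
}

#' Build an (untrained) atrous segmentation network
#'
#' Layer plan: 3x3 stem conv (stride 2) -> residual stage 1 (stride 2) ->
#' residual stage 2 (stride 1, dilation 2) -> ASPP (1x1 branch, three dilated
#' 3x3 branches at the configured rates, global-average-pooling branch;
#' concatenated and projected) -> 1x1 head -> bilinear upsampling to input
#' resolution -> sigmoid. Weight initialisation is deterministic given the
#' config seed.
#'
#' @param config a [seg_config()].
#' @return A `SegModel` with fields `params`, `config`, `history`.
#' @export
build_acnn <- function(config = seg_config()) {
  w <- config$widths
  r <- config$atrous_rates
  params <- with_seed(config$seed, list(
    stem   = new_conv(3, 3, 1, w["stem"], stride = 2, pad = 1),
    res1a  = new_conv(3, 3, w["stem"], w["stage1"], stride = 2, pad = 1),
    res1b  = new_conv(3, 3, w["stage1"], w["stage1"], pad = 1),
    short1 = new_conv(1, 1, w["stem"], w["stage1"], stride = 2),
    res2a  = new_conv(3, 3, w["stage1"], w["stage2"], pad = 2, dil = 2),
    res2b  = new_conv(3, 3, w["stage2"], w["stage2"], pad = 2, dil = 2),
    short2 = new_conv(1, 1, w["stage1"], w["stage2"]),
    aspp0  = new_conv(1, 1, w["stage2"], w["aspp"]),
    aspp1  = new_conv(3, 3, w["stage2"], w["aspp"], pad = r[1], dil = r[1]),
    aspp2  = new_conv(3, 3, w["stage2"], w["aspp"], pad = r[2], dil = r[2]),
    aspp3  = new_conv(3, 3, w["stage2"], w["aspp"], pad = r[3], dil = r[3]),
    asppP  = new_conv(1, 1, w["stage2"], w["aspp"]),
    proj   = new_conv(1, 1, 5 * w["aspp"], w["aspp"]),
    head   = new_conv(1, 1, w["aspp"], 1)
  ))
  structure(list(params = params, config = config, history = numeric(0)),
            class = "SegModel")
}

#' Total trainable parameter count of a SegModel
#' @param model a `SegModel`.
#' @return integer.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$w) + length(p$b), numeric(1)))
}

conv_f <- function(p, x) conv2d_fwd(x, p$w, p$b, p$stride, p$pad, p$dil)
relu <- function(x) { x[x < 0] <- 0; x }

# forward pass; returns logits at input resolution plus the caches needed for
# backprop (pre-activation inputs of every conv / relu)
acnn_forward <- function(model, x) {
  p <- model$params
  cache <- list(x = x)
  z_stem <- conv_f(p$stem, x);            a_stem <- relu(z_stem)
  z1a <- conv_f(p$res1a, a_stem);         a1a <- relu(z1a)
  z1b <- conv_f(p$res1b, a1a)
  s1  <- conv_f(p$short1, a_stem)
  z1  <- z1b + s1;                        a1 <- relu(z1)
  z2a <- conv_f(p$res2a, a1);             a2a <- relu(z2a)
  z2b <- conv_f(p$res2b, a2a)
  s2  <- conv_f(p$short2, a1)
  z2  <- z2b + s2;                        a2 <- relu(z2)
  d <- dim(a2)  # (h, w, c, n)
  zb0 <- conv_f(p$aspp0, a2); ab0 <- relu(zb0)
  zb1 <- conv_f(p$aspp1, a2); ab1 <- relu(zb1)
  zb2 <- conv_f(p$aspp2, a2); ab2 <- relu(zb2)
  zb3 <- conv_f(p$aspp3, a2); ab3 <- relu(zb3)
  pool <- apply(a2, c(3, 4), mean)                       # (c, n)
  poolx <- array(pool, dim = c(1, 1, d[3], d[4]))
  zbp1 <- conv_f(p$asppP, poolx); abp1 <- relu(zbp1)     # (1,1,ca,n)
  ca <- dim(abp1)[3]
  abp <- array(rep(abp1, each = d[1] * d[2]), dim = c(d[1], d[2], ca, d[4]))
  cat_ <- array(0, dim = c(d[1], d[2], 5 * ca, d[4]))
  cat_[, , 1:ca, ] <- ab0;            cat_[, , ca + 1:ca, ] <- ab1
  cat_[, , 2 * ca + 1:ca, ] <- ab2;   cat_[, , 3 * ca + 1:ca, ] <- ab3
  cat_[, , 4 * ca + 1:ca, ] <- abp
  zp <- conv_f(p$proj, cat_); ap <- relu(zp)
  zh <- conv_f(p$head, ap)
  logits <- bilinear_up_fwd(zh, dim(x)[1], dim(x)[2])
  cache <- list(x = x, z_stem = z_stem, a_stem = a_stem, z1a = z1a, a1a = a1a,
                z1 = z1, a1 = a1, z2a = z2a, a2a = a2a, z2 = z2, a2 = a2,
                zb0 = zb0, zb1 = zb1, zb2 = zb2, zb3 = zb3,
                poolx = poolx, zbp1 = zbp1, abp1 = abp1,
                cat_ = cat_, zp = zp, ap = ap, zh = zh)
  list(logits = logits, cache = cache)
}

drelu <- function(g, z) { g[z <= 0] <- 0; g }

# exact gradients of every parameter given d(loss)/d(logits)
acnn_backward <- function(model, cache, g_logits) {
  p <- model$params; grads <- list()
  bwd <- function(name, xin, gy) {
    r <- conv2d_bwd(xin, p[[name]]$w, gy, p[[name]]$stride, p[[name]]$pad,
                    p[[name]]$dil)
    grads[[name]] <<- list(w = r$gw, b = r$gb)
    r$gx
  }
  g_zh <- bilinear_up_bwd(g_logits, dim(cache$zh)[1], dim(cache$zh)[2])
  g_ap <- bwd("head", cache$ap, g_zh)
  g_zp <- drelu(g_ap, cache$zp)
  g_cat <- bwd("proj", cache$cat_, g_zp)
  d <- dim(cache$a2); ca <- dim(cache$abp1)[3]
  g_a2 <- array(0, dim = d)
  g_a2 <- g_a2 + bwd("aspp0", cache$a2, drelu(g_cat[, , 1:ca, , drop = FALSE], cache$zb0))
  g_a2 <- g_a2 + bwd("aspp1", cache$a2, drelu(g_cat[, , ca + 1:ca, , drop = FALSE], cache$zb1))
  g_a2 <- g_a2 + bwd("aspp2", cache$a2, drelu(g_cat[, , 2 * ca + 1:ca, , drop = FALSE], cache$zb2))
  g_a2 <- g_a2 + bwd("aspp3", cache$a2, drelu(g_cat[, , 3 * ca + 1:ca, , drop = FALSE], cache$zb3))
  # pooling branch: broadcast backward = spatial sum; pool backward = 1/(h*w)
  g_abp <- g_cat[, , 4 * ca + 1:ca, , drop = FALSE]
  g_abp1 <- array(apply(g_abp, c(3, 4), sum), dim = c(1, 1, ca, d[4]))
  g_zbp1 <- drelu(g_abp1, cache$zbp1)
  g_poolx <- bwd("asppP", cache$poolx, g_zbp1)
  g_pool_full <- array(rep(g_poolx / (d[1] * d[2]), each = d[1] * d[2]), dim = d)
  g_a2 <- g_a2 + g_pool_full
  g_z2 <- drelu(g_a2, cache$z2)
  g_a1 <- bwd("short2", cache$a1, g_z2)
  g_a2a <- bwd("res2b", cache$a2a, g_z2)
  g_z2a <- drelu(g_a2a, cache$z2a)
  g_a1 <- g_a1 + bwd("res2a", cache$a1, g_z2a)
  g_z1 <- drelu(g_a1, cache$z1)
  g_astem <- bwd("short1", cache$a_stem, g_z1)
  g_a1a <- bwd("res1b", cache$a1a, g_z1)
  g_z1a <- drelu(g_a1a, cache$z1a)
  g_astem <- g_astem + bwd("res1a", cache$a_stem, g_z1a)
  g_zstem <- drelu(g_astem, cache$z_stem)
  bwd("stem", cache$x, g_zstem)
  grads
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# numerically safe per-pixel binary cross-entropy of logits vs {0,1} targets
bce_loss <- function(logits, y) {
  mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
}

frames_to_x <- function(frames) {
  if (is.list(frames)) frames <- array(unlist(frames),
                                       dim = c(dim(frames[[1]]), length(frames)))
  if (length(dim(frames)) == 2L) frames <- array(frames, dim = c(dim(frames), 1))
  array(frames, dim = c(dim(frames)[1], dim(frames)[2], 1, dim(frames)[3]))
}

#' Train the segmentation network
#'
#' Minimises mean pixel-wise binary cross-entropy with Adam (an adaptive
#' fixed-step gradient-descent variant) at the configured learning rate; no
#' augmentation. Batches are reshuffled each epoch under the config seed, so
#' a rerun with the same data and seed reproduces the same weights.
#'
#' @param model a `SegModel` from [build_acnn()].
#' @param frames `(row, col, frame)` array (or list of matrices) in \[0, 1\].
#' @param masks matching logical array/list of binary masks.
#' @param epochs overrides `config$epochs` when given.
#' @param verbose print the loss every 20 epochs.
#' @return The trained `SegModel`; `$history` holds the per-epoch mean loss.
#' @export
train_seg <- function(model, frames, masks, epochs = NULL, verbose = FALSE) {
  cfg <- model$config
  x_all <- frames_to_x(frames)
  y_all <- frames_to_x(masks) * 1.0
  stop_if(!identical(dim(x_all), dim(y_all)),
          "frames and masks must have matching shapes")
  stop_if(!identical(as.integer(dim(x_all)[1:2]), cfg$input_size),
          "frame size does not match config input_size")
  n <- dim(x_all)[4]
  stop_if(n < 1, "need at least one frame/mask pair")
  epochs <- if (is.null(epochs)) cfg$epochs else as.integer(epochs)
  if (epochs == 0L) return(model)
  adam <- list(m = NULL, v = NULL, t = 0, b1 = 0.9, b2 = 0.999, eps = 1e-8)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(cfg$seed + ep, sample.int(n))
    losses <- c()
    for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      xb <- x_all[, , , b, drop = FALSE]
      yb <- y_all[, , , b, drop = FALSE]
      fw <- acnn_forward(model, xb)
      losses <- c(losses, bce_loss(fw$logits, yb))
      g_logits <- (sigmoid(fw$logits) - yb) / length(yb)
      grads <- acnn_backward(model, fw$cache, g_logits)
      adam$t <- adam$t + 1
      if (is.null(adam$m)) {
        adam$m <- rapply(grads, function(g) g * 0, how = "replace")
        adam$v <- adam$m
      }
      for (nm in names(grads)) for (slot in c("w", "b")) {
        g <- grads[[nm]][[slot]]
        adam$m[[nm]][[slot]] <- adam$b1 * adam$m[[nm]][[slot]] + (1 - adam$b1) * g
        adam$v[[nm]][[slot]] <- adam$b2 * adam$v[[nm]][[slot]] + (1 - adam$b2) * g^2
        mhat <- adam$m[[nm]][[slot]] / (1 - adam$b1^adam$t)
        vhat <- adam$v[[nm]][[slot]] / (1 - adam$b2^adam$t)
        model$params[[nm]][[slot]] <- model$params[[nm]][[slot]] -
          cfg$learning_rate * mhat / (sqrt(vhat) + adam$eps)
      }
    }
    model$history <- c(model$history, mean(losses))
    if (verbose && ep %% 20 == 0)
      message(sprintf("epoch %d: loss %.5f", ep, mean(losses)))
  }
  model
}

#' Predict an LV mask for one frame
#'
#' @param model a trained `SegModel`.
#' @param frame numeric matrix matching the config input size, values \[0, 1\].
#' @return logical matrix (`TRUE` = LV): probability >= config threshold.
#' @export
predict_mask <- function(model, frame) {
  cfg <- model$config
  stop_if(!identical(as.integer(dim(frame)), cfg$input_size),
          "frame size does not match config input_size")
  x <- frames_to_x(frame)
  probs <- sigmoid(acnn_forward(model, x)$logits)[, , 1, 1]
  probs >= cfg$threshold
}

#' Predict LV masks for every frame of a video
#'
#' @param model a trained `SegModel`.
#' @param video an [echo_video()] (resized upstream to the config size).
#' @return logical `(row, col, frame)` array.
#' @export
segment_video <- function(model, video) {
  n <- dim(video$frames)[3]
  out <- array(FALSE, dim = dim(video$frames))
  # batched forward keeps the per-frame overhead down
  x <- frames_to_x(video$frames)
  probs <- sigmoid(acnn_forward(model, x)$logits)
  for (i in seq_len(n)) out[, , i] <- probs[, , 1, i] >= model$config$threshold
  out
}

#' Dice similarity coefficient of two binary masks
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty.
#'
#' @param a,b logical matrices of equal shape.
#' @return DSC in \[0, 1\].
#' @export
dice <- function(a, b) {
  stop_if(!identical(dim(a), dim(b)), "masks must share one shape")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1.0)
  2 * sum(a & b) / (sa + sb)
}
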