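#' Configuration of the 2D segmentation network
#'
#' Hyperparameters of the U-Net / Attention U-Net liver-ROI segmenter. The
#' encoder applies, per level, two 3x3 convolutions (each batch-normalised and
#' ReLU-activated) followed by 2x2 max pooling; the decoder mirrors it with
#' 2x2/stride-2 transpose-convolution up-sampling and skip connections
#' (attention-gated for `arch = "attention_unet"`); a final 1x1 convolution
#' with sigmoid produces the mask probability map.
#'
#' @param arch "unet" or "attention_unet".
#' @param in_channels Input channels (grayscale B-mode replicated to 3).
#' @param input_shape (height, width); must be divisible by
#'   `2^(length(encoder_widths) - 1)`.
#' @param encoder_widths Strictly increasing channel counts per level; the
#'   last entry is the bottleneck width.
#' @param batch_size Mini-batch size (default 2).
#' @param epochs Training epochs (default 100).
#' @param lr Adam initial learning rate (default 2e-4).
#' @param betas Adam betas (default 0.9, 0.999).
#' @param seed RNG seed for initialisation and batch shuffling.
#' @return Object of class `seg_config`.
#' @export
seg_config <- function(arch = c("unet", "attention_unet"), in_channels = 3L,
                       input_shape = c(192L, 256L),
                       encoder_widths = c(32L, 64L, 128L, 256L, 512L),
                       batch_size = 2L, epochs = 100L, lr = 2e-4,
                       betas = c(0.9, 0.999), seed = 1L) {
  arch <- match.arg(arch)
  w <- as.integer(encoder_widths)
  if (any(diff(w) <= 0)) stop("encoder_widths must be strictly increasing")
  depth <- length(w) - 1L
  if (any(as.integer(input_shape) %% 2L^depth != 0L))
    stop(sprintf("configuration error: input shape must be divisible by %d",
                 2L^depth))
  structure(list(arch = arch, in_channels = as.integer(in_channels),
                 input_shape = as.integer(input_shape), encoder_widths = w,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr, betas = betas,
                 seed = as.integer(seed)),
            class = "seg_config")
}

#' Build a segmentation network
#'
#' Initialises all parameters (He-normal convolutions, unit-gain batch norm)
#' from the config seed. Two builds with the same seed are identical.
#'
#' @param cfg A [seg_config()].
#' @return Object of class `segnet` with `params`, `rstats` (batch-norm
#'   running statistics), `cfg`.
#' @export
build_segnet <- function(cfg) {
  stopifnot(inherits(cfg, "seg_config"))
  set.seed(cfg$seed)
  w <- cfg$encoder_widths; D <- length(w)
  p <- list(); rs <- list()
  add_bn <- function(pfx, C) {
    p[[paste0(pfx, "_g")]] <<- rep(1, C)
    p[[paste0(pfx, "_b")]] <<- rep(0, C)
    rs[[paste0(pfx, "_m")]] <<- rep(0, C)
    rs[[paste0(pfx, "_v")]] <<- rep(1, C)
  }
  add_dconv <- function(pfx, cin, cout) {
    p[[paste0(pfx, "_c1_w")]] <<- he_init(cout, cin * 9, cin * 9)
    p[[paste0(pfx, "_c1_b")]] <<- rep(0, cout)
    add_bn(paste0(pfx, "_bn1"), cout)
    p[[paste0(pfx, "_c2_w")]] <<- he_init(cout, cout * 9, cout * 9)
    p[[paste0(pfx, "_c2_b")]] <<- rep(0, cout)
    add_bn(paste0(pfx, "_bn2"), cout)
  }
  for (l in seq_len(D))
    add_dconv(paste0("enc", l), if (l == 1) cfg$in_channels else w[l - 1], w[l])
  for (l in seq_len(D - 1)) {
    p[[paste0("dec", l, "_up_w")]] <- he_init(w[l] * 4, w[l + 1], w[l + 1])
    p[[paste0("dec", l, "_up_b")]] <- rep(0, w[l])
    add_dconv(paste0("dec", l), 2L * w[l], w[l])
    if (cfg$arch == "attention_unet") {
      ci <- max(1L, w[l] %/% 2L)
      p[[paste0("att", l, "_wx")]] <- xavier_init(ci, w[l])
      p[[paste0("att", l, "_wg")]] <- xavier_init(ci, w[l])
      p[[paste0("att", l, "_bg")]] <- rep(0, ci)
      p[[paste0("att", l, "_psi")]] <- xavier_init(1L, ci)
      p[[paste0("att", l, "_bpsi")]] <- 0
    }
  }
  p$head_w <- xavier_init(1L, w[1])
  p$head_b <- 0
  structure(list(params = p, rstats = rs, cfg = cfg, trained = FALSE,
                 history = NULL),
            class = "segnet")
}

#' Number of trainable parameters
#'
#' @param net A `segnet` or `clf1d` object.
#' @return Integer parameter count.
#' @export
count_params <- function(net) sum(vapply(net$params, length, integer(1)))

#' @export
print.segnet <- function(x, ...) {
  cat(sprintf("<segnet %s> widths %s, input %dx%d, %d parameters, %s\n",
              x$cfg$arch, paste(x$cfg$encoder_widths, collapse = "-"),
              x$cfg$input_shape[1], x$cfg$input_shape[2], count_params(x),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# double conv block: conv-bn-relu twice. Returns activations and caches.
dconv_fw <- function(xs, pfx, p, rs, training) {
  c1 <- lapply(xs, function(x)
    conv2d_fwc(x, p[[paste0(pfx, "_c1_w")]], p[[paste0(pfx, "_c1_b")]], 3L, 3L))
  bn1 <- bn2d_fw(lapply(c1, `[[`, "y"),
                 p[[paste0(pfx, "_bn1_g")]], p[[paste0(pfx, "_bn1_b")]],
                 rs[[paste0(pfx, "_bn1_m")]], rs[[paste0(pfx, "_bn1_v")]],
                 training)
  a1 <- lapply(bn1$ys, function(y) y * (y > 0))
  c2 <- lapply(a1, function(x)
    conv2d_fwc(x, p[[paste0(pfx, "_c2_w")]], p[[paste0(pfx, "_c2_b")]], 3L, 3L))
  bn2 <- bn2d_fw(lapply(c2, `[[`, "y"),
                 p[[paste0(pfx, "_bn2_g")]], p[[paste0(pfx, "_bn2_b")]],
                 rs[[paste0(pfx, "_bn2_m")]], rs[[paste0(pfx, "_bn2_v")]],
                 training)
  a2 <- lapply(bn2$ys, function(y) y * (y > 0))
  list(out = a2, cin1 = dim(xs[[1]])[3], cols1 = lapply(c1, `[[`, "cols"),
       a1 = a1, cols2 = lapply(c2, `[[`, "cols"), bn1 = bn1, bn2 = bn2)
}

dconv_bw <- function(gouts, cache, pfx, p, addg, need_gx = TRUE) {
  B <- length(gouts)
  gy2 <- lapply(seq_len(B), function(b) gouts[[b]] * (cache$out[[b]] > 0))
  bn2b <- bn2d_bw(gy2, cache$bn2, p[[paste0(pfx, "_bn2_g")]])
  addg(paste0(pfx, "_bn2_g"), bn2b$dgamma)
  addg(paste0(pfx, "_bn2_b"), bn2b$dbeta)
  ga1 <- vector("list", B)
  for (b in seq_len(B)) {
    cb <- conv2d_bwc(cache$cols2[[b]], p[[paste0(pfx, "_c2_w")]],
                     bn2b$gxs[[b]], 3L, 3L, dim(cache$a1[[b]])[3])
    addg(paste0(pfx, "_c2_w"), cb$gw)
    addg(paste0(pfx, "_c2_b"), cb$gb)
    ga1[[b]] <- cb$gx
  }
  gy1 <- lapply(seq_len(B), function(b) ga1[[b]] * (cache$a1[[b]] > 0))
  bn1b <- bn2d_bw(gy1, cache$bn1, p[[paste0(pfx, "_bn1_g")]])
  addg(paste0(pfx, "_bn1_g"), bn1b$dgamma)
  addg(paste0(pfx, "_bn1_b"), bn1b$dbeta)
  gxs <- vector("list", B)
  for (b in seq_len(B)) {
    cb <- conv2d_bwc(cache$cols1[[b]], p[[paste0(pfx, "_c1_w")]],
                     bn1b$gxs[[b]], 3L, 3L, cache$cin1, need_gx)
    addg(paste0(pfx, "_c1_w"), cb$gw)
    addg(paste0(pfx, "_c1_b"), cb$gb)
    gxs[[b]] <- cb$gx
  }
  gxs
}

# full forward pass; training mode keeps caches and updated running stats
seg_fw <- function(p, rs, cfg, xs, training) {
  D <- length(cfg$encoder_widths)
  att <- cfg$arch == "attention_unet"
  enc <- vector("list", D); pools <- vector("list", D - 1)
  cur <- xs
  for (l in seq_len(D)) {
    dc <- dconv_fw(cur, paste0("enc", l), p, rs, training)
    if (training) {
      rs[[paste0("enc", l, "_bn1_m")]] <- dc$bn1$rm
      rs[[paste0("enc", l, "_bn1_v")]] <- dc$bn1$rv
      rs[[paste0("enc", l, "_bn2_m")]] <- dc$bn2$rm
      rs[[paste0("enc", l, "_bn2_v")]] <- dc$bn2$rv
    }
    enc[[l]] <- dc
    if (l < D) {
      pl <- lapply(dc$out, maxpool2d_fw)
      pools[[l]] <- pl
      cur <- lapply(pl, `[[`, "y")
    } else cur <- dc$out
  }
  dec <- vector("list", D - 1); ups <- vector("list", D - 1)
  atts <- vector("list", D - 1)
  for (l in rev(seq_len(D - 1))) {
    deeper <- cur
    up <- lapply(deeper, function(u)
      convT2d_fw(u, p[[paste0("dec", l, "_up_w")]],
                 p[[paste0("dec", l, "_up_b")]]))
    ups[[l]] <- list(x_in = deeper, out = up)
    skips <- lapply(enc[[l]]$out, identity)
    if (att) {
      ac <- lapply(seq_along(skips), function(b)
        att_fw(skips[[b]], up[[b]],
               p[[paste0("att", l, "_wx")]], p[[paste0("att", l, "_wg")]],
               p[[paste0("att", l, "_bg")]], p[[paste0("att", l, "_psi")]],
               p[[paste0("att", l, "_bpsi")]]))
      atts[[l]] <- ac
      skips <- lapply(ac, `[[`, "y")
    }
    cats <- lapply(seq_along(up), function(b) cat3(up[[b]], skips[[b]]))
    dc <- dconv_fw(cats, paste0("dec", l), p, rs, training)
    if (training) {
      rs[[paste0("dec", l, "_bn1_m")]] <- dc$bn1$rm
      rs[[paste0("dec", l, "_bn1_v")]] <- dc$bn1$rv
      rs[[paste0("dec", l, "_bn2_m")]] <- dc$bn2$rm
      rs[[paste0("dec", l, "_bn2_v")]] <- dc$bn2$rv
    }
    dec[[l]] <- dc
    cur <- dc$out
  }
  d1 <- dim(cur[[1]]); n <- d1[1] * d1[2]
  logits <- lapply(cur, function(u)
    matrix(matrix(u, n, d1[3]) %*% t(p$head_w) + p$head_b, d1[1], d1[2]))
  list(logits = logits, enc = enc, pools = pools, dec = dec, ups = ups,
       atts = atts, final = cur, rs = rs)
}

# forward + backward + loss for one mini-batch
seg_train_step <- function(p, rs, cfg, xs, ys) {
  fw <- seg_fw(p, rs, cfg, xs, training = TRUE)
  B <- length(xs)
  D <- length(cfg$encoder_widths)
  att <- cfg$arch == "attention_unet"
  genv <- new.env(parent = emptyenv())
  addg <- function(nm, v) {
    if (is.null(genv[[nm]])) genv[[nm]] <- v else genv[[nm]] <- genv[[nm]] + v
  }
  loss <- 0
  gfinal <- vector("list", B)
  d1 <- dim(fw$final[[1]]); n <- d1[1] * d1[2]
  for (b in seq_len(B)) {
    bl <- bce_logits(fw$logits[[b]], ys[[b]])
    loss <- loss + bl$loss / B
    dz <- bl$dz / B
    addg("head_w", matrix(dz, 1, n) %*% matrix(fw$final[[b]], n, d1[3]))
    addg("head_b", sum(dz))
    gfinal[[b]] <- array(matrix(dz, n, 1) %*% p$head_w, d1)
  }
  # decoder backward, shallow to deep
  gcur <- gfinal
  gskip <- vector("list", D)
  for (l in seq_len(D - 1)) {
    gcat <- dconv_bw(gcur, fw$dec[[l]], paste0("dec", l), p, addg)
    wl <- cfg$encoder_widths[l]
    gup <- lapply(gcat, function(g) g[, , seq_len(wl), drop = FALSE])
    gsk <- lapply(gcat, function(g) g[, , wl + seq_len(wl), drop = FALSE])
    if (att) {
      gx <- vector("list", B)
      for (b in seq_len(B)) {
        ab <- att_bw(gsk[[b]], fw$atts[[l]][[b]],
                     p[[paste0("att", l, "_wx")]],
                     p[[paste0("att", l, "_wg")]],
                     p[[paste0("att", l, "_psi")]])
        addg(paste0("att", l, "_wx"), ab$gwx)
        addg(paste0("att", l, "_wg"), ab$gwg)
        addg(paste0("att", l, "_bg"), ab$gbg)
        addg(paste0("att", l, "_psi"), ab$gpsi)
        addg(paste0("att", l, "_bpsi"), ab$gbpsi)
        gx[[b]] <- ab$gx
        gup[[b]] <- gup[[b]] + ab$gg
      }
      gsk <- gx
    }
    gskip[[l]] <- gsk
    gdeeper <- vector("list", B)
    for (b in seq_len(B)) {
      cb <- convT2d_bw(fw$ups[[l]]$x_in[[b]],
                       p[[paste0("dec", l, "_up_w")]], gup[[b]])
      addg(paste0("dec", l, "_up_w"), cb$gw)
      addg(paste0("dec", l, "_up_b"), cb$gb)
      gdeeper[[b]] <- cb$gx
    }
    gcur <- gdeeper
  }
  # encoder backward, deep to shallow; gcur holds grad w.r.t. enc D output
  gout <- gcur
  for (l in rev(seq_len(D))) {
    if (l < D) {
      unpool <- lapply(seq_len(B), function(b) {
        pl <- fw$pools[[l]][[b]]
        d <- dim(fw$enc[[l]]$out[[b]])
        maxpool2d_bw(gin_deeper[[b]], pl$idx, d[1], d[2])
      })
      gout <- lapply(seq_len(B), function(b) gskip[[l]][[b]] + unpool[[b]])
    }
    gin <- dconv_bw(gout, fw$enc[[l]], paste0("enc", l), p, addg,
                    need_gx = l > 1L)
    gin_deeper <- gin
  }
  list(loss = loss, grads = as.list(genv), rs = fw$rs)
}

seg_eval_loss <- function(p, rs, cfg, xs, ys) {
  fw <- seg_fw(p, rs, cfg, xs, training = FALSE)
  mean(vapply(seq_along(xs), function(b)
    bce_logits(fw$logits[[b]], ys[[b]])$loss, numeric(1)))
}

to_3ch <- function(x, in_channels) {
  if (inherits(x, "bmode_image")) x <- x$pixels
  if (is.matrix(x)) array(rep(x, in_channels), c(dim(x), in_channels))
  else x
}

#' Train a segmentation network
#'
#' Mini-batch Adam training with binary cross-entropy loss on the sigmoid
#' output. The model with the best validation loss is retained (training loss
#' when no validation pairs are given). Deterministic for a fixed seed and
#' data order.
#'
#' @param net A `segnet` from [build_segnet()].
#' @param images,masks Training pairs: lists of matrices (grayscale images in
#'   \[0,1\], replicated internally to the configured channel count) and
#'   binary masks, all of the configured input shape.
#' @param val_images,val_masks Optional validation pairs.
#' @param verbose Print per-epoch losses.
#' @return The trained `segnet` with a `history` data frame (epoch,
#'   train_loss, val_loss).
#' @export
train_segnet <- function(net, images, masks, val_images = NULL,
                         val_masks = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "segnet"))
  cfg <- net$cfg
  if (length(images) == 0) stop("empty training set")
  if (length(images) != length(masks)) stop("images/masks length mismatch")
  xs <- lapply(images, to_3ch, cfg$in_channels)
  ys <- lapply(masks, function(m) {
    m <- if (inherits(m, "liver_mask")) m$pixels else m
    if (!all(m %in% c(0, 1))) stop("masks must be binary")
    as.matrix(m)
  })
  has_val <- !is.null(val_images) && length(val_images) > 0
  if (has_val) {
    vxs <- lapply(val_images, to_3ch, cfg$in_channels)
    vys <- lapply(val_masks, function(m)
      as.matrix(if (inherits(m, "liver_mask")) m$pixels else m))
  }
  p <- net$params; rs <- net$rstats
  state <- adam_init(p)
  set.seed(cfg$seed + 1L)
  n <- length(xs)
  hist <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                     val_loss = NA_real_)
  best <- list(loss = Inf, p = p, rs = rs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    bl <- 0; nb <- 0
    for (s in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      st <- seg_train_step(p, rs, cfg, xs[idx], ys[idx])
      rs <- st$rs
      upd <- adam_step(p, st$grads, state, cfg$lr, cfg$betas)
      p <- upd$params; state <- upd$state
      bl <- bl + st$loss; nb <- nb + 1
    }
    hist$train_loss[ep] <- bl / nb
    sel <- hist$train_loss[ep]
    if (has_val) {
      hist$val_loss[ep] <- seg_eval_loss(p, rs, cfg, vxs, vys)
      sel <- hist$val_loss[ep]
    }
    if (sel < best$loss)
      best <- list(loss = sel, p = deep_copy(p), rs = deep_copy(rs))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %s", ep, hist$train_loss[ep],
                      if (has_val) sprintf("%.5f", hist$val_loss[ep]) else "-"))
  }
  net$params <- best$p; net$rstats <- best$rs
  net$history <- hist; net$trained <- TRUE
  net
}

#' Segmentation probability map
#'
#' Runs the network in inference mode (batch-norm running statistics) on one
#' image and returns the sigmoid probability map.
#'
#' @param net A `segnet`.
#' @param image Matrix or `bmode_image` of the configured input shape.
#' @return Matrix of probabilities in (0, 1).
#' @export
segment_prob <- function(net, image) {
  stopifnot(inherits(net, "segnet"))
  x <- to_3ch(image, net$cfg$in_channels)
  if (!all(dim(x)[1:2] == net$cfg$input_shape)) stop("shape mismatch")
  fw <- seg_fw(net$params, net$rstats, net$cfg, list(x), training = FALSE)
  1 / (1 + exp(-fw$logits[[1]]))
}

#' Binarise a probability map
#'
#' @param prob Matrix of probabilities.
#' @param threshold Decision threshold (default 0.5); values at or above it
#'   map to 1.
#' @return Integer 0/1 matrix.
#' @export
threshold_mask <- function(prob, threshold = 0.5) {
  (as.matrix(prob) >= threshold) * 1L
}

#' Segment the liver ROI in a B-mode image
#'
#' Sigmoid output thresholded at 0.5.
#'
#' @param net A trained `segnet`.
#' @param image Matrix or `bmode_image` of the configured input shape.
#' @param threshold Decision threshold.
#' @return Object of class `liver_mask` (binary `pixels` in network space).
#' @export
segment_bmode <- function(net, image, threshold = 0.5) {
  pm <- threshold_mask(segment_prob(net, image), threshold)
  fid <- if (inherits(image, "bmode_image")) image$source_frame_id else NULL
  structure(list(pixels = pm, space = "network", source_frame_id = fid),
            class = "liver_mask")
}

#' Resize a network-space mask back to signal space
#'
#' Bicubic interpolation to the RF grid followed by re-binarisation at 0.5.
#'
#' @param mask `liver_mask` or binary matrix (network space).
#' @param out_shape Target shape, default c(1247, 256).
#' @return `liver_mask` with binary `pixels` of `out_shape`.
#' @export
resize_mask_to_signal <- function(mask, out_shape = c(1247L, 256L)) {
  px <- if (inherits(mask, "liver_mask")) mask$pixels else as.matrix(mask)
  if (!all(px %in% c(0, 1))) stop("mask must be binary")
  out <- (resize_image(px, out_shape) >= 0.5) * 1L
  structure(list(pixels = out, space = "signal",
                 source_frame_id = if (inherits(mask, "liver_mask"))
                   mask$source_frame_id else NULL),
            class = "liver_mask")
}

#' @export
print.liver_mask <- function(x, ...) {
  cat(sprintf("<liver_mask> %d x %d (%s space), %.1f%% positive\n",
              nrow(x$pixels), ncol(x$pixels), x$space, 100 * mean(x$pixels)))
  invisible(x)
}
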