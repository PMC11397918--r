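#' Configuration of the 1D spectral classifier
#'
#' The fibrosis-stage classifier is a 1D CNN over single spectrum lines:
#' four 1D convolution layers (tanh-activated) each followed by max pooling,
#' then a flattened feature vector through four fully-connected layers (tanh
#' on the hidden ones) to a 2-class logit head.
#'
#' @param conv_channels Four channel counts.
#' @param kernel_sizes Four odd kernel sizes.
#' @param pool_sizes Four pooling factors; `input_len` must be divisible by
#'   their running products.
#' @param fc_widths Four fully-connected widths; the last must be 2.
#' @param input_len Input line length (default 768, the gate length).
#' @param batch_size Mini-batch size in lines (default 256).
#' @param epochs Training epochs (default 100).
#' @param lr Adam initial learning rate (default 2e-4).
#' @param betas Adam betas.
#' @param seed RNG seed.
#' @return Object of class `clf_config`.
#' @export
clf_config <- function(conv_channels = c(4L, 8L, 16L, 32L),
                       kernel_sizes = c(7L, 5L, 5L, 3L),
                       pool_sizes = c(4L, 4L, 2L, 2L),
                       fc_widths = c(64L, 32L, 16L, 2L),
                       input_len = 768L, batch_size = 256L, epochs = 100L,
                       lr = 2e-4, betas = c(0.9, 0.999), seed = 1L) {
  if (length(conv_channels) != 4L || length(kernel_sizes) != 4L ||
      length(pool_sizes) != 4L || length(fc_widths) != 4L)
    stop("configuration error: exactly 4 conv, 4 pool and 4 fc stages")
  if (any(kernel_sizes %% 2L == 0L))
    stop("configuration error: kernel sizes must be odd")
  if (fc_widths[4] != 2L) stop("configuration error: final width must be 2")
  lens <- input_len / cumprod(pool_sizes)
  if (any(lens != floor(lens)) || any(lens < 1))
    stop("configuration error: pooled length reaches 0 or is fractional")
  structure(list(conv_channels = as.integer(conv_channels),
                 kernel_sizes = as.integer(kernel_sizes),
                 pool_sizes = as.integer(pool_sizes),
                 fc_widths = as.integer(fc_widths),
                 input_len = as.integer(input_len),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr, betas = betas,
                 seed = as.integer(seed), flat_len = as.integer(
                   lens[4] * conv_channels[4])),
            class = "clf_config")
}

#' Build a 1D CNN classifier
#'
#' Initialises all parameters from the config seed (Xavier-normal, suited to
#' the tanh activations). Two builds with the same seed are identical.
#'
#' @param cfg A [clf_config()].
#' @return Object of class `clf1d` with `params`, `cfg`.
#' @export
build_clf <- function(cfg) {
  stopifnot(inherits(cfg, "clf_config"))
  set.seed(cfg$seed)
  p <- list()
  cin <- 1L
  for (i in 1:4) {
    co <- cfg$conv_channels[i]; k <- cfg$kernel_sizes[i]
    p[[paste0("conv", i, "_w")]] <- xavier_init(co, cin * k)
    p[[paste0("conv", i, "_b")]] <- rep(0, co)
    cin <- co
  }
  fin <- cfg$flat_len
  for (j in 1:4) {
    fo <- cfg$fc_widths[j]
    p[[paste0("fc", j, "_w")]] <- xavier_init(fo, fin)
    p[[paste0("fc", j, "_b")]] <- rep(0, fo)
    fin <- fo
  }
  structure(list(params = p, cfg = cfg, trained = FALSE, history = NULL),
            class = "clf1d")
}

#' @export
print.clf1d <- function(x, ...) {
  cat(sprintf("<clf1d> conv %s, fc %s, input %d, %d parameters, %s\n",
              paste(x$cfg$conv_channels, collapse = "-"),
              paste(x$cfg$fc_widths, collapse = "-"), x$cfg$input_len,
              count_params(x), if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# forward pass on a matrix of lines (input_len x B); returns logits (2 x B)
# and, when keep = TRUE, the caches needed for backprop
clf_fw <- function(p, cfg, x, keep = FALSE) {
  B <- ncol(x)
  a <- array(x, c(cfg$input_len, 1L, B))
  caches <- if (keep) vector("list", 4) else NULL
  for (i in 1:4) {
    if (keep) {
      cv <- conv1d_fwc(a, p[[paste0("conv", i, "_w")]],
                       p[[paste0("conv", i, "_b")]], cfg$kernel_sizes[i],
                       act = TRUE)
      at <- cv$y
      pl <- maxpool1d_fw(at, cfg$pool_sizes[i])
      caches[[i]] <- list(cols = cv$cols, cin = dim(a)[2], at = at,
                          idx = pl$idx, L = nrow(at))
    } else {
      at <- conv1d_fw(a, p[[paste0("conv", i, "_w")]],
                      p[[paste0("conv", i, "_b")]], cfg$kernel_sizes[i],
                      act = TRUE)
      pl <- maxpool1d_fw(at, cfg$pool_sizes[i])
    }
    a <- pl$y
  }
  flat <- a; dim(flat) <- c(cfg$flat_len, B)
  hs <- if (keep) vector("list", 4) else NULL
  h <- flat
  for (j in 1:3) {
    h <- tanh(p[[paste0("fc", j, "_w")]] %*% h + p[[paste0("fc", j, "_b")]])
    if (keep) hs[[j]] <- h
  }
  z <- p$fc4_w %*% h + p$fc4_b
  list(logits = z, flat = flat, hs = hs, caches = caches)
}

softmax2 <- function(z) {
  zm <- pmax(z[1, ], z[2, ])
  e1 <- exp(z[1, ] - zm); e2 <- exp(z[2, ] - zm)
  rbind(e1, e2) / rep(e1 + e2, each = 2)
}

# forward + backward for one mini-batch of lines; y in {0,1}
clf_train_step <- function(p, cfg, x, y) {
  B <- ncol(x)
  fw <- clf_fw(p, cfg, x, keep = TRUE)
  pr <- softmax2(fw$logits)
  iy <- cbind(y + 1L, seq_len(B))
  loss <- -mean(log(pmax(pr[cbind(y + 1L, seq_len(B))], 1e-300)))
  gz <- pr
  gz[iy] <- gz[iy] - 1
  gz <- gz / B
  g <- list()
  h_in <- list(fw$flat, fw$hs[[1]], fw$hs[[2]], fw$hs[[3]])
  gh <- gz
  for (j in 4:1) {
    g[[paste0("fc", j, "_w")]] <- gh %*% t(h_in[[j]])
    g[[paste0("fc", j, "_b")]] <- .rowSums(gh, nrow(gh), B)
    gh <- t(p[[paste0("fc", j, "_w")]]) %*% gh
    if (j > 1) gh <- gh * (1 - h_in[[j]]^2)   # tanh derivative
  }
  ga <- gh
  dim(ga) <- c(cfg$input_len / prod(cfg$pool_sizes), cfg$conv_channels[4], B)
  for (i in 4:1) {
    cc <- fw$caches[[i]]
    ga <- maxpool1d_bw(ga, cc$idx, cc$L)
    ga <- ga * (1 - cc$at^2)
    cb <- conv1d_bwc(cc$cols, p[[paste0("conv", i, "_w")]], ga,
                     cfg$kernel_sizes[i], cc$cin, need_gx = i > 1L)
    g[[paste0("conv", i, "_w")]] <- cb$gw
    g[[paste0("conv", i, "_b")]] <- cb$gb
    ga <- cb$gx
  }
  list(loss = loss, grads = g)
}

clf_eval_loss <- function(p, cfg, x, y, chunk = 1024L) {
  n <- ncol(x); tot <- 0
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    pr <- softmax2(clf_fw(p, cfg, x[, idx, drop = FALSE])$logits)
    tot <- tot + sum(-log(pmax(pr[cbind(y[idx] + 1L, seq_along(idx))], 1e-300)))
  }
  tot / n
}

samples_to_lines <- function(samples) {
  x <- do.call(cbind, lapply(samples, `[[`, "values"))
  y <- unlist(lapply(samples, function(s) rep(s$label, ncol(s$values))))
  list(x = x, y = as.integer(y))
}

#' Train the 1D spectral classifier
#'
#' Every scan line of every gated sample is an independent training instance
#' carrying the sample's binary label; optimisation is mini-batch Adam with
#' softmax cross-entropy. The model with the best validation loss is retained
#' (training loss when no validation samples are given).
#'
#' @param net A `clf1d` from [build_clf()].
#' @param train_samples List of `gated_sample` objects (or a list with
#'   `values`/`label`) covering both classes.
#' @param val_samples Optional validation samples.
#' @param verbose Print per-epoch losses.
#' @return Trained `clf1d` with a `history` data frame.
#' @export
train_clf <- function(net, train_samples, val_samples = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(net, "clf1d"))
  cfg <- net$cfg
  tr <- samples_to_lines(train_samples)
  if (length(unique(tr$y)) < 2L) stop("single-class training data")
  if (nrow(tr$x) != cfg$input_len) stop("samples must match input_len")
  has_val <- !is.null(val_samples) && length(val_samples) > 0
  if (has_val) va <- samples_to_lines(val_samples)
  p <- net$params
  state <- adam_init(p)
  set.seed(cfg$seed + 1L)
  n <- ncol(tr$x)
  hist <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                     val_loss = NA_real_)
  best <- list(loss = Inf, p = p)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    bl <- 0; nb <- 0
    for (s in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      st <- clf_train_step(p, cfg, tr$x[, idx, drop = FALSE], tr$y[idx])
      upd <- adam_step(p, st$grads, state, cfg$lr, cfg$betas)
      p <- upd$params; state <- upd$state
      bl <- bl + st$loss; nb <- nb + 1
    }
    hist$train_loss[ep] <- bl / nb
    sel <- hist$train_loss[ep]
    if (has_val) {
      hist$val_loss[ep] <- clf_eval_loss(p, cfg, va$x, va$y)
      sel <- hist$val_loss[ep]
    }
    if (sel < best$loss) best <- list(loss = sel, p = deep_copy(p))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %s", ep, hist$train_loss[ep],
                      if (has_val) sprintf("%.5f", hist$val_loss[ep]) else "-"))
  }
  net$params <- best$p; net$history <- hist; net$trained <- TRUE
  net
}

#' Per-line class probabilities for one gated sample
#'
#' @param net A `clf1d`.
#' @param values Matrix `input_len x n_lines` (one column per line).
#' @return Matrix 2 x n_lines of softmax probabilities (row 2 = positive
#'   class).
#' @export
clf_line_probs <- function(net, values) {
  stopifnot(inherits(net, "clf1d"))
  if (nrow(values) != net$cfg$input_len) stop("incompatible input length")
  softmax2(clf_fw(net$params, net$cfg, values)$logits)
}

#' Assemble a whole-frame prediction from per-line classes
#'
#' Implements the whole-frame voting rule: with `n_c` lines agreeing with the
#' true label and `n_w` disagreeing, `p = n_c / (n_c + n_w)` and the frame is
#' counted correct iff `p > 0.5` (strict). The predicted class is the per-line
#' majority; an exact tie resolves to the class opposite the true label so
#' that `p = 0.5` counts as incorrect.
#'
#' @param pred_classes Integer vector of per-line predicted classes (0/1).
#' @param true_label True binary label of the frame.
#' @return Object of class `frame_prediction` with `n_c`, `n_w`, `p`,
#'   `frame_correct`, `predicted_class`, `true_label`.
#' @export
frame_prediction <- function(pred_classes, true_label) {
  n_c <- sum(pred_classes == true_label)
  n_w <- sum(pred_classes != true_label)
  p <- n_c / (n_c + n_w)
  pred <- if (n_c == n_w) 1L - as.integer(true_label)
          else if (n_c > n_w) as.integer(true_label)
          else 1L - as.integer(true_label)
  structure(list(n_c = n_c, n_w = n_w, p = p, frame_correct = p > 0.5,
                 predicted_class = pred, true_label = as.integer(true_label)),
            class = "frame_prediction")
}

#' Whole-frame prediction for one gated sample
#'
#' Feeds each of the sample's lines to the classifier, takes per-line argmax
#' classes, and aggregates them with [frame_prediction()].
#'
#' @param net A trained `clf1d`.
#' @param sample A `gated_sample`.
#' @param true_label True label; defaults to the sample's label.
#' @return A `frame_prediction`.
#' @export
predict_frame <- function(net, sample, true_label = sample$label) {
  if (!isTRUE(net$trained)) warning("network has not been trained")
  pr <- clf_line_probs(net, sample$values)
  cls <- as.integer(pr[2, ] > pr[1, ])
  frame_prediction(cls, true_label)
}

#' @export
print.frame_prediction <- function(x, ...) {
  cat(sprintf("<frame_prediction> n_c=%d n_w=%d p=%.4f -> %s (true %d, predicted %d)\n",
              x$n_c, x$n_w, x$p, if (x$frame_correct) "correct" else "incorrect",
              x$true_label, x$predicted_class))
  invisible(x)
}

#' Continuous frame scores for ROC analysis
#'
#' The frame score is the mean positive-class probability over the sample's
#' lines; it is invariant to line order and always lies in \[0, 1\].
#'
#' @param net A trained `clf1d`.
#' @param samples List of `gated_sample` objects.
#' @return Numeric vector of frame scores.
#' @export
score_frames <- function(net, samples) {
  vapply(samples, function(s) mean(clf_line_probs(net, s$values)[2, ]),
         numeric(1))
}
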