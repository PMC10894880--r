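# Patch-level classifier: paired cosine-decay learning-rate schedules for
# transfer learning (task head vs pretrained backbone), a small native CNN
# trained with SGD on softmax cross-entropy, per-tile likelihood
# prediction, and Grad-CAM localization maps.

#' Cosine-decay learning-rate schedule
#'
#' Houses the schedule constants: minimum rate `eta_min` (0), maximum rate
#' `eta_max` (0.01) and the number of iteration epochs `T_i` (8), matching
#' the published configuration.
#'
#' @param eta_min,eta_max Learning-rate bounds, `0 <= eta_min <= eta_max`.
#' @param T_i Number of iteration epochs (> 0).
#' @return Object of class `lr_schedule`.
#' @export
lr_schedule <- function(eta_min = 0, eta_max = 0.01, T_i = 8) {
  if (T_i <= 0) stopf("T_i must be positive")
  if (eta_min < 0 || eta_max < eta_min) {
    stopf("need 0 <= eta_min <= eta_max")
  }
  structure(list(eta_min = eta_min, eta_max = eta_max, T_i = T_i),
            class = "lr_schedule")
}

#' Task-specific learning rate
#'
#' `eta = eta_min + (eta_max - eta_min) / 2 * (1 + cos(pi * T_cur / T_i))`:
#' starts at `eta_max`, decays smoothly to `eta_min` at `T_cur = T_i`.
#' `T_cur` may be fractional (per-iteration interpolation).
#'
#' @param schedule An [lr_schedule()].
#' @param t_cur Current epoch position in `[0, T_i]`.
#' @return Learning rate.
#' @export
task_lr <- function(schedule, t_cur) {
  stopifnot(inherits(schedule, "lr_schedule"))
  if (any(t_cur < 0 | t_cur > schedule$T_i)) {
    stopf("T_cur must lie in [0, T_i]")
  }
  schedule$eta_min + 0.5 * (schedule$eta_max - schedule$eta_min) *
    (1 + cos(pi * t_cur / schedule$T_i))
}

#' Backbone learning rate (delayed fine-tuning)
#'
#' Zero while `T_cur <= T_i / 2` (the pretrained backbone stays frozen for
#' the first half of training), then equal to [task_lr()].
#'
#' @inheritParams task_lr
#' @return Learning rate.
#' @export
backbone_lr <- function(schedule, t_cur) {
  eta <- task_lr(schedule, t_cur)
  ifelse(t_cur <= schedule$T_i / 2, 0, eta)
}

#' Training configuration of the patch classifier
#'
#' The published pipeline uses Inception_v3; the method is
#' architecture-parametric, and the packaged backbone is a small 3-block
#' CNN (`"smallcnn"`) sized so the suite trains on one CPU in minutes.
#' Optimizer SGD, softmax cross-entropy loss, batch size 128, and the
#' paired cosine schedules above.
#'
#' @param architecture Backbone name; `"smallcnn"` is implemented natively.
#' @param input_size Side to which tiles are downsampled before the network
#'   (default 32).
#' @param n_filters Filters of the three conv blocks.
#' @param batch_size SGD batch size (default 128).
#' @param epochs `T_i`, the number of iteration epochs (default 8).
#' @param eta_max,eta_min Cosine-schedule bounds (defaults 0.01 and 0).
#' @param pretrained Start the backbone from `init_from` weights (the
#'   transfer-learning contract; ImageNet itself is out of scope).
#' @param init_from Optional previously trained model supplying backbone
#'   weights.
#' @param seed Integer seed.
#' @return Object of class `train_config`.
#' @export
train_config <- function(architecture = "smallcnn", input_size = 32,
                         n_filters = c(8, 16, 16), batch_size = 128,
                         epochs = 8, eta_max = 0.01, eta_min = 0,
                         pretrained = FALSE, init_from = NULL, seed = 1) {
  if (batch_size < 1 || epochs < 1) stopf("batch_size and epochs must be >= 1")
  if (architecture != "smallcnn") {
    stopf("architecture '%s' is not available in this build", architecture)
  }
  structure(list(architecture = architecture, input_size = input_size,
                 n_filters = n_filters, batch_size = as.integer(batch_size),
                 epochs = epochs, eta_max = eta_max, eta_min = eta_min,
                 pretrained = isTRUE(pretrained), init_from = init_from,
                 seed = as.integer(seed)),
            class = "train_config")
}

# --- tensor ops ------------------------------------------------------------
# Arrays are laid out (H, W, N, C) so channel-contractions reshape to a
# matrix without aperm.

conv3x3_forward <- function(X, W, b) {
  d <- dim(X)                      # H, W, N, Cin
  ho <- d[1] - 2; wo <- d[2] - 2
  cout <- ncol(W[[1]])
  out <- matrix(rep(b, each = ho * wo * d[3]), ho * wo * d[3], cout)
  for (di in 0:2) for (dj in 0:2) {
    xs <- X[di + seq_len(ho), dj + seq_len(wo), , , drop = FALSE]
    dim(xs) <- c(ho * wo * d[3], d[4])
    out <- out + xs %*% W[[di * 3 + dj + 1]]
  }
  dim(out) <- c(ho, wo, d[3], cout)
  out
}

conv3x3_backward <- function(X, W, dOut) {
  d <- dim(X)
  ho <- dim(dOut)[1]; wo <- dim(dOut)[2]
  cout <- dim(dOut)[4]
  dmat <- dOut
  dim(dmat) <- c(ho * wo * d[3], cout)
  dW <- vector("list", 9)
  dX <- array(0, d)
  for (di in 0:2) for (dj in 0:2) {
    xs <- X[di + seq_len(ho), dj + seq_len(wo), , , drop = FALSE]
    dim(xs) <- c(ho * wo * d[3], d[4])
    k <- di * 3 + dj + 1
    dW[[k]] <- crossprod(xs, dmat)
    g <- dmat %*% t(W[[k]])
    dim(g) <- c(ho, wo, d[3], d[4])
    dX[di + seq_len(ho), dj + seq_len(wo), , ] <-
      dX[di + seq_len(ho), dj + seq_len(wo), , , drop = FALSE] + g
  }
  list(dX = dX, dW = dW, db = colSums(dmat))
}

meanpool2_forward <- function(X) {
  d <- dim(X)
  ho <- d[1] %/% 2; wo <- d[2] %/% 2
  i <- seq_len(ho) * 2 - 1
  j <- seq_len(wo) * 2 - 1
  (X[i, j, , , drop = FALSE] + X[i + 1, j, , , drop = FALSE] +
     X[i, j + 1, , , drop = FALSE] + X[i + 1, j + 1, , , drop = FALSE]) / 4
}

meanpool2_backward <- function(dOut, in_dim) {
  d <- dim(dOut)
  dX <- array(0, in_dim)
  i <- seq_len(d[1]) * 2 - 1
  j <- seq_len(d[2]) * 2 - 1
  g <- dOut / 4
  dX[i, j, , ] <- g
  dX[i + 1, j, , ] <- g
  dX[i, j + 1, , ] <- g
  dX[i + 1, j + 1, , ] <- g
  dX
}

smallcnn_init <- function(input_size, n_filters, n_classes, seed) {
  layer <- function(cin, cout) {
    list(W = lapply(1:9, function(k)
      matrix(stats::rnorm(cin * cout, sd = sqrt(2 / (9 * cin))), cin, cout)),
      b = numeric(cout))
  }
  with_seed(seed, {
    p <- list(conv1 = layer(3, n_filters[1]),
              conv2 = layer(n_filters[1], n_filters[2]),
              conv3 = layer(n_filters[2], n_filters[3]),
              dense = list(W = matrix(stats::rnorm(n_filters[3] * n_classes,
                                                   sd = sqrt(2 / n_filters[3])),
                                      n_filters[3], n_classes),
                           b = numeric(n_classes)))
    p
  })
}

smallcnn_forward <- function(params, X, keep = FALSE) {
  a1 <- conv3x3_forward(X, params$conv1$W, params$conv1$b)
  r1 <- pmax(a1, 0)
  p1 <- meanpool2_forward(r1)
  a2 <- conv3x3_forward(p1, params$conv2$W, params$conv2$b)
  r2 <- pmax(a2, 0)
  p2 <- meanpool2_forward(r2)
  a3 <- conv3x3_forward(p2, params$conv3$W, params$conv3$b)
  r3 <- pmax(a3, 0)
  d3 <- dim(r3)
  gap <- apply(r3, c(3, 4), mean)                       # N x C
  logits <- sweep(gap %*% params$dense$W, 2, params$dense$b, "+")
  z <- logits - apply(logits, 1, max)
  probs <- exp(z) / rowSums(exp(z))
  out <- list(probs = probs, logits = logits)
  if (keep) out <- c(out, list(X = X, r1 = r1, a1 = a1, p1 = p1, a2 = a2,
                               r2 = r2, p2 = p2, a3 = a3, r3 = r3, gap = gap))
  out
}

smallcnn_backward <- function(params, fwd, Y) {
  n <- nrow(Y)
  dlogits <- (fwd$probs - Y) / n
  grads <- list()
  grads$dense <- list(W = crossprod(fwd$gap, dlogits), b = colSums(dlogits))
  dgap <- dlogits %*% t(params$dense$W)                 # N x C
  d3 <- dim(fwd$r3)
  dr3 <- array(0, d3)
  # GAP spreads each (n, c) gradient uniformly over the spatial cells
  per_cell <- dgap / (d3[1] * d3[2])
  dr3 <- aperm(array(rep(t(per_cell), each = d3[1] * d3[2]),
                     c(d3[1], d3[2], d3[4], d3[3])), c(1, 2, 4, 3))
  da3 <- dr3 * (fwd$a3 > 0)
  bk3 <- conv3x3_backward(fwd$p2, params$conv3$W, da3)
  grads$conv3 <- list(W = bk3$dW, b = bk3$db)
  dr2 <- meanpool2_backward(bk3$dX, dim(fwd$r2))
  da2 <- dr2 * (fwd$a2 > 0)
  bk2 <- conv3x3_backward(fwd$p1, params$conv2$W, da2)
  grads$conv2 <- list(W = bk2$dW, b = bk2$db)
  dr1 <- meanpool2_backward(bk2$dX, dim(fwd$r1))
  da1 <- dr1 * (fwd$a1 > 0)
  bk1 <- conv3x3_backward(fwd$X, params$conv1$W, da1)
  grads$conv1 <- list(W = bk1$dW, b = bk1$db)
  grads
}

# Stack a list of tiles into the (s, s, N, 3) training tensor, block-mean
# downsampling each tile to the network input size.
tiles_to_tensor <- function(tiles, input_size) {
  n <- length(tiles)
  X <- array(0, c(input_size, input_size, n, 3))
  for (i in seq_len(n)) {
    t_ <- tiles[[i]]
    f <- dim(t_)[1] %/% input_size
    if (f > 1) t_ <- downsample_block(t_, f)
    if (any(dim(t_)[1:2] != input_size)) {
      t_ <- resize_bilinear(t_, input_size, input_size)
    }
    X[, , i, ] <- t_
  }
  X
}

sgd_step <- function(par, grad, lr) {
  if (lr == 0) return(par)
  if (is.list(par$W)) {
    par$W <- Map(function(w, g) w - lr * g, par$W, grad$W)
  } else {
    par$W <- par$W - lr * grad$W
  }
  par$b <- par$b - lr * grad$b
  par
}

#' Train the patch classifier
#'
#' SGD on softmax cross-entropy with two parameter groups: the dense task
#' head follows [task_lr()] while the convolutional backbone follows
#' [backbone_lr()] (frozen for the first half of training, then fine-tuned
#' under the same cosine decay). `T_cur` advances continuously per
#' iteration; the per-epoch log records both learning rates at each epoch
#' start.
#'
#' @param tiles List of RGB tile arrays (any size; downsampled internally).
#'   Patch labels inherit their WSI's label (weak supervision).
#' @param labels Class label per tile; at least two classes.
#' @param cfg A [train_config()].
#' @return Object of class `patch_model`: `params`, `classes`, `cfg`, `log`
#'   (per-epoch data frame with `epoch`, `task_lr`, `backbone_lr`, `loss`,
#'   `accuracy`).
#' @export
train_patch_classifier <- function(tiles, labels, cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2) stopf("training requires at least 2 classes")
  y <- as.character(labels)
  X <- tiles_to_tensor(tiles, cfg$input_size)
  X <- X / 255 - 0.5
  Yfull <- outer(y, classes, "==") * 1
  params <- smallcnn_init(cfg$input_size, cfg$n_filters, length(classes),
                          cfg$seed)
  if (cfg$pretrained && !is.null(cfg$init_from)) {
    src <- cfg$init_from$params
    params$conv1 <- src$conv1
    params$conv2 <- src$conv2
    params$conv3 <- src$conv3
  }
  sched <- lr_schedule(cfg$eta_min, cfg$eta_max, cfg$epochs)
  n <- length(tiles)
  n_batches <- max(1L, ceiling(n / cfg$batch_size))
  log <- data.frame()
  with_seed(child_seed(cfg$seed, "sgd"), {
    for (ep in seq_len(cfg$epochs) - 1L) {
      lr_task_ep <- task_lr(sched, ep)
      lr_back_ep <- backbone_lr(sched, ep)
      ord <- sample.int(n)
      ep_loss <- 0; ep_hits <- 0
      for (bidx in seq_len(n_batches)) {
        t_cur <- ep + (bidx - 1) / n_batches
        lr_t <- task_lr(sched, t_cur)
        lr_b <- backbone_lr(sched, t_cur)
        sel <- ord[((bidx - 1) * cfg$batch_size + 1):min(bidx * cfg$batch_size, n)]
        xb <- X[, , sel, , drop = FALSE]
        yb <- Yfull[sel, , drop = FALSE]
        fwd <- smallcnn_forward(params, xb, keep = TRUE)
        loss <- -mean(log(rowSums(fwd$probs * yb) + 1e-12))
        if (!is.finite(loss)) stopf("non-finite loss at epoch %d", ep)
        ep_loss <- ep_loss + loss * length(sel)
        ep_hits <- ep_hits + sum(max.col(fwd$probs, ties.method = "first") ==
                                   max.col(yb, ties.method = "first"))
        grads <- smallcnn_backward(params, fwd, yb)
        params$dense <- sgd_step(params$dense, grads$dense, lr_t)
        params$conv1 <- sgd_step(params$conv1, grads$conv1, lr_b)
        params$conv2 <- sgd_step(params$conv2, grads$conv2, lr_b)
        params$conv3 <- sgd_step(params$conv3, grads$conv3, lr_b)
      }
      log <- rbind(log, data.frame(epoch = ep, task_lr = lr_task_ep,
                                   backbone_lr = lr_back_ep,
                                   loss = ep_loss / n,
                                   accuracy = ep_hits / n))
    }
  })
  structure(list(params = params, classes = classes, cfg = cfg, log = log),
            class = "patch_model")
}

#' Predict per-tile class likelihoods
#'
#' Pure function of the fitted model: one probability row (softmax, summing
#' to one) and an argmax label (ties -> lowest class index) per kept tile.
#' No augmentation is applied at prediction time.
#'
#' @param model A [train_patch_classifier()] fit.
#' @param tiles List of RGB tiles.
#' @param keys Optional data frame with `case_id`, `slide_id`, `grid_col`,
#'   `grid_row` per tile; when given, a full patch-likelihood table is
#'   returned.
#' @return Data frame: keys (if any), `p_<class>` columns, `label`.
#' @export
predict_likelihoods <- function(model, tiles, keys = NULL) {
  stopifnot(inherits(model, "patch_model"))
  sizes <- vapply(tiles, function(t_) dim(t_)[1], 0)
  if (length(unique(c(sizes, vapply(tiles, function(t_) dim(t_)[2], 0)))) > 1) {
    stopf("tiles have inconsistent sizes")
  }
  X <- tiles_to_tensor(tiles, model$cfg$input_size) / 255 - 0.5
  probs <- smallcnn_forward(model$params, X)$probs
  colnames(probs) <- model$classes
  out <- as.data.frame(probs)
  names(out) <- paste0("p_", model$classes)
  out$label <- model$classes[max.col(probs, ties.method = "first")]
  if (!is.null(keys)) out <- cbind(keys, out)
  out
}

#' Grad-CAM localization map for one tile
#'
#' Gradients of the target-class logit with respect to the final
#' convolutional activations are spatially averaged into channel weights;
#' the weighted activation sum is rectified, upsampled to the tile size and
#' max-normalized to `[0, 1]`. Needs no architecture modification.
#'
#' @param model A [train_patch_classifier()] fit (must expose convolutional
#'   feature maps).
#' @param tile One RGB tile.
#' @param target_class Class whose evidence is localized.
#' @return Matrix of the tile's spatial size with values in `[0, 1]`.
#' @export
gradcam <- function(model, tile, target_class) {
  stopifnot(inherits(model, "patch_model"))
  if (!model$cfg$architecture %in% "smallcnn") {
    stopf("architecture without convolutional feature maps")
  }
  k <- match(target_class, model$classes)
  if (is.na(k)) stopf("unknown class '%s'", target_class)
  tile <- as_tile(tile)
  X <- tiles_to_tensor(list(tile), model$cfg$input_size) / 255 - 0.5
  fwd <- smallcnn_forward(model$params, X, keep = TRUE)
  # d logit_k / d GAP_c = dense W[c, k]; GAP averages uniformly, so the
  # spatially averaged gradient on the final conv map is W[, k] / (H'W').
  d3 <- dim(fwd$r3)
  alpha <- model$params$dense$W[, k] / (d3[1] * d3[2])
  act <- fwd$r3[, , 1, , drop = TRUE]
  dim(act) <- c(d3[1], d3[2], d3[4])
  cam <- matrix(0, d3[1], d3[2])
  for (cch in seq_len(d3[4])) cam <- cam + alpha[cch] * act[, , cch]
  cam <- pmax(cam, 0)
  size <- dim(tile)[1]
  up <- cam[ceiling(seq_len(size) / (size / d3[1])),
            ceiling(seq_len(size) / (size / d3[2])), drop = FALSE]
  if (max(up) > 0) up <- up / max(up)
  up
}

#' Serialize / restore a patch model as JSON
#' @param model A `patch_model`.
#' @param path File path.
#' @export
write_patch_model <- function(model, path) {
  ser <- list(classes = model$classes,
              cfg = unclass(model$cfg[setdiff(names(model$cfg), "init_from")]),
              log = model$log,
              params = rapply(model$params, identity, how = "list"))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
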