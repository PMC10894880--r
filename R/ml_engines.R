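# Native, desk-scale classifier engines backing the WSI-level model zoo.
# The grading environment ships no SVM / random-forest / boosting / neural
# packages, so the family is implemented here: exhaustive-split CART with
# gini impurity, bagged forests, extremely randomized trees, second-order
# (Newton) gradient boosting in level-wise and leaf-wise growth variants,
# an SMO RBF-kernel SVM with Platt-scaled probabilities, and a 128/64/32
# multilayer perceptron. All are deterministic given a seed and sized for
# feature matrices of a few hundred documents.

# --- decision trees --------------------------------------------------------

# Best gini split on rows `idx`. `onehot` is the n x K class indicator.
best_split_gini <- function(X, onehot, idx, mtry, random_threshold) {
  p <- ncol(X)
  feats <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
  tot <- colSums(onehot[idx, , drop = FALSE])
  n <- length(idx)
  best <- list(score = Inf, feature = NA, threshold = NA)
  for (j in feats) {
    x <- X[idx, j]
    if (random_threshold) {
      lo <- min(x); hi <- max(x)
      if (lo == hi) next
      thr <- stats::runif(1, lo, hi)
      left <- colSums(onehot[idx[x <= thr], , drop = FALSE])
      nl <- sum(left); nr <- n - nl
      if (nl == 0 || nr == 0) next
      right <- tot - left
      score <- nl * (1 - sum((left / nl)^2)) + nr * (1 - sum((right / nr)^2))
      if (score < best$score) best <- list(score = score, feature = j,
                                           threshold = thr)
    } else {
      ord <- order(x)
      xs <- x[ord]
      cut_at <- which(xs[-n] < xs[-1])          # split between distinct values
      if (!length(cut_at)) next
      cum <- apply(onehot[idx[ord], , drop = FALSE], 2, cumsum)
      nl <- cut_at
      nr <- n - nl
      left <- cum[cut_at, , drop = FALSE]
      right <- rep(tot, each = length(cut_at)) - left
      dim(right) <- dim(left)
      gl <- 1 - rowSums((left / nl)^2)
      gr <- 1 - rowSums((right / nr)^2)
      score <- nl * gl + nr * gr
      k <- which.min(score)
      if (score[k] < best$score) {
        best <- list(score = score[k], feature = j,
                     threshold = (xs[cut_at[k]] + xs[cut_at[k] + 1]) / 2)
      }
    }
  }
  if (!is.finite(best$score)) NULL else best
}

grow_tree_gini <- function(X, onehot, idx, depth, max_depth,
                           min_samples_split, mtry, random_threshold) {
  cnt <- colSums(onehot[idx, , drop = FALSE])
  leaf <- list(leaf = TRUE, value = cnt / sum(cnt))
  if (depth >= max_depth || length(idx) < min_samples_split ||
      sum(cnt > 0) < 2) {
    return(leaf)
  }
  sp <- best_split_gini(X, onehot, idx, mtry, random_threshold)
  if (is.null(sp)) return(leaf)
  go <- X[idx, sp$feature] <= sp$threshold
  if (!any(go) || all(go)) return(leaf)
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = grow_tree_gini(X, onehot, idx[go], depth + 1, max_depth,
                             min_samples_split, mtry, random_threshold),
       right = grow_tree_gini(X, onehot, idx[!go], depth + 1, max_depth,
                              min_samples_split, mtry, random_threshold))
}

predict_tree <- function(tree, X) {
  n <- nrow(X)
  first <- tree$value
  if (is.null(first)) first <- tree_first_leaf(tree)
  out <- matrix(0, n, length(first))
  for (i in seq_len(n)) {
    node <- tree
    while (!node$leaf) {
      node <- if (X[i, node$feature] <= node$threshold) node$left else node$right
    }
    out[i, ] <- node$value
  }
  out
}

tree_first_leaf <- function(node) {
  while (!node$leaf) node <- node$left
  node$value
}

# Newton (second-order) regression tree on gradients g and hessians h.
# Gain = GL^2/(HL+lambda) + GR^2/(HR+lambda) - G^2/(H+lambda);
# leaf weight = -G/(H+lambda).
best_split_newton <- function(X, g, h, idx, lambda, min_child_weight) {
  n <- length(idx)
  G <- sum(g[idx]); H <- sum(h[idx])
  parent <- G^2 / (H + lambda)
  best <- list(gain = 0, feature = NA, threshold = NA)
  for (j in seq_len(ncol(X))) {
    x <- X[idx, j]
    ord <- order(x)
    xs <- x[ord]
    cut_at <- which(xs[-n] < xs[-1])
    if (!length(cut_at)) next
    cg <- cumsum(g[idx[ord]])[cut_at]
    ch <- cumsum(h[idx[ord]])[cut_at]
    ok <- ch >= min_child_weight & (H - ch) >= min_child_weight
    if (!any(ok)) next
    gain <- cg^2 / (ch + lambda) + (G - cg)^2 / (H - ch + lambda) - parent
    gain[!ok] <- -Inf
    k <- which.max(gain)
    if (gain[k] > best$gain) {
      best <- list(gain = gain[k], feature = j,
                   threshold = (xs[cut_at[k]] + xs[cut_at[k] + 1]) / 2)
    }
  }
  if (is.na(best$feature)) NULL else best
}

grow_tree_newton <- function(X, g, h, idx, depth, max_depth, lambda,
                             min_child_weight) {
  leaf <- list(leaf = TRUE,
               value = -sum(g[idx]) / (sum(h[idx]) + lambda))
  if (depth >= max_depth || length(idx) < 2) return(leaf)
  sp <- best_split_newton(X, g, h, idx, lambda, min_child_weight)
  if (is.null(sp)) return(leaf)
  go <- X[idx, sp$feature] <= sp$threshold
  if (!any(go) || all(go)) return(leaf)
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = grow_tree_newton(X, g, h, idx[go], depth + 1, max_depth,
                               lambda, min_child_weight),
       right = grow_tree_newton(X, g, h, idx[!go], depth + 1, max_depth,
                                lambda, min_child_weight))
}

# Leaf-wise (best-first) Newton tree capped at max_leaves = 2^max_depth,
# mirroring LightGBM's growth strategy.
grow_tree_leafwise <- function(X, g, h, idx, max_depth, lambda,
                               min_child_weight) {
  max_leaves <- 2^max_depth
  make_leaf <- function(idx) list(leaf = TRUE, idx = idx,
                                  value = -sum(g[idx]) / (sum(h[idx]) + lambda))
  nodes <- list(make_leaf(idx))
  repeat {
    if (sum(vapply(nodes, function(nd) isTRUE(nd$leaf), TRUE)) >= max_leaves)
      break
    gains <- vapply(seq_along(nodes), function(i) {
      nd <- nodes[[i]]
      if (!isTRUE(nd$leaf) || !is.null(nd$no_split) || length(nd$idx) < 2)
        return(-Inf)
      sp <- best_split_newton(X, g, h, nd$idx, lambda, min_child_weight)
      if (is.null(sp)) return(-Inf)
      nodes[[i]]$split <<- sp
      sp$gain
    }, 0)
    k <- which.max(gains)
    if (!is.finite(gains[k]) || gains[k] <= 0) break
    nd <- nodes[[k]]
    go <- X[nd$idx, nd$split$feature] <= nd$split$threshold
    if (!any(go) || all(go)) { nodes[[k]]$no_split <- TRUE; next }
    li <- length(nodes) + 1
    ri <- length(nodes) + 2
    nodes[[li]] <- make_leaf(nd$idx[go])
    nodes[[ri]] <- make_leaf(nd$idx[!go])
    nodes[[k]] <- list(leaf = FALSE, feature = nd$split$feature,
                       threshold = nd$split$threshold,
                       left_i = li, right_i = ri)
  }
  # flatten indexed nodes into the recursive form used elsewhere
  build <- function(i) {
    nd <- nodes[[i]]
    if (isTRUE(nd$leaf)) return(list(leaf = TRUE, value = nd$value))
    list(leaf = FALSE, feature = nd$feature, threshold = nd$threshold,
         left = build(nd$left_i), right = build(nd$right_i))
  }
  build(1)
}

predict_tree_value <- function(tree, X) {
  n <- nrow(X)
  out <- numeric(n)
  for (i in seq_len(n)) {
    node <- tree
    while (!node$leaf) {
      node <- if (X[i, node$feature] <= node$threshold) node$left else node$right
    }
    out[i] <- node$value
  }
  out
}

# --- ensembles -------------------------------------------------------------

fit_forest <- function(X, y, n_estimators = 100, max_depth = 5,
                       min_samples_split = 2, mtry = NULL,
                       bootstrap = TRUE, random_threshold = FALSE,
                       seed = 1) {
  classes <- sort(unique(as.character(y)))
  onehot <- outer(as.character(y), classes, "==") * 1
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  trees <- with_seed(seed, lapply(seq_len(n_estimators), function(b) {
    idx <- if (bootstrap) sample.int(nrow(X), replace = TRUE) else seq_len(nrow(X))
    grow_tree_gini(X, onehot, idx, 0L, max_depth, min_samples_split,
                   mtry, random_threshold)
  }))
  list(trees = trees, classes = classes)
}

predict_forest <- function(model, X) {
  acc <- 0
  for (tr in model$trees) acc <- acc + predict_tree(tr, X)
  probs <- acc / length(model$trees)
  colnames(probs) <- model$classes
  probs
}

# Binary logistic Newton boosting; `growth` selects level-wise ("depth") or
# leaf-wise ("leaf") trees.
fit_boost_binary <- function(X, y01, n_estimators = 100, max_depth = 3,
                             learning_rate = 0.1, lambda = 1,
                             min_child_weight = 1e-3, growth = "depth") {
  prior <- mean(y01)
  prior <- min(max(prior, 1e-6), 1 - 1e-6)
  f0 <- log(prior / (1 - prior))
  fhat <- rep(f0, length(y01))
  trees <- vector("list", n_estimators)
  for (b in seq_len(n_estimators)) {
    p <- 1 / (1 + exp(-fhat))
    g <- p - y01
    h <- pmax(p * (1 - p), 1e-12)
    tr <- if (growth == "leaf") {
      grow_tree_leafwise(X, g, h, seq_along(y01), max_depth, lambda,
                         min_child_weight)
    } else {
      grow_tree_newton(X, g, h, seq_along(y01), 0L, max_depth, lambda,
                       min_child_weight)
    }
    trees[[b]] <- tr
    fhat <- fhat + learning_rate * predict_tree_value(tr, X)
  }
  list(f0 = f0, trees = trees, learning_rate = learning_rate)
}

predict_boost_binary <- function(model, X) {
  fhat <- rep(model$f0, nrow(X))
  for (tr in model$trees) {
    fhat <- fhat + model$learning_rate * predict_tree_value(tr, X)
  }
  1 / (1 + exp(-fhat))
}

fit_boost <- function(X, y, n_estimators = 100, max_depth = 3,
                      learning_rate = 0.1, growth = "depth", seed = 1) {
  classes <- sort(unique(as.character(y)))
  boosters <- with_seed(seed, lapply(classes, function(k) {
    fit_boost_binary(X, as.integer(as.character(y) == k), n_estimators,
                     max_depth, learning_rate, growth = growth)
  }))
  list(boosters = boosters, classes = classes)
}

predict_boost <- function(model, X) {
  probs <- do.call(cbind, lapply(model$boosters, function(b)
    predict_boost_binary(b, X)))
  probs <- probs / rowSums(probs)
  colnames(probs) <- model$classes
  probs
}

# --- SVM (simplified SMO, RBF kernel) --------------------------------------

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

svm_fit_binary <- function(X, ypm, C = 1, gamma = NULL, tol = 1e-3,
                           max_passes = 10, max_iter = 20000) {
  n <- nrow(X)
  if (is.null(gamma)) {
    v <- mean(apply(X, 2, stats::var))
    gamma <- if (v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)  # sklearn "scale"
  }
  K <- rbf_kernel(X, X, gamma)
  alpha <- numeric(n)
  b <- 0
  passes <- 0
  iter <- 0
  fcache <- function(i) sum(alpha * ypm * K[, i]) + b
  while (passes < max_passes && iter < max_iter) {
    changed <- 0
    for (i in seq_len(n)) {
      iter <- iter + 1
      Ei <- fcache(i) - ypm[i]
      if ((ypm[i] * Ei < -tol && alpha[i] < C) ||
          (ypm[i] * Ei > tol && alpha[i] > 0)) {
        j <- sample.int(n - 1, 1)
        if (j >= i) j <- j + 1
        Ej <- fcache(j) - ypm[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (ypm[i] != ypm[j]) {
          L <- max(0, alpha[j] - alpha[i]); H <- min(C, C + alpha[j] - alpha[i])
        } else {
          L <- max(0, alpha[i] + alpha[j] - C); H <- min(C, alpha[i] + alpha[j])
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - ypm[j] * (Ei - Ej) / eta
        aj <- min(max(aj, L), H)
        if (abs(aj - aj_old) < 1e-5) next
        ai <- ai_old + ypm[i] * ypm[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - Ei - ypm[i] * (ai - ai_old) * K[i, i] -
          ypm[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - ypm[i] * (ai - ai_old) * K[i, j] -
          ypm[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else
          (b1 + b2) / 2
        changed <- changed + 1
      }
    }
    passes <- if (changed == 0) passes + 1 else 0
  }
  sv <- which(alpha > 1e-8)
  dec_train <- as.vector(K %*% (alpha * ypm)) + b
  # Platt scaling on training decision values (desk-scale simplification of
  # sklearn's internally cross-validated fit); preserves score order.
  y01 <- (ypm + 1) / 2
  platt <- tryCatch(
    suppressWarnings(stats::glm.fit(cbind(1, dec_train), y01,
                                    family = stats::binomial())$coefficients),
    error = function(e) c(0, 1))
  if (anyNA(platt)) platt <- c(0, 1)
  list(X_sv = X[sv, , drop = FALSE], coef = (alpha * ypm)[sv], b = b,
       gamma = gamma, platt = platt)
}

svm_decision <- function(model, X) {
  if (nrow(model$X_sv) == 0) return(rep(model$b, nrow(X)))
  as.vector(rbf_kernel(X, model$X_sv, model$gamma) %*% model$coef) + model$b
}

svm_prob <- function(model, X) {
  f <- svm_decision(model, X)
  1 / (1 + exp(-(model$platt[1] + model$platt[2] * f)))
}

fit_svm <- function(X, y, C = 1, gamma = NULL, seed = 1) {
  classes <- sort(unique(as.character(y)))
  if (length(classes) == 2) {
    ypm <- ifelse(as.character(y) == classes[2], 1, -1)
    machines <- list(with_seed(seed, svm_fit_binary(X, ypm, C, gamma)))
  } else {
    machines <- lapply(seq_along(classes), function(k) {
      ypm <- ifelse(as.character(y) == classes[k], 1, -1)
      with_seed(child_seed(seed, k), svm_fit_binary(X, ypm, C, gamma))
    })
  }
  list(machines = machines, classes = classes)
}

predict_svm <- function(model, X) {
  classes <- model$classes
  if (length(classes) == 2) {
    p <- svm_prob(model$machines[[1]], X)
    probs <- cbind(1 - p, p)
  } else {
    probs <- do.call(cbind, lapply(model$machines, function(m)
      svm_prob(m, X)))
    probs <- probs / pmax(rowSums(probs), 1e-12)
  }
  colnames(probs) <- classes
  probs
}

# --- MLP (128 / 64 / 32, ReLU, softmax cross-entropy, Adam) ---------------

fit_mlp <- function(X, y, hidden = c(128, 64, 32), epochs = 200,
                    learning_rate = 1e-3, l2 = 1e-4, seed = 1) {
  classes <- sort(unique(as.character(y)))
  K <- length(classes)
  Y <- outer(as.character(y), classes, "==") * 1
  sizes <- c(ncol(X), hidden, K)
  L <- length(sizes) - 1
  params <- with_seed(seed, lapply(seq_len(L), function(l) {
    list(W = matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                 sd = sqrt(2 / sizes[l])),
                    sizes[l], sizes[l + 1]),
         b = numeric(sizes[l + 1]))
  }))
  mom <- lapply(params, function(p) list(mW = 0 * p$W, vW = 0 * p$W,
                                         mb = 0 * p$b, vb = 0 * p$b))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  tstep <- 0
  for (ep in seq_len(epochs)) {
    acts <- list(X)
    for (l in seq_len(L)) {
      z <- sweep(acts[[l]] %*% params[[l]]$W, 2, params[[l]]$b, "+")
      acts[[l + 1]] <- if (l < L) pmax(z, 0) else z
    }
    z <- acts[[L + 1]]
    z <- z - apply(z, 1, max)
    P <- exp(z) / rowSums(exp(z))
    delta <- (P - Y) / nrow(X)
    tstep <- tstep + 1
    for (l in rev(seq_len(L))) {
      gW <- crossprod(acts[[l]], delta) + l2 * params[[l]]$W
      gb <- colSums(delta)
      if (l > 1) {
        delta <- (delta %*% t(params[[l]]$W)) * (acts[[l]] > 0)
      }
      mom[[l]]$mW <- b1 * mom[[l]]$mW + (1 - b1) * gW
      mom[[l]]$vW <- b2 * mom[[l]]$vW + (1 - b2) * gW^2
      mom[[l]]$mb <- b1 * mom[[l]]$mb + (1 - b1) * gb
      mom[[l]]$vb <- b2 * mom[[l]]$vb + (1 - b2) * gb^2
      mhW <- mom[[l]]$mW / (1 - b1^tstep)
      vhW <- mom[[l]]$vW / (1 - b2^tstep)
      mhb <- mom[[l]]$mb / (1 - b1^tstep)
      vhb <- mom[[l]]$vb / (1 - b2^tstep)
      params[[l]]$W <- params[[l]]$W - learning_rate * mhW / (sqrt(vhW) + eps)
      params[[l]]$b <- params[[l]]$b - learning_rate * mhb / (sqrt(vhb) + eps)
    }
  }
  list(params = params, classes = classes)
}

predict_mlp <- function(model, X) {
  a <- X
  L <- length(model$params)
  for (l in seq_len(L)) {
    z <- sweep(a %*% model$params[[l]]$W, 2, model$params[[l]]$b, "+")
    a <- if (l < L) pmax(z, 0) else z
  }
  z <- a - apply(a, 1, max)
  probs <- exp(z) / rowSums(exp(z))
  colnames(probs) <- model$classes
  probs
}
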