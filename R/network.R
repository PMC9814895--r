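# The 3D convolutional pose classifier.
#
# Architecture: input (C channels, D^3 voxels) -> [conv 3^3 stride 1 pad 1,
# ReLU, max-pool 2^3] x n -> fully connected -> softmax over {decoy, native}
# plus a sigmoid contact-mode-score regression head sharing the FC layer.
# Training minimizes lambda_cls * log-loss + lambda_cms * hinged
# pseudo-Huber CMS loss with an SGD-with-momentum variant.

#' Convert a channel stack to a network input tensor
#'
#' @param stack a [channel_stack()] (or an array already in tensor layout).
#' @return Numeric array of dim `c(C, D, D, D)` (channel-fastest).
#' @export
stack_to_tensor <- function(stack) {
  if (inherits(stack, "channel_stack")) return(stack$data)
  stopifnot(is.array(stack), length(dim(stack)) == 4)
  stack
}

#' Training configuration for the pose classifier
#'
#' Defaults are the desk-scale profile: a coarse grid, small filter counts
#' and 2000 iterations, sized so that a full train/evaluate cycle runs on one
#' CPU in about a minute. `profile = "full"` switches to the full-scale
#' settings (48^3 input, filters 32/64/128, 40000 iterations) used for
#' production-size training.
#'
#' @param iterations number of SGD iterations (batches).
#' @param batch_size minibatch size.
#' @param learning_rate base learning rate.
#' @param momentum classical momentum coefficient.
#' @param lr_decay multiplicative decay applied at `lr_step` of training.
#' @param lr_step fraction of iterations after which the decay applies.
#' @param lambda_cls,lambda_cms loss weights for the classification and CMS
#'   heads.
#' @param delta pseudo-Huber transition scale for the CMS loss.
#' @param cms_cutoff CMS below which a pose is "undefined" and only a hinge
#'   penalty applies (0.44).
#' @param filters convolution filter counts, one per conv layer.
#' @param augment apply random rigid augmentation per sample (requires
#'   re-rasterization; off in the desk profile).
#' @param seed integer seed fixing initialization and batch sampling.
#' @param profile `"desk"` or `"full"`.
#' @return A `training_config` list.
#' @export
training_config <- function(iterations = 2000, batch_size = 16,
                            learning_rate = 0.01, momentum = 0.9,
                            lr_decay = 0.1, lr_step = 0.75,
                            lambda_cls = 1, lambda_cms = 1,
                            delta = 1, cms_cutoff = 0.44,
                            filters = c(8, 16, 32), augment = FALSE,
                            seed = 1, profile = c("desk", "full")) {
  profile <- match.arg(profile)
  if (profile == "full") {
    if (missing(iterations)) iterations <- 40000
    if (missing(filters)) filters <- c(32, 64, 128)
  }
  if (iterations < 1) stopf("iterations must be >= 1")
  structure(list(iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 lr_decay = lr_decay, lr_step = lr_step,
                 lambda_cls = lambda_cls, lambda_cms = lambda_cms,
                 delta = delta, cms_cutoff = cms_cutoff,
                 filters = filters, augment = isTRUE(augment),
                 seed = as.integer(seed), profile = profile),
            class = "training_config")
}

#' Build an initialized pose-classifier network
#'
#' @param n_channels input channel count C (34 protein+ligand, 35 with the
#'   occupancy channel, 37 with thermo channels, plus any probe channels).
#' @param dims input edge length in voxels; must be divisible by
#'   `2^length(filters)` (each conv block halves the edge by max pooling).
#' @param filters filter counts per conv layer.
#' @param seed integer seed; initialization is deterministic per seed
#'   (He-scaled normal weights, zero biases).
#' @return An object of class `hydranet` (untrained).
#' @export
build_network <- function(n_channels, dims = 8, filters = c(8, 16, 32), seed = 1) {
  n_conv <- length(filters)
  if (dims %% (2^n_conv) != 0)
    stopf("dims (%d) must be divisible by 2^%d for %d pooling steps",
          dims, n_conv, n_conv)
  with_seed(seed, {
    layers <- vector("list", n_conv)
    cin <- n_channels
    for (k in seq_len(n_conv)) {
      cout <- filters[k]
      sd <- sqrt(2 / (27 * cin))
      w <- array(rnorm(cout * cin * 27, sd = sd), dim = c(cin, cout, 3, 3, 3))
      layers[[k]] <- list(w = w, b = numeric(cout))
      cin <- cout
    }
    d_out <- dims / 2^n_conv
    n_feat <- cin * d_out^3
    fc <- list(w = matrix(rnorm(n_feat * 3, sd = sqrt(2 / n_feat)), n_feat, 3),
               b = numeric(3))
  })
  structure(list(n_channels = n_channels, dims = as.integer(dims),
                 filters = filters, seed = as.integer(seed),
                 layers = layers, fc = fc, trained = FALSE,
                 loss_trace = NULL, config = NULL),
            class = "hydranet")
}

# Forward pass. `keep = TRUE` records per-layer activations for the
# training backward pass and for relevance propagation.
nn_forward <- function(net, x, keep = FALSE) {
  x <- stack_to_tensor(x)
  dm <- dim(x)
  if (dm[1] != net$n_channels || dm[2] != net$dims)
    stopf("input tensor is %dx%d^3 but the network expects %dx%d^3",
          dm[1], dm[2], net$n_channels, net$dims)
  cur <- as.numeric(x)
  d <- net$dims
  cin <- net$n_channels
  acts <- if (keep) list(input = cur) else NULL
  rec <- list()
  for (k in seq_along(net$layers)) {
    ly <- net$layers[[k]]
    cout <- dim(ly$w)[2]
    pre <- .conv3d_fwd_cpp(cur, as.numeric(ly$w), ly$b, cin, cout, d)
    post <- pmax(pre, 0)
    pl <- .maxpool_fwd_cpp(post, cout, d)
    if (keep) rec[[k]] <- list(pre = pre, post = post, pooled = pl$y,
                               argmax = pl$argmax, d_in = d, cin = cin,
                               cout = cout)
    cur <- pl$y
    d <- d / 2L
    cin <- cout
  }
  feat <- cur
  logits <- drop(crossprod(net$fc$w, feat)) + net$fc$b
  z <- logits[1:2] - max(logits[1:2])
  p <- exp(z) / sum(exp(z))
  out <- list(p_decoy = p[1], p_native = p[2],
              cms_pred = 1 / (1 + exp(-logits[3])), logits = logits)
  if (keep) { out$layers <- rec; out$feat <- feat; out$input <- acts$input }
  out
}

#' Two-class pose classification loss
#'
#' Log loss on the native-class probability: `-log p` for a native pose,
#' `-log(1 - p)` for a decoy. Probabilities outside `(0, 1)` are clamped to
#' `[1e-7, 1 - 1e-7]` with a warning.
#'
#' @param p_native predicted probability that the pose is native.
#' @param is_native logical label.
#' @return Non-negative loss (vectorized).
#' @export
classification_loss <- function(p_native, is_native) {
  if (any(p_native <= 0 | p_native >= 1)) {
    warnf("probabilities clamped to [1e-7, 1 - 1e-7]")
    p_native <- pmin(pmax(p_native, 1e-7), 1 - 1e-7)
  }
  ifelse(is_native, -log(p_native), -log(1 - p_native))
}

pseudo_huber <- function(a, delta) delta^2 * (sqrt(1 + (a / delta)^2) - 1)

#' Hinged pseudo-Huber contact-mode-score loss
#'
#' For poses whose true CMS is at least `cutoff` (0.44), a pseudo-Huber loss
#' on the prediction error. Poses below the cutoff have no meaningful
#' overlap with the native pose ("undefined"); they incur a penalty only if
#' the prediction exceeds the cutoff (hinge):
#' `pseudoHuber(max(0, cms_pred - cutoff))`.
#'
#' @param cms_pred,cms_true predicted and true contact mode scores in
#'   `[0, 1]` (vectorized).
#' @param delta pseudo-Huber transition scale.
#' @param cutoff the CMS "undefined" cutoff (0.44).
#' @return Non-negative loss.
#' @export
cms_loss <- function(cms_pred, cms_true, delta = 1, cutoff = 0.44) {
  stopifnot(delta > 0)
  ifelse(cms_true >= cutoff,
         pseudo_huber(cms_pred - cms_true, delta),
         pseudo_huber(pmax(0, cms_pred - cutoff), delta))
}

# Gradient of the combined loss wrt the three FC outputs, plus the loss.
loss_and_dlogits <- function(fwd, is_native, cms_true, config) {
  p <- c(fwd$p_decoy, fwd$p_native)
  target <- if (is_native) c(0, 1) else c(1, 0)
  l_cls <- -log(max(p[if (is_native) 2 else 1], 1e-12))
  dlog <- numeric(3)
  dlog[1:2] <- config$lambda_cls * (p - target)
  cpred <- fwd$cms_pred
  if (cms_true >= config$cms_cutoff) {
    a <- cpred - cms_true
  } else {
    a <- max(0, cpred - config$cms_cutoff)
  }
  l_cms <- pseudo_huber(a, config$delta)
  dph <- a / sqrt(1 + (a / config$delta)^2)
  dlog[3] <- config$lambda_cms * dph * cpred * (1 - cpred)
  list(loss = config$lambda_cls * l_cls + config$lambda_cms * l_cms,
       dlogits = dlog)
}

# Backward pass: gradients for all weights given dlogits.
nn_backward <- function(net, fwd, dlogits) {
  grads <- list(fc_w = fwd$feat %o% dlogits, fc_b = dlogits)
  dcur <- drop(net$fc$w %*% dlogits)
  conv_grads <- vector("list", length(net$layers))
  for (k in rev(seq_along(net$layers))) {
    rec <- fwd$layers[[k]]
    dpost <- .maxpool_bwd_cpp(dcur, rec$argmax, length(rec$post))
    dpre <- dpost * (rec$pre > 0)
    below <- if (k == 1) fwd$input else fwd$layers[[k - 1]]$pooled
    gw <- .conv3d_bwd_w_cpp(below, dpre, rec$cin, rec$cout, rec$d_in)
    conv_grads[[k]] <- gw
    if (k > 1)
      dcur <- .conv3d_bwd_x_cpp(dpre, as.numeric(net$layers[[k]]$w),
                                rec$cin, rec$cout, rec$d_in)
  }
  grads$conv <- conv_grads
  grads
}

# Flatten a dataset (list of systems) into parallel sample vectors.
flatten_dataset <- function(dataset) {
  tensors <- list(); labels <- logical(0); cms <- numeric(0)
  sys_idx <- integer(0); pose_ids <- character(0)
  for (s in seq_along(dataset)) {
    sys <- dataset[[s]]
    stacks <- lapply(sys$stacks, stack_to_tensor)
    tensors <- c(tensors, stacks)
    labels <- c(labels, sys$labels)
    cms <- c(cms, if (!is.null(sys$cms)) sys$cms else rep(1, length(stacks)))
    sys_idx <- c(sys_idx, rep(s, length(stacks)))
    pose_ids <- c(pose_ids, if (!is.null(sys$pose_ids)) sys$pose_ids
                  else sprintf("pose_%03d", seq_along(stacks)))
  }
  list(tensors = tensors, labels = labels, cms = cms, sys_idx = sys_idx,
       pose_ids = pose_ids)
}

#' Train the pose classifier
#'
#' Fits the 3D CNN on a labeled pose dataset with minibatch SGD plus
#' momentum, minimizing `lambda_cls * classification loss + lambda_cms *
#' hinged pseudo-Huber CMS loss`. Training is deterministic per
#' `config$seed` (which fixes both the initialization and the batch
#' sampling).
#'
#' @param dataset a list of systems; each system is a list with `stacks` (a
#'   list of [channel_stack()]s or tensors, one per pose), `labels` (logical
#'   is-native per pose), optional `cms` (numeric in `[0, 1]` per pose) and
#'   optional `pose_ids`. Must contain at least one native and one decoy
#'   pose overall.
#' @param config a [training_config()].
#' @return A fitted `hydranet`. Its `loss_trace` holds the per-iteration
#'   batch loss; `summary()` reports the best-so-far (non-increasing)
#'   envelope.
#' @export
train_pose_classifier <- function(dataset, config = training_config()) {
  flat <- flatten_dataset(dataset)
  n <- length(flat$tensors)
  if (n < 2) stopf("dataset must contain at least two poses")
  if (all(flat$labels) || !any(flat$labels))
    stopf("dataset must contain at least one native and one decoy pose")
  dm <- dim(flat$tensors[[1]])
  net <- build_network(dm[1], dm[2], config$filters, seed = config$seed)
  net$config <- config
  vel <- list(fc_w = net$fc$w * 0, fc_b = numeric(3),
              conv = lapply(net$layers, function(l)
                list(dw = as.numeric(l$w) * 0, db = l$b * 0)))
  trace <- numeric(config$iterations)
  with_seed(derive_seed(config$seed, 1), {
    for (it in seq_len(config$iterations)) {
      lr <- config$learning_rate *
        if (it > config$lr_step * config$iterations) config$lr_decay else 1
      batch <- sample.int(n, config$batch_size, replace = n < config$batch_size)
      gacc <- NULL
      loss <- 0
      for (s in batch) {
        fwd <- nn_forward(net, flat$tensors[[s]], keep = TRUE)
        ld <- loss_and_dlogits(fwd, flat$labels[s], flat$cms[s], config)
        loss <- loss + ld$loss
        g <- nn_backward(net, fwd, ld$dlogits)
        if (is.null(gacc)) gacc <- g
        else {
          gacc$fc_w <- gacc$fc_w + g$fc_w
          gacc$fc_b <- gacc$fc_b + g$fc_b
          for (k in seq_along(g$conv)) {
            gacc$conv[[k]]$dw <- gacc$conv[[k]]$dw + g$conv[[k]]$dw
            gacc$conv[[k]]$db <- gacc$conv[[k]]$db + g$conv[[k]]$db
          }
        }
      }
      bs <- length(batch)
      vel$fc_w <- config$momentum * vel$fc_w - lr * gacc$fc_w / bs
      vel$fc_b <- config$momentum * vel$fc_b - lr * gacc$fc_b / bs
      net$fc$w <- net$fc$w + vel$fc_w
      net$fc$b <- net$fc$b + vel$fc_b
      for (k in seq_along(net$layers)) {
        vel$conv[[k]]$dw <- config$momentum * vel$conv[[k]]$dw -
          lr * gacc$conv[[k]]$dw / bs
        vel$conv[[k]]$db <- config$momentum * vel$conv[[k]]$db -
          lr * gacc$conv[[k]]$db / bs
        net$layers[[k]]$w <- array(as.numeric(net$layers[[k]]$w) +
                                   vel$conv[[k]]$dw, dim = dim(net$layers[[k]]$w))
        net$layers[[k]]$b <- net$layers[[k]]$b + vel$conv[[k]]$db
      }
      trace[it] <- loss / bs
    }
  })
  net$trained <- TRUE
  net$loss_trace <- trace
  net
}

#' @export
print.hydranet <- function(x, ...) {
  cat(sprintf("hydranet: %d input channels, %d^3 voxels, conv filters (%s), %s\n",
              x$n_channels, x$dims, paste(x$filters, collapse = ", "),
              if (x$trained) "trained" else "untrained"))
  if (x$trained)
    cat(sprintf("  final batch loss %.4f (initial %.4f) over %d iterations\n",
                tail(x$loss_trace, 1), x$loss_trace[1], length(x$loss_trace)))
  invisible(x)
}

#' @export
summary.hydranet <- function(object, ...) {
  out <- list(n_channels = object$n_channels, dims = object$dims,
              filters = object$filters, trained = object$trained,
              n_parameters = length(coef(object)))
  if (object$trained) {
    out$initial_loss <- object$loss_trace[1]
    out$final_loss <- tail(object$loss_trace, 1)
    out$best_so_far <- cummin(object$loss_trace)
  }
  class(out) <- "summary.hydranet"
  out
}

#' @export
print.summary.hydranet <- function(x, ...) {
  cat(sprintf("hydranet with %d parameters (%d channels, %d^3 input)\n",
              x$n_parameters, x$n_channels, x$dims))
  if (x$trained)
    cat(sprintf("  loss %.4f -> %.4f (best %.4f)\n", x$initial_loss,
                x$final_loss, min(x$best_so_far)))
  invisible(x)
}

#' @export
coef.hydranet <- function(object, ...) {
  unlist(c(lapply(object$layers, function(l) c(as.numeric(l$w), l$b)),
           list(as.numeric(object$fc$w), object$fc$b)))
}

#' Predict native-pose probabilities
#'
#' @param object a trained `hydranet`.
#' @param newdata a [channel_stack()], a tensor, or a list of either.
#' @param ... unused.
#' @return A data frame with `p_native` and `cms_pred`, one row per input.
#' @export
predict.hydranet <- function(object, newdata, ...) {
  items <- if (inherits(newdata, "channel_stack") ||
               (is.array(newdata) && length(dim(newdata)) == 4)) list(newdata)
           else newdata
  res <- lapply(items, function(x) {
    f <- nn_forward(object, x)
    c(f$p_native, f$cms_pred)
  })
  m <- do.call(rbind, res)
  data.frame(p_native = m[, 1], cms_pred = m[, 2])
}

#' Score and rank the poses of one system
#'
#' @param net a trained `hydranet`.
#' @param stacks list of pose inputs ([channel_stack()]s or tensors).
#' @param pose_ids character ids, used for deterministic tie-breaking
#'   (lexicographic) among equal scores.
#' @param labels optional logical is-native labels, carried through.
#' @return Data frame ordered by decreasing `p_native` with columns
#'   `pose_id`, `p_native`, `rank` and (if given) `is_native`.
#' @export
score_and_rank <- function(net, stacks, pose_ids = NULL, labels = NULL) {
  if (is.null(pose_ids)) pose_ids <- sprintf("pose_%03d", seq_along(stacks))
  p <- predict(net, stacks)$p_native
  ord <- order(-p, pose_ids)
  out <- data.frame(pose_id = pose_ids[ord], p_native = p[ord],
                    rank = seq_along(ord))
  if (!is.null(labels)) out$is_native <- labels[ord]
  out
}

#' Top-N pose ranking success
#'
#' The fraction of systems with at least one native-labeled pose among the
#' first `n` ranks.
#'
#' @param rankings a list with one element per system: either the data frame
#'   from [score_and_rank()] (with an `is_native` column) or a logical
#'   vector of labels in rank order.
#' @param n the N in top-N.
#' @return Fraction in `[0, 1]`.
#' @export
topn_success <- function(rankings, n) {
  if (n < 1) stopf("N must be >= 1")
  hits <- vapply(rankings, function(r) {
    lab <- if (is.data.frame(r)) r$is_native else r
    if (length(lab) == 0) stopf("every system needs at least one pose")
    any(head(lab, n))
  }, logical(1))
  mean(hits)
}
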