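# Model assembly, loss, gradient computation, Adam updates, metrics, and the
# ablation variants. The scheduler (psystem.R) drives these pieces; they are
# also callable directly as a plain pipeline.

# Deterministic derived seeds: every source of randomness (parameter init,
# per-iteration per-view dropout masks) draws from a seed computed here, so
# sub-cell execution order cannot affect results. Kept below 2^31.
derive_seed <- function(base, a = 0L, b = 0L) {
  m <- 2147483629
  s <- (as.numeric(base) %% m)
  s <- (s * 69069 + as.numeric(a) * 40503 + as.numeric(b) * 10007 + 1) %% m
  as.integer(s) + 1L
}

# Precomputed immutable pieces of a network used every iteration.
network_data <- function(net) {
  nbrs <- lapply(net$views, neighborhoods, include_self = TRUE)
  edges <- lapply(nbrs, edge_expansion)
  multilabel <- is_multilabel(net)
  c_dim <- n_classes(net)
  if (multilabel) {
    y_mat <- net$labels
  } else {
    y_mat <- matrix(0, n_nodes(net), c_dim)
    y_mat[cbind(seq_len(n_nodes(net)), net$labels + 1L)] <- 1
  }
  masks <- net$masks
  if (is.null(masks) || is.null(masks$train)) {
    stop("network needs a train mask to be trained")
  }
  list(x = net$features, edges = edges, y = net$labels, y_mat = y_mat,
       masks = masks, k = n_views(net), n_classes = c_dim,
       multilabel = multilabel, task = if (multilabel) "multilabel" else "multiclass")
}

#' Initialize all model parameters for a network
#'
#' One attention encoder per view (identical architecture, independent
#' Glorot draws from per-view derived seeds) plus view-fusion parameters.
#' The last encoder layer emits `n_classes` dimensions, so the fused
#' representation is directly softmax-ready; no extra linear head sits
#' between fusion and the class probabilities.
#'
#' @param network a `multiview_network`.
#' @param config configuration list (see [default_config()]).
#' @return list with `encoders` (one `view_encoder` per view), `fusion`
#'   (or NULL under mean fusion), and bookkeeping fields.
#' @export
init_model <- function(network, config = default_config()) {
  mc <- config$model
  fc <- config$fusion
  c_dim <- n_classes(network)
  dims <- c(ncol(network$features), rep(mc$hidden_dim, mc$layers - 1L), c_dim)
  base <- config$train$seed
  encoders <- lapply(seq_len(n_views(network)), function(m) {
    init_encoder(dims, heads = mc$heads, seed = derive_seed(base, 0L, m),
                 leaky_slope = mc$leaky_slope,
                 dropout_input = mc$dropout_input,
                 dropout_attention = mc$dropout_attention)
  })
  fusion <- NULL
  if (identical(fc$mode, "attention")) {
    set.seed(derive_seed(base, 0L, 0L))
    fusion <- init_fusion(c_dim, f_hidden = fc$hidden_dim,
                          leaky_slope = mc$leaky_slope)
  }
  list(encoders = encoders, fusion = fusion,
       fusion_mode = fc$mode, scope = fc$scope, query = fc$query)
}

# Full forward pass with caches. In training mode the dropout masks of view m
# at iteration `iter` come from a derived seed, independent of execution order.
model_forward <- function(model, nd, training = FALSE, iter = 0L,
                          base_seed = 1L) {
  k <- nd$k
  view_caches <- vector("list", k)
  view_reps <- vector("list", k)
  for (m in seq_len(k)) {
    seed <- if (training) derive_seed(base_seed, iter, m) else NULL
    vc <- view_encode_cache(nd$x, nd$edges[[m]], model$encoders[[m]],
                            training = training, seed = seed)
    view_caches[[m]] <- vc
    view_reps[[m]] <- vc$out
  }
  if (model$fusion_mode == "attention") {
    fc <- fusion_forward_cache(view_reps, model$fusion, model$scope,
                               model$query)
    z <- fc$Z
  } else {
    fc <- NULL
    z <- mean_fuse(view_reps)
  }
  pred <- predict_labels(z, nd$task)
  list(view_caches = view_caches, view_reps = view_reps, fusion_cache = fc,
       Z = z, prob = pred$prob, labels = pred$labels)
}

# dZ of the masked cross-entropy for both tasks: (P - Y) on masked rows.
loss_grad_z <- function(prob, y_mat, mask) {
  dz <- prob - y_mat
  dz[!mask, ] <- 0
  dz
}

# Full backward pass; returns gradients shaped like the parameter list.
model_backward <- function(model, nd, fwd, mask, training = TRUE) {
  dz <- loss_grad_z(fwd$prob, nd$y_mat, mask)
  if (model$fusion_mode == "attention") {
    fb <- fusion_backward(dz, fwd$fusion_cache, model$fusion)
    d_views <- fb$d_views
    fusion_grads <- list(Tm = fb$dTm, b = fb$db)
  } else {
    d_views <- lapply(seq_len(nd$k), function(j) dz / nd$k)
    fusion_grads <- NULL
  }
  encoder_grads <- vector("list", nd$k)
  for (m in seq_len(nd$k)) {
    bk <- view_encode_backward(d_views[[m]], fwd$view_caches[[m]],
                               nd$edges[[m]], model$encoders[[m]],
                               training = training)
    encoder_grads[[m]] <- bk$layer_grads
  }
  list(encoders = encoder_grads, fusion = fusion_grads)
}

# --- flat parameter walk (shared by Adam and tests) ----------------------

param_arrays <- function(model) {
  out <- list()
  for (m in seq_along(model$encoders)) {
    enc <- model$encoders[[m]]
    for (l in seq_along(enc$layers)) {
      for (h in seq_along(enc$layers[[l]]$heads)) {
        hd <- enc$layers[[l]]$heads[[h]]
        out[[sprintf("enc%d.l%d.h%d.W", m, l, h)]] <- hd$W
        out[[sprintf("enc%d.l%d.h%d.a", m, l, h)]] <- hd$a
      }
    }
  }
  if (!is.null(model$fusion)) {
    out[["fusion.Tm"]] <- model$fusion$Tm
    out[["fusion.b"]] <- model$fusion$b
  }
  out
}

grad_arrays <- function(model, grads) {
  out <- list()
  for (m in seq_along(model$encoders)) {
    for (l in seq_along(grads$encoders[[m]])) {
      for (h in seq_along(grads$encoders[[m]][[l]])) {
        g <- grads$encoders[[m]][[l]][[h]]
        out[[sprintf("enc%d.l%d.h%d.W", m, l, h)]] <- g$W
        out[[sprintf("enc%d.l%d.h%d.a", m, l, h)]] <- g$a
      }
    }
  }
  if (!is.null(model$fusion)) {
    out[["fusion.Tm"]] <- grads$fusion$Tm
    out[["fusion.b"]] <- grads$fusion$b
  }
  out
}

set_param_arrays <- function(model, arrays) {
  for (m in seq_along(model$encoders)) {
    enc <- model$encoders[[m]]
    for (l in seq_along(enc$layers)) {
      for (h in seq_along(enc$layers[[l]]$heads)) {
        model$encoders[[m]]$layers[[l]]$heads[[h]]$W <-
          arrays[[sprintf("enc%d.l%d.h%d.W", m, l, h)]]
        model$encoders[[m]]$layers[[l]]$heads[[h]]$a <-
          arrays[[sprintf("enc%d.l%d.h%d.a", m, l, h)]]
      }
    }
  }
  if (!is.null(model$fusion)) {
    model$fusion$Tm <- arrays[["fusion.Tm"]]
    model$fusion$b <- arrays[["fusion.b"]]
  }
  model
}

adam_init <- function(model) {
  pa <- param_arrays(model)
  list(m = lapply(pa, function(x) x * 0), v = lapply(pa, function(x) x * 0),
       t = 0L)
}

# One Adam step with decoupled-style L2 weight decay folded into the gradient
# (the convention of the optimizer this family of models is trained with).
adam_step <- function(model, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  pa <- param_arrays(model)
  ga <- grad_arrays(model, grads)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(pa)) {
    g <- ga[[nm]] + weight_decay * pa[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    pa[[nm]] <- pa[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(model = set_param_arrays(model, pa), state = state)
}

# --- loss and metrics ----------------------------------------------------

#' Cross-entropy loss over a node subset
#'
#' Multiclass: categorical cross-entropy `-sum_i log p_i[y_i]` over masked
#' nodes (the binary form applied per class to a softmax is ill-posed).
#' Multilabel/binary: `-sum_i sum_c [y log p + (1-y) log(1-p)]`. Probabilities
#' are clipped to `[1e-12, 1 - 1e-12]` before the logarithms.
#'
#' @param y 0-based class indices (multiclass) or V x C binary matrix.
#' @param p V x C probability matrix.
#' @param mask logical vector of nodes to include (non-empty).
#' @param task `"multiclass"` or `"multilabel"`.
#' @return scalar loss, >= 0.
#' @export
cross_entropy <- function(y, p, mask = NULL,
                          task = c("multiclass", "multilabel")) {
  task <- match.arg(task)
  p <- as.matrix(p)
  if (is.null(mask)) mask <- rep(TRUE, nrow(p))
  if (!any(mask)) stop("empty mask in cross_entropy")
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  if (task == "multiclass") {
    idx <- cbind(which(mask), y[mask] + 1L)
    -sum(log(pc[idx]))
  } else {
    ym <- y[mask, , drop = FALSE]
    pm <- pc[mask, , drop = FALSE]
    -sum(ym * log(pm) + (1 - ym) * log(1 - pm))
  }
}

#' Classification accuracy over a node subset
#' @param y_true,y_pred 0-based class indices (multiclass) or binary matrices
#'   (multilabel; elementwise accuracy). @param mask logical node subset.
#' @return value in `[0, 1]`.
#' @export
accuracy_score <- function(y_true, y_pred, mask = NULL) {
  v <- if (is.matrix(y_true)) nrow(y_true) else length(y_true)
  if (is.null(mask)) mask <- rep(TRUE, v)
  if (!any(mask)) stop("empty mask in accuracy_score")
  if (is.matrix(y_true)) {
    mean(y_true[mask, , drop = FALSE] == y_pred[mask, , drop = FALSE])
  } else {
    mean(y_true[mask] == y_pred[mask])
  }
}

#' Micro-averaged precision, recall and F1
#'
#' Inputs are binary indicator structures (multiclass labels are expanded to
#' one-hot internally). Zero-denominator convention: precision or recall is 0
#' when its denominator is 0, and F1 is 0 when P + R = 0.
#'
#' @param y_true,y_pred 0-based class index vectors or binary matrices.
#' @param mask logical node subset. @param n_classes class count (needed for
#'   one-hot expansion when labels are index vectors).
#' @return named list with `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(y_true, y_pred, mask = NULL,
                                n_classes = NULL) {
  to_mat <- function(y) {
    if (is.matrix(y)) return(y)
    cc <- if (is.null(n_classes)) max(y_true, y_pred) + 1L else n_classes
    m <- matrix(0L, length(y), cc)
    m[cbind(seq_along(y), y + 1L)] <- 1L
    m
  }
  yt <- to_mat(y_true); yp <- to_mat(y_pred)
  if (is.null(mask)) mask <- rep(TRUE, nrow(yt))
  yt <- yt[mask, , drop = FALSE]; yp <- yp[mask, , drop = FALSE]
  tp <- sum(yt == 1 & yp == 1)
  fp <- sum(yt == 0 & yp == 1)
  fn <- sum(yt == 1 & yp == 0)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(precision = prec, recall = rec, f1 = f1)
}

#' Pick the best-iteration predictions from a training trace
#'
#' Returns the stored hard predictions of the iteration with minimum
#' selection loss; the earliest iteration wins exact ties.
#'
#' @param trace a `train_trace` (fields `selection_loss`, `predictions`).
#' @return list with `labels`, `prob`, `iteration`.
#' @export
select_best <- function(trace) {
  if (length(trace$selection_loss) == 0L) stop("empty training trace")
  best <- which.min(trace$selection_loss)   # which.min takes the first minimum
  list(labels = trace$predictions[[best]], prob = trace$prob[[best]],
       iteration = best)
}

# Selection loss for r42: validation loss when a validation mask exists,
# else training loss.
selection_mask <- function(nd, selection = "auto") {
  if (selection == "train_loss") return(nd$masks$train)
  if (selection == "val_loss") {
    if (is.null(nd$masks$val)) stop("selection = val_loss but no val mask")
    return(nd$masks$val)
  }
  if (!is.null(nd$masks$val) && any(nd$masks$val)) nd$masks$val else nd$masks$train
}

#' One training iteration (gradient step plus post-step evaluation)
#'
#' Performs one full-batch Adam step on the masked cross-entropy, then an
#' eval-mode forward pass to record losses and hard predictions on all nodes.
#'
#' @param model parameter list from [init_model()]. @param nd network data
#'   (internal form). @param opt Adam state. @param config configuration.
#' @param iter 1-based iteration number (seeds the dropout masks).
#' @return list with updated `model`, `opt`, `train_loss`, `val_loss`,
#'   `selection_loss`, `prob`, `labels`.
#' @export
train_epoch <- function(model, nd, opt, config, iter) {
  tc <- config$train
  fwd <- model_forward(model, nd, training = TRUE, iter = iter,
                       base_seed = tc$seed)
  grads <- model_backward(model, nd, fwd, nd$masks$train, training = TRUE)
  if (tc$learning_rate > 0) {
    up <- adam_step(model, grads, opt, tc$learning_rate, tc$weight_decay)
    model <- up$model; opt <- up$state
  }
  ev <- model_forward(model, nd, training = FALSE)
  train_loss <- cross_entropy(nd$y, ev$prob, nd$masks$train, nd$task)
  if (!is.finite(train_loss)) {
    stop(sprintf("non-finite training loss at iteration %d", iter))
  }
  val_loss <- if (!is.null(nd$masks$val) && any(nd$masks$val)) {
    cross_entropy(nd$y, ev$prob, nd$masks$val, nd$task)
  } else NA_real_
  sel_mask <- selection_mask(nd, tc$selection)
  sel_loss <- cross_entropy(nd$y, ev$prob, sel_mask, nd$task)
  list(model = model, opt = opt, train_loss = train_loss, val_loss = val_loss,
       selection_loss = sel_loss, prob = ev$prob, labels = ev$labels)
}

#' Restrict a multi-view network to a single view
#' @param net a `multiview_network`. @param view 1-based view index.
#' @return a k = 1 `multiview_network`.
#' @export
single_view_network <- function(net, view = 1L) {
  multiview_network(net$node_ids, net$features, net$labels,
                    net$views[view], masks = net$masks,
                    label_levels = net$label_levels)
}

#' Evaluate predictions into a per-split metric report
#' @param net network with masks. @param labels predicted labels.
#' @return nested list split -> {accuracy, precision, recall, f1}.
#' @export
metric_report <- function(net, labels) {
  splits <- list(train = net$masks$train, val = net$masks$val,
                 test = net$masks$test)
  splits <- splits[!vapply(splits, is.null, TRUE)]
  out <- list()
  for (nm in names(splits)) {
    msk <- splits[[nm]]
    if (!any(msk)) next
    prf <- precision_recall_f1(net$labels, labels, msk,
                               n_classes = n_classes(net))
    out[[nm]] <- c(list(accuracy = accuracy_score(net$labels, labels, msk)),
                   prf)
  }
  out
}

#' Run the informative-plus-noise ablation study
#'
#' For each seed, generates the fixed two-view benchmark (one informative
#' planted-community view, one pure-noise view), trains the full
#' attention-fusion model, the mean-fusion variant (MMV) and the single-view
#' variant on the noise view (SV), and records test accuracy. For the full
#' model it also records the trained per-node fusion weight of the
#' informative view, averaged over the labeled (train + validation) nodes.
#'
#' @param seeds integer vector of generator/training seeds.
#' @param config configuration list; the training protocol is identical for
#'   all variants.
#' @return data.frame with one row per seed: `seed`, `full`, `mmv`, `sv`
#'   (test accuracies) and `informative_weight`.
#' @export
ablation_study <- function(seeds = 1:5, config = default_config()) {
  rows <- lapply(seeds, function(s) {
    net <- informative_plus_noise_benchmark(seed = s)
    cfg <- config
    cfg$train$seed <- s
    full <- ablation_run(net, "full", cfg)
    mmv <- ablation_run(net, "mmv", cfg)
    sv <- ablation_run(net, "sv", cfg, sv_view = 2L)   # the noise view
    st <- full$result$state
    fwd <- model_forward(st$model, st$nd, training = FALSE)
    labeled <- net$masks$train | net$masks$val
    w_inf <- mean(fwd$fusion_cache$marginal[labeled, 1L])
    data.frame(seed = s,
               full = full$metrics$test$accuracy,
               mmv = mmv$metrics$test$accuracy,
               sv = sv$metrics$test$accuracy,
               informative_weight = w_inf)
  })
  do.call(rbind, rows)
}

#' Train one model variant and report metrics
#'
#' Variants: `"full"` (attention fusion over all views), `"mmv"` (mean
#' fusion), `"sv"` (single-view pipeline on `sv_view`). The training
#' protocol is otherwise identical.
#'
#' @param network a `multiview_network` with a train mask.
#' @param variant `"full"`, `"sv"` or `"mmv"`.
#' @param config configuration list. @param sv_view view index for `"sv"`.
#' @return list with `metrics` (per-split report), `labels`, `trace`,
#'   `result` (the full run result).
#' @export
ablation_run <- function(network, variant = c("full", "sv", "mmv"),
                         config = default_config(), sv_view = 1L) {
  variant <- match.arg(variant)
  cfg <- config
  net <- network
  if (variant == "mmv") cfg$fusion$mode <- "mean"
  if (variant == "sv") net <- single_view_network(network, sv_view)
  res <- fit_mvgat(net, cfg)
  list(metrics = metric_report(net, res$labels), labels = res$labels,
       trace = res$trace, result = res)
}
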