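# The coupled membrane (P) system scheduler: k+4 cells, object stores,
# directed communication channels, synchronized maximal-parallel steps over
# the k view sub-cells, and the termination/output contract.
#
# "Maximal parallelism" is realized as a synchronized bulk step: all enabled
# rules of a round are computed from the round's entry state, then all
# effects are committed at once. Each sub-cell's dropout randomness comes
# from a seed derived from (base seed, iteration, view), so results are
# independent of the order in which sub-cells are executed.

subcell_name <- function(m) sprintf("cell2_sub%d", m)

# The wired channel set: the only routes objects may travel. One-way:
# (1,2), (2,3), (3,4), (4,environment). Two-way: (1,4). The fan-out between
# the cell2 hub and its k sub-cells is internal and two-way (views go in,
# view representations come back).
system_channels <- function(k) {
  data.frame(
    src = c("cell1", "cell2", "cell3", "cell4", "cell1",
            rep("cell2", k)),
    dst = c("cell2", "cell3", "cell4", "environment", "cell4",
            vapply(seq_len(k), subcell_name, "")),
    direction = c("one_way", "one_way", "one_way", "one_way", "two_way",
                  rep("two_way", k)),
    stringsAsFactors = FALSE)
}

log_transfer <- function(state, src, dst, object) {
  ch <- state$channels
  ok <- any(ch$src == src & ch$dst == dst) ||
    any(ch$direction == "two_way" & ch$src == dst & ch$dst == src)
  if (!ok) {
    stop(sprintf("no channel from %s to %s: refusing to transfer '%s'",
                 src, dst, object))
  }
  state$audit[[length(state$audit) + 1L]] <-
    list(iteration = state$iteration, src = src, dst = dst, object = object)
  state
}

#' Build the coupled P system for a multi-view network
#'
#' Constructs the k+4 cells — `cell1` (input), the k view sub-cells under the
#' `cell2` fan-out hub, `cell3` (fusion), `cell4` (loss/selection) and the
#' environment-facing output — wires the directed channels, and initializes
#' all model parameters from the configured seed. At construction `cell1`
#' holds the network object `G` and every other object store is empty.
#'
#' @param network a validated `multiview_network` with a train mask.
#' @param config configuration list (see [default_config()]).
#' @return object of class `mvgat_system`.
#' @export
build_system <- function(network, config = default_config()) {
  issues <- validate_network(network)
  if (length(issues) > 0L) stop(paste(issues, collapse = "; "))
  k <- n_views(network)
  if (k < 1L) stop("network has no views")
  max_iter <- config$system$max_iterations
  if (is.null(max_iter)) max_iter <- config$train$epochs
  if (max_iter < 1L) stop("max_iterations must be >= 1")
  cells <- c(
    list(cell1 = list(objects = list(G = network),
                      rules = c("r11", "r12", "r13"))),
    stats::setNames(
      lapply(seq_len(k), function(m)
        list(objects = list(), rules = c("r21", "r22", "r23"))),
      vapply(seq_len(k), subcell_name, "")),
    list(cell3 = list(objects = list(), rules = c("r31", "r32", "r33")),
         cell4 = list(objects = list(), rules = c("r41", "r42")),
         environment = list(objects = list(), rules = character(0)))
  )
  nd <- network_data(network)
  model <- init_model(network, config)
  structure(list(
    cells = cells, channels = system_channels(k), k = k,
    iteration = 0L, max_iterations = as.integer(max_iter),
    config = config, nd = nd, model = model, opt = adam_init(model),
    r1_applied = FALSE, audit = list(),
    trace = list(train_loss = numeric(0), val_loss = numeric(0),
                 selection_loss = numeric(0), predictions = list(),
                 prob = list())),
    class = "mvgat_system")
}

#' @export
print.mvgat_system <- function(x, ...) {
  cat(sprintf("<mvgat_system: %d cells (k = %d views), iteration %d/%d>\n",
              length(x$cells), x$k, x$iteration, x$max_iterations))
  invisible(x)
}

#' Number of cells in the system
#' @param state an `mvgat_system`.
#' @return integer, k + 4.
#' @export
n_cells <- function(state) length(state$cells)

#' Apply the decomposition rules of cell 1
#'
#' Routes the network held in `cell1` outward: node features and the k edge
#' sets go to the `cell2` hub and are fanned out so sub-cell m holds exactly
#' view m's edge set plus the shared features; the true labels travel over
#' the two-way (1,4) channel to `cell4`. The decomposition is
#' non-destructive: `G` stays in `cell1`, because every later iteration
#' re-reads it.
#'
#' @param state an `mvgat_system`.
#' @return updated state.
#' @export
apply_R1 <- function(state) {
  g <- state$cells$cell1$objects$G
  if (is.null(g)) stop("cell1 does not hold the network object G")
  state <- log_transfer(state, "cell1", "cell2", "features")
  state <- log_transfer(state, "cell1", "cell2", "edge_sets")
  for (m in seq_len(state$k)) {
    sc <- subcell_name(m)
    state <- log_transfer(state, "cell2", sc, sprintf("E%d+x", m))
    state$cells[[sc]]$objects$edge_set <- g$views[[m]]
    state$cells[[sc]]$objects$x <- g$features
  }
  state <- log_transfer(state, "cell1", "cell4", "y")
  state$cells$cell4$objects$y <- g$labels
  state$r1_applied <- TRUE
  state
}

#' One synchronized system iteration
#'
#' Runs one maximal-parallel round: every sub-cell encodes its view from the
#' round's entry parameters (R2; any execution order gives identical
#' results), `cell3` fuses the view representations and predicts labels
#' (R3), `cell4` computes the loss and stores the predictions (R4), and one
#' optimizer step is committed at the round boundary.
#'
#' @param state an `mvgat_system` with R1 applied (applied automatically on
#'   the first call).
#' @param subcell_order optional permutation of `1:k` fixing the order in
#'   which sub-cells are executed; the result is the same for every order.
#' @return updated state.
#' @export
system_step <- function(state, subcell_order = NULL) {
  if (state$iteration >= state$max_iterations) {
    stop("system already reached max_iterations")
  }
  if (!state$r1_applied) state <- apply_R1(state)
  if (is.null(subcell_order)) subcell_order <- seq_len(state$k)
  stopifnot(length(subcell_order) == state$k,
            setequal(subcell_order, seq_len(state$k)))
  iter <- state$iteration + 1L
  tc <- state$config$train
  nd <- state$nd
  model <- state$model

  # R2, maximally parallel: each sub-cell computes from the entry snapshot.
  view_caches <- vector("list", state$k)
  view_reps <- vector("list", state$k)
  for (m in subcell_order) {
    sc <- subcell_name(m)
    obj <- state$cells[[sc]]$objects
    edges <- nd$edges[[m]]
    vc <- view_encode_cache(obj$x, edges, model$encoders[[m]],
                            training = TRUE,
                            seed = derive_seed(tc$seed, iter, m))
    view_caches[[m]] <- vc
    view_reps[[m]] <- vc$out
    state$cells[[sc]]$objects$X <- vc$out
    state <- log_transfer(state, sc, "cell2", sprintf("X%d", m))
  }
  state <- log_transfer(state, "cell2", "cell3", "view_representations")
  state$cells$cell3$objects$view_reps <- view_reps

  # R3: view attention, fusion, prediction.
  if (model$fusion_mode == "attention") {
    fcache <- fusion_forward_cache(view_reps, model$fusion, model$scope,
                                   model$query)
    z <- fcache$Z
  } else {
    fcache <- NULL
    z <- mean_fuse(view_reps)
  }
  pred <- predict_labels(z, nd$task)
  state$cells$cell3$objects$Z <- z
  state <- log_transfer(state, "cell3", "cell4", "p")
  state$cells$cell4$objects$p <- pred$prob

  # R4: loss on the training nodes, gradient, one optimizer step.
  fwd <- list(view_caches = view_caches, view_reps = view_reps,
              fusion_cache = fcache, Z = z, prob = pred$prob,
              labels = pred$labels)
  grads <- model_backward(model, nd, fwd, nd$masks$train, training = TRUE)
  if (tc$learning_rate > 0) {
    up <- adam_step(model, grads, state$opt, tc$learning_rate,
                    tc$weight_decay)
    model <- up$model
    state$opt <- up$state
  }
  state$model <- model

  # Post-step evaluation recorded in cell4's store (r41).
  ev <- model_forward(model, nd, training = FALSE)
  train_loss <- cross_entropy(nd$y, ev$prob, nd$masks$train, nd$task)
  if (!is.finite(train_loss)) {
    stop(sprintf("non-finite loss at iteration %d", iter))
  }
  val_loss <- if (!is.null(nd$masks$val) && any(nd$masks$val)) {
    cross_entropy(nd$y, ev$prob, nd$masks$val, nd$task)
  } else NA_real_
  sel_loss <- cross_entropy(nd$y, ev$prob,
                            selection_mask(nd, tc$selection), nd$task)
  tr <- state$trace
  tr$train_loss <- c(tr$train_loss, train_loss)
  tr$val_loss <- c(tr$val_loss, val_loss)
  tr$selection_loss <- c(tr$selection_loss, sel_loss)
  tr$predictions[[iter]] <- ev$labels
  tr$prob[[iter]] <- ev$prob
  state$trace <- tr
  state$cells$cell4$objects$L <- sel_loss
  state <- log_transfer(state, "cell4", "cell1", "continue_signal")
  state$iteration <- iter
  state
}

#' Run the system to termination
#'
#' Iterates [system_step()] until the iteration budget is exhausted, then
#' `cell4` emits to the environment the stored predictions of the iteration
#' with minimum selection loss (validation loss when a validation mask
#' exists, else training loss; earliest iteration on ties).
#'
#' @param state a freshly built `mvgat_system`.
#' @return list with `labels` (final predicted labels), `prob` (their
#'   probabilities), `best_iteration`, `trace` (data.frame of per-iteration
#'   losses), and the final `state`.
#' @export
run_system <- function(state) {
  if (state$max_iterations < 1L) stop("max_iterations must be >= 1")
  if (!state$r1_applied) state <- apply_R1(state)
  while (state$iteration < state$max_iterations) {
    state <- system_step(state)
  }
  best <- select_best(state$trace)
  state <- log_transfer(state, "cell4", "environment", "final_labels")
  state$cells$environment$objects$labels <- best$labels
  trace_df <- data.frame(
    iteration = seq_along(state$trace$train_loss),
    train_loss = state$trace$train_loss,
    val_loss = state$trace$val_loss,
    selection_loss = state$trace$selection_loss,
    selected = seq_along(state$trace$train_loss) == best$iteration)
  list(labels = best$labels, prob = best$prob,
       best_iteration = best$iteration, trace = trace_df, state = state)
}

#' Train a multi-view attention model
#'
#' Convenience wrapper: builds the coupled P system for `network` and runs it
#' to termination.
#'
#' @param network a `multiview_network` with a train mask.
#' @param config configuration list (see [default_config()]).
#' @return the [run_system()] result.
#' @export
fit_mvgat <- function(network, config = default_config()) {
  run_system(build_system(network, config))
}

#' Audit the communication log of a finished system
#'
#' @param state an `mvgat_system`.
#' @return data.frame of transfers (iteration, src, dst, object); every row
#'   is guaranteed to use a wired channel.
#' @export
audit_log <- function(state) {
  do.call(rbind, lapply(state$audit, function(tr)
    data.frame(iteration = tr$iteration, src = tr$src, dst = tr$dst,
               object = tr$object, stringsAsFactors = FALSE)))
}
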