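# Per-view encoder: multi-head neighborhood attention layers.
#
# The production path works on a directed-edge expansion of the neighbor
# index (src -> dst for every j in N_src, self-loops included), so cost is
# O(edges) per head; a dense V x V oracle lives in the test suite only.

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope) ifelse(x > 0, 1, slope)
elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))

activation_fun <- function(name) {
  switch(name,
         elu = list(f = elu, grad = elu_grad),
         identity = list(f = identity, grad = function(x) rep(1, length(x))),
         stop(sprintf("unknown activation '%s'", name)))
}

#' Directed-edge expansion of a neighbor index
#'
#' Internal helper shared by the encoder and its tests: for every node i and
#' every j in N_i emits a directed edge (i, j). `split_idx[[i]]` holds the
#' edge positions belonging to node i, in ascending-neighbor order.
#' @param nbr a `neighbor_index`.
#' @keywords internal
edge_expansion <- function(nbr) {
  v <- length(nbr)
  deg <- lengths(nbr)
  if (any(deg == 0L)) {
    stop("empty neighborhood found; build neighborhoods with include_self = TRUE")
  }
  src <- rep.int(seq_len(v), deg)
  dst <- unlist(nbr, use.names = FALSE)
  ends <- cumsum(deg)
  starts <- ends - deg + 1L
  split_idx <- lapply(seq_len(v), function(i) starts[i]:ends[i])
  list(src = src, dst = dst, split_idx = split_idx, n_nodes = v)
}

# Numerically-stable softmax over edge scores grouped by source node.
group_softmax <- function(z, edges) {
  gmax <- vapply(edges$split_idx, function(ix) max(z[ix]), 0)
  w <- exp(z - gmax[edges$src])
  denom <- rowsum(w, edges$src, reorder = TRUE)[, 1L]
  unname(w / denom[edges$src])
}

# Backward of group_softmax: given d(alpha), return d(z).
group_softmax_grad <- function(alpha, dalpha, edges) {
  s <- rowsum(alpha * dalpha, edges$src, reorder = TRUE)[, 1L]
  alpha * (dalpha - s[edges$src])
}

#' Initialize one attention head
#'
#' Glorot-uniform weights for the linear map `W` (f_in x f_out) and the
#' length-2*f_out scoring vector `a`. Draws from the current RNG state.
#' @param f_in,f_out input/output dimension.
#' @return list with `W` and `a`.
#' @export
init_head <- function(f_in, f_out) {
  lw <- sqrt(6 / (f_in + f_out))
  la <- sqrt(6 / (2 * f_out + 1))
  list(W = matrix(stats::runif(f_in * f_out, -lw, lw), f_in, f_out),
       a = stats::runif(2L * f_out, -la, la))
}

#' Initialize a per-view attention encoder
#'
#' Builds a stack of multi-head attention layers. `dims` gives the feature
#' dimension entering layer 1 followed by the per-head output dimension of
#' each layer; concat-mode layers multiply their emitted width by the head
#' count, and the next layer's input dimension accounts for that.
#' By default all layers but the last concatenate heads (with ELU applied
#' per head) and the last layer averages heads with an identity activation,
#' leaving its output softmax-ready.
#'
#' @param dims integer vector, length >= 2: input dim, then per-head output
#'   dim of each layer.
#' @param heads number of attention heads per layer.
#' @param seed integer seed; identical seeds give bitwise-identical parameters.
#' @param modes per-layer mode, `"concat"` or `"average"`; default concat for
#'   hidden layers, average for the last.
#' @param activations per-layer activation, `"elu"` or `"identity"`; default
#'   ELU for hidden layers, identity for the last.
#' @param leaky_slope negative-branch slope of the scoring nonlinearity.
#' @param dropout_input,dropout_attention dropout probabilities (active in
#'   training mode only).
#' @return object of class `view_encoder`.
#' @export
init_encoder <- function(dims, heads = 8L, seed = 1L, modes = NULL,
                         activations = NULL, leaky_slope = 0.2,
                         dropout_input = 0.6, dropout_attention = 0.6) {
  if (length(dims) < 2L) stop("dims must list input dim plus at least one layer")
  n_layers <- length(dims) - 1L
  if (is.null(modes)) {
    modes <- c(rep("concat", n_layers - 1L), "average")
  }
  if (is.null(activations)) {
    activations <- c(rep("elu", n_layers - 1L), "identity")
  }
  stopifnot(length(modes) == n_layers, length(activations) == n_layers)
  set.seed(as.integer(seed))
  layers <- vector("list", n_layers)
  f_in <- dims[1L]
  for (l in seq_len(n_layers)) {
    f_out <- dims[l + 1L]
    layers[[l]] <- list(
      heads = lapply(seq_len(heads), function(h) init_head(f_in, f_out)),
      mode = modes[l], activation = activations[l],
      leaky_slope = leaky_slope, f_in = f_in, f_out = f_out)
    f_in <- if (modes[l] == "concat") f_out * heads else f_out
  }
  structure(list(layers = layers, dropout_input = dropout_input,
                 dropout_attention = dropout_attention, out_dim = f_in),
            class = "view_encoder")
}

#' Attention coefficients of one head over a neighbor index
#'
#' For each node i and neighbor j in N_i computes
#' `alpha_ij = softmax_j leakyrelu(a' [W x_i || W x_j])`, the normalized
#' importance of j to i. Scores are stabilized by per-neighborhood max
#' subtraction, so magnitudes up to about 1e4 do not overflow.
#'
#' @param x V x F_in feature matrix.
#' @param nbr a `neighbor_index` built with self-loops.
#' @param head list with `W` (F_in x F_out) and `a` (length 2*F_out).
#' @param leaky_slope negative-branch slope.
#' @return list, per node, of coefficients aligned with the neighbor order;
#'   each vector sums to 1.
#' @export
attention_coefficients <- function(x, nbr, head, leaky_slope = 0.2) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(head$W)) {
    stop(sprintf("feature dim %d does not match W rows %d", ncol(x), nrow(head$W)))
  }
  edges <- edge_expansion(nbr)
  h <- x %*% head$W
  f_out <- ncol(h)
  e1 <- drop(h %*% head$a[seq_len(f_out)])
  e2 <- drop(h %*% head$a[f_out + seq_len(f_out)])
  z <- leaky_relu(e1[edges$src] + e2[edges$dst], leaky_slope)
  alpha <- group_softmax(z, edges)
  lapply(edges$split_idx, function(ix) alpha[ix])
}

#' Aggregate neighbor features under attention coefficients
#'
#' Row i of the result is `sum_{j in N_i} alpha_ij (W x_j)`. No activation is
#' applied; that belongs to [layer_forward()].
#'
#' @param x V x F_in features. @param alpha per-node coefficient lists as
#'   returned by [attention_coefficients()]. @param nbr the matching
#'   `neighbor_index`. @param head head parameters.
#' @return V x F_out matrix.
#' @export
head_update <- function(x, alpha, nbr, head) {
  edges <- edge_expansion(nbr)
  if (length(alpha) != length(nbr) ||
      !all(lengths(alpha) == lengths(nbr))) {
    stop("alpha structure does not match the neighbor index")
  }
  a_edge <- unlist(alpha, use.names = FALSE)
  h <- as.matrix(x) %*% head$W
  rowsum(h[edges$dst, , drop = FALSE] * a_edge, edges$src, reorder = TRUE)
}

# One layer forward on the edge expansion, returning a cache for backprop.
layer_forward_cache <- function(x, edges, layer, training = FALSE,
                                dropout_attention = 0) {
  heads <- layer$heads
  phi <- length(heads)
  act <- activation_fun(layer$activation)
  head_caches <- vector("list", phi)
  pre <- NULL
  outs <- vector("list", phi)
  for (hd in seq_len(phi)) {
    p <- heads[[hd]]
    h <- x %*% p$W
    f_out <- ncol(h)
    e1 <- drop(h %*% p$a[seq_len(f_out)])
    e2 <- drop(h %*% p$a[f_out + seq_len(f_out)])
    zraw <- e1[edges$src] + e2[edges$dst]
    z <- leaky_relu(zraw, layer$leaky_slope)
    alpha <- group_softmax(z, edges)
    if (training && dropout_attention > 0) {
      mask <- stats::rbinom(length(alpha), 1L, 1 - dropout_attention)
      alpha_used <- alpha * mask / (1 - dropout_attention)
    } else {
      mask <- NULL
      alpha_used <- alpha
    }
    m <- rowsum(h[edges$dst, , drop = FALSE] * alpha_used, edges$src,
                reorder = TRUE)
    head_caches[[hd]] <- list(h = h, zraw = zraw, alpha = alpha, mask = mask,
                              alpha_used = alpha_used, m = m)
    outs[[hd]] <- m
  }
  if (layer$mode == "concat") {
    out <- do.call(cbind, lapply(outs, act$f))
  } else if (layer$mode == "average") {
    pre <- Reduce(`+`, outs) / phi
    out <- act$f(pre)
  } else {
    stop(sprintf("unknown layer mode '%s'", layer$mode))
  }
  list(out = out, x = x, head_caches = head_caches, pre = pre)
}

# Backward of layer_forward_cache. Returns dX and per-head parameter grads.
layer_backward <- function(dout, cache, edges, layer, dropout_attention = 0,
                           training = FALSE) {
  heads <- layer$heads
  phi <- length(heads)
  act <- activation_fun(layer$activation)
  f_out <- layer$f_out
  dx <- matrix(0, nrow(cache$x), ncol(cache$x))
  grads <- vector("list", phi)
  for (hd in seq_len(phi)) {
    p <- heads[[hd]]
    hc <- cache$head_caches[[hd]]
    if (layer$mode == "concat") {
      cols <- (hd - 1L) * f_out + seq_len(f_out)
      dm <- dout[, cols, drop = FALSE] * matrix(act$grad(hc$m), nrow(hc$m), f_out)
    } else {
      dm <- dout * matrix(act$grad(cache$pre), nrow(dout), f_out) / phi
    }
    # m_i = sum_j alpha_used_ij h_j
    dalpha_used <- rowSums(dm[edges$src, , drop = FALSE] *
                             hc$h[edges$dst, , drop = FALSE])
    dh <- rowsum(hc$alpha_used * dm[edges$src, , drop = FALSE], edges$dst,
                 reorder = TRUE)
    if (!is.null(hc$mask)) {
      dalpha <- dalpha_used * hc$mask / (1 - dropout_attention)
    } else {
      dalpha <- dalpha_used
    }
    dz <- group_softmax_grad(hc$alpha, dalpha, edges)
    dzraw <- dz * leaky_relu_grad(hc$zraw, layer$leaky_slope)
    a1 <- p$a[seq_len(f_out)]
    a2 <- p$a[f_out + seq_len(f_out)]
    da1 <- drop(crossprod(hc$h, rowsum(dzraw, edges$src, reorder = TRUE)[, 1L]))
    da2 <- drop(crossprod(hc$h, rowsum(dzraw, edges$dst, reorder = TRUE)[, 1L]))
    dh <- dh +
      tcrossprod(rowsum(dzraw, edges$src, reorder = TRUE)[, 1L], a1) +
      tcrossprod(rowsum(dzraw, edges$dst, reorder = TRUE)[, 1L], a2)
    grads[[hd]] <- list(W = crossprod(cache$x, dh), a = c(da1, da2))
    dx <- dx + dh %*% t(p$W)
  }
  list(dx = dx, grads = grads)
}

#' One attention layer forward
#'
#' Concat mode applies the activation per head and concatenates the Phi head
#' outputs (width Phi * F_out); average mode averages head outputs first and
#' then applies the activation (width F_out). Attention dropout is active only
#' in training mode and draws from the current RNG state.
#'
#' @param x V x F_in features. @param nbr `neighbor_index` with self-loops.
#' @param layer one layer of a `view_encoder` (fields `heads`, `mode`,
#'   `activation`, `leaky_slope`). @param training logical.
#' @param dropout_attention dropout probability on the normalized
#'   coefficients.
#' @return V x out matrix.
#' @export
layer_forward <- function(x, nbr, layer, training = FALSE,
                          dropout_attention = 0) {
  edges <- edge_expansion(nbr)
  layer_forward_cache(as.matrix(x), edges, layer, training,
                      dropout_attention)$out
}

#' Encode one view
#'
#' Full per-view pipeline: input-feature dropout, then the encoder's layer
#' stack. Deterministic given `seed` and `training`; in eval mode no dropout
#' is applied and `seed` is irrelevant.
#'
#' @param x V x F features. @param nbr `neighbor_index` with self-loops.
#' @param enc a `view_encoder`. @param training logical. @param seed RNG seed
#'   for the dropout masks (required when training with nonzero dropout).
#' @return V x out_dim view representation.
#' @export
view_encode <- function(x, nbr, enc, training = FALSE, seed = NULL) {
  edges <- edge_expansion(nbr)
  view_encode_cache(as.matrix(x), edges, enc, training, seed)$out
}

# Forward with full cache; used by the trainer.
view_encode_cache <- function(x, edges, enc, training = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  input_mask <- NULL
  x_in <- x
  if (training && enc$dropout_input > 0) {
    input_mask <- matrix(stats::rbinom(length(x), 1L, 1 - enc$dropout_input),
                         nrow(x), ncol(x))
    x_in <- x * input_mask / (1 - enc$dropout_input)
  }
  layer_caches <- vector("list", length(enc$layers))
  cur <- x_in
  for (l in seq_along(enc$layers)) {
    lc <- layer_forward_cache(cur, edges, enc$layers[[l]], training,
                              enc$dropout_attention)
    layer_caches[[l]] <- lc
    cur <- lc$out
  }
  list(out = cur, x_raw = x, input_mask = input_mask,
       layer_caches = layer_caches)
}

# Backward through a whole view encoder; returns per-layer head grads.
view_encode_backward <- function(dout, cache, edges, enc, training = FALSE) {
  n_layers <- length(enc$layers)
  layer_grads <- vector("list", n_layers)
  d <- dout
  for (l in rev(seq_len(n_layers))) {
    bk <- layer_backward(d, cache$layer_caches[[l]], edges, enc$layers[[l]],
                         enc$dropout_attention, training)
    layer_grads[[l]] <- bk$grads
    d <- bk$dx
  }
  list(layer_grads = layer_grads, dx = d)
}
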