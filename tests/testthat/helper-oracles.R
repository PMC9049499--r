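# Shared fixtures and independent dense oracles used across the test files.
# The oracles deliberately take the brute-force route (dense V x V score
# matrices, explicit loops) so they share no code path with the package's
# edge-list implementation.

# Random Erdos-Renyi multiview ingredients ---------------------------------

random_edge_set <- function(v, p = 0.4) {
  pairs <- t(utils::combn(v, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  edge_set(pairs[keep, , drop = FALSE], v)
}

random_head <- function(f_in, f_out) {
  list(W = matrix(stats::rnorm(f_in * f_out), f_in, f_out),
       a = stats::rnorm(2L * f_out))
}

# Dense adjacency (self-loops included) from an edge set.
dense_adjacency <- function(es) {
  v <- es$n_nodes
  adj <- diag(TRUE, v)
  e <- es$edges
  if (nrow(e) > 0L) {
    adj[e] <- TRUE
    adj[e[, c(2L, 1L)]] <- TRUE
  }
  adj
}

# Dense oracle for one attention head's coefficients: full V x V score
# matrix with -Inf off-neighborhood, row softmax.
dense_alpha <- function(x, adj, head, slope = 0.2) {
  h <- x %*% head$W
  f_out <- ncol(h)
  e1 <- drop(h %*% head$a[seq_len(f_out)])
  e2 <- drop(h %*% head$a[f_out + seq_len(f_out)])
  s <- outer(e1, e2, `+`)
  s <- ifelse(s > 0, s, slope * s)
  s[!adj] <- -Inf
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  e / rowSums(e)
}

# Dense oracle for a whole multi-head layer.
dense_layer <- function(x, adj, layer) {
  act <- if (layer$activation == "elu") {
    function(z) ifelse(z > 0, z, exp(pmin(z, 0)) - 1)
  } else identity
  outs <- lapply(layer$heads, function(hd) {
    a <- dense_alpha(x, adj, hd, layer$leaky_slope)
    a %*% (x %*% hd$W)
  })
  if (layer$mode == "concat") {
    do.call(cbind, lapply(outs, act))
  } else {
    act(Reduce(`+`, outs) / length(outs))
  }
}

# Tiny trainable two-view network used by training tests.
tiny_trainable_network <- function(seed = 1L, v = 20L) {
  set.seed(seed)
  cls <- rep(c(0L, 1L), length.out = v)
  within_pairs <- function(members) t(utils::combn(members, 2L))
  view1 <- edge_set(rbind(within_pairs(which(cls == 0L)),
                          within_pairs(which(cls == 1L))), v)
  view2 <- random_edge_set(v, 0.2)
  feats <- cbind(ifelse(cls == 0L, 1, -1) + stats::rnorm(v, sd = 0.2),
                 matrix(stats::rnorm(v * 2L, sd = 0.5), v, 2L))
  multiview_network(as.character(seq_len(v)), feats, cls,
                    list(view1, view2),
                    masks = list(train = seq_len(v) %% 2L == 0L,
                                 test = seq_len(v) %% 2L == 1L))
}

# Small fast config for training tests.
fast_config <- function(epochs = 10L, seed = 1L) {
  cfg <- default_config()
  cfg$model$hidden_dim <- 4L
  cfg$model$heads <- 2L
  cfg$train$epochs <- epochs
  cfg$train$seed <- seed
  cfg
}
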