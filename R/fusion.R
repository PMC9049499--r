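# Attention over views: per-node coefficients between views, fusion of the
# k per-view representations into one global representation Z, prediction.

#' Initialize view-fusion parameters
#'
#' Glorot-uniform linear map `Tm` (F x F') and scoring vector `b`
#' (length 2*F'), drawn from the current RNG state.
#' @param f_in view-representation dimension F.
#' @param f_hidden scoring dimension F'.
#' @param leaky_slope negative-branch slope of the scoring nonlinearity
#'   (kept identical to the node-attention convention).
#' @return list with `Tm`, `b`, `leaky_slope`.
#' @export
init_fusion <- function(f_in, f_hidden = 8L, leaky_slope = 0.2) {
  lt <- sqrt(6 / (f_in + f_hidden))
  lb <- sqrt(6 / (2 * f_hidden + 1))
  list(Tm = matrix(stats::runif(f_in * f_hidden, -lt, lt), f_in, f_hidden),
       b = stats::runif(2L * f_hidden, -lb, lb),
       leaky_slope = leaky_slope)
}

# Unified forward with cache.
# scope "per_node": one coefficient set per node; "global": views are pooled
# (node mean) first, one coefficient set for the whole graph.
# query "mean_over_queries": beta is a QxK table per node (Q = k query views)
# and the fusion marginal averages over queries; "mean_view": the single
# query is the elementwise mean of the views (Q = 1).
fusion_forward_cache <- function(view_reps, params, scope = "per_node",
                                 query = "mean_over_queries") {
  k <- length(view_reps)
  if (k < 1L) stop("need at least one view representation")
  dims <- vapply(view_reps, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("view representations must share dimensions")
  }
  v <- dims[1, 1]
  if (nrow(params$Tm) != dims[2, 1]) {
    stop(sprintf("fusion Tm expects dim %d, view representations have %d",
                 nrow(params$Tm), dims[2, 1]))
  }
  f_hidden <- ncol(params$Tm)
  b1 <- params$b[seq_len(f_hidden)]
  b2 <- params$b[f_hidden + seq_len(f_hidden)]
  slope <- params$leaky_slope

  if (scope == "global") {
    keys <- lapply(view_reps, function(xx) matrix(colMeans(xx), 1L))
  } else if (scope == "per_node") {
    keys <- view_reps
  } else stop(sprintf("unknown fusion scope '%s'", scope))
  n <- nrow(keys[[1L]])

  t_list <- lapply(keys, function(xx) xx %*% params$Tm)      # n x F'
  u <- vapply(t_list, function(tt) drop(tt %*% b1), numeric(n)) # n x k
  w <- vapply(t_list, function(tt) drop(tt %*% b2), numeric(n)) # n x k
  u <- matrix(u, n, k)
  w <- matrix(w, n, k)

  if (query == "mean_view") {
    xq <- Reduce(`+`, keys) / k
    tq <- xq %*% params$Tm
    uq <- matrix(drop(tq %*% b1), n, 1L)
    q_idx <- NULL
    n_q <- 1L
  } else if (query == "mean_over_queries") {
    uq <- u
    q_idx <- seq_len(k)
    n_q <- k
    xq <- NULL; tq <- NULL
  } else stop(sprintf("unknown fusion query mode '%s'", query))

  zraw <- vector("list", n_q)   # per query: n x k score matrix
  beta <- vector("list", n_q)
  for (qi in seq_len(n_q)) {
    zr <- uq[, qi] + w
    zl <- leaky_relu(zr, slope)
    zl <- zl - apply(zl, 1L, max)
    e <- exp(zl)
    beta[[qi]] <- e / rowSums(e)
    zraw[[qi]] <- zr
  }
  marg_small <- Reduce(`+`, beta) / n_q                      # n x k
  marginal <- if (scope == "global") {
    matrix(marg_small, v, k, byrow = TRUE)
  } else marg_small

  z <- matrix(0, v, dims[2, 1])
  for (j in seq_len(k)) z <- z + marginal[, j] * view_reps[[j]]

  list(Z = z, marginal = marginal, beta = beta, zraw = zraw,
       t_list = t_list, u = u, w = w, uq = uq, xq = xq, tq = tq,
       keys = keys, view_reps = view_reps, scope = scope, query = query,
       n = n, k = k, v = v, f = dims[2, 1], f_hidden = f_hidden)
}

# Backward of fusion_forward_cache: dZ -> grads for Tm, b and each view rep.
fusion_backward <- function(dz, cache, params) {
  k <- cache$k; n <- cache$n; v <- cache$v
  f_hidden <- cache$f_hidden
  b1 <- params$b[seq_len(f_hidden)]
  b2 <- params$b[f_hidden + seq_len(f_hidden)]
  slope <- params$leaky_slope

  d_views <- vector("list", k)
  dmarg_full <- matrix(0, v, k)
  for (j in seq_len(k)) {
    d_views[[j]] <- cache$marginal[, j] * dz
    dmarg_full[, j] <- rowSums(dz * cache$view_reps[[j]])
  }
  dmarg <- if (cache$scope == "global") {
    matrix(colSums(dmarg_full), 1L, k)
  } else dmarg_full

  n_q <- length(cache$beta)
  du <- matrix(0, n, k)       # grad wrt u (per-view query scores)
  duq1 <- matrix(0, n, 1L)    # grad wrt the single mean-view query score
  dw <- matrix(0, n, k)
  for (qi in seq_len(n_q)) {
    dbeta <- dmarg / n_q
    bq <- cache$beta[[qi]]
    dzl <- bq * (dbeta - rowSums(bq * dbeta))
    dzr <- dzl * leaky_relu_grad(cache$zraw[[qi]], slope)
    if (cache$query == "mean_view") duq1[, 1L] <- duq1[, 1L] + rowSums(dzr)
    else du[, qi] <- du[, qi] + rowSums(dzr)
    dw <- dw + dzr
  }

  dt_list <- lapply(seq_len(k), function(j) tcrossprod(dw[, j], b2))
  db2 <- drop(Reduce(`+`, lapply(seq_len(k), function(j)
    crossprod(cache$t_list[[j]], dw[, j]))))
  if (cache$query == "mean_view") {
    dtq <- tcrossprod(duq1[, 1L], b1)
    db1 <- drop(crossprod(cache$tq, duq1[, 1L]))
    dT <- crossprod(cache$xq, dtq)
    dxq <- dtq %*% t(params$Tm)
    dkeys <- lapply(seq_len(k), function(j) dxq / k)
  } else {
    db1 <- numeric(f_hidden)
    for (j in seq_len(k)) {
      dt_list[[j]] <- dt_list[[j]] + tcrossprod(du[, j], b1)
      db1 <- db1 + drop(crossprod(cache$t_list[[j]], du[, j]))
    }
    dT <- matrix(0, nrow(params$Tm), ncol(params$Tm))
    dkeys <- vector("list", k)
  }
  for (j in seq_len(k)) {
    dT <- dT + crossprod(cache$keys[[j]], dt_list[[j]])
    dk <- dt_list[[j]] %*% t(params$Tm)
    dkeys[[j]] <- if (is.null(dkeys[[j]])) dk else dkeys[[j]] + dk
  }
  for (j in seq_len(k)) {
    if (cache$scope == "global") {
      d_views[[j]] <- d_views[[j]] +
        matrix(dkeys[[j]][1L, ] / v, v, cache$f, byrow = TRUE)
    } else {
      d_views[[j]] <- d_views[[j]] + dkeys[[j]]
    }
  }
  list(dTm = dT, db = c(db1, db2), d_views = d_views)
}

#' Attention coefficients between views
#'
#' For each node v and query view i, `beta_ij(v)` is the softmax over key
#' views j of `leakyrelu(b' [Tm x_v^(i) || Tm x_v^(j)])`. The per-view fusion
#' marginal averages `beta_ij(v)` over query views i, which is the symmetric
#' resolution that reduces to the identity at k = 1 and keeps the fused
#' representation a per-node convex combination of the views.
#'
#' @param view_reps list of k V x F matrices.
#' @param params fusion parameters from [init_fusion()].
#' @param scope `"per_node"` (default) or `"global"` (views pooled by node
#'   mean before scoring, one coefficient set for the whole graph).
#' @param query `"mean_over_queries"` (default) or `"mean_view"` (the single
#'   query is the elementwise mean of views).
#' @return object of class `view_attention`: `beta` (list over query views of
#'   n x k matrices), `marginal` (V x k, rows sum to 1), `scope`, `query`.
#' @export
view_attention <- function(view_reps, params, scope = "per_node",
                           query = "mean_over_queries") {
  cache <- fusion_forward_cache(view_reps, params, scope, query)
  structure(list(beta = cache$beta, marginal = cache$marginal,
                 scope = scope, query = query, k = cache$k),
            class = "view_attention")
}

#' Fuse view representations under a view attention
#'
#' Row v of the result is `sum_j marginal_j(v) x_v^(j)`: a per-node convex
#' combination of the view rows.
#'
#' @param view_reps list of k V x F matrices.
#' @param attn a `view_attention` whose marginal matches `view_reps`.
#' @return V x F fused matrix Z.
#' @export
fuse <- function(view_reps, attn) {
  k <- length(view_reps)
  if (!inherits(attn, "view_attention") || attn$k != k) {
    stop("view_attention does not match the number of views")
  }
  z <- matrix(0, nrow(view_reps[[1L]]), ncol(view_reps[[1L]]))
  for (j in seq_len(k)) z <- z + attn$marginal[, j] * view_reps[[j]]
  z
}

#' Unweighted mean fusion of views
#'
#' The mean-fusion ablation: elementwise average of the k view
#' representations, with no learned weights.
#' @param view_reps non-empty list of V x F matrices.
#' @return V x F matrix.
#' @export
mean_fuse <- function(view_reps) {
  if (length(view_reps) < 1L) stop("need at least one view representation")
  Reduce(`+`, view_reps) / length(view_reps)
}

#' Class probabilities and hard labels from fused logits
#'
#' Multiclass: row softmax (max-subtracted) and argmax with lowest-class-index
#' tie-break. Multilabel: elementwise sigmoid and threshold 0.5.
#'
#' @param z V x C logit matrix.
#' @param task `"multiclass"` or `"multilabel"`.
#' @return list with `prob` (V x C) and `labels` (0-based integer vector for
#'   multiclass; V x C binary matrix for multilabel).
#' @export
predict_labels <- function(z, task = c("multiclass", "multilabel")) {
  task <- match.arg(task)
  z <- as.matrix(z)
  if (any(!is.finite(z))) stop("non-finite logits")
  if (task == "multiclass") {
    zs <- z - apply(z, 1L, max)
    e <- exp(zs)
    prob <- e / rowSums(e)
    labels <- max.col(prob, ties.method = "first") - 1L
  } else {
    prob <- 1 / (1 + exp(-z))
    labels <- (prob > 0.5) * 1L
  }
  list(prob = prob, labels = labels)
}
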