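# Per-view encoder: coefficients, head updates, layers, encoder stack,
# initialization, and the encoder's structural properties.

test_that("attention coefficients normalize and match closed-form cases", {
  # |N_i| = 1: single-element softmax is exactly 1
  iso <- edge_set(NULL, 2L)
  nbr <- neighborhoods(iso, include_self = TRUE)
  x <- matrix(c(1, 2), 2, 1)
  a <- attention_coefficients(x, nbr, list(W = matrix(1), a = c(1, 1)))
  expect_identical(a[[1]], 1)

  # zero W: every score equal, coefficients uniform over N_i
  es <- random_edge_set(6L, 0.5)
  nbr2 <- neighborhoods(es, include_self = TRUE)
  x2 <- matrix(stats::rnorm(12), 6, 2)
  a2 <- attention_coefficients(x2, nbr2,
                               list(W = matrix(0, 2, 2), a = c(1, 2, 3, 4)))
  for (i in 1:6) {
    expect_equal(a2[[i]], rep(1 / length(nbr2[[i]]), length(nbr2[[i]])))
  }

  # 3-node path, scalar case, against a dense enumeration
  path3 <- edge_set(rbind(c(1, 2), c(2, 3)), 3L)
  nbr3 <- neighborhoods(path3, include_self = TRUE)
  x3 <- matrix(c(1, 2, 3), 3, 1)
  head3 <- list(W = matrix(1), a = c(1, 1))
  got <- attention_coefficients(x3, nbr3, head3, leaky_slope = 0.2)
  oracle <- dense_alpha(x3, dense_adjacency(path3), head3, 0.2)
  for (i in 1:3) {
    expect_equal(got[[i]], unname(oracle[i, nbr3[[i]]]), tolerance = 1e-10)
  }
})

test_that("attention softmax is stable for scores of magnitude 1e4", {
  es <- edge_set(rbind(c(1, 2), c(2, 3), c(1, 3)), 3L)
  nbr <- neighborhoods(es, include_self = TRUE)
  x <- matrix(c(1e4, -1e4, 5e3), 3, 1)
  a <- attention_coefficients(x, nbr, list(W = matrix(1), a = c(1, 1)))
  for (i in 1:3) {
    expect_true(all(is.finite(a[[i]])))
    expect_equal(sum(a[[i]]), 1, tolerance = 1e-12)
  }
})

test_that("head_update aggregates neighbor features correctly", {
  # alpha one-hot on self with identity W reproduces the input
  es <- random_edge_set(5L, 0.5)
  nbr <- neighborhoods(es, include_self = TRUE)
  x <- matrix(stats::rnorm(10), 5, 2)
  alpha_self <- lapply(1:5, function(i) as.numeric(nbr[[i]] == i))
  hd <- list(W = diag(2), a = rep(0, 4))
  expect_equal(head_update(x, alpha_self, nbr, hd), x, ignore_attr = TRUE)

  # convexity: identical neighbor features under uniform alpha reproduce them
  es2 <- edge_set(rbind(c(1, 2), c(1, 3)), 3L)
  nbr2 <- neighborhoods(es2, include_self = FALSE)
  xx <- rbind(c(9, 9), c(4, 2), c(4, 2))
  nbr2[[1]] <- c(2L, 3L)  # node 1 sees its two identical neighbors
  alpha <- list(c(0.5, 0.5), 1, 1)
  got <- head_update(xx, alpha, nbr2, hd)
  expect_equal(got[1, ], c(4, 2), ignore_attr = TRUE)

  # random case vs dense matmul oracle
  set.seed(21)
  es3 <- random_edge_set(8L, 0.4)
  nbr3 <- neighborhoods(es3, include_self = TRUE)
  x3 <- matrix(stats::rnorm(24), 8, 3)
  hd3 <- random_head(3L, 2L)
  al <- attention_coefficients(x3, nbr3, hd3)
  amat <- matrix(0, 8, 8)
  for (i in 1:8) amat[i, nbr3[[i]]] <- al[[i]]
  expect_equal(head_update(x3, al, nbr3, hd3), amat %*% (x3 %*% hd3$W),
               tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(head_update(x3, al[-1], nbr3, hd3), "structure")
})

test_that("layer_forward handles concat and average head modes", {
  set.seed(31)
  es <- random_edge_set(7L, 0.4)
  nbr <- neighborhoods(es, include_self = TRUE)
  x <- matrix(stats::rnorm(21), 7, 3)

  # single head with identity activation: concat and average coincide
  hd <- random_head(3L, 2L)
  mk <- function(mode, heads) list(heads = heads, mode = mode,
                                   activation = "identity",
                                   leaky_slope = 0.2, f_in = 3L, f_out = 2L)
  expect_identical(layer_forward(x, nbr, mk("concat", list(hd))),
                   layer_forward(x, nbr, mk("average", list(hd))))

  # four identical heads in concat mode give four horizontal copies
  lay4 <- mk("concat", rep(list(hd), 4L))
  out4 <- layer_forward(x, nbr, lay4)
  single <- layer_forward(x, nbr, mk("concat", list(hd)))
  expect_identical(out4, cbind(single, single, single, single))

  # two random heads vs per-head dense pipeline, both modes, ELU
  for (mode in c("concat", "average")) {
    lay <- mk(mode, list(random_head(3L, 2L), random_head(3L, 2L)))
    lay$activation <- "elu"
    expect_equal(layer_forward(x, nbr, lay),
                 dense_layer(x, dense_adjacency(es), lay),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_error(layer_forward(x, nbr, mk("bogus", list(hd))), "mode")
})

test_that("view_encode is deterministic and reduces to layer_forward at depth 1", {
  set.seed(41)
  es <- random_edge_set(9L, 0.3)
  nbr <- neighborhoods(es, include_self = TRUE)
  x <- matrix(stats::rnorm(36), 9, 4)
  enc <- init_encoder(c(4L, 3L), heads = 2L, seed = 5L,
                      modes = "average", activations = "identity",
                      dropout_input = 0, dropout_attention = 0)
  expect_identical(view_encode(x, nbr, enc),
                   layer_forward(x, nbr, enc$layers[[1]]))

  # eval mode twice: identical (no dropout applied)
  enc2 <- init_encoder(c(4L, 3L, 2L), heads = 2L, seed = 5L)
  expect_identical(view_encode(x, nbr, enc2), view_encode(x, nbr, enc2))

  # training mode with a fixed seed: dropout masks replay exactly
  o1 <- view_encode(x, nbr, enc2, training = TRUE, seed = 99L)
  o2 <- view_encode(x, nbr, enc2, training = TRUE, seed = 99L)
  expect_identical(o1, o2)
  # and a different seed gives different masks
  o3 <- view_encode(x, nbr, enc2, training = TRUE, seed = 100L)
  expect_false(identical(o1, o3))
})

test_that("encoder initialization is seeded Glorot-uniform", {
  e1 <- init_encoder(c(6L, 4L, 2L), heads = 3L, seed = 17L)
  e2 <- init_encoder(c(6L, 4L, 2L), heads = 3L, seed = 17L)
  expect_identical(e1, e2)
  e3 <- init_encoder(c(6L, 4L, 2L), heads = 3L, seed = 18L)
  expect_false(identical(e1, e3))

  # all first-layer W entries respect the Glorot bound
  bound <- sqrt(6 / (6 + 4))
  for (hd in e1$layers[[1]]$heads) {
    expect_true(all(abs(hd$W) <= bound))
  }

  # sample mean of >= 1e4 Glorot draws is 0 within 4 standard errors
  big <- init_encoder(c(100L, 100L), heads = 1L, seed = 4L,
                      modes = "average", activations = "identity")
  w <- big$layers[[1]]$heads[[1]]$W
  lim <- sqrt(6 / 200)
  se <- (lim / sqrt(3)) / sqrt(length(w))
  expect_lt(abs(mean(w)), 4 * se)

  expect_error(init_encoder(c(5L)), "at least one layer")
})

test_that("coefficients normalize per neighborhood across random cases", {
  set.seed(51)
  for (rep in 1:20) {
    v <- sample(4:12, 1)
    es <- random_edge_set(v, stats::runif(1, 0.2, 0.8))
    nbr <- neighborhoods(es, include_self = TRUE)
    x <- matrix(stats::rnorm(v * 3L), v, 3L)
    al <- attention_coefficients(x, nbr, random_head(3L, 2L))
    expect_equal(vapply(al, sum, 0), rep(1, v), tolerance = 1e-6)
  }
})

test_that("the encoder is permutation-equivariant in eval mode", {
  set.seed(61)
  for (rep in 1:20) {
    v <- sample(5:10, 1)
    es <- random_edge_set(v, 0.4)
    x <- matrix(stats::rnorm(v * 3L), v, 3L)
    enc <- init_encoder(c(3L, 4L, 2L), heads = 2L, seed = rep)
    out <- view_encode(x, neighborhoods(es), enc)

    q <- sample(v)                      # new index i holds old node q[i]
    inv <- integer(v); inv[q] <- seq_len(v)
    es_p <- edge_set(cbind(inv[es$edges[, 1]], inv[es$edges[, 2]]), v)
    out_p <- view_encode(x[q, , drop = FALSE], neighborhoods(es_p), enc)
    expect_equal(out_p, out[q, , drop = FALSE], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("a single layer is local: nodes outside N_i cannot affect node i", {
  set.seed(71)
  es <- random_edge_set(10L, 0.25)
  nbr <- neighborhoods(es, include_self = TRUE)
  x <- matrix(stats::rnorm(30), 10, 3)
  lay <- list(heads = list(random_head(3L, 2L), random_head(3L, 2L)),
              mode = "average", activation = "elu", leaky_slope = 0.2,
              f_in = 3L, f_out = 2L)
  base <- layer_forward(x, nbr, lay)
  for (i in 1:10) {
    outside <- setdiff(1:10, nbr[[i]])
    if (length(outside) == 0L) next
    x2 <- x
    x2[outside, ] <- x2[outside, , drop = FALSE] + 100
    pert <- layer_forward(x2, nbr, lay)
    expect_identical(pert[i, ], base[i, ])
  }
})

test_that("empty neighborhoods are rejected with guidance", {
  es <- edge_set(rbind(c(1, 2)), 3L)
  nbr <- neighborhoods(es, include_self = FALSE)  # node 3 has no neighbors
  x <- matrix(stats::rnorm(6), 3, 2)
  expect_error(attention_coefficients(x, nbr, random_head(2L, 2L)),
               "include_self")
  expect_error(attention_coefficients(x[, 1, drop = FALSE],
                                      neighborhoods(es), random_head(2L, 2L)),
               "dim")
})
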