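# Loss, optimization, best-iteration selection, metrics, ablation variants.

test_that("cross_entropy matches closed forms and a scalar loop", {
  # perfect binary prediction: loss vanishes up to the clipping floor
  y <- matrix(c(1, 0, 0, 1, 1, 0), 3, 2)
  expect_lt(cross_entropy(y, y, task = "multilabel"), 6 * 1e-11)

  # p = 0.5 everywhere on a binary task: V * ln 2 per label column
  v <- 7L
  yb <- matrix(rep(c(0, 1), length.out = v), v, 1)
  expect_equal(cross_entropy(yb, matrix(0.5, v, 1), task = "multilabel"),
               v * log(2), tolerance = 1e-12)

  # random 5-node case vs explicit per-term loop (both tasks)
  set.seed(5)
  p <- matrix(stats::runif(15, 0.05, 0.95), 5, 3)
  p <- p / rowSums(p)
  yc <- sample(0:2, 5, TRUE)
  loop <- 0
  for (i in 1:5) loop <- loop - log(p[i, yc[i] + 1])
  expect_equal(cross_entropy(yc, p), loop, tolerance = 1e-10)

  ym <- matrix(stats::rbinom(15, 1, 0.5), 5, 3)
  loop2 <- 0
  for (i in 1:5) for (c0 in 1:3) {
    loop2 <- loop2 - (ym[i, c0] * log(p[i, c0]) +
                        (1 - ym[i, c0]) * log(1 - p[i, c0]))
  }
  expect_equal(cross_entropy(ym, p, task = "multilabel"), loop2,
               tolerance = 1e-10)

  expect_error(cross_entropy(yc, p, mask = rep(FALSE, 5)), "empty mask")
})

test_that("loss is non-negative and invariant to node ordering", {
  set.seed(6)
  for (rep in 1:10) {
    p <- matrix(stats::runif(20), 5, 4); p <- p / rowSums(p)
    y <- sample(0:3, 5, TRUE)
    l <- cross_entropy(y, p)
    expect_gte(l, 0)
    q <- sample(5)
    expect_equal(cross_entropy(y[q], p[q, ]), l, tolerance = 1e-12)
  }
})

test_that("a zero learning rate freezes parameters and loss", {
  net <- tiny_trainable_network()
  cfg <- fast_config(epochs = 3L)
  cfg$train$learning_rate <- 0
  res <- fit_mvgat(net, cfg)
  expect_equal(res$trace$train_loss,
               rep(res$trace$train_loss[1], 3), tolerance = 1e-12)
  st <- res$state
  model0 <- init_model(net, cfg)
  expect_identical(param_arrays(st$model), param_arrays(model0))
})

test_that("training is seed-reproducible and fits the separable fixture", {
  net <- tiny_trainable_network()
  cfg <- fast_config(epochs = 50L)
  res1 <- fit_mvgat(net, cfg)
  res2 <- fit_mvgat(net, cfg)
  expect_identical(res1$trace, res2$trace)
  expect_identical(res1$labels, res2$labels)
  expect_lt(res1$trace$train_loss[50], res1$trace$train_loss[1])
})

test_that("train_epoch takes one step and reports post-step losses", {
  net <- tiny_trainable_network()
  cfg <- fast_config()
  nd <- network_data(net)
  model <- init_model(net, cfg)
  opt <- adam_init(model)
  e1 <- train_epoch(model, nd, opt, cfg, iter = 1L)
  expect_false(identical(param_arrays(e1$model), param_arrays(model)))
  expect_true(is.finite(e1$train_loss) && e1$train_loss >= 0)
  expect_length(e1$labels, n_nodes(net))
  # with no validation mask, selection falls back to the training loss
  expect_identical(e1$selection_loss, e1$train_loss)
  # the scheduler's first iteration agrees with the direct call
  st <- system_step(build_system(net, cfg))
  expect_equal(st$trace$train_loss[1], e1$train_loss, tolerance = 1e-10)
})

test_that("select_best takes the earliest minimum-loss iteration", {
  mk <- function(losses) {
    list(selection_loss = losses,
         predictions = lapply(seq_along(losses), function(i) rep(i, 3)),
         prob = lapply(seq_along(losses), function(i) matrix(i, 3, 2)))
  }
  expect_equal(select_best(mk(c(0.9, 0.4, 0.6)))$iteration, 2L)
  expect_equal(select_best(mk(c(0.9, 0.7, 0.5)))$iteration, 3L)
  expect_equal(select_best(mk(c(0.5, 0.5)))$iteration, 1L)

  # invariant to appending strictly worse iterations
  base <- mk(c(0.8, 0.3, 0.6))
  longer <- mk(c(0.8, 0.3, 0.6, 0.9, 0.31))
  expect_equal(select_best(base)$labels, select_best(longer)$labels)
})

test_that("accuracy follows the correct/total definition", {
  expect_equal(accuracy_score(c(0, 1, 2), c(0, 1, 2)), 1.0)
  expect_equal(accuracy_score(c(0, 1, 2), c(1, 2, 0)), 0.0)
  expect_equal(accuracy_score(c(0, 1, 0, 1), c(0, 1, 0, 0)), 0.75)
  expect_error(accuracy_score(c(0, 1), c(0, 1), mask = c(FALSE, FALSE)),
               "empty mask")
})

test_that("precision/recall/F1 follow the stated conventions", {
  # perfect prediction
  y <- matrix(c(1, 0, 1, 0), 2, 2)
  prf <- precision_recall_f1(y, y)
  expect_equal(unlist(prf), c(precision = 1, recall = 1, f1 = 1))

  # TP = 1, FP = 1, FN = 1 -> all 0.5
  yt <- matrix(c(1, 1, 0), 1, 3)
  yp <- matrix(c(1, 0, 1), 1, 3)
  expect_equal(unlist(precision_recall_f1(yt, yp)),
               c(precision = 0.5, recall = 0.5, f1 = 0.5))

  # TP = 0, FP = 2, FN = 3 -> zeros under the zero convention
  yt2 <- matrix(c(1, 1, 1, 0, 0), 1, 5)
  yp2 <- matrix(c(0, 0, 0, 1, 1), 1, 5)
  expect_equal(unlist(precision_recall_f1(yt2, yp2)),
               c(precision = 0, recall = 0, f1 = 0))
})

test_that("metrics are permutation-invariant, bounded, and F1 is harmonic", {
  set.seed(8)
  for (rep in 1:10) {
    y <- sample(0:2, 12, TRUE)
    p <- sample(0:2, 12, TRUE)
    prf <- precision_recall_f1(y, p, n_classes = 3L)
    acc <- accuracy_score(y, p)
    expect_true(all(unlist(prf) >= 0 & unlist(prf) <= 1))
    expect_true(acc >= 0 && acc <= 1)
    q <- sample(12)
    expect_equal(precision_recall_f1(y[q], p[q], n_classes = 3L), prf)
    expect_equal(accuracy_score(y[q], p[q]), acc)
    # harmonic-mean closed form recomputed independently
    if (prf$precision + prf$recall > 0) {
      expect_equal(prf$f1, 2 / (1 / prf$precision + 1 / prf$recall),
                   tolerance = 1e-12)
    }
  }
})

test_that("ablation variants collapse as expected on a one-view network", {
  net <- single_view_network(tiny_trainable_network(), 1L)
  cfg <- fast_config(epochs = 5L)
  full <- ablation_run(net, "full", cfg)
  mmv <- ablation_run(net, "mmv", cfg)
  sv <- ablation_run(net, "sv", cfg, sv_view = 1L)
  expect_identical(full$labels, mmv$labels)
  expect_identical(full$trace$train_loss, mmv$trace$train_loss)
  expect_identical(full$labels, sv$labels)
  expect_error(ablation_run(net, "bogus", cfg), "arg")
})

test_that("a multilabel network trains through the same pipeline", {
  set.seed(9)
  v <- 16L
  y <- cbind(rep(c(1, 0), each = 8), rep(c(0, 1), each = 8),
             rep(c(1, 0), length.out = v))
  feats <- y + matrix(stats::rnorm(v * 3, sd = 0.3), v, 3)
  net <- multiview_network(as.character(1:v), feats, y,
                           list(random_edge_set(v, 0.3)),
                           masks = list(train = seq_len(v) %% 2L == 0L,
                                        test = seq_len(v) %% 2L == 1L))
  cfg <- fast_config(epochs = 30L)
  res <- fit_mvgat(net, cfg)
  expect_true(is.matrix(res$labels))
  expect_lt(res$trace$train_loss[30], res$trace$train_loss[1])
  rep_m <- metric_report(net, res$labels)
  expect_true(rep_m$train$f1 >= 0 && rep_m$train$f1 <= 1)
})
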