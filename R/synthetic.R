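# Synthetic multi-view networks: planted-community (SBM) edge sets with
# per-view informativeness, Gaussian-blob features, stratified splits, and
# the small fixed fixtures the test-suite trains on.

#' Specification for a multi-view planted-community generator
#'
#' Each view is an independent stochastic block model over the same shared
#' community assignment: within-community pairs get an edge with that view's
#' `p_in`, between-community pairs with `p_out`. Equal `p_in` and `p_out`
#' makes a view pure structural noise. Features are Gaussian blobs: the mean
#' of community c sits at `class_separation * e_c` on the first C coordinate
#' axes, with isotropic `noise_sd`.
#'
#' @param n node count. @param n_classes community count C.
#' @param views list of `c(p_in, p_out)` pairs, one per view.
#' @param feature_dim F (must be >= C). @param class_separation distance of
#'   community means from the origin. @param noise_sd feature standard
#'   deviation. @param train_frac,val_frac split fractions (sum <= 1).
#' @param seed integer seed.
#' @return object of class `sbm_spec`.
#' @export
sbm_spec <- function(n, n_classes, views, feature_dim,
                     class_separation = 1, noise_sd = 1,
                     train_frac = 0.2, val_frac = 0.2, seed = 1L) {
  probs <- unlist(views)
  if (any(probs < 0 | probs > 1)) stop("edge probabilities must lie in [0, 1]")
  if (train_frac + val_frac > 1) stop("split fractions sum above 1")
  if (n < n_classes) stop("need at least one node per community")
  if (feature_dim < n_classes) {
    stop("feature_dim must be >= n_classes (one mean axis per community)")
  }
  structure(list(n = as.integer(n), n_classes = as.integer(n_classes),
                 views = views, feature_dim = as.integer(feature_dim),
                 class_separation = class_separation, noise_sd = noise_sd,
                 train_frac = train_frac, val_frac = val_frac,
                 seed = as.integer(seed)),
            class = "sbm_spec")
}

#' Generate a multi-view planted-community network
#'
#' Communities are assigned round-robin and then shuffled by the seed; each
#' view samples its pair indicators independently; features are community
#' Gaussian blobs; masks come from seeded stratified sampling so every
#' community appears in every split. Identical spec and seed give a
#' bitwise-identical network.
#'
#' @param spec an `sbm_spec`.
#' @return a `multiview_network` with train/val/test masks.
#' @export
generate_multiview_sbm <- function(spec) {
  stopifnot(inherits(spec, "sbm_spec"))
  set.seed(spec$seed)
  n <- spec$n
  comm <- sample(rep_len(seq_len(spec$n_classes) - 1L, n))
  pairs <- utils::combn(n, 2L)
  same <- comm[pairs[1L, ]] == comm[pairs[2L, ]]
  views <- lapply(spec$views, function(pp) {
    p_edge <- ifelse(same, pp[1L], pp[2L])
    keep <- stats::runif(ncol(pairs)) < p_edge
    edge_set(t(pairs[, keep, drop = FALSE]), n)
  })
  mu <- matrix(0, n, spec$feature_dim)
  mu[cbind(seq_len(n), comm + 1L)] <- spec$class_separation
  features <- mu + matrix(stats::rnorm(n * spec$feature_dim,
                                       sd = spec$noise_sd),
                          n, spec$feature_dim)
  train <- logical(n); val <- logical(n)
  for (c0 in seq_len(spec$n_classes) - 1L) {
    members <- which(comm == c0)
    n_tr <- max(1L, round(length(members) * spec$train_frac))
    n_va <- if (spec$val_frac > 0) {
      max(1L, round(length(members) * spec$val_frac))
    } else 0L
    picked <- sample(members, n_tr + n_va)
    train[picked[seq_len(n_tr)]] <- TRUE
    if (n_va > 0L) val[picked[n_tr + seq_len(n_va)]] <- TRUE
  }
  masks <- list(train = train, val = val, test = !(train | val))
  if (all(!val)) masks$val <- NULL
  multiview_network(sprintf("n%03d", seq_len(n)), features, comm, views,
                    masks = masks,
                    label_levels = sprintf("c%d", seq_len(spec$n_classes) - 1L))
}

#' The informative-plus-noise two-view benchmark
#'
#' A fixed study condition for the ablation contrast: 120 nodes in 3 balanced
#' communities; view 1 is informative (p_in = 0.25, p_out = 0.02), view 2 is
#' pure structural noise (p_in = p_out = 0.08); 10 Gaussian features with
#' class separation 1.0 and noise sd 1.0; 20% train, 20% validation.
#'
#' @param seed integer seed.
#' @return a `multiview_network`.
#' @export
informative_plus_noise_benchmark <- function(seed = 1L) {
  generate_multiview_sbm(sbm_spec(
    n = 120L, n_classes = 3L,
    views = list(c(0.25, 0.02), c(0.08, 0.08)),
    feature_dim = 10L, class_separation = 1.0, noise_sd = 1.0,
    train_frac = 0.2, val_frac = 0.2, seed = seed))
}

# Deterministic, seed-free feature table of the 30-node toy fixture:
# first axis carries the class sign, the remaining axes add small exact
# decimal perturbations so the cosine-similarity view stays class-pure.
toy_features <- function() {
  i <- seq_len(30L)
  cls <- rep(c(0L, 1L), each = 15L)
  cbind(ifelse(cls == 0L, 1, -1),
        ((i * 7L) %% 11L - 5L) / 10,
        ((i * 3L) %% 13L - 6L) / 10,
        ((i * 5L) %% 17L - 8L) / 10)
}

#' The committed 30-node toy fixture
#'
#' Hard-coded and seed-free: 30 nodes in two classes of 15, linearly
#' separable features; view 1 is two disjoint 15-cliques, view 2 is the
#' cosine-similarity view of the features with `top_k = 3`. Ten nodes (five
#' per class) form the train mask, the rest are test. The same construction
#' is committed as plain-text files under `inst/extdata/toy/`.
#'
#' @return a `multiview_network`.
#' @export
fixture_toy_network <- function() {
  features <- toy_features()
  cls <- rep(c(0L, 1L), each = 15L)
  clique <- function(members) t(utils::combn(members, 2L))
  view1 <- edge_set(rbind(clique(1:15), clique(16:30)), 30L)
  view2 <- build_similarity_view(features, top_k = 3L)
  train <- seq_len(30L) %% 3L == 1L
  multiview_network(sprintf("t%02d", seq_len(30L)), features, cls,
                    list(view1, view2),
                    masks = list(train = train, test = !train),
                    label_levels = c("c0", "c1"))
}

#' Write a multi-view network to plain-text files
#'
#' Emits one edge list per view (`view<m>.edges`), a "content"-dialect
#' feature+label table (`nodes.content`), and, when masks are present, a
#' two-column `masks.tsv` (node_id, split).
#'
#' @param net a `multiview_network`. @param dir output directory.
#' @return invisibly, the vector of written paths.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (m in seq_len(n_views(net))) {
    p <- file.path(dir, sprintf("view%d.edges", m))
    write_edge_list(net$views[[m]], p, node_ids = net$node_ids)
    paths <- c(paths, p)
  }
  lab <- if (is.null(net$label_levels)) as.character(net$labels) else
    net$label_levels[net$labels + 1L]
  p <- file.path(dir, "nodes.content")
  write_feature_table(net$node_ids, net$features, lab, p)
  paths <- c(paths, p)
  if (!is.null(net$masks)) {
    split <- rep("test", n_nodes(net))
    if (!is.null(net$masks$val)) split[net$masks$val] <- "val"
    split[net$masks$train] <- "train"
    p <- file.path(dir, "masks.tsv")
    writeLines(paste(net$node_ids, split, sep = "\t"), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read the masks file written by [write_network()]
#' @param path masks.tsv path. @param node_ids node ids fixing the order.
#' @return list of logical vectors train/val/test.
#' @export
read_masks <- function(path, node_ids) {
  tab <- utils::read.table(path, sep = "\t", col.names = c("id", "split"),
                           colClasses = "character")
  split <- tab$split[match(node_ids, tab$id)]
  out <- list(train = split == "train",
              val = split == "val",
              test = split == "test")
  if (!any(out$val)) out$val <- NULL
  out
}
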