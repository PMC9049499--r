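#' Construct an undirected edge set
#'
#' An `edge_set` stores the edges of one view of a multi-view network as a
#' two-column integer matrix of unordered node pairs. Node indices are 1-based
#' and drawn from `1..n_nodes`. Self-loops are not stored here; they are
#' injected later, when neighborhoods are built for the attention encoder.
#'
#' @param pairs two-column integer matrix (or empty) of node index pairs.
#' @param n_nodes number of nodes the indices are drawn from.
#' @return An object of class `edge_set` with elements `edges` (m x 2 integer
#'   matrix, each row sorted ascending, rows sorted and unique) and `n_nodes`.
#' @export
edge_set <- function(pairs, n_nodes) {
  n_nodes <- as.integer(n_nodes)
  if (is.null(pairs) || length(pairs) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    if (any(!is.finite(pairs)) || any(pairs < 1L) || any(pairs > n_nodes)) {
      stop("edge indices must lie in [1, n_nodes]")
    }
    keep <- pairs[, 1L] != pairs[, 2L]
    pairs <- pairs[keep, , drop = FALSE]
    lo <- pmin(pairs[, 1L], pairs[, 2L])
    hi <- pmax(pairs[, 1L], pairs[, 2L])
    key <- (as.numeric(lo) - 1) * n_nodes + as.numeric(hi)
    ord <- order(key)
    dup <- duplicated(key[ord])
    edges <- cbind(lo[ord][!dup], hi[ord][!dup])
  }
  structure(list(edges = edges, n_nodes = n_nodes), class = "edge_set")
}

#' @export
print.edge_set <- function(x, ...) {
  cat(sprintf("<edge_set: %d undirected edges over %d nodes>\n",
              nrow(x$edges), x$n_nodes))
  invisible(x)
}

#' Number of edges in an edge set
#' @param es an `edge_set`.
#' @return integer edge count.
#' @export
n_edges <- function(es) nrow(es$edges)

#' Load a two-column edge list from a text file
#'
#' Reads whitespace/tab-separated node-id pairs, one edge per line (the
#' citation-list dialect used by the common citation benchmarks). Duplicate
#' lines and reversed duplicates collapse to a single undirected edge;
#' self-loop lines are dropped with a warning.
#'
#' @param path file path.
#' @param id_map optional named integer vector mapping external id -> 1-based
#'   index. When absent, ids are assigned indices in order of first appearance.
#' @return list with `edge_set` and `id_map` (named integer vector).
#' @export
load_edge_list <- function(path, id_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge line %d in '%s': expected 2 tokens, got %d",
                 lineno[bad[1L]], path, lengths(toks)[bad[1L]]))
  }
  a <- vapply(toks, `[[`, "", 1L)
  b <- vapply(toks, `[[`, "", 2L)
  if (is.null(id_map)) {
    ids <- unique(as.vector(rbind(a, b)))   # first-appearance order, row-major
    id_map <- stats::setNames(seq_along(ids), ids)
  } else {
    missing <- setdiff(unique(c(a, b)), names(id_map))
    if (length(missing) > 0L) {
      stop(sprintf("edge list '%s' refers to unknown id '%s'", path, missing[1L]))
    }
  }
  ia <- id_map[a]
  ib <- id_map[b]
  n_self <- sum(ia == ib)
  if (n_self > 0L) {
    warning(sprintf("dropped %d self-loop line(s) in '%s'", n_self, path))
  }
  list(edge_set = edge_set(cbind(ia, ib), length(id_map)), id_map = id_map)
}

#' Write an edge set as a two-column text file
#'
#' @param es an `edge_set`.
#' @param path output path.
#' @param node_ids optional character vector of external ids (defaults to the
#'   1-based indices themselves).
#' @export
write_edge_list <- function(es, path, node_ids = NULL) {
  if (is.null(node_ids)) node_ids <- as.character(seq_len(es$n_nodes))
  e <- es$edges
  writeLines(paste(node_ids[e[, 1L]], node_ids[e[, 2L]], sep = "\t"), path)
  invisible(path)
}

#' Load a feature+label table
#'
#' Two dialects: `"content"` is the row layout `id feat_1 ... feat_F label`
#' with whitespace separators and no header (as used by the common citation
#' benchmarks); `"csv"` is the same columns with a header row. Labels are
#' mapped to contiguous 0-based class indices in sorted label-string order so
#' the mapping is reproducible across loads.
#'
#' @param path file path.
#' @param dialect `"content"` or `"csv"`.
#' @return list with `node_ids` (character), `features` (V x F numeric matrix),
#'   `labels` (0-based integer class indices), `label_levels` (sorted label
#'   strings).
#' @export
load_feature_table <- function(path, dialect = c("content", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                          check.names = FALSE)
    rows <- lapply(seq_len(nrow(df)), function(i) as.character(df[i, ]))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- strsplit(trimws(lines), "[[:space:]]+")
  }
  if (length(rows) == 0L) stop(sprintf("feature table '%s' is empty", path))
  ncol_row <- lengths(rows)
  if (length(unique(ncol_row)) != 1L) {
    bad <- which(ncol_row != ncol_row[1L])[1L]
    stop(sprintf("ragged feature table '%s': row %d has %d columns, expected %d",
                 path, bad, ncol_row[bad], ncol_row[1L]))
  }
  p <- ncol_row[1L]
  if (p < 2L) stop("feature table needs at least an id and a label column")
  node_ids <- vapply(rows, `[[`, "", 1L)
  label_str <- vapply(rows, `[[`, "", p)
  nf <- p - 2L
  features <- matrix(0, nrow = length(rows), ncol = nf)
  if (nf > 0L) {
    for (i in seq_along(rows)) {
      vals <- suppressWarnings(as.numeric(rows[[i]][2:(p - 1L)]))
      if (anyNA(vals)) {
        j <- which(is.na(vals))[1L]
        stop(sprintf("non-numeric feature token in '%s' at row %d, feature column %d",
                     path, i, j))
      }
      features[i, ] <- vals
    }
  }
  label_levels <- sort(unique(label_str))
  labels <- match(label_str, label_levels) - 1L
  list(node_ids = node_ids, features = features, labels = labels,
       label_levels = label_levels)
}

#' Write a feature+label table in the "content" dialect
#'
#' @param node_ids character ids. @param features V x F matrix.
#' @param labels character or factor labels (one per node). @param path output.
#' @export
write_feature_table <- function(node_ids, features, labels, path) {
  feat_txt <- apply(features, 1L, function(r) paste(format(r, scientific = FALSE, trim = TRUE), collapse = "\t"))
  if (ncol(features) == 0L) feat_txt <- rep("", length(node_ids))
  body <- ifelse(nzchar(feat_txt),
                 paste(node_ids, feat_txt, as.character(labels), sep = "\t"),
                 paste(node_ids, as.character(labels), sep = "\t"))
  writeLines(body, path)
  invisible(path)
}

#' Construct a multi-view network
#'
#' The central data container: one shared node set with features and labels,
#' plus `k >= 1` edge sets (views) over those nodes.
#'
#' @param node_ids character vector of external node identifiers.
#' @param features V x F numeric matrix.
#' @param labels integer vector of 0-based class indices (multi-class) or a
#'   V x C binary matrix (multi-label).
#' @param views list of `edge_set`, all with `n_nodes == V`.
#' @param masks optional list with logical vectors `train`, `val`, `test`
#'   (any subset of the three), each of length V; present masks must be
#'   pairwise disjoint.
#' @param label_levels optional character vector naming the classes.
#' @return object of class `multiview_network`.
#' @export
multiview_network <- function(node_ids, features, labels, views,
                              masks = NULL, label_levels = NULL) {
  net <- structure(
    list(node_ids = as.character(node_ids),
         features = as.matrix(features),
         labels = labels,
         views = views,
         masks = masks,
         label_levels = label_levels),
    class = "multiview_network")
  issues <- validate_network(net)
  if (length(issues) > 0L) {
    stop("invalid multiview_network: ", paste(issues, collapse = "; "))
  }
  net
}

#' Number of views / nodes / classes of a multi-view network
#' @param net a `multiview_network`.
#' @export
n_views <- function(net) length(net$views)

#' @rdname n_views
#' @export
n_nodes <- function(net) length(net$node_ids)

#' @rdname n_views
#' @export
n_classes <- function(net) {
  if (is.matrix(net$labels)) ncol(net$labels) else max(net$labels) + 1L
}

#' Is the task multi-label?
#' @param net a `multiview_network`.
#' @export
is_multilabel <- function(net) is.matrix(net$labels)

#' @export
print.multiview_network <- function(x, ...) {
  cat(sprintf("<multiview_network: %d nodes, %d features, %d views, %d classes%s>\n",
              n_nodes(x), ncol(x$features), n_views(x), n_classes(x),
              if (is_multilabel(x)) " (multilabel)" else ""))
  invisible(x)
}

#' Check the structural invariants of a multi-view network
#'
#' Reporting-only: returns a character vector of violations (empty means
#' valid) and never mutates or throws.
#'
#' @param net a `multiview_network` (or a bare list with the same fields).
#' @return character vector of violation messages.
#' @export
validate_network <- function(net) {
  issues <- character(0)
  v <- length(net$node_ids)
  if (!is.matrix(net$features) || nrow(net$features) != v) {
    issues <- c(issues, sprintf("feature matrix has %d rows, expected %d",
                                NROW(net$features), v))
  } else if (any(!is.finite(net$features))) {
    bad <- which(!is.finite(net$features), arr.ind = TRUE)[1L, ]
    issues <- c(issues, sprintf("non-finite feature at row %d, col %d",
                                bad[1L], bad[2L]))
  }
  if (is.matrix(net$labels)) {
    if (nrow(net$labels) != v) {
      issues <- c(issues, "label matrix row count != node count")
    }
    if (!all(net$labels %in% c(0, 1))) {
      issues <- c(issues, "multilabel matrix must be binary")
    }
  } else {
    if (length(net$labels) != v) {
      issues <- c(issues, "label vector length != node count")
    } else if (any(net$labels < 0L)) {
      issues <- c(issues, "class indices must be >= 0")
    }
  }
  if (length(net$views) < 1L) issues <- c(issues, "need at least one view")
  for (m in seq_along(net$views)) {
    es <- net$views[[m]]
    if (!inherits(es, "edge_set")) {
      issues <- c(issues, sprintf("view %d is not an edge_set", m))
    } else if (es$n_nodes != v) {
      issues <- c(issues, sprintf("view %d has n_nodes = %d, expected %d",
                                  m, es$n_nodes, v))
    }
  }
  if (!is.null(net$masks)) {
    mk <- net$masks[!vapply(net$masks, is.null, TRUE)]
    for (nm in names(mk)) {
      if (length(mk[[nm]]) != v) {
        issues <- c(issues, sprintf("mask '%s' length != node count", nm))
      }
    }
    if (length(mk) > 1L) {
      tot <- Reduce(`+`, mk)
      if (any(tot > 1L)) issues <- c(issues, "masks overlap")
    }
  }
  issues
}

#' Build a view from cosine similarity of node features
#'
#' Links every node to its `top_k` most cosine-similar other nodes; the edge
#' set is the union over directions, so degrees can exceed `top_k`. Zero-norm
#' feature rows have similarity 0 to everything. Ties are broken by ascending
#' node index, which makes the construction deterministic.
#'
#' @param features V x F numeric matrix (V >= 2).
#' @param top_k number of nearest neighbors per node (0 < top_k < V).
#' @return an `edge_set` over the V nodes.
#' @export
build_similarity_view <- function(features, top_k = 10L) {
  features <- as.matrix(features)
  v <- nrow(features)
  if (top_k <= 0L) stop("top_k must be positive")
  if (v < 2L) stop("need at least 2 nodes to build a similarity view")
  if (top_k >= v) stop("top_k must be smaller than the number of nodes")
  nrm <- sqrt(rowSums(features^2))
  x <- features
  nz <- nrm > 0
  x[nz, ] <- x[nz, , drop = FALSE] / nrm[nz]
  x[!nz, ] <- 0                      # zero-norm rows: similarity 0 everywhere
  sim <- tcrossprod(x)
  diag(sim) <- -Inf
  src <- integer(0); dst <- integer(0)
  for (i in seq_len(v)) {
    # order(-sim) with index tie-break: highest similarity first, then lowest index
    nb <- order(-sim[i, ], seq_len(v))[seq_len(top_k)]
    src <- c(src, rep.int(i, top_k))
    dst <- c(dst, nb)
  }
  edge_set(cbind(src, dst), v)
}

#' Adjacency lists of an edge set
#'
#' Returns, per node, the sorted vector of neighbor indices. With
#' `include_self = TRUE` (the default, and what the attention encoder
#' requires) every node lists itself even when isolated, so no neighborhood
#' is empty and the attention softmax is always defined.
#'
#' @param es an `edge_set`.
#' @param include_self add each node to its own neighborhood?
#' @return object of class `neighbor_index`: a list of sorted integer vectors.
#' @export
neighborhoods <- function(es, include_self = TRUE) {
  v <- es$n_nodes
  e <- es$edges
  src <- c(e[, 1L], e[, 2L])
  dst <- c(e[, 2L], e[, 1L])
  if (include_self) {
    src <- c(src, seq_len(v))
    dst <- c(dst, seq_len(v))
  }
  nbr <- vector("list", v)
  if (length(src) > 0L) {
    ord <- order(src, dst)
    nbr_raw <- split(dst[ord], factor(src[ord], levels = seq_len(v)))
    nbr <- unname(nbr_raw)
  } else {
    nbr <- replicate(v, integer(0), simplify = FALSE)
  }
  structure(nbr, class = "neighbor_index", include_self = include_self)
}

#' Write hard predictions as a TSV
#'
#' @param node_ids character ids. @param pred 0-based predicted class indices.
#' @param prob probability of the predicted class per node.
#' @param path output path. @param label_levels optional class names.
#' @export
write_predictions <- function(node_ids, pred, prob, path, label_levels = NULL) {
  lab <- if (is.null(label_levels)) as.character(pred) else label_levels[pred + 1L]
  utils::write.table(
    data.frame(node_id = node_ids, predicted_label = lab,
               probability = prob, stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
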