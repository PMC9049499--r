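# Configuration: nested list with sections data / model / fusion / train /
# system, read from YAML and merged over the defaults below.

#' Default configuration
#'
#' Defaults follow the established settings for this model family: 2 layers,
#' 8 attention heads, hidden dimension 8, input and attention dropout 0.6,
#' LeakyReLU slope 0.2, Adam with learning rate 0.005 and weight decay 5e-4,
#' 200 training iterations.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    data = list(
      views = list(),            # paths to edge-list files, one per view
      features = NULL,           # feature+label table path
      dialect = "content",
      similarity_view = list(enabled = FALSE, top_k = 10L)
    ),
    model = list(
      hidden_dim = 8L,
      heads = 8L,
      layers = 2L,
      dropout_input = 0.6,
      dropout_attention = 0.6,
      leaky_slope = 0.2
    ),
    fusion = list(
      mode = "attention",        # attention | mean
      scope = "per_node",        # per_node | global
      query = "mean_over_queries", # mean_over_queries | mean_view
      hidden_dim = 8L
    ),
    train = list(
      epochs = 200L,
      learning_rate = 0.005,
      weight_decay = 5e-4,
      seed = 1L,
      selection = "auto"         # auto | train_loss | val_loss
    ),
    system = list(
      max_iterations = NULL      # defaults to train$epochs
    )
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a YAML configuration file
#'
#' Values present in the file override [default_config()]; everything else
#' keeps its default.
#' @param path YAML file path.
#' @return nested configuration list.
#' @export
read_config <- function(path) {
  merge_config(default_config(), yaml::read_yaml(path))
}

#' Load a multi-view network as described by a configuration
#'
#' Reads the feature table first (fixing the node universe and order), then
#' each view's edge list against that id map, and optionally appends a
#' cosine-similarity view built from the features.
#'
#' @param config configuration list with a populated `data` section.
#' @param base_dir directory that relative paths are resolved against.
#' @return a `multiview_network` (without masks).
#' @export
load_network_from_config <- function(config, base_dir = ".") {
  dc <- config$data
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  ft <- load_feature_table(resolve(dc$features), dc$dialect)
  id_map <- stats::setNames(seq_along(ft$node_ids), ft$node_ids)
  views <- lapply(dc$views, function(p) {
    load_edge_list(resolve(p), id_map = id_map)$edge_set
  })
  if (isTRUE(dc$similarity_view$enabled)) {
    views <- c(views, list(build_similarity_view(ft$features,
                                                 dc$similarity_view$top_k)))
  }
  multiview_network(ft$node_ids, ft$features, ft$labels, views,
                    label_levels = ft$label_levels)
}

#' Deterministic hash of a configuration (for run logs)
#' @param config configuration list.
#' @return short hex string.
#' @export
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  codes <- utf8ToInt(txt)
  h <- 5381
  for (cc in codes) h <- (h * 33 + cc) %% 2147483647
  sprintf("%08x", as.integer(h))
}
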