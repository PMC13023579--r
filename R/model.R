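# Full model assembly: view branches, optional cross-attention fusion, and
# the MLP classifier head.

#' Describe a model variant for training or ablation
#'
#' @param model one of `"gcn"` (plain 2-layer GCN baseline), `"fgcn"`
#'   (frequency graph branch only), `"fgcn_tcnn"` (branches concatenated, no
#'   fusion) or `"fgcn_tcnn_caf"` (full model)
#' @param views subset of `"eeg_f"`, `"eeg_t"`, `"fnirs_t"`; branches are
#'   instantiated only for the selected views
#' @param order TCNN convolution order, `"sfts"` or `"tfss"`
#' @param delta scaling factor of the adjacency distance prior
#' @param label optional display label
#' @return object of class `model_variant`
#' @export
model_variant <- function(model = c("fgcn_tcnn_caf", "fgcn_tcnn", "fgcn", "gcn"),
                          views = c("eeg_f", "eeg_t", "fnirs_t"),
                          order = c("sfts", "tfss"), delta = 9,
                          label = NULL) {
  model <- match.arg(model)
  order <- match.arg(order)
  stopifnot(length(views) >= 1L, all(views %in% .caf_views))
  if (model %in% c("gcn", "fgcn") && !"eeg_f" %in% views) {
    stop("graph-only variants require the eeg_f view")
  }
  uses_caf <- model == "fgcn_tcnn_caf" && length(views) >= 2L
  structure(
    list(
      model = model, views = views, order = order, delta = delta,
      uses_caf = uses_caf,
      label = label %||% paste0(model, ":", paste(views, collapse = "+"))
    ),
    class = "model_variant"
  )
}

#' Build an untrained model for a variant
#'
#' Draws all weights under the current RNG state; call `set.seed()` first for
#' reproducible initialization.
#'
#' @param variant a [model_variant()]
#' @param montage a [make_montage()] (needed when the frequency view is used)
#' @param fgcn_cfg,caf_cfg,head architecture configurations; `head` is a list
#'   with `hidden` width and `dropout`
#' @param n_classes number of output classes
#' @return object of class `emofuse_model` holding the parameter list and
#'   configuration
#' @export
build_model <- function(variant, montage = NULL,
                        fgcn_cfg = fgcn_config(), caf_cfg = caf_config(),
                        head = list(hidden = 256L, dropout = 0.5),
                        n_classes = 4L) {
  params <- list()
  tcnn_cfgs <- list()
  if ("eeg_f" %in% variant$views) {
    if (is.null(montage)) stop("montage required for the frequency view")
    adj <- init_adjacency(montage, variant$delta)
    fp <- fgcn_params(
      fgcn_cfg, adj,
      learn_adjacency = variant$model != "gcn",
      with_skip_gat = variant$model != "gcn"
    )
    params <- c(params, fp)
  }
  if ("eeg_t" %in% variant$views) {
    tcnn_cfgs$eeg <- tcnn_config("eeg", variant$order)
    params <- c(params, tcnn_params(tcnn_cfgs$eeg))
  }
  if ("fnirs_t" %in% variant$views) {
    tcnn_cfgs$fnirs <- tcnn_config("fnirs", variant$order)
    params <- c(params, tcnn_params(tcnn_cfgs$fnirs))
  }
  if (variant$uses_caf) {
    params <- c(params, caf_params(caf_cfg, variant$views, fgcn_cfg))
    in_dim <- 2L * length(.caf_pairs(variant$views)) * caf_cfg$d_model
  } else {
    in_dim <- 0L
    if ("eeg_f" %in% variant$views) {
      in_dim <- in_dim + fgcn_cfg$n_nodes *
        if (variant$model == "gcn") 2L * fgcn_cfg$gcn_dims[2] else fgcn_cfg$gat_out
    }
    in_dim <- in_dim + 90L * sum(c("eeg_t", "fnirs_t") %in% variant$views)
  }
  params$head_W1 <- init_mat(in_dim, head$hidden)
  params$head_b1 <- init_vec(head$hidden)
  params$head_W2 <- init_mat(head$hidden, n_classes)
  params$head_b2 <- init_vec(n_classes)
  structure(
    list(
      params = params, variant = variant,
      fgcn_cfg = fgcn_cfg, caf_cfg = caf_cfg, tcnn_cfgs = tcnn_cfgs,
      head = head, n_classes = n_classes,
      learn_adjacency = "eeg_f" %in% variant$views && variant$model != "gcn"
    ),
    class = "emofuse_model"
  )
}

# classifier head on a (B, d) node
.head_node <- function(t, getp, x, dropout, training) {
  z <- ad_linear(t, x, getp("head_W1"), getp("head_b1"))
  z <- ad_leaky_relu(t, z, 0.01)
  z <- ad_dropout(t, z, dropout, training)
  ad_linear(t, z, getp("head_W2"), getp("head_b2"))
}

# batch: list of arrays in internal layout (see .batch_views); returns the
# (B, n_classes) logits node
.model_forward_node <- function(t, model, batch, training = FALSE,
                                record = NULL) {
  v <- model$variant
  params <- model$params
  attr(params, "learn_adjacency") <- model$learn_adjacency
  getp <- param_fetcher(t, params)
  parts <- list() # named intermediate outputs per view
  if ("eeg_f" %in% v$views) {
    fg <- .fgcn_forward_node(
      t, params,
      ad_const(t, batch$eeg_de), ad_const(t, batch$eeg_psd),
      model$fgcn_cfg,
      training = training,
      variant = if (v$model == "gcn") "gcn" else "fgcn",
      record = record
    )
    parts$eeg_f <- fg$embedding # (62, d, B)
  }
  if ("eeg_t" %in% v$views) {
    parts$eeg_t <- .tcnn_forward_node(
      t, getp, ad_const(t, batch$eeg_time), model$tcnn_cfgs$eeg
    )
  }
  if ("fnirs_t" %in% v$views) {
    parts$fnirs_t <- .tcnn_forward_node(
      t, getp, ad_const(t, batch$fnirs_time), model$tcnn_cfgs$fnirs
    )
  }
  if (v$uses_caf) {
    tokens <- list()
    for (tag in intersect(.caf_views, v$views)) {
      x <- if (tag == "eeg_f") {
        parts$eeg_f
      } else {
        # pooled map (9, 10, B): tokens are the 9 steps, features the 10 maps
        parts[[tag]]$map
      }
      tokens[[tag]] <- .tokenize_node(t, x, tag, getp)
    }
    fused <- .caf_fuse_node(t, tokens, getp, model$caf_cfg, record)
  } else {
    blocks <- list()
    if (!is.null(parts$eeg_f)) {
      d <- dim(parts$eeg_f$value)
      blocks <- c(blocks, list(
        ad_t(t, ad_reshape(t, parts$eeg_f, c(d[1] * d[2], d[3])))
      ))
    }
    for (tag in c("eeg_t", "fnirs_t")) {
      if (!is.null(parts[[tag]])) {
        blocks <- c(blocks, list(parts[[tag]]$embedding))
      }
    }
    fused <- if (length(blocks) == 1L) blocks[[1]] else ad_cbind(t, blocks)
  }
  .head_node(t, getp, fused, model$head$dropout, training)
}

# slice normalized views into the internal batched layout
.batch_views <- function(views, idx) {
  list(
    eeg_de = aperm(views$eeg_de[idx, , , drop = FALSE], c(2, 3, 1)),
    eeg_psd = aperm(views$eeg_psd[idx, , , drop = FALSE], c(2, 3, 1)),
    eeg_time = aperm(views$eeg_time[idx, , , drop = FALSE], c(3, 2, 1)),
    fnirs_time = aperm(views$fnirs_time[idx, , , drop = FALSE], c(3, 2, 1))
  )
}

#' Classifier head (numeric interface)
#'
#' Linear -> LeakyReLU -> dropout (training only) -> linear; returns class
#' probabilities via softmax.
#'
#' @param fused `B x d` fusion features
#' @param W1,b1,W2,b2 head weights (`d x h`, `h`, `h x K`, `K`)
#' @return list with `logits` (`B x K`) and `probs` (rows summing to one)
#' @export
classify <- function(fused, W1, b1, W2, b2) {
  t <- ad_tape()
  getp <- param_fetcher(
    t, list(head_W1 = W1, head_b1 = b1, head_W2 = W2, head_b2 = b2),
    constant = TRUE
  )
  logits <- .head_node(t, getp, ad_const(t, fused), 0, training = FALSE)$value
  e <- exp(logits - apply(logits, 1, max))
  list(logits = logits, probs = e / rowSums(e))
}

#' Predict class labels with a trained model
#'
#' @param model a trained `emofuse_model`
#' @param views normalized [build_views()] tensors
#' @param idx window indices to predict (default all)
#' @param batch_size forward-pass batch size
#' @return list with integer `pred` (class indices) and `probs`
#' @export
predict_model <- function(model, views, idx = seq_along(views$labels),
                          batch_size = 256L) {
  probs <- matrix(0, length(idx), model$n_classes)
  for (s in split(seq_along(idx), ceiling(seq_along(idx) / batch_size))) {
    t <- ad_tape()
    logits <- .model_forward_node(
      t, model, .batch_views(views, idx[s]),
      training = FALSE
    )$value
    e <- exp(logits - apply(logits, 1, max))
    probs[s, ] <- e / rowSums(e)
  }
  list(pred = max.col(probs, ties.method = "first"), probs = probs)
}

#' Export cross-attention weights for channel-importance inspection
#'
#' Runs one forward pass and returns, for every fusion path, the attention
#' array (`n_query_tokens x n_key_tokens x B`); each row sums to one, so the
#' summed attention mass over key tokens equals the number of query tokens.
#'
#' @param model a trained full model (`fgcn_tcnn_caf`)
#' @param views normalized view tensors
#' @param idx window indices of the probe batch
#' @return named list of attention arrays (`caf_alpha_*`), plus the GAT
#'   attention matrices (`gat_alpha_*`)
#' @export
export_attention <- function(model, views, idx = seq_len(min(64L, length(views$labels)))) {
  rec <- new.env(parent = emptyenv())
  t <- ad_tape()
  .model_forward_node(t, model, .batch_views(views, idx),
    training = FALSE, record = rec
  )
  as.list(rec)
}
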