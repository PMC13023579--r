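# Frequency-domain graph branch.
#
# A distance-prior adjacency (edge weight delta / d_ij^2 clipped to
# [0.1, 1]) initializes a learnable 62 x 62 matrix. DE and PSD band features
# each pass through two graph-convolution layers (5 -> 10 -> 15) with
# symmetric degree normalization recomputed from the current adjacency every
# forward pass; the input and both layer outputs are concatenated per branch
# (30 dims), the two branches concatenated (60 dims), and a 6-head additive
# graph attention layer over the fully connected node set produces the
# per-node frequency embedding (6 heads x 10 dims).

#' Distance-prior edge weights
#'
#' Piecewise rule: `delta / d^2`, clipped to 1 from above and 0.1 from below;
#' diagonal set to zero (self-loops enter later as the identity term).
#'
#' @param dist matrix of pairwise channel distances (cm)
#' @param delta scaling factor (default 9)
#' @return matrix of edge weights in `[0.1, 1]` with zero diagonal
#' @export
adjacency_prior <- function(dist, delta = 9) {
  if (delta <= 0) stop("delta must be positive")
  a <- delta / dist^2
  a <- pmin(pmax(a, 0.1), 1)
  diag(a) <- 0
  a
}

#' Initialize the learnable adjacency from a montage
#'
#' The clipped distance prior is symmetrically degree-normalized
#' (`D^-1/2 A D^-1/2`) and stored as the trainable initial value.
#'
#' @param montage a [make_montage()] object
#' @param delta scaling factor of the distance prior
#' @return object of class `adjacency`: `A` (normalized, trainable init),
#'   `prior` (clipped pre-normalization weights), `delta`, `channel_names`
#' @export
init_adjacency <- function(montage, delta = 9) {
  d <- channel_distances(montage)
  prior <- adjacency_prior(d, delta)
  s <- 1 / sqrt(rowSums(prior))
  A <- prior * outer(s, s)
  dimnames(A) <- dimnames(prior)
  structure(
    list(
      A = A, prior = prior, delta = delta,
      channel_names = montage$eeg_names
    ),
    class = "adjacency"
  )
}

#' FGCN architecture configuration
#'
#' @param in_dim input features per node (5 bands)
#' @param gcn_dims widths of the two graph-convolution layers
#' @param gat_heads number of attention heads
#' @param gat_out_per_head output width per head
#' @param dropout_gcn,dropout_gat dropout rates after the GCN layers / GAT
#' @param n_nodes number of graph nodes (EEG channels)
#' @export
fgcn_config <- function(in_dim = 5L, gcn_dims = c(10L, 15L), gat_heads = 6L,
                        gat_out_per_head = 10L, dropout_gcn = 0.3,
                        dropout_gat = 0.3, n_nodes = 62L) {
  cfg <- list(
    in_dim = in_dim, gcn_dims = gcn_dims, gat_heads = gat_heads,
    gat_out_per_head = gat_out_per_head, dropout_gcn = dropout_gcn,
    dropout_gat = dropout_gat, n_nodes = n_nodes,
    branch_dim = in_dim + sum(gcn_dims)
  )
  cfg$gat_in <- 2L * cfg$branch_dim
  cfg$gat_out <- gat_heads * gat_out_per_head
  cfg
}

# parameter set for the FGCN (call under the caller's seed)
fgcn_params <- function(cfg, adjacency, learn_adjacency = TRUE,
                        with_skip_gat = TRUE) {
  p <- list(fgcn_A = adjacency$A)
  for (br in c("de", "psd")) {
    p[[paste0("fgcn_", br, "_W1")]] <- init_mat(cfg$in_dim, cfg$gcn_dims[1])
    p[[paste0("fgcn_", br, "_b1")]] <- init_vec(cfg$gcn_dims[1])
    p[[paste0("fgcn_", br, "_W2")]] <- init_mat(cfg$gcn_dims[1], cfg$gcn_dims[2])
    p[[paste0("fgcn_", br, "_b2")]] <- init_vec(cfg$gcn_dims[2])
  }
  if (with_skip_gat) {
    for (h in seq_len(cfg$gat_heads)) {
      p[[paste0("fgcn_gat_W", h)]] <- init_mat(cfg$gat_in, cfg$gat_out_per_head)
      p[[paste0("fgcn_gat_a1_", h)]] <- init_mat(cfg$gat_out_per_head, 1)
      p[[paste0("fgcn_gat_a2_", h)]] <- init_mat(cfg$gat_out_per_head, 1)
    }
  }
  attr(p, "learn_adjacency") <- learn_adjacency
  p
}

# symmetric-normalized propagation matrix from the current adjacency:
# P = D^-1/2 (clamp(A, 0) + I) D^-1/2
.fgcn_prop_matrix <- function(t, A_node, n) {
  Ac <- ad_clamp_min(t, A_node, 0)
  At <- ad_add(t, Ac, ad_const(t, diag(n)))
  dg <- ad_rowsum(t, At)
  s <- ad_pow(t, dg, -0.5)
  ad_mul(t, At, ad_mm(t, s, ad_t(t, s)))
}

# one graph-convolution layer: ReLU(P H W + b); H is (n, d, B)
.gcn_layer_node <- function(t, P, H, W, b) {
  d <- dim(H$value)
  HM <- ad_reshape(t, H, c(d[1], d[2] * d[3]))
  PH <- ad_reshape(t, ad_mm(t, P, HM), d)
  Z <- ad_add_bias(t, ad_bmm_shared(t, PH, W), b, 2)
  ad_relu(t, Z)
}

# additive multi-head graph attention over the fully connected node set;
# H is (n, d_in, B); getp fetches parameter nodes; returns (n, heads*dh, B).
# Attention logits are built directly in (node i, batch) x (node j) matrix
# layout: e[(i,b), j] = a1'Wh_i + a2'Wh_j, so the softmax and the weighted
# aggregation run without permuting any (n, n, B) array.
.gat_node <- function(t, H, getp, heads, record = NULL) {
  d <- dim(H$value)
  n <- d[1]
  B <- d[3]
  HM <- ad_reshape(t, ad_aperm(t, H, c(1, 3, 2)), c(n * B, d[2])) # rows (i,b)
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    W <- getp(paste0("fgcn_gat_W", h))
    a1 <- getp(paste0("fgcn_gat_a1_", h))
    a2 <- getp(paste0("fgcn_gat_a2_", h))
    WhM <- ad_mm(t, HM, W) # (n*B, dh), rows (i,b)
    dh <- ncol(WhM$value)
    f1 <- ad_reshape(t, ad_mm(t, WhM, a1), c(n * B)) # source term per (i,b)
    f2m <- ad_t(t, ad_reshape(t, ad_mm(t, WhM, a2), c(n, B))) # (B, n) over j
    E <- ad_gather_rows(t, f2m, rep(seq_len(B), each = n)) # (n*B, n)
    E <- ad_add_bias(t, E, f1, 1)
    E <- ad_leaky_relu(t, E, 0.2)
    alpha <- ad_softmax_rows(t, E) # softmax over neighbours j
    if (!is.null(record)) record[[paste0("gat_alpha_", h)]] <- alpha$value
    Wh3 <- ad_aperm(t, ad_reshape(t, WhM, c(n, B, dh)), c(1, 3, 2)) # (n,dh,B)
    agg <- ad_bmm_blocked(t, alpha, Wh3) # (n, dh, B)
    outs[[h]] <- ad_leaky_relu(t, agg, 0.2)
  }
  ad_cat(t, outs, 2)
}

# full FGCN forward on tape nodes; de/psd are (n, 5, B) nodes
.fgcn_forward_node <- function(t, params, de, psd, cfg, training = FALSE,
                               variant = "fgcn", record = NULL) {
  learn_a <- isTRUE(attr(params, "learn_adjacency"))
  pn <- param_fetcher(t, params)
  A_node <- if (learn_a) pn("fgcn_A") else ad_const(t, params$fgcn_A)
  P <- .fgcn_prop_matrix(t, A_node, cfg$n_nodes)
  branch <- function(X, br) {
    H1 <- .gcn_layer_node(
      t, P, X, pn(paste0("fgcn_", br, "_W1")), pn(paste0("fgcn_", br, "_b1"))
    )
    H1d <- ad_dropout(t, H1, cfg$dropout_gcn, training)
    H2 <- .gcn_layer_node(
      t, P, H1d, pn(paste0("fgcn_", br, "_W2")), pn(paste0("fgcn_", br, "_b2"))
    )
    H2d <- ad_dropout(t, H2, cfg$dropout_gcn, training)
    list(H1 = H1d, H2 = H2d, skip = ad_cat(t, list(X, H1d, H2d), 2))
  }
  bde <- branch(de, "de")
  bpsd <- branch(psd, "psd")
  if (identical(variant, "gcn")) {
    # plain two-layer GCN baseline: layer-2 outputs only, no skip, no GAT
    out <- ad_cat(t, list(bde$H2, bpsd$H2), 2)
    return(list(embedding = out, branch_width = dim(bde$H2$value)[2]))
  }
  H <- ad_cat(t, list(bde$skip, bpsd$skip), 2) # (n, 60, B)
  emb <- .gat_node(t, H, pn, cfg$gat_heads, record)
  emb <- ad_dropout(t, emb, cfg$dropout_gat, training)
  list(
    embedding = emb,
    branch_width = dim(bde$skip$value)[2],
    gat_in_width = dim(H$value)[2]
  )
}

#' One graph-convolution layer (numeric interface)
#'
#' `ReLU(D^-1/2 (A + I) D^-1/2 H W + b)` with the degree matrix recomputed
#' from `A` (clamped non-negative).
#'
#' @param H node features: `n x d` matrix or `n x d x B` array
#' @param A `n x n` adjacency (without self-loops)
#' @param W `d x d_out` weight matrix
#' @param b length-`d_out` bias (default zeros)
#' @return propagated features with the same batch shape as `H`
#' @export
gcn_layer <- function(H, A, W, b = rep(0, ncol(W))) {
  single <- length(dim(H)) == 2L
  if (single) H <- array(H, c(dim(H), 1L))
  t <- ad_tape()
  P <- .fgcn_prop_matrix(t, ad_const(t, A), nrow(A))
  out <- .gcn_layer_node(t, P, ad_const(t, H), ad_const(t, W), ad_const(t, b))
  v <- out$value
  if (single) v <- v[, , 1]
  v
}

#' One multi-head graph-attention layer (numeric interface)
#'
#' Additive attention over the fully connected node set (self-loops
#' included): `e_ij = LeakyReLU(a1' W h_i + a2' W h_j)`, softmax over `j`,
#' `h_i' = LeakyReLU(sum_j alpha_ij W h_j)`, heads concatenated.
#'
#' @param H `n x d` matrix or `n x d x B` array of node features
#' @param W_list list of per-head `d x d_head` weight matrices
#' @param a1_list,a2_list lists of per-head `d_head x 1` attention vectors
#' @param return_attention also return the attention matrices
#' @return attended features (and optionally a list of `n x n` attention
#'   matrices, rows summing to one)
#' @export
gat_layer <- function(H, W_list, a1_list, a2_list, return_attention = FALSE) {
  single <- length(dim(H)) == 2L
  if (single) H <- array(H, c(dim(H), 1L))
  heads <- length(W_list)
  params <- list()
  for (h in seq_len(heads)) {
    params[[paste0("fgcn_gat_W", h)]] <- W_list[[h]]
    params[[paste0("fgcn_gat_a1_", h)]] <- a1_list[[h]]
    params[[paste0("fgcn_gat_a2_", h)]] <- a2_list[[h]]
  }
  t <- ad_tape()
  rec <- if (return_attention) new.env(parent = emptyenv()) else NULL
  out <- .gat_node(t, ad_const(t, H), param_fetcher(t, params, constant = TRUE), heads, rec)
  v <- out$value
  if (single) v <- v[, , 1]
  if (!return_attention) {
    return(v)
  }
  n <- dim(H)[1]
  B <- dim(H)[3]
  att <- lapply(seq_len(heads), function(h) {
    a <- aperm(array(rec[[paste0("gat_alpha_", h)]], c(n, B, n)), c(1, 3, 2))
    if (single) a[, , 1] else a
  })
  list(output = v, attention = att)
}

#' FGCN forward pass (numeric interface)
#'
#' @param eeg_de,eeg_psd `W x n x 5` arrays of band features
#' @param adjacency an [init_adjacency()] object (or a parameter list from a
#'   trained model via `params`)
#' @param cfg an [fgcn_config()]
#' @param params optional explicit parameter list (otherwise drawn under
#'   `seed`)
#' @param seed RNG seed for weight initialization when `params` is missing
#' @return list with `embedding` (`W x n x gat_out`), `branch_width` (the
#'   per-node dimension after skip concatenation) and `gat_in_width`
#' @export
fgcn_forward <- function(eeg_de, eeg_psd, adjacency, cfg = fgcn_config(),
                         params = NULL, seed = 1L) {
  stopifnot(dim(eeg_de)[2] == cfg$n_nodes, dim(eeg_de)[3] == cfg$in_dim)
  if (is.null(params)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(seed)
    params <- fgcn_params(cfg, adjacency)
  }
  t <- ad_tape()
  de <- ad_const(t, aperm(eeg_de, c(2, 3, 1)))
  psd <- ad_const(t, aperm(eeg_psd, c(2, 3, 1)))
  res <- .fgcn_forward_node(t, params, de, psd, cfg, training = FALSE)
  list(
    embedding = aperm(res$embedding$value, c(3, 1, 2)),
    branch_width = res$branch_width,
    gat_in_width = res$gat_in_width
  )
}

#' Write / read an adjacency matrix as CSV with a channel-name header
#' @param adjacency an `adjacency` object or plain matrix
#' @param path file path
#' @export
write_adjacency <- function(adjacency, path) {
  A <- if (inherits(adjacency, "adjacency")) adjacency$A else adjacency
  dt <- data.table::as.data.table(A, keep.rownames = "channel")
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  dt <- data.table::fread(path)
  ch <- dt$channel
  A <- as.matrix(dt[, -1])
  rownames(A) <- ch
  A
}
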