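# Dual-path cross-attention fusion across the three views.
#
# Each view is kept as a token sequence (graph nodes for the frequency view,
# pooled time steps for the time views) and linearly projected to a shared
# model width. For every view pair, queries from one view attend over the
# other's tokens and vice versa (scaled dot-product, single head); both
# attended sequences are mean-pooled over tokens. Three pairs give six pooled
# vectors, concatenated in a fixed documented order.

#' CAF configuration
#'
#' @param d_model shared attention width for all views
#' @param scale `"sqrt"` divides attention logits by `sqrt(d_model)` (scaled
#'   dot-product); `"linear"` divides by `d_model`
#' @export
caf_config <- function(d_model = 32L, scale = c("sqrt", "linear")) {
  list(d_model = d_model, scale = match.arg(scale))
}

# fixed view order and pairing; fusion blocks are concatenated in this order
.caf_views <- c("eeg_f", "eeg_t", "fnirs_t")
.caf_pairs <- function(views) {
  all_pairs <- list(
    c("eeg_f", "eeg_t"), c("eeg_f", "fnirs_t"), c("eeg_t", "fnirs_t")
  )
  Filter(function(p) all(p %in% views), all_pairs)
}

# token widths before projection: graph nodes carry the GAT embedding,
# time views carry the 10 pooled feature maps per step
.caf_token_dim <- function(tag, fgcn_cfg) {
  switch(tag,
    eeg_f = fgcn_cfg$gat_out,
    eeg_t = 10L,
    fnirs_t = 10L,
    stop("unknown view tag: ", tag)
  )
}

caf_params <- function(cfg, views, fgcn_cfg = fgcn_config()) {
  p <- list()
  for (v in views) {
    din <- .caf_token_dim(v, fgcn_cfg)
    p[[paste0("caf_proj_", v, "_W")]] <- init_mat(din, cfg$d_model)
    p[[paste0("caf_proj_", v, "_b")]] <- init_vec(cfg$d_model)
  }
  for (pr in .caf_pairs(views)) {
    key <- paste(pr, collapse = ".")
    for (s in c("q1", "k1", "v1", "q2", "k2", "v2")) {
      p[[paste0("caf_", key, "_", s)]] <- init_mat(cfg$d_model, cfg$d_model)
    }
  }
  p
}

# project a view to a token sequence node: input (n_tokens, d_in, B)
.tokenize_node <- function(t, x, tag, getp) {
  W <- getp(paste0("caf_proj_", tag, "_W"))
  b <- getp(paste0("caf_proj_", tag, "_b"))
  ad_add_bias(t, ad_bmm_shared(t, x, W), b, 2)
}

# one attention direction: queries Q (nq, D, B) over keys/values of H
# (nk, D, B); returns the pooled attended vector (D, B)
.attend_node <- function(t, Hq, Hk, Wq, Wk, Wv, cfg, record = NULL,
                         record_key = NULL) {
  D <- cfg$d_model
  Q <- ad_bmm_shared(t, Hq, Wq)
  K <- ad_bmm_shared(t, Hk, Wk)
  V <- ad_bmm_shared(t, Hk, Wv)
  S <- ad_bmm(t, Q, ad_aperm(t, K, c(2, 1, 3))) # (nq, nk, B)
  S <- ad_scale(t, S, 1 / if (cfg$scale == "sqrt") sqrt(D) else D)
  d <- dim(S$value)
  SM <- ad_reshape(t, ad_aperm(t, S, c(1, 3, 2)), c(d[1] * d[3], d[2]))
  alpha <- ad_softmax_rows(t, SM)
  if (!is.null(record)) {
    record[[record_key]] <- aperm(
      array(alpha$value, c(d[1], d[3], d[2])), c(1, 3, 2)
    ) # (nq, nk, B)
  }
  alpha3 <- ad_aperm(t, ad_reshape(t, alpha, c(d[1], d[3], d[2])), c(1, 3, 2))
  att <- ad_bmm(t, alpha3, V) # (nq, D, B)
  dm <- dim(att$value)
  pooled <- ad_colmean(t, ad_reshape(t, att, c(dm[1], dm[2] * dm[3])))
  ad_reshape(t, pooled, c(dm[2], dm[3])) # (D, B)
}

# six-path fusion over available views; tokens is a named list of
# (n_tokens, D, B) nodes; returns (B, n_paths * D) node
.caf_fuse_node <- function(t, tokens, getp, cfg, record = NULL) {
  blocks <- list()
  for (pr in .caf_pairs(names(tokens))) {
    key <- paste(pr, collapse = ".")
    H1 <- tokens[[pr[1]]]
    H2 <- tokens[[pr[2]]]
    g <- function(s) getp(paste0("caf_", key, "_", s))
    # H1 attended by queries from H2, then the symmetric path
    b1 <- .attend_node(
      t, H2, H1, g("q2"), g("k1"), g("v1"), cfg, record,
      paste0("caf_alpha_", key, "_1")
    )
    b2 <- .attend_node(
      t, H1, H2, g("q1"), g("k2"), g("v2"), cfg, record,
      paste0("caf_alpha_", key, "_2")
    )
    blocks <- c(blocks, list(b1, b2))
  }
  ad_t(t, ad_cat(t, blocks, 1)) # (B, n_paths * D)
}

#' Project view features to a token sequence (numeric interface)
#'
#' @param x view features: `B x 62 x d` (frequency view, one token per graph
#'   node) or `B x 10 x 9` pre-flatten map (time views, one token per pooled
#'   step)
#' @param tag one of `"eeg_f"`, `"eeg_t"`, `"fnirs_t"`
#' @param cfg a [caf_config()]
#' @param params optional parameter list; drawn under `seed` otherwise
#' @param seed RNG seed
#' @return `B x n_tokens x d_model` token array
#' @export
tokenize_view <- function(x, tag, cfg = caf_config(), params = NULL, seed = 1L) {
  if (!tag %in% .caf_views) stop("unknown view tag: ", tag)
  if (is.null(params)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(seed)
    params <- caf_params(cfg, .caf_views)
  }
  # to internal (n_tokens, d_in, B): frequency view tokens are dim 2 of x;
  # time-view tokens are the 9 pooled steps (dim 3 of the B x 10 x 9 map)
  xi <- if (tag == "eeg_f") aperm(x, c(2, 3, 1)) else aperm(x, c(3, 2, 1))
  t <- ad_tape()
  getp <- param_fetcher(t, params, constant = TRUE)
  out <- .tokenize_node(t, ad_const(t, xi), tag, getp)
  aperm(out$value, c(3, 1, 2))
}

#' Dual-path cross-attention between two token sequences (numeric interface)
#'
#' Computes `H1' = softmax(Q2 K1^T / sqrt(D)) V1` (queries from `h2` attend
#' over `h1`'s tokens) and the symmetric `H2'`, then mean-pools each over its
#' tokens.
#'
#' @param h1,h2 `B x n_tokens x d_model` token arrays
#' @param cfg a [caf_config()]
#' @param params named list with projection matrices `q1,k1,v1,q2,k2,v2`
#'   (each `d_model x d_model`); drawn under `seed` otherwise
#' @param seed RNG seed
#' @param return_attention also return the two attention arrays
#' @return list with pooled `h1_attended`, `h2_attended` (`B x d_model`) and
#'   optionally `attention` (list of `nq x nk x B` arrays, rows summing to 1)
#' @export
cross_attend <- function(h1, h2, cfg = caf_config(), params = NULL, seed = 1L,
                         return_attention = FALSE) {
  stopifnot(dim(h1)[3] == cfg$d_model, dim(h2)[3] == cfg$d_model)
  if (is.null(params)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(seed)
    params <- stats::setNames(
      lapply(1:6, function(i) init_mat(cfg$d_model, cfg$d_model)),
      c("q1", "k1", "v1", "q2", "k2", "v2")
    )
  }
  t <- ad_tape()
  pc <- function(nm) ad_const(t, params[[nm]])
  H1 <- ad_const(t, aperm(h1, c(2, 3, 1)))
  H2 <- ad_const(t, aperm(h2, c(2, 3, 1)))
  rec <- new.env(parent = emptyenv())
  b1 <- .attend_node(t, H2, H1, pc("q2"), pc("k1"), pc("v1"), cfg, rec, "a1")
  b2 <- .attend_node(t, H1, H2, pc("q1"), pc("k2"), pc("v2"), cfg, rec, "a2")
  out <- list(h1_attended = t(b1$value), h2_attended = t(b2$value))
  if (return_attention) out$attention <- list(rec$a1, rec$a2)
  out
}

#' Six-path fusion of the three views (numeric interface)
#'
#' Pairs `(eeg_f, eeg_t)`, `(eeg_f, fnirs_t)`, `(eeg_t, fnirs_t)` each yield
#' two pooled attended vectors, concatenated in that fixed order.
#'
#' @param tokens named list of `B x n_tokens x d_model` arrays with names
#'   among `eeg_f`, `eeg_t`, `fnirs_t`
#' @param cfg a [caf_config()]
#' @param params optional parameter list; drawn under `seed` otherwise
#' @param seed RNG seed
#' @return `B x (2 * n_pairs * d_model)` fusion matrix
#' @export
caf_fuse <- function(tokens, cfg = caf_config(), params = NULL, seed = 1L) {
  if (length(tokens) < 2L) stop("fusion needs at least two views")
  if (is.null(params)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(seed)
    params <- caf_params(cfg, names(tokens))
  }
  t <- ad_tape()
  getp <- param_fetcher(t, params, constant = TRUE)
  # bypass the (already applied) projection: feed tokens directly
  tk <- lapply(tokens, function(x) ad_const(t, aperm(x, c(2, 3, 1))))
  out <- .caf_fuse_node(t, tk, getp, cfg)
  out$value
}
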