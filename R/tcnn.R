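# Time-domain convolutional branch for the 11 Hz views (22 samples/window).
#
# Spatial-first order (the default): a multi-scale spatial block (one global
# channel kernel plus 3x1 and 5x1 local kernels, 20 maps each, local maps
# collapsed over channels by a max -> 60 maps), pointwise compression,
# a multi-scale temporal block (1x3 / 1x5 / 1x7 kernels, 7 maps each -> 21),
# depthwise-separable temporal convolution (depthwise 1x5, pointwise -> 10),
# 1x5 average pooling with stride 2 (22 -> 9 steps) and a 90 -> 90 fully
# connected map. Every convolution is followed by layer normalization over
# the filter axis and a square activation. The reversed temporal-first order
# swaps the roles of the two multi-scale blocks (temporal block emits 60
# maps over the raw channel grid, spatial block then collapses to 21) with
# identical shapes from the depthwise stage onward.
#
# Internal layout is (time, feature, batch); the user-facing wrappers accept
# (batch, channel, time) arrays.

#' TCNN architecture configuration
#'
#' @param modality `"eeg"` (62 channels) or `"fnirs"` (18 channels)
#' @param order `"sfts"` spatial-first (default) or `"tfss"` temporal-first
#' @param n_time samples per window in the time views
#' @export
tcnn_config <- function(modality = c("eeg", "fnirs"),
                        order = c("sfts", "tfss"), n_time = 22L) {
  modality <- match.arg(modality)
  order <- match.arg(order)
  list(
    modality = modality,
    n_channels = if (modality == "eeg") 62L else 18L,
    order = order,
    n_time = n_time,
    msc_filters = 20L, mtc_filters = 7L,
    pool_k = 5L, pool_stride = 2L,
    embed_dim = 90L
  )
}

# parameter set; names are prefixed so EEG and fNIRS branches coexist
tcnn_params <- function(cfg, prefix = cfg$modality) {
  C <- cfg$n_channels
  p <- list()
  nm <- function(s) paste0("tcnn_", prefix, "_", s)
  if (cfg$order == "sfts") {
    p[[nm("msc_Wg")]] <- init_mat(C, 20)
    p[[nm("msc_W3")]] <- init_mat(3, 20, fan_in = 3)
    p[[nm("msc_W5")]] <- init_mat(5, 20, fan_in = 5)
    p[[nm("msc_b")]] <- init_vec(60)
    p[[nm("ln1_g")]] <- init_vec(60, 1)
    p[[nm("ln1_beta")]] <- init_vec(60)
    p[[nm("dc_W")]] <- init_mat(60, 60)
    p[[nm("dc_b")]] <- init_vec(60)
    p[[nm("ln2_g")]] <- init_vec(60, 1)
    p[[nm("ln2_beta")]] <- init_vec(60)
    for (k in c(3, 5, 7)) {
      p[[nm(paste0("mtc_W", k))]] <- init_mat(60 * k, 7)
    }
    p[[nm("mtc_b")]] <- init_vec(21)
  } else {
    # temporal-first: multi-scale temporal block on the raw channel grid
    for (k in c(3, 5, 7)) {
      p[[nm(paste0("mtcr_W", k))]] <- init_mat(k, 20, fan_in = k)
    }
    p[[nm("mtcr_b")]] <- init_vec(60)
    p[[nm("ln1_g")]] <- init_vec(60, 1)
    p[[nm("ln1_beta")]] <- init_vec(60)
    p[[nm("dc_W")]] <- init_mat(60, 60)
    p[[nm("dc_b")]] <- init_vec(60)
    p[[nm("ln2_g")]] <- init_vec(60, 1)
    p[[nm("ln2_beta")]] <- init_vec(60)
    p[[nm("mscr_Wg")]] <- init_mat(C * 60, 7)
    p[[nm("mscr_W3")]] <- init_mat(3 * 60, 7)
    p[[nm("mscr_W5")]] <- init_mat(5 * 60, 7)
    p[[nm("mscr_b")]] <- init_vec(21)
  }
  p[[nm("ln3_g")]] <- init_vec(21, 1)
  p[[nm("ln3_beta")]] <- init_vec(21)
  p[[nm("dsc_Wd")]] <- init_mat(21, 5, fan_in = 5)
  p[[nm("dsc_bd")]] <- init_vec(21)
  p[[nm("ln4_g")]] <- init_vec(21, 1)
  p[[nm("ln4_beta")]] <- init_vec(21)
  p[[nm("dsc_Wp")]] <- init_mat(21, 10)
  p[[nm("dsc_bp")]] <- init_vec(10)
  p[[nm("ln5_g")]] <- init_vec(10, 1)
  p[[nm("ln5_beta")]] <- init_vec(10)
  p[[nm("fc_W")]] <- init_mat(90, 90)
  p[[nm("fc_b")]] <- init_vec(90)
  p
}

# layer norm over dimension `dim_f` of an array node, with gain/bias;
# the common 3-D case over the filter axis runs in the compiled kernel
.ln_over_dim <- function(t, x, g, b, dim_f) {
  d <- dim(x$value)
  if (length(d) == 3L && dim_f == 2L) {
    return(ad_layernorm_filters(t, x, g, b))
  }
  nd <- length(d)
  perm <- c(seq_len(nd)[-dim_f], dim_f)
  y <- ad_aperm(t, x, perm)
  y <- ad_reshape(t, y, c(prod(d[-dim_f]), d[dim_f]))
  y <- ad_layernorm_rows(t, y)
  y <- ad_mul_bias(t, y, g, 2)
  y <- ad_add_bias(t, y, b, 2)
  y <- ad_reshape(t, y, d[perm])
  ad_aperm(t, y, order(perm))
}

# centred shift offsets for an odd kernel
.offs <- function(k) seq_len(k) - (k + 1L) %/% 2L

# temporal conv: input (T, F, B), kernel 1 x k with `nf` filters mixing all
# F maps (compiled kernel; W rows offset-major)
.mtc_conv <- function(t, x, W, k) {
  ad_conv_time(t, x, W, k)
}

# spatial-first multi-scale block: (T, C, B) -> (T, 60, B)
.msc_block <- function(t, x, getp, nm) {
  g <- ad_bmm_shared(t, x, getp(nm("msc_Wg")))
  xc <- ad_aperm(t, x, c(2, 1, 3)) # (C, T, B) for the local branches
  l3 <- ad_conv_spatial_max(t, xc, getp(nm("msc_W3")), 3L)
  l5 <- ad_conv_spatial_max(t, xc, getp(nm("msc_W5")), 5L)
  z <- ad_cat(t, list(g, l3, l5), 2)
  ad_add_bias(t, z, getp(nm("msc_b")), 2)
}

# temporal-first multi-scale block on the raw grid: (T, C, B) -> (T, C, 60, B)
.mtcr_block <- function(t, x, getp, nm) {
  d <- dim(x$value)
  outs <- lapply(c(3L, 5L, 7L), function(k) {
    W <- getp(nm(paste0("mtcr_W", k)))
    shifts <- lapply(.offs(k), function(o) {
      s <- ad_shift(t, x, 1, o)
      ad_reshape(t, s, c(prod(d), 1L))
    })
    G <- ad_cbind(t, shifts) # (T*C*B, k)
    Z <- ad_mm(t, G, W) # (T*C*B, 20)
    ad_reshape(t, Z, c(d[1], d[2], d[3], 20L)) # (T, C, B, 20)
  })
  z <- ad_cat(t, outs, 4) # (T, C, B, 60)
  z <- ad_aperm(t, z, c(1, 2, 4, 3)) # (T, C, 60, B)
  ad_add_bias(t, z, getp(nm("mtcr_b")), 3)
}

# spatial block after the temporal-first stack: (T, C, 60, B) -> (T, 21, B)
.mscr_block <- function(t, x, getp, nm) {
  d <- dim(x$value) # (T, C, M, B)
  Tt <- d[1]
  C <- d[2]
  M <- d[3]
  B <- d[4]
  xg <- ad_aperm(t, x, c(1, 4, 2, 3)) # (T, B, C, M)
  xg <- ad_reshape(t, xg, c(Tt * B, C * M))
  g <- ad_mm(t, xg, getp(nm("mscr_Wg"))) # (T*B, 7)
  g <- ad_aperm(t, ad_reshape(t, g, c(Tt, B, 7L)), c(1, 3, 2))
  local <- function(k, W) {
    shifts <- lapply(.offs(k), function(o) {
      s <- ad_shift(t, x, 2, o) # shift over channel height
      s <- ad_aperm(t, s, c(1, 2, 4, 3)) # (T, C, B, M)
      ad_reshape(t, s, c(Tt * C * B, M))
    })
    G <- ad_cbind(t, shifts) # (T*C*B, M*k)
    Z <- ad_mm(t, G, W) # (T*C*B, 7)
    Z <- ad_reshape(t, Z, c(Tt, C, B, 7L))
    Z <- ad_aperm(t, Z, c(1, 3, 4, 2)) # (T, B, 7, C)
    Z <- ad_reshape(t, Z, c(Tt * B * 7L, C))
    Z <- ad_rowmax(t, Z)
    Z <- ad_reshape(t, Z, c(Tt, B, 7L))
    ad_aperm(t, Z, c(1, 3, 2))
  }
  l3 <- local(3L, getp(nm("mscr_W3")))
  l5 <- local(5L, getp(nm("mscr_W5")))
  z <- ad_cat(t, list(g, l3, l5), 2) # (T, 21, B)
  ad_add_bias(t, z, getp(nm("mscr_b")), 2)
}

# depthwise 1x5 over time, per-feature kernels: (T, F, B) -> (T, F, B)
.dsc_depthwise <- function(t, x, Wd, bd) {
  ad_add_bias(t, ad_depthwise_time(t, x, Wd), bd, 2)
}

# 1x5 average pooling, stride 2: (T=22, F, B) -> (9, F, B)
.avg_pool <- function(t, x, k = 5L, stride = 2L) {
  d <- dim(x$value)
  n_out <- (d[1] - k) %/% stride + 1L
  starts <- (seq_len(n_out) - 1L) * stride + 1L
  xm <- ad_reshape(t, x, c(d[1], d[2] * d[3]))
  acc <- NULL
  for (o in seq_len(k) - 1L) {
    s <- ad_gather_rows(t, xm, starts + o)
    acc <- if (is.null(acc)) s else ad_add(t, acc, s)
  }
  ad_reshape(t, ad_scale(t, acc, 1 / k), c(n_out, d[2], d[3]))
}

# full TCNN forward on a (T, C, B) node; returns pre-flatten map and
# embedding; `record` (an environment) collects per-stage output dims
.tcnn_forward_node <- function(t, getp, x, cfg, record = NULL) {
  nm <- function(s) paste0("tcnn_", cfg$modality, "_", s)
  tr <- function(stage, node) {
    if (!is.null(record)) record[[stage]] <- dim(node$value)
    node
  }
  lnsq <- function(z, i) {
    z <- .ln_over_dim(t, z, getp(nm(paste0("ln", i, "_g"))),
      getp(nm(paste0("ln", i, "_beta"))),
      dim_f = 2L
    )
    ad_square(t, z)
  }
  if (cfg$order == "sfts") {
    z <- tr("msc", .msc_block(t, x, getp, nm)) # (T, 60, B)
    z <- lnsq(z, 1)
    z <- tr("dc", ad_add_bias(
      t, ad_bmm_shared(t, z, getp(nm("dc_W"))), getp(nm("dc_b")), 2
    ))
    z <- lnsq(z, 2)
    mt <- lapply(c(3L, 5L, 7L), function(k) {
      .mtc_conv(t, z, getp(nm(paste0("mtc_W", k))), k)
    })
    z <- tr("mtc", ad_add_bias(t, ad_cat(t, mt, 2), getp(nm("mtc_b")), 2))
    z <- lnsq(z, 3) # (T, 21, B)
  } else {
    z4 <- .mtcr_block(t, x, getp, nm) # (T, C, 60, B)
    z4 <- .ln_over_dim(t, z4, getp(nm("ln1_g")), getp(nm("ln1_beta")), dim_f = 3L)
    z4 <- ad_square(t, z4)
    d4 <- dim(z4$value)
    zm <- ad_aperm(t, z4, c(1, 2, 4, 3)) # (T, C, B, 60)
    zm <- ad_reshape(t, zm, c(prod(d4[c(1, 2, 4)]), 60L))
    zm <- ad_linear(t, zm, getp(nm("dc_W")), getp(nm("dc_b")))
    zm <- ad_reshape(t, zm, d4[c(1, 2, 4, 3)])
    z4 <- tr("dc", ad_aperm(t, zm, c(1, 2, 4, 3)))
    z4 <- .ln_over_dim(t, z4, getp(nm("ln2_g")), getp(nm("ln2_beta")), dim_f = 3L)
    z4 <- ad_square(t, z4)
    z4 <- tr("mtc", z4)
    z <- tr("msc", .mscr_block(t, z4, getp, nm)) # (T, 21, B)
    z <- lnsq(z, 3)
  }
  z <- tr("dsc_depthwise", .dsc_depthwise(t, z, getp(nm("dsc_Wd")), getp(nm("dsc_bd"))))
  z <- lnsq(z, 4)
  z <- tr("dsc_pointwise", ad_add_bias(
    t, ad_bmm_shared(t, z, getp(nm("dsc_Wp"))), getp(nm("dsc_bp")), 2
  ))
  z <- lnsq(z, 5) # (T, 10, B)
  map <- tr("pool", .avg_pool(t, z, cfg$pool_k, cfg$pool_stride)) # (9, 10, B)
  d <- dim(map$value)
  flat <- ad_reshape(t, map, c(d[1] * d[2], d[3])) # (90, B)
  emb <- tr("fc", ad_linear(t, ad_t(t, flat), getp(nm("fc_W")), getp(nm("fc_b"))))
  list(map = map, embedding = emb)
}

#' Multi-scale spatial convolution block (numeric interface)
#'
#' One global channel kernel plus 3x1 and 5x1 local kernels (20 maps each,
#' local maps collapsed over channels by a max), concatenated to 60 feature
#' maps over the 22 time steps, then layer norm and square activation.
#'
#' @param x `B x C x T` array (C = 62 for EEG, 18 for fNIRS)
#' @param cfg a [tcnn_config()]
#' @param params optional parameter list; drawn under `seed` otherwise
#' @param seed RNG seed for weight initialization
#' @return `B x 60 x T` array
#' @export
msc_forward <- function(x, cfg = tcnn_config("eeg"), params = NULL, seed = 1L) {
  C <- dim(x)[2]
  if (C != cfg$n_channels) {
    stop("input has ", C, " channels but config expects ", cfg$n_channels)
  }
  if (is.null(params)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(seed)
    params <- tcnn_params(cfg)
  }
  t <- ad_tape()
  getp <- param_fetcher(t, params, constant = TRUE)
  nm <- function(s) paste0("tcnn_", cfg$modality, "_", s)
  xin <- ad_const(t, aperm(x, c(3, 2, 1))) # (T, C, B)
  z <- .msc_block(t, xin, getp, nm)
  z <- .ln_over_dim(t, z, getp(nm("ln1_g")), getp(nm("ln1_beta")), dim_f = 2L)
  z <- ad_square(t, z)
  aperm(z$value, c(3, 2, 1))
}

#' TCNN forward pass (numeric interface)
#'
#' @param x `B x C x T` array of a time view
#' @param trace also return the per-stage output dimensions (internal
#'   layout is time x features x batch; the trace reports batch-first)
#' @inheritParams msc_forward
#' @return list with `embedding` (`B x 90`), `map` (`B x 10 x 9`, the
#'   pre-flatten pooled feature map used for fusion tokenization) and,
#'   with `trace = TRUE`, `trace`: a named list of stage output dims
#' @export
tcnn_forward <- function(x, cfg = tcnn_config("eeg"), params = NULL, seed = 1L,
                         trace = FALSE) {
  C <- dim(x)[2]
  if (C != cfg$n_channels) {
    stop("input has ", C, " channels but config expects ", cfg$n_channels)
  }
  if (is.null(params)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(seed)
    params <- tcnn_params(cfg)
  }
  t <- ad_tape()
  getp <- param_fetcher(t, params, constant = TRUE)
  rec <- if (trace) new.env(parent = emptyenv()) else NULL
  res <- .tcnn_forward_node(t, getp, ad_const(t, aperm(x, c(3, 2, 1))), cfg, rec)
  out <- list(
    embedding = res$embedding$value,
    map = aperm(res$map$value, c(3, 2, 1))
  )
  if (trace) {
    tr <- as.list(rec)
    # report batch-first: internal (T, F, B) or (T, C, F, B) -> B last-first
    out$trace <- lapply(tr, function(d) {
      if (length(d) == 2L) d else rev(d)
    })
  }
  out
}
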