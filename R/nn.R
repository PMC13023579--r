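# Parameter initialization and the AdamW optimizer.

# memoized node fetcher: each named parameter becomes exactly one tape node
# per forward pass (repeated fetches must not shadow earlier gradient ids)
param_fetcher <- function(t, params, constant = FALSE) {
  cache <- new.env(parent = emptyenv())
  function(nm) {
    nd <- cache[[nm]]
    if (is.null(nd)) {
      v <- params[[nm]]
      if (is.null(v)) stop("unknown parameter: ", nm)
      nd <- if (constant) ad_const(t, v) else ad_param(t, v, nm)
      cache[[nm]] <- nd
    }
    nd
  }
}

# fan-in uniform initialization (the usual default for linear/conv layers)
init_mat <- function(nr, nc, fan_in = nr) {
  lim <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

init_vec <- function(n, val = 0) rep(val, n)

#' Initialize AdamW optimizer state
#' @param params named list of numeric parameters
#' @return optimizer state for [adamw_step()]
#' @export
adamw_init <- function(params) {
  list(
    step = 0L,
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0)
  )
}

#' One AdamW update
#'
#' Decoupled weight decay as in the AdamW formulation; decay is skipped for
#' biases and normalization gains (names ending in `_b`, `_g` or `_beta`).
#'
#' @param state from [adamw_init()]
#' @param params named list of parameters
#' @param grads named list of gradients (same names)
#' @param lr learning rate
#' @param beta1,beta2,eps Adam moment coefficients
#' @param weight_decay decoupled decay coefficient
#' @param frozen names of parameters excluded from the update (e.g. a fixed,
#'   non-learnable adjacency)
#' @return list with updated `params` and `state`
#' @export
adamw_step <- function(state, params, grads, lr = 1e-3,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 0.01, frozen = character(0)) {
  state$step <- state$step + 1L
  c1 <- 1 - beta1^state$step
  c2 <- 1 - beta2^state$step
  for (nm in setdiff(names(params), frozen)) {
    g <- grads[[nm]]
    if (is.null(g) || length(g) == 1L && length(params[[nm]]) > 1L) {
      g <- params[[nm]] * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
    if (!grepl("(_b|_g|_beta)$", nm)) {
      upd <- upd + weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}
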