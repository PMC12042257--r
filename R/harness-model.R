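# Smoke-scale encoder-decoder: forward pass, hand-derived backward pass,
# Adam training loop and greedy decoding, all in base R matrix code. The
# purpose is to prove the corruption objectives are learnable and to back
# the parameter audit with an instantiated model, not to train at scale.

# -- primitives -------------------------------------------------------------

gelu <- function(u) u * stats::pnorm(u)
gelu_grad <- function(u) stats::pnorm(u) + u * stats::dnorm(u)

rmsnorm_fwd <- function(x, w, eps = 1e-6) {
  inv <- 1 / sqrt(rowMeans(x^2) + eps)
  xn <- x * inv
  y <- xn * rep(w, each = nrow(x))
  list(y = y, cache = list(x = x, inv = inv, w = w))
}

rmsnorm_bwd <- function(dy, cache) {
  x <- cache$x; inv <- cache$inv; w <- cache$w
  n <- nrow(x); d <- ncol(x)
  dxn <- dy * rep(w, each = n)
  dw <- colSums(dy * (x * inv))
  s <- rowSums(dxn * x)
  dx <- dxn * inv - x * (s * inv^3 / d)
  list(dx = dx, dw = dw)
}

softmax_rows <- function(s) {
  m <- apply(s, 1, max)
  e <- exp(s - m)
  e / rowSums(e)
}

# T5-style relative position bucketing; returns 1-based bucket matrix
# (queries x keys)
relpos_buckets <- function(n_q, n_k, bidirectional, num_buckets,
                           max_distance = 128) {
  rel <- outer(seq_len(n_q), seq_len(n_k), function(i, j) j - i)
  if (bidirectional) {
    nb <- num_buckets %/% 2L
    ret <- ifelse(rel > 0, nb, 0L)
    arel <- abs(rel)
  } else {
    nb <- num_buckets
    ret <- 0L
    arel <- pmax(-rel, 0L)
  }
  max_exact <- nb %/% 2L
  safe <- pmax(arel, 1)
  large <- max_exact + floor(
    log(safe / max_exact) / log(max_distance / max_exact) * (nb - max_exact))
  large <- pmin(large, nb - 1L)
  matrix(ret + ifelse(arel < max_exact, arel, large) + 1L, n_q, n_k)
}

# bias array (n_q x n_k x heads) gathered from a bucket table
relpos_bias <- function(table, buckets) {
  H <- ncol(table)
  n_q <- nrow(buckets); n_k <- ncol(buckets)
  array(table[as.vector(buckets), ], dim = c(n_q, n_k, H))
}

attn_fwd <- function(xq, xkv, p, n_heads, head_dim, bias = NULL, mask = NULL) {
  Q <- xq %*% p$wq; K <- xkv %*% p$wk; V <- xkv %*% p$wv
  n <- nrow(xq); m <- nrow(xkv)
  O <- matrix(0, n, n_heads * head_dim)
  A_list <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- (h - 1L) * head_dim + seq_len(head_dim)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) /
      sqrt(head_dim)
    if (!is.null(bias)) S <- S + bias[, , h]
    if (!is.null(mask)) S[!mask] <- -1e9
    A <- softmax_rows(S)
    A_list[[h]] <- A
    O[, idx] <- A %*% V[, idx, drop = FALSE]
  }
  out <- O %*% p$wo
  list(out = out,
       cache = list(xq = xq, xkv = xkv, Q = Q, K = K, V = V, O = O,
                    A = A_list, p = p, n_heads = n_heads,
                    head_dim = head_dim, has_bias = !is.null(bias)))
}

attn_bwd <- function(dout, cache) {
  p <- cache$p; H <- cache$n_heads; hd <- cache$head_dim
  dO <- dout %*% t(p$wo)
  dwo <- crossprod(cache$O, dout)
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dV <- matrix(0, nrow(cache$V), ncol(cache$V))
  dbias <- if (cache$has_bias) {
    array(0, dim = c(nrow(cache$Q), nrow(cache$K), H))
  }
  for (h in seq_len(H)) {
    idx <- (h - 1L) * hd + seq_len(hd)
    A <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    dA <- tcrossprod(dOh, cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))
    if (cache$has_bias) dbias[, , h] <- dS
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(hd)
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) / sqrt(hd)
  }
  list(
    dxq = dQ %*% t(p$wq),
    dxkv = dK %*% t(p$wk) + dV %*% t(p$wv),
    dp = list(wq = crossprod(cache$xq, dQ), wk = crossprod(cache$xkv, dK),
              wv = crossprod(cache$xkv, dV), wo = dwo),
    dbias = dbias
  )
}

ffn_fwd <- function(x, p, gated) {
  u0 <- x %*% p$wi0
  g <- gelu(u0)
  if (gated) {
    u1 <- x %*% p$wi1
    h <- g * u1
  } else {
    u1 <- NULL
    h <- g
  }
  list(out = h %*% p$wo,
       cache = list(x = x, u0 = u0, u1 = u1, g = g, h = h, p = p,
                    gated = gated))
}

ffn_bwd <- function(dout, cache) {
  p <- cache$p
  dh <- dout %*% t(p$wo)
  dwo <- crossprod(cache$h, dout)
  if (cache$gated) {
    dg <- dh * cache$u1
    du1 <- dh * cache$g
    dwi1 <- crossprod(cache$x, du1)
    dx1 <- du1 %*% t(p$wi1)
  } else {
    dg <- dh
    dwi1 <- NULL
    dx1 <- 0
  }
  du0 <- dg * gelu_grad(cache$u0)
  dwi0 <- crossprod(cache$x, du0)
  dx <- du0 %*% t(p$wi0) + dx1
  dp <- list(wi0 = dwi0, wo = dwo)
  if (cache$gated) dp$wi1 <- dwi1
  list(dx = dx, dp = dp)
}

# -- stacks -----------------------------------------------------------------

encoder_fwd <- function(enc_ids, params, config) {
  x <- params$embed[enc_ids, , drop = FALSE]
  n <- length(enc_ids)
  buckets <- relpos_buckets(n, n, TRUE, config$rel_pos_buckets)
  bias <- relpos_bias(params$enc$relpos, buckets)
  caches <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    p <- params$enc$layers[[l]]
    n1 <- rmsnorm_fwd(x, p$norm1)
    at <- attn_fwd(n1$y, n1$y, p$att, config$n_heads, config$head_dim,
                   bias = bias)
    x <- x + at$out
    n2 <- rmsnorm_fwd(x, p$norm2)
    ff <- ffn_fwd(n2$y, p$ff, config$ffn_gated)
    x <- x + ff$out
    caches[[l]] <- list(n1 = n1$cache, at = at$cache, n2 = n2$cache,
                        ff = ff$cache)
  }
  fn <- rmsnorm_fwd(x, params$enc$final_norm)
  list(h = fn$y, caches = caches, final = fn$cache, buckets = buckets)
}

encoder_bwd <- function(dh, enc_cache, params, config) {
  g <- list(layers = vector("list", config$n_layers))
  fb <- rmsnorm_bwd(dh, enc_cache$final)
  g$final_norm <- fb$dw
  dx <- fb$dx
  drelpos <- matrix(0, config$rel_pos_buckets, config$n_heads)
  bvec <- as.vector(enc_cache$buckets)
  for (l in rev(seq_len(config$n_layers))) {
    cc <- enc_cache$caches[[l]]
    fbk <- ffn_bwd(dx, cc$ff)
    n2b <- rmsnorm_bwd(fbk$dx, cc$n2)
    dx <- dx + n2b$dx
    ab <- attn_bwd(dx, cc$at)
    for (h in seq_len(config$n_heads)) {
      tab <- rowsum(as.vector(ab$dbias[, , h]), bvec)
      drelpos[as.integer(rownames(tab)), h] <-
        drelpos[as.integer(rownames(tab)), h] + tab[, 1]
    }
    n1b <- rmsnorm_bwd(ab$dxq + ab$dxkv, cc$n1)
    dx <- dx + n1b$dx
    g$layers[[l]] <- list(norm1 = n1b$dw, att = ab$dp, norm2 = n2b$dw,
                          ff = fbk$dp)
  }
  g$relpos <- drelpos
  list(grads = g, dembed_rows = dx)
}

decoder_fwd <- function(dec_ids, h_enc, params, config) {
  x <- params$embed[dec_ids, , drop = FALSE]
  n <- length(dec_ids)
  buckets <- relpos_buckets(n, n, FALSE, config$rel_pos_buckets)
  bias <- relpos_bias(params$dec$relpos, buckets)
  causal <- outer(seq_len(n), seq_len(n), ">=")
  caches <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    p <- params$dec$layers[[l]]
    n1 <- rmsnorm_fwd(x, p$norm1)
    sa <- attn_fwd(n1$y, n1$y, p$self, config$n_heads, config$head_dim,
                   bias = bias, mask = causal)
    x <- x + sa$out
    n2 <- rmsnorm_fwd(x, p$norm2)
    ca <- attn_fwd(n2$y, h_enc, p$cross, config$n_heads, config$head_dim)
    x <- x + ca$out
    n3 <- rmsnorm_fwd(x, p$norm3)
    ff <- ffn_fwd(n3$y, p$ff, config$ffn_gated)
    x <- x + ff$out
    caches[[l]] <- list(n1 = n1$cache, sa = sa$cache, n2 = n2$cache,
                        ca = ca$cache, n3 = n3$cache, ff = ff$cache)
  }
  fn <- rmsnorm_fwd(x, params$dec$final_norm)
  list(h = fn$y, caches = caches, final = fn$cache, buckets = buckets)
}

decoder_bwd <- function(dh, dec_cache, params, config) {
  g <- list(layers = vector("list", config$n_layers))
  fb <- rmsnorm_bwd(dh, dec_cache$final)
  g$final_norm <- fb$dw
  dx <- fb$dx
  dh_enc <- 0
  drelpos <- matrix(0, config$rel_pos_buckets, config$n_heads)
  bvec <- as.vector(dec_cache$buckets)
  for (l in rev(seq_len(config$n_layers))) {
    cc <- dec_cache$caches[[l]]
    fbk <- ffn_bwd(dx, cc$ff)
    n3b <- rmsnorm_bwd(fbk$dx, cc$n3)
    dx <- dx + n3b$dx
    cb <- attn_bwd(dx, cc$ca)
    dh_enc <- dh_enc + cb$dxkv
    n2b <- rmsnorm_bwd(cb$dxq, cc$n2)
    dx <- dx + n2b$dx
    sb <- attn_bwd(dx, cc$sa)
    for (h in seq_len(config$n_heads)) {
      tab <- rowsum(as.vector(sb$dbias[, , h]), bvec)
      drelpos[as.integer(rownames(tab)), h] <-
        drelpos[as.integer(rownames(tab)), h] + tab[, 1]
    }
    n1b <- rmsnorm_bwd(sb$dxq + sb$dxkv, cc$n1)
    dx <- dx + n1b$dx
    g$layers[[l]] <- list(norm1 = n1b$dw, self = sb$dp, norm2 = n2b$dw,
                          cross = cb$dp, norm3 = n3b$dw, ff = fbk$dp)
  }
  g$relpos <- drelpos
  list(grads = g, dembed_rows = dx, dh_enc = dh_enc)
}

# teacher-forced cross-entropy for one example; returns loss and the full
# gradient tree (same shape as params)
example_loss_and_grads <- function(params, config, enc_ids, label_ids,
                                   pad_id, want_grads = TRUE) {
  dec_in <- c(pad_id, label_ids[-length(label_ids)])
  enc <- encoder_fwd(enc_ids, params, config)
  dec <- decoder_fwd(dec_in, enc$h, params, config)
  logits <- tcrossprod(dec$h, params$embed)
  mx <- apply(logits, 1, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  n_pos <- length(label_ids)
  picked <- logits[cbind(seq_len(n_pos), label_ids)]
  loss <- mean(lse - picked)
  if (!want_grads) return(list(loss = loss))

  probs <- exp(logits - lse)
  dlogits <- probs
  dlogits[cbind(seq_len(n_pos), label_ids)] <-
    dlogits[cbind(seq_len(n_pos), label_ids)] - 1
  dlogits <- dlogits / n_pos
  dembed <- crossprod(dlogits, dec$h)     # tied output head
  dhdec <- dlogits %*% params$embed
  db <- decoder_bwd(dhdec, dec, params, config)
  eb <- encoder_bwd(db$dh_enc, enc, params, config)
  # embedding rows gathered at input positions
  dembed <- dembed +
    rowsum_into(db$dembed_rows, dec_in, nrow(params$embed)) +
    rowsum_into(eb$dembed_rows, enc_ids, nrow(params$embed))
  grads <- list(embed = dembed,
                enc = eb$grads,
                dec = db$grads)
  list(loss = loss, grads = grads)
}

rowsum_into <- function(rows, ids, n_rows) {
  out <- matrix(0, n_rows, ncol(rows))
  tab <- rowsum(rows, ids)
  out[as.integer(rownames(tab)), ] <- tab
  out
}

# -- flatten / unflatten ----------------------------------------------------

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(vec, skeleton) {
  pos <- 0L
  walk <- function(s) {
    if (is.list(s)) return(lapply(s, walk))
    n <- length(s)
    out <- vec[pos + seq_len(n)]
    pos <<- pos + n
    if (!is.null(dim(s))) dim(out) <- dim(s)
    out
  }
  walk(skeleton)
}

# -- training and decoding --------------------------------------------------

#' Smoke-scale training of the encoder-decoder on corruption examples
#'
#' Full-batch Adam on teacher-forced cross-entropy over a small corpus of
#' corruption examples. This demonstrates that the denoising objectives
#' are learnable (a tiny model memorizes a handful of examples); it is
#' not a route to a production model.
#'
#' @param corpus Non-empty list of `corruption_example`s (or lists with
#'   `input_tokens` / `target_tokens`).
#' @param steps Maximum optimizer steps.
#' @param config An [architecture_config()]; defaults to a tiny 2-layer
#'   model of width 64.
#' @param seed Integer seed for initialization (training itself is
#'   deterministic).
#' @param lr Adam learning rate.
#' @param stop_below Optional loss value at which training stops early.
#' @return Object of class `harness_model`: list with `params`, `config`,
#'   `vocab`, and `loss_trace` (mean corpus loss per completed step).
#' @export
smoke_train <- function(corpus, steps = 500,
                        config = architecture_config(
                          n_layers = 2, n_heads = 4, d_model = 64,
                          d_ff = 128, head_dim = 16),
                        seed = 1, lr = 2e-3, stop_below = NULL) {
  if (length(corpus) == 0) stop("empty training corpus")
  vocab <- build_vocabulary()
  pad_id <- match("<pad>", vocab$tokens)
  examples <- lapply(corpus, function(ex) {
    list(enc = vocab_ids(vocab, ex$input_tokens),
         lab = vocab_ids(vocab, ex$target_tokens))
  })
  params <- init_model(config, seed = seed)
  theta <- flatten_params(params)
  m <- numeric(length(theta)); v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- numeric(0)
  if (steps >= 1) for (step in seq_len(steps)) {
    params <- unflatten_params(theta, params)
    tot_loss <- 0
    gsum <- NULL
    for (ex in examples) {
      r <- example_loss_and_grads(params, config, ex$enc, ex$lab, pad_id)
      tot_loss <- tot_loss + r$loss
      gf <- flatten_params(r$grads)
      gsum <- if (is.null(gsum)) gf else gsum + gf
    }
    grad <- gsum / length(examples)
    loss <- tot_loss / length(examples)
    m <- b1 * m + (1 - b1) * grad
    v <- b2 * v + (1 - b2) * grad^2
    mhat <- m / (1 - b1^step)
    vhat <- v / (1 - b2^step)
    theta <- theta - lr * mhat / (sqrt(vhat) + eps)
    trace <- c(trace, loss)
    if (!is.null(stop_below) && loss < stop_below) break
  }
  structure(
    list(params = unflatten_params(theta, params), config = config,
         vocab = vocab, loss_trace = trace),
    class = "harness_model"
  )
}

#' @export
print.harness_model <- function(x, ...) {
  cat("<harness_model>",
      format(n_param_elements(x$params), big.mark = ","), "parameters,",
      length(x$loss_trace), "training steps",
      if (length(x$loss_trace) > 0) {
        sprintf("(final loss %.4f)", x$loss_trace[length(x$loss_trace)])
      } else "", "\n")
  invisible(x)
}

#' Greedy decoding from a harness model
#'
#' Argmax decoding until `<eos>` is produced or `max_len` tokens are
#' emitted.
#'
#' @param model A [smoke_train()] model.
#' @param input_tokens Character vector of input tokens (all must be in
#'   the vocabulary).
#' @param max_len Maximum generated length.
#' @return Character vector of generated tokens (includes the closing
#'   `<eos>` when produced).
#' @export
greedy_decode <- function(model, input_tokens, max_len = 64) {
  stopifnot(inherits(model, "harness_model"), max_len >= 1)
  vocab <- model$vocab
  enc_ids <- vocab_ids(vocab, input_tokens)
  pad_id <- match("<pad>", vocab$tokens)
  eos_id <- match("<eos>", vocab$tokens)
  enc <- encoder_fwd(enc_ids, model$params, model$config)
  out_ids <- integer(0)
  for (i in seq_len(max_len)) {
    dec_in <- c(pad_id, out_ids)
    dec <- decoder_fwd(dec_in, enc$h, model$params, model$config)
    logits <- tcrossprod(dec$h[nrow(dec$h), , drop = FALSE],
                         model$params$embed)
    nxt <- which.max(logits[1, ])
    out_ids <- c(out_ids, nxt)
    if (nxt == eos_id) break
  }
  vocab$tokens[out_ids]
}
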