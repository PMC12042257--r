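# Architecture accounting and parameter initialization for the
# encoder-decoder harness. The layout follows the T5 family: pre-RMSNorm
# sublayers (weight-only norms), multi-head attention without bias terms,
# a gated two-input feed-forward block, one learned relative-position
# bias table per stack, and an input embedding tied to the output head.

#' Encoder-decoder architecture configuration
#'
#' Defaults reproduce the audited full-scale configuration: 8 encoder and
#' 8 decoder layers, 10 heads of dimension 64, embedding size 640,
#' feed-forward dimension 2048, 203-token vocabulary, gated feed-forward
#' projections, tied embedding. The full-scale training schedule
#' (142,599 steps, effective batch 2,880, learning rate 1.414e-4) is
#' recorded for documentation; only smoke-scale training is executable
#' here.
#'
#' @param n_layers Layers in the encoder and in the decoder (each).
#' @param n_heads Attention heads.
#' @param d_model Embedding / residual width.
#' @param d_ff Feed-forward inner width.
#' @param vocab_size Vocabulary size.
#' @param ffn_gated Use the gated 3-projection feed-forward block?
#' @param head_dim Per-head width; `n_heads * head_dim` must equal
#'   `d_model`.
#' @param rel_pos_buckets Relative-position bias buckets per stack.
#' @return An object of class `architecture_config`.
#' @export
architecture_config <- function(n_layers = 8, n_heads = 10, d_model = 640,
                                d_ff = 2048, vocab_size = 203,
                                ffn_gated = TRUE, head_dim = d_model / n_heads,
                                rel_pos_buckets = 32) {
  stopifnot(n_layers >= 1, n_heads >= 1, d_model >= 1, d_ff >= 1,
            vocab_size >= 4, rel_pos_buckets >= 4,
            rel_pos_buckets %% 2 == 0)
  if (n_heads * head_dim != d_model) {
    stop("n_heads * head_dim must equal d_model")
  }
  structure(
    list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
         d_model = as.integer(d_model), d_ff = as.integer(d_ff),
         vocab_size = as.integer(vocab_size), ffn_gated = isTRUE(ffn_gated),
         head_dim = as.integer(head_dim),
         rel_pos_buckets = as.integer(rel_pos_buckets),
         full_scale_schedule = list(steps = 142599L, batch_size = 2880L,
                                    learning_rate = 1.414e-4)),
    class = "architecture_config"
  )
}

#' @export
print.architecture_config <- function(x, ...) {
  cat(sprintf(
    "<architecture_config> %d+%d layers, %d heads x %d, d_model %d, d_ff %d (%s), vocab %d\n",
    x$n_layers, x$n_layers, x$n_heads, x$head_dim, x$d_model, x$d_ff,
    if (x$ffn_gated) "gated" else "ungated", x$vocab_size))
  cat(sprintf("  learnable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Closed-form learnable-parameter count
#'
#' Sums the shared input embedding (tied to the output head), per-layer
#' attention projections (Q, K, V, O), feed-forward projections (three
#' when gated, two otherwise), weight-only layer norms (two per encoder
#' layer, three per decoder layer, plus one final norm per stack), and
#' one relative-position bias table per stack. Equals an
#' instantiate-and-count over [init_model()] exactly.
#'
#' @param config An [architecture_config()].
#' @return Integer-valued numeric parameter count.
#' @examples
#' count_parameters(architecture_config())
#' @export
count_parameters <- function(config) {
  stopifnot(inherits(config, "architecture_config"))
  d <- config$d_model
  inner <- config$n_heads * config$head_dim
  attn <- 3 * d * inner + inner * d
  ffn <- (if (config$ffn_gated) 3 else 2) * d * config$d_ff
  enc_layer <- attn + ffn + 2 * d
  dec_layer <- 2 * attn + ffn + 3 * d
  config$vocab_size * d +
    config$n_layers * (enc_layer + dec_layer) +
    2 * d +                                   # final norms, both stacks
    2 * config$rel_pos_buckets * config$n_heads
}

# -- parameter initialization ----------------------------------------------

rand_mat <- function(nr, nc, scale) {
  matrix(stats::rnorm(nr * nc, sd = scale), nr, nc)
}

init_attention <- function(d, inner, scale) {
  list(wq = rand_mat(d, inner, scale), wk = rand_mat(d, inner, scale),
       wv = rand_mat(d, inner, scale), wo = rand_mat(inner, d, scale))
}

init_ffn <- function(d, d_ff, gated, scale) {
  f <- list(wi0 = rand_mat(d, d_ff, scale), wo = rand_mat(d_ff, d, scale))
  if (gated) f$wi1 <- rand_mat(d, d_ff, scale)
  f
}

#' Initialize harness model parameters
#'
#' Instantiates every learnable tensor of the architecture as an R
#' matrix/vector; the total element count equals
#' [count_parameters()] exactly.
#'
#' @param config An [architecture_config()].
#' @param seed Optional integer seed for the random initialization.
#' @return Nested list of parameter arrays.
#' @export
init_model <- function(config, seed = NULL) {
  stopifnot(inherits(config, "architecture_config"))
  with_seed(seed, {
    d <- config$d_model
    inner <- config$n_heads * config$head_dim
    scale <- 1 / sqrt(d)
    enc_layers <- lapply(seq_len(config$n_layers), function(i) {
      list(norm1 = rep(1, d),
           att = init_attention(d, inner, scale),
           norm2 = rep(1, d),
           ff = init_ffn(d, config$d_ff, config$ffn_gated, scale))
    })
    dec_layers <- lapply(seq_len(config$n_layers), function(i) {
      list(norm1 = rep(1, d),
           self = init_attention(d, inner, scale),
           norm2 = rep(1, d),
           cross = init_attention(d, inner, scale),
           norm3 = rep(1, d),
           ff = init_ffn(d, config$d_ff, config$ffn_gated, scale))
    })
    list(
      embed = rand_mat(config$vocab_size, d, scale),
      enc = list(layers = enc_layers, final_norm = rep(1, d),
                 relpos = rand_mat(config$rel_pos_buckets, config$n_heads, 0.1)),
      dec = list(layers = dec_layers, final_norm = rep(1, d),
                 relpos = rand_mat(config$rel_pos_buckets, config$n_heads, 0.1))
    )
  })
}

#' Count the elements of an instantiated parameter tree
#'
#' The instantiate-and-count side of the parameter audit: sums the
#' lengths of every array produced by [init_model()].
#'
#' @param params A nested parameter list from [init_model()].
#' @return Total number of scalar parameters.
#' @export
n_param_elements <- function(params) {
  sum(rapply(params, length, how = "unlist"))
}
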