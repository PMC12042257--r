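test_that("closed-form parameter count equals instantiate-and-count", {
  set.seed(90)
  for (i in 1:5) {
    n_heads <- sample(1:4, 1)
    head_dim <- sample(c(2, 4, 8), 1)
    cfg <- architecture_config(
      n_layers = sample(1:3, 1),
      n_heads = n_heads,
      d_model = n_heads * head_dim,
      d_ff = sample(c(16, 32, 64), 1),
      vocab_size = sample(10:300, 1),
      ffn_gated = runif(1) < 0.5,
      head_dim = head_dim,
      rel_pos_buckets = sample(c(8, 16, 32), 1))
    expect_equal(count_parameters(cfg), n_param_elements(init_model(cfg)))
  }
  # tied embedding: doubling the vocabulary adds exactly d_model per token
  a <- architecture_config(vocab_size = 203)
  b <- architecture_config(vocab_size = 406)
  expect_equal(count_parameters(b) - count_parameters(a), 203 * 640)
  expect_error(architecture_config(n_heads = 7, d_model = 64, head_dim = 10),
               "head_dim")
})

test_that("analytic gradients match finite differences", {
  cfg <- architecture_config(n_layers = 1, n_heads = 2, d_model = 8,
                             d_ff = 12, head_dim = 4, rel_pos_buckets = 8)
  params <- init_model(cfg, seed = 91)
  enc_ids <- c(104L, 110L, 120L, 130L, 140L)
  lab_ids <- c(50L, 60L, 3L)
  r <- chemspan:::example_loss_and_grads(params, cfg, enc_ids, lab_ids, 1L)
  theta <- chemspan:::flatten_params(params)
  ga <- chemspan:::flatten_params(r$grads)
  eps <- 1e-5
  set.seed(92)
  idx <- sample(length(theta), 40)
  for (i in idx) {
    bump <- function(h) {
      tp <- theta; tp[i] <- tp[i] + h
      chemspan:::example_loss_and_grads(
        chemspan:::unflatten_params(tp, params), cfg, enc_ids, lab_ids, 1L,
        want_grads = FALSE)$loss
    }
    num <- (bump(eps) - bump(-eps)) / (2 * eps)
    expect_lt(abs(num - ga[i]), 1e-5 + 1e-3 * abs(num))
  }
})

test_that("training reduces the loss and is reproducible", {
  ex <- corrupt_smiles("CCOCCNCCOCC", spans = cbind(start = 2L, length = 3L))
  m1 <- smoke_train(list(ex), steps = 60, seed = 93)
  expect_length(m1$loss_trace, 60)
  first_q <- mean(m1$loss_trace[1:15])
  last_q <- mean(m1$loss_trace[46:60])
  expect_lt(last_q, first_q)
  m2 <- smoke_train(list(ex), steps = 1, seed = 93)
  expect_equal(m2$loss_trace[1], m1$loss_trace[1])
  m0 <- smoke_train(list(ex), steps = 0, seed = 93)
  expect_length(m0$loss_trace, 0)
  expect_error(smoke_train(list(), steps = 1), "empty")
})

test_that("greedy decoding terminates, stays in-vocabulary, and is deterministic", {
  ex <- corrupt_smiles("CCOCC", spans = cbind(start = 1L, length = 2L))
  model <- smoke_train(list(ex), steps = 5, seed = 94)
  one <- greedy_decode(model, ex$input_tokens, max_len = 1)
  expect_length(one, 1)
  out <- greedy_decode(model, ex$input_tokens, max_len = 12)
  expect_lte(length(out), 12)
  expect_true(all(out %in% model$vocab$tokens))
  expect_identical(out, greedy_decode(model, ex$input_tokens, max_len = 12))
  expect_error(greedy_decode(model, c("Span-Mask:", "žž")), "outside")
})
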