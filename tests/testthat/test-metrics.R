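test_that("concordance index matches its definition on edge cases", {
  y <- c(1, 2, 3, 4)
  expect_equal(concordance_index(y, exp(y)), 1.0)
  expect_equal(concordance_index(y, rep(5, 4)), 0.5)
  expect_error(concordance_index(c(2, 2, 2), c(1, 2, 3)), "tied")
  # invariance under strictly monotone transforms of the predictions
  set.seed(60)
  yt <- rnorm(30); yp <- rnorm(30)
  expect_equal(concordance_index(yt, yp),
               concordance_index(yt, tanh(yp) * 3 + 2))
})

test_that("concordance index equals the O(n^2) brute-force oracle", {
  set.seed(61)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    yt <- sample(rnorm(n))
    yp <- yt + rnorm(n, sd = runif(1, 0, 3))
    if (runif(1) < 0.3) yp <- round(yp)      # induce prediction ties
    expect_equal(concordance_index(yt, yp), ci_oracle(yt, yp))
  }
})

test_that("F-max attains its bounds on perfect and uninformative scores", {
  truth <- rbind(c(1, 0, 0), c(0, 1, 1))
  expect_equal(f_max(truth, truth)$f_max, 1.0)
  zero <- f_max(truth, matrix(0, 2, 3))
  expect_equal(zero$f_max, 0.0)
  expect_true(all(zero$sweep$f1 == 0))
  expect_error(f_max(matrix(0, 2, 3), matrix(1, 2, 3)), "no positive")
})

test_that("F-max equals the exhaustive threshold sweep oracle", {
  set.seed(62)
  for (i in 1:100) {
    truth <- matrix(rbinom(20, 1, 0.4), 5, 4)
    if (!any(truth)) truth[1, 1] <- 1
    scores <- matrix(round(runif(20), 2), 5, 4)   # duplicate scores likely
    expect_equal(f_max(truth, scores)$f_max, f_max_oracle(truth, scores))
  }
})

test_that("AUPRC integrates the step curve exactly", {
  truth <- matrix(c(1, 1, 0, 1, 0, 0), 1)
  scores <- matrix(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4), 1)
  # hand-integrated: (1/3)(1) + (1/3)(1) + (1/3)(3/4)
  expect_equal(auprc(truth, scores), 2 / 3 + 1 / 4)
  expect_equal(auprc(truth, truth), 1.0)
  # label-independent scores converge to the positive prevalence
  set.seed(63)
  truth_big <- matrix(rbinom(20000, 1, 0.3), 100)
  scores_big <- matrix(runif(20000), 100)
  expect_lt(abs(auprc(truth_big, scores_big) - 0.3), 0.02)
})

test_that("regression suite reproduces the QSAR validation formulas", {
  y <- c(5.1, 6.3, 4.8, 7.2, 5.9, 6.8, 4.2, 7.9, 5.5, 6.1)
  p <- c(5.4, 6.0, 5.1, 6.9, 6.2, 6.5, 4.6, 7.4, 5.2, 6.4)
  got <- regression_suite(y, p)
  # independent route: stats::cor and a through-origin lm fit
  expect_equal(got$rmse, sqrt(mean((y - p)^2)))
  expect_equal(got$pearson_r, cor(y, p))
  expect_equal(got$r_squared, cor(y, p)^2)
  fit0 <- lm(y ~ 0 + p)
  r02 <- 1 - sum(residuals(fit0)^2) / sum((y - mean(y))^2)
  expect_equal(got$r0_squared, r02)
  expect_equal(got$rm_squared,
               cor(y, p)^2 * (1 - sqrt(max(0, cor(y, p)^2 - r02))))
})

test_that("regression suite honours its identities and bounds", {
  y <- c(1.2, 3.4, 2.2, 5.6, 4.4)
  ident <- regression_suite(y, y)
  expect_equal(ident$rmse, 0)
  expect_equal(ident$r_squared, 1)
  expect_equal(ident$r0_squared, 1)
  expect_equal(ident$rm_squared, 1)
  set.seed(64)
  for (i in 1:25) {
    yt <- rnorm(20); yp <- yt * runif(1, 0.5, 2) + rnorm(20)
    g <- regression_suite(yt, yp)
    expect_lte(g$rm_squared, g$r_squared + 1e-12)
    # permutation invariance
    o <- sample(20)
    expect_equal(regression_suite(yt[o], yp[o])$rm_squared, g$rm_squared)
  }
  expect_error(regression_suite(rep(1, 5), rnorm(5)), "variance")
})

test_that("adduct-task accuracy canonicalizes and penalizes malformed output", {
  recs <- synth_covalent_records(20, seed = 65)
  refs <- lapply(recs, function(r) build_adduct_example(r)$target_tokens)
  acc <- adduct_task_accuracy(refs, refs)
  expect_equal(acc$adduct_accuracy, 1.0)
  expect_equal(acc$position_accuracy, 1.0)
  bad <- lapply(refs, function(x) c("<P>G", "C"))
  acc0 <- adduct_task_accuracy(bad, refs)
  expect_equal(acc0$adduct_accuracy, 0.0)
  expect_equal(acc0$position_accuracy, 0.0)
  # an atom-order rewrite of the adduct SMILES still counts as correct
  ex <- build_adduct_example(covalent_record("GCG", "CCO", 2, "[*]CC#N"))
  rewritten <- "OC(=O)C(N)CSCC#N"   # same grafted cysteine, different atom order
  expect_false(identical(rewritten, ex$grafted_smiles))
  pred <- c("<P>G", "<extra_id_99>",
            as.character(tokenize(rewritten, "smiles")),
            "<extra_id_98>", "<P>G", "<eos>")
  acc1 <- adduct_task_accuracy(list(pred), list(ex$target_tokens))
  expect_equal(acc1$adduct_accuracy, 1.0)
  expect_error(adduct_task_accuracy(refs[1:2], refs[1:3]), "length")
})
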