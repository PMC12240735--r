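test_that("vocabulary holds the 20 amino acids plus the classification token", {
  v <- peptide_vocabulary()
  expect_length(v, 21L)
  expect_equal(v[["[CLS]"]], 0L)
  expect_setequal(names(v), c("[CLS]", amino_acids))
  expect_equal(peptide_vocabulary(), v) # stable mapping
})

test_that("tokenizer prepends [CLS] and is deterministic", {
  tok <- tokenize("HMTEVVRHC")
  expect_equal(dim(tok), c(1L, 10L))
  expect_equal(tok[1, 1], 0L)
  expect_identical(tok, tokenize("HMTEVVRHC"))
  both <- tokenize(c("HMTEVVRHC", "SLLMWITQC"))
  expect_equal(dim(both), c(2L, 10L))
  expect_equal(both[1, ], tok[1, ])
  expect_error(tokenize(c("AAA", "AAAA")), "equal length")
})

test_that("dG prediction is deterministic, batched, and length-checked", {
  m <- new_predictor(encoder_config(), seed = 5L)
  peps <- c("HMTEVVRHC", "SLLMWITQC", "RMFPNAPYL")
  dg1 <- predict_dG(m, peps)
  expect_true(all(is.finite(dg1)))
  expect_identical(dg1, predict_dG(m, peps))
  # batch equals element-wise singles; permutation permutes outputs
  singles <- vapply(peps, function(p) predict_dG(m, p), numeric(1))
  expect_equal(dg1, unname(singles))
  expect_equal(predict_dG(m, rev(peps)), rev(dg1))
  expect_error(predict_dG(m, "AAAA"), "9-mer")
})

test_that("binding probability is the inverse-sigmoid of dG", {
  m <- new_predictor(encoder_config(), seed = 5L)
  m$offset <- 0.7
  peps <- c("HMTEVVRHC", "SLLMWITQC", "RMFPNAPYL")
  dg <- predict_dG(m, peps)
  p <- predict_binding_prob(m, peps)
  expect_equal(p, plogis(-(dg + 0.7)))
  expect_true(all(p > 0 & p < 1))
  # strictly decreasing in dG
  expect_equal(order(p), order(-dg))
  # midpoint and round trip
  expect_equal(mimoscan:::dg_to_prob(-0.7, 0.7), 0.5)
  expect_equal(mimoscan:::prob_to_dg(p, 0.7), dg, tolerance = 1e-9)
})

test_that("ddG is the difference of mutant and parent dG and antisymmetric", {
  m <- new_predictor(encoder_config(), seed = 5L)
  muts <- enumerate_single_mutants("HMTEVVRHC")
  preds <- predict_ddg(m, muts)
  expect_equal(nrow(preds), 171L)
  dg_parent <- predict_dG(m, "HMTEVVRHC")
  dg_mut <- predict_dG(m, preds$sequence[1])
  expect_equal(preds$ddg_pred[1], dg_mut - dg_parent)
  # reversing the substitution under the same state negates ddG
  fwd <- predict_ddg(m, "V5I", parent = "HMTEVVRHC")
  rev_code <- "I5V"
  bwd <- predict_ddg(m, rev_code, parent = fwd$sequence)
  expect_equal(fwd$ddg_pred, -bwd$ddg_pred, tolerance = 1e-12)
})

test_that("mutant matrix has the heatmap layout with blank wild-type cells", {
  m <- new_predictor(encoder_config(), seed = 5L)
  preds <- predict_ddg(m, enumerate_single_mutants("HMTEVVRHC"))
  mat <- mutant_matrix(preds)
  expect_equal(dim(mat), c(20L, 9L))
  expect_equal(sum(is.na(mat)), 9L) # one wild-type cell per position
  wt <- strsplit("HMTEVVRHC", "")[[1]]
  expect_true(all(is.na(mat[cbind(wt, 1:9)])))
  expect_equal(mat["I", "5"], preds$ddg_pred[preds$code == "V5I"])
})

test_that("checkpoints round-trip through JSON", {
  m <- new_predictor(encoder_config(), seed = 11L)
  m$offset <- -0.25
  path <- tempfile(fileext = ".json")
  write_checkpoint(m, path)
  m2 <- read_checkpoint(path)
  peps <- c("HMTEVVRHC", "SLLMWITQC")
  expect_equal(predict_dG(m2, peps), predict_dG(m, peps), tolerance = 1e-12)
  expect_equal(m2$offset, m$offset)
  expect_equal(m2$config, m$config)
})

test_that("analytic gradients match central finite differences", {
  cfg <- encoder_config(embed_dim = 8L, heads = 2L, layers = 2L,
                        max_length = 5L, ffn_dim = 12L)
  model <- new_predictor(cfg, seed = 42L)
  tok <- tokenize(c("ACDEF", "GHIKL", "MNPQR", "WYVTS"))
  y <- c(1, 0)        # BCE rows
  targets <- c(0.5, 2) # MSE rows

  loss_fn <- function(theta) {
    m <- mimoscan:::unflatten_params(model, theta)
    dg <- mimoscan:::.nn_core(m$params, tok, cfg$heads, numeric(0), FALSE)$dg
    b <- mimoscan:::bce_pieces(dg[1:2], m$offset, y)
    ms <- mimoscan:::mse_pieces(dg[3:4], targets)
    b$loss + 0.3 * ms$loss
  }
  theta <- mimoscan:::flatten_params(model)
  out <- mimoscan:::.nn_step_flat(theta, model$params$pe, tok, cfg$heads,
                                  cfg$layers, cfg$ffn_dim, 21L, y, targets,
                                  0.3)
  ga <- out$grad
  h <- 1e-6
  set.seed(1)
  idx <- sort(sample(length(theta), 80))
  gn <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (loss_fn(tp) - loss_fn(tm)) / (2 * h)
  }, numeric(1))
  denom <- pmax(abs(gn) + abs(ga[idx]), 1e-4)
  expect_lt(max(abs(gn - ga[idx]) / denom), 1e-4)
  # the last two entries are the head bias and the binary offset
  for (i in (length(theta) - 1L):length(theta)) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    expect_equal(ga[i], (loss_fn(tp) - loss_fn(tm)) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("flat and list parameter paths agree exactly", {
  cfg <- encoder_config(embed_dim = 8L, heads = 2L, layers = 2L,
                        max_length = 5L, ffn_dim = 12L)
  m <- new_predictor(cfg, seed = 42L)
  tok <- tokenize(c("ACDEF", "GHIKL", "MNPQR", "WYVTS"))
  y <- c(1, 0)
  targets <- c(-1.5, 2.2)
  theta <- mimoscan:::flatten_params(m)
  out <- mimoscan:::.nn_step_flat(theta, m$params$pe, tok, cfg$heads,
                                  cfg$layers, cfg$ffn_dim, 21L, y, targets,
                                  0.7)
  dg <- mimoscan:::.nn_core(m$params, tok, cfg$heads, numeric(0), FALSE)$dg
  expect_equal(out$dg, dg, tolerance = 1e-14)
  b <- mimoscan:::bce_pieces(dg[1:2], m$offset, y)
  ms <- mimoscan:::mse_pieces(dg[3:4], targets)
  ref <- mimoscan:::.nn_core(m$params, tok, cfg$heads,
                             c(b$g_dg, 0.7 * ms$g_dg), TRUE)
  gref <- mimoscan:::flatten_grads(ref$grads, b$g_offset, m)
  expect_equal(out$grad, gref, tolerance = 1e-14)
  expect_equal(out$loss_bce, b$loss)
  expect_equal(out$loss_mse, ms$loss)
})
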