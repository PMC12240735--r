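test_that("dual loss is the k-weighted sum and rejects negative input", {
  expect_equal(dual_loss(0.3, 0.2, 1), 0.5)
  expect_equal(dual_loss(0.4, 123, 0), 0.4)
  expect_equal(dual_loss(0, 0.25, 0.8), 0.2)
  expect_error(dual_loss(-0.1, 0.2, 1), "non-negative")
})

test_that("k updates to the BCE/MSE ratio, never decreases, and clamps", {
  expect_equal(update_k(1e-4, 0.5, 0.5), 1)          # ratio 1
  expect_equal(update_k(1, 0.2, 0.4), 1)             # ratio below k: keep
  expect_equal(update_k(1e-4, 1.0, 0.1), 1)          # ratio 10 clamps to 1
  expect_equal(update_k(1e-4, 0.001, 10), 1e-4)      # tiny ratio floors
  expect_equal(update_k(0.3, 0, 1), 0.3)             # zero BCE keeps k
  expect_equal(update_k(0.3, 1, 0), 0.3)             # degenerate MSE: unchanged
  # monotone under any admissible input
  set.seed(2)
  k <- 1e-4
  for (i in 1:50) {
    k2 <- update_k(k, runif(1, 0, 2), runif(1, 0.01, 2))
    expect_gte(k2, k)
    expect_lte(k2, 1)
    k <- k2
  }
})

test_that("binary records with conflicting labels are rejected", {
  bad <- tibble::tibble(sequence = c("HMTEVVRHC", "HMTEVVRHC"),
                        label = c(0L, 1L))
  expect_error(pretrain(bad), "conflicting")
  # consistent duplicates collapse silently
  ok <- mimoscan:::validate_binary(
    tibble::tibble(sequence = c("HMTEVVRHC", "HMTEVVRHC", "SLLMWITQC"),
                   label = c(1L, 1L, 0L))
  )
  expect_equal(nrow(ok), 2L)
  expect_error(pretrain(tibble::tibble(sequence = "HMTEVVRHC", label = 1L)),
               "per class|folds")
})

test_that("pretraining separates a noiseless synthetic task", {
  cfg <- quick_generator(label_noise = 0, n_binary = 4000L)
  ls <- generate_landscape(cfg)
  binary <- generate_binary_dataset(ls, cfg)
  # separable with a margin: drop peptides whose energy sits within
  # 0.75 kcal/mol of the binder threshold so the two classes are
  # genuinely distinguishable, then the model must rank them apart
  dg <- mimoscan:::landscape_dg(ls, binary$sequence)
  binary <- binary[abs(dg - attr(binary, "threshold")) > 0.75, ]
  model <- pretrain(binary, quick_train(max_epochs = 80L, patience = 10L),
                    encoder_config())
  expect_true(model$trained)
  expect_gt(max(model$history$val_auc), 0.95)
  # folds partition the data evenly
  folds <- model$folds
  expect_length(folds, nrow(binary))
  sizes <- table(folds)
  expect_lte(diff(range(sizes)), 1)
})

test_that("pretraining is reproducible under a fixed seed", {
  fx <- shared_fixture()
  small <- fx$binary[1:300, ]
  tc <- quick_train(max_epochs = 4L)
  m1 <- pretrain(small, tc)
  m2 <- pretrain(small, tc)
  expect_identical(mimoscan:::flatten_params(m1),
                   mimoscan:::flatten_params(m2))
  expect_equal(m1$history, m2$history)
})

test_that("an untrained model scores at chance on random labels", {
  m <- new_predictor(encoder_config(), seed = 99L)
  set.seed(21)
  peps <- vapply(1:400, function(i) random_peptide(), character(1))
  labels <- rep(c(0L, 1L), 200)
  expect_equal(auc(-predict_dG(m, peps), labels), 0.5, tolerance = 0.1)
})

test_that("fine-tuning requires free-energy records and tracks k per epoch", {
  fx <- shared_fixture()
  expect_error(finetune(fx$model, fx$binary, NULL), "pretrain")
  expect_error(finetune(fx$model, fx$binary,
                        tibble::tibble(sequence = character(0),
                                       dg = numeric(0))),
               "pretrain")
  truth <- generate_fep_truth(fx$landscape, noise_sd = 0)
  targets <- anchor_ddg(truth[1:20, ], fx$model, fx$cfg$parent)
  ft <- finetune(fx$model, fx$binary, targets, quick_train())
  h <- ft$history[ft$history$stage == "finetune", ]
  expect_equal(nrow(h), 10L)
  # k starts at k_init, never decreases, never exceeds k_max
  expect_equal(h$k[1], 1e-4)
  expect_true(all(diff(h$k) >= 0))
  expect_true(all(h$k >= 1e-4 & h$k <= 1))
  expect_true(all(is.finite(h$loss_mse)))
})

test_that("fine-tuning on the model's own predictions is a fixed point", {
  fx <- shared_fixture()
  muts <- enumerate_single_mutants(fx$cfg$parent)
  seqs <- muts$sequence[seq(1, 171, by = 10)]
  self_targets <- tibble::tibble(sequence = seqs,
                                 dg = predict_dG(fx$model, seqs))
  tc <- quick_train(finetune_epochs = 5L, learning_rate = 2e-4)
  ft <- finetune(fx$model, fx$binary, self_targets, tc)
  h <- ft$history[ft$history$stage == "finetune", ]
  expect_lt(tail(h$loss_mse, 1), 0.02)
  expect_equal(predict_dG(ft, seqs), self_targets$dg, tolerance = 0.25)
})

test_that("anchoring converts relative observations to absolute targets", {
  fx <- shared_fixture()
  obs <- tibble::tibble(code = c("H1A", "V5I"), ddg = c(0.7, -1.2))
  targets <- anchor_ddg(obs, fx$model, fx$cfg$parent)
  anchor <- predict_dG(fx$model, fx$cfg$parent)
  expect_equal(targets$dg, anchor + obs$ddg)
  expect_equal(targets$sequence,
               parse_mutant_code(obs$code, fx$cfg$parent)$sequence)
})

test_that("tidy and glance expose the training history", {
  fx <- shared_fixture()
  h <- tidy(fx$model)
  expect_true(all(c("epoch", "loss_bce", "val_auc") %in% names(h)))
  g <- glance(fx$model)
  expect_equal(g$stage, "pretrained")
  expect_equal(g$epochs, nrow(h))
  expect_error(tidy(new_predictor()), "history")
})
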