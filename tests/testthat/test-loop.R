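# Loop tests run on the shared small fixture with very short fine-tunes:
# they check orchestration contracts, not model quality.
loop_train <- function() quick_train(finetune_epochs = 2L)

test_that("screening respects the budget and never repeats an oracle query", {
  fx <- shared_fixture()
  oracle <- landscape_oracle(fx$landscape)
  pol <- acquisition_policy("DFS", objective_fold_increase = 1e6)
  sc <- run_screen(fx$model, fx$binary, oracle, fx$cfg$parent, pol,
                   budget = 5L, train = loop_train())
  expect_s3_class(sc, "mimoscan_screen")
  expect_equal(nrow(sc$observations), 5L)
  expect_false(anyDuplicated(sc$observations$code) > 0)
  expect_equal(sc$stop_reason, "budget_exhausted")
  # cumulative counts grow by the elected amounts
  expect_equal(sc$history$n_sampled, cumsum(sc$history$n_new))
  # the sampled set grows monotonically across iterations
  expect_true(all(diff(sc$history$n_sampled) > 0))
})

test_that("oracle queries under DFS hit the global unsampled minimum", {
  fx <- shared_fixture()
  oracle <- landscape_oracle(fx$landscape)
  pol <- acquisition_policy("DFS", objective_fold_increase = 1e6)
  sc <- run_screen(fx$model, fx$binary, oracle, fx$cfg$parent, pol,
                   budget = 3L, train = loop_train())
  # brute-force check against each stored prediction snapshot
  muts <- enumerate_single_mutants(fx$cfg$parent)
  preds0 <- predict_ddg(fx$model, muts)
  first <- sc$history$elected[[1]][1]
  expect_equal(first, preds0$code[which.min(preds0$ddg_pred)])
  sampled <- sc$history$elected[[1]]
  preds1 <- sc$history$predictions[[1]]
  pool <- preds1[!preds1$code %in% sampled, ]
  expect_equal(sc$history$elected[[2]][1],
               pool$code[which.min(pool$ddg_pred)])
})

test_that("DFS and DFS+B0 elect identical samples", {
  fx <- shared_fixture()
  oracle <- landscape_oracle(fx$landscape)
  tr <- loop_train()
  sc_dfs <- run_screen(fx$model, fx$binary, oracle, fx$cfg$parent,
                       acquisition_policy("DFS", objective_fold_increase = 1e6),
                       budget = 4L, train = tr)
  sc_b0 <- run_screen(fx$model, fx$binary, oracle, fx$cfg$parent,
                      acquisition_policy("DFS_Bn", breadth = 0L,
                                         objective_fold_increase = 1e6),
                      budget = 4L, train = tr)
  expect_equal(sc_dfs$observations$code, sc_b0$observations$code)
  expect_equal(sc_dfs$observations$ddg, sc_b0$observations$ddg)
})

test_that("screening is reproducible under a fixed configuration", {
  fx <- shared_fixture()
  oracle <- landscape_oracle(fx$landscape)
  pol <- acquisition_policy("DFS", objective_fold_increase = 1e6)
  sc1 <- run_screen(fx$model, fx$binary, oracle, fx$cfg$parent, pol,
                    budget = 3L, train = loop_train())
  sc2 <- run_screen(fx$model, fx$binary, oracle, fx$cfg$parent, pol,
                    budget = 3L, train = loop_train())
  expect_equal(sc1$observations, sc2$observations)
  expect_equal(sc1$history$predictions[[3]], sc2$history$predictions[[3]])
})

test_that("a confirmed objective stops the loop before the budget", {
  fx <- shared_fixture()
  # every substitution improves binding far beyond the 100-fold objective,
  # so the very first oracle observation confirms it
  deep <- fx$landscape
  deep$e[deep$e != 0] <- -5
  deep$noise_sd <- 0
  oracle <- landscape_oracle(deep)
  sc <- run_screen(fx$model, fx$binary, oracle, fx$cfg$parent,
                   acquisition_policy("DFS"), budget = 25L,
                   train = loop_train())
  expect_equal(sc$stop_reason, "objective_met")
  expect_equal(nrow(sc$history), 1L)
  expect_lte(min(sc$observations$ddg), sc$threshold)
  expect_lt(nrow(sc$observations), 25L)
})

test_that("failing oracles are skipped and recorded", {
  fx <- shared_fixture()
  inner <- landscape_oracle(fx$landscape)
  calls <- 0L
  flaky <- function(codes) {
    calls <<- calls + 1L
    if (calls == 2L) stop("simulated FEP failure")
    inner(codes)
  }
  pol <- acquisition_policy("DFS", objective_fold_increase = 1e6)
  expect_warning(
    sc <- run_screen(fx$model, fx$binary, flaky, fx$cfg$parent, pol,
                     budget = 3L, train = loop_train()),
    "skipping"
  )
  expect_equal(nrow(sc$observations), 3L)
  expect_length(sc$failed, 1L)
  expect_false(sc$failed %in% sc$observations$code)
})

test_that("evaluation against truth scores every snapshot", {
  fx <- shared_fixture()
  oracle <- landscape_oracle(fx$landscape)
  pol <- acquisition_policy("DFS", objective_fold_increase = 1e6)
  sc <- run_screen(fx$model, fx$binary, oracle, fx$cfg$parent, pol,
                   budget = 3L, train = loop_train())
  truth <- generate_fep_truth(fx$landscape, noise_sd = 0)
  ev <- evaluate_vs_truth(sc, truth)
  expect_equal(nrow(ev), nrow(sc$history))
  expect_equal(ev$n_samples, sc$history$n_sampled)
  expect_true(all(ev$precision >= 0 & ev$precision <= 1))
  # missing mutants are an input error
  expect_error(evaluate_vs_truth(sc, truth[-1, ]), "missing")
  # a snapshot that predicts the truth exactly scores 1 - exp(-10)
  perfect <- sc
  ideal <- truth[c("code", "ddg_true")]
  names(ideal) <- c("code", "ddg_pred")
  perfect$history$predictions <- lapply(
    perfect$history$predictions, function(p) {
      dplyr::mutate(p, ddg_pred = ideal$ddg_pred[match(code, ideal$code)])
    })
  evp <- evaluate_vs_truth(perfect, truth)
  expect_equal(evp$precision, rep(1 - exp(-10), nrow(evp)), tolerance = 1e-12)
  expect_equal(evp$recall, rep(1 - exp(-10), nrow(evp)), tolerance = 1e-12)
})

test_that("benchmark curves align runs at matched sample counts", {
  toy <- dplyr::bind_rows(
    tibble::tibble(strategy = "A", seed = 1, iteration = 1:3,
                   n_samples = c(1, 2, 3), precision = c(0.1, 0.2, 0.3),
                   recall = c(0.3, 0.2, 0.1), srcc = 0),
    tibble::tibble(strategy = "B", seed = 1, iteration = 1:2,
                   n_samples = c(2, 4), precision = c(0.5, 0.7),
                   recall = c(0.6, 0.8), srcc = 0)
  )
  curves <- benchmark_curves(toy)
  # common grid spans max(first) .. min(last) = 2..3 with LOCF for B
  expect_equal(sort(unique(curves$n_samples)), c(2, 3))
  b3 <- curves$precision[curves$strategy == "B" & curves$n_samples == 3]
  expect_equal(b3, 0.5) # carried forward from n = 2
  a2 <- curves$precision[curves$strategy == "A" & curves$n_samples == 2]
  expect_equal(a2, 0.2)
})

test_that("screen tidiers summarise the campaign", {
  fx <- shared_fixture()
  oracle <- landscape_oracle(fx$landscape)
  pol <- acquisition_policy("DFS", objective_fold_increase = 1e6)
  sc <- run_screen(fx$model, fx$binary, oracle, fx$cfg$parent, pol,
                   budget = 2L, train = loop_train())
  td <- tidy(sc)
  expect_false(any(c("elected", "predictions") %in% names(td)))
  g <- glance(sc)
  expect_equal(g$n_sampled, 2L)
  expect_equal(g$strategy, "DFS")
  expect_equal(g$best_ddg, min(sc$observations$ddg))
})
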