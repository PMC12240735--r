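# Shared fixtures. Everything is generated in code; the one moderately
# expensive object (a small pretrained model) is built once per test run
# and reused across files.

P53_PEPTIDE <- "HMTEVVRHC"

# Desk-scale training settings used throughout the suite: larger
# learning rate and smaller batches than the production defaults so the
# tiny synthetic problems converge in seconds.
quick_train <- function(...) {
  defaults <- list(batch_size = 128L, learning_rate = 2e-3,
                   max_epochs = 30L, patience = 6L, finetune_epochs = 10L,
                   seed = 7L)
  do.call(train_config, utils::modifyList(defaults, list(...)))
}

quick_generator <- function(...) {
  defaults <- list(n_binary = 600L, seed = 7L)
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

# Lazily-built shared fixture: landscape + binary data + pretrained model.
.fixture_env <- new.env(parent = emptyenv())
shared_fixture <- function() {
  if (is.null(.fixture_env$fx)) {
    cfg <- quick_generator()
    ls <- generate_landscape(cfg)
    binary <- generate_binary_dataset(ls, cfg)
    model <- pretrain(binary, quick_train(), encoder_config())
    .fixture_env$fx <- list(cfg = cfg, landscape = ls, binary = binary,
                            model = model)
  }
  .fixture_env$fx
}

random_peptide <- function(n = 9L) {
  paste(sample(amino_acids, n, replace = TRUE), collapse = "")
}
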