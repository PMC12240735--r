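#' Read / write the binary immunogenicity CSV dialect
#'
#' Columns `sequence,label`; the loader validates sequences and labels
#' exactly as [pretrain()] does, so files written by the synthetic
#' generator and user-supplied extracts load identically.
#'
#' @param path CSV file path.
#' @return A binary records tibble.
#' @export
read_binary_csv <- function(path) {
  validate_binary(readr::read_csv(path, show_col_types = FALSE,
                                  col_types = readr::cols(
                                    sequence = readr::col_character(),
                                    label = readr::col_integer()
                                  )))
}

#' @rdname read_binary_csv
#' @param data Binary records tibble.
#' @export
write_binary_csv <- function(data, path) {
  readr::write_csv(data[c("sequence", "label")], path)
  invisible(path)
}

#' Read / write ddG observation CSV
#'
#' Columns `mutant_code, ddg_kcal_mol, sd_kcal_mol, n_replicas,
#' parent_sequence`; the reader validates codes against the parent and
#' returns the package's observation tibble.
#'
#' @param path CSV file path.
#' @return Observation tibble (`code`, `ddg`, `sd`, `n_replicas`,
#'   `source`) with the parent in attribute `"parent"`.
#' @export
read_ddg_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("mutant_code", "ddg_kcal_mol", "parent_sequence")
  if (!all(needed %in% names(raw))) {
    abort(sprintf("ddG CSV needs columns: %s.",
                  paste(needed, collapse = ", ")))
  }
  parent <- unique(raw$parent_sequence)
  if (length(parent) != 1L) abort("ddG CSV mixes parent sequences.")
  parse_mutant_code(raw$mutant_code, parent)
  if (anyDuplicated(raw$mutant_code)) {
    abort("Duplicate mutant codes in ddG CSV.")
  }
  out <- tibble(
    code = raw$mutant_code,
    ddg = raw$ddg_kcal_mol,
    sd = raw$sd_kcal_mol %||% 0,
    n_replicas = as.integer(raw$n_replicas %||% 1L),
    source = "fep_import"
  )
  attr(out, "parent") <- parse_peptide(parent)
  out
}

#' @rdname read_ddg_csv
#' @param observations Observation tibble.
#' @param parent Parent peptide sequence.
#' @export
write_ddg_csv <- function(observations, parent, path) {
  readr::write_csv(tibble(
    mutant_code = observations$code,
    ddg_kcal_mol = observations$ddg,
    sd_kcal_mol = observations$sd,
    n_replicas = observations$n_replicas,
    parent_sequence = parent
  ), path)
  invisible(path)
}

#' Write a training history as JSONL
#'
#' One epoch per line; reread with [read_history_jsonl()].
#'
#' @param history History tibble (see [tidy.mimoscan_predictor()]).
#' @param path Output path.
#' @export
write_history_jsonl <- function(history, path) {
  lines <- vapply(seq_len(nrow(history)), function(i) {
    jsonlite::toJSON(as.list(history[i, ]), auto_unbox = TRUE,
                     digits = NA, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_history_jsonl
#' @export
read_history_jsonl <- function(path) {
  purrr::map_dfr(readLines(path), function(l) {
    rec <- jsonlite::fromJSON(l)
    rec <- lapply(rec, function(v) if (is.null(v)) NA else v)
    as_tibble(rec)
  })
}

#' Materialise a complete synthetic fixture directory
#'
#' Writes everything a screening campaign reads: the binary dataset
#' CSV, the exhaustive surrogate truth table CSV, and a JSON copy of
#' the generator configuration.
#'
#' @param dir Output directory (created if missing).
#' @param config A [generator_config()].
#' @return `dir`, invisibly.
#' @export
simulate_data_dir <- function(dir, config = generator_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ls <- generate_landscape(config)
  binary <- generate_binary_dataset(ls, config)
  truth <- generate_fep_truth(ls)
  write_binary_csv(binary, file.path(dir, "binary.csv"))
  write_ddg_csv(truth, config$parent, file.path(dir, "fep_truth.csv"))
  jsonlite::write_json(
    unclass(config), file.path(dir, "generator_config.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}
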