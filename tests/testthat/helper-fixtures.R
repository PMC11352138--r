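# Shared fixtures, built lazily and memoized across test files.
.fx <- new.env(parent = emptyenv())

fx_model <- function() {
  if (is.null(.fx$model)) .fx$model <- build_synthetic_reference()
  .fx$model
}

fx_db <- function() {
  if (is.null(.fx$db)) .fx$db <- load_allele_db()
  .fx$db
}

fx_panel <- function() {
  if (is.null(.fx$panel)) .fx$panel <- make_eqa_panel(fx_model(), fx_db())
  .fx$panel
}

fx_run_study <- function() {
  if (is.null(.fx$run_study)) {
    .fx$run_study <- run_panel(fx_panel(), fx_model(), fx_db(),
                               mode = "study")
  }
  .fx$run_study
}

# a diploid sample built from explicit haplotype genomic sequences
sample_from_sequences <- function(id, seq1, seq2, model) {
  s <- list(sample_id = id,
            haplotypes = list(
              list(allele = "custom", rhd = seq1, masked_exons = integer()),
              list(allele = "custom", rhd = seq2, masked_exons = integer())),
            truth = c("custom", "custom"),
            control = model$control_sequence, role = "sample")
  class(s) <- "rhd_sample"
  s
}
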