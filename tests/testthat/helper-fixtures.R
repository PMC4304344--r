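# shared small simulation fixtures, built once per test run
fixture_env <- new.env()

small_ref <- function() {
  if (is.null(fixture_env$small_ref)) {
    cfg <- simulation_config(seed = 42L, chrom_length = 60000L,
                             srna_depth = 2e4, pare_depth = 8000,
                             tissues = "leaf")
    fixture_env$small_ref <- build_reference(cfg)
  }
  fixture_env$small_ref
}

# abundance matrix with explicit library design, for screen/candidate tests
design_matrix <- function(values, seqs, tissue = "leaf") {
  stages <- senescence_stages()
  m <- matrix(values, nrow = length(seqs), ncol = 4, byrow = TRUE,
              dimnames = list(seqs, paste0("L", c("Y", "M", "SeE", "SeL"))))
  attr(m, "library_info") <- data.frame(
    library_id = colnames(m), tissue = tissue, stage = stages,
    stringsAsFactors = FALSE)
  m
}
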