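# shared fixtures, all generated in code

small_config <- function(...) {
  args <- list(n_participants = 40, n_features = 120,
               n_resilience_features = 12, n_age_features = 8,
               n_glucuronide_spectra = 6, n_drug_metabolites = 4,
               n_distractor_spectra = 8, seed = 42)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# memoized small world so expensive generation runs once per test session
get_small_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- generate_world(small_config())
    w
  }
})

# minimal hand-built feature table
toy_table <- function(areas, rt = NULL, mz = NULL, sample_ids = NULL,
                      values = "areas") {
  areas <- as.matrix(areas)
  p <- nrow(areas)
  feature_table(
    data.frame(feature_id = sprintf("F%02d", seq_len(p)),
               mz = if (is.null(mz)) seq(200, 300, length.out = p) else mz,
               rt = if (is.null(rt)) rep(5, p) else rt),
    areas,
    sample_ids = if (is.null(sample_ids)) sprintf("S%d", seq_len(ncol(areas)))
                 else sample_ids,
    values = values)
}

# filtered small-world table restricted to study samples (rclr-ready)
ft_keep_samples_for_test <- function(w) {
  tab <- blank_filter(dead_volume_filter(w$table), w$metadata)
  samp <- w$metadata$sample_id[!w$metadata$is_blank]
  resilmet:::ft_keep_samples(tab, samp)
}

toy_metadata <- function(sample_ids, blank = rep(FALSE, length(sample_ids)),
                         age = NULL, participant = NULL) {
  data.frame(sample_id = sample_ids,
             participant_id = if (is.null(participant))
               ifelse(blank, NA, paste0("P", seq_along(sample_ids)))
               else participant,
             visit = 1L,
             age = if (is.null(age)) ifelse(blank, NA, 70) else age,
             is_blank = blank,
             stringsAsFactors = FALSE)
}
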