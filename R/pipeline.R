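#' Run the full analysis pipeline on a synthetic world
#'
#' End-to-end orchestration of the two analysis branches on generated data:
#' simulate; fit the cognition trajectory model and derive resilience
#' scores; condition the feature table (resilience branch); tune and fit the
#' one-component sparse PLS with cross-validation and permutation testing;
#' validate externally on the held-out visit; run the hurdle model and
#' fold-change analysis over the selected features; run the aging-branch
#' per-feature age mixed models; and execute the spectral queries
#' (glucuronide neutral losses and the drug-metabolite discovery chain).
#'
#' @param config a [sim_config()]; its seed drives every stage.
#' @param keep `"auto"` (tuned via [tune_keep()]) or an integer sparsity.
#' @param folds CV folds.
#' @param n_perm permutations for [permutation_test()].
#' @param branch `"both"`, `"resilience"` or `"aging"`.
#' @param out_dir optional directory; when given, stage outputs are written
#'   as CSV/MGF/JSON.
#' @return list of stage outputs plus a `manifest` echoing every parameter.
#' @export
run_pipeline <- function(config = sim_config(), keep = "auto", folds = 10,
                         n_perm = 100, branch = c("both", "resilience", "aging"),
                         out_dir = NULL) {
  branch <- match.arg(branch)
  world <- generate_world(config)
  out <- list(world = world)

  traj <- fit_trajectory(world$records)
  scores <- resilience_scores(traj)
  out$trajectory <- traj
  out$resilience <- scores

  if (branch %in% c("both", "resilience")) {
    prep <- preprocess_spls(world$table, world$metadata)
    out$preprocess <- prep
    X <- t(prep$table$areas)
    y <- scores$resilience[match(prep$selection$participant_id,
                                 scores$participant_id)]
    if (identical(keep, "auto")) {
      tuning <- tune_keep(X, y, folds = folds, seed = config$seed)
      keep_n <- tuning$keep
      out$tuning <- tuning
    } else keep_n <- as.integer(keep)
    fit <- fit_spls1(X, y, keep_n)
    cv <- cross_validate(X, y, keep_n, k = folds, seed = config$seed)
    perm <- permutation_test(X, y, keep_n, n_perm = n_perm, seed = config$seed)
    out$spls <- fit
    out$cv <- cv
    out$permutation <- perm

    # external branch: same features, held-out visit, same transforms
    ext_tab <- ft_keep_samples(prep$filtered_all_visits, prep$external$sample_id)
    ext_tab <- ft_subset(ext_tab, ext_tab$features$feature_id %in%
                           prep$table$features$feature_id)
    ext_tab <- rclr(ext_tab)
    ext_tab <- residualize_covariate(ext_tab, world$metadata, "age")
    y_ext <- scores$resilience[match(prep$external$participant_id,
                                     scores$participant_id)]
    out$external <- external_validate(fit, t(ext_tab$areas), y_ext,
                                      folds = folds, seed = config$seed)

    # association follow-up over the selected features, selected visit only
    sel_tab <- ft_keep_samples(world$table, prep$selection$sample_id)
    sel_tab <- ft_subset(sel_tab, sel_tab$features$feature_id %in% fit$selected)
    res_by_sample <- stats::setNames(y, prep$selection$sample_id)
    out$hurdle <- hurdle(sel_tab, res_by_sample)
    groups <- split_resilience_groups(res_by_sample)
    out$fold_change <- fold_change(sel_tab, groups)
    out$groups <- groups
  }

  if (branch %in% c("both", "aging")) {
    lp <- preprocess_lmm(world$table, world$metadata)
    out$lmm_report <- lp$report
    out$lmm_age <- lmm_age(lp$table, world$metadata,
                           selection_rule = "require_singular")
  }

  # spectral queries against the generated spectrum set
  out$glucuronide_matches <- neutral_loss_query(
    world$spectra, c(176.0321, 194.0425))
  parent_rows <- world$truth$spectrum_labels$label == "parent_drug"
  parents <- drug_parents()
  out$drug_matches <- drug_metabolite_pipeline(
    world$spectra, parents, world$truth$parent_occurrences)

  out$manifest <- list(
    config = unclass(config), seed = config$seed, keep = if (exists("keep_n")) keep_n else NA,
    folds = folds, n_perm = n_perm, branch = branch,
    stage_order = c("simulate", "trajectory", "preprocess", "spls", "cv",
                    "permutation", "external", "hurdle", "fold_change",
                    "lmm_age", "spectra")[
                      c(TRUE, TRUE, rep(branch != "aging", 7),
                        branch != "resilience", TRUE)],
    version = as.character(utils::packageVersion("resilmet")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(world$table, file.path(out_dir, "feature_table.csv"))
    write_metadata(world$metadata, file.path(out_dir, "metadata.csv"))
    write_mgf(world$spectra, file.path(out_dir, "spectra.mgf"))
    write_ground_truth(world$truth, file.path(out_dir, "ground_truth.json"))
    utils::write.csv(scores, file.path(out_dir, "resilience_scores.csv"),
                     row.names = FALSE)
    if (!is.null(out$spls)) {
      per_feature <- data.frame(feature_id = names(out$spls$w),
                                weight = unname(out$spls$w),
                                selected = names(out$spls$w) %in% out$spls$selected,
                                stability = unname(out$cv$stability[names(out$spls$w)]))
      utils::write.csv(per_feature, file.path(out_dir, "spls_features.csv"),
                       row.names = FALSE)
    }
    if (!is.null(out$hurdle))
      utils::write.csv(out$hurdle, file.path(out_dir, "hurdle.csv"),
                       row.names = FALSE)
    if (!is.null(out$lmm_age))
      utils::write.csv(out$lmm_age$results, file.path(out_dir, "lmm_age.csv"),
                       row.names = FALSE)
    jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}
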