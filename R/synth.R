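#' Generate a synthetic longitudinal cognition cohort
#'
#' Draws one composite cognitive z-score per participant per visit from a
#' linear mixed model: fixed intercept, a fixed decline of
#' `population_slope` SD-units per decade after age 70, small sex and
#' education offsets, plus participant-level random intercepts and random
#' slopes and a Gaussian visit residual. The participant's true random slope
#' (SD-units per decade) is the ground-truth resilience the downstream
#' recovery tests target: positive values mean a flatter-than-average
#' trajectory, i.e. more stable cognition.
#'
#' @param config a [sim_config()].
#' @return list with `records` (data.frame: participant_id, visit, age, sex,
#'   education, z_score) and `truth` (list carrying `true_random_slopes`,
#'   a named vector in SD-units per decade, and `true_random_intercepts`).
#'   Reproducible: identical config (including seed) gives identical output.
#' @export
generate_cohort <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_participants
  ids <- sprintf("P%04d", seq_len(n))
  baseline_age <- stats::rnorm(n, config$baseline_age_mean, config$baseline_age_sd)
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.64, 0.36))
  education <- pmin(pmax(round(stats::rnorm(n, 14, 3)), 8), 20)
  b0 <- stats::rnorm(n, 0, config$intercept_sd)
  b1 <- stats::rnorm(n, 0, config$slope_sd)
  names(b0) <- names(b1) <- ids

  rec <- expand.grid(visit = seq_len(config$n_visits), idx = seq_len(n),
                     KEEP.OUT.ATTRS = FALSE)
  rec <- rec[order(rec$idx, rec$visit), ]
  age <- baseline_age[rec$idx] + (rec$visit - 1) * config$visit_spacing
  t_dec <- (age - 70) / 10
  z <- config$population_slope * t_dec +
    config$sex_effect * (sex[rec$idx] == "female") +
    config$education_effect * (education[rec$idx] - 14) +
    b0[rec$idx] + b1[rec$idx] * t_dec +
    stats::rnorm(nrow(rec), 0, config$resid_sd)

  records <- data.frame(
    participant_id = ids[rec$idx],
    visit = rec$visit,
    age = age,
    sex = sex[rec$idx],
    education = education[rec$idx],
    z_score = z,
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  list(records = records,
       truth = list(true_random_slopes = b1, true_random_intercepts = b0))
}

#' Generate a synthetic LC-MS feature table with planted signal
#'
#' Emulates a peak-picked untargeted LC-MS quantification table for the
#' cohort's serum samples plus blank channels. Feature log-abundances are
#' Gaussian around a feature-specific baseline; planted resilience features
#' additionally carry a linear term in the participant's *true* random slope
#' (signed), planted age features a within-person linear term in age. Areas
#' below `detection_limit` are recorded as 0, which induces the informative
#' presence/absence structure the hurdle model targets (left-censoring:
#' low-abundance samples are the ones that go missing). Blank samples sit at
#' `blank_level` except for a small set of contaminant features whose blank
#' signal exceeds their signal in real samples.
#'
#' @param config a [sim_config()].
#' @param cohort output of [generate_cohort()] under the same config.
#' @return list with `table` (a [feature_table()]), `metadata` (sample
#'   metadata data.frame incl. blank rows) and `truth` (the cohort truth
#'   extended with planted feature ids and signs).
#' @export
generate_feature_table <- function(config, cohort) {
  config <- validate_sim_config(config)
  set.seed(config$seed + 1L)
  records <- cohort$records
  truth <- cohort$truth
  p <- config$n_features

  sample_id <- sprintf("%s_V%d", records$participant_id, records$visit)
  metadata <- data.frame(
    sample_id = sample_id,
    participant_id = records$participant_id,
    visit = records$visit,
    age = records$age,
    sex = records$sex,
    education = records$education,
    is_blank = FALSE,
    stringsAsFactors = FALSE
  )
  if (config$n_blanks > 0) {
    metadata <- rbind(metadata, data.frame(
      sample_id = sprintf("BLANK_%02d", seq_len(config$n_blanks)),
      participant_id = NA_character_, visit = NA_integer_, age = NA_real_,
      sex = NA_character_, education = NA_integer_, is_blank = TRUE,
      stringsAsFactors = FALSE
    ))
  }

  feature_id <- sprintf("F%05d", seq_len(p))
  mz <- stats::runif(p, 150, 1500)
  rt <- stats::runif(p, 0.7, 12.5)
  n_early <- round(config$early_rt_frac * p)
  early <- if (n_early > 0) sample.int(p, n_early) else integer(0)
  rt[early] <- stats::runif(n_early, 0.05, 0.69)

  late <- setdiff(seq_len(p), early)
  pickable <- sample(late) # shuffled once; planted sets are disjoint slices
  need <- config$n_contaminants + config$n_resilience_features + config$n_age_features
  if (need > length(pickable))
    stop("not enough late-eluting features to plant contaminants and signals; ",
         "increase n_features or lower early_rt_frac")
  contam <- sort(pickable[seq_len(config$n_contaminants)])
  res_idx <- sort(pickable[config$n_contaminants + seq_len(config$n_resilience_features)])
  age_idx <- sort(pickable[config$n_contaminants + config$n_resilience_features +
                             seq_len(config$n_age_features)])
  # glucuronide-bearing spectra later attach to negative-sign resilience
  # features; keep their precursors away from the low-mass edge
  mz[res_idx] <- stats::runif(length(res_idx), 300, 1200)

  res_signs <- sample(c(-1, 1), length(res_idx), replace = TRUE)
  need_neg <- min(config$n_glucuronide_spectra, length(res_idx)) - sum(res_signs < 0)
  if (need_neg > 0) res_signs[which(res_signs > 0)[seq_len(need_neg)]] <- -1
  age_signs <- sample(c(-1, 1), length(age_idx), replace = TRUE)

  meanlog <- stats::rnorm(p, config$feature_meanlog, config$feature_meanlog_sd)
  meanlog[contam] <- log(config$detection_limit + 1) + 0.5

  n_samp <- nrow(records)
  L <- matrix(stats::rnorm(p * n_samp, 0, config$feature_sigma), p, n_samp) + meanlog
  b1 <- truth$true_random_slopes[records$participant_id]
  if (length(res_idx))
    L[res_idx, ] <- L[res_idx, ] +
      config$effect_size_resilience * outer(res_signs, b1)
  if (length(age_idx))
    L[age_idx, ] <- L[age_idx, ] +
      config$effect_size_age * outer(age_signs, records$age - config$baseline_age_mean)
  areas <- exp(L)

  if (config$n_blanks > 0) {
    B <- matrix(config$blank_level *
                  exp(stats::rnorm(p * config$n_blanks, 0, 0.5)),
                p, config$n_blanks)
    B[contam, ] <- exp(stats::rnorm(length(contam) * config$n_blanks,
                                    log(config$detection_limit + 1) + 2.5, 0.3))
    areas <- cbind(areas, B)
  }
  areas[areas < config$detection_limit] <- 0

  table <- feature_table(
    data.frame(feature_id = feature_id, mz = mz, rt = rt,
               stringsAsFactors = FALSE),
    areas, metadata$sample_id
  )
  truth$resilience_feature_ids <- feature_id[res_idx]
  truth$resilience_signs <- stats::setNames(res_signs, feature_id[res_idx])
  truth$age_feature_ids <- feature_id[age_idx]
  truth$age_signs <- stats::setNames(age_signs, feature_id[age_idx])
  truth$contaminant_ids <- feature_id[contam]
  truth$early_rt_ids <- feature_id[early]
  list(table = table, metadata = metadata, truth = truth)
}

# beta-blocker parents whose metabolites the drug pipeline hunts for:
# [M+H]+ of metoprolol and atenolol, and the four shared fragment ions of
# their common aryloxypropanolamine backbone
drug_parents <- function() {
  data.frame(name = c("metoprolol", "atenolol"),
             mz = c(268.1907, 267.1703),
             rt = c(6.8, 5.6),
             stringsAsFactors = FALSE)
}

#' @rdname generate_spectra
#' @export
backbone_fragments <- function() c(72.0806, 98.0964, 116.1070, 133.0643)

#' Generate synthetic MS/MS spectra with planted query targets
#'
#' Builds a labeled spectrum set on top of a generated feature table:
#' glucuronide conjugates whose spectra contain a fragment at precursor
#' minus 176.0321 Da (half additionally minus 194.0425 Da); two beta-blocker
#' parent drugs (metoprolol- and atenolol-like) carrying the four shared
#' aryloxypropanolamine backbone fragments (m/z 72.0806, 98.0964, 116.1070,
#' 133.0643); drug metabolites that share the backbone fragments, sit at the
#' parent precursor plus a known modification delta mass (glucuronidation,
#' hydroxylation, demethylation or combinations), elute strictly earlier
#' than their parent and occur only in samples where the parent occurs; and
#' distractors that each violate exactly one of those properties (wrong
#' neutral loss, too few backbone fragments, later retention time, or no
#' sample co-occurrence). Fragment m/z carry Gaussian instrument noise of SD
#' `fragment_noise_sd`.
#'
#' @param config a [sim_config()].
#' @param tab output of [generate_feature_table()].
#' @return list with `spectra` (a list of spectrum records: spectrum_id,
#'   feature_id, precursor_mz, rt in minutes, peaks matrix sorted by m/z,
#'   samples) and `truth` extended with `spectrum_labels` (data.frame:
#'   spectrum_id, label, parent, modification, violation).
#' @export
generate_spectra <- function(config, tab) {
  config <- validate_sim_config(config)
  set.seed(config$seed + 2L)
  table <- tab$table
  metadata <- tab$metadata
  truth <- tab$truth
  real_samples <- metadata$sample_id[!metadata$is_blank]
  noise <- function(k) stats::rnorm(k, 0, config$fragment_noise_sd)
  spectra <- list()
  labels <- list()
  sp_n <- 0L
  add_spectrum <- function(feature_id, precursor, rt, frag_mz, samples,
                           label, parent = NA_character_,
                           modification = NA_character_,
                           violation = NA_character_) {
    sp_n <<- sp_n + 1L
    id <- sprintf("SP%04d", sp_n)
    ord <- order(frag_mz)
    peaks <- cbind(mz = frag_mz[ord],
                   intensity = stats::runif(length(frag_mz), 1e3, 1e6)[ord])
    spectra[[id]] <<- list(spectrum_id = id, feature_id = feature_id,
                           precursor_mz = precursor, rt = rt, peaks = peaks,
                           samples = samples)
    labels[[id]] <<- data.frame(spectrum_id = id, label = label,
                                parent = parent, modification = modification,
                                violation = violation, stringsAsFactors = FALSE)
    id
  }
  # filler fragments must stay clear of the diagnostic m/z windows (the
  # glucuronide losses and the backbone ions) so distractors violate exactly
  # the property they are built to violate
  rand_frags <- function(k, precursor) {
    reserved <- c(precursor - c(176.0321, 194.0425), backbone_fragments())
    out <- numeric(k)
    for (i in seq_len(k)) {
      repeat {
        v <- stats::runif(1, 50, max(60, precursor - 20))
        if (all(abs(v - reserved) > 0.05)) break
      }
      out[i] <- v
    }
    out
  }
  occ_of <- function(fid) {
    a <- table$areas[fid, real_samples]
    names(a)[a > 0]
  }

  # glucuronide conjugates, attached to negative-sign resilience features
  # (they accumulate in low-resilience individuals)
  gl_pool <- truth$resilience_feature_ids[truth$resilience_signs < 0]
  gl_pool <- gl_pool[table$features$mz[match(gl_pool, table$features$feature_id)] > 250]
  extra <- setdiff(table$features$feature_id[table$features$mz > 250 &
                                               table$features$rt >= 0.7],
                   c(truth$resilience_feature_ids, truth$age_feature_ids,
                     truth$contaminant_ids))
  gl_ids <- c(gl_pool, sample(extra))[seq_len(min(config$n_glucuronide_spectra,
                                                  length(gl_pool) + length(extra)))]
  for (i in seq_along(gl_ids)) {
    fid <- gl_ids[i]
    row <- match(fid, table$features$feature_id)
    prec <- table$features$mz[row]
    fr <- c(prec - 176.0321 + noise(1),
            if (i %% 2 == 0) prec - 194.0425 + noise(1),
            rand_frags(4, prec))
    add_spectrum(fid, prec, table$features$rt[row], fr, occ_of(fid),
                 label = "glucuronide")
  }

  # parent drugs
  parents <- drug_parents()
  bb <- backbone_fragments()
  parent_occ <- list()
  for (i in seq_len(nrow(parents))) {
    occ <- sample(real_samples, max(2, round(0.3 * length(real_samples))))
    parent_occ[[parents$name[i]]] <- occ
    add_spectrum(NA_character_, parents$mz[i], parents$rt[i],
                 c(bb + noise(4), rand_frags(3, parents$mz[i])),
                 occ, label = "parent_drug", parent = parents$name[i])
  }

  mods <- modification_table()
  mod_cycle <- c("glucuronidation", "hydroxylation", "demethylation",
                 "hydroxylation+glucuronidation", "demethylation+glucuronidation")
  met_spec <- function(kind, violation = NA_character_) {
    # one drug-metabolite-like spectrum; `kind` selects which property breaks
    i <- (sp_n %% nrow(parents)) + 1L
    pname <- parents$name[i]
    mod <- mod_cycle[(sp_n %% length(mod_cycle)) + 1L]
    delta <- mods$delta[match(mod, mods$name)]
    prec <- parents$mz[i] + delta + noise(1)
    rt <- if (kind == "late_rt") parents$rt[i] + stats::runif(1, 0.5, 2.0)
          else parents$rt[i] - stats::runif(1, 0.8, 3.5)
    pocc <- parent_occ[[pname]]
    occ <- if (kind == "no_cooccurrence")
      sample(setdiff(real_samples, pocc), min(5, length(setdiff(real_samples, pocc))))
    else sample(pocc, max(1, round(0.6 * length(pocc))))
    frags <- if (kind == "missing_fragments")
      c(bb[1:2] + noise(2), rand_frags(4, prec))
    else c(bb + noise(4), rand_frags(2, prec))
    add_spectrum(NA_character_, prec, rt, frags, occ,
                 label = if (kind == "metabolite") "drug_metabolite" else "distractor",
                 parent = pname, modification = mod, violation = violation)
  }
  for (k in seq_len(config$n_drug_metabolites)) met_spec("metabolite")

  # distractors: each violates exactly one property
  viol_cycle <- c("wrong_loss", "missing_fragments", "late_rt", "no_cooccurrence")
  for (k in seq_len(config$n_distractor_spectra)) {
    v <- viol_cycle[(k - 1L) %% length(viol_cycle) + 1L]
    if (v == "wrong_loss") {
      fid <- sample(extra, 1)
      row <- match(fid, table$features$feature_id)
      prec <- table$features$mz[row]
      add_spectrum(fid, prec, table$features$rt[row],
                   c(prec - 176.0321 - 0.15 + noise(1), rand_frags(4, prec)),
                   occ_of(fid), label = "distractor", violation = "wrong_loss")
    } else {
      met_spec(v, violation = v)
    }
  }

  truth$spectrum_labels <- do.call(rbind, unname(labels))
  truth$parent_occurrences <- parent_occ
  list(spectra = unname(spectra), truth = truth)
}

#' Generate the complete synthetic world
#'
#' Convenience wrapper running [generate_cohort()],
#' [generate_feature_table()] and [generate_spectra()] under one config.
#'
#' @param config a [sim_config()].
#' @return list: `records`, `table`, `metadata`, `spectra`, `truth`.
#' @examples
#' world <- generate_world(sim_config(n_participants = 20, n_features = 50))
#' world$table
#' @export
generate_world <- function(config = sim_config()) {
  cohort <- generate_cohort(config)
  tab <- generate_feature_table(config, cohort)
  sp <- generate_spectra(config, tab)
  list(records = cohort$records, table = tab$table, metadata = tab$metadata,
       spectra = sp$spectra, truth = sp$truth)
}
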