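#' Synthetic cohort generator configuration
#'
#' Assembles and validates the parameters of the synthetic world the
#' generator emulates: a longitudinal aging cohort (by default 237
#' participants sampled at 3 visits spaced 4 years apart, baseline age
#' centered on 70) whose composite cognitive z-scores decline by 0.7 SD per
#' decade on average, with participant-level random intercepts and slopes;
#' an untargeted LC-MS feature table with zero-inflated log-normal peak
#' areas, planted age- and resilience-associated features, blank channels
#' and contaminants; and MS/MS spectra carrying glucuronide neutral losses
#' and parent-drug/metabolite fragment relationships.
#'
#' @param n_participants number of participants (default 237).
#' @param n_visits visits per participant (default 3).
#' @param baseline_age_mean,baseline_age_sd baseline age distribution, years.
#' @param visit_spacing years between consecutive visits (default 4).
#' @param population_slope fixed cognitive slope, SD-units per decade after
#'   age 70 (default -0.7).
#' @param slope_sd between-person SD of the random slope, SD-units per decade.
#' @param intercept_sd between-person SD of the random intercept, SD-units.
#' @param resid_sd visit-level residual SD of the composite z-score.
#' @param sex_effect,education_effect small fixed covariate offsets (SD-units
#'   for female sex; SD-units per year of education) so the covariate
#'   machinery is exercised.
#' @param n_features number of LC-MS features.
#' @param n_age_features,n_resilience_features planted signal feature counts.
#' @param effect_size_age log-abundance change per year of age.
#' @param effect_size_resilience log-abundance change per unit resilience
#'   (SD-units per decade of random-slope deviation).
#' @param feature_meanlog,feature_meanlog_sd across-feature distribution of
#'   baseline log peak area.
#' @param feature_sigma within-feature residual log-abundance SD.
#' @param detection_limit peak areas below this are recorded as 0 (controls
#'   zero inflation); >= 0.
#' @param blank_level typical blank-channel peak area for contaminants' real
#'   signal floor.
#' @param n_blanks number of blank samples.
#' @param n_contaminants blank-dominated contaminant features.
#' @param early_rt_frac fraction of features eluting before 0.7 min (dead
#'   volume).
#' @param n_glucuronide_spectra,n_drug_metabolites,n_distractor_spectra
#'   planted MS/MS spectrum counts.
#' @param fragment_noise_sd Gaussian instrument noise on fragment m/z, Da.
#' @param seed integer seed; the whole synthetic world is a deterministic
#'   function of the configuration including this seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 237,
                       n_visits = 3,
                       baseline_age_mean = 70,
                       baseline_age_sd = 3,
                       visit_spacing = 4,
                       population_slope = -0.7,
                       slope_sd = 0.3,
                       intercept_sd = 0.4,
                       resid_sd = 0.5,
                       sex_effect = 0.2,
                       education_effect = 0.05,
                       n_features = 500,
                       n_age_features = 20,
                       n_resilience_features = 30,
                       effect_size_age = 0.05,
                       effect_size_resilience = 0.5,
                       feature_meanlog = 11.5,
                       feature_meanlog_sd = 1.0,
                       feature_sigma = 0.5,
                       detection_limit = exp(10),
                       blank_level = 1e3,
                       n_blanks = 6,
                       n_contaminants = NULL,
                       early_rt_frac = 0.10,
                       n_glucuronide_spectra = 8,
                       n_drug_metabolites = 6,
                       n_distractor_spectra = 8,
                       fragment_noise_sd = 0.002,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$n_contaminants))
    cfg$n_contaminants <- max(2L, round(0.02 * n_features))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field, min = 1) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < min || v != round(v))
      stop("invalid `", field, "`: must be an integer >= ", min, call. = FALSE)
  }
  chk_pos <- function(field, strict = TRUE) {
    v <- cfg[[field]]
    ok <- is.numeric(v) && length(v) == 1 && !is.na(v) && (if (strict) v > 0 else v >= 0)
    if (!ok) stop("invalid `", field, "`: must be ",
                  if (strict) "strictly positive" else "non-negative", call. = FALSE)
  }
  chk_num <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v))
      stop("invalid `", field, "`: must be a single number", call. = FALSE)
  }
  for (f in c("n_participants", "n_visits", "n_features")) chk_count(f)
  for (f in c("n_age_features", "n_resilience_features", "n_blanks",
              "n_contaminants", "n_glucuronide_spectra", "n_drug_metabolites",
              "n_distractor_spectra")) chk_count(f, min = 0)
  for (f in c("baseline_age_sd", "visit_spacing", "feature_meanlog_sd",
              "feature_sigma", "blank_level"))
    chk_pos(f)
  # zero heterogeneity / zero noise are legitimate degenerate worlds
  for (f in c("slope_sd", "intercept_sd", "resid_sd", "detection_limit",
              "fragment_noise_sd", "early_rt_frac"))
    chk_pos(f, strict = FALSE)
  for (f in c("baseline_age_mean", "population_slope", "sex_effect",
              "education_effect", "effect_size_age", "effect_size_resilience",
              "feature_meanlog")) chk_num(f)
  chk_count("seed", min = 0)
  if (cfg$n_age_features + cfg$n_resilience_features > cfg$n_features)
    stop("invalid `n_age_features`/`n_resilience_features`: ",
         "planted features exceed `n_features`", call. = FALSE)
  if (cfg$early_rt_frac >= 1)
    stop("invalid `early_rt_frac`: must be < 1", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

#' Load a generator configuration from a JSON document
#'
#' Reads a flat key-value JSON file and merges it over the [sim_config()]
#' defaults, which are documented in one place there. Unknown keys are
#' rejected; values must match the type of the default they override.
#'
#' @param path JSON file with a single flat object; an empty object yields
#'   all defaults.
#' @return validated `sim_config`.
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw) == 0) return(sim_config())
  if (is.null(names(raw)) || any(names(raw) == ""))
    stop("config must be a flat key-value object")
  defaults <- formals(sim_config)
  known <- names(defaults)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(raw)) {
    if (!is.numeric(raw[[k]]) || length(raw[[k]]) != 1)
      stop("config key `", k, "`: expected a single number, got ",
           class(raw[[k]])[1])
  }
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}
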