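#' Fit the longitudinal cognition trajectory model
#'
#' Linear mixed-effects model for composite cognitive z-scores: fixed
#' effects for time (in decades after age 70, so the slope reads as SD-units
#' per decade), sex and education, with correlated participant-level random
#' intercepts and random slopes. Person-specific slope deviations are the
#' best linear unbiased predictions (BLUPs) of the random slope; a
#' per-participant ordinary-least-squares alternative (no shrinkage) is
#' available via `method = "ols"`.
#'
#' If the correlated random-effects fit fails to converge, the model is
#' refit with the intercept-slope correlation fixed at zero and flagged.
#' A noise-free degenerate cohort (zero residual variance) is detected and
#' solved exactly rather than passed to the numerical optimizer.
#'
#' @param records long-format data.frame: participant_id, visit, age, sex,
#'   education, z_score. At least 80% of participants need >= 2 visits.
#' @param method `"blup"` (mixed-model conditional means, default) or
#'   `"ols"` (per-participant slope refits minus the fixed slope).
#' @return object of class `trajectory_fit`: `fixed_effects` (intercept,
#'   slope per decade, sex, education), `random_sd` (intercept, slope),
#'   `random_correlation`, `resid_sd`, `slope_deviation` (named vector,
#'   SD-units per decade), `converged`, `singular`, `method`.
#' @export
fit_trajectory <- function(records, method = c("blup", "ols")) {
  method <- match.arg(method)
  req <- c("participant_id", "age", "z_score")
  missing <- setdiff(req, names(records))
  if (length(missing))
    stop("records lack column(s): ", paste(missing, collapse = ", "))
  nv <- table(records$participant_id)
  if (all(nv < 2))
    stop("no participant has >= 2 visits; slopes are unidentifiable")
  if (mean(nv >= 2) < 0.8)
    stop("fewer than 80% of participants have >= 2 visits")
  d <- records
  d$t <- (d$age - 70) / 10
  d$female <- if (is.null(d$sex)) 0 else as.numeric(d$sex == "female")
  d$edu_c <- if (is.null(d$education)) 0 else d$education - mean(d$education)
  pids <- sort(unique(d$participant_id))

  # degenerate noise-free design: the fixed + per-person part fits exactly
  ols_global <- stats::lm(z_score ~ t + female + edu_c, data = d)
  if (stats::sigma(ols_global) < 1e-8 && method == "blup") {
    fe <- stats::coef(ols_global)
    return(new_trajectory_fit(
      fixed_effects = c(intercept = unname(fe["(Intercept)"]),
                        slope_per_decade = unname(fe["t"]),
                        female = unname(fe["female"]),
                        education = unname(fe["edu_c"])),
      random_sd = c(intercept = 0, slope = 0), random_correlation = 0,
      resid_sd = 0,
      slope_deviation = stats::setNames(rep(0, length(pids)), pids),
      converged = TRUE, singular = TRUE, method = "blup"))
  }

  if (method == "ols") {
    fe <- stats::coef(ols_global)
    dev <- vapply(pids, function(p) {
      dp <- d[d$participant_id == p, ]
      if (nrow(dp) < 2 || stats::var(dp$t) == 0) return(NA_real_)
      unname(stats::coef(stats::lm(z_score ~ t, data = dp))["t"]) - unname(fe["t"])
    }, numeric(1))
    return(new_trajectory_fit(
      fixed_effects = c(intercept = unname(fe["(Intercept)"]),
                        slope_per_decade = unname(fe["t"]),
                        female = unname(fe["female"]),
                        education = unname(fe["edu_c"])),
      random_sd = c(intercept = NA_real_, slope = NA_real_),
      random_correlation = NA_real_, resid_sd = stats::sigma(ols_global),
      slope_deviation = stats::setNames(dev, pids),
      converged = TRUE, singular = FALSE, method = "ols"))
  }

  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- suppressWarnings(suppressMessages(try(
    lme4::lmer(z_score ~ t + female + edu_c + (1 + t | participant_id),
               data = d, REML = TRUE, control = ctrl), silent = TRUE)))
  converged <- !inherits(fit, "try-error") && conv_ok(fit)
  if (!converged) {
    fit2 <- suppressWarnings(suppressMessages(try(
      lme4::lmer(z_score ~ t + female + edu_c + (1 + t || participant_id),
                 data = d, REML = TRUE, control = ctrl), silent = TRUE)))
    if (!inherits(fit2, "try-error")) fit <- fit2
    if (inherits(fit, "try-error"))
      stop("trajectory model could not be fit: ", attr(fit, "condition")$message)
  }
  fe <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_int <- vc$sdcor[vc$grp == "participant_id" & vc$var1 == "(Intercept)" &
                       is.na(vc$var2)][1]
  sd_slope <- vc$sdcor[vc$grp %in% c("participant_id", "participant_id.1") &
                         vc$var1 == "t" & is.na(vc$var2)]
  sd_slope <- sd_slope[!is.na(sd_slope)][1]
  rho <- vc$sdcor[!is.na(vc$var2)]
  rho <- if (length(rho)) rho[1] else 0
  re <- lme4::ranef(fit)$participant_id
  dev <- stats::setNames(re[["t"]], rownames(re))[pids]
  new_trajectory_fit(
    fixed_effects = c(intercept = unname(fe["(Intercept)"]),
                      slope_per_decade = unname(fe["t"]),
                      female = unname(fe["female"]),
                      education = unname(fe["edu_c"])),
    random_sd = c(intercept = sd_int, slope = sd_slope),
    random_correlation = rho,
    resid_sd = stats::sigma(fit),
    slope_deviation = dev,
    converged = converged,
    singular = lme4::isSingular(fit, tol = 1e-5),
    method = "blup")
}

conv_ok <- function(fit) {
  cc <- fit@optinfo$conv$lme4
  is.null(cc$code) || cc$code >= 0
}

new_trajectory_fit <- function(...) structure(list(...), class = "trajectory_fit")

#' @export
print.trajectory_fit <- function(x, ...) {
  cat("<trajectory_fit> cognitive decline model (", x$method, ")\n", sep = "")
  cat(sprintf("  fixed slope: %.3f SD/decade; random slope SD: %s; resid SD: %.3f\n",
              x$fixed_effects["slope_per_decade"],
              format(x$random_sd["slope"], digits = 3), x$resid_sd))
  cat(sprintf("  %d participants; converged: %s; singular: %s\n",
              length(x$slope_deviation), x$converged, x$singular))
  invisible(x)
}

#' Per-participant cognitive resilience scores
#'
#' The resilience score is the difference between the person-specific slope
#' and the overall model slope, i.e. exactly the participant's slope
#' deviation: (fixed slope + deviation) - fixed slope. Higher scores mean a
#' flatter-than-average trajectory and thus more stable cognition. Under a
#' balanced design the BLUPs center at zero, so the cohort mean score is
#' approximately 0.
#'
#' @param fit a converged [fit_trajectory()] result.
#' @return data.frame: participant_id, resilience (SD-units per decade),
#'   se_flag (TRUE when the underlying fit needed the uncorrelated-random
#'   fallback or did not converge cleanly).
#' @export
resilience_scores <- function(fit) {
  stopifnot(inherits(fit, "trajectory_fit"))
  data.frame(participant_id = names(fit$slope_deviation),
             resilience = unname(fit$slope_deviation),
             se_flag = !fit$converged,
             stringsAsFactors = FALSE)
}
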