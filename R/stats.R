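#' Benjamini-Hochberg adjusted q-values
#'
#' Textbook step-up adjustment: order the m p-values increasingly, set
#' q_(i) = min over j >= i of p_(j) * m / j, clipped at 1. Order-preserving
#' and monotone by construction.
#'
#' @param p numeric vector of p-values in [0, 1] (no NAs).
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no NAs")
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

#' Per-feature age association by linear mixed models
#'
#' For each feature, fits log-abundance ~ centered age with a participant
#' random intercept and random age slope, over all visits. The fixed age
#' slope's p-value uses the normal approximation to the t statistic;
#' p-values are BH-corrected across features. A fit is flagged `singular`
#' when the random-slope variance estimate sits at the zero boundary, i.e.
#' no detectable inter-individual heterogeneity in the age slope. Because
#' the roles of singular fits differ between reported analyses (the aging
#' branch keeps features *without* detectable heterogeneity, the
#' resilience follow-up keeps non-singular ones), the selection rule is an
#' explicit argument, applied after BH, and both counts are reported.
#'
#' @param table a log-scale [feature_table()] restricted to study samples
#'   (see [preprocess_lmm()]).
#' @param metadata sample metadata (participant_id, age).
#' @param selection_rule `"require_singular"` or `"require_nonsingular"`.
#' @param q_cutoff BH threshold for the reported set (default 0.05).
#' @return list: `results` (data.frame feature_id, age_slope, slope_se,
#'   p_fixed, q_fixed, singular_fit, converged, selected),
#'   `n_significant_singular`, `n_significant_nonsingular`.
#' @export
lmm_age <- function(table, metadata,
                    selection_rule = c("require_singular", "require_nonsingular"),
                    q_cutoff = 0.05) {
  selection_rule <- match.arg(selection_rule)
  stopifnot(table$values %in% c("log"))
  md <- metadata[match(table$sample_ids, metadata$sample_id), ]
  if (any(md$is_blank)) stop("blank samples present; remove them first")
  nv <- table(md$participant_id)
  if (all(nv < 2))
    stop("no participant has >= 2 visits; age slopes are unidentifiable")
  age_c <- md$age - mean(md$age)
  pid <- md$participant_id
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore", calc.derivs = FALSE)
  rows <- lapply(seq_len(nrow(table$areas)), function(j) {
    y <- table$areas[j, ]
    fit <- suppressWarnings(suppressMessages(try(
      lme4::lmer(y ~ age_c + (1 + age_c | pid), REML = TRUE, control = ctrl),
      silent = TRUE)))
    if (inherits(fit, "try-error")) {
      return(data.frame(feature_id = table$features$feature_id[j],
                        age_slope = NA_real_, slope_se = NA_real_,
                        p_fixed = NA_real_, singular_fit = NA,
                        converged = FALSE, stringsAsFactors = FALSE))
    }
    co <- summary(fit)$coefficients
    est <- co["age_c", "Estimate"]
    se <- co["age_c", "Std. Error"]
    data.frame(feature_id = table$features$feature_id[j],
               age_slope = est, slope_se = se,
               p_fixed = 2 * stats::pnorm(-abs(est / se)),
               singular_fit = lme4::isSingular(fit, tol = 1e-5),
               converged = TRUE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_fixed <- NA_real_
  ok <- res$converged & !is.na(res$p_fixed)
  res$q_fixed[ok] <- bh_adjust(res$p_fixed[ok])
  sig <- ok & res$q_fixed < q_cutoff
  n_sing <- sum(sig & res$singular_fit, na.rm = TRUE)
  n_nonsing <- sum(sig & !res$singular_fit, na.rm = TRUE)
  res$selected <- sig & (if (selection_rule == "require_singular")
    res$singular_fit else !res$singular_fit)
  list(results = res,
       n_significant_singular = n_sing,
       n_significant_nonsingular = n_nonsing,
       selection_rule = selection_rule)
}

#' Two-step hurdle association with resilience
#'
#' Step 1 asks whether a feature's presence/absence (area > 0) is associated
#' with cognitive resilience, by logistic regression (IRLS via `glm`); it is
#' skipped (inestimable) when either presence group has fewer than
#' `min_group` samples or when complete separation is detected. Step 2 asks
#' whether, among the samples where the feature is detected, its
#' log-transformed abundance is a linear function of resilience (OLS).
#' P-values are BH-corrected within each step across estimable features.
#'
#' @param table a raw-area [feature_table()] restricted to the selected
#'   visit's samples (one per participant).
#' @param resilience named numeric: resilience score per sample id (or a
#'   vector aligned with the table's samples).
#' @param min_group minimum samples per presence group for step 1.
#' @return data.frame per feature: n_present, n_absent, step1_estimable,
#'   presence_logodds, p1, q1, step2_estimable, abundance_slope, p2, q2.
#' @export
hurdle <- function(table, resilience, min_group = 5) {
  if (!is.null(names(resilience)))
    resilience <- resilience[table$sample_ids]
  if (length(resilience) != length(table$sample_ids) || anyNA(resilience))
    stop("resilience must cover every sample in the table")
  if (stats::var(resilience) == 0) stop("constant resilience score")
  res <- lapply(seq_len(nrow(table$areas)), function(j) {
    a <- table$areas[j, ]
    present <- a > 0
    out <- data.frame(feature_id = table$features$feature_id[j],
                      n_present = sum(present), n_absent = sum(!present),
                      step1_estimable = FALSE, presence_logodds = NA_real_,
                      p1 = NA_real_, step2_estimable = FALSE,
                      abundance_slope = NA_real_, p2 = NA_real_,
                      separation = FALSE, stringsAsFactors = FALSE)
    if (sum(present) >= min_group && sum(!present) >= min_group) {
      w <- NULL
      fit1 <- withCallingHandlers(
        stats::glm(present ~ resilience, family = stats::binomial()),
        warning = function(cond) {
          w <<- conditionMessage(cond)
          invokeRestart("muffleWarning")
        })
      sep <- (!is.null(w) && grepl("fitted probabilities", w)) ||
        abs(stats::coef(fit1)["resilience"]) > 15
      out$separation <- sep
      if (!sep) {
        out$step1_estimable <- TRUE
        out$presence_logodds <- unname(stats::coef(fit1)["resilience"])
        out$p1 <- summary(fit1)$coefficients["resilience", "Pr(>|z|)"]
      }
    }
    if (sum(present) >= 3 && stats::var(resilience[present]) > 0) {
      fit2 <- stats::lm(log(a[present]) ~ resilience[present])
      sm <- suppressWarnings(summary(fit2))$coefficients
      if (nrow(sm) == 2) {
        out$step2_estimable <- TRUE
        out$abundance_slope <- sm[2, "Estimate"]
        out$p2 <- sm[2, "Pr(>|t|)"]
      }
    }
    out
  })
  res <- do.call(rbind, res)
  res$q1 <- NA_real_
  res$q1[res$step1_estimable] <- bh_adjust(res$p1[res$step1_estimable])
  res$q2 <- NA_real_
  res$q2[res$step2_estimable] <- bh_adjust(res$p2[res$step2_estimable])
  res
}

#' Split a cohort into low / high resilience groups
#'
#' Median split mirroring a quartile-based grouping: the lower two quartiles
#' form the low group, the upper two the high group. Samples tied with the
#' median go low; with distinct scores the group sizes differ by at most 1.
#'
#' @param resilience numeric scores (>= 4 values), optionally named.
#' @return factor with levels `low`, `high`, named like the input.
#' @export
split_resilience_groups <- function(resilience) {
  if (length(resilience) < 4) stop("need at least 4 samples to form groups")
  med <- stats::median(resilience)
  grp <- factor(ifelse(resilience <= med, "low", "high"),
                levels = c("low", "high"))
  names(grp) <- names(resilience)
  grp
}

#' Per-feature fold change between resilience groups
#'
#' log2 ratio of mean peak areas (high over low), computed over detected
#' (non-zero) samples, with a two-sided Wilcoxon rank-sum test on the log
#' areas and BH correction across tested features. A feature absent in one
#' entire group gets an infinite-coded fold change and its test is skipped.
#'
#' @param table a raw-area [feature_table()].
#' @param groups factor from [split_resilience_groups()] aligned with (or
#'   named by) the table's samples.
#' @return data.frame: feature_id, log2_fc, p, q, tested.
#' @export
fold_change <- function(table, groups) {
  if (!is.null(names(groups))) groups <- groups[table$sample_ids]
  if (length(groups) != length(table$sample_ids))
    stop("groups must align with the table's samples")
  if (!all(table(groups) > 0)) stop("both groups must be non-empty")
  lo <- groups == "low"; hi <- groups == "high"
  res <- lapply(seq_len(nrow(table$areas)), function(j) {
    a <- table$areas[j, ]
    alo <- a[lo & a > 0]; ahi <- a[hi & a > 0]
    if (!length(alo) || !length(ahi)) {
      fc <- if (!length(alo) && !length(ahi)) NA_real_
            else if (!length(alo)) Inf else -Inf
      return(data.frame(feature_id = table$features$feature_id[j],
                        log2_fc = fc, p = NA_real_, tested = FALSE,
                        stringsAsFactors = FALSE))
    }
    p <- if (length(alo) > 1 || length(ahi) > 1)
      suppressWarnings(stats::wilcox.test(log(ahi), log(alo))$p.value)
    else NA_real_
    data.frame(feature_id = table$features$feature_id[j],
               log2_fc = log2(mean(ahi) / mean(alo)),
               p = p, tested = !is.na(p), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- NA_real_
  res$q[res$tested] <- bh_adjust(res$p[res$tested])
  res
}

#' Acylcarnitine chain-length class from an annotation string
#'
#' Parses a `C<carbons>:<double bonds>` token (e.g. "C12:1 carnitine") and
#' maps the carbon count to the conventional chain classes: short (C2-C5),
#' medium (C6-C12), long (C13-C21), very long (>= C22). Unparseable input
#' (or C0/C1) yields class `unknown` rather than an error.
#'
#' @param annotation_text character vector of annotation strings.
#' @return data.frame: annotation, carbon_count, unsaturation, class.
#' @export
chain_class <- function(annotation_text) {
  parse1 <- function(s) {
    m <- regmatches(s, regexpr("C([0-9]+)(:([0-9]+))?", s))
    if (!length(m))
      return(data.frame(annotation = s, carbon_count = NA_integer_,
                        unsaturation = NA_integer_, class = "unknown",
                        stringsAsFactors = FALSE))
    parts <- strsplit(sub("^C", "", m), ":")[[1]]
    cc <- as.integer(parts[1])
    un <- if (length(parts) > 1) as.integer(parts[2]) else 0L
    cls <- if (cc >= 2 && cc <= 5) "short"
      else if (cc >= 6 && cc <= 12) "medium"
      else if (cc >= 13 && cc <= 21) "long"
      else if (cc >= 22) "very_long"
      else "unknown"
    data.frame(annotation = s, carbon_count = cc, unsaturation = un,
               class = cls, stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(annotation_text, parse1))
}

#' Per-class fraction of negative associations
#'
#' For a set of features with loading weights and class labels, reports the
#' fraction of each class's members whose weight is negative (i.e.
#' negatively associated with resilience).
#'
#' @param weights numeric loading weights.
#' @param class_labels character/factor class label per weight.
#' @return data.frame: class, n, fraction_negative.
#' @export
direction_summary <- function(weights, class_labels) {
  if (!length(weights)) stop("empty weight vector")
  if (length(weights) != length(class_labels))
    stop("weights and class_labels must align")
  classes <- unique(as.character(class_labels))
  do.call(rbind, lapply(classes, function(cl) {
    w <- weights[class_labels == cl]
    if (!length(w)) stop("empty class: ", cl)
    data.frame(class = cl, n = length(w), fraction_negative = mean(w < 0),
               stringsAsFactors = FALSE)
  }))
}
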