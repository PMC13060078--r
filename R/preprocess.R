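#' Dead-volume filter
#'
#' Removes features eluting before `rt_min` minutes (un-retained material in
#' the injection dead volume; default 0.7 min).
#'
#' @param table a [feature_table()].
#' @param rt_min minimum retention time in minutes.
#' @return filtered table.
#' @export
dead_volume_filter <- function(table, rt_min = 0.7) {
  ft_subset(table, table$features$rt >= rt_min)
}

#' Blank filter
#'
#' Keeps a feature only when its aggregate peak area in study samples is at
#' least `factor` times its aggregate area in blank samples. The aggregate
#' is the mean (or max) over non-zero entries; a feature never detected in
#' blanks has blank aggregate 0 and is always kept.
#'
#' @param table a [feature_table()] on the raw area scale.
#' @param metadata sample metadata with `is_blank`.
#' @param factor required sample-to-blank ratio (default 5).
#' @param aggregate `"mean"` (default) or `"max"` over non-zero entries.
#' @return filtered table.
#' @export
blank_filter <- function(table, metadata, factor = 5,
                         aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  blanks <- intersect(table$sample_ids, metadata$sample_id[metadata$is_blank])
  if (!length(blanks))
    stop("no blank samples in the table; skip the blank filter explicitly ",
         "if your design has none")
  samples <- setdiff(table$sample_ids, blanks)
  agg <- function(v) {
    v <- v[v > 0]
    if (!length(v)) return(0)
    if (aggregate == "mean") mean(v) else max(v)
  }
  a_samp <- apply(table$areas[, samples, drop = FALSE], 1, agg)
  a_blank <- apply(table$areas[, blanks, drop = FALSE], 1, agg)
  ft_subset(table, a_samp >= factor * a_blank)
}

#' Sparsity (minimum presence) filter
#'
#' Keeps a feature only when it is detected (area > 0) in at least
#' `min_presence_frac` of the non-blank samples.
#'
#' @param table a [feature_table()].
#' @param min_presence_frac required presence fraction in (0, 1].
#' @param metadata optional metadata; when given, blanks are excluded from
#'   the denominator.
#' @return filtered table.
#' @export
sparsity_filter <- function(table, min_presence_frac, metadata = NULL) {
  if (min_presence_frac <= 0 || min_presence_frac > 1)
    stop("`min_presence_frac` must be in (0, 1]")
  cols <- if (is.null(metadata)) table$sample_ids
          else non_blank_samples(table, metadata)
  pres <- rowMeans(table$areas[, cols, drop = FALSE] > 0)
  ft_subset(table, pres >= min_presence_frac)
}

#' Per-feature pseudocount and log transform
#'
#' Replaces zeros by half the minimum non-zero value of that feature, then
#' applies the natural log. Features that are zero everywhere cannot be
#' transformed and must be removed (by [sparsity_filter()]) first.
#'
#' @param table a [feature_table()] on the raw area scale.
#' @param metadata optional metadata; when given, blank columns are dropped
#'   before transforming.
#' @return table with `values = "log"`.
#' @export
pseudocount_log <- function(table, metadata = NULL) {
  a <- table$areas
  if (!is.null(metadata)) a <- a[, non_blank_samples(table, metadata), drop = FALSE]
  for (j in seq_len(nrow(a))) {
    nz <- a[j, ] > 0
    if (!any(nz))
      stop("all-zero feature ", table$features$feature_id[j],
           "; apply sparsity_filter first")
    a[j, !nz] <- min(a[j, nz]) / 2
  }
  tab <- if (is.null(metadata)) table else ft_keep_samples(table, colnames(a))
  ft_replace(tab, log(a), "log")
}

# restrict a table to a subset of samples (columns)
ft_keep_samples <- function(table, samples) {
  feature_table(table$features, table$areas[, samples, drop = FALSE],
                samples, values = table$values)
}

#' Robust centered log-ratio (RCLR) transform
#'
#' Per sample (column), every observed entry becomes its log value centered
#' on the mean log over that sample's *observed* (non-zero) entries; zeros
#' become `NA` ("missing", excluded from the mean). This makes the table
#' scale-invariant per sample, which is the standard treatment for
#' compositional LC-MS data with non-detects.
#'
#' @param table a [feature_table()] on the raw area scale.
#' @return table with `values = "rclr"`; non-detects are `NA`.
#' @export
rclr <- function(table) {
  a <- table$areas
  out <- matrix(NA_real_, nrow(a), ncol(a))
  for (s in seq_len(ncol(a))) {
    obs <- a[, s] > 0
    if (sum(obs) < 2)
      stop("sample ", table$sample_ids[s], " has fewer than 2 observed features")
    lg <- log(a[obs, s])
    out[obs, s] <- lg - mean(lg)
  }
  ft_replace(table, out, "rclr")
}

#' Residualize features on a covariate
#'
#' Replaces each feature by the residuals of its simple linear regression on
#' a sample-level covariate (age by default), fit over the feature's
#' observed (non-missing) entries only. Removes, e.g., the confounding of
#' cross-sectional age with resilience before the multivariate fit.
#'
#' @param table a transformed [feature_table()] (blank columns removed).
#' @param metadata sample metadata providing the covariate.
#' @param covariate metadata column name, default `"age"`.
#' @return table with `values = "residuals"`.
#' @export
residualize_covariate <- function(table, metadata, covariate = "age") {
  x <- metadata[[covariate]][match(table$sample_ids, metadata$sample_id)]
  if (anyNA(x))
    stop("covariate `", covariate, "` missing for sample ",
         table$sample_ids[which(is.na(x))[1]])
  if (stats::var(x) == 0) {
    warning("constant covariate `", covariate, "`; returning table unchanged")
    return(ft_replace(table, table$areas, "residuals"))
  }
  a <- table$areas
  out <- a
  for (j in seq_len(nrow(a))) {
    obs <- !is.na(a[j, ])
    if (sum(obs) < 3) next
    xj <- x[obs]; yj <- a[j, obs]
    beta <- stats::cov(xj, yj) / stats::var(xj)
    out[j, obs] <- yj - mean(yj) - beta * (xj - mean(xj))
  }
  ft_replace(table, out, "residuals")
}

#' Near-zero-variance filter
#'
#' Drops features whose variance (over observed entries) falls below
#' `var_eps` or whose single most frequent value occupies more than
#' `dominance` of the samples.
#'
#' @param table a transformed [feature_table()].
#' @param var_eps variance floor.
#' @param dominance maximum allowed frequency share of the modal value.
#' @return filtered table.
#' @export
nzv_filter <- function(table, var_eps = 1e-8, dominance = 0.95) {
  keep <- vapply(seq_len(nrow(table$areas)), function(j) {
    v <- table$areas[j, ]
    v <- v[!is.na(v)]
    if (length(v) < 2) return(FALSE)
    if (stats::var(v) < var_eps) return(FALSE)
    max(table(v)) / length(v) <= dominance
  }, logical(1))
  ft_subset(table, keep)
}

#' Age-harmonizing visit selection
#'
#' Selects one visit per participant so that the standard deviation of the
#' selected ages across the cohort is minimal, removing the confounding of
#' inclusion age. The objective decomposes: for any fixed target age m the
#' selection minimizing the sum of squared deviations from m picks each
#' participant's age nearest to m, and the overall optimum is the best such
#' nearest-age selection over m. The selection can only change where m
#' crosses a midpoint between two of one participant's ages, so scanning one
#' representative m per interval between consecutive midpoints enumerates
#' every candidate selection and attains the exact global optimum. A final
#' coordinate-descent sweep (re-choosing each participant's visit at the
#' achieved selection) confirms the fixed point. The result is
#' deterministic; ties break toward the earlier visit, and the achieved SD
#' never exceeds the best uniform single-visit choice.
#'
#' @param metadata sample metadata (non-blank rows used).
#' @return list: `selection` (data.frame participant_id, visit, age,
#'   sample_id), `age_sd` (achieved SD, years), `uniform_sd` (best
#'   single-visit SD), `n_candidates` (target-age intervals scanned).
#' @export
select_visit_min_age_sd <- function(metadata) {
  md <- metadata[!metadata$is_blank, ]
  if (!nrow(md)) stop("no non-blank samples")
  parts <- unique(md$participant_id)
  ages <- lapply(parts, function(p) {
    mp <- md[md$participant_id == p, ]
    mp[order(mp$visit), ]
  })
  names(ages) <- parts
  n <- length(parts)

  # best uniform visit index, as the reference upper bound
  max_v <- max(vapply(ages, nrow, integer(1)))
  uniform_sd <- vapply(seq_len(max_v), function(k) {
    stats::sd(vapply(ages, function(mp) mp$age[min(k, nrow(mp))], numeric(1)))
  }, numeric(1))

  # midpoints between any two ages of the same participant = breakpoints of
  # the nearest-age selection as a function of the target age m
  mids <- unlist(lapply(ages, function(mp) {
    a <- mp$age
    if (length(a) < 2) return(numeric(0))
    cmb <- utils::combn(a, 2)
    (cmb[1, ] + cmb[2, ]) / 2
  }))
  all_ages <- unlist(lapply(ages, function(mp) mp$age))
  brk <- sort(unique(c(mids, range(all_ages))))
  reps <- unique(c(brk, (brk[-1] + brk[-length(brk)]) / 2))

  nearest_pick <- function(m) {
    vapply(ages, function(mp) {
      d <- abs(mp$age - m)
      which(d <= min(d) + 1e-12)[1] # tie -> earlier visit
    }, integer(1))
  }
  best_sd <- Inf
  pick <- nearest_pick(reps[1])
  for (m in reps) {
    pk <- nearest_pick(m)
    cur <- vapply(seq_len(n), function(i) ages[[i]]$age[pk[i]], numeric(1))
    s <- stats::sd(cur)
    if (s < best_sd - 1e-12) {
      best_sd <- s
      pick <- pk
    }
  }
  # confirm the fixed point with one coordinate-descent pass
  cur <- vapply(seq_len(n), function(i) ages[[i]]$age[pick[i]], numeric(1))
  for (i in seq_len(n)) {
    cand <- ages[[i]]$age
    sds <- vapply(cand, function(a) { v <- cur; v[i] <- a; stats::sd(v) },
                  numeric(1))
    best <- which(sds <= min(sds) + 1e-12)[1]
    pick[i] <- best
    cur[i] <- cand[best]
  }
  sel <- do.call(rbind, lapply(seq_len(n), function(i) {
    mp <- ages[[i]][pick[i], ]
    data.frame(participant_id = parts[i], visit = mp$visit, age = mp$age,
               sample_id = mp$sample_id, stringsAsFactors = FALSE)
  }))
  rownames(sel) <- NULL
  list(selection = sel, age_sd = stats::sd(cur),
       uniform_sd = min(uniform_sd), n_candidates = length(reps))
}

#' External-validation visit selection
#'
#' For each participant, picks among the *unselected* visits the one closest
#' in age to the selected visit (ties toward the earlier visit).
#' Single-visit participants are dropped with a warning.
#'
#' @param metadata sample metadata.
#' @param selected the `selection` data.frame from
#'   [select_visit_min_age_sd()].
#' @return data.frame participant_id, visit, age, sample_id (disjoint from
#'   the selected map).
#' @export
select_external_visit <- function(metadata, selected) {
  md <- metadata[!metadata$is_blank, ]
  out <- list()
  dropped <- character(0)
  for (i in seq_len(nrow(selected))) {
    p <- selected$participant_id[i]
    mp <- md[md$participant_id == p & md$visit != selected$visit[i], ]
    if (!nrow(mp)) { dropped <- c(dropped, p); next }
    mp <- mp[order(abs(mp$age - selected$age[i]), mp$visit), ]
    out[[length(out) + 1L]] <- data.frame(
      participant_id = p, visit = mp$visit[1], age = mp$age[1],
      sample_id = mp$sample_id[1], stringsAsFactors = FALSE)
  }
  if (length(dropped))
    warning("dropped single-visit participant(s): ",
            paste(dropped, collapse = ", "))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Feature-table conditioning for the sparse PLS branch
#'
#' Applies the resilience-branch preprocessing in order: dead-volume filter,
#' blank filter, visit selection minimizing age SD, restriction to selected
#' samples, minimum-presence filter, RCLR, age residualization and
#' near-zero-variance removal. Returns the processed table together with a
#' report of survivor counts per step.
#'
#' @param table raw [feature_table()] including blank columns.
#' @param metadata sample metadata.
#' @param rt_min dead-volume cutoff, minutes.
#' @param blank_factor sample/blank ratio.
#' @param min_presence minimum presence fraction among selected samples
#'   (default 0.4, the resilience branch's operational cutoff).
#' @param residualize_age residualize each feature on age (default TRUE).
#' @return list: `table` (processed), `selection`, `external` (held-out
#'   visit map), `report` (data.frame step, n_features), `age_sd`.
#' @export
preprocess_spls <- function(table, metadata, rt_min = 0.7, blank_factor = 5,
                            min_presence = 0.4, residualize_age = TRUE) {
  report <- list(data.frame(step = "input", n_features = nrow(table$areas)))
  step <- function(tab, name) {
    report[[length(report) + 1L]] <<- data.frame(step = name,
                                                 n_features = nrow(tab$areas))
    tab
  }
  tab <- step(dead_volume_filter(table, rt_min), "dead_volume")
  tab <- step(blank_filter(tab, metadata, blank_factor), "blank")
  vis <- select_visit_min_age_sd(metadata)
  ext <- select_external_visit(metadata, vis$selection)
  tab_sel <- ft_keep_samples(tab, vis$selection$sample_id)
  tab_sel <- step(sparsity_filter(tab_sel, min_presence), "presence")
  tab_sel <- rclr(tab_sel)
  if (residualize_age)
    tab_sel <- residualize_covariate(tab_sel, metadata, "age")
  tab_sel <- step(nzv_filter(tab_sel), "nzv")
  list(table = tab_sel, selection = vis$selection, external = ext,
       filtered_all_visits = tab,
       report = do.call(rbind, report), age_sd = vis$age_sd)
}

#' Feature-table conditioning for the mixed-model branches
#'
#' The longitudinal (all-visit) branch: dead-volume and blank filters,
#' minimum-presence selection across non-blank samples, then per-feature
#' pseudocount + log transform.
#'
#' @inheritParams preprocess_spls
#' @param min_presence minimum presence fraction (default 0.3, the aging
#'   branch's operational cutoff).
#' @return list: `table` (log scale, blanks removed), `report`.
#' @export
preprocess_lmm <- function(table, metadata, rt_min = 0.7, blank_factor = 5,
                           min_presence = 0.3) {
  report <- list(data.frame(step = "input", n_features = nrow(table$areas)))
  step <- function(tab, name) {
    report[[length(report) + 1L]] <<- data.frame(step = name,
                                                 n_features = nrow(tab$areas))
    tab
  }
  tab <- step(dead_volume_filter(table, rt_min), "dead_volume")
  tab <- step(blank_filter(tab, metadata, blank_factor), "blank")
  tab <- ft_keep_samples(tab, non_blank_samples(tab, metadata))
  tab <- step(sparsity_filter(tab, min_presence), "presence")
  tab <- pseudocount_log(tab)
  list(table = tab, report = do.call(rbind, report))
}
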