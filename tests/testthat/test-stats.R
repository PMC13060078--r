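test_that("BH adjustment matches hand computation and the reference implementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, NA)), "\\[0, 1\\]")
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
})

test_that("BH keeps the null discovery fraction nominal", {
  frac <- vapply(1:5, function(s) {
    set.seed(500 + s)
    mean(bh_adjust(runif(1000)) < 0.05)
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})

test_that("hurdle step 1 matches an independent likelihood-maximization oracle", {
  pres <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  res <- c(3, 2, 1, -1, -2, -3)
  tab <- toy_table(matrix(ifelse(pres, exp(5), 0), 1),
                   sample_ids = paste0("S", 1:6))
  h <- hurdle(tab, setNames(res, paste0("S", 1:6)), min_group = 3)
  expect_true(h$step1_estimable)
  expect_gt(h$presence_logodds, 0)
  nll <- function(b) -sum(dbinom(pres, 1, plogis(b[1] + b[2] * res), log = TRUE))
  oracle <- optim(c(0, 0), nll)$par[2]
  expect_equal(h$presence_logodds, oracle, tolerance = 1e-3)
})

test_that("separation and missing presence variation are flagged, not fitted", {
  res <- setNames(c(3, 2, 1, -1, -2, -3), paste0("S", 1:6))
  sep_tab <- toy_table(matrix(c(1, 1, 1, 0, 0, 0) * exp(5), 1),
                       sample_ids = names(res))
  h <- hurdle(sep_tab, res, min_group = 3)
  expect_false(h$step1_estimable)
  expect_true(h$separation)
  expect_true(h$step2_estimable) # abundance part still runs on detected samples

  all_present <- toy_table(matrix(exp(5 + seq(0, 1, length.out = 6)), 1),
                           sample_ids = names(res))
  h2 <- hurdle(all_present, res)
  expect_false(h2$step1_estimable)
  expect_true(h2$step2_estimable)
  expect_equal(h2$n_present, 6)
  expect_error(hurdle(all_present, setNames(rep(1, 6), names(res))), "constant")
})

test_that("hurdle decomposition and step-2 power on planted features", {
  hits <- vapply(1:5, function(s) {
    cfg <- sim_config(n_participants = 237, n_features = 60,
                      n_resilience_features = 8, n_age_features = 2,
                      effect_size_resilience = 0.5, seed = 600 + s)
    w <- generate_feature_table(cfg, generate_cohort(cfg))
    sel <- w$metadata[!w$metadata$is_blank & w$metadata$visit == 1, ]
    tab <- resilmet:::ft_keep_samples(w$table, sel$sample_id)
    res <- setNames(w$truth$true_random_slopes[sel$participant_id],
                    sel$sample_id)
    h <- hurdle(tab, res)
    expect_equal(h$n_present + h$n_absent,
                 rep(length(sel$sample_id), nrow(h)))
    neg <- names(w$truth$resilience_signs[w$truth$resilience_signs < 0])[1]
    row <- h[h$feature_id == neg, ]
    isTRUE(row$step2_estimable) && row$abundance_slope < 0 && row$q2 < 0.05
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("resilience grouping is a median split with ties going low", {
  g <- split_resilience_groups(c(1, 2, 3, 4))
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  g2 <- split_resilience_groups(rep(1, 6))
  expect_true(all(g2 == "low"))
  set.seed(32)
  g3 <- split_resilience_groups(rnorm(237))
  expect_lte(abs(sum(g3 == "low") - sum(g3 == "high")), 1)
})

test_that("fold changes behave on constructed groups", {
  a <- c(10, 12, 14, 10, 12, 14)
  tab <- toy_table(matrix(a, 1), sample_ids = paste0("S", 1:6))
  grp <- factor(rep(c("low", "high"), each = 3), levels = c("low", "high"))
  fc <- fold_change(tab, setNames(grp, paste0("S", 1:6)))
  expect_equal(fc$log2_fc, 0)
  expect_gt(fc$p, 0.9)

  tab2 <- toy_table(matrix(c(10, 12, 14, 20, 24, 28), 1),
                    sample_ids = paste0("S", 1:6))
  fc2 <- fold_change(tab2, setNames(grp, paste0("S", 1:6)))
  expect_equal(fc2$log2_fc, 1)

  tab3 <- toy_table(matrix(c(10, 12, 14, 0, 0, 0), 1),
                    sample_ids = paste0("S", 1:6))
  fc3 <- fold_change(tab3, setNames(grp, paste0("S", 1:6)))
  expect_equal(fc3$log2_fc, -Inf)
  expect_false(fc3$tested)
})

test_that("planted glucuronide-like features sit higher in the low-resilience group", {
  w <- get_small_world()
  sel <- w$metadata[!w$metadata$is_blank & w$metadata$visit == 1, ]
  tab <- resilmet:::ft_keep_samples(w$table, sel$sample_id)
  res <- setNames(w$truth$true_random_slopes[sel$participant_id], sel$sample_id)
  groups <- split_resilience_groups(res)
  gl_feats <- unique(na.omit(vapply(w$spectra, function(s)
    if (isTRUE(s$spectrum_id %in% w$truth$spectrum_labels$spectrum_id[
      w$truth$spectrum_labels$label == "glucuronide"])) s$feature_id
    else NA_character_, character(1))))
  gl_feats <- intersect(gl_feats, w$truth$resilience_feature_ids)
  fc <- fold_change(resilmet:::ft_subset(tab, tab$features$feature_id %in% gl_feats),
                    groups)
  expect_gt(mean(fc$log2_fc < 0, na.rm = TRUE), 0.5)
})

test_that("chain classes follow the C2-C5 / C6-C12 / C13-C21 / >=C22 boundaries", {
  cc <- chain_class(c("C12:1 carnitine", "C2:0", "C5:0", "C6:1", "C13:0",
                      "C21:0", "C22:0", "no token here", "C1"))
  expect_equal(cc$class,
               c("medium", "short", "short", "medium", "long", "long",
                 "very_long", "unknown", "unknown"))
  expect_equal(cc$carbon_count[1], 12L)
  expect_equal(cc$unsaturation[1], 1L)
})

test_that("direction summaries count negative associations per class", {
  ds <- direction_summary(c(-1, -2, 3), rep("carnitine", 3))
  expect_equal(ds$fraction_negative, 2 / 3)
  expect_equal(direction_summary(c(1, 2), rep("x", 2))$fraction_negative, 0)
  expect_error(direction_summary(numeric(0), character(0)), "empty")

  set.seed(33)
  n <- 200
  signs <- rep(c(-1, 1), c(160, 40)) # 80% negative class at high SNR
  w <- signs * abs(rnorm(n, 1, 0.2))
  ds2 <- direction_summary(w, rep("planted", n))
  expect_lt(abs(ds2$fraction_negative - 0.8), 0.1)
})

test_that("age mixed models recover fixed slopes and reduce to OLS without heterogeneity", {
  cfg <- sim_config(n_participants = 60, n_features = 12,
                    n_age_features = 6, n_resilience_features = 2,
                    effect_size_age = 0.08, feature_sigma = 0.1,
                    detection_limit = 0, seed = 12)
  w <- generate_feature_table(cfg, generate_cohort(cfg))
  lp <- preprocess_lmm(w$table, w$metadata, min_presence = 0.1)
  lm_res <- lmm_age(lp$table, w$metadata, selection_rule = "require_singular")
  res <- lm_res$results
  planted <- res[res$feature_id %in% w$truth$age_feature_ids, ]
  expect_true(all(planted$q_fixed < 0.05))
  signs <- w$truth$age_signs[planted$feature_id]
  expect_equal(sign(planted$age_slope), unname(signs))
  expect_equal(lm_res$n_significant_singular +
                 lm_res$n_significant_nonsingular,
               sum(res$q_fixed < 0.05, na.rm = TRUE))

  # no participant heterogeneity: mixed fit is singular and matches plain OLS
  j <- match(planted$feature_id[1], lp$table$features$feature_id)
  y <- lp$table$areas[j, ]
  md <- w$metadata[match(lp$table$sample_ids, w$metadata$sample_id), ]
  ols <- unname(coef(lm(y ~ I(md$age - mean(md$age))))[2])
  expect_equal(planted$age_slope[1], ols, tolerance = 1e-3)
})
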