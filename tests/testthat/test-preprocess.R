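test_that("dead-volume filter drops only early-eluting features", {
  tab <- toy_table(matrix(1:4, 2), rt = c(0.5, 0.9))
  expect_equal(dead_volume_filter(tab)$features$feature_id, "F02")
  expect_equal(dim(dead_volume_filter(tab, rt_min = 0)), dim(tab))

  w <- get_small_world()
  filt <- dead_volume_filter(w$table)
  removed <- setdiff(w$table$features$feature_id, filt$features$feature_id)
  expect_setequal(removed, w$truth$early_rt_ids)
})

test_that("blank filter applies the 5x rule and removes planted contaminants", {
  areas <- rbind(c(600, 600, 100), # kept: 600 >= 5 * 100
                 c(400, 400, 100)) # removed
  tab <- toy_table(areas, sample_ids = c("S1", "S2", "B1"))
  md <- toy_metadata(c("S1", "S2", "B1"), blank = c(FALSE, FALSE, TRUE))
  out <- blank_filter(tab, md, factor = 5)
  expect_equal(out$features$feature_id, "F01")
  expect_error(blank_filter(tab, toy_metadata(c("S1", "S2", "B1"))),
               "no blank samples")

  w <- get_small_world()
  filt <- blank_filter(w$table, w$metadata)
  expect_false(any(w$truth$contaminant_ids %in% filt$features$feature_id))
  expect_true(all(w$truth$resilience_feature_ids %in% filt$features$feature_id))
})

test_that("sparsity filter matches a direct recount oracle", {
  tab <- toy_table(rbind(c(rep(1, 50), rep(0, 50)), rep(1, 100)))
  expect_equal(nrow(sparsity_filter(tab, 0.4)$areas), 2)
  expect_equal(sparsity_filter(tab, 1.0)$features$feature_id, "F02")
  expect_error(sparsity_filter(tab, 0), "min_presence_frac")

  w <- get_small_world()
  md <- w$metadata
  samp <- md$sample_id[!md$is_blank]
  oracle <- sum(rowMeans(w$table$areas[, samp] > 0) >= 0.4)
  expect_equal(nrow(sparsity_filter(w$table, 0.4, md)$areas), oracle)
})

test_that("pseudocount-log uses half the per-feature minimum non-zero value", {
  tab <- toy_table(rbind(c(0, 4, 8), c(1, 2, 4)))
  out <- pseudocount_log(tab)
  expect_equal(unname(out$areas[1, ]), log(c(2, 4, 8)))
  expect_equal(unname(out$areas[2, ]), log(c(1, 2, 4)))
  expect_identical(out$values, "log")
  # monotonicity within each feature is preserved
  w <- get_small_world()
  filt <- sparsity_filter(w$table, 0.3, w$metadata)
  lg <- pseudocount_log(filt, w$metadata)
  raw <- filt$areas[, lg$sample_ids]
  for (j in c(1, 5, 10)) {
    ord <- order(raw[j, ])
    expect_true(all(diff(lg$areas[j, ord]) >= -1e-12))
  }
  expect_error(pseudocount_log(toy_table(rbind(c(0, 0, 0)))), "all-zero")
})

test_that("rclr centers each sample's observed log values", {
  tab <- toy_table(rbind(c(10, exp(1)), c(10, exp(3)), c(10, 0)))
  out <- rclr(tab)
  expect_equal(unname(out$areas[, 1]), c(0, 0, 0))
  expect_equal(unname(out$areas[, 2]), c(-1, 1, NA))

  w <- get_small_world()
  samp_tab <- ft_keep_samples_for_test(w)
  r <- rclr(samp_tab)
  col_means <- apply(r$areas, 2, mean, na.rm = TRUE)
  expect_lt(max(abs(col_means)), 1e-10)
  expect_error(rclr(toy_table(rbind(c(1, 0), c(2, 0)))), "fewer than 2")
})

test_that("rclr agrees with the vegan reference implementation", {
  w <- get_small_world()
  tab <- ft_keep_samples_for_test(w)
  ours <- rclr(tab)$areas
  ref <- t(vegan::decostand(t(tab$areas), method = "rclr", impute = FALSE))
  obs <- tab$areas > 0
  expect_equal(ours[obs], ref[obs], tolerance = 1e-10)
  expect_true(all(is.na(ours[!obs])))
})

test_that("covariate residualization matches closed-form least squares", {
  age <- c(66, 68, 70, 72, 74)
  y <- c(1.0, 2.1, 2.9, 4.2, 4.8)
  tab <- toy_table(matrix(y, 1), sample_ids = paste0("S", 1:5))
  tab$values <- "rclr"
  md <- toy_metadata(paste0("S", 1:5), age = age)
  out <- residualize_covariate(tab, md)
  beta <- cov(age, y) / var(age)
  expect_equal(unname(out$areas[1, ]), y - mean(y) - beta * (age - mean(age)),
               tolerance = 1e-12)
  # perfectly linear feature residualizes to ~0
  tab2 <- toy_table(matrix(2 * age - 100, 1), sample_ids = paste0("S", 1:5))
  expect_equal(unname(residualize_covariate(tab2, md)$areas[1, ]),
               rep(0, 5), tolerance = 1e-10)
  expect_warning(residualize_covariate(
    tab, toy_metadata(paste0("S", 1:5), age = rep(70, 5))), "constant")
})

test_that("near-zero-variance filter matches a recomputation oracle", {
  set.seed(1)
  areas <- rbind(rep(3.3, 50), rnorm(50), c(rep(1, 49), 2))
  tab <- toy_table(areas, values = "rclr")
  out <- nzv_filter(tab)
  expect_equal(out$features$feature_id, "F02") # constant and 98%-dominant dropped
  keep_oracle <- apply(areas, 1, function(v)
    var(v) >= 1e-8 && max(table(v)) / length(v) <= 0.95)
  expect_equal(nrow(out$areas), sum(keep_oracle))
})

test_that("visit selection matches exhaustive search on small cohorts", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 6
    ages <- matrix(runif(n * 3, 65, 80), n, 3)
    md <- data.frame(
      sample_id = sprintf("P%d_V%d", rep(1:n, each = 3), rep(1:3, n)),
      participant_id = sprintf("P%d", rep(1:n, each = 3)),
      visit = rep(1:3, n),
      age = as.vector(t(ages)),
      is_blank = FALSE)
    sel <- select_visit_min_age_sd(md)
    combos <- expand.grid(rep(list(1:3), n))
    best <- min(apply(combos, 1, function(ix)
      sd(ages[cbind(1:n, as.integer(ix))])))
    expect_equal(sel$age_sd, best, tolerance = 1e-12)
    expect_lte(sel$age_sd, sel$uniform_sd + 1e-12)
  }
})

test_that("identical age grids make any uniform visit optimal", {
  n <- 8
  md <- data.frame(
    sample_id = sprintf("P%d_V%d", rep(1:n, each = 3), rep(1:3, n)),
    participant_id = sprintf("P%d", rep(1:n, each = 3)),
    visit = rep(1:3, n),
    age = rep(c(70, 74, 78), n),
    is_blank = FALSE)
  sel <- select_visit_min_age_sd(md)
  expect_equal(sel$age_sd, 0)
  expect_equal(length(unique(sel$selection$visit)), 1L)
})

test_that("external visit choice is nearest in age with earlier-visit ties", {
  md <- data.frame(
    sample_id = c("P1_V1", "P1_V2", "P1_V3"),
    participant_id = "P1", visit = 1:3, age = c(70, 74, 78),
    is_blank = FALSE)
  selected <- data.frame(participant_id = "P1", visit = 2L, age = 74,
                         sample_id = "P1_V2")
  ext <- select_external_visit(md, selected)
  expect_equal(ext$visit, 1L) # 70 and 78 equidistant: earlier wins
  selected3 <- data.frame(participant_id = "P1", visit = 3L, age = 78,
                          sample_id = "P1_V3")
  expect_equal(select_external_visit(md, selected3)$visit, 2L)

  w <- get_small_world()
  sel <- select_visit_min_age_sd(w$metadata)
  ext <- select_external_visit(w$metadata, sel$selection)
  key <- function(d) paste(d$participant_id, d$visit)
  expect_length(intersect(key(sel$selection), key(ext)), 0)
  expect_setequal(ext$participant_id, sel$selection$participant_id)
})

test_that("the composition transform is invariant to per-sample scaling", {
  w <- get_small_world()
  tab <- ft_keep_samples_for_test(w)
  scaled <- tab
  fac <- runif(ncol(tab$areas), 0.5, 20)
  scaled$areas <- sweep(tab$areas, 2, fac, "*")
  r1 <- rclr(tab)$areas
  r2 <- rclr(scaled)$areas
  obs <- tab$areas > 0
  expect_equal(r1[obs], r2[obs], tolerance = 1e-9)
})

test_that("the branch pipelines report non-increasing feature counts", {
  w <- get_small_world()
  prep <- preprocess_spls(w$table, w$metadata)
  expect_true(all(diff(prep$report$n_features) <= 0))
  expect_equal(nrow(prep$selection), small_config()$n_participants)
  lp <- preprocess_lmm(w$table, w$metadata)
  expect_true(all(diff(lp$report$n_features) <= 0))
  expect_identical(lp$table$values, "log")
})
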