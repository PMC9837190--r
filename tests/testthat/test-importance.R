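test_that("knockout bookkeeping covers every unit exactly once", {
  st <- tiny_study()
  dec <- tiny_decoder()
  ev <- 1:200
  rko <- knockout_analysis(dec, st$windows, "region", eval_idx = ev)
  knocked <- unlist(lapply(split(st$rates$units$unit_id,
                                 st$rates$units$region), identity))
  expect_setequal(knocked, dec$unit_ids)
  # per-region n_units sum to the population size
  expect_equal(sum(rko$n_units[!duplicated(rko$target)]),
               length(dec$unit_ids))
  expect_error(knockout_eval(dec, st$windows, integer(0)), "nonempty")
  expect_error(knockout_eval(dec, st$windows, 999L), "unknown unit")
})

test_that("knockout results are invariant to group enumeration order", {
  st <- tiny_study()
  dec <- tiny_decoder()
  g <- st$rates$units$unit_id[st$rates$units$region == "occipital"]
  a <- knockout_eval(dec, st$windows, g, eval_idx = 1:150)
  b <- knockout_eval(dec, st$windows, rev(g), eval_idx = 1:150)
  expect_equal(a$delta_kld, b$delta_kld)
  expect_equal(a$normalized, a$delta_kld / a$n_units)
  # mean imputation is a milder perturbation than zeroing tuned units
  m <- knockout_eval(dec, st$windows, g, eval_idx = 1:150,
                     impute = "mean")
  expect_true(all(is.finite(m$delta_kld)))
  expect_lte(mean(m$delta_kld), mean(a$delta_kld) + 0.05)
})

test_that("a single-electrode region has exactly zero synergy", {
  st <- tiny_study()
  dec <- tiny_decoder()
  # collapse the hippocampus units onto one electrode
  dec2 <- dec
  dec2$units$electrode_id[dec2$units$region == "hippocampus"] <- 1L
  ws <- st$windows
  ws$rates$units$electrode_id[ws$rates$units$region == "hippocampus"] <- 1L
  ev <- 1:150
  rko <- knockout_analysis(dec2, ws, "region", eval_idx = ev)
  eko <- knockout_analysis(dec2, ws, "electrode", eval_idx = ev)
  syn <- synergy_statistic(rko[rko$region == "hippocampus", ],
                           eko[eko$region == "hippocampus", ])
  expect_equal(syn$values$synergy, rep(0, 4))
})

test_that("synergy refuses mismatched evaluation sets or missing electrodes", {
  st <- tiny_study()
  dec <- tiny_decoder()
  rko <- knockout_analysis(dec, st$windows, "region", eval_idx = 1:100)
  eko <- knockout_analysis(dec, st$windows, "electrode", eval_idx = 1:99)
  expect_error(synergy_statistic(rko, eko), "different evaluation sets")
  eko2 <- knockout_analysis(dec, st$windows, "electrode", eval_idx = 1:100)
  drop_one <- eko2[eko2$target != eko2$target[1], ]
  attr(drop_one, "baseline") <- attr(eko2, "baseline")
  expect_error(synergy_statistic(rko, drop_one), "cover region")
})

test_that("the uniquely informative region ranks first by normalized loss", {
  gains <- matrix(1, 24, 4)
  for (u in 1:8) gains[u, ((u - 1) %% 4) + 1] <- 3
  pop <- population_spec(4, regions = c("occipital", "frontal", "parietal"),
                         units_per_region = 8, baseline_hz = c(2, 6),
                         gains = gains, seed = 1)
  st <- simulate_study(timeline_config(duration_s = 600, prevalence = 0.15),
                       pop, seed = 1, artifact_screen = FALSE)
  dec <- fit_decoder(st$windows, "lstm", hidden = 16, fc_dim = 16,
                     epochs = 3, lr = 2e-3, fold_subset = 1,
                     train_max = 2000, val_max = 400, test_max = 400,
                     seed = 1)
  ev <- seq(1, length(st$windows$centre), by = 4)
  rko <- knockout_analysis(dec, st$windows, "region", eval_idx = ev)
  agg <- tapply(rko$normalized, rko$region, mean)
  expect_equal(names(which.max(agg)), "occipital")
})

test_that("split retraining enforces balance and shares fold plans", {
  st <- tiny_study()   # 8 occipital vs 4 hippocampus units: unbalanced
  expect_error(
    split_retrain(st$rates, st$labels, "occipital", arch = "lstm"),
    "unbalanced")
  # a balanced split trains two decoders on identical folds
  st2 <- simulate_study(timeline_config(duration_s = 240, prevalence = 0.2),
                        population_spec(4, regions = c("occipital",
                                                       "frontal"),
                                        units_per_region = 6, gain = 4,
                                        tuned_fraction = 1, seed = 1),
                        seed = 2, artifact_screen = FALSE)
  out <- split_retrain(st2$rates, st2$labels, "occipital", arch = "lstm",
                       hidden = 6, fc_dim = 6, epochs = 1, fold_subset = 1,
                       train_max = 300, val_max = 80, test_max = 100,
                       seed = 1)
  expect_identical(out$important$folds, out$rest$folds)
  expect_length(out$f1_important, 4)
  expect_length(out$f1_rest, 4)
})

test_that("binomial importance summaries reproduce exact intervals", {
  ci <- clopper_pearson(3, 8)
  expect_equal(round(unname(ci), 2), c(37.50, 8.52, 75.51))
  # zero successes pin the lower bound at 0
  expect_equal(unname(clopper_pearson(0, 8)["ci_lo"]), 0)
  vals <- c(0.6, 0.7, 0.2, 0.9, 0.1, 0.4, 0.3, 0.55)
  s <- summarize_importance(vals, rep("occipital", 8), threshold = 0.5)
  expect_equal(s$k, 4)
  expect_equal(s$percent, 50)
  expect_equal(unname(round(as.numeric(
    s[, c("ci_lo", "ci_hi")]), 2)), c(15.70, 84.30))
})
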