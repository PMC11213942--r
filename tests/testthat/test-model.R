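# small data sets for fast fitting tests
linear_growth_records <- function(n = 30, stages = 4, step = 0.1) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    h1 <- 0.2 + 0.5 * (i - 1) / max(1, n - 1)
    h <- h1 + step * (seq_len(stages) - 1)
    data.frame(plant_id = i, date_index = seq_len(stages),
               height = h, crown_area = pi * (0.3 * h)^2)
  }))
}

test_that("dataset splitting is by plant with largest-remainder rounding", {
  rec <- generate_growth_dataset(100, seed = 1)
  s <- split_dataset(rec, c(0.6, 0.2, 0.2), seed = 3)
  ids <- attr(s, "plant_ids")
  expect_equal(lengths(ids), c(train = 60, val = 20, test = 20))
  expect_length(intersect(ids$train, ids$test), 0)
  expect_length(intersect(ids$train, ids$val), 0)
  # a plant's series never straddles splits
  expect_true(all(table(rec$plant_id[rec$plant_id %in% as.numeric(ids$train)]) == 4))

  rec101 <- generate_growth_dataset(101, seed = 1)
  s101 <- split_dataset(rec101, c(0.6, 0.2, 0.2), seed = 3)
  expect_equal(lengths(attr(s101, "plant_ids")), c(train = 61, val = 20, test = 20))

  s2 <- split_dataset(rec, c(0.6, 0.2, 0.2), seed = 3)
  expect_identical(attr(s, "plant_ids"), attr(s2, "plant_ids"))
  expect_error(split_dataset(rec[rec$plant_id <= 4, ]), "at least 5")
  expect_error(split_dataset(rec, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("training converges on noiseless linear growth", {
  rec <- linear_growth_records(30)
  set.seed(80)
  m <- init_model(hidden = 16, fcn_units = 8)
  fit <- train_model(m, rec, epochs = 400, batch_size = 10,
                     learning_rate = 3e-3, seed = 80)
  expect_lt(utils::tail(fit$history$train_loss, 1), 1e-3)
  # a held-in prediction lands near the linear continuation
  s1 <- rec[rec$plant_id == 15 & rec$date_index <= 3, ]
  pred <- predict_next(fit$model, s1)
  truth <- rec$height[rec$plant_id == 15 & rec$date_index == 4]
  expect_lt(abs(pred$height - truth) / truth, 0.05)
})

test_that("constant series are predicted to within 2 percent", {
  rec <- do.call(rbind, lapply(1:20, function(i)
    data.frame(plant_id = i, date_index = 1:4,
               height = 0.4 + 0.01 * i, crown_area = 0.1 + 0.002 * i)))
  set.seed(81)
  m <- init_model(hidden = 16, fcn_units = 8)
  fit <- train_model(m, rec, epochs = 300, batch_size = 10,
                     learning_rate = 3e-3, seed = 81)
  s <- rec[rec$plant_id == 10 & rec$date_index <= 3, ]
  pred <- predict_next(fit$model, s)
  expect_lt(abs(pred$height - 0.5) / 0.5, 0.02)
  expect_lt(abs(pred$crown_area - 0.12) / 0.12, 0.02)
})

test_that("seeded training is bit-reproducible", {
  rec <- generate_growth_dataset(40, seed = 5)
  run <- function() {
    m <- init_model(hidden = 8, fcn_units = 4, seed = 82)
    train_model(m, rec, epochs = 30, batch_size = 20, seed = 82)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("prediction validates series length and positivity", {
  rec <- generate_growth_dataset(20, seed = 6)
  set.seed(83)
  m <- init_model(hidden = 4, fcn_units = 2)
  fit <- train_model(m, rec, epochs = 5, batch_size = 20, seed = 83)
  s <- rec[rec$plant_id == 1, ]
  expect_error(predict_next(fit$model, s), "input length")
  bad <- s[1:3, ]; bad$crown_area[2] <- 0
  expect_error(predict_next(fit$model, bad), "crown_area > 0")
  expect_error(predict_next(init_model(), s[1:3, ]), "not been trained")
  # bias-only model predicts the same record for every plant
  z <- zero_model(fit$model)
  z$params$final$b <- c(0.5, 0.5)
  p1 <- predict_next(z, rec[rec$plant_id == 1 & rec$date_index <= 3, ])
  p2 <- predict_next(z, rec[rec$plant_id == 7 & rec$date_index <= 3, ])
  expect_equal(p1$height, p2$height)
  expect_equal(p1$crown_area, p2$crown_area)
})

test_that("the fitted forecaster exposes the standard S3 surface", {
  rec <- generate_growth_dataset(60, noise_sd = 0.03, seed = 7)
  fit <- temporal_cropnet(rec, hidden = 12, fcn_units = 6, epochs = 60,
                          batch_size = 20, seed = 7)
  expect_s3_class(fit, "temporal_cropnet")
  expect_output(print(fit), "temporal_cropnet fit")
  expect_output(summary(fit), "SMAPE")
  expect_named(fit$test_eval, c("height", "crown_area"))
  expect_type(coef(fit), "list")
  r <- residuals(fit)
  expect_equal(colnames(r), c("height", "crown_area"))
  expect_equal(nrow(r), length(fit$split$train))
  f <- fitted(fit)
  expect_true(all(f$date_index == 4))
  pr <- predict(fit, rec[rec$plant_id %in% 1:5 & rec$date_index <= 3, ])
  expect_equal(nrow(pr), 5)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("shuffling training targets destroys predictive skill", {
  rec <- generate_growth_dataset(80, noise_sd = 0.03, seed = 9)
  fit <- temporal_cropnet(rec, hidden = 16, fcn_units = 8, epochs = 400,
                          batch_size = 25, learning_rate = 3e-3, seed = 9)
  smape_good <- fit$test_eval$height$smape_percent

  # permute the target-stage records across plants (by plant, seeded)
  shuf <- rec
  set.seed(99)
  t4 <- which(shuf$date_index == 4)
  perm <- sample(t4)
  shuf$height[t4] <- rec$height[perm]
  shuf$crown_area[t4] <- rec$crown_area[perm]
  fit_shuf <- temporal_cropnet(shuf, hidden = 16, fcn_units = 8, epochs = 400,
                               batch_size = 25, learning_rate = 3e-3, seed = 9)
  # evaluate the shuffled-target model against the TRUE targets
  sets <- split_dataset(rec, c(0.6, 0.2, 0.2), seed = 9)
  ev <- evaluation_report(predict(fit_shuf, sets$test[sets$test$date_index <= 3, ]),
                          sets$test[sets$test$date_index == 4, ], "height")
  expect_gte(ev$smape_percent, 3 * smape_good)
})

test_that("cross-validation partitions plants once each and reproduces", {
  rec <- generate_growth_dataset(40, noise_sd = 0, seed = 10)
  cv <- cross_validate(rec, cv_folds = 5, seed = 11, hidden = 12,
                       fcn_units = 6, epochs = 400, batch_size = 16,
                       learning_rate = 3e-3)
  expect_length(cv$folds, 5)
  expect_equal(sort(as.integer(names(cv$fold_assignment))), 1:40)
  expect_equal(unname(table(cv$fold_assignment)), rep(8L, 5),
               ignore_attr = TRUE)
  # noiseless logistic growth: folds learn it to a tight error
  expect_lt(cv$mean_smape[["height"]], 2)
  # fold membership and results reproduce under the seed (cheap config)
  cva <- cross_validate(rec, cv_folds = 5, seed = 11, hidden = 4,
                        fcn_units = 2, epochs = 25, batch_size = 16)
  cvb <- cross_validate(rec, cv_folds = 5, seed = 11, hidden = 4,
                        fcn_units = 2, epochs = 25, batch_size = 16)
  expect_identical(cva$fold_assignment, cvb$fold_assignment)
  expect_equal(cva$mean_smape, cvb$mean_smape)
  expect_output(print(cv), "cross-validation")
})

test_that("model checkpoints round-trip through JSON", {
  rec <- generate_growth_dataset(20, seed = 12)
  set.seed(84)
  m <- init_model(hidden = 6, fcn_units = 3)
  fit <- train_model(m, rec, epochs = 10, batch_size = 20, seed = 84)
  f <- tempfile(fileext = ".json")
  save_model(fit$model, f)
  back <- load_model(f)
  s <- rec[rec$plant_id == 3 & rec$date_index <= 3, ]
  expect_equal(predict_next(back, s), predict_next(fit$model, s),
               tolerance = 1e-12)
  expect_error(suppressWarnings(load_model(tempfile())))
})
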