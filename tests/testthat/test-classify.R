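test_that("Gaussian naive Bayes fitting matches closed-form estimates", {
  x <- cbind(c(0, 0, 1, 1))
  fit <- gnb_fit(x, c(0, 0, 1, 1))
  expect_equal(unname(fit$mean[, 1]), c(0, 1))
  expect_equal(unname(fit$priors), c(0.5, 0.5))
  set.seed(5)
  x <- matrix(stats::rnorm(50 * 4, sd = 2), 50, 4)
  y <- rep(c(0, 1), 25)
  fit <- gnb_fit(x, y)
  for (k in 1:2) {
    cl <- c(0, 1)[k]
    expect_equal(unname(fit$mean[k, ]), colMeans(x[y == cl, ]))
    expect_equal(unname(fit$var[k, ]), apply(x[y == cl, ], 2, var))
  }
  expect_equal(unname(fit$priors), c(mean(y == 0), mean(y == 1)))
  # constant feature: variance floored, prediction still finite
  xc <- cbind(x, 0.3183)
  fitc <- gnb_fit(xc, y)
  expect_true(all(fitc$var > 0))
  expect_false(any(is.na(gnb_predict(fitc, xc[1, ]))))
  expect_error(gnb_fit(x, rep(0, 50)), "class")
})

test_that("naive Bayes prediction follows the product rule", {
  fit <- gnb_fit(rbind(c(0, 0), c(0.2, 0.2), c(1, 1), c(0.8, 0.8)),
                 c(0, 0, 1, 1))
  # exactly symmetric classes, midpoint input: 0.5 / 0.5
  p <- gnb_predict(fit, c(0.5, 0.5))
  expect_equal(p$p_irregular, 0.5)
  # log-domain result equals the direct product of densities times priors
  x <- c(0.2, 0.7)
  direct <- vapply(1:2, function(k) {
    fit$priors[k] * prod(stats::dnorm(x, fit$mean[k, ], sqrt(fit$var[k, ])))
  }, numeric(1))
  direct <- direct / sum(direct)
  p <- gnb_predict(fit, x)
  expect_equal(c(p$p_irregular, p$p_regular), unname(direct), tolerance = 1e-9)
  expect_equal(p$p_irregular + p$p_regular, 1)
  # input at a tight class mean is recognized with near certainty
  set.seed(8)
  x2 <- rbind(matrix(stats::rnorm(40, 0, 0.05), 20), matrix(stats::rnorm(40, 3, 0.05), 20))
  fit2 <- gnb_fit(x2, rep(c(0, 1), each = 20))
  expect_gt(gnb_predict(fit2, c(0, 0))$p_irregular, 0.99)
  expect_error(gnb_predict(fit2, c(1, 2, 3)), "features")
})

test_that("the CNN trains deterministically and reduces its loss", {
  ds <- make_dataset(6, 6, seed = 31, size = 64)
  imgs <- lapply(ds, function(s) s$mask * 255)
  brds <- lapply(ds, mask_border_map)
  feats <- suppressWarnings(as.matrix(lesion_features(ds)[, 2:28]))
  labs <- vapply(ds, `[[`, integer(1), "label")
  spec <- cnn_spec(input_size = 64, filters = c(4, 8, 8, 16, 16),
                   dense_units = 16, epochs = 3, seed = 12)
  mod <- cnn_train(imgs, brds, feats, labs, spec)
  expect_lt(mod$loss_history[3], mod$loss_history[1])
  p <- cnn_predict(mod, imgs, brds, feats)
  expect_true(all(p$p_regular > 0 & p$p_regular < 1))
  expect_equal(p$p_irregular + p$p_regular, rep(1, 12))
  # repeat training with the same seed: identical weights and predictions
  mod2 <- cnn_train(imgs, brds, feats, labs, spec)
  expect_identical(mod$weights, mod2$weights)
  expect_identical(p, cnn_predict(mod2, imgs, brds, feats))
  bad <- imgs
  bad[[1]] <- matrix(0, 32, 32)
  expect_error(cnn_train(bad, brds, feats, labs, spec), "sizes")
})

test_that("the CNN separates well-separated synthetic classes", {
  train <- make_dataset(10, 10, seed = 61, size = 64)
  test <- make_dataset(5, 5, seed = 62, size = 64)
  prep <- function(ds) {
    list(imgs = lapply(ds, function(s) s$mask * 255),
         brds = lapply(ds, mask_border_map),
         feats = suppressWarnings(as.matrix(lesion_features(ds)[, 2:28])),
         labs = vapply(ds, `[[`, integer(1), "label"))
  }
  tr <- prep(train)
  te <- prep(test)
  spec <- cnn_spec(input_size = 64, filters = c(8, 8, 16, 16, 32),
                   dense_units = 16, epochs = 5, seed = 3)
  mod <- cnn_train(tr$imgs, tr$brds, tr$feats, tr$labs, spec)
  p <- cnn_predict(mod, te$imgs, te$brds, te$feats)
  acc <- mean(as.integer(p$p_regular >= 0.5) == te$labs)
  expect_gte(acc, 0.8)
})

test_that("ensemble fusion follows its exact arithmetic and bounds", {
  expect_equal(ensemble_score(c(0.8, 0.2), c(0.9, 0.1)), 0.37)
  expect_equal(ensemble_score(c(0.5, 0.5), c(0.5, 0.5)), 0.25)
  expect_equal(ensemble_score(c(1, 0), c(1, 0)), 0.5)
  expect_equal(ensemble_score(c(0, 1), c(0, 1)), 0.5)
  set.seed(4)
  p1 <- stats::runif(50)
  p2 <- stats::runif(50)
  s <- ensemble_score(cbind(p1, 1 - p1), cbind(p2, 1 - p2))
  expect_true(all(s >= 0 & s <= 0.5))
  expect_error(ensemble_score(c(0.7, 0.2), c(0.5, 0.5)), "sum to 1")
})

test_that("the adaptive threshold and decision rule branch as specified", {
  expect_equal(decision_threshold(c(0.2, 0.4, 0.6)), 0.5)
  expect_equal(decision_threshold(rep(0.3, 5)), 0.3)
  set.seed(6)
  s <- stats::runif(20, 0, 0.5)
  expect_gte(decision_threshold(s), mean(s))
  expect_error(decision_threshold(numeric(0)), "nonempty")
  expect_equal(decide(0.3, 0.5), "regular")
  expect_equal(decide(0.7, 0.5), "irregular")
  expect_equal(decide(0.5, 0.5), "irregular") # tie policy
})

test_that("evaluation reproduces the published confusion arithmetic", {
  # 40 irregular (3 called regular), 7 regular (all correct)
  decisions <- c(rep("irregular", 37), rep("regular", 3), rep("regular", 7))
  labels <- c(rep(0, 40), rep(1, 7))
  m <- evaluate(decisions, labels)
  expect_equal(round(m$accuracy, 1), 93.6)
  expect_equal(round(m$sensitivity, 1), 100)
  expect_equal(round(m$specificity, 1), 92.5)
  expect_equal(round(m$f_score, 1), 96.1)
  expect_equal(sum(m$confusion), 47)
  perfect <- evaluate(rep(c("regular", "irregular"), 5), rep(c(1, 0), 5))
  expect_equal(perfect$accuracy, 100)
  expect_error(evaluate(c("regular"), c(2)), "labels")
  m1 <- make_regular_lesion(size = 128, axes = c(30, 30), seed = 1)$mask
  expect_equal(jaccard_index(m1, m1), 100)
  expect_equal(jaccard_index(m1, 1 - m1), 0)
})

test_that("tidiers expose model internals as tibbles", {
  set.seed(5)
  x <- matrix(stats::rnorm(40), 20, 2)
  fit <- gnb_fit(x, rep(c(0, 1), 10))
  td <- tidy(fit)
  expect_equal(nrow(td), 4L)
  expect_equal(names(td), c("class", "feature", "mean", "variance"))
  expect_equal(glance(fit)$n, 20L)
  m <- evaluate(rep(c("regular", "irregular"), 5), rep(c(1, 0), 5))
  expect_equal(sum(tidy(m)$count), 10L)
  expect_equal(glance(m)$accuracy, 100)
})

test_that("naive Bayes probabilities agree with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(14)
  x <- rbind(matrix(stats::rnorm(60, 0), 30), matrix(stats::rnorm(60, 1.5), 30))
  colnames(x) <- c("f1", "f2")
  y <- rep(c(0, 1), each = 30)
  fit <- gnb_fit(x, y)
  ref <- e1071::naiveBayes(x, factor(y))
  xt <- rbind(c(0.3, 0.8), c(1.2, 0.1), c(0.75, 0.75))
  colnames(xt) <- colnames(x)
  p_ref <- predict(ref, xt, type = "raw")
  p <- gnb_predict(fit, xt)
  expect_equal(p$p_irregular, unname(p_ref[, "0"]), tolerance = 1e-6)
})
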