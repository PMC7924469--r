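#' Fit a Gaussian naive Bayes border classifier
#'
#' Estimates, per class and per feature, the sample mean and variance of a
#' Gaussian likelihood, plus class priors from the label frequencies. Class 1
#' in all probability outputs is *irregular* (label 0) and class 2 is
#' *regular* (label 1). Variances are floored at `1e-9` times the largest
#' overall feature variance so constant features (such as the order-0 Zernike
#' magnitude) cannot produce degenerate densities.
#'
#' @param x Feature matrix or data frame, one row per lesion (27 columns for
#'   the standard descriptor; any width is accepted).
#' @param y Labels: 1 = regular, 0 = irregular; at least two samples of each.
#' @return A `gnb_model` with `priors`, `mean`, `var` (class x feature), and
#'   the feature names.
#' @examples
#' x <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 3), 10))
#' fit <- gnb_fit(x, rep(c(0, 1), each = 10))
#' fit$priors
#' @export
gnb_fit <- function(x, y) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) abort("labels must be 0 (irregular) or 1 (regular)")
  if (length(y) != nrow(x)) abort("x and y lengths differ")
  if (min(table(factor(y, levels = c(0, 1)))) < 2L) {
    abort("need at least 2 samples in each class")
  }
  classes <- c(irregular = 0L, regular = 1L)
  per_class <- function(fun) {
    res <- vapply(classes, fun, numeric(ncol(x)))
    m <- if (is.matrix(res)) t(res) else matrix(res, nrow = 2L)
    rownames(m) <- names(classes)
    m
  }
  mu <- per_class(function(cl) colMeans(x[y == cl, , drop = FALSE]))
  v <- per_class(function(cl) apply(x[y == cl, , drop = FALSE], 2L, stats::var))
  floor_v <- 1e-9 * max(apply(x, 2L, stats::var), 1e-3)
  v <- pmax(v, floor_v)
  structure(
    list(priors = c(irregular = mean(y == 0L), regular = mean(y == 1L)),
         mean = mu, var = v, features = colnames(x), n = nrow(x)),
    class = "gnb_model"
  )
}

#' @export
print.gnb_model <- function(x, ...) {
  cat(sprintf("<gnb_model> %d features, priors: irregular %.3f / regular %.3f (n = %d)\n",
              ncol(x$mean), x$priors[["irregular"]], x$priors[["regular"]], x$n))
  invisible(x)
}

#' Predict class probabilities with Gaussian naive Bayes
#'
#' Per-class product of the Gaussian feature likelihoods times the prior,
#' evaluated in the log domain and normalized to sum to 1 (the evidence term
#' is constant across classes and cancels).
#'
#' @param model A [gnb_fit()] result.
#' @param x A feature vector or a matrix/data frame of rows to score.
#' @return A tibble with columns `p_irregular`, `p_regular` (rows sum to 1).
#' @export
gnb_predict <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$mean)) {
    abort(sprintf("expected %d features, got %d", ncol(model$mean), ncol(x)))
  }
  loglik <- vapply(1:2, function(k) {
    mu <- model$mean[k, ]
    sd <- sqrt(model$var[k, ])
    rowSums(matrix(stats::dnorm(t(x), mu, sd, log = TRUE), ncol = ncol(x),
                   byrow = TRUE)) + log(model$priors[k])
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) loglik <- matrix(loglik, 1L)
  mx <- apply(loglik, 1L, max)
  p <- exp(loglik - mx)
  p <- p / rowSums(p)
  tibble::tibble(p_irregular = p[, 1L], p_regular = p[, 2L])
}

#' Train the CNN border classifier
#'
#' Trains the compact convolutional network described by [cnn_spec()] on
#' stacked (smoothed segmented image, border map) inputs with the 27-value
#' irregularity descriptor as auxiliary input, using binary cross-entropy and
#' Adam from a fixed seed. The sigmoid output is read as the probability of a
#' *regular* border (label 1 = regular).
#'
#' @param images List of grayscale matrices (smoothed segmented lesions), all
#'   the same size.
#' @param borders List of binary border maps, same length and sizes.
#' @param features Numeric matrix (n x 27) of irregularity descriptors.
#' @param labels Numeric/integer labels, 1 = regular, 0 = irregular.
#' @param spec A [cnn_spec()].
#' @return A `cnn_model` carrying the learned weights, the feature
#'   standardization, and the per-epoch training `loss_history`.
#' @export
cnn_train <- function(images, borders, features, labels, spec = cnn_spec()) {
  n <- length(images)
  if (n == 0L) abort("empty training set")
  if (length(borders) != n || nrow(features) != n || length(labels) != n) {
    abort("images, borders, features and labels must have matching lengths")
  }
  dims <- unique(vapply(images, function(m) paste(dim(m), collapse = "x"), ""))
  if (length(dims) != 1L) {
    abort(sprintf("inconsistent image sizes: %s", paste(dims, collapse = ", ")))
  }
  features <- as.matrix(features)
  y <- as.numeric(labels)
  old <- .Random.seed_exists()
  set.seed(spec$seed)
  ctr <- colMeans(features)
  scl <- apply(features, 2L, stats::sd)
  scl[scl < 1e-12] <- 1
  fstd <- sweep(sweep(features, 2L, ctr), 2L, scl, "/")
  model <- cnn_init(spec)
  opt <- adam_state(model)
  x_all <- cnn_stack_inputs(images, borders, spec$input_size)
  losses <- numeric(spec$epochs)
  for (ep in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = spec$batch_size)) {
      idx <- ord[start:min(start + spec$batch_size - 1L, n)]
      xb <- x_all[, , , idx, drop = FALSE]
      fb <- fstd[idx, , drop = FALSE]
      yb <- y[idx]
      fwd <- cnn_forward(model, xb, fb, keep = TRUE)
      eps <- 1e-12
      ep_loss <- ep_loss - sum(yb * log(fwd$s + eps) + (1 - yb) * log(1 - fwd$s + eps))
      g <- cnn_backward(model, fwd, yb)
      res <- cnn_apply_grads(model, g, opt, spec$lr)
      model <- res$model
      opt <- res$opt
    }
    losses[ep] <- ep_loss / n
  }
  .restore_seed(old)
  structure(
    list(weights = model, spec = spec, feat_center = ctr, feat_scale = scl,
         loss_history = losses),
    class = "cnn_model"
  )
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %d conv layers (%s filters), input %dx%dx2, final loss %.4f\n",
              length(x$spec$filters), paste(x$spec$filters, collapse = "/"),
              x$spec$input_size, x$spec$input_size,
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Predict class probabilities with the CNN
#'
#' Runs the trained network and converts the sigmoid output `s = p(regular)`
#' into the class pair `(1 - s, s)`.
#'
#' @param model A [cnn_train()] result.
#' @param images,borders A matrix each (single lesion) or lists of matrices.
#' @param features The 27-value descriptor (vector) or matrix of rows.
#' @return A tibble with `p_irregular`, `p_regular`, one row per sample.
#' @export
cnn_predict <- function(model, images, borders, features) {
  if (is.matrix(images)) images <- list(images)
  if (is.matrix(borders)) borders <- list(borders)
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  features <- as.matrix(features)
  fstd <- sweep(sweep(features, 2L, model$feat_center), 2L, model$feat_scale, "/")
  n <- length(images)
  s <- numeric(n)
  bs <- model$spec$batch_size
  for (start in seq(1L, n, by = bs)) {
    idx <- start:min(start + bs - 1L, n)
    xb <- cnn_stack_inputs(images[idx], borders[idx], model$spec$input_size)
    s[idx] <- cnn_forward(model$weights, xb, fstd[idx, , drop = FALSE])$s
  }
  tibble::tibble(p_irregular = 1 - s, p_regular = s)
}

#' Ensemble probability of two classifiers
#'
#' Fuses the CNN and Gaussian naive Bayes class probabilities into the score
#' \deqn{P = (CNN_{p1} GnB_{p1} + CNN_{p2} GnB_{p2}) / 2,}
#' where class 1 is irregular and class 2 regular. `P` lies in `[0, 0.5]` and
#' attains 0.5 exactly when both models agree with certainty.
#'
#' @param cnn_p,gnb_p Probability pairs `(p_irregular, p_regular)`: length-2
#'   vectors, or two-column matrices/data frames scored row by row.
#' @return Numeric vector of fused scores.
#' @examples
#' ensemble_score(c(0.8, 0.2), c(0.9, 0.1)) # 0.37
#' @export
ensemble_score <- function(cnn_p, gnb_p) {
  as_pair <- function(p) {
    if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
    p <- as.matrix(p)
    if (ncol(p) != 2L) abort("probability input must have two columns")
    if (any(abs(rowSums(p) - 1) > 1e-6)) abort("class probabilities must sum to 1")
    p
  }
  a <- as_pair(cnn_p)
  b <- as_pair(gnb_p)
  if (nrow(a) != nrow(b)) abort("probability inputs must have matching rows")
  (a[, 1L] * b[, 1L] + a[, 2L] * b[, 2L]) / 2
}

#' Adaptive decision threshold over a score batch
#'
#' `threshold = (max(P) + mean(P)) / 2` over the batch of test scores; it
#' always lies at or above the batch mean.
#'
#' @param scores Nonempty numeric vector of ensemble scores.
#' @return Scalar threshold.
#' @examples
#' decision_threshold(c(0.2, 0.4, 0.6)) # 0.5
#' @export
decision_threshold <- function(scores) {
  if (length(scores) == 0L) abort("scores must be nonempty")
  (max(scores) + mean(scores)) / 2
}

#' Final border decision
#'
#' A score strictly below the threshold is called regular; above, irregular.
#' A score exactly at the threshold is called irregular (the costlier error is
#' calling an irregular border regular, so ties go to irregular).
#'
#' @param scores Numeric ensemble scores.
#' @param threshold Decision threshold (see [decision_threshold()]).
#' @return Character vector of `"regular"` / `"irregular"`.
#' @export
decide <- function(scores, threshold) {
  ifelse(scores < threshold, "regular", "irregular")
}

#' Classification metrics for border decisions
#'
#' Confusion counts and the standard rates for the regular/irregular decision
#' problem: accuracy, sensitivity (recall of the regular class), specificity
#' (recall of the irregular class), and the F-score with irregular as the
#' positive class — the convention under which all four rates are mutually
#' consistent for this task. All rates are percentages.
#'
#' @param decisions Character (`"regular"`/`"irregular"`) or numeric (1/0)
#'   predictions.
#' @param labels True labels: 1 = regular, 0 = irregular.
#' @return A `lesion_metrics` list with `confusion` (2 x 2 matrix,
#'   rows = truth), `accuracy`, `sensitivity`, `specificity`, `f_score`, `n`.
#' @examples
#' evaluate(c("regular", "irregular"), c(1, 0))$accuracy
#' @export
evaluate <- function(decisions, labels) {
  if (length(decisions) != length(labels)) abort("decisions and labels differ in length")
  if (is.character(decisions) || is.factor(decisions)) {
    decisions <- as.character(decisions)
    if (!all(decisions %in% c("regular", "irregular"))) {
      abort("decisions must be 'regular' or 'irregular'")
    }
    pred <- as.integer(decisions == "regular")
  } else {
    pred <- as.integer(decisions)
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)) || !all(pred %in% c(0L, 1L))) {
    abort("labels must be 1 = regular or 0 = irregular")
  }
  conf <- table(truth = factor(labels, levels = c(0, 1), labels = c("irregular", "regular")),
                predicted = factor(pred, levels = c(0, 1), labels = c("irregular", "regular")))
  conf <- unclass(conf)
  tp_irr <- conf["irregular", "irregular"]
  fn_irr <- conf["irregular", "regular"]
  fp_irr <- conf["regular", "irregular"]
  tp_reg <- conf["regular", "regular"]
  accuracy <- 100 * (tp_irr + tp_reg) / length(labels)
  sensitivity <- if (sum(labels == 1L) > 0) 100 * tp_reg / sum(labels == 1L) else NA_real_
  specificity <- if (sum(labels == 0L) > 0) 100 * tp_irr / sum(labels == 0L) else NA_real_
  precision_irr <- if (tp_irr + fp_irr > 0) tp_irr / (tp_irr + fp_irr) else NA_real_
  recall_irr <- if (tp_irr + fn_irr > 0) tp_irr / (tp_irr + fn_irr) else NA_real_
  f_score <- if (!is.na(precision_irr) && !is.na(recall_irr) &&
                 precision_irr + recall_irr > 0) {
    100 * 2 * precision_irr * recall_irr / (precision_irr + recall_irr)
  } else NA_real_
  structure(
    list(confusion = conf, accuracy = accuracy, sensitivity = sensitivity,
         specificity = specificity, f_score = f_score, n = length(labels)),
    class = "lesion_metrics"
  )
}

#' @export
print.lesion_metrics <- function(x, ...) {
  cat(sprintf("<lesion_metrics> n = %d\n", x$n))
  print(x$confusion)
  cat(sprintf("accuracy %.1f%% | sensitivity %.1f%% | specificity %.1f%% | F-score %.1f%%\n",
              x$accuracy, x$sensitivity, x$specificity, x$f_score))
  invisible(x)
}

#' Jaccard index of two binary masks
#'
#' Intersection over union, as a percentage: 100 means perfect agreement,
#' 0 means no overlap.
#'
#' @param a,b Binary matrices of equal size.
#' @return Scalar percentage.
#' @export
jaccard_index <- function(a, b) {
  a <- as_binary_mask(a)
  b <- as_binary_mask(b)
  if (!all(dim(a) == dim(b))) abort("masks must have equal dimensions")
  u <- sum(a | b)
  if (u == 0L) abort("both masks are empty")
  100 * sum(a & b) / u
}
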