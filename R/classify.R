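#' Specification of one classifier family
#'
#' The five families follow the study design: a decision tree capped at 5
#' splits (DT), linear discriminant analysis (LDA), k-nearest neighbours on
#' z-scored features (KNN), a Gaussian-kernel support vector machine on
#' z-scored features (SVM), and logistic-loss boosting of depth-1 trees
#' with 243 learning cycles at learning rate 0.59256 (BOOST).
#'
#' @param name one of `"dt"`, `"lda"`, `"knn"`, `"svm"`, `"boost"`.
#' @param params fixed hyperparameters.
#' @param normalize z-score the features (fitted on the training split).
#' @param search named list of searchable ranges, or `NULL`.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(name, params = list(), normalize = FALSE,
                       search = NULL) {
  name <- match.arg(name, c("dt", "lda", "knn", "svm", "boost"))
  if (!is.null(params$learning_rate) && params$learning_rate <= 0)
    abort_canegait("learning rate must be positive", "canegait_config_error")
  if (!is.null(params$n_rounds) && params$n_rounds < 1)
    abort_canegait("boosting cycles must be >= 1", "canegait_config_error")
  structure(list(name = name, params = params, normalize = normalize,
                 search = search),
            class = "model_spec")
}

#' The five default model specifications
#'
#' @param config a [default_run_config()]; its `models` entry supplies the
#'   fixed hyperparameters.
#' @return named list of [model_spec()] objects.
#' @export
default_model_specs <- function(config = default_run_config()) {
  m <- config$models
  list(
    dt = model_spec("dt", params = list(max_splits = m$dt$max_splits)),
    lda = model_spec("lda"),
    knn = model_spec("knn", params = list(k = m$knn$k), normalize = TRUE,
                     search = list(k = seq(1, 25, by = 2))),
    svm = model_spec("svm",
                     params = list(cost = m$svm$cost, gamma = m$svm$gamma),
                     normalize = TRUE,
                     search = list(log2_cost = c(-3, 7),
                                   log2_gamma = c(-9, 1))),
    boost = model_spec("boost",
                       params = list(n_rounds = m$boost$n_rounds,
                                     learning_rate = m$boost$learning_rate,
                                     max_depth = m$boost$max_depth)))
}

#' Fit and apply a z-score normalization
#'
#' Centre and scale (sample standard deviation, n - 1) are fitted on the
#' training features only and applied to both splits. Constant training
#' features map to zero in both outputs, with a warning.
#'
#' @param train training feature matrix / data frame.
#' @param newdata features to transform with the training parameters.
#' @return list with `train`, `newdata`, `center`, `scale`.
#' @export
zscore_fit_apply <- function(train, newdata = train) {
  train <- as.matrix(train)
  newdata <- as.matrix(newdata)
  if (nrow(train) == 0)
    abort_canegait("empty training split", "canegait_data_error")
  center <- colMeans(train)
  scale <- apply(train, 2, stats::sd)
  const <- !is.finite(scale) | scale == 0
  if (any(const)) {
    warning(sprintf("constant feature(s) mapped to 0: %s",
                    paste(colnames(train)[const], collapse = ", ")))
    scale[const] <- 1
  }
  tr <- sweep(sweep(train, 2, center), 2, scale, "/")
  nw <- sweep(sweep(newdata, 2, center), 2, scale, "/")
  tr[, const] <- 0
  nw[, const] <- 0
  list(train = tr, newdata = nw, center = center, scale = scale)
}

#' Assign trials to cross-validation folds
#'
#' `mode = "trial"` reproduces the study protocol: trials are split at
#' random into folds whose sizes differ by at most one, so trials from the
#' same subject can land in both training and test sets (the leakage-prone
#' design). `mode = "subject"` keeps all trials of a subject in a single
#' fold (the methodologically sound alternative), balancing fold sizes
#' greedily by trial count.
#'
#' @param n_trials number of trials.
#' @param n_folds number of folds (default 10).
#' @param mode `"trial"` or `"subject"`.
#' @param subject_ids required for subject mode: one id per trial.
#' @param seed integer seed.
#' @return integer fold index per trial (1..n_folds), class
#'   `fold_assignment` with `mode` and `seed` attributes.
#' @export
assign_folds <- function(n_trials, n_folds = 10, mode = c("trial", "subject"),
                         subject_ids = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (n_trials < n_folds)
    abort_canegait(sprintf("cannot split %d trials into %d folds",
                           n_trials, n_folds), "canegait_data_error")
  folds <- with_seed(seed, {
    if (mode == "trial") {
      sizes <- rep(n_trials %/% n_folds, n_folds)
      extra <- n_trials %% n_folds
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      sample(rep.int(seq_len(n_folds), sizes))
    } else {
      if (is.null(subject_ids) || length(subject_ids) != n_trials)
        abort_canegait("subject mode requires one subject_id per trial",
                       "canegait_data_error")
      counts <- table(subject_ids)
      subs <- sample(names(counts))          # shuffle, then largest first
      subs <- subs[order(-counts[subs])]
      load <- numeric(n_folds)
      sub_fold <- integer(length(subs))
      names(sub_fold) <- subs
      for (s in subs) {
        f <- which.min(load)
        sub_fold[s] <- f
        load[f] <- load[f] + counts[[s]]
      }
      unname(sub_fold[as.character(subject_ids)])
    }
  })
  structure(as.integer(folds), class = "fold_assignment",
            mode = mode, seed = seed)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy = (tp + tn) / total (one minus the misclassification rate),
#' precision = tp / (tp + fp), recall = tp / (tp + fn), F1 = harmonic mean
#' of precision and recall. Ratios with a zero denominator are reported as
#' `NA` (absent), never as zero. Counts need not be integers, so
#' fold-averaged matrices can be analysed too.
#'
#' @param tp,fp,fn,tn confusion counts for a declared positive class.
#' @return list with `accuracy`, `precision`, `recall`, `f1` (proportions
#'   in `[0, 1]`).
#' @export
metrics_from_confusion <- function(tp, fp, fn, tn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn); tn <- unname(tn)
  total <- tp + fp + fn + tn
  if (total <= 0)
    abort_canegait("empty confusion matrix", "canegait_data_error")
  if (min(tp, fp, fn, tn) < 0)
    abort_canegait("confusion counts must be non-negative",
                   "canegait_data_error")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(accuracy = (tp + tn) / total, precision = precision,
       recall = recall, f1 = f1)
}

#' ROC curve and AUC from continuous scores
#'
#' AUC is the probability that a randomly chosen positive instance
#' outscores a randomly chosen negative one, with ties counted one half
#' (the rank / trapezoidal form); it is invariant under strictly monotone
#' transforms of the scores. ROC points come from sweeping a threshold
#' over the distinct score values.
#'
#' @param scores continuous classifier scores (higher = more positive).
#' @param labels true labels.
#' @param positive the positive class label.
#' @return list with `auc` and `roc` (data frame of `fpr`, `tpr`,
#'   `threshold`).
#' @export
roc_auc <- function(scores, labels, positive = "frail") {
  pos <- labels == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    abort_canegait("both classes must be present to compute a ROC curve",
                   "canegait_data_error")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  keep <- c(diff(s) != 0, TRUE)    # last index of each distinct score
  tpr <- cumsum(p)[keep] / n_pos
  fpr <- cumsum(!p)[keep] / n_neg
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, s[keep]))
  list(auc = auc, roc = roc)
}

fit_score_model <- function(spec, xtr, ytr, xte, positive, seed = 1) {
  with_seed(seed, {
    switch(spec$name,
      dt = {
        df <- data.frame(y = factor(ytr), xtr, check.names = FALSE)
        fit <- rpart::rpart(y ~ ., data = df, method = "class",
                            control = rpart::rpart.control(
                              cp = 0, xval = 0, minsplit = 5,
                              maxcompete = 0, maxsurrogate = 0))
        cpt <- fit$cptable
        max_splits <- spec$params$max_splits %||% 5
        ok <- which(cpt[, "nsplit"] <= max_splits)
        if (length(ok) && max(cpt[, "nsplit"]) > max_splits) {
          i <- max(ok)
          cp_hi <- cpt[i, "CP"]
          cp_lo <- cpt[min(i + 1, nrow(cpt)), "CP"]
          fit <- rpart::prune(fit, cp = (cp_hi + cp_lo) / 2)
        }
        predict(fit, newdata = data.frame(xte, check.names = FALSE),
                type = "prob")[, positive]
      },
      lda = {
        fit <- MASS::lda(xtr, grouping = factor(ytr))
        predict(fit, newdata = xte)$posterior[, positive]
      },
      knn = {
        k <- spec$params$k %||% 5
        pred <- class::knn(train = xtr, test = xte, cl = factor(ytr),
                           k = k, prob = TRUE)
        pr <- attr(pred, "prob")
        ifelse(pred == positive, pr, 1 - pr)
      },
      svm = {
        gamma <- spec$params$gamma %||% (1 / ncol(xtr))
        fit <- e1071::svm(x = xtr, y = factor(ytr), kernel = "radial",
                          cost = spec$params$cost %||% 1, gamma = gamma,
                          probability = TRUE)
        pr <- attr(predict(fit, newdata = xte, probability = TRUE),
                   "probabilities")
        pr[, positive]
      },
      boost = {
        y01 <- as.integer(ytr == positive)
        dtr <- xgboost::xgb.DMatrix(as.matrix(xtr), label = y01)
        bst <- xgboost::xgb.train(
          params = list(objective = "binary:logistic",
                        max_depth = spec$params$max_depth %||% 1,
                        eta = spec$params$learning_rate %||% 0.59256,
                        nthread = 1),
          data = dtr, nrounds = spec$params$n_rounds %||% 243, verbose = 0)
        predict(bst, xgboost::xgb.DMatrix(as.matrix(xte)))
      })
  })
}

#' Train and evaluate one model under cross-validation
#'
#' Fits the model family on each training split (normalizing per split
#' when the spec requires it), scores the held-out fold with a continuous
#' score, and accumulates per-fold metrics, the aggregated confusion
#' matrix, and the pooled ROC. Fold-level metrics are averaged across
#' folds (undefined ratios are dropped from the average, not counted as
#' zero); metrics recomputed from the aggregated matrix are reported
#' alongside.
#'
#' @param x feature matrix / data frame.
#' @param y label vector.
#' @param spec a [model_spec()].
#' @param folds fold assignment from [assign_folds()].
#' @param positive positive class label.
#' @param seed integer seed for estimator-internal randomness.
#' @return object of class `cv_result`.
#' @export
train_eval_cv <- function(x, y, spec, folds, positive = "frail", seed = 1) {
  x <- as.matrix(x)
  y <- as.character(y)
  n_folds <- max(folds)
  fold_rows <- list()
  cm <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  pooled_scores <- numeric(length(y))

  for (f in seq_len(n_folds)) {
    te <- folds == f
    if (length(unique(y[!te])) < 2)
      abort_canegait(
        sprintf("training split for fold %d contains a single class; re-seed the fold assignment", f),
        "canegait_single_class_error")
    xtr <- x[!te, , drop = FALSE]
    xte <- x[te, , drop = FALSE]
    if (isTRUE(spec$normalize)) {
      z <- zscore_fit_apply(xtr, xte)
      xtr <- z$train
      xte <- z$newdata
    }
    sc <- fit_score_model(spec, xtr, y[!te], xte, positive,
                          seed = derive_seed(seed, spec$name, f))
    pooled_scores[te] <- sc
    pred_pos <- sc >= 0.5
    is_pos <- y[te] == positive
    k <- c(tp = sum(pred_pos & is_pos), fp = sum(pred_pos & !is_pos),
           fn = sum(!pred_pos & is_pos), tn = sum(!pred_pos & !is_pos))
    cm <- cm + k
    m <- metrics_from_confusion(k["tp"], k["fp"], k["fn"], k["tn"])
    auc_f <- if (length(unique(is_pos)) == 2)
      roc_auc(sc, y[te], positive)$auc else NA_real_
    fold_rows[[f]] <- data.frame(
      fold = f, n = sum(te), accuracy = m$accuracy,
      precision = m$precision, recall = m$recall, f1 = m$f1, auc = auc_f)
  }

  fold_metrics <- do.call(rbind, fold_rows)
  avg <- lapply(fold_metrics[c("accuracy", "precision", "recall", "f1",
                               "auc")],
                function(v) mean(v, na.rm = TRUE))
  pooled <- roc_auc(pooled_scores, y, positive)
  structure(
    list(model = spec$name, fold_metrics = fold_metrics, avg = avg,
         confusion = as.list(cm),
         confusion_metrics = metrics_from_confusion(cm["tp"], cm["fp"],
                                                    cm["fn"], cm["tn"]),
         roc = pooled$roc, pooled_auc = pooled$auc,
         positive = positive),
    class = "cv_result")
}

#' Randomized hyperparameter search under cross-validation
#'
#' Draws candidates from the spec's declared search ranges and keeps the
#' one minimizing the mean cross-validated misclassification rate (the
#' default configuration is always among the candidates, so the tuned loss
#' never exceeds the default's). Fixed study hyperparameters (DT split
#' cap, boosting cycles and learning rate) have no search space and are
#' returned unchanged. The search is evaluated on the same folds it
#' reports on (non-nested), matching the study protocol.
#'
#' @param spec a [model_spec()].
#' @param x,y features and labels.
#' @param folds fold assignment.
#' @param seed integer seed.
#' @param budget number of candidate configurations (>= 1).
#' @param positive positive class label.
#' @return the tuned `model_spec`, with attribute `cv_loss`.
#' @export
hyperparameter_search <- function(spec, x, y, folds, seed = 1, budget = 30,
                                  positive = "frail") {
  if (budget < 1)
    abort_canegait("search budget must be >= 1", "canegait_config_error")
  cand <- list(spec)
  if (!is.null(spec$search) && budget > 1) {
    cand <- c(cand, with_seed(derive_seed(seed, "hpsearch"), {
      lapply(seq_len(budget - 1), function(i) {
        s <- spec
        if (spec$name == "knn")
          s$params$k <- sample(spec$search$k, 1)
        if (spec$name == "svm") {
          s$params$cost <- 2^stats::runif(1, spec$search$log2_cost[1],
                                          spec$search$log2_cost[2])
          s$params$gamma <- 2^stats::runif(1, spec$search$log2_gamma[1],
                                           spec$search$log2_gamma[2])
        }
        s
      })
    }))
  }
  loss <- vapply(cand, function(s) {
    cv <- train_eval_cv(x, y, s, folds, positive = positive, seed = seed)
    1 - mean(cv$fold_metrics$accuracy)
  }, numeric(1))
  best <- cand[[which.min(loss)]]
  attr(best, "cv_loss") <- min(loss)
  best
}

#' Run the full five-model classification benchmark
#'
#' Assigns tenfold cross-validation folds, optionally tunes the searchable
#' hyperparameters (KNN's k; SVM's cost and kernel width), trains and
#' evaluates all five model families, and returns per-model results plus a
#' ranked summary table (fold-averaged accuracy, precision, recall, F1 as
#' percentages, and AUC).
#'
#' @param features feature-table data frame with labels.
#' @param config a [default_run_config()].
#' @param seed integer seed (defaults to `config$cv$seed`).
#' @param search run the randomized hyperparameter search.
#' @return object of class `cv_report`: list with `results` (per model),
#'   `summary` (data frame), `folds`.
#' @export
run_classification <- function(features, config = default_run_config(),
                               seed = NULL, search = TRUE) {
  seed <- seed %||% config$cv$seed
  positive <- config$positive_class
  x <- as.matrix(features[canegait_features()])
  y <- features$frail_label
  folds <- assign_folds(nrow(x), n_folds = config$cv$n_folds,
                        mode = config$cv$mode,
                        subject_ids = features$subject_id,
                        seed = derive_seed(seed, "folds"))
  specs <- default_model_specs(config)
  results <- lapply(specs, function(spec) {
    if (search && !is.null(spec$search))
      spec <- hyperparameter_search(spec, x, y, folds, seed = seed,
                                    budget = config$cv$search_budget,
                                    positive = positive)
    train_eval_cv(x, y, spec, folds, positive = positive, seed = seed)
  })
  summary <- do.call(rbind, lapply(results, function(res) {
    data.frame(model = toupper(res$model),
               accuracy_pct = 100 * res$avg$accuracy,
               precision_pct = 100 * res$avg$precision,
               recall_pct = 100 * res$avg$recall,
               f1_pct = 100 * res$avg$f1,
               auc = res$avg$auc,
               pooled_auc = res$pooled_auc)
  }))
  summary <- summary[order(-summary$accuracy_pct), ]
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary, folds = folds,
                 positive = positive, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Tenfold cross-validated frailty classification (positive: %s)\n",
              x$positive))
  df <- x$summary
  df[-1] <- lapply(df[-1], function(v) round(v, 3))
  print(df, row.names = FALSE)
  invisible(x)
}
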