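#' Stratified train/validation/test split
#'
#' One repeat of the hold-out protocol: a stratified random split takes
#' \code{testFrac} of the samples as the test set; the validation set is
#' \code{valFrac} (40 by default) percent of the remaining
#' training/validation pool. Partitions are disjoint, exhaustive, and
#' seeded by \code{(seed, repeatIndex)}. If any partition misses a class
#' the split is redrawn, up to 100 attempts.
#'
#' @param labels binary label vector (one per sample).
#' @param testFrac fraction held out for testing (0.2 or 0.5 in the
#'   standard protocols).
#' @param valFrac fraction of the train/validation pool used for
#'   validation (default 0.4).
#' @param seed integer seed.
#' @param repeatIndex repeat number folded into the seed (default 1).
#' @return list of integer index vectors \code{train}, \code{validation},
#'   \code{test}.
#' @export
splitHoldout <- function(labels, testFrac = 0.2, valFrac = 0.4, seed = 1L,
                         repeatIndex = 1L) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2L)
    stop("both classes must be present")
  stopifnot(testFrac > 0, testFrac < 1, valFrac > 0, valFrac < 1)
  for (attempt in seq_len(100L)) {
    parts <- withSeed(deriveSeed(seed, repeatIndex, attempt), {
      test <- integer(0); val <- integer(0); train <- integer(0)
      for (cl in classes) {
        idx <- sample(which(labels == cl))
        nTest <- round(testFrac * length(idx))
        rest <- idx[seq_len(length(idx) - nTest)]
        test <- c(test, idx[seq_len(nTest) + length(rest)])
        nVal <- round(valFrac * length(rest))
        val <- c(val, rest[seq_len(nVal)])
        train <- c(train, rest[seq_len(length(rest) - nVal) + nVal])
      }
      list(train = sort(train), validation = sort(val), test = sort(test))
    })
    ok <- all(vapply(parts, function(p)
      length(p) > 0 && length(unique(labels[p])) == length(classes),
      logical(1)))
    if (ok) return(parts)
  }
  stop("could not produce a split with all classes in every partition")
}

# F1 of predicted probabilities at threshold 0.5 for the positive class.
f1AtHalf <- function(prob, truth, positive) {
  pred <- ifelse(prob > 0.5, positive, paste0("not_", positive))
  truthPos <- ifelse(truth == positive, positive, paste0("not_", positive))
  met <- metricsFromCounts(oneVsAllCounts(truthPos, pred, positive))
  f <- met["F1"]
  if (is.na(f)) 0 else f
}

#' Tune and train one survival classifier
#'
#' Fits a binary STS-vs-LTS classifier on the training partition and picks
#' its single tuned hyper-parameter by maximising F1 on the validation
#' partition. For \code{"xgboost"} the tuned parameter is the maximum tree
#' depth over \code{depthGrid} (other boosting settings pinned: 100 rounds,
#' learning rate 0.3, binary logistic objective); ties prefer the smallest
#' depth. For \code{"lasso"}/\code{"ridge"} it is the penalty weight over
#' the regularisation path of a penalized logistic regression; ties prefer
#' the largest penalty. Lasso is pure L1 (alpha = 1), ridge pure L2
#' (alpha = 0), the standard glmnet convention.
#'
#' @param xTrain,yTrain training features (matrix) and labels.
#' @param xVal,yVal validation features and labels.
#' @param algorithm \code{"xgboost"}, \code{"lasso"} or \code{"ridge"}.
#' @param depthGrid candidate maximum depths for xgboost; default the
#'   standard grid c(2,4,6,8,10,12,14,16,18,20,30,40,50,60).
#' @param nrounds boosting rounds (default 100).
#' @param eta learning rate (default 0.3).
#' @param positive positive class for F1 (default \code{"STS"} when
#'   present, else first sorted label).
#' @param seed integer seed for the booster.
#' @return list with \code{model}, \code{algorithm}, \code{parameter} (the
#'   chosen depth or lambda), \code{validationF1}, \code{positive} and
#'   \code{predict}, a function mapping a feature matrix to positive-class
#'   probabilities.
#' @export
tuneAndTrain <- function(xTrain, yTrain, xVal, yVal,
                         algorithm = c("xgboost", "lasso", "ridge"),
                         depthGrid = defaultDepthGrid(), nrounds = 100L,
                         eta = 0.3, positive = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  yTrain <- as.character(yTrain); yVal <- as.character(yVal)
  if (length(unique(yTrain)) < 2L)
    stop("degenerate training labels: both classes required")
  if (is.null(positive))
    positive <- if ("STS" %in% yTrain) "STS" else sort(unique(yTrain))[1]
  if (algorithm == "xgboost") {
    dtr <- xgboost::xgb.DMatrix(as.matrix(xTrain),
                                label = as.numeric(yTrain == positive))
    fits <- lapply(depthGrid, function(d)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = d,
                      eta = eta, nthread = 1, seed = as.integer(seed)),
        data = dtr, nrounds = nrounds, verbose = 0))
    f1s <- vapply(seq_along(fits), function(i)
      f1AtHalf(stats::predict(fits[[i]], as.matrix(xVal)), yVal, positive),
      numeric(1))
    best <- which.max(f1s)   # grid ascending: ties resolve to smallest depth
    model <- fits[[best]]
    list(model = model, algorithm = algorithm,
         parameter = depthGrid[best], validationF1 = f1s[best],
         positive = positive,
         predict = function(x) as.numeric(
           stats::predict(model, as.matrix(x))))
  } else {
    alpha <- if (algorithm == "lasso") 1 else 0
    yf <- factor(yTrain, levels = c(setdiff(sort(unique(yTrain)), positive),
                                    positive))
    fit <- glmnet::glmnet(as.matrix(xTrain), yf, family = "binomial",
                          alpha = alpha, nlambda = 50)
    probs <- stats::predict(fit, as.matrix(xVal), type = "response")
    f1s <- unname(apply(probs, 2, f1AtHalf, truth = yVal,
                        positive = positive))
    best <- which.max(f1s)   # path descending: ties resolve to largest lambda
    lam <- fit$lambda[best]
    list(model = fit, algorithm = algorithm, parameter = lam,
         validationF1 = f1s[best], positive = positive,
         predict = function(x) as.numeric(
           stats::predict(fit, as.matrix(x), s = lam, type = "response")))
  }
}

#' The standard maximum-depth tuning grid
#'
#' @return integer vector c(2,4,...,20,30,40,50,60).
#' @export
defaultDepthGrid <- function() c(2L, 4L, 6L, 8L, 10L, 12L, 14L, 16L, 18L,
                                 20L, 30L, 40L, 50L, 60L)

#' Repeated hold-out protocol for one cell type
#'
#' Runs \code{nRepeats} independent cycles of stratified split, optional
#' SMOTE on the training partition only, hyper-parameter tuning on the
#' validation partition, and evaluation on the untouched test partition.
#' Per-repeat sensitivity, specificity, F1, accuracy and AUC are collected
#' together with their arithmetic means; fitted boosters are kept for
#' feature-importance aggregation.
#'
#' No information flows from test to train: SMOTE and tuning see only the
#' train/validation partitions.
#'
#' @param features a \linkS4class{CellTypeFeatures} or numeric matrix with
#'   sample ids as row names (masked samples are dropped).
#' @param labels named binary label vector (names = sample ids), or a
#'   survival table data.frame with \code{sample_id} and \code{group}.
#' @param nRepeats number of repeats (default 100; 1000 for importance
#'   runs).
#' @param testFrac test fraction (default 0.2; 0.5 variant supported).
#' @param valFrac validation fraction of the train/validation pool
#'   (default 0.4).
#' @param algorithm \code{"xgboost"}, \code{"lasso"} or \code{"ridge"}.
#' @param smoteRatio optional SMOTE target ratio string (e.g. \code{"1:1"});
#'   \code{NULL} disables rebalancing.
#' @param smoteK SMOTE neighbours (default 5).
#' @param depthGrid,nrounds,eta booster settings, see [tuneAndTrain()].
#' @param positive positive class (default \code{"STS"} when present).
#' @param seed integer seed; repeat r uses the derived seed (seed, r).
#' @param keepModels keep fitted models for [aggregateImportance()]
#'   (default \code{TRUE} for xgboost).
#' @return list with \code{perRepeat} (data.frame of per-repeat metrics and
#'   chosen parameter), \code{means} (named numeric), \code{models},
#'   \code{classifiersTrained} (= nRepeats), \code{featureNames},
#'   \code{positive}.
#' @export
repeatedProtocol <- function(features, labels, nRepeats = 100L,
                             testFrac = 0.2, valFrac = 0.4,
                             algorithm = c("xgboost", "lasso", "ridge"),
                             smoteRatio = NULL, smoteK = 5L,
                             depthGrid = defaultDepthGrid(), nrounds = 100L,
                             eta = 0.3, positive = NULL, seed = 1L,
                             keepModels = TRUE) {
  algorithm <- match.arg(algorithm)
  x <- if (is(features, "CellTypeFeatures")) featureValues(features)
       else as.matrix(features)
  if (is.data.frame(labels))
    labels <- stats::setNames(labels$group, labels$sample_id)
  if (is.null(rownames(x)) || is.null(names(labels)))
    stop("features need sample ids as row names and labels must be named")
  common <- intersect(rownames(x), names(labels))
  if (length(common) < 4L)
    stop("too few samples with both features and labels")
  x <- x[common, , drop = FALSE]
  y <- as.character(labels[common])
  if (is.null(positive))
    positive <- if ("STS" %in% y) "STS" else sort(unique(y))[1]
  negative <- setdiff(unique(y), positive)[1]
  perRepeat <- vector("list", nRepeats)
  models <- if (keepModels && algorithm == "xgboost")
    vector("list", nRepeats) else NULL
  for (r in seq_len(nRepeats)) {
    sp <- splitHoldout(y, testFrac = testFrac, valFrac = valFrac,
                       seed = seed, repeatIndex = r)
    xTr <- x[sp$train, , drop = FALSE]; yTr <- y[sp$train]
    if (!is.null(smoteRatio)) {
      sm <- smoteResample(xTr, yTr, ratio = smoteRatio, k = smoteK,
                          seed = deriveSeed(seed, r, 7L))
      xTr <- sm$x; yTr <- sm$y
    }
    fit <- tuneAndTrain(xTr, yTr, x[sp$validation, , drop = FALSE],
                        y[sp$validation], algorithm = algorithm,
                        depthGrid = depthGrid, nrounds = nrounds, eta = eta,
                        positive = positive, seed = deriveSeed(seed, r, 11L))
    prob <- fit$predict(x[sp$test, , drop = FALSE])
    yTest <- y[sp$test]
    pred <- ifelse(prob > 0.5, positive, negative)
    met <- metricsFromCounts(oneVsAllCounts(yTest, pred, positive))
    auc <- if (length(unique(yTest)) == 2L)
      aucScore(prob, yTest, positive = positive) else NA_real_
    perRepeat[[r]] <- data.frame(
      repeatIndex = r, parameter = fit$parameter,
      ACC = met["ACC"], SEN = met["SEN"], SPE = met["SPE"],
      F1 = met["F1"], AUC = auc, row.names = NULL)
    if (!is.null(models)) models[[r]] <- fit$model
  }
  perRepeat <- do.call(rbind, perRepeat)
  means <- colMeans(perRepeat[, c("ACC", "SEN", "SPE", "F1", "AUC")],
                    na.rm = TRUE)
  list(perRepeat = perRepeat, means = means, models = models,
       classifiersTrained = nRepeats, featureNames = colnames(x),
       positive = positive)
}

#' Cell-type-specific models over a whole cohort
#'
#' Drives [repeatedProtocol()] over a list of per-cell-type feature
#' matrices, as in the standard design of one independent classifier per
#' repeat and cell type (100 repeats x 7 cell types = 700 classifiers).
#'
#' @param featuresList named list of \linkS4class{CellTypeFeatures} (or
#'   matrices), one per cell type.
#' @param labels named label vector or survival table.
#' @param ... arguments passed on to [repeatedProtocol()].
#' @return list with \code{perCellType} (one protocol result per cell
#'   type), \code{classifiersTrained} (total across cell types), and
#'   \code{meanMetrics} (data.frame, one row per cell type).
#' @export
runCellTypeModels <- function(featuresList, labels, ...) {
  if (is.null(names(featuresList)))
    names(featuresList) <- vapply(featuresList, function(f)
      if (is(f, "CellTypeFeatures")) f@cellType else "?", character(1))
  res <- lapply(featuresList, repeatedProtocol, labels = labels, ...)
  meanMetrics <- do.call(rbind, lapply(names(res), function(ct)
    data.frame(cellType = ct, t(res[[ct]]$means), row.names = NULL)))
  list(perCellType = res,
       classifiersTrained = sum(vapply(res, `[[`, numeric(1),
                                       "classifiersTrained")),
       meanMetrics = meanMetrics)
}

#' Aggregate feature importance over repeated runs
#'
#' Summarises fitted boosters from a repeated protocol by, per feature, the
#' number of runs in which the feature was used in at least one split (the
#' selection count) and the mean gain over those runs. The output is sorted
#' by selection count, then mean gain, descending — the most frequently
#' selected, stable features first.
#'
#' @param models list of fitted xgboost models (from
#'   \code{repeatedProtocol(..., keepModels = TRUE)$models}).
#' @param featureNames feature names of the design matrix.
#' @return data.frame with columns \code{feature}, \code{selectionCount},
#'   \code{meanGain} (NA for never-used features).
#' @export
aggregateImportance <- function(models, featureNames) {
  counts <- stats::setNames(integer(length(featureNames)), featureNames)
  gains <- stats::setNames(vector("list", length(featureNames)),
                           featureNames)
  for (m in models) {
    imp <- tryCatch(xgboost::xgb.importance(model = m),
                    error = function(e) NULL)
    if (is.null(imp) || nrow(imp) == 0) next
    for (i in seq_len(nrow(imp))) {
      f <- imp$Feature[i]
      if (!f %in% featureNames) next
      counts[f] <- counts[f] + 1L
      gains[[f]] <- c(gains[[f]], imp$Gain[i])
    }
  }
  meanGain <- vapply(gains, function(g)
    if (length(g)) mean(g) else NA_real_, numeric(1))
  out <- data.frame(feature = featureNames,
                    selectionCount = as.integer(counts),
                    meanGain = meanGain, row.names = NULL)
  out[order(-out$selectionCount, -ifelse(is.na(out$meanGain), -Inf,
                                         out$meanGain)), , drop = FALSE]
}

#' Median-split stratification of per-sample scores
#'
#' Splits samples into \code{"low"} and \code{"high"} groups around the
#' cohort median of a score (e.g. a DREMI feature): high means strictly
#' above the median, ties go to low. The groups feed downstream survival
#' analysis (Kaplan-Meier, Cox) by standard routines.
#'
#' @param scores numeric vector of per-sample scores (optionally named).
#' @return character vector of \code{"low"}/\code{"high"}, same names.
#' @examples
#' stratifyByMedian(c(a = 1, b = 2, c = 3, d = 4))
#' @export
stratifyByMedian <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 samples")
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (max(scores) == min(scores))
    stop("all scores identical: no stratification possible")
  med <- stats::median(scores)
  stats::setNames(ifelse(scores > med, "high", "low"), names(scores))
}
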