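# Per-motif gradient-boosted classifiers: training with a stratified 4:1
# split, k-fold cross-validation, ROC/AUC, and JSON+base64 persistence.

#' The twelve concrete RRACH 5-mers
#'
#' Lexicographically sorted expansion of `[AG][AG]AC[ACT]`
#' (2 x 2 x 1 x 1 x 3 = 12 motifs).
#'
#' @return character vector of length 12.
#' @examples
#' enumerateRrachMotifs()
#' @export
enumerateRrachMotifs <- function() {
  g <- expand.grid(p1 = c("A", "G"), p2 = c("A", "G"), p3 = "A",
                   p4 = "C", p5 = c("A", "C", "T"),
                   stringsAsFactors = FALSE)
  sort(apply(g, 1L, paste, collapse = ""))
}

#' Training configuration
#'
#' @param split_ratio train fraction of the stratified shuffle split
#'   (default 0.8, i.e. a 4:1 train:test split).
#' @param cv_folds folds for cross-validation (default 10).
#' @param seed integer seed controlling the split, fold assignment, and
#'   the booster RNG.
#' @param nrounds,max_depth,eta boosting hyperparameters (number of trees
#'   K, tree depth, learning rate) with logistic loss.
#' @param scale_pos_weight optional positive-class reweighting (default
#'   `NULL`, no reweighting).
#' @param extra named list of additional parameters passed through to the
#'   boosting library.
#' @return list of class `trainConfig`.
#' @export
trainConfig <- function(split_ratio = 0.8, cv_folds = 10L, seed = 1L,
                        nrounds = 100L, max_depth = 6L, eta = 0.3,
                        scale_pos_weight = NULL, extra = list()) {
  stopifnot(split_ratio > 0, split_ratio < 1, cv_folds >= 2L, nrounds >= 1L)
  structure(list(split_ratio = split_ratio, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed), nrounds = as.integer(nrounds),
                 max_depth = as.integer(max_depth), eta = eta,
                 scale_pos_weight = scale_pos_weight, extra = extra),
            class = "trainConfig")
}

.xgbParams <- function(config, seed) {
  p <- c(list(objective = "binary:logistic", max_depth = config$max_depth,
              eta = config$eta, nthread = 1L, seed = as.integer(seed)),
         config$extra)
  if (!is.null(config$scale_pos_weight))
    p$scale_pos_weight <- config$scale_pos_weight
  p
}

.featureMatrix <- function(features) {
  fn <- siteFeatureNames()
  miss <- setdiff(fn, names(features))
  if (length(miss))
    stop("feature schema mismatch: missing column(s) ",
         paste(miss, collapse = ", "))
  m <- as.matrix(features[, fn, drop = FALSE])
  storage.mode(m) <- "double"
  # centre-minus-flank contrasts: within a motif the four flanking bases
  # are fixed, so these cancel the residual per-read normalization
  # offset, which single-feature tree splits cannot do on their own
  flank <- c("m2", "m1", "p1", "p2")
  cm <- m[, "mean_c0"] - rowMeans(m[, paste0("mean_", flank), drop = FALSE])
  cd <- m[, "median_c0"] -
    rowMeans(m[, paste0("median_", flank), drop = FALSE])
  cbind(m, contrast_mean = cm, contrast_median = cd)
}

.fitMotif <- function(X, y, config, seed) {
  b <- xgboost::xgb.train(
    params = .xgbParams(config, seed),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1L),
    nrounds = config$nrounds, verbose = 0L)
  xgboost::xgb.save.raw(b)
}

.predictRaw <- function(raw, X) {
  as.numeric(predict(xgboost::xgb.load.raw(raw), X))
}

# stratified shuffle split: per-class permutation, first `frac` to train
.stratifiedTrainIdx <- function(y, frac, seed) {
  set.seed(seed)
  idx <- logical(length(y))
  for (cls in unique(y)) {
    w <- which(y == cls)
    n_tr <- max(1L, floor(length(w) * frac))
    idx[sample(w)[seq_len(n_tr)]] <- TRUE
  }
  idx
}

#' Train the twelve per-motif classifiers
#'
#' Splits the labeled site feature vectors of each motif into train and
#' held-out parts with a stratified shuffle split at `split_ratio`, fits
#' one gradient-boosted ensemble per motif, and evaluates the pooled
#' held-out predictions (confusion counts at probability 0.5, ROC, AUC).
#' A motif with fewer than two examples of either class is flagged
#' untrainable; predicting on it later raises an error.
#'
#' @param labeled data.frame with the 20 feature columns of
#'   [siteFeatureNames()], a `motif` column, and a 0/1 `label` column
#'   (1 = modified).
#' @param config a [trainConfig()].
#' @return list with `bundle` (a [ModelBundle]) and `report` (an
#'   evaluation list: `tp fp tn fn tpr fpr accuracy auc roc per_motif`).
#' @export
trainBundle <- function(labeled, config = trainConfig()) {
  stopifnot(is.data.frame(labeled), all(c("motif", "label") %in% names(labeled)),
            all(labeled$label %in% c(0L, 1L)))
  motifs <- enumerateRrachMotifs()
  unknown <- setdiff(unique(labeled$motif), motifs)
  if (length(unknown))
    stop("labeled data contains non-RRACH motif(s): ",
         paste(unknown, collapse = ", "))
  X <- .featureMatrix(labeled)
  y <- as.integer(labeled$label)

  models <- list()
  oof_scores <- numeric(); oof_labels <- integer(); oof_motif <- character()
  for (i in seq_along(motifs)) {
    mo <- motifs[i]
    w <- which(labeled$motif == mo)
    tab <- table(factor(y[w], levels = 0:1))
    if (length(w) == 0L || any(tab < 2L)) {
      models[[mo]] <- list(trainable = FALSE, raw = NULL,
                           n_train = 0L, n_test = 0L)
      next
    }
    tr <- .stratifiedTrainIdx(y[w], config$split_ratio, config$seed + i)
    raw <- .fitMotif(X[w[tr], , drop = FALSE], y[w[tr]], config,
                     config$seed + i)
    te <- w[!tr]
    if (length(te)) {
      p <- .predictRaw(raw, X[te, , drop = FALSE])
      oof_scores <- c(oof_scores, p)
      oof_labels <- c(oof_labels, y[te])
      oof_motif <- c(oof_motif, rep(mo, length(te)))
    }
    models[[mo]] <- list(trainable = TRUE, raw = raw,
                         n_train = sum(tr), n_test = length(te))
  }
  bundle <- new("ModelBundle", models = models[motifs],
                schema_version = featureSchema(),
                config = unclass(config))
  report <- .evalReport(oof_scores, oof_labels, oof_motif)
  list(bundle = bundle, report = report)
}

.evalReport <- function(scores, labels, motif = NULL, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L); fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L); fn <- sum(pred == 0L & labels == 1L)
  cm <- confusionMetrics(tp, fp, tn, fn)
  ra <- if (length(unique(labels)) == 2L) rocAuc(scores, labels)
        else list(roc = NULL, auc = NA_real_)
  per_motif <- NULL
  if (!is.null(motif) && length(motif)) {
    per_motif <- do.call(rbind, lapply(split(seq_along(motif), motif),
      function(ii) {
        auc <- if (length(unique(labels[ii])) == 2L)
          rocAuc(scores[ii], labels[ii])$auc else NA_real_
        data.frame(motif = motif[ii[1L]], n = length(ii), auc = auc)
      }))
    rownames(per_motif) <- NULL
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       tpr = cm$tpr, fpr = cm$fpr, accuracy = cm$accuracy,
       auc = ra$auc, roc = ra$roc, per_motif = per_motif,
       scores = scores, labels = labels)
}

#' k-fold cross-validation of the per-motif classifiers
#'
#' Stratified within motif x class so that both classes appear in every
#' fold.  For each fold, per-motif models are refitted on the remaining
#' folds and the held-out fold is scored; the ROC/AUC is computed once
#' over all pooled out-of-fold probabilities.
#'
#' @inheritParams trainBundle
#' @param folds number of folds (default from `config`).
#' @param seed seed for the fold assignment (default from `config`).
#' @return evaluation list as in [trainBundle()], pooled over folds.
#' @export
crossValidate <- function(labeled, folds = NULL, seed = NULL,
                          config = trainConfig()) {
  folds <- as.integer(folds %||% config$cv_folds)
  seed <- as.integer(seed %||% config$seed)
  stopifnot(folds >= 2L)
  if (nrow(labeled) < folds) stop("fewer examples than folds")
  X <- .featureMatrix(labeled)
  y <- as.integer(labeled$label)
  mo <- as.character(labeled$motif)

  set.seed(seed)
  fold <- integer(nrow(labeled))
  for (g in split(seq_len(nrow(labeled)), list(mo, y), drop = TRUE)) {
    fold[sample(g)] <- rep_len(seq_len(folds), length(g))
  }
  oof <- rep(NA_real_, nrow(labeled))
  for (k in seq_len(folds)) {
    te <- which(fold == k)
    tr <- which(fold != k)
    for (m in unique(mo[te])) {
      trm <- tr[mo[tr] == m]
      tem <- te[mo[te] == m]
      if (length(unique(y[trm])) < 2L)
        stop("motif ", m, " has a single class in training folds")
      raw <- .fitMotif(X[trm, , drop = FALSE], y[trm], config, seed + k)
      oof[tem] <- .predictRaw(raw, X[tem, , drop = FALSE])
    }
  }
  .evalReport(oof, y, mo)
}

#' Classification metrics from confusion counts
#'
#' `TPR = TP/(TP+FN)`, `FPR = FP/(FP+TN)` (the standard false positive
#' rate, i.e. 1 - specificity), `accuracy = (TP+TN)/(TP+FP+TN+FN)`.
#' A zero denominator yields `NA`.
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return list with `tpr`, `fpr`, `accuracy`.
#' @examples
#' confusionMetrics(3, 1, 4, 1)   # tpr 0.75, fpr 0.2, accuracy 7/9
#' @export
confusionMetrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  list(tpr = safe(tp, tp + fn), fpr = safe(fp, fp + tn),
       accuracy = safe(tp + tn, tp + fp + tn + fn))
}

#' ROC curve and AUC
#'
#' Sweeps the threshold over the distinct scores (ties grouped at one
#' threshold) and integrates the curve with the trapezoidal rule, which
#' makes the AUC identical to the Mann-Whitney pair statistic
#' `P(score+ > score-) + 0.5 P(tie)`.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (both classes must be present).
#' @return list with `roc` (data.frame `fpr`, `tpr`, monotone
#'   nondecreasing from (0,0) to (1,1)) and `auc`.
#' @examples
#' rocAuc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc   # 1
#' @export
rocAuc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # group ties: cumulative counts at each distinct score
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last]; fp <- cumsum(1 - y)[last]
  roc <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1L) + tail(roc$tpr, -1L)) / 2)
  list(roc = roc, auc = auc)
}

#' Predict modification probabilities for site feature vectors
#'
#' Routes every row of `features` to the classifier of its motif and
#' returns the per-read modification probability.  The feature schema of
#' the bundle must match; a motif without a trained model raises an
#' error.
#'
#' @param bundle a [ModelBundle].
#' @param features data.frame with `motif` and the 20 feature columns.
#' @return numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
predictSites <- function(bundle, features) {
  stopifnot(is(bundle, "ModelBundle"))
  if (!identical(bundle@schema_version, featureSchema()))
    stop("feature schema mismatch: bundle has ", bundle@schema_version,
         ", package expects ", featureSchema())
  if (!nrow(features)) return(numeric())
  X <- .featureMatrix(features)
  mo <- as.character(features$motif)
  p <- rep(NA_real_, nrow(features))
  for (m in unique(mo)) {
    mod <- bundle@models[[m]]
    if (is.null(mod) || !isTRUE(mod$trainable))
      stop("no model for motif ", m)
    w <- mo == m
    p[w] <- .predictRaw(mod$raw, X[w, , drop = FALSE])
  }
  p
}

#' @rdname predictSites
#' @param v a single site feature vector (one-row data.frame).
#' @export
predictSite <- function(bundle, v) {
  stopifnot(nrow(v) == 1L)
  predictSites(bundle, v)
}

#' Persist / restore a model bundle
#'
#' The bundle file is a single JSON document holding the schema version,
#' the training configuration, and the twelve serialized ensembles as
#' base64 strings; reloading reproduces bit-identical predictions.
#'
#' @param bundle a [ModelBundle].
#' @param path bundle file (conventionally `.nsm`).
#' @return `saveBundle` returns `path` invisibly; `loadBundle` the
#'   restored [ModelBundle].
#' @export
saveBundle <- function(bundle, path) {
  stopifnot(is(bundle, "ModelBundle"))
  doc <- list(
    format = "nanostoich-bundle", version = 1L,
    schema_version = bundle@schema_version,
    config = bundle@config[!vapply(bundle@config, is.null, TRUE)],
    models = lapply(bundle@models, function(m) list(
      trainable = m$trainable, n_train = m$n_train, n_test = m$n_test,
      raw = if (isTRUE(m$trainable)) jsonlite::base64_enc(m$raw) else NULL)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname saveBundle
#' @export
loadBundle <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "nanostoich-bundle"))
    stop("not a nanostoich model bundle: ", path)
  models <- lapply(doc$models, function(m) list(
    trainable = isTRUE(m$trainable),
    n_train = as.integer(m$n_train), n_test = as.integer(m$n_test),
    raw = if (isTRUE(m$trainable)) jsonlite::base64_dec(m$raw) else NULL))
  new("ModelBundle", models = models[enumerateRrachMotifs()],
      schema_version = as.character(doc$schema_version),
      config = doc$config)
}
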