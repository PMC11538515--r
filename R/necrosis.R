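#' Label treatment conditions by necrosis status
#'
#' A condition (compound, organ, dose, time) is *positive* when at least
#' one replicate rat carries a finding matching `finding_term`
#' (case-insensitive substring), *negative* when no replicate has any
#' pathology finding at all, and *excluded* otherwise (some finding, but
#' not the target one) — excluded conditions take part in neither training
#' nor testing. Controls are dropped by default since the endpoint is a
#' treatment-level outcome.
#'
#' @param metadata Sample metadata tibble with a `findings` list-column.
#' @param finding_term Finding to screen for (default `"necrosis"`).
#' @param include_controls Keep dose = control conditions.
#' @return Tibble: `condition`, `compound`, `organ`, `dose`, `time_days`,
#'   `status`.
#' @export
label_conditions <- function(metadata, finding_term = "necrosis",
                             include_controls = FALSE) {
  meta <- metadata
  if (!include_controls) meta <- dplyr::filter(meta, .data$dose != "control")
  key <- condition_key(meta)
  groups <- split(seq_len(nrow(meta)), key)
  purrr::map_dfr(groups, function(idx) {
    f <- meta$findings[idx]
    has_term <- any(vapply(f, function(v)
      any(grepl(finding_term, v, ignore.case = TRUE)), TRUE))
    none <- all(lengths(f) == 0L)
    tibble::tibble(condition = key[idx[1]], compound = meta$compound[idx[1]],
                   organ = meta$organ[idx[1]], dose = meta$dose[idx[1]],
                   time_days = meta$time_days[idx[1]],
                   status = if (has_term) "positive"
                            else if (none) "negative" else "excluded")
  })
}

#' Assemble condition-level features and labels for the necrosis model
#'
#' Joins [condition_profiles()] (replicate-averaged log2 profiles) with
#' [label_conditions()]; excluded conditions are dropped.
#'
#' @inheritParams label_conditions
#' @param expression Genes x samples log2 matrix.
#' @return List: `features` (conditions x genes matrix) and `labels`
#'   (tibble with `condition` and `status`).
#' @export
necrosis_dataset <- function(expression, metadata, finding_term = "necrosis",
                             include_controls = FALSE) {
  lab <- label_conditions(metadata, finding_term, include_controls)
  lab <- dplyr::filter(lab, .data$status != "excluded")
  prof <- condition_profiles(expression, metadata)
  keep <- intersect(lab$condition, colnames(prof$profiles))
  lab <- lab[match(keep, lab$condition), ]
  list(features = t(prof$profiles[, keep, drop = FALSE]), labels = lab)
}

#' Balance a labelled condition set
#'
#' Keeps all positives and a seeded random draw of an equal number of
#' negatives (the published models balanced 113/113 liver and 26/26
#' kidney conditions this way).
#'
#' @param labels Tibble with a `status` column (`positive`/`negative`).
#' @param seed Seed for the negative draw.
#' @return The balanced subset of `labels`, positives first.
#' @export
balanced_training_set <- function(labels, seed = 1L) {
  pos <- dplyr::filter(labels, .data$status == "positive")
  neg <- dplyr::filter(labels, .data$status == "negative")
  if (nrow(pos) == 0L) stop("no positive conditions", call. = FALSE)
  if (nrow(neg) < nrow(pos))
    stop("fewer negatives (", nrow(neg), ") than positives (", nrow(pos),
         ")", call. = FALSE)
  picked <- with_seed(seed, sample(nrow(neg), nrow(pos)))
  dplyr::bind_rows(pos, neg[sort(picked), ])
}

#' Train the necrosis logistic-regression classifier
#'
#' L2-penalised logistic regression (ridge, regularisation strength
#' C = 1, i.e. lambda = 1/n in glmnet's parameterisation) on features
#' z-scored with training-set statistics. Decision threshold 0.5.
#'
#' @param features Conditions x genes matrix.
#' @param status Character vector (`positive`/`negative`) aligned with the
#'   rows of `features`.
#' @param C Inverse regularisation strength.
#' @return A `necrosis_lr` object; `predict()` it on new condition
#'   features, `tidy()` for coefficients.
#' @export
train_necrosis_lr <- function(features, status, C = 1) {
  stopifnot(is.matrix(features), nrow(features) == length(status))
  y <- as.integer(status == "positive")
  if (length(unique(y)) < 2L)
    stop("both classes must be present for training", call. = FALSE)
  center <- colMeans(features)
  scale_ <- apply(features, 2L, stats::sd)
  scale_[scale_ == 0] <- 1
  x <- scale(features, center = center, scale = scale_)
  fit <- withCallingHandlers(
    glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                   lambda = 1 / (C * nrow(x)), standardize = FALSE),
    # glmnet warns on small class counts; the balanced design already
    # guarantees both classes are present, so keep small fits quiet
    warning = function(w) {
      if (grepl("fewer than", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(fit = fit, center = center, scale = scale_,
                 genes = colnames(features), n = nrow(x)),
            class = "necrosis_lr")
}

#' @rdname train_necrosis_lr
#' @param object A `necrosis_lr`.
#' @param newdata Conditions x genes matrix over the training genes.
#' @param ... Unused.
#' @export
predict.necrosis_lr <- function(object, newdata, ...) {
  stopifnot(identical(colnames(newdata), object$genes))
  x <- scale(newdata, center = object$center, scale = object$scale)
  prob <- as.numeric(stats::predict(object$fit, x, type = "response"))
  tibble::tibble(condition = rownames(newdata) %||% seq_len(nrow(newdata)),
                 probability = prob,
                 status = ifelse(prob > 0.5, "positive", "negative"))
}

#' @rdname train_necrosis_lr
#' @param x A `necrosis_lr`.
#' @export
tidy.necrosis_lr <- function(x, ...) {
  cf <- as.matrix(stats::coef(x$fit))
  tibble::tibble(term = rownames(cf), estimate = cf[, 1L])
}

#' @rdname train_necrosis_lr
#' @export
glance.necrosis_lr <- function(x, ...) {
  tibble::tibble(n_train = x$n, n_features = length(x$genes),
                 lambda = x$fit$lambda)
}

#' Confusion counts
#'
#' Either construct directly from the four counts, or cross-tabulate truth
#' against predictions with `confusion_counts()`.
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A `confusion_counts` object.
#' @export
confusion <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(counts), class = "confusion_counts")
}

#' @rdname confusion
#' @param truth,predicted Character vectors of `positive`/`negative`.
#' @param positive Label of the positive class.
#' @export
confusion_counts <- function(truth, predicted, positive = "positive") {
  stopifnot(length(truth) == length(predicted))
  if (!length(truth)) stop("empty test set", call. = FALSE)
  t_pos <- truth == positive
  p_pos <- predicted == positive
  confusion(tp = sum(t_pos & p_pos), tn = sum(!t_pos & !p_pos),
            fp = sum(!t_pos & p_pos), fn = sum(t_pos & !p_pos))
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Classifier performance metrics from a confusion matrix
#'
#' Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` (0 when any
#' factor of the denominator is 0, where the quotient is undefined),
#' accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)` and specificity
#' `TN/(TN+FP)`.
#'
#' @param x A `confusion_counts` object.
#' @return One-row tibble: `mcc`, `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
classifier_metrics <- function(x) {
  stopifnot(inherits(x, "confusion_counts"))
  tp <- x$tp; tn <- x$tn; fp <- x$fp; fn <- x$fn
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  tibble::tibble(mcc = mcc,
                 accuracy = (tp + tn) / (tp + tn + fp + fn),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp))
}

#' Evaluate the necrosis classifier on a test set
#'
#' @param model A [train_necrosis_lr()] fit.
#' @param features Conditions x genes test matrix.
#' @param status True statuses (`positive`/`negative`) per row.
#' @return A `classifier_eval`: list with `confusion`
#'   (`confusion_counts`) and `metrics` (tibble); `glance()` flattens
#'   both.
#' @export
evaluate_classifier <- function(model, features, status) {
  if (!nrow(features)) stop("empty test set", call. = FALSE)
  pred <- predict(model, features)
  conf <- confusion_counts(status, pred$status)
  structure(list(confusion = conf, metrics = classifier_metrics(conf),
                 predictions = pred),
            class = "classifier_eval")
}

#' @export
print.classifier_eval <- function(x, ...) {
  print(x$confusion)
  print(x$metrics)
  invisible(x)
}

#' @rdname evaluate_classifier
#' @param x A `classifier_eval`.
#' @param ... Unused.
#' @export
glance.classifier_eval <- function(x, ...) {
  dplyr::bind_cols(tibble::as_tibble(unclass(x$confusion)), x$metrics)
}
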