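#' Area under the ROC curve
#'
#' Rank-based AUC: U / (n1 * n0) with midrank tie handling, equal to the
#' probability that a random case outscores a random control (ties counted
#' half).
#'
#' @param scores numeric risk scores
#' @param labels 0/1 (or two-level factor; second level = case)
#' @return scalar AUC in [0, 1]
#' @export
auc <- function(scores, labels) {
  y <- if (is.factor(labels)) as.numeric(labels == levels(labels)[2L])
       else as.numeric(labels)
  stopifnot(length(scores) == length(y), all(y %in% 0:1))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Multilocus genetic risk model via LASSO with nested cross-validation
#'
#' For each named candidate feature set, an L1-penalized logistic
#' regression is evaluated by outer k-fold cross-validation; within each
#' training split an inner cross-validation picks the penalty by the 1-SE
#' rule on AUC (the largest lambda whose mean inner AUC is within one
#' standard error of the maximum, favouring parsimonious models), the model
#' is refit on the training split at that lambda, and scored on the
#' held-out fold.  Covariate columns listed in `covariates` are appended to
#' every candidate set (including the empty set, giving a covariate-only
#' baseline).
#'
#' @param features sample x feature numeric matrix (SNP dosages and
#'   covariates), standardized internally by glmnet
#' @param labels 0/1 or two-level factor (second level = case)
#' @param candidate_sets named list of character vectors of feature columns;
#'   an entry may be `character()` for the covariate-only model
#' @param covariates character vector of covariate columns appended to all
#'   sets (default none)
#' @param outer_folds number of outer CV folds (default 10)
#' @param seed integer seed controlling both fold layers
#' @return object of class `RiskModel`: list with `per_set` (per candidate
#'   set: per-fold AUC, median AUC, per-fold lambda and selected features)
#'   and `folds` (outer fold assignment)
#' @export
fit_risk_model <- function(features, labels, candidate_sets,
                           covariates = character(), outer_folds = 10L,
                           seed = 1L) {
  X <- as.matrix(features)
  y <- if (is.factor(labels)) as.numeric(labels == levels(labels)[2L])
       else as.numeric(labels)
  stopifnot(nrow(X) == length(y), all(y %in% 0:1))
  if (sum(y == 1) < 20L || sum(y == 0) < 20L) {
    stop("need at least 20 samples per class")
  }
  stopifnot(is.list(candidate_sets), length(names(candidate_sets)) ==
              length(candidate_sets))
  all_feats <- colnames(X)
  set.seed(child_seed(seed, "outer_folds"))
  fold <- sample(rep(seq_len(outer_folds), length.out = length(y)))
  per_set <- lapply(names(candidate_sets), function(set_name) {
    cols <- union(candidate_sets[[set_name]], covariates)
    missing <- setdiff(cols, all_feats)
    if (length(missing)) {
      stop(sprintf("candidate set '%s' references unknown feature(s): %s",
                   set_name, paste(missing, collapse = ", ")))
    }
    if (length(cols) == 0L) {
      stop(sprintf("candidate set '%s' is empty and no covariates were given",
                   set_name))
    }
    fold_auc <- numeric(outer_folds)
    fold_lambda <- numeric(outer_folds)
    selected <- vector("list", outer_folds)
    for (k in seq_len(outer_folds)) {
      tr <- fold != k
      Xtr <- X[tr, cols, drop = FALSE]
      if (length(cols) < 2L) {
        # glmnet needs >= 2 columns; a single feature is scored directly
        score <- X[!tr, cols, drop = TRUE]
        fold_auc[k] <- auc(score, y[!tr])
        fold_lambda[k] <- NA_real_
        selected[[k]] <- cols
        next
      }
      set.seed(child_seed(seed, sprintf("inner_%s_%d", set_name, k)))
      foldid <- sample(rep(seq_len(10L), length.out = sum(tr)))
      cvfit <- glmnet::cv.glmnet(Xtr, y[tr], family = "binomial",
                                 type.measure = "auc", foldid = foldid)
      lam <- cvfit$lambda.1se  # largest lambda within 1 SE of the max AUC
      fold_lambda[k] <- lam
      cf <- coef(cvfit, s = lam)[-1L, 1L]
      selected[[k]] <- cols[cf != 0]
      score <- predict(cvfit, newx = X[!tr, cols, drop = FALSE], s = lam,
                       type = "link")[, 1L]
      fold_auc[k] <- if (length(unique(score)) == 1L) 0.5
                     else auc(score, y[!tr])
    }
    list(set = set_name, fold_auc = fold_auc,
         median_auc = median(fold_auc), lambda = fold_lambda,
         selected = selected)
  })
  names(per_set) <- names(candidate_sets)
  structure(list(per_set = per_set, folds = fold, seed = seed),
            class = "RiskModel")
}

#' @export
print.RiskModel <- function(x, ...) {
  cat("Risk model evaluation (outer folds:", length(unique(x$folds)), ")\n")
  for (s in x$per_set) {
    cat(sprintf("  %-20s median AUC %.3f\n", s$set, s$median_auc))
  }
  invisible(x)
}
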