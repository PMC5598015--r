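# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Nested linear model F test from residual sums of squares
#'
#' @param rss_full,rss_reduced residual sums of squares of the two fits
#' @param df1 difference in model degrees of freedom
#' @param df2 residual degrees of freedom of the full model
#' @return list with `statistic` and `p.value`
#' @keywords internal
#' @noRd
nested_f_test <- function(rss_reduced, rss_full, df1, df2) {
  stopifnot(df1 >= 1, df2 >= 1)
  f <- ((rss_reduced - rss_full) / df1) / (rss_full / df2)
  f <- pmax(f, 0)
  list(statistic = f, p.value = pf(f, df1, df2, lower.tail = FALSE))
}

# Connected components of an undirected graph given as an edge list over
# `ids` (union-find with path compression).  Returns an integer component
# label per id.
components_union_find <- function(ids, from, to) {
  parent <- seq_along(ids)
  idx <- stats::setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(from)) {
    a <- find(idx[[from[e]]])
    b <- find(idx[[to[e]]])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(ids), find, integer(1L))
  match(roots, unique(roots))
}

# Drop aliased (linearly dependent) columns from a design matrix via QR.
# Returns the pruned matrix; warns with the dropped column names when
# `warn` is TRUE.
drop_aliased <- function(X, warn = TRUE, context = "design") {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    if (warn) {
      warning(sprintf("%s: dropping aliased column(s): %s",
                      context, paste(dropped, collapse = ", ")), call. = FALSE)
    }
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}

# Multi-response least squares: residual sum of squares per response column
# for responses Y (n x m) against design X (n x p).  Also returns residuals
# and coefficients when asked.
ols_rss <- function(X, Y, want_coef = FALSE) {
  fit <- lm.fit(X, Y)
  res <- as.matrix(fit$residuals)
  out <- list(rss = colSums(res^2), rank = fit$rank)
  if (want_coef) out$coef <- as.matrix(fit$coefficients)
  out
}

# Deterministic child seed derived from a parent seed and a component tag,
# kept below 2^31 so it is a valid R integer.
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

stopifnot_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0 | x > 1)) {
    stop(sprintf("%s must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
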