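#' Pearson correlation with t-distribution p-value
#'
#' @param x,y numeric vectors of equal length (n >= 3), finite variance.
#' @return list with `r`, `p` (two-sided, t with n-2 df) and `n`.
#' @export
pearson_cor <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate-input: zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Box-Cox power transformation
#'
#' `(x^lambda - 1) / lambda` for lambda != 0, `log(x)` for lambda == 0.
#' With `lambda = "auto"` the exponent maximizing the profile log-likelihood
#' of the normal model is chosen over the grid `[-3, 3]` in steps of 0.01.
#' Zeros (e.g. windows with recombination rate 0) are handled by adding a
#' shift of half the smallest positive value before transforming.
#'
#' @param x non-negative numeric vector.
#' @param lambda numeric exponent or `"auto"`.
#' @return list with `y` (transformed values), `lambda` and `shift`.
#' @export
boxcox_transform <- function(x, lambda = "auto") {
  x <- x[is.finite(x)]
  if (any(x < 0)) stop("domain-error: negative values")
  shift <- 0
  if (any(x == 0)) {
    pos <- x[x > 0]
    if (!length(pos)) stop("domain-error: all values zero")
    shift <- min(pos) / 2
  }
  z <- x + shift
  bc <- function(lam) {
    if (abs(lam) < 1e-12) log(z) else (z^lam - 1) / lam
  }
  if (identical(lambda, "auto")) {
    grid <- seq(-3, 3, by = 0.01)
    n <- length(z)
    slog <- sum(log(z))
    ll <- vapply(grid, function(lam) {
      y <- bc(lam)
      -n / 2 * log(mean((y - mean(y))^2)) + (lam - 1) * slog
    }, numeric(1))
    lambda <- grid[which.max(ll)]
  }
  list(y = bc(lambda), lambda = lambda, shift = shift)
}

#' Variance inflation factors
#'
#' For each predictor j, `1 / (1 - R2_j)` where `R2_j` is the R-squared of
#' regressing predictor j on all the others — the standard multicollinearity
#' diagnostic.  Exactly collinear predictors are reported as `Inf` with a
#' warning.
#'
#' @param predictors numeric matrix or data.frame (>= 2 columns, more rows
#'   than columns).
#' @return named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(predictors) {
  X <- as.matrix(predictors)
  p <- ncol(X)
  if (p < 2) stop("need at least 2 predictors")
  if (nrow(X) <= p) stop("need more rows than predictors")
  out <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  if (any(!is.finite(out))) warning("exact collinearity: infinite VIF")
  out
}

#' Standardized multiple linear regression
#'
#' Ordinary least squares on z-scored response and predictors, reporting
#' standardized coefficients (beta), per-predictor p-values, adjusted
#' R-squared and VIFs.  Rows with any missing value are dropped listwise.
#'
#' @param response numeric vector.
#' @param predictors numeric matrix or data.frame.
#' @return list with `beta`, `pvalues`, `vif` (named vectors), `adjusted_r2`,
#'   `retained` (predictor names), `n`.
#' @export
ols_standardized <- function(response, predictors) {
  X <- as.matrix(predictors)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- is.finite(response) & rowSums(!is.finite(X)) == 0
  y <- response[keep]
  X <- X[keep, , drop = FALSE]
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop("underdetermined: need n > p + 1")
  Xs <- scale(X)
  ys <- as.numeric(scale(y))
  fit <- stats::lm(ys ~ Xs)
  sm <- summary(fit)
  beta <- stats::coef(fit)[-1]
  pv <- sm$coefficients[-1, 4]
  names(beta) <- names(pv) <- colnames(X)
  list(
    beta = beta,
    pvalues = pv,
    vif = if (p >= 2) vif(X) else stats::setNames(1, colnames(X)),
    adjusted_r2 = sm$adj.r.squared,
    retained = colnames(X),
    n = n
  )
}

#' Backward stepwise regression by p-value
#'
#' Starting from the full standardized model, repeatedly removes the
#' predictor with the largest p-value while that p-value exceeds `alpha`,
#' refitting after each removal; returns the final model (possibly with no
#' predictors retained).
#'
#' @inheritParams ols_standardized
#' @param alpha removal threshold on the per-predictor p-value (default
#'   0.05).
#' @param criterion `"pvalue"` (default) or `"aic"` for AIC-based removal.
#' @return as [ols_standardized()]; with zero retained predictors, a list
#'   with empty `beta` and `adjusted_r2 = 0`.
#' @export
backward_stepwise <- function(response, predictors, alpha = 0.05,
                              criterion = c("pvalue", "aic")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(predictors)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  current <- colnames(X)
  repeat {
    if (!length(current)) {
      return(list(beta = numeric(0), pvalues = numeric(0), vif = numeric(0),
                  adjusted_r2 = 0, retained = character(0),
                  n = sum(is.finite(response))))
    }
    fit <- ols_standardized(response, X[, current, drop = FALSE])
    if (criterion == "pvalue") {
      worst <- which.max(fit$pvalues)
      if (fit$pvalues[worst] <= alpha) return(fit)
      current <- setdiff(current, names(fit$pvalues)[worst])
    } else {
      keep <- is.finite(response) & rowSums(!is.finite(X)) == 0
      dat <- data.frame(y = response[keep], X[keep, current, drop = FALSE])
      full <- stats::lm(y ~ ., data = dat)
      aics <- vapply(current, function(v) {
        stats::AIC(stats::update(full, stats::as.formula(paste(". ~ . -", v))))
      }, numeric(1))
      if (min(aics) >= stats::AIC(full)) return(fit)
      current <- setdiff(current, names(which.min(aics)))
    }
  }
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Probability-mass method: with margins fixed, the p-value is the sum of
#' hypergeometric probabilities of all tables whose probability does not
#' exceed that of the observed table (the dominant two-sided convention).
#'
#' @param tab 2x2 matrix of non-negative integer counts with all margins
#'   positive.
#' @return two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))  # 1/3
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    stop("need a 2x2 table of non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate-table: zero margin")
  }
  m <- sum(tab[1, ])            # row-1 margin
  n <- sum(tab[2, ])            # row-2 margin
  k <- sum(tab[, 1])            # column-1 margin
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  # relative tolerance guards against ties lost to floating point
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

#' Welch two-sample t-test
#'
#' @param x,y numeric vectors (each n >= 2).
#' @return list with `t` and two-sided `p`.
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("insufficient-data: need n >= 2 per group")
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Classical one-way ANOVA
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `F` and `p`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("insufficient-data: need >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) {
    stop("insufficient-data: every group needs n >= 2")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
  Fv <- unname(ow$statistic)
  p <- ow$p.value
  if (is.nan(Fv)) { Fv <- 0; p <- 1 }   # all groups identical
  list(F = Fv, p = p)
}
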