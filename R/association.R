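#' Yeo-Johnson power transformation
#'
#' The power-family transformation defined on the whole real line:
#' for y >= 0, ((y+1)^lambda - 1)/lambda (log(y+1) at lambda = 0); for
#' y < 0, -(((-y)+1)^(2-lambda) - 1)/(2-lambda) (-log(1-y) at lambda = 2).
#' Strictly increasing in y for every lambda and continuous in lambda
#' (the log branches are the lambda -> 0 and lambda -> 2 limits).
#' lambda = 1 is the identity on nonnegative data.
#'
#' @param y numeric vector.
#' @param lambda transformation parameter (finite scalar).
#' @return transformed vector.
#' @export
yeo_johnson <- function(y, lambda) {
  stopifnot(is.finite(lambda), length(lambda) == 1L)
  out <- y
  pos <- !is.na(y) & y >= 0
  if (abs(lambda) < 1e-8) {
    out[pos] <- log1p(y[pos])
  } else {
    out[pos] <- ((y[pos] + 1)^lambda - 1) / lambda
  }
  neg <- !is.na(y) & y < 0
  if (abs(2 - lambda) < 1e-8) {
    out[neg] <- -log1p(-y[neg])
  } else {
    out[neg] <- -((-y[neg] + 1)^(2 - lambda) - 1) / (2 - lambda)
  }
  out
}

# Gaussian profile log-likelihood of the Yeo-Johnson parameter:
# -n/2 log(sigma2_mle) + (lambda - 1) * sum sign(y) log(|y|+1).
.yj_loglik <- function(y, lambda) {
  z <- yeo_johnson(y, lambda)
  s2 <- mean((z - mean(z))^2)
  if (s2 <= 0) return(-Inf)
  -length(y) / 2 * log(s2) + (lambda - 1) * sum(sign(y) * log1p(abs(y)))
}

#' Maximum-likelihood Yeo-Johnson parameter
#'
#' Maximises the Gaussian profile log-likelihood of the transformation
#' parameter over `interval` (golden-section/parabolic search via
#' [stats::optimize()], tolerance 1e-6). A constant input has no
#' information about lambda and returns 1 with attribute
#' `flag = "constant_input"`.
#'
#' @param y numeric vector (>= 5 finite values).
#' @param interval search interval for lambda.
#' @param tol search tolerance.
#' @return the fitted lambda (scalar, possibly flagged).
#' @export
fit_lambda <- function(y, interval = c(-5, 5), tol = 1e-6) {
  y <- y[is.finite(y)]
  if (length(y) < 5L) stop("need at least 5 finite values to fit lambda")
  if (stats::var(y) == 0) {
    out <- 1
    attr(out, "flag") <- "constant_input"
    return(out)
  }
  opt <- stats::optimize(function(l) .yj_loglik(y, l),
                         interval = interval, maximum = TRUE, tol = tol)
  opt$maximum
}

#' Robust linear regression (Huber M-estimation)
#'
#' Iteratively reweighted least squares with the Huber psi (tuning
#' constant 1.345, MAD scale), converging when the coefficient change
#' falls below `acc` or after `maxit` iterations; Tukey's bisquare is
#' available as an alternative. The fit quality is summarised as the
#' squared Pearson correlation between fitted and observed responses.
#'
#' @param x,y predictor and response vectors.
#' @param psi `"huber"` (default) or `"bisquare"`.
#' @param k Huber tuning constant.
#' @param maxit,acc IRLS iteration cap and convergence tolerance.
#' @return a `robust_fit`: list with `slope`, `intercept`, `scale`,
#'   `iterations`, `converged`, `r2`, `n_used`.
#' @export
robust_regress <- function(x, y, psi = c("huber", "bisquare"), k = 1.345,
                           maxit = 100L, acc = 1e-8) {
  psi <- match.arg(psi)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0) stop("degenerate design: all x values equal")
  fit <- if (psi == "huber") {
    MASS::rlm(y ~ x, psi = MASS::psi.huber, k = k, scale.est = "MAD",
              maxit = maxit, acc = acc)
  } else {
    MASS::rlm(y ~ x, psi = MASS::psi.bisquare, scale.est = "MAD",
              maxit = maxit, acc = acc)
  }
  co <- stats::coef(fit)
  structure(list(slope = unname(co[2L]), intercept = unname(co[1L]),
                 scale = fit$s, iterations = length(fit$conv),
                 converged = fit$converged,
                 r2 = stats::cor(stats::fitted(fit), y)^2,
                 n_used = length(x)),
            class = "robust_fit")
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf(
    "robust_fit: slope %.4f, intercept %.4f (scale %.4f, r2 = %.3f, n = %d)\n",
    x$slope, x$intercept, x$scale, x$r2, x$n_used))
  invisible(x)
}

#' Methylation-expression association
#'
#' The biopsy association analysis: both the per-sample methylation level
#' (mean per-read methylation by default; the highly-methylated-strand
#' score via `x_var`) and the relative expression are Yeo-Johnson
#' transformed with independently fitted lambdas, then related by Huber
#' robust regression. R squared is the squared correlation between fitted
#' and observed transformed expression.
#'
#' @param scores_df data.frame with `sample_id` and the methylation
#'   columns (`mean_meth` and/or `high_meth`).
#' @param expr_df data.frame with `sample_id`, `relative`, and optionally
#'   `excluded` (excluded samples are dropped, as are the calibrator's
#'   rows if flagged).
#' @param x_var which methylation summary to regress on.
#' @param psi robust loss, passed to [robust_regress()].
#' @return list with `fit` (a `robust_fit`), `lambda_x`, `lambda_y`,
#'   `n_used`, and `data` (merged sample table with transformed values).
#' @export
associate <- function(scores_df, expr_df,
                      x_var = c("mean_meth", "high_meth"),
                      psi = "huber") {
  x_var <- match.arg(x_var)
  stopifnot("sample_id" %in% names(scores_df),
            x_var %in% names(scores_df),
            all(c("sample_id", "relative") %in% names(expr_df)))
  if ("excluded" %in% names(expr_df))
    expr_df <- expr_df[!expr_df$excluded, ]
  d <- merge(scores_df[, c("sample_id", x_var)],
             expr_df[, c("sample_id", "relative")], by = "sample_id")
  d <- d[is.finite(d[[x_var]]) & is.finite(d$relative), ]
  lambda_x <- fit_lambda(d[[x_var]])
  lambda_y <- fit_lambda(d$relative)
  d$x_t <- yeo_johnson(d[[x_var]], as.numeric(lambda_x))
  d$y_t <- yeo_johnson(d$relative, as.numeric(lambda_y))
  fit <- robust_regress(d$x_t, d$y_t, psi = psi)
  list(fit = fit, lambda_x = as.numeric(lambda_x),
       lambda_y = as.numeric(lambda_y), n_used = fit$n_used, data = d)
}
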