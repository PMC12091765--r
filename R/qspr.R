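# QSPR regression: ordinary least squares of a physico-chemical property on a
# topological index, linear (Y = A + B*TI) or cubic
# (Y = A + B*TI + C*TI^2 + D*TI^3), with the significance statistics the
# field reports: R, R^2, standard error of the estimate SE = sqrt(SSE/df),
# Fisher F with (1, n-2) or (3, n-4) degrees of freedom, and its upper-tail
# p-value, called significant below 0.05.

#' Fit a QSPR regression model
#'
#' Ordinary least squares of \code{y} on \code{x} (linear) or on
#' \code{(x, x^2, x^3)} (cubic). The cubic design is centred and scaled
#' internally before solving - index magnitudes span five orders, so the raw
#' cubic basis is badly conditioned - and the coefficients are mapped back to
#' the raw basis exactly.
#'
#' @param x numeric index values (no missing values; the caller filters).
#' @param y numeric property values of equal length.
#' @param kind \code{"linear"} or \code{"cubic"}.
#' @return An object of class \code{qspr_fit}: coefficients \code{A},
#'   \code{B} (and \code{C}, \code{D} for cubic), \code{R}, \code{R2},
#'   \code{SE}, \code{F}, \code{p}, \code{n}, and the significance
#'   \code{indicator} at the 0.05 level.
#' @examples
#' fit <- qspr_fit(c(0, 1, 2), c(0, 1, 1))
#' coef(fit)              # A = 1/6, B = 0.5
#' predict(fit, c(3, 4))
#' @export
qspr_fit <- function(x, y, kind = c("linear", "cubic")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (anyNA(x) || anyNA(y)) {
    stop("missing values in x or y; filter before fitting", call. = FALSE)
  }
  n <- length(x)
  n_coef <- if (kind == "linear") 2L else 4L
  if (n < n_coef + 1L) {
    stop(sprintf("insufficient data: %s fit needs n >= %d, got %d",
                 kind, n_coef + 1L, n), call. = FALSE)
  }
  if (length(unique(x)) < n_coef) {
    stop(sprintf("degenerate fit: %s model needs at least %d distinct x values",
                 kind, n_coef), call. = FALSE)
  }
  if (kind == "linear") {
    lmfit <- stats::lm(y ~ x)
    cf <- stats::setNames(unname(stats::coef(lmfit)), c("A", "B"))
  } else {
    m <- mean(x); s <- stats::sd(x)
    z <- (x - m) / s
    lmfit <- stats::lm(y ~ z + I(z^2) + I(z^3))
    a <- unname(stats::coef(lmfit))
    cf <- c(
      A = a[1] - a[2] * m / s + a[3] * m^2 / s^2 - a[4] * m^3 / s^3,
      B = a[2] / s - 2 * a[3] * m / s^2 + 3 * a[4] * m^2 / s^3,
      C = a[3] / s^2 - 3 * a[4] * m / s^3,
      D = a[4] / s^3)
  }
  res <- stats::residuals(lmfit)
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("degenerate fit: y has zero variance", call. = FALSE)
  ssr <- sst - sse
  df1 <- n_coef - 1L
  df2 <- n - n_coef
  r2 <- 1 - sse / sst
  fstat <- (ssr / df1) / (sse / df2)
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  structure(list(
    kind = kind, coefficients = cf, n = n,
    R = sqrt(max(r2, 0)), R2 = r2,
    SE = sqrt(sse / df2), F = fstat, p = p,
    df = c(df1, df2),
    indicator = if (p < 0.05) "significant" else "insignificant",
    x = x, y = y, fitted = unname(stats::fitted(lmfit)),
    residuals = unname(res)), class = "qspr_fit")
}

#' @export
coef.qspr_fit <- function(object, ...) object$coefficients

#' @export
fitted.qspr_fit <- function(object, ...) object$fitted

#' @export
residuals.qspr_fit <- function(object, ...) object$residuals

#' Predict from a QSPR fit
#'
#' Applies the full-precision fitted coefficients (never the rounded, printed
#' ones) to new index values; missing inputs yield missing predictions.
#'
#' @param object a \code{qspr_fit}.
#' @param newdata numeric vector of index values; defaults to the training x.
#' @param ... unused.
#' @return Numeric vector of predicted property values.
#' @export
predict.qspr_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else as.numeric(newdata)
  cf <- object$coefficients
  out <- cf[["A"]] + cf[["B"]] * x
  if (object$kind == "cubic") out <- out + cf[["C"]] * x^2 + cf[["D"]] * x^3
  names(out) <- names(newdata)
  out
}

#' @export
print.qspr_fit <- function(x, ...) {
  cat(sprintf("<qspr_fit> %s model, n = %d\n", x$kind, x$n))
  print(round(x$coefficients, 6))
  cat(sprintf("R2 = %.4f  SE = %.4f  F(%d,%d) = %.4f  p = %.4g  [%s]\n",
              x$R2, x$SE, x$df[1], x$df[2], x$F, x$p, x$indicator))
  invisible(x)
}

#' @export
summary.qspr_fit <- function(object, ...) {
  print(object)
  cat("residual range:", paste(round(range(object$residuals), 4), collapse = " .. "),
      "\n")
  invisible(object)
}

#' Simulate responses from a fitted QSPR model
#'
#' Draws \code{nsim} Gaussian response vectors around the fitted values with
#' standard deviation \code{SE}.
#'
#' @param object a \code{qspr_fit}.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A data frame with \code{nsim} columns.
#' @export
simulate.qspr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(nsim, object$fitted + stats::rnorm(object$n, 0, object$SE))
  as.data.frame(out)
}

#' Pearson correlation over pairwise-complete observations
#'
#' @param x,y numeric vectors of equal length; pairs with a missing member
#'   are dropped.
#' @return The correlation coefficient.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("insufficient data: need >= 3 complete pairs",
                           call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  stats::cor(x, y)
}

.check_drug_sets <- function(indices, properties) {
  a <- rownames(indices); b <- rownames(properties)
  if (!setequal(a, b)) {
    stop("mismatched drug sets; only in indices: {",
         paste(setdiff(a, b), collapse = ", "), "}; only in properties: {",
         paste(setdiff(b, a), collapse = ", "), "}", call. = FALSE)
  }
}

#' Run the full QSPR study
#'
#' For every (index, property) pair, computes the Pearson correlation and
#' fits the requested regression model(s).
#'
#' Sample-selection \code{policy}:
#' \describe{
#'   \item{\code{"pairwise"}}{each computation uses all drugs with both
#'     values present (n = 8, or 7 where the property is missing).}
#'   \item{\code{"complete-case"}}{drugs missing any property (remdesivir)
#'     are dropped from every computation (n = 7 throughout).}
#'   \item{\code{"paper-mixed"}}{correlations are pairwise-complete while
#'     coefficient fits are complete-case; this is the combination that
#'     reproduces the published correlation and coefficient tables
#'     simultaneously.}
#' }
#'
#' @param indices data frame of index values, drugs as row names.
#' @param properties data frame of property values, drugs as row names;
#'   missing values as \code{NA}.
#' @param kind \code{"linear"}, \code{"cubic"} or \code{"both"}.
#' @param policy see Details.
#' @return A list with \code{correlations} (index x property matrix),
#'   \code{fits} (data frame of per-pair statistics), \code{models} (nested
#'   list of \code{qspr_fit} objects, \code{models[[kind]][[index]][[property]]}),
#'   and the \code{policy}.
#' @export
qspr_study <- function(indices, properties,
                       kind = c("linear", "cubic", "both"),
                       policy = c("paper-mixed", "pairwise", "complete-case")) {
  kind <- match.arg(kind)
  policy <- match.arg(policy)
  .check_drug_sets(indices, properties)
  properties <- properties[rownames(indices), , drop = FALSE]
  kinds <- if (kind == "both") c("linear", "cubic") else kind

  complete <- stats::complete.cases(properties)
  fit_rows <- function(sel) if (policy %in% c("complete-case", "paper-mixed"))
    sel & complete else sel
  cor_rows <- function(sel) if (policy == "complete-case") sel & complete else sel

  idx_names <- colnames(indices); prop_names <- colnames(properties)
  correlations <- matrix(NA_real_, length(idx_names), length(prop_names),
                         dimnames = list(idx_names, prop_names))
  fits <- NULL
  models <- stats::setNames(vector("list", length(kinds)), kinds)
  for (kd in kinds) models[[kd]] <- stats::setNames(
    replicate(length(idx_names), list()), idx_names)

  for (ix in idx_names) {
    for (pr in prop_names) {
      have <- !is.na(properties[[pr]])
      crows <- cor_rows(have)
      correlations[ix, pr] <- pearson_correlation(indices[crows, ix],
                                                  properties[crows, pr])
      frows <- fit_rows(have)
      for (kd in kinds) {
        fit <- qspr_fit(indices[frows, ix], properties[frows, pr], kd)
        models[[kd]][[ix]][[pr]] <- fit
        cf <- coef(fit)
        fits <- rbind(fits, data.frame(
          index = ix, property = pr, kind = kd, n = fit$n,
          R = fit$R, R2 = fit$R2, SE = fit$SE, F = fit$F,
          A = cf[["A"]], B = cf[["B"]],
          C = if (kd == "cubic") cf[["C"]] else NA_real_,
          D = if (kd == "cubic") cf[["D"]] else NA_real_,
          p = fit$p, indicator = fit$indicator))
      }
    }
  }
  rownames(fits) <- NULL
  list(correlations = correlations, fits = fits, models = models,
       policy = policy)
}

#' Actual-versus-predicted table
#'
#' Applies a fitted model to every drug's index value, including drugs that
#' were excluded from the fit because of missing property values.
#'
#' @param fit a \code{qspr_fit}.
#' @param x named numeric vector of index values for all drugs.
#' @param actual optional named numeric vector of observed property values.
#' @param coef_digits if non-\code{NULL}, round the coefficients to this many
#'   decimals before predicting. The default (\code{NULL}) uses full
#'   precision; published comparison tables are typically generated from the
#'   rounded coefficients they print, so reproducing one requires the
#'   matching \code{coef_digits}.
#' @return A data frame with columns \code{actual} (if given) and
#'   \code{predicted}.
#' @export
prediction_table <- function(fit, x, actual = NULL, coef_digits = NULL) {
  if (!is.null(coef_digits)) {
    fit$coefficients <- round(fit$coefficients, coef_digits)
  }
  pred <- predict(fit, x)
  out <- data.frame(predicted = unname(pred), row.names = names(x))
  if (!is.null(actual)) out <- cbind(actual = unname(actual[names(x)]), out)
  out
}
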