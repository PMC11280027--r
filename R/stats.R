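# Statistical operations: Welch's t-test wrapper, binned box-plot style
# summaries, and the sigmoidal permeability-to-absorption fit.

#' Welch's two-sample t-test
#'
#' Two-sided t-test assuming unequal variances, with Welch-Satterthwaite
#' degrees of freedom (delegates to [stats::t.test()]).
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
#' @examples
#' welch_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop_pf("each sample needs at least 2 observations")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      # identical constant samples: no evidence of a difference
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    stop_pf("both samples have zero variance")
  }
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Binned summary with optional adjacent-bin Welch tests
#'
#' Median and quartiles (type-7 interpolation, the R default) of a value
#' per bin, in bin-level order, with optional Welch's t-tests between
#' adjacent bins only.
#'
#' @param bin factor (or coercible) of bin labels.
#' @param value numeric values (e.g. fafg or f_a).
#' @param pairwise_tests if `TRUE`, Welch tests between adjacent bins.
#' @return list with `summary` (data.frame `bin, n, median, q1, q3`) and
#'   `tests` (data.frame `bin_a, bin_b, t, df, p`, or `NULL`).
#' @export
binned_summary <- function(bin, value, pairwise_tests = FALSE) {
  if (!is.factor(bin)) bin <- factor(bin)
  keep <- !is.na(bin) & !is.na(value)
  bin <- bin[keep]  # subsetting keeps the declared levels
  value <- value[keep]
  present <- levels(bin)[levels(bin) %in% unique(as.character(bin))]
  if (length(present) < nlevels(bin)) {
    warning(sprintf("empty bin(s) omitted: %s",
                    paste(setdiff(levels(bin), present), collapse = ", ")))
  }
  summ <- do.call(rbind, lapply(present, function(b) {
    v <- value[bin == b]
    data.frame(bin = b, n = length(v), median = median(v),
               q1 = unname(quantile(v, 0.25)),
               q3 = unname(quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  }))
  tests <- NULL
  if (pairwise_tests && length(present) >= 2) {
    tests <- do.call(rbind, lapply(seq_len(length(present) - 1), function(i) {
      a <- value[bin == present[i]]
      b <- value[bin == present[i + 1]]
      if (length(a) < 2 || length(b) < 2) return(NULL)
      wt <- welch_t_test(a, b)
      data.frame(bin_a = present[i], bin_b = present[i + 1],
                 t = wt$t, df = wt$df, p = wt$p, stringsAsFactors = FALSE)
    }))
  }
  list(summary = summ, tests = tests)
}

#' Sigmoidal fit of fraction absorbed against permeability
#'
#' Least-squares fit of the logistic-in-log10 model
#' `fa = 1 / (1 + 10^(hill_slope * (log10_p50 - log10(papp))))`,
#' with the upper asymptote fixed at 1 (complete absorption). A coarse grid
#' over (log10_p50, hill_slope) seeds a Levenberg-Marquardt refinement.
#'
#' @param papp positive permeabilities (cm/s).
#' @param fa fractions absorbed in \[0, 1\].
#' @return object of class `"fa_sigmoid"`: coefficients `log10_p50` and
#'   `hill_slope`, `r2` (1 - SS_res/SS_tot), `fitted`, `residuals`,
#'   `converged`, `n`, plus `diagnostics` when the refinement failed.
#' @export
#' @examples
#' p <- 10^seq(-7, -4.5, length.out = 12)
#' fa <- 1 / (1 + 10^(1 * (log10(3e-6) - log10(p))))
#' fit <- fit_fa_sigmoid(p, fa)
#' coef(fit)
fit_fa_sigmoid <- function(papp, fa) {
  keep <- is.finite(papp) & is.finite(fa)
  papp <- papp[keep]; fa <- fa[keep]
  if (length(papp) < 4) stop_pf("at least 4 (papp, fa) pairs required")
  if (any(papp <= 0)) stop_pf("papp must be > 0")
  if (length(unique(fa)) == 1) {
    stop_pf("all fa values identical: sigmoid fit degenerate")
  }
  x <- log10(papp)
  model <- function(l50, slope) 1 / (1 + 10^(slope * (l50 - x)))
  ss <- function(l50, slope) sum((fa - model(l50, slope))^2)

  grid <- expand.grid(l50 = seq(min(x) - 1, max(x) + 1, length.out = 25),
                      slope = c(0.25, 0.5, 1, 2, 4))
  ss_grid <- mapply(ss, grid$l50, grid$slope)
  start <- grid[which.min(ss_grid), ]

  df <- data.frame(x = x, fa = fa)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fa ~ 1 / (1 + 10^(slope * (l50 - x))),
      data = df, start = list(l50 = start$l50, slope = start$slope),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    cf <- c(l50 = start$l50, slope = start$slope)
    converged <- FALSE
    diagnostics <- conditionMessage(fit)
  } else {
    cf <- coef(fit)
    converged <- TRUE
    diagnostics <- NULL
  }
  pred <- model(cf[["l50"]], cf[["slope"]])
  ss_res <- sum((fa - pred)^2)
  ss_tot <- sum((fa - mean(fa))^2)
  structure(
    list(coefficients = c(log10_p50 = unname(cf[["l50"]]),
                          hill_slope = unname(cf[["slope"]])),
         r2 = 1 - ss_res / ss_tot, ss_res = ss_res,
         fitted = pred, residuals = fa - pred,
         data = df, n = length(fa),
         converged = converged, diagnostics = diagnostics),
    class = "fa_sigmoid"
  )
}

#' @export
coef.fa_sigmoid <- function(object, ...) object$coefficients

#' @export
fitted.fa_sigmoid <- function(object, ...) object$fitted

#' @export
residuals.fa_sigmoid <- function(object, ...) object$residuals

#' Predicted fraction absorbed at new permeabilities
#' @param object an `fa_sigmoid` fit.
#' @param newdata optional numeric vector of Papp values (cm/s); defaults to
#'   the fitting data.
#' @param ... unused.
#' @export
predict.fa_sigmoid <- function(object, newdata = NULL, ...) {
  cf <- object$coefficients
  x <- if (is.null(newdata)) object$data$x else log10(newdata)
  1 / (1 + 10^(cf[["hill_slope"]] * (cf[["log10_p50"]] - x)))
}

#' @export
print.fa_sigmoid <- function(x, ...) {
  cat("<fa_sigmoid fit>\n")
  cat(sprintf("  p50: %.3g cm/s, hill slope: %.3g, R^2 = %.3f (n = %d)%s\n",
              10^x$coefficients[["log10_p50"]], x$coefficients[["hill_slope"]],
              x$r2, x$n,
              if (x$converged) "" else " [did not converge]"))
  invisible(x)
}

#' @export
summary.fa_sigmoid <- function(object, ...) {
  cat("Sigmoidal fa ~ Papp fit (upper asymptote fixed at 1)\n")
  print(object)
  cat(sprintf("  residual SS: %.4g\n", object$ss_res))
  invisible(object)
}
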