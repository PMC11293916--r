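#' Mean absolute error between paired measurements
#'
#' Reports the mean and the sample standard deviation (n - 1 denominator)
#' of the absolute elementwise differences, the usual
#' "mean +/- sd" form of agreement tables. Symmetric in its arguments.
#'
#' @param x,y Numeric vectors of equal length (>= 1).
#' @return One-row tibble: `mean`, `sd` (`NA` for a single pair), `n`.
#' @export
mae <- function(x, y) {
  if (length(x) != length(y)) {
    abort("mae: x and y must have the same length")
  }
  if (length(x) < 1) abort("mae: need at least one pair")
  d <- abs(x - y)
  tibble::tibble(mean = mean(d),
                 sd = if (length(d) > 1) sd(d) else NA_real_,
                 n = length(d))
}

#' Intraclass correlation coefficient with confidence interval
#'
#' ICC from the two-way ANOVA mean-squares decomposition of a subjects x
#' raters matrix. The default, ICC(2,1) (two-way random effects, absolute
#' agreement, single measure), is the standard form for method-comparison
#' designs where raters are a sample and systematic offsets between raters
#' must count against agreement. Also available: ICC(3,1) (raters fixed,
#' consistency) and the average-measure forms ICC(2,k) and ICC(3,k).
#' Confidence intervals use the classical F-distribution formulation
#' (Shrout-Fleiss), with average-measure bounds obtained by
#' Spearman-Brown scaling of the single-measure bounds.
#'
#' A matrix with zero variance everywhere (all raters constant and equal)
#' makes the ANOVA ratio undefined; it is reported as perfect agreement
#' (estimate 1) with a warning.
#'
#' @param ratings Numeric matrix or data frame, subjects in rows, raters in
#'   columns; >= 2 subjects, >= 2 raters, no missing cells (apply listwise
#'   deletion upstream).
#' @param type `"ICC2"`, `"ICC3"`, `"ICC2k"` or `"ICC3k"`.
#' @param alpha Two-sided CI level (default 0.05 for a 95% CI).
#' @return One-row tibble: `type`, `estimate`, `ci_low`, `ci_high`,
#'   `n_subjects`, `n_raters`.
#' @export
icc <- function(ratings, type = c("ICC2", "ICC3", "ICC2k", "ICC3k"),
                alpha = 0.05) {
  type <- match.arg(type)
  m <- as.matrix(ratings)
  if (any(is.na(m))) abort("icc: missing cells; apply listwise deletion first")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) abort("icc: need >= 2 subjects and >= 2 raters")

  grand <- mean(m)
  rm_ <- rowMeans(m); cm <- colMeans(m)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)              # between subjects
  msc <- n * sum((cm - grand)^2) / (k - 1)               # between raters
  mse <- sum((m - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm) + grand)^2) / ((n - 1) * (k - 1))

  if (msr < .Machine$double.eps && mse < .Machine$double.eps &&
      msc < .Machine$double.eps) {
    warn("icc: zero total variance; reporting perfect agreement on a constant")
    return(tibble::tibble(type = type, estimate = 1, ci_low = 1, ci_high = 1,
                          n_subjects = n, n_raters = k))
  }

  est2 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  est3 <- (msr - mse) / (msr + (k - 1) * mse)

  ci2_single <- function() {
    fj <- msc / mse
    a <- k * est2 * fj + n * (1 + (k - 1) * est2) - k * est2
    v <- ((k - 1) * (n - 1) * a^2) /
      ((n - 1) * k^2 * est2^2 * fj^2 + (n * (1 + (k - 1) * est2) - k * est2)^2)
    fu <- qf(1 - alpha / 2, n - 1, v)
    fl <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fu * mse) /
      (fu * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fl * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fl * msr)
    c(lo, hi)
  }
  ci3_single <- function() {
    f <- msr / mse
    fl <- f / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  sb <- function(r) k * r / (1 + (k - 1) * r)   # Spearman-Brown step-up

  # the raw ANOVA estimator is reported unclamped (it can fall outside
  # [-1, 1] for degenerate matrices, exactly as the reference formulas do)
  res <- switch(type,
    ICC2 = c(est2, ci2_single()),
    ICC3 = c(est3, ci3_single()),
    ICC2k = c(sb(est2), sb(ci2_single())),
    ICC3k = c(sb(est3), sb(ci3_single())))
  tibble::tibble(type = type, estimate = res[1], ci_low = res[2],
                 ci_high = res[3], n_subjects = n, n_raters = k)
}

#' Unweighted Cohen's kappa
#'
#' Chance-corrected agreement for two raters on categorical codes; offered
#' alongside the ICC on integer-coded curve types, where it is the
#' statistically sounder choice.
#'
#' @param x,y Vectors of category labels of equal length.
#' @return Kappa estimate (1 = perfect agreement, 0 = chance level).
#' @export
cohen_kappa <- function(x, y) {
  if (length(x) != length(y)) abort("cohen_kappa: unequal lengths")
  lev <- sort(unique(c(x, y)))
  tab <- table(factor(x, lev), factor(y, lev)) / length(x)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (abs(1 - pe) < .Machine$double.eps) return(1)
  (po - pe) / (1 - pe)
}

angle_indicators <- c("pt", "mt", "tll", "t5_t12_kyphosis",
                      "bend_pt", "bend_mt", "bend_tll")

#' Agreement report between two sets of case measurements
#'
#' Pairs two raters' measurements by `case_id` and reports, per indicator,
#' the MAE (mean +/- sd) and ICC with 95% CI for the seven angle
#' indicators, and the ICC on integer-coded curve types 1-6 together with
#' Cohen's kappa. Cases missing an indicator in either rater are dropped
#' listwise for that indicator, with a message giving the count. Treating
#' the categorical type codes as interval data for an ICC is questionable
#' but mirrors common agreement-table practice; kappa is reported
#' alongside as the sounder alternative.
#'
#' @param pred,ref Lists of `case_measurement` objects, or their
#'   [tidy_measurements()] tibbles.
#' @param icc_type ICC form, see [icc()].
#' @return An `agreement_report` tibble: `indicator`, `n`, `mae_mean`,
#'   `mae_sd`, `icc`, `icc_low`, `icc_high`, `kappa` (`NA` for angles).
#' @export
compare_measurements <- function(pred, ref, icc_type = "ICC2") {
  to_tbl <- function(z) {
    if (inherits(z, "data.frame")) tibble::as_tibble(z) else tidy_measurements(z)
  }
  p <- to_tbl(pred); r <- to_tbl(ref)
  j <- dplyr::inner_join(p, r, by = "case_id", suffix = c("_pred", "_ref"))
  if (nrow(j) == 0) abort("no overlapping case_ids between pred and ref")

  row_for <- function(ind) {
    a <- j[[paste0(ind, "_pred")]]
    b <- j[[paste0(ind, "_ref")]]
    ok <- !is.na(a) & !is.na(b)
    dropped <- sum(!ok)
    if (dropped > 0) {
      inform(paste0(ind, ": dropped ", dropped,
                    " case(s) with missing values"))
    }
    if (sum(ok) < 2) {
      return(tibble::tibble(indicator = ind, n = sum(ok),
                            mae_mean = NA_real_, mae_sd = NA_real_,
                            icc = NA_real_, icc_low = NA_real_,
                            icc_high = NA_real_, kappa = NA_real_))
    }
    e <- mae(a[ok], b[ok])
    ic <- icc(cbind(a[ok], b[ok]), type = icc_type)
    tibble::tibble(indicator = ind, n = e$n, mae_mean = e$mean,
                   mae_sd = e$sd, icc = ic$estimate, icc_low = ic$ci_low,
                   icc_high = ic$ci_high, kappa = NA_real_)
  }
  out <- purrr::map(angle_indicators, row_for) |> dplyr::bind_rows()

  a <- j$lenke_type_pred; b <- j$lenke_type_ref
  ok <- !is.na(a) & !is.na(b)
  if (sum(!ok) > 0) {
    inform(paste0("lenke_type: dropped ", sum(!ok),
                  " case(s) with missing values"))
  }
  lr <- if (sum(ok) >= 2) {
    ic <- icc(cbind(as.numeric(a[ok]), as.numeric(b[ok])), type = icc_type)
    tibble::tibble(indicator = "lenke_type", n = sum(ok),
                   mae_mean = NA_real_, mae_sd = NA_real_,
                   icc = ic$estimate, icc_low = ic$ci_low,
                   icc_high = ic$ci_high,
                   kappa = cohen_kappa(a[ok], b[ok]))
  } else {
    tibble::tibble(indicator = "lenke_type", n = sum(ok),
                   mae_mean = NA_real_, mae_sd = NA_real_, icc = NA_real_,
                   icc_low = NA_real_, icc_high = NA_real_, kappa = NA_real_)
  }
  out <- dplyr::bind_rows(out, lr)
  class(out) <- c("agreement_report", class(out))
  out
}

#' Format an agreement report as an aligned text table
#'
#' @param report An `agreement_report` tibble.
#' @return Character vector of table lines (also printed by the
#'   `print` method).
#' @export
format_agreement <- function(report) {
  fmt <- function(v, d = 3) ifelse(is.na(v), "-", formatC(v, digits = d,
                                                          format = "f"))
  lines <- c(
    sprintf("%-16s %4s  %-15s %-22s %6s", "indicator", "n",
            "MAE (mean+/-sd)", "ICC (95% CI)", "kappa"),
    sprintf("%-16s %4d  %-15s %-22s %6s",
            report$indicator, report$n,
            ifelse(is.na(report$mae_mean), "-",
                   paste0(fmt(report$mae_mean, 2), " +/- ",
                          fmt(report$mae_sd, 2))),
            ifelse(is.na(report$icc), "-",
                   paste0(fmt(report$icc), " (", fmt(report$icc_low), ", ",
                          fmt(report$icc_high), ")")),
            fmt(report$kappa)))
  lines
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(format_agreement(x), sep = "\n")
  invisible(x)
}
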