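#' Observer adjudication
#'
#' Resolves the two observers' measurements into one final value per
#' patient. When the observers agree to within the threshold (default
#' 1 mm) the final value is their mean; a discrepancy of more than the
#' threshold is flagged and a third observer's adjudicated value becomes
#' final (by default; `flagged_value = "mean"` keeps the two-observer mean
#' even for flagged cases). A flagged case without an adjudicated value is
#' an error naming the offending position.
#'
#' @param data A data frame with observer columns, or a numeric vector of
#'   first-observer values.
#' @param obs1,obs2 Column names (tidy interface) of the two observers'
#'   measurements (mm). Defaults `obs1_mm`, `obs2_mm`.
#' @param adjudicated Column name of the adjudicated value (`obs3_mm`), or
#'   a numeric vector in the vector interface; may be NA where not needed.
#' @param threshold Discrepancy (mm) above which adjudication is required,
#'   default 1.
#' @param flagged_value `"adjudicated"` (default) or `"mean"`: what the
#'   final value is for flagged cases.
#' @return The input tibble with columns `final_mm` and `flagged` added
#'   (data-frame interface), or a tibble with `final_mm`, `flagged`
#'   (vector interface).
#' @examples
#' adjudicate(tibble::tibble(obs1_mm = c(2, 2), obs2_mm = c(2.4, 3.5),
#'                           obs3_mm = c(NA, 2)))
#' @export
adjudicate <- function(data, obs1 = "obs1_mm", obs2 = "obs2_mm",
                       adjudicated = "obs3_mm", threshold = 1,
                       flagged_value = c("adjudicated", "mean")) {
  flagged_value <- match.arg(flagged_value)
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (is.data.frame(data)) {
    o1 <- data[[obs1]]
    o2 <- data[[obs2]]
    adj <- if (adjudicated %in% names(data)) data[[adjudicated]] else
      rep(NA_real_, nrow(data))
    res <- adjudicate_values(o1, o2, adj, threshold, flagged_value,
                             labels = data$id %||% seq_along(o1))
    data$final_mm <- res$final
    data$flagged <- res$flagged
    return(tibble::as_tibble(data))
  }
  o2 <- obs2
  if (is.character(o2)) stop("vector interface needs numeric obs2",
                             call. = FALSE)
  adj <- if (is.numeric(adjudicated)) adjudicated else
    rep(NA_real_, length(data))
  res <- adjudicate_values(data, o2, adj, threshold, flagged_value,
                           labels = seq_along(data))
  tibble::tibble(final_mm = res$final, flagged = res$flagged)
}

adjudicate_values <- function(o1, o2, adj, threshold, flagged_value, labels) {
  if (any(!is.finite(o1)) || any(!is.finite(o2))) {
    stop("observer values must be present and finite", call. = FALSE)
  }
  flagged <- abs(o1 - o2) > threshold
  final <- (o1 + o2) / 2
  if (flagged_value == "adjudicated") {
    need <- flagged & !is.finite(adj)
    if (any(need)) {
      stop("missing adjudication: discrepancy > ", threshold,
           " mm without adjudicated value for ",
           paste(labels[need], collapse = ", "), call. = FALSE)
    }
    final[flagged] <- adj[flagged]
  }
  list(final = final, flagged = flagged)
}

#' Two-sample t-test for subgroup differences
#'
#' Compares bilateral length differences between the two levels of a
#' grouping factor (age group, sex, malunion side). Welch's unequal-
#' variance test by default; `var_equal = TRUE` gives Student's pooled
#' test. Groups with zero variance are handled explicitly: identical
#' group means give t = 0, p = 1, separated zero-variance groups give
#' p = 0.
#'
#' @param values Numeric vector (mm).
#' @param groups Two-level factor (or coercible) of the same length.
#' @param var_equal Use the pooled-variance Student test, default FALSE.
#' @return A tibble with `t`, `df`, `p`, group labels, per-group n, mean,
#'   sd.
#' @export
subgroup_t_test <- function(values, groups, var_equal = FALSE) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) {
    stop("groups must have exactly 2 levels", call. = FALSE)
  }
  sp <- split(values, groups)
  if (any(vapply(sp, length, 1L) < 2)) {
    stop("insufficient data: each group needs n >= 2", call. = FALSE)
  }
  v <- vapply(sp, stats::var, 1)
  m <- vapply(sp, mean, 1)
  if (all(v < 1e-24)) {
    tt <- list(statistic = if (abs(m[1] - m[2]) < 1e-12) 0 else
                 sign(m[1] - m[2]) * Inf,
               parameter = sum(lengths(sp)) - 2,
               p.value = if (abs(m[1] - m[2]) < 1e-12) 1 else 0)
  } else {
    tt <- stats::t.test(sp[[1]], sp[[2]], var.equal = var_equal)
  }
  tibble::tibble(
    group1 = levels(groups)[1], group2 = levels(groups)[2],
    n1 = length(sp[[1]]), n2 = length(sp[[2]]),
    mean1 = m[1], mean2 = m[2],
    sd1 = sqrt(v[1]), sd2 = sqrt(v[2]),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = unname(tt$p.value)
  )
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test against a normal with mean and SD estimated from the
#' sample. Because the parameters are estimated, the Lilliefors-corrected
#' test (default) is used; `lilliefors = FALSE` restores the naive KS test,
#' which is anticonservative in this situation. Constant input is treated
#' as a rejection with a warning (a point mass is not a normal).
#'
#' @param values Numeric vector, n >= 5.
#' @param lilliefors Apply the Lilliefors correction, default TRUE.
#' @return A tibble with `statistic`, `p`, `method`.
#' @export
ks_normality <- function(values, lilliefors = TRUE) {
  values <- values[is.finite(values)]
  if (length(values) < 5) {
    stop("insufficient data: normality check needs n >= 5", call. = FALSE)
  }
  if (stats::sd(values) < 1e-12) {
    warning("constant values: degenerate distribution treated as ",
            "non-normal (p = 0)")
    return(tibble::tibble(statistic = 1, p = 0,
                          method = "degenerate (zero variance)"))
  }
  if (lilliefors) {
    kt <- nortest::lillie.test(values)
    tibble::tibble(statistic = unname(kt$statistic), p = kt$p.value,
                   method = "Lilliefors-corrected Kolmogorov-Smirnov")
  } else {
    kt <- suppressWarnings(stats::ks.test(values, "pnorm", mean(values),
                                          stats::sd(values)))
    tibble::tibble(statistic = unname(kt$statistic), p = kt$p.value,
                   method = "Kolmogorov-Smirnov (estimated parameters)")
  }
}

#' Intraclass correlation for two observers, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC from
#' the standard mean-squares decomposition, with the 95% confidence
#' interval by the F-distribution method (McGraw & Wong). This is the
#' standard form for two interchangeable raters under the Koo & Li
#' interpretation guidelines.
#'
#' @param obs_matrix n x 2 numeric matrix (or data frame) of the two
#'   observers' measurements (mm), n >= 5, no missing cells.
#' @param conf_level Confidence level, default 0.95.
#' @return A tibble with `icc`, `ci_low`, `ci_high`, `n`, `k`.
#' @export
icc_two_observers <- function(obs_matrix, conf_level = 0.95) {
  x <- as.matrix(obs_matrix)
  if (ncol(x) != 2) stop("obs_matrix must have exactly 2 columns",
                         call. = FALSE)
  if (nrow(x) < 5) stop("insufficient data: ICC needs n >= 5 subjects",
                        call. = FALSE)
  if (any(!is.finite(x))) stop("missing cells in observer matrix",
                               call. = FALSE)
  n <- nrow(x)
  k <- ncol(x)

  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  grand <- mean(x)
  ssr <- k * sum((row_m - grand)^2)           # subjects
  ssc <- n * sum((col_m - grand)^2)           # observers
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- if (denom < 1e-24) 1 else (msr - mse) / denom

  alpha <- 1 - conf_level
  if (msc < 1e-24 && mse < 1e-24) {
    # perfect agreement: interval collapses
    lo <- hi <- 1
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    if (!is.finite(a) || !is.finite(b)) {
      lo <- hi <- 1
    } else {
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      fl <- stats::qf(1 - alpha / 2, n - 1, v)
      fu <- stats::qf(1 - alpha / 2, v, n - 1)
      lo <- n * (msr - fl * mse) /
        (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
      hi <- n * (fu * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fu * msr)
    }
  }
  tibble::tibble(icc = icc, ci_low = lo, ci_high = hi, n = n, k = k)
}

#' Minimum sample size for estimating a mean
#'
#' Smallest n such that the half-width of the two-sided normal confidence
#' interval for a mean with known SD is at most `half_width`:
#' `n = ceiling((z_{1-alpha/2} * sd / half_width)^2)`.
#'
#' @param sd Standard deviation (mm), > 0.
#' @param half_width Desired confidence-interval half-width (mm), > 0.
#' @param alpha Two-sided significance level in (0, 1), default 0.05.
#' @return Integer sample size.
#' @examples
#' sample_size_mean(1.95, 0.5, 0.05) # 59
#' @export
sample_size_mean <- function(sd, half_width, alpha = 0.05) {
  if (!is.numeric(sd) || sd <= 0) stop("sd must be > 0", call. = FALSE)
  if (!is.numeric(half_width) || half_width <= 0) {
    stop("half_width must be > 0", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm(1 - alpha / 2)
  as.integer(ceiling((z * sd / half_width)^2))
}

#' Mean of the folded normal distribution
#'
#' E|X| for X ~ N(mu, sigma^2):
#' `sigma * sqrt(2/pi) * exp(-mu^2 / (2 sigma^2)) + mu * (1 - 2 Phi(-mu/sigma))`;
#' `|mu|` when sigma = 0. Links the signed and absolute summaries of a
#' cohort of bilateral differences (e.g. signed N(1.02, 2.98) mm implies a
#' population mean absolute difference of about 2.52 mm).
#'
#' @param mu Mean of the signed distribution (mm).
#' @param sigma SD of the signed distribution (mm), >= 0.
#' @return E|X| in mm.
#' @export
folded_normal_mean <- function(mu, sigma) {
  if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  ifelse(sigma == 0, abs(mu),
         sigma * sqrt(2 / pi) * exp(-mu^2 / (2 * sigma^2)) +
           mu * (1 - 2 * stats::pnorm(-mu / sigma)))
}
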