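#' Convert raw TLX ticks to percentages
#'
#' The six-scale workload questionnaire is answered on horizontal scales
#' with 21 ticks; tick `k` maps to `(k - 1) / 20 * 100` percent, so the
#' response range becomes 0% (minimum possible) to 100% (maximum
#' possible) in steps of 5.
#'
#' @param ticks Integer vector (or named vector/list of the six scales)
#'   with values in 1..21.
#' @return Numeric vector of percentages, names preserved.
#' @export
tlx_percent <- function(ticks) {
  ticks <- unlist(ticks)
  if (any(ticks != round(ticks)) || any(ticks < 1 | ticks > 21))
    stop("TLX ticks must be integers in 1..21", call. = FALSE)
  (ticks - 1) / 20 * 100
}

#' Paired-samples t-test
#'
#' Standard paired t statistic with two-sided p-value and `df = n - 1`,
#' after pairwise deletion of incomplete pairs. Zero variance of the
#' differences (e.g. `b = a + c` exactly) is a degenerate input and raises
#' an error rather than returning an infinite statistic.
#'
#' @param a,b Paired numeric vectors.
#' @return List with elements `t`, `df`, `p`, `n`, `mean_diff`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  d <- a[ok] - b[ok]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  s <- stats::sd(d)
  if (s <= 1e-10 * max(1, max(abs(d))))
    stop("zero variance of paired differences", call. = FALSE)
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1), n = n,
       mean_diff = mean(d))
}

#' Two-way repeated-measures ANOVA (2 x 3 within-subjects)
#'
#' Both factors vary within participants: eye-tracker model (2 levels)
#' crossed with dynamicity condition (3 levels). Participants with any
#' missing cell are dropped (listwise deletion). Each effect is tested
#' against its own effect-by-participant interaction, and partial eta
#' squared is `SS_effect / (SS_effect + SS_error)`. Degrees of freedom are
#' uncorrected; `gg_correct = TRUE` applies a Greenhouse-Geisser epsilon
#' to the dynamicity and interaction tests for users who want it.
#'
#' @param data Long data frame with columns `participant`, `device`,
#'   `dynamicity`, `value` (one row per cell).
#' @param gg_correct Apply Greenhouse-Geisser correction (default FALSE).
#' @return Data frame with one row per effect (`device`, `dynamicity`,
#'   `device:dynamicity`): `F`, `df1`, `df2`, `p`, `pes` (partial eta
#'   squared), `n` (complete participants).
#' @export
rm_anova_2x3 <- function(data, gg_correct = FALSE) {
  stopifnot(all(c("participant", "device", "dynamicity", "value") %in%
                  names(data)))
  data$participant <- as.character(data$participant)
  data$device <- as.character(data$device)
  data$dynamicity <- as.character(data$dynamicity)
  a_lv <- sort(unique(data$device))
  b_lv <- sort(unique(data$dynamicity))
  stopifnot(length(a_lv) == 2, length(b_lv) == 3)
  cells_per <- tapply(is.finite(data$value), data$participant, sum)
  complete <- names(cells_per)[!is.na(cells_per) & cells_per == 6]
  keep <- data$participant %in% complete & is.finite(data$value)
  data <- data[keep, , drop = FALSE]
  n <- length(complete)
  if (n < 2) stop("need at least 2 complete participants", call. = FALSE)
  if (nrow(data) != 6 * n) stop("duplicated cells in input", call. = FALSE)

  y <- array(NA_real_, c(n, 2, 3))
  pi_ <- match(data$participant, complete)
  ai <- match(data$device, a_lv)
  bi <- match(data$dynamicity, b_lv)
  y[cbind(pi_, ai, bi)] <- data$value

  g <- mean(y)
  m_a <- apply(y, 2, mean); m_b <- apply(y, 3, mean)
  m_s <- apply(y, 1, mean)
  m_ab <- apply(y, c(2, 3), mean)
  m_as <- apply(y, c(1, 2), mean)
  m_bs <- apply(y, c(1, 3), mean)

  ss_a <- n * 3 * sum((m_a - g)^2)
  ss_b <- n * 2 * sum((m_b - g)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, 3)) -
                      outer(rep(1, 2), m_b) + g)^2)
  ss_as <- 3 * sum((m_as - matrix(m_s, n, 2) -
                      matrix(m_a, n, 2, byrow = TRUE) + g)^2)
  ss_bs <- 2 * sum((m_bs - matrix(m_s, n, 3) -
                      matrix(m_b, n, 3, byrow = TRUE) + g)^2)
  full <- array(0, c(n, 2, 3))
  for (i in 1:n) for (j in 1:2) for (k in 1:3)
    full[i, j, k] <- y[i, j, k] - m_ab[j, k] - m_as[i, j] - m_bs[i, k] +
      m_a[j] + m_b[k] + m_s[i] - g
  ss_abs <- sum(full^2)

  eff <- function(name, ss_e, df1, ss_err, df2, eps = 1) {
    Fv <- (ss_e / df1) / (ss_err / df2)
    data.frame(effect = name, F = Fv, df1 = df1 * eps, df2 = df2 * eps,
               p = stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE),
               pes = ss_e / (ss_e + ss_err), n = n,
               stringsAsFactors = FALSE)
  }
  eps_b <- eps_ab <- 1
  if (gg_correct) {
    eps_b <- gg_epsilon(m_bs)
    d_ab <- y[, 1, ] - y[, 2, ]
    eps_ab <- gg_epsilon(d_ab)
  }
  rbind(eff("device", ss_a, 1, ss_as, n - 1),
        eff("dynamicity", ss_b, 2, ss_bs, 2 * (n - 1), eps_b),
        eff("device:dynamicity", ss_ab, 2, ss_abs, 2 * (n - 1), eps_ab))
}

# Greenhouse-Geisser epsilon from the covariance of the repeated measures
gg_epsilon <- function(m) {
  S <- stats::cov(m)
  k <- ncol(S)
  sbar <- mean(S)
  num <- k^2 * (mean(diag(S)) - sbar)^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * sbar^2)
  max(1 / (k - 1), min(1, num / den))
}

#' Pearson / point-biserial correlation
#'
#' Pearson product-moment correlation with two-sided p-value after
#' pairwise deletion. When `x` is binary (0/1) this is numerically
#' identical to the point-biserial correlation, so group-membership
#' predictors need no special casing.
#'
#' @param x,y Numeric vectors (x may be binary 0/1).
#' @return List with `r`, `p`, `n`.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input has no defined correlation", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Overall accuracy as an averaged z-score
#'
#' Standardizes each condition's accuracies across participants (sample
#' SD, n - 1) and averages each participant's available z-scores over the
#' conditions, yielding one comparable overall-accuracy scalar per
#' participant even when some condition cells are missing. Conditions with
#' zero variance are skipped with a warning.
#'
#' @param m Numeric matrix, participants x conditions (NAs allowed).
#' @return Numeric vector of per-participant overall z-scores.
#' @export
overall_accuracy_z <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 2)
  z <- m
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      warning("condition ", j, " has zero variance; skipped", call. = FALSE)
      z[, j] <- NA_real_
    } else {
      z[, j] <- (v - mean(v, na.rm = TRUE)) / s
    }
  }
  rowMeans(z, na.rm = TRUE)
}
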