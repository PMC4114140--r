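#' Two-sided Mann-Whitney rank-sum test
#'
#' Mann-Whitney U with mid-rank ties. Two modes: a normal approximation
#' with tie-corrected variance and no continuity correction, and an
#' exact-enumeration mode that enumerates all assignments of the observed
#' (mid-)ranks to the two groups. `mode = "auto"` picks exact enumeration
#' when the combined sample size is at most 12.
#'
#' @param group_a,group_b Numeric observation vectors (each of length >= 1,
#'   and >= 2 combined distinct assignments).
#' @param mode `"auto"`, `"normal"` or `"exact"`.
#' @return An object of class `htest` with the U statistic of `group_a`,
#'   the two-sided p-value, and the group sizes in `parameter`.
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4), mode = "exact")$p.value # 2/6
#' @export
rank_sum_test <- function(group_a, group_b,
                          mode = c("auto", "normal", "exact")) {
  mode <- match.arg(mode)
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  na <- length(group_a); nb <- length(group_b)
  if (na == 0 || nb == 0) stop("both groups must be non-empty")
  N <- na + nb
  if (mode == "auto") mode <- if (N <= 12) "exact" else "normal"
  r <- rank(c(group_a, group_b))
  W <- sum(r[seq_len(na)])
  U <- W - na * (na + 1) / 2
  mu <- na * nb / 2
  if (mode == "normal") {
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all observations tied
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "Mann-Whitney rank-sum test (tie-corrected normal approximation)"
  } else {
    # the permutation distribution of U is symmetric about mu, ties included
    sets <- combn(N, na)
    Us <- colSums(matrix(r[sets], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    method <- "Mann-Whitney rank-sum test (exact enumeration)"
  }
  structure(list(statistic = c(U = U), p.value = p,
                 parameter = c(n_a = na, n_b = nb),
                 method = method,
                 data.name = paste(deparse(substitute(group_a)), "vs",
                                   deparse(substitute(group_b)))),
            class = "htest")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson chi-square with 1 degree of freedom and no continuity
#' correction.
#'
#' @param table A 2x2 matrix of non-negative counts; every marginal must be
#'   positive (all expected counts > 0).
#' @return An object of class `htest`.
#' @examples
#' chi_square_2x2(matrix(c(9, 18, 17, 4), 2))
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("a 2x2 table is required")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal: every row and column total must be positive")
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  X2 <- sum((table - E)^2 / E)
  structure(list(statistic = c(`X-squared` = X2),
                 parameter = c(df = 1),
                 p.value = pchisq(X2, df = 1, lower.tail = FALSE),
                 method = "Pearson chi-square test (df = 1, no continuity correction)",
                 data.name = deparse(substitute(table))),
            class = "htest")
}
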