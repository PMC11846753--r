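# Exact Wilcoxon tests by full enumeration, with midranks for ties.
# Small-sample enumeration: all 2^n sign patterns for the paired
# signed-rank test, all C(n1+n2, n1) group labelings for the rank-sum
# test. Beyond the enumeration limits a normal approximation with
# continuity correction is used.

#' Exact Wilcoxon tests
#'
#' Paired (signed-rank) or unpaired (rank-sum) two-sided Wilcoxon test
#' with the null distribution enumerated exactly for small samples
#' (`n <= 12` per group by default); ties are midranked and zero paired
#' differences are dropped. The two-sided p doubles the smaller tail,
#' capped at 1.
#'
#' @param x,y Numeric samples (equal length when `paired = TRUE`).
#' @param paired Paired signed-rank test instead of rank sum.
#' @param exact_limit Largest per-group n for exact enumeration.
#' @return Tibble with `statistic`, `p_value`, `method`, `exact`.
#' @export
wilcoxon_test <- function(x, y, paired = FALSE, exact_limit = 12) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) >= 1, length(y) >= 1)
  if (paired) {
    if (length(x) != length(y)) stop("paired test needs equal lengths", call. = FALSE)
    d <- x - y
    d <- d[d != 0]
    n <- length(d)
    if (n == 0) {
      return(tibble::tibble(statistic = NA_real_, p_value = 1,
                            method = "wilcoxon signed-rank", exact = TRUE))
    }
    r <- rank(abs(d))
    w <- sum(r[d > 0])
    if (n <= exact_limit) {
      # all 2^n sign assignments
      signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
      w_null <- as.vector(signs %*% r)
      p_le <- mean(w_null <= w + 1e-9)
      p_ge <- mean(w_null >= w - 1e-9)
      p <- min(1, 2 * min(p_le, p_ge))
      exact <- TRUE
    } else {
      mu <- sum(r) / 2
      sig <- sqrt(sum(r^2) / 4)
      z <- (w - mu - sign(w - mu) * 0.5) / sig
      p <- min(1, 2 * stats::pnorm(-abs(z)))
      exact <- FALSE
    }
    tibble::tibble(statistic = w, p_value = p,
                   method = "wilcoxon signed-rank", exact = exact)
  } else {
    n1 <- length(x); n2 <- length(y)
    r <- rank(c(x, y))
    w <- sum(r[seq_len(n1)])
    if (n1 <= exact_limit && n2 <= exact_limit) {
      combos <- utils::combn(n1 + n2, n1)
      w_null <- colSums(matrix(r[combos], nrow = n1))
      p_le <- mean(w_null <= w + 1e-9)
      p_ge <- mean(w_null >= w - 1e-9)
      p <- min(1, 2 * min(p_le, p_ge))
      exact <- TRUE
    } else {
      mu <- n1 * (n1 + n2 + 1) / 2
      tie_tab <- table(r)
      n <- n1 + n2
      sig <- sqrt(n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1))))
      z <- (w - mu - sign(w - mu) * 0.5) / sig
      p <- min(1, 2 * stats::pnorm(-abs(z)))
      exact <- FALSE
    }
    tibble::tibble(statistic = w, p_value = p,
                   method = "wilcoxon rank-sum", exact = exact)
  }
}

#' One-sample normality test (Kolmogorov-Smirnov)
#'
#' KS test against a normal distribution with moment-estimated mean and
#' SD.
#'
#' @param values Numeric vector, `n >= 3`.
#' @return Tibble with `statistic`, `p_value`, `method`.
#' @export
normality_test <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("normality test needs n >= 3", call. = FALSE)
  if (stats::sd(values) == 0) stop("constant input; normality test degenerate", call. = FALSE)
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values))
  )
  tibble::tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
                 method = "one-sample KS vs fitted normal")
}
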