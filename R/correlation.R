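# Correlation machinery shared by all screens. Spearman uses average ranks
# for ties; small samples (n <= 7) get exact permutation p-values so the
# t-approximation is never trusted where it is weakest.

# All permutations of 1..n as a (n! x n) integer matrix, insertion order.
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(rep(k, nrow(sub)), matrix(rest[sub], nrow = nrow(sub)))
  }))
  dimnames(out) <- NULL
  out
}

#' Correlation test between a load and drug sensitivity
#'
#' Computes a Spearman or Pearson correlation on pairwise-complete
#' observations with a one-sided (`alternative = "greater"`, the default:
#' the working hypothesis is that sensitivity increases with load) or
#' two-sided p-value. Spearman uses average ranks for ties; its p-value is
#' an exact permutation enumeration over all `n!` orderings when `n <= 7`
#' and the t-approximation with `n - 2` degrees of freedom otherwise.
#' Pearson always uses the t-distribution with `n - 2` degrees of freedom.
#'
#' @param x,y Aligned numeric vectors.
#' @param method `"spearman"` or `"pearson"`.
#' @param alternative `"greater"` (H1: coefficient > 0) or `"two.sided"`.
#' @return A list with `estimate`, `p.value`, `n` (pairwise-complete count)
#'   and `untestable` (`TRUE` when `n < 3` or either vector is constant, in
#'   which case estimate and p are `NA` and the result must be excluded
#'   from any FDR family).
#' @examples
#' corTest(1:4, c(10, 20, 30, 40))$estimate # 1
#' corTest(1:3, 3:1)$p.value                # 1: anti-monotone, H1 rho > 0
#' @export
corTest <- function(x, y, method = c("spearman", "pearson"),
                    alternative = c("greater", "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(estimate = NA_real_, p.value = NA_real_, n = n,
                untestable = TRUE))
  est <- stats::cor(x, y, method = method)
  if (method == "spearman" && n <= 7L) {
    perms <- .permutations(n)
    rx <- rank(x); ry <- rank(y)
    rperm <- apply(perms, 1L, function(ix) stats::cor(rx, ry[ix]))
    p <- if (alternative == "greater") mean(rperm >= est - 1e-12)
         else mean(abs(rperm) >= abs(est) - 1e-12)
  } else {
    tt <- est * sqrt((n - 2) / max(1 - est^2, .Machine$double.eps))
    p <- if (alternative == "greater") stats::pt(tt, n - 2, lower.tail = FALSE)
         else min(1, 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE))
  }
  list(estimate = est, p.value = p, n = n, untestable = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_(j >= i) m * p_(j) / j`, clipped at 1 and
#' returned in input order. An empty input yields an empty output.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order.
#' @export
bhAdjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}
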