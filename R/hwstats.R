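#' Hardy-Weinberg goodness-of-fit test and inbreeding coefficient
#'
#' From observed genotype counts at a biallelic locus, estimates allele
#' frequencies by allele counting (`p = (2 n_AA + n_Aa) / 2n`), computes
#' Hardy-Weinberg expected counts `n (p^2, 2pq, q^2)`, a chi-square
#' goodness-of-fit statistic on 1 degree of freedom (three classes, one
#' estimated parameter; no continuity correction, which keeps the algebraic
#' identity `chi2 = n F^2` exact), and the inbreeding coefficient as the
#' proportional deficit of heterozygotes, `F = 1 - O_Aa / E_Aa`.
#'
#' A monomorphic sample (`p` of 0 or 1) returns `chi2 = 0` with `F` not
#' available and a warning flag; expected counts below 5 set a small-count
#' flag (the chi-square approximation weakens) without refusing the test.
#'
#' @param counts Genotype counts as a numeric vector `(n_AA, n_Aa, n_aa)`
#'   (optionally named), a data frame with columns `AA`, `Aa`, `aa`, or three
#'   separate arguments via `...`.
#' @param ... Alternative scalar interface: `hw_test(50, 30, 20)`.
#' @return An object of class `hw_test`: list with `observed`, `expected`,
#'   `p_hat`, `q_hat`, `chi2`, `df` (1), `p_value`, `f_hat`, `n` and logical
#'   flags `monomorphic`, `small_expected`.
#' @examples
#' hw_test(c(50, 30, 20))
#' hw_test(c(25, 50, 25))  # exact HW proportions: chi2 = 0, F = 0
#' @export
hw_test <- function(counts, ...) {
  extra <- list(...)
  if (length(extra) == 2L && is.numeric(counts) && length(counts) == 1L) {
    counts <- c(counts, extra[[1]], extra[[2]])
  }
  if (is.data.frame(counts)) {
    if (!all(c("AA", "Aa", "aa") %in% names(counts)) || nrow(counts) != 1L) {
      abort("A data-frame input needs one row with columns AA, Aa, aa.")
    }
    counts <- c(counts$AA, counts$Aa, counts$aa)
  }
  if (!is.numeric(counts) || length(counts) != 3L || any(is.na(counts)) ||
      any(counts < 0) || any(counts != floor(counts))) {
    abort("`counts` must be three non-negative integers (n_AA, n_Aa, n_aa).")
  }
  obs <- setNames(as.numeric(counts), c("AA", "Aa", "aa"))
  n <- sum(obs)
  if (n < 1) abort("Total count must be at least 1.")

  p_hat <- (2 * obs[["AA"]] + obs[["Aa"]]) / (2 * n)
  q_hat <- 1 - p_hat
  expected <- n * c(AA = p_hat^2, Aa = 2 * p_hat * q_hat, aa = q_hat^2)
  monomorphic <- p_hat %in% c(0, 1)

  nz <- expected > 0
  chi2 <- sum((obs[nz] - expected[nz])^2 / expected[nz])
  df <- 1L
  p_value <- pchisq(chi2, df = df, lower.tail = FALSE)
  f_hat <- if (expected[["Aa"]] > 0) 1 - obs[["Aa"]] / expected[["Aa"]] else NA_real_
  if (monomorphic) {
    warn("Sample is monomorphic: Hardy-Weinberg fit is trivial and F is undefined.")
  }

  structure(list(
    observed = obs, expected = expected, n = n,
    p_hat = p_hat, q_hat = q_hat,
    chi2 = chi2, df = df, p_value = p_value, f_hat = f_hat,
    monomorphic = monomorphic,
    small_expected = any(expected < 5)
  ), class = "hw_test")
}

#' @export
print.hw_test <- function(x, ...) {
  cat("Hardy-Weinberg goodness-of-fit\n")
  cat(sprintf("  counts (AA, Aa, aa): %s   n = %g\n",
              paste(x$observed, collapse = ", "), x$n))
  cat(sprintf("  p = %.4f, q = %.4f\n", x$p_hat, x$q_hat))
  cat(sprintf("  expected: %s\n", paste(format(x$expected, digits = 4), collapse = ", ")))
  cat(sprintf("  chi-square = %.4f, df = %d, p-value = %.4g\n", x$chi2, x$df, x$p_value))
  cat(sprintf("  inbreeding coefficient F = %s\n",
              if (is.na(x$f_hat)) "not available (no expected heterozygotes)"
              else sprintf("%.4f", x$f_hat)))
  if (x$small_expected) cat("  note: some expected counts < 5; chi-square approximation is rough\n")
  invisible(x)
}

#' @export
tidy.hw_test <- function(x, ...) {
  tibble(
    genotype = c("AA", "Aa", "aa"),
    observed = unname(x$observed),
    expected = unname(x$expected),
    residual = unname((x$observed - x$expected) /
                        ifelse(x$expected > 0, sqrt(x$expected), NA_real_))
  )
}

#' @export
glance.hw_test <- function(x, ...) {
  tibble(n = x$n, p_hat = x$p_hat, q_hat = x$q_hat, chi2 = x$chi2,
         df = x$df, p_value = x$p_value, f_hat = x$f_hat,
         monomorphic = x$monomorphic, small_expected = x$small_expected)
}

#' @export
autoplot.hw_test <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("observed", "expected"),
                        names_to = "kind", values_to = "count")
  d$genotype <- factor(d$genotype, levels = c("AA", "Aa", "aa"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$genotype, y = .data$count,
                                  fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(title = sprintf("chi-square = %.3f (df 1), F = %.3f",
                                  object$chi2, object$f_hat),
                  y = "count") +
    ggplot2::theme_minimal()
}
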