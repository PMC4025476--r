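#' Solve the Breeder's equation
#'
#' `R = h2 * S`: response to selection equals heritability times the
#' selection differential. Give exactly two of the three quantities and the
#' third is solved for. A heritability outside `[0, 1]` is rejected with a
#' diagnostic, as is solving for `h2` when `S = 0`.
#'
#' @param h2 Heritability in `[0, 1]` (trait-variance ratio, unitless).
#' @param s Selection differential, in trait units.
#' @param r Response to selection, in trait units.
#' @return A one-row tibble with columns `h2`, `s`, `r` and `solved_for`.
#' @examples
#' breeders_solve(h2 = 0.5, s = 10)   # r = 5
#' breeders_solve(r = 3, s = 10)      # h2 = 0.3
#' @export
breeders_solve <- function(h2 = NULL, s = NULL, r = NULL) {
  given <- !vapply(list(h2, s, r), is.null, logical(1))
  if (sum(given) != 2L) {
    abort("Give exactly two of `h2`, `s`, `r`; the third is solved for.")
  }
  if (!is.null(h2)) check_prob(h2, "h2")
  unknown <- c("h2", "s", "r")[!given]
  if (unknown == "r") {
    r <- h2 * s
  } else if (unknown == "h2") {
    if (s == 0) abort("Cannot solve for heritability when the selection differential is 0.")
    h2 <- r / s
    if (h2 < 0 || h2 > 1) {
      abort(sprintf("Implied heritability %.4g is outside [0, 1]: R and S are inconsistent with the model.", h2))
    }
  } else {
    if (h2 == 0) {
      if (r != 0) abort("No selection differential satisfies R = h2*S when h2 = 0 and R != 0.")
      abort("S is indeterminate when h2 = 0 and R = 0.")
    }
    s <- r / h2
  }
  tibble(h2 = h2, s = s, r = r, solved_for = unknown)
}

#' Solve the exponential population growth model
#'
#' `N_t = N0 * exp(r t)` in continuous time, with the intrinsic rate of
#' increase supplied directly as `r` or as birth minus death rate
#' (`r = b - d`). Give all quantities but one; the missing one is solved in
#' closed form (logarithms for `r` or `t`).
#'
#' @param n0 Initial population size (> 0).
#' @param r Intrinsic rate of increase per unit time. Alternatively give
#'   `b` and `d`.
#' @param b,d Per-capita birth and death rates (`r = b - d`).
#' @param t Elapsed time (>= 0 when given).
#' @param nt Population size at time `t` (> 0 when given).
#' @return A one-row tibble with `n0`, `r`, `t`, `nt`, `solved_for` and, when
#'   rates were supplied, `b` and `d`.
#' @examples
#' growth_solve(n0 = 100, r = 0.1, t = 10)        # nt = 100 * e
#' growth_solve(n0 = 100, b = 0.3, d = 0.1, t = 5)
#' growth_solve(n0 = 100, nt = 200, r = 0.05)     # doubling time
#' @export
growth_solve <- function(n0 = NULL, r = NULL, b = NULL, d = NULL,
                         t = NULL, nt = NULL) {
  if (!is.null(b) || !is.null(d)) {
    if (is.null(b) || is.null(d)) abort("Give both `b` and `d` (r = b - d).")
    if (!is.null(r)) abort("Give either `r` or the pair (`b`, `d`), not both.")
    r <- b - d
  }
  given <- !vapply(list(nt, t, r, n0), is.null, logical(1))
  if (sum(given) != 3L) {
    abort("Give all but one of `nt`, `t`, `r` (or `b`/`d`), `n0`.")
  }
  unknown <- c("nt", "t", "r", "n0")[!given]
  if (!is.null(n0) && n0 <= 0) abort("`n0` must be positive.")
  if (!is.null(nt) && nt <= 0) abort("`nt` must be positive.")
  if (!is.null(t) && t < 0) abort("`t` must be non-negative.")

  if (unknown == "nt") {
    nt <- n0 * exp(r * t)
  } else if (unknown == "t") {
    if (r == 0) {
      if (nt != n0) abort("No finite time reaches a different size when r = 0.")
      abort("Time is indeterminate when r = 0 and nt = n0.")
    }
    t <- log(nt / n0) / r
    if (t < 0) abort("The implied time is negative: the population moves away from `nt` under this r.")
  } else if (unknown == "r") {
    if (t == 0) {
      if (nt != n0) abort("No growth rate changes the size in zero time.")
      abort("Growth rate is indeterminate when t = 0.")
    }
    r <- log(nt / n0) / t
  } else {
    n0 <- nt / exp(r * t)
  }
  out <- tibble(n0 = n0, r = r, t = t, nt = nt, solved_for = unknown)
  if (!is.null(b)) {
    out$b <- b
    out$d <- d
  }
  out
}
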