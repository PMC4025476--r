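#' Genotype frequencies under inbreeding
#'
#' Wright's single-locus parameterization: with allele frequency `p` (and
#' `q = 1 - p`) and inbreeding coefficient `F`, genotype proportions are
#' `p^2 + Fpq`, `2pq(1 - F)`, `q^2 + Fpq`. `F = 0` recovers Hardy-Weinberg
#' proportions; `F = 1` removes heterozygotes entirely.
#'
#' @param p Frequency of the tracked allele, in `[0, 1]`.
#' @param f Inbreeding coefficient, in `[0, 1]`.
#' @return Named numeric vector `c(AA =, Aa =, aa =)` summing to 1, where
#'   `AA` is the homozygote for the tracked allele.
#' @examples
#' genotype_frequencies(0.5, 0)   # 0.25 0.50 0.25
#' genotype_frequencies(0.5, 1)   # 0.5 0 0.5
#' @export
genotype_frequencies <- function(p, f = 0) {
  check_prob(p, "p")
  check_prob(f, "f")
  q <- 1 - p
  c(AA = p^2 + f * p * q, Aa = 2 * p * q * (1 - f), aa = q^2 + f * p * q)
}

#' Relative fitnesses of the three genotypes
#'
#' @param w_AA,w_Aa,w_aa Non-negative relative fitnesses of the tracked-allele
#'   homozygote, the heterozygote and the other homozygote. At least one must
#'   be positive.
#' @return Named numeric vector of class `selection_scheme`.
#' @examples
#' selection_scheme(1, 1, 0.8)   # recessive disadvantage
#' @export
selection_scheme <- function(w_AA = 1, w_Aa = 1, w_aa = 1) {
  w <- c(AA = w_AA, Aa = w_Aa, aa = w_aa)
  if (any(!is.finite(w)) || any(w < 0)) abort("Fitnesses must be finite and >= 0.")
  if (all(w == 0)) abort("At least one fitness must be positive.")
  structure(w, class = "selection_scheme")
}

as_selection_scheme <- function(w) {
  if (inherits(w, "selection_scheme")) return(w)
  if (is.numeric(w) && length(w) == 3L) return(selection_scheme(w[1], w[2], w[3]))
  abort("`fitness` must be a selection_scheme or a numeric vector (w_AA, w_Aa, w_aa).")
}

# post-selection expected genotype proportions; errors if mean fitness is 0
post_selection_props <- function(p, w, f) {
  g <- genotype_frequencies(p, f)
  wbar <- sum(g * w)
  if (wbar == 0) {
    abort("Mean fitness is zero: every genotype present has fitness 0 (degenerate population).")
  }
  g * w / wbar
}

#' One deterministic generation of viability selection
#'
#' Applies genotypic selection to the inbreeding-adjusted genotype
#' proportions: with post-selection mean fitness
#' `wbar = P_AA w_AA + P_Aa w_Aa + P_aa w_aa`, the next frequency is
#' `p' = (P_AA w_AA + P_Aa w_Aa / 2) / wbar`.
#'
#' @inheritParams genotype_frequencies
#' @param fitness A [selection_scheme()] or numeric `(w_AA, w_Aa, w_aa)`.
#' @return The next-generation allele frequency.
#' @examples
#' step_deterministic(0.5, c(1, 1, 0.8))  # 0.5/0.95
#' @export
step_deterministic <- function(p, fitness, f = 0) {
  w <- as_selection_scheme(fitness)
  pr <- post_selection_props(p, w, f)
  unname(pr["AA"] + pr["Aa"] / 2)
}

#' One stochastic generation in a finite population
#'
#' Draws the `N` offspring genotypes multinomially from the post-selection
#' expected genotype proportions, then counts alleles:
#' `p' = (2 n_AA + n_Aa) / (2N)`. This genotype-sampling scheme (rather than
#' binomial allele sampling) is the simulator's drift contract; at `F = 0`
#' both have mean `p` and variance `pq/(2N)`.
#'
#' @inheritParams step_deterministic
#' @param n Population size (finite positive integer).
#' @return List with `p` (next frequency) and `counts` (named genotype counts).
#' @examples
#' set.seed(1)
#' step_stochastic(0.5, c(1, 1, 1), n = 50)
#' @export
step_stochastic <- function(p, fitness, f = 0, n) {
  if (!is_count(n)) abort("`n` must be a finite positive integer.")
  w <- as_selection_scheme(fitness)
  pr <- post_selection_props(p, w, f)
  cnt <- as.integer(rmultinom(1, n, pr))
  names(cnt) <- names(pr)
  list(p = (2 * cnt[[1]] + cnt[[2]]) / (2 * n), counts = cnt)
}

#' Simulate allele-frequency trajectories
#'
#' Forward simulation of one biallelic locus under genotypic selection,
#' inbreeding and (for finite `n`) genetic drift. With `n = Inf` (the
#' default) evolution is purely deterministic and a single trajectory is
#' returned; with finite `n`, `replicates` independent stochastic trajectories
#' are simulated, each generation drawing `n` offspring genotypes from the
#' post-selection expected proportions. Frequencies 0 and 1 are absorbing;
#' after absorption the trajectory is held at the boundary and the absorption
#' generation recorded.
#'
#' @param p0 Initial frequency of the tracked allele.
#' @param fitness A [selection_scheme()] or numeric `(w_AA, w_Aa, w_aa)`,
#'   where `AA` is the tracked allele's homozygote.
#' @param n Population size: a positive integer, or `Inf` for the
#'   deterministic model (default).
#' @param f Inbreeding coefficient in `[0, 1]`.
#' @param generations Number of generations to simulate (default 400).
#' @param replicates Number of independent populations (finite `n` only).
#' @param seed Optional master seed; each replicate runs on an independent
#'   substream derived from it, so the full trajectory set is reproducible.
#' @param allele Label of the tracked allele (cosmetic, default `"A"`).
#' @return A tibble of class `trajectory_set` with columns `replicate`,
#'   `generation` (0..`generations`; generation 0 is exactly `p0`) and `freq`,
#'   plus attributes `config` (all parameters) and `absorption` (per-replicate
#'   tibble: `replicate`, `state` fixed/lost/segregating, `absorbed_at`).
#' @examples
#' simulate_drift(0.5, c(1, 1, 0.8), generations = 50)            # deterministic
#' simulate_drift(0.5, n = 50, replicates = 4, generations = 100, seed = 1)
#' @export
simulate_drift <- function(p0, fitness = c(1, 1, 1), n = Inf, f = 0,
                           generations = 400, replicates = 1, seed = NULL,
                           allele = "A") {
  check_prob(p0, "p0")
  check_prob(f, "f")
  w <- as_selection_scheme(fitness)
  if (!is_count(generations)) abort("`generations` must be a positive integer.")
  if (!is_count(replicates)) abort("`replicates` must be a positive integer.")
  infinite <- is.infinite(n)
  if (!infinite && !is_count(n)) abort("`n` must be a positive integer or Inf.")

  gens <- as.integer(generations)
  run_one <- function() {
    freq <- numeric(gens + 1L)
    freq[1] <- p0
    p <- p0
    absorbed <- if (p %in% c(0, 1)) 0L else NA_integer_
    for (t in seq_len(gens)) {
      if (is.na(absorbed)) {
        p <- if (infinite) step_deterministic(p, w, f) else step_stochastic(p, w, f, n)$p
        if (!infinite && p %in% c(0, 1)) absorbed <- t
      }
      freq[t + 1L] <- p
    }
    list(freq = freq, absorbed = absorbed)
  }

  if (infinite) {
    runs <- list(run_one())
    replicates <- 1L
  } else {
    seeds <- if (is.null(seed)) rep(list(NULL), replicates) else as.list(derive_seeds(seed, replicates))
    runs <- lapply(seeds, function(s) with_seed(s, run_one()))
  }

  out <- tibble(
    replicate = rep(seq_len(replicates), each = gens + 1L),
    generation = rep(0:gens, replicates),
    freq = unlist(lapply(runs, `[[`, "freq"))
  )
  final <- vapply(runs, function(r) r$freq[gens + 1L], numeric(1))
  absorption <- tibble(
    replicate = seq_len(replicates),
    state = ifelse(final == 1, "fixed", ifelse(final == 0, "lost", "segregating")),
    absorbed_at = vapply(runs, `[[`, integer(1), "absorbed")
  )
  structure(out,
            class = c("trajectory_set", class(out)),
            config = list(p0 = p0, fitness = unclass(w), n = n, f = f,
                          generations = gens, replicates = replicates,
                          seed = seed, allele = allele),
            absorption = absorption)
}

#' Fixation/loss summary of a stochastic trajectory set
#'
#' Classifies each replicate at its final generation as fixed (frequency 1),
#' lost (0) or still segregating, and averages the absorption time over
#' absorbed replicates. Under neutrality the fixation proportion estimates the
#' initial allele frequency.
#'
#' @param ts A finite-population [simulate_drift()] result.
#' @return A one-row tibble: `replicates`, `prop_fixed`, `prop_lost`,
#'   `prop_segregating`, `mean_absorption_time` (NA if nothing absorbed).
#' @examples
#' ts <- simulate_drift(0.3, n = 20, replicates = 50, generations = 200, seed = 1)
#' fixation_summary(ts)
#' @export
fixation_summary <- function(ts) {
  cfg <- attr(ts, "config")
  if (is.null(cfg)) abort("`ts` must come from simulate_drift().")
  if (is.infinite(cfg$n)) {
    abort("Fixation summaries require a finite population (drift); this trajectory set is deterministic.")
  }
  ab <- attr(ts, "absorption")
  tibble(
    replicates = nrow(ab),
    prop_fixed = mean(ab$state == "fixed"),
    prop_lost = mean(ab$state == "lost"),
    prop_segregating = mean(ab$state == "segregating"),
    mean_absorption_time = if (all(is.na(ab$absorbed_at))) NA_real_ else
      mean(ab$absorbed_at, na.rm = TRUE)
  )
}

#' @export
tidy.trajectory_set <- function(x, ...) {
  ab <- attr(x, "absorption")
  as_tibble(x) |> dplyr::left_join(ab, by = "replicate")
}

#' @export
glance.trajectory_set <- function(x, ...) {
  cfg <- attr(x, "config")
  ab <- attr(x, "absorption")
  tibble(
    p0 = cfg$p0, n = cfg$n, f = cfg$f,
    w_AA = cfg$fitness[["AA"]], w_Aa = cfg$fitness[["Aa"]], w_aa = cfg$fitness[["aa"]],
    generations = cfg$generations, replicates = cfg$replicates,
    prop_fixed = mean(ab$state == "fixed"),
    prop_lost = mean(ab$state == "lost"),
    final_mean_freq = mean(x$freq[x$generation == cfg$generations])
  )
}

#' @export
autoplot.trajectory_set <- function(object, ...) {
  cfg <- attr(object, "config")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$generation, y = .data$freq,
                                       group = .data$replicate,
                                       colour = factor(.data$replicate))) +
    ggplot2::geom_line(alpha = 0.8, show.legend = cfg$replicates <= 10) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "generation",
                  y = sprintf("frequency of allele %s", cfg$allele),
                  colour = "replicate",
                  title = sprintf("N = %s, w = (%g, %g, %g), F = %g",
                                  ifelse(is.infinite(cfg$n), "Inf", cfg$n),
                                  cfg$fitness[["AA"]], cfg$fitness[["Aa"]],
                                  cfg$fitness[["aa"]], cfg$f)) +
    ggplot2::theme_minimal()
}
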