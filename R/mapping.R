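#' Build a testcross mapping problem
#'
#' A mapping problem records the phenotype-class counts of a testcross: a
#' multiple heterozygote crossed to a fully recessive homozygote, so each
#' offspring phenotype reads out one gamete of the heterozygote directly.
#' Class labels are one character per locus in the presented locus order,
#' uppercase for the dominant form and lowercase for the recessive form
#' (e.g. `"AbC"`).
#'
#' @param counts Named numeric vector of class counts (names are class
#'   labels), or a data frame with columns `class` and `count`. All `2^k`
#'   classes must be present for `k` loci.
#' @param loci Locus names in the order the classes are written (defaults to
#'   the uppercase letters appearing in the labels, in label order).
#' @return An object of class `mapping_problem`: list with `loci` and
#'   `classes` (tibble `class`, `count`).
#' @examples
#' mapping_problem(c(AB = 450, ab = 450, Ab = 50, aB = 50))
#' @export
mapping_problem <- function(counts, loci = NULL) {
  if (is.data.frame(counts)) {
    if (!all(c("class", "count") %in% names(counts))) {
      abort("A data-frame input needs columns `class` and `count`.")
    }
    cl <- counts$class
    ct <- counts$count
  } else {
    cl <- names(counts)
    ct <- as.numeric(counts)
  }
  if (is.null(cl) || any(!nzchar(cl))) abort("Every class needs a label.")
  k <- nchar(cl[1])
  if (!k %in% c(2L, 3L)) abort("Mapping problems support 2 or 3 loci.")
  if (any(nchar(cl) != k)) abort("All class labels must name the same loci.")
  if (length(cl) != 2^k) {
    abort(sprintf("Expected %d phenotype classes for %d loci, got %d.", 2^k, k, length(cl)))
  }
  if (anyDuplicated(cl)) abort("Duplicate class labels.")
  if (any(is.na(ct)) || any(ct < 0)) abort("Counts must be non-negative.")
  if (sum(ct) <= 0) abort("Total offspring count must be positive.")
  if (is.null(loci)) loci <- toupper(strsplit(cl[1], "")[[1]])
  if (length(loci) != k || anyDuplicated(loci)) {
    abort("`loci` must give one unique name per class-label position.")
  }
  # every label must be a case pattern over the presented loci, all combos present
  expected <- apply(expand.grid(rep(list(c(TRUE, FALSE)), k)), 1, function(up) {
    paste(ifelse(up, toupper(loci), tolower(loci)), collapse = "")
  })
  if (!setequal(cl, expected)) {
    abort("Class labels must cover every dominant/recessive combination of the presented loci.")
  }
  structure(list(loci = as.character(loci),
                 classes = tibble(class = cl, count = ct)),
            class = "mapping_problem")
}

#' @export
print.mapping_problem <- function(x, ...) {
  cat(sprintf("<mapping_problem> %d loci (%s), n = %g\n",
              length(x$loci), paste(x$loci, collapse = ", "), sum(x$classes$count)))
  print(x$classes, n = nrow(x$classes))
  invisible(x)
}

# group the classes of a problem into complementary pairs with summed counts
complementary_pairs <- function(classes) {
  pair_id <- vapply(classes$class, function(cl) {
    sort_c(c(cl, swap_case(cl)))[1]
  }, character(1))
  classes |>
    dplyr::mutate(pair = pair_id) |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(total = sum(.data$count),
                     members = list(sort_c(.data$class)), .groups = "drop")
}

# positions at which two class labels disagree
mismatch_positions <- function(a, b) {
  which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# 2x2 chi-square test of independence between two loci of a problem
interval_independence <- function(problem, locus_a, locus_b) {
  ia <- match(locus_a, problem$loci)
  ib <- match(locus_b, problem$loci)
  lab <- strsplit(problem$classes$class, "")
  up_a <- vapply(lab, function(ch) ch[ia] == toupper(ch[ia]), logical(1))
  up_b <- vapply(lab, function(ch) ch[ib] == toupper(ch[ib]), logical(1))
  tab <- matrix(0, 2, 2)
  for (i in seq_along(lab)) {
    tab[2 - up_a[i], 2 - up_b[i]] <- tab[2 - up_a[i], 2 - up_b[i]] + problem$classes$count[i]
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(chi2 = NA_real_, p_value = NA_real_))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), p_value = ht$p.value)
}

new_mapping_solution <- function(k, order, phase, r, coincidence = NA_real_,
                                 unlinked, ambiguous = FALSE, independence = NULL,
                                 n) {
  structure(list(
    k = k, order = order, phase = phase,
    r = r, cM = 100 * r,
    coincidence = coincidence,
    interference = if (is.na(coincidence)) NA_real_ else 1 - coincidence,
    unlinked = unlinked, ambiguous = ambiguous,
    independence = independence, n = n
  ), class = "mapping_solution")
}

#' Solve a three-point testcross problem
#'
#' Classic three-point analysis from the eight phenotype-class counts of a
#' testcross: the two most frequent complementary classes are the parental
#' (non-recombinant) gametes and define the phase; the two rarest are the
#' double crossovers; the locus whose allele flips between the parental and
#' double-crossover classes is the middle gene. Each interval's recombination
#' fraction counts its single crossovers plus all double crossovers:
#' `r = (SCO + DCO) / n`. The coefficient of coincidence is
#' `(DCO/n) / (r1 r2)` and interference is its complement.
#'
#' An interval with `r` at or above `unlinked_threshold` is flagged as likely
#' unlinked, and a 2x2 chi-square test of independence between its two loci
#' is reported alongside, since the point estimate alone is noisy. When
#' count ties make the parental or double-crossover pair non-unique the
#' ambiguity flag is set and ties are broken lexicographically — never
#' silently guessed.
#'
#' @param problem A [mapping_problem()] with 3 loci (8 classes).
#' @param unlinked_threshold Estimated `r` at or above which an interval is
#'   flagged as likely unlinked (default 0.45).
#' @return An object of class `mapping_solution`: inferred `order` (ends in
#'   alphabetical order; an order and its reverse are equivalent), `phase`
#'   (the two parental class labels, `"ABC/abc"` style), `r`, `cM`
#'   (`= 100 r`), `coincidence`, `interference`, `unlinked` flags,
#'   `ambiguous`, `independence` (per-interval chi-square) and `n`.
#' @examples
#' p <- mapping_problem(c(ABC = 360, abc = 360, aBC = 40, Abc = 40,
#'                        ABc = 90, abC = 90, AbC = 10, aBc = 10))
#' solve_threepoint(p)   # order A-B-C, r = 0.10 and 0.20, c = 1
#' @export
solve_threepoint <- function(problem, unlinked_threshold = 0.45) {
  if (!inherits(problem, "mapping_problem")) abort("`problem` must be a mapping_problem.")
  if (length(problem$loci) != 3L) abort("solve_threepoint() needs a 3-locus problem (8 classes).")
  cls <- problem$classes
  n <- sum(cls$count)
  pairs <- complementary_pairs(cls)
  ambiguous <- FALSE

  pick <- function(pairs, which_max = TRUE) {
    tot <- if (which_max) max(pairs$total) else min(pairs$total)
    hit <- pairs[pairs$total == tot, ]
    if (nrow(hit) > 1L) {
      hit <- hit[order(hit$pair, method = "radix"), ]
      list(row = hit[1, ], tie = TRUE)
    } else list(row = hit, tie = FALSE)
  }

  par_pick <- pick(pairs, TRUE)
  parental <- par_pick$row
  ambiguous <- ambiguous || par_pick$tie
  rest <- pairs[pairs$pair != parental$pair, ]
  dco_pick <- pick(rest, FALSE)
  dco <- dco_pick$row
  ambiguous <- ambiguous || dco_pick$tie
  sco_pairs <- rest[rest$pair != dco$pair, ]

  P <- parental$members[[1]][1]
  # middle locus: the single position flipped between a parental class and the
  # matching DCO class (complementary classes flip complementary position sets)
  mm <- lapply(dco$members[[1]], mismatch_positions, a = P)
  mid_pos <- mm[[which.min(lengths(mm))]]
  if (length(mid_pos) != 1L) abort("Could not identify a unique middle locus.")
  middle <- problem$loci[mid_pos]

  # each single-crossover pair flips exactly one end locus relative to parental
  sco_end <- character(2)
  sco_total <- numeric(2)
  for (i in 1:2) {
    mmi <- lapply(sco_pairs$members[[i]], mismatch_positions, a = P)
    pos <- mmi[[which.min(lengths(mmi))]]
    if (length(pos) != 1L || pos == mid_pos) {
      abort("Counts are inconsistent with a three-point testcross structure.")
    }
    sco_end[i] <- problem$loci[pos]
    sco_total[i] <- sco_pairs$total[i]
  }

  ends <- sort_c(sco_end)
  ord <- c(ends[1], middle, ends[2])
  r <- vapply(ends, function(e) {
    min((sco_total[sco_end == e] + dco$total) / n, 0.5)
  }, numeric(1))
  names(r) <- c(paste(ord[1], ord[2], sep = "-"), paste(ord[2], ord[3], sep = "-"))
  coincidence <- if (prod(r) > 0) (dco$total / n) / prod(r) else NA_real_
  unlinked <- setNames(r >= unlinked_threshold, names(r))
  independence <- dplyr::bind_rows(lapply(1:2, function(i) {
    locus_pair <- strsplit(names(r)[i], "-", fixed = TRUE)[[1]]
    ind <- interval_independence(problem, locus_pair[1], locus_pair[2])
    tibble(interval = names(r)[i], chi2 = ind$chi2, p_value = ind$p_value)
  }))

  new_mapping_solution(
    k = 3L, order = ord,
    phase = paste(parental$members[[1]], collapse = "/"),
    r = r, coincidence = coincidence, unlinked = unlinked,
    ambiguous = ambiguous, independence = independence, n = n
  )
}

#' Solve a two-point testcross problem
#'
#' The recombination fraction is the summed frequency of the two minority
#' (recombinant) complementary classes; the majority pair defines the phase.
#' Equal pair totals (the 1:1:1:1 pattern of independent assortment) give
#' `r = 0.5` with the ambiguity and unlinked flags set.
#'
#' @inheritParams solve_threepoint
#' @param problem A [mapping_problem()] with 2 loci (4 classes).
#' @return A `mapping_solution`; see [solve_threepoint()].
#' @examples
#' solve_twopoint(mapping_problem(c(AB = 450, ab = 450, Ab = 50, aB = 50)))
#' @export
solve_twopoint <- function(problem, unlinked_threshold = 0.45) {
  if (!inherits(problem, "mapping_problem")) abort("`problem` must be a mapping_problem.")
  if (length(problem$loci) != 2L) abort("solve_twopoint() needs a 2-locus problem (4 classes).")
  cls <- problem$classes
  n <- sum(cls$count)
  pairs <- complementary_pairs(cls)
  tie <- pairs$total[1] == pairs$total[2]
  rec <- which.min(pairs$total)
  parental <- pairs[-rec, ]
  if (tie) parental <- pairs[order(pairs$pair, method = "radix"), ][1, ]
  r <- min(pairs$total[rec] / n, 0.5)
  ord <- sort_c(problem$loci)
  names(r) <- paste(ord[1], ord[2], sep = "-")
  ind <- interval_independence(problem, ord[1], ord[2])
  new_mapping_solution(
    k = 2L, order = ord,
    phase = paste(parental$members[[1]], collapse = "/"),
    r = r, coincidence = NA_real_,
    unlinked = setNames(r >= unlinked_threshold, names(r)),
    ambiguous = tie,
    independence = tibble(interval = names(r), chi2 = ind$chi2, p_value = ind$p_value),
    n = n
  )
}

#' Solve a testcross mapping problem of either size
#'
#' Dispatches to [solve_twopoint()] or [solve_threepoint()] by locus count.
#'
#' @inheritParams solve_threepoint
#' @return A `mapping_solution`.
#' @export
solve_mapping <- function(problem, unlinked_threshold = 0.45) {
  if (!inherits(problem, "mapping_problem")) abort("`problem` must be a mapping_problem.")
  if (length(problem$loci) == 2L) solve_twopoint(problem, unlinked_threshold)
  else solve_threepoint(problem, unlinked_threshold)
}

#' @export
print.mapping_solution <- function(x, ...) {
  cat(sprintf("<mapping_solution> order: %s%s\n", paste(x$order, collapse = " - "),
              if (x$ambiguous) "  [ambiguous: count ties]" else ""))
  cat(sprintf("  phase: %s\n", x$phase))
  for (i in seq_along(x$r)) {
    cat(sprintf("  %s: r = %.4f (%.2f cM)%s\n", names(x$r)[i], x$r[i], x$cM[i],
                if (x$unlinked[i]) "  [likely unlinked]" else ""))
  }
  if (!is.na(x$coincidence)) {
    cat(sprintf("  coincidence = %.4f, interference = %.4f\n",
                x$coincidence, x$interference))
  }
  invisible(x)
}

#' @export
tidy.mapping_solution <- function(x, ...) {
  out <- tibble(interval = names(x$r), r = unname(x$r), cM = unname(x$cM),
                unlinked = unname(x$unlinked))
  if (!is.null(x$independence)) {
    out <- dplyr::left_join(out, x$independence, by = "interval")
  }
  out
}

#' @export
glance.mapping_solution <- function(x, ...) {
  tibble(k = x$k, order = paste(x$order, collapse = "-"), phase = x$phase,
         coincidence = x$coincidence, interference = x$interference,
         ambiguous = x$ambiguous, n = x$n)
}

# Exact gamete-class probabilities of the multiple heterozygote.
# h1_dom: logical per locus (true order) — is the dominant allele on homolog 1?
# Returns named probabilities over phenotype-class labels in true locus order.
gamete_class_probs <- function(loci, r, coincidence = 1, h1_dom = rep(TRUE, length(loci))) {
  k <- length(loci)
  sym <- function(dom) ifelse(dom, toupper(loci), tolower(loci))
  h1 <- h1_dom
  probs <- c()
  if (k == 2L) {
    pat <- list(c(0L), c(1L))
    pp <- c(1 - r[1], r[1])
  } else {
    dd <- coincidence * r[1] * r[2]
    pat <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
    pp <- c(1 - r[1] - r[2] + dd, r[1] - dd, r[2] - dd, dd)
  }
  if (any(pp < -1e-12)) abort("Coincidence too large for these recombination fractions (negative class probability).")
  pp <- pmax(pp, 0)
  all_lab <- apply(expand.grid(rep(list(c(TRUE, FALSE)), k)), 1, function(up) {
    paste(ifelse(up, toupper(loci), tolower(loci)), collapse = "")
  })
  out <- setNames(numeric(length(all_lab)), all_lab)
  for (start1 in c(TRUE, FALSE)) {
    for (j in seq_along(pat)) {
      on_h1 <- start1
      dom <- logical(k)
      dom[1] <- if (on_h1) h1[1] else !h1[1]
      for (i in seq_len(k - 1L)) {
        if (pat[[j]][i] == 1L) on_h1 <- !on_h1
        dom[i + 1L] <- if (on_h1) h1[i + 1L] else !h1[i + 1L]
      }
      lab <- paste(sym(dom), collapse = "")
      out[lab] <- out[lab] + pp[j] / 2
    }
  }
  out
}

#' Generate a random testcross mapping problem with its answer key
#'
#' Draws a map scenario — shuffled true gene order, per-interval recombination
#' fractions (each interval set to 0.5, i.e. unlinked, with probability
#' `p_unlinked`, otherwise uniform over `r_range`), a random phase of the
#' heterozygous parent — computes the exact gamete-class probabilities
#' (parental `(1 - r1)(1 - r2) + c r1 r2` bookkeeping, double crossovers with
#' probability `c r1 r2`, complementary classes split equally), then samples
#' `n` offspring multinomially (or takes exact expected counts with
#' `exact = TRUE`). Locus presentation order is shuffled so the solver cannot
#' read the order off the column order.
#'
#' @param k Number of loci, 2 or 3.
#' @param n Number of offspring.
#' @param r_range Range recombination fractions are drawn from (subset of
#'   (0, 0.5)).
#' @param p_unlinked Probability each interval is made unlinked (r = 0.5).
#' @param coincidence Coefficient of coincidence for double crossovers
#'   (default 1: no interference).
#' @param exact If `TRUE`, class counts are the exact expectations `n p`
#'   rather than a multinomial sample.
#' @param seed Optional seed; the same seed reproduces the identical problem.
#' @param loci Locus names (default first `k` letters).
#' @return A list of class `mapping_exercise`: `problem` (a
#'   [mapping_problem()]) and `key` (the true `mapping_solution`).
#' @examples
#' ex <- generate_mapping_problem(k = 3, n = 1000, seed = 42)
#' solve_threepoint(ex$problem)
#' ex$key
#' @export
generate_mapping_problem <- function(k = 3, n = 1000, r_range = c(0.05, 0.35),
                                     p_unlinked = 0, coincidence = 1,
                                     exact = FALSE, seed = NULL,
                                     loci = LETTERS[seq_len(k)]) {
  if (!k %in% c(2, 3)) abort("`k` must be 2 or 3.")
  if (!is_count(n)) abort("`n` must be a positive integer.")
  if (length(r_range) != 2L || r_range[1] <= 0 || r_range[2] >= 0.5 ||
      r_range[1] > r_range[2]) {
    abort("`r_range` must lie strictly inside (0, 0.5).")
  }
  check_prob(p_unlinked, "p_unlinked")
  if (coincidence < 0) abort("`coincidence` must be >= 0.")

  with_seed(seed, {
    true_order <- sample(loci)
    n_int <- k - 1L
    r <- vapply(seq_len(n_int), function(i) {
      if (runif(1) < p_unlinked) 0.5 else runif(1, r_range[1], r_range[2])
    }, numeric(1))
    c_use <- if (any(r == 0.5)) 1 else coincidence
    h1_dom <- sample(c(TRUE, FALSE), k, replace = TRUE)
    probs <- gamete_class_probs(true_order, r, c_use, h1_dom)
    counts <- if (exact) probs * n else as.numeric(rmultinom(1, n, probs))
    names(counts) <- names(probs)

    presented <- sample(loci)
    perm <- match(presented, true_order)
    relabel <- function(lab) {
      paste(strsplit(lab, "")[[1]][perm], collapse = "")
    }
    names(counts) <- vapply(names(counts), relabel, character(1))
    problem <- mapping_problem(counts, loci = presented)

    # canonical key: ends alphabetical; reversing the order reverses r
    ord <- true_order
    if (ord[1] > ord[k]) {
      ord <- rev(ord)
      r <- rev(r)
    }
    names(r) <- paste(ord[-k], ord[-1], sep = "-")
    sym <- ifelse(h1_dom, toupper(true_order), tolower(true_order))
    h1_lab <- relabel(paste(sym, collapse = ""))
    phase_pair <- sort_c(c(h1_lab, swap_case(h1_lab)))
    key <- new_mapping_solution(
      k = as.integer(k), order = ord,
      phase = paste(phase_pair, collapse = "/"),
      r = r, coincidence = if (k == 3L) c_use else NA_real_,
      unlinked = setNames(r >= 0.5, names(r)),
      ambiguous = FALSE, independence = NULL, n = n
    )
    structure(list(problem = problem, key = key), class = "mapping_exercise")
  })
}
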