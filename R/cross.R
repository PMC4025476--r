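#' Simulate a genetic cross exactly
#'
#' Crosses a female and a male genotype and returns the exact offspring
#' genotype and phenotype distributions together with their reduced integer
#' ratios (e.g. `3:1`, `9:3:3:1`). All probabilities are exact rationals
#' (integer numerator over a power-of-two denominator), so ratio reduction is
#' bit-exact. Offspring sex follows the father's X- or Y-bearing gamete;
#' X-linked loci are transmitted accordingly (sons are hemizygous for the
#' maternal allele).
#'
#' Phenotype classes (and both ratio tables) are pooled across sexes when no
#' locus is X-linked, and reported per sex otherwise — the standard classroom
#' presentation, where sons and daughters of an X-linked cross are listed
#' separately.
#'
#' @param mother,father A [multi_genotype()] or a genotype string (parsed
#'   against `loci`; mother female, father male).
#' @param loci A [locus_set()].
#' @return An object of class `cross_result`: a list with `parents`, `loci`,
#'   `genotype_dist` and `phenotype_dist` (tibbles with exact `num`/`den`
#'   probabilities) and `genotype_ratio` / `phenotype_ratio` (tibbles of
#'   coprime integer ratio terms, sorted by descending probability, ties
#'   broken lexicographically).
#' @examples
#' loci <- locus_set(1)
#' cross("Aa", "Aa", loci)          # 1:2:1 genotypes, 3:1 phenotypes
#' cross("AaBb", "AaBb", locus_set(2))  # 9:3:3:1
#' @export
cross <- function(mother, father, loci) {
  check_locus_set(loci)
  if (is.character(mother)) mother <- multi_genotype(mother, "female", loci)
  if (is.character(father)) father <- multi_genotype(father, "male", loci)
  if (mother$sex != "female" || father$sex != "male") {
    abort("`mother` must be female and `father` male (same-sex crosses are invalid).")
  }
  check_conforms(mother, loci)
  check_conforms(father, loci)

  em <- enumerate_gametes(mother, loci)
  ef <- enumerate_gametes(father, loci)
  n_loci <- nrow(loci)
  any_x <- any(loci$x_linked)

  rows <- vector("list", length(em$weight) * length(ef$weight))
  k <- 0L
  for (i in seq_along(em$weight)) {
    ma <- em$alleles[[i]]
    for (j in seq_along(ef$weight)) {
      fa <- ef$alleles[[j]]
      female_off <- ef$carries_x[j]
      alleles <- vector("list", n_loci)
      for (l in seq_len(n_loci)) {
        if (loci$x_linked[l]) {
          alleles[[l]] <- if (female_off) {
            pair <- c(ma[l], fa[l])
            pair[order(match(pair, c(loci$dominant[l], loci$recessive[l])))]
          } else {
            ma[l]  # hemizygous son: maternal X allele only
          }
        } else {
          pair <- c(ma[l], fa[l])
          alleles[[l]] <- pair[order(match(pair, c(loci$dominant[l], loci$recessive[l])))]
        }
      }
      k <- k + 1L
      rows[[k]] <- list(
        sex = if (female_off) "female" else "male",
        genotype = genotype_label(alleles, loci),
        phenotype = phenotype_label_of(alleles, loci),
        w = em$weight[i] * ef$weight[j]
      )
    }
  }
  den <- as.integer(em$den) * as.integer(ef$den)
  df <- tibble(
    sex = vapply(rows, `[[`, character(1), "sex"),
    genotype = vapply(rows, `[[`, character(1), "genotype"),
    phenotype = vapply(rows, `[[`, character(1), "phenotype"),
    num = vapply(rows, `[[`, integer(1), "w")
  )

  genotype_dist <- df |>
    dplyr::count(.data$sex, .data$genotype, wt = .data$num, name = "num") |>
    dplyr::mutate(den = den, prob = .data$num / den) |>
    dplyr::arrange(dplyr::desc(.data$num), .data$sex, .data$genotype)

  phen <- df |> dplyr::count(.data$sex, .data$phenotype, wt = .data$num, name = "num")
  if (!any_x) {
    phen <- phen |>
      dplyr::count(.data$phenotype, wt = .data$num, name = "num") |>
      dplyr::mutate(sex = NA_character_, .before = 1)
  }
  phenotype_dist <- phen |>
    dplyr::mutate(den = den, prob = .data$num / den) |>
    dplyr::arrange(dplyr::desc(.data$num), .data$sex, .data$phenotype)

  geno_for_ratio <- if (any_x) genotype_dist else {
    genotype_dist |>
      dplyr::count(.data$genotype, wt = .data$num, name = "num") |>
      dplyr::mutate(sex = NA_character_, .before = 1) |>
      dplyr::arrange(dplyr::desc(.data$num), .data$genotype)
  }

  structure(list(
    parents = list(mother = mother, father = father),
    loci = loci,
    genotype_dist = genotype_dist,
    phenotype_dist = phenotype_dist,
    genotype_ratio = make_ratio(geno_for_ratio, "genotype"),
    phenotype_ratio = make_ratio(phenotype_dist, "phenotype")
  ), class = "cross_result")
}

make_ratio <- function(dist, class_col) {
  out <- dist
  out$ratio <- reduce_ratio(out$num)
  # descending probability, ties broken lexicographically by class label
  out <- out[order(-out$num, out[[class_col]], method = "radix"), ]
  dplyr::select(out, dplyr::any_of(c("sex", class_col, "ratio")))
}

#' @export
print.cross_result <- function(x, ...) {
  cat(sprintf("<cross_result> %s (female) x %s (male), %d locus/loci\n",
              x$parents$mother$label, x$parents$father$label, nrow(x$loci)))
  fmt_ratio <- function(r, col) {
    by_sex <- split(r, if (all(is.na(r$sex))) rep("pooled", nrow(r)) else r$sex)
    for (nm in names(by_sex)) {
      part <- by_sex[[nm]]
      cat(sprintf("  %s: %s  (%s)\n", nm,
                  paste(part$ratio, collapse = ":"),
                  paste(part[[col]], collapse = " : ")))
    }
  }
  cat("Phenotype ratio:\n"); fmt_ratio(x$phenotype_ratio, "phenotype")
  cat("Genotype ratio:\n"); fmt_ratio(x$genotype_ratio, "genotype")
  invisible(x)
}

#' Default single-gene cross
#'
#' The cross shown on start-up: heterozygotes at every locus (one autosomal
#' locus by default), e.g. `Aa x Aa` with the familiar 3:1 phenotype ratio.
#'
#' @param n_loci Number of autosomal loci (default 1).
#' @return A [cross()] result.
#' @examples
#' default_cross()
#' @export
default_cross <- function(n_loci = 1) {
  loci <- locus_set(n_loci)
  het <- paste(paste0(loci$dominant, loci$recessive), collapse = "")
  cross(het, het, loci)
}

#' Sample a finite brood from a cross
#'
#' Draws `n` offspring multinomially from the exact offspring genotype
#' distribution.
#'
#' @param result A [cross()] result.
#' @param n Brood size (positive integer).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `sex`, `genotype`, `phenotype`-free counts:
#'   `count` per genotype class (zero-count classes retained).
#' @examples
#' sample_brood(default_cross(), 10, seed = 1)
#' @export
sample_brood <- function(result, n, seed = NULL) {
  if (!inherits(result, "cross_result")) abort("`result` must be a cross_result.")
  if (!is_count(n)) abort("`n` must be a positive integer.")
  gd <- result$genotype_dist
  counts <- with_seed(seed, as.integer(rmultinom(1, n, gd$prob)))
  tibble(sex = gd$sex, genotype = gd$genotype, count = counts)
}

#' Cross a selected pair of offspring
#'
#' Continues a multi-generation crossing experiment: pick one female and one
#' male (e.g. from a previous cross's offspring classes) and cross them.
#'
#' @param selected A data frame with columns `sex` and `genotype` (genotype
#'   strings) containing exactly one female and one male, or a list of two
#'   [multi_genotype()] objects.
#' @param loci A [locus_set()].
#' @return A [cross()] result for the selected pair.
#' @examples
#' loci <- locus_set(1)
#' f1 <- data.frame(sex = c("female", "male"), genotype = c("AA", "aa"))
#' next_generation(f1, loci)   # all offspring Aa
#' @export
next_generation <- function(selected, loci) {
  check_locus_set(loci)
  if (is.list(selected) && !is.data.frame(selected) &&
      all(vapply(selected, inherits, logical(1), "multi_genotype"))) {
    selected <- data.frame(
      sex = vapply(selected, `[[`, character(1), "sex"),
      genotype = vapply(selected, `[[`, character(1), "label")
    )
  }
  if (!is.data.frame(selected) || !all(c("sex", "genotype") %in% names(selected))) {
    abort("`selected` must be a data frame with columns `sex` and `genotype`.")
  }
  females <- selected$genotype[selected$sex == "female"]
  males <- selected$genotype[selected$sex == "male"]
  if (length(females) != 1L || length(males) != 1L) {
    abort("Select exactly one female and one male to found the next generation.")
  }
  cross(females, males, loci)
}

#' @export
tidy.cross_result <- function(x, type = c("phenotype", "genotype"), ...) {
  type <- match.arg(type)
  if (type == "phenotype") {
    dist <- x$phenotype_dist
    ratio <- x$phenotype_ratio
    by <- c("sex", "phenotype")
  } else {
    dist <- x$genotype_dist
    ratio <- x$genotype_ratio
    by <- c("sex", "genotype")
  }
  if (all(is.na(ratio$sex)) && !all(is.na(dist$sex))) {
    dist <- dist |>
      dplyr::count(dplyr::across(dplyr::all_of(by[2])), wt = .data$num, name = "num") |>
      dplyr::mutate(sex = NA_character_, .before = 1, den = dist$den[1],
                    prob = .data$num / .data$den)
  }
  dplyr::left_join(dist, ratio, by = by) |>
    dplyr::arrange(dplyr::desc(.data$num), .data[[by[2]]])
}

#' @export
glance.cross_result <- function(x, ...) {
  tibble(
    n_loci = nrow(x$loci),
    any_x_linked = any(x$loci$x_linked),
    n_genotype_classes = nrow(x$genotype_dist),
    n_phenotype_classes = nrow(x$phenotype_dist),
    mother = x$parents$mother$label,
    father = x$parents$father$label
  )
}

#' @export
autoplot.cross_result <- function(object, type = c("phenotype", "genotype"), ...) {
  type <- match.arg(type)
  d <- tidy(object, type = type)
  d$class <- d[[type]]
  d$sex <- ifelse(is.na(d$sex), "pooled", d$sex)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$class, -.data$prob),
                                  y = .data$prob, fill = .data$sex)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = paste(type, "class"), y = "probability",
                  title = sprintf("%s × %s", object$parents$mother$label,
                                  object$parents$father$label)) +
    ggplot2::theme_minimal()
}
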