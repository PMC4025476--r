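#' Define a set of independently assorting biallelic loci
#'
#' Builds the locus table used by every cross-simulation function. Each locus
#' is biallelic with complete dominance; loci may be autosomal or X-linked and
#' always assort independently. By convention the dominant allele symbol is the
#' uppercase locus name and the recessive allele the lowercase name; both can
#' be overridden per locus. Sex determination is XY and the Y chromosome
#' carries no alleles of modeled loci.
#'
#' @param n Number of loci (default 1). Ignored when `names` is given.
#' @param names Locus names (single letters by default: `"A"`, `"B"`, ...).
#' @param x_linked Logical, recycled across loci: is each locus X-linked?
#' @param dominant,recessive Optional allele symbols (single characters),
#'   recycled across loci. Defaults: uppercase / lowercase of the locus name.
#' @param max_loci Cap on the number of loci (default 4, settable via
#'   `options(genevolve.max_loci = )`). Exhaustive genotype enumeration grows
#'   as `4^n`, so the cap keeps enumeration instant.
#' @return A tibble of class `locus_set` with columns `name`, `dominant`,
#'   `recessive`, `x_linked`.
#' @examples
#' locus_set(2)
#' locus_set(names = "W", x_linked = TRUE)
#' @export
locus_set <- function(n = 1, names = NULL, x_linked = FALSE,
                      dominant = NULL, recessive = NULL,
                      max_loci = getOption("genevolve.max_loci", 4L)) {
  if (is.null(names)) {
    if (!is_count(n)) abort("`n` must be a positive integer.")
    names <- LETTERS[seq_len(n)]
  }
  n <- length(names)
  if (n < 1 || n > max_loci) {
    abort(sprintf("Number of loci must be between 1 and %d (see `max_loci`).", max_loci))
  }
  if (anyDuplicated(names)) abort("Locus names must be unique.")
  dominant <- rep_len(dominant %||% toupper(names), n)
  recessive <- rep_len(recessive %||% tolower(names), n)
  x_linked <- rep_len(x_linked, n)
  if (any(nchar(dominant) != 1L) || any(nchar(recessive) != 1L)) {
    abort("Allele symbols must be single characters (required by the genotype string syntax).")
  }
  if (any(dominant == recessive)) {
    abort("Dominant and recessive allele symbols must differ at every locus.")
  }
  out <- tibble(name = names, dominant = dominant,
                recessive = recessive, x_linked = x_linked)
  class(out) <- c("locus_set", class(out))
  out
}

#' Construct a multilocus genotype
#'
#' Parses the compact genotype string syntax: one allele pair per locus,
#' concatenated in locus order, e.g. `"AaBb"`. A male's X-linked locus is
#' hemizygous and written as the allele followed by a dash (`"A-"`).
#'
#' @param genotype Genotype string, e.g. `"AaBb"` or `"a-Bb"` for a male with
#'   an X-linked first locus.
#' @param sex `"female"` or `"male"`.
#' @param loci A [locus_set()].
#' @return An object of class `multi_genotype`: a list with elements `sex`,
#'   `alleles` (one character vector per locus; length 1 for a hemizygous
#'   male X-linked locus) and `label`.
#' @examples
#' loci <- locus_set(2)
#' multi_genotype("AaBb", "female", loci)
#' @export
multi_genotype <- function(genotype, sex = c("female", "male"), loci) {
  sex <- match.arg(sex)
  check_locus_set(loci)
  chars <- strsplit(genotype, "", fixed = TRUE)[[1]]
  alleles <- vector("list", nrow(loci))
  pos <- 1L
  for (i in seq_len(nrow(loci))) {
    hemi <- loci$x_linked[i] && sex == "male"
    take <- 2L
    if (pos + take - 1L > length(chars)) {
      abort(sprintf("Genotype string '%s' is too short for %d loci.", genotype, nrow(loci)))
    }
    pair <- chars[pos:(pos + take - 1L)]
    pos <- pos + take
    valid <- c(loci$dominant[i], loci$recessive[i])
    if (hemi) {
      if (pair[2] != "-") {
        abort(sprintf("Locus %s is X-linked: a male genotype must be written as allele plus '-' (e.g. '%s-').",
                      loci$name[i], loci$dominant[i]))
      }
      pair <- pair[1]
    }
    if (!all(pair %in% valid)) {
      abort(sprintf("Allele(s) '%s' are not valid for locus %s (expected '%s' or '%s').",
                    paste(setdiff(pair, valid), collapse = "', '"),
                    loci$name[i], loci$dominant[i], loci$recessive[i]))
    }
    # normalize pair order: dominant allele first
    if (length(pair) == 2L) pair <- pair[order(match(pair, valid))]
    alleles[[i]] <- pair
  }
  if (pos != length(chars) + 1L) {
    abort(sprintf("Genotype string '%s' has trailing characters for this locus set.", genotype))
  }
  new_multi_genotype(sex, alleles, loci)
}

new_multi_genotype <- function(sex, alleles, loci) {
  structure(
    list(sex = sex, alleles = alleles, label = genotype_label(alleles, loci)),
    class = "multi_genotype"
  )
}

genotype_label <- function(alleles, loci) {
  paste(vapply(seq_along(alleles), function(i) {
    a <- alleles[[i]]
    if (length(a) == 1L) paste0(a, "-") else paste0(a, collapse = "")
  }, character(1)), collapse = "")
}

check_locus_set <- function(loci) {
  if (!inherits(loci, "locus_set")) abort("`loci` must be created with `locus_set()`.")
  invisible(loci)
}

check_conforms <- function(g, loci) {
  if (!inherits(g, "multi_genotype")) abort("Genotypes must be created with `multi_genotype()`.")
  if (length(g$alleles) != nrow(loci)) {
    abort("Genotype does not conform to the locus set (wrong number of loci).")
  }
  for (i in seq_len(nrow(loci))) {
    valid <- c(loci$dominant[i], loci$recessive[i])
    hemi <- loci$x_linked[i] && g$sex == "male"
    if (length(g$alleles[[i]]) != (if (hemi) 1L else 2L) ||
        !all(g$alleles[[i]] %in% valid)) {
      abort(sprintf("Genotype does not conform to locus %s.", loci$name[i]))
    }
  }
  invisible(g)
}

#' @export
print.multi_genotype <- function(x, ...) {
  cat(sprintf("<multi_genotype> %s %s\n", x$label, x$sex))
  invisible(x)
}

#' Phenotype of a multilocus genotype under complete dominance
#'
#' Each locus shows the dominant form iff at least one dominant allele is
#' present; a hemizygous male's single X-linked allele decides on its own.
#'
#' @inheritParams multi_genotype
#' @param g A [multi_genotype()].
#' @return A tibble with one row per locus: `locus`, `form`
#'   (`"dominant"`/`"recessive"`), `symbol` (the allele symbol conventionally
#'   used to write that form). The compact phenotype label (symbols pasted in
#'   locus order) is attached as attribute `"label"`.
#' @examples
#' loci <- locus_set(1)
#' phenotype_of(multi_genotype("Aa", "female", loci), loci)
#' @export
phenotype_of <- function(g, loci) {
  check_locus_set(loci)
  check_conforms(g, loci)
  dom <- vapply(seq_len(nrow(loci)), function(i) {
    loci$dominant[i] %in% g$alleles[[i]]
  }, logical(1))
  out <- tibble(
    locus = loci$name,
    form = ifelse(dom, "dominant", "recessive"),
    symbol = ifelse(dom, loci$dominant, loci$recessive)
  )
  attr(out, "label") <- paste(out$symbol, collapse = "")
  out
}

# fast internal variant: phenotype label straight from an allele list
phenotype_label_of <- function(alleles, loci) {
  paste(vapply(seq_len(nrow(loci)), function(i) {
    if (loci$dominant[i] %in% alleles[[i]]) loci$dominant[i] else loci$recessive[i]
  }, character(1)), collapse = "")
}

# Internal gamete enumeration with exact integer weights.
#
# Returns list(alleles = list of per-locus allele characters (NA marks the
# Y-bearing gamete at X-linked loci), weight = integer, den = common
# denominator, carries_x = logical). All X-linked loci of a male ride on the
# same X chromosome, so a male gamete carries either every X-linked allele or
# none (a single X-vs-Y draw); autosomal loci assort independently of it.
enumerate_gametes <- function(g, loci) {
  n <- nrow(loci)
  male <- g$sex == "male"
  per_locus <- vector("list", n)
  for (i in seq_len(n)) {
    a <- g$alleles[[i]]
    if (male && loci$x_linked[i]) {
      per_locus[[i]] <- list(x = a, weights = 1L)  # resolved by the X/Y branch
    } else if (a[1] == a[2]) {
      per_locus[[i]] <- list(opts = a[1], weights = 2L)
    } else {
      per_locus[[i]] <- list(opts = a, weights = c(1L, 1L))
    }
  }
  xl <- which(loci$x_linked)
  auto <- which(!loci$x_linked | !male)
  if (male) auto <- which(!loci$x_linked)

  expand_auto <- function(fixed) {
    # fixed: named list locus index -> allele (for male X branch) or NA (Y branch)
    idx <- if (male) auto else seq_len(n)
    combos <- list(list(alleles = rep(NA_character_, n), weight = 1L))
    for (i in idx) {
      opts <- per_locus[[i]]$opts
      w <- per_locus[[i]]$weights
      combos <- unlist(lapply(combos, function(cmb) {
        lapply(seq_along(opts), function(j) {
          al <- cmb$alleles
          al[i] <- opts[j]
          list(alleles = al, weight = cmb$weight * w[j])
        })
      }), recursive = FALSE)
    }
    lapply(combos, function(cmb) {
      for (i in seq_along(fixed)) {
        cmb$alleles[as.integer(names(fixed)[i])] <- fixed[[i]]
      }
      cmb
    })
  }

  if (!male) {
    combos <- expand_auto(list())
    den <- prod(rep(2L, n))
    return(list(
      alleles = lapply(combos, `[[`, "alleles"),
      weight = vapply(combos, `[[`, integer(1), "weight"),
      den = as.integer(den),
      carries_x = rep(TRUE, length(combos))
    ))
  }
  # male: X branch and Y branch, each with probability 1/2
  xfix <- setNames(lapply(xl, function(i) per_locus[[i]]$x), as.character(xl))
  yfix <- setNames(lapply(xl, function(i) NA_character_), as.character(xl))
  xcombos <- expand_auto(xfix)
  ycombos <- expand_auto(yfix)
  den <- as.integer(2L^(length(auto) + 1L))
  list(
    alleles = c(lapply(xcombos, `[[`, "alleles"), lapply(ycombos, `[[`, "alleles")),
    weight = c(vapply(xcombos, `[[`, integer(1), "weight"),
               vapply(ycombos, `[[`, integer(1), "weight")),
    den = den,
    carries_x = rep(c(TRUE, FALSE), c(length(xcombos), length(ycombos)))
  )
}

#' Exact gamete distribution of a genotype
#'
#' Enumerates all gametes a genotype can produce with their exact
#' probabilities (integer numerator over a power-of-two denominator). Each
#' allele of a heterozygous pair is drawn with probability 1/2 and loci assort
#' independently. A male's X-linked loci segregate together with the X: his
#' gametes carry either all X-linked alleles or a Y (each with probability
#' 1/2), shown as `-` at the X-linked positions of the gamete label.
#'
#' @inheritParams phenotype_of
#' @return A tibble with columns `gamete` (label), `num`, `den` (exact
#'   rational probability `num/den`) and `prob` (numeric convenience value).
#' @examples
#' loci <- locus_set(2)
#' gamete_distribution(multi_genotype("AaBb", "female", loci), loci)
#' @export
gamete_distribution <- function(g, loci) {
  check_locus_set(loci)
  check_conforms(g, loci)
  en <- enumerate_gametes(g, loci)
  labels <- vapply(en$alleles, function(a) {
    paste(ifelse(is.na(a), "-", a), collapse = "")
  }, character(1))
  agg <- rowsum(en$weight, labels)
  out <- tibble(
    gamete = rownames(agg),
    num = as.integer(agg[, 1]),
    den = en$den
  )
  out$prob <- out$num / out$den
  out[order(-out$num, out$gamete, method = "radix"), ]
}
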