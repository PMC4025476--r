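# Independent brute-force oracles, deliberately written with plain loops and
# no calls into the package's enumeration code.

# Enumerate every equally likely meiotic outcome of one parent.
# alleles: list of per-locus character vectors (length 2; a male X-linked
# locus holds length 1). Returns a list of outcomes, each
# list(alleles = chr vector with NA at X-linked loci of a Y-bearing sperm,
#      x = does the gamete carry an X chromosome).
oracle_gametes <- function(alleles, x_linked, sex) {
  outcomes <- list(list(alleles = character(0), x = TRUE))
  for (i in seq_along(alleles)) {
    a <- alleles[[i]]
    if (sex == "male" && x_linked[i]) {
      # resolved by the X/Y split below
      outcomes <- lapply(outcomes, function(o) {
        o$alleles <- c(o$alleles, "?")
        o
      })
    } else {
      outcomes <- unlist(lapply(outcomes, function(o) {
        lapply(a, function(al) {
          o2 <- o
          o2$alleles <- c(o2$alleles, al)
          o2
        })
      }), recursive = FALSE)
    }
  }
  if (sex == "female") return(outcomes)
  # every sperm is X-bearing or Y-bearing with equal probability
  unlist(lapply(outcomes, function(o) {
    xo <- o
    xo$x <- TRUE
    for (i in seq_along(alleles)) {
      if (x_linked[i]) xo$alleles[i] <- alleles[[i]][1]
    }
    yo <- o
    yo$x <- FALSE
    yo$alleles[x_linked] <- NA_character_
    list(xo, yo)
  }), recursive = FALSE)
}

# Exhaustive offspring (sex, genotype-label) probabilities for a cross,
# counting every equally likely gamete pair.
oracle_cross <- function(mother_alleles, father_alleles, loci_df) {
  xl <- loci_df$x_linked
  mg <- oracle_gametes(mother_alleles, xl, "female")
  fg <- oracle_gametes(father_alleles, xl, "male")
  tab <- list()
  for (m in mg) {
    for (f in fg) {
      sex <- if (f$x) "female" else "male"
      parts <- character(length(xl))
      for (i in seq_along(xl)) {
        if (xl[i] && sex == "male") {
          parts[i] <- paste0(m$alleles[i], "-")
        } else {
          pair <- c(m$alleles[i], f$alleles[i])
          ord <- c(loci_df$dominant[i], loci_df$recessive[i])
          pair <- pair[order(match(pair, ord))]
          parts[i] <- paste0(pair, collapse = "")
        }
      }
      key <- paste(sex, paste(parts, collapse = ""))
      tab[[key]] <- (if (is.null(tab[[key]])) 0 else tab[[key]]) + 1
    }
  }
  total <- length(mg) * length(fg)
  out <- data.frame(
    key = names(tab),
    prob = unlist(tab) / total,
    stringsAsFactors = FALSE
  )
  out$sex <- sub(" .*", "", out$key)
  out$genotype <- sub(".* ", "", out$key)
  out[order(out$key), c("sex", "genotype", "prob")]
}

# Direct-arithmetic Hardy-Weinberg oracle (independent of hw_test()).
oracle_hw <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  e <- n * c(p^2, 2 * p * q, q^2)
  o <- c(n_AA, n_Aa, n_aa)
  keep <- e > 0
  chi2 <- sum((o[keep] - e[keep])^2 / e[keep])
  f <- if (e[2] > 0) 1 - n_Aa / e[2] else NA_real_
  list(p = p, expected = e, chi2 = chi2, f = f)
}

gcd_test <- function(x) {
  g <- x[1]
  for (v in x[-1]) {
    a <- g
    b <- v
    while (b != 0) {
      t <- a %% b
      a <- b
      b <- t
    }
    g <- a
  }
  as.integer(g)
}

# Random valid genotype strings for a locus set (for property loops).
random_genotype <- function(loci, sex) {
  paste(vapply(seq_len(nrow(loci)), function(i) {
    al <- c(loci$dominant[i], loci$recessive[i])
    if (loci$x_linked[i] && sex == "male") {
      paste0(sample(al, 1), "-")
    } else {
      pair <- sample(al, 2, replace = TRUE)
      pair <- pair[order(match(pair, al))]
      paste0(pair, collapse = "")
    }
  }, character(1)), collapse = "")
}

genotype_to_alleles <- function(g, loci, sex) {
  chars <- strsplit(g, "")[[1]]
  lapply(seq_len(nrow(loci)), function(i) {
    pair <- chars[(2 * i - 1):(2 * i)]
    if (loci$x_linked[i] && sex == "male") pair[1] else pair
  })
}
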