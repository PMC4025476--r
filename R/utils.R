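# Internal helpers: integer rational reduction and seed plumbing.

gcd2 <- function(a, b) {
  while (b != 0) {
    tmp <- a %% b
    a <- b
    b <- tmp
  }
  a
}

# greatest common divisor of a vector of non-negative integers
gcd_all <- function(x) {
  x <- x[x > 0]
  if (length(x) == 0L) return(1L)
  Reduce(gcd2, x)
}

# reduce integer weights to the smallest coprime ratio terms
reduce_ratio <- function(num) {
  g <- gcd_all(num)
  as.integer(num / g)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. seed = NULL evaluates code with the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# One master seed spawns independent per-item seeds so items are individually
# reproducible. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n, replace = FALSE))
}

# swap upper/lower case of every character (complementary phenotype class)
swap_case <- function(x) {
  chartr(paste0(c(letters, LETTERS), collapse = ""),
         paste0(c(LETTERS, letters), collapse = ""), x)
}

# locale-independent sort (C collation: uppercase before lowercase)
sort_c <- function(x, decreasing = FALSE) sort(x, decreasing = decreasing, method = "radix")

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1], not %s.", name,
                  paste(format(x), collapse = ", ")))
  }
  invisible(x)
}
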