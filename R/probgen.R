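#' Generate a seeded batch of practice problems with answer keys
#'
#' Instructor-facing batch generator covering every problem type the package
#' solves. One master seed spawns an independent substream per item, so any
#' single item can be regenerated without the rest, and the same seed always
#' yields a byte-identical batch file.
#'
#' Per-type generation:
#' * `"mapping"` — delegates to [generate_mapping_problem()]; the stored key
#'   is the true generating scenario.
#' * `"hw"` — draws an allele frequency `p` uniformly from `p_range` and an
#'   inbreeding coefficient from `f_range`, samples `n` genotypes
#'   multinomially from the inbreeding-adjusted proportions; key =
#'   [hw_test()] on the counts.
#' * `"breeders"` — draws heritability and selection differential from their
#'   ranges, designates one of the three Breeder's-equation quantities as the
#'   unknown; key = the completed triple from [breeders_solve()].
#' * `"growth"` — draws initial size, intrinsic rate and time, designates one
#'   of `nt`, `t`, `r`, `n0` as the unknown; key = the completed set from
#'   [growth_solve()].
#'
#' @param type One of `"mapping"`, `"hw"`, `"breeders"`, `"growth"`.
#' @param count Number of problems (instructors commonly generate 100 and
#'   hand-pick from them).
#' @param params Named list overriding the type's generation parameters (see
#'   Details above; defaults: mapping `k = 3, n = 1000, r_range = c(0.05,
#'   0.35), p_unlinked = 0, coincidence = 1, exact = FALSE`; hw `n = 200,
#'   p_range = c(0.1, 0.9), f_range = c(0, 0)`; breeders `h2_range = c(0.1,
#'   0.9), s_range = c(1, 20)`; growth `n0_range = c(10, 1000), r_range =
#'   c(0.01, 0.2), t_range = c(1, 50)`).
#' @param seed Master seed (integer). Optional but recommended.
#' @return An object of class `problem_batch`: list with `type`, `count`,
#'   `seed`, `params`, `tolerances` and `items` (each item a list with
#'   `item`, `seed`, `problem`, `solution`).
#' @examples
#' b <- generate_batch("hw", count = 3, seed = 11)
#' b$items[[1]]$problem
#' @export
generate_batch <- function(type = c("mapping", "hw", "breeders", "growth"),
                           count = 1, params = list(), seed = NULL) {
  type <- match.arg(type)
  if (!is_count(count)) abort("`count` must be a positive integer.")
  defaults <- switch(type,
    mapping = list(k = 3, n = 1000, r_range = c(0.05, 0.35), p_unlinked = 0,
                   coincidence = 1, exact = FALSE),
    hw = list(n = 200, p_range = c(0.1, 0.9), f_range = c(0, 0)),
    breeders = list(h2_range = c(0.1, 0.9), s_range = c(1, 20)),
    growth = list(n0_range = c(10, 1000), r_range = c(0.01, 0.2),
                  t_range = c(1, 50))
  )
  bad <- setdiff(names(params), names(defaults))
  if (length(bad) > 0) {
    abort(sprintf("Unknown parameter(s) for type '%s': %s.", type,
                  paste(bad, collapse = ", ")))
  }
  params <- modifyList(defaults, params)
  seeds <- if (is.null(seed)) rep(list(NULL), count) else as.list(derive_seeds(seed, count))

  items <- lapply(seq_len(count), function(i) {
    s <- seeds[[i]]
    it <- switch(type,
      mapping = {
        ex <- generate_mapping_problem(k = params$k, n = params$n,
                                       r_range = params$r_range,
                                       p_unlinked = params$p_unlinked,
                                       coincidence = params$coincidence,
                                       exact = params$exact, seed = s)
        list(problem = ex$problem, solution = ex$key)
      },
      hw = with_seed(s, {
        p <- runif(1, params$p_range[1], params$p_range[2])
        f <- runif(1, params$f_range[1], params$f_range[2])
        cnt <- as.integer(rmultinom(1, params$n, genotype_frequencies(p, f)))
        names(cnt) <- c("AA", "Aa", "aa")
        list(problem = list(counts = as.list(cnt), true_p = p, true_f = f),
             solution = as.list(glance(suppressWarnings(hw_test(cnt)))))
      }),
      breeders = with_seed(s, {
        h2 <- round(runif(1, params$h2_range[1], params$h2_range[2]), 2)
        sdiff <- round(runif(1, params$s_range[1], params$s_range[2]), 2)
        full <- breeders_solve(h2 = h2, s = sdiff)
        unknown <- sample(c("h2", "s", "r"), 1)
        given <- as.list(full[setdiff(c("h2", "s", "r"), unknown)])
        list(problem = list(given = given, unknown = unknown),
             solution = as.list(full[c("h2", "s", "r")]))
      }),
      growth = with_seed(s, {
        n0 <- round(runif(1, params$n0_range[1], params$n0_range[2]))
        rr <- round(runif(1, params$r_range[1], params$r_range[2]), 3)
        tt <- round(runif(1, params$t_range[1], params$t_range[2]))
        full <- growth_solve(n0 = n0, r = rr, t = tt)
        unknown <- sample(c("nt", "t", "r", "n0"), 1)
        given <- as.list(full[setdiff(c("n0", "r", "t", "nt"), unknown)])
        list(problem = list(given = given, unknown = unknown),
             solution = as.list(full[c("n0", "r", "t", "nt")]))
      })
    )
    c(list(item = i, seed = if (is.null(s)) NA_integer_ else s), it)
  })

  structure(list(
    type = type, count = as.integer(count),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    params = params,
    tolerances = list(r_abs = 0.005, rel = 1e-3),
    items = items
  ), class = "problem_batch")
}

#' @export
print.problem_batch <- function(x, ...) {
  cat(sprintf("<problem_batch> %d %s problem(s), seed %s\n",
              x$count, x$type, x$seed))
  invisible(x)
}

#' @export
glance.problem_batch <- function(x, ...) {
  tibble(type = x$type, count = x$count, seed = x$seed)
}

# ---- serialization ---------------------------------------------------------

solution_to_list <- function(sol) {
  if (inherits(sol, "mapping_solution")) {
    list(order = sol$order, phase = sol$phase, r = as.list(sol$r),
         cM = as.list(sol$cM), coincidence = sol$coincidence,
         unlinked = as.list(sol$unlinked), n = sol$n)
  } else sol
}

problem_to_list <- function(prob) {
  if (inherits(prob, "mapping_problem")) {
    list(loci = prob$loci,
         classes = lapply(seq_len(nrow(prob$classes)), function(i) {
           list(phenotype = prob$classes$class[i], count = prob$classes$count[i])
         }))
  } else prob
}

#' Write a problem batch to JSON
#'
#' The batch file is self-describing: it embeds the generation parameters,
#' master seed and grading tolerances alongside every problem/solution pair.
#' The same batch always serializes to the identical bytes.
#'
#' @param batch A [generate_batch()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_problem_batch <- function(batch, path) {
  if (!inherits(batch, "problem_batch")) abort("`batch` must come from generate_batch().")
  obj <- list(
    type = batch$type, count = batch$count, seed = batch$seed,
    params = batch$params, tolerances = batch$tolerances,
    items = lapply(batch$items, function(it) {
      list(item = it$item, seed = it$seed,
           problem = problem_to_list(it$problem),
           solution = solution_to_list(it$solution))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a problem batch from JSON
#'
#' @param path Path to a file written by [write_problem_batch()].
#' @return A `problem_batch` with mapping problems restored as
#'   [mapping_problem()] objects.
#' @export
read_problem_batch <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  items <- lapply(obj$items, function(it) {
    if (obj$type == "mapping") {
      counts <- setNames(
        vapply(it$problem$classes, function(cl) as.numeric(cl$count), numeric(1)),
        vapply(it$problem$classes, function(cl) cl$phenotype, character(1))
      )
      it$problem <- mapping_problem(counts, loci = unlist(it$problem$loci))
      sol <- it$solution
      it$solution <- new_mapping_solution(
        k = length(it$problem$loci),
        order = unlist(sol$order),
        phase = sol$phase,
        r = unlist(sol$r),
        coincidence = sol$coincidence %||% NA_real_,
        unlinked = unlist(sol$unlinked),
        n = sol$n
      )
    }
    it
  })
  structure(list(
    type = obj$type, count = as.integer(obj$count), seed = obj$seed,
    params = lapply(obj$params, function(p) unlist(p)),
    tolerances = obj$tolerances, items = items
  ), class = "problem_batch")
}

# ---- answer checking -------------------------------------------------------

num_close <- function(given, expected, tol_abs = NULL, tol_rel = NULL) {
  if (is.null(given) || any(is.na(given)) || length(given) != length(expected)) return(FALSE)
  if (!is.null(tol_abs)) return(all(abs(given - expected) <= tol_abs))
  all(abs(given - expected) <= abs(expected) * tol_rel + 1e-12)
}

#' Check a student answer against a problem's solution
#'
#' Recomputes the key for `problem` with the corresponding solver and
#' compares the answer field by field: recombination fractions within an
#' absolute tolerance (default 0.005), other numeric fields within a relative
#' tolerance (default 1e-3); gene order as a sequence (a reversed order is
#' the same map); phase as an unordered pair of parental classes. Every field
#' is judged independently so partial credit is visible.
#'
#' @param problem A [mapping_problem()], a batch item from
#'   [generate_batch()], or a list with `counts` (HW) / `given` + `unknown`
#'   (breeders, growth).
#' @param answer Named list of answered fields, e.g.
#'   `list(order = c("A","B","C"), r = c(0.1, 0.2))` or `list(r = 5)`.
#' @param type Problem type; inferred for mapping problems and batch items.
#' @param tol_r Absolute tolerance on recombination fractions.
#' @param tol_rel Relative tolerance on other numeric fields.
#' @return A tibble of class `answer_verdict` with columns `field`,
#'   `expected`, `given`, `pass`, plus attribute `all_pass`.
#' @examples
#' p <- mapping_problem(c(AB = 450, ab = 450, Ab = 50, aB = 50))
#' check_answer(p, list(r = 0.101, phase = "AB/ab"))
#' @export
check_answer <- function(problem, answer, type = NULL,
                         tol_r = 0.005, tol_rel = 1e-3) {
  if (is.list(problem) && !is.null(problem$problem)) {
    # a batch item; the stored type wins if discoverable
    type <- type %||% attr(problem, "type")
    problem <- problem$problem
  }
  if (inherits(problem, "mapping_problem")) type <- "mapping"
  if (is.null(type)) {
    if (!is.null(problem$counts)) type <- "hw"
    else if (!is.null(problem$unknown)) {
      type <- if ("h2" %in% c(names(problem$given), problem$unknown)) "breeders" else "growth"
    } else abort("Cannot infer the problem type; pass `type`.")
  }
  if (!is.list(answer) || is.null(names(answer))) {
    abort("`answer` must be a named list of answered fields.")
  }

  rows <- list()
  add <- function(field, expected, given, pass) {
    rows[[length(rows) + 1L]] <<- tibble(
      field = field,
      expected = paste(format(expected, digits = 6), collapse = " "),
      given = paste(format(given, digits = 6), collapse = " "),
      pass = pass
    )
  }

  if (type == "mapping") {
    key <- solve_mapping(problem)
    for (field in names(answer)) {
      given <- answer[[field]]
      if (field == "order") {
        ok <- identical(as.character(given), key$order) ||
          identical(as.character(given), rev(key$order))
        add("order", paste(key$order, collapse = "-"), paste(given, collapse = "-"), ok)
      } else if (field == "phase") {
        gv <- if (length(given) == 1L) strsplit(given, "/", fixed = TRUE)[[1]] else given
        kv <- strsplit(key$phase, "/", fixed = TRUE)[[1]]
        add("phase", key$phase, paste(gv, collapse = "/"), setequal(gv, kv))
      } else if (field %in% c("r", "cM")) {
        expected <- if (field == "r") key$r else key$cM
        tol <- if (field == "r") tol_r else 100 * tol_r
        gv <- unlist(given)
        if (!is.null(names(gv)) && all(names(gv) %in% names(key$r))) {
          expected <- expected[names(gv)]
        } else if (length(gv) == length(expected)) {
          # unnamed: accept either map orientation
          if (!num_close(gv, expected, tol_abs = tol) &&
              num_close(gv, rev(expected), tol_abs = tol)) {
            expected <- rev(expected)
          }
        }
        for (j in seq_along(gv)) {
          nm <- names(gv)[j] %||% names(expected)[j]
          add(paste0(field, "[", nm %||% j, "]"), expected[j], gv[j],
              num_close(gv[j], expected[j], tol_abs = tol))
        }
      } else if (field %in% c("coincidence", "interference")) {
        expected <- key[[field]]
        add(field, expected, given, num_close(given, expected, tol_rel = tol_rel))
      } else if (field == "unlinked") {
        add(field, key$unlinked, given,
            length(given) == length(key$unlinked) && all(given == key$unlinked))
      } else {
        add(field, NA_character_, given, FALSE)
      }
    }
  } else if (type == "hw") {
    cnt <- unlist(problem$counts)[c("AA", "Aa", "aa")]
    key <- glance(suppressWarnings(hw_test(cnt)))
    for (field in names(answer)) {
      if (field %in% names(key)) {
        add(field, key[[field]], answer[[field]],
            num_close(answer[[field]], key[[field]], tol_rel = tol_rel))
      } else add(field, NA_character_, answer[[field]], FALSE)
    }
  } else {
    given <- problem$given
    key <- if (type == "breeders") {
      do.call(breeders_solve, given[intersect(names(given), c("h2", "s", "r"))])
    } else {
      do.call(growth_solve, given[intersect(names(given), c("n0", "r", "b", "d", "t", "nt"))])
    }
    for (field in names(answer)) {
      if (field %in% names(key)) {
        add(field, key[[field]], answer[[field]],
            num_close(answer[[field]], key[[field]], tol_rel = tol_rel))
      } else add(field, NA_character_, answer[[field]], FALSE)
    }
  }

  out <- dplyr::bind_rows(rows)
  class(out) <- c("answer_verdict", class(out))
  attr(out, "all_pass") <- all(out$pass)
  out
}
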