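#' Triangular (tent) basis for piecewise-linear additive terms
#'
#' A set of piecewise-linear "tent" functions on equally spaced knots in
#' [0,1]: basis j is 1 at knot j, 0 at all other knots, linear in between.
#' At every x in [0,1] the basis values sum to 1 (partition of unity) and
#' at most two are nonzero, so an additive term expanded in this basis is
#' an arbitrary piecewise-linear function of its input.
#'
#' @param n_basis number of basis functions (default 6).
#' @return list of class \code{"al_tri_basis"} with \code{n_basis} and
#'   \code{knots}.
#' @export
triangular_basis_spec <- function(n_basis = 6) {
  if (n_basis < 2) stop("need at least 2 basis functions")
  structure(list(n_basis = as.integer(n_basis),
                 knots = seq(0, 1, length.out = n_basis)),
            class = "al_tri_basis")
}

#' Evaluate the triangular basis
#'
#' Inputs outside [0,1] are clipped (the number clipped is reported in the
#' \code{"clipped"} attribute).
#'
#' @param x numeric vector.
#' @param spec an \code{al_tri_basis}.
#' @return matrix length(x) x n_basis; rows sum to 1 with at most two
#'   nonzero entries.
#' @export
triangular_basis <- function(x, spec = triangular_basis_spec()) {
  clipped <- sum(x < 0 | x > 1)
  x <- pmin(pmax(x, 0), 1)
  h <- 1 / (spec$n_basis - 1)
  out <- vapply(spec$knots,
                function(k) pmax(0, 1 - abs(x - k) / h),
                numeric(length(x)))
  if (!is.matrix(out)) out <- matrix(out, nrow = length(x))
  attr(out, "clipped") <- clipped
  out
}

# Parse "j" / "j:k" term labels into band index pairs (k = NA for mains).
parse_term <- function(term) {
  parts <- as.integer(strsplit(term, ":", fixed = TRUE)[[1]])
  if (length(parts) == 1) return(c(parts, NA_integer_))
  if (length(parts) != 2 || parts[1] >= parts[2]) {
    stop(sprintf("bad term '%s': interactions must be 'j:k' with j < k", term))
  }
  parts
}

#' Validate a term set
#'
#' Terms are written in the field's "j" (main effect of band j) and "j:k"
#' (elementwise product of bands j and k, j < k) notation.
#'
#' @param terms character vector of term labels.
#' @return the terms, validated and de-duplicated order-preserving.
#' @export
term_set <- function(terms) {
  terms <- as.character(terms)
  invisible(lapply(terms, parse_term))
  if (anyDuplicated(terms)) stop("duplicate terms in term set")
  terms
}

# Value of one term for a band matrix (n pixels x k bands).
term_values <- function(bands, term) {
  jk <- parse_term(term)
  if (any(jk[!is.na(jk)] > ncol(bands))) {
    stop(sprintf("term '%s' refers to a band not present in the stack", term))
  }
  if (is.na(jk[2])) bands[, jk[1]] else bands[, jk[1]] * bands[, jk[2]]
}

#' Build a design matrix from image bands and a term set
#'
#' Without a basis: one column per term (raw value) plus an intercept.
#' With a basis: a single global intercept plus, per term, the basis
#' expansion of the term's value with the first basis column dropped —
#' leaving n_basis - 1 (by default 5) coefficients per term. Dropping one
#' column per term removes the confounding between the tents' partition of
#' unity and the intercept. Term values are clipped to [0,1] before
#' expansion (count reported via attribute \code{"clipped"}).
#'
#' @param stack either an n_rows x n_cols x k image array or an n x k band
#'   matrix (e.g. from \code{sample_pixels}).
#' @param terms character term set (see \code{term_set}).
#' @param basis an \code{al_tri_basis}, or NULL for raw values.
#' @param intercept include an intercept column (default TRUE).
#' @return numeric design matrix with named columns.
#' @export
build_design <- function(stack, terms, basis = NULL, intercept = TRUE) {
  bands <- if (length(dim(stack)) == 3) {
    k <- dim(stack)[3]
    matrix(stack, ncol = k)
  } else {
    as.matrix(stack)
  }
  terms <- term_set(terms)
  cols <- list()
  clipped <- 0L
  if (intercept) cols[["(Intercept)"]] <- rep(1, nrow(bands))
  for (tm in terms) {
    v <- term_values(bands, tm)
    if (is.null(basis)) {
      cols[[tm]] <- v
    } else {
      B <- triangular_basis(v, basis)
      clipped <- clipped + attr(B, "clipped")
      B <- B[, -1, drop = FALSE]
      colnames(B) <- sprintf("%s.b%d", tm, 2:basis$n_basis)
      for (cn in colnames(B)) cols[[cn]] <- B[, cn]
    }
  }
  out <- do.call(cbind, cols)
  attr(out, "clipped") <- clipped
  out
}

#' Genetic-algorithm settings
#'
#' @param pop population size (default 100).
#' @param generations number of generations (default 150).
#' @param tournament tournament size for parent selection (default 3).
#' @param mutation per-gene swap-mutation probability, in (0,1)
#'   (default 0.05).
#' @param seed optional integer seed applied at the start of the search.
#' @return list of class \code{"al_ga_config"}.
#' @export
ga_config <- function(pop = 100, generations = 150, tournament = 3,
                      mutation = 0.05, seed = NULL) {
  stopifnot(pop > 1, generations > 0, tournament > 0,
            mutation > 0, mutation < 1)
  structure(list(pop = as.integer(pop), generations = as.integer(generations),
                 tournament = as.integer(tournament), mutation = mutation,
                 seed = seed),
            class = "al_ga_config")
}

#' Fixed-size subset selection by genetic algorithm
#'
#' Searches for the size-k subset of a candidate pool minimising a
#' user-supplied objective (e.g. validation deviance of a model built on
#' the subset). Operators: tournament selection; subset-union crossover
#' (the child is drawn from the union of its parents, keeping genes common
#' to both, then repaired to size k); per-gene swap mutation (a gene is
#' replaced by a random non-member). The best individual is carried over
#' unchanged each generation (elitism), so the result is never worse than
#' the best of the initial population. Objective values are cached, so the
#' objective is called once per distinct subset.
#'
#' @param pool character vector (or any vector) of candidate items.
#' @param k subset size (1 <= k <= length(pool)).
#' @param objective function(subset) -> single number, lower is better.
#' @param cfg an \code{al_ga_config}.
#' @return list of class \code{"al_ga_result"}: \code{best} (subset, in
#'   pool order), \code{objective} (its value), \code{trace} (best value
#'   per generation).
#' @export
ga_select <- function(pool, k, objective, cfg = ga_config()) {
  npool <- length(pool)
  if (k > npool) stop("k exceeds pool size")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (k == npool) {
    val <- objective(pool)
    return(structure(list(best = pool, objective = val, trace = val),
                     class = "al_ga_result"))
  }
  cache <- new.env(parent = emptyenv())
  evalsub <- function(idx) {
    key <- paste(idx, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- objective(pool[idx])
    cache[[key]] <- v
    v
  }
  popl <- replicate(cfg$pop, sort(sample.int(npool, k)), simplify = FALSE)
  fit <- vapply(popl, evalsub, 0)
  trace <- numeric(cfg$generations)
  for (g in seq_len(cfg$generations)) {
    elite <- which.min(fit)
    newpop <- list(popl[[elite]])
    while (length(newpop) < cfg$pop) {
      pick <- function() {
        cand <- sample.int(cfg$pop, cfg$tournament, replace = TRUE)
        popl[[cand[which.min(fit[cand])]]]
      }
      p1 <- pick(); p2 <- pick()
      common <- intersect(p1, p2)
      un <- union(p1, p2)
      child <- if (length(common) >= k) {
        sample(common, k)
      } else {
        c(common, sample(setdiff(un, common), k - length(common)))
      }
      mut <- runif(k) < cfg$mutation
      if (any(mut)) {
        repl <- sample(setdiff(seq_len(npool), child), sum(mut))
        child[mut] <- repl
      }
      newpop[[length(newpop) + 1]] <- sort(child)
    }
    popl <- newpop
    fit <- vapply(popl, evalsub, 0)
    trace[g] <- min(fit)
  }
  bi <- which.min(fit)
  structure(list(best = pool[popl[[bi]]], objective = fit[bi], trace = trace),
            class = "al_ga_result")
}

#' @export
print.al_ga_result <- function(x, ...) {
  cat(sprintf("<GA result: objective %.6g, subset {%s}>\n",
              x$objective, paste(x$best, collapse = ", ")))
  invisible(x)
}

#' Model search over subset sizes
#'
#' Runs \code{ga_select} for each requested model size and returns the best
#' subset per size plus the overall winner (minimum objective across
#' sizes). Per-size seeds are offset from \code{cfg$seed} so sizes are
#' searched independently but reproducibly.
#'
#' @param pool candidate term pool.
#' @param sizes vector of subset sizes to consider.
#' @param objective function(subset) -> number, lower better (typically
#'   validation deviance of the model refit on the subset).
#' @param cfg an \code{al_ga_config}.
#' @return list of class \code{"al_model_search"}: \code{per_size} (named
#'   list of \code{al_ga_result}), \code{best} (subset), \code{best_size},
#'   \code{best_objective}.
#' @export
model_search <- function(pool, sizes, objective, cfg = ga_config()) {
  if (any(sizes < 1)) stop("sizes must be positive")
  per <- lapply(seq_along(sizes), function(i) {
    ci <- cfg
    if (!is.null(ci$seed)) ci$seed <- ci$seed + i - 1L
    ga_select(pool, sizes[i], objective, ci)
  })
  names(per) <- as.character(sizes)
  objs <- vapply(per, `[[`, 0, "objective")
  bi <- which.min(objs)
  structure(list(per_size = per, best = per[[bi]]$best,
                 best_size = sizes[bi], best_objective = objs[bi]),
            class = "al_model_search")
}
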