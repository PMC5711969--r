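#' Autologistic regression model object
#'
#' The joint distribution of the coded pixel classes z is
#' \deqn{P(Z = z) \propto \exp\{ (X\beta)^T z + (\lambda/2) z^T A z \},}
#' where X is the per-pixel design matrix, A the 4-neighbour adjacency and
#' \eqn{\lambda \ge 0} the spatial association. \eqn{\lambda = 0} gives
#' independent pixels (ordinary logistic regression). In conditional form
#' the log-odds that pixel i is in the high class given all others are
#' \deqn{(H-L)\,( x_i^T\beta + \lambda \sum_{j\sim i} z_j )}
#' for the standard model, or, for the centred variant,
#' \deqn{(H-L)\,( x_i^T\beta + \lambda \sum_{j\sim i} (z_j - \mu_j) ),}
#' where \eqn{\mu_j} is the independence expectation of \eqn{Z_j}. The
#' (H-L) factor makes fitted probabilities at \eqn{\lambda = 0} identical
#' across codings when the convention \code{beta = b/(H-L)} (b the plain
#' logistic coefficients) is used.
#'
#' The centred variant is represented jointly as the standard form with
#' unary coefficients \eqn{\alpha_i = x_i^T\beta - \lambda\sum_{j\sim i}\mu_j},
#' which reproduces exactly the centred conditionals above.
#'
#' @param beta numeric coefficient vector (model scale, i.e. divided by the
#'   coding span).
#' @param lambda spatial association, finite and >= 0.
#' @param coding \code{"pm1"} (default) or \code{"01"}, or a coding object.
#' @param centred logical; use the centred variant?
#' @param columns optional character vector of design-column names.
#' @return An object of class \code{"al_model"}.
#' @export
autologistic_model <- function(beta, lambda, coding = "pm1", centred = FALSE,
                               columns = NULL) {
  beta <- as.numeric(beta)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0) {
    stop("lambda must be a single finite value >= 0")
  }
  if (any(!is.finite(beta))) stop("beta must be finite")
  structure(
    list(beta = beta, lambda = as.numeric(lambda), coding = coding(coding),
         centred = isTRUE(centred), columns = columns),
    class = "al_model"
  )
}

#' @export
print.al_model <- function(x, ...) {
  cat(sprintf("<autologistic model: %s, {%g,%g} coding, lambda = %g, r = %d>\n",
              if (x$centred) "centred" else "standard",
              x$coding$low, x$coding$high, x$lambda, length(x$beta)))
  invisible(x)
}

# Linear predictor as an n_rows x n_cols matrix; validates shapes.
linear_predictor <- function(model, X, graph) {
  X <- as.matrix(X)
  if (nrow(X) != graph$n) stop("design matrix rows must equal pixel count")
  if (ncol(X) != length(model$beta)) {
    stop("beta length does not match design matrix columns")
  }
  if (any(!is.finite(X))) stop("design matrix has non-finite entries")
  matrix(as.numeric(X %*% model$beta), graph$n_rows, graph$n_cols)
}

#' Independence expectation of each pixel
#'
#' The expected coded value of each pixel under \eqn{\lambda = 0}:
#' \eqn{\mu_i = L + (H-L)\,\mathrm{antilogit}\{(H-L)\, x_i^T\beta\}}. For the
#' (0,1) coding this is antilogit(x'b); for (-1,1) it equals tanh(x'b).
#'
#' @inheritParams negpotential
#' @return numeric matrix of expectations, lattice-shaped.
#' @export
independence_expectation <- function(model, X, graph) {
  eta <- linear_predictor(model, X, graph)
  cod <- model$coding
  cod$low + cod$span * antilogit(cod$span * eta)
}

# Unary coefficient field alpha_i of the joint exponent: eta for the
# standard model, eta - lambda * sum of neighbour mus for the centred one.
unary_field <- function(model, X, graph) {
  eta <- linear_predictor(model, X, graph)
  if (model$centred && model$lambda != 0) {
    mu <- independence_expectation(model, X, graph)
    eta <- eta - model$lambda * neighbor_sum(mu, graph)
  }
  eta
}

#' Joint negpotential (log unnormalised probability)
#'
#' Evaluates the exponent \eqn{\alpha^T z + (\lambda/2) z^T A z} of the
#' joint PMF at the state z, with \eqn{\alpha} the unary coefficients
#' (covariate term, centred-adjusted if applicable).
#'
#' @param model an \code{al_model}.
#' @param X design matrix (n pixels x r).
#' @param z coded binary field matrix.
#' @param graph an \code{al_lattice}.
#' @return a single number.
#' @export
negpotential <- function(model, X, z, graph) {
  if (!is.matrix(z) || nrow(z) != graph$n_rows || ncol(z) != graph$n_cols) {
    stop("field shape does not match lattice")
  }
  check_field(z, model$coding)
  alpha <- unary_field(model, X, graph)
  # lambda/2 * z'Az = lambda * sum over undirected edges of z_i z_j
  val <- sum(alpha * z) + (model$lambda / 2) * sum(z * neighbor_sum(z, graph))
  if (!is.finite(val)) stop("negpotential overflowed; parameters too extreme")
  val
}

#' Full conditional probabilities of the high class
#'
#' For every pixel, the probability that it takes the high value given the
#' current values of all other pixels:
#' logit \eqn{\pi_i = (H-L)(\alpha_i + \lambda \sum_{j\sim i} z_j)} with
#' \eqn{\alpha} the (possibly centred-adjusted) unary field. Extreme logits
#' saturate to 0/1 without NaN.
#'
#' @inheritParams negpotential
#' @return probability matrix, lattice-shaped.
#' @export
conditional_probabilities <- function(model, X, z, graph) {
  if (!is.matrix(z) || nrow(z) != graph$n_rows || ncol(z) != graph$n_cols) {
    stop("field shape does not match lattice")
  }
  alpha <- unary_field(model, X, graph)
  s <- neighbor_sum(z, graph)
  antilogit(model$coding$span * (alpha + model$lambda * s))
}

# All 2^n coded states of an n-pixel lattice, one row per state, columns in
# column-major pixel order. Row order: pixel 1 varies fastest.
state_table <- function(n, cod) {
  if (n > 20) stop("enumeration refused for n_pixels > 20")
  m <- 2^n
  states <- matrix(cod$low, m, n)
  s <- 0:(m - 1)
  for (b in seq_len(n)) {
    states[bitwAnd(s, bitwShiftL(1L, b - 1L)) > 0, b] <- cod$high
  }
  states
}

#' Exact PMF by exhaustive enumeration
#'
#' Enumerates all \eqn{2^n} states of a small lattice and returns their
#' exact probabilities under the model. Intended as a brute-force oracle
#' for testing the intractable normalising constant; refuses n > 20.
#'
#' @inheritParams negpotential
#' @return list with \code{states} (2^n x n matrix of coded values,
#'   column-major pixel order) and \code{prob} (normalised probabilities).
#' @export
enumerate_pmf <- function(model, X, graph) {
  n <- graph$n
  cod <- model$coding
  states <- state_table(n, cod)
  alpha <- as.vector(unary_field(model, X, graph))
  u <- as.numeric(states %*% alpha)
  if (nrow(graph$edges) > 0) {
    ei <- graph$edges[, 1]; ej <- graph$edges[, 2]
    u <- u + model$lambda *
      rowSums(states[, ei, drop = FALSE] * states[, ej, drop = FALSE])
  }
  u <- u - max(u)
  p <- exp(u)
  list(states = states, prob = p / sum(p))
}

#' Exact marginal probabilities of the high class
#'
#' Sums the enumerated PMF; the brute-force counterpart of Gibbs-based
#' marginal estimation. Refuses n > 20.
#'
#' @inheritParams negpotential
#' @return probability matrix, lattice-shaped.
#' @export
exact_marginals <- function(model, X, graph) {
  pmf <- enumerate_pmf(model, X, graph)
  hi <- pmf$states == model$coding$high
  matrix(as.numeric(crossprod(hi, pmf$prob)), graph$n_rows, graph$n_cols)
}

#' Convert joint-model parameters between codings
#'
#' Re-expresses an autologistic joint distribution, given by a per-pixel
#' unary coefficient field and a pairwise coefficient, in the other coding
#' so that the distribution over relabelled states is unchanged. With
#' z01 = (zpm + 1)/2 the algebra gives lambda_pm = lambda_01 / 4 and
#' alpha_pm_i = alpha_01_i / 2 + lambda_01 d_i / 4 (d_i the vertex degree),
#' and conversely lambda_01 = 4 lambda_pm,
#' alpha_01_i = 2 alpha_pm_i - 2 lambda_pm d_i. The degree term means a
#' regression-constrained unary field (alpha = X beta) does not generally
#' stay regression-constrained on lattices with unequal degrees.
#'
#' @param unary numeric matrix of per-pixel unary coefficients.
#' @param lambda pairwise coefficient.
#' @param graph an \code{al_lattice}.
#' @param from,to codings (\code{"01"} / \code{"pm1"} or coding objects).
#' @return list with \code{unary} (matrix) and \code{lambda}.
#' @export
convert_coding <- function(unary, lambda, graph, from, to) {
  from <- coding(from); to <- coding(to)
  if (!is.matrix(unary) || nrow(unary) != graph$n_rows ||
      ncol(unary) != graph$n_cols) {
    stop("unary field shape does not match lattice")
  }
  if (from$name == to$name) return(list(unary = unary, lambda = lambda))
  d <- degree_matrix(graph)
  if (from$name == "01" && to$name == "pm1") {
    list(unary = unary / 2 + lambda * d / 4, lambda = lambda / 4)
  } else if (from$name == "pm1" && to$name == "01") {
    list(unary = 2 * unary - 2 * lambda * d, lambda = 4 * lambda)
  } else {
    stop("unsupported coding pair")
  }
}

#' Serialize / restore a fitted model as JSON
#'
#' @param model an \code{al_model}.
#' @param path file path.
#' @return \code{read_model_json} returns the restored \code{al_model}.
#' @export
write_model_json <- function(model, path) {
  obj <- list(beta = model$beta, lambda = model$lambda,
              coding = model$coding$name, centred = model$centred,
              columns = model$columns)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  autologistic_model(obj$beta, obj$lambda, coding = obj$coding,
                     centred = obj$centred, columns = obj$columns)
}
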