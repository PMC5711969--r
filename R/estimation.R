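#' Balanced pixel sampling across a split
#'
#' Pools all pixels of the scenes in one split and draws a class-stratified
#' sample without replacement: exactly round(n * high_fraction) foreground
#' and the remainder background pixels, uniformly across all images of the
#' split. Balanced (50/50) sampling equalises the implicit misclassification
#' costs of the two classes when their prevalences differ.
#'
#' @param scene_set an \code{al_scene_set}.
#' @param split which split to sample from.
#' @param n total sample size.
#' @param high_fraction foreground share of the sample (default 0.5).
#' @param seed integer seed (mandatory, for reproducibility).
#' @return list of class \code{"al_pixel_sample"}: \code{bands} (n x k
#'   matrix of band values), \code{high} (logical foreground indicator),
#'   \code{provenance} (data frame: scene id, row, col),
#'   \code{high_fraction}.
#' @export
sample_pixels <- function(scene_set, split, n, high_fraction = 0.5,
                          seed) {
  if (missing(seed)) stop("seed is required")
  scenes <- scenes_split(scene_set, split)
  n_high <- round(n * high_fraction)
  n_low <- n - n_high
  # global pixel table: scene index, linear pixel index, class
  sizes <- vapply(scenes, function(s) length(s$foreground), 0L)
  offs <- cumsum(c(0L, sizes))
  fg_all <- unlist(lapply(scenes, function(s) as.vector(s$foreground)))
  hi_idx <- which(fg_all); lo_idx <- which(!fg_all)
  if (length(hi_idx) < n_high) {
    stop(sprintf("not enough high-class pixels: need %d, have %d",
                 n_high, length(hi_idx)))
  }
  if (length(lo_idx) < n_low) {
    stop(sprintf("not enough low-class pixels: need %d, have %d",
                 n_low, length(lo_idx)))
  }
  set.seed(seed)
  take <- c(sample(hi_idx, n_high), sample(lo_idx, n_low))
  scene_of <- findInterval(take - 1L, offs, rightmost.closed = FALSE)
  within <- take - offs[scene_of]
  k <- dim(scenes[[1]]$image)[3]
  bands <- matrix(0, length(take), k)
  prov <- data.frame(scene = character(length(take)),
                     row = integer(length(take)),
                     col = integer(length(take)))
  for (si in unique(scene_of)) {
    sel <- scene_of == si
    sc <- scenes[[si]]
    nr <- nrow(sc$foreground)
    w <- within[sel]
    r <- ((w - 1L) %% nr) + 1L
    cc <- ((w - 1L) %/% nr) + 1L
    for (ch in seq_len(k)) bands[sel, ch] <- sc$image[, , ch][w]
    prov$scene[sel] <- sc$id; prov$row[sel] <- r; prov$col[sel] <- cc
  }
  structure(list(bands = bands, high = fg_all[take], provenance = prov,
                 high_fraction = high_fraction),
            class = "al_pixel_sample")
}

#' Logistic regression fit on the model's coefficient scale
#'
#' Maximises the Bernoulli log-likelihood of the foreground indicator with
#' logit p = x'b (optionally L1-penalised via glmnet), then stores
#' beta = b / (H - L). With this convention the conditional form of the
#' autologistic model at lambda = 0 reproduces the fitted probabilities
#' exactly under either coding.
#'
#' @param design numeric design matrix including any intercept column (as
#'   produced by \code{build_design}).
#' @param high logical (or 0/1) response.
#' @param coding target coding for the returned model.
#' @param l1_penalty LASSO penalty (glmnet lambda); 0 = ordinary fit.
#' @return list of class \code{"al_logistic_fit"}: \code{beta} (model
#'   scale), \code{b} (logit scale), \code{deviance} (training),
#'   \code{fitted}, \code{separation} flag.
#' @export
fit_logistic <- function(design, high, coding = "pm1", l1_penalty = 0) {
  cod <- coding(coding)
  y <- as.numeric(high)
  design <- as.matrix(design)
  if (l1_penalty > 0) {
    b <- glmnet_coefs(design, y, l1_penalty)
    p <- as.numeric(antilogit(design %*% b))
    return(structure(list(beta = b / cod$span, b = b,
                          deviance = deviance_binary(y, p), fitted = p,
                          separation = FALSE, coding = cod,
                          columns = colnames(design)),
                     class = "al_logistic_fit"))
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    if (is.null(bad)) bad <- qrd$pivot[(qrd$rank + 1):ncol(design)]
    stop(sprintf("design matrix is rank deficient; collinear columns: %s",
                 paste(bad, collapse = ", ")))
  }
  separated <- FALSE
  nonconv <- FALSE
  fit <- withCallingHandlers(
    glm.fit(design, y, family = binomial()),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg)) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      } else if (grepl("did not converge", msg)) {
        nonconv <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (nonconv && !separated) warning("glm.fit did not converge")
  if (separated) {
    warning("perfect separation detected; refitting with a small L1 penalty")
    b <- glmnet_coefs(design, y, 1e-4)
  } else {
    b <- fit$coefficients
  }
  p <- as.numeric(antilogit(design %*% b))
  structure(list(beta = b / cod$span, b = b,
                 deviance = deviance_binary(y, p), fitted = p,
                 separation = separated, coding = cod,
                 columns = colnames(design)),
            class = "al_logistic_fit")
}

# L1-penalised coefficients at a single penalty, intercept handled through
# the design's own intercept column (glmnet's intercept disabled).
glmnet_coefs <- function(design, y, penalty) {
  icol <- which(apply(design, 2, function(v) all(v == v[1])))
  pf <- rep(1, ncol(design))
  pf[icol] <- 0  # never shrink the intercept column
  fit <- glmnet::glmnet(design, y, family = "binomial", alpha = 1,
                        lambda = penalty, intercept = FALSE,
                        standardize = FALSE, penalty.factor = pf)
  as.numeric(fit$beta[, 1])
}

#' Bernoulli deviance of predicted probabilities
#'
#' \eqn{-2 \sum [y \log p + (1-y)\log(1-p)]} with the foreground indicator
#' as y; probabilities clamped to [1e-12, 1 - 1e-12].
#'
#' @param high logical (or 0/1) truth.
#' @param probs predicted probabilities of the high class.
#' @return a single number.
#' @export
deviance_binary <- function(high, probs) {
  y <- as.numeric(high)
  p <- pmin(pmax(as.numeric(probs), 1e-12), 1 - 1e-12)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Log pseudolikelihood of labelled scenes
#'
#' The sum, over images and pixels, of the log full-conditional probability
#' of each observed label given its observed neighbours — the tractable
#' surrogate for the joint log-likelihood. At lambda = 0 it equals the
#' independence Bernoulli log-likelihood exactly.
#'
#' @param model an \code{al_model}.
#' @param scenes list of scenes (each with \code{image} and
#'   \code{foreground}).
#' @param x_builder function(scene) -> design matrix.
#' @return a single number (log pseudolikelihood).
#' @export
pseudolikelihood <- function(model, scenes, x_builder) {
  tot <- 0
  for (sc in scenes) {
    graph <- build_lattice(nrow(sc$foreground), ncol(sc$foreground))
    X <- x_builder(sc)
    z <- encode_field(sc$foreground, model$coding)
    p <- conditional_probabilities(model, X, z, graph)
    p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
    tot <- tot + sum(ifelse(sc$foreground, log(p), log1p(-p)))
  }
  tot
}

# Internal: negative log PL and its analytic gradient over (beta, lambda),
# vectorised over precomputed per-scene pieces.
mpl_objective <- function(par, pre, cod, centred) {
  r <- ncol(pre[[1]]$X)
  beta <- par[seq_len(r)]; lambda <- par[r + 1]
  span <- cod$span
  nll <- 0; gb <- numeric(r); gl <- 0
  for (d in pre) {
    eta <- as.numeric(d$X %*% beta)
    if (centred) {
      sig <- antilogit(span * eta)
      mu <- cod$low + span * sig
      m <- as.numeric(neighbor_sum(matrix(mu, d$nr, d$nc), d$graph))
      t <- span * (eta + lambda * (d$s - m))
    } else {
      t <- span * (eta + lambda * d$s)
    }
    # -loglik via stable log sigmoid
    nll <- nll - sum(plogis(ifelse(d$y, t, -t), log.p = TRUE))
    w <- d$y - antilogit(t)
    if (centred) {
      # d mu_j / d beta = span^2 sig_j (1 - sig_j) x_j
      dsig <- span^2 * sig * (1 - sig)
      nsw <- as.numeric(neighbor_sum(matrix(w, d$nr, d$nc), d$graph))
      gb <- gb - span * (crossprod(d$X, w) -
                           lambda * crossprod(d$X, dsig * nsw))
      gl <- gl - span * sum(w * (d$s - m))
    } else {
      gb <- gb - span * as.numeric(crossprod(d$X, w))
      gl <- gl - span * sum(w * d$s)
    }
  }
  list(value = nll, gradient = c(as.numeric(gb), gl))
}

#' Maximum pseudolikelihood estimation
#'
#' Jointly maximises the log pseudolikelihood over (beta, lambda) with
#' L-BFGS-B and the analytic gradient; lambda is box-constrained to
#' [0, lambda_max].
#'
#' @param scenes list of labelled scenes.
#' @param x_builder function(scene) -> design matrix.
#' @param coding model coding.
#' @param centred fit the centred variant?
#' @param init optional list(beta, lambda) starting point; default is a
#'   zero beta and lambda = 0.5 (in the pipeline, the stage-1 logistic fit
#'   is passed here).
#' @param lambda_max upper box constraint (default 10).
#' @return list of class \code{"al_mpl_fit"}: \code{model} (an
#'   \code{al_model} at the optimum), \code{logPL}, \code{converged},
#'   \code{iterations}, \code{message}.
#' @export
fit_mpl <- function(scenes, x_builder, coding = "pm1", centred = FALSE,
                    init = NULL, lambda_max = 10) {
  if (length(scenes) < 1) stop("at least one labelled scene is required")
  cod <- coding(coding)
  pre <- lapply(scenes, function(sc) {
    nr <- nrow(sc$foreground); nc <- ncol(sc$foreground)
    graph <- build_lattice(nr, nc)
    z <- encode_field(sc$foreground, cod)
    list(X = as.matrix(x_builder(sc)), y = as.numeric(sc$foreground),
         s = as.numeric(neighbor_sum(z, graph)),
         graph = graph, nr = nr, nc = nc)
  })
  r <- ncol(pre[[1]]$X)
  par0 <- if (is.null(init)) c(numeric(r), 0.5) else c(init$beta, init$lambda)
  opt <- optim(par0,
               fn = function(p) mpl_objective(p, pre, cod, centred)$value,
               gr = function(p) mpl_objective(p, pre, cod, centred)$gradient,
               method = "L-BFGS-B",
               lower = c(rep(-Inf, r), 0), upper = c(rep(Inf, r), lambda_max),
               control = list(maxit = 500, factr = 1e4, pgtol = 1e-8))
  if (opt$convergence != 0) {
    warning(sprintf("MPL optimisation did not converge (%s)", opt$message))
  }
  model <- autologistic_model(opt$par[seq_len(r)], opt$par[r + 1],
                              coding = cod, centred = centred,
                              columns = colnames(pre[[1]]$X))
  structure(list(model = model, logPL = -opt$value,
                 converged = opt$convergence == 0,
                 iterations = opt$counts[["function"]],
                 message = opt$message),
            class = "al_mpl_fit")
}

#' Plug-in selection of the spatial association parameter
#'
#' Stage 2 of the two-stage estimator: with the stage-1 regression
#' coefficients held fixed, each candidate lambda is evaluated by
#' predicting marginal probabilities on every validation image (Gibbs
#' sampling) and scoring either the overall misclassification rate at the
#' cutoff, or the Bernoulli deviance of the marginals. The minimiser is
#' returned; ties break toward the smallest lambda. Per-image Gibbs seeds
#' are derived from the master seed and the image index only, so all
#' lambdas (and model variants) see common random numbers.
#'
#' @param beta fixed stage-1 coefficients (model scale).
#' @param grid candidate lambda values (include 0; ascending recommended).
#' @param scenes validation scenes.
#' @param x_builder function(scene) -> design matrix.
#' @param coding,centred model variant being tuned.
#' @param criterion \code{"error"} (default) or \code{"deviance"}.
#' @param cutoff classification cutoff for the error criterion.
#' @param cfg an \code{al_gibbs_config}.
#' @param seed master seed.
#' @return list of class \code{"al_lambda_search"}: \code{lambda} (grid),
#'   \code{criterion} (values), \code{best} (selected lambda),
#'   \code{criterion_name}.
#' @export
tune_lambda_plugin <- function(beta, grid, scenes, x_builder,
                               coding = "pm1", centred = FALSE,
                               criterion = c("error", "deviance"),
                               cutoff = 0.5, cfg = gibbs_config(), seed = 1L) {
  criterion <- match.arg(criterion)
  if (length(grid) < 1) stop("lambda grid must be non-empty")
  cod <- coding(coding)
  pre <- lapply(scenes, function(sc) {
    list(X = x_builder(sc), fg = sc$foreground,
         graph = build_lattice(nrow(sc$foreground), ncol(sc$foreground)))
  })
  crit <- numeric(length(grid))
  for (li in seq_along(grid)) {
    model <- autologistic_model(beta, grid[li], coding = cod,
                                centred = centred)
    bad <- 0; tot <- 0; dev <- 0
    for (si in seq_along(pre)) {
      set.seed(derive_seed(seed, 31L * si))
      p <- gibbs_marginals(model, pre[[si]]$X, pre[[si]]$graph, cfg)
      if (criterion == "error") {
        predicted_high <- p > cutoff
        bad <- bad + sum(predicted_high != pre[[si]]$fg)
        tot <- tot + length(p)
      } else {
        dev <- dev + deviance_binary(pre[[si]]$fg, p)
      }
    }
    crit[li] <- if (criterion == "error") bad / tot else dev
  }
  best <- min(grid[crit == min(crit)])
  structure(list(lambda = grid, criterion = crit, best = best,
                 criterion_name = criterion),
            class = "al_lambda_search")
}

#' @export
print.al_lambda_search <- function(x, ...) {
  cat(sprintf("<lambda search (%s): best lambda = %g (criterion %.6g)>\n",
              x$criterion_name, x$best, min(x$criterion)))
  invisible(x)
}
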