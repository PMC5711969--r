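#' Gibbs sampler settings
#'
#' @param burnin discarded sweeps (>= 0). Default 200.
#' @param retained averaged sweeps (>= 1). Default 500.
#' @param scan \code{"checkerboard"} (vectorisable two-colour scheme, valid
#'   because the 4-neighbour lattice is bipartite) or \code{"raster"}.
#' @param rao_blackwell if TRUE (default) estimate each marginal as the mean
#'   of the pixel's conditional probability at its update times, rather than
#'   the mean of sampled indicators; lower variance.
#' @return list of class \code{"al_gibbs_config"}.
#' @export
gibbs_config <- function(burnin = 200, retained = 500,
                         scan = c("checkerboard", "raster"),
                         rao_blackwell = TRUE) {
  scan <- match.arg(scan)
  if (burnin < 0) stop("burnin must be >= 0")
  if (retained < 1) stop("retained sweeps must be >= 1")
  structure(list(burnin = as.integer(burnin), retained = as.integer(retained),
                 scan = scan, rao_blackwell = isTRUE(rao_blackwell)),
            class = "al_gibbs_config")
}

#' Marginal probabilities by Gibbs sampling
#'
#' Estimates the per-pixel marginal probability of the high class under the
#' fitted autologistic model by running a Gibbs sampler and averaging.
#' The chain is initialised with an independent draw from the lambda = 0
#' model. When \code{model$lambda == 0} the pixels are independent and the
#' closed form antilogit\{(H-L) X beta\} is returned exactly (this is also
#' what the Rao-Blackwellised average converges to trivially).
#'
#' Reproducibility: driven by R's RNG; call \code{set.seed()} first.
#'
#' @param model an \code{al_model}.
#' @param X design matrix (n pixels x r).
#' @param graph an \code{al_lattice}.
#' @param cfg an \code{al_gibbs_config}.
#' @return probability matrix, lattice-shaped.
#' @export
gibbs_marginals <- function(model, X, graph, cfg = gibbs_config()) {
  alpha <- unary_field(model, X, graph)
  cod <- model$coding
  if (model$lambda == 0) {
    return(antilogit(cod$span * alpha))
  }
  res <- gibbs_run_cpp(alpha, model$lambda, cod$low, cod$high,
                       cfg$burnin, cfg$retained,
                       cfg$scan == "checkerboard", cfg$rao_blackwell)
  res$marginal
}

#' Draw one realisation from the model
#'
#' Runs \code{sweeps} Gibbs sweeps from an independent initial draw and
#' returns the final state; used for simulating labelled data from a known
#' model (e.g. parameter-recovery studies).
#'
#' @inheritParams gibbs_marginals
#' @param sweeps number of sweeps (>= 1).
#' @param scan sweep scheme.
#' @return coded binary field matrix.
#' @export
gibbs_sample <- function(model, X, graph, sweeps = 500,
                         scan = c("checkerboard", "raster")) {
  scan <- match.arg(scan)
  alpha <- unary_field(model, X, graph)
  cod <- model$coding
  res <- gibbs_run_cpp(alpha, model$lambda, cod$low, cod$high,
                       as.integer(sweeps), 1L, scan == "checkerboard", TRUE)
  res$state
}

#' Threshold a probability map into classes
#'
#' A pixel is assigned the high class iff its probability strictly exceeds
#' the cutoff; ties (p == c) go to the low class.
#'
#' @param p probability matrix.
#' @param c cutoff in (0,1); 0.5 by default.
#' @param coding output coding.
#' @return coded binary field matrix.
#' @export
classify <- function(p, c = 0.5, coding = "pm1") {
  if (length(c) != 1L || !is.finite(c) || c <= 0 || c >= 1) {
    stop("cutoff must lie strictly inside (0,1)")
  }
  encode_field(p > c, coding)
}

#' Confusion counts and error rates
#'
#' Compares a predicted field with the truth (same coding), treating the
#' high class as positive.
#'
#' @param pred,truth coded binary fields of identical shape.
#' @param coding their coding.
#' @return list of class \code{"al_confusion"} with counts \code{tp},
#'   \code{fp}, \code{fn}, \code{tn} and rates \code{error_high} (share of
#'   true-high pixels misclassified), \code{error_low}, \code{error_overall}.
#' @export
confusion <- function(pred, truth, coding = "pm1") {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  cod <- coding(coding)
  ph <- pred == cod$high; th <- truth == cod$high
  tp <- sum(ph & th); fp <- sum(ph & !th)
  fn <- sum(!ph & th); tn <- sum(!ph & !th)
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         error_high = if (tp + fn > 0) fn / (tp + fn) else NA_real_,
         error_low = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
         error_overall = (fp + fn) / (tp + fp + fn + tn)),
    class = "al_confusion"
  )
}

#' @export
print.al_confusion <- function(x, ...) {
  cat(sprintf(
    "<confusion: overall %.2f%%, high-class %.2f%%, low-class %.2f%%>\n",
    100 * x$error_overall, 100 * x$error_high, 100 * x$error_low))
  invisible(x)
}
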