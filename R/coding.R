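#' Binary class codings
#'
#' The two pixel classes are mapped to numeric values \eqn{\{L, H\}} ("low"
#' and "high"). Two named codings are supported: \code{"01"} with
#' \eqn{(L,H) = (0,1)}, and \code{"pm1"} with \eqn{(L,H) = (-1,1)}. The
#' choice of coding is not a cosmetic relabelling: with the spatial
#' association parameter \eqn{\lambda > 0} the two codings define genuinely
#' different restricted models, and only the \code{"pm1"} coding makes the
#' neighbour term symmetric around zero.
#'
#' @param name \code{"pm1"} or \code{"01"}, or an existing coding object
#'   (returned unchanged).
#' @return An object of class \code{"al_coding"} with fields \code{low},
#'   \code{high}, \code{span} (= high - low) and \code{name}.
#' @examples
#' coding("pm1")$span  # 2
#' coding("01")$high   # 1
#' @export
coding <- function(name = c("pm1", "01")) {
  if (inherits(name, "al_coding")) return(name)
  name <- match.arg(name)
  lh <- switch(name, "pm1" = c(-1, 1), "01" = c(0, 1))
  structure(
    list(low = lh[1], high = lh[2], span = lh[2] - lh[1], name = name),
    class = "al_coding"
  )
}

#' @export
print.al_coding <- function(x, ...) {
  cat(sprintf("<coding {%g,%g}>\n", x$low, x$high))
  invisible(x)
}

#' Numerically stable inverse logit
#'
#' @param x numeric vector/matrix of log-odds.
#' @return values of \eqn{1/(1+e^{-x})}; saturates to 0/1 without NaN for
#'   extreme inputs.
#' @export
antilogit <- function(x) plogis(x)

#' Map a foreground indicator to coded values
#'
#' @param ind logical or 0/1 matrix/vector (TRUE / 1 = high class).
#' @param cod target coding.
#' @return numeric field with values in \{low, high\}, same shape.
#' @export
encode_field <- function(ind, cod) {
  cod <- coding(cod)
  out <- ifelse(ind > 0, cod$high, cod$low)
  if (is.matrix(ind)) dim(out) <- dim(ind)
  out
}

# Validate that a field only contains the coding's two values.
check_field <- function(z, cod) {
  cod <- coding(cod)
  if (!all(z == cod$low | z == cod$high)) {
    stop(sprintf("binary field contains values outside {%g,%g}",
                 cod$low, cod$high))
  }
  invisible(z)
}
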