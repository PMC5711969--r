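#' Ellipse generator settings
#'
#' Controls the random elliptical foreground regions of simulated scenes.
#' Each ellipse is drawn as: first focus uniform on the unit square; second
#' focus displaced from it in a uniform direction by a U(0, max_focus_sep)
#' distance (redrawn until it lands inside the unit square); major-axis
#' length 2a equal to the inter-focus distance plus a U(slack) margin, so
#' every ellipse is valid (2a >= inter-focus distance).
#'
#' @param n number of ellipses per scene (default 25).
#' @param max_focus_sep upper bound of the inter-focus distance (default 0.2).
#' @param axis_slack length-2 range of the major-axis slack added to the
#'   focal distance (default c(0.02, 0.2)).
#' @return list of class \code{"al_ellipse_params"}.
#' @export
ellipse_params <- function(n = 25, max_focus_sep = 0.2,
                           axis_slack = c(0.02, 0.2)) {
  if (n < 0) stop("ellipse count must be >= 0")
  stopifnot(max_focus_sep > 0, length(axis_slack) == 2, all(axis_slack >= 0))
  structure(list(n = as.integer(n), max_focus_sep = max_focus_sep,
                 axis_slack = sort(axis_slack)),
            class = "al_ellipse_params")
}

#' Draw random ellipses in the unit square
#'
#' @param params an \code{al_ellipse_params}.
#' @return data frame with one row per ellipse: focus coordinates
#'   \code{f1x, f1y, f2x, f2y} and major-axis length \code{major} (= 2a).
#'   Uses R's RNG; seed upstream.
#' @export
sample_ellipses <- function(params = ellipse_params()) {
  n <- params$n
  out <- data.frame(f1x = numeric(n), f1y = numeric(n),
                    f2x = numeric(n), f2y = numeric(n), major = numeric(n))
  for (i in seq_len(n)) {
    f1 <- runif(2)
    repeat {
      ang <- runif(1, 0, 2 * pi)
      len <- runif(1, 0, params$max_focus_sep)
      f2 <- f1 + len * c(cos(ang), sin(ang))
      if (all(f2 >= 0 & f2 <= 1)) break
    }
    d <- sqrt(sum((f2 - f1)^2))
    out[i, ] <- c(f1, f2, d + runif(1, params$axis_slack[1],
                                    params$axis_slack[2]))
  }
  out
}

#' Rasterise an ellipse union onto the pixel grid
#'
#' The image is mapped onto the unit square; a pixel (centre coordinates)
#' is foreground iff the sum of its distances to the two foci is at most
#' the major-axis length, for at least one ellipse.
#'
#' @param ellipses data frame from \code{sample_ellipses}.
#' @param n_rows,n_cols raster dimensions.
#' @return logical matrix, TRUE = foreground.
#' @export
rasterize_foreground <- function(ellipses, n_rows, n_cols) {
  px <- (col(matrix(0, n_rows, n_cols)) - 0.5) / n_cols
  py <- (row(matrix(0, n_rows, n_cols)) - 0.5) / n_rows
  fg <- matrix(FALSE, n_rows, n_cols)
  for (i in seq_len(nrow(ellipses))) {
    e <- ellipses[i, ]
    d <- sqrt((px - e$f1x)^2 + (py - e$f1y)^2) +
         sqrt((px - e$f2x)^2 + (py - e$f2y)^2)
    fg <- fg | (d <= e$major)
  }
  fg
}

#' Gaussian Markov random field texture settings
#'
#' The class texture model: per channel, a constant (the class mean on the
#' [0,1] intensity scale, applied through the logit link) plus a zero-mean
#' stationary GMRF on the pixel lattice with a 3x3 (8-neighbour)
#' neighbourhood. The precision stencil has 1 at the centre and
#' \code{-dependence} at each of the 8 neighbours; stability on the torus
#' requires dependence < 1/8. \code{dependence} may be given as a fraction
#' via \code{dependence_frac} (of the stability bound); the default gives
#' strong, long-range spatial correlation.
#'
#' The texture is treated as a fixed continuous-scene field observed at the
#' image resolution: unless a raw \code{dependence} is supplied, the
#' effective stencil coefficient at an n x n image approaches the stability
#' bound as n grows, such that the correlation length stays constant in
#' unit-square (scene) coordinates. \code{dependence_frac} states the
#' fraction of the bound at the reference resolution \code{ref_size}
#' (default: 0.9 at 100 x 100); at other resolutions the distance to the
#' bound scales with (ref_size^2 / n_pixels). This keeps the classification
#' task equally hard at every image size.
#'
#' @param mean per-channel class means on the [0,1] scale.
#' @param sd marginal standard deviation of the field (logit scale), > 0.
#'   Default 1.2 (see the methods vignette for the calibration).
#' @param dependence raw stencil coefficient, in [0, 1/8); when given it is
#'   used verbatim at every size (no resolution scaling).
#' @param dependence_frac fraction of the stability bound 1/8 at the
#'   reference resolution (default 0.99).
#' @param ref_size reference side length for \code{dependence_frac}
#'   (default 100).
#' @return list of class \code{"al_gmrf_spec"}.
#' @export
gmrf_spec <- function(mean, sd = 1.2, dependence = NULL,
                      dependence_frac = 0.99, ref_size = 100) {
  if (!is.null(dependence) && (dependence < 0 || dependence >= 1 / 8)) {
    stop("dependence must lie in [0, 1/8) for a valid 3x3 stencil")
  }
  if (dependence_frac < 0 || dependence_frac >= 1) {
    stop("dependence_frac must lie in [0, 1)")
  }
  if (sd <= 0) stop("sd must be > 0")
  if (any(mean <= 0 | mean >= 1)) stop("class means must lie in (0,1)")
  structure(list(mean = mean, sd = sd, dependence = dependence,
                 dependence_frac = dependence_frac, ref_size = ref_size),
            class = "al_gmrf_spec")
}

# Effective stencil coefficient at a given lattice size.
gmrf_dependence <- function(spec, n_rows, n_cols) {
  if (!is.null(spec$dependence)) return(spec$dependence)
  frac <- 1 - (1 - spec$dependence_frac) * spec$ref_size^2 / (n_rows * n_cols)
  max(frac, 0) / 8
}

# Spectrum (circulant eigenvalues of the precision) on an nr x nc torus:
# Lambda(w) = 1 - 2 dep [cos w1 + cos w2 + 2 cos w1 cos w2].
gmrf_spectrum <- function(n_rows, n_cols, dependence) {
  w1 <- 2 * pi * (seq_len(n_rows) - 1) / n_rows
  w2 <- 2 * pi * (seq_len(n_cols) - 1) / n_cols
  c1 <- cos(w1); c2 <- cos(w2)
  lam <- 1 - 2 * dependence *
    (outer(c1, rep(1, n_cols)) + outer(rep(1, n_rows), c2) +
       2 * outer(c1, c2))
  if (any(lam <= 0)) stop("precision spectrum not positive; dependence too large")
  lam
}

#' Sample a zero-mean GMRF on the torus
#'
#' Exact stationary sampling by spectral (FFT) filtering of white noise:
#' the field is the circular convolution of i.i.d. N(0,1) noise with the
#' real symmetric filter whose squared transfer function is the inverse
#' precision spectrum, then scaled analytically so the marginal variance
#' equals \code{spec$sd^2}. Fields are torus-stationary; crop or use as-is.
#'
#' @param n_rows,n_cols field dimensions.
#' @param spec an \code{al_gmrf_spec} (only \code{sd} and \code{dependence}
#'   are used; the class mean is applied by \code{compose_scene}).
#' @return numeric matrix. Uses R's RNG; seed upstream.
#' @export
sample_gmrf <- function(n_rows, n_cols, spec) {
  dep <- gmrf_dependence(spec, n_rows, n_cols)
  s <- 1 / gmrf_spectrum(n_rows, n_cols, dep)  # covariance spectrum
  e <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  f <- Re(fft(sqrt(s) * fft(e), inverse = TRUE)) / (n_rows * n_cols)
  # stationary marginal variance of f is mean(s); rescale to sd^2
  f * (spec$sd / sqrt(mean(s)))
}

# Dense covariance of the sampled field on a small torus (test oracle):
# circulant with eigenvalue field s, scaled as in sample_gmrf.
gmrf_exact_covariance <- function(n_rows, n_cols, spec) {
  n <- n_rows * n_cols
  if (n > 400) stop("dense covariance oracle limited to small lattices")
  s <- 1 / gmrf_spectrum(n_rows, n_cols, gmrf_dependence(spec, n_rows, n_cols))
  scale2 <- spec$sd^2 / mean(s)
  # first column of the circulant covariance = ifft of eigenvalues
  base <- Re(fft(s, inverse = TRUE)) / n
  sig <- matrix(0, n, n)
  rows <- (seq_len(n_rows) - 1); cols <- (seq_len(n_cols) - 1)
  for (i in seq_len(n)) {
    ri <- (i - 1) %% n_rows; ci <- (i - 1) %/% n_rows
    dr <- ((rows - ri) %% n_rows) + 1
    dc <- ((cols - ci) %% n_cols) + 1
    sig[i, ] <- as.vector(base[dr, dc])
  }
  sig * scale2
}

#' Compose a two-class multi-band scene
#'
#' For each channel, two independent GMRF draws are made (background and
#' foreground); the pixel intensity is antilogit(logit(class mean) + field),
#' so all values lie strictly inside (0,1), and each pixel takes the draw of
#' its true class.
#'
#' @param mask logical foreground matrix.
#' @param bg,fg \code{al_gmrf_spec}s for the two classes (channel counts
#'   must match).
#' @return numeric array n_rows x n_cols x channels.
#' @export
compose_scene <- function(mask, bg, fg) {
  k <- length(bg$mean)
  if (length(fg$mean) != k) stop("class specs disagree on channel count")
  nr <- nrow(mask); nc <- ncol(mask)
  img <- array(0, c(nr, nc, k))
  for (ch in seq_len(k)) {
    vb <- antilogit(qlogis(bg$mean[ch]) + sample_gmrf(nr, nc, bg))
    vf <- antilogit(qlogis(fg$mean[ch]) + sample_gmrf(nr, nc, fg))
    img[, , ch] <- ifelse(mask, vf, vb)
  }
  img
}

#' Default class textures for simulated RGB scenes
#'
#' Background mean colour (0.75, 0.65, 0.55) (reddish/yellowish), foreground
#' (0.6, 0.5, 0.7) (bluish/purple); both with marginal sd 1.2 on the logit
#' scale and resolution-scaled dependence (0.99 of the stability bound at
#' 100 x 100). The classes overlap substantially, making the segmentation
#' task deliberately hard; the noise scale was calibrated once so the
#' plug-in pipeline's test error at 100 x 100 falls in the published
#' 18-21% regime (see the methods vignette).
#'
#' @name default_scene_specs
#' @export
default_background_spec <- function() gmrf_spec(c(0.75, 0.65, 0.55))

#' @rdname default_scene_specs
#' @export
default_foreground_spec <- function() gmrf_spec(c(0.6, 0.5, 0.7))

# Deterministic per-scene seed derived from a master seed (kept < 2^31).
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 1e6) * 2011 + 104729 * i) %% 2147483629L
}

#' Generate a labelled scene set
#'
#' Draws \code{n} independent scenes of one size with known truth masks and
#' assigns image-level train/validation/test split tags. Each scene's RNG
#' seed is derived deterministically from the master seed, so regeneration
#' is bit-identical and independent of execution order.
#'
#' @param size scene side length in pixels (square scenes).
#' @param n number of scenes (default 90).
#' @param split named integer vector (train, validation, test) summing to n;
#'   default equal thirds.
#' @param ellipses an \code{al_ellipse_params}.
#' @param bg,fg class texture specs.
#' @param seed master seed (integer).
#' @return object of class \code{"al_scene_set"}: list of scenes (each with
#'   \code{image}, \code{foreground} logical mask, \code{split}, \code{seed},
#'   \code{id}) plus the generation parameters.
#' @export
generate_scenes <- function(size, n = 90,
                            split = c(train = n %/% 3, validation = n %/% 3,
                                      test = n - 2 * (n %/% 3)),
                            ellipses = ellipse_params(),
                            bg = default_background_spec(),
                            fg = default_foreground_spec(),
                            seed = 1L) {
  if (sum(split) != n) stop("split counts must sum to n")
  tags <- rep(c("train", "validation", "test"),
              times = c(split[["train"]], split[["validation"]],
                        split[["test"]]))
  scenes <- vector("list", n)
  for (i in seq_len(n)) {
    si <- derive_seed(seed, i)
    set.seed(si)
    ell <- sample_ellipses(ellipses)
    mask <- rasterize_foreground(ell, size, size)
    img <- compose_scene(mask, bg, fg)
    scenes[[i]] <- list(image = img, foreground = mask, split = tags[i],
                        seed = si, id = sprintf("scene_%04d", i))
  }
  structure(list(scenes = scenes, size = size, seed = seed,
                 params = list(ellipses = ellipses, bg = bg, fg = fg)),
            class = "al_scene_set")
}

#' Generate suites at several sizes
#'
#' @param sizes vector of side lengths.
#' @param ... passed to \code{generate_scenes}; per-size seeds are offset
#'   from \code{seed} so suites are independent.
#' @param seed master seed.
#' @return named list of \code{al_scene_set}, one per size.
#' @export
generate_suite <- function(sizes, ..., seed = 1L) {
  out <- lapply(seq_along(sizes), function(k) {
    generate_scenes(sizes[k], ..., seed = derive_seed(seed, 7000 + k))
  })
  names(out) <- as.character(sizes)
  out
}

#' @export
print.al_scene_set <- function(x, ...) {
  tab <- table(vapply(x$scenes, `[[`, "", "split"))
  cat(sprintf("<scene set: %d scenes of %dx%d [%s]>\n",
              length(x$scenes), x$size, x$size,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Subset a scene set by split tag
#'
#' @param scene_set an \code{al_scene_set}.
#' @param split \code{"train"}, \code{"validation"} or \code{"test"}.
#' @return list of scenes.
#' @export
scenes_split <- function(scene_set, split) {
  split <- match.arg(split, c("train", "validation", "test"))
  out <- Filter(function(s) s$split == split, scene_set$scenes)
  if (length(out) == 0) stop(sprintf("scene set has no '%s' split", split))
  out
}
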