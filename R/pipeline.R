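#' Design builder for scene images
#'
#' Returns a function(scene) -> design matrix, for use by the estimation
#' and prediction steps. The default uses the raw band values of the image
#' stack (plus intercept); supplying a basis gives the piecewise-linear
#' additive expansion.
#'
#' @param terms term set (default the three RGB main effects).
#' @param basis optional \code{al_tri_basis}.
#' @param intercept include an intercept (default TRUE).
#' @return function taking a scene (list with \code{image}) or a bare image
#'   array and returning the design matrix.
#' @export
design_builder <- function(terms = c("1", "2", "3"), basis = NULL,
                           intercept = TRUE) {
  force(terms); force(basis); force(intercept)
  function(scene) {
    img <- if (is.list(scene)) scene$image else scene
    build_design(img, terms, basis = basis, intercept = intercept)
  }
}

#' Evaluate a fitted model on a set of scenes
#'
#' Predicts marginal probabilities for every scene (Gibbs sampling, or the
#' closed form when lambda = 0), thresholds at the cutoff, and tabulates
#' confusion counts per scene and pooled. Per-scene seeds derive from the
#' master seed and scene index.
#'
#' @param model an \code{al_model}.
#' @param scenes list of scenes with truth masks.
#' @param x_builder function(scene) -> design matrix.
#' @param cutoff classification cutoff (default 0.5).
#' @param cfg an \code{al_gibbs_config}.
#' @param seed master seed.
#' @return list: \code{pooled} (\code{al_confusion}), \code{per_scene}
#'   (data frame of per-image error rates), \code{deviance} (pooled
#'   marginal deviance).
#' @export
evaluate_model <- function(model, scenes, x_builder, cutoff = 0.5,
                           cfg = gibbs_config(), seed = 1L) {
  tp <- fp <- fn <- tn <- 0
  dev <- 0
  rows <- vector("list", length(scenes))
  for (si in seq_along(scenes)) {
    sc <- scenes[[si]]
    graph <- build_lattice(nrow(sc$foreground), ncol(sc$foreground))
    set.seed(derive_seed(seed, 31L * si))
    p <- gibbs_marginals(model, x_builder(sc), graph, cfg)
    pred <- classify(p, cutoff, model$coding)
    truth <- encode_field(sc$foreground, model$coding)
    cm <- confusion(pred, truth, model$coding)
    tp <- tp + cm$tp; fp <- fp + cm$fp; fn <- fn + cm$fn; tn <- tn + cm$tn
    dev <- dev + deviance_binary(sc$foreground, p)
    rows[[si]] <- data.frame(scene = sc$id, overall = cm$error_overall,
                             high = cm$error_high, low = cm$error_low)
  }
  pooled <- structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         error_high = if (tp + fn > 0) fn / (tp + fn) else NA_real_,
         error_low = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
         error_overall = (fp + fn) / (tp + fp + fn + tn)),
    class = "al_confusion")
  list(pooled = pooled, per_scene = do.call(rbind, rows), deviance = dev)
}

#' Two-stage plug-in classifier construction
#'
#' The full training flow: draw a balanced pixel sample from the training
#' images, fit the independence logistic regression, hold its coefficients
#' fixed and choose the spatial association lambda on the validation
#' images, then evaluate the final autologistic classifier on the test
#' images (which are untouched until this last step).
#'
#' @param scene_set an \code{al_scene_set} with all three splits.
#' @param x_builder function(scene) -> design matrix (default: raw RGB
#'   bands + intercept).
#' @param n_sample training/validation pixel sample size (default 1e5).
#' @param high_fraction foreground share of the sample (default 0.5).
#' @param coding model coding (default \code{"pm1"}; the plug-in shortcut
#'   is only effective in this coding).
#' @param centred centred variant? (default FALSE).
#' @param lambda_grid candidate lambdas (default 0, 0.05, ..., 2).
#' @param criterion stage-2 selection criterion, \code{"error"} or
#'   \code{"deviance"}.
#' @param cutoff classification cutoff.
#' @param cfg an \code{al_gibbs_config}.
#' @param seed master seed for sampling, tuning and evaluation.
#' @param evaluate_test evaluate on the test split (default TRUE).
#' @return list of class \code{"al_two_stage"}: \code{stage1}
#'   (\code{al_logistic_fit}), \code{search} (\code{al_lambda_search}),
#'   \code{model} (final \code{al_model}), \code{test} (evaluation, or
#'   NULL), \code{config}.
#' @export
run_two_stage <- function(scene_set, x_builder = design_builder(),
                          n_sample = 1e5, high_fraction = 0.5,
                          coding = "pm1", centred = FALSE,
                          lambda_grid = seq(0, 2, by = 0.05),
                          criterion = c("error", "deviance"), cutoff = 0.5,
                          cfg = gibbs_config(), seed = 1L,
                          evaluate_test = TRUE) {
  criterion <- match.arg(criterion)
  cod <- coding(coding)
  samp <- sample_pixels(scene_set, "train", n_sample, high_fraction,
                        seed = derive_seed(seed, 1L))
  design <- x_builder(samp$bands)
  stage1 <- fit_logistic(design, samp$high, coding = cod)
  search <- tune_lambda_plugin(stage1$beta, lambda_grid,
                               scenes_split(scene_set, "validation"),
                               x_builder, coding = cod, centred = centred,
                               criterion = criterion, cutoff = cutoff,
                               cfg = cfg, seed = derive_seed(seed, 2L))
  model <- autologistic_model(stage1$beta, search$best, coding = cod,
                              centred = centred, columns = stage1$columns)
  test <- NULL
  if (evaluate_test) {
    test <- evaluate_model(model, scenes_split(scene_set, "test"), x_builder,
                           cutoff = cutoff, cfg = cfg,
                           seed = derive_seed(seed, 3L))
  }
  structure(list(stage1 = stage1, search = search, model = model,
                 test = test,
                 config = list(n_sample = n_sample,
                               high_fraction = high_fraction,
                               coding = cod$name, centred = centred,
                               lambda_grid = lambda_grid,
                               criterion = criterion, cutoff = cutoff,
                               gibbs = unclass(cfg), seed = seed)),
            class = "al_two_stage")
}

#' @export
print.al_two_stage <- function(x, ...) {
  cat("<two-stage autologistic fit>\n")
  print(x$model)
  print(x$search)
  if (!is.null(x$test)) {
    cat("test: "); print(x$test$pooled)
  }
  invisible(x)
}

#' Plug-in vs MPL comparison across image sizes
#'
#' For each size: generate (or reuse) a scene suite, build the plug-in
#' classifier, fit the same model by maximum pseudolikelihood on the
#' training images (initialised at the stage-1 fit), and evaluate both on
#' the test images. The stage-2 criterion is the overall validation error
#' at the cutoff (the package default), and all coefficients are reported
#' on the {-1,1} coding scale.
#'
#' @param sizes image side lengths (default c(100, 200)).
#' @param n_per_size scenes per size (default 90).
#' @param split named split counts.
#' @param suite optional pre-generated named list of scene sets (as from
#'   \code{generate_suite}); generated when NULL.
#' @param n_sample stage-1 pixel sample size.
#' @param lambda_grid candidate lambdas.
#' @param cfg an \code{al_gibbs_config}.
#' @param seed master seed.
#' @return data frame with one plug-in and one MPL row per size: size,
#'   method, intercept, R, G, B coefficients, lambda, test error (%).
#' @export
run_size_comparison <- function(sizes = c(100, 200), n_per_size = 90,
                       split = c(train = n_per_size %/% 3,
                                 validation = n_per_size %/% 3,
                                 test = n_per_size - 2 * (n_per_size %/% 3)),
                       suite = NULL, n_sample = 1e5,
                       lambda_grid = seq(0, 2, by = 0.05),
                       cfg = gibbs_config(), seed = 1L) {
  if (is.null(suite)) {
    suite <- generate_suite(sizes, n = n_per_size, split = split, seed = seed)
  }
  xb <- design_builder()
  rows <- list()
  for (sz in names(suite)) {
    ss <- suite[[sz]]
    ts <- run_two_stage(ss, x_builder = xb, n_sample = n_sample,
                        lambda_grid = lambda_grid, criterion = "error",
                        cfg = cfg, seed = derive_seed(seed, 11L))
    mpl <- fit_mpl(scenes_split(ss, "train"), xb,
                   init = list(beta = ts$stage1$beta, lambda = 0.5))
    ev_mpl <- evaluate_model(mpl$model, scenes_split(ss, "test"), xb,
                             cfg = cfg, seed = derive_seed(seed, 3L))
    mk <- function(method, beta, lambda, err) {
      data.frame(size = as.integer(sz), method = method,
                 intercept = beta[1], R = beta[2], G = beta[3], B = beta[4],
                 lambda = lambda, error_pct = 100 * err)
    }
    rows[[length(rows) + 1]] <- mk("plug-in", ts$model$beta,
                                   ts$model$lambda,
                                   ts$test$pooled$error_overall)
    rows[[length(rows) + 1]] <- mk("MPL", mpl$model$beta, mpl$model$lambda,
                                   ev_mpl$pooled$error_overall)
  }
  do.call(rbind, rows)
}

#' Prediction error versus lambda for the four model variants
#'
#' With the stage-1 coefficients shared by all variants, sweeps lambda and
#' records the pooled test error of the standard and centred models under
#' both codings. Lambda is parameterised on the {-1,1} scale; for the
#' {0,1}-coded variants the equivalent pairwise value 4*lambda is used, and
#' the {0,1} coefficients are the logit-scale b (i.e. 2x the {-1,1} beta),
#' so all variants produce identical fitted probabilities at lambda = 0.
#' Common per-image random numbers are used across variants and lambdas.
#'
#' @param scene_set an \code{al_scene_set}.
#' @param lambda_grid lambdas on the {-1,1} scale.
#' @param n_sample stage-1 pixel sample size.
#' @param cfg an \code{al_gibbs_config}.
#' @param seed master seed.
#' @return data frame: lambda_pm, variant, error (proportion).
#' @export
run_variant_curves <- function(scene_set, lambda_grid = seq(0, 0.5, by = 0.05),
                     n_sample = 1e5, cfg = gibbs_config(), seed = 1L) {
  xb <- design_builder()
  samp <- sample_pixels(scene_set, "train", n_sample, 0.5,
                        seed = derive_seed(seed, 1L))
  design <- build_design(samp$bands, c("1", "2", "3"))
  fitpm <- fit_logistic(design, samp$high, coding = "pm1")
  beta_pm <- fitpm$beta        # b / 2
  beta_01 <- fitpm$b           # b
  test <- scenes_split(scene_set, "test")
  variants <- list(
    list(name = "standard_pm1", coding = "pm1", centred = FALSE,
         beta = beta_pm, lmul = 1),
    list(name = "standard_01", coding = "01", centred = FALSE,
         beta = beta_01, lmul = 4),
    list(name = "centred_pm1", coding = "pm1", centred = TRUE,
         beta = beta_pm, lmul = 1),
    list(name = "centred_01", coding = "01", centred = TRUE,
         beta = beta_01, lmul = 4)
  )
  rows <- list()
  for (v in variants) {
    for (lam in lambda_grid) {
      model <- autologistic_model(v$beta, lam * v$lmul, coding = v$coding,
                                  centred = v$centred)
      ev <- evaluate_model(model, test, xb, cfg = cfg,
                           seed = derive_seed(seed, 5L))
      rows[[length(rows) + 1]] <- data.frame(
        lambda_pm = lam, variant = v$name,
        error = ev$pooled$error_overall)
    }
  }
  do.call(rbind, rows)
}

#' Write / read a scene set as plain-text files
#'
#' Each scene is stored as a tab-separated table (row, col, mask, one
#' column per band at full precision) plus a JSON manifest holding sizes,
#' splits, seeds and generator parameters. Masks round-trip exactly; band
#' values round-trip to double precision.
#'
#' @param scene_set an \code{al_scene_set}.
#' @param dir directory (created if needed).
#' @return \code{read_scene_set} returns the restored \code{al_scene_set}.
#' @export
write_scene_set <- function(scene_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(size = scene_set$size, seed = scene_set$seed,
                   params = list(
                     ellipses = unclass(scene_set$params$ellipses),
                     bg = unclass(scene_set$params$bg),
                     fg = unclass(scene_set$params$fg)),
                   scenes = lapply(scene_set$scenes, function(s) {
                     list(id = s$id, split = s$split, seed = s$seed)
                   }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (s in scene_set$scenes) {
    nr <- nrow(s$foreground); nc <- ncol(s$foreground)
    k <- dim(s$image)[3]
    df <- data.frame(row = as.vector(row(s$foreground)),
                     col = as.vector(col(s$foreground)),
                     mask = as.integer(as.vector(s$foreground)))
    for (ch in seq_len(k)) {
      df[[sprintf("band%d", ch)]] <- as.vector(s$image[, , ch])
    }
    utils::write.table(format(df, digits = 17, scientific = TRUE,
                              trim = TRUE),
                       file.path(dir, paste0(s$id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_scene_set
#' @export
read_scene_set <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  scenes <- lapply(seq_len(nrow(manifest$scenes)), function(i) {
    info <- manifest$scenes[i, ]
    df <- utils::read.table(file.path(dir, paste0(info$id, ".tsv")),
                            header = TRUE, sep = "\t")
    nr <- max(df$row); nc <- max(df$col)
    bandcols <- grep("^band", names(df), value = TRUE)
    img <- array(0, c(nr, nc, length(bandcols)))
    ord <- order(df$col, df$row)  # column-major
    for (ch in seq_along(bandcols)) {
      img[, , ch] <- matrix(df[[bandcols[ch]]][ord], nr, nc)
    }
    mask <- matrix(df$mask[ord] > 0, nr, nc)
    list(image = img, foreground = mask, split = info$split,
         seed = info$seed, id = info$id)
  })
  structure(list(scenes = scenes, size = manifest$size,
                 seed = manifest$seed, params = manifest$params),
            class = "al_scene_set")
}

#' Write evaluation metrics as CSV
#'
#' One row per scene plus a pooled row, with the master seed embedded for
#' provenance.
#'
#' @param evaluation result of \code{evaluate_model}.
#' @param path output CSV path.
#' @param seed seed to record.
#' @export
write_metrics_csv <- function(evaluation, path, seed = NA) {
  df <- evaluation$per_scene
  df <- rbind(df, data.frame(scene = "POOLED",
                             overall = evaluation$pooled$error_overall,
                             high = evaluation$pooled$error_high,
                             low = evaluation$pooled$error_low))
  df$seed <- seed
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a lambda search curve as CSV
#'
#' @param search an \code{al_lambda_search}.
#' @param path output CSV path.
#' @export
write_search_csv <- function(search, path) {
  utils::write.csv(data.frame(lambda = search$lambda,
                              criterion = search$criterion), path,
                   row.names = FALSE)
  invisible(path)
}
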