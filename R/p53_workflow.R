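# Auto-adjusted p53 positivity quantification: a per-slide classifier is
# trained on the slide's own positive and negative control nuclei (on-slide
# serous-carcinoma / lymph-node controls in routine practice) and applied to
# the tumor nuclei, making the percent-positive readout self-normalizing
# against staining batch variation. Lin's concordance correlation benchmarks
# agreement with observers.

#' Build the per-slide control training set
#'
#' Segments both control tiles (deconvolution + Otsu), extracts nucleus
#' features, keeps only intensity and texture columns (positivity must not
#' depend on nuclear shape), and labels nuclei wholesale by tile of origin:
#' positive-control nuclei 1, negative-control nuclei 0.
#'
#' @param set A slide image set: list with `positive_control`,
#'   `negative_control` (each with an `image` element or a bare
#'   [stain_image()]) and `tumor_tiles`.
#' @param min_nuclei Minimum segmentable nuclei required per control.
#' @return A data.frame of intensity/texture features plus a `positive`
#'   label column.
#' @export
build_control_training_set <- function(set, min_nuclei = 20) {
  get_img <- function(x) if (inherits(x, "stain_image")) x else x$image
  feats_of <- function(tile, what) {
    img <- get_img(tile)
    # counterstained immunostain: every nucleus carries hematoxylin whether
    # or not it carries DAB, so segment on the counterstain channel
    mask <- segment_deconv_otsu(img, target = "H")
    tab <- extract_nucleus_features(img, mask)
    if (nrow(tab) < min_nuclei) {
      stop("insufficient control material: ", nrow(tab), " nuclei in the ",
           what, " control (need >= ", min_nuclei, ")")
    }
    tab
  }
  pos <- feats_of(set$positive_control, "positive")
  neg <- feats_of(set$negative_control, "negative")
  cols <- intersect(intensity_texture_columns(pos),
                    intensity_texture_columns(neg))
  out <- rbind(cbind(pos[, cols, drop = FALSE], positive = 1L),
               cbind(neg[, cols, drop = FALSE], positive = 0L))
  rownames(out) <- NULL
  out
}

#' Train the per-slide positive/negative nucleus classifier
#'
#' An ensemble-of-trees classifier on the control nuclei, with an 80/20
#' stratified internal split for the reported accuracy; the returned model is
#' refitted on all control nuclei.
#'
#' @param labeled A [build_control_training_set()] result.
#' @param seed Integer seed.
#' @return A list with `model` (randomForest), `accuracy` (held-out) and
#'   `feature_columns`.
#' @export
train_slide_classifier <- function(labeled, seed = 1) {
  y <- factor(labeled$positive, levels = c(0, 1))
  if (nlevels(droplevels(y)) < 2) stop("both control classes are required")
  x <- labeled[, setdiff(colnames(labeled), "positive"), drop = FALSE]
  set.seed(seed)
  test_idx <- unlist(lapply(split(seq_along(y), y), function(i) {
    sample(i, max(1L, round(0.2 * length(i))))
  }))
  fit <- randomForest::randomForest(x = x[-test_idx, , drop = FALSE],
                                    y = y[-test_idx])
  acc <- mean(stats::predict(fit, x[test_idx, , drop = FALSE]) == y[test_idx])
  set.seed(seed)
  full <- randomForest::randomForest(x = x, y = y)
  list(model = full, accuracy = acc, feature_columns = colnames(x))
}

#' Compute percent p53 positivity for a slide
#'
#' Tumor nuclei are pooled across the tumor tiles, classified by the
#' slide's own control-trained model, and the percentage of positive nuclei
#' among all nuclei reported.
#'
#' @param set Slide image set (see [build_control_training_set()]).
#' @param seed Integer seed.
#' @return A list of class `"positivity_result"`: `percent_positive`,
#'   `n_positive`, `n_total`, `control_model_accuracy`.
#' @export
compute_p53_positivity <- function(set, seed = 1) {
  labeled <- build_control_training_set(set)
  clf <- train_slide_classifier(labeled, seed = seed)
  get_img <- function(x) if (inherits(x, "stain_image")) x else x$image
  tabs <- lapply(set$tumor_tiles, function(tile) {
    img <- get_img(tile)
    mask <- segment_deconv_otsu(img, target = "H")
    extract_nucleus_features(img, mask)
  })
  tabs <- tabs[vapply(tabs, nrow, 1L) > 0L]
  if (!length(tabs)) stop("no tumor nuclei segmented")
  pooled <- do.call(rbind, lapply(tabs, function(t) {
    miss <- setdiff(clf$feature_columns, colnames(t))
    for (m in miss) t[[m]] <- 0
    t[, clf$feature_columns, drop = FALSE]
  }))
  pred <- stats::predict(clf$model, pooled)
  n_pos <- sum(pred == "1")
  n_tot <- nrow(pooled)
  structure(list(percent_positive = 100 * n_pos / n_tot,
                 n_positive = n_pos, n_total = n_tot,
                 control_model_accuracy = clf$accuracy),
            class = "positivity_result")
}

#' @export
print.positivity_result <- function(x, ...) {
  cat(sprintf("p53 positivity: %.1f%% (%d / %d nuclei; control model accuracy %.3f)\n",
              x$percent_positive, x$n_positive, x$n_total,
              x$control_model_accuracy))
  invisible(x)
}

#' Binarize a continuous p53 percentage
#'
#' The composite codeletion model converts the continuous percent-positive
#' scale to a binary call at an 80% threshold.
#'
#' @param percent Numeric percent-positive values in \[0, 100\].
#' @param threshold Cut point (default 80).
#' @return Integer vector of 0/1.
#' @export
binarize_p53 <- function(percent, threshold = 80) {
  as.integer(percent >= threshold)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between two continuous readings, penalizing both dispersion and
#' location shift:
#' \deqn{\rho_c = \frac{2\,\mathrm{cov}(x,y)}
#'   {\mathrm{var}(x)+\mathrm{var}(y)+(\bar x-\bar y)^2}}
#' with population (1/n) moments. The 95% CI uses the Fisher z
#' transformation with Lin's asymptotic variance.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return A list with `ccc` and `ci95` (length-2 vector).
#' @export
lin_ccc <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length")
  if (n < 3) stop("need at least 3 pairs")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (vx == 0 && vy == 0) stop("both vectors are constant")
  ccc <- 2 * sxy / (vx + vy + (mx - my)^2)
  if (abs(ccc) >= 1 - 1e-12) {
    return(list(ccc = ccc, ci95 = c(ccc, ccc)))
  }
  r <- if (vx > 0 && vy > 0) sxy / sqrt(vx * vy) else 0
  u <- (mx - my) / (vx * vy)^(1 / 4)
  z <- atanh(ccc)
  se_z <- if (abs(r) > 1e-12) {
    sqrt(((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
          2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
          ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2))
  } else {
    1 / sqrt(n - 3)
  }
  ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se_z)
  list(ccc = ccc, ci95 = ci)
}
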