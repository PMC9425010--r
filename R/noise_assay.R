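# Stain-colored image-noise assay: learn the (R -> G, R -> B) color manifold
# of the stain pixels, inject a stated percentage of color-consistent noise
# pixels, and trace segmentation robustness curves over a noise grid.

#' Fit a stain color model predicting G and B from R
#'
#' Support-vector regression (radial basis kernel, mirroring the assay's
#' design; `family = "linear"` substitutes a linear fit for speed) is trained
#' on the stain pixels so that injected noise pixels lie on the stain's color
#' manifold — purple for H&E, brown for DAB.
#'
#' @param img A [stain_image()].
#' @param stain_mask Label mask marking stain (nucleus) pixels; at least 100
#'   required.
#' @param seed Integer seed.
#' @param family `"svm"` (default) or `"linear"`.
#' @param max_pixels Training subsample cap (SVM cost control).
#' @return An object of class `"noise_color_model"` with `predict_gb(r)`
#'   returning a 2-column matrix of predicted G and B (clipped to
#'   \[0, 255\]), plus the observed `r_range` among stain pixels.
#' @export
fit_noise_color_model <- function(img, stain_mask, seed = 1,
                                  family = c("svm", "linear"),
                                  max_pixels = 2000) {
  stopifnot(inherits(img, "stain_image"))
  family <- match.arg(family)
  sel <- stain_mask > 0
  if (sum(sel) < 100) stop("need at least 100 stain pixels; have ", sum(sel))
  r <- img$pixels[, , 1][sel]
  g <- img$pixels[, , 2][sel]
  b <- img$pixels[, , 3][sel]
  set.seed(seed)
  if (length(r) > max_pixels) {
    i <- sample.int(length(r), max_pixels)
    r <- r[i]; g <- g[i]; b <- b[i]
  }
  if (family == "svm" && stats::sd(r) > .Machine$double.eps^0.5) {
    set.seed(seed)
    fit_g <- e1071::svm(x = matrix(r), y = g, type = "eps-regression",
                        kernel = "radial", cost = 10, gamma = 0.05)
    set.seed(seed)
    fit_b <- e1071::svm(x = matrix(r), y = b, type = "eps-regression",
                        kernel = "radial", cost = 10, gamma = 0.05)
    pred <- function(rr) {
      cbind(stats::predict(fit_g, matrix(rr)),
            stats::predict(fit_b, matrix(rr)))
    }
  } else if (stats::sd(r) > .Machine$double.eps^0.5) {
    fit_g <- stats::lm(g ~ r, data = data.frame(r = r, g = g))
    fit_b <- stats::lm(b ~ r, data = data.frame(r = r, b = b))
    pred <- function(rr) {
      nd <- data.frame(r = rr)
      cbind(stats::predict(fit_g, nd), stats::predict(fit_b, nd))
    }
  } else {
    mg <- mean(g); mb <- mean(b)
    pred <- function(rr) cbind(rep(mg, length(rr)), rep(mb, length(rr)))
  }
  structure(list(predict_gb = function(rr) {
    gb <- pred(rr)
    gb[gb < 0] <- 0; gb[gb > 255] <- 255
    gb
  }, r_range = range(r), stain_kind = img$stain_kind, family = family),
  class = "noise_color_model")
}

#' Inject stain-colored noise pixels into a tile
#'
#' Exactly `round(noise_pct / 100 * H * W)` pixel positions are sampled
#' without replacement and each replaced by a color drawn from the stain
#' manifold: R uniform over the model's observed R range, G and B predicted
#' from R.
#'
#' @param img A [stain_image()].
#' @param noise_pct Percentage of pixels to replace, in \[0, 100\].
#' @param model A [fit_noise_color_model()] result.
#' @param seed Integer seed.
#' @return A new [stain_image()]; the input is untouched elsewhere.
#' @export
inject_noise <- function(img, noise_pct, model, seed = 1) {
  stopifnot(inherits(img, "stain_image"),
            inherits(model, "noise_color_model"))
  if (noise_pct < 0 || noise_pct > 100) stop("`noise_pct` must be in [0, 100]")
  d <- dim(img$pixels)
  n_pix <- d[1] * d[2]
  n_noise <- round(noise_pct / 100 * n_pix)
  if (n_noise == 0) return(img)
  set.seed(seed)
  pos <- sample.int(n_pix, n_noise)
  r_star <- stats::runif(n_noise, model$r_range[1], model$r_range[2])
  gb <- model$predict_gb(r_star)
  px <- img$pixels
  px[pos] <- round(r_star)
  px[pos + n_pix] <- round(gb[, 1])
  px[pos + 2 * n_pix] <- round(gb[, 2])
  stain_image(px, img$stain_kind)
}

#' Run the segmentation noise-robustness assay
#'
#' For each noise percentage one noise realization is drawn (a fresh seeded
#' realization per percentage, shared across methods for a fair comparison),
#' each segmentation method is applied, and the mask is scored against the
#' ground truth.
#'
#' @param img A [stain_image()].
#' @param truth Ground-truth label mask.
#' @param methods Character subset of `c("deconv", "kmeans", "ccc")`.
#' @param pcts Noise grid (default the standard
#'   `c(0, 5, 10, 15, 25, 50, 75, 90)`).
#' @param seed Integer seed (drives the color model and noise stream).
#' @param model Optional pre-fitted [fit_noise_color_model()]; fitted from
#'   `img`/`truth` otherwise.
#' @return A data.frame: `method`, `pct`, `accuracy`, `iou`.
#' @export
run_noise_assay <- function(img, truth, methods = c("deconv", "kmeans", "ccc"),
                            pcts = c(0, 5, 10, 15, 25, 50, 75, 90),
                            seed = 1, model = NULL) {
  stopifnot(identical(dim(truth), dim(img$pixels)[1:2]))
  methods <- match.arg(methods, c("deconv", "kmeans", "ccc"),
                       several.ok = TRUE)
  if (is.null(model)) model <- fit_noise_color_model(img, truth, seed = seed)
  segment_one <- function(im, method) {
    switch(method,
           deconv = segment_deconv_otsu(im),
           kmeans = segment_kmeans(im, seed = seed),
           ccc = segment_ccc(im, seed = seed))
  }
  rows <- list()
  for (i in seq_along(pcts)) {
    noisy <- inject_noise(img, pcts[i], model, seed = seed + i)
    for (m in methods) {
      sc <- evaluate_segmentation(segment_one(noisy, m), truth)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, pct = pcts[i], accuracy = sc$accuracy, iou = sc$iou)
    }
  }
  do.call(rbind, rows)
}
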