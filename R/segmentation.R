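# Unsupervised nuclear segmentation of H&E and DAB photomicrograph tiles:
# color deconvolution + Otsu + watershed, k-means pixel clustering, and the
# patch-based Cut-Cluster-Classify method, plus mask evaluation (accuracy,
# intersection-over-union).

## ---- containers ---------------------------------------------------------

#' Construct a stained-tissue RGB tile
#'
#' @param pixels H x W x 3 numeric array, channels R, G, B in \[0, 255\].
#' @param stain_kind `"HE"` (hematoxylin-eosin) or `"DAB"` (brown chromogen
#'   immunohistochemistry, e.g. Olig2 or p53).
#' @return An object of class `"stain_image"`.
#' @export
stain_image <- function(pixels, stain_kind = c("DAB", "HE")) {
  stain_kind <- match.arg(stain_kind)
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) stop("`pixels` must be H x W x 3")
  if (d[1] < 16L || d[2] < 16L) stop("tile must be at least 16 x 16")
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255]")
  }
  structure(list(pixels = pixels, stain_kind = stain_kind),
            class = "stain_image")
}

#' @export
print.stain_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<stain_image %dx%d, stain = %s>\n", d[1], d[2], x$stain_kind))
  invisible(x)
}

#' Read an RGB tile from a PNG or TIFF file
#'
#' @param path Image file (8-bit RGB PNG or TIFF).
#' @param stain_kind Stain of the tile, `"DAB"` or `"HE"`.
#' @return A [stain_image()].
#' @export
read_stain_image <- function(path, stain_kind = c("DAB", "HE")) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
  a <- a[, , 1:3, drop = FALSE]
  # EBImage stores x (columns) first; transpose to row-major H x W
  px <- aperm(a, c(2, 1, 3)) * 255
  stain_image(round(px), match.arg(stain_kind))
}

#' Write an RGB tile to a PNG or TIFF file
#' @param img A [stain_image()].
#' @param path Output path (extension selects the format).
#' @export
write_stain_image <- function(img, path) {
  a <- aperm(img$pixels / 255, c(2, 1, 3))
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}

#' Read / write an integer label mask (0 = background, 1..K = nuclei)
#'
#' Masks are stored as single-channel images with intensity `label / scale`:
#' 16-bit TIFF (`scale` 65535, up to 65535 labels) or 8-bit PNG (`scale`
#' 255, up to 255 labels; PNG files are always written 8-bit).
#' @param path Mask file (`.tif`/`.tiff` or `.png`).
#' @return Integer matrix of labels.
#' @export
read_label_mask <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  m <- t(a)
  scale <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) 65535 else 255
  matrix(as.integer(round(m * scale)), nrow = nrow(m))
}

#' @rdname read_label_mask
#' @param mask Integer label matrix.
#' @export
write_label_mask <- function(mask, path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    EBImage::writeImage(EBImage::Image(t(mask) / 65535), path,
                        bits.per.sample = 16L)
  } else {
    if (max(mask) > 255) {
      stop("PNG label masks support at most 255 labels; use a .tif path")
    }
    EBImage::writeImage(EBImage::Image(t(mask) / 255), path)
  }
  invisible(path)
}

## ---- stain vectors and optical density ----------------------------------

#' Default stain optical-density matrices
#'
#' Unit-norm stain OD vectors after Ruifrok & Johnston: hematoxylin, eosin
#' and DAB, with the third row the residual (cross product) channel. Rows are
#' named `H`, `E`/`D`, `X`.
#'
#' @param stain_kind `"HE"` or `"DAB"` (hematoxylin + DAB).
#' @return A 3 x 3 matrix with unit-norm rows.
#' @export
default_stain_matrix <- function(stain_kind = c("DAB", "HE")) {
  stain_kind <- match.arg(stain_kind)
  hema <- c(0.650, 0.704, 0.286)
  eos  <- c(0.072, 0.990, 0.105)
  dab  <- c(0.268, 0.570, 0.776)
  unit <- function(v) v / sqrt(sum(v^2))
  r1 <- unit(hema)
  r2 <- unit(if (stain_kind == "HE") eos else dab)
  r3 <- unit(c(r1[2] * r2[3] - r1[3] * r2[2],
               r1[3] * r2[1] - r1[1] * r2[3],
               r1[1] * r2[2] - r1[2] * r2[1]))
  m <- rbind(r1, r2, r3)
  rownames(m) <- c("H", if (stain_kind == "HE") "E" else "D", "X")
  colnames(m) <- c("R", "G", "B")
  m
}

# RGB intensity [0,255] -> optical density; white (255) maps to exactly 0.
.rgb_to_od <- function(p) -log10((p + 1) / 256)
.od_to_rgb <- function(od) 256 * 10^(-od) - 1

#' Color deconvolution into per-stain optical-density channels
#'
#' Converts an RGB tile to optical density and unmixes it through the inverse
#' stain matrix, yielding hematoxylin, DAB (or eosin) and residual channels.
#' Negative unmixed concentrations are clipped to zero.
#'
#' @param img A [stain_image()].
#' @param stain_matrix 3 x 3 matrix of unit-norm stain OD row vectors;
#'   defaults to [default_stain_matrix()] for the tile's stain kind.
#' @return A list of class `"opt_density_image"` with one H x W matrix per
#'   stain (named by the matrix row names).
#' @export
color_deconvolve <- function(img, stain_matrix = NULL) {
  stopifnot(inherits(img, "stain_image"))
  if (is.null(stain_matrix)) stain_matrix <- default_stain_matrix(img$stain_kind)
  if (abs(det(stain_matrix)) < 1e-8) stop("stain matrix is singular")
  d <- dim(img$pixels)
  od <- .rgb_to_od(matrix(img$pixels, ncol = 3))
  conc <- od %*% solve(stain_matrix)
  conc[conc < 0] <- 0
  out <- lapply(seq_len(3), function(j) matrix(conc[, j], d[1], d[2]))
  names(out) <- rownames(stain_matrix)
  class(out) <- "opt_density_image"
  out
}

#' Forward stain synthesis from optical-density concentrations
#'
#' Inverse of [color_deconvolve()]: composes per-stain OD concentration maps
#' through the stain matrix into RGB intensities. Used by the synthetic tile
#' generator so that deconvolution is exercised on-manifold.
#'
#' @param conc H x W x 3 array of stain concentrations (same row order as
#'   `stain_matrix`).
#' @param stain_matrix 3 x 3 unit-norm stain OD matrix.
#' @return H x W x 3 numeric RGB array in \[0, 255\] (not rounded).
#' @export
forward_stain_synthesis <- function(conc, stain_matrix) {
  d <- dim(conc)
  od <- matrix(conc, ncol = 3) %*% stain_matrix
  px <- .od_to_rgb(od)
  px[px < 0] <- 0; px[px > 255] <- 255
  array(px, d)
}

## ---- helpers -------------------------------------------------------------

# drop objects touching the 1-pixel image frame
.remove_border_objects <- function(labels) {
  border <- unique(c(labels[1, ], labels[nrow(labels), ],
                     labels[, 1], labels[, ncol(labels)]))
  border <- border[border > 0]
  if (length(border)) labels[labels %in% border] <- 0L
  labels
}

.relabel <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  if (!length(u)) return(matrix(0L, nrow(labels), ncol(labels)))
  out <- match(labels, u, nomatch = 0L)
  matrix(as.integer(out), nrow(labels))
}

.bwlabel_mat <- function(bw) {
  lab <- EBImage::bwlabel(EBImage::Image(t(bw * 1)))
  matrix(as.integer(t(EBImage::imageData(lab))), nrow = nrow(bw))
}

## ---- segmenters ----------------------------------------------------------

#' Segment nuclei by color deconvolution, Otsu thresholding and watershed
#'
#' The fixed pipeline: deconvolve to the nuclear stain channel (DAB for
#' immunostains, hematoxylin for H&E), median filter, Otsu threshold on a
#' 256-bin histogram of the rescaled channel, fill holes, remove
#' border-touching (incomplete) nuclei, then split touching nuclei by
#' distance-transform watershed.
#'
#' @param img A [stain_image()].
#' @param target Stain channel to threshold; defaults by stain kind (`"D"`
#'   for DAB, `"H"` for H&E). `"HD"` thresholds the summed hematoxylin + DAB
#'   density — appropriate for immunostains with a hematoxylin counterstain,
#'   where negative nuclei carry no DAB at all (the p53 workflow's case).
#' @param median_radius Median filter radius in pixels.
#' @param min_od Absolute optical-density floor for foreground; prevents
#'   Otsu from hallucinating nuclei on blank tiles.
#' @param min_size Objects smaller than this (pixels) are discarded.
#' @param watershed_tolerance Minimum depth between distance-transform
#'   maxima for an object split.
#' @return Integer label matrix (0 = background, 1..K nuclei).
#' @export
segment_deconv_otsu <- function(img, target = NULL, median_radius = 2,
                                min_od = 0.15, min_size = 20,
                                watershed_tolerance = 1) {
  stopifnot(inherits(img, "stain_image"))
  if (is.null(target)) target <- if (img$stain_kind == "DAB") "D" else "H"
  od <- color_deconvolve(img)
  if (target == "HD") {
    if (!all(c("H", "D") %in% names(od))) {
      stop("target 'HD' requires an H-DAB stain image")
    }
    ch <- od$H + od$D
  } else {
    if (!target %in% names(od)) {
      stop("target channel '", target, "' does not match stain kind ",
           img$stain_kind)
    }
    ch <- od[[target]]
  }
  top <- max(ch)
  if (top <= min_od) return(matrix(0L, nrow(ch), ncol(ch)))
  ch01 <- ch / top
  filt <- EBImage::medianFilter(EBImage::Image(t(ch01)), size = median_radius)
  thr <- EBImage::otsu(filt, range = c(0, 1), levels = 256)
  thr <- max(thr, min_od / top)
  bw <- EBImage::fillHull(filt > thr)
  labs <- EBImage::bwlabel(bw)
  labs_m <- matrix(as.integer(t(EBImage::imageData(labs))), nrow = nrow(ch))
  labs_m <- .remove_border_objects(labs_m)
  bw2 <- labs_m > 0
  if (!any(bw2)) return(matrix(0L, nrow(ch), ncol(ch)))
  dm <- EBImage::distmap(EBImage::Image(t(bw2 * 1)))
  ws <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  out <- matrix(as.integer(t(EBImage::imageData(ws))), nrow = nrow(ch))
  sizes <- tabulate(out[out > 0])
  small <- which(sizes > 0 & sizes < min_size)
  if (length(small)) out[out %in% small] <- 0L
  .relabel(out)
}

#' Segment nuclei by k-means clustering of RGB pixels
#'
#' All pixels are clustered on (R, G, B); the cluster whose centroid carries
#' the maximal nuclear-stain optical density (the darkest stain cluster) is
#' taken as foreground and its connected components labeled.
#'
#' @param img A [stain_image()].
#' @param k Number of pixel clusters (>= 2; default 3: nuclei, cytoplasm or
#'   counterstain, background).
#' @param seed Integer seed (k-means initialization).
#' @param min_size Minimum object size in pixels.
#' @return Integer label matrix.
#' @export
segment_kmeans <- function(img, k = 3, seed = 1, min_size = 20) {
  stopifnot(inherits(img, "stain_image"))
  if (k < 2) stop("`k` must be >= 2")
  d <- dim(img$pixels)
  px <- matrix(img$pixels, ncol = 3)
  if (nrow(unique(px)) < k) {
    warning("degenerate image: fewer distinct colors than clusters; ",
            "returning empty mask")
    return(matrix(0L, d[1], d[2]))
  }
  set.seed(seed)
  km <- stats::kmeans(px, centers = k, nstart = 3, iter.max = 100,
                      algorithm = "MacQueen")
  m <- default_stain_matrix(img$stain_kind)
  target <- if (img$stain_kind == "DAB") "D" else "H"
  cent_od <- .rgb_to_od(km$centers) %*% solve(m)
  fg_cluster <- which.max(cent_od[, match(target, rownames(m))])
  bw <- matrix(km$cluster == fg_cluster, d[1], d[2])
  out <- .bwlabel_mat(bw)
  sizes <- tabulate(out[out > 0])
  small <- which(sizes > 0 & sizes < min_size)
  if (length(small)) out[out %in% small] <- 0L
  .relabel(out)
}

#' Segment nuclei by the Cut-Cluster-Classify (CCC) patch method
#'
#' Every overlapping `patch_size` x `patch_size` gray-level patch is a point
#' in patch space. A k-nearest-neighbor density estimate is thresholded
#' (Cut), the high-density patches are clustered into two groups (Cluster),
#' sub-threshold patches are assigned to the nearest cluster centroid
#' (Classify), and each pixel takes the majority vote over the overlapping
#' patches that contain it. The cluster with darker mean intensity is the
#' nucleus class.
#'
#' @param img A [stain_image()].
#' @param patch_size Odd patch edge in pixels (>= 3).
#' @param density_threshold Quantile of the kNN-distance distribution
#'   separating high-density (clustered) from low-density (classified)
#'   patches.
#' @param k_density Neighbor rank used for the density estimate.
#' @param n_ref Size of the seeded reference subsample used to evaluate
#'   patch density.
#' @param seed Integer seed (reference subsample + k-means).
#' @param min_size Minimum object size in pixels.
#' @return Integer label matrix.
#' @export
segment_ccc <- function(img, patch_size = 5, density_threshold = 0.85,
                        k_density = 4, n_ref = 2000, seed = 1,
                        min_size = 20) {
  stopifnot(inherits(img, "stain_image"))
  if (patch_size < 3 || patch_size %% 2 == 0) {
    stop("`patch_size` must be odd and >= 3")
  }
  d <- dim(img$pixels)
  if (d[1] < patch_size || d[2] < patch_size) {
    stop("image smaller than the patch size")
  }
  gray <- (img$pixels[, , 1] + img$pixels[, , 2] + img$pixels[, , 3]) / (3 * 255)
  if (stats::sd(gray) < 1e-6) {
    warning("uniform image: one cluster only; returning empty mask")
    return(matrix(0L, d[1], d[2]))
  }
  nh <- d[1] - patch_size + 1L
  nw <- d[2] - patch_size + 1L
  n_patch <- nh * nw
  patches <- matrix(0, n_patch, patch_size^2)
  col <- 1L
  for (dj in 0:(patch_size - 1L)) {
    for (di in 0:(patch_size - 1L)) {
      patches[, col] <- as.vector(gray[(1L + di):(nh + di), (1L + dj):(nw + dj)])
      col <- col + 1L
    }
  }
  set.seed(seed)
  ref_idx <- sample.int(n_patch, min(n_ref, n_patch))
  refs <- patches[ref_idx, , drop = FALSE]
  # squared distances from every patch to the reference subsample, blocked
  ref_sq <- rowSums(refs^2)
  kdist <- numeric(n_patch)
  k_eff <- min(k_density, nrow(refs) - 1L)
  block <- 20000L
  for (s in seq(1L, n_patch, by = block)) {
    e <- min(s + block - 1L, n_patch)
    p <- patches[s:e, , drop = FALSE]
    nb <- nrow(p)
    # neighbor ranking within a row is unaffected by the row's own squared
    # norm, so defer it until after the k-th neighbor is found
    d2 <- -2 * tcrossprod(p, refs) + rep(ref_sq, each = nb)
    rows <- seq_len(nb)
    val <- numeric(nb)
    for (pass in seq_len(k_eff + 1L)) {
      j <- max.col(-d2, ties.method = "first")
      val <- d2[cbind(rows, j)]
      d2[cbind(rows, j)] <- Inf
    }
    val <- val + rowSums(p^2)
    val[val < 0] <- 0
    kdist[s:e] <- sqrt(val)
  }
  thr <- stats::quantile(kdist, density_threshold, names = FALSE)
  high <- kdist <= thr
  if (sum(high) < 2L) high <- rep(TRUE, n_patch)
  km <- stats::kmeans(patches[high, , drop = FALSE], centers = 2,
                      nstart = 3, iter.max = 100, algorithm = "MacQueen")
  # Classify: nearest-centroid assignment of the sub-threshold patches
  assign_all <- integer(n_patch)
  assign_all[high] <- km$cluster
  if (any(!high)) {
    p <- patches[!high, , drop = FALSE]
    d2c <- outer(rowSums(p^2), rowSums(km$centers^2), "+") -
      2 * tcrossprod(p, km$centers)
    assign_all[!high] <- max.col(-d2c)
  }
  # pixel-level majority vote over the patches covering each pixel
  lab_mat <- matrix(assign_all, nh, nw)
  votes1 <- matrix(0L, d[1], d[2])
  votes2 <- matrix(0L, d[1], d[2])
  for (dj in 0:(patch_size - 1L)) {
    for (di in 0:(patch_size - 1L)) {
      sel1 <- (lab_mat == 1L)
      votes1[(1L + di):(nh + di), (1L + dj):(nw + dj)] <-
        votes1[(1L + di):(nh + di), (1L + dj):(nw + dj)] + sel1
      votes2[(1L + di):(nh + di), (1L + dj):(nw + dj)] <-
        votes2[(1L + di):(nh + di), (1L + dj):(nw + dj)] + (!sel1 & lab_mat > 0L)
    }
  }
  pix_cluster <- ifelse(votes1 >= votes2, 1L, 2L)
  mean_int <- c(mean(gray[pix_cluster == 1L]), mean(gray[pix_cluster == 2L]))
  nucleus_cluster <- which.min(mean_int)
  bw <- pix_cluster == nucleus_cluster
  out <- .bwlabel_mat(bw)
  sizes <- tabulate(out[out > 0])
  small <- which(sizes > 0 & sizes < min_size)
  if (length(small)) out[out %in% small] <- 0L
  .relabel(out)
}

#' Evaluate a predicted mask against ground truth
#'
#' Both masks are binarized (label > 0). Accuracy is the fraction of
#' agreeing pixels; IoU is intersection over union of the foregrounds, with
#' the empty-vs-empty case defined as perfect agreement (IoU = 1).
#'
#' @param pred,truth Integer label matrices of identical shape.
#' @return A list with elements `accuracy` and `iou`, both in \[0, 1\].
#' @export
evaluate_segmentation <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("mask shapes differ")
  p <- pred > 0
  t_ <- truth > 0
  acc <- mean(p == t_)
  uni <- sum(p | t_)
  iou <- if (uni == 0) 1 else sum(p & t_) / uni
  list(accuracy = acc, iou = iou)
}
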