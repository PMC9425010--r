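# Per-nucleus morphometry: shape, image-moment, intensity and Haralick
# texture features per RGB channel, de-duplication of channel-invariant
# columns, pooled PCA to a variance target, seeded nucleus sampling, kNN
# density features (d10/d20/d40/d60) and shape-histogram features.

#' Extract per-nucleus features from a tile and its label mask
#'
#' For each RGB channel, the full feature set (basic intensity statistics,
#' shape, image moments and Haralick texture on the nucleus and its expanded
#' surroundings) is computed per labeled nucleus; channel-invariant columns
#' that repeat identically across channels are dropped. Nuclei touching the
#' image border (incomplete nuclei) are excluded first.
#'
#' @param img A [stain_image()].
#' @param mask Integer label mask aligned to `img`.
#' @param exclude_border Drop border-touching nuclei (default `TRUE`).
#' @return A data.frame with one row per retained nucleus: `label` plus the
#'   de-duplicated feature columns (prefixed `r.`, `g.`, `b.` by channel).
#'   Empty mask (or no retained nucleus) yields a zero-row table.
#' @export
extract_nucleus_features <- function(img, mask, exclude_border = TRUE) {
  stopifnot(inherits(img, "stain_image"))
  if (!identical(dim(mask), dim(img$pixels)[1:2])) {
    stop("mask not aligned to image")
  }
  m <- mask
  if (exclude_border) m <- .remove_border_objects(m)
  m <- .relabel(m)
  n_obj <- max(m)
  if (n_obj == 0L) return(data.frame(label = integer(0)))
  m_eb <- EBImage::Image(t(m))
  chans <- c(r = 1L, g = 2L, b = 3L)
  out <- vector("list", 3L)
  for (i in seq_along(chans)) {
    ref <- EBImage::Image(t(img$pixels[, , chans[i]] / 255))
    # pass the method functions explicitly: computeFeatures resolves bare
    # method names on the search path, which fails when EBImage is only
    # imported
    f <- EBImage::computeFeatures(
      m_eb, ref = ref, xname = "nuc",
      methods.noref = list(EBImage::computeFeatures.moment,
                           EBImage::computeFeatures.shape),
      methods.ref = list(EBImage::computeFeatures.basic,
                         EBImage::computeFeatures.moment,
                         EBImage::computeFeatures.haralick))
    colnames(f) <- sub("^nuc\\.", paste0(names(chans)[i], "."), colnames(f))
    out[[i]] <- f
  }
  tab <- do.call(cbind, out)
  tab[!is.finite(tab)] <- 0
  # drop columns exactly equal to an earlier column (shape/moment features
  # recomputed per channel are identical)
  keep <- rep(TRUE, ncol(tab))
  seen <- list()
  for (j in seq_len(ncol(tab))) {
    key <- paste(signif(tab[, j], 12), collapse = "\r")
    if (!is.null(seen[[key]])) keep[j] <- FALSE else seen[[key]] <- j
  }
  tab <- tab[, keep, drop = FALSE]
  df <- data.frame(label = seq_len(n_obj), tab, check.names = FALSE)
  rownames(df) <- NULL
  df
}

# columns of a nucleus feature table by family, via the registry naming
# scheme (<channel>.<context>.<family>.<stat>)
.feature_cols <- function(table, pattern) {
  grep(pattern, colnames(table), value = TRUE)
}

#' Select the intensity + texture feature columns of a nucleus table
#'
#' Returns the basic-intensity (`.b.`) and Haralick texture (`.h.`) columns;
#' shape and moment features are excluded. This is the feature subset the
#' p53 positivity classifier is allowed to use (positivity must not depend
#' on nuclear shape).
#'
#' @param table A nucleus feature table from [extract_nucleus_features()].
#' @return Character vector of column names.
#' @export
intensity_texture_columns <- function(table) {
  .feature_cols(table, "\\.(b|h)\\.")
}

#' PCA reduction of a nucleus feature table to a variance target
#'
#' Columns are standardized (zero mean, unit variance; zero-variance columns
#' dropped with a warning) and the minimal number of principal components
#' whose cumulative explained variance reaches the target is retained.
#'
#' @param table Nucleus feature table (or plain numeric data.frame/matrix);
#'   a `label` column, if present, is ignored.
#' @param variance_target Proportion of variance to represent, in (0, 1\].
#' @return A list with `scores` (nucleus x PC matrix), `model` (the
#'   [stats::prcomp()] fit), `n_pc` and `explained` (cumulative proportions).
#' @export
pca_reduce <- function(table, variance_target = 0.9) {
  if (variance_target <= 0 || variance_target > 1) {
    stop("`variance_target` must be in (0, 1]")
  }
  x <- as.matrix(table[, setdiff(colnames(table), "label"), drop = FALSE])
  if (nrow(x) < 2L) stop("need at least 2 rows for PCA")
  sds <- apply(x, 2, stats::sd)
  zero <- sds < .Machine$double.eps^0.5
  if (any(zero)) {
    warning(sum(zero), " zero-variance column(s) dropped before PCA")
    x <- x[, !zero, drop = FALSE]
  }
  if (ncol(x) == 0L) stop("no non-degenerate columns left")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  expl <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  n_pc <- which(expl >= variance_target - 1e-12)[1L]
  list(scores = pc$x[, seq_len(n_pc), drop = FALSE], model = pc,
       n_pc = n_pc, explained = expl)
}

#' kNN density features of nuclei in principal-component space
#'
#' Samples `n_sample` nuclei without replacement (a fixed sample size removes
#' the effect of cellularity), computes all pairwise Euclidean distances, and
#' for each nucleus the distance to its k-th nearest other nucleus for each
#' k. Large k-th-neighbor distances mean sparse packing in feature space,
#' i.e. pleomorphic nuclei; tight packing means monomorphism.
#'
#' @param scores Nucleus x PC numeric matrix.
#' @param n_sample Number of nuclei to sample (default 350). If fewer rows
#'   are available all rows are used and the result is flagged.
#' @param ks Neighbor ranks (default 10, 20, 40, 60); all must be below the
#'   number of points used.
#' @param seed Integer seed for the sampling.
#' @return A list with `features` (named vector `mean_dk`, `median_dk`,
#'   `sd_dk` per k), `n_sampled` and `undersampled` flag.
#' @export
density_features <- function(scores, n_sample = 350, ks = c(10, 20, 40, 60),
                             seed = 1) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  undersampled <- n < n_sample
  if (undersampled) {
    warning("only ", n, " nuclei available (< n_sample = ", n_sample,
            "): using all")
    n_sample <- n
  }
  if (n_sample <= max(ks)) {
    stop("need more than max(ks) = ", max(ks), " points; have ", n_sample)
  }
  set.seed(seed)
  idx <- sample.int(n, n_sample)
  pts <- scores[idx, , drop = FALSE]
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  sorted <- apply(dm, 1L, sort)  # columns = points, rows = ranks
  feats <- c()
  for (k in ks) {
    dk <- sorted[k, ]
    feats[[paste0("mean_d", k)]] <- mean(dk)
    feats[[paste0("median_d", k)]] <- stats::median(dk)
    feats[[paste0("sd_d", k)]] <- stats::sd(dk)
  }
  list(features = unlist(feats), n_sampled = n_sample,
       undersampled = undersampled)
}

#' Histogram features of the nuclear shape distributions
#'
#' Mean, standard deviation, moment skewness and Fisher excess kurtosis of
#' the major axis, eccentricity and area across the nuclei of a case. A
#' constant feature reports SD 0 and, by convention, skewness and kurtosis 0
#' (flagged in the `degenerate` attribute).
#'
#' @param table Nucleus feature table with at least 4 rows.
#' @return Named numeric vector of 12 values
#'   (`<feature>_{mean,sd,kurtosis,skewness}`), with attribute `degenerate`
#'   naming any constant features.
#' @export
histogram_features <- function(table) {
  if (nrow(table) < 4L) stop("need at least 4 nuclei for kurtosis")
  pick <- function(pat) {
    cols <- .feature_cols(table, pat)
    if (!length(cols)) stop("no column matching ", pat)
    table[[cols[1L]]]
  }
  vars <- list(majoraxis = pick("\\.m\\.majoraxis$"),
               eccentricity = pick("\\.m\\.eccentricity$"),
               area = pick("\\.s\\.area$"))
  out <- c()
  degenerate <- character(0)
  for (nm in names(vars)) {
    x <- vars[[nm]]
    s <- stats::sd(x)
    if (s < .Machine$double.eps^0.5) {
      degenerate <- c(degenerate, nm)
      sk <- 0; ku <- 0; s <- 0
    } else {
      sk <- e1071::skewness(x, type = 1)
      ku <- e1071::kurtosis(x, type = 1)
    }
    out[paste0(nm, "_mean")] <- mean(x)
    out[paste0(nm, "_sd")] <- s
    out[paste0(nm, "_kurtosis")] <- ku
    out[paste0(nm, "_skewness")] <- sk
  }
  attr(out, "degenerate") <- degenerate
  out
}

#' Rank case-level features by mutual information with a diagnostic label
#'
#' Each numeric feature is discretized ([discretize()]), its mutual
#' information with the label computed, and significance assessed by label
#' permutation. Features with p below `alpha` form the significant set used
#' for downstream modeling.
#'
#' @param case_features Case x feature data.frame (numeric columns).
#' @param label Per-case class vector (binary).
#' @param n_bins Bins for discretization (equal frequency).
#' @param n_perm Number of permutations.
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @return A data.frame ranked by decreasing information: `feature`, `bits`,
#'   `percent_of_max`, `p_value`, `significant`.
#' @export
select_features_by_information <- function(case_features, label, n_bins = 5,
                                           n_perm = 999, alpha = 0.05,
                                           seed = 1) {
  num <- vapply(case_features, is.numeric, TRUE)
  feats <- case_features[, num, drop = FALSE]
  h_label <- shannon_entropy(label)
  if (h_label <= 0) stop("label has zero entropy")
  res <- lapply(seq_along(feats), function(j) {
    x <- suppressWarnings(discretize(feats[[j]], n_bins = n_bins))
    bits <- mutual_information(x, label)
    p <- permutation_significance(mutual_information, x, label,
                                  n_perm = n_perm, seed = seed + j)
    data.frame(feature = colnames(feats)[j], bits = bits,
               percent_of_max = 100 * bits / h_label, p_value = p)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_value <= alpha
  out[order(-out$bits), , drop = FALSE]
}
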