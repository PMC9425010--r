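# Discrete information-theory engine: plug-in (maximum-likelihood) estimates
# of entropy, mutual information and conditional mutual information in bits,
# percent-of-maximum information relative to the label entropy, incremental
# information gain of a candidate biomarker, and permutation significance.

## ---- internal coding helpers -------------------------------------------

# Encode a vector as integer codes 1..n_levels. Factors keep their level set;
# everything else is coded over its observed sorted unique values.
.as_codes <- function(x) {
  if (is.factor(x)) {
    list(code = as.integer(x), n = nlevels(x))
  } else {
    f <- factor(x)
    list(code = as.integer(f), n = nlevels(f))
  }
}

# Cartesian-product joint coding of one or more variables. `vars` is a list
# of equal-length vectors; the joint level count is the product of the
# member level counts (unobserved cells contribute nothing to plug-in H).
.joint_codes <- function(vars) {
  stopifnot(length(vars) >= 1)
  ns <- lengths(vars)
  if (length(unique(ns)) != 1L) {
    stop("all variables must have equal length (got ",
         paste(unique(ns), collapse = ", "), ")")
  }
  cs <- lapply(vars, .as_codes)
  code <- cs[[1L]]$code
  n <- cs[[1L]]$n
  if (length(cs) > 1L) {
    for (i in 2:length(cs)) {
      # guard against integer overflow on wide joints
      if (as.double(n) * cs[[i]]$n > .Machine$integer.max) {
        # re-code the accumulated joint compactly before extending
        f <- factor(code)
        code <- as.integer(f)
        n <- nlevels(f)
      }
      code <- (code - 1L) * cs[[i]]$n + cs[[i]]$code
      n <- n * cs[[i]]$n
    }
  }
  list(code = code, n = n)
}

.entropy_codes <- function(code, n_levels) {
  cnt <- tabulate(code, nbins = n_levels)
  cnt <- cnt[cnt > 0L]
  p <- cnt / sum(cnt)
  -sum(p * log2(p))
}

.mi_codes <- function(cx, cy) {
  hx <- .entropy_codes(cx$code, cx$n)
  hy <- .entropy_codes(cy$code, cy$n)
  hxy <- .entropy_codes((cx$code - 1L) * cy$n + cy$code, cx$n * cy$n)
  max(0, hx + hy - hxy)
}

# Accept a single vector, a list of vectors, or a data.frame of columns.
.as_varlist <- function(x) {
  if (is.data.frame(x)) as.list(x) else if (is.list(x)) x else list(x)
}

## ---- public API ---------------------------------------------------------

#' Discretize a numeric vector into categorical bins
#'
#' Continuous inputs (patient age, percent p53 positivity) enter the discrete
#' information quantities only after binning. Equal-frequency binning keeps
#' every cell populated at modest cohort sizes and is the package default.
#'
#' @param x Numeric vector; must be finite.
#' @param n_bins Number of bins, at least 2. If `x` has fewer distinct values
#'   than `n_bins`, bins collapse to the distinct values with a warning.
#' @param strategy `"equal_frequency"` (quantile edges) or `"equal_width"`.
#' @return A factor with a `"breaks"` attribute holding the bin edges. Ties
#'   always land in the same bin.
#' @examples
#' table(discretize(1:100, 4))
#' @export
discretize <- function(x, n_bins = 5,
                       strategy = c("equal_frequency", "equal_width")) {
  strategy <- match.arg(strategy)
  if (!is.numeric(x)) stop("`x` must be numeric")
  if (any(!is.finite(x))) stop("`x` must be finite")
  if (n_bins < 2) stop("`n_bins` must be >= 2")
  ux <- sort(unique(x))
  if (length(ux) == 1L) {
    warning("constant vector: returning a single level")
    f <- factor(rep("bin1", length(x)))
    attr(f, "breaks") <- c(ux, ux)
    return(f)
  }
  if (length(ux) < n_bins) {
    warning("fewer distinct values (", length(ux), ") than bins (", n_bins,
            "): collapsing to distinct-value bins")
    f <- factor(x, levels = ux)
    attr(f, "breaks") <- ux
    return(f)
  }
  breaks <- if (strategy == "equal_frequency") {
    unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                           names = FALSE, type = 7))
  } else {
    seq(min(x), max(x), length.out = n_bins + 1)
  }
  if (length(breaks) < 3L) breaks <- c(min(x), stats::median(ux), max(x))
  f <- cut(x, breaks = breaks, include.lowest = TRUE, right = FALSE)
  # cut() with right = FALSE drops max(x) unless the last interval closes
  f[x >= breaks[length(breaks)]] <- levels(f)[nlevels(f)]
  f <- droplevels(f)
  attr(f, "breaks") <- breaks
  f
}

#' Shannon entropy of a discrete variable (bits)
#'
#' Plug-in estimate \eqn{-\sum \hat p \log_2 \hat p} over observed levels,
#' with the convention \eqn{0 \log 0 = 0}.
#'
#' @param x Vector or factor of category codes (non-empty).
#' @return Entropy in bits, a non-negative scalar.
#' @examples
#' shannon_entropy(c(0, 1, 0, 1)) # 1 bit
#' @export
shannon_entropy <- function(x) {
  if (length(x) == 0L) stop("`x` must be non-empty")
  cx <- .as_codes(x)
  .entropy_codes(cx$code, cx$n)
}

#' Mutual information between discrete variables (bits)
#'
#' Plug-in estimate \eqn{I(X;Y) = H(X) + H(Y) - H(X,Y)}. Either argument may
#' be a set of variables (a list or data.frame), in which case the set enters
#' as the joint variable formed by the cartesian product of member levels —
#' this is how combined biomarker panels are scored.
#'
#' @param x,y Vectors/factors, or lists/data.frames of equal-length
#'   vectors, all the same length.
#' @return Mutual information in bits (non-negative).
#' @examples
#' mutual_information(c(0, 1, 0, 1), c(0, 1, 0, 1)) # 1 bit
#' @export
mutual_information <- function(x, y) {
  cx <- .joint_codes(.as_varlist(x))
  cy <- .joint_codes(.as_varlist(y))
  if (length(cx$code) != length(cy$code)) {
    stop("`x` and `y` must have equal length")
  }
  .mi_codes(cx, cy)
}

#' Conditional mutual information I(X;Y|Z) (bits)
#'
#' Plug-in estimate \eqn{I(X;Y|Z) = H(X,Z) + H(Y,Z) - H(X,Y,Z) - H(Z)}.
#' Used to score a biomarker's residual information about the diagnosis once
#' another variable (e.g. 1p/19q status) is known.
#'
#' @param x,y,z Vectors/factors, or lists/data.frames of equal-length vectors.
#' @return Conditional mutual information in bits (non-negative).
#' @export
conditional_mutual_information <- function(x, y, z) {
  lx <- .as_varlist(x); ly <- .as_varlist(y); lz <- .as_varlist(z)
  n <- length(lx[[1L]])
  if (length(ly[[1L]]) != n || length(lz[[1L]]) != n) {
    stop("`x`, `y` and `z` must have equal length")
  }
  hz  <- with(.joint_codes(lz), .entropy_codes(code, n))
  hxz <- with(.joint_codes(c(lx, lz)), .entropy_codes(code, n))
  hyz <- with(.joint_codes(c(ly, lz)), .entropy_codes(code, n))
  hxyz <- with(.joint_codes(c(lx, ly, lz)), .entropy_codes(code, n))
  max(0, hxz + hyz - hxyz - hz)
}

#' Information carried by a feature set, as percent of maximum
#'
#' The maximum information any feature set can supply about a diagnostic
#' label is the label entropy H(label); a panel's value is reported as
#' \eqn{100 \cdot I(\mathrm{joint(features)}; \mathrm{label}) / H(\mathrm{label})}.
#' The percentage is invariant to the logarithm base (bits vs nats).
#'
#' @param features A vector/factor or a list/data.frame of them (the panel).
#' @param label Diagnostic label; must have positive entropy.
#' @param n_perm Optional permutation count for a significance test of the
#'   mutual information (label permuted).
#' @param seed Optional seed for the permutation stream.
#' @return An object of class `"info_result"`: a list with `statistic`
#'   (bits), `percent_of_max`, and when `n_perm` is given, `p_value` and
#'   `n_permutations`.
#' @export
percent_of_max_info <- function(features, label, n_perm = NULL, seed = NULL) {
  h_label <- shannon_entropy(label)
  if (h_label <= 0) stop("H(label) = 0: percent of maximum is undefined")
  stat <- mutual_information(features, label)
  res <- list(statistic = stat,
              percent_of_max = 100 * stat / h_label,
              p_value = NULL, n_permutations = NULL)
  if (!is.null(n_perm)) {
    res$p_value <- permutation_significance(mutual_information, features,
                                            label, n_perm = n_perm,
                                            seed = seed)
    res$n_permutations <- n_perm
  }
  class(res) <- "info_result"
  res
}

#' @export
print.info_result <- function(x, ...) {
  cat(sprintf("information: %.4f bits (%.1f%% of maximum)\n",
              x$statistic, x$percent_of_max))
  if (!is.null(x$p_value)) {
    cat(sprintf("permutation p = %.4g (%d permutations)\n",
                x$p_value, x$n_permutations))
  }
  invisible(x)
}

#' Incremental information gain of adding a biomarker to a panel
#'
#' \eqn{\Delta = I(\mathrm{joint}(base \cup new); label) -
#' I(\mathrm{joint}(base); label)}. Non-negative for the plug-in estimator on
#' the same sample; a significantly positive gain despite strong marginal
#' correlation between the markers (p53 and ATRX being the motivating case)
#' indicates non-redundant — possibly synergistic — diagnostic information.
#'
#' @param base_features Existing panel (vector or list/data.frame).
#' @param new_feature Candidate addition (vector/factor).
#' @param label Diagnostic label.
#' @return Information gain in bits.
#' @export
incremental_gain <- function(base_features, new_feature, label) {
  base <- .as_varlist(base_features)
  combined <- c(base, .as_varlist(new_feature))
  mutual_information(combined, label) - mutual_information(base, label)
}

#' Permutation significance of an information statistic
#'
#' The label vector is permuted `n_perm` times and the statistic recomputed;
#' the p-value uses the add-one formula
#' \eqn{p = (1 + \#\{perm \ge obs\}) / (n_{perm} + 1)}, which never returns 0.
#'
#' @param statistic_fn Function of `(x, label)` returning a scalar, e.g.
#'   [mutual_information()].
#' @param x First argument passed through unchanged.
#' @param label The vector to permute.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional integer seed.
#' @return Permutation p-value in (0, 1].
#' @export
permutation_significance <- function(statistic_fn, x, label, n_perm = 999,
                                     seed = NULL) {
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  observed <- statistic_fn(x, label)
  n <- length(label)
  # fast path: mutual information on precomputed codes
  if (identical(statistic_fn, mutual_information)) {
    cx <- .joint_codes(.as_varlist(x))
    cy <- .as_codes(label)
    ge <- 0L
    for (i in seq_len(n_perm)) {
      yp <- list(code = cy$code[sample.int(n)], n = cy$n)
      if (.mi_codes(cx, yp) >= observed) ge <- ge + 1L
    }
    return((1 + ge) / (n_perm + 1))
  }
  ge <- 0L
  for (i in seq_len(n_perm)) {
    if (statistic_fn(x, label[sample.int(n)]) >= observed) ge <- ge + 1L
  }
  (1 + ge) / (n_perm + 1)
}

#' Significance stars for permutation p-values
#'
#' Thresholds 0.05 / 0.01 / 0.001 / 0.0001 map to one to four stars.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of `""`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "")) |> as.character()
}
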