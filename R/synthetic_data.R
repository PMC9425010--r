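# Seeded generators for every input the pipeline consumes: stained tiles
# with exact ground-truth masks, on-slide control sets with planted p53
# fractions, cohort tables with the planted age / p53 / ATRX / codeletion
# association structure, and a miniature entity-specification fixture.

## ---- stained tile generator ----------------------------------------------

# rasterize one ellipse into label and concentration matrices (in place)
.paint_ellipse <- function(canvas, cx, cy, a, b, theta, value) {
  h <- nrow(canvas); w <- ncol(canvas)
  r0 <- max(1L, floor(cy - a)); r1 <- min(h, ceiling(cy + a))
  c0 <- max(1L, floor(cx - a)); c1 <- min(w, ceiling(cx + a))
  if (r0 > r1 || c0 > c1) return(canvas)
  rr <- r0:r1; cc <- c0:c1
  dy <- rr - cy
  dx <- rep(cc - cx, each = length(rr))
  dyr <- rep(dy, times = length(cc))
  u <- (dx * cos(theta) + dyr * sin(theta)) / a
  v <- (-dx * sin(theta) + dyr * cos(theta)) / b
  inside <- matrix(u^2 + v^2 <= 1, length(rr), length(cc))
  sub <- canvas[rr, cc]
  sub[inside] <- value
  canvas[rr, cc] <- sub
  canvas
}

#' Simulate a stained photomicrograph tile with ground truth
#'
#' Draws elliptical nuclei with Gaussian-perturbed geometry on a pale
#' background and renders them through the same Ruifrok-Johnston forward
#' optical-density model that [color_deconvolve()] inverts. H&E nuclei are
#' hematoxylin-purple; on DAB tiles, planted-positive nuclei are DAB-brown
#' and negative nuclei pale hematoxylin-blue. Placement is non-overlapping by
#' rejection sampling unless `allow_touching` plants touching pairs. The
#' returned mask is exact.
#'
#' @param n_nuclei Number of nuclei (>= 1).
#' @param stain_kind `"DAB"` or `"HE"`.
#' @param positive_fraction For DAB tiles, the fraction of nuclei planted
#'   positive; exactly `round(positive_fraction * n_nuclei)` are flagged.
#' @param pleomorphism Non-negative SD multiplier on nucleus radius, axis
#'   ratio and stain intensity (0 = monomorphic).
#' @param width,height Canvas size in pixels.
#' @param mean_radius Mean nucleus radius in pixels.
#' @param noise_sd Gaussian pixel noise SD (intensity units).
#' @param intensity_scale Global multiplier on nuclear stain optical density
#'   (simulates staining batch variation).
#' @param allow_touching If `TRUE`, nuclei are placed in touching pairs
#'   (for watershed-splitting tests).
#' @param allow_border If `TRUE`, nuclei may straddle the image border.
#' @param seed Integer seed.
#' @return A list with `image` (a [stain_image()]), `mask` (integer label
#'   matrix, exact ground truth) and `nuclei` (a data.frame with one row per
#'   nucleus: label, center, axes, orientation, `positive` flag).
#' @export
make_slide <- function(n_nuclei = 20, stain_kind = c("DAB", "HE"),
                       positive_fraction = 1, pleomorphism = 0.5,
                       width = 192, height = 192, mean_radius = 8,
                       noise_sd = 2, intensity_scale = 1,
                       allow_touching = FALSE, allow_border = FALSE,
                       seed = 1) {
  stain_kind <- match.arg(stain_kind)
  stopifnot(n_nuclei >= 1, positive_fraction >= 0, positive_fraction <= 1,
            pleomorphism >= 0)
  set.seed(seed)
  h <- height; w <- width
  rad <- pmax(3, stats::rnorm(n_nuclei, mean_radius, pleomorphism * 3))
  ratio <- pmin(3, pmax(1, stats::rnorm(n_nuclei, 1.25, pleomorphism * 0.25)))
  a <- rad * sqrt(ratio)
  b <- rad / sqrt(ratio)
  theta <- stats::runif(n_nuclei, 0, pi)
  # placement by rejection sampling on bounding circles
  cx <- numeric(n_nuclei); cy <- numeric(n_nuclei)
  margin <- if (allow_border) -mean_radius else 2
  placed <- 0L
  attempts <- 0L
  while (placed < n_nuclei) {
    attempts <- attempts + 1L
    if (attempts > 10000L) {
      stop("could not place ", n_nuclei, " non-overlapping nuclei in ",
           w, "x", h, "; use a larger canvas")
    }
    i <- placed + 1L
    x <- stats::runif(1, a[i] + margin, w - a[i] - margin + 1)
    y <- stats::runif(1, a[i] + margin, h - a[i] - margin + 1)
    ok <- TRUE
    if (placed > 0L) {
      dmin <- a[i] + a[seq_len(placed)] + 2
      if (any((x - cx[seq_len(placed)])^2 + (y - cy[seq_len(placed)])^2 <
              dmin^2)) ok <- FALSE
    }
    if (ok) {
      cx[i] <- x; cy[i] <- y; placed <- i
      if (allow_touching && placed < n_nuclei) {
        # plant a partner overlapping this nucleus
        j <- placed + 1L
        ang <- stats::runif(1, 0, 2 * pi)
        sep <- 0.95 * (rad[i] + rad[j])
        xj <- min(max(x + sep * cos(ang), a[j] + 2), w - a[j] - 1)
        yj <- min(max(y + sep * sin(ang), a[j] + 2), h - a[j] - 1)
        clash <- FALSE
        if (placed > 1L) {
          others <- setdiff(seq_len(placed), i)
          dmin <- a[j] + a[others] + 2
          clash <- any((xj - cx[others])^2 + (yj - cy[others])^2 < dmin^2)
        }
        if (!clash) { cx[j] <- xj; cy[j] <- yj; placed <- j }
      }
    }
  }
  n_pos <- round(positive_fraction * n_nuclei)
  positive <- rep(FALSE, n_nuclei)
  if (n_pos > 0) positive[sample.int(n_nuclei, n_pos)] <- TRUE

  mask <- matrix(0L, h, w)
  conc1 <- matrix(0, h, w)  # hematoxylin
  conc2 <- matrix(0, h, w)  # DAB or eosin
  stain_m <- default_stain_matrix(stain_kind)
  if (stain_kind == "HE") {
    conc2[] <- 0.08  # eosinophilic background haze
    conc1[] <- 0.03
  } else {
    conc1[] <- 0.04  # faint counterstain haze
    conc2[] <- 0.01
  }
  od_jit <- function(mu) {
    pmax(0.2, stats::rnorm(n_nuclei, mu, pleomorphism * 0.12))
  }
  od_main <- od_jit(if (stain_kind == "HE") 0.85 else 0.9) * intensity_scale
  od_neg <- od_jit(0.55) * intensity_scale  # hematoxylin counterstain
  for (i in seq_len(n_nuclei)) {
    mask <- .paint_ellipse(mask, cx[i], cy[i], a[i], b[i], theta[i], i)
    if (stain_kind == "HE") {
      conc1 <- .paint_ellipse(conc1, cx[i], cy[i], a[i], b[i], theta[i],
                              od_main[i])
      conc2 <- .paint_ellipse(conc2, cx[i], cy[i], a[i], b[i], theta[i], 0.05)
    } else if (positive[i]) {
      conc2 <- .paint_ellipse(conc2, cx[i], cy[i], a[i], b[i], theta[i],
                              od_main[i])
      conc1 <- .paint_ellipse(conc1, cx[i], cy[i], a[i], b[i], theta[i],
                              0.30 * intensity_scale)
    } else {
      conc1 <- .paint_ellipse(conc1, cx[i], cy[i], a[i], b[i], theta[i],
                              od_neg[i])
      conc2 <- .paint_ellipse(conc2, cx[i], cy[i], a[i], b[i], theta[i], 0.02)
    }
  }
  conc <- array(c(conc1, conc2, matrix(0, h, w)), c(h, w, 3))
  px <- forward_stain_synthesis(conc, stain_m)
  if (noise_sd > 0) px <- px + stats::rnorm(length(px), 0, noise_sd)
  px <- round(pmin(pmax(px, 0), 255))
  list(image = stain_image(px, stain_kind),
       mask = mask,
       nuclei = data.frame(label = seq_len(n_nuclei), x = cx, y = cy,
                           a = a, b = b, theta = theta, positive = positive))
}

#' Simulate an on-slide control set for the p53 workflow
#'
#' One diffusely positive control tile (fraction 1), one negative control
#' tile (fraction 0) and `n_tumor_tiles` tumor tiles at the requested planted
#' fraction, all sharing the same color model and staining-intensity factor.
#'
#' @param tumor_fraction Planted positive fraction of the tumor tiles.
#' @param n_tumor_tiles Number of tumor tiles (default 4).
#' @param n_nuclei Nuclei per tile.
#' @param intensity_scale Global stain-intensity factor applied to all tiles.
#' @param pleomorphism,width,height,noise_sd Passed to [make_slide()].
#' @param seed Integer seed.
#' @return A list of class `"slide_image_set"` with `positive_control`,
#'   `negative_control`, `tumor_tiles` (each a [make_slide()] result) and
#'   `tumor_fraction`.
#' @export
make_slide_set <- function(tumor_fraction = 0.3, n_tumor_tiles = 4,
                           n_nuclei = 40, intensity_scale = 1,
                           pleomorphism = 0.5, width = 192, height = 192,
                           noise_sd = 2, seed = 1) {
  mk <- function(frac, s) {
    make_slide(n_nuclei = n_nuclei, stain_kind = "DAB",
               positive_fraction = frac, pleomorphism = pleomorphism,
               width = width, height = height, noise_sd = noise_sd,
               intensity_scale = intensity_scale, seed = s)
  }
  tumor <- lapply(seq_len(n_tumor_tiles),
                  function(i) mk(tumor_fraction, seed + 100 + i))
  structure(list(positive_control = mk(1, seed + 1),
                 negative_control = mk(0, seed + 2),
                 tumor_tiles = tumor,
                 tumor_fraction = tumor_fraction),
            class = "slide_image_set")
}

## ---- cohort generator -----------------------------------------------------

#' Simulate an IDH-mutant glioma cohort with planted associations
#'
#' Ancestral sampling: codeletion ~ Bernoulli(prevalence); age Gaussian per
#' class truncated at 18 years with the codeleted class older; p53 positivity
#' Bernoulli with class-conditional rates (anti-associated with codeletion);
#' ATRX mutation coupled to both p53 and codeletion (mutation essentially
#' excluded in codeleted tumors, enriched in p53-positive non-codeleted
#' tumors); gender independent of everything.
#'
#' @param n Number of patients.
#' @param codel_prevalence P(1p/19q codeleted).
#' @param age_mean_codel,age_mean_noncodel,age_sd Age model (years).
#' @param p_p53_codel,p_p53_noncodel Class-conditional p53 positivity rates.
#' @param p_atrx_codel P(ATRX mutant | codeleted).
#' @param p_atrx_noncodel_p53pos,p_atrx_noncodel_p53neg Coupling of ATRX to
#'   p53 within non-codeleted tumors.
#' @param gender_balance P(male).
#' @param missing_atrx_rate Fraction of rows with ATRX set to `NA`.
#' @param seed Integer seed.
#' @return A data.frame with columns `age`, `gender` (`"M"`/`"F"`), `p53`
#'   (0/1), `ATRX` (`"mutant"`/`"wildtype"`/`NA`), `codel_1p19q` (0/1).
#' @export
make_cohort <- function(n = 1000, codel_prevalence = 0.445,
                        age_mean_codel = 47, age_mean_noncodel = 38,
                        age_sd = 12, p_p53_codel = 0.10,
                        p_p53_noncodel = 0.70, p_atrx_codel = 0.05,
                        p_atrx_noncodel_p53pos = 0.85,
                        p_atrx_noncodel_p53neg = 0.45,
                        gender_balance = 0.5, missing_atrx_rate = 0,
                        seed = 1) {
  set.seed(seed)
  codel <- stats::rbinom(n, 1, codel_prevalence)
  mu <- ifelse(codel == 1, age_mean_codel, age_mean_noncodel)
  age <- stats::rnorm(n, mu, age_sd)
  while (any(age < 18)) {  # truncate at 18 by resampling
    i <- age < 18
    age[i] <- stats::rnorm(sum(i), mu[i], age_sd)
  }
  p53 <- stats::rbinom(n, 1, ifelse(codel == 1, p_p53_codel, p_p53_noncodel))
  p_atrx <- ifelse(codel == 1, p_atrx_codel,
                   ifelse(p53 == 1, p_atrx_noncodel_p53pos,
                          p_atrx_noncodel_p53neg))
  atrx <- ifelse(stats::rbinom(n, 1, p_atrx) == 1, "mutant", "wildtype")
  if (missing_atrx_rate > 0) {
    atrx[stats::runif(n) < missing_atrx_rate] <- NA_character_
  }
  gender <- ifelse(stats::rbinom(n, 1, gender_balance) == 1, "M", "F")
  data.frame(age = age, gender = gender, p53 = p53, ATRX = atrx,
             codel_1p19q = codel)
}

## ---- entity-spec fixture ---------------------------------------------------

#' Write a miniature 8-entity brain-tumor simulation specification
#'
#' A small, fully synthetic counterpart of a literature-derived entity by
#' feature table: 8 CNS tumor entities with distinct age, site, Ki67 and
#' binary-marker signatures. Two entities (grade 2 and grade 3 IDH-mutant
#' astrocytoma) deliberately overlap so the population classifier has a
#' realistic confusion structure; the rest are separable.
#'
#' @param path Output CSV path (defaults to a tempfile).
#' @return The path, invisibly usable with [load_entity_spec()].
#' @export
make_entity_spec_fixture <- function(path = tempfile(fileext = ".csv")) {
  df <- data.frame(
    entity = c("astrocytoma_idh_mut_g2", "oligodendroglioma",
               "glioblastoma_idh_wt", "pilocytic_astrocytoma",
               "ependymoma_pf", "medulloblastoma", "meningioma",
               "astrocytoma_idh_mut_g3"),
    weight = c(0.12, 0.08, 0.30, 0.08, 0.07, 0.07, 0.20, 0.08),
    age_family = "truncnorm",
    age_p1 = c(38, 47, 62, 12, 8, 7, 55, 42),
    age_p2 = c(10, 10, 10, 6, 5, 4, 12, 10),
    ki67_family = "truncnorm",
    ki67_p1 = c(4, 6, 25, 2, 4, 40, 3, 10),
    ki67_p2 = c(2, 3, 8, 1, 2, 10, 2, 3),
    p_male = c(0.55, 0.55, 0.6, 0.5, 0.55, 0.65, 0.35, 0.55),
    check.names = FALSE
  )
  df[["site:cerebrum"]]   <- c(0.90, 0.95, 0.95, 0.15, 0.05, 0.02, 0.85, 0.90)
  df[["site:cerebellum"]] <- c(0.04, 0.02, 0.02, 0.70, 0.35, 0.95, 0.05, 0.04)
  df[["site:brainstem"]]  <- c(0.03, 0.02, 0.02, 0.10, 0.30, 0.02, 0.02, 0.03)
  df[["site:spine"]]      <- c(0.03, 0.01, 0.01, 0.05, 0.30, 0.01, 0.08, 0.03)
  df[["feat:gfap"]]          <- c(0.95, 0.80, 0.95, 0.98, 0.90, 0.10, 0.02, 0.95)
  df[["feat:olig2"]]         <- c(0.90, 0.98, 0.80, 0.60, 0.10, 0.10, 0.02, 0.90)
  df[["feat:idh1_r132h"]]    <- c(0.90, 0.90, 0.02, 0.00, 0.00, 0.00, 0.00, 0.90)
  df[["feat:codel_1p19q"]]   <- c(0.02, 0.98, 0.02, 0.00, 0.00, 0.00, 0.00, 0.02)
  df[["feat:atrx_loss"]]     <- c(0.80, 0.05, 0.10, 0.02, 0.02, 0.02, 0.02, 0.80)
  df[["feat:p53"]]           <- c(0.75, 0.10, 0.40, 0.05, 0.10, 0.30, 0.10, 0.75)
  df[["feat:necrosis"]]      <- c(0.05, 0.05, 0.95, 0.02, 0.10, 0.30, 0.02, 0.15)
  df[["feat:synaptophysin"]] <- c(0.02, 0.05, 0.02, 0.02, 0.05, 0.95, 0.05, 0.02)
  df[["feat:ema"]]           <- c(0.02, 0.02, 0.02, 0.02, 0.60, 0.02, 0.90, 0.02)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

## ---- end-to-end per-case feature generator ---------------------------------

#' Generate composite case feature vectors with planted class structure
#'
#' Builds, per synthetic case, the three feature families the codeletion
#' model consumes: (1) nuclear density features computed from a simulated
#' Olig2 tile through the real feature-extraction path (feature table, pooled
#' PCA, kNN distances), with codeleted (oligodendroglioma-like) cases planted
#' monomorphic and non-codeleted (astrocytoma-like) cases pleomorphic;
#' (2) a percent-p53 value mirroring the observed class-conditional
#' distributions (codeleted mostly low, non-codeleted widely spread); and
#' (3) an ATRX/age codeletion probability from a model fitted on a simulated
#' global cohort.
#'
#' @param n_cases Number of cases (balanced classes, `floor(n/2)` codeleted).
#' @param n_nuclei Nuclei per simulated tile.
#' @param n_sample Nuclei sampled per case for density features.
#' @param ks Neighbor ranks for density features.
#' @param pleo_codel,pleo_noncodel Planted pleomorphism per class.
#' @param seed Integer seed.
#' @return A data.frame: one row per case with density features, `p53_percent`,
#'   `atrx_age_prob` and the true `codel_1p19q` label.
#' @export
make_case_features <- function(n_cases = 60, n_nuclei = 55, n_sample = 45,
                               ks = c(10, 20), pleo_codel = 0.25,
                               pleo_noncodel = 1.3, seed = 1) {
  set.seed(seed)
  codel <- rep(c(1, 0), length.out = n_cases)
  # global cohort for the ATRX/age probability feature
  cohort <- make_cohort(n = 1200, seed = seed + 7919)
  atrx_model <- fit_atrx_age_model(cohort, seed = seed + 13)
  tables <- vector("list", n_cases)
  age <- numeric(n_cases)
  atrx <- character(n_cases)
  p53_percent <- numeric(n_cases)
  for (i in seq_len(n_cases)) {
    pleo <- if (codel[i] == 1) pleo_codel else pleo_noncodel
    sl <- make_slide(n_nuclei = n_nuclei, stain_kind = "DAB",
                     positive_fraction = 1, pleomorphism = pleo,
                     width = 288, height = 288, seed = seed + i)
    tables[[i]] <- extract_nucleus_features(sl$image, sl$mask)
    if (codel[i] == 1) {
      age[i] <- max(18, stats::rnorm(1, 47, 12))
      atrx[i] <- if (stats::runif(1) < 0.05) "mutant" else "wildtype"
      p53_percent[i] <- stats::runif(1, 0, 15)
    } else {
      age[i] <- max(18, stats::rnorm(1, 38, 12))
      atrx[i] <- if (stats::runif(1) < 0.7) "mutant" else "wildtype"
      p53_percent[i] <- stats::runif(1, 20, 95)
    }
  }
  # pooled PCA across cases so per-case distances are comparable
  pooled <- do.call(rbind, tables)
  pca <- pca_reduce(pooled, variance_target = 0.9)
  idx_end <- cumsum(vapply(tables, nrow, 1L))
  idx_start <- c(1L, utils::head(idx_end, -1L) + 1L)
  dens <- lapply(seq_len(n_cases), function(i) {
    sc <- pca$scores[idx_start[i]:idx_end[i], , drop = FALSE]
    density_features(sc, n_sample = min(n_sample, nrow(sc)), ks = ks,
                     seed = seed + i)
  })
  dens_df <- do.call(rbind, lapply(dens, function(d) {
    as.data.frame(as.list(d$features))
  }))
  prob <- predict_codel_prob(atrx_model, data.frame(ATRX = atrx, age = age))
  cbind(dens_df,
        data.frame(p53_percent = p53_percent, atrx_age_prob = prob,
                   age = age, ATRX = atrx, codel_1p19q = codel))
}
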