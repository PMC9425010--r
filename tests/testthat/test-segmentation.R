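# Color deconvolution, the three segmentation methods, mask IO and scoring.

test_that("stain_image validates its input", {
  px <- array(128, c(16, 16, 3))
  img <- stain_image(px, "DAB")
  expect_s3_class(img, "stain_image")
  expect_error(stain_image(matrix(1, 16, 16)), "H x W x 3")
  expect_error(stain_image(array(300, c(16, 16, 3))), "\\[0, 255\\]")
  expect_error(stain_image(array(0, c(8, 8, 3))), "16 x 16")
})

test_that("default stain matrices have unit rows and match stain chemistry", {
  for (kind in c("DAB", "HE")) {
    m <- default_stain_matrix(kind)
    expect_equal(unname(sqrt(rowSums(m^2))), rep(1, 3), tolerance = 1e-12)
  }
  expect_true("D" %in% rownames(default_stain_matrix("DAB")))
  expect_true("E" %in% rownames(default_stain_matrix("HE")))
  expect_true("H" %in% rownames(default_stain_matrix("DAB")))
})

test_that("white pixels carry exactly zero optical density", {
  px <- array(255, c(16, 16, 3))
  od <- color_deconvolve(stain_image(px, "DAB"))
  for (ch in od) expect_equal(max(abs(ch)), 0)
})

test_that("forward synthesis and deconvolution are mutual inverses", {
  set.seed(1)
  n <- 24 * 24
  conc <- array(c(runif(n, 0, 0.8), runif(n, 0, 0.8), rep(0, n)),
                c(24, 24, 3))
  m <- default_stain_matrix("DAB")
  px <- forward_stain_synthesis(conc, m)
  back <- color_deconvolve(stain_image(px, "DAB"), m)
  expect_equal(back$H, conc[, , 1], tolerance = 1e-9)
  expect_equal(back$D, conc[, , 2], tolerance = 1e-9)
})

test_that("deconv-Otsu recovers count and IoU on a clean DAB tile", {
  s <- dab_slide()
  m <- segment_deconv_otsu(s$image)
  expect_equal(max(m), 20)
  sc <- evaluate_segmentation(m, s$mask)
  expect_gte(sc$iou, 0.9)
  expect_gte(sc$accuracy, 0.95)
})

test_that("deconv-Otsu works on H&E via the hematoxylin channel", {
  s <- he_slide()
  m <- segment_deconv_otsu(s$image)
  sc <- evaluate_segmentation(m, s$mask)
  expect_gte(sc$iou, 0.85)
})

test_that("deconv-Otsu returns an empty mask on a blank tile", {
  px <- array(250, c(64, 64, 3))
  m <- segment_deconv_otsu(stain_image(px, "DAB"))
  expect_equal(max(m), 0)
})

test_that("border-touching nuclei are eliminated", {
  s <- make_slide(n_nuclei = 12, stain_kind = "DAB", allow_border = TRUE,
                  seed = 9)
  m <- segment_deconv_otsu(s$image)
  edge <- c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)])
  expect_true(all(edge == 0))
})

test_that("watershed splits planted touching nuclei", {
  s <- make_slide(n_nuclei = 10, stain_kind = "DAB", allow_touching = TRUE,
                  seed = 4)
  m <- segment_deconv_otsu(s$image)
  # the binarized truth has ~6 merged blobs; watershed must recover most of
  # the 10 planted nuclei
  blobs <- max(.bwlabel_compare <- EBImage::bwlabel(EBImage::Image(t(s$mask > 0))))
  expect_gt(max(m), blobs)
  expect_gte(max(m), 9)
})

test_that("the target channel must match the stain kind", {
  expect_error(segment_deconv_otsu(he_slide()$image, target = "D"),
               "does not match")
  expect_error(segment_deconv_otsu(he_slide()$image, target = "HD"),
               "H-DAB")
})

test_that("k-means segmentation recovers the clean tile", {
  s <- dab_slide()
  m <- segment_kmeans(s$image, seed = 1)
  sc <- evaluate_segmentation(m, s$mask)
  expect_gte(sc$iou, 0.8)
  expect_error(segment_kmeans(s$image, k = 1), ">= 2")
})

test_that("cut-cluster-classify segmentation recovers the clean tile", {
  s <- dab_slide()
  m <- segment_ccc(s$image, seed = 1)
  sc <- evaluate_segmentation(m, s$mask)
  expect_gte(sc$iou, 0.8)
})

test_that("evaluate_segmentation scores binarized overlap correctly", {
  a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L
  b <- matrix(0L, 4, 4); b[1:2, 1:2] <- 3L; b[3, 3] <- 4L
  sc <- evaluate_segmentation(a, b)
  expect_equal(sc$accuracy, 15 / 16)
  expect_equal(sc$iou, 4 / 5)
  # empty vs empty is perfect agreement by convention
  z <- matrix(0L, 4, 4)
  expect_equal(evaluate_segmentation(z, z)$iou, 1)
  expect_equal(evaluate_segmentation(z, b)$iou, 0)
  expect_error(evaluate_segmentation(a, matrix(0L, 3, 3)), "shapes differ")
})

test_that("image and mask round-trip through files losslessly", {
  s <- dab_slide()
  f_img <- tempfile(fileext = ".png")
  f_tif <- tempfile(fileext = ".tif")
  f_png <- tempfile(fileext = ".png")
  write_stain_image(s$image, f_img)
  expect_equal(read_stain_image(f_img, "DAB")$pixels, s$image$pixels)
  write_label_mask(s$mask, f_tif)
  expect_equal(read_label_mask(f_tif), s$mask)
  write_label_mask(s$mask, f_png)
  expect_equal(read_label_mask(f_png), s$mask)
  # PNG is 8-bit: wide label ranges must be refused, not corrupted
  expect_error(write_label_mask(matrix(300L, 4, 4), f_png), "at most 255")
  unlink(c(f_img, f_tif, f_png))
})
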