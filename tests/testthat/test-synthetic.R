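test_that("the two-class generator honors counts and is bitwise reproducible", {
  p <- htp_gen_params(n_samples = 20, class1_fraction = 0.2, canvas_side = 96, seed = 4)
  ds1 <- generate_htp_like(p)
  expect_length(ds1$images, 20)
  expect_equal(sum(ds1$labels), 4)             # exactly round(20 * 0.2)
  ds2 <- generate_htp_like(p)
  expect_identical(ds1$labels, ds2$labels)
  for (i in c(1, 7, 20))
    expect_identical(ds1$images[[i]]$pixels, ds2$images[[i]]$pixels)
  # a different seed changes the drawings but not the counts
  ds3 <- generate_htp_like(htp_gen_params(n_samples = 20, class1_fraction = 0.2,
                                          canvas_side = 96, seed = 5))
  expect_equal(sum(ds3$labels), 4)
  expect_false(identical(ds1$images[[1]]$pixels, ds3$images[[1]]$pixels))
  expect_error(htp_gen_params(canvas_side = 32), "canvas too small")
  expect_error(htp_gen_params(class1_fraction = 0), "class1_fraction")
})

test_that("depressed-class sketches are darker across seeds", {
  darker <- vapply(1:15, function(s) {
    ds <- generate_htp_like(htp_gen_params(n_samples = 30, canvas_side = 96, seed = 100 + s))
    mi <- vapply(ds$images, function(im) mean(im$pixels), numeric(1))
    mean(mi[ds$labels == 1]) < mean(mi[ds$labels == 0])
  }, logical(1))
  expect_gte(sum(darker), 14)
})

test_that("class-conditional signal is monotone in the darkness margin", {
  # with motif probabilities equalized, the darkness margin is the only
  # class signal; a threshold probe on mean intensity tracks it
  eq_motifs <- list(normal = c(rain = 0.3, cracks = 0.3, bare = 0.3, smooth = 0.6),
                    depressed = c(rain = 0.3, cracks = 0.3, bare = 0.3, smooth = 0.6))
  probe_acc <- function(margin) {
    ds <- generate_htp_like(htp_gen_params(n_samples = 120, class1_fraction = 0.5,
                                           canvas_side = 96, darkness_margin = margin,
                                           motif_probs = eq_motifs, seed = 11))
    mi <- vapply(ds$images, function(im) mean(im$pixels), numeric(1))
    tr <- seq_len(60); te <- 61:120
    fit <- suppressWarnings(stats::glm((ds$labels == 1)[tr] ~ mi[tr], family = "binomial"))
    pred <- stats::predict(fit, newdata = data.frame(mi = mi)[te, , drop = FALSE],
                           type = "response") > 0.5
    mean(pred == (ds$labels[te] == 1))
  }
  acc <- vapply(c(0, 0.15, 0.4), probe_acc, numeric(1))
  # no-signal control sits near chance; accuracy is non-decreasing in the margin
  expect_lt(acc[1], 0.7)
  expect_gte(acc[2] + 0.05, acc[1])
  expect_gte(acc[3] + 0.05, acc[2])
  expect_gt(acc[3], 0.8)
})

test_that("glyph corpus is balanced white-on-black with per-sample jitter", {
  p <- qd_gen_params(n_classes = 10, n_train = 2, n_val = 1, n_test = 1,
                     canvas_side = 64, seed = 6)
  qd <- generate_quickdraw_like(p)
  expect_length(qd$images, 40)
  expect_equal(as.vector(table(qd$labels)), rep(4, 10))
  expect_equal(sum(qd$split == "train"), 20)
  for (im in qd$images[c(1, 15, 40)]) {
    expect_equal(im$background, "black")
    expect_equal(im$pixels[1, 1, 1], 0)        # corner stays background
    expect_gte(min(im$pixels), 0)
    expect_lte(max(im$pixels), 255)
    expect_gt(max(im$pixels), 200)             # strokes are white
  }
  # same class order, different jitter across seeds
  qd2 <- generate_quickdraw_like(qd_gen_params(n_classes = 10, n_train = 2, n_val = 1,
                                               n_test = 1, canvas_side = 64, seed = 7))
  expect_identical(qd$labels, qd2$labels)
  expect_false(identical(qd$images[[1]]$pixels, qd2$images[[1]]$pixels))
  expect_error(qd_gen_params(n_classes = 99), "glyph families")
})

test_that("color inversion is an involution that matches the clinical polarity", {
  img <- sketch_image(matrix(0, 8, 8), background = "black")
  inv <- invert_colors(img)
  expect_true(all(inv$pixels == 255))
  expect_equal(inv$background, "white")
  expect_identical(invert_colors(inv)$pixels, img$pixels)

  qd <- generate_quickdraw_like(qd_gen_params(n_classes = 2, n_train = 1, n_val = 1,
                                              n_test = 1, canvas_side = 64, seed = 8))
  conv <- invert_colors(qd$images[[1]])
  expect_equal(conv$background, "white")
  # after conversion: light background, dark strokes
  expect_gt(mean(conv$pixels), 180)
  expect_lt(min(conv$pixels), 60)
})

test_that("datasets round-trip through PNG files and a manifest", {
  ds <- small_htp(n = 3, canvas = 96)
  dir <- tempfile(); on.exit(unlink(dir, recursive = TRUE))
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_length(list.files(dir, pattern = "\\.png$"), 3)
  back <- read_dataset(dir)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$images[[2]]$pixels, ds$images[[2]]$pixels)
})
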