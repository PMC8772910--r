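test_that("normalized histogram counts member pixels", {
  h <- compute_histogram(c(0, 0, 255, 255))
  expect_equal(h$h[1], 0.5)
  expect_equal(h$h[256], 0.5)
  expect_equal(sum(h$h), 1)
  expect_equal(compute_histogram(rep(7, 5))$h[8], 1)
  expect_error(compute_histogram(c(0, 256)), "0..255")
  expect_error(compute_histogram(integer(0)), "no pixel")

  set.seed(21)
  v <- sample(0:255, 256, TRUE)
  expect_equal(compute_histogram(v)$h, oracle_histogram(v))
})

test_that("HS features match hand values on a two-point symmetric histogram", {
  hs <- hs_features(compute_histogram(c(0, 0, 255, 255)))
  expect_equal(hs[["Mean"]], 127.5)
  expect_equal(hs[["Variance"]], 16256.25)
  expect_equal(hs[["Skewness"]], 0)
  expect_equal(hs[["Kurtosis"]], -2)
  expect_equal(hs[["Perc01"]], 0)
  expect_equal(hs[["Perc50"]], 0)
  expect_equal(hs[["Perc90"]], 255)
})

test_that("HS features of a constant plane are degenerate but defined", {
  hs <- hs_features(compute_histogram(rep(42, 30)))
  expect_equal(hs[["Variance"]], 0)
  expect_equal(hs[["Skewness"]], 0)
  expect_equal(hs[["Kurtosis"]], 0)
  expect_equal(hs[["Maxm01"]], 1)
  expect_equal(hs[["Perc01"]], 42)
  expect_equal(hs[["Perc99"]], 42)
  expect_equal(hs[["Domn01"]], 42)
})

test_that("HS features match the direct-summation oracle on random planes", {
  for (seed in 1:20) {
    v <- as.vector(random_plane(seed))
    got <- hs_features(compute_histogram(v))
    expect_equal(got, oracle_hs(v), tolerance = 1e-12)
  }
})

test_that("run-length matrices count maximal runs, masks break them", {
  row <- matrix(c(5L, 5L, 5L, 5L), 1, 4)
  m <- build_glrlm(row, direction = 0)
  expect_equal(m$np, 1)
  expect_equal(m$counts[6, 4], 1)
  expect_equal(sum(m$counts), 1)

  alt <- matrix(c(1L, 2L, 1L, 2L), 1, 4)
  m2 <- build_glrlm(alt, direction = 0)
  expect_equal(m2$np, 4)
  expect_true(all(which(m2$counts > 0, arr.ind = TRUE)[, "col"] == 1))

  # a masked-out pixel splits one run of 4 into two runs of 1 and 2
  mask <- roi_mask(matrix(c(TRUE, TRUE, FALSE, TRUE), 1, 4))
  m3 <- build_glrlm(row, mask, direction = 0)
  expect_equal(m3$counts[6, 2], 1)
  expect_equal(m3$counts[6, 1], 1)
  expect_equal(m3$total_pixels, 3)

  expect_error(build_glrlm(row, direction = 30), "direction")
})

test_that("GLRLM features match hand evaluation and the j==1 degenerate case", {
  single <- glrlm_features(build_glrlm(matrix(rep(5L, 4), 1, 4), direction = 0))
  expect_equal(single[["GLN"]], 1)
  expect_equal(single[["RLN"]], 1)
  expect_equal(single[["LRE"]], 16)
  expect_equal(single[["SRE"]], 0.0625)
  expect_equal(single[["Fraction"]], 0.25)
  expect_equal(single[["MRLN"]], 1)
  expect_equal(single[["MGLN"]], 1)

  allone <- glrlm_features(build_glrlm(matrix(c(1L, 2L, 1L, 2L), 1, 4),
                                       direction = 0))
  expect_equal(allone[["LRE"]], 1)
  expect_equal(allone[["SRE"]], 1)
  expect_equal(allone[["Fraction"]], 1)
})

test_that("GLRLM matches the scan-line oracle in every direction", {
  for (seed in 1:8) {
    plane <- random_plane(seed, 8, 8, bits = 3)
    mask <- if (seed %% 2) NULL else roi_rect(8, 8, c(2, 7), c(2, 6))
    for (dir in c(0, 45, 90, 135)) {
      got <- build_glrlm(plane, mask, dir, bits = 3)
      want <- oracle_glrlm_matrix(plane, mask, dir, bits = 3)
      len <- ncol(got$counts)
      expect_equal(unname(got$counts), unname(want[, seq_len(len), drop = FALSE]),
                   ignore_attr = TRUE)
      if (ncol(want) > len) expect_equal(sum(want[, -seq_len(len)]), 0)
      expect_equal(glrlm_features(got), oracle_glrlm_features(want),
                   tolerance = 1e-12)
    }
  }
})

test_that("co-occurrence accumulation is symmetric and normalized", {
  pair <- matrix(c(1L, 2L), 1, 2)
  raw <- build_glcm(pair, d = 1, direction = 0, normalize = FALSE)
  expect_equal(raw$p[2, 3], 1)
  expect_equal(raw$p[3, 2], 1)
  expect_equal(sum(raw$p), 2)

  checker <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  norm <- build_glcm(checker, d = 1, direction = 0)
  expect_equal(norm$p[1, 2], 0.5)
  expect_equal(norm$p[2, 1], 0.5)
  expect_equal(sum(norm$p), 1)

  const <- build_glcm(matrix(9L, 3, 3), d = 1, direction = 0)
  expect_equal(const$p[10, 10], 1)
  expect_equal(sum(const$p > 0), 1)

  tiny <- roi_mask(matrix(c(TRUE, rep(FALSE, 3)), 2, 2))
  expect_error(build_glcm(matrix(0L, 2, 2), tiny, d = 1, direction = 0),
               "no valid pixel pair")
})

test_that("Haralick features match hand values on degenerate matrices", {
  const <- glcm_features(build_glcm(matrix(9L, 3, 3), d = 1, direction = 0))
  expect_equal(const[["AngScMom"]], 1)
  expect_equal(const[["Contrast"]], 0)
  expect_equal(const[["Entropy"]], 0)
  expect_equal(const[["InvDefMom"]], 1)
  expect_equal(const[["Correlat"]], 0) # degenerate marginal convention

  checker <- glcm_features(build_glcm(matrix(c(0L, 1L, 1L, 0L), 2, 2),
                                      d = 1, direction = 0))
  expect_equal(checker[["Contrast"]], 1)
  expect_equal(checker[["AngScMom"]], 0.5)
  expect_equal(checker[["Entropy"]], 1) # log base 2

  expect_error(
    glcm_features(build_glcm(matrix(9L, 3, 3), d = 1, direction = 0,
                             normalize = FALSE)),
    "normalized"
  )
})

test_that("GLCM features match the double-loop oracle with marginals", {
  for (seed in 1:6) {
    plane <- random_plane(seed, 8, 8, bits = 4)
    mask <- if (seed %% 2) NULL else roi_rect(8, 8, c(2, 8), c(1, 7))
    for (dir in c(0, 45, 90, 135)) {
      got <- glcm_features(build_glcm(plane, mask, 1, dir, bits = 4))
      want <- oracle_glcm_features(oracle_glcm_matrix(plane, mask, 1, dir, bits = 4))
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("texture feature vector is complete, ordered, and deterministic", {
  plane <- random_plane(31, 12, 12)
  tf <- texture_features(plane)
  fams <- texture_feature_names()
  expect_equal(names(tf), c(fams$hs, fams$glrlm, fams$glcm))
  expect_equal(length(tf), 31)
  expect_true(all(is.finite(tf)))
  expect_identical(tf, texture_features(plane))
  expect_true(tf[["AngScMom"]] > 0 && tf[["AngScMom"]] <= 1)
  expect_true(tf[["SRE"]] > 0 && tf[["SRE"]] <= 1)
  expect_true(all(tf[c("SumEntrp", "Entropy", "DifEntrp")] >= 0))
})

test_that("constant planes zero the spread features and saturate uniformity", {
  tf <- texture_features(matrix(77L, 10, 10))
  expect_equal(unname(tf[c("Variance", "Contrast", "Entropy",
                           "SumEntrp", "DifEntrp")]),
               rep(0, 5))
  expect_equal(tf[["AngScMom"]], 1)
  expect_equal(tf[["InvDefMom"]], 1)
})

test_that("horizontal mirroring leaves 0-degree GLCM features unchanged", {
  for (seed in 1:5) {
    plane <- random_plane(seed, 9, 11)
    mirrored <- plane[, ncol(plane):1]
    f1 <- glcm_features(build_glcm(plane, d = 1, direction = 0))
    f2 <- glcm_features(build_glcm(mirrored, d = 1, direction = 0))
    expect_equal(f1, f2, tolerance = 1e-12)
  }
})

test_that("gray-level shifts move location features and spare spread features", {
  plane <- random_plane(5, 10, 10, bits = 6) # headroom for the shift
  shift <- 50L
  f1 <- texture_features(plane)
  f2 <- texture_features(plane + shift)
  spared <- c("Variance", "Contrast", "Entropy", "AngScMom", "SumEntrp",
              "DifEntrp", "DifVarnc", "SumVarnc", "SumOfSqs", "Skewness",
              "Kurtosis", "Maxm01", "Maxm10",
              "GLN", "RLN", "LRE", "SRE", "Fraction", "MRLN", "MGLN")
  expect_equal(f1[spared], f2[spared], tolerance = 1e-9)
  shifted_by_1 <- c("Mean", "Perc01", "Perc10", "Perc50", "Perc90", "Perc99",
                    "Domn01", "Domn10")
  expect_equal(f1[shifted_by_1] + shift, f2[shifted_by_1], tolerance = 1e-9)
  expect_equal(f1[["SumAverg"]] + 2 * shift, f2[["SumAverg"]], tolerance = 1e-9)
})

test_that("feature values are invariant to pixel traversal order", {
  # histogram and matrices are set statistics; rotating the plane by 180
  # degrees reverses every scan line without changing runs or pairs
  plane <- random_plane(8, 10, 10)
  rot <- plane[nrow(plane):1, ncol(plane):1]
  expect_equal(texture_features(plane), texture_features(rot),
               tolerance = 1e-12)
})

test_that("requantization compresses the gray range order-preservingly", {
  plane <- matrix(c(0L, 63L, 64L, 255L), 2, 2)
  q <- requantize_plane(plane, 2)
  expect_equal(as.vector(q), c(0L, 0L, 1L, 3L))
})

test_that("extraction yields 372 texture cells per image and skips bad images", {
  masks <- default_roi_masks(c(40, 50))
  cfg <- sim_config(image_size = c(40, 50), seed = 5)
  field <- generate_temperature_field(cfg, "A", "H1", "post", "H", masks)
  img <- render_pseudocolor(field)
  tex_cfg <- texture_config(bits = 5)
  tab <- extract_all_features(
    list(img1 = img, img2 = img), masks,
    fields = list(img1 = field, img2 = field), config = tex_cfg
  )
  feat_cols <- grep("^ROI[0-9]+_[RGB]_", names(tab), value = TRUE)
  expect_equal(length(feat_cols), 372)
  expect_equal(length(grep("_T(aver|max|min)$", names(tab))), 12)
  expect_equal(nrow(tab), 2)
  # duplicate image gives identical rows
  expect_equal(unlist(tab[1, feat_cols]), unlist(tab[2, feat_cols]))

  # an image with mismatched masks is skipped, the run continues
  small <- render_pseudocolor(matrix(30, 10, 10))
  expect_warning(
    tab2 <- extract_all_features(list(ok = img, bad = small), masks,
                                 config = tex_cfg),
    "skipping image bad"
  )
  expect_equal(tab2$image_id, "ok")
})

test_that("long pivot preserves cell values and keys", {
  masks <- default_roi_masks(c(30, 40))[1:2]
  img <- render_pseudocolor(matrix(runif(1200, 25, 35), 30, 40))
  wide <- extract_all_features(list(a = img), masks,
                               config = texture_config(bits = 4))
  long <- feature_table_long(wide)
  expect_equal(nrow(long), 2 * 3 * 31)
  cell <- long[long$roi == "ROI1" & long$component == "R" &
                 long$feature == "Mean", "value"]
  expect_equal(cell, wide[["ROI1_R_Mean"]])
})
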