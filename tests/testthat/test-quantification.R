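test_that("cystic index is the union fraction of the image", {
  s <- cyst_set(100, 100, "kidney")
  expect_equal(cystic_index(s), 0)
  # one cyst covering exactly half the image (columns 0..49)
  half <- cyst_set(100, 100, "kidney", calibration(1),
                   list(cyst_contour(1, rbind(c(0, 0), c(49, 0), c(49, 99),
                                              c(0, 99)), 100, 100)))
  expect_equal(cystic_index(half), 50)
  # overlapping polygons are counted once: compare to a rasterize-union
  # oracle over 30 random rectangles
  set.seed(61)
  cysts <- lapply(1:30, function(i) {
    x0 <- sample(0:70, 1); y0 <- sample(0:70, 1)
    w <- sample(5:25, 1); h <- sample(5:25, 1)
    cyst_contour(i, rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h),
                          c(x0, y0 + h)), 100, 100)
  })
  rset <- cyst_set(100, 100, "liver", calibration(1), cysts)
  acc <- matrix(FALSE, 100, 100)
  for (cy in cysts) acc <- acc | mask_region(cy, 100, 100)
  expect_equal(cystic_index(rset), 100 * sum(acc) / 1e4)
  # a tissue mask restricts numerator and denominator
  tm <- matrix(FALSE, 100, 100); tm[, 1:50] <- TRUE
  expect_equal(cystic_index(half, tm), 100)
})

test_that("cyst counting is the set cardinality", {
  s <- cyst_set(50, 50, "kidney")
  expect_equal(count_cysts(s), 0)
  s <- add_cyst(s, square_poly(5, 5, 6))
  expect_equal(count_cysts(s), 1)
  set.seed(62)
  n <- sample(3:9, 1)
  for (k in seq_len(n)) s <- add_cyst(s, square_poly(5 + 4 * k, 20, 3))
  expect_equal(count_cysts(s), n + 1)
})

test_that("size profile bins diameters with an overflow tail", {
  mk <- function(diams) {
    cysts <- lapply(seq_along(diams), function(i) {
      a <- round(pi * (diams[i] / 2)^2)
      structure(list(id = i, area_px = a,
                     equiv_diameter_px = diams[i], origin = "auto",
                     region = integer(a)),
                class = "cyst_contour")
    })
    s <- cyst_set(2000, 2000, "kidney")
    s$cysts <- cysts
    names(s$cysts) <- seq_along(diams)
    s
  }
  p <- size_profile(mk(c(50, 150, 650)), 100)
  expect_equal(as.integer(p), c(1, 1, 0, 0, 0, 1))
  p0 <- size_profile(cyst_set(100, 100, "kidney"), 100)
  expect_equal(as.integer(p0), rep(0L, 6))
  # 200 random diameters vs direct binning oracle; mass conservation
  set.seed(63)
  d <- runif(200, 1, 900)
  p2 <- size_profile(mk(d), 100)
  oracle <- integer(6)
  for (x in d) {
    b <- min(floor(x / 100), 5) + 1
    oracle[b] <- oracle[b] + 1L
  }
  expect_equal(as.integer(p2), oracle)
  expect_equal(sum(p2), 200)
})

test_that("severity classes follow the organ-specific cut points", {
  expect_equal(classify_severity(22.25, "kidney"), "mild_cystic")
  expect_equal(classify_severity(63.26, "kidney"), "severely_cystic")
  expect_equal(classify_severity(35, "kidney"), "cystic")     # boundary up
  expect_equal(classify_severity(55, "kidney"), "cystic")
  expect_equal(classify_severity(55.01, "kidney"), "severely_cystic")
  expect_equal(classify_severity(4.9, "liver"), "mild_cystic")
  expect_equal(classify_severity(5, "liver"), "cystic")
  expect_equal(classify_severity(15, "liver"), "cystic")
  expect_equal(classify_severity(22.78, "liver"), "severely_cystic")
  expect_error(classify_severity(120, "kidney"), "0, 100")
})

test_that("CSV export writes one row per image and parses back", {
  f <- tempfile(fileext = ".csv")
  export_csv(list(), f)
  empty <- read.csv(f)
  expect_equal(nrow(empty), 0)
  expect_equal(names(empty)[1:6],
               c("image_id", "um_per_px", "width_px", "height_px",
                 "cystic_index_pct", "n_cysts"))
  s <- cyst_set(200, 100, "liver", calibration(2.5))
  s <- add_cyst(s, square_poly(10, 10, 20))
  q <- quant_result(s, image_id = "img01")
  export_csv(list(q), f)
  back <- read.csv(f)
  expect_equal(nrow(back), 1)
  expect_equal(back$um_per_px, 2.5)
  expect_equal(back$cystic_index_pct, cystic_index(s))
  expect_equal(back$n_cysts, 1)
  expect_equal(sum(back[1, 7:12]), back$n_cysts)
})

test_that("annotation XML round-trips cyst sets and edit logs exactly", {
  s <- cyst_set(120, 90, "liver", calibration(1.37))
  s <- add_cyst(s, square_poly(10, 10, 20))
  s <- split_cyst(s, 1, rbind(c(19.5, 8), c(19.5, 31)))
  s <- add_cyst(s, square_poly(60, 40, 15))
  s <- merge_cysts(s, cystquant:::set_ids(s)[1:2])
  f <- tempfile(fileext = ".xml")
  export_annotations_xml(s, f)
  back <- import_annotations_xml(f)
  expect_true(cysts_equal(back, s))
  expect_identical(lapply(edit_log(back), unclass),
                   lapply(edit_log(s), unclass))
  expect_identical(back$cursor, s$cursor)
  expect_identical(back$organ, s$organ)
  expect_equal(back$calibration$um_per_px, 1.37)
  # undo state survives the round trip
  su <- undo_edit(s)
  export_annotations_xml(su, f)
  backu <- import_annotations_xml(f)
  expect_true(cysts_equal(backu, su))
  expect_identical(length(edit_log(backu)), length(edit_log(su)))
  # malformed input errors
  bad <- tempfile(fileext = ".xml")
  writeLines("<cyst_annotation><unclosed>", bad)
  expect_error(import_annotations_xml(bad))
  writeLines("<other/>", bad)
  expect_error(import_annotations_xml(bad), "not a cyst annotation")
})

test_that("random cyst sets round-trip bit-exactly through XML", {
  f <- tempfile(fileext = ".xml")
  set.seed(67)
  for (trial in 1:25) {
    s <- cyst_set(150, 150, sample(c("kidney", "liver"), 1),
                  calibration(runif(1, 0.3, 4)))
    for (k in seq_len(sample(1:6, 1))) {
      x0 <- sample(0:120, 1); y0 <- sample(0:120, 1)
      s <- add_cyst(s, square_poly(x0, y0, sample(3:20, 1)))
    }
    export_annotations_xml(s, f)
    back <- import_annotations_xml(f)
    expect_true(cysts_equal(back, s))
    expect_equal(back$calibration$um_per_px, s$calibration$um_per_px)
  }
})

test_that("supervised deletion of distractor detections lowers the index", {
  spec <- fixture_spec(n_cysts = 8, n_ducts = 5, n_vessels = 3,
                       speckle_amplitude = 25, seed = 71)
  gen <- generate_histology_image(spec)
  # wide range so distractors are detected too
  rec <- recognize_cysts(gen$image, "kidney", diameter_range(4, 120))
  ci_before <- cystic_index(rec$cyst_set)
  s <- rec$cyst_set
  for (d in gen$truth$distractors) {
    dm <- logical(s$height * s$width)
    dm[d$region] <- TRUE
    for (cy in s$cysts) {
      if (sum(dm[cy$region]) > 0.5 * cy$area_px) {
        s <- delete_cyst(s, cy$id)
        break
      }
    }
  }
  ci_after <- cystic_index(s)
  expect_lt(ci_after, ci_before)
  counts <- counts_from_log(rec$cyst_set, s)
  expect_equal(counts$fp, length(edit_log(s)))
})
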