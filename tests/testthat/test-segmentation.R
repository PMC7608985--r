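test_that("green-channel extraction matches per-pixel channel slicing", {
  set.seed(1)
  arr <- array(sample(0:255, 12 * 15 * 3, TRUE), c(12, 15, 3))
  img <- rgb_image(arr)
  g <- extract_green(img)
  expect_s3_class(g, "grey_image")
  # brute-force per-pixel oracle
  for (y in 1:12) for (x in 1:15)
    expect_identical(unclass(g)[y, x], as.integer(arr[y, x, 2]))
  # single pixel spot check and r=g=b identity
  expect_identical(unclass(extract_green(rgb_image(array(c(10, 200, 30),
                                                         c(1, 1, 3)))))[1, 1],
                   200L)
  flat <- rgb_image(matrix(42, 3, 3))
  expect_equal(unclass(extract_green(flat)), matrix(42L, 3, 3),
               ignore_attr = TRUE)
})

test_that("global mean threshold keeps the mean real and is strict", {
  # constant image: nothing strictly exceeds its own mean
  th <- global_mean_threshold(grey_image(matrix(100, 5, 5)))
  expect_equal(th$mean_level, 100)
  expect_false(any(th$mask))
  # half 0 / half 200: mean 100, exactly the bright half is foreground
  m <- matrix(c(rep(0, 8), rep(200, 8)), 4, 4)
  th2 <- global_mean_threshold(grey_image(m))
  expect_equal(th2$mean_level, 100)
  expect_equal(unname(unclass(th2$mask)), m > 100)
  # random image vs naive double-loop oracle
  set.seed(2)
  r <- matrix(sample(0:255, 30 * 20, TRUE), 30, 20)
  th3 <- global_mean_threshold(grey_image(r))
  mu <- sum(r) / length(r)
  oracle <- matrix(FALSE, 30, 20)
  for (i in 1:30) for (j in 1:20) oracle[i, j] <- r[i, j] > mu
  expect_equal(unname(unclass(th3$mask)), oracle)
})

test_that("k-means refinement reaches the optimal 1-D two-class partition", {
  # fixed point: exact two-valued partition is returned unchanged
  v <- matrix(c(rep(0, 10), rep(200, 10)), 4, 5)
  g <- grey_image(v)
  init <- binary_mask(v > 100)
  expect_equal(unname(unclass(kmeans_refine(g, init))), unname(unclass(init)))
  # degenerate init returned unchanged
  allbg <- binary_mask(matrix(FALSE, 4, 5))
  expect_equal(unname(unclass(kmeans_refine(g, allbg))), unname(unclass(allbg)))
  expect_equal(unname(unclass(kmeans_refine(grey_image(matrix(7, 4, 5)),
                                            allbg))),
               unname(unclass(allbg)))
  # bimodal mixture: agree with the exhaustive cut-point oracle
  set.seed(5)
  x <- pmin(255, pmax(0, round(c(rnorm(2000, 60, 12), rnorm(1000, 190, 15)))))
  gm <- grey_image(matrix(x, 50, 60))
  th <- global_mean_threshold(gm)
  ik <- kmeans_refine(gm, th$mask)
  best <- Inf; best_t <- NA
  for (t in 0:254) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(lo) || !length(hi)) next
    w <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (w < best) { best <- w; best_t <- t }
  }
  expect_equal(unname(unclass(ik)), matrix(x > best_t, 50, 60))
})

test_that("morphological opening removes noise and is anti-extensive", {
  # isolated pixel, liver element -> removed
  m <- matrix(FALSE, 20, 20); m[10, 10] <- TRUE
  out <- denoise_open(binary_mask(m), "liver")
  expect_false(any(out))
  # empty mask stays empty
  expect_false(any(denoise_open(binary_mask(matrix(FALSE, 10, 10)), "liver")))
  # kidney: disk of diameter dmin + 6 survives within the erode-dilate bound
  rng <- diameter_range(9, 100)
  dm <- disk_mask(60, 60, 30, 30, (9 + 6) / 2)
  opened <- denoise_open(binary_mask(dm), "kidney", rng)
  # brute-force opening oracle: erosion then dilation with the same kernel
  kern <- disk_kernel(9) > 0
  ker_off <- which(kern, arr.ind = TRUE) - (nrow(kern) + 1) / 2
  erode <- matrix(FALSE, 60, 60)
  for (i in 1:60) for (j in 1:60) {
    ii <- i + ker_off[, 1]; jj <- j + ker_off[, 2]
    inb <- ii >= 1 & ii <= 60 & jj >= 1 & jj <= 60
    erode[i, j] <- all(inb) && all(dm[cbind(ii, jj)])
  }
  dilate <- matrix(FALSE, 60, 60)
  for (p in which(erode)) {
    i <- (p - 1) %% 60 + 1; j <- (p - 1) %/% 60 + 1
    ii <- i + ker_off[, 1]; jj <- j + ker_off[, 2]
    inb <- ii >= 1 & ii <= 60 & jj >= 1 & jj <= 60
    dilate[cbind(ii[inb], jj[inb])] <- TRUE
  }
  expect_equal(unname(unclass(opened)), dilate)
  # anti-extensivity on random masks, both organs
  set.seed(7)
  for (k in 1:5) {
    rm_ <- binary_mask(matrix(runif(40 * 40) < 0.4, 40, 40))
    expect_true(all(unclass(denoise_open(rm_, "liver")) <= unclass(rm_)))
    expect_true(all(unclass(denoise_open(rm_, "kidney", rng)) <= unclass(rm_)))
  }
})

test_that("contour extraction matches a flood-fill labeling oracle", {
  # single rectangle
  m <- matrix(FALSE, 12, 14); m[3:7, 4:9] <- TRUE
  cs <- extract_contours(binary_mask(m))
  expect_length(cs, 1)
  expect_equal(cs[[1]]$area_px, 5 * 6)
  expect_equal(cs[[1]]$origin, "auto")
  # annulus: hole counts as cyst area
  ann <- disk_mask(30, 30, 14, 14, 10) & !disk_mask(30, 30, 14, 14, 5)
  ca <- extract_contours(binary_mask(ann))
  expect_length(ca, 1)
  expect_equal(ca[[1]]$area_px, sum(disk_mask(30, 30, 14, 14, 10)))
  # k disjoint disks
  dm <- disk_mask(40, 80, 12, 12, 6) | disk_mask(40, 80, 40, 20, 8) |
    disk_mask(40, 80, 65, 28, 5)
  cd <- extract_contours(binary_mask(dm))
  expect_length(cd, 3)
  lab <- oracle_label(dm)
  for (cy in cd) {
    got <- mask_region(cy, 40, 80)
    k <- lab[which(got)[1]]
    expect_equal(got, oracle_fill_holes(lab == k))
  }
  # random-mask equivalence (heavier version runs in the acceptance suite)
  set.seed(11)
  for (trial in 1:20) {
    rm_ <- matrix(runif(40 * 40) < runif(1, 0.25, 0.6), 40, 40)
    cs <- extract_contours(binary_mask(rm_))
    lab <- oracle_label(rm_)
    expect_length(cs, max(lab))
    areas_got <- sort(vapply(cs, function(c) c$area_px, numeric(1)))
    areas_want <- sort(vapply(seq_len(max(lab)), function(k)
      sum(oracle_fill_holes(lab == k)), numeric(1)))
    expect_equal(areas_got, areas_want)
  }
})

test_that("contour areas cover the mask foreground exactly when hole-free", {
  set.seed(13)
  for (trial in 1:10) {
    m <- matrix(FALSE, 30, 30)
    for (k in 1:4) {
      c <- sample(6:24, 2)
      m <- m | disk_mask(30, 30, c[1], c[2], sample(2:4, 1))
    }
    cs <- extract_contours(binary_mask(m))
    total <- sum(vapply(cs, function(c) c$area_px, numeric(1)))
    expect_gte(total, sum(m))   # >= because enclosed holes are filled
    holes <- sum(oracle_fill_holes_all(m)) - sum(m)
    expect_equal(total, sum(m) + holes)
  }
})

test_that("diameter filtering keeps exactly the in-range cysts and is monotone", {
  m <- matrix(FALSE, 60, 60)
  m[disk_mask(60, 60, 15, 15, 10)] <- TRUE    # d ~ 20
  cs <- extract_contours(binary_mask(m))
  expect_length(filter_by_diameter(cs, diameter_range(15, 50)), 1)
  expect_length(filter_by_diameter(cs, diameter_range(25, 50)), 0)
  # random sizes vs direct per-element check; narrowing never adds survivors
  set.seed(17)
  fake <- lapply(1:100, function(i) {
    a <- sample(5:2000, 1)
    structure(list(id = i, area_px = a, equiv_diameter_px = equiv_diameter(a),
                   origin = "auto"), class = "cyst_contour")
  })
  rng1 <- diameter_range(10, 40); rng2 <- diameter_range(15, 35)
  surv1 <- filter_by_diameter(fake, rng1)
  d <- vapply(fake, function(c) c$equiv_diameter_px, numeric(1))
  expect_identical(vapply(surv1, function(c) c$id, numeric(1)),
                   vapply(fake[d >= 10 & d <= 40], function(c) c$id, numeric(1)))
  expect_lte(length(filter_by_diameter(fake, rng2)), length(surv1))
})

test_that("full recognition is deterministic and recovers clean ellipses", {
  spec <- fixture_spec(n_cysts = 12, seed = 401)
  gen <- generate_histology_image(spec)
  rng <- diameter_range(12, 100)
  rec1 <- recognize_cysts(gen$image, "kidney", rng)
  rec2 <- recognize_cysts(gen$image, "kidney", rng)
  expect_identical(lapply(unname(rec1$cyst_set$cysts), unclass),
                   lapply(unname(rec2$cyst_set$cysts), unclass))
  expect_equal(count_cysts(rec1$cyst_set), 12)
  # per-cyst area within 5% of generator ground truth
  st <- detection_stats(rec1$cyst_set, gen$truth$cysts)
  expect_equal(st$recall, 1)
  for (pr in seq_len(nrow(st$matches))) {
    a_det <- rec1$cyst_set$cysts[[st$matches[pr, 1]]]$area_px
    a_tru <- gen$truth$cysts$cysts[[st$matches[pr, 2]]]$area_px
    expect_lt(abs(a_det - a_tru) / a_tru, 0.05)
  }
  # anti-extensivity of the opened mask w.r.t. the k-means mask
  expect_true(all(unclass(rec1$trace$opened) <= unclass(rec1$trace$kmeans_refined)))
  # tissue-only image -> no cysts
  flat <- flat_rgb(64, 64, 200, 140, 170)
  rec0 <- recognize_cysts(flat, "liver", rng)
  expect_equal(count_cysts(rec0$cyst_set), 0)
})
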