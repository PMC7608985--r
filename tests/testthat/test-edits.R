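base_set <- function() {
  s <- cyst_set(120, 100, "kidney")
  s <- add_cyst(s, square_poly(10, 10, 10))
  s <- add_cyst(s, square_poly(40, 40, 20))
  s
}

test_that("delete removes exactly the target and errors on unknown ids", {
  s <- base_set()
  s2 <- delete_cyst(s, 1)
  expect_equal(count_cysts(s2), 1)
  expect_identical(cystquant:::set_ids(s2), 2L)
  expect_error(delete_cyst(s, 99), "no cyst with id")
  only <- delete_cyst(delete_cyst(s, 1), 2)
  expect_equal(count_cysts(only), 0)
})

test_that("add validates polygons and add/delete are inverse", {
  s <- cyst_set(120, 100, "kidney")
  s1 <- add_cyst(s, square_poly(5, 5, 10))
  expect_equal(count_cysts(s1), 1)
  expect_equal(s1$cysts[[1]]$area_px, 100)
  expect_equal(s1$cysts[[1]]$origin, "manual")
  expect_error(add_cyst(s, rbind(c(0, 0), c(5, 5))), "simple")
  expect_error(add_cyst(s, rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))),
               "simple")                        # bow-tie self-intersection
  expect_error(add_cyst(s, square_poly(115, 95, 10)), "inside the image")
  s2 <- delete_cyst(s1, cystquant:::set_ids(s1))
  expect_true(cysts_equal(s2, s))
})

test_that("complete retires the old detection and reissues a fresh id", {
  s <- base_set()
  old_ids <- cystquant:::set_ids(s)
  s2 <- complete_cyst(s, 1, square_poly(8, 8, 14))
  expect_equal(count_cysts(s2), 2)
  expect_false(1L %in% cystquant:::set_ids(s2))
  new_id <- setdiff(cystquant:::set_ids(s2), old_ids)
  expect_equal(get_cyst(s2, new_id)$origin, "derived")
  expect_equal(get_cyst(s2, new_id)$area_px, 14 * 14)
  # identical replacement polygon still appends an edit record
  s3 <- complete_cyst(s, 2, square_poly(40, 40, 20))
  expect_equal(length(edit_log(s3)), length(edit_log(s)) + 1)
  expect_equal(utils::tail(edit_log(s3), 1)[[1]]$kind, "complete")
  expect_error(complete_cyst(s, 99, square_poly(0, 0, 5)), "no cyst with id")
})

test_that("split bisects along the cut line and conserves area", {
  s <- cyst_set(60, 40, "kidney")
  s <- add_cyst(s, square_poly(10, 10, 20))    # 20 x 20 square, area 400
  parent <- s$cysts[[1]]
  s2 <- split_cyst(s, 1, rbind(c(19.5, 8), c(19.5, 31)))
  expect_equal(count_cysts(s2), 2)
  areas <- sort(vapply(s2$cysts, function(c) c$area_px, numeric(1)))
  cut_px <- 20
  expect_gte(sum(areas), parent$area_px - cut_px)
  expect_lte(sum(areas), parent$area_px)
  expect_true(all(vapply(s2$cysts, function(c) c$origin, character(1)) ==
                    "derived"))
  # split then merge restores a single cyst within the cut-line loss
  ids <- cystquant:::set_ids(s2)
  s3 <- merge_cysts(s2, ids)
  expect_equal(count_cysts(s3), 1)
  expect_gte(s3$cysts[[1]]$area_px, parent$area_px - cut_px)
  # polyline outside the cyst -> error
  expect_error(split_cyst(s, 1, rbind(c(50, 0), c(50, 39))),
               "does not cross")
  # polyline that fails to bisect -> error
  expect_error(split_cyst(s, 1, rbind(c(15, 15), c(17, 17))),
               "exactly 2")
})

test_that("merge takes the union for touching cysts and bridges small gaps", {
  s <- cyst_set(100, 60, "kidney")
  # two overlapping disk-ish polygons: merged area = |union|
  s <- add_cyst(s, square_poly(10, 10, 20))
  s <- add_cyst(s, square_poly(20, 15, 20))
  union_area <- sum(mask_region(s$cysts[[1]], 60, 100) |
                      mask_region(s$cysts[[2]], 60, 100))
  s2 <- merge_cysts(s, c(1, 2))
  expect_equal(count_cysts(s2), 1)
  expect_equal(s2$cysts[[1]]$area_px, union_area)
  # small gap: bridged, merged area >= union
  g <- cyst_set(100, 60, "kidney")
  g <- add_cyst(g, square_poly(10, 10, 10))
  g <- add_cyst(g, square_poly(26, 10, 10))     # 6 px gap
  g2 <- merge_cysts(g, c(1, 2))
  expect_equal(count_cysts(g2), 1)
  expect_gte(g2$cysts[[1]]$area_px, 200)
  # far apart: beyond bridge reach -> error
  f <- cyst_set(200, 60, "kidney")
  f <- add_cyst(f, square_poly(5, 10, 10))
  f <- add_cyst(f, square_poly(150, 10, 10))
  expect_error(merge_cysts(f, c(1, 2)), "too far apart")
  expect_error(merge_cysts(f, 1), "at least 2")
})

test_that("remove_inner_cysts deletes only fully contained automatic cysts", {
  s <- cyst_set(100, 100, "kidney")
  auto_in <- cyst_contour(1, square_poly(20, 20, 8), 100, 100, "auto")
  auto_cross <- cyst_contour(2, square_poly(38, 38, 10), 100, 100, "auto")
  s <- cyst_set(100, 100, "kidney", calibration(1), list(auto_in, auto_cross))
  s <- add_cyst(s, square_poly(15, 15, 30))     # manual container 15..44
  container <- max(cystquant:::set_ids(s))
  s2 <- remove_inner_cysts(s, container)
  expect_false(1L %in% cystquant:::set_ids(s2))   # strictly inside -> gone
  expect_true(2L %in% cystquant:::set_ids(s2))    # crosses boundary -> kept
  # container must be manual
  expect_error(remove_inner_cysts(s, 1), "manually drawn")
  # nothing inside: geometry unchanged, one record appended
  s3 <- cyst_set(100, 100, "kidney", calibration(1), list(auto_cross))
  s3 <- add_cyst(s3, square_poly(60, 60, 20))
  n_before <- count_cysts(s3)
  s4 <- remove_inner_cysts(s3, max(cystquant:::set_ids(s3)))
  expect_equal(count_cysts(s4), n_before)
  expect_equal(utils::tail(edit_log(s4), 1)[[1]]$kind, "remove_inner")
})

test_that("add_smaller_cysts recovers tiny cysts and is idempotent", {
  # a realistically cystic kidney section (cystic load well above the
  # bimodality threshold of the global-mean cut) carrying 5 tiny true
  # cysts below the primary range plus tubule distractors
  spec <- fixture_spec(n_cysts = 12, cyst_d_range = c(50, 110),
                       n_small_cysts = 5, n_tubules = 5, seed = 151)
  gen <- generate_histology_image(spec)
  tr <- generate_lbp_training_set(fixture_spec(seed = 1), 60, seed = 52)
  model <- train_small_cyst_classifier(tr$features, tr$labels,
                                       grid_search_config(seed = 8))
  rec <- recognize_cysts(gen$image, "kidney", diameter_range(14, 150))
  s2 <- add_smaller_cysts(rec$cyst_set, gen$image, model,
                          diameter_range(4, 14))
  added <- utils::tail(edit_log(s2), 1)[[1]]$created
  added_set <- s2; added_set$cysts <- added
  names(added_set$cysts) <- vapply(added, function(c) as.character(c$id),
                                   character(1))
  st <- detection_stats(added_set, gen$truth$small_cysts, 0.3)
  expect_gte(st$tp, 4)                       # >= 4 of 5 tiny cysts added
  expect_lte(length(added) - st$tp, 1)       # at most one tubule accepted
  # no sub-dmin bright regions -> unchanged
  clean <- fixture_spec(n_cysts = 10, cyst_d_range = c(50, 110), seed = 154)
  gen2 <- generate_histology_image(clean)
  rec2 <- recognize_cysts(gen2$image, "kidney", diameter_range(14, 150))
  s3 <- add_smaller_cysts(rec2$cyst_set, gen2$image, model,
                          diameter_range(4, 14))
  expect_equal(count_cysts(s3), count_cysts(rec2$cyst_set))
  # second consecutive run adds nothing (overlap exclusion)
  s4 <- add_smaller_cysts(s2, gen$image, model, diameter_range(4, 14))
  expect_equal(count_cysts(s4), count_cysts(s2))
  expect_error(add_smaller_cysts(rec$cyst_set, gen$image, list(),
                                 diameter_range(4, 14)), "trained")
  expect_error(add_smaller_cysts(rec$cyst_set, gen$image, model,
                                 diameter_range(4, 20)), "primary dmin")
})

test_that("undo and redo move the cursor without mutating records", {
  s <- base_set()
  s2 <- delete_cyst(s, 1)
  u <- undo_edit(s2)
  expect_true(cysts_equal(u, s))
  r <- redo_edit(u)
  expect_true(cysts_equal(r, s2))
  expect_identical(lapply(edit_log(r), unclass), lapply(edit_log(s2), unclass))
  expect_error(undo_edit(cyst_set(10, 10, "kidney")), "nothing to undo")
  expect_error(redo_edit(r), "nothing to redo")
  # k random edits, undo x k -> initial set, over seeded scenarios
  for (sd in 1:10) {
    sc <- generate_edit_scenario(sd)
    s <- sc$final
    while (s$cursor > 0) s <- undo_edit(s)
    expect_true(cysts_equal(s, sc$initial))
  }
})

test_that("the final set is a pure function of the initial set and log", {
  for (sd in c(3, 14, 27)) {
    sc <- generate_edit_scenario(sd)
    replayed <- replay_edits(sc$initial, sc$log)
    expect_true(cysts_equal(replayed, sc$final))
    # every edit appended exactly one record
    expect_equal(length(sc$log), sc$final$cursor)
  }
})
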