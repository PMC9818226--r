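test_that("the VIP/p screen applies strict double inequalities", {
  s <- screen_key_compounds(data.frame(
    id = c("a", "b", "c", "d"),
    vip = c(1.2, 1.0, 1.2, 0.9),
    p = c(0.01, 0.001, 0.05, 0.01)
  ))
  expect_equal(s$passed[match(c("a", "b", "c", "d"), s$id)],
               c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(attr(s, "n_passed"), 1)
  # passing set ordered by descending VIP
  keys <- key_compounds(screen_key_compounds(data.frame(
    id = c("x", "y"), vip = c(1.1, 1.5), p = c(0.01, 0.01)
  )))
  expect_equal(keys$id, c("y", "x"))
})

test_that("vector interface requires matching compound sets", {
  expect_error(
    screen_key_compounds(vip = c(a = 1.2), p = c(b = 0.01)),
    class = "aromascreen_key_error"
  )
  s <- screen_key_compounds(vip = c(a = 1.2, b = 0.5),
                            p = c(b = 0.5, a = 0.01))
  expect_equal(s$id[s$passed], "a")
})

test_that("the curated key-compound statistics pass the screen in full", {
  s <- screen_key_compounds(docynia_key_stats())
  expect_equal(attr(s, "n_passed"), 23)
  expect_true(all(s$passed))
  # tightening the VIP cut-off strictly filters by the printed values
  s2 <- screen_key_compounds(docynia_key_stats(), vip_min = 1.1)
  expect_equal(attr(s2, "n_passed"),
               sum(docynia_key_stats()$vip > 1.1 &
                     docynia_key_stats()$p < 0.05))
  expect_lt(attr(s2, "n_passed"), 23)
})

test_that("reference selection maximises content over threshold with first-wins ties", {
  thr <- threshold_table(c("a", "b", "c"), c(0.1, 0.001, NA))
  expect_equal(select_reference(c(a = 10, b = 1, c = 99), thr), "b")
  # tie: equal activity, first in compound order wins
  thr2 <- threshold_table(c("a", "b"), c(0.1, 0.2))
  expect_equal(select_reference(c(a = 1, b = 2), thr2), "a")
  expect_equal(select_reference(c(a = 5), threshold_table("a", 0.1)), "a")
  expect_error(select_reference(c(a = 5), threshold_table("a", NA)),
               class = "aromascreen_validation_error")
})

test_that("reference dataset yields the expected per-group reference compounds", {
  rc <- docynia_relative_content()
  thr <- docynia_thresholds()
  expect_equal(select_reference(content_means(rc, "DY"), thr),
               "\u03b2-Ionone")
  expect_equal(select_reference(content_means(rc, "DM"), thr),
               "Phenethyl acetate")
})

test_that("rOAV normalises to the reference and is scale invariant", {
  bion <- "\u03b2-Ionone"
  contents <- setNames(c(0.11, 0.99), c("Hexanal", bion))
  thr <- threshold_table(c("Hexanal", bion), c(0.005, 0.00012))
  r <- compute_roav(contents, thr, quiet = TRUE)
  expect_equal(attr(r, "reference"), bion)
  expect_identical(r$roav[r$name == bion], 100)
  expect_equal(round(r$roav[r$name == "Hexanal"], 2), 0.27)
  expect_equal(max(r$roav), 100)

  r2 <- compute_roav(contents * 7.3, thr, quiet = TRUE)
  expect_equal(r2$roav, r$roav, tolerance = 1e-12)
})

test_that("compounds without thresholds are excluded with a note, never silently", {
  contents <- c(a = 5, b = 1)
  thr <- threshold_table(c("a", "b"), c(0.1, NA))
  expect_message(r <- compute_roav(contents, thr), "excluded")
  expect_equal(r$name, "a")
  expect_equal(attr(r, "excluded"), "b")
})

test_that("rOAV categories honour the conventional boundaries", {
  expect_equal(classify_roav(c(13.18, 0.28, 1.0, 0.1, 0.05)),
               c("critical", "modifying", "critical", "negligible",
                 "negligible"))
  expect_error(classify_roav(-0.1), class = "aromascreen_validation_error")
})

test_that("aroma profiles sum rOAV over descriptor terms for active compounds", {
  thr <- threshold_table(c("a", "b"), c(0.1, 0.1),
                         c("woody;floral", "floral"))
  r <- compute_roav(c(a = 5, b = 5), thr, quiet = TRUE)
  prof <- aroma_profile(r, thr)
  expect_equal(prof$score[prof$term == "woody"], 100)
  expect_equal(prof$score[prof$term == "floral"], 200)
  expect_equal(prof$rank, order(-prof$score))
})

test_that("negligible compounds do not contribute to aroma profiles", {
  thr <- threshold_table(c("a", "b"), c(0.001, 1000), c("rose", "rose"))
  r <- compute_roav(c(a = 5, b = 5), thr, quiet = TRUE)
  expect_equal(r$category[r$name == "b"], "negligible")
  prof <- aroma_profile(r, thr)
  expect_equal(prof$score[prof$term == "rose"], 100)
})

test_that("mature-fruit profile ranks floral above woody", {
  rc <- docynia_relative_content()
  thr <- docynia_thresholds()
  contents <- content_means(rc, "DM")
  r <- compute_roav(contents[names(contents) %in% thr$name], thr,
                    group = "DM", quiet = TRUE)
  prof <- aroma_profile(r, thr)
  expect_gt(prof$score[prof$term == "floral"],
            prof$score[prof$term == "woody"])
})
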