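test_that("peak table CSV round-trips areas bit-identically and preserves order", {
  pt <- random_peak_table(n_compounds = 5, seed = 11)
  # knock out a couple of cells to exercise the detected flags
  pt$detected[2, 1] <- FALSE
  pt$areas[2, 1] <- 0
  pt$detected[5, 4] <- FALSE
  pt$areas[5, 4] <- 0

  dir <- withr::local_tempdir()
  write_peak_table(pt, file.path(dir, "peaks.csv"),
                   file.path(dir, "samples.csv"))
  back <- read_peak_table(file.path(dir, "peaks.csv"),
                          file.path(dir, "samples.csv"))

  expect_identical(back$areas, pt$areas)
  expect_identical(back$detected, pt$detected)
  expect_identical(back$compounds$id, pt$compounds$id)
  expect_identical(back$samples, pt$samples)
  expect_identical(back$groups, pt$groups)
})

test_that("empty area cells become area 0 with detected = FALSE", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "id,name,cas,formula,class,rt_min,match_score,S1,S2",
    "c1,hexanal,,,aldehyde,5.4,90,10,",
    "c2,octanal,,,aldehyde,11.1,85,5,7"
  ), file.path(dir, "peaks.csv"))
  writeLines(c("sample_id,group", "S1,A", "S2,B"),
             file.path(dir, "samples.csv"))
  pt <- read_peak_table(file.path(dir, "peaks.csv"),
                        file.path(dir, "samples.csv"))
  expect_equal(dim(pt$areas), c(2, 2))
  expect_false(pt$detected["c1", "S2"])
  expect_identical(pt$areas["c1", "S2"], 0)
})

test_that("reader errors name the offending column / cell", {
  dir <- withr::local_tempdir()
  writeLines(c("id,name,cas,formula,rt_min,S1", "c1,x,,,5,1"),
             file.path(dir, "noclass.csv"))
  writeLines(c("sample_id,group", "S1,A"), file.path(dir, "samples.csv"))
  expect_error(
    read_peak_table(file.path(dir, "noclass.csv"),
                    file.path(dir, "samples.csv")),
    "class", class = "aromascreen_format_error"
  )

  writeLines(c(
    "id,name,cas,formula,class,rt_min,match_score,S1",
    "c1,x,,,ester,5,90,oops"
  ), file.path(dir, "badnum.csv"))
  expect_error(
    read_peak_table(file.path(dir, "badnum.csv"),
                    file.path(dir, "samples.csv")),
    "row 1, column 'S1'", class = "aromascreen_parse_error"
  )
})

test_that("constructor enforces the structural invariants", {
  cmp <- tiny_compounds(2)
  areas <- matrix(1:4, 2)
  groups <- c(S1 = "A", S2 = "B")
  ok <- peak_table(cmp, areas, groups)
  expect_s3_class(ok, "peak_table")

  cmp_dup <- cmp
  cmp_dup$id <- c("c1", "c1")
  expect_error(peak_table(cmp_dup, areas, groups),
               class = "aromascreen_validation_error")

  cmp_bad <- cmp
  cmp_bad$class <- "plastic"
  expect_error(peak_table(cmp_bad, areas, groups),
               class = "aromascreen_validation_error")

  expect_error(peak_table(cmp, -areas, groups),
               class = "aromascreen_validation_error")
})

test_that("alkane ladder and threshold readers validate their contracts", {
  dir <- withr::local_tempdir()
  writeLines(c("carbon_number,rt_min", "8,5.10", "7,3.00"),
             file.path(dir, "ladder.csv"))
  lad <- read_alkane_ladder(file.path(dir, "ladder.csv"))
  expect_equal(nrow(lad), 2)
  expect_equal(lad$carbon_number, c(7L, 8L))  # sorted on read

  writeLines(c("carbon_number,rt_min", "7,5.10", "8,3.00"),
             file.path(dir, "bad_ladder.csv"))
  expect_error(read_alkane_ladder(file.path(dir, "bad_ladder.csv")),
               class = "aromascreen_validation_error")

  writeLines(c("name,threshold_mg_per_kg,descriptors",
               "Hexanal,0.005,green;grass;fruity"),
             file.path(dir, "thr.csv"))
  thr <- read_threshold_table(file.path(dir, "thr.csv"))
  expect_equal(thr$threshold_mg_per_kg, 0.005)
  expect_equal(thr$descriptors[[1]], c("green", "grass", "fruity"))

  expect_error(threshold_table("x", 0),
               class = "aromascreen_validation_error")
})

test_that("long-format reader matches the wide-format result", {
  pt <- random_peak_table(n_compounds = 3, seed = 4)
  dir <- withr::local_tempdir()
  long <- do.call(rbind, lapply(seq_along(pt$samples), function(j) {
    data.frame(pt$compounds[, c("id", "name", "cas", "formula", "class",
                                "rt_min", "match_score")],
               sample = pt$samples[j], area = pt$areas[, j])
  }))
  readr::write_csv(long, file.path(dir, "long.csv"))
  got <- read_peak_table(file.path(dir, "long.csv"), pt$groups,
                         format = "long")
  expect_equal(got$areas, pt$areas)
  expect_identical(got$compounds$id, pt$compounds$id)
})
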