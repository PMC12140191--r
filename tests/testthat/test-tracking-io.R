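# Tracking-table dialect: parsing, validation, exact round trips.

valid_lines <- c(
  "scorer,net,net,net,net,net,net",
  "bodyparts,nose,nose,nose,ear,ear,ear",
  "coords,x,y,likelihood,x,y,likelihood",
  "0,1,10,0.99,5,50,0.98",
  "1,2,20,0.95,6,60,0.97",
  "2,3,30,0.90,7,70,0.96"
)

test_that("a hand-written table parses with the expected series", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(valid_lines, f)
  tab <- read_tracking_table(f)
  expect_equal(tab$bodyparts, c("nose", "ear"))
  expect_equal(tab$scorer, "net")
  expect_equal(unname(tab$x[, "nose"]), c(1, 2, 3))
  expect_equal(unname(tab$y[, "ear"]), c(50, 60, 70))
  expect_equal(unname(tab$confidence[, "nose"]), c(0.99, 0.95, 0.90))
})

test_that("write emits bodypart-major x,y,likelihood columns", {
  tab <- tracking_table(
    x = cbind(c(1, 2, 3)), y = cbind(c(10, 20, 30)),
    confidence = cbind(c(0.5, 0.6, 0.7)), bodyparts = "nose", scorer = "net"
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_tracking_table(tab, f)
  expect_identical(
    readLines(f),
    c("scorer,net,net,net",
      "bodyparts,nose,nose,nose",
      "coords,x,y,likelihood",
      "0,1,10,0.5", "1,2,20,0.6", "2,3,30,0.7")
  )
})

test_that("read after write is the identity on random tables", {
  for (seed in 1:20) {
    tab <- random_tracking_table(
      n_frames = sample(0:40, 1), n_parts = sample(1:4, 1), seed = seed
    )
    f <- withr::local_tempfile(fileext = ".csv")
    write_tracking_table(tab, f)
    back <- read_tracking_table(f)
    expect_identical(back$bodyparts, tab$bodyparts)
    expect_identical(back$scorer, tab$scorer)
    expect_equal(back$x, tab$x)
    expect_equal(back$y, tab$y)
    expect_equal(back$confidence, tab$confidence)
  }
})

test_that("an empty table round-trips as a header-only file", {
  z <- matrix(numeric(0), 0, 2)
  tab <- tracking_table(z, z, z, c("a", "b"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_tracking_table(tab, f)
  expect_length(readLines(f), 3)
  back <- read_tracking_table(f)
  expect_equal(nrow(back$x), 0)
  expect_equal(back$bodyparts, c("a", "b"))
})

test_that("the reader rejects mutated headers and malformed bodies", {
  write_mut <- function(lines) {
    f <- tempfile(fileext = ".csv")
    writeLines(lines, f)
    f
  }
  mutate <- function(lines, row, col, value) {
    cells <- strsplit(lines[row], ",", fixed = TRUE)[[1]]
    cells[col] <- value
    lines[row] <- paste(cells, collapse = ",")
    lines
  }
  # z coordinate
  expect_error(read_tracking_table(write_mut(mutate(valid_lines, 3, 3, "z"))),
               "format error")
  # duplicate body part
  expect_error(read_tracking_table(
    write_mut(mutate(mutate(mutate(valid_lines, 2, 5, "nose"),
                            2, 6, "nose"), 2, 7, "nose"))
  ), "format error")
  # fuzz: any single mutated header token is rejected
  set.seed(1)
  for (k in 1:40) {
    row <- sample(1:3, 1)
    col <- sample(1:7, 1)
    bad <- mutate(valid_lines, row, col, paste0("xx", k))
    expect_error(read_tracking_table(write_mut(bad)), "format error")
  }
  # non-numeric data cell
  expect_error(read_tracking_table(write_mut(mutate(valid_lines, 5, 2, "oops"))),
               "non-numeric")
  # non-contiguous frame index
  expect_error(read_tracking_table(write_mut(mutate(valid_lines, 6, 1, "7"))),
               "contiguous")
  # ragged data row
  expect_error(read_tracking_table(
    write_mut(c(valid_lines[1:4], "1,2,20,0.95"))
  ), "format error")
  # missing header
  expect_error(read_tracking_table(write_mut(valid_lines[3:6])), "format error")
})

test_that("empty cells surface as NaN positions with confidence 0", {
  lines <- valid_lines
  lines[4] <- "0,,10,,5,50,0.98"
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, f)
  tab <- read_tracking_table(f)
  expect_true(is.nan(tab$x[1, "nose"]))
  expect_equal(unname(tab$confidence[1, "nose"]), 0)
  expect_equal(unname(tab$x[1, "ear"]), 5)
})
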