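test_that("explicit file names decode to grid positions and prefix", {
  rec <- parse_filename("map01_32_15_img4", "explicit")
  expect_equal(rec$grid_x, 32L)
  expect_equal(rec$grid_y, 15L)
  expect_equal(rec$map_prefix, "map01_")
  expect_true(is.na(rec$progressive_index))

  origin <- parse_filename("map01_0_0_ref.txt", "explicit")
  expect_equal(c(origin$grid_x, origin$grid_y), c(0L, 0L))

  # prefixes may themselves contain underscores
  rec2 <- parse_filename("cell_a_7_3_img1", "explicit")
  expect_equal(rec2$map_prefix, "cell_a_")
  expect_equal(c(rec2$grid_x, rec2$grid_y), c(7L, 3L))

  expect_error(parse_filename("map01_32", "explicit"), class = "fcv_parse_error")
  expect_error(parse_filename("map01_x_15_img4", "explicit"), class = "fcv_parse_error")
})

test_that("progressive file names decode to 1-based indices", {
  rec <- parse_filename("map01_33", "progressive")
  expect_equal(rec$progressive_index, 33L)
  expect_equal(rec$map_prefix, "map01_")
  expect_error(parse_filename("map01_abc", "progressive"), class = "fcv_parse_error")
  expect_error(parse_filename("map01_0", "progressive"), class = "fcv_parse_error")
})

test_that("progressive indices resolve per scan modality", {
  # hand arithmetic: curve 33 with 16 per row sits at the start of row 2
  expect_equal(
    decode_position(33, 16, "row_x_row"),
    tibble::tibble(grid_x = 0L, grid_y = 2L)
  )
  # raster: raw column 3 on the (even, right-to-left) second row mirrors to 12
  expect_equal(
    decode_position(20, 16, "raster"),
    tibble::tibble(grid_x = 12L, grid_y = 1L)
  )
  expect_equal(
    decode_position(1, 16, "raster"),
    tibble::tibble(grid_x = 0L, grid_y = 0L)
  )
  expect_error(decode_position(0, 16), class = "fcv_range_error")
  expect_error(decode_position(65, 16, n_rows = 4), class = "fcv_range_error")
})

test_that("index-to-grid decoding is a bijection for both modalities", {
  for (modality in c("row_x_row", "raster")) {
    for (cpr in c(1L, 3L, 5L)) {
      n_rows <- 4L
      pos <- decode_position(seq_len(cpr * n_rows), cpr, modality, n_rows)
      expect_equal(nrow(dplyr::distinct(pos)), cpr * n_rows)
      expect_setequal(pos$grid_x, 0:(cpr - 1))
      expect_setequal(pos$grid_y, 0:(n_rows - 1))
    }
  }
})

test_that("curves load from two-column text, with strict format checks", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(sprintf("%g\t%g", 1:10, sin(1:10)), f)
  curve <- load_curve(f)
  expect_s3_class(curve, "fv_curve")
  expect_equal(nrow(curve), 10L)
  expect_equal(curve$z, as.numeric(1:10))

  # decimal commas are accepted on input
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0,5 1,25", "1,0 2,5", "1,5 3,75", "2,0 5,0"), f2)
  expect_equal(load_curve(f2)$deflection, c(1.25, 2.5, 3.75, 5))

  # a header line is a format error unless skipped explicitly
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# z deflection", sprintf("%g %g", 1:5, 1:5)), f3)
  expect_error(load_curve(f3), "line 1", class = "fcv_format_error")
  expect_equal(nrow(load_curve(f3, skip = 1)), 5L)

  f4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1", "2", "3", "4"), f4)
  expect_error(load_curve(f4), class = "fcv_format_error")
  f5 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 2", "3 4"), f5)
  expect_error(load_curve(f5), "fewer than 4", class = "fcv_format_error")
})

test_that("region selection is inclusive of both corners", {
  grid <- tidyr::expand_grid(grid_y = 0:49, grid_x = 0:49)
  expect_equal(nrow(select_region(grid, fv_region())), 2500L)
  sub <- select_region(grid, fv_region(c(10, 10), c(19, 19)))
  expect_equal(nrow(sub), 100L)
  expect_equal(range(sub$grid_x), c(10, 19))
  expect_equal(nrow(select_region(grid, fv_region(c(0, 0), c(0, 0)))), 1L)
  expect_error(fv_region(c(5, 5), c(4, 9)), class = "fcv_region_error")
  expect_error(
    select_region(grid, fv_region(c(0, 0), c(50, 10))),
    class = "fcv_region_error"
  )
})

test_that("map text export follows the labelled-matrix layout", {
  map <- fv_map(c(0, 1, 0, 1), c(0, 0, 1, 1), c(1, 2, 3, 4), unit = "nm")
  f <- withr::local_tempfile(fileext = ".txt")
  write_map_txt(map, f)
  lines <- readLines(f)
  expect_length(lines, 3L)
  expect_equal(lines[1], "0 0 1") # corner sentinel then X labels
  expect_equal(strsplit(lines[2], " ")[[1]][1], "0") # leading Y label
  m <- map_matrix(read_map_txt(f))
  expect_equal(m, matrix(1:4, 2, 2, byrow = TRUE,
    dimnames = list(c("0", "1"), c("0", "1"))
  ))
})

test_that("map text round-trips bit-identically, including missing cells", {
  set.seed(42)
  vals <- rnorm(30) * 1e3
  vals[17] <- NaN
  map <- fv_map(rep(0:5, 5), rep(0:4, each = 6), vals, unit = "kPa")
  f <- withr::local_tempfile(fileext = ".txt")
  write_map_txt(map, f)
  back <- read_map_txt(f, unit = "kPa")
  expect_identical(back$value, map$value)
  expect_identical(back$x, map$x)
  # the missing cell is written as a "nan" token
  expect_match(paste(readLines(f), collapse = "\n"), "nan")
})

test_that("exported text satisfies the Gwyddion raw-import recipe", {
  map <- fv_map(rep(0:6, 4), rep(0:3, each = 7), seq_len(28), unit = "")
  f <- withr::local_tempfile(fileext = ".txt")
  write_map_txt(map, f)
  lines <- readLines(f)[-1] # "start from line" 1
  tokens <- unlist(lapply(strsplit(lines, "[ \t]+"), function(x) x[-1])) # skip 1/row
  expect_length(tokens, 4 * 7)
  expect_false(anyNA(suppressWarnings(as.numeric(tokens))))
})

test_that("map images are one pixel per cell with a monotone grey ramp", {
  f <- withr::local_tempfile(fileext = ".png")
  write_map_image(fv_map(c(0, 1, 0, 1), c(0, 0, 1, 1), rep(7, 4)), f)
  img <- png::readPNG(f)
  expect_equal(dim(img)[1:2], c(2L, 2L))
  expect_true(all(img == img[1, 1]))

  # two-level map: darker pixel = lower value, row y = 0 at the bottom
  f2 <- withr::local_tempfile(fileext = ".png")
  write_map_image(fv_map(c(0, 1, 0, 1), c(0, 0, 1, 1), c(0, 0, 5, 5)), f2)
  img2 <- png::readPNG(f2) # grayscale: rows x cols
  expect_true(mean(img2[2, ]) < mean(img2[1, ])) # bottom image row = y 0 = low
  expect_error(
    write_map_image(fv_map(0, 0, NaN), withr::local_tempfile()),
    class = "fcv_io_error"
  )
})
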