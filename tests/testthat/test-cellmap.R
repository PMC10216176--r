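test_that("cell tables parse, validate, and reject malformed input", {
  b <- bounds(c(0, 1000), c(0, 1000), c(0, 200))
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,x,y,z,cell_type",
               "1,10,20,30,CANCER_CSC",
               "2,50,60,70,T_EFF",
               "3,100,200,100,TREG"), f)
  cm <- read_cells(f, b)
  expect_equal(n_cells(cm), 3)
  expect_equal(cm$cells$cell_type,
               c("CANCER_CSC", "T_EFF", "TREG"))

  writeLines(c("id,x,y,z,cell_type", "1,10,20,30,NEUTROPHIL"), f)
  expect_error(read_cells(f, b), "NEUTROPHIL")

  writeLines("id,x,y,z,cell_type", f)
  expect_equal(n_cells(read_cells(f, b)), 0)

  writeLines(c("id,x,y,cell_type", "1,10,20,CANCER_CSC"), f)
  expect_error(read_cells(f, b), "missing column")

  writeLines(c("id,x,y,z,cell_type", "1,10,20,30,CANCER_CSC",
               "2,2000,20,30,CANCER_CSC"), f)
  expect_error(read_cells(f, b), "row 2")
})

test_that("write/read round-trip is lossless and preserves row counts", {
  set.seed(42)
  n <- 2500
  cm <- cell_map(
    data.frame(id = seq_len(n), x = runif(n, 0, 1000),
               y = runif(n, 0, 1000), z = runif(n, 0, 200),
               cell_type = sample(CELL_TYPES, n, replace = TRUE)),
    bounds(c(0, 1000), c(0, 1000), c(0, 200)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cells(cm, f)
  expect_equal(length(readLines(f)), n + 1) # header + one row per cell
  back <- read_cells(f, cm$bounds)
  expect_identical(back$cells$x, cm$cells$x)
  expect_identical(back$cells$y, cm$cells$y)
  expect_identical(back$cells$z, cm$cells$z)
  expect_identical(back$cells$cell_type, cm$cells$cell_type)

  empty <- cell_map(cm$cells[0, ], cm$bounds)
  write_cells(empty, f)
  expect_equal(n_cells(read_cells(f, cm$bounds)), 0)
})

test_that("slicing keeps the slab, drops z, and tolerates empty slices", {
  cm <- cell_map(
    data.frame(id = 1:3, x = c(1, 2, 3) * 100, y = rep(500, 3),
               z = c(90, 100, 150),
               cell_type = "CANCER_PROGENITOR"),
    bounds(c(0, 1000), c(0, 1000), c(0, 200)))
  sl <- slice_2d(cm, z_center = 100, thickness = 20)
  expect_equal(n_cells(sl), 2)
  expect_equal(sl$dimensionality, 2L)
  expect_false("z" %in% names(sl$cells))

  expect_equal(n_cells(slice_2d(cm, z_center = 100, thickness = 400)), 3)
  expect_equal(n_cells(slice_2d(cm, z_center = 10, thickness = 2)), 0)
  expect_error(slice_2d(cm, thickness = 0), "thickness")
})

test_that("ROI cropping is half-open, bounded, and never invents cells", {
  set.seed(7)
  n <- 20000
  slide <- cell_map(
    data.frame(id = seq_len(n), x = runif(n, 0, 10000),
               y = runif(n, 0, 10000), cell_type = "T_EFF"),
    bounds(c(0, 10000), c(0, 10000)))
  tile <- crop_roi(slide, center_roi(slide))
  inside <- slide$cells$x >= 4500 & slide$cells$x < 5500 &
    slide$cells$y >= 4500 & slide$cells$y < 5500
  expect_equal(n_cells(tile), sum(inside)) # exact membership count
  expect_equal(n_cells(tile) / n, 0.01, tolerance = 0.25) # ~1% by area
  expect_lte(n_cells(tile), n_cells(slide))
  expect_equal(tile$bounds$xlim, c(4500, 5500))

  edges <- cell_map(
    data.frame(id = 1:2, x = c(4500, 5500), y = c(5000, 5000),
               cell_type = "T_EFF"),
    bounds(c(0, 10000), c(0, 10000)))
  cropped <- crop_roi(edges, roi(c(5000, 5000)))
  expect_equal(cropped$cells$id, 1L) # low edge in, high edge out

  expect_equal(n_cells(crop_roi(slide, roi(c(5000, 5000), 10000, 10000))),
               n) # ROI equal to the slide is the identity
  expect_error(crop_roi(slide, roi(c(100, 100), 1000, 1000)),
               "exceeds")
})

test_that("slice-then-crop equals cropping the 3-D sub-box then slicing", {
  set.seed(11)
  n <- 5000
  cm <- cell_map(
    data.frame(id = seq_len(n), x = runif(n, 0, 2000),
               y = runif(n, 0, 2000), z = runif(n, 0, 200),
               cell_type = sample(c("CANCER_CSC", "T_EFF"), n,
                                  replace = TRUE)),
    bounds(c(0, 2000), c(0, 2000), c(0, 200)))
  r <- roi(c(1000, 1000), 800, 600)
  a <- crop_roi(slice_2d(cm), r)
  # manual 3-D sub-box restriction with the same half-open convention
  keep <- cm$cells$x >= 600 & cm$cells$x < 1400 &
    cm$cells$y >= 700 & cm$cells$y < 1300
  sub <- cell_map(cm$cells[keep, ], cm$bounds)
  b <- crop_roi(slice_2d(sub), r)
  expect_equal(sort(a$cells$id), sort(b$cells$id))
})

test_that("type groupings are total, validated, and configurable", {
  g <- type_grouping()
  expect_setequal(names(g), CELL_TYPES)
  expect_true(all(g[c("T_EFF", "T_CYT", "T_EXH", "TREG")] == "IMMUNE"))
  g2 <- type_grouping(TREG = "EXCLUDED")
  expect_equal(unname(g2[["TREG"]]), "EXCLUDED")
  expect_error(type_grouping(B_CELL = "IMMUNE"), "unknown cell type")
  expect_error(type_grouping(TREG = "STROMA"), "classes")
})
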