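test_that("MSH v2.2 round trip preserves nodes, elements and regions", {
  ph <- build_phantom(tiny_geometry())
  f <- withr::local_tempfile(fileext = ".msh")
  write_msh(ph$mesh, f)
  back <- read_msh(f)
  expect_equal(back$nodes, ph$mesh$nodes, ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(back$tets, ph$mesh$tets, ignore_attr = TRUE)
  expect_equal(back$region, ph$mesh$region)
})

test_that("VTU export writes a well-formed unstructured grid with fields", {
  ph <- build_phantom(tiny_geometry())
  f <- withr::local_tempfile(fileext = ".vtu")
  u <- matrix(0.1, nrow(ph$mesh$nodes), 3)
  write_vtu(ph$mesh, f, point_data = list(displacement = u))
  txt <- readLines(f)
  expect_true(any(grepl("UnstructuredGrid", txt)))
  expect_true(any(grepl(sprintf('NumberOfPoints="%d"', nrow(ph$mesh$nodes)), txt)))
  expect_true(any(grepl('Name="displacement"', txt)))
  expect_error(write_vtu(ph$mesh, f, point_data = list(bad = 1:3)), "node count")
})

test_that("landmark JSON round trip preserves names and indices", {
  ph <- build_phantom(tiny_geometry())
  f <- withr::local_tempfile(fileext = ".json")
  write_landmarks_json(ph$landmarks, f)
  back <- read_landmarks_json(f, mesh = ph$mesh)
  expect_equal(unclass(back), unclass(ph$landmarks), ignore_attr = TRUE)
  expect_equal(names(back), names(ph$landmarks))
  expect_equal(attr(back, "coords"), attr(ph$landmarks, "coords"))
})

test_that("landmark time histories export as CSV", {
  ctx <- tiny_ctx()
  f <- solve_viscoelastic(ctx$mesh, ctx$bc, input_vector(x_adv = 3),
                          time_grid = ctx$tg, system = ctx$sys)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_landmark_history(f, ctx$landmarks, csv)
  df <- read.csv(csv)
  expect_equal(names(df), c("time", "N", "UL", "LL", "RC", "LC"))
  expect_equal(nrow(df), length(ctx$tg))
})
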