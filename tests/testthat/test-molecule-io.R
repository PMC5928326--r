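test_that("GRO frames are read with nm positions and the box line", {
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(c(
    "three atoms",
    "    3",
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "MOL", "C1", 1, 0.1, 0.2, 0.3),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "MOL", "C2", 2, 0.4, 0.5, 0.6),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "MOL", "C3", 3, 0.7, 0.8, 0.9),
    "   2.0   2.0   2.0"), path)
  fr <- read_coordinates(path, "gro")
  expect_length(fr, 1L)
  expect_equal(fr[[1]]$box, c(2, 2, 2))
  expect_equal(fr[[1]]$coordinates[2, ], c(0.4, 0.5, 0.6))
})

test_that("XYZ coordinates are converted from Angstrom to nm", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "comment", "C 1.00 0.00 0.00", "H 0.00 2.50 0.00"), path)
  fr <- read_coordinates(path, "xyz")
  expect_equal(fr[[1]]$coordinates[1, 1], 0.100)
  expect_equal(fr[[1]]$coordinates[2, 2], 0.250)
})

test_that("coordinate write/read round-trips within format precision", {
  set.seed(11)
  frames <- lapply(1:3, function(f)
    trajectory_frame((f - 1) * 2,
                     matrix(round(runif(15, 0, 1.5), 3), ncol = 3),
                     c(2, 2, 2)))
  for (fmt in c("gro", "xyz")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_coordinates(frames, path, fmt)
    back <- read_coordinates(path, fmt)
    expect_length(back, 3L)
    for (f in 1:3)
      expect_equal(back[[f]]$coordinates, frames[[f]]$coordinates,
                   tolerance = 1e-6)
  }
})

test_that("malformed and structurally inconsistent coordinate files error", {
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("bad", "    2",
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "M", "A", 1, 0, 0, 0),
               "garbage line here that is way too short?",
               "  2.0 2.0 2.0"), path)
  expect_error(read_coordinates(path, "gro"), "line")
  path2 <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("t", "    1",
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "M", "A", 1, 0, 0, 0),
               "  2.0 2.0 2.0 0.0 0.0 0.5 0.0 0.0 0.0"), path2)
  expect_error(read_coordinates(path2, "gro"), "triclinic")
  path3 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "t", "C 0 0 0", "2", "t", "C 0 0 0", "C 1 1 1"), path3)
  expect_error(read_coordinates(path3, "xyz"), "inconsistent atom count")
})

test_that("ITP subset parsing handles charge groups and tolerant charges", {
  path <- withr::local_tempfile(fileext = ".itp")
  writeLines(c("[ moleculetype ]", "TWO 3", "[ atoms ]",
               "1 C 1 MOL C1 1  0.2 12.011",
               "2 C 1 MOL C2 1 -0.2 12.011"), path)
  top <- read_topology_subset(path)
  expect_equal(top$net_charge, 0L)
  expect_equal(length(unique(top$atoms$charge_group)), 1L)

  path2 <- withr::local_tempfile(fileext = ".itp")
  writeLines(c("[ atoms ]",
               "1 C 1 MOL C1 1  0.2 12.011",
               "2 C 1 MOL C2 1 -0.1 12.011"), path2)
  w <- testthat::capture_warnings(top2 <- read_topology_subset(path2))
  expect_match(w, "integer", all = FALSE)
  expect_s3_class(top2, "molecule_topology")

  path3 <- withr::local_tempfile(fileext = ".itp")
  writeLines(c("[ bonds ]", "1 2 2"), path3)
  expect_error(read_topology_subset(path3), "\\[atoms\\]")
})

test_that("benzene-like fixture round-trips with 6 neutral charge groups", {
  b <- gen_toy_molecule("benzene_like")
  path <- withr::local_tempfile(fileext = ".itp")
  write_topology_subset(b, path)
  back <- read_topology_subset(path)
  expect_equal(nrow(back$atoms), 12L)
  gs <- tapply(back$atoms$charge, back$atoms$charge_group, sum)
  expect_length(gs, 6L)
  expect_true(all(abs(gs) < 1e-6))
  expect_equal(back$atoms$charge, b$atoms$charge, tolerance = 1e-6)
})

test_that("observable tables skip comments, reject ragged/empty input", {
  path <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c("@ title \"energy\"", "# comment", "0.0 1.5"), path)
  tab <- read_observable_table(path)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab[[2]], 1.5)

  path2 <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c("@ title \"x\"", "# only comments"), path2)
  expect_error(read_observable_table(path2), "empty")

  path3 <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c("0.0 1.0 2.0", "1.0 2.0"), path3)
  expect_error(read_observable_table(path3), "ragged")
})

test_that("observable tables and site reports round-trip losslessly", {
  tab <- data.frame(time = c(0, 2, 4), V1 = c(1.5, -2.25, 3.125))
  path <- withr::local_tempfile(fileext = ".xvg")
  write_observable_table(tab, path)
  back <- read_observable_table(path)
  expect_equal(as.data.frame(back), tab, ignore_attr = TRUE)

  row <- data.frame(Molecule = "water", Atom = "Ow", Aver_HB = 1.73,
                    tau_HB = 2.11, lifetime_HB = 0.47, dG_HB = 6.38,
                    Percent = 98.58, CN = 4.11, OBD_HB = 0.18,
                    Orientation = "Undefined")
  rpath <- withr::local_tempfile(fileext = ".csv")
  write_report(row, rpath)
  back2 <- read_report(rpath)
  expect_equal(back2$tau_HB, 2.11)
  expect_equal(back2$Orientation, "Undefined")
  expect_equal(back2$Percent, 98.58)
})
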