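test_that("hollow shell volume matches the analytic sphere within 10 percent", {
  sc <- generate_hollow_structure(8)
  cav <- rolling_probe_volume(sc)
  truth <- attr(sc, "true_cavity_volume")
  expect_lt(abs(cav$cavity_volume - truth) / truth, 0.10)
  # the dominant component is the sealed interior
  expect_gt(max(cav$component_volumes), 0.85 * truth)
  expect_equal(sum(cav$component_volumes), cav$cavity_volume)
  expect_lte(cav$cavity_volume, cav$excluded_volume_large)
})

test_that("a solid cluster carries no cavity beyond grid noise", {
  cs <- rolling_probe_volume(solid_cluster())
  expect_lt(cs$cavity_volume, 50)
})

test_that("halving the grid changes the shell volume by less than 3 percent", {
  sc <- generate_hollow_structure(6)
  v1 <- rolling_probe_volume(sc, grid_spacing = 0.5)$cavity_volume
  v2 <- rolling_probe_volume(sc, grid_spacing = 0.25)$cavity_volume
  expect_lt(abs(v2 - v1) / v1, 0.03)
})

test_that("cavity volume is invariant to rigid-body motion within 2 percent", {
  sc <- generate_hollow_structure(6)
  v1 <- rolling_probe_volume(sc)$cavity_volume
  a <- sc$atoms
  th <- 0.37
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(a[c("x", "y", "z")]) %*% rot
  moved <- structure_coords(data.frame(
    element = a$element, x = xyz[, 1] + 0.31, y = xyz[, 2] + 0.17,
    z = xyz[, 3] + 0.23, radius = a$radius))
  v2 <- rolling_probe_volume(moved)$cavity_volume
  expect_lt(abs(v2 - v1) / v1, 0.02)
})

test_that("cavity volume does not decrease with the large probe radius", {
  sc <- generate_hollow_structure(6)
  v30 <- rolling_probe_volume(sc, large_probe = 3.0)$cavity_volume
  v25 <- rolling_probe_volume(sc, large_probe = 2.5)$cavity_volume
  expect_gte(v30, v25 - 1e-9)
})

test_that("probe and grid preconditions are enforced", {
  sc <- generate_hollow_structure(6)
  expect_error(rolling_probe_volume(sc, grid_spacing = 1.0), "grid_spacing")
  expect_error(rolling_probe_volume(sc, small_probe = 3, large_probe = 2))
})

test_that("PDB structures round-trip through read_structure", {
  tmp <- tempfile(fileext = ".pdb")
  sc <- generate_hollow_structure(6)
  write_structure_pdb(sc, tmp)
  back <- read_structure(tmp)
  expect_equal(nrow(back$atoms), nrow(sc$atoms))
  expect_equal(back$atoms$x, sc$atoms$x, tolerance = 1e-3)
  expect_equal(back$atoms$radius, rep(1.7, nrow(sc$atoms)))
  # and the volume computed from the file matches the in-memory one
  v_file <- rolling_probe_volume(back)$cavity_volume
  v_mem <- rolling_probe_volume(sc)$cavity_volume
  expect_equal(v_file, v_mem, tolerance = 0.02)
})

test_that("minimal ATOM records parse with element-based radii", {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00  0.00           C",
    "END"), tmp)
  sc <- read_structure(tmp)
  expect_equal(nrow(sc$atoms), 2)
  expect_equal(sc$atoms$x, c(1.0, 2.5))
  expect_equal(sc$atoms$radius, c(1.55, 1.70))
})

test_that("multi-model files honor model selection; unknown elements warn", {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       5.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "END"), tmp)
  expect_equal(read_structure(tmp, model = 1)$atoms$x, 0)
  expect_equal(read_structure(tmp, model = 2)$atoms$x, 5)
  expect_error(read_structure(tmp, model = 3), "model")
  tmp2 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  X1  UNK A   1       0.000   0.000   0.000  1.00  0.00           X",
    "END"), tmp2)
  expect_warning(sc <- read_structure(tmp2), "fallback")
  expect_equal(sc$atoms$radius, 1.7)
})
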