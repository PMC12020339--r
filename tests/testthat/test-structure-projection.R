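test_that("rotation grid enumerates Euler triples", {
  expect_equal(nrow(rotation_grid(180)), 8)
  expect_equal(nrow(rotation_grid(90)), 64)
  expect_equal(nrow(rotation_grid(30)), 1728)
  g <- rotation_grid(90)
  expect_true(all(g %in% c(0, 90, 180, 270)))
  expect_equal(nrow(unique(as.data.frame(g))), 64)
  expect_error(rotation_grid(77), "divisor")
})

test_that("single-sphere projection is rotation invariant and equals pi r^2", {
  sp <- molecular_structure("C", matrix(0, 1, 3), radius = 0.15)
  expect_equal(projected_area(sp, c(0, 0, 0)), pi * 0.15^2,
               tolerance = 0.01)
  for (rot in list(c(30, 60, 90), c(123, 45, 7), c(300, 210, 150)))
    expect_equal(projected_area(sp, rot), pi * 0.15^2, tolerance = 0.01)
})

test_that("two-atom projections match analytic disk unions", {
  # coincident when the pair lies along the projection axis, disjoint side-on
  pair <- molecular_structure(c("C", "C"),
                              rbind(c(0, 0, 0), c(0, 0, 1)),
                              radius = c(0.15, 0.15))
  expect_equal(projected_area(pair, c(0, 0, 0)), pi * 0.15^2,
               tolerance = 0.01)
  expect_equal(projected_area(pair, c(90, 0, 0)), 2 * pi * 0.15^2,
               tolerance = 0.01)
  # overlapping disks: closed-form two-circle union (lens formula)
  overlap <- molecular_structure(c("C", "C"),
                                 rbind(c(0, 0, 0), c(0.15, 0, 0)),
                                 radius = c(0.15, 0.15))
  expect_equal(projected_area(overlap, c(0, 0, 0)),
               two_circle_union(0.15, 0.15), tolerance = 0.01)
  # separations between touching and overlapping, under arbitrary z-rotation
  for (d in c(0.05, 0.12, 0.22, 0.29)) {
    m <- molecular_structure(c("N", "N"), rbind(c(0, 0, 0), c(d, 0, 0)),
                             radius = c(0.15, 0.15))
    expect_equal(projected_area(m, c(0, 0, 137), resolution = 0.01),
                 two_circle_union(0.15, d), tolerance = 0.01)
  }
})

test_that("area distribution of a rod has end-on minimum and side-on maximum", {
  rod <- molecular_structure(rep("C", 3),
                             cbind(0, 0, c(-0.3, 0, 0.3)), radius = rep(0.15, 3))
  res <- area_distribution(rod, step_degrees = 90, resolution = 0.02)
  expect_s3_class(res, "projection_result")
  expect_equal(length(res$areas), 64)
  expect_equal(unname(res$summary["min"]), pi * 0.15^2, tolerance = 0.01)
  expect_equal(unname(res$summary["max"]), 3 * pi * 0.15^2, tolerance = 0.01)
  expect_true(res$summary["min"] <= res$summary["mean"] &&
              res$summary["mean"] <= res$summary["max"])
  # brute force over a denser grid never finds a smaller minimum than the
  # analytic end-on value
  dense <- area_distribution(rod, step_degrees = 45, resolution = 0.02)
  expect_gte(min(dense$areas), pi * 0.15^2 * 0.99)
})

test_that("projection invariants hold: monotonicity, convergence, z-invariance", {
  set.seed(21)
  xyz <- matrix(rnorm(15, sd = 0.3), 5, 3)
  m5 <- molecular_structure(rep("C", 5), xyz)
  m6 <- molecular_structure(rep("C", 6), rbind(xyz, c(0.5, 0.5, 0)))
  for (i in 1:5) {
    rot <- runif(3, 0, 360)
    expect_gte(projected_area(m6, rot) + 1e-9, projected_area(m5, rot))
  }
  # halving the raster step changes the area by < 1%
  a1 <- projected_area(m5, c(10, 20, 30), resolution = 0.02)
  a2 <- projected_area(m5, c(10, 20, 30), resolution = 0.01)
  expect_lt(abs(a1 - a2) / a2, 0.01)
  # identical-radius structures: rotation about the projection axis only
  base <- projected_area(m5, c(40, 70, 0))
  for (az in c(45, 160, 280))
    expect_equal(projected_area(m5, c(40, 70, az)), base, tolerance = 0.015)
  # all areas at least as large as the largest single disk
  expect_gte(min(area_distribution(m5, 90)$areas), pi * 0.17^2 * 0.99)
})

test_that("unknown elements fall back to the default radius with a warning", {
  expect_warning(r <- vdw_radius(c("C", "Xx")), "Xx")
  expect_equal(r, c(0.170, 0.17))
  expect_silent(vdw_radius(c("C", "N", "O", "S", "H")))
})

test_that("PDB round trip preserves geometry", {
  st <- build_peptide_structure("RAG")
  # write a minimal PDB by hand and read it back
  pdb <- tempfile(fileext = ".pdb")
  lines <- sprintf(
    "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(st)), substr(st$atom, 1, 4), "ALA", st$resno,
    st$x * 10, st$y * 10, st$z * 10, st$element)
  writeLines(c(lines, "END"), pdb)
  back <- read_structure_pdb(pdb)
  expect_equal(nrow(back), nrow(st))
  expect_equal(back$x, st$x, tolerance = 1e-3)
  expect_equal(back$radius, st$radius)
  # projected areas agree
  expect_equal(projected_area(back, c(15, 30, 45)),
               projected_area(st, c(15, 30, 45)), tolerance = 0.01)
})

test_that("idealized peptide builder produces sane geometry", {
  st <- build_peptide_structure("RRRRRRRG")
  expect_s3_class(st, "molecular_structure")
  # 7 Arg (11 heavy atoms) + Gly (4) + OXT
  expect_equal(nrow(st), 7 * 11 + 4 + 1)
  expect_true(all(st$radius > 0))
  # consecutive CA-CA distance is the standard ~0.38 nm for trans peptides
  ca <- st[st$atom == "CA", c("x", "y", "z")]
  d <- sqrt(rowSums(diff(as.matrix(ca))^2))
  expect_true(all(abs(d - 0.38) < 0.02))
  # no steric collapse: no two atoms closer than a covalent bond
  xyz <- as.matrix(st[, c("x", "y", "z")])
  dm <- as.matrix(dist(xyz))
  diag(dm) <- Inf
  expect_gt(min(dm), 0.11)
  expect_error(build_peptide_structure("RB7"), "B")
})

test_that("projection TSV export writes the grid and summary", {
  sp <- molecular_structure("C", matrix(0, 1, 3), radius = 0.15)
  res <- area_distribution(sp, step_degrees = 180)
  tsv <- tempfile(fileext = ".tsv")
  write_projection_tsv(res, tsv)
  tab <- read.delim(tsv)
  expect_named(tab, c("euler_x", "euler_y", "euler_z", "area_nm2"))
  expect_equal(nrow(tab), 8)
  js <- jsonlite::read_json(paste0(tsv, ".summary.json"))
  expect_equal(js$min, unname(res$summary["min"]))
})
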