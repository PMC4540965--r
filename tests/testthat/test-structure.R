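# Structural context: distances, contacts, accessibility parsing and
# computation, burial classes, weighted pair accessibility.

toy_context <- function() {
  atoms <- data.frame(
    chain = "A", resno = rep(1:3, each = 2), ins = "",
    resid = rep(c("GLY", "ALA", "SER"), each = 2),
    x = c(0, 1, 3, 4, 0, 0), y = c(0, 0, 4, 4, 0, 0),
    z = c(0, 0, 0, 0, 8, 9),
    element = "C")
  map <- data.frame(column = 1:3, chain = "A", resno = 1:3)
  structure_context(atoms, map = map)
}

test_that("minimum heavy-atom distance is the 3-4-5 triangle answer", {
  atoms <- data.frame(chain = "A", resno = c(1, 2), ins = "",
                      resid = c("GLY", "GLY"),
                      x = c(0, 3), y = c(0, 4), z = c(0, 0), element = "C")
  ctx <- structure_context(atoms)
  expect_equal(min_heavy_atom_distance(ctx, "A:1", "A:2"), 5)
  expect_equal(min_heavy_atom_distance(ctx, "A:2", "A:1"), 5)
  expect_error(min_heavy_atom_distance(ctx, "A:1", "B:9"), "not in structure")
  shared <- structure_context(data.frame(
    chain = "A", resno = c(1, 2), ins = "", resid = "GLY",
    x = 0, y = 0, z = 0, element = "C"))
  expect_equal(min_heavy_atom_distance(shared, "A:1", "A:2"), 0)
})

test_that("contact maps match hand-computed labels and are monotone", {
  ctx <- toy_context()
  # min distances: 1-2: sqrt(2^2+4^2)=4.472; 1-3: 8; 2-3: sqrt(9+16+64)=9.434
  cm <- contact_map(ctx, threshold = 5)
  expect_equal(cm$contact, c(TRUE, FALSE, FALSE))
  expect_equal(cm$distance, c(sqrt(20), 8, sqrt(89)), tolerance = 1e-12)
  tiny <- contact_map(ctx, threshold = 0.5)
  expect_false(any(tiny$contact))
  all_in <- contact_map(ctx, threshold = 100)
  expect_true(all(all_in$contact))
  # monotone: contacts at t1 < t2 are a subset
  for (pair in seq_len(nrow(cm)))
    expect_true(!tiny$contact[pair] | cm$contact[pair])
  # sequence-separation exclusion labels near pairs NA
  sep <- contact_map(ctx, threshold = 100, min_separation = 2)
  expect_true(is.na(sep$contact[sep$j - sep$i < 2][1]))
  expect_error(contact_map(ctx, threshold = -1), "positive")
})

test_that("naccess-style rsa files parse the relative all-atom column", {
  f <- withr::local_tempfile(fileext = ".rsa")
  writeLines(c(
    "REM  File of summed (Sum) and % (per.) accessibilities for",
    sprintf("RES %-3s %1s%4d%9.2f%6.1f%7.2f%6.1f", "GLU", "A", 20, 139.10, 80.0, 100.2, 70.1),
    sprintf("RES %-3s %1s%4d%9.2f%6.1f%7.2f%6.1f", "ALA", "A", 21, 0.00, 0.0, 0.0, 0.0),
    sprintf("RES %-3s %1s%4d%9.2f%6.1f%7.2f%6.1f", "SER", " ", 22, 55.00, 45.5, 30.0, 20.0)),
    f)
  acc <- read_rsa(f)
  expect_equal(unname(acc["A:20"]), 80.0)
  expect_equal(unname(acc["A:21"]), 0.0)
  expect_equal(unname(acc[":22"]), 45.5)   # blank chain preserved as empty
  expect_equal(unname(attr(acc, "resid")["A:20"]), "GLU")
  fdup <- withr::local_tempfile(fileext = ".rsa")
  writeLines(rep(sprintf("RES %-3s %1s%4d%9.2f%6.1f", "GLU", "A", 20, 1, 1), 2), fdup)
  expect_error(read_rsa(fdup), "duplicate")
  fbad <- withr::local_tempfile(fileext = ".rsa")
  writeLines("RES GLU A  xx   bad", fbad)
  expect_error(read_rsa(fbad), "line 1")
})

test_that("internal SASA behaves like an accessibility measure", {
  lone <- structure_context(data.frame(
    chain = "A", resno = 1, ins = "", resid = "GLY",
    x = 0, y = 0, z = 0, element = "C"))
  acc <- compute_sasa(lone)
  expect_gt(unname(acc["A:1"]), 80)   # isolated residue is fully exposed
  # occlusion grows monotonically as a partner atom approaches
  fracs <- vapply(c(10, 6, 4, 3, 2.5), function(d) {
    ctx <- structure_context(data.frame(
      chain = "A", resno = c(1, 2), ins = "", resid = "GLY",
      x = c(0, d), y = 0, z = 0, element = "C"))
    unname(compute_sasa(ctx)["A:1"])
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
  # a residue enclosed in a dense shell is nearly completely buried
  sphere <- coevar:::sphere_points(80) * 3.0
  shell <- data.frame(chain = "A", resno = 2, ins = "", resid = "GLY",
                      x = sphere[, 1], y = sphere[, 2], z = sphere[, 3],
                      element = "C")
  core <- rbind(data.frame(chain = "A", resno = 1, ins = "", resid = "GLY",
                           x = 0, y = 0, z = 0, element = "C"), shell)
  ctx <- structure_context(core)
  expect_lt(unname(compute_sasa(ctx)["A:1"]), 5)
  # deterministic for a fixed sphere-point count
  expect_identical(compute_sasa(ctx), compute_sasa(ctx))
})

test_that("volume-weighted pair accessibility is the weighted mean", {
  atoms <- data.frame(chain = "A", resno = c(1, 2), ins = "",
                      resid = c("TYPE1", "TYPE2"),
                      x = c(0, 10), y = 0, z = 0, element = "C")
  ctx <- structure_context(atoms,
                           accessibility = c("A:1" = 10, "A:2" = 40),
                           volumes = c(TYPE1 = 100, TYPE2 = 200))
  expect_equal(weighted_mean_accessibility(ctx, "A:1", "A:2"), 30)
  equal <- structure_context(atoms, accessibility = c("A:1" = 10, "A:2" = 40),
                             volumes = c(TYPE1 = 50, TYPE2 = 50))
  expect_equal(weighted_mean_accessibility(equal, "A:1", "A:2"), 25)
  zero <- structure_context(atoms, accessibility = c("A:1" = 0, "A:2" = 0),
                            volumes = c(TYPE1 = 100, TYPE2 = 200))
  expect_equal(weighted_mean_accessibility(zero, "A:1", "A:2"), 0)
  bad <- structure_context(atoms, accessibility = c("A:1" = 1, "A:2" = 2),
                           volumes = c(TYPE1 = 100))
  expect_error(weighted_mean_accessibility(bad, "A:1", "A:2"), "volume")
})

test_that("burial classes follow the accessibility thresholds", {
  expect_identical(burial_class(0), "completely_buried")
  expect_identical(burial_class(9.9), "core")
  expect_identical(burial_class(50), "exposed")
  expect_identical(burial_class(c(0, 5, 10, 80)),
                   c("completely_buried", "core", "exposed", "exposed"))
  expect_identical(burial_class(5, core_threshold = 4), "exposed")
})

test_that("buried pair census counts pairs and close fractions", {
  n <- 10
  set.seed(9)
  coords <- matrix(rnorm(3 * n, sd = 4), ncol = 3)
  atoms <- data.frame(chain = "A", resno = 1:n, ins = "", resid = "ALA",
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      element = "C")
  acc <- stats::setNames(c(rep(0, 4), runif(n - 4, 20, 80)),
                         paste0("A:", 1:n))
  ctx <- structure_context(atoms, accessibility = acc)
  out <- buried_pair_summary(ctx, threshold = 10)
  expect_identical(out$n_buried_residues, 4L)
  expect_identical(out$n_pairs, 6L)
  D <- as.matrix(dist(coords[1:4, ]))
  expect_equal(out$fraction_within_threshold,
               100 * mean(D[upper.tri(D)] < 10))
})

test_that("pseudo-PDB files round-trip through the PDB reader", {
  coords <- matrix(c(0, 0, 0, 4, 0, 0, 0, 5, 0), ncol = 3, byrow = TRUE)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pseudo_pdb(coords, f)
  ctx <- read_pdb_context(f)
  expect_equal(nrow(ctx$residues), 3)
  expect_equal(min_heavy_atom_distance(ctx, "A:1", "A:2"), 4)
  expect_equal(min_heavy_atom_distance(ctx, "A:2", "A:3"), sqrt(41))
})
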