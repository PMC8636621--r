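carbon_at <- function(chain, resno, x, y = 0, z = 0) {
  data.frame(chain = chain, resno = resno, insert = "", resname = "ALA",
             elety = "CA", element = "C", x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

test_that("an isolated carbon sphere matches the analytic area within 1%", {
  s <- mk_structure(carbon_at("A", 1, 0))
  analytic <- 4 * pi * (1.7 + 1.4)^2
  for (np in c(240, 960, 3840)) {
    a <- sasa(s, n_points = np)
    expect_lt(abs(a$total / analytic - 1), 0.01)
  }
})

test_that("well-separated atoms contribute additively; enclosed atoms vanish", {
  s <- mk_structure(rbind(carbon_at("A", 1, 0), carbon_at("A", 3, 100)))
  a <- sasa(s)
  expect_equal(a$total, 2 * 4 * pi * 3.1^2, tolerance = 1e-6)
  # atom caged by a shell of 26 neighbours on a 2.5 A lattice
  shell <- expand.grid(x = c(-2.5, 0, 2.5), y = c(-2.5, 0, 2.5),
                       z = c(-2.5, 0, 2.5))
  df <- do.call(rbind, lapply(seq_len(nrow(shell)), function(i)
    carbon_at("A", 2 * i, shell$x[i], shell$y[i], shell$z[i])))
  s2 <- mk_structure(df)
  a2 <- sasa(s2)
  centre <- which(shell$x == 0 & shell$y == 0 & shell$z == 0)
  expect_lt(a2$atom_area[centre], 1e-6)
})

test_that("two-sphere buried area matches the spherical-cap closed form", {
  s <- mk_structure(rbind(carbon_at("A", 1, 0), carbon_at("B", 1, 4)))
  b <- buried_surface_area(s, "chain A", "chain B", n_points = 3840)
  analytic <- 2 * 2 * pi * 3.1 * (3.1 - 2)  # both caps, R = 3.1, d = 4
  expect_lt(abs(b$bsa / analytic - 1), 0.02)
  # symmetry and the halved convention
  b2 <- buried_surface_area(s, "chain B", "chain A", n_points = 3840)
  expect_equal(b$bsa, b2$bsa, tolerance = 1e-9)
  bh <- buried_surface_area(s, "chain A", "chain B", halved = TRUE,
                            n_points = 960)
  expect_equal(bh$bsa * 2,
               buried_surface_area(s, "chain A", "chain B",
                                   n_points = 960)$bsa,
               tolerance = 1e-9)
})

test_that("non-interacting groups bury nothing", {
  s <- mk_structure(rbind(carbon_at("A", 1, 0), carbon_at("B", 1, 100)))
  b <- buried_surface_area(s, "chain A", "chain B")
  expect_lt(abs(b$bsa), 1)
})

test_that("sub-group decomposition reduces to the total for the whole group", {
  s <- mk_structure(rbind(carbon_at("A", 1, 0), carbon_at("A", 3, 3),
                          carbon_at("B", 1, 6)))
  b <- buried_surface_area(s, "chain A", "chain B",
                           subgroups_a = list(whole = "chain A",
                                              near = "chain A and resid 3"))
  expect_equal(b$subgroups$bsa[1], b$bsa, tolerance = 1e-9)
  expect_equal(b$subgroups$percent[1], 100, tolerance = 1e-9)
  expect_lte(b$subgroups$bsa[2], b$subgroups$bsa[1] + 1e-9)
  expect_error(buried_surface_area(s, "chain A", "chain A"), "overlap")
})

test_that("ensemble B-factors recover the isotropic analytic value", {
  set.seed(11)
  T <- 1e4; n <- 100
  top <- bead_structure("A", seq_len(n), x = seq(0, by = 15, length.out = n))
  base <- as.numeric(t(as.matrix(top$atom[, c("x", "y", "z")])))
  xyz <- matrix(rep(base, each = T), T) + matrix(rnorm(T * 3 * n, sd = 0.5), T)
  e <- new_ensemble(top, xyz)
  B <- computed_bfactors(e)
  expect_lt(abs(mean(B) / (8 * pi^2 * 0.25) - 1), 0.05)
  # zero fluctuation gives exactly zero
  e0 <- new_ensemble(top, matrix(rep(base, each = 3), 3))
  expect_true(all(computed_bfactors(e0, fit = FALSE) == 0))
  # doubling sigma quadruples B (same noise realization rescaled)
  xyz2 <- matrix(rep(base, each = T), T) + 2 * (xyz - matrix(rep(base, each = T), T))
  B2 <- computed_bfactors(new_ensemble(top, xyz2), fit = FALSE)
  expect_equal(B2, 4 * computed_bfactors(e, fit = FALSE), tolerance = 1e-9)
  expect_error(computed_bfactors(new_ensemble(top, matrix(base, 1))),
               "single frame")
})

rotated_pair <- function(theta_deg) {
  set.seed(21)
  anchor <- data.frame(chain = "A", resno = 1:6, insert = "", resname = "ALA",
                       elety = "CA", element = "C",
                       x = runif(6, 0, 10), y = runif(6, 0, 10),
                       z = runif(6, 0, 10), stringsAsFactors = FALSE)
  dup <- data.frame(chain = "D", resno = 1:6, insert = "", resname = "DA",
                    elety = "P", element = "P",
                    x = runif(6, 20, 30), y = runif(6, 0, 10),
                    z = runif(6, 0, 10), stringsAsFactors = FALSE)
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  co <- as.matrix(dup[, c("x", "y", "z")])
  ctr <- colMeans(co)
  co2 <- sweep(sweep(co, 2, ctr) %*% t(R), 2, ctr, "+")
  dup2 <- dup; dup2[, c("x", "y", "z")] <- co2
  list(a = mk_structure(rbind(anchor, dup)),
       b = mk_structure(rbind(anchor, dup2)))
}

test_that("constructed duplex rotations are recovered to machine precision", {
  pr <- rotated_pair(14)
  r <- duplex_rotation_angle(pr$a, pr$b, "chain A", "chain D")
  expect_lt(abs(r$angle - 14), 1e-6)
  expect_equal(abs(r$axis[3]), 1, tolerance = 1e-6)
  # identity gives zero (up to SVD rounding)
  r0 <- duplex_rotation_angle(pr$a, pr$a, "chain A", "chain D")
  expect_lt(r0$angle, 1e-4)
  # theta then -theta composes to zero
  fwd <- rotated_pair(9)
  r_fwd <- duplex_rotation_angle(fwd$a, fwd$b, "chain A", "chain D")
  r_bwd <- duplex_rotation_angle(fwd$b, fwd$a, "chain A", "chain D")
  expect_equal(r_fwd$angle, r_bwd$angle, tolerance = 1e-9)
})

test_that("map-model CCC is 1 against a self-simulated map and ~0 against noise", {
  pr <- rotated_pair(0)
  m <- simulate_density(pr$a, resolution = 4)
  expect_equal(map_model_ccc(pr$a, m, resolution = 4), 1.0, tolerance = 1e-6)
  set.seed(31)
  noise <- new_density_map(array(rnorm(length(m$grid)), dim(m$grid)),
                           m$voxel, m$origin, 4)
  expect_lt(abs(map_model_ccc(pr$a, noise)), 0.05)
})

test_that("a mispositioned model correlates strictly worse", {
  pr <- rotated_pair(0)
  m <- simulate_density(pr$a, resolution = 4, pad = 30)
  shifted <- pr$a
  shifted$atom$x <- shifted$atom$x + 20
  cc_in <- map_model_ccc(pr$a, m, 4)
  cc_out <- map_model_ccc(shifted, m, 4)
  expect_lt(cc_out, cc_in)
})

test_that("CCC is invariant under affine rescaling of either density", {
  pr <- rotated_pair(0)
  m <- simulate_density(pr$a, resolution = 4)
  set.seed(41)
  expt <- new_density_map(m$grid + array(rnorm(length(m$grid), sd = 2),
                                         dim(m$grid)), m$voxel, m$origin, 4)
  c1 <- map_model_ccc(pr$a, expt, 4)
  scaled <- new_density_map(3.7 * expt$grid + 11, expt$voxel, expt$origin, 4)
  expect_equal(map_model_ccc(pr$a, scaled, 4), c1, tolerance = 1e-9)
})

test_that("CCP4/MRC maps round-trip through the binary format", {
  pr <- rotated_pair(0)
  m <- simulate_density(pr$a, resolution = 5, voxel = 1.5)
  f <- withr::local_tempfile(fileext = ".mrc")
  write_ccp4_map(m, f)
  m2 <- read_ccp4_map(f)
  expect_equal(dim(m2$grid), dim(m$grid))
  expect_lt(max(abs(m2$grid - m$grid)), 1e-5 * max(abs(m$grid)))
  expect_equal(m2$voxel, m$voxel, tolerance = 1e-6)
  expect_equal(m2$origin, m$origin, tolerance = 1e-5)
})
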