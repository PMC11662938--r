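test_that("superhelix fitting recovers ideal solenoid parameters", {
  sol <- generate_ideal_solenoid(solenoid_spec(4.8, 40, 25, 18))
  fp <- fit_superhelix(sol)
  expect_equal(fp$rise, 4.8, tolerance = 1e-6)
  expect_equal(fp$twist, 40, tolerance = 1e-6)
  expect_equal(fp$radius, 25, tolerance = 1e-6)
  expect_equal(fp$pitch, 43.2, tolerance = 1e-6)
  expect_equal(fp$repeats_per_turn, 9, tolerance = 1e-6)

  sol2 <- generate_ideal_solenoid(solenoid_spec(8.5, 36, 25, 18))
  fp2 <- fit_superhelix(sol2)
  expect_equal(fp2$pitch, 85, tolerance = 1e-6)
  expect_equal(fp2$repeats_per_turn, 10, tolerance = 1e-6)

  # pitch invariant holds for every fit
  expect_equal(fp$pitch, fp$rise * 360 / fp$twist, tolerance = 1e-9)

  # collinear reference points are degenerate
  line <- matrix(c(rep(0, 10), rep(0, 10), seq_len(10)), ncol = 3)
  expect_error(fit_superhelix(line), "degenerate")
})

test_that("solenoid geometry places repeats on the stated helix", {
  # twist 40 deg, rise 4.8: repeat 9 sits directly above repeat 0
  sol <- generate_ideal_solenoid(solenoid_spec(4.8, 40, 25, 18))
  cent <- pprfret:::repeat_centroids(sol)
  expect_equal(cent[10, 1:2], cent[1, 1:2], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(cent[10, 3] - cent[1, 3], 43.2, tolerance = 1e-9,
               ignore_attr = TRUE)
  # twist 36, rise 8.5: repeat 10 above repeat 0 at 85 angstrom
  sol2 <- generate_ideal_solenoid(solenoid_spec(8.5, 36, 25, 18))
  cent2 <- pprfret:::repeat_centroids(sol2)
  expect_equal(cent2[11, 1:2], cent2[1, 1:2], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(cent2[11, 3] - cent2[1, 3], 85, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("superhelix fit is invariant to global rigid motion", {
  sol <- generate_ideal_solenoid(solenoid_spec(4.8, 40, 25, 18),
                                 atoms_per_repeat = 4)
  th <- 0.7; ph <- 1.3
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), -sin(ph), 0, sin(ph), cos(ph)), 3, 3,
               byrow = TRUE)
  R <- Rx %*% Rz
  moved <- sol
  xyz <- as.matrix(sol$atom[, c("x", "y", "z")]) %*% t(R)
  moved$atom$x <- xyz[, 1] + 11.2
  moved$atom$y <- xyz[, 2] - 40.1
  moved$atom$z <- xyz[, 3] + 3.3
  fp0 <- fit_superhelix(sol)
  fp1 <- fit_superhelix(moved)
  expect_equal(fp1$rise, fp0$rise, tolerance = 1e-9)
  expect_equal(fp1$twist, fp0$twist, tolerance = 1e-9)
  expect_equal(fp1$radius, fp0$radius, tolerance = 1e-9)
})

test_that("PDB round trip preserves coordinates and annotations", {
  sol <- generate_ideal_solenoid(solenoid_spec(4.8, 40, 25, 6),
                                 atoms_per_repeat = 4)
  f <- tempfile(fileext = ".pdb")
  write_structure(sol, f)
  back <- read_structure(f, sol$repeats)
  expect_equal(back$atom$x, sol$atom$x, tolerance = 1e-3)
  expect_equal(back$atom$y, sol$atom$y, tolerance = 1e-3)
  expect_equal(back$atom$z, sol$atom$z, tolerance = 1e-3)
  expect_equal(nrow(back$repeats), 6L)
  unlink(f)
  # overlapping annotation is rejected
  bad <- data.frame(start = c(1, 3), end = c(5, 8))
  expect_error(coordinate_set(sol$atom, bad), "overlap")
})

test_that("screw decomposition recovers constructed hinge rotations", {
  # compose-back property on random rigid transforms
  set.seed(12)
  for (r in 1:10) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    th <- runif(1, 5, 170) * pi / 180
    K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
                byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    t <- rnorm(3, 0, 5)
    sc <- screw_decompose(R, t)
    expect_equal(sc$rotation_angle, th * 180 / pi, tolerance = 1e-9)
    expect_equal(sqrt(sum(sc$screw_axis^2)), 1, tolerance = 1e-9)
    back <- screw_compose(sc)
    pts <- matrix(rnorm(15, 0, 10), 5, 3)
    orig <- pts %*% t(R) + matrix(t, 5, 3, byrow = TRUE)
    rec <- pts %*% t(back$R) + matrix(back$t, 5, 3, byrow = TRUE)
    expect_lt(max(abs(orig - rec)), 1e-9)
  }
})

test_that("inter-repeat transforms find a constructed 12-degree hinge", {
  sol <- generate_ideal_solenoid(solenoid_spec(8.5, 36, 25, 4),
                                 atoms_per_repeat = 6)
  # rotate repeats 2..4 of a copy by 12 degrees about a hinge through the
  # junction point, axis along y
  hinge_point <- c(25, 0, 8.5)
  u <- c(0, 1, 0)
  th <- 12 * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  b <- sol
  sel <- b$atom$resno >= b$repeats$start[2]
  xyz <- as.matrix(b$atom[sel, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, hinge_point)
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, hinge_point, "+")
  b$atom[sel, c("x", "y", "z")] <- xyz
  res <- inter_repeat_transforms(sol, b)
  expect_equal(res$rotation_angle[1], 12, tolerance = 1e-6)
  expect_equal(res$rotation_angle[2], 0, tolerance = 1e-6)
  expect_lt(max(res$superposition_rmsd), 1e-9)

  # identity: all angles and RMSDs vanish (angle tolerance reflects the
  # conditioning of acos near 1)
  res0 <- inter_repeat_transforms(sol, sol)
  expect_lt(max(res0$rotation_angle), 1e-5)
  expect_lt(max(res0$superposition_rmsd), 1e-9)

  # mismatched atom sets are reported
  chopped <- sol
  chopped$atom <- chopped$atom[-2, ]
  expect_error(inter_repeat_transforms(sol, chopped), "mismatch")
})

test_that("pair distances and Forster conversion are exact", {
  a <- coordinate_set(
    data.frame(chain = "A", resno = c(1, 2), elety = "CA", resid = "ALA",
               x = c(0, 3), y = c(0, 4), z = c(0, 0)),
    data.frame(start = 1, end = 2))
  b <- coordinate_set(
    data.frame(chain = "A", resno = c(1, 2), elety = "CA", resid = "ALA",
               x = c(0, 0), y = c(0, 0), z = c(0, 0)),
    data.frame(start = 1, end = 2))
  pd <- pair_distances(a, b, data.frame(resno1 = 1, resno2 = 2))
  expect_equal(pd$r_a, 5)
  expect_equal(pd$r_b, 0)
  # missing atom yields a per-pair note, not an error
  pd2 <- pair_distances(a, b, data.frame(resno1 = c(1, 1),
                                         resno2 = c(2, 9)))
  expect_equal(pd2$r_a[1], 5)
  expect_true(nzchar(pd2$note[2]))

  expect_equal(predict_fret_from_distance(54, 54), 0.5)
  expect_equal(predict_fret_from_distance(40, 54), 0.8582, tolerance = 1e-4)
  e <- predict_fret_from_distance(seq(10, 150, by = 10), 54)
  expect_true(all(diff(e) < 0))
  expect_lt(e[15], 0.01)
  expect_error(predict_fret_from_distance(40, -1), "positive")
})

test_that("FRET-pair screening finds pairs straddling the Forster radius", {
  apo <- generate_ideal_solenoid(solenoid_spec(8.5, 36, 25, 18))
  bound <- generate_ideal_solenoid(solenoid_spec(4.8, 40, 25, 18))
  hits <- screen_fret_pairs(apo, bound, r0 = 54, separation = 8)
  expect_gt(nrow(hits), 0)
  # chord prediction: sqrt((2 r sin(4 * twist))^2 + (8 * rise)^2)
  r_apo_expect <- sqrt((2 * 25 * sin(8 * 36 / 2 * pi / 180))^2 + 68^2)
  r_bound_expect <- sqrt((2 * 25 * sin(8 * 40 / 2 * pi / 180))^2 + 38.4^2)
  expect_equal(hits$r_apo[1], r_apo_expect, tolerance = 1e-6)
  expect_equal(hits$r_bound[1], r_bound_expect, tolerance = 1e-6)
  expect_true(all(hits$r_apo > 54 & hits$r_bound < 54))
  # identical conformations: nothing straddles
  expect_equal(nrow(screen_fret_pairs(apo, apo, 54, 8)), 0L)
})
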