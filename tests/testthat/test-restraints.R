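test_that("sphere sampling reproduces closed-form areas and symmetry", {
  # isolated atom: SASA = 4 pi (r_vdw + probe)^2
  one <- make_structure(0, 0, 0, radius = 1.9)
  s <- compute_sasa(one, probe_radius = 1.4, n_points = 960)
  expect_equal(s$atom_sasa, 4 * pi * 3.3^2, tolerance = 0.01 * 4 * pi * 3.3^2)

  # atom enclosed in a tight shell of neighbours is fully buried
  shell <- sphere_points(30) * 2.0
  buried <- make_structure(c(0, shell[, 1]), c(0, shell[, 2]),
                           c(0, shell[, 3]), radius = c(1.7, rep(1.9, 30)),
                           residue_number = rep(1L, 31))
  sb <- compute_sasa(buried, 1.4, 960)
  expect_equal(sb$atom_sasa[1], 0)

  # two identical overlapping atoms split area symmetrically
  two <- make_structure(c(0, 2.0), c(0, 0), c(0, 0), radius = 1.7,
                        residue_number = c(1L, 2L))
  st2 <- compute_sasa(two, 1.4, 960)
  expect_equal(st2$atom_sasa[1], st2$atom_sasa[2], tolerance = 1e-6)

  # zero-separation duplicates are rejected
  dup <- make_structure(c(0, 0), c(0, 0), c(0, 0))
  expect_error(compute_sasa(dup, 1.4, 960), "zero separation")
  expect_error(compute_sasa(two, 1.4, n_points = 50), "92")
})

test_that("sphere sampling agrees with a Monte-Carlo ray oracle", {
  set.seed(31)
  cl <- make_structure(x = c(0, 1.8, 0.5, -1.2, 0.3),
                       y = c(0, 0.3, 1.6, 0.8, -1.5),
                       z = c(0, 0.2, -0.4, 1.1, 0.9),
                       residue_number = rep(1L, 5))
  s <- compute_sasa(cl, 1.4, 960)
  r <- cl$radius + 1.4
  xyz <- as.matrix(cl[, c("x", "y", "z")])
  mc <- vapply(1:5, function(i) {
    n <- 40000
    v <- matrix(rnorm(3 * n), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    pts <- v * r[i] + matrix(xyz[i, ], n, 3, byrow = TRUE)
    free <- rep(TRUE, n)
    for (j in setdiff(1:5, i)) {
      free <- free &
        rowSums((pts - matrix(xyz[j, ], n, 3, byrow = TRUE))^2) > r[j]^2
    }
    4 * pi * r[i]^2 * mean(free)
  }, 0)
  expect_equal(s$atom_sasa, mc, tolerance = 0.02)
})

test_that("SASA converges as the point density doubles", {
  st <- gen_toy_structure(20, "helix")
  tot1 <- sum(compute_sasa(st, 1.4, 960)$atom_sasa)
  tot2 <- sum(compute_sasa(st, 1.4, 1920)$atom_sasa)
  expect_lt(abs(tot2 - tot1) / tot1, 0.005)
})

test_that("relative accessibility divides by the reference maxima", {
  st <- gen_toy_structure(5, "extended")
  s <- compute_sasa(st)
  rel <- suppressMessages(relative_sasa(s))
  manual <- 100 * as.numeric(s$residue_sasa) / max_asa_reference()["ALA"]
  expect_equal(unname(rel), manual)

  # buried residue -> 0%; SASA equal to the maximum -> 100%
  fake <- s
  fake$residue_sasa[] <- c(0, max_asa_reference()["ALA"],
                           rep(50, length(fake$residue_sasa) - 2))
  rel2 <- suppressMessages(relative_sasa(fake))
  expect_equal(unname(rel2[1]), 0)
  expect_equal(unname(rel2[2]), 100)

  # GLY spot check against the table entry
  fake$residue_type[] <- "GLY"
  fake$residue_sasa[] <- 42
  expect_equal(unname(suppressMessages(relative_sasa(fake))[1]),
               42 / 104 * 100)

  fake$residue_type[] <- "XXX"
  expect_error(relative_sasa(fake), "missing from reference")
})

test_that("active selection intersects perturbation with accessibility", {
  st <- gen_toy_structure(3, "extended", first_residue = 101L)
  csp <- c(`101` = 0.15, `102` = 0.12, `103` = 0.08)
  rel <- c(`101` = 60, `102` = 30, `103` = 80)
  sel <- select_air_residues(csp, rel, st)
  expect_equal(sel$active, 101L)        # 102 fails accessibility, 103 CSP
  expect_error(select_air_residues(c(`101` = 0.01), rel, st), "review")
})

test_that("passive residues are accessible neighbours of the active set", {
  st <- gen_toy_structure(12, "extended", first_residue = 1L)
  csp <- stats::setNames(c(0.5, rep(0.01, 11)), 1:12)
  rel <- stats::setNames(rep(60, 12), 1:12)
  sel <- select_air_residues(csp, rel, st, passive_radius = 6.5)
  expect_equal(sel$active, 1L)
  expect_true(2L %in% sel$passive)                  # immediate neighbour
  expect_false(12L %in% sel$passive)                # ~40 A away
  expect_length(intersect(sel$active, sel$passive), 0)

  # burying the neighbours empties the passive set
  rel2 <- stats::setNames(c(60, rep(10, 11)), 1:12)
  sel2 <- select_air_residues(csp, rel2, st)
  expect_length(sel2$passive, 0)
})

test_that("raising either threshold never enlarges the active set", {
  set.seed(5)
  res <- 1:20
  csp <- stats::setNames(runif(20, 0, 0.3), res)
  rel <- stats::setNames(runif(20, 0, 100), res)
  st <- gen_toy_structure(20, "extended")
  active_at <- function(ct, st_) {
    out <- try(select_air_residues(csp, rel, st, csp_threshold = ct,
                                   sasa_threshold = st_)$active,
               silent = TRUE)
    if (inherits(out, "try-error")) integer() else out
  }
  for (ct in c(0.05, 0.10, 0.15, 0.20))
    for (st_ in c(30, 45, 60)) {
      a <- active_at(ct, st_)
      expect_true(all(active_at(ct + 0.05, st_) %in% a))
      expect_true(all(active_at(ct, st_ + 15) %in% a))
    }
})

test_that("AIR files carry one block per active residue and round-trip", {
  set1 <- restraint_set(active_A = 99L, active_B = 405L)
  f <- withr::local_tempfile(fileext = ".tbl")
  write_air_restraints(set1, f)
  txt <- readLines(f)
  expect_equal(sum(grepl("^assign", txt)), 2L)      # both directions
  expect_false(any(grepl("passive", txt)))

  set2 <- restraint_set(active_A = c(99L, 130L, 160L), passive_A = c(98L, 101L),
                        active_B = c(405L, 406L, 407L), passive_B = 403L)
  write_air_restraints(set2, f)
  back <- read_air_restraints(f)
  expect_equal(back$active_A, set2$active_A)
  expect_equal(back$passive_A, set2$passive_A)
  expect_equal(back$active_B, set2$active_B)
  expect_equal(back$passive_B, set2$passive_B)
  expect_equal(back$distance_bounds, c(2.0, 2.0, 0.0))

  expect_error(restraint_set(active_A = integer(), active_B = 1L),
               "at least one active")
})

test_that("accessibility reports export per-residue values", {
  st <- gen_toy_structure(4, "helix")
  s <- compute_sasa(st)
  rel <- suppressMessages(relative_sasa(s))
  f <- withr::local_tempfile(fileext = ".csv")
  write_sasa_report(s, rel, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 4L)
  expect_equal(back$rel_sasa, unname(rel))
})
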