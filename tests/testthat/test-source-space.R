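fake_dipole <- function(location, rv = 0.02) {
  structure(list(location = location, moment = c(0, 0, 1), rv = rv,
                 sphere = fix_sphere, n_electrodes = 64),
            class = "dipole_fit")
}

fake_record <- function(subject, location, map, index = 1, model = 1,
                        rv = 0.02) {
  structure(list(subject_id = subject, model_id = model,
                 component_index = as.integer(index), scalp_map = map,
                 positions = fix_electrodes,
                 dipole = fake_dipole(location, rv),
                 class = "cortical"),
            class = "component_record")
}

test_that("the residual-variance gate and artifact rules classify as
          documented", {
  fs <- 512
  set.seed(1)
  cortical_act <- as.numeric(signal::filter(
    signal::butter(4, c(8, 12) / 256, "pass"), stats::rnorm(20 * fs)))
  ## RV above 15% is rejected regardless of anything else
  expect_equal(classify_component(fake_dipole(c(0, 0, 50), rv = 0.20),
                                  cortical_act, fs), "rejected_rv")
  ## central dipole, alpha spectrum, tiny RV: cortical
  expect_equal(classify_component(fake_dipole(c(0, 0, 50), rv = 0),
                                  cortical_act, fs), "cortical")
  ## anterior-inferior dipole with low-frequency dominated activity: ocular
  blink <- numeric(20 * fs)
  for (o in seq(1, 19 * fs, by = 2.5 * fs)) {
    tt <- seq(0, 0.3, by = 1 / fs)
    blink[o + seq_along(tt)] <- sin(2 * pi * tt / 0.3)
  }
  blink <- 25 * blink + as.numeric(signal::filter(
    signal::butter(2, c(1, 7) / 256, "pass"), stats::rnorm(20 * fs)))
  expect_equal(classify_component(fake_dipole(c(0, 74, -24)),
                                  blink, fs), "ocular")
  ## outside-brain dipole with rising high-frequency spectrum: muscular
  emg <- as.numeric(signal::filter(
    signal::butter(4, c(40, 150) / 256, "pass"), stats::rnorm(20 * fs)))
  expect_equal(classify_component(fake_dipole(c(62, -43, -32)),
                                  emg, fs), "muscular")
  expect_error(classify_component(NULL, emg, fs), "missing")
})

test_that("synthetic ocular sources from the generator are recognised", {
  hits <- 0
  for (sd in 1:10) {
    src <- default_sources()
    ev <- quick_events(4)
    sim <- simulate_sources(ev, src["ocular"], fs = 512,
                            n_samples = attr(ev, "n_samples"), seed = sd)
    cls <- classify_component(fake_dipole(src$ocular$location),
                              sim$activations[1, ], 512)
    hits <- hits + (cls == "ocular")
  }
  expect_gte(hits, 9)
})

test_that("two dipole groups 40 mm apart are perfectly partitioned and
          retention follows the 6-of-8 rule", {
  set.seed(2)
  ## 8 subjects x 2 groups; one group misses subjects 7 and 8
  recs <- list()
  for (s in 1:8) {
    mapA <- scalp_potential(c(-20, 0, 50), c(0, 0, 1), fix_electrodes,
                            fix_sphere)
    recs[[length(recs) + 1]] <- fake_record(
      sprintf("S%02d", s), c(-20, 0, 50) + stats::rnorm(3, 0, 2),
      mapA + stats::rnorm(64, 0, 0.02 * stats::sd(mapA)), index = 1)
    if (s <= 6) {
      mapB <- scalp_potential(c(20, 0, 10), c(1, 0, 0), fix_electrodes,
                              fix_sphere)
      recs[[length(recs) + 1]] <- fake_record(
        sprintf("S%02d", s), c(20, 0, 10) + stats::rnorm(3, 0, 2),
        mapB + stats::rnorm(64, 0, 0.02 * stats::sd(mapB)), index = 2)
    }
  }
  cl <- cluster_components(recs, k = 2, seed = 1, n_subjects = 8)
  sizes <- sort(vapply(cl, function(x) length(x$members), integer(1)))
  expect_equal(sizes, c(6L, 8L))
  ## each cluster contains one planted group only
  for (x in cl) {
    idx <- vapply(x$records, `[[`, integer(1), "component_index")
    expect_equal(length(unique(idx)), 1L)
    expect_true(x$retained)           # 8 >= 6 and 6 >= 6
  }
  ## a cluster with 5 subjects is not retained
  recs5 <- recs[vapply(recs, function(r)
    r$component_index == 2 || r$subject_id <= "S05", logical(1))]
  cl5 <- cluster_components(recs5, k = 2, seed = 1, n_subjects = 8)
  ret <- vapply(cl5, `[[`, logical(1), "retained")
  expect_equal(sort(vapply(cl5, `[[`, integer(1), "subject_count")),
               c(5L, 6L))
  expect_equal(sum(ret), 1L)
})

test_that("the partition is invariant to the order of the input records", {
  set.seed(3)
  recs <- list()
  for (s in 1:6) for (g in 1:2) {
    loc <- if (g == 1) c(-25, 10, 45) else c(25, -10, 45)
    map <- scalp_potential(loc, c(0, 0, 1), fix_electrodes, fix_sphere)
    recs[[length(recs) + 1]] <- fake_record(
      sprintf("S%02d", s), loc + stats::rnorm(3, 0, 2),
      map + stats::rnorm(64, 0, 0.02 * stats::sd(map)), index = g)
  }
  cl1 <- cluster_components(recs, k = 2, seed = 5)
  cl2 <- cluster_components(rev(recs), k = 2, seed = 5)
  key <- function(cl) sort(vapply(cl, function(x)
    paste(sort(vapply(x$records, function(r)
      paste0(r$subject_id, "_", r$component_index), character(1))),
      collapse = "|"), character(1)))
  expect_identical(key(cl1), key(cl2))
  expect_error(cluster_components(recs[1:3], k = 10), "fewer")
})

test_that("the 3x location weight makes clustering side with dipole
          location when location and topography disagree", {
  set.seed(4)
  ## two location groups; topographies deliberately assigned so that map
  ## similarity crosses the location split
  recs <- list()
  mapX <- scalp_potential(c(0, 40, 40), c(0, 1, 0), fix_electrodes,
                          fix_sphere)
  mapY <- scalp_potential(c(0, -40, 40), c(0, -1, 0), fix_electrodes,
                          fix_sphere)
  k <- 0
  for (s in 1:6) for (g in 1:2) {
    k <- k + 1
    loc <- if (g == 1) c(-30, 0, 45) else c(30, 0, 45)
    map <- if (k %% 2 == 0) mapX else mapY   # alternating, crossing groups
    recs[[length(recs) + 1]] <- fake_record(
      sprintf("S%02d", s), loc + stats::rnorm(3, 0, 1),
      map + stats::rnorm(64, 0, 0.02 * stats::sd(map)), index = g)
  }
  cl <- cluster_components(recs, k = 2, seed = 2, location_weight = 3)
  for (x in cl) {
    xs <- vapply(x$records, function(r) r$dipole$location[1], numeric(1))
    expect_true(all(xs > 0) || all(xs < 0))
  }
})
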