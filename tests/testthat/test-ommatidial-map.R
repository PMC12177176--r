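# Neighbour graph, interommatidial angles, spherical coordinates and
# cross-individual averaging.

test_that("angular difference behaves on the canonical cases", {
  expect_equal(angular_difference(c(1, 0, 0), c(2, 0, 0)), 0)
  expect_equal(angular_difference(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angular_difference(c(1, 0, 0), c(-1, 0, 0)), 180)
  expect_error(angular_difference(c(0, 0, 0), c(1, 0, 0)),
               class = "splitgaze_degenerate_geometry")
})

test_that("neighbour search returns the k angularly nearest facets", {
  # one centre facet plus a 6-ring at equal pitch: ring members exactly
  ax <- hex_cap_axes(7, 10)
  expect_setequal(find_neighbors(ax, 1, k = 6), 2:7)

  # k is clipped by availability
  three <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_setequal(find_neighbors(three, 2, k = 6), c(1, 3))

  # random 40-axis section agrees with the exhaustive all-pairs oracle
  withr::with_seed(5, {
    ax <- matrix(rnorm(120), 40, 3)
    ax <- ax / sqrt(rowSums(ax^2))
    for (i in c(1, 17, 40)) {
      angs <- vapply(seq_len(40), function(j) {
        if (j == i) Inf else angular_difference(ax[j, ], ax[i, ])
      }, numeric(1))
      oracle <- order(angs)[1:6]
      expect_setequal(find_neighbors(ax, i), oracle)
    }
  })

  expect_error(find_neighbors(three, 9), class = "splitgaze_schema_error")
})

test_that("mean interommatidial angle averages centre-to-neighbour angles", {
  centre <- c(0, 0, 1)
  ring10 <- t(vapply(seq(0, 300, by = 60) * pi / 180, function(p) {
    c(sin(10 * pi / 180) * cos(p), sin(10 * pi / 180) * sin(p),
      cos(10 * pi / 180))
  }, numeric(3)))
  expect_equal(mean_interommatidial_angle(centre, ring10), 10,
               tolerance = 1e-9)

  two <- rbind(c(sin(5 * pi / 180), 0, cos(5 * pi / 180)),
               c(sin(15 * pi / 180), 0, cos(15 * pi / 180)))
  expect_equal(mean_interommatidial_angle(centre, two), 10, tolerance = 1e-9)
  expect_error(mean_interommatidial_angle(centre, matrix(0, 0, 3)),
               class = "splitgaze_schema_error")
})

test_that("uniform-pitch hexagonal patches give interior means near pitch", {
  ax <- hex_cap_axes(37, 14.4)  # centre + 3 full rings
  interior <- 1:7               # centre facet and its first ring
  per <- vapply(interior, function(i) {
    nb <- find_neighbors(ax, i)
    mean(angular_difference(ax[nb, , drop = FALSE], ax[i, ]))
  }, numeric(1))
  expect_true(all(abs(per - 14.4) < 0.5))
})

test_that("the neighbour relation is used without assuming symmetry", {
  # an outlier: its neighbours are the cluster, but it is nobody's neighbour
  ax <- rbind(hex_cap_axes(7, 5), c(1, 0, 0))
  nb_out <- find_neighbors(ax, 8, k = 6)
  expect_true(all(nb_out %in% 1:7))
  nb_centre <- find_neighbors(ax, 1, k = 6)
  expect_false(8 %in% nb_centre)
})

test_that("eye_map flags wide neighbourhoods and reports both sections", {
  eye <- generate_eye()
  m <- eye_map(lens_geometry(eye$lenses))
  ss <- section_summary(m)
  expect_equal(ss$n[ss$section == "dorsal"], 42)
  expect_equal(ss$n[ss$section == "ventral"], 31)
  expect_true(all(m$azimuth > -180 & m$azimuth <= 180))
  expect_true(all(m$elevation >= -90 & m$elevation <= 90))
  expect_true(all(m$interommatidial_angle >= 0))
  expect_type(m$flagged, "logical")
})

test_that("per-section map means match the generator's nominal values", {
  for (seed in 1:3) {
    eye <- generate_eye(seed = seed)
    m <- eye_map(lens_geometry(eye$lenses), pool_sections = FALSE)
    got <- section_summary(m)
    expect_equal(got$interommatidial_mean[got$section == "dorsal"],
                 unname(eye$truth$io_nominal["dorsal"]), tolerance = 1e-6)
    expect_equal(got$interommatidial_mean[got$section == "ventral"],
                 unname(eye$truth$io_nominal["ventral"]), tolerance = 1e-6)
  }
})

test_that("axis_to_azel matches the body-frame convention", {
  expect_equal(as.numeric(axis_to_azel(c(1, 0, 0))), c(0, 0))
  expect_equal(axis_to_azel(c(0, 0, 1))$elevation, 90)
  # pitched frame: an axis fixed in space appears pitched down
  expect_equal(axis_to_azel(c(1, 0, 0), body_pitch = 90)$elevation, -90,
               tolerance = 1e-9)
  # cross-check against the rotation model applied to the same vector
  v <- c(0.5, -0.3, 0.8)
  got <- axis_to_azel(v, body_pitch = 37)
  R <- rotation_matrix(pitch = 37)
  ref <- axis_to_azel(as.numeric(t(R) %*% v))
  expect_equal(got$azimuth, ref$azimuth, tolerance = 1e-9)
  expect_equal(got$elevation, ref$elevation, tolerance = 1e-9)
})

test_that("eye averaging is exact on copies and errors on mismatch", {
  eye <- generate_eye(synthetic_eye_spec(n_dorsal = 4, n_ventral = 3))
  norm <- normalize_to_head_width(eye$lenses, eye$head)
  avg <- average_eyes(list(norm, norm, norm))
  cc <- setdiff(names(norm), c("animal_id"))
  expect_equal(as.data.frame(avg[cc]), as.data.frame(norm[cc]),
               tolerance = 1e-12)

  shift <- function(df, d) { df$p1_x <- df$p1_x + d; df }
  two <- average_eyes(list(shift(norm, 0.5), shift(norm, -0.5)))
  expect_equal(two$p1_x, norm$p1_x, tolerance = 1e-12)

  short <- norm[-2, ]
  expect_error(average_eyes(list(norm, short)), "absent homolog",
               class = "splitgaze_schema_error")
})

test_that("averaging six jittered eyes beats any single copy", {
  eye <- generate_eye(synthetic_eye_spec(n_dorsal = 5, n_ventral = 4))
  truth <- eye$lenses
  cc <- grep("^(p[1-6]|apex)_", names(truth), value = TRUE)
  tm <- as.matrix(truth[cc])
  wins <- 0L
  n_rep <- 100
  for (s in 1:n_rep) {
    copies <- withr::with_seed(1000 + s, lapply(1:6, function(k) {
      jit <- truth
      jit[cc] <- tm + matrix(rnorm(length(tm), 0, 0.2), nrow(tm))
      jit
    }))
    avg <- average_eyes(copies)
    rms <- function(df) sqrt(mean((as.matrix(df[cc]) - tm)^2))
    if (rms(avg) < min(vapply(copies, rms, numeric(1)))) wins <- wins + 1L
  }
  expect_gte(wins, 0.95 * n_rep)
})
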