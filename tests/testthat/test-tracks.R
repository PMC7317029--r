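# track_analysis module: trajectory metrics, directionality, group speed,
# actin-spot correlation.

straight_track <- function(id = "t1", to = c(3, 4, 0), t_end = 10) {
  data.frame(track_id = id, t_min = c(0, t_end),
             x_um = c(0, to[1]), y_um = c(0, to[2]), z_um = c(0, to[3]))
}

test_that("track_stats: 3-4-5 triangle, out-and-back, printed-quotient speed", {
  st <- track_stats(straight_track())
  expect_equal(st$length_um, 5)
  expect_equal(st$displacement_um, 5)
  expect_equal(st$straightness, 1)
  expect_equal(st$speed_um_min, 0.5)

  oab <- data.frame(track_id = "t", t_min = c(0, 5, 10),
                    x_um = c(0, 5, 0), y_um = 0, z_um = 0)
  s2 <- track_stats(oab)
  expect_equal(s2$length_um, 10)
  expect_equal(s2$displacement_um, 0)
  expect_equal(s2$straightness, 0)

  # a cell that moved 38 um in 8 min migrates at 4.75 um/min
  fast <- data.frame(track_id = "t", t_min = c(0, 8), x_um = c(0, 38),
                     y_um = 0, z_um = 0)
  expect_equal(track_stats(fast)$speed_um_min, 4.75)

  # 2-D input accepted; zero-length flagged
  flat <- track_stats(straight_track()[, c("track_id", "t_min", "x_um", "y_um")])
  expect_equal(flat$length_um, 5)
  still <- data.frame(track_id = "t", t_min = c(0, 3), x_um = 0, y_um = 0)
  s3 <- track_stats(still)
  expect_true(s3$degenerate)
  expect_true(is.na(s3$straightness))

  bad <- data.frame(track_id = "t", t_min = c(0, 3, 3), x_um = 1:3,
                    y_um = 0, z_um = 0)
  expect_error(track_stats(bad), "strictly increasing")
  expect_error(track_stats(straight_track()[1, ]), ">= 2 samples")
})

test_that("displacement <= length and rigid-motion invariance", {
  sim <- gen_tracks(400, 400, persistence = 0.7, seed = 3)
  st <- track_stats(sim$tracks)
  expect_true(all(st$displacement_um <= st$length_um + 1e-9))

  # rotation + translation leave straightness unchanged
  theta <- 0.83
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  tr <- sim$tracks[sim$tracks$track_id == sim$tracks$track_id[1], ]
  xyz <- as.matrix(tr[, c("x_um", "y_um", "z_um")]) %*% t(R)
  moved <- tr
  moved[, c("x_um", "y_um", "z_um")] <- sweep(xyz, 2, c(10, -4, 2), "+")
  expect_equal(track_stats(moved)$straightness,
               track_stats(tr)$straightness, tolerance = 1e-9)
})

test_that("directionality verdicts: straight, random-walk, modes", {
  straight <- track_stats(do.call(rbind, lapply(1:5, function(i)
    straight_track(paste0("t", i)))))
  v <- directionality_test(straight)
  expect_equal(v$verdict, "directional")
  expect_equal(v$p, 1)

  # 25 uncorrelated random walks at observed-cell scale
  rw <- track_stats(gen_tracks(0, 25, speed_um_min = 0.53,
                               persistence = 0, seed = 8)$tracks)
  v2 <- directionality_test(rw)
  expect_equal(v2$verdict, "non-directional")
  expect_lt(v2$p, 0.05)
  expect_true(v2$inverse_test)

  # straightness-threshold and TOST modes agree on the extremes
  expect_equal(directionality_test(straight,
                                   method = "straightness")$verdict,
               "directional")
  expect_equal(directionality_test(rw, method = "straightness")$verdict,
               "non-directional")
  expect_equal(directionality_test(rw, method = "tost")$verdict,
               "non-directional")

  expect_error(directionality_test(straight[1:2, ]), ">= 3")
})

test_that("group means match hand-computed averages", {
  set.seed(2)
  mk <- function(id, len, disp) {
    # planar L-shaped track with given length and displacement
    a <- (len + disp) / 2; b <- (len - disp) / 2
    data.frame(track_id = id, t_min = c(0, 15, 30),
               x_um = c(0, a, a - b), y_um = 0, z_um = 0)
  }
  grp <- track_stats(rbind(mk("s1", 41.55, 26.55), mk("s2", 41.55, 26.55),
                           mk("s3", 41.55, 26.55)))
  v <- directionality_test(grp)
  expect_equal(v$mean_length, 41.55)
  expect_equal(v$mean_displacement, 26.55)
})

test_that("group_speed: identical groups, planted fold change, spot classes", {
  st <- data.frame(track_id = paste0("t", 1:8),
                   speed_um_min = rep(c(1, 2), 4),
                   genotype = rep(c("A", "B"), each = 4),
                   n_actin_spots = rep(c(3, 1), each = 4))
  st$speed_um_min <- rep(c(1, 2, 1, 2), 2)
  r <- group_speed(st, "genotype")
  expect_equal(r$fold_change, 1)
  expect_gt(r$p, 0.9)

  # planted speeds 1.46 vs 0.53 with no noise -> fold change 2.75
  st2 <- data.frame(track_id = paste0("t", 1:10),
                    speed_um_min = rep(c(1.46, 0.53), each = 5),
                    genotype = rep(c("SA1KD", "lgl4"), each = 5))
  r2 <- group_speed(st2, "genotype")
  expect_equal(r2$fold_change, 1.46 / 0.53, tolerance = 1e-12)
  expect_equal(round(r2$fold_change, 2), 2.75)

  # multi-spot cells migrate faster: 3x planted speed, n = 5 per group
  sim <- rbind(
    track_stats(gen_tracks(5, 0, speed_um_min = 1.5, seed = 4)$tracks),
    track_stats(gen_tracks(0, 5, speed_um_min = 0.5, seed = 5)$tracks))
  r3 <- group_speed(sim, "n_actin_spots")
  expect_equal(r3$groups$group, c("multiple", "single"))
  expect_lt(r3$p, 0.01)
  expect_equal(r3$fold_change, 3, tolerance = 1e-6)

  expect_error(group_speed(st[st$genotype == "A", ], "genotype"), ">= 2")
  expect_error(group_speed(st[c(1, 2, 3, 5), ], "genotype"), "fewer than 2")
})

test_that("spot_invasion_correlation: monotone, anti-monotone, midranks", {
  r <- spot_invasion_correlation(c(10, 20, 30, 40), c(1, 4, 9, 16))
  expect_equal(r$rho, 1)
  expect_equal(r$r_s2, 1)
  r2 <- spot_invasion_correlation(c(10, 20, 30), c(9, 4, 1))
  expect_equal(r2$rho, -1)

  # 10 animals with two ties: compare against hand-ranked Pearson
  x <- c(5, 10, 10, 20, 25, 30, 35, 40, 40, 50)
  y <- c(2, 4, 6, 7, 7, 12, 14, 16, 15, 20)
  r3 <- spot_invasion_correlation(x, y)
  expect_equal(r3$rho, cor(rank(x), rank(y)))

  const <- spot_invasion_correlation(c(5, 5, 5), c(1, 2, 3))
  expect_true(const$degenerate)
  expect_error(spot_invasion_correlation(1:2, 1:2), ">= 3")
})

test_that("track CSV round trip", {
  sim <- gen_tracks(2, 2, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(sim, path)
  back <- read_tracks(path)
  expect_equal(back$x_um, sim$tracks$x_um, tolerance = 1e-9)
  expect_equal(track_stats(back)$length_um, track_stats(sim$tracks)$length_um,
               tolerance = 1e-9)
})
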