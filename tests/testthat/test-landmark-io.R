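test_that("TPS records parse with counts, ids and scale applied", {
  f <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=2", "0 0", "1 1", "ID=a", "",
               "LM=1", "2 4", "ID=b", "SCALE=0.5"), f)
  cfgs <- read_tps(f)
  expect_length(cfgs, 2L)
  expect_equal(cfgs[[1]]$specimen_id, "a")
  expect_equal(cfgs[[1]]$coords, rbind(c(0, 0), c(1, 1)))
  expect_equal(cfgs[[2]]$coords, rbind(c(1, 2)))  # scale multiplied
  expect_equal(cfgs[[2]]$scale, 0.5)
})

test_that("malformed TPS input raises informative parse errors", {
  f <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=3", "0 0", "1 1", "ID=a"), f)
  expect_error(read_tps(f), "LM=3")
  writeLines(c("LM=2", "0 zero", "1 1", "ID=a"), f)
  expect_error(read_tps(f), "line 2")
})

test_that("TPS write/read round trip preserves coordinates, ids, scale", {
  cfgs <- list(square_config("s1"), square_config("s2", scale = 0.25),
               random_config(7, seed = 3, id = "s3"))
  f <- withr::local_tempfile(fileext = ".tps")
  write_tps(cfgs, f)
  back <- read_tps(f)
  for (i in seq_along(cfgs)) {
    expect_equal(back[[i]]$coords, cfgs[[i]]$coords, tolerance = 1e-12)
    expect_equal(back[[i]]$specimen_id, cfgs[[i]]$specimen_id)
    expect_equal(back[[i]]$scale, cfgs[[i]]$scale)
  }
  expect_error(write_tps(list(), f), "empty")
})

test_that("curve resampling spaces points evenly by arc length", {
  seg <- resample_curve(rbind(c(0, 0), c(10, 0)), 5)
  expect_equal(seg[, 1], c(0, 2.5, 5, 7.5, 10))
  expect_equal(seg[, 2], rep(0, 5))
  # n = 2 returns the endpoints of any polyline
  poly <- rbind(c(0, 0), c(1, 2), c(3, 1), c(4, 4))
  expect_equal(resample_curve(poly, 2), poly[c(1, 4), ])
  # right angle: midpoint of total arc length 2 is the corner
  ra <- resample_curve(rbind(c(0, 0), c(1, 0), c(1, 1)), 3)
  expect_equal(ra[2, ], c(1, 0))
  expect_error(resample_curve(rbind(c(1, 1), c(1, 1)), 3), "degenerate")
})

test_that("resampled spacings have negligible coefficient of variation", {
  set.seed(42)
  for (rep in 1:5) {
    m <- 4 + rep
    poly <- cbind(sort(runif(m, 0, 10)), rnorm(m))
    pts <- resample_curve(poly, 17)
    gaps <- sqrt(rowSums(diff(pts)^2))
    # consecutive points may straddle polyline vertices; compare arc length
    # along the polyline instead of chord length
    arc <- function(p, q, poly) {
      # both p and q lie on the polyline; project cumulative arc length
      seg <- sqrt(rowSums(diff(poly)^2))
      cum <- c(0, cumsum(seg))
      pos <- function(pt) {
        for (j in seq_len(nrow(poly) - 1)) {
          d <- poly[j + 1, ] - poly[j, ]
          t <- sum((pt - poly[j, ]) * d) / sum(d^2)
          if (t >= -1e-9 && t <= 1 + 1e-9 &&
              sum((poly[j, ] + t * d - pt)^2) < 1e-18)
            return(cum[j] + t * seg[j])
        }
        NA_real_
      }
      pos(q) - pos(p)
    }
    arcs <- vapply(seq_len(nrow(pts) - 1),
                   function(i) arc(pts[i, ], pts[i + 1, ], poly), numeric(1))
    expect_false(anyNA(arcs))
    expect_lt(sd(arcs) / mean(arcs), 1e-9)
  }
})

test_that("mirroring produces exact bilateral symmetry", {
  cfg <- bilateral_config()
  # perturb the left side, then rebuild it from the right
  cfg$coords[3, ] <- cfg$coords[3, ] + c(0.3, -0.2)
  cfg$coords[5, ] <- cfg$coords[5, ] + c(-0.1, 0.4)
  out <- mirror_fill(cfg, use_side = "right")
  # axis is the y-axis (midline points at x = 0): left = reflected right
  expect_equal(out$coords[3, ], c(-1.5, 1), tolerance = 1e-9)
  expect_equal(out$coords[5, ], c(-1, -1), tolerance = 1e-9)
  # kept side unchanged
  expect_equal(out$coords[c(4, 6), ], cfg$coords[c(4, 6), ])
  # already-symmetric configuration is a fixed point
  sym <- bilateral_config()
  expect_equal(mirror_fill(sym, "right")$coords, sym$coords,
               tolerance = 1e-9)
})

test_that("mirroring twice is an involution and symmetry holds off-axis", {
  # rotate + translate so the sagittal axis is not a coordinate axis
  cfg <- bilateral_config()
  cfg$coords <- apply_similarity(cfg$coords, angle = 0.7, shift = c(3, -2))
  once <- mirror_fill(cfg, "right")
  twice <- mirror_fill(mirror_fill(once, "left"), "right")
  expect_equal(twice$coords, once$coords, tolerance = 1e-9)
  # mutual reflection across the fitted axis for every pair
  axis <- frillmorph:::fit_axis(once$coords[once$midline_ids, ])
  for (r in seq_len(nrow(once$pair_map))) {
    l <- once$coords[once$pair_map[r, 1], ]
    rt <- once$coords[once$pair_map[r, 2], ]
    expect_equal(frillmorph:::reflect_across(rt, axis), l,
                 tolerance = 1e-9)
  }
  bad <- cfg
  bad$coords[bad$midline_ids, ] <- matrix(rep(c(1, 1), 2), 2, byrow = TRUE)
  expect_error(mirror_fill(bad, "right"), "coincident")
})

test_that("landmark subsetting reindexes roles, midline and pairs", {
  cfg <- bilateral_config()
  expect_equal(subset_landmarks(cfg, 1:6)$coords, cfg$coords)
  # drop one side of a pair: pair dropped with a warning
  expect_warning(sub <- subset_landmarks(cfg, c(1, 2, 3, 5, 6)),
                 "split")
  expect_equal(nrow(sub$pair_map), 1L)
  expect_equal(sub$pair_map, cbind(4L, 5L), ignore_attr = TRUE)
  # single point keeps reindexed id 1
  one <- suppressWarnings(subset_landmarks(cfg, 3))
  expect_equal(nrow(one$coords), 1L)
  expect_error(subset_landmarks(cfg, integer(0)), "nonempty")
  # fenestra-exclusion shape: 45 points minus 8 leaves 37
  big <- random_config(45, seed = 9)
  expect_equal(nrow(subset_landmarks(big, setdiff(1:45, 36:43))$coords), 37L)
})
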