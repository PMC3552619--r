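test_that("column statistics follow the zero-skipping rule", {
  cases <- list(
    list(col = c(1, 1, 1),        h = 3, c = 0),
    list(col = c(1, -1, 1, -1),   h = 4, c = 3),
    list(col = c(1, 0, -1, 0, 0, -1), h = 6, c = 1),  # gaps skipped
    list(col = c(0, 0, 0),        h = 0, c = 0),
    list(col = c(0, 1, 0, 1),     h = 4, c = 0))
  for (cs in cases) {
    st <- column_stats(section_from_matrix(matrix(cs$col, nrow = 1)))
    expect_equal(st$h, cs$h, info = paste(cs$col, collapse = ","))
    expect_equal(st$c, cs$c, info = paste(cs$col, collapse = ","))
  }
})

test_that("intermixing index and patch size reproduce the defining sums", {
  # two columns: (h=10, c=4) and (h=20, c=2)
  m <- rbind(c(rep(c(1, -1), 5), rep(0, 10)),
             rep(c(1, 1, 1, -1, -1, -1, -1, -1, -1, -1), 2))
  s <- section_from_matrix(m)
  st <- column_stats(s)
  expect_equal(st$h, c(10, 20))
  expect_equal(st$c, c(9, 3))  # first column alternates every pixel
  # construct the printed example exactly: c = 4 and 2
  m2 <- rbind(c(1, 1, -1, -1, 1, 1, -1, -1, 1, 1, rep(0, 10)),
              c(rep(1, 7), rep(-1, 7), rep(1, 6)))
  st2 <- column_stats(section_from_matrix(m2))
  expect_equal(st2$h, c(10, 20))
  expect_equal(st2$c, c(4, 2))
  expect_equal(intermixing_index(section_from_matrix(m2)),
               (4 * 10 + 2 * 20) / 30)
  expect_equal(patch_size(section_from_matrix(m2)),
               (100 / 5 + 400 / 3) / 30)

  # single-color section: IM 0, patch size = height
  mono <- section_from_matrix(matrix(1, 5, 12))
  expect_equal(intermixing_index(mono), 0)
  expect_equal(patch_size(mono), 12)

  # perfectly layered: IM 1
  lay <- section_from_matrix(cbind(matrix(1, 4, 6), matrix(-1, 4, 6)))
  expect_equal(intermixing_index(lay), 1)

  expect_error(intermixing_index(section_from_matrix(matrix(0, 3, 3))),
               "undefined")
})

test_that("pixel size carries patch size and heights into micrometres", {
  s <- section_from_matrix(matrix(1, 4, 10), pixel_size = 5)
  expect_equal(patch_size(s), 50)
  expect_equal(community_height(s), 50)
})

test_that("community height is the interpolated 90th percentile", {
  m <- matrix(0L, 100, 100)
  for (i in 1:100) if (i >= 1) m[i, seq_len(i)] <- 1L
  s <- section_from_matrix(m)   # heights 1..100
  expect_equal(community_height(s), 90.1)

  # all-equal heights
  expect_equal(community_height(section_from_matrix(matrix(1, 7, 15))), 15)

  # an isolated spike is excluded by the percentile
  m2 <- matrix(0L, 50, 300)
  m2[, 1:10] <- 1L
  m2[25, ] <- 1L
  expect_lt(community_height(section_from_matrix(m2)), 20)
})

test_that("intermixing normalization is linear in the reference height", {
  expect_equal(normalize_im(3, 20, 40), 6)
  expect_equal(normalize_im(5, 35, 35), 5)
  expect_equal(normalize_im(2, 10, 40), normalize_im(2, 30, 120))
  expect_error(normalize_im(2, 0), "height")
})

test_that("IM is invariant under color swap, reflection, and translation", {
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(sample(c(-1L, 0L, 1L), 30 * 12, TRUE, c(.3, .2, .5)), 30, 12)
    # make gravity-like sections irrelevant: metrics must not care
    s <- section_from_matrix(m)
    im <- intermixing_index(s)
    expect_equal(intermixing_index(section_from_matrix(-m)), im)
    expect_equal(intermixing_index(section_from_matrix(m[30:1, ])), im)
    shift <- rbind(m[7:30, ], m[1:6, ])
    expect_equal(intermixing_index(section_from_matrix(shift)), im)
  }
})

test_that("periodic stacks obey the closed forms IM = h/lambda - 1", {
  for (lam in c(1, 2, 4, 8)) {
    h <- 40
    fx <- make_section("periodic_intermixed", width = 10, height = h,
                       lambda = lam)
    expect_equal(intermixing_index(fx$section), h / lam - 1)
    expect_equal(patch_size(fx$section), lam)
    expect_equal(fx$expected$im, h / lam - 1)
  }
  # bound: 0 <= IM <= height - 1
  expect_lte(intermixing_index(make_section("periodic_intermixed",
                                            height = 40,
                                            lambda = 1)$section), 39)
})

test_that("pairwise views reduce multi-population sections", {
  ids <- matrix(c(1, 2, 3, 0, 5,
                  2, 1, 3, 4, 1,
                  3, 3, 2, 1, 2,
                  1, 2, 0, 2, 1,
                  5, 4, 1, 2, 3), 5, 5, byrow = TRUE)
  s <- structure(ids, encoding = "ids", pixel_size = 1,
                 class = c("section_image", "matrix", "array"))
  pv <- pairwise_view(s, c(1, 2))
  # hand-reduced equivalent
  manual <- ifelse(ids == 1, 1L, ifelse(ids == 2, -1L, 0L))
  expect_equal(unclass(pv), manual, ignore_attr = TRUE)
  expect_equal(intermixing_index(pv),
               intermixing_index(section_from_matrix(manual)))
  expect_error(pairwise_view(s, c(8, 9)), "population id")

  # two-population signed sections are their own pairwise view
  s2 <- section_from_matrix(matrix(c(1, -1, 0, 1), 2))
  expect_equal(unclass(pairwise_view(s2, c(1, 2))), unclass(s2))
  expect_equal(unclass(pairwise_view(s2, c(2, 1))), -unclass(s2))
})

test_that("analysis-window tiling is translation-consistent", {
  fx <- make_section("periodic_intermixed", width = 60, height = 40,
                     lambda = 4)
  s <- fx$section   # pixel_size 1 -> window_width in pixels
  units <- tile_analysis_units(s, window_width = 20)
  expect_equal(nrow(units), 3)
  expect_true(all(units$im == fx$expected$im))

  # section narrower than the window: a single unit
  expect_equal(nrow(tile_analysis_units(s, window_width = 100)), 1)

  # 2.1-window-wide section gives 2 full units (partial trailing dropped)
  s2 <- section_from_matrix(unclass(s)[1:42, ])
  expect_equal(nrow(tile_analysis_units(s2, window_width = 20)), 2)

  # concatenating two identical sections doubles the units, same summaries
  s3 <- section_from_matrix(rbind(unclass(s), unclass(s)))
  u3 <- tile_analysis_units(s3, window_width = 20)
  expect_equal(nrow(u3), 6)
  expect_equal(u3$im, rep(units$im, 2))
  expect_error(tile_analysis_units(s, window_width = 0.2), "window")
})

test_that("digitization recovers known sections from rendered channels", {
  fx <- make_section("periodic_intermixed", width = 30, height = 40,
                     lambda = 4)
  ch <- render_channels(fx$section)           # noiseless
  s <- digitize(ch$channel_r, ch$channel_g, background = c(100, 100),
                pixel_size = 1)
  expect_equal(unclass(s), unclass(fx$section), ignore_attr = TRUE)
  expect_equal(intermixing_index(s), fx$expected$im)

  # swapped channels negate all labels
  s_swap <- digitize(ch$channel_g, ch$channel_r, background = c(100, 100))
  expect_equal(unclass(s_swap), -unclass(fx$section), ignore_attr = TRUE)

  # pure single-channel image maps every signal pixel to that channel
  g <- matrix(1000, 5, 8); r <- matrix(100, 5, 8)
  expect_true(all(digitize(r, g, background = c(100, 100)) == 1))

  # 5% relative noise: at least 99% of labels agree
  set.seed(21)
  agree <- replicate(5, {
    ch <- render_channels(fx$section, noise_sigma = 0.05)
    s <- digitize(ch$channel_r, ch$channel_g, background = c(100, 100))
    mean(unclass(s) == unclass(fx$section))
  })
  expect_gte(min(agree), 0.99)

  # all-background input warns and returns all zeros
  expect_warning(
    s0 <- digitize(matrix(100, 4, 4), matrix(100, 4, 4),
                   background = c(100, 100)),
    "background")
  expect_true(all(s0 == 0))
})

test_that("auto background estimation matches the dominant intensity", {
  fx <- make_section("layered", width = 20, height = 30)
  ch <- render_channels(fx$section, background = 50, signal = 800)
  s <- digitize(ch$channel_r, ch$channel_g, background = "auto")
  expect_equal(unclass(s), unclass(fx$section), ignore_attr = TRUE)
})
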