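test_that("select_target picks the most correlated anchor, stably", {
  fx <- fixture_anchor_map(4, 120, seed = 7)
  a <- fx$anchors
  # anchor pattern + tiny noise selects that anchor
  cms <- a$patterns["happy", ] +
    withr::with_seed(1, rnorm(a$voxel_count, 0, 0.01))
  expect_equal(as.character(select_target(cms, a)), "happy")
  # a negated anchor is maximally dissimilar to itself
  expect_false(as.character(select_target(-a$patterns["sad", ], a)) == "sad")
  # agrees with the brute-force pairwise correlation loop
  for (seed in 1:20) {
    cms <- withr::with_seed(seed + 50, rnorm(a$voxel_count))
    oracle <- which.max(vapply(seq_len(a$n_cond), function(i) {
      stats::cor(cms, a$patterns[i, ])
    }, numeric(1)))
    expect_equal(as.character(select_target(cms, a)), a$labels[oracle])
  }
  expect_error(select_target(rep(1, a$voxel_count), a), "zero-variance")
})

test_that("pattern strength is the centered projection coefficient", {
  tms <- voxel_pattern(c(1, 0, 2, -1, 3), label = "happy")
  # self-projection
  s <- pattern_strength(tms, tms)
  expect_equal(s$strength, 1)
  expect_equal(s$similarity, 1)
  expect_equal(s$angle_theta, 0, tolerance = 1e-6)  # acos amplifies eps near 1
  expect_equal(s$target_label, "happy")
  # doubled engagement: same angle, doubled strength
  s2 <- pattern_strength(voxel_pattern(2 * tms$values), tms)
  expect_equal(s2$strength, 2)
  expect_equal(s2$similarity, 1)
  # centered-orthogonal pattern
  vt <- tms$values - mean(tms$values)
  orth <- c(vt[2], -vt[1], 0, 0, 0)  # orthogonal to centered tms after centering?
  orth <- orth - mean(orth)
  orth <- orth - sum(orth * vt) / sum(vt^2) * vt  # force exact orthogonality
  s0 <- pattern_strength(orth + mean(tms$values), tms)
  expect_equal(s0$strength, 0, tolerance = 1e-12)
  expect_equal(s0$similarity, 0, tolerance = 1e-12)
  expect_equal(s0$angle_theta, pi / 2, tolerance = 1e-8)
  # random pairs match the definitional dot-product oracle and the
  # consistency identity strength = r * ||cms_c|| / ||tms_c||
  for (seed in 1:20) {
    vv <- withr::with_seed(seed, matrix(rnorm(40), 2))
    cms <- vv[1, ]; t2 <- vv[2, ]
    s <- pattern_strength(cms, voxel_pattern(t2))
    cc <- cms - mean(cms); tc <- t2 - mean(t2)
    expect_equal(s$strength, sum(cc * tc) / sum(tc * tc), tolerance = 1e-12)
    expect_equal(s$strength,
                 s$similarity * sqrt(sum(cc^2)) / sqrt(sum(tc^2)),
                 tolerance = 1e-10)
  }
  expect_error(pattern_strength(c(1, 2, 3), c(5, 5, 5)), "zero norm")
})

test_that("the similarity/intensity dissociation holds exactly under scaling", {
  fx <- fixture_anchor_map(4, 100, seed = 21)
  a <- fx$anchors
  for (seed in 1:25) {
    cms <- withr::with_seed(seed, rnorm(a$voxel_count))
    k <- withr::with_seed(seed + 1000, runif(1, 0.1, 10))
    tms <- voxel_pattern(a$patterns["content", ], label = "content")
    s1 <- pattern_strength(cms, tms)
    sk <- pattern_strength(k * cms, tms)
    expect_equal(sk$similarity, s1$similarity, tolerance = 1e-10)
    expect_equal(sk$angle_theta, s1$angle_theta, tolerance = 1e-10)
    expect_equal(sk$strength, k * s1$strength, tolerance = 1e-10)
    # map position is scale-invariant under the correlation metric
    expect_equal(project_pattern(fx$map, a, k * cms),
                 project_pattern(fx$map, a, cms), tolerance = 1e-8)
  }
})

test_that("map frames size the marker affinely in clipped strength", {
  fx <- fixture_anchor_map(4, 80, seed = 3)
  style <- feedback_style(s_min = 4, s_max = 20, strength_cap = 1.5)
  mk <- function(strength) {
    intensity <- structure(list(target_label = "happy", similarity = 0.5,
                                angle_theta = acos(0.5), strength = strength),
                           class = "intensity_result")
    map_frame(fx$map, c(0.1, 0.2), intensity, style)$marker_size
  }
  expect_equal(mk(0), 4)
  expect_equal(mk(-1), 4)          # negative strength renders at minimum
  expect_equal(mk(1.5), 20)
  expect_equal(mk(99), 20)         # clipped at strength_cap
  expect_equal(mk(0.75), 12)       # midpoint of the affine map
  expect_gt(mk(1.0), mk(0.5))      # monotone within range
})

test_that("generic circular layout spaces anchors equally from the top", {
  lay <- circular_layout(c("happy", "content", "sad", "angry"))
  expect_equal(as.numeric(lay),
               (pi / 2 + 2 * pi * (0:3) / 4) %% (2 * pi))
  gaps <- diff(c(sort(lay), sort(lay)[1] + 2 * pi))
  expect_equal(unname(gaps), rep(pi / 2, 4))
})

test_that("dissimilarity layout separates the most dissimilar pair", {
  # all-equal RDM -> equal spacing
  eq <- as_rdm(matrix(1, 3, 3) - diag(3), c("a", "b", "c"))
  lay <- circular_layout(c("a", "b", "c"), eq, mode = "dissimilarity")
  gaps <- diff(c(sort(lay), sort(lay)[1] + 2 * pi))
  expect_equal(unname(gaps), rep(2 * pi / 3, 3), tolerance = 1e-10)

  # one dominant dissimilarity -> that pair ends up maximally separated,
  # matching the exhaustive necklace search oracle
  m <- matrix(1, 4, 4) - diag(4)
  m[1, 3] <- m[3, 1] <- 8
  rdm <- as_rdm(m, c("a", "b", "c", "d"))
  lay <- circular_layout(c("a", "b", "c", "d"), rdm, mode = "dissimilarity")
  sep <- function(i, j) {
    g <- abs(lay[i] - lay[j]) %% (2 * pi)
    min(g, 2 * pi - g)
  }
  pairs <- utils::combn(4, 2)
  seps <- apply(pairs, 2, function(p) sep(p[1], p[2]))
  dominant <- which(apply(pairs, 2, function(p) all(p == c(1, 3))))
  expect_equal(which.max(seps), dominant)
  # the chosen necklace does not place the dominant pair adjacently
  ordering <- attr(lay, "ordering")
  pos_a <- match("a", ordering); pos_c <- match("c", ordering)
  expect_false(abs(pos_a - pos_c) %in% c(1, 3))

  expect_error(circular_layout(letters[1:9],
                               as_rdm(matrix(1, 9, 9) - diag(9), letters[1:9]),
                               mode = "dissimilarity"),
               "8 anchors")
  expect_error(circular_layout(c("a", "b"), mode = "dissimilarity"),
               "requires an RDM")
})

test_that("the arrow formula interpolates between target and neighbour", {
  lay <- circular_layout(c("a", "b", "c", "d"))  # equal quarter gaps
  # neighbour similarity 0 -> arrow exactly at the target
  r <- c(a = 0.8, b = 0, c = -0.2, d = 0)
  ar <- arrow_angle(r, lay)
  expect_equal(ar$dist, 0)
  expect_equal(ar$arrow_angle, unname(lay["a"]))
  # equal target and neighbour similarity -> dist 0.5, halfway
  r <- c(a = 0.6, b = 0.6, c = 0, d = 0)
  ar <- arrow_angle(r, lay)
  expect_equal(ar$dist, 0.5)
  expect_equal(ar$target_label, "a")
  expect_equal(ar$neighbour_label, "b")
  expect_equal(ar$arrow_angle,
               unname((lay["a"] + 0.5 * (pi / 2)) %% (2 * pi)))
  # t = 0.6, nb = 0.3: dist = 1 - 0.6/0.9 = 1/3 of the quarter gap
  r <- c(a = 0.6, b = 0.3, c = 0, d = 0.1)
  ar <- arrow_angle(r, lay)
  expect_equal(ar$dist, 1 - 0.6 / 0.9)
  expect_equal(ar$arrow_angle,
               unname((lay["a"] + (1 / 3) * (pi / 2)) %% (2 * pi)))
  # all-nonpositive similarities -> pinned at target, flagged
  r <- c(a = -0.1, b = -0.5, c = -0.9, d = -0.2)
  ar <- arrow_angle(r, lay)
  expect_true(ar$degenerate)
  expect_equal(ar$dist, 0)
  expect_equal(ar$arrow_angle, unname(lay["a"]))
})

test_that("dist stays in [0, 0.5] and the arrow stays inside the gap", {
  lay4 <- circular_layout(c("a", "b", "c", "d"))
  for (seed in 1:50) {
    r <- withr::with_seed(seed, runif(4, -1, 1))
    names(r) <- names(lay4)
    ar <- arrow_angle(r, lay4)
    expect_gte(ar$dist, 0)
    expect_lte(ar$dist, 0.5)
    # angular distance from target to arrow never exceeds the gap to the
    # chosen neighbour
    gap <- abs(lay4[ar$target_label] - lay4[ar$neighbour_label]) %% (2 * pi)
    gap <- min(gap, 2 * pi - gap)
    off <- abs(lay4[ar$target_label] - ar$arrow_angle) %% (2 * pi)
    off <- min(off, 2 * pi - off)
    expect_lte(off, gap + 1e-12)
  }
  # two anchors: the single other anchor serves as both neighbours
  lay2 <- circular_layout(c("a", "b"))
  ar <- arrow_angle(c(a = 0.5, b = 0.5), lay2)
  expect_equal(ar$dist, 0.5)
  expect_equal(ar$neighbour_label, "b")
})

test_that("circular frames fill exactly one thermometer (or none)", {
  lay <- circular_layout(c("happy", "content", "sad", "angry"))
  style <- feedback_style(fill_cap = 1.5)
  mk_int <- function(strength, target = "happy") {
    structure(list(target_label = target, similarity = 0.4,
                   angle_theta = acos(0.4), strength = strength),
              class = "intensity_result")
  }
  sims <- c(happy = 0.4, content = 0.1, sad = -0.2, angry = 0)
  fr <- circular_frame(sims, mk_int(0.75), lay, style)
  expect_equal(sum(fr$thermometer_fills > 0), 1)
  expect_equal(unname(fr$thermometer_fills["happy"]), 0.5)
  # zero / capped strength
  expect_equal(sum(circular_frame(sims, mk_int(0), lay, style)$
                     thermometer_fills), 0)
  expect_equal(unname(circular_frame(sims, mk_int(1.5), lay,
                                     style)$thermometer_fills["happy"]), 1)
  # a target switch moves the single nonzero fill
  sims2 <- c(happy = 0.1, content = 0.5, sad = -0.2, angry = 0)
  fr2 <- circular_frame(sims2, mk_int(0.75, "content"), lay, style)
  expect_equal(names(which(fr2$thermometer_fills > 0)), "content")
  expect_error(circular_frame(sims, mk_int(1, "joyful"), lay, style),
               "not in the layout")
})
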