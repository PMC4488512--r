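test_that("planted helices are assigned to their class with hand-traced bounds", {
  cases <- list(list(class = "alpha", n = 12L),
                list(class = "310", n = 8L),
                list(class = "pi", n = 8L))
  for (cs in cases) {
    fx <- make_helix_in_coil(cs$class, n_helix = cs$n, n_flank = 6L)
    ann <- assign_segment(fx$xyz)
    expect_equal(nrow(ann), 1, info = cs$class)
    expect_equal(ann$helix_type, cs$class)
    expect_equal(ann$handedness, "right")
    ## the annotation lies on the planted residues (junction fits may trim
    ## or extend by the pseudocode's window mechanics)
    expect_gte(ann$start, fx$helix_start)
    expect_lte(ann$start, fx$helix_start + 2L)
    expect_gte(ann$end, fx$helix_end - 3L)
    expect_lte(ann$end, fx$helix_end + 1L)
    ## boundaries match an independent hand-trace of the pseudocode
    tr <- trace_segment(fx$xyz)
    expect_equal(ann$start, tr$start)
    expect_equal(ann$end, tr$end)
    expect_equal(ann$helix_type, tr$type)
  }
})

test_that("a 6-residue 3-10 plant traces to the same (empty) result", {
  fx <- make_helix_in_coil("310", n_helix = 6L, n_flank = 6L)
  ann <- assign_segment(fx$xyz)
  tr <- trace_segment(fx$xyz)
  expect_equal(nrow(ann), nrow(tr))
  expect_equal(ann$start, tr$start)
})

test_that("pi precedence: an ideal pi helix never yields an alpha call", {
  fx <- make_helix_in_coil("pi", n_helix = 8L, n_flank = 6L)
  ann <- assign_segment(fx$xyz)
  expect_false(any(ann$helix_type == "alpha"))
  expect_true(any(ann$helix_type == "pi"))
  ## an ideal alpha helix never yields a pi call (score separation)
  fx2 <- make_helix_in_coil("alpha", n_helix = 12L, n_flank = 6L)
  expect_false(any(assign_segment(fx2$xyz)$helix_type == "pi"))
})

test_that("minimum lengths hold for every emitted annotation", {
  minlen <- c(alpha = 4L, "310" = 3L, pi = 5L)
  fixtures <- list(
    make_helix_in_coil("alpha", 12L, 6L)$xyz,
    make_helix_in_coil("310", 8L, 6L)$xyz,
    make_helix_in_coil("pi", 8L, 6L)$xyz,
    make_kinked_pair("alpha", 8L)$xyz,
    generate_ideal_calphas(standard_curve("alpha"), 20, 0.1, 7))
  for (xyz in fixtures) {
    ann <- assign_segment(xyz)
    if (nrow(ann))
      expect_true(all(ann$end - ann$start + 1L >= minlen[ann$helix_type]))
  }
})

test_that("no residue carries two assignments", {
  fixtures <- list(make_helix_in_coil("pi", 8L, 4L)$xyz,
                   make_kinked_pair("alpha", 8L)$xyz)
  for (xyz in fixtures) {
    ann <- assign_segment(xyz)
    covered <- unlist(lapply(seq_len(nrow(ann)), function(k)
      ann$start[k]:ann$end[k]))
    expect_false(any(duplicated(covered)))
  }
})

test_that("short segments and all-coil segments yield nothing", {
  expect_equal(nrow(assign_segment(matrix(0, 0, 3))), 0)
  xyz4 <- generate_ideal_calphas(standard_curve("pi"), 4)
  expect_equal(nrow(assign_segment(xyz4)), 0)    # cannot reach length 5
  xyz3 <- generate_ideal_calphas(standard_curve("alpha"), 3)
  expect_equal(nrow(assign_segment(xyz3)), 0)
  strand <- generate_ideal_calphas(helical_curve(0.96, 3.34, 177.9), 15)
  expect_equal(nrow(assign_segment(strand)), 0)
})

test_that("a mirrored alpha fixture is assigned left-handed with matching bounds", {
  fx_r <- make_helix_in_coil("alpha", 12L, 6L, handedness = "right")
  ann_r <- assign_segment(fx_r$xyz)
  ## mirror the whole trace: the same helix must come back left-handed
  ## with identical boundaries
  ann_m <- assign_segment(mirror_coordinates(fx_r$xyz))
  expect_equal(ann_m$handedness, "left")
  expect_equal(ann_m$helix_type, "alpha")
  expect_equal(ann_m$start, ann_r$start)
  expect_equal(ann_m$end, ann_r$end)
  ## a fixture with only the planted helix mirrored is also found left-handed
  fx_l <- make_helix_in_coil("alpha", 12L, 6L, handedness = "left")
  ann_l <- assign_segment(fx_l$xyz)
  expect_equal(nrow(ann_l), 1)
  expect_equal(ann_l$handedness, "left")
  expect_equal(ann_l$helix_type, "alpha")
})

test_that("kinked helix pairs are split and never merged", {
  kp <- make_kinked_pair("alpha", n_each = 10L, kink_deg = 60)
  ann <- assign_segment(kp$xyz)
  alpha <- ann[ann$helix_type == "alpha", ]
  expect_equal(nrow(alpha), 2)
  expect_lte(alpha$end[1], kp$junction)
  expect_gte(alpha$start[2], kp$junction + 1L)
})

test_that("the 3-10 delta extension creates the minimum-length helix", {
  ## one g-passing residue; both following delta checks pass
  prof <- stub_profile(g = c(100, 3, 100, 100, 100, 100),
                       a = c(50, 5, 0, 0, 0, 0),
                       sd = c(1, 1, 0.05, 0.05, 1, 1), n = 6)
  res <- assign_310(prof)
  expect_equal(nrow(res$annotations), 1)
  expect_equal(res$annotations$start, 2)
  expect_equal(res$annotations$end, 4)           # 3-residue minimum emerges
  ## failing one delta check kills the run (< 3 residues)
  prof2 <- stub_profile(g = c(100, 3, 100, 100, 100, 100),
                        a = c(50, 5, 0, 0, 0, 0),
                        sd = c(1, 1, 0.05, 0.5, 1, 1), n = 6)
  expect_equal(nrow(assign_310(prof2)$annotations), 0)
})

test_that("alpha merging requires every intermediate residue to pass", {
  base <- function(mid_a = 20, mid_h = 50, mid_sd = 0.1) {
    h <- c(5, 5, 5, 5, mid_h, mid_h, 5, 5, 5, 5, 100, 100, 100)
    a <- c(0, 1, 1, 1, mid_a, mid_a, 1, 1, 1, 1, 80, 80, 80)
    sd <- c(rep(0.05, 4), mid_sd, mid_sd, rep(0.05, 7))
    stub_profile(h = h, a = a, sd = sd,
                 g = rep(100, 13), pi_s = rep(100, 13), n = 13)
  }
  merged <- assign_alpha(base())
  expect_equal(nrow(merged$annotations), 1)      # gentle bend: merged
  expect_equal(merged$annotations$start, 1)
  expect_gte(merged$annotations$end, 10)
  sharp <- assign_alpha(base(mid_a = 85))
  expect_equal(nrow(sharp$annotations), 2)       # a > a_max: not merged
  loose <- assign_alpha(base(mid_sd = 0.5))
  expect_equal(nrow(loose$annotations), 2)       # delta > delta_max
  ## helices >= 4 residues apart never merge regardless of the gap profile
  h <- c(rep(5, 4), rep(25, 4), rep(5, 4))
  far <- assign_alpha(stub_profile(h = h, a = rep(1, 12), sd = rep(0.05, 12),
                                   g = rep(100, 12), pi_s = rep(100, 12),
                                   n = 12))
  expect_equal(nrow(far$annotations), 2)
})

test_that("C-terminal extension is gated and clipped", {
  ## h jumps above h_T but stays below h_max: extend by two
  h <- c(5, 5, 5, 5, 100, 100, 500, 500)
  a <- c(0, 1, 1, 1, 30, 30, 80, 80)
  prof <- stub_profile(h = h, a = a, sd = rep(0.05, 8),
                       g = rep(100, 8), pi_s = rep(100, 8), n = 8)
  res <- assign_alpha(prof)
  expect_equal(res$annotations$end, 6)
  ## next residue already assigned: no extension
  state <- rep(FALSE, 8); state[5] <- TRUE
  res2 <- assign_alpha(prof, state = state)
  expect_equal(res2$annotations$end, 4)
  ## helix ending one residue before the segment end gains at most that one
  h3 <- c(5, 5, 5, 5, 100)
  prof3 <- stub_profile(h = h3, a = c(0, 1, 1, 1, 30), sd = rep(0.05, 5),
                        g = rep(100, 5), pi_s = rep(100, 5), n = 5)
  expect_equal(assign_alpha(prof3)$annotations$end, 5)
})

test_that("raising h_T only grows the alpha-assigned set", {
  xyz <- make_helix_in_coil("alpha", 12L, 6L, noise_sigma = 0.1,
                            seed = 11)$xyz
  prof <- profile_segment(xyz)
  covered <- function(th) {
    res <- assign_alpha(prof, th)
    unlist(lapply(seq_len(nrow(res$annotations)), function(k)
      res$annotations$start[k]:res$annotations$end[k]))
  }
  lo <- covered(threshold_config(h_T = 10))
  hi <- covered(threshold_config(h_T = 30))
  expect_true(all(lo %in% hi))
})

test_that("assignment is deterministic end to end", {
  fx <- make_helix_in_coil("alpha", 10L, 5L, noise_sigma = 0.08, seed = 2)
  a <- assign_segment(fx$xyz)
  b <- assign_segment(fx$xyz)
  expect_identical(a, b)
})

test_that("an emitted alpha helix refits a single helical curve closely", {
  for (sg in c(0.05, 0.15)) {
    fx <- make_helix_in_coil("alpha", 10L, 5L, noise_sigma = sg, seed = 6)
    ann <- assign_segment(fx$xyz)
    alpha <- ann[ann$helix_type == "alpha", ]
    for (k in seq_len(nrow(alpha))) {
      idx <- alpha$start[k]:alpha$end[k]
      if (length(idx) > 12) next
      sub <- fx$xyz[idx, , drop = FALSE]
      est <- initial_estimates(sub[1:4, ])
      cur <- helical_curve(est$r, est$p, est$t)
      model <- curve_point(cur, seq_along(idx) - 1)
      sup <- kabsch_superpose(model, sub)
      cur_placed <- helical_curve(est$r, est$p, est$t,
                                  origin = sup$translation,
                                  rotation = sup$rotation)
      d <- vapply(seq_along(idx), function(j)
        closest_point_distance(cur_placed, sub[j, ], c(j - 2, j)),
        numeric(1))
      expect_lt(sqrt(mean(d^2)), 0.5)
    }
  }
})
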