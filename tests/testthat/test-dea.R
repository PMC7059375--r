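test_that("toy frontiers reproduce the closed-form distances", {
  # lone unit spans its own frontier
  p1 <- toy_panel(data.frame(id = "a", x = 2, y = 3))
  for (r in c("crs", "vrs", "nirs"))
    expect_equal(unname(solve_dea(p1, r)$lambda), 1, tolerance = 1e-9)

  # A(1,2) dominates B(1,1) under CRS: B can double its output
  pab <- toy_panel(data.frame(id = c("A", "B"), x = c(1, 1), y = c(2, 1)))
  expect_equal(unname(solve_dea(pab, "crs")$lambda), c(1, 2),
               tolerance = 1e-9)

  # C(0.5, 0.5) is VRS-efficient (no convex combination reaches it) but
  # CRS-inefficient against A's ray
  pac <- toy_panel(data.frame(id = c("A", "C"), x = c(1, 0.5),
                              y = c(2, 0.5)))
  expect_equal(unname(solve_dea(pac, "vrs")$lambda), c(1, 1),
               tolerance = 1e-9)
  expect_equal(unname(solve_dea(pac, "crs")$lambda), c(1, 2),
               tolerance = 1e-9)
  # grid-search oracle agrees on the toy panel
  expect_equal(oracle_dea_grid(pac, 2, "crs"), 2, tolerance = 1e-3)
  expect_equal(oracle_dea_grid(pac, 2, "vrs"), 1, tolerance = 1e-3)
})

test_that("CRS scores match the ratio-form closed form on 1x1 panels", {
  for (seed in 1:5) {
    n <- sample(3:20, 1)
    pan <- random_panel(n, 1, 1, seed = 100 + seed)
    lam <- solve_dea(pan, "crs")$lambda
    expected <- vapply(seq_len(n), function(i)
      oracle_crs_ratio(pan$X[1, ], pan$Y[1, ], i), numeric(1))
    expect_equal(unname(lam), expected, tolerance = 1e-9)
  }
})

test_that("LP scores agree with the brute-force grid oracle", {
  cases <- list(c(n = 5, p = 1, q = 2), c(n = 6, p = 2, q = 1),
                c(n = 6, p = 2, q = 2))
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    pan <- random_panel(cs["n"], cs["p"], cs["q"], seed = 200 + ci)
    for (r in c("crs", "vrs", "nirs")) {
      lam <- solve_dea(pan, r)$lambda
      for (i in seq_len(cs[["n"]])) {
        expect_equal(unname(lam[i]), oracle_dea_grid(pan, i, r),
                     tolerance = 0.02,
                     label = sprintf("panel %d unit %d %s", ci, i, r))
      }
    }
  }
})

test_that("distances nest across technologies and respect units invariance", {
  for (seed in 1:3) {
    pan <- random_panel(10, 2, 2, seed = 300 + seed)
    l_crs <- solve_dea(pan, "crs")$lambda
    l_vrs <- solve_dea(pan, "vrs")$lambda
    l_nirs <- solve_dea(pan, "nirs")$lambda
    expect_true(all(l_vrs <= l_nirs + 1e-9))
    expect_true(all(l_nirs <= l_crs + 1e-9))

    scaled <- pan
    scaled$X[1, ] <- scaled$X[1, ] * 1000
    scaled$Y[2, ] <- scaled$Y[2, ] * 0.004
    for (r in c("crs", "vrs", "nirs"))
      expect_equal(solve_dea(scaled, r)$lambda, solve_dea(pan, r)$lambda,
                   tolerance = 1e-9)
  }
})

test_that("reference-set monotonicity: dominated units are inert, dominating units tighten", {
  pan <- random_panel(8, 2, 2, seed = 42)
  base <- solve_dea(pan, "vrs")$lambda
  d <- as.data.frame(pan)

  dominated <- d[1, ]
  dominated$id <- "dominated"
  dominated[c("x1", "x2")] <- dominated[c("x1", "x2")] * 1.5
  dominated[c("y1", "y2")] <- dominated[c("y1", "y2")] * 0.5
  p2 <- toy_panel(rbind(d[-2], dominated[-2]))
  expect_equal(unname(solve_dea(p2, "vrs")$lambda[seq_len(8)]),
               unname(base), tolerance = 1e-9)

  dominating <- d[1, ]
  dominating$id <- "dominating"
  dominating[c("y1", "y2")] <- vapply(c("y1", "y2"),
                                      function(cn) max(d[[cn]]) * 2,
                                      numeric(1))
  dominating[c("x1", "x2")] <- vapply(c("x1", "x2"),
                                      function(cn) min(d[[cn]]),
                                      numeric(1))
  p3 <- toy_panel(rbind(d[-2], dominating[-2]))
  expect_true(all(solve_dea(p3, "vrs")$lambda[seq_len(8)] >=
                    base - 1e-9))
})

test_that("efficiency table satisfies the TE = PTE x SE decomposition", {
  pan <- random_panel(12, 2, 2, seed = 7)
  eff <- efficiency_table(pan)
  expect_equal(eff$te, eff$pte * eff$se, tolerance = 1e-9)
  expect_true(all(eff$te <= eff$pte + 1e-12))
  expect_true(all(eff$se > 0 & eff$se <= 1))
  expect_true(any(eff$te == 1))
  expect_true(any(eff$pte == 1))

  # identical units all sit on the frontier together
  same <- toy_panel(data.frame(id = letters[1:4], x = 2, y = 3))
  es <- efficiency_table(same)
  expect_equal(es$te, rep(1, 4))
  expect_equal(es$pte, rep(1, 4))
  expect_equal(es$se, rep(1, 4))
  expect_equal(es$rts_class, rep("CRS", 4))
})

test_that("returns-to-scale classification follows the NIRS rule", {
  expect_equal(classify_rts(1, 1, 1), "CRS")
  expect_error(classify_rts(0.5, 1, 1), ">= 1")
  expect_error(classify_rts(1, 1, 1, tol = -1), "nonnegative")

  # toy unit C lies below the most productive scale: lambda_nirs equals
  # lambda_crs, hence IRS (verified against the grid oracle)
  pac <- toy_panel(data.frame(id = c("A", "C"), x = c(1, 0.5),
                              y = c(2, 0.5)))
  eff <- efficiency_table(pac)
  expect_equal(eff$rts_class[2], "IRS")
  expect_equal(oracle_dea_grid(pac, 2, "nirs"), eff$lambda_nirs[2],
               tolerance = 1e-3)

  # a unit strictly beyond the most productive scale of a concave
  # 1-in/1-out frontier is DRS: frontier y = sqrt(x), MPS at the
  # steepest ray through small units
  d <- data.frame(id = c("s", "m", "big"), x = c(1, 4, 16),
                  y = sqrt(c(1, 4, 16)))
  pan <- toy_panel(d)
  eff <- efficiency_table(pan)
  expect_equal(eff$rts_class[3], "DRS")
  expect_equal(eff$rts_class[1], "CRS")
})
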