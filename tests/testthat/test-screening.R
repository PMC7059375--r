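make_candidates <- function(n = 60, seed = 3) {
  set.seed(seed)
  base1 <- rnorm(n, 10, 2)
  base2 <- rnorm(n, 5, 1)
  out1 <- 2 * base1 + rnorm(n, 0, 0.5)
  out2 <- base2 + rnorm(n, 0, 0.3)
  data.frame(
    in_a = base1,
    in_a_dup = base1,                     # perfectly collinear with in_a
    in_b = base2 + rnorm(n, 0, 0.2),
    in_noise = rnorm(n),                  # unrelated to any output
    out_1 = out1,
    out_2 = out2)
}

test_that("collinear candidates are pruned and annotated", {
  d <- make_candidates()
  rep <- screen_variables(d, inputs = c("in_a", "in_a_dup", "in_b",
                                        "in_noise"),
                          outputs = c("out_1", "out_2"))
  dup_drop <- rep$dropped[rep$dropped$rule == "correlation rule", ]
  expect_equal(nrow(dup_drop), 1L)
  expect_true(dup_drop$variable %in% c("in_a", "in_a_dup"))
  expect_equal(dup_drop$detail, 1, tolerance = 1e-12)
  expect_equal(sum(c("in_a", "in_a_dup") %in% rep$final_inputs), 1L)
})

test_that("noise inputs fail the R-squared screen", {
  d <- make_candidates()
  rep <- screen_variables(d, inputs = c("in_a", "in_b", "in_noise"),
                          outputs = c("out_1", "out_2"))
  expect_false("in_noise" %in% rep$final_inputs)
  expect_true(all(c("in_a", "in_b") %in% rep$final_inputs))
  noise_row <- rep$dropped[rep$dropped$variable == "in_noise", ]
  expect_equal(noise_row$rule, "R-squared screen")
  expect_lt(noise_row$detail, 0.5)
})

test_that("clustering recovers planted variable groups", {
  set.seed(8)
  n <- 80
  f1 <- rnorm(n); f2 <- rnorm(n)
  d <- data.frame(a1 = f1 + rnorm(n, 0, 0.1),
                  a2 = 2 * f1 + rnorm(n, 0, 0.1),
                  a3 = -f1 + rnorm(n, 0, 0.1),
                  b1 = f2 + rnorm(n, 0, 0.1),
                  b2 = 3 * f2 + rnorm(n, 0, 0.1),
                  b3 = -0.5 * f2 + rnorm(n, 0, 0.1))
  rep <- screen_variables(d, inputs = c("a1", "a2", "a3"),
                          outputs = c("b1", "b2", "b3"),
                          r_threshold = 0.995, k = 2)
  cl <- rep$clusters
  expect_equal(length(unique(cl[c("a1", "a2", "a3")])), 1L)
  expect_equal(length(unique(cl[c("b1", "b2", "b3")])), 1L)
  expect_false(cl[["a1"]] == cl[["b1"]])
})

test_that("screening is invariant to candidate column order", {
  d <- make_candidates()
  r1 <- screen_variables(d, inputs = c("in_a", "in_a_dup", "in_b",
                                       "in_noise"),
                         outputs = c("out_1", "out_2"))
  r2 <- screen_variables(d[rev(names(d))],
                         inputs = c("in_noise", "in_b", "in_a_dup",
                                    "in_a"),
                         outputs = c("out_2", "out_1"))
  expect_setequal(r1$final_inputs, r2$final_inputs)
  expect_setequal(r1$final_outputs, r2$final_outputs)
})

test_that("constant columns are dropped with a warning", {
  d <- make_candidates()
  d$flat <- 3
  expect_warning(
    rep <- screen_variables(d, inputs = c("in_a", "in_b", "flat"),
                            outputs = c("out_1", "out_2")),
    "constant")
  expect_false("flat" %in% rep$final_inputs)
})

test_that("pooled t-test matches the hand formula and the permutation oracle", {
  a <- c(4.1, 5.2, 4.8, 5.5, 4.9, 5.3, 4.6, 5.1, 5.0, 4.7)
  b <- a + 2
  cg <- compare_groups(a, b)
  sp <- sqrt((9 * var(a) + 9 * var(b)) / 18)
  expect_equal(cg$statistic, (mean(a) - mean(b)) / (sp * sqrt(2 / 10)),
               tolerance = 1e-12)
  # antisymmetry
  cg2 <- compare_groups(b, a)
  expect_equal(cg2$statistic, -cg$statistic, tolerance = 1e-12)
  expect_equal(cg2$p.value, cg$p.value, tolerance = 1e-12)
  # identical groups
  cg3 <- compare_groups(a, a)
  expect_equal(cg3$statistic, 0)
  expect_equal(cg3$p.value, 1)
  expect_error(compare_groups(rep(1, 5), rep(2, 5)), "zero pooled")
  # permutation cross-check on an overlapping fixture
  set.seed(5)
  g1 <- rnorm(12, 5, 1); g2 <- rnorm(12, 5.8, 1)
  cg4 <- compare_groups(g1, g2)
  expect_lt(abs(cg4$p.value - oracle_perm_p(g1, g2)), 0.02)
})

test_that("band distribution counts half-open bands with a frontier band", {
  bd <- band_distribution(c(0.5, 0.85, 1.0))
  expect_equal(bd$count[bd$band == "[0, 0.7)"], 1L)
  expect_equal(bd$count[bd$band == "[0.8, 0.9)"], 1L)
  expect_equal(bd$count[bd$band == "=1"], 1L)
  expect_equal(sum(bd$percent), 100, tolerance = 1e-9)

  all1 <- band_distribution(rep(1, 7))
  expect_equal(all1$percent[all1$band == "=1"], 100)

  for (seed in 1:5) {
    set.seed(seed)
    s <- runif(50, 0.01, 1)
    expect_equal(sum(band_distribution(s)$percent), 100,
                 tolerance = 1e-9)
    expect_equal(sum(band_distribution(s)$count), 50L)
  }
  expect_error(band_distribution(c(0.5, 1.2)), "0, 1")
  expect_error(band_distribution(c(0.5), band_edges = c(0, 0.4, 0.3, 1)),
               "increasing")
})
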