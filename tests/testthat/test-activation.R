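test_that("EM recovers well-separated mixture components", {
  set.seed(101)
  v <- c(rnorm(500, 4, 1), rnorm(500, 10, 1))
  cal <- fit_mixture(v)
  expect_equal(cal$degenerate_flag, "ok")
  expect_lt(abs(cal$off_mean - 4), 0.3)
  expect_lt(abs(cal$on_mean - 10), 0.3)
  expect_gte(cal$on_mean, cal$off_mean)
  expect_lt(abs(cal$on_weight - 0.5), 0.1)

  # cross-check against an independent EM implementation
  withr::local_package("mclust")
  mfit <- Mclust(v, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(abs(cal$off_mean - min(mfit$parameters$mean)), 0.1)
  expect_lt(abs(cal$on_mean - max(mfit$parameters$mean)), 0.1)
})

test_that("degenerate inputs are flagged, not errored", {
  cal <- fit_mixture(rep(7, 100))
  expect_equal(cal$degenerate_flag, "constant")
  expect_equal(activation_probability(c(1, 7, 20), cal), rep(0.5, 3))

  set.seed(7)
  cal1 <- fit_mixture(rnorm(1000, 7, 1))
  expect_equal(cal1$degenerate_flag, "unimodal")
  expect_equal(activation_probability(7, cal1), 0.5)
})

test_that("fit_mixture validates its input", {
  expect_error(fit_mixture(rnorm(10)), "at least 50")
  expect_error(fit_mixture(c(rnorm(60), NA)), "finite")
  expect_error(fit_mixture(c(rnorm(60), Inf)), "finite")
  expect_error(activation_probability(NaN, fit_mixture(rnorm(100))),
               "finite")
})

test_that("posterior probability follows the two-component formula", {
  cal <- structure(list(feature_id = "f", off_mean = 4, off_sd = 1,
                        on_mean = 10, on_sd = 1, on_weight = 0.5,
                        n_reference = 100L, degenerate_flag = "ok"),
                   class = "mixture_calibration")
  # symmetric midpoint with equal weights and sds
  expect_equal(activation_probability(7, cal), 0.5)
  # at the ON mean with well-separated components
  expect_gt(activation_probability(10, cal), 0.99)
  # monotone in expression when sds are equal
  xs <- seq(0, 14, by = 0.25)
  expect_true(all(diff(activation_probability(xs, cal)) >= 0))
  # matches the explicit density ratio at arbitrary points
  for (x in c(2.3, 5.1, 8.8)) {
    num <- 0.5 * dnorm(x, 10, 1)
    expect_equal(activation_probability(x, cal),
                 num / (num + 0.5 * dnorm(x, 4, 1)), tolerance = 1e-12)
  }
})

test_that("union combination has its closed forms and algebraic properties", {
  expect_equal(combine_to_gene(0.5), 0.5)
  expect_equal(combine_to_gene(c(0.5, 0.5)), 0.75)
  expect_equal(combine_to_gene(c(0.9, 0, 0)), 0.9)
  expect_equal(node_probability(rep(0.2, 9)), 1 - 0.8^9)
  expect_equal(node_probability(c(1, 0.3)), 1)
  expect_equal(node_probability(0), 0)
  expect_error(combine_to_gene(numeric(0)), "empty")
  expect_error(combine_to_gene(1.2), "\\[0, 1\\]")

  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(1:6, 1))
    u <- combine_probabilities(p)
    expect_gte(u, max(p))          # bounded below by any member
    expect_lte(u, 1)
    expect_equal(u, combine_probabilities(rev(p)))            # commutative
    if (length(p) > 1)                                        # associative
      expect_equal(u, combine_probabilities(
        c(combine_probabilities(p[1:2]), p[-(1:2)], 0)))
  }
  expect_equal(combine_probabilities(c(0.2, 0.6), "mean"), 0.4)
  expect_equal(combine_probabilities(c(0.2, 0.6), "min"), 0.2)
})

test_that("calibrated scoring recovers planted ON samples", {
  set.seed(11)
  n <- 400
  on <- runif(n) < 0.5
  v <- ifelse(on, rnorm(n, 10, 1), rnorm(n, 4, 1))  # >= 4 sd separation
  cal <- fit_mixture(v)
  post <- activation_probability(v, cal)
  expect_gte(mean(post[on]), 0.9)
  expect_lte(mean(post[!on]), 0.1)
  expect_true(all(post >= 0 & post <= 1))
})

test_that("matrix scoring pipeline keeps probabilities in [0,1] end to end", {
  set.seed(21)
  expr <- rbind(ps1 = c(rnorm(30, 4, 1), rnorm(30, 10, 1)),
                ps2 = c(rnorm(30, 10, 1), rnorm(30, 4, 1)),
                ps3 = rep(5, 60))
  colnames(expr) <- sprintf("s%02d", 1:60)
  cals <- fit_calibrations(expr, min_n = 50)
  expect_equal(cals$ps3$degenerate_flag, "constant")

  pm <- probeset_probabilities(expr, cals)
  expect_equal(dim(pm), c(60L, 3L))
  expect_true(all(pm >= 0 & pm <= 1))
  expect_equal(unname(pm[, "ps3"]), rep(0.5, 60))

  map <- data.frame(probeset_id = c("ps1", "ps2", "ps3"),
                    gene_id = c("gA", "gA", "gB"))
  gp <- gene_probabilities(pm, map)
  expect_equal(colnames(gp), c("gA", "gB"))
  expect_equal(unname(gp[, "gA"]),
               unname(1 - (1 - pm[, "ps1"]) * (1 - pm[, "ps2"])))

  # node with an unmeasured gene drops it; fully unmeasured node gets 0.5
  g <- pathway_graph("pw",
                     data.frame(source = "N1", target = "N2",
                                sign = "activation"),
                     genes = list(N1 = c("gA", "gZ"), N2 = "gMissing"),
                     receptors = "N1", effectors = "N2")
  expect_warning(np <- node_probabilities(gp, g), "no measured gene")
  expect_equal(unname(np[, "N1"]), unname(gp[, "gA"]))
  expect_equal(unname(np[, "N2"]), rep(0.5, 60))
})

test_that("calibrations survive a TSV round trip", {
  set.seed(31)
  expr <- matrix(rnorm(100 * 2, 6, 2), 2,
                 dimnames = list(c("a", "b"), sprintf("s%d", 1:100)))
  cals <- fit_calibrations(expr)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_calibrations(cals, f)
  back <- read_calibrations(f)
  expect_equal(back$a$on_mean, cals$a$on_mean, tolerance = 1e-9)
  expect_equal(activation_probability(5, back$b),
               activation_probability(5, cals$b), tolerance = 1e-9)
})
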