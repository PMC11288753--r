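# independent BH step-up oracle: q_i = min over j >= rank(i) of
# p_(j) * m / j, capped at 1
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- pmin(p[o] * m / seq_len(m), 1)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

test_that("welch t behaves on identity, shift and swap", {
  expect_equal(welchT(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(welchT(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  set.seed(1)
  a <- rnorm(50) + 10
  b <- rnorm(50)
  expect_lt(welchT(a, b)$p, 1e-10)
  w1 <- welchT(a, b); w2 <- welchT(b, a)
  expect_equal(w1$p, w2$p)
  expect_equal(w1$effect, -w2$effect)
  expect_error(welchT(1, c(1, 2)), "n >= 2")
})

test_that("zero-variance samples follow the stated conventions", {
  eq <- welchT(c(2, 2, 2), c(2, 2))
  expect_equal(eq$p, 1)
  expect_equal(eq$note, "zero_variance_equal")
  sep <- welchT(c(2, 2, 2), c(3, 3))
  expect_equal(sep$p, 0)
  expect_equal(sep$note, "zero_variance_separated")
})

test_that("noiseless additive designs have zero interaction SS", {
  r <- rep(c("r1", "r2", "r3"), each = 8)
  c_ <- rep(rep(c("c1", "c2"), each = 4), 3)
  rEff <- c(r1 = 0, r2 = 1, r3 = 2.5)
  cEff <- c(c1 = 0, c2 = 0.7)
  y <- rEff[r] + cEff[c_]
  out <- twoWayFactorial(y, r, c_)
  int <- out$effects[out$effects$term == "R:C", ]
  expect_lt(int$sumsq, 1e-10)
  expect_equal(int$p, 1)
})

test_that("identical responses give the all-ones p convention", {
  out <- twoWayFactorial(rep(3, 12), rep(c("a", "b"), 6),
                         rep(c("x", "x", "y", "y"), 3))
  expect_true(all(out$effects$p == 1))
  expect_true(all(out$effects$note == "constant_response"))
  expect_null(out$posthoc)
})

test_that("empty cells and thin cells are refused by name", {
  r <- c("a", "a", "b", "b")
  c_ <- c("x", "x", "x", "x")
  expect_error(twoWayFactorial(1:4, r, c_), "2 levels")
  r2 <- c("a", "a", "a", "b", "b", "b")
  c2 <- c("x", "x", "y", "x", "x", "x")
  expect_error(twoWayFactorial(1:6, r2, c2), "b x y")
})

test_that("the factorial design detects the condition effect with power", {
  # two conditions x five cell types, generator-default deltas and
  # per-nucleus jitter, n = 15 per cell
  deltas <- c(stomata = 0.50, pavement = 0.15, spongy_mesophyll = 0.15,
              bundle_sheath = 0.20, vascular_bundle = 0.45)
  hits <- 0L
  for (run in 1:100) {
    set.seed(500 + run)
    cellType <- rep(names(deltas), each = 30)
    condition <- rep(rep(c("control", "infested"), each = 15), 5)
    y <- 1 + deltas[cellType] * (condition == "infested") +
      rnorm(length(cellType), 0, 0.05)
    out <- twoWayFactorial(y, condition, cellType)
    if (out$effects$significant[out$effects$term == "R"]) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("post hoc tables appear only when gated significant", {
  set.seed(99)
  r <- rep(c("ctl", "inf"), each = 10)
  c_ <- rep(rep(c("t1", "t2"), each = 5), 2)
  # strong interaction
  y <- rnorm(20, 0, 0.1) + ifelse(r == "inf" & c_ == "t2", 3, 0)
  out <- twoWayFactorial(y, r, c_, posthoc = "sidak")
  expect_false(is.null(out$posthoc))
  # pure noise: no post hoc
  yn <- rnorm(20)
  outN <- twoWayFactorial(yn, r, c_)
  if (!any(outN$effects$significant)) expect_null(outN$posthoc)
})

test_that("BH q-values match the step-up oracle", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhFdr(0.2), 0.2)
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  set.seed(7)
  for (i in 1:25) {
    p <- runif(sample(2:40, 1))
    expect_equal(bhFdr(p), bhOracle(p))
  }
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("q-values dominate p-values and ignore input order", {
  set.seed(8)
  p <- runif(30)
  q <- bhFdr(p)
  expect_true(all(q >= p))
  perm <- sample(30)
  expect_equal(bhFdr(p[perm]), q[perm])
})

test_that("count comparison flags only the depleted class", {
  set.seed(9)
  mk <- function(cond, meso) {
    n <- length(meso)
    data.frame(image = paste0(cond, seq_len(n)), condition = cond,
               stomata = 10 + rbinom(n, 2, 0.5),
               pavement = 8 + rbinom(n, 2, 0.5),
               spongy_mesophyll = meso,
               bundle_sheath = 5 + rbinom(n, 2, 0.5),
               vascular_bundle = 5 + rbinom(n, 2, 0.5))
  }
  tab <- rbind(mk("control", 60 + rbinom(8, 4, 0.5)),
               mk("infested", 42 + rbinom(8, 4, 0.5)))
  out <- countComparison(tab)
  expect_lt(out$q[out$cell_type == "spongy_mesophyll"], 0.05)
  others <- out$q[!out$cell_type %in% c("spongy_mesophyll", "total")]
  expect_true(all(others > 0.05))
  expect_lt(out$effect[out$cell_type == "spongy_mesophyll"], 0)
})

test_that("identical count tables give the p = 1 convention", {
  base <- data.frame(image = paste0("i", 1:4),
                     condition = rep(c("control", "infested"), each = 2),
                     stomata = 10, pavement = 8, spongy_mesophyll = 60,
                     bundle_sheath = 5, vascular_bundle = 5)
  out <- countComparison(base)
  expect_true(all(out$p == 1))
  expect_true(all(out$q == 1))
  one <- base[c(1, 3), ]
  expect_error(countComparison(one), ">= 2 images")
})

test_that("pearson R2 handles exact, orthogonal and textbook cases", {
  x <- 1:10
  expect_equal(pearsonR2(x, 2 * x + 1), 1.0)
  set.seed(10)
  z <- rnorm(50)
  y <- rnorm(50)
  yOrth <- residuals(lm(y ~ z))            # orthogonal to z by construction
  expect_lt(pearsonR2(z, yOrth), 1e-12)
  # hand formula oracle: x = {1,2,3}, y = {1,2,4} -> 81/84
  expect_equal(pearsonR2(c(1, 2, 3), c(1, 2, 4)), 81 / 84)
  expect_equal(round(pearsonR2(c(1, 2, 3), c(1, 2, 4)), 4), 0.9643)
  expect_error(pearsonR2(c(1, 1, 1), 1:3), "constant")
  expect_error(pearsonR2(1:2, 1:2), "n >= 3")
})
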