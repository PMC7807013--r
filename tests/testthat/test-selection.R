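test_that("AICc and QAICc closed forms", {
  expect_equal(aicc(-47, k = 3, n = 20), 101.5)
  expect_error(aicc(-47, k = 19, n = 20), "exceed")
  # QAICc at chat = 1 equals AICc with one extra parameter
  expect_equal(qaicc(-47, chat = 1, k = 3, n = 20), aicc(-47, k = 4, n = 20))
  # the small-sample correction vanishes as n grows
  expect_lt(abs(aicc(-47, 3, 1e6) - (2 * 47 + 2 * 3)), 1e-4)
})

test_that("delta-2 / fewest-parameters rule on constructed tables", {
  sel <- select_delta2(c(100, 101.1, 103), k = c(4, 2, 1))
  expect_equal(which(sel$final), 2L)
  expect_equal(sel$in_delta2, c(TRUE, TRUE, FALSE))
  # shift invariance
  sel2 <- select_delta2(c(100, 101.1, 103) + 57.3, k = c(4, 2, 1))
  expect_equal(sel2$final, sel$final)
  # tie in k broken by the better criterion
  sel3 <- select_delta2(c(100, 100.5, 101.9), k = c(2, 2, 5))
  expect_equal(which(sel3$final), 1L)
})

test_that("candidate sets respect marginality", {
  d <- data.frame(y = rnorm(60),
                  a = gl(2, 30), b = gl(2, 15, 60), x = rnorm(60))
  st <- rank_subsets(model_spec("y", c("a", "b", "a:b", "x"), "gaussian"), d)
  with_int <- grepl("a:b", st$model)
  for (m in st$model[with_int]) {
    trm <- strsplit(m, " \\+ ")[[1]]
    expect_true(all(c("a", "b") %in% trm), label = m)
  }
  # 2^2 subsets of {a, x} joined by b... enumerated count: all subsets of
  # {a,b,x} (8) plus interaction models {a,b,ab} x {1,x} (2) = 10
  expect_equal(nrow(st), 10L)
})

test_that("null-true data selects the null model in the majority of reps", {
  n_final_null <- 0L
  for (r in 1:100) {
    set.seed(3000 + r)
    d <- data.frame(y = rnorm(100), x = rnorm(100), g = gl(2, 50))
    st <- rank_subsets(model_spec("y", c("x", "g"), "gaussian"), d)
    if (st$model[st$final] == "1") n_final_null <- n_final_null + 1L
  }
  expect_gt(n_final_null, 50L)
})

test_that("a strong interaction is retained by selection", {
  retained <- 0L
  for (r in 1:30) {
    set.seed(4000 + r)
    n <- 141
    strategy <- sample(c("m", "r"), n, replace = TRUE)
    area <- sample(c("A", "B"), n, replace = TRUE)
    y <- 1.0 * (strategy == "m" & area == "B") + rnorm(n)
    st <- rank_subsets(model_spec("y", c("strategy", "area",
                                         "strategy:area"), "gaussian"),
                       data.frame(y, strategy, area))
    if (grepl("strategy:area", st$model[st$final])) retained <- retained + 1L
  }
  expect_gte(retained / 30, 0.7)
})

test_that("overdispersion estimate is calibrated", {
  set.seed(21)
  # binomial-true: chat near 1 (raw value, before flooring)
  m <- 20
  x <- rnorm(200)
  y <- rbinom(200, m, plogis(0.3 * x))
  d <- data.frame(p = y / m, x = x)
  fit <- suppressWarnings(glm(p ~ x, family = binomial(),
                              weights = rep(m, 200), data = d))
  ch <- estimate_chat(fit)
  expect_gte(attr(ch, "raw"), 0.8)
  expect_lte(attr(ch, "raw"), 1.2)
  expect_gte(ch, 1)

  # beta-binomial (rho = 0.1): chat above 1 in nearly all reps
  above <- 0L
  for (r in 1:40) {
    set.seed(500 + r)
    ab <- 1 / 0.1 - 1  # intra-class correlation rho = 0.1
    pr <- rbeta(200, 0.5 * ab, 0.5 * ab)
    yb <- rbinom(200, m, pr)
    fb <- suppressWarnings(glm(I(yb / m) ~ 1, family = binomial(),
                               weights = rep(m, 200)))
    if (attr(estimate_chat(fb), "raw") > 1) above <- above + 1L
  }
  expect_gte(above / 40, 0.95)

  # zero residual df
  d2 <- data.frame(y = c(0, 1), x = c(0, 1))
  f2 <- suppressWarnings(glm(y ~ x, family = binomial(), data = d2))
  expect_error(estimate_chat(f2), "zero residual df")
})

test_that("post-hoc contrasts localise an area-specific deficit", {
  # deficit only in area B: the B contrast should carry the signal
  b_smaller <- 0L
  for (r in 1:20) {
    set.seed(700 + r)
    n <- 200
    strategy <- factor(sample(c("migrant", "resident"), n, replace = TRUE))
    area <- factor(sample(c("A", "B"), n, replace = TRUE))
    y <- -1.0 * (strategy == "migrant" & area == "B") + rnorm(n)
    fit <- lm(y ~ strategy * area)
    ph <- posthoc_contrasts(fit)
    pA <- ph$p_adjusted[1]
    pB <- ph$p_adjusted[2]
    if (pB < pA) b_smaller <- b_smaller + 1L
  }
  expect_gte(b_smaller / 20, 0.9)
})

test_that("adjusted p-values dominate raw p-values", {
  set.seed(9)
  n <- 120
  strategy <- factor(sample(c("migrant", "resident"), n, replace = TRUE))
  area <- factor(sample(c("A", "B"), n, replace = TRUE))
  y <- rnorm(n)
  fit <- lm(y ~ strategy * area)
  ph <- posthoc_contrasts(fit)
  raw <- 2 * pnorm(-abs(ph$statistic))
  expect_true(all(ph$p_adjusted >= raw - 1e-10))
  expect_true(all(ph$p_adjusted >= 0 & ph$p_adjusted <= 1))
})

test_that("post-hoc contrasts refuse a final model without the interaction", {
  d <- data.frame(y = rnorm(50),
                  strategy = factor(sample(c("m", "r"), 50, TRUE)),
                  area = factor(sample(c("A", "B"), 50, TRUE)))
  fit <- lm(y ~ strategy + area, data = d)
  expect_error(posthoc_contrasts(fit), "interaction")
})

test_that("type-I error of adjusted contrasts stays at or below nominal", {
  rejections <- 0L
  n_reps <- 200
  for (r in seq_len(n_reps)) {
    set.seed(9000 + r)
    n <- 100
    strategy <- factor(sample(c("m", "r"), n, replace = TRUE))
    area <- factor(sample(c("A", "B"), n, replace = TRUE))
    fit <- lm(rnorm(n) ~ strategy * area)
    ph <- posthoc_contrasts(fit)
    if (any(ph$p_adjusted[1:2] < 0.05)) rejections <- rejections + 1L
  }
  # family-wise over the two strategy contrasts; allow Monte Carlo slack
  expect_lte(rejections / n_reps, 0.05 + 2 * sqrt(0.05 * 0.95 / n_reps))
})
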