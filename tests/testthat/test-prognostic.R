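merged_fixture <- function(values, life, sex = "female", age = 6,
                           strains = NULL) {
  n <- length(values)
  if (is.null(strains)) strains <- sprintf("S%d", seq_len(n))
  tab <- make_table(strain = strains, sex = sex, age = age,
                    values = list(f = values))
  ls <- tiny_lifespans(unique(strains), sexes = sex,
                       life = life[!duplicated(strains)])
  m <- merge_lifespan(tab, ls)
  m$life_expectancy <- life  # allow per-record control in fixtures
  m
}

test_that("correlate_lifespan: identity, relevance gate and degenerate cells", {
  life <- c(18, 22, 26, 30, 34)
  m <- merged_fixture(values = life, life = life)
  cell <- correlate_lifespan(m, "f", "female", 6)
  expect_equal(cell$pearson_r, 1)
  expect_true(cell$relevant)

  # |r| above r_min but p above alpha: the p gate wins
  set.seed(21)
  repeat {
    x <- rnorm(8); y <- rnorm(8)
    r <- cor(x, y)
    p <- cor.test(x, y)$p.value
    if (abs(r) >= 0.25 && p > 0.2) break
  }
  m2 <- merged_fixture(values = x, life = 20 + 2 * y)
  cell2 <- correlate_lifespan(m2, "f", "female", 6)
  expect_gte(abs(cell2$pearson_r), 0.2)
  expect_false(cell2$relevant)

  m3 <- merged_fixture(values = rep(1, 5), life = c(18, 22, 26, 30, 34))
  cell3 <- correlate_lifespan(m3, "f", "female", 6)
  expect_true(cell3$degenerate)
  expect_false(cell3$relevant)
  expect_true(is.na(cell3$pearson_r))
})

test_that("correlate_lifespan matches the covariance/SD oracle on a 6-pair table", {
  vals <- c(2.3, 1.9, 3.4, 2.8, 1.2, 2.0)
  life <- c(24, 21, 31, 28, 17, 22)
  m <- merged_fixture(values = vals, life = life)
  cell <- correlate_lifespan(m, "f", "female", 6)
  oracle <- cov(vals, life) / (sd(vals) * sd(life))
  expect_equal(cell$pearson_r, oracle, tolerance = 1e-12)
})

test_that("cox_univariate: null case, sign concordance and separation flag", {
  set.seed(8)
  life <- runif(200, 15, 35)
  m_null <- merged_fixture(values = rnorm(200), life = life)
  null_fit <- cox_univariate(m_null, "f", "female", 6)
  expect_lt(abs(null_fit$coefficient), 0.2)
  expect_gt(null_fit$p_value, 0.05)

  # strong positive association with lifespan: hazard-decreasing
  m_pos <- merged_fixture(values = life + rnorm(200, 0, 2), life = life)
  pos_fit <- cox_univariate(m_pos, "f", "female", 6)
  expect_lt(pos_fit$coefficient, 0)
  expect_gt(pos_fit$display_sign, 0)
  expect_equal(sign(pos_fit$display_sign),
               sign(correlate_lifespan(m_pos, "f", "female", 6)$pearson_r))

  # perfect ranking: monotone likelihood, flagged and capped
  life5 <- c(18, 22, 26, 30, 34)
  m_sep <- merged_fixture(values = life5, life = life5)
  sep_fit <- cox_univariate(m_sep, "f", "female", 6)
  expect_true(sep_fit$separation)
  expect_lte(abs(sep_fit$coefficient), 15)
  expect_gt(sep_fit$display_sign, 0)
})

test_that("cox_univariate matches the grid-search partial-likelihood oracle", {
  set.seed(31)
  for (i in 1:5) {
    vals <- rnorm(5)
    life <- sample(seq(16, 32, by = 4)) + runif(5, -1, 1)  # tie-free
    m <- merged_fixture(values = vals, life = life)
    fit <- cox_univariate(m, "f", "female", 6)
    z <- standardize(vals)
    expect_equal(fit$coefficient, oracle_cox_coef(z, life), tolerance = 1e-4)
  }
})

test_that("tie-free partial likelihood is invariant to monotone time transforms", {
  set.seed(14)
  vals <- rnorm(12)
  life <- runif(12, 15, 35)
  m1 <- merged_fixture(values = vals, life = life)
  m2 <- merged_fixture(values = vals, life = life^3 / 100)
  f1 <- cox_univariate(m1, "f", "female", 6)
  f2 <- cox_univariate(m2, "f", "female", 6)
  expect_equal(f1$coefficient, f2$coefficient, tolerance = 1e-6)
})

test_that("cox_multivariate reduces to univariate and detects collinearity", {
  set.seed(17)
  n <- 60
  life <- runif(n, 15, 35)
  tab <- make_table(strain = sprintf("S%d", rep(1:15, each = 4)),
                    sex = "female", age = 6,
                    values = list(a = 0.3 * life + rnorm(n),
                                  b = -0.2 * life + rnorm(n)))
  tab$a2 <- 2 * tab$a - 1
  attr(tab, "features") <- c("a", "b", "a2")
  ls <- tiny_lifespans(sprintf("S%d", 1:15), life = runif(15, 15, 35))
  m <- merge_lifespan(tab, ls)
  m$life_expectancy <- life

  uni <- cox_univariate(m, "a", "female", 6)
  multi1 <- cox_multivariate(m, "a", "female", 6)
  expect_equal(multi1$coefficient, uni$coefficient, tolerance = 1e-8)
  expect_true(!is.null(attr(multi1, "n_strains")))

  multi2 <- cox_multivariate(m, c("a", "b"), "female", 6)
  expect_equal(multi2$coefficient[1], uni$coefficient,
               tolerance = 2 * multi2$se[1])

  err <- expect_error(cox_multivariate(m, c("a", "a2"), "female", 6),
                      class = "agemarkers_collinearity_error")
  expect_match(conditionMessage(err), "a2")

  expect_error(cox_multivariate(m[1:3, ], c("a", "b"), "female", 6),
               class = "agemarkers_insufficient_data")
})

test_that("relevance is monotone in |r| and in p", {
  life <- c(18, 22, 26, 30, 34, 21, 27, 33)
  set.seed(9)
  m <- merged_fixture(values = life + rnorm(8, 0, 6), life = life)
  strict <- correlate_lifespan(m, "f", "female", 6, r_min = 0.9)
  loose <- correlate_lifespan(m, "f", "female", 6, r_min = 0.0)
  expect_true(loose$relevant >= strict$relevant)
  tight_alpha <- correlate_lifespan(m, "f", "female", 6, alpha = 1e-12)
  expect_true(loose$relevant >= tight_alpha$relevant)
})
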