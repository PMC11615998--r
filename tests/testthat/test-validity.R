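# Independent enumeration oracle for the exact rank-sum p-value: walk every
# C(n1+n2, n1) assignment of the pooled values and count assignments with a
# U at least as extreme (two-sided via the symmetric tail).
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2
  U <- u_of(seq_len(n1))
  us <- apply(combn(n1 + n2, n1), 2, u_of)
  lo <- min(U, n1 * n2 - U)
  min(1, 2 * mean(us <= lo))
}

test_that("exact rank-sum p-values match enumeration", {
  t <- rank_sum_test(1:3, 4:6)
  expect_equal(t$statistic, 0)
  expect_equal(t$p_value, 0.1)          # 2/20 labelings
  t2 <- rank_sum_test(1:2, 3)
  expect_equal(t2$statistic, 0)
  expect_equal(t2$p_value, 2 / 3)
  set.seed(31)
  for (i in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    v <- sample(1000, n1 + n2)          # no ties
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    expect_equal(rank_sum_test(x, y)$p_value, oracle_ranksum_p(x, y))
  }
})

test_that("rank-sum is symmetric and handles ties/large samples", {
  x <- c(1, 2, 2, 3, 5, 5, 8)
  y <- c(2, 4, 5, 6, 6, 9)
  expect_equal(rank_sum_test(x, y)$p_value, rank_sum_test(y, x)$p_value)
  # identical samples: p = 1
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # normal approximation close to exact for moderate n (sanity property)
  set.seed(5)
  for (i in 1:10) {
    v <- sample(10000, 16)
    x <- v[1:8]; y <- v[9:16]
    expect_lt(abs(rank_sum_test(x, y)$p_value - oracle_ranksum_p(x, y)),
              0.05)
  }
  expect_error(rank_sum_test(numeric(0), 1:3), "empty")
})

test_that("2x2 chi-square matches the closed form", {
  t <- chi_square_2x2(10, 10, 10, 10)
  expect_equal(t$statistic, 0)
  expect_equal(t$p_value, 1)
  t2 <- chi_square_2x2(20, 10, 10, 20)
  expect_equal(t2$statistic, 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30))
  expect_equal(t2$statistic, 20 / 3, tolerance = 1e-12)
  # ad = bc gives 0; zero margin errors
  expect_equal(chi_square_2x2(6, 3, 4, 2)$statistic, 0)
  expect_error(chi_square_2x2(0, 0, 5, 5), "zero margin")
  # large counts must not overflow
  expect_true(is.finite(chi_square_2x2(5000L, 400L, 300L, 4800L)$statistic))
})

make_sep_cohort <- function() {
  n <- 300
  sg_rows <- 1:150
  age <- c(rep(30, 150), rep(50, 150)) + rep_len(c(0, .1, .2), n)
  expo <- c(rep(5, 150), rep(15, 150)) + rep_len(c(0, .1, .2), n)
  leq <- c(rep(82, 150), rep(88, 150)) + rep_len(c(0, .1, .2), n)
  ht <- c(rep(60, 150), rep(10, 150)) + rep_len(c(0, .5, 1), n)
  tiny_cohort(ht, age = age, exposure_time = expo, leq_8h = leq)
}

test_that("constructed separation scores 4/4 concordant", {
  x <- make_sep_cohort()
  sel <- structure(list(
    method_id = "mX", sg_ids = x$id[1:150], rg_ids = x$id[151:300],
    score = setNames(rep(1, 300), x$id),
    metadata = list(phenotype = list(frequencies = c(4, 12.5),
                                     ear = "bilateral"))),
    class = "nihl_selection")
  fv <- assess_method(x, sel)
  expect_equal(fv$n_expected, 4)
  expect_equal(fv$n_concordant, 4)
  expect_equal(fv$n_discordant_significant, 0)
})

test_that("null selections are rarely concordant", {
  set.seed(77)
  n <- 300
  x <- tiny_cohort(round(rnorm(n, 30, 10), 1),
                   age = round(runif(n, 25, 55), 1),
                   exposure_time = round(runif(n, 2, 20), 1),
                   leq_8h = round(runif(n, 80, 92), 1))
  conc <- replicate(100, {
    pick <- sample(n, 300)
    sel <- structure(list(
      method_id = "null", sg_ids = x$id[pick[1:150]],
      rg_ids = x$id[pick[151:300]],
      score = setNames(rep(1, n), x$id),
      metadata = list(phenotype = list(frequencies = 4, ear = "left"))),
      class = "nihl_selection")
    assess_method(x, sel)$n_concordant
  })
  expect_lt(mean(conc), 0.2)   # expected 0 with high probability
})

test_that("method ranking follows concordance then discordance then id", {
  mk <- function(id, nc, nd) structure(
    list(method_id = id, n_expected = 4, n_concordant = nc,
         n_discordant_significant = nd, detail = list()),
    class = "nihl_face_validity")
  out <- rank_methods(list(mk("m2", 1, 3), mk("m6", 4, 0), mk("m4", 0, 0)))
  expect_equal(sapply(out, `[[`, "method_id"), c("m6", "m2", "m4"))
  # tie on concordance: fewer discordant-significant first
  out2 <- rank_methods(list(mk("m1", 3, 1), mk("m5", 3, 0)))
  expect_equal(out2[[1]]$method_id, "m5")
  # full tie: method id order
  out3 <- rank_methods(list(mk("m3", 0, 0), mk("m1", 0, 0)))
  expect_equal(out3[[1]]$method_id, "m1")
})

test_that("tiny groups are marked indeterminate, not concordant", {
  x <- tiny_cohort(c(10, 20, 30))
  sel <- structure(list(
    method_id = "mX", sg_ids = "w01", rg_ids = c("w02", "w03"),
    score = c(w01 = 1, w02 = 1, w03 = 1),
    metadata = list(phenotype = list(frequencies = 4, ear = "left"))),
    class = "nihl_selection")
  fv <- assess_method(x, sel)
  expect_equal(fv$n_concordant, 0)
  expect_true(all(vapply(fv$detail[1:4], `[[`, logical(1),
                         "indeterminate")))
})
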