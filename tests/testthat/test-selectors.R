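test_that("single-stratum ranking matches direct sort-and-slice", {
  x <- tiny_cohort(1:10)  # HT scores 1..10, one stratum
  s <- stratum_spec("age", c(-Inf, Inf), "leq_8h", c(-Inf, Inf))
  sel <- select_stratified_extremes(x, s, frequencies = 4, ear = "left",
                                    fraction = 0.2)
  expect_setequal(sel$sg_ids, c("w10", "w09"))
  expect_setequal(sel$rg_ids, c("w01", "w02"))
  # fraction 0.5 on 4 distinct scores: both groups size 2, disjoint
  x4 <- tiny_cohort(c(3, 1, 4, 2))
  sel4 <- select_stratified_extremes(x4, s, 4, "left", 0.5)
  expect_length(sel4$sg_ids, 2)
  expect_length(sel4$rg_ids, 2)
  expect_length(intersect(sel4$sg_ids, sel4$rg_ids), 0)
})

test_that("9 strata of 20 workers at fraction 0.2 give 36 per group", {
  set.seed(1)
  n <- 180
  x <- tiny_cohort(round(runif(n, 0, 80), 1),
                   age = rep(c(30, 40, 55), each = 60),
                   leq_8h = rep(rep(c(80, 88, 95), each = 20), 3),
                   exposure_time = 10)
  s <- stratum_spec("age", c(-Inf, 35, 50, Inf),
                    "leq_8h", c(-Inf, 85, 91.5, Inf))
  sel <- select_stratified_extremes(x, s, 4, "left", 0.2)
  expect_length(sel$sg_ids, 36)  # 9 * floor(0.2 * 20)
  expect_length(sel$rg_ids, 36)
  # oracle: per stratum, brute-force sort-and-slice
  key <- paste(findInterval(x$age, c(35, 50)),
               findInterval(x$leq_8h, c(85, 91.5)))
  sg <- rg <- character(0)
  for (k in unique(key)) {
    i <- which(key == k)
    o <- oracle_extremes(x$id[i], x$L_4[i], 4)
    sg <- c(sg, o$high); rg <- c(rg, o$low)
  }
  expect_setequal(sel$sg_ids, sg)
  expect_setequal(sel$rg_ids, rg)
})

test_that("undersized strata are skipped with a warning", {
  x <- tiny_cohort(1:4)
  s <- stratum_spec("age", c(-Inf, Inf), "leq_8h", c(-Inf, Inf))
  expect_warning(sel <- select_stratified_extremes(x, s, 4, "left", 0.1),
                 "skipped")
  expect_length(sel$sg_ids, 0)
})

test_that("bidimensional cut equals the brute-force diagonal oracle", {
  set.seed(7)
  n <- 1000
  x <- tiny_cohort(round(rnorm(n, 30, 10), 1))
  x <- set_ht(x, "L_6", round(rnorm(n, 25, 8), 1))
  sel <- select_bidimensional_extremes(x, 4, 6, fraction = 0.1)
  z <- (scale(x$L_4)[, 1] + scale(x$L_6)[, 1]) / 2
  o <- oracle_extremes(x$id, z, 100)
  expect_setequal(sel$sg_ids, o$high)
  expect_setequal(sel$rg_ids, o$low)
  # antisymmetric pair: both score 0, neither selected at fraction < 0.5
  x2 <- tiny_cohort(c(10, 30))
  x2 <- set_ht(x2, "L_6", c(30, 10))
  sel2 <- select_bidimensional_extremes(x2, 4, 6, fraction = 0.25)
  expect_length(sel2$sg_ids, 0)
  expect_length(sel2$rg_ids, 0)
  expect_error(select_bidimensional_extremes(tiny_cohort(c(5, 5, 5)), 4, 6),
               "zero variance")
})

test_that("residual selection matches the normal-equations oracle", {
  set.seed(11)
  n <- 50
  leq <- round(runif(n, 75, 95), 1)
  x <- tiny_cohort(round(20 + rnorm(n, 0, 12), 1), leq_8h = leq,
                   exposure_time = round(runif(n, 2, 30), 1))
  for (m in c("linear", "quadratic")) {
    sel <- select_residual_extremes(x, c(3, 4, 6), m, fraction = 0.1)
    y <- (x$L_3 + x$L_4 + x$L_6 + x$R_3 + x$R_4 + x$R_6) / 6
    X <- if (m == "linear") cbind(1, x$cne) else cbind(1, x$cne, x$cne^2)
    beta <- solve(t(X) %*% X, t(X) %*% y)   # explicit normal equations
    r <- y - drop(X %*% beta)
    o <- oracle_extremes(x$id, r, 5)
    expect_setequal(sel$sg_ids, o$high)
    expect_setequal(sel$rg_ids, o$low)
    expect_equal(unname(sel$metadata$coefficients), drop(beta),
                 tolerance = 1e-8)
  }
})

test_that("a single perturbed point is the unique top residual", {
  cne_target <- seq(81, 100, length.out = 20)
  leq <- cne_target - 10  # exposure 10 y adds exactly 10 dB
  ht <- round(2 * cne_target - 150, 1)
  ht[7] <- ht[7] + 10
  x <- tiny_cohort(ht, leq_8h = leq, exposure_time = 10)
  sel <- select_residual_extremes(x, c(3, 4, 6), "linear", fraction = 0.05)
  expect_equal(sel$sg_ids, "w07")
  # floor arithmetic: fraction 0.1 of n = 20 gives 2 per group
  sel2 <- select_residual_extremes(x, c(3, 4, 6), "linear", fraction = 0.1)
  expect_length(sel2$sg_ids, 2)
  expect_length(sel2$rg_ids, 2)
})

test_that("selectors are permutation-equivariant and SG/RG disjoint", {
  set.seed(23)
  n <- 300
  x <- tiny_cohort(round(rnorm(n, 30, 15), 1),
                   age = round(runif(n, 20, 60), 1),
                   leq_8h = round(runif(n, 78, 96), 1),
                   exposure_time = round(runif(n, 2, 25), 1))
  x <- set_ht(x, "L_6", round(rnorm(n, 25, 12), 1))
  perm <- subset_ids <- sample(n)
  xp <- cohort(as.data.frame(x)[perm, ])
  run_all <- function(z) list(
    b = select_bidimensional_extremes(z, 4, 6, fraction = 0.1),
    rl = select_residual_extremes(z, c(3, 4, 6), "linear", fraction = 0.1),
    rq = select_residual_extremes(z, c(3, 4, 6), "quadratic",
                                  fraction = 0.2),
    s = select_stratified_extremes(
      z, stratum_spec("age", c(-Inf, 35, 50, Inf),
                      "leq_8h", c(-Inf, 85, 91.5, Inf)),
      c(4, 6), "left", 0.2))
  a <- run_all(x); b <- run_all(xp)
  for (k in names(a)) {
    expect_setequal(a[[k]]$sg_ids, b[[k]]$sg_ids)
    expect_setequal(a[[k]]$rg_ids, b[[k]]$rg_ids)
    expect_length(intersect(a[[k]]$sg_ids, a[[k]]$rg_ids), 0)
  }
})

test_that("every selector separates latent susceptibility on the default cohort", {
  x <- shared_cohort()
  for (m in paste0("m", 1:5)) {
    sel <- suppressWarnings(run_classical_method(x, m))$selection
    xm <- apply_method_criteria(x, m)$cohort
    s_sg <- xm$latent_s[match(sel$sg_ids, xm$id)]
    s_rg <- xm$latent_s[match(sel$rg_ids, xm$id)]
    expect_gt(median(s_sg), median(s_rg))
    expect_lt(rank_sum_test(s_sg, s_rg)$p_value, 0.01)
  }
})
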