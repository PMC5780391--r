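test_that("chain schedule bookkeeping is exact", {
  expect_equal(n_retained(gibbs_config_production()), 10000L)
  expect_equal(n_retained(gibbs_config(28000, 3000, 25)), 1000L)
  expect_error(gibbs_config(1000, 100, 7), "divisible")
  expect_error(gibbs_config(100, 100, 1), "burn_in")
})

test_that("priors must be proper", {
  expect_error(prior_spec(nu0_m = 0), "strictly positive")
  expect_error(prior_spec(S0_e = -1), "strictly positive")
  pr <- prior_spec()
  expect_equal(unname(pr$m["nu0"]), 0.002)
})

test_that("intercept-only posterior matches the conjugate closed form", {
  set.seed(31)
  y <- stats::rnorm(40, mean = 3, sd = 2)
  trials <- data.frame(male = "m", partner = "p", stranger = "s",
                       value = y, stringsAsFactors = FALSE)
  A <- diag(3)
  rownames(A) <- colnames(A) <- c("m", "p", "s")
  pr <- prior_spec()
  fit <- gibbs_fit(trials, A, priors = pr,
                   config = gibbs_config(3000, 1000, 1, seed = 32),
                   effects = character(0))
  expect_named(fit$draws, c("beta", "var_e"))

  n <- length(y)
  sse <- sum((y - mean(y))^2)
  nu0 <- unname(pr$e["nu0"]); S0 <- unname(pr$e["S0"])
  df <- n - 1 + nu0
  post_mean <- (sse + nu0 * S0) / (df - 2)
  draws <- fit$draws$var_e
  mc_se <- stats::sd(draws) / sqrt(effective_sample_size(draws))
  expect_lt(abs(mean(draws) - post_mean), 5 * mc_se)
})

test_that("the sampler recovers a known male heritability", {
  ped <- generate_colony_pedigree()
  trips <- assign_partners_strangers(ped, seed = 2)
  truth <- variance_truth(beta = 10, var_m = 2, var_e = 2)
  dat <- simulate_phenotypes(ped, trips, truth, seed = 3)
  A <- additive_relationship(ped)
  fit <- gibbs_fit(dat$trials, A,
                   config = gibbs_config(14000, 2000, 12, seed = 4))
  expect_equal(nrow(fit$draws), 1000L)
  expect_true(all(fit$draws$var_m > 0))
  h2 <- heritability_from_samples(fit)
  est <- h2$h2_mean[h2$component == "male"]
  expect_lt(abs(est - 0.5), 0.2)

  # the two estimator routes agree on the same data
  values <- stats::setNames(dat$trials$value, dat$trials$male)
  po <- parent_offspring_regression(values, ped)
  expect_lt(abs(po$h2 - est), 0.3)
})

test_that("gibbs_fit validates its inputs", {
  A <- diag(2); rownames(A) <- colnames(A) <- c("a", "b")
  trials <- data.frame(male = "z", partner = "a", stranger = "b",
                       value = c(1, 2), stringsAsFactors = FALSE)
  expect_error(gibbs_fit(trials, A), "absent from A")
  expect_error(gibbs_fit(trials, unname(diag(2))), "dimnames")
})

test_that("heritability ratios follow the mean-of-ratios convention", {
  s <- fake_samples(data.frame(beta = c(0, 0),
                               var_m = c(1, 1), var_p = c(1, 1),
                               var_s = c(1, 1), var_e = c(1, 1)))
  h2 <- heritability_from_samples(s)
  expect_equal(h2$h2_mean[h2$component %in% c("male", "partner", "stranger")],
               rep(0.25, 3))
  expect_equal(h2$h2_sd, rep(0, 4))

  s0 <- fake_samples(data.frame(beta = 0, var_m = 0, var_p = 1,
                                var_s = 1, var_e = 2))
  expect_equal(heritability_from_samples(s0)$h2_mean[1], 0)

  s2 <- fake_samples(data.frame(beta = c(0, 0), var_m = c(1, 3),
                                var_p = c(0, 0), var_s = c(0, 0),
                                var_e = c(1, 1)))
  expect_equal(heritability_from_samples(s2)$h2_mean[1], (0.5 + 0.75) / 2)

  # per-draw shares always sum to one
  set.seed(8)
  sr <- fake_samples(data.frame(beta = stats::rnorm(50),
                                var_m = stats::rchisq(50, 3),
                                var_p = stats::rchisq(50, 3),
                                var_s = stats::rchisq(50, 3),
                                var_e = stats::rchisq(50, 3)))
  ratios <- attr(heritability_from_samples(sr), "ratios")
  expect_equal(unname(rowSums(ratios)), rep(1, 50))
  expect_true(all(rowSums(ratios[, 1:3]) <= 1))

  sz <- fake_samples(data.frame(beta = 0, var_m = 0, var_p = 0,
                                var_s = 0, var_e = 0))
  expect_error(heritability_from_samples(sz), "degenerate")
})

test_that("effective sample size matches closed-form oracles", {
  set.seed(91)
  n <- 10000
  white <- stats::rnorm(n)
  expect_equal(effective_sample_size(white), n, tolerance = 0.2)

  rho <- 0.5
  chain <- ar1_chain(n, rho)
  expect_equal(effective_sample_size(chain), n * (1 - rho) / (1 + rho),
               tolerance = 0.25)

  expect_true(is.na(effective_sample_size(rep(2, 500))))
})

test_that("convergence diagnostics summarise and flag chains", {
  set.seed(14)
  d <- data.frame(beta = stats::rnorm(500), var_m = stats::rchisq(500, 2),
                  var_e = rep(1, 500))
  diag <- convergence_diagnostics(fake_samples(d))
  expect_equal(diag$estimator, "initial positive sequence")
  expect_true(diag$summary$flagged_constant[diag$summary$parameter == "var_e"])
  expect_true(is.na(diag$summary$ess[diag$summary$parameter == "var_e"]))
  expect_false(any(diag$summary$flagged_constant[1:2]))
  expect_equal(dim(diag$autocorrelation), c(10L, 3L))
  expect_true(all(abs(diag$autocorrelation[, 1:2]) <= 1))

  expect_error(convergence_diagnostics(fake_samples(d[1:50, ])),
               "at least 100")
})

test_that("parent-offspring regression doubles the sire slope", {
  ped <- data.frame(animal = c("s1", "s2", "s3", "o1", "o2", "o3"),
                    sire = c(NA, NA, NA, "s1", "s2", "s3"),
                    dam = NA, stringsAsFactors = FALSE)
  v <- c(s1 = 1, s2 = 2, s3 = 3, o1 = 1, o2 = 2, o3 = 3)
  po <- suppressWarnings(parent_offspring_regression(v, ped))
  expect_equal(po$h2, 2)
  expect_true(po$out_of_bounds)

  expect_error(parent_offspring_regression(v[c("s1", "o1")], ped),
               "at least two")
  flatv <- c(s1 = 1, s2 = 1, s3 = 1, o1 = 0, o2 = 1, o3 = 2)
  expect_error(parent_offspring_regression(flatv, ped), "no variation")
})

test_that("parent-offspring regression recovers simulated heritability", {
  simulate_pairs <- function(h2, n, seed) {
    set.seed(seed)
    vg <- h2; ve <- 1 - h2
    bs <- stats::rnorm(n, 0, sqrt(vg))
    bo <- 0.5 * bs + stats::rnorm(n, 0, sqrt(0.75 * vg + 1e-12))
    sire_ids <- sprintf("s%04d", seq_len(n))
    off_ids <- sprintf("o%04d", seq_len(n))
    ped <- data.frame(animal = c(sire_ids, off_ids),
                      sire = c(rep(NA, n), sire_ids),
                      dam = NA, stringsAsFactors = FALSE)
    v <- stats::setNames(c(bs + stats::rnorm(n, 0, sqrt(ve)),
                           bo + stats::rnorm(n, 0, sqrt(ve))),
                         c(sire_ids, off_ids))
    parent_offspring_regression(v, ped)
  }
  po4 <- simulate_pairs(0.4, 2000, seed = 51)
  expect_lt(abs(po4$h2 - 0.4), 0.1)
  expect_gt(po4$se, 0)
  po0 <- simulate_pairs(0, 2000, seed = 52)
  expect_lt(abs(po0$h2), 0.1)
})
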