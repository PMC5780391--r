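test_that("colony generator follows the full-sib crossing scheme", {
  founders <- generate_colony_pedigree(n_founder_blocks = 3,
                                       n_generations = 0)
  expect_true(all(is.na(founders$sire) & all(is.na(founders$dam))))

  ped <- generate_colony_pedigree(n_founder_blocks = 1, n_generations = 1,
                                  litter_size = 2)
  A <- additive_relationship(ped)
  males <- ped$animal[ped$sex == "M" & !is.na(ped$sire)]
  block_males <- males[ped$generation[match(males, ped$animal)] == 1]
  expect_length(block_males, 2)
  expect_equal(A[block_males[1], block_males[2]], 0.5) # full-sib males
  # each founder pairing left male offspring
  matings <- attr(ped, "matings")
  for (k in seq_len(nrow(matings))) {
    kids <- ped$animal[!is.na(ped$sire) & ped$sire == matings$sire[k]]
    expect_true(any(ped$sex[match(kids, ped$animal)] == "M"))
  }
  # every non-founder has both parents present
  nf <- !is.na(ped$sire)
  expect_true(all(ped$sire[nf] %in% ped$animal))
  expect_true(all(ped$dam[nf] %in% ped$animal))

  expect_identical(generate_colony_pedigree(seed = 5),
                   generate_colony_pedigree(seed = 5))
})

test_that("colony defaults emulate the study scale", {
  ped <- generate_colony_pedigree()
  expect_equal(nrow(ped), 406)
  expect_equal(sum(ped$sex == "M" & !is.na(ped$sire)), 182)
  # mate females are full sibs with a = 0.5 and unrelated to their male
  A <- additive_relationship(ped)
  matings <- attr(ped, "matings")
  expect_true(all(A[cbind(matings$sire, matings$dam)] == 0))
  # each female sib pair shares parents
  dams <- matings$dam
  sibs <- split(dams, paste(ped$sire[match(dams, ped$animal)]))
  pair <- sibs[[which(lengths(sibs) == 2)[1]]]
  expect_equal(A[pair[1], pair[2]], 0.5)
})

test_that("breeding values have the requested pedigree covariance", {
  A <- additive_relationship(trio_pedigree())
  expect_identical(simulate_breeding_values(A, 0, seed = 1),
                   stats::setNames(numeric(3), rownames(A)))

  # independent animals: sample variance approaches the target
  n <- 10000
  A <- diag(n)
  rownames(A) <- colnames(A) <- sprintf("i%05d", seq_len(n))
  u <- simulate_breeding_values(A, 2.5, seed = 11)
  expect_equal(stats::var(u), 2.5, tolerance = 0.05)

  # full-sib pairs: empirical covariance approaches 0.5 * variance
  npair <- 1000
  blocks <- replicate(npair, matrix(c(1, 0.5, 0.5, 1), 2), simplify = FALSE)
  Afs <- as.matrix(Matrix::bdiag(blocks))
  rownames(Afs) <- colnames(Afs) <- sprintf("p%04d", seq_len(2 * npair))
  v <- simulate_breeding_values(Afs, 3, seed = 12)
  odd <- v[seq(1, 2 * npair, 2)]
  even <- v[seq(2, 2 * npair, 2)]
  expect_equal(mean(odd * even), 0.5 * 3, tolerance = 0.1)

  expect_identical(simulate_breeding_values(A[1:5, 1:5], 1, seed = 3),
                   simulate_breeding_values(A[1:5, 1:5], 1, seed = 3))
  bad <- matrix(c(1, 2, 2, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(simulate_breeding_values(bad, 1, seed = 1), "factorization")
})

test_that("partner and stranger assignments are unrelated females", {
  ped <- generate_colony_pedigree(n_founder_blocks = 3, n_generations = 2,
                                  litter_size = 5)
  trips <- assign_partners_strangers(ped, seed = 4)
  A <- additive_relationship(ped)
  sex <- stats::setNames(ped$sex, ped$animal)
  expect_true(all(sex[trips$partner] == "F"))
  expect_true(all(sex[trips$stranger] == "F"))
  expect_true(all(trips$partner != trips$stranger))
  expect_true(all(A[cbind(trips$male, trips$partner)] == 0))
  expect_true(all(A[cbind(trips$male, trips$stranger)] == 0))
  expect_identical(trips, assign_partners_strangers(ped, seed = 4))

  # a male related to every female cannot be assigned
  trio <- pedigree(c("s", "d", "x"), c(NA, NA, "s"), c(NA, NA, "d"),
                   sex = c("M", "F", "M"))
  expect_error(assign_partners_strangers(trio, seed = 1),
               "no two unrelated females")
})

test_that("phenotypes decompose exactly into their generative components", {
  ped <- generate_colony_pedigree(n_founder_blocks = 2, n_generations = 1,
                                  litter_size = 4)
  trips <- assign_partners_strangers(ped, seed = 2)

  # all variance components zero: every record equals the grand mean
  silent <- simulate_phenotypes(ped, trips,
                                variance_truth(beta = 59, var_e = 0),
                                seed = 9)
  expect_true(all(silent$trials$value == 59))

  truth <- variance_truth(beta = 5, var_m = 1, var_p = 2, var_s = 0.5,
                          var_e = 1.5)
  dat <- simulate_phenotypes(ped, trips, truth, seed = 10)
  recon <- truth$beta + dat$effects$m[dat$trials$male] +
    dat$effects$p[dat$trials$partner] +
    dat$effects$s[dat$trials$stranger] + dat$effects$e
  expect_identical(unname(dat$trials$value - recon), rep(0, nrow(trips)))

  expect_identical(dat, simulate_phenotypes(ped, trips, truth, seed = 10))
  expect_false(identical(dat$trials$value,
                         simulate_phenotypes(ped, trips, truth,
                                             seed = 11)$trials$value))
})

test_that("generative variance adds across unrelated components", {
  # distinct unrelated animals per trial: y is iid with variance = total
  nt <- 2000
  ids <- sprintf("u%05d", seq_len(3 * nt))
  ped <- pedigree(ids, sex = rep(c("M", "F", "F"), nt))
  trips <- data.frame(male = ids[seq(1, 3 * nt, 3)],
                      partner = ids[seq(2, 3 * nt, 3)],
                      stranger = ids[seq(3, 3 * nt, 3)],
                      stringsAsFactors = FALSE)
  truth <- variance_truth(beta = 0, var_m = 1, var_p = 1, var_s = 1,
                          var_e = 1)
  dat <- simulate_phenotypes(ped, trips, truth, seed = 21)
  expect_equal(stats::var(dat$trials$value), 4, tolerance = 0.4)
})

test_that("trials CSV round-trips and truth serialises", {
  trials <- data.frame(male = "m1", partner = "f1", stranger = "f2",
                       trait = "partner_time", value = 12.5,
                       stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(trials, path)
  expect_equal(read_trials(path), trials, ignore_attr = TRUE)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("male,partner,stranger,trait,value", "m,f,g,t,oops"), bad)
  expect_error(read_trials(bad), "data line 1")

  tpath <- withr::local_tempfile(fileext = ".json")
  write_truth(variance_truth(beta = 2, var_m = 1), tpath)
  back <- jsonlite::read_json(tpath, simplifyVector = TRUE)
  expect_equal(back$var_m, 1)
  expect_equal(back$beta, 2)
})
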