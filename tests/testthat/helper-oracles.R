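# Independent oracles used across the suite.

# Recursive-coancestry oracle for the relationship matrix: kinship f by the
# textbook recursion, memoized; a_ij = 2 f(i, j). Written against the
# definition, independent of the tabular recursion in the package.
oracle_relationship <- function(ped) {
  animal <- as.character(ped$animal)
  sire <- as.character(ped$sire)
  dam <- as.character(ped$dam)
  sire[!is.na(sire) & (sire == "" | sire == "0")] <- NA
  dam[!is.na(dam) & (dam == "" | dam == "0")] <- NA
  pos <- stats::setNames(seq_along(animal), animal)
  si <- stats::setNames(sire, animal)
  di <- stats::setNames(dam, animal)
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- if (pos[[i]] <= pos[[j]]) paste(i, j) else paste(j, i)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      0.5 * (1 + f(si[[i]], di[[i]]))
    } else {
      # recurse through the later-born animal's parents
      if (pos[[i]] < pos[[j]]) { tmp <- i; i <- j; j <- tmp }
      0.5 * (f(si[[i]], j) + f(di[[i]], j))
    }
    memo[[key]] <- val
    val
  }
  n <- length(animal)
  A <- matrix(0, n, n, dimnames = list(animal, animal))
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      A[i, j] <- A[j, i] <- 2 * f(animal[i], animal[j])
    }
  }
  A
}

# Random valid pedigree (sorted parents-first by construction).
random_pedigree <- function(n, p_founder = 0.35) {
  animal <- sprintf("a%02d", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i >= 3 && stats::runif(1) > p_founder) {
      par <- sample(i - 1L, 2L)
      sire[i] <- animal[par[1]]
      dam[i] <- animal[par[2]]
    }
  }
  pedigree(animal, sire, dam)
}

# AR(1) chain with known autocorrelation.
ar1_chain <- function(n, rho, sd = 1) {
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd / sqrt(1 - rho^2))
  innov <- stats::rnorm(n - 1, 0, sd)
  for (t in 2:n) x[t] <- rho * x[t - 1] + innov[t - 1]
  x
}

# Wrap a draws data frame as a gibbs_samples object for functions that only
# consume retained draws.
fake_samples <- function(draws) {
  structure(list(draws = draws,
                 config = gibbs_config(n_iter = nrow(draws), burn_in = 0,
                                       thin = 1, seed = 1),
                 effects = character(0)),
            class = "gibbs_samples")
}

# Small fixed trio pedigree: unrelated sire and dam, one offspring.
trio_pedigree <- function() {
  validate_and_sort(pedigree(c("s", "d", "x"), c(NA, NA, "s"),
                             c(NA, NA, "d")))
}
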