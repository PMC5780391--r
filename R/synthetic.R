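# Synthetic colonies emulating the study's crossing scheme, and phenotype
# simulation under the generative animal model.

#' Variance-component truth for phenotype simulation
#'
#' Bundles the grand mean and the four variance components of the animal
#' model: additive genetic variance of the focal male (`var_m`), of the
#' partner female (`var_p`), of the stranger female (`var_s`), and residual
#' variance (`var_e`). Units are trait units (and trait units squared).
#'
#' @param beta grand mean (trait units).
#' @param var_m,var_p,var_s,var_e non-negative variance components.
#' @return A `variance_truth` object.
#' @export
variance_truth <- function(beta = 0, var_m = 0, var_p = 0, var_s = 0,
                           var_e = 1) {
  v <- c(var_m = var_m, var_p = var_p, var_s = var_s, var_e = var_e)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("variance components must be finite and non-negative")
  }
  structure(list(beta = beta, var_m = var_m, var_p = var_p, var_s = var_s,
                 var_e = var_e),
            class = "variance_truth")
}

#' True heritabilities implied by a variance truth
#'
#' @param truth a [variance_truth()].
#' @return Named vector `c(h2_m, h2_p, h2_s)`; zeros if total variance is 0.
#' @export
true_heritability <- function(truth) {
  tot <- truth$var_m + truth$var_p + truth$var_s + truth$var_e
  if (tot <= 0) return(c(h2_m = 0, h2_p = 0, h2_s = 0))
  c(h2_m = truth$var_m, h2_p = truth$var_p, h2_s = truth$var_s) / tot
}

#' Generate a colony pedigree under the full-sib crossing scheme
#'
#' Emulates the breeding design of the source colony: each founder block
#' contributes a pair of full-sib males (sons of one founder couple), each
#' mated to one of two unrelated full-sib females (daughters of a fresh,
#' unrelated founder couple). In each subsequent generation, up to two male
#' offspring per litter are mated, again to fresh unrelated full-sib
#' females. Litters alternate sexes starting with a male, so a litter of 7
#' holds 4 males and 3 females.
#'
#' With `n_generations = 0` only parentless founder couples are emitted.
#' The default scale (7 blocks, 2 offspring generations, litter size 7)
#' yields 406 pedigree animals of which 182 are non-founder males — the
#' phenotyped cohort.
#'
#' The construction is fully deterministic; `seed` is accepted for interface
#' symmetry with the stochastic generators.
#'
#' @param n_founder_blocks number of founder blocks.
#' @param n_generations number of offspring generations (0 = founders only).
#' @param litter_size offspring per mating (>= 1).
#' @param seed integer seed (unused randomness; kept for determinism
#'   contracts).
#' @return A sorted [pedigree()] with `sex` and `generation` columns and a
#'   `matings` attribute (data frame of sire/dam couples).
#' @export
generate_colony_pedigree <- function(n_founder_blocks = 7, n_generations = 2,
                                     litter_size = 7, seed = 1) {
  stopifnot(n_founder_blocks >= 1, n_generations >= 0, litter_size >= 1)
  animal <- character(0); sire <- character(0); dam <- character(0)
  sex <- character(0); gen <- integer(0)
  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("V%04d", counter)
  }
  add <- function(s, d, sx, g) {
    id <- new_id()
    animal <<- c(animal, id); sire <<- c(sire, s); dam <<- c(dam, d)
    sex <<- c(sex, sx); gen <<- c(gen, g)
    id
  }
  # a fresh unrelated founder couple plus two full-sib daughters
  new_female_pair <- function(g) {
    fs <- add(NA_character_, NA_character_, "M", g - 1L)
    fd <- add(NA_character_, NA_character_, "F", g - 1L)
    c(add(fs, fd, "F", g), add(fs, fd, "F", g))
  }
  matings <- list()
  active <- list() # each element: c(sire, dam)
  for (b in seq_len(n_founder_blocks)) {
    bs <- add(NA_character_, NA_character_, "M", 0L)
    bd <- add(NA_character_, NA_character_, "F", 0L)
    if (n_generations >= 1) {
      m1 <- add(bs, bd, "M", 1L)
      m2 <- add(bs, bd, "M", 1L)
      fem <- new_female_pair(1L)
      active <- c(active, list(c(m1, fem[1]), c(m2, fem[2])))
    }
  }
  matings <- active
  if (n_generations >= 1) {
    for (g in seq_len(n_generations)) {
      next_active <- list()
      for (pair in active) {
        litter_sex <- rep(c("M", "F"), length.out = litter_size)
        kids <- vapply(litter_sex, function(sx) {
          add(pair[1], pair[2], sx, g + 1L)
        }, character(1))
        if (g < n_generations) {
          sons <- kids[litter_sex == "M"]
          sons <- utils::head(sons, 2L)
          if (length(sons)) {
            fem <- new_female_pair(g + 1L)
            for (k in seq_along(sons)) {
              next_active <- c(next_active, list(c(sons[k], fem[k])))
            }
          }
        }
      }
      matings <- c(matings, next_active)
      active <- next_active
    }
  }
  ped <- pedigree(animal, sire, dam, sex = sex, generation = gen)
  ped <- validate_and_sort(ped)
  attr(ped, "matings") <- if (length(matings)) {
    data.frame(sire = vapply(matings, `[`, character(1), 1),
               dam = vapply(matings, `[`, character(1), 2),
               stringsAsFactors = FALSE)
  } else {
    data.frame(sire = character(0), dam = character(0))
  }
  ped
}

.is_diagonal <- function(A) {
  off <- A
  diag(off) <- 0
  max(abs(off)) == 0
}

#' Simulate breeding values with pedigree covariance
#'
#' Draws one additive genetic value per animal from N(0, A * variance) via a
#' lower-triangular factor of A: `u = sqrt(variance) * L z` with `z`
#' standard normal. A zero variance returns exact zeros.
#'
#' @param A positive semi-definite relationship matrix with id dimnames.
#' @param variance non-negative scalar genetic variance.
#' @param seed integer seed.
#' @return Named numeric vector of breeding values (pedigree order).
#' @export
simulate_breeding_values <- function(A, variance, seed = 1) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), variance >= 0)
  n <- nrow(A)
  ids <- rownames(A)
  if (variance == 0) {
    return(stats::setNames(numeric(n), ids))
  }
  set.seed(seed)
  z <- stats::rnorm(n)
  u <- if (.is_diagonal(A)) {
    sqrt(diag(A)) * z
  } else {
    L <- tryCatch(t(chol(A)), error = function(e) {
      stop("factorization of A failed (matrix not positive definite): ",
           conditionMessage(e))
    })
    drop(L %*% z)
  }
  stats::setNames(sqrt(variance) * u, ids)
}

#' Assign unrelated partner and stranger females to focal males
#'
#' For every focal male, picks two distinct females with zero additive
#' relationship to him (a = 0 in A): the pair-bond partner and the stranger
#' of the preference test. Defaults to all non-founder males as focal
#' animals, mirroring the phenotyped cohort.
#'
#' @param ped a pedigree with a `sex` column.
#' @param seed integer seed (selection among eligible females is random but
#'   reproducible).
#' @param males optional character vector of focal male ids.
#' @return Data frame with columns `male`, `partner`, `stranger`.
#' @export
assign_partners_strangers <- function(ped, seed = 1, males = NULL) {
  if (!"sex" %in% names(ped)) stop("pedigree needs a sex column")
  ped <- validate_and_sort(ped)
  A <- additive_relationship(ped)
  ids <- ped$animal
  females <- ids[!is.na(ped$sex) & ped$sex == "F"]
  if (is.null(males)) {
    males <- ids[!is.na(ped$sex) & ped$sex == "M" &
                   (!is.na(ped$sire) | !is.na(ped$dam))]
  }
  if (!length(males)) stop("no focal males available")
  if (!length(females)) stop("pedigree contains no females")
  set.seed(seed)
  partner <- character(length(males))
  stranger <- character(length(males))
  for (k in seq_along(males)) {
    unrel <- females[A[males[k], females] == 0]
    if (length(unrel) < 2L) {
      stop("no two unrelated females available for male ", males[k])
    }
    pick <- sample(unrel, 2L)
    partner[k] <- pick[1]
    stranger[k] <- pick[2]
  }
  data.frame(male = males, partner = partner, stranger = stranger,
             stringsAsFactors = FALSE)
}

#' Simulate phenotypes under the generative animal model
#'
#' Each trial value is `beta + m[male] + p[partner] + s[stranger] + e`, with
#' the three breeding-value vectors drawn with pedigree covariance
#' (`N(0, A sigma2)`) and independent residuals `e ~ N(0, var_e)`. All
#' hidden components are retained so recovery experiments can be scored and
#' the bookkeeping identity checked exactly.
#'
#' Component draws use derived seeds `seed`, `seed + 1`, `seed + 2`,
#' `seed + 3` (residual, male, partner, stranger), so a dataset is a pure
#' function of `(pedigree, triples, truth, seed)`.
#'
#' @param ped pedigree containing every animal referenced in `triples`.
#' @param triples data frame with columns `male`, `partner`, `stranger`
#'   (one row per trial; see [assign_partners_strangers()]).
#' @param truth a [variance_truth()].
#' @param seed integer seed.
#' @param trait trait label stored in the trials table.
#' @return A `synthetic_dataset`: list with `trials` (male, partner,
#'   stranger, trait, value), `truth`, and `effects` (hidden m, p, s, e).
#' @export
simulate_phenotypes <- function(ped, triples, truth, seed = 1,
                                trait = "phenotype") {
  stopifnot(inherits(truth, "variance_truth"),
            all(c("male", "partner", "stranger") %in% names(triples)))
  ped <- validate_and_sort(ped)
  A <- additive_relationship(ped)
  ids <- rownames(A)
  refs <- unique(c(triples$male, triples$partner, triples$stranger))
  if (!all(refs %in% ids)) {
    stop("triples reference animals absent from the pedigree: ",
         paste(utils::head(setdiff(refs, ids), 5), collapse = ", "))
  }
  same <- triples$male == triples$partner | triples$male == triples$stranger |
    triples$partner == triples$stranger
  if (any(same)) stop("male, partner and stranger must be distinct per trial")
  nt <- nrow(triples)
  set.seed(seed)
  e <- stats::rnorm(nt, 0, sqrt(truth$var_e))
  m <- simulate_breeding_values(A, truth$var_m, seed = seed + 1)
  p <- simulate_breeding_values(A, truth$var_p, seed = seed + 2)
  s <- simulate_breeding_values(A, truth$var_s, seed = seed + 3)
  value <- truth$beta + m[triples$male] + p[triples$partner] +
    s[triples$stranger] + e
  trials <- data.frame(male = triples$male, partner = triples$partner,
                       stranger = triples$stranger, trait = trait,
                       value = unname(value), stringsAsFactors = FALSE)
  structure(list(trials = trials, truth = truth,
                 effects = list(m = m, p = p, s = s, e = e)),
            class = "synthetic_dataset")
}

#' Read / write trial tables
#'
#' The trials CSV dialect has header columns `male`, `partner`, `stranger`,
#' `trait`, `value`.
#'
#' @param trials data frame of trials.
#' @param path file path.
#' @return `read_trials` returns the trials data frame.
#' @export
write_trials <- function(trials, path) {
  need <- c("male", "partner", "stranger", "trait", "value")
  stopifnot(all(need %in% names(trials)))
  utils::write.csv(trials[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("male", "partner", "stranger", "trait", "value")
  if (!all(need %in% names(raw))) {
    stop("trials file must have header columns ",
         paste(need, collapse = ", "))
  }
  raw$value <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(raw$value))
  if (length(bad)) {
    stop("malformed trials row (non-numeric value) at data line ", bad[1])
  }
  raw[, need]
}

#' Write the hidden truth of a synthetic dataset as JSON
#'
#' @param truth a [variance_truth()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
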