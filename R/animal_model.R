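# Bayesian animal model with direct and indirect additive genetic effects,
# fitted by Gibbs sampling.
#
# Model:  y = 1 beta + Z_m m + Z_p p + Z_s s + e
#         m ~ N(0, A s2_m), p ~ N(0, A s2_p), s ~ N(0, A s2_s),
#         e ~ N(0, I s2_e), flat prior on beta,
#         scaled-inverse-chi-square priors on each variance component.

.EFFECT_CODES <- c(male = "m", partner = "p", stranger = "s")

#' Prior specification for the variance components
#'
#' Each variance component (male, partner, stranger genetic variances and
#' the residual) gets an independent scaled-inverse-chi-square prior with
#' degrees of belief `nu0` and scale `S0`. The defaults (`nu0 = 0.002`,
#' `S0 = 1`) are proper but near-noninformative, the common weak choice for
#' animal-model variance components. The intercept prior is flat.
#'
#' @param nu0_m,S0_m,nu0_p,S0_p,nu0_s,S0_s,nu0_e,S0_e strictly positive
#'   hyperparameters per component.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(nu0_m = 0.002, S0_m = 1, nu0_p = 0.002, S0_p = 1,
                       nu0_s = 0.002, S0_s = 1, nu0_e = 0.002, S0_e = 1) {
  h <- c(nu0_m, S0_m, nu0_p, S0_p, nu0_s, S0_s, nu0_e, S0_e)
  if (any(!is.finite(h)) || any(h <= 0)) {
    stop("prior hyperparameters must be strictly positive")
  }
  structure(list(m = c(nu0 = nu0_m, S0 = S0_m),
                 p = c(nu0 = nu0_p, S0 = S0_p),
                 s = c(nu0 = nu0_s, S0 = S0_s),
                 e = c(nu0 = nu0_e, S0 = S0_e)),
            class = "prior_spec")
}

#' Gibbs chain schedule
#'
#' The production schedule of the analysis is 280,000 iterations with a
#' 30,000-iteration burn-in, thinning every 25th draw — 10,000 retained
#' samples. The default here is the scaled-down desk schedule
#' (28,000 / 3,000 / 25, i.e. 1,000 retained draws).
#'
#' @param n_iter total iterations.
#' @param burn_in discarded initial iterations (`< n_iter`).
#' @param thin keep every `thin`-th post-burn-in draw;
#'   `(n_iter - burn_in)` must be divisible by `thin`.
#' @param seed integer seed for the sampler.
#' @return A `gibbs_config` object.
#' @export
gibbs_config <- function(n_iter = 28000, burn_in = 3000, thin = 25, seed = 1) {
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < n_iter, thin >= 1)
  if ((n_iter - burn_in) %% thin != 0) {
    stop("(n_iter - burn_in) must be divisible by thin")
  }
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "gibbs_config")
}

#' Retained draw count of a chain schedule
#'
#' @param config a [gibbs_config()].
#' @return `(n_iter - burn_in) / thin` as an integer.
#' @export
n_retained <- function(config) {
  as.integer((config$n_iter - config$burn_in) / config$thin)
}

#' Paper-scale chain schedule
#'
#' Convenience constructor for the production schedule
#' (280,000 / 30,000 / 25).
#'
#' @param seed integer seed.
#' @return A [gibbs_config()].
#' @export
gibbs_config_production <- function(seed = 1) {
  gibbs_config(n_iter = 280000, burn_in = 30000, thin = 25, seed = seed)
}

# One-off whitening of an effect block: returns U with U' Ainv U = I and
# U' Z'Z U = diag(lambda), so the full-conditional precision
# Z'Z/s2e + Ainv/s2u is diagonal in the transformed coordinates and each
# iteration costs O(N^2) instead of O(N^3).
.effect_whitening <- function(L, Li, counts) {
  G <- sweep(Li, 2L, sqrt(counts), "*")
  M <- tcrossprod(G)
  ee <- eigen(M, symmetric = TRUE)
  U <- backsolve(t(L), ee$vectors)
  list(U = U, lambda = pmax(ee$values, 0))
}

#' Fit the animal model by Gibbs sampling
#'
#' Cycles the full conditionals of the model: (i) the intercept from its
#' normal conditional under a flat prior; (ii) each additive genetic effect
#' vector as one multivariate-normal block draw with precision
#' `Z'Z / s2_e + A^-1 / s2_u`; (iii) each genetic variance from a
#' scaled-inverse-chi-square with degrees `q + nu0` and scale
#' `(u' A^-1 u + nu0 S0) / (q + nu0)` where `q` is the number of pedigree
#' animals; (iv) the residual variance analogously from the residual sum of
#' squares. Draws are retained per the [gibbs_config()] schedule and the
#' whole run is deterministic given `config$seed`.
#'
#' @param trials data frame with columns `male`, `partner`, `stranger`,
#'   `value` (and optionally `trait`); one row per phenotype record.
#' @param A positive-definite relationship matrix over all pedigree animals
#'   (id dimnames required).
#' @param priors a [prior_spec()].
#' @param config a [gibbs_config()].
#' @param effects which additive genetic effects to fit; any subset of
#'   `c("male", "partner", "stranger")`. Density-type traits measured on the
#'   male alone are typically fitted with `effects = "male"`;
#'   `character(0)` gives the intercept + residual model.
#' @return A `gibbs_samples` object: `draws` (data frame with columns
#'   `beta`, `var_m`/`var_p`/`var_s` for fitted effects, `var_e`), plus the
#'   config, priors and effects echo.
#' @export
gibbs_fit <- function(trials, A, priors = prior_spec(),
                      config = gibbs_config(),
                      effects = c("male", "partner", "stranger")) {
  stopifnot(inherits(config, "gibbs_config"), inherits(priors, "prior_spec"))
  if (length(effects)) {
    effects <- match.arg(effects, names(.EFFECT_CODES), several.ok = TRUE)
  }
  y <- as.numeric(trials$value)
  nt <- length(y)
  if (nt < 2L) stop("need at least two trials")
  ids <- rownames(A)
  if (is.null(ids)) stop("A must carry animal ids as dimnames")
  n <- nrow(A)
  for (eff in effects) {
    if (!all(trials[[eff]] %in% ids)) {
      stop("trials reference ", eff, " ids absent from A")
    }
  }

  Ainv <- inverse_relationship(A)
  # Ainv = L L' with L lower triangular; Li = L^-1
  L <- t(chol(Ainv))
  need_white <- length(effects) > 0L
  Li <- if (need_white) forwardsolve(L, diag(n)) else NULL

  codes <- .EFFECT_CODES[effects]
  idx <- lapply(effects, function(eff) match(trials[[eff]], ids))
  names(idx) <- codes
  white <- lapply(idx, function(ix) {
    w <- .effect_whitening(L, Li, tabulate(ix, nbins = n))
    # Z U, so that Z'res enters the transformed coordinates in one product
    w$ZU <- w$U[ix, , drop = FALSE]
    w
  })

  set.seed(config$seed)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  k <- length(codes)
  beta <- mean(y)
  var_u <- stats::setNames(rep(vy / (2 * max(k, 1)), k), codes)
  var_e <- vy / 2
  fit <- lapply(codes, function(cc) numeric(nt))
  names(fit) <- codes
  uAu <- stats::setNames(numeric(k), codes)

  n_keep <- n_retained(config)
  draw_names <- c("beta", if (k) paste0("var_", codes), "var_e")
  out <- matrix(NA_real_, n_keep, length(draw_names),
                dimnames = list(NULL, draw_names))
  kept <- 0L

  total_fit <- numeric(nt)
  for (it in seq_len(config$n_iter)) {
    # (i) intercept
    r_all <- y - total_fit
    beta <- mean(r_all) + stats::rnorm(1) * sqrt(var_e / nt)
    # (ii) effect blocks
    for (cc in codes) {
      res <- y - beta - (total_fit - fit[[cc]])
      r <- crossprod(white[[cc]]$ZU, res) / var_e
      prec <- white[[cc]]$lambda / var_e + 1 / var_u[[cc]]
      v <- drop(r) / prec + stats::rnorm(n) / sqrt(prec)
      uAu[[cc]] <- sum(v * v)
      new_fit <- drop(white[[cc]]$ZU %*% v)
      total_fit <- total_fit - fit[[cc]] + new_fit
      fit[[cc]] <- new_fit
    }
    # (iii) genetic variances
    for (cc in codes) {
      pr <- priors[[cc]]
      var_u[[cc]] <- (uAu[[cc]] + pr["nu0"] * pr["S0"]) /
        stats::rchisq(1, n + pr["nu0"])
    }
    # (iv) residual variance
    e <- y - beta - total_fit
    pre <- priors[["e"]]
    var_e <- unname((sum(e * e) + pre["nu0"] * pre["S0"]) /
                      stats::rchisq(1, nt + pre["nu0"]))
    if (!is.finite(var_e) || (k && any(!is.finite(var_u)))) {
      stop("sampler diverged (non-finite variance) at iteration ", it)
    }
    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L) {
      kept <- kept + 1L
      out[kept, ] <- c(beta, unname(var_u), var_e)
    }
  }

  structure(list(draws = as.data.frame(out), config = config,
                 priors = priors, effects = effects,
                 n_animals = n, n_trials = nt),
            class = "gibbs_samples")
}

#' Posterior heritability estimates from retained draws
#'
#' For every retained draw, total phenotypic variance is the sum of all
#' fitted variance components and each heritability is that component's
#' share; the posterior mean of the per-draw ratios is the point estimate
#' and the posterior SD its standard error (mean-of-ratios convention).
#'
#' @param samples a `gibbs_samples` object from [gibbs_fit()].
#' @return A `heritability_estimate`: data frame with one row per genetic
#'   effect (`component`, `h2_mean`, `h2_sd`) plus a `residual_fraction`
#'   row; the per-draw ratio matrix is attached as attribute `"ratios"`.
#' @export
heritability_from_samples <- function(samples) {
  d <- samples$draws
  if (!nrow(d)) stop("no retained draws")
  vc <- grep("^var_", names(d), value = TRUE)
  tot <- rowSums(d[vc])
  if (any(tot <= 0)) {
    stop("degenerate draw: zero total phenotypic variance")
  }
  ratios <- as.matrix(d[vc]) / tot
  comp_names <- c(var_m = "male", var_p = "partner", var_s = "stranger",
                  var_e = "residual")[vc]
  est <- data.frame(component = unname(comp_names),
                    h2_mean = unname(colMeans(ratios)),
                    h2_sd = unname(apply(ratios, 2, stats::sd)),
                    stringsAsFactors = FALSE)
  colnames(ratios) <- unname(comp_names)
  structure(est, ratios = ratios, class = c("heritability_estimate",
                                            "data.frame"))
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat("Posterior heritability estimates (mean-of-ratios over retained draws)\n")
  df <- as.data.frame(x)
  df$h2_mean <- sprintf("%.3f", df$h2_mean)
  df$h2_sd <- sprintf("%.3f", df$h2_sd)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Effective sample size of a chain
#'
#' Initial-positive-sequence estimator: autocovariances are summed in
#' adjacent pairs and truncated at the first non-positive pair sum; the
#' asymptotic variance is `-g0 + 2 * sum(pair sums)` and
#' `ESS = n * g0 / asymptotic variance`. Returns `NA` for a constant chain
#' (ESS undefined).
#'
#' @param x numeric chain.
#' @return Effective sample size (may exceed `length(x)` for antithetic
#'   chains), or `NA_real_` if undefined.
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 4L) return(NA_real_)
  if (stats::var(x) == 0) return(NA_real_)
  lag_max <- min(n - 1L, max(200L, 10L * floor(sqrt(n))))
  ac <- stats::acf(x, lag.max = lag_max, type = "covariance",
                   plot = FALSE, demean = TRUE)$acf[, 1, 1]
  g0 <- ac[1]
  npair <- floor(length(ac) / 2)
  if (npair < 1L) return(n)
  gsum <- ac[2 * seq_len(npair) - 1] + ac[2 * seq_len(npair)]
  neg <- which(gsum <= 0)
  m <- if (length(neg)) neg[1] - 1L else npair
  if (m < 1L) return(as.numeric(n))
  s2 <- -g0 + 2 * sum(gsum[seq_len(m)])
  n * g0 / s2
}

#' Convergence diagnostics for retained draws
#'
#' Per parameter: posterior mean and SD, effective sample size (by the
#' initial-positive-sequence estimator; see [effective_sample_size()]), and
#' autocorrelations at lags 1..`max_lag`. A constant chain is flagged (ESS
#' `NA`) rather than raising an error. The draws themselves serve as the
#' trace for plotting.
#'
#' @param samples a `gibbs_samples` object with at least 100 retained draws.
#' @param max_lag highest autocorrelation lag reported.
#' @return A `gibbs_diagnostics` list: `estimator`, `summary` (data frame
#'   with `parameter`, `mean`, `sd`, `ess`, `flagged_constant`),
#'   `autocorrelation` (lag x parameter matrix).
#' @export
convergence_diagnostics <- function(samples, max_lag = 10) {
  d <- samples$draws
  if (nrow(d) < 100L) stop("need at least 100 retained draws")
  pars <- names(d)
  ess <- vapply(d, effective_sample_size, numeric(1))
  constant <- vapply(d, function(x) stats::var(x) == 0, logical(1))
  ac <- vapply(d, function(x) {
    if (stats::var(x) == 0) return(rep(NA_real_, max_lag))
    stats::acf(x, lag.max = max_lag, plot = FALSE,
               demean = TRUE)$acf[-1, 1, 1]
  }, numeric(max_lag))
  ac <- matrix(ac, nrow = max_lag,
               dimnames = list(paste0("lag", seq_len(max_lag)), pars))
  summary <- data.frame(parameter = pars,
                        mean = vapply(d, mean, numeric(1)),
                        sd = vapply(d, stats::sd, numeric(1)),
                        ess = ess,
                        flagged_constant = constant,
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(estimator = "initial positive sequence",
                 summary = summary, autocorrelation = ac,
                 n_draws = nrow(d)),
            class = "gibbs_diagnostics")
}

#' @export
print.gibbs_diagnostics <- function(x, ...) {
  cat("Chain diagnostics (", x$n_draws, " retained draws; ESS estimator: ",
      x$estimator, ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Parent-offspring regression heritability
#'
#' Regresses male-offspring phenotype on sire phenotype; with a single
#' parent measured, `h2 = 2 * slope` with standard error twice the slope's.
#' Estimates outside [0, 1] are reported as-is but flagged.
#'
#' @param values per-animal phenotypes: a data frame with columns `animal`,
#'   `value`, or a named numeric vector.
#' @param ped the pedigree linking sires to offspring; if it has a `sex`
#'   column, offspring are restricted to males.
#' @return A `po_regression` list: `h2`, `se`, `slope`, `slope_se`,
#'   `n_pairs`, `out_of_bounds`.
#' @export
parent_offspring_regression <- function(values, ped) {
  if (is.data.frame(values)) {
    stopifnot(all(c("animal", "value") %in% names(values)))
    v <- stats::setNames(as.numeric(values$value), as.character(values$animal))
  } else {
    v <- values
    if (is.null(names(v))) stop("values must be named by animal id")
  }
  sire <- .normalise_parent(ped$sire)
  animal <- as.character(ped$animal)
  keep <- !is.na(sire) & animal %in% names(v) & sire %in% names(v)
  if ("sex" %in% names(ped)) {
    keep <- keep & !is.na(ped$sex) & ped$sex == "M"
  }
  if (sum(keep) < 2L) stop("need at least two sire-son phenotype pairs")
  sv <- unname(v[sire[keep]])
  ov <- unname(v[animal[keep]])
  if (stats::var(sv) == 0) stop("no variation in sire phenotypes")
  fit <- stats::lm(ov ~ sv)
  cf <- summary(fit)$coefficients
  slope <- cf["sv", "Estimate"]
  slope_se <- cf["sv", "Std. Error"]
  h2 <- 2 * slope
  structure(list(h2 = h2, se = 2 * slope_se, slope = slope,
                 slope_se = slope_se, n_pairs = sum(keep),
                 out_of_bounds = (h2 < 0 || h2 > 1)),
            class = "po_regression")
}

#' @export
print.po_regression <- function(x, ...) {
  cat(sprintf(
    "Parent-offspring regression: h2 = %.3f (SE %.3f) from %d sire-son pairs%s\n",
    x$h2, x$se, x$n_pairs,
    if (x$out_of_bounds) " [outside 0..1]" else ""))
  invisible(x)
}
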