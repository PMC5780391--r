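# End-to-end workflows: simulate -> fit -> report, the recovery experiment,
# and the behaviour/correlation screen. Pure functions of (config, inputs);
# optional on-disk outputs are CSV/JSON.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from YAML
#'
#' Thin wrapper around [yaml::read_yaml()] filling package defaults for the
#' chain schedule (`n_iter`, `burn_in`, `thin`, `seed`), priors and
#' Bonferroni family sizes. All analysis thresholds live in the config, not
#' in code; the shipped defaults are the study's values.
#'
#' @param path YAML file path.
#' @return A named list (`run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(seed = 1, n_iter = 28000, burn_in = 3000, thin = 25,
                   nu0 = 0.002, S0 = 1, table1_family = 13,
                   screen_alpha = 7.5e-5,
                   effects = c("male", "partner", "stranger"))
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  structure(cfg, class = c("run_config", "list"))
}

.sub_config <- function(config, seed) {
  gibbs_config(config$n_iter, config$burn_in, config$thin, seed = seed)
}

#' Variance-component recovery experiment on synthetic colonies
#'
#' For every truth in `truth_grid` and every replicate: simulates a colony
#' pedigree under the crossing scheme, assigns unrelated partner/stranger
#' females, generates phenotypes under the generative animal model, fits the
#' Gibbs sampler, and scores the posterior heritability means against the
#' known truth. Sub-seeds are derived deterministically from `seed`, so the
#' whole report is reproducible.
#'
#' @param truth_grid list of [variance_truth()] objects.
#' @param n_replicates replicates per truth.
#' @param config a [gibbs_config()] (its seed is overridden per fit).
#' @param priors a [prior_spec()].
#' @param effects genetic effects fitted (see [gibbs_fit()]).
#' @param n_founder_blocks,n_generations,litter_size colony-scheme
#'   parameters (see [generate_colony_pedigree()]).
#' @param seed master seed.
#' @return A `recovery_report`: data frame with one row per truth x
#'   replicate (`truth_id`, `replicate`, `seed`, true and estimated h2 per
#'   effect, `bias_m`, `abs_error_m`, `covered_m` = truth within posterior
#'   mean +/- 2 SD for the male effect). Attribute `config` echoes the run.
#' @export
run_recovery_experiment <- function(truth_grid, n_replicates = 1,
                                    config = gibbs_config(),
                                    priors = prior_spec(),
                                    effects = c("male", "partner", "stranger"),
                                    n_founder_blocks = 7, n_generations = 2,
                                    litter_size = 7, seed = 1) {
  stopifnot(length(truth_grid) >= 1, n_replicates >= 1)
  if (n_generations < 1) {
    stop("infeasible design: a founders-only colony has no phenotyped males")
  }
  rows <- list()
  for (i in seq_along(truth_grid)) {
    truth <- truth_grid[[i]]
    stopifnot(inherits(truth, "variance_truth"))
    th <- true_heritability(truth)
    for (r in seq_len(n_replicates)) {
      s <- seed + 1000L * (i - 1L) + 10L * (r - 1L)
      ped <- generate_colony_pedigree(n_founder_blocks, n_generations,
                                      litter_size, seed = s)
      trips <- assign_partners_strangers(ped, seed = s + 1L)
      dat <- simulate_phenotypes(ped, trips, truth, seed = s + 2L)
      A <- additive_relationship(ped)
      fit <- gibbs_fit(dat$trials, A, priors = priors,
                       config = .sub_config(config, s + 3L),
                       effects = effects)
      h2 <- heritability_from_samples(fit)
      est <- function(comp, col) {
        i2 <- match(comp, h2$component)
        if (is.na(i2)) NA_real_ else h2[[col]][i2]
      }
      m_mean <- est("male", "h2_mean"); m_sd <- est("male", "h2_sd")
      rows[[length(rows) + 1L]] <- data.frame(
        truth_id = i, replicate = r, seed = s,
        true_h2_m = unname(th["h2_m"]), true_h2_p = unname(th["h2_p"]),
        true_h2_s = unname(th["h2_s"]),
        est_h2_m = m_mean, sd_h2_m = m_sd,
        est_h2_p = est("partner", "h2_mean"),
        est_h2_s = est("stranger", "h2_mean"),
        bias_m = m_mean - unname(th["h2_m"]),
        abs_error_m = abs(m_mean - unname(th["h2_m"])),
        covered_m = abs(m_mean - unname(th["h2_m"])) <= 2 * m_sd,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  class(out) <- c("recovery_report", "data.frame")
  out
}

#' Fit the animal model for each configured trait
#'
#' Builds the relationship matrix from the pedigree, then fits every trait
#' present in (or requested from) the trials table, returning posterior
#' heritability estimates and convergence diagnostics per trait. With
#' `out_dir` set, retained draws are written as CSV and the estimates plus
#' diagnostics as JSON, together with the chain schedule and seed.
#'
#' @param trials trials table (`male`, `partner`, `stranger`, `trait`,
#'   `value`).
#' @param ped the colony pedigree.
#' @param traits traits to fit; default all traits in `trials`.
#' @param config a [gibbs_config()].
#' @param priors a [prior_spec()].
#' @param effects genetic effects fitted.
#' @param out_dir optional output directory.
#' @return A `heritability_report`: list with one element per trait
#'   (`samples`, `estimate`, `diagnostics`) plus the config echo.
#' @export
run_heritability <- function(trials, ped, traits = NULL,
                             config = gibbs_config(),
                             priors = prior_spec(),
                             effects = c("male", "partner", "stranger"),
                             out_dir = NULL) {
  ped <- validate_and_sort(ped)
  A <- additive_relationship(ped)
  have <- unique(trials$trait)
  traits <- traits %||% have
  missing <- setdiff(traits, have)
  if (length(missing)) {
    stop("trait(s) absent from trials: ", paste(missing, collapse = ", "))
  }
  results <- list()
  for (tr in traits) {
    sub <- trials[trials$trait == tr, ]
    fit <- gibbs_fit(sub, A, priors = priors, config = config,
                     effects = effects)
    results[[tr]] <- list(
      samples = fit,
      estimate = heritability_from_samples(fit),
      diagnostics = if (nrow(fit$draws) >= 100) {
        convergence_diagnostics(fit)
      } else NULL)
  }
  report <- structure(list(traits = results, config = config,
                           effects = effects, seed = config$seed),
                      class = "heritability_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (tr in names(results)) {
      utils::write.csv(results[[tr]]$samples$draws,
                       file.path(out_dir, paste0("draws_", tr, ".csv")),
                       row.names = FALSE)
    }
    est <- lapply(results, function(x) {
      out <- as.data.frame(x$estimate)
      attr(out, "ratios") <- NULL
      list(estimate = out,
           ess = if (!is.null(x$diagnostics)) {
             stats::setNames(x$diagnostics$summary$ess,
                             x$diagnostics$summary$parameter)
           } else NULL)
    })
    jsonlite::write_json(
      list(config = unclass(config), effects = effects, estimates = est),
      file.path(out_dir, "heritability_estimates.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}

#' Behavioural and correlational screen
#'
#' Produces the before/after paired-comparison table, the partner-preference
#' summary, and (when a density table is supplied) the full Spearman screen
#' of behaviours against regional V1aR densities. The partner-preference
#' assay is summarised rather than paired, since it is measured once per
#' male after mating.
#'
#' @param behaviours long-format behaviour table.
#' @param densities optional density table; `NULL` or empty omits the
#'   correlation screen.
#' @param base_alpha family-wise level for the paired table.
#' @param table_family Bonferroni divisor for the paired table (default:
#'   number of behaviours).
#' @param screen_alpha explicit per-test level for the Spearman screen
#'   (`NULL` = Bonferroni over the tests performed).
#' @param partner_assay assay label holding partner-contact durations.
#' @return A `behaviour_screen` list: `paired`, `partner_preference`,
#'   `spearman` (possibly `NULL`).
#' @export
run_behaviour_screen <- function(behaviours, densities = NULL,
                                 base_alpha = 0.05, table_family = NULL,
                                 screen_alpha = NULL,
                                 partner_assay = "partner_preference") {
  pp_rows <- behaviours$assay == partner_assay
  paired <- paired_before_after(behaviours[!pp_rows, , drop = FALSE],
                                base_alpha = base_alpha,
                                family_size = table_family)
  pp <- if (any(pp_rows)) {
    partner_preference_summary(behaviours$value[pp_rows])
  } else NULL
  sp <- if (!is.null(densities) && nrow(densities) > 0) {
    spearman_screen(behaviours[!pp_rows, , drop = FALSE], densities,
                    base_alpha = base_alpha, alpha = screen_alpha)
  } else NULL
  structure(list(paired = paired, partner_preference = pp, spearman = sp),
            class = "behaviour_screen")
}
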