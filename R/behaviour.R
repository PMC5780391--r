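# Behavioural statistics: paired before/after-mating comparisons,
# partner-preference summaries, and the Spearman screen of behaviours
# against regional V1aR densities, all under Bonferroni control.

#' Bonferroni-corrected per-test significance level
#'
#' @param family_size number of tests in the family (>= 1).
#' @param base_alpha family-wise significance level in (0, 1).
#' @return `base_alpha / family_size`.
#' @examples
#' signif(bonferroni_alpha(13), 1) # the 0.004 used for the 13-behaviour table
#' @export
bonferroni_alpha <- function(family_size, base_alpha = 0.05) {
  if (length(family_size) != 1L || !is.finite(family_size) ||
      family_size < 1 || family_size != as.integer(family_size)) {
    stop("family_size must be a single integer >= 1")
  }
  if (!is.finite(base_alpha) || base_alpha <= 0 || base_alpha >= 1) {
    stop("base_alpha must lie in (0, 1)")
  }
  base_alpha / family_size
}

#' Paired before/after-mating comparisons
#'
#' For every (assay, behaviour) pair, runs the classic paired t-test on the
#' per-animal differences `after - before` (pairing by animal id). Animals
#' measured in only one phase are excluded and counted; behaviours with
#' fewer than two complete pairs are skipped with a warning. The
#' significance flag applies the Bonferroni-corrected level over the
#' behaviour family.
#'
#' @param measurements long-format data frame with columns `animal`,
#'   `assay`, `behaviour`, `phase` (`"before"` / `"after"`), `value`.
#' @param base_alpha family-wise level.
#' @param family_size Bonferroni divisor; defaults to the number of
#'   behaviours analysed.
#' @return Data frame (one row per behaviour): means and standard errors per
#'   phase, mean difference, `t`, `df`, `p`, `significant`. Attributes:
#'   `alpha` (the per-test level used), `n_unpaired` (excluded animals),
#'   `direction` (`"after - before"`).
#' @export
paired_before_after <- function(measurements, base_alpha = 0.05,
                                family_size = NULL) {
  need <- c("animal", "assay", "behaviour", "phase", "value")
  stopifnot(all(need %in% names(measurements)))
  if (!all(measurements$phase %in% c("before", "after"))) {
    stop("phase must be 'before' or 'after'")
  }
  groups <- unique(measurements[, c("assay", "behaviour")])
  rows <- list()
  n_unpaired <- 0L
  for (g in seq_len(nrow(groups))) {
    sub <- measurements[measurements$assay == groups$assay[g] &
                          measurements$behaviour == groups$behaviour[g], ]
    before <- sub[sub$phase == "before", c("animal", "value")]
    after <- sub[sub$phase == "after", c("animal", "value")]
    common <- intersect(before$animal, after$animal)
    excl <- length(unique(sub$animal)) - length(common)
    if (excl > 0L) {
      n_unpaired <- n_unpaired + excl
      warning(excl, " animal(s) missing a phase for ",
              groups$behaviour[g], "; excluded from pairing")
    }
    if (length(common) < 2L) {
      warning("fewer than 2 complete pairs for ", groups$behaviour[g],
              "; behaviour skipped")
      next
    }
    b <- before$value[match(common, before$animal)]
    a <- after$value[match(common, after$animal)]
    d <- a - b
    nn <- length(d)
    if (stats::sd(d) == 0) {
      tt <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      pp <- if (mean(d) == 0) 1 else 0
      dfree <- nn - 1L
    } else {
      ht <- stats::t.test(a, b, paired = TRUE)
      tt <- unname(ht$statistic)
      pp <- ht$p.value
      dfree <- unname(ht$parameter)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      assay = groups$assay[g], behaviour = groups$behaviour[g], n = nn,
      mean_before = mean(b), se_before = stats::sd(b) / sqrt(nn),
      mean_after = mean(a), se_after = stats::sd(a) / sqrt(nn),
      mean_diff = mean(d), t = tt, df = dfree, p = pp,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no behaviour had enough paired measurements")
  out <- do.call(rbind, rows)
  fam <- if (is.null(family_size)) nrow(out) else family_size
  alpha <- bonferroni_alpha(fam, base_alpha)
  out$significant <- out$p < alpha
  attr(out, "alpha") <- alpha
  attr(out, "family_size") <- fam
  attr(out, "n_unpaired") <- n_unpaired
  attr(out, "direction") <- "after - before"
  out
}

# All permutations of 1..n as an n! x n matrix (n <= 7 kept small).
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(seq_len(n)[-i][sub], nrow(sub)))
  }))
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rank correlation with average ranks for ties. The two-sided p-value is
#' computed by full enumeration of all `n!` rank permutations when
#' `n <= exact_max` (default 7), and by the t-approximation
#' `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom otherwise.
#' A constant vector gives an undefined correlation (`NA`).
#'
#' @param x,y paired numeric vectors (pairs with missing values dropped).
#' @param exact_max largest n for which the exact permutation p-value is
#'   enumerated.
#' @return List with `estimate` (rho), `p.value`, `n`, `method`.
#' @export
spearman_test <- function(x, y, exact_max = 7) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    return(list(estimate = NA_real_, p.value = NA_real_, n = n,
                method = "undefined (constant input)"))
  }
  rho <- stats::cor(rx, ry)
  rho <- max(-1, min(1, rho))
  if (n <= exact_max) {
    rxc <- rx - mean(rx); ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    perms <- .permutations(n)
    rho_all <- as.vector(matrix(ryc[perms], nrow(perms)) %*% rxc) / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact permutation enumeration"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    method <- "t approximation"
  }
  list(estimate = rho, p.value = p, n = n, method = method)
}

#' Screen behaviours against regional V1aR section densities
#'
#' For every behaviour, three contrasts are formed — the before phase, the
#' after phase, and the per-animal difference `after - before` — and each is
#' rank-correlated (Spearman, see [spearman_test()]) against V1aR density in
#' every brain section (plus the per-region `total_average`, computed from
#' the section densities when not supplied). Combinations with fewer than
#' `min_n` complete pairs are reported with `NA`. The significance flag uses
#' either an explicit per-test `alpha` or the Bonferroni-corrected level
#' over `family_size` tests (default: the number of correlations computed).
#'
#' @param behaviours long-format behaviour table (`animal`, `assay`,
#'   `behaviour`, `phase`, `value`).
#' @param densities density table (`animal`, `region`, `section`,
#'   `density`); `section` may be an integer index or `"total_average"`.
#' @param base_alpha family-wise level for the Bonferroni default.
#' @param family_size Bonferroni divisor (defaults to the number of tests
#'   performed).
#' @param alpha explicit per-test level overriding the Bonferroni default
#'   (e.g. `7.5e-5`).
#' @param min_n minimum complete pairs per correlation.
#' @return Data frame with one row per behaviour-contrast x region-section:
#'   `assay`, `behaviour`, `contrast`, `region`, `section`, `n`, `rho`,
#'   `p`, `significant`. Attribute `alpha` gives the per-test level used.
#' @export
spearman_screen <- function(behaviours, densities, base_alpha = 0.05,
                            family_size = NULL, alpha = NULL, min_n = 4) {
  stopifnot(all(c("animal", "assay", "behaviour", "phase", "value") %in%
                  names(behaviours)),
            all(c("animal", "region", "section", "density") %in%
                  names(densities)))
  densities$section <- as.character(densities$section)
  # add per-region total averages where absent
  for (reg in unique(densities$region)) {
    dreg <- densities[densities$region == reg, ]
    if (!"total_average" %in% dreg$section) {
      avg <- tapply(dreg$density, dreg$animal, mean)
      densities <- rbind(densities,
                         data.frame(animal = names(avg), region = reg,
                                    section = "total_average",
                                    density = as.numeric(avg),
                                    stringsAsFactors = FALSE))
    }
  }
  groups <- unique(behaviours[, c("assay", "behaviour")])
  sections <- unique(densities[, c("region", "section")])
  contrast_values <- function(sub, contrast) {
    before <- sub[sub$phase == "before", c("animal", "value")]
    after <- sub[sub$phase == "after", c("animal", "value")]
    switch(contrast,
           before = before,
           after = after,
           difference = {
             common <- intersect(before$animal, after$animal)
             data.frame(animal = common,
                        value = after$value[match(common, after$animal)] -
                          before$value[match(common, before$animal)],
                        stringsAsFactors = FALSE)
           })
  }
  rows <- list()
  for (g in seq_len(nrow(groups))) {
    sub <- behaviours[behaviours$assay == groups$assay[g] &
                        behaviours$behaviour == groups$behaviour[g], ]
    for (contrast in c("before", "after", "difference")) {
      cv <- contrast_values(sub, contrast)
      if (!nrow(cv)) next
      for (s in seq_len(nrow(sections))) {
        dsub <- densities[densities$region == sections$region[s] &
                            densities$section == sections$section[s],
                          c("animal", "density")]
        common <- intersect(cv$animal, dsub$animal)
        nn <- length(common)
        if (nn < min_n) {
          res <- list(estimate = NA_real_, p.value = NA_real_, n = nn)
        } else {
          res <- spearman_test(cv$value[match(common, cv$animal)],
                               dsub$density[match(common, dsub$animal)])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          assay = groups$assay[g], behaviour = groups$behaviour[g],
          contrast = contrast, region = sections$region[s],
          section = sections$section[s], n = res$n,
          rho = res$estimate, p = res$p.value, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no behaviour-density combination to screen")
  out <- do.call(rbind, rows)
  n_tests <- sum(!is.na(out$p))
  alpha_use <- if (!is.null(alpha)) {
    alpha
  } else {
    bonferroni_alpha(if (is.null(family_size)) max(n_tests, 1L)
                     else family_size, base_alpha)
  }
  out$significant <- !is.na(out$p) & out$p < alpha_use
  attr(out, "alpha") <- alpha_use
  attr(out, "n_tests") <- n_tests
  out
}

#' Summary of partner-preference times
#'
#' Mean, standard error, extrema and histogram bin counts of the time males
#' spent in contact with the partner (minutes by convention; bins default to
#' 10-minute widths, matching the usual presentation of the preference
#' distribution).
#'
#' @param values numeric vector, one partner-contact duration per male.
#' @param bin_width histogram bin width (same units as `values`).
#' @return A `pp_summary` list: `n`, `mean`, `se`, `min`, `max`, `breaks`,
#'   `counts`.
#' @export
partner_preference_summary <- function(values, bin_width = 10) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no partner-preference values supplied")
  if (any(values < 0)) stop("durations must be non-negative")
  n <- length(values)
  upper <- bin_width * (floor(max(values) / bin_width) + 1L)
  breaks <- seq(0, upper, by = bin_width)
  counts <- graphics::hist(values, breaks = breaks, plot = FALSE,
                           right = FALSE)$counts
  structure(list(n = n, mean = mean(values),
                 se = if (n > 1) stats::sd(values) / sqrt(n) else NA_real_,
                 min = min(values), max = max(values),
                 breaks = breaks, counts = counts),
            class = "pp_summary")
}

#' @export
print.pp_summary <- function(x, ...) {
  cat(sprintf(
    "Partner preference: n = %d, mean = %.1f +/- %.1f (SE), range %.0f-%.0f\n",
    x$n, x$mean, x$se, x$min, x$max))
  invisible(x)
}
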