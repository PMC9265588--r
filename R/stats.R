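# Day-vs-night group statistics: exact Mann-Whitney, nested mixed-model
# ANOVA, the volume-mass regression and its implied density.

#' Mann-Whitney U test (exact, tie-aware)
#'
#' Rank-sum test with midrank ties. The exact null distribution of the rank
#' sum is computed by dynamic programming over the observed (possibly tied)
#' midranks — equivalent to enumerating all arrangements — whenever
#' `n1 * n2 <= exact_limit`; otherwise the normal approximation with tie
#' correction and continuity correction is used. Two-sided p is twice the
#' smaller tail, capped at 1.
#'
#' @param x,y Numeric samples (each at least 2 values).
#' @param method `"auto"` (default), `"exact"`, or `"normal"`.
#' @param exact_limit Switch to the normal approximation when `n1 * n2`
#'   exceeds this (default 400).
#' @return A `glim_mw` list: `statistic` (U, the smaller of the two), `u1`
#'   (U of `x`), `p.value`, `method`, `n1`, `n2`.
#' @examples
#' mann_whitney(c(1, 2, 3, 4), c(5, 6, 7, 8))$p.value  # 2/70
#' @export
mann_whitney <- function(x, y, method = c("auto", "exact", "normal"),
                         exact_limit = 400) {
  method <- match.arg(method)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each sample needs at least 2 values", call. = FALSE)
  N <- n1 + n2
  r <- rank(c(x, y))          # midranks
  r1 <- sum(r[seq_len(n1)])
  u1 <- r1 - n1 * (n1 + 1) / 2
  u <- min(u1, n1 * n2 - u1)
  if (stats::var(c(x, y)) == 0) {
    message("all values identical across both samples; p = 1")
    return(structure(list(statistic = u, u1 = u1, p.value = 1,
                          method = "exact", n1 = n1, n2 = n2),
                     class = "glim_mw"))
  }
  use_exact <- method == "exact" || (method == "auto" && n1 * n2 <= exact_limit)
  if (use_exact) {
    dist <- ranksum_distribution(r, n1)       # doubled rank-sum counts
    s1 <- as.integer(round(2 * r1))
    lo <- sum(dist$count[dist$sum2 <= s1])
    hi <- sum(dist$count[dist$sum2 >= s1])
    p <- min(1, 2 * min(lo, hi) / sum(dist$count))
    meth <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie <- table(r)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (sig2 <= 0) { p <- 1 } else {
      z <- u1 - mu
      z <- (z - sign(z) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    meth <- "normal"
  }
  structure(list(statistic = u, u1 = u1, p.value = p, method = meth,
                 n1 = n1, n2 = n2),
            class = "glim_mw")
}

# Exact distribution of the doubled rank sum of a size-n1 subset of the
# midranks `r`: dynamic programming (subset-sum with a size track). Counts
# stay exact in doubles up to choose(40, 20) ~ 1.4e11 << 2^53.
ranksum_distribution <- function(r, n1) {
  dr <- as.integer(round(2 * r))
  S <- sum(dr)
  M <- matrix(0, nrow = n1 + 1, ncol = S + 1)
  M[1, 1] <- 1
  for (i in seq_along(dr)) {
    kmax <- min(i, n1)
    for (k in kmax:1) {
      src <- M[k, seq_len(S + 1 - dr[i])]
      if (any(src != 0)) {
        tgt <- (dr[i] + 1):(S + 1)
        M[k + 1, tgt] <- M[k + 1, tgt] + src
      }
    }
  }
  nz <- which(M[n1 + 1, ] != 0)
  list(sum2 = nz - 1L, count = M[n1 + 1, nz])
}

#' @export
print.glim_mw <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), %s two-sided p = %.4g\n",
              x$statistic, x$n1, x$n2, x$method, x$p.value))
  invisible(x)
}

#' Mixed-model one-way ANOVA with animal as random factor
#'
#' Fits `value ~ group + (1 | animal_id)` by REML and reports the Type-III
#' F test for the group effect with Satterthwaite denominator degrees of
#' freedom, the variance components, and the Tukey-adjusted pairwise contrast
#' (with two groups this is the same single contrast; it is reported for
#' completeness). The random intercept accounts for cells nested within
#' animals.
#'
#' @param records A cell table (see [build_cell_table()]) with columns
#'   `group`, `animal_id`, and the measurement column.
#' @param variable `"volume"` or `"dry_mass"` (columns `volume_um3` /
#'   `drymass_pg`), or the name of any numeric column.
#' @return A `glim_mixed_anova` list: `F`, `p`, `df_num`, `df_den`,
#'   `var_animal`, `var_residual`, `contrast` tibble, and the fitted model.
#' @export
mixed_anova <- function(records, variable = c("volume", "dry_mass")) {
  col <- variable_column(records, variable)
  d <- data.frame(value = records[[col]],
                  group = factor(records$group),
                  animal_id = factor(paste(records$group, records$animal_id)))
  if (nlevels(d$group) < 2) stop("both groups must be present", call. = FALSE)
  n_an <- tapply(d$animal_id, d$group, function(a) length(unique(a)))
  if (any(n_an < 2)) {
    stop("each group needs at least 2 animals (random effect inestimable)",
         call. = FALSE)
  }
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(value ~ group + (1 | animal_id), data = d, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore",
                                               calc.derivs = FALSE))
  ))
  a <- suppressMessages(stats::anova(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  em <- suppressMessages(emmeans::emmeans(fit, "group"))
  ct <- as.data.frame(suppressMessages(emmeans::contrast(em, "pairwise", adjust = "tukey")))
  structure(
    list(F = a[["F value"]][1], p = a[["Pr(>F)"]][1],
         df_num = a[["NumDF"]][1], df_den = a[["DenDF"]][1],
         var_animal = vc$vcov[vc$grp == "animal_id"],
         var_residual = vc$vcov[vc$grp == "Residual"],
         contrast = tibble::as_tibble(ct),
         variable = col, model = fit),
    class = "glim_mixed_anova"
  )
}

#' @export
print.glim_mixed_anova <- function(x, ...) {
  cat(sprintf("Mixed ANOVA on %s: F(%g, %.1f) = %.4g, p = %.4g\n",
              x$variable, x$df_num, x$df_den, x$F, x$p))
  cat(sprintf("  variance components: animal %.4g, residual %.4g\n",
              x$var_animal, x$var_residual))
  invisible(x)
}

variable_column <- function(records, variable) {
  if (length(variable) == 1 && variable %in% names(records)) return(variable)
  variable <- match.arg(variable[1], c("volume", "dry_mass"))
  switch(variable, volume = "volume_um3", dry_mass = "drymass_pg")
}

#' Volume-vs-mass regression and implied density
#'
#' Ordinary least squares of cell volume (L) on dry mass (g) within one
#' group. The reciprocal of the slope is the group's mass density in g/L
#' (reported at full precision; the print method shows 2 significant
#' figures, the conventional display precision for these densities).
#'
#' @param records Cell table.
#' @param group `"day"` or `"night"`.
#' @param exclude_damaged Drop damaged (negative-mass) cells first
#'   (default TRUE).
#' @return A `glim_mv_fit`: `slope_L_per_g`, `intercept_um3`, `r`,
#'   `density_g_per_L`, `n`, `group`, and the `lm` fit.
#' @export
fit_mass_volume <- function(records, group, exclude_damaged = TRUE) {
  d <- records[records$group == group, ]
  if (exclude_damaged && "damaged" %in% names(d)) d <- d[!d$damaged, ]
  if (nrow(d) < 3) stop("need at least 3 cells for the volume-mass fit", call. = FALSE)
  mass_g <- d$drymass_pg * 1e-12
  vol_L <- d$volume_um3 * 1e-15
  if (stats::var(mass_g) == 0) stop("zero mass variance; slope undefined", call. = FALSE)
  fit <- stats::lm(vol_L ~ mass_g)
  slope <- unname(stats::coef(fit)[2])
  structure(
    list(slope_L_per_g = slope,
         intercept_um3 = unname(stats::coef(fit)[1]) * 1e15,
         r = stats::cor(mass_g, vol_L),
         density_g_per_L = 1 / slope,
         n = nrow(d), group = group, model = fit),
    class = "glim_mv_fit"
  )
}

#' @export
print.glim_mv_fit <- function(x, ...) {
  cat(sprintf("%s: volume = %.3g L/g x mass + %.3g um^3 (r = %.3f, n = %d)\n",
              x$group, x$slope_L_per_g, x$intercept_um3, x$r, x$n))
  cat(sprintf("  implied density: %s g/L\n",
              format(signif(x$density_g_per_L, 2))))
  invisible(x)
}

#' Day-vs-night group comparison
#'
#' For each variable (volume and dry mass by default): group sizes, means
#' with SEM over cells, the percent change from day to night, the
#' Mann-Whitney test, and the mixed-model ANOVA with animal as random factor.
#' Both tests are always reported; the `significant` flag is taken from the
#' mixed model by default because it respects the nesting of cells within
#' animals.
#'
#' @param records Cell table with both groups present.
#' @param variables Character vector of variables (default volume and
#'   dry_mass).
#' @param alpha_level Significance level (default 0.05).
#' @param significance Which test drives the `significant` flag:
#'   `"mixed"` (default) or `"mann_whitney"`.
#' @param exclude_damaged Drop damaged cells first (default TRUE).
#' @return A `glim_comparison` tibble, one row per variable, with columns
#'   `variable`, `n_day`, `n_night`, `mean_day`, `sem_day`, `mean_night`,
#'   `sem_night`, `percent_change`, `mw_U`, `mw_p`, `mixed_F`, `mixed_p`,
#'   `significant`.
#' @export
compare_groups <- function(records, variables = c("volume", "dry_mass"),
                           alpha_level = 0.05,
                           significance = c("mixed", "mann_whitney"),
                           exclude_damaged = TRUE) {
  significance <- match.arg(significance)
  if (exclude_damaged && "damaged" %in% names(records)) {
    records <- records[!records$damaged, ]
  }
  for (g in c("day", "night")) {
    if (sum(records$group == g) == 0) {
      stop(sprintf("group '%s' is missing or empty", g), call. = FALSE)
    }
  }
  rows <- lapply(variables, function(v) {
    col <- variable_column(records, v)
    day <- records[[col]][records$group == "day"]
    night <- records[[col]][records$group == "night"]
    sem <- function(x) stats::sd(x) / sqrt(length(x))
    mw <- mann_whitney(day, night)
    ma <- tryCatch(mixed_anova(records, v), error = function(e) {
      message(sprintf("mixed ANOVA unavailable for %s: %s", v, conditionMessage(e)))
      NULL
    })
    pc <- (mean(night) - mean(day)) / mean(day) * 100
    sig_p <- if (significance == "mixed") (if (is.null(ma)) NA_real_ else ma$p) else mw$p.value
    tibble::tibble(
      variable = v, n_day = length(day), n_night = length(night),
      mean_day = mean(day), sem_day = sem(day),
      mean_night = mean(night), sem_night = sem(night),
      percent_change = pc,
      mw_U = mw$statistic, mw_p = mw$p.value,
      mixed_F = if (is.null(ma)) NA_real_ else ma$F,
      mixed_p = if (is.null(ma)) NA_real_ else ma$p,
      significant = isTRUE(sig_p < alpha_level)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("glim_comparison", class(out))
  attr(out, "alpha_level") <- alpha_level
  attr(out, "significance") <- significance
  out
}

#' Render a comparison as a markdown report
#'
#' @param comparison A `glim_comparison` from [compare_groups()].
#' @param fits Optional list of `glim_mv_fit` objects to append.
#' @return Character vector of markdown lines.
#' @export
report_markdown <- function(comparison, fits = NULL) {
  ln <- c("# Day vs night comparison", "",
          sprintf("Significance from the %s test at alpha = %g.",
                  attr(comparison, "significance") %||% "mixed",
                  attr(comparison, "alpha_level") %||% 0.05), "",
          "| variable | n (day/night) | day mean +/- SEM | night mean +/- SEM | change (%) | Mann-Whitney p | mixed ANOVA p | significant |",
          "|---|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(comparison))) {
    r <- comparison[i, ]
    ln <- c(ln, sprintf(
      "| %s | %d/%d | %.3g +/- %.2g | %.3g +/- %.2g | %+.1f | %.3g | %.3g | %s |",
      r$variable, r$n_day, r$n_night, r$mean_day, r$sem_day,
      r$mean_night, r$sem_night, r$percent_change, r$mw_p, r$mixed_p,
      ifelse(r$significant, "yes", "no")))
  }
  if (!is.null(fits)) {
    ln <- c(ln, "", "## Volume-mass fits", "")
    for (f in fits) {
      ln <- c(ln, sprintf("- %s: slope %.3g L/g, r = %.3f, density %s g/L (n = %d)",
                          f$group, f$slope_L_per_g, f$r,
                          format(signif(f$density_g_per_L, 2)), f$n))
    }
  }
  ln
}

# ---- broom-style accessors ------------------------------------------------

#' Tidy a fitted glimquant object
#'
#' Broom-style one-row-per-term summaries for [mann_whitney()],
#' [mixed_anova()], and [fit_mass_volume()] results.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
tidy.glim_mw <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p.value,
                 method = x$method, n1 = x$n1, n2 = x$n2)
}

#' @rdname tidy
#' @export
tidy.glim_mixed_anova <- function(x, ...) {
  tibble::tibble(term = "group", statistic = x$F, df = x$df_num,
                 df.residual = x$df_den, p.value = x$p,
                 var.animal = x$var_animal, var.residual = x$var_residual)
}

#' @rdname tidy
#' @export
tidy.glim_mv_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept_um3, x$slope_L_per_g),
                 unit = c("um^3", "L/g"))
}

#' One-line model summary
#' @param x A fitted object.
#' @param ... Unused.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname glance
#' @export
glance.glim_mv_fit <- function(x, ...) {
  tibble::tibble(group = x$group, slope_L_per_g = x$slope_L_per_g,
                 density_g_per_L = x$density_g_per_L, r = x$r, n = x$n)
}
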