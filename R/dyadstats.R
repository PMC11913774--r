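#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment of a vector of p-values.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, never smaller than the raw ones.
#' @export
fdr_adjust <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

# z-standardize a column, recording its center/scale.
standardize <- function(x) {
  mu <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize a constant predictor", call. = FALSE)
  }
  structure((x - mu) / s, center = mu, scale = s)
}

#' Assemble the dyad-level model design
#'
#' Joins the block-level synchrony outcome with condition labels, behavioral
#' predictors and the within-dyad questionnaire/HRV scores, building for each
#' within-dyad variable its dyad SUM (`s1 + s2`) and absolute difference
#' (`|s1 - s2|`) per the dyadic-analysis approach for between-dyad outcomes.
#' Continuous predictors are z-standardized (centers/scales stored in the
#' `scaling` attribute; raw columns kept with suffix `_raw`). Block novelty
#' is carried both as a factor and as the dummy `novelty_old` (old = 1,
#' new = 0), the coding under which higher synchrony in novel blocks yields a
#' negative coefficient.
#'
#' @param study A `synthetic_study` (supplies subjects and block labels).
#' @param synchrony A [study_synchrony()] table.
#' @param hrv Optional [study_hrv()] table (adds `sum_hrv_change` /
#'   `absdiff_hrv_change`).
#' @param behavior Optional [study_behavior()] table (adds standardized
#'   grasp/start time differences).
#' @return A data frame of class `dyad_design`, one row per dyad x task
#'   block, with outcome `synchrony_scaled`.
#' @export
build_dyad_design <- function(study, synchrony, hrv = NULL, behavior = NULL) {
  task <- synchrony[synchrony$block_type != "baseline", ]
  design <- data.frame(
    dyad = task$dyad,
    block = task$block,
    synchrony_scaled = task$scaled,
    block_type = factor(task$block_type, levels = c("free", "leader_follower")),
    movement = factor(task$movement, levels = c("same", "opposite")),
    novelty = factor(task$novelty, levels = c("new", "old")),
    novelty_old = as.numeric(task$novelty == "old")
  )

  scaling <- list()
  add_scaled <- function(design, name, values) {
    z <- standardize(values)
    design[[paste0(name, "_raw")]] <- values
    design[[name]] <- as.numeric(z)
    scaling[[name]] <<- c(center = attr(z, "center"), scale = attr(z, "scale"))
    design
  }

  # Within-dyad questionnaire scores -> SUM and ABSDIFF per dyad.
  sub <- study$subjects
  for (v in c("social_anxiety", "perspective_taking")) {
    s1 <- sub[[v]][sub$subject == 1][match(design$dyad, sub$dyad[sub$subject == 1])]
    s2 <- sub[[v]][sub$subject == 2][match(design$dyad, sub$dyad[sub$subject == 2])]
    design <- add_scaled(design, paste0("sum_", v), s1 + s2)
    design <- add_scaled(design, paste0("absdiff_", v), abs(s1 - s2))
  }

  if (!is.null(hrv)) {
    key_d <- paste(design$dyad, design$block)
    h1 <- hrv[hrv$subject == 1, ]
    h2 <- hrv[hrv$subject == 2, ]
    c1 <- h1$hrv_change_ms[match(key_d, paste(h1$dyad, h1$block))]
    c2 <- h2$hrv_change_ms[match(key_d, paste(h2$dyad, h2$block))]
    design <- add_scaled(design, "sum_hrv_change", c1 + c2)
    design <- add_scaled(design, "absdiff_hrv_change", abs(c1 - c2))
  }

  if (!is.null(behavior)) {
    key_d <- paste(design$dyad, design$block)
    key_b <- paste(behavior$dyad, behavior$block)
    design <- add_scaled(design, "grasp_time_difference",
                         behavior$grasp_time_difference_ms[match(key_d, key_b)])
    design <- add_scaled(design, "start_time_difference",
                         behavior$start_time_difference_ms[match(key_d, key_b)])
  }

  miss <- !is.finite(design$synchrony_scaled)
  if (any(miss)) {
    message(sprintf("dropping %d rows with missing outcomes", sum(miss)))
    design <- design[!miss, ]
  }
  attr(design, "scaling") <- scaling
  class(design) <- c("dyad_design", "data.frame")
  design
}

#' Fit a linear mixed model and report its fixed effects
#'
#' Estimation backend for the dyad-level designs: a Gaussian linear mixed
#' model fit by REML with Satterthwaite p-values. If the requested
#' random-effects structure fails to converge or is singular, the model is
#' refit down a ladder ending at a by-dyad random intercept, and the step is
#' recorded. Wald confidence intervals are the default; a parametric
#' bootstrap (percentile intervals via [lme4::bootMer()]) is available behind
#' `ci_method = "boot"`. Benjamini-Hochberg adjusted p-values are reported
#' for the non-intercept fixed effects, and the model is compared against a
#' random-intercept-only null by a likelihood-ratio test (both refit by ML).
#' Marginal and conditional R-squared follow the usual variance-partition
#' formula for Gaussian mixed models.
#'
#' @param design A [build_dyad_design()] table (any data frame works).
#' @param formula_spec Model formula as a string, e.g.
#'   `"synchrony_scaled ~ novelty_old + sum_social_anxiety + (1 | dyad)"`.
#' @param ci_method `"wald"` or `"boot"`.
#' @param n_boot Bootstrap replicates when `ci_method = "boot"`.
#' @param conf_level Confidence level of the intervals.
#' @param compare_null Also fit the by-group random-intercept null and report
#'   the likelihood-ratio comparison.
#' @param seed Seed for the bootstrap.
#' @return A list of class `model_report`: `coefficients` (term, estimate,
#'   se, ci, raw and FDR-adjusted p), `r2` (marginal/conditional),
#'   `null_comparison`, `formula`, `singular`, `model`.
#' @export
fit_mixed_model <- function(design, formula_spec,
                            ci_method = c("wald", "boot"), n_boot = 500,
                            conf_level = 0.95, compare_null = TRUE,
                            seed = NULL) {
  ci_method <- match.arg(ci_method)
  form <- stats::as.formula(formula_spec)
  vars <- all.vars(form)
  missing_vars <- setdiff(vars, names(design))
  if (length(missing_vars) > 0) {
    stop("unknown predictor(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  group_var <- vars[length(vars)] # grouping factor of the last random term

  fit_one <- function(f) {
    suppressMessages(suppressWarnings(
      lmerTest::lmer(f, data = design, REML = TRUE,
                     control = lme4::lmerControl(check.conv.singular = "ignore"))
    ))
  }
  ladder_used <- formula_spec
  model <- tryCatch(fit_one(form), error = function(e) NULL)
  bad <- is.null(model) || lme4::isSingular(model, tol = 1e-4)
  has_slopes <- grepl("\\|", formula_spec) &&
    grepl("[^1[:space:]]+[[:space:]]*\\|", formula_spec)
  if (bad && has_slopes) {
    # Drop all random slopes, keep the by-group intercept.
    fixed_part <- sub("\\s*\\+\\s*\\([^)]*\\|[^)]*\\)", "", formula_spec)
    ladder_used <- paste0(fixed_part, " + (1 | ", group_var, ")")
    m2 <- tryCatch(fit_one(stats::as.formula(ladder_used)), error = function(e) NULL)
    if (!is.null(m2)) model <- m2
  }
  if (is.null(model)) stop("mixed model failed to converge", call. = FALSE)

  smry <- summary(model)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- smry[, "Estimate"]
  se <- smry[, "Std. Error"]
  ci_lo <- est - z * se
  ci_hi <- est + z * se
  if (ci_method == "boot") {
    bs <- with_seed(seed, suppressWarnings(suppressMessages(
      lme4::bootMer(model, lme4::fixef, nsim = n_boot, type = "parametric")
    )))
    qs <- apply(bs$t, 2, stats::quantile,
                probs = c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                na.rm = TRUE)
    ci_lo <- qs[1, ]
    ci_hi <- qs[2, ]
  }
  p_raw <- smry[, "Pr(>|t|)"]
  not_int <- rownames(smry) != "(Intercept)"
  p_fdr <- p_raw
  p_fdr[not_int] <- fdr_adjust(p_raw[not_int])

  coefs <- data.frame(
    term = rownames(smry),
    estimate = unname(est),
    se = unname(se),
    ci_lower = unname(ci_lo),
    ci_upper = unname(ci_hi),
    df = unname(smry[, "df"]),
    p_value = unname(p_raw),
    p_fdr = unname(p_fdr),
    row.names = NULL
  )

  # Variance partition R^2 (Gaussian case).
  vc <- lme4::VarCorr(model)
  var_rand <- sum(vapply(vc, function(m) sum(diag(m)), numeric(1)))
  var_resid <- attr(vc, "sc")^2
  fe <- lme4::fixef(model)
  X <- stats::model.matrix(model)
  var_fixed <- stats::var(as.numeric(X %*% fe))
  tot <- var_fixed + var_rand + var_resid
  r2 <- c(marginal = var_fixed / tot, conditional = (var_fixed + var_rand) / tot)

  null_cmp <- NULL
  if (compare_null) {
    null_form <- stats::as.formula(
      paste(as.character(form)[2], "~ 1 + (1 |", group_var, ")")
    )
    m_ml <- tryCatch(suppressWarnings(suppressMessages(
      lme4::refitML(model)
    )), error = function(e) NULL)
    m0 <- tryCatch(suppressWarnings(suppressMessages(
      lme4::lmer(null_form, data = design, REML = FALSE)
    )), error = function(e) NULL)
    if (!is.null(m_ml) && !is.null(m0)) {
      an <- stats::anova(m0, m_ml)
      null_cmp <- list(
        chisq = an$Chisq[2], df = an$Df[2], p_value = an[["Pr(>Chisq)"]][2],
        aic_model = an$AIC[2], aic_null = an$AIC[1]
      )
    }
  }

  structure(
    list(
      coefficients = coefs,
      r2 = r2,
      null_comparison = null_cmp,
      formula = ladder_used,
      singular = lme4::isSingular(model, tol = 1e-4),
      model = model
    ),
    class = "model_report"
  )
}

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report>", x$formula, "\n")
  print(x$coefficients, row.names = FALSE, digits = 3)
  cat(sprintf("R2 marginal %.3f, conditional %.3f\n",
              x$r2["marginal"], x$r2["conditional"]))
  if (!is.null(x$null_comparison)) {
    cat(sprintf("vs null: chisq = %.2f (df %d), p = %.3g\n",
                x$null_comparison$chisq, x$null_comparison$df,
                x$null_comparison$p_value))
  }
  invisible(x)
}

#' Saturated-then-trimmed dyadic model procedure
#'
#' Fits the saturated model containing the between-dyad predictors plus both
#' the SUM and the ABSDIFF term of each within-dyad predictor, with a by-dyad
#' random intercept (and optional random slopes). If none of the ABSDIFF
#' terms reaches `alpha` (raw p), they are removed and the trimmed, SUM-only
#' model is refit and reported; otherwise the saturated model is reported.
#' FDR adjustment is applied within the reported coefficient family.
#'
#' @param design A [build_dyad_design()] table.
#' @param outcome Outcome column name.
#' @param between Character vector of between-dyad predictor columns.
#' @param within Character vector of within-dyad base names; for each, the
#'   design must contain `sum_<name>` and `absdiff_<name>`.
#' @param random Random-effects part of the formula.
#' @param alpha Significance level of the trim decision.
#' @param ... Passed on to [fit_mixed_model()].
#' @return A list of class `trim_report`: the final `report`, the
#'   `saturated` report, and `trimmed` (logical).
#' @export
saturated_then_trim <- function(design,
                                outcome = "synchrony_scaled",
                                between = c("block_type", "novelty_old"),
                                within = c("social_anxiety", "perspective_taking"),
                                random = "(1 | dyad)",
                                alpha = 0.05, ...) {
  sums <- paste0("sum_", within)
  absdiffs <- paste0("absdiff_", within)
  if (length(c(between, sums)) < 2) {
    stop("need at least 2 predictors", call. = FALSE)
  }
  form_sat <- paste(
    outcome, "~", paste(c(between, sums, absdiffs), collapse = " + "),
    "+", random
  )
  sat <- fit_mixed_model(design, form_sat, ...)
  p_abs <- sat$coefficients$p_value[sat$coefficients$term %in% absdiffs]
  trim <- length(p_abs) > 0 && all(p_abs >= alpha)
  final <- sat
  if (trim) {
    form_trim <- paste(
      outcome, "~", paste(c(between, sums), collapse = " + "), "+", random
    )
    final <- fit_mixed_model(design, form_trim, ...)
  }
  structure(
    list(report = final, saturated = sat, trimmed = trim),
    class = "trim_report"
  )
}

#' @export
print.trim_report <- function(x, ...) {
  cat(sprintf("<trim_report> %s model reported\n",
              if (x$trimmed) "trimmed (SUM-only)" else "saturated"))
  print(x$report)
  invisible(x)
}

#' Long lag-group table for the block x lag-group model
#'
#' Reshapes the per-block lag-group means into the long format consumed by a
#' Block x LagGroup mixed model (one row per dyad, block and lag group).
#'
#' @param synchrony A [study_synchrony()] table with lag-group columns.
#' @return Data frame: `dyad`, `block`, `block_label`, `lag_group` (factor
#'   negative/zero/positive), `mean_ccf`.
#' @export
lag_group_contrast <- function(synchrony) {
  need <- c("dyad", "block", "block_type", "lag_negative", "lag_zero", "lag_positive")
  stopifnot(all(need %in% names(synchrony)))
  if (any(!is.finite(synchrony$lag_zero))) {
    stop("missing lag-group means; compute CCFs with 25 lags", call. = FALSE)
  }
  groups <- c("negative", "zero", "positive")
  out <- do.call(rbind, lapply(seq_along(groups), function(i) {
    data.frame(
      dyad = synchrony$dyad,
      block = synchrony$block,
      block_label = ifelse(synchrony$block_type == "baseline", "baseline",
                           ifelse(synchrony$block_type == "free", "free",
                                  paste0("leader_", sub("s", "", synchrony$leader)))),
      lag_group = groups[i],
      mean_ccf = synchrony[[paste0("lag_", groups[i])]]
    )
  }))
  out$lag_group <- factor(out$lag_group, levels = groups)
  out <- out[order(out$dyad, out$block, out$lag_group), ]
  rownames(out) <- NULL
  out
}
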