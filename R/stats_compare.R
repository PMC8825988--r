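#' Assemble the per-flight feature table
#'
#' One row per bat x flight with the per-flight mean acoustic features —
#' the analysis unit for the condition comparisons.
#'
#' @param summaries Data frame with columns \code{bat_id},
#'   \code{flight_id}, \code{condition} (\code{single1}/\code{group}/
#'   \code{single2}), \code{space} (\code{narrow}/\code{wide}) and any of
#'   the response columns \code{tfm_bandwidth}, \code{tfm_duration},
#'   \code{pulse_duration}, \code{silent_time}, \code{rf_sd}. Missing
#'   responses stay \code{NA}.
#' @return The validated table (class \code{"feature_table"}).
#' @export
build_feature_table <- function(summaries) {
  req <- c("bat_id", "flight_id", "condition", "space")
  if (!all(req %in% names(summaries)))
    stop("feature table needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  bad_cond <- setdiff(unique(summaries$condition),
                      c("single1", "group", "single2"))
  if (length(bad_cond))
    stop("unknown condition(s): ", paste(bad_cond, collapse = ", "),
         call. = FALSE)
  bad_space <- setdiff(unique(summaries$space), c("narrow", "wide"))
  if (length(bad_space))
    stop("unknown space(s): ", paste(bad_space, collapse = ", "),
         call. = FALSE)
  key <- paste(summaries$bat_id, summaries$flight_id)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    first <- summaries[!duplicated(key), ]
    resp <- intersect(c("tfm_bandwidth", "tfm_duration", "pulse_duration",
                        "silent_time", "rf_sd"), names(summaries))
    for (d in unique(dup)) {
      rows <- summaries[key == d, resp, drop = FALSE]
      if (nrow(unique(rows)) > 1L)
        stop("conflicting duplicate rows for (bat, flight) key: ", d,
             call. = FALSE)
    }
    summaries <- first
  }
  summaries$condition <- factor(summaries$condition,
                                levels = c("single1", "group", "single2"))
  summaries$space <- factor(summaries$space, levels = c("narrow", "wide"))
  class(summaries) <- c("feature_table", "data.frame")
  summaries
}

#' Compare acoustic features across flight conditions
#'
#' Fits the study's linear mixed model for one response: flight condition,
#' flight space and their interaction as fixed effects, bat identity as a
#' random intercept; significance of the fixed effects by type II Wald
#' chi-square tests and, for condition, Tukey-adjusted pairwise contrasts.
#' For the reference-frequency s.d. (whose distribution differs strongly
#' between spaces) a separate condition-only model is fitted per space.
#' Estimation is delegated to \pkg{lme4}, the Wald tests to \pkg{car} and
#' the contrasts to \pkg{emmeans}.
#'
#' @param table A [build_feature_table()] table.
#' @param response Response column name.
#' @param per_space Fit a separate condition-only model per space
#'   (default: only for \code{rf_sd}).
#' @return Object of class \code{"condition_comparison"}: per model,
#'   the \pkg{lme4} fit, the Wald chi-square table, the Tukey contrast
#'   table, a residual-diagnostics summary and a singular-fit flag.
#' @export
compare_conditions <- function(table, response,
                               per_space = identical(response, "rf_sd")) {
  stopifnot(inherits(table, "data.frame"), response %in% names(table))
  tab <- table[!is.na(table[[response]]), ]
  tab$condition <- droplevels(factor(tab$condition,
                                     levels = c("single1", "group", "single2")))
  if (nlevels(tab$condition) < 2L)
    stop("need at least two flight conditions to compare", call. = FALSE)
  tab$.y <- tab[[response]]

  fit_one <- function(dat, formula) {
    fit <- lme4::lmer(formula, data = dat, REML = TRUE)
    singular <- lme4::isSingular(fit)
    wald <- as.data.frame(car::Anova(fit, type = 2))
    em <- emmeans::emmeans(fit, "condition")
    contrasts <- as.data.frame(emmeans::contrast(em, "pairwise",
                                                 adjust = "tukey"))
    unadj <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "none"))
    contrasts$p.unadjusted <- unadj$p.value
    res <- stats::residuals(fit)
    diag <- data.frame(
      resid_sd = stats::sd(res),
      shapiro_p = if (length(res) >= 3 && length(res) <= 5000)
        stats::shapiro.test(res)$p.value else NA_real_)
    list(fit = fit, wald = wald, contrasts = contrasts, diagnostics = diag,
         singular = singular)
  }

  models <- if (per_space) {
    sp <- lapply(split(tab, droplevels(tab$space)), function(d)
      fit_one(d, .y ~ condition + (1 | bat_id)))
    sp
  } else {
    f <- if (nlevels(droplevels(tab$space)) > 1L)
      .y ~ condition * space + (1 | bat_id)
    else .y ~ condition + (1 | bat_id)
    list(all = fit_one(tab, f))
  }
  structure(list(response = response, per_space = per_space,
                 models = models),
            class = "condition_comparison")
}

#' @exportS3Method base::print
print.condition_comparison <- function(x, ...) {
  cat("Condition comparison for", x$response,
      if (x$per_space) "(separate model per space)" else "", "\n")
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat("\n--", nm, if (m$singular) "[singular fit]" else "", "\n")
    cat("Type II Wald chi-square:\n"); print(round(m$wald, 4))
    cat("Tukey-adjusted contrasts:\n")
    print(m$contrasts[, c("contrast", "estimate", "SE", "p.value")],
          digits = 4)
  }
  invisible(x)
}

#' @exportS3Method base::summary
summary.condition_comparison <- function(object, ...) {
  do.call(rbind, lapply(names(object$models), function(nm) {
    ct <- object$models[[nm]]$contrasts
    ct$model <- nm; ct$response <- object$response
    ct
  }))
}

#' Simulate a feature table with a known group-flight effect
#'
#' Generates a balanced bat x condition table from the random-intercept
#' model \code{y = baseline + effect x 1[group] + b_bat + e}, the testbed
#' for validating the comparison harness (type-I error and power).
#'
#' @param n_bats Number of bats.
#' @param effect True group-condition effect (response units).
#' @param sigma_bat Between-bat s.d. (random intercept).
#' @param sigma_res Residual s.d.
#' @param baseline Grand mean.
#' @param space Space label for all rows.
#' @param response Name of the response column to create.
#' @param seed Optional seed.
#' @return A [build_feature_table()] table.
#' @export
simulate_feature_table <- function(n_bats = 9, effect = 0, sigma_bat = 0.5,
                                   sigma_res = 1, baseline = 13,
                                   space = "narrow",
                                   response = "tfm_bandwidth", seed = NULL) {
  gen <- function() {
    conds <- c("single1", "group", "single2")
    b <- stats::rnorm(n_bats, 0, sigma_bat)
    df <- expand.grid(bat_id = sprintf("bat%02d", seq_len(n_bats)),
                      condition = conds, stringsAsFactors = FALSE)
    df$space <- space
    df$flight_id <- paste(df$condition, df$bat_id, sep = "_")
    df[[response]] <- baseline + effect * (df$condition == "group") +
      b[match(df$bat_id, unique(df$bat_id))] +
      stats::rnorm(nrow(df), 0, sigma_res)
    df
  }
  tab <- if (is.null(seed)) gen() else with_seed(seed, gen())
  build_feature_table(tab)
}

#' Rejection rate of the group-vs-single contrasts over simulated tables
#'
#' Monte-Carlo harness: simulates feature tables with a given true group
#' effect, runs [compare_conditions()] on each, and reports how often a
#' Tukey-adjusted group-vs-single contrast is significant. With
#' \code{effect = 0} this is the empirical type-I error of the
#' group-vs-single comparison; with a nonzero effect it is its power.
#'
#' @param n_rep Number of simulated tables.
#' @param effect True group effect passed to [simulate_feature_table()].
#' @param alpha Significance level.
#' @param seed Base seed; replicate r uses \code{seed + r}.
#' @param ... Further arguments to [simulate_feature_table()].
#' @return List: \code{rate} (rejection proportion), \code{n_rep},
#'   \code{alpha}, \code{effect}.
#' @export
condition_test_rejection_rate <- function(n_rep = 200, effect = 0,
                                          alpha = 0.05, seed = 1, ...) {
  hits <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    tab <- simulate_feature_table(effect = effect, seed = seed + r, ...)
    cmp <- compare_conditions(tab, "tfm_bandwidth", per_space = FALSE)
    ct <- cmp$models[[1]]$contrasts
    gs <- grepl("group", ct$contrast)
    hits[r] <- any(ct$p.value[gs] < alpha)
  }
  list(rate = mean(hits), n_rep = n_rep, alpha = alpha, effect = effect)
}
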