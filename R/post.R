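#' Assemble the accuracy table for the post-analysis
#'
#' Pools all repeat x trait x timepoint x algorithm x biom accuracies into
#' one long data.frame with sum-to-zero factor coding, the substrate of the
#' mixed-model post-analysis. A full default benchmark yields
#' 5 x 12 x 3 x 4 x 2 = 1440 rows. Rows with missing accuracy are dropped
#' with a message.
#'
#' @param results a `cv_result` data.frame from [run_cv()].
#' @return data.frame: `Timepoint`, `Algorithm`, `Trait`, `Biom` (factors),
#'   `Replicate`, `accuracy`.
#' @export
assemble_table <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("trait", "timepoint", "algorithm", "biom",
                  "repeat_index", "accuracy") %in% names(results)))
  bad <- !is.finite(results$accuracy)
  if (any(bad)) {
    message(sum(bad), " cell(s) with undefined accuracy dropped")
    results <- results[!bad, , drop = FALSE]
  }
  out <- data.frame(
    Timepoint = factor(results$timepoint,
                       levels = unique(results$timepoint)),
    Algorithm = factor(results$algorithm),
    Trait = factor(results$trait),
    Biom = factor(ifelse(results$biom, "biom", "null"),
                  levels = c("null", "biom")),
    Replicate = results$repeat_index,
    accuracy = results$accuracy)
  for (v in c("Timepoint", "Algorithm", "Trait", "Biom"))
    stats::contrasts(out[[v]]) <- stats::contr.sum(nlevels(out[[v]]))
  out
}

#' Fit the post-analysis linear mixed model
#'
#' REML fit of
#' `accuracy ~ (Timepoint + Algorithm + Trait + Biom)^2 +
#'  (1 | Timepoint:Algorithm:Trait:Biom)`:
#' all four main effects, all six pairwise interactions, and a random
#' four-way interaction absorbing cell-level departures. Sum-to-zero
#' contrasts are enforced so the Type III tests are meaningful.
#'
#' @param records accuracy table from [assemble_table()].
#' @param random include the random four-way interaction (default `TRUE`);
#'   `FALSE` fits the fixed-effects model by least squares instead.
#' @return `lmerModLmerTest` fit (or `lm` when `random = FALSE`).
#' @export
fit_post_lmm <- function(records, random = TRUE) {
  stopifnot(is.data.frame(records),
            all(c("Timepoint", "Algorithm", "Trait", "Biom", "accuracy")
                %in% names(records)))
  for (v in c("Timepoint", "Algorithm", "Trait", "Biom"))
    stats::contrasts(records[[v]]) <- stats::contr.sum(nlevels(records[[v]]))
  fixed <- "accuracy ~ (Timepoint + Algorithm + Trait + Biom)^2"
  if (!random) return(stats::lm(stats::as.formula(fixed), data = records))
  f <- stats::as.formula(paste(fixed,
                               "+ (1 | Timepoint:Algorithm:Trait:Biom)"))
  fit <- lmerTest::lmer(f, data = records, REML = TRUE,
                        control = lme4::lmerControl(
                          check.conv.singular = "ignore",
                          calc.derivs = FALSE))
  fit
}

#' Type III ANOVA of the post-analysis fit
#'
#' Marginal F-tests per fixed term; Satterthwaite denominator degrees of
#' freedom for the mixed fit, classical F for the least-squares fit.
#'
#' @param fit output of [fit_post_lmm()].
#' @return data.frame with `term`, `sum_sq`, `mean_sq`, `f_value`,
#'   `p_value` (10 rows for the full factorial: 4 main + 6 pairwise).
#' @export
type3_anova <- function(fit) {
  if (inherits(fit, "lmerMod")) {
    tab <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
    out <- data.frame(term = rownames(tab),
                      sum_sq = tab[["Sum Sq"]],
                      mean_sq = tab[["Mean Sq"]],
                      f_value = tab[["F value"]],
                      p_value = tab[["Pr(>F)"]],
                      stringsAsFactors = FALSE)
  } else {
    stopifnot(inherits(fit, "lm"))
    tab <- car::Anova(fit, type = 3)
    tab <- tab[!rownames(tab) %in% c("(Intercept)", "Residuals"), ,
               drop = FALSE]
    out <- data.frame(term = rownames(tab),
                      sum_sq = tab[["Sum Sq"]],
                      mean_sq = tab[["Sum Sq"]] / tab[["Df"]],
                      f_value = tab[["F value"]],
                      p_value = tab[["Pr(>F)"]],
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Least-squares means for a model term
#'
#' Marginal means over a balanced reference grid of the remaining factors,
#' with standard errors from the fitted covariance.
#'
#' @param fit output of [fit_post_lmm()].
#' @param term a term string such as `"Biom"` or `"Timepoint:Biom"`.
#' @return data.frame of estimates and SEs, one row per level combination.
#' @export
ls_means <- function(fit, term) {
  spec <- stats::as.formula(paste("~", term))
  em <- emmeans::emmeans(fit, spec, lmer.df = "satterthwaite")
  out <- as.data.frame(em)
  names(out)[names(out) == "emmean"] <- "estimate"
  out
}
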