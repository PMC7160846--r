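# Confusion-matrix and ANOVA reporting of the decoding and behavioral results.

#' Build a confusion matrix from true and predicted levels
#'
#' Rows index the true stickiness level, columns the classifier prediction.
#'
#' @param true_levels,predicted_levels Equal-length label vectors.
#' @param levels The admissible level set (default 1:3).
#' @param direction,region,subject Optional metadata carried as attributes.
#' @return A `levels x levels` integer matrix of class `confusion_matrix`.
#' @export
confusion_from_predictions <- function(true_levels, predicted_levels,
                                       levels = 1:3, direction = NULL,
                                       region = NULL, subject = NULL) {
  if (length(true_levels) != length(predicted_levels))
    stop("confusion_from_predictions(): label vectors differ in length")
  unknown <- setdiff(unique(c(true_levels, predicted_levels)), levels)
  if (length(unknown))
    stop("confusion_from_predictions(): unknown label(s) ",
         paste(unknown, collapse = ", "))
  counts <- table(true = factor(true_levels, levels = levels),
                  predicted = factor(predicted_levels, levels = levels))
  m <- matrix(as.integer(counts), length(levels), length(levels),
              dimnames = dimnames(counts))
  structure(m, class = c("confusion_matrix", class(m)),
            direction = direction, region = region, subject = subject)
}

#' Row-normalized (row-stochastic) view of a confusion matrix
#' @param cm A `confusion_matrix`.
#' @return Matrix of per-true-level prediction rates.
#' @export
confusion_rates <- function(cm) {
  rs <- rowSums(cm)
  rs[rs == 0] <- 1
  unclass(cm) / rs
}

#' Overall accuracy of a confusion matrix
#' @param cm A `confusion_matrix`.
#' @return `trace / total`.
#' @export
confusion_accuracy <- function(cm) sum(diag(cm)) / sum(cm)

#' Compare the two cross-decoding directions
#'
#' Tests whether a region decodes with similar performance in both transfer
#' directions (e.g. trained on skin and tested on glove vs the reverse). Each
#' subject's confusion matrix is z-scored across its own cells; the diagonal
#' (correct-prediction) z-values of the two directions are then compared with
#' a two-sample t-test. A non-significant result supports averaging the two
#' cross-validation steps.
#'
#' @param matrices_dir1,matrices_dir2 Lists of per-subject
#'   `confusion_matrix` objects (same subjects, same region).
#' @param var_equal Passed to [stats::t.test()] (default `TRUE`, the classic
#'   two-sample t).
#' @return List with `t`, `df`, `p`, the per-direction diagonal z-values, and
#'   `standardization = "per-subject z-score across the 9 cells"`.
#' @export
compare_directions <- function(matrices_dir1, matrices_dir2,
                               var_equal = TRUE) {
  if (length(matrices_dir1) != length(matrices_dir2))
    stop("compare_directions(): direction lists differ in length")
  if (length(matrices_dir1) < 3L)
    stop("compare_directions(): at least 3 subjects per direction required")
  diag_z <- function(cm) {
    r <- as.vector(confusion_rates(cm))
    z <- (r - mean(r)) / stats::sd(r)
    diag(matrix(z, nrow(cm), ncol(cm)))
  }
  z1 <- unlist(lapply(matrices_dir1, diag_z))
  z2 <- unlist(lapply(matrices_dir2, diag_z))
  tt <- stats::t.test(z1, z2, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, z_dir1 = z1, z_dir2 = z2,
       standardization = "per-subject z-score across the 9 cells")
}

new_anova_result <- function(effects, posthoc = NULL, note = NULL) {
  structure(list(effects = effects, posthoc = posthoc, note = note),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  print(x$effects, row.names = FALSE)
  if (!is.null(x$posthoc)) {
    cat("Post hoc (Tukey):\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' One-way ANOVA of per-level correct-prediction rates
#'
#' Tests whether the cross-decoding correct-prediction rate differs between
#' the three stickiness levels, pooling subjects and regions as observations,
#' followed by Tukey HSD pairwise comparisons.
#'
#' @param diagonals Data frame with columns `level` and `rate` (one row per
#'   subject x region x level observation); `subject`/`region` columns are
#'   allowed and ignored by the pooled model.
#' @return An `anova_result`; `effects` holds F, dfs and p for the level
#'   effect, `posthoc` the Tukey-adjusted pairwise comparisons.
#' @export
level_accuracy_anova <- function(diagonals) {
  stopifnot(all(c("level", "rate") %in% names(diagonals)))
  diagonals$level <- factor(diagonals$level)
  if (any(table(diagonals$level) < 2L))
    stop("level_accuracy_anova(): at least 2 observations per level required")
  fit <- stats::aov(rate ~ level, data = diagonals)
  sm <- summary(fit)[[1]]
  degenerate <- sm["Residuals", "Sum Sq"] < .Machine$double.eps^0.5
  eff <- data.frame(effect = "level",
                    F = sm["level", "F value"],
                    df_num = sm["level", "Df"],
                    df_den = sm["Residuals", "Df"],
                    p = sm["level", "Pr(>F)"])
  tk <- stats::TukeyHSD(fit)$level
  posthoc <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                        p_adjusted = tk[, "p adj"], row.names = NULL)
  new_anova_result(eff, posthoc,
                   note = if (degenerate) "degenerate: zero residual variance")
}

#' Two-way repeated-measures ANOVA of perceived-stickiness ratings
#'
#' Fully within-subject two-factor ANOVA (touch condition x intensity level),
#' each effect tested against its own subject-interaction error stratum; at
#' n = 18 subjects with 2 conditions and 4 levels the dfs are (1, 17),
#' (3, 51) and (3, 51). Tukey post hoc compares the two conditions within
#' each level on the condition-by-level cell means, using the studentized
#' range over all 8 cell means and the pooled within-subject error.
#'
#' @param ratings Data frame with columns `subject`, `condition`, `level`,
#'   `rating`; the subject x condition x level table must be complete.
#' @return An `anova_result`: `effects` has one row per effect (condition,
#'   level, condition:level) with F, dfs and p; `posthoc` one row per level
#'   with the condition difference and the Tukey-adjusted p.
#' @export
behavioral_rm_anova <- function(ratings) {
  stopifnot(all(c("subject", "condition", "level", "rating") %in%
                  names(ratings)))
  ratings$subject <- factor(ratings$subject)
  ratings$condition <- factor(ratings$condition)
  ratings$level <- factor(ratings$level)
  cells <- table(ratings$subject, ratings$condition, ratings$level)
  if (any(cells != 1L))
    stop("behavioral_rm_anova(): the subject x condition x level table must ",
         "be complete with one observation per cell")
  fit <- stats::aov(rating ~ condition * level +
                      Error(subject / (condition * level)), data = ratings)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tab <- sm[[paste0("Error: ", stratum)]][[1]]
    row <- trimws(rownames(tab)) == term
    err <- trimws(rownames(tab)) == "Residuals"
    data.frame(effect = term, F = tab[row, "F value"],
               df_num = tab[row, "Df"], df_den = tab[err, "Df"],
               p = tab[row, "Pr(>F)"], ss = tab[row, "Sum Sq"],
               ss_error = tab[err, "Sum Sq"])
  }
  effects <- rbind(pull("subject:condition", "condition"),
                   pull("subject:level", "level"),
                   pull("subject:condition:level", "condition:level"))
  ss_subject <- sm[["Error: subject"]][[1]]["Residuals", "Sum Sq"]
  ss_total <- sum((ratings$rating - mean(ratings$rating))^2)

  # Tukey on the 8 condition-by-level cell means; error pooled over the three
  # within-subject error strata.
  strata <- c("subject:condition", "subject:level", "subject:condition:level")
  ss <- df <- 0
  for (s in strata) {
    tab <- sm[[paste0("Error: ", s)]][[1]]
    err <- trimws(rownames(tab)) == "Residuals"
    ss <- ss + tab[err, "Sum Sq"]
    df <- df + tab[err, "Df"]
  }
  mse <- ss / df
  n_sub <- nlevels(ratings$subject)
  cell_means <- tapply(ratings$rating,
                       list(ratings$condition, ratings$level), mean)
  n_means <- length(cell_means)
  posthoc <- do.call(rbind, lapply(levels(ratings$level), function(lv) {
    dmean <- cell_means[1, lv] - cell_means[2, lv]
    q_obs <- abs(dmean) / sqrt(mse / n_sub)
    data.frame(level = lv,
               pair = paste(rownames(cell_means)[1], "-",
                            rownames(cell_means)[2]),
               diff = dmean,
               p_adjusted = stats::ptukey(q_obs, nmeans = n_means, df = df,
                                          lower.tail = FALSE))
  }))
  out <- new_anova_result(effects, posthoc,
                          note = paste0("Tukey over ", n_means,
                                        " cell means, pooled error df = ", df))
  out$ss_subject <- ss_subject
  out$ss_total <- ss_total
  out
}
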