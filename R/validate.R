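#' Concurrent-validity analysis of image vs force-plate parameters
#'
#' Runs the full validity workflow per stance condition:
#' \enumerate{
#'   \item group comparisons (atypical vs control) of every image
#'     parameter with the Mann-Whitney U test;
#'   \item normality screening of every parameter, with natural-log
#'     transformation of non-normal variables before the parametric
#'     steps;
#'   \item the full image-by-plate Pearson correlation matrix with
#'     strength labels, pooled across groups and (when both groups are
#'     present) within the atypical group alone, since pooling two
#'     groups with different sway magnitudes can inflate correlations;
#'   \item for each force-plate outcome, predictor selection
#'     (`|r| > 0.25`, `p < 0.05`, pairwise collinearity `<= 0.80`) and
#'     an Enter-method regression with Cohen effect-size labelling.
#' }
#'
#' @param image_params Data frame of image parameters, one row per
#'   trial, with key columns `subject_id`, `group`, `condition` and the
#'   nine `Vmean_COMx` ... `Ctotal_COMr` columns.
#' @param cop_params Same, with `Vmean_COPx` ... `Ctotal_COPr`.
#' @param transform Apply the normality-gated log transform before the
#'   correlation/regression steps (default `TRUE`).
#' @param group_levels The two group labels, atypical first (default
#'   `c("cp", "control")`).
#' @return An object of class `validation_report`: a list with
#'   `group_tests`, `correlations`, `models` (data frame summary),
#'   `model_fits` (the `enter_regression` objects), `transforms` and
#'   `selection_log`.
#' @export
run_validation <- function(image_params, cop_params, transform = TRUE,
                           group_levels = c("cp", "control")) {
  com_cols <- sway_columns("COM")
  cop_cols <- sway_columns("COP")
  keys <- c("subject_id", "condition")
  for (k in c(keys, com_cols)) {
    if (!k %in% names(image_params)) {
      stop(sprintf("image table is missing column `%s`", k), call. = FALSE)
    }
  }
  for (k in c(keys, cop_cols)) {
    if (!k %in% names(cop_params)) {
      stop(sprintf("COP table is missing column `%s`", k), call. = FALSE)
    }
  }
  ik <- paste(image_params$subject_id, image_params$condition)
  ck <- paste(cop_params$subject_id, cop_params$condition)
  if (!setequal(ik, ck) || anyDuplicated(ik) || anyDuplicated(ck)) {
    missing_in_cop <- setdiff(ik, ck)
    missing_in_img <- setdiff(ck, ik)
    stop(sprintf(
      "image and COP tables do not match 1:1 on subject x condition%s%s",
      if (length(missing_in_cop)) paste0("; missing from COP table: ",
        paste(utils::head(missing_in_cop, 5), collapse = ", ")) else "",
      if (length(missing_in_img)) paste0("; missing from image table: ",
        paste(utils::head(missing_in_img, 5), collapse = ", ")) else ""),
      call. = FALSE)
  }
  grp <- if ("group" %in% names(image_params)) image_params$group else NULL
  merged <- merge(image_params, cop_params[, c(keys, cop_cols)], by = keys)
  conds <- unique(merged$condition)
  group_tests <- list(); correlations <- list(); models <- list()
  transforms <- list(); fits <- list(); sel_log <- character(0)

  maybe_transform <- function(v) {
    # constant or tiny columns pass through untransformed
    rep_ <- tryCatch(assess_normality(v), error = function(e) NULL)
    if (is.null(rep_) || !transform) {
      return(list(values = v, transformed = FALSE, offset = 0,
                  shapiro_p = if (is.null(rep_)) NA_real_ else rep_$shapiro_p))
    }
    tr <- log_transform_if_needed(v, rep_)
    tr$shapiro_p <- rep_$shapiro_p
    tr
  }

  for (cond in conds) {
    sub <- merged[merged$condition == cond, , drop = FALSE]
    # (1) group comparisons of image parameters
    if (!is.null(grp) && all(group_levels %in% sub$group)) {
      for (col in com_cols) {
        a <- sub[[col]][sub$group == group_levels[1]]
        b <- sub[[col]][sub$group == group_levels[2]]
        mw <- mann_whitney_u(a, b)
        group_tests[[length(group_tests) + 1L]] <- data.frame(
          condition = cond, parameter = col,
          u_statistic = mw$u_statistic, p_value = mw$p_value,
          method = mw$method,
          median_cp = mw$median_a, iqr_cp = mw$iqr_a,
          median_control = mw$median_b, iqr_control = mw$iqr_b,
          stringsAsFactors = FALSE)
      }
    }
    # (2) normality-gated transform of all analysis columns
    tsub <- sub
    for (col in c(com_cols, cop_cols)) {
      tr <- maybe_transform(sub[[col]])
      tsub[[col]] <- tr$values
      transforms[[length(transforms) + 1L]] <- data.frame(
        condition = cond, parameter = col, shapiro_p = tr$shapiro_p,
        transformed = tr$transformed, offset = tr$offset,
        stringsAsFactors = FALSE)
    }
    # (3) correlation matrix, pooled and atypical-group-only
    scopes <- list(pooled = tsub)
    if (!is.null(grp) && all(group_levels %in% sub$group)) {
      scopes[[group_levels[1]]] <- tsub[tsub$group == group_levels[1], , drop = FALSE]
    }
    for (scope in names(scopes)) {
      dat <- scopes[[scope]]
      for (icol in com_cols) for (ccol in cop_cols) {
        pc <- tryCatch(pearson_correlation(dat[[icol]], dat[[ccol]]),
                       error = function(e) NULL)
        if (is.null(pc)) next
        correlations[[length(correlations) + 1L]] <- data.frame(
          condition = cond, scope = scope,
          image_parameter = icol, cop_parameter = ccol,
          r = pc$r, p_value = pc$p_value, n = pc$n,
          strength = pc$strength_label, stringsAsFactors = FALSE)
      }
    }
    # (4) predictor selection + Enter regression per plate outcome
    ic_mat <- suppressWarnings(stats::cor(tsub[, com_cols]))
    for (ccol in cop_cols) {
      cand <- do.call(rbind, lapply(com_cols, function(icol) {
        pc <- tryCatch(pearson_correlation(tsub[[icol]], tsub[[ccol]]),
                       error = function(e) NULL)
        if (is.null(pc)) return(NULL)
        data.frame(parameter = icol, r = pc$r, p = pc$p_value,
                   stringsAsFactors = FALSE)
      }))
      if (is.null(cand) || !nrow(cand)) next
      sel <- select_predictors(cand, ic_mat)
      sel_log <- c(sel_log, sprintf("[%s / %s] %s", cond, ccol, attr(sel, "log")))
      if (!length(sel)) {
        models[[length(models) + 1L]] <- data.frame(
          condition = cond, outcome = ccol, predictors = "",
          n_predictors = 0L, r_squared = NA_real_,
          adjusted_r_squared = NA_real_, f_p_value = NA_real_,
          effect_size = NA_character_, stringsAsFactors = FALSE)
        next
      }
      fit <- fit_linear_regression_enter(tsub, ccol, sel)
      fits[[paste(cond, ccol, sep = "/")]] <- fit
      models[[length(models) + 1L]] <- data.frame(
        condition = cond, outcome = ccol,
        predictors = paste(sel, collapse = "+"),
        n_predictors = length(sel), r_squared = fit$r_squared,
        adjusted_r_squared = fit$adjusted_r_squared,
        f_p_value = fit$f_p_value, effect_size = fit$effect_size_label,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(
    group_tests = if (length(group_tests)) do.call(rbind, group_tests) else data.frame(),
    correlations = do.call(rbind, correlations),
    models = if (length(models)) do.call(rbind, models) else data.frame(),
    model_fits = fits,
    transforms = do.call(rbind, transforms),
    selection_log = sel_log,
    conditions = conds
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  conditions: %s\n", paste(x$conditions, collapse = ", ")))
  cat(sprintf("  %d group tests, %d correlations, %d regression models\n",
              nrow(x$group_tests), nrow(x$correlations), nrow(x$models)))
  if (nrow(x$models)) {
    ok <- !is.na(x$models$r_squared)
    if (any(ok)) {
      best <- x$models[ok, ][which.max(x$models$r_squared[ok]), ]
      cat(sprintf("  best model: %s ~ %s (R2=%.3f, %s) in %s\n",
                  best$outcome, best$predictors, best$r_squared,
                  best$effect_size, best$condition))
    }
  }
  invisible(x)
}

#' Write a validation report to disk
#'
#' Emits `group_tests.csv`, `correlations.csv`, `models.csv`,
#' `transforms.csv` and a human-readable `summary.txt` into `dir`.
#'
#' @param report A [run_validation()] result.
#' @param dir Output directory (created if absent).
#' @export
write_validation_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$group_tests, file.path(dir, "group_tests.csv"), row.names = FALSE)
  write.csv(report$correlations, file.path(dir, "correlations.csv"), row.names = FALSE)
  write.csv(report$models, file.path(dir, "models.csv"), row.names = FALSE)
  write.csv(report$transforms, file.path(dir, "transforms.csv"), row.names = FALSE)
  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  writeLines("Concurrent validity of video-derived sway parameters vs force plate", con)
  writeLines(strrep("=", 68), con)
  for (cond in report$conditions) {
    writeLines(sprintf("\nCondition %s", cond), con)
    m <- report$models[report$models$condition == cond & !is.na(report$models$r_squared), ]
    if (nrow(m)) {
      for (i in seq_len(nrow(m))) {
        writeLines(sprintf("  %-12s ~ %-40s R2=%.3f (%s)",
                           m$outcome[i], m$predictors[i], m$r_squared[i],
                           m$effect_size[i]), con)
      }
    } else {
      writeLines("  no predictor survived selection for any outcome", con)
    }
    cr <- report$correlations
    cr <- cr[cr$condition == cond & cr$scope == "pooled", ]
    if (nrow(cr)) {
      top <- cr[which.max(abs(cr$r)), ]
      writeLines(sprintf("  strongest pooled correlation: %s vs %s, r=%.3f (%s)",
                         top$image_parameter, top$cop_parameter, top$r,
                         top$strength), con)
    }
  }
  if (length(report$selection_log)) {
    writeLines("\nPredictor-selection log", con)
    writeLines(paste0("  ", report$selection_log), con)
  }
  invisible(dir)
}
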