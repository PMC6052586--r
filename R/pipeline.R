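# End-to-end analyses: clinical-analog outcome table and the full Monte
# Carlo report comparing the two lens groups under both formulas.

#' Clinical-analog refractive outcome report
#'
#' For each formula and each lens group: predicted refraction at the
#' implanted power, signed prediction errors (observed postoperative SE
#' minus prediction), their [summarize_errors()] summary, and the two-group
#' comparisons — Mann-Whitney on the absolute errors, Student's t on the
#' absolute errors, and chi-square on the within-threshold split.
#'
#' @param cohort Cohort data.frame (see [read_cohort()] for the schema).
#' @param lenses Named list of [iol_lens()] objects covering every
#'   `lens_name` in the cohort.
#' @param formulas Character vector of formulas to evaluate.
#' @param chi_threshold Threshold (D) whose within/without split is compared
#'   by chi-square (default 0.50).
#' @inheritParams predict_refraction
#' @param thresholds Thresholds for the error summaries.
#' @return An object of class `iol_clinical_report`: per formula, a list
#'   with per-group `iol_error_summary` objects and the comparison tests.
#' @export
run_clinical_analog <- function(cohort, lenses = default_lens_registry(),
                                formulas = c("haigis", "srkt"),
                                thresholds = c(0.25, 0.50, 0.75, 1.00),
                                chi_threshold = 0.50, vertex = 12,
                                corneal_index = 1.3315) {
  check_cohort_table(cohort)
  lens_by_name <- stats::setNames(lenses,
                                  vapply(lenses, `[[`, character(1), "name"))
  groups <- sort(unique(cohort$lens_name))
  miss <- setdiff(groups, names(lens_by_name))
  if (length(miss))
    stop("no lens model registered for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  res <- lapply(formulas, function(f) {
    f <- match_formula(f)
    per_group <- lapply(groups, function(g) {
      sub <- cohort[cohort$lens_name == g, , drop = FALSE]
      pred <- predict_refraction(f, sub, lens_by_name[[g]],
                                 sub$implanted_power_D, vertex = vertex,
                                 corneal_index = corneal_index)
      summarize_errors(prediction_error(sub$postop_se_D, pred), thresholds)
    })
    names(per_group) <- groups
    comparisons <- NULL
    if (length(groups) == 2L) {
      e1 <- abs(per_group[[1]]$errors); e2 <- abs(per_group[[2]]$errors)
      degenerate <- stats::var(c(e1, e2)) == 0
      tl <- sprintf("%.2f", chi_threshold)
      a <- per_group[[1]]$counts_within[[tl]]
      c_ <- per_group[[2]]$counts_within[[tl]]
      comparisons <- list(
        degenerate = degenerate,
        mann_whitney_abs = if (!degenerate) mann_whitney(e1, e2),
        t_abs = if (!degenerate) student_t(e1, e2),
        chi_square_within = if (!degenerate)
          chi_square_2x2(a, length(e1) - a, c_, length(e2) - c_),
        chi_threshold = chi_threshold)
    }
    list(groups = per_group, comparisons = comparisons)
  })
  names(res) <- vapply(formulas, match_formula, character(1))
  structure(list(formulas = res, groups = groups, n_eyes = nrow(cohort)),
            class = "iol_clinical_report")
}

#' @export
print.iol_clinical_report <- function(x, ...) {
  cat(sprintf("Clinical-analog refractive outcomes (%d eyes)\n", x$n_eyes))
  for (f in names(x$formulas)) {
    cat(sprintf("\n%s formula\n", toupper(f)))
    fr <- x$formulas[[f]]
    for (g in names(fr$groups)) {
      s <- fr$groups[[g]]
      cat(sprintf(
        "  %-12s MedAE %.2f (IQR %.2f: %.2f)  MAE %.2f (%.2f)  within ±0.50 D: %.1f%%\n",
        g, s$medae, s$iqr[1], s$iqr[2], s$mae, stats::sd(abs(s$errors)),
        s$pct_within[["0.50"]]))
    }
    cmp <- fr$comparisons
    if (!is.null(cmp)) {
      if (isTRUE(cmp$degenerate)) {
        cat("  comparisons degenerate (no error variance)\n")
      } else {
        cat(sprintf(
          "  Mann-Whitney p = %.3f   t-test p = %.3f   chi-square (±%.2f D) p = %.3f\n",
          cmp$mann_whitney_abs$p, cmp$t_abs$p, cmp$chi_threshold,
          cmp$chi_square_within$p))
      }
    }
  }
  invisible(x)
}

#' Full Monte Carlo tolerance report for a paired-lens cohort
#'
#' Runs [run_mc_study()] for every formula and both lens groups (each group
#' at its own manufacturing tolerance SD), then compares the groups within
#' each replicate: Mann-Whitney on absolute errors and chi-square on the
#' within-`chi_threshold` split.
#'
#' @inheritParams run_clinical_analog
#' @param n_replicates Replicates per study (default 10).
#' @param seed Integer study seed; each formula-group study derives its own
#'   substream.
#' @param chi_threshold Threshold compared by chi-square (default 0.25 D,
#'   the scale on which simulated errors live).
#' @return An object of class `iol_mc_report`: `studies` (nested by formula
#'   then group, each an `iol_mc_study`), `comparisons` (data.frame with one
#'   row per formula x replicate: Mann-Whitney and chi-square p-values), and
#'   the run parameters.
#' @export
run_mc_report <- function(cohort, lenses = default_lens_registry(),
                          formulas = c("haigis", "srkt"), n_replicates = 10,
                          seed = 1, thresholds = c(0.25, 0.50, 0.75, 1.00),
                          chi_threshold = 0.25, vertex = 12,
                          corneal_index = 1.3315) {
  check_cohort_table(cohort)
  lens_by_name <- stats::setNames(lenses,
                                  vapply(lenses, `[[`, character(1), "name"))
  groups <- sort(unique(cohort$lens_name))
  stopifnot(length(groups) == 2L)
  formulas <- vapply(formulas, match_formula, character(1))
  studies <- list()
  cmp_rows <- list()
  tl <- sprintf("%.2f", chi_threshold)
  for (fi in seq_along(formulas)) {
    f <- formulas[fi]
    studies[[f]] <- list()
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      sub <- cohort[cohort$lens_name == g, , drop = FALSE]
      studies[[f]][[g]] <- run_mc_study(
        f, sub, lens_by_name[[g]], n_replicates = n_replicates,
        seed = seed + 101L * fi + 11L * gi, thresholds = thresholds,
        vertex = vertex, corneal_index = corneal_index)
    }
    s1 <- studies[[f]][[groups[1]]]; s2 <- studies[[f]][[groups[2]]]
    for (r in seq_len(n_replicates)) {
      e1 <- abs(s1$errors[, r]); e2 <- abs(s2$errors[, r])
      degenerate <- stats::var(c(e1, e2)) == 0
      a <- s1$replicates[[paste0("n_within_", tl)]][r]
      c_ <- s2$replicates[[paste0("n_within_", tl)]][r]
      cmp_rows[[length(cmp_rows) + 1L]] <- data.frame(
        formula = f, replicate = r, degenerate = degenerate,
        mw_p = if (degenerate) NA_real_ else mann_whitney(e1, e2)$p,
        chisq_p = if (degenerate) NA_real_ else
          chi_square_2x2(a, length(e1) - a, c_, length(e2) - c_)$p)
    }
  }
  comparisons <- do.call(rbind, cmp_rows)
  rownames(comparisons) <- NULL
  structure(
    list(studies = studies, comparisons = comparisons, groups = groups,
         formulas = formulas, n_replicates = n_replicates, seed = seed,
         chi_threshold = chi_threshold),
    class = "iol_mc_report")
}

#' @export
print.iol_mc_report <- function(x, ...) {
  cat(sprintf("Monte Carlo tolerance report (seed %d, %d replicates)\n",
              x$seed, x$n_replicates))
  for (f in x$formulas) {
    cat(sprintf("\n%s formula\n", toupper(f)))
    for (g in x$groups) {
      st <- x$studies[[f]][[g]]
      m <- st$aggregate$medae
      p <- st$aggregate$pct_within[["0.25"]]
      cat(sprintf(
        "  %-12s (SD %.2f D): MedAE %.2f D [%.2f - %.2f], within ±0.25 D %.1f - %.1f%%\n",
        g, st$tolerance_sd, m["median"], m["min"], m["max"],
        p["min"], p["max"]))
    }
    cp <- x$comparisons[x$comparisons$formula == f & !x$comparisons$degenerate, ]
    if (nrow(cp))
      cat(sprintf(
        "  replicates with both comparison p < 0.001: %d of %d\n",
        sum(cp$mw_p < 0.001 & cp$chisq_p < 0.001), x$n_replicates))
  }
  invisible(x)
}

#' Persist a Monte Carlo report
#'
#' Writes a tidy CSV (one row per formula x group x replicate) and a JSON
#' aggregate block (grand medians, ranges, pooled percentages, seed).
#'
#' @param report An `iol_mc_report`.
#' @param csv_path,json_path Output file paths (either may be `NULL` to
#'   skip).
#' @param overwrite Refuse to clobber existing files unless `TRUE`.
#' @return Invisibly, the tidy data.frame written to `csv_path`.
#' @export
write_mc_report <- function(report, csv_path = NULL, json_path = NULL,
                            overwrite = FALSE) {
  stopifnot(inherits(report, "iol_mc_report"))
  rows <- list()
  for (f in report$formulas)
    for (g in report$groups) {
      st <- report$studies[[f]][[g]]
      df <- st$replicates
      df <- cbind(formula = f, group = g, tolerance_sd = st$tolerance_sd,
                  seed = st$seed, df)
      rows[[length(rows) + 1L]] <- df
    }
  tidy <- do.call(rbind, rows)
  rownames(tidy) <- NULL
  if (!is.null(csv_path)) {
    if (file.exists(csv_path) && !overwrite)
      stop("'", csv_path, "' exists; pass overwrite = TRUE", call. = FALSE)
    utils::write.csv(tidy, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    if (file.exists(json_path) && !overwrite)
      stop("'", json_path, "' exists; pass overwrite = TRUE", call. = FALSE)
    agg <- lapply(report$studies, function(by_group)
      lapply(by_group, function(st)
        list(tolerance_sd = st$tolerance_sd, seed = st$seed,
             medae = as.list(st$aggregate$medae),
             pct_within = lapply(st$aggregate$pct_within, as.list))))
    jsonlite::write_json(list(seed = report$seed, aggregate = agg),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(tidy)
}
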