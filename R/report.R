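#' Build the cohort statistical report
#'
#' Produces the three report tables of a pre/post multi-arm indentation
#' study:
#' \describe{
#'   \item{paired}{per arm and measure: pre/post mean, SE and SD, and the
#'     paired t-test (thickness in mm, moduli in kPa).}
#'   \item{ratios}{per measure: arm means of the post/pre percentage
#'     ratios with SE and SD, the one-way between-subjects ANOVA across
#'     arms, and Fisher LSD pairwise p-values.}
#'   \item{correlations}{per arm: Pearson correlations among the
#'     thickness and E1/E2/E3 percentage ratios.}
#' }
#' Significance stars follow the conventional notation: `*` p < 0.05,
#' `**` p < 0.01. Both SE and SD are reported.
#'
#' @param records data frame of per-subject results with columns
#'   `subject_id`, `group`, and `<measure>_pre` / `<measure>_post` for each
#'   of `thickness`, `E1`, `E2`, `E3`.
#' @return an object of class `cohort_report`: list of data frames
#'   `paired`, `ratios` (NULL for a single-arm design), `correlations`,
#'   plus the `records` with ratio columns appended.
#' @export
build_report <- function(records) {
  measures <- c("thickness", "E1", "E2", "E3")
  need <- c(paste0(measures, "_pre"), paste0(measures, "_post"))
  if (!all(need %in% names(records)))
    stop("records must contain *_pre and *_post columns for ",
         paste(measures, collapse = ", "), call. = FALSE)
  groups <- sort(unique(records$group))
  if (any(table(records$group) < 2))
    stop("every arm needs at least 2 subjects", call. = FALSE)

  for (m in measures)
    records[[paste0(m, "_ratio")]] <- ratio_percent(
      stats::setNames(records[[paste0(m, "_pre")]],
                      rep(m, nrow(records))),
      stats::setNames(records[[paste0(m, "_post")]],
                      rep(m, nrow(records))))

  se <- function(x) stats::sd(x) / sqrt(length(x))

  paired <- do.call(rbind, lapply(groups, function(gr) {
    sub <- records[records$group == gr, ]
    do.call(rbind, lapply(measures, function(m) {
      pre <- sub[[paste0(m, "_pre")]]
      post <- sub[[paste0(m, "_post")]]
      pt <- paired_test(pre, post)
      data.frame(group = gr, measure = m, n = length(pre),
                 pre_mean = mean(pre), pre_se = se(pre),
                 pre_sd = stats::sd(pre),
                 post_mean = mean(post), post_se = se(post),
                 post_sd = stats::sd(post),
                 t = pt$t, df = pt$df, p = pt$p, sig = p_stars(pt$p))
    }))
  }))

  ratios <- NULL
  if (length(groups) >= 2) {
    ratios <- do.call(rbind, lapply(measures, function(m) {
      by_g <- lapply(groups, function(gr) {
        x <- records[[paste0(m, "_ratio")]][records$group == gr]
        x[!is.na(x)]
      })
      names(by_g) <- as.character(groups)
      av <- oneway_anova_lsd(by_g)
      row <- data.frame(measure = m)
      for (gi in seq_along(groups)) {
        gn <- as.character(groups[gi])
        row[[paste0("mean_", gn)]] <- mean(by_g[[gi]])
        row[[paste0("se_", gn)]] <- se(by_g[[gi]])
        row[[paste0("sd_", gn)]] <- stats::sd(by_g[[gi]])
      }
      row$anova_F <- av$F
      row$anova_p <- av$p
      row$anova_sig <- p_stars(av$p)
      for (k in seq_len(nrow(av$lsd))) {
        pair <- paste0("lsd_", av$lsd$group1[k], "_vs_", av$lsd$group2[k])
        row[[paste0(pair, "_p")]] <- av$lsd$p[k]
        row[[paste0(pair, "_sig")]] <- p_stars(av$lsd$p[k])
      }
      row
    }))
  } else {
    message("single-arm design: ANOVA/LSD table skipped")
  }

  correlations <- do.call(rbind, lapply(groups, function(gr) {
    sub <- records[records$group == gr, paste0(measures, "_ratio")]
    names(sub) <- measures
    pm <- tryCatch(pearson_matrix(sub), error = function(e) {
      message("arm ", gr, ": correlations skipped (", conditionMessage(e), ")")
      nas <- matrix(NA_real_, length(measures), length(measures),
                    dimnames = list(measures, measures))
      list(r = nas, p = nas)
    })
    cmb <- utils::combn(measures, 2)
    do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
      i <- cmb[1, k]; j <- cmb[2, k]
      data.frame(group = gr, pair = paste(i, "&", j),
                 r = pm$r[i, j], p = pm$p[i, j],
                 sig = p_stars(pm$p[i, j]))
    }))
  }))

  structure(list(paired = paired, ratios = ratios,
                 correlations = correlations, records = records),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, digits = 3, ...) {
  cat("== Paired pre/post comparisons (per arm) ==\n")
  print(format(x$paired, digits = digits), row.names = FALSE)
  if (!is.null(x$ratios)) {
    cat("\n== Post/pre percentage ratios: ANOVA across arms + Fisher LSD ==\n")
    print(format(x$ratios, digits = digits), row.names = FALSE)
  }
  cat("\n== Pearson correlations among ratios (per arm) ==\n")
  print(format(x$correlations, digits = digits), row.names = FALSE)
  cat("\nSignificance: * p < 0.05, ** p < 0.01\n")
  invisible(x)
}

## deterministic table serialization: fixed 10-significant-digit formatting
format_table_fixed <- function(df) {
  out <- df
  for (nm in names(out))
    if (is.numeric(out[[nm]]))
      out[[nm]] <- formatC(out[[nm]], digits = 10, format = "g")
  out
}

#' Write a cohort report as delimited-text tables
#'
#' Writes `paired.csv`, `ratios.csv`, `correlations.csv` and `subjects.csv`
#' into `dir` with deterministic formatting (byte-identical for identical
#' inputs).
#'
#' @param report a `cohort_report`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  tabs <- list(paired = report$paired, ratios = report$ratios,
               correlations = report$correlations,
               subjects = report$records)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) next
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(format_table_fixed(tabs[[nm]]), p, row.names = FALSE,
                     quote = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
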