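#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Sorts the raw p values ascending, sets adjusted p_(i) =
#' 1 - (1 - p_(i))^(m - i + 1), enforces the running maximum along the
#' step-down order, clips to 1, and restores the original order. Adjusted
#' values are always >= raw values.
#'
#' @param raw_p numeric vector of p values in (0, 1].
#' @return list with `raw`, `adjusted`, `order` (the ascending permutation
#'   used).
#' @examples
#' holm_sidak(c(0.01, 0.04))$adjusted  # 0.0199, 0.04
#' @export
holm_sidak <- function(raw_p) {
  stopifnot(is.numeric(raw_p), length(raw_p) >= 1,
            all(raw_p > 0 & raw_p <= 1))
  m <- length(raw_p)
  ord <- order(raw_p)
  ps <- raw_p[ord]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[ord] <- adj
  list(raw = raw_p, adjusted = out, order = ord)
}

#' One-way ANOVA with Tukey pairwise comparisons
#'
#' Standard one-way F test across the groups followed by Tukey's honest
#' significant difference for all pairs (studentized range), via
#' [stats::aov()] and [stats::TukeyHSD()]. Groups are treated as
#' independent samples.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values).
#' @return list with `F`, `p`, `df`, and `pairwise` (data frame:
#'   `group1`, `group2`, `diff`, `p_adj`).
#' @export
anova_tukey <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes < 2))
    stop(sprintf("group '%s' has fewer than 2 values",
                 names(groups)[which(sizes < 2)[1]]))
  d <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes), levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = d)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  pairwise <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                         diff = tk[, "diff"], p_adj = tk[, "p adj"],
                         row.names = NULL)
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       df = c(an[["Df"]][1], an[["Df"]][2]), pairwise = pairwise)
}

#' Cross-modality lesion comparison report
#'
#' Assembles per-subject lesion severity and volume for the three
#' modalities (FDG, early-phase and late-phase dynamic tracer), runs the
#' one-way ANOVA + Tukey comparison for each metric, and computes the
#' pairwise Pearson correlations of the dynamic-tracer metrics against
#' FDG. With a single subject the ANOVA/correlations are flagged
#' unavailable and only the means are reported.
#'
#' @param metrics data frame with columns `subject`, `modality` (values
#'   `fdg`, `early`, `late`) and the metric columns `severity_pct`,
#'   `volume_mL`.
#' @return A `modality_comparison`: list with `table` (input reshaped wide),
#'   `anova` (per metric), `correlations` (per metric and modality pair),
#'   `means` (per modality and metric).
#' @export
fig_report <- function(metrics) {
  stopifnot(all(c("subject", "modality", "severity_pct", "volume_mL") %in%
                  names(metrics)),
            all(metrics$modality %in% c("fdg", "early", "late")))
  mods <- c("fdg", "early", "late")
  means <- stats::aggregate(cbind(severity_pct, volume_mL) ~ modality,
                            data = metrics, FUN = mean)
  n_sub <- length(unique(metrics$subject))
  anova <- correlations <- NULL
  if (n_sub >= 2) {
    anova <- lapply(c(severity_pct = "severity_pct", volume_mL = "volume_mL"),
                    function(col) {
      groups <- lapply(mods, function(m)
        metrics[[col]][metrics$modality == m])
      names(groups) <- mods
      anova_tukey(groups)
    })
    wide <- stats::reshape(
      metrics[c("subject", "modality", "severity_pct", "volume_mL")],
      direction = "wide", idvar = "subject", timevar = "modality")
    cor_rows <- list()
    for (col in c("severity_pct", "volume_mL")) {
      for (m in c("early", "late")) {
        x <- wide[[paste(col, "fdg", sep = ".")]]
        y <- wide[[paste(col, m, sep = ".")]]
        ct <- tryCatch(pearson_r_p(x, y),
                       error = function(e) list(r = NA_real_, p = NA_real_,
                                                n = sum(is.finite(x + y))))
        cor_rows[[length(cor_rows) + 1L]] <-
          data.frame(metric = col, pair = paste0("fdg_vs_", m),
                     r = ct$r, p = ct$p, n = ct$n)
      }
    }
    correlations <- do.call(rbind, cor_rows)
  }
  structure(list(table = metrics, means = means, anova = anova,
                 correlations = correlations, n_subjects = n_sub),
            class = "modality_comparison")
}

#' @export
print.modality_comparison <- function(x, ...) {
  cat(sprintf("<modality_comparison> %d subjects\n", x$n_subjects))
  print(x$means)
  if (!is.null(x$anova)) {
    for (m in names(x$anova))
      cat(sprintf("  %s: F = %.3g, p = %.3g\n", m, x$anova[[m]]$F,
                  x$anova[[m]]$p))
  }
  if (!is.null(x$correlations)) print(x$correlations)
  invisible(x)
}

#' Write a modality-comparison report to CSV and markdown
#'
#' @param report a [fig_report()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "modality_comparison"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "lesion_metrics.csv")
  utils::write.csv(report$table, p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(report$correlations)) {
    p <- file.path(dir, "cross_modality_correlations.csv")
    utils::write.csv(report$correlations, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  md <- c("# Cross-modality lesion comparison", "",
          sprintf("Subjects: %d", report$n_subjects), "", "## Group means",
          utils::capture.output(print(report$means)))
  if (!is.null(report$anova)) {
    md <- c(md, "", "## One-way ANOVA + Tukey")
    for (m in names(report$anova)) {
      a <- report$anova[[m]]
      md <- c(md, sprintf("- %s: F(%d, %d) = %.3g, p = %.3g", m, a$df[1],
                          a$df[2], a$F, a$p),
              utils::capture.output(print(a$pairwise)))
    }
  }
  p <- file.path(dir, "report.md")
  writeLines(md, p)
  paths <- c(paths, p)
  invisible(paths)
}
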