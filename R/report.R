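signif_recursive <- function(x, digits = 4) {
  if (is.list(x)) return(lapply(x, signif_recursive, digits = digits))
  if (is.numeric(x)) return(signif(x, digits))
  x
}

summary_block <- function(s) {
  list(label = s$label, n = s$n,
       d_nm = as.list(s$d_nm), h_nm = as.list(s$h_nm),
       ar = as.list(s$ar), D_nm = as.list(s$D_nm),
       occupancy = if (is.finite(s$occupancy)) s$occupancy else NA)
}

#' Write an analysis report (JSON + text table, optional figures)
#'
#' Emits a machine-readable JSON report — population summaries, AR power-law
#' fits, the two-sample t-test, the capture model, and a provenance block
#' (seed, config hash, package version) — plus a human-readable table.
#' Sections without content are written as JSON `null`, never omitted, and
#' floats are rounded to 4 significant digits so regenerating from the same
#' inputs is byte-identical.
#'
#' @param summaries list of [summarize_population()] objects.
#' @param fits list of [fit_ar_model()] objects parallel to `summaries`, or
#'   NULL.
#' @param test an [student_t_test()] result or NULL.
#' @param capture an [apply_capture_filter()] result or NULL.
#' @param config configuration list to echo (hashed for provenance).
#' @param seed master seed to record.
#' @param out_json path of the JSON report.
#' @param out_table optional path of the text table.
#' @param plot_file optional path of a PDF with the AR-vs-d scatter plus
#'   fitted curves and per-population D histograms.
#' @param particles optional list of particle data.frames (per population)
#'   used only for the figures.
#' @return `out_json`, invisibly.
#' @export
make_report <- function(summaries, fits = NULL, test = NULL, capture = NULL,
                        config = NULL, seed = NA_integer_, out_json,
                        out_table = NULL, plot_file = NULL,
                        particles = NULL) {
  if (!length(summaries)) stop("at least one population summary is required")
  report <- list(
    populations = lapply(summaries, summary_block),
    ar_fits = if (is.null(fits) || !length(fits)) NA else
      lapply(fits, function(f)
        list(c_nm3 = f$c, intercept = f$intercept, n_points = f$n_points,
             rms_residual = f$rms_residual)),
    t_test = if (is.null(test)) NA else
      list(t_statistic = test$t_statistic,
           degrees_of_freedom = test$degrees_of_freedom,
           p_two_sided = test$p_two_sided, alpha = test$alpha,
           significant = test$significant),
    capture_model = if (is.null(capture)) NA else
      list(critical_diameter_nm = capture$model$critical_diameter_nm,
           n_total = capture$n_total, n_captured = capture$n_captured,
           mean_D_before_nm = capture$mean_before,
           mean_D_after_nm = capture$mean_after),
    provenance = list(seed = seed,
                      config_hash = object_hash(config),
                      package = "evnanoarray",
                      version = as.character(packageVersion("evnanoarray"))))
  report <- signif_recursive(report, 4)
  jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)

  if (!is.null(out_table)) {
    txt <- character(0)
    for (i in seq_along(summaries)) {
      txt <- c(txt, utils::capture.output(print(summaries[[i]])))
      if (!is.null(fits) && length(fits) >= i && !is.null(fits[[i]]))
        txt <- c(txt, utils::capture.output(print(fits[[i]])))
      txt <- c(txt, "")
    }
    if (!is.null(test)) txt <- c(txt, utils::capture.output(print(test)))
    if (!is.null(capture)) txt <- c(txt, utils::capture.output(print(capture)))
    writeLines(txt, out_table)
  }

  if (!is.null(plot_file)) {
    pdf(plot_file, width = 7, height = 5)
    on.exit(dev.off(), add = TRUE)
    if (!is.null(fits) && length(fits)) {
      for (i in seq_along(fits)) {
        p <- if (!is.null(particles) && length(particles) >= i)
          particles[[i]] else NULL
        plot(fits[[i]], particles = p,
             main = paste0("AR ~ c d^-3: ", summaries[[i]]$label))
      }
    }
    if (!is.null(particles)) {
      for (i in seq_along(particles)) {
        pp <- particles[[i]]
        pp <- pp[pp$klass == "EV" & is.finite(pp$D_nm), , drop = FALSE]
        if (nrow(pp))
          hist(pp$D_nm, breaks = 20, xlab = "suspension diameter D (nm)",
               main = paste0("D distribution: ", summaries[[i]]$label))
      }
    }
  }
  invisible(out_json)
}
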