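## Markdown report over a pipeline bundle: one section per analysis block,
## every number traceable to a TSV written by runPipeline().

.mdTable <- function(df, digits = 4) {
  num <- vapply(df, is.numeric, NA)
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1L, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  c(hdr, sep, rows)
}

#' Render a pipeline bundle as a markdown report
#'
#' One section per analysis block: read filtering (the stacked-bar
#' breakdown as a table), coverage and saturation, background error rates,
#' the contamination comparison, sensitivity by expected-MAF bin, and
#' concordance classes. Errors listing the missing artifacts when the
#' bundle lacks the sections its stages should have produced.
#'
#' @param bundle result of [runPipeline()].
#' @param path optional file to write the markdown to.
#' @return Character vector of markdown lines, invisibly when \code{path}
#'   is given.
#' @export
renderReport <- function(bundle, path = NULL) {
  stages <- bundle$stages
  if (is.null(stages)) stop("incomplete bundle: missing 'stages'")
  need <- c(metrics = "metrics", background = "background",
            contamination = "contamination", sensitivity = "sensitivity",
            concordance = "concordance")
  expected <- intersect(unname(need), stages)
  missing <- expected[!vapply(expected,
                              function(e) !is.null(bundle[[e]]), NA)]
  if (length(missing))
    stop("incomplete bundle: missing artifact(s): ",
         paste(missing, collapse = ", "))
  md <- c("# Pooled-capture sequencing performance report", "")
  md <- c(md, sprintf("Master seed: %s; target span: %d bp; %d samples.",
                      format(bundle$config$seed),
                      as.integer(targetSpan(bundle$truth$regions)),
                      length(bundle$config$masses)), "")
  if (!is.null(bundle$metrics)) {
    md <- c(md, "## Read filtering", "",
            .mdTable(bundle$metrics$breakdown[, c(
              "sample", "input_mass_ng", "total",
              paste0("rate_", .FILTER_CATS))]), "",
            "## Coverage", "", .mdTable(bundle$metrics$coverage), "",
            "## Saturation (mean pass-filter depth vs total reads)", "",
            .mdTable(bundle$metrics$saturation), "")
  }
  if (!is.null(bundle$background)) {
    md <- c(md, "## Background error rates", "",
            .mdTable(bundle$background$summary), "")
  }
  if (!is.null(bundle$contamination)) {
    rep_ <- bundle$contamination$report
    md <- c(md, "## Cross-contamination", "",
            .mdTable(rep_@perSample), "",
            sprintf(paste0("Test-group means: single %.4g, multi %.4g; ",
                           "control-group means: single %.4g, multi %.4g."),
                    rep_@testMeans[["single"]], rep_@testMeans[["multi"]],
                    rep_@controlMeans[["single"]],
                    rep_@controlMeans[["multi"]]),
            sprintf("Contamination estimate: %.4g (injected %.4g).",
                    contaminationEstimate(rep_),
                    bundle$contamination$injected), "")
  }
  if (!is.null(bundle$sensitivity)) {
    md <- c(md, "## Detection sensitivity by expected MAF", "",
            .mdTable(bundle$sensitivity$table), "")
  }
  if (!is.null(bundle$concordance)) {
    cls <- concordanceClasses(bundle$concordance)
    md <- c(md, "## Multi-library concordance", "",
            .mdTable(data.frame(class = names(cls),
                                variants = as.numeric(cls))), "")
  }
  if (!is.null(path)) {
    writeLines(md, path)
    return(invisible(md))
  }
  md
}
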