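#' Per-sample methylation event totals
#'
#' Multiplies each observed code count by the event weights of that
#' code and sums events of the same kind: the total number of DM, DNM,
#' MSP and NMSP events (and their CG/CHG splits) implied by all
#' explanations of all scored markers of a sample. The sum
#' DM + DNM + MSP + NMSP is the per-sample denominator used to
#' normalise the characteristics.
#'
#' @param counts An \code{msap_code_counts} matrix (16 x samples), from
#'   [extract_codes()], [read_code_counts()] or [msap_code_counts()].
#' @param include_absent Include markers scored \code{0000} (absent
#'   from all four digests)? Such patterns are only identifiable with
#'   replicated stressed samples, but the model assigns them weights;
#'   default \code{TRUE}.
#' @return Numeric matrix with rows DM, DNM, MSP, NMSP, M, NM,
#'   DNM_CHG, DNM_CG, DM_CHG, DM_CG and Total (the denominator), one
#'   column per sample.
#' @examples
#' counts <- read_code_counts(msap_example("triticale_code_counts.tsv"))
#' event_totals(counts)[, "NT1"]
#' @export
event_totals <- function(counts, include_absent = TRUE) {
  if (!inherits(counts, "msap_code_counts")) counts <- msap_code_counts(counts)
  if (any(counts < 0)) stop("negative code count", call. = FALSE)
  cnt <- unclass(counts)
  if (!include_absent) cnt["0000", ] <- 0L
  w <- msap_weights()
  wm <- as.matrix(w[.EVENTS])
  rownames(wm) <- w$code
  tot <- t(wm) %*% cnt[w$code, , drop = FALSE]
  tot <- rbind(tot, Total = colSums(tot[c("DM", "DNM", "MSP", "NMSP"), ,
                                        drop = FALSE]))
  if (any(tot["Total", ] == 0))
    warning("sample(s) with no scoreable markers (denominator 0): ",
            paste(colnames(tot)[tot["Total", ] == 0], collapse = ", "),
            call. = FALSE)
  tot
}

#' Relative quantitative MSAP characteristics
#'
#' Normalises event totals by the per-sample denominator and expresses
#' them as percentages: NMSP\%, MSP\%, DM\%, DNM\%, M\%, NM\% and the
#' context splits DM-CG\%, DM-CHG\%, DNM-CG\%, DNM-CHG\%. Values are
#' returned at full precision; round only for display (see
#' [format_characteristics()]).
#'
#' @param totals Event-total matrix from [event_totals()].
#' @return Numeric matrix (10 characteristics x samples), unrounded.
#' @export
relative_characteristics <- function(totals) {
  if (any(totals["Total", ] == 0))
    stop("no scoreable markers: denominator is 0 for sample(s) ",
         paste(colnames(totals)[totals["Total", ] == 0], collapse = ", "),
         call. = FALSE)
  ord <- c("NMSP", "MSP", "DM", "DNM", "M", "NM",
           "DM_CG", "DM_CHG", "DNM_CG", "DNM_CHG")
  pct <- 100 * sweep(totals[ord, , drop = FALSE], 2, totals["Total", ], "/")
  rownames(pct) <- paste0(ord, "%")
  pct
}

#' Format a characteristics table for reporting
#'
#' Rounds to 2 decimals, half away from zero. Chained statistics
#' (group means, SDs, cluster distances) must use the unrounded table.
#'
#' @param pct Matrix from [relative_characteristics()].
#' @param digits Decimal places.
#' @return Rounded numeric matrix.
#' @export
format_characteristics <- function(pct, digits = 2) {
  round_half_away(pct, digits)
}

#' Group means and standard deviations of the characteristics
#'
#' @param pct Unrounded characteristics matrix
#'   ([relative_characteristics()]).
#' @param groups Named character/factor vector or a vector aligned with
#'   the samples (columns of \code{pct}) assigning each to a group.
#' @return Data frame with one row per (group, characteristic): mean
#'   and sample (n-1) standard deviation, both computed on unrounded
#'   values; \code{sd} is \code{NA} for singleton groups.
#' @export
group_summary <- function(pct, groups) {
  groups <- .align_groups(groups, colnames(pct))
  out <- do.call(rbind, lapply(split(colnames(pct), groups), function(ss) {
    sub <- pct[, ss, drop = FALSE]
    data.frame(characteristic = rownames(pct),
               n = length(ss),
               mean = rowMeans(sub),
               sd = if (length(ss) > 1) apply(sub, 1, stats::sd) else NA_real_,
               row.names = NULL)
  }))
  out <- cbind(group = rep(levels(factor(groups)),
                           each = nrow(pct)), out)
  rownames(out) <- NULL
  out
}

.align_groups <- function(groups, samples) {
  if (!is.null(names(groups))) {
    miss <- setdiff(samples, names(groups))
    if (length(miss))
      stop("no group assignment for sample(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    groups <- groups[samples]
  } else if (length(groups) != length(samples))
    stop("`groups` must be named by sample or match the number of samples",
         call. = FALSE)
  as.character(groups)
}

#' Read a two-column sample-to-group map
#'
#' @param path Tab-delimited file, columns sample and group, with a
#'   header line.
#' @return Named character vector (names = samples).
#' @export
read_groups <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", colClasses = "character")
  if (ncol(df) < 2) stop("group map needs two columns", call. = FALSE)
  stats::setNames(df[[2]], df[[1]])
}

#' Fit the relative quantitative MSAP model
#'
#' The central entry point: takes an experiment (either the four-track
#' binary bundle or per-sample four-bit code counts), applies the
#' event-weight model, and returns the per-sample event totals and
#' normalised characteristics as a fitted-model object.
#'
#' @param x An [msap_bundle()], an \code{msap_code_counts} matrix, or
#'   anything [msap_code_counts()] accepts.
#' @param groups Optional sample-to-group assignment (named vector or
#'   vector aligned with samples), e.g. tolerant/non-tolerant.
#' @param include_absent Score markers with code \code{0000}? See
#'   [event_totals()].
#' @return An object of class \code{msap} with components
#'   \code{counts}, \code{totals}, \code{characteristics} (unrounded),
#'   \code{weights}, \code{groups} and \code{call}. Methods:
#'   \code{print}, \code{summary}, \code{coef} (the unrounded
#'   characteristics matrix), \code{plot} (Ward dendrogram of the
#'   samples).
#' @examples
#' counts <- read_code_counts(msap_example("triticale_code_counts.tsv"))
#' fit <- msap(counts, groups = read_groups(msap_example("triticale_groups.tsv")))
#' summary(fit)
#' @export
msap <- function(x, groups = NULL, include_absent = TRUE) {
  if (inherits(x, "msap_bundle")) x <- extract_codes(x)
  counts <- if (inherits(x, "msap_code_counts")) x else msap_code_counts(x)
  totals <- event_totals(counts, include_absent = include_absent)
  pct <- relative_characteristics(totals)
  if (!is.null(groups)) groups <- .align_groups(groups, colnames(pct))
  structure(list(counts = counts, totals = totals, characteristics = pct,
                 weights = msap_weights(), groups = groups,
                 include_absent = include_absent, call = match.call()),
            class = "msap")
}

#' @export
print.msap <- function(x, digits = 2, ...) {
  cat("Relative quantitative MSAP fit:",
      ncol(x$counts), "sample(s),",
      sum(x$counts), "scored markers\n")
  cat("Characteristics (% of all events, rounded to", digits, "decimals):\n")
  print(format_characteristics(x$characteristics, digits))
  invisible(x)
}

#' @export
coef.msap <- function(object, ...) object$characteristics

#' @export
summary.msap <- function(object, digits = 2, ...) {
  out <- list(fit = object, digits = digits,
              groups = object$groups,
              group_summary = if (!is.null(object$groups))
                group_summary(object$characteristics, object$groups))
  class(out) <- "summary.msap"
  out
}

#' @export
print.summary.msap <- function(x, ...) {
  fit <- x$fit
  print(fit, digits = x$digits)
  cat("\nEvent totals (counts over all explanations):\n")
  print(fit$totals)
  if (!is.null(x$group_summary)) {
    gs <- x$group_summary
    cat("\nGroup summaries (mean ± sample SD, unrounded inputs):\n")
    gs$mean <- round_half_away(gs$mean, x$digits)
    gs$sd <- round_half_away(gs$sd, x$digits)
    print(gs, row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.msap <- function(x, ...) {
  data.frame(sample = colnames(x$characteristics),
             t(x$characteristics), check.names = FALSE, ...)
}

#' @export
plot.msap <- function(x, ...) {
  plot(msap_cluster(x), ...)
}

#' Write event totals / characteristics tables
#'
#' Tab-delimited, one row per event type or characteristic, one column
#' per sample; hyphens in event names (DM-CHG).
#'
#' @param x A fitted [msap()] object.
#' @param events_path,characteristics_path Output paths (\code{NULL}
#'   to skip either).
#' @param digits Decimals for the characteristics table.
#' @param header Optional \code{#}-prefixed comment lines.
#' @return Invisibly, \code{x}.
#' @export
write_msap_tables <- function(x, events_path = NULL,
                              characteristics_path = NULL,
                              digits = 2, header = NULL) {
  wr <- function(m, path) {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(header)) writeLines(paste0("# ", header), con)
    df <- data.frame(quantity = .hyphen(rownames(m)), m, check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(events_path)) wr(x$totals, events_path)
  if (!is.null(characteristics_path))
    wr(format_characteristics(x$characteristics, digits), characteristics_path)
  invisible(x)
}
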