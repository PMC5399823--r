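#' One-way ANOVA of MSAP characteristics with variance explained
#'
#' Standard fixed-effects one-way analysis of variance of each
#' characteristic across groups, reporting alongside the F test the
#' share of variance explained by the grouping,
#' eta-squared = SS_between / SS_total.
#'
#' @param x A fitted [msap()] object or an unrounded characteristics
#'   matrix (characteristics x samples); a plain numeric vector is
#'   treated as a single response.
#' @param groups Group assignment (named by sample or aligned with the
#'   samples); defaults to the fit's stored groups.
#' @return Data frame of class \code{msap_anova}, one row per
#'   characteristic: \code{F}, \code{df1}, \code{df2}, \code{p} and
#'   \code{var_explained} in [0, 1].
#' @examples
#' counts <- read_code_counts(msap_example("triticale_code_counts.tsv"))
#' fit <- msap(counts, groups = read_groups(msap_example("triticale_groups.tsv")))
#' msap_anova(fit)
#' @export
msap_anova <- function(x, groups = NULL) {
  if (inherits(x, "msap")) {
    if (is.null(groups)) groups <- x$groups
    x <- x$characteristics
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list("value", names(x)))
  if (is.null(groups)) stop("`groups` is required", call. = FALSE)
  groups <- factor(.align_groups(groups, colnames(x)))
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (length(groups) <= nlevels(groups))
    stop("need more observations than groups", call. = FALSE)
  out <- do.call(rbind, lapply(rownames(x), function(ch) {
    y <- x[ch, ]
    a <- stats::anova(stats::lm(y ~ groups))
    ssb <- a$`Sum Sq`[1]
    sst <- sum(a$`Sum Sq`)
    data.frame(characteristic = ch,
               F = a$`F value`[1],
               df1 = a$Df[1], df2 = a$Df[2],
               p = a$`Pr(>F)`[1],
               var_explained = if (sst > 0) ssb / sst else 0)
  }))
  rownames(out) <- NULL
  class(out) <- c("msap_anova", "data.frame")
  out
}

#' @export
print.msap_anova <- function(x, ...) {
  cat("One-way ANOVA of MSAP characteristics",
      "(var_explained = SS_between / SS_total)\n")
  print.data.frame(x, row.names = FALSE, digits = 4, ...)
  invisible(x)
}
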