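#' Read a binary MSAP marker matrix
#'
#' Reads a tab-delimited presence/absence matrix: first column marker
#' identifiers, header row sample identifiers, cells 0, 1 or \code{NA}.
#' Anything else is a parse error naming the offending cell; duplicate
#' marker or sample identifiers are rejected. Missing calls are kept as
#' \code{NA} -- they are never silently imputed, and are handled
#' downstream by [extract_codes()].
#'
#' @param path Path to the file. Lines starting with \code{#} are
#'   ignored.
#' @return Integer matrix (markers x samples) with dimnames.
#' @export
read_marker_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("marker matrix ", path, " must have a header row of sample ids ",
         "and at least one marker row", call. = FALSE)
  markers <- df[[1]]
  samples <- colnames(df)[-1]
  if (anyDuplicated(markers))
    stop("duplicate marker ids in ", path, ": ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(samples))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  ok <- vals %in% c("0", "1", "NA") | is.na(vals)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-binary cell in %s: marker '%s', sample '%s' has value '%s' (expected 0, 1 or NA)",
      path, markers[bad[1]], samples[bad[2]], vals[bad[1], bad[2]]),
      call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.integer(vals)), nrow = nrow(vals),
              dimnames = list(markers, samples))
  m
}

#' Write a binary marker matrix as tab-delimited text
#'
#' @param x Integer 0/1 matrix with marker row names and sample column
#'   names.
#' @param path Output path.
#' @param id_col Name of the first (marker id) column.
#' @param header Optional comment lines written with a \code{#} prefix.
#' @return Invisibly, \code{x}.
#' @export
write_marker_matrix <- function(x, path, id_col = "marker", header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  df <- data.frame(rownames(x), x, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Bundle the four digest/condition tracks of an MSAP experiment
#'
#' An MSAP experiment on control and stressed samples yields four
#' binary matrices: EcoRI/HpaII and EcoRI/MspI digests of the control
#' material and of its stressed counterpart. The four tracks must agree
#' on marker and sample sets; they are reordered to the marker and
#' sample order of the control HpaII track.
#'
#' @param control_hpa,control_msp,stressed_hpa,stressed_msp Integer 0/1
#'   matrices (markers x samples) as returned by [read_marker_matrix()].
#' @return An object of class \code{msap_bundle}: a named list of the
#'   four harmonized matrices.
#' @export
msap_bundle <- function(control_hpa, control_msp, stressed_hpa, stressed_msp) {
  tracks <- list(control_hpa = control_hpa, control_msp = control_msp,
                 stressed_hpa = stressed_hpa, stressed_msp = stressed_msp)
  ref <- tracks[[1]]
  for (nm in names(tracks)[-1]) {
    tr <- tracks[[nm]]
    dm <- setdiff(rownames(ref), rownames(tr))
    dx <- setdiff(rownames(tr), rownames(ref))
    if (length(dm) || length(dx))
      stop("marker sets differ between control_hpa and ", nm,
           if (length(dm)) paste0("; missing from ", nm, ": ",
                                  paste(utils::head(dm, 5), collapse = ", ")),
           if (length(dx)) paste0("; extra in ", nm, ": ",
                                  paste(utils::head(dx, 5), collapse = ", ")),
           call. = FALSE)
    if (!setequal(colnames(ref), colnames(tr)))
      stop("sample sets differ between control_hpa and ", nm, call. = FALSE)
    tracks[[nm]] <- tr[rownames(ref), colnames(ref), drop = FALSE]
  }
  structure(tracks, class = "msap_bundle")
}

#' Read an experiment bundle from a manifest file
#'
#' The manifest is flat \code{key=value} text naming the four track
#' files relative to the manifest's directory, with keys
#' \code{control_hpa}, \code{control_msp}, \code{stressed_hpa},
#' \code{stressed_msp}.
#'
#' @param path Manifest path.
#' @return An [msap_bundle()].
#' @export
read_msap_bundle <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2))
    stop("manifest ", path, " must contain key=value lines", call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  need <- c("control_hpa", "control_msp", "stressed_hpa", "stressed_msp")
  miss <- setdiff(need, keys)
  if (length(miss))
    stop("manifest ", path, " is missing keys: ",
         paste(miss, collapse = ", "), call. = FALSE)
  dir <- dirname(path)
  tr <- lapply(need, function(k)
    read_marker_matrix(file.path(dir, vals[match(k, keys)])))
  do.call(msap_bundle, tr)
}

#' Reduce an experiment bundle to per-sample four-bit code counts
#'
#' For every marker and sample the four presence bits are concatenated
#' in the order (control-HpaII, control-MspI, stressed-HpaII,
#' stressed-MspI) and tallied over the sixteen codes, including
#' \code{0000}. Markers with a missing call in any track are dropped
#' for that sample only; the number of dropped calls is reported via
#' \code{message()} and attached as attribute \code{n_dropped}.
#'
#' @param bundle An [msap_bundle()].
#' @return A 16 x n_samples integer matrix of class
#'   \code{msap_code_counts}, rows named by code.
#' @examples
#' m <- matrix(1L, 2, 1, dimnames = list(c("a", "b"), "s1"))
#' z <- matrix(0L, 2, 1, dimnames = list(c("a", "b"), "s1"))
#' extract_codes(msap_bundle(m, z, m, z))  # both markers are code 1010
#' @export
extract_codes <- function(bundle) {
  stopifnot(inherits(bundle, "msap_bundle"))
  codes <- msap_codes()
  samples <- colnames(bundle$control_hpa)
  counts <- matrix(0L, 16L, length(samples), dimnames = list(codes, samples))
  dropped <- 0L
  for (s in samples) {
    bits <- cbind(bundle$control_hpa[, s], bundle$control_msp[, s],
                  bundle$stressed_hpa[, s], bundle$stressed_msp[, s])
    keep <- stats::complete.cases(bits)
    dropped <- dropped + sum(!keep)
    cc <- apply(bits[keep, , drop = FALSE], 1, paste, collapse = "")
    tab <- table(factor(cc, levels = codes))
    counts[, s] <- as.integer(tab)
  }
  if (dropped > 0)
    message("extract_codes: dropped ", dropped,
            " marker calls with missing values")
  structure(counts, n_dropped = dropped,
            class = c("msap_code_counts", class(counts)))
}

#' Construct/validate a code-count matrix
#'
#' @param x Matrix or data frame with four-bit code row names and one
#'   column per sample. Codes absent from \code{x} get count 0.
#' @return 16 x n integer matrix of class \code{msap_code_counts}.
#' @export
msap_code_counts <- function(x) {
  x <- as.matrix(x)
  .check_code(rownames(x))
  if (anyDuplicated(rownames(x)))
    stop("duplicate codes in count matrix", call. = FALSE)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
    stop("code counts must be non-negative integers", call. = FALSE)
  full <- matrix(0L, 16L, ncol(x),
                 dimnames = list(msap_codes(), colnames(x)))
  full[rownames(x), ] <- as.integer(x)
  structure(full, class = c("msap_code_counts", class(full)))
}

#' Read per-sample code counts from tab-delimited text
#'
#' Rows are four-bit codes, columns samples; codes not listed default
#' to zero. This is the direct entry point for data already tallied by
#' code (as experiments are commonly reported).
#'
#' @param path File path; \code{#} lines are ignored.
#' @return 16 x n integer matrix of class \code{msap_code_counts}.
#' @examples
#' counts <- read_code_counts(msap_example("triticale_code_counts.tsv"))
#' counts["1010", "NT1"]
#' @export
read_code_counts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("code-count file ", path, " is empty or has no sample columns",
         call. = FALSE)
  vals <- suppressWarnings(matrix(as.numeric(as.matrix(df[, -1, drop = FALSE])),
                                  nrow = nrow(df)))
  if (any(is.na(vals)))
    stop("non-numeric count in ", path, call. = FALSE)
  rownames(vals) <- df[[1]]
  colnames(vals) <- colnames(df)[-1]
  msap_code_counts(vals)
}

#' Write a code-count matrix as tab-delimited text
#'
#' @param x An \code{msap_code_counts} matrix.
#' @param path Output path or \code{""} for stdout.
#' @param header Optional comment lines (\code{#}-prefixed).
#' @return Invisibly, \code{x}.
#' @export
write_code_counts <- function(x, path = "", header = NULL) {
  con <- if (identical(path, "")) stdout() else file(path, "w")
  if (!identical(path, "")) on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  df <- data.frame(code = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Path to a packaged example data file
#'
#' @param file File name under the package's \code{extdata}; with no
#'   argument, lists the available files.
#' @return A file path (or a vector of file names).
#' @export
msap_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "msapquant")))
  path <- system.file("extdata", file, package = "msapquant")
  if (path == "") stop("no packaged file called ", file, call. = FALSE)
  path
}
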