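#' Admissible methylation states of a HpaII/MspI restriction site
#'
#' The CCGG/GGCC duplex recognised by the isoschizomers HpaII and MspI
#' carries four cytosines: an external (5'-most) and an internal one on
#' each strand. Of the sixteen conceivable methylation configurations,
#' only six have been documented and are admitted by the model:
#'
#' \describe{
#'   \item{U}{unmethylated on all four positions}
#'   \item{HE}{hemimethylated at the external position (one strand)}
#'   \item{FE}{both external cytosines methylated}
#'   \item{HI}{hemimethylated at the internal position (one strand)}
#'   \item{FI}{both internal cytosines methylated}
#'   \item{FM}{fully methylated}
#' }
#'
#' Hemimethylated states do not record which strand carries the mark;
#' the two strand assignments are one equivalence class. Mixed
#' external/internal partial patterns are excluded: they have not been
#' described for this site and extending the set is a deliberate act
#' (edit the single constant backing this function).
#'
#' @return A data frame with one row per admissible state, columns
#'   \code{state} and the four methylation flags \code{ext_top},
#'   \code{ext_bottom}, \code{int_top}, \code{int_bottom} (0/1).
#' @examples
#' msap_states()
#' @export
msap_states <- function() {
  data.frame(state = rownames(.STATES), .STATES, row.names = NULL,
             stringsAsFactors = FALSE)
}

# Single source of truth for the admissible state space. Row order is the
# canonical ordering used for deterministic explanation lists.
.STATES <- matrix(
  c(0, 0, 0, 0,   # U
    1, 0, 0, 0,   # HE
    1, 1, 0, 0,   # FE
    0, 0, 1, 0,   # HI
    0, 0, 1, 1,   # FI
    1, 1, 1, 1),  # FM
  nrow = 6, byrow = TRUE,
  dimnames = list(c("U", "HE", "FE", "HI", "FI", "FM"),
                  c("ext_top", "ext_bottom", "int_top", "int_bottom")))

# Event vector layout shared by the whole package (Table-2 style order).
.EVENTS <- c("DM", "DNM", "MSP", "NMSP", "M", "NM",
             "DNM_CHG", "DNM_CG", "DM_CHG", "DM_CG")

.check_state <- function(state) {
  bad <- setdiff(state, rownames(.STATES))
  if (length(bad))
    stop("inadmissible site state(s): ", paste(bad, collapse = ", "),
         "; admissible states are ", paste(rownames(.STATES), collapse = ", "),
         call. = FALSE)
  invisible(state)
}

.check_code <- function(code) {
  if (!is.character(code) || any(!grepl("^[01]{4}$", code)))
    stop("a four-bit code must be a string of four 0/1 digits, got: ",
         paste(utils::head(code), collapse = ", "), call. = FALSE)
  invisible(code)
}

#' All sixteen four-bit MSAP codes
#'
#' Bit order is (control-HpaII, control-MspI, stressed-HpaII,
#' stressed-MspI), e.g. \code{"1110"} is a fragment present everywhere
#' except the stressed MspI digest.
#'
#' @return Character vector of the 16 codes, \code{"0000"} to \code{"1111"}.
#' @export
msap_codes <- function() {
  apply(expand.grid(0:1, 0:1, 0:1, 0:1)[, 4:1], 1, paste, collapse = "")
}

#' Digestion profile implied by a site state
#'
#' HpaII cuts sites that are non-methylated or carry a single methylated
#' external cytosine; MspI cuts non-methylated sites and those with one
#' or two methylated internal cytosines. A fragment therefore appears in
#' a digest exactly when the enzyme can cut.
#'
#' @param state Character vector of admissible state names
#'   (see [msap_states()]).
#' @return Integer matrix with one row per state and columns \code{hpa},
#'   \code{msp} (1 = fragment present in that digest).
#' @examples
#' digest_profile(c("U", "HE", "FM"))
#' @export
digest_profile <- function(state) {
  .check_state(state)
  s <- .STATES[state, , drop = FALSE]
  ext <- s[, "ext_top"] + s[, "ext_bottom"]
  int <- s[, "int_top"] + s[, "int_bottom"]
  cbind(hpa = as.integer(int == 0 & ext <= 1),
        msp = as.integer(ext == 0))
}

#' Site states consistent with a digestion profile
#'
#' Inverse of [digest_profile()]: the set of admissible states that
#' would produce a given presence/absence pair.
#'
#' @param hpa,msp 0/1 presence of the fragment in the EcoRI/HpaII and
#'   EcoRI/MspI digests.
#' @return Character vector of state names in canonical order.
#' @examples
#' consistent_states(0, 0)  # FE or FM
#' @export
consistent_states <- function(hpa, msp) {
  if (!hpa %in% 0:1 || !msp %in% 0:1)
    stop("digest profile bits must be 0 or 1", call. = FALSE)
  p <- digest_profile(rownames(.STATES))
  rownames(.STATES)[p[, "hpa"] == hpa & p[, "msp"] == msp]
}

#' Count methylation events for one control-to-stressed transition
#'
#' Each of the four cytosine positions of the site contributes exactly
#' one event when a control state is compared with a stressed state:
#' methylated in both = MSP, unmethylated in both = NMSP, methylated
#' only in the control = DM (demethylation), methylated only under
#' stress = DNM (de novo methylation). Changes at the external
#' positions are assigned to the CHG sequence context, changes at the
#' internal positions to CG.
#'
#' @param control,stressed Admissible state names.
#' @return Named integer vector with components DM, DNM, MSP, NMSP,
#'   M (= DNM + MSP), NM (= DM + NMSP) and the context splits DNM_CHG,
#'   DNM_CG, DM_CHG, DM_CG.
#' @examples
#' transition_events("FM", "HI")  # 2 external + 1 internal demethylation
#' @export
transition_events <- function(control, stressed) {
  .check_state(c(control, stressed))
  a <- .STATES[control, ]
  b <- .STATES[stressed, ]
  ctx <- c("CHG", "CHG", "CG", "CG")  # external, external, internal, internal
  ev <- stats::setNames(integer(length(.EVENTS)), .EVENTS)
  for (i in 1:4) {
    if (a[i] == 1 && b[i] == 1) ev["MSP"] <- ev["MSP"] + 1L
    else if (a[i] == 0 && b[i] == 0) ev["NMSP"] <- ev["NMSP"] + 1L
    else if (a[i] == 1 && b[i] == 0) {
      ev["DM"] <- ev["DM"] + 1L
      ev[paste0("DM_", ctx[i])] <- ev[paste0("DM_", ctx[i])] + 1L
    } else {
      ev["DNM"] <- ev["DNM"] + 1L
      ev[paste0("DNM_", ctx[i])] <- ev[paste0("DNM_", ctx[i])] + 1L
    }
  }
  ev["M"] <- ev["DNM"] + ev["MSP"]
  ev["NM"] <- ev["DM"] + ev["NMSP"]
  ev
}

#' Enumerate all explanations of a four-bit code
#'
#' A four-bit code fixes the digestion profile of the control site
#' (bits 1-2) and of the stressed site (bits 3-4). Every pair of
#' admissible states consistent with those two profiles is one
#' explanation of the code; the pairs are listed in canonical state
#' order (U, HE, FE, HI, FI, FM), control varying slowest.
#'
#' @param code A four-bit code string such as \code{"0011"}.
#' @return Data frame with columns \code{control}, \code{stressed} and
#'   the event counts of each transition.
#' @examples
#' enumerate_explanations("0000")  # (FE,FM) x (FE,FM): 4 explanations
#' @export
enumerate_explanations <- function(code) {
  .check_code(code)
  bits <- as.integer(strsplit(code, "")[[1]])
  ctrl <- consistent_states(bits[1], bits[2])
  strs <- consistent_states(bits[3], bits[4])
  grid <- expand.grid(stressed = strs, control = ctrl,
                      stringsAsFactors = FALSE)[, c("control", "stressed")]
  ev <- t(mapply(transition_events, grid$control, grid$stressed))
  rownames(ev) <- NULL
  cbind(grid, as.data.frame(ev))
}

#' Aggregated event weights of a four-bit code
#'
#' Sums the event counts over all explanations of the code, treating
#' every explanation as equally probable. The weights are raw sums, not
#' averages: each explanation contributes its full four events, so a
#' code with k explanations carries 4k events in total.
#'
#' @param code A four-bit code string.
#' @return Named integer vector of aggregated event counts, with
#'   attribute \code{n_explanations}.
#' @examples
#' code_weights("0000")
#' @export
code_weights <- function(code) {
  ex <- enumerate_explanations(code)
  w <- vapply(.EVENTS, function(e) sum(ex[[e]]), integer(1))
  structure(w, n_explanations = nrow(ex))
}

#' The full 16-code event-weight table
#'
#' Derives, from enzyme behaviour alone, the number of demethylation
#' (DM), de novo methylation (DNM), methylated-site preservation (MSP)
#' and non-methylated-site preservation (NMSP) events -- plus the
#' CG/CHG context splits and the derived totals M = DNM + MSP and
#' NM = DM + NMSP -- attached to each of the sixteen four-bit codes.
#' This table is the core of the relative quantitative method: observed
#' code counts are multiplied by these weights and summed.
#'
#' @return A data frame of class \code{msap_weights} with one row per
#'   code and columns \code{code}, \code{n_explanations} and the ten
#'   event counts.
#' @examples
#' msap_weights()
#' @export
msap_weights <- function() {
  codes <- msap_codes()
  w <- t(vapply(codes, function(cc) {
    cw <- code_weights(cc)
    c(n_explanations = attr(cw, "n_explanations"), cw)
  }, numeric(length(.EVENTS) + 1L)))
  out <- data.frame(code = codes, w, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("msap_weights", "data.frame")
  out
}

#' @export
print.msap_weights <- function(x, ...) {
  cat("MSAP event-weight table: 16 four-bit codes",
      "(bit order: control-HpaII, control-MspI, stressed-HpaII, stressed-MspI)\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Write the event-weight table as tab-delimited text
#'
#' Column order mirrors the conventional presentation: code, number of
#' explanations, DM, DNM, MSP, NMSP, M, NM, then the context splits.
#' Underscores in event names are written as hyphens (DNM-CHG etc.).
#'
#' @param x A table from [msap_weights()] (built on the fly if missing).
#' @param path Output file path or \code{""} for stdout.
#' @param header Optional character vector of comment lines (written
#'   prefixed with \code{#}).
#' @return Invisibly, the table.
#' @export
write_weights <- function(x = msap_weights(), path = "", header = NULL) {
  out <- x
  ev <- names(out) %in% .EVENTS
  names(out)[ev] <- .hyphen(names(out)[ev])
  con <- if (identical(path, "")) stdout() else file(path, "w")
  if (!identical(path, "")) on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
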