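#' Configuration for a simulated MSAP experiment
#'
#' Describes the data-generating situation the quantification method
#' is aimed at: each marker is an independent CCGG site whose control
#' methylation state is drawn from \code{state_probs}; stress then
#' flips each cytosine position independently -- a methylated position
#' demethylates with the context's \code{p_dm_*}, an unmethylated one
#' gains methylation with \code{p_dnm_*} (external positions are CHG
#' context, internal CG). Proposals that leave the six admissible
#' states are redrawn (rejection sampling), because the model's state
#' space has no mixed patterns.
#'
#' Defaults emulate a small stress experiment: state frequencies are
#' uniform over the six admissible states (no empirical frequencies
#' are established for control tissue) and change rates are of the
#' order observed in cereal stress studies, with CG change more
#' frequent than CHG and demethylation more frequent than de novo
#' methylation.
#'
#' @param n_markers Markers (sites) per sample.
#' @param n_samples Number of samples.
#' @param state_probs Probability vector over the six states, in the
#'   order U, HE, FE, HI, FI, FM; must sum to 1.
#' @param p_dm_cg,p_dm_chg Per-position demethylation probabilities in
#'   CG (internal) and CHG (external) context.
#' @param p_dnm_cg,p_dnm_chg Per-position de novo methylation
#'   probabilities.
#' @param seed Integer seed; the simulation is bit-reproducible.
#' @return Validated list of class \code{msap_sim_config}.
#' @export
msap_sim_config <- function(n_markers = 440, n_samples = 10,
                            state_probs = rep(1 / 6, 6),
                            p_dm_cg = 0.05, p_dm_chg = 0.015,
                            p_dnm_cg = 0.04, p_dnm_chg = 0.005,
                            seed = 1) {
  if (length(state_probs) != 6 || any(state_probs < 0) ||
      abs(sum(state_probs) - 1) > 1e-12)
    stop("state_probs must be 6 non-negative values summing to 1",
         call. = FALSE)
  for (p in c(p_dm_cg, p_dm_chg, p_dnm_cg, p_dnm_chg))
    if (!is.numeric(p) || length(p) != 1 || p < 0 || p > 1)
      stop("change probabilities must be single values in [0, 1]",
           call. = FALSE)
  if (n_markers < 1 || n_samples < 1)
    stop("n_markers and n_samples must be positive", call. = FALSE)
  structure(list(n_markers = as.integer(n_markers),
                 n_samples = as.integer(n_samples),
                 state_probs = stats::setNames(state_probs,
                                               rownames(.STATES)),
                 p_dm_cg = p_dm_cg, p_dm_chg = p_dm_chg,
                 p_dnm_cg = p_dnm_cg, p_dnm_chg = p_dnm_chg,
                 seed = as.integer(seed)),
            class = "msap_sim_config")
}

# Stress one matrix of site states (rows = sites, 4 flag columns).
# Rejection sampling keeps every stressed site inside the admissible
# space; returns the accepted flag matrix.
.stress_sites <- function(ctrl_flags, config, max_iter = 10000L) {
  p_dm <- c(config$p_dm_chg, config$p_dm_chg, config$p_dm_cg, config$p_dm_cg)
  p_dnm <- c(config$p_dnm_chg, config$p_dnm_chg,
             config$p_dnm_cg, config$p_dnm_cg)
  n <- nrow(ctrl_flags)
  out <- matrix(NA_integer_, n, 4)
  todo <- seq_len(n)
  admissible <- apply(.STATES, 1, paste, collapse = "")
  iter <- 0L
  n_proposals <- 0L
  while (length(todo)) {
    iter <- iter + 1L
    n_proposals <- n_proposals + length(todo)
    if (iter > max_iter)
      stop("rejection sampling failed to reach an admissible state in ",
           max_iter, " iterations; the change probabilities make every ",
           "outcome inadmissible for some control state", call. = FALSE)
    cf <- ctrl_flags[todo, , drop = FALSE]
    u <- matrix(stats::runif(length(cf)), nrow(cf))
    pm <- matrix(p_dm, nrow(cf), 4, byrow = TRUE)
    pn <- matrix(p_dnm, nrow(cf), 4, byrow = TRUE)
    prop <- ifelse(cf == 1L, ifelse(u < pm, 0L, 1L),
                   ifelse(u < pn, 1L, 0L))
    key <- apply(prop, 1, paste, collapse = "")
    ok <- key %in% admissible
    out[todo[ok], ] <- prop[ok, , drop = FALSE]
    todo <- todo[!ok]
  }
  structure(out, n_proposals = n_proposals, n_sites = n)
}

#' Simulate an MSAP experiment with known ground truth
#'
#' Generates the four binary digest tracks of a control/stressed MSAP
#' experiment (see [msap_sim_config()] for the model) together with
#' the realised per-position event counts, so that estimates from the
#' quantification pipeline can be compared against truth.
#'
#' @param config An [msap_sim_config()]; alternatively pass its
#'   arguments via \code{...}.
#' @param ... Arguments forwarded to [msap_sim_config()] when
#'   \code{config} is missing.
#' @return Object of class \code{msap_sim}: list with \code{bundle}
#'   (an [msap_bundle()]), \code{truth} (matrix of realised DM/DNM/
#'   MSP/NMSP counts and context splits, samples in columns),
#'   \code{rejection_rate} (share of proposals redrawn) and
#'   \code{config}.
#' @examples
#' sim <- simulate_msap(n_markers = 200, n_samples = 2, seed = 7)
#' fit <- msap(sim$bundle)
#' recovery_report(sim, fit)
#' @export
simulate_msap <- function(config, ...) {
  if (missing(config)) config <- msap_sim_config(...)
  stopifnot(inherits(config, "msap_sim_config"))
  set.seed(config$seed)
  nm <- config$n_markers
  ns <- config$n_samples
  samples <- sprintf("S%02d", seq_len(ns))
  markers <- sprintf("m%05d", seq_len(nm))
  mk <- function() matrix(0L, nm, ns, dimnames = list(markers, samples))
  tracks <- list(control_hpa = mk(), control_msp = mk(),
                 stressed_hpa = mk(), stressed_msp = mk())
  truth <- matrix(0L, length(.EVENTS), ns,
                  dimnames = list(.EVENTS, samples))
  state_names <- rownames(.STATES)
  n_proposals <- 0L
  for (s in seq_len(ns)) {
    ctrl <- sample(state_names, nm, replace = TRUE, prob = config$state_probs)
    cf <- .STATES[ctrl, , drop = FALSE]
    sf <- .stress_sites(cf, config)
    n_proposals <- n_proposals + attr(sf, "n_proposals")
    # realised per-position events
    ctx <- c("CHG", "CHG", "CG", "CG")
    for (i in 1:4) {
      dm <- cf[, i] == 1 & sf[, i] == 0
      dnm <- cf[, i] == 0 & sf[, i] == 1
      truth["DM", s] <- truth["DM", s] + sum(dm)
      truth["DNM", s] <- truth["DNM", s] + sum(dnm)
      truth["MSP", s] <- truth["MSP", s] + sum(cf[, i] == 1 & sf[, i] == 1)
      truth["NMSP", s] <- truth["NMSP", s] + sum(cf[, i] == 0 & sf[, i] == 0)
      truth[paste0("DM_", ctx[i]), s] <- truth[paste0("DM_", ctx[i]), s] + sum(dm)
      truth[paste0("DNM_", ctx[i]), s] <- truth[paste0("DNM_", ctx[i]), s] + sum(dnm)
    }
    pc <- digest_profile(ctrl)
    key <- apply(sf, 1, paste, collapse = "")
    skey <- apply(.STATES, 1, paste, collapse = "")
    ps <- digest_profile(state_names[match(key, skey)])
    tracks$control_hpa[, s] <- pc[, "hpa"]
    tracks$control_msp[, s] <- pc[, "msp"]
    tracks$stressed_hpa[, s] <- ps[, "hpa"]
    tracks$stressed_msp[, s] <- ps[, "msp"]
  }
  truth["M", ] <- truth["DNM", ] + truth["MSP", ]
  truth["NM", ] <- truth["DM", ] + truth["NMSP", ]
  structure(list(bundle = do.call(msap_bundle, tracks),
                 truth = truth,
                 rejection_rate = 1 - (nm * ns) / n_proposals,
                 config = config),
            class = "msap_sim")
}

#' @export
print.msap_sim <- function(x, ...) {
  cat("Simulated MSAP experiment:", x$config$n_markers, "markers x",
      x$config$n_samples, "samples (seed", x$config$seed, ")\n")
  cat("Realised event counts:\n")
  print(x$truth)
  invisible(x)
}

#' Compare estimated characteristics with simulated truth
#'
#' Tabulates, per sample and event type, the realised event fraction
#' (truth counts over 4 x n_markers) against the model's estimated
#' percentage. The two are not expected to coincide: the
#' equal-probability weighting has an intrinsic baseline because
#' ambiguous codes (e.g. 0101, 0000) carry change events in some of
#' their explanations even when nothing changed. Monotone association
#' with the simulated rates, not unbiasedness, is the recovery claim.
#'
#' @param sim An [simulate_msap()] result.
#' @param fit An [msap()] fit of \code{sim$bundle}.
#' @return Data frame: sample, event, true percentage, estimated
#'   percentage.
#' @export
recovery_report <- function(sim, fit) {
  stopifnot(inherits(sim, "msap_sim"), inherits(fit, "msap"))
  if (!setequal(colnames(sim$truth), colnames(fit$characteristics)))
    stop("samples of the simulation and the fit differ", call. = FALSE)
  ev <- c("DM", "DNM", "MSP", "NMSP",
          "DM_CG", "DM_CHG", "DNM_CG", "DNM_CHG")
  denom <- 4 * sim$config$n_markers
  do.call(rbind, lapply(colnames(sim$truth), function(s) {
    data.frame(sample = s, event = ev,
               true_pct = 100 * sim$truth[ev, s] / denom,
               estimated_pct = fit$characteristics[paste0(ev, "%"), s],
               row.names = NULL)
  }))
}
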