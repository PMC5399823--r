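# Independent oracles and frozen reference tables used across the suite.

# --- brute-force weight-table oracle -----------------------------------------
# Deliberately a separate code path from the package: digestion encoded as a
# literal lookup of the documented enzyme behaviour, events accumulated by a
# plain double loop over all 6 x 6 state pairs.
oracle_weight_table <- function() {
  flags <- list(U = c(0, 0, 0, 0), HE = c(1, 0, 0, 0), FE = c(1, 1, 0, 0),
                HI = c(0, 0, 1, 0), FI = c(0, 0, 1, 1), FM = c(1, 1, 1, 1))
  digest <- list(U = c(1, 1), HE = c(1, 0), FE = c(0, 0),
                 HI = c(0, 1), FI = c(0, 1), FM = c(0, 0))
  ev_names <- c("DM", "DNM", "MSP", "NMSP", "M", "NM",
                "DNM_CHG", "DNM_CG", "DM_CHG", "DM_CG")
  codes <- sort(apply(expand.grid(0:1, 0:1, 0:1, 0:1), 1, paste, collapse = ""))
  W <- matrix(0, 16, length(ev_names) + 1,
              dimnames = list(codes, c("n_explanations", ev_names)))
  for (cn in names(flags)) for (sn in names(flags)) {
    code <- paste(c(digest[[cn]], digest[[sn]]), collapse = "")
    W[code, "n_explanations"] <- W[code, "n_explanations"] + 1
    for (i in 1:4) {
      ctx <- if (i <= 2) "CHG" else "CG"
      a <- flags[[cn]][i]; b <- flags[[sn]][i]
      if (a == 1 && b == 1) W[code, "MSP"] <- W[code, "MSP"] + 1
      if (a == 0 && b == 0) W[code, "NMSP"] <- W[code, "NMSP"] + 1
      if (a == 1 && b == 0) {
        W[code, "DM"] <- W[code, "DM"] + 1
        W[code, paste0("DM_", ctx)] <- W[code, paste0("DM_", ctx)] + 1
      }
      if (a == 0 && b == 1) {
        W[code, "DNM"] <- W[code, "DNM"] + 1
        W[code, paste0("DNM_", ctx)] <- W[code, paste0("DNM_", ctx)] + 1
      }
    }
  }
  W[, "M"] <- W[, "DNM"] + W[, "MSP"]
  W[, "NM"] <- W[, "DM"] + W[, "NMSP"]
  W
}

# --- brute-force one-way ANOVA oracle ----------------------------------------
oracle_anova <- function(y, g) {
  g <- as.factor(g)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(unlist(lapply(split(y, g), function(v) (v - mean(v))^2)))
  k <- nlevels(g); n <- length(y)
  Fv <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = Fv, df1 = k - 1, df2 = n - k,
       p = stats::pf(Fv, k - 1, n - k, lower.tail = FALSE),
       var_explained = if (ssb + ssw > 0) ssb / (ssb + ssw) else 0)
}

# --- frozen published tables (triticale Al-stress experiment) ----------------
lines10 <- c(paste0("NT", 1:5), paste0("T", 1:5))

published_event_totals <- local({
  m <- rbind(
    DM      = c(225, 206, 225, 235, 202, 228, 231, 224, 218, 206),
    DNM     = c(142, 142, 142, 142, 142, 148, 148, 142, 142, 142),
    MSP     = c(936, 937, 936, 938, 937, 939, 936, 937, 940, 937),
    NMSP    = c(2217, 2211, 2217, 2221, 2219, 2221, 2221, 2213, 2228, 2211),
    M       = c(1078, 1079, 1078, 1080, 1079, 1087, 1084, 1079, 1082, 1079),
    NM      = c(2442, 2417, 2442, 2456, 2421, 2449, 2452, 2437, 2446, 2417),
    DNM_CHG = c(0, 0, 0, 0, 0, 4, 4, 0, 0, 0),
    DNM_CG  = c(142, 142, 142, 142, 142, 144, 144, 142, 142, 142),
    DM_CHG  = c(51, 38, 51, 57, 36, 52, 55, 50, 46, 38),
    DM_CG   = c(174, 168, 174, 178, 166, 176, 176, 174, 172, 168),
    Total   = c(3520, 3496, 3520, 3536, 3500, 3536, 3536, 3516, 3528, 3496))
  colnames(m) <- lines10
  m
})

# Per-line percentages as printed. Six cells of the printed table are
# internally inconsistent (e.g. T1 and T2 share the ratio 176/3536 yet print
# as 4.98 vs 4.99); they are listed in published_pct_typos with the value the
# published arithmetic itself implies.
published_characteristics <- local({
  m <- rbind(
    "NMSP%"    = c(62.98, 63.24, 62.98, 62.81, 63.40, 62.81, 62.81, 62.94, 63.15, 63.24),
    "MSP%"     = c(26.59, 26.80, 26.59, 26.53, 26.77, 26.56, 26.47, 26.65, 26.64, 26.80),
    "DM%"      = c(6.39, 5.87, 6.39, 6.65, 5.77, 6.45, 6.53, 6.37, 6.18, 5.89),
    "DNM%"     = c(4.03, 4.06, 4.03, 4.02, 4.06, 4.19, 4.19, 4.04, 4.02, 4.06),
    "M%"       = c(30.63, 30.86, 30.63, 30.54, 30.83, 30.74, 30.66, 30.69, 30.67, 30.86),
    "NM%"      = c(69.38, 69.14, 69.38, 69.46, 69.17, 69.26, 69.34, 69.31, 69.33, 69.14),
    "DM_CG%"   = c(4.94, 4.80, 4.94, 5.03, 4.74, 4.98, 4.99, 4.95, 4.88, 4.80),
    "DM_CHG%"  = c(1.45, 1.09, 1.45, 1.61, 1.03, 1.47, 1.55, 1.42, 1.30, 1.09),
    "DNM_CG%"  = c(4.03, 4.06, 4.03, 4.02, 4.06, 4.07, 4.07, 4.04, 4.03, 4.06),
    "DNM_CHG%" = c(0, 0, 0, 0, 0, 0.11, 0.11, 0, 0, 0))
  colnames(m) <- lines10
  m
})

published_pct_typos <- data.frame(
  characteristic = c("DM%", "DM_CG%", "DM_CG%", "DM_CHG%", "DNM_CG%", "DM_CG%"),
  sample = c("NT2", "NT2", "T2", "T2", "T4", "T5"),
  implied = c(5.89, 4.81, 4.98, 1.56, 4.02, 4.81),
  stringsAsFactors = FALSE)

# "Average ± SD" columns as printed (mean, sd) x (NT, T). A minority of cells
# are off by 0.01 from any consistent (mean, n-1 SD, rounding) convention;
# published_avg_typos lists them with the value implied by exact arithmetic.
published_group_stats <- local({
  ch <- rownames(published_characteristics)
  m <- cbind(
    NT_mean = c(63.08, 26.66, 6.22, 4.04, 30.69, 69.31, 4.89, 1.32, 4.04, 0.00),
    NT_sd   = c(0.23, 0.12, 0.37, 0.01, 0.13, 0.14, 0.11, 0.25, 0.01, 0.00),
    T_mean  = c(62.99, 26.62, 6.28, 4.10, 30.72, 69.28, 4.91, 1.36, 4.05, 0.05),
    T_sd    = c(0.19, 0.12, 0.25, 0.08, 0.08, 0.08, 0.07, 0.18, 0.02, 0.06))
  rownames(m) <- ch
  m
})

published_avg_typos <- data.frame(
  characteristic = c("M%", "NM%", "DM_CHG%", "DNM%", "M%", "DM_CG%", "DNM_CG%",
                     "DM_CG%", "DM_CHG%", "NMSP%", "DM%"),
  column = c("NT_mean", "NT_mean", "NT_mean", "NT_sd", "NT_sd", "NT_sd", "NT_sd",
             "T_mean", "T_mean", "T_sd", "T_sd"),
  implied = c(30.70, 69.30, 1.33, 0.02, 0.14, 0.12, 0.02,
              4.92, 1.37, 0.20, 0.26),
  stringsAsFactors = FALSE)

triticale_fit <- function(...) {
  counts <- read_code_counts(msap_example("triticale_code_counts.tsv"))
  msap(counts, groups = read_groups(msap_example("triticale_groups.tsv")), ...)
}
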