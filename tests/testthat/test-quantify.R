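test_that("event totals reproduce the published per-line table exactly", {
  fit <- triticale_fit()
  expect_equal(fit$totals[rownames(published_event_totals), ],
               published_event_totals)
})

test_that("characteristics reproduce the published percentages", {
  fit <- triticale_fit()
  got <- format_characteristics(fit$characteristics)
  expected <- published_characteristics
  # six published cells are print typos, inconsistent with the published
  # arithmetic itself; assert the implied values there (see helper)
  for (i in seq_len(nrow(published_pct_typos)))
    expected[published_pct_typos$characteristic[i],
             published_pct_typos$sample[i]] <- published_pct_typos$implied[i]
  expect_equal(got[rownames(expected), colnames(expected)], expected)
})

test_that("group summaries use unrounded values and n-1 standard deviation", {
  fit <- triticale_fit()
  gs <- group_summary(fit$characteristics, fit$groups)
  pick <- function(g, ch, what)
    round_half_away(gs[gs$group == g & gs$characteristic == ch, what][1], 2)
  expect_equal(pick("NT", "DM%", "mean"), 6.22)
  expect_equal(pick("NT", "DM%", "sd"), 0.37)
  expect_equal(pick("T", "DM%", "mean"), 6.28)
  expect_equal(pick("T", "DNM_CHG%", "mean"), 0.05)
  expect_equal(pick("T", "DNM_CHG%", "sd"), 0.06)
  # identical samples give zero SD; singleton groups an undefined one
  counts <- msap_code_counts(matrix(c(5, 5, 5), 1, 3,
                                    dimnames = list("1010", c("a", "b", "c"))))
  pct <- relative_characteristics(event_totals(counts))
  gs2 <- group_summary(pct, c(a = "g1", b = "g1", c = "g2"))
  expect_true(all(gs2$sd[gs2$group == "g1"] == 0))
  expect_true(all(is.na(gs2$sd[gs2$group == "g2"])))
})

test_that("characteristics satisfy their internal identities on random data", {
  set.seed(7)
  for (rep in 1:5) {
    counts <- matrix(rpois(32, 20), 16, 2, dimnames = list(msap_codes(), c("x", "y")))
    pct <- relative_characteristics(event_totals(msap_code_counts(counts)))
    expect_equal(colSums(pct[c("NMSP%", "MSP%", "DM%", "DNM%"), ]),
                 c(x = 100, y = 100))
    expect_equal(colSums(pct[c("M%", "NM%"), ]), c(x = 100, y = 100))
    expect_equal(pct["DM%", ], pct["DM_CG%", ] + pct["DM_CHG%", ])
    expect_equal(pct["DNM%", ], pct["DNM_CG%", ] + pct["DNM_CHG%", ])
  }
})

test_that("characteristics are scale-equivariant and totals additive", {
  counts <- unclass(read_code_counts(msap_example("triticale_code_counts.tsv")))
  pct1 <- relative_characteristics(event_totals(msap_code_counts(counts)))
  pct7 <- relative_characteristics(event_totals(msap_code_counts(counts * 7L)))
  expect_equal(pct1, pct7)

  set.seed(11)
  a <- matrix(rpois(16, 10), 16, 1, dimnames = list(msap_codes(), "s"))
  b <- matrix(rpois(16, 10), 16, 1, dimnames = list(msap_codes(), "s"))
  expect_equal(event_totals(msap_code_counts(a + b)),
               event_totals(msap_code_counts(a)) +
                 event_totals(msap_code_counts(b)))
})

test_that("unambiguous codes carry no change events; ambiguous codes do", {
  # model baseline: 1111/1010-only samples show zero DM% and DNM%, while
  # 0101 or 0000 markers contribute change events even with no true change
  clean <- msap_code_counts(matrix(c(30, 10), 2, 1,
                                   dimnames = list(c("1111", "1010"), "s")))
  pct <- relative_characteristics(event_totals(clean))
  expect_equal(pct["DM%", "s"], 0)
  expect_equal(pct["DNM%", "s"], 0)

  biased <- msap_code_counts(matrix(c(30, 10, 5), 3, 1,
                                    dimnames = list(c("1111", "0101", "0000"), "s")))
  pctb <- relative_characteristics(event_totals(biased))
  expect_gt(pctb["DM%", "s"], 0)
  expect_gt(pctb["DNM%", "s"], 0)

  only1111 <- msap_code_counts(matrix(12, 1, 1, dimnames = list("1111", "s")))
  p <- relative_characteristics(event_totals(only1111))
  expect_equal(p["NMSP%", "s"], 100)
  expect_equal(sum(p[setdiff(rownames(p), c("NMSP%", "NM%")), "s"]), 0)
})

test_that("the 0000 inclusion flag and degenerate denominators behave", {
  counts <- msap_code_counts(matrix(c(10, 5), 2, 1,
                                    dimnames = list(c("1111", "0000"), "s")))
  with_abs <- event_totals(counts)
  without <- event_totals(counts, include_absent = FALSE)
  expect_equal(with_abs["Total", "s"], 10 * 4 + 5 * 16)
  expect_equal(without["Total", "s"], 40)

  zero <- msap_code_counts(matrix(0L, 16, 1, dimnames = list(msap_codes(), "s")))
  expect_warning(tot <- event_totals(zero), "no scoreable markers")
  expect_error(relative_characteristics(tot), "denominator is 0")
  expect_error(event_totals(matrix(-1, 16, 1,
                                   dimnames = list(msap_codes(), "s"))),
               "non-negative")
})

test_that("report rounding is half away from zero", {
  expect_equal(round_half_away(69.375), 69.38)
  expect_equal(round_half_away(30.625), 30.63)
  expect_equal(round_half_away(-1.125), -1.13)
  expect_equal(round_half_away(2.25, 1), 2.3)
})

test_that("the fitted object exposes the standard methods", {
  fit <- triticale_fit()
  expect_s3_class(fit, "msap")
  expect_equal(coef(fit), fit$characteristics)
  expect_output(print(fit), "10 sample")
  expect_output(print(summary(fit)), "Group summaries")
  df <- as.data.frame(fit)
  expect_equal(df$sample, lines10)

  dir <- withr::local_tempdir()
  write_msap_tables(fit, events_path = file.path(dir, "events.tsv"),
                    characteristics_path = file.path(dir, "chars.tsv"),
                    header = "run")
  ev <- read.table(file.path(dir, "events.tsv"), header = TRUE, sep = "\t",
                   comment.char = "#", check.names = FALSE)
  expect_equal(ev$quantity[1:4], c("DM", "DNM", "MSP", "NMSP"))
  expect_equal(ev$NT1[ev$quantity == "Total"], 3520)
})
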