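## All design tests run on the parental chains with seeded surrogate tables.
make_tables <- function(...) {
  simulateCandidateTables(par_chains$VH, par_chains$VL, ...)
}

test_that("enumeration proposes exactly the net-positive charge changes", {
  cands <- enumerateCandidates(par_chains$VH, par_chains$VL)
  expect_true(all(cands$charge_delta > 0))
  ## a neutral CDR site offers the three basic residues (among others)
  l53 <- cands[cands$chain == "L" & cands$position == "53", ]
  expect_true(all(c("K", "R", "H") %in% l53$mut))
  expect_equal(l53$charge_delta[l53$mut == "K"],
               residueCharge("K", 5.5) - 0, tolerance = 1e-6)
  ## an acidic site offers neutralisations, with the amide among them
  h6 <- cands[cands$chain == "H" & cands$position == "6", ]
  expect_true("Q" %in% h6$mut)
  expect_equal(h6$charge_delta[h6$mut == "Q"], -residueCharge("E", 5.5),
               tolerance = 1e-6)
  ## a fully basic chain yields no candidates
  none <- enumerateCandidates(NumberedChain("VH", strrep("R", 10)),
                              NumberedChain("VL", strrep("R", 10)))
  expect_equal(nrow(none), 0L)
})

test_that("tolerance filter is strict and never silently drops sites", {
  cands <- enumerateCandidates(par_chains$VH, par_chains$VL)[1:4, ]
  cands$ddg_binding <- c(0.0, 1.5, 0.5, NA)
  cands$ddg_stability <- c(0.0, 0.2, 1.0, 0.3)
  out <- filterTolerated(cands)
  expect_equal(out$pass_tolerated, c(TRUE, FALSE, FALSE, FALSE))
  expect_match(out$reasons[2], "ddg_above_tolerance")
  expect_match(out$reasons[3], "ddg_above_tolerance")  # 1.0 is not < 1.0
  expect_match(out$reasons[4], "ddg_missing")
  ## a relaxed tolerance admits the 1-2 kcal/mol interface band
  out2 <- filterTolerated(cands, designConfig(ddg_tolerance = 2.0))
  expect_true(out2$pass_tolerated[2])
})

test_that("CDR rules allow only amide neutralisation and basic introduction", {
  cands <- enumerateCandidates(par_chains$VH, par_chains$VL)
  out <- restrictCdrSubstitutions(cands)
  cdr <- out[out$region == "CDR", ]
  dk <- cdr[cdr$wt == "D" & cdr$mut == "K", ]
  expect_true(all(!dk$pass_cdr_rules))           # D->K banned in CDRs
  expect_true(all(cdr$pass_cdr_rules[cdr$wt == "E" & cdr$mut == "Q"]))
  expect_true(all(cdr$pass_cdr_rules[cdr$wt == "N" & cdr$mut == "K"]))
  expect_true(all(!cdr$pass_cdr_rules[cdr$wt == "D" & cdr$mut == "Q"]))
  ## framework candidates are untouched by this filter
  expect_true(all(out$pass_cdr_rules[out$region == "framework"]))
  ## the round-2 patch mode widens the alphabet at flagged sites only
  out2 <- restrictCdrSubstitutions(cands,
                                   designConfig(cdr_mode = "patch-extended"))
  d50 <- out2[out2$chain == "L" & out2$position == "50" & out2$mut == "L", ]
  expect_true(all(d50$pass_cdr_rules))           # L50 is a patch site
})

test_that("germline filter applies the 10% rule to framework sites", {
  cands <- enumerateCandidates(par_chains$VH, par_chains$VL)
  fw <- cands[cands$region == "framework", ]
  pick <- fw[match(c("H 13 K", "H 23 R", "H 6 Q", "L 7 K"),
                   paste(fw$chain, fw$position, fw$mut)), ]
  gl <- data.frame(
    chain = c("H", "H", "H", "H", "H"),
    position = c("13", "23", "23", "6", "6"),
    residue = c("K", "K", "R", "Q", "E"),
    frequency = c(0.25, 0.03, 0.02, 0.60, 0.40))
  out <- filterFrameworkByGermline(
    enumerateCandidates(par_chains$VH, par_chains$VL, germline = gl)[
      match(paste(pick$chain, pick$position, pick$wt, pick$mut),
            paste(cands$chain, cands$position, cands$wt, cands$mut)), ])
  expect_true(out$pass_germline[1])     # P(K or R) = 0.25 > 0.10
  expect_false(out$pass_germline[2])    # P(K or R) = 0.05
  expect_true(out$pass_germline[3])     # wt E, 60% Q alternative
  expect_false(out$pass_germline[4])    # site missing from the table
  expect_match(out$reasons[4], "germline_site_missing")
})

test_that("score-reduction keeps designs at least one predictor improves", {
  cands <- enumerateCandidates(par_chains$VH, par_chains$VL)
  sub <- cands[match(c("H 94 K R", "L 53 N K", "L 96 D K"),
                     paste(cands$chain, cands$position, cands$wt,
                           cands$mut)), ]
  out <- filterScoreReduction(sub, par_chains$VH, par_chains$VL)
  ## K94R: charge-neutral but Arg is more hydrophilic than Lys, so the
  ## hydrophobicity index and hence the score strictly decrease
  expect_true(out$pass_score_reduction[1])
  expect_lt(out$score_delta[1], 0)
  expect_true(out$pass_score_reduction[2])
  expect_error(filterScoreReduction(sub, par_chains$VH, par_chains$VL,
                                    predictors = list()),
               "at least one")
})

test_that("filters commute and every rejection carries a reason", {
  tabs <- make_tables(seed = 4, fraction_tolerated = 0.5,
                      fraction_permissive = 0.5)
  base <- enumerateCandidates(par_chains$VH, par_chains$VL,
                              ddg = tabs$ddg, germline = tabs$germline)
  filters <- list(
    function(x) filterTolerated(x),
    function(x) restrictCdrSubstitutions(x),
    function(x) filterFrameworkByGermline(x),
    function(x) filterScoreReduction(x, par_chains$VH, par_chains$VL))
  key <- function(d) paste(d$chain, d$position, d$mut)

  ref <- Reduce(function(x, f) f(x), filters, base)
  accepted_ref <- key(acceptedCandidates(ref))
  set.seed(42)
  for (i in 1:3) {
    perm <- sample(filters)
    out <- Reduce(function(x, f) f(x), perm, base)
    expect_setequal(key(acceptedCandidates(out)), accepted_ref)
  }
  ## accepted + rejected = enumerated, and all rejected have reasons
  pass <- Reduce(`&`, ref[grep("^pass_", names(ref))])
  expect_equal(sum(pass) + sum(!pass), nrow(base))
  expect_true(all(nzchar(ref$reasons[!pass])))
})

test_that("prioritisation ranks patch sites first and combines chains", {
  tabs <- make_tables(seed = 1, fraction_tolerated = 1,
                      fraction_permissive = 1)
  rep <- runDesignRound(par_chains$VH, par_chains$VL,
                        ddg = tabs$ddg, germline = tabs$germline)
  acc <- rep$accepted
  ## patch-proximal candidates sort ahead of the rest
  expect_true(all(diff(acc$near_negative_patch) <= 0))
  ## every heavy-chain design carries the obligatory K94R exactly once
  hc <- rep$combinations$heavy_chain
  hc <- hc[nzchar(hc)]
  expect_true(all(vapply(strsplit(hc, "_"), function(t)
    sum(t == "K94R") == 1L, logical(1))))
  ## explicit top selections reproduce the published best combination
  cfg <- designConfig(combine_hc = c("E6Q", "Q13K"), combine_lc = "N53K")
  combo <- prioritizeAndCombine(rep$candidates, cfg)$combinations
  combo <- combo[combo$name == "D-combo", ]
  expect_equal(combo$heavy_chain, "E6Q_Q13K_K94R")
  expect_equal(combo$light_chain, "N53K")
  ## K94R in the selection is not duplicated
  cfg2 <- designConfig(combine_hc = c("K94R", "E6Q"), combine_lc = "N53K")
  combo2 <- prioritizeAndCombine(rep$candidates, cfg2)$combinations
  expect_equal(combo2$heavy_chain[combo2$name == "D-combo"], "E6Q_K94R")

  ## empty candidate sets produce empty reports
  none <- runDesignRound(par_chains$VH, par_chains$VL,
                         ddg = transform(tabs$ddg, ddg_binding = 5),
                         germline = tabs$germline)
  expect_equal(nrow(none$accepted), 0L)
  expect_equal(nrow(none$combinations), 0L)
})

test_that("design reports serialise to JSON with full traces", {
  tabs <- make_tables(seed = 2)
  rep <- runDesignRound(par_chains$VH, par_chains$VL,
                        ddg = tabs$ddg, germline = tabs$germline)
  tmp <- tempfile(fileext = ".json")
  writeDesignReport(rep, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(nrow(back$candidates), nrow(rep$candidates))
  expect_equal(back$config$ddg_tolerance, 1.0)
  unlink(tmp)
})
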