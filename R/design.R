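## The two-round mutation-design triage pipeline.  Candidates are proposed as
## net-positive charge-change substitutions, then filtered by predicted
## stability/affinity tolerance, CDR substitution rules, framework germline
## frequency, and predictor score reduction; survivors are prioritised by
## charge-patch proximity and combined across chains.  Filters never drop
## rows: each adds its own pass column and machine-readable reasons, so the
## filters commute and every rejection is traceable.

#' Design pipeline configuration
#'
#' @param ddg_tolerance tolerance (kcal/mol) for predicted change in
#'   stability and in binding affinity; candidates must be strictly below it
#'   in both (default 1.0).  Round-2 interface designs used a relaxed 2.0.
#' @param germline_threshold minimum germline frequency for framework
#'   substitutions (default 0.10, strict inequality).
#' @param require_score_reduction keep only candidates for which at least one
#'   registered viscosity predictor strictly decreases (default TRUE).
#' @param obligatory_hc mutation string appended to every heavy-chain design
#'   (default `"K94R"`, the glycation-risk removal); appended at most once.
#' @param cdr_mode `"strict"` applies the round-1 CDR rules everywhere;
#'   `"patch-extended"` exempts flagged negative-patch sites from the CDR
#'   substitution alphabet, as used for the round-2 patch designs.
#' @param n_combine_hc,n_combine_lc how many top-ranked candidates per chain
#'   enter the combined heavy x light design (the published procedure does
#'   not fix this count; it is a knob).
#' @param combine_hc,combine_lc optional explicit mutation token selections
#'   (e.g. `c("E6Q", "Q13K")`) overriding the ranking for the combination
#'   step.
#' @return A list of class `FilterConfig`.
#' @export
designConfig <- function(ddg_tolerance = 1.0, germline_threshold = 0.10,
                         require_score_reduction = TRUE,
                         obligatory_hc = "K94R",
                         cdr_mode = c("strict", "patch-extended"),
                         n_combine_hc = 2, n_combine_lc = 1,
                         combine_hc = NULL, combine_lc = NULL) {
  stopifnot(ddg_tolerance > 0, germline_threshold > 0)
  structure(list(ddg_tolerance = ddg_tolerance,
                 germline_threshold = germline_threshold,
                 require_score_reduction = require_score_reduction,
                 obligatory_hc = obligatory_hc,
                 cdr_mode = match.arg(cdr_mode),
                 n_combine_hc = n_combine_hc, n_combine_lc = n_combine_lc,
                 combine_hc = combine_hc, combine_lc = combine_lc),
            class = "FilterConfig")
}

.mut_token <- function(cands)
  paste0(cands$wt, cands$position, cands$mut)

#' Enumerate net-positive charge-change candidates
#'
#' Proposes, for every position of both chains, every substitution whose
#' side-chain charge at pH 5.5 strictly exceeds the wild type's (adding a
#' basic residue, or removing/neutralising an acidic one).  Candidates are
#' annotated with their region (CDR or framework), the pH-5.5 charge delta,
#' predicted stability/affinity changes from the supplied table, germline
#' frequencies, and negative-patch/interface flags.  A site missing from the
#' prediction table is flagged (`ddg_missing`), never silently dropped.
#'
#' @param vh,vl parental chains ([NumberedChain-class]).
#' @param ddg a prediction table with columns `chain`, `position`, `mut`,
#'   `ddg_binding`, `ddg_stability` and optionally `interface`; see
#'   [simulateCandidateTables()] for the surrogate generator and its CSV
#'   layout.  `NULL` leaves the columns `NA`.
#' @param germline a germline amino-acid frequency table with columns
#'   `chain`, `position`, `residue`, `frequency`.  `NULL` leaves frequencies
#'   `NA`.
#' @param patch_sites negative-patch flags, default [negativePatchSites()].
#' @param pH pH at which charge deltas are evaluated (default 5.5).
#' @return A candidate data frame, one row per (site, substitution).
#' @export
enumerateCandidates <- function(vh, vl, ddg = NULL, germline = NULL,
                                patch_sites = negativePatchSites(),
                                pH = 5.5) {
  qaa <- residueCharge(.AA1, pH)
  names(qaa) <- .AA1
  per_chain <- function(chain, code) {
    reg <- annotateRegions(chain)
    rows <- lapply(seq_len(nrow(reg)), function(i) {
      wt <- reg$residue[i]
      delta <- qaa - qaa[[wt]]
      muts <- names(delta)[delta > 0 & names(delta) != wt]
      if (!length(muts)) return(NULL)
      data.frame(chain = code, position = reg$position[i], wt = wt,
                 mut = muts,
                 region = if (grepl("^CDR", reg$region[i])) "CDR"
                          else "framework",
                 charge_delta = unname(delta[muts]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  cands <- rbind(per_chain(vh, "H"), per_chain(vl, "L"))
  if (is.null(cands))
    cands <- data.frame(chain = character(), position = character(),
                        wt = character(), mut = character(),
                        region = character(), charge_delta = numeric(),
                        stringsAsFactors = FALSE)
  rownames(cands) <- NULL

  n_c <- nrow(cands)
  cands$ddg_binding <- rep(NA_real_, n_c)
  cands$ddg_stability <- rep(NA_real_, n_c)
  cands$interface <- rep(FALSE, n_c)
  if (!is.null(ddg)) {
    key <- paste(cands$chain, cands$position, cands$mut)
    dkey <- paste(ddg$chain, ddg$position, ddg$mut)
    idx <- match(key, dkey)
    cands$ddg_binding <- ddg$ddg_binding[idx]
    cands$ddg_stability <- ddg$ddg_stability[idx]
    if ("interface" %in% names(ddg))
      cands$interface <- ifelse(is.na(idx), FALSE, ddg$interface[idx])
  }

  ## site-level germline summaries: P(K or R), and for acidic wild types the
  ## aggregate frequency of neutral-or-positive alternatives
  cands$germline_positive_freq <- rep(NA_real_, n_c)
  cands$germline_alt_freq <- rep(NA_real_, n_c)
  if (!is.null(germline)) {
    skey <- paste(germline$chain, germline$position)
    ckey <- paste(cands$chain, cands$position)
    pos_by_site <- tapply(
      germline$frequency * (germline$residue %in% c("K", "R")), skey, sum)
    alt_by_site <- tapply(
      germline$frequency * !(germline$residue %in% c("D", "E")), skey, sum)
    cands$germline_positive_freq <- as.numeric(pos_by_site[ckey])
    cands$germline_alt_freq <- as.numeric(alt_by_site[ckey])
  }

  key <- paste(cands$chain, cands$position)
  pkey <- paste(patch_sites$chain, patch_sites$position)
  cands$near_negative_patch <- key %in% pkey
  cands$reasons <- rep("", n_c)
  cands
}

.add_reason <- function(cands, fail, reason) {
  cands$reasons <- ifelse(fail,
                          ifelse(nzchar(cands$reasons),
                                 paste(cands$reasons, reason, sep = ";"),
                                 reason),
                          cands$reasons)
  cands
}

#' Tolerance filter on predicted stability and affinity changes
#'
#' Keeps candidates predicted to be tolerated: both the binding and the
#' stability change strictly below the configured tolerance (1.0 kcal/mol by
#' default).  Candidates with missing predictions fail with reason
#' `ddg_missing`.
#'
#' @param cands a candidate frame from [enumerateCandidates()].
#' @param config a [designConfig()].
#' @return The frame with logical column `pass_tolerated` and updated
#'   `reasons`.
#' @export
filterTolerated <- function(cands, config = designConfig()) {
  tol <- config$ddg_tolerance
  missing <- is.na(cands$ddg_binding) | is.na(cands$ddg_stability)
  ok <- !missing & cands$ddg_binding < tol & cands$ddg_stability < tol
  cands$pass_tolerated <- ok
  cands <- .add_reason(cands, missing, "ddg_missing")
  .add_reason(cands, !missing & !ok,
              sprintf("ddg_above_tolerance(%.2f)", tol))
}

#' CDR substitution rules
#'
#' Within the CDRs, acidic wild types may only be neutralised to their amide
#' (Glu to Gln, Asp to Asn) and neutral wild types may only gain a basic
#' residue (Arg, Lys or His); every other CDR substitution is rejected.
#' Framework candidates are untouched.  Under `cdr_mode = "patch-extended"`
#' flagged negative-patch sites are exempted, admitting the wider alphabet
#' explored around a targeted patch (e.g. Asp to Lys/Leu/Tyr).
#'
#' @inheritParams filterTolerated
#' @return The frame with logical column `pass_cdr_rules`.
#' @export
restrictCdrSubstitutions <- function(cands, config = designConfig()) {
  in_cdr <- cands$region == "CDR"
  allowed <- !in_cdr |
    (cands$wt == "E" & cands$mut == "Q") |
    (cands$wt == "D" & cands$mut == "N") |
    (!cands$wt %in% c("D", "E") & cands$mut %in% c("R", "K", "H"))
  if (config$cdr_mode == "patch-extended")
    allowed <- allowed | (in_cdr & cands$near_negative_patch)
  cands$pass_cdr_rules <- allowed
  .add_reason(cands, !allowed, "cdr_substitution_not_allowed")
}

#' Germline-frequency filter for framework candidates
#'
#' A framework substitution is kept iff it introduces Lys/Arg at a site where
#' human antibody sequences show a Lys-or-Arg frequency above the threshold,
#' or it removes an acidic wild type at a site where neutral-or-positive
#' alternatives together exceed the threshold (both strict, default 10%).
#' Framework candidates whose site is absent from the table are rejected
#' with reason `germline_site_missing`.  CDR candidates are untouched.
#'
#' @inheritParams filterTolerated
#' @return The frame with logical column `pass_germline`.
#' @export
filterFrameworkByGermline <- function(cands, config = designConfig()) {
  fw <- cands$region == "framework"
  thr <- config$germline_threshold
  missing <- fw & is.na(cands$germline_positive_freq) &
    is.na(cands$germline_alt_freq)
  pos_rule <- cands$mut %in% c("K", "R") &
    !is.na(cands$germline_positive_freq) &
    cands$germline_positive_freq > thr
  alt_rule <- cands$wt %in% c("D", "E") &
    !is.na(cands$germline_alt_freq) &
    cands$germline_alt_freq > thr
  ok <- !fw | (!missing & (pos_rule | alt_rule))
  cands$pass_germline <- ok
  cands <- .add_reason(cands, missing, "germline_site_missing")
  .add_reason(cands, fw & !missing & !ok,
              sprintf("germline_frequency_below(%.2f)", thr))
}

#' Viscosity-score reduction filter
#'
#' Scores each candidate as the design it would actually become and keeps it
#' if at least one registered viscosity predictor strictly decreases
#' relative to the parent.  Heavy-chain candidates are evaluated together
#' with the obligatory heavy-chain mutation from the configuration (K94R by
#' default), because every emitted heavy-chain design carries it — the
#' asymmetry term can make a charge-adding substitution look worse in
#' isolation than the design it belongs to.  Light-chain candidates are
#' evaluated alone.  The sequence-based score ([sharmaScore()]) is the
#' built-in predictor; others (e.g. a structure-based score supplied
#' externally) can be registered as functions `(vh, vl) -> numeric`.
#'
#' @inheritParams filterTolerated
#' @param vh,vl parental chains the candidates refer to.
#' @param predictors named list of predictor functions; must be non-empty.
#' @return The frame with logical column `pass_score_reduction` and a
#'   `score_delta` column from the first predictor.
#' @export
filterScoreReduction <- function(cands, vh, vl,
                                 predictors = list(
                                   sharma = function(vh, vl)
                                     sharmaScore(vh, vl)$eta_pred),
                                 config = designConfig()) {
  if (!length(predictors))
    stop("at least one viscosity predictor must be registered")
  obl <- config$obligatory_hc
  vh_base <- vh
  if (!is.null(obl) && nzchar(obl))
    vh_base <- applyMutations(vh, parseMutations(obl, "H"))
  base <- vapply(predictors, function(f) f(vh, vl), numeric(1))
  deltas <- matrix(NA_real_, nrow(cands), length(predictors))
  for (i in seq_len(nrow(cands))) {
    m <- cands[i, c("chain", "position", "wt", "mut")]
    if (m$chain == "H") {
      ## evaluate the candidate as shipped: with the obligatory mutation,
      ## unless the candidate targets that mutation's own site
      ref <- if (residueAt(vh_base, m$position) != residueAt(vh, m$position))
        vh else vh_base
      mvh <- applyMutations(ref, m); mvl <- vl
    } else {
      mvh <- vh; mvl <- applyMutations(vl, m)
    }
    deltas[i, ] <- vapply(predictors, function(f) f(mvh, mvl),
                          numeric(1)) - base
  }
  ok <- apply(deltas < 0, 1, any)
  cands$score_delta <- deltas[, 1]
  cands$pass_score_reduction <- if (config$require_score_reduction) ok
                                else rep(TRUE, nrow(cands))
  .add_reason(cands, !cands$pass_score_reduction, "no_predictor_score_reduction")
}

#' Extract the accepted candidate set
#'
#' A candidate is accepted when it passes every filter that has been run
#' (all `pass_*` columns `TRUE`).  Because each filter is a pure predicate
#' contributing its own column, the accepted set does not depend on filter
#' order.
#'
#' @param cands a candidate frame after one or more filters.
#' @return The accepted subset, rows in original order.
#' @export
acceptedCandidates <- function(cands) {
  pcols <- grep("^pass_", names(cands), value = TRUE)
  if (!length(pcols)) return(cands)
  keep <- Reduce(`&`, cands[pcols])
  cands[keep, , drop = FALSE]
}

.append_obligatory <- function(tokens, obligatory) {
  if (is.null(obligatory) || !nzchar(obligatory)) return(tokens)
  if (obligatory %in% tokens) tokens else c(tokens, obligatory)
}

.token_string <- function(tokens, chain) {
  if (!length(tokens)) return("")
  muts <- do.call(rbind, lapply(tokens, parseMutations, chain = chain))
  formatMutations(.order_mutations(muts))
}

#' Prioritise accepted candidates and emit variant designs
#'
#' Ranks the accepted candidates — negative-patch-proximal sites first, then
#' by charge gain and score reduction — and emits variant definitions: every
#' accepted candidate as a single-chain design, plus one combined design
#' crossing the top heavy-chain candidates with the top light-chain
#' candidates (counts, or explicit selections, from the configuration).  The
#' obligatory heavy-chain mutation (glycation-risk removal K94R by default)
#' is appended exactly once to every design that mutates the heavy chain.
#'
#' @param cands a filtered candidate frame.
#' @param config a [designConfig()].
#' @return A list of class `DesignReport` with elements `candidates` (full
#'   trace), `accepted`, `combinations` (data frame `name`, `heavy_chain`,
#'   `light_chain`) and `config`.
#' @export
prioritizeAndCombine <- function(cands, config = designConfig()) {
  acc <- acceptedCandidates(cands)
  ord <- order(!acc$near_negative_patch, -acc$charge_delta,
               if (!is.null(acc$score_delta)) acc$score_delta
               else numeric(nrow(acc)))
  acc <- acc[ord, , drop = FALSE]

  obl <- config$obligatory_hc
  designs <- list()
  for (i in seq_len(nrow(acc))) {
    tok <- .mut_token(acc[i, ])
    if (acc$chain[i] == "H") {
      hc <- .token_string(.append_obligatory(tok, obl), "H"); lc <- ""
    } else {
      hc <- ""; lc <- .token_string(tok, "L")
    }
    designs[[length(designs) + 1L]] <-
      data.frame(name = sprintf("D-%03d", i), heavy_chain = hc,
                 light_chain = lc, stringsAsFactors = FALSE)
  }

  top_tokens <- function(chain_code, n, override) {
    if (!is.null(override)) return(override)
    sub <- acc[acc$chain == chain_code, , drop = FALSE]
    sub <- sub[!duplicated(sub$position), , drop = FALSE]
    utils::head(.mut_token(sub), n)
  }
  hc_tok <- top_tokens("H", config$n_combine_hc, config$combine_hc)
  lc_tok <- top_tokens("L", config$n_combine_lc, config$combine_lc)
  if (length(hc_tok) && length(lc_tok)) {
    designs[[length(designs) + 1L]] <- data.frame(
      name = "D-combo",
      heavy_chain = .token_string(.append_obligatory(hc_tok, obl), "H"),
      light_chain = .token_string(lc_tok, "L"),
      stringsAsFactors = FALSE)
  }
  combos <- if (length(designs)) do.call(rbind, designs)
            else data.frame(name = character(), heavy_chain = character(),
                            light_chain = character())
  structure(list(candidates = cands, accepted = acc, combinations = combos,
                 config = config),
            class = "DesignReport")
}

#' @export
print.DesignReport <- function(x, ...) {
  cat(sprintf("Design report: %d candidates, %d accepted, %d designs\n",
              nrow(x$candidates), nrow(x$accepted), nrow(x$combinations)))
  invisible(x)
}

#' Run a full design round
#'
#' Convenience orchestrator: enumerate, filter (tolerance, CDR rules,
#' germline, score reduction), prioritise and combine.
#'
#' @inheritParams enumerateCandidates
#' @param config a [designConfig()].
#' @param predictors passed to [filterScoreReduction()].
#' @return A `DesignReport`, see [prioritizeAndCombine()].
#'
#' @examples
#' p <- parentalChains()
#' tabs <- simulateCandidateTables(p$VH, p$VL, seed = 1,
#'                                 fraction_tolerated = 1)
#' rep <- runDesignRound(p$VH, p$VL, ddg = tabs$ddg, germline = tabs$germline)
#' rep
#' @export
runDesignRound <- function(vh, vl, ddg, germline,
                           patch_sites = negativePatchSites(),
                           config = designConfig(),
                           predictors = list(
                             sharma = function(vh, vl)
                               sharmaScore(vh, vl)$eta_pred)) {
  cands <- enumerateCandidates(vh, vl, ddg, germline, patch_sites)
  cands <- filterTolerated(cands, config)
  cands <- restrictCdrSubstitutions(cands, config)
  cands <- filterFrameworkByGermline(cands, config)
  cands <- filterScoreReduction(cands, vh, vl, predictors, config)
  prioritizeAndCombine(cands, config)
}

#' Serialise a design report to JSON
#'
#' Writes the full filter traces, the accepted set, the emitted designs and
#' the configuration snapshot.
#'
#' @param report a `DesignReport`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDesignReport <- function(report, path) {
  jsonlite::write_json(
    list(config = unclass(report$config),
         candidates = report$candidates,
         accepted = report$accepted,
         combinations = report$combinations),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
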