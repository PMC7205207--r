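## Charge model constants.  Side-chain pKa values (Asp 3.9, Glu 4.3, His 6.0,
## Lys 10.8, Arg 12.5) and the Eisenberg consensus hydrophobicity scale split
## into its hydrophobic (positive) and hydrophilic (negative) residue sets.

.PKA <- c(D = 3.9, E = 4.3, H = 6.0, K = 10.8, R = 12.5)
.IS_ACID <- c(D = TRUE, E = TRUE, H = FALSE, K = FALSE, R = FALSE)

.HYDROPHOBIC <- c(A = 0.62, C = 0.29, F = 1.19, G = 0.48, I = 1.38, L = 1.06,
                  M = 0.64, P = 0.12, V = 1.08, W = 0.81, Y = 0.26)
.HYDROPHILIC <- c(D = -0.90, E = -0.74, H = -0.40, K = -1.50, N = -0.78,
                  Q = -0.85, R = -2.53, S = -0.18, T = -0.05)

## Sequence-based viscosity score coefficients:
## log10(eta) = 0.15 + 1.26*HI - 0.043*q - 0.02*qsym
.SHARMA_COEF <- c(intercept = 0.15, hi = 1.26, q = -0.043, qsym = -0.02)

#' Charge and hydrophobicity constants
#'
#' `pkaTable()` returns the side-chain pKa values used by the charge model,
#' with an `acid` attribute marking Asp/Glu (negative when deprotonated) as
#' opposed to His/Lys/Arg (positive when protonated).  `eisenbergScale()`
#' returns the Eisenberg consensus hydrophobicity values as a list with the
#' disjoint `hydrophobic` (score > 0) and `hydrophilic` (score < 0) residue
#' sets that together cover all 20 canonical residues.
#'
#' @return See description.
#' @export
pkaTable <- function() {
  out <- .PKA
  attr(out, "acid") <- .IS_ACID
  out
}

#' @rdname pkaTable
#' @export
eisenbergScale <- function() {
  list(hydrophobic = .HYDROPHOBIC, hydrophilic = .HYDROPHILIC)
}

#' Fractional side-chain charge of a residue
#'
#' Henderson-Hasselbalch fractional charges for the five ionizable side
#' chains: acids contribute \eqn{-1/(1+10^{pKa-pH})} and bases
#' \eqn{+1/(1+10^{pH-pKa})}; all other canonical residues contribute zero.
#' Terminal amine/carboxyl groups are not modelled (side chains only).
#'
#' @param aa character vector of one-letter residue codes.
#' @param pH solution pH, in (0, 14).
#' @return Numeric vector of fractional charges (elementary-charge units).
#'
#' @examples
#' residueCharge("D", 5.5)   # mostly deprotonated aspartate
#' residueCharge("H", 7.4)   # mostly neutral histidine
#' @export
residueCharge <- function(aa, pH = 5.5) {
  stopifnot(is.numeric(pH), length(pH) == 1L, pH > 0, pH < 14)
  aa <- toupper(aa)
  bad <- setdiff(unique(aa), .AA1)
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  out <- numeric(length(aa))
  ion <- aa %in% names(.PKA)
  if (any(ion)) {
    pka <- .PKA[aa[ion]]
    acid <- .IS_ACID[aa[ion]]
    out[ion] <- ifelse(acid,
                       -1 / (1 + 10^(pka - pH)),
                       1 / (1 + 10^(pH - pka)))
  }
  out
}

.as_residues <- function(x) {
  if (is(x, "NumberedChain")) return(x@residues)
  if (is.character(x) && length(x) == 1L) return(strsplit(toupper(x), "")[[1]])
  toupper(as.character(x))
}

#' Net side-chain charge of a chain
#'
#' Sum of [residueCharge()] over all residues of the chain.
#'
#' @param chain a [NumberedChain-class] or a plain amino-acid string.
#' @param pH solution pH.
#' @return Net charge in elementary-charge units.
#' @export
chainCharge <- function(chain, pH = 5.5) {
  sum(residueCharge(.as_residues(chain), pH))
}

#' Fv net charge and charge asymmetry
#'
#' Computes the VH and VL net side-chain charges at the given pH, their sum
#' (the Fv net charge, q) and their product (the charge asymmetry, qsym).
#' A negative qsym indicates oppositely charged domains, a configuration
#' associated with self-association at high concentration.
#'
#' @param vh,vl the heavy and light variable-domain chains
#'   ([NumberedChain-class] or plain strings).
#' @param pH solution pH; 5.5 is the formulation pH used for all packaged
#'   scores.
#' @return An object of class `FvChargeReport`: a list with elements `q_vh`,
#'   `q_vl`, `q`, `qsym`, `pH`.
#'
#' @examples
#' p <- parentalChains()
#' fvCharge(p$VH, p$VL)
#' @export
fvCharge <- function(vh, vl, pH = 5.5) {
  q_vh <- chainCharge(vh, pH)
  q_vl <- chainCharge(vl, pH)
  structure(list(q_vh = q_vh, q_vl = q_vl, q = q_vh + q_vl,
                 qsym = q_vh * q_vl, pH = pH),
            class = "FvChargeReport")
}

#' @export
print.FvChargeReport <- function(x, ...) {
  cat(sprintf("Fv charge report (pH %.2f)\n", x$pH))
  cat(sprintf("  q(VH) = %+.3f   q(VL) = %+.3f\n", x$q_vh, x$q_vl))
  cat(sprintf("  q     = %+.3f   qsym  = %+.3f\n", x$q, x$qsym))
  invisible(x)
}

#' Hydrophobicity index of an Fv
#'
#' Ratio of the summed Eisenberg scores of the hydrophobic residues of
#' VH + VL to the magnitude of the summed scores of the hydrophilic residues.
#' Always positive; errors if the Fv contains no hydrophilic residue (the
#' denominator would vanish).
#'
#' @inheritParams fvCharge
#' @return The dimensionless hydrophobicity index.
#' @export
hydrophobicityIndex <- function(vh, vl) {
  aa <- c(.as_residues(vh), .as_residues(vl))
  bad <- setdiff(unique(aa), .AA1)
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  hb <- sum(.HYDROPHOBIC[aa[aa %in% names(.HYDROPHOBIC)]])
  hl <- sum(.HYDROPHILIC[aa[aa %in% names(.HYDROPHILIC)]])
  if (hl == 0)
    stop("chain pair has no hydrophilic residues; hydrophobicity index undefined")
  hb / abs(hl)
}

#' Sequence-based viscosity score
#'
#' Predicted high-concentration viscosity from sequence alone:
#' \deqn{\eta_{pred} = 10^{\,0.15 + 1.26\,HI - 0.043\,q - 0.02\,q_{sym}}}
#' with the Fv net charge q and charge asymmetry qsym evaluated at pH 5.5 and
#' the hydrophobicity index HI computed over the full Fv (VH + VL).  Being a
#' power of ten the score is strictly positive; it decreases with increasing
#' net charge and with decreasing charge asymmetry magnitude.
#'
#' @inheritParams fvCharge
#' @return An object of class `SharmaScore`: a list with elements `hi`, `q`,
#'   `qsym`, `eta_pred` (cP) and `coefficients`.
#'
#' @examples
#' p <- parentalChains()
#' sharmaScore(p$VH, p$VL)$eta_pred
#' @export
sharmaScore <- function(vh, vl) {
  fc <- fvCharge(vh, vl, pH = 5.5)
  hi <- hydrophobicityIndex(vh, vl)
  log_eta <- .SHARMA_COEF[["intercept"]] + .SHARMA_COEF[["hi"]] * hi +
    .SHARMA_COEF[["q"]] * fc$q + .SHARMA_COEF[["qsym"]] * fc$qsym
  structure(list(hi = hi, q = fc$q, qsym = fc$qsym,
                 eta_pred = 10^log_eta, coefficients = .SHARMA_COEF),
            class = "SharmaScore")
}

#' @export
print.SharmaScore <- function(x, ...) {
  cat(sprintf("Sequence viscosity score: %.2f cP (HI %.3f, q %+.2f, qsym %+.2f)\n",
              x$eta_pred, x$hi, x$q, x$qsym))
  invisible(x)
}

#' Net CDR charge at physiological pH
#'
#' Sums the Henderson-Hasselbalch side-chain charges at pH 7.4 over the six
#' CDRs, a developability flag for non-specificity risk: a net positive CDR
#' charge has been associated with increased red flags in polyreactivity and
#' self-association assays.  CDR limits default to Kabat but are
#' configurable, since published CDR-charge values depend on the boundary
#' convention of their source.
#'
#' @inheritParams fvCharge
#' @param pH solution pH (default 7.4).
#' @param boundaries CDR boundary set, see [kabatCdrBoundaries()].
#' @return An object of class `CdrChargeReport`: a list with the `net` charge
#'   and the `per_cdr` contributions (named H-CDR1..3, L-CDR1..3).
#' @export
cdrCharge <- function(vh, vl, pH = 7.4, boundaries = kabatCdrBoundaries()) {
  stopifnot(is(vh, "NumberedChain"), is(vl, "NumberedChain"))
  per <- c()
  for (ch in list(vh, vl)) {
    reg <- annotateRegions(ch, boundaries)
    pre <- if (chainRole(ch) == "VH") "H-" else "L-"
    for (cdr in c("CDR1", "CDR2", "CDR3")) {
      aa <- reg$residue[reg$region == cdr]
      per[paste0(pre, cdr)] <- sum(residueCharge(aa, pH))
    }
  }
  structure(list(net = sum(per), per_cdr = per, pH = pH),
            class = "CdrChargeReport")
}

#' @export
print.CdrChargeReport <- function(x, ...) {
  cat(sprintf("Net CDR charge at pH %.1f: %+.2f\n", x$pH, x$net))
  print(round(x$per_cdr, 3))
  invisible(x)
}

#' Score every variant of a panel
#'
#' Batch scorer: builds each variant of the panel from its mutation strings
#' and recomputes the full set of sequence scores.  This is the package's
#' regression surface against the packaged panel: the recomputed `q` column
#' reproduces the published Fv-charge column within +/-0.01 for every row.
#'
#' @param panel a panel data frame, see [variantPanel()].
#' @param cdr logical; also compute the pH-7.4 net CDR charge (slightly
#'   slower).
#' @return A data frame with one row per variant: `name`, `q_vh`, `q_vl`,
#'   `q`, `qsym`, `hi`, `sharma_score` and (optionally) `cdr_charge`.
#' @export
scoreVariantPanel <- function(panel = variantPanel(), cdr = FALSE) {
  rows <- lapply(panel$name, function(nm) {
    ch <- buildVariant(nm, panel)
    fc <- fvCharge(ch$VH, ch$VL)
    sc <- sharmaScore(ch$VH, ch$VL)
    out <- data.frame(name = nm, q_vh = fc$q_vh, q_vl = fc$q_vl, q = fc$q,
                      qsym = fc$qsym, hi = sc$hi, sharma_score = sc$eta_pred,
                      stringsAsFactors = FALSE)
    if (cdr) out$cdr_charge <- cdrCharge(ch$VH, ch$VL)$net
    out
  })
  do.call(rbind, rows)
}
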