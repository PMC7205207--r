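## Seeded synthetic-data generators.  These emulate the two external inputs
## of the workflow that are not shipped with the package: raw cone-and-plate
## concentration-viscosity series, and the candidate-level prediction tables
## (stability/affinity changes and germline amino-acid frequencies) that an
## external structure-based predictor would provide.

#' Simulate a concentration-viscosity curve
#'
#' Draws a noisy Ross-Minton curve: at each grid concentration, `replicates`
#' measurements are generated as the true model value times a log-normal
#' multiplicative error (`exp(N(0, rel_sd^2))`), then averaged, with the
#' replicate standard deviation reported per point.  Multiplicative noise
#' reflects cone-and-plate practice — measurement error scales with the
#' reading — and keeps viscosities positive.  Defaults emulate a serial
#' dilution of a moderately viscous antibody over the 25-160 mg/ml range
#' (true \eqn{[\eta]} = 0.010 ml/mg, k/v = 0.45, so the 20 cP crossing lies
#' near 126 mg/ml), measured in duplicate at 2% relative error.
#'
#' @param concentrations measurement grid, mg/ml; all points must lie below
#'   the singular concentration of the true parameters.
#' @param intrinsic_viscosity,k_over_v,eta0 true model parameters.
#' @param rel_sd relative (log-scale) standard deviation of one measurement.
#' @param replicates measurements per concentration.
#' @param seed optional integer seed; the same seed reproduces the curve
#'   exactly.
#' @param molecule molecule name for the output.
#' @return A `ViscosityCurve` data frame (see [viscosityCurve()]) with the
#'   true parameters attached as attribute `"truth"`.
#'
#' @examples
#' curve <- simulateViscosityCurve(seed = 7)
#' coef(fitRossMinton(curve))
#' @export
simulateViscosityCurve <- function(concentrations = seq(25, 160,
                                                        length.out = 8),
                                   intrinsic_viscosity = 0.010,
                                   k_over_v = 0.45, eta0 = 1.1,
                                   rel_sd = 0.02, replicates = 2,
                                   seed = NULL,
                                   molecule = "synthetic") {
  stopifnot(rel_sd >= 0, replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  mu <- rossMintonViscosity(concentrations, intrinsic_viscosity, k_over_v,
                            eta0)   # errors beyond the singularity
  reps <- matrix(mu, nrow = length(mu), ncol = replicates) *
    exp(matrix(stats::rnorm(length(mu) * replicates, 0, rel_sd),
               nrow = length(mu)))
  curve <- viscosityCurve(concentrations, rowMeans(reps),
                          sd = apply(reps, 1, stats::sd), n = replicates,
                          molecule = molecule)
  attr(curve, "truth") <- c(intrinsic_viscosity = intrinsic_viscosity,
                            k_over_v = k_over_v, eta0 = eta0)
  curve
}

#' Generate surrogate prediction tables for the design pipeline
#'
#' Builds the two tables the mutation triage consumes, with controllable
#' pass/fail structure so every filter has positive and negative cases:
#'
#' * a stability/affinity table covering every net-positive charge-change
#'   candidate of the two chains: a `fraction_tolerated` share of sites
#'   draws both changes uniformly below the 1 kcal/mol tolerance, the rest
#'   above it (interface-flagged sites draw in the 1-2 kcal/mol band
#'   explored for round-2 patch designs);
#' * a germline frequency table for all framework sites: a
#'   `fraction_permissive` share of sites receives Lys/Arg (and, for acidic
#'   wild types, neutral-alternative) frequencies above the 10% threshold,
#'   the rest below it.
#'
#' Tables are exactly reproducible for a given seed.  Writing them with
#' [utils::write.csv()] gives the CSV layout [enumerateCandidates()] reads
#' back (`chain`, `position`, `wt`, `mut`, `ddg_binding`, `ddg_stability`,
#' `interface` / `chain`, `position`, `residue`, `frequency`).
#'
#' @param vh,vl parental chains.
#' @param seed integer seed.
#' @param fraction_tolerated share of sites whose substitutions are
#'   predicted tolerated.
#' @param fraction_permissive share of framework sites with germline
#'   frequencies above threshold.
#' @param interface_positions optional character vector of `"H:pos"` /
#'   `"L:pos"` site keys flagged as binding-interface residues.
#' @return A list with data frames `ddg` and `germline`.
#' @export
simulateCandidateTables <- function(vh, vl, seed = 1,
                                    fraction_tolerated = 0.8,
                                    fraction_permissive = 0.7,
                                    interface_positions = NULL) {
  set.seed(seed)
  base <- enumerateCandidates(vh, vl, ddg = NULL, germline = NULL)
  sites <- unique(base[c("chain", "position", "wt")])
  skey <- paste(sites$chain, sites$position, sep = ":")
  tolerated <- stats::runif(nrow(sites)) < fraction_tolerated
  interface <- skey %in% interface_positions

  ckey <- paste(base$chain, base$position, sep = ":")
  idx <- match(ckey, skey)
  n <- nrow(base)
  lo <- stats::runif(n, 0, 0.9)
  mid <- stats::runif(n, 1.05, 2)
  hi <- stats::runif(n, 2.5, 6)
  pick <- ifelse(tolerated[idx], 1L, ifelse(interface[idx], 2L, 3L))
  ddg <- data.frame(chain = base$chain, position = base$position,
                    wt = base$wt, mut = base$mut,
                    ddg_binding = cbind(lo, mid, hi)[cbind(seq_len(n), pick)],
                    ddg_stability = stats::runif(n, 0, 0.9),
                    interface = interface[idx],
                    stringsAsFactors = FALSE)
  ddg$ddg_stability[pick == 3L] <- stats::runif(sum(pick == 3L), 1.5, 4)

  fw_rows <- function(chain) {
    reg <- annotateRegions(chain)
    reg[!grepl("^CDR", reg$region), , drop = FALSE]
  }
  fw <- rbind(cbind(chain = "H", fw_rows(vh)),
              cbind(chain = "L", fw_rows(vl)))
  permissive <- stats::runif(nrow(fw)) < fraction_permissive
  gl <- lapply(seq_len(nrow(fw)), function(i) {
    wt <- fw$residue[i]
    pos_f <- if (permissive[i]) stats::runif(1, 0.15, 0.6)
             else stats::runif(1, 0, 0.045)
    alt_f <- if (permissive[i]) stats::runif(1, 0.15, 0.6)
             else stats::runif(1, 0, 0.045)
    res <- c("K", "R", "Q", wt)
    freq <- c(pos_f / 2, pos_f / 2, alt_f,
              max(0, 1 - pos_f - alt_f))
    data.frame(chain = fw$chain[i], position = fw$position[i],
               residue = res, frequency = freq, stringsAsFactors = FALSE)
  })
  germline <- do.call(rbind, gl)
  ## a wild-type K/R/Q row would duplicate a synthetic row; aggregate
  key <- paste(germline$chain, germline$position, germline$residue)
  germline <- stats::aggregate(frequency ~ chain + position + residue,
                               germline, sum)
  list(ddg = ddg, germline = germline)
}
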