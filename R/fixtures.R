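## Packaged study data: the parental anti-PDGF-BB antibody (AB-001) VH/VL
## sequences with their Kabat numbering maps, the published 38-variant design
## panel with its in-silico scores and fitted viscosity endpoints, the
## non-specificity panel for the top clones, and the negative-charge-patch
## site flags used by the design pipeline.

## Embedded linear sequences used as a checksum for the numbering CSVs: the
## fixture loader refuses to return a map whose residues do not concatenate
## to these exactly.
.AB001_VH <- paste0(
  "EVQLLESGGGLVQPGGSLRLSCAASGFTFSSYAMSWVRQAPGKGLEWVSYISDDGSLKYY",
  "ADSVKGRFTISRDNSKNTLYLQMNSLRAEDTAVYYCAKHPYWYGGQLDLWGQGTLVTVSS")
.AB001_VL <- paste0(
  "SYELTQPPSVSVSPGQTASITCSGDSLGSYFVHWYQQKPGQSPVLVIYDDSNRPSGIPER",
  "FSGSNSGNTATLTISGTQAMDEADYYCSAFTHNSDVFGGGTKLTVL")

## FR1 of the lambda germline IGLV3-21*01 (22 residues, ungapped), the
## framework used to remove the light-chain N-terminal clipping liability.
.IGLV3_21_FR1 <- "SYVLTQPPSVSVAPGKTARITC"

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "AbViscosity",
                      mustWork = FALSE)
  if (!nzchar(path))
    path <- file.path("inst", "extdata", file)  # pre-install convenience
  if (!file.exists(path)) stop("fixture not found: ", file)
  path
}

.read_numbering <- function(file, role, expected) {
  map <- utils::read.csv(.extdata(file), stringsAsFactors = FALSE,
                         colClasses = "character")
  seq <- paste(map$residue, collapse = "")
  if (!identical(seq, expected))
    stop("numbering fixture ", file,
         " does not reproduce the embedded parental sequence")
  NumberedChain(role, map$residue, positions = map$position)
}

#' Parental antibody chains with Kabat numbering
#'
#' Loads the parental anti-PDGF-BB VH (120 aa) and VL (106 aa, lambda)
#' domains from the packaged numbering fixtures.  The heavy chain carries
#' Kabat insertion codes 52a, 82a-c and 100a-c; the lambda light chain has
#' the canonical Kabat gap at position 10 (so linear residue 10 is labelled
#' 11).  The loader checks the fixture against embedded reference sequences
#' and errors on any discrepancy; the assignment itself is validated by the
#' panel-wide wild-type checks of the test suite (every published mutation
#' string applies without a wild-type mismatch).
#'
#' @return A list with elements `VH` and `VL`, both [NumberedChain-class].
#'
#' @examples
#' p <- parentalChains()
#' residueAt(p$VH, "52a")   # "D": the CDR-H2 patch aspartate
#' residueAt(p$VL, "53")    # "N": the key CDR-L2 site
#' @export
parentalChains <- function() {
  list(VH = .read_numbering("ab001_vh_kabat.csv", "VH", .AB001_VH),
       VL = .read_numbering("ab001_vl_kabat.csv", "VL", .AB001_VL))
}

#' Germline FR1 sequence for the light-chain framework swap
#'
#' @return The 22-residue FR1 of lambda germline IGLV3-21*01.
#' @export
germlineFR1 <- function() .IGLV3_21_FR1

#' The packaged design panel
#'
#' `variantPanel()` returns the published 38-variant panel: variant names,
#' heavy/light mutation strings (verbatim, Kabat coordinates), the published
#' Fv charge and the three reference viscosity predictors (sequence score,
#' structure-based score, spatial charge map), plus the Ross-Minton-fitted
#' viscosity endpoints (viscosity at 100 and 150 mg/ml with extrapolation
#' flags, and the concentration at which viscosity reaches 20 cP).  A
#' `round` column (`parental`/`R1`/`R2`) is derived from the variant names.
#' `nonspecificityPanel()` returns the non-specificity panel for the five
#' top clones (net CDR charge at pH 7.4, DNA/insulin ELISA and AC-SINS
#' self-association scores).
#'
#' Two second-round designs (R2-002, R2-003) precipitated during
#' concentration and have no viscosity columns; they are absent from the
#' panel.
#'
#' @return A data frame; see Description.
#' @export
variantPanel <- function() {
  panel <- utils::read.csv(.extdata("variant_panel.csv"),
                           stringsAsFactors = FALSE)
  panel$round <- ifelse(panel$name == "AB-001", "parental",
                        ifelse(grepl("^R1-", panel$name), "R1", "R2"))
  panel
}

#' @rdname variantPanel
#' @export
nonspecificityPanel <- function() {
  utils::read.csv(.extdata("nonspecificity_panel.csv"),
                  stringsAsFactors = FALSE)
}

#' Negative-charge-patch site flags
#'
#' Kabat positions flagged as belonging to (or bordering) the surface
#' negative-charge patches of the parental antibody: the CDR-L2-centred
#' light-chain patch (L49-L53, L96) and the heavy-chain patch around CDR-H2
#' (H52a, H53, H61).  These flags are an input annotation for design
#' prioritisation; they were derived from electrostatic surface maps, which
#' this package does not compute.
#'
#' @return A data frame with columns `chain` (`"H"`/`"L"`) and `position`.
#' @export
negativePatchSites <- function() {
  utils::read.csv(.extdata("negative_patch_sites.csv"),
                  stringsAsFactors = FALSE,
                  colClasses = c("character", "character"))
}

## ---- variant construction --------------------------------------------------

.resolve_chain <- function(spec, which, base, panel) {
  alias <- regmatches(spec, regexec("^(.+)_(HC|LC)$", spec))[[1]]
  if (length(alias) == 3L) {
    ref <- alias[2]
    slot <- if (alias[3] == "HC") "VH" else "VL"
    return(buildVariant(ref, panel)[[slot]])
  }
  chain_code <- if (which == "VH") "H" else "L"
  applyMutations(base[[which]], parseMutations(spec, chain_code))
}

#' Build a variant's chains from the panel
#'
#' Resolves a panel row to fully mutated VH/VL chains.  Mutation strings are
#' applied to the round's base molecule: round-1 strings are relative to the
#' parental AB-001 chains, round-2 strings relative to R2-001.  Aliases of
#' the form `<name>_HC` / `<name>_LC` resolve recursively through the panel.
#' R2-001 itself is defined as the R1-016 chains with the light-chain FR1
#' replaced by the IGLV3-21*01 germline framework (see [swapFramework1()]).
#'
#' Every application is wild-type-checked, so a successful build certifies
#' the numbering fixture for that variant's sites.
#'
#' @param name a variant name present in the panel, or `"AB-001"`.
#' @param panel the design panel (default [variantPanel()]).
#' @return A list with elements `VH` and `VL` ([NumberedChain-class]).
#'
#' @examples
#' v <- buildVariant("R1-016")
#' residueAt(v$VH, "6")   # "Q" after E6Q
#' @export
buildVariant <- function(name, panel = variantPanel()) {
  if (name == "AB-001") return(parentalChains())
  if (name == "R2-001") {
    base <- buildVariant("R1-016", panel)
    fw1 <- swapFramework1(base$VL, .IGLV3_21_FR1)
    return(list(VH = base$VH, VL = applyMutations(base$VL, fw1)))
  }
  row <- panel[panel$name == name, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown variant: ", name)
  base_name <- if (grepl("^R2-", name)) "R2-001" else "AB-001"
  base <- buildVariant(base_name, panel)
  list(VH = .resolve_chain(row$heavy_chain, "VH", base, panel),
       VL = .resolve_chain(row$light_chain, "VL", base, panel))
}
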