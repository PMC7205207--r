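#' @import methods
NULL

.AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' NumberedChain: a scheme-numbered antibody variable domain
#'
#' An immunoglobulin variable-domain chain stored as an ordered set of
#' (position label, residue) pairs.  Position labels follow an antibody
#' numbering scheme (Kabat for everything shipped with this package), so they
#' include insertion codes such as `"52a"` or `"100b"` and may skip integers
#' (lambda light chains have no residue at Kabat position 10).  Keeping the
#' labels with the sequence is what allows mutations published in scheme
#' coordinates to be applied and validated against their stated wild-type
#' residues.
#'
#' @slot role chain role, `"VH"` (heavy variable) or `"VL"` (light variable).
#' @slot positions character vector of unique position labels, in sequence
#'   order.
#' @slot residues character vector of one-letter amino-acid codes, parallel to
#'   `positions`.
#' @slot scheme numbering scheme name; `"kabat"` for the packaged fixtures.
#'
#' @seealso [NumberedChain()], [applyMutations()], [annotateRegions()]
#' @exportClass NumberedChain
setClass("NumberedChain",
  representation(
    role = "character",
    positions = "character",
    residues = "character",
    scheme = "character"
  )
)

setValidity("NumberedChain", function(object) {
  msg <- character()
  if (length(object@role) != 1L || !object@role %in% c("VH", "VL"))
    msg <- c(msg, "role must be \"VH\" or \"VL\"")
  if (length(object@positions) != length(object@residues))
    msg <- c(msg, "positions and residues must have equal length")
  if (anyDuplicated(object@positions))
    msg <- c(msg, "position labels must be unique")
  bad <- setdiff(unique(object@residues), .AA1)
  if (length(bad))
    msg <- c(msg, paste0("non-canonical residue code(s): ",
                         paste(bad, collapse = ", ")))
  if (length(object@scheme) != 1L)
    msg <- c(msg, "scheme must be a single string")
  if (length(msg)) msg else TRUE
})

#' RossMintonFit: a fitted concentration-viscosity model
#'
#' Holds the two free parameters of the Ross-Minton equation
#' \deqn{\eta(c) = \eta_0 \exp\!\left(\frac{[\eta]\,c}{1 - (k/\nu)[\eta]\,c}\right)}
#' estimated from a concentration-viscosity curve: the intrinsic viscosity
#' \eqn{[\eta]} (ml/mg) and the crowding-to-shape factor ratio \eqn{k/\nu}
#' (dimensionless; the two factors enter only through their ratio).  The
#' solvent viscosity \eqn{\eta_0} is held fixed during fitting.
#'
#' @slot eta0 solvent viscosity (cP), fixed during fitting.
#' @slot intrinsicViscosity estimated intrinsic viscosity (ml/mg).
#' @slot kOverV estimated crowding/shape factor ratio (dimensionless).
#' @slot rSquared coefficient of determination on the untransformed cP scale.
#' @slot covariance 2x2 parameter covariance matrix from the nonlinear
#'   least-squares fit (order: intrinsic viscosity, k/v).
#' @slot df residual degrees of freedom.
#' @slot scale the scale the residuals were minimised on, `"log"` or
#'   `"linear"`.
#' @slot converged logical convergence flag.
#' @slot iterations iteration count reported by the optimiser.
#' @slot curve the (concentration, viscosity) data the model was fitted to.
#'
#' @seealso [fitRossMinton()], [predictViscosity()],
#'   [concentrationAtThreshold()]
#' @exportClass RossMintonFit
setClass("RossMintonFit",
  representation(
    eta0 = "numeric",
    intrinsicViscosity = "numeric",
    kOverV = "numeric",
    rSquared = "numeric",
    covariance = "matrix",
    df = "integer",
    scale = "character",
    converged = "logical",
    iterations = "integer",
    curve = "data.frame"
  )
)

setValidity("RossMintonFit", function(object) {
  msg <- character()
  if (object@eta0 <= 0) msg <- c(msg, "eta0 must be positive")
  if (object@intrinsicViscosity <= 0)
    msg <- c(msg, "intrinsic viscosity must be positive")
  if (object@kOverV < 0) msg <- c(msg, "k/v must be non-negative")
  if (!identical(dim(object@covariance), c(2L, 2L)))
    msg <- c(msg, "covariance must be a 2x2 matrix")
  if (length(msg)) msg else TRUE
})
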