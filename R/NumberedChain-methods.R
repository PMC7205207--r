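#' Construct a NumberedChain
#'
#' @param role `"VH"` or `"VL"`.
#' @param residues amino-acid sequence, either a single string or a character
#'   vector of one-letter codes.
#' @param positions character vector of position labels, parallel to the
#'   residues.  Defaults to plain sequential numbering `"1"`, `"2"`, ... which
#'   is appropriate for ad-hoc sequences; use the packaged Kabat maps (see
#'   [parentalChains()]) for antibody work in published coordinates.
#' @param scheme numbering scheme name (default `"kabat"`).
#'
#' @return A [NumberedChain-class] object.
#'
#' @examples
#' ch <- NumberedChain("VL", "SYELTQ")
#' chainSequence(ch)
#' residueAt(ch, "3")
#' @export
NumberedChain <- function(role, residues, positions = NULL, scheme = "kabat") {
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(as.character(residues))
  if (is.null(positions))
    positions <- as.character(seq_along(residues))
  new("NumberedChain", role = role, positions = as.character(positions),
      residues = residues, scheme = scheme)
}

#' Accessors for NumberedChain objects
#'
#' `chainRole()` returns `"VH"` or `"VL"`; `positionLabels()` the ordered
#' position labels; `chainSequence()` the plain linear amino-acid string;
#' `residueAt()` the one-letter residue at a given position label.
#'
#' @param x a [NumberedChain-class].
#' @param label a position label, e.g. `"53"` or `"52a"`.
#' @name NumberedChain-accessors
NULL

#' @rdname NumberedChain-accessors
#' @export
setMethod("chainRole", "NumberedChain", function(x) x@role)

#' @rdname NumberedChain-accessors
#' @export
setMethod("positionLabels", "NumberedChain", function(x) x@positions)

#' @rdname NumberedChain-accessors
#' @export
setMethod("chainSequence", "NumberedChain",
          function(x) paste(x@residues, collapse = ""))

#' @rdname NumberedChain-accessors
#' @export
setMethod("residueAt", "NumberedChain", function(x, label) {
  i <- match(as.character(label), x@positions)
  if (anyNA(i))
    stop("unknown position label(s): ",
         paste(label[is.na(i)], collapse = ", "))
  x@residues[i]
})

#' @export
setMethod("length", "NumberedChain", function(x) length(x@residues))

#' @export
setMethod("as.character", "NumberedChain", function(x) chainSequence(x))

setMethod("show", "NumberedChain", function(object) {
  cat(sprintf("NumberedChain (%s, %s scheme, %d residues)\n",
              object@role, object@scheme, length(object@residues)))
  s <- chainSequence(object)
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(" ", s, "\n")
})

## ---- mutation application --------------------------------------------------

#' Apply point substitutions to a numbered chain
#'
#' Replaces residues at the given position labels, after checking that the
#' residue currently at each label equals the stated wild type.  The wild-type
#' check is deliberately strict: it is what validates a numbering fixture
#' against mutations published in scheme coordinates.
#'
#' @param chain a [NumberedChain-class].
#' @param mutations a mutation data frame as returned by [parseMutations()]
#'   (columns `position`, `wt`, `mut`; a `chain` column, if present, is
#'   ignored here).  An empty frame returns the chain unchanged.
#'
#' @return A new [NumberedChain-class] with the substitutions applied; labels
#'   and length are unchanged.
#'
#' @examples
#' vl <- parentalChains()$VL
#' mut <- applyMutations(vl, parseMutations("N53K", "L"))
#' residueAt(mut, "53")
#' @export
applyMutations <- function(chain, mutations) {
  stopifnot(is(chain, "NumberedChain"))
  if (NROW(mutations) == 0L) return(chain)
  res <- chain@residues
  idx <- match(mutations$position, chain@positions)
  if (anyNA(idx))
    stop("unknown position label(s): ",
         paste(mutations$position[is.na(idx)], collapse = ", "))
  found <- res[idx]
  bad <- found != mutations$wt
  if (any(bad))
    stop("wild-type mismatch at ",
         paste(sprintf("%s (expected %s, found %s)",
                       mutations$position[bad], mutations$wt[bad],
                       found[bad]), collapse = "; "))
  res[idx] <- mutations$mut
  initialize(chain, residues = res)
}

## ---- region annotation -----------------------------------------------------

#' Kabat CDR boundaries
#'
#' The classical Kabat complementarity-determining-region limits: heavy chain
#' CDR1 31-35, CDR2 50-65, CDR3 95-102; light chain CDR1 24-34, CDR2 50-56,
#' CDR3 89-97.  Positions with insertion codes (52a, 100b, ...) belong to the
#' region of their parent integer position.
#'
#' @return A list with elements `VH` and `VL`, each a 3x2 matrix of inclusive
#'   (start, end) integer bounds for CDR1-CDR3.
#' @export
kabatCdrBoundaries <- function() {
  list(
    VH = matrix(c(31, 35, 50, 65, 95, 102), ncol = 2, byrow = TRUE,
                dimnames = list(c("CDR1", "CDR2", "CDR3"), c("start", "end"))),
    VL = matrix(c(24, 34, 50, 56, 89, 97), ncol = 2, byrow = TRUE,
                dimnames = list(c("CDR1", "CDR2", "CDR3"), c("start", "end")))
  )
}

.label_number <- function(labels) {
  n <- suppressWarnings(as.integer(sub("[A-Za-z]+$", "", labels)))
  if (anyNA(n))
    stop("malformed position label(s): ",
         paste(labels[is.na(n)], collapse = ", "))
  n
}

#' Partition a chain into framework and CDR regions
#'
#' Assigns every position of the chain to one of FR1, CDR1, FR2, CDR2, FR3,
#' CDR3, FR4 under the configured CDR boundaries (Kabat by default).
#' Insertion codes inherit the region of their parent position, so Kabat
#' heavy-chain 52a falls in CDR2 and 100a-c in CDR3.
#'
#' @param chain a [NumberedChain-class].
#' @param boundaries CDR boundary set as produced by [kabatCdrBoundaries()].
#'
#' @return A data frame with columns `position`, `residue`, `region`, one row
#'   per chain position in order.  The regions partition the chain.
#' @export
annotateRegions <- function(chain, boundaries = kabatCdrBoundaries()) {
  stopifnot(is(chain, "NumberedChain"))
  b <- boundaries[[chainRole(chain)]]
  num <- .label_number(chain@positions)
  if (any(num < 1L) || any(num > 113L))
    stop("position label outside the numbering scheme range: ",
         paste(chain@positions[num < 1L | num > 113L], collapse = ", "))
  region <- rep("FR1", length(num))
  region[num >= b["CDR1", "start"] & num <= b["CDR1", "end"]] <- "CDR1"
  region[num > b["CDR1", "end"] & num < b["CDR2", "start"]] <- "FR2"
  region[num >= b["CDR2", "start"] & num <= b["CDR2", "end"]] <- "CDR2"
  region[num > b["CDR2", "end"] & num < b["CDR3", "start"]] <- "FR3"
  region[num >= b["CDR3", "start"] & num <= b["CDR3", "end"]] <- "CDR3"
  region[num > b["CDR3", "end"]] <- "FR4"
  data.frame(position = chain@positions, residue = chain@residues,
             region = region, stringsAsFactors = FALSE)
}

## ---- framework-1 germline swap ---------------------------------------------

#' Derive the substitutions implied by replacing framework 1 with a germline
#'
#' Aligns the chain's FR1 linear segment position-by-position (no gaps)
#' against a germline FR1 of the same length and returns the implied point
#' substitutions.  This realises framework germline swaps such as grafting a
#' lambda light chain onto the IGLV3-21*01 FR1 to remove an N-terminal
#' clipping liability.
#'
#' @param chain a [NumberedChain-class].
#' @param germline_fw1 germline FR1 amino-acid string; must have the same
#'   length as the chain's FR1 segment (gapped alignment is out of scope).
#' @param boundaries CDR boundary set, used to locate FR1.
#'
#' @return A mutation data frame (columns `chain`, `position`, `wt`, `mut`)
#'   ready for [applyMutations()]; zero rows if FR1 already matches.
#'
#' @examples
#' vl <- parentalChains()$VL
#' swapFramework1(vl, germlineFR1())
#' @export
swapFramework1 <- function(chain, germline_fw1,
                           boundaries = kabatCdrBoundaries()) {
  stopifnot(is(chain, "NumberedChain"))
  reg <- annotateRegions(chain, boundaries)
  fr1 <- reg$region == "FR1"
  gl <- strsplit(toupper(germline_fw1), "")[[1]]
  if (length(gl) != sum(fr1))
    stop(sprintf("germline FR1 length (%d) does not match the chain FR1 length (%d)",
                 length(gl), sum(fr1)))
  wt <- chain@residues[fr1]
  diff <- which(wt != gl)
  data.frame(
    chain = rep(if (chainRole(chain) == "VH") "H" else "L", length(diff)),
    position = chain@positions[fr1][diff],
    wt = wt[diff], mut = gl[diff], stringsAsFactors = FALSE)
}

## ---- FASTA I/O -------------------------------------------------------------

#' Read or write plain chain sequences as FASTA
#'
#' Thin wrappers around [Biostrings::readAAStringSet()] /
#' [Biostrings::writeXStringSet()].  The description line carries the chain
#' role as `name|role`, e.g. `AB-001_VH|VH`.  Reading returns plain
#' sequentially numbered chains; attach a numbering fixture separately when
#' scheme coordinates are required.
#'
#' @param path file path.
#' @param chains a named list of [NumberedChain-class] objects (for writing).
#' @return `readChainFasta()`: a named list of [NumberedChain-class] objects.
#' @export
readChainFasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(aas), function(i) {
    nm <- names(aas)[i]
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    role <- if (length(parts) > 1L && parts[2] %in% c("VH", "VL"))
      parts[2] else "VH"
    NumberedChain(role, as.character(aas[[i]]))
  })
  names(out) <- vapply(names(aas), function(nm)
    strsplit(nm, "|", fixed = TRUE)[[1]][1], character(1))
  out
}

#' @rdname readChainFasta
#' @export
writeChainFasta <- function(chains, path) {
  seqs <- Biostrings::AAStringSet(vapply(chains, chainSequence, character(1)))
  names(seqs) <- paste0(names(chains), "|",
                        vapply(chains, chainRole, character(1)))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
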