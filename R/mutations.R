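## Mutation strings are underscore-joined tokens <wt><label><mut>, the format
## used throughout published variant tables, e.g. "E6Q_Q13K_K94R".  Labels are
## scheme positions and may carry a one-letter insertion code ("D52aN").

.MUT_TOKEN <- "^([A-Za-z])([0-9]+[A-Za-z]?)([A-Za-z])$"

#' Parse an underscore-joined mutation string
#'
#' Each token has the form `<wt><position><mut>` with an optional insertion
#' code on the position (`"D52aN"`, `"Q100bK"`).  Tokens are case-insensitive;
#' residues are normalised to upper case and insertion codes to lower case.
#' A chain alias of the form `<variant>_HC` / `<variant>_LC` (for example
#' `"AB-001_LC"`) denotes "no mutations relative to that chain" and parses to
#' an empty mutation set carrying the alias as an attribute.
#'
#' @param spec the mutation string, e.g. `"E6Q_Q13K_K94R"`.
#' @param chain `"H"` or `"L"`: the chain the mutations apply to.
#'
#' @return A data frame with columns `chain`, `position`, `wt`, `mut`, one
#'   row per token in input order.  For an alias, a zero-row frame with
#'   attribute `"alias"` set to the alias string.
#'
#' @examples
#' parseMutations("E6Q_Q13K_K94R", "H")
#' parseMutations("D52aN_K94R", "H")
#' parseMutations("AB-001_LC", "L")   # alias: empty mutation set
#' @export
parseMutations <- function(spec, chain = c("H", "L")) {
  chain <- match.arg(chain)
  stopifnot(is.character(spec), length(spec) == 1L)
  empty <- data.frame(chain = character(), position = character(),
                      wt = character(), mut = character(),
                      stringsAsFactors = FALSE)
  if (grepl("_(HC|LC)$", spec)) {
    attr(empty, "alias") <- spec
    return(empty)
  }
  tokens <- strsplit(spec, "_", fixed = TRUE)[[1]]
  if (!length(tokens)) return(empty)
  m <- regmatches(tokens, regexec(.MUT_TOKEN, tokens))
  bad <- lengths(m) != 4L
  if (any(bad))
    stop("malformed mutation token(s): ", paste(tokens[bad], collapse = ", "))
  out <- do.call(rbind, lapply(m, function(g)
    data.frame(chain = chain,
               position = tolower(g[3]),
               wt = toupper(g[2]), mut = toupper(g[4]),
               stringsAsFactors = FALSE)))
  same <- out$wt == out$mut
  if (any(same))
    stop("wild-type equals mutant in token(s): ",
         paste(tokens[same], collapse = ", "))
  out
}

#' Render mutations back to an underscore-joined string
#'
#' Inverse of [parseMutations()]: `formatMutations(parseMutations(s))`
#' reproduces `s` for any well-formed mutation string.
#'
#' @param mutations a mutation data frame (columns `position`, `wt`, `mut`).
#' @return A single string, `""` for an empty mutation set.
#' @export
formatMutations <- function(mutations) {
  if (NROW(mutations) == 0L) return("")
  paste(paste0(mutations$wt, mutations$position, mutations$mut),
        collapse = "_")
}

#' Invert a mutation set
#'
#' Swaps wild-type and mutant residues, so that applying a mutation set and
#' then its inverse restores the original chain exactly.
#'
#' @param mutations a mutation data frame.
#' @return The inverted mutation data frame.
#' @export
invertMutations <- function(mutations) {
  if (NROW(mutations) == 0L) return(mutations)
  data.frame(chain = mutations$chain, position = mutations$position,
             wt = mutations$mut, mut = mutations$wt,
             stringsAsFactors = FALSE)
}

## order mutations by scheme position (integer part, then insertion code)
.order_mutations <- function(mutations) {
  if (NROW(mutations) == 0L) return(mutations)
  num <- .label_number(mutations$position)
  ins <- sub("^[0-9]+", "", mutations$position)
  mutations[order(num, ins), , drop = FALSE]
}
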