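#' Build residue key strings
#'
#' Residues are identified by \code{"<chain>:<number><icode>"} using author
#' numbering; the insertion code is appended only when present.
#'
#' @param chain one-character chain identifiers.
#' @param resno integer author residue numbers.
#' @param icode insertion codes ("" or NA when absent).
#' @return character vector of keys.
#' @export
residueKey <- function(chain, resno, icode = "") {
  if (length(resno) == 0L) return(character())
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste0(chain, ":", resno, icode)
}

## Split keys back into (chain, resno, icode); inverse of residueKey().
parseResidueKey <- function(keys) {
  m <- regmatches(keys, regexec("^(.+?):(-?[0-9]+)([A-Za-z]?)$", keys))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed residue key(s): ", toString(keys[bad]))
  data.frame(chain = vapply(m, `[`, "", 2L),
             resno = as.integer(vapply(m, `[`, "", 3L)),
             icode = vapply(m, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

#' Order residue keys
#'
#' Total order (chain, residue number, insertion code) used for deterministic
#' tie-breaking throughout the package.
#'
#' @param keys character vector of residue keys.
#' @return integer permutation, as \code{\link[base]{order}}.
#' @export
orderResidueKeys <- function(keys) {
  p <- parseResidueKey(keys)
  order(p$chain, p$resno, p$icode)
}

sortResidueKeys <- function(keys) keys[orderResidueKeys(keys)]
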