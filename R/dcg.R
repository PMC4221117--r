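## The dynamic contact graph (DCG) encodes the interdomain contacts of two
## conformations as one directed bipartite multigraph: forward edges (A -> B)
## are contacts of conformation 1, backward edges (B -> A) contacts of
## conformation 2. Decomposing the DCG into elemental subgraphs yields the
## four contact-change counts N = (N_maint, N_exchpart, N_exchpair, N_new).
##
## Decomposition rule (canonical in this package):
##   1. Every pair present in both conformations is a maintained element;
##      these edges are removed first (forced by the definition).
##   2. The remaining forward-only and backward-only edges are matched
##      one-to-one, first maximizing the number of exchanged-partner elements
##      (a forward and a backward edge sharing exactly one residue), then the
##      number of exchanged-pair elements (sharing no residue); unmatched
##      edges are new. The exchanged-partner step is an exact
##      maximum-cardinality bipartite matching between the two edge sets.
##      After a maximum matching no leftover forward/backward edges can share
##      a residue, so all leftover cross-pairs are valid exchanged pairs and
##      n_exchpair = min(leftover forward, leftover backward); the counts are
##      therefore invariant across optimal matchings.

#' Construct an ElementalCounts vector
#'
#' @param nMaint,nExchpart,nExchpair,nNew non-negative integer counts of
#'   maintained, exchanged-partner, exchanged-pair and new contact changes.
#' @return an \linkS4class{ElementalCounts}.
#' @export
ElementalCounts <- function(nMaint = 0, nExchpart = 0, nExchpair = 0,
                            nNew = 0) {
  new("ElementalCounts", nMaint = as.integer(nMaint),
      nExchpart = as.integer(nExchpart), nExchpair = as.integer(nExchpair),
      nNew = as.integer(nNew))
}

#' Elemental counts as a named numeric vector
#'
#' @param x an \linkS4class{ElementalCounts}.
#' @return named numeric(4): nMaint, nExchpart, nExchpair, nNew.
#' @export
countsVector <- function(x) {
  if (is(x, "Decomposition")) x <- x@counts
  if (is(x, "ElementalCounts"))
    return(c(nMaint = x@nMaint, nExchpart = x@nExchpart,
             nExchpair = x@nExchpair, nNew = x@nNew))
  x <- as.numeric(x)
  if (length(x) != 4L) stop("expected 4 elemental counts")
  names(x) <- c("nMaint", "nExchpart", "nExchpair", "nNew")
  x
}

edgeId <- function(df) if (nrow(df)) paste(df$a, df$b, sep = "\t") else character()

idToEdges <- function(ids) {
  if (!length(ids))
    return(data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE))
  sp <- strsplit(ids, "\t", fixed = TRUE)
  data.frame(a = vapply(sp, `[`, "", 1L), b = vapply(sp, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

# Sort edges by (a, b) residue-key order for deterministic processing.
sortEdges <- function(df) {
  if (!nrow(df)) return(df)
  ka <- sortResidueKeys(unique(df$a)); kb <- sortResidueKeys(unique(df$b))
  df <- df[order(match(df$a, ka), match(df$b, kb)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build a dynamic contact graph from two contact sets
#'
#' @param contacts1,contacts2 \linkS4class{ContactSet}s of conformations 1
#'   and 2, computed under the same \linkS4class{DomainSpec}.
#' @return a \linkS4class{DynamicContactGraph}.
#' @export
buildDCG <- function(contacts1, contacts2) {
  fwd <- sortEdges(contacts1@pairs)
  bwd <- sortEdges(contacts2@pairs)
  new("DynamicContactGraph",
      nodesA = sortResidueKeys(unique(c(fwd$a, bwd$a))),
      nodesB = sortResidueKeys(unique(c(fwd$b, bwd$b))),
      forward = fwd, backward = bwd)
}

# TRUE when a forward-only and a backward-only edge share exactly one
# residue (the exchanged-partner adjacency). Domain-A and domain-B keys live
# in disjoint sets, so only same-side equality can occur.
sharesOneNode <- function(a1, b1, a2, b2) (a1 == a2) + (b1 == b2) == 1L

buildDecomposition <- function(graph, maint, matchFB, fOnly, bOnly) {
  # maint: data.frame of maintained pairs; matchFB: integer index into bOnly
  # rows for each fOnly row (NA = unmatched); leftovers paired in order.
  elements <- list()
  addEl <- function(type, edges) {
    elements[[length(elements) + 1L]] <<- list(type = type, edges = edges)
  }
  if (nrow(maint)) for (i in seq_len(nrow(maint)))
    addEl("maintained",
          data.frame(dir = c("F", "B"), a = maint$a[i], b = maint$b[i],
                     stringsAsFactors = FALSE))
  matched <- which(!is.na(matchFB))
  for (i in matched)
    addEl("exchanged-partner",
          data.frame(dir = c("F", "B"),
                     a = c(fOnly$a[i], bOnly$a[matchFB[i]]),
                     b = c(fOnly$b[i], bOnly$b[matchFB[i]]),
                     stringsAsFactors = FALSE))
  fLeft <- setdiff(seq_len(nrow(fOnly)), matched)
  bLeft <- setdiff(seq_len(nrow(bOnly)), matchFB[matched])
  nPair <- min(length(fLeft), length(bLeft))
  if (nPair) for (k in seq_len(nPair))
    addEl("exchanged-pair",
          data.frame(dir = c("F", "B"),
                     a = c(fOnly$a[fLeft[k]], bOnly$a[bLeft[k]]),
                     b = c(fOnly$b[fLeft[k]], bOnly$b[bLeft[k]]),
                     stringsAsFactors = FALSE))
  newF <- fLeft[setdiff(seq_along(fLeft), seq_len(nPair))]
  newB <- bLeft[setdiff(seq_along(bLeft), seq_len(nPair))]
  for (i in newF)
    addEl("new", data.frame(dir = "F", a = fOnly$a[i], b = fOnly$b[i],
                            stringsAsFactors = FALSE))
  for (i in newB)
    addEl("new", data.frame(dir = "B", a = bOnly$a[i], b = bOnly$b[i],
                            stringsAsFactors = FALSE))
  counts <- ElementalCounts(nrow(maint), length(matched), nPair,
                            length(newF) + length(newB))
  dec <- new("Decomposition", counts = counts, elements = elements)
  stopifnot(nrow(graph@forward) + nrow(graph@backward) ==
              2L * (counts@nMaint + counts@nExchpart + counts@nExchpair) +
              counts@nNew)
  dec
}

#' Decompose a dynamic contact graph into elemental contact changes
#'
#' Applies the canonical decomposition rule: maintained contacts first, then
#' a maximum-cardinality matching of the remaining forward-only and
#' backward-only edges into exchanged-partner elements (edges sharing exactly
#' one residue), exchanged-pair elements from the leftovers, and new elements
#' for whatever remains unmatched. Counts are invariant across optimal
#' matchings; the reported assignment is the deterministic one obtained by
#' processing edges in residue-key order.
#'
#' @param graph a \linkS4class{DynamicContactGraph}.
#' @return a \linkS4class{Decomposition}.
#' @export
decomposeDCG <- function(graph) {
  fid <- edgeId(graph@forward); bid <- edgeId(graph@backward)
  maint <- sortEdges(idToEdges(intersect(fid, bid)))
  fOnly <- sortEdges(idToEdges(setdiff(fid, bid)))
  bOnly <- sortEdges(idToEdges(setdiff(bid, fid)))
  nF <- nrow(fOnly); nB <- nrow(bOnly)
  matchFB <- rep(NA_integer_, nF)
  if (nF > 0L && nB > 0L) {
    adj <- outer(seq_len(nF), seq_len(nB), function(i, j)
      sharesOneNode(fOnly$a[i], fOnly$b[i], bOnly$a[j], bOnly$b[j]))
    ij <- which(adj, arr.ind = TRUE)
    if (nrow(ij)) {
      g <- igraph::make_bipartite_graph(
        types = c(rep(FALSE, nF), rep(TRUE, nB)),
        edges = as.vector(t(cbind(ij[, 1L], nF + ij[, 2L]))),
        directed = FALSE)
      mm <- igraph::max_bipartite_match(g)$matching
      m <- mm[seq_len(nF)]
      matchFB <- ifelse(is.na(m), NA_integer_, as.integer(m) - nF)
    }
  }
  buildDecomposition(graph, maint, matchFB, fOnly, bOnly)
}

#' Exhaustive decomposition (test oracle)
#'
#' Enumerates every one-to-one matching of the forward-only and
#' backward-only edges by branch-and-bound and returns the optimum under the
#' same priority order as \code{\link{decomposeDCG}}. It also verifies that
#' every maximum matching yields the same counts. Intended for graphs of at
#' most ~14 edges; larger graphs raise an error pointing at
#' \code{decomposeDCG}.
#'
#' @param graph a \linkS4class{DynamicContactGraph}.
#' @return a \linkS4class{Decomposition}.
#' @export
decomposeDCGBruteForce <- function(graph) {
  if (nrow(graph@forward) + nrow(graph@backward) > 14L)
    stop("graph too large for exhaustive decomposition; use decomposeDCG()")
  fid <- edgeId(graph@forward); bid <- edgeId(graph@backward)
  maint <- sortEdges(idToEdges(intersect(fid, bid)))
  fOnly <- sortEdges(idToEdges(setdiff(fid, bid)))
  bOnly <- sortEdges(idToEdges(setdiff(bid, fid)))
  nF <- nrow(fOnly); nB <- nrow(bOnly)
  adj <- if (nF && nB)
    outer(seq_len(nF), seq_len(nB), function(i, j)
      sharesOneNode(fOnly$a[i], fOnly$b[i], bOnly$a[j], bOnly$b[j]))
  else matrix(FALSE, max(nF, 1L), max(nB, 1L))
  best <- 0L; bestMatch <- rep(NA_integer_, max(nF, 1L))
  search <- function(i, usedB, cur, m, collect) {
    if (i > nF) {
      if (!collect && m > best) { best <<- m; bestMatch <<- cur }
      if (collect && m == best) {
        # invariance audit: under every optimal matching, leftover forward
        # and backward edges must share no residue, so that
        # n_exchpair = min(leftovers) holds regardless of which optimal
        # matching was taken
        fLeft <- which(is.na(cur))
        bLeft <- setdiff(seq_len(nB), cur[!is.na(cur)])
        for (fi in fLeft) for (bj in bLeft)
          if (adj[fi, bj])
            stop("internal: leftover edges share a residue under an ",
                 "optimal matching")
      }
      return()
    }
    if (m + (nF - i + 1L) < best) return()   # bound: cannot reach best
    search(i + 1L, usedB, cur, m, collect)   # leave edge i unmatched
    js <- which(adj[i, ] & !usedB)
    for (j in js) {
      usedB[j] <- TRUE; cur[i] <- j
      search(i + 1L, usedB, cur, m + 1L, collect)
      usedB[j] <- FALSE; cur[i] <- NA_integer_
    }
  }
  if (nF > 0L) {
    search(1L, rep(FALSE, max(nB, 1L)), rep(NA_integer_, nF), 0L, FALSE)
    # second pass visits every maximum matching and audits its leftovers
    search(1L, rep(FALSE, max(nB, 1L)), rep(NA_integer_, nF), 0L, TRUE)
  }
  buildDecomposition(graph, maint, bestMatch[seq_len(nF)], fOnly, bOnly)
}

#' @rdname elementalCounts
#' @export
setMethod("elementalCounts", "Decomposition", function(x, ...) x@counts)

#' Elemental contact-change counts
#'
#' For a \linkS4class{DynamicContactGraph} the graph is decomposed first.
#'
#' @param x a \linkS4class{Decomposition} or \linkS4class{DynamicContactGraph}.
#' @param ... unused.
#' @return an \linkS4class{ElementalCounts}.
#' @name elementalCounts
NULL

#' @rdname elementalCounts
#' @export
setMethod("elementalCounts", "DynamicContactGraph",
          function(x, ...) decomposeDCG(x)@counts)

#' Write a DCG as an edge-list text file
#'
#' One line per edge: \code{"F <a> <b>"} for conformation-1 contacts and
#' \code{"B <a> <b>"} for conformation-2 contacts.
#'
#' @param graph a \linkS4class{DynamicContactGraph}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeDCG <- function(graph, path) {
  lines <- c(
    if (nrow(graph@forward))
      paste("F", graph@forward$a, graph@forward$b),
    if (nrow(graph@backward))
      paste("B", graph@backward$a, graph@backward$b))
  writeLines(as.character(lines), path)
  invisible(path)
}

#' Read a DCG edge-list text file
#'
#' @param path input path.
#' @return a \linkS4class{DynamicContactGraph}.
#' @export
readDCG <- function(path) {
  if (!file.exists(path)) stop("cannot read DCG file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  sp <- strsplit(lines, "[ \t]+")
  bad <- vapply(sp, length, 1L) != 3L
  if (any(bad)) stop("malformed DCG line: '", lines[bad][1], "'")
  dir <- vapply(sp, `[`, "", 1L)
  if (!all(dir %in% c("F", "B")))
    stop("DCG edge direction must be F or B")
  df <- data.frame(dir = dir, a = vapply(sp, `[`, "", 2L),
                   b = vapply(sp, `[`, "", 3L), stringsAsFactors = FALSE)
  fwd <- sortEdges(df[df$dir == "F", c("a", "b"), drop = FALSE])
  bwd <- sortEdges(df[df$dir == "B", c("a", "b"), drop = FALSE])
  new("DynamicContactGraph",
      nodesA = sortResidueKeys(unique(df$a)),
      nodesB = sortResidueKeys(unique(df$b)),
      forward = fwd, backward = bwd)
}

#' Write a decomposition report
#'
#' Tab-separated \code{element_type<TAB>edges} lines followed by a summary
#' line \code{"N = (n_maint, n_exchpart, n_exchpair, n_new)"}.
#'
#' @param decomposition a \linkS4class{Decomposition}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeDecomposition <- function(decomposition, path) {
  lines <- vapply(decomposition@elements, function(el) {
    e <- el$edges
    paste(el$type,
          paste(sprintf("%s:%s->%s", e$dir, e$a, e$b), collapse = " "),
          sep = "\t")
  }, "")
  n <- countsVector(decomposition@counts)
  lines <- c(lines, sprintf("N = (%d, %d, %d, %d)", n[1], n[2], n[3], n[4]))
  writeLines(lines, path)
  invisible(path)
}

#' Export a DCG in Graphviz DOT format
#'
#' Domain-A residues are drawn filled, domain-B residues open; edge
#' direction encodes the conformation the contact belongs to.
#'
#' @param graph a \linkS4class{DynamicContactGraph}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeDot <- function(graph, path) {
  q <- function(x) paste0('"', x, '"')
  lines <- c("digraph DCG {",
             "  rankdir=LR;",
             paste0("  ", q(graph@nodesA),
                    " [shape=box, style=filled, fillcolor=gray70];"),
             paste0("  ", q(graph@nodesB), " [shape=box];"),
             if (nrow(graph@forward))
               paste0("  ", q(graph@forward$a), " -> ", q(graph@forward$b), ";"),
             if (nrow(graph@backward))
               paste0("  ", q(graph@backward$b), " -> ", q(graph@backward$a), ";"),
             "}")
  writeLines(as.character(lines), path)
  invisible(path)
}
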