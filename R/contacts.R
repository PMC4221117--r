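## Interdomain residue contacts: two residues are in contact when any heavy
## atom of one is within `cutoff` (default 4 A, inclusive) of any heavy atom
## of the other. Bending-region residues and residues with a heavy atom
## within `axisCutoff` (default 5.5 A) of the interdomain screw axis are
## excluded before contacts are collected.

# Minimum pairwise distance between two coordinate sets (n x 3, m x 3).
minInterAtomDistance <- function(xyzI, xyzJ) {
  d2 <- outer(rowSums(xyzI^2), rowSums(xyzJ^2), "+") -
    2 * (xyzI %*% t(xyzJ))
  sqrt(max(0, min(d2)))
}

#' Are two residues in contact?
#'
#' TRUE when the minimum heavy-atom distance between the two residues is
#' within the cutoff (inclusive).
#'
#' @param xyzI,xyzJ numeric matrices (n x 3) of heavy-atom coordinates.
#' @param cutoff contact distance in Angstrom (default 4.0).
#' @return logical scalar.
#' @export
residuesInContact <- function(xyzI, xyzJ, cutoff = 4.0) {
  xyzI <- rbind(xyzI); xyzJ <- rbind(xyzJ)
  if (nrow(xyzI) == 0L || nrow(xyzJ) == 0L)
    stop("residue has no heavy atoms")
  minInterAtomDistance(xyzI, xyzJ) <= cutoff
}

# Perpendicular distance of points (n x 3) to the infinite line
# point + t * direction (direction unit length).
pointLineDistance <- function(xyz, point, direction) {
  xyz <- rbind(xyz)
  v <- sweep(xyz, 2L, point)
  t <- as.numeric(v %*% direction)
  perp <- v - outer(t, direction)
  sqrt(rowSums(perp^2))
}

#' Residues excluded from contact computation
#'
#' Returns the bending-region residues together with every residue having at
#' least one heavy atom whose perpendicular distance to the (infinite)
#' interdomain screw-axis line is within \code{axisCutoff} (inclusive).
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param spec a \linkS4class{DomainSpec}.
#' @param axis a \linkS4class{ScrewAxis}.
#' @param axisCutoff exclusion distance from the axis in Angstrom
#'   (default 5.5).
#' @return character vector of residue keys.
#' @export
excludedResidues <- function(structure, spec, axis, axisCutoff = 5.5) {
  at <- structure@atoms
  d <- pointLineDistance(as.matrix(at[, c("x", "y", "z")]),
                         axis@point, axis@direction)
  nearAxis <- unique(at$key[d <= axisCutoff])
  sortResidueKeys(union(spec@bending, nearAxis))
}

# Split a structure's atoms by residue key, restricted to `keys`, returning
# a named list of coordinate matrices. Missing keys are dropped (with an
# optional warning handled by the caller).
residueCoordList <- function(structure, keys) {
  at <- structure@atoms[structure@atoms$key %in% keys, , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  split.data.frame(xyz, factor(at$key, levels = unique(at$key)))
}

#' Compute interdomain residue contacts for one conformation
#'
#' Collects all residue pairs (a in domain A, b in domain B) in contact at
#' the heavy-atom cutoff, after removing bending-region residues and
#' residues near the interdomain screw axis (see
#' \code{\link{excludedResidues}}). The default search prunes residue pairs
#' by a centroid-plus-radius bound before the all-atom check;
#' \code{method = "exhaustive"} runs the plain all-pairs all-atom scan and
#' serves as the reference in tests.
#'
#' @param structure a \linkS4class{ProteinStructure} (in the frame of the
#'   fixed-domain superposition the axis is expressed in).
#' @param spec a \linkS4class{DomainSpec}.
#' @param axis a \linkS4class{ScrewAxis}.
#' @param cutoff heavy-atom contact distance, Angstrom (default 4.0).
#' @param axisCutoff near-axis exclusion distance, Angstrom (default 5.5).
#' @param method "pruned" (default) or "exhaustive".
#' @return a \linkS4class{ContactSet}; pairs sorted by (a, b) residue-key
#'   order.
#' @export
interdomainContacts <- function(structure, spec, axis, cutoff = 4.0,
                                axisCutoff = 5.5,
                                method = c("pruned", "exhaustive")) {
  method <- match.arg(method)
  excl <- excludedResidues(structure, spec, axis, axisCutoff)
  keysA <- setdiff(spec@domainA, excl)
  keysB <- setdiff(spec@domainB, excl)
  present <- unique(structure@atoms$key)
  missA <- setdiff(keysA, present); missB <- setdiff(keysB, present)
  if (length(missA) == length(keysA) && length(missB) == length(keysB) &&
      (length(keysA) + length(keysB)) > 0L)
    stop("no spec residues present in structure '", structure@label, "'")
  if (length(missA) || length(missB))
    warning(length(missA) + length(missB),
            " spec residue(s) absent from structure '", structure@label,
            "' were skipped")
  keysA <- intersect(keysA, present); keysB <- intersect(keysB, present)
  pairs <- data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE)
  if (length(keysA) && length(keysB)) {
    coordsA <- residueCoordList(structure, keysA)
    coordsB <- residueCoordList(structure, keysB)
    keysA <- names(coordsA); keysB <- names(coordsB)
    if (method == "pruned") {
      # centroid + covering radius per residue; only pairs whose centroid
      # distance can beat cutoff are checked atom-by-atom
      centf <- function(m) colMeans(m)
      radf <- function(m) sqrt(max(rowSums(sweep(m, 2L, colMeans(m))^2)))
      cA <- t(vapply(coordsA, centf, numeric(3)))
      cB <- t(vapply(coordsB, centf, numeric(3)))
      rA <- vapply(coordsA, radf, 0)
      rB <- vapply(coordsB, radf, 0)
      d2 <- outer(rowSums(cA^2), rowSums(cB^2), "+") - 2 * (cA %*% t(cB))
      bound <- outer(rA, rB, "+") + cutoff
      cand <- which(d2 <= bound^2, arr.ind = TRUE)
    } else {
      cand <- as.matrix(expand.grid(seq_along(coordsA), seq_along(coordsB)))
    }
    if (nrow(cand)) {
      hit <- vapply(seq_len(nrow(cand)), function(k) {
        residuesInContact(coordsA[[cand[k, 1L]]], coordsB[[cand[k, 2L]]],
                          cutoff)
      }, NA)
      pairs <- data.frame(a = keysA[cand[hit, 1L]],
                          b = keysB[cand[hit, 2L]],
                          stringsAsFactors = FALSE)
    }
  }
  o <- order(match(pairs$a, sortResidueKeys(unique(pairs$a))),
             match(pairs$b, sortResidueKeys(unique(pairs$b))))
  pairs <- pairs[o, , drop = FALSE]
  rownames(pairs) <- NULL
  new("ContactSet", label = structure@label, pairs = pairs)
}

#' Write a ContactSet to tab-separated text
#'
#' One pair per line, \code{"chainA:resnumA\\tchainB:resnumB"}, preceded by a
#' \code{"# conformation <label>"} header line.
#'
#' @param contacts a \linkS4class{ContactSet}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeContactSet <- function(contacts, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste("# conformation", contacts@label), con)
  if (nrow(contacts@pairs))
    writeLines(paste(contacts@pairs$a, contacts@pairs$b, sep = "\t"), con)
  invisible(path)
}

#' Read a ContactSet written by writeContactSet
#'
#' @param path input path.
#' @return a \linkS4class{ContactSet}.
#' @export
readContactSet <- function(path) {
  if (!file.exists(path)) stop("cannot read contact set: ", path)
  lines <- readLines(path)
  lab <- sub("^# conformation\\s+", "",
             lines[startsWith(lines, "# conformation")][1])
  if (is.na(lab)) lab <- "unknown"
  body <- lines[!startsWith(lines, "#") & trimws(lines) != ""]
  if (length(body)) {
    sp <- strsplit(body, "\t", fixed = TRUE)
    bad <- vapply(sp, length, 1L) != 2L
    if (any(bad)) stop("malformed contact line: '", body[bad][1], "'")
    pairs <- data.frame(a = vapply(sp, `[`, "", 1L),
                        b = vapply(sp, `[`, "", 2L),
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(a = character(), b = character(),
                        stringsAsFactors = FALSE)
  }
  new("ContactSet", label = lab, pairs = pairs)
}
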