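## Screw-axis geometry. By Chasles' theorem the interdomain displacement is a
## rotation about a unique axis plus a translation along it. The location of
## that axis relative to the protein body and to the bending regions carries
## mechanical information: an axis threading a bending region (a "mechanical
## hinge") behaves like the hinge of a door, while an axis outside the
## protein implies the rotation is accompanied by an in-plane translation.

#' Is the screw axis outside the body of the protein?
#'
#' TRUE when no heavy atom of the structure lies within \code{cutoff}
#' (inclusive) of the infinite axis line; i.e. "outside" means a minimum
#' axis-atom distance strictly greater than the cutoff.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param axis a \linkS4class{ScrewAxis}.
#' @param cutoff distance in Angstrom (default 5.5).
#' @return logical scalar.
#' @export
axisOutsideProtein <- function(structure, axis, cutoff = 5.5) {
  at <- structure@atoms
  if (nrow(at) == 0L) stop("structure has no atoms")
  d <- pointLineDistance(as.matrix(at[, c("x", "y", "z")]),
                         axis@point, axis@direction)
  min(d) > cutoff
}

#' Bending regions of a domain spec
#'
#' Groups the bending residues into contiguous backbone segments: residues
#' consecutive in (chain, residue number, insertion code) form one region.
#'
#' @param spec a \linkS4class{DomainSpec}.
#' @return list of character vectors of residue keys, one per region.
#' @export
bendingRegions <- function(spec) {
  keys <- sortResidueKeys(spec@bending)
  if (!length(keys)) return(list())
  p <- parseResidueKey(keys)
  brk <- c(TRUE, p$chain[-1] != p$chain[-nrow(p)] |
             (p$resno[-1] - p$resno[-nrow(p)]) > 1L)
  split(keys, cumsum(brk))
}

#' Mechanical hinges of an interdomain screw axis
#'
#' A mechanical hinge is a bending region with at least one C-alpha atom
#' within \code{cutoff} (inclusive) of the axis line. Bending residues
#' without a C-alpha in the structure are skipped with a warning.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param spec a \linkS4class{DomainSpec}.
#' @param axis a \linkS4class{ScrewAxis}.
#' @param cutoff distance in Angstrom (default 5.5).
#' @return list of bending regions (character vectors of residue keys) that
#'   qualify; empty list when none do.
#' @export
mechanicalHinges <- function(structure, spec, axis, cutoff = 5.5) {
  regions <- bendingRegions(spec)
  if (!length(regions)) return(list())
  at <- structure@atoms
  ca <- at[at$elety == "CA", , drop = FALSE]
  caKeys <- ca$key
  hit <- vapply(regions, function(keys) {
    have <- keys %in% caKeys
    if (any(!have))
      warning("bending residue(s) without C-alpha skipped: ",
              toString(keys[!have]))
    if (!any(have)) return(FALSE)
    sel <- ca[ca$key %in% keys, c("x", "y", "z"), drop = FALSE]
    any(pointLineDistance(as.matrix(sel), axis@point, axis@direction) <=
          cutoff)
  }, NA)
  regions[hit]
}

#' @rdname pitch
#' @export
setMethod("pitch", "ScrewAxis", function(axis) {
  if (axis@angle <= 0)
    stop("pitch is undefined for zero rotation angle")
  abs(axis@translation) / axis@angle
})

#' Pitch of a screw movement
#'
#' Absolute translation along the axis per degree of rotation
#' (Angstrom/degree). Undefined (error) for a zero rotation angle.
#'
#' @param axis a \linkS4class{ScrewAxis}.
#' @return numeric scalar, Angstrom per degree.
#' @name pitch
NULL

#' @rdname motionType
#' @export
setMethod("motionType", "ScrewAxis", function(axis) {
  if (axis@percentClosure > 50) "closure" else "twist"
})

#' Closure or twist annotation
#'
#' A movement with percentage closure > 50 is annotated "closure",
#' otherwise (<= 50) "twist".
#'
#' @param axis a \linkS4class{ScrewAxis}.
#' @return "closure" or "twist".
#' @name motionType
NULL

#' Full geometric analysis of an interdomain screw axis
#'
#' Combines the axis-outside-protein test, mechanical-hinge detection (and
#' thus the effective-hinge-axis property), the pitch and the closure/twist
#' annotation into one report.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param spec a \linkS4class{DomainSpec}.
#' @param axis a \linkS4class{ScrewAxis}.
#' @param cutoff distance cutoff in Angstrom for both the outside test and
#'   mechanical hinges (default 5.5).
#' @return an \linkS4class{AxisAnalysis}.
#' @export
analyzeAxis <- function(structure, spec, axis, cutoff = 5.5) {
  mh <- mechanicalHinges(structure, spec, axis, cutoff)
  new("AxisAnalysis",
      axisOutsideProtein = axisOutsideProtein(structure, axis, cutoff),
      mechanicalHinges = mh,
      hasEffectiveHingeAxis = length(mh) > 0L,
      pitch = if (axis@angle > 0) abs(axis@translation) / axis@angle
              else NA_real_,
      motionType = motionType(axis))
}

#' Write an axis analysis report
#'
#' Key/value text block.
#'
#' @param analysis an \linkS4class{AxisAnalysis}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeAxisAnalysis <- function(analysis, path) {
  writeLines(c(
    paste("axis_outside_protein", tolower(analysis@axisOutsideProtein)),
    paste("n_mechanical_hinges", length(analysis@mechanicalHinges)),
    paste("effective_hinge_axis", tolower(analysis@hasEffectiveHingeAxis)),
    paste("pitch_A_per_deg", format(analysis@pitch, digits = 10)),
    paste("motion_type", analysis@motionType)), path)
  invisible(path)
}
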