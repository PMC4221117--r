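#' @rdname elementalCounts
#' @export
setGeneric("elementalCounts", function(x, ...) standardGeneric("elementalCounts"))

#' @rdname pitch
#' @export
setGeneric("pitch", function(axis) standardGeneric("pitch"))

#' @rdname motionType
#' @export
setGeneric("motionType", function(axis) standardGeneric("motionType"))

#' @rdname residueKeys
#' @export
setGeneric("residueKeys", function(x) standardGeneric("residueKeys"))

#' @rdname contactPairs
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))

#' Residue keys of an object
#'
#' @param x a \linkS4class{ProteinStructure} or \linkS4class{DomainSpec}.
#' @return character vector of residue keys (for a \code{DomainSpec}, the
#'   union of the three roles).
#' @name residueKeys
NULL

#' @rdname residueKeys
#' @export
setMethod("residueKeys", "ProteinStructure",
          function(x) unique(x@atoms$key))

#' @rdname residueKeys
#' @export
setMethod("residueKeys", "DomainSpec",
          function(x) c(x@domainA, x@domainB, x@bending))

#' Contact pairs of a ContactSet
#'
#' @param x a \linkS4class{ContactSet}.
#' @return data.frame with character columns \code{a}, \code{b}.
#' @name contactPairs
NULL

#' @rdname contactPairs
#' @export
setMethod("contactPairs", "ContactSet", function(x) x@pairs)

#' @describeIn domainResidues residues of domain A
#' @export
domainA <- function(spec) spec@domainA

#' Accessors for DomainSpec roles
#'
#' @param spec a \linkS4class{DomainSpec}.
#' @return character vector of residue keys.
#' @name domainResidues
NULL

#' @describeIn domainResidues residues of domain B
#' @export
domainB <- function(spec) spec@domainB

#' @describeIn domainResidues bending-region residues
#' @export
bendingResidues <- function(spec) spec@bending

#' Atom table of a ProteinStructure
#'
#' @param x a \linkS4class{ProteinStructure}.
#' @return the atom data.frame (one row per heavy atom).
#' @export
atoms <- function(x) x@atoms

#' Conformation label
#'
#' @param x a \linkS4class{ProteinStructure} or \linkS4class{ContactSet}.
#' @return character label.
#' @export
conformationLabel <- function(x) x@label

setMethod("show", "ProteinStructure", function(object) {
  cat("ProteinStructure '", object@label, "': ",
      length(unique(object@atoms$key)), " residues, ",
      nrow(object@atoms), " heavy atoms, chains ",
      toString(sort(unique(object@atoms$chain))), "\n", sep = "")
})

setMethod("show", "DomainSpec", function(object) {
  cat("DomainSpec: |domainA| =", length(object@domainA),
      " |domainB| =", length(object@domainB),
      " |bending| =", length(object@bending), "\n")
})

setMethod("show", "ScrewAxis", function(object) {
  cat(sprintf(paste0("ScrewAxis: point (%.3f, %.3f, %.3f), direction ",
                     "(%.4f, %.4f, %.4f)\n  rotation %.2f deg, translation ",
                     "%.3f A, closure %.1f%%\n"),
              object@point[1], object@point[2], object@point[3],
              object@direction[1], object@direction[2], object@direction[3],
              object@angle, object@translation, object@percentClosure))
})

setMethod("show", "ContactSet", function(object) {
  cat("ContactSet '", object@label, "': ", nrow(object@pairs),
      " interdomain contact pairs\n", sep = "")
})

setMethod("show", "DynamicContactGraph", function(object) {
  cat("DynamicContactGraph: |A| =", length(object@nodesA),
      " |B| =", length(object@nodesB),
      " forward edges:", nrow(object@forward),
      " backward edges:", nrow(object@backward), "\n")
})

setMethod("show", "ElementalCounts", function(object) {
  cat(sprintf("N = (%d, %d, %d, %d)  [maintained, exchanged-partner, exchanged-pair, new]\n",
              object@nMaint, object@nExchpart, object@nExchpair, object@nNew))
})

setMethod("show", "Decomposition", function(object) {
  show(object@counts)
  tab <- table(vapply(object@elements, `[[`, "", "type"))
  if (length(tab))
    cat("  elements:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "LogisticModel", function(object) {
  cat(sprintf(paste0("LogisticModel: alpha = %+.4f*Nmaint %+.4f*Nexchpart ",
                     "%+.4f*Nexchpair %+.4f*Nnew %+.4f;  y = 1/(1+exp(alpha))\n"),
              object@w[1], object@w[2], object@w[3], object@w[4], object@b))
  if (!object@converged) cat("  (fit did not converge)\n")
})

setMethod("show", "TrainingSet", function(object) {
  cat("TrainingSet:", length(object@id), "items (",
      sum(object@label == 0L), "hinge,", sum(object@label == 1L), "shear )\n")
})

setMethod("show", "AxisAnalysis", function(object) {
  cat("AxisAnalysis:\n",
      " axis_outside_protein: ", object@axisOutsideProtein, "\n",
      " n_mechanical_hinges: ", length(object@mechanicalHinges), "\n",
      " effective_hinge_axis: ", object@hasEffectiveHingeAxis, "\n",
      " pitch_A_per_deg: ", format(object@pitch), "\n",
      " motion_type: ", object@motionType, "\n", sep = "")
})
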