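#' @import methods
NULL

## Residues are identified throughout by a key string "<chain>:<resno><icode>"
## (author numbering, insertion code appended when present), e.g. "A:42" or
## "A:42B". Keys carry a total order (chain, number, insertion code) used for
## deterministic tie-breaking; see residueKey() / orderResidueKeys().

#' ProteinStructure: heavy-atom coordinates of one conformation
#'
#' Holds the heavy atoms of a single protein conformation, indexed by residue.
#' Hydrogens (and deuterium) are removed at parse time; every residue retains
#' at least one heavy atom.
#'
#' @slot atoms data.frame with columns \code{key} (residue key string),
#'   \code{chain}, \code{resno}, \code{icode}, \code{resid} (residue name),
#'   \code{elety} (atom name), \code{x}, \code{y}, \code{z} (Angstrom).
#' @slot label free-text conformation label (e.g. a PDB accession).
#' @exportClass ProteinStructure
setClass("ProteinStructure",
  representation(atoms = "data.frame", label = "character"))

setValidity("ProteinStructure", function(object) {
  need <- c("key", "chain", "resno", "icode", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(object@atoms)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@atoms) == 0L)
    return("structure has no atoms")
  if (any(is.na(object@atoms$x) | is.na(object@atoms$y) | is.na(object@atoms$z)))
    return("atom coordinates contain NA")
  TRUE
})

#' DomainSpec: residue sets of the two domains and the bending regions
#'
#' The residue-level decomposition of a two-domain protein: domain A, domain B
#' and the bending regions connecting them, as produced by a DynDom-style
#' analysis. The three sets are pairwise disjoint and both domains are
#' non-empty.
#'
#' @slot domainA,domainB,bending character vectors of residue keys.
#' @exportClass DomainSpec
setClass("DomainSpec",
  representation(domainA = "character", domainB = "character",
                 bending = "character"))

setValidity("DomainSpec", function(object) {
  if (length(object@domainA) == 0L || length(object@domainB) == 0L)
    return("domainA and domainB must be non-empty")
  ab <- intersect(object@domainA, object@domainB)
  if (length(ab)) return(paste("residues in both domains:", toString(ab)))
  bb <- intersect(object@bending, c(object@domainA, object@domainB))
  if (length(bb)) return(paste("bending residues also in a domain:", toString(bb)))
  if (anyDuplicated(object@domainA) || anyDuplicated(object@domainB) ||
      anyDuplicated(object@bending))
    return("duplicate residue keys within a role")
  TRUE
})

#' ScrewAxis: the interdomain screw axis and its motion parameters
#'
#' By Chasles' theorem the displacement of one domain relative to the other is
#' a screw movement about a unique axis: a rotation about the axis combined
#' with a translation along it. The axis is stored as a point plus a unit
#' direction, together with the rotation angle, the axial translation, and
#' DynDom's percentage closure.
#'
#' @slot point numeric(3), any point on the axis (Angstrom).
#' @slot direction numeric(3), unit vector along the axis.
#' @slot angle rotation angle in degrees, >= 0.
#' @slot translation signed displacement along the axis (Angstrom).
#' @slot percentClosure percentage closure in [0, 100].
#' @exportClass ScrewAxis
setClass("ScrewAxis",
  representation(point = "numeric", direction = "numeric", angle = "numeric",
                 translation = "numeric", percentClosure = "numeric"))

setValidity("ScrewAxis", function(object) {
  if (length(object@point) != 3L || length(object@direction) != 3L)
    return("point and direction must be length-3 numeric")
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-6)
    return("direction must be a unit vector (|d| = 1 within 1e-6)")
  if (length(object@angle) != 1L || object@angle < 0)
    return("angle must be a single value >= 0 degrees")
  if (length(object@percentClosure) != 1L ||
      object@percentClosure < 0 || object@percentClosure > 100)
    return("percentClosure must lie in [0, 100]")
  if (length(object@translation) != 1L || !is.finite(object@translation))
    return("translation must be a single finite value")
  TRUE
})

#' ContactSet: interdomain residue contacts of one conformation
#'
#' The set of ordered residue pairs (a in domain A, b in domain B) whose
#' minimum heavy-atom distance is within the contact cutoff, after the
#' bending-region and near-axis exclusions.
#'
#' @slot label conformation label.
#' @slot pairs data.frame with character columns \code{a} and \code{b}
#'   (residue keys); no duplicate rows.
#' @exportClass ContactSet
setClass("ContactSet",
  representation(label = "character", pairs = "data.frame"))

setValidity("ContactSet", function(object) {
  if (!all(c("a", "b") %in% names(object@pairs)))
    return("pairs must have columns a and b")
  if (anyDuplicated(paste(object@pairs$a, object@pairs$b)))
    return("duplicate contact pairs")
  TRUE
})

#' DynamicContactGraph: contacts of two conformations as a directed graph
#'
#' A directed bipartite multigraph on the residues of domains A and B.
#' An edge runs from A to B if the pair is in contact in conformation 1
#' ("forward") and from B to A if in contact in conformation 2 ("backward");
#' a maintained contact contributes one edge in each direction.
#'
#' @slot nodesA,nodesB character vectors of residue keys.
#' @slot forward,backward data.frame(a, b): pairs in contact in conformation 1
#'   and conformation 2 respectively.
#' @exportClass DynamicContactGraph
setClass("DynamicContactGraph",
  representation(nodesA = "character", nodesB = "character",
                 forward = "data.frame", backward = "data.frame"))

setValidity("DynamicContactGraph", function(object) {
  for (nm in c("forward", "backward")) {
    e <- slot(object, nm)
    if (!all(c("a", "b") %in% names(e))) return(paste(nm, "needs columns a, b"))
    if (nrow(e)) {
      if (!all(e$a %in% object@nodesA)) return(paste(nm, "edge endpoint not in nodesA"))
      if (!all(e$b %in% object@nodesB)) return(paste(nm, "edge endpoint not in nodesB"))
      if (anyDuplicated(paste(e$a, e$b))) return(paste("duplicate", nm, "edges"))
    }
  }
  TRUE
})

#' ElementalCounts: the four elemental contact-change counts
#'
#' The feature vector N = (N_maint, N_exchpart, N_exchpair, N_new) counting
#' maintained, exchanged-partner, exchanged-pair and new contact changes in a
#' decomposed dynamic contact graph. This 4-vector is the sole input to the
#' hinge/shear classifier.
#'
#' @slot nMaint,nExchpart,nExchpair,nNew non-negative integer counts.
#' @exportClass ElementalCounts
setClass("ElementalCounts",
  representation(nMaint = "integer", nExchpart = "integer",
                 nExchpair = "integer", nNew = "integer"))

setValidity("ElementalCounts", function(object) {
  v <- c(object@nMaint, object@nExchpart, object@nExchpair, object@nNew)
  if (length(v) != 4L || any(is.na(v)) || any(v < 0L))
    return("all four counts must be single non-negative integers")
  TRUE
})

#' Decomposition: a dynamic contact graph resolved into elemental changes
#'
#' Assigns every edge of a dynamic contact graph to exactly one elemental
#' subgraph: maintained (one forward + one backward edge on the same pair),
#' exchanged-partner (a forward and a backward edge sharing exactly one
#' residue), exchanged-pair (a forward and a backward edge sharing no
#' residue), or new (a single unmatched edge).
#'
#' @slot counts an \linkS4class{ElementalCounts}.
#' @slot elements list; each element is a list with fields \code{type}
#'   (one of "maintained", "exchanged-partner", "exchanged-pair", "new")
#'   and \code{edges} (data.frame with columns dir ("F"/"B"), a, b).
#' @exportClass Decomposition
setClass("Decomposition",
  representation(counts = "ElementalCounts", elements = "list"))

#' LogisticModel: the hinge/shear logistic regression model
#'
#' Stores the model y(N) = 1 / (1 + exp(alpha)) with
#' alpha = w . N + b, the convention in which the published coefficients are
#' printed: negative weights favour shear (y -> 1), positive weights favour
#' hinge (y -> 0). Note this is the negative of the usual logit
#' parameterisation; \code{logit(y) = -(w . N + b)}.
#'
#' @slot w named numeric(4): coefficients for (nMaint, nExchpart, nExchpair,
#'   nNew), in that order.
#' @slot b scalar bias.
#' @slot converged logical; FALSE when fitting hit the iteration cap
#'   (e.g. complete separation).
#' @exportClass LogisticModel
setClass("LogisticModel",
  representation(w = "numeric", b = "numeric", converged = "logical"),
  prototype(converged = TRUE))

setValidity("LogisticModel", function(object) {
  if (length(object@w) != 4L || !all(is.finite(object@w)))
    return("w must be finite numeric(4)")
  if (length(object@b) != 1L || !is.finite(object@b))
    return("b must be a single finite value")
  TRUE
})

#' TrainingSet: labelled elemental-count vectors
#'
#' Labelled training data for the hinge/shear classifier: one row per domain
#' movement, the four elemental counts as features, and a binary label
#' (0 = predominantly hinge, 1 = predominantly shear).
#'
#' @slot id character identifiers.
#' @slot counts integer matrix, one row per item, columns
#'   nMaint/nExchpart/nExchpair/nNew.
#' @slot label integer vector of 0 (hinge) / 1 (shear).
#' @exportClass TrainingSet
setClass("TrainingSet",
  representation(id = "character", counts = "matrix", label = "integer"))

setValidity("TrainingSet", function(object) {
  n <- length(object@id)
  if (n == 0L) return("training set is empty")
  if (nrow(object@counts) != n || length(object@label) != n)
    return("id, counts and label must have matching lengths")
  if (ncol(object@counts) != 4L) return("counts must have 4 columns")
  if (!all(object@label %in% c(0L, 1L))) return("labels must be 0 or 1")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

#' AxisAnalysis: geometric annotation of an interdomain screw axis
#'
#' @slot axisOutsideProtein TRUE when no heavy atom lies within the cutoff of
#'   the axis line.
#' @slot mechanicalHinges list of bending regions (character vectors of
#'   residue keys) with at least one C-alpha within the cutoff of the axis.
#' @slot hasEffectiveHingeAxis TRUE when at least one mechanical hinge exists.
#' @slot pitch axial translation per degree of rotation (Angstrom/degree).
#' @slot motionType "closure" (percentage closure > 50) or "twist".
#' @exportClass AxisAnalysis
setClass("AxisAnalysis",
  representation(axisOutsideProtein = "logical", mechanicalHinges = "list",
                 hasEffectiveHingeAxis = "logical", pitch = "numeric",
                 motionType = "character"))
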