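## Deterministic synthetic fixtures. Two poly-alanine-like domains (N, CA,
## C, O, CB heavy atoms per residue) face each other across a flat
## interface; conformation 2 is conformation 1 with domain B moved by an
## exact rigid screw motion about a declared axis, domain A fixed. The three
## motion regimes emulated:
##   hinge      - rotation about an axis along one edge of the interface;
##                opening separates the interfaces, so conformation-1
##                contacts become "new" contact changes;
##   shear      - small rotation about the interface normal through its
##                centre; the interface is preserved, so contacts are
##                predominantly "maintained";
##   no_contact - the domains are too far apart for contacts in either
##                conformation.

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Heavy-atom template of one residue, CA at the origin (Angstrom).
residueTemplate <- function() {
  m <- rbind(N  = c(-1.20,  0.85, 0.00),
             CA = c( 0.00,  0.00, 0.00),
             C  = c( 1.32,  0.72, 0.00),
             O  = c( 1.45,  1.94, 0.10),
             CB = c(-0.35, -0.95, 1.15))
  colnames(m) <- c("x", "y", "z")
  m
}

# Rodrigues rotation matrix for unit axis u and angle in degrees.
rotationMatrix <- function(u, angleDeg) {
  th <- angleDeg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3L, 3L,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Apply the screw motion (rotate by angleDeg about point+direction, then
# translate along the axis) to an n x 3 coordinate matrix.
applyScrew <- function(xyz, axis, angleDeg = axis@angle,
                       translation = axis@translation) {
  R <- rotationMatrix(axis@direction, angleDeg)
  rel <- sweep(as.matrix(xyz), 2L, axis@point)
  out <- rel %*% t(R)
  out <- sweep(out, 2L, axis@point, "+")
  sweep(out, 2L, translation * axis@direction, "+")
}

# One grid domain: k x k residues, CA on a square lattice in a z-plane.
buildDomainAtoms <- function(chain, k, spacing, z0, flipZ = FALSE,
                             jitter = 0) {
  tpl <- residueTemplate()
  if (flipZ) tpl[, "z"] <- -tpl[, "z"]
  rows <- vector("list", k * k)
  for (j in seq_len(k)) for (i in seq_len(k)) {
    resno <- (j - 1L) * k + i
    xyz <- sweep(tpl, 2L, c((i - 1L) * spacing, (j - 1L) * spacing, z0), "+")
    if (jitter > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, jitter), nrow(xyz))
    rows[[resno]] <- data.frame(
      key = residueKey(chain, resno), chain = chain, resno = resno,
      icode = "", resid = "ALA", elety = rownames(tpl),
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Bending residues (chain A, resno 900+) placed at given CA positions.
buildBendingAtoms <- function(positions) {
  tpl <- residueTemplate()
  rows <- lapply(seq_len(nrow(positions)), function(r) {
    resno <- 899L + r
    xyz <- sweep(tpl, 2L, as.numeric(positions[r, ]), "+")
    data.frame(key = residueKey("A", resno), chain = "A", resno = resno,
               icode = "", resid = "ALA", elety = rownames(tpl),
               x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a two-conformation domain-movement fixture
#'
#' Builds two poly-alanine-like domains facing each other across a flat
#' interface and moves domain B by an exact rigid screw motion to produce
#' conformation 2 (domain A fixed, i.e. both conformations share the
#' fixed-domain superposition frame). The returned axis is exactly the screw
#' axis of the applied motion.
#'
#' @param kind "hinge", "shear" or "no_contact".
#' @param nPerSide residues per grid side; each domain has nPerSide^2
#'   residues (default 5).
#' @param angle rotation angle in degrees; defaults 30 (hinge), 5 (shear),
#'   5 (no_contact).
#' @param translation translation along the axis applied to domain B in
#'   conformation 2 (default 0).
#' @param spacing lattice spacing in Angstrom (default 3.8, a C-alpha step).
#' @param gap interface separation between the domain planes (default 5.8 for
#'   contact-forming kinds, 14 for no_contact).
#' @param percentClosure percentage closure recorded on the axis; defaults
#'   84 (hinge), 30 (shear), 50 (no_contact).
#' @param jitter standard deviation of seeded coordinate noise in Angstrom
#'   (default 0.05).
#' @param seed integer seed making the fixture deterministic (default 1).
#' @return list with elements \code{conf1}, \code{conf2}
#'   (\linkS4class{ProteinStructure}), \code{spec}
#'   (\linkS4class{DomainSpec}) and \code{axis} (\linkS4class{ScrewAxis}).
#' @export
makeMotionFixture <- function(kind = c("hinge", "shear", "no_contact"),
                              nPerSide = 5L, angle = NULL, translation = 0,
                              spacing = 3.8, gap = NULL,
                              percentClosure = NULL, jitter = 0.05,
                              seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(angle))
    angle <- switch(kind, hinge = 30, shear = 5, no_contact = 5)
  if (is.null(gap))
    gap <- switch(kind, hinge = 5.8, shear = 5.8, no_contact = 14)
  if (is.null(percentClosure))
    percentClosure <- switch(kind, hinge = 84, shear = 30, no_contact = 50)
  k <- as.integer(nPerSide)
  ext <- (k - 1L) * spacing
  centre <- c(ext / 2, ext / 2)
  withLocalSeed(seed, {
    atomsA <- buildDomainAtoms("A", k, spacing, 0, FALSE, jitter)
    atomsB <- buildDomainAtoms("B", k, spacing, gap, TRUE, jitter)
  })
  if (kind == "hinge") {
    # axis along -y at one edge of the interface, between the planes;
    # positive rotation about (0,-1,0) swings domain B up and away
    axis <- ScrewAxis(point = c(-4, centre[2], gap / 2),
                      direction = c(0, -1, 0), angle = angle,
                      translation = translation,
                      percentClosure = percentClosure)
    bendPos <- rbind(c(-4, centre[2] - 2, gap / 2),
                     c(-4, centre[2] + 2, gap / 2))
  } else {
    # interface normal through the interface centre
    axis <- ScrewAxis(point = c(centre[1], centre[2], 0),
                      direction = c(0, 0, 1), angle = angle,
                      translation = translation,
                      percentClosure = percentClosure)
    bendPos <- rbind(c(-8, centre[2] - 2, gap / 2),
                     c(-8, centre[2] + 2, gap / 2))
  }
  atomsBend <- buildBendingAtoms(bendPos)
  xyzB2 <- applyScrew(as.matrix(atomsB[, c("x", "y", "z")]), axis)
  atomsB2 <- atomsB
  atomsB2[, c("x", "y", "z")] <- xyzB2
  # impossible-geometry guard: domains must not interpenetrate
  clash <- function(a, b) {
    minInterAtomDistance(as.matrix(a[, c("x", "y", "z")]),
                         as.matrix(b[, c("x", "y", "z")])) < 1.5
  }
  if (clash(atomsA, atomsB) || clash(atomsA, atomsB2))
    stop("impossible geometry: domains overlap (reduce angle or widen gap)")
  conf1 <- new("ProteinStructure", atoms = rbind(atomsA, atomsB, atomsBend),
               label = paste0(kind, "_conf1"))
  conf2 <- new("ProteinStructure", atoms = rbind(atomsA, atomsB2, atomsBend),
               label = paste0(kind, "_conf2"))
  spec <- DomainSpec(domainA = unique(atomsA$key),
                     domainB = unique(atomsB$key),
                     bending = unique(atomsBend$key))
  list(conf1 = conf1, conf2 = conf2, spec = spec, axis = axis)
}

#' Write a motion fixture to files
#'
#' Writes \code{conf1.pdb}, \code{conf2.pdb}, \code{domains.txt} and
#' \code{axis.txt} under \code{dir}.
#'
#' @param fixture result of \code{\link{makeMotionFixture}}.
#' @param dir output directory (created if absent).
#' @return invisibly, a named character vector of the four paths.
#' @export
writeFixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(conf1 = file.path(dir, "conf1.pdb"),
             conf2 = file.path(dir, "conf2.pdb"),
             domains = file.path(dir, "domains.txt"),
             axis = file.path(dir, "axis.txt"))
  writeStructure(fixture$conf1, paths["conf1"])
  writeStructure(fixture$conf2, paths["conf2"])
  writeDomainSpec(fixture$spec, paths["domains"])
  writeScrewAxis(fixture$axis, paths["axis"])
  invisible(paths)
}

#' Generate a random dynamic contact graph
#'
#' Uniformly samples distinct forward and (independently) distinct backward
#' edges on node sets A:1..A:nNodesA and B:1..B:nNodesB; the forward and
#' backward sets may overlap, producing maintained contacts.
#'
#' @param nForward,nBackward numbers of forward/backward edges.
#' @param nNodesA,nNodesB node-set sizes.
#' @param seed integer seed.
#' @return a \linkS4class{DynamicContactGraph}.
#' @export
makeRandomDCG <- function(nForward, nBackward, nNodesA, nNodesB, seed = 1L) {
  nPairs <- nNodesA * nNodesB
  if (nForward > nPairs || nBackward > nPairs)
    stop("requested edges exceed possible pairs (", nPairs, ")")
  withLocalSeed(seed, {
    pick <- function(nEdge) {
      idx <- sample.int(nPairs, nEdge)
      data.frame(a = residueKey("A", ((idx - 1L) %% nNodesA) + 1L),
                 b = residueKey("B", ((idx - 1L) %/% nNodesA) + 1L),
                 stringsAsFactors = FALSE)
    }
    fwd <- pick(nForward); bwd <- pick(nBackward)
  })
  new("DynamicContactGraph",
      nodesA = residueKey("A", seq_len(nNodesA)),
      nodesB = residueKey("B", seq_len(nNodesB)),
      forward = sortEdges(fwd), backward = sortEdges(bwd))
}

#' Generate a labelled synthetic training set
#'
#' Draws elemental-count vectors from a two-regime mixture (shear-like and
#' hinge-like Poisson means) and labels each item Bernoulli(y(N)) under the
#' supplied model, i.e. treating the model output as the posterior
#' probability of shear. The default means give interface sizes of a few to
#' a dozen contact pairs and a true-model hinge/shear separability (AUC
#' around 0.8) comparable to expert-labelled data.
#'
#' @param n number of items (>= 10).
#' @param model generating \linkS4class{LogisticModel} (default the
#'   published one).
#' @param lambdaShear,lambdaHinge Poisson means for the four counts in the
#'   shear-like and hinge-like regimes (defaults c(6,2,1,2) and
#'   c(2,1,2,5)).
#' @param pShear mixing proportion of the shear-like regime (default 0.5).
#' @param seed integer seed.
#' @return a \linkS4class{TrainingSet}.
#' @export
makeTrainingSet <- function(n, model = publishedModel(),
                            lambdaShear = c(6, 2, 1, 2),
                            lambdaHinge = c(2, 1, 2, 5),
                            pShear = 0.5, seed = 1L) {
  if (n < 10L) stop("training sets need at least 10 items")
  if (length(lambdaShear) != 4L || length(lambdaHinge) != 4L ||
      any(lambdaShear < 0) || any(lambdaHinge < 0) ||
      (sum(lambdaShear) == 0 && sum(lambdaHinge) == 0))
    stop("degenerate count-distribution parameters")
  if (pShear < 0 || pShear > 1) stop("pShear must lie in [0, 1]")
  withLocalSeed(seed, {
    regime <- stats::rbinom(n, 1L, pShear)
    counts <- t(vapply(regime, function(r)
      stats::rpois(4L, if (r == 1L) lambdaShear else lambdaHinge),
      integer(4L)))
    y <- predictMotion(counts, model)
    label <- stats::rbinom(n, 1L, y)
  })
  TrainingSet(counts, label, sprintf("syn%04d", seq_len(n)))
}
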