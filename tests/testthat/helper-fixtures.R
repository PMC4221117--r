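# Shared fixture builders: tiny in-code PDB files and toy structures.

# Write fixed-width PDB records from a data.frame with columns
# type, serial, name, alt, resn, chain, resno, icode, x, y, z, elem.
writeMiniPdb <- function(df, path, modelBlocks = NULL) {
  fmt <- function(r) {
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            r$type, r$serial, r$name, r$alt, r$resn, r$chain, r$resno,
            r$icode, r$x, r$y, r$z, 1, 0, r$elem)
  }
  lines <- vapply(seq_len(nrow(df)), function(i) fmt(df[i, ]), "")
  if (!is.null(modelBlocks)) {
    out <- character()
    for (b in seq_along(modelBlocks)) {
      sel <- modelBlocks[[b]]
      out <- c(out, sprintf("MODEL     %4d", b), lines[sel], "ENDMDL")
    }
    lines <- out
  }
  writeLines(c(lines, "END"), path)
  path
}

pdbRow <- function(serial, name, chain, resno, x, y, z, elem = substr(name, 1, 1),
                   type = "ATOM", alt = "", resn = "ALA", icode = "") {
  data.frame(type = type, serial = serial, name = name, alt = alt,
             resn = resn, chain = chain, resno = resno, icode = icode,
             x = x, y = y, z = z, elem = elem, stringsAsFactors = FALSE)
}

# A ProteinStructure built directly from (key -> single CA atom) positions.
toyStructure <- function(positions, label = "toy", elety = "CA") {
  rows <- lapply(names(positions), function(k) {
    p <- parts <- positions[[k]]
    kk <- strsplit(k, ":")[[1]]
    data.frame(key = k, chain = kk[1], resno = as.integer(kk[2]), icode = "",
               resid = "ALA", elety = elety, x = p[1], y = p[2], z = p[3],
               stringsAsFactors = FALSE)
  })
  new("ProteinStructure", atoms = do.call(rbind, rows), label = label)
}

# Add extra atoms (n x 3 with names) to an existing residue of a structure.
addAtoms <- function(structure, key, xyz, elety = "CB") {
  kk <- strsplit(key, ":")[[1]]
  xyz <- rbind(xyz)
  extra <- data.frame(key = key, chain = kk[1], resno = as.integer(kk[2]),
                      icode = "", resid = "ALA",
                      elety = rep_len(elety, nrow(xyz)),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  new("ProteinStructure", atoms = rbind(structure@atoms, extra),
      label = structure@label)
}

zAxis <- function(angle = 10, translation = 0, closure = 50)
  ScrewAxis(c(0, 0, 0), c(0, 0, 1), angle, translation, closure)

# An axis far away from everything near the origin.
remoteAxis <- function() ScrewAxis(c(1e4, 1e4, 0), c(0, 0, 1), 10)

# Small DCG from explicit edge vectors ("A:1" style keys).
dcgOf <- function(forwardA = character(), forwardB = character(),
                  backwardA = character(), backwardB = character()) {
  fwd <- data.frame(a = forwardA, b = forwardB, stringsAsFactors = FALSE)
  bwd <- data.frame(a = backwardA, b = backwardB, stringsAsFactors = FALSE)
  new("DynamicContactGraph",
      nodesA = unique(c(forwardA, backwardA)),
      nodesB = unique(c(forwardB, backwardB)),
      forward = fwd, backward = bwd)
}

# Mann-Whitney AUC, the independent oracle for ROC areas.
aucByPairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}
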