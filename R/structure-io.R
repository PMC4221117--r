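## PDB reading is delegated to bio3d; this layer reduces the file to the
## package's heavy-atom data model (model 1, first altloc, protein residues).

# Element symbol per atom, preferring the PDB element column and falling back
# to the atom-name heuristic (strip leading digits, take the first letter).
inferElement <- function(elesy, elety) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  miss <- el == ""
  if (any(miss)) {
    nm <- toupper(sub("^[0-9]+", "", trimws(elety[miss])))
    el[miss] <- substr(nm, 1L, 1L)
  }
  el
}

#' Read a PDB file into a ProteinStructure
#'
#' Parses a PDB-format coordinate file and keeps the heavy atoms of the first
#' model: hydrogens and deuteriums are dropped, only the first-listed
#' alternate location of each atom is kept, and HETATM records are excluded
#' unless requested. Residues keep their author numbering and insertion
#' codes.
#'
#' @param path path to a PDB-format file.
#' @param chains optional character vector of chain identifiers to keep.
#' @param includeHet keep HETATM residues as well (default FALSE).
#' @param label conformation label; defaults to the file name without
#'   extension.
#' @return a \linkS4class{ProteinStructure}.
#' @export
readStructure <- function(path, chains = NULL, includeHet = FALSE,
                          label = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e)
                    stop("failed to parse PDB file '", path, "': ",
                         conditionMessage(e)))
  at <- pdb$atom
  if (!includeHet) at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (nrow(at)) {
    # first-listed altloc per atom identity
    ident <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    at <- at[!duplicated(ident), , drop = FALSE]
    el <- inferElement(at$elesy, at$elety)
    at <- at[!(el %in% c("H", "D")), , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("no residues selected from ", path)
  icode <- ifelse(is.na(at$insert), "", at$insert)
  df <- data.frame(key = residueKey(at$chain, at$resno, icode),
                   chain = at$chain, resno = at$resno, icode = icode,
                   resid = at$resid, elety = at$elety,
                   x = at$x, y = at$y, z = at$z,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  new("ProteinStructure", atoms = df, label = label)
}

#' Write a ProteinStructure to a PDB file
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeStructure <- function(structure, path) {
  at <- structure@atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(at)),
                   resno = at$resno, resid = at$resid,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = at$chain, insert = at$icode)
  invisible(path)
}

# Coordinates of one residue as an n x 3 matrix.
residueCoords <- function(structure, key) {
  sel <- structure@atoms$key == key
  as.matrix(structure@atoms[sel, c("x", "y", "z"), drop = FALSE])
}

#' Construct a DomainSpec
#'
#' @param domainA,domainB,bending character vectors of residue keys
#'   (see \code{\link{residueKey}}); \code{bending} may be empty.
#' @return a validated \linkS4class{DomainSpec}.
#' @export
DomainSpec <- function(domainA, domainB, bending = character()) {
  new("DomainSpec",
      domainA = sortResidueKeys(unique(domainA)),
      domainB = sortResidueKeys(unique(domainB)),
      bending = sortResidueKeys(unique(bending)))
}

# Expand "A:3-7,B:10-12" into residue keys.
expandRanges <- function(txt) {
  parts <- trimws(strsplit(txt, ",")[[1]])
  keys <- character()
  for (p in parts[parts != ""]) {
    m <- regmatches(p, regexec("^(.+?):(-?[0-9]+)(?:-(-?[0-9]+))?$", p))[[1]]
    if (length(m) != 4L) stop("malformed residue range: '", p, "'")
    from <- as.integer(m[3])
    to <- if (m[4] == "") from else as.integer(m[4])
    if (to < from) stop("descending residue range: '", p, "'")
    keys <- c(keys, residueKey(m[2], from:to))
  }
  keys
}

#' Read a domain specification
#'
#' Accepts plain-text lines of the form
#' \code{"<role> <chain>:<start>-<end>[,<chain>:<start>-<end>...]"} with roles
#' \code{domainA}, \code{domainB} and \code{bending} (case-insensitive;
#' \code{domain_a} etc. also accepted). Multiple lines per role accumulate.
#'
#' @param path path to a spec file, or NULL when \code{text} is given.
#' @param text character vector of lines (alternative to \code{path}).
#' @return a validated \linkS4class{DomainSpec}; overlapping roles raise an
#'   error.
#' @export
readDomainSpec <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path) || !file.exists(path))
      stop("cannot read domain spec: ", path)
    text <- readLines(path)
  }
  text <- trimws(text)
  text <- text[text != "" & !startsWith(text, "#")]
  roles <- list(domaina = character(), domainb = character(),
                bending = character())
  for (ln in text) {
    sp <- regmatches(ln, regexec("^(\\S+)[ \t=]+(\\S.*)$", ln))[[1]]
    if (length(sp) != 3L) stop("malformed domain spec line: '", ln, "'")
    role <- gsub("_", "", tolower(sp[2]))
    if (!role %in% names(roles))
      stop("unknown role '", sp[2], "' (expected domainA/domainB/bending)")
    roles[[role]] <- c(roles[[role]], expandRanges(sp[3]))
  }
  DomainSpec(roles$domaina, roles$domainb, roles$bending)
}

#' Construct a ScrewAxis
#'
#' @param point numeric(3), a point on the axis (Angstrom).
#' @param direction numeric(3); normalized internally, must be non-zero.
#' @param angle rotation angle in degrees (>= 0).
#' @param translation signed translation along the axis (Angstrom).
#' @param percentClosure percentage closure in [0, 100].
#' @return a validated \linkS4class{ScrewAxis}.
#' @export
ScrewAxis <- function(point, direction, angle, translation = 0,
                      percentClosure = 50) {
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm < 1e-12)
    stop("axis direction has zero length")
  new("ScrewAxis", point = as.numeric(point),
      direction = as.numeric(direction) / nrm,
      angle = as.numeric(angle), translation = as.numeric(translation),
      percentClosure = as.numeric(percentClosure))
}

#' Read a screw-axis specification
#'
#' Two dialects are accepted. (1) A key/value config file with keys
#' \code{point}, \code{direction} (three whitespace- or comma-separated
#' numbers each), \code{angle_deg}, \code{translation_A},
#' \code{percent_closure}. (2) A DynDom-style "arrow molecule" PDB whose
#' first and last atoms are the axis termini; rotation angle, translation and
#' percentage closure are then supplied via the arguments.
#'
#' @param path path to either dialect.
#' @param angle,translation,percentClosure motion parameters used with the
#'   arrow-PDB dialect (the config dialect carries its own).
#' @return a validated \linkS4class{ScrewAxis}.
#' @export
readScrewAxis <- function(path, angle = NULL, translation = 0,
                          percentClosure = 50) {
  if (!file.exists(path)) stop("cannot read axis spec: ", path)
  lines <- readLines(path)
  isPdb <- any(grepl("^(ATOM|HETATM)", lines))
  if (isPdb) {
    pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    at <- pdb$atom
    if (nrow(at) < 2L) stop("arrow PDB needs at least two atoms: ", path)
    p1 <- as.numeric(at[1L, c("x", "y", "z")])
    p2 <- as.numeric(at[nrow(at), c("x", "y", "z")])
    if (is.null(angle))
      stop("arrow-PDB axis dialect requires an explicit rotation angle")
    return(ScrewAxis(p1, p2 - p1, angle, translation, percentClosure))
  }
  kv <- list()
  for (ln in trimws(lines)) {
    if (ln == "" || startsWith(ln, "#")) next
    sp <- regmatches(ln, regexec("^(\\S+)\\s*[= \t]\\s*(\\S.*)$", ln))[[1]]
    if (length(sp) != 3L) stop("malformed axis config line: '", ln, "'")
    kv[[tolower(sp[2])]] <- as.numeric(strsplit(trimws(sp[3]), "[, \t]+")[[1]])
  }
  need <- c("point", "direction", "angle_deg")
  miss <- setdiff(need, names(kv))
  if (length(miss)) stop("axis config missing key(s): ", toString(miss))
  ScrewAxis(kv$point, kv$direction, kv$angle_deg,
            if (!is.null(kv$translation_a)) kv$translation_a else translation,
            if (!is.null(kv$percent_closure)) kv$percent_closure
            else percentClosure)
}

#' Write a screw-axis config file
#'
#' @param axis a \linkS4class{ScrewAxis}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeScrewAxis <- function(axis, path) {
  writeLines(c(
    paste("point", paste(format(axis@point, digits = 10), collapse = " ")),
    paste("direction", paste(format(axis@direction, digits = 10), collapse = " ")),
    paste("angle_deg", format(axis@angle, digits = 10)),
    paste("translation_A", format(axis@translation, digits = 10)),
    paste("percent_closure", format(axis@percentClosure, digits = 10))), path)
  invisible(path)
}

#' Write a domain spec file
#'
#' Serializes each role as residue-range lines readable by
#' \code{\link{readDomainSpec}}.
#'
#' @param spec a \linkS4class{DomainSpec}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeDomainSpec <- function(spec, path) {
  rangesOf <- function(keys) {
    if (!length(keys)) return(NULL)
    p <- parseResidueKey(sortResidueKeys(keys))
    if (any(p$icode != ""))
      stop("cannot serialize insertion-coded residues as ranges")
    out <- character()
    i <- 1L
    while (i <= nrow(p)) {
      j <- i
      while (j < nrow(p) && p$chain[j + 1L] == p$chain[i] &&
             p$resno[j + 1L] == p$resno[j] + 1L) j <- j + 1L
      out <- c(out, paste0(p$chain[i], ":", p$resno[i], "-", p$resno[j]))
      i <- j + 1L
    }
    paste(out, collapse = ",")
  }
  lines <- c(paste("domainA", rangesOf(spec@domainA)),
             paste("domainB", rangesOf(spec@domainB)))
  if (length(spec@bending))
    lines <- c(lines, paste("bending", rangesOf(spec@bending)))
  writeLines(lines, path)
  invisible(path)
}
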