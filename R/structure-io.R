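# Residue-node structure model built from PDB coordinates.

# Three-letter codes treated as amino-acid nodes; everything else retained
# from HETATM records becomes a ligand node.
.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "SEC", "PYL"
)

.backbone_names <- c("N", "CA", "C", "O")

# Water and common monoatomic ions dropped by default: crystallographic
# solvent is not part of the propagation network.
.default_exclude <- c(
  "HOH", "WAT", "DOD", "H2O",
  "NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "CO", "NI", "CU", "CD",
  "BR", "IOD", "CS", "LI", "RB", "SR", "BA", "F"
)

#' Read a protein structure into a residue-node model
#'
#' Parses PDB-format coordinates into an ordered list of residue-level nodes.
#' Each amino-acid residue and each retained HETATM group (e.g. a bound
#' ligand) becomes one node carrying its heavy atoms. Waters and common
#' monoatomic ions are excluded by default, hydrogens and deuteriums are
#' always dropped, and alternate-location conflicts are resolved by keeping
#' the highest-occupancy conformer (ties broken by the alphabetically first
#' altloc code). Only one model of a multi-model file is read.
#'
#' @param file Path to a PDB file, or `NULL` when `text` is given.
#' @param text Character vector of PDB-format lines (alternative to `file`).
#' @param model Model number to read from a multi-model file (default 1).
#' @param keep_hetatm Keep non-water HETATM groups as ligand nodes
#'   (default `TRUE`).
#' @param exclude Residue names to drop (applied to HETATM groups);
#'   defaults to water and common monoatomic ions.
#' @return An object of class `structure_model`: a list with `nodes`
#'   (data frame: chain, resno, insert, resname, kind, n_atoms, label),
#'   `atoms` (data frame: node index, name, element, is_backbone, occupancy,
#'   x, y, z) and `title`.
#' @examples
#' pdb <- make_helix(6)
#' m <- read_structure(text = pdb)
#' m$nodes
#' @export
read_structure <- function(file = NULL, text = NULL, model = 1,
                           keep_hetatm = TRUE, exclude = .default_exclude) {
  if (is.null(file) && is.null(text))
    stop("supply either 'file' or 'text'")
  if (is.null(file)) {
    file <- tempfile(fileext = ".pdb")
    on.exit(unlink(file), add = TRUE)
    writeLines(text, file)
    title <- "text input"
  } else {
    title <- basename(file)
  }
  raw <- readLines(file, warn = FALSE)
  rec <- substr(raw, 1, 6)
  has_atoms <- any(rec %in% c("ATOM  ", "HETATM") |
                     startsWith(raw, "ATOM") | startsWith(raw, "HETATM"))
  if (!has_atoms) {
    bad <- if (length(raw)) raw[1] else "<empty file>"
    stop("no ATOM/HETATM records found; first line was: ", bad)
  }

  multi <- model > 1
  pdb <- bio3d::read.pdb(file, multi = multi, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (multi) {
    if (nrow(pdb$xyz) < model)
      stop("model ", model, " requested but file has ", nrow(pdb$xyz),
           " models")
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }

  at$elesy[is.na(at$elesy) | at$elesy == ""] <-
    .element_from_name(at$elety[is.na(at$elesy) | at$elesy == ""])
  at <- at[!(toupper(at$elesy) %in% c("H", "D")), , drop = FALSE]

  is_het <- at$type == "HETATM"
  at <- at[!(is_het & at$resid %in% exclude), , drop = FALSE]
  if (!keep_hetatm) at <- at[at$type != "HETATM", , drop = FALSE]
  if (nrow(at) == 0) stop("selection retained zero atoms")

  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$o[is.na(at$o)] <- 1

  at$.ord <- seq_len(nrow(at))
  key <- paste(at$chain, at$resno, at$insert, sep = "\r")
  node_of <- match(key, unique(key))        # file order of first atom

  # altloc resolution: within (node, atom name) keep max occupancy,
  # ties -> alphabetically first altloc code
  ak <- paste(node_of, at$elety, sep = "\r")
  ord <- order(ak, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  node_of <- node_of[ord]
  keep <- !duplicated(ak[ord])
  at <- at[keep, , drop = FALSE]
  node_of <- node_of[keep]
  # restore file order of retained atoms, grouped by node
  ord2 <- order(node_of, at$.ord)
  at <- at[ord2, , drop = FALSE]
  node_of <- node_of[ord2]

  first <- !duplicated(node_of)
  kind <- ifelse(at$type[first] == "ATOM" | at$resid[first] %in% .standard_aa,
                 "amino_acid", "ligand")
  kind[at$type[first] == "HETATM" & !(at$resid[first] %in% .standard_aa)] <-
    "ligand"
  nodes <- data.frame(
    chain = at$chain[first],
    resno = at$resno[first],
    insert = at$insert[first],
    resname = at$resid[first],
    kind = kind,
    n_atoms = as.integer(tabulate(node_of, nbins = sum(first))),
    stringsAsFactors = FALSE
  )
  nodes$label <- paste0(nodes$chain, "/", nodes$resno, nodes$insert)

  atoms <- data.frame(
    node = node_of,
    name = at$elety,
    element = toupper(at$elesy),
    occupancy = at$o,
    is_backbone = at$elety %in% .backbone_names &
      nodes$kind[node_of] == "amino_acid",
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  rownames(atoms) <- NULL

  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  structure(list(nodes = nodes, atoms = atoms, title = title),
            class = "structure_model")
}

.element_from_name <- function(name) {
  # strip leading digits, take leading alphabetic run, first char for
  # standard organic atoms
  el <- sub("^[0-9]*", "", name)
  el <- sub("([A-Za-z]+).*", "\\1", el)
  ifelse(substr(el, 1, 1) %in% c("H"), "H", substr(el, 1, 1))
}

#' @export
print.structure_model <- function(x, ...) {
  cat("Residue-node structure model:", x$title, "\n")
  cat("  nodes:", nrow(x$nodes),
      sprintf("(%d amino acid, %d ligand)",
              sum(x$nodes$kind == "amino_acid"),
              sum(x$nodes$kind == "ligand")), "\n")
  cat("  atoms:", nrow(x$atoms), "\n")
  cat("  chains:", paste(unique(x$nodes$chain), collapse = ", "), "\n")
  invisible(x)
}

#' Resolve a residue selection to node indices
#'
#' Selection expressions are comma-separated terms of the form
#' `"A/57"` (chain/residue), `"A/50-58"` (residue range),
#' `"chain B"` (all nodes of a chain) or `"resname BEF"` (by residue name).
#'
#' @param model A `structure_model`.
#' @param spec Selection expression string, or an integer vector of node
#'   indices (returned unchanged after validation).
#' @return Integer vector of node indices in model order, duplicates removed.
#' @examples
#' m <- read_structure(text = make_helix(8))
#' select_nodes(m, "A/1")
#' select_nodes(m, "A/2-4")
#' @export
select_nodes <- function(model, spec) {
  stopifnot(inherits(model, "structure_model"))
  nd <- model$nodes
  if (is.numeric(spec)) {
    idx <- as.integer(spec)
    if (any(idx < 1 | idx > nrow(nd)))
      stop("node index out of range 1..", nrow(nd))
    return(sort(unique(idx)))
  }
  terms <- trimws(strsplit(spec, ",")[[1]])
  terms <- terms[nzchar(terms)]
  if (!length(terms)) stop("empty selection")
  idx <- integer(0)
  for (tm in terms) {
    if (grepl("^chain\\s+\\S+$", tm, ignore.case = TRUE)) {
      ch <- sub("^chain\\s+", "", tm, ignore.case = TRUE)
      hit <- which(nd$chain == ch)
    } else if (grepl("^resname\\s+\\S+$", tm, ignore.case = TRUE)) {
      rn <- toupper(sub("^resname\\s+", "", tm, ignore.case = TRUE))
      hit <- which(toupper(nd$resname) == rn)
    } else if (grepl("^\\S+/-?[0-9]+--?[0-9]+$", tm)) {
      ch <- sub("/.*", "", tm)
      rng <- sub("^[^/]*/", "", tm)
      m2 <- regmatches(rng, regexec("^(-?[0-9]+)-(-?[0-9]+)$", rng))[[1]]
      lo <- as.integer(m2[2]); hi <- as.integer(m2[3])
      hit <- which(nd$chain == ch & nd$resno >= lo & nd$resno <= hi)
    } else if (grepl("^\\S+/-?[0-9]+[A-Za-z]?$", tm)) {
      ch <- sub("/.*", "", tm)
      rest <- sub("^[^/]*/", "", tm)
      ic <- sub("^-?[0-9]+", "", rest)
      no <- as.integer(sub("([0-9]+).*", "\\1", rest))
      hit <- which(nd$chain == ch & nd$resno == no & nd$insert == ic)
    } else {
      stop("cannot parse selection term: '", tm, "'")
    }
    idx <- c(idx, hit)
  }
  idx <- sort(unique(idx))
  if (!length(idx))
    stop("selection '", spec, "' matched no nodes; available chains: ",
         paste(unique(nd$chain), collapse = ", "))
  idx
}

#' Write a structure with ACI values encoded in the B-factor column
#'
#' Emits the model's atoms in PDB format with each atom's B-factor replaced
#' by `100 * ACI` of its node (clamped to `[0, 999.99]`), the conventional
#' way to colour a structure by a per-residue score in molecular viewers.
#'
#' @param model A `structure_model`.
#' @param profile An [aci_profile] covering all nodes, or a numeric vector
#'   of per-node values in `[0, 1]`.
#' @param file Optional output path. When `NULL` the PDB text is returned.
#' @return Character vector of PDB lines (invisibly when `file` is given).
#' @export
write_aci_pdb <- function(model, profile, file = NULL) {
  stopifnot(inherits(model, "structure_model"))
  aci <- if (inherits(profile, "aci_profile")) profile$aci else profile
  if (length(aci) != nrow(model$nodes))
    stop("profile covers ", length(aci), " nodes but model has ",
         nrow(model$nodes))
  b <- pmin(pmax(100 * aci, 0), 999.99)
  at <- model$atoms
  nd <- model$nodes
  out <- file
  tmp <- if (is.null(out)) tempfile(fileext = ".pdb") else out
  type <- ifelse(nd$kind[at$node] == "amino_acid", "ATOM", "HETATM")
  bio3d::write.pdb(
    file = tmp,
    type = type,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = nd$resno[at$node],
    resid = nd$resname[at$node],
    eleno = seq_len(nrow(at)),
    elety = at$name,
    chain = nd$chain[at$node],
    insert = nd$insert[at$node],
    o = at$occupancy,
    b = b[at$node],
    elesy = at$element
  )
  txt <- readLines(tmp, warn = FALSE)
  if (is.null(out)) {
    unlink(tmp)
    txt
  } else {
    invisible(txt)
  }
}

#' Export the node table
#'
#' @param model A `structure_model`.
#' @param file Optional CSV path.
#' @return Data frame with one row per node (chain, resnum, icode, resname,
#'   kind, n_atoms).
#' @export
node_table <- function(model, file = NULL) {
  stopifnot(inherits(model, "structure_model"))
  tab <- model$nodes[, c("chain", "resno", "insert", "resname", "kind",
                         "n_atoms")]
  names(tab) <- c("chain", "resnum", "icode", "resname", "kind", "n_atoms")
  if (!is.null(file)) utils::write.csv(tab, file, row.names = FALSE)
  tab
}

# chain-local sequence adjacency (|seq_index| == 1 within a chain); used by
# the contact counter's backbone exclusion
.adjacent_pairs <- function(model) {
  nd <- model$nodes
  n <- nrow(nd)
  if (n < 2) return(cbind(integer(0), integer(0)))
  i <- seq_len(n - 1)
  ok <- nd$chain[i] == nd$chain[i + 1]
  cbind(i[ok], i[ok] + 1L)
}
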