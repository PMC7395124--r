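# Synthetic structures and networks with analytically known propagation
# behaviour: an ideal helical trace, a two-domain toy joined by a single
# linker, and direct network construction from an edge list.

.pdb_atom_line <- function(serial, name, resname, chain, resno, xyz,
                           record = "ATOM") {
  sprintf("%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial,
          if (nchar(name) < 4) paste0(" ", name) else name,
          resname, chain, resno, xyz[1], xyz[2], xyz[3], 1, 0,
          substr(name, 1, 1))
}

#' Ideal helical backbone trace
#'
#' Generates a backbone-only helical trace in PDB format: CA atoms on a
#' cylinder of radius 2.3 Å with a rise of 1.5 Å and a twist of 100 degrees
#' per residue, plus pseudo N, C and O atoms at fixed local offsets. The
#' offsets are chosen so the 3.4 Å contact cutoff yields single contacts at
#' sequence separations 3 and 4 (the helical hydrogen-bonding register) and
#' nothing beyond: a banded, connected contact graph. Output is
#' deterministic.
#'
#' @param n Number of residues (>= 2).
#' @param chain Chain identifier (default "A").
#' @return Character vector of PDB lines.
#' @examples
#' m <- read_structure(text = make_helix(3))
#' m$nodes$n_atoms       # 4 atoms per residue
#' @export
make_helix <- function(n, chain = "A") {
  stopifnot(n >= 2)
  twist <- 100 * pi / 180; rise <- 1.5; radius <- 2.3
  lines <- character(0)
  serial <- 1L
  for (i in seq_len(n) - 1L) {
    th <- i * twist
    u <- c(cos(th), sin(th), 0)          # radial
    tg <- c(-sin(th), cos(th), 0)        # tangent
    k <- c(0, 0, 1)                      # axis
    ca <- radius * u + (i * rise) * k
    atoms <- list(
      N  = ca - 0.6 * tg - 1.2 * k - 0.3 * u,
      CA = ca,
      C  = ca + 0.6 * tg + 1.2 * k - 0.3 * u
    )
    atoms$O <- atoms$C + 1.2 * k
    for (nm in names(atoms)) {
      lines <- c(lines, .pdb_atom_line(serial, nm, "ALA", chain, i + 1L,
                                       atoms[[nm]]))
      serial <- serial + 1L
    }
  }
  c(lines, "TER", "END")
}

#' Two compact domains joined by a single linker
#'
#' Two dense clusters of pseudo-residues connected by an extended linker
#' chain. Every inter-domain route runs through the linker, so pathway
#' sampling from one domain to the other must traverse all linker nodes, and
#' removing the linker disconnects the domains. Each pseudo-residue carries a
#' CA and a CB atom (the CB keeps consecutive linker residues in contact
#' despite the backbone-adjacency exclusion).
#'
#' @param n_per_domain Residues per domain (>= 4).
#' @param linker_len Number of linker residues (default 4).
#' @param include_linker Set `FALSE` to omit the linker (disconnects the
#'   domains).
#' @return Character vector of PDB lines; domain 1 is chain A, the linker
#'   chain L, domain 2 chain B.
#' @export
make_two_domain <- function(n_per_domain, linker_len = 4,
                            include_linker = TRUE) {
  stopifnot(n_per_domain >= 4, linker_len >= 1)
  sp <- 3.0                              # intra-domain grid spacing, Å
  grid <- function(n, origin) {
    side <- ceiling(n^(1 / 3))
    pts <- expand.grid(x = 0:(side - 1), y = 0:(side - 1), z = 0:(side - 1))
    pts <- as.matrix(pts[seq_len(n), ]) * sp
    sweep(pts, 2, origin, "+")
  }
  d1 <- grid(n_per_domain, c(0, 0, 0))
  mx <- max(d1[, 1])                     # domain-1 extent along x
  # linker along +x from the (mx, 0, 0) corner; domain 2 starts one linker
  # step beyond the last linker node, so the domains never touch directly
  lk <- cbind(mx + sp * seq_len(linker_len), 0, 0)
  d2 <- grid(n_per_domain, c(mx + sp * (linker_len + 1), 0, 0))

  lines <- character(0); serial <- 1L
  emit <- function(xyz, chain, resno) {
    l1 <- .pdb_atom_line(serial, "CA", "GLY", chain, resno, xyz)
    l2 <- .pdb_atom_line(serial + 1L, "CB", "GLY", chain, resno,
                         xyz + c(0, 1.5, 0))
    serial <<- serial + 2L
    c(l1, l2)
  }
  for (i in seq_len(n_per_domain))
    lines <- c(lines, emit(d1[i, ], "A", i))
  if (include_linker)
    for (i in seq_len(linker_len))
      lines <- c(lines, emit(lk[i, ], "L", i))
  for (i in seq_len(n_per_domain))
    lines <- c(lines, emit(d2[i, ], "B", i))
  c(lines, "TER", "END")
}

#' Build a propagation network directly from an edge list
#'
#' Bypasses structure parsing for engine tests and abstract topologies
#' (chains, stars, cycles). Edges are undirected unless `directed = TRUE`.
#'
#' @param edges Matrix or data frame with columns (i, j, P); probabilities in
#'   `[0, 1)`. May have zero rows.
#' @param n_nodes Number of nodes (default: largest index mentioned).
#' @param directed Treat rows as directed edges (default `FALSE`).
#' @return A `prop_matrix`.
#' @examples
#' star <- make_network(cbind(1, 2:5, 0.5))
#' aci_profile(star, source = 1, n_rounds = 1000, seed = 1)
#' @export
make_network <- function(edges, n_nodes = NULL, directed = FALSE) {
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 3)
    stop("edges must have three columns: i, j, P")
  n <- if (is.null(n_nodes)) {
    if (nrow(edges)) max(edges[, 1:2]) else 0L
  } else n_nodes
  if (n < 1) stop("network must have at least one node")
  probs <- matrix(0, n, n, dimnames = list(as.character(seq_len(n)),
                                           as.character(seq_len(n))))
  if (nrow(edges)) {
    p <- edges[, 3]
    if (any(p < 0 | p >= 1))
      stop("edge probabilities must lie in [0, 1)")
    probs[edges[, 1:2, drop = FALSE]] <- p
    if (!directed) probs[edges[, c(2, 1), drop = FALSE]] <- p
  }
  .new_prop_matrix(probs)
}

#' Read/write a network as an edge-list CSV
#'
#' @param net A `prop_matrix`.
#' @param file CSV path.
#' @return `write_network` returns `file` invisibly; `read_network` returns
#'   the reconstructed `prop_matrix`.
#' @export
write_network <- function(net, file) {
  stopifnot(inherits(net, "prop_matrix"))
  idx <- which(net$probs > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  tab <- data.frame(i = idx[, 1], j = idx[, 2], P = net$probs[idx])
  utils::write.csv(cbind(tab, n_nodes = nrow(net$probs)), file,
                   row.names = FALSE)
  invisible(file)
}

#' @rdname write_network
#' @export
read_network <- function(file) {
  tab <- utils::read.csv(file)
  make_network(as.matrix(tab[, c("i", "j", "P")]),
               n_nodes = tab$n_nodes[1], directed = TRUE)
}
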