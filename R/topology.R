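#' Atom addresses
#'
#' Every atom used by the analyses is addressed as
#' `"monomer:residue_number:atom_name"`, e.g. `"B:405:NH1"` for the NH1 atom
#' of residue 405 in monomer B.  Residue numbers are taken verbatim from the
#' input (2P0M numbering for rabbit ALOX15); no renumbering is ever applied.
#'
#' @param monomer chain / monomer label (e.g. `"A"`, `"B"`).
#' @param resnum integer residue number.
#' @param atom atom name string (e.g. `"CD2"`).
#' @return a single address string.
#' @examples
#' atom_address("B", 405, "NH1")
#' @export
atom_address <- function(monomer, resnum, atom) {
  paste(monomer, resnum, atom, sep = ":")
}

parse_address <- function(address) {
  parts <- strsplit(address, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 3L)
    stop("malformed atom address: '", address,
         "' (expected monomer:resnum:atom)", call. = FALSE)
  list(monomer = parts[[1L]], resnum = as.integer(parts[[2L]]),
       atom = parts[[3L]])
}

#' Construct a topology / selection specification
#'
#' A topology binds the atom table of a trajectory to the selections every
#' downstream analysis needs: the hydroxide oxygen of the Fe3+-OH cofactor,
#' the reactive (bisallylic) substrate carbon and its two prochiral
#' hydrogens, the substrate heavy atoms used for binding-mode clustering,
#' hydrogen-bond anchor donors/acceptors, helix segments and inter-monomer
#' contact pairs.
#'
#' `h_proS` / `h_proR` may be the sentinel `"AUTO"`, in which case
#' [assign_prochiral_hydrogens()] derives the labels geometrically; this
#' requires `bonds` covering the reactive carbon and `branch_priority`
#' naming which of its two carbon neighbours outranks the other.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resnum`, `monomer`.
#' @param cofactor_oxygen address of the iron-bound hydroxide oxygen.
#' @param reactive_carbon address of the bisallylic carbon (C13 for
#'   arachidonic acid, C11 for linoleic acid).
#' @param h_proS,h_proR addresses of the prochiral hydrogens, or `"AUTO"`.
#' @param iron optional address of the catalytic iron.
#' @param substrate_heavy_atoms character vector of addresses.
#' @param carboxylate_oxygens character vector of addresses.
#' @param anchor_donors list of `c(donor_heavy_atom, bonded_hydrogen)`
#'   address pairs.
#' @param anchor_acceptors character vector of addresses.
#' @param helix_segments named list; each element a list with `monomer`,
#'   `from`, `to` (residue range).
#' @param interface_pairs list of `c(address, address)` contact pairs.
#' @param bonds list of `c(address, address)` covalent bonds (only needed
#'   for `AUTO` prochiral assignment).
#' @param branch_priority address of the higher-priority carbon neighbour of
#'   `reactive_carbon` (required for `AUTO`).
#' @return an object of class `lox_topology`.
#' @seealso [read_topology_config()]
#' @export
topology_spec <- function(atoms,
                          cofactor_oxygen = NULL,
                          reactive_carbon = NULL,
                          h_proS = NULL,
                          h_proR = NULL,
                          iron = NULL,
                          substrate_heavy_atoms = character(),
                          carboxylate_oxygens = character(),
                          anchor_donors = list(),
                          anchor_acceptors = character(),
                          helix_segments = list(),
                          interface_pairs = list(),
                          bonds = list(),
                          branch_priority = NULL) {
  required <- c("serial", "name", "element", "resname", "resnum", "monomer")
  if (!is.data.frame(atoms) || !all(required %in% names(atoms)))
    stop("atoms must be a data.frame with columns ",
         paste(required, collapse = ", "), call. = FALSE)
  atoms <- as.data.frame(atoms)[, required]
  atoms$serial <- as.integer(atoms$serial)
  atoms$resnum <- as.integer(atoms$resnum)
  if (anyDuplicated(atoms$serial))
    stop("atom serial numbers must be unique", call. = FALSE)
  key <- paste(atoms$monomer, atoms$resnum, atoms$name, sep = ":")
  if (anyDuplicated(key))
    stop("duplicate (monomer, residue_number, atom_name) in topology: ",
         key[anyDuplicated(key)][1L], call. = FALSE)
  if (!is.null(h_proS) && !is.null(h_proR) &&
      !identical(h_proS, "AUTO") && identical(h_proS, h_proR))
    stop("h_proS and h_proR must differ", call. = FALSE)

  top <- structure(
    list(atoms = atoms,
         address = key,
         cofactor_oxygen = cofactor_oxygen,
         reactive_carbon = reactive_carbon,
         h_proS = h_proS,
         h_proR = h_proR,
         iron = iron,
         substrate_heavy_atoms = substrate_heavy_atoms,
         carboxylate_oxygens = carboxylate_oxygens,
         anchor_donors = anchor_donors,
         anchor_acceptors = anchor_acceptors,
         helix_segments = helix_segments,
         interface_pairs = interface_pairs,
         bonds = bonds,
         branch_priority = branch_priority),
    class = "lox_topology")

  # fail early on dangling references
  fixed <- c(cofactor_oxygen, reactive_carbon, iron, branch_priority,
             substrate_heavy_atoms, carboxylate_oxygens, anchor_acceptors,
             unlist(anchor_donors), unlist(interface_pairs), unlist(bonds))
  fixed <- setdiff(fixed, "AUTO")
  for (a in c(fixed,
              if (!identical(h_proS, "AUTO")) c(h_proS, h_proR)))
    resolve_address(top, a)
  top
}

#' Resolve an atom address against a topology
#'
#' @param topology a `lox_topology`.
#' @param address address string (see [atom_address()]).
#' @return the (1-based) row index of the atom in the topology's atom table.
#' @export
resolve_address <- function(topology, address) {
  stopifnot(inherits(topology, "lox_topology"))
  idx <- match(address, topology$address)
  if (is.na(idx))
    stop("unresolved atom address: '", address, "'", call. = FALSE)
  idx
}

resolve_addresses <- function(topology, addresses) {
  vapply(addresses, resolve_address, integer(1L), topology = topology,
         USE.NAMES = FALSE)
}

#' @export
print.lox_topology <- function(x, ...) {
  cat("<lox_topology> ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$monomer)), " monomer(s)\n", sep = "")
  if (!is.null(x$reactive_carbon))
    cat("  reactive carbon: ", x$reactive_carbon,
        "  cofactor O: ", x$cofactor_oxygen, "\n", sep = "")
  invisible(x)
}

#' Read a topology / selection configuration file
#'
#' The configuration is a YAML (or JSON) document with an `atoms` table and
#' the selection fields of [topology_spec()].  All selections are written as
#' `monomer:resnum:atom` addresses.  Unknown top-level keys are rejected so
#' that typos do not silently disable an analysis.
#'
#' When the config is paired with a PDB file via [read_multimodel_pdb()],
#' the `atoms` table may be omitted: it is then taken from the PDB records.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @param atoms optional atom table overriding / replacing the one in the
#'   file (used by the PDB reader).
#' @return a `lox_topology`.
#' @export
read_topology_config <- function(path, atoms = NULL) {
  if (!file.exists(path))
    stop("topology config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)

  known <- c("atoms", "cofactor_oxygen", "reactive_carbon", "h_proS",
             "h_proR", "iron", "substrate_heavy_atoms",
             "carboxylate_oxygens", "anchor_donors", "anchor_acceptors",
             "helix_segments", "interface_pairs", "bonds",
             "branch_priority")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown topology config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  if (is.null(atoms)) {
    if (is.null(cfg$atoms))
      stop("topology config has no atoms table and none was supplied",
           call. = FALSE)
    atoms <- as.data.frame(cfg$atoms)
  }
  pair_list <- function(x) {
    if (is.null(x)) return(list())
    if (is.data.frame(x)) x <- as.matrix(x)
    if (is.matrix(x)) return(lapply(seq_len(nrow(x)), function(i) x[i, ]))
    lapply(x, unlist)
  }
  topology_spec(
    atoms = atoms,
    cofactor_oxygen = cfg$cofactor_oxygen,
    reactive_carbon = cfg$reactive_carbon,
    h_proS = cfg$h_proS,
    h_proR = cfg$h_proR,
    iron = cfg$iron,
    substrate_heavy_atoms = unlist(cfg$substrate_heavy_atoms) %||% character(),
    carboxylate_oxygens = unlist(cfg$carboxylate_oxygens) %||% character(),
    anchor_donors = pair_list(cfg$anchor_donors),
    anchor_acceptors = unlist(cfg$anchor_acceptors) %||% character(),
    helix_segments = cfg$helix_segments %||% list(),
    interface_pairs = pair_list(cfg$interface_pairs),
    bonds = pair_list(cfg$bonds),
    branch_priority = cfg$branch_priority)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
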