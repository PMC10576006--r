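#' Specify one planted inter-chain contact for the toy-structure generator
#'
#' @param res_name_a,res_name_b three-letter residue names.
#' @param atom_a,atom_b atom names placed at the target distance.
#' @param distance target atom-atom distance, Angstrom.
#' @param res_id_a,res_id_b residue numbers.
#' @param chain_a,chain_b chain ids.
#' @return list of class `planted_contact`.
#' @export
planted_contact <- function(res_name_a, atom_a, res_name_b, atom_b, distance,
                            res_id_a, res_id_b,
                            chain_a = "A", chain_b = "B") {
  structure(list(res_name_a = res_name_a, atom_a = atom_a,
                 res_name_b = res_name_b, atom_b = atom_b,
                 distance = distance, res_id_a = res_id_a,
                 res_id_b = res_id_b, chain_a = chain_a, chain_b = chain_b),
            class = "planted_contact")
}

#' Generate a toy two-chain structure with planted contacts
#'
#' Each planted contact is realised as a minimal residue pair across the two
#' chains: the named atoms sit on a common axis at exactly the target
#' distance, with a CA atom 3 A behind each so residues are recognisable.
#' Successive plants are spaced 20 A apart so they cannot contact each
#' other. The emitted PDB text parses back to atoms whose pairwise distances
#' match the specification within 0.01 A (PDB coordinate precision is 3
#' decimals). Overlapping atoms (< 1 A) are rejected.
#'
#' @param plants list of [planted_contact()]s; empty list gives a valid file
#'   with zero atoms.
#' @return PDB-format text (character scalar).
#' @export
gen_toy_interface <- function(plants = list()) {
  if (!length(plants)) return("END")
  rows <- list()
  serial <- 0
  for (i in seq_along(plants)) {
    p <- plants[[i]]
    if (p$distance < 1.0)
      stop("planted atoms closer than 1.0 A would overlap")
    y <- 20 * (i - 1)
    add <- function(chain, resid, resname, atom, x) {
      rows[[length(rows) + 1]] <<- data.frame(
        chain = chain, residue_id = resid, icode = "",
        residue_name = resname, atom_name = atom, altloc = "",
        element = substr(gsub("[0-9]", "", atom), 1, 1),
        x = x, y = y, z = 0, occupancy = 1)
    }
    add(p$chain_a, p$res_id_a, p$res_name_a, "CA", -3)
    add(p$chain_a, p$res_id_a, p$res_name_a, p$atom_a, 0)
    add(p$chain_b, p$res_id_b, p$res_name_b, p$atom_b, p$distance)
    add(p$chain_b, p$res_id_b, p$res_name_b, "CA", p$distance + 3)
  }
  atoms <- do.call(rbind, rows)
  # reject accidental overlaps anywhere in the assembly
  d <- as.matrix(stats::dist(atoms[, c("x", "y", "z")]))
  diag(d) <- Inf
  if (any(d < 1.0)) stop("generated structure contains overlapping atoms")
  write_pdb(structure(list(atoms = atoms, model_id = 1),
                      class = "coordinate_set"))
}
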