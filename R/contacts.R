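# Atom typing for contact classes. Apolar side-chain atoms are C/S atoms not
# bonded to N or O (LIGPLOT-style); the table is explicit per residue so the
# definition is auditable.
.carboxylate_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.basic_n_atoms <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
                       HIS = c("ND1", "NE2"))
.apolar_atoms <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"), LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"), PRO = c("CB", "CG", "CD"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  THR = "CG2", LYS = c("CB", "CG", "CD"), ARG = c("CB", "CG"),
  GLU = c("CB", "CG"), GLN = c("CB", "CG"), ASP = "CB", ASN = "CB",
  HIS = "CB", SER = "CB", CYS = c("CB", "SG"))

#' Default contact criteria (Angstrom)
#'
#' LIGPLOT-style cutoffs: hydrogen bond 3.35 (donor/acceptor heavy atoms),
#' salt bridge 4.0 (carboxylate O to basic N), hydrophobic 3.9 (apolar C/S
#' side-chain pairs).
#' @return named numeric vector.
#' @export
contact_criteria <- function(hbond = 3.35, salt_bridge = 4.0,
                             hydrophobic = 3.9) {
  c(hbond = hbond, salt_bridge = salt_bridge, hydrophobic = hydrophobic)
}

.is_polar_heavy <- function(atoms) atoms$element %in% c("N", "O")

.is_carboxylate_o <- function(atoms) {
  mapply(function(rn, an) an %in% (.carboxylate_atoms[[rn]] %||% character(0)),
         atoms$residue_name, atoms$atom_name, USE.NAMES = FALSE)
}

.is_basic_n <- function(atoms) {
  mapply(function(rn, an) an %in% (.basic_n_atoms[[rn]] %||% character(0)),
         atoms$residue_name, atoms$atom_name, USE.NAMES = FALSE)
}

.is_apolar <- function(atoms) {
  mapply(function(rn, an) an %in% (.apolar_atoms[[rn]] %||% character(0)),
         atoms$residue_name, atoms$atom_name, USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect inter-chain contacts
#'
#' All atom pairs between the two chain selections are classified as
#' `salt_bridge` (carboxylate O of Asp/Glu to Lys NZ / Arg NH*,NE / His ring
#' N within 4.0 A), `hbond` (N/O to N/O within 3.35 A) or `hydrophobic`
#' (apolar side-chain C/S pair within 3.9 A). A pair qualifying for several
#' classes reports only its most specific one (salt_bridge > hbond >
#' hydrophobic). Symmetric in the two selections up to pair ordering.
#'
#' @param coords a `coordinate_set`.
#' @param chains_a,chains_b non-overlapping chain id vectors.
#' @param criteria cutoffs from [contact_criteria()].
#' @return object of class `contact_set`: data.frame `contacts` with columns
#'   `chain_a`, `res_a`, `resname_a`, `atom_a`, `chain_b`, `res_b`,
#'   `resname_b`, `atom_b`, `distance`, `class`.
#' @export
detect_contacts <- function(coords, chains_a, chains_b,
                            criteria = contact_criteria()) {
  a <- coords$atoms[coords$atoms$chain %in% chains_a, , drop = FALSE]
  b <- coords$atoms[coords$atoms$chain %in% chains_b, , drop = FALSE]
  if (length(intersect(chains_a, chains_b)))
    stop("chain selections must not overlap")
  if (nrow(coords$atoms) > 0 && (nrow(a) == 0 || nrow(b) == 0))
    stop("empty chain selection")
  empty <- data.frame(chain_a = character(0), res_a = integer(0),
                      resname_a = character(0), atom_a = character(0),
                      chain_b = character(0), res_b = integer(0),
                      resname_b = character(0), atom_b = character(0),
                      distance = double(0), class = character(0))
  if (nrow(a) == 0 || nrow(b) == 0)
    return(structure(list(contacts = empty, criteria = criteria),
                     class = "contact_set"))
  dx <- outer(a$x, b$x, "-"); dy <- outer(a$y, b$y, "-")
  dz <- outer(a$z, b$z, "-")
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  maxcut <- max(criteria)
  hits <- which(dist <= maxcut, arr.ind = TRUE)
  if (!nrow(hits))
    return(structure(list(contacts = empty, criteria = criteria),
                     class = "contact_set"))
  ia <- hits[, 1]; ib <- hits[, 2]; d <- dist[hits]
  sb <- ((.is_carboxylate_o(a)[ia] & .is_basic_n(b)[ib]) |
         (.is_basic_n(a)[ia] & .is_carboxylate_o(b)[ib])) &
        d <= criteria[["salt_bridge"]]
  hb <- .is_polar_heavy(a)[ia] & .is_polar_heavy(b)[ib] &
        d <= criteria[["hbond"]]
  hp <- .is_apolar(a)[ia] & .is_apolar(b)[ib] &
        d <= criteria[["hydrophobic"]]
  cls <- ifelse(sb, "salt_bridge", ifelse(hb, "hbond",
                ifelse(hp, "hydrophobic", NA_character_)))
  keep <- !is.na(cls)
  contacts <- data.frame(
    chain_a = a$chain[ia][keep], res_a = a$residue_id[ia][keep],
    resname_a = a$residue_name[ia][keep], atom_a = a$atom_name[ia][keep],
    chain_b = b$chain[ib][keep], res_b = b$residue_id[ib][keep],
    resname_b = b$residue_name[ib][keep], atom_b = b$atom_name[ib][keep],
    distance = d[keep], class = cls[keep])
  contacts <- contacts[order(contacts$res_a, contacts$res_b,
                             contacts$atom_a, contacts$atom_b), ]
  rownames(contacts) <- NULL
  structure(list(contacts = contacts, criteria = criteria),
            class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("<contact_set> %d contacts (%s)\n", nrow(x$contacts),
              paste(sprintf("%s=%d", names(table(x$contacts$class)),
                            table(x$contacts$class)), collapse = ", ")))
  invisible(x)
}

#' Interface residue sets per chain
#'
#' Union of residues appearing in any contact, per chain, sorted by residue
#' number.
#'
#' @param contacts a `contact_set`.
#' @return named list of integer residue vectors, one per chain.
#' @export
interface_residues <- function(contacts) {
  df <- contacts$contacts
  chains <- sort(unique(c(df$chain_a, df$chain_b)))
  out <- lapply(chains, function(ch) {
    sort(unique(c(df$res_a[df$chain_a == ch], df$res_b[df$chain_b == ch])))
  })
  stats::setNames(out, chains)
}

#' Overlap between structural interface residues and NMR perturbation classes
#'
#' Compares an interface residue set with the residues a classified CSP
#' profile marks perturbed (shifted/attenuated/enhanced), reporting the
#' intersection, each side's exclusives, and the Jaccard index.
#'
#' @param interface integer residue numbers at the structural interface
#'   (same numbering as the CSP profile, asserted by the caller).
#' @param csp classified `csp_profile` ([classify_residues()]).
#' @param what classes counted as perturbed.
#' @return list with `n_interface`, `n_perturbed`, `both`,
#'   `interface_only`, `perturbed_only`, `jaccard`, `notes`.
#' @export
csp_overlap <- function(interface, csp,
                        what = c("shifted", "attenuated", "enhanced")) {
  pert <- perturbed_residues(csp, what)
  interface <- sort(unique(as.integer(interface)))
  notes <- character(0)
  if (length(interface) && nrow(csp) &&
      (max(interface) < min(csp$residue) || min(interface) > max(csp$residue)))
    notes <- "interface and CSP residue ranges are disjoint: numbering mismatch?"
  un <- union(interface, pert)
  list(n_interface = length(interface), n_perturbed = length(pert),
       both = intersect(interface, pert),
       interface_only = setdiff(interface, pert),
       perturbed_only = setdiff(pert, interface),
       jaccard = if (length(un)) length(intersect(interface, pert)) / length(un)
                 else NA_real_,
       notes = notes)
}

#' Write contacts as TSV
#'
#' Columns: chainA, resA, atomA, chainB, resB, atomB, distance_A, class.
#' @param contacts a `contact_set`.
#' @param path output path.
#' @export
write_contacts <- function(contacts, path) {
  df <- contacts$contacts
  out <- data.frame(chainA = df$chain_a, resA = df$res_a, atomA = df$atom_a,
                    chainB = df$chain_b, resB = df$res_b, atomB = df$atom_b,
                    distance_A = round(df$distance, 3), class = df$class)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
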