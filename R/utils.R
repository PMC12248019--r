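# Shared vocabularies and small helpers.

RNA_RESNAMES <- c("A", "C", "G", "U", "N")
DNA_RESNAMES <- c("DA", "DC", "DG", "DT", "DN")
AA_RESNAMES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

# van der Waals radii (Angstrom) for the steric-clash rule
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80, H = 1.20)

#' @keywords internal
polymer_type_of <- function(resname) {
  ifelse(resname %in% RNA_RESNAMES, "RNA",
         ifelse(resname %in% DNA_RESNAMES, "DNA",
                ifelse(resname %in% AA_RESNAMES, "protein", "ligand")))
}

# representative atom name for a polymer type
rep_atom_for <- function(polymer_type) {
  ifelse(polymer_type %in% c("RNA", "DNA"), "C4'",
         ifelse(polymer_type == "protein", "CA", NA_character_))
}

# unique residue key "chain|resno|insert"
residue_key <- function(chain, resno, insert = "") {
  insert <- ifelse(is.na(insert), "", insert)
  paste(chain, resno, insert, sep = "|")
}

# canonical unordered pair id from two residue keys (global order applied)
pair_id <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "--")
}

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.7
  unname(r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
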