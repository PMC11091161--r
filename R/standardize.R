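#' Standardization policy
#'
#' @param drop_zero_occupancy also drop atoms with occupancy 0 (a pragmatic
#'   stand-in for removing disordered elements from reference structures;
#'   off by default).
#' @return a `StandardizePolicy` list.
#' @export
standardize_policy <- function(drop_zero_occupancy = FALSE) {
  list(drop_zero_occupancy = isTRUE(drop_zero_occupancy))
}

#' Reduce a structure to clean canonical heavy atoms
#'
#' Removes hydrogens (and deuterium), waters, hetero and non-canonical
#' residues (e.g. MSE is dropped, not remapped), and collapses alternate
#' locations to the highest-occupancy conformer (ties broken by the
#' lexicographically first altloc id). Duplicate atoms within a residue
#' (same name after altloc collapse) keep their first occurrence. The result
#' contains at most one atom per (residue, atom name) and only heavy atoms
#' of the 20 canonical amino acids.
#'
#' Idempotent: standardizing a standardized structure is a no-op.
#'
#' @param s a `locohd_structure`.
#' @param policy a [standardize_policy()].
#' @return a new `locohd_structure`.
#' @export
standardize <- function(s, policy = standardize_policy()) {
  a <- as.data.frame(s)
  keep <- is_canonical_aa(a$resname) &
    !(toupper(a$element) %in% c("H", "D")) &
    !grepl("^[0-9]*[HD]", a$atom_name)
  if (policy$drop_zero_occupancy) keep <- keep & a$occupancy > 0
  a <- a[keep, , drop = FALSE]
  if (!nrow(a)) stop_empty("no canonical heavy atoms remain after standardization")

  # altloc collapse: within (residue, atom name) keep max occupancy,
  # tie-break lexicographically smallest altloc, then file order
  a$.ord <- seq_len(nrow(a))
  id <- paste(a$res_key, a$atom_name, sep = "@")
  a <- a[order(id, -a$occupancy, a$altloc, a$.ord), , drop = FALSE]
  a <- a[!duplicated(paste(a$res_key, a$atom_name, sep = "@")), , drop = FALSE]
  a <- a[order(a$.ord), , drop = FALSE]  # restore file order
  a$.ord <- NULL
  a$altloc <- ""
  a$occupancy <- 1
  new_structure(a, attr(s, "model_id"))
}
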