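#' Pair chains of two structures by sequence alignment
#'
#' Every reference chain is globally aligned against every model chain
#' (match +1, mismatch -1, gap -2); chains are then assigned greedily by
#' descending alignment score. Aligned positions where both residues are
#' present and share the same residue name become mapping pairs, so the
#' mapping is injective in both directions and type-consistent by
#' construction. Chain renames and truncations are therefore recovered
#' automatically.
#'
#' @param reference,model standardized `locohd_structure`s.
#' @param min_identity minimum fractional identity (matches over the shorter
#'   chain length) for a chain pair to be accepted; default 0.3.
#' @return data frame with columns `ref_key`, `model_key`, `ref_chain`,
#'   `model_chain` (class `locohd_chain_mapping`).
#' @export
pair_chains <- function(reference, model, min_identity = 0.3) {
  ref_chains <- unique(reference$chain)
  mod_chains <- unique(model$chain)
  sub_mat <- {
    letters20 <- unname(AA1)
    m <- matrix(-1, 20, 20, dimnames = list(letters20, letters20))
    diag(m) <- 1
    m
  }
  cand <- expand.grid(rc = ref_chains, mc = mod_chains,
                      stringsAsFactors = FALSE)
  aligns <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    sr <- chain_sequence(reference, cand$rc[i])
    sm <- chain_sequence(model, cand$mc[i])
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(sr), Biostrings::AAString(sm),
      substitutionMatrix = sub_mat, gapOpening = 0, gapExtension = 2,
      type = "global")
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    q <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    nmatch <- sum(p == q & p != "-")
    aligns[[i]] <- list(score = Biostrings::score(aln), p = p, q = q,
                        identity = nmatch / min(nchar(sr), nchar(sm)))
  }
  cand$score <- vapply(aligns, `[[`, 0, "score")
  cand$identity <- vapply(aligns, `[[`, 0, "identity")

  # greedy assignment by descending score among pairs above the threshold
  ord <- order(-cand$score)
  used_r <- character(0); used_m <- character(0)
  pairs <- list()
  for (i in ord) {
    if (cand$identity[i] < min_identity) next
    if (cand$rc[i] %in% used_r || cand$mc[i] %in% used_m) next
    used_r <- c(used_r, cand$rc[i]); used_m <- c(used_m, cand$mc[i])
    pairs[[length(pairs) + 1L]] <- i
  }
  if (!length(pairs)) {
    stop_domain("no chain pair reaches identity %.2f; chains cannot be paired",
                min_identity)
  }

  rows <- list()
  for (i in unlist(pairs)) {
    a <- aligns[[i]]
    rk <- residue_keys_of_chain(reference, cand$rc[i])
    mk <- residue_keys_of_chain(model, cand$mc[i])
    ri <- 0L; mi <- 0L
    for (k in seq_along(a$p)) {
      if (a$p[k] != "-") ri <- ri + 1L
      if (a$q[k] != "-") mi <- mi + 1L
      if (a$p[k] != "-" && a$q[k] != "-" && a$p[k] == a$q[k]) {
        rows[[length(rows) + 1L]] <-
          data.frame(ref_key = rk[ri], model_key = mk[mi],
                     ref_chain = cand$rc[i], model_chain = cand$mc[i],
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("locohd_chain_mapping", "data.frame")
  out
}

residue_keys_of_chain <- function(s, chain) {
  unique(s$res_key[s$chain == chain])
}

#' Restrict two structures to their common residues and atoms
#'
#' Both outputs contain exactly the mapped residues, and within each mapped
#' residue the intersection of the two atom-name sets, in identical
#' corresponding order (reference residue order, reference atom order).
#'
#' @param reference,model standardized `locohd_structure`s.
#' @param mapping a [pair_chains()] mapping valid for both.
#' @return list with elements `reference` and `model`.
#' @export
prune_to_common <- function(reference, model, mapping) {
  ref_rows <- list(); mod_rows <- list()
  for (i in seq_len(nrow(mapping))) {
    ra <- reference[reference$res_key == mapping$ref_key[i], , drop = FALSE]
    ma <- model[model$res_key == mapping$model_key[i], , drop = FALSE]
    common <- intersect(ra$atom_name, ma$atom_name)
    if (!length(common)) next
    ra <- ra[match(common, ra$atom_name), , drop = FALSE]
    ma <- ma[match(common, ma$atom_name), , drop = FALSE]
    ref_rows[[length(ref_rows) + 1L]] <- ra
    mod_rows[[length(mod_rows) + 1L]] <- ma
  }
  if (!length(ref_rows)) stop_empty("no common atoms between the two structures")
  list(reference = new_structure(do.call(rbind, ref_rows), attr(reference, "model_id")),
       model = new_structure(do.call(rbind, mod_rows), attr(model, "model_id")))
}
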