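# Primitive typing schemes: FA, CG, FA+Cent, CG+Cent.
#
# A scheme maps a standardized structure to a "primitive atom cloud": a set
# of labeled points. FA types every heavy atom individually from a 7-label
# chemical alphabet (O_neg, O_neu, N_pos, N_neu, C_ali, C_aro, S); CG
# replaces chemical groups by single sites from its own 7-label alphabet
# (AmideC, OH, Pos, Neg, Aro, Ali, S), some of them group centroids. The
# "+Cent" variants add one Cent pseudo-atom per residue at the heavy-atom
# geometric center. Rule tables live in plain-text config files under
# inst/extdata and can be overridden wholesale via `scheme_file`.

SCHEME_NAMES <- c("FA", "CG", "FA+Cent", "CG+Cent")

FA_TYPE_SET <- c("O_neg", "O_neu", "N_pos", "N_neu", "C_ali", "C_aro", "S")
CG_TYPE_SET <- c("AmideC", "OH", "Pos", "Neg", "Aro", "Ali", "S")

read_scheme_rules <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^\\s*(#|$)", raw)]
  tab <- utils::read.delim(text = paste(raw, collapse = "\n"),
                           stringsAsFactors = FALSE)
  needed <- c("residue", "ptype", "mode", "atoms")
  if (!all(needed %in% names(tab))) {
    stop_config("scheme file %s lacks columns %s", path,
                paste(setdiff(needed, names(tab)), collapse = ", "))
  }
  tab
}

scheme_base_file <- function(base) {
  system.file("extdata",
              if (base == "FA") "typing_fa.tsv" else "typing_cg.tsv",
              package = "locohd", mustWork = TRUE)
}

#' Inspect a primitive typing scheme
#'
#' Returns the full declarative rule table of a scheme together with its
#' ordered primitive type set, so the mapping is inspectable, testable and
#' serializable.
#'
#' @param scheme_name one of `"FA"`, `"CG"`, `"FA+Cent"`, `"CG+Cent"`.
#' @param scheme_file optional path to an alternative rule table (same
#'   format as the packaged ones) replacing the base FA/CG rules.
#' @return list with elements `name`, `base` (FA or CG), `has_cent`,
#'   `type_set` (ordered), `rules` (data frame).
#' @export
list_scheme <- function(scheme_name, scheme_file = NULL) {
  if (!scheme_name %in% SCHEME_NAMES) {
    stop_config("unknown typing scheme '%s' (choose from %s)",
                scheme_name, paste(SCHEME_NAMES, collapse = ", "))
  }
  base <- if (startsWith(scheme_name, "FA")) "FA" else "CG"
  has_cent <- grepl("\\+Cent$", scheme_name)
  rules <- read_scheme_rules(
    if (is.null(scheme_file)) scheme_base_file(base) else scheme_file)
  type_set <- if (base == "FA") FA_TYPE_SET else CG_TYPE_SET
  extra <- setdiff(unique(rules$ptype), c(type_set, "Cent"))
  if (length(extra)) type_set <- c(type_set, sort(extra))  # user tables may extend
  if (has_cent) type_set <- c(type_set, "Cent")
  list(name = scheme_name, base = base, has_cent = has_cent,
       type_set = type_set, rules = rules)
}

new_cloud <- function(ptype, x, y, z, res_key, scheme, type_set,
                      provenance = NA_character_) {
  cloud <- data.frame(ptype = ptype, x = x, y = y, z = z, res_key = res_key,
                      stringsAsFactors = FALSE)
  structure(cloud, scheme = scheme, type_set = type_set,
            provenance = provenance,
            class = c("locohd_cloud", "data.frame"))
}

#' @export
print.locohd_cloud <- function(x, ...) {
  cat(sprintf("<locohd_cloud> scheme %s: %d primitive atoms, %d residues\n",
              attr(x, "scheme"), nrow(x), length(unique(x$res_key))))
  invisible(x)
}

#' Map a standardized structure to a primitive atom cloud
#'
#' Applies a typing scheme. FA emits one primitive atom per heavy atom and
#' fails loudly on any uncovered atom; CG emits atom-wise and group-centroid
#' sites per its rule table and silently omits uncovered atoms (that is part
#' of the scheme definition). Group sites are computed from the member atoms
#' actually present (at least one), which keeps truncated side chains usable;
#' such incomplete groups are reported via a message. `+Cent` schemes append
#' one Cent site per residue at its heavy-atom centroid. Output order is
#' deterministic: residues in file order, primitives in rule order within a
#' residue, Cent last.
#'
#' @param s a standardized `locohd_structure`.
#' @param scheme_name scheme name (see [list_scheme()]).
#' @param scheme_file optional rule-table override.
#' @return a `locohd_cloud` data frame (`ptype`, `x`, `y`, `z`, `res_key`)
#'   with attributes `scheme`, `type_set`, `provenance`.
#' @export
apply_scheme <- function(s, scheme_name, scheme_file = NULL) {
  sch <- list_scheme(scheme_name, scheme_file)
  keys <- residue_keys(s)
  out_ptype <- character(0); out_xyz <- list(); out_key <- character(0)
  incomplete <- character(0)

  # pre-index rules: exact (residue|atom) and wildcard (*|atom) atom rules
  atom_rules <- sch$rules[sch$rules$mode == "atom", , drop = FALSE]
  group_rules <- sch$rules[sch$rules$mode == "group", , drop = FALSE]
  atom_lut <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(atom_rules))) {
    for (a in strsplit(atom_rules$atoms[i], ",", fixed = TRUE)[[1L]]) {
      assign(paste(atom_rules$residue[i], a, sep = "|"),
             atom_rules$ptype[i], envir = atom_lut)
    }
  }
  lookup_atom <- function(resname, atom) {
    k1 <- paste(resname, atom, sep = "|")
    if (!is.null(v <- atom_lut[[k1]])) return(v)
    atom_lut[[paste("*", atom, sep = "|")]]
  }

  for (key in keys) {
    res <- s[s$res_key == key, , drop = FALSE]
    resname <- res$resname[1L]
    has_oxt <- "OXT" %in% res$atom_name

    if (sch$base == "FA") {
      for (j in seq_len(nrow(res))) {
        atom <- res$atom_name[j]
        pt <- if (has_oxt && atom %in% c("O", "OXT")) "O_neg" else
          lookup_atom(resname, atom)
        if (is.null(pt)) {
          stop_config("FA typing: no rule covers atom %s of residue %s",
                      atom, key)
        }
        out_ptype <- c(out_ptype, pt)
        out_xyz[[length(out_xyz) + 1L]] <- c(res$x[j], res$y[j], res$z[j])
        out_key <- c(out_key, key)
      }
    } else {
      emit <- function(pt, xyz) {
        out_ptype <<- c(out_ptype, pt)
        out_xyz[[length(out_xyz) + 1L]] <<- xyz
        out_key <<- c(out_key, key)
      }
      # atom-mode rules, residue-specific and wildcard, in table order
      for (i in seq_len(nrow(atom_rules))) {
        if (!atom_rules$residue[i] %in% c("*", resname)) next
        for (a in strsplit(atom_rules$atoms[i], ",", fixed = TRUE)[[1L]]) {
          j <- match(a, res$atom_name)
          if (is.na(j)) next
          # wildcard rule suppressed when a residue-specific rule names the atom
          if (atom_rules$residue[i] == "*" &&
              !is.null(atom_lut[[paste(resname, a, sep = "|")]])) next
          emit(atom_rules$ptype[i], c(res$x[j], res$y[j], res$z[j]))
        }
      }
      for (i in seq_len(nrow(group_rules))) {
        if (!group_rules$residue[i] %in% c("*", resname)) next
        members <- strsplit(group_rules$atoms[i], ",", fixed = TRUE)[[1L]]
        j <- match(members, res$atom_name)
        present <- j[!is.na(j)]
        if (!length(present)) next
        if (length(present) < length(members)) {
          incomplete <- c(incomplete, sprintf("%s %s", key, group_rules$ptype[i]))
        }
        emit(group_rules$ptype[i],
             c(mean(res$x[present]), mean(res$y[present]), mean(res$z[present])))
      }
      if (has_oxt) {
        j <- match(c("O", "OXT"), res$atom_name)
        j <- j[!is.na(j)]
        emit("Neg", c(mean(res$x[j]), mean(res$y[j]), mean(res$z[j])))
      }
    }

    if (sch$has_cent) {
      out_ptype <- c(out_ptype, "Cent")
      out_xyz[[length(out_xyz) + 1L]] <-
        c(mean(res$x), mean(res$y), mean(res$z))
      out_key <- c(out_key, key)
    }
  }
  if (length(incomplete)) {
    message("apply_scheme: group sites from incomplete atom groups: ",
            paste(incomplete, collapse = "; "))
  }
  xyz <- do.call(rbind, out_xyz)
  new_cloud(out_ptype, xyz[, 1L], xyz[, 2L], xyz[, 3L], out_key,
            sch$name, sch$type_set,
            provenance = sprintf("model %s", attr(s, "model_id")))
}
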