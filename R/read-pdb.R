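#' Read a protein structure file
#'
#' Parses PDB (`ATOM`/`HETATM`/`MODEL`/`ENDMDL` records, fixed-width v3
#' columns) or mmCIF (`atom_site` loop). Multi-model files yield one
#' structure per model, in file order, so NMR ensembles and trajectory
#' frames exported as multi-model PDB come back as a list of frames.
#'
#' No chemical interpretation happens here: hydrogens, waters, altlocs and
#' hetero residues are all retained and left to [standardize()].
#'
#' @param path path to the file.
#' @param format one of `"auto"` (by extension, default), `"pdb"`, `"mmcif"`.
#' @return list of [new_structure()] objects, one per model.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     "pdb" = "pdb", "ent" = "pdb",
                     "cif" = "mmcif", "mmcif" = "mmcif",
                     stop_config("cannot infer format from extension '.%s' of %s",
                                 ext, path))
  }
  lines <- readLines(path, warn = FALSE)
  models <- if (format == "pdb") parse_pdb_lines(lines, path) else
    parse_mmcif_lines(lines, path)
  if (!length(models)) stop_parse("no atom records found in %s", path)
  models
}

parse_pdb_lines <- function(lines, path) {
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(lines, "MODEL")
  if (!any(is_atom)) return(list())

  # model id per line: 1 before any MODEL record, else the last MODEL seen
  model_no <- cumsum(is_model)
  model_ids <- rep(1L, length(lines))
  if (any(is_model)) {
    declared <- suppressWarnings(as.integer(substr(lines[is_model], 11L, 14L)))
    declared[is.na(declared)] <- seq_len(sum(is_model))[is.na(declared)]
    model_ids <- ifelse(model_no == 0L, declared[1L], declared[pmax(model_no, 1L)])
  }

  idx <- which(is_atom)
  ln <- lines[idx]
  num <- function(s, lo, hi, what) {
    v <- suppressWarnings(as.numeric(substr(s, lo, hi)))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop_parse("%s: unparsable %s in line %d: '%s'",
                 path, what, idx[bad[1L]], lines[idx[bad[1L]]])
    }
    v
  }
  occ <- suppressWarnings(as.numeric(substr(ln, 55L, 60L)))
  occ[!is.finite(occ)] <- 1
  atoms <- data.frame(
    chain = substr(ln, 22L, 22L),
    resnum = as.integer(num(ln, 23L, 26L, "residue number")),
    icode = trimws(substr(ln, 27L, 27L)),
    resname = trimws(substr(ln, 18L, 20L)),
    atom_name = trimws(substr(ln, 13L, 16L)),
    element = trimws(substr(ln, 77L, 78L)),
    altloc = trimws(substr(ln, 17L, 17L)),
    occupancy = occ,
    x = num(ln, 31L, 38L, "x coordinate"),
    y = num(ln, 39L, 46L, "y coordinate"),
    z = num(ln, 47L, 54L, "z coordinate"),
    stringsAsFactors = FALSE
  )
  atoms$element[atoms$element == ""] <- element_from_name(atoms$atom_name[atoms$element == ""])
  split_models(atoms, model_ids[idx])
}

split_models <- function(atoms, model_ids) {
  uniq <- unique(model_ids)
  lapply(uniq, function(m) new_structure(atoms[model_ids == m, , drop = FALSE], m))
}

# Minimal mmCIF reader: only the atom_site loop, whitespace-tokenized with
# single/double-quote support; multi-line (;) values are not expected in
# atom_site and are rejected.
parse_mmcif_lines <- function(lines, path) {
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (!length(hdr_idx)) return(list())
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  start <- max(hdr_idx) + 1L
  rows <- character(0)
  for (i in start:length(lines)) {
    l <- trimws(lines[i])
    if (l == "" ) next
    if (startsWith(l, "#") || startsWith(l, "_") || startsWith(l, "loop_") ||
        startsWith(l, "data_")) break
    if (startsWith(l, ";")) stop_parse("%s: multi-line atom_site values unsupported (line %d)", path, i)
    rows <- c(rows, l)
  }
  if (!length(rows)) return(list())
  toks <- lapply(rows, cif_tokens)
  nf <- length(fields)
  ok <- vapply(toks, length, 1L) == nf
  if (!all(ok)) {
    stop_parse("%s: atom_site row with %d fields, expected %d",
               path, length(toks[[which(!ok)[1L]]]), nf)
  }
  tab <- as.data.frame(do.call(rbind, toks), stringsAsFactors = FALSE)
  names(tab) <- fields
  get <- function(...) {
    for (f in c(...)) if (f %in% fields) return(tab[[f]])
    NULL
  }
  blank_if_dot <- function(v) ifelse(v %in% c(".", "?"), "", v)
  xyz <- function(f) {
    v <- suppressWarnings(as.numeric(tab[[f]]))
    if (any(!is.finite(v))) stop_parse("%s: unparsable %s in atom_site", path, f)
    v
  }
  occv <- get("occupancy")
  occv <- if (is.null(occv)) rep(1, nrow(tab)) else {
    o <- suppressWarnings(as.numeric(occv)); o[!is.finite(o)] <- 1; o
  }
  atoms <- data.frame(
    chain = blank_if_dot(get("auth_asym_id", "label_asym_id")),
    resnum = as.integer(get("auth_seq_id", "label_seq_id")),
    icode = blank_if_dot(if (is.null(get("pdbx_PDB_ins_code"))) rep(".", nrow(tab)) else get("pdbx_PDB_ins_code")),
    resname = get("auth_comp_id", "label_comp_id"),
    atom_name = gsub('"', "", get("auth_atom_id", "label_atom_id")),
    element = blank_if_dot(if (is.null(get("type_symbol"))) rep(".", nrow(tab)) else get("type_symbol")),
    altloc = blank_if_dot(if (is.null(get("label_alt_id"))) rep(".", nrow(tab)) else get("label_alt_id")),
    occupancy = occv,
    x = xyz("Cartn_x"), y = xyz("Cartn_y"), z = xyz("Cartn_z"),
    stringsAsFactors = FALSE
  )
  model_col <- get("pdbx_PDB_model_num")
  model_ids <- if (is.null(model_col)) rep(1L, nrow(atoms)) else as.integer(model_col)
  split_models(atoms, model_ids)
}

cif_tokens <- function(line) {
  out <- character(0)
  i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch %in% c("'", '"')) {
      j <- i + 1L
      while (j <= n && substr(line, j, j) != ch) j <- j + 1L
      out <- c(out, substr(line, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1L
      out <- c(out, substr(line, i, j - 1L))
      i <- j
    }
  }
  out
}

#' Write structures as a (multi-model) PDB file
#'
#' Fixture/debug writer producing standard fixed-width ATOM records; a list
#' of structures becomes a MODEL/ENDMDL series. Round-trips through
#' [read_structure()].
#'
#' @param structures a `locohd_structure` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structures, path) {
  if (inherits(structures, "locohd_structure")) structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(structures) > 1L
  for (k in seq_along(structures)) {
    s <- structures[[k]]
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    nm <- s$atom_name
    nm4 <- ifelse(nchar(nm) >= 4L, substr(nm, 1L, 4L), sprintf(" %-3s", nm))
    writeLines(sprintf(
      "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(s)), nm4, s$altloc, s$resname, s$chain, s$resnum,
      ifelse(s$icode == "", " ", s$icode),
      s$x, s$y, s$z, s$occupancy, 0, s$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
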