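# Atomic-structure ingestion: parse PDB/mmCIF files into a light atom-table
# model, write models back out (optionally painting per-residue values into
# B-factors), extract Calpha traces and count atoms by chemical role.

#' Construct a structure model from an atom table
#'
#' A `structure_model` is a thin S3 container: an identifier plus a tibble of
#' atoms. It is the common currency of all structure operations in the
#' package. Most users obtain one from [read_structure()] or from the
#' synthetic generators ([make_helical_bundle()]); this constructor is exposed
#' for programmatic model building.
#'
#' @param atoms A data frame with one row per atom and columns `chain`,
#'   `resno` (author residue number), `ins` (insertion code, `""` if none),
#'   `resid` (3-letter residue name), `het` (logical HETATM flag), `elety`
#'   (atom name, e.g. `"CA"`), `element`, `x`, `y`, `z` (angstrom), `o`
#'   (occupancy) and `b` (B-factor).
#' @param id Character label for the model.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, id = "model") {
  atoms <- as_tibble(atoms)
  required <- c("chain", "resno", "ins", "resid", "het", "elety", "element",
                "x", "y", "z", "o", "b")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) {
    abort("atom coordinates must be finite")
  }
  structure(list(id = id, atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  n_res <- nrow(distinct(x$atoms, .data$chain, .data$resno, .data$ins))
  cat(sprintf("<structure_model> %s: %d atoms, %d residues, chains %s\n",
              x$id, nrow(x$atoms), n_res,
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Read an atomic structure from a PDB or mmCIF file
#'
#' Parses all ATOM/HETATM records of the first model. Alternate locations are
#' collapsed to a single conformer by keeping the highest-occupancy altloc
#' (ties broken by altloc letter), since single-conformer Calpha traces are
#' what rigid superposition assumes.
#'
#' @param path Path to a coordinate file.
#' @param format `"auto"` (default, by file extension), `"pdb"` or `"mmcif"`.
#' @param id Model label; defaults to the file name without extension.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      pdb = "pdb", ent = "pdb",
      cif = "mmcif", mmcif = "mmcif",
      abort(paste0("cannot infer format from extension '.", ext,
                   "'; pass format explicitly"))
    )
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE)
    else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse ", format, " file ",
                                     path, ": ", conditionMessage(e)))
  )
  at <- as_tibble(parsed$atom)
  if (nrow(at) == 0) abort(paste0("no atoms parsed from ", path))
  atoms <- tibble(
    chain   = ifelse(is.na(at$chain), "A", as.character(at$chain)),
    resno   = as.integer(at$resno),
    ins     = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid   = as.character(at$resid),
    het     = at$type == "HETATM",
    elety   = as.character(at$elety),
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     guess_element(at$elety), as.character(at$elesy)),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    alt = ifelse(is.na(at$alt), "", as.character(at$alt))
  )
  atoms <- resolve_altloc(atoms)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  structure_model(atoms, id = id)
}

# Keep one conformer per atom: highest occupancy, ties by altloc letter.
resolve_altloc <- function(atoms) {
  if (all(atoms$alt == "")) return(select(atoms, -"alt"))
  atoms |>
    group_by(.data$chain, .data$resno, .data$ins, .data$resid, .data$elety) |>
    arrange(dplyr::desc(.data$o), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$chain, .data$resno, .data$ins) |>
    select(-"alt")
}

guess_element <- function(elety) {
  e <- sub("^[0-9']+", "", trimws(elety))
  two <- toupper(substr(e, 1, 2))
  one <- toupper(substr(e, 1, 1))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "NA", "CL", "BR", "SE", "CU"),
         two, one)
}

#' Write a structure model to a PDB file
#'
#' Optionally paints a per-residue scalar (e.g. a Calpha conservation profile)
#' into the B-factor column of every atom of the listed residues — the
#' standard trick for colouring structures by an external quantity in
#' molecular viewers.
#'
#' @param model A [structure_model()].
#' @param path Output file path.
#' @param bfactor_map Optional data frame with columns `resno` and `value`
#'   (and optionally `chain`); all atoms of each listed residue receive the
#'   mapped B-factor. Values must fit the fixed-width PDB field (< 1000 in
#'   magnitude).
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, bfactor_map = NULL) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  b <- at$b
  if (!is.null(bfactor_map)) {
    bm <- as_tibble(bfactor_map)
    if (!all(c("resno", "value") %in% names(bm))) {
      abort("bfactor_map needs columns resno and value")
    }
    if (any(abs(bm$value) >= 1000) || any(bm$value <= -100)) {
      abort("bfactor_map value outside the PDB B-factor field width")
    }
    key <- if ("chain" %in% names(bm)) paste(at$chain, at$resno)
           else as.character(at$resno)
    map_key <- if ("chain" %in% names(bm)) paste(bm$chain, bm$resno)
               else as.character(bm$resno)
    idx <- match(key, map_key)
    b[!is.na(idx)] <- bm$value[idx[!is.na(idx)]]
  }
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = ifelse(at$het, "HETATM", "ATOM"),
    resno = at$resno, resid = at$resid,
    eleno = seq_len(nrow(at)), elety = at$elety,
    chain = at$chain, insert = ifelse(at$ins == "", NA, at$ins),
    o = at$o, b = round(b, 2), elesy = at$element
  )
  invisible(path)
}

#' Extract the Calpha trace of one chain
#'
#' Returns the ordered Calpha coordinates of the non-hetero residues of a
#' chain — the input of all superposition and conservation operations.
#' Residues lacking a Calpha atom are skipped with a warning.
#'
#' @param model A [structure_model()].
#' @param chain Chain identifier (default: first chain in the model).
#' @return A `ca_trace`: a tibble with columns `resno`, `ins`, `aa`
#'   (one-letter code), `x`, `y`, `z`, carrying the structure id and chain as
#'   attributes.
#' @export
extract_ca_trace <- function(model, chain = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(chain)) chain <- model$atoms$chain[1]
  at <- filter(model$atoms, .data$chain == !!chain)
  if (nrow(at) == 0) abort(paste0("chain '", chain, "' not found in ", model$id))
  res <- filter(at, !.data$het)
  ca <- filter(res, .data$elety == "CA")
  n_res <- nrow(distinct(res, .data$resno, .data$ins))
  if (nrow(ca) < n_res) {
    warn(sprintf("%s chain %s: %d residue(s) lack a CA atom and were skipped",
                 model$id, chain, n_res - nrow(ca)))
  }
  if (any(duplicated(paste(ca$resno, ca$ins)))) {
    abort(paste0("duplicate CA atoms per residue in ", model$id,
                 " chain ", chain))
  }
  out <- tibble(
    resno = ca$resno, ins = ca$ins,
    aa = aa_three_to_one(ca$resid),
    x = ca$x, y = ca$y, z = ca$z
  )
  new_ca_trace(out, id = model$id, chain = chain)
}

new_ca_trace <- function(tbl, id, chain) {
  attr(tbl, "structure_id") <- id
  attr(tbl, "chain") <- chain
  class(tbl) <- c("ca_trace", class(tbl))
  tbl
}

trace_id <- function(trace) attr(trace, "structure_id") %||% "trace"

trace_xyz <- function(trace) as.matrix(trace[, c("x", "y", "z")])

aa_three_to_one <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out) | out == ""] <- "X"
  out
}

#' Default residue-name to chemical-role table
#'
#' Maps residue names to the roles used by [count_atoms_by_role()]: the 20
#' standard amino acids (plus MSE/SEC/PYL) to `protein`, water names to
#' `water`, retinal variants to `retinal` and monoolein/oleic lipid dialects
#' to `lipid`. Editable: lipid naming differs between depositions (OLC vs
#' OLA), so pass a modified copy rather than changing code.
#'
#' @return A named list of character vectors, one per role.
#' @export
default_role_map <- function() {
  list(
    protein = c(bio3d::aa.table$aa3[seq_len(20)], "MSE", "SEC", "PYL"),
    water   = c("HOH", "WAT", "DOD", "H2O"),
    retinal = c("RET", "ATR", "LYR"),
    lipid   = c("OLC", "OLA", "OLB", "MO", "PLM", "MYR", "LFA", "PEE", "PGW")
  )
}

#' Count atoms by chemical role
#'
#' Partitions the atoms of a model into protein / water / retinal / lipid /
#' other using a residue-name role table; the categories partition the atom
#' set, so the row sums to the total atom count.
#'
#' @param model A [structure_model()].
#' @param role_map Named list of residue-name vectors, see
#'   [default_role_map()].
#' @return A one-row tibble with columns `protein`, `water`, `retinal`,
#'   `lipid`, `other` and `total`.
#' @export
count_atoms_by_role <- function(model, role_map = default_role_map()) {
  stopifnot(inherits(model, "structure_model"))
  resid <- model$atoms$resid
  role <- rep("other", length(resid))
  for (r in c("protein", "water", "retinal", "lipid")) {
    role[resid %in% role_map[[r]]] <- r
  }
  tibble(
    protein = sum(role == "protein"),
    water   = sum(role == "water"),
    retinal = sum(role == "retinal"),
    lipid   = sum(role == "lipid"),
    other   = sum(role == "other"),
    total   = length(role)
  )
}
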