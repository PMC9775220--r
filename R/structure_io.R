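# Structure and profile I/O.
#
# A conformer ensemble is stored bio3d-style: a single atom table shared by
# all models (the topology) plus an nmodels x 3*natoms coordinate matrix.
# Author residue numbering (chain, resno, insertion code) is the canonical
# addressing scheme throughout the package.

new_confens <- function(atoms, xyz, model_ids = seq_len(nrow(xyz))) {
  stopifnot(is.data.frame(atoms), is.matrix(xyz),
            ncol(xyz) == 3L * nrow(atoms), nrow(xyz) >= 1L)
  if (anyDuplicated(atom_keys(atoms)) &&
      anyDuplicated(paste(atom_keys(atoms), atoms$elety))) {
    stop("duplicate (chain, resno, icode, atom name) entries in topology",
         call. = FALSE)
  }
  obj <- list(
    atoms = atoms,
    xyz = xyz,
    model_ids = as.integer(model_ids),
    topology_hash = topology_hash(atoms)
  )
  class(obj) <- "confens"
  obj
}

atom_keys <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$icode, sep = "|")
}

topology_hash <- function(atoms) {
  sig <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$resid,
               atoms$elety, atoms$het, collapse = ";")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(sig, tf)
  unname(tools::md5sum(tf))
}

#' Number of models / atoms in an ensemble
#' @param ens a `confens` object
#' @return integer count
#' @export
n_models <- function(ens) nrow(ens$xyz)

#' @rdname n_models
#' @export
n_atoms <- function(ens) nrow(ens$atoms)

#' Coordinates of one model as an N x 3 matrix
#' @param ens a `confens` object
#' @param model model index (1-based position, not PDB MODEL serial)
#' @return numeric matrix with columns x, y, z (Angstrom)
#' @export
conf_coords <- function(ens, model = 1L) {
  stopifnot(model >= 1L, model <= n_models(ens))
  m <- matrix(ens$xyz[model, ], ncol = 3L, byrow = TRUE)
  colnames(m) <- c("x", "y", "z")
  m
}

#' @export
print.confens <- function(x, ...) {
  cat(sprintf("<confens> %d model(s), %d atoms, %d residues\n",
              n_models(x), n_atoms(x), length(unique(atom_keys(x$atoms)))))
  invisible(x)
}

.guess_element <- function(elety, resid, het) {
  e <- toupper(trimws(elety))
  e <- gsub("[0-9']", "", e)
  two <- substr(e, 1, 2)
  known2 <- c("CU", "FE", "ZN", "MG", "MN", "NA", "CL", "BR", "SE", "NI",
              "CO", "CA", "K")
  ifelse(het & two %in% known2 & toupper(trimws(resid)) == two,
         two, substr(e, 1, 1))
}

.parse_model_block <- function(lines, offsets) {
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  offsets <- offsets[keep]
  if (length(lines) == 0L) {
    stop("PDB model block contains no ATOM/HETATM records", call. = FALSE)
  }
  # Validate fixed-width coordinate fields before handing off to bio3d so
  # that a malformed record is reported with its line number.
  bad_len <- nchar(lines) < 54
  coords <- cbind(substr(lines, 31, 38), substr(lines, 39, 46),
                  substr(lines, 47, 54))
  suppressWarnings(cnum <- matrix(as.numeric(coords), ncol = 3L))
  bad <- bad_len | apply(!is.finite(cnum), 1L, any)
  if (any(bad)) {
    stop(sprintf("malformed ATOM/HETATM record at line %d",
                 offsets[which(bad)[1]]), call. = FALSE)
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(c(lines, "END"), tf)
  pdb <- suppressWarnings(bio3d::read.pdb(tf, rm.alt = FALSE,
                                          verbose = FALSE))
  a <- pdb$atom
  icode <- ifelse(is.na(a$insert), "", a$insert)
  elesy <- if (!is.null(a$elesy)) trimws(a$elesy) else rep("", nrow(a))
  het <- a$type == "HETATM"
  element <- ifelse(is.na(elesy) | elesy == "",
                    .guess_element(a$elety, a$resid, het),
                    toupper(elesy))
  atoms <- data.frame(
    elety = trimws(a$elety), resid = trimws(a$resid),
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno, icode = icode, element = element, het = het,
    occ = ifelse(is.na(a$o), 1, a$o), b = ifelse(is.na(a$b), 0, a$b),
    alt = ifelse(is.na(a$alt), "", a$alt),
    x = a$x, y = a$y, z = a$z,
    stringsAsFactors = FALSE
  )
  # Altloc policy: keep the highest-occupancy alternate location, ties
  # resolved by altloc letter order, so downstream geometry is single valued.
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$elety)
  ord <- order(key, -atoms$occ, atoms$alt)
  atoms <- atoms[ord, ]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$icode,
                                   atoms$elety)), ]
  atoms <- atoms[order(match(paste(atoms$chain, atoms$resno, atoms$icode,
                                   atoms$elety), unique(key))), ]
  rownames(atoms) <- NULL
  atoms$alt <- NULL
  atoms
}

#' Read a (multi-model) PDB file as a conformer ensemble
#'
#' MODEL/ENDMDL blocks become one conformer each; a file without MODEL
#' records yields a single conformer.  HETATM records are retained and
#' flagged in the atom table (`het` column).  All models must share an
#' identical topology (same chain/residue/atom sequence); alternate
#' locations are collapsed to the highest-occupancy conformer.
#'
#' @param path path to a PDB-format text file
#' @return a `confens` object
#' @export
read_pdb_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  starts <- which(rec == "MODEL ")
  if (length(starts) == 0L) {
    blocks <- list(seq_along(lines))
    ids <- 1L
  } else {
    ends <- which(rec == "ENDMDL")
    if (length(ends) < length(starts)) ends <- c(ends, length(lines) + 1L)
    blocks <- Map(function(s, e) seq(s + 1L, e - 1L), starts, ends)
    ids <- suppressWarnings(as.integer(substr(lines[starts], 7, 14)))
    ids[is.na(ids)] <- seq_along(ids)[is.na(ids)]
  }
  parsed <- lapply(seq_along(blocks), function(k) {
    idx <- blocks[[k]]
    .parse_model_block(lines[idx], idx)
  })
  ref <- parsed[[1]]
  ref_sig <- paste(ref$chain, ref$resno, ref$icode, ref$resid, ref$elety)
  for (k in seq_along(parsed)) {
    sig <- paste(parsed[[k]]$chain, parsed[[k]]$resno, parsed[[k]]$icode,
                 parsed[[k]]$resid, parsed[[k]]$elety)
    if (!identical(sig, ref_sig)) {
      stop(sprintf(paste0("inconsistent topology: model %d does not match ",
                          "model 1 (%d vs %d atoms)"),
                   k, length(sig), length(ref_sig)), call. = FALSE)
    }
  }
  xyz <- do.call(rbind, lapply(parsed, function(a) {
    as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  }))
  rownames(xyz) <- NULL
  atoms <- ref[, c("elety", "resid", "chain", "resno", "icode", "element",
                   "het", "occ", "b")]
  new_confens(atoms, xyz, ids)
}

#' Write a conformer ensemble as a (multi-model) PDB file
#'
#' @param ens a `confens` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pdb_models <- function(ens, path) {
  stopifnot(inherits(ens, "confens"))
  a <- ens$atoms
  name4 <- ifelse(nchar(a$elety) >= 4, substr(a$elety, 1, 4),
                  sprintf(" %-3s", a$elety))
  multi <- n_models(ens) > 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(n_models(ens))) {
    if (multi) writeLines(sprintf("MODEL     %4d", ens$model_ids[m]), con)
    xyz <- conf_coords(ens, m)
    writeLines(sprintf(
      "%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(a$het, "HETATM", "ATOM"), seq_len(nrow(a)), name4, "",
      a$resid, a$chain, a$resno, ifelse(a$icode == "", " ", a$icode),
      xyz[, 1], xyz[, 2], xyz[, 3], a$occ, a$b,
      formatC(a$element, width = 2)), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Restrict an ensemble to a chain / residue range / set of atom names
#'
#' An empty selection is an error, never an empty result, so that a typo in
#' a residue range fails loudly.
#'
#' @param ens a `confens` object
#' @param chain chain identifier, or `NULL` for all chains
#' @param residue_range integer vector `c(first, last)` in author numbering,
#'   or `NULL` for all residues
#' @param atom_names character vector of atom names (e.g. `"CA"`), or `NULL`
#' @return the restricted `confens`; the input is untouched
#' @export
select_subset <- function(ens, chain = NULL, residue_range = NULL,
                          atom_names = NULL) {
  stopifnot(inherits(ens, "confens"))
  a <- ens$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2L)
    keep <- keep & a$resno >= residue_range[1] & a$resno <= residue_range[2]
  }
  if (!is.null(atom_names)) keep <- keep & a$elety %in% atom_names
  if (!any(keep)) {
    stop(sprintf("empty selection (chain=%s, residues=%s, atoms=%s)",
                 if (is.null(chain)) "*" else paste(chain, collapse = ","),
                 if (is.null(residue_range)) "*" else
                   paste(residue_range, collapse = "-"),
                 if (is.null(atom_names)) "*" else
                   paste(atom_names, collapse = ",")), call. = FALSE)
  }
  cols <- as.vector(t(outer((which(keep) - 1L) * 3L, 1:3, "+")))
  sub <- a[keep, , drop = FALSE]
  rownames(sub) <- NULL
  new_confens(sub, ens$xyz[, cols, drop = FALSE], ens$model_ids)
}

# ---- SAXS profile I/O -------------------------------------------------------

new_saxs_profile <- function(s, intensity, sigma) {
  stopifnot(length(s) == length(intensity), length(s) == length(sigma))
  if (any(diff(s) <= 0)) stop("s grid must be strictly increasing",
                              call. = FALSE)
  if (any(sigma <= 0)) stop("all sigma must be positive", call. = FALSE)
  structure(data.frame(s = s, intensity = intensity, sigma = sigma),
            class = c("saxs_profile", "data.frame"))
}

new_saxs_curve <- function(s, intensity) {
  stopifnot(length(s) == length(intensity))
  structure(data.frame(s = s, intensity = intensity),
            class = c("saxs_curve", "data.frame"))
}

#' Read an experimental SAXS profile (3-column text)
#'
#' Expects whitespace-separated columns s, I(s), sigma(s); lines starting
#' with `#` are skipped.  Momentum transfer is converted to inverse Angstrom
#' internally (BM29-style deposits are frequently in inverse nm, which is
#' the classic silent unit mix-up).  Rows with non-positive sigma are
#' dropped with a message.
#'
#' @param path path to the profile
#' @param s_unit unit of the first column: `"invA"` (default) or `"invnm"`
#' @return a `saxs_profile` data frame (columns s, intensity, sigma)
#' @export
read_saxs_profile <- function(path, s_unit = c("invA", "invnm")) {
  s_unit <- match.arg(s_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, comment.char = "#",
                           colClasses = "numeric", fill = FALSE)
  if (ncol(tab) < 3L) {
    stop("SAXS profile must have >= 3 columns (s, I, sigma); got ",
         ncol(tab), call. = FALSE)
  }
  s <- tab[[1]]
  if (s_unit == "invnm") s <- s / 10
  i <- tab[[2]]
  sig <- tab[[3]]
  bad <- sig <= 0
  if (any(bad)) {
    message(sprintf("dropped %d point(s) with sigma <= 0", sum(bad)))
  }
  if (all(bad)) stop("profile empty after filtering sigma <= 0",
                     call. = FALSE)
  new_saxs_profile(s[!bad], i[!bad], sig[!bad])
}

#' Write a SAXS profile or theoretical curve as `.dat`-style text
#'
#' @param x a `saxs_profile` or `saxs_curve`
#' @param path output path
#' @param s_unit unit for the emitted s column
#' @return `path`, invisibly
#' @export
write_saxs_profile <- function(x, path, s_unit = c("invA", "invnm")) {
  s_unit <- match.arg(s_unit)
  s <- if (s_unit == "invnm") x$s * 10 else x$s
  hdr <- sprintf("# s (%s)  I(s)%s",
                 ifelse(s_unit == "invA", "1/A", "1/nm"),
                 if (!is.null(x$sigma)) "  sigma" else "")
  m <- if (!is.null(x$sigma)) cbind(s, x$intensity, x$sigma)
       else cbind(s, x$intensity)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(m, digits = 10, scientific = TRUE), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Coordinates of a single named atom
#'
#' Resolves an author-numbering atom address (chain, residue number,
#' insertion code, atom name) in one model of an ensemble.
#'
#' @param ens a `confens`
#' @param chain chain id
#' @param resno residue number
#' @param elety atom name (e.g. `"CU"`, `"CA"`)
#' @param icode insertion code, usually blank
#' @param model model index
#' @return numeric length-3 vector (Angstrom)
#' @export
atom_coords <- function(ens, chain, resno, elety, icode = "", model = 1L) {
  a <- ens$atoms
  hit <- which(a$chain == chain & a$resno == resno & a$icode == icode &
                 a$elety == elety)
  if (length(hit) != 1L) {
    stop(sprintf("atom address %s/%d%s/%s resolves to %d atoms",
                 chain, resno, icode, elety, length(hit)), call. = FALSE)
  }
  conf_coords(ens, model)[hit, ]
}
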