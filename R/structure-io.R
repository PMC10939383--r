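#' Read a protein backbone from a PDB file
#'
#' Parses a PDB file (or raw PDB text) and keeps only the backbone atoms
#' N, C-alpha, C and O. Side-chain atoms, hydrogens, waters and hetero
#' groups are discarded; selenomethionine (MSE) is accepted and mapped to
#' methionine; all other non-canonical residues are skipped with a
#' warning. Only the first model of a multi-model file and the first
#' alternate location (altloc ' ' or 'A') of each atom are used. Residues
#' missing any of N, C-alpha or C are skipped and counted.
#'
#' @param source Path to a PDB file, or a character vector/string of PDB
#'   text (detected by the presence of newlines or ATOM records).
#' @param chain_filter Optional character vector of chain identifiers to
#'   keep.
#' @param structure_id Identifier stored on the returned object; defaults
#'   to the file name (or `"structure"` for raw text).
#' @return A `backbone` object: a list with `structure_id`, `residues`
#'   (one row per residue with chain, author numbering, insertion code,
#'   one-letter amino acid and the N/CA/C/O coordinates in Angstrom;
#'   `cb_*` columns hold the virtual C-beta once placed), and `n_skipped`,
#'   the number of residues dropped for missing backbone atoms.
#' @seealso [write_pdb()], [sequence_of()], [place_virtual_cbeta()]
#' @export
read_backbone <- function(source, chain_filter = NULL, structure_id = NULL) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    if (is.null(structure_id)) {
      structure_id <- sub("\\.(pdb|ent)$", "", basename(source))
    }
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
    if (is.null(structure_id)) structure_id <- "structure"
  }

  is_atom <- grepl("^(ATOM|HETATM)", lines)
  if (!any(is_atom)) {
    stop("not a PDB file: no ATOM/HETATM records found")
  }
  bad <- which(is_atom & (nchar(lines) < 54 |
                 is.na(suppressWarnings(as.numeric(substr(lines, 31, 38))))))
  if (length(bad)) {
    stop("malformed PDB ATOM record at line ", bad[1], ": ",
         substr(lines[bad[1]], 1, 30))
  }

  # first model only
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1) {
    endmdl <- grep("^ENDMDL", lines)
    stop_at <- if (length(endmdl)) endmdl[1] else length(lines)
    lines <- lines[seq_len(stop_at)]
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom

  keep <- (at$type == "ATOM" | (at$type == "HETATM" & at$resid == "MSE")) &
    (is.na(at$alt) | at$alt %in% c("", "A")) &
    at$elety %in% c("N", "CA", "C", "O")
  at <- at[keep, , drop = FALSE]
  at$chain[is.na(at$chain)] <- " "
  at$insert[is.na(at$insert)] <- ""
  if (!is.null(chain_filter)) {
    at <- at[at$chain %in% chain_filter, , drop = FALSE]
  }

  aa <- AA_THREE_TO_ONE[at$resid]
  if (anyNA(aa)) {
    dropped <- unique(at$resid[is.na(aa)])
    warning("skipping non-canonical residue type(s): ",
            paste(dropped, collapse = ", "))
    at <- at[!is.na(aa), , drop = FALSE]
    aa <- aa[!is.na(aa)]
  }

  if (nrow(at) == 0) stop("no usable backbone residues in input")

  # duplicate atoms within a residue (e.g. repeated altloc 'A'): keep first
  rid <- paste(at$chain, at$resno, at$insert, sep = "|")
  dup <- duplicated(paste(rid, at$elety))
  at <- at[!dup, , drop = FALSE]
  aa <- aa[!dup]
  rid <- rid[!dup]

  chains <- unique(at$chain)
  rows <- list()
  n_skipped <- 0L
  for (ch in chains) {
    sub <- at[at$chain == ch, , drop = FALSE]
    sub_rid <- rid[at$chain == ch]
    for (r in unique(sub_rid)) {
      res <- sub[sub_rid == r, , drop = FALSE]
      get <- function(name) {
        i <- match(name, res$elety)
        if (is.na(i)) return(NULL)
        c(res$x[i], res$y[i], res$z[i])
      }
      n <- get("N"); ca <- get("CA"); cc <- get("C")
      if (is.null(n) || is.null(ca) || is.null(cc)) {
        n_skipped <- n_skipped + 1L
        next
      }
      o <- get("O")
      if (is.null(o)) o <- c(NA_real_, NA_real_, NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, resno = res$resno[1], ins = res$insert[1],
        aa = AA_THREE_TO_ONE[res$resid[1]],
        n_x = n[1], n_y = n[2], n_z = n[3],
        ca_x = ca[1], ca_y = ca[2], ca_z = ca[3],
        c_x = cc[1], c_y = cc[2], c_z = cc[3],
        o_x = o[1], o_y = o[2], o_z = o[3],
        cb_x = NA_real_, cb_y = NA_real_, cb_z = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no usable backbone residues in input")
  res_df <- do.call(rbind, rows)
  # within-chain order by author numbering + insertion code
  ord <- order(match(res_df$chain, chains), res_df$resno, res_df$ins)
  res_df <- res_df[ord, , drop = FALSE]
  rownames(res_df) <- NULL

  new_backbone(structure_id, res_df, n_skipped = n_skipped)
}

new_backbone <- function(structure_id, residues, n_skipped = 0L,
                         resolution = NA_real_) {
  structure(
    list(structure_id = structure_id, residues = residues,
         n_skipped = n_skipped, resolution = resolution),
    class = "backbone")
}

#' @export
print.backbone <- function(x, ...) {
  ch <- table(x$residues$chain)
  cat("<backbone> ", x$structure_id, ": ",
      nrow(x$residues), " residues in ", length(ch), " chain(s) [",
      paste(names(ch), ch, sep = ":", collapse = ", "), "]",
      if (x$n_skipped > 0) paste0("; ", x$n_skipped, " skipped"), "\n",
      sep = "")
  invisible(x)
}

#' Number of residues in a backbone
#' @param structure A `backbone` object.
#' @return Integer residue count.
#' @export
n_residues <- function(structure) nrow(structure$residues)

#' Coordinate matrix of one backbone atom type
#'
#' @param structure A `backbone` object.
#' @param atom One of `"n"`, `"ca"`, `"c"`, `"o"`, `"cb"`.
#' @return n x 3 matrix of coordinates in Angstrom (rows follow residue
#'   order; `NA` rows where the atom is absent).
#' @export
atom_coords <- function(structure, atom = "ca") {
  r <- structure$residues
  as.matrix(r[, paste0(atom, c("_x", "_y", "_z"))])
}

#' One-letter sequence of each chain
#'
#' @param structure A `backbone` object.
#' @param collapse If `TRUE` (default) return one string per chain; if
#'   `FALSE` return the per-residue letter vector.
#' @return Named character vector, one element per chain (or one letter
#'   per residue when `collapse = FALSE`).
#' @export
sequence_of <- function(structure, collapse = TRUE) {
  r <- structure$residues
  if (!collapse) return(r$aa)
  chains <- unique(r$chain)
  out <- vapply(chains, function(ch) {
    paste(r$aa[r$chain == ch], collapse = "")
  }, character(1))
  names(out) <- chains
  out
}

#' Write a backbone to a PDB file
#'
#' Emits fixed-width ATOM records for N, CA, C, O (and CB when the
#' virtual C-beta has been placed), a TER record per chain and a final
#' END record, via the standard PDB writer.
#'
#' @param structure A `backbone` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  r <- structure$residues
  if (nrow(r) == 0) stop("cannot write an empty structure")
  atoms <- c("n", "ca", "c", "o")
  has_cb <- !anyNA(r$cb_x)
  if (has_cb) atoms <- c(atoms, "cb")
  elety_of <- c(n = "N", ca = "CA", c = "C", o = "O", cb = "CB")
  elesy_of <- c(n = "N", ca = "C", c = "C", o = "O", cb = "C")

  per_res <- lapply(seq_len(nrow(r)), function(i) {
    use <- atoms
    if (!has_cb) use <- atoms
    use <- use[!vapply(use, function(a) is.na(r[[paste0(a, "_x")]][i]),
                       logical(1))]
    data.frame(res_i = i, atom = use, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_res)
  xyz <- t(vapply(seq_len(nrow(tab)), function(k) {
    i <- tab$res_i[k]; a <- tab$atom[k]
    c(r[[paste0(a, "_x")]][i], r[[paste0(a, "_y")]][i],
      r[[paste0(a, "_z")]][i])
  }, numeric(3)))

  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.vector(t(xyz)),
    type = rep("ATOM", nrow(tab)),
    eleno = seq_len(nrow(tab)),
    elety = unname(elety_of[tab$atom]),
    resid = unname(AA_ONE_TO_THREE[r$aa[tab$res_i]]),
    chain = r$chain[tab$res_i],
    resno = r$resno[tab$res_i],
    insert = ifelse(r$ins[tab$res_i] == "", NA, r$ins[tab$res_i]),
    elesy = unname(elesy_of[tab$atom]),
    chainter = TRUE, end = TRUE)
  invisible(path)
}
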