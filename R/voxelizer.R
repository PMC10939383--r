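#' Voxelisation configuration
#'
#' Parameters controlling how a residue's backbone environment is
#' rendered into a density tensor. The cubic frame has edge
#' `frame_edge_length` (Angstrom, default 12) discretised into
#' `voxels_per_side` voxels per edge (odd, default 21, so the central
#' C-alpha falls in a centre voxel). `atom_encoding` selects the atom
#' channels: `"CNO"` collapses all carbons into one channel, `"CNOCB"`
#' gives the virtual C-beta its own channel, and the default `"CNOCBCA"`
#' additionally separates the C-alpha. Atoms are rendered either as
#' truncated Gaussians (`density_mode = "gaussian"`, sigma = vdW
#' radius / 2, cut at 2 sigma, accumulated additively) or as single
#' nearest-voxel occupancies. An optional property channel encodes
#' per-residue polarity or charge (-1/0/+1) at the C-alpha voxel.
#'
#' @param frame_edge_length Cube edge length in Angstrom (> 0).
#' @param voxels_per_side Odd number of voxels per edge.
#' @param atom_encoding One of `"CNO"`, `"CNOCB"`, `"CNOCBCA"`.
#' @param density_mode One of `"gaussian"`, `"occupancy"`.
#' @param property_channel One of `"none"`, `"polarity"`, `"charge"`.
#' @param vdw_radii Named element -> Angstrom map for C, N, O.
#' @return A `voxel_config` object.
#' @export
voxel_config <- function(frame_edge_length = 12,
                         voxels_per_side = 21,
                         atom_encoding = c("CNOCBCA", "CNOCB", "CNO"),
                         density_mode = c("gaussian", "occupancy"),
                         property_channel = c("none", "polarity", "charge"),
                         vdw_radii = VDW_RADII) {
  atom_encoding <- match.arg(atom_encoding)
  density_mode <- match.arg(density_mode)
  property_channel <- match.arg(property_channel)
  if (!is.numeric(frame_edge_length) || frame_edge_length <= 0) {
    stop("frame_edge_length must be positive")
  }
  voxels_per_side <- as.integer(voxels_per_side)
  if (voxels_per_side < 1 || voxels_per_side %% 2L == 0L) {
    stop("voxels_per_side must be a positive odd integer")
  }
  stopifnot(all(c("C", "N", "O") %in% names(vdw_radii)))
  structure(
    list(frame_edge_length = frame_edge_length,
         voxels_per_side = voxels_per_side,
         atom_encoding = atom_encoding,
         density_mode = density_mode,
         property_channel = property_channel,
         vdw_radii = vdw_radii),
    class = "voxel_config")
}

#' Channel names of a configuration
#' @param config A `voxel_config`.
#' @return Character vector of channel names (property channel last).
#' @export
config_channels <- function(config) {
  ch <- switch(config$atom_encoding,
               CNO = c("C", "N", "O"),
               CNOCB = c("C", "N", "O", "CB"),
               CNOCBCA = c("C", "N", "O", "CB", "CA"))
  if (config$property_channel != "none") ch <- c(ch, "property")
  ch
}

# atom kind -> (channel name, element) under an encoding
encoding_map <- function(encoding) {
  switch(encoding,
    CNO = data.frame(atom = c("n", "ca", "c", "o", "cb"),
                     channel = c("N", "C", "C", "O", "C"),
                     element = c("N", "C", "C", "O", "C")),
    CNOCB = data.frame(atom = c("n", "ca", "c", "o", "cb"),
                       channel = c("N", "C", "C", "O", "CB"),
                       element = c("N", "C", "C", "O", "C")),
    CNOCBCA = data.frame(atom = c("n", "ca", "c", "o", "cb"),
                         channel = c("N", "CA", "C", "O", "CB"),
                         element = c("N", "C", "C", "O", "C")))
}

#' Polarity class of an amino acid
#'
#' Binarises residues by the Zimmerman polarity scale with the threshold
#' at 20: values below 20 are non-polar (-1), all others polar (+1).
#' Under this rule the polar class is exactly \{R, K, H, D, E\}.
#'
#' @param amino_acid One-letter code(s).
#' @return Integer vector of -1/+1.
#' @export
assign_polarity <- function(amino_acid) {
  aa_index(amino_acid)  # validates the codes
  unname(ifelse(ZIMMERMAN_POLARITY[amino_acid] < 20, -1L, 1L))
}

#' Formal charge class of an amino acid
#'
#' D and E map to -1; K, R and H to +1; all other residues to 0.
#'
#' @param amino_acid One-letter code(s).
#' @return Integer vector of -1/0/+1.
#' @export
assign_charge <- function(amino_acid) {
  aa_index(amino_acid)  # validates the codes
  unname(as.integer(AA_FORMAL_CHARGE[amino_acid]))
}

# world-frame atom table of a structure: coords + atom kind + residue row
structure_atom_table <- function(structure, encoding) {
  emap <- encoding_map(encoding)
  r <- structure$residues
  n <- nrow(r)
  pieces <- lapply(seq_len(nrow(emap)), function(k) {
    a <- emap$atom[k]
    m <- as.matrix(r[, paste0(a, c("_x", "_y", "_z"))])
    ok <- !is.na(m[, 1])
    if (!any(ok)) return(NULL)
    data.frame(x = m[ok, 1], y = m[ok, 2], z = m[ok, 3],
               channel = emap$channel[k], element = emap$element[k],
               res_row = which(ok))
  })
  do.call(rbind, pieces)
}

# render one atom's truncated gaussian into a V^3 slab (in place helper)
render_gaussian <- function(slab, p, sigma, centers, V) {
  cut <- 2 * sigma
  rng <- lapply(1:3, function(d) which(abs(centers - p[d]) <= cut))
  if (any(lengths(rng) == 0)) {
    return(slab)
  }
  dx2 <- (centers[rng[[1]]] - p[1])^2
  dy2 <- (centers[rng[[2]]] - p[2])^2
  dz2 <- (centers[rng[[3]]] - p[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  g <- exp(-d2 / (2 * sigma^2))
  g[d2 > cut^2] <- 0
  sub <- slab[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  slab[rng[[1]], rng[[2]], rng[[3]]] <- sub + g
  slab
}

nearest_voxel <- function(p, delta, V) {
  i <- round(p / delta + (V - 1) / 2) + 1
  pmin(pmax(as.integer(i), 1L), V)
}

#' Voxelise one residue's environment into a frame
#'
#' Canonically orients the structure on the target residue (C-alpha at
#' the cube centre, N-CA-C plane on the XY plane), collects every
#' backbone atom (plus virtual C-beta) lying inside the cube, and
#' renders each into its element channel. The target residue
#' contributes only its backbone and virtual C-beta, which are identical
#' for all amino-acid classes, so the frame carries no label leakage.
#'
#' @param structure A `backbone` object.
#' @param chain Chain identifier of the target residue.
#' @param residue_index 1-based position of the target residue within
#'   its chain.
#' @param config A `voxel_config`.
#' @param constraints Optional numeric vector, one value per residue of
#'   the whole structure, overriding the sequence-derived property value
#'   at non-`NA` positions (only with a property channel).
#' @return A `frame` object: list with `tensor` (V x V x V x C array),
#'   `label` (one-letter amino acid), `label_index` (1..20) and `meta`.
#' @export
voxelise_frame <- function(structure, chain, residue_index, config,
                           constraints = NULL) {
  if (anyNA(structure$residues$cb_x)) {
    structure <- ensure_virtual_cbeta(structure)
  }
  r <- structure$residues
  in_chain <- which(r$chain == chain)
  if (residue_index < 1 || residue_index > length(in_chain)) {
    stop("residue_index out of range for chain ", chain)
  }
  target <- in_chain[residue_index]

  tf <- residue_canonical_transform(
    c(r$n_x[target], r$n_y[target], r$n_z[target]),
    c(r$ca_x[target], r$ca_y[target], r$ca_z[target]),
    c(r$c_x[target], r$c_y[target], r$c_z[target]))

  V <- config$voxels_per_side
  edge <- config$frame_edge_length
  delta <- edge / V
  centers <- (seq_len(V) - 1 - (V - 1) / 2) * delta
  channels <- config_channels(config)
  tensor <- array(0, dim = c(V, V, V, length(channels)),
                  dimnames = list(NULL, NULL, NULL, channels))

  at <- structure_atom_table(structure, config$atom_encoding)
  pc <- transform_apply(tf, as.matrix(at[, c("x", "y", "z")]))
  inside <- abs(pc[, 1]) <= edge / 2 & abs(pc[, 2]) <= edge / 2 &
    abs(pc[, 3]) <= edge / 2
  at <- at[inside, , drop = FALSE]
  pc <- pc[inside, , drop = FALSE]

  for (k in seq_len(nrow(at))) {
    ci <- match(at$channel[k], channels)
    if (config$density_mode == "gaussian") {
      sigma <- config$vdw_radii[[at$element[k]]] / 2
      tensor[, , , ci] <- render_gaussian(tensor[, , , ci], pc[k, ],
                                          sigma, centers, V)
    } else {
      iv <- nearest_voxel(pc[k, ], delta, V)
      tensor[iv[1], iv[2], iv[3], ci] <- 1
    }
  }

  property_value <- NULL
  if (config$property_channel != "none") {
    if (!is.null(constraints) && length(constraints) != nrow(r)) {
      stop("constraint vector length (", length(constraints),
           ") does not match residue count (", nrow(r), ")")
    }
    assign_fun <- if (config$property_channel == "polarity") {
      assign_polarity
    } else {
      assign_charge
    }
    values <- assign_fun(r$aa)
    if (!is.null(constraints)) {
      ov <- !is.na(constraints)
      values[ov] <- constraints[ov]
    }
    pci <- length(channels)
    cas <- transform_apply(tf, as.matrix(r[, c("ca_x", "ca_y", "ca_z")]))
    ca_in <- abs(cas[, 1]) <= edge / 2 & abs(cas[, 2]) <= edge / 2 &
      abs(cas[, 3]) <= edge / 2
    for (i in which(ca_in)) {
      iv <- nearest_voxel(cas[i, ], delta, V)
      tensor[iv[1], iv[2], iv[3], pci] <- values[i]
    }
    property_value <- values[target]
  }

  structure(
    list(tensor = tensor,
         label = r$aa[target],
         label_index = match(r$aa[target], AA_ALPHABET),
         property_value = property_value,
         meta = list(structure_id = structure$structure_id,
                     chain = chain, residue_index = residue_index,
                     resno = r$resno[target])),
    class = "frame")
}

#' Voxelise every residue of a structure
#'
#' Produces one frame per residue with complete backbone geometry, in
#' chain/sequence order. Residues whose local frame is degenerate
#' (collinear N-CA-C) are skipped and reported.
#'
#' @inheritParams voxelise_frame
#' @return List with `frames` (list of `frame` objects) and `skipped`
#'   (data.frame of skipped positions, possibly empty).
#' @export
voxelise_structure <- function(structure, config, constraints = NULL) {
  structure <- ensure_virtual_cbeta(structure)
  r <- structure$residues
  frames <- list()
  skipped <- list()
  for (ch in unique(r$chain)) {
    idx <- which(r$chain == ch)
    for (i in seq_along(idx)) {
      f <- tryCatch(
        voxelise_frame(structure, ch, i, config, constraints),
        error = function(e) e)
      if (inherits(f, "error")) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          chain = ch, residue_index = i, reason = conditionMessage(f))
      } else {
        frames[[length(frames) + 1L]] <- f
      }
    }
  }
  skipped <- if (length(skipped)) {
    do.call(rbind, skipped)
  } else {
    data.frame(chain = character(), residue_index = integer(),
               reason = character())
  }
  list(frames = frames, skipped = skipped)
}
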