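#' Build a frame dataset from structures
#'
#' Voxelises every residue of every input structure and stacks the
#' resulting tensors into a single N x V x V x V x C array with integer
#' labels (1..20, alphabetical one-letter order) and per-frame metadata.
#' Record order is deterministic: input structure order, then
#' chain/sequence order.
#'
#' @param structures List of `backbone` objects (a single structure is
#'   accepted).
#' @param config A `voxel_config`.
#' @param path Optional path; when given the dataset is also written
#'   with [write_dataset()].
#' @return A `frame_dataset`: list with `tensors`, `labels`, `meta`
#'   (data.frame with structure_id, chain, residue_index, amino_acid),
#'   `config` and `splits` (empty until [split_dataset()] is called).
#' @export
build_dataset <- function(structures, config, path = NULL) {
  if (inherits(structures, "backbone")) structures <- list(structures)
  all_frames <- list()
  skipped <- 0L
  for (s in structures) {
    vx <- voxelise_structure(s, config)
    all_frames <- c(all_frames, vx$frames)
    skipped <- skipped + nrow(vx$skipped)
  }
  if (length(all_frames) == 0) stop("no voxelisable residues in input")
  d <- dim(all_frames[[1]]$tensor)
  tensors <- array(0, dim = c(length(all_frames), d))
  for (i in seq_along(all_frames)) {
    if (!all(dim(all_frames[[i]]$tensor) == d)) {
      stop("internal error: inconsistent frame tensor shapes")
    }
    tensors[i, , , , ] <- all_frames[[i]]$tensor
  }
  meta <- do.call(rbind, lapply(all_frames, function(f) {
    data.frame(structure_id = f$meta$structure_id, chain = f$meta$chain,
               residue_index = f$meta$residue_index,
               amino_acid = f$label, stringsAsFactors = FALSE)
  }))
  ds <- structure(
    list(tensors = tensors,
         labels = vapply(all_frames, function(f) f$label_index, integer(1)),
         meta = meta, config = config,
         splits = list(), n_skipped = skipped),
    class = "frame_dataset")
  if (!is.null(path)) write_dataset(ds, path)
  ds
}

#' @export
print.frame_dataset <- function(x, ...) {
  d <- dim(x$tensors)
  cat("<frame_dataset> ", d[1], " frames of ",
      paste(d[-1], collapse = "x"), " (",
      length(unique(x$meta$structure_id)), " structure(s))\n", sep = "")
  if (length(x$splits)) {
    cat("  splits:",
        paste(names(x$splits), lengths(x$splits), sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Persist / reload a frame dataset
#'
#' The on-disk record is a faithful serialisation of the in-memory
#' object (tensor stack, labels, metadata, configuration and splits);
#' reloading reproduces the tensors bit-exactly.
#'
#' @param dataset A `frame_dataset`.
#' @param path File path (conventionally `.rds`).
#' @return `write_dataset` returns `path` invisibly; `read_dataset`
#'   returns the `frame_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "frame_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  ds <- readRDS(path)
  if (!inherits(ds, "frame_dataset")) stop("not a frame_dataset file: ", path)
  ds
}

split_indices <- function(dataset, split) {
  if (is.null(split)) return(seq_along(dataset$labels))
  if (!split %in% names(dataset$splits)) stop("unknown split: ", split)
  dataset$splits[[split]]
}

#' Per-class frame counts
#'
#' @param dataset A `frame_dataset`.
#' @param split Optional split name (`"train"`, `"validation"`,
#'   `"test"`); `NULL` counts the whole dataset.
#' @return Named integer vector of length 20 (alphabet order), summing
#'   to the split size.
#' @export
class_counts <- function(dataset, split = NULL) {
  idx <- split_indices(dataset, split)
  counts <- tabulate(dataset$labels[idx], nbins = 20L)
  names(counts) <- AA_ALPHABET
  counts
}

# deterministic per-(seed, epoch) stream key; kept below 2^31
derive_seed <- function(seed, epoch) {
  as.integer((as.double(seed) * 48271 + as.double(epoch) * 16807 + 1) %%
               2147483647)
}

#' Balanced per-epoch training indices
#'
#' Implements undersampling with per-epoch resampling: the number of
#' frames for each amino-acid class is capped at the count of the least
#' abundant class present in the split. Classes above the cap contribute
#' a fresh uniform subset (drawn without replacement from *all* of that
#' class's frames) each epoch, so that over many epochs the network sees
#' more unique frames than a single capped draw would allow, while every
#' epoch stays class-balanced. Classes at or below the cap are included
#' in full. The epoch plan depends only on `(seed, epoch)`.
#'
#' @param dataset A `frame_dataset` with splits assigned.
#' @param split Split name (default `"train"`).
#' @param epoch Epoch number (integer, used to key the random stream).
#' @param seed Integer seed.
#' @return An `epoch_plan`: list with `epoch`, `indices` (shuffled frame
#'   indices into the dataset) and `seed`.
#' @export
balanced_epoch_indices <- function(dataset, split = "train", epoch = 1L,
                                   seed = 1L) {
  idx <- split_indices(dataset, split)
  if (length(idx) == 0) stop("split '", split, "' is empty")
  labels <- dataset$labels[idx]
  counts <- tabulate(labels, nbins = 20L)
  present <- which(counts > 0)
  cap <- min(counts[present])
  chosen <- withr::with_seed(derive_seed(seed, epoch), {
    sel <- unlist(lapply(present, function(cl) {
      pool <- idx[labels == cl]
      if (length(pool) > cap) sample(pool, cap) else pool
    }), use.names = FALSE)
    sample(sel)
  })
  structure(list(epoch = as.integer(epoch), indices = chosen,
                 seed = as.integer(seed)),
            class = "epoch_plan")
}

#' Assign train/validation/test splits at structure level
#'
#' Whole structures, not individual frames, are randomly assigned to
#' splits, so overlapping frames from one protein never straddle a
#' split boundary.
#'
#' @param dataset A `frame_dataset`.
#' @param fractions Named positive fractions summing to at most 1, e.g.
#'   `c(train = 0.7, validation = 0.15, test = 0.15)`.
#' @param seed Integer seed (assignment is deterministic under it).
#' @return The dataset with `splits` set (named lists of frame indices).
#' @export
split_dataset <- function(dataset,
                          fractions = c(train = 0.7, validation = 0.15,
                                        test = 0.15),
                          seed = 1L) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    stop("fractions must be named")
  }
  if (any(fractions <= 0) || sum(fractions) > 1 + 1e-9) {
    stop("fractions must be positive and sum to at most 1")
  }
  ids <- unique(dataset$meta$structure_id)
  assignment <- withr::with_seed(as.integer(seed), {
    shuffled <- sample(ids)
    n <- length(shuffled)
    sizes <- floor(fractions * n)
    # distribute the remainder (if fractions sum to 1) to the largest splits
    rem <- if (abs(sum(fractions) - 1) < 1e-9) n - sum(sizes) else 0
    if (rem > 0) {
      extra <- order(fractions, decreasing = TRUE)[seq_len(rem)]
      sizes[extra] <- sizes[extra] + 1
    }
    out <- list(); start <- 1
    for (k in seq_along(fractions)) {
      take <- sizes[k]
      out[[names(fractions)[k]]] <-
        if (take > 0) shuffled[start:(start + take - 1)] else character()
      start <- start + take
    }
    out
  })
  dataset$splits <- lapply(assignment, function(sids) {
    which(dataset$meta$structure_id %in% sids)
  })
  dataset
}

#' Export class counts to CSV
#'
#' @param dataset A `frame_dataset`.
#' @param path Output CSV path.
#' @param split Optional split name.
#' @return `path`, invisibly.
#' @export
export_class_counts <- function(dataset, path, split = NULL) {
  counts <- class_counts(dataset, split)
  utils::write.csv(
    data.frame(amino_acid = names(counts), count = as.integer(counts)),
    path, row.names = FALSE)
  invisible(path)
}
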