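split_seq <- function(seq) {
  if (length(seq) == 1 && nchar(seq) != 1) strsplit(seq, "")[[1]] else seq
}

#' Confusion matrix and recall metrics for a sequence pair
#'
#' Compares a predicted sequence against its reference position by
#' position. Positions with `'X'` in either sequence are dropped (and
#' counted). Macro-recall is the mean of per-class recalls over the
#' classes present in the reference -- with a constant single-class
#' predictor against a reference containing all 20 amino acids it equals
#' 1/20 = 5%, the metric's per-class cap. A `strict` mode divides by all
#' 20 classes regardless of support.
#'
#' @param true_seq,pred_seq Equal-length sequence strings (or letter
#'   vectors).
#' @param strict Divide the recall sum by 20 instead of by the number of
#'   classes present in the reference.
#' @return List with `confusion` (20 x 20 true x predicted counts),
#'   `per_class` (precision/recall/F1/support per amino acid),
#'   `macro_recall`, `accuracy` and `n_dropped`.
#' @export
confusion_and_recall <- function(true_seq, pred_seq, strict = FALSE) {
  t_l <- split_seq(true_seq); p_l <- split_seq(pred_seq)
  if (length(t_l) != length(p_l)) {
    stop("sequences have different lengths (", length(t_l), " vs ",
         length(p_l), ")")
  }
  drop <- t_l == "X" | p_l == "X"
  t_l <- t_l[!drop]; p_l <- p_l[!drop]
  tf <- factor(t_l, levels = AA_ALPHABET)
  pf <- factor(p_l, levels = AA_ALPHABET)
  confusion <- table(true = tf, predicted = pf)
  support <- rowSums(confusion)
  predicted_n <- colSums(confusion)
  tp <- diag(confusion)
  recall <- ifelse(support > 0, tp / support, NA_real_)
  precision <- ifelse(predicted_n > 0, tp / predicted_n, NA_real_)
  f1 <- ifelse(!is.na(recall) & !is.na(precision) & (recall + precision) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  present <- support > 0
  macro_recall <- if (strict) {
    sum(recall[present]) / 20
  } else {
    mean(recall[present])
  }
  list(confusion = confusion,
       per_class = data.frame(amino_acid = AA_ALPHABET,
                              precision = as.numeric(precision),
                              recall = as.numeric(recall),
                              f1 = as.numeric(f1),
                              support = as.numeric(support)),
       macro_recall = macro_recall,
       accuracy = sum(tp) / length(t_l),
       n_dropped = sum(drop))
}

#' Per-amino-acid prediction bias
#'
#' Signed percentage difference between predicted and reference
#' amino-acid frequencies over a set of paired sequences:
#' `bias(aa) = 100 * (count in predictions - count in references) /
#' total positions`. Positive values mark over-predicted residues; the
#' biases always sum to zero.
#'
#' @param true_seqs,pred_seqs Character vectors of paired equal-length
#'   sequences.
#' @return Named numeric vector of length 20 (percent).
#' @export
prediction_bias <- function(true_seqs, pred_seqs) {
  if (length(true_seqs) != length(pred_seqs)) {
    stop("sequence lists have different lengths")
  }
  t_l <- unlist(strsplit(true_seqs, ""))
  p_l <- unlist(strsplit(pred_seqs, ""))
  if (length(t_l) != length(p_l)) {
    stop("paired sequences have different total lengths")
  }
  keep <- t_l != "X" & p_l != "X"
  t_l <- t_l[keep]; p_l <- p_l[keep]
  tc <- table(factor(t_l, levels = AA_ALPHABET))
  pc <- table(factor(p_l, levels = AA_ALPHABET))
  bias <- 100 * (as.numeric(pc) - as.numeric(tc)) / length(t_l)
  names(bias) <- AA_ALPHABET
  bias
}

#' Net charge and isoelectric point of a sequence
#'
#' Henderson-Hasselbalch net charge summed over the termini and the
#' ionisable residues (D, E, C, Y, H, K, R) using the EMBOSS pKa set;
#' the isoelectric point is found by bisection on pH in [0, 14] to
#' |charge| < 1e-4.
#'
#' @param seq Sequence string (canonical letters; `'X'` ignored).
#' @param pH pH at which to evaluate the net charge (default 7).
#' @return `sequence_charge`: net charge (elementary charges);
#'   `isoelectric_point`: pI (pH units).
#' @export
sequence_charge <- function(seq, pH = 7.0) {
  letters <- split_seq(seq)
  letters <- letters[letters != "X"]
  if (length(letters) == 0) stop("empty sequence")
  pos_counts <- c(Nterm = 1, K = sum(letters == "K"),
                  R = sum(letters == "R"), H = sum(letters == "H"))
  neg_counts <- c(Cterm = 1, D = sum(letters == "D"),
                  E = sum(letters == "E"), C = sum(letters == "C"),
                  Y = sum(letters == "Y"))
  pos <- sum(pos_counts / (1 + 10^(pH - EMBOSS_PKA$positive[names(pos_counts)])))
  neg <- sum(neg_counts / (1 + 10^(EMBOSS_PKA$negative[names(neg_counts)] - pH)))
  pos - neg
}

#' @rdname sequence_charge
#' @export
isoelectric_point <- function(seq) {
  lo <- 0; hi <- 14
  # charge is strictly decreasing in pH; bisect to machine-level width
  while (hi - lo > 1e-8) {
    mid <- (lo + hi) / 2
    if (sequence_charge(seq, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Mean absolute error
#'
#' @param true_values,pred_values Equal-length numeric vectors.
#' @return Mean of absolute differences.
#' @export
mae <- function(true_values, pred_values) {
  if (length(true_values) == 0) stop("empty input")
  if (length(true_values) != length(pred_values)) {
    stop("length mismatch")
  }
  mean(abs(true_values - pred_values))
}

#' Shannon entropy of a probability matrix
#'
#' Per-row Shannon entropy in bits (`0 * log 0 = 0`) and its mean over
#' rows. For 20 classes the maximum is `log2(20)` = 4.32 bits, attained
#' by the uniform distribution; one-hot rows score 0.
#'
#' @param matrix n x 20 probability matrix.
#' @return List with `per_row` (bits) and `mean` (bits).
#' @export
mean_entropy <- function(matrix) {
  per_row <- apply(matrix, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  list(per_row = as.numeric(per_row), mean = mean(per_row))
}

#' Length-normalised RMSD
#'
#' `RMSD100 = RMSD / (1 + ln(sqrt(n / 100)))`, which makes RMSD values
#' comparable across proteins of different lengths (equal to the raw
#' RMSD at n = 100).
#'
#' @param rmsd RMSD in Angstrom (>= 0).
#' @param n Residue count (>= 1).
#' @return RMSD100 in Angstrom.
#' @export
rmsd100 <- function(rmsd, n) {
  if (n < 1) stop("n must be >= 1")
  if (rmsd < 0) stop("rmsd must be >= 0")
  rmsd / (1 + log(sqrt(n / 100)))
}

#' C-alpha RMSD between two equal-length backbones
#'
#' Superposes the C-alpha traces with [kabsch_superpose()] (sequential
#' 1:1 correspondence) and reports the RMSD together with its
#' length-normalised RMSD100.
#'
#' @param a,b `backbone` objects with equal residue counts.
#' @return List with `rmsd` and `rmsd100` (Angstrom).
#' @export
structure_rmsd <- function(a, b) {
  ca_a <- atom_coords(a, "ca")
  ca_b <- atom_coords(b, "ca")
  if (nrow(ca_a) != nrow(ca_b)) {
    stop("structures have different residue counts (", nrow(ca_a),
         " vs ", nrow(ca_b), ")")
  }
  fit <- kabsch_superpose(ca_a, ca_b)
  list(rmsd = fit$rmsd, rmsd100 = rmsd100(fit$rmsd, nrow(ca_a)))
}

#' Backbone packing density
#'
#' For each residue, counts the non-hydrogen backbone atoms (N, C-alpha,
#' C, O of all residues, the residue's own atoms included; the virtual
#' C-beta is excluded) whose distance to that residue's C-alpha is at
#' most `radius`.
#'
#' @param structure A `backbone` object.
#' @param radius Sphere radius in Angstrom (default 7).
#' @return List with `per_residue` (integer counts) and `mean`.
#' @export
packing_density <- function(structure, radius = 7) {
  r <- structure$residues
  if (nrow(r) == 0) stop("empty structure")
  atoms <- do.call(rbind, lapply(c("n", "ca", "c", "o"), function(a) {
    m <- atom_coords(structure, a)
    m[!is.na(m[, 1]), , drop = FALSE]
  }))
  cas <- atom_coords(structure, "ca")
  counts <- vapply(seq_len(nrow(cas)), function(i) {
    d2 <- rowSums(sweep(atoms, 2, cas[i, ])^2)
    sum(d2 <= radius^2)
  }, numeric(1))
  list(per_residue = as.integer(counts), mean = mean(counts))
}

#' Assemble a design evaluation report
#'
#' Bundles the sequence metrics (confusion/recall, bias, charge and pI
#' MAE) and, when probability output or structures are supplied, the
#' entropy and shape metrics, into one list that serialises cleanly to
#' JSON.
#'
#' @param true_seq,pred_seq Reference and designed sequence strings.
#' @param prob_matrix Optional n x 20 probability matrix for entropy.
#' @param structure_a,structure_b Optional `backbone` pair for
#'   RMSD/RMSD100.
#' @param packing_structure Optional `backbone` for packing density.
#' @param packing_radius Packing sphere radius (Angstrom).
#' @return A `metric_report` list.
#' @export
metric_report <- function(true_seq, pred_seq, prob_matrix = NULL,
                          structure_a = NULL, structure_b = NULL,
                          packing_structure = NULL, packing_radius = 7) {
  cr <- confusion_and_recall(true_seq, pred_seq)
  bias <- prediction_bias(true_seq, pred_seq)
  rep <- list(
    macro_recall = cr$macro_recall,
    accuracy = cr$accuracy,
    confusion = unclass(cr$confusion),
    per_class = cr$per_class,
    bias_pct = bias,
    charge_mae = mae(sequence_charge(true_seq), sequence_charge(pred_seq)),
    pi_mae = mae(isoelectric_point(true_seq), isoelectric_point(pred_seq)),
    conventions = list(
      charge_model = "Henderson-Hasselbalch, EMBOSS pKa set, pH 7",
      packing = paste0("backbone N/CA/C/O within ", packing_radius,
                       " A of CA, own atoms included, virtual CB excluded"),
      entropy_base = 2))
  if (!is.null(prob_matrix)) {
    rep$mean_entropy_bits <- mean_entropy(prob_matrix)$mean
  }
  if (!is.null(structure_a) && !is.null(structure_b)) {
    sr <- structure_rmsd(structure_a, structure_b)
    rep$rmsd <- sr$rmsd
    rep$rmsd100 <- sr$rmsd100
  }
  if (!is.null(packing_structure)) {
    rep$mean_packing_density <-
      packing_density(packing_structure, packing_radius)$mean
    rep$packing_radius <- packing_radius
  }
  structure(rep, class = "metric_report")
}
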