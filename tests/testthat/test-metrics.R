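test_that("worked 5-mer example: recalls, macro and accuracy by hand", {
  cr <- confusion_and_recall("AAVVG", "AVVVG")
  # A: 1/2 recovered, V: 2/2, G: 1/1 -> macro over present = (1/2+1+1)/3
  expect_equal(cr$per_class$recall[cr$per_class$amino_acid == "A"], 0.5)
  expect_equal(cr$per_class$recall[cr$per_class$amino_acid == "V"], 1)
  expect_equal(cr$per_class$recall[cr$per_class$amino_acid == "G"], 1)
  expect_equal(cr$macro_recall, 5 / 6)
  expect_equal(cr$accuracy, 4 / 5)
  expect_equal(sum(cr$confusion), 5)
})

test_that("constant predictor against all 20 classes scores the 5% cap", {
  ref <- paste(AA_ALPHABET, collapse = "")
  pred <- strrep("A", 20)
  cr <- confusion_and_recall(ref, pred)
  expect_equal(cr$macro_recall, 0.05)
  # strict mode gives the same number here (all classes present)
  expect_equal(confusion_and_recall(ref, pred, strict = TRUE)$macro_recall,
               0.05)
})

test_that("perfect predictions score 1 and length mismatches error", {
  cr <- confusion_and_recall("ACDEFG", "ACDEFG")
  expect_equal(cr$macro_recall, 1)
  expect_equal(cr$accuracy, 1)
  expect_error(confusion_and_recall("AAA", "AA"), "length")
  # X positions are dropped and counted
  crx <- confusion_and_recall("AXA", "AAA")
  expect_equal(crx$n_dropped, 1)
  expect_equal(crx$accuracy, 1)
})

test_that("macro-recall of a random predictor on balanced classes is ~5%", {
  n <- 1e5
  set.seed(77)
  truth <- paste(rep(AA_ALPHABET, length.out = n), collapse = "")
  pred <- paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
  expect_lt(abs(confusion_and_recall(truth, pred)$macro_recall - 0.05),
            0.01)
})

test_that("prediction bias is the signed frequency difference in percent", {
  expect_equal(max(abs(prediction_bias("ACDE", "ACDE"))), 0)
  b <- prediction_bias("AG", "AA")
  expect_equal(unname(b["A"]), 50)
  expect_equal(unname(b["G"]), -50)
  expect_equal(sum(abs(b[!names(b) %in% c("A", "G")])), 0)
  # conservation: biases always sum to zero
  set.seed(12)
  t_s <- paste(sample(AA_ALPHABET, 200, replace = TRUE), collapse = "")
  p_s <- paste(sample(AA_ALPHABET, 200, replace = TRUE), collapse = "")
  expect_lt(abs(sum(prediction_bias(t_s, p_s))), 1e-9)
  expect_error(prediction_bias(c("AA", "CC"), c("AA")), "length")
})

test_that("net charge behaves physically and pI zeroes it", {
  expect_gt(sequence_charge("KKKK", 7), 0)
  expect_lt(sequence_charge("DDDD", 7), 0)
  # monotone decreasing in pH
  phs <- seq(0, 14, by = 0.5)
  qs <- vapply(phs, function(p) sequence_charge("ACDKYRH", p), numeric(1))
  expect_true(all(diff(qs) < 0))
  for (seq in c("GGGG", "KKDD", "ACDEFGHIKLMNPQRSTVWY")) {
    pi <- isoelectric_point(seq)
    expect_lt(abs(sequence_charge(seq, pi)), 1e-4)
  }
  # fine grid-scan oracle on one sequence
  grid <- seq(0, 14, by = 1e-4)
  qg <- abs(vapply(grid, function(p) sequence_charge("KKDD", p),
                   numeric(1)))
  expect_lt(abs(isoelectric_point("KKDD") - grid[which.min(qg)]), 1e-3)
  expect_error(sequence_charge(""), "empty")
})

test_that("mae is the plain mean absolute difference", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(0, 2), c(1, 1)), 1.0)
  expect_equal(mae(c(0, 2), c(1, 1)), mae(c(1, 1), c(0, 2)))
  expect_error(mae(1:3, 1:2), "length")
  expect_error(mae(numeric(), numeric()), "empty")
})

test_that("entropy hits its closed forms and the log2(20) cap", {
  uniform <- matrix(1 / 20, 7, 20)
  ent <- mean_entropy(uniform)
  expect_equal(round(ent$mean, 2), 4.32)
  expect_equal(ent$mean, log2(20), tolerance = 1e-12)
  onehot <- diag(20)
  expect_equal(mean_entropy(onehot)$mean, 0)
  half <- matrix(c(0.5, 0.5, rep(0, 18)), 1, 20, byrow = TRUE)
  expect_equal(mean_entropy(half)$mean, 1.0)
  # row order invariance
  set.seed(2)
  m <- matrix(stats::rgamma(5 * 20, 1), 5, 20)
  m <- m / rowSums(m)
  expect_equal(mean_entropy(m[5:1, ])$mean, mean_entropy(m)$mean)
})

test_that("rmsd100 matches its closed form", {
  expect_equal(rmsd100(1.7, 100), 1.7)
  expect_equal(rmsd100(2.0, 400), 2.0 / (1 + log(2)))
  expect_equal(rmsd100(0, 321), 0)
  expect_error(rmsd100(1, 0), "n must")
})

test_that("structure_rmsd composes kabsch and rmsd100", {
  h <- make_helix(20)
  h2 <- transform_backbone(ensure_virtual_cbeta(h),
                           random_rigid_transform(17))
  sr <- structure_rmsd(h, h2)
  expect_equal(sr$rmsd, 0, tolerance = 1e-6)
  expect_equal(sr$rmsd100, 0, tolerance = 1e-6)
  # uniform displacement along one axis survives superposition partially;
  # compare against direct kabsch on the CA coordinates
  h3 <- h
  h3$residues$ca_x <- h3$residues$ca_x + stats::rnorm(20, sd = 1)
  direct <- kabsch_superpose(atom_coords(h, "ca"), atom_coords(h3, "ca"))
  sr3 <- structure_rmsd(h, h3)
  expect_equal(sr3$rmsd, direct$rmsd, tolerance = 1e-9)
  expect_equal(sr3$rmsd100, rmsd100(sr3$rmsd, 20), tolerance = 1e-12)
  expect_error(structure_rmsd(h, make_helix(10)), "residue counts")
})

test_that("packing density counts backbone atoms in the 7 A sphere", {
  s <- read_backbone(single_ala_pdb())
  pd <- packing_density(s)
  # an isolated residue sees only its own N, CA, C, O
  expect_equal(pd$per_residue, 4L)
  expect_equal(pd$mean, 4)
  h <- make_helix(20)
  pd7 <- packing_density(h, 7)
  pd5 <- packing_density(h, 5)
  expect_true(all(pd7$per_residue >= pd5$per_residue))
  # helices pack denser than extended strands
  st <- make_strand(20)
  expect_gt(pd7$mean, packing_density(st, 7)$mean)
})

test_that("metric_report bundles the suite consistently", {
  h <- make_helix(12, sequence = "AAVVGGAAVVGG")
  rep <- metric_report("AAVVGGAAVVGG", "AAVVGGAAVVGA",
                       prob_matrix = matrix(1 / 20, 12, 20),
                       structure_a = h, structure_b = h,
                       packing_structure = h)
  expect_equal(rep$rmsd, 0, tolerance = 1e-9)
  expect_equal(rep$mean_entropy_bits, log2(20), tolerance = 1e-9)
  expect_equal(rep$charge_mae, 0, tolerance = 1e-9)  # G->A changes no charge
  expect_lt(rep$accuracy, 1)
  expect_gt(rep$mean_packing_density, 4)
})
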