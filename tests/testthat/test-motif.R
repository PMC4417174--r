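test_that("positional IC spans 0 to 2 bits and matches the entropy route", {
  expect_equal(positional_ic(rep(0.25, 4)), 0)
  expect_equal(positional_ic(c(1, 0, 0, 0)), 2)
  expect_equal(positional_ic(c(0.5, 0.5, 0, 0)), 1)
  withr::with_seed(111, {
    for (i in 1:50) {
      p <- runif(4); p <- p / sum(p)
      expect_equal(positional_ic(p), brute_force_ic(p), tolerance = 1e-12)
      # permutation invariance over bases
      expect_equal(positional_ic(sample(p)), positional_ic(p), tolerance = 1e-12)
      # single-base columns are the unique maximum
      expect_lt(positional_ic(p), 2)
    }
  })
  expect_error(positional_ic(c(0.5, 0.5, 0.5, -0.5)),
               class = "etsdyn_validation_error")
  expect_error(positional_ic(c(0.3, 0.3, 0.3, 0.3)),
               class = "etsdyn_validation_error")
})

test_that("total IC sums positions; stacks sum to the positional IC", {
  uniform10 <- motif_matrix(matrix(0.25, 4, 10))
  expect_equal(total_ic(uniform10)$total_ic, 0)
  sharp10 <- demo_motifs()$sharp
  expect_equal(total_ic(sharp10)$total_ic, 20)
  two <- motif_matrix(cbind(c(1, 0, 0, 0), c(0.5, 0.5, 0, 0)))
  prof <- total_ic(two)
  expect_equal(prof$total_ic, 3)
  expect_equal(colSums(prof$stack_heights), prof$positional_ic,
               ignore_attr = TRUE)
  expect_true(all(prof$positional_ic >= 0 & prof$positional_ic <= 2))
})

test_that("total IC is additive over concatenated motifs", {
  withr::with_seed(112, {
    pa <- matrix(runif(20), 4); pa <- sweep(pa, 2, colSums(pa), "/")
    pb <- matrix(runif(12), 4); pb <- sweep(pb, 2, colSums(pb), "/")
  })
  a <- motif_matrix(pa); b <- motif_matrix(pb); ab <- motif_matrix(cbind(pa, pb))
  expect_equal(total_ic(ab)$total_ic,
               total_ic(a)$total_ic + total_ic(b)$total_ic, tolerance = 1e-12)
})

test_that("ic_difference subtracts totals, is antisymmetric, enforces length", {
  m <- demo_motifs()
  expect_equal(ic_difference(m$sharp, m$sharp), 0)
  d <- ic_difference(m$sharp, m$soft)
  expect_equal(ic_difference(m$soft, m$sharp), -d)
  # constructed 20-bit vs 17-bit pair differs by 3
  cols17 <- cbind(matrix(rep(diag(4)[, 1], 7), nrow = 4),
                  matrix(0.5 * (diag(4)[, 1] + diag(4)[, 2]), 4, 3))
  m17 <- motif_matrix(cols17[, c(1:7, 8:10)])
  m20 <- motif_matrix(matrix(rep(diag(4)[, 1], 10), nrow = 4))
  expect_equal(ic_difference(m20, m17), 3, tolerance = 1e-12)
  short <- motif_matrix(matrix(0.25, 4, 8))
  expect_error(ic_difference(m$sharp, short), class = "etsdyn_validation_error")
})

test_that("delta_total_ic implements the discrimination-energetics bound", {
  res <- delta_total_ic(1e-10, 1e-5, 1e-10, 1e-7)
  expect_equal(res$delta_total_ic, log(2) * log2(100), tolerance = 1e-9)
  expect_equal(round(res$delta_total_ic, 3), 4.605)
  expect_gte(res$delta_total_ic, 2)
  # A = B gives zero; swap negates
  expect_equal(delta_total_ic(1e-10, 1e-6, 1e-10, 1e-6)$delta_total_ic, 0)
  swapped <- delta_total_ic(1e-10, 1e-7, 1e-10, 1e-5)
  expect_equal(swapped$delta_total_ic, -res$delta_total_ic, tolerance = 1e-12)
  # linear in epsilon_r; ratio terms 1 bit apart at eps = 1 give 1 bit
  one <- delta_total_ic(1e-9, 2e-9, 1e-9, 1e-9, epsilon_r = 1)
  expect_equal(one$delta_total_ic, 1, tolerance = 1e-12)
  half <- delta_total_ic(1e-10, 1e-5, 1e-10, 1e-7, epsilon_r = log(2) / 2)
  expect_equal(half$delta_total_ic, res$delta_total_ic / 2, tolerance = 1e-12)
  expect_error(delta_total_ic(-1e-10, 1e-5, 1e-10, 1e-7),
               class = "etsdyn_validation_error")
})

test_that("IC from counts equals IC from normalized probabilities", {
  withr::with_seed(113, {
    counts <- matrix(rpois(40, 50) + 1, 4, 10)
  })
  from_counts <- motif_matrix(counts = counts)
  from_probs <- motif_matrix(sweep(counts, 2, colSums(counts), "/"))
  expect_equal(total_ic(from_counts)$total_ic, total_ic(from_probs)$total_ic,
               tolerance = 1e-12)
})

test_that("JASPAR parser reads bracketed counts and round-trips", {
  path <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">MA0000.0 demo",
               "A [ 10  0 ]",
               "C [  0  5 ]",
               "G [  0  5 ]",
               "T [  0  0 ]"), path)
  m <- read_motif(path, "jaspar")
  expect_equal(ncol(m$probs), 2)
  expect_equal(m$probs[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(m$probs[, 2], c(A = 0, C = 0.5, G = 0.5, T = 0))
  out <- withr::local_tempfile(fileext = ".jaspar")
  write_motif(m, out, "jaspar")
  m2 <- read_motif(out, "jaspar")
  expect_equal(m2$probs, m$probs, tolerance = 1e-12)
})

test_that("MEME-minimal parser reads probability blocks", {
  path <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF demo",
               "letter-probability matrix: alength= 4 w= 3 nsites= 20 E= 0",
               " 0.25 0.25 0.25 0.25",
               " 1.0 0.0 0.0 0.0",
               " 0.0 0.5 0.5 0.0"), path)
  m <- read_motif(path, "meme_minimal")
  expect_equal(ncol(m$probs), 3)
  expect_equal(total_ic(m)$total_ic, 0 + 2 + 1, tolerance = 1e-9)
  bad <- withr::local_tempfile()
  writeLines(c("MOTIF x", "letter-probability matrix: alength= 4 w= 2",
               "0.5 0.5"), bad)
  expect_error(read_motif(bad, "meme_minimal"), class = "etsdyn_parse_error")
})

test_that("counts TSV parser round-trips and rejects all-zero columns", {
  m <- gen_motif_counts(demo_motifs()$soft, 200, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_motif(m, path, "counts_tsv")
  m2 <- read_motif(path, "counts_tsv")
  expect_equal(m2$probs, m$probs, tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c("A [ 1 0 ]", "C [ 1 0 ]", "G [ 0 0 ]", "T [ 1 0 ]"), bad)
  expect_error(read_motif(bad, "jaspar"), class = "etsdyn_validation_error")
})
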