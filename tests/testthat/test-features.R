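test_that("feature dimensionalities match the registry for every spec", {
  g <- generate_family("Dim", n_genes = 6, length_codons = c(60, 80), seed = 4)
  reg <- feature_specs()
  for (i in seq_len(nrow(reg))) {
    fm <- gene_features(g, reg$name[i])
    expect_equal(ncol(fm) - 1L, reg$dim[i], info = reg$name[i])
    if (!is.na(reg$k[i])) {
      expect_equal(reg$dim[i], 4L^reg$k[i], info = reg$name[i])
    }
  }
  expect_equal(feature_dim("aa"), 20L)
  expect_equal(feature_dim("posnt"), 12L)
})

test_that("oligonucleotide frequencies count overlapping ACGT windows", {
  f1 <- oligo_freqs("ACGT", k = 1)
  expect_equal(unname(f1), rep(0.25, 4))
  expect_equal(names(f1), c("A", "C", "G", "T"))

  f2 <- oligo_freqs("AAAA", k = 2)
  expect_equal(unname(f2["AA"]), 1)
  expect_equal(sum(f2), 1)

  # 5 overlapping 4-mers of ACGTACGT: ACGT, CGTA, GTAC, TACG, ACGT
  f4 <- oligo_freqs("ACGTACGT", k = 4)
  expect_equal(unname(f4["ACGT"]), 2 / 5)
  expect_equal(unname(f4["CGTA"]), 1 / 5)
  expect_equal(unname(f4["GTAC"]), 1 / 5)
  expect_equal(unname(f4["TACG"]), 1 / 5)
  expect_equal(sum(f4), 1)

  # windows containing N are skipped
  fN <- oligo_freqs("ACNGT", k = 2)
  expect_equal(sum(fN), 1)
  expect_equal(unname(fN["AC"]), 0.5)
  expect_equal(unname(fN["GT"]), 0.5)

  expect_error(oligo_freqs("NNNN", k = 2), class = "atyp_unencodable_error")
  expect_error(oligo_freqs("ACGT", k = 5), class = "atyp_parameter_error")
})

test_that("GC content excludes ambiguity codes and is strand-symmetric", {
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("AATT"), 0)
  expect_equal(gc_content("GCGC"), 1)
  expect_equal(gc_content("ACGTNNNN"), 0.5)
  expect_error(gc_content("NNN"), class = "atyp_unencodable_error")

  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  set.seed(11)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
    expect_equal(gc_content(s), gc_content(revcomp(s)))
  }
})

test_that("codon usage reads frame 0 and drops trailing partial codons", {
  cu <- codon_usage("ATGATG")
  expect_equal(unname(cu["ATG"]), 1)

  cu3 <- codon_usage("ATGAAATAA")
  expect_equal(unname(cu3[c("ATG", "AAA", "TAA")]), rep(1 / 3, 3))
  expect_equal(sum(cu3), 1)

  expect_warning(cu_trunc <- codon_usage("ATGAAAA"), "partial codon")
  expect_equal(cu_trunc, codon_usage("ATGAAA"))

  expect_error(suppressWarnings(codon_usage("AT")),
               class = "atyp_unencodable_error")
})

test_that("relative codon usage normalizes within synonymous families", {
  expect_equal(unname(relative_codon_usage("ATGATG")["ATG"]), 1)

  r <- relative_codon_usage("AAAAAG")
  expect_equal(unname(r[c("AAA", "AAG")]), c(0.5, 0.5))

  # six-codon leucine family: TTA x2, TTG x1, the four CTN codons unobserved
  rl <- relative_codon_usage("TTATTATTG")
  expect_equal(unname(rl["TTA"]), 2 / 3)
  expect_equal(unname(rl["TTG"]), 1 / 3)
  expect_equal(unname(rl[c("CTT", "CTC", "CTA", "CTG")]), rep(0, 4))

  # an amino-acid family with zero observed codons is imputed uniform
  expect_equal(unname(rl[c("AAA", "AAG")]), c(0.5, 0.5))  # Lys unobserved
  expect_equal(unname(rl[c("TAA", "TAG", "TGA")]), rep(1 / 3, 3))  # stops

  # every synonymous family sums to 1
  fams <- atypicalr:::codon_families("1")
  for (fam in fams) {
    expect_equal(sum(rl[fam]), 1)
  }
})

test_that("amino-acid frequencies translate with the standard code, stops excluded", {
  a <- amino_acid_freqs("ATGATG")
  expect_equal(unname(a["aa_M"]), 1)
  expect_length(a, 20L)

  a2 <- amino_acid_freqs("ATGAAATAA")
  expect_equal(unname(a2["aa_M"]), 0.5)
  expect_equal(unname(a2["aa_K"]), 0.5)
  expect_equal(sum(a2), 1)

  expect_error(amino_acid_freqs("TAATAA"), class = "atyp_unencodable_error")
})

test_that("position-specific nucleotide frequencies sum to 1 per codon position", {
  p <- position_nt_freqs("ATG")
  expect_length(p, 12L)
  expect_equal(unname(p[c("p1_A", "p2_T", "p3_G")]), c(1, 1, 1))
  expect_equal(sum(p), 3)

  p2 <- position_nt_freqs("ATGGTA")
  expect_equal(unname(p2[c("p1_A", "p1_G")]), c(0.5, 0.5))
  expect_equal(unname(p2["p2_T"]), 1)
  expect_equal(unname(p2[c("p3_G", "p3_A")]), c(0.5, 0.5))
  for (pos in 1:3) {
    expect_equal(sum(p2[paste0("p", pos, "_", c("A", "C", "G", "T"))]), 1)
  }
})

test_that("gene_features builds row-per-gene tables and reports exclusions", {
  g <- generate_family("M", n_genes = 5, length_codons = c(10, 15), seed = 6)
  fm <- gene_features(g, "mono")
  expect_s3_class(fm, "atyp_features")
  expect_equal(fm$gene_id, g$gene_id)
  expect_equal(unname(rowSums(atypicalr:::feature_values(fm))), rep(1, 5))

  # all-N gene is excluded and reported
  gN <- dplyr::bind_rows(g, gene_table("allN", "M", strrep("N", 30)))
  fmN <- gene_features(gN, "mono")
  expect_equal(nrow(fmN), 5L)
  excl <- attr(fmN, "excluded")
  expect_equal(excl$gene_id, "allN")

  # a duplicated sequence appears as two identical rows
  gd <- dplyr::bind_rows(g, dplyr::mutate(g[1, ], gene_id = "dup"))
  fmd <- gene_features(gd, "di")
  x <- atypicalr:::feature_values(fmd)
  expect_equal(unname(x[6, ]), unname(x[1, ]))

  # fewer than 4 encodable genes is an error
  small <- gene_table(c("a", "b", "c"), "S", rep("ATGAAATAA", 3))
  expect_error(gene_features(small, "mono"), class = "atyp_validation_error")
})

test_that("standardization gives population z-scores and zeroes constant columns", {
  x <- features_from_matrix(cbind(c(1, 3), c(5, 5)), standardized = FALSE)
  z <- standardize_features(x)
  v <- atypicalr:::feature_values(z)
  expect_equal(unname(v[, 1]), c(-1, 1))  # population sd of (1,3) is 1
  expect_equal(unname(v[, 2]), c(0, 0))   # constant column maps to zeros

  g <- generate_family("Z", n_genes = 10, length_codons = c(30, 60), seed = 8)
  fm <- standardize_features(gene_features(g, "codon_usage"))
  vals <- atypicalr:::feature_values(fm)
  nonconst <- apply(vals, 2, function(col) any(col != 0))
  expect_true(all(abs(colMeans(vals[, nonconst])) < 1e-9))
  pop_var <- colMeans(sweep(vals[, nonconst], 2, colMeans(vals[, nonconst]))^2)
  expect_true(all(abs(pop_var - 1) < 1e-6))

  # idempotence
  fm2 <- standardize_features(fm)
  expect_equal(atypicalr:::feature_values(fm2), vals, tolerance = 1e-9)

  expect_error(standardize_features(features_from_matrix(matrix(1, 1, 2),
                                                         standardized = FALSE)),
               class = "atyp_validation_error")
})

test_that("feature rows are permutation-equivariant in gene order", {
  g <- generate_family("P", n_genes = 8, length_codons = c(20, 40), seed = 10)
  perm <- c(5, 1, 8, 2, 7, 3, 6, 4)
  for (spec in c("di", "codon_usage", "position_nt")) {
    a <- gene_features(g, spec)
    b <- gene_features(g[perm, ], spec)
    expect_equal(atypicalr:::feature_values(b),
                 atypicalr:::feature_values(a)[perm, ], info = spec)
  }
})

test_that("homopolymer codon repeats link trinucleotide and codon signatures", {
  # for a repeated homopolymer codon the trinucleotide frequency equals 1
  s <- strrep("AAA", 10)
  expect_equal(unname(oligo_freqs(s, 3)["AAA"]), 1)
  expect_equal(unname(codon_usage(s)["AAA"]), 1)
  # for a general repeated codon, its trinucleotide frequency is >= 1/3
  s2 <- strrep("ATG", 10)
  expect_gte(oligo_freqs(s2, 3)["ATG"], 1 / 3)
})

test_that("experimental GC regression residualizes features against GC content", {
  g <- generate_family("GR", n_genes = 20, length_codons = c(40, 80), seed = 14)
  fm <- gene_features(g, "di", gc_regression = TRUE)
  expect_true(attr(fm, "gc_regressed"))
  expect_equal(ncol(fm) - 1L, 16L)  # dimensionality unchanged
  gc <- vapply(g$seq, gc_content, numeric(1))
  vals <- atypicalr:::feature_values(fm)
  # residual columns are orthogonal to GC and centered
  for (j in seq_len(ncol(vals))) {
    expect_lt(abs(sum(vals[, j] * (gc - mean(gc)))), 1e-9)
    expect_lt(abs(mean(vals[, j])), 1e-9)
  }
  # default path is unaffected
  expect_false(attr(gene_features(g, "di"), "gc_regressed"))
})

test_that("feature tables round-trip through TSV", {
  g <- generate_family("T", n_genes = 5, length_codons = c(10, 12), seed = 12)
  fm <- gene_features(g, "posnt")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "features.tsv")
  write_features_tsv(fm, path)
  back <- read_features_tsv(path)
  expect_equal(names(back), names(fm))
  expect_equal(back$gene_id, fm$gene_id)
  expect_equal(as.matrix(back[, -1]), atypicalr:::feature_values(fm),
               ignore_attr = TRUE, tolerance = 1e-12)
})
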