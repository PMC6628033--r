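test_that("config validation enforces the experiment's invariants", {
  expect_error(f2_sim_config(causal_pos = 12345), "marker positions")
  expect_error(f2_sim_config(error_rate = 0.6), "error_rate")
  expect_error(f2_sim_config(depth = 0), "depth")
  expect_error(
    f2_sim_config(markers = tibble::tibble(chrom = "chr4", pos = 30e6),
                  causal_chrom = NA),
    "outside their chromosome")
  cfg <- f2_sim_config(seed = 3)
  expect_s3_class(cfg, "f2_sim_config")
  expect_identical(cfg$bulk_size, 33L)
})

test_that("zero genetic length gives perfect within-chromosome linkage", {
  cfg <- f2_sim_config(chrom_lengths = c(chrA = 1e6),
                       genetic_lengths = c(chrA = 0),
                       marker_spacing = 1e5, causal_chrom = "chrA",
                       causal_pos = 5e5, n_individuals = 50, seed = 4)
  pop <- simulate_f2(cfg)
  per_row_range <- apply(pop$genotypes, 1, function(g) length(unique(g)))
  expect_true(all(per_row_range == 1L))
})

test_that("mutant phenotype frequency converges to the Mendelian 1/4", {
  cfg <- f2_sim_config(marker_spacing = 1e6, causal_pos = 11e6,
                       n_individuals = 12000, seed = 5)
  pop <- simulate_f2(cfg)
  p_hat <- mean(pop$phenotype == "mutant")
  tol <- 3 * sqrt(0.25 * 0.75 / 12000)
  expect_lt(abs(p_hat - 0.25), tol)
})

test_that("markers unlinked to the causal locus are at frequency 1/2 among mutants", {
  cfg <- f2_sim_config(
    chrom_lengths = c(chr4 = 20e6, chr1 = 10e6),
    genetic_lengths = c(chr4 = 0.8, chr1 = 0.5),
    marker_spacing = 5e6, causal_chrom = "chr4", causal_pos = 10e6,
    n_individuals = 12000, seed = 6)
  pop <- simulate_f2(cfg)
  mut <- pop$genotypes[pop$phenotype == "mutant", , drop = FALSE]
  unlinked <- which(pop$markers$chrom == "chr1")[1]
  freq <- mean(mut[, unlinked]) / 2
  expect_lt(abs(freq - 0.5), 0.02)
})

test_that("bulks are drawn from the right phenotype classes and sizes are checked", {
  cfg <- f2_sim_config(marker_spacing = 1e6, causal_pos = 11e6,
                       n_individuals = 156, bulk_size = 33, seed = 8)
  pop <- simulate_f2(cfg)
  n_mut <- sum(pop$phenotype == "mutant")
  expect_gte(n_mut, 33)  # this seed gives a feasible mutant class
  bulks <- select_bulks(pop)
  expect_identical(nrow(bulks$mutant$genotypes), 33L)
  expect_identical(nrow(bulks$wildtype$genotypes), 33L)
  expect_true(all(bulks$mutant$phenotype == "mutant"))
  expect_true(all(bulks$wildtype$phenotype == "wildtype"))
  # requesting more than a class holds names the class and the counts
  expect_error(select_bulks(pop, bulk_size = n_mut + 1),
               sprintf("mutant class: only %d", n_mut))
  empty <- select_bulks(pop, bulk_size = 0)
  expect_identical(nrow(empty$mutant$genotypes), 0L)
  expect_error(bulk_allele_freq(empty$mutant), "empty")
})

test_that("bulk allele frequencies follow the recessive model", {
  cfg <- f2_sim_config(marker_spacing = 1e6, causal_pos = 11e6,
                       n_individuals = 3000, seed = 9)
  pop <- simulate_f2(cfg)
  ci <- which(pop$markers$chrom == "chr4" & pop$markers$pos == 11e6)
  bulks <- select_bulks(pop, bulk_size = 100)
  # mutant bulk is fixed for the parent-B allele at the causal marker
  expect_identical(bulk_allele_freq(bulks$mutant)$freq[ci], 1)
  # the wildtype class is 1 AA : 2 Aa, so its expected frequency is 1/3
  wt_class <- pop$genotypes[pop$phenotype == "wildtype", ci]
  expect_lt(abs(mean(wt_class) / 2 - 1 / 3), 0.02)
  # a bulk of one heterozygote sits at exactly 0.5
  het <- manual_population(matrix(1L, 1, 1),
                           tibble::tibble(chrom = "chr4", pos = 1e6),
                           "wildtype")
  expect_identical(bulk_allele_freq(het)$freq, 0.5)
})

test_that("read sampling hits its degenerate and binomial expectations", {
  fixed1 <- sample_reads(1, depth = 30, error_rate = 0, depth_model = "fixed",
                         seed = 1)
  expect_identical(fixed1$ref_depth, 0L)
  expect_identical(fixed1$alt_depth, 30L)
  fixed0 <- sample_reads(0, depth = 30, error_rate = 0, depth_model = "fixed",
                         seed = 1)
  expect_identical(fixed0$alt_depth, 0L)
  draws <- sample_reads(rep(0.5, 10000), depth = 80, error_rate = 0, seed = 2)
  frac <- sum(draws$alt_depth) / sum(draws$ref_depth + draws$alt_depth)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / (10000 * 80)))
  expect_error(sample_reads(1.2, depth = 10), "\\[0, 1\\]")
})

test_that("at effectively infinite depth the causal-site index is exactly 1", {
  cfg <- f2_sim_config(marker_spacing = 1e6, causal_pos = 11e6,
                       n_individuals = 200, depth = 1e5,
                       depth_model = "fixed", error_rate = 0, seed = 10)
  rec <- simulate_bulk_seq(cfg)
  causal <- rec[rec$pos == 11e6, ]
  expect_identical(snp_index(causal$mut_ref, causal$mut_alt), 1)
})

test_that("linkage decays with genetic distance from the causal locus", {
  dists <- c(0, 3e6, 8e6)
  pos <- 11e6 + dists
  dev <- matrix(NA_real_, nrow = 30, ncol = length(pos))
  for (r in seq_len(30)) {
    cfg <- f2_sim_config(marker_spacing = 1e6, causal_pos = 11e6,
                         n_individuals = 200, seed = 100 + r)
    pop <- simulate_f2(cfg)
    bulks <- select_bulks(pop)
    freq <- bulk_allele_freq(bulks$mutant)
    idx <- match(pos, freq$pos)
    dev[r, ] <- abs(freq$freq[idx] - 0.5)
  }
  m <- colMeans(dev)
  expect_true(all(diff(m) < 0))
})

test_that("the same master seed reproduces the data byte for byte", {
  cfg <- f2_sim_config(marker_spacing = 2e5, causal_pos = 11.2e6,
                       n_individuals = 80, bulk_size = 10, seed = 77)
  r1 <- simulate_bulk_seq(cfg)
  r2 <- simulate_bulk_seq(f2_sim_config(marker_spacing = 2e5,
                                        causal_pos = 11.2e6,
                                        n_individuals = 80, bulk_size = 10,
                                        seed = 77))
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_simulated_vcf(r1, f1)
  write_simulated_vcf(r2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("a null configuration breaks the genotype-phenotype link", {
  cfg <- f2_sim_config(marker_spacing = 1e6, causal_chrom = NA,
                       n_individuals = 8000, seed = 12)
  pop <- simulate_f2(cfg)
  expect_lt(abs(mean(pop$phenotype == "mutant") - 0.25), 0.02)
  # phenotype is independent of every marker genotype
  m <- pop$genotypes[pop$phenotype == "mutant", 11, drop = FALSE]
  expect_lt(abs(mean(m) / 2 - 0.5), 0.025)
})
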