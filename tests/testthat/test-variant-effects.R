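test_that("all 64 codons translate to the hand-keyed standard code", {
  codons <- names(HAND_CODE)
  expect_identical(translate_codon(codons), unname(HAND_CODE))
  expect_identical(translate_codon("TTT"), "F")
  expect_identical(translate_codon("TGA"), "*")
  expect_error(translate_codon("TTN"), "Invalid codon")
  expect_error(translate_codon("TT"), "Invalid codon")
})

test_that("codon-pair effects are classified per the amino-acid change", {
  expect_identical(classify_effect("TTT", "TAT"), "missense")
  expect_identical(classify_effect("CCT", "CCG"), "synonymous")
  expect_identical(classify_effect("TGG", "TAG"), "nonsense")
  expect_identical(classify_effect("TGA", "GGA"), "stop_loss")
  expect_error(classify_effect("AAA", "TTT"), "expected exactly 1")
  expect_error(classify_effect("AAA", "AAA"), "expected exactly 1")
})

# A toy gene pair used for coordinate arithmetic: same codons on + and -.
toy_setup <- function() {
  # genome 1..400; a forward gene with CDS [101..106] = ATGGAA (M E)
  seq <- paste0(strrep("C", 100), "ATGGAA", strrep("C", 94),
                # at 201..206 the reverse-complement gene: genomic TTCCAT
                # reads ATGGAA on the minus strand
                "TTCCAT", strrep("C", 194))
  ref <- setNames(seq, "chrT")
  fwd <- toy_gene("fwd", strand = "+", starts = 101L, ends = 106L)
  rev <- toy_gene("rev", strand = "-", starts = 201L, ends = 206L)
  list(ref = ref, fwd = fwd, rev = rev)
}

test_that("forward-strand SNPs map to the right codon slot", {
  ts <- toy_setup()
  # CDS offset of position 105 is 5 -> codon 2, within-codon position 2
  ann <- snp_to_codon(ts$fwd, ts$ref, pos = 105L, ref = "A", alt = "T")
  expect_identical(ann$codon_number, 2L)
  expect_identical(ann$codon_pos, 2L)
  expect_identical(ann$ref_codon, "GAA")
  expect_identical(ann$alt_codon, "GTA")
  expect_identical(ann$ref_aa, "E")
  expect_identical(ann$alt_aa, "V")
  expect_identical(ann$effect, "missense")
})

test_that("minus-strand SNPs are complemented onto the transcript", {
  ts <- toy_setup()
  # genomic 206 is transcript position 1 (the A of ATG); genomic base T
  ann <- snp_to_codon(ts$rev, ts$ref, pos = 206L, ref = "T", alt = "C")
  expect_identical(ann$codon_number, 1L)
  expect_identical(ann$codon_pos, 1L)
  expect_identical(ann$ref_codon, "ATG")
  expect_identical(ann$alt_codon, "GTG")  # alt C complements to G
  expect_identical(ann$ref_aa, "M")
  expect_identical(ann$effect, "missense")
})

test_that("mirror genes give identical amino-acid outcomes on both strands", {
  ts <- toy_setup()
  # the same transcript change expressed through either strand
  fwd <- snp_to_codon(ts$fwd, ts$ref, pos = 104L, ref = "G", alt = "A")
  rev <- snp_to_codon(ts$rev, ts$ref, pos = 203L, ref = "C", alt = "T")
  expect_identical(fwd$ref_codon, rev$ref_codon)
  expect_identical(fwd$alt_codon, rev$alt_codon)
  expect_identical(fwd$effect, rev$effect)
})

test_that("non-CDS positions and reference mismatches are handled", {
  ts <- toy_setup()
  two_exon <- toy_gene("g2", strand = "+", starts = c(101L, 111L),
                       ends = c(103L, 116L))
  between <- snp_to_codon(two_exon, ts$ref, pos = 105L, ref = "A", alt = "G")
  expect_identical(between$effect, "non_coding")
  expect_error(snp_to_codon(ts$fwd, ts$ref, pos = 101L, ref = "G", alt = "T"),
               "Reference mismatch")
})

test_that("two-exon genes accumulate CDS offsets across the intron", {
  # CDS [101..103] + [111..116]: transcript = ATG GAA ??? needs bases at
  # 111..116; build a dedicated reference
  seq <- paste0(strrep("A", 100), "ATG", strrep("T", 7), "GAACCC",
                strrep("A", 100))
  ref <- setNames(seq, "chrT")
  gene <- toy_gene("g3", strand = "+", starts = c(101L, 111L),
                   ends = c(103L, 116L))
  ann <- snp_to_codon(gene, ref, pos = 112L, ref = "A", alt = "T")
  expect_identical(ann$codon_number, 2L)   # offset 3 + 2 = 5
  expect_identical(ann$codon_pos, 2L)
  expect_identical(ann$ref_codon, "GAA")
})

test_that("third-position wobble in four-fold families is synonymous", {
  bases <- c("A", "C", "G", "T")
  fourfold <- c("GC", "GG", "CC", "CG", "AC", "GT", "CT", "TC")
  for (stem in fourfold) {
    for (b1 in bases) for (b2 in setdiff(bases, b1)) {
      expect_identical(
        classify_effect(paste0(stem, b1), paste0(stem, b2)), "synonymous")
    }
  }
})

test_that("bulk annotation joins variants to overlapping genes with counts", {
  ts <- toy_setup()
  genes <- dplyr::bind_rows(ts$fwd, ts$rev)
  rec <- tibble::tibble(
    chrom = "chrT", pos = c(105L, 206L, 150L),
    ref = c("A", "T", "C"), alt = c("T", "C", "G"),
    mut_ref = c(0L, 2L, 50L), mut_alt = c(80L, 78L, 50L),
    wt_ref = c(50L, 50L, 50L), wt_alt = c(30L, 30L, 50L)
  )
  ann <- annotate_variants(rec, genes, ts$ref)
  expect_identical(nrow(ann), 2L)  # pos 150 overlaps no CDS
  expect_setequal(ann$gene_id, c("fwd", "rev"))
  counts <- attr(ann, "effect_counts")
  expect_identical(counts$n[counts$effect == "missense"], 2L)

  # the homozygosity pre-filter keeps only mutant-pool indices >= cutoff
  ann_f <- annotate_variants(rec, genes, ts$ref, min_mut_index = 0.99)
  expect_identical(nrow(ann_f), 1L)
  expect_identical(ann_f$pos, 105L)

  empty <- annotate_variants(rec, genes[0, ], ts$ref)
  expect_identical(nrow(empty), 0L)
})

test_that("co-segregation is perfect only at the causal marker", {
  cfg <- f2_sim_config(marker_spacing = 1e6, causal_pos = 11e6,
                       n_individuals = 300, seed = 51)
  pop <- simulate_f2(cfg)
  at_causal <- cosegregation_rate(pop, "chr4", 11e6)
  expect_identical(at_causal$concordance, 1)
  far <- cosegregation_rate(pop, "chr4", 1e6)
  expect_lt(far$concordance, 1)
  expect_error(cosegregation_rate(pop, "chr4", 123), "not found")
})
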