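# Independent oracles used across tests. These re-derive expectations by a
# different route than the package implementation.

# Standard genetic code, keyed in by hand from the canonical 16x4 table.
HAND_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

# Exact null distribution of the per-site delta SNP-index, by closed-form
# enumeration: the pooled allele count of n F2 plants is Binomial(2n, 1/2)
# (each plant contributes two independent alleles), and the alternate read
# count given the pool frequency is Binomial(depth, f). Independent of the
# package's multinomial + binomial sampling route.
enumerate_null_index <- function(bulk_size, depth) {
  k <- 0:(2 * bulk_size)
  pf <- dbinom(k, 2 * bulk_size, 0.5)
  f <- k / (2 * bulk_size)
  a <- 0:depth
  p <- vapply(a, function(ai) sum(pf * dbinom(ai, depth, f)), numeric(1))
  data.frame(index = a / depth, prob = p)
}

enumerate_null_delta <- function(bulk_size, depth) {
  ix <- enumerate_null_index(bulk_size, depth)
  d <- outer(ix$index, ix$index, `-`)
  p <- outer(ix$prob, ix$prob)
  agg <- tapply(as.vector(p), round(as.vector(d), 10), sum)
  data.frame(delta = as.numeric(names(agg)), prob = as.vector(agg))
}

# Quantile of |delta| from an exact distribution.
enumerated_abs_quantile <- function(dist, level) {
  a <- tapply(dist$prob, abs(dist$delta), sum)
  v <- as.numeric(names(a))
  o <- order(v)
  cdf <- cumsum(a[o])
  v[o][which(cdf >= level)[1]]
}

# Toy single-chromosome reference with deterministic sequence content.
toy_reference <- function(len = 400, chrom = "chrT", seed = 42) {
  set.seed(seed)
  setNames(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = ""), chrom)
}

# Build a one-gene model tibble.
toy_gene <- function(gene_id = "g1", chrom = "chrT", strand = "+",
                     starts, ends, phase = 0L) {
  tibble::tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                 start = starts, end = ends, phase = phase)
}

# Hand-rolled F2 population object for unit tests (bypasses the simulator).
manual_population <- function(geno, markers, phenotype,
                              config = f2_sim_config(n_individuals = nrow(geno),
                                                     bulk_size = 1, seed = 1)) {
  structure(list(genotypes = geno, markers = markers, phenotype = phenotype,
                 config = config),
            class = "f2_population")
}
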