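# Shared fixtures, built in code at test time.

# Small, fast simulation world for unit tests.
tiny_config <- function(...) {
  sim_config(n_genes = 60, n_spikeins = 8, seed = 42, ...)
}

# Hand-built stranded coverage: one chromosome, constant or supplied values.
make_coverage <- function(plus, minus = plus, bin_size = 10,
                          chrom = "chrI") {
  len <- length(plus) * bin_size
  stranded_coverage(
    stats::setNames(list(list(plus = plus, minus = minus)), chrom),
    bin_size, stats::setNames(len, chrom))
}

# Hand-built two-gene annotation on one chromosome.
make_annotation <- function(starts, ends, strands, chrom = "chrI",
                            chrom_length = max(ends) + 200,
                            is_spikein = FALSE) {
  n <- length(starts)
  genes <- data.frame(
    gene_id = sprintf("g%02d", seq_len(n)),
    chrom = chrom, start = starts, end = ends, strand = strands,
    polyA_site = ifelse(strands == "+", ends, starts),
    is_spikein = rep_len(is_spikein, n),
    stringsAsFactors = FALSE)
  termread:::new_genome_annotation(
    genes, stats::setNames(chrom_length, chrom))
}

# Minimal count table with spike-ins appended.
make_count_table <- function(counts, n_spike = 2,
                             conditions = c("minus_auxin", "plus_auxin")) {
  counts <- as.matrix(counts)
  n_rep <- ncol(counts) / length(conditions)
  spike <- matrix(rep(100, n_spike * ncol(counts)), nrow = n_spike)
  all_counts <- rbind(counts, spike)
  gi <- data.frame(
    gene_id = c(sprintf("g%03d", seq_len(nrow(counts))),
                sprintf("spike%02d", seq_len(n_spike))),
    chrom = "chrI", strand = "+",
    is_spikein = c(rep(FALSE, nrow(counts)), rep(TRUE, n_spike)),
    stringsAsFactors = FALSE)
  samples <- data.frame(
    sample = paste0(rep(conditions, each = n_rep), "_rep",
                    seq_len(n_rep)),
    condition = rep(conditions, each = n_rep),
    stringsAsFactors = FALSE)
  count_table(all_counts, gi, samples)
}

# Ground-truth strand-pair set: own change = log2 e' ratio (pure
# interference effect), opposite change from noise-free expected coverage.
ground_truth_pairs <- function(cfg) {
  ann <- generate_genome(cfg)
  sm <- simulate_expected_coverage(ann, cfg, "minus_auxin")
  sp <- simulate_expected_coverage(ann, cfg, "plus_auxin")
  lfc <- log2(sp$truth$e_prime / sm$truth$e_prime)
  de_gt <- data.frame(gene_id = sp$truth$gene_id,
                      log2fc = as.numeric(lfc),
                      stringsAsFactors = FALSE)
  opposite_strand_pairs(de_gt, ann,
                        list(minus_auxin = sm$coverage,
                             plus_auxin = sp$coverage))
}
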