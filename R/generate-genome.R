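#' Generate a synthetic genome annotation
#'
#' Lays out `n_genes` non-overlapping genes along one main chromosome
#' (`chrI`) plus `n_spikeins` condition-invariant genes on a dedicated
#' `spikes` chromosome. Strands are assigned by a two-state Markov chain so
#' that realized junction fractions approach the `strand_scheme` targets.
#' Every junction between adjacent genes is labeled `codirectional` (same
#' strand), `convergent` (3' ends facing) or `divergent` (5' ends facing).
#'
#' Coordinates are 0-based half-open; the poly(A) site sits at the 3'
#' boundary of the gene (interval end on the plus strand, interval start on
#' the minus strand).
#'
#' @param config a [sim_config()].
#' @return an object of class `genome_annotation`: a list with `genes`
#'   (data.frame: gene_id, chrom, start, end, strand, polyA_site,
#'   is_spikein), `junctions` (data.frame: chrom, left_gene, right_gene,
#'   type), and `chrom_lengths` (named integer vector).
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "genome"), {
    main <- layout_chromosome(
      n = config$n_genes, chrom = "chrI",
      chrom_length = config$chrom_length,
      len_range = config$gene_length_range,
      gap_mean = config$intergap_mean, gap_sd = config$intergap_sd,
      p_same = config$strand_scheme[["codirectional"]],
      id_prefix = "gene")
    spikes <- layout_chromosome(
      n = config$n_spikeins, chrom = "spikes",
      chrom_length = NA_integer_,
      len_range = config$gene_length_range,
      gap_mean = config$intergap_mean, gap_sd = config$intergap_sd,
      p_same = 1,  # all plus strand; orientation is irrelevant for spike-ins
      id_prefix = "spike")
    genes <- rbind(cbind(main, is_spikein = FALSE),
                   cbind(spikes, is_spikein = TRUE))
    rownames(genes) <- NULL
    chrom_lengths <- c(
      chrI = config$chrom_length,
      spikes = as.integer(max(spikes$end) + config$intergap_mean))
    new_genome_annotation(genes, chrom_lengths)
  })
}

# Sequential placement of genes with truncated-normal gaps and
# Markov-chain strand assignment.
layout_chromosome <- function(n, chrom, chrom_length, len_range,
                              gap_mean, gap_sd, p_same, id_prefix) {
  lens <- as.integer(round(stats::runif(n, len_range[1], len_range[2])))
  gaps <- as.integer(pmax(50, round(stats::rnorm(n, gap_mean, gap_sd))))
  starts <- cumsum(gaps) + cumsum(c(0L, lens[-n]))
  ends <- starts + lens
  if (!is.na(chrom_length)) {
    if (sum(lens) > chrom_length)
      stop("infeasible packing: total gene length (", sum(lens),
           " bp) exceeds chrom_length (", chrom_length, " bp)")
    if (max(ends) > chrom_length)
      stop("infeasible packing: layout ends at ", max(ends),
           " bp but chrom_length is ", chrom_length,
           " bp; increase chrom_length or reduce gaps/genes")
  }
  strand <- character(n)
  strand[1] <- sample(c("+", "-"), 1)
  if (n > 1) {
    same <- stats::runif(n - 1) < p_same
    for (i in 2:n) {
      strand[i] <- if (same[i - 1]) strand[i - 1] else
        setdiff(c("+", "-"), strand[i - 1])
    }
  }
  data.frame(
    gene_id = sprintf("%s%04d", id_prefix, seq_len(n)),
    chrom = chrom,
    start = starts,
    end = ends,
    strand = strand,
    polyA_site = ifelse(strand == "+", ends, starts),
    stringsAsFactors = FALSE)
}

new_genome_annotation <- function(genes, chrom_lengths) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand",
                  "polyA_site") %in% names(genes)))
  if (is.null(genes$is_spikein)) genes$is_spikein <- FALSE
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  if (any(genes$start >= genes$end))
    stop("gene intervals must satisfy start < end")
  if (any(genes$polyA_site < genes$start | genes$polyA_site > genes$end))
    stop("polyA_site must lie within [start, end]")
  bad <- unlist(lapply(split(genes, genes$chrom), function(g) {
    ss <- split(g, g$strand)
    unlist(lapply(ss, function(h) {
      if (nrow(h) < 2) return(FALSE)
      h <- h[order(h$start), ]
      any(h$start[-1] < h$end[-nrow(h)])
    }))
  }))
  if (any(bad)) stop("gene intervals overlap on the same strand")
  ann <- list(genes = genes,
              junctions = compute_junctions(genes),
              chrom_lengths = chrom_lengths)
  class(ann) <- "genome_annotation"
  ann
}

# Junction type between two adjacent genes (left before right in genome
# coordinates): same strand -> codirectional; (+,-) -> 3' ends face each
# other (convergent); (-,+) -> 5' ends face each other (divergent).
junction_type <- function(left_strand, right_strand) {
  ifelse(left_strand == right_strand, "codirectional",
         ifelse(left_strand == "+", "convergent", "divergent"))
}

compute_junctions <- function(genes) {
  out <- lapply(split(genes, genes$chrom), function(g) {
    g <- g[order(g$start), ]
    if (nrow(g) < 2) return(NULL)
    i <- seq_len(nrow(g) - 1)
    data.frame(chrom = g$chrom[i],
               left_gene = g$gene_id[i],
               right_gene = g$gene_id[i + 1],
               type = junction_type(g$strand[i], g$strand[i + 1]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Realized junction-type fractions of an annotation
#'
#' @param annotation a `genome_annotation`.
#' @param chrom restrict to one chromosome (default: the non-spike genome).
#' @return named fractions over codirectional/convergent/divergent.
#' @export
junction_fractions <- function(annotation, chrom = "chrI") {
  j <- annotation$junctions
  j <- j[j$chrom %in% chrom, ]
  tab <- table(factor(j$type, levels = c("codirectional", "convergent",
                                         "divergent")))
  as.vector(tab) / sum(tab) -> fr
  names(fr) <- names(tab)
  fr
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes on",
      length(x$chrom_lengths), "chromosome(s) (",
      sum(x$genes$is_spikein), "spike-ins )\n")
  fr <- junction_fractions(x)
  cat("  junctions:", paste(names(fr), round(fr, 3), sep = "=",
                            collapse = ", "), "\n")
  invisible(x)
}
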