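# Readers/writers for GFF3/BED6 annotations, strand-split bedGraph tracks,
# and gene x sample count tables. All on-disk coordinates follow the format
# conventions (GFF3 1-based closed, BED/bedGraph 0-based half-open); the
# in-memory representation is 0-based half-open.

#' Write a genome annotation to GFF3 or BED6
#'
#' GFF3 carries the poly(A) site and spike-in flag as attributes
#' (`polyA_site` stored as a 0-based coordinate so that write/read
#' round-trips are exact); BED6 encodes only the interval, name, and
#' strand.
#'
#' @param annotation a `genome_annotation`.
#' @param path output file path.
#' @param format `"gff3"` or `"bed"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path,
                             format = guess_annotation_format(path)) {
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- annotation$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand)
  GenomeInfoDb::seqlengths(gr) <-
    annotation$chrom_lengths[GenomeInfoDb::seqlevels(gr)]
  if (format == "gff3") {
    gr$type <- "gene"
    gr$ID <- g$gene_id
    gr$polyA_site <- as.integer(g$polyA_site)
    gr$is_spikein <- tolower(as.character(g$is_spikein))
    rtracklayer::export(gr, path, format = "gff3")
  } else if (format == "bed") {
    gr$name <- g$gene_id
    gr$score <- 0L
    rtracklayer::export(gr, path, format = "bed")
  } else stop("unsupported annotation format: ", format)
  invisible(path)
}

guess_annotation_format <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
  else if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
  else stop("cannot guess annotation format from: ", path)
}

#' Read a genome annotation from GFF3 or BED6
#'
#' Neighbor (junction) relations are recomputed from gene order. For BED
#' input, which has no attribute column, the poly(A) site is placed at the
#' 3' boundary of each interval and spike-ins are recognized by a `spike`
#' name prefix or the `spikes` chromosome.
#'
#' @param path input file path.
#' @param format `"gff3"` or `"bed"` (default from the file extension).
#' @return a `genome_annotation`.
#' @export
read_annotation <- function(path, format = guess_annotation_format(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = format),
                 error = function(e)
                   stop("malformed ", format, " file '", path, "': ",
                        conditionMessage(e)))
  if (length(gr) == 0) stop("no records in ", path)
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("all records must be stranded (+/-) in ", path)
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  if (format == "gff3") {
    id <- gr$ID
    pA <- as.integer(gr$polyA_site)
    if (any(is.na(pA)))
      stop("GFF3 gene records must carry a polyA_site attribute: ", path)
    spike <- !is.na(gr$is_spikein) & gr$is_spikein == "true"
  } else {
    id <- gr$name
    pA <- ifelse(strand == "+", end0, start0)
    spike <- grepl("^spike", id) |
      as.character(GenomeInfoDb::seqnames(gr)) == "spikes"
  }
  genes <- data.frame(gene_id = id,
                      chrom = as.character(GenomeInfoDb::seqnames(gr)),
                      start = start0, end = end0, strand = strand,
                      polyA_site = pA, is_spikein = spike,
                      stringsAsFactors = FALSE)
  sl <- GenomeInfoDb::seqlengths(gr)
  if (any(is.na(sl))) {
    obs <- tapply(genes$end, genes$chrom, max)
    sl[is.na(sl)] <- obs[names(sl)[is.na(sl)]]
  }
  new_genome_annotation(genes, sl)
}

#' Write stranded coverage as a strand-split bedGraph pair
#'
#' Produces `<prefix>.plus.bedgraph` and `<prefix>.minus.bedgraph`.
#' Adjacent equal-valued bins are collapsed into one interval and
#' zero-valued bins are omitted.
#'
#' @param coverage a `stranded_coverage`.
#' @param prefix output path prefix.
#' @return named character vector of the two file paths, invisibly.
#' @export
write_bedgraph <- function(coverage, prefix) {
  stopifnot(inherits(coverage, "stranded_coverage"))
  bs <- coverage$bin_size
  paths <- c(plus = paste0(prefix, ".plus.bedgraph"),
             minus = paste0(prefix, ".minus.bedgraph"))
  for (strand in c("plus", "minus")) {
    pieces <- lapply(names(coverage$tracks), function(chrom) {
      v <- coverage$tracks[[chrom]][[strand]]
      if (!length(v)) return(NULL)
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts0 <- c(0L, ends[-length(ends)]) * bs
      ends0 <- pmin(ends * bs, coverage$chrom_lengths[[chrom]])
      keep <- r$values != 0
      if (!any(keep)) return(NULL)
      data.frame(chrom = chrom, start0 = starts0[keep],
                 end0 = ends0[keep], score = r$values[keep])
    })
    df <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
    gr <- if (is.null(df)) GenomicRanges::GRanges(score = numeric(0))
    else GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(start = df$start0 + 1L, end = df$end0),
      score = df$score)
    rtracklayer::export(gr, paths[[strand]], format = "bedGraph")
  }
  invisible(paths)
}

validate_bedgraph_gr <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = BiocGenerics::start(gr),
                   end = BiocGenerics::end(gr))
  for (chrom in unique(df$chrom)) {
    d <- df[df$chrom == chrom, ]
    if (is.unsorted(d$start))
      stop("bedGraph intervals are not sorted within ", chrom,
           " in ", path)
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)] + 1))
      stop("overlapping bedGraph intervals within ", chrom, " in ", path)
  }
  invisible(gr)
}

#' Read a strand-split bedGraph pair into stranded coverage
#'
#' Intervals must be sorted and non-overlapping within each file. Values
#' are rasterized onto a regular bin grid by bin midpoint; positions not
#' covered by any interval are 0.
#'
#' @param plus_path,minus_path bedGraph files for the two strands.
#' @param bin_size bin width (bp) of the output grid.
#' @param chrom_lengths optional named lengths; defaults to the largest
#'   interval end seen per chromosome.
#' @param normalization tag for the result (`"raw"` or `"CPM"`).
#' @return a `stranded_coverage`.
#' @export
read_bedgraph <- function(plus_path, minus_path, bin_size = 10,
                          chrom_lengths = NULL, normalization = "raw") {
  grs <- lapply(c(plus = plus_path, minus = minus_path), function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    gr <- tryCatch(rtracklayer::import(p, format = "bedGraph"),
                   error = function(e)
                     stop("malformed bedGraph file '", p, "': ",
                          conditionMessage(e)))
    validate_bedgraph_gr(gr, p)
  })
  chroms <- unique(unlist(lapply(grs, function(g)
    as.character(GenomeInfoDb::seqnames(g)))))
  if (!length(chroms)) stop("no intervals in bedGraph input")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(chrom) {
      m <- vapply(grs, function(g) {
        g <- g[as.character(GenomeInfoDb::seqnames(g)) == chrom]
        if (length(g)) max(BiocGenerics::end(g)) else 0L
      }, numeric(1))
      as.integer(max(m))
    }, integer(1))
  }
  tracks <- lapply(chroms, function(chrom) {
    nb <- n_bins_for(chrom_lengths[[chrom]], bin_size)
    mid1 <- (seq_len(nb) - 1L) * bin_size + as.integer(ceiling(bin_size / 2))
    mids <- GenomicRanges::GRanges(chrom, IRanges::IRanges(mid1, width = 1))
    lapply(grs, function(g) {
      v <- numeric(nb)
      hit <- GenomicRanges::findOverlaps(mids, g, select = "first")
      cov <- !is.na(hit)
      v[cov] <- g$score[hit[cov]]
      v
    }) -> by_strand
    list(plus = by_strand$plus, minus = by_strand$minus)
  })
  names(tracks) <- chroms
  stranded_coverage(tracks, bin_size, chrom_lengths, normalization)
}

#' Write a count table to TSV
#'
#' Columns: gene_id, chrom, strand, is_spikein, then one column per sample.
#' The condition is encoded in the sample name (`<condition>_rep<i>`).
#'
#' @param table a `count_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  gi <- table$gene_info
  df <- cbind(gi[, c("gene_id", "chrom", "strand", "is_spikein")],
              as.data.frame(table$counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a count table from TSV
#'
#' @param path TSV written by [write_counts()] (or of the same layout).
#' @return a `count_table`; conditions are parsed from sample names.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  meta_cols <- c("gene_id", "chrom", "strand", "is_spikein")
  if (!all(meta_cols %in% names(df)))
    stop("count TSV must have columns ", paste(meta_cols, collapse = ", "),
         ": ", path)
  sample_cols <- setdiff(names(df), meta_cols)
  if (!length(sample_cols)) stop("no sample columns in ", path)
  counts <- as.matrix(df[, sample_cols, drop = FALSE])
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be nonnegative numbers: ", path)
  cond <- sub("_rep[0-9]+$", "", sample_cols)
  count_table(counts, df[, meta_cols],
              data.frame(sample = sample_cols, condition = cond,
                         stringsAsFactors = FALSE))
}

#' Smooth and CPM-scale a coverage track
#'
#' Applies a centered running mean of width `smooth_length` (deeptools-style
#' `--smoothLength`; edge windows are truncated and renormalized, so a
#' constant track is unchanged), optionally rebinning first, then rescales
#' to counts per million so that the summed signal over all bins of both
#' strands is exactly 1e6.
#'
#' @param coverage a raw `stranded_coverage`.
#' @param bin_size output bin width (a multiple of the input bin width).
#' @param smooth_length smoothing window (bp), >= `bin_size`.
#' @param normalize apply CPM scaling (default TRUE).
#' @return a `stranded_coverage` tagged `"CPM"` (or `"raw"` if
#'   `normalize = FALSE`).
#' @export
smooth_and_bin <- function(coverage, bin_size = 10, smooth_length = 20,
                           normalize = TRUE) {
  stopifnot(inherits(coverage, "stranded_coverage"))
  if (smooth_length < bin_size)
    stop("smooth_length must be >= bin_size")
  if (!sum(vapply(coverage$tracks, function(t) length(t$plus),
                  integer(1))))
    stop("empty coverage track")
  if (bin_size %% coverage$bin_size != 0)
    stop("bin_size must be a multiple of the input bin size (",
         coverage$bin_size, ")")
  agg <- as.integer(bin_size / coverage$bin_size)
  w <- max(1L, as.integer(round(smooth_length / bin_size)))
  tracks <- lapply(coverage$tracks, function(tr) {
    lapply(tr, function(v) {
      if (agg > 1) {
        n_out <- ceiling(length(v) / agg)
        pad <- n_out * agg - length(v)
        v <- colSums(matrix(c(v, numeric(pad)), nrow = agg)) / agg
      }
      running_mean(v, w)
    })
  })
  out <- stranded_coverage(tracks, bin_size, coverage$chrom_lengths)
  if (normalize) cpm_normalize(out) else out
}

# Centered running mean of width w bins; window is [i - floor((w-1)/2),
# i + ceiling((w-1)/2)] truncated at the track ends and renormalized.
running_mean <- function(v, w) {
  if (w <= 1 || length(v) < 2) return(v)
  n <- length(v)
  i <- seq_len(n)
  lo <- pmax(1L, i - floor((w - 1) / 2))
  hi <- pmin(n, i + ceiling((w - 1) / 2))
  cs <- cumsum(c(0, v))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Scale a coverage track to counts per million
#'
#' CPM is computed jointly over both strands of all chromosomes:
#' `value * 1e6 / total signal`.
#'
#' @param coverage a `stranded_coverage`.
#' @return the CPM-tagged `stranded_coverage`.
#' @export
cpm_normalize <- function(coverage) {
  stopifnot(inherits(coverage, "stranded_coverage"))
  total <- coverage_total(coverage)
  if (total <= 0) stop("cannot CPM-normalize a track with zero total signal")
  tracks <- lapply(coverage$tracks, function(tr)
    lapply(tr, function(v) v * 1e6 / total))
  stranded_coverage(tracks, coverage$bin_size, coverage$chrom_lengths,
                    normalization = "CPM")
}
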