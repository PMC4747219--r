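## Promoter windows, ChIP-peak overlap statistics and per-gene CNV summaries.
##
## All interval data frames are 0-based half-open (BED convention); they
## are converted to 1-based closed IRanges only at the overlap boundary.

as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Strand-aware proximal promoter window
#'
#' The proximal promoter spans `upstream` bp before and `downstream` bp
#' after the strand-aware transcription start site (default -450/+50 bp):
#' plus-strand genes use the interval start as TSS with window
#' `[start - upstream, start + downstream)`; minus-strand genes mirror it
#' around the interval end.  Windows are clipped at coordinate 0.
#'
#' @param genes Data frame with columns chrom, start, end, strand and
#'   (optionally) gene_id; 0-based half-open.
#' @param upstream,downstream Window extents in bp.
#' @return Data frame of windows: gene_id, chrom, start, end, strand,
#'   tss_pos.
#' @export
promoter_window <- function(genes, upstream = 450L, downstream = 50L) {
  if (any(genes$start >= genes$end)) stop("interval start must be < end", call. = FALSE)
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$start, genes$end)
  w_start <- ifelse(plus, tss - upstream, tss - downstream)
  w_end <- ifelse(plus, tss + downstream, tss + upstream)
  w_start <- pmax(w_start, 0L)
  data.frame(
    gene_id = if ("gene_id" %in% names(genes)) genes$gene_id
              else if ("name" %in% names(genes)) genes$name
              else paste0("gene", seq_len(nrow(genes))),
    chrom = genes$chrom, start = as.integer(w_start), end = as.integer(w_end),
    strand = genes$strand, tss_pos = as.integer(tss),
    stringsAsFactors = FALSE)
}

overlaps_any0 <- function(query, subject) {
  IRanges::overlapsAny(as_granges0(query), as_granges0(subject))
}

#' Higher-confidence peaks reproduced across replicates
#'
#' Keeps the first replicate's intervals that overlap (>= 1 bp) at least
#' one interval in every other replicate, reported on the first
#' replicate's coordinates.
#'
#' @param replicates List of peak data frames (chrom, start, end).
#' @return Subset of the first replicate.
#' @export
consensus_peaks <- function(replicates) {
  if (length(replicates) < 1L) stop("no replicates", call. = FALSE)
  first <- replicates[[1L]]
  if (length(replicates) == 1L) return(first)
  keep <- rep(TRUE, nrow(first))
  for (r in replicates[-1L]) keep <- keep & overlaps_any0(first, r)
  first[keep, , drop = FALSE]
}

#' Compare ChIP-peak overlap frequencies of two promoter sets
#'
#' A promoter "hits" when it overlaps at least one peak by at least 1 bp
#' (strand ignored; peaks are unstranded).  The hit/miss counts of the two
#' promoter sets form a 2x2 table tested with a two-sided Fisher's exact
#' test; the reported odds ratio is the sample odds ratio.
#'
#' Divergent gene pairs may share one bidirectional promoter.  When a
#' divergent pair's two windows overlap each other and the same peak, the
#' unique-counting convention scores that occurrence once; with
#' `doubling = TRUE` it is counted twice, because a factor bound at a
#' bidirectional promoter can drive transcription in both directions.
#'
#' @param promotersA,promotersB Promoter window data frames
#'   ([promoter_window()] output, with gene_id).
#' @param peaks Peak intervals (chrom, start, end).
#' @param divergent_pairs_in_A Optional data frame with gene_a/gene_b
#'   columns naming divergent pairs whose genes sit in `promotersA`.
#' @param doubling Apply the bidirectional-promoter doubling rule.
#' @return List with `table` (2x2: hit/miss x A/B), `odds_ratio`, `p`.
#' @export
cbr_overlap_test <- function(promotersA, promotersB, peaks,
                             divergent_pairs_in_A = NULL, doubling = FALSE) {
  if (nrow(promotersA) < 1L || nrow(promotersB) < 1L)
    stop("promoter sets must be non-empty", call. = FALSE)
  hitA <- if (nrow(peaks)) overlaps_any0(promotersA, peaks) else rep(FALSE, nrow(promotersA))
  hitB <- if (nrow(peaks)) overlaps_any0(promotersB, peaks) else rep(FALSE, nrow(promotersB))
  hitsA <- sum(hitA)
  if (!is.null(divergent_pairs_in_A) && nrow(divergent_pairs_in_A) && nrow(peaks)) {
    grA <- as_granges0(promotersA)
    grP <- as_granges0(peaks)
    ov <- GenomicRanges::findOverlaps(grA, grP)
    peaks_of <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
    for (i in seq_len(nrow(divergent_pairs_in_A))) {
      ia <- which(promotersA$gene_id == divergent_pairs_in_A$gene_a[i])
      ib <- which(promotersA$gene_id == divergent_pairs_in_A$gene_b[i])
      if (length(ia) != 1L || length(ib) != 1L) next
      windows_touch <- promotersA$chrom[ia] == promotersA$chrom[ib] &&
        promotersA$start[ia] < promotersA$end[ib] &&
        promotersA$start[ib] < promotersA$end[ia]
      if (!windows_touch) next
      shared_peak <- length(intersect(peaks_of[[as.character(ia)]],
                                      peaks_of[[as.character(ib)]])) > 0L
      if (shared_peak && !doubling) hitsA <- hitsA - 1L
    }
  }
  tab <- matrix(c(hitsA, nrow(promotersA) - sum(hitA),
                  sum(hitB), nrow(promotersB) - sum(hitB)),
                nrow = 2L,
                dimnames = list(c("hit", "miss"), c("setA", "setB")))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[2, 1] * tab[1, 2])
  p <- if (sum(tab[1, ]) == 0) 1 else fisher.test(tab)$p.value
  list(table = tab, odds_ratio = unname(or), p = unname(p))
}

#' Per-gene copy-number value from SNP-level CNV data
#'
#' SNPs assigned to a gene are those inside its interval plus the single
#' nearest SNP strictly upstream and the single nearest strictly
#' downstream of the interval (when they exist); the gene's value is the
#' arithmetic mean of the assigned SNP values.
#'
#' @param gene List or one-row data frame with start, end and (optionally)
#'   chrom, gene_id; 0-based half-open.
#' @param snps Data frame with columns pos, value and (optionally) chrom.
#' @return List with gene_id, mean_cnv, n_snps.
#' @export
cnv_gene_value <- function(gene, snps) {
  if ("chrom" %in% names(snps) && !is.null(gene$chrom))
    snps <- snps[snps$chrom == gene$chrom, , drop = FALSE]
  if (nrow(snps) < 1L)
    stop("no SNPs on the gene's chromosome", call. = FALSE)
  inside <- snps$pos >= gene$start & snps$pos < gene$end
  up <- snps$pos < gene$start
  down <- snps$pos >= gene$end
  vals <- snps$value[inside]
  if (any(up)) vals <- c(vals, snps$value[up][which.max(snps$pos[up])])
  if (any(down)) vals <- c(vals, snps$value[down][which.min(snps$pos[down])])
  list(gene_id = if (!is.null(gene$gene_id)) gene$gene_id else NA_character_,
       mean_cnv = mean(vals), n_snps = length(vals))
}

#' Wilcoxon matched-pairs test of two CNV value sets
#'
#' Signed-rank test on the paired differences; zero differences are
#' dropped (Wilcoxon's convention), the distribution is exact for up to 25
#' non-zero tie-free differences and the normal approximation is used
#' otherwise.  With no non-zero differences the sets are identical and
#' p = 1.
#'
#' @param valuesA,valuesB Matched numeric vectors (>= 6 pairs).
#' @return List with the signed-rank statistic `W` and two-sided `p`.
#' @export
cnv_matched_test <- function(valuesA, valuesB) {
  if (length(valuesA) != length(valuesB))
    stop("matched value sets must have equal length", call. = FALSE)
  if (length(valuesA) < 6L) stop("need at least 6 matched pairs", call. = FALSE)
  d <- valuesA - valuesB
  d <- d[d != 0]
  if (!length(d)) return(list(W = 0, p = 1))
  exact <- length(d) <= 25L && !anyDuplicated(abs(d))
  wt <- suppressWarnings(wilcox.test(d, mu = 0, exact = exact, correct = !exact))
  list(W = unname(wt$statistic), p = unname(wt$p.value))
}
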