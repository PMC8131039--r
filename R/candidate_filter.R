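# Candidate-gene exclusion over QTL intervals, variant impact annotations,
# expression and DEG membership.

#' Assemble gene records from raw fixture tables
#'
#' Derives the `expressed` flag (maximum expression above `floor`) and
#' `is_deg` flag (membership in the DEG id list) for each gene span.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param expression numeric matrix (genes x samples) with gene ids as row
#'   names, or `NULL` to mark every gene expressed.
#' @param degs character vector of DEG gene ids.
#' @param floor expression level at or below which a gene counts as not
#'   detectably expressed.
#' @return `genes` with logical `expressed` and `is_deg` columns.
#' @export
build_gene_records <- function(genes, expression = NULL, degs = character(),
                               floor = 0) {
  out <- genes[c("gene_id", "chrom", "start", "end")]
  out$expressed <- if (is.null(expression)) TRUE else {
    mx <- apply(expression, 1, max)
    unname(mx[out$gene_id] > floor)
  }
  out$is_deg <- out$gene_id %in% degs
  out
}

# half-open interval overlap of one span with any interval of a table
overlaps_any <- function(chrom, start, end, intervals) {
  same <- intervals$chrom == chrom
  any(same & intervals$start < end & start < intervals$end)
}

#' Filter candidate genes within QTL intervals
#'
#' A gene survives iff it (R1) overlaps at least one QTL interval by >= 1 bp;
#' (R2) carries at least one variant that disrupts a promoter cis-element or
#' a protein functional domain; (R3) is detectably expressed; and (R4) is
#' not a gene whose impactful variants all sit in the promoter while the
#' gene is absent from the DEG list. The audit trail records, for each
#' excluded gene, the first rule (in R1..R4 order) that removed it; because
#' the rules are conjunctive the surviving set does not depend on this
#' order.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `expressed`, `is_deg` (see [build_gene_records()]).
#' @param variants data.frame with `gene_id`, `region`
#'   (`promoter`/`CDS_domain`/`CDS_other`/`other`), `disrupts_cis_element`,
#'   `disrupts_domain` (see [read_minimal_vcf()]).
#' @param qtls interval data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [read_bed()].
#' @return list with `kept` (surviving gene ids) and `audit` (data.frame
#'   `gene_id`, `kept`, `excluded_by`).
#' @export
filter_candidates <- function(genes, variants, qtls) {
  stopifnot(all(c("gene_id", "chrom", "start", "end",
                  "expressed", "is_deg") %in% names(genes)))
  audit <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    v <- variants[variants$gene_id == g$gene_id, , drop = FALSE]
    impactful <- v[v$disrupts_cis_element | v$disrupts_domain, , drop = FALSE]
    rule <- NA_character_
    if (!overlaps_any(g$chrom, g$start, g$end, qtls)) {
      rule <- "R1_outside_qtl"
    } else if (nrow(impactful) == 0L) {
      rule <- "R2_no_impactful_variant"
    } else if (!g$expressed) {
      rule <- "R3_not_expressed"
    } else if (all(impactful$region == "promoter") && !g$is_deg) {
      rule <- "R4_promoter_only_not_deg"
    }
    data.frame(gene_id = g$gene_id, kept = is.na(rule),
               excluded_by = rule, stringsAsFactors = FALSE)
  })
  audit <- do.call(rbind, audit)
  list(kept = audit$gene_id[audit$kept], audit = audit)
}
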